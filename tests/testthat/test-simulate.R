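small_cfg <- function(seed = 31, ...) {
  sim_config(n_snps_per_chrom = 400, n_chroms = 3, n_admixed = 6,
             n_source1 = 5, n_source2 = 5, n_outgroup = 5, seed = seed, ...)
}

test_that("generators are deterministic under a fixed seed", {
  cfg <- small_cfg()
  f1 <- simulate_source_frequencies(cfg)
  f2 <- simulate_source_frequencies(cfg)
  expect_identical(f1$freq, f2$freq)
  t1 <- simulate_ancestry_tracts(cfg)
  t2 <- simulate_ancestry_tracts(cfg)
  expect_identical(t1, t2)
  c1 <- simulate_cohort(cfg)
  c2 <- simulate_cohort(cfg)
  expect_identical(c1$ds$calls, c2$ds$calls)
  expect_false(identical(
    simulate_cohort(small_cfg(seed = 32))$ds$calls, c1$ds$calls))
})

test_that("Balding-Nichols drift has the no-drift limit and the right FST", {
  set.seed(100)
  q <- runif(1e4, 0.05, 0.95)
  p <- drift_frequencies(q, 1e-6)
  expect_lt(max(abs(p - q)), 0.01)
  expect_error(drift_frequencies(q, 0), "F must lie")
  expect_error(drift_frequencies(q, 1), "F must lie")

  # ratio-of-sums Hudson FST between two pops drifted F from one ancestor:
  # E num = 2 F q(1-q), E den = 2 q(1-q), so the estimator targets F
  F_true <- 0.2
  q <- runif(5e4, 0.05, 0.95)
  p1 <- drift_frequencies(q, F_true)
  p2 <- drift_frequencies(q, F_true)
  num <- sum((p1 - p2)^2)
  den <- sum(p1 * (1 - p2) + p2 * (1 - p1))
  fst_hat <- 1 - (sum(p1 * (1 - p1) + p2 * (1 - p2))) / den
  expect_lt(abs(fst_hat - F_true) / F_true, 0.2)
  expect_lt(abs(num / den - F_true) / F_true, 0.2)
})

test_that("tract process has the Markov switch rate and stationary fraction", {
  cfg <- sim_config(n_snps_per_chrom = 10, n_chroms = 1, chrom_length = 1,
                    n_admixed = 500, n_source1 = 1, n_source2 = 1,
                    n_outgroup = 1, admixture_generations = 30,
                    alpha_autosome = 0.4, seed = 55)
  tr <- simulate_ancestry_tracts(cfg)
  n_copies <- nrow(dplyr::distinct(tr, sample, copy))
  expect_equal(n_copies, 1000)
  # tract boundaries are true ancestry switches (adjacent tracts merged)
  switches <- nrow(tr) - n_copies
  lambda <- 2 * 0.4 * 0.6 * 30 * n_copies     # 2 alpha (1-alpha) n per Morgan
  expect_lt(abs(switches - lambda), 3 * sqrt(lambda))
  # stationary source2 fraction = alpha
  frac <- sum((tr$end - tr$start)[tr$ancestry == "source2"]) / n_copies
  p_se <- sqrt(0.4 * 0.6 / n_copies)  # conservative binomial-style scale
  expect_lt(abs(frac - 0.4), 3 * sqrt(0.4 * 0.6 * (1 + 2 * 30) / (30 * n_copies)))
  # tracts tile each chromosome copy without overlap
  by_copy <- split(tr, interaction(tr$sample, tr$copy, drop = TRUE))
  lens <- vapply(by_copy, function(d) sum(d$end - d$start), numeric(1))
  expect_true(all(abs(lens - cfg$chrom_length) < 1e-12))
  gaps <- vapply(by_copy, function(d) max(abs(d$start[-1] - d$end[-nrow(d)]), 0),
                 numeric(1))
  expect_true(all(gaps < 1e-12))
})

test_that("alpha = 1 yields a single source2 tract per chromosome copy", {
  cfg <- sim_config(n_snps_per_chrom = 10, n_chroms = 2, n_admixed = 3,
                    n_source1 = 1, n_source2 = 1, n_outgroup = 1,
                    alpha_autosome = 1, alpha_X = 1, seed = 8)
  tr <- simulate_ancestry_tracts(cfg)
  expect_true(all(tr$ancestry == "source2"))
  expect_equal(nrow(tr), 3 * 2 * 2)   # sample x chrom x copy
  expect_true(all(tr$start == 0 & tr$end == cfg$chrom_length))
})

test_that("truth-tract ancestry autocovariance decays as alpha(1-alpha)exp(-nd)", {
  cfg <- sim_config(n_snps_per_chrom = 10, n_chroms = 1, chrom_length = 1,
                    n_admixed = 400, n_source1 = 1, n_source2 = 1,
                    n_outgroup = 1, admixture_generations = 30,
                    alpha_autosome = 0.4, seed = 91)
  tr <- simulate_ancestry_tracts(cfg)
  grid <- seq(0.005, 0.995, by = 0.01)
  by_copy <- split(tr, interaction(tr$sample, tr$copy, drop = TRUE))
  states <- vapply(by_copy, function(d) {
    (d$ancestry == "source2")[findInterval(grid, d$start)]
  }, logical(length(grid)))
  for (d in c(0.02, 0.05, 0.1, 0.2)) {
    lag <- round(d / 0.01)
    i <- seq_len(length(grid) - lag)
    x <- as.vector(states[i, ]); y <- as.vector(states[i + lag, ])
    emp <- mean(x * y) - mean(x) * mean(y)
    theo <- 0.4 * 0.6 * exp(-30 * d)
    # Monte-Carlo scale: ~400*2 copies, heavy within-copy correlation
    expect_lt(abs(emp - theo), 0.015)
  }
})

test_that("cohort genotypes honour missingness, ploidy and sex-symmetric alpha", {
  cfg <- sim_config(n_snps_per_chrom = 800, n_chroms = 4, n_admixed = 10,
                    include_x = TRUE, alpha_autosome = 0.4, alpha_X = 0.4,
                    missing_rate = 0.3, seed = 12)
  coh <- simulate_cohort(cfg)
  calls <- coh$ds$calls
  n_calls <- length(calls)
  miss <- mean(is.na(calls))
  expect_lt(abs(miss - 0.3), 3 * sqrt(0.3 * 0.7 / n_calls))
  expect_true(all(calls %in% c(0L, 2L, NA_integer_)))  # pseudo-haploid

  # with alpha_X = alpha_autosome the mean Papuan-allele dosage of admixed
  # samples agrees between autosomes and X within sampling noise
  tr <- coh$truth$tracts
  fa <- with(tr[tr$chrom != "X", ],
             sum((end - start)[ancestry == "source2"]) / sum(end - start))
  fx <- with(tr[tr$chrom == "X", ],
             sum((end - start)[ancestry == "source2"]) / sum(end - start))
  n_x_copies <- nrow(dplyr::distinct(tr[tr$chrom == "X", ], sample, copy))
  se <- sqrt(0.4 * 0.6 * (1 + 2 * 30) / (30 * n_x_copies))
  expect_lt(abs(fa - fx), 3 * se)
})

test_that("toy calibration curves are linear, offset and monotone", {
  tc <- simulate_toy_calibration_curve(slope = 1, wiggle_amp = 0,
                                       reservoir_offset = 500)
  at <- function(curve, cal) curve$mu[match(cal, curve$cal_bp)]
  expect_equal(at(tc$marine, 1000), 1500)
  expect_equal(at(tc$terrestrial, 1000), 1000)
  expect_equal(tc$terrestrial$cal_bp, seq(0, 6000, by = 5))

  # monotone when the wiggle amplitude is below slope * step scale
  tw <- simulate_toy_calibration_curve(slope = 1, wiggle_amp = 3)
  expect_true(all(diff(tw$terrestrial$mu) > 0))
  expect_error(simulate_toy_calibration_curve(slope = -1), "slope")
})

test_that("simulated outputs round-trip through the on-disk formats", {
  coh <- simulate_cohort(small_cfg())
  dir <- withr::local_tempdir()
  write_sim_outputs(coh, dir, prefix = "demo")
  back <- read_eigenstrat(file.path(dir, "demo"), pseudo_haploid = TRUE)
  expect_equal(unname(back$calls), unname(coh$ds$calls))
  truth <- jsonlite::read_json(file.path(dir, "demo_truth.json"))
  expect_equal(truth$alpha_autosome, coh$truth$alpha_autosome)
  expect_equal(truth$generations, coh$truth$generations)
  tr <- utils::read.table(file.path(dir, "demo_tracts.tsv"), header = TRUE,
                          sep = "\t")
  expect_equal(nrow(tr), nrow(coh$truth$tracts))
})
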