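# Minimal decay_curve with known noiseless values for exact inversion tests.
synthetic_curve <- function(A, n_gen, c0, binsize = 0.002, maxdis = 0.5,
                            n_chroms = 2) {
  n_bins <- ceiling(maxdis / binsize)
  centers <- (seq_len(n_bins) - 0.5) * binsize
  vals <- A * exp(-n_gen * centers) + c0
  den <- matrix(1, n_chroms, n_bins)
  structure(list(
    bins = tibble::tibble(bin_center = centers, value = vals,
                          se = NA_real_, n_pairs = rep(10, n_bins)),
    chrom_num = matrix(rep(vals, each = n_chroms), n_chroms) / n_chroms * 1,
    chrom_den = den / n_chroms, chrom_pairs = den * 10,
    chroms = as.character(seq_len(n_chroms)), binsize = binsize,
    maxdis = maxdis, alpha = 0.4, n_targets = 1
  ), class = "decay_curve")
}

test_that("noiseless exponential bins invert to the exact parameters", {
  cv <- synthetic_curve(A = 0.01, n_gen = 25, c0 = 0)
  fit <- fit_exponential(cv, mindis = 0.005)
  expect_equal(fit$n_generations, 25, tolerance = 1e-3)
  expect_equal(fit$amplitude, 0.01, tolerance = 1e-4)
  expect_equal(fit$affine, 0, tolerance = 1e-6)

  cv2 <- synthetic_curve(A = 0.004, n_gen = 80, c0 = 2e-4)
  fit2 <- fit_exponential(cv2, mindis = 0.005)
  expect_equal(fit2$n_generations, 80, tolerance = 1e-3 * 80)
  expect_equal(fit2$affine, 2e-4, tolerance = 1e-6)
})

test_that("an unadmixed target yields a flat curve", {
  coh <- complete_cohort()
  src <- coh$ds$samples$id[coh$ds$samples$population == "SourceEA"]
  cv <- ancestry_covariance_curve(coh$ds, src, "SourceEA", "SourcePAP",
                                  maxdis = 0.5)
  bins <- dplyr::filter(cv$bins, .data$bin_center >= 0.005,
                        is.finite(.data$value), is.finite(.data$se))
  # essentially all bins within 3 jackknife SE of zero, none wildly off
  frac_in <- mean(abs(bins$value) <= 3 * bins$se)
  expect_gte(frac_in, 0.97)
  expect_error(fit_exponential(cv), "no decay signal")
})

test_that("the curve is the SNP-weighted combination of per-chromosome curves", {
  coh <- complete_cohort()
  adm <- coh$ds$samples$id[coh$ds$samples$population == "Admixed"]
  full <- ancestry_covariance_curve(coh$ds, adm, "SourceEA", "SourcePAP",
                                    maxdis = 0.4, alpha = 0.4)
  chroms <- unique(coh$ds$variants$chrom)[1:3]
  sub <- restrict(coh$ds, variants = coh$ds$variants$chrom %in% chroms)
  part <- ancestry_covariance_curve(sub, adm, "SourceEA", "SourcePAP",
                                    maxdis = 0.4, alpha = 0.4)
  # per-chromosome accumulators of the joint run reproduce the partial run
  ci <- match(chroms, full$chroms)
  num <- colSums(full$chrom_num[ci, , drop = FALSE])
  den <- colSums(full$chrom_den[ci, , drop = FALSE])
  ok <- den > 0
  expect_equal(unname(num[ok] / den[ok]),
               part$bins$value[ok], tolerance = 1e-10)
})

test_that("admixture time is recovered within the jackknife CI", {
  coh <- shared_cohort()
  adm <- coh$ds$samples$id[coh$ds$samples$population == "Admixed"]
  cv <- ancestry_covariance_curve(coh$ds, adm, "SourceEA", "SourcePAP")
  fit <- fit_exponential(cv)
  expect_gt(fit$n_generations, 0)
  expect_true(fit$ci95[["young"]] <= coh$truth$generations &&
                coh$truth$generations <= fit$ci95[["old"]])
  # log-linear slope of the positive early bins approximates -n
  bins <- dplyr::filter(cv$bins, .data$bin_center >= 0.01,
                        .data$bin_center <= 0.1, .data$value > 0)
  sl <- coef(lm(log(bins$value) ~ bins$bin_center))[2]
  expect_lt(abs(-sl - coh$truth$generations), 3 * 3.5 + 10)
})

test_that("amplitude scales with alpha(1-alpha)", {
  fits <- lapply(c(0.1, 0.5), function(alpha) {
    cfg <- sim_config(n_snps_per_chrom = 1200, n_chroms = 8, n_admixed = 10,
                      alpha_autosome = alpha, missing_rate = 0, seed = 620)
    coh <- simulate_cohort(cfg)
    adm <- coh$ds$samples$id[coh$ds$samples$population == "Admixed"]
    fit_exponential(ancestry_covariance_curve(coh$ds, adm, "SourceEA",
                                              "SourcePAP", maxdis = 0.5))
  })
  expect_gt(fits[[2]]$amplitude, fits[[1]]$amplitude)
})

test_that("merging targets preserves the curve and tightens the jackknife", {
  coh <- complete_cohort()
  adm <- coh$ds$samples$id[coh$ds$samples$population == "Admixed"]
  groups <- merge_targets(coh$ds, list(solo = adm[1], all = adm))
  expect_s3_class(groups, "target_groups")
  expect_error(merge_targets(coh$ds, list(bad = character(0))), "empty")
  expect_error(merge_targets(coh$ds, list(bad = "ghost")), "unknown")
  expect_error(merge_targets(coh$ds, list(adm[1])), "named")

  solo <- ancestry_covariance_curve(coh$ds, groups$solo, "SourceEA",
                                    "SourcePAP", maxdis = 0.3, alpha = 0.4)
  solo_direct <- ancestry_covariance_curve(coh$ds, adm[1], "SourceEA",
                                           "SourcePAP", maxdis = 0.3,
                                           alpha = 0.4)
  expect_equal(solo$bins$value, solo_direct$bins$value)

  # duplicating a sample leaves the curve shape intact but shrinks the SE
  dup <- genotype_dataset(
    coh$ds$variants,
    dplyr::bind_rows(coh$ds$samples,
                     dplyr::mutate(coh$ds$samples[match(adm[1], coh$ds$samples$id), ],
                                   id = "ADM_dup")),
    cbind(coh$ds$calls, coh$ds$calls[, match(adm[1], coh$ds$samples$id)]),
    pseudo_haploid = TRUE
  )
  both <- ancestry_covariance_curve(dup, c(adm[1], "ADM_dup"), "SourceEA",
                                    "SourcePAP", maxdis = 0.3, alpha = 0.4)
  expect_equal(both$bins$value, solo$bins$value, tolerance = 1e-10)

  # merging all admixed samples averages over many more individual pairs:
  # the per-bin jackknife noise must drop substantially
  merged <- ancestry_covariance_curve(coh$ds, adm, "SourceEA", "SourcePAP",
                                      maxdis = 0.3, alpha = 0.4)
  expect_lt(mean(merged$bins$se, na.rm = TRUE),
            mean(solo$bins$se, na.rm = TRUE))
})

test_that("chromosome-jackknife CIs achieve near-nominal coverage", {
  cover <- 0
  for (i in 1:100) {
    cfg <- sim_config(n_snps_per_chrom = 1000, n_chroms = 16, n_admixed = 12,
                      n_source1 = 8, n_source2 = 8, n_outgroup = 2,
                      missing_rate = 0, admixture_generations = 30,
                      seed = 9100 + i)
    coh <- simulate_cohort(cfg)
    adm <- coh$ds$samples$id[coh$ds$samples$population == "Admixed"]
    cv <- ancestry_covariance_curve(coh$ds, adm, "SourceEA", "SourcePAP",
                                    maxdis = 0.5)
    fit <- fit_exponential(cv)
    cover <- cover + (fit$ci95[["young"]] <= 30 && 30 <= fit$ci95[["old"]])
  }
  expect_gte(cover, 85)
})

test_that("pair bookkeeping: disjoint SNP-set unions add pair counts", {
  coh <- complete_cohort()
  adm <- coh$ds$samples$id[coh$ds$samples$population == "Admixed"]
  full <- ancestry_covariance_curve(coh$ds, adm, "SourceEA", "SourcePAP",
                                    maxdis = 0.4, alpha = 0.4)
  expect_equal(unname(colSums(full$chrom_pairs)), full$bins$n_pairs)
  expect_error(
    ancestry_covariance_curve(coh$ds, adm, "SourceEA", "SourcePAP",
                              binsize = 0.001, maxdis = 1e-9),
    "no same-chromosome"
  )
})
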