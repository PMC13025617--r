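#' Configuration for the synthetic admixed-cohort generator
#'
#' The generator emulates the study design the package targets: an
#' East-Asian-like and a Papuan-like source population diverged by genetic
#' drift, an admixed cohort created by a single admixture pulse `n`
#' generations ago with Papuan fraction `alpha_autosome` on the autosomes
#' and `alpha_X` on the X chromosome (sex-biased admixture), pseudo-haploid
#' sampling with missing data, and unadmixed reference/right populations for
#' f4 and qpAdm-style analyses.
#'
#' The population tree has two internal branches (an East-Asian-like clade
#' carrying `SourceEA` + `RightEA`, a Papuan-like clade carrying `SourcePAP`
#' + `RightPAP`) plus two deep outgroups (`RightDeep1`, `RightDeep2`)
#' branching straight from the ancestor. All drift is Balding-Nichols.
#'
#' @param n_snps_per_chrom SNPs per chromosome.
#' @param n_chroms Number of autosomes.
#' @param chrom_length Chromosome genetic length in Morgans.
#' @param drift_F Named vector of terminal-branch drift parameters in (0,1),
#'   one per population.
#' @param clade_F Named vector with internal-branch drifts `EastAsian`,
#'   `Papuan`.
#' @param alpha_autosome Papuan admixture fraction on the autosomes.
#' @param alpha_X Papuan admixture fraction on the X chromosome.
#' @param admixture_generations Generations since the admixture pulse.
#' @param n_admixed,n_source1,n_source2,n_outgroup Sample sizes (n_outgroup
#'   applies to each right population).
#' @param include_x Simulate an X chromosome.
#' @param missing_rate Per-call missing probability.
#' @param pseudo_haploid Collapse to one sampled allele per site.
#' @param seed Integer seed; all generator randomness flows from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_snps_per_chrom = 2000, n_chroms = 22,
                       chrom_length = 1.0,
                       drift_F = c(SourceEA = 0.02, SourcePAP = 0.02,
                                   RightEA = 0.02, RightPAP = 0.02,
                                   RightDeep1 = 0.10, RightDeep2 = 0.15),
                       clade_F = c(EastAsian = 0.06, Papuan = 0.08),
                       alpha_autosome = 0.4, alpha_X = 0.25,
                       admixture_generations = 30,
                       n_admixed = 20, n_source1 = 10, n_source2 = 10,
                       n_outgroup = 10, include_x = FALSE,
                       missing_rate = 0.05, pseudo_haploid = TRUE,
                       seed = 1L) {
  cfg <- list(
    n_snps_per_chrom = as.integer(n_snps_per_chrom),
    n_chroms = as.integer(n_chroms), chrom_length = chrom_length,
    drift_F = drift_F, clade_F = clade_F,
    alpha_autosome = alpha_autosome, alpha_X = alpha_X,
    admixture_generations = admixture_generations,
    n_admixed = as.integer(n_admixed), n_source1 = as.integer(n_source1),
    n_source2 = as.integer(n_source2), n_outgroup = as.integer(n_outgroup),
    include_x = isTRUE(include_x), missing_rate = missing_rate,
    pseudo_haploid = isTRUE(pseudo_haploid), seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  probs <- c(cfg$alpha_autosome, cfg$alpha_X, cfg$missing_rate)
  if (any(probs < 0 | probs > 1) || cfg$missing_rate >= 1) {
    stop("alpha and missing_rate must lie in [0,1] (missing_rate < 1)", call. = FALSE)
  }
  if (any(cfg$drift_F <= 0 | cfg$drift_F >= 1) ||
      any(cfg$clade_F <= 0 | cfg$clade_F >= 1)) {
    stop("drift parameters F must lie in (0,1)", call. = FALSE)
  }
  if (cfg$chrom_length <= 0) stop("chrom_length must be positive", call. = FALSE)
  if (cfg$admixture_generations <= 0) {
    stop("admixture_generations must be positive", call. = FALSE)
  }
  invisible(cfg)
}

#' Balding-Nichols drift of allele frequencies
#'
#' Draws descendant-population frequencies `p ~ Beta(q(1-F)/F, (1-q)(1-F)/F)`
#' from ancestral frequencies `q` with drift parameter `F` (so
#' `Var(p) = F q (1-q)`). `F` below 1e-9 returns `q` unchanged.
#'
#' @param q Ancestral frequencies in (0,1).
#' @param F_drift Drift parameter in (0,1).
#' @return Drifted frequencies, same length as `q`.
#' @export
drift_frequencies <- function(q, F_drift) {
  if (F_drift <= 0 || F_drift >= 1) stop("F must lie in (0,1)", call. = FALSE)
  if (F_drift < 1e-9) return(q)
  k <- (1 - F_drift) / F_drift
  stats::rbeta(length(q), q * k, (1 - q) * k)
}

sim_variant_map <- function(cfg) {
  chroms <- as.character(seq_len(cfg$n_chroms))
  if (cfg$include_x) chroms <- c(chroms, "X")
  purrr::map_dfr(chroms, function(ch) {
    gpos <- sort(stats::runif(cfg$n_snps_per_chrom, 0, cfg$chrom_length))
    tibble::tibble(
      id = sprintf("snp_%s_%05d", ch, seq_len(cfg$n_snps_per_chrom)),
      chrom = ch,
      pos = as.integer(round(gpos * 1e8) + seq_len(cfg$n_snps_per_chrom)),
      gpos = gpos, ref = "A", alt = "G"
    )
  })
}

#' True population allele frequencies under the simulated demography
#'
#' Draws ancestral frequencies `q ~ Uniform(0.05, 0.95)` per SNP and applies
#' Balding-Nichols drift along the population tree described in
#' [sim_config()]. Deterministic given `cfg$seed`.
#'
#' @param cfg A [sim_config()].
#' @return A `freq_table` of true (noise-free) population frequencies with
#'   `n = Inf` marking exactly known frequencies.
#' @export
simulate_source_frequencies <- function(cfg) {
  validate_sim_config(cfg)
  set.seed(cfg$seed)
  variants <- sim_variant_map(cfg)
  n <- nrow(variants)
  q <- stats::runif(n, 0.05, 0.95)
  q_ea <- drift_frequencies(q, cfg$clade_F[["EastAsian"]])
  q_pap <- drift_frequencies(q, cfg$clade_F[["Papuan"]])
  parent <- list(
    SourceEA = q_ea, RightEA = q_ea,
    SourcePAP = q_pap, RightPAP = q_pap,
    RightDeep1 = q, RightDeep2 = q
  )
  pops <- names(parent)
  freq <- vapply(pops, function(p) drift_frequencies(parent[[p]], cfg$drift_F[[p]]),
                 numeric(n))
  dimnames(freq) <- list(variants$id, pops)
  structure(
    list(variants = variants, pops = pops, freq = freq,
         n = matrix(Inf, n, length(pops), dimnames = dimnames(freq))),
    class = "freq_table"
  )
}

#' Simulate ancestry tracts for the admixed cohort
#'
#' One-pulse admixture approximation: along each haploid chromosome copy,
#' recombination breakpoints fall as a Poisson process with rate `n` per
#' Morgan (`n` = generations since admixture) and the ancestry after each
#' breakpoint is redrawn i.i.d. as Papuan-like (`source2`) with probability
#' `alpha`. Adjacent same-ancestry segments are merged, so tract boundaries
#' are true ancestry switches; tracts tile `[0, chrom_length]`. Males carry
#' a single X copy; X tracts use `alpha_X`.
#'
#' @param cfg A [sim_config()].
#' @return Tibble with columns `sample`, `copy`, `chrom`, `start`, `end`
#'   (Morgans) and `ancestry` (`"source1"`/`"source2"`).
#' @export
simulate_ancestry_tracts <- function(cfg) {
  validate_sim_config(cfg)
  set.seed(cfg$seed + 1L)
  samples <- sim_sample_table(cfg)
  adm <- samples[samples$population == "Admixed", ]
  chroms <- as.character(seq_len(cfg$n_chroms))
  if (cfg$include_x) chroms <- c(chroms, "X")
  out <- vector("list", nrow(adm) * length(chroms) * 2)
  k <- 0
  for (i in seq_len(nrow(adm))) {
    for (ch in chroms) {
      alpha <- if (ch == "X") cfg$alpha_X else cfg$alpha_autosome
      n_copies <- if (ch == "X" && adm$sex[i] == "M") 1L else 2L
      for (cp in seq_len(n_copies)) {
        k <- k + 1
        out[[k]] <- one_copy_tracts(cfg$chrom_length, cfg$admixture_generations,
                                    alpha)
        out[[k]]$sample <- adm$id[i]; out[[k]]$copy <- cp; out[[k]]$chrom <- ch
      }
    }
  }
  dplyr::bind_rows(out[seq_len(k)])[, c("sample", "copy", "chrom",
                                        "start", "end", "ancestry")]
}

one_copy_tracts <- function(len, n_gen, alpha) {
  n_breaks <- stats::rpois(1, n_gen * len)
  breaks <- sort(stats::runif(n_breaks, 0, len))
  states <- ifelse(stats::runif(n_breaks + 1) < alpha, "source2", "source1")
  keep <- c(TRUE, states[-1] != states[-length(states)])
  starts <- c(0, breaks)[keep]
  tibble::tibble(
    start = starts, end = c(starts[-1], len), ancestry = states[keep]
  )
}

sim_sample_table <- function(cfg) {
  mk <- function(pop, n, prefix) {
    if (n == 0) return(NULL)
    tibble::tibble(
      id = sprintf("%s%02d", prefix, seq_len(n)), population = pop,
      sex = rep(c("M", "F"), length.out = n), date_bp = NA_real_
    )
  }
  dplyr::bind_rows(
    mk("Admixed", cfg$n_admixed, "ADM"),
    mk("SourceEA", cfg$n_source1, "SEA"),
    mk("SourcePAP", cfg$n_source2, "SPA"),
    mk("RightEA", cfg$n_outgroup, "REA"),
    mk("RightPAP", cfg$n_outgroup, "RPA"),
    mk("RightDeep1", cfg$n_outgroup, "RD1"),
    mk("RightDeep2", cfg$n_outgroup, "RD2")
  )
}

#' Simulate a full admixed cohort with known truth
#'
#' Draws true population frequencies ([simulate_source_frequencies()]),
#' ancestry tracts for the admixed samples ([simulate_ancestry_tracts()]),
#' then genotypes: each haploid allele is Bernoulli in the frequency of its
#' local ancestry's source population; unadmixed samples draw from their own
#' population's frequency. Diploid dosages are collapsed to pseudo-haploid
#' calls (one allele sampled uniformly per site) when `cfg$pseudo_haploid`,
#' mirroring random-read genotyping of ancient DNA; males are haploid on the
#' X; missingness is i.i.d.
#'
#' @param cfg A [sim_config()].
#' @return List with `ds` (a [genotype_dataset()]) and `truth` (tracts,
#'   alphas, generations, the true frequency table and per-sample Papuan
#'   dosage fractions).
#' @export
simulate_cohort <- function(cfg) {
  validate_sim_config(cfg)
  freqs <- simulate_source_frequencies(cfg)
  tracts <- simulate_ancestry_tracts(cfg)
  set.seed(cfg$seed + 2L)
  samples <- sim_sample_table(cfg)
  variants <- freqs$variants
  n_v <- nrow(variants); n_s <- nrow(samples)
  p1 <- freqs$freq[, "SourceEA"]; p2 <- freqs$freq[, "SourcePAP"]
  on_x <- variants$chrom == "X"

  hap1 <- matrix(NA_integer_, n_v, n_s)
  hap2 <- matrix(NA_integer_, n_v, n_s)
  adm_dose2 <- matrix(0, n_v, n_s)  # local Papuan ancestry dosage (truth)

  tract_key <- split(tracts, interaction(tracts$sample, tracts$chrom,
                                         tracts$copy, drop = TRUE))
  for (j in seq_len(n_s)) {
    pop <- samples$population[j]
    if (pop == "Admixed") {
      for (ch in unique(variants$chrom)) {
        vi <- which(variants$chrom == ch)
        n_copies <- if (ch == "X" && samples$sex[j] == "M") 1L else 2L
        for (cp in seq_len(n_copies)) {
          tr <- tract_key[[paste(samples$id[j], ch, cp, sep = ".")]]
          anc2 <- tr$ancestry[findInterval(variants$gpos[vi], tr$start)] == "source2"
          p_loc <- ifelse(anc2, p2[vi], p1[vi])
          a <- as.integer(stats::runif(length(vi)) < p_loc)
          if (cp == 1L) hap1[vi, j] <- a else hap2[vi, j] <- a
          adm_dose2[vi, j] <- adm_dose2[vi, j] + anc2
        }
        if (n_copies == 1L) adm_dose2[vi, j] <- adm_dose2[vi, j] * 2
      }
    } else {
      p <- freqs$freq[, pop]
      hap1[, j] <- as.integer(stats::runif(n_v) < p)
      hap2[, j] <- as.integer(stats::runif(n_v) < p)
      if (cfg$include_x && samples$sex[j] == "M") hap2[on_x, j] <- NA_integer_
    }
  }

  male <- samples$sex == "M"
  haploid_x <- cfg$include_x & outer(on_x, male, "&")
  if (cfg$pseudo_haploid) {
    pick2 <- matrix(stats::runif(n_v * n_s) < 0.5, n_v, n_s)
    pick2[haploid_x] <- FALSE
    allele <- ifelse(pick2, hap2, hap1)
    calls <- 2L * allele
  } else {
    h2 <- hap2
    h2[haploid_x] <- hap1[haploid_x]  # male X: single allele, coded 0/2
    calls <- hap1 + h2
  }
  if (cfg$missing_rate > 0) {
    calls[matrix(stats::runif(n_v * n_s) < cfg$missing_rate, n_v, n_s)] <- NA_integer_
  }

  ds <- genotype_dataset(variants, samples, calls,
                         pseudo_haploid = cfg$pseudo_haploid)
  adm_idx <- samples$population == "Admixed"
  truth <- list(
    tracts = tracts,
    alpha_autosome = cfg$alpha_autosome, alpha_X = cfg$alpha_X,
    generations = cfg$admixture_generations,
    freqs = freqs,
    papuan_dose = {
      d <- adm_dose2[!on_x, adm_idx, drop = FALSE] / 2
      stats::setNames(colMeans(d), samples$id[adm_idx])
    }
  )
  list(ds = ds, truth = truth)
}

#' Toy terrestrial and marine calibration-curve pair
#'
#' A monotone synthetic stand-in for the IntCal20/Marine20 pair used to test
#' the calibration machinery without external downloads: the terrestrial
#' curve is `mu(cal) = slope * cal + wiggle_amp * sin(2 pi cal / 500)` on a
#' 0-6000 calBP grid at 5-year steps, and the marine curve adds a constant
#' reservoir offset.
#'
#' @param slope 14C years per calendar year (1 gives a 1:1 curve).
#' @param wiggle_amp Amplitude of the sinusoidal wiggle, 14C years.
#' @param reservoir_offset Marine reservoir age, 14C years.
#' @param sigma_14c Curve uncertainty, 14C years.
#' @return List with `terrestrial` and `marine` [cal_curve()] objects.
#' @export
simulate_toy_calibration_curve <- function(slope = 1, wiggle_amp = 0,
                                           reservoir_offset = 500,
                                           sigma_14c = 15) {
  if (slope <= 0) stop("slope must be positive", call. = FALSE)
  cal <- seq(0, 6000, by = 5)
  mu <- slope * cal + wiggle_amp * sin(2 * pi * cal / 500)
  list(
    terrestrial = cal_curve(cal, mu, rep(sigma_14c, length(cal))),
    marine = cal_curve(cal, mu + reservoir_offset, rep(sigma_14c, length(cal)))
  )
}

#' Write a simulated cohort to disk
#'
#' Emits the EIGENSTRAT trio, the truth as JSON, and the ancestry tracts as
#' a BED-like TSV (`sample, copy, chrom, start_M, end_M, ancestry`).
#'
#' @param cohort Result of [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @param prefix File name prefix.
#' @return `dir`, invisibly.
#' @export
write_sim_outputs <- function(cohort, dir, prefix = "sim") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_eigenstrat(cohort$ds, file.path(dir, prefix))
  utils::write.table(
    cohort$truth$tracts, file.path(dir, paste0(prefix, "_tracts.tsv")),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  truth <- cohort$truth[c("alpha_autosome", "alpha_X", "generations")]
  truth$papuan_dose <- as.list(cohort$truth$papuan_dose)
  jsonlite::write_json(truth, file.path(dir, paste0(prefix, "_truth.json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
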