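# Shared fixtures, built lazily once per test run.
.fixtures <- new.env(parent = emptyenv())

# Moderate admixed cohort with missingness and an X chromosome; truth:
# alpha_autosome = 0.4, alpha_X = 0.25, n = 30 generations.
shared_cohort <- function() {
  if (is.null(.fixtures$coh)) {
    cfg <- sim_config(n_snps_per_chrom = 1500, n_chroms = 12, n_admixed = 16,
                      include_x = TRUE, missing_rate = 0.05, seed = 2024)
    .fixtures$coh <- simulate_cohort(cfg)
  }
  .fixtures$coh
}

# Complete-data cohort (no missingness), autosomes only.
complete_cohort <- function() {
  if (is.null(.fixtures$complete)) {
    cfg <- sim_config(n_snps_per_chrom = 1200, n_chroms = 10, n_admixed = 12,
                      missing_rate = 0, seed = 77)
    .fixtures$complete <- simulate_cohort(cfg)
  }
  .fixtures$complete
}

standard_model <- function(target = "Admixed") {
  admixture_model(target, c("SourceEA", "SourcePAP"),
                  c("RightDeep1", "RightEA", "RightPAP", "RightDeep2"))
}

# Small hand-buildable diploid dataset.
toy_dataset <- function(n_v = 30, n_s = 8, seed = 3, pseudo = FALSE,
                        missing_rate = 0.1, with_x = FALSE) {
  set.seed(seed)
  chroms <- if (with_x) c(rep("1", n_v - 10), rep("X", 10)) else rep("1", n_v)
  variants <- tibble::tibble(
    id = sprintf("rs%03d", seq_len(n_v)), chrom = chroms,
    pos = unname(unlist(lapply(split(seq_len(n_v), chroms)[unique(chroms)],
                               seq_along))) * 100L,
    gpos = unname(unlist(lapply(split(seq_len(n_v), chroms)[unique(chroms)],
                                function(i) seq_along(i) * 1e-4))),
    ref = "A", alt = "C"
  )
  samples <- tibble::tibble(
    id = sprintf("S%02d", seq_len(n_s)),
    population = rep(c("P1", "P2"), length.out = n_s),
    sex = rep(c("M", "F"), length.out = n_s)
  )
  vals <- if (pseudo) c(0L, 2L) else 0:2
  calls <- matrix(sample(vals, n_v * n_s, replace = TRUE), n_v, n_s)
  calls[matrix(runif(n_v * n_s) < missing_rate, n_v, n_s)] <- NA_integer_
  if (with_x && !pseudo) {
    xi <- which(variants$chrom == "X"); mi <- which(samples$sex == "M")
    calls[xi, mi][calls[xi, mi] == 1L] <- 2L
  }
  genotype_dataset(variants, samples, calls, pseudo_haploid = pseudo)
}

# Frequency table with an extra admixed column = exact mixture of the sources.
freqs_with_mixture <- function(cfg, alpha, name = "Mix") {
  fr <- simulate_source_frequencies(cfg)
  fr$freq <- cbind(fr$freq,
                   (1 - alpha) * fr$freq[, "SourceEA"] +
                     alpha * fr$freq[, "SourcePAP"])
  fr$n <- cbind(fr$n, Inf)
  colnames(fr$freq)[ncol(fr$freq)] <- colnames(fr$n)[ncol(fr$n)] <- name
  fr$pops <- c(fr$pops, name)
  fr
}
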