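#' f4-statistics with block-jackknife standard errors
#'
#' The f4-statistic for populations (A, B; C, D) is the average over SNPs of
#' `(pA - pB)(pC - pD)`. Under a population tree in which (A,B) and (C,D)
#' are clades with no gene flow between them the expectation is zero, so a
#' Z-score far from zero is evidence of admixture or unmodelled gene flow.
#' Each statistic uses all SNPs at which its own four population frequencies
#' are defined (the "allsnps" convention); standard errors come from a
#' weighted delete-one-block jackknife with per-block SNP counts as weights.
#'
#' @param x A [genotype_dataset()] or a `freq_table` from
#'   [allele_frequencies()].
#' @param a,b,c,d Population labels.
#' @param blocks A [make_blocks()] partition; default contiguous 5 cM blocks.
#' @return A one-row `f4_result` tibble: `pop_a`..`pop_d`, `estimate`, `se`,
#'   `z`, `n_snps`, `n_blocks`, plus list-columns `block_est` and
#'   `block_weight` holding the per-block decomposition.
#' @export
f4 <- function(x, a, b, c, d, blocks = NULL) {
  freqs <- get_freqs(x)
  if (is.null(blocks)) blocks <- make_blocks(freqs)
  f4_scan(freqs, tibble::tibble(pop_a = a, pop_b = b, pop_c = c, pop_d = d),
          blocks)
}

# Shared engine: one row of per-block f4 statistics per requested quadruple.
f4_scan <- function(freqs, quads, blocks) {
  missing_pops <- setdiff(unique(unlist(quads)), freqs$pops)
  if (length(missing_pops) > 0) {
    stop("population(s) not in frequency table: ",
         paste(missing_pops, collapse = ", "), call. = FALSE)
  }
  assignment <- blocks$assignment
  stopifnot(length(assignment) == nrow(freqs$freq))
  rows <- purrr::pmap(quads, function(pop_a, pop_b, pop_c, pop_d) {
    pr <- (freqs$freq[, pop_a] - freqs$freq[, pop_b]) *
      (freqs$freq[, pop_c] - freqs$freq[, pop_d])
    usable <- !is.na(pr)
    if (!any(usable)) {
      stop(sprintf("no SNP has defined frequencies for all of (%s, %s; %s, %s)",
                   pop_a, pop_b, pop_c, pop_d), call. = FALSE)
    }
    bl <- assignment[usable]
    sums <- rowsum(pr[usable], bl)
    cnts <- as.integer(rowsum(rep(1L, sum(usable)), bl))
    block_est <- as.numeric(sums) / cnts
    jk <- jackknife(block_est, cnts)
    tibble::tibble(
      pop_a = pop_a, pop_b = pop_b, pop_c = pop_c, pop_d = pop_d,
      estimate = jk$estimate, se = jk$se,
      z = if (jk$se > 0) jk$estimate / jk$se else 0,
      n_snps = sum(usable), n_blocks = jk$n_blocks,
      block_est = list(block_est), block_weight = list(cnts)
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("f4_result", class(out))
  out
}

#' Scan a set of target populations for asymmetric ancestry
#'
#' Computes `f4(target, baseline; pop_c, pop_d)` for each target: a test of
#' whether the target shares more ancestry with `pop_c` (positive Z) or
#' `pop_d` (negative Z) than the baseline does. Raw Z-scores are reported
#' with no multiple-testing correction.
#'
#' @inheritParams f4
#' @param targets Character vector of target population labels.
#' @param baseline Baseline population (pop B in every statistic).
#' @param pop_c,pop_d The contrasted reference pair (e.g. a Papuan-ancestry
#'   and an East-Asian-ancestry representative).
#' @return An `f4_result` tibble with one row per target.
#' @export
symmetry_scan <- function(x, targets, baseline, pop_c, pop_d, blocks = NULL) {
  freqs <- get_freqs(x)
  if (is.null(blocks)) blocks <- make_blocks(freqs)
  quads <- tibble::tibble(pop_a = targets, pop_b = baseline,
                          pop_c = pop_c, pop_d = pop_d)
  f4_scan(freqs, quads, blocks)
}

#' @export
tidy.f4_result <- function(x, ...) {
  tibble::as_tibble(x)[, c("pop_a", "pop_b", "pop_c", "pop_d",
                           "estimate", "se", "z", "n_snps", "n_blocks")]
}
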