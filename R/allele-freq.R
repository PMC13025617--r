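#' Per-population allele frequencies
#'
#' Computes the alternate-allele frequency and the number of observed allele
#' slots for each population at each variant. A diploid call contributes two
#' allele slots; pseudo-haploid calls and male X-chromosome calls contribute
#' one (the single sampled allele). A frequency is missing exactly when a
#' population has no called allele at the site.
#'
#' @param ds A [genotype_dataset()].
#' @param groups Optional grouping: a named character vector
#'   (names = sample ids, values = population labels) or a data frame with
#'   columns `sample_id`, `population`. Defaults to the dataset's own
#'   population column.
#' @return A `freq_table`: list with `variants` (tibble), `pops` (labels),
#'   `freq` and `n` matrices (variants x populations); `freq` is `NA` where
#'   `n` is zero.
#' @export
allele_frequencies <- function(ds, groups = NULL) {
  stopifnot(inherits(ds, "gt_dataset"))
  pop <- ds$samples$population
  if (!is.null(groups)) {
    if (is.data.frame(groups)) {
      groups <- stats::setNames(groups$population, groups$sample_id)
    }
    idx <- match(names(groups), ds$samples$id)
    if (anyNA(idx)) {
      stop("unknown sample id(s) in groups: ",
           paste(utils::head(names(groups)[is.na(idx)], 5), collapse = ", "),
           call. = FALSE)
    }
    pop <- rep(NA_character_, n_samples(ds))
    pop[idx] <- unname(groups)
  }
  use <- !is.na(pop)
  if (!any(use)) stop("no samples assigned to any population", call. = FALSE)
  pops <- sort(unique(pop[use]))

  G <- ds$calls[, use, drop = FALSE]
  # allele slots per call: 2 for diploid, 1 for pseudo-haploid and male X
  W <- matrix(2, nrow(G), ncol(G))
  if (ds$pseudo_haploid) {
    W[] <- 1
  } else {
    male <- ds$samples$sex[use] == "M"
    on_x <- ds$variants$chrom == "X"
    if (any(male) && any(on_x)) W[on_x, male] <- 1
  }
  W[is.na(G)] <- 0
  G0 <- G
  G0[is.na(G0)] <- 0L

  P <- 1 * outer(pop[use], pops, "==")
  alt <- (G0 * W / 2) %*% P
  slots <- W %*% P
  freq <- alt / slots
  freq[slots == 0] <- NA_real_
  dimnames(freq) <- dimnames(slots) <- list(ds$variants$id, pops)

  empty <- colSums(slots) == 0
  if (any(empty)) {
    stop("population(s) with no called genotypes at any site: ",
         paste(pops[empty], collapse = ", "), call. = FALSE)
  }
  structure(
    list(variants = ds$variants, pops = pops, freq = freq, n = slots),
    class = "freq_table"
  )
}

#' @export
print.freq_table <- function(x, ...) {
  cat(sprintf("<freq_table> %d variants x %d populations: %s\n",
              nrow(x$freq), length(x$pops), paste(x$pops, collapse = ", ")))
  invisible(x)
}

#' @export
tidy.freq_table <- function(x, ...) {
  out <- tibble::tibble(
    variant = rep(x$variants$id, length(x$pops)),
    chrom = rep(x$variants$chrom, length(x$pops)),
    population = rep(x$pops, each = nrow(x$freq)),
    freq = as.vector(x$freq),
    n = as.vector(x$n)
  )
  out
}

get_freqs <- function(x, groups = NULL) {
  if (inherits(x, "freq_table")) return(x)
  if (inherits(x, "gt_dataset")) return(allele_frequencies(x, groups))
  stop("expected a gt_dataset or freq_table", call. = FALSE)
}
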