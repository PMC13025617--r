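#' Genotype dataset container
#'
#' Bundles a variant map, a sample table and a matrix of alternate-allele
#' dosages into a single object used by all downstream ancestry analyses.
#' Pseudo-haploid data (one randomly sampled allele per site, the standard
#' representation for low-coverage ancient DNA) carry only dosages 0 and 2;
#' truly diploid data may also carry 1.
#'
#' @param variants A data frame with columns `id`, `chrom` (labels `"1"`
#'   ... `"22"` or `"X"`; `"23"` is accepted and recoded to `"X"`), `pos`
#'   (1-based physical position, bp), `gpos` (genetic position, Morgans),
#'   `ref`, `alt` (single characters). Physical positions must be strictly
#'   increasing and genetic positions non-decreasing within a chromosome.
#' @param samples A data frame with columns `id`, `population`, and
#'   optionally `sex` (`"M"`, `"F"` or `"U"`, default `"U"`) and `date_bp`
#'   (point date in calendar years before 1950 CE, `NA` if undated).
#' @param calls Integer matrix of alternate-allele dosages, one row per
#'   variant and one column per sample; `NA` marks missing data.
#' @param pseudo_haploid Logical flag. If `NULL` (default) the flag is
#'   auto-detected (no dosage 1 on the autosomes) with a warning, since the
#'   distinction changes allele-count bookkeeping downstream.
#'
#' @return An object of class `gt_dataset`: a list with elements `variants`
#'   (tibble), `samples` (tibble), `calls` (integer matrix) and
#'   `pseudo_haploid` (logical).
#' @export
genotype_dataset <- function(variants, samples, calls, pseudo_haploid = NULL) {
  variants <- tibble::as_tibble(variants)
  samples <- tibble::as_tibble(samples)
  stopifnot(all(c("id", "chrom", "pos", "gpos", "ref", "alt") %in% names(variants)))
  stopifnot(all(c("id", "population") %in% names(samples)))
  if (!"sex" %in% names(samples)) samples$sex <- "U"
  if (!"date_bp" %in% names(samples)) samples$date_bp <- NA_real_
  samples$sex[is.na(samples$sex)] <- "U"
  if (!all(samples$sex %in% c("M", "F", "U"))) {
    stop("sample sex must be one of 'M', 'F', 'U'", call. = FALSE)
  }
  if (any(!nzchar(samples$population) | is.na(samples$population))) {
    stop("every sample needs a non-empty population label", call. = FALSE)
  }
  variants$chrom <- as.character(variants$chrom)
  variants$chrom[variants$chrom == "23"] <- "X"
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (nrow(calls) != nrow(variants) || ncol(calls) != nrow(samples)) {
    stop(sprintf(
      "call matrix is %d x %d but there are %d variants and %d samples",
      nrow(calls), ncol(calls), nrow(variants), nrow(samples)
    ), call. = FALSE)
  }
  if (!all(calls %in% c(0L, 1L, 2L, NA_integer_))) {
    stop("calls must be 0, 1, 2 or NA", call. = FALSE)
  }
  dimnames(calls) <- list(variants$id, samples$id)

  for (ch in unique(variants$chrom)) {
    i <- which(variants$chrom == ch)
    if (any(diff(variants$pos[i]) <= 0)) {
      stop(sprintf("physical positions not strictly increasing on chromosome %s", ch),
           call. = FALSE)
    }
    if (any(diff(variants$gpos[i]) < 0)) {
      stop(sprintf("genetic positions decrease on chromosome %s", ch), call. = FALSE)
    }
  }
  same <- !is.na(variants$ref) & !is.na(variants$alt) & variants$ref == variants$alt
  if (any(same)) stop("ref and alt alleles must differ", call. = FALSE)

  auto <- variants$chrom != "X"
  if (is.null(pseudo_haploid)) {
    pseudo_haploid <- !any(calls[auto, , drop = FALSE] == 1L, na.rm = TRUE)
    warning("pseudo_haploid flag not supplied; auto-detected as ",
            pseudo_haploid, call. = FALSE)
  }
  if (pseudo_haploid && any(calls[auto, , drop = FALSE] == 1L, na.rm = TRUE)) {
    stop("pseudo-haploid data cannot contain dosage 1 on the autosomes", call. = FALSE)
  }
  male_x <- calls[!auto, samples$sex == "M", drop = FALSE]
  if (any(male_x == 1L, na.rm = TRUE)) {
    stop("male X calls must be haploid-coded (0, 2 or missing)", call. = FALSE)
  }

  structure(
    list(variants = variants, samples = samples, calls = calls,
         pseudo_haploid = isTRUE(pseudo_haploid)),
    class = "gt_dataset"
  )
}

#' @export
print.gt_dataset <- function(x, ...) {
  cat(sprintf(
    "<gt_dataset> %d variants x %d samples (%s)\n",
    nrow(x$variants), nrow(x$samples),
    if (x$pseudo_haploid) "pseudo-haploid" else "diploid"
  ))
  cat("  chromosomes:", paste(unique(x$variants$chrom), collapse = " "), "\n")
  pops <- table(x$samples$population)
  cat("  populations:",
      paste(sprintf("%s(%d)", names(pops), pops), collapse = " "), "\n")
  invisible(x)
}

#' @rdname genotype_dataset
#' @param x A `gt_dataset`.
#' @export
n_variants <- function(x) nrow(x$variants)

#' @rdname genotype_dataset
#' @export
n_samples <- function(x) nrow(x$samples)

#' Subset a genotype dataset
#'
#' Restricts a dataset to a subset of variants, samples, or a chromosome
#' class (autosomes vs the X chromosome), preserving order and all
#' container invariants. Used e.g. to contrast autosomal with X-chromosomal
#' ancestry when testing for sex-biased admixture.
#'
#' @param ds A [genotype_dataset()].
#' @param variants Variant ids (character), indices, or logical mask; `NULL`
#'   keeps all.
#' @param samples Sample ids, indices, or logical mask; `NULL` keeps all.
#' @param chrom_class Optional `"autosomes"` or `"X"`.
#' @return A `gt_dataset`; errors if the result would be empty.
#' @export
restrict <- function(ds, variants = NULL, samples = NULL, chrom_class = NULL) {
  stopifnot(inherits(ds, "gt_dataset"))
  vi <- resolve_index(variants, ds$variants$id, "variant")
  si <- resolve_index(samples, ds$samples$id, "sample")
  if (!is.null(chrom_class)) {
    chrom_class <- match.arg(chrom_class, c("autosomes", "X"))
    keep <- if (chrom_class == "X") ds$variants$chrom == "X" else ds$variants$chrom != "X"
    vi <- intersect(vi, which(keep))
  }
  if (length(vi) == 0L) stop("no variants left after filtering", call. = FALSE)
  if (length(si) == 0L) stop("no samples left after filtering", call. = FALSE)
  genotype_dataset(
    ds$variants[vi, , drop = FALSE],
    ds$samples[si, , drop = FALSE],
    ds$calls[vi, si, drop = FALSE],
    pseudo_haploid = ds$pseudo_haploid
  )
}

resolve_index <- function(sel, ids, what) {
  if (is.null(sel)) return(seq_along(ids))
  if (is.logical(sel)) {
    stopifnot(length(sel) == length(ids))
    return(which(sel))
  }
  if (is.numeric(sel)) {
    if (any(sel < 1 | sel > length(ids))) stop(what, " index out of range", call. = FALSE)
    return(sort(unique(as.integer(sel))))
  }
  idx <- match(sel, ids)
  if (anyNA(idx)) {
    stop(sprintf("unknown %s id(s): %s", what,
                 paste(utils::head(sel[is.na(idx)], 5), collapse = ", ")),
         call. = FALSE)
  }
  sort(unique(idx))
}

#' Convert between centimorgans and Morgans
#'
#' Genetic positions are stored internally in Morgans; these helpers convert
#' to and from the centimorgan scale used by most published genetic maps.
#' @param x Numeric vector of positions.
#' @return Numeric vector on the other scale.
#' @export
cm_to_morgans <- function(x) x / 100

#' @rdname cm_to_morgans
#' @export
morgans_to_cm <- function(x) x * 100

is_autosome <- function(chrom) chrom != "X"
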