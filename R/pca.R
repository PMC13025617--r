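#' Projection principal component analysis
#'
#' Axes are computed from reference samples only (centred on the reference
#' allele-frequency mean and normalised by `sqrt(p(1-p))`); all other
#' samples are then projected by least squares using only their non-missing
#' sites, the standard approach for placing low-coverage ancient samples on
#' axes defined by high-quality data without letting their missingness
#' distort the axes.
#'
#' @param ds A [genotype_dataset()].
#' @param reference_pops Populations whose samples define the axes.
#' @param projected_samples Sample ids to project; default all samples not
#'   in a reference population.
#' @param n_axes Number of principal components (default 2).
#' @return A `pca_projection` with a `coords` tibble (`id`, `population`,
#'   `role`, `PC1`, `PC2`, ...), the SNP `loadings`, and singular values.
#' @export
pca_fit_project <- function(ds, reference_pops, projected_samples = NULL,
                            n_axes = 2) {
  stopifnot(inherits(ds, "gt_dataset"))
  ref_idx <- which(ds$samples$population %in% reference_pops)
  if (length(ref_idx) == 0) stop("no reference samples found", call. = FALSE)
  if (length(ref_idx) < n_axes) {
    stop(sprintf("%d reference samples cannot define %d axes",
                 length(ref_idx), n_axes), call. = FALSE)
  }
  if (is.null(projected_samples)) {
    projected_samples <- ds$samples$id[-ref_idx]
  }
  proj_idx <- match(projected_samples, ds$samples$id)
  if (anyNA(proj_idx)) stop("unknown projected sample id(s)", call. = FALSE)

  G <- ds$calls / 2
  ref <- G[, ref_idx, drop = FALSE]
  call_rate <- rowMeans(!is.na(ref))
  p <- rowMeans(ref, na.rm = TRUE)
  keep <- call_rate > 0 & p > 0 & p < 1
  if (!any(keep)) stop("no polymorphic sites among reference samples", call. = FALSE)
  norm <- sqrt(p[keep] * (1 - p[keep]))
  Z <- (G[keep, , drop = FALSE] - p[keep]) / norm
  Zr <- Z[, ref_idx, drop = FALSE]
  Zr[is.na(Zr)] <- 0
  # columns are already centred across reference samples: p is the
  # reference mean, so coordinates have zero mean per axis by construction
  sv <- svd(t(Zr), nu = n_axes, nv = n_axes)
  loadings <- sv$v                       # SNPs x axes
  ref_coords <- sv$u %*% diag(sv$d[seq_len(n_axes)], n_axes)

  project_one <- function(z) {
    obs <- !is.na(z)
    V <- loadings[obs, , drop = FALSE]
    drop(solve(crossprod(V), crossprod(V, z[obs])))
  }
  proj_coords <- t(vapply(proj_idx, function(j) project_one(Z[, j]),
                          numeric(n_axes)))

  axis_names <- paste0("PC", seq_len(n_axes))
  coords <- tibble::tibble(
    id = c(ds$samples$id[ref_idx], ds$samples$id[proj_idx]),
    population = c(ds$samples$population[ref_idx],
                   ds$samples$population[proj_idx]),
    role = rep(c("reference", "projected"),
               c(length(ref_idx), length(proj_idx)))
  )
  coords <- dplyr::bind_cols(
    coords,
    tibble::as_tibble(stats::setNames(
      as.data.frame(rbind(ref_coords, proj_coords)), axis_names
    ))
  )
  structure(list(coords = coords, loadings = loadings,
                 d = sv$d[seq_len(n_axes)], n_snps = sum(keep)),
            class = "pca_projection")
}

#' @export
print.pca_projection <- function(x, ...) {
  cat(sprintf("<pca_projection> %d samples on %d axes (%d SNPs)\n",
              nrow(x$coords), length(x$d), x$n_snps))
  invisible(x)
}

#' @export
tidy.pca_projection <- function(x, ...) x$coords

#' @export
autoplot.pca_projection <- function(object, ...) {
  ggplot2::ggplot(object$coords,
                  ggplot2::aes(.data$PC1, .data$PC2,
                               colour = .data$population,
                               shape = .data$role)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(x = "PC1", y = "PC2") +
    ggplot2::theme_minimal()
}
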