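#' Ancestry-covariance decay curve
#'
#' Measures admixture linkage disequilibrium: in a population formed by a
#' single admixture pulse `n` generations ago, the covariance of ancestry
#' between two loci at genetic distance `d` Morgans decays as
#' `alpha(1-alpha) exp(-n d)`, because recombination breaks ancestry blocks
#' at rate `d` per generation. Ancestry at each SNP is probed through the
#' source allele-frequency difference: SNP `s` gets weight
#' `w_s = p1_s - p2_s` and each individual the residual
#' `x_is = g_is/2 - mu_s`, where `mu_s` is the mixture mean frequency at the
#' individual-set's admixture fraction `alpha` (re-estimated internally by
#' least squares unless supplied). The curve bins same-chromosome SNP pairs
#' by distance; a bin's value is the weighted average of `x_is x_it` with
#' weights `w_s w_t`, normalised by `sum |w_s w_t|`. Missing calls skip the
#' affected individual-pair terms. Only autosomes are used.
#'
#' @param ds A [genotype_dataset()].
#' @param target_samples Sample ids of the admixed target individuals.
#' @param source1,source2 Population labels of the two ancestry sources
#'   (East-Asian-like and Papuan-like in the motivating application).
#' @param binsize Bin width in Morgans (default 0.001, i.e. 0.1 cM).
#' @param maxdis Maximum pair distance in Morgans (default 1.0; note the
#'   unit — a genetic map in cM must be converted first).
#' @param alpha Optional fixed admixture fraction of `source2`; `NULL`
#'   re-estimates it from the data.
#' @return A `decay_curve`: a `bins` tibble (`bin_center`, `value`, `se`,
#'   `n_pairs`) plus per-chromosome accumulators for the chromosome
#'   jackknife, and the `alpha` used.
#' @export
ancestry_covariance_curve <- function(ds, target_samples, source1, source2,
                                      binsize = 0.001, maxdis = 1.0,
                                      alpha = NULL) {
  stopifnot(inherits(ds, "gt_dataset"))
  if (length(target_samples) < 1) stop("need at least one target sample", call. = FALSE)
  auto <- restrict(ds, chrom_class = "autosomes")
  freqs <- allele_frequencies(auto)
  for (p in c(source1, source2)) {
    if (!p %in% freqs$pops) stop("population not found: ", p, call. = FALSE)
  }
  p1 <- freqs$freq[, source1]; p2 <- freqs$freq[, source2]
  tj <- match(target_samples, auto$samples$id)
  if (anyNA(tj)) stop("unknown target sample id(s)", call. = FALSE)
  G <- auto$calls[, tj, drop = FALSE] / 2

  usable <- !is.na(p1) & !is.na(p2) & (p1 != p2)
  if (!any(usable)) stop("no SNPs with distinct defined source frequencies", call. = FALSE)
  p1 <- p1[usable]; p2 <- p2[usable]
  G <- G[usable, , drop = FALSE]
  vmap <- auto$variants[usable, ]
  w <- p1 - p2

  if (is.null(alpha)) {
    gbar <- rowMeans(G, na.rm = TRUE)
    ok <- !is.na(gbar)
    alpha <- sum((gbar[ok] - p1[ok]) * (p2[ok] - p1[ok])) /
      sum((p2[ok] - p1[ok])^2)
    alpha <- min(max(alpha, 0), 1)
  }
  mu <- (1 - alpha) * p1 + alpha * p2
  X <- G - mu

  n_bins <- ceiling(maxdis / binsize)
  chroms <- unique(vmap$chrom)
  num <- den <- npairs <- matrix(0, length(chroms), n_bins,
                                 dimnames = list(chroms, NULL))
  for (ci in seq_along(chroms)) {
    vi <- which(vmap$chrom == chroms[ci])
    if (length(vi) < 2) next
    acc <- accumulate_pairs(X[vi, , drop = FALSE], w[vi], vmap$gpos[vi],
                            binsize, maxdis, n_bins)
    num[ci, ] <- acc$num; den[ci, ] <- acc$den; npairs[ci, ] <- acc$npairs
  }
  if (sum(npairs) == 0) {
    stop("no same-chromosome SNP pairs within maxdis", call. = FALSE)
  }
  tot_num <- colSums(num); tot_den <- colSums(den); tot_np <- colSums(npairs)
  value <- ifelse(tot_den > 0, tot_num / tot_den, NA_real_)
  centers <- (seq_len(n_bins) - 0.5) * binsize

  se <- rep(NA_real_, n_bins)
  if (length(chroms) >= 2) {
    for (b in which(tot_den > 0)) {
      loo <- (tot_num[b] - num[, b]) / (tot_den[b] - den[, b])
      se[b] <- loo_jackknife_se(loo, den[, b], value[b])
    }
  }
  structure(list(
    bins = tibble::tibble(bin_center = centers, value = value, se = se,
                          n_pairs = tot_np),
    chrom_num = num, chrom_den = den, chrom_pairs = npairs,
    chroms = chroms, binsize = binsize, maxdis = maxdis, alpha = alpha,
    n_targets = length(tj)
  ), class = "decay_curve")
}

# Bin-accumulated weighted cross-products for one chromosome, chunked over
# rows to bound memory at ~chunk x S doubles.
accumulate_pairs <- function(X, w, gpos, binsize, maxdis, n_bins,
                             chunk = 1024L) {
  S <- nrow(X)
  X0 <- X; X0[is.na(X0)] <- 0
  M <- !is.na(X)
  storage.mode(M) <- "double"
  num <- den <- npairs <- numeric(n_bins)
  for (lo in seq(1L, S - 1L, by = chunk)) {
    hi <- min(lo + chunk - 1L, S - 1L)
    rows <- lo:hi
    C <- X0[rows, , drop = FALSE] %*% t(X0)
    K <- M[rows, , drop = FALSE] %*% t(M)
    D <- abs(outer(gpos[rows], gpos, "-"))
    upper <- outer(rows, seq_len(S), "<")  # each unordered pair once
    ok <- upper & D > 0 & D <= maxdis & K > 0
    if (!any(ok)) next
    bin <- ceiling(D[ok] / binsize)
    wprod <- (w[rows] %o% w)[ok]
    avg <- C[ok] / K[ok]
    num <- num + tapply_sum(wprod * avg, bin, n_bins)
    den <- den + tapply_sum(abs(wprod), bin, n_bins)
    npairs <- npairs + tapply_sum(rep(1, length(bin)), bin, n_bins)
  }
  list(num = num, den = den, npairs = npairs)
}

tapply_sum <- function(x, bin, n_bins) {
  out <- numeric(n_bins)
  s <- rowsum(x, bin)
  out[as.integer(rownames(s))] <- s
  out
}

#' Fit an exponential decay to an ancestry-covariance curve
#'
#' Least-squares fit of `A exp(-n d) + c` to the binned curve over
#' `[mindis, maxdis]`, with bins weighted by their total normalising weight.
#' The decay rate `n` is the number of generations since admixture. `n` is
#' found by a coarse logarithmic grid search followed by local refinement
#' (the model is linear in `A` and `c` given `n`). The standard error comes
#' from a delete-one-chromosome jackknife of the complete fit.
#'
#' @param curve A [ancestry_covariance_curve()] result.
#' @param mindis Smallest pair distance used, Morgans (default 0.005;
#'   near-zero bins are contaminated by background LD).
#' @param affine Fit the constant background term `c` (default) or pin it
#'   to zero.
#' @param n_max Upper bound of the decay-rate search, generations.
#' @return A `decay_fit`: `n_generations`, `se_generations`, `ci95`,
#'   `amplitude`, `affine`, per-chromosome leave-one-out estimates.
#' @export
fit_exponential <- function(curve, mindis = 0.005, affine = TRUE,
                            n_max = 500) {
  stopifnot(inherits(curve, "decay_curve"))
  sel <- which(curve$bins$bin_center >= mindis &
                 curve$bins$bin_center <= curve$maxdis &
                 is.finite(curve$bins$value) & curve$bins$n_pairs > 0)
  if (length(sel) < 5) stop("fewer than 5 usable bins in the fit range", call. = FALSE)
  d_all <- curve$bins$bin_center[sel]

  tot_den <- colSums(curve$chrom_den)[sel]
  fit_one <- function(d, value, wts) {
    obj <- function(n) exp_rss(n, d, value, wts, affine)$rss
    grid <- exp(seq(log(0.5), log(n_max), length.out = 80))
    best <- grid[which.min(vapply(grid, obj, numeric(1)))]
    opt <- stats::optimize(obj, lower = best / 3, upper = best * 3)
    par <- exp_rss(opt$minimum, d, value, wts, affine)
    list(n = opt$minimum, A = par$A, c = par$c)
  }
  full <- fit_one(d_all, curve$bins$value[sel], tot_den)
  if (full$A <= 0) {
    stop("no decay signal: fitted amplitude is not positive", call. = FALSE)
  }

  n_chroms <- length(curve$chroms)
  loo_n <- rep(NA_real_, n_chroms)
  chrom_w <- rowSums(curve$chrom_den)
  if (n_chroms >= 2) {
    for (ci in seq_len(n_chroms)) {
      numc <- colSums(curve$chrom_num[-ci, , drop = FALSE])[sel]
      denc <- colSums(curve$chrom_den[-ci, , drop = FALSE])[sel]
      vals <- ifelse(denc > 0, numc / denc, NA_real_)
      okb <- is.finite(vals)
      if (sum(okb) < 5) next
      loo_n[ci] <- fit_one(d_all[okb], vals[okb], denc[okb])$n
    }
    se <- loo_jackknife_se(loo_n, chrom_w, full$n)
  } else {
    se <- NA_real_
  }
  structure(list(
    n_generations = full$n, se_generations = se,
    ci95 = c(old = full$n + 1.96 * se, young = full$n - 1.96 * se),
    amplitude = full$A, affine = if (affine) full$c else 0,
    mindis = mindis, maxdis = curve$maxdis, binsize = curve$binsize,
    alpha = curve$alpha,
    loo = tibble::tibble(chrom = curve$chroms, n_hat = loo_n)
  ), class = "decay_fit")
}

exp_rss <- function(n, d, value, wts, affine) {
  basis <- exp(-n * d)
  if (affine) {
    fit <- stats::lm.wfit(cbind(basis, 1), value, wts)
    A <- fit$coefficients[1]; cc <- fit$coefficients[2]
  } else {
    fit <- stats::lm.wfit(cbind(basis), value, wts)
    A <- fit$coefficients[1]; cc <- 0
  }
  list(rss = sum(wts * fit$residuals^2), A = unname(A), c = unname(cc))
}

#' Group target samples for joint dating runs
#'
#' Individuals of similar age can be merged into one target set so that the
#' decay curve averages over more individual pairs, tightening the
#' chromosome-jackknife error without altering any genotypes.
#'
#' @param ds A [genotype_dataset()].
#' @param sample_groups Named list of sample-id vectors.
#' @return The validated named list, classed `target_groups`.
#' @export
merge_targets <- function(ds, sample_groups) {
  stopifnot(inherits(ds, "gt_dataset"), is.list(sample_groups))
  if (is.null(names(sample_groups)) || any(!nzchar(names(sample_groups)))) {
    stop("sample_groups must be a named list", call. = FALSE)
  }
  for (g in names(sample_groups)) {
    ids <- sample_groups[[g]]
    if (length(ids) == 0) stop("empty target group: ", g, call. = FALSE)
    bad <- setdiff(ids, ds$samples$id)
    if (length(bad) > 0) {
      stop(sprintf("group %s references unknown sample(s): %s", g,
                   paste(bad, collapse = ", ")), call. = FALSE)
    }
  }
  structure(sample_groups, class = "target_groups")
}

#' @export
print.decay_curve <- function(x, ...) {
  cat(sprintf(
    "<decay_curve> %d bins of %.4g M up to %.3g M, %d chromosomes, alpha = %.3f\n",
    nrow(x$bins), x$binsize, x$maxdis, length(x$chroms), x$alpha))
  invisible(x)
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf(
    "<decay_fit> n = %.1f +/- %.1f generations (95%% CI %.0f-%.0f), A = %.3g, c = %.3g\n",
    x$n_generations, x$se_generations, x$ci95["old"], x$ci95["young"],
    x$amplitude, x$affine))
  invisible(x)
}

#' @export
tidy.decay_curve <- function(x, ...) x$bins

#' @export
tidy.decay_fit <- function(x, ...) {
  tibble::tibble(
    term = c("n_generations", "amplitude", "affine"),
    estimate = c(x$n_generations, x$amplitude, x$affine),
    se = c(x$se_generations, NA_real_, NA_real_)
  )
}

#' @export
glance.decay_fit <- function(x, ...) {
  tibble::tibble(n_generations = x$n_generations,
                 se_generations = x$se_generations,
                 ci95_old = x$ci95[["old"]], ci95_young = x$ci95[["young"]],
                 amplitude = x$amplitude, affine = x$affine,
                 alpha = x$alpha, mindis = x$mindis, maxdis = x$maxdis)
}

#' Plot an ancestry-covariance decay curve with an optional fit
#'
#' @param object A `decay_curve`.
#' @param fit Optional `decay_fit` overlay.
#' @param max_d Truncate the x-axis (Morgans).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.decay_curve <- function(object, fit = NULL, max_d = 0.3, ...) {
  df <- dplyr::filter(object$bins, is.finite(.data$value),
                      .data$bin_center <= max_d)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$bin_center, .data$value)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::labs(x = "genetic distance (Morgans)",
                  y = "weighted ancestry covariance") +
    ggplot2::theme_minimal()
  if (!is.null(fit)) {
    d <- seq(min(df$bin_center), max(df$bin_center), length.out = 200)
    line <- tibble::tibble(
      bin_center = d,
      value = fit$amplitude * exp(-fit$n_generations * d) + fit$affine
    )
    p <- p + ggplot2::geom_line(data = line, colour = "firebrick")
  }
  p
}
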