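#' Specify a qpAdm-style admixture model
#'
#' A target population is modelled as a mixture of `k` source populations,
#' tested against a set of `m >= k + 1` "right" populations (outgroups
#' differentially related to the sources). No population may appear in two
#' roles.
#'
#' @param target Target population label.
#' @param sources Character vector of source labels (k >= 1).
#' @param rights Character vector of right-population labels; the first is
#'   used as the fixed base of the f4 system.
#' @return An `admixture_model` list.
#' @export
admixture_model <- function(target, sources, rights) {
  all_pops <- c(target, sources, rights)
  if (anyDuplicated(all_pops)) {
    stop("a population appears in more than one role", call. = FALSE)
  }
  if (length(rights) < length(sources) + 1) {
    stop(sprintf(
      "model not identifiable: %d source(s) need at least %d right populations",
      length(sources), length(sources) + 1
    ), call. = FALSE)
  }
  structure(list(target = target, sources = sources, rights = rights),
            class = "admixture_model")
}

#' Build the f4 system for a qpAdm-style fit
#'
#' With base right population `R0` (the first right), the system is
#' `y_j = f4(target, R0; R_j, R0)` and `X_ij = f4(source_i, R0; R_j, R0)`
#' over the remaining rights `R_j`. If the target's f4 profile is the
#' mixture `sum_i w_i` of the source profiles, then `y = X' w`. Per-block
#' decompositions of every statistic are retained for jackknife covariance
#' and weight errors.
#'
#' @param x A [genotype_dataset()] or `freq_table`.
#' @param model An [admixture_model()].
#' @param blocks A [make_blocks()] partition; default 5 cM blocks.
#' @return An `f4_system` list: `y` (length m-1), `X` (k x (m-1)),
#'   per-stat block estimate and weight matrices, and bookkeeping.
#' @export
build_f4_vector <- function(x, model, blocks = NULL) {
  stopifnot(inherits(model, "admixture_model"))
  freqs <- get_freqs(x)
  if (is.null(blocks)) blocks <- make_blocks(freqs)
  r0 <- model$rights[1]
  rj <- model$rights[-1]
  k <- length(model$sources); m1 <- length(rj)
  lefts <- c(model$target, model$sources)
  quads <- tidyr::expand_grid(pop_a = lefts, pop_c = rj)
  quads <- tibble::tibble(pop_a = quads$pop_a, pop_b = r0,
                          pop_c = quads$pop_c, pop_d = r0)
  stats <- f4_scan(freqs, quads, blocks)

  n_blocks <- nrow(blocks$blocks)
  n_stats <- nrow(stats)
  block_est <- matrix(NA_real_, n_blocks, n_stats)
  block_wt <- matrix(0, n_blocks, n_stats)
  for (s in seq_len(n_stats)) {
    # block ids are dense 1..n_blocks but a stat may lack some blocks
    ids <- usable_block_ids(freqs, stats[s, ], blocks)
    block_est[ids, s] <- stats$block_est[[s]]
    block_wt[ids, s] <- stats$block_weight[[s]]
  }
  est <- stats$estimate
  y_idx <- which(stats$pop_a == model$target)
  structure(list(
    y = est[y_idx],
    X = matrix(est[stats$pop_a != model$target], nrow = k, byrow = TRUE,
               dimnames = list(model$sources, rj)),
    stats = stats, block_est = block_est, block_wt = block_wt,
    y_idx = y_idx,
    x_idx = matrix(which(stats$pop_a != model$target), nrow = k, byrow = TRUE),
    model = model, n_snps = stats$n_snps
  ), class = "f4_system")
}

usable_block_ids <- function(freqs, stat_row, blocks) {
  pr <- (freqs$freq[, stat_row$pop_a] - freqs$freq[, stat_row$pop_b]) *
    (freqs$freq[, stat_row$pop_c] - freqs$freq[, stat_row$pop_d])
  sort(unique(blocks$assignment[!is.na(pr)]))
}

#' Fit admixture weights by constrained generalised least squares
#'
#' Minimises `(y - X'w)' Sigma^-1 (y - X'w)` subject to `sum(w) = 1`, where
#' `Sigma` is the block-jackknife covariance of the residual f4 vector
#' (estimated at an initial fit and refined once). Weight standard errors
#' and covariance come from a delete-one-block refit of the whole system;
#' the model-fit tail probability is the upper tail of the minimised
#' quadratic form against a chi-square with `(m-1) - (k-1)` degrees of
#' freedom. Near-singular covariances get a ridge `1e-6 * trace / dim` on
#' the diagonal, with a warning.
#'
#' @param fv An `f4_system` from [build_f4_vector()].
#' @return An `admixture_fit`: named `weights` (summing to 1), `se`,
#'   `weight_cov`, `fit_p`, `chisq`, `dof`, per-right `resid_z`, `n_snps`.
#' @export
qpadm_fit <- function(fv) {
  stopifnot(inherits(fv, "f4_system"))
  k <- nrow(fv$X); m1 <- length(fv$y)
  bw <- fv$block_wt[, fv$y_idx[1]]  # y-stat SNP counts as block weights
  if (sum(bw > 0) < 2) stop("need at least 2 usable blocks", call. = FALSE)

  be <- fv$block_est
  for (s in seq_len(ncol(be))) {  # blocks missing a stat: neutral fill
    nas <- is.na(be[, s])
    if (any(nas)) be[nas, s] <- fv$stats$estimate[s]
  }

  resid_blocks <- function(w) {
    eb <- be[, fv$y_idx, drop = FALSE]
    for (i in seq_len(k)) {
      eb <- eb - w[i] * be[, fv$x_idx[i, ], drop = FALSE]
    }
    eb
  }
  solve_w <- function(X, y, Omega) {
    if (k == 1) return(1)
    A <- X %*% Omega %*% t(X)
    b <- X %*% Omega %*% y
    Ai_b <- solve(A, b); Ai_1 <- solve(A, rep(1, k))
    drop(Ai_b + Ai_1 * (1 - sum(Ai_b)) / sum(Ai_1))
  }

  w_hat <- if (k == 1) 1 else {
    solve_w(fv$X, fv$y, diag(m1))
  }
  # iterate covariance estimation and GLS to the self-consistent fixed
  # point, which is invariant to the choice of base right population
  Sigma <- NULL
  for (iter in 1:25) {
    jc <- jackknife_cov(resid_blocks(w_hat), bw)
    Sigma <- ridge_guard(jc$cov)
    Omega <- solve(Sigma)
    w_new <- solve_w(fv$X, fv$y, Omega)
    done <- max(abs(w_new - w_hat)) < 1e-12
    w_hat <- w_new
    if (done || k == 1) break
  }
  e <- drop(fv$y - crossprod(fv$X, w_hat))
  chisq <- drop(t(e) %*% solve(Sigma, e))
  dof <- m1 - (k - 1)
  fit_p <- stats::pchisq(chisq, dof, lower.tail = FALSE)

  # delete-one-block refits for the weight covariance
  full <- jackknife_cov(fv$block_est |> replace_na_cols(fv$stats$estimate), bw)
  keep <- bw > 0
  loo_w <- matrix(NA_real_, sum(keep), k)
  Omega <- solve(Sigma)
  rows <- which(keep)
  for (gi in seq_along(rows)) {
    th <- full$loo[gi, ]
    Xg <- matrix(th[as.vector(t(fv$x_idx))], nrow = k, byrow = TRUE)
    yg <- th[fv$y_idx]
    loo_w[gi, ] <- solve_w(Xg, yg, Omega)
  }
  if (k == 1) {
    w_cov <- matrix(0, 1, 1)
  } else {
    w_cov <- loo_jackknife_cov(loo_w, bw[keep], w_hat)
  }
  se <- sqrt(pmax(diag(w_cov), 0))
  names(w_hat) <- names(se) <- fv$model$sources
  structure(list(
    model = fv$model, weights = w_hat, se = se, weight_cov = w_cov,
    fit_p = fit_p, chisq = chisq, dof = dof,
    resid = e, resid_z = e / sqrt(pmax(diag(Sigma), 1e-300)),
    n_snps = stats::median(fv$n_snps), n_blocks = sum(keep)
  ), class = "admixture_fit")
}

replace_na_cols <- function(m, fill) {
  for (s in seq_len(ncol(m))) {
    nas <- is.na(m[, s])
    if (any(nas)) m[nas, s] <- fill[s]
  }
  m
}

ridge_guard <- function(Sigma) {
  kap <- tryCatch(kappa(Sigma, exact = TRUE), error = function(e) Inf)
  if (!is.finite(kap) || kap > 1e10) {
    lambda <- 1e-6 * sum(diag(Sigma)) / nrow(Sigma)
    warning("near-singular f4 covariance; adding ridge ", signif(lambda, 3),
            " (consider more blocks or rights)", call. = FALSE)
    Sigma <- Sigma + diag(lambda, nrow(Sigma))
  }
  Sigma
}

#' One-call qpAdm-style fit
#'
#' Convenience wrapper: [build_f4_vector()] then [qpadm_fit()].
#'
#' @inheritParams build_f4_vector
#' @return An `admixture_fit`.
#' @export
qpadm <- function(x, model, blocks = NULL) {
  qpadm_fit(build_f4_vector(x, model, blocks))
}

#' @export
print.admixture_fit <- function(x, ...) {
  cat(sprintf("<admixture_fit> target %s ~ %s\n", x$model$target,
              paste(x$model$sources, collapse = " + ")))
  for (i in seq_along(x$weights)) {
    cat(sprintf("  %-12s %.3f +/- %.3f\n", names(x$weights)[i],
                x$weights[i], x$se[i]))
  }
  cat(sprintf("  fit: chisq %.2f on %d df, p = %.3g (%d SNPs, %d blocks)\n",
              x$chisq, x$dof, x$fit_p, x$n_snps, x$n_blocks))
  invisible(x)
}

#' @export
tidy.admixture_fit <- function(x, ...) {
  tibble::tibble(source = names(x$weights), weight = unname(x$weights),
                 se = unname(x$se))
}

#' @export
glance.admixture_fit <- function(x, ...) {
  tibble::tibble(target = x$model$target, fit_p = x$fit_p, chisq = x$chisq,
                 dof = x$dof, n_snps = x$n_snps, n_blocks = x$n_blocks)
}

#' Autosome versus X-chromosome sex-bias Z-score
#'
#' Compares the weight of one source (by convention the Papuan-related one)
#' between a fit on the autosomes and a fit on the X chromosome. Because
#' females carry two X copies and males one, a source contributed mostly by
#' males leaves less of its ancestry on the X: positive Z means male-biased
#' admixture from `source`.
#'
#' @param fit_autosome,fit_x `admixture_fit` objects (or lists with elements
#'   `weights` and `se`) from the autosomal and X-chromosomal data.
#' @param source Which source's weight to compare; defaults to the last
#'   source of the autosomal fit.
#' @return The Z-score `(w_auto - w_X) / sqrt(se_auto^2 + se_X^2)`.
#' @export
sex_bias_z <- function(fit_autosome, fit_x, source = NULL) {
  source <- source %||% names(fit_autosome$weights)[length(fit_autosome$weights)]
  wa <- fit_autosome$weights[[source]]; sa <- fit_autosome$se[[source]]
  wx <- fit_x$weights[[source]]; sx <- fit_x$se[[source]]
  if (sa == 0 && sx == 0) {
    stop("both fits report zero standard error; Z undefined", call. = FALSE)
  }
  (wa - wx) / sqrt(sa^2 + sx^2)
}
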