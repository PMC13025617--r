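#' Inverse-variance-weighted f4 regression
#'
#' Fits `y = intercept + slope * x` across a set of populations where each
#' point is a pair of f4-statistics (an x-axis affinity and a y-axis
#' affinity) with standard errors. Points are weighted by `1/sy^2`. A
#' population whose ancestry is not explained by the cline shows up as a
#' residual many standard errors from zero; residual standard errors are
#' obtained by deleting each jackknife block, rebuilding the f4 inputs,
#' refitting the regression and taking the jackknife spread of the residual.
#'
#' @param points Data frame with columns `x`, `y`, `sy` (standard error of
#'   `y`); an optional `label` column names the points. Alternatively build
#'   `points` with [f4_regression_points()] to carry per-block f4
#'   decompositions for jackknife residuals.
#' @param x_blocks,y_blocks Optional blocks-by-points matrices of per-block
#'   f4 estimates (filled automatically by [f4_regression_points()]).
#' @param x_weights,y_weights Matching blocks-by-points matrices of
#'   per-block SNP counts.
#' @return An `f4_regression` object with `slope`, `intercept` and a point
#'   table (`residual`, `resid_se`, `resid_z`, `weight`); access tidily via
#'   [generics::tidy()] / [generics::glance()].
#' @export
f4_regression <- function(points, x_blocks = NULL, y_blocks = NULL,
                          x_weights = NULL, y_weights = NULL) {
  points <- tibble::as_tibble(points)
  stopifnot(all(c("x", "y", "sy") %in% names(points)))
  if (nrow(points) < 3) stop("need at least 3 points", call. = FALSE)
  if (!"label" %in% names(points)) {
    points$label <- paste0("pt", seq_len(nrow(points)))
  }
  for (nm in c("x_blocks", "y_blocks", "x_weights", "y_weights")) {
    m <- get(nm)
    if (is.null(m) && nm %in% names(attributes(points))) {
      assign(nm, attr(points, nm))
    }
  }
  w <- 1 / points$sy^2
  fit <- wls_line(points$x, points$y, w)
  resid <- points$y - (fit$intercept + fit$slope * points$x)

  if (!is.null(x_blocks)) {
    stopifnot(!is.null(y_blocks), !is.null(x_weights), !is.null(y_weights))
    B <- nrow(x_blocks)
    if (B < 2) stop("need at least 2 blocks for jackknife residuals", call. = FALSE)
    res_loo <- matrix(NA_real_, B, nrow(points))
    for (g in seq_len(B)) {
      xg <- loo_mean(x_blocks, x_weights, g)
      yg <- loo_mean(y_blocks, y_weights, g)
      fg <- wls_line(xg, yg, w)
      res_loo[g, ] <- yg - (fg$intercept + fg$slope * xg)
    }
    bw <- rowSums(x_weights, na.rm = TRUE) + rowSums(y_weights, na.rm = TRUE)
    resid_se <- vapply(seq_len(nrow(points)), function(i) {
      loo_jackknife_se(res_loo[, i], bw, resid[i])
    }, numeric(1))
  } else {
    # no block decomposition supplied: leverage-based WLS residual SE
    h <- wls_leverage(points$x, w)
    resid_se <- points$sy * sqrt(pmax(1 - h, 0))
  }
  out <- list(
    slope = fit$slope, intercept = fit$intercept,
    points = tibble::tibble(
      label = points$label, x = points$x, y = points$y, sy = points$sy,
      weight = w, fitted = fit$intercept + fit$slope * points$x,
      residual = resid, resid_se = resid_se,
      resid_z = ifelse(resid_se > 0, resid / resid_se, 0)
    )
  )
  class(out) <- "f4_regression"
  out
}

wls_line <- function(x, y, w) {
  sw <- sum(w); sx <- sum(w * x); sy <- sum(w * y)
  sxx <- sum(w * x^2); sxy <- sum(w * x * y)
  denom <- sw * sxx - sx^2
  if (abs(denom) < 1e-30 * sw * max(sxx, 1e-300)) {
    stop("degenerate regression: x values carry no spread", call. = FALSE)
  }
  slope <- (sw * sxy - sx * sy) / denom
  list(slope = slope, intercept = (sy - slope * sx) / sw)
}

wls_leverage <- function(x, w) {
  sw <- sum(w); sx <- sum(w * x); sxx <- sum(w * x^2)
  denom <- sw * sxx - sx^2
  xbar <- sx / sw
  w * (1 / sw + (x - xbar)^2 / (denom / sw))
}

loo_mean <- function(block_est, block_w, g) {
  num <- colSums(block_est[-g, , drop = FALSE] * block_w[-g, , drop = FALSE],
                 na.rm = TRUE)
  den <- colSums(block_w[-g, , drop = FALSE], na.rm = TRUE)
  num / den
}

# jackknife SE from delete-one values of a (possibly nonlinear) statistic,
# given the full-data estimate and block weights
loo_jackknife_se <- function(loo, w, est) {
  keep <- !is.na(loo) & w > 0
  loo <- loo[keep]; w <- w[keep]
  g <- length(loo); n <- sum(w)
  if (g < 2) return(NA_real_)
  h <- n / w
  tau <- h * est - (h - 1) * loo
  theta_j <- mean(tau)
  sqrt(mean((tau - theta_j)^2 / (h - 1)))
}

#' Assemble regression points from two sets of f4-statistics
#'
#' Pairs row `i` of `x_stats` with row `i` of `y_stats` (both `f4_result`
#' tibbles computed on the same block partition) into the input expected by
#' [f4_regression()], carrying the per-block decompositions needed for
#' jackknife residual errors.
#'
#' @param x_stats,y_stats `f4_result` tibbles of equal row count from [f4()]
#'   or [symmetry_scan()].
#' @param labels Optional point labels; defaults to the x-statistic's
#'   `pop_a`.
#' @return A tibble with attributes `x_blocks`, `y_blocks`, `x_weights`,
#'   `y_weights`.
#' @export
f4_regression_points <- function(x_stats, y_stats, labels = NULL) {
  stopifnot(nrow(x_stats) == nrow(y_stats))
  all_blocks <- sort(unique(c(
    unlist(purrr::map(x_stats$block_est, seq_along)),
    unlist(purrr::map(y_stats$block_est, seq_along))
  )))
  expand <- function(stats) {
    est <- matrix(NA_real_, length(all_blocks), nrow(stats))
    wt <- matrix(0, length(all_blocks), nrow(stats))
    for (i in seq_len(nrow(stats))) {
      b <- seq_along(stats$block_est[[i]])
      est[b, i] <- stats$block_est[[i]]
      wt[b, i] <- stats$block_weight[[i]]
    }
    list(est = est, wt = wt)
  }
  ex <- expand(x_stats); ey <- expand(y_stats)
  pts <- tibble::tibble(
    label = labels %||% x_stats$pop_a,
    x = x_stats$estimate, y = y_stats$estimate, sy = y_stats$se
  )
  attr(pts, "x_blocks") <- ex$est; attr(pts, "x_weights") <- ex$wt
  attr(pts, "y_blocks") <- ey$est; attr(pts, "y_weights") <- ey$wt
  pts
}

#' @export
print.f4_regression <- function(x, ...) {
  cat(sprintf("<f4_regression> slope %.4g, intercept %.4g, %d points\n",
              x$slope, x$intercept, nrow(x$points)))
  invisible(x)
}

#' @export
tidy.f4_regression <- function(x, ...) x$points

#' @export
glance.f4_regression <- function(x, ...) {
  tibble::tibble(slope = x$slope, intercept = x$intercept,
                 n_points = nrow(x$points),
                 max_abs_resid_z = max(abs(x$points$resid_z), na.rm = TRUE))
}
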