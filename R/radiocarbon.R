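#' Calibration curve container
#'
#' A radiocarbon calibration curve maps calendar age (calBP, years before
#' 1950 CE) to the expected conventional 14C age and its 1-sigma
#' uncertainty.
#'
#' @param cal_bp Calendar grid, calBP, sorted increasing.
#' @param mu Expected 14C age, years BP.
#' @param sigma Curve uncertainty, 14C years (> 0).
#' @return A `cal_curve` tibble with columns `cal_bp`, `mu`, `sigma`.
#' @export
cal_curve <- function(cal_bp, mu, sigma) {
  stopifnot(length(cal_bp) == length(mu), length(mu) == length(sigma))
  if (is.unsorted(cal_bp, strictly = TRUE)) {
    stop("cal_bp grid must be strictly increasing", call. = FALSE)
  }
  if (any(sigma <= 0)) stop("curve sigma must be positive", call. = FALSE)
  structure(tibble::tibble(cal_bp = cal_bp, mu = mu, sigma = sigma),
            class = c("cal_curve", class(tibble::tibble())))
}

#' Read a calibration curve in the standard .14c column format
#'
#' Expects at least three columns (calBP, 14C age, 1-sigma error); lines
#' starting with `#` are skipped. The curve is linearly interpolated onto a
#' uniform 5-year grid; values at the original knots are preserved exactly
#' when the knots sit on the grid.
#'
#' @param path Path to a `.14c` file (comma or whitespace separated).
#' @param step Output grid step in years (default 5).
#' @return A [cal_curve()].
#' @export
read_curve_14c <- function(path, step = 5) {
  lines <- readLines(path)
  lines <- lines[!startsWith(trimws(lines), "#") & nzchar(trimws(lines))]
  sep <- if (grepl(",", lines[1])) "," else ""
  raw <- utils::read.table(text = lines, sep = sep, header = FALSE)
  if (nrow(raw) < 2 || ncol(raw) < 3) {
    stop("curve file needs >= 2 rows and 3 columns (calBP, 14C age, error): ",
         path, call. = FALSE)
  }
  cal <- as.numeric(raw[[1]]); mu <- as.numeric(raw[[2]])
  sig <- as.numeric(raw[[3]])
  o <- order(cal)
  cal <- cal[o]; mu <- mu[o]; sig <- sig[o]
  if (any(diff(cal) <= 0)) {
    stop("calBP column is not monotone: ", path, call. = FALSE)
  }
  grid <- seq(ceiling(min(cal) / step) * step, floor(max(cal) / step) * step,
              by = step)
  cal_curve(grid,
            stats::approx(cal, mu, grid)$y,
            stats::approx(cal, sig, grid)$y)
}

#' Write a calibration curve in .14c format
#'
#' @param curve A [cal_curve()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_curve_14c <- function(curve, path) {
  writeLines(c("# calBP, 14C age (BP), 1-sigma error",
               sprintf("%g,%g,%g", curve$cal_bp, curve$mu, curve$sigma)),
             path)
  invisible(path)
}

#' Apply a marine reservoir offset to a curve
#'
#' Shifts the expected 14C age by the local reservoir offset `Delta R` and
#' adds its uncertainty in quadrature:
#' `mu <- mu + dR`, `sigma <- sqrt(sigma^2 + dR_sd^2)`.
#'
#' @param curve A [cal_curve()] (normally the marine curve).
#' @param delta_r_mean Offset mean, 14C years (negative in well-mixed
#'   Pacific surface waters).
#' @param delta_r_sd Offset uncertainty, 14C years (>= 0).
#' @return A [cal_curve()].
#' @export
apply_reservoir <- function(curve, delta_r_mean, delta_r_sd = 0) {
  stopifnot(inherits(curve, "cal_curve"), delta_r_sd >= 0)
  cal_curve(curve$cal_bp, curve$mu + delta_r_mean,
            sqrt(curve$sigma^2 + delta_r_sd^2))
}

#' Mix terrestrial and marine calibration curves for a marine-protein diet
#'
#' Blends the curves in the 14C-age domain according to the fraction `p` of
#' marine carbon in dietary protein:
#' `mu = (1-p) mu_T + p mu_M` and
#' `sigma^2 = (1-p)^2 sigma_T^2 + p^2 sigma_M^2 + sd_p^2 (mu_M - mu_T)^2`,
#' the first-order propagation of uncertainty in the diet fraction itself.
#'
#' @param terrestrial,marine [cal_curve()]s on a common calendar grid; apply
#'   any reservoir offset to the marine curve first.
#' @param marine_fraction Mean diet fraction `p` in `[0, 1]`.
#' @param marine_fraction_sd Uncertainty of `p` (default 0).
#' @return A [cal_curve()].
#' @export
mix_curves <- function(terrestrial, marine, marine_fraction,
                       marine_fraction_sd = 0) {
  stopifnot(inherits(terrestrial, "cal_curve"), inherits(marine, "cal_curve"))
  if (marine_fraction < 0 || marine_fraction > 1) {
    stop("marine_fraction must lie in [0, 1]", call. = FALSE)
  }
  if (length(terrestrial$cal_bp) != length(marine$cal_bp) ||
      any(terrestrial$cal_bp != marine$cal_bp)) {
    stop("curves are not on a common calendar grid", call. = FALSE)
  }
  p <- marine_fraction
  mu <- (1 - p) * terrestrial$mu + p * marine$mu
  sig <- sqrt((1 - p)^2 * terrestrial$sigma^2 + p^2 * marine$sigma^2 +
                marine_fraction_sd^2 * (marine$mu - terrestrial$mu)^2)
  cal_curve(terrestrial$cal_bp, mu, sig)
}

#' Calibrate a radiocarbon measurement
#'
#' Computes the posterior over calendar age under a flat calendar prior:
#' `posterior(cal) ~ Normal(age_14c; mu(cal), sqrt(sigma_m^2 + sigma(cal)^2))`
#' normalised over the grid. The curve is interpolated onto a fine internal
#' grid (default 1 year) so posterior moments and the highest-posterior-
#' density region are grid-robust; the HPD level is the conventional 95.4%.
#'
#' @param age_14c Measured 14C age, years BP.
#' @param sigma_m Measurement error, 14C years.
#' @param curve A [cal_curve()] (already reservoir-corrected / mixed).
#' @param level HPD mass (default 0.954).
#' @param step Internal calendar grid step, years.
#' @return A `calibrated_date`: `mean`, `sd`, `hpd` tibble
#'   (`old`, `young`, `mass` per interval), the envelope `hpd_range`, and
#'   the normalised `posterior` tibble.
#' @export
calibrate_14c <- function(age_14c, sigma_m, curve, level = 0.954, step = 1) {
  stopifnot(inherits(curve, "cal_curve"), sigma_m > 0)
  grid <- seq(min(curve$cal_bp), max(curve$cal_bp), by = step)
  mu <- stats::approx(curve$cal_bp, curve$mu, grid)$y
  sig <- stats::approx(curve$cal_bp, curve$sigma, grid)$y
  lik <- stats::dnorm(age_14c, mu, sqrt(sigma_m^2 + sig^2))
  total <- sum(lik)
  if (!is.finite(total) || total < 1e-12) {
    stop("measurement off curve: posterior mass vanishes everywhere", call. = FALSE)
  }
  post <- lik / total
  m <- sum(grid * post)
  s <- sqrt(sum((grid - m)^2 * post))

  o <- order(post, decreasing = TRUE)
  need <- o[seq_len(which(cumsum(post[o]) >= level)[1])]
  inside <- sort(need)
  brk <- which(diff(inside) > 1)
  starts <- c(1, brk + 1); ends <- c(brk, length(inside))
  hpd <- tibble::tibble(
    old = grid[inside[ends]], young = grid[inside[starts]],
    mass = vapply(seq_along(starts), function(i) {
      sum(post[inside[starts[i]]:inside[ends[i]]])
    }, numeric(1))
  )
  hpd <- dplyr::arrange(hpd, dplyr::desc(.data$old))
  structure(list(
    age_14c = age_14c, sigma_m = sigma_m,
    mean = m, sd = s, hpd = hpd,
    hpd_range = c(old = max(hpd$old), young = min(hpd$young)),
    level = level,
    posterior = tibble::tibble(cal_bp = grid, density = post)
  ), class = "calibrated_date")
}

#' @export
print.calibrated_date <- function(x, ...) {
  cat(sprintf(
    "<calibrated_date> %0.f +/- %.0f 14C BP -> %.0f +/- %.0f calBP (%.1f%% HPD %0.f-%0.f)\n",
    x$age_14c, x$sigma_m, x$mean, x$sd, 100 * x$level,
    x$hpd_range["old"], x$hpd_range["young"]))
  invisible(x)
}

#' @export
tidy.calibrated_date <- function(x, ...) x$hpd

#' @export
glance.calibrated_date <- function(x, ...) {
  tibble::tibble(mean = x$mean, sd = x$sd,
                 hpd_old = x$hpd_range[["old"]],
                 hpd_young = x$hpd_range[["young"]],
                 hpd_mass = sum(x$hpd$mass), n_intervals = nrow(x$hpd))
}

#' @export
autoplot.calibrated_date <- function(object, ...) {
  ggplot2::ggplot(object$posterior,
                  ggplot2::aes(.data$cal_bp, .data$density)) +
    ggplot2::geom_area(fill = "steelblue", alpha = 0.6) +
    ggplot2::geom_vline(xintercept = unname(object$hpd_range),
                        linetype = "dashed") +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "calendar age (calBP)", y = "posterior density") +
    ggplot2::theme_minimal()
}

#' Calibration sensitivity to reservoir offset and diet fraction
#'
#' Re-calibrates one measurement over a grid of marine reservoir offsets
#' (`Delta R`) and marine diet fractions, the two assumptions a mixed
#' marine/terrestrial calibration depends on.
#'
#' @param age_14c,sigma_m The measurement.
#' @param terrestrial,marine [cal_curve()]s on a common grid (marine
#'   *without* any reservoir correction; it is applied per cell).
#' @param delta_r Data frame with columns `mean`, `sd` (one row per offset),
#'   or a numeric vector of means (sd 0).
#' @param marine_fraction Data frame with columns `mean`, `sd`, or a numeric
#'   vector of means (sd 0).
#' @return A tibble with one row per (`Delta R`, diet) cell: the posterior
#'   mean, sd, HPD envelope, and the full `calibrated_date` in a `cal`
#'   list-column.
#' @export
sensitivity_grid <- function(age_14c, sigma_m, terrestrial, marine,
                             delta_r, marine_fraction) {
  delta_r <- as_mean_sd(delta_r, "delta_r")
  marine_fraction <- as_mean_sd(marine_fraction, "marine_fraction")
  if (nrow(delta_r) == 0 || nrow(marine_fraction) == 0) {
    stop("delta_r and marine_fraction must be non-empty", call. = FALSE)
  }
  cells <- tidyr::expand_grid(
    dr = seq_len(nrow(delta_r)), mf = seq_len(nrow(marine_fraction))
  )
  purrr::pmap_dfr(cells, function(dr, mf) {
    p_mean <- marine_fraction$mean[mf]; p_sd <- marine_fraction$sd[mf]
    mar <- apply_reservoir(marine, delta_r$mean[dr], delta_r$sd[dr])
    mixed <- mix_curves(terrestrial, mar, p_mean, p_sd)
    cal <- calibrate_14c(age_14c, sigma_m, mixed)
    tibble::tibble(
      delta_r_mean = delta_r$mean[dr], delta_r_sd = delta_r$sd[dr],
      marine_fraction = p_mean, marine_fraction_sd = p_sd,
      mean = cal$mean, sd = cal$sd,
      hpd_old = cal$hpd_range[["old"]], hpd_young = cal$hpd_range[["young"]],
      cal = list(cal)
    )
  })
}

as_mean_sd <- function(x, what) {
  if (is.data.frame(x)) {
    stopifnot(all(c("mean", "sd") %in% names(x)))
    tibble::tibble(mean = x$mean, sd = x$sd)
  } else {
    tibble::tibble(mean = as.numeric(x), sd = 0)
  }
}
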