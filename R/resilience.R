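# Mean-square displacement from elastic neutron-scattering intensities
# and the macromolecular resilience estimate.

#' Extract MSD(T) from an elastic scan
#'
#' Per temperature, fits ln S vs q^2 by (weighted) least squares over the
#' instrument q-range and inverts the Gaussian approximation
#' S(q, dt) = exp(-q^2 <x^2> / 6): <x^2> = -6 x slope. Weights are
#' S^2 / sigma_S^2 (delta method for the log transform) when intensity
#' uncertainties are available and positive, unit otherwise.
#'
#' @param scan data frame with columns `temperature`, `q`, `S` and
#'   optionally `sigma_S` (as from [synth_elastic_scan()]).
#' @param q_range q window used for the fit, 1/Angstrom.
#' @param weighted use intensity uncertainties as weights.
#' @return Data frame of class `msd_series`: `temperature`, `msd`, `se`.
#' @export
msd_from_scan <- function(scan, q_range = c(0.27, 1.97), weighted = TRUE) {
  stopifnot(all(c("temperature", "q", "S") %in% names(scan)))
  temps <- sort(unique(scan$temperature))
  rows <- lapply(temps, function(tt) {
    sub <- scan[scan$temperature == tt & scan$q >= q_range[1] &
                  scan$q <= q_range[2], , drop = FALSE]
    if (nrow(sub) < 3)
      stop(sprintf("fewer than 3 q points in range at T = %g K", tt))
    if (any(sub$S <= 0))
      stop(sprintf("non-positive intensities in q range at T = %g K", tt))
    w <- NULL
    if (weighted && "sigma_S" %in% names(sub) && all(sub$sigma_S > 0))
      w <- sub$S^2 / sub$sigma_S^2
    fit <- lm(log(S) ~ I(q^2), data = sub, weights = w)
    sl <- coef(fit)[["I(q^2)"]]
    # noiseless scans fit exactly; the zero-variance summary is still valid
    se <- suppressWarnings(
      summary(fit)$coefficients["I(q^2)", "Std. Error"])
    data.frame(temperature = tt, msd = -6 * sl, se = 6 * se)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("msd_series", class(out))
  out
}

#' Fit macromolecular resilience from an MSD series
#'
#' Weighted straight-line fit of MSD vs temperature (weights 1/se^2 when
#' standard errors are present, unit otherwise; for a linear model the
#' Levenberg-Marquardt solution coincides with weighted least squares),
#' then k' = `constant` / slope with the error propagated from the slope
#' standard error. The conversion constant 0.00276 yields N/m for MSD in
#' Angstrom^2 and T in K.
#'
#' @param msd `msd_series` data frame (`temperature`, `msd`, optional
#'   `se`).
#' @param t_range optional temperature window, K.
#' @param constant force-constant conversion (default 0.00276).
#' @return List with `k_prime`, `k_error` (N/m), `slope`, `slope_se`
#'   (Angstrom^2/K), `intercept`, `n`, `t_range`.
#' @export
fit_resilience <- function(msd, t_range = NULL, constant = 0.00276) {
  d <- as.data.frame(msd)
  if (!is.null(t_range))
    d <- d[d$temperature >= t_range[1] & d$temperature <= t_range[2], ]
  if (nrow(d) < 3) stop("need at least 3 temperatures in range")
  w <- NULL
  if ("se" %in% names(d) && all(is.finite(d$se)) && all(d$se > 0))
    w <- 1 / d$se^2
  fit <- lm(msd ~ temperature, data = d, weights = w)
  sl <- coef(fit)[["temperature"]]
  se <- suppressWarnings(
    summary(fit)$coefficients["temperature", "Std. Error"])
  if (sl <= 0) stop("non-physical softening: MSD slope is not positive")
  list(k_prime = constant / sl, k_error = constant * se / sl^2,
       slope = sl, slope_se = se,
       intercept = coef(fit)[["(Intercept)"]], n = nrow(d),
       t_range = range(d$temperature))
}
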