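# Flux partitioning: fit a Lloyd-Taylor respiration law to nighttime NEE,
# extrapolate to daytime, and subtract daytime NEE to obtain "observed" GPP.

#' Lloyd-Taylor respiration law
#'
#' `R(T) = r_ref * exp(e0 * (1/(t_ref - t0) - 1/(T - t0)))`, the standard
#' exponential temperature response used for ecosystem respiration, with
#' fixed reference temperature `t_ref = 15` degC and shift `t0 = -46.02`
#' degC.
#'
#' @param t temperature (degC), vectorized; must exceed `t0`.
#' @param r_ref respiration at the reference temperature (same units as the
#'   returned rate, here g C m-2 day-1 full-day equivalent).
#' @param e0 temperature sensitivity (K).
#' @param t_ref,t0 reference and shift temperatures (degC).
#' @return respiration rate.
#' @export
lloyd_taylor <- function(t, r_ref, e0, t_ref = 15, t0 = -46.02) {
  r_ref * exp(e0 * (1 / (t_ref - t0) - 1 / (t - t0)))
}

#' Fit nighttime respiration
#'
#' Nonlinear least squares of the Lloyd-Taylor law against nighttime
#' respiration rates (nighttime NEE expressed as positive efflux,
#' normalized to a full-day-equivalent rate). Starting values come from a
#' log-linear regression; the fit is bounded to positive `r_ref` and `e0`.
#' A single fit per site stands in for the moving-window temperature-
#' sensitivity estimation of the full tower-processing algorithm.
#'
#' @param night_t nighttime temperature series (degC).
#' @param night_resp nighttime respiration rate series (positive efflux).
#' @param t_ref,t0 fixed law constants (degC).
#' @param min_n minimum number of usable points (default 10).
#' @return object of class `respiration_fit` with fields `r_ref`, `e0`,
#'   `t_ref`, `t0`, `rss`, `n_nights`.
#' @export
fit_nighttime_respiration <- function(night_t, night_resp, t_ref = 15,
                                      t0 = -46.02, min_n = 10) {
  ok <- !is.na(night_t) & !is.na(night_resp)
  night_t <- night_t[ok]
  night_resp <- night_resp[ok]
  n <- length(night_t)
  if (n < min_n)
    stop("respiration fit error: only ", n, " usable nights (need ",
         min_n, ")")
  if (stats::sd(night_t) < 1e-8)
    stop("respiration fit error: constant nighttime temperature, ",
         "e0 unidentifiable")
  x <- 1 / (t_ref - t0) - 1 / (night_t - t0)
  pos <- night_resp > 0
  start <- if (sum(pos) >= 2L && stats::sd(x[pos]) > 0) {
    cf <- stats::coef(stats::lm(log(night_resp[pos]) ~ x[pos]))
    list(r_ref = exp(cf[[1]]), e0 = max(cf[[2]], 10))
  } else {
    list(r_ref = max(mean(night_resp), 0.1), e0 = 200)
  }
  fit <- tryCatch(
    stats::nls(night_resp ~ r_ref * exp(e0 * x),
               start = start, algorithm = "port",
               lower = c(r_ref = 1e-8, e0 = 1e-3),
               control = stats::nls.control(maxiter = 200,
                                            warnOnly = FALSE)),
    error = function(e) stop("respiration fit did not converge: ",
                             conditionMessage(e)))
  cf <- stats::coef(fit)
  structure(list(r_ref = unname(cf["r_ref"]), e0 = unname(cf["e0"]),
                 t_ref = t_ref, t0 = t0,
                 rss = sum(stats::resid(fit)^2), n_nights = n),
            class = "respiration_fit")
}

#' @export
print.respiration_fit <- function(x, ...) {
  cat(sprintf(
    "<respiration_fit> r_ref = %.4g g C m-2 d-1 at %.3g degC, e0 = %.4g K\n",
    x$r_ref, x$t_ref, x$e0))
  cat(sprintf("  %d nights, rss = %.4g\n", x$n_nights, x$rss))
  invisible(x)
}

#' Fit a site's respiration law from its nighttime NEE
#'
#' Convenience wrapper extracting the nighttime temperature
#' (`(t_avg + t_min) / 2`) and the nighttime NEE normalized from a
#' per-night integral to a full-day-equivalent rate using the night
#' fraction from the site latitude and day of year.
#'
#' @param series a [site_series()] with `nee_night` and latitude.
#' @param ... passed to [fit_nighttime_respiration()].
#' @return a `respiration_fit`.
#' @export
fit_site_respiration <- function(series, ...) {
  stopifnot(inherits(series, "site_series"))
  if (is.na(series$latitude)) stop("series has no latitude")
  rec <- series$records
  nf <- 1 - day_fraction(series$latitude, doy_of(rec$date))
  usable <- nf > 1e-6
  fit_nighttime_respiration(nighttime_temp(rec$t_avg, rec$t_min)[usable],
                            (rec$nee_night / nf)[usable], ...)
}

#' Partition NEE into observed GPP
#'
#' Daytime ecosystem respiration is the fitted law evaluated at daytime
#' temperature (`(t_avg + t_max) / 2`), scaled by the daytime fraction of
#' the day; GPP is then respiration minus daytime NEE, so net daytime
#' uptake (negative NEE) yields positive GPP. Negative GPP values are
#' floored at zero and counted.
#'
#' @param series a [site_series()] with `nee_day` and latitude.
#' @param fit a `respiration_fit`, by default fitted from the series' own
#'   nighttime NEE.
#' @return data.frame with columns `date`, `reco_day`, `gpp`; the number of
#'   floored days is attached as attribute `n_floored` (and messaged).
#' @export
partition_gpp <- function(series, fit = fit_site_respiration(series)) {
  stopifnot(inherits(series, "site_series"),
            inherits(fit, "respiration_fit"))
  rec <- series$records
  df <- day_fraction(series$latitude, doy_of(rec$date))
  reco_day <- lloyd_taylor(daytime_temp(rec$t_avg, rec$t_max),
                           fit$r_ref, fit$e0, fit$t_ref, fit$t0) * df
  gpp <- reco_day - rec$nee_day
  n_floored <- sum(gpp < 0, na.rm = TRUE)
  if (n_floored) message(n_floored, " partitioned day(s) floored at 0")
  gpp <- pmax(gpp, 0)
  out <- data.frame(date = rec$date, reco_day = reco_day, gpp = gpp)
  attr(out, "n_floored") <- n_floored
  out
}
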