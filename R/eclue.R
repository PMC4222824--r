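# Light-use-efficiency GPP model: GPP = eps_max * fPAR * PAR * stress,
# with a quadratic cardinal-temperature scalar and an evaporative-fraction
# (inverse Bowen ratio) moisture scalar.

#' Light-use-efficiency model parameters
#'
#' The model structure is fixed (linear NDVI-to-fPAR mapping, quadratic
#' temperature scalar, `LE/(LE+H)` moisture scalar, stresses combined by
#' minimum); every coefficient is a configuration knob. `eps_max` is
#' expressed in g C per mol of absorbed quanta here; the common
#' g C MJ-1 figure converts at roughly 4.6 mol PAR per MJ (the default
#' 0.465 g C mol-1 corresponds to about 2.14 g C MJ-1).
#'
#' @param eps_max potential light use efficiency (g C mol-1 quanta).
#' @param t_min,t_opt,t_max cardinal temperatures (degC), `t_min < t_opt <
#'   t_max`.
#' @param fpar_slope,fpar_intercept linear NDVI to fPAR coefficients.
#' @param stress_combine `"min"` (default) or `"product"`.
#' @return an object of class `lue_params`.
#' @export
lue_params <- function(eps_max = 0.465, t_min = 0, t_opt = 20.33,
                       t_max = 40, fpar_slope = 1.24,
                       fpar_intercept = -0.168,
                       stress_combine = c("min", "product")) {
  stopifnot(eps_max > 0, t_min < t_opt, t_opt < t_max)
  structure(list(eps_max = eps_max, t_min = t_min, t_opt = t_opt,
                 t_max = t_max, fpar_slope = fpar_slope,
                 fpar_intercept = fpar_intercept,
                 stress_combine = match.arg(stress_combine)),
            class = "lue_params")
}

#' Temperature stress scalar
#'
#' `Ts = (t - t_min)(t - t_max) / ((t - t_min)(t - t_max) - (t - t_opt)^2)`,
#' clamped to `[0, 1]` and zero outside the open interval
#' `(t_min, t_max)`. Equals 1 at the optimum.
#'
#' @param t air temperature (degC), vectorized.
#' @param params a [lue_params()].
#' @return stress in `[0, 1]`.
#' @export
temperature_stress <- function(t, params) {
  num <- (t - params$t_min) * (t - params$t_max)
  den <- num - (t - params$t_opt)^2
  ts <- ifelse(den == 0, 0, num / den)
  ts[t <= params$t_min | t >= params$t_max] <- 0
  clamp(ts, 0, 1)
}

#' Moisture stress scalar from the Bowen ratio
#'
#' The evaporative fraction `Ws = LE / (LE + H)`, i.e. the inverse-Bowen-
#' ratio form, clamped to `[0, 1]`. Days with non-positive available energy
#' (`LE + H <= 0`) have no defined stress and yield `NA` (with a warning),
#' or an error when `strict = TRUE`; such days are excluded downstream.
#'
#' @param le latent heat flux (W m-2).
#' @param h sensible heat flux (W m-2).
#' @param strict error instead of flagging undefined days.
#' @return stress in `[0, 1]`, `NA` where undefined.
#' @export
moisture_stress <- function(le, h, strict = FALSE) {
  bad <- (le + h) <= 0
  if (any(bad)) {
    if (strict) stop("undefined moisture stress: LE + H <= 0")
    warning(sum(bad), " day(s) with LE + H <= 0 flagged as undefined")
  }
  ws <- ifelse(bad, NA_real_, le / (le + h))
  clamp(ws, 0, 1)
}

#' Daily GPP from the light-use-efficiency model
#'
#' `GPP = eps_max * fPAR * PAR * f(Ts, Ws)` with
#' `fPAR = clamp(slope * NDVI + intercept, 0, 1)` and `f` the minimum (or,
#' optionally, the product) of the temperature and moisture stress scalars.
#'
#' @param par daily incident PAR (mol quanta m-2 day-1).
#' @param ndvi NDVI in `[0, 1]`.
#' @param t air temperature (degC).
#' @param le,h latent/sensible heat flux (W m-2).
#' @param params a [lue_params()].
#' @return daily GPP (g C m-2 day-1), `NA` where moisture stress is
#'   undefined.
#' @export
eclue_daily_gpp <- function(par, ndvi, t, le, h, params = lue_params()) {
  stopifnot(all(ndvi >= 0 & ndvi <= 1, na.rm = TRUE))
  fpar <- clamp(params$fpar_slope * ndvi + params$fpar_intercept, 0, 1)
  ts <- temperature_stress(t, params)
  ws <- moisture_stress(le, h)
  stress <- if (params$stress_combine == "product") ts * ws else pmin(ts, ws)
  params$eps_max * fpar * par * stress
}

#' Run the LUE model over a site series
#'
#' Daily GPP from the series' drivers and its (gap-filled,
#' daily-interpolated) 8-day NDVI.
#'
#' @param series a [site_series()] with an `ndvi` component.
#' @param params a [lue_params()].
#' @return numeric vector of daily GPP (g C m-2 day-1).
#' @export
eclue_gpp <- function(series, params = lue_params()) {
  stopifnot(inherits(series, "site_series"))
  rec <- series$records
  ndvi <- interp_to_daily(series$ndvi, rec$date)
  eclue_daily_gpp(rec$par, ndvi, rec$t_avg, rec$le, rec$h, params)
}

#' Calibrate the potential light use efficiency
#'
#' One-parameter least squares of `eps_max` against observed GPP: since the
#' model is linear in `eps_max`, the optimum is the closed-form ratio
#' `sum(x * obs) / sum(x^2)` with `x` the per-day product of the remaining
#' factors. Days with undefined stress or missing observations are dropped.
#'
#' @param series a [site_series()] with `gpp_obs` and NDVI.
#' @param params a [lue_params()] providing the other coefficients.
#' @return a [lue_params()] with the fitted `eps_max`.
#' @export
fit_eps_max <- function(series, params = lue_params()) {
  obs <- series$records$gpp_obs
  unit <- params
  unit$eps_max <- 1
  x <- eclue_gpp(series, unit)
  ok <- !is.na(x) & !is.na(obs)
  if (sum(ok) < 2L || sum(x[ok]^2) == 0)
    stop("cannot calibrate eps_max: no usable days")
  params$eps_max <- sum(x[ok] * obs[ok]) / sum(x[ok]^2)
  params
}
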