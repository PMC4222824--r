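# Leaf-level C3 (Farquhar) and C4 (Collatz) gross photosynthesis with
# Q10 temperature kinetics, scaled to canopy daily GPP through a single
# big leaf with Beer's-law light absorption.

#' Leaf photosynthesis parameters
#'
#' All leaf-level constants of the forward model. Defaults follow the
#' Farquhar/Collatz model lineage; none of them is asserted as a measured
#' value and every one is a configuration knob. Units are SI mole fractions
#' and mol CO2 m-2 s-1 rates.
#'
#' @param vcmax25 maximum Rubisco carboxylation rate at 25 degC
#'   (mol CO2 m-2 s-1).
#' @param alpha3,alpha4 intrinsic quantum efficiencies of CO2 uptake for the
#'   C3 and C4 pathways (mol CO2 per mol absorbed quanta).
#' @param kc25,ko25 Michaelis-Menten coefficients for CO2 and O2 at 25 degC
#'   (mol mol-1).
#' @param tau25 Rubisco specificity factor at 25 degC (dimensionless); the
#'   CO2 compensation point is `o2 / (2 * tau)`.
#' @param o2 intercellular O2 mole fraction (mol mol-1).
#' @param tpu_ratio triose-phosphate-limited capacity as a fraction of the
#'   (temperature-adjusted) Vcmax; default 1/2.2.
#' @param k_c4 initial slope of the C4 CO2 response (mol m-2 s-1).
#' @param q10_vm,q10_kc,q10_ko,q10_tau Q10 temperature coefficients;
#'   `q10_tau < 1` makes specificity fall (and the compensation point rise)
#'   with temperature.
#' @param ci_ca_c3,ci_ca_c4 fixed intercellular-to-ambient CO2 ratios used
#'   in place of a stomatal-conductance closure.
#' @param ca ambient CO2 mole fraction (mol mol-1).
#' @param colimit `"min"` for a hard minimum of the limiting rates (the
#'   default), `"quadratic"` for smoothed colimitation.
#' @param theta_cl,beta_cl coupling coefficients of the quadratic mode
#'   (light/Rubisco, then with the third capacity).
#' @return an object of class `photo_params`.
#' @export
photo_params <- function(vcmax25 = 65e-6,
                         alpha3 = 0.060, alpha4 = 0.050,
                         kc25 = 1.5e-4, ko25 = 0.25, tau25 = 4500,
                         o2 = 0.209, tpu_ratio = 1 / 2.2, k_c4 = 0.7,
                         q10_vm = 2.0, q10_kc = 2.1, q10_ko = 1.2,
                         q10_tau = 0.57,
                         ci_ca_c3 = 0.7, ci_ca_c4 = 0.4, ca = 370e-6,
                         colimit = c("min", "quadratic"),
                         theta_cl = 0.970, beta_cl = 0.990) {
  p <- list(vcmax25 = vcmax25, alpha3 = alpha3, alpha4 = alpha4,
            kc25 = kc25, ko25 = ko25, tau25 = tau25, o2 = o2,
            tpu_ratio = tpu_ratio, k_c4 = k_c4,
            q10_vm = q10_vm, q10_kc = q10_kc, q10_ko = q10_ko,
            q10_tau = q10_tau, ci_ca_c3 = ci_ca_c3, ci_ca_c4 = ci_ca_c4,
            ca = ca, colimit = match.arg(colimit),
            theta_cl = theta_cl, beta_cl = beta_cl)
  rates <- unlist(p[c("vcmax25", "alpha3", "alpha4", "kc25", "ko25",
                      "tau25", "o2", "tpu_ratio", "k_c4", "ca")])
  q10s <- unlist(p[c("q10_vm", "q10_kc", "q10_ko", "q10_tau")])
  stopifnot(all(rates >= 0), all(q10s > 0),
            p$ci_ca_c3 > 0, p$ci_ca_c3 <= 1,
            p$ci_ca_c4 > 0, p$ci_ca_c4 <= 1)
  structure(p, class = "photo_params")
}

#' Leaf environment
#'
#' @param qp flux density of PAR absorbed by the leaf
#'   (mol quanta m-2 s-1).
#' @param ci intercellular CO2 mole fraction (mol mol-1).
#' @param t_leaf leaf temperature (degC).
#' @return a list of the three (recycled) vectors.
#' @export
leaf_env <- function(qp, ci, t_leaf) {
  stopifnot(all(qp >= 0), all(ci >= 0))
  n <- max(length(qp), length(ci), length(t_leaf))
  list(qp = rep_len(qp, n), ci = rep_len(ci, n),
       t_leaf = rep_len(t_leaf, n))
}

#' Temperature-adjusted kinetic constants
#'
#' Scales Vcmax and the Michaelis-Menten coefficients by
#' `q10^((T - 25) / 10)` and derives the CO2 compensation point
#' `gamma_star = o2 / (2 * tau)` from the temperature-adjusted specificity.
#'
#' @param params a [photo_params()].
#' @param t_leaf leaf temperature (degC), vectorized.
#' @return list with components `vm`, `kc`, `ko`, `gamma_star`.
#' @export
kinetics_at_temperature <- function(params, t_leaf) {
  f <- function(q10) q10^((t_leaf - 25) / 10)
  tau <- params$tau25 * f(params$q10_tau)
  list(vm = params$vcmax25 * f(params$q10_vm),
       kc = params$kc25 * f(params$q10_kc),
       ko = params$ko25 * f(params$q10_ko),
       gamma_star = params$o2 / (2 * tau))
}

limiting_rates <- function(je, jc, js, colimit, theta, beta) {
  gross <- if (colimit == "quadratic") {
    quad_colimit(quad_colimit(je, jc, theta), js, beta)
  } else {
    pmin(je, jc, js)
  }
  lab <- c("light", "rubisco", "export")
  limiter <- lab[max.col(-cbind(je, jc, js), ties.method = "first")]
  data.frame(je = je, jc = jc, js = js, gross = gross, limiter = limiter,
             stringsAsFactors = FALSE)
}

#' C3 gross photosynthesis rate
#'
#' Gross assimilation as the minimum of the light-limited rate
#' `JE = alpha3 * qp * (ci - g*) / (ci + 2 g*)`, the Rubisco-limited rate
#' `JC = vm * (ci - g*) / (ci + kc (1 + o2/ko))`, and the
#' triose-phosphate-export-limited rate `JS = tpu_ratio * vm`, with kinetics
#' temperature-adjusted internally. Below the compensation point `g*` the
#' carboxylation-driven rates are floored at zero, so gross assimilation is
#' never negative.
#'
#' @param env a [leaf_env()].
#' @param params a [photo_params()].
#' @return data.frame with columns `je`, `jc`, `js`, `gross`
#'   (mol CO2 m-2 s-1) and `limiter`.
#' @export
c3_gross_rate <- function(env, params) {
  k <- kinetics_at_temperature(params, env$t_leaf)
  grad <- pmax(env$ci - k$gamma_star, 0)
  je <- params$alpha3 * env$qp * grad / (env$ci + 2 * k$gamma_star)
  jc <- k$vm * grad / (env$ci + k$kc * (1 + params$o2 / k$ko))
  js <- params$tpu_ratio * k$vm
  limiting_rates(je, jc, js, params$colimit, params$theta_cl,
                 params$beta_cl)
}

#' C4 gross photosynthesis rate
#'
#' Minimum of three capacities: light-limited `JE = alpha4 * qp`,
#' Rubisco-limited `JC = vm`, and the CO2-limited response at low
#' intercellular CO2, `JS = k_c4 * ci`.
#'
#' @inheritParams c3_gross_rate
#' @return data.frame as for [c3_gross_rate()].
#' @export
c4_gross_rate <- function(env, params) {
  k <- kinetics_at_temperature(params, env$t_leaf)
  je <- params$alpha4 * env$qp
  jc <- k$vm
  js <- params$k_c4 * env$ci
  limiting_rates(je, jc, js, params$colimit, params$theta_cl,
                 params$beta_cl)
}

#' Canopy daily GPP for one or more days
#'
#' Big-leaf scaling of the leaf rate: mean daytime absorbed PAR is the
#' daily PAR total spread over the daylength and reduced by Beer's-law
#' canopy absorption `1 - exp(-k_ext * lai)`; the leaf model is evaluated
#' at the daily mean air temperature with `ci = ci_ca * ca`; the resulting
#' rate is integrated over the daylength and converted to grams of carbon.
#'
#' @param t_avg daily mean air temperature (degC).
#' @param par daily incident PAR (mol quanta m-2 day-1).
#' @param doy day of year.
#' @param latitude degrees.
#' @param lai leaf area index (m2 m-2), `>= 0`.
#' @param params a [photo_params()].
#' @param pathway `"C3"` or `"C4"`.
#' @param k_ext canopy light-extinction coefficient (default 0.5).
#' @return daily GPP, g C m-2 day-1 (vectorized).
#' @export
canopy_daily_gpp <- function(t_avg, par, doy, latitude, lai, params,
                             pathway = c("C3", "C4"), k_ext = 0.5) {
  pathway <- match.arg(pathway)
  if (any(lai < 0)) stop("negative LAI")
  fn <- make_canopy_gpp_fn(t_avg, par, doy, latitude, lai, params, pathway,
                           k_ext)
  fn(params$vcmax25)
}

# Builds a closure mapping vcmax25 -> daily GPP with all vcmax-independent
# per-day quantities precomputed. This is the single forward path: both
# canopy_daily_gpp() and the MCMC likelihood call it, the latter thousands
# of times with different vcmax.
make_canopy_gpp_fn <- function(t_avg, par, doy, latitude, lai, params,
                               pathway, k_ext = 0.5) {
  dl_s <- daylength_hours(latitude, doy) * 3600
  absorbed <- (1 - exp(-k_ext * lai))
  qp <- ifelse(dl_s > 0, par / dl_s, 0) * absorbed
  conv <- dl_s * GRAMS_C_PER_MOL
  f10 <- function(q10) q10^((t_avg - 25) / 10)
  fvm <- f10(params$q10_vm)
  if (pathway == "C3") {
    gamma_star <- params$o2 / (2 * params$tau25 * f10(params$q10_tau))
    kc <- params$kc25 * f10(params$q10_kc)
    ko <- params$ko25 * f10(params$q10_ko)
    ci <- params$ci_ca_c3 * params$ca
    grad <- pmax(ci - gamma_star, 0)
    je <- params$alpha3 * qp * grad / (ci + 2 * gamma_star)
    # JC = vcmax25 * fvm * fc ; JS = vcmax25 * fvm * tpu_ratio
    fc <- grad / (ci + kc * (1 + params$o2 / ko))
  } else {
    ci <- params$ci_ca_c4 * params$ca
    je <- params$alpha4 * qp
    fc <- 1
  }
  colimit <- params$colimit
  theta <- params$theta_cl
  beta <- params$beta_cl
  tpu <- params$tpu_ratio
  k_c4 <- params$k_c4
  function(vcmax25) {
    vm <- vcmax25 * fvm
    if (pathway == "C3") {
      jc <- vm * fc
      js <- tpu * vm
    } else {
      jc <- vm
      js <- rep_len(k_c4 * ci, length(jc))
    }
    gross <- if (colimit == "quadratic") {
      quad_colimit(quad_colimit(je, jc, theta), js, beta)
    } else {
      pmin(je, jc, js)
    }
    gross * conv
  }
}

#' Forward daily GPP over a site series
#'
#' Runs the canopy model over every day of a series, taking the leaf area
#' index from the series' (gap-filled, daily-interpolated) 8-day LAI.
#'
#' @param series a [site_series()] with an `lai` component and latitude.
#' @param params a [photo_params()]; when `NULL`, the PFT catalogue default
#'   Vcmax for `series$pft` is used.
#' @param pathway `"C3"` or `"C4"`; default from the PFT catalogue.
#' @param k_ext canopy light-extinction coefficient.
#' @return numeric vector of daily GPP (g C m-2 day-1).
#' @export
forward_gpp <- function(series, params = NULL, pathway = NULL, k_ext = 0.5) {
  stopifnot(inherits(series, "site_series"))
  if (is.na(series$latitude)) stop("series has no latitude")
  entry <- pft_entry(series$pft)
  params <- params %||% photo_params(vcmax25 = entry$vcmax_default)
  pathway <- pathway %||% entry$pathway
  rec <- series$records
  lai <- interp_to_daily(series$lai, rec$date)
  canopy_daily_gpp(rec$t_avg, rec$par, doy_of(rec$date), series$latitude,
                   lai, params, pathway, k_ext)
}
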