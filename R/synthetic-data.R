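# Synthetic sites with known truth: seeded seasonal meteorology, 8-day
# NDVI/LAI with quality flags, and NEE manufactured from a chosen true
# Vcmax plus Lloyd-Taylor respiration, so partitioning, inversion and the
# validation metrics can be exercised end to end.

#' Configuration of a synthetic site
#'
#' @param site_id short token.
#' @param pft PFT label; `true_vcmax` must lie within the catalogue
#'   inversion bounds for this PFT.
#' @param latitude degrees.
#' @param n_years integer number of 365-day years.
#' @param true_vcmax the generating Vcmax25 (mol CO2 m-2 s-1).
#' @param gpp_noise_sd observation noise on daily GPP/NEE
#'   (g C m-2 day-1); a free knob, not an empirical claim.
#' @param resp_ref,resp_e0 Lloyd-Taylor parameters of the generating
#'   respiration (g C m-2 day-1 at 15 degC; K).
#' @param ndvi_flag_frac fraction of 8-day points flagged unreliable.
#' @param weather_noise scale factor on the meteorological noise terms
#'   (0 gives exactly sinusoidal temperature).
#' @param seed integer seed; all generator randomness derives from it.
#' @return an object of class `synthetic_site_config`.
#' @export
synthetic_site_config <- function(site_id = "SYN-001",
                                  pft = "Temperate broadleaf trees",
                                  latitude = 45, n_years = 2,
                                  true_vcmax = 40e-6, gpp_noise_sd = 0.5,
                                  resp_ref = 2, resp_e0 = 200,
                                  ndvi_flag_frac = 0.1, weather_noise = 1,
                                  seed = 1) {
  stopifnot(n_years >= 1, gpp_noise_sd >= 0, weather_noise >= 0,
            ndvi_flag_frac >= 0, ndvi_flag_frac <= 1)
  entry <- pft_entry(pft)
  if (true_vcmax < entry$vcmax_lo || true_vcmax > entry$vcmax_hi)
    stop("true_vcmax outside the catalogue bounds for ", pft)
  structure(list(site_id = site_id, pft = normalize_pft(pft),
                 latitude = latitude, n_years = as.integer(n_years),
                 true_vcmax = true_vcmax, gpp_noise_sd = gpp_noise_sd,
                 resp_ref = resp_ref, resp_e0 = resp_e0,
                 ndvi_flag_frac = ndvi_flag_frac,
                 weather_noise = weather_noise, seed = as.integer(seed)),
            class = "synthetic_site_config")
}

# Seasonal phase: temperature/radiation peak near day 200 in the northern
# hemisphere, half a year later in the southern.
season_peak <- function(latitude) if (latitude >= 0) 200 else 18

#' Generate daily meteorology for a synthetic site
#'
#' Temperature follows a latitude-dependent sinusoid (warmer and less
#' seasonal toward the equator) plus Gaussian noise; daily PAR follows the
#' daylength cycle reduced by a random cloud fraction; latent/sensible heat
#' split an energy proxy by a seasonal evaporative fraction. Identical
#' seeds give identical output, and no global RNG state leaks.
#'
#' @param config a [synthetic_site_config()].
#' @return a [site_series()] with drivers only (fluxes `NA`).
#' @export
generate_weather <- function(config) {
  stopifnot(inherits(config, "synthetic_site_config"))
  n <- config$n_years * 365L
  dates <- as.Date("2001-01-01") + seq_len(n) - 1L
  doy <- ((seq_len(n) - 1L) %% 365L) + 1L
  lat <- config$latitude
  wn <- config$weather_noise
  peak <- season_peak(lat)
  season <- cos(2 * pi * (doy - peak) / 365)
  with_seed(config$seed, {
    t_base <- 27 - 0.38 * abs(lat)
    t_amp <- 0.32 * abs(lat) + 1
    t_avg <- t_base + t_amp * season + stats::rnorm(n, 0, 1.5 * wn)
    drange <- pmax(8 + stats::rnorm(n, 0, 1.5 * wn), 1)
    dl <- daylength_hours(lat, doy)
    cloud_frac <- stats::plogis(stats::qlogis(0.4) +
                                  stats::rnorm(n, 0, 0.9 * max(wn, 1e-9)))
    par <- 95 * (dl / 24)^2 * (1 - 0.7 * cloud_frac)
    rh <- clamp(60 + 25 * cloud_frac + stats::rnorm(n, 0, 8 * wn), 5, 100)
    wet <- stats::runif(n) < 0.25 + 0.2 * cloud_frac
    precip <- ifelse(wet, stats::rexp(n, rate = 1 / 4), 0)
    energy <- par * 4.6 # crude available-energy proxy, W m-2
    ef <- stats::plogis(0.8 * season + stats::rnorm(n, 0, 0.4 * wn))
    records <- data.frame(date = dates, t_avg = t_avg,
                          t_max = t_avg + drange / 2,
                          t_min = t_avg - drange / 2,
                          rh = rh, precip = precip, par = par,
                          cloud_frac = cloud_frac,
                          le = ef * energy, h = (1 - ef) * energy)
    site_series(config$site_id, config$pft, records, latitude = lat)
  })
}

#' Generate 8-day NDVI and LAI with quality flags
#'
#' Both indices track a smoothed growing-season signal derived from the
#' weather series' temperature (so greenness co-varies with warmth), with
#' a configured fraction of points flagged unreliable and corrupted, the
#' way cloud-contaminated satellite retrievals bias low.
#'
#' @param config a [synthetic_site_config()].
#' @param weather a [site_series()] from [generate_weather()].
#' @return the series with `ndvi` and `lai` components attached
#'   (`ceiling(n_days / 8)` points each).
#' @export
generate_ndvi_lai <- function(config, weather) {
  stopifnot(inherits(weather, "site_series"))
  rec <- weather$records
  n <- nrow(rec)
  idx <- seq(1L, n, by = 8L)
  smooth_t <- stats::filter(rec$t_avg, rep(1 / 17, 17), sides = 2)
  smooth_t[is.na(smooth_t)] <- rec$t_avg[is.na(smooth_t)]
  g <- clamp(as.numeric(smooth_t[idx]) / 20, 0, 1)
  with_seed(config$seed + 1L, {
    ndvi <- clamp(0.15 + 0.65 * g + stats::rnorm(length(idx), 0, 0.02),
                  0, 1)
    lai <- pmax(6 * g^1.2 + stats::rnorm(length(idx), 0, 0.1), 0)
    flag <- stats::runif(length(idx)) < config$ndvi_flag_frac
    corrupt <- stats::runif(length(idx), 0.2, 0.8)
    weather$ndvi <- data.frame(date = rec$date[idx],
                               value = ifelse(flag, ndvi * corrupt, ndvi),
                               qc = as.integer(flag))
    weather$lai <- data.frame(date = rec$date[idx],
                              value = ifelse(flag, lai * corrupt, lai),
                              qc = as.integer(flag))
  })
  weather
}

#' Simulate tower observations from a known truth
#'
#' The generating GPP is the package's own forward canopy model run at the
#' configured true Vcmax; respiration follows the Lloyd-Taylor law with the
#' configured parameters, split into day/night integrals by daylength.
#' Daily observed GPP is truth plus Gaussian noise, and daytime NEE is
#' daytime respiration minus that same noisy GPP (so the information the
#' partitioner can recover is consistent); nighttime NEE gets an
#' independent noise draw. The noise-free generating series are attached as
#' attribute `truth` (components `gpp_true`, `reco_day`, `reco_night`).
#'
#' @param config a [synthetic_site_config()].
#' @param drivers a [site_series()] with drivers and LAI (see
#'   [generate_ndvi_lai()]).
#' @param params optional [photo_params()]; defaults to the catalogue
#'   parameter set for `config$pft` with `vcmax25 = config$true_vcmax`.
#' @return the series with `nee_day`, `nee_night`, `gpp_obs` filled.
#' @export
simulate_observations <- function(config, drivers, params = NULL) {
  stopifnot(inherits(config, "synthetic_site_config"),
            inherits(drivers, "site_series"))
  entry <- pft_entry(config$pft)
  params <- params %||% photo_params(vcmax25 = config$true_vcmax)
  gpp_true <- forward_gpp(drivers, params, pathway = entry$pathway)
  rec <- drivers$records
  df <- day_fraction(config$latitude, doy_of(rec$date))
  reco_day <- lloyd_taylor(daytime_temp(rec$t_avg, rec$t_max),
                           config$resp_ref, config$resp_e0) * df
  reco_night <- lloyd_taylor(nighttime_temp(rec$t_avg, rec$t_min),
                             config$resp_ref, config$resp_e0) * (1 - df)
  with_seed(config$seed + 2L, {
    eps_day <- stats::rnorm(nrow(rec), 0, config$gpp_noise_sd)
    eps_night <- stats::rnorm(nrow(rec), 0, config$gpp_noise_sd)
    drivers$records$gpp_obs <- gpp_true + eps_day
    drivers$records$nee_day <- reco_day - (gpp_true + eps_day)
    drivers$records$nee_night <- reco_night + eps_night
  })
  attr(drivers, "truth") <- list(gpp_true = gpp_true, reco_day = reco_day,
                                 reco_night = reco_night)
  drivers
}

#' Generate a complete synthetic site
#'
#' Weather, flagged NDVI/LAI, and observations in one call.
#'
#' @param config a [synthetic_site_config()].
#' @param params optional [photo_params()] override.
#' @return a complete [site_series()] with `truth` attribute.
#' @export
generate_site <- function(config, params = NULL) {
  simulate_observations(config,
                        generate_ndvi_lai(config, generate_weather(config)),
                        params)
}

#' Published per-site validation metrics (packaged fixture)
#'
#' The 62-site validation table shipped with the package: per site, the
#' vegetation type and the R2 / RMSE (g C m-2 day-1) / RPE (%) triple for
#' both the process-based model and the light-use-efficiency model, exactly
#' as published.
#'
#' @return data.frame with 62 rows and columns `site_id`, `pft`,
#'   `ibis_r2`, `ibis_rmse`, `ibis_rpe`, `eclue_r2`, `eclue_rmse`,
#'   `eclue_rpe`.
#' @export
table2_fixture <- function() {
  path <- system.file("extdata", "table2_site_metrics.tsv",
                      package = "gppval", mustWork = TRUE)
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  counts <- c(DBF = 14L, EBF = 4L, ENF = 20L, GRA = 11L, MF = 7L, SAV = 6L)
  stopifnot(nrow(x) == 62L, !anyDuplicated(x$site_id),
            identical(as.integer(table(x$pft)[names(counts)]),
                      unname(counts)))
  x
}

#' Reshape the fixture to one row per (site, model)
#'
#' @param fixture output of [table2_fixture()].
#' @return data.frame with columns `site_id`, `pft`, `model`, `r2`,
#'   `rmse`, `rpe`.
#' @export
site_metrics_long <- function(fixture = table2_fixture()) {
  out <- do.call(rbind, lapply(c(IBIS = "ibis", `EC-LUE` = "eclue"),
    function(px) {
      data.frame(site_id = fixture$site_id, pft = fixture$pft,
                 r2 = fixture[[paste0(px, "_r2")]],
                 rmse = fixture[[paste0(px, "_rmse")]],
                 rpe = fixture[[paste0(px, "_rpe")]],
                 stringsAsFactors = FALSE)
    }))
  out$model <- rep(c("IBIS", "EC-LUE"), each = nrow(fixture))
  rownames(out) <- NULL
  out[c("site_id", "pft", "model", "r2", "rmse", "rpe")]
}

#' Published global GPP estimates (packaged fixture)
#'
#' Global mean annual GPP (and its interannual standard deviation) for the
#' three model configurations, in Pg C yr-1, as published.
#'
#' @return data.frame with columns `model`, `gpp_mean`, `gpp_sd`.
#' @export
global_gpp_fixture <- function() {
  path <- system.file("extdata", "global_gpp_summary.tsv",
                      package = "gppval", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}
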