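# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so generators never leak global random state.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Smaller root of theta*x^2 - (a+b)*x + a*b = 0; used by the optional
# quadratic colimitation mode. Falls back to min(a, b) when theta -> 0.
quad_colimit <- function(a, b, theta) {
  if (theta <= 0) return(pmin(a, b))
  disc <- pmax((a + b)^2 - 4 * theta * a * b, 0)
  ((a + b) - sqrt(disc)) / (2 * theta)
}

#' Solar declination and daylength
#'
#' Standard solar geometry used for the day/night split: declination from
#' day of year, daylength from latitude and declination, with clamping for
#' polar day and night.
#'
#' @param lat latitude in degrees.
#' @param doy day of year (1-366).
#' @return daylength in hours, in `[0, 24]`.
#' @export
daylength_hours <- function(lat, doy) {
  decl <- -23.44 * cos(2 * pi * (doy + 10) / 365) # degrees
  coshr <- -tan(lat * pi / 180) * tan(decl * pi / 180)
  coshr <- clamp(coshr, -1, 1)
  2 * acos(coshr) * 180 / pi / 15
}

day_fraction <- function(lat, doy) daylength_hours(lat, doy) / 24

doy_of <- function(date) as.integer(format(date, "%j"))

# Daytime/nighttime air temperature approximations from the daily triple.
daytime_temp <- function(t_avg, t_max) (t_avg + t_max) / 2
nighttime_temp <- function(t_avg, t_min) (t_avg + t_min) / 2

GRAMS_C_PER_MOL <- 12.011
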