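# Validation statistics: per-site R2 / RMSE / RPE, biome aggregation,
# threshold censuses, paired model comparison, and toy area-weighted
# global upscaling.

#' Per-site validation metrics
#'
#' Computes the three model-performance statistics on a paired daily
#' series: the coefficient of determination (by default the squared
#' Pearson correlation, the scatterplot convention; optionally
#' `1 - SSE/SST`), the root mean square error, and the relative predictive
#' error `RPE = (mean(sim) - mean(obs)) / mean(obs) * 100`.
#'
#' @param obs observed daily values.
#' @param sim simulated daily values, same length.
#' @param r2_method `"pearson"` (default) or `"ss"`.
#' @return list with components `r2`, `rmse`, `rpe`.
#' @export
compute_metrics <- function(obs, sim, r2_method = c("pearson", "ss")) {
  r2_method <- match.arg(r2_method)
  if (length(obs) != length(sim)) stop("obs and sim lengths differ")
  ok <- !is.na(obs) & !is.na(sim)
  obs <- obs[ok]
  sim <- sim[ok]
  if (length(obs) < 2L) stop("need at least two paired values")
  if (stats::sd(obs) == 0 || stats::sd(sim) == 0)
    stop("R2 undefined: zero variance in obs or sim")
  if (mean(obs) == 0) stop("RPE undefined: zero observed mean")
  r2 <- if (r2_method == "pearson") {
    stats::cor(obs, sim)^2
  } else {
    1 - sum((obs - sim)^2) / sum((obs - mean(obs))^2)
  }
  list(r2 = r2,
       rmse = sqrt(mean((sim - obs)^2)),
       rpe = (mean(sim) - mean(obs)) / mean(obs) * 100)
}

#' Aggregate site metrics by PFT
#'
#' Arithmetic means of R2, RMSE and RPE per (PFT, model) at full
#' precision; printing rounds to two decimals, the reporting convention.
#'
#' @param metrics data.frame with columns `site_id`, `pft`, `model`, `r2`,
#'   `rmse`, `rpe` (see [site_metrics_long()]).
#' @param pfts allowed PFT labels; anything else is a labeling error.
#' @return data.frame of class `pft_summary` with columns `pft`, `model`,
#'   `mean_r2`, `mean_rmse`, `mean_rpe`, `n_sites`.
#' @export
aggregate_by_pft <- function(metrics,
                             pfts = c("DBF", "EBF", "ENF", "GRA", "MF",
                                      "SAV")) {
  bad <- setdiff(unique(metrics$pft), pfts)
  if (length(bad))
    stop("unknown PFT label(s): ", paste(bad, collapse = ", "))
  agg <- aggregate(cbind(r2, rmse, rpe) ~ pft + model, metrics, mean)
  n <- aggregate(site_id ~ pft + model, metrics, length)
  out <- merge(agg, n, by = c("pft", "model"))
  names(out) <- c("pft", "model", "mean_r2", "mean_rmse", "mean_rpe",
                  "n_sites")
  out <- out[order(out$model, out$pft), ]
  rownames(out) <- NULL
  class(out) <- c("pft_summary", "data.frame")
  out
}

#' @export
print.pft_summary <- function(x, digits = 2, ...) {
  y <- as.data.frame(x)
  for (cc in c("mean_r2", "mean_rmse", "mean_rpe"))
    y[[cc]] <- round(y[[cc]], digits)
  print(y, ...)
  invisible(x)
}

#' Census of sites by RPE threshold
#'
#' Counts sites whose relative predictive error is strictly below or above
#' a threshold.
#'
#' @param metrics data.frame with an `rpe` column (filter to one model
#'   first).
#' @param comparator `"below"` or `"above"`.
#' @param threshold percent.
#' @return integer count.
#' @export
census_rpe <- function(metrics, comparator = c("below", "above"),
                       threshold = 0) {
  comparator <- match.arg(comparator)
  if (!nrow(metrics)) stop("empty metrics table")
  if (comparator == "below") sum(metrics$rpe < threshold)
  else sum(metrics$rpe > threshold)
}

#' Relative difference in percent
#'
#' `(a - b) / b * 100` against the reference `b`.
#'
#' @param a value.
#' @param b reference, nonzero.
#' @return percent difference.
#' @export
relative_difference <- function(a, b) {
  if (any(b == 0)) stop("relative difference undefined: zero reference")
  (a - b) / b * 100
}

#' Paired comparison of model metrics
#'
#' Paired-samples t test on per-site differences, matched by `site_id`.
#' A constant nonzero difference has zero variance; the statistic is then
#' reported as signed infinity with a message rather than an error.
#'
#' @param metrics_a,metrics_b data.frames with columns `site_id` and
#'   `value` (or a metric column named by `column`).
#' @param column name of the compared column (default `"value"`).
#' @return list with `t`, `p`, `df`, `mean_diff`, `n`.
#' @export
paired_compare <- function(metrics_a, metrics_b, column = "value") {
  if (!setequal(metrics_a$site_id, metrics_b$site_id) ||
        anyDuplicated(metrics_a$site_id) || anyDuplicated(metrics_b$site_id))
    stop("pairing error: site_id sets do not match one-to-one")
  i <- match(metrics_a$site_id, metrics_b$site_id)
  d <- metrics_a[[column]] - metrics_b[[column]][i]
  n <- length(d)
  if (n < 3L) stop("need at least three matched sites")
  sdd <- stats::sd(d)
  if (sdd == 0) {
    if (mean(d) == 0) {
      t <- 0
      p <- 1
    } else {
      message("degenerate pairing: constant nonzero difference")
      t <- sign(mean(d)) * Inf
      p <- 0
    }
  } else {
    t <- mean(d) / (sdd / sqrt(n))
    p <- 2 * stats::pt(-abs(t), df = n - 1)
  }
  list(t = t, p = p, df = n - 1L, mean_diff = mean(d), n = n)
}

#' Toy area-weighted global upscaling
#'
#' Sums per-area annual GPP over grid-cell areas and converts grams to
#' petagrams: `sum(gpp * area) * 1e-15`. A demonstration of the
#' aggregation arithmetic, not a real global product.
#'
#' @param cell_gpp matrix/vector of annual GPP (g C m-2 yr-1).
#' @param cell_area matrix/vector of cell areas (m2), congruent with
#'   `cell_gpp`.
#' @return global total, Pg C yr-1.
#' @export
upscale_global <- function(cell_gpp, cell_area) {
  if (!identical(dim(cell_gpp), dim(cell_area)) ||
        length(cell_gpp) != length(cell_area))
    stop("grid error: gpp and area shapes differ")
  if (any(cell_area <= 0)) stop("grid error: non-positive cell area")
  sum(cell_gpp * cell_area) * 1e-15
}
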