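# Metropolis-Hastings inversion of Vcmax against observed daily GPP,
# posterior-mode point estimation, and per-PFT pooling of site optima.

#' MCMC configuration
#'
#' @param n_samples chain length (default 10000).
#' @param burn_in samples excluded from mode estimation (default 1000);
#'   proposal tuning, when enabled, happens only here.
#' @param proposal_sd random-walk proposal standard deviation
#'   (mol CO2 m-2 s-1); default 5% of the prior range.
#' @param prior_lo,prior_hi uniform prior bounds (defaults 1e-6 and 300e-6,
#'   the catalogue inversion range).
#' @param likelihood_sd iid Gaussian observation error on daily GPP
#'   (g C m-2 day-1).
#' @param seed integer seed.
#' @param mode_bin_width histogram bin width for the posterior mode
#'   (default 1e-6, i.e. 1 umol, the precision of the catalogue).
#' @param tune logical; adapt the proposal during burn-in toward the
#'   `tune_target` acceptance band, then freeze it (keeping the post-burn-in
#'   kernel fixed and valid).
#' @param tune_target acceptance-rate band for tuning.
#' @return an object of class `mcmc_config`.
#' @export
mcmc_config <- function(n_samples = 10000L, burn_in = 1000L,
                        proposal_sd = NULL, prior_lo = 1e-6,
                        prior_hi = 300e-6, likelihood_sd = 1, seed = 1L,
                        mode_bin_width = 1e-6, tune = TRUE,
                        tune_target = c(0.2, 0.5)) {
  proposal_sd <- proposal_sd %||% (0.05 * (prior_hi - prior_lo))
  stopifnot(prior_lo < prior_hi, n_samples > burn_in, proposal_sd > 0,
            likelihood_sd > 0, mode_bin_width > 0)
  structure(list(n_samples = as.integer(n_samples),
                 burn_in = as.integer(burn_in), proposal_sd = proposal_sd,
                 prior_lo = prior_lo, prior_hi = prior_hi,
                 likelihood_sd = likelihood_sd, seed = as.integer(seed),
                 mode_bin_width = mode_bin_width, tune = tune,
                 tune_target = tune_target),
            class = "mcmc_config")
}

# Closure mapping vcmax -> unnormalized log posterior for one site.
make_log_posterior <- function(series, params, config, pathway = NULL) {
  stopifnot(inherits(series, "site_series"))
  entry <- pft_entry(series$pft)
  pathway <- pathway %||% entry$pathway
  rec <- series$records
  obs_ok <- !is.na(rec$gpp_obs)
  if (!any(obs_ok)) stop("series has no observed GPP days")
  lai <- interp_to_daily(series$lai, rec$date)
  gpp_fn <- make_canopy_gpp_fn(rec$t_avg[obs_ok], rec$par[obs_ok],
                               doy_of(rec$date)[obs_ok], series$latitude,
                               lai[obs_ok], params, pathway)
  obs <- rec$gpp_obs[obs_ok]
  sd <- config$likelihood_sd
  lo <- config$prior_lo
  hi <- config$prior_hi
  function(vcmax) {
    if (!is.finite(vcmax) || vcmax < lo || vcmax > hi) return(-Inf)
    sum(stats::dnorm(obs, gpp_fn(vcmax), sd, log = TRUE))
  }
}

#' Unnormalized log posterior of Vcmax
#'
#' Uniform prior on `[prior_lo, prior_hi]` (negative infinity outside) and
#' an iid Gaussian likelihood of the observed daily GPP around the forward
#' canopy model run at the candidate Vcmax, with standard deviation
#' `likelihood_sd`.
#'
#' @param vcmax candidate value (mol CO2 m-2 s-1), vectorized.
#' @param series a [site_series()] with `gpp_obs`.
#' @param params a [photo_params()] supplying all non-inverted parameters.
#' @param config an [mcmc_config()].
#' @return log density values (unnormalized).
#' @export
log_posterior <- function(vcmax, series, params, config = mcmc_config()) {
  lp <- make_log_posterior(series, params, config)
  vapply(vcmax, lp, numeric(1))
}

#' Metropolis-Hastings sampling of Vcmax
#'
#' Random-walk Gaussian proposals with the standard accept rule. When
#' tuning is enabled, the proposal scale is adapted every 100 burn-in
#' iterations toward the target acceptance band and frozen afterwards.
#' An overall post-burn-in acceptance rate below 1% triggers a warning,
#' but the chain is still returned.
#'
#' @param series a [site_series()] with `gpp_obs`.
#' @param params a [photo_params()]; its `vcmax25` seeds the chain start
#'   when inside the prior, otherwise the prior midpoint is used.
#' @param config an [mcmc_config()].
#' @param log_post optional replacement target, a function
#'   `vcmax -> log density` (used for testing and extension).
#' @return object of class `mcmc_chain` with fields `samples`, `log_post`,
#'   `acceptance_rate` (post-burn-in), `proposal_sd` (final), `mode`,
#'   `config`.
#' @export
mh_sample <- function(series, params, config = mcmc_config(),
                      log_post = NULL) {
  lp <- log_post %||% make_log_posterior(series, params, config)
  n <- config$n_samples
  burn <- config$burn_in
  sdp <- config$proposal_sd
  samples <- numeric(n)
  lps <- numeric(n)
  cur <- if (!is.null(params) && params$vcmax25 > config$prior_lo &&
               params$vcmax25 < config$prior_hi) {
    params$vcmax25
  } else {
    (config$prior_lo + config$prior_hi) / 2
  }
  cur_lp <- lp(cur)
  if (!is.finite(cur_lp)) stop("chain start has zero posterior density")
  acc_post <- 0L
  acc_win <- 0L
  with_seed(config$seed, {
    for (i in seq_len(n)) {
      prop <- cur + stats::rnorm(1, 0, sdp)
      prop_lp <- lp(prop)
      if (is.finite(prop_lp) &&
            log(stats::runif(1)) < prop_lp - cur_lp) {
        cur <- prop
        cur_lp <- prop_lp
        acc_win <- acc_win + 1L
        if (i > burn) acc_post <- acc_post + 1L
      }
      samples[i] <- cur
      lps[i] <- cur_lp
      if (config$tune && i <= burn && i %% 100L == 0L) {
        rate <- acc_win / 100
        if (rate < config$tune_target[1]) sdp <- sdp / 2
        if (rate > config$tune_target[2]) sdp <- sdp * 1.6
        acc_win <- 0L
      } else if (i %% 100L == 0L) {
        acc_win <- 0L
      }
    }
  })
  rate <- acc_post / (n - burn)
  if (rate < 0.01)
    warning("post-burn-in acceptance rate below 1% (",
            format(rate, digits = 3), ")")
  chain <- structure(list(samples = samples, log_post = lps,
                          acceptance_rate = rate, proposal_sd = sdp,
                          mode = NA_real_, config = config),
                     class = "mcmc_chain")
  chain$mode <- posterior_mode(chain)
  chain
}

#' @export
print.mcmc_chain <- function(x, ...) {
  cat(sprintf(
    "<mcmc_chain> %d samples (burn-in %d), acceptance %.2f\n",
    length(x$samples), x$config$burn_in, x$acceptance_rate))
  cat(sprintf("  mode = %.6g mol CO2 m-2 s-1 (bin width %.3g)\n",
              x$mode, x$config$mode_bin_width))
  invisible(x)
}

#' Posterior mode of a chain
#'
#' Histogram of the post-burn-in samples at the configured bin width
#' (anchored at the lower prior bound); the optimum is the center of the
#' most populated bin, the highest-frequency value. Count ties break
#' toward the bin with the higher mean log posterior.
#'
#' @param chain an `mcmc_chain`.
#' @return mode estimate (mol CO2 m-2 s-1).
#' @export
posterior_mode <- function(chain) {
  cfg <- chain$config
  keep <- seq.int(cfg$burn_in + 1L, length(chain$samples))
  x <- chain$samples[keep]
  lp <- chain$log_post[keep]
  bin <- floor((x - cfg$prior_lo) / cfg$mode_bin_width)
  counts <- tapply(x, bin, length)
  best <- as.numeric(names(counts)[counts == max(counts)])
  if (length(best) > 1L) {
    mlp <- tapply(lp, bin, mean)[as.character(best)]
    best <- best[which.max(mlp)]
  }
  cfg$prior_lo + (best + 0.5) * cfg$mode_bin_width
}

#' Grid-search posterior maximum
#'
#' Brute-force maximization of the log posterior over an equally spaced
#' grid; the independent check on the sampled mode.
#'
#' @inheritParams mh_sample
#' @param resolution grid spacing (mol CO2 m-2 s-1).
#' @return the grid point with the highest posterior density.
#' @export
grid_posterior_max <- function(series, params, config = mcmc_config(),
                               resolution = 0.25e-6) {
  lp <- make_log_posterior(series, params, config)
  grid <- seq(config$prior_lo, config$prior_hi, by = resolution)
  grid[which.max(vapply(grid, lp, numeric(1)))]
}

#' Pool site-level Vcmax optima by PFT
#'
#' The per-PFT parameter scheme: each PFT's Vcmax is the arithmetic mean of
#' the site-level inverted optima, alongside a one-way ANOVA testing
#' whether the optima differ among PFTs. The ANOVA is omitted (with a
#' message) when fewer than two PFTs have at least two sites.
#'
#' @param site_optima data.frame with columns `site_id`, `pft`,
#'   `vcmax_opt`.
#' @return list with `table` (data.frame `pft`, `n_sites`, `vcmax_mean`)
#'   and `anova` (list `f`, `p`, `df1`, `df2`, or `NULL`).
#' @export
pool_by_pft <- function(site_optima) {
  stopifnot(all(c("site_id", "pft", "vcmax_opt") %in% names(site_optima)))
  if (!nrow(site_optima)) stop("no site optima to pool")
  tab <- aggregate(vcmax_opt ~ pft, site_optima, mean)
  names(tab)[2] <- "vcmax_mean"
  tab$n_sites <- as.integer(table(site_optima$pft)[tab$pft])
  tab <- tab[c("pft", "n_sites", "vcmax_mean")]
  grp_n <- table(site_optima$pft)
  av <- NULL
  if (length(grp_n) >= 2L && sum(grp_n >= 2L) >= 2L) {
    # One-way decomposition written out so the degenerate all-equal case
    # yields F = 0 rather than 0/0.
    x <- site_optima$vcmax_opt
    g <- factor(site_optima$pft)
    gm <- tapply(x, g, mean)
    ssb <- sum(table(g) * (gm - mean(x))^2)
    ssw <- sum((x - gm[g])^2)
    df1 <- nlevels(g) - 1L
    df2 <- length(x) - nlevels(g)
    f <- if (ssb == 0) 0 else (ssb / df1) / (ssw / df2)
    av <- list(f = f, p = stats::pf(f, df1, df2, lower.tail = FALSE),
               df1 = df1, df2 = df2)
  } else {
    message("ANOVA omitted: need at least two PFTs with two or more sites")
  }
  list(table = tab, anova = av)
}
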