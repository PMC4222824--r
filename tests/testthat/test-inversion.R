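# Smaller chains than the production default keep the unit suite fast; the
# full 10000-sample configuration is exercised in test-acceptance.R.

test_that("log posterior is -Inf outside the prior and maximal at truth", {
  s <- make_site(seed = 31, true_vcmax = 40e-6, n_years = 1, noise = 0)
  p <- photo_params()
  cfg <- mcmc_config(seed = 1)
  expect_equal(log_posterior(0.5e-6, s, p, cfg), -Inf)
  expect_equal(log_posterior(400e-6, s, p, cfg), -Inf)
  grid <- seq(5e-6, 150e-6, by = 1e-6)
  lp <- log_posterior(grid, s, p, cfg)
  expect_equal(grid[which.max(lp)], 40e-6)
})

test_that("log posterior matches brute-force per-day Gaussian summation", {
  s <- make_site(seed = 31, true_vcmax = 40e-6, n_years = 1)
  cfg <- mcmc_config(likelihood_sd = 0.8)
  p <- photo_params()
  grid <- seq(cfg$prior_lo, cfg$prior_hi, length.out = 50)
  got <- log_posterior(grid, s, p, cfg)
  lai <- fill_temporal_gaps(s$lai)
  lai_d <- approx(as.numeric(lai$date), lai$value,
                  xout = as.numeric(s$records$date), rule = 2)$y
  oracle <- vapply(grid, function(v) {
    pv <- photo_params(vcmax25 = v)
    sim <- mapply(function(t, par, doy, lai1) {
      canopy_daily_gpp(t, par, doy, 45, lai1, pv, "C3")
    }, s$records$t_avg, s$records$par,
       as.integer(format(s$records$date, "%j")), lai_d)
    sum(dnorm(s$records$gpp_obs, sim, 0.8, log = TRUE))
  }, numeric(1))
  expect_equal(got, oracle, tolerance = 1e-10)
})

test_that("a series with no observed days is refused", {
  s <- make_site(seed = 31, n_years = 1)
  s$records$gpp_obs <- NA_real_
  expect_error(log_posterior(40e-6, s, photo_params(), mcmc_config()),
               "no observed GPP")
})

test_that("a flat target inside the prior accepts every proposal", {
  s <- make_site(seed = 31, n_years = 1)
  cfg <- mcmc_config(n_samples = 2000, burn_in = 200, proposal_sd = 1e-6,
                     seed = 4, tune = FALSE)
  flat <- function(v) if (v < cfg$prior_lo || v > cfg$prior_hi) -Inf else 0
  ch <- mh_sample(s, photo_params(vcmax25 = 150e-6), cfg, log_post = flat)
  expect_equal(ch$acceptance_rate, 1.0)
})

test_that("chains are seed-deterministic and respect the prior support", {
  s <- make_site(seed = 31, n_years = 1)
  cfg <- mcmc_config(n_samples = 1500, burn_in = 300, seed = 9)
  p <- photo_params(vcmax25 = 30e-6)
  ch1 <- mh_sample(s, p, cfg)
  ch2 <- mh_sample(s, p, cfg)
  expect_identical(ch1$samples, ch2$samples)
  expect_true(all(ch1$samples >= cfg$prior_lo &
                    ch1$samples <= cfg$prior_hi))
  expect_gt(ch1$acceptance_rate, 0)
})

test_that("chain mode lands near the grid-search posterior maximum", {
  s <- make_site(seed = 11, true_vcmax = 40e-6, n_years = 2, noise = 0.5)
  cfg <- mcmc_config(n_samples = 4000, burn_in = 800, seed = 11)
  p <- photo_params(vcmax25 = 30e-6)
  ch <- mh_sample(s, p, cfg)
  g <- grid_posterior_max(s, p, cfg, resolution = 0.25e-6)
  expect_lt(abs(ch$mode - g), 3e-6)
})

test_that("posterior mode follows the highest-frequency rule", {
  cfg <- mcmc_config(n_samples = 1100, burn_in = 100, seed = 1)
  const <- structure(list(samples = c(numeric(100),
                                      rep(50.2e-6, 1000)),
                          log_post = numeric(1100), config = cfg),
                     class = "mcmc_chain")
  expect_equal(posterior_mode(const), 50.5e-6, tolerance = 1e-9)
  # constructed bimodal chain: the heavier mode wins
  bim <- const
  bim$samples <- c(numeric(100), rep(20.5e-6, 600), rep(80.5e-6, 400))
  expect_equal(posterior_mode(bim), 20.5e-6, tolerance = 1e-9)
  # unimodal chain: mode within one bin of the sample median
  set.seed(5)
  uni <- const
  uni$samples <- c(numeric(100), rnorm(1000, 60e-6, 3e-6))
  m <- posterior_mode(uni)
  expect_lt(abs(m - median(uni$samples[-(1:100)])), 3e-6)
})

test_that("tighter likelihoods concentrate the chain monotonically", {
  s <- make_site(seed = 11, true_vcmax = 40e-6, n_years = 1, noise = 0.5)
  p <- photo_params(vcmax25 = 40e-6)
  vars <- vapply(c(2, 1, 0.5), function(sd) {
    cfg <- mcmc_config(n_samples = 3000, burn_in = 600, seed = 13,
                       likelihood_sd = sd)
    ch <- mh_sample(s, p, cfg)
    var(ch$samples[-(1:600)])
  }, numeric(1))
  expect_true(all(diff(vars) < 0))
})

test_that("PFT pooling averages site optima and runs the ANOVA", {
  one <- data.frame(site_id = c("a", "b"), pft = "GRA",
                    vcmax_opt = c(30e-6, 50e-6))
  expect_message(p1 <- pool_by_pft(one), "ANOVA omitted")
  expect_equal(p1$table$vcmax_mean, 40e-6)
  expect_null(p1$anova)
  # all equal across groups: F = 0 by convention
  eq <- data.frame(site_id = letters[1:6],
                   pft = rep(c("GRA", "ENF"), each = 3),
                   vcmax_opt = 25e-6)
  expect_equal(pool_by_pft(eq)$anova$f, 0)
})

test_that("pooled ANOVA equals the brute-force sum-of-squares oracle", {
  set.seed(9)
  d <- data.frame(site_id = paste0("s", 1:15),
                  pft = rep(c("DBF", "ENF", "GRA"), each = 5),
                  vcmax_opt = rnorm(15, 40e-6, 8e-6))
  got <- pool_by_pft(d)$anova
  fit <- stats::anova(stats::lm(vcmax_opt ~ factor(pft), d))
  expect_equal(got$f, fit$`F value`[1], tolerance = 1e-10)
  expect_equal(got$p, fit$`Pr(>F)`[1], tolerance = 1e-10)
  expect_equal(pool_by_pft(d)$table$vcmax_mean,
               unname(tapply(d$vcmax_opt, d$pft, mean)),
               ignore_attr = TRUE)
})
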