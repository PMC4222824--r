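# Independent in-test oracle: the three limiting-rate formulas written out
# directly, kept separate from the package's vectorized implementation.
oracle_c3 <- function(qp, ci, t, p) {
  f <- function(q10) q10^((t - 25) / 10)
  vm <- p$vcmax25 * f(p$q10_vm)
  kc <- p$kc25 * f(p$q10_kc)
  ko <- p$ko25 * f(p$q10_ko)
  gs <- p$o2 / (2 * p$tau25 * f(p$q10_tau))
  je <- p$alpha3 * qp * max(ci - gs, 0) / (ci + 2 * gs)
  jc <- vm * max(ci - gs, 0) / (ci + kc * (1 + p$o2 / ko))
  js <- p$tpu_ratio * vm
  c(je = je, jc = jc, js = js, gross = min(je, jc, js))
}

test_that("kinetics reduce to the reference constants at 25 degC", {
  p <- photo_params()
  k <- kinetics_at_temperature(p, 25)
  expect_equal(k$vm, p$vcmax25)
  expect_equal(k$kc, p$kc25)
  expect_equal(k$ko, p$ko25)
  expect_equal(k$gamma_star, p$o2 / (2 * p$tau25))
})

test_that("one Q10 decade doubles vm and the specificity falls with T", {
  p <- photo_params(q10_vm = 2)
  expect_equal(kinetics_at_temperature(p, 35)$vm, 2 * p$vcmax25)
  # q10_tau < 1: compensation point rises with temperature
  g15 <- kinetics_at_temperature(p, 15)$gamma_star
  g35 <- kinetics_at_temperature(p, 35)$gamma_star
  expect_true(g15 < kinetics_at_temperature(p, 25)$gamma_star)
  expect_true(g35 > kinetics_at_temperature(p, 25)$gamma_star)
})

test_that("kinetics at 15 degC match direct re-evaluation", {
  p <- photo_params()
  k <- kinetics_at_temperature(p, 15)
  expect_equal(k$vm, p$vcmax25 * p$q10_vm^(-1))
  expect_equal(k$kc, p$kc25 * p$q10_kc^(-1))
  expect_equal(k$ko, p$ko25 * p$q10_ko^(-1))
  expect_equal(k$gamma_star, p$o2 / (2 * p$tau25 * p$q10_tau^(-1)))
})

test_that("C3 rate vanishes at the compensation point and in darkness", {
  p <- photo_params()
  gs <- kinetics_at_temperature(p, 25)$gamma_star
  at_gs <- c3_gross_rate(leaf_env(1500e-6, gs, 25), p)
  expect_equal(at_gs$je, 0)
  expect_equal(at_gs$jc, 0)
  expect_equal(at_gs$gross, 0)
  dark <- c3_gross_rate(leaf_env(0, 0.7 * 370e-6, 25), p)
  expect_equal(dark$gross, 0)
  expect_equal(dark$limiter, "light")
  # sub-compensation ci floors at zero, never negative
  sub <- c3_gross_rate(leaf_env(1500e-6, gs / 2, 25), p)
  expect_equal(sub$gross, 0)
})

test_that("C3 rates equal the brute-force formula evaluation", {
  p <- photo_params(vcmax25 = 65e-6)
  cases <- expand.grid(qp = c(100e-6, 700e-6, 1500e-6),
                       ci = c(150e-6, 0.7 * 370e-6),
                       t = c(5, 15, 25, 35))
  for (i in seq_len(nrow(cases))) {
    got <- c3_gross_rate(leaf_env(cases$qp[i], cases$ci[i], cases$t[i]), p)
    want <- oracle_c3(cases$qp[i], cases$ci[i], cases$t[i], p)
    expect_equal(got$gross, unname(want["gross"]), tolerance = 1e-12)
    expect_equal(unlist(got[c("je", "jc", "js")]),
                 want[c("je", "jc", "js")], ignore_attr = TRUE,
                 tolerance = 1e-12)
  }
})

test_that("C4 rate is the minimum of the three linear capacities", {
  p <- photo_params(vcmax25 = 15e-6)
  expect_equal(c4_gross_rate(leaf_env(500e-6, 0, 25), p)$gross, 0)
  sat <- c4_gross_rate(leaf_env(0.05, 10e-3, 25), p)
  expect_equal(sat$gross, p$vcmax25)
  expect_equal(sat$limiter, "rubisco")
  env <- leaf_env(300e-6, 40e-6, 30)
  got <- c4_gross_rate(env, p)
  vm <- p$vcmax25 * p$q10_vm^((30 - 25) / 10)
  expect_equal(got$gross,
               min(p$alpha4 * 300e-6, vm, p$k_c4 * 40e-6),
               tolerance = 1e-12)
})

test_that("gross rate invariants hold over randomized parameter draws", {
  set.seed(42)
  for (rep in 1:200) {
    p <- photo_params(vcmax25 = runif(1, 5e-6, 150e-6),
                      alpha3 = runif(1, 0.03, 0.09),
                      tpu_ratio = runif(1, 0.3, 1),
                      q10_vm = runif(1, 1.5, 2.5))
    env <- leaf_env(runif(1, 0, 2000e-6), runif(1, 0, 500e-6),
                    runif(1, -5, 40))
    r <- c3_gross_rate(env, p)
    expect_equal(r$gross, min(r$je, r$jc, r$js))
    expect_true(all(unlist(r[c("je", "jc", "js", "gross")]) >= 0))
    r4 <- c4_gross_rate(env, p)
    expect_equal(r4$gross, min(r4$je, r4$jc, r4$js))
    expect_true(r4$gross >= 0)
  }
})

test_that("gross rate is monotone in vcmax, light, and (C3) ci", {
  p0 <- photo_params()
  env <- leaf_env(800e-6, 0.7 * 370e-6, 20)
  vs <- seq(5e-6, 150e-6, length.out = 30)
  g_v <- vapply(vs, function(v) {
    c3_gross_rate(env, photo_params(vcmax25 = v))$gross
  }, numeric(1))
  expect_true(all(diff(g_v) >= 0))
  qs <- seq(0, 2000e-6, length.out = 30)
  g_q <- vapply(qs, function(q) {
    c3_gross_rate(leaf_env(q, env$ci, 20), p0)$gross
  }, numeric(1))
  expect_true(all(diff(g_q) >= 0))
  gs <- kinetics_at_temperature(p0, 20)$gamma_star
  cis <- seq(gs * 1.01, 600e-6, length.out = 30)
  g_c <- vapply(cis, function(ci) {
    c3_gross_rate(leaf_env(800e-6, ci, 20), p0)$gross
  }, numeric(1))
  expect_true(all(diff(g_c) >= -1e-18))
})

test_that("the limiter leaves the light regime exactly once as qp grows", {
  set.seed(5)
  for (rep in 1:20) {
    p <- photo_params(vcmax25 = runif(1, 10e-6, 100e-6))
    t_leaf <- runif(1, 5, 30)
    qs <- seq(1e-6, 3000e-6, length.out = 400)
    lim <- vapply(qs, function(q) {
      c3_gross_rate(leaf_env(q, 0.7 * 370e-6, t_leaf), p)$limiter
    }, character(1))
    is_light <- lim == "light"
    expect_equal(sum(diff(is_light) != 0), 1L)
    expect_true(is_light[1])
  }
})

test_that("canopy GPP: no leaves, no light, no carbon", {
  p <- photo_params()
  expect_equal(canopy_daily_gpp(20, 40, 180, 45, 0, p, "C3"), 0)
  expect_error(canopy_daily_gpp(20, 40, 180, 45, -1, p, "C3"), "LAI")
})

test_that("canopy GPP doubles with PAR under strict light limitation", {
  p <- photo_params(vcmax25 = 300e-6) # huge vm so light always binds
  g1 <- canopy_daily_gpp(20, 5, 180, 45, 3, p, "C3")
  g2 <- canopy_daily_gpp(20, 10, 180, 45, 3, p, "C3")
  expect_equal(g2, 2 * g1, tolerance = 1e-12)
})

test_that("canopy GPP equals a step-by-step composition of its parts", {
  p <- photo_params(vcmax25 = 40e-6)
  t_avg <- 18; par <- 35; doy <- 160; lat <- 45; lai <- 3.2; k <- 0.5
  dl <- daylength_hours(lat, doy) * 3600
  qp <- par / dl * (1 - exp(-k * lai))
  leaf <- c3_gross_rate(leaf_env(qp, p$ci_ca_c3 * p$ca, t_avg), p)
  want <- leaf$gross * dl * 12.011
  got <- canopy_daily_gpp(t_avg, par, doy, lat, lai, p, "C3")
  expect_equal(got, want, tolerance = 1e-10)
})

test_that("quadratic colimitation smooths but never exceeds the minimum", {
  pm <- photo_params()
  pq <- photo_params(colimit = "quadratic")
  env <- leaf_env(600e-6, 0.7 * 370e-6, 22)
  expect_lte(c3_gross_rate(env, pq)$gross, c3_gross_rate(env, pm)$gross)
  expect_gt(c3_gross_rate(env, pq)$gross, 0)
})
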