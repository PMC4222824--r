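# Shared fixture builders; everything is generated in code under fixed
# seeds, no data files beyond the packaged published tables.

make_site <- function(seed = 11, true_vcmax = 40e-6, n_years = 2,
                      noise = 0.5, ...) {
  generate_site(synthetic_site_config(seed = seed, true_vcmax = true_vcmax,
                                      n_years = n_years,
                                      gpp_noise_sd = noise, ...))
}

expect_series_valid <- function(s) {
  rec <- s$records
  expect_true(all(rec$t_min <= rec$t_avg & rec$t_avg <= rec$t_max))
  expect_true(all(rec$par >= 0 & rec$precip >= 0))
  expect_true(all(rec$cloud_frac >= 0 & rec$cloud_frac <= 1))
  expect_true(all(rec$rh >= 0 & rec$rh <= 100))
}
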