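test_that("generation is bit-identical for the same seed", {
  r1 <- generate_record(holocene_preset(seed = 5))
  r2 <- generate_record(holocene_preset(seed = 5))
  expect_identical(r1$isotopes, r2$isotopes)
  expect_identical(as.data.frame(r1$truth), as.data.frame(r2$truth))
  expect_identical(lapply(r1$covariates, as.data.frame),
                   lapply(r2$covariates, as.data.frame))
  expect_identical(r1$assemblage, r2$assemblage)
  r3 <- generate_record(holocene_preset(seed = 6))
  expect_false(identical(r1$isotopes$d30si_permil, r3$isotopes$d30si_permil))
})

test_that("with all noise off the truth equals the regime means exactly", {
  cfg <- scenario_config(seed = 1, n_samples = 40, process_sd = 0,
                         measurement_sd_delta = 0)
  rec <- generate_record(cfg)
  reg <- rec$truth$age_kyr > 5.45
  expect_equal(unique(rec$truth$value[!reg]), 0.342)
  expect_equal(unique(rec$truth$value[reg]), 0.483)
  expect_equal(rec$isotopes$d30si_permil,
               delta_from_utilization(rec$truth$value, cfg$system))
  expect_equal(rec$n_clipped, 0)
})

test_that("noise-free d30Si always lies inside the admissible band", {
  for (seed in 1:5) {
    rec <- generate_record(holocene_preset(seed = seed))
    band <- admissible_band(rec$config$system)
    d_true <- delta_from_utilization(rec$truth$value, rec$config$system)
    expect_true(all(d_true >= band[1] & d_true <= band[2]))
  }
})

test_that("the AR(1) coefficient is recovered from a long single-regime series", {
  cfg <- scenario_config(seed = 12, n_samples = 1e4, age_span = c(0.2, 100),
                         regime_boundaries = numeric(0),
                         regime_utilization_means = 0.45,
                         ar1_coefficient = 0.3, process_sd = 0.03,
                         measurement_sd_delta = 0)
  rec <- generate_record(cfg)
  rho_hat <- stats::acf(rec$truth$value, lag.max = 1, plot = FALSE)$acf[2]
  expect_lt(abs(rho_hat - 0.3), 0.03)
  sd_hat <- sd(rec$truth$value)
  expect_lt(abs(sd_hat - 0.03), 0.005)
})

test_that("covariates hit their configured regime-wise correlations", {
  cfg <- scenario_config(
    seed = 8, n_samples = 2000, age_span = c(0.2, 40.2),
    regime_boundaries = 20.2,
    regime_utilization_means = c(0.342, 0.483),
    ar1_coefficient = 0.3, process_sd = 0.03, measurement_sd_delta = 0,
    covariate_specs = list(
      cov = list(correlations = c(0.3, -0.6), interval_kyr = 0.02,
                 base = 5, scale = 2)))
  rec <- generate_record(cfg)
  cov <- rec$covariates$cov
  u_at <- interpolate_to_ages(rec$truth, cov$age_kyr)
  for (regime in 1:2) {
    idx <- if (regime == 1) cov$age_kyr < 20.2 else cov$age_kyr > 20.2
    idx <- idx & !is.na(u_at)
    expect_gte(sum(idx), 500)
    rho_hat <- cor(cov$value[idx], u_at[idx])
    expect_lt(abs(rho_hat - c(0.3, -0.6)[regime]), 0.1)
  }
})

test_that("the Holocene preset encodes the documented study geometry", {
  cfg <- holocene_preset()
  expect_equal(cfg$age_span, c(0.2, 12.6))
  expect_equal(cfg$measurement_sd_delta, 0.03)
  expect_equal(cfg$regime_utilization_means, c(0.342, 0.483))
  expect_equal(cfg$regime_boundaries, 5.45)
  expect_equal(cfg$n_samples, 80L)
  expect_equal(cfg$cryophilic_p, 0.006)
  rec <- generate_record(cfg)
  expect_equal(nrow(rec$isotopes), 80L)
  expect_true(all(diff(rec$isotopes$age_kyr) > 0))
  expect_equal(rec$exempt, "sww")
})

test_that("generated assemblages keep the cryophilic fraction small and bounded", {
  rec <- generate_record(holocene_preset(seed = 3))
  per_sample <- tapply(
    rec$assemblage$rel_abundance_pct[rec$assemblage$eco_class == "cryophilic"],
    rec$assemblage$age_kyr[rec$assemblage$eco_class == "cryophilic"], sum)
  expect_true(all(per_sample <= 2 + 1e-9))
  expect_lt(abs(mean(per_sample) - 0.6), 0.4)
  sums <- tapply(rec$assemblage$rel_abundance_pct, rec$assemblage$age_kyr, sum)
  expect_true(all(abs(sums - 100) < 1e-9))
})

test_that("config invariants are enforced", {
  expect_error(scenario_config(1, regime_boundaries = 13), "inside the age span")
  expect_error(scenario_config(1, regime_boundaries = c(5, 4),
                               regime_utilization_means = c(.3, .4, .5)),
               "strictly increasing")
  expect_error(scenario_config(1, ar1_coefficient = 1), "< 1")
  expect_error(scenario_config(1, process_sd = -0.1), ">= 0")
  expect_error(scenario_config(1, regime_utilization_means = c(0.3)),
               "one regime mean")
})
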