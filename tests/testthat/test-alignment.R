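test_that("interpolation passes through samples and hits the midpoint", {
  s <- proxy_series(c(1, 2), c(10, 20), name = "cov")
  expect_equal(interpolate_to_ages(s, 1.5), 15, ignore_attr = TRUE)
  expect_equal(interpolate_to_ages(s, 2), 20, ignore_attr = TRUE)
})

test_that("interpolation matches the two-point oracle and never extrapolates", {
  set.seed(17)
  age <- sort(runif(30, 0, 12))
  val <- rnorm(30)
  s <- proxy_series(age, val, name = "cov")
  targets <- runif(20, -1, 13)
  got <- interpolate_to_ages(s, targets)
  want <- interp_oracle(age, val, targets)
  expect_equal(as.numeric(got), want, tolerance = 1e-12)
  outside <- which(targets < min(age) | targets > max(age))
  expect_true(all(is.na(got[outside])))
  expect_equal(attr(got, "outside"), outside)
})

test_that("the age-gap rule keeps coincident targets and drops over-gap ones", {
  s <- proxy_series(c(1.00, 1.20, 1.40), c(1, 2, 3), name = "cov")
  gf <- age_gap_filter(s, c(1.20, 1.14), tolerance_years = 50)
  expect_equal(gf$gap_years, c(0, 60))
  expect_equal(gf$keep, c(TRUE, FALSE))
  gf2 <- age_gap_filter(s, c(1.14, 5), tolerance_years = Inf)
  expect_true(all(gf2$keep))
  # bracket rule uses the worse of the two bracketing distances
  gf3 <- age_gap_filter(s, 1.05, tolerance_years = 100, gap_rule = "bracket")
  expect_equal(gf3$gap_years, 150)
  expect_error(age_gap_filter(s, 1, tolerance_years = 0), "> 0")
})

test_that("exclusion count is monotone non-increasing in the tolerance", {
  set.seed(23)
  s <- proxy_series(sort(runif(25, 0, 10)), rnorm(25), name = "cov")
  targets <- sort(runif(40, 0, 10))
  drops <- vapply(c(10, 25, 50, 100, 400),
                  function(tol) sum(!age_gap_filter(s, targets, tol)$keep),
                  numeric(1))
  expect_true(all(diff(drops) <= 0))
})

test_that("a covariate sampled at identical ages aligns exactly with no exclusions", {
  ages <- seq(1, 5, by = 0.5)
  util <- proxy_series(ages, seq(0.3, 0.5, length.out = length(ages)),
                       name = "utilization")
  cov <- proxy_series(ages, sin(ages), name = "cov")
  am <- align_covariates(util, list(cov = cov))
  expect_equal(am$data$cov, sin(ages))
  expect_equal(nrow(am$exclusions), 0L)
  expect_equal(nrow(am$data), length(ages))
})

test_that("a fixture engineered with six over-gap rows logs exactly six exclusions", {
  # covariate observed every 0.05 kyr (gaps <= 25 yr everywhere) except six
  # holes punched around six targets, leaving their nearest observation
  # 100 yr away
  ages <- seq(0.5, 10, by = 0.25)
  util <- proxy_series(ages, rep(0.4, length(ages)), name = "utilization")
  cov_ages <- seq(0.4, 10.2, by = 0.05)
  bad_targets <- ages[c(3, 9, 15, 21, 27, 33)]
  for (b in bad_targets) cov_ages <- cov_ages[abs(cov_ages - b) > 0.07]
  cov <- proxy_series(cov_ages, rnorm(length(cov_ages)), name = "cov")
  am <- align_covariates(util, list(cov = cov), tolerance_years = 50)
  expect_equal(nrow(am$exclusions), 6L)
  expect_equal(sort(am$exclusions$age_kyr), sort(bad_targets))
  expect_equal(nrow(am$data), length(ages) - 6L)
  expect_true(all(am$exclusions$gap_years > 50))
})

test_that("an exempt coarse covariate changes only its column, never row membership", {
  ages <- seq(1, 9, by = 0.2)
  util <- proxy_series(ages, rep(0.4, length(ages)), name = "utilization")
  dense <- proxy_series(seq(0.9, 9.1, by = 0.1), rnorm(83), name = "dense")
  coarse_ages <- seq(0.8, 9.2, by = 1.7)
  coarse <- proxy_series(coarse_ages, rnorm(length(coarse_ages)), name = "sww")
  with_sww <- align_covariates(util, list(dense = dense, sww = coarse),
                               exempt = "sww")
  without <- align_covariates(util, list(dense = dense))
  expect_equal(with_sww$data$age_kyr, without$data$age_kyr)
  expect_equal(with_sww$data$dense, without$data$dense)
  expect_true("sww" %in% names(with_sww$data))
  # the coarse series would have been heavily excluded under the gap rule
  strict <- suppressWarnings(align_covariates(util, list(dense = dense, sww = coarse)))
  expect_lt(nrow(strict$data), nrow(with_sww$data))
})

test_that("alignment is idempotent and order-independent across covariates", {
  set.seed(29)
  ages <- sort(runif(20, 1, 9))
  util <- proxy_series(ages, runif(20, 0.2, 0.6), name = "utilization")
  a <- proxy_series(seq(0.9, 9.1, by = 0.12), rnorm(69), name = "a")
  b <- proxy_series(seq(0.95, 9.05, by = 0.31), rnorm(27), name = "b")
  m1 <- align_covariates(util, list(a = a, b = b))
  m2 <- align_covariates(util, list(b = b, a = a))
  expect_equal(m1$data$age_kyr, m2$data$age_kyr)
  expect_equal(m1$data$a, m2$data$a)
  expect_equal(m1$data$b, m2$data$b)
  # idempotence: realigning the retained rows drops nothing further
  util2 <- proxy_series(m1$data$age_kyr, m1$data$utilization,
                        name = "utilization")
  m3 <- align_covariates(util2, list(a = a, b = b))
  expect_equal(m3$data$age_kyr, m1$data$age_kyr)
})

test_that("per-zone alignment restricts rows to each zone span", {
  ages <- seq(0.5, 10, by = 0.5)
  util <- proxy_series(ages, runif(length(ages), 0.2, 0.6),
                       name = "utilization")
  cov <- proxy_series(seq(0.4, 10.1, by = 0.1), rnorm(98), name = "cov")
  zones <- data.frame(zone = 1:2, age_min_kyr = c(0.5, 5.5),
                      age_max_kyr = c(5.0, 10.0))
  per <- align_by_zone(util, list(cov = cov), zones)
  expect_named(per, c("zone1", "zone2"))
  expect_true(all(per$zone1$data$age_kyr <= 5.0))
  expect_true(all(per$zone2$data$age_kyr >= 5.5))
})
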