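# Calibration coefficients under the three protocols

test_that("a coefficient is the dose-signal quotient with propagated variance", {
  nd <- derive_coefficient(uq(45, 0), corrected_signal(45000, 0),
                           "megavoltage")
  expect_equal(nd$value, 0.001)
  expect_equal(nd$variance, 0)
  expect_equal(nd$protocol, "megavoltage")

  # homogeneity: scaling the dose scales the coefficient
  nd1 <- derive_coefficient(uq_from_rel(30, 5), corrected_signal(3e4, 100),
                            "ct_air")
  nd2 <- derive_coefficient(uq_from_rel(90, 5), corrected_signal(3e4, 100),
                            "ct_air")
  expect_equal(nd2$value, 3 * nd1$value)
  expect_equal(rel_2sigma(as_uq(nd2)), rel_2sigma(as_uq(nd1)))

  # propagation matches the closed-form component combination
  s <- uq_from_rel(45000, 1.3)
  d <- uq_from_rel(45, 0.9)
  nd <- derive_coefficient(d, s, "megavoltage")
  expect_equal(rel_2sigma(as_uq(nd)), coefficient_uncertainty(1.3, 0.9),
               tolerance = 1e-10)

  expect_error(derive_coefficient(uq(45, 0), uq(-1, 0), "vendor"), "positive")
  expect_error(derive_coefficient(uq(0, 0), uq(100, 0), "vendor"), "positive")
})

test_that("the vendor batch adjustment is the sensitivity-mean ratio", {
  v <- vendor_standard_set(c(3, 20),
                           list(corrected_signal(3000, 0),
                                corrected_signal(20000, 0)),
                           0.85, 0.93)
  expect_equal(round(vendor_batch_adjustment(v), 3), 1.094)
  v$calibration_batch_mean_sensitivity <- 0.93
  expect_equal(vendor_batch_adjustment(v), 1)
  v$calibration_batch_mean_sensitivity <- 0.5
  v$experimental_batch_mean_sensitivity <- 1
  expect_equal(vendor_batch_adjustment(v), 2)
  expect_error(vendor_standard_set(c(3, 20), list(corrected_signal(1, 0)),
                                   0.85, 0.93), "one signal per dose level")
})

test_that("vendor calibration fits through the origin and applies the adjustment", {
  # exact line through origin, equal batches: slope recovered exactly
  N <- 2e-3
  v <- vendor_standard_set(c(3, 20),
                           list(corrected_signal(3 / N, 0),
                                corrected_signal(20 / N, 0)),
                           0.93, 0.93)
  nd <- calibrate_vendor(v, dose_rel_2sigma = 0)
  expect_equal(nd$value, N, tolerance = 1e-12)
  expect_equal(nd$protocol, "vendor")

  # zero level is carried but ignored by the fit
  v3 <- vendor_standard_set(c(0, 3, 20),
                            list(corrected_signal(40, 10),
                                 corrected_signal(3 / N, 0),
                                 corrected_signal(20 / N, 0)),
                            0.93, 0.93)
  expect_equal(calibrate_vendor(v3, dose_rel_2sigma = 0)$value, N,
               tolerance = 1e-12)

  expect_error(calibrate_vendor(
    vendor_standard_set(c(0, 0), list(corrected_signal(10, 0),
                                      corrected_signal(10, 0)), 1, 1)),
    "all dose levels are zero")
})

test_that("vendor calibration is invariant to a global calibration-batch rescale", {
  # corrected signals of a batch scale as 1/batch-mean; the adjustment
  # must cancel that scale exactly
  N <- 1e-3; e <- 0.93
  nd_for <- function(c_mean) {
    sig <- lapply(c(3, 20), function(D)
      corrected_signal((D / N) * (e / c_mean), 0))
    calibrate_vendor(vendor_standard_set(c(3, 20), sig, c_mean, e),
                     dose_rel_2sigma = 0)$value
  }
  expect_equal(nd_for(0.85), nd_for(0.93), tolerance = 1e-12)
  expect_equal(nd_for(0.85), N, tolerance = 1e-12)
})

test_that("vendor coefficient noise recovery stays within the propagated interval", {
  set.seed(21)
  N <- 1e-3
  reps <- 100
  vals <- replicate(reps, {
    sig <- lapply(c(3, 20), function(D)
      corrected_signal((D / N) * exp(rnorm(1, 0, 0.0065)),
                       ((D / N) * 0.0065)^2))
    calibrate_vendor(vendor_standard_set(c(3, 20), sig, 0.93, 0.93),
                     dose_rel_2sigma = 5)$value
  })
  expect_lt(abs(mean(vals) / N - 1), 3 * sd(vals) / sqrt(reps) / N)
})

test_that("CT free-in-air calibration pools doses and signals", {
  nd <- calibrate_ct_air(list(corrected_signal(30000, 0)),
                         list(uq(30, 0)))
  expect_equal(nd$value, 0.001)
  expect_equal(nd$protocol, "ct_air")

  # systematic dose component does not average down over repeats
  doses <- lapply(1:3, function(i) uq_from_rel(30, 5))
  pooled <- pool_uncertain(doses)
  expect_equal(rel_2sigma(pooled), 5, tolerance = 1e-6)

  # the coefficient uncertainty sits slightly above the 5% dose term
  sigs <- lapply(c(29900, 30000, 30100, 29950, 30050, 30000),
                 function(v) corrected_signal(v, 100))
  nd <- calibrate_ct_air(sigs, doses)
  expect_gt(rel_2sigma(as_uq(nd)), 5)
  expect_lt(rel_2sigma(as_uq(nd)), 5.6)

  expect_error(calibrate_ct_air(list(), doses), "at least one")
})

test_that("Co-60 decay correction follows the half-life law", {
  src <- co60_source(45, "2020-01-01", half_life_days = 1925.28)
  d0 <- decay_corrected_dose(src, "2020-01-01", 1)
  expect_equal(d0$expected, 45)
  expect_equal(rel_2sigma(d0), 0.9)

  one_hl <- as.Date("2020-01-01") + 1925.28
  d1 <- decay_corrected_dose(src, one_hl, 1)
  expect_equal(d1$expected, 45 / 2, tolerance = 1e-3)

  # closed form at an arbitrary interval
  d2 <- decay_corrected_dose(src, "2021-01-01", 2)
  dt <- as.numeric(as.Date("2021-01-01") - as.Date("2020-01-01"))
  expect_equal(d2$expected, 45 * 2^(-dt / 1925.28) * 2)

  expect_error(decay_corrected_dose(src, "2019-12-31", 1), "precedes")
  expect_error(decay_corrected_dose(src, "2020-06-01", 0), "positive")
})

test_that("megavoltage calibration divides delivered dose by the pooled signal", {
  sigs <- lapply(c(16500, 16520, 16480, 16500), function(v)
    corrected_signal(v, 25))
  nd <- calibrate_megavoltage(sigs, uq_from_rel(45, 0.9))
  expect_equal(nd$value, 45 / 16500, tolerance = 1e-6)
  expect_equal(nd$protocol, "megavoltage")
  # near the closed-form 1.3% (+) 0.9% combination
  expect_lt(abs(rel_2sigma(as_uq(nd)) - coefficient_uncertainty(
    200 * sd(c(16500, 16520, 16480, 16500)) / 2 / 16500, 0.9)), 0.3)
})

test_that("coefficient records round-trip through JSON", {
  nd <- calibration_coefficient(1.234e-3, 2.5e-9, "ct_air", "batchA")
  path <- withr::local_tempfile(fileext = ".json")
  write_coefficient(nd, path)
  back <- read_coefficient(path)
  expect_equal(back$value, nd$value)
  expect_equal(back$variance, nd$variance)
  expect_equal(back$protocol, "ct_air")
  expect_equal(back$batch_id, "batchA")
})
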