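# Dose computation and protocol comparison

test_that("dose is the product of the factor chain", {
  tb <- load_kq_tables()
  sig <- corrected_signal(1000, 0)
  cal_cond <- measurement_condition(120, "free-in-air", "none")
  nd <- calibration_coefficient(0.03, 0, "ct_air")
  d <- compute_dose(sig, nd, factor_set_for("ct_air", cal_cond, tb))
  expect_equal(d$dose_mGy, 30)
  expect_equal(d$variance, 0)

  # megavoltage path picks up k_G = 1.03 and the tabulated k_Q
  cond <- measurement_condition(120, "center", "32 cm")
  nd_mv <- calibration_coefficient(0.03, 0, "megavoltage")
  d_mv <- compute_dose(sig, nd_mv, factor_set_for("megavoltage", cond, tb))
  expect_equal(d_mv$dose_mGy, 30 * 1.03 * 0.33)
})

test_that("dose is strictly multiplicative in each factor", {
  tb <- load_kq_tables()
  cond <- measurement_condition(120, "center", "32 cm")
  f <- factor_set_for("ct_air", cond, tb)
  nd <- calibration_coefficient(1e-3, 0, "ct_air")
  d1 <- compute_dose(corrected_signal(3e4, 0), nd, f)
  d2 <- compute_dose(corrected_signal(3 * 3e4, 0), nd, f)
  expect_equal(d2$dose_mGy, 3 * d1$dose_mGy)
  nd3 <- calibration_coefficient(3e-3, 0, "ct_air")
  expect_equal(compute_dose(corrected_signal(3e4, 0), nd3, f)$dose_mGy,
               3 * d1$dose_mGy)
})

test_that("protocol tags must agree between coefficient and factors", {
  tb <- load_kq_tables()
  cond <- measurement_condition(120, "center", "32 cm")
  nd <- calibration_coefficient(1e-3, 0, "ct_air")
  expect_error(compute_dose(corrected_signal(100, 0), nd,
                            factor_set_for("megavoltage", cond, tb)),
               "protocol mismatch")
  expect_error(compute_dose(corrected_signal(-5, 1), nd,
                            factor_set_for("ct_air", cond, tb)),
               "non-positive")
})

test_that("percent difference uses the unsigned reference convention", {
  expect_equal(percent_difference(31.8, 30.4), 100 * 1.4 / 31.8)
  expect_equal(percent_difference(30, 30), 0)
  expect_equal(percent_difference(34.1, 28.4), 100 * 5.7 / 34.1)
  # scale invariance
  expect_equal(percent_difference(2 * 34.1, 2 * 28.4),
               percent_difference(34.1, 28.4))
  # signed variant keeps the direction
  expect_equal(percent_difference(30, 33, signed = TRUE), -10)
  expect_equal(percent_difference(30, 27, signed = TRUE), 10)
  expect_error(percent_difference(0, 10), "non-zero")
})

test_that("comparison summaries average the absolute differences", {
  rows <- data.frame(chamber_mGy = 30, ct_air_mGy = 30)
  cmp <- comparison_summary(rows)
  expect_equal(attr(cmp, "averages")[["ct_air"]], 0)

  rows <- data.frame(chamber_mGy = c(30, 40),
                     vendor_mGy = c(27, 44),
                     ct_air_mGy = c(30, 40))
  cmp <- comparison_summary(rows)
  expect_equal(cmp$vendor_pct, c(10, 10))
  expect_equal(attr(cmp, "averages")[["vendor"]], 10)
  expect_equal(attr(cmp, "averages")[["ct_air"]], 0)

  expect_error(comparison_summary(data.frame(chamber_mGy = numeric(0))),
               "non-empty")
  expect_error(comparison_summary(data.frame(x = 1)), "chamber_mGy")
})

test_that("the packaged validation dataset is consistent with the design table", {
  tab <- table3_doses()
  des <- table1_conditions()
  expect_equal(nrow(tab), 11L)
  expect_equal(nrow(des), 11L)
  expect_equal(tab$kvp, des$kvp)
  expect_equal(tab$energy_keV, des$mean_spectral_energy_keV)
  expect_true(all(tab$chamber_mGy >= 25 & tab$chamber_mGy <= 40))
  # every design row builds a valid condition
  for (r in seq_len(nrow(des))) {
    cond <- condition_from_row(des[r, ])
    expect_s3_class(cond, "measurement_condition")
  }
})

test_that("uncertainty budgets itemize the chain and beat quadrature", {
  tb <- load_kq_tables()
  cond <- measurement_condition(120, "center", "32 cm",
                                mean_spectral_energy_keV = 54.7)
  f <- factor_set_for("ct_air", cond, tb)
  sig <- uq_from_rel(3e4, 1.3, "M_corr")
  nd <- uq_from_rel(1e-3, coefficient_uncertainty(1.3, 5), "N_D")
  b <- dose_uncertainty_budget(sig, nd, f)
  expect_equal(b$component,
               c("M_corr", "N_D", "k_L", "k_F", "k_G", "k_theta", "k_Q",
                 "total"))
  comp <- b$rel_2sigma_pct[b$component != "total"]
  total <- b$rel_2sigma_pct[b$component == "total"]
  rss <- sqrt(sum(comp^2))
  expect_gt(total, rss)                 # exact cross terms push it above
  expect_lt(total, rss + 0.05)          # but only slightly, at these scales

  # all components zero -> total zero
  cal_cond <- measurement_condition(120, "free-in-air", "none")
  b0 <- dose_uncertainty_budget(uq(3e4, 0), uq(1e-3, 0),
                                factor_set_for("ct_air", cal_cond, tb))
  expect_equal(b0$rel_2sigma_pct, rep(0, 8))
})

test_that("the shipped component defaults reproduce the published budget shape", {
  # demonstration budget: reading 1.3%; dose-to-standards 5/5/0.9%;
  # k-factor defaults from the shipped configuration
  tb <- load_kq_tables()
  cond <- measurement_condition(120, "center", "32 cm",
                                mean_spectral_energy_keV = 55.3)
  dose_unc <- c(vendor = 5, ct_air = 5, megavoltage = 0.9)
  totals <- vapply(names(dose_unc), function(p) {
    nd <- uq_from_rel(1e-3, coefficient_uncertainty(1.3, dose_unc[[p]]))
    b <- dose_uncertainty_budget(uq_from_rel(3e4, 1.3), nd,
                                 factor_set_for(p, cond, tb))
    b$rel_2sigma_pct[b$component == "total"]
  }, numeric(1))
  expect_gt(totals[["vendor"]], totals[["megavoltage"]])
  expect_gt(totals[["vendor"]], totals[["ct_air"]])
  # CT-based calibration has the lowest total; Co-60 close behind
  expect_lt(totals[["ct_air"]], totals[["megavoltage"]])
  expect_true(all(totals > 5 & totals < 20))
})
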