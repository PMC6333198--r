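# Corrected-signal estimation from repeated reads

test_that("depletion correction restores later reads to first-read equivalent", {
  # identity case: one read, no depletion
  s <- reading_sequence("d1", "b1", 100)
  z <- correct_reading_sequence(s, depletion_model(0))
  expect_equal(z$value, 100)

  # per-read arithmetic oracle: each read divided by 0.984^(j-1)
  counts <- c(100, 98.4, 96.83)
  expected <- mean(counts / 0.984^(0:2))
  z <- correct_reading_sequence(reading_sequence("d1", "b1", counts),
                                depletion_model(0.016))
  expect_equal(z$value, expected)
  expect_equal(z$value, 100, tolerance = 1e-4)
  expect_lt(z$variance, 1e-5)

  # noise-free reads generated with loss d are equalized to machine precision
  d <- 0.016
  true_sig <- 2500
  gen <- true_sig * (1 - d)^(0:4)
  corr <- gen * depletion_factors(depletion_model(d), 5)
  expect_equal(corr, rep(true_sig, 5), tolerance = 1e-12)
})

test_that("sensitivity scaling and background follow the printed order", {
  # brute-force per-read arithmetic with k_s = 0.93
  counts <- c(100, 100, 100)
  by_hand <- 0.93 * mean(100 / 0.984^(0:2))
  z <- correct_reading_sequence(reading_sequence("d1", "b1", counts),
                                depletion_model(0.016),
                                element_sensitivity("d1", 0.93))
  expect_equal(z$value, by_hand)

  # background subtracted last, treated as exact
  z_bg <- correct_reading_sequence(reading_sequence("d1", "b1", counts),
                                   depletion_model(0.016),
                                   element_sensitivity("d1", 0.93),
                                   background = 5)
  expect_equal(z_bg$value, by_hand - 5)
  expect_equal(z_bg$variance, z$variance)
})

test_that("correction is linear in counts and reduces to the plain mean", {
  counts <- c(120, 118, 119.5)
  z1 <- correct_reading_sequence(reading_sequence("d", "b", counts),
                                 depletion_model(0))
  expect_equal(z1$value, mean(counts))
  z2 <- correct_reading_sequence(reading_sequence("d", "b", 3.7 * counts),
                                 depletion_model(0.016))
  z3 <- correct_reading_sequence(reading_sequence("d", "b", counts),
                                 depletion_model(0.016))
  expect_equal(z2$value, 3.7 * z3$value, tolerance = 1e-12)
})

test_that("the retention convention is exposed as a toggle", {
  dep_rest <- depletion_model(0.016, "restore")
  dep_ret <- depletion_model(0.016, "retention")
  expect_equal(depletion_factors(dep_rest, 3), 0.984^-(0:2))
  expect_equal(depletion_factors(dep_ret, 3), 0.984^(0:2))
  expect_error(depletion_model(0.6), "0.5")
  expect_error(depletion_model(-0.01), "0.5")
})

test_that("single-read variance falls back to the reader-noise model", {
  z <- correct_reading_sequence(reading_sequence("d", "b", 100),
                                depletion_model(0))
  expect_equal(z$variance, (100 * 0.8 / 200)^2)  # 0.8% at 2 sigma
  z2 <- correct_reading_sequence(reading_sequence("d", "b", 100),
                                 depletion_model(0),
                                 reader_noise_rel_2sigma = 2)
  expect_equal(z2$variance, 1)
})

test_that("invalid inputs and non-physical results are handled", {
  expect_error(reading_sequence("d", "b", numeric(0)), "at least one read")
  expect_error(reading_sequence("d", "b", c(10, -1)), "non-negative")
  expect_error(correct_reading_sequence(reading_sequence("d", "b", 10),
                                        background = -1), "non-negative")
  expect_warning(
    z <- correct_reading_sequence(reading_sequence("d", "b", c(10, 10)),
                                  depletion_model(0), background = 50),
    "non-physical")
  expect_true(isTRUE(attr(z, "nonphysical")))
})

test_that("pooling uses the sample variance of the mean", {
  sigs <- list(corrected_signal(10, 0), corrected_signal(10, 0))
  z <- pool_corrected_signals(sigs)
  expect_equal(z$value, 10)
  expect_equal(z$variance, 0)

  sigs <- list(corrected_signal(9, 0), corrected_signal(11, 0))
  z <- pool_corrected_signals(sigs)
  expect_equal(z$value, 10)
  expect_equal(z$variance, var(c(9, 11)) / 2)  # s^2/n = 1
  expect_equal(z$n_dosimeters, 2L)

  expect_error(pool_corrected_signals(list()), "non-empty")
})

test_that("pooled uncertainty of replicate dosimeters matches the generating noise", {
  # 6 dosimeters x 3 reads with 0.8%/2-sigma read noise and 1%/2-sigma
  # sensitivity scatter: the pooled rel 2-sigma should estimate the true
  # spread of the pooled mean.
  set.seed(33)
  truth <- scanner_truth_model()
  reps <- 200
  out <- replicate(reps, {
    set <- osldose:::simulate_osld_set(truth, 3e4, 6L, 3L)
    p <- pool_corrected_signals(set$signals)
    c(p$value, sqrt(p$variance))
  })
  empirical_sd <- sd(out[1, ])
  mean_propagated_sd <- mean(out[2, ])
  expect_lt(abs(mean_propagated_sd / empirical_sd - 1), 0.25)
  # and the scale is the percent-level of the quoted reading uncertainty
  rel2 <- 200 * mean_propagated_sd / mean(out[1, ])
  expect_gt(rel2, 0.1); expect_lt(rel2, 1.3)
})

test_that("element sensitivities are the signal ratios and average to one", {
  ks <- measure_element_sensitivity(c(90, 110))
  expect_equal(vapply(ks, `[[`, numeric(1), "k_s"), c(0.9, 1.1))

  ks <- measure_element_sensitivity(rep(123.4, 5))
  expect_true(all(vapply(ks, `[[`, numeric(1), "k_s") == 1))

  set.seed(4)
  sig <- runif(12, 5e3, 2e4)
  ks <- vapply(measure_element_sensitivity(sig), `[[`, numeric(1), "k_s")
  expect_equal(mean(ks), 1, tolerance = 1e-12)

  expect_error(measure_element_sensitivity(100), "at least 2")
  expect_error(measure_element_sensitivity(c(100, -5)), "positive")
})

test_that("true multiplicative sensitivities are recovered from a common dose", {
  set.seed(9)
  t_i <- exp(rnorm(20, 0, 0.02))
  signals <- 1e4 * t_i * exp(rnorm(20, 0, 0.002))
  ks <- vapply(measure_element_sensitivity(signals), `[[`, numeric(1), "k_s")
  expect_equal(ks, t_i / mean(t_i), tolerance = 0.01)
})

test_that("reading and sensitivity CSV round-trip", {
  seqs <- list(reading_sequence("d1", "b1", c(100.5, 99.1, 97.6)),
               reading_sequence("d2", "b1", c(200.25, 197)))
  path <- withr::local_tempfile(fileext = ".csv")
  write_readings_csv(seqs, path)
  back <- read_readings_csv(path)
  expect_equal(back$d1$counts, seqs[[1]]$counts)
  expect_equal(back$d2$counts, seqs[[2]]$counts)
  expect_equal(back$d2$J, 2L)

  spath <- withr::local_tempfile(fileext = ".csv")
  writeLines("dosimeter_id,k_s,batch_id,batch_mean\nd1,0.97,b1,1\nd2,1.03,b1,1",
             spath)
  sens <- read_sensitivity_csv(spath)
  expect_equal(sens$d2$k_s, 1.03)
  expect_error(read_readings_csv(spath), "columns")
})
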