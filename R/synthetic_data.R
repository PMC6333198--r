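#' Scanner truth model for synthetic sessions
#'
#' Defines the ground truth a synthetic study is generated from: the true
#' dose per measurement condition, the true beam-quality chain per
#' protocol, the true calibration coefficients, and the noise scales of
#' the reader and the dosimeter batch. Defaults mirror the reference study
#' conditions: per-condition doses between 25 and 40 mGy, per-read
#' depletion of 1.6%, multiplicative read noise of 0.8% (2 sigma), element
#' sensitivities spread 1.0% (2 sigma) around the batch mean, and batch
#' mean inherent sensitivities 0.85 (calibration) and 0.93 (experimental).
#'
#' The element-sensitivity convention matches the signal module: a
#' dosimeter's raw response is proportional to `1/k_s`, so applying the
#' multiplicative k_s correction cancels element-to-element variation, and
#' a whole batch's corrected signals scale with (experimental mean /
#' own-batch mean) -- which is what makes the vendor batch adjustment
#' recover the experimental-batch coefficient exactly at zero noise.
#'
#' @param conditions Design data.frame (default [table1_conditions()]).
#' @param true_dose_mGy True dose per condition (defaults to the packaged
#'   validation chamber doses).
#' @param kq_tables A [kq_tables] object; the true beam-quality factors
#'   are seeded from its energy table.
#' @param true_nd Named vector of true calibration coefficients
#'   (mGy/count) for `vendor`, `ct_air`, `megavoltage`.
#' @param read_noise_rel Relative 1-sigma multiplicative read noise
#'   (default 0.004, i.e. 0.8% at 2 sigma).
#' @param sensitivity_spread_rel Relative 1-sigma spread of element
#'   sensitivities within a batch (default 0.005, i.e. 1.0% at 2 sigma).
#' @param sensitivity_measurement_rel Relative 1-sigma error of the
#'   *measured* element-sensitivity factors used in correction (default
#'   0.005).
#' @param depletion_per_read Per-read signal loss (default 0.016).
#' @param batch_means Named vector of batch mean inherent sensitivities;
#'   defaults `c(calibration = 0.85, experimental = 0.93)`.
#' @param chamber_repeat_rel Relative 1-sigma repeatability of an ion
#'   chamber reading (default 0.0025).
#' @param zero_dose_counts Floor counts read from an unirradiated
#'   standard (default 50).
#' @param noise_model `"lognormal"` (default; signals are positive and
#'   uncertainties are quoted relatively) or `"gaussian"`.
#' @return An object of class `scanner_truth`.
#' @export
scanner_truth_model <- function(conditions = table1_conditions(),
                                true_dose_mGy = NULL,
                                kq_tables = load_kq_tables(),
                                true_nd = NULL,
                                read_noise_rel = 0.004,
                                sensitivity_spread_rel = 0.005,
                                sensitivity_measurement_rel = 0.005,
                                depletion_per_read = 0.016,
                                batch_means = c(calibration = 0.85,
                                                experimental = 0.93),
                                chamber_repeat_rel = 0.0025,
                                zero_dose_counts = 50,
                                noise_model = c("lognormal", "gaussian")) {
  noise_model <- match.arg(noise_model)
  if (is.null(true_dose_mGy)) true_dose_mGy <- table3_doses()$chamber_mGy
  if (length(true_dose_mGy) != nrow(conditions))
    stop("one true dose per condition is required", call. = FALSE)
  if (any(true_dose_mGy <= 0)) stop("true doses must be positive", call. = FALSE)
  if (read_noise_rel < 0 || read_noise_rel >= 0.5 ||
      sensitivity_spread_rel < 0 || sensitivity_spread_rel >= 0.5)
    stop("noise fractions must lie in [0, 0.5)", call. = FALSE)
  if (is.null(true_nd)) {
    # ct_air anchors the scale; the other two are chosen consistent with
    # the mean of the energy table so cross-protocol doses agree to ~1%.
    kq_ct <- kq_tables$by_energy$ct_air
    kq_mv <- kq_tables$by_energy$megavoltage
    true_nd <- c(vendor = 1e-3 * mean(kq_ct) / kq_tables$vendor_kq,
                 ct_air = 1e-3,
                 megavoltage = 1e-3 * mean(kq_ct / kq_mv) /
                   kq_tables$k_G$megavoltage)
  }
  structure(
    list(conditions = conditions, true_dose_mGy = true_dose_mGy,
         kq_tables = kq_tables, true_nd = true_nd,
         read_noise_rel = read_noise_rel,
         sensitivity_spread_rel = sensitivity_spread_rel,
         sensitivity_measurement_rel = sensitivity_measurement_rel,
         depletion_per_read = depletion_per_read,
         batch_means = batch_means,
         chamber_repeat_rel = chamber_repeat_rel,
         zero_dose_counts = zero_dose_counts,
         noise_model = noise_model),
    class = "scanner_truth"
  )
}

# unit-mean multiplicative noise draws
mult_noise <- function(truth, n, sd) {
  if (sd == 0) return(rep(1, n))
  if (truth$noise_model == "lognormal")
    exp(stats::rnorm(n, -0.5 * log1p(sd^2), sqrt(log1p(sd^2))))
  else 1 + stats::rnorm(n, 0, sd)
}

#' True beam-quality factor under a protocol
#'
#' The generating k_Q for one condition: the energy-table value for the
#' CT and megavoltage protocols, and the vendor constant (1.19) for the
#' vendor protocol, so that each protocol's chain inverts exactly.
#'
#' @param truth A [scanner_truth].
#' @param protocol Protocol tag.
#' @param condition Row index into `truth$conditions` or a one-row
#'   data.frame from it.
#' @return The true k_Q (scalar).
#' @export
true_kq <- function(truth, protocol, condition) {
  row <- resolve_condition(truth, condition)
  if (protocol == "vendor") return(truth$kq_tables$vendor_kq)
  lookup_kq_by_energy(truth$kq_tables, protocol,
                      row$mean_spectral_energy_keV)$expected
}

resolve_condition <- function(truth, condition) {
  if (is.data.frame(condition)) return(condition)
  truth$conditions[condition, , drop = FALSE]
}

#' True (noise-free) corrected signal for a condition and protocol
#'
#' Inverts the dose equation: `M = D / (N_D * k_G * k_Q)` with the
#' protocol's own chain, i.e. the corrected signal an experimental-batch
#' dosimeter would yield.
#'
#' @param truth A [scanner_truth].
#' @param protocol Protocol tag.
#' @param condition Row index or one-row data.frame.
#' @param kq_override Optional generating k_Q (e.g. a jittered draw);
#'   default is [true_kq()].
#' @return Signal in counts.
#' @export
true_signal <- function(truth, protocol, condition, kq_override = NULL) {
  row <- resolve_condition(truth, condition)
  idx <- row$condition
  D <- truth$true_dose_mGy[match(idx, truth$conditions$condition)]
  kq <- if (is.null(kq_override)) true_kq(truth, protocol, row) else kq_override
  kg <- truth$kq_tables$k_G[[protocol]]
  D / (truth$true_nd[[protocol]] * kg * kq)
}

#' Simulate one raw reading sequence
#'
#' Generates J reads of one dosimeter whose corrected signal should
#' recover `signal_counts`: read j has expectation
#' `signal_counts * batch_scale / k_s * (1 - depletion)^(j-1)`, with
#' multiplicative read noise. `batch_scale` is (experimental batch mean /
#' own batch mean), the residual scale the vendor batch adjustment
#' corrects for.
#'
#' @param truth A [scanner_truth].
#' @param signal_counts Target corrected signal (counts) for an
#'   experimental-batch dosimeter; see [true_signal()].
#' @param dosimeter_id Identifier for the sequence.
#' @param J Number of reads (default 3).
#' @param k_s True element-sensitivity factor of this dosimeter
#'   (default 1).
#' @param batch `"experimental"` (default) or `"calibration"`.
#' @param noise Draw read noise? `FALSE` gives the exact expectations.
#' @return A [reading_sequence].
#' @export
simulate_reading_sequence <- function(truth, signal_counts,
                                      dosimeter_id = "d1", J = 3L,
                                      k_s = 1, batch = "experimental",
                                      noise = TRUE) {
  if (J < 1L) stop("'J' must be at least 1", call. = FALSE)
  if (signal_counts <= 0) stop("'signal_counts' must be positive", call. = FALSE)
  scale <- truth$batch_means[["experimental"]] / truth$batch_means[[batch]]
  base <- signal_counts * scale / k_s
  retention <- (1 - truth$depletion_per_read)^(seq_len(J) - 1L)
  eps <- if (noise) mult_noise(truth, J, truth$read_noise_rel) else rep(1, J)
  reading_sequence(dosimeter_id, batch, base * retention * eps)
}

# Draw a set of dosimeters, simulate their sequences at a common signal,
# and return the corrected signals (corrected with *measured* k_s).
simulate_osld_set <- function(truth, signal_counts, n_dosimeters, J,
                              batch = "experimental", noise = TRUE,
                              id_prefix = "d") {
  k_true <- if (noise)
    mult_noise(truth, n_dosimeters, truth$sensitivity_spread_rel)
  else rep(1, n_dosimeters)
  k_meas <- if (noise)
    k_true * mult_noise(truth, n_dosimeters, truth$sensitivity_measurement_rel)
  else k_true
  dep <- depletion_model(truth$depletion_per_read)
  seqs <- vector("list", n_dosimeters)
  signals <- vector("list", n_dosimeters)
  for (i in seq_len(n_dosimeters)) {
    id <- paste0(id_prefix, i)
    seqs[[i]] <- simulate_reading_sequence(truth, signal_counts, id, J,
                                           k_s = k_true[i], batch = batch,
                                           noise = noise)
    signals[[i]] <- correct_reading_sequence(
      seqs[[i]], dep, element_sensitivity(id, k_meas[i], batch))
  }
  list(sequences = seqs, signals = signals, k_true = k_true, k_meas = k_meas)
}

#' Simulate the inputs of one calibration session
#'
#' Generates, under a shared truth, everything a calibration protocol
#' consumes: for `"vendor"`, a standard set at dose levels 0/3/20 mGy
#' read from the calibration batch (five dosimeters per level, common
#' delivered-dose error); for `"ct_air"`, six free-in-air standards and
#' three chamber doses (5% systematic 2-sigma plus repeatability); for
#' `"megavoltage"`, four standards and a 45 mGy decay-corrected delivered
#' dose (0.9% at 2 sigma). At `noise = FALSE` every calibration recovers
#' `truth$true_nd[[protocol]]` exactly.
#'
#' @param truth A [scanner_truth].
#' @param protocol Protocol tag.
#' @param noise Draw noise? Default `TRUE`.
#' @param n_reads Reads per standard (default 3).
#' @return A list with the protocol's inputs plus `true_nd`; fields
#'   depend on the protocol (`standard_set`, or `signals` +
#'   `chamber_doses` / `delivered`).
#' @export
simulate_calibration_inputs <- function(truth,
                                        protocol = c("vendor", "ct_air",
                                                     "megavoltage"),
                                        noise = TRUE, n_reads = 3L) {
  protocol <- match.arg(protocol)
  nd <- truth$true_nd[[protocol]]
  if (protocol == "vendor") {
    levels <- c(0, 3, 20)
    sys <- if (noise) mult_noise(truth, 1, 5 / 200) else 1
    signals <- lapply(levels, function(D) {
      target <- if (D > 0) (D * sys) / nd else truth$zero_dose_counts
      set <- simulate_osld_set(truth, target, n_dosimeters = 5L, J = n_reads,
                               batch = "calibration", noise = noise,
                               id_prefix = sprintf("std%g_", D))
      pool_corrected_signals(set$signals)
    })
    list(protocol = protocol,
         standard_set = vendor_standard_set(
           levels, signals,
           calibration_batch_mean_sensitivity = truth$batch_means[["calibration"]],
           experimental_batch_mean_sensitivity = truth$batch_means[["experimental"]]),
         dose_systematic = sys, true_nd = nd)
  } else if (protocol == "ct_air") {
    # the chamber and the OSLD receive the same physical dose; the 5%
    # (2-sigma) uncertainty is the chamber calibration chain's *reporting*
    # error, so it perturbs the reported dose, not the OSLD signal
    D_nom <- 30
    sys <- if (noise) mult_noise(truth, 1, 5 / 200) else 1
    set <- simulate_osld_set(truth, D_nom / nd, n_dosimeters = 6L,
                             J = n_reads, noise = noise, id_prefix = "cal_d")
    rep_eps <- if (noise) mult_noise(truth, 3L, truth$chamber_repeat_rel)
               else rep(1, 3L)
    doses <- lapply(rep_eps, function(e)
      uq_from_rel(D_nom * sys * e, 5, "D_chamber"))
    list(protocol = protocol, signals = set$signals, chamber_doses = doses,
         dose_systematic = sys, true_nd = nd)
  } else {
    src <- co60_source(45, as.Date("2024-01-01"))
    delivered_nominal <- decay_corrected_dose(src, as.Date("2024-01-01"), 1)
    sys <- if (noise) mult_noise(truth, 1, 0.9 / 200) else 1
    D_true <- delivered_nominal$expected * sys
    set <- simulate_osld_set(truth, D_true / nd, n_dosimeters = 4L,
                             J = n_reads, noise = noise, id_prefix = "mv_d")
    delivered <- uq(delivered_nominal$expected, delivered_nominal$variance,
                    "D_Co60")
    list(protocol = protocol, signals = set$signals, delivered = delivered,
         dose_systematic = sys, true_nd = nd)
  }
}

#' Run a simulated calibration session end to end
#'
#' Convenience wrapper: [simulate_calibration_inputs()] followed by the
#' matching `calibrate_*` function.
#'
#' @param truth A [scanner_truth].
#' @param protocol Protocol tag.
#' @param ... Passed to [simulate_calibration_inputs()].
#' @return A [calibration_coefficient].
#' @export
simulate_calibration <- function(truth, protocol, ...) {
  inp <- simulate_calibration_inputs(truth, protocol, ...)
  switch(inp$protocol,
    vendor = calibrate_vendor(inp$standard_set),
    ct_air = calibrate_ct_air(inp$signals, inp$chamber_doses),
    megavoltage = calibrate_megavoltage(inp$signals, inp$delivered))
}

#' Simulate the pooled measurement signal at one condition
#'
#' Generates the replicate-dosimeter readings at a measurement condition
#' under one protocol's true chain and pools them. With `jitter_kq = TRUE`
#' the generating beam-quality (and geometry) factors are drawn around
#' their tabulated values with the configured relative uncertainties, so
#' that empirical dose errors are consistent with the propagated budget.
#'
#' @param truth A [scanner_truth].
#' @param condition Row index or one-row data.frame of the design.
#' @param protocol Protocol tag.
#' @param n_dosimeters,n_reads Replication (defaults 6 and 3).
#' @param noise Draw noise? Default `TRUE`.
#' @param jitter_kq Draw the generating k_Q (and k_G) around the table
#'   values? Default equals `noise`.
#' @return List with `pooled` ([corrected_signal]), `signals`,
#'   `sequences`, and the generating `kq` and `kg`.
#' @export
simulate_measurement_signals <- function(truth, condition, protocol,
                                         n_dosimeters = 6L, n_reads = 3L,
                                         noise = TRUE, jitter_kq = noise) {
  row <- resolve_condition(truth, condition)
  kq <- true_kq(truth, protocol, row)
  kg <- truth$kq_tables$k_G[[protocol]]
  if (jitter_kq) {
    kq_sd <- truth$kq_tables$rel_2sigma[[paste0("kq_", protocol)]] / 200
    kq <- kq * mult_noise(truth, 1, kq_sd)
    if (kg != 1)
      kg <- kg * mult_noise(truth, 1, truth$kq_tables$rel_2sigma$k_G / 200)
  }
  M <- {
    idx <- row$condition
    D <- truth$true_dose_mGy[match(idx, truth$conditions$condition)]
    D / (truth$true_nd[[protocol]] * kg * kq)
  }
  set <- simulate_osld_set(truth, M, n_dosimeters, n_reads, noise = noise,
                           id_prefix = paste0("c", row$condition, "_d"))
  list(pooled = pool_corrected_signals(set$signals), signals = set$signals,
       sequences = set$sequences, k_true = set$k_true, k_meas = set$k_meas,
       kq = kq, kg = kg)
}

#' Simulate a full measurement study
#'
#' Generates a seeded synthetic session over a design: at each condition,
#' replicate dosimeter reading sequences (six dosimeters, three reads
#' each by default) anchored to the chosen protocol's true chain, plus
#' repeated ion-chamber measurements (three by default) with ambient
#' temperature/pressure variation. The same seed always reproduces the
#' same session.
#'
#' @param truth A [scanner_truth].
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @param design Data.frame of conditions (default the truth's design).
#' @param n_dosimeters,n_reads,n_chamber Replication (defaults 6, 3, 3).
#' @param protocol_anchor Protocol whose chain generates the signals
#'   (default `"ct_air"`).
#' @param noise Draw noise? `FALSE` gives an exact, round-trippable
#'   session.
#' @param jitter_kq Draw the generating k_Q around the table value?
#'   Default equals `noise`.
#' @return An object of class `synthetic_session`: `seed`, `readings`
#'   (per-condition lists of [reading_sequence]), `sensitivities`
#'   (data.frame of true and measured k_s), `chamber` (data.frame of
#'   chamber records), `conditions`, `truth`, `generating` (per-condition
#'   k_Q and k_G draws).
#' @export
simulate_study <- function(truth, seed = NULL, design = truth$conditions,
                           n_dosimeters = 6L, n_reads = 3L, n_chamber = 3L,
                           protocol_anchor = "ct_air", noise = TRUE,
                           jitter_kq = noise) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (nrow(design) == 0L) stop("'design' must be non-empty", call. = FALSE)
  cal <- chamber_calibration(N_k = 8.5, P_elec = 1, muen_ratio = 1.06)
  readings <- list(); sens_rows <- list(); chamber_rows <- list()
  generating <- list()
  for (r in seq_len(nrow(design))) {
    row <- design[r, , drop = FALSE]
    sim <- simulate_measurement_signals(truth, row, protocol_anchor,
                                        n_dosimeters, n_reads, noise,
                                        jitter_kq)
    key <- as.character(row$condition)
    readings[[key]] <- sim$sequences
    generating[[key]] <- list(kq = sim$kq, kg = sim$kg)
    sens_rows[[key]] <- data.frame(
      condition = row$condition,
      dosimeter_id = vapply(sim$sequences, `[[`, character(1), "dosimeter_id"),
      k_s_true = sim$k_true, k_s = sim$k_meas)
    D <- truth$true_dose_mGy[match(row$condition,
                                   truth$conditions$condition)]
    temps <- if (noise) stats::rnorm(n_chamber, 22, 0.3) else rep(22, n_chamber)
    press <- if (noise) stats::rnorm(n_chamber, 101.33, 0.3)
             else rep(101.33, n_chamber)
    eps <- if (noise) mult_noise(truth, n_chamber, truth$chamber_repeat_rel)
           else rep(1, n_chamber)
    q <- vapply(seq_len(n_chamber), function(i) {
      m <- chamber_measurement(1, temps[i], press[i])
      (D * eps[i]) / (pressure_temperature_factor(m) * cal$P_elec *
                        cal$N_k * cal$muen_ratio)
    }, numeric(1))
    chamber_rows[[key]] <- data.frame(
      condition = row$condition, reading_q = q, temperature_C = temps,
      pressure_kPa = press, N_k = cal$N_k, P_elec = cal$P_elec,
      muen_ratio = cal$muen_ratio)
  }
  structure(
    list(seed = seed, readings = readings,
         sensitivities = do.call(rbind, sens_rows),
         chamber = do.call(rbind, chamber_rows),
         conditions = design, truth = truth, generating = generating,
         protocol_anchor = protocol_anchor),
    class = "synthetic_session"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a synthetic session to plain-text files
#'
#' Writes `readings.csv` (one row per read, dosimeter ids prefixed with
#' their condition), `chamber.csv`, and `truth.json`. Given the same
#' seeded session the outputs are byte-identical across runs.
#'
#' @param session A [synthetic_session].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_session_csv <- function(session, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  seqs <- unlist(session$readings, recursive = FALSE, use.names = FALSE)
  write_readings_csv(seqs, file.path(dir, "readings.csv"))
  utils::write.csv(session$chamber, file.path(dir, "chamber.csv"),
                   row.names = FALSE, quote = FALSE)
  truth <- session$truth
  jsonlite::write_json(
    list(seed = session$seed, protocol_anchor = session$protocol_anchor,
         true_dose_mGy = truth$true_dose_mGy,
         true_nd = as.list(truth$true_nd),
         read_noise_rel = truth$read_noise_rel,
         sensitivity_spread_rel = truth$sensitivity_spread_rel,
         depletion_per_read = truth$depletion_per_read,
         batch_means = as.list(truth$batch_means)),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
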