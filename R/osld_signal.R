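#' Raw OSLD reading sequence
#'
#' Ordered reader counts from repeated non-destructive reads of one
#' dosimeter. Read order matters: each read depletes a small fraction of
#' the stored signal, so later reads are systematically lower.
#'
#' @param dosimeter_id Dosimeter identifier.
#' @param batch_id Production-batch identifier.
#' @param counts Numeric vector of non-negative reader counts, in read
#'   order (j = 1..J).
#' @return An object of class `reading_sequence`.
#' @export
reading_sequence <- function(dosimeter_id, batch_id, counts) {
  if (length(counts) < 1L)
    stop("a reading sequence needs at least one read", call. = FALSE)
  if (!is.numeric(counts) || any(!is.finite(counts)) || any(counts < 0))
    stop("counts must be finite and non-negative", call. = FALSE)
  structure(
    list(dosimeter_id = as.character(dosimeter_id),
         batch_id = as.character(batch_id),
         counts = as.numeric(counts),
         J = length(counts)),
    class = "reading_sequence"
  )
}

#' @export
print.reading_sequence <- function(x, ...) {
  cat(sprintf("<reading_sequence> %s (batch %s), J = %d reads\n  counts: %s\n",
              x$dosimeter_id, x$batch_id, x$J,
              paste(signif(x$counts, 6), collapse = ", ")))
  invisible(x)
}

#' Per-read signal depletion model
#'
#' Each optical read removes a small fraction of the trapped-charge signal
#' (about 1.6% per read for a 7-s strong-LED readout of the nanoDot). The
#' stored parameter is the physical per-read loss; by default read j is
#' restored to its first-read equivalent by multiplying with
#' `(1 - loss)^-(j-1)`. The alternative `"retention"` convention instead
#' multiplies by the raw retention factor `(1 - loss)^(j-1)`, for users
#' whose commissioning expresses the correction that way.
#'
#' @param per_read_loss Fraction of signal lost per read, in `[0, 0.5)`.
#'   Default 0.016.
#' @param convention `"restore"` (default) or `"retention"`.
#' @return An object of class `depletion_model`.
#' @export
depletion_model <- function(per_read_loss = 0.016,
                            convention = c("restore", "retention")) {
  convention <- match.arg(convention)
  if (!is.numeric(per_read_loss) || length(per_read_loss) != 1L ||
      per_read_loss < 0 || per_read_loss >= 0.5)
    stop("'per_read_loss' must be a single fraction in [0, 0.5)", call. = FALSE)
  structure(list(per_read_loss = per_read_loss, convention = convention),
            class = "depletion_model")
}

#' Depletion correction factors for reads 1..J
#'
#' @param dep A [depletion_model].
#' @param J Number of reads.
#' @return Numeric vector of length J of multiplicative corrections for
#'   reads 1..J.
#' @export
depletion_factors <- function(dep, J) {
  retention <- 1 - dep$per_read_loss
  if (dep$convention == "restore") retention^(-(seq_len(J) - 1L))
  else retention^(seq_len(J) - 1L)
}

#' Per-dosimeter element sensitivity factor
#'
#' The multiplicative correction k_s applied to a dosimeter's reads in the
#' corrected-signal equation. The convention throughout the package is
#' that a dosimeter's raw response is proportional to 1/k_s, so that
#' multiplying by k_s (as the formalism prints it) cancels the
#' element-to-element variation.
#'
#' @param dosimeter_id Dosimeter identifier.
#' @param k_s Positive sensitivity factor.
#' @param batch_id Optional batch identifier.
#' @param batch_mean Optional batch-mean sensitivity (e.g. the 0.85 / 0.93
#'   inherent means of a calibration vs experimental batch).
#' @return An object of class `element_sensitivity`.
#' @export
element_sensitivity <- function(dosimeter_id, k_s, batch_id = NA_character_,
                                batch_mean = NA_real_) {
  if (!is.numeric(k_s) || length(k_s) != 1L || !is.finite(k_s) || k_s <= 0)
    stop("'k_s' must be a single positive number", call. = FALSE)
  structure(
    list(dosimeter_id = as.character(dosimeter_id), k_s = as.numeric(k_s),
         batch_id = as.character(batch_id), batch_mean = as.numeric(batch_mean)),
    class = "element_sensitivity"
  )
}

#' Corrected OSLD signal
#'
#' A depletion-, sensitivity- and background-corrected mean signal with its
#' variance (the variance of the mean, in counts squared).
#'
#' @param value Corrected mean signal in counts.
#' @param variance Variance of the mean, counts^2.
#' @param n_dosimeters Number of dosimeters pooled into the value.
#' @param n_reads_each Number of reads per dosimeter.
#' @param dosimeter_id,batch_id Optional provenance identifiers.
#' @return An object of class `corrected_signal`.
#' @export
corrected_signal <- function(value, variance, n_dosimeters = 1L,
                             n_reads_each = 1L,
                             dosimeter_id = NA_character_,
                             batch_id = NA_character_) {
  if (!is.numeric(variance) || variance < 0)
    stop("'variance' must be non-negative", call. = FALSE)
  out <- structure(
    list(value = as.numeric(value), variance = as.numeric(variance),
         n_dosimeters = as.integer(n_dosimeters),
         n_reads_each = as.integer(n_reads_each),
         dosimeter_id = as.character(dosimeter_id),
         batch_id = as.character(batch_id)),
    class = "corrected_signal"
  )
  if (out$value <= 0) attr(out, "nonphysical") <- TRUE
  out
}

#' @export
print.corrected_signal <- function(x, ...) {
  cat(sprintf("<corrected_signal> %.6g counts (var %.4g), %d dosimeter(s) x %d read(s)\n",
              x$value, x$variance, x$n_dosimeters, x$n_reads_each))
  if (isTRUE(attr(x, "nonphysical")))
    cat("  ** flagged non-physical (value <= 0) **\n")
  invisible(x)
}

#' @export
as_uq.corrected_signal <- function(x, label = "M_corr") {
  uq(x$value, x$variance, label)
}

#' Correct a raw reading sequence for depletion, sensitivity and background
#'
#' Computes `k_s * mean_j(counts_j * c_d^(j-1)) - background`, where the
#' per-read factor `c_d` restores (or, under the retention convention,
#' applies) the per-read depletion. The variance is the unbiased sample
#' variance of the depletion-corrected, sensitivity-scaled reads divided by
#' J (variance of the mean); background is treated as exact. For a single
#' read the variance falls back to a configured reader-noise model.
#'
#' @param seq A [reading_sequence].
#' @param dep A [depletion_model] (default: 1.6% per read, restoring).
#' @param sens An [element_sensitivity], or `NULL` for k_s = 1.
#' @param background Exact background signal in counts, subtracted last
#'   (default 0).
#' @param reader_noise_rel_2sigma Relative 2-sigma reader noise in percent
#'   used for the J = 1 variance fallback (default 0.8).
#' @return A [corrected_signal]. A result `<= 0` is returned flagged with
#'   attribute `nonphysical` and a warning rather than an error, since
#'   unirradiated background standards legitimately sit near zero.
#' @examples
#' s <- reading_sequence("d1", "b1", c(100, 98.4, 96.83))
#' correct_reading_sequence(s, depletion_model(0.016))
#' @export
correct_reading_sequence <- function(seq, dep = depletion_model(),
                                     sens = NULL, background = 0,
                                     reader_noise_rel_2sigma = 0.8) {
  if (!inherits(seq, "reading_sequence"))
    stop("'seq' must be a reading_sequence", call. = FALSE)
  if (!is.numeric(background) || length(background) != 1L || background < 0)
    stop("'background' must be a single non-negative number", call. = FALSE)
  k_s <- if (is.null(sens)) 1 else sens$k_s
  corrected <- k_s * seq$counts * depletion_factors(dep, seq$J)
  value <- mean(corrected) - background
  variance <- if (seq$J >= 2L) {
    stats::var(corrected) / seq$J
  } else {
    (mean(corrected) * reader_noise_rel_2sigma / 200)^2
  }
  out <- corrected_signal(value, variance, n_dosimeters = 1L,
                          n_reads_each = seq$J,
                          dosimeter_id = seq$dosimeter_id,
                          batch_id = seq$batch_id)
  if (value <= 0)
    warning("corrected signal is non-positive for dosimeter ",
            seq$dosimeter_id, "; flagged as non-physical", call. = FALSE)
  out
}

#' Pool corrected signals from replicate dosimeters
#'
#' Averages the corrected signals of dosimeters irradiated under one
#' condition. The variance of the pooled mean is the unbiased sample
#' variance of the individual values divided by n: the observed
#' between-dosimeter scatter already contains the within-dosimeter read
#' noise in expectation, so the two are not added twice. With a single
#' signal its own variance is passed through.
#'
#' @param signals Non-empty list of [corrected_signal] objects.
#' @return A pooled [corrected_signal].
#' @export
pool_corrected_signals <- function(signals) {
  if (!is.list(signals) || length(signals) == 0L)
    stop("'signals' must be a non-empty list", call. = FALSE)
  if (!all(vapply(signals, inherits, logical(1), "corrected_signal")))
    stop("all elements must be corrected_signal objects", call. = FALSE)
  values <- vapply(signals, `[[`, numeric(1), "value")
  n <- length(values)
  value <- mean(values)
  variance <- if (n >= 2L) stats::var(values) / n else signals[[1L]]$variance
  reads <- vapply(signals, `[[`, integer(1), "n_reads_each")
  corrected_signal(value, variance, n_dosimeters = n,
                   n_reads_each = reads[1L],
                   batch_id = signals[[1L]]$batch_id)
}

#' Measure element sensitivities from a common-dose irradiation
#'
#' A whole batch is irradiated to one common dose and read; each
#' dosimeter's relative factor is its own corrected signal divided by the
#' batch-mean signal, so the returned factors average to exactly 1 over
#' the batch that defines them.
#'
#' @param signals List of [corrected_signal] objects (element-sensitivity
#'   correction not yet applied), or a numeric vector of signals. At least
#'   two dosimeters.
#' @param batch_id Optional batch identifier stamped on the results.
#' @return List of [element_sensitivity] objects, one per input, with
#'   `batch_mean` set to the mean of the returned factors (1 by
#'   construction).
#' @export
measure_element_sensitivity <- function(signals, batch_id = NA_character_) {
  if (is.list(signals)) {
    ids <- vapply(signals, function(s) s$dosimeter_id, character(1))
    values <- vapply(signals, `[[`, numeric(1), "value")
  } else {
    values <- as.numeric(signals)
    ids <- names(signals)
    if (is.null(ids)) ids <- paste0("d", seq_along(values))
  }
  if (length(values) < 2L)
    stop("element sensitivity needs at least 2 dosimeters", call. = FALSE)
  if (any(values <= 0))
    stop("all signals must be positive to define sensitivities", call. = FALSE)
  k_s <- values / mean(values)
  lapply(seq_along(k_s), function(i)
    element_sensitivity(ids[i], k_s[i], batch_id = batch_id, batch_mean = 1))
}

#' Read raw reading sequences from CSV
#'
#' Expected columns: `dosimeter_id`, `batch_id`, `read_index` (1-based),
#' `counts`; one row per read.
#'
#' @param path Path to the CSV file.
#' @return Named list of [reading_sequence] objects (one per dosimeter, in
#'   first-appearance order, reads sorted by `read_index`).
#' @export
read_readings_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("dosimeter_id", "batch_id", "read_index", "counts")
  if (!all(need %in% names(df)))
    stop("readings CSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  ids <- unique(df$dosimeter_id)
  out <- lapply(ids, function(id) {
    rows <- df[df$dosimeter_id == id, , drop = FALSE]
    rows <- rows[order(rows$read_index), , drop = FALSE]
    reading_sequence(id, rows$batch_id[1L], rows$counts)
  })
  names(out) <- ids
  out
}

#' Write raw reading sequences to CSV
#'
#' Inverse of [read_readings_csv]. Counts are written at full precision
#' (`digits = 15`) so that a seeded simulation round-trips byte-identically.
#'
#' @param sequences List of [reading_sequence] objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_readings_csv <- function(sequences, path) {
  rows <- do.call(rbind, lapply(sequences, function(s)
    data.frame(dosimeter_id = s$dosimeter_id, batch_id = s$batch_id,
               read_index = seq_len(s$J),
               counts = formatC(s$counts, digits = 15, format = "g"),
               stringsAsFactors = FALSE)))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read element sensitivities from CSV
#'
#' Expected columns: `dosimeter_id`, `k_s`, `batch_id`, `batch_mean`.
#'
#' @param path Path to the CSV file.
#' @return Named list of [element_sensitivity] objects.
#' @export
read_sensitivity_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("dosimeter_id", "k_s", "batch_id", "batch_mean")
  if (!all(need %in% names(df)))
    stop("sensitivity CSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  out <- lapply(seq_len(nrow(df)), function(i)
    element_sensitivity(df$dosimeter_id[i], df$k_s[i], df$batch_id[i],
                        df$batch_mean[i]))
  names(out) <- df$dosimeter_id
  out
}
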