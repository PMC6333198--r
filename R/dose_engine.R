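#' Dose result
#'
#' Absorbed dose to water at the dosimeter position with its propagated
#' variance, the protocol that produced it, and (optionally) the
#' measurement condition.
#'
#' @param dose_mGy Dose in mGy. Positive.
#' @param variance Variance in mGy^2.
#' @param protocol Protocol tag.
#' @param condition Optional [measurement_condition].
#' @return An object of class `dose_result`.
#' @export
dose_result <- function(dose_mGy, variance, protocol, condition = NULL) {
  if (dose_mGy <= 0) stop("dose must be positive", call. = FALSE)
  if (variance < 0) stop("variance must be non-negative", call. = FALSE)
  structure(list(dose_mGy = dose_mGy, variance = variance,
                 protocol = protocol, condition = condition),
            class = "dose_result")
}

#' @export
print.dose_result <- function(x, ...) {
  cat(sprintf("<dose_result> %s: %.1f mGy +/- %.1f (2-sigma, %.1f%%)\n",
              x$protocol, x$dose_mGy, 2 * sqrt(x$variance),
              rel_2sigma(uq(x$dose_mGy, x$variance))))
  invisible(x)
}

#' @export
as_uq.dose_result <- function(x, label = "D") uq(x$dose_mGy, x$variance, label)

#' Compute absorbed dose from signal, coefficient and correction factors
#'
#' The dose formalism
#' `D = M_corr x N_D x k_L x k_F x k_G x k_theta x k_Q`,
#' with the variance propagated through the whole factor chain by the
#' exact product rule (recursively, factor by factor). The protocol tags
#' of the coefficient and the factor set must agree: under the vendor
#' protocol the chain is effectively `M x N x k_Q,vendor`; under the CT
#' protocol k_G is 1; under the megavoltage protocol k_G = 1.03 enters.
#'
#' @param signal A [corrected_signal] (positive value).
#' @param nd A [calibration_coefficient].
#' @param factors A [correction_factor_set] with matching protocol.
#' @return A [dose_result] carrying a `factors` attribute with the
#'   per-factor breakdown.
#' @examples
#' sig <- corrected_signal(1000, 0)
#' nd <- calibration_coefficient(0.03, 0, "ct_air")
#' cond <- measurement_condition(120, "free-in-air", "none")
#' compute_dose(sig, nd, factor_set_for("ct_air", cond))
#' @export
compute_dose <- function(signal, nd, factors) {
  stopifnot(inherits(signal, "corrected_signal"),
            inherits(nd, "calibration_coefficient"),
            inherits(factors, "correction_factor_set"))
  if (nd$protocol != factors$protocol)
    stop("protocol mismatch: coefficient is '", nd$protocol,
         "', factor set is '", factors$protocol, "'", call. = FALSE)
  if (signal$value <= 0)
    stop("cannot compute dose from a non-positive signal", call. = FALSE)
  chain <- list(as_uq(signal), as_uq(nd), factors$k_L, factors$k_F,
                factors$k_G, factors$k_theta, factors$k_Q)
  d <- var_chain(chain, "D")
  out <- dose_result(d$expected, d$variance, nd$protocol)
  attr(out, "factors") <- factors
  out
}

#' Percent difference between a reference and a test dose
#'
#' `100 * |reference - test| / reference` by default (the unsigned
#' convention used in the validation tables); `signed = TRUE` keeps the
#' sign of `reference - test`.
#'
#' @param reference Reference dose ([dose_result], [uq] or number); must
#'   be non-zero.
#' @param test Test dose (same types).
#' @param signed Keep the sign? Default `FALSE`.
#' @return Percent difference (scalar), at full precision.
#' @export
percent_difference <- function(reference, test, signed = FALSE) {
  ref <- dose_value(reference)
  tst <- dose_value(test)
  if (ref == 0) stop("reference dose must be non-zero", call. = FALSE)
  d <- 100 * (ref - tst) / ref
  if (signed) d else abs(d)
}

dose_value <- function(x) {
  if (inherits(x, "dose_result")) x$dose_mGy
  else if (inherits(x, "uq")) x$expected
  else if (is.numeric(x) && length(x) == 1L) as.numeric(x)
  else stop("cannot interpret a dose from class ",
            paste(class(x), collapse = "/"), call. = FALSE)
}

#' Protocol comparison summary
#'
#' Per-condition percent differences of each protocol's OSLD dose from the
#' chamber dose, plus the unweighted mean of the absolute percent
#' differences per protocol (the "Average" row of a validation table).
#'
#' @param rows A data.frame with a `chamber_mGy` column and one or more of
#'   `vendor_mGy`, `ct_air_mGy`, `megavoltage_mGy`; any other columns
#'   (condition labels, kVp, energy) are carried through.
#' @param signed Passed to [percent_difference].
#' @return A data.frame of class `dose_comparison` with a `*_pct` column
#'   per protocol, at full precision, and an attribute `averages` (named
#'   vector of column means of the absolute differences). Its print method
#'   rounds to one decimal for display.
#' @export
comparison_summary <- function(rows, signed = FALSE) {
  if (!is.data.frame(rows) || nrow(rows) == 0L)
    stop("'rows' must be a non-empty data.frame", call. = FALSE)
  if (!"chamber_mGy" %in% names(rows))
    stop("'rows' must have a 'chamber_mGy' column", call. = FALSE)
  protos <- intersect(c("vendor", "ct_air", "megavoltage"),
                      sub("_mGy$", "", grep("_mGy$", names(rows), value = TRUE)))
  protos <- setdiff(protos, "chamber")
  if (!length(protos))
    stop("no protocol dose columns (*_mGy) found", call. = FALSE)
  out <- rows
  averages <- numeric(0)
  for (p in protos) {
    pct <- mapply(percent_difference, rows$chamber_mGy,
                  rows[[paste0(p, "_mGy")]],
                  MoreArgs = list(signed = signed))
    out[[paste0(p, "_pct")]] <- pct
    averages[p] <- mean(abs(pct))
  }
  attr(out, "averages") <- averages
  class(out) <- c("dose_comparison", class(out))
  out
}

#' @export
print.dose_comparison <- function(x, ...) {
  shown <- as.data.frame(x)
  num <- vapply(shown, is.numeric, logical(1))
  shown[num] <- lapply(shown[num], round, digits = 1)
  print(shown, row.names = FALSE)
  av <- attr(x, "averages")
  cat("Average |% diff|:",
      paste(sprintf("%s = %.1f", names(av), av), collapse = ", "), "\n")
  invisible(x)
}

#' Published validation doses (11 CT conditions)
#'
#' The packaged comparison dataset: for eleven CT measurement conditions
#' (80-140 kVp; center, periphery and surface positions in 16 and 32 cm
#' CTDI phantoms), the ion-chamber dose and the OSLD dose under each of
#' the three calibration protocols, with the printed percent differences.
#' These are transcribed published values (rounded to one decimal), not
#' simulated data.
#'
#' @return A data.frame with columns `condition`, `kvp`, `energy_keV`,
#'   `chamber_mGy`, and `<protocol>_mGy` / `<protocol>_pct` for the
#'   vendor, ct_air and megavoltage protocols.
#' @export
table3_doses <- function() {
  utils::read.csv(system.file("extdata", "table3_doses.csv",
                              package = "osldose"))
}

#' Validation measurement conditions (11 CT conditions)
#'
#' The scanning parameters and dosimeter positions of the packaged
#' validation design: kVp, phantom, position, scan type and extent, and
#' the mean spectral energy at the dosimeter position from spectral
#' characterization of the scanner.
#'
#' @return A data.frame with columns `condition`, `phantom`, `position`,
#'   `kvp`, `scan_extent_mm`, `scan_type`, `mean_spectral_energy_keV`.
#' @export
table1_conditions <- function() {
  utils::read.csv(system.file("extdata", "table1_conditions.csv",
                              package = "osldose"))
}

#' Condition descriptor from a validation-design row
#'
#' @param row One row of [table1_conditions()].
#' @return A [measurement_condition].
#' @export
condition_from_row <- function(row) {
  measurement_condition(
    kvp = row$kvp, position = row$position, phantom = row$phantom,
    scan_type = row$scan_type, scan_extent_mm = row$scan_extent_mm,
    mean_spectral_energy_keV = row$mean_spectral_energy_keV)
}
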