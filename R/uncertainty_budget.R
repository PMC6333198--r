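#' Calibration-coefficient uncertainty from its components
#'
#' Combines the relative 2-sigma uncertainty of the corrected OSLD reading
#' with that of the dose delivered to the standards, through the exact
#' product rule applied to the dose-over-signal quotient. With the
#' reference component values (reading 1.3%; delivered dose 5% for the
#' vendor and CT protocols, 0.9% for the megavoltage protocol) this gives
#' 5.2% and 1.6% respectively.
#'
#' @param reading_rel_2sigma Relative 2-sigma of the corrected OSLD
#'   signal, percent.
#' @param dose_rel_2sigma Relative 2-sigma of the dose delivered to the
#'   standards, percent.
#' @return Relative 2-sigma of the coefficient, percent (full precision).
#' @examples
#' coefficient_uncertainty(1.3, 0.9)  # ~1.58 -> reported as 1.6
#' coefficient_uncertainty(1.3, 5)    # ~5.17 -> reported as 5.2
#' @export
coefficient_uncertainty <- function(reading_rel_2sigma, dose_rel_2sigma) {
  d <- uq_from_rel(1, dose_rel_2sigma, "D_standards")
  s <- uq_from_rel(1, reading_rel_2sigma, "M_corr")
  rel_2sigma(uq_quotient(d, s, "N_D"))
}

#' Itemized dose uncertainty budget
#'
#' Reports, for one dose determination, the relative 2-sigma uncertainty
#' of every factor in the dose chain (corrected signal, calibration
#' coefficient, k_L, k_F, k_G, k_theta, k_Q) and the total obtained by the
#' exact product rule folded over the chain. Because of the exact cross
#' term, the total is always at least the root-sum-square of the
#' components, strictly greater whenever two or more are non-zero.
#'
#' @param signal A [corrected_signal] or [uq] for the corrected reading.
#' @param nd A [calibration_coefficient] or [uq].
#' @param factors A [correction_factor_set].
#' @return A data.frame of class `uncertainty_budget` with columns
#'   `component`, `expected`, `rel_2sigma_pct`, ending in a `total` row;
#'   attribute `total` holds the total as a [uq].
#' @examples
#' cond <- measurement_condition(120, "center", "32 cm",
#'                               mean_spectral_energy_keV = 54.7)
#' nd <- uq_from_rel(0.001, coefficient_uncertainty(1.3, 5), "N_D")
#' sig <- uq_from_rel(30000, 1.3, "M_corr")
#' dose_uncertainty_budget(sig, nd, factor_set_for("ct_air", cond))
#' @export
dose_uncertainty_budget <- function(signal, nd, factors) {
  stopifnot(inherits(factors, "correction_factor_set"))
  chain <- list(
    M_corr = as_uq(signal, "M_corr"),
    N_D = as_uq(nd, "N_D"),
    k_L = factors$k_L, k_F = factors$k_F, k_G = factors$k_G,
    k_theta = factors$k_theta, k_Q = factors$k_Q
  )
  if (any(vapply(chain, function(x) x$expected, numeric(1)) == 0))
    stop("all chain components must have non-zero expectation", call. = FALSE)
  total <- var_chain(unname(chain), "D")
  df <- data.frame(
    component = c(names(chain), "total"),
    expected = c(vapply(chain, `[[`, numeric(1), "expected"), total$expected),
    rel_2sigma_pct = c(vapply(chain, rel_2sigma, numeric(1)),
                       rel_2sigma(total))
  )
  attr(df, "total") <- total
  class(df) <- c("uncertainty_budget", class(df))
  df
}

#' @export
print.uncertainty_budget <- function(x, ...) {
  df <- as.data.frame(x)
  df$expected <- signif(df$expected, 6)
  df$rel_2sigma_pct <- round(df$rel_2sigma_pct, 2)
  print(df, row.names = FALSE)
  invisible(x)
}
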