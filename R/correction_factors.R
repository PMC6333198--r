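#' Load the beam-quality correction-factor tables
#'
#' The k_Q tables ship as versioned JSON configuration rather than
#' hard-coded constants, because the values are specific to the scanner
#' spectrum they were derived for. The file carries three lookup routes:
#' a per-condition table keyed by mean spectral energy (for spectra that
#' have been characterized), simplified tables keyed by nominal kVp and
#' measurement position (the clinically practical route), and the vendor's
#' single constant (1.19 for all CT measurements). It also carries the
#' geometry factor k_G per protocol and the default relative 2-sigma
#' uncertainties attached to each factor on lookup.
#'
#' Loading validates value ranges and checks that k_Q is non-decreasing in
#' mean spectral energy / kVp and ordered surface >= periphery >= center.
#' Non-monotone adjacent pairs in the energy table are *flagged* (stored in
#' the `monotonicity_exceptions` attribute), not silently reordered: the
#' shipped table contains one such printed pair (58.1 keV / 58.7 keV).
#'
#' @param path Path to a table JSON; default is the file shipped with the
#'   package.
#' @return An object of class `kq_tables`.
#' @export
load_kq_tables <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "kq_tables.json", package = "osldose")
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  tbl <- structure(
    list(by_energy = as.data.frame(cfg$by_energy),
         by_kvp_position = lapply(cfg$by_kvp_position, as.data.frame),
         vendor_kq = cfg$vendor_kq,
         k_G = cfg$k_G,
         rel_2sigma = cfg$rel_2sigma,
         version = cfg$version),
    class = "kq_tables"
  )
  validate_kq_tables(tbl)
}

validate_kq_tables <- function(tbl) {
  be <- tbl$by_energy
  need <- c("energy_keV", "ct_air", "megavoltage")
  if (!all(need %in% names(be)))
    stop("energy table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (is.unsorted(be$energy_keV, strictly = TRUE))
    stop("energy table must be strictly increasing in energy", call. = FALSE)
  exceptions <- list()
  for (col in c("ct_air", "megavoltage")) {
    dec <- which(diff(be[[col]]) < 0)
    for (i in dec)
      exceptions[[length(exceptions) + 1L]] <- data.frame(
        table = "by_energy", column = col,
        energy_low = be$energy_keV[i], energy_high = be$energy_keV[i + 1L],
        value_low = be[[col]][i], value_high = be[[col]][i + 1L])
  }
  for (proto in names(tbl$by_kvp_position)) {
    kp <- tbl$by_kvp_position[[proto]]
    if (!all(c("kvp", "surface", "periphery", "center") %in% names(kp)))
      stop("kvp/position table for '", proto, "' is incomplete", call. = FALSE)
    for (col in c("surface", "periphery", "center"))
      if (any(diff(kp[[col]]) < 0))
        stop("k_Q must be non-decreasing in kVp in the '", proto, "' table",
             call. = FALSE)
    if (any(kp$surface < kp$periphery) || any(kp$periphery < kp$center))
      stop("k_Q must be ordered surface >= periphery >= center ('",
           proto, "' table)", call. = FALSE)
  }
  rng_ct <- range(tbl$by_kvp_position$ct_air[c("surface", "periphery", "center")])
  if (rng_ct[1] < 0.5 || rng_ct[2] > 1.5)
    stop("CT-protocol k_Q values outside a plausible range", call. = FALSE)
  rng_mv <- range(tbl$by_kvp_position$megavoltage[c("surface", "periphery",
                                                    "center")])
  if (rng_mv[1] < 0.1 || rng_mv[2] > 0.6)
    stop("megavoltage-protocol k_Q values outside a plausible range",
         call. = FALSE)
  attr(tbl, "monotonicity_exceptions") <-
    if (length(exceptions)) do.call(rbind, exceptions) else
      data.frame(table = character(), column = character(),
                 energy_low = numeric(), energy_high = numeric(),
                 value_low = numeric(), value_high = numeric())
  tbl
}

#' @export
print.kq_tables <- function(x, ...) {
  cat(sprintf("<kq_tables> version %s\n", x$version))
  cat(sprintf("  energy table: %d rows (%.1f-%.1f keV)\n",
              nrow(x$by_energy), min(x$by_energy$energy_keV),
              max(x$by_energy$energy_keV)))
  cat(sprintf("  kVp/position tables: %s; vendor k_Q = %.2f\n",
              paste(names(x$by_kvp_position), collapse = ", "), x$vendor_kq))
  ex <- attr(x, "monotonicity_exceptions")
  if (nrow(ex)) cat(sprintf("  flagged non-monotone pairs: %d\n", nrow(ex)))
  invisible(x)
}

#' Measurement condition descriptor
#'
#' One CT irradiation condition: tube potential, phantom, dosimeter
#' position, scan type and extent, and (if characterized) the mean
#' spectral energy at the dosimeter position.
#'
#' @param kvp Tube potential; one of 80, 120, 140.
#' @param position One of `"center"`, `"periphery"`, `"surface"`,
#'   `"free-in-air"`.
#' @param phantom One of `"32 cm"`, `"16 cm"`, `"none"`.
#' @param scan_type `"axial"` or `"helical"`.
#' @param scan_extent_mm Scan extent in mm (positive).
#' @param mean_spectral_energy_keV Optional mean spectral energy in keV,
#'   in (20, 100) for CT beams.
#' @return An object of class `measurement_condition`.
#' @export
measurement_condition <- function(kvp,
                                  position = c("center", "periphery",
                                               "surface", "free-in-air"),
                                  phantom = c("32 cm", "16 cm", "none"),
                                  scan_type = c("axial", "helical"),
                                  scan_extent_mm = 40,
                                  mean_spectral_energy_keV = NULL) {
  position <- match.arg(position)
  phantom <- match.arg(phantom)
  scan_type <- match.arg(scan_type)
  if (!kvp %in% c(80, 120, 140))
    stop("'kvp' must be one of 80, 120, 140", call. = FALSE)
  if (scan_extent_mm <= 0) stop("'scan_extent_mm' must be positive",
                                call. = FALSE)
  if (!is.null(mean_spectral_energy_keV) &&
      (mean_spectral_energy_keV <= 20 || mean_spectral_energy_keV >= 100))
    stop("mean spectral energy must lie in (20, 100) keV for CT beams",
         call. = FALSE)
  structure(list(kvp = kvp, position = position, phantom = phantom,
                 scan_type = scan_type, scan_extent_mm = scan_extent_mm,
                 mean_spectral_energy_keV = mean_spectral_energy_keV),
            class = "measurement_condition")
}

#' Look up k_Q by nominal kVp and measurement position
#'
#' The clinically practical route: k_Q depends mostly on kVp and position
#' and only weakly on phantom size or scan extent, so a 3 x 3 table per
#' protocol suffices. The free-in-air position under the CT protocol is
#' the calibration condition itself and maps to exactly 1.
#'
#' @param tables A [kq_tables] object.
#' @param protocol `"vendor"`, `"ct_air"` or `"megavoltage"`.
#' @param cond A [measurement_condition].
#' @return A [uq] with the tabulated value and the configured relative
#'   uncertainty. Missing keys raise an error listing the available keys;
#'   there is no silent extrapolation.
#' @export
lookup_kq <- function(tables, protocol, cond) {
  stopifnot(inherits(tables, "kq_tables"),
            inherits(cond, "measurement_condition"))
  if (protocol == "vendor")
    return(uq_from_rel(tables$vendor_kq, tables$rel_2sigma$kq_vendor,
                       "k_Q"))
  if (cond$position == "free-in-air") {
    if (protocol == "ct_air") return(uq(1, 0, "k_Q"))
    stop("free-in-air conditions are not tabulated for the '", protocol,
         "' protocol; supply a mean spectral energy instead", call. = FALSE)
  }
  kp <- tables$by_kvp_position[[protocol]]
  if (is.null(kp))
    stop("no kVp/position table for protocol '", protocol, "'; available: ",
         paste(names(tables$by_kvp_position), collapse = ", "), call. = FALSE)
  row <- match(cond$kvp, kp$kvp)
  if (is.na(row))
    stop("kVp ", cond$kvp, " not tabulated; available: ",
         paste(kp$kvp, collapse = ", "), call. = FALSE)
  # "periphery" rows are tabulated at 1 cm depth
  col <- cond$position
  if (!col %in% c("surface", "periphery", "center"))
    stop("position '", col, "' not tabulated; available: surface, ",
         "periphery (1 cm depth), center", call. = FALSE)
  unc <- tables$rel_2sigma[[paste0("kq_", protocol)]]
  uq_from_rel(kp[[col]][row], unc, "k_Q")
}

#' Look up k_Q by mean spectral energy
#'
#' Linear interpolation in the per-condition energy table; exact at
#' tabulated nodes, with no extrapolation outside the table's span.
#'
#' @param tables A [kq_tables] object.
#' @param protocol `"ct_air"` or `"megavoltage"` (the vendor constant has
#'   no energy dependence).
#' @param energy_keV Mean spectral energy in keV, inside the table's span.
#' @return A [uq] with the interpolated value and the configured relative
#'   uncertainty.
#' @export
lookup_kq_by_energy <- function(tables, protocol, energy_keV) {
  stopifnot(inherits(tables, "kq_tables"))
  if (protocol == "vendor")
    return(uq_from_rel(tables$vendor_kq, tables$rel_2sigma$kq_vendor, "k_Q"))
  be <- tables$by_energy
  if (!protocol %in% names(be))
    stop("no energy column for protocol '", protocol, "'", call. = FALSE)
  span <- range(be$energy_keV)
  if (energy_keV < span[1] || energy_keV > span[2])
    stop(sprintf("energy %.1f keV outside the tabulated span [%.1f, %.1f]; no extrapolation",
                 energy_keV, span[1], span[2]), call. = FALSE)
  val <- stats::approx(be$energy_keV, be[[protocol]], xout = energy_keV,
                       method = "linear", ties = "ordered")$y
  unc <- tables$rel_2sigma[[paste0("kq_", protocol)]]
  uq_from_rel(val, unc, "k_Q")
}

#' Full correction-factor set for a protocol and condition
#'
#' Assembles the k_L, k_F, k_G, k_theta and k_Q factors of the dose
#' equation. Under the measurement conventions this package assumes
#' (dosimeters placed flat in the bore, no relative fading, linear
#' response at CT doses) k_L = k_F = k_theta = 1 exactly; k_G is 1 for the
#' vendor and CT protocols and 1.03 for the megavoltage protocol (static
#' en-face calibration vs rotating-source measurement); k_Q comes from the
#' energy table when a mean spectral energy is supplied (the
#' characterized-spectrum route), otherwise from the kVp/position table.
#'
#' @param protocol `"vendor"`, `"ct_air"` or `"megavoltage"`.
#' @param cond A [measurement_condition].
#' @param tables A [kq_tables] object (default: packaged tables).
#' @param prefer_energy If `TRUE` (default) and the condition carries a
#'   mean spectral energy, the energy-interpolated k_Q wins over the
#'   kVp/position value.
#' @return An object of class `correction_factor_set` with [uq] fields
#'   `k_L`, `k_F`, `k_G`, `k_theta`, `k_Q` and the protocol tag.
#' @export
factor_set_for <- function(protocol = c("vendor", "ct_air", "megavoltage"),
                           cond, tables = load_kq_tables(),
                           prefer_energy = TRUE) {
  protocol <- match.arg(protocol)
  stopifnot(inherits(cond, "measurement_condition"))
  k_q <- if (protocol != "vendor" && prefer_energy &&
             !is.null(cond$mean_spectral_energy_keV) &&
             cond$position != "free-in-air") {
    lookup_kq_by_energy(tables, protocol, cond$mean_spectral_energy_keV)
  } else {
    lookup_kq(tables, protocol, cond)
  }
  kg_val <- tables$k_G[[protocol]]
  k_g <- if (kg_val == 1) uq(1, 0, "k_G")
         else uq_from_rel(kg_val, tables$rel_2sigma$k_G, "k_G")
  structure(
    list(k_L = uq_from_rel(1, tables$rel_2sigma$k_L, "k_L"),
         k_F = uq_from_rel(1, tables$rel_2sigma$k_F, "k_F"),
         k_G = k_g,
         k_theta = uq_from_rel(1, tables$rel_2sigma$k_theta, "k_theta"),
         k_Q = k_q,
         protocol = protocol),
    class = "correction_factor_set"
  )
}

#' @export
print.correction_factor_set <- function(x, ...) {
  cat(sprintf("<correction_factor_set> protocol %s\n", x$protocol))
  for (nm in c("k_L", "k_F", "k_G", "k_theta", "k_Q"))
    cat(sprintf("  %-8s %.4g (rel 2-sigma %.2f%%)\n", nm, x[[nm]]$expected,
                if (x[[nm]]$expected != 0) rel_2sigma(x[[nm]]) else 0))
  invisible(x)
}
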