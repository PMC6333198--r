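#' Uncertain quantity
#'
#' The currency of the propagation engine: a scalar expected value paired
#' with an absolute variance. All dose-equation factors (corrected signal,
#' calibration coefficient, correction factors) are carried through the
#' pipeline as `uq` objects so that variances propagate by exact moments
#' rather than by first-order quadrature.
#'
#' @param expected Expected value E(X). Finite scalar.
#' @param variance Variance var(X). Non-negative finite scalar.
#' @param label Optional identifier used in printed budgets.
#' @return An object of class `uq` with fields `expected`, `variance`,
#'   `label`.
#' @examples
#' x <- uq(1, 0.01, "N_D")
#' rel_2sigma(x)
#' @export
uq <- function(expected, variance = 0, label = NULL) {
  if (!is.numeric(expected) || length(expected) != 1L || !is.finite(expected))
    stop("'expected' must be a single finite number", call. = FALSE)
  if (!is.numeric(variance) || length(variance) != 1L || !is.finite(variance) ||
      variance < 0)
    stop("'variance' must be a single non-negative finite number", call. = FALSE)
  structure(
    list(expected = as.numeric(expected), variance = as.numeric(variance),
         label = label),
    class = "uq"
  )
}

#' @export
print.uq <- function(x, ...) {
  lab <- if (is.null(x$label)) "" else paste0(" [", x$label, "]")
  cat(sprintf("<uq>%s E = %.6g, var = %.6g", lab, x$expected, x$variance))
  if (x$expected != 0)
    cat(sprintf(" (rel 2-sigma = %.3g%%)", rel_2sigma(x)))
  cat("\n")
  invisible(x)
}

#' Coerce to an uncertain quantity
#'
#' Numbers become exact (zero-variance) quantities; corrected signals and
#' calibration coefficients keep their value and variance.
#'
#' @param x Object to coerce.
#' @param label Optional label for the result.
#' @return A [uq] object.
#' @export
as_uq <- function(x, label = NULL) UseMethod("as_uq")

#' @export
as_uq.uq <- function(x, label = NULL) {
  if (!is.null(label)) x$label <- label
  x
}

#' @export
as_uq.numeric <- function(x, label = NULL) {
  if (length(x) != 1L) stop("cannot coerce a vector to a single 'uq'", call. = FALSE)
  uq(x, 0, label)
}

#' Relative expanded uncertainty at coverage factor 2
#'
#' Returns `100 * 2 * sqrt(var(X)) / |E(X)|`, the reporting convention used
#' throughout the package's budgets ("2-sigma percent").
#'
#' @param x A [uq] object (or anything [as_uq] accepts).
#' @return Relative 2-sigma uncertainty in percent.
#' @export
rel_2sigma <- function(x) {
  x <- as_uq(x)
  if (x$expected == 0) stop("relative uncertainty undefined for zero expectation",
                            call. = FALSE)
  100 * 2 * sqrt(x$variance) / abs(x$expected)
}

#' Build an uncertain quantity from a relative 2-sigma percentage
#'
#' @param expected Expected value.
#' @param rel_2sigma_pct Relative expanded (k = 2) uncertainty in percent.
#' @param label Optional label.
#' @return A [uq] object with `variance = (expected * pct / 200)^2`.
#' @export
uq_from_rel <- function(expected, rel_2sigma_pct, label = NULL) {
  if (rel_2sigma_pct < 0) stop("relative uncertainty must be >= 0", call. = FALSE)
  uq(expected, (abs(expected) * rel_2sigma_pct / 200)^2, label)
}

#' Exact variance of a product of independent random variables
#'
#' For independent X and Y,
#' `var(XY) = var(X) var(Y) + var(X) E(Y)^2 + var(Y) E(X)^2`.
#' This identity is exact for any distributions (no normality or
#' small-relative-error assumption); the leading cross term is what makes
#' the result strictly exceed the first-order quadrature approximation
#' whenever both variances are positive.
#'
#' @param x,y [uq] objects (or anything [as_uq] accepts), assumed
#'   independent.
#' @param label Optional label for the product.
#' @return A [uq] with `E = E(X) E(Y)` and the exact product variance.
#' @examples
#' var_product(uq(1, 0.01), uq(1, 0.04))$variance  # 0.0504
#' @export
var_product <- function(x, y, label = NULL) {
  x <- as_uq(x); y <- as_uq(y)
  v <- x$variance * y$variance +
    x$variance * y$expected^2 +
    y$variance * x$expected^2
  uq(x$expected * y$expected, v, label)
}

#' Exact variance of a product chain
#'
#' Applies [var_product] recursively over an ordered list of mutually
#' independent factors (the dose equation's
#' `M_corr x N_D x k_L x k_F x k_G x k_theta x k_Q` chain). The result is
#' independent of the fold order and of any parenthesization.
#'
#' @param factors Non-empty list of [uq] objects (or coercibles).
#' @param label Optional label for the result.
#' @return A [uq] for the product of all factors.
#' @export
var_chain <- function(factors, label = NULL) {
  if (!is.list(factors) || length(factors) == 0L)
    stop("'factors' must be a non-empty list", call. = FALSE)
  out <- Reduce(var_product, lapply(factors, as_uq), right = TRUE)
  out$label <- label
  out
}

#' Variance of a sum of (possibly correlated) random variables
#'
#' `var(X + Y) = var(X) + var(Y) + 2 cov(X, Y)`, exact for any joint
#' distribution. The covariance must satisfy the Cauchy-Schwarz bound
#' `|cov| <= sqrt(var(X) var(Y))`.
#'
#' @param x,y [uq] objects (or coercibles).
#' @param cov Covariance between X and Y (default 0, independence).
#' @return A [uq] for X + Y.
#' @export
var_sum <- function(x, y, cov = 0) {
  x <- as_uq(x); y <- as_uq(y)
  bound <- sqrt(x$variance * y$variance)
  if (abs(cov) > bound + 1e-12 * max(bound, 1))
    stop("covariance violates the Cauchy-Schwarz bound", call. = FALSE)
  v <- x$variance + y$variance + 2 * cov
  uq(x$expected + y$expected, max(v, 0))
}

#' Reciprocal of an uncertain quantity (first order)
#'
#' `E(1/Y)` is approximated by `1/E(Y)` and `var(1/Y)` by
#' `var(Y)/E(Y)^4`, i.e. the relative variance of the denominator is
#' preserved. Combined with [var_product] this gives the quotient
#' propagation used for calibration coefficients (dose / signal).
#'
#' @param y A [uq] with non-zero expectation.
#' @return A [uq] for 1/Y.
#' @export
uq_reciprocal <- function(y) {
  y <- as_uq(y)
  if (y$expected == 0) stop("cannot invert a quantity with zero expectation",
                            call. = FALSE)
  uq(1 / y$expected, y$variance / y$expected^4, y$label)
}

#' Quotient of two uncertain quantities
#'
#' X / Y computed as X * (1/Y): the reciprocal at first order, then the
#' exact product-variance identity.
#'
#' @param x Numerator [uq].
#' @param y Denominator [uq] with non-zero expectation.
#' @param label Optional label.
#' @return A [uq] for X / Y.
#' @export
uq_quotient <- function(x, y, label = NULL) {
  var_product(as_uq(x), uq_reciprocal(y), label)
}

#' Scale an uncertain quantity by an exact constant
#'
#' @param x A [uq].
#' @param a Exact scalar.
#' @return `uq(a * E, a^2 * var)`.
#' @export
uq_scale <- function(x, a) {
  x <- as_uq(x)
  uq(a * x$expected, a^2 * x$variance, x$label)
}

#' Variance of a pooled mean OSLD signal with correlated reads
#'
#' Repeated reads of one dosimeter share the latent true signal (and its
#' element-sensitivity factor) and so are correlated; reads of different
#' dosimeters are independent. This applies the covariance sum rule across
#' the J reads of each dosimeter (common covariance = the shared latent
#' variance), averages the resulting per-dosimeter variances across the I
#' independent dosimeters, and finally applies the exact product rule for
#' the element-sensitivity factor.
#'
#' The correlation model is: read = latent + noise, with `cov(read_j,
#' read_j') = var(latent)` for j != j' of the same dosimeter. The
#' per-dosimeter mean then has variance `var(latent) + var(noise)/J` (no
#' 1/J reduction of the shared part).
#'
#' @param read_matrix Numeric matrix of depletion-corrected reads, one row
#'   per dosimeter, one column per read.
#' @param shared_var Variance of the shared (between-read-correlated) latent
#'   component. If `NULL`, estimated from the matrix as
#'   `max(var(row means) - noise_var/J, 0)`.
#' @param noise_var Variance of the independent per-read noise. If `NULL`,
#'   estimated as the pooled within-dosimeter sample variance.
#' @param k_s A [uq] for the element-sensitivity factor applied to the mean
#'   (default exact 1).
#' @return A [uq] for the sensitivity-scaled grand mean signal.
#' @export
mean_signal_variance <- function(read_matrix, shared_var = NULL,
                                 noise_var = NULL, k_s = uq(1, 0)) {
  if (!is.matrix(read_matrix) || !is.numeric(read_matrix))
    stop("'read_matrix' must be a numeric matrix (dosimeters x reads)",
         call. = FALSE)
  I <- nrow(read_matrix); J <- ncol(read_matrix)
  if (I < 1L || J < 1L) stop("need at least one dosimeter and one read",
                             call. = FALSE)
  if (is.null(noise_var)) {
    noise_var <- if (J >= 2L) mean(apply(read_matrix, 1L, stats::var)) else 0
  }
  row_means <- rowMeans(read_matrix)
  if (is.null(shared_var)) {
    shared_var <- if (I >= 2L) max(stats::var(row_means) - noise_var / J, 0) else 0
  }
  # Eq.-9 fold over the J reads of one dosimeter: var(sum) =
  # J*var(read) + J(J-1)*shared_var; mean => /J^2.
  per_dot_var <- shared_var + noise_var / J
  grand <- uq(mean(row_means), per_dot_var / I)
  var_product(grand, as_uq(k_s), "M_corr")
}

#' Monte Carlo oracle for moment propagation
#'
#' Samples a user-specified expression of independent (or jointly normal
#' correlated) random inputs and reports the sample mean and variance with
#' their standard errors. Used to validate the exact-moment propagation
#' rules ([var_product], [var_sum], [var_chain]) on seeded batteries.
#'
#' @param vars Named list of distribution descriptors, each a list with
#'   `dist` ("normal" or "lognormal"), `mean`, and `sd` (moments of the
#'   sampled variable itself, not of log-space).
#' @param expr A function taking a data.frame of samples (columns named as
#'   `vars`) and returning one numeric vector of the same length.
#' @param n Number of samples (>= 1e4).
#' @param seed Integer seed; the same seed always reproduces the result.
#' @param cor Optional correlation matrix (dimnames matching `vars`)
#'   imposed on the underlying Gaussian draws. Exact for normal marginals;
#'   approximate in the tails for lognormal ones.
#' @return A list of class `mc_estimate` with `expected`, `variance`,
#'   `se_expected`, `se_variance`, `n`.
#' @export
mc_oracle <- function(vars, expr, n = 1e6, seed = 1L, cor = NULL) {
  if (n < 1e4) stop("'n' must be at least 1e4 for a usable oracle", call. = FALSE)
  if (!length(vars) || is.null(names(vars)) || any(!nzchar(names(vars))))
    stop("'vars' must be a named list of distribution descriptors", call. = FALSE)
  n <- as.integer(n)
  k <- length(vars)
  set.seed(as.integer(seed))
  z <- matrix(stats::rnorm(n * k), n, k, dimnames = list(NULL, names(vars)))
  if (!is.null(cor)) {
    cor <- cor[names(vars), names(vars), drop = FALSE]
    ev <- eigen(cor, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8) stop("'cor' is not positive semi-definite", call. = FALSE)
    z <- z %*% chol(cor)
    colnames(z) <- names(vars)
  }
  samples <- as.data.frame(lapply(names(vars), function(nm) {
    d <- vars[[nm]]
    if (is.null(d$dist) || is.null(d$mean) || is.null(d$sd))
      stop("descriptor for '", nm, "' needs 'dist', 'mean', 'sd'", call. = FALSE)
    switch(d$dist,
      normal = d$mean + d$sd * z[, nm],
      lognormal = {
        if (d$mean <= 0) stop("lognormal mean must be positive", call. = FALSE)
        s2 <- log1p((d$sd / d$mean)^2)
        exp(log(d$mean) - s2 / 2 + sqrt(s2) * z[, nm])
      },
      stop("unknown distribution '", d$dist, "'", call. = FALSE)
    )
  }))
  names(samples) <- names(vars)
  y <- expr(samples)
  if (length(y) != n) stop("'expr' must return one value per sample", call. = FALSE)
  m <- mean(y)
  v <- stats::var(y)
  m4 <- mean((y - m)^4)
  structure(
    list(expected = m, variance = v,
         se_expected = sqrt(v / n),
         se_variance = sqrt(max(m4 - v^2, 0) / n),
         n = n),
    class = "mc_estimate"
  )
}

#' @export
print.mc_estimate <- function(x, ...) {
  cat(sprintf("<mc_estimate> n = %d\n  E = %.6g (SE %.3g)\n  var = %.6g (SE %.3g)\n",
              x$n, x$expected, x$se_expected, x$variance, x$se_variance))
  invisible(x)
}
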