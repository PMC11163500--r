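#' Detector output ratio
#'
#' Output ratio of a clinical field to the machine-specific reference
#' field, \eqn{OR = M_{det}^{clin} / M_{det}^{msr}}, from detector readings
#' per monitor unit. With repeated readings, the ratio of the mean signals
#' is reported and the type-A (k=1) uncertainty is propagated by quadrature
#' of the relative standard errors of numerator and denominator. The ratio
#' is invariant under a common rescaling of the MU normalization.
#'
#' @param Mclin,Mmsr detector readings (signal/MU) at the clinical and msr
#'   field; vectors of repeats or single values. All readings must be
#'   positive.
#' @param fieldSize optional nominal field size in mm (metadata).
#' @return list with `fieldSize`, `Mclin`, `Mmsr` (mean signals),
#'   `value` (the OR) and `uncertainty` (k=1; `NA` without repeats).
#' @examples
#' outputRatio(c(1.00, 1.01, 0.99), c(2.00, 2.02, 1.98))
#' @export
outputRatio <- function(Mclin, Mmsr, fieldSize = NA_real_) {
  if (min(Mclin) <= 0 || min(Mmsr) <= 0)
    stop("detector readings must be positive")
  mc <- mean(Mclin); mm <- mean(Mmsr)
  or <- mc / mm
  relse <- function(x) if (length(x) > 1L)
    stats::sd(x) / sqrt(length(x)) / mean(x) else NA_real_
  u <- sqrt(relse(Mclin)^2 + relse(Mmsr)^2) * or
  list(fieldSize = fieldSize, Mclin = mc, Mmsr = mm,
       value = or, uncertainty = u)
}

#' Apply a total correction factor to an output ratio
#'
#' The corrected output factor is the uncorrected detector output ratio
#' multiplied by the total perturbation correction
#' \eqn{k = P_{housing} P_{sens} P_{vol}} for that field size.
#'
#' @param or an output-ratio value or the list returned by [outputRatio()].
#' @param kTotal total correction factor (> 0).
#' @return corrected output factor (numeric).
#' @export
correctedOutputFactor <- function(or, kTotal) {
  if (any(kTotal <= 0)) stop("'kTotal' must be positive")
  val <- if (is.list(or)) or$value else or
  val * kTotal
}

#' Parametric output-factor field-size curve
#'
#' The saturating two-component output-factor parameterization
#' \deqn{OF(s) = p \frac{s^n}{a^n + s^n} \left(1 - e^{-b s}\right)}
#' with nominal field size `s` in mm. This single function defines the fit
#' form used throughout the package, so an alternative parameterization
#' can be swapped in at one place.
#'
#' @param s nominal field size(s) in mm.
#' @param params named vector or list with `p`, `a`, `b`, `n`.
#' @return OF values.
#' @export
ofCurve <- function(s, params) {
  params <- as.list(params)
  with(params, p * s^n / (a^n + s^n) * (1 - exp(-b * s)))
}

#' Fit the parametric output-factor curve
#'
#' Nonlinear least-squares fit of [ofCurve()] to measured output factors
#' versus nominal field size, with five deterministic multi-starts
#' spanning half-saturation sizes `a` of 2-10 mm and Hill exponents `n` of
#' 1-3; the start reaching the lowest residual sum wins. Non-convergence
#' from every start is an error listing the tried starts.
#'
#' @param sizes nominal field sizes in mm (at least 5, spanning the range).
#' @param ofValues output factors in (0, 1.2].
#' @return list with `params` (named p, a, b, n), `residuals`,
#'   `maxAbsResidual` and the underlying `fit` object.
#' @export
fitOFCurve <- function(sizes, ofValues) {
  if (length(sizes) < 5L)
    stop("at least 5 field sizes are required")
  if (min(ofValues) <= 0 || max(ofValues) > 1.2)
    stop("output factors must lie in (0, 1.2]")
  starts <- list(c(a = 2, n = 1), c(a = 5, n = 2), c(a = 10, n = 3),
                 c(a = 2, n = 3), c(a = 10, n = 1))
  resFun <- function(par)
    ofValues - ofCurve(sizes, stats::setNames(par, c("p", "a", "b", "n")))
  best <- NULL; bestRSS <- Inf
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = c(p = max(ofValues), a = st[["a"]], b = 0.5, n = st[["n"]]),
        fn = resFun,
        lower = c(p = 1e-3, a = 1e-3, b = 1e-4, n = 0.1),
        upper = c(p = 3, a = 50, b = 20, n = 15),
        control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-12,
                                             ptol = 1e-12)),
      error = function(e) NULL)
    if (!is.null(fit) && all(is.finite(fit$par))) {
      rss <- sum(resFun(fit$par)^2)
      if (rss < bestRSS) { bestRSS <- rss; best <- fit }
    }
  }
  if (is.null(best))
    stop("output-factor fit failed to converge from all starting points: ",
         paste(vapply(starts, function(s)
           sprintf("(a=%g, n=%g)", s[["a"]], s[["n"]]), character(1L)),
           collapse = ", "))
  params <- stats::setNames(best$par, c("p", "a", "b", "n"))
  res <- ofValues - ofCurve(sizes, params)
  list(params = params, residuals = res, maxAbsResidual = max(abs(res)),
       fit = best)
}

#' Maximum difference between two fitted output-factor curves
#'
#' Evaluates both parameter sets on a 0.1 mm grid over the given field-size
#' range and returns the maximum absolute difference, the agreement metric
#' used when comparing independently fitted curves.
#'
#' @param paramsA,paramsB parameter sets (named p, a, b, n).
#' @param range field-size range in mm, default 4 to 25 mm.
#' @return maximum absolute OF difference over the range.
#' @export
compareFits <- function(paramsA, paramsB, range = c(4, 25)) {
  s <- seq(range[1L], range[2L], by = 0.1)
  max(abs(ofCurve(s, paramsA) - ofCurve(s, paramsB)))
}
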