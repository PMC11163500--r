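#' Extract the red channel of a film scan
#'
#' Radiochromic film analysis uses the red channel, where the film's
#' darkening response is strongest over the therapeutic dose range.
#'
#' @param scan a [FilmScan-class] (or a height x width x 3 array).
#' @return numeric matrix of red-channel pixel values, unchanged.
#' @export
redChannel <- function(scan) {
  px <- if (is(scan, "FilmScan")) scan@pixels else scan
  d <- dim(px)
  if (length(d) != 3L || d[3L] != 3L)
    stop("expected a 3-channel image")
  px[, , 1L]
}

#' Net optical density of an exposed film
#'
#' Computes the net optical density per pixel,
#' \eqn{netOD = \log_{10}(I_{unexposed} / I_{exposed})}, against an
#' unexposed reference piece of the same film batch. Darkening films give
#' non-negative netOD.
#'
#' @param exposed,unexposed single-channel intensity matrices of identical
#'   shape; the unexposed reference may also be a scalar mean intensity.
#'   All intensities must be positive.
#' @return matrix of netOD values.
#' @export
netResponse <- function(exposed, unexposed) {
  if (length(unexposed) > 1L && !identical(dim(exposed), dim(unexposed)))
    stop("exposed and unexposed images must have the same shape")
  if (min(exposed) <= 0 || min(unexposed) <= 0)
    stop("intensities must be positive")
  log10(unexposed / exposed)
}

#' Fit a third-degree polynomial film calibration
#'
#' Least-squares cubic mapping net optical density to dose in Gy, the
#' standard radiochromic-film calibration form. The fitted curve is
#' verified to be strictly monotone increasing over the calibrated
#' response range; a non-monotone fit is an error (usually a sign that
#' more or better-spread calibration points are needed).
#'
#' @param doses calibration doses in Gy (at least 4 distinct values,
#'   within a 0 to 2 Gy design).
#' @param responses measured netOD per dose (distinct values).
#' @return A [CalibrationCurve-class].
#' @examples
#' truth <- c(0, 0.5, 4, 2.5)
#' x <- seq(0, 0.55, length.out = 10)
#' d <- truth[1] + truth[2] * x + truth[3] * x^2 + truth[4] * x^3
#' fitCalibration(d, x)
#' @export
fitCalibration <- function(doses, responses) {
  if (length(doses) != length(responses))
    stop("'doses' and 'responses' must have the same length")
  if (length(unique(doses)) < 4L)
    stop("at least 4 distinct calibration points are required")
  if (anyDuplicated(responses))
    stop("duplicate response values")
  if (min(doses) < 0 || max(doses) > 2.2)
    stop("calibration doses must lie within the 0-2 Gy design range")
  fit <- stats::lm(doses ~ responses + I(responses^2) + I(responses^3))
  cf <- unname(stats::coef(fit))
  rr <- range(responses)
  x <- seq(rr[1L], rr[2L], length.out = 201L)
  if (any(cf[2L] + 2 * cf[3L] * x + 3 * cf[4L] * x^2 <= 0))
    stop("fitted calibration is not monotone over the response range; ",
         "add calibration points or widen their spread")
  new("CalibrationCurve", coefficients = cf, responseRange = rr,
      doseRange = range(doses))
}

#' 2D median filter with reflected edges
#'
#' Standard two-dimensional median filter over a square window; image
#' borders are handled by reflection. Used to suppress film scan noise.
#' Idempotent on piecewise-constant regions away from edges.
#'
#' @param image numeric matrix.
#' @param window odd window size >= 3.
#' @return filtered matrix of the same shape.
#' @export
medianFilterImage <- function(image, window = 3L) {
  if (window < 3L || window %% 2L == 0L)
    stop("'window' must be an odd integer >= 3")
  h <- (window - 1L) %/% 2L
  nr <- nrow(image); nc <- ncol(image)
  if (nr <= h || nc <= h) stop("image smaller than the filter window")
  ridx <- c((h + 1L):2L, seq_len(nr), (nr - 1L):(nr - h))
  cidx <- c((h + 1L):2L, seq_len(nc), (nc - 1L):(nc - h))
  pad <- image[ridx, cidx]
  k <- window * window
  X <- matrix(0, nr * nc, k)
  m <- 0L
  for (dc in 0:(window - 1L)) for (dr in 0:(window - 1L)) {
    m <- m + 1L
    X[, m] <- as.vector(pad[dr + seq_len(nr), dc + seq_len(nc)])
  }
  matrix(rowOrderStat(X, (k + 1L) %/% 2L), nr, nc)
}

#' Convert a film scan to a dose map
#'
#' Runs the film pipeline on one scan: red-channel extraction, net optical
#' density against the unexposed reference, and calibration to dose in Gy.
#' The grid spacing follows from the scanner resolution
#' (`25.4 / dpi` mm per pixel). Pixels whose response falls outside the
#' calibrated range are flagged; more than `maxOutOfRange` of them is an
#' error.
#'
#' @param scan a [FilmScan-class].
#' @param unexposedRef a [FilmScan-class] of unexposed film (or a scalar
#'   red-channel reference intensity).
#' @param calibration a [CalibrationCurve-class].
#' @param maxOutOfRange maximum tolerated fraction of out-of-range pixels.
#' @param rangeSlack absolute netOD slack permitted beyond the calibrated
#'   response range before a pixel counts as out of range (noise allowance).
#' @return A [RadialDoseMap-class] with dose in Gy, origin at the image
#'   center, and attribute `outOfRangeFraction`.
#' @export
filmDoseMap <- function(scan, unexposedRef, calibration,
                        maxOutOfRange = 0.01, rangeSlack = 0.02) {
  stopifnot(is(scan, "FilmScan"), is(calibration, "CalibrationCurve"))
  red <- redChannel(scan)
  ref <- if (is(unexposedRef, "FilmScan"))
    stats::median(redChannel(unexposedRef)) else unexposedRef
  od <- netResponse(red, ref)
  rr <- calibration@responseRange
  out <- mean(od < rr[1L] - rangeSlack | od > rr[2L] + rangeSlack)
  if (out > maxOutOfRange)
    stop(sprintf("%.1f%% of pixels fall outside the calibrated response range",
                 100 * out))
  # predict inside range +/- slack so noise at the range ends is not
  # half-clipped (which would bias doses near the calibration limits)
  dose <- predictDose(calibration, pmin(pmax(od, rr[1L] - rangeSlack),
                                        rr[2L] + rangeSlack))
  map <- RadialDoseMap(pmax(dose, 0), spacing = 25.4 / scan@dpi)
  attr(map, "outOfRangeFraction") <- out
  map
}

# center of a field in a dose map, via the 50% crossings of the two
# orthogonal profiles through the current maximum region
fieldCenterIndex <- function(map) {
  v <- doseValues(map)
  i <- which(v == max(v), arr.ind = TRUE)[1L, ]
  rowprof <- data.frame(position_mm = seq_len(ncol(v)), value = v[i[1L], ])
  colprof <- data.frame(position_mm = seq_len(nrow(v)), value = v[, i[2L]])
  cx <- profileMetrics(rowprof)$center
  cy <- profileMetrics(colprof)$center
  c(row = cy, col = cx)
}

#' Film output factor from clinical and reference dose maps
#'
#' Ratio of median-filtered central film doses of a clinical field to the
#' machine-specific reference field. Each map is centered via the 50%
#' crossings of its orthogonal profiles; a square region around the center
#' is median filtered and the central `roi` x `roi` pixels are averaged.
#' With repeated films per field, the value is the mean of per-repeat
#' ratios and the uncertainty the standard deviation of that mean. The
#' ratio is invariant under common rescaling of both films' exposure.
#'
#' @param clinMaps,msrMaps a [RadialDoseMap-class] or list of repeats.
#' @param roi central region size in pixels (odd).
#' @param filterWindow median filter window in pixels (odd).
#' @return list with `value`, `uncertainty` (k=1 standard error; `NA` for
#'   single films) and `perRepeat`.
#' @export
filmOutputFactor <- function(clinMaps, msrMaps, roi = 5L,
                             filterWindow = 5L) {
  asList <- function(x) if (is(x, "RadialDoseMap")) list(x) else x
  clinMaps <- asList(clinMaps); msrMaps <- asList(msrMaps)
  central <- function(map) {
    v <- doseValues(map)
    ctr <- fieldCenterIndex(map)
    half <- (roi - 1L) %/% 2L + (filterWindow - 1L) %/% 2L
    r0 <- round(ctr["row"]); c0 <- round(ctr["col"])
    if (r0 - half < 1L || r0 + half > nrow(v) ||
        c0 - half < 1L || c0 + half > ncol(v))
      stop("central region exceeds the film area")
    patch <- v[(r0 - half):(r0 + half), (c0 - half):(c0 + half)]
    f <- medianFilterImage(patch, filterWindow)
    hr <- (roi - 1L) %/% 2L
    cc <- (nrow(f) + 1L) %/% 2L
    mean(f[(cc - hr):(cc + hr), (cc - hr):(cc + hr)])
  }
  cv <- vapply(clinMaps, central, numeric(1L))
  mv <- vapply(msrMaps, central, numeric(1L))
  n <- min(length(cv), length(mv))
  per <- if (length(cv) == length(mv)) cv / mv
         else rep(mean(cv), n) / rep(mean(mv), n)
  val <- mean(per)
  unc <- if (length(per) > 1L) stats::sd(per) / sqrt(length(per))
         else NA_real_
  list(value = val, uncertainty = unc, perRepeat = per)
}
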