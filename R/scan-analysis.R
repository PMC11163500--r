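#' Normalize a beam profile to its maximum
#'
#' Scales a profile so that its (optionally smoothed) maximum equals 100.
#' The scaling factor is recorded in the `"normalizationValue"` attribute.
#' Normalization is idempotent.
#'
#' @param profile data.frame with `position_mm` and `value` columns.
#' @param smoothWindow optional odd moving-average window applied only for
#'   locating the maximum (the returned values are the unsmoothed samples
#'   rescaled); `NULL` by default, to avoid biasing sharp profiles.
#' @return normalized profile data.frame (max = 100), with attribute
#'   `normalizationValue` holding the signal value mapped to 100.
#' @export
normalizeProfile <- function(profile, smoothWindow = NULL) {
  df <- asProfileFrame(profile)
  ref <- if (is.null(smoothWindow)) df$value
         else movingAverage(df$value, smoothWindow)
  top <- max(ref)
  if (top <= 0) stop("profile has no strictly positive values")
  out <- data.frame(position_mm = df$position_mm,
                    value = df$value / top * 100)
  attr(out, "normalizationValue") <- top
  out
}

# All crossings of 'level', located by linear interpolation between
# bracketing samples; returns positions sorted left to right.
levelCrossings <- function(pos, val, level) {
  d <- val - level
  hit <- which(d == 0)
  out <- pos[hit]
  s <- d[-length(d)] * d[-1L]
  idx <- which(s < 0)
  if (length(idx)) {
    x0 <- pos[idx]; x1 <- pos[idx + 1L]
    y0 <- d[idx]; y1 <- d[idx + 1L]
    out <- c(out, x0 - y0 * (x1 - x0) / (y1 - y0))
  }
  sort(unique(out))
}

#' Full width at half maximum of a profile
#'
#' The distance between the two 50% crossings of the normalized profile,
#' each located by linear interpolation between the bracketing samples.
#' With more than one crossing per side, the outermost crossings are used
#' (with a warning), which is robust for noisy shoulders. The result is
#' invariant under positive rescaling of the profile and translation of the
#' position axis.
#'
#' @param profile data.frame with `position_mm` and `value`; normalized
#'   internally.
#' @return FWHM in mm.
#' @examples
#' x <- seq(-5, 5, 0.2)
#' profileFWHM(data.frame(position_mm = x,
#'                        value = exp(-x^2 / (2 * 1.27393^2))))
#' @export
profileFWHM <- function(profile) {
  df <- normalizeProfile(profile)
  cr <- levelCrossings(df$position_mm, df$value, 50)
  peak <- df$position_mm[which.max(df$value)]
  left <- cr[cr < peak]; right <- cr[cr > peak]
  if (!length(left)) stop("no 50% crossing on the left side")
  if (!length(right)) stop("no 50% crossing on the right side")
  if (length(left) > 1L || length(right) > 1L)
    warning("multiple 50% crossings; using the outermost")
  max(right) - min(left)
}

#' 20%-80% penumbra width of a profile edge
#'
#' The absolute distance between the linearly interpolated 20% and 80%
#' crossings on one side of the normalized profile. The profile is
#' re-centered at the midpoint of its outermost 50% crossings before the
#' side is selected. Outermost crossings are used on each level.
#'
#' @param profile data.frame with `position_mm` and `value`.
#' @param side `"left"` or `"right"` field edge.
#' @return penumbra width in mm.
#' @export
profilePenumbra <- function(profile, side = c("left", "right")) {
  side <- match.arg(side)
  df <- normalizeProfile(profile)
  c50 <- levelCrossings(df$position_mm, df$value, 50)
  if (length(c50) < 2L) stop("profile does not cross 50% on both sides")
  center <- (min(c50) + max(c50)) / 2
  pick <- function(level) {
    cr <- levelCrossings(df$position_mm, df$value, level)
    cr <- if (side == "left") cr[cr <= center] else cr[cr >= center]
    if (!length(cr))
      stop(sprintf("no %g%% crossing on the %s side", level, side))
    if (side == "left") min(cr) else max(cr)
  }
  abs(pick(20) - pick(80))
}

#' Profile metrics: FWHM, penumbrae, center
#'
#' @param profile data.frame with `position_mm` and `value`.
#' @return list with `fwhm`, `penumbraLeft`, `penumbraRight`, `center` (mm,
#'   midpoint of the 50% crossings) and `normalizationValue`.
#' @export
profileMetrics <- function(profile) {
  df <- normalizeProfile(profile)
  c50 <- levelCrossings(df$position_mm, df$value, 50)
  list(fwhm = profileFWHM(df),
       penumbraLeft = profilePenumbra(df, "left"),
       penumbraRight = profilePenumbra(df, "right"),
       center = (min(c50) + max(c50)) / 2,
       normalizationValue = attr(normalizeProfile(profile),
                                 "normalizationValue"))
}

#' Percentage-depth-dose metrics
#'
#' Locates the depth of dose maximum on a locally smoothed depth curve
#' (moving average, default window 5 samples, with parabolic sub-sample
#' refinement around the smoothed maximum) and evaluates the percentage
#' dose at requested depths by linear interpolation, relative to the
#' smoothed maximum.
#'
#' @param pdd data.frame with columns `depth_mm` (ordered) and `value`
#'   (positive).
#' @param depths depths of interest in mm (must lie within the scanned
#'   range).
#' @param smoothWindow odd moving-average window for locating the maximum.
#' @return list with `dMax` (mm) and `percentDoseAt` (named numeric,
#'   percent of maximum at each requested depth).
#' @export
pddMetrics <- function(pdd, depths = numeric(0), smoothWindow = 5L) {
  df <- asProfileFrame(pdd, cols = c("depth_mm", "value"))
  z <- df$position_mm; v <- df$value
  if (any(v <= 0)) stop("PDD values must be positive")
  sm <- movingAverage(v, smoothWindow)
  i <- which.max(sm)
  dMax <- z[i]
  if (i > 1L && i < length(z)) {
    # parabolic refinement through the three samples around the maximum
    den <- sm[i - 1L] - 2 * sm[i] + sm[i + 1L]
    if (den < 0)
      dMax <- z[i] + 0.5 * (sm[i - 1L] - sm[i + 1L]) / den * (z[i + 1L] - z[i])
  }
  top <- max(sm)
  pct <- NULL
  if (length(depths)) {
    if (min(depths) < min(z) || max(depths) > max(z))
      stop("requested depth outside the scanned range")
    pct <- stats::approx(z, v, xout = depths)$y / top * 100
    names(pct) <- format(depths, trim = TRUE)
  }
  list(dMax = dMax, percentDoseAt = pct)
}
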