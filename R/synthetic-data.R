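# Default kernel-width multiplier vs water depth. The multipliers scale
# both Gaussian components of the kernel and are calibrated once so the
# generated 3 mm cone reproduces the measured dosimetric field sizes
# (FWHM 3.0 / 3.3 / 3.6 / 4.4 / 4.8 mm at depths 7-250 mm).
defaultDepthTable <- function() {
  data.frame(depth_mm = c(7, 50, 100, 200, 250),
             mult = c(0.9871, 1.2258, 1.4185, 1.8685, 2.0788))
}

#' Construct a synthetic beam description
#'
#' Defaults describe the modelled radiosurgery cone beams: a two-Gaussian
#' dose-deposition kernel (narrow core plus 8% broad scatter tail) whose
#' core width is calibrated so the 3 mm cone at 7 mm depth has FWHM
#' 3.0 mm and 20-80% penumbra about 1.35 mm, a depth table reproducing the
#' measured field-size growth to 250 mm depth, and 0.5% relative scan
#' noise.
#'
#' @param nominalDiameter cone diameter in mm (3 to 25).
#' @param coreSigma,tailSigma,tailWeight kernel mixture parameters
#'   (mm, mm, weight).
#' @param depthTable data.frame `depth_mm`, `mult` of kernel width
#'   multipliers.
#' @param noiseLevel relative additive Gaussian noise on generated scans.
#' @return A [BeamSpec-class].
#' @export
beamSpec <- function(nominalDiameter = 3, coreSigma = 0.8946,
                     tailSigma = 2.0, tailWeight = 0.08,
                     depthTable = defaultDepthTable(),
                     noiseLevel = 0.005) {
  new("BeamSpec", nominalDiameter = nominalDiameter,
      coreSigma = coreSigma, tailSigma = tailSigma,
      tailWeight = tailWeight, depthTable = depthTable,
      noiseLevel = noiseLevel)
}

# kernel width multiplier at a depth (linear between table rows, clamped)
depthMultiplier <- function(spec, depth) {
  tab <- spec@depthTable
  if (depth < min(tab$depth_mm) || depth > max(tab$depth_mm))
    stop("depth outside the anchored range (",
         min(tab$depth_mm), "-", max(tab$depth_mm), " mm)")
  stats::approx(tab$depth_mm, tab$mult, xout = depth)$y
}

# Analytic radial dose of a uniform top-hat fluence (radius R) convolved
# with the two-Gaussian kernel: for each component, the convolution of a
# unit disk with a normalized 2D Gaussian equals the probability that an
# offset 2D Gaussian lands inside the disk, a noncentral chi-square tail.
coneDoseFunction <- function(spec, depth = 7) {
  m <- depthMultiplier(spec, depth)
  R <- spec@nominalDiameter / 2
  sig <- c(spec@coreSigma, spec@tailSigma) * m
  w <- c(1 - spec@tailWeight, spec@tailWeight)
  function(r) {
    out <- 0
    for (i in seq_along(sig))
      out <- out + w[i] * stats::pchisq((R / sig[i])^2, df = 2,
                                        ncp = (r / sig[i])^2)
    out
  }
}

#' Dose-deposition kernel of a beam specification
#'
#' The two-Gaussian kernel of a [BeamSpec-class] at a given depth, sampled
#' for use with [convolveRadial()] or [vanCittert()].
#'
#' @param spec a [BeamSpec-class].
#' @param depth water depth in mm (within the depth table range).
#' @param spacing radial sample spacing in mm.
#' @return A [DoseKernel-class].
#' @export
specKernel <- function(spec, depth = 7, spacing = 0.1) {
  m <- depthMultiplier(spec, depth)
  mixtureKernel(spec@coreSigma * m, spec@tailSigma * m,
                spec@tailWeight, spacing = spacing)
}

#' Generate a synthetic lateral dose profile with ground truth
#'
#' Produces the lateral scan of a cone beam at a given depth: the analytic
#' convolution of the nominal-diameter top-hat fluence with the beam's
#' two-Gaussian kernel, sampled on a signed position axis, with optional
#' seeded additive Gaussian noise. The analytic (noiseless) FWHM and
#' 20-80% penumbra are returned alongside, computed by root finding on the
#' closed-form curve; no pipeline stage reads the ground truth.
#'
#' @param spec a [BeamSpec-class].
#' @param depth water depth in mm.
#' @param seed integer seed for the noise (`NULL` for noiseless).
#' @param spacing sample spacing in mm.
#' @param halfWidth profile half-extent in mm; defaults to the cone radius
#'   plus 3.5 mm of margin, scaled with depth.
#' @param noiseLevel relative additive noise; defaults to the spec's.
#' @return list with `profile` (data.frame `position_mm`, `value`) and
#'   `truth` (list `fwhm`, `penumbra`, `centralDose`, `fun`).
#' @examples
#' p <- makeDoseProfile(beamSpec(3), depth = 7, seed = 1)
#' p$truth$fwhm
#' @export
makeDoseProfile <- function(spec, depth = 7, seed = NULL, spacing = 0.1,
                            halfWidth = NULL, noiseLevel = NULL) {
  stopifnot(is(spec, "BeamSpec"))
  if (is.null(noiseLevel)) noiseLevel <- spec@noiseLevel
  f <- coneDoseFunction(spec, depth)
  if (is.null(halfWidth))
    halfWidth <- spec@nominalDiameter / 2 +
      3.5 * depthMultiplier(spec, depth)
  pos <- seq(-halfWidth, halfWidth, by = spacing)
  clean <- f(abs(pos))
  d0 <- f(0)
  lev <- function(p) stats::uniroot(function(r) f(r) - p * d0,
                                    c(0, halfWidth + 10))$root
  truth <- list(fwhm = 2 * lev(0.5), penumbra = lev(0.2) - lev(0.8),
                centralDose = d0, fun = f)
  vals <- if (noiseLevel > 0)
    withSeed(seed, clean + stats::rnorm(length(clean),
                                        sd = noiseLevel * max(clean)))
  else clean
  list(profile = data.frame(position_mm = pos, value = pmax(vals, 0)),
       truth = truth)
}

#' Generate a noiseless 2D synthetic dose map
#'
#' The analytic cone dose distribution rasterized on a uniform grid, for
#' volume-averaging and film studies. Evaluated via a fine radial lookup
#' table (0.01 mm) to keep large film-resolution grids cheap.
#'
#' @param spec a [BeamSpec-class].
#' @param depth water depth in mm.
#' @param spacing grid spacing in mm.
#' @param halfWidth grid half-extent in mm (default as in
#'   [makeDoseProfile()]).
#' @param centralDose if given, the map is rescaled so the central-axis
#'   dose equals this value (e.g. in Gy for film generation).
#' @return A [RadialDoseMap-class].
#' @export
makeDoseMap <- function(spec, depth = 7, spacing = 0.1, halfWidth = NULL,
                        centralDose = NULL) {
  stopifnot(is(spec, "BeamSpec"))
  f <- coneDoseFunction(spec, depth)
  if (is.null(halfWidth))
    halfWidth <- spec@nominalDiameter / 2 +
      3.5 * depthMultiplier(spec, depth)
  rfine <- seq(0, halfWidth * sqrt(2) + spacing, by = 0.01)
  vfine <- f(rfine)
  if (!is.null(centralDose)) vfine <- vfine / f(0) * centralDose
  hw <- as.integer(ceiling(halfWidth / spacing - 1e-9))
  vals <- radialToGrid(rfine, vfine, spacing, hw)
  RadialDoseMap(vals, spacing)
}

# anchors for the synthetic PDD family: depth of maximum and percentage
# dose at 100 mm vs cone diameter, interpolated linearly between the
# characterized sizes
pddAnchors <- function(fieldDiameter) {
  s <- c(3, 4, 25)
  list(dMax = stats::approx(s, c(4.8, 5.0, 7.8), xout = fieldDiameter)$y,
       p100 = stats::approx(s, c(35.6, 36.7, 41.2), xout = fieldDiameter)$y)
}

#' Generate a synthetic percentage-depth-dose curve
#'
#' Build-up/fall-off model \eqn{A (1 - e^{-\mu_1 z}) e^{-\mu_2 z}} with
#' \eqn{(\mu_1, \mu_2)} solved so the analytic depth of maximum and the
#' percentage dose at 100 mm depth match the characterized anchors for the
#' requested cone diameter (4.8 mm / 35.6% at 3 mm diameter up to
#' 7.8 mm / 41.2% at 25 mm; linear interpolation in between). The analytic
#' \eqn{d_{max} = \ln(1 + \mu_1/\mu_2)/\mu_1} is returned as ground truth.
#'
#' @param fieldDiameter cone diameter in mm (3 to 25).
#' @param seed integer seed for noise (`NULL` for noiseless).
#' @param depths sampled depths in mm.
#' @param noiseLevel relative additive Gaussian noise.
#' @return list with `pdd` (data.frame `depth_mm`, `value`, maximum 100)
#'   and `truth` (list `dMax`, `mu1`, `mu2`, `p100`).
#' @export
makePDD <- function(fieldDiameter, seed = NULL,
                    depths = seq(0.2, 250, by = 0.2),
                    noiseLevel = 0.002) {
  if (fieldDiameter < 3 || fieldDiameter > 25)
    stop("'fieldDiameter' must lie in [3, 25] mm")
  anch <- pddAnchors(fieldDiameter)
  obj <- function(par) {
    mu1 <- exp(par[1L]); mu2 <- exp(par[2L])
    dm <- log1p(mu1 / mu2) / mu1
    pk <- (1 - exp(-mu1 * dm)) * exp(-mu2 * dm)
    p1 <- (1 - exp(-mu1 * 100)) * exp(-mu2 * 100) / pk * 100
    (dm - anch$dMax)^2 + (p1 - anch$p100)^2
  }
  o <- stats::optim(log(c(0.5, 0.008)), obj, method = "Nelder-Mead",
                    control = list(reltol = 1e-14, maxit = 5000))
  mu1 <- exp(o$par[1L]); mu2 <- exp(o$par[2L])
  dm <- log1p(mu1 / mu2) / mu1
  pk <- (1 - exp(-mu1 * dm)) * exp(-mu2 * dm)
  clean <- (1 - exp(-mu1 * depths)) * exp(-mu2 * depths) / pk * 100
  vals <- if (noiseLevel > 0)
    withSeed(seed, clean + stats::rnorm(length(clean),
                                        sd = noiseLevel * max(clean)))
  else clean
  list(pdd = data.frame(depth_mm = depths, value = pmax(vals, 1e-6)),
       truth = list(dMax = dm, mu1 = mu1, mu2 = mu2,
                    p100 = (1 - exp(-mu1 * 100)) * exp(-mu2 * 100) / pk * 100))
}

#' Construct a synthetic film response model
#'
#' Defaults emulate the red-channel response of a radiochromic film over
#' 0-2 Gy: a monotone ground-truth cubic netOD-to-dose map reaching about
#' 2 Gy at netOD 0.56, unexposed intensity 40000 of the 16-bit range, 1%
#' multiplicative pixel noise, and a 600 dpi scan.
#'
#' @param calibration ground-truth cubic (constant first), netOD to Gy.
#' @param unexposedIntensity mean unexposed red-channel intensity.
#' @param pixelNoise relative multiplicative Gaussian pixel noise.
#' @param dpi scanner resolution.
#' @return A [FilmModel-class].
#' @export
filmModel <- function(calibration = c(0, 0.5, 4.0, 2.5),
                      unexposedIntensity = 40000, pixelNoise = 0.01,
                      dpi = 600) {
  new("FilmModel", calibration = calibration,
      unexposedIntensity = unexposedIntensity, pixelNoise = pixelNoise,
      dpi = dpi)
}

# invert the model's monotone cubic (dose -> netOD) via a fine lookup
inverseCalibration <- function(model, maxOD = 1.0) {
  x <- seq(0, maxOD, by = 1e-4)
  cf <- model@calibration
  d <- cf[1L] + cf[2L] * x + cf[3L] * x^2 + cf[4L] * x^3
  stats::approxfun(d, x, rule = 2)
}

# forward film model: per-pixel dose matrix -> 3-channel 16-bit pixels.
# Green and blue channels respond weaker (0.45x / 0.20x netOD), matching
# the red channel being the analysis channel.
doseToFilmPixels <- function(doseMatrix, model, noise = TRUE) {
  inv <- inverseCalibration(model)
  od <- inv(pmax(doseMatrix, 0))
  px <- array(0, dim = c(nrow(doseMatrix), ncol(doseMatrix), 3L))
  scale <- c(1, 0.45, 0.20)
  for (ch in 1:3) {
    I <- model@unexposedIntensity * 10^(-od * scale[ch])
    if (noise && model@pixelNoise > 0)
      I <- I * (1 + stats::rnorm(length(I), sd = model@pixelNoise))
    px[, , ch] <- matrix(pmin(pmax(round(I), 1), 65535), nrow(doseMatrix))
  }
  px
}

#' Generate a synthetic film measurement set
#'
#' Produces repeated film scans of a known dose distribution plus an
#' unexposed reference piece, through the inverse of the ground-truth
#' calibration with seeded multiplicative pixel noise and 16-bit
#' quantization. The ground truth travels alongside the films; the
#' analysis pipeline never reads it.
#'
#' @param doseTruth either a single dose in Gy (a homogeneously irradiated
#'   film patch) or a [RadialDoseMap-class] whose spacing matches the film
#'   pixel pitch `25.4 / dpi`.
#' @param model a [FilmModel-class].
#' @param nRepeats number of repeated films.
#' @param seed integer seed.
#' @param patchPx edge length in pixels for homogeneous patches.
#' @return list with `films` (list of [FilmScan-class]), `unexposed`
#'   (a [FilmScan-class]) and `truth` (list `dose`, `model`).
#' @export
makeFilmSet <- function(doseTruth, model = filmModel(), nRepeats = 5L,
                        seed = NULL, patchPx = 64L) {
  stopifnot(is(model, "FilmModel"))
  doseMatrix <- if (is(doseTruth, "RadialDoseMap")) {
    if (abs(gridSpacing(doseTruth) - 25.4 / model@dpi) >
        1e-6 * gridSpacing(doseTruth))
      stop("dose map spacing must equal the film pixel pitch 25.4/dpi")
    doseValues(doseTruth)
  } else matrix(doseTruth, patchPx, patchPx)
  withSeed(seed, {
    films <- lapply(seq_len(nRepeats), function(i)
      FilmScan(doseToFilmPixels(doseMatrix, model), dpi = model@dpi,
               metadata = list(repeat_index = i)))
    unexposed <- FilmScan(
      doseToFilmPixels(matrix(0, nrow(doseMatrix), ncol(doseMatrix)),
                       model),
      dpi = model@dpi, metadata = list(unexposed = TRUE))
    list(films = films, unexposed = unexposed,
         truth = list(dose = doseTruth, model = model))
  })
}

#' Default ground-truth output-factor curve parameters
#'
#' Parameters of [ofCurve()] fitted once to the published output factors
#' of the characterized cones (0.447, 0.724, 0.811 and 1 at 3, 4, 5 and
#' 25 mm) and frozen as the generator's truth.
#'
#' @return named numeric vector `p`, `a`, `b`, `n`.
#' @export
defaultOFParams <- function() {
  c(p = 0.9958, a = 3.102, b = 1.209, n = 3.458)
}

#' Generate synthetic detector output-ratio readings
#'
#' Detector readings per field size constructed so the perturbation
#' correction round-trips: the reading is the true output factor divided
#' by the interpolated total correction factor for that field size, times
#' seeded multiplicative noise. Applying [correctedOutputFactor()] with
#' the same k-table therefore recovers the true output factor up to noise.
#'
#' @param sizes nominal field sizes in mm (within 3 to 25 mm).
#' @param trueParams ground-truth [ofCurve()] parameters.
#' @param nRepeats repeated readings per field size.
#' @param noiseLevel relative multiplicative reading noise.
#' @param seed integer seed.
#' @return data.frame with one row per repeat: `field_mm`, `reading`;
#'   attribute `truth` carries `trueOF`, `kTotal` and the parameters.
#' @export
makeORSeries <- function(sizes = c(3, 4, 5, 7.5, 10, 12.5, 15, 20, 25),
                         trueParams = defaultOFParams(), nRepeats = 5L,
                         noiseLevel = 0.005, seed = NULL) {
  trueOF <- ofCurve(sizes, trueParams)
  k <- interpKTotal(sizes)
  readings <- withSeed(seed, {
    lapply(seq_along(sizes), function(i)
      trueOF[i] / k[i] *
        (1 + stats::rnorm(nRepeats, sd = noiseLevel)))
  })
  out <- data.frame(field_mm = rep(sizes, each = nRepeats),
                    reading = unlist(readings))
  attr(out, "truth") <- list(trueOF = stats::setNames(trueOF, sizes),
                             kTotal = stats::setNames(k, sizes),
                             params = trueParams)
  out
}
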