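#' @import methods
NULL

#' Radially symmetric 2D dose distribution on a uniform Cartesian grid
#'
#' Container for a two-dimensional dose distribution \eqn{D(x, y)} sampled on
#' a uniform grid, with the beam axis located at a stored grid index. Dose
#' values are in arbitrary (normalizable) units; all downstream profile
#' metrics are invariant under positive rescaling.
#'
#' @slot spacing numeric(1), grid spacing in mm per cell.
#' @slot values numeric matrix of dose values (finite, non-negative).
#' @slot origin integer(2), 1-based (row, col) index of the beam axis.
#'
#' @seealso [RadialDoseMap()], [convolveRadial()], [extractProfile()]
#' @export
setClass("RadialDoseMap",
  representation(spacing = "numeric", values = "matrix", origin = "integer"))

setValidity("RadialDoseMap", function(object) {
  msg <- character()
  if (length(object@spacing) != 1L || !is.finite(object@spacing) ||
      object@spacing <= 0)
    msg <- c(msg, "'spacing' must be a single positive number")
  if (!all(is.finite(object@values)))
    msg <- c(msg, "'values' must be finite")
  else if (min(object@values) < 0)
    msg <- c(msg, "'values' must be non-negative")
  if (length(object@origin) != 2L ||
      any(object@origin < 1L) ||
      object@origin[1L] > nrow(object@values) ||
      object@origin[2L] > ncol(object@values))
    msg <- c(msg, "'origin' must index a cell inside 'values'")
  if (length(msg)) msg else TRUE
})

#' Construct a RadialDoseMap
#'
#' @param values numeric matrix of dose values. Values negative by less than
#'   `clampTolerance` times the maximum (e.g. FFT round-off) are clamped to
#'   zero; more negative values are an error.
#' @param spacing grid spacing in mm.
#' @param origin 1-based (row, col) index of the beam axis; defaults to the
#'   central cell of an odd-sized grid.
#' @param clampTolerance relative tolerance for clamping small negative
#'   round-off values.
#' @return A [RadialDoseMap-class] object.
#' @export
RadialDoseMap <- function(values, spacing, origin = NULL,
                          clampTolerance = 1e-8) {
  values <- as.matrix(values)
  mx <- max(values, 0)
  neg <- values < 0
  if (any(neg)) {
    if (min(values) < -clampTolerance * max(mx, 1))
      stop("dose values must be non-negative")
    values[neg] <- 0
  }
  if (is.null(origin))
    origin <- as.integer((dim(values) + 1L) %/% 2L)
  new("RadialDoseMap", spacing = as.numeric(spacing), values = values,
      origin = as.integer(origin))
}

#' Radial dose-deposition kernel
#'
#' Pencil-beam dose-deposition kernel \eqn{K_D(r)} sampled on a uniform
#' radial axis starting at \eqn{r = 0}. The kernel is treated as an
#' area-integrated radial function; its 2D integral
#' \eqn{2\pi\int K_D(r)\,r\,dr} is stored explicitly and is not forced to
#' one, so the forward model reports dose in kernel-integral units.
#'
#' @slot spacing numeric(1), radial sample spacing in mm.
#' @slot values numeric vector of kernel values from r = 0 outward.
#' @slot normalization numeric(1), the 2D integral of the kernel.
#'
#' @seealso [DoseKernel()], [gaussianKernel()], [convolveRadial()]
#' @export
setClass("DoseKernel",
  representation(spacing = "numeric", values = "numeric",
                 normalization = "numeric"))

setValidity("DoseKernel", function(object) {
  msg <- character()
  if (length(object@spacing) != 1L || object@spacing <= 0)
    msg <- c(msg, "'spacing' must be a single positive number")
  if (!all(is.finite(object@values)) || any(object@values < 0))
    msg <- c(msg, "kernel values must be finite and non-negative")
  if (object@normalization <= 0)
    msg <- c(msg, "kernel integral must be positive")
  if (length(msg)) msg else TRUE
})

#' Construct a DoseKernel from radial samples
#'
#' @param values kernel values sampled at radii `0, spacing, 2*spacing, ...`.
#' @param spacing radial sample spacing in mm.
#' @param normalization the kernel's 2D integral; when omitted it is
#'   computed from the same 2D rasterization the convolution engine uses,
#'   so flat-field dose equals fluence times this integral exactly.
#' @return A [DoseKernel-class] object.
#' @export
DoseKernel <- function(values, spacing, normalization = NULL) {
  values <- as.numeric(values)
  if (is.null(normalization)) {
    r <- (seq_along(values) - 1) * spacing
    normalization <- sum(radialToGrid(r, values, spacing,
                                      length(values) - 1L,
                                      method = "monoH.FC")) * spacing^2
  }
  new("DoseKernel", spacing = as.numeric(spacing), values = values,
      normalization = as.numeric(normalization))
}

#' Virtual fluence source as a superposition of radial step functions
#'
#' Represents a radially symmetric photon fluence
#' \eqn{\psi(r) = \sum_i w_i \, 1[r \le R_i]} as weighted step functions,
#' the form in which derived sources are fed to a dose engine. Individual
#' weights may be negative, but the evaluated fluence must be non-negative
#' everywhere and is zero beyond the largest step radius.
#'
#' @slot stepRadii strictly increasing step radii in mm.
#' @slot stepWeights fluence weight per step.
#'
#' @seealso [StepFluenceSource()], [decomposeSteps()], [evaluateFluence()]
#' @export
setClass("StepFluenceSource",
  representation(stepRadii = "numeric", stepWeights = "numeric"))

setValidity("StepFluenceSource", function(object) {
  msg <- character()
  r <- object@stepRadii
  if (length(r) < 1L || any(diff(r) <= 0) || any(r <= 0))
    msg <- c(msg, "'stepRadii' must be positive and strictly increasing")
  if (length(object@stepWeights) != length(r))
    msg <- c(msg, "'stepWeights' must match 'stepRadii' in length")
  else {
    # fluence inside step i (and inside all larger steps) is the tail sum
    psi <- rev(cumsum(rev(object@stepWeights)))
    if (any(psi < -1e-12 * max(abs(psi), 1)))
      msg <- c(msg, "evaluated fluence must be non-negative everywhere")
  }
  if (length(msg)) msg else TRUE
})

#' @rdname StepFluenceSource-class
#' @param stepRadii strictly increasing step radii (mm).
#' @param stepWeights weight of each step.
#' @export
StepFluenceSource <- function(stepRadii, stepWeights) {
  new("StepFluenceSource", stepRadii = as.numeric(stepRadii),
      stepWeights = as.numeric(stepWeights))
}

#' Result of a van-Cittert deconvolution
#'
#' @slot fluence data.frame with columns `r` (mm) and `value`, the recovered
#'   radial fluence.
#' @slot iterationsUsed integer(1), iterations actually performed.
#' @slot residualHistory numeric, relative L2 residual after each iteration.
#' @slot forwardDose [RadialDoseMap-class], the re-convolved forward dose
#'   used for validation.
#' @slot converged logical(1), whether the residual tolerance was reached.
#' @slot settings list of the settings used.
#'
#' @seealso [vanCittert()], [validateForward()]
#' @export
setClass("DeconvolutionResult",
  representation(fluence = "data.frame", iterationsUsed = "integer",
                 residualHistory = "numeric", forwardDose = "RadialDoseMap",
                 converged = "logical", settings = "list"))

setValidity("DeconvolutionResult", function(object) {
  if (length(object@residualHistory) != object@iterationsUsed)
    return("'residualHistory' length must equal 'iterationsUsed'")
  TRUE
})

#' Detector perturbation factors for one or more field sizes
#'
#' Holds the perturbation decomposition of a detector's small-field response:
#' the housing density factor, the sensitive-volume material factor, the
#' volume-averaging factor, and the total output correction
#' \eqn{k = P_{housing} \cdot P_{sens} \cdot P_{vol}}. Each factor is a
#' ratio-of-ratios normalized to the machine-specific reference (msr) field,
#' so all factors are exactly one at the msr field. Missing (unreported)
#' components are NA; the stored total is then not derivable from the
#' components.
#'
#' @slot fieldSize numeric, nominal field size(s) in mm.
#' @slot pHousing,pSens,pVol numeric, component factors (NA when absent).
#' @slot kTotal numeric, total output correction factor.
#' @slot signals list, optionally the underlying simulated signals
#'   (M_diode, M_si_vol, D_w_vol, D_w_point per field).
#'
#' @seealso [perturbationFromSignals()], [packagedFactorTable()]
#' @export
setClass("PerturbationSet",
  representation(fieldSize = "numeric", pHousing = "numeric",
                 pSens = "numeric", pVol = "numeric", kTotal = "numeric",
                 signals = "list"))

setValidity("PerturbationSet", function(object) {
  n <- length(object@fieldSize)
  if (any(lengths(list(object@pHousing, object@pSens, object@pVol,
                       object@kTotal)) != n))
    return("all factor slots must have one value per field size")
  if (any(c(object@pHousing, object@pSens, object@pVol, object@kTotal) <= 0,
          na.rm = TRUE))
    return("perturbation factors must be positive")
  full <- !is.na(object@pHousing) & !is.na(object@pSens) & !is.na(object@pVol)
  prod3 <- object@pHousing * object@pSens * object@pVol
  rel <- abs(object@kTotal[full] - prod3[full]) / object@kTotal[full]
  # printed literature totals are rounded; computed sets must telescope
  if (any(rel > 1e-3))
    return("kTotal inconsistent with the product of its components")
  TRUE
})

#' Film calibration curve (third-degree polynomial)
#'
#' Maps net optical density (netOD) to dose in Gy through a cubic
#' polynomial, the standard radiochromic-film calibration form. The curve
#' must be strictly monotone increasing over the calibrated response range
#' and pass within 0.02 Gy of zero dose at zero response (when zero response
#' is inside the range).
#'
#' @slot coefficients numeric(4), polynomial coefficients (constant first):
#'   dose = c0 + c1 x + c2 x^2 + c3 x^3 with x = netOD.
#' @slot responseRange numeric(2), netOD range over which the fit is valid.
#' @slot doseRange numeric(2), dose range (Gy) of the calibration design.
#'
#' @seealso [fitCalibration()], [predictDose()]
#' @export
setClass("CalibrationCurve",
  representation(coefficients = "numeric", responseRange = "numeric",
                 doseRange = "numeric"))

setValidity("CalibrationCurve", function(object) {
  msg <- character()
  if (length(object@coefficients) != 4L)
    msg <- c(msg, "'coefficients' must have length 4 (cubic, constant first)")
  else {
    rr <- object@responseRange
    x <- seq(rr[1L], rr[2L], length.out = 201L)
    cf <- object@coefficients
    deriv <- cf[2L] + 2 * cf[3L] * x + 3 * cf[4L] * x^2
    if (any(deriv <= 0))
      msg <- c(msg, "curve must be strictly monotone increasing over 'responseRange'")
    if (rr[1L] <= 0 && rr[2L] >= 0 && abs(cf[1L]) > 0.02)
      msg <- c(msg, "dose at zero response must lie within 0.02 Gy of zero")
  }
  if (length(msg)) msg else TRUE
})

#' Scanned radiochromic film
#'
#' A 3-channel (RGB) film scan with 16-bit pixel values plus the scanner
#' resolution and exposure metadata.
#'
#' @slot pixels numeric array `height x width x 3`, values in 0..65535.
#' @slot dpi numeric(1), scanner resolution in dots per inch.
#' @slot metadata list, free-form exposure metadata (e.g. MU, field label).
#'
#' @seealso [redChannel()], [filmDoseMap()], [makeFilmSet()]
#' @export
setClass("FilmScan",
  representation(pixels = "array", dpi = "numeric", metadata = "list"))

setValidity("FilmScan", function(object) {
  msg <- character()
  d <- dim(object@pixels)
  if (length(d) != 3L || d[3L] != 3L)
    msg <- c(msg, "'pixels' must be a height x width x 3 array")
  if (min(object@pixels) < 0 || max(object@pixels) > 65535)
    msg <- c(msg, "pixel values must lie within 16-bit range (0..65535)")
  if (length(object@dpi) != 1L || object@dpi <= 0)
    msg <- c(msg, "'dpi' must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' @rdname FilmScan-class
#' @param pixels height x width x 3 numeric array, 16-bit range.
#' @param dpi scanner resolution in dots per inch.
#' @param metadata optional list of exposure metadata.
#' @export
FilmScan <- function(pixels, dpi, metadata = list()) {
  new("FilmScan", pixels = pixels, dpi = as.numeric(dpi),
      metadata = metadata)
}

#' Synthetic beam description for the data generator
#'
#' Describes a circular cone beam for the synthetic generator: the nominal
#' diameter, a two-Gaussian dose-deposition kernel (narrow core plus broad
#' scatter tail), a depth table of kernel-width multipliers emulating
#' profile broadening with depth, and the measurement noise level. The
#' defaults are calibrated so that the generated 3 mm beam at 7 mm depth has
#' FWHM 3.0 mm and 20-80% penumbra about 1.35 mm, and its depth broadening
#' follows the measured field sizes at 7-250 mm depth.
#'
#' @slot nominalDiameter numeric(1), cone diameter in mm (3 to 25).
#' @slot coreSigma,tailSigma numeric(1), Gaussian widths (mm) of the kernel
#'   core and tail at the reference depth.
#' @slot tailWeight numeric(1), weight of the tail component in `[0, 1)`.
#' @slot depthTable data.frame with columns `depth_mm` and `mult`: kernel
#'   width multiplier vs depth (linearly interpolated between rows).
#' @slot noiseLevel numeric(1), relative (to maximum) additive Gaussian
#'   noise applied to generated scan samples.
#'
#' @seealso [beamSpec()], [makeDoseProfile()], [makeDoseMap()]
#' @export
setClass("BeamSpec",
  representation(nominalDiameter = "numeric", coreSigma = "numeric",
                 tailSigma = "numeric", tailWeight = "numeric",
                 depthTable = "data.frame", noiseLevel = "numeric"))

setValidity("BeamSpec", function(object) {
  msg <- character()
  if (object@nominalDiameter < 3 || object@nominalDiameter > 25)
    msg <- c(msg, "'nominalDiameter' must lie in [3, 25] mm")
  if (object@coreSigma <= 0 || object@tailSigma <= 0)
    msg <- c(msg, "kernel widths must be positive")
  if (object@tailWeight < 0 || object@tailWeight >= 1)
    msg <- c(msg, "'tailWeight' must lie in [0, 1)")
  if (object@noiseLevel < 0)
    msg <- c(msg, "'noiseLevel' must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Synthetic film response model
#'
#' Ground-truth model for generated film scans: a monotone cubic mapping
#' netOD to dose (the same form the calibration pipeline fits), the
#' intensity of unexposed film, the multiplicative pixel noise, and the
#' scanner resolution.
#'
#' @slot calibration numeric(4), ground-truth cubic (constant first) mapping
#'   netOD to dose in Gy; monotone over the working range.
#' @slot unexposedIntensity numeric(1), mean 16-bit intensity of unexposed
#'   film in the red channel.
#' @slot pixelNoise numeric(1), relative multiplicative Gaussian pixel noise.
#' @slot dpi numeric(1), scanner resolution.
#'
#' @seealso [filmModel()], [makeFilmSet()]
#' @export
setClass("FilmModel",
  representation(calibration = "numeric", unexposedIntensity = "numeric",
                 pixelNoise = "numeric", dpi = "numeric"))

setValidity("FilmModel", function(object) {
  msg <- character()
  if (length(object@calibration) != 4L)
    msg <- c(msg, "'calibration' must be a cubic (4 coefficients)")
  if (object@unexposedIntensity <= 0 || object@unexposedIntensity > 65535)
    msg <- c(msg, "'unexposedIntensity' must lie in (0, 65535]")
  if (object@pixelNoise < 0)
    msg <- c(msg, "'pixelNoise' must be non-negative")
  if (object@dpi <= 0)
    msg <- c(msg, "'dpi' must be positive")
  if (length(msg)) msg else TRUE
})
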