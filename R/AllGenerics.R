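#' Accessors for dosimetry containers
#'
#' `gridSpacing` returns the grid (or radial) spacing in mm; `doseValues`
#' the dose matrix of a [RadialDoseMap-class]; `originIndex` the 1-based
#' beam-axis index; `kernelValues` and `kernelIntegral` the radial samples
#' and stored 2D integral of a [DoseKernel-class]; `stepRadii` and
#' `stepWeights` the step representation of a [StepFluenceSource-class].
#'
#' @param object a package container object.
#' @return The corresponding slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("gridSpacing", function(object) standardGeneric("gridSpacing"))
#' @rdname accessors
#' @export
setGeneric("doseValues", function(object) standardGeneric("doseValues"))
#' @rdname accessors
#' @export
setGeneric("originIndex", function(object) standardGeneric("originIndex"))
#' @rdname accessors
#' @export
setGeneric("kernelValues", function(object) standardGeneric("kernelValues"))
#' @rdname accessors
#' @export
setGeneric("kernelIntegral", function(object)
  standardGeneric("kernelIntegral"))
#' @rdname accessors
#' @export
setGeneric("stepRadii", function(object) standardGeneric("stepRadii"))
#' @rdname accessors
#' @export
setGeneric("stepWeights", function(object) standardGeneric("stepWeights"))

#' Evaluate a step-function fluence at given radii
#'
#' @param object a [StepFluenceSource-class].
#' @param r radii (mm) at which to evaluate; negative radii are reflected.
#' @return numeric vector \eqn{\psi(r)}.
#' @export
setGeneric("evaluateFluence", function(object, r)
  standardGeneric("evaluateFluence"))

#' Predict dose from a film calibration curve
#'
#' @param object a [CalibrationCurve-class].
#' @param response net optical density values.
#' @return dose in Gy.
#' @export
setGeneric("predictDose", function(object, response)
  standardGeneric("predictDose"))

#' @rdname accessors
#' @export
setMethod("gridSpacing", "RadialDoseMap", function(object) object@spacing)
#' @rdname accessors
#' @export
setMethod("gridSpacing", "DoseKernel", function(object) object@spacing)
#' @rdname accessors
#' @export
setMethod("doseValues", "RadialDoseMap", function(object) object@values)
#' @rdname accessors
#' @export
setMethod("originIndex", "RadialDoseMap", function(object) object@origin)
#' @rdname accessors
#' @export
setMethod("kernelValues", "DoseKernel", function(object) object@values)
#' @rdname accessors
#' @export
setMethod("kernelIntegral", "DoseKernel", function(object)
  object@normalization)
#' @rdname accessors
#' @export
setMethod("stepRadii", "StepFluenceSource", function(object)
  object@stepRadii)
#' @rdname accessors
#' @export
setMethod("stepWeights", "StepFluenceSource", function(object)
  object@stepWeights)

#' @rdname evaluateFluence
setMethod("evaluateFluence", "StepFluenceSource", function(object, r) {
  r <- abs(r)
  # psi(r) = sum of weights of all steps with radius >= r
  vapply(r, function(ri) sum(object@stepWeights[object@stepRadii >= ri - 1e-12]),
         numeric(1L))
})

#' @rdname predictDose
setMethod("predictDose", "CalibrationCurve", function(object, response) {
  cf <- object@coefficients
  cf[1L] + cf[2L] * response + cf[3L] * response^2 + cf[4L] * response^3
})

setMethod("show", "RadialDoseMap", function(object) {
  d <- dim(object@values)
  cat(sprintf("RadialDoseMap: %d x %d grid, spacing %.4g mm (%.3g x %.3g mm)\n",
              d[1L], d[2L], object@spacing,
              d[1L] * object@spacing, d[2L] * object@spacing))
  cat(sprintf("  origin at (%d, %d); central-axis dose %.6g; max %.6g\n",
              object@origin[1L], object@origin[2L],
              object@values[object@origin[1L], object@origin[2L]],
              max(object@values)))
})

setMethod("show", "DoseKernel", function(object) {
  cat(sprintf("DoseKernel: %d radial samples, spacing %.4g mm, support %.3g mm\n",
              length(object@values), object@spacing,
              (length(object@values) - 1L) * object@spacing))
  cat(sprintf("  2D integral %.6g\n", object@normalization))
})

setMethod("show", "StepFluenceSource", function(object) {
  cat(sprintf("StepFluenceSource: %d steps, max radius %.3g mm, psi(0) = %.6g\n",
              length(object@stepRadii), max(object@stepRadii),
              sum(object@stepWeights)))
})

setMethod("show", "DeconvolutionResult", function(object) {
  cat(sprintf("DeconvolutionResult: %d iterations, final residual %.3g (%s)\n",
              object@iterationsUsed,
              utils::tail(object@residualHistory, 1L),
              if (object@converged) "converged" else "not converged"))
})

setMethod("show", "PerturbationSet", function(object) {
  cat("PerturbationSet:\n")
  print(as.data.frame(object))
})

#' Coerce a PerturbationSet to a data.frame
#'
#' @param x a [PerturbationSet-class].
#' @param ... unused.
#' @return data.frame with one row per field size.
#' @export
setMethod("as.data.frame", "PerturbationSet", function(x, ...) {
  data.frame(field_mm = x@fieldSize, p_housing = x@pHousing,
             p_sens = x@pSens, p_vol = x@pVol, k_total = x@kTotal)
})

setMethod("show", "CalibrationCurve", function(object) {
  cf <- object@coefficients
  cat(sprintf("CalibrationCurve: dose = %.4g + %.4g x + %.4g x^2 + %.4g x^3 (x = netOD)\n",
              cf[1L], cf[2L], cf[3L], cf[4L]))
  cat(sprintf("  response range [%.4g, %.4g], dose range [%.3g, %.3g] Gy\n",
              object@responseRange[1L], object@responseRange[2L],
              object@doseRange[1L], object@doseRange[2L]))
})

setMethod("show", "FilmScan", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("FilmScan: %d x %d px, 3 channels, %g dpi (%.3g x %.3g mm)\n",
              d[1L], d[2L], object@dpi,
              d[1L] * 25.4 / object@dpi, d[2L] * 25.4 / object@dpi))
})

setMethod("show", "BeamSpec", function(object) {
  cat(sprintf("BeamSpec: %g mm cone; kernel core sigma %.4g mm, tail sigma %.4g mm (weight %.3g)\n",
              object@nominalDiameter, object@coreSigma, object@tailSigma,
              object@tailWeight))
  cat(sprintf("  noise level %.3g; depth table %d rows\n",
              object@noiseLevel, nrow(object@depthTable)))
})
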