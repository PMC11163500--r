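#' Detector geometry and density over-response configuration
#'
#' Describes the modelled diode detector: the sensitive-disk diameter, the
#' mass densities of housing and chip (metadata), and the field-size
#' dependent density over-response tables used by the signal emulator. The
#' over-response tables are shipped data derived from the packaged
#' perturbation factors (an over-response is the reciprocal of the
#' corresponding perturbation factor); they are interpolated linearly in
#' field size and are exactly one at the reference field.
#'
#' @param sensitiveDiameter diameter of the sensitive disk in mm.
#' @param housingDensity housing (epoxy) mass density in g/cm^3, metadata.
#' @param chipDensity chip material density in g/cm^3, metadata (stored as
#'   published).
#' @param housingResponse,chipResponse data.frames with columns `field_mm`
#'   and `factor`: relative over-response vs field size. Defaults are
#'   derived from [packagedFactorTable()].
#' @return list of class-free geometry configuration.
#' @seealso [emulateSignalProfile()], [pVolGeometric()]
#' @export
detectorGeometry <- function(sensitiveDiameter = 1.5,
                             housingDensity = 1.15,
                             chipDensity = 1.4,
                             housingResponse = NULL,
                             chipResponse = NULL) {
  if (sensitiveDiameter <= 0) stop("'sensitiveDiameter' must be positive")
  if (housingDensity <= 0 || chipDensity <= 0)
    stop("densities must be positive")
  tab <- packagedFactorTable()
  if (is.null(housingResponse)) {
    keep <- !is.na(tab$p_housing)
    housingResponse <- data.frame(field_mm = tab$field_mm[keep],
                                  factor = 1 / tab$p_housing[keep])
  }
  if (is.null(chipResponse)) {
    keep <- !is.na(tab$p_sens)
    chipResponse <- data.frame(field_mm = tab$field_mm[keep],
                               factor = 1 / tab$p_sens[keep])
  }
  list(sensitiveDiameter = sensitiveDiameter,
       housingDensity = housingDensity, chipDensity = chipDensity,
       housingResponse = housingResponse, chipResponse = chipResponse)
}

# interpolate an over-response table at a field size (linear, clamped)
interpResponse <- function(table, fieldSize) {
  stats::approx(table$field_mm, table$factor, xout = fieldSize,
                rule = 2)$y
}

#' Mean dose over a detector disk
#'
#' Area-weighted mean of a gridded dose map over a disk of the given
#' diameter. Each grid cell entering the disk is weighted by the exact
#' geometric overlap area between the disk and the cell, so the quadrature
#' error is governed only by the cell-center sampling of the dose
#' (second order in the grid spacing). Converges to the point value as the
#' diameter approaches zero.
#'
#' @param map a [RadialDoseMap-class].
#' @param diameter disk diameter in mm.
#' @param center disk center (x, y) in mm relative to the beam axis.
#' @return mean dose over the disk.
#' @export
volumeAverage <- function(map, diameter, center = c(0, 0)) {
  stopifnot(is(map, "RadialDoseMap"), diameter > 0)
  sp <- gridSpacing(map)
  v <- doseValues(map)
  o <- originIndex(map)
  a <- diameter / 2
  cx <- center[1L]; cy <- center[2L]
  # x runs along columns, y along rows; cell centers in mm
  xs <- (seq_len(ncol(v)) - o[2L]) * sp
  ys <- (seq_len(nrow(v)) - o[1L]) * sp
  if (cx - a < xs[1L] - sp / 2 || cx + a > xs[length(xs)] + sp / 2 ||
      cy - a < ys[1L] - sp / 2 || cy + a > ys[length(ys)] + sp / 2)
    stop("disk exceeds the dose grid")
  ci <- which(xs >= cx - a - sp & xs <= cx + a + sp)
  ri <- which(ys >= cy - a - sp & ys <= cy + a + sp)
  xg <- rep(xs[ci], each = length(ri))
  yg <- rep(ys[ri], times = length(ci))
  w <- diskRectOverlap(cx, cy, a, xg - sp / 2, xg + sp / 2,
                       yg - sp / 2, yg + sp / 2)
  d <- as.vector(v[ri, ci, drop = FALSE])
  sum(w * d) / sum(w)
}

# mean dose over an axis-aligned square footprint (the "point" scoring
# voxel); exact cell-overlap weighting as for the disk
squareAverage <- function(map, side, center = c(0, 0)) {
  sp <- gridSpacing(map)
  v <- doseValues(map)
  o <- originIndex(map)
  h <- side / 2
  cx <- center[1L]; cy <- center[2L]
  xs <- (seq_len(ncol(v)) - o[2L]) * sp
  ys <- (seq_len(nrow(v)) - o[1L]) * sp
  ci <- which(xs >= cx - h - sp & xs <= cx + h + sp)
  ri <- which(ys >= cy - h - sp & ys <= cy + h + sp)
  xg <- rep(xs[ci], each = length(ri))
  yg <- rep(ys[ri], times = length(ci))
  ovl <- function(lo1, hi1, lo2, hi2)
    pmax(0, pmin(hi1, hi2) - pmax(lo1, lo2))
  w <- ovl(xg - sp / 2, xg + sp / 2, cx - h, cx + h) *
       ovl(yg - sp / 2, yg + sp / 2, cy - h, cy + h)
  d <- as.vector(v[ri, ci, drop = FALSE])
  sum(w * d) / sum(w)
}

#' Geometric volume-averaging perturbation factor
#'
#' Computes the volume-averaging factor
#' \deqn{P_{vol} = \frac{[D_{point}/D_{vol}]_{clin}}{[D_{point}/D_{vol}]_{msr}}}
#' where \eqn{D_{point}} is the central dose scored over a 0.2 mm square
#' voxel footprint and \eqn{D_{vol}} the mean dose over the sensitive disk,
#' both evaluated with the detector centered on the beam axis (the only
#' supported position). \eqn{P_{vol} \ge 1} for centrally peaked fields and
#' tends to one in the flat-field limit.
#'
#' @param doseClin,doseMsr [RadialDoseMap-class] objects for the clinical
#'   and machine-specific-reference fields.
#' @param geometry see [detectorGeometry()].
#' @param pointSide side length (mm) of the central scoring voxel footprint.
#' @param center must be the beam axis `c(0, 0)`; off-center evaluation is
#'   rejected.
#' @return the unitless factor P_vol.
#' @export
pVolGeometric <- function(doseClin, doseMsr, geometry = detectorGeometry(),
                          pointSide = 0.2, center = c(0, 0)) {
  if (any(center != 0))
    stop("off-center evaluation is not supported: the detector is centered")
  ratio <- function(map)
    squareAverage(map, pointSide) /
      volumeAverage(map, geometry$sensitiveDiameter)
  ratio(doseClin) / ratio(doseMsr)
}

#' Perturbation factors from stepwise simulated signals
#'
#' Assembles the perturbation decomposition from the four stepwise signal
#' quantities of a detector simulation chain, for a clinical field and the
#' msr field: `M_diode` (full detector model), `M_si_vol` (housing replaced
#' by water), `D_w_vol` (sensitive volume also replaced by water), and
#' `D_w_point` (point dose voxel). Each factor is the ratio of consecutive
#' steps, normalized to the msr field:
#' \deqn{P_{housing} = \frac{[M_{si,vol}/M_{diode}]_{clin}}{[M_{si,vol}/M_{diode}]_{msr}},\quad
#'   P_{sens} = \frac{[D_{w,vol}/M_{si,vol}]_{clin}}{[\cdot]_{msr}},\quad
#'   P_{vol} = \frac{[D_{w,point}/D_{w,vol}]_{clin}}{[\cdot]_{msr}}.}
#' The product telescopes exactly to the total correction
#' \eqn{k = [D_{w,point}/M_{diode}]_{clin} / [D_{w,point}/M_{diode}]_{msr}}.
#'
#' @param clin,msr named numeric vectors (or lists) with elements
#'   `M_diode`, `M_si_vol`, `D_w_vol`, `D_w_point`; all positive.
#' @param fieldSize nominal clinical field size in mm (metadata).
#' @return A [PerturbationSet-class] with the factors and the signals.
#' @examples
#' clin <- c(M_diode = 1.02, M_si_vol = 1.00, D_w_vol = 0.99, D_w_point = 1.06)
#' msr <- c(M_diode = 1.00, M_si_vol = 1.00, D_w_vol = 1.00, D_w_point = 1.00)
#' perturbationFromSignals(clin, msr, fieldSize = 3)
#' @export
perturbationFromSignals <- function(clin, msr, fieldSize = NA_real_) {
  need <- c("M_diode", "M_si_vol", "D_w_vol", "D_w_point")
  clin <- unlist(clin)[need]; msr <- unlist(msr)[need]
  if (any(is.na(clin)) || any(is.na(msr)))
    stop("signals must provide M_diode, M_si_vol, D_w_vol and D_w_point")
  if (any(clin <= 0) || any(msr <= 0))
    stop("all signals must be positive")
  pH <- (clin["M_si_vol"] / clin["M_diode"]) /
        (msr["M_si_vol"] / msr["M_diode"])
  pS <- (clin["D_w_vol"] / clin["M_si_vol"]) /
        (msr["D_w_vol"] / msr["M_si_vol"])
  pV <- (clin["D_w_point"] / clin["D_w_vol"]) /
        (msr["D_w_point"] / msr["D_w_vol"])
  new("PerturbationSet", fieldSize = as.numeric(fieldSize),
      pHousing = unname(pH), pSens = unname(pS), pVol = unname(pV),
      kTotal = unname(pH * pS * pV),
      signals = list(clin = clin, msr = msr))
}

#' Packaged detector perturbation-factor table
#'
#' Returns the shipped table of published perturbation factors of the
#' modelled diode detector for the circular cones at which they were
#' reported (3, 4, 5 and 25 mm). Components that were not reported for a
#' field size are `NA` and are never interpolated silently; the total
#' correction for those sizes is the published total. At the 25 mm msr
#' field all factors are one by construction. For the 3 mm cone the housing
#' factor was published both as 0.973 (rounded) and 0.9725; the table
#' carries 0.9725 as the working value and the rounded variant in
#' `p_housing_alt`.
#'
#' @param fieldSize optional field size(s) in mm to select; must lie within
#'   3 to 25 mm. `NULL` returns the full table.
#' @return data.frame with columns `field_mm`, `p_housing`,
#'   `p_housing_alt`, `p_sens`, `p_vol`, `k_total`, `note`.
#' @export
packagedFactorTable <- function(fieldSize = NULL) {
  path <- system.file("extdata", "perturbation_factors.csv",
                      package = "smallfieldr", mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (is.null(fieldSize)) return(tab)
  if (any(fieldSize < 3 | fieldSize > 25))
    stop("field size outside the characterized 3-25 mm range")
  out <- tab[match(fieldSize, tab$field_mm), , drop = FALSE]
  if (any(is.na(out$field_mm)))
    stop("no packaged factors at field size(s) ",
         paste(fieldSize[is.na(out$field_mm)], collapse = ", "),
         " mm; entries are never interpolated silently")
  rownames(out) <- NULL
  out
}

#' Interpolated total correction factor
#'
#' Linear interpolation of the packaged total correction factor `k_total`
#' between the published field sizes; used by the synthetic detector
#' reading generator and the correction round-trip.
#'
#' @param fieldSize field size(s) in mm within 3 to 25 mm.
#' @return interpolated k_total value(s).
#' @export
interpKTotal <- function(fieldSize) {
  if (any(fieldSize < 3 | fieldSize > 25))
    stop("field size outside the characterized 3-25 mm range")
  tab <- packagedFactorTable()
  stats::approx(tab$field_mm, tab$k_total, xout = fieldSize)$y
}

#' Emulate the detector signal profile M(r)
#'
#' Parametric emulator of a finite-size diode scanning a dose distribution:
#' at each scan position the signal is the mean dose over the sensitive
#' disk multiplied by the field-size-interpolated density over-response
#' (housing times chip tables). Deterministic. The emulated signal profile
#' of a small field is slightly broader than the underlying dose profile,
#' with the broadening monotone in the sensitive diameter.
#'
#' @param map a [RadialDoseMap-class] dose distribution.
#' @param geometry see [detectorGeometry()].
#' @param positions scan positions in mm along the lateral axis; every disk
#'   must lie inside the grid.
#' @param fieldSize nominal field size in mm, used to look up the density
#'   over-response; `NA` applies unity response.
#' @return data.frame with columns `position_mm` and `value`.
#' @export
emulateSignalProfile <- function(map, geometry = detectorGeometry(),
                                 positions, fieldSize = NA_real_) {
  stopifnot(is(map, "RadialDoseMap"))
  resp <- if (is.na(fieldSize)) 1
          else interpResponse(geometry$housingResponse, fieldSize) *
               interpResponse(geometry$chipResponse, fieldSize)
  vals <- vapply(positions, function(p)
    volumeAverage(map, geometry$sensitiveDiameter, center = c(p, 0)),
    numeric(1L))
  data.frame(position_mm = positions, value = vals * resp)
}
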