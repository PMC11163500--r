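#' Read and write profile tables
#'
#' Profiles and depth curves travel as two-column CSV files with a header
#' (`position_mm,value` for lateral profiles, `depth_mm,value` for depth
#' curves).
#'
#' @param path file path.
#' @param profile data.frame to write.
#' @param cols column names used on write.
#' @return `readProfileCSV` returns the data.frame; `writeProfileCSV`
#'   returns `path` invisibly.
#' @export
readProfileCSV <- function(path) {
  df <- utils::read.csv(path)
  if (ncol(df) < 2L) stop("expected a two-column CSV with a header")
  df
}

#' @rdname readProfileCSV
#' @export
writeProfileCSV <- function(profile, path,
                            cols = c("position_mm", "value")) {
  df <- asProfileFrame(profile, cols = cols)
  names(df) <- cols
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write and read dose maps as 32-bit float TIFF with a sidecar
#'
#' Dose maps are stored as single-channel 32-bit float TIFF plus a
#' key-value sidecar text file (same path with `.txt` appended) carrying
#' the grid spacing and origin, which TIFF alone does not preserve.
#'
#' @param map a [RadialDoseMap-class].
#' @param path TIFF path.
#' @return `writeDoseMapTIFF` returns `path` invisibly;
#'   `readDoseMapTIFF` the reconstructed [RadialDoseMap-class].
#' @export
writeDoseMapTIFF <- function(map, path) {
  stopifnot(is(map, "RadialDoseMap"))
  tiff::writeTIFF(doseValues(map), path, bits.per.sample = 32L,
                  reduce = FALSE)
  o <- originIndex(map)
  writeLines(c(sprintf("spacing_mm=%.10g", gridSpacing(map)),
               sprintf("origin_row=%d", o[1L]),
               sprintf("origin_col=%d", o[2L])),
             paste0(path, ".txt"))
  invisible(path)
}

#' @rdname writeDoseMapTIFF
#' @export
readDoseMapTIFF <- function(path) {
  vals <- tiff::readTIFF(path, as.is = FALSE)
  side <- readLines(paste0(path, ".txt"))
  kv <- strsplit(side, "=", fixed = TRUE)
  keys <- vapply(kv, `[`, character(1L), 1L)
  num <- as.numeric(vapply(kv, `[`, character(1L), 2L))
  RadialDoseMap(vals, spacing = num[keys == "spacing_mm"],
                origin = c(num[keys == "origin_row"],
                           num[keys == "origin_col"]))
}

#' Write and read film scans as uncompressed 48-bit RGB TIFF
#'
#' Film scans are stored uncompressed with 16 bits per channel; the
#' scanner resolution travels in a key-value sidecar text file (same path
#' with `.txt` appended).
#'
#' @param scan a [FilmScan-class].
#' @param path TIFF path.
#' @param dpi resolution override when no sidecar is present.
#' @return `writeFilmTIFF` returns `path` invisibly; `readFilmTIFF` the
#'   [FilmScan-class].
#' @export
writeFilmTIFF <- function(scan, path) {
  stopifnot(is(scan, "FilmScan"))
  tiff::writeTIFF(scan@pixels / 65535, path, bits.per.sample = 16L,
                  compression = "none", reduce = FALSE)
  writeLines(sprintf("dpi=%.10g", scan@dpi), paste0(path, ".txt"))
  invisible(path)
}

#' @rdname writeFilmTIFF
#' @export
readFilmTIFF <- function(path, dpi = NULL) {
  # 16-bit samples come back normalized to [0, 1]; restore integer counts
  img <- round(tiff::readTIFF(path) * 65535)
  if (is.null(dpi)) {
    side <- paste0(path, ".txt")
    if (!file.exists(side))
      stop("no resolution sidecar found; supply 'dpi'")
    kv <- strsplit(readLines(side), "=", fixed = TRUE)
    keys <- vapply(kv, `[`, character(1L), 1L)
    dpi <- as.numeric(vapply(kv, `[`, character(1L), 2L))[keys == "dpi"]
  }
  FilmScan(array(as.numeric(img), dim = dim(img)), dpi = dpi)
}

#' Store and load a film calibration as JSON
#'
#' @param curve a [CalibrationCurve-class].
#' @param path JSON path.
#' @param batch optional film batch identifier stored alongside.
#' @return `writeCalibrationJSON` returns `path` invisibly;
#'   `readCalibrationJSON` the [CalibrationCurve-class] (batch id in
#'   attribute `batch`).
#' @export
writeCalibrationJSON <- function(curve, path, batch = NULL) {
  stopifnot(is(curve, "CalibrationCurve"))
  obj <- list(coefficients = curve@coefficients,
              response_range = curve@responseRange,
              dose_range_gy = curve@doseRange)
  if (!is.null(batch)) obj$batch <- batch
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeCalibrationJSON
#' @export
readCalibrationJSON <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  curve <- new("CalibrationCurve",
               coefficients = as.numeric(obj$coefficients),
               responseRange = as.numeric(obj$response_range),
               doseRange = as.numeric(obj$dose_range_gy))
  if (!is.null(obj$batch)) attr(curve, "batch") <- obj$batch
  curve
}
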