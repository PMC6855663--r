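#' Read a calliper-measurement CSV into a TumourCohort
#'
#' Expected columns: `animal_id`, `group`, `day`, `length_mm`, `width_mm`,
#' `height_mm` (header required, UTF-8, decimal point). Missed visits are
#' rows with all three dimensions empty. An optional fates CSV
#' (`animal_id`, `fate`, `fate_day`) records killed animals; without it
#' every animal is treated as followed to its last measurement.
#'
#' @param path measurements CSV path.
#' @param controlGroup label of the untreated arm.
#' @param fatesPath optional fates CSV path.
#' @return A [TumourCohort-class].
#' @export
readMeasurementCSV <- function(path, controlGroup, fatesPath = NULL) {
  m <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("animal_id", "group", "day", "length_mm", "width_mm", "height_mm")
  missing <- setdiff(need, names(m))
  if (length(missing))
    stop(sprintf("%s: missing columns: %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  fates <- if (!is.null(fatesPath)) read.csv(fatesPath, stringsAsFactors = FALSE)
  TumourCohort(m, controlGroup = controlGroup, fates = fates)
}

#' Write a cohort's measurement (and fate) tables to CSV
#'
#' @param cohort a [TumourCohort-class].
#' @param path measurements CSV path.
#' @param fatesPath optional fates CSV path.
#' @return `path`, invisibly.
#' @export
writeMeasurementCSV <- function(cohort, path, fatesPath = NULL) {
  write.csv(measurements(cohort), path, row.names = FALSE)
  if (!is.null(fatesPath)) write.csv(fates(cohort), fatesPath, row.names = FALSE)
  invisible(path)
}

#' Read a time-activity concentration CSV
#'
#' Expected columns: `time_h`, `concentration`, and optionally `unit`
#' (`MBq_per_g` or `percent_IA_per_g`; one value for the whole series).
#'
#' @param path CSV path.
#' @param injectedActivityMBq injected activity for percent-IA input.
#' @return A [TimeActivitySeries-class].
#' @export
readTimeActivityCSV <- function(path, injectedActivityMBq = NA_real_) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("time_h", "concentration") %in% names(d)))
    stop(sprintf("%s: need columns time_h, concentration", path), call. = FALSE)
  unit <- if ("unit" %in% names(d)) unique(d$unit) else "MBq_per_g"
  if (length(unit) != 1L)
    stop(sprintf("%s: mixed units in one series", path), call. = FALSE)
  timeActivitySeries(d$time_h, d$concentration, unit = unit,
                     injectedActivityMBq = injectedActivityMBq)
}

#' Write a stained section to a PNG file
#'
#' The RGB raster goes to `path`; the ROI polygon is written alongside as a
#' CSV (`x`, `y`, 0-based pixel coordinates) when `roiPath` is given.
#'
#' @param section a [StainedSection-class].
#' @param path PNG output path.
#' @param roiPath optional ROI CSV path.
#' @return `path`, invisibly.
#' @export
writeSectionPNG <- function(section, path, roiPath = NULL) {
  png::writePNG(section@image, path)
  if (!is.null(roiPath))
    write.csv(data.frame(x = section@roi[, 1], y = section@roi[, 2]),
              roiPath, row.names = FALSE)
  invisible(path)
}

#' Read a stained section from a PNG or TIFF file
#'
#' @param path image path (`.png`, `.tif`/`.tiff`).
#' @param stain `"MT"` or `"Ki67"`.
#' @param roiPath CSV of ROI polygon vertices (`x`, `y`).
#' @param pixelSizeUm pixel size in micrometres.
#' @return A [StainedSection-class].
#' @export
readSection <- function(path, stain, roiPath, pixelSizeUm = 0.25) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = , tiff = tiff::readTIFF(path),
    stop("unsupported image format: ", ext, call. = FALSE))
  if (length(dim(img)) == 3L && dim(img)[3] > 3L) img <- img[, , 1:3]
  roi <- read.csv(roiPath, stringsAsFactors = FALSE)
  stainedSection(img, stain = stain, roi = as.matrix(roi[, c("x", "y")]),
                 pixelSizeUm = pixelSizeUm)
}
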