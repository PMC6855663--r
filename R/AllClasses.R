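#' @import methods
NULL

## ---------------------------------------------------------------------------
## TumourCohort
## ---------------------------------------------------------------------------

#' Cohort of calliper-measured tumour-bearing animals
#'
#' Container for a combination-therapy study: one row of `measurements` per
#' animal per visit day (calliper length/width/height in mm, all three `NA`
#' for a missed visit), one row of `fates` per animal recording whether it
#' was followed to the end of the study or killed (with the day), and the
#' label of the untreated control arm.
#'
#' Day 0 is the first treatment day and every animal must carry a complete
#' day-0 baseline measurement; days are strictly increasing within an animal.
#'
#' @slot measurements data.frame with columns `animal_id`, `group`, `day`,
#'   `length_mm`, `width_mm`, `height_mm`.
#' @slot fates data.frame with columns `animal_id`, `fate`
#'   (`"followed-to-end"` or `"killed"`) and `fate_day`.
#' @slot controlGroup label of the untreated control arm.
#' @export
setClass("TumourCohort",
  slots = c(measurements = "data.frame",
            fates = "data.frame",
            controlGroup = "character"))

validTumourCohort <- function(object) {
  m <- object@measurements
  f <- object@fates
  msgs <- character()
  need <- c("animal_id", "group", "day", "length_mm", "width_mm", "height_mm")
  if (!all(need %in% names(m)))
    return(paste("measurements must have columns:", paste(need, collapse = ", ")))
  if (!all(c("animal_id", "fate", "fate_day") %in% names(f)))
    return("fates must have columns: animal_id, fate, fate_day")
  if (any(m$day < 0, na.rm = TRUE)) msgs <- c(msgs, "days must be >= 0")
  dims <- as.matrix(m[, c("length_mm", "width_mm", "height_mm")])
  partial <- rowSums(is.na(dims)) %in% c(1L, 2L)
  if (any(partial))
    msgs <- c(msgs, "calliper dimensions must be all present or all absent per visit")
  if (any(dims <= 0, na.rm = TRUE))
    msgs <- c(msgs, "calliper dimensions must be strictly positive")
  for (id in unique(m$animal_id)) {
    mi <- m[m$animal_id == id, , drop = FALSE]
    if (any(diff(mi$day) <= 0)) {
      msgs <- c(msgs, sprintf("days not strictly increasing for animal '%s'", id))
    }
    base <- mi[mi$day == 0, , drop = FALSE]
    if (nrow(base) != 1L || anyNA(base[, c("length_mm", "width_mm", "height_mm")]))
      msgs <- c(msgs, sprintf("animal '%s' lacks a complete day-0 baseline", id))
    if (length(unique(mi$group)) != 1L)
      msgs <- c(msgs, sprintf("animal '%s' assigned to more than one group", id))
  }
  if (!setequal(unique(m$animal_id), f$animal_id) || anyDuplicated(f$animal_id))
    msgs <- c(msgs, "fates must have exactly one row per measured animal")
  if (!all(f$fate %in% c("followed-to-end", "killed")))
    msgs <- c(msgs, "fate must be 'followed-to-end' or 'killed'")
  killed <- f[f$fate == "killed", , drop = FALSE]
  if (nrow(killed)) {
    last <- vapply(killed$animal_id,
                   function(id) max(m$day[m$animal_id == id]), numeric(1))
    if (any(killed$fate_day < last))
      msgs <- c(msgs, "fate_day must be >= last measurement day for killed animals")
  }
  if (length(object@controlGroup) != 1L ||
      !object@controlGroup %in% m$group)
    msgs <- c(msgs, "controlGroup must name a non-empty arm")
  if (length(msgs)) msgs else TRUE
}
setValidity("TumourCohort", validTumourCohort)

#' Construct a TumourCohort
#'
#' @param measurements data.frame of calliper measurements (see
#'   [TumourCohort-class]).
#' @param controlGroup label of the untreated arm.
#' @param fates optional data.frame (`animal_id`, `fate`, `fate_day`); when
#'   omitted every animal is `"followed-to-end"` with `fate_day` set to its
#'   last measurement day.
#' @return A [TumourCohort-class] object.
#' @examples
#' m <- data.frame(animal_id = "a1", group = "control", day = c(0, 3),
#'                 length_mm = c(10, 11), width_mm = c(8, 9),
#'                 height_mm = c(8, 9))
#' TumourCohort(m, controlGroup = "control")
#' @export
TumourCohort <- function(measurements, controlGroup, fates = NULL) {
  measurements <- as.data.frame(measurements)
  measurements <- measurements[order(measurements$animal_id, measurements$day), ]
  rownames(measurements) <- NULL
  if (is.null(fates)) {
    ids <- unique(measurements$animal_id)
    fates <- data.frame(
      animal_id = ids,
      fate = "followed-to-end",
      fate_day = vapply(ids, function(id)
        max(measurements$day[measurements$animal_id == id]), numeric(1)),
      stringsAsFactors = FALSE)
  }
  fates <- as.data.frame(fates)
  rownames(fates) <- NULL
  new("TumourCohort", measurements = as.data.frame(measurements),
      fates = fates, controlGroup = controlGroup)
}

#' @describeIn TumourCohort-class calliper measurement table.
#' @param object,x a `TumourCohort`.
#' @export
setGeneric("measurements", function(x) standardGeneric("measurements"))
#' @rdname TumourCohort-class
#' @export
setMethod("measurements", "TumourCohort", function(x) x@measurements)

#' @rdname TumourCohort-class
#' @export
setGeneric("fates", function(x) standardGeneric("fates"))
#' @rdname TumourCohort-class
#' @export
setMethod("fates", "TumourCohort", function(x) x@fates)

#' @rdname TumourCohort-class
#' @export
setGeneric("controlGroup", function(x) standardGeneric("controlGroup"))
#' @rdname TumourCohort-class
#' @export
setMethod("controlGroup", "TumourCohort", function(x) x@controlGroup)

#' @rdname TumourCohort-class
#' @export
setGeneric("arms", function(x) standardGeneric("arms"))
#' @rdname TumourCohort-class
#' @export
setMethod("arms", "TumourCohort", function(x) unique(x@measurements$group))

setMethod("show", "TumourCohort", function(object) {
  m <- object@measurements
  cat("TumourCohort:", length(unique(m$animal_id)), "animals in",
      length(unique(m$group)), "arms\n")
  tab <- table(m$group[!duplicated(m$animal_id)])
  for (g in names(tab))
    cat(sprintf("  %s%s: n = %d\n", g,
                if (g == object@controlGroup) " (control)" else "", tab[[g]]))
  cat("  visit days:", paste(sort(unique(m$day)), collapse = ", "), "\n")
})

## ---------------------------------------------------------------------------
## TimeActivitySeries
## ---------------------------------------------------------------------------

#' Time-activity concentration series for one tissue
#'
#' Activity concentration of a radiopharmaceutical in a tissue versus time
#' after injection, the input to mono-exponential washout fitting and
#' time-integrated-activity estimation. Concentrations may be in MBq/g or in
#' percent of injected activity per gram; the latter requires
#' `injectedActivityMBq` so the series can be converted before fitting.
#'
#' @slot times hours post injection, strictly increasing, >= 0.
#' @slot concentrations activity concentration, all > 0.
#' @slot unit `"MBq_per_g"` or `"percent_IA_per_g"`.
#' @slot injectedActivityMBq injected activity (MBq), `NA` when not needed.
#' @export
setClass("TimeActivitySeries",
  slots = c(times = "numeric", concentrations = "numeric",
            unit = "character", injectedActivityMBq = "numeric"))

setValidity("TimeActivitySeries", function(object) {
  msgs <- character()
  if (length(object@times) != length(object@concentrations))
    msgs <- c(msgs, "times and concentrations must have the same length")
  if (length(object@times) < 2L)
    msgs <- c(msgs, "at least 2 time points are required")
  if (any(object@times < 0) || any(diff(object@times) <= 0))
    msgs <- c(msgs, "times must be >= 0 and strictly increasing")
  if (any(object@concentrations <= 0))
    msgs <- c(msgs, "concentrations must be strictly positive")
  if (!object@unit %in% c("MBq_per_g", "percent_IA_per_g"))
    msgs <- c(msgs, "unit must be 'MBq_per_g' or 'percent_IA_per_g'")
  if (length(msgs)) msgs else TRUE
})

#' Construct a TimeActivitySeries
#'
#' @param times hours post injection.
#' @param concentrations activity concentrations, > 0.
#' @param unit `"MBq_per_g"` (default) or `"percent_IA_per_g"`.
#' @param injectedActivityMBq injected activity in MBq; required to convert
#'   percent-injected-activity data.
#' @return A [TimeActivitySeries-class].
#' @examples
#' timeActivitySeries(c(1, 24, 72), c(2.0, 1.1, 0.3))
#' @export
timeActivitySeries <- function(times, concentrations, unit = "MBq_per_g",
                               injectedActivityMBq = NA_real_) {
  new("TimeActivitySeries", times = as.numeric(times),
      concentrations = as.numeric(concentrations), unit = unit,
      injectedActivityMBq = as.numeric(injectedActivityMBq))
}

setMethod("show", "TimeActivitySeries", function(object) {
  cat(sprintf("TimeActivitySeries: %d points, %.3g-%.3g h, unit %s\n",
              length(object@times), min(object@times), max(object@times),
              object@unit))
})

## ---------------------------------------------------------------------------
## StainedSection / TissueMasks
## ---------------------------------------------------------------------------

#' A digitised stained tumour section
#'
#' An RGB raster of a scanned histological section together with its pixel
#' size, the stain it carries (Masson's trichrome `"MT"` or `"Ki67"`), and a
#' closed tumour region-of-interest polygon drawn to exclude the capsule.
#'
#' Coordinate convention: pixel-centre coordinates, origin at the top-left
#' pixel centre, x to the right, y down, 0-based. Image arrays are indexed
#' `image[y + 1, x + 1, channel]` with channel values in `[0, 1]`.
#'
#' @slot image numeric array `height x width x 3`, values in `[0, 1]`.
#' @slot pixelSizeUm pixel edge length in micrometres (default 0.25).
#' @slot stain `"MT"` or `"Ki67"`.
#' @slot roi closed polygon, an `n x 2` matrix of (x, y) pixel coordinates.
#' @export
setClass("StainedSection",
  slots = c(image = "array", pixelSizeUm = "numeric",
            stain = "character", roi = "matrix"))

setValidity("StainedSection", function(object) {
  msgs <- character()
  d <- dim(object@image)
  if (length(d) != 3L || d[3] != 3L)
    msgs <- c(msgs, "image must be a height x width x 3 array")
  if (min(object@image) < 0 || max(object@image) > 1)
    msgs <- c(msgs, "image values must lie in [0, 1]")
  if (object@pixelSizeUm <= 0) msgs <- c(msgs, "pixelSizeUm must be > 0")
  if (!object@stain %in% c("MT", "Ki67"))
    msgs <- c(msgs, "stain must be 'MT' or 'Ki67'")
  if (ncol(object@roi) != 2L || nrow(object@roi) < 3L)
    msgs <- c(msgs, "roi must be an n x 2 polygon with n >= 3")
  else if (length(d) == 3L &&
           (any(object@roi[, 1] < 0) || any(object@roi[, 1] > d[2] - 1) ||
            any(object@roi[, 2] < 0) || any(object@roi[, 2] > d[1] - 1)))
    msgs <- c(msgs, "roi must lie within image bounds")
  if (length(msgs)) msgs else TRUE
})

#' Construct a StainedSection
#'
#' @param image `height x width x 3` array in `[0, 1]`.
#' @param stain `"MT"` or `"Ki67"`.
#' @param roi `n x 2` polygon (x, y) in 0-based pixel coordinates.
#' @param pixelSizeUm pixel size in micrometres.
#' @return A [StainedSection-class].
#' @export
stainedSection <- function(image, stain, roi, pixelSizeUm = 0.25) {
  new("StainedSection", image = image, pixelSizeUm = pixelSizeUm,
      stain = stain, roi = as.matrix(roi))
}

setMethod("show", "StainedSection", function(object) {
  d <- dim(object@image)
  cat(sprintf("StainedSection (%s): %d x %d px @ %.3g um, ROI %d vertices\n",
              object@stain, d[2], d[1], object@pixelSizeUm, nrow(object@roi)))
})

#' Pixel-class masks for one stained section
#'
#' Binary masks produced by colour-threshold segmentation of a
#' [StainedSection-class] and, for trichrome sections, necrosis
#' segmentation. `tissue` is stained tumour tissue inside the ROI after
#' removal of background (cracks) and fold artefacts, so the partition
#' invariants are `positive` inside `tissue`, `necrotic` and `viable`
#' disjoint with union `tissue`. The integer `labels` raster keeps the raw
#' per-pixel class (0 outside ROI, 1 background/crack, 2 fold, 3
#' counterstained tissue, 4 positive stain, 5 necrosis colour class).
#'
#' @slot background logical matrix: background/crack or fold artefact pixels.
#' @slot tissue logical matrix: tumour tissue (excludes artefacts).
#' @slot positive logical matrix: positively stained pixels.
#' @slot necrotic logical matrix: necrotic tumour.
#' @slot viable logical matrix: viable (non-necrotic) tumour.
#' @slot labels integer matrix of raw pixel classes.
#' @slot pixelSizeUm pixel size carried over from the section.
#' @export
setClass("TissueMasks",
  slots = c(background = "matrix", tissue = "matrix", positive = "matrix",
            necrotic = "matrix", viable = "matrix", labels = "matrix",
            pixelSizeUm = "numeric"))

setValidity("TissueMasks", function(object) {
  msgs <- character()
  dims <- lapply(list(object@background, object@tissue, object@positive,
                      object@necrotic, object@viable, object@labels), dim)
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1L)
    msgs <- c(msgs, "all masks must share one shape")
  if (any(object@positive & !object@tissue))
    msgs <- c(msgs, "positive pixels must lie within tissue")
  if (any(object@necrotic & object@viable))
    msgs <- c(msgs, "necrotic and viable must be disjoint")
  if (!identical(object@necrotic | object@viable, object@tissue))
    msgs <- c(msgs, "necrotic and viable must partition tissue")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "TissueMasks", function(object) {
  npx <- function(m) sum(m)
  cat(sprintf(paste0("TissueMasks: %d tissue px (%d positive, %d necrotic,",
                     " %d viable), %d artefact px\n"),
              npx(object@tissue), npx(object@positive), npx(object@necrotic),
              npx(object@viable), npx(object@background)))
})

## ---------------------------------------------------------------------------
## SurvivalCurve
## ---------------------------------------------------------------------------

#' Kaplan-Meier progression-free survival curve
#'
#' Right-continuous product-limit step function: `survival[i]` is the
#' estimated proportion of animals without tumour progression just after
#' `time[i]`. S(0) = 1 is implicit.
#'
#' @slot time distinct observed times, increasing.
#' @slot survival estimate after each time, non-increasing, in `[0, 1]`.
#' @slot nRisk number at risk at each time.
#' @slot nEvent progression events at each time.
#' @slot nCensor censorings at each time.
#' @export
setClass("SurvivalCurve",
  slots = c(time = "numeric", survival = "numeric", nRisk = "numeric",
            nEvent = "numeric", nCensor = "numeric"))

setValidity("SurvivalCurve", function(object) {
  msgs <- character()
  n <- length(object@time)
  if (any(vapply(list(object@survival, object@nRisk, object@nEvent,
                      object@nCensor), length, integer(1)) != n))
    msgs <- c(msgs, "all slots must have equal length")
  if (n && any(diff(object@time) <= 0))
    msgs <- c(msgs, "times must be strictly increasing")
  if (any(object@survival < 0 | object@survival > 1))
    msgs <- c(msgs, "survival must lie in [0, 1]")
  if (n > 1 && any(diff(object@survival) > 1e-12))
    msgs <- c(msgs, "survival must be non-increasing")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "SurvivalCurve", function(object) {
  cat(sprintf("SurvivalCurve: %d time points, final S = %.3f\n",
              length(object@time),
              if (length(object@survival)) tail(object@survival, 1) else 1))
})

#' @describeIn SurvivalCurve-class step function as a data.frame.
#' @param x a `SurvivalCurve`.
#' @export
setGeneric("asStepFunction", function(x) standardGeneric("asStepFunction"))
#' @rdname SurvivalCurve-class
#' @export
setMethod("asStepFunction", "SurvivalCurve", function(x) {
  data.frame(time = x@time, survival = x@survival, n_risk = x@nRisk,
             n_event = x@nEvent, n_censor = x@nCensor)
})
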