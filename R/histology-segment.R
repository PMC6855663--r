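## Reference stain colours (RGB in [0,1]) shared by the default thresholds
## and the synthetic section renderer. Real slides vary; thresholds are a
## manual calibration step and fully user-overridable.
stainPalette <- function() {
  list(
    background = c(0.96, 0.96, 0.96),  # glass / cracks, near-white
    fold = c(0.15, 0.12, 0.18),        # over-dark folded tissue
    mtCounter = c(0.72, 0.35, 0.55),   # trichrome cytoplasm, red-purple
    mtPositive = c(0.25, 0.35, 0.78),  # collagen, aniline blue
    necrosis = c(0.93, 0.72, 0.78),    # pale eosin-dominant necrosis
    ki67Counter = c(0.45, 0.48, 0.72), # haematoxylin counterstain
    ki67Positive = c(0.55, 0.33, 0.14) # DAB, brown
  )
}

#' Default colour thresholds for pixel classification
#'
#' Hue/saturation/value windows for each pixel class of a stained section.
#' Shared classes: background (cracks, glass; bright and unsaturated) and
#' fold artefacts (over-dark). Stain-specific positive classes: aniline-blue
#' collagen for Masson's trichrome, DAB brown for Ki67. Trichrome sections
#' additionally carry a necrosis colour class (pale, eosin-dominant pink).
#' Hue is in `[0, 1]`; windows with `hMin > hMax` wrap through red.
#'
#' These defaults are calibrated against the reference palette used by the
#' synthetic renderer and are meant to be overridden (list-edit any entry)
#' when segmenting real scanner output, where threshold choice is a
#' pathologist-approved calibration step.
#'
#' @param stain `"MT"` or `"Ki67"`.
#' @return Nested list of threshold windows.
#' @export
defaultThresholds <- function(stain = c("MT", "Ki67")) {
  stain <- match.arg(stain)
  base <- list(
    background = list(sMax = 0.10, vMin = 0.85),
    fold = list(vMax = 0.30))
  if (stain == "MT") {
    c(base, list(
      positive = list(hMin = 0.52, hMax = 0.75, sMin = 0.35, vMin = 0.30,
                      vMax = 0.95),
      necrosis = list(hMin = 0.80, hMax = 0.08, sMin = 0.12, sMax = 0.40,
                      vMin = 0.82)))
  } else {
    c(base, list(
      positive = list(hMin = 0.02, hMax = 0.15, sMin = 0.50, vMin = 0.25,
                      vMax = 0.80),
      necrosis = NULL))
  }
}

## Integer codes for the raw pixel classes stored in TissueMasks@labels.
.PX_OUT <- 0L; .PX_BACKGROUND <- 1L; .PX_FOLD <- 2L
.PX_COUNTER <- 3L; .PX_POSITIVE <- 4L; .PX_NECROSIS <- 5L

#' Colour-threshold pixel classification of a stained section
#'
#' Assigns every pixel inside the tumour ROI to exactly one class by
#' thresholding in hue/saturation/value space, in priority order: fold
#' artefact (over-dark), background/crack (bright, unsaturated), positive
#' stain, necrosis colour class (trichrome only), counterstained tissue
#' (everything else). Pixels outside the ROI are ignored.
#'
#' The returned [TissueMasks-class] has `tissue` = counterstain + positive +
#' necrosis-colour pixels, `background` = cracks and folds, and — pending
#' [segmentNecrosis()] — `viable` equal to `tissue` with `necrotic` empty.
#'
#' @param section a [StainedSection-class].
#' @param thresholds threshold list, see [defaultThresholds()].
#' @return A [TissueMasks-class].
#' @export
classifyPixels <- function(section, thresholds = defaultThresholds(section@stain)) {
  stopifnot(is(section, "StainedSection"))
  img <- section@image
  d <- dim(img)[1:2]
  roi <- rasterizePolygon(section@roi, d)
  idx <- which(roi)
  if (!length(idx)) stop("ROI covers no pixels", call. = FALSE)
  rgb <- rbind(img[, , 1][idx], img[, , 2][idx], img[, , 3][idx])
  hsv <- grDevices::rgb2hsv(rgb, maxColorValue = 1)
  h <- hsv[1, ]; s <- hsv[2, ]; v <- hsv[3, ]

  lab <- rep(.PX_COUNTER, length(idx))
  th <- thresholds
  if (!is.null(th$necrosis)) {
    ne <- th$necrosis
    isNec <- hueIn(h, ne$hMin, ne$hMax) & s >= ne$sMin & s <= ne$sMax &
      v >= ne$vMin
    lab[isNec] <- .PX_NECROSIS
  }
  po <- th$positive
  isPos <- hueIn(h, po$hMin, po$hMax) & s >= po$sMin &
    v >= po$vMin & v <= po$vMax
  lab[isPos] <- .PX_POSITIVE
  isBg <- s <= th$background$sMax & v >= th$background$vMin
  lab[isBg] <- .PX_BACKGROUND
  isFold <- v <= th$fold$vMax
  lab[isFold] <- .PX_FOLD

  labels <- matrix(.PX_OUT, d[1], d[2])
  labels[idx] <- lab
  tissue <- labels >= .PX_COUNTER
  if (!any(tissue))
    stop("thresholds label zero tissue pixels", call. = FALSE)
  new("TissueMasks",
      background = labels == .PX_BACKGROUND | labels == .PX_FOLD,
      tissue = tissue,
      positive = labels == .PX_POSITIVE,
      necrotic = matrix(FALSE, d[1], d[2]),
      viable = tissue,
      labels = labels,
      pixelSizeUm = section@pixelSizeUm)
}

#' Partition trichrome tissue into necrotic and viable tumour
#'
#' Necrotic tumour appears in trichrome sections as connected pale,
#' eosin-dominant regions. Pixels of that colour class are morphologically
#' closed, connected components are extracted, and components smaller than
#' `minRegionAreaUm2` are absorbed back into viable tissue; what remains is
#' the necrotic mask. The complement within tissue is viable tumour.
#'
#' @param masks a [TissueMasks-class] from a trichrome section.
#' @param minRegionAreaUm2 minimum necrotic-component area (um^2).
#' @param closingRadiusPx radius (pixels) of the disc used for closing.
#' @return The updated [TissueMasks-class].
#' @export
segmentNecrosis <- function(masks, minRegionAreaUm2 = 50, closingRadiusPx = 2) {
  stopifnot(is(masks, "TissueMasks"))
  cand <- masks@labels == .PX_NECROSIS
  necrotic <- matrix(FALSE, nrow(cand), ncol(cand))
  if (any(cand)) {
    closed <- cand
    if (closingRadiusPx > 0) {
      brush <- EBImage::makeBrush(2 * closingRadiusPx + 1, shape = "disc")
      closed <- EBImage::closing(cand * 1, brush) > 0.5
    }
    comp <- EBImage::bwlabel(closed)
    areasPx <- tabulate(comp[comp > 0])
    pxArea <- masks@pixelSizeUm^2
    keep <- which(areasPx * pxArea >= minRegionAreaUm2)
    if (length(keep))
      necrotic <- matrix(comp %in% keep, nrow(cand), ncol(cand)) & masks@tissue
  }
  new("TissueMasks",
      background = masks@background, tissue = masks@tissue,
      positive = masks@positive, necrotic = necrotic,
      viable = masks@tissue & !necrotic, labels = masks@labels,
      pixelSizeUm = masks@pixelSizeUm)
}
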