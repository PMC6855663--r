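#' Positive-area fractions from segmented section masks
#'
#' Ki67 is quantified only in viable tumour: the percentage of the viable
#' area (necrosis excluded via the mask transferred from the trichrome
#' section) that is positively stained. Trichrome collagen is quantified
#' over the entire tumour tissue (background and artefacts excluded).
#' Areas are converted to mm^2 via each section's pixel size.
#'
#' @param ki67Masks [TissueMasks-class] of the Ki67 section whose
#'   `viable`/`necrotic` masks have been transferred from the trichrome
#'   section (see [analyzeSectionPair()]).
#' @param mtMasks [TissueMasks-class] of the trichrome section, after
#'   [segmentNecrosis()].
#' @return list with `ki67PercentViable`, `mtPercentWhole`,
#'   `viableAreaMm2`, `ki67TumourAreaMm2`, `mtTumourAreaMm2`,
#'   `necroticFractionMt`.
#' @export
quantifySections <- function(ki67Masks, mtMasks) {
  stopifnot(is(ki67Masks, "TissueMasks"), is(mtMasks, "TissueMasks"))
  mm2 <- function(npx, pixelSizeUm) npx * pixelSizeUm^2 * 1e-6
  nViable <- sum(ki67Masks@viable)
  if (nViable == 0) {
    warning("empty viable region on the Ki67 section; Ki67 percentage undefined",
            call. = FALSE)
    ki67Pct <- NA_real_
  } else {
    ki67Pct <- 100 * sum(ki67Masks@positive & ki67Masks@viable) / nViable
  }
  nTissueMt <- sum(mtMasks@tissue)
  list(
    ki67PercentViable = ki67Pct,
    mtPercentWhole = 100 * sum(mtMasks@positive) / nTissueMt,
    viableAreaMm2 = mm2(nViable, ki67Masks@pixelSizeUm),
    ki67TumourAreaMm2 = mm2(sum(ki67Masks@tissue), ki67Masks@pixelSizeUm),
    mtTumourAreaMm2 = mm2(nTissueMt, mtMasks@pixelSizeUm),
    necroticFractionMt = sum(mtMasks@necrotic) / nTissueMt)
}

#' End-to-end quantification of a registered section pair
#'
#' Runs the full digital-pathology chain on one trichrome / Ki67 section
#' pair: colour-threshold classification of both sections, necrosis
#' segmentation on the trichrome section, control-point registration
#' (trichrome as moving, Ki67 as fixed), transfer of the necrotic mask onto
#' the Ki67 raster, and positive-fraction quantification.
#'
#' @param mtSection trichrome [StainedSection-class].
#' @param ki67Section Ki67 [StainedSection-class].
#' @param controlPoints paired pixel coordinates, see [fitRegistration()].
#' @param model registration model, `"similarity"` (default) or `"affine"`.
#' @param thresholdsMT,thresholdsKi67 threshold lists
#'   ([defaultThresholds()]).
#' @param minRegionAreaUm2,closingRadiusPx passed to [segmentNecrosis()].
#' @return list with the [quantifySections()] results plus
#'   `registrationRmsPx`, the fitted `transform`, and both
#'   [TissueMasks-class] objects (`mtMasks`, `ki67Masks`).
#' @export
analyzeSectionPair <- function(mtSection, ki67Section, controlPoints,
                               model = c("similarity", "affine"),
                               thresholdsMT = defaultThresholds("MT"),
                               thresholdsKi67 = defaultThresholds("Ki67"),
                               minRegionAreaUm2 = 50, closingRadiusPx = 2) {
  stopifnot(mtSection@stain == "MT", ki67Section@stain == "Ki67")
  mtMasks <- segmentNecrosis(classifyPixels(mtSection, thresholdsMT),
                             minRegionAreaUm2 = minRegionAreaUm2,
                             closingRadiusPx = closingRadiusPx)
  kiMasks <- classifyPixels(ki67Section, thresholdsKi67)
  tf <- fitRegistration(controlPoints, model = match.arg(model))
  necroticOnKi <- transferMask(mtMasks@necrotic, tf,
                               targetShape = dim(ki67Section@image)[1:2])
  kiMasks <- new("TissueMasks",
                 background = kiMasks@background, tissue = kiMasks@tissue,
                 positive = kiMasks@positive,
                 necrotic = kiMasks@tissue & necroticOnKi,
                 viable = kiMasks@tissue & !necroticOnKi,
                 labels = kiMasks@labels, pixelSizeUm = kiMasks@pixelSizeUm)
  res <- quantifySections(kiMasks, mtMasks)
  c(res, list(registrationRmsPx = tf$rmsPx, transform = tf,
              mtMasks = mtMasks, ki67Masks = kiMasks))
}
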