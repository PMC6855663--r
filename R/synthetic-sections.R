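#' Layout for a synthetic stained-section pair
#'
#' Describes the synthetic tumour section rendered by
#' [renderSectionPair()]: canvas size, an elliptical tumour ROI, a necrotic
#' sub-region, target positive-pixel fractions for both stains, crack/fold
#' artefact counts, the similarity transform relating the Ki67 section to
#' the trichrome section, and rendering noise.
#'
#' @param canvasPx `c(height, width)` in pixels.
#' @param necroticFraction target necrotic fraction of tumour tissue.
#' @param ki67Fraction target Ki67-positive fraction of viable tissue.
#' @param mtFraction target collagen-positive fraction of tumour tissue.
#' @param crackCount,foldCount number of crack / fold artefacts.
#' @param rotationDeg,scale,translationPx similarity transform (trichrome
#'   frame to Ki67 frame) embedded in the pair.
#' @param noiseSd Gaussian rendering noise SD on each RGB channel.
#' @param pixelSizeUm pixel size in micrometres.
#' @return Layout list for [renderSectionPair()].
#' @export
sectionLayout <- function(canvasPx = c(200, 200), necroticFraction = 0.15,
                          ki67Fraction = 0.64, mtFraction = 0.03,
                          crackCount = 2, foldCount = 2, rotationDeg = 3,
                          scale = 1, translationPx = c(5, -3),
                          noiseSd = 0.012, pixelSizeUm = 0.25) {
  for (f in c(necroticFraction, ki67Fraction, mtFraction))
    stopIfNot(f >= 0 && f <= 1, "fractions must lie in [0, 1]")
  stopIfNot(all(canvasPx >= 48), "canvas must be at least 48 px")
  list(canvasPx = canvasPx, necroticFraction = necroticFraction,
       ki67Fraction = ki67Fraction, mtFraction = mtFraction,
       crackCount = crackCount, foldCount = foldCount,
       rotationDeg = rotationDeg, scale = scale,
       translationPx = translationPx, noiseSd = noiseSd,
       pixelSizeUm = pixelSizeUm)
}

## Similarity transform about the canvas centre plus a translation.
layoutTransform <- function(layout) {
  th <- layout$rotationDeg * pi / 180
  A <- layout$scale * matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  ctr <- rev(layout$canvasPx - 1) / 2  # (x, y)
  tvec <- ctr - as.numeric(A %*% ctr) + layout$translationPx
  structure(list(A = A, t = tvec, model = "similarity", n = NA_integer_,
                 rmsPx = 0), class = "sectionTransform")
}

#' Render a registered trichrome / Ki67 synthetic section pair
#'
#' Draws an elliptical tumour inside the canvas with a necrotic sub-region,
#' scatters collagen-positive pixels over the tumour tissue and
#' Ki67-positive pixels over viable tissue at the configured fractions,
#' adds near-white crack lines and dark fold blobs, and renders both stains
#' from the shared reference palette with Gaussian noise. The Ki67 section
#' is the same layout under the layout's similarity transform (resampled
#' nearest-neighbour), so the pair comes with exactly matching control
#' points and a ground-truth record of the achieved pixel fractions (the
#' achieved fractions can differ slightly from the requested ones because
#' regions are rasterised).
#'
#' @param layout a [sectionLayout()].
#' @param seed integer seed.
#' @param nControlPoints number of control-point pairs (>= 2).
#' @return list with `mt` and `ki67` ([StainedSection-class]),
#'   `controlPoints` (data.frame for [fitRegistration()]) and `truth`
#'   (achieved `ki67PercentViable`, `mtPercentWhole`, `necroticFraction`,
#'   and the embedded `transform`).
#' @export
renderSectionPair <- function(layout = sectionLayout(), seed = 1,
                              nControlPoints = 5) {
  pal <- stainPalette()
  h <- layout$canvasPx[1]; w <- layout$canvasPx[2]
  withSeed(seed, {
    ## Tumour ROI: ellipse with a safety margin so the transformed ROI
    ## stays on the canvas.
    cx <- (w - 1) / 2; cy <- (h - 1) / 2
    rx <- 0.36 * w; ry <- 0.33 * h
    ang <- seq(0, 2 * pi, length.out = 73)[-73]
    roi <- cbind(cx + rx * cos(ang), cy + ry * sin(ang))
    tissue0 <- rasterizePolygon(roi, c(h, w))

    labels <- matrix(0L, h, w)
    labels[tissue0] <- 3L  # viable counterstain by default

    ## Necrotic disc placed off-centre inside the tumour.
    if (layout$necroticFraction > 0) {
      area <- sum(tissue0)
      r <- sqrt(layout$necroticFraction * area / pi)
      ncx <- cx + runif(1, -0.2, 0.2) * rx
      ncy <- cy + runif(1, -0.2, 0.2) * ry
      xs <- matrix(rep(seq_len(w) - 1, each = h), h, w)
      ys <- matrix(rep(seq_len(h) - 1, times = w), h, w)
      disc <- (xs - ncx)^2 + (ys - ncy)^2 <= r^2
      labels[disc & tissue0] <- 5L
    }

    ## Cracks: thin near-white lines through the tissue.
    xs <- matrix(rep(seq_len(w) - 1, each = h), h, w)
    ys <- matrix(rep(seq_len(h) - 1, times = w), h, w)
    for (k in seq_len(layout$crackCount)) {
      th <- runif(1, 0, pi)
      off <- runif(1, -0.5, 0.5) * min(rx, ry)
      d <- (xs - cx) * sin(th) - (ys - cy) * cos(th) - off
      labels[abs(d) <= 1 & tissue0] <- 1L
    }
    ## Folds: small over-dark blobs.
    for (k in seq_len(layout$foldCount)) {
      fx <- cx + runif(1, -0.6, 0.6) * rx
      fy <- cy + runif(1, -0.6, 0.6) * ry
      fr <- runif(1, 2, 4)
      labels[(xs - fx)^2 + (ys - fy)^2 <= fr^2 & tissue0] <- 2L
    }

    ## Positive pixels: collagen over tumour tissue, Ki67 over viable.
    tissueIdx <- which(labels == 3L | labels == 5L)
    viableIdx <- which(labels == 3L)
    mtPosIdx <- sample(viableIdx,
                       min(round(layout$mtFraction * length(tissueIdx)),
                           length(viableIdx)))
    ki67PosIdx <- sample(viableIdx,
                         round(layout$ki67Fraction * length(viableIdx)))
    labelsMT <- labels; labelsMT[mtPosIdx] <- 4L
    labelsKi <- labels; labelsKi[ki67PosIdx] <- 4L

    renderFrom <- function(lab, colours) {
      img <- array(0, dim = c(h, w, 3))
      for (cls in names(colours)) {
        idx <- which(lab == as.integer(cls))
        for (ch in 1:3) {
          plane <- img[, , ch]
          plane[idx] <- colours[[cls]][ch]
          img[, , ch] <- plane
        }
      }
      img <- img + array(rnorm(length(img), 0, layout$noiseSd), dim = dim(img))
      pmin(pmax(img, 0), 1)
    }
    mtColours <- list(`0` = pal$background, `1` = pal$background,
                      `2` = pal$fold, `3` = pal$mtCounter,
                      `4` = pal$mtPositive, `5` = pal$necrosis)
    kiColours <- list(`0` = pal$background, `1` = pal$background,
                      `2` = pal$fold, `3` = pal$ki67Counter,
                      `4` = pal$ki67Positive, `5` = pal$necrosis)
    mtImg <- renderFrom(labelsMT, mtColours)

    ## Ki67 frame: same layout under the embedded similarity transform.
    tf <- layoutTransform(layout)
    inv <- invertTransform(tf)
    src <- applyTransform(inv, cbind(as.vector(xs), as.vector(ys)))
    xi <- round(src[, 1]); yi <- round(src[, 2])
    ok <- xi >= 0 & xi < w & yi >= 0 & yi < h
    labKiFixed <- matrix(0L, h, w)
    labKiFixed[cbind(as.vector(ys), as.vector(xs))[ok, , drop = FALSE] + 1L] <-
      labelsKi[cbind(yi, xi)[ok, , drop = FALSE] + 1L]
    kiImg <- renderFrom(labKiFixed, kiColours)

    roiKi <- applyTransform(tf, roi)
    roiKi[, 1] <- pmin(pmax(roiKi[, 1], 0), w - 1)
    roiKi[, 2] <- pmin(pmax(roiKi[, 2], 0), h - 1)

    ## Control points: centre plus points on the ROI ellipse, mapped
    ## exactly through the embedded transform.
    angCp <- seq(0, 2 * pi, length.out = nControlPoints)[-nControlPoints]
    mv <- rbind(c(cx, cy),
                cbind(cx + 0.9 * rx * cos(angCp), cy + 0.9 * ry * sin(angCp)))
    mv <- mv[seq_len(nControlPoints), , drop = FALSE]
    fx <- applyTransform(tf, mv)
    controlPoints <- data.frame(x_moving = mv[, 1], y_moving = mv[, 2],
                                x_fixed = fx[, 1], y_fixed = fx[, 2])

    nTissue <- length(tissueIdx)
    nViableKi <- sum(labKiFixed == 3L | labKiFixed == 4L)
    truth <- list(
      ki67PercentViable = 100 * length(ki67PosIdx) / length(viableIdx),
      mtPercentWhole = 100 * length(mtPosIdx) / nTissue,
      necroticFraction = sum(labels == 5L) / nTissue,
      transform = tf)

    list(mt = stainedSection(mtImg, "MT", roi, layout$pixelSizeUm),
         ki67 = stainedSection(kiImg, "Ki67", roiKi, layout$pixelSizeUm),
         controlPoints = controlPoints, truth = truth)
  })
}
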