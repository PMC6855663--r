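## Small hand-built section: a rectangle of counterstain with an optional
## patch of another palette colour, inside a rectangular ROI.
patchSection <- function(stain, patchColour = NULL, base = NULL,
                         n = 40, patchRows = 11:20) {
  pal <- radiosynergy:::stainPalette()
  base <- base %||% if (stain == "MT") pal$mtCounter else pal$ki67Counter
  img <- array(rep(rep(base, each = n * n)), dim = c(n, n, 3))
  if (!is.null(patchColour))
    for (ch in 1:3) img[patchRows, , ch] <- patchColour[ch]
  roi <- cbind(c(2, n - 3, n - 3, 2), c(2, 2, n - 3, n - 3))
  stainedSection(img, stain, roi)
}

test_that("a uniform near-white section yields the empty-tissue error", {
  pal <- radiosynergy:::stainPalette()
  sec <- patchSection("Ki67", base = pal$background)
  expect_error(classifyPixels(sec), "zero tissue")
})

test_that("a pure DAB patch on counterstain is labelled positive, rest negative", {
  pal <- radiosynergy:::stainPalette()
  sec <- patchSection("Ki67", patchColour = pal$ki67Positive)
  masks <- classifyPixels(sec)
  expect_true(validObject(masks))
  inroi <- masks@labels > 0
  expect_true(all(masks@positive[11:20, 4:38]))
  expect_false(any(masks@positive[22:36, ]))
  expect_true(all(masks@tissue[inroi]))  # no artefacts in this fixture
})

test_that("synthetic sections recover a 40% positive layout within 2 points", {
  pair <- renderSectionPair(sectionLayout(ki67Fraction = 0.40,
                                          necroticFraction = 0),
                            seed = 40)
  masks <- classifyPixels(pair$ki67)
  measured <- 100 * sum(masks@positive) / sum(masks@viable)
  expect_lt(abs(measured - pair$truth$ki67PercentViable), 2)
})

test_that("mask partition invariants hold after classification and necrosis segmentation", {
  pair <- renderSectionPair(sectionLayout(necroticFraction = 0.3), seed = 6)
  masks <- classifyPixels(pair$mt)
  expect_true(validObject(masks))
  seg <- segmentNecrosis(masks)
  expect_true(validObject(seg))
  expect_identical(seg@necrotic | seg@viable, seg@tissue)
  expect_false(any(seg@necrotic & seg@viable))
})

test_that("necrosis segmentation recovers a 30%-area region and ignores speckles", {
  ## no necrosis at all
  pair0 <- renderSectionPair(sectionLayout(necroticFraction = 0), seed = 2)
  seg0 <- segmentNecrosis(classifyPixels(pair0$mt))
  expect_equal(sum(seg0@necrotic), 0)
  expect_identical(seg0@viable, seg0@tissue)
  ## one 30% disc
  pair <- renderSectionPair(sectionLayout(necroticFraction = 0.3), seed = 12)
  seg <- segmentNecrosis(classifyPixels(pair$mt))
  frac <- sum(seg@necrotic) / sum(seg@tissue)
  expect_lt(abs(frac - pair$truth$necroticFraction), 0.02)
  ## speckles below the area threshold are absorbed into viable tissue
  masks <- classifyPixels(pair0$mt)
  lab <- masks@labels
  tissueIdx <- which(lab == 3L)
  lab[sample(tissueIdx, 5)] <- 5L  # isolated single-pixel speckles
  speck <- new("TissueMasks", background = masks@background,
               tissue = masks@tissue, positive = masks@positive,
               necrotic = masks@necrotic, viable = masks@viable,
               labels = lab, pixelSizeUm = masks@pixelSizeUm)
  segS <- segmentNecrosis(speck, minRegionAreaUm2 = 50, closingRadiusPx = 0)
  expect_equal(sum(segS@necrotic), 0)
})

test_that("registration recovers identity, translation and rotation exactly", {
  pts <- data.frame(x_moving = c(10, 50, 10, 60), y_moving = c(10, 10, 60, 50))
  ## identity
  idPts <- cbind(pts, x_fixed = pts$x_moving, y_fixed = pts$y_moving)
  tf <- fitRegistration(idPts)
  expect_equal(tf$A, diag(2), tolerance = 1e-12)
  expect_equal(tf$t, c(0, 0), tolerance = 1e-12)
  expect_equal(tf$rmsPx, 0, tolerance = 1e-12)
  ## pure translation (+10, -5)
  trPts <- cbind(pts, x_fixed = pts$x_moving + 10, y_fixed = pts$y_moving - 5)
  tf <- fitRegistration(trPts)
  expect_equal(tf$A, diag(2), tolerance = 1e-12)
  expect_equal(tf$t, c(10, -5), tolerance = 1e-12)
  ## 30-degree rotation about the centroid
  th <- 30 * pi / 180
  ctr <- colMeans(pts)
  rot <- t(apply(pts, 1, function(p) {
    d <- p - ctr
    ctr + c(cos(th) * d[1] - sin(th) * d[2], sin(th) * d[1] + cos(th) * d[2])
  }))
  roPts <- cbind(pts, x_fixed = rot[, 1], y_fixed = rot[, 2])
  tf <- fitRegistration(roPts)
  expect_lt(abs(atan2(tf$A[2, 1], tf$A[1, 1]) - th), 1e-6)
  expect_lt(tf$rmsPx, 1e-9)
  ## affine needs non-collinear points
  bad <- data.frame(x_moving = 1:3, y_moving = 2 * (1:3),
                    x_fixed = 1:3, y_fixed = 2 * (1:3))
  expect_error(fitRegistration(bad, model = "affine"), "collinear")
})

test_that("mask transfer is nearest-neighbour, binary, and handles out-of-frame", {
  mask <- matrix(FALSE, 20, 20)
  mask[5:10, 5:10] <- TRUE
  id <- fitRegistration(data.frame(x_moving = c(0, 19, 0), y_moving = c(0, 0, 19),
                                   x_fixed = c(0, 19, 0), y_fixed = c(0, 0, 19)))
  expect_identical(transferMask(mask, id), mask)
  ## translation by (+3, +2): mask shifts by exactly that offset
  tr <- fitRegistration(data.frame(x_moving = c(0, 19, 0), y_moving = c(0, 0, 19),
                                   x_fixed = c(3, 22, 3), y_fixed = c(2, 2, 21)))
  shifted <- transferMask(mask, tr)
  expect_true(all(shifted[(5:10) + 2, (5:10) + 3]))
  expect_equal(sum(shifted), sum(mask))
  ## pushed partially out of frame: retained area equals the overlap
  full <- matrix(TRUE, 20, 20)
  tr2 <- fitRegistration(data.frame(x_moving = c(0, 19, 0), y_moving = c(0, 0, 19),
                                    x_fixed = c(15, 34, 15), y_fixed = c(0, 0, 19)))
  out <- transferMask(full, tr2)
  expect_equal(sum(out), 20 * 5)  # only columns 15..19 remain in frame
})

test_that("quantification returns 100% when positive fills viable and flags empty viable", {
  pal <- radiosynergy:::stainPalette()
  sec <- patchSection("Ki67", patchColour = pal$ki67Positive,
                      patchRows = 3:37)
  masks <- classifyPixels(sec)
  res <- quantifySections(masks, masks)
  expect_equal(res$ki67PercentViable, 100)
  empty <- new("TissueMasks",
               background = masks@background, tissue = masks@tissue,
               positive = masks@positive,
               necrotic = masks@tissue, viable = masks@tissue & FALSE,
               labels = masks@labels, pixelSizeUm = masks@pixelSizeUm)
  expect_warning(resE <- quantifySections(empty, masks), "empty viable")
  expect_true(is.na(resE$ki67PercentViable))
})

test_that("quantification is stable under a different embedded similarity transform", {
  l1 <- sectionLayout(ki67Fraction = 0.5, mtFraction = 0.05,
                      rotationDeg = 0, translationPx = c(0, 0))
  l2 <- sectionLayout(ki67Fraction = 0.5, mtFraction = 0.05,
                      rotationDeg = 7, scale = 0.97, translationPx = c(-6, 4))
  r1 <- suppressWarnings(with(renderSectionPair(l1, seed = 9),
                              analyzeSectionPair(mt, ki67, controlPoints)))
  r2 <- suppressWarnings(with(renderSectionPair(l2, seed = 9),
                              analyzeSectionPair(mt, ki67, controlPoints)))
  expect_lt(abs(r1$ki67PercentViable - r2$ki67PercentViable), 1.5)
  expect_lt(abs(r1$mtPercentWhole - r2$mtPercentWhole), 1)
})

test_that("positive fractions of zero are recovered as zero", {
  pair <- renderSectionPair(sectionLayout(ki67Fraction = 0, mtFraction = 0),
                            seed = 5)
  res <- suppressWarnings(
    analyzeSectionPair(pair$mt, pair$ki67, pair$controlPoints))
  expect_lt(res$ki67PercentViable, 0.5)
  expect_lt(res$mtPercentWhole, 0.5)
})
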