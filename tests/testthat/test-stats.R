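test_that("one-way ANOVA matches the hand-computed table and base R", {
  av <- oneWayAnova(list(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(av$F, 0); expect_equal(av$p, 1)
  av <- oneWayAnova(list(c(1, 2), c(3, 4)))
  expect_equal(av$F, 8)  # MS_b = 4, MS_w = 0.5, df (1, 2)
  expect_equal(av$p, pf(8, 1, 2, lower.tail = FALSE))
  ## cross-check against aov() on random data
  set.seed(8)
  for (i in 1:10) {
    k <- sample(2:4, 1)
    samp <- lapply(seq_len(k), function(j) rnorm(sample(3:8, 1), mean = j / 2))
    av <- oneWayAnova(samp)
    y <- unlist(samp)
    gr <- factor(rep(seq_len(k), lengths(samp)))
    ref <- summary(aov(y ~ gr))[[1]]
    expect_equal(av$F, ref[["F value"]][1], tolerance = 1e-10)
    expect_equal(av$p, ref[["Pr(>F)"]][1], tolerance = 1e-10)
  }
  expect_error(oneWayAnova(list(1, 2)), "degrees of freedom")
})

test_that("pooled and Welch t-tests match the hand computation and t.test", {
  tt <- twoSampleT(c(1, 2, 3), c(1, 2, 3))
  expect_equal(tt$t, 0); expect_equal(tt$p, 1)
  tt <- twoSampleT(c(1, 2, 3), c(2, 3, 4))
  expect_equal(tt$t, -1.224745, tolerance = 1e-6)
  expect_equal(tt$df, 4)
  expect_equal(tt$p, 0.2878641, tolerance = 1e-6)
  set.seed(9)
  for (i in 1:10) {
    a <- rnorm(sample(3:9, 1)); b <- rnorm(sample(3:9, 1), 0.5)
    tp <- twoSampleT(a, b, equalVar = TRUE)
    rp <- t.test(a, b, var.equal = TRUE)
    expect_equal(tp$t, unname(rp$statistic), tolerance = 1e-10)
    expect_equal(tp$p, rp$p.value, tolerance = 1e-10)
    tw <- twoSampleT(a, b, equalVar = FALSE)
    rw <- t.test(a, b)
    expect_equal(tw$t, unname(rw$statistic), tolerance = 1e-10)
    expect_equal(tw$df, unname(rw$parameter), tolerance = 1e-10)
  }
})

test_that("zero-variance input follows the continuity conventions", {
  expect_warning(tt <- twoSampleT(c(1, 1), c(2, 2)), "infinite")
  expect_equal(tt$p, 0); expect_equal(tt$t, -Inf)
  expect_warning(av <- oneWayAnova(list(c(1, 1), c(2, 2))), "infinite")
  expect_equal(av$p, 0)
})

test_that("ANOVA with two groups satisfies F = t^2 to machine precision", {
  set.seed(17)
  for (i in 1:25) {
    a <- rnorm(sample(2:10, 1)); b <- rnorm(sample(2:10, 1), 1)
    av <- oneWayAnova(list(a, b))
    tt <- twoSampleT(a, b, equalVar = TRUE)
    expect_equal(av$F, tt$t^2, tolerance = 1e-12)
    expect_equal(av$p, tt$p, tolerance = 1e-12)
  }
})

test_that("Holm adjustment matches the step-down definition and its examples", {
  expect_equal(holmAdjust(0.03), 0.03)
  expect_equal(holmAdjust(c(0.01, 0.02, 0.03)), c(0.03, 0.04, 0.04))
  expect_equal(holmAdjust(c(0.5, 0.5)), c(1, 1))
  expect_error(holmAdjust(c(0.5, 1.2)), "\\[0, 1\\]")
  ## permutation equivariance
  set.seed(3)
  p <- runif(7)
  perm <- sample(7)
  expect_equal(holmAdjust(p)[perm], holmAdjust(p[perm]))
  ## agreement with stats::p.adjust as an independent implementation
  for (i in 1:50) {
    p <- runif(sample(1:10, 1))
    expect_equal(holmAdjust(p), p.adjust(p, method = "holm"))
  }
})

test_that("Holm is never more conservative than Bonferroni and dominates raw p", {
  set.seed(4)
  for (i in 1:50) {
    p <- runif(sample(2:10, 1))
    adj <- holmAdjust(p)
    expect_true(all(adj <= pmin(1, length(p) * p) + 1e-15))
    expect_true(all(adj >= p))
    expect_true(all(adj <= 1))
  }
})

test_that("per-day comparisons produce coherent Holm families", {
  co <- simulateGrowthCohort(growthPreset("reference"), seed = 3)
  tab <- groupComparisons(co)
  expect_true(all(c("day", "comparison", "statistic", "raw_p", "adjusted_p",
                    "significant") %in% names(tab)))
  expect_true(all(tab$adjusted_p >= tab$raw_p - 1e-15))
  ## every analysed day carries one ANOVA row and all 6 pairwise rows
  for (d in unique(tab$day)) {
    rows <- tab[tab$day == d, ]
    expect_equal(sum(rows$comparison == "anova"), 1)
    expect_equal(sum(rows$comparison != "anova"), choose(4, 2))
    ## per-day family: the pairwise adjustment is self-contained
    pw <- rows[rows$comparison != "anova", ]
    expect_equal(pw$adjusted_p, holmAdjust(pw$raw_p))
  }
  ## all-days family adjusts the pooled pairwise family
  tabAll <- groupComparisons(co, family = "all-days")
  pwAll <- tabAll[tabAll$comparison != "anova", ]
  expect_equal(pwAll$adjusted_p, holmAdjust(pwAll$raw_p))
})
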