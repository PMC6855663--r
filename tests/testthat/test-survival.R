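## Cohort with one animal whose RTV trace is prescribed exactly.
cohortFromRTV <- function(rtv, days, fate = "followed-to-end",
                          fateDay = max(days)) {
  cohortFromVolumes(list(300 * rtv), days = days,
                    fates = data.frame(animal_id = "a01", fate = fate,
                                       fate_day = fateDay))
}

test_that("progression is the first RTV > 1 at or after the nadir", {
  ## initial response, then regrowth past baseline
  r <- detectProgression(cohortFromRTV(c(1, 0.8, 0.9, 1.1), c(0, 3, 7, 10)))
  expect_equal(r$time, 10); expect_true(r$event)
  ## monotone growth: first day above baseline
  r <- detectProgression(cohortFromRTV(c(1, 1.2, 1.5), c(0, 3, 7)))
  expect_equal(r$time, 3); expect_true(r$event)
  ## never exceeds baseline: censored at end of follow-up
  r <- detectProgression(cohortFromRTV(c(1, 0.7, 0.6), c(0, 3, 7),
                                       fateDay = 16))
  expect_equal(r$time, 16); expect_false(r$event)
  ## a transient blip before the nadir does not count
  r <- detectProgression(cohortFromRTV(c(1, 1.2, 0.8, 0.9, 1.3),
                                       c(0, 3, 7, 10, 14)))
  expect_equal(r$time, 14); expect_true(r$event)
})

test_that("animals killed before progressing are events at the kill day", {
  r <- detectProgression(cohortFromRTV(c(1, 0.7, 0.6), c(0, 3, 7),
                                       fate = "killed", fateDay = 9))
  expect_equal(r$time, 9); expect_true(r$event)
})

test_that("progression detection is invariant to volume rescaling", {
  rtv <- c(1, 0.9, 0.95, 1.2)
  d <- c(0, 3, 7, 10)
  r1 <- detectProgression(cohortFromVolumes(list(250 * rtv), days = d))
  r2 <- detectProgression(cohortFromVolumes(list(1900 * rtv), days = d))
  expect_equal(r1$time, r2$time)
  expect_equal(r1$event, r2$event)
})

test_that("product-limit estimator matches the hand-computed examples", {
  cv <- kmEstimator(c(3, 7, 10), c(TRUE, TRUE, TRUE))
  expect_equal(cv@survival, c(2 / 3, 1 / 3, 0))
  cv <- kmEstimator(c(4, 9), c(FALSE, FALSE))
  expect_equal(cv@survival, c(1, 1))
  cv <- kmEstimator(c(3, 5, 7), c(TRUE, FALSE, TRUE))
  expect_equal(cv@survival[cv@time == 3], 2 / 3)
  expect_equal(cv@survival[cv@time == 7], 0)  # risk set shrank 3 -> 1
})

test_that("with no censoring the estimator equals 1 - ECDF of event times", {
  set.seed(21)
  for (i in 1:10) {
    tt <- sample(1:15, 8, replace = TRUE)
    cv <- kmEstimator(tt, rep(TRUE, 8))
    ecdfS <- 1 - ecdf(tt)(cv@time)
    expect_equal(cv@survival, ecdfS, tolerance = 1e-12)
  }
})

test_that("a censored observation later than all events leaves the curve unchanged before it", {
  cv1 <- kmEstimator(c(2, 5, 8), c(TRUE, TRUE, TRUE))
  cv2 <- kmEstimator(c(2, 5, 8, 12), c(TRUE, TRUE, TRUE, FALSE))
  keep <- cv2@time <= 8
  expect_equal(cv2@time[keep], cv1@time)
  ## risk sets grow by one, so recompute the expectation directly
  expect_equal(cv2@survival[keep], cumprod(1 - 1 / c(4, 3, 2)))
})

test_that("estimator agrees with the survival package on random censored samples", {
  skip_if_not_installed("survival")
  set.seed(33)
  for (i in 1:20) {
    n <- sample(3:12, 1)
    tt <- sample(1:10, n, replace = TRUE)
    ev <- runif(n) < 0.7
    if (!any(ev)) ev[1] <- TRUE
    cv <- kmEstimator(tt, ev)
    sf <- survival::survfit(survival::Surv(tt, ev) ~ 1)
    expect_equal(cv@survival[match(sf$time, cv@time)], sf$surv,
                 tolerance = 1e-12)
  }
})

test_that("median time to progression is the first crossing of 0.5", {
  expect_equal(medianTTP(new("SurvivalCurve", time = 3, survival = 0.4,
                             nRisk = 5, nEvent = 3, nCensor = 0)), 3)
  expect_true(is.na(suppressMessages(
    medianTTP(new("SurvivalCurve", time = 3, survival = 0.6, nRisk = 5,
                  nEvent = 2, nCensor = 0)))))
  cv <- kmEstimator(c(3, 7, 10), c(TRUE, TRUE, TRUE))
  expect_equal(medianTTP(cv), 7)  # S(3) = 2/3 > 0.5, S(7) = 1/3
})

test_that("an animal with no post-baseline visits is censored at day 0 with a warning", {
  co <- cohortFromVolumes(list(500), days = 0)
  expect_warning(r <- detectProgression(co), "post-baseline")
  expect_equal(r$time, 0); expect_false(r$event)
})
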