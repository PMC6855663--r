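#' Treatment-arm specification for the growth simulator
#'
#' One arm of a simulated combination-therapy study. The underlying
#' kinetic model is two-compartment: a surviving fraction `fsRad` of the
#' tumour keeps growing exponentially after irradiation while the
#' complement regresses at `regressionRate`; an untreated arm is
#' `fsRad = 1`. Drug (gemcitabine-like) treatment multiplies the net
#' growth rate by `gemMultiplier` for the whole tumour during the dosing
#' window, so that radiation and drug act independently
#' (multiplicatively) on volume. On a combination arm the interaction
#' multiplier `iota` scales the surviving fraction: `iota = 1` keeps the
#' two effects exactly independent in the noiseless mean (the
#' Bliss-independent reference case), `iota < 1` injects extra radiation
#' kill, i.e. synergy.
#'
#' @param name arm label.
#' @param n number of animals.
#' @param followUpDays last scheduled visit day for the arm.
#' @param fsRad radiation surviving fraction in (0, 1].
#' @param regressionRate regression rate (1/day) of the killed compartment.
#' @param gemMultiplier growth-rate multiplier during the dosing window
#'   (1 = no drug, 0 = growth arrest).
#' @param iota interaction multiplier on the surviving fraction.
#' @return Named list describing the arm.
#' @export
armSpec <- function(name, n, followUpDays, fsRad = 1, regressionRate = 0.10,
                    gemMultiplier = 1, iota = 1) {
  stopIfNot(fsRad > 0 && fsRad <= 1, "fsRad must lie in (0, 1]")
  stopIfNot(fsRad * iota > 0 && fsRad * iota <= 1,
            "fsRad * iota must lie in (0, 1]")
  stopIfNot(n >= 1, "n must be >= 1")
  list(name = name, n = n, followUpDays = followUpDays, fsRad = fsRad,
       regressionRate = regressionRate, gemMultiplier = gemMultiplier,
       iota = iota)
}

#' Growth-simulator configuration
#'
#' Study-level parameters for [simulateGrowthCohort()]. Defaults emulate a
#' subcutaneous xenograft study: baseline volumes lognormal with arithmetic
#' mean 570 and SD 406 mm^3, control-arm exponential growth at 0.052/day,
#' twice-weekly calliper visits, lognormal measurement noise with 10% CV,
#' drug dosing over days 0-13, and a humane-endpoint volume cap.
#'
#' @param arms list of [armSpec()] entries.
#' @param controlArm label of the untreated arm.
#' @param growthRate exponential growth rate g (1/day) of untreated tumour.
#' @param baselineMeanMm3,baselineSdMm3 arithmetic mean / SD of the
#'   lognormal baseline-volume distribution (mm^3).
#' @param noiseCv lognormal measurement-noise coefficient of variation.
#' @param gemWindowDays end of the drug dosing window (days; window starts
#'   at day 0).
#' @param schedule visit days; default twice weekly (alternating +3/+4)
#'   from 0 to the longest follow-up.
#' @param killVolumeMm3 humane-endpoint volume cap (mm^3).
#' @param weightLossHazardPerDay daily hazard of a weight-loss kill.
#' @param interactionArms optional named list (`rad`, `gem`, `combo`)
#'   mapping arms to their roles in the Bliss analysis.
#' @return Config list for [simulateGrowthCohort()].
#' @export
growthConfig <- function(arms, controlArm, growthRate = 0.052,
                         baselineMeanMm3 = 570, baselineSdMm3 = 406,
                         noiseCv = 0.10, gemWindowDays = 13,
                         schedule = NULL, killVolumeMm3 = 4000,
                         weightLossHazardPerDay = 0,
                         interactionArms = NULL) {
  names(arms) <- vapply(arms, `[[`, character(1), "name")
  stopIfNot(controlArm %in% names(arms), "controlArm must be one of the arms")
  if (!is.null(interactionArms)) {
    bad <- setdiff(unlist(interactionArms), names(arms))
    if (length(bad))
      stop("interactionArms reference unknown arms: ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  stopIfNot(noiseCv >= 0, "noiseCv must be >= 0")
  if (is.null(schedule)) {
    maxDay <- max(vapply(arms, `[[`, numeric(1), "followUpDays"))
    schedule <- c(0, cumsum(rep(c(3, 4), length.out = 2 * ceiling(maxDay / 7))))
    schedule <- schedule[schedule <= maxDay]
  }
  list(arms = arms, controlArm = controlArm, growthRate = growthRate,
       baselineMeanMm3 = baselineMeanMm3, baselineSdMm3 = baselineSdMm3,
       noiseCv = noiseCv, gemWindowDays = gemWindowDays, schedule = schedule,
       killVolumeMm3 = killVolumeMm3,
       weightLossHazardPerDay = weightLossHazardPerDay,
       interactionArms = interactionArms)
}

#' Preset growth-simulator configurations
#'
#' Three shipped study designs. `"reference"` emulates a four-arm
#' radiation + gemcitabine xenograft study (untreated control n = 12,
#' radiation monotherapy n = 5 with surviving fraction 0.22, drug
#' monotherapy n = 10 with growth arrest during dosing, combination n = 6
#' with independent effects). `"strong-synergy"` is the same design with
#' interaction multiplier 0.3 on the combination arm. `"null"` has four
#' arms of untreated animals (n = 6 each) for false-positive-rate checks.
#'
#' @param name preset name.
#' @param nPerArm optional integer overriding every arm's sample size.
#' @return A [growthConfig()] list.
#' @export
growthPreset <- function(name = c("reference", "null", "strong-synergy"),
                         nPerArm = NULL) {
  name <- match.arg(name)
  cfg <- switch(name,
    "reference" = , "strong-synergy" = {
      iota <- if (name == "strong-synergy") 0.3 else 1
      growthConfig(
        arms = list(
          armSpec("control", n = 12, followUpDays = 30),
          armSpec("rad", n = 5, followUpDays = 44, fsRad = 0.22),
          armSpec("gem", n = 10, followUpDays = 44, gemMultiplier = 0),
          armSpec("rad_gem", n = 6, followUpDays = 58, fsRad = 0.22,
                  gemMultiplier = 0, iota = iota)),
        controlArm = "control",
        interactionArms = list(rad = "rad", gem = "gem", combo = "rad_gem"))
    },
    "null" = growthConfig(
      arms = list(
        armSpec("control", n = 6, followUpDays = 30),
        armSpec("arm_a", n = 6, followUpDays = 30),
        armSpec("arm_b", n = 6, followUpDays = 30),
        armSpec("arm_c", n = 6, followUpDays = 30)),
      controlArm = "control"))
  if (!is.null(nPerArm))
    cfg$arms <- lapply(cfg$arms, function(a) { a$n <- nPerArm; a })
  cfg
}

## Noiseless model RTV for one arm at times t (vectorised).
modelRTV <- function(t, cfg, arm) {
  g <- cfg$growthRate
  fs <- arm$fsRad * arm$iota
  gemFactor <- exp(g * (arm$gemMultiplier - 1) * pmin(t, cfg$gemWindowDays))
  (fs * exp(g * t) + (1 - fs) * exp(-arm$regressionRate * t)) * gemFactor
}

#' Simulate a calliper-measured cohort with known ground truth
#'
#' Generates a [TumourCohort-class] under the two-compartment kinetic model
#' described in [armSpec()]: per animal, a lognormal baseline volume, the
#' noiseless model volume at each scheduled visit, multiplied by lognormal
#' measurement noise, re-expressed as a calliper length/width/height triple
#' whose ellipsoid product reproduces the volume exactly (anisotropy jitter
#' is bounded and volume-preserving). Humane-endpoint rules are applied:
#' an animal is killed at the first visit whose measured volume exceeds the
#' volume cap, or by a random daily weight-loss hazard; later visits are
#' dropped and the fate recorded. Output is byte-identical for a fixed
#' (config, seed) pair.
#'
#' @param config a [growthConfig()] list.
#' @param seed integer seed; all randomness derives from it.
#' @return A [TumourCohort-class].
#' @examples
#' cohort <- simulateGrowthCohort(growthPreset("reference"), seed = 1)
#' cohort
#' @export
simulateGrowthCohort <- function(config, seed) {
  withSeed(seed, {
    sdlogNoise <- sqrt(log(1 + config$noiseCv^2))
    cvB <- config$baselineSdMm3 / config$baselineMeanMm3
    sdlogB <- sqrt(log(1 + cvB^2))
    meanlogB <- log(config$baselineMeanMm3) - sdlogB^2 / 2
    meas <- list(); fate <- list()
    for (arm in config$arms) {
      days <- config$schedule[config$schedule <= arm$followUpDays]
      for (i in seq_len(arm$n)) {
        id <- sprintf("%s_%02d", arm$name, i)
        v0 <- rlnorm(1, meanlogB, sdlogB)
        true <- v0 * modelRTV(days, config, arm)
        eps <- if (config$noiseCv > 0)
          rlnorm(length(days), -sdlogNoise^2 / 2, sdlogNoise) else rep(1, length(days))
        vol <- true * eps
        vol[1] <- v0 * eps[1]  # day 0 baseline (modelRTV(0) == 1)
        animalFate <- "followed-to-end"; fateDay <- max(days)
        overCap <- which(vol > config$killVolumeMm3 & days > 0)
        keep <- seq_along(days)
        if (length(overCap)) {
          keep <- seq_len(min(overCap))
          animalFate <- "killed"; fateDay <- days[min(overCap)]
        }
        if (config$weightLossHazardPerDay > 0) {
          pDie <- 1 - exp(-config$weightLossHazardPerDay * diff(days))
          hit <- which(runif(length(pDie)) < pDie)
          if (length(hit) && (min(hit) + 1) <= max(keep)) {
            keep <- seq_len(min(hit) + 1)
            animalFate <- "killed"; fateDay <- days[min(hit) + 1]
          }
        }
        days_i <- days[keep]; vol_i <- vol[keep]
        base <- (6 * vol_i / pi)^(1 / 3)
        j1 <- runif(length(base), 0.9, 1.1)
        j2 <- runif(length(base), 0.9, 1.1)
        meas[[id]] <- data.frame(
          animal_id = id, group = arm$name, day = days_i,
          length_mm = base * j1, width_mm = base * j2,
          height_mm = base / (j1 * j2), stringsAsFactors = FALSE)
        fate[[id]] <- data.frame(animal_id = id, fate = animalFate,
                                 fate_day = fateDay, stringsAsFactors = FALSE)
      }
    }
    TumourCohort(do.call(rbind, meas), controlGroup = config$controlArm,
                 fates = do.call(rbind, fate))
  })
}
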