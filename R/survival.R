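#' Detect tumour progression per animal
#'
#' Applies the progression rule used for progression-free survival: a tumour
#' has progressed on the first measurement day (after day 0) on which its
#' relative tumour volume exceeds 1, evaluated at or after the RTV nadir so
#' that an initial treatment response is allowed to run its course before
#' regrowth counts. For tumours that never shrink below baseline the rule
#' reduces to the first day with RTV > 1. Animals killed before reaching
#' that day are counted as progression events on their kill day; animals
#' that never progress are censored at the end of their follow-up.
#'
#' @param cohort a [TumourCohort-class].
#' @param rtvs optional precomputed output of [relativeVolumes()].
#' @return data.frame with columns `animal_id`, `group`, `time` (days) and
#'   `event` (`TRUE` = progressed or killed, `FALSE` = censored).
#' @export
detectProgression <- function(cohort, rtvs = relativeVolumes(cohort)) {
  stopifnot(is(cohort, "TumourCohort"))
  f <- fates(cohort)
  out <- do.call(rbind, lapply(split(rtvs, rtvs$animal_id), function(ri) {
    ri <- ri[!is.na(ri$rtv), ]
    fi <- f[f$animal_id == ri$animal_id[1], ]
    post <- ri[ri$day > 0, , drop = FALSE]
    if (!nrow(post)) {
      warning(sprintf("animal '%s' has no post-baseline measurements; censored at day 0",
                      ri$animal_id[1]), call. = FALSE)
      return(data.frame(animal_id = ri$animal_id[1], group = ri$group[1],
                        time = 0, event = FALSE))
    }
    nadirDay <- ri$day[which.min(ri$rtv)]
    cand <- post$day[post$rtv > 1 & post$day >= nadirDay]
    if (length(cand)) {
      time <- min(cand); event <- TRUE
    } else if (fi$fate == "killed") {
      time <- fi$fate_day; event <- TRUE
    } else {
      time <- fi$fate_day; event <- FALSE
    }
    data.frame(animal_id = ri$animal_id[1], group = ri$group[1],
               time = time, event = event)
  }))
  rownames(out) <- NULL
  out
}

#' Kaplan-Meier product-limit estimator
#'
#' Estimates the survivor (progression-free) function from right-censored
#' times. At each distinct observed time the risk set includes every animal
#' whose time is >= that time, so on tied event/censoring times the events
#' are counted first and the censored animals leave the risk set afterwards.
#'
#' @param time observed times (> 0), one per animal.
#' @param event logical; `TRUE` for a progression event, `FALSE` for a
#'   censored observation. May also be passed as a single data.frame with
#'   columns `time` and `event` in `time`.
#' @return A [SurvivalCurve-class].
#' @examples
#' kmEstimator(c(3, 7, 10), c(TRUE, TRUE, TRUE))
#' @export
kmEstimator <- function(time, event) {
  if (is.data.frame(time)) {
    event <- time$event
    time <- time$time
  }
  stopifnot(length(time) == length(event), length(time) >= 1)
  event <- as.logical(event)
  times <- sort(unique(time))
  nRisk <- nEvent <- nCensor <- numeric(length(times))
  for (i in seq_along(times)) {
    nRisk[i] <- sum(time >= times[i])
    nEvent[i] <- sum(time == times[i] & event)
    nCensor[i] <- sum(time == times[i] & !event)
  }
  surv <- cumprod(1 - nEvent / nRisk)
  new("SurvivalCurve", time = times, survival = surv, nRisk = nRisk,
      nEvent = nEvent, nCensor = nCensor)
}

#' Median time to progression from a survival curve
#'
#' The smallest step time at which the survivor function is <= 0.5. When the
#' curve never reaches 0.5 the median is undefined and `NA` is returned with
#' a message.
#'
#' @param curve a [SurvivalCurve-class].
#' @return Median time in days, or `NA_real_` when undefined.
#' @export
medianTTP <- function(curve) {
  stopifnot(is(curve, "SurvivalCurve"))
  hit <- which(curve@survival <= 0.5)
  if (!length(hit)) {
    message("survival never reaches 0.5; median time to progression undefined")
    return(NA_real_)
  }
  curve@time[min(hit)]
}
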