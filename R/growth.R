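#' Tumour volume from calliper dimensions assuming an ellipsoid
#'
#' Converts calliper length, width and height (mm) to a volume under the
#' standard ellipsoid convention with semi-axes equal to half of each
#' calliper dimension, `V = (pi/6) * l * w * h`.
#'
#' Arguments are vectorised. `NA` triples (missed visits) propagate as `NA`;
#' a zero dimension gives a zero volume; negative dimensions are an error.
#'
#' @param length,width,height calliper dimensions in mm, each >= 0.
#' @return Volume(s) in mm^3.
#' @examples
#' ellipsoidVolume(12.4, 9.6, 9.6)
#' @export
ellipsoidVolume <- function(length, width, height) {
  if (any(c(length, width, height) < 0, na.rm = TRUE))
    stop("calliper dimensions must be >= 0", call. = FALSE)
  (pi / 6) * length * width * height
}

#' Per-animal volumes and relative tumour volumes
#'
#' Computes each animal's tumour volume per visit and its relative tumour
#' volume, RTV(t) = V(t) / V(day 0). Missed visits stay `NA`; nothing is
#' interpolated. Every animal needs a positive day-0 baseline volume (the
#' cohort validity guarantees the baseline measurement exists).
#'
#' @param cohort a [TumourCohort-class].
#' @return data.frame with columns `animal_id`, `group`, `day`,
#'   `volume_mm3`, `rtv`.
#' @export
relativeVolumes <- function(cohort) {
  stopifnot(is(cohort, "TumourCohort"))
  m <- measurements(cohort)
  m$volume_mm3 <- ellipsoidVolume(m$length_mm, m$width_mm, m$height_mm)
  out <- do.call(rbind, lapply(split(m, m$animal_id), function(mi) {
    v0 <- mi$volume_mm3[mi$day == 0]
    if (length(v0) != 1L || is.na(v0) || v0 <= 0)
      stop(sprintf("animal '%s' has no positive day-0 baseline volume",
                   mi$animal_id[1]), call. = FALSE)
    mi$rtv <- mi$volume_mm3 / v0
    mi
  }))
  rownames(out) <- NULL
  out[order(out$animal_id, out$day),
      c("animal_id", "group", "day", "volume_mm3", "rtv")]
}

#' Group-level mean RTV curves with ratio to control
#'
#' Summarises per-animal relative tumour volumes into per-arm, per-day mean
#' and standard error of the mean, over the animals still measured on that
#' day (shrinking-n follow-up; days on which an arm has no measured animal
#' are dropped from that arm's curve with a message). The SEM of a
#' single-animal day is 0 by convention. `ratio_to_control` divides an arm's
#' mean RTV by the control arm's mean RTV on the same day; the control arm's
#' own ratio is identically 1.
#'
#' @param cohort a [TumourCohort-class].
#' @param rtvs optional precomputed output of [relativeVolumes()].
#' @return data.frame with columns `group`, `day`, `mean_rtv`, `sem_rtv`,
#'   `n`, `ratio_to_control`.
#' @export
summariseGroups <- function(cohort, rtvs = relativeVolumes(cohort)) {
  stopifnot(is(cohort, "TumourCohort"))
  rtvs <- rtvs[!is.na(rtvs$rtv), ]
  agg <- do.call(rbind, lapply(split(rtvs, list(rtvs$group, rtvs$day),
                                     drop = TRUE), function(d) {
    data.frame(group = d$group[1], day = d$day[1],
               mean_rtv = mean(d$rtv),
               sem_rtv = if (nrow(d) > 1) sd(d$rtv) / sqrt(nrow(d)) else 0,
               n = nrow(d), stringsAsFactors = FALSE)
  }))
  rownames(agg) <- NULL
  allDays <- sort(unique(rtvs$day))
  empty <- setdiff(
    paste(rep(unique(rtvs$group), each = length(allDays)), allDays),
    paste(agg$group, agg$day))
  if (length(empty))
    message("days with no measured animals dropped from curves: ",
            paste(empty, collapse = "; "))
  ctrl <- agg[agg$group == controlGroup(cohort), c("day", "mean_rtv")]
  names(ctrl)[2] <- "control_mean_rtv"
  agg <- merge(agg, ctrl, by = "day", all.x = TRUE)
  agg$ratio_to_control <- agg$mean_rtv / agg$control_mean_rtv
  agg$control_mean_rtv <- NULL
  agg <- agg[order(agg$group, agg$day),
             c("group", "day", "mean_rtv", "sem_rtv", "n", "ratio_to_control")]
  rownames(agg) <- NULL
  agg
}
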