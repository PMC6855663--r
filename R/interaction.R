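#' Fractional response of a treated arm relative to control
#'
#' F = 1 - RTV_arm / RTV_control, computed on group mean relative tumour
#' volumes at a common day. F = 0 means no effect, F = 1 complete
#' disappearance. Values outside `[0, 1]` (an arm growing faster than
#' control, or past complete regression) are passed through unclamped with
#' a warning, because the independence model's probabilistic reading breaks
#' there and that should be visible, not hidden.
#'
#' @param rtvArm mean RTV of the treated arm.
#' @param rtvControl mean RTV of the control arm, > 0.
#' @return Fractional response(s).
#' @export
fractionalResponse <- function(rtvArm, rtvControl) {
  if (any(rtvControl <= 0))
    stop("rtvControl must be > 0", call. = FALSE)
  f <- 1 - rtvArm / rtvControl
  if (any(f < 0 | f > 1, na.rm = TRUE))
    warning("fractional response outside [0, 1]; independence model interpretation is strained",
            call. = FALSE)
  f
}

#' Bliss-independence predicted additive response
#'
#' Predicted combined fractional response of two independently acting
#' treatments: `f_add = f_rad + f_gem - f_rad * f_gem`, equivalently
#' `1 - (1 - f_rad) * (1 - f_gem)` on surviving fractions.
#'
#' @param fRad,fGem monotherapy fractional responses. Values outside
#'   `[0, 1]` are accepted with a warning.
#' @return Predicted additive fractional response.
#' @examples
#' blissAdditive(0.71, 0.52)
#' @export
blissAdditive <- function(fRad, fGem) {
  if (any(fRad < 0 | fRad > 1 | fGem < 0 | fGem > 1, na.rm = TRUE))
    warning("fractional response outside [0, 1] entering the independence model",
            call. = FALSE)
  fRad + fGem - fRad * fGem
}

#' RTV implied by a predicted additive response
#'
#' Inverts the fractional-response definition to express the predicted
#' additive effect on the RTV scale: `rtv = (1 - f_add) * rtv_control`,
#' suitable for plotting next to the measured combination curve.
#'
#' @param fAdd predicted additive fractional response.
#' @param rtvControl control-arm mean RTV, > 0.
#' @return Predicted additive RTV.
#' @export
predictedAdditiveRTV <- function(fAdd, rtvControl) {
  if (any(rtvControl <= 0)) stop("rtvControl must be > 0", call. = FALSE)
  (1 - fAdd) * rtvControl
}

#' Classify a combination effect against the additive prediction
#'
#' The observed combination response is synergistic, additive or
#' antagonistic according to whether it is larger than, equal to or smaller
#' than the predicted additive response. Exact equality is measure-zero on
#' real data, so a symmetric tolerance band around `fAdd` may be supplied
#' within which the effect is called additive (default 0: the strict rule).
#'
#' @param fObs observed combination fractional response.
#' @param fAdd predicted additive fractional response.
#' @param tolerance half-width of the additive band, >= 0.
#' @return Character vector in `{"synergistic", "additive", "antagonistic"}`.
#' @export
classifyInteraction <- function(fObs, fAdd, tolerance = 0) {
  stopIfNot(all(tolerance >= 0), "tolerance must be >= 0")
  ifelse(fObs > fAdd + tolerance, "synergistic",
         ifelse(fObs < fAdd - tolerance, "antagonistic", "additive"))
}

#' Per-day Bliss interaction analysis of a combination arm
#'
#' Evaluates, for every measurement day shared by the four arms, the
#' monotherapy fractional responses, the predicted additive response and
#' its RTV, the observed combination response, and the interaction
#' classification. Works on group mean RTVs as produced by
#' [summariseGroups()].
#'
#' @param groupSummary output of [summariseGroups()].
#' @param radArm,gemArm labels of the two monotherapy arms.
#' @param comboArm label of the combination arm.
#' @param controlArm label of the untreated control arm.
#' @param tolerance additive-band half-width for [classifyInteraction()].
#' @return data.frame with columns `day`, `f_rad`, `f_gem`, `f_add`,
#'   `f_obs`, `rtv_predicted_additive`, `classification`.
#' @export
interactionAnalysis <- function(groupSummary, radArm, gemArm, comboArm,
                                controlArm, tolerance = 0) {
  need <- c(radArm, gemArm, comboArm, controlArm)
  missing <- setdiff(need, groupSummary$group)
  if (length(missing))
    stop("arms not present in group summary: ", paste(missing, collapse = ", "),
         call. = FALSE)
  pick <- function(arm) {
    d <- groupSummary[groupSummary$group == arm, c("day", "mean_rtv")]
    names(d)[2] <- arm
    d
  }
  tab <- Reduce(function(a, b) merge(a, b, by = "day"), lapply(need, pick))
  tab <- tab[tab$day > 0, , drop = FALSE]
  fRad <- fractionalResponse(tab[[radArm]], tab[[controlArm]])
  fGem <- fractionalResponse(tab[[gemArm]], tab[[controlArm]])
  fAdd <- blissAdditive(fRad, fGem)
  fObs <- fractionalResponse(tab[[comboArm]], tab[[controlArm]])
  out <- data.frame(
    day = tab$day, f_rad = fRad, f_gem = fGem, f_add = fAdd, f_obs = fObs,
    rtv_predicted_additive = predictedAdditiveRTV(fAdd, tab[[controlArm]]),
    classification = classifyInteraction(fObs, fAdd, tolerance),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
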