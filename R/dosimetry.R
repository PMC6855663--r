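## Unit constants for the absorbed-dose conversion.
.DECAYS_PER_MBQ_H <- 3.6e9      # 1 MBq * 1 h = 1e6 decays/s * 3600 s
.JOULES_PER_KEV <- 1.602e-16
.G_PER_KG <- 1e3

#' Dose-calculation parameters
#'
#' Physical constants for the mean absorbed dose estimate. The defaults
#' model only the beta-particle contribution of 177Lu: mean energy emitted
#' per decay 147.9 keV and absorbed fraction 1 (all emitted beta energy
#' absorbed locally in the tissue of interest).
#'
#' @param energyPerDecayKeV mean energy emitted per decay, sum of E_i * Y_i
#'   over the modelled transitions (keV).
#' @param absorbedFraction fraction of emitted energy absorbed in the
#'   tissue, in (0, 1].
#' @return Named list used by [meanAbsorbedDose()].
#' @export
doseParameters <- function(energyPerDecayKeV = 147.9, absorbedFraction = 1) {
  stopIfNot(energyPerDecayKeV > 0, "energyPerDecayKeV must be > 0")
  stopIfNot(absorbedFraction > 0 && absorbedFraction <= 1,
            "absorbedFraction must lie in (0, 1]")
  list(energyPerDecayKeV = energyPerDecayKeV,
       absorbedFraction = absorbedFraction)
}

## Convert a series to MBq/g, using the injected activity for %IA/g input.
asMBqPerG <- function(series) {
  if (series@unit == "MBq_per_g") return(series@concentrations)
  a0 <- series@injectedActivityMBq
  if (is.na(a0) || a0 <= 0)
    stop("percent_IA_per_g input requires a positive injectedActivityMBq",
         call. = FALSE)
  series@concentrations / 100 * a0
}

#' Fit a mono-exponential washout curve
#'
#' Fits C(t) = C0 * exp(-lambda * t) to a time-activity concentration
#' series. The default fit is ordinary least squares on the log-transformed
#' concentrations; `method = "nls"` refines that solution by nonlinear least
#' squares on the original scale as a sensitivity check. A non-decaying fit
#' (lambda <= 0) is an error because the time-integrated activity would
#' diverge.
#'
#' @param series a [TimeActivitySeries-class] (>= 2 points).
#' @param method `"loglinear"` (default) or `"nls"`.
#' @return list with `C0` (MBq/g) and `lambdaEff` (1/h).
#' @examples
#' s <- timeActivitySeries(c(0, 10), c(10, 5))
#' fitMonoexponential(s)  # lambdaEff = log(2)/10
#' @export
fitMonoexponential <- function(series, method = c("loglinear", "nls")) {
  stopifnot(is(series, "TimeActivitySeries"))
  method <- match.arg(method)
  conc <- asMBqPerG(series)
  t <- series@times
  fit <- lm(log(conc) ~ t)
  c0 <- unname(exp(coef(fit)[1]))
  lambda <- unname(-coef(fit)[2])
  if (method == "nls") {
    ## scaleOffset keeps the convergence test defined on zero-residual data
    nfit <- stats::nls(conc ~ C0 * exp(-lambda * t),
                       start = list(C0 = c0, lambda = max(lambda, 1e-6)),
                       control = stats::nls.control(maxiter = 200,
                                                    scaleOffset = 1))
    c0 <- unname(coef(nfit)["C0"])
    lambda <- unname(coef(nfit)["lambda"])
  }
  if (!is.finite(lambda) || lambda <= 0)
    stop("fitted curve does not decay (lambda <= 0); time-integrated activity diverges",
         call. = FALSE)
  list(C0 = c0, lambdaEff = lambda)
}

#' Time-integrated activity concentration
#'
#' Analytic integral of the fitted mono-exponential from the time of
#' injection (t = 0) to infinity: `C0 / lambda`. The fitted curve is
#' extrapolated back to t = 0 even when the first sample is later.
#'
#' @param C0 fitted initial concentration (MBq/g), >= 0.
#' @param lambdaEff effective decay constant (1/h), must be > 0.
#' @return Time-integrated activity concentration in MBq h/g.
#' @export
timeIntegratedActivity <- function(C0, lambdaEff) {
  stopIfNot(all(C0 >= 0), "C0 must be >= 0")
  if (any(lambdaEff <= 0))
    stop("lambdaEff must be > 0; the integral to infinity diverges otherwise",
         call. = FALSE)
  C0 / lambdaEff
}

#' Mean absorbed dose from time-integrated activity
#'
#' Mean absorbed dose per the internal-dosimetry formalism, in its per-mass
#' form: dose = A~ * (energy per decay) * (absorbed fraction), where A~ is
#' the time-integrated activity concentration. Unit conversions applied:
#' 1 MBq h = 3.6e9 decays, 1 keV = 1.602e-16 J, per-gram to per-kilogram.
#'
#' @param aTilde time-integrated activity concentration (MBq h/g), >= 0.
#' @param params a [doseParameters()] list.
#' @return Mean absorbed dose in Gy.
#' @examples
#' meanAbsorbedDose(100)  # 8.53 Gy with the 177Lu beta defaults
#' @export
meanAbsorbedDose <- function(aTilde, params = doseParameters()) {
  if (any(aTilde < 0)) stop("aTilde must be >= 0", call. = FALSE)
  aTilde * .DECAYS_PER_MBQ_H * params$energyPerDecayKeV * .JOULES_PER_KEV *
    params$absorbedFraction * .G_PER_KG
}

#' Full dosimetry chain on a time-activity series
#'
#' Convenience wrapper running fit, integration and dose conversion, and
#' reporting the effective half-life.
#'
#' @inheritParams fitMonoexponential
#' @param params a [doseParameters()] list.
#' @return list with `C0`, `lambdaEff`, `halfLifeH`, `aTilde`, `doseGy`.
#' @export
absorbedDoseFromSeries <- function(series, params = doseParameters(),
                                   method = c("loglinear", "nls")) {
  fit <- fitMonoexponential(series, method = method)
  aTilde <- timeIntegratedActivity(fit$C0, fit$lambdaEff)
  list(C0 = fit$C0, lambdaEff = fit$lambdaEff,
       halfLifeH = log(2) / fit$lambdaEff, aTilde = aTilde,
       doseGy = meanAbsorbedDose(aTilde, params))
}

#' Human-equivalent dose by body-surface-area scaling
#'
#' Converts an animal dose in mg/kg to a human-equivalent dose in mg/m^2 by
#' multiplying with the species Km factor (body weight / body surface area),
#' approximately 3 for mouse.
#'
#' @param animalDoseMgKg dose in mg/kg, >= 0.
#' @param kmFactor species conversion factor, > 0 (default 3, mouse).
#' @return Human-equivalent dose in mg/m^2.
#' @examples
#' humanEquivalentDose(60)  # 180 mg/m^2
#' @export
humanEquivalentDose <- function(animalDoseMgKg, kmFactor = 3) {
  if (any(animalDoseMgKg < 0)) stop("dose must be >= 0", call. = FALSE)
  if (any(kmFactor <= 0)) stop("kmFactor must be > 0", call. = FALSE)
  animalDoseMgKg * kmFactor
}
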