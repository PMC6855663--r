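#' Simulate a tracer washout time-activity series
#'
#' Mono-exponential washout C(t) = C0 exp(-lambda t) sampled at the given
#' times with multiplicative lognormal noise of the stated coefficient of
#' variation (mean 1, so the noise is unbiased on the concentration scale).
#' Reproducible for a fixed seed; `noiseCv = 0` returns the exact model
#' values.
#'
#' @param C0 initial concentration (MBq/g), > 0.
#' @param lambdaEff effective decay constant (1/h), > 0.
#' @param times sampling times (h), strictly increasing.
#' @param noiseCv lognormal noise CV, >= 0.
#' @param seed integer seed.
#' @return A [TimeActivitySeries-class].
#' @examples
#' simulateTimeActivity(2, 0.05, c(1, 24, 72, 168), noiseCv = 0.05, seed = 7)
#' @export
simulateTimeActivity <- function(C0, lambdaEff, times, noiseCv = 0, seed = 1) {
  stopIfNot(C0 > 0, "C0 must be > 0")
  stopIfNot(lambdaEff > 0, "lambdaEff must be > 0")
  stopIfNot(noiseCv >= 0, "noiseCv must be >= 0")
  withSeed(seed, {
    conc <- C0 * exp(-lambdaEff * times)
    if (noiseCv > 0) {
      sdlog <- sqrt(log(1 + noiseCv^2))
      conc <- conc * rlnorm(length(times), -sdlog^2 / 2, sdlog)
    }
    timeActivitySeries(times, conc)
  })
}
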