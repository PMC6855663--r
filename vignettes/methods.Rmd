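---
title: "Models and methods behind radiosynergy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind radiosynergy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

radiosynergy analyses preclinical combination studies of radiation and a
chemotherapeutic radiosensitiser in tumour-bearing mice. This vignette
records the models the package implements, the assumptions they make,
the tunable parameters and why their defaults are what they are, and the
design decisions taken where more than one defensible choice existed.

## Tumour volume and RTV

Calliper triples are converted with the standard calliper-ellipsoid
convention $V = \frac{\pi}{6}\, l\, w\, h$, i.e. an ellipsoid whose
semi-axes are half of each calliper dimension. Other conventions exist
(notably $V = \frac{1}{2} l w^2$ when only two dimensions are taken);
with three measured dimensions per visit, $\pi/6$ times their product is
the natural and most widely used choice, and it is what
`ellipsoidVolume()` implements. The relative tumour volume is
$\mathrm{RTV}(t) = V(t)/V(0)$ per animal, with day 0 the first treatment
day; a positive complete baseline is therefore required and enforced by
the `TumourCohort` validity method.

Missed visits are gaps: nothing is interpolated, and group curves are
computed over the animals actually measured on each nominal visit day
(shrinking-*n* follow-up). The SEM of a one-animal day is defined as 0
so that summary curves stay well-defined to the end of follow-up. Days
are taken as nominal schedule days; the package does not bin or align
off-schedule visits, so input tables must already carry nominal days.

## Progression and Kaplan–Meier estimation

Progression is "larger than at treatment start, after the initial
response has run its course", operationalised as: the first measurement
day $t > 0$ with $\mathrm{RTV}(t) > 1$ occurring **at or after the RTV
nadir**. For a tumour that never responds the nadir is the baseline and
the rule degenerates to the first day above baseline — for an untreated
exponentially growing tumour, the first visit. The inequality is strict:
sitting exactly at baseline is not progression. Killed animals are
progression events at the kill day regardless of their RTV at the time;
a humane-endpoint kill is a tumour-burden outcome and treating it as
censoring would bias the curves optimistically. This scoring of a
killed-but-regressing animal is our choice, not an established
convention, and is confined to `detectProgression()`.

The product-limit estimator is implemented directly (risk sets over
distinct times, events before censorings on ties, right-continuous
steps). The `survival` package is used in the test-suite as an
independent cross-check, never as the implementation. No confidence
intervals are drawn. The median time to progression is the first step
time with $S \le 0.5$, and `NA` (with a message) when the curve never
gets there.

## Internal dosimetry

The washout model is mono-exponential,
$C(t) = C_0 e^{-\lambda t}$, fitted by ordinary least squares on
$\log C$ — the classical choice for sparse biodistribution data, with
the pleasant property of being exact on noiseless input. A nonlinear
least-squares refinement (`method = "nls"`) is available as a
sensitivity check; it weights large concentrations more and can differ
on noisy data. A non-decaying fit ($\lambda \le 0$) is an error, because
the time-integrated activity

$$\tilde{A} = \int_0^\infty C_0 e^{-\lambda t}\,dt = \frac{C_0}{\lambda}$$

would diverge. Integration runs from injection ($t = 0$) to infinity,
extrapolating the fitted curve back to 0 even when the first sample is
later. The mean absorbed dose uses the per-mass form of the
internal-dosimetry formalism,
$D = \tilde{A} \cdot \sum_i E_i Y_i \cdot \phi$, with unit conversions
1 MBq·h = 3.6×10⁹ decays, 1 keV = 1.602×10⁻¹⁶ J and g → kg. The
defaults $\sum E Y = 147.9$ keV and $\phi = 1$ model only the beta
contribution of ¹⁷⁷Lu, absorbed locally; photon cross-dose and
voxel-level dosimetry are out of scope. Percent-injected-activity input
is converted to MBq/g via the injected activity before fitting.
Reproducing a real study's absolute tumour dose additionally requires
that study's biodistribution series, which is external data; the
package documents the chain and verifies it against closed forms and
simulations instead.

`humanEquivalentDose()` is plain body-surface-area scaling,
mg/kg × Km, Km ≈ 3 for mouse.

## Bliss independence

On group mean RTVs, per day: $F = 1 - \mathrm{RTV}_{\text{mono}} /
\mathrm{RTV}_{\text{control}}$ and
$F_{\text{add}} = F_{\text{rad}} + F_{\text{gem}} - F_{\text{rad}}
F_{\text{gem}}$. The observed combination response is synergistic,
additive or antagonistic as it is larger than, equal to or smaller than
$F_{\text{add}}$. Exact equality is measure-zero on data, so
`classifyInteraction()` takes a tolerance half-width within which the
call is "additive". The default tolerance is 0 (the strict rule); the
pipeline preset uses 0.05, chosen a priori from the sampling noise of
group means at the simulator's settings (with 10% measurement CV and
$n = 200$ per arm the standard error of $F_{\text{obs}} -
F_{\text{add}}$ is about 0.01–0.015, so 0.05 is a 3–5 σ band, while
real-effect departures of interest are larger still). Fractional
responses outside $[0,1]$ — an arm growing faster than control, or past
complete regression — are propagated unclamped with a warning: the
probabilistic reading of the independence model breaks there and that
should be visible. Interaction is evaluated on group means, not per
animal, and no inferential test on $F_{\text{obs}} - F_{\text{add}}$ is
provided: inventing one would overstate what the day-by-day comparison
can support.

## Group statistics and multiplicity

Per analysed day, a one-way fixed-effects ANOVA across all arms and all
pairwise two-sample t-tests, Holm-corrected. All three procedures are
implemented from the defining formulas (sums of squares, pooled
variance, step-down maximum) and validated in the tests against `aov`,
`t.test` and `p.adjust`, which act purely as oracles. The pooled
Student's t is the default because that is what "Student's t-test"
means; the Welch variant is a flag away, and is worth using when arm
variances differ visibly. Tests are two-sided throughout.

Which comparisons form one correction family is genuinely ambiguous in
this kind of study. The default family is *all pairwise comparisons at
one measurement day*, matching the per-day reporting style of growth
curves; `family = "all-days"` pools every pairwise comparison across
days into a single family and is the right choice when the claim under
control is "any difference at any time" (it is what the null-study
false-positive test uses). Omnibus ANOVA p-values are Holm-adjusted as
their own family across days in both modes. Degenerate inputs follow
continuity conventions: all-identical observations give $F = 0, p = 1$
(or $t = 0, p = 1$); zero variance with unequal means gives an infinite
statistic and $p = 0$, flagged.

## Histology quantification

Pixel classification is by thresholds in HSV space, in priority order:
fold artefact (over-dark), background/crack (bright and unsaturated),
positive stain (aniline-blue collagen for trichrome, DAB brown for
Ki67), necrosis colour class (pale, eosin-dominant — trichrome only),
counterstained tissue (the remainder). Every ROI pixel gets exactly one
label; "tissue" means the last three classes, so artefacts are excluded
from every denominator. Thresholding-in-HSV was chosen over stain
deconvolution as the default because it is transparent to calibrate and
matches how such in-house tools are typically built; the threshold
schema is a plain list and every window is user-overridable, which
reflects the reality that colour calibration against a pathologist's
judgement is a manual step. The shipped windows are calibrated against
the synthetic renderer's reference palette and are **not** expected to
transfer to real scanner output unchanged.

Necrosis segmentation takes the necrosis colour class, applies
morphological closing (disc radius 2 px by default) to bridge speckle,
labels connected components and discards those below `minRegionAreaUm2`
(default 50 µm²) — small pale patches are absorbed back into viable
tissue rather than counted as necrosis. Registration from control
points defaults to a similarity transform (rotation + isotropic scale +
translation), solved exactly as a complex least-squares problem;
adjacent 4 µm sections justify excluding shear, and an affine model is
available when it does not hold. Masks move between rasters by
nearest-neighbour lookup through the inverse transform, so binary masks
stay binary and label images are never interpolated; pixels mapping
outside the source frame stay unlabelled. Coordinates are 0-based pixel
centres, origin top-left, x right, y down.

Ki67 is quantified as the positive percentage of *viable* tumour area
(the necrotic mask transferred from the trichrome section), collagen as
the positive percentage of the *whole* tumour tissue area. Percentages
are area-based, not nucleus-count-based — the tool measures stained
area fraction, and nucleus-level counting is explicitly out of scope.

## The synthetic-data module

The generators exist so that every analysis stage has inputs with known
ground truth; they are first-class, tested code.

**Growth.** Per animal,
$$V(t) = V_0\left[f_s\, e^{g t} + (1-f_s)\, e^{-d t}\right]
 \cdot e^{g (m - 1)\min(t, w)} \cdot \varepsilon(t),$$
a two-compartment response: a surviving fraction $f_s$ keeps growing at
the untreated rate $g$ while the rest regresses at rate $d$, the drug
multiplies the net growth rate by $m$ during the dosing window
$[0, w]$, and $\varepsilon$ is lognormal measurement noise with fixed
CV. The drug factor deliberately multiplies the **whole** tumour volume
rather than only the surviving compartment: volume-level independence
of the two effects is exactly what makes the combination
Bliss-independent in the noiseless mean (applying the drug only to the
surviving compartment leaves a residual
$(1-f_s)e^{-(d+g)t}(1 - e^{g(m-1)t})$ between observed and predicted
response, i.e. a built-in spurious "antagonism"), and the simulator's
job is to provide a calibrated null against which the classifier can be
tested. The interaction multiplier $\iota$ scales the surviving
fraction on the combination arm only: $\iota = 1$ is the independent
reference, $\iota < 1$ injects genuine synergy.

Default calibration, fixed once from the qualitative pattern such
studies report and from closed-form algebra before any test was run:
baseline volumes lognormal with arithmetic mean 570 / SD 406 mm³;
$g = 0.052$/day (control doubling time ≈ 13 days); drug arm $m = 0$
(growth arrest during dosing, which puts the drug arm's RTV ratio to
control at $e^{-13g} \approx 0.51$ after the window — the "moderate
monotherapy effect" regime); radiation arm $f_s = 0.22$, $d = 0.10$/day
(nadir RTV ≈ 0.65 around day 13, regrowth at the control rate);
measurement CV 0.10 (typical calliper repeatability); dosing window 13
days; twice-weekly visits. The two-compartment model produces a smooth
early decline, not the shallow-then-steep shape real irradiated tumours
sometimes show — it is a stand-in chosen as the simplest model with a
delayed nadir and regrowth, not a radiobiological claim. The
strong-synergy preset uses $\iota = 0.3$, which separates observed from
predicted response by ≈ 0.08 at the widest point — comfortably outside
the 0.05 additive band. The humane-endpoint volume cap defaults to
4000 mm³: a literal 10%-of-body-weight rule (~2500 mm³) would kill
normally growing control animals before a 30-day follow-up ends, so the
cap is set where it truncates only outliers. Calliper triples are
recovered from volumes by inverting the ellipsoid product with bounded
anisotropy jitter that preserves the product exactly, so volumes
round-trip with no noise of their own.

What the generator does **not** emulate: biologically mechanistic
drug PK/PD, linear-quadratic dose response, inter-animal heterogeneity
in treatment sensitivity, correlated measurement errors, or off-schedule
visits. A passing pipeline on synthetic cohorts therefore demonstrates
the *arithmetic and inference machinery*, not field performance on any
real study.

**Tracer kinetics.** Mono-exponential washout with unbiased
multiplicative lognormal noise; at 5% CV and six samples the median
fitted $\lambda$ over hundreds of replicates sits within 2% of truth,
which the acceptance script re-measures at run time.

**Sections.** An elliptical tumour with an off-centre necrotic disc,
crack lines and fold blobs, positive pixels placed at exact counts (so
ground truth is the achieved, not requested, fraction), rendered from a
fixed reference palette with Gaussian noise (SD 0.012). The Ki67 image
is the same layout under an embedded similarity transform, resampled
nearest-neighbour, with control points mapped exactly — hence the
registration residual on them is numerically zero. Default canvas
200×200 px at 0.25 µm: large enough that fraction-recovery errors are
dominated by classification, small enough that the full acceptance grid
(nine section pairs) runs in seconds. Real slides differ in every hard
way: stain variability, uneven illumination, genuinely ambiguous
colours, non-rigid deformation between adjacent sections. Threshold
recalibration against expert judgement is expected there.

All generators are pure functions of (config, seed): they save and
restore the caller's RNG state, and repeated calls are byte-identical.

## Pipeline and reproducibility

`runPipeline()` chains the stages, writes tidy CSVs, a markdown summary
and a JSON manifest with the package version, the config, the seed and
an MD5 checksum per output; identical config + seed gives identical
checksums. Module-level randomness derives from the master seed through
named substreams. The command-line wrapper in
`inst/scripts/radiosynergy-cli.R` is a thin layer over these exported
functions with exit codes 0/1/2 (ok / user error / internal error).

## Problem sizes

The shipped test-suite and acceptance script use: all event/censor
patterns of up to six survival times against a brute-force
product-limit oracle; 1000 random p-value families against a
brute-force Holm; 1000-replicate null simulations for test size;
500-replicate washout fits; cohorts of 200 animals per arm for
interaction-classification checks (sampling SD of the day-level
classification statistic ≈ 0.01); and nine rendered section pairs
across ground-truth grids. These sizes make the stochastic checks
stable to a few per mille while keeping a full run in tens of seconds.

## Known limitations

- The progression rule depends on measured RTV only; it cannot
  distinguish regrowth from measurement noise on a single visit.
- Dosimetry is mean absorbed dose from one tissue concentration curve;
  no photon cross-dose, organ S-values or voxel maps.
- The interaction analysis is descriptive (no test on
  $F_{\text{obs}} - F_{\text{add}}$), and evaluated on group means.
- Which comparisons the correction family should contain is a judgement
  call; both supported families are defensible and can disagree.
- Image analysis assumes flat RGB rasters with a hand-drawn ROI and
  manually picked control points; no whole-slide pyramids, no automated
  landmark detection, no nucleus counting.
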