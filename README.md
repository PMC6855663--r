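# radiosynergy

Analysis toolkit for preclinical studies that combine radiation therapy
(external beam or a systemic radiopharmaceutical such as
<sup>177</sup>Lu-octreotate) with a chemotherapeutic radiosensitiser
(e.g. gemcitabine) in tumour-bearing mice. It is written for the people
who run and analyse such studies — medical physicists, radiobiologists
and biostatisticians — and covers the full chain from calliper
measurements and tracer kinetics to stained-section image quantification,
with a synthetic-data module so every stage is testable without animal
data.

## What it computes

**Tumour growth.** Calliper length/width/height triples become volumes
under the ellipsoid convention *V* = (π/6)·*l*·*w*·*h*, and each animal's
relative tumour volume is RTV(*t*) = *V*(*t*)/*V*(0) with day 0 the first
treatment day. Arms are summarised per day by mean RTV ± SEM over the
animals still on study, plus the ratio of each arm's mean RTV to the
untreated control's.

**Progression-free survival.** A tumour has progressed on the first day
its RTV exceeds 1 at or after its nadir (so an initial response may run
its course); animals killed earlier count as events at the kill day,
animals that never progress are censored. Curves use the Kaplan–Meier
product-limit estimator, implemented here and cross-checked against the
`survival` package in the tests; median time to progression is the first
crossing of *S* = 0.5.

**Internal dosimetry.** A mono-exponential washout
*C*(*t*) = *C*₀·e<sup>−λt</sup> is fitted to time–activity concentration
data (log-linear least squares, with a nonlinear refinement option). The
time-integrated activity concentration is Ã = *C*₀/λ (injection to
infinity) and the mean absorbed dose follows the internal-dosimetry
formalism *D* = Ã·ΣᵢEᵢYᵢ·φ/M in per-mass form; defaults model only the
<sup>177</sup>Lu beta contribution (ΣEY = 147.9 keV, φ = 1). A Km-factor
conversion (mg/kg × 3 for mouse) gives human-equivalent mg/m² doses.

**Bliss interaction.** Per measurement day, monotherapy fractional
responses *F* = 1 − RTV<sub>mono</sub>/RTV<sub>control</sub> combine into
the predicted additive response
*F*<sub>add</sub> = *F*<sub>rad</sub> + *F*<sub>gem</sub> −
*F*<sub>rad</sub>·*F*<sub>gem</sub>; the observed combination response is
classified synergistic / additive / antagonistic against
*F*<sub>add</sub> (with a configurable tolerance band).

**Group statistics.** Per-day one-way ANOVA across all arms and pairwise
Student's t-tests (Welch optional), with Bonferroni–Holm step-down
correction; all three are implemented from first principles and verified
against `aov`, `t.test` and `p.adjust`.

**Histology quantification.** Masson's trichrome / Ki67 section pairs
are segmented by HSV colour thresholds inside a tumour ROI (background
cracks and fold artefacts removed), necrosis is segmented on the
trichrome image (morphological closing + minimum region area), the
sections are registered from control points (similarity or affine least
squares), the viable/necrotic mask is transferred to the Ki67 raster by
nearest-neighbour resampling, and the outputs are the Ki67-positive
percentage of viable tumour and the collagen-positive percentage of the
whole tumour area.

## Worked example

```r
library(radiosynergy)

cohort <- simulateGrowthCohort(growthPreset("reference"), seed = 1)
cohort
#> TumourCohort: 33 animals in 4 arms
#>   control (control): n = 12
#>   gem: n = 10
#>   rad: n = 5
#>   rad_gem: n = 6
#>   visit days: 0, 3, 7, 10, 14, 17, 21, 24, 28, 31, 35, 38, 42, 45, 49, 52, 56

groups  <- summariseGroups(cohort)
records <- detectProgression(cohort)
sapply(split(records, records$group),
       function(r) medianTTP(kmEstimator(r)))
#> control     gem     rad rad_gem
#>       3      10      31      42
```

The untreated animals progress at the first visit (median TTP 3 days),
drug monotherapy delays progression moderately, radiation substantially,
and the combination most — the qualitative pattern such studies are
designed to show. The per-day interaction table on the group means:

```r
tab <- interactionAnalysis(groups, "rad", "gem", "rad_gem", "control",
                           tolerance = 0.05)
round(tab[tab$day %in% c(7, 14, 24), 1:5], 3)
#>   day f_rad f_gem f_add f_obs
#> 2   7 0.528 0.334 0.686 0.652
#> 4  14 0.659 0.470 0.819 0.823
#> 7  24 0.757 0.478 0.873 0.872
```

Here the observed combination response tracks the Bliss prediction
(classification "additive" on every day), as it must: the `"reference"`
preset generates the two treatment effects independently. The dosimetry
chain on simulated washout data:

```r
ta <- simulateTimeActivity(2, 0.05, c(1, 8, 24, 48, 96, 168),
                           noiseCv = 0.05, seed = 1)
str(absorbedDoseFromSeries(ta))
#> $ C0       : num 2.01      # MBq/g
#> $ lambdaEff: num 0.0501    # 1/h
#> $ halfLifeH: num 13.8
#> $ aTilde   : num 40        # MBq h/g
#> $ doseGy   : num 3.41

humanEquivalentDose(60, kmFactor = 3)
#> [1] 180                    # mg/m2
```

An end-to-end run (report CSVs, markdown summary, reproducibility
manifest) is one call — `runPipeline(list(preset = "reference"), "out",
seed = 1)` — or one shell command via the thin CLI in
`inst/scripts/radiosynergy-cli.R`.

## Limitations

Absolute absorbed doses for a real study require that study's own
biodistribution data; the shipped defaults only fix the physical
constants. The image module targets flat RGB rasters (PNG/TIFF), not
pyramidal whole-slide formats, and quantifies area fractions, not
nucleus counts. See the methods vignette (`vignettes/methods.Rmd`) for
the models, assumptions and parameter choices in full.
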