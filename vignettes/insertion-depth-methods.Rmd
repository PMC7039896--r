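---
title: "Predicting cochlear implant electrode insertion depth: models, validation and agreement"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting cochlear implant electrode insertion depth: models, validation and agreement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(ciplanr)
library(dplyr)
```

## The problem

Before cochlear implantation, the surgeon must judge how deep a given
electrode array will sit in the patient's cochlea. The cochlear duct length
(CDL) varies substantially between individuals, and over- or under-insertion
both carry costs: intracochlear trauma on one side, reduced apical coverage
on the other. Full three-dimensional reconstruction of the cochlea from
clinical CT is not practical in routine care, but the *basal turn* is
reliably visible. Two analytical models therefore estimate the CDL from one
or two linear measurements taken on an oblique CT plane aligned with the
basal turn (the "cochlear view"):

* the **diameter** `A`, from the round window through the helicotrema to
  the far lateral wall, and
* the **width** `B`, perpendicular to `A` through the helicotrema.

ciplanr implements both models, their inversions from linear depth to
insertion angle, the forward prediction of where an electrode array of known
geometry will end up, the postoperative validation of those predictions, and
the observer-agreement statistics used to compare the two models. A
synthetic-cohort generator emulates the measurement-noise structure of a
two-observer CT study so that every stage is testable without patient data.

## The two models

**Logarithmic-spiral (adopted Escudé) model.** The duct length at the
electrode level, at insertion angle $\theta$ (degrees, 0 at the round
window), is

$$\mathrm{CDL}_i(\theta) = p_1\,(A - 2\,\delta)\,\ln(1 + \theta/p_2),
  \qquad p_1 = 2.62,\; p_2 = 235^\circ,$$

where $\delta$ is the assumed distance between the lateral wall and a
lateral-wall electrode array ($\delta = 0.5$ mm by default, so 1 mm is
subtracted from `A`). Inversion is closed-form:
$\theta = p_2\,(e^{L/(p_1 (A - 2\delta))} - 1)$.

**Elliptic-Circular Approximation (ECA).** Using both measurements (with
$\delta = 0.35$ mm), the basal turn length at the electrode level is

$$\mathrm{BTL}_i = 1.18\,a + 2.69\,b - \sqrt{0.72\,a\,b},
  \qquad a = A - 0.7,\; b = B - 0.7,$$

and the duct length at angle $\theta$ is a tabulated *percentage* of it,

$$\mathrm{CDL}_i(\theta) = \frac{p_\mathrm{BTL}(\theta)}{100}\,\mathrm{BTL}_i,
  \qquad p_\mathrm{BTL}(\theta) = 8.3\cdot10^{-8}\theta^3
  - 2.4\cdot10^{-4}\theta^2 + 0.34\,\theta + 3.7 .$$

The percentage cubic comes from a polynomial fit on micro-CT
reconstructions and is tabulated over 1-900 degrees (`pbtl_table()`). Since
the stated values are percentages (about 3.7 at 0 degrees, about 100 at a
full turn), the product uses $p_\mathrm{BTL}/100$; without the division the
"length" would exceed the basal turn length a hundredfold.

```{r}
cdl_escude(A = 9.2, theta_deg = 360)
cdl_eca(A = 9.2, B = 6.8, theta_deg = 360)
```

### Numerical choices

* **Valid angular domain.** Both models are restricted to
  $\theta \in [0, 900]$ degrees, the range over which the percentage cubic
  is tabulated and increasing. Requests outside raise an error; nothing is
  extrapolated.
* **ECA inversion.** `angle_eca()` brackets the root on $[0, 900]$ with
  `stats::uniroot` at an angular tolerance of $10^{-10}$ degrees; the
  objective is a positive constant times a strictly increasing cubic, so
  bisection-grade root finding is robust and the roundtrip error is far
  below $10^{-6}$ degrees (the suite verifies this on a grid over
  $A \in \{7.5, 9, 10.5\}$ and $\theta$ up to 890 degrees).
* **The intercept artifact.** $p_\mathrm{BTL}(0) = 3.7\%$, not 0: the fit
  does not vanish at the round window. The package preserves the published
  polynomial rather than renormalising it, and `angle_eca()` refuses
  lengths below $\mathrm{CDL}_i(0)$ with an explanatory error instead of
  silently clipping to 0.
* **Offsets are parameters.** `cochlear_params()` exposes both lateral-wall
  offsets, so running the spiral model with the ECA's 0.35 mm offset — a
  sensitivity variant worth checking because the differing offsets are one
  candidate explanation for the spiral model's larger overestimation — is
  `cochlear_params(escude_offset = 0.35)`, not a code change. (A smaller
  offset lengthens the modelled duct and so *reduces* predicted angles.)

## From model to electrode prediction

An `electrode_spec()` carries the three lengths that matter: tip-to-stopper
(28 mm for the built-in FLEX28), first-contact-to-stopper (26.8 mm) and
tip-to-C1 (1.2 mm). Predictions assume a *full insertion* with the stopper
at the round window, so the predicted linear depth at the first contact C1
is 26.8 mm and the angular depth is the model inversion of that length for
the subject's own (A, B); the tip values invert the full 28 mm. C1 is the
validation reference because the bare silicone tip is not visible on
postoperative CT.

```{r}
meas <- tibble::tibble(subject_id = c("s1", "s2"),
                       A_mm = c(9.2, 8.7), B_mm = c(6.8, 6.5))
predict_insertion(meas, model = "both") |>
  select(subject_id, model, angular_c1_deg, angular_tip_deg)
```

Geometries that cannot seat the full array inside the 900-degree domain
yield `NA` with a warning and are excluded from summaries with an explicit
count — partial insertions are represented only on the observed side, never
the predicted side.

## Postoperative validation

Postoperative imaging gives the *angular* depth of C1. `complete_observed()`
turns it into a linear depth by evaluating the chosen model forward at the
subject's own geometry, adds 1.2 mm for the tip, and inverts back for the
tip angle. `prediction_error()` then subtracts, with the sign convention
**actual − predicted**: negative errors mean the prediction overestimated
the achieved depth. `summarize_errors()` reports the mean and sample SD
(n−1; the clinical-literature default) of the *absolute* errors per model
and observer — absolute value taken per record before averaging — together
with signed means that show the direction of systematic misprediction.
`exceedance_report()` summarises how often the achieved insertion exceeds
the prediction, both empirically and under a normal model fitted to the
signed errors (with the conventional one- and two-SD planning tails, about
16% and 2.3%, alongside).

## Observer agreement

* `bland_altman()` uses limits of agreement at the mean difference
  **± exactly 2 SD** (not 1.96 SD) — the convention adopted throughout this
  package's reports and plots.
* `icc_agreement()` computes the intraclass correlation from the two-way
  ANOVA mean squares. The form is **two-way random effects, absolute
  agreement, single measures** (ICC(2,1)) by default: observers are a
  random sample of possible raters, and the clinical question is whether a
  *single* measurement can be trusted in absolute terms. Average-measures
  ICC(2,k) is available via `form = "average"`; the form in effect is
  printed in every report. Qualitative labels use the Landis-Koch bands
  (`agreement_label()`), under which 0.58 is "moderate", 0.74
  "substantial" and 0.90 "almost perfect".
* `compare_method_variability()` asks whether one model yields
  systematically smaller per-subject observer disagreement than the other:
  a two-sided Wilcoxon signed-rank test on per-subject |observer 1 −
  observer 2| values under each model, paired by subject. The published
  comparisons describe testing the *standard deviations* of differences;
  an SD is a single number per group, so the paired construction on
  per-subject absolute disagreements is this package's concrete reading,
  documented rather than asserted as the original procedure.

**Wilcoxon numerics.** For 25 or fewer informative pairs without ties the
exact distribution is used. Beyond that, the usual normal approximation
with continuity correction can deviate from the exact p-value by more than
0.01 around n = 12; ciplanr's large-sample branch therefore adds the
fourth-cumulant Edgeworth term (the signed-rank statistic is symmetric, so
the third-order term vanishes), which keeps the deviation at a few
thousandths from about eight pairs upward and handles ties through midrank
moments. The suite checks this against brute-force enumeration of all sign
patterns.

## The synthetic cohort generator

`generate_cohort()` simulates the study design the analyses expect: 46
subjects, two observers, two observations each. What it emulates, and what
it does not:

* **Anatomy.** True (A, B) from a correlated bivariate normal truncated to
  A ∈ [7, 11], B ∈ [5, 8] mm with A > B enforced by rejection (cap 1000
  redraws), keeping the distribution smooth rather than clipped. The
  defaults (9.1 ± 0.4 mm, 6.8 ± 0.4 mm, correlation 0.5) are package
  assumptions chosen to span the clinical range — no published per-subject
  distribution backs them.
* **Measurement noise.** Per-measurement SDs are back-computed from
  published intra-observer difference SDs via the √2 law (a difference of
  two independent equally noisy measurements has √2 times the
  per-measurement SD): 0.47/0.53 mm (A) and 0.40/0.44 mm (B) difference
  SDs for observers 1 and 2. Observer 2 reads A higher by 0.12 mm and B by
  0.10 mm (the published inter-observer mean differences).
* **Session noise (opt-in).** In the emulated design the inter-observer
  difference SD for A (0.27 mm) is *smaller* than the intra-observer one
  (0.47 mm), which is only possible if part of each measurement's deviation
  is shared between observers within a session. The `session_sd_*`
  parameters inject such a shared component (the values solving the three
  difference-SD equations are about 0.298 mm for A and 0.066 mm for B).
  This is off by default: the default configuration follows the simpler
  independent-noise calibration, because the published agreement pattern
  between the two models' predictions (better for the two-measurement
  model) cannot be produced by any error-propagation model that also
  honours the 0.41 mm inter-observer width SD — propagating 0.41 mm of
  unshared B disagreement through the ECA yields roughly 40 degrees of
  angle disagreement, far above the roughly 17 degrees reported. One of
  those published figures must reflect something the reported SDs do not
  capture; the generator does not attempt to resolve this, and tests that
  target the agreement *pattern* use the independent-noise default.
* **Achieved insertion.** The actual linear depth at C1 is the nominal
  26.8 mm minus a truncated-at-zero normal shortfall, mean 0.58 mm (the
  published mean underestimation of achieved depth) and SD 0.5 mm — chosen
  once so that roughly two SDs span the 1–2 mm error attributed to
  stopper seating in the round-window niche. The corresponding angle comes
  from inverting the *generating model* (ECA by default, configurable) at
  the subject's true geometry, so model-recovery tests have an unambiguous
  ground truth and cross-model evaluation quantifies pure model mismatch.
  Each observer reads that angle with additive noise (SD 8 degrees, a
  package assumption; postoperative repeatability is not published).
* **Not modelled:** CT images and the reslicing workflow, contact-picking
  anatomy, scala height, micro-blockages, electrode bending, malformed or
  ossified cochleae, perimodiolar arrays. Passing tests on this generator
  therefore show that the *pipeline* recovers what it assumes — correct
  algebra, calibration and statistics — not that the models fit real
  cochleae.

All randomness flows through one seed:

```{r}
coh <- generate_cohort(cohort_config(n_subjects = 10), seed = 42)
coh
```

## The full pipeline

```{r}
res <- run_pipeline(coh$measurements, coh$observed, model = "both")
res$error_summary
res$agreement |> select(model, analysis, observer, sd_diff, icc, icc_label)
```

On ECA-generated cohorts the ECA's pooled mean absolute error is smaller
than the spiral model's essentially always (the acceptance suite requires
at least 95 of 100 study-sized seeds), and with a positive shortfall the
signed errors are negative on average — systematic overestimation, the
qualitative signature the validation is designed to detect.

## Problem sizes used by the test suite

Desk-scale checks run on single geometries or grids of a few hundred
points. Distributional properties (√2-law recovery, bias recovery,
noise-monotonicity) use cohorts of 500 subjects; the model-comparison
recovery runs 100 independent 46-subject cohorts. These sizes give the
relevant Monte-Carlo standard errors comfortable margins relative to the
tested tolerances (15% for SD recovery, 2 standard errors for bias
recovery) while keeping the whole suite inside a minute or two.

## Known limitations

* The ECA's nonzero length at 0 degrees is inherited from the published
  fit; depths shallower than `cdl_eca(A, B, 0)` are outside the model.
* Reference-point conversion between tip and C1 requires the subject's own
  (A, B); without geometry columns, tip-level errors must stand in for
  C1-level ones.
* The published per-subject validation table is not redistributed with the
  package, so the exact cohort-level reference values can only be
  recomputed once a user supplies that table
  (`inst/extdata/clinical_per_subject.csv`); the corresponding acceptance
  test reports the data as missing until then.
* The Wilcoxon construction for "which model is more consistent between
  observers" is one defensible reading of an ambiguous published
  procedure; its form is stated in every report.
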