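---
title: "Modelling GCL loss after branch retinal artery occlusion and planning neuroprotection trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling GCL loss after BRAO and planning neuroprotection trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(braotrial)
```

## The problem

Branch retinal artery occlusion (BRAO) infarcts a sector of the inner
retina. The retinal ganglion cell layer (GCL) in the affected sector thins
progressively on spectral-domain OCT, and because ganglion cell axons form
the optic nerve, that thinning is the natural structural endpoint for a
neuroprotection trial. BRAO is rare enough that recruiting is hard, so the
planning question is concrete: *given the natural time course of GCL loss,
how many patients per arm does a trial of a given duration need to detect a
drug of a given efficacy?*

`braotrial` implements that chain as a pipeline:

1. quadrant-resolved layer thicknesses (affected eye vs a reference) →
   percent change,
2. percent change over days since onset → a single-phase exponential decay
   fit,
3. fitted curve + hypothetical drug efficacy → standardized effect size
   (Cohen's d),
4. effect size → minimum per-group sample size for a two-sided two-sample
   t-test.

A synthetic-cohort generator with a known ground-truth ledger makes every
stage testable without patient data.

## Data model and the percent-change statistic

Thickness tables are plain CSV
(`patient_id,eye,status,day,ring,quadrant,layer,thickness_um`): one row per
(patient, eye, visit day, ring, quadrant, layer) mean thickness in
micrometers, on the ETDRS grid's temporal/superior/nasal/inferior quadrants.
Only the inner 3 mm ring takes part in the default analysis; outer-ring rows
are parsed but ignored. Days since occlusion onset are carried directly in
the file, so no date arithmetic happens in the package. Eye laterality
(OD/OS) is metadata only; quadrant codes are already in T/S/N/I terms so no
mirrored-quadrant remapping is applied.

The tracked statistic is

$$\%\,\mathrm{change} = -\,(1 - A/R)\cdot 100,$$

with $A$ the affected-eye and $R$ the reference thickness. Thickening
($A > R$) gives positive values and is retained: the formula admits it and
noise makes it inevitable; clipping would bias fits.

The reference $R$ is the healthy fellow eye when the patient has one
(averaged across its visits), otherwise the quadrant-specific mean of a
normative profile built from healthy eyes. Sources are never mixed within
one (quadrant, layer) cell, and the selection reports which source was used.

The tracked quadrant is the one with the most negative percent change at the
patient's *earliest* scan, then held fixed for all follow-ups; re-selecting
per visit would let noise pick a different quadrant each time and confound
the series. Ties break in the fixed order T < S < N < I. "Most affected" is
operationalized as largest *relative* (percent) loss rather than largest
absolute micrometer loss — a documented package choice, since relative loss
is what the downstream regression consumes.

## The decay model

Percent change versus day is fitted by nonlinear least squares to the
single-phase decay

$$y(t) = (Y_0 - P)\,e^{-kt} + P,$$

where $Y_0$ is the percent change at day 0 (for an acute infarct, close to
the measurement floor of 0 but already negative), $P$ the final plateau
(total sector loss), and $k \ge 0$ the per-day rate. $k$ is bounded at 0:
this is a loss process, not growth.

Numerical choices, all deterministic:

* **Initialisation.** $Y_0$ starts at the mean percent change of the
  earliest quartile of days, $P$ at the mean of the latest quartile, and
  $k$ at $\ln 2 / \mathrm{median}(day)$ (a half-life at the median day).
* **Optimiser.** Levenberg–Marquardt (`minpack.lm::nlsLM`) with relative
  tolerances of 1e-10 and up to 500 iterations, run from the base start and
  five fixed scaled restarts; the lowest-SSE converged solution wins. If
  every start is rejected, a bounded quasi-Newton pass (L-BFGS-B) on the
  same objective is the fallback before an explicit failure — convergence is
  never silently faked.
* **Degenerate inputs.** Fewer than 4 points or a single distinct day is an
  error; an exactly constant series collapses analytically to the $k = 0$
  limit with $R^2$ reported as undefined (SST = 0).
* **Uncertainty.** Standard errors come from the usual NLS linearisation
  $\hat\sigma^2 (J^\top J)^{-1}$.

Fit quality is reported as $R^2 = 1 - SSE/SST$, the residual standard
deviation $S_{y.x} = \sqrt{SSE/(n-3)}$, and an extra-sum-of-squares F-test
against the constant-mean model. $S_{y.x}$ is not a nuisance number here: it
is the scatter of real eyes around the mean course, and therefore the
denominator that converts a projected treatment effect into Cohen's d. The
interpretation of "the standard error of the regression line" as $S_{y.x}$
(rather than the standard error of the mean prediction) is a package
decision; it is the reading consistent with the published sample sizes,
which back-solve to a constant $\sigma \approx 24$ percent-units across all
cells (see below).

## From fitted course to trial size

For a trial of duration $t$ days and a drug of efficacy $e \in [0, 1]$:

* placebo mean = $\hat y(t)$, the fitted natural course;
* treated mean = $(1 - e)\,\hat y(t)$ — full efficacy abolishes all loss,
  zero efficacy leaves the natural course. This linear scaling is the
  simplest mapping consistent with the published grid and is documented as a
  reconstruction, with $\sigma$ an explicit input;
* $d = e\,\lvert\hat y(t)\rvert / \sigma$;
* $n$ per group = smallest integer giving power $\ge$ 0.8 for a two-sided
  two-sample t-test at $\alpha = 0.05$, computed by iterating the exact
  noncentral-t power function (noncentrality $d\sqrt{n/2}$, $2n-2$ df). The
  noncentral-t, not the normal approximation, matters here: the strongest
  cells need only 6–21 patients, where the approximation is off by whole
  patients. The normal approximation and a 50,000-replicate Monte-Carlo
  t-test simulation serve as cross-check oracles in the test suite.

The per-patient framing follows the published design: each patient
contributes one affected and one unaffected eye, but the statistical unit is
the unpaired two-group comparison, as specified there. Paired or crossover
designs, dropout and multiplicity are out of scope.

```{r grid}
curve <- decay_fit(y0 = -9.5, plateau = -55.7, k = 0.01)
sigma <- calibrate_sigma(curve, d_digits = 2)
build_grid(curve, sigma = sigma, d_digits = 2)
```

## Reconstructing a published grid: sigma calibration and rounding

When a published planning table was computed from an unreported residual SD,
`calibrate_sigma()` reconstructs it: scan a fine grid of candidate
$\sigma$ values, rebuild the table for each, and keep the least-squares
match (the objective is piecewise constant because cell counts are integers,
so a deterministic scan with a mid-plateau tie-break replaces smooth
optimisation). A `leave_out` argument excludes a cell from the objective
when that cell is itself the quantity being validated.

Two findings from that reconstruction are worth recording:

* Back-solving $\sigma$ cell by cell gives a narrow band (~23.9–24.8), but
  *no* single unrounded $\sigma$ reproduces every published cell within two
  patients — the implied $\sigma$ intervals of the low-efficacy (large-$n$)
  cells are mutually disjoint.
* If Cohen's d is rounded to two decimals before the sample-size lookup —
  the precision effect sizes are conventionally tabulated at — a single
  $\sigma = 24.2$ reproduces 19 of 20 cells exactly and the last within one
  patient. The package therefore treats two-decimal rounding (`d_digits =
  2`) as the reconstruction mode, while the default (`d_digits = NULL`)
  keeps full precision for prospective planning. An exhaustive search over
  power-function variants and rounding policies found no recipe that
  reproduces all 20 cells exactly, so one-patient discrepancies against the
  published table are expected and documented rather than tuned away.

## The synthetic cohort

`simulate_cohort()` emulates the *structure* of a small retrospective BRAO
series, with all settings bundled in `cohort_params()`:

* 17 patients, 1–5 scans each with a declining count distribution (expected
  total ≈ 38 scans), scan days over 0–1040 days post onset; an optional
  early-weighted schedule concentrates half the scans in the first 100 days
  to mimic denser acute follow-up.
* One lesioned quadrant per patient (BRAO is sector-limited); the affected
  GCL cell follows the true decay curve with additive Gaussian noise *on the
  percent scale* (default SD 24), because that is the scale the regression
  is fitted on; raw micrometers are back-computed from the reference
  thickness. Realized percent change is floored at −99.9 so thicknesses stay
  positive; with the default parameters this touches ~3% of plateau-stage
  draws and is recorded as-is in the ledger.
* The reference eye is drawn once per patient from the normative profile
  and held constant across visits; other affected-eye cells get a small
  percent-scale jitter (`unaffected_noise_sd`, default 1) representing
  measurement repeatability, so "unaffected quadrants scatter around 0%" is
  a testable property rather than an exact identity. Setting it to 0 makes
  the affected eye an exact copy of the reference outside the lesion.
* Between-patient heterogeneity of the decay rate is exposed
  (`between_patient_sd_k`) but defaults to 0: individual patients plainly
  differ (shallow vs steep courses), but no defensible magnitude is
  available, so the generator makes no claim about it.
* The built-in normative profile values (GCL ≈ 50 µm in inner-ring
  quadrants, SDs ≈ 8% of the mean) are configurable placeholders of
  realistic magnitude, not population estimates.

Every cohort ships with a ground-truth ledger (per-scan true and realized
percent change, per-patient rate), and generation is byte-reproducible from
the seed without disturbing the caller's RNG.

What the generator does *not* emulate — and what passing tests therefore do
not show about real data: segmentation error structure, reperfusion and
acute-vs-chronic dynamics, co-morbid thinning or thickening (diabetic
retinopathy, AMD), correlated multi-quadrant involvement, and within-patient
serial correlation beyond the shared curve. Real aggregate data will fit
more loosely than the generator's homoscedastic Gaussian world.

## Validation scales

The test suite validates the chain at the study's own scale, chosen as the
smallest sizes at which the checks are sharp: parameter recovery uses 200
replicates of 500-point series (each parameter within 3 estimated SEs of
truth in ≥90% of replicates); the fitted-vs-simulated power comparison uses
50,000 Monte-Carlo t-test replicates at d ∈ {0.3, 0.5, 0.8, 1.2} with
agreement within one patient; grid reproduction covers all 20 published
cells within two patients. Noiseless series must be recovered to at least
six significant figures — nonlinear optimisation, but an exact-interpolation
problem.

## Known limitations

* Pooling all patients into one aggregate regression treats scans as
  independent; a mixed-effects decay model would respect repeated measures
  but is deliberately out of scope (the planning chain is defined on the
  aggregate fit).
* $\sigma$ enters the effect size as a constant; duration-dependent scatter
  would change the long-trial cells.
* The efficacy model is a proportional scaling of mean loss; a drug that
  delays rather than scales loss (changes $k$, not the endpoint mean) needs
  a different treated-mean mapping.
* The most-affected-quadrant rule is measured at the noisiest (earliest,
  single-scan) moment; with heavy noise it can track a quadrant other than
  the true lesion. That is a property of the rule itself, faithfully
  reproduced.
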