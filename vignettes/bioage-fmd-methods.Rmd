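---
title: "Methods: biological age, Gompertz mortality and the FMD lifecourse simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: biological age, Gompertz mortality and the FMD lifecourse simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bioagefmd)
```

# What this package computes

`bioagefmd` implements an analysis chain for evaluating a periodic
fasting-mimicking diet (FMD) intervention through the lens of biological
age:

1. **KDM biological age** from a panel of seven clinical chemistry
   biomarkers (albumin, alkaline phosphatase, serum creatinine, CRP,
   HbA1c, systolic blood pressure, total cholesterol).
2. **Gompertz proportional-hazard mortality models** turning a
   biological/chronological age pair into median remaining life expectancy
   and 20-year (cause-specific) mortality risk.
3. A **lifecourse microsimulation** of three FMD cycles repeated annually
   until age 70, driven by two published linear response surfaces.
4. **Trial statistics**: exact/asymptotic Wilcoxon signed-rank change
   tests, biweight midcorrelation, responder logistic regression, HOMA-IR
   and the lymphoid-to-myeloid ratio.
5. **Synthetic cohort generators** with known ground truth, so that every
   stage is testable end to end without access to survey or trial data.

# The KDM biological age estimator

Each biomarker is modelled in a reference population as linear in
chronological age, $x_j = q_j + k_j \, \mathrm{age}$, with residual scale
$s_j$. For a person with panel $x_1,\dots,x_m$ and chronological age
$CA$, the estimator is the precision-weighted combination

$$
BA_{EC} \;=\;
\frac{\sum_{j=1}^{m} (x_j - q_j)\,k_j / s_j^2 \;+\; CA / s_{BA}^2}
     {\sum_{j=1}^{m} (k_j/s_j)^2 \;+\; 1 / s_{BA}^2},
$$

where $s_{BA}^2$ is the variance of the deviation of biological from
chronological age. Each term $(x_j - q_j)/k_j$ is the age implied by one
marker; the estimator is a weighted mean of the $m$ implied ages and $CA$,
with weights $(k_j/s_j)^2$ and $1/s_{BA}^2$.

**Regression direction.** The estimator has its defining identity --- a
person lying exactly on every regression line scores $BA_{EC} = CA$ ---
only when each *marker is regressed on age* (slope $k_j$ in marker units
per year). Method descriptions in the applied literature sometimes state
the reverse direction; we fit marker-on-age, which preserves the identity
and matches the original Klemera–Doubal construction. The identity is
enforced to $10^{-10}$ years in the test suite, alongside invariance to
marker ordering and to positive rescaling of any marker (both are exact
algebraic properties of the formula).

**$s_{BA}^2$ estimation.** The quantity is defined only verbally in the
applied literature. We estimate it as the empirical variance over the
reference cohort of $BA_E - CA$, where $BA_E$ is the marker-only
estimator (the same formula without the $CA$ term). A fixed override is
accepted for users who want to reproduce a published parameter set
exactly. Under independent marker noise the theoretical value is
$1/\sum_j (k_j/s_j)^2$, which `kdm_truth_from_model()` uses.

**CRP scale.** No transformation is applied by default; an optional
natural-log transform (`log_crp = TRUE`) is provided because parts of the
method literature log-transform CRP. The flag is stored with the fitted
parameters so scoring always matches fitting. No winsorizing or other
marker transformation is applied; missing markers are refused rather than
imputed, because the weights assume a complete panel.

**Weight adjustment.** To express a follow-up biological age "assuming no
change in weight", follow-up biological age (or the change in biological
age, `variant = "change"`) is regressed on the change in body weight by
OLS, and the per-person residuals are re-centered at the cohort mean
response. A constant weight-change vector leaves the regression undefined
and is an error.

**Responder classification.** A *non-responder* (flag 1) is a participant
whose biological age *strictly* increased from baseline to follow-up;
exact ties count as response, reading "increased" strictly.

# Gompertz proportional-hazard mortality

The hazard is $h(t) = \lambda\, e^{\gamma t}$ with a person-level scale
$\lambda = \exp(\beta_{Age}\,Age + \beta_{BioAge}\,BioAge\; [+\,
\beta_{Weight}\,Weight] + c)$, giving the survival function

$$
s(t) = \exp\!\left\{ \frac{\lambda}{\gamma}\left(1 - e^{\gamma t}\right) \right\}.
$$

Parameters are estimated by maximizing the right-censored log-likelihood
$\sum_i \delta_i(\log\lambda_i + \gamma t_i) +
(\lambda_i/\gamma)(1 - e^{\gamma t_i})$ with BFGS and an analytic
gradient. Numerical choices: $\gamma$ is unconstrained but initialized at
0.1/year; the cumulative-hazard factor switches to a series expansion for
$|\gamma t| < 10^{-6}$ so the exponential limit $\gamma \to 0$ is handled
smoothly; non-convergence triggers jittered restarts and ultimately an
error, never a silent partial fit. The fit is cross-checked in the test
suite against an independent Gompertz implementation (`flexsurv`) on
simulated data, and parameter recovery from a known truth (n = 20,000) is
required to be within 10% for every coefficient.

*Median remaining life expectancy* solves $s(t) = 0.5$ by bracketed root
finding; the closed form $t = \gamma^{-1}\log(1 - (\gamma/\lambda)\log
0.5)$ exists and serves as an independent oracle (agreement to $10^{-8}$
years over randomized parameter grids). *20-year mortality risk* is
$1 - s(20)$.

*Competing risks* are implemented as cause-specific hazards: a model for
one cause treats deaths from other causes as censored. This choice (rather
than a subdistribution/Fine–Gray model) matches the survival machinery
above, which the cause-specific fits simply reuse. When a weight term is
included and "no weight change" scenarios are evaluated, baseline weight
enters both the baseline and follow-up hazard scales, so the contrast
isolates the biological-age change.

*Relative reduction* between a baseline and follow-up risk is
$100\,(p_0 - p_1)/p_0$, reported to one decimal by default (configurable,
to match the precision a given figure is quoted at).

# The FMD lifecourse simulation

Each simulated year has three anchor points: **A** (start of year),
**C** (after three monthly FMD cycles, about 3 months in), **D** (after
the rebound on a normal diet; carried to the next year as its point A).
Two published OLS response surfaces drive the updates:

$$
\Delta_{A \to C} = 0.1017 - 0.1906\,BioAge + 0.1227\,Age,
$$
$$
\Delta_{C \to D} = 0.6687 - 0.5567\,BioAge_A + 0.4008\,BioAge_C + 0.1157\,Age .
$$

Chronological age advances one year per iteration; "Age" in both surfaces
is the age at point A of the current year (the natural reading; the
source description does not state it explicitly).

**Closed-form oracle.** Composing the two surfaces gives an affine
one-year map $B_{y+1} = a B_y + b A_y + c$ with
$a = 0.57710752$, $b = 0.28757816$, $c = 0.81116136$. The iterative
engine must match this recurrence at every year to $10^{-10}$, and the
annual increment converges geometrically to the fixed-point slope
$b/(1-a) \approx 0.6800$ years of biological age per chronological year,
independent of the starting state.

Note: summaries of this kind of simulation sometimes quote a stabilized
rate of about 0.85 years/year. The deterministic fixed point of the
coefficients above is $\approx 0.680$, and no choice of decay mode,
weighting, or starting state changes that asymptote; reproducing 0.85
would require the unpublished coefficient uncertainties or figure-level
summarization choices. The package therefore documents its computed value
and does not force agreement.

**Decay sensitivity.** The published sensitivity analysis shrinks the
effect in later years, described as "dividing by 2 multiplied by years
since baseline" with worked examples of one half in year 2 and one
quarter in year 3. Formula and examples agree at years 1–2 but diverge
afterwards ($1/(2y)$ vs $1/2^y$, i.e. 1/6 vs 1/8 at year 3). Both
readings are implemented (`"linear"`, the literal formula, is the decay
default; `"doubling"` matches a geometric reading); the divergence is
asserted in the tests rather than silently resolved. The decay multiplies
both the cycle and the rebound change, since the description does not
distinguish them; `one_year_update()` exposes a flag to decay the cycle
change only.

**Uncertainty and survey weighting.** Coefficient standard errors default
to zero because they are not published; the simulation is then fully
deterministic, independent of the seed, and every Monte Carlo draw is
identical (the engine short-circuits the draw machinery in that case).
With standard errors supplied, coefficients are redrawn per draw from
$N(\hat\beta, SE)$. Survey weights select how many draws contribute to a
person's mean trajectory: $k = \mathrm{round}(w / 548.5)$, rounded half
away from zero and clamped below at 1 so every person contributes at
least one draw (published weights range from 6 to 1000 after this
division; the clamp is our choice for out-of-range synthetic weights).
Requesting more draws than were simulated is an error. Mortality during
the simulated period is deliberately ignored — trajectories are
conditional on survival — so late-life biological ages should be read as
conditional projections, not population forecasts.

# Synthetic data: what it emulates and what it does not

The generators reproduce exactly the structure the analysis assumes:

- ages uniform on a configurable range (default 30–90), the simplest
  distribution satisfying the linear-in-age marker model;
- markers on their age lines plus *independent* Gaussian noise. The joint
  covariance among the seven markers in real populations is not emulated
  (flagged; configurable only through the per-marker noise scales);
- mortality from the Gompertz law via exact inversion
  $t = \gamma^{-1}\log(1 - (\gamma/\lambda)\log u)$, right-censored at a
  fixed horizon (default 23 years), with causes assigned by a
  configurable multinomial (defaults roughly matching the adult US
  cause-of-death mix);
- survey weights log-normal on the divisor scale (median near
  $148 \times 548.5$), floored at 1, so that division by 548.5 spans
  roughly 6–1000;
- trial cohorts as paired baseline/follow-up panels with signed
  per-marker intervention effects, follow-up measurement noise at half
  the cross-sectional scale, a configurable fraction of sign-flipped
  "constructed non-responders", and a normal weight-change distribution
  (default mean −2.5 kg, SD 2 kg, a modest loss typical of three diet
  cycles).

Default marker lines (intercept, slope/year, noise SD) are plausible
adult cross-sectional trends: albumin (4.90 g/dL, −0.010, 0.20), alkaline
phosphatase (55 U/L, +0.50, 10), creatinine (0.70 mg/dL, +0.004, 0.08),
CRP (0.20 mg/L, +0.040, 0.80, raw scale), HbA1c (4.70%, +0.015, 0.30),
systolic BP (95 mmHg, +0.60, 12), total cholesterol (150 mg/dL, +1.00,
20). The noise scales are set so each marker line is individually
informative at the reference sizes used in validation (slope standard
error about 1.6% of the slope at n = 5000, making the 5% recovery check a
3-sigma band), which implies $s_{BA} \approx 7.9$ years. Real
cross-sectional populations are noisier per marker; fitting them to the
same precision requires correspondingly larger reference samples. Passing
tests on these cohorts therefore demonstrates correctness of the
estimators and solvers under the model's own assumptions — not that real
NHANES marginals, marker correlations, or missing-data patterns are
captured.

Because the KDM score is a weighted mean of marker-implied ages *and*
chronological age, a marker shift "worth" $\Delta$ years along every line
moves the score by only $\Delta \cdot w/(w + 1/s_{BA}^2)$ with $w =
\sum_j (k_j/s_j)^2$ (exactly $\Delta/2$ when $s_{BA}^2$ takes its
theoretical value). `marker_effects_for_bioage_shift()` inflates the
marker effects by the inverse of this attenuation by default, so a
requested −2.5-year intervention produces a −2.5-year change in *scored*
biological age.

# Trial statistics

- **Paired change test**: the trial design is paired, so the primary test
  is the Wilcoxon *signed-rank* on paired differences (some reports label
  such tests "rank sum"; the two-sample rank-sum variant is available via
  `paired = FALSE`). Zero differences are dropped. For up to 12 nonzero
  differences the null is enumerated exactly over all $2^n$ sign
  patterns; beyond that a normal approximation with tie, continuity, and
  Edgeworth (fourth-cumulant) corrections is used, keeping the
  exact-vs-asymptotic discrepancy near $10^{-3}$ in p at the crossover.
- **Biweight midcorrelation**: median-centered, MAD-scaled with the
  standard 9×MAD cap; observations at or beyond the cap get zero weight.
  Zero MAD is an error unless a Pearson fallback is requested. P-values
  use the t-approximation with $n-2$ degrees of freedom (a permutation
  alternative was considered; the t-approximation matches common usage
  and is what the correlation's p-values are interpreted against here).
- **Responder logistic regression**: IRLS maximum likelihood with Wald
  tests; perfect separation is detected (fitted probabilities pinned at
  0/1) and reported as an error naming the suspect covariate. The
  implementation is cross-checked against `glm()` and against the
  closed-form 2×2 odds ratio, and its type-I error is calibrated by
  simulation.
- **Clinical indices**: HOMA-IR = glucose × insulin / 405 (mg/dL ×
  µU/mL); lymphoid-to-myeloid ratio = lymphocytes / (neutrophils +
  monocytes) by default, since the ratio's denominator is not defined
  uniformly in the literature — eosinophils and basophils can be included
  by flag.

# The pipeline

`run_pipeline()` sequences the stages with a single seed: generate
reference population → fit KDM → generate and score the trial → fit
all-cause and cause-specific Gompertz models → per-person life expectancy
and risk at baseline vs follow-up with relative reductions → responder
classification, paired change test, weight adjustment → optional
lifecourse simulation. Outputs written by `write_cohort()` carry a JSON
sidecar with the seed and a configuration hash. The at-risk filter keeps
participants with at least one of: BMI > 25, CRP > 1.0 mg/L, fasting
glucose > 99 mg/dL, systolic BP ≥ 130 mmHg — the CRP and blood-pressure
cutoffs are not universally defined, so they are explicit, documented
arguments.

Default problem sizes (reference n = 4000, trial n = 52, simulation on a
200-person subsample with a single deterministic draw) keep a full run in
seconds while leaving every estimate comfortably inside its validated
tolerance band; all sizes are arguments.

# Known limitations

- Marker noises are independent; real biomarker panels are correlated,
  so synthetic cohorts understate the redundancy among markers.
- Cause-specific hazards, not subdistribution hazards: cause-specific
  20-year "risks" do not sum to the all-cause risk in the presence of
  competing events.
- The lifecourse simulation extrapolates two short-horizon linear
  response surfaces over decades and ignores mortality; under geometric
  decay the late trajectory freezes (biological age stops changing while
  chronological age advances), which is an artifact of the stated model,
  not a biological claim.
- Absolute life-expectancy levels depend on the mortality coefficients
  used; the reference coefficients behind published absolute values (for
  example a median life expectancy near 83 years) are not published, so
  only *contrasts* (gains, relative reductions) are meaningful here.
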