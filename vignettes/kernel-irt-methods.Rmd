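---
title: "Kernel-smoothed IRT for rating-scale shortening: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kernel-smoothed IRT for rating-scale shortening: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ksirt)
```

## The measurement model

`ksirt` treats a polytomous rating-scale subscale (J items, ordered options
`option_min..option_max`) as a set of nonparametric item response functions
over a single latent severity. No parametric curve family is assumed;
instead every quantity is a kernel-weighted average over a rank-based
severity estimate.

**Latent scores.** Subjects are ordered by their subscale summed score
$S_i$; mid-ranks $r_i$ (ties averaged) map to
$\hat\theta_i = \Phi^{-1}\!\big(r_i/(N+1)\big)$. The $N+1$ denominator keeps
quantiles strictly inside $(0,1)$, so no subject receives an infinite score;
tied summed scores share one $\hat\theta$, and $\hat\theta$ is nondecreasing
in $S$. By construction $\hat\theta$ is (discretely) standard normal
whatever the raw score distribution looks like — severity is measured on
the normal-quantile metric.

**Option characteristic curves.** For item $j$ and option $m$,
$$\hat P_j(m\mid\theta_q)=
\frac{\sum_i K\!\big((\theta_q-\hat\theta_i)/h\big)\,\mathbf 1[x_{ij}=m]}
     {\sum_i K\!\big((\theta_q-\hat\theta_i)/h\big)},$$
with $K$ the standard Gaussian kernel, evaluated on an equally spaced grid
(default 51 points on $[-3,3]$). Probabilities at each grid point are
nonnegative and sum to one by construction. Derived curves:

* ICC: $e_j(\theta)=\sum_m m\,\hat P_j(m\mid\theta)$ with conditional
  variance $v_j(\theta)$;
* expected subscale score $T(\theta)=\sum_j e_j(\theta)$, passed through an
  isotonic projection (`stats::isoreg`) because sampling noise can produce
  local decreases and the linking step requires a monotone $T$;
* item information $I_j=(e_j')^2/v_j$ (derivatives by central differences,
  one-sided at the grid ends; defined as 0 where $v_j=0$, which forces
  $e_j'=0$), averaged over items for the subscale information curve;
* score density: a Gaussian kernel density of $\hat\theta$ transformed to
  the score axis by $f_X(T(\theta))=f_\theta(\theta)/T'(\theta)$ and
  renormalized to integrate to one (trapezoid rule) — the transform errors
  if $T$ is flat anywhere, with advice to widen the bandwidth;
* summed-score standard error $\sqrt{\sum_j v_j(\theta)}$, the conditional
  SD of the summed score (about 3 for a typical 7-item subscale); an
  information-based variant $1/\sqrt{J\bar I}$ sits behind
  `se_method = "information"`.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `bandwidth` | $1.1\,N^{-1/5}$ | kernel SD on the $\theta$ scale; the standard rate-optimal choice for standard-normal latent scores (≈ 0.21 at $N\!\approx\!3600$). Larger values bias curves toward their mean, smaller values add variance. |
| `grid` | 51 points on $[-3,3]$ | evaluation range of the severity metric; $\pm 3$ covers 99.7% of a normal population |
| `p_flat` | 0.3 | criterion 2: an item whose non-extreme option curves never exceed this is rated No |
| `tau` | 0.05 | criterion 4: an option's support is where its curve reaches at least this probability |
| median option | midpoint of the option range (4 for 1–7) | where the criterion-5 slope is read off |

Slopes are taken with respect to $\theta$ (the normal metric), not the
expected-score axis: typical well-behaved items then have slopes of a few
tenths to ~1, and the 0.40 retention cut is meaningful; on the raw-score
axis all slopes would collapse toward $1/J$.

## The five selection criteria

The published procedure rated items by visual inspection of the curves;
`ksirt` fixes deterministic operationalizations (all thresholds
overridable):

1. **Options used** — the number of option levels reached by the ICC
   maximum, $\mathrm{round}(\max_q e_j)-\mathrm{option\_min}+1$; Yes iff ≥ 5.
2. **Rapid increase** — No when every non-extreme option curve stays at or
   below `p_flat`, or no option's probability ever doubles along the grid;
   Yes when a majority of above-floor options reach half their maximum at or
   below the median expected score (the severity of the median subject,
   $\theta=0$ under rank-normal scoring); otherwise Somewhat (rises occur
   only above the median).
3. **Ordered modal regions** — each option's modal region (where it is the
   argmax) must sit between its neighbours'; empty or out-of-order regions
   are violations. Yes = 0, Somewhat = 1–4, No ≥ 5.
4. **Span** — an option is displaced when its support is empty, or (two
   lowest options) lies entirely above the 25th percentile of the achievable
   expected-score range, or (two highest) entirely below the 75th; No when
   ≥ 4 options are displaced.
5. **Slope** — Yes iff the ICC slope at the median option is ≥ 0.40
   (inclusive).

**Classification.** Very Good with ≥ 4 Yes, Good with exactly 3, Weak
otherwise; Somewhat carries no weight and no criterion is a veto. This
Yes-count rule is not spelled out in the published tables but is the unique
simple rule consistent with all 30 printed rating rows (a retained item
with a No on criterion 5 confirms there is no veto); the test suite locks
that agreement at 30/30. Non-Weak items form the short scale, preserving
subscale membership; a subscale that would lose all items is an error.

## Synthetic cohorts

The generator is a logistic graded response model:
$P(m\mid\theta)=L\!\big(a(\theta-b_m)\big)-L\!\big(a(\theta-b_{m+1})\big)$
with ordered cumulative thresholds. The published analysis fits no
parametric model; the GRM is used because it produces exactly the ordered,
unimodal-region option geometry the method expects from a healthy item, and
it gives a closed-form oracle for recovery tests.

Archetypes (`make_archetype`):

* **ideal** — $a=1.8$, thresholds equally spaced over $[-2,2]$: every
  option owns a well-separated severity region.
* **flat** — $a=0.3$ with only the lower option boundaries inside the
  observable range: the used options' curves are nearly level and the upper
  options are essentially never endorsed. This mirrors how
  non-discriminating items present in real rating data — flat *and*
  range-restricted. A purely flat geometry with evenly spread thresholds
  was rejected: because each subject's own response is part of the ranking
  score, a high-variance junk item acquires a spurious estimated slope and
  ICC range at the grid edges (top-ranked subjects are top-ranked partly
  *because* they endorsed high options on the junk item), and such an item
  would not reliably classify Weak.
* **ceiling_compressed** — top threshold at 3.8: the extreme option is
  endorsed with probability < 0.05 even at $\theta=2$, mimicking the rarely
  used "extreme" rating.
* **disordered_regions** — low discrimination plus near-coincident interior
  thresholds: cumulative thresholds stay ordered (a GRM requirement) but
  interior options lose their modal regions, which is what criterion 3
  penalizes.

`panss_cohort_config()` builds a 30-item cohort with mildly varied
ideal-type items, top thresholds pushed up (the extreme option is rare), and
a right-skewed severity distribution — a skew-normal with shape 4, location
−0.8, scale 1.4, chosen once so that high summed scores are rarer than low
ones, as in trial populations. Covariates (age, gender, diagnosis, race),
when requested, are drawn independently of severity with category
frequencies typical of schizophrenia trial baselines.

**What the generator does not emulate:** rater effects and rater drift,
longitudinal structure, treatment arms, local item dependence beyond the
single factor, and the real instrument's multidimensionality (the real
General Psychopathology subscale fails the eigenvalue-ratio rule; an
all-ideal synthetic subscale passes it). Passing recovery and
classification tests on these cohorts therefore shows the estimator and the
criteria behave as specified under a known one-factor truth — not that the
published item-level ratings would be reproduced from clinical data, which
remain proprietary and are shipped only as printed-table fixtures.

**Metric alignment.** Recovery tests compare estimated curves with
generator curves point-by-point, which is meaningful only when the
generator trait is standard normal (the rank-based $\hat\theta$ is normal
by construction). Cohorts used for recovery and archetype-classification
checks therefore set `severity = normal(0, 1)`; the skewed default is used
everywhere the comparison is within the fitted metric.

## Numerical choices

* Rank ties: mid-ranks, so tied summed scores share one latent score.
* Derivatives: central differences in the grid interior, one-sided at the
  ends; exact for linear curves including the endpoints.
* Criterion-5 evaluation point: the grid point where $|e_j - 4|$ is
  minimal, ties broken toward lower severity.
* Score-function inversion: linear interpolation between bracketing grid
  points; a score on a flat segment resolves to the segment's severity
  midpoint; out-of-range scores clamp to the nearer end with a warning.
* Conversion tables: integer short-form scores over the achievable range
  $[\lceil\min T\rceil, \lfloor\max T\rfloor]$; mapped scores rounded
  half-up, matching published integer tables.
* Validation subjects whose short-form score falls outside the table are
  matched to the nearest row and counted.
* Split halves: $\lceil N/2\rceil$ evaluation / $\lfloor N/2\rfloor$
  validation, deterministic under the seed; cohort simulation derives
  per-stage child seeds from one master seed.
* Cleaning precedence: a row matching several removal reasons is tallied
  under diagnosis first, then missingness; tallies always reconcile with
  input = retained + removed.

## Design choices where the method was open

* **Item–total correlation** is the ordinary Pearson correlation of item
  score with subscale summed score; the traditional "biserial" label in
  this literature refers to this exploratory statistic, not the
  dichotomous-variable biserial formula (the items have seven levels).
* **PCA** runs on the Pearson correlation matrix (unrotated), which is the
  scale on which published eigenvalues (summing to the item count) live;
  polychoric PCA is deliberately not the default.
* **Unidimensionality** is declared at an eigenvalue ratio ≥ 3, inclusive
  — a published ratio of 3.005 counted as unidimensional, which pins the
  boundary down.
* **Linking route**: expected-score inversion through the common severity
  grid. A posterior-mean (EAP) summed-score method exists in parametric
  IRT, but the kernel approach supplies exactly one monotone expected-score
  function per form, so inversion plus interpolation is the route fully
  determined by the machinery here; pattern-scoring EAP is out of scope.
* **Short-form scoring** re-estimates latent scores from the short form's
  own summed scores (self-contained), rather than reusing full-form ranks.
* **Interfaces**: the pipeline is exposed as R functions
  (`run_pipeline()`, `render_report()`) plus the `scripts/acceptance.R`
  entry point; both write TSV/JSON outputs, so shell-level orchestration
  adds nothing over calling the functions.

## Problem sizes used in validation

Unit and property tests run on cohorts of 400–3,000 subjects; curve
recovery and archetype stability use N = 3,000 (ten seeds); the
cleaning/splitting and linking checks use cohorts of 7,348 and 7,187
subjects, mirroring the sample sizes of the motivating study. On these
sizes the whole estimation stack is vectorized dense linear algebra
(51-point grid × N kernel weights) and a full pipeline run takes well under
a second.

## Known limitations

* Estimates at the extreme grid ends rest on few subjects; curve values and
  slopes read off near $|\theta| \gtrsim 2.5$ are noisy, and because each
  item participates in its own ranking score, junk items show spurious
  discrimination there (see the flat-archetype note above).
* Criteria 2–4 are deterministic surrogates for what were expert visual
  judgments; agreement with the published ratings is asserted via the
  printed tables, not re-derivable from data.
* Listwise deletion only; no imputation of missing item scores.
* One option range per instrument; no per-item option ranges, no rater
  model, no differential item functioning.
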