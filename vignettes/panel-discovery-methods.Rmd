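---
title: "Methods: longitudinal MoM normalization and parsimonious LDA panel discovery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: longitudinal MoM normalization and parsimonious LDA panel discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Early preeclampsia (diagnosed and delivered before 34 weeks of gestation) is
preceded by changes in the maternal plasma proteome, but plasma protein
abundance also changes physiologically with gestational age (GA). A
longitudinal case-control design — repeated plasma samples at roughly
4-week prenatal visits, profiled on a high-plex affinity assay — therefore
needs two things before any marker can be judged: a normalization that makes
a 10-week sample comparable to a 30-week sample, and an evaluation scheme
that does not reward a marker-selection procedure for having seen the test
patients. `pepanel` implements both, plus the downstream differential
abundance and enrichment analyses, as a reusable pipeline over a cohort
table (`patient, GA at sample, GA at diagnosis, group flags, one column per
protein`).

# Multiples of the mean (MoM)

Raw relative-fluorescence values are first thresholded: per protein, values
above twice the 98th percentile of all samples are reset to that ceiling
(the linear-interpolation quantile estimator; the ceiling is stored and
replayed on new data). After `log2` transform, each protein's control-group
abundance is modeled as

$$ y_{ij} = \mu_g(\mathrm{GA}_{ij}) + b_i + \varepsilon_{ij}, \qquad
   b_i \sim N(0, \tau_g^2), \; \varepsilon_{ij} \sim N(0, \sigma_g^2), $$

where $\mu_g$ is a cubic regression spline and $b_i$ a per-patient random
intercept, fitted by REML (`lme4`). The MoM value of any sample — case or
control — is $2^{\,y - \hat\mu_g(\mathrm{GA})}$: the ratio of the observed
abundance to the expected abundance at the same GA in normal pregnancy (a
geometric-mean reference, since the fit is on the log2 scale). Curves are
fitted once on controls and frozen; case samples never influence the
reference. Downstream analyses work on log2 MoM.

Numerical choices worth knowing:

* "Cubic splines, 3 knots" is realized as 3 *interior* knots at the
  25/50/75% quantiles of control-sample GA, boundary knots at the observed
  control GA range. Predictions outside that range are clamped to the
  boundary (with a warning) rather than extrapolated.
* The random-effects structure is a subject intercept only — the minimal
  structure consistent with repeated measures; random slopes or penalized
  smoothers are deliberately not fitted.
* A protein whose mixed-model fit fails (constant abundance, singular fit)
  falls back to ordinary spline least squares with $\tau^2 = 0$, with a
  warning.

# Interval views

Analyses run per gestational-age interval: 8–16, 16.1–22, 22.1–28, 28.1–32
(and optionally 32.1–36) weeks. Membership is half-open $(\ell, u]$ with the
first interval closed at 8; values in the typographic gaps (16.05) join the
upper interval, reading the printed ".1" bounds as display precision of a
continuous variable. Case samples at or after the GA at diagnosis are
censored (strict inequality). When a patient has several eligible samples in
one interval, the one closest to the interval midpoint — computed from the
printed bounds, e.g. $(22.1+28)/2 = 25.05$ — is used, ties to the earlier
sample. The midpoint rule is this package's convention: it is deterministic
and symmetric, and the original analysis did not state its rule.

Four contrasts label patients case/control/excluded: all early-PE cases vs
normal pregnancy; only cases with placental maternal-vascular-malperfusion
(MVM) lesions; only severe cases; and early PE vs the combined group of
normal pregnancies and late-PE cases.

# Panel selection

Within an interval view (one sample per patient):

1. **Filter**: proteins whose case/control arithmetic mean MoM ratio differs
   from 1 by less than 10% are dropped (boundary inclusive).
2. **Rank**: for each surviving protein, a linear discriminant (pooled
   within-class covariance; the raw discriminant projection is the risk
   score, since class priors do not move ROC metrics) is fitted with one
   patient left out at a time; the out-of-fold scores give the partial AUC
   over false-positive rates below 50% (unnormalized, in $[0, 0.5]$).
   Proteins are ranked by pAUC, ties by AUC, then identifier — fully
   deterministic.
3. **Grow**: candidate models are the nested top-1, top-2, …, top-5 prefix
   sets of that ranking. Size $k+1$ is accepted only if its leave-one-out
   pAUC improves on size $k$ by at least 0.01 (on the unnormalized scale;
   the McClish-normalized alternative would halve the effective bar and can
   be emulated with `gain = 0.005`). Selection stops at the first rejection.
4. **Refit** the accepted set on all patients of the view.

Degenerate pooled covariances (a constant feature inside a fold) are ridged
by $10^{-8}\,\mathrm{tr}(S)/p$. Sensitivity is reported at the largest
achievable empirical FPR not exceeding 10% — a conservative step-function
reading, which is why achieved specificities come out slightly above 0.90.

**A consequence of the unnormalized gain scale.** The pAUC over FPR < 0.5 is
bounded by 0.5, so once a panel is strong the next marker cannot add much
area: three independent markers of 1 log2-unit shift (per-sample sd 0.5)
already reach a noiseless pAUC of 0.493, leaving at most 0.007 — below the
0.01 bar — for a fourth equally strong marker. Parsimony is the intended
behavior of the rule, but it means inclusion percentages concentrate on the
top 2–3 markers of an interval; no selection rule tweak is applied to
counteract this.

# Resampling evaluation

The *entire* pipeline above (filter, rank, grow, refit) reruns inside every
training set of an outer resampling loop, so reported performance carries no
selection optimism:

* **Bootstrap** (200 iterations): cases and controls are resampled
  separately with replacement to their original sizes; out-of-bag patients
  form the test set; iterations whose out-of-bag set lacks a class are
  redrawn (the count is logged) so the number of iterations stays fixed.
* **Repeated cross-validation**: 67 repeats of stratified 3-fold CV give
  exactly 201 train/test pairs; fold sizes per class differ by at most one.

A master seed spawns per-iteration substreams, making every iteration
reproducible in isolation and the report a pure function of (view,
parameters, seed). Aggregates are means with empirical 2.5/97.5-percentile
intervals; per-protein inclusion frequencies (share of iterations whose
accepted panel contains the protein) are reported at the inclusive 10%
threshold.

# Differential abundance

Per interval, log2 MoM is regressed on group plus BMI, smoking status,
maternal age and nulliparity (linear terms; the covariate table is optional,
and its absence degrades to the unadjusted comparison with a warning).
Residual variances are pooled across the interval's proteins with the
scaled-inverse-chi-square empirical-Bayes model: the prior degrees of
freedom $d_0$ and prior variance $s_0^2$ come from moment matching of
$\log s_g^2$ via the digamma/trigamma identities (with a Newton
trigamma-inverse), and the moderated statistic
$t_g = \hat\beta_g / (\tilde s_g \sqrt{v_g})$ with
$\tilde s_g^2 = (d_0 s_0^2 + d\, s_g^2)/(d_0 + d)$ is referred to a
$t_{d_0+d}$ distribution. This machinery is implemented in the package
(limma serves as an independent cross-check in the test suite, where the
two agree to $10^{-8}$). Benjamini–Hochberg q-values are computed within
each interval-by-contrast family; significance is q < 0.1. Fold changes are
reported in the signed linear convention: $2^\beta$ for $\beta \ge 0$, else
$-2^{-\beta}$.

# Enrichment

Significant proteins are tested for over-representation in annotated term
sets (GMT input) against the full assay panel as background: upper-tail
hypergeometric p-values (one-sided, as only enrichment is of interest), BH
q-values across all tested terms, and the plain cross-product odds ratio
with infinities flagged rather than continuity-corrected. A term is called
only with at least 3 hits and q < 0.1. Annotation is taken as provided — no
ontology-graph propagation, no live downloads.

# The synthetic cohort generator

Because the real assay data cannot be redistributed, a generator emulates
the study conditions so every stage is testable end to end: 33 cases / 90
controls (24 flagged MVM, 23 severe), enrolment at 8–12 weeks, visits every
4 ± 0.5 weeks until delivery with 2–6 profiled samples per patient (counts
skewed low, echoing the reported medians of 3 pre-diagnosis samples for
cases and 2 for controls), case diagnosis GA uniform on 24.6–33.4 weeks
with delivery before 34 weeks, and controls delivering around 39.5 weeks.
Post-diagnosis samples are generated and flagged so the censoring path is
exercised.

Abundances are $2^{\,\text{baseline}_g(\mathrm{GA}) + b_{ig} + \text{effect} +
\varepsilon}$: per-protein baselines mix constant, linear and smooth
log2-scale GA curves; subject intercepts $b_{ig}$ are drawn per protein
(matching the per-protein mixed model — an earlier shared-intercept variant
induced cross-protein correlation that visibly biased null group
differences); $\tau = 0.3$ and $\sigma = 0.4$ log2 units are the package's
conventions, stated in all reports. Case effects enter directly on the log2
MoM scale and ramp linearly from an onset GA, mimicking late-diverging
trajectories. The default plants four markers of shift 1.0 with onsets
0/10/14/16 weeks and 4-week ramps (all fully active from 20 weeks); equal
shifts were chosen so that marker-recovery properties reflect the selection
machinery rather than a favorable effect-size ordering. The ground truth
records the planted markers and the closed-form oracle AUC
$\Phi\!\left(\lVert\text{shift}\rVert / \sqrt{2(\tau^2+\sigma^2)}\right)$
per interval (exact where markers are fully active).

What the generator does *not* emulate: real fluorescence magnitudes, plate
effects, inter-protein correlation, or heavy-tailed assay noise. Passing
tests on synthetic cohorts demonstrate that the machinery is correct and
optimism-free under the assumed model; they do not certify performance on
real assay data.

# Problem sizes and seeds

The test suite and the acceptance script run at the study's own scale —
33/90 patients, 200-protein panels, 200 bootstrap iterations, 67×3 CV
pairs — with 8–12 seeds for calibration aggregates (pooled type-I error
uses ~6,400 null p-values). Monte-Carlo recovery checks use 40 replicates.
All randomness flows from explicit seeds; reruns are bit-reproducible.

# Known limitations

* The deposited study file is required for the data-integrity and
  printed-performance reproductions; it is not redistributed with the
  package, and the corresponding checks fail until it is placed under
  `inst/extdata/deposited/`.
* The midpoint sample-selection rule and the unnormalized pAUC gain scale
  are this package's documented conventions where the original text is
  silent; both are parameterized.
* Intervals are analyzed independently; no cross-interval random-effect
  modeling is attempted.
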