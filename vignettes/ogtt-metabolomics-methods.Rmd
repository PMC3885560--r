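---
title: "Methods: longitudinal OGTT metabolomics analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: longitudinal OGTT metabolomics analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ogttmetab)
```

## The study design this package analyzes

`ogttmetab` implements the statistical machinery of a pre/post intervention
plasma metabolomics study built around the oral glucose tolerance test
(OGTT): subjects drink 75 g of glucose after an overnight fast and plasma is
sampled at 0, 30, 60, 90 and 120 minutes, once before a diet-and-exercise
intervention ("pre") and once after ("post"). Each sample yields peak
heights for a few hundred GC-TOF metabolites plus clinical glucose and
insulin. The design is unbalanced by construction: of 15 subjects enrolled
pre-intervention, 12 complete the post-intervention week, and OGTT series
are available for 13 subjects pre-intervention (completers nested within
OGTT subjects nested within enrollees). Every stage of the pipeline is
written to tolerate exactly this raggedness.

Because cohort data of this kind are rarely public, the package ships a
synthetic-cohort generator (`generate_cohort()`) that reproduces the
*statistical* structure of such a study together with a planted ground
truth, so that every downstream stage — filtering, normalization, mixed
models, PLS-DA, networks, correlations — is testable end to end without any
download.

## The synthetic cohort

Peak heights are log-normal. For metabolite $m$, subject $s$, phase $f$ and
time $t$:

$$\log y = \mu_m + a_m\,g_m(t) + \delta_m(f, t) + b_{s,m} + \varepsilon,$$

with $b_{s,m} \sim N(0, \sigma_b^2)$ a subject intercept shared across that
subject's observations of one metabolite, $\varepsilon \sim N(0,
\sigma_e^2)$ residual noise (defaults $\sigma_b = 0.4$, $\sigma_e = 0.3$ on
the natural-log scale, typical of GC-TOF relative abundances), and
$\mu_m \sim N(\log 10^4, 1)$ a metabolite-specific baseline. $g_m$ is the
metabolite's OGTT archetype, a piecewise-linear template over the five
sampling times in units of one total SD
$\sigma_u = \sqrt{\sigma_b^2 + \sigma_e^2}$:

* *lipid-suppressed* — monotone decline to $-1$ SD by 120 min (insulin
  suppresses lipolysis, so free fatty acids and ketones fall);
* *carb-raised* — peak of $+1$ SD at 30 min decaying thereafter
  (glucose-load products);
* *late-rise xeno* — monotone rise to $+1$ SD at 120 min (slowly absorbed
  diet/microbiome-derived molecules);
* *fasting-shifted* and *inert* — flat time-courses.

The default class mix is 25/20/5/10/40%. Amplitudes $a_m$ are drawn
uniformly in $[0.8, 1.6]$ so archetype strength varies per metabolite. The
templates claim no kinetic realism; they reproduce the qualitative response
classes the analysis must distinguish.

$\delta_m$ carries the planted intervention effect for the `n_planted`
responder metabolites (default 20, split evenly between channels): a
*fasting* responder shifts its whole post-phase profile by
`effect_size_fasting` $\times\,\sigma_u$ (default 1.5), which moves fasting
concentrations but — being constant in $t$ — leaves the baseline-subtracted
AUC untouched; an *auc* responder gains a post-phase excursion bump (0, 0.6,
1, 0.8, 0.5 at the five times) scaled by `effect_size_auc`
$\times\,\sigma_u$. Directions are random signs. Missingness is
missing-completely-at-random at the metabolite-sample level (default 5%),
the simplest mechanism consistent with a presence-fraction reporting rule.

Glucose/insulin series use fixed curve templates (fasting glucose 93 mg/dL
peaking at 155; fasting insulin 18.5 µU/mL peaking at 170) with log-normal
subject multipliers shared between phases, and post-intervention improvement
factors (insulin ×0.70, glucose ×0.97). These values were chosen once so the
cohort-mean Matsuda index sits near 2.0 pre- and 2.9 post-intervention and
fasting insulin falls by roughly a quarter — the phenotype scale of an
insulin-resistant cohort that responds to a fitness/weight-loss
intervention. Because the subject multipliers are shared across phases,
setting the improvement factors to 1 and `gi_subject_sd = 0` makes pre and
post series identical per subject, a useful null.

What the generator does *not* emulate: metabolite-metabolite correlation
(features are independent given the subject), non-random missingness at the
detection limit, batch effects, and skew beyond log-normality. Passing tests
therefore demonstrate correctness of the statistical machinery under the
stated model, not robustness to every pathology of real GC-TOF data.

## Preprocessing

* **Presence filter** (`presence_filter()`): a metabolite is reported if
  detected in at least 50% of samples, where a sample is one (subject,
  phase, time) observation; the bound is inclusive.
* **Sum normalization** (`sum_normalize()`): within each sample, reported
  peak heights are divided by the sample's total reported intensity.
  Missing stays missing — a missing value is never coded as 0, because 0 is
  a legal peak height and the presence filter needs true missingness.
* **Transform to normality** (`select_transform()`): candidates are
  identity, log, square root, cube root, square, and power transforms over
  $\lambda \in \{-2, -1, -0.5, 0.5, 1, 2\}$; the candidate minimizing the
  Anderson–Darling $A^2$ wins, with ties broken toward the simpler family.
  $A^2$ uses estimated mean/SD and the small-sample multiplier
  $(1 + 4/n - 25/n^2)$, under which the 5% critical value is 0.752.
  Nonpositive values make log/power candidates infeasible rather than
  triggering a silent offset, since offsets change inference invisibly.
  The power transforms are applied in the sign-adjusted form
  $\mathrm{sign}(\lambda)\,x^\lambda$, an increasing affine image of the
  classic Box–Cox $(x^\lambda - 1)/\lambda$: the $A^2$ score and the
  mixed-model $t$ are affine invariant, and the shifted form loses all
  precision when $x^\lambda$ is many decades smaller than $1/\lambda$
  (normalized abundances are $\sim 10^{-4}$, so $x^2 \approx 10^{-8}$
  against the constant $0.5$).
* **Order of operations**: normalization precedes transform selection. The
  alternative order is defensible; this one is fixed and documented so
  results are reproducible.
* **Autoscaling** (`autoscale()`): per-feature mean 0, SD 1 with the
  $n-1$ denominator used throughout the package; held-out samples are
  always projected with training centers/scales.

## Clinical indices

QUICKI is $1/(\log_{10} I_0 + \log_{10} G_0)$ — base-10 logarithms are
required to reproduce the conventional 0.315 screening threshold from
$G_0 = 100$ mg/dL, $I_0 = 15$ µU/mL. HOMA is $G_0 I_0 / 405$ (mg/dL
convention); note these same derivation inputs give 3.70, not the 3.67
sometimes quoted as a screening cutoff — the package reproduces the formula,
not the quote. The Matsuda index is
$10000 / \sqrt{G_0 I_0 \bar G \bar I}$ with $\bar G, \bar I$ unweighted
means over all five scheduled draws; with five equally spaced samples the
unweighted mean equals the trapezoid mean up to endpoint weights, and the
unweighted form is the simplest to pin down exactly.

## Excursions

`incremental_auc()` integrates $v(t) - v(0)$ by the trapezoid rule, so a
constant profile has AUC exactly 0 and suppressed metabolites have negative
AUC — total AUC of nonnegative intensities could never be negative, which is
why the incremental definition is the only one consistent with signed
excursion tables (a total-AUC mode exists behind a flag for sensitivity
analysis). Interior missing timepoints are bridged linearly; a missing
terminal point shortens the integration span rather than extrapolating, and
the span is recorded. Per metabolite and phase, subject AUCs are tested
against zero with a two-sided one-sample $t$ ($df = n-1$), equivalent to
asking whether the 95% CI of the excursion covers zero; phases with fewer
than 3 usable subjects are flagged untestable, zero-variance cases
degenerate. The two phase flags classify each metabolite as responsive in
`both`, `pre_only`, `post_only` or `neither`.

## Univariate intervention models

Each metabolite's transformed values are fit with the random-intercept
model $y = \mu + \beta\,\mathrm{phase} + b_s + \varepsilon$ by REML,
profiling the single variance ratio $\theta = \sigma_b^2/\sigma_e^2$ by
one-dimensional optimization of the REML criterion over $\log\theta \in
[-15, 15]$, with the boundary $\theta = 0$ checked explicitly and reported.
For fixed $\theta$ the GLS solution is closed-form through per-subject block
inversion (Sherman–Morrison), so unbalanced 15-pre/12-post data need no
special casing. Inference on $\beta$ uses a Wald $t$ with residual
(containment) degrees of freedom $N - n_{\mathrm{subjects}} - 1$ — a
closed-form, conservative choice for this one-factor design, in place of
Satterthwaite approximations. On balanced complete pairs with $\theta$ off
its boundary this $t$ reduces exactly to the paired $t$-test, which the test
suite exploits, and the unbalanced fit is verified against `lme4` to six
decimals. The response is centered before the quadratic forms are
accumulated; without this, near-constant transformed variables lose the
residual sum of squares to cancellation.

Group means and fold changes (post/pre) are reported on the raw normalized
scale — the scale of a printed concentration table — while tests run on the
transformed scale; the table states both. Multiplicity is handled by
Benjamini–Hochberg q-values (via `stats::p.adjust`) at $q \le 0.05$, with
raw-$p$ and $q$ significance reported separately: in a 12–15 subject cohort
it is expected that metabolites pass raw $p < 0.05$ while none survive FDR
control, and the table makes that distinction visible.

## PLS-DA

`plsda()` implements NIPALS PLS1 from scratch: unit-norm weight vectors,
orthogonal scores, X-deflation per component, coefficients
$W(P^TW)^{-1}q$. Class labels are coded 0/1 (pre/post order respected) and
centered; a numeric response with more than two values (OGTT time) makes the
same function a PLS regression. The component count is the maximizer of
leave-one-out Q2 — $1 - \mathrm{PRESS}/\mathrm{TSS}$ with autoscaling
re-estimated inside every fold — capped at 5 components. LV1 is oriented so
the positive class (or the response) has positive score correlation, fixing
the NIPALS sign indeterminacy.

**Feature selection** follows a weight-significance filter: features split
by the sign of their full-model LV1 weight; within each sign group a
feature's leave-one-out fold weights are tested against the group's mean
weight by a one-sample $t$, selected at $p < 0.05$ when the feature's mean
weight is also more extreme than the group mean (away from zero). The
replicate source is the open design question here: a single fitted model
has one weight per feature, so replicates must come from the
cross-validation folds. Leave-one-out replicates concentrate around the
full-model estimate with variance roughly $1/n$ of the sampling variance,
so a naive SD$/\sqrt{n}$ standard error would declare nearly every feature
significant; the implementation therefore uses the standard jackknife
variance estimator $\widehat{SE}^2 = \frac{n-1}{n}\sum_i (w_{(-i)} - \bar
w)^2$, which restores the intended calibration (under exchangeable noise
roughly 5% of features per sign group are selected).

**The combined model** pools the selected fasting features, selected AUC
features and the clinical indices (Matsuda, QUICKI, fasting insulin and
glucose), refits, and re-selects. Features that were selected in a base
model but dropped on refit are retained as flagged "add-backs", and each
final feature is categorized fasting-only / AUC-only / both / clinical.

**Permutation validation** (`performance_distributions()`): 100 random
stratified 2/3–1/3 splits; per split, the model is fit on the training
portion (component count by LOO within the split) and scored by training
Q2, test RMSEP and test AUROC (Mann–Whitney pair counting, half credit for
ties); the null repeats the identical procedure with labels permuted
independently per split. Empirical p-values use the add-one rule
$(1 + \#\mathrm{exceedances})/(n+1)$, which can never return 0.

**The OGTT time model** first removes the intervention main effect by
centering every metabolite within phase, then regresses the adjusted matrix
on time. Its LV1 loadings (positive = rises through the OGTT, negative =
suppressed) are the vertex attributes of the chemical-similarity network.

Missing values entering any PLS matrix are imputed with the feature's
training mean (0 after autoscaling) and counted in the model object.

## Chemical-similarity network

Tanimoto similarity $|A \cap B| / |A \cup B|$ over binary fingerprints;
edges strictly above 0.7 (a pair at exactly 0.7 gets no edge); vertices
carry the signed LV1 loading, its magnitude as size, and a tri-state
direction (`increase` / `decrease` / `unclear`, the last also covering
metabolites without a loading). Fingerprints are an *input*: the core
consumes any consistent bit-vector file (bitstring or MSB-first hex) rather
than computing descriptors from structures, which keeps it testable with
synthetic fingerprints; `generate_fingerprints()` provides clustered ones
whose within-family similarities concentrate above the threshold.

## Cross-correlation panel

Before correlating phenotype with metabolite variables, features are pruned
to those whose PLS loading deviates from the mean loading by strictly more
than one SD (`loading_prefilter()`). Spearman rho is Pearson on
average-ranked values, pairwise-complete (mirroring the 13/12 subject
availability); the two-sided p comes from
$t = \rho\sqrt{(n-2)/(1-\rho^2)}$ with $n-2$ df, with perfect monotone
pairs reported at the machine floor. p-values are left unadjusted with the
conventional star coding, and a BH column is provided alongside.

## Numerical choices and degenerate inputs

* Sample SD uses $n-1$ everywhere, consistent with the $t$ statistics.
* Ties in transform selection break toward the simpler family in the fixed
  order identity < log < sqrt < cube-root < square < power.
* `fit_random_intercept` on an all-constant response returns $\beta = 0$,
  $p = 1$; a zero-variance paired difference with nonzero mean is flagged
  degenerate rather than reported as infinitely significant.
* Features constant inside a CV fold are centered and given unit scale
  (contributing nothing) instead of erroring the fold; zero-variance
  features in a full fit are an error naming the feature.
* Empty fingerprint pairs have similarity 0 by definition, with a warning.

## Scale of the shipped analyses

The `analysis/` drivers run the full pipeline on the default synthetic
cohort (321 metabolites, 15/13/12 subjects, 20 planted responders, 100
permutation splits); the test suite exercises the same machinery on smaller
cohorts (10–60 metabolites) plus Monte-Carlo calibration studies of 1,000
pooled null mixed-model fits and 20-cohort recovery runs — sizes chosen to
give stable rates (binomial SE below 0.01 on the type-I rate) while keeping
the whole suite in the low minutes on a single core.

With the default ground truth split across channels (10 fasting + 10 AUC
responders at 1.5 SD), the single-endpoint fasting PLS-DA model sees only
10 informative features among 321 and its cross-validated separation is
weak — an honest reflection of how little multivariate signal such a design
carries — while the AUC model, helped by the archetype excursions, validates
positively. The recovery analyses that quantify selection sensitivity
concentrate all planted effects on one channel instead, which is the
configuration a power analysis of the selection filter requires.

## Known limitations

The mixed model supports exactly one fixed factor (phase) with a subject
random intercept — no covariates, no longitudinal slopes. PLS-DA is
two-class PLS1; no OPLS, sparse PLS, multi-class coding or VIP scores (the
selection filter is weight-based by design). The AUC quadrature is
trapezoidal with no pharmacokinetic smoothing. No imputation beyond
PLS-internal mean imputation: univariate stages exclude missing values
pairwise. Fingerprint generation is a fixture generator, not a
cheminformatics engine.
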