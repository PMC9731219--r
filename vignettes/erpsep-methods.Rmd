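---
title: "Separating categorical and covariate effects in single-trial ERPs"
author: "erpsep authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Separating categorical and covariate effects in single-trial ERPs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(erpsep)
```

## The problem

Category-evoked EEG experiments compare event-related potentials (ERPs)
between two stimulus classes — say natural versus manufactured objects.
The stimuli, however, differ in many uncontrolled properties:
psycho-linguistic descriptors of the depicted item (lexical frequency,
age of acquisition, familiarity, ...) and low-level image features
(contrast, entropy, spectral content, ...).  When such covariates are
imbalanced across categories, any classifier or statistical contrast
can pick up covariate-driven voltage differences and misattribute them
to the category.  `erpsep` implements a two-level mass-univariate
linear-modeling workflow that (i) localizes both categorical and
covariate effects on the channels-by-time grid, (ii) quantifies how
much explained variance each covariate family contributes beyond pure
model dimensionality, and (iii) tests whether the categorical effect is
statistically separable from the covariate effects — ending in an
"unbiased ROI" that a brain-computer-interface classifier may use
safely.

## First level: mass-univariate GLM per subject

For each subject, channel and timepoint the single-trial voltages are
modeled as

$$ y = X\beta + \varepsilon $$

where the design matrix $X$ has, in order, two category columns, the
covariate columns, and a constant.  Under the default *signed* coding a
trial carries $+1$ in its own category column and $-1$ in the other;
*dummy* coding ($1/0$) is also provided.  Covariates enter as z-scores
(population-SD convention, computed per subject over that subject's
trials, because first-level models are per subject), so betas read as
microvolts per SD.  The constant absorbs the subject's mean response;
between-subject variability is thereby modeled at the first level and
the group inference operates on the estimated coefficients.

All channel/timepoint regressions share one design, so the whole fit is
a single minimum-norm pseudo-inverse applied to every response at once.
The pseudo-inverse (relative singular-value cutoff
`eps * max(dim)`) matters: the signed category block has rank 1 and the
dummy block plus constant is singular, so a plain `solve()` would fail.
Fitted values and $R^2$ are invariant to the choice of generalized
inverse; reported category betas are the minimum-norm representatives
and their *difference* — the categorical contrast
$c = \beta_{\mathrm{cat1}} - \beta_{\mathrm{cat2}}$ — is
parameterization-free and equals the injected category amplitude on
noiseless data.

$R^2$ is computed from the full model with total sum of squares about
the across-trial mean, so the constant contributes nothing.  At points
where the voltage is identical on every trial (possible only in
noiseless synthetic data) $R^2$ is defined as 0.  A fit is refused when
trials do not exceed design columns: with as many parameters as
observations the model interpolates noise.

## Naive baselines: pricing dimensionality

A model with more covariates explains more variance even when the
covariates are pure noise — on $n$ trials, $k$ independent random
regressors plus one effective category dimension explain
$(k+1)/(n-1)$ of the variance in expectation.  To price this
dimensionality, every covariate model gets a *naive* twin: the category
and constant columns are copied verbatim and each covariate column is
replaced by an independent standard-normal draw (identity covariance —
the minimal full-rank choice of matched dimension), z-scored like a
real covariate.  Thirty naive repetitions are fitted by default and
their $R^2$ maps averaged.  The *excess*
$R^2_{\mathrm{model}} - \bar R^2_{\mathrm{naive}}$ isolates the variance
attributable to the actual covariate values; stacks of these maps feed
the cluster test to localize covariate influence.

## Second level: robust cluster inference

Group inference runs a one-sample Yuen trimmed-mean t-test across
subjects at every channel/timepoint (default 20% trim).  The statistic
uses the winsorized sample variance with standard error
$\sqrt{s_w^2 (n-1) / (h(h-1))}$ and degrees of freedom $h-1$, where
$h = n - 2\lfloor \gamma n \rfloor$; at $\gamma = 0$ it is exactly the
Student t.  We adopted this df-consistent standard-error form over the
$s_w/((1-2\gamma)\sqrt n)$ alternative because the latter mixes the
nominal trim fraction with the realized $\lfloor \gamma n \rfloor$
trimming, which makes its small-sample type-I rate swing with whether
$\gamma n$ is an integer; the form above keeps the same $h$ in the
standard error and the degrees of freedom and its calibration is
checked directly by the packaged Monte-Carlo tests.

Multiple comparisons over the grid are handled by spatio-temporal
cluster mass: points with uncorrected $p$ below the cluster-forming
threshold (default 0.05; two-sided for contrasts, one-sided positive
for $R^2$-excess maps, which are signed by construction) are joined
when adjacent in time on one channel or spatially adjacent at one
timepoint.  Channel adjacency is an explicit input — a JSON
label-to-neighbours file or the 8-connectivity grid helper — because
guessing electrode neighbourhoods is a classic source of silent errors.
Cluster mass is the sum of $|T|$ over members (stated in the result
metadata).

The null distribution enforces the null hypothesis by subtracting the
per-point trimmed mean from every subject's map and then draws
sign-flipped resamples: each subject's whole centred map is multiplied
by a random $\pm 1$ (a Rademacher wild bootstrap), and the maximal
cluster mass of each resample is recorded.  We deliberately chose
sign-flipping over resampling subjects with replacement: at 15 subjects
and 20% trim, with-replacement resamples frequently duplicate subjects
until the winsorized variance collapses, which inflates the null
max-cluster-mass tail severely and makes the test wildly conservative;
the sign-flip null tracks the sampling distribution of the max cluster
mass closely — the packaged null simulations verify that the
family-wise error rate is restored to its nominal level — and is the
standard one-sample scheme in EEG cluster inference.  Corrected p-values are $(1 + \#\{\text{null} \ge
\text{mass}\})/(1 + B)$, so they are never below $1/(B+1)$.  A
threshold-free cluster enhancement (TFCE) transform with the
field-standard $E = 0.5$, $H = 2$ is available as an alternative to a
fixed cluster-forming threshold.

## Separability: the explained-variance decomposition

Four models are fitted per subject: *categorical* (categories only),
*psycho* (categories + psycho-linguistic covariates), *image*
(categories + image covariates) and *psycho-image* (all covariates).
Because the naive mean $R^2$ of a covariate model equals the
categorical model's $R^2$ plus its pure dimensionality inflation, the
dimensionality-corrected model maps are

$$ \tilde R^2_m = R^2_m - \bar R^2_{\mathrm{naive},m} +
   R^2_{\mathrm{cat}} . $$

On these maps the decomposition reads, per subject and grid point,

$$ R^2_{\mathrm{comp.psycho}} = \tilde R^2_{\mathrm{pi}} -
   \tilde R^2_{\mathrm{img}}, \qquad
   R^2_{\mathrm{comp.cat}} = \tilde R^2_{\mathrm{psy}} -
   R^2_{\mathrm{comp.psycho}}, \qquad
   R^2_{\mathrm{loss}} = R^2_{\mathrm{cat}} - R^2_{\mathrm{comp.cat}}, $$

with the mirrored image-family version obtained by swapping psycho and
image.  Algebraically the loss reduces to
$\tilde R^2_{\mathrm{pi}} - \tilde R^2_{\mathrm{psy}} -
\tilde R^2_{\mathrm{img}} + R^2_{\mathrm{cat}}$ — the sub-additivity of
the covariate families' explained variance.  Note this expression is
symmetric in the two families, so `r2_loss_psycho` and `r2_loss_image`
coincide point-by-point; both are kept for interface symmetry, and the
family-specific quantities that genuinely differ are the computed
effects `computed_psycho` and `computed_image`.  It is zero when the
categorical, psycho and image effects are mutually orthogonal, and goes
negative when the two covariate families share variance.  Negative
values are legitimate outputs and are preserved everywhere.

One property deserves emphasis because it bounds what a verdict can
mean: a covariate that is *perfectly* collinear with the category code
adds no explained variance beyond the category columns in any model, so
it cancels from the decomposition identically — in the packaged
confound simulations the loss stays at noise scale at every confound
strength from $\rho = 0$ to $0.9$.  A pure within-point
category–covariate confound is fundamentally unidentifiable from a
single dataset; what the workflow *does* detect is a partially
confounded covariate ($|\rho| < 1$), whose category-orthogonal
component raises the $R^2$ excess in its own window, flags an overlap
with contrast clusters, and removes those points from the unbiased ROI.

ROI summaries average each subject's map over the cluster members
(unweighted mean; the peak value is available as a non-default
alternative), then report the across-subject 20%-trimmed mean with a
percentile-bootstrap 95% CI (1000 resamples of subjects — the
literature reports 95% CIs without a recipe, and the percentile
bootstrap of the trimmed mean is the matching robust choice).  Whether
such intervals should pool channel-time values instead of per-subject
ROI means is not settled; we use per-subject means, consistent with the
second-level logic.  The verdict is `"separable"` when the loss CI lies
entirely below the categorical-model CI — the strictest reading of
"significantly lower" — `"not separable"` when the loss CI reaches at
least as high as the categorical CI (lower bound at or above the
categorical lower bound, or upper bound at or above the categorical
upper bound), and `"inconclusive"` for a loss CI that merely grazes the
categorical CI from below.  A Yuen test of the paired per-subject
difference is attached as a secondary check.

## The synthetic-data generator

Because the deposited study data are an optional reproduction input
only, every stage is validated on synthetic ERPs with known ground
truth.  The generator's defaults describe the desk-scale study
conditions used throughout the tests: 15 subjects, 100 trials split
evenly between two categories, a 4 x 4 electrode grid (16 channels),
epochs from -200 to 500 ms at 128 Hz (90 samples), a 1 uV categorical
effect at 300–380 ms on the frontal grid quadrant, one covariate effect
of 1 uV per SD at 50–100 ms on the posterior quadrant, unit-SD Gaussian
trial noise and a 0.5 uV between-subject constant offset.  The 1 uV
effect against 1 uV point noise gives a per-window single-trial
$R^2 \approx 0.5$ and comfortable but not trivial group-level power at
15 subjects — the regime the method targets.  Covariates are drawn from
a configurable correlation matrix; naming a `"category"` row correlates
a covariate with the -1/+1 category code (drawn conditionally on the
balanced codes, so the requested correlation is exact in expectation),
which is how confounds are injected.  Draws are z-scored per subject
before entering the signal.

Two shapes are deliberate simplifications: effects are boxcars over
their windows (a Hann taper is available) and noise is white by default
(a moving-average kernel of stated width adds temporal autocorrelation).
Real ERPs have smooth morphology, 1/f noise, spatially correlated
sources and artifacts; none of that is emulated, and preprocessing is
explicitly out of scope.  Passing tests therefore demonstrate the
statistical machinery — estimation, calibration, localization,
decomposition algebra — not robustness to real-world recording
conditions.

## Numerical choices and degenerate inputs

* Pseudo-inverse cutoff: `eps * max(dim)` relative to the largest
  singular value.
* Trimming: $\lfloor \gamma n \rfloor$ per tail, stable sort.
* Zero winsorized variance: an error for the scalar Yuen test; inside
  maps the point is treated as $T = 0$, $p = 1$ (it cannot form a
  cluster).
* Z-scoring a constant column is refused with the column named.
* Cluster reports order by start time, ties by descending peak
  statistic.
* Empty adjacency degrades to per-channel temporal clustering; an empty
  suprathreshold mask yields a valid empty result.
* Child seeds (naive repetitions, bootstrap) derive deterministically
  from the user seed; identical seeds give bit-identical output.

## Problem sizes used in the validation suite

The packaged tests run the chain at the generator's default scale:
first-level exactness on noiseless data; nested-$R^2$ monotonicity over
the full 16 x 90 grid; naive calibration against $(k+1)/(n-1)$ for
$k \in \{5, 10, 23\}$ at 100 trials; cluster formation against a
brute-force flood-fill oracle on 100 random masks; family-wise error on
100 null simulations of 15 subjects with 200 bootstrap resamples each;
effect localization and separability on the default two-window designs
with 500–1000 bootstrap/CI resamples and 10–30 naive repetitions.
These sizes were chosen once as the smallest configurations at which
the Monte-Carlo tolerances above are meaningful.

## Known limitations

* The loss statistic cannot see a perfectly collinear confound (see
  above); the overlap report is the instrument for partial confounds.
* No paired or two-sample second-level designs, no second-level
  regressions, no source reconstruction or time-frequency analysis.
* First-level estimation is ordinary least squares; robustness enters
  only at the second level, and residual autocorrelation is not
  modeled.
* Covariate feature extraction from stimuli (image statistics,
  psycho-linguistic norms) is upstream of this package.
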