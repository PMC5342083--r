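---
title: "Modelling age trajectories in cross-sectional expression cohorts"
author: "ageTrends"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling age trajectories in cross-sectional expression cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ageTrends)
```

## The problem

Population-based transcriptome cohorts are cross-sectional: each subject is
measured once, at one age, and the cohort's age distribution is rarely even.
Two questions drive the analysis this package implements. First, which
probes change expression with age, and in which direction? Second, *when* do
they change — is the alteration spread evenly across adulthood, or
concentrated around a critical age (the **age-position**)?

Linear models answer the first question but silently assume a constant rate
of change, which makes the second question unaskable. A quadratic model of
log2 intensity on age is the smallest model that lets the rate itself vary,
and its fitted trajectories can be clustered by shape and intersected to
locate where opposite-direction trends conjoin.

## The model

For probe $i$ and subject $j$ with age $x_j$ the expression
$E_{ij}$ (log2 scale) is modelled as

$$E_{ij} = \alpha_i + \beta_i x_j + \gamma_i x_j^2 + \varepsilon_{ij},$$

fitted by weighted least squares with per-sample weights $w_j$, i.e.
minimising $\sum_j w_j (E_{ij} - \alpha_i - \beta_i x_j - \gamma_i
x_j^2)^2$. The quadratic is deliberately knot-free (a degree-2 spline with
no interior knots is a single quadratic polynomial), keeping the model's
assumptions minimal.

### Sample weighting

Cohort age distributions are often positively skewed — the elderly are
under-represented. To stop the dense young side of the cohort from
dominating every fit, each sample receives a weight inversely proportional
to its age-neighbourhood size:

$$N_i = \#\{\,j : |x_j - x_i| \le h\,\}, \qquad w_i = 1/N_i,$$

with half-width $h = 5$ years by default (a closed window, so an 11-year
span at integer ages; set $h = 4.5$ for an exact decade). Weights are kept
in raw $1/N_i$ form: every downstream statistic is invariant to a global
weight rescaling, so no renormalisation is needed. Numerically, the fit
engine divides weights by their maximum before entering the loss; this
changes nothing mathematically and has the convenient side effect that an
equal-weight cohort takes the bit-identical code path as an unweighted run.

### Testing, FDR and fold change

Each probe's quadratic fit is compared against the intercept-only model
with an F-test,

$$F = \frac{(\mathrm{RSS}_0 - \mathrm{RSS}_1)/2}{\mathrm{RSS}_1/(n-3)}
\sim F_{2,\,n-3} \text{ under } H_0,$$

using weighted residual sums of squares when weighting is on. P-values are
Benjamini–Hochberg adjusted; probes with $q < 0.05$ **and** an absolute
fold change $\ge 1.2$ are kept. The fold change of a probe is
$\mathrm{sign}(\Delta)\, 2^{|\Delta|}$ where $\Delta$ is the fitted
trajectory's value at the oldest grid age minus its value at the youngest
("endpoints" mode). Because a symmetric quadratic can have a near-zero
endpoint difference yet a large excursion, an "amplitude" mode
($2^{\max - \min}$, direction still from the endpoints) is provided; the
mode used is recorded in every result.

### Clustering and the age-position

Smoothed trajectories of the significant probes are standardized (each
minus its own mean over the age grid) so they group by shape, then
clustered by Lloyd-style K-means with farthest-point seeding and several
restarts:

* **Euclidean distance** groups trends; clusters whose centroids correlate
  at $r \ge 0.9$ (signed, so mirrored trends never merge) are merged and
  singleton clusters dropped, typically leaving two major profiles of
  opposite inclination.
* **Absolute-correlation distance** $d(a,b) = 1 - |r(a,b)|$ unites a trend
  with its mirror image. Within the largest such cluster, members are split
  by the sign of their correlation with the centroid, each sign group is
  averaged, and the **age-position** is reported as the age where the two
  mean trajectories cross (linear interpolation between grid years; if
  several crossings exist, the steepest is primary and the rest are
  reported as secondary). The alternative reading — the vertex
  $-\beta/(2\gamma)$ of a quadratic fitted to the sign-aligned mean — is
  available as `method = "quadratic-vertex"`; every report names the method
  used. Decades follow the convention $\lfloor \mathrm{age}/10 \rfloor + 1$,
  so the seventh decade spans ages 60–69.

## What the synthetic cohorts emulate

`simulateDataset()` generates a stated world with known truth: ages drawn
uniformly or from a right-skewed Beta$(1, 1+s)$ family rescaled to the age
range (at $s = 0$ the two modes coincide; $s = 2$ reproduces the positive
skewness of a younger-heavy cohort), per-probe baselines $\mathcal N(8,1)$
on the log2 scale, and mean trajectories from a small archetype set —
null, linear up/down, flat-then-linear **hinges** up/down with the bend at
a planted change-point, and quadratics with their vertex there — plus
homoscedastic Gaussian noise (SD 0.5 by default). The hinge is the
canonical non-null shape because the scientific claim under test is that
change concentrates late in life; pure quadratics exercise the
well-specified case, hinges a mild misspecification. Presets
`rsLikeCohort()` (n = 762, ages 46–89, skew 2) and `shipLikeCohort()`
(n = 991, ages 21–81, skew 0.3) mirror the two cohort designs the method
was built for. `simulatePlatformPair()` adds two probe panels measuring an
overlapping gene set, for overlap/concordance analyses.

What the generator does **not** emulate: probe cross-hybridisation, batch
or array-position effects, heteroscedastic or heavy-tailed noise, and
count-based noise models. A green test therefore establishes correctness of
the algorithms under the stated statistical world, not robustness to every
artefact of real arrays.

## Numerical choices

* Quantile normalisation averages reference values across tied ranks, so
  ties stay tied.
* Double centering subtracts row means then column means; both margins are
  then zero to 1e-10 and the operation is idempotent and linear.
* The detection prefilter keeps probes detected ($p < 0.05$) in *strictly
  more than* 10% of samples, and is off by default (one of the two cohort
  designs deposited unfiltered data).
* The shared design matrix $[1, x, x^2]$ is factorised once per cohort by
  QR on $\sqrt{w}X$, so a cohort of thousands of probes is fitted in a
  single pass.
* A perfect fit ($\mathrm{RSS}_1 = 0$) reports the smallest representable
  positive p-value and is flagged rather than dividing by zero.
* K-means ties (equidistant centroids, equal restart objectives) resolve
  to the lowest index, making the whole clustering stage a pure function of
  its inputs and seed.
* The age grid is integer years spanning the *observed* age range. In a
  strongly skewed cohort the oldest observed age can fall short of the
  nominal range top, so fold changes — computed on the grid — do not
  extrapolate beyond the data.

## Design decisions that were genuinely open

* **Weights enter the loss, not the covariate.** The formula as usually
  typeset can be read as multiplying age by the weight; that reading
  destroys the age axis and contradicts the purpose of weighting
  (compensating the uneven sample distribution's influence on the tests),
  so only the weighted-least-squares reading is implemented.
* **k before merging** is nowhere pinned down by the analyses this package
  reimplements; the default is $k = 10$, and because redundant clusters are
  merged and singletons dropped, the final trend count is insensitive to
  $k$ over a wide range.
* **Probe-to-gene collapse** uses the majority direction of a gene's
  significant probes; internal ties are excluded and reported, never
  silently dropped.
* **Age splits** use younger $= [\,\cdot < c\,]$, older $= [\,\cdot \ge
  c\,]$, and each subset recomputes its own weights when re-analysed.

## Known limitations

Two limitations are structural, measured by this package's own acceptance
suite, and worth stating plainly.

**The weighted F-test is anticonservative under skewed ages.** The weights
$1/N_i$ are a deterministic function of age, so sparse (old) samples carry
both high weight and high leverage. Under homoscedastic null noise the
weighted F statistic then exceeds its nominal $F_{2,n-3}$ reference: in an
RS-like skew-2 cohort roughly 30% of null probes reach $p < 0.05$, and BH
adjustment of such p-values does not control the FDR. No effective-sample-
size or sandwich correction is applied — the reimplemented procedure has
none — so weighted q-values should be read as a *ranking*, not as
calibrated error rates; the unweighted test (uniform null p-values,
verified by test) is the calibrated alternative.

**The crossing estimator dates the midpoint of change, not its onset.**
The crossing of the two centered opposite mean trajectories occurs where a
trajectory passes its own lifetime mean. For a hinge that is flat until age
$c$ and then ramps to the range top $H$ over a range of length $R$, that
point lies roughly $(H-c)^2/(2R)$ years *after* $c$ — about +7 years for a
hinge at 65 on ages 46–89 — and quadratic smoothing does not remove the
offset. The estimator is precise (replicate spread ≈ ±1.5 years) but
systematically late for onset-type change; the quadratic-vertex alternative
errs early. Detected age-positions should be interpreted as "the age by
which the bulk of the change has accrued".

## A worked run

```{r, eval = FALSE}
spec <- rsLikeCohort(n = 500, nProbes = 1000, fracSignal = 0.3,
                     delta = 0.8, seed = 1)
sim <- simulateDataset(spec)
res <- runPipeline(sim$dataset, analysisConfig(randomSeed = 1L))
res$summary
res$agePosition
```

The run is a pure function of (inputs, config, seed); re-running writes
byte-identical outputs, each stamped with a fingerprint of the
configuration and the seed.
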