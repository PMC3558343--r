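---
title: "tilewave: model, estimation and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{tilewave: model, estimation and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tilewave)
```

## The functional model

Tiling arrays probe a genome at near-regular spacing irrespective of
annotation, so the natural unit of analysis is the probe signal as a
function of genomic position. `tilewave` models the `N x T` matrix of log2
intensities on one chromosome strand as

$$Y = XB + E,$$

with a design matrix $X$ ($N \times q$) describing the experiment and $B$
($q \times T$) holding $q$ unknown *effect functions* of probe position.
The errors are taken independent Gaussian with constant variance. Each
supported design keeps the effect functions estimable (near-)orthogonally:

* **two-group**: intercept plus a $\pm 1$ dummy; the intercept captures
  overall expression (transcript discovery) and the contrast differential
  expression.
* **multi-group (Helmert)**: contrast $j$ compares group $j+1$ with the
  mean of all preceding groups; for balanced designs
  $X^\top X$ is diagonal with entries
  $N, \sum_{i\le 2}N_i, 2\sum_{i\le 3}N_i, \dots, (q-1)\sum_{i\le q}N_i$.
  With unbalanced group sizes these contrasts are *not* mutually
  orthogonal; the fit is unaffected because estimation always runs through
  the orthonormalized basis (below).
* **time course**: orthogonal polynomials of the array times, built by
  Gram–Schmidt (QR) of the Vandermonde matrix of centered times, so
  unbalanced and non-equidistant designs work too. Row $d+1$ of $B$ is the
  degree-$d$ trend.
* **circadian**: one Fourier harmonic
  $[1, \sin(2\pi t/P), \cos(2\pi t/P)]$. The period $P$ is a required,
  explicit parameter (24 h in a day/night experiment); higher harmonics
  are out of scope. For equally spaced full-cycle designs
  $X^\top X = \mathrm{diag}(N, N/2, N/2)$, which equals
  $\mathrm{diag}(N, q, q)$ exactly when there are two arrays per time
  point.
* **custom**: any full-rank matrix, e.g. a two-factor model with
  interactions.

Every design object carries the interpretable coding `$X`, an orthonormal
basis `$Xo` of the same column space, and the upper-triangular factor
`$tri` with `Xo %*% tri == X`. The QR sign convention (positive diagonal
of `tri`) makes results reproducible across linear-algebra backends. The
canonical "raw" scaling of a polynomial column divides the orthonormal
column by its smallest nonzero entry, which reproduces the classical
integer contrasts (`(-1,0,1)`, `(1,-2,1)`, ...) on equidistant designs.

## Estimation in the wavelet domain

Each array's probe signal is reflection-padded to the next power of two
and projected onto an orthonormal discrete wavelet basis (periodized Haar
by default, Daubechies-4 optionally). Orthonormality gives an exact
round trip and Parseval's identity; padded positions are dropped after
reconstruction and never enter inference. Haar is the default because the
model treats coefficients generically, Haar boundaries are exactly
localized, and every worked example stays hand-checkable.

At each wavelet location $(j,k)$ the transformed model is an independent
Bayesian regression

$$D(j,k)\mid\beta^* \sim N\!\big(X''\beta^*(j,k),\, I\sigma^2(j,k)\big),
\qquad
\beta^*_m(j,k) \sim N\!\big(0,\, \tau_m(j,k)\,\sigma^2(j,k)\big),$$

fitted on the orthonormal $X''$ and mapped back through
$\mathrm{tri}^{-1}$ — exactly the back-transformation required for
non-orthogonal (multi-factor) designs, and an algebraic no-op for
orthogonal ones. Hyperparameters are estimated by marginal maximum
likelihood with a coordinate (Gauss–Seidel) sweep:
$\sigma^2 \leftarrow (\lVert D\rVert^2 - \frac{\tau}{1+\tau}\lVert
X''^\top D\rVert^2)/N$, then the positive-part moment update
$\tau \leftarrow (\lVert X''^\top D\rVert^2/(q\sigma^2) - 1)_+$. The test
suite verifies this fixed point against a dense two-dimensional grid
search of the marginal likelihood. The posterior is
$\beta^*_m \mid D \sim N(s\, b_m,\ \sigma^2 s)$ with
$s = \tau/(1+\tau)$ and $b = X''^\top D$: empirical-Bayes shrinkage that
borrows strength from neighbouring probes at every scale.

Two estimation choices matter in practice and are deliberate:

* **Smoothing is common across effects by default** (`smoothing =
  "common"`): every inference mode combines effect functions (group
  differences, fitted means, amplitudes), and combining is only coherent
  when the components are smoothed equally, which also requires the
  normalized design (hence `normalize = TRUE` design defaults). A separate
  $\tau_m$ per effect remains available (`smoothing = "per_effect"`).
* **The noise variance is pooled within each wavelet scale** (`noise =
  "scale"`): under the working model of independent probe errors an
  orthonormal transform leaves $\sigma^2$ constant within (indeed across)
  scales, so pooling matches the generative model exactly while still
  permitting scale-dependent variance when probe-domain correlation is
  present. It also stabilizes what is otherwise a 1-degree-of-freedom
  empirical-Bayes problem per coefficient: with free per-location
  $\sigma^2(j,k)$ the posterior is overconfident at randomly large null
  coefficients, and measured null calibration degrades by a factor of
  about three. The free estimator is available as `noise = "location"`.

## Detection and regions

For an effect track with Gaussian posterior, the local false discovery
probability of an over-expression call at threshold $\delta$ is
$P(F\beta(t) < \delta \mid Y)$, and under-expression uses
$P(F\beta(t) > -\delta \mid Y)$; the two directions are reported
separately (a two-sided view combines them by their minimum). The
circadian amplitude depends non-linearly on its components, so its local
probability is the proportion of posterior draws with
$A_{sim}(t) < \delta$ (seeded, $\ge 100$ draws, default 10\,000).

Significance uses the direct-posterior-probability Bayesian FDR rule:
sort local probabilities, declare the largest prefix whose running mean
stays at or below $\alpha$. One refinement: only probes whose posterior
odds favour a true call (local probability $< 0.5$) are eligible.
Without it the running mean can absorb probes that are *certainly* null —
on noise-free data the plain prefix rule declares a handful of
probability-one probes simply because enough zeros precede them. The test
suite checks the rule against exhaustive search over all probe subsets.

Default thresholds follow the worked case studies: $\delta = \log_2 1.2$
for differential calls and $\delta = \log_2 1.1$ for circadian
amplitudes. Transcript-discovery (means-mode) thresholds are
experiment-specific and must be supplied explicitly;
`delta_quantile()` offers an empirical upper-quantile convenience, not a
calibrated background model.

Regions are maximal runs of index-consecutive significant probes, merged
across insignificant gaps of at most `max_gap_bp` (measured between probe
intervals, bedtools-style; default twice the median probe spacing) and
split wherever consecutive probes are farther apart than ten times the
median spacing, so regions never bridge large unprobed holes. Runs with
fewer than `min_probes = 4` significant probes are dropped. Coordinates
are 0-based half-open internally and in BED output, 1-based closed in
GFF3. Strands are never merged. Gene mapping retains genes with at least
15 % of their length covered by detected regions; unannotated candidates
must have zero overlap with the annotation padded by 500 bp (a pragmatic
stand-in for "near a gene or its promoter", strand-blind) and length
$\ge 200$ bp.

## The synthetic-data generator

`simulate_tiling()` realizes the working model exactly: equally spaced
probes on one chromosome strand (35 bp spacing, 25 bp probes by default),
$Y = XB + E$ with iid Gaussian noise, and $B$ assembled from a baseline
plus boxcar (optionally half-cosine-tapered) bumps on chosen effect
roles. For the two-group contrast the planted amplitude is the
between-condition log2 difference (the $\pm1$ coding makes the
coefficient half of it). Identical seeds give identical experiments and
the caller's RNG state is untouched.

What the generator does *not* emulate: probe-sequence (GC/affinity)
effects, cross-hybridization, spatial array artifacts, heteroscedastic
arrays, or correlated noise (an AR(1) flag is deliberately out of scope
here). Passing calibration on simulated data therefore demonstrates
correctness of the estimator under its own assumptions, not robustness to
platform artifacts; real studies should treat the null calibration
figures as best-case.

Default study conditions used in tests and the acceptance script: 3 + 3
arrays, $T = 1024$ probes, $\sigma = 0.3$ log2 units, a 128-probe planted
region with a 1.0 log2 between-condition difference, 20 calibration
replicates and 50 end-to-end replicates — small enough to run in minutes,
large enough that the stochastic checks have sensible operating
characteristics.

## Numerical choices and degenerate inputs

* Convergence: maximum relative parameter change below `tol = 1e-6`,
  `max_iter = 100`; non-convergence warns and returns the current state.
* $\sigma^2$ is floored at $10^{-12}$ so noise-free input degenerates
  gracefully (shrinkage $\to$ 1, the fit reproduces probe-wise least
  squares; verified to $10^{-8}$ against per-probe OLS).
* Degenerate posteriors ($sd = 0$) collapse the local probability to a
  point mass in $\{0, 1\}$.
* Rank-deficient custom designs are refused naming the first dependent
  column; identical time vectors and non-positive periods are refused at
  design construction.
* Variance back-propagation through the inverse transform uses the
  squared synthesis pyramid for Haar (exact, since each coefficient
  reaches a probe through one filter path) and the explicit squared
  synthesis matrix for Daubechies-4 (cached per plan), both validated
  against brute force.

## Interfaces

The package is a library in the classic R modelling idiom: `wfm()`
returns a classed fit with `print`, `summary`, `coef`, `fitted`,
`residuals`, `predict` and `plot` methods, and the inference functions
consume the fit. Batch use goes through `wfm_pipeline()`, which executes
`simulate` / `fit` / `infer` / `regions` / `benchmark` tasks from a
JSON/YAML configuration, reads and writes the documented interchange
formats (probes-by-arrays TSV, BED6, bedGraph, GFF3), records a JSON
provenance file per run, and gates inference modes by the fit's design
class (`effects` needs a time-course fit, `circadian` a circadian fit).
Fits are serialized by `wfm_save()` as plain-text TSV + JSON archives
that reload exactly, so one fit feeds any number of inference passes.
A shell entry point is intentionally absent: the functions, configs and
this vignette are the interface, matching how the package is used from R.

## Known limitations

* The empirical-Bayes posterior ignores hyperparameter uncertainty; local
  probabilities at very small $N$ are approximate.
* Independence of posteriors across effects is exact only in the
  orthonormal basis; contrasts on heavily collinear custom designs
  inherit the mapped covariance but no cross-location dependence.
* Probes are treated as equally spaced within a region; spacing enters
  only through the region-calling gap rules.
* One Fourier harmonic: sharply non-sinusoidal rhythms load partially on
  the harmonic and lose amplitude.
* CEL-file import, probe remapping and normalization are upstream
  concerns; the package starts from a probe-level log2 matrix.
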