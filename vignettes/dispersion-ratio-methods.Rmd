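---
title: "Dispersion-ratio component selection for e-nose classification: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dispersion-ratio component selection for e-nose classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enoseWilks)
```

## The model

An electronic-nose measurement is a matrix of conductance ratios
$R_i(t) = G/G_0$, one row per metal-oxide sensor, sampled on a regular time
grid (interval $\Delta t$, default 1 s; 80 points by default). `enoseWilks`
assumes the ratios are strictly positive, that all samples in a dataset share
the sensor count and time grid, and nothing else about the curve shapes.

Each curve is reduced to its mean differential coefficient
$$D_\mathrm{ave} = \frac{1}{n-1}\sum_{z=1}^{n-1}\frac{x_{z+1}-x_z}{\Delta t}
 = \frac{x_n - x_1}{(n-1)\Delta t},$$
the average response velocity. Both forms are implemented (`dave()`); the
telescoped closed form is the production path and the literal sum is kept as
a cross-check, since they are algebraically identical and the closed form is
O(1). No baseline subtraction or smoothing is applied.

PCA (`fitPCA()`) eigendecomposes the sample covariance (divisor $n-1$) of
the *unstandardised* features. Two deliberate choices:

* **No correlation scaling.** $D_\mathrm{ave}$ features share units across
  sensors, and the dispersion-ratio search downstream is scale-invariant per
  component anyway, so standardisation would only obscure the raw eigenvalue
  spectrum (typically $10^{-5}$–$10^{-11}$ on ratio-per-second data).
* **Divisor $n-1$.** The convention is not observable downstream: a common
  factor on the covariance rescales all eigenvalues together and cancels in
  every Λ ratio and classification.

PCA is fitted on *all* samples, train and test together, before the PNN
split. This mirrors the workflow this package validates and is a documented
leakage caveat, not something the package silently "fixes": the projection,
not the class labels, is shared.

## The dispersion ratio and its absolute-value variant

For scores $X_{igk}$ (component $i$, class $g$, sample $k$), with class
means $u_{ig}$ and grand means $u_i$:

$$d_{ij} = \sum_g \sum_k (X_{igk}-u_{ig})(X_{jgk}-u_{jg}), \qquad
  a_{ij} = \sum_g \sum_k (X_{igk}-u_{i})(X_{jgk}-u_{j}),$$

and the Wilks statistic $\Lambda = |D|/|A|$ ranks component subsets: small
$\Lambda$ = small within-class scatter relative to total scatter = good
separation. The regular $\Lambda$ lies in $[0,1]$ because $A - D$ (the
between-class scatter) is positive semi-definite.

Off-diagonal terms $(X_{igk}-u_{ig})(X_{jgk}-u_{jg})$ can have either sign
and cancel in the sum, which can make a poorly separating pair *look* good.
The improved variant takes the absolute value of every cross-product before
summation. Because $|xy| = |x||y|$, both improved matrices are plain
cross-products of element-wise absolute deviations, which is how they are
computed. Diagonals (squares) are unchanged, and for $m=2$ both improved
determinants are non-negative by Cauchy–Schwarz. The improved $\Lambda$ is
**not** bounded by 1; `writePipelineReport()` flags any pair above 1 rather
than clamping.

`pairSearch()` evaluates all $\binom{p}{2}$ pairs (optionally all triples,
$m=3$) from a single pair of full scatter matrices, since each $2\times2$
sub-determinant only needs entries $(i,i)$, $(j,j)$, $(i,j)$. Ties take the
lexicographically lowest $(i,j)$ — ties essentially never occur on real data
but the rule makes the search deterministic. Reports round Λ to 4 decimals;
selection always uses full precision. When both variants are requested the
improved table drives the selection and the regular table is emitted
alongside, so either reading of a published ratio table can be inspected.

## Numerical choices

* **Eigenvector signs:** each loading column is flipped so its
  largest-magnitude entry is positive (ties: lowest index), making loadings
  reproducible across linear-algebra backends. Within a degenerate eigenvalue
  tie the subspace rotation itself remains backend-dependent; only the
  ordering and sign rule are pinned.
* **Eigenvalue floor:** values in $[-10^{-12}\,\lambda_{\max}, 0)$ are
  clipped to 0; anything lower errors.
* **$2\times2$ determinants** ($ad-bc$) use a compensated Dekker-split
  product, recovering the rounding error of $bc$ before subtraction —
  relevant when $D$ is nearly singular.
* **Singularity:** $|\det A| < 10^{-300}$ raises an error suggesting fewer
  components or more samples; `pairwiseMahalanobis()` offers an explicit
  `regularize` switch adding $10^{-12}\,\mathrm{tr}(S_p)$ to the diagonal.
* **PNN underflow:** with spreads of $10^{-5}$ and scores of magnitude
  $10^{-2}$, $\exp((z-1)/\sigma^2)$ underflows to 0 for *every* pattern.
  Activations are therefore computed in log space and rescaled so the
  largest pattern activation is exactly 1. All class scores are multiplied
  by one positive constant, so the arg-max, the spread→0 nearest-neighbour
  limit and the spread→∞ class-count limit are unchanged; reported
  activations are the rescaled ones.

## Class separation and the PNN

`classCentroids()` uses the pooled within-class covariance with divisor
$N-c$. Published e-nose studies rarely state which covariance their
"Mahalanobis distance" uses (global, pooled, per-class); pooled is the
standard discriminant-analysis choice, is affine-invariant, and keeps
distances comparable across component pairs. Consequently, absolute MD
values from other software are not expected to be reproduced — only the
relative ordering has meaning here.

The PNN stores one pattern neuron per training sample. (Descriptions that
fix the hidden-layer size at the full sample count even when only part of it
is trained on are internally inconsistent; the pattern-per-training-sample
rule is the defining property of a PNN.) Two kernels:

* `dot_product` (default): unit-normalise patterns and queries,
  $g(z) = \exp((z-1)/\sigma^2)$ — on unit vectors exactly the Gaussian
  kernel $\exp(-\lVert q-w\rVert^2/2\sigma^2)$. Normalisation makes the
  classifier angle-only, which suits centred PC scores where classes occupy
  distinct directions.
* `euclidean`: the Gaussian on raw vectors, the behaviour of classical
  MATLAB-style PNN implementations on unnormalised data. The two differ
  whenever inputs are not unit vectors.

Class priors are uniform (plain summation). Arg-max ties go to the lowest
class index and are flagged. `spreadGridSearch()` scans
$\sigma \in \{1,2,\dots,10\}\times10^{-5}$ by default and selects the
lexicographic maximum of (train accuracy, test accuracy), smallest spread on
ties — the "both accuracies highest at the same time" rule. The split is
ordered, not random: first 15 samples per class train, the remaining 5 test,
so results are deterministic given the stored sample order.

## What the generator emulates — and what it does not

`simulateENose()` draws, per sample and sensor, an asymptote
$\theta^* = \theta_{gs} + \mathcal N(0, \mathrm{withinSd}_s)$ and the curve
$$R(t) = 1 + (\theta^\ast - 1)\,(1 - e^{-t/\tau}) + \mathcal N(0,
\mathrm{noiseSd}),$$
clipped below at $10^{-6}$. First-order rise kinetics match the saturating
curves of metal-oxide sensors and give a closed-form expected feature
(`expectedDave()`) for testing; baseline ratio 1 is the sensor in zero gas.
Defaults — 6 classes × 20 samples, 10 sensors, 80 s at 1 s, $\tau = 10$ s,
asymptotes 1.6–3.4, withinSd 0.03, noiseSd 0.01 — emulate a multi-variety
grain experiment on a 10-sensor array.

Not emulated: sensor drift, humidity/temperature response, inter-sensor
noise correlation, non-exponential transients, and the clipped-Gaussian tail
at near-zero asymptotes. Passing tests on synthetic data therefore
demonstrate the *algorithms* behave as specified, not that any instrument
meets these assumptions.

Scenario presets (`scenarioConfig()`): `default`, `well_separated` (each
class a distinct sensor-pattern direction), `null` (no class signal — the
negative control: regular Λ near 1 everywhere, PNN near the 1/6 chance
level), and `hidden_discriminant`. The latter places large class-independent
variability on sensors 1–4 and the entire class signal on a hexagon of class
means in the (sensor 5, sensor 6) plane, whose total variance sits well
below the noisy sensors. The discriminative signal then surfaces only in two
minor principal components. The signal spans a 2-d subspace deliberately: a
volatile signature is rarely 1-dimensional, and a single hidden axis paired
with a high-variance noise component would make any 2-d classifier read
mostly noise.

## Problem sizes and test design

The suite checks the scatter/Λ implementation against a literal double-loop
enumeration oracle on over a hundred random datasets (2–4 classes, 3–6
samples each, 2–3 components), PCA against characteristic-polynomial roots
and an SVD route, D_ave against its summation form, and the PNN against a
brute-force nearest-neighbour classifier in the matched metric. Synthetic
end-to-end runs use the full default size (120 samples × 10 sensors × 80
points), which completes in seconds; property suites use small random
instances under fixed seeds.

## Known limitations

* The improved Λ is a heuristic ranking score; no distributional theory
  (Rao/Bartlett F-approximations) is attached to it, by design.
* Exhaustive search is quadratic (cubic for triples) in the component count
  — fine for sensor arrays, not for high-dimensional feature spaces.
* Fitting PCA before the train/test split shares the projection with the
  test set (see above).
* The pooled-covariance MD assumes roughly common within-class covariance;
  strongly heteroscedastic classes violate it.
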