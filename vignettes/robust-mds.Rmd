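---
title: "Detecting and correcting orthogonal outliers before MDS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and correcting orthogonal outliers before MDS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Multidimensional scaling (MDS) embeds observations in a low-dimensional
Euclidean space from their pairwise dissimilarities alone, and is a staple of
exploratory analysis for biological data — beta-diversity ordinations,
cell-shape metrics, expression profiles. It is, however, sensitive to
*orthogonal outliers*: points that agree with the bulk of the data within the
low-dimensional "main" subspace but carry a large component perpendicular to
it. Such points do not look aberrant in any single pairwise distance, yet
they tilt the embedding and blur the structure of the regular observations.

`orthomds` addresses this with distance-only geometry. It estimates the
dimension $d^*$ of the main subspace, flags the orthogonal outliers, and
replaces their distances by distances to their orthogonal projection onto the
main subspace, producing a corrected distance matrix that embeds cleanly.

## Simplex heights from distances

The device is the height of a simplex. For $m$ base points and an apex $x$,
the height of $x$ over the base's affine hull satisfies

$$h = \frac{m\,V_m}{V_{m-1}},$$

where $V_m$ is the $m$-dimensional content of the $(m{+}1)$-vertex simplex
and $V_{m-1}$ the content of the base. Both contents come from pairwise
distances alone through Cayley–Menger determinants,

$$V_n^2 = \frac{|\det CM_n|}{2^n (n!)^2},$$

with $CM_n$ the bordered matrix of squared distances. No coordinates are
needed, so the construction applies to any dissimilarity matrix that is
approximately Euclidean.

The key observation: test a dimension $n$ by sampling, for each point $x_i$,
$S$ bases of $n+1$ other points and recording the median apex height
$h_i^n$. While $n < d^*$ the base hulls are thin slices of the main subspace
and all heights stay comparable. Once $n \ge d^*$ the sampled hulls span the
main subspace, and the median height of a *regular* point collapses to noise
scale, while that of an orthogonal outlier becomes its distance to the main
subspace. Writing $\tilde h_n$ for the mean of $(h_1^n, \dots, h_N^n)$, the
estimator

$$\bar n = \arg\max_n \tilde h_{n-1} / \tilde h_n$$

picks the dimension at which the height distribution collapses. Outliers are
then the points whose median height at $\bar n$ stands out from the
distribution of all $N$ median heights:

$$O = \{\, i : h_i^{\bar n} > \tilde h_{\bar n} + c\,\sigma_{\bar n} \,\},$$

with $\sigma_{\bar n}$ the population standard deviation and $c$ a
user-settable multiplier defaulting to 3 (the three-sigma rule).

When outliers are common they contaminate the sampled bases themselves: a
base containing $k$ outliers spans $k$ extra directions, so the apparent
dimension inflates. The number of outliers in a uniformly sampled base of
$n+1$ points is hypergeometric with expectation $(n+1)p$, which motivates
the a-posteriori correction

$$n^* = \bar n - \lfloor (\bar n + 1)\,\hat p \rfloor, \qquad
  \hat p = |O|/N,$$

floored at 1. Finally, the correction stage embeds the data by classical
(Torgerson) MDS — skipped when original coordinates are supplied — fits a
PCA basis of dimension $n^*$ through the regular points, projects each
outlier onto it, and recomputes all pairwise distances.

## Parameters that matter

* `S` (default 100): simplices sampled per point and dimension. The sample
  median of heights is asymptotically normal around the true median with
  spread proportional to $1/\sqrt S$; 100 draws put the median error well
  below the separation between noise-scale and outlier-scale heights.
* `c` (default 3): the threshold multiplier, a trade-off between missed
  outliers and false flags. Larger values are stricter.
* `dims`: the tested window, by default $1 \dots \min(N-2, 50)$. It is
  always capped at the affine rank of the configuration minus one, see
  below.
* `project_dim`: whether outliers are projected on the subspace of the
  debiased dimension (`"debiased"`, default) or of the raw estimate. The
  debiased dimension is what the evidence supports once the outlier
  fraction is accounted for, so it is the default; the switch exists
  because the two differ only when outliers are plentiful, in which case
  inspecting both is prudent.

## The synthetic generators

Two generators reproduce the kinds of data the method is meant for and give
every test a known ground truth.

`sim_cross()` lays 25 points along two perpendicular unit segments in the
plane $z = 0$ and displaces 3 of them orthogonally, with magnitude uniform
in $[10, 30]$ and random sign — a minimal scene in which the main subspace,
its dimension (2), and the outliers are unambiguous.

`sim_gaussian_subspace()` draws $N$ points with standard-Gaussian
coordinates in the first $d^*$ dimensions, adds isotropic noise of variance
`noise_var` (default $2\times10^{-4}$) across the whole ambient space, and
plants `round(p * N)` outliers by giving each one, in a single randomly
chosen orthogonal coordinate, a displacement uniform on $[-30, 30]$ redrawn
until its magnitude is at least 10. Design choices that deserve comment:

* **Ambient dimension.** The default is `extra_dims = 50` orthogonal
  coordinates. The ambient dimension must comfortably exceed every tested
  dimension: as $n$ approaches the affine rank $r$ of the data, sampled
  bases exhaust the ambient directions and all heights collapse for reasons
  that have nothing to do with the main subspace, which manufactures a
  spurious spike in the ratio curve at $n = r - 1$. We verified this
  directly — with few orthogonal coordinates the estimator locks onto the
  rank edge rather than $d^*$. A wide ambient space also reflects the
  method's target applications, where the nominal dimension (genes, taxa)
  dwarfs the intrinsic one. For the same reason `orthomds()` caps the
  tested window at $r - 1$ and warns when the cap bites.
* **One orthogonal coordinate per outlier.** Each outlier's displacement is
  a single direction in the orthogonal space regardless of how many
  coordinates carry it; what matters for the dimension bias is whether
  *different* outliers span independent directions. Giving each outlier its
  own random coordinate keeps the planted orthogonal distance on the stated
  $[10, 30]$ scale and makes distinct outliers (near-)orthogonal, which is
  the regime the hypergeometric bias model describes.
* **Amplitude floor.** The redraw floor of 10 guarantees every planted
  outlier is separated from the noise (orthogonal norms below 0.1 with high
  probability), so recovery metrics are about the method, not about
  undetectably small plants.
* **Main-subspace scale.** Regular coordinates are standard Gaussian
  (variance 1); the default noise variance then puts the three scales —
  noise ($\sim 0.014$), in-subspace spread ($\sim 1$), outlier offsets
  ($\ge 10$) — in sharply separated decades.

What the generators do *not* emulate: multimodal or clustered regular
structure, curved (nonlinear) main subspaces, non-Euclidean dissimilarities,
heteroscedastic noise. Passing tests on these generators therefore
demonstrate correctness of the estimator under its own model assumptions,
not robustness to every pathology of real data.

## Numerical choices

* All simplex geometry runs on squared distances; determinants are evaluated
  in sign-and-log form (no overflow up to the ~50-dimensional simplices the
  defaults reach), and $|\det|$ is used, which shields mildly non-Euclidean
  input against sign flips. Draws whose determinant sign is anomalous are
  counted and reported in the run summary.
* The compiled kernel computes each height from one LU factorisation of the
  base's Cayley–Menger matrix via the bordered-determinant identity
  $h^2 = |b^\top CM^{-1} b| / 2$, rather than two full determinants.
* **Degeneracy.** A flat base (e.g. collinear points in a planar dataset)
  makes the height ratio 0/0. A base is declared degenerate when its
  Cayley–Menger matrix is numerically rank-deficient — smallest LU pivot
  below $10^{-12}$ times the largest entry — a criterion that separates
  round-off-level determinants from genuine noise-scale extent by many
  orders of magnitude. Degenerate draws are resampled (up to 50 retries per
  draw) and counted; a point that exhausts $50 S$ retries at one dimension
  raises an error naming it, since that indicates the input itself is
  rank-deficient at that dimension.
* Ties in the ratio criterion break toward the smallest dimension; the
  ratio's denominators carry an $\varepsilon = 10^{-12}$ guard; the argmax
  starts at the second tested dimension.
* Even $S$ medians average the two central order statistics. The population
  (divide-by-$N$) convention is used for $\sigma_{\bar n}$.
* Classical MDS clips negative eigenvalues to zero and counts them;
  principal-axis signs are fixed (largest-magnitude loading positive) so
  repeated runs are bit-identical.

## Limitations

* **A hard detectability bound.** For any one-sided mean-plus-$c\sigma$ rule
  applied to a distribution in which a fraction $p$ of values sit at a
  common large amplitude and the rest near zero, the threshold exceeds the
  amplitude itself unless $p < 1/(1+c^2)$ — one tenth for $c = 3$,
  regardless of how large the amplitude is. Fractions at or above this
  bound cannot be fully flagged, and as $p$ approaches it the flagged set
  shrinks toward half. Two visible consequences in this package's own test
  conditions: the 25-point cross carries $p = 0.12$, so its three planted
  outliers are never all flagged simultaneously even though the dimension
  estimate (2) is always recovered and the flagged subset is always a
  subset of the plants; and in the $d^* = 40$ sweep the measured $\hat p$
  increasingly undershoots the true $p$ as it nears 0.1, so the
  hypergeometric correction can under-correct by one dimension at the top
  of the range. Lowering `c` relaxes the bound at the cost of false flags.
* The dimension estimate assumes a single main subspace; clustered data
  with comparable between-cluster separation confound the height criterion.
* The correction projects outliers; points that are aberrant *within* the
  main subspace are out of scope.
* Heights come from sampled simplices, so all decisions are stochastic;
  fix the seed for exact reproducibility.

## Problem sizes in the test suite

The package's tests exercise the estimator at the study scales: the
25-point cross over ten seeds; $N = 1000$, $d^* = 10$, $p = 0.05$ with the
window $1\dots20$; and an $N = 1000$, $d^* = 40$ sweep over
$p \in \{0.02, \dots, 0.1\}$ with the window $30\dots50$. Unit and property
tests use smaller configurations ($N \le 200$, a few dozen samples per
point) chosen so each test still separates signal from noise decisively.

## A worked run

```{r, eval = FALSE}
library(orthomds)
set.seed(7)
sim <- sim_gaussian_subspace(N = 200, d_star = 2, p = 0.05)
fit <- orthomds(sim_dist(sim), dims = 1:8, S = 100)
fit
plot(fit)          # height profile and ratio curve
residuals(fit)     # per-point estimated orthogonal distances
fit$corrected_D    # distance matrix with outliers projected
```
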