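# orthomds

Robust multidimensional scaling for biological dissimilarity data:
detection and correction of *orthogonal outliers* — observations that agree
with the bulk of the data inside its low-dimensional main subspace but carry
a large perpendicular component. Such points distort MDS/PCoA embeddings of
beta-diversity matrices, elastic cell-shape distances, expression profiles
and the like, while looking unremarkable in any single pairwise distance.

## The method

Everything runs on the N×N distance matrix **D** alone. For each point
x_i and each tested dimension n, sample S simplices on n+1 other points and
take the median height of x_i over their affine hulls. Heights come from
distances only, via Cayley–Menger determinants:

    V_n^2 = |det CM_n| / (2^n (n!)^2),        h = n V_n / V_{n-1}.

While n < d\* (the main-subspace dimension) all heights are comparable; at
n ≥ d\* the median height of a regular point collapses to noise scale while
an orthogonal outlier's median height becomes its distance to the main
subspace. With h̃_n the mean of the per-point medians:

* dimension estimate: n̄ = argmax_n h̃_{n−1}/h̃_n;
* outliers: O = { i : h_i^n̄ > h̃_n̄ + c·σ_n̄ } (default c = 3);
* debiasing: sampled bases occasionally contain outliers (hypergeometric,
  expectation (n+1)p), so n\* = n̄ − ⌊(n̄+1)·|O|/N⌋;
* correction: embed by classical MDS (skipped when coordinates are given),
  fit an n\*-dimensional PCA basis through the regular points, project the
  outliers onto it, and recompute all pairwise distances.

The sampling loop is compiled (Rcpp/RcppArmadillo); a fit with N = 1000 and
twenty tested dimensions takes a few seconds.

## Worked example

```r
library(orthomds)
set.seed(7)
sim <- sim_gaussian_subspace(N = 200, d_star = 2, p = 0.05)  # 10 planted outliers
fit <- orthomds(sim_dist(sim), dims = 1:8, S = 100)
fit
#> Robust MDS with orthogonal-outlier correction
#>   200 points; tested dimensions 1..8 (S = 100, c = 3)
#>   raw dimension estimate:      2
#>   outliers flagged:            9 (fraction 0.045)
#>   debiased dimension estimate: 2 (bias 0)
```

The fit recovers the planted dimension (2) and flags 9 of the 10 planted
outliers (the tenth drew an amplitude below the three-sigma threshold):

```r
sim$outlier_idx
#> 9 54 57 83 116 143 176 179 187 198
fit$outliers
#> 9 54 57 83 116 143 176 179 187
```

`fit$corrected_D` is the distance matrix after projecting the flagged
points onto the fitted plane. Against the ground-truth distances (planted
outliers replaced by their exact projections) the correction reduces the
Shepard RMSE from 6.08 (uncorrected) to 1.03:

```r
truth <- true_corrected_dist(sim)
shepard(truth, fit$corrected_D)$rmse   #> 1.0342
shepard(truth, sim_dist(sim))$rmse     #> 6.0847
```

`summary(fit)` prints the per-dimension height table, `plot(fit)` shows the
height profile and the ratio curve, and `residuals(fit)` returns each
point's estimated orthogonal distance.

A command-line interface wraps the same pipeline:

```sh
Rscript exec/orthomds simulate --kind gaussian --N 200 --dstar 2 --p 0.05 --seed 7 --out-dir data
Rscript exec/orthomds run --input data/coords.csv --format coords --seed 7 --out-dir results
```

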