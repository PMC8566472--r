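# banddepth

Band-based similarity indices and Modified Band Depth for classifying and
clustering gene expression profiles.

## The problem

Classification and clustering of expression data stand or fall with the
choice of a (dis)similarity between profiles. The Euclidean distance
assumes noise-free coordinates on a common scale; correlation distance
assumes linearity. Both can be wrecked by a single mis-scaled or noisy
gene. `banddepth` implements a family of *sample-dependent* similarity
measures built from the combinatorics of the Modified Band Depth (MBD):
for a sample of `n` profiles in `d` dimensions, a *j-band* is the
coordinate-wise min/max envelope of `j` observations, and

```
MBD[n,J](y_i) = sum_{j=2..J} (1 / (d * C(n,j))) * sum_k N_k^(j)(y_i)
```

where `N_k^(j)(y_i)` counts the bands whose k-th interval contains the
point's k-th coordinate. For a *pair* of profiles the bands split, per
coordinate `k` and band size `j`, into a 2x2 contingency table — `a` bands
contain both coordinates, `b` only the first, `c` only the second, `d`
neither — to which any binary similarity coefficient can be applied.
Eight classics are built in (simple matching, Jaccard, **Simpson**
`a / min(a+b, a+c)`, Forbes, Dice, Anderberg, Ochiai, Russell–Rao),
aggregated as

```
S = sum_{j=2..J} sum_{k=1..d} S[k,j] / (d * (J - 1)),     D = 1 - S.
```

Because only per-column order statistics enter the counts, the measures
are invariant to any strictly increasing transform applied per gene —
which is exactly what makes them robust where Euclidean-type distances
collapse. All counts are computed by closed-form combinatorics
(complement principle and inclusion–exclusion on first-occurrence ranks
and multiplicities, exact 128-bit integer arithmetic), so the cost is
linear in `J` and quadratic in `n`, never `C(n, j)`.

The package also ships the evaluation harness used to benchmark such
measures: a deterministic kNN for precomputed dissimilarity blocks
(benchmark tie rules), PAM and complete-linkage wrappers, clustering error
rate (minimum disagreement over label permutations) and adjusted Rand
index, B/W and variance gene filters, stratified repeated CV, two Gaussian
simulation models and experiment runners returning tidy tibbles.

## A worked example

Two groups in 10 dimensions; the 6th coordinate is pure noise with its
variance inflated by `delta = 2` — a classic failure mode for Euclidean
distance, invisible to the band measure:

```r
library(banddepth)

expr <- model2(delta = 2, n_per_group = 20, seed = 1)

d_band <- band_dissimilarity(expr$x, J = 2, coefficient = "S")
d_eucl <- dissimilarity(expr$x, dist_spec("euclidean"))

for (d in list(d_band, d_eucl)) {
  part <- pam_cluster(d, G = 2)
  cat(clustering_error(part$assignment, expr$labels),
      adjusted_rand_index(part$assignment, expr$labels), "\n")
}
#> 0.05 0.805
#> 0.35 0.06629834
```

The Simpson band dissimilarity recovers the two groups almost perfectly
(5% clustering error, ARI 0.81) while PAM on the Euclidean distance is
dominated by the inflated noise coordinate (35% error, ARI 0.07).

Depths order the sample from centre outwards:

```r
depth <- mbd(expr$x, J = 3)
head(depth[order(-depth$mbd), ], 3)
#> # A tibble: 3 × 2
#>   sample_id   mbd
#>   <chr>     <dbl>
#> 1 s28        1.13
#> 2 s38        1.12
#> 3 s33        1.09
```

Every result type has `tidy()` / `glance()` / `autoplot()` methods;
experiment runners (`run_clustering_experiment()`,
`run_classification_experiment()`) return per-replicate tibbles. A thin
command-line front end lives at `inst/cli/banddepth.R`
(`depth | dissim | knn | cluster | reproduce` subcommands over CSV/TSV
matrices).

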