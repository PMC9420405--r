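# craniomod

Allometry and heterochrony of the two cranial modules — an R package and
analysis workflow for craniometric studies of the hominid skull.

## The scientific problem

The cranium divides into two modules: the **neurocranium** (braincase,
proxied here by the classical measurements GOL, XCB, BBH) and the
**splanchnocranium** (face: BPL, NPH, ZYB). Through growth the face
enlarges much faster than the braincase (negative neurocranial / positive
splanchnocranial ontogenetic allometry); through evolution, species differ
in the relative neurocranial size their adults reach. When the ontogenetic
polarity is known, between-species differences in a size–shape morphospace
decompose into two independent heterochronic readings:

* **ontogenetic scaling** — truncation (paedomorphosis) or extension
  (peramorphosis) of a conserved growth trajectory;
* **lateral transposition** — a parallel shift of the whole trajectory:
  different shape at the same size.

The package implements the full analysis chain for six-variable
craniometric tables, for researchers in evolutionary morphometrics and
paleoanthropology:

1. **Preprocessing** — base-10 logs; Mosimann size standardization
   (`log10(x / gm(x))`, one geometric mean per specimen).
2. **Two-block PLS** (`fit_pls`) — SVD of the between-block association
   matrix of the size-scaled data: loadings, singular values, % squared
   covariation, block scores, block-score correlations; projection of new
   specimens into a fixed space.
3. **Factor model** (`fit_factors`) — correlation-matrix PCA of the raw
   logs with loadings rescaled to eigenvector × √eigenvalue, communalities
   h², unit-variance scores, and the isometric-vector angle diagnostic
   separating the shape factor from the size factor.
4. **Allometry** (`fit_rma`, `clarke_test`, `compare_intercepts`,
   `centroid_angles`) — reduced major axis regression
   (slope = sign(r)·sd(y)/sd(x)) with analytic slope CIs and seeded BCa
   intercept CIs; Clarke's test for slope differences
   (T = |log b₁ − log b₂| / √(s₁²+s₂²), sᵢ² = (1−rᵢ²)/(nᵢ−2), effective
   df); ontogenetic centroid-trajectory angles.
5. **Heterochrony** (`decompose_trajectory`, `compute_eq`,
   `cranial_associations`, `partial_correlation`) — along-trajectory vs
   perpendicular decomposition with paedo-/peramorphic and transposition
   labels; encephalization quotient EQ = ECV/(a·BM^b) and its
   correlation/partial-correlation analysis.
6. **Robustness** (`perturb_and_project`) — bounded multiplicative
   measurement-error simulation re-projected into the fixed ordination.
7. **Synthetic data** (`generate_dataset`, `simulate_hominid_sample`) — a
   generator of multi-group log-linear allometric growth with
   transpositions, used as the standing study-structured sample.

## Worked example

```r
library(craniomod)
ds <- simulate_hominid_sample(seed = 1)   # 91 specimens, 6 groups

fm <- fit_factors(log_matrix(ds), k = 2)
fm
#> Correlation-matrix factor model, k = 2, n = 91
#> eigenvalues: 3.637017 2.277624 0.035621 0.024063 0.016294 0.009382
#> % variance:  60.6170 37.9604  0.5937  0.4010  0.2716  0.1564
#>         F1    F2    h2
#> GOL  0.785 0.600 0.976
#> BBH  0.844 0.520 0.983
#> XCB  0.775 0.618 0.982
#> NPH -0.829 0.553 0.992
#> BPL -0.825 0.559 0.993
#> ZYB -0.584 0.805 0.989
```

Factor 1 (60.6% of variance) contrasts the neurocranial against the
splanchnocranial variables — a shape axis ordering specimens by relative
braincase size. Factor 2 (38.0%) loads all six variables positively — a
size axis, confirmed by the isometric-vector diagnostic:

```r
round(unlist(isometry_angles(fm)), 1)
#> angle_to_factor1 angle_to_factor2
#>             77.1             12.9
```

The direction of pure size change lies 12.9° from factor 2 and 77.1° from
factor 1. The size-scaled two-block PLS shows the two modules covary along
essentially one dimension:

```r
fit_pls(shape_matrix(ds))
#> Two-block PLS (correlation mode), n = 91
#> singular values: 2.897604 0.022070 0.001444
#> % covariation:   9.999e+01 5.801e-03 2.484e-05
#> score correlation: 0.9985 0.3474 0.0673
```

Dimension 1 carries >99.99% of the squared covariation with a block-score
correlation of 0.998: a relatively large braincase goes with a relatively
small face. Within one species, the ontogenetic allometry in the factor
plane:

```r
sel <- ds$group == "Pan_like"
fit_rma(fm$scores[sel, 1], fm$scores[sel, 2],
        x_label = "factor I", y_label = "factor II")
#> RMA factor II ~ factor I: slope -3.1648 [-3.8413, -2.6075],
#>   intercept -2.4486, r -0.935, n 17, P(r=0) 3.722e-08
```

The negative slope says size (factor II) rises as relative neurocranial
size (factor I) falls — the ancestral negative allometry.

## The analysis workflow

`analysis/01_simulate.R` … `05_robustness.R` run the whole study-shaped
analysis over the package, writing tables under `results/`: the simulated
sample, PLS/factor loadings and scores, per-group RMA fits, centroid
angles, the clade slope/intercept contrast, the scaling–transposition
decomposition, encephalization correlations and partials, and the
measurement-error robustness summary. Run them in order from the
repository root:

```sh
for f in analysis/0*.R; do Rscript "$f"; done
```

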