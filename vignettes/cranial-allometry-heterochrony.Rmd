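---
title: "Methods: allometry and heterochrony of the two cranial modules"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: allometry and heterochrony of the two cranial modules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(craniomod)
```

## The problem and the data model

The hominid cranium has two developmentally and functionally distinct
modules: the neurocranium (braincase) and the splanchnocranium (face). Their
relative sizes change both through growth — the face grows much faster than
the braincase, a strong positive splanchnocranial / negative neurocranial
ontogenetic allometry — and through evolution, where species differ in the
relative neurocranial size they reach. Comparing the two kinds of change
lets heterochronies be read off a size–shape morphospace: a descendant that
truncates or extends a conserved growth trajectory is paedomorphic or
peramorphic by *ontogenetic scaling*, while a descendant whose whole
trajectory is shifted — a different shape at the same size — is related by
*lateral transposition*.

Each specimen carries six standard craniometric lengths in mm: `GOL`, `XCB`,
`BBH` (length, breadth and height proxies of the neurocranium) and `BPL`,
`NPH`, `ZYB` (the same for the splanchnocranium), plus taxon, group and an
`adult`/`juvenile` age class, and optionally body mass (kg), endocranial
volume (cm³) and geological age. All analyses work on base-10 logarithms of
the mm values; the fixed analysis order (GOL, BBH, XCB, NPH, BPL, ZYB)
keeps loading signs comparable across fits. Specimens with a missing or
non-positive measurement are rejected at validation; there is no
imputation, because measurement reconstruction belongs upstream of this
kind of analysis.

## Size standardization and the two ordinations

Two matrices feed the ordinations:

* the **log matrix**, `log10(x)`, used by the factor model, so size remains
  in the data;
* the **shape matrix** of Mosimann log-shape variables,
  `log10(x / gm(x))` with `gm(x)` the specimen's geometric mean over all
  six variables jointly, used by the two-block PLS. Implemented as log
  followed by row-centering, each row sums to zero (to 1e−10) and scaling a
  specimen by any constant leaves its row unchanged. One geometric mean per
  cranium — not one per block — so the two blocks stay comparable.

**Two-block PLS.** `fit_pls()` decomposes the 3×3 between-block association
matrix by SVD. The default association is the cross-**correlation** matrix:
its leading singular value is bounded by 3, which puts it on the scale a
craniometric analysis of six highly integrated variables actually produces
(≈2.9 on the synthetic sample); cross-covariances of log-shape variables
would be orders of magnitude smaller. Covariance mode is retained as an
option. Scores are the centered (and, in correlation mode, standardized)
block data projected on the unit-norm singular vectors, with centering and
scaling statistics stored so fossils or perturbed replicates can be placed
into a space fitted on another subset (`project_pls()`). Sign convention:
each dimension is oriented so the neurocranial loadings sum positive; the
splanchnocranial sign is then data-driven (negative on study-structured
data, so "relatively large braincase" and "relatively small face" score
together).

**Factor model.** `fit_factors()` eigen-decomposes the 6×6 Pearson
correlation matrix — the correlation matrix, not the covariance matrix,
because craniometric variables differ in scale and the analysis should
weight them equally; its trace (6) also makes percent-variance figures
immediate. Loadings are eigenvectors × √eigenvalue and factor scores are
standardized to unit sample variance, so each loading is exactly the
correlation between its variable and the factor, and communalities
`h² = rowSums(L²)` lie in [0, 1]. Factor 1 is signed so neurocranial
variables load positive; every other factor so its loadings sum positive
(all six positive on factor 2: size grows with the score).

**Isometry diagnostic.** Whether factor 2 really is "size" is checked by
mapping the isometric direction `(1,…,1)/√6` — equal proportional change in
every measurement — through the scoring transformation (division by the
training SDs, then the scoring coefficients `V Λ^{-1/2}`). The angles of
its image to the two factor axes, folded to [0°, 90°], are complementary in
the retained plane; a small angle to factor 2 licenses reading factor 2 as
size and factor 1 as shape. The scoring-coefficient mapping is our choice
of operationalization; on adult-dominated craniometric structure it puts
the isometric image within ≈5–15° of factor 2.

## Allometric trajectories

`fit_rma()` fits the reduced major axis: `slope = sign(r)·sd(y)/sd(x)`,
symmetric in x and y — appropriate when neither score is an error-free
predictor. The 95% slope CI uses the analytic Jolicoeur/McArdle form
`slope·(√(B+1) ± √B)`, `B = (1−r²)·F(0.95; 1, n−2)/(n−2)`; intercept CIs
default to a seeded BCa bootstrap (2000 replicates) because no comparably
standard analytic interval exists for the RMA intercept, with the
slope-CI-propagated analytic interval available as an option. `P(r = 0)`
is the usual t test on n−2 df.

Two RMA slopes are compared with Clarke's large-sample test on the log
slope difference:

> `T = |log b₁ − log b₂| / √(s₁² + s₂²)`, `sᵢ² = (1 − rᵢ²)/(nᵢ − 2)`,

referred to a t distribution with Welch–Satterthwaite effective degrees of
freedom `df = (s₁²+s₂²)² / (s₁⁴/(n₁−2) + s₂⁴/(n₂−2))`. `sᵢ²` is the
asymptotic sampling variance of the log RMA slope under bivariate
normality. The test's size is verified by simulation in the test suite
(2000 null replicates at n = 50; rejection rate must fall in
[0.035, 0.065]). Slopes of opposite sign cannot be compared on the log
scale and raise an error rather than a silent absolute-value fudge.

Ontogenetic direction is summarized by `centroid_angles()`: the angle of
the (adult centroid − juvenile centroid) vector from the positive factor-1
axis, folded to [0°, 180°]. Angles above 90° mean relative neurocranial
size falls as size grows — the ancestral negative allometry.

## Heterochrony decomposition

`decompose_trajectory()` makes the scaling/transposition reading
operational. Given a reference RMA trajectory with an ontogenetic polarity
(the juvenile→adult direction), a target centroid is orthogonally projected
onto the line direction and its normal:

* `along` — signed displacement along the trajectory; beyond the reference
  centroid in the adult direction ⇒ *peramorphic*, behind it ⇒
  *paedomorphic*, within a configurable dead band (default 0.1 score
  units — about a tenth of a factor SD, small enough to matter
  scientifically, large enough to absorb centroid noise) ⇒ none;
* `offset` — signed perpendicular displacement; if it exceeds the
  reference line's 95% prediction-band half-width at that along-coordinate
  (perpendicular residual SD, widened for leverage), the target is
  *laterally transposed*.

`along² + offset²` equals the squared centroid distance, and the
decomposition is rigid-rotation equivariant. The labels quantify what is
otherwise a qualitative reading of a morphospace plot; the thresholds are
artifact decisions and are exposed as arguments.

## Encephalization associations

`compute_eq()` computes `EQ = ECV / (a·BM^b)` with defaults a = 1.77,
b = 0.76, a widely used primate scaling; the constants materially change EQ
and are therefore carried in every result and must be stated with any
reported value. `cranial_associations()` gives pairwise Pearson
correlations (complete cases, optionally per group) among the two factor
scores, log BM, log ECV and EQ; `partial_correlation()` implements the
first-order partial `r_xy·z` with a t test on n−3 df. The interesting
contrast on study-structured data: within a directional fossil lineage,
shape (factor 1) correlates with log ECV even after controlling EQ, but
not with EQ after controlling ECV — the trend tracks absolute brain size.

## Measurement-error robustness

`perturb_and_project()` multiplies each of a specimen's six measurements by
independent draws from Uniform(1−e, 1+e) — the most direct encoding of
"inaccuracies of up to e" — re-applies the model's own preprocessing and
scores the replicate in the fixed ordination (never refitting it). A
truncated-Gaussian option (SD e/2, truncated at ±e) is provided. Summaries:
the cloud's centroid shift from the original score and its RMS radius.
Because both scoring maps are linear in the log measurements, a fixed set
of perturbation draws displaces every specimen equally;
`robustness_summary()` therefore assigns each specimen its own derived
seed. The canonical setting is 500 replicates at e = 0.05; on the synthetic
sample this gives dispersions of ≈0.1 factor-score SD — fossils stay where
they were.

## The synthetic generator

`generate_dataset()` draws, for each specimen, a log10 cranial size `s`
from its group-and-stage Gaussian and sets
`log10(measurement) = c_g + s·b + (s − s̄_adult)·t_g + ε`,
with `b` the shared per-variable allometric slopes, `c_g` the group's
intercept vector (its lateral transposition), `t_g` an optional trend that
couples the transposition to size within a group, and `ε` Gaussian on the
log scale (multiplicative lognormal in mm). Body mass and endocranial
volume follow their own log-linear models in `s`, configurable per group.
Size proxies biological age — juveniles simply get a lower size mean —
which is exactly the assumption of the allometric-heterochrony approach.

`simulate_hominid_sample()` fixes one configuration as the package's
standing study-structured dataset (~91 specimens): four extant-like species
(adults plus a minority of juveniles) sharing strong module allometries
(`b` ≈ 0.3–0.4 neurocranial, 1.5–1.8 splanchnocranial, so facial lengths
nearly double over an ontogeny while vault lengths grow ~10–15%), a
human-like group strongly transposed toward a larger relative neurocranium,
an australopith-like fossil group whose ECV is independent of size, and an
extinct-Homo-like group whose transposition trends with size and whose ECV
scales with it. Proportions matter: the sample must be adult-dominated for
the shape contrast to lead the eigenstructure (with juvenile-heavy samples
the size factor takes over and all loadings turn positive); the chosen mix
reproduces the qualitative study structure — shape factor first
(≈60% vs ≈38%), a single dominant PLS dimension (>99.9%, block-score
r ≈ 0.998), within-species centroid angles in (90°, 180°), parallel clade
trajectories with non-overlapping intercept CIs — stably across seeds.

What the generator does *not* emulate: sexual dimorphism as a distinct
mixture (it is folded into the adult size SD), non-normal size
distributions, correlated measurement error between variables taken on the
same photograph, taphonomic missingness, and any within-group covariance
beyond the single latent size axis. Tests passing on synthetic data
therefore validate the estimators' algebra and calibration, not claims
about real crania.

A note on identifiability: with a *single* group the generator's signal is
rank one (size and shape change are perfectly coupled along the
trajectory), so a correlation-matrix PCA cannot separate a shape factor
from a size factor and the factor-plane slope has no stable sign.
Generating-parameter recovery is therefore tested on two laterally
transposed groups — the minimal configuration with the study's structure —
where the within-group population RMA slope is computed analytically by
pushing the generating covariance `σ_s² bbᵀ + τ²I` through the fitted
scoring map and compared with the fitted CI (coverage ≥ 90/100
replicates).

## Numerical choices and degenerate inputs

* Eigen/SVD come from base `eigen(symmetric = TRUE)`/`svd`; no iterative
  fitting anywhere, so determinism is structural (the only randomness is
  the generator, the bootstrap and the perturbation draws, all seeded).
* Sign indeterminacy of eigenvectors/singular vectors is resolved by the
  orientation conventions above, applied to u/v as a pair in the PLS so
  reconstruction is preserved.
* Constant columns, zero variances, n below the minimum for each
  estimator, opposite-sign slopes in the Clarke test, zero-length polarity
  vectors and collinear partial-correlation controls all raise immediate
  errors naming the offender.
* An exactly-on-line target against a noise-free reference (prediction
  threshold 0) is kept "on-trajectory" by a 1e−12 absolute guard.
* `r` exactly 0 in an RMA takes positive slope sign with a warning;
  unreachable on real scores.

## Problem sizes

The test suite runs at desk scale by design: the standing synthetic sample
has 91 specimens; Monte-Carlo calibrations use 2000 replicates (Clarke and
partial-correlation size), 100–200 replicates for coverage/geometry
oracles, and n = 200–500 for parameter recovery; robustness checks use
200–500 perturbation replicates. The whole suite completes in well under a
minute, and the acceptance analysis in a few seconds.

## Known limitations

* Six linear measurements summarize each module; the method sees gross
  proportions only, not local shape.
* The Clarke-test variance is asymptotic; at very small n (fossil
  subsets of ~10) its p-values are indicative, which is why the
  intercept contrast is interval-based rather than test-based.
* The BCa intercept interval inherits the bootstrap's small-sample
  wobble below n ≈ 15.
* Heterochrony labels depend on the chosen reference trajectory and
  polarity; they are descriptions of morphospace geometry, never claims
  about the underlying developmental process.
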