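---
title: "Mapping shape QTL from 3D landmarks: models, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping shape QTL from 3D landmarks: models, choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(morphoqtl)
```

# The problem

A backcross (N2) between two inbred mouse strains segregates exactly two
genotype classes at every autosomal locus — homozygote (AA) and heterozygote
(AB) — which makes it the simplest design in which to ask where in the genome
the shape of a bone is controlled. The phenotype here is not a scalar but a
landmark configuration: k points in 2 or 3 dimensions digitized on each
specimen (13 fixed anatomical landmarks on a hemi-mandible, optionally
augmented by hundreds of surface semilandmarks). After removing position,
scale and orientation, shape lives in a (kd − d − d(d−1)/2 − 1)-dimensional
space, and a locus affects it as a *vector*: a direction and magnitude of
deformation of the whole configuration.

`morphoqtl` implements the full chain: superimposition and semilandmark
processing, genotype probabilities on a centimorgan map, multivariate
multiple-QTL model search, per-QTL effect summaries, and comparison of the
QTL-based genetic covariance (G) matrices that different phenotyping choices
produce. A synthetic-data generator reproduces the study design end to end so
each stage is testable without any external data.

# Superimposition

`gpa()` performs full generalized Procrustes analysis: every configuration is
centered, scaled to unit centroid size, and iteratively rotated (orthogonal
Procrustes, reflections forbidden) onto the running mean, which is itself
renormalized each round until it stops moving (`tol = 1e-10`, default
`max_iter = 100`; in practice 3–6 iterations suffice). Procrustes coordinates
are analyzed directly — no tangent-space projection is applied — because the
variation in this regime is small (Procrustes distances of order 1e-2) and
the tangent approximation error is quadratic in it.

Two choices deserve a note:

* **Orientation of the common frame.** A Procrustes mean is defined only up
  to rotation. The converged solution is rotated onto the principal axes of
  the mean shape, flattest direction last, with axis signs fixed by the third
  moment of the landmark coordinates along each axis (a smooth function of
  the shape, so noise cannot flip it; ties fall back to the
  largest-coordinate landmark). This gives "x/y/z" a reproducible meaning,
  which the per-axis decomposition of QTL effects (`plane_decomposition()`)
  needs.
* **Separate GPAs per landmark set.** Landmark-only and semilandmark
  datasets are superimposed independently; their shape spaces are different
  and are only compared through the coordinates of the shared fixed
  landmarks.

# Semilandmarks

A template of surface points is drawn on a reference mesh by Poisson-disk
sampling (`poisson_disk_template()`): area-weighted random candidates are
accepted greedily at a minimum pairwise distance, with a radius solved
iteratively when a target count is requested, and optional exclusion regions
(teeth, in the motivating data). The template is carried onto each specimen
by the thin-plate spline interpolating the 13 fixed landmarks
(`transfer_template()`), then projected to the specimen's surface by exact
nearest-point-on-triangle search (`project_to_mesh()` handles vertex, edge
and face-interior cases).

Sliding (`slide_semilandmarks()`) relaxes the semilandmarks against the
reference by minimizing thin-plate-spline bending energy. Each iteration
solves the constrained generalized least squares in closed form, with each
semilandmark restricted to its local tangent plane (from mesh vertex normals
at the nearest surface point), then re-projects onto the mesh; default 3
iterations. Within an iteration the energy cannot increase; re-projection can
raise it slightly, which is why a handful of iterations rather than one is
used. Fixed landmarks never move. The TPS kernel is r^2 log r in 2D and
−r in 3D; the 3D sign is chosen so the bending-energy quadratic form is
positive semidefinite, making energies non-negative and zero exactly on
affine maps.

# Simulated 2D flattening

To quantify what a 2D imaging protocol loses, `flatten_to_2d()` emulates it:
each configuration is aligned to its principal axes, a resting plane is
defined by three anchor landmarks (optionally refined to the innermost mesh
vertices along the plane normal, with the normal kept pointing into the
body so the refinement settles on the resting side), and all landmarks are
projected orthogonally onto that plane. The in-plane basis is the principal
axes of the projected configuration, second axis right-handed about the
plane normal. Because any per-specimen sign rule can still land an
occasional specimen on its mirror image, `flatten_sample()` harmonizes
chirality across the sample against the first specimen — GPA never reflects,
so a single mirrored specimen would otherwise contaminate the leading PC.

# Measurement error

`measurement_error_anova()` runs a two-way Procrustes ANOVA on jointly
superimposed digitization sessions: specimen as random factor, session as
fixed factor, degrees of freedom multiplied by the shape-space dimension.
The session F tests for systematic inter-session differences; the
measurement-error percentage is the within-specimen variance component over
the total, overall and per landmark. The per-landmark version applies the
same variance-component ratio to each landmark's coordinates.

# The mapping model

Phenotype scores are the leading principal components of the aligned
coordinates retaining 95% of variance by default (`pca_reduce()`); Procrustes
data are rank-deficient, and the discarded dimensions are dominated by
registration noise. Effects are rotated back to coordinate space for
reporting, so norms and axis decompositions are in Procrustes units.

For individual i the model is

y_i | M_i ~ N_q( mu + sum_c x_ic beta_c + sum_j p_ij beta_j , S )

with covariates x (log centroid size, sex, direction of cross) and p_ij the
probability of the heterozygous genotype at QTL j given the flanking marker
observations M_i. Those probabilities come from a two-state hidden Markov
model on the cM map (`calc_genoprob()`): Haldane map function (no
interference), genotyping-error emission (default prior 0.001), pseudomarkers
at a configurable step (default 1 cM). Regression on the expected dosage is
the Haley–Knott approximation, which matches the model as written.

## Test statistics and LOD scales

Covariate and per-term inference uses Pillai's trace V = tr(H(H+E)^-1) with
the standard F approximation; at q = 1 this reduces exactly to the
univariate F test. The genome scan (`qtl_scan()`) reports two monotone
transforms of the same added-term statistic:

* `lod` = −log10 of the Pillai F p-value — the inference scale;
* `lod_lr` = (n/2) log10(|E_red|/|E_full|) = −(n/2) log10(1 − V) — the
  multivariate likelihood-ratio LOD, which at q = 1 is the classic
  Haley–Knott LOD.

Model selection runs on the likelihood-ratio scale, for a structural reason:
the LR model LOD telescopes exactly over nested models, so the penalized
score pLOD(model) = LOD − T·|model| increases under an addition precisely
when the added QTL's conditional LOD exceeds the penalty T, and the backward
rule "drop if removal raises pLOD" is identical to "drop if conditional
LOD < T". P-value-based alternatives were examined and rejected: the joint
Pillai F p-value saturates as model size grows (a QTL with single-scan LOD 13
added ~2 to a 10-QTL model's −log10 p), and a sum of per-QTL type-III LODs is
not nested-consistent, letting linked sub-threshold ghost loci survive the
backward phase. Both LOD scales are reported per QTL in the fitted model.

Because the scan maximum and permutation exceedances are invariant under a
monotone transform at fixed residual df, the choice of scale does not move
peak positions or change which scans are genome-wide significant; residual
df does drift slightly as the model grows (n − p − 1), a negligible effect at
the study's n.

## Permutation penalty

`perm_threshold()` permutes the rows of the covariate-adjusted phenotype
residuals against the genotype block (1000 permutations by default), runs a
single-QTL genome scan per permutation, and takes the 95th percentile of the
genome-wide maximum LOD. Permuting residuals rather than raw phenotypes
keeps the covariate structure out of the null; the per-permutation scan then
uses intercept-only residual df (n − 2), marginally different from the
covariate-adjusted df of the real scan. The threshold is returned on either
LOD scale (`stat = "lr"` for the search, `"pillai"` for reporting).

## Search, intervals, effects

`forward_backward_search()` repeatedly adds the genome-wide best QTL given
the current model, refines every position by per-chromosome profile scans
holding the others fixed (up to 3 sweeps, iterated to stability), attempts
backward drops, records every visited model, and returns the visited model
maximizing pLOD. Same-chromosome QTL are kept ≥ 10 cM apart; ties break
deterministically toward the lower chromosome then position. Bayes credible
intervals come from the normalized 10^LOD profile (LR scale — the classic
choice for interval support) as the smallest highest-density set of grid
positions reaching 95% coverage.

`effect_summaries()` reports, per QTL: the Procrustes norm of the effect
vector; the type-III percentage of total Procrustes variance (%SST,
denominated in the full variance including discarded PCs); the projection
scores v = Y beta'/||beta|| with the percentage of their variance explained
by the QTL; the closed-form expectation of that percentage for unlinked
backcross QTL, ||beta||^4 / (beta (B'B + 4 Sigma_e) beta'), implemented in
the reading that reduces to genetic/(genetic + environmental) variance in
the beta direction (for one QTL with isotropic error it is
||beta||^2/(||beta||^2 + 4 sigma^2)); and the fraction of the effect along
each coordinate axis. Projection scores are computed on the
covariate-adjusted phenotype so the empirical ratio and its expectation
refer to the same variance decomposition.

# G matrices and their comparison

`qtl_G()` assembles G = B'CB from the coordinate-space effect rows and the
dosage covariance C — empirical by default (capturing linkage between
same-chromosome QTL), or the unlinked backcross closed form I/4. P
(`phenotypic_cov()`) is the covariance of covariate-adjusted Procrustes
coordinates by default, consistent with the mapping model; the raw
covariance is a toggle. Comparisons:

* `root_euclidean_distance()` — Frobenius distance of symmetric matrix
  square roots;
* `gmax_angle_test()` — angle between leading eigenvectors folded to
  [0°, 90°], with p from uniformly random axis pairs in the same dimension.
  When leading eigenvalues are near-tied the leading axes of two matrices
  can permute; the function exposes a `which` argument to examine
  alternative pairings rather than silently swapping, and warns on ties;
* `krzanowski_subspace()` — H = sum of projectors onto each matrix's leading
  eigenspace (smallest set reaching 90% of variance); each H eigenvalue
  equals the sum of squared cosines of the angles to the subspaces, upper
  bound the number of matrices;
* `multivariate_heritability()` — eigenvalues of G P^− (Moore–Penrose
  inverse, rank tolerance 1e-10 relative), clipped into [0, 1] with the
  clipping counted.

# The synthetic study

`sim_mandible_study()` fixes the generative conditions once: 427 individuals
of an N2 backcross on 19 autosomes with mouse-like cM lengths and 15 cM
marker spacing (~130 markers); 13 3D landmarks on a flat, elongated,
mandible-like reference of unit centroid size; genotyping error 0.002 and
missingness 0.02; 15 QTL with effect norms spaced over 0.004–0.012
Procrustes units, directions biased into the flat plane (out-of-plane
components scaled by 0.4); covariate effects sized so that size, sex and
cross-direction explain a few percent of the total Procrustes variance with
direction-of-cross the largest; isotropic individual error with total trace
0.002 (diagonal and two-factor error structures are available, since the
real error structure is not identifiable from published summaries). With
these defaults the planted QTL carry ~12% of the total Procrustes variance
and per-QTL shares of ~0.2–1.8%, the magnitudes typical of mouse mandible
data. Effect vectors are projected into the shape tangent space at the
reference (translations, rotations and scaling removed), so superimposition
recovers them without shrinkage; the size covariate doubles as the
de-superimposition scale so measured log centroid size is the planted
allometric variable. Genotype dosages at QTL between markers are drawn from
the exact Markov-bridge distribution given the flanking true genotypes.

What the generator does *not* emulate: curved-manifold digitization error
(error is Gaussian in coordinates), measurement error correlated along the
surface, epistasis, imprinting or QTL-by-covariate interactions, X-linked
loci, and segregation distortion. Passing tests therefore demonstrate the
correctness and calibration of the machinery under the stated model, not
robustness to those violations.

# Numerical choices and degenerate inputs

* Orthogonal Procrustes rotations flip the smallest singular vector when the
  optimum is a reflection; a reflection-only optimum therefore yields the
  best proper rotation.
* TPS systems are solved directly; collinear (2D) or coplanar (3D) control
  points raise an explicit singular-system error.
* The sliding normal equations carry a 1e-10 relative ridge, since tangent
  directions of nearly-affine displacement fields can be degenerate.
* Genotype probabilities use scaled forward–backward recursions; a zero
  emission row cannot occur for error_prob > 0.
* Flat LOD profiles return the whole chromosome as interval, flagged.
* Zero-norm effects, empty models, zero P matrices, rank-deficient designs
  (with the aliased columns named) raise errors rather than propagating NaN.

# Problem sizes used in the shipped checks

The test suite exercises the machinery at sizes chosen to estimate each
property well while keeping a full run in about a minute of CPU: genome-scan
calibration over 200 null studies of n = 200 with 200 permutations each;
recovery of three planted QTL (directional h² ≈ 0.15 each) over 50
replicates at n = 430 with 20 markers per chromosome; the h²-expectation
check at n = 5000; end-to-end 3D and 2D pipeline runs at n = 427 with 150
permutations. `scripts/acceptance.R` reruns the full study (both arms, 1000
permutations) and writes the headline quantities as JSON.

# Known limitations

* Haley–Knott regression slightly underestimates effect variances at typed
  markers with missing neighbors compared with a full mixture likelihood;
  at this marker density the difference is far below the reported digits.
* The pseudo-marker grid snaps requested positions to the nearest grid
  point; intervals are reported at grid resolution.
* %SST values are type-III and do not sum exactly to 100 with correlated
  dosages; they do on orthogonal designs.
* The search is greedy; two tightly linked QTL in repulsion can be fit as
  one intermediate locus, the standard failure mode of forward selection on
  linked predictors.
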