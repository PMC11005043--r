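---
title: "Predicting enzyme variant activity change from sequence, structure and dynamics biodescriptors"
author: "fcaflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting enzyme variant activity change from sequence, structure and dynamics biodescriptors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fcaflow)
```

## The problem

Directed-evolution campaigns produce libraries of enzyme variants — here,
epPCR-style libraries with zero to nine co-occurring substitutions at a
limited set of hot-spot positions — together with an activity readout. The
response modelled throughout this package is the *fold change in activities*
(FCA): each variant's activity is first normalized by the template enzyme's
activity under the same conditions (a *fold activity*), once without and
once with a pre-incubation heating step, and FCA is the difference between
the two folds (the with-heating fold minus the without-heating fold by
default; the sign convention is an argument of `computeFCA()` because only
"the difference between settings" is defined by the assay).

The scientific question is whether molecular-dynamics (MD) derived
descriptors of a variant's structure add predictive value over
sequence-derived descriptors, and which physical features drive the
prediction. The package implements the full workflow: featurization into a
tagged biodescriptor table, statistical quality control of the trajectories
that feed it, model benchmarking, and interpretability diagnostics — plus a
seeded synthetic-data generator so that every stage is testable at desk
scale without any simulation engine.

## The biodescriptor table

A variant is described by 192 features in three blocks, held in a
`FeatureTable` (a `SummarizedExperiment` with features as rows, variants as
columns, block and aggregation tags in `rowData` and the FCA response in
`colData`):

* **SEQ (80)** — 66 scale descriptors: the per-residue values of ten
  published physicochemical scale families (BLOSUM indices 10, Cruciani 3,
  FASGAI 6, Kidera 10, MS-WHIM 3, ProtFP 8, ST-scales 8, T-scales 5,
  VHSE 8, zScales 5) averaged over the sequence; plus 14 global properties
  (length, molecular weight, isoelectric point, aromaticity,
  charged-residue fraction, GRAVY, net charge at pH 8, reduced molar
  extinction coefficient, mean flexibility, helix/turn/sheet propensity
  fractions, aliphatic index, Boman index). All 80 are composition-based
  and therefore invariant to residue order; position-encoded descriptors
  are deliberately not used. The ten-family completion of the named scale
  sets is the unique standard combination whose dimensions sum to 66. One
  deviation from the obvious global-property set: the instability index
  requires the 400-entry dipeptide weight matrix, which no installed source
  provides; the charged-residue fraction at the assay pH takes its place so
  the count stays at 14.
* **MD (32)** — twelve geometry series (superposed RMSD and mass-weighted
  radius of gyration, each for heavy-atom/backbone/C&alpha; selections over
  the whole protein and over the binding site) summarized per replicate by
  their frame mean and aggregated across replicates into a mean and a
  population SD (24 columns), plus the eight mean secondary-structure
  fractions (&alpha;-helix, 3-10 helix, parallel and antiparallel sheet,
  turn, bend, coil, other). The composition 24 + 8 = 32 is this package's
  reconstruction of an unenumerated feature set and is deliberately
  explicit in the column names.
* **POCKET (80)** — binding-site descriptors: frame-summarized pocket
  geometry (convex-hull volume, maximum extent, mean depth to the hull
  surface), total site SASA (Shrake–Rupley), site hydrophobicity
  (Kyte–Doolittle mean), per-slot residue occupancy and normalized
  B-factor (`B = (8*pi^2/3) * RMSF^2`, z-scored across the site) for 16
  canonical site-residue slots ordered by residue id, and six chemistry
  counts at pH 8 (His uncharged, pKa ~6). Sites smaller or larger than 16
  residues are zero-padded or truncated with a warning. These are
  documented geometric/chemical proxies for cavity-detection outputs, not a
  reimplementation of an alpha-sphere method: the convex hull is
  deterministic, dependency-light and rank-correlates with cavity size on
  toy systems.

The binding site itself is fixed once from the template: all residues with
a heavy atom within 3.5 &Aring; (inclusive) of a ligand heavy atom.

Replicate aggregation everywhere follows one rule (`aggregateReplicates()`):
each per-replicate scalar (a frame mean, an occupancy, a z-score) is
reduced to its mean over replicates and the population SD (ddof = 0) over
replicates. A single replicate therefore has SD 0, and frozen trajectories
zero out every `_std` column.

## Secondary structure

`assignSecondaryStructure()` is a compact DSSP-style assignment: amide
hydrogens are reconstructed 1 &Aring; from N along the preceding carbonyl
C=O direction (prolines and the N-terminus donate nothing); the
Kabsch–Sander electrostatic energy
`E = 0.084 * 332 * (1/rON + 1/rCH - 1/rOH - 1/rCN)` kcal/mol defines a
hydrogen bond below -0.5 kcal/mol; &alpha;- and 3-10 helices require two
consecutive i&rarr;i+4 / i&rarr;i+3 turn bonds; strand labels come from the
parallel/antiparallel bridge patterns; isolated turn bonds mark turns;
C&alpha; curvature above 70&deg; marks bends; everything else is coil.
Deliberate simplifications (documented non-goals): no chain-break handling,
no &pi;-helix priority rules, no PBC unwrapping — the synthetic
trajectories are whole molecules. Pairs with C&alpha; separation above
9 &Aring; are skipped, the standard DSSP screen.

## The synthetic generator

The generator stands in for a simulation engine, not for physics. Its job
is to produce data with the statistical structure the downstream analysis
assumes: autocorrelated frames, replicate-to-replicate variability, and
variant-specific secondary-structure content.

* `makeTemplate()` builds an idealized backbone by internal-to-Cartesian
  chain construction: helices at (&phi;,&psi;) = (-57&deg;,-47&deg;),
  strands at (-119&deg;,113&deg;), four-residue type-I &beta;-turns in the
  loops, randomized coil dihedrals elsewhere, and a small peptide-like
  ligand anchored 3 &Aring; outside designated residues so a non-empty
  binding site always exists. The default study template has 101 residues,
  two helices (8–28, 44–64) and six turn segments.
* `makeVariantLibrary()` draws, per variant, a truncated-Poisson
  (mean 3.4, maximum 9) number of substitutions at 30 hot-spot positions
  (18 in helices, 12 in turns). These defaults are the study conditions:
  30/101 = 29.7% of positions can ever be mutated, the mean pairwise
  identity stays above 90%, and roughly a quarter of variants carry five or
  more mutations. They were fixed from the experimental library's printed
  summary statistics and are not tuning knobs.
* `simulateReplicates()` adds a stationary mean-reverting (AR(1),
  &rho; = 0.9 by default) Gaussian deviation to the template, per
  coordinate, with stationary SD equal to a per-atom amplitude: the base
  0.15 &Aring;, scaled by 1.5 in loops and by 3 at mutated positions
  (&plusmn;1 residue). This is the simplest process with the two properties
  the robustness statistics actually probe — autocorrelation within a
  trajectory and variability between replicates — and it makes helix and
  turn content degrade where mutations land, which is what gives the
  variant library genuine secondary-structure variation. With &rho; = 0 and
  amplitude *a*, the closed-form stationary RMSF is *a*&radic;3; the test
  suite verifies the generator against this at 10&#8308; frames.
* `plantResponse()` defines the ground truth:
  `FCA = sum_j coef_j * z(feature_j) + eps`, with per-column
  standardization and Gaussian noise. The default coefficients,
  +1 on the mean &alpha;-helix fraction and -1 on the mean turn fraction
  with noise SD 0.5, mirror the qualitative experimental finding that
  helix content associates with higher FCA and turn content with lower.
  Because the response is planted on *observed* features, recovery
  experiments remain valid at any trajectory length. The planted response
  is linear; no epistasis term is included by default because no functional
  form is available to emulate.

What passing tests on this generator do **not** show: that real MD
trajectories have Gaussian fluctuations, that real FCA is linear in any
descriptor, or that the effect sizes are realistic. They show that *if*
signal of the planted kind is present, the pipeline's featurization,
model-selection and interpretation machinery finds it and attributes it to
the right features.

## Trajectory robustness statistics

Replicate MD runs are noisy; before features are trusted, the package
provides the evaluation protocol used on the experimental trajectories:

* `chunkAnovaMatrix()` splits each RMSD series into contiguous 10 ns chunks
  and compares every chunk against the first by one-way ANOVA (frames
  pooled across replicates by default; a nested per-replicate-mean mode is
  available because the pooling rule is genuinely ambiguous). The
  significance level is an uncorrected 0.05, matching single-threshold
  heatmap practice; multiplicity handling is left to the caller.
  On stationary series with independent frames the type-I error is
  calibrated at &alpha; (verified on 200 synthetic variants). Frame
  autocorrelation inflates the pooled-frames test — a known caveat of the
  protocol, which is why the calibration uses white series.
* `hausdorffDistance()`/`psaMatrix()` implement path-similarity analysis:
  trajectories as sequences of conformations, the frame metric being
  pairwise superposed RMSD, the directed distance `max_p min_q RMSD(p,q)`,
  symmetrized, then Ward clustering of the pairwise matrix. Bands at
  0.5/3.0 &Aring; classify path pairs as identical / intermediate / highly
  different (`classifySimilarity()`).
* `retentionShuffleTest()` checks that replicate differences survive
  averaging: 20 folds, each drawing the same random 80% of frames in every
  replicate (paired subsampling, so identical replicates give identical
  fold means), then ANOVA across replicates on the fold means; retention is
  declared at p &lt; 0.05.
* `chooseMinLength()` turns the chunk ANOVA into a decision: the largest
  horizon through which at least 80% of variants show no significant
  difference from the first chunk. If the first chunk is representative of
  the whole horizon, its length alone is returned as informative; if no
  horizon qualifies, the longest is returned with a warning.

## Model benchmarking

`screenModels()` fits a roster of library-backed learners (baseline mean,
linear, ridge, lasso, radial SVM, CART, random forest, gradient-boosted
trees, a small neural network, and Poisson/Gamma GLMs) with default
parameters, scores them on the held-out test set, and excludes models with
negative test R&sup2; or whose response-domain requirement the data violate
(the Poisson and Gamma entries exist precisely to exercise that rule: FCA
takes negative values). Survivors rank by R&sup2;, ties by RMSE, then fit
time. A learner that throws is recorded, never fatal. Note one boundary
fact: on held-out data the horizontal-line baseline itself scores slightly
below zero almost surely, so the strict R&sup2; &lt; 0 rule excludes it.

Features are min–max rescaled with extrema from the training rows only
(constant columns map to 0; out-of-range values are not clipped). The 80/20
split floors the training size, so 312 variants give 249/63.
`tuneRandomSearch()` draws random hyperparameter sets and scores them by
mean negative MAE over 5-fold CV. `bootstrapCompare()` refits the tuned
model on bootstrap resamples of the training set (500 iterations by
default) and scores each on the fixed test set, for each of the seven
feature-block combinations (`blockSubsets()`); `anovaTukey()` then runs
one-way ANOVA and Tukey HSD across the per-dataset metric distributions.
The headline learner is xgboost's gradient-boosted tree ensemble — the
installed gradient-boosting library in this stack.

## Interpretation

`permutationImportance()` measures the drop in a score metric when one
column is permuted (sign-flipped for error metrics, exact zero for constant
columns). `treeImportances()` extracts gain and split-count rankings from
the fitted booster. `shapSummary()` delegates per-instance attribution to
the booster's TreeSHAP and is validated against `shapleyExactSmall()`, an
exact coalition-enumeration Shapley oracle with background-mean
substitution (at most 12 features, local accuracy to 1e-10); the two
provably coincide on stump ensembles whose cover statistics equal the
background frequencies, which is the regime the equality test uses.

The concordance between the two rankings (the fraction of the top-20
permutation features that also appear in the top-20 SHAP ranking) is
evaluated with both rankings computed over the full variant set, the same
convention the SHAP summary itself uses: on a 63-variant test set the
near-zero tail of either ranking is estimation noise and the overlap
statistic is meaningless there.

`errorThresholdLabels()` labels residuals beyond their empirical 5%/95%
quantiles (type-7, linear interpolation — the convention had to be fixed
somewhere) as poor predictions, and `hypergeometricEnrichment()` tests
whether flagged variants (by default, five or more co-occurring mutations)
are over-represented among them: one-sided upper tail of
Hypergeometric(N, K, s) via log-gamma summation, enrichment fold
(k/s)/(K/N). Whether the population N is the test set or the full library
is the caller's choice — both are meaningful and the experimental report
leaves it ambiguous.

## Numerical choices

* Kabsch superposition uses SVD with the proper-rotation determinant
  correction; RMSD series use a lean path that reads the post-fit RMSD off
  the singular values and floors results below 1e-5 &Aring; to zero
  (floating-point cancellation on identical conformations sits at the
  square-root-of-epsilon scale, far below any physical RMSD).
* Collinear point sets are rejected as degenerate (second singular value
  relative test at 1e-10).
* The convex hull is a small incremental algorithm (C++ for the per-frame
  path, with an R implementation kept as an independent cross-check in the
  tests); volume comes from facet tetrahedra against an interior point.
* SASA uses deterministic golden-spiral sphere points (960 for the
  standalone operation, 96 per atom in the per-frame pipeline, where the
  few-percent per-atom sampling error averages out over frames and
  replicates, and occluders are pre-screened by template neighbour lists
  with a 3 Å fluctuation margin).
* The isoelectric point is solved by bisection on the EMBOSS-pKa
  Henderson–Hasselbalch net charge to |charge| &lt; 1e-4, verified against
  a dense pH grid.
* Seeding: every stochastic operation takes a seed; nested streams are
  derived with a fixed integer mix kept below 2^31, and generator calls
  restore the caller's RNG state.

## Problem sizes used by the tests and the acceptance script

The packaged experiments run at desk scale, chosen as the package's own
defaults: the schema check featurizes 20 variants at the default 101
frames per trajectory; the parameter-recovery experiment uses 300 variants,
five replicates and 21 frames per trajectory (the planted response is a
function of the measured features, so shorter trajectories change only the
measurement noise, not the validity of the recovery check); trajectory
robustness statistics use a single variant simulated for ten 10 ns chunks;
the calibration experiments use 200 synthetic variants and 60 seeds. A
config switch (`frames_per_traj`) scales trajectories up to 1001 frames per
10 ns when full-length series are wanted.

## Worked example

```{r example, eval = FALSE}
library(fcaflow)

spec <- synthSpec(nVariants = 40L, framesPerTraj = 21L, seed = 1L)
study <- buildStudyFeatureTable(spec)
study$table
#> FeatureTable: 40 variants x 192 features (SEQ 80 | MD 32 | POCKET 80)

sp <- trainTestSplit(study$table, seed = 1L)
sc <- minmaxScale(featureMatrix(study$table), fitRows = sp$train)
y <- responseFCA(study$table)
lr <- learnerRoster(seed = 1L)
fit <- lr$gbt$fit(sc$scaled[sp$train, ], y[sp$train])
regressionMetrics(y[sp$test], lr$gbt$predict(fit, sc$scaled[sp$test, ]))
```

## Known limitations

* The planted response is linear in z-scored features that are themselves
  driven by discrete mutation counts with saturating effects, so its
  distribution is lumpier and more skewed than a typical experimental FCA
  distribution; the generator emulates the library's composition statistics
  faithfully, but not the response's exact distributional shape.

* The generator's fluctuations are isotropic Gaussian with a single
  mean-reversion constant; real MD has correlated collective modes,
  anisotropy and slow transitions. Conclusions about the *pipeline* carry
  over; conclusions about *proteins* do not.
* The pocket descriptors are geometric proxies; they are not alpha-sphere
  cavity measurements and carry no druggability semantics.
* The DSSP-style assignment omits edge cases (chain breaks, &pi;-helices);
  on idealized and mildly perturbed geometry it reproduces the expected
  labels, which is the regime the synthetic data occupies.
* The 66-scale tables were transcribed into the package source from the
  primary literature; each family's citation is in the source. Downstream
  checks treat the tables themselves as ground truth.
* Sequences must be equal-length (no alignment); mutation positions are
  1-based over the mature sequence with no offset handling.
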