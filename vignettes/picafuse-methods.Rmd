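---
title: "Parallel ICA with reference: model, calibration and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Parallel ICA with reference: model, calibration and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette records the model the package implements, the calibration
of its synthetic cohort generator, and the design decisions taken where
the method leaves room — the reasoning a maintainer needs before turning
any of its knobs.

## The model

Both modalities are treated as linear mixtures of statistically
independent sources.  For the imaging modality, `X1` (subjects x in-mask
voxels of gray-matter concentration) is decomposed as `X1 = A1 S1`; for
the genomic modality, `X2` (subjects x SNPs, minor-allele dosages entered
as centered unit-variance columns with mean imputation of missing calls)
as `X2 = A2 S2`.  The rows of `S` are the component maps and SNP weight
profiles; the columns of `A = W^-1` are per-subject loadings.

Estimation is natural-gradient Infomax: with `U = W X + W0` and the
logistic transfer `Y = 1/(1+exp(-U))`, each mini-batch applies

    W <- W + lr * (I + (1 - 2Y) U' / B) W
    W0 <- W0 + lr * rowMeans(1 - 2Y)

after PCA whitening to `k` components per modality.  The logistic score
matches super-Gaussian sources, which both modalities' components are:
spatial maps are localized (near-zero over most of the brain) and SNP
profiles are sparse (most loci carry no weight).

Two additional terms act on the genomic modality and the coupling:

* **Reference similarity.**  For each reference gene a nonnegative
  unit-norm weight vector over its SNP columns is supplied.  Each epoch,
  the gene is bound to the component with the largest reference-weighted
  share of its weight mass at those loci, and a gradient step on
  `|| |s|/||s|| - r ||^2` (restricted to the gene's columns, weighted
  `1 - lambda`) is blended with the `lambda`-weighted Infomax direction.
  With `lambda = 1` the update is exactly the unconstrained one.
  The binding score is mass concentration rather than a correlation with
  `r`: a correlation degenerates when the reference weights are uniform
  (zero variance) and, for near-uniform references, is maximal for flat
  noise rows rather than for components actually concentrated at the
  gene.
* **Correlation enhancement.**  After each epoch the `n1 x n2` table of
  loading-column correlations is computed; pairs exceeding an engagement
  threshold receive analytic gradient-ascent steps on
  `Corr^2(A1_i, A2_j)`, back-propagated to the unmixing matrices through
  the (diagonal) whitening geometry.

## Why the enhancement term is gated the way it is

The enhancement term is an amplifier: once a pair engages, gradient
ascent raises its correlation regardless of whether the coupling is real.
At 715 subjects with an 8 x 8 component grid, the *null* maximal pair
correlation (max of 64 correlations with standard error ~ `1/sqrt(n)`)
sits around 0.09–0.11, so an engagement threshold at 0.10 lets the term
latch onto chance pairings — measured directly, subject-mismatched runs
then report maximal correlations of 0.24–0.31 and the permutation null is
destroyed.  Three safeguards keep the term useful:

1. engagement is decided on an exponentially smoothed (`alpha = 0.2`)
   correlation table, so one noisy epoch cannot trip it;
2. when a reference matrix is supplied, only pairs whose genomic member
   is a reference-bound component are eligible — the reference nominates
   the component of interest, and chance pairings of the unconstrained
   components are never amplified;
3. the default threshold (0.12) sits above the typical null maximum at
   the cohort sizes the package targets, and the enhancement rate is
   annealed together with the Infomax rates.

With these in place the enhancement raises a genuinely coupled pair by a
few hundredths of correlation and leaves mismatched data untouched, which
is what permits a calibrated permutation test.

## Optimizer settings

Defaults: `k = 8` components per modality (the pair family stays small —
64 tests), `lambda = 0.9`, learning rates 0.03 with a deterministic
per-epoch decay of 0.995 plus a 0.9 annealing factor whenever the total
objective decreases, batch size 256, up to 512 epochs, convergence when
the mean absolute unmixing change drops below 1e-6.  Rates of 0.01
converge too slowly for the imaging rotation (still drifting after 512
epochs); 0.03 with decay reaches the same solution in ~250.  Component
sign is fixed by making each row's largest-magnitude weight positive;
argmax ties in pair selection break to the lower index pair.

Two failure modes are guarded: an epoch whose unmixing matrix falls below
reciprocal condition number 1e-8 is rejected with the rate halved, and a
finished run with near-duplicate component rows (absolute correlation
above 0.95 — the classic Infomax row-collapse) is restarted up to twice
at half the rates from a re-derived initialization.  Collapse occurred in
roughly one in five small-cohort resampling runs before the guard.

## The synthetic cohort generator

The generator produces the statistical structure the analysis assumes,
with a `predict_hd` preset fixing the emulated study sample: 715
subjects, 50 site/scanner combinations, CAG repeats ~ N(42.5, 2.5^2)
truncated at 36 (rounded to integers), a coupled component pair with
loading correlation 0.17 carried by 28 tail subjects, and four
reference-gene SNPs among the coupled component's ten largest weights.

* **Genotypes.**  A latent Gaussian per SNP with equicorrelated LD blocks
  (10 SNPs, latent correlation 0.3), thresholded at the Hardy–Weinberg
  quantiles of a per-SNP MAF drawn from (0.10, 0.50); the lower bound
  keeps realized sample MAFs above 0.05 at n = 715.  Component signal is
  injected on the latent scale before thresholding, so dosages stay in
  {0,1,2} while carrying the planted structure (thresholding attenuates
  the per-SNP signal by ~20%, which the analysis sees as real data
  would).  Related pairs copy the latent background (not the signal) with
  correlation 0.95; missing calls are planted completely at random.
* **Component geometry.**  Active SNP counts default to 4% (coupled) and
  3% (other components) of the panel, so the component eigenvalue gap and
  the fraction of structured columns are invariant across desk scales.
  Spatial maps are sums of three Gaussian blobs with widths scaled to the
  grid; the primary blob centers are spread maximin-greedily because
  near-coincident peaks make the sources nearly collinear and degrade the
  rotation for some seeds.
* **Tail-driven coupling.**  The coupled SNP loading draws the bulk from
  a normal truncated inside 1.8 SD and the tails from 2.3–4.0 SD, so
  after standardization the planted tails are exactly the subjects with
  `|z| >= 2`.  The imaging loading couples only through the tail subjects
  (bulk residuals are orthogonalized), and the coupling scale is solved
  numerically so the realized sample correlation equals the target
  exactly.  Removing the tails therefore removes the correlation by
  construction.
* **Confounds and clinical scores.**  Age, sex and per-site offsets are
  added to the voxels as smooth spatial patterns; clinical measures are
  linear in the coupled imaging loading with noncentrality `F - 1`
  (making the expected F statistic equal the target, default 5.5 at
  ~674 complete cases) and signs following the measure conventions
  (timed tests and the motor score worsen upward, correct counts improve
  upward).

What the generator does **not** emulate: scanner artifacts beyond
additive site offsets, realistic chromosome maps or LD decay, ancestry
structure (the MDS stage runs but has nothing to find), genotyping batch
effects, and any nonlinearity between brain structure and clinical
scores.  Passing tests therefore demonstrate that the pipeline recovers
the structure it assumes, not that the assumptions hold in real cohorts.

Noise scales (`gmc_signal_sd = 0.08` against `gmc_noise_sd = 0.03`,
`snp_signal_var = 0.45`) were chosen once so that the planted coupled
pair is recoverable to within ±0.05 of its embedded correlation at the
preset dimensions; they live in the specification object, not in code.

## Preprocessing and QC decisions

* Filter order is missingness (SNP level, then sample level, iterated to
  a fixed point), MAF (strictly greater than 0.05), windowed LD pruning
  (r^2 ceiling 0.5, window 50, step 5, windows never spanning
  chromosomes), then relatedness exclusion — the conventional ordering.
* Relatedness uses a method-of-moments identity-by-descent estimate from
  identity-by-state counts and allele frequencies; pairs above 0.18 are
  grouped into families by union–find and the first member in subject
  order is kept.  Exact parity with other implementations is not a goal.
* MDS ancestry factors (classical scaling of the allele-sharing distance)
  are computed but applied nowhere by default; they are offered as
  optional adjusters, the least invasive reading of their role.
* Voxelwise nuisance regression fits intercept + age + sex + (L-1) site
  dummies per voxel and returns residuals with the intercept added back,
  keeping values on a concentration-like scale (a flag disables the
  restoration).  With 52 design columns at n = 715, the regression
  removes ~7% of any subject-level signal's variance by chance alone —
  an attenuation the real design shares, and the main reason recovered
  pair correlations sit slightly below the embedded value.

## Validation conventions

* The permutation test shuffles the genomic modality's subject rows and
  reruns the full coupled decomposition each time.  Row permutation
  leaves a column-centered matrix's subject-space covariance — hence its
  whitened representation — bit-identical, so the implementation whitens
  once and permutes only the loading-recovery map: an exact algebraic
  identity, not an approximation.  The reported ratio is
  `#(null >= observed)/n_perm`, with an add-one smoothed variant behind a
  flag.  A fast mode that only re-correlates fixed loadings is available
  and labeled as the approximation it is.
* k-fold replication matches the full run's maximal pair to each fold's
  components by loading correlation over the shared subjects.  Weight-map
  matching was tried first and is unreliable here: estimated maps carry
  noise on the ~96% inactive loci, and fold runs share 90% of subjects,
  so cross-run map correlations are dominated by shared-noise alignments.
  The matched maps' weight-vector similarity is still reported per fold.
  A fold replicates when the matched pair is significant at 0.05 after
  Bonferroni correction over the pair family.
* Influence flags require Cook's distance above `4/n` **and** leverage
  above three times the mean hat value.  The bare `4/n` rule flags
  high-residual subjects of ordinary leverage (about three expected at
  n = 715), which contradicts the tail-specificity the diagnostic is
  meant to establish; the leverage gate restricts flags to subjects more
  than ~2.2 SD out on the genomic loading, matching the
  studentized-residual-by-hat reading of an influence plot.  Both
  thresholds are arguments.

## Clinical association

Each measure is modeled by ordinary least squares on an intercept plus
the covariate (component loading or single-SNP dosage) and optional
adjusters, complete-case per measure; the covariate's F test (`df1 = 1`,
so `F = t^2`) is reported with a Bonferroni adjustment over the
seven-measure family and a direction call mapping the coefficient sign
through the measure's metadata (`protective` when a higher covariate
predicts better performance; `n.s.` below significance).  Degrees of
freedom follow the actual complete cases rather than any fixed target.
A joint multivariate test is out of scope; the reported statistics are
univariate by design.

## Problem sizes used by the tests

Module tests run on cohorts of 70–300 subjects with a few hundred SNPs
and voxels and 3–4 components; the end-to-end recovery checks use the
full preset (715 x 5,000 SNPs x 8,000 voxels, five seeds) and a reduced
preset (2,000 x 2,000) for the 100-permutation null, sizes chosen so the
whole suite completes in a few minutes on one CPU while the preset runs
keep the study's subject count and effect sizes exact.

## Known limitations

The optimizer is a stochastic natural-gradient scheme: different seeds
give slightly different rotations, and the recovered pair correlation
varies by ±0.02–0.03 around its expectation across seeds.  The
reference constraint assumes the candidate gene's signal is concentrated
enough to win the mass-binding; diffuse references bind unstably.  The
permutation test inherits the enhancement term's gating: with thresholds
lowered far below the null maximum, the null inflates and the test loses
calibration.  Dosage thresholding bounds the genomic loading recovery
near 0.97 regardless of sample size.
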