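---
title: "Methods: multimodal brain-behavior PLS correlation in bbpls"
author: "bbpls authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multimodal brain-behavior PLS correlation in bbpls}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

`bbpls` implements partial least squares (PLS) correlation between a block
of ordinal symptom items and a block of multimodal imaging features. With
`Y` the z-scored participants x items matrix and `X` the z-scored
participants x imaging-components matrix, the method decomposes the
cross-covariance

    R = t(Y) %*% X = U S t(V)

by singular value decomposition. Each latent component (LC) pairs a
behavioral weight vector (a column of `U`) with an imaging weight vector
(a column of `V`); participants receive composite scores `LX = X V` and
`LY = Y U`, and the interpretable effect maps are *loadings*: Pearson
correlations of the original (residualized) variables with the composite
scores. The covariance explained by component `l` is
`S[l]^2 / sum(S^2)`.

PLS correlation makes few assumptions — it is a descriptive decomposition
of a cross-covariance — but the inferential machinery around it assumes
(i) exchangeability of participants *within acquisition site* under the
null, which is why permutations and bootstraps are site-constrained, and
(ii) approximate normality of bootstrap loading distributions, which
underlies the z-score / two-sided-normal-p summary.

# Pipeline stages and their parameters

1. **Matched split** (`matchedSplit`). Participants are split
   discovery:replication at a target ratio (default 2/3) within strata of
   site x sex x age tertile x overall-psychopathology tertile, where the
   psychopathology score is the first principal component of the item
   table. Tertile binning was chosen as the simplest reproducible
   stratification of continuous matching variables; the exact matching
   algorithm of large consortium studies is rarely published, and a
   stratified randomization reproduces its intent (balanced margins)
   transparently.
2. **Item filtering** (`dropDegenerateItems`). Zero-variance items are
   dropped per subsample, before residualization — the two subsamples may
   legitimately drop different items, and the replication machinery
   intersects item sets when applying discovery weights.
3. **Confound regression** (`buildDesign`, `residualize`). Ordinary
   least squares residualization on intercept, age, age^2, sex, and
   reference-coded site and ethnicity dummies. Functional connectivity
   (rest and task) additionally adjusts for mean framewise displacement
   and mean DVARS; thickness and volume for total intracranial volume;
   surface area for total surface area. Site enters as fixed-effect
   dummies — the standard reading of "regressed out" — rather than a
   hierarchical model; no empirical-Bayes harmonization is applied, by
   design. Residualization is fitted within each subsample separately so
   no information leaks from replication into discovery.
4. **Dimensionality reduction** (`fitPCA`, default threshold 0.5).
   Per-modality PCA keeps the smallest number of components whose
   cumulative explained variance reaches the threshold. Columns are
   centered but *not* variance-scaled: the downstream PLS z-scores the
   concatenated scores, and scaling inside the PCA would both
   double-normalize and make the cumulative-variance rule depend on an
   arbitrary per-feature rescaling. The 50% default balances modality
   contributions (FC has vastly more features than the structural
   modalities); the sensitivity grid {0.1, 0.3, 0.5, 0.7, 0.9} is
   supported by rerunning with a different `varianceThreshold`.
5. **PLS fit** (`fitPLS`). Full SVD; all `min(items, pcs)` components
   are computed, the first 5 carried into inference. The SVD fixes signs
   only up to a reflection per component, so a deterministic convention
   is imposed: the column sum of `U` must be non-negative (ties broken by
   the largest-magnitude entry). A component on which every item loads
   with the same sign — the general-psychopathology pattern — therefore
   appears with positive loadings. `cor(LX[,l], LY[,l])` is non-negative
   automatically because the covariance of the paired scores equals the
   singular value.
6. **Permutation inference** (`permutationTest`, paper-scale default
   10,000). Behavior rows are permuted within site, the PLS refit, and
   the first five singular values compared component-by-component with
   the observed ones. P-values use the add-one convention
   `(1 + #{null >= obs}) / (1 + n_perm)` — a valid finite-sample p with
   lower bound `1/(n_perm+1)` — and the five p-values form one
   Benjamini-Hochberg family at q = 0.05. Permuted singular vectors are
   *not* Procrustes-rotated to the observed space before extracting null
   singular values; the direct comparison is the literal reading of
   permuting and testing singular values, and this simplification is
   deliberate and documented here.
7. **Bootstrap stability** (`bootstrapLoadings`, paper-scale default
   1,000). Participants are resampled with replacement within site, both
   blocks re-z-scored, the PLS refit, and each replicate component
   matched to the original by greedy maximal |dot product| of behavioral
   weights (sign-aligned) — this guards against component order flips in
   replicates; ambiguous matches (two |dot| within 1e-6) fall back to
   the original order. FC loadings are averaged into the
   `K (K + 1) / 2 = 171` within/between blocks of the 18 networks before
   the bootstrap SD is taken, limiting the number of comparisons.
   z = observed loading / bootstrap SD, two-sided normal p, FDR jointly
   across all features, blocks and components of the run (the run's
   post hoc family).
8. **Connectivity gradients** (`diffusionEmbedding`, alpha = 0.5,
   t = 0, row density 0.10). The group-mean FC (full sample, raw
   averaging of correlations; a Fisher-z option is a one-line
   preprocessing step the user can apply to the edge matrix) is
   row-thresholded to the top 10% entries per row (ties at the cutoff all
   kept), converted to cosine affinities (negatives clipped to zero to
   keep the Markov operator valid — rare after thresholding), and
   embedded by diffusion maps: degrees `d`, alpha-normalized kernel
   `W = A / (d^alpha d^alpha)`, Markov operator `P = W / rowSums(W)`,
   eigendecomposition through the symmetric conjugate. `t = 0` is
   interpreted as the multi-scale eigenvalue scaling
   `lambda / (1 - lambda)`, following the convention of the toolboxes
   that popularized FC gradients; the plain `lambda^t` variant is
   available through `diffusionTime > 0`. Variance explained is defined
   as `lambda_i / sum(lambda)` over retained non-trivial eigenvalues —
   the field's reports rarely state their formula, so this definition is
   fixed here and used consistently. Gradients are computed on cortical
   parcels only, and can be Procrustes-aligned (orthogonal, no scaling)
   to a reference gradient set; the package ships no external reference,
   and tests use synthetic references.
9. **Spin tests** (`buildSpinNull`, `spinCorrelation`, paper-scale
   default 1,000 spins). Parcel-level nearest-neighbour spins: one
   uniform random rotation per spin applied to left-hemisphere parcel
   centroids, its x-mirrored counterpart to the right, and each parcel
   reassigned the value of the nearest rotated source parcel (duplicates
   permitted — the standard parcel-level convention). The map under test
   is spun while the gradient stays fixed, preserving the spatial
   autocorrelation of the tested map; p-values are two-sided on |r|.
10. **Replication** (`outOfSampleProject`, `loadingReplication`).
    Replication blocks are residualized and z-scored with
    replication-sample statistics (mirroring the within-sample
    residualization), then pushed through discovery PCA coefficients and
    discovery PLS weights. Behavioral loading agreement uses plain
    Pearson r; cortical maps use spin correlations; FC agreement is
    computed at the 171-block level.
11. **Held-out modalities and covariate post hocs**
    (`contextualizeHeldout`, `covariateAssociations`). Held-out features
    (task FC, tract FA/MD) are correlated with the fitted composite
    scores on overlapping participants and bootstrapped within site;
    sex uses pooled-variance two-sample t tests and age/age^2 Pearson
    correlations, FDR-corrected as one family.

# The synthetic cohort generator

Because the motivating data (a restricted multi-site developmental
cohort) cannot be redistributed, `generateCohort` builds a cohort with
the same *statistical anatomy*, and `SyntheticGroundTruth` retains what
was planted so recovery is testable:

* **Parcellation**: cortical parcels on two hemispheric unit spheres via
  a deterministic Fibonacci lattice; 17 cortical networks as
  nearest-seed spatial caps (so parcel maps are spatially
  autocorrelated); all subcortical parcels form network 18. The
  full-scale setting (400 + 19 parcels) reproduces the canonical
  87,571-edge count; the default desk scale is 100 + 19.
* **Latent structure**: participant factor scores `F` (rank 3 by
  default) drive items, structural features, FC edges and held-out
  modalities through unit-norm loading columns scaled by
  `latentStrengths = c(5, 4, 3)` against unit residual noise. These
  defaults plant clearly detectable covariance modes — the regime the
  recovery tests are about; weaker regimes are a config away.
* **Behavior**: item liabilities are discretized at fixed thresholds
  chosen from the theoretical liability SD to give marginal prevalences
  of roughly 70/20/10 percent for levels 0/1/2, mimicking the rare-event
  skew of symptom checklists. Item-level prevalences of the motivating
  instrument are not public; this split is a fixture choice, not an
  empirical claim. One item is forced constant, emulating the item
  dropped in real cohorts.
* **Confounds**: additive site mean shifts (drawn once per dataset — the
  simplest batch effect that site-aware resampling must respect), age,
  sex, head-motion, and volume-normalizer effects.
* **FC**: generated at the edge level on top of a fixed network
  block-model baseline (within-network 0.5; between-network decaying
  with the spherical distance of the network seeds; weak to subcortex)
  rather than from simulated time series — the pipeline consumes edges,
  and the baseline guarantees a group-mean matrix with meaningful
  community structure for the gradients stage. FC noise is
  `0.1 * noiseSd` on the correlation scale; values are clipped to
  [-1, 1] and matrices are symmetric with unit diagonal by construction.

What the generator does **not** emulate: temporal autocorrelation and
censoring artifacts of real fMRI, scanner-specific multivariate batch
structure (site effects are mean shifts only), item response styles, or
missing data. Passing recovery tests therefore demonstrates correctness
of the estimation machinery under the planted model, not robustness to
every pathology of real data.

# Numerical choices

* PCA `k` is the smallest count with cumulative variance fraction >=
  threshold; an eigenvalue tied (relative 1e-9) with the one at the cut
  pulls in the extra component. PCA coefficient signs follow the
  largest-|entry|-positive convention, making serialized models
  reproducible.
* Zero-variance features encountered when computing loadings are
  recorded as `NA`, warned about, and excluded from FDR families.
* Bootstrap draws that flatten a rare ordinal item z-score it to a zero
  column rather than failing (`zscoreSafe`), and the affected
  correlations propagate as `NA` into the bootstrap SD with
  `na.rm = TRUE`.
* Residualization uses a single QR decomposition; rank-deficient designs
  are rejected, with the collinear columns named.
* Disconnected affinity graphs are rejected before embedding (BFS
  component check); asymmetric or negative affinities are rejected.
* All stochastic stages derive their streams from one master seed via
  `deriveSeed(master, stageKey)` (a 31-bit polynomial hash), so reruns
  are bit-identical and stages can be re-executed independently.

# A note on out-of-sample loading agreement

Behavioral loadings are `cor(item_j, Y U)`, which contains a mechanical
self-term proportional to `u_j`. Discovery loadings and
projected-replication loadings therefore correlate substantially even
when no true signal is present — the agreement statistic is a biased
measure of generalizability on its own. The package consequently also
reports the out-of-sample *composite correlation*
`cor(LX_rep, LY_rep)`, which vanishes under the null and is the honest
analog of the in-sample component correlation; the tests assert both
behaviors.

# Problem sizes used by the test suite

The suite runs the full pipeline at desk scale as the package's own
validation conditions: the default synthetic cohort (600 participants, 5
sites, 100 + 19 parcels, 119 items, rank-3 structure) for recovery and
generalizability checks; 200 zero-signal datasets with 199 permutations
each for permutation calibration; 200 smooth map pairs with 99 spins for
spin calibration; reduced resampling sizes (about 100-200 draws) for
bootstrap properties. Paper-scale settings (10,000 permutations, 1,000
bootstraps, 1,000 spins, 400 cortical parcels) remain plain arguments.

# Known limitations

* Fixed-effect site adjustment only; no hierarchical or empirical-Bayes
  site harmonization.
* No sparse or regularized PLS variant, and no canonical correlation
  analysis; the decomposition is the plain cross-covariance SVD.
* Spin nulls are parcel-level nearest-neighbour rotations; vertex-level
  spinning and variogram-matched surrogates are out of scope.
* Group-level gradients only; no individual-level embeddings.
* The permutation null compares singular values directly, without
  rotating permuted singular vector spaces; see stage 6 above.
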