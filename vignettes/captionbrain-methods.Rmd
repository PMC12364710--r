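---
title: "Models and methods behind captionbrain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind captionbrain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(captionbrain)
```

`captionbrain` implements a pipeline for relating caption-embedding models to
visually evoked fMRI responses: representational similarity analysis (RSA)
with subset sampling and searchlights, fractional-ridge encoding and decoding
models, dictionary-lookup caption reconstruction, control feature models, and
noise-ceiling-corrected model comparison. This vignette documents the models,
their assumptions, the tunable parameters, and the design decisions taken
where the methods literature leaves choices open.

## The generative model behind the synthetic cohort

All estimators are exercised against synthetic cohorts with known ground
truth. The generator assumes:

* **Scenes.** Each scene has a latent content vector $z_i \in \mathbb{R}^k$
  with iid standard-normal coordinates. Its *true* caption embedding is
  $e_i = A z_i$, where $A$ is a fixed random semi-orthogonal map scaled so
  every embedding dimension has unit variance. Orthogonality keeps the
  stimulus covariance well conditioned: with a generic Gaussian map, the
  weakest embedding directions carry almost no stimulus variance, are
  swamped by caption jitter, and become unidentifiable for any regression —
  which would say nothing about the estimators and everything about a
  degenerate stimulus set.
* **Captions.** Each of the `n_captions` (default 5, matching crowd-sourced
  caption sets) caption embeddings is $e_i + \varepsilon$, with
  $\varepsilon$ iid Gaussian of sd `caption_noise` (default 0.3, i.e. 30 %
  of the per-dimension signal scale — enough to make inter-rater averaging
  matter without hiding the scene). The mean caption embedding is the
  arithmetic mean over captions, so the per-scene error of the mean shrinks
  like $\sigma\sqrt{d/5}$.
* **Categories.** `m` binary labels are thresholded linear readouts of the
  latent, $c_{ij} = \mathbf{1}(z_i^\top v_j > 0)$. This guarantees the
  asymmetry the comparison analyses probe: categories are (up to the
  threshold nonlinearity) decodable from embeddings, while embeddings cannot
  be rebuilt from the coarse binary labels.
* **Words.** Each caption carries word-vector surrogates tagged noun/verb:
  noun vectors are a second (orthogonal) linear image of the latent plus
  jitter; verb vectors are pure noise. Part-of-speech-filtered feature models
  therefore have a ground-truth ordering to detect.
* **Responses.** Voxels live on a 3D grid; each region is a block of voxels
  whose ground-truth weight rows $W$ are supported on a designated embedding
  subspace (plus optional isotropic `leakage`). A trial beta is
  $g_s\,(W e_i) + o_s + \eta$ with per-session gain $g_s$ and offset $o_s$
  drawn uniformly from `gain_range` (default 0.8–1.2) and `offset_range`
  (default ±0.1), and homoscedastic Gaussian noise per voxel — the simplest
  noise model consistent with beta-weight inputs. Each stimulus is repeated
  `n_reps` (default 3) times, assigned to `n_sessions` sessions by a seeded
  shuffle. The session count is a free parameter (default 4) since typical
  per-participant session counts after exclusions vary.
* **Cohorts.** `n_shared` scenes are seen by all participants and `n_unique`
  scenes are mutually exclusive per participant, mirroring shared/unique
  designs. Participant brains share geometry and regions; their weights are
  the base weights plus Gaussian jitter (`participant_weight_jitter`).

One global `seed` is expanded into per-component child seeds by
`derive_seed()` (a documented integer hash), so changing, say, the dictionary
does not perturb the trial noise.

**What the generator does not emulate:** hemodynamics and GLM estimation
(betas are drawn directly), spatially correlated noise, heteroscedastic or
non-Gaussian noise, voxel-level gain fields, real linguistic structure in
captions (dictionary "texts" are synthetic identifiers), and non-linear
brain–embedding relationships. Tests that pass on this cohort certify the
estimators' correctness and calibration under the stated model, not the
empirical claims about real cortex.

## Preprocessing and RDM construction

Betas are z-scored per voxel across single trials *within each session*,
stimuli without the full repetition count are dropped, and repetitions are
averaged (`preprocess_betas()`). RDM entries are Pearson-correlation
distances $1 - r$ between average patterns; RDMs are symmetric, zero-diagonal
and bounded by $[0, 2]$, and invariant to per-stimulus positive affine
transforms of patterns.

A consequence worth stating explicitly: pattern-correlation RDMs are computed
across voxels after centring each pattern, so *scalar* per-session gains and
offsets cancel exactly in the RDM — the within-session z-scoring matters for
the encoding/decoding models (which predict raw voxel values across sessions)
rather than for RDM geometry, and it additionally equalizes voxel scales.
For the same reason, `true_response_rdm()` standardizes the noiseless
responses per voxel before computing the ground-truth RDM: per-voxel
standardization changes RDM geometry, so the "truth" model must pass through
the same transformation as the data it is compared with.

Degenerate cases follow fixed policies: a zero-variance pattern gets neutral
distance 1 (logged); a constant voxel-session block gets z-scores of 0
(logged); a session with one trial is an error.

## Subset-sampled RSA, searchlights, ceilings, inference

* Stimuli are partitioned once (seeded shuffle) into disjoint subsets of
  `subset_size` (default 100; remainders that cannot fill a subset are
  discarded, which reproduces the 100/62/54 split counts for pools of
  10,000/6,234/5,445). Correlations between the per-subset brain and model
  RDM upper triangles are averaged on the raw r scale, without Fisher
  transformation.
* The same partition is reused across searchlight spheres *and across
  models*, so maps and model contrasts compare like with like; this is a
  package decision where practice varies.
* Searchlight spheres use integer lattice points within Euclidean distance
  `radius` (default 6) of the centre, in voxel units (isotropic grid
  assumed); a sphere is kept only if strictly more than
  `min_inside_fraction` (default 0.5) of its lattice points are in the mask,
  and out-of-mask voxels are dropped from its members.
* The RSA noise ceiling of a participant is the upper-triangle correlation
  between their shared-stimulus RDM and the element-wise mean of the other
  participants' RDMs. Model scores are corrected by the **ratio**
  r/ceiling — the correction formula is a package decision (subtraction is
  the alternative); participants with non-positive ceilings are excluded
  from correction rather than sign-flipped.
* Group inference is a per-location two-tailed one-sample (or paired) t-test
  across participants with Benjamini–Hochberg FDR at `alpha = 0.05`. Zero
  variance with zero mean yields $t = 0, p = 1$; zero variance with nonzero
  mean is undefined and excluded from the FDR family with a warning.
  Sentence-contrast maps are deliberately left uncorrected, as exploratory
  maps.

## Fractional ridge regression

Encoding (embeddings → voxels) and decoding (voxels → embeddings) use the
same machinery. Ridge solutions are parameterized by the *fraction*
$f = \lVert \beta(\gamma)\rVert / \lVert \beta_{OLS}\rVert$: along the SVD of
the centred design, the rotated OLS coefficients $\alpha_j$ are shrunk by
$d_j^2 / (d_j^2 + \gamma)$, and $\gamma$ is solved per target by root
finding (`uniroot`, tolerance $\sqrt{\epsilon}$) so the achieved norm ratio
equals the requested fraction — the defining contract, tested to 1e-3.
Fraction 1 is OLS; rank-deficient designs fall back to the minimum-norm OLS
solution with a warning.

Model selection scans 20 fractions (0.05–1.00 step 0.05) with 5-fold
cross-validation; folds are contiguous blocks of a seeded shuffle. The
fraction maximizing the mean held-out Pearson r is selected **per target**
(per voxel in encoding, per embedding dimension in decoding), with ties going
to the smallest fraction (more regularization, deterministic). Designs and
targets are centred on training statistics and the intercept restored at
prediction; both choices are package decisions where the methods description
is silent. Constant training targets are flagged: smallest fraction, zero
weights, `NA` downstream.

## Decoding, lookup and ranks

Per test stimulus, the prediction score is the Pearson correlation between
predicted and target embedding. The inter-caption noise ceiling is the
leave-one-out consistency of the caption embeddings (each caption against
the mean of the others, averaged). Dictionary lookup retrieves the entry with
the highest Pearson correlation to the prediction — correlation, not cosine:
vectors are centred first, which matters for embeddings with nonzero means.
Ties break to the lowest entry index; scoring is computed in fixed-size
blocks with results provably independent of block size. Ranks sort scores
descending (rank 0 best; 515 test stimuli give worst rank 514), ties by
stimulus index.

## Readout probes

`readout_probe()` fits a linear map (with bias) by minimizing mean cosine
distance with gradient descent and a backtracking line search, initialized at
a lightly ridged least-squares solution; training loss decreases
monotonically until the relative change falls below `tol = 1e-6`. The floor
is the mean-training-target predictor evaluated on the same test items. In
the decodability-asymmetry analysis the frozen "network features" are
surrogated by the generator's own representations plus Gaussian observation
noise (sd 0.5) — an idealization of imperfectly trained networks chosen once;
with noiseless category features the first comparison would be trivially
lost to an identity readout.

## Problem sizes and numerical choices

The reference cohort used by the test suite and `scripts/acceptance.R` is 8
participants × (100 shared + 500 unique) stimuli × 200 voxels in two
selective regions, embedding dimension $d = k = 16$, caption noise 0.3,
trial SNR 10 (per-voxel signal variance over noise variance), 3 repetitions,
4 sessions. These sizes keep a full pipeline run in tens of seconds while
leaving all recovery margins wide; $k = d$ makes the ground-truth weights
fully identifiable (weights are only ever recoverable within the span of
stimulus variation). Monte-Carlo checks use 3–10 fixed seeds per claim.
Zero-noise recovery tests use a single session with unit gain, where
standardization is an exact per-voxel affine map and recovery is exact by
construction.

## Known limitations

* No surface projection, flatmap rendering, spatial smoothing, or anatomical
  ROI definitions; ROIs are voxel index sets.
* Real text encoders, word-vector tables and POS taggers are out of core;
  the feature builders accept externally computed embeddings, and synthetic
  scenes carry ground-truth tags.
* Cohort serialization is plain text (CSV + JSON manifest) with optional
  NIfTI export of response volumes; there is no HDF5 reader/writer.
* The homoscedastic, spatially independent noise model makes the synthetic
  noise ceilings more benign than real fMRI reliability; corrected scores on
  real data would carry more ceiling uncertainty than these tests exhibit.
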