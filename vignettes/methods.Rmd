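---
title: "Methods: synthetic model, analysis choices, and numerical conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic model, analysis choices, and numerical conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pulvicor)
```

This vignette documents the generative model behind the synthetic
datasets, why the defaults are what they are, and the numerical
conventions used throughout the analyses. The synthetic data exist to
give every analysis a planted ground truth; they emulate the *structure*
of a pulvino-cortical fMRI study, not the physics of any scanner.

## The generative model

### Cortical area series

Each hemisphere carries 39 named cortical areas split into two networks:
24 occipito-temporal areas (V1 through anterior temporal) and 15
fronto-parietal areas. Each area has a hierarchy position `gradient` in
`[0, 1]` within its network. Per subject and hemisphere, latent area
series are drawn from a zero-mean Gaussian process with covariance

```
Sigma = b * J + (w - b) * (f + (1 - f) * K) * S
```

where `J` is all-ones, `S[i, j] = 1` iff areas `i` and `j` share a
network, `K[i, j] = exp(-(g_i - g_j)^2 / (2 * l^2))` is a Gaussian kernel
over hierarchy positions, `b = between_network_corr` (default 0.1),
`w = within_network_corr` (default 0.4), `l = gradient_length` (default
0.25) and `f = network_floor` (default 0.5). The matrix is positive
semi-definite by construction (a sum of a rank-one term, a scaled Gram
kernel and a block-diagonal term).

The `network_floor` term deserves a comment. With a pure kernel
(`f = 0`), two areas at opposite ends of the same network's hierarchy
would be no more correlated than areas of different networks, so the
planted two-network partition would not be the most assortative structure
in the data — the generator would contradict its own ground-truth labels.
The floor guarantees a uniform within-network excess of
`f * (w - b) = 0.15` for every same-network pair, while the kernel term
grades the remainder along the hierarchy so that neighboring areas
correlate more than distant ones. `f = 1` recovers a plain two-factor
model; `f = 0` a pure gradient.

Observed area series add white measurement noise
(`area_noise_sd = 0.3`) and nuisance structure shared with the voxels.

### Pulvinar voxels

Each hemisphere's pulvinar is a rectangular voxel lattice (default
5 x 5 x 6 at 2 mm). Voxels below the lattice's median z form the ventral
compartment and mix occipito-temporal latents; the rest form the dorsal
compartment and mix fronto-parietal latents. Each voxel gets a preferred
hierarchy position by projecting its coordinates onto a compartment axis
(ventral: anterior-lateral to posterior-medial; dorsal: posterior to
anterior), and its mixing weights over the compartment's areas follow a
Gaussian tuning curve of width `topography_width = 0.15` around that
preference, normalized to unit L2 norm. Voxel series are these mixtures
plus white noise (`noise_sd = 1`, i.e. noise comparable to signal) and
nuisance structure.

### Nuisance structure

Every subject receives quadratic drifts, six random-walk motion series
with voxel-specific loadings, two smooth global components
(ventricle-like and white-matter-like), and sparse spikes. The "measured"
motion and global regressors are carried in the dataset, so the
preprocessing stage faces the same problem a real pipeline faces:
structured contamination with imperfect but usable regressors.

### Movie, task, and peak datasets

* `generate_movie_dataset()` builds a shared stimulus drive per region
  type and repetition. Short-timescale responses sample the stimulus
  instantaneously; long-timescale responses are trailing moving averages
  over `trw_spec["dorsal"] = 12` s. Scrambling permutes stimulus segments
  of 0.5–1.6 s with one shared permutation across subjects. A trailing
  average of a scrambled stimulus decorrelates across subjects, while the
  instantaneous response is merely reordered — exactly the asymmetry the
  ISC contrast is designed to detect.
* `generate_block_design_dataset()` convolves block regressors with a
  double-gamma HRF and planted per-voxel betas;
  `generate_laterality_dataset()` plants stronger contralateral tuning
  ventrally and stronger attentional modulation dorsally;
  `generate_category_dataset()` plants a compact face-selective cluster
  in a posterior-medial-ventral position for the leave-one-out ROI
  analysis.
* `generate_dorsal_peaks()` draws three groups of functional peaks
  (attention, tool, default-mode) with sub-millimetre within-group spread
  (`spread_mm = 0.5`), matching the reproducibility one expects from
  functionally matched area pairs.

### What the generator does and does not emulate

It reproduces the statistical structure the analyses consume: network
covariance, graded topography, hemodynamic lag, realistic nuisance, and
subject-to-subject independence of noise. It does not emulate spatial
autocorrelation of scanner noise, susceptibility dropout, registration
error, or physiological aliasing; conclusions about those belong to real
data, not to this package.

## Numerical conventions

* **Correlation averaging.** Correlations are always averaged in
  Fisher-z space (`atanh`/`tanh`), both across subjects
  (`pseudo_group_profile()`, `group_connectivity()`) and across split
  halves. Averaging raw `r` values biases toward zero.
* **Self-entry exclusion.** When a voxel's profile is matched against
  area A's profile, A's own entry is dropped from both vectors
  (`profile_similarity_map()`, `include_self = FALSE` by default).
  Including it lets a voxel that merely correlates with A (first-order)
  masquerade as having A's fingerprint (second-order).
* **Block response summaries.** Per-block response means and SDs are
  taken over a window lagged 6 s behind the block to respect hemodynamic
  delay; the d-prime index uses the pooled-SD form
  `(mu_a - mu_b) / sqrt((sd_a^2 + sd_b^2) / 2)`, which is antisymmetric
  and scale invariant.
* **Preprocessing order.** Initial volumes covering 21.6 s are dropped,
  then despiking (2.5 SD clip), band-pass 0.01–0.1 Hz (4th-order
  Butterworth, forward-backward), quadratic detrend, nuisance regression
  (motion + derivatives + ventricle + white matter; no global-mean
  regressor, which would induce negative correlations), then 4 mm FWHM
  mask-normalized smoothing. Filtering precedes nuisance regression so
  the regressors are fit to the same frequency band they are meant to
  clean.
* **Modularity clustering.** `spectral_clusters()` implements Newman's
  leading-eigenvector bisection with Kernighan–Lin fine-tuning after each
  split, stopping when the leading eigenvector is sign-uniform or the
  modularity gain is non-positive. Negative similarity entries are
  zeroed by default (`zero_negative`): modularity is defined for
  non-negative weights. The test suite cross-checks cluster quality and
  the modularity value against `igraph`.
* **Procrustes tests.** `procrustes_fit()` uses the SVD solution with
  the symmetric normalized SSE `1 - trace(S)^2 / (ssx * ssy)`;
  `permutation_test_mds()` permutes row assignments (globally or within
  clusters) with a dedicated RNG substream, reporting the percentile of
  the observed SSE in the null. Equivalence with
  `vegan::procrustes(symmetric = TRUE)` is verified in the tests.
* **Determinism.** All stochastic steps run under `with_seed()` with
  substreams derived from a label hash (`substream_seed()`), so
  independent stages have independent streams, results never depend on
  call order, and the caller's RNG state is restored.

## Default problem sizes

Thirteen subjects with 312 resting timepoints at TR 1.8 s, eleven movie
subjects with two repetitions of a 345 s movie at TR 1.5 s, and sixteen
category-task subjects: large enough that group statistics behave like
group statistics (stable Fisher-z means, meaningful FDR correction,
leave-one-out folds of 10+ subjects), small enough that the complete
pipeline runs in seconds:

```{r quick-run}
rest <- generate_resting_dataset(sim_config(seed = 1, n_subjects = 4))
conn <- connectivity_analysis(preprocess_dataset(rest))
ns <- network_structure(conn)
ns$clusters$n_clusters
table(ns$clusters$labels,
      rest$truth$network_assignment[names(ns$clusters$labels)])
```

Even with only 4 subjects the planted networks are typically recovered;
the packaged defaults add comfortable margin.
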