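---
title: "Methods: simulating federated chemoradiotherapy-response prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating federated chemoradiotherapy-response prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fedcrt)
```

## The problem

Predicting whether a non-small cell lung cancer (NSCLC) patient will
respond to chemoradiotherapy (CRT) from the pre-treatment planning CT is
a binary image-classification problem: the input is a tumor-centered 3D
patch, the label is the RECIST assessment dichotomized as responsive
(CR/PR) versus nonresponsive (SD/PD). Multicenter cohorts are needed for
generalizable models, but patient imaging cannot be pooled across
hospitals. Federated learning (FL) addresses this: each hospital trains
locally and only model parameters travel. This package implements the
whole pipeline — preprocessing, a compact 3D CNN, synchronous FedAvg,
evaluation, and cohort-comparison statistics — driven by a synthetic
multi-site phantom generator, so every stage runs and is testable with
no patient data at all.

## Pipeline and model

Each patient contributes a CT volume and a binary tumor (GTV) mask.
Both are resampled to 1 mm isotropic spacing; a cubic patch (64 voxels
standard, 16 for the reduced desk-scale presets) is cut with the tumor
centroid at its center; intensities are windowed and scaled to [0, 1].
Training-time augmentation applies a random horizontal flip, a rotation
about the cranio-caudal axis within ±15°, a pad-and-random-crop, and
brightness/contrast jitter with factor 0.2 (saturation and hue are
recorded but inert on single-channel data).

The classifier (`build_model()`) is a three-stage 3D CNN: each stage is
convolution (3³ kernels, same-padding) → ReLU → 2³ max-pooling, followed
by a hidden fully-connected layer, a 2-unit output layer and a softmax.
Channel counts, kernel size and hidden width are configurable; the
defaults (16/32/64 channels, hidden 128) are the smallest conventional
choice consistent with that layer structure, and
`tiny_model_config()` (16³ input, 4/8/16 channels, hidden 32) is the
desk-scale preset used throughout the test suite. Convolutions are
implemented as im2col plus one BLAS matrix multiplication per layer with
hand-derived backward passes; gradients are validated against central
finite differences in the test suite.

Training (`train_local()`) is plain minibatch cross-entropy with Adam or
(plain, momentum-free) SGD. Three presets mirror the published
hyperparameter sets: centralized (batch 8, lr 0.001, Adam, 100 epochs),
two-client simulation (batch 16, lr 0.001, SGD), three-client real-world
(batch 16, lr 0.001, Adam). The returned model is always the last
epoch's — no early stopping or selection — which keeps runs exactly
reproducible.

## Federated averaging

`run_federated()` simulates the synchronous protocol in process: each
round the server broadcasts the global parameters, every client trains
`local_epochs` epochs on its own split, and `aggregate_fedavg()` replaces
the global model with the weighted average
$\theta \leftarrow \sum_k \frac{n_k}{\sum_j n_j}\,\theta_k$,
where $n_k$ is client $k$'s training-split size (the data actually
trained on, not the site's total). The default schedule is 10 rounds of
50 local epochs. Design choices where the protocol leaves room:

* **In-process hand-off.** The client/server boundary is an explicit
  parameter-set exchange, so a networked transport could replace it
  without touching the training code.
* **Optimizer state.** Client Adam moments are reset after each
  broadcast (stateless clients). Consequence: with SGD, a one-client
  federation is *bit-identical* to an uninterrupted centralized run,
  because client epoch seeds continue across rounds — this reduction is
  asserted in the tests.
* **Participation.** All clients participate every round; no sampling,
  stragglers, or privacy mechanisms (out of scope).

## The phantom generator

`make_phantom()` builds a homogeneous background containing one
ellipsoidal tumor of elevated intensity; `generate_cohort()` draws
per-patient tumor geometry, labels and demographics for several sites
and writes NIfTI pairs plus a manifest. It emulates exactly the
statistical structure the analysis assumes:

* **Multi-site imbalance and shift.** Sites have unequal sizes (the
  emulated cohort is 102/42/32/69 across four hospitals) and site-level
  intensity offset, acquisition noise and native voxel spacing — the
  controllable stand-in for non-IID hospital effects. How the real
  fourth hospital's distribution actually differed is not quantified
  anywhere, so this parametrization is a model of site shift, not a
  reconstruction of it.
* **Prevalence.** Default responsive fraction 0.45 (110 of 245).
  Exact-count label mode is the default so per-site class counts are
  deterministic; a Bernoulli mode draws them stochastically.
* **Label-morphology coupling.** Tumor semi-axes are drawn from
  class-conditional normals; `label_effect_size` in [0, 1] interpolates
  the class means between their common average (0: nothing to learn)
  and full separation (1). `label_noise` flips the drawn class with the
  given probability. A tumor-size effect is the simplest morphological
  signal a 3D CNN can learn; it is *not* a claim about real response
  biology.
* **Seed discipline.** One master seed; per-patient seeds follow the
  fixed counter scheme `(master + 100003·counter) mod (2³¹−1)`, so
  extending a cohort never changes earlier patients (exact in Bernoulli
  label mode, where labels are per-patient draws).

What the phantoms deliberately do **not** model: lung anatomy, CT
physics and reconstruction artifacts, multi-lesion disease, or any real
radiomic signature. Passing tests therefore demonstrate that the
*pipeline machinery* is correct and that FL matches centralized training
under controlled site shift — not that the network would reach any
particular accuracy on hospital data.

## Numerical choices

* **Resampling.** Images use separable cubic B-spline interpolation
  with the exact interpolation prefilter (per axis, the basis matrix at
  the output coordinates times the inverse of the basis at the input
  nodes, mirror boundary), so resampling onto the input grid is the
  identity to solver precision. Masks use nearest-neighbor: B-splines on
  a binary mask would produce non-binary values, and nearest-neighbor is
  the standard way to keep a label map binary. Output shape per axis is
  `round(shape · spacing / target)`.
* **Geometry conventions.** Arrays are kept in R's native (x, y, z)
  axis order with 1-based voxel indices, matching how RNifti presents
  NIfTI data; the patch center voxel is index `floor(size/2) + 1`.
  Centroids round half-up per axis.
* **Normalization.** The intensity window is configurable: a fixed
  [−1000, 400] HU-style window suits real CT; phantom cohorts use their
  global min–max (computed once per cohort) since phantom units are
  arbitrary. Out-of-volume padding uses the normalized minimum 0
  (air-like).
* **Augmentation geometry.** "Horizontal flip" is a left-right (x)
  flip of the axial plane and rotation is about the z axis — the
  natural 3D reading of a 2D-style augmentation list; the unparameterized
  "random cropping" is pad-by-4-voxels then a random crop back to size.
  These are declared choices, not inferences.
* **Max-pooling ties** resolve to the first maximum in a fixed scan
  order, so gradients never double-count.
* **Positive class.** Metrics default to "responsive" as positive but
  the orientation is configurable — the published tables are consistent
  with the opposite convention, and nothing in the package hard-codes
  either.
* **AUC and CI.** AUC uses the rank (Mann–Whitney) identity, ties
  counting ½ — identical to the trapezoidal ROC area. The interval is a
  stratified percentile bootstrap (default 2000 replicates, seeded);
  stratification keeps both classes in every replicate. The CI method
  behind the published intervals is unstated; the percentile bootstrap
  is the assumption-free reproducible choice.
* **Cohort statistics.** Pearson chi-square with no continuity
  correction (this is the variant that reproduces the published r×c
  p-values), classical one-way ANOVA accepting raw samples or
  mean/sd/n summaries, Fisher's exact test for 2×2 tables with a seeded
  Monte-Carlo variant for larger ones.

## Problem sizes

The test suite and the reproduction script run everything at desk
scale, chosen so the full pipeline exercises every code path in a few
minutes of CPU: an 8³-input micro network for gradient and reduction
checks, and a three-site phantom cohort of 60/30/30 patients with a
strong morphological effect (mean semi-axes 3.5 vs 6.5 mm, SD 0.8),
16³ patches, the reduced network, and a 5-round × 2-local-epoch
schedule for the centralized-vs-federated parity benchmark
(`parity_benchmark()`). Both arms are scored on the same held-out set —
the pooled per-site validation splits, which never influence weights.
The standard 64³ configuration is the default everywhere and runs the
same code, just larger.

## Limitations

Phantom simplicity is the main one (above). Beyond it: training is
CPU-only and single-threaded BLAS-bound, so the full 64³ network at the
published 100-epoch budget is a long run; bit-level reproducibility is
guaranteed only on a fixed platform/BLAS; FedProx-style strategies,
client sampling, secure aggregation and DICOM/RT-struct conversion are
out of scope; and whether the published training-row metrics are
last-epoch or best-epoch values is unknowable from the text — this
package reports last-epoch values.
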