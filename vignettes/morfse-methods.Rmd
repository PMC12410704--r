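---
title: "Gated mixtures of lesion-specific experts: model, phantoms and evaluation protocol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gated mixtures of lesion-specific experts: model, phantoms and evaluation protocol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

Radiologists read the two main mammographic lesion families with different
criteria: for calcifications they assess the shape of individual deposits
and the distribution of the cluster; for masses they assess shape, margin
definition and spiculation.  `morfse` implements a mixture-of-experts
classifier that encodes this division of labor.  A two-class gate network
estimates the probability that a patch's lesion content is
calcification-like (`wc`) or mass-like (`wm`), and those probabilities
weight two three-class expert networks:

```
y = wc * Expert_c(x) + wm * Expert_m(x),   wc + wm = 1
```

where each expert emits (cancer, benign, normal) probabilities.  The
constraint `wc + wm = 1` is enforced *structurally* — the gate ends in a
two-class softmax head — rather than by post-hoc renormalization, so the
mixture is a convex combination and `y` is automatically a probability
vector.  Two baselines bracket the contribution of the gate: the
*conventional* variant is a single three-class network trained on all
patches without finding information, and the *no-gate* variant fixes
`wc = wm = 0.5`, i.e. a plain ensemble average of the two experts.

The three networks are trained independently on routed subsets: the gate
on lesion patches labeled by finding (a patch tagged with both findings
contributes one training instance per tag — the simplest rule consistent
with a two-class head; a multi-label head was the alternative and is out
of scope); the calcification expert on calcification patches plus all
normals; the mass expert on mass patches plus all normals; the
conventional baseline on everything.  There is no joint end-to-end
training and no sparse top-k routing — with two experts the dense mixture
is the model.

## The backbone

The architecture is pluggable behind `backbone_spec()`.  The desk-scale
backbone, `smallcnn`, is a four-block convolutional network (3x3
convolutions with same padding, ReLU, 2x2 average pooling; channel widths
4-8-16-16) followed by global average pooling and a linear softmax head.
It is implemented from scratch in this package — im2col convolution
kernels in compiled code, BLAS matrix products, analytic backpropagation
(verified against numerical gradients in the test suite), and Adam on the
cross-entropy loss.  Patches are resized bilinearly to the backbone's
input side (default 32 px) and standardized with fixed intensity
statistics (mean 0.5, sd 0.25 on the `[0, 1]` scale).

`resnet18` names the full-scale configuration (ImageNet-pretrained, 224 px
input).  Its weights and runtime are not bundled; the spec value exists so
serialized configurations interoperate, and constructing it signals an
informative error.  All mixture arithmetic is backbone-agnostic, which the
tests check by mixing recorded probability tables directly.

Default training hyperparameters follow the full-scale protocol (Adam,
learning rate 1e-5, weight decay 0, batch 64, 30 epochs).  That learning
rate presumes a pretrained backbone being fine-tuned; `fast_mode` — the
profile used by the tests and the acceptance script — caps the schedule at
8 epochs and batch 32, resizes input to 32 px, and raises the learning
rate to 2e-3, which is what a randomly initialized small CNN needs to
converge on a few hundred patches.

## The synthetic phantom generator

Every downstream stage is testable without a clinical download because
`gen_dataset()` fabricates labeled patches whose malignancy cues are
*finding-specific by construction* — the property the mixture architecture
needs to demonstrate any benefit:

* **Background**: white noise blurred at a configurable correlation length
  (default 6 px at a 64 px patch), generated on a padded grid and cropped
  so the field is stationary to the edge; intensity centered at 0.3.  In
  the infinite-correlation limit the background is a constant field.
* **Calcifications**: clusters of hyperintense Gaussian dots.  Malignant
  clusters are tight (radius 12 px) with many (12 +/- 2.5), small
  (sigma 0.9-1.6 px), eccentric ("pleomorphic") dots; benign clusters are
  loose (radius 22 px) with few (5 +/- 1.5), large (2.0-2.8 px),
  near-round dots.
* **Masses**: a filled region whose boundary is a truncated Fourier series
  in polar angle.  Benign masses are near-elliptical (harmonic amplitude
  0.03, axis ratio 0.7-0.95) with a sharp margin (0.8 px blur); malignant
  masses are irregular (amplitude 0.22), ill-defined (3 px margin blur)
  and carry eight sharp radial spicules added after the margin blur,
  because spicules are a high-frequency cue in their own right.
* **Normals**: background texture only.

All lengths scale linearly with `image_size / 64`; 512 px rendering is
available for visual fidelity but the tests run at 64 px.  Intensities
live in `[0, 1]` with lesions hyperintense, matching mammographic
appearance.  Additive pixel noise defaults to sd 0.02.

Determinism is strict: each patch draws from a private stream whose seed
is derived from the master seed and a (cell, index) counter, so enlarging
one cell never reshuffles another, and generator calls never disturb the
caller's RNG state.  The default dataset mix apportions patches to
cancer : benign : normal as 1462 : 248 : 1054 (largest-remainder rounding,
lesion classes split evenly between the two findings), mirroring the
class imbalance of the public accession this pipeline is designed around.

What the phantoms do *not* emulate: breast density variation, scanner
physics, anatomy-scale context, or overlapping tissue structures.  A green
test suite therefore shows the pipeline is correct and that gating helps
*when finding-specific cues exist*; it does not certify clinical
performance.

One measurement subtlety is documented rather than hidden: in tight
malignant clusters, physically overlapping dots merge under any
local-maxima detector, so the detected dot count under-reads the
configured count.  The tests check exact gap recovery on a spread-cluster
configuration and directional separation at the defaults.

## Source-data construction rules

For real mammography-style inputs the package applies the standard patch
construction procedure: per-lesion crops (512 px default) centered on the
segmentation-mask centroid; multi-component masks split into individual
lesions; lesions tagged focal asymmetric density (FAD) relabeled as mass;
distortion tags dropped (distortion-only lesions excluded); and normal
patches drawn by rejection sampling inside the Otsu-binarized breast area
(>= 90% foreground per window, capped at 1000 draws, one patch per normal
image by default).  Conventions the source description leaves open are
fixed here: windows are 0-based half-open and shifted inward at image
edges (no padding, preserving real-tissue statistics); the centroid is the
unweighted mean of mask coordinates rounded half-up; Otsu runs on the full
image, with a fixed dark floor of 0.1 as fallback when the image is too
low-contrast for a meaningful split (Otsu always splits, even a uniform
frame).  The DICOM reader is deliberately minimal — monochrome,
single-frame, uncompressed little-endian transfer syntaxes — and PNG
fixtures use the same `[0, 1]` scale.  Datasets are persisted as 16-bit
TIFF plus a CSV manifest; 16-bit quantization happens once at write time
and round-trips exactly thereafter.

## Evaluation protocol

`run_repeated_cv()` draws **one** patient-grouped, class-stratified
partition into K = 5 folds, then repeats the full train-and-predict cycle
R times with repetition-specific initialization and batch-order seeds.
Grouping by patient is a deliberate strengthening over a per-patch split:
patches of one patient are correlated, and splitting them across folds
would leak.  Re-randomizing folds per repetition was the alternative
reading of "repeated five times"; a fixed partition keeps the per-fold
integration of mean out-of-fold (OOF) predictions well defined, which is
why it was chosen.  Every (repetition, fold) records the training patch
ids of all four networks, and the test suite audits exhaustively that no
patch was ever scored by a model that saw it.

Per-patch predictions are averaged over repetitions and integrated into a
single OOF table for all three variants.  The binary reduction for ROC
analysis is the raw `p_cancer` component (not renormalized against
benign), with truth cancer vs benign-plus-normal.  Per-finding AUCs subset
to patches carrying the finding tag, cancer vs benign; normals carry no
finding tag and are excluded by default (a switch adds them to the
negatives).

## ROC statistics

`binary_auc()` computes the pairwise-probability AUC (ties count one half)
via midranks in O(n log n); the tests hold it to brute-force pairwise
enumeration.  Variances use the DeLong structural-components estimator:
with V10 the per-positive mean psi values and V01 the per-negative ones,
`var(AUC) = S10/m + S01/n`.  The paired test for two score vectors on the
same patches uses the full component covariance,
`var(d) = (S10aa + S10bb - 2 S10ab)/m + (S01aa + S01bb - 2 S01ab)/n`,
`z = d / sqrt(var(d))`, two-sided normal p-values, significance at 0.05.
Degenerate cases are fixed by convention: identical scores give p = 1;
perfectly separated scores give variance 0.  Confidence intervals are
normal-approximation on the AUC scale, clipped to `[0, 1]` — the CI method
is a package choice, as is the raw-`p_cancer` reduction.  The tests
cross-check variance against a 10,000-draw bootstrap, the paired p-value
against a sign-flip permutation oracle and an independent implementation
(pROC), and the null rejection rate against its nominal level.

## Problem sizes and what the numbers mean

The test suite and `scripts/acceptance.R` run at the scale the generator
defines as standard: about 600 patches in the accession's proportions
(317 cancer / 54 benign / 229 normal), 64 px patches, `fast_mode`
training, K = 5, and R = 2 (acceptance script) or one repetition per
master seed across five seeds (specialization test).  At this scale a full
cross-validation of all four networks takes about a minute per repetition
on one CPU core.

Two behaviors of the desk-scale runs are worth naming.  First, the
headline pattern reproduces the architecture's qualitative claim: the
gated mixture beats both the conventional single network and the
equal-weight ensemble on overall cancer-vs-rest AUC, the paired DeLong
test calls those gaps significant, the conventional-vs-ensemble gap is
not, and the gate identifies finding types essentially perfectly.  Second,
per-finding AUCs are unstable for calcifications: the benign class is rare
by construction (about 27 benign-calcification patches, of which ~21 per
training split), and small dots lose most of their contrast when patches
are downsampled to the 32 px training input, so the calcification expert
is data- and resolution-starved for the cancer-vs-benign distinction
within its own finding.  This is reported as-is rather than patched over;
at full scale (512 px inputs, pretrained backbone, thousands of patches)
that subset is far better conditioned.

## Known limitations

* The phantom generator is a test bed, not a simulator; effect sizes are
  explicit dials and results on it bound only the pipeline's correctness.
* The smallcnn backbone is intentionally tiny; it demonstrates the
  architecture's mechanics, not attainable clinical accuracy.
* DICOM support covers monochrome uncompressed files only.
* Checkpoint weight files are R serializations with a JSON sidecar; they
  are runtime artifacts, not an exchange format.
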