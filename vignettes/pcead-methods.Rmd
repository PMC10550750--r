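---
title: "Anomaly-detection tumor segmentation: model, calibration and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Anomaly-detection tumor segmentation: model, calibration and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: the model behind
each stage, the parameters that matter, what the synthetic benchmark does
and does not establish, and the design decisions taken where the method
left room.

## The model

Tumor segmentation is framed as anomaly detection: a generative model is
trained to reproduce *normal* tissue, and pixels it cannot reproduce are
flagged. Nothing tumor-specific is ever learned, which is both the
method's appeal (no pixel annotations needed for training) and its known
limitation (any departure from normal — inflamed tissue, ink, artifacts —
is flagged alongside tumor).

**Reconstruction.** The reconstructor is a progressive GAN trained as a
context encoder. The generator is a symmetric encoder–decoder: `fromRGB`
(1×1 conv) into the channel schedule, 3×3 conv + 2×2 average pooling down
to a 4×4 bottleneck, then nearest-neighbor upsampling + 3×3 conv back up,
and `toRGB` to colour, with a sigmoid keeping outputs in [0, 1]. Networks
grow from 4×4 by doubling; during each growth step both ends blend an
old path (previous level, up/downsampled) with the new convolutional
block as `(1−α)·old + α·new`, α ramping linearly from 0 to 1 over the
fade-in images. At α = 0 the grown network *exactly* reproduces the
previous level's output upsampled by nearest neighbor (the test suite
pins this to 1e−5), which is what makes growth non-disruptive. The
discriminator mirrors the encoder and feeds a dense score; the loss is
least-squares GAN plus an L1 reconstruction term:

    L_G = λ_rec · mean |x − G(masked x)| + λ_adv · ½ (D(G(masked x)) − 1)²

Inpainting masks the centred square of side `f·s` (default f = 0.5) with
the training-set mean colour; the generator must rebuild it from context.
L1 is used (rather than L2) because the downstream error model works on
absolute errors, so training and scoring optimise the same quantity.

**Error model (NERD).** For a patch x and its reconstruction x̂, the
per-pixel error vector is `e = |x − x̂| ∈ R³` over RGB. Errors from
held-out normal slides are pooled into a single 3-variate Gaussian
N(μ, Σ) — the *normal error reference distribution* — fitted by streaming
(Welford/Chan) moments so no error tensor is ever materialised in full.
A per-pixel-position model is not possible because patches are not
spatially registered, so one pooled 3-D Gaussian is the natural choice.
Note e is a folded (absolute-value) quantity, so the Gaussian is a
working approximation, not an exact distribution; the threshold below is
therefore calibrated empirically rather than taken from theory.

**Scoring and threshold.** Pixels are scored by Mahalanobis distance
`d(e) = sqrt((e−μ)ᵀ(Σ+εI)⁻¹(e−μ))` (ε = 1e−6 only guards invertibility).
The cut-off τ is the empirical (1−q) nearest-rank quantile of d pooled
over a third tranche of normal slides; a pixel is anomalous iff `d > τ`
(strictly). q — the fraction of normal tissue one is willing to flag — is
the single most consequential tunable (default 0.05). If the errors
really were Gaussian, d² would be χ²₃ and τ(q = 0.05) = sqrt(7.815) ≈ 2.80;
the suite verifies this closed form on Gaussian draws, while on the
synthetic benchmark's half-normal-ish errors the empirical τ lands
slightly above it — exactly why the quantile rule, not the χ² constant,
is the definition.

**Whitespace.** Anomaly calls are defined on tissue. Otsu's threshold on
8-bit luminance (0.299R + 0.587G + 0.114B) of a downsampled thumbnail
separates bright whitespace from tissue; patches are taken from grid
cells with ≥ `min_tissue_fraction` tissue, and — important in practice —
whitespace pixels *within* those patches are excluded from the NERD fit,
from calibration, and from prediction, by re-applying the slide's
luminance threshold at patch resolution. Without this, border-patch
whitespace (reconstruction error ≈ the tissue–background contrast, an
order of magnitude above tissue noise) inflates Σ and masks real
anomalies.

**Polygons and metrics.** Flagged pixels are labelled with 4-connected
components and traced on the pixel lattice, so polygon area equals the
member-pixel count exactly and the confusion matrix is an integer
computation. Components below `min_area` (default 256 px²) are dropped —
this is what keeps isolated calibration-rate exceedances (the expected
q of tissue) from surfacing as predictions. Per-patch polygons are merged
by re-rasterising on the common lattice and re-tracing, which is an exact
union for lattice polygons. Evaluation rasterises predicted and annotated
sets with pixel-centre inclusion (polygons half-open on max edges, so
abutting polygons never double-count) and reports sensitivity,
specificity and F1 per slide, cohort mean ± SD (n−1), and a slide-level
presence call (positive iff total predicted area ≥ `min_area`, i.e. any
surviving prediction). 0/0 metrics are reported as NA and excluded from
cohort means with a warning; the TN universe is the tissue bounding box
by default (a whole-slide region is configurable, but TN over vast
whitespace inflates specificity).

## Parameters at a glance

| parameter | default | meaning |
|---|---|---|
| `patch_size` | 64 px (desk scale) | grid tile side at level 0; the architecture supports up to 1024 |
| `min_tissue_fraction` | 0.5 | minimum tissue coverage for a patch to enter the pipeline |
| `downsample` (thumbnail) | 32 (16 at desk scale) | Otsu thumbnail factor |
| `max_resolution` | 16 (desk) … 1024 | top of the progressive ladder |
| `channels` | 32 at 4×4, tapering to 8 | width schedule per level |
| `λ_rec`, `λ_adv` | 1, 0.05 | loss weights; reconstruction dominates |
| `lr`, batch | 2e−3 (Adam, β₁ = 0.5), 8 | optimiser settings |
| `clip_norm` | 1 | global L2 gradient-norm ceiling per update |
| `f` (inpaint fraction) | 0.5 | masked square side as a patch fraction |
| `fade_fraction` | 0.5 | share of each level's budget spent ramping α |
| `q` | 0.05 | allowed normal-pixel exceedance; sets τ |
| `ε` | 1e−6 | covariance ridge |
| `min_area` | 256 px² | minimum predicted component |
| `closing_radius` | 0 | optional morphological closing before tracing |
| eval `downsample` | 1–4 | raster step for the confusion matrix |

## The synthetic benchmark

Real WSIs are gigapixel clinical data and cannot accompany a package, so
the fixtures module emulates the features the pipeline actually relies
on: bright whitespace (0.96), a stationary normal-tissue texture (a
separable-exponential Gaussian random field, correlation length 8 px,
SD 0.05, around an H&E-like base colour (0.80, 0.55, 0.68)), planted
anomalies (discs with a colour shift of magnitude ≈ 0.3 toward a darker
purple — hypercellular tumor takes up more hematoxylin), optional green
ink strokes reproducing the documented artifact false-positive mode, and
exact truth polygons. The tissue block is rectangular (6% margin) and
slides are 8-bit quantised like real scans. Cohorts mirror the canonical
normal-slide split structure (100/20/20 proportions over the three
training phases) with all tumor slides in the inference split; every
slide is generated from a seed derived from the cohort seed, so cohorts
are bit-reproducible.

What passing on this benchmark shows: the *pipeline math* is right —
calibration holds its rate, planted anomalies separate by an order of
magnitude in Mahalanobis distance, polygons and confusion counts are
exact, slide-level calls behave. What it does not show: performance on
real histology, where normal tissue is heterogeneous (glands, mucosa,
vessels all differ in texture), tumors are not uniform colour shifts,
staining varies between labs, and peritumoral/benign anomalies blur the
boundary. The clinical numbers of the source cohort are therefore not
claims of this package.

The oracle reconstructor — `base + (1−shrink)(x − base)`, shrink 0.8 —
is the deterministic stand-in for the frozen GAN in end-to-end tests; it
has exactly the property the GAN is trained toward (small errors on
normal texture, large on anything colour-shifted) without GPU-scale
training, and it plugs through the same `reconstruct()` generic.

## Numerical choices and degenerate inputs

* Otsu maximises between-class variance over splits {0..t−1}/{t..255};
  ties take the smallest t; "tissue" is strictly `luminance < t`. A
  histogram with all mass in one bin (blank slide) is an error, not a
  guess.
* Downsampling is 2×2 area averaging (matching the discriminator's
  pooling); nearest-neighbor is available for ablation. Pyramids are the
  full power-of-two ladder.
* Σ = 0 (constant errors) stays usable through ε; distances at the mean
  are exactly 0; tiny negative quadratic forms from round-off are
  clamped to 0 before the square root.
* Nearest-rank quantile: τ = sorted[⌈(1−q)·n⌉]; q = 0 gives the maximum.
* Ring tracing keeps 4-connected components separate at pinch vertices
  by always taking the sharpest right turn; exterior rings are positively
  oriented (x right, y down), holes negatively; collinear vertices are
  dropped. Even-odd scanline rasterisation with pixel-centre inclusion
  makes polygonise∘rasterise the identity on lattice polygons.
* Record shards quantise images to 8 bits; anything that came from an
  8-bit source round-trips bit-exactly. Corrupt shards fail with the
  shard path and record index.
* Gradients of both networks are clipped to a global L2 norm of 1 per
  update: at batch size 8 the least-squares adversarial term occasionally
  spikes, and an unclipped spike can saturate the sigmoid output head
  beyond recovery. Clipping leaves ordinary updates untouched (their
  norms sit well below 1) and only caps the spikes.
* Training is deterministic given the seed on a single-threaded BLAS;
  all randomness in the pipeline flows from one root seed with fixed
  per-phase offsets.

## Design decisions where the method was open

* **Adversarial term:** least-squares GAN by default — stable at tiny
  batch sizes and resolutions; the adversarial weight is deliberately
  small (0.05) since the anomaly score derives from the reconstruction
  path, not the discriminator.
* **Error scope:** reconstruction errors are taken over the full patch
  (`error_scope = "full"`), with a masked-only mode available; with
  compositing, signal concentrates in the inpainted square either way.
* **Inpaint geometry:** a centred square of half the side, filled with
  the dataset mean colour — the simplest geometry that forces context
  use.
* **Threshold rule:** the empirical quantile with q = 0.05. Nothing in
  the method fixes how the cut-off should be "selected" from normal
  slides; the quantile makes q a meaningful, auditable rate and is the
  package's documented convention.
* **Merging and post-processing:** non-overlapping tiling, exact lattice
  union across patches, `min_area` 256 px², no closing — all
  config-surfaced since no canonical convention exists.
* **Problem sizes:** the shipped tests train to 16×16 on 200 patches
  (about 1–2 minutes) and run the end-to-end cohort at 512² with
  64-px patches — sizes chosen so the full suite exercises every stage
  while staying a desk-scale computation; the architecture itself is
  resolution-agnostic up to 1024.

## Known limitations

* The anomaly definition is one-sided: anything un-normal is "tumor".
  Ink, artifacts and benign-but-unusual tissue are flagged (the ink
  fixture demonstrates this deliberately).
* A single pooled 3-D Gaussian cannot represent multi-modal normal
  error structure; heterogeneous real tissue would likely need a richer
  reference distribution.
* Pixel-level scoring at the model's working resolution is upscaled to
  level 0 by the patch-size ratio, so prediction boundaries are blocky
  at coarse working resolutions.
* The R implementation of the GAN is single-threaded CPU code: faithful
  and testable, but not a route to 1024×1024 photorealism.
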