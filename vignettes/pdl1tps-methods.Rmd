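---
title: "Automated PD-L1 tumor proportion scoring: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated PD-L1 tumor proportion scoring: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The scoring problem

PD-L1 expression on tumor cells, assessed on 22C3 immunohistochemistry (IHC),
is reported as the tumor proportion score

$$\mathrm{TPS}(\%) = \frac{\#\ \text{PD-L1 positive tumor cells}}{\#\ \text{viable tumor cells}} \times 100,$$

where a tumor cell counts as positive if it shows at least partial membrane
staining, and interstitial cells, immune cells, and necrotic areas are
excluded. Slides are reported in three classes: negative (TPS < 1%), low
(1--49%), and high ($\ge$ 50%). Manual counting across a whole slide with
millions of cells is slow and subjective; `pdl1tps` implements an automated
three-stage pipeline that mirrors how a pathologist works:

1. **Tumor-region segmentation** (supervised) produces a viable-tumor mask at
   20x,
2. **Positive-membrane detection** (unsupervised image processing) produces a
   positive-stain mask from the DAB channel at 40x,
3. **Nuclei detection** (supervised, point-based) counts cells at 40x; cells
   are labelled against the two masks and aggregated into the slide TPS.

Because no clinical cohort ships with the package, a synthetic H-DAB
generator provides fully ground-truthed pseudo-slides; every stage and the
end-to-end score are tested against planted truth.

## Stain model and colour deconvolution

Brightfield IHC follows Beer--Lambert absorption: optical density
$\mathrm{OD} = -\log_{10}(I/I_0)$ is linear in stain concentration. A
`stain_model()` holds three unit-norm OD vectors (hematoxylin, DAB,
residual); `deconvolve()` multiplies each pixel's OD triplet by the inverse
stain matrix and clamps negative concentrations to zero, the standard
practice for pixels outside the stain simplex.

Numerical choices:

* Default vectors are the classical published H-DAB values. The residual is
  the per-component complement $\sqrt{1 - h_i^2 - d_i^2}$, normalized. An
  orthogonal (cross-product) residual would contain a negative component;
  rendering a positive residual concentration through it would produce
  negative OD, which the non-negativity clamp destroys, breaking the
  render/unmix round trip. The complement keeps the whole forward model
  inside the non-negative OD cone, so `od_to_rgb()` and `deconvolve()` invert
  each other to machine precision on float images and to one intensity level
  after 8-bit quantization.
* Intensities are clamped below at $I_0/255$ before the log so OD stays
  finite; the background level defaults to 255 per channel and is
  configurable per image.

## Positive-membrane detection

The detector is deterministic and needs no annotation. On the DAB
concentration plane of a 40x tile (0.2375 um/px):

1. **DoG band-pass gate.** A difference of Gaussians
   ($\sigma_{\text{narrow}} = 1$, $\sigma_{\text{wide}} = 2$ px) selects
   membrane-scale ridges; only pixels with positive (rectified) response can
   become candidates. Membranes are ~2--4 px thick at this resolution, which
   sits inside this pass-band; diffuse background (e.g. weak necrotic DAB)
   is rejected. Kernels are explicitly sampled Gaussians truncated at
   $4\sigma$ and normalized to unit sum, so the impulse response equals the
   kernel difference exactly.
2. **Luminance-adaptive multi-thresholding (LAMT).** The tile is split into
   64-px blocks; each block chooses among five candidate thresholds (the
   50th--90th percentiles of its DAB values). The middle candidate is the
   default; blocks whose mean luminance falls below the global mean --
   strongly stained neighbourhoods -- shift one step darker. The selected
   threshold is floored at an absolute minimum DAB OD (`min_dab = 0.15`):
   percentile thresholds are scale-free, and without the floor a DAB-free
   tile would promote noise to candidates. The floor preserves monotonicity
   in stain strength (scaling all DAB up never shrinks the candidate set).
3. **Luminance-weighted thresholding.** Candidates must be dark enough in
   the original RGB: darkness $1 - Y \ge 0.25$, with $Y$ the Rec. 601 luma
   $(0.299R + 0.587G + 0.114B)/255$. This removes faint blush that the DAB
   plane alone over-calls.
4. **Morphological cleanup.** Opening (radius 1) removes dot noise, closing
   (radius 2) seals small membrane gaps, enclosed holes up to 50 px are
   filled, and components under 20 px are dropped. The hole-fill cap is
   deliberately smaller than a cell interior (~80--170 px here): filling
   complete rings into discs would misstate the stained area. The cleanup is
   idempotent.

All parameters live in `membrane_params()` and can be overridden from YAML.

## Tumor-region segmentation

`build_res50_unet()` constructs a U-Net-style encoder-decoder. The encoder
is a bottleneck residual network (default preset: stages of 3/4/6/3 blocks,
widths 256/512/1024/2048, i.e. the 50-layer layout) in which the last two
stages keep stride 1 and use dilation rates 2 and 4 instead, giving output
stride 8; an ASPP block with four parallel dilated 3x3 convolutions (rates
1, 2, 4, 7) sits between encoder and decoder to aggregate multi-scale
context. The decoder upsamples 8 -> 4 -> 2 -> 1 with skip connections from
the stride-4 and stride-2 encoder features; since the last two encoder
stages stay at stride 8, their outputs feed the ASPP only. The stem's
max-pool is replaced by a stride-2 convolution, which keeps the numerical
core down to a single conv primitive without changing the stride plan.

Training choices (the loss/optimizer are not part of the architecture
contract and are package choices): per-pixel softmax cross-entropy averaged
with soft Dice on the tumor channel -- robust to tumor/stroma imbalance --
optimized with Adam. Initialization is He-style with the final convolution
of each residual block scaled down (0.1), which stabilizes deep residual
training without normalization layers. Inputs enter as $1 - I/255$ so white
background maps to zero. No pretrained weights are used anywhere, keeping
runs deterministic for a given seed.

The networks run on a small tape-based reverse-mode autodiff implemented in
the package (im2col + BLAS GEMM convolutions in C++); at the tile sizes used
here a training run is a few CPU-minutes, and the architecture graph is
introspectable (`receptive_field()`, `count_params()`).

**Reduced-scale configuration.** Tests and the acceptance script use
`width_multiplier = 1/8` and one block per stage: the identical architecture
contract (stride plan, dilation, ASPP, skips) at ~210k parameters, which a
CPU trains in minutes. The full-width preset builds and runs but is not
trained in the test suite.

## Nuclei detection

Centres are regressed as a **repel-coded proximity map**: with $d_1 \le d_2$
the distances to the two nearest centres,

$$R(p) = \max(0, 1 - d_1/r)^{\alpha}\,\bigl(1 - \beta\, d_1 / \max(d_2, \varepsilon)\bigr),$$

with defaults $r = 10$ px, $\alpha = 2$, $\beta = 0.8$. The map is 1 exactly
at centres, 0 beyond $r$, and suppressed in the corridor between close
nuclei so adjacent cells remain separable peaks.

The detector (`build_micronet()`) is a U-Net-like network with
multi-resolution inputs: downscaled copies of the tile (factors 1, 2, 4) are
injected at the matching encoder depths, and with deep supervision each
coarser level emits an auxiliary sigmoid map trained against the
correspondingly downsampled target, so the number of outputs equals the
number of resolution branches. The loss is an MSE with positive pixels
up-weighted (x11 at the peak), countering the empty-background majority;
auxiliary losses enter at half weight.

Peaks become points via greedy NMS: all pixels above `score_threshold`
are visited in decreasing score order (ties row-major) and kept if no kept
point lies closer than `min_distance` (default 5 px, about half a nucleus at
40x). The implementation is exactly this greedy procedure (in C++), so it
agrees bit-for-bit with a brute-force oracle. The operating threshold is
calibrated after training on a handful of training tiles (pooled-F1 maximum
over a fixed 0.10--0.70 grid) and stored with the model: the regression
head's score scale varies between training runs while the ranking does not
(the score-sweep AUC is stable), so a fixed threshold would make the
reported F1 an accident of the seed. The uncalibrated default remains 0.3.

Evaluation matches detections to annotations one-to-one by
maximum-cardinality bipartite matching on pairs strictly closer than 10 px;
F1 follows from TP/FP/FN. Since point detection has no true negatives, the
reported "AUC" is the area under the monotone-staircased precision-recall
curve swept over the detector's confidence thresholds, labelled explicitly
as a score-sweep AUC.

## Scoring

`classify_nuclei()` labels each detected point: it is a tumor cell iff the
20x tumor mask is set at `(floor(x/2), floor(y/2))` (integer floor mapping
between magnifications), and positive iff any positive-stain pixel lies
within a disc of radius $\rho = 8$ px (40x) around the centre -- membrane
staining surrounds the nucleus rather than covering it, so point-in-mask
would systematically miss rings. The disc is the exact Euclidean
neighbourhood, implemented as one mask dilation plus a single-pixel lookup.
Slide TPS is cell-weighted: counts are summed over tiles before the ratio,
never averaged per tile, which is the literal reading of the definition for
a system that counts every cell. A slide with zero viable tumor cells
raises an "insufficient viable tumor cells" error rather than returning a
number.

In the whole-image pipeline, detection tiles may overlap; each tile owns the
detections inside its "core" (overlap split midway between neighbours, cores
clamped to the image so they partition it), so boundary nuclei are counted
exactly once.

## Synthetic data: what it emulates and what it does not

`generate_slide()` renders, at 40x: tumor nests thresholded from a smoothed
Gaussian noise field (cohesive, irregular shapes; the 4 largest components,
~45% of the canvas); elliptical tumor nuclei (long axis 8--14 px) placed on
a jittered hard-core lattice with 20 px minimum spacing, approximately one
cell diameter, i.e. touching cells; smaller stromal/immune nuclei outside
the nests; DAB membrane rings (gap 0.5 px, thickness 3--4 px, full rings or
partial arcs of 140--300 degrees) on each tumor cell independently positive
with probability TPS/100; optional necrosis (diffuse weak DAB, no nuclei,
excluded from the viable mask) and optional membrane-positive immune cells
planted well outside nests to reproduce the documented histiocyte failure
mode. Concentration fields are rendered through the stain model, blurred
optionally, and quantized with Gaussian camera noise (sd 3); the 20x level
is a 2x block mean.

Three geometric facts are guaranteed by construction and asserted in tests:
every positive cell keeps at least one membrane pixel inside its 8-px
scoring disc; no neighbouring cell's membrane can enter a negative cell's
disc (spacing 20 px exceeds the maximal ring reach 11.5 px plus the disc
radius 8 px); ring thickness 3--4 px survives the radius-1 opening of the
membrane detector. Together they make the oracle pipeline exact: scoring
truth masks and truth centres returns the realized TPS identically, which
separates scoring errors from upstream model errors.

What the generator does **not** emulate: real chromatin texture, nucleoli,
cytoplasmic DAB, tissue folds, out-of-focus regions, scanner colour
variation, or stain spill-over between serial cells. Passing tests
therefore demonstrate that the algorithms are implemented correctly and
behave as designed under controlled morphology -- not that the trained
models would transfer to clinical slides; the stated clinical-cohort
figures of systems of this kind are out of reach without such data.

## Problem sizes and seeds

The acceptance run trains the segmenter on 32 synthetic 512x512 tiles at 20x
(15 epochs on random 128-px crops, Adam, lr 1e-3, batch 4) and the detector
on 64 synthetic 256x256 tiles at 40x (14 epochs, 128-px crops, lr 2e-3),
then scores 12 held-out 1024-px pseudo-slides, four per expression level --
sizes chosen so the full run is a few CPU-minutes while leaving hundreds of
cells per slide. All randomness flows from explicit seeds through a single
seeded-RNG wrapper; training, generation, and the bootstrap are reproducible
bit-for-bit for a given seed. The training-set emitter keeps the 3:7
negative:positive slide ratio used for the patch datasets.

## Evaluation statistics

`agreement_report()` computes MAE between predicted and reference TPS with a
95% CI from a seeded nonparametric percentile bootstrap over cases (2000
resamples -- the CI method is a package choice, assumption-free at small n),
the Pearson correlation with its two-sided t-test p-value, the 3-class
accuracy, and the 3x3 confusion matrix (rows = truth). `subgroup_mae()`
restricts the MAE by true expression level, optionally dropping negative
cases, mirroring how such systems are reported per expression stratum.

## Known limitations

* The LAMT and luminance-weighting steps follow the semantics described for
  them (block-local percentile candidates, brightness-shifted selection;
  Rec. 601 luma) but the originally published variants are not reproduced
  verbatim; both are fully parameterised so alternatives can be dropped in.
* The 3-class decision inherits the discontinuity at the 1% boundary: on
  near-negative slides a handful of false-positive membrane pixels can lift
  the TPS across the threshold. This is the same failure mode documented
  for this class of systems, and the regression test exercises exactly it.
* The "AUC" is a score-sweep PR AUC, not an ROC AUC over a negative class;
  reports label it accordingly.
* Membrane completeness (partial vs circumferential staining) is not
  scored; a cell with any adjacent positive stain counts as positive.
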