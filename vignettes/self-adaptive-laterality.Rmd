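---
title: "Self-adaptive training for eye-laterality detection from fundus photographs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Self-adaptive training for eye-laterality detection from fundus photographs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fundusAdapt)
```

## The problem

A macula-centred colour fundus photograph shows the optic disc displaced
horizontally toward the nasal side, so the disc sits on opposite sides of
the image in left and right eyes. Eye laterality (which eye a photograph
depicts) is basic metadata for any ophthalmic image pipeline, yet it is
often missing or wrong in pooled datasets collected from many cameras.
`fundusAdapt` implements a complete laterality-detection pipeline: image
size normalisation, four enhancement methods, a GAP-headed convolutional
classifier emitting a probability vector $(P_1, P_2)$ for (left, right),
a monitor-driven *self-adaptive* training strategy, class activation maps,
and ROC-based evaluation. Because clinical photographs cannot ship with a
package, a synthetic generator reproduces the geometric structure the
classifier exploits, making every stage testable end to end.

## The self-adaptive strategy

Training health after epoch $n$ is summarised by the monitor

$$M_n = (1 - \mathrm{Accuracy}_n) \cdot \mathrm{Loss}_n,$$

both measured on the validation set; smaller is better, and $M_n = 0$
exactly when accuracy is perfect or loss vanishes. Two mechanisms react to
it, implemented in `controllerObserve()` as a pure state machine over
plain values (metrics in, actions out), so any metric stream can be
replayed against it:

* **Self-adaptive learning rate.** The rate starts at a deliberately
  large $l_0 = 0.1$. If $M_{n+1} < M_n$ the rate is untouched; otherwise
  an *alert period* starts with baseline $M_n$. If the monitor fails to
  drop below the baseline for $k = 5$ consecutive epochs the rate is
  multiplied by $\alpha = 0.5$; a single sub-baseline epoch cancels the
  alert. We read the $k$-epoch condition against the *fixed* baseline
  (the last strictly improving epoch), and after a reduction the alert
  ends and comparison re-arms from the current monitor; chained
  reductions occur when stagnation persists. A floor of $10^{-5}$
  prevents underflow in long runs.
* **Self-adaptive best-model pool.** A snapshot enters the single-slot
  pool after epoch $n$ only when $M_n \le M_{best} \le M_{threshold}$,
  accuracy $\ge 0.95$ and loss $\le 0.1$, with
  $M_{threshold} = 0.005$. $M_{best}$ is initialised to
  $M_{threshold}$ so the chained condition is satisfiable from an empty
  pool (with $M_{best} = \infty$ it never could be); ties replace the
  snapshot so the most recent weights are kept. Every 10 epochs the
  pool's best weights are reloaded into training; the reload restores
  weights only and resets optimiser momentum. Note the gates are
  mutually consistent: the largest monitor attainable inside the gate
  region is exactly $(1 - 0.95) \times 0.1 = 0.005 = M_{threshold}$. The
  pool's monitor comparison carries a $10^{-12}$ absolute tolerance so an
  epoch sitting exactly on that corner is admissible despite
  floating-point rounding.

Within an epoch, actions are applied in the fixed order save, reduce,
reload, so an epoch that enters the pool at a period boundary can be
reloaded immediately. The strategy is used for the laterality model only;
the preprocessing comparison (`comparePreprocessing()`) trains at a fixed
rate (default 0.01) with no controller, with identical splits and initial
weights across methods so curves differ only through the preprocessing.

## Size normalisation and enhancement

`normalizeFundus()` composes four steps: (1) `cropDarkBorder()` scores
each row/column by the sum of the per-pixel maximum channel and keeps the
span above 2% of the peak line sum — a robust reading of "cut the black
edge by pixel summation" that tolerates dark-but-nonzero sensor noise;
(2) `toSquare()` centre-crops the longer dimension (odd excess comes off
the trailing side); (3) `resizeFundus()` resamples bilinearly to
$299 \times 299$ (tests use smaller sides); (4) `circularMask()` zeroes
everything beyond 95% of the fundus radius, taken as half the post-crop
square side — after border cropping the fundus circle spans the square,
which avoids a separate circle-fitting step. Applying the mask, the
square crop or the resize a second time at the target geometry is a
no-op; re-running the *full* chain is not exactly idempotent, because the
masked rim itself reads as a dark border on the second pass.

Four enhancement methods feed the classifier comparison:

* **ORIGINAL** — the input unchanged;
* **CLAHE** — contrast-limited adaptive histogram equalisation (clip 2,
  8×8 tiles) applied to the CIELAB luminance only, preserving hue. The
  CLAHE kernel requires sides divisible by the tile grid; other sides
  are bilinearly resampled to the next multiple of 8 and back, which
  keeps the operation exactly equivariant under horizontal mirroring;
* **LSACR** — local-space-average-colour removal,
  $\mathrm{clip}(4I - 4G_\sigma(I) + 128)$ per channel with
  $\sigma = \text{side}/30$; with $\alpha = \beta$ a constant image maps
  to the neutral 128;
* **GRAY** — Rec.601 luma replicated to all three channels.

In the pipeline the circular mask is re-applied after enhancement:
histogram-based methods can lift masked-out rim pixels slightly above
zero, and no method should introduce signal outside the fundus region.

## The classifier and its optimiser

Both backbones end in global average pooling followed by one affine layer
to two logits, so class activation maps are well-defined.
`"inception_v3"` follows the Inception-V3 topology (stem plus 11
inception modules, asymmetric 7×1/1×7 factorisations included) at its
native 299-pixel input; it is built without batch normalisation, which
keeps the layer engine small, and is intended for forward-pass fidelity
rather than desk-scale training. `"tiny"` is a four-block conv/pool stack
(8–16–32–32 channels) for CPU-scale experiments. The engine itself —
im2col convolution and pooling with full backward passes — is compiled
code inside the package; gradients are verified against finite
differences in the test suite.

Training is plain SGD: momentum 0.9 and L2 penalty
$\lambda \sum w^2$ with $\lambda = 10^{-4}$ (the gradient contribution is
$2\lambda w$). Two numerical choices make the deliberately large
$l_0 = 0.1$ workable for a freshly initialised network: inputs are scaled
to $[-1, 1]$ (the Inception convention), and the mean mini-batch gradient
is clipped to a global L2 norm of 2 (`gradClip`; 0 disables). Without
clipping, the first epochs at $l_0 = 0.1$ with momentum 0.9 drive the
ReLUs into permanent inactivity and the network never leaves chance
accuracy; with it, desk-scale runs reach perfect validation accuracy
within a handful of epochs. Augmentation draws an integer horizontal
shift (magnitude uniform on $\{0,\dots,10\}$ pixels, random sign) and a
rotation uniform on $[-30°, +30°]$ — we read "rotation of 30 degree" as a
bound, not a fixed angle — and applies both as a single bilinear warp
with black fill. Ties at $P_1 = P_2$ resolve to *left*, a fixed,
documented convention.

## The synthetic cohort

`generateFundusImage()` renders what the classifier needs and nothing
more: a bright orange-red fundus disc (base colour ≈ (200, 90, 40),
Gaussian pixel noise $\sigma = 8$ so the enhancement comparison has
realistic work), black side bars of 12.5% of the width, an overexposed
rim annulus, a darker central macula, an elliptical optic disc displaced
by 0.55 fundus radii toward the laterality side, and quadratic vessel
arcs from the disc. Right-eye images are exact mirrors of the left-eye
rendering at the same seed, so the two classes are perfect mirror
populations and the mirror-swap property of a trained model is a
meaningful check. A poor-quality mode occludes at least half the fundus
(half-plane or disk) or crop-shifts the disc partially out of frame,
exercising the exclusion rule `isPoorQuality()` (≥ 50% obscured, or the
disc only partly visible). The nasal offset and structure radii are not
calibrated to clinical measurements — no public measurement of that
geometry accompanies the datasets this emulates — so passing tests show
the *pipeline* recovers planted structure; they say nothing about
accuracy on real photographs, where disc contrast, field of view and
pathology vary far more.

## Desk-scale problem sizes

The package's reference experiments, chosen once and used by the test
suite: 400 clean synthetic images on a 256×192 canvas, normalised to a
64-pixel input, tiny backbone, 8:2 stratified split, 20 epochs, batch 32,
training seeds {101, 202, 303}. Under these conditions the self-adaptive
run reaches ≥ 95% validation accuracy well inside 20 epochs, the CAM
centroid (threshold 0.5) falls within a quarter of the image side of the
true disc centre for the large majority of correctly classified images,
and mirroring an image flips the predicted label. The full-scale
configuration of the source experiments (thousands of photographs,
Inception-V3 at 299 pixels, hundreds of epochs) is accepted through the
same interfaces.

## Evaluation conventions

Left eye is the positive class throughout. `rocAuc()` sweeps the unique
scores (an image is called left iff $P_1 \ge t$); the area under that
curve equals the Mann–Whitney probability that a random left-eye score
exceeds a random right-eye score, ties counting one half — the test suite
checks the sweep against a brute-force pairwise count. Confidence
intervals are Wilson score intervals for proportions and the DeLong
variance estimator for the AUC; the source experiments do not name their
interval methods, so reproduced intervals on other data may differ in the
last decimals. Reported label metrics use the 0.5 threshold with the
left tie-break, matching `predictLaterality()`.

## Known limitations

* The synthetic cohort is geometrically faithful but photometrically
  simple; enhancement rankings measured on it (e.g. CLAHE vs LSACR) need
  not transfer to clinical images.
* The Inception-V3 backbone omits batch normalisation and ships with no
  pretrained weights; training it from scratch at desk scale is out of
  scope.
* Training determinism holds for the package's own single-threaded
  kernels; the controller is pure and replayable by construction.
* The observation that left-eye and right-eye models attend to
  differently sized regions is not operationalised; no contract encodes
  it.
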