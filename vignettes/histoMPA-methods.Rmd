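---
title: "histoMPA: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{histoMPA: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(histoMPA)
```

histoMPA classifies histopathology image tiles into five lung/colon tissue
categories with a pipeline of four stages: CLAHE contrast enhancement,
depthwise-separable convolutional features, Marine Predators Algorithm (MPA)
hyperparameter search, and a deep-belief-network (DBN) classifier. This
vignette records the model choices, the parameters that matter, and the
numerical conventions, in enough detail that a maintainer can predict the
code's behavior without reading it.

## CLAHE preprocessing

Adaptive histogram equalization amplifies noise in flat regions; CLAHE bounds
that amplification by clipping each contextual block's histogram before the
CDF is computed. Our implementation:

* The image is padded by **reflection** so that a `blockSize = (rows, cols)`
  grid divides it evenly; every block therefore uses the same mapping
  formula, with no special-cased border blocks.
* Each block's histogram (`nBins = 256` over [0, 255]) is clipped at
  `clipLimit * blockPixels / nBins` — i.e. the clip limit is a multiple of
  the uniform bin height, so `clipLimit = 1` flattens the histogram
  completely and `clipLimit = Inf` disables clipping. The clipped excess is
  redistributed **uniformly in a single pass**; we do not iterate
  re-clipping. This is a documented dialect choice: iterative redistribution
  changes mappings by at most one bin's mass and complicates the oracle
  arithmetic.
* The mapping of bin *b* is `(cdf(b) - cdfMin) / (N - cdfMin) * 255` with
  `cdfMin` the first nonzero CDF entry — the classical equalization formula,
  which sends the flattened histogram to an identity ramp.
* Pixels are mapped by **bilinear interpolation** between the four
  surrounding block-center mappings; outside the outer centers the nearest
  block applies alone.
* **Degenerate blocks**: a block whose pre-clip histogram occupies a single
  bin (a constant region) gets the identity mapping. Equalizing a constant
  region is undefined, and any CDF-based choice drifts the region's
  brightness by a level or two per application; the identity convention
  keeps constant images fixed points of the transform, which is also what
  makes `clahe(clahe(x)) = clahe(x)` hold exactly for constant `x`.
* **Color**: RGB tiles are converted to CIELAB
  (`grDevices::convertColor`), only the L channel is equalized, and the
  result converted back. This preserves the hematoxylin/eosin hue, which
  carries class information; equalizing channels independently (available as
  `colorMode = "per_channel"`) shifts hue. Defaults `clipLimit = 2`,
  `blockSize = c(8, 8)` are the common CLAHE working point; no published
  values exist for this pipeline, so both are exposed in the config.

A note on the monotonicity property: each block mapping is a non-decreasing
function of intensity (a CDF is monotone), and on a single-block image the
output preserves the pixel order exactly. Across blocks, bilinear blending
of *different* monotone mappings need not preserve the order of two pixels
at different positions, so the invariant is asserted where it is
well-defined: per mapping, and image-wide for single-block configurations.

## Feature extraction

The extractor is a small stack of depthwise-separable convolution blocks —
per-channel `k x k` filtering, then a 1×1 pointwise channel mixer, ReLU after
each stage, "same" zero padding — ending in global average pooling (GAP).
The default is 4 blocks, channels `3-16-32-64-64`, strides `1-2-1-2`, input
`64 x 64`, giving a 64-dimensional feature vector. The published description
of this pipeline names MobileNet without a variant, input size, or weights;
ImageNet checkpoints are out of scope, so the default mode is
**fixed-seed random weights** (He-scaled), which makes the feature map a
deterministic function of the pixels and is sufficient for the well-separated
synthetic classes. An optional `weightsMode = "trained"` recalibrates the
final block's pointwise weights with exact softmax-head gradients through
GAP/ReLU on the training rows (the head is discarded afterwards); earlier
blocks stay frozen. We chose ReLU over the logistic sigmoid used elsewhere
in the pipeline because saturating nonlinearities in randomly-initialized
convolution stacks destroy most of the signal variance.

Features are z-scored per column with statistics fitted on **training rows
only**; zero-variance columns map to zero rather than dividing by zero.

## The MPA optimizer

MPA is a population metaheuristic; lower fitness is better. One run is:
uniform initialization in the box, an initial evaluation, then `iMax`
iterations of {phase update, FADs perturbation, re-evaluation, per-agent
memory saving, elite update}. The conventions that required a decision:

* **Phase schedule**: iterations `0 .. floor(iMax/3) - 1` are phase 1,
  the next `floor(2*iMax/3) - floor(iMax/3)` phase 2, the rest phase 3.
* **Phase 2 halves**: the first `ceiling(n/2)` agents take the Lévy
  exploration rule, the remainder the Brownian exploitation rule. The
  printed sources are ambiguous about the middle agent for odd `n`; the
  ceiling assignment is our convention.
* **Step factors**: phase 1 and the Lévy half of phase 2 scale steps by
  `P * R` (uniform vector, `P = 0.5`); the Brownian half of phase 2 and all
  of phase 3 scale by `P * CF` with `CF = (1 - I/iMax)^(2I/iMax)`.
* **Phase 3 rule**: the self-consistent form
  `Step = RL ⊗ (RL ⊗ Elite − Prey)` is the default; a literal variant
  without the inner Lévy factor is available as `eq11Literal = TRUE` because
  some printed descriptions omit it.
* **FADs rule**: with probability `FADs = 0.2` an agent takes a masked long
  jump `CF * (lb + R ⊗ (ub − lb)) ⊗ U` with `U` a per-coordinate
  Bernoulli(`FADs`) mask; otherwise it moves along the difference of two
  random population members scaled by `FADs(1−r) + r`. The printed equation
  for this rule is typographically corrupted in our source material; we
  implement the canonical rule from the original MPA formulation, which the
  surrounding prose describes.
* **Boundaries**: every move is clamped to `[lb, ub]`. **Elite ties**: the
  elite is replaced only on strict improvement, which keeps plateau runs
  stable. **Lévy draws** use Mantegna's algorithm with stability exponent
  1.5.

Memory saving plus strict elitism make the best-so-far history
non-increasing by construction; the test suite asserts this for every run it
performs.

### Hyperparameter tuning

The tuner searches a 6-dimensional box: log10 RBM learning rate and log10
fine-tune learning rate on `[-4, -1]`, two hidden-layer sizes on `[8, 256]`,
CD steps on `[1, 5]`, fine-tune epochs on `[5, 60]`; integer coordinates are
decoded by rounding (`decodeCandidate()`). Fitness is the **classifier error
rate in percent** on an inner validation split — a stratified 20% of the
training split, held out before any candidate is trained — so the outer test
split never influences the search. Fitness is deterministic given the
bundle: classifier training inside it is seeded, and the optimizer's own RNG
stream is protected from it.

## The DBN classifier

The first RBM uses **Gaussian visible units** (unit precision) because its
input is standardized real-valued features; deeper RBMs are
Bernoulli–Bernoulli on the previous layer's hidden probabilities. Training
is CD-k: hidden states are sampled, visible reconstructions use the
conditional mean (a standard stabilization that is also the natural choice
for Gaussian units), and the final statistics use probabilities. Minibatch
size is 32 throughout.

The stacked recognition pass is `h1 = sigmoid(b1 + v'W1)`,
`hl = sigmoid(bl + h(l-1)'Wl)` — the bottom-up direction; the top-down
generative conditionals exist in the model but features flow upward. A
softmax head on the top layer is **always warm-started** by full-batch
softmax regression on the frozen top activations (200 steps, learning rate
1.0 — cheap, convex, and it makes `ftEpochs = 0` a natural "frozen DBN +
linear head" model rather than a special case), then the whole stack is
fine-tuned jointly by minibatch backpropagation on cross-entropy.

The optional stacked autoencoder (sigmoid encoder, mirrored decoder with an
identity output layer, mean-squared reconstruction loss `sum((xhat-x)^2)/N`)
sits between standardization and the DBN behind `ae$enabled` (default off:
with 64-dimensional features, compression mostly costs accuracy at this
scale).

## Synthetic data: what it does and does not show

`generateTiles()` emulates the *statistical shape* of stained tile data:
each class has a base stain-like color, a Poisson number of darker
elliptical nuclei-like blobs, spatially correlated texture (moving-average
smoothed noise), and clipped Gaussian pixel noise. Distinct classes differ
primarily in base color and secondarily in blob density and texture scale;
the default recipes are separable enough that a mean-color nearest-centroid
rule classifies over 90% of tiles. Generation is a pure function of
`(recipes, n, size, seed)`.

This is deliberately *not* a histology simulator: no stain physics, no
tissue morphology, no scanner artifacts, no label noise, no class imbalance.
Passing the end-to-end tests therefore demonstrates that the pipeline's
plumbing, determinism, leakage guards, optimizer, and classifier training
are correct — not that the defaults would reach any particular accuracy on
real slides, where features and hyperparameters would need to be re-tuned
on real training data.

## Problem sizes and budgets

The test and acceptance workloads are sized for a single desktop CPU: the
end-to-end run uses 5 × 60 tiles of 64 × 64 with an MPA budget of `n = 6`,
`iMax = 6` (42 classifier trainings); optimizer benchmarks use 10-D sphere
(n = 25, 300 iterations, 5 seeds) and 10-D Rastrigin (n = 25, 100
iterations, 11 seeds, budget-matched against pure random search); RBM oracle
checks use a 4-visible/3-hidden model where the partition function is
enumerable. These sizes are the package's own study conditions; the same
code runs larger configurations unchanged.

## Numerical conventions and edge cases

* `sigmoid()` is branch-stable: no overflow at `|x| = 1000`.
* `computeCF(0, iMax) = 1` and `computeCF(iMax, iMax) = 0` exactly;
  `0^0 = 1` applies at `I = 0`.
* Degenerate optimizer runs (`n = 1`, `d = 1`, `iMax = 0`) are defined:
  `iMax = 0` returns the best member of the initial population.
* A fitness function returning a non-finite value aborts the run with the
  offending candidate in the message — silent NaN propagation in a
  metaheuristic is very hard to debug downstream.
* Stratified splitting requires two samples per class and guarantees both
  sides non-empty per class; rounding is per class, `round(n_c * fraction)`.
* Per-class metrics with empty denominators (no predicted positives) report
  0 rather than NaN; a class absent from the truth has undefined AUC and is
  excluded from the macro AUC with a warning.
* All stochastic stages take explicit seeds, and seeded subroutines
  save/restore the caller's RNG state, so end-to-end runs are bit-identical
  per seed.

## Known limitations

* The feature extractor's random-weight mode is a stand-in for a trained
  backbone; its `trained` mode adapts only the final pointwise layer.
* CLAHE assumes 8-bit intensity semantics ([0, 255]).
* The autoencoder and DBN use plain SGD (no momentum/Adam); at desk scale
  this is sufficient and keeps the update rules transparent, but large
  configurations would train slowly.
* The MPA implementation is single-threaded by design; per-seed
  reproducibility is guaranteed, parallel fitness evaluation is not
  attempted.
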