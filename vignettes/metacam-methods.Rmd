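---
title: "Consensus CAM ensembles, ROAD evaluation, and the experiment grid"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus CAM ensembles, ROAD evaluation, and the experiment grid}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metacamr)
```

## The problem

Class activation maps (CAMs) explain a convolutional classifier's
prediction by scoring each image pixel for its contribution to a target
class. Most follow one formulation: at a chosen layer with feature maps
$A_k$, the map is $L^c = \sum_k \alpha^c_k A_k$ (usually followed by a
ReLU), and the many published variants differ only in how the channel
weights $\alpha^c_k$ — or their elementwise analogues — are derived from
gradients, perturbations, or principal components. No single variant wins
across images, target classes and models, which is the problem this package
addresses: instead of choosing one CAM, it ensembles many and keeps only
what they agree on.

## The consensus ensemble

Component maps are first min-max normalized to $[0,1]$; maps that come out
degenerate (all-zero or non-finite) for a given image/model are dropped
before any calculation. Three combination rules are provided:

* **mean** — the pixelwise average of the $n$ maps;
* **weighted** — $\sum_n w_n L_n / \sum_n w_n$, with $w_n$ derived from
  each component's own ROAD score via `weight_transform()` (min-max,
  amplified softmax, or plain softmax). Because the weights are computed on
  the very (image, class, model) triple being explained, this mode is
  evaluation-driven, and is documented as such;
* **consensus** (the default and the method's core) — the maps are summed
  and only the top-$k\%$ of summed activations are kept, all other pixels
  set to zero. A region activated by a single wayward component cannot
  survive the threshold; agreement can.

The threshold uses the linear-interpolation percentile of the flattened
pixel values, and ties at the threshold value are all kept. Both choices
make the operation deterministic and invariant to pixel traversal order;
the retained set can therefore be slightly larger than $k\%$, never
smaller. The thresholded map is renormalized to $[0,1]$ by default, since
the retained sums otherwise live on a scale that grows with $n$.

Because the best $k$ depends on the image, class and model, `metacam()`
searches a grid (default $5, 10, \ldots, 95$) and returns the map whose
ROAD score is maximal; ties resolve to the smallest $k$, i.e. the most
selective map. The search table is returned with the result, so the chosen
$k$ can always be audited against its own exhaustive evaluation. The same
search applies to a single CAM (`adaptive_threshold_search()` with one
map), which is the fair baseline to compare the ensemble against.

## ROAD scoring

Maps are compared with a pixel-perturbation faithfulness metric. For a
percentile $p$, the most relevant $p\%$ of pixels (MRP) and the least
relevant $p\%$ (LRP) are each replaced by *noisy linear imputation*: every
masked pixel is required to equal the weighted average of its
8-neighbourhood (edge neighbours $1/6$, corner neighbours $1/12$,
renormalized where neighbours are missing at borders), giving a sparse
linear system with the unmasked pixels as boundary data, solved per
channel; zero-mean Gaussian noise (default SD $0.01$ on unit-scaled
intensities) is then added to the imputed pixels. This "blurs away" the
selected region without the hard masking artefacts that leak information.
The combined score is

$$\mathrm{ROAD}(L) = \frac{1}{|P|}\sum_{p \in P}
  \frac{C^p_{LRP} - C^p_{MRP}}{2}, \qquad P = \{20, 40, 60, 80\}$$

where $C$ is the model's softmax confidence in the target class on the
perturbed image. A faithful map loses confidence when its most relevant
pixels are removed and keeps it when its least relevant pixels are removed,
so larger is better, and with probabilities as confidences the score is
bounded in $[-0.5, 0.5]$. Two conventions deserve note. First, the mean
over percentiles is used rather than the sum: for a fixed percentile set
the two differ by a constant factor and rank maps identically, but the
mean stays on one scale when the percentile set changes. Second,
"confidence" is the softmax probability rather than the raw logit:
probabilities are bounded, which keeps scores comparable across models
with different logit scales. Setting `noise_std = 0` makes scoring fully
deterministic, which the exactness tests rely on.

## The inclusion/exclusion grid and CRE

Which components should enter the ensemble is an empirical question. The
grid module groups methods by family — A: HiResCAM +
GradCAM-Elementwise, B: GradCAM + GradCAM++, C: XGradCAM, D: AblationCAM +
ScoreCAM, E: LayerCAM, F: FullGrad — and enumerates all $2^6 = 64$ binary
inclusion codes; each scorable code is run as a consensus ensemble with
adaptive thresholding. The all-zero code is enumerated for count fidelity
but is unscorable (an empty consensus is undefined) and is excluded from
scoring and from the median below; the grouping is configurable, and the
eigen methods sit outside the default grid because their per-image cost is
disproportionate in 64-experiment sweeps, though they can be added.

The **Cumulative Residual Effect** summarizes a grid: each scored
experiment's residual is its ROAD score minus the median over all scored
experiments (for an even count, the mean of the two middle values), and a
group's CRE is the sum of residuals over the experiments that include it.
Positive CRE means the group's inclusion tended to lift performance above
the median. Residuals make the statistic invariant to adding a constant to
all scores, and CREs from different images, classes or models aggregate by
group-wise summation.

## The synthetic benchmark

The package tests itself on generated data with exactly known ground
truth, built by three fixtures:

* `gen_scene()` plants a bright disc (intensity $0.8$–$1.0$, radius
  $s/8$) in one quadrant of an $s \times s$ image ($s = 64$ by default)
  over a smooth noise background in $[0.05, 0.3]$; the class label is the
  quadrant. Optionally a *decoy* — a dimmer square (intensity
  $0.45$–$0.6$) in a different quadrant, a plausible subject of another
  class — is planted too, emulating two-subject images on which
  non-discriminative CAMs highlight the wrong object. Both supports are
  recorded exactly and are disjoint by construction.
* `gen_cam_stack()` simulates component CAMs of controllable quality:
  $\mathrm{normalize}(f \cdot \mathrm{blur}(\text{mask}) + \eta \cdot
  \text{noise})$ with fidelity $f$, noise level $\eta$, and an option to
  target the decoy mask. The stack used throughout the tests — three good
  maps ($f \in [0.85, 0.95]$, $\eta \in [0.1, 0.2]$), one decoy-seeking
  map and one pure-noise map — represents a realistic mix of mostly
  reliable components with one systematically wrong and one uninformative
  member.
* `train_tiny_model()` trains the in-package CNN: two convolutions (5×5
  stride 2, then 3×3 stride 2; about 1500 parameters) over the image plus
  two fixed coordinate planes, a global-average-pooling head, Adam with
  weight decay, 400 scenes with an 80/20 split. The coordinate planes let
  channels encode absolute position, which the quadrant task requires once
  spatial information is pooled away; the GAP head is the canonical CAM
  setting, making logit gradients at the CAM layer spatially constant per
  channel exactly as on standard GAP architectures. Training reaches 100%
  held-out accuracy at the defaults in well under two minutes on one CPU
  and fails loudly below 90%.

What passing on this benchmark shows — and what it does not. The scenes
have a single bright, localized, high-contrast subject; real images have
textured objects, context correlations and multiple scales. Results here
demonstrate the *mechanics*: that consensus suppresses wrong and random
components, that adaptive thresholding picks its own argmax, that the
implemented CAMs localize a signal their model genuinely uses. They do not
certify performance on natural images, for which the adapter contract
(`model_handle()`) exists: any classifier that can expose class scores,
layer activations and gradients plugs into every method unchanged.

## Numerical choices and degenerate inputs

* Min-max normalization of a constant map returns the all-zero map (a
  valid but uninformative result) rather than dividing by zero; such maps
  are subsequently dropped by `drop_invalid()`.
* All guarded denominators use $\varepsilon = 10^{-7}$ (XGradCAM channel
  sums, AblationCAM's original score).
* The singular-vector sign in the eigen methods is fixed so the entry of
  largest magnitude is positive; without a convention the map could flip
  arbitrarily between runs of the SVD.
* ScoreCAM channel scores pass through a softmax before weighting (the
  reference convention), switchable to raw scores via `score_norm`.
* The "amplified softmax" weight transform multiplies the ROAD values by
  the smallest power of ten $s \ge 1$ with $\max_n |s \cdot v_n| \ge 10$
  before the softmax; the exponential transform is implemented as a plain
  softmax, the two differing only in that amplification step.
* A fully-masked imputation system is anchored by giving every pixel the
  channel mean as a virtual neighbour; otherwise the system matrix is
  strictly diagonally dominant at every pixel adjacent to boundary data
  and uniquely solvable.
* Bilinear resampling uses half-pixel centre alignment, so constant maps
  resample exactly to constants and a map already at target size is
  returned untouched.
* FullGrad aggregates the input-gradient term and one term per
  convolutional bias; each term is rectified by absolute value, lifted to
  image resolution and min-max normalized before summation. Dense-layer
  biases, which have no spatial extent, are omitted.
* Per-CAM weights are used only in the mean/weighted modes; consensus mode
  treats every surviving component equally, the thresholded sum carrying
  the agreement information.

## Problem sizes used in the shipped checks

The test-suite and the acceptance script run entirely on the synthetic
benchmark: imputation exactness on one hundred random instances up to
8×8 against a dense solve; recovery of planted saliency over 20 seeded
two-subject scenes with the 3-good/1-decoy/1-random stack, binarizing
supports at $k = 10$ (about twice the planted subject's 5% area, leaving
room for the blur halo); a full 64-experiment grid with a 5-point
threshold grid on one scene; and 20-scene localization checks for the
gradient CAMs. These sizes were chosen to make every quantity
recomputable from a cold start in a few minutes while keeping each
statistical margin wide (the consensus-vs-corrupted IoU comparison, for
instance, passes 20/20 with an order-of-magnitude gap at these settings).

## Known limitations

The ensemble is output-based: components are combined after the fact, with
no learned interaction between methods. ROAD-driven weighting and
threshold selection use the evaluation metric inside the method, so ROAD
comparisons between differently-tuned maps should be read with that in
mind (the adaptive baseline applies the same tuning to single CAMs for
fairness). The CLI covers only the in-package fixture classifier; real
models are used through the R adapter API. LayerCAM is implemented for a
single layer, without multi-layer fusion, and the eigen methods use only
the first principal component — on multi-subject images the appropriate
component rank is genuinely ambiguous, which is precisely the failure mode
the decoy fixtures simulate.
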