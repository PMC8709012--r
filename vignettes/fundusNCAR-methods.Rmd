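---
title: "Deep features, multilevel selection and evaluation: the methods behind fundusNCAR"
author: "fundusNCAR authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deep features, multilevel selection and evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(fundusNCAR)
```

# The problem

Eight ophthalmic conditions — AMD, cataract, diabetic retinopathy,
glaucoma, hypertensive retinopathy, pathological myopia, "other" findings
and normal eyes — leave characteristic traces in colour fundus
photographs: changes at the optic disc, in the vessel tree, at the
macula, or in the global transparency of the media.  `fundusNCAR`
implements a three-stage classification workflow for such images:

1. a **residual CNN + LSTM hybrid** is trained end-to-end with a softmax
   head and then used as a *deep-feature extractor*: the activations of
   its first fully connected layer (350 wide by default) become the
   feature vector of each image;
2. **NCAR**, a two-level filter feature selector, reduces those features:
   level 1 weighs them by neighbourhood component analysis (NCA) and
   thresholds; level 2 re-weighs the survivors by ReliefF and thresholds
   again;
3. the selected features feed a conventional classifier (RBF-SVM by
   default; DT, LD, NB and KNN are also wired in), evaluated by
   stratified 10-fold cross-validation with per-class sensitivity,
   specificity, precision, F-score and one-vs-rest AUC.

Because the original clinical dataset cannot be shipped, the package
carries a first-class synthetic-data module: labelled Gaussian feature
tables with a known informative subset, and eight-class "phantom" fundus
images with class-specific structures.  Every stage is tested against
those.

# The feature extractor

## Architecture

`modelConfig()` describes the graph; `buildModel()` materialises it with
seeded weights:

* a 3×3 convolutional stem (8 filters) with batch normalisation and ReLU;
* six blocks, each *conv → BN → ReLU → conv → BN*; in the residual
  variants the block input is added back before a final ReLU, with a 1×1
  projection (plus BN) on the skip path whenever the channel count or
  stride changes; filter counts default to 16, 16, 32, 32, 64, 64 and
  every second block downsamples with stride 2, taking a 125×125 input
  to a 16×16×64 map;
* the map is *unfolded* row-wise into a 16-step sequence (each step the
  row's width × channel activations, column index fastest) and passed
  through an LSTM with 100 units; the last hidden state summarises the
  image.  The non-LSTM variants flatten the map instead;
* a fully connected layer of width 350 (the deep features), ReLU,
  dropout (rate 0.2), and a softmax class head.

The four `variant` presets (`cnn`, `cnn_lstm`, `rcnn`, `rcnn_lstm`)
drop/keep the skip connections and the LSTM stage so that ablation
comparisons can be scripted.

Unstated details we had to fix: the filter counts, stride schedule and
downsampling pattern (the defaults above keep the parameter count modest
while making the 350-wide FC layer reachable from 125×125 inputs); the
deep features are taken *pre-ReLU* at FC1, which preserves sign
information; the LSTM contributes its final hidden state; dropout sits
between FC1 and the class head.

## Training

`trainConfig()` defaults to the reference protocol: mini-batch 128,
learning rate 0.001, up to 150 epochs, stochastic gradient descent with
momentum 0.9, cross-entropy loss.  Training, shuffling and dropout are
driven by one seed, so runs are exactly reproducible at a fixed thread
count.

The engine behind the model is written in vectorised R on top of BLAS:
convolution by shifted-slice matrix products (the padded input is kept
as an `(Hp·Wp) × (N·C)` matrix so each kernel offset is a row subset),
spatial batch normalisation with *population* (1/n) batch variance,
truncated-free backpropagation through time for the LSTM, and SGDM over
a nested parameter list.  The scalar layer formulas are implemented a
second time, independently, in `batchNormalize()`, `sigmoid()`,
`softmax()` and `lstmStep()`; the test suite requires the two routes to
agree within 1e-5 and checks the full backward pass against central
finite differences coordinate-by-coordinate.  (The only coordinates that
deviate are batch-norm scale/shift parameters, whose perturbation moves
an entire channel across the ReLU kink — there the analytic value is the
exact subgradient and the finite-difference quotient is the noisy one.)

# NCA feature weighting (level 1)

For weights $w \in \mathbb{R}^p$ define the weighted distance
$d_w(x_i, x_j) = \sum_r w_r^2\,|x_{ir} - x_{jr}|$ and the
stochastic-neighbour distribution
$p_{ij} \propto \exp(-d_w(x_i,x_j)/\sigma)$, $p_{ii}=0$.  With
$P_i = \sum_{j:\,y_j = y_i} p_{ij}$, NCA maximises the regularised
leave-one-out objective

$$F(w) \;=\; \frac1n \sum_i P_i \;-\; \lambda \sum_r w_r^2 .$$

Choices the formulation leaves open, and what we chose:

* **Distance.** The neighbour kernel and distance are not pinned down by
  the objective alone.  We use the weighted L1 form with squared
  weights, the standard choice for NCA *feature selection*: it keeps the
  effective weight non-negative and matches the $w_r^2$ penalty.
* **Kernel width.** $\sigma = 1$ after z-scoring the features
  (`standardize = TRUE` by default) makes the scale-free default
  meaningful.
* **Regularisation.** $\lambda$ defaults to $1/n$, the common heuristic;
  it is configurable because the appropriate value is data-dependent —
  large $\lambda$ provably drives all weights towards 0 (tested).
* **Optimisation.** Gradient ascent from $w = \mathbf{1}$ with
  backtracking: a step that would lower $F$ is halved (up to 30 times)
  and accepted steps gently re-grow the step size.  The recorded
  objective trace is therefore non-decreasing by construction.  The
  analytic gradient is verified against central finite differences to
  1e-6 relative error.
* **Degeneracies.** All-identical rows give uniform $p_{ij} = 1/(n-1)$
  (the zero-distance limit); a single class is refused — $P_i$ is then
  trivially maximal and the weights unidentified.

`selectByWeight()` keeps features with $w_r \ge$ threshold (default
0.0005); removal is strictly-less-than.

# ReliefF weighting (level 2)

Weights start at zero.  For each reference instance $R_i$ (all $n$ by
default — deterministic; a seeded subsample of size $m$ optionally), the
$k$ nearest same-class *hits* subtract their range-normalised
per-feature differences, and the $k$ nearest *misses* in each other
class add theirs, scaled by $P(C)\,/\,(1 - P(\mathrm{class}(R_i)))$;
all terms are divided by $m k$.  With range-normalised differences every
weight lies in $[-1, 1]$.

Unstated details we fixed: neighbour search uses Manhattan distance on
the range-normalised features (consistent with the `diff` measure);
ties are broken by the lowest instance index; the self-match is
excluded; $k$ defaults to 10 — the protocol's operating value — rather
than the alternative "classes − 1" reading, and is clipped with a
warning when a class is too small.  Classes with a single member are an
error (hits are undefined).  The implementation is required by the test
suite to agree *exactly* with a brute-force double-loop evaluation of
the update rule on dozens of random instances.

# NCAR: the two levels together

`ncarSelect()` chains the levels: NCA weights on all $p$ features,
threshold `thr1` (default 0.0005); ReliefF weights *recomputed on the
surviving columns*, threshold `thr2` (default 0.01); the final mask maps
back to original indices.  Raising either threshold can only shrink the
selection (tested as a nesting property), and an empty level-1 result is
an error advising a lower `thr1`.

Absolute thresholds are calibrated to a particular weight scale, which
is data-dependent.  The reference protocol's own operating point is
therefore also expressible by *counts* — 350 deep features reduced to 58
after level 1 and 30 after level 2, and its classifier comparisons fix
the number of selected features outright.  `ncarSelect(n1 =, n2 =)`
implements that scale-free operating point: keep the top-`n` features
per level; the recorded threshold is then the weight of the `n`-th best
feature.  The phantom experiments below use `n1 = 58, n2 = 30`.

A literal single-vector reduction variant is also provided as
`ratioReduce()`: element $i$ of a feature vector is removed iff both
`std/fea[i]` and `avg/fea[i]` exceed a threshold, with `avg` and the
population `std` computed once from the input and not updated during
the loop; zero elements make the ratios infinite and are removed for any
finite threshold.  This variant operates on one feature vector, is not
equivalent to the two-level procedure, and is kept separate for
completeness.

# Evaluation harness

`perClassMetrics()` derives one-vs-rest sensitivity, specificity,
precision and F-score from a pooled confusion matrix (truth in rows);
zero-denominator ratios are reported as `NaN` with a warning.
`macroAverage()` is the unweighted class mean.  `stratifiedCV()` deals
each class round-robin over seeded folds, z-scores features with
training-fold statistics only, pools held-out predictions, and computes
one-vs-rest AUCs (via pROC) from per-class decision scores —
class-posterior columns for DT/LD/NB, aggregated pairwise margins for
the SVM (libsvm's probability machinery is avoided because it is
internally randomised), and vote fractions from an internal KNN scorer
(`class::knn` does not expose the full score matrix).

`runPipeline()` has two modes.  `"paper"` reproduces the reference
protocol: the extractor is trained on *all* images and the selector run
once on all features, with only the final classifier cross-validated.
That protocol leaks label information from the evaluation folds into the
upstream stages, so accuracies from it are optimistic; it is the default
for fidelity, and this caveat is deliberate and loud.  `"honest"` nests
extraction and selection inside each training fold.  The test suite
checks the expected direction: on weak-signal tables with many noise
columns, honest-mode accuracy does not beat paper-mode accuracy in
expectation.

# Synthetic data: what it does and does not emulate

**Feature tables.** Class means of the informative columns sit on a
regular simplex (axes cycled when there are more informative columns
than simplex dimensions) scaled so the pairwise separation is
`effectSize × noiseSd`; all other columns are pure Gaussian noise; class
sizes are balanced within one.  This gives exact ground truth for
selector benchmarks: which columns *should* be selected is known by
construction.

**Phantom images.** Each phantom is a dark circular fundus field with a
radial shading profile, an optic disc and radiating vessels; classes add
their characteristic structure with per-image jitter: an enlarged,
cupped disc (glaucoma), global grey haze (cataract), scattered bright
exudate-like and dark haemorrhage-like spots (diabetes), many highly
tortuous vessels (hypertension), a macular drusen cluster (AMD), a
peripapillary atrophy crescent with a tilted disc (pathological myopia),
a ring of scar-like dots (other), and none (normal).  Images are RGB in
[0, 1], written as lossless PNG, and pixel-reproducible: one master seed
feeds independent per-stream generators, so adding a stream never
perturbs existing fixtures.

These phantoms make the classes machine-separable through coarse,
localised cues.  They do **not** emulate real fundus photography —
camera vignetting and colour profiles, anatomical variability, lesion
morphology, label noise or class imbalance (the clinical dataset is
heavily imbalanced; the phantoms are balanced).  A passing phantom
pipeline demonstrates that the code trains, extracts, selects and
evaluates correctly — not that the architecture would reach any
particular accuracy on clinical data.

# Problem sizes and numerical choices in the shipped tests

The test and acceptance runs use sizes chosen to exercise every code
path at desk scale: the end-to-end run trains the scaled-down extractor
(2 blocks of 16 filters, 32 LSTM units, 350 deep features) on 320
phantoms of 32×32 for 30 epochs with learning rate 0.01 — at this data
and iteration budget the reference learning rate of 0.001 is
unnecessarily conservative, and 0.01 reaches a fitted training set
within the epoch budget.  Selector benchmarks use tables of n = 500,
p = 40 with 8 informative columns at effect size 3, and n = 200 for the
weight-ordering properties.  The default 125-pixel, 6-block, 100-unit
architecture is exercised for construction and single-image feature
extraction.  All stochastic checks fix their seeds.

Other numerical choices: batch-norm uses the population (1/n) variance,
matching the printed formula, with ε = 1e-5 and running statistics
(momentum 0.9) for inference; the LSTM forget-gate bias is initialised
to 1 (standard practice for gradient flow); convolution weights use He
initialisation; `max.col` tie-breaking is pinned to `"first"` everywhere
so evaluation is deterministic; the printed per-class table of the
reference results reproduces its F-scores from the printed
sensitivity/precision pairs only within one unit in the fourth decimal,
consistent with those inputs themselves being rounded — the acceptance
machinery asserts agreement at that resolution rather than bit equality.

# Known limitations

* Pure-R training is CPU-bound; the default 125-pixel/6-block model is
  practical for feature extraction and small studies, not for
  ImageNet-scale training.
* NCA is fitted by full-batch ascent; its O(n²p) memory/time means
  n in the low thousands is the comfortable range.
* ReliefF supports numeric features only (deep features are numeric);
  nominal/missing-value `diff` variants are out of scope.
* The `"paper"` evaluation mode is intentionally faithful to a leaky
  protocol; use `"honest"` mode for unbiased generalisation estimates.
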