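# fundusNCAR

Deep-feature extraction with a residual CNN+LSTM hybrid, multilevel
NCA/ReliefF feature selection (NCAR), and a cross-validated classifier
evaluation harness for ophthalmic (fundus) image classification — with
synthetic phantom data so the whole workflow is testable end to end
without any external dataset.

## Who this is for

Researchers studying automated detection of ophthalmic disease from
colour fundus photographs (AMD, cataract, diabetic retinopathy,
glaucoma, hypertensive retinopathy, pathological myopia, other findings,
normal), and more generally anyone who wants a self-contained, seeded R
implementation of the *deep features → filter feature selection →
classical classifier* pattern with honest evaluation tooling.

## What it computes

**Feature extractor.** A residual CNN with six conv–BN–ReLU–conv–BN
blocks (skip connections, stride-2 downsampling every second block)
whose final activation map is unfolded row-wise into a sequence and
summarised by an LSTM with 100 units; the activations of the first fully
connected layer (width 350) are the deep features. Trained end-to-end
with SGDM (batch 128, learning rate 0.001, up to 150 epochs) and
cross-entropy. Ablation variants (`cnn`, `cnn_lstm`, `rcnn`,
`rcnn_lstm`) toggle the skip connections and the LSTM stage. The network
engine (convolution, batch normalisation, LSTM backpropagation through
time) is implemented in vectorised R over BLAS and is verified in the
test suite against independent scalar reference layers and against
finite-difference gradients.

**NCAR selection.** Level 1 fits neighbourhood component analysis
feature weights by maximising

    F(w) = (1/n) Σ_i P_i − λ Σ_r w_r²,

where `P_i` is the probability that a stochastic nearest neighbour of
sample *i* under the weighted distance
`d_w(x_i, x_j) = Σ_r w_r² |x_ir − x_jr|` shares its class; weights below
a threshold (default 0.0005) are dropped. Level 2 recomputes ReliefF
importance weights on the survivors —

    W(a) ← W(a) − Σ_j diff(a, R_i, H_j)/(mk)
               + Σ_{C≠class(R_i)} P(C)/(1−P(class(R_i))) Σ_j diff(a, R_i, M_j)/(mk)

— and drops importances below a second threshold (default 0.01). A
scale-free, count-based operating point (`n1 = 58`, `n2 = 30`, the
reference protocol's own survivor counts) is also available.

**Evaluation.** Stratified 10-fold cross-validation over SVM (RBF), DT,
LD, NB and KNN, with pooled confusion matrices, per-class one-vs-rest
sensitivity/specificity/precision/F-score, macro averages and
one-vs-rest AUCs. `runPipeline()` chains extract → select → classify in
either the reference (`"paper"`, selection outside the CV) or the
leakage-free (`"honest"`, everything nested in the folds) protocol.

**Synthetic data.** `generateFeatureTable()` plants class signal on a
simplex in a known informative subset; `generatePhantomImages()` renders
eight-class fundus-like phantoms (optic disc, vessels, class-specific
lesions/haze/tortuosity) that are pixel-reproducible under a seed.

## Worked example

```r
library(fundusNCAR)

tab <- generateFeatureTable(synthTableSpec(
  nSamples = 300, nFeatures = 20, nInformative = 4,
  nClasses = 3, effectSize = 3, seed = 42))

sel <- ncarSelect(tab$X, tab$y, ncaConfig(maxIters = 50), relieffConfig())
sel
#> SelectionResult: 5 / 20 features kept (thr1 0.0005 -> 20, thr2 0.01)
selectedFeatures(sel)
#> [1]  1  2  3  4 13

rep <- stratifiedCV(tab$X[, keepMask(sel)], tab$y,
                    classifierSpec("SVM"), k = 10, seed = 1)
rep
#> MetricsReport: 3 classes, 300 samples, accuracy 0.8633
#>   macro sens 0.8633 spec 0.9317 prec 0.8646 F 0.8635, macro AUC 0.9593
```

The table plants its class signal in features 1–4; NCAR recovers all
four (feature 13 is a false positive at these thresholds) and the
selected 5-of-20 subset supports 86% cross-validated accuracy on a
3-class problem whose Bayes accuracy is well below 100% at effect size 3.
The full image pipeline is one call:

```r
ph <- generatePhantomImages(synthImageSpec(nPerClass = 40, imageSize = 32,
                                           seed = 1))
res <- runPipeline(images = ph$images, labels = ph$labels,
                   modelCfg = modelConfig(nResidualBlocks = 2,
                     stemFilters = 8, blockFilters = c(16L, 16L),
                     lstmUnits = 32L, fc1Width = 350L, nClasses = 8,
                     inputSize = 32L),
                   trainCfg = trainConfig(batchSize = 64,
                     learningRate = 0.01, maxEpochs = 30, seed = 1),
                   n1 = 58, n2 = 30, seed = 1)
accuracy(res$metrics)     # cross-validated accuracy on 30/350 features
```

A command-line wrapper with `synth-gen`, `train`, `extract`, `select`,
`evaluate` and `run-all` subcommands is installed at
`inst/scripts/fundus-ncar` (YAML config plus `--flag value` overrides;
every run writes a parameter log).

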