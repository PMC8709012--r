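fundusNCAR 0.1.0 | command: frobnicate | 2026-09-19 07:51:56
R version: R version 4.3.3 (2024-02-29)
  seed = 1
  out = .
  type = images
  nPerClass = 10
  imageSize = 125
  classes = AMD,Cataract,Diabetes,Glaucoma,Hypertension,Normal,Other,PM
  nSamples = 200
  nFeatures = 20
  nInformative = 4
  nClasses = 2
  effectSize = 3
  noiseSd = 1
  blocks = 6
  stemFilters = 8
  blockFilters = 16,16,32,32,64,64
  lstmUnits = 100
  fc1 = 350
  dropout = 0.2
  variant = rcnn_lstm
  batch = 128
  lr = 0.001
  epochs = 150
  momentum = 0.9
  thr1 = 5e-04
  thr2 = 0.01
  lambda = NA
  kNeighbors = 10
  classifier = SVM
  folds = 10
  mode = paper
  images = NA
  features = NA
  model = NA
  mask = NA
  config = NA
  log = NA
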