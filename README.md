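# RNALocNet

Sequence-based prediction of RNA subcellular localization in R.

Where an RNA resides — nucleus, cytoplasm, exosome, cytosol, ribosome,
membrane, ER — constrains what it can do, and for long noncoding RNAs the
compartment is often the best available clue to function. RNALocNet
implements a deep sequence classifier for this task that accepts
transcripts of *any* length (no padding, no truncation) and deals with the
strong class imbalance of curated localization data. It is aimed at
computational biologists who want a self-contained, inspectable
implementation: every layer, loss and metric is in the package, tested
against brute-force oracles and numerical gradients.

## The model

A sequence of length *L* is encoded per nucleotide as an *L* × 8 matrix:
one-hot (A/T/C/G), the electron-ion interaction pseudopotential
(A 0.1260, T 0.1335, C 0.1340, G 0.0806), and the nucleotide chemical
property triple (ring structure, functional group, hydrogen bonding).
The network is then

1. **CM encoder** — two parallel branches (conv kernels 3 and 5), each
   three stages of valid 1D convolution → ReLU → *adaptive* max pooling
   (64, 64, 32 filters; pooled to 512, 256, 128 positions), mapping any
   *L* to a fixed 128 × 32 feature map per branch;
2. **Long-short term attention + Bi-LSTM** — 6-head attention whose keys
   combine a short-term window (128) with *r* = 4 dynamically projected
   long-range summary rows (column-softmax projection, dual layer
   normalization), fused per position with a 16-hidden bidirectional
   LSTM into 128 × 64;
3. **TextCNN head** — parallel convolutions of width 1/3/5 with global
   max pooling (192 features per branch), concatenated across branches
   and classified by one fully connected layer: softmax over the five
   lncRNA compartments, or sigmoid for multi-label mRNA mode.

Training minimizes a focal loss, −α(1−p)^γ log p with γ = 2 (multi-class),
or its per-class-weighted multi-label generalization, with AdamW.
Evaluation reports ACC, macro precision/recall/F1, macro MCC, micro/macro
AUROC and micro AUPRC. A synthetic-data module generates motif-planted,
length- and imbalance-realistic benchmarks so the whole pipeline runs
without any external data, and an occlusion module attributes predictions
to sequence positions.

## Worked example

```r
library(RNALocNet)

## a synthetic 5-class benchmark: distinct motifs planted at p = 0.95
spec <- learnableSyntheticSpec(nPerClass = 30, lengthRange = c(200, 600),
                               seed = 11)
ds <- generateLocDataset(spec)
ds
#> LocDataset with 150 sequences (single-label, 5 classes)
#>   lengths: 200-596 nt (median 390)
#>   classes: Nucleus=30, Exosome=30, Cytoplasm=30, Cytosol=30, Ribosome=30

fold <- stratifiedFolds(labels(ds), k = 5, seed = 1)
cfg <- locNetConfig(cm = list(dropout = 0), lsta = list(dropout = 0),
                    bilstm = list(dropout = 0), textcnn = list(dropout = 0),
                    train = list(lr = 1e-3, batch_size = 8, epochs = 10,
                                 seed = 1))
model <- trainLocModel(ds[fold != 1], ds[fold == 1], config = cfg)
model
#> LocModel (single-label, 5 classes: Nucleus, Exosome, Cytoplasm, Cytosol, Ribosome)
#>   151813 parameters; CM kernels 3/5; interface 128x32
#>   trained 10 epochs (best valid maF1 0.283)

probs <- predictProbs(model, ds[fold == 1])
computeMetrics(probs, as.integer(labels(ds[fold == 1])), classNames(ds))
#> ACC 0.3667 | maP 0.2556 | maR 0.3667 | maF1 0.2833 | MCC 0.1976
#> miAUC 0.7361 | maAUC 0.6861 | miAUPRC 0.5155
```

The ranking metrics (miAUC 0.74) show real signal after only ten epochs
at this small size, but hard-class separation needs far longer schedules
— the methods vignette (`vignettes/localization-methods.Rmd`) analyses
why: the repeat motifs (poly-T, AC-repeat) are learned quickly while
single-occurrence motifs require the convolution filters to be sculpted
over many hundreds of epochs.

Occlusion attribution for one held-out sequence:

```r
id <- names(sequences(ds))[fold == 1][1]
tr <- occlusionAttribution(model, sequences(ds)[[id]], window = 15,
                           stride = 5, id = id)
attributionBed(tr, n = 3)   # top windows, BED-like 0-based intervals
```

A thin command-line wrapper (`inst/scripts/rnalocnet`) exposes
`generate`, `train`, `cv`, `gridsearch`, `predict`, `evaluate` and
`attribute` subcommands over the same functions.

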