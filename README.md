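# geneTexture

Fixed-length discriminant feature vectors for DNA sequences, built from
nucleotide co-occurrence matrices with GLCM-style texture statistics, and
a weighted-metric classification protocol for labeled sequence sets such
as per-species essential-gene collections.

## What it computes

For a sequence *S* over {A, C, T, G}, eight co-occurrence matrices
(named I..P) are counted: cell (r, s) of a matrix tallies the positions
where row pattern *r* — one of a fixed inventory of 1-, 2- and
3-base patterns — occurs immediately followed by column base *s*,
with overlapping scan. Each matrix is normalized by its grand total and
summarised by five texture statistics (0-based indices r, s):

- energy Σ G′(r,s)²
- entropy −Σ G′(r,s) ln G′(r,s)
- homogeneity Σ G′(r,s)/(1+(r−s)²)
- contrast Σ G′(r,s)(r−s)²
- dissimilarity Σ G′(r,s)|r−s|

Concatenated over the eight matrices this gives the 40-dimensional
vector f1..f40. Four classical estimators on the purine/pyrimidine
encoding (A,G→1; C,T→0) optionally extend it to 44 dimensions: Shannon
entropy (SE), modified Shannon entropy (MSE), single-scale rescaled-range
Hurst exponent (HE), and an indicator-matrix fractal dimension (FD)
computed deterministically via exact submatrix expectations.

Labeled sets are classified with KNN, a decision tree or an SVM under
five repeated stratified 50/50 splits (or five-fold CV), optionally after
explained-variance PCA, and scored with class-size-weighted one-vs-rest
accuracy, precision, recall and F1. A Markov-chain generator provides a
three-class synthetic benchmark so the whole pipeline is testable without
any external download.

## Worked example

```r
library(geneTexture)

g  <- generateMarkovSequences(defaultBenchmarkSpecs(), seed = 42)
se <- assembleFeatures(g$sequences, g$labels$label)   # 40 x 450

round(coocFeatureVector(as.character(g$sequences[[1]]))[1:10], 4)
#>     f1     f2     f3     f4     f5     f6     f7     f8     f9    f10
#> 0.0959 2.5461 0.7102 1.4654 0.7272 0.0981 2.5323 0.7154 1.4547 0.7167

evaluateProtocol(se, "svm", seed = 42)
#> EvalReport: svm, repeated-split (5 splits), seed 42
#>   dimension 40, scaling on
#>   weighted: accuracy 99.64  precision 99.48  recall 99.47  F1 99.47
```

f1..f5 are the energy, entropy, homogeneity, contrast and dissimilarity
of matrix I (adjacent base pairs); f6..f10 the same for matrix J, and so
on. The weighted F1 near 100 shows the SVM recovering the three Markov
classes, whose signal lives exactly in the low-order transition structure
the features measure; permuting the labels collapses F1 to the
no-information level (~31 on this benchmark).

The classical estimators work standalone:

```r
b <- encodeBinary(as.character(g$sequences[[1]]))
shannonEntropy(b)                      # ~1 (balanced purine content)
hurstExponent(b)                       # 0.6527
fractalDimension(as.character(g$sequences[[1]]))   # -1.7545
```

A thin command-line front end (`inst/scripts/genetexture.R`) exposes the
same pipeline as `synth`, `featurize` and `classify` subcommands over
FASTA + label-TSV files and CSV feature tables.

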