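---
title: "Co-occurrence texture features for DNA sequence classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Co-occurrence texture features for DNA sequence classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(geneTexture)
```

## The model

geneTexture represents a DNA sequence over the alphabet A, C, T, G by a
fixed-length vector of texture statistics computed from eight nucleotide
co-occurrence matrices, in the spirit of the gray-level co-occurrence
matrices (GLCM) used in image texture analysis. The row patterns of the
eight matrices are fixed:

| Matrix | Row patterns (q rows) |
|---|---|
| I | A, C, T, G |
| J | AA, CC, TT, GG |
| K | AC, AT, AG, CT, CG, TG |
| L | CA, TA, GA, TC, GC, GT |
| M | ACT, ACG, ATG, CTG |
| N | CAT, CAG, TAG, TCG |
| O | ATC, AGC, AGT, CGT |
| P | TCA, GCA, GTA, GTC |

Each matrix has four columns (A, C, T, G). Cell $(r, s)$ of a matrix
counts the positions $i \le L - m$ at which the sequence carries row
pattern $r$ (of length $m$) followed immediately by base $s$, scanning
every position with step 1 so that occurrences overlap. This is the 1-D
specialisation of the GLCM offset: the "neighbouring pixel" is the base
immediately after the pattern. For matrix I the grand total is therefore
exactly $L - 1$, the number of adjacent base pairs.

Each count matrix $G$ is normalized by its grand total to $G'$ and
summarised by five statistics, with $r, s$ the 0-based row and column
indices:

* energy $\sum G'(r,s)^2$,
* entropy $-\sum G'(r,s)\,\ln G'(r,s)$ (natural log, $0 \ln 0 = 0$),
* homogeneity $\sum G'(r,s) / (1 + (r-s)^2)$,
* contrast $\sum G'(r,s)\,(r-s)^2$,
* dissimilarity $\sum G'(r,s)\,|r-s|$.

The per-sequence feature vector concatenates the five statistics of the
eight matrices in the order I, J, K, L, M, N, O, P — 40 features,
named `f1`..`f40`.

For the 6-row matrices K and L the symmetric summation bounds of the
classical GLCM formulas are dimensionally inconsistent; the sums here run
over all cells of the $q \times 4$ matrix, with $(r - s)$ taken on the
integer indices. Matrices with grand total zero (sequences shorter than
$m + 1$, or row patterns absent) are kept as all-zero normalized matrices
with all five statistics defined as 0, so vectors stay total and
fixed-length rather than propagating NaN.

## Classical estimators

Four estimators on the purine/pyrimidine encoding (A, G $\to$ 1;
C, T $\to$ 0) optionally extend the vector to 44 features:

**Shannon entropy (SE).** $-\sum_{i \in \{0,1\}} p_i \log_2 p_i$ of the
empirical bit frequencies; 0 for a constant sequence, 1 for a balanced
one.

**Modified Shannon entropy (MSE).** A word-based entropy
$-\sum_j w_j \log_2 w_j$ in which the word inventory is tied to the
longest run $\ell^*$ of identical bits. The construction admits two
defensible readings, both implemented: in `"window"` mode (the default)
the words are the overlapping $\ell^*$-length windows of the bit string;
in `"runs"` mode the words are the maximal runs themselves. The chosen
mode is recorded in the assembly metadata. The window reading was made
the default because it always produces a well-populated word inventory
(every position contributes), whereas the run reading can concentrate
mass on few run types for strongly persistent sequences.

**Hurst exponent (HE).** The single-scale rescaled-range estimate: with
$m$ the mean bit, $X_t = \sum_{i \le t}(D_i - m)$,
$R_n = \max X - \min X$ and $S_n$ the population standard deviation
(divisor $n$), the estimate solves $R_n / S_n = (n/2)^{HE}$, i.e.
$HE = \log(R_n/S_n) / \log(n/2)$. No multi-window log–log regression is
performed — the estimator is the literal single-scale solution — so it
carries the well-known finite-$n$ upward bias of R/S analysis: on iid
balanced coin flips of length $2^{16}$ the mean estimate sits near 0.55
rather than the asymptotic 0.5. The test suite asserts the mean over 200
such draws inside [0.45, 0.62], documenting rather than correcting the
bias (corrected estimators such as Anis–Lloyd are deliberately out of
scope). A constant bit sequence has $S_n = 0$ and raises an error rather
than returning a silent number; at assembly time such failures are imputed
with the column mean and flagged.

**Fractal dimension (FD).** The sequence is mapped to its $N \times N$
indicator matrix ($1$ where two positions carry the same base — the
sequence's dot-plot against itself), and
$FD = -\frac{1}{N}\sum_{n=2}^{N} \log \sigma(n) / \log n$ where
$\sigma(n)$ is the average number of 1s in an $n \times n$ submatrix.
Instead of sampling submatrix positions at random, $\sigma(n)$ is
computed exactly as the mean over all $(N-n+1)^2$ contiguous placements —
the expectation of the sampling procedure — via two-level 2-D prefix
sums, which keeps the whole profile $O(N^2)$ and makes FD fully
deterministic. With this sign convention FD is negative (e.g. $-1.5$
for a mononucleotide sequence of length 4); the literal value is kept
since only the feature's discriminative content matters. Long sequences
are truncated to the first `cap` bases (default 1000) before the
$O(N^2)$ matrix is built; the cap is recorded in the assembly metadata.

## Classification protocol

`assembleFeatures()` returns a `SummarizedExperiment` (features as rows,
sequences as columns, labels in `colData`). `evaluateProtocol()` then
runs, by default, **five repetitions of a stratified 50/50 train/test
split**, reporting the mean over repetitions; a stratified five-fold
cross-validation mode (`"cv5"`) is also provided. The repeated-split
default reads the protocol of "split in half, then five-fold, average
over test data" as five independent halvings; both interpretations are
recorded verbatim in the report so results are never ambiguous.

Within each split, all data-dependent preprocessing is fit on the
training half only: the z-score scaler (on by default, since KNN and SVM
are scale-sensitive; zero-variance columns map to 0), any missing-value
imputation (training-column means) and the optional PCA. PCA retains the
smallest number of components whose cumulative explained-variance ratio
reaches the `pcaVariation` threshold, and reports the eigenvalue
spectrum; the retained dimension is non-decreasing in the threshold by
construction.

Three classifiers are exposed with fixed, configurable defaults chosen
as the standard textbook settings: KNN with $k = 5$ and Euclidean
distance, a CART decision tree with Gini splits (rpart), and an SVM with
RBF kernel and cost 1 (e1071/libsvm). Multiclass SVM uses libsvm's
native pairwise (one-vs-one) coupling, the same convention as
scikit-learn's SVC. Classifier internals are deliberately not
re-implemented. One master seed governs every split and tie-break and is
recorded in the report.

Performance is scored with class-size-weighted one-vs-rest metrics: from
a single multiclass prediction, per-class TP/TN/FP/FN are formed
one-vs-rest and accuracy, precision, recall and F1 are averaged with
weights $n_i / \sum n_i$. Note two non-standard consequences, both kept
deliberately: the weighted accuracy includes true negatives and so
upper-bounds plain multiclass accuracy, and the weighted recall equals
plain multiclass accuracy exactly. A class never predicted has its
precision (and hence F1) defined as 0. Weighted metrics are the right
headline for species sets with strong class imbalance.

## The synthetic benchmark

`defaultBenchmarkSpecs()` defines three classes of order-2 Markov chains
over A, C, T, G. Every transition row places probability 0.55 on one
favoured base and 0.15 on each other base; the favoured base is what
distinguishes the classes — repeat the last base ("rep"), move to its
cyclic successor ("cyc"), or return to the first base of the
conditioning pair ("ret"). Any two classes differ on at least 12 of the
16 conditioning pairs, giving a mean row-wise total-variation distance
of at least 0.3. Order-2 chains were chosen because the co-occurrence
features are $(m+1)$-mer statistics with $m \le 3$: the classes differ
exactly in the low-order transition structure the features measure, so
the benchmark is a genuine parameter-recovery experiment, not a
tautology. The default set draws 150 sequences per class with lengths
uniform on 300–3000 (mirroring the scale of curated essential-gene
sets); an imbalanced preset (150/50/25) exercises the weighted metrics,
and a null preset (three identical iid-uniform classes) provides the
negative control. Generation is vectorised across sequences and exactly
reproducible from a single seed.

What the benchmark does *not* emulate: codon structure, GC-content
gradients, repeats, or any biological signal beyond low-order transition
frequencies. A high weighted F1 on the benchmark therefore shows that
the pipeline recovers low-order compositional class structure — the
signal the features are designed for — and nothing more; performance on
real essential-gene sets depends on how much of their species signal
lives in that structure.

## Numerical choices and limitations

* Entropy uses the natural log for the texture statistic and base-2 for
  SE/MSE, matching the respective conventions; $0 \log 0 = 0$
  throughout.
* Co-occurrence counting is overlapping and strictly forward (pattern
  followed by base); no symmetric accumulation or additional offsets.
* The Hurst estimator requires length $> 2$ (the scale factor
  $\log(n/2)$ vanishes at $n = 2$) and non-constant bits.
* Test problem sizes: oracle equivalence uses 200 random sequences of
  length 5–500; the recovery experiment uses the default 450-sequence
  benchmark; the Hurst Monte-Carlo uses 200 draws of length $2^{16}$.
* The 44-feature path is computed per sequence in pure R; for very large
  collections the fractal-dimension cap dominates runtime and can be
  lowered.
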