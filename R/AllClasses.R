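#' @include geneTexture-package.R
NULL

## Single-base column alphabet shared by every co-occurrence matrix and by
## the Markov generator. The T-before-G order follows the field convention
## for these matrices (columns A, C, T, G).
BASES <- c("A", "C", "T", "G")

#' BinarySequence: purine/pyrimidine encoding of a DNA sequence
#'
#' Holds the 0/1 encoding of a nucleotide sequence (purines A,G as 1;
#' pyrimidines C,T as 0) together with its identifier. The empirical symbol
#' frequencies are available through [p0()] and [p1()].
#'
#' @slot id character(1) record identifier.
#' @slot bits integer vector of 0s and 1s, one per base.
#'
#' @seealso [encodeBinary()], [shannonEntropy()], [hurstExponent()]
#' @exportClass BinarySequence
setClass("BinarySequence",
  representation(id = "character", bits = "integer"),
  validity = function(object) {
    msg <- NULL
    if (length(object@bits) < 1L)
      msg <- c(msg, "bits must have length >= 1")
    if (length(object@bits) && !all(object@bits %in% c(0L, 1L)))
      msg <- c(msg, "bits must be 0 or 1")
    if (length(object@id) != 1L)
      msg <- c(msg, "id must be a single string")
    if (is.null(msg)) TRUE else msg
  }
)

#' CoocMatrix: one nucleotide co-occurrence matrix
#'
#' A q x 4 count matrix for one of the eight pattern sets I..P: cell (r, s)
#' counts the positions where row pattern r occurs immediately followed by
#' column base s. The normalized form divides by the grand total (all-zero
#' when the grand total is zero).
#'
#' @slot patternSet character(1), one of "I".."P".
#' @slot counts q x 4 integer matrix, rows named by pattern, columns A,C,T,G.
#' @slot normalized q x 4 numeric matrix summing to 1 (or all zero).
#'
#' @seealso [countCooc()], [textureFeatures()], [coocPatternSets()]
#' @exportClass CoocMatrix
setClass("CoocMatrix",
  representation(patternSet = "character", counts = "matrix",
                 normalized = "matrix"),
  validity = function(object) {
    msg <- NULL
    if (length(object@patternSet) != 1L || !nzchar(object@patternSet))
      msg <- c(msg, "patternSet must be a single non-empty name")
    if (ncol(object@counts) != 4L || ncol(object@normalized) != 4L)
      msg <- c(msg, "counts and normalized must have 4 columns (A,C,T,G)")
    if (any(object@counts < 0))
      msg <- c(msg, "counts must be non-negative")
    tot <- sum(object@normalized)
    if (!(abs(tot) < 1e-9 || abs(tot - 1) < 1e-9))
      msg <- c(msg, "normalized must sum to 0 or 1")
    if (is.null(msg)) TRUE else msg
  }
)

#' EvalReport: classification protocol results
#'
#' Per-class one-vs-rest confusion counts (averaged over splits/folds) and
#' class-size-weighted accuracy, precision, recall and F1 in percent,
#' together with the full protocol metadata needed to reproduce the run.
#'
#' @slot classifier character(1): "knn", "dt" or "svm".
#' @slot protocol character(1): "repeated-split" or "cv5".
#' @slot seed integer(1) master seed.
#' @slot metrics named numeric: accuracy, precision, recall, f1 (percent).
#' @slot perClass data.frame with columns class, TP, TN, FP, FN, n
#'   (mean counts per split/fold).
#' @slot dimension integer(1) feature dimension seen by the classifier.
#' @slot pcaVariation numeric(1) explained-variance threshold, or NA.
#' @slot scaled logical(1) whether z-score standardization was applied.
#' @slot repeats integer(1) number of splits or folds averaged.
#'
#' @seealso [evaluateProtocol()], [weightedMetrics()]
#' @exportClass EvalReport
setClass("EvalReport",
  representation(classifier = "character", protocol = "character",
                 seed = "integer", metrics = "numeric",
                 perClass = "data.frame", dimension = "integer",
                 pcaVariation = "numeric", scaled = "logical",
                 repeats = "integer"),
  validity = function(object) {
    msg <- NULL
    need <- c("accuracy", "precision", "recall", "f1")
    if (!all(need %in% names(object@metrics)))
      msg <- c(msg, "metrics must contain accuracy, precision, recall, f1")
    else if (any(object@metrics[need] < -1e-9 | object@metrics[need] > 100 + 1e-9))
      msg <- c(msg, "metrics must lie in [0, 100]")
    if (is.null(msg)) TRUE else msg
  }
)

#' MarkovClassSpec: one synthetic sequence class
#'
#' Describes a class of synthetic DNA sequences drawn from an order-1 or
#' order-2 Markov chain over A,C,T,G: the first `order` bases are drawn iid
#' from `init`, and each later base from the transition row indexed by the
#' preceding `order`-mer.
#'
#' @slot classLabel character(1) class label.
#' @slot order integer(1), 1 or 2.
#' @slot init numeric(4) initial base distribution (A,C,T,G), sums to 1.
#' @slot transition stochastic matrix, 4 x 4 (order 1) or 16 x 4 (order 2);
#'   rows named by the conditioning k-mer, columns A,C,T,G.
#' @slot nSequences integer(1) number of sequences to draw.
#' @slot lengthRange integer(2) inclusive min/max sequence length.
#'
#' @seealso [markovClassSpec()], [generateMarkovSequences()],
#'   [defaultBenchmarkSpecs()]
#' @exportClass MarkovClassSpec
setClass("MarkovClassSpec",
  representation(classLabel = "character", order = "integer",
                 init = "numeric", transition = "matrix",
                 nSequences = "integer", lengthRange = "integer"),
  validity = function(object) {
    msg <- NULL
    if (!object@order %in% c(1L, 2L))
      msg <- c(msg, "order must be 1 or 2")
    if (length(object@init) != 4L || any(object@init < 0) ||
        abs(sum(object@init) - 1) > 1e-12)
      msg <- c(msg, "init must be 4 non-negative probabilities summing to 1")
    nStates <- 4L^object@order
    if (nrow(object@transition) != nStates || ncol(object@transition) != 4L)
      msg <- c(msg, sprintf("transition must be %d x 4", nStates))
    else {
      if (any(object@transition < 0))
        msg <- c(msg, "transition probabilities must be non-negative")
      if (any(abs(rowSums(object@transition) - 1) > 1e-12))
        msg <- c(msg, "every transition row must sum to 1")
    }
    if (object@nSequences < 1L)
      msg <- c(msg, "nSequences must be >= 1")
    if (length(object@lengthRange) != 2L ||
        object@lengthRange[1] > object@lengthRange[2] ||
        object@lengthRange[1] < 1L)
      msg <- c(msg, "lengthRange must be (min, max) with 1 <= min <= max")
    if (is.null(msg)) TRUE else msg
  }
)
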