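#' @include cooc.R classic.R
NULL

#' Assemble a labeled feature matrix from sequences
#'
#' Computes the 40-dimensional co-occurrence feature vector for every
#' sequence and, optionally, appends the four classical estimators
#' (SE, HE, MSE, FD) computed on the purine/pyrimidine encoding. The result
#' is a \code{SummarizedExperiment} with features as rows and sequences as
#' columns, the class label in \code{colData} and the computation
#' parameters in \code{metadata}.
#'
#' A sequence with constant purine/pyrimidine composition has an undefined
#' Hurst exponent; such entries are imputed with the column mean of the
#' remaining sequences and flagged in \code{colData()$heImputed}. If every
#' sequence fails, assembly errors.
#'
#' @param seqs A [Biostrings::DNAStringSet] (or named character vector) of
#'   A/C/G/T sequences.
#' @param labels Class label per sequence, or NULL for an unlabeled set.
#'   When supplied, at least two distinct classes are required.
#' @param includeClassic If TRUE append SE, HE, MSE, FD rows (44 features).
#' @param mseMode Word model for the modified Shannon entropy
#'   ([modifiedShannonEntropy()]): `"window"` or `"runs"`.
#' @param fdCap Indicator-matrix cap for [fractalDimension()].
#' @return A \code{SummarizedExperiment}; assay `"features"` is a
#'   (40 or 44) x n numeric matrix with rownames f1..f40[, SE, HE, MSE, FD].
#' @examples
#' seqs <- Biostrings::DNAStringSet(c(a1 = "ACGTACGTAC", b1 = "AAAACCCCGG",
#'                                    a2 = "ACGTTGCAAC", b2 = "AAAAGGGGCC"))
#' se <- assembleFeatures(seqs, labels = c("a", "b", "a", "b"))
#' dim(se)  # 40 x 4
#' @export
assembleFeatures <- function(seqs, labels = NULL, includeClassic = FALSE,
                             mseMode = c("window", "runs"), fdCap = 1000L) {
  mseMode <- match.arg(mseMode)
  if (is.character(seqs)) seqs <- DNAStringSet(seqs)
  n <- length(seqs)
  if (n < 1L) stop("no sequences supplied")
  ids <- names(seqs)
  if (is.null(ids)) ids <- paste0("seq", seq_len(n))
  if (!is.null(labels)) {
    labels <- as.character(labels)
    if (length(labels) != n)
      stop("labels must match the number of sequences")
    if (length(unique(labels)) < 2L)
      stop("at least 2 classes required (got ",
           length(unique(labels)), ")")
  }
  strs <- as.character(seqs)
  feat <- suppressWarnings(vapply(strs, coocFeatureVector, numeric(40)))
  rownames(feat) <- paste0("f", seq_len(40))
  heImputed <- logical(n)
  if (includeClassic) {
    classic <- vapply(strs, function(s) {
      b <- encodeBinary(s)
      he <- tryCatch(hurstExponent(b), error = function(e) NA_real_)
      c(SE = shannonEntropy(b),
        HE = he,
        MSE = modifiedShannonEntropy(b, mode = mseMode),
        FD = fractalDimension(s, cap = fdCap))
    }, numeric(4))
    heImputed <- is.na(classic["HE", ])
    if (all(heImputed))
      stop("Hurst exponent failed for every sequence; cannot impute")
    if (any(heImputed)) {
      classic["HE", heImputed] <- mean(classic["HE", !heImputed])
      warning(sprintf("imputed Hurst exponent for %d sequence(s)",
                      sum(heImputed)))
    }
    feat <- rbind(feat, classic)
  }
  colnames(feat) <- ids
  cd <- DataFrame(row.names = ids)
  if (!is.null(labels)) cd$label <- labels
  if (includeClassic) cd$heImputed <- heImputed
  se <- SummarizedExperiment(
    assays = list(features = feat),
    colData = cd,
    metadata = list(includeClassic = includeClassic,
                    mseMode = if (includeClassic) mseMode else NA_character_,
                    fdCap = if (includeClassic) as.integer(fdCap) else NA_integer_)
  )
  se
}

#' Extract the sample-by-feature matrix and labels from an assembled set
#'
#' @param se SummarizedExperiment from [assembleFeatures()].
#' @return list(x = n x d numeric matrix, y = factor of labels or NULL,
#'   ids = character).
#' @export
featureMatrix <- function(se) {
  x <- t(assay(se, "features"))
  y <- if ("label" %in% colnames(colData(se)))
    factor(colData(se)$label) else NULL
  list(x = x, y = y, ids = colnames(se))
}
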