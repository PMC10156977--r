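#' @include AllClasses.R seqio.R patternSets.R
NULL

## k-mer occurrence counts of a character vector of bases, as a named table
## over exactly the requested words (overlapping scan, step 1).
.countWords <- function(chars, words) {
  k <- nchar(words[1])
  L <- length(chars)
  if (L < k) return(setNames(integer(length(words)), words))
  if (k == 1L) {
    kmers <- chars
  } else {
    idx <- seq_len(L - k + 1L)
    kmers <- chars[idx]
    for (j in seq_len(k - 1L)) kmers <- paste0(kmers, chars[idx + j])
  }
  tab <- table(factor(kmers, levels = words))
  setNames(as.integer(tab), words)
}

#' Count one nucleotide co-occurrence matrix
#'
#' Builds the count matrix for a single pattern set: cell (r, s) counts the
#' positions i (1 <= i <= L - m, m = pattern length) where the m-mer at i
#' equals row pattern r and the base at i + m equals column base s.
#' Occurrences overlap and every position is scanned (step 1). Sequences
#' shorter than m + 1 yield an all-zero matrix with a warning.
#'
#' @param seq DNA sequence (character or [Biostrings::DNAString]).
#' @param patternSet Name of the pattern set, one of `"I"`..`"P"`, or a
#'   character vector of equal-length row patterns.
#' @return A [CoocMatrix-class] with integer `counts` and `normalized`
#'   (counts divided by the grand total; all-zero for a zero total).
#' @examples
#' m <- countCooc("AACG", "I")
#' counts(m)            # (A,A)=1, (A,C)=1, (C,G)=1; total 3 = L - 1
#' sum(counts(m))
#' @export
countCooc <- function(seq, patternSet) {
  sets <- coocPatternSets()
  if (is.character(patternSet) && length(patternSet) == 1L &&
      patternSet %in% names(sets)) {
    setName <- patternSet
    patterns <- sets[[patternSet]]
  } else {
    patterns <- as.character(patternSet)
    if (length(unique(nchar(patterns))) != 1L)
      stop("all row patterns must share one length")
    setName <- "custom"
  }
  chars <- .seqChars(seq)
  counts <- .coocCountsOne(chars, patterns)
  .asCoocMatrix(setName, counts)
}

.coocCountsOne <- function(chars, patterns) {
  m <- nchar(patterns[1])
  words <- as.vector(outer(patterns, BASES, paste0))
  n <- .countWords(chars, words)
  matrix(n, nrow = length(patterns), ncol = 4L,
         dimnames = list(patterns, BASES))
}

.asCoocMatrix <- function(setName, counts) {
  tot <- sum(counts)
  normalized <- if (tot > 0) counts / tot else counts * 0
  storage.mode(counts) <- "integer"
  if (tot == 0)
    warning("co-occurrence matrix ", setName,
            " is all-zero (sequence too short or no pattern occurs)")
  new("CoocMatrix", patternSet = setName, counts = counts,
      normalized = normalized)
}

#' @describeIn CoocMatrix-class the integer count matrix.
#' @param x A `CoocMatrix`.
#' @export
counts <- function(x) {
  stopifnot(is(x, "CoocMatrix"))
  x@counts
}

#' @describeIn CoocMatrix-class the normalized (grand-total) matrix.
#' @export
normalizedCounts <- function(x) {
  stopifnot(is(x, "CoocMatrix"))
  x@normalized
}

#' @describeIn CoocMatrix-class the pattern-set name.
#' @export
patternSetName <- function(x) {
  stopifnot(is(x, "CoocMatrix"))
  x@patternSet
}

setMethod("show", "CoocMatrix", function(object) {
  cat(sprintf("CoocMatrix %s (%d x 4), grand total %d\n",
              object@patternSet, nrow(object@counts), sum(object@counts)))
  print(object@counts)
})

#' Texture features of a normalized co-occurrence matrix
#'
#' Computes the five scalar texture statistics of the normalized matrix G':
#' energy = sum G'^2; entropy = -sum G' ln G' (natural log, 0 ln 0 = 0);
#' homogeneity = sum G' / (1 + (r-s)^2); contrast = sum G' (r-s)^2;
#' dissimilarity = sum G' |r-s|; with r, s the 0-based row and column
#' indices, summed over every cell of the q x 4 matrix. An all-zero
#' normalized matrix yields all five features equal to 0.
#'
#' @param mat A [CoocMatrix-class], or a normalized numeric matrix.
#' @return Named numeric of length 5: energy, entropy, homogeneity,
#'   contrast, dissimilarity.
#' @examples
#' u <- matrix(1/16, 4, 4)
#' textureFeatures(u)["energy"]   # 16 * (1/16)^2 = 0.0625
#' @export
textureFeatures <- function(mat) {
  G <- if (is(mat, "CoocMatrix")) mat@normalized else as.matrix(mat)
  d <- row(G) - col(G)          # (r - s) with 0-based indices
  pos <- G > 0
  energy <- sum(G^2)
  entropy <- -sum(G[pos] * log(G[pos]))
  homogeneity <- sum(G / (1 + d^2))
  contrast <- sum(G * d^2)
  dissimilarity <- sum(G * abs(d))
  c(energy = energy, entropy = entropy, homogeneity = homogeneity,
    contrast = contrast, dissimilarity = dissimilarity)
}

#' The 40-dimensional co-occurrence feature vector
#'
#' Concatenates the five texture features of each of the eight
#' co-occurrence matrices in the fixed order I, J, K, L, M, N, O, P; within
#' each matrix the order is energy, entropy, homogeneity, contrast,
#' dissimilarity. Names are f1..f40.
#'
#' @param seq DNA sequence (character or [Biostrings::DNAString]).
#' @return Named numeric of length 40.
#' @examples
#' length(coocFeatureVector("ACGTACGTACGT"))  # 40
#' @export
coocFeatureVector <- function(seq) {
  chars <- .seqChars(seq)
  sets <- coocPatternSets()
  out <- numeric(0)
  for (nm in names(sets)) {
    counts <- .coocCountsOne(chars, sets[[nm]])
    tot <- sum(counts)
    G <- if (tot > 0) counts / tot else counts * 0
    out <- c(out, textureFeatures(G))
  }
  setNames(out, paste0("f", seq_len(40)))
}

#' Feature names of the 40-dimensional vector
#'
#' Maps f1..f40 to their matrix and statistic, e.g. f1 = I.energy,
#' f6 = J.energy.
#'
#' @return data.frame with columns `name`, `matrix`, `statistic`.
#' @export
coocFeatureKey <- function() {
  stats <- c("energy", "entropy", "homogeneity", "contrast", "dissimilarity")
  mats <- names(coocPatternSets())
  data.frame(name = paste0("f", seq_len(40)),
             matrix = rep(mats, each = 5),
             statistic = rep(stats, times = 8),
             stringsAsFactors = FALSE)
}

#' Dump all eight count matrices of a sequence as CSV files
#'
#' Writes one CSV per matrix (rows labeled by pattern, columns A,C,T,G)
#' into a directory, for inspection.
#'
#' @param seq DNA sequence.
#' @param dir Output directory (created if absent).
#' @param prefix File-name prefix.
#' @return Invisibly, the vector of written paths.
#' @export
dumpCoocMatrices <- function(seq, dir, prefix = "cooc") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  chars <- .seqChars(seq)
  sets <- coocPatternSets()
  paths <- character(0)
  for (nm in names(sets)) {
    counts <- .coocCountsOne(chars, sets[[nm]])
    p <- file.path(dir, sprintf("%s_%s.csv", prefix, nm))
    write.csv(as.data.frame(counts), p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
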