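#' @include AllClasses.R seqio.R
NULL

#' Shannon entropy of a binary sequence
#'
#' Base-2 entropy of the empirical purine/pyrimidine frequencies,
#' -sum p_i log2 p_i with the 0 log 0 = 0 convention. Lies in [0, 1]:
#' 0 for a constant sequence, 1 for a balanced one.
#'
#' @param bin A [BinarySequence-class] or a 0/1 vector.
#' @return Numeric in [0, 1], in bits.
#' @examples
#' shannonEntropy(c(0, 1, 0, 1))  # 1
#' shannonEntropy(c(0, 0, 0, 0))  # 0
#' @export
shannonEntropy <- function(bin) {
  b <- .binBits(bin)
  p <- c(mean(b == 0L), mean(b == 1L))
  p <- p[p > 0]
  -sum(p * log2(p)) + 0  # + 0 avoids IEEE negative zero
}

## Maximal runs of a 0/1 vector: lengths and symbols.
.runs <- function(b) {
  r <- rle(b)
  list(lengths = r$lengths, values = r$values)
}

#' Modified Shannon entropy over binary words
#'
#' Word-based entropy -sum w_j log2 w_j where the words are built from the
#' purine/pyrimidine encoding. The word length is tied to the longest run
#' of identical symbols, and two readings of the word inventory are
#' provided:
#' \describe{
#'   \item{`"window"` (default)}{let l* be the longest run of identical
#'     bits; the words are the overlapping l*-length windows of the
#'     sequence and w_j their empirical frequencies.}
#'   \item{`"runs"`}{the words are the maximal runs themselves (e.g. "11",
#'     "0"); w_j is the frequency of each distinct run word among all
#'     runs.}
#' }
#'
#' @param bin A [BinarySequence-class] or 0/1 vector.
#' @param mode `"window"` or `"runs"`.
#' @return Non-negative numeric, in bits; 0 when only one word type occurs.
#' @examples
#' modifiedShannonEntropy(c(1, 1, 0, 1, 0))          # 1.5
#' modifiedShannonEntropy(c(1, 1, 0, 1, 0), "runs")  # 1.5
#' @export
modifiedShannonEntropy <- function(bin, mode = c("window", "runs")) {
  mode <- match.arg(mode)
  b <- .binBits(bin)
  if (mode == "window") {
    lstar <- max(.runs(b)$lengths)
    n <- length(b)
    if (lstar >= n) return(0)
    idx <- seq_len(n - lstar + 1L)
    words <- b[idx]
    for (j in seq_len(lstar - 1L)) words <- paste0(words, b[idx + j])
    w <- table(words) / length(words)
  } else {
    r <- .runs(b)
    words <- vapply(seq_along(r$lengths), function(i)
      paste(rep(r$values[i], r$lengths[i]), collapse = ""), character(1))
    w <- table(words) / length(words)
  }
  w <- as.numeric(w)
  -sum(w * log2(w)) + 0
}

#' Hurst exponent by single-scale rescaled-range analysis
#'
#' Estimates the Hurst exponent of the purine/pyrimidine bit series from
#' the rescaled range at the full series length: with m the mean bit,
#' X_t the cumulative deviations sum_{i<=t}(D_i - m), R_n = max X - min X
#' and S_n the population standard deviation (divisor n), the estimate
#' solves R_n/S_n = (n/2)^HE, i.e. HE = log(R_n/S_n) / log(n/2).
#' Around 0.5 the series is memoryless; values above 0.5 indicate
#' persistence, below 0.5 anti-persistence. The single-scale estimator
#' carries the known finite-n upward bias of R/S analysis.
#'
#' @param bin A [BinarySequence-class] or 0/1 vector; length must exceed 2
#'   and the bits must not be all equal (S_n = 0 is undefined).
#' @param intermediates If TRUE, return a list with the audit quantities
#'   m, X, Rn, Sn and HE instead of the bare estimate.
#' @return Numeric estimate, or a list when `intermediates = TRUE`.
#' @examples
#' hurstExponent(rep(c(0, 1), 32))
#' @export
hurstExponent <- function(bin, intermediates = FALSE) {
  b <- .binBits(bin)
  n <- length(b)
  if (n <= 2L)
    stop("Hurst exponent needs length > 2 (log(n/2) must be positive)")
  m <- mean(b)
  Sn <- sqrt(mean((b - m)^2))
  if (Sn == 0)
    stop("Hurst exponent undefined for a constant sequence (zero variance)")
  X <- cumsum(b - m)
  Rn <- max(X) - min(X)
  HE <- log(Rn / Sn) / log(n / 2)
  if (!intermediates) return(HE)
  list(m = m, X = X, Rn = Rn, Sn = Sn, HE = HE)
}

#' Indicator matrix of a DNA sequence
#'
#' The N x N binary matrix with cell (i, j) = 1 when bases i and j are
#' equal, the 2-D dot-plot of the sequence against itself. Always symmetric
#' with a unit diagonal. Long sequences are truncated to the first `cap`
#' bases before the O(N^2) matrix is built.
#'
#' @param seq DNA sequence (character or [Biostrings::DNAString]).
#' @param cap Maximum N (default 1000).
#' @return N x N integer 0/1 matrix.
#' @examples
#' indicatorMatrix("AC")  # identity
#' indicatorMatrix("AA")  # all ones
#' @export
indicatorMatrix <- function(seq, cap = 1000L) {
  chars <- .seqChars(seq)
  N <- min(length(chars), as.integer(cap))
  chars <- chars[seq_len(N)]
  m <- outer(chars, chars, "==")
  storage.mode(m) <- "integer"
  m
}

## Mean 1-count over all contiguous n x n submatrices, for every n in
## 2..N, via double prefix sums: the sum over window positions of the
## window sums is an O(1) combination of block sums of the first-level
## prefix matrix.
.sigmaProfile <- function(A) {
  N <- nrow(A)
  pref2 <- function(M) {  # 2-D prefix sum with a zero border
    P <- matrix(0, nrow(M) + 1L, ncol(M) + 1L)
    P[-1L, -1L] <- t(apply(apply(M, 2L, cumsum), 1L, cumsum))
    P
  }
  P <- pref2(A)   # P[i+1, j+1] = sum A[1..i, 1..j]
  Q <- pref2(P)
  block <- function(r1, r2, c1, c2)  # sum P[r1..r2, c1..c2]
    Q[r2 + 1L, c2 + 1L] - Q[r1, c2 + 1L] - Q[r2 + 1L, c1] + Q[r1, c1]
  vapply(2:N, function(n) {
    K <- N - n + 1L
    tot <- block(n + 1L, n + K, n + 1L, n + K) -
           block(1L, K, n + 1L, n + K) -
           block(n + 1L, n + K, 1L, K) +
           block(1L, K, 1L, K)
    tot / K^2
  }, numeric(1))
}

#' Fractal dimension from the indicator matrix
#'
#' Computes sigma(n), the average number of 1s over all contiguous n x n
#' submatrices of the N x N indicator matrix — the exact expectation of
#' sampling submatrix positions at random — and returns
#' FD = -(1/N) sum_{n=2}^{N} log sigma(n) / log n (ratio of logarithms,
#' base-free). The literal sign convention is kept, so values are negative
#' for any non-trivial matrix; as a discriminant feature the sign is
#' immaterial. Fully deterministic: no sampling is involved.
#'
#' @param seq DNA sequence (character or [Biostrings::DNAString]) of
#'   effective length (after `cap`) at least 2.
#' @param cap Maximum indicator-matrix size (default 1000); computed via
#'   2-D prefix sums, O(N^2) overall.
#' @param profile If TRUE, also return the sigma(n) profile.
#' @return Numeric FD, or list(fd, sigma) when `profile = TRUE`.
#' @examples
#' fractalDimension("AAAA")  # -(1/4) * (2 + 2 + 2) = -1.5
#' @export
fractalDimension <- function(seq, cap = 1000L, profile = FALSE) {
  A <- indicatorMatrix(seq, cap = cap)
  N <- nrow(A)
  if (N < 2L) stop("fractal dimension needs at least 2 bases")
  sigma <- .sigmaProfile(A)
  fd <- -(1 / N) * sum(log(sigma) / log(2:N))
  if (!profile) return(fd)
  list(fd = fd, sigma = setNames(sigma, paste0("n", 2:N)))
}
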