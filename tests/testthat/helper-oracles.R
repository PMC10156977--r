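# Independent straight-line oracles used to cross-check the implementation.
# These deliberately share no code with the package internals.

# Brute-force co-occurrence counter: scan every position, compare substrings.
bruteCooc <- function(seq, patterns, alphabet = c("A", "C", "T", "G")) {
  m <- nchar(patterns[1])
  L <- nchar(seq)
  out <- matrix(0L, length(patterns), length(alphabet),
                dimnames = list(patterns, alphabet))
  if (L < m + 1) return(out)
  for (i in seq_len(L - m)) {
    pat <- substr(seq, i, i + m - 1)
    nxt <- substr(seq, i + m, i + m)
    r <- match(pat, patterns)
    s <- match(nxt, alphabet)
    if (!is.na(r) && !is.na(s)) out[r, s] <- out[r, s] + 1L
  }
  out
}

# Naive sigma(n): enumerate every contiguous n x n submatrix.
bruteSigma <- function(A, n) {
  N <- nrow(A)
  K <- N - n + 1
  tot <- 0
  for (i in seq_len(K)) for (j in seq_len(K))
    tot <- tot + sum(A[i:(i + n - 1), j:(j + n - 1)])
  tot / K^2
}

bruteFractalDimension <- function(A) {
  N <- nrow(A)
  s <- vapply(2:N, function(n) bruteSigma(A, n), numeric(1))
  -(1 / N) * sum(log(s) / log(2:N))
}

# Straight-line weighted one-vs-rest metrics from a confusion matrix
# (rows = truth, cols = prediction).
bruteWeightedMetrics <- function(cm) {
  C <- nrow(cm)
  n <- rowSums(cm)
  tot <- sum(cm)
  acc <- prec <- rec <- f1 <- numeric(C)
  for (i in seq_len(C)) {
    TP <- cm[i, i]
    FN <- n[i] - TP
    FP <- sum(cm[, i]) - TP
    TN <- tot - TP - FN - FP
    acc[i] <- (TP + TN) / (TP + TN + FP + FN)
    prec[i] <- if (TP + FP > 0) TP / (TP + FP) else 0
    rec[i] <- if (TP + FN > 0) TP / (TP + FN) else 0
    f1[i] <- if (prec[i] + rec[i] > 0)
      2 * prec[i] * rec[i] / (prec[i] + rec[i]) else 0
  }
  w <- n / sum(n)
  100 * c(accuracy = sum(w * acc), precision = sum(w * prec),
          recall = sum(w * rec), f1 = sum(w * f1))
}

# Direct evaluation of the single-scale R/S estimate.
bruteHurst <- function(bits) {
  n <- length(bits)
  m <- sum(bits) / n
  X <- numeric(n)
  acc <- 0
  for (t in seq_len(n)) {
    acc <- acc + (bits[t] - m)
    X[t] <- acc
  }
  Rn <- max(X) - min(X)
  Sn <- sqrt(sum((bits - m)^2) / n)
  log(Rn / Sn) / log(n / 2)
}

randomDNA <- function(L) paste(sample(c("A", "C", "G", "T"), L,
                                      replace = TRUE), collapse = "")
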