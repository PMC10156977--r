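#' @include AllClasses.R
NULL

## All conditioning k-mers for a chain of the given order, in A,C,T,G
## product order (first base varies slowest).
.stateKmers <- function(order) {
  if (order == 1L) return(BASES)
  as.vector(t(outer(BASES, BASES, paste0)))
}

#' Construct a Markov class specification
#'
#' @param classLabel Class label.
#' @param transition Stochastic matrix: 4 x 4 (order 1) or 16 x 4
#'   (order 2); columns in A,C,T,G order. Row names default to the
#'   conditioning k-mers in A,C,T,G product order.
#' @param nSequences Number of sequences to draw for this class.
#' @param lengthRange Inclusive (min, max) sequence length.
#' @param init Initial base distribution over A,C,T,G (default uniform);
#'   the first `order` bases are drawn iid from it.
#' @return A validated [MarkovClassSpec-class].
#' @export
markovClassSpec <- function(classLabel, transition, nSequences,
                            lengthRange, init = rep(0.25, 4)) {
  transition <- as.matrix(transition)
  order <- if (nrow(transition) == 4L) 1L else 2L
  rownames(transition) <- .stateKmers(order)
  colnames(transition) <- BASES
  new("MarkovClassSpec", classLabel = as.character(classLabel),
      order = order, init = as.numeric(init), transition = transition,
      nSequences = as.integer(nSequences),
      lengthRange = as.integer(lengthRange))
}

setMethod("show", "MarkovClassSpec", function(object) {
  cat(sprintf(
    "MarkovClassSpec '%s': order %d, %d sequences, lengths %d-%d\n",
    object@classLabel, object@order, object@nSequences,
    object@lengthRange[1], object@lengthRange[2]))
})

## One transition row putting `w` on the favoured base and (1-w)/3 on the
## rest; index in A,C,T,G order.
.biasRow <- function(favoured, w) {
  row <- rep((1 - w) / 3, 4)
  row[favoured] <- w
  row
}

#' Default three-class synthetic benchmark
#'
#' Three order-2 Markov classes whose transition rows place probability
#' 0.55 on a class-specific favoured base (the remaining 0.15 on each
#' other base): class "rep" favours repeating the last base, class "cyc"
#' favours the cyclic successor A->C->T->G->A of the last base, and class
#' "ret" favours returning to the first base of the conditioning pair.
#' Any two classes differ on at least 12 of the 16 rows, giving a mean
#' row-wise total-variation distance of at least 0.2, so the
#' trinucleotide-level signal is learnable by the co-occurrence features.
#' Defaults: 150 sequences per class, lengths 300-3000.
#'
#' @param preset `"default"` (150/150/150), `"imbalanced"` (150/50/25) or
#'   `"null"` (three iid-uniform classes with no signal).
#' @return List of three [MarkovClassSpec-class] objects.
#' @export
defaultBenchmarkSpecs <- function(preset = c("default", "imbalanced",
                                             "null")) {
  preset <- match.arg(preset)
  n <- switch(preset,
              default = c(150L, 150L, 150L),
              imbalanced = c(150L, 50L, 25L),
              null = c(150L, 150L, 150L))
  lr <- c(300L, 3000L)
  states <- .stateKmers(2L)
  lastBase <- match(substr(states, 2, 2), BASES)
  firstBase <- match(substr(states, 1, 1), BASES)
  w <- 0.55
  mk <- function(favoured) t(vapply(favoured, .biasRow, numeric(4), w = w))
  if (preset == "null") {
    unif <- matrix(0.25, 16, 4)
    return(list(
      markovClassSpec("null1", unif, n[1], lr),
      markovClassSpec("null2", unif, n[2], lr),
      markovClassSpec("null3", unif, n[3], lr)))
  }
  list(
    markovClassSpec("rep", mk(lastBase), n[1], lr),
    markovClassSpec("cyc", mk(lastBase %% 4L + 1L), n[2], lr),
    markovClassSpec("ret", mk(firstBase), n[3], lr)
  )
}

#' Mean row-wise total-variation distance between two transition matrices
#'
#' @param a,b Stochastic matrices of identical shape.
#' @return Mean over rows of 0.5 * sum |a_row - b_row|.
#' @export
tvDistance <- function(a, b) {
  stopifnot(all(dim(a) == dim(b)))
  mean(0.5 * rowSums(abs(a - b)))
}

#' Stationary base distribution of a Markov class
#'
#' Left eigenvector (eigenvalue 1) of the chain on its state space,
#' marginalised to single-base frequencies.
#'
#' @param spec A [MarkovClassSpec-class].
#' @return Named numeric(4) over A,C,T,G summing to 1.
#' @export
stationaryDistribution <- function(spec) {
  stopifnot(is(spec, "MarkovClassSpec"))
  states <- .stateKmers(spec@order)
  nS <- length(states)
  ## transition on the state space: state (prefix) -> next state
  Tm <- matrix(0, nS, nS, dimnames = list(states, states))
  for (i in seq_len(nS)) {
    for (b in seq_len(4L)) {
      nxt <- if (spec@order == 1L) BASES[b]
             else paste0(substr(states[i], 2, 2), BASES[b])
      Tm[i, nxt] <- Tm[i, nxt] + spec@transition[i, b]
    }
  }
  e <- eigen(t(Tm))
  v <- Re(e$vectors[, which.min(abs(e$values - 1))])
  v <- v / sum(v)
  last <- substr(states, spec@order, spec@order)
  out <- vapply(BASES, function(b) sum(v[last == b]), numeric(1))
  setNames(out, BASES)
}

#' Generate labeled synthetic sequences from Markov class specs
#'
#' Draws `nSequences` sequences per class, lengths uniform on the class's
#' `lengthRange`, deterministically for a given seed. Sequence ids encode
#' class and index (e.g. "rep_001").
#'
#' @param specs List of [MarkovClassSpec-class] objects.
#' @param seed Integer seed; identical seeds give identical output.
#' @return list(sequences = named [Biostrings::DNAStringSet],
#'   labels = data.frame(id, label)).
#' @examples
#' out <- generateMarkovSequences(defaultBenchmarkSpecs(), seed = 7)
#' table(out$labels$label)
#' @export
generateMarkovSequences <- function(specs, seed = 1L) {
  if (!length(specs)) stop("at least one class spec required")
  lapply(specs, function(s) {
    stopifnot(is(s, "MarkovClassSpec"))
    validObject(s)
  })
  set.seed(as.integer(seed))
  allSeqs <- character(0)
  allIds <- character(0)
  allLabels <- character(0)
  for (spec in specs) {
    n <- spec@nSequences
    lens <- sample(spec@lengthRange[1]:spec@lengthRange[2], n,
                   replace = TRUE)
    maxL <- max(lens)
    ord <- spec@order
    baseM <- matrix(0L, n, maxL)
    for (j in seq_len(ord))
      baseM[, j] <- sample.int(4L, n, replace = TRUE, prob = spec@init)
    cum <- t(apply(spec@transition, 1L, cumsum))
    state <- if (ord == 1L) baseM[, 1L]
             else (baseM[, 1L] - 1L) * 4L + baseM[, 2L]
    if (maxL > ord) {
      for (t in (ord + 1L):maxL) {
        u <- runif(n)
        p <- cum[state, , drop = FALSE]
        nb <- 1L + (u > p[, 1L]) + (u > p[, 2L]) + (u > p[, 3L])
        baseM[, t] <- nb
        state <- if (ord == 1L) nb
                 else (state - 1L) %% 4L * 4L + nb
      }
    }
    seqsChr <- vapply(seq_len(n), function(i)
      paste(BASES[baseM[i, seq_len(lens[i])]], collapse = ""),
      character(1))
    ids <- sprintf("%s_%03d", spec@classLabel, seq_len(n))
    allSeqs <- c(allSeqs, seqsChr)
    allIds <- c(allIds, ids)
    allLabels <- c(allLabels, rep(spec@classLabel, n))
  }
  seqs <- DNAStringSet(setNames(allSeqs, allIds))
  list(sequences = seqs,
       labels = data.frame(id = allIds, label = allLabels,
                           stringsAsFactors = FALSE))
}

#' Write a synthetic set as FASTA plus label TSV
#'
#' @param synth Output of [generateMarkovSequences()].
#' @param fastaPath,labelsPath Output paths.
#' @return Invisibly, c(fastaPath, labelsPath).
#' @export
writeSynthData <- function(synth, fastaPath, labelsPath) {
  writeXStringSet(synth$sequences, fastaPath)
  write.table(synth$labels, labelsPath, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(c(fastaPath, labelsPath))
}
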