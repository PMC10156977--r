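#' @include AllClasses.R
NULL

## Coerce a sequence argument (character(1), DNAString, or one element of a
## DNAStringSet) to an uppercase character vector of single bases, checking
## the A/C/G/T alphabet.
.seqChars <- function(seq) {
  if (is(seq, "XString") || is(seq, "XStringSet")) seq <- as.character(seq)
  if (!is.character(seq) || length(seq) != 1L)
    stop("'seq' must be a single DNA sequence (character or DNAString)")
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  if (length(chars) < 1L) stop("sequence must have length >= 1")
  bad <- setdiff(unique(chars), c("A", "C", "G", "T"))
  if (length(bad))
    stop("sequence contains non-ACGT characters: ",
         paste(bad, collapse = ", "))
  chars
}

#' Read and validate a DNA FASTA file
#'
#' Reads a multi-record FASTA file, uppercases the sequences and applies a
#' policy to records containing ambiguity characters (N or other IUPAC
#' codes). Record order is preserved.
#'
#' @param path Path to a FASTA file.
#' @param ambiguousPolicy What to do with records containing non-ACGT
#'   characters: `"drop-record"` (default) removes the record with a
#'   warning, `"strip-chars"` deletes the offending characters, `"error"`
#'   aborts.
#' @return A [Biostrings::DNAStringSet] over the strict A/C/G/T alphabet,
#'   named by the FASTA identifiers.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">s1", "ACGTacgt", ">s2", "TTNGA"), fa)
#' readFastaDNA(fa)            # s2 dropped with a warning
#' readFastaDNA(fa, "strip-chars")
#' @export
readFastaDNA <- function(path,
                         ambiguousPolicy = c("drop-record", "strip-chars",
                                             "error")) {
  ambiguousPolicy <- match.arg(ambiguousPolicy)
  if (!file.exists(path)) stop("file not found: ", path)
  firstLines <- readLines(path, n = 50L)
  nonEmpty <- which(nzchar(trimws(firstLines)))
  if (!length(nonEmpty)) stop("empty FASTA file: ", path)
  if (!startsWith(trimws(firstLines[nonEmpty[1]]), ">"))
    stop(sprintf("malformed FASTA in %s: line %d does not start a record",
                 path, nonEmpty[1]))
  seqs <- readBStringSet(path)
  if (!length(seqs)) stop("empty FASTA file: ", path)
  raw <- toupper(as.character(seqs))
  if (any(!nzchar(raw)))
    stop("FASTA contains empty-sequence records: ",
         paste(names(seqs)[!nzchar(raw)], collapse = ", "))
  clean <- !grepl("[^ACGT]", raw)
  if (!all(clean)) {
    offending <- names(seqs)[!clean]
    if (ambiguousPolicy == "error") {
      stop("records with ambiguity characters: ",
           paste(offending, collapse = ", "))
    } else if (ambiguousPolicy == "drop-record") {
      warning(sprintf("dropped %d record(s) with ambiguity characters: %s",
                      length(offending),
                      paste(offending, collapse = ", ")))
      raw <- raw[clean]
    } else {
      warning(sprintf("stripped ambiguity characters from %d record(s): %s",
                      length(offending),
                      paste(offending, collapse = ", ")))
      raw <- gsub("[^ACGT]", "", raw)
      if (any(!nzchar(raw)))
        stop("record(s) empty after stripping ambiguity characters: ",
             paste(names(raw)[!nzchar(raw)], collapse = ", "))
    }
  }
  DNAStringSet(raw)
}

#' Encode a DNA sequence as purine/pyrimidine bits
#'
#' Purines (A, G) map to 1 and pyrimidines (C, T) map to 0, preserving
#' length. The resulting binary sequence is the input to the Shannon
#' entropy, modified Shannon entropy and Hurst exponent estimators.
#'
#' @param seq A DNA sequence: character string or
#'   [Biostrings::DNAString]; only A/C/G/T allowed (case-insensitive).
#' @param id Record identifier stored with the encoding.
#' @return A [BinarySequence-class] object.
#' @examples
#' b <- encodeBinary("ACGT")
#' bits(b)        # 1 0 1 0
#' p0(b); p1(b)   # 0.5 0.5
#' @export
encodeBinary <- function(seq, id = "seq") {
  chars <- .seqChars(seq)
  new("BinarySequence", id = as.character(id),
      bits = as.integer(chars %in% c("A", "G")))
}

#' @describeIn BinarySequence-class the 0/1 vector.
#' @param x A `BinarySequence`.
#' @export
bits <- function(x) {
  stopifnot(is(x, "BinarySequence"))
  x@bits
}

#' @describeIn BinarySequence-class empirical frequency of 0 (pyrimidines).
#' @export
p0 <- function(x) 1 - p1(x)

#' @describeIn BinarySequence-class empirical frequency of 1 (purines).
#' @export
p1 <- function(x) {
  stopifnot(is(x, "BinarySequence"))
  sum(x@bits) / length(x@bits)
}

setMethod("show", "BinarySequence", function(object) {
  n <- length(object@bits)
  cat(sprintf("BinarySequence '%s': length %d, p1 = %.4f\n",
              object@id, n, sum(object@bits) / n))
})

## Accept a BinarySequence or a bare numeric/integer 0-1 vector.
.binBits <- function(bin) {
  if (is(bin, "BinarySequence")) return(bin@bits)
  if (is.numeric(bin) && length(bin) >= 1L && all(bin %in% c(0, 1)))
    return(as.integer(bin))
  stop("expected a BinarySequence or a 0/1 vector")
}

#' Read a sequence-label sidecar table
#'
#' Reads a two-column tab-separated file (id, label) with no header, the
#' layout the synthetic generator writes and the natural companion for
#' per-species FASTA files.
#'
#' @param path Path to the TSV file.
#' @return data.frame with columns `id` and `label` (character).
#' @export
readLabels <- function(path) {
  df <- read.delim(path, header = FALSE, col.names = c("id", "label"),
                   colClasses = "character")
  if (!nrow(df)) stop("empty label file: ", path)
  df
}

#' Write a feature table as CSV
#'
#' Writes one row per record with columns `id`, `label`, then the feature
#' values in canonical order (f1..f40, then SE, HE, MSE, FD when present).
#' The file round-trips through [readFeatureTable()].
#'
#' @param features numeric matrix, rows = records, columns named by feature.
#' @param ids character vector of record identifiers.
#' @param labels character vector of class labels (may be NA).
#' @param path Output CSV path.
#' @return Invisibly, the written data.frame.
#' @export
writeFeatureTable <- function(features, ids, labels, path) {
  features <- as.matrix(features)
  if (length(ids) != nrow(features) || length(labels) != nrow(features))
    stop("ids, labels and feature rows must have equal length")
  if (is.null(colnames(features)))
    stop("feature columns must be named")
  df <- data.frame(id = as.character(ids), label = as.character(labels),
                   features, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' Read a feature table written by [writeFeatureTable()]
#'
#' @param path CSV path.
#' @return list with `features` (numeric matrix), `ids`, `labels`.
#' @export
readFeatureTable <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("id", "label") %in% colnames(df)[1:2]))
    stop("feature table must start with columns id, label")
  feat <- as.matrix(df[, -(1:2), drop = FALSE])
  storage.mode(feat) <- "double"
  list(features = feat, ids = as.character(df$id),
       labels = as.character(df$label))
}
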