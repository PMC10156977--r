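#' @include features.R
NULL

#' Class-size-weighted one-vs-rest metrics
#'
#' Given per-class one-vs-rest confusion counts (TP, TN, FP, FN, n for each
#' class, taken from a single multiclass prediction), computes accuracy,
#' precision, recall and F1 in percent, each as the n_i-weighted average of
#' the per-class value. The accuracy is the one-vs-rest form that includes
#' true negatives, so it upper-bounds plain multiclass accuracy. A class
#' with TP + FP = 0 has precision defined as 0 (and F1 = 0).
#'
#' @param perClass data.frame or matrix with columns TP, TN, FP, FN, n
#'   (one row per class); all counts non-negative.
#' @return Named numeric: accuracy, precision, recall, f1 (percent).
#' @examples
#' cm <- confusionCounts(rep(c("a", "b"), each = 5),
#'                       rep(c("a", "b"), each = 5))
#' weightedMetrics(cm)  # all 100
#' @export
weightedMetrics <- function(perClass) {
  pc <- as.data.frame(perClass)
  need <- c("TP", "TN", "FP", "FN", "n")
  if (!all(need %in% colnames(pc)))
    stop("perClass must have columns TP, TN, FP, FN, n")
  if (any(as.matrix(pc[, need]) < 0)) stop("negative counts")
  w <- pc$n / sum(pc$n)
  accI <- (pc$TP + pc$TN) / (pc$TP + pc$TN + pc$FP + pc$FN)
  precI <- ifelse(pc$TP + pc$FP > 0, pc$TP / (pc$TP + pc$FP), 0)
  recI <- ifelse(pc$TP + pc$FN > 0, pc$TP / (pc$TP + pc$FN), 0)
  f1I <- ifelse(precI + recI > 0, 2 * precI * recI / (precI + recI), 0)
  100 * c(accuracy = sum(w * accI), precision = sum(w * precI),
          recall = sum(w * recI), f1 = sum(w * f1I))
}

#' Per-class one-vs-rest confusion counts of a multiclass prediction
#'
#' @param truth,pred factors or character vectors of equal length.
#' @param classes Optional class order; defaults to the union of levels.
#' @return data.frame with columns class, TP, TN, FP, FN, n (n = true
#'   class size).
#' @export
confusionCounts <- function(truth, pred, classes = NULL) {
  truth <- as.character(truth); pred <- as.character(pred)
  if (length(truth) != length(pred)) stop("truth and pred length mismatch")
  if (is.null(classes)) classes <- sort(unique(c(truth, pred)))
  out <- lapply(classes, function(cl) {
    tp <- sum(truth == cl & pred == cl)
    fn <- sum(truth == cl & pred != cl)
    fp <- sum(truth != cl & pred == cl)
    tn <- sum(truth != cl & pred != cl)
    data.frame(class = cl, TP = tp, TN = tn, FP = fp, FN = fn,
               n = tp + fn, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

## z-score parameters fit on the training matrix; zero-variance columns are
## mapped to 0 so downstream eigen-decompositions stay well-posed.
.fitScaler <- function(x) {
  mu <- colMeans(x)
  sig <- apply(x, 2L, sd)
  sig[sig == 0 | !is.finite(sig)] <- Inf  # divides the centered column to 0
  list(mu = mu, sig = sig)
}

.applyScaler <- function(x, sc) sweep(sweep(x, 2L, sc$mu), 2L, sc$sig, "/")

#' PCA reduction by explained-variance threshold
#'
#' Standardizes the training matrix (z-score fit on train, applied to
#' test; zero-variance columns mapped to 0), performs PCA on the training
#' set and keeps the smallest number of components whose cumulative
#' explained-variance ratio reaches `variation`. Both sets are projected
#' with the training rotation.
#'
#' @param train,test numeric matrices (samples x features) with matching
#'   columns.
#' @param variation Explained-variance threshold in (0, 1].
#' @return list(train, test, d, eigenvalues): projected matrices, retained
#'   dimension and the full eigenvalue spectrum in descending order.
#' @examples
#' x <- matrix(rnorm(60), 20, 3); x[, 3] <- 0
#' r <- pcaReduce(x[1:10, ], x[11:20, ], variation = 0.99)
#' r$d
#' @export
pcaReduce <- function(train, test, variation) {
  if (!is.numeric(variation) || length(variation) != 1L ||
      variation <= 0 || variation > 1)
    stop("variation must lie in (0, 1]")
  train <- as.matrix(train); test <- as.matrix(test)
  sc <- .fitScaler(train)
  ztr <- .applyScaler(train, sc)
  zte <- .applyScaler(test, sc)
  pc <- prcomp(ztr, center = FALSE, scale. = FALSE)
  ev <- pc$sdev^2
  ratio <- cumsum(ev) / sum(ev)
  d <- which(ratio >= variation - 1e-12)[1]
  list(train = pc$x[, seq_len(d), drop = FALSE],
       test = zte %*% pc$rotation[, seq_len(d), drop = FALSE],
       d = as.integer(d),
       eigenvalues = ev)
}

## Fit one classifier on (xtr, ytr) and predict labels for xte.
.fitPredict <- function(classifier, xtr, ytr, xte, knnK, svmCost) {
  if (classifier == "knn") {
    as.character(class::knn(xtr, xte, cl = ytr, k = knnK))
  } else if (classifier == "dt") {
    df <- data.frame(.y = ytr, xtr, check.names = TRUE)
    fit <- rpart(.y ~ ., data = df, method = "class")
    nd <- data.frame(xte, check.names = TRUE)
    colnames(nd) <- colnames(df)[-1]
    as.character(predict(fit, nd, type = "class"))
  } else {
    fit <- svm(xtr, ytr, kernel = "radial", cost = svmCost, scale = FALSE)
    as.character(predict(fit, xte))
  }
}

## Stratified index split: per class, floor(n/2) samples to train for a
## 50/50 split, or fold assignment for k-fold CV.
.stratifiedHalf <- function(y) {
  train <- integer(0)
  for (cl in levels(y)) {
    idx <- which(y == cl)
    take <- sample(idx, floor(length(idx) / 2))
    train <- c(train, take)
  }
  sort(train)
}

.stratifiedFolds <- function(y, k) {
  fold <- integer(length(y))
  for (cl in levels(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Train and evaluate a classifier under the split protocol
#'
#' Runs the full evaluation protocol on an assembled feature set: under
#' `"repeated-split"` (default), five repetitions of a stratified 50/50
#' train/test split; under `"cv5"`, stratified five-fold cross-validation.
#' Within each split the z-score scaler (and optional PCA) is fit on the
#' training half only and applied to the test half, the classifier is
#' trained and the test predictions are scored with [weightedMetrics()];
#' the report averages metrics and per-class counts over splits. Any
#' missing feature values (e.g. failed Hurst exponents not imputed at
#' assembly) are imputed per split with training-column means.
#'
#' @param se SummarizedExperiment from [assembleFeatures()] with a `label`
#'   column; every class needs at least 2 samples.
#' @param classifier `"knn"`, `"dt"` or `"svm"`. Defaults: KNN k = 5 with
#'   Euclidean distance; decision tree with Gini splits; SVM with RBF
#'   kernel and cost 1.
#' @param protocol `"repeated-split"` or `"cv5"`.
#' @param seed Master seed governing every split and classifier tie-break.
#' @param pcaVariation Explained-variance threshold in (0, 1] to PCA-reduce
#'   each split, or NULL for no reduction.
#' @param scale Fit-on-train z-score standardization (default TRUE).
#' @param knnK Neighbours for KNN.
#' @param svmCost SVM cost parameter.
#' @param repeats Repetitions of the 50/50 split (ignored for cv5).
#' @return An [EvalReport-class].
#' @export
evaluateProtocol <- function(se, classifier = c("knn", "dt", "svm"),
                             protocol = c("repeated-split", "cv5"),
                             seed = 1L, pcaVariation = NULL, scale = TRUE,
                             knnK = 5L, svmCost = 1, repeats = 5L) {
  classifier <- match.arg(classifier)
  protocol <- match.arg(protocol)
  fm <- featureMatrix(se)
  if (is.null(fm$y)) stop("feature set has no labels")
  x <- fm$x; y <- droplevels(fm$y)
  if (nlevels(y) < 2L) stop("at least 2 classes required")
  small <- table(y) < 2L
  if (any(small))
    stop("class(es) with fewer than 2 samples: ",
         paste(names(which(small)), collapse = ", "))
  seed <- as.integer(seed)
  classes <- levels(y)

  runSplit <- function(trainIdx, testIdx) {
    xtr <- x[trainIdx, , drop = FALSE]
    xte <- x[testIdx, , drop = FALSE]
    ytr <- y[trainIdx]; yte <- y[testIdx]
    if (anyNA(xtr) || anyNA(xte)) {  # per-split train-mean imputation
      mu <- colMeans(xtr, na.rm = TRUE)
      for (j in which(colSums(is.na(rbind(xtr, xte))) > 0)) {
        xtr[is.na(xtr[, j]), j] <- mu[j]
        xte[is.na(xte[, j]), j] <- mu[j]
      }
    }
    if (scale) {
      sc <- .fitScaler(xtr)
      xtr <- .applyScaler(xtr, sc)
      xte <- .applyScaler(xte, sc)
    }
    d <- ncol(xtr)
    if (!is.null(pcaVariation)) {
      red <- pcaReduce(xtr, xte, pcaVariation)
      xtr <- red$train; xte <- red$test; d <- red$d
    }
    pred <- .fitPredict(classifier, xtr, ytr, xte, knnK, svmCost)
    cc <- confusionCounts(yte, pred, classes = classes)
    list(metrics = weightedMetrics(cc), counts = cc, d = d)
  }

  set.seed(seed)
  results <- if (protocol == "repeated-split") {
    lapply(seq_len(repeats), function(r) {
      trainIdx <- .stratifiedHalf(y)
      runSplit(trainIdx, setdiff(seq_along(y), trainIdx))
    })
  } else {
    fold <- .stratifiedFolds(y, 5L)
    lapply(seq_len(5L), function(f)
      runSplit(which(fold != f), which(fold == f)))
  }

  metrics <- colMeans(do.call(rbind, lapply(results, `[[`, "metrics")))
  countMats <- lapply(results, function(r)
    as.matrix(r$counts[, c("TP", "TN", "FP", "FN", "n")]))
  meanCounts <- Reduce(`+`, countMats) / length(countMats)
  perClass <- data.frame(class = classes, meanCounts,
                         stringsAsFactors = FALSE)
  new("EvalReport",
      classifier = classifier, protocol = protocol, seed = seed,
      metrics = metrics, perClass = perClass,
      dimension = as.integer(results[[1]]$d),
      pcaVariation = if (is.null(pcaVariation)) NA_real_ else pcaVariation,
      scaled = isTRUE(scale),
      repeats = if (protocol == "repeated-split") as.integer(repeats) else 5L)
}

#' @describeIn EvalReport-class the weighted metrics (percent).
#' @param x An `EvalReport`.
#' @export
reportMetrics <- function(x) {
  stopifnot(is(x, "EvalReport"))
  x@metrics
}

#' @describeIn EvalReport-class the mean per-class confusion counts.
#' @export
reportPerClass <- function(x) {
  stopifnot(is(x, "EvalReport"))
  x@perClass
}

#' @describeIn EvalReport-class protocol metadata as a list.
#' @export
reportProtocol <- function(x) {
  stopifnot(is(x, "EvalReport"))
  list(classifier = x@classifier, protocol = x@protocol, seed = x@seed,
       dimension = x@dimension, pcaVariation = x@pcaVariation,
       scaled = x@scaled, repeats = x@repeats)
}

#' Serialize an EvalReport to JSON
#'
#' @param x An [EvalReport-class].
#' @param path Output path.
#' @return Invisibly, the written path.
#' @export
writeEvalReport <- function(x, path) {
  stopifnot(is(x, "EvalReport"))
  obj <- c(reportProtocol(x),
           list(metrics = as.list(x@metrics), perClass = x@perClass))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

setMethod("show", "EvalReport", function(object) {
  cat(sprintf("EvalReport: %s, %s (%d splits), seed %d\n",
              object@classifier, object@protocol, object@repeats,
              object@seed))
  cat(sprintf("  dimension %d%s, scaling %s\n", object@dimension,
              if (is.na(object@pcaVariation)) ""
              else sprintf(" (PCA, variation %.2f)", object@pcaVariation),
              if (object@scaled) "on" else "off"))
  m <- object@metrics
  cat(sprintf(
    "  weighted: accuracy %.2f  precision %.2f  recall %.2f  F1 %.2f\n",
    m["accuracy"], m["precision"], m["recall"], m["f1"]))
})
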