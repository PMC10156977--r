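test_that("weighted metrics match the straight-line oracle", {
  # fixed 3-class confusion matrix
  cm <- matrix(c(8, 1, 1,
                 2, 6, 2,
                 0, 0, 10), 3, 3, byrow = TRUE)
  truth <- rep(c("a", "b", "c"), times = rowSums(cm))
  pred <- unlist(lapply(1:3, function(i)
    rep(c("a", "b", "c"), times = cm[i, ])))
  got <- weightedMetrics(confusionCounts(truth, pred))
  expect_equal(got, bruteWeightedMetrics(cm), tolerance = 1e-10,
               ignore_attr = TRUE)

  # perfect prediction
  perfect <- weightedMetrics(confusionCounts(truth, truth))
  expect_equal(unname(perfect), rep(100, 4))

  # random confusion matrices: oracle agreement plus the one-vs-rest
  # accuracy >= plain accuracy property
  set.seed(81)
  for (i in 1:200) {
    C <- sample(2:5, 1)
    cm <- matrix(rpois(C * C, 4), C, C)
    diag(cm) <- diag(cm) + rpois(C, 6)
    if (any(rowSums(cm) == 0)) next
    truth <- rep(seq_len(C), times = rowSums(cm))
    pred <- unlist(lapply(seq_len(C), function(r)
      rep(seq_len(C), times = cm[r, ])))
    got <- weightedMetrics(confusionCounts(as.character(truth),
                                           as.character(pred)))
    expect_equal(got, bruteWeightedMetrics(cm), tolerance = 1e-10,
                 ignore_attr = TRUE)
    plainAcc <- 100 * sum(diag(cm)) / sum(cm)
    expect_gte(got[["accuracy"]], plainAcc - 1e-9)
    # weighted recall equals plain multiclass accuracy
    expect_equal(got[["recall"]], plainAcc, tolerance = 1e-10)
    expect_true(all(got >= 0 & got <= 100 + 1e-9))
  }
  expect_error(weightedMetrics(data.frame(TP = -1, TN = 1, FP = 0,
                                          FN = 0, n = 1)), "negative")
})

test_that("PCA reduction respects the variance threshold and train/test separation", {
  set.seed(91)
  x <- matrix(rnorm(200 * 6), 200, 6)
  x[, 5] <- 3 * x[, 1] + rnorm(200, sd = 0.01)  # near-collinear
  x[, 6] <- 0                                    # constant column
  tr <- x[1:100, ]; te <- x[101:200, ]
  r85 <- pcaReduce(tr, te, 0.85)
  r99 <- pcaReduce(tr, te, 0.99)
  r100 <- pcaReduce(tr, te, 1.0)
  expect_lte(r85$d, r99$d)
  expect_lte(r99$d, r100$d)
  expect_equal(ncol(r85$train), r85$d)
  expect_equal(ncol(r85$test), r85$d)
  expect_equal(r100$d, qr(scale(tr[, 1:5]))$rank + 0L, tolerance = 0)
  expect_equal(r85$eigenvalues, sort(r85$eigenvalues, decreasing = TRUE))
  # two-feature toy data with one constant column
  toy <- cbind(rnorm(50), 1)
  rt <- pcaReduce(toy[1:25, ], toy[26:50, ], 0.99)
  expect_equal(rt$d, 1L)
  expect_error(pcaReduce(tr, te, 0), "variation")
  expect_error(pcaReduce(tr, te, 1.2), "variation")
})

# small separable two-class feature set used by several protocol tests
makeToySE <- function(n = 40, sep = 6, seed = 1) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n / 2 * 3), n / 2, 3),
             matrix(rnorm(n / 2 * 3, mean = sep), n / 2, 3))
  feat <- t(x)
  rownames(feat) <- paste0("f", 1:3)
  colnames(feat) <- paste0("s", seq_len(n))
  SummarizedExperiment::SummarizedExperiment(
    assays = list(features = feat),
    colData = S4Vectors::DataFrame(
      label = rep(c("a", "b"), each = n / 2),
      row.names = colnames(feat)))
}

test_that("separable data reach perfect weighted F1 with every classifier", {
  se <- makeToySE()
  for (clf in c("knn", "dt", "svm")) {
    rep <- evaluateProtocol(se, clf, seed = 2)
    expect_equal(reportMetrics(rep)[["f1"]], 100)
  }
  # cv5 protocol too
  repCV <- evaluateProtocol(se, "svm", protocol = "cv5", seed = 2)
  expect_equal(reportMetrics(repCV)[["f1"]], 100)
})

test_that("evaluation is deterministic for a fixed seed", {
  se <- makeToySE(sep = 1.2, seed = 9)
  r1 <- evaluateProtocol(se, "knn", seed = 7)
  r2 <- evaluateProtocol(se, "knn", seed = 7)
  expect_identical(reportMetrics(r1), reportMetrics(r2))
  expect_identical(reportPerClass(r1), reportPerClass(r2))
  r3 <- evaluateProtocol(se, "knn", seed = 8)
  # different seed draws different splits (metrics may differ)
  expect_false(identical(reportProtocol(r1)$seed, reportProtocol(r3)$seed))
})

test_that("protocol preconditions are enforced and metadata recorded", {
  se <- makeToySE()
  one <- se[, 1:20]  # single class
  expect_error(evaluateProtocol(one, "svm"), "2 classes")
  tiny <- se[, c(1, 21:40)]  # class "a" has one sample
  expect_error(evaluateProtocol(tiny, "svm"), "a")

  rep <- evaluateProtocol(se, "svm", seed = 3, pcaVariation = 0.95)
  meta <- reportProtocol(rep)
  expect_equal(meta$classifier, "svm")
  expect_equal(meta$protocol, "repeated-split")
  expect_equal(meta$pcaVariation, 0.95)
  expect_true(meta$scaled)
  expect_lte(meta$dimension, 3)
  p <- withr::local_tempfile(fileext = ".json")
  writeEvalReport(rep, p)
  js <- jsonlite::read_json(p)
  expect_equal(js$classifier, "svm")
  expect_equal(js$metrics$f1, reportMetrics(rep)[["f1"]])
})

test_that("assembled features have the right shape and labels", {
  out <- generateMarkovSequences(
    list(markovClassSpec("x", matrix(0.25, 4, 4), 5, c(60, 120)),
         markovClassSpec("y", matrix(0.25, 4, 4), 5, c(60, 120))),
    seed = 12)
  se40 <- assembleFeatures(out$sequences, out$labels$label)
  expect_equal(dim(se40), c(40L, 10L))
  expect_false(anyNA(SummarizedExperiment::assay(se40)))
  se44 <- assembleFeatures(out$sequences, out$labels$label,
                           includeClassic = TRUE, fdCap = 64)
  expect_equal(dim(se44), c(44L, 10L))
  expect_equal(rownames(se44)[41:44], c("SE", "HE", "MSE", "FD"))
  expect_error(assembleFeatures(out$sequences, rep("x", 10)), "2 classes")
})

test_that("failed Hurst exponents are imputed and flagged", {
  seqs <- Biostrings::DNAStringSet(c(
    ok1 = "ACGTTCAGGACCTGAATGCG", ok2 = "TGCATGCAAGGTTCACGTAC",
    bad = "AGAGAGAGAGAGAGAGAGAG",  # all purine -> zero-variance bits
    ok3 = "CCATGGTACGTTAGCATCGA"))
  expect_warning(
    se <- assembleFeatures(seqs, c("u", "v", "u", "v"),
                           includeClassic = TRUE, fdCap = 20),
    "imputed")
  expect_false(anyNA(SummarizedExperiment::assay(se)))
  expect_equal(unname(SummarizedExperiment::colData(se)$heImputed),
               c(FALSE, FALSE, TRUE, FALSE))
  he <- SummarizedExperiment::assay(se)["HE", ]
  expect_equal(unname(he[3]), mean(he[c(1, 2, 4)]))
})
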