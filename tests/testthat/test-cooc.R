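test_that("pattern sets match the fixed inventory", {
  sets <- coocPatternSets()
  expect_named(sets, c("I", "J", "K", "L", "M", "N", "O", "P"))
  expect_equal(sets$I, c("A", "C", "T", "G"))
  expect_equal(sets$J, c("AA", "CC", "TT", "GG"))
  expect_equal(sets$K, c("AC", "AT", "AG", "CT", "CG", "TG"))
  expect_equal(sets$L, c("CA", "TA", "GA", "TC", "GC", "GT"))
  expect_equal(sets$M, c("ACT", "ACG", "ATG", "CTG"))
  expect_equal(sets$N, c("CAT", "CAG", "TAG", "TCG"))
  expect_equal(sets$O, c("ATC", "AGC", "AGT", "CGT"))
  expect_equal(sets$P, c("TCA", "GCA", "GTA", "GTC"))
  # L is the set of reversals of K
  rev2 <- function(x) paste0(substr(x, 2, 2), substr(x, 1, 1))
  expect_setequal(vapply(sets$K, rev2, character(1)), sets$L)
})

test_that("co-occurrence counting matches hand-derived small cases", {
  m <- countCooc("AACG", "I")
  expect_equal(sum(counts(m)), 3)  # L - 1 adjacent pairs
  expect_equal(counts(m)["A", "A"], 1, ignore_attr = TRUE)
  expect_equal(counts(m)["A", "C"], 1, ignore_attr = TRUE)
  expect_equal(counts(m)["C", "G"], 1, ignore_attr = TRUE)

  m2 <- countCooc("AAAA", "I")
  expect_equal(counts(m2)["A", "A"], 3, ignore_attr = TRUE)
  expect_equal(normalizedCounts(m2)["A", "A"], 1, ignore_attr = TRUE)

  mj <- counts(countCooc("AAAC", "J"))
  expect_equal(mj["AA", "A"], 1, ignore_attr = TRUE)  # from "AAA"
  expect_equal(mj["AA", "C"], 1, ignore_attr = TRUE)  # from "AAC"
  expect_equal(sum(mj), 2)

  mm <- counts(countCooc("ACGT", "M"))
  expect_equal(mm["ACG", "T"], 1, ignore_attr = TRUE)
  expect_equal(sum(mm), 1)
})

test_that("counting agrees with the brute-force oracle on random sequences", {
  set.seed(42)
  sets <- coocPatternSets()
  for (rep in seq_len(200)) {
    s <- randomDNA(sample(5:500, 1))
    nm <- names(sets)[((rep - 1) %% 8) + 1]  # rotate through all 8 sets
    got <- suppressWarnings(counts(countCooc(s, nm)))
    want <- bruteCooc(s, sets[[nm]])
    expect_equal(got, want, ignore_attr = TRUE)
  }
  # every set on a handful of sequences
  for (i in 1:10) {
    s <- randomDNA(sample(5:200, 1))
    for (nm in names(sets)) {
      expect_equal(suppressWarnings(counts(countCooc(s, nm))),
                   bruteCooc(s, sets[[nm]]), ignore_attr = TRUE)
    }
  }
})

test_that("set-I grand total is L - 1 and normalization sums to one", {
  set.seed(7)
  for (i in 1:25) {
    L <- sample(2:300, 1)
    s <- randomDNA(L)
    m <- countCooc(s, "I")
    expect_equal(sum(counts(m)), L - 1)
    expect_equal(sum(normalizedCounts(m)), 1, tolerance = 1e-12)
  }
})

test_that("degenerate short sequences give all-zero matrices with a warning", {
  expect_warning(m <- countCooc("AC", "M"), "all-zero")
  expect_true(all(counts(m) == 0))
  expect_true(all(normalizedCounts(m) == 0))
  expect_equal(unname(textureFeatures(m)), rep(0, 5))
})

test_that("texture features match closed forms and stay in range", {
  u <- textureFeatures(matrix(1 / 16, 4, 4))
  expect_equal(u[["energy"]], 1 / 16)

  diagm <- diag(4) / 4
  d <- textureFeatures(diagm)
  expect_equal(d[["contrast"]], 0)
  expect_equal(d[["dissimilarity"]], 0)
  expect_equal(d[["homogeneity"]], 1)

  single <- matrix(0, 4, 4); single[2, 3] <- 1
  s <- textureFeatures(single)
  expect_equal(s[["entropy"]], 0)
  expect_equal(s[["energy"]], 1)

  # invariant ranges on random normalized matrices (incl. 6 x 4 shapes)
  set.seed(99)
  for (i in 1:50) {
    q <- sample(c(4, 6), 1)
    g <- matrix(rexp(q * 4), q, 4)
    g <- g / sum(g)
    tf <- textureFeatures(g)
    expect_gte(tf[["energy"]], 0); expect_lte(tf[["energy"]], 1)
    expect_gte(tf[["entropy"]], 0)
    expect_gte(tf[["homogeneity"]], 0); expect_lte(tf[["homogeneity"]], 1)
    expect_gte(tf[["contrast"]], 0)
    expect_gte(tf[["dissimilarity"]], 0)
  }
})

test_that("the 40-dimensional vector concatenates the eight matrices in order", {
  set.seed(13)
  s <- randomDNA(400)
  v <- coocFeatureVector(s)
  expect_length(v, 40)
  expect_named(v, paste0("f", 1:40))
  expect_equal(unname(v[1:5]),
               unname(textureFeatures(countCooc(s, "I"))))
  expect_equal(unname(v[16:20]),
               unname(textureFeatures(countCooc(s, "L"))))
  expect_equal(unname(v[36:40]),
               unname(textureFeatures(countCooc(s, "P"))))
})

test_that("a mononucleotide sequence loads only the I and J blocks", {
  s <- strrep("A", 1000)
  v <- suppressWarnings(coocFeatureVector(s))
  expect_equal(unname(v[1:5]), c(1, 0, 1, 0, 0))  # all mass on (A,A)
  # J: all mass in the (AA, A) cell -> same closed form
  expect_equal(unname(v[6:10]), c(1, 0, 1, 0, 0))
  expect_equal(unname(v[11:40]), rep(0, 30))
})

test_that("reversal changes the K vs L blocks for a non-palindromic sequence", {
  s <- "AACGTT"
  r <- paste(rev(strsplit(s, "")[[1]]), collapse = "")
  vs <- suppressWarnings(coocFeatureVector(s))
  vr <- suppressWarnings(coocFeatureVector(r))
  expect_false(isTRUE(all.equal(vs[11:20], vr[11:20])))
})
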