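test_that("Bray-Curtis matches the closed form", {
  cm <- cmat(rbind(c(1, 0), c(0, 1)))
  expect_equal(dissValues(brayCurtis(cm))[2, 1], 1)          # disjoint
  cm2 <- cmat(rbind(c(3, 7, 2), c(3, 7, 2)))
  expect_equal(dissValues(brayCurtis(cm2))[2, 1], 0)         # identical
  cm3 <- cmat(rbind(c(6, 2, 0), c(2, 2, 4)))
  expect_equal(dissValues(brayCurtis(cm3))[2, 1], 8 / 16)    # hand sum
  expect_error(brayCurtis(cmat(rbind(c(0, 0), c(1, 2)))), "0/0")
})

test_that("Bray-Curtis ignores taxa absent from both samples of a pair", {
  cm <- randomCommunity(5, 6, seed = 2)
  withZero <- cmat(cbind(counts(cm), extra = 0L),
                   samples = sampleIDs(cm), taxa = c(taxonIDs(cm), "extra"))
  expect_equal(dissValues(brayCurtis(withZero)), dissValues(brayCurtis(cm)))
})

test_that("alternative measures match closed forms", {
  # the 3-4-5 triangle pair; all-zero rows are legal for these measures
  cmE <- CommunityMatrix(rbind(c(3, 4), c(0, 0)),
                         sampleIDs = c("a", "b"), taxonIDs = c("t1", "t2"))
  expect_equal(dissValues(altDissimilarity(cmE, "euclidean"))[2, 1], 5)
  expect_equal(dissValues(altDissimilarity(cmE, "cityblock"))[2, 1], 7)
  expect_error(altDissimilarity(cmE, "jaccard"))
})

test_that("Monte-Carlo Raup-Crick is bounded, symmetric and near-minimal for clones", {
  cm <- cmat(rbind(c(5, 3, 2, 0, 0), c(5, 3, 2, 0, 0), c(0, 0, 1, 4, 4)))
  d <- altDissimilarity(cm, "raup_crick", nNull = 499, seed = 7)
  v <- dissValues(d)
  expect_true(all(v >= 0 & v <= 1))
  expect_equal(v, t(v))
  # identical presence sets attain the matrix minimum, at the exact
  # hypergeometric tail P(shared >= 3 | 5 taxa, richness 3 and 3) = 0.1
  expect_equal(v[2, 1], min(v[upper.tri(v)]))
  expect_equal(v[2, 1], phyper(2, 3, 2, 3, lower.tail = FALSE),
               tolerance = 0.35)
  expect_gt(v[3, 1], v[2, 1])
  # deterministic given seed
  d2 <- altDissimilarity(cm, "raup_crick", nNull = 499, seed = 7)
  expect_identical(dissValues(d2), v)
})

test_that("all measures give symmetric non-negative zero-diagonal matrices", {
  for (seed in 1:5) {
    cm <- randomCommunity(6, 8, seed = seed)
    mats <- list(brayCurtis(cm),
                 altDissimilarity(cm, "euclidean"),
                 altDissimilarity(cm, "cityblock"),
                 altDissimilarity(cm, "raup_crick", nNull = 99, seed = seed))
    for (d in mats) {
      v <- dissValues(d)
      expect_equal(v, t(v))
      expect_true(all(diag(v) == 0))
      expect_true(all(v >= 0))
    }
  }
})

test_that("Bray-Curtis agrees with the vegan reference", {
  cm <- randomCommunity(7, 10, seed = 31)
  expect_equal(c(as.dist(dissValues(brayCurtis(cm)))),
               c(vegan::vegdist(counts(cm), "bray")), tolerance = 1e-12)
})

test_that("dissimilarity CSV export round-trips", {
  cm <- randomCommunity(4, 5, seed = 5)
  d <- brayCurtis(cm)
  f <- withr::local_tempfile(fileext = ".csv")
  writeDissimilarity(d, f)
  df <- read.csv(f, check.names = FALSE)
  expect_equal(as.matrix(df[, -1]), dissValues(d),
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("the Mantel decline pattern is measure-agnostic (parity pilot)", {
  # three gradient datasets, four dissimilarity measures: the mean Mantel R
  # curve over the five proportions must rank near-identically
  measures <- c("bray", "euclidean", "cityblock", "raup_crick")
  dissOf <- function(cm, meas, seed) {
    if (meas == "bray") brayCurtis(cm)
    else altDissimilarity(cm, meas, nNull = 99, seed = seed)
  }
  props <- c(0.50, 0.25, 0.10, 0.05, 0.025)
  curveOf <- matrix(0, length(props), length(measures),
                    dimnames = list(NULL, measures))
  for (ds in 1:3) {
    cm <- simulateGradientDataset(randomGradientSpec(15, 15, 100,
                                                     seed = 500 + ds))
    complete <- lapply(measures, function(ms) dissOf(cm, ms, seed = ds))
    names(complete) <- measures
    for (pi in seq_along(props)) {
      for (r in 1:8) {
        sub <- subsampleMatrix(cm, props[pi],
                               seed = commsize:::deriveSeed(600, ds, pi, r))
        for (ms in measures) {
          D2 <- dissOf(sub, ms, seed = commsize:::deriveSeed(700, ds, pi, r))
          curveOf[pi, ms] <- curveOf[pi, ms] +
            mantelTest(complete[[ms]], D2, 0L)@r / (3 * 8)
        }
      }
    }
  }
  for (i in 1:3) for (j in (i + 1):4) {
    expect_gte(cor(curveOf[, i], curveOf[, j], method = "spearman"), 0.9)
  }
})
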