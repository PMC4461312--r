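test_that("Mantel r reproduces hand-computed correlations", {
  D1 <- d3(c(1, 2, 3))
  expect_equal(mantelTest(D1, D1, 99, seed = 1)@r, 1)
  expect_equal(mantelTest(D1, d3(c(3, 2, 1)), 0L)@r, -1)
  expect_equal(mantelTest(D1, d3(c(1, 3, 2)), 0L)@r, 0.5)
})

test_that("Mantel permutation p matches exhaustive enumeration on small n", {
  set.seed(15)
  for (i in 1:4) {
    n <- sample(4:5, 1)
    v1 <- as.matrix(dist(matrix(rnorm(n * 2), n, 2)))
    v2 <- as.matrix(dist(matrix(rnorm(n * 2), n, 2)))
    D1 <- dmat(v1); D2 <- dmat(v2)
    oracle <- mantelEnumOracle(D1, D2)
    res <- mantelTest(D1, D2, 999, seed = i)
    expect_equal(res@r, oracle$r, tolerance = 1e-12)
    # Monte-Carlo estimate within sampling error of the exact p
    se <- sqrt(oracle$p * (1 - oracle$p) / 1000)
    expect_lt(abs(res@pValue - oracle$p), 4 * se + 2e-3)
  }
})

test_that("Mantel agrees with vegan and is symmetric in its arguments", {
  cm1 <- randomCommunity(8, 10, seed = 51)
  cm2 <- cmat(counts(subsampleMatrix(cm1, 0.5, seed = 2)))
  D1 <- brayCurtis(cm1)
  D2 <- brayCurtis(cm2)
  ref <- vegan::mantel(as.dist(dissValues(D1)), as.dist(dissValues(D2)),
                       permutations = 99)
  expect_equal(mantelTest(D1, D2, 0L)@r, unname(ref$statistic),
               tolerance = 1e-12)
  expect_equal(mantelTest(D1, D2, 0L)@r, mantelTest(D2, D1, 0L)@r)
})

test_that("Mantel contract errors fire", {
  D1 <- d3(c(1, 2, 3))
  big <- dmat(as.matrix(dist(matrix(rnorm(8), 4, 2))))
  expect_error(mantelTest(D1, big), "mismatch|same samples")
  expect_warning(res <- mantelTest(D1, d3(c(2, 2, 2)), 99, seed = 1),
                 "zero variance")
  expect_true(is.na(res@r))
})

test_that("Procrustes aligns exact similarity transforms to zero residual", {
  set.seed(7)
  X <- matrix(rnorm(12), 6, 2)
  th <- pi / 2
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  Y <- 2 * X %*% R + rep(c(3, -1), each = 6)
  expect_lt(procrustesFit(X, Y)$ssResidual, 1e-10)
  # reflections are permitted
  expect_lt(procrustesFit(X, X %*% diag(c(1, -1)))$ssResidual, 1e-10)
  # transform slots satisfy their contracts
  fit <- procrustesFit(X, Y, symmetric = FALSE)
  Rhat <- fit$transform@rotation
  expect_equal(crossprod(Rhat), diag(2), tolerance = 1e-10)
  expect_gt(fit$transform@scale, 0)
  expect_error(procrustesFit(X, matrix(1, 6, 2)), "degenerate")
})

test_that("Procrustes residual matches a numeric grid/local-search oracle", {
  set.seed(23)
  for (i in 1:4) {
    X <- matrix(rnorm(10), 5, 2)
    Y <- matrix(rnorm(10), 5, 2)
    fit <- procrustesFit(X, Y, symmetric = FALSE)
    expect_equal(fit$ssResidual, procrustesGridOracle(X, Y),
                 tolerance = 1e-6)
  }
})

test_that("Procrustes and PROTEST agree with the vegan reference", {
  set.seed(31)
  X <- matrix(rnorm(16), 8, 2)
  Y <- matrix(rnorm(16), 8, 2)
  expect_equal(procrustesFit(X, Y, symmetric = TRUE)$ssResidual,
               vegan::procrustes(X, Y, symmetric = TRUE)$ss,
               tolerance = 1e-10)
  ref <- vegan::protest(X, Y, permutations = 199)
  mine <- protestTest(X, Y, 199, seed = 5)
  expect_equal(mine@concordance, unname(ref$t0)^2, tolerance = 1e-10)
  expect_equal(mine@ssResidual, unname(ref$ss), tolerance = 1e-10)
})

test_that("PROTEST concordance is a similarity-invariant 0-1 statistic", {
  set.seed(19)
  X <- matrix(rnorm(14), 7, 2)
  Y <- matrix(rnorm(14), 7, 2)
  base <- protestTest(X, Y, 0L)@concordance
  th <- 1.1
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  expect_equal(protestTest(5 * X %*% R + 2, Y %*% diag(c(-1, 1)) / 3,
                           0L)@concordance,
               base, tolerance = 1e-10)
  expect_true(base >= 0 && base <= 1)
  # perfect fit: concordance 1 and small p against the permutation null
  res <- protestTest(X, 2 * X %*% R + 1, 999, seed = 2)
  expect_equal(res@concordance, 1, tolerance = 1e-10)
  expect_lte(res@pValue, 0.01)
})

test_that("PROTEST p at n = 3 matches exhaustive enumeration", {
  set.seed(77)
  X <- matrix(rnorm(6), 3, 2)
  Y <- matrix(rnorm(6), 3, 2)
  conc <- function(A, B) {
    As <- scale(A, scale = FALSE); Bs <- scale(B, scale = FALSE)
    As <- As / sqrt(sum(As^2)); Bs <- Bs / sqrt(sum(Bs^2))
    sum(svd(crossprod(Bs, As))$d)^2
  }
  obs <- conc(X, Y)
  perms <- gtoolsPermutations(3)
  exact <- mean(apply(perms, 1, function(p) conc(X, Y[p, ])) >= obs - 1e-12)
  res <- protestTest(X, Y, 999, seed = 8)
  se <- sqrt(exact * (1 - exact) / 1000)
  expect_lt(abs(res@pValue - exact), 4 * se + 2e-3)
})

test_that("comparison results serialise to a tidy table", {
  D1 <- d3(c(1, 2, 3))
  mt <- mantelTest(D1, d3(c(1, 3, 2)), 99, seed = 1)
  pt <- protestTest(matrix(rnorm(8), 4, 2), matrix(rnorm(8), 4, 2),
                    99, seed = 1)
  tab <- comparisonTable(mt, pt, seed = 1L)
  expect_equal(nrow(tab), 2L)
  expect_equal(tab$statistic, c("mantel_r", "protest_concordance"))
})

test_that("Mantel r is invariant to a common relabelling of both matrices", {
  cm <- randomCommunity(7, 9, seed = 55)
  D1 <- brayCurtis(cm)
  D2 <- brayCurtis(cmat(counts(subsampleMatrix(cm, 0.5, seed = 1))))
  r0 <- mantelTest(D1, D2, 0L)@r
  set.seed(3)
  p <- sample(7)
  relab <- function(D) {
    v <- dissValues(D)[p, p]
    dimnames(v) <- list(rownames(v), rownames(v))
    dmat(v)
  }
  expect_equal(mantelTest(relab(D1), relab(D2), 0L)@r, r0, tolerance = 1e-12)
})
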