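#' Mantel permutation test between two dissimilarity matrices
#'
#' The R-statistic is the Pearson correlation of the two matrices'
#' vectorised off-diagonal entries, so it behaves like an ordinary product
#' moment correlation between the two sets of pairwise dissimilarities.
#' The null distribution is obtained by jointly permuting the rows and
#' columns of the second matrix (a random relabelling of its samples) and
#' the one-tailed p-value uses the observed-included convention
#' p = (#\{r_perm >= r_obs\} + 1) / (nPermutations + 1).
#'
#' @param D1,D2 [DissimilarityMatrix-class] objects over the same samples
#'   in the same order (n >= 3).
#' @param nPermutations permutation count (default 999; 0 skips the test
#'   and returns `NA` for p).
#' @param seed integer seed; the test is deterministic given `seed`.
#' @return a [MantelResult-class].
#' @export
mantelTest <- function(D1, D2, nPermutations = 999L, seed = NULL) {
  m1 <- dissValues(D1)
  m2 <- dissValues(D2)
  n <- nrow(m1)
  if (n != nrow(m2)) stop("dimension mismatch between D1 and D2")
  if (!identical(rownames(m1), rownames(m2)))
    stop("D1 and D2 must cover the same samples in the same order")
  if (n < 3L) stop("need at least 3 samples")
  lt <- lower.tri(m1)
  v1 <- m1[lt]
  v2 <- m2[lt]
  if (stats::sd(v1) == 0 || stats::sd(v2) == 0) {
    warning("zero variance in off-diagonal dissimilarities; r undefined")
    return(new("MantelResult", r = NA_real_, pValue = NA_real_,
               nPermutations = as.integer(nPermutations)))
  }
  r <- stats::cor(v1, v2)
  if (nPermutations < 1L)
    return(new("MantelResult", r = r, pValue = NA_real_,
               nPermutations = 0L))
  ij <- which(lt, arr.ind = TRUE)
  ij1 <- ij[, 1L]
  ij2 <- ij[, 2L]
  # mean and sd of the permuted vector equal those of v2 (same values),
  # so only the cross-product changes across permutations
  v1c <- v1 - mean(v1)
  denom <- sqrt(sum(v1c^2)) * stats::sd(v2) * sqrt(length(v1) - 1)
  p <- withSeed(seed, {
    hits <- 0L
    for (b in seq_len(nPermutations)) {
      pm <- sample.int(n)
      v2p <- m2[(pm[ij2] - 1L) * n + pm[ij1]]
      if (sum(v1c * v2p) / denom >= r) hits <- hits + 1L
    }
    (hits + 1) / (nPermutations + 1)
  })
  new("MantelResult", r = r, pValue = p,
      nPermutations = as.integer(nPermutations))
}

setMethod("show", "MantelResult", function(object) {
  cat(sprintf("Mantel test: r = %.4f, p = %s (%d permutations)\n",
              object@r,
              if (is.na(object@pValue)) "NA" else
                format(object@pValue, digits = 4),
              object@nPermutations))
})

#' Procrustes superimposition of one configuration onto another
#'
#' Finds the translation, rotation/reflection and dilation of `Y` that
#' minimises the sum of squared distances to `X`.  With
#' `symmetric = TRUE` (default) both configurations are first centred and
#' scaled to unit sum of squares, making the residual symmetric in the two
#' arguments; `symmetric = FALSE` gives the classical asymmetric best fit
#' of raw `Y` onto raw `X`.
#'
#' @param X,Y numeric n x k configurations with matched rows (same samples,
#'   same order).
#' @param symmetric logical, see above.
#' @return a list with elements `transform` (a
#'   [ProcrustesTransform-class]), `Yfitted` (Y after the transform, on the
#'   scale of `X` as used in the fit) and `ssResidual`.
#' @export
procrustesFit <- function(X, Y, symmetric = TRUE) {
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  if (!all(dim(X) == dim(Y))) stop("X and Y must have the same shape")
  cx <- colMeans(X)
  cy <- colMeans(Y)
  Xc <- sweep(X, 2L, cx)
  Yc <- sweep(Y, 2L, cy)
  ssx <- sum(Xc^2)
  ssy <- sum(Yc^2)
  if (ssx == 0 || ssy == 0) stop("degenerate configuration: all points identical")
  if (symmetric) {
    Xc <- Xc / sqrt(ssx)
    Yc <- Yc / sqrt(ssy)
    ssx <- ssy <- 1
  }
  sv <- svd(crossprod(Yc, Xc))
  R <- sv$u %*% t(sv$v)            # orthogonal, reflection allowed
  sc <- sum(sv$d) / ssy            # optimal dilation
  Yrot <- sc * Yc %*% R
  ss <- sum((Xc - Yrot)^2)
  transl <- as.numeric(cx - sc * cy %*% R)
  fitted <- if (symmetric) Yrot else sweep(Yrot, 2L, cx, "+")
  list(transform = new("ProcrustesTransform", rotation = R, scale = sc,
                       translation = if (symmetric) numeric(ncol(X))
                                     else transl),
       Yfitted = fitted,
       ssResidual = ss)
}

#' PROTEST: permutation test of Procrustes concordance
#'
#' The observed statistic is `concordance = 1 - ssResidual` from the
#' symmetric Procrustes fit (both configurations normalised to unit sum of
#' squares), so it lies in [0, 1] with 1 meaning the ordinations are
#' identical up to translation, reflection, rotation and dilation.  This is
#' the orientation in which the community literature reports its
#' "m2-values" (closer to 1 = more similar).  The null permutes the row
#' order of `Y` and refits; the one-tailed p-value uses the
#' observed-included convention.
#'
#' @param X,Y configurations or [Ordination-class] objects with matched
#'   rows (n >= 3).
#' @param nPermutations default 999; 0 skips the test (p = `NA`).
#' @param seed integer seed.
#' @return a [ProtestResult-class].
#' @export
protestTest <- function(X, Y, nPermutations = 999L, seed = NULL) {
  if (is(X, "Ordination")) X <- ordCoords(X)
  if (is(Y, "Ordination")) Y <- ordCoords(Y)
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  if (!all(dim(X) == dim(Y))) stop("X and Y must have the same shape")
  if (nrow(X) < 3L) stop("need at least 3 samples")
  Xc <- sweep(X, 2L, colMeans(X))
  Yc <- sweep(Y, 2L, colMeans(Y))
  ssx <- sum(Xc^2)
  ssy <- sum(Yc^2)
  if (ssx == 0 || ssy == 0) stop("degenerate configuration: all points identical")
  Xs <- Xc / sqrt(ssx)
  Ys <- Yc / sqrt(ssy)
  conc <- sum(svd(crossprod(Ys, Xs))$d)^2
  conc <- min(conc, 1)             # guard rounding above 1
  if (nPermutations < 1L)
    return(new("ProtestResult", concordance = conc, ssResidual = 1 - conc,
               pValue = NA_real_, nPermutations = 0L))
  n <- nrow(X)
  p <- withSeed(seed, {
    hits <- 0L
    for (b in seq_len(nPermutations)) {
      cp <- sum(svd(crossprod(Ys[sample.int(n), , drop = FALSE], Xs))$d)^2
      if (cp >= conc) hits <- hits + 1L
    }
    (hits + 1) / (nPermutations + 1)
  })
  new("ProtestResult", concordance = conc, ssResidual = 1 - conc,
      pValue = p, nPermutations = as.integer(nPermutations))
}

setMethod("show", "ProtestResult", function(object) {
  cat(sprintf("PROTEST: concordance = %.4f, p = %s (%d permutations)\n",
              object@concordance,
              if (is.na(object@pValue)) "NA" else
                format(object@pValue, digits = 4),
              object@nPermutations))
})

#' Serialise comparison statistics to a tidy data.frame
#'
#' @param ... [MantelResult-class] or [ProtestResult-class] objects.
#' @param seed optional seed to record alongside.
#' @return data.frame with columns statistic, value, p_value,
#'   n_permutations, seed.
#' @export
comparisonTable <- function(..., seed = NA_integer_) {
  rows <- lapply(list(...), function(r) {
    if (is(r, "MantelResult"))
      data.frame(statistic = "mantel_r", value = r@r, p_value = r@pValue,
                 n_permutations = r@nPermutations, seed = seed)
    else if (is(r, "ProtestResult"))
      data.frame(statistic = "protest_concordance", value = r@concordance,
                 p_value = r@pValue, n_permutations = r@nPermutations,
                 seed = seed)
    else stop("unsupported result type")
  })
  do.call(rbind, rows)
}
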