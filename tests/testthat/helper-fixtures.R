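# Shared fixtures and independent oracles for the test suite.

cmat <- function(m, samples = NULL, taxa = NULL) {
  if (is.null(samples)) samples <- sprintf("s%02d", seq_len(nrow(m)))
  if (is.null(taxa)) taxa <- sprintf("t%02d", seq_len(ncol(m)))
  CommunityMatrix(m, sampleIDs = samples, taxonIDs = taxa)
}

randomCommunity <- function(n, S, seed, lambda = 20) {
  set.seed(seed)
  m <- matrix(rpois(n * S, lambda), n, S)
  m[, colSums(m) == 0] <- 1   # keep every taxon observed
  cmat(m)
}

dmat <- function(v, measure = "test") {
  if (is.null(rownames(v)))
    dimnames(v) <- list(sprintf("s%02d", seq_len(nrow(v))),
                        sprintf("s%02d", seq_len(nrow(v))))
  new("DissimilarityMatrix", values = v, measure = measure)
}

# 3x3 dissimilarity matrix from its off-diagonal entries (d12, d13, d23)
d3 <- function(off) {
  v <- matrix(0, 3, 3)
  v[lower.tri(v)] <- off
  v <- v + t(v)
  dmat(v)
}

# --- independent oracles -------------------------------------------------

# exact one-tailed Mantel p by enumerating all n! relabellings of D2
mantelEnumOracle <- function(D1, D2) {
  m1 <- dissValues(D1)
  m2 <- dissValues(D2)
  n <- nrow(m1)
  lt <- lower.tri(m1)
  v1 <- m1[lt]
  robs <- cor(v1, m2[lt])
  perms <- gtoolsPermutations(n)
  rs <- apply(perms, 1L, function(p) cor(v1, m2[p, p][lt]))
  list(r = robs, p = mean(rs >= robs - 1e-12))
}

# all permutations of 1..n (small n only)
gtoolsPermutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- gtoolsPermutations(n - 1L)
  out <- NULL
  for (i in seq_len(n)) {
    rest <- seq_len(n)[-i]
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub))))
  }
  unname(out)
}

# asymmetric Procrustes residual by numeric search over rotation angle and
# reflection, with closed-form optimal scale/translation per angle
procrustesGridOracle <- function(X, Y) {
  Xc <- scale(X, scale = FALSE)
  Yc <- scale(Y, scale = FALSE)
  ssFor <- function(theta, refl) {
    R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
    if (refl) R <- R %*% diag(c(1, -1))
    YR <- Yc %*% R
    sc <- sum(Xc * YR) / sum(YR^2)
    sum((Xc - sc * YR)^2)
  }
  best <- Inf
  for (refl in c(FALSE, TRUE)) {
    coarse <- vapply(seq(0, 2 * pi, length.out = 720), ssFor,
                     numeric(1), refl = refl)
    th0 <- seq(0, 2 * pi, length.out = 720)[which.min(coarse)]
    opt <- optimize(ssFor, c(th0 - 0.02, th0 + 0.02), refl = refl,
                    tol = 1e-12)
    best <- min(best, opt$objective)
  }
  best
}

# brute-force subsample draw by shuffling the expanded individual pool
subsampleShuffleOracle <- function(x, k) {
  pool <- rep(seq_along(x), x)
  tabulate(sample(pool, k), nbins = length(x))
}
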