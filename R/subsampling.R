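#' Subsampling scheme constructor
#'
#' Five proportional sizes (50%, 25%, 10%, 5%, 2.5% of each sample's
#' individuals) with 1000 replicates per proportion by default, i.e. 5000
#' subsampled matrices per dataset.
#'
#' @param proportions fractions in (0, 1].
#' @param nReplicates replicates per proportion.
#' @param seed master integer seed.
#' @return a [SubsampleScheme-class].
#' @export
SubsampleScheme <- function(proportions = c(0.50, 0.25, 0.10, 0.05, 0.025),
                            nReplicates = 1000L, seed = 1L) {
  new("SubsampleScheme", proportions = as.numeric(proportions),
      nReplicates = as.integer(nReplicates), seed = as.integer(seed))
}

#' Draw k individuals without replacement from one sample
#'
#' A multivariate-hypergeometric draw: the sample's individuals form a
#' pool labelled by taxon and k of them are taken uniformly without
#' replacement.  Implemented as sequential conditional hypergeometric
#' draws per taxon (no explicit pool expansion), so it is O(taxa) per
#' sample.
#'
#' @param x non-negative integer count vector.
#' @param k number of individuals to retain, 0 <= k <= sum(x).
#' @param seed optional seed; when `NULL` the current RNG stream is used.
#' @return integer vector summing to `k` with every component <= `x`.
#' @export
subsampleCounts <- function(x, k, seed = NULL) {
  N <- sum(x)
  if (k > N) stop("k exceeds the number of individuals in the sample")
  if (k < 0) stop("k must be non-negative")
  draw <- function() {
    out <- numeric(length(x))
    left <- N
    need <- k
    for (i in seq_along(x)) {
      if (need == 0) break
      # individuals of taxon i among the `need` drawn from `left` remaining
      xi <- rhyper(1L, x[i], left - x[i], need)
      out[i] <- xi
      need <- need - xi
      left <- left - x[i]
    }
    out
  }
  if (is.null(seed)) draw() else withSeed(seed, draw())
}

#' Subsample every sample of a matrix to a fixed proportion
#'
#' Each row is independently reduced to k = max(1, round(p * rowsum))
#' individuals (round-half-up), drawn without replacement; the floor of 1
#' keeps every sample non-empty so Bray-Curtis stays defined at the
#' smallest proportions.  Taxon columns left with no individuals anywhere
#' are dropped; the row count is always preserved.
#'
#' @param x a [CommunityMatrix-class].
#' @param proportion fraction in (0, 1].
#' @param seed optional seed (`NULL` = current RNG stream).
#' @return a [CommunityMatrix-class].
#' @export
subsampleMatrix <- function(x, proportion, seed = NULL) {
  if (proportion <= 0 || proportion > 1)
    stop("proportion must lie in (0, 1]")
  m <- counts(x)
  run <- function() {
    # same sequential conditional-hypergeometric scheme as
    # subsampleCounts(), vectorised across rows: one rhyper call per taxon
    out <- m
    left <- rowSums(m)
    need <- pmax(1, halfUp(proportion * left))
    for (t in seq_len(ncol(m))) {
      xt <- rhyper(nrow(m), m[, t], left - m[, t], need)
      out[, t] <- xt
      need <- need - xt
      left <- left - m[, t]
    }
    keep <- colSums(out) > 0
    if (sum(keep) < 2L)
      stop("degenerate subsample: fewer than 2 taxa retained")
    CommunityMatrix(out[, keep, drop = FALSE], metadata = x@metadata)
  }
  if (is.null(seed)) run() else withSeed(seed, run())
}

#' Deterministic replicate grid for a subsampling scheme
#'
#' Enumerates every (proportion, replicate) cell of the scheme with its
#' derived seed, so replicates are independent work units that can be run
#' in any order and reproduced individually.
#'
#' @param scheme a [SubsampleScheme-class].
#' @return data.frame with columns proportion, replicate, seed.
#' @export
replicateGrid <- function(scheme) {
  g <- expand.grid(replicate = seq_len(scheme@nReplicates),
                   pIndex = seq_along(scheme@proportions))
  data.frame(proportion = scheme@proportions[g$pIndex],
             replicate = g$replicate,
             seed = mapply(function(p, r) deriveSeed(scheme@seed, p, r),
                           g$pIndex, g$replicate))
}

#' Stream subsample replicates through a function
#'
#' Applies `FUN(subsampledMatrix, proportion, replicate)` to every cell of
#' the replicate grid, generating each subsampled matrix lazily (one in
#' memory at a time).
#'
#' @param x a [CommunityMatrix-class].
#' @param scheme a [SubsampleScheme-class].
#' @param FUN function of (matrix, proportion, replicate); its results are
#'   returned as a list in grid order.  The default returns the matrices
#'   themselves (memory-heavy for large schemes).
#' @return list of `FUN` results, one per (proportion, replicate).
#' @export
replicateStream <- function(x, scheme,
                            FUN = function(m, p, r) m) {
  grid <- replicateGrid(scheme)
  lapply(seq_len(nrow(grid)), function(i) {
    sub <- subsampleMatrix(x, grid$proportion[i], seed = grid$seed[i])
    FUN(sub, grid$proportion[i], grid$replicate[i])
  })
}
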