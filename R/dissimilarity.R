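#' Bray-Curtis dissimilarity between all sample pairs
#'
#' d(x, y) = sum |x_i - y_i| / sum (x_i + y_i), computed on raw counts: no
#' standardisation or transformation is applied anywhere in this package
#' (ordinations are likewise run without auto-transformation), so the
#' dissimilarities reflect absolute abundance structure.
#'
#' @param x a [CommunityMatrix-class]; no sample may be all-zero.
#' @return a [DissimilarityMatrix-class] with entries in [0, 1].
#' @examples
#' cm <- CommunityMatrix(matrix(c(6, 2, 2, 2, 0, 4), 2, 3,
#'        dimnames = list(c("a", "b"), c("t1", "t2", "t3"))))
#' dissValues(brayCurtis(cm))["a", "b"]  # 0.5
#' @export
brayCurtis <- function(x) {
  m <- counts(x)
  if (any(rowSums(m) == 0))
    stop("undefined dissimilarity (0/0): matrix contains all-zero samples")
  v <- as.matrix(vegan::vegdist(m, method = "bray"))
  diag(v) <- 0
  new("DissimilarityMatrix", values = v, measure = "bray")
}

#' Alternative dissimilarity measures
#'
#' The distance-measure parity companions to [brayCurtis()]: Euclidean,
#' city-block (Manhattan), and a Monte-Carlo Raup-Crick.  The Raup-Crick
#' variant works on presence/absence: for each pair it estimates the
#' probability, under a null that fixes each sample's richness and treats
#' all observed taxa as equiprobable, that two random samples share at
#' least as many taxa as observed (observed-included convention), so
#' strongly overlapping samples score near 0 and disjoint ones near 1.
#'
#' @param x a [CommunityMatrix-class].
#' @param measure one of `"euclidean"`, `"cityblock"`, `"raup_crick"`.
#' @param nNull Monte-Carlo draws for the Raup-Crick null (default 999).
#' @param seed seed for the Raup-Crick randomisation.
#' @return a [DissimilarityMatrix-class].
#' @export
altDissimilarity <- function(x, measure = c("euclidean", "cityblock",
                                            "raup_crick"),
                             nNull = 999L, seed = NULL) {
  measure <- match.arg(measure)
  m <- counts(x)
  v <- switch(measure,
    euclidean = as.matrix(vegan::vegdist(m, method = "euclidean")),
    cityblock = as.matrix(vegan::vegdist(m, method = "manhattan")),
    raup_crick = raupCrickMC(m, nNull = nNull, seed = seed))
  diag(v) <- 0
  new("DissimilarityMatrix", values = v, measure = measure)
}

# Monte-Carlo Raup-Crick on presence/absence: null preserves per-sample
# richness, taxa equiprobable over the observed taxon pool.
raupCrickMC <- function(m, nNull = 999L, seed = NULL) {
  pa <- m > 0
  n <- nrow(pa)
  Tt <- ncol(pa)
  rich <- rowSums(pa)
  withSeed(seed, {
    v <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
    for (i in seq_len(n - 1L)) {
      for (j in seq((i + 1L), n)) {
        obs <- sum(pa[i, ] & pa[j, ])
        # shared richness under the null is hypergeometric(Tt, rich_i, rich_j)
        shared <- stats::rhyper(nNull, rich[i], Tt - rich[i], rich[j])
        d <- (sum(shared >= obs) + 1) / (nNull + 1)
        v[i, j] <- v[j, i] <- d
      }
    }
    v
  })
}

#' @rdname accessors
setMethod("dissValues", "DissimilarityMatrix", function(object) object@values)

#' @rdname accessors
setMethod("sampleIDs", "DissimilarityMatrix",
          function(object) rownames(object@values))

#' @rdname accessors
setMethod("nSamples", "DissimilarityMatrix",
          function(object) nrow(object@values))

setMethod("show", "DissimilarityMatrix", function(object) {
  v <- object@values
  off <- v[lower.tri(v)]
  cat(sprintf("DissimilarityMatrix (%s): %d samples, range %.3f-%.3f\n",
              object@measure, nrow(v), min(off), max(off)))
})

#' Write a dissimilarity matrix as square CSV
#'
#' @param x a [DissimilarityMatrix-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeDissimilarity <- function(x, path) {
  utils::write.csv(data.frame(sample_id = sampleIDs(x), dissValues(x),
                              check.names = FALSE),
                   path, row.names = FALSE)
  invisible(path)
}
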