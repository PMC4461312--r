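#' Least-squares monotone (isotonic) fit of distances on dissimilarity rank
#'
#' Pool-adjacent-violators fit of configuration distances against the rank
#' order of the observed dissimilarities; the fitted values are the
#' "disparities" of non-metric scaling.  Pairs must already be ordered by
#' ascending dissimilarity.  Tied dissimilarities are handled by averaging
#' within the tied block (all members of a tie receive a common disparity);
#' `ties = "untied"` instead leaves ties free by ordering them by ascending
#' distance, the least-constrained treatment.
#'
#' @param dissimilarities numeric vector, ascending (ties allowed).
#' @param distances numeric vector of the same length.
#' @param ties `"averaged"` (default) or `"untied"`.
#' @return the fitted non-decreasing disparity vector, same length and
#'   order as the input.
#' @examples
#' isotonicFit(c(0.1, 0.2, 0.3), c(1, 3, 2))  # 1, 2.5, 2.5
#' @export
isotonicFit <- function(dissimilarities, distances,
                        ties = c("averaged", "untied")) {
  ties <- match.arg(ties)
  n <- length(distances)
  if (n == 0L) stop("empty input")
  if (length(dissimilarities) != n)
    stop("dissimilarities and distances must have equal length")
  if (is.unsorted(dissimilarities))
    stop("pairs must be ordered by ascending dissimilarity")
  if (ties == "untied") {
    ord <- order(dissimilarities, distances)
    fit <- pava(distances[ord], rep(1, n))
    out <- numeric(n)
    out[ord] <- fit
    return(out)
  }
  blocks <- match(dissimilarities, unique(dissimilarities))
  y <- tapply(distances, blocks, mean)
  w <- tabulate(blocks)
  fit <- pava(as.numeric(y), w)
  fit[blocks]
}

# weighted pool-adjacent-violators, non-decreasing least squares
pava <- function(y, w) {
  n <- length(y)
  val <- y
  wt <- w
  len <- rep(1L, n)
  k <- 0L
  for (i in seq_len(n)) {
    k <- k + 1L
    val[k] <- y[i]; wt[k] <- w[i]; len[k] <- 1L
    while (k > 1L && val[k - 1L] > val[k]) {
      val[k - 1L] <- (val[k - 1L] * wt[k - 1L] + val[k] * wt[k]) /
        (wt[k - 1L] + wt[k])
      wt[k - 1L] <- wt[k - 1L] + wt[k]
      len[k - 1L] <- len[k - 1L] + len[k]
      k <- k - 1L
    }
  }
  rep(val[seq_len(k)], len[seq_len(k)])
}

#' Kruskal stress-1 of a configuration
#'
#' sqrt( sum (d_ij - dhat_ij)^2 / sum d_ij^2 ) over all off-diagonal pairs,
#' where d are the configuration's Euclidean distances and dhat the
#' disparities from [isotonicFit()] of d against the observed
#' dissimilarities.
#'
#' @param coords n x k configuration.
#' @param D a [DissimilarityMatrix-class] with n samples.
#' @param ties passed to [isotonicFit()].
#' @return stress-1 (>= 0).  A configuration with all points identical is
#'   degenerate and returns 1 with a warning.
#' @export
stress1 <- function(coords, D, ties = "averaged") {
  coords <- as.matrix(coords)
  v <- dissValues(D)
  if (nrow(coords) != nrow(v))
    stop("coords rows must match the dissimilarity dimension")
  dis <- v[lower.tri(v)]
  d <- as.numeric(stats::dist(coords))
  if (all(d == 0)) {
    warning("degenerate configuration: all points identical")
    return(1)
  }
  ord <- order(dis)
  dhat <- numeric(length(d))
  dhat[ord] <- isotonicFit(dis[ord], d[ord], ties = ties)
  sqrt(sum((d - dhat)^2) / sum(d^2))
}

#' Two-dimensional non-metric multidimensional scaling
#'
#' Minimises Kruskal stress-1 by monotone regression from one
#' classical-scaling start plus `nStarts` random starts, returning the
#' lowest-stress centred configuration.  The iterative engine is
#' \code{\link[vegan]{monoMDS}} (global model, stress-1, primary tie
#' treatment); this wrapper adds the multi-start protocol, seeding and the
#' [Ordination-class] container.  No transformation is applied to the
#' dissimilarities (ranks only), matching ordination with
#' auto-transformation disabled.
#'
#' @param D a [DissimilarityMatrix-class].
#' @param dims number of dimensions (fixed default 2).
#' @param nStarts random starts in addition to the classical-scaling start
#'   (default 20).
#' @param maxIter iteration cap per start (default 200).
#' @param tol relative stress-change convergence tolerance (default 1e-6).
#' @param seed integer; the whole multi-start procedure is deterministic
#'   given `seed`.
#' @return an [Ordination-class].
#' @export
nmdsOrdination <- function(D, dims = 2L, nStarts = 20L, maxIter = 200L,
                           tol = 1e-6, seed = NULL) {
  v <- dissValues(D)
  n <- nrow(v)
  # zero dissimilarities between distinct samples break rank-ordering;
  # nudge them by +1e-12 (documented)
  off <- v[lower.tri(v)]
  if (any(off == 0)) {
    v[v == 0] <- 1e-12
    diag(v) <- 0
  }
  d <- stats::as.dist(v)
  withSeed(seed, {
    starts <- vector("list", nStarts + 1L)
    y0 <- suppressWarnings(stats::cmdscale(d, k = dims))
    if (ncol(y0) < dims)
      y0 <- cbind(y0, matrix(0, n, dims - ncol(y0)))
    starts[[1L]] <- y0
    for (s in seq_len(nStarts))
      starts[[s + 1L]] <- matrix(stats::runif(n * dims, -1, 1), n, dims)
    best <- NULL
    bestIdx <- 0L
    for (s in seq_along(starts)) {
      fit <- vegan::monoMDS(d, y = starts[[s]], k = dims, model = "global",
                            maxit = maxIter, smin = 1e-8,
                            sratmax = 1 - tol)
      if (is.null(best) || fit$stress < best$stress) {
        best <- fit
        bestIdx <- s - 1L
      }
    }
    co <- scale(best$points, center = TRUE, scale = FALSE)
    attr(co, "scaled:center") <- NULL
    dimnames(co) <- list(rownames(v), paste0("axis", seq_len(dims)))
    new("Ordination", coords = co, stress = best$stress,
        converged = best$icause != 1L, nStarts = as.integer(nStarts),
        bestStart = bestIdx)
  })
}

#' @rdname accessors
setMethod("ordCoords", "Ordination", function(object) object@coords)

#' @rdname accessors
setMethod("ordStress", "Ordination", function(object) object@stress)

#' @rdname accessors
setMethod("nSamples", "Ordination", function(object) nrow(object@coords))

setMethod("show", "Ordination", function(object) {
  cat(sprintf(
    "Ordination: %d samples in %d dimensions, stress-1 = %.4g%s\n",
    nrow(object@coords), ncol(object@coords), object@stress,
    if (object@converged) "" else " (not converged)"))
})

#' Export an ordination as CSV
#'
#' Writes sample_id, axis1, axis2 and prints a one-line stress report.
#'
#' @param x an [Ordination-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeOrdination <- function(x, path) {
  utils::write.csv(data.frame(sample_id = rownames(ordCoords(x)),
                              ordCoords(x)),
                   path, row.names = FALSE)
  message(sprintf("stress-1 = %.6g (%s)", ordStress(x),
                  if (x@converged) "converged" else "not converged"))
  invisible(path)
}
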