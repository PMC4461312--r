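#' Gaussian taxon response curve
#'
#' Expected abundance of a taxon at gradient position g:
#' `peak * exp(-(g - mu)^2 / (2 * sigma^2))` -- a Gaussian scaled so its
#' maximum equals `peak` at the taxon's optimum `mu`, falling towards 0 in
#' the tails (the extremes of the taxon's environmental range).
#'
#' @param g gradient position(s).
#' @param mu optimum position.
#' @param sigma niche breadth (> 0).
#' @param peak maximum abundance at the optimum.
#' @return numeric abundance(s), same length as `g`.
#' @examples
#' taxonResponse(50, 50, 10, 100)   # 100
#' taxonResponse(60, 50, 10, 100)   # 100 * exp(-1/2) ~ 60.65
#' @export
taxonResponse <- function(g, mu, sigma, peak) {
  if (any(sigma <= 0)) stop("sigma must be positive")
  peak * exp(-(g - mu)^2 / (2 * sigma^2))
}

#' Draw a random gradient specification
#'
#' Per-taxon parameters are drawn independently: optimum
#' mu ~ Uniform(1, G), niche breadth sigma ~ Uniform(sigmaRange[1] * G,
#' sigmaRange[2] * G), and peak abundance ~ Uniform(peakRange).  The
#' defaults (sigma 5--25% of the gradient, peaks 1--100) put simulated
#' median sample sizes in the hundreds for G = 100 designs.
#'
#' @param nSamples,nTaxa,G design dimensions: number of samples, number of
#'   taxa, gradient length.
#' @param seed integer seed (drives both the parameter draws here and,
#'   stored in the spec, the position draws in
#'   [simulateGradientDataset()]).
#' @param sigmaRange,peakRange sampling ranges, see above.
#' @param positionMode `"unique-integer"` (default when nSamples <= G) or
#'   `"uniform-real"`.
#' @return a [GradientSpec-class].
#' @export
randomGradientSpec <- function(nSamples, nTaxa, G, seed,
                               sigmaRange = c(0.05, 0.25),
                               peakRange = c(1, 100),
                               positionMode = NULL) {
  if (length(sigmaRange) != 2L || any(sigmaRange <= 0) || diff(sigmaRange) < 0)
    stop("invalid sigmaRange")
  if (length(peakRange) != 2L || any(peakRange <= 0) || diff(peakRange) < 0)
    stop("invalid peakRange")
  if (is.null(positionMode))
    positionMode <- if (nSamples <= G) "unique-integer" else "uniform-real"
  withSeed(deriveSeed(seed, 11L), {
    new("GradientSpec",
        gradientLength = as.numeric(G), nTaxa = as.integer(nTaxa),
        nSamples = as.integer(nSamples),
        mu = stats::runif(nTaxa, 1, G),
        sigma = stats::runif(nTaxa, sigmaRange[1L] * G, sigmaRange[2L] * G),
        peak = stats::runif(nTaxa, peakRange[1L], peakRange[2L]),
        positionMode = positionMode,
        seed = as.integer(seed))
  })
}

#' Simulate a community matrix along a gradient
#'
#' Sampling positions are drawn from the spec's seed: distinct integers in
#' 1..G in `"unique-integer"` mode (one unique gradient location per
#' sample) or i.i.d. Uniform(1, G) reals in `"uniform-real"` mode (needed
#' when a design asks for more samples than integer positions).  The count
#' of taxon t in the sample at position g is the response-curve height
#' rounded half-up to an integer; taxa that round to zero everywhere are
#' dropped.  Positions are stored in the result's metadata.
#'
#' @param spec a [GradientSpec-class].
#' @param positions optional numeric vector overriding the random draw
#'   (e.g. to force a sample onto a taxon's optimum).
#' @return a [CommunityMatrix-class]; deterministic given the spec.
#' @export
simulateGradientDataset <- function(spec, positions = NULL) {
  validObject(spec)
  G <- spec@gradientLength
  n <- spec@nSamples
  if (is.null(positions)) {
    positions <- withSeed(deriveSeed(spec@seed, 13L), {
      if (spec@positionMode == "unique-integer") sample.int(G, n)
      else stats::runif(n, 1, G)
    })
  }
  h <- outer(positions, seq_len(spec@nTaxa),
             function(g, t) taxonResponse(g, spec@mu[t], spec@sigma[t],
                                          spec@peak[t]))
  m <- halfUp(h)
  dimnames(m) <- list(sprintf("sample%03d", seq_len(n)),
                      sprintf("taxon%03d", seq_len(spec@nTaxa)))
  keep <- colSums(m) > 0
  if (sum(keep) < 2L)
    stop("degenerate simulation: fewer than 2 observed taxa")
  CommunityMatrix(m[, keep, drop = FALSE],
                  metadata = list(positions = positions,
                                  gradient_length = G,
                                  seed = spec@seed))
}

#' Build a selected-abundance dataset with controlled evenness
#'
#' Every sample holds exactly `perSampleTotal` individuals (default 200)
#' spread over `richness` shared taxa as a geometric rank-abundance series
#' whose decay is solved numerically so that each sample's realised Pielou
#' J hits its target.  Samples within a dataset differ by a dominance
#' gradient: per-sample J targets are spread symmetrically around the
#' class target (so the class mean stays on target), which makes every
#' sample a different community along a gradient of dominance structure.
#' `structureId` sets the compositional range of that gradient -- the
#' Bray-Curtis distance between the first and last community, 0.20 + 0.05
#' per id unit -- and the J half-width needed to traverse it is solved per
#' class, so low- and high-evenness datasets cover the same dissimilarity
#' range and differ only in within-sample evenness.  `"low"` and `"high"`
#' classes centre the gradient on their respective targets (defaults 0.58
#' and 0.79); `"mixed"` datasets alternate low- and high-centred samples,
#' each parity carrying its own gradient.
#'
#' @param spec a [SelectedSpec-class].
#' @return a [CommunityMatrix-class]; every row sums exactly to
#'   `perSampleTotal`.
#' @export
buildSelectedDataset <- function(spec) {
  validObject(spec)
  n <- spec@nSamples
  S <- spec@richness
  total <- spec@perSampleTotal
  bcTarget <- 0.20 + 0.05 * spec@structureId
  gradient <- function(centre, k) {
    if (k == 1L) return(centre)
    spread <- spreadForRange(S, centre, bcTarget)
    centre + spread * (seq_len(k) - (k + 1) / 2) / (k - 1)
  }
  targets <- switch(spec@evennessClass,
    low = gradient(spec@targetJ[1L], n),
    high = gradient(spec@targetJ[2L], n),
    mixed = {
      lowIdx <- seq(1L, n, by = 2L)
      highIdx <- seq(2L, n, by = 2L)
      tg <- numeric(n)
      tg[lowIdx] <- gradient(spec@targetJ[1L], length(lowIdx))
      tg[highIdx] <- gradient(spec@targetJ[2L], length(highIdx))
      tg
    })
  m <- matrix(0, n, S,
              dimnames = list(sprintf("sample%03d", seq_len(n)),
                              sprintf("taxon%03d", seq_len(S))))
  for (i in seq_len(n))
    m[i, ] <- geometricAbundances(S, total, targets[i])
  CommunityMatrix(m,
                  metadata = list(evenness_class = spec@evennessClass,
                                  structure_id = spec@structureId,
                                  target_J = targets,
                                  seed = spec@seed))
}

# Continuous geometric rank-abundance profile (sums to 1) with Pielou J
# equal to targetJ, via uniroot on the decay parameter.
geometricProfile <- function(S, targetJ) {
  Jof <- function(theta) {
    p <- theta^(seq_len(S) - 1)
    p <- p / sum(p)
    -sum(p * log(p)) / log(S)
  }
  if (targetJ >= 1) return(rep(1 / S, S))
  lo <- 1e-6
  if (Jof(lo) > targetJ)
    stop(sprintf("J = %.2f unattainable at richness %d", targetJ, S))
  theta <- stats::uniroot(function(t) Jof(t) - targetJ, c(lo, 1 - 1e-9),
                          tol = 1e-10)$root
  p <- theta^(seq_len(S) - 1)
  p / sum(p)
}

# J half-width around `centre` whose endpoint profiles are a Bray-Curtis
# distance of `bcTarget` apart (capped at the attainable J range).
spreadForRange <- function(S, centre, bcTarget) {
  jmin <- 0.18
  jmax <- 0.995
  maxSpread <- 2 * min(centre - jmin, jmax - centre)
  bcOf <- function(sp) {
    a <- geometricProfile(S, centre - sp / 2)
    b <- geometricProfile(S, centre + sp / 2)
    sum(abs(a - b)) / 2
  }
  if (bcOf(maxSpread) <= bcTarget) return(maxSpread)
  stats::uniroot(function(sp) bcOf(sp) - bcTarget, c(1e-4, maxSpread),
                 tol = 1e-6)$root
}

# Integer abundance vector of length S summing to `total` whose Pielou J is
# as close as possible to targetJ, via a geometric series a_i ~ theta^(i-1)
# integerised by largest remainder (every taxon kept at >= 1 individual).
# Errors when no decay parameter gets within 0.05 of the target.
geometricAbundances <- function(S, total, targetJ) {
  if (S < 2L) stop("richness must be >= 2 for a defined J")
  candidate <- function(theta) {
    p <- theta^(seq_len(S) - 1)
    p <- p / sum(p)
    a <- largestRemainder(p * total, total)
    if (any(a == 0L)) {           # keep every taxon present
      need <- a == 0L
      a[need] <- 1L
      excess <- sum(a) - total
      ord <- order(a, decreasing = TRUE)
      k <- 1L
      while (excess > 0L) {
        if (a[ord[k]] > 1L) { a[ord[k]] <- a[ord[k]] - 1L; excess <- excess - 1L }
        k <- if (k == S) 1L else k + 1L
      }
    }
    a
  }
  thetas <- seq(0.02, 1, by = 0.0025)
  best <- NULL
  bestGap <- Inf
  jlo <- Inf; jhi <- -Inf
  for (th in thetas) {
    a <- candidate(th)
    J <- pielouEvenness(a)
    jlo <- min(jlo, J); jhi <- max(jhi, J)
    gap <- abs(J - targetJ)
    if (gap < bestGap) { bestGap <- gap; best <- a }
  }
  if (bestGap > 0.05)
    stop(sprintf(
      "no geometric decay reaches J = %.2f at richness %d (attainable %.2f-%.2f)",
      targetJ, S, jlo, jhi))
  sort(best, decreasing = TRUE)
}

# round non-negative reals to integers preserving their (integer) sum
largestRemainder <- function(x, total) {
  f <- floor(x)
  rem <- total - sum(f)
  if (rem > 0) {
    ord <- order(x - f, decreasing = TRUE)
    f[ord[seq_len(rem)]] <- f[ord[seq_len(rem)]] + 1
  }
  as.integer(f)
}

#' The 22 gradient design rows
#'
#' The factorial design used for the gradient simulations: each row fixes
#' the number of samples, number of taxa and gradient length.  The
#' full-scale experiment instantiates every row 10 times (220 datasets);
#' desk-scale runs use one dataset per row.
#'
#' @param replicates datasets per design row (default 1).
#' @param maxG cap on gradient length; rows above the cap are reduced to
#'   `maxG` (with `NULL`, rows are used as designed).  Long-gradient rows
#'   produce samples of tens of thousands of individuals, so desk-scale
#'   runs cap G at 100.
#' @return data.frame with columns row, n_samples, n_taxa, gradient_size,
#'   replicates.
#' @export
gradientDesignTable <- function(replicates = 1L, maxG = NULL) {
  d <- data.frame(
    row = 1:22,
    n_samples = c(15, 15, 20, 20, 20, 20, 20, 20, 20, 25, 30, 30, 40, 50,
                  50, 50, 50, 50, 50, 75, 100, 200),
    n_taxa = c(15, 15, 20, 20, 30, 40, 40, 50, 50, 100, 20, 60, 20, 20,
               50, 50, 75, 100, 200, 50, 50, 50),
    gradient_size = c(1000, 5000, 100, 5000, 100, 100, 100, 100, 100, 100,
                      100, 100, 100, 100, 100, 5000, 100, 100, 100, 100,
                      100, 100))
  if (!is.null(maxG)) d$gradient_size <- pmin(d$gradient_size, maxG)
  d$replicates <- as.integer(replicates)
  d
}

#' Default selected-abundance design
#'
#' Factorial over evenness class (low, high, mixed), number of samples
#' (5, 10) and richness (10, 20, 50), with `structures` composition
#' structures per cell.
#'
#' @param structures structure ids per design cell (default 1:4).
#' @param classes evenness classes to include.
#' @return data.frame with columns evenness_class, n_samples, richness,
#'   structure_id.
#' @export
selectedDesignTable <- function(structures = 1:4,
                                classes = c("low", "high", "mixed")) {
  expand.grid(evenness_class = classes, n_samples = c(5L, 10L),
              richness = c(10L, 20L, 50L), structure_id = as.integer(structures),
              KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
}

#' Generate a suite of datasets from a design table
#'
#' One dataset per design row and replicate, each with a seed derived
#' deterministically from the master seed so any dataset can be rebuilt
#' from (row, replicate, seed).  A manifest of realised properties is
#' attached as `attr(, "manifest")`.
#'
#' @param design a data.frame from [gradientDesignTable()] (columns
#'   n_samples, n_taxa, gradient_size, optionally replicates) or
#'   [selectedDesignTable()] (columns evenness_class, n_samples, richness,
#'   optionally structure_id).
#' @param seed master integer seed.
#' @param type `"gradient"` or `"selected"`; guessed from the columns when
#'   missing.
#' @return named list of [CommunityMatrix-class] objects with a manifest
#'   attribute (dataset_id, row, replicate, seed, median_sample_size,
#'   mean_evenness, ...).
#' @export
generateSuite <- function(design, seed, type = NULL) {
  if (is.null(type))
    type <- if ("gradient_size" %in% names(design)) "gradient" else "selected"
  reps <- if ("replicates" %in% names(design)) design$replicates
          else rep(1L, nrow(design))
  out <- list()
  man <- list()
  for (i in seq_len(nrow(design))) {
    for (r in seq_len(reps[i])) {
      dseed <- deriveSeed(seed, i, r)
      id <- sprintf("d%02d_r%02d", i, r)
      cm <- if (type == "gradient") {
        spec <- randomGradientSpec(design$n_samples[i], design$n_taxa[i],
                                   design$gradient_size[i], seed = dseed)
        simulateGradientDataset(spec)
      } else {
        spec <- new("SelectedSpec",
                    nSamples = as.integer(design$n_samples[i]),
                    richness = as.integer(design$richness[i]),
                    perSampleTotal = 200L,
                    evennessClass = as.character(design$evenness_class[i]),
                    targetJ = c(0.58, 0.79),
                    structureId = as.integer(
                      if ("structure_id" %in% names(design))
                        design$structure_id[i] else 1L),
                    seed = dseed)
        buildSelectedDataset(spec)
      }
      s <- summarizeSamples(cm)
      out[[id]] <- cm
      man[[id]] <- data.frame(dataset_id = id, row = i, replicate = r,
                              seed = dseed,
                              n_samples = nSamples(cm), n_taxa = nTaxa(cm),
                              median_sample_size = s@medianSampleSize,
                              mean_evenness = s@meanEvenness)
    }
  }
  manifest <- do.call(rbind, man)
  rownames(manifest) <- NULL
  if (type == "selected") {
    ridx <- manifest$row
    manifest$evenness_class <- as.character(design$evenness_class[ridx])
    manifest$richness <- design$richness[ridx]
    manifest$structure_id <- if ("structure_id" %in% names(design))
      design$structure_id[ridx] else 1L
  }
  attr(out, "manifest") <- manifest
  out
}
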