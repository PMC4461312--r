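#' @import methods
NULL

#' Taxon-by-sample count matrix
#'
#' The unit of all analysis in this package: a matrix of non-negative integer
#' abundance counts with one row per collected sample and one column per
#' taxon.  "Sample size" throughout means the number of individuals counted
#' in one sample, i.e. one row sum -- not the number of samples.
#'
#' @slot counts integer matrix, samples x taxa, with unique dimnames.
#' @slot metadata list of free-form annotations (gradient positions,
#'   evenness class, generator seed, flags).
#'
#' @seealso [CommunityMatrix()] for the validating constructor,
#'   [readCommunityMatrix()] for delimited-text input.
#' @exportClass CommunityMatrix
setClass("CommunityMatrix",
  representation(counts = "matrix", metadata = "list"),
  prototype(metadata = list())
)

setValidity("CommunityMatrix", function(object) {
  m <- object@counts
  msg <- character()
  if (!is.numeric(m)) {
    msg <- c(msg, "counts must be a numeric matrix")
  } else {
    if (nrow(m) < 2L || ncol(m) < 2L)
      msg <- c(msg, "need at least 2 samples and 2 taxa")
    bad <- which(m < 0, arr.ind = TRUE)
    if (nrow(bad) > 0L)
      msg <- c(msg, sprintf("negative count at sample '%s', taxon '%s'",
                            rownames(m)[bad[1L, 1L]], colnames(m)[bad[1L, 2L]]))
    if (any(m != floor(m)))
      msg <- c(msg, "counts must be integers (fractional abundances are rejected, not rounded)")
  }
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    msg <- c(msg, "counts must carry sample (row) and taxon (column) names")
  } else {
    if (anyDuplicated(rownames(m)))
      msg <- c(msg, "duplicate sample ids")
    if (anyDuplicated(colnames(m)))
      msg <- c(msg, "duplicate taxon ids")
  }
  if (length(msg)) msg else TRUE
})

#' Per-sample summary of a community matrix
#'
#' Row totals ("sample sizes"), their median, per-sample Pielou evenness and
#' its mean over samples where J is defined (richness > 1).
#'
#' @slot sampleSizes named integer-valued vector of row sums.
#' @slot medianSampleSize median of the row sums (mean of the two middle
#'   values for an even number of samples).
#' @slot richness named vector of per-sample counts of taxa present.
#' @slot evenness named numeric vector of per-sample Pielou J; `NA` where
#'   undefined (single-taxon sample).
#' @slot meanEvenness mean of the defined J values.
#' @exportClass SampleSummary
setClass("SampleSummary",
  representation(sampleSizes = "numeric", medianSampleSize = "numeric",
                 richness = "numeric", evenness = "numeric",
                 meanEvenness = "numeric")
)

#' Pairwise sample dissimilarity matrix
#'
#' @slot values square symmetric numeric matrix, zero diagonal, labelled by
#'   sample id.
#' @slot measure identifier of the dissimilarity used ("bray", "euclidean",
#'   "cityblock", "raup_crick").
#' @exportClass DissimilarityMatrix
setClass("DissimilarityMatrix",
  representation(values = "matrix", measure = "character")
)

setValidity("DissimilarityMatrix", function(object) {
  v <- object@values
  msg <- character()
  if (nrow(v) != ncol(v)) msg <- c(msg, "values must be square")
  if (any(v < 0)) msg <- c(msg, "dissimilarities must be non-negative")
  if (any(abs(diag(v)) > 0)) msg <- c(msg, "diagonal must be exactly 0")
  if (!isTRUE(all.equal(v, t(v), tolerance = 1e-12)))
    msg <- c(msg, "values must be symmetric")
  if (is.null(rownames(v))) msg <- c(msg, "values must carry sample labels")
  if (length(msg)) msg else TRUE
})

#' Two-dimensional NMDS ordination
#'
#' @slot coords n x 2 centred configuration, rows labelled by sample id.
#' @slot stress Kruskal stress-1 of the configuration.
#' @slot converged logical; FALSE when no start converged.
#' @slot nStarts number of random starts attempted (in addition to the
#'   classical-scaling start).
#' @slot bestStart index of the winning start (0 = classical scaling).
#' @exportClass Ordination
setClass("Ordination",
  representation(coords = "matrix", stress = "numeric", converged = "logical",
                 nStarts = "integer", bestStart = "integer")
)

#' Mantel test result
#'
#' @slot r Pearson correlation of the two matrices' off-diagonal entries;
#'   `NA` when either vector has zero variance.
#' @slot pValue one-tailed permutation p-value, observed-included convention.
#' @slot nPermutations number of permutations (0 = no test, p is `NA`).
#' @exportClass MantelResult
setClass("MantelResult",
  representation(r = "numeric", pValue = "numeric", nPermutations = "integer")
)

#' PROTEST result
#'
#' `concordance` is on the 0-1 scale with 1 = identical ordinations (one
#' minus the symmetric Procrustes residual after both configurations are
#' normalised to unit sum of squares).
#'
#' @slot concordance number in [0, 1].
#' @slot ssResidual symmetric Procrustes sum of squared residuals,
#'   `1 - concordance`.
#' @slot pValue one-tailed permutation p-value (rows of the second
#'   configuration permuted), observed-included convention.
#' @slot nPermutations integer.
#' @exportClass ProtestResult
setClass("ProtestResult",
  representation(concordance = "numeric", ssResidual = "numeric",
                 pValue = "numeric", nPermutations = "integer")
)

#' Procrustes superimposition transform
#'
#' The similarity transform (rotation/reflection, dilation, translation)
#' that maps the second configuration onto the first with least squared
#' error.
#'
#' @slot rotation 2x2 orthogonal matrix (det +1 or -1; reflections allowed).
#' @slot scale positive dilation factor.
#' @slot translation length-2 shift applied after rotation and scaling.
#' @exportClass ProcrustesTransform
setClass("ProcrustesTransform",
  representation(rotation = "matrix", scale = "numeric",
                 translation = "numeric")
)

setValidity("ProcrustesTransform", function(object) {
  R <- object@rotation
  if (max(abs(crossprod(R) - diag(ncol(R)))) > 1e-10)
    return("rotation must be orthogonal")
  TRUE
})

#' Gaussian gradient-simulation specification
#'
#' Per-taxon Gaussian response parameters along a one-dimensional
#' environmental gradient of integer length `gradientLength`: each taxon has
#' an optimum position `mu`, niche breadth `sigma` and peak abundance
#' `peak`; a sample collected at position g counts
#' `round(peak * exp(-(g - mu)^2 / (2 sigma^2)))` individuals of that taxon.
#'
#' @slot gradientLength positive integer G.
#' @slot nTaxa,nSamples integers.
#' @slot mu,sigma,peak numeric vectors of length `nTaxa` (1 <= mu <= G,
#'   sigma > 0, peak > 0).
#' @slot positionMode "unique-integer" (sampling positions are distinct
#'   integers in 1..G; requires nSamples <= G) or "uniform-real".
#' @slot seed integer seed governing position draws.
#' @exportClass GradientSpec
setClass("GradientSpec",
  representation(gradientLength = "numeric", nTaxa = "integer",
                 nSamples = "integer", mu = "numeric", sigma = "numeric",
                 peak = "numeric", positionMode = "character",
                 seed = "integer")
)

setValidity("GradientSpec", function(object) {
  msg <- character()
  n <- object@nTaxa
  if (length(object@mu) != n || length(object@sigma) != n ||
      length(object@peak) != n)
    msg <- c(msg, "mu, sigma, peak must each have length nTaxa")
  if (any(object@sigma <= 0)) msg <- c(msg, "all sigma must be positive")
  if (any(object@peak <= 0)) msg <- c(msg, "all peak must be positive")
  if (any(object@mu < 1 | object@mu > object@gradientLength))
    msg <- c(msg, "mu must lie within [1, gradientLength]")
  if (!object@positionMode %in% c("unique-integer", "uniform-real"))
    msg <- c(msg, "positionMode must be 'unique-integer' or 'uniform-real'")
  if (object@positionMode == "unique-integer" &&
      object@nSamples > object@gradientLength)
    msg <- c(msg, "unique-integer positions need nSamples <= gradientLength; use positionMode = 'uniform-real'")
  if (length(msg)) msg else TRUE
})

#' Selected-abundance dataset specification
#'
#' Communities with a controlled Pielou evenness: every sample holds exactly
#' `perSampleTotal` individuals distributed over `richness` taxa following a
#' geometric rank-abundance series whose decay is solved numerically so that
#' realised J matches `targetJ`.
#'
#' @slot nSamples,richness integers.
#' @slot perSampleTotal individuals per sample (default 200).
#' @slot evennessClass "low", "high" or "mixed" (alternating low/high
#'   samples).
#' @slot targetJ length-2 numeric, the low and high evenness targets
#'   (defaults 0.58 and 0.79).
#' @slot structureId integer 1..9 controlling how taxon identities shift
#'   from sample to sample (larger = faster compositional turnover).
#' @slot seed integer.
#' @exportClass SelectedSpec
setClass("SelectedSpec",
  representation(nSamples = "integer", richness = "integer",
                 perSampleTotal = "integer", evennessClass = "character",
                 targetJ = "numeric", structureId = "integer",
                 seed = "integer")
)

setValidity("SelectedSpec", function(object) {
  msg <- character()
  if (!object@evennessClass %in% c("low", "high", "mixed"))
    msg <- c(msg, "evennessClass must be 'low', 'high' or 'mixed'")
  if (object@richness > object@perSampleTotal)
    msg <- c(msg, "richness cannot exceed perSampleTotal")
  if (length(object@targetJ) != 2L || any(object@targetJ <= 0) ||
      any(object@targetJ > 1))
    msg <- c(msg, "targetJ must be two values in (0, 1]")
  if (object@structureId < 1L || object@structureId > 9L)
    msg <- c(msg, "structureId must be in 1..9")
  if (length(msg)) msg else TRUE
})

#' Subsampling scheme
#'
#' @slot proportions fractions of each sample's individuals to retain
#'   (default 0.50, 0.25, 0.10, 0.05, 0.025).
#' @slot nReplicates independent subsampled matrices per proportion
#'   (default 1000).
#' @slot seed master seed; per-replicate seeds are derived
#'   deterministically from (seed, proportion index, replicate index).
#' @exportClass SubsampleScheme
setClass("SubsampleScheme",
  representation(proportions = "numeric", nReplicates = "integer",
                 seed = "integer")
)

setValidity("SubsampleScheme", function(object) {
  msg <- character()
  if (any(object@proportions <= 0 | object@proportions > 1))
    msg <- c(msg, "proportions must lie in (0, 1]")
  if (object@nReplicates < 1L) msg <- c(msg, "nReplicates must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Plateau-threshold detection result
#'
#' @slot statistic "mantel" or "protest".
#' @slot breakpointSize estimated sample size at the plateau/decline break
#'   (on the original individuals scale).
#' @slot plateauValue mean fitted statistic over the plateau (right)
#'   segment.
#' @slot hasBreakpoint FALSE when the two-segment fit does not improve on a
#'   single line or the right segment is not flat.
#' @slot method identifier of the fitting method.
#' @exportClass ThresholdResult
setClass("ThresholdResult",
  representation(statistic = "character", breakpointSize = "numeric",
                 plateauValue = "numeric", hasBreakpoint = "logical",
                 method = "character")
)
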