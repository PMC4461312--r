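#' Construct a CommunityMatrix
#'
#' Validating constructor for the package's central data type: a
#' samples-by-taxa matrix of non-negative integer abundance counts.
#' Dimnames are required (or supplied via `sampleIDs`/`taxonIDs`) and must
#' be unique; fractional or negative entries are rejected.
#'
#' @param counts numeric matrix, rows = samples, columns = taxa.
#' @param sampleIDs,taxonIDs optional character vectors overriding the
#'   dimnames of `counts`.
#' @param metadata optional list of annotations carried along unchecked.
#' @return a [CommunityMatrix-class] object.
#' @examples
#' m <- matrix(c(5, 0, 3, 2, 7, 1), 2, 3,
#'             dimnames = list(c("s1", "s2"), c("t1", "t2", "t3")))
#' cm <- CommunityMatrix(m)
#' nSamples(cm)
#' @export
CommunityMatrix <- function(counts, sampleIDs = NULL, taxonIDs = NULL,
                            metadata = list()) {
  counts <- as.matrix(counts)
  if (!is.null(sampleIDs)) rownames(counts) <- sampleIDs
  if (!is.null(taxonIDs)) colnames(counts) <- taxonIDs
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("sample%02d", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("taxon%02d", seq_len(ncol(counts)))
  storage.mode(counts) <- "double"
  new("CommunityMatrix", counts = counts, metadata = metadata)
}

#' @rdname accessors
setMethod("counts", "CommunityMatrix", function(object) object@counts)

#' @rdname accessors
setMethod("sampleIDs", "CommunityMatrix",
          function(object) rownames(object@counts))

#' @rdname accessors
setMethod("taxonIDs", "CommunityMatrix",
          function(object) colnames(object@counts))

#' @rdname accessors
setMethod("nSamples", "CommunityMatrix", function(object) nrow(object@counts))

#' @rdname accessors
setMethod("nTaxa", "CommunityMatrix", function(object) ncol(object@counts))

setMethod("show", "CommunityMatrix", function(object) {
  cat(sprintf("CommunityMatrix: %d samples x %d taxa\n",
              nSamples(object), nTaxa(object)))
  ss <- rowSums(object@counts)
  cat(sprintf("  sample sizes (individuals/sample): median %g, range %g-%g\n",
              midMedian(ss), min(ss), max(ss)))
  if (length(object@metadata))
    cat("  metadata:", paste(names(object@metadata), collapse = ", "), "\n")
})

#' Read a taxon-by-sample matrix from delimited text
#'
#' Expects a header row and a first column of labels.  Files may be laid
#' out either with samples as rows (the package's canonical orientation) or
#' taxa as rows; the latter is transposed on read.  The delimiter is taken
#' from the file extension (".csv" = comma, otherwise tab) unless given.
#'
#' @param path file path.
#' @param orientation `"samples-as-rows"` or `"taxa-as-rows"`.
#' @param delimiter optional single character overriding auto-detection.
#' @return a [CommunityMatrix-class].
#' @seealso [writeCommunityMatrix()]
#' @export
readCommunityMatrix <- function(path,
                                orientation = c("samples-as-rows",
                                                "taxa-as-rows"),
                                delimiter = NULL) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(delimiter))
    delimiter <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = delimiter,
                          row.names = 1, check.names = FALSE,
                          stringsAsFactors = FALSE, comment.char = "",
                          quote = "\"", fileEncoding = "UTF-8")
  bad <- which(!vapply(df, is.numeric, logical(1)))
  if (length(bad))
    stop(sprintf("non-numeric entries in column '%s'", names(df)[bad[1L]]))
  m <- as.matrix(df)
  if (orientation == "taxa-as-rows") m <- t(m)
  CommunityMatrix(m)
}

#' Write a CommunityMatrix as delimited text
#'
#' @param x a [CommunityMatrix-class].
#' @param path output file; extension picks the delimiter as in
#'   [readCommunityMatrix()].
#' @param delimiter optional override.
#' @return `path`, invisibly.
#' @export
writeCommunityMatrix <- function(x, path, delimiter = NULL) {
  if (is.null(delimiter))
    delimiter <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- data.frame(sample_id = sampleIDs(x), counts(x),
                   check.names = FALSE)
  utils::write.table(df, path, sep = delimiter, row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Pielou's evenness J
#'
#' J = H' / ln S, with H' the Shannon entropy of the relative abundances of
#' the S taxa present (count > 0).  J is undefined when only one taxon is
#' present (ln S = 0) and is then returned as `NA` rather than coerced to 0
#' or 1.
#'
#' @param x non-negative count vector with at least one positive entry.
#' @return J in [0, 1], or `NA` when S = 1.
#' @examples
#' pielouEvenness(c(5, 5, 5, 5))   # 1
#' pielouEvenness(c(10, 10, 80))   # about 0.58
#' @export
pielouEvenness <- function(x) {
  if (any(x < 0)) stop("negative counts")
  x <- x[x > 0]
  if (length(x) == 0L) stop("empty sample")
  if (length(x) == 1L) return(NA_real_)
  p <- x / sum(x)
  H <- -sum(p * log(p))
  H / log(length(p))
}

#' Summarize a community matrix sample by sample
#'
#' @param x a [CommunityMatrix-class].
#' @return a [SampleSummary-class] holding per-sample sizes (row sums),
#'   their median, per-sample richness and Pielou J, and the mean of the
#'   defined J values.
#' @export
summarizeSamples <- function(x) {
  m <- counts(x)
  sizes <- rowSums(m)
  J <- apply(m, 1L, pielouEvenness)
  new("SampleSummary",
      sampleSizes = sizes,
      medianSampleSize = midMedian(sizes),
      richness = rowSums(m > 0),
      evenness = J,
      meanEvenness = mean(J, na.rm = TRUE))
}

setMethod("show", "SampleSummary", function(object) {
  cat(sprintf("SampleSummary: %d samples\n", length(object@sampleSizes)))
  cat(sprintf("  median sample size: %g\n", object@medianSampleSize))
  cat(sprintf("  mean evenness (J, defined samples): %.3f\n",
              object@meanEvenness))
})

#' Write per-sample summaries as CSV
#'
#' One row per sample (sample_id, n_individuals, richness, J) followed by
#' no footer; the per-dataset scalars are returned invisibly.
#'
#' @param x a [CommunityMatrix-class].
#' @param path output CSV path.
#' @return invisibly, a one-row data.frame (median_sample_size,
#'   mean_evenness).
#' @export
writeSampleSummary <- function(x, path) {
  s <- summarizeSamples(x)
  utils::write.csv(
    data.frame(sample_id = names(s@sampleSizes),
               n_individuals = unname(s@sampleSizes),
               richness = unname(s@richness),
               J = unname(s@evenness)),
    path, row.names = FALSE)
  invisible(data.frame(median_sample_size = s@medianSampleSize,
                       mean_evenness = s@meanEvenness))
}

#' Drop empty taxon columns
#'
#' Removes taxa observed in no sample (all-zero columns).  Sample rows are
#' never removed -- row count must be preserved so subsample and complete
#' matrices stay paired for Mantel and PROTEST -- but all-zero rows set a
#' `zero_rows` flag in the metadata and raise a warning.
#'
#' @param x a [CommunityMatrix-class].
#' @return a [CommunityMatrix-class] without all-zero taxon columns.
#' @export
dropEmptyTaxa <- function(x) {
  m <- counts(x)
  keep <- colSums(m) > 0
  if (sum(keep) < 2L)
    stop("degenerate matrix: fewer than 2 taxa with positive counts")
  md <- x@metadata
  zr <- rowSums(m) == 0
  if (any(zr)) {
    warning("matrix contains all-zero sample rows (retained)")
    md$zero_rows <- names(which(zr))
  }
  if (all(keep) && !any(zr)) return(x)
  CommunityMatrix(m[, keep, drop = FALSE], metadata = md)
}
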