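#' Default analysis settings
#'
#' Settings used by [compareOne()] and [runExperiment()]: permutation
#' counts for the two tests and NMDS controls.  `statistics` selects which
#' comparisons to run ("mantel", "protest" or both); dropping "protest"
#' skips the ordinations entirely, which is much faster when only Mantel R
#' is needed.
#'
#' @param mantelPermutations,protestPermutations permutation counts
#'   (0 = statistic only, no test).
#' @param nmdsStarts random NMDS starts in addition to the
#'   classical-scaling start; 0 keeps only the metric start, the fast
#'   choice for large replicate streams.
#' @param nmdsMaxIter,nmdsTol NMDS iteration cap and convergence
#'   tolerance.
#' @param statistics character subset of c("mantel", "protest").
#' @return a list of settings.
#' @export
analysisSettings <- function(mantelPermutations = 999L,
                             protestPermutations = 999L,
                             nmdsStarts = 20L, nmdsMaxIter = 200L,
                             nmdsTol = 1e-6,
                             statistics = c("mantel", "protest")) {
  list(mantelPermutations = as.integer(mantelPermutations),
       protestPermutations = as.integer(protestPermutations),
       nmdsStarts = as.integer(nmdsStarts),
       nmdsMaxIter = as.integer(nmdsMaxIter),
       nmdsTol = nmdsTol,
       statistics = statistics)
}

#' Compare one subsampled matrix with its complete dataset
#'
#' Computes the Mantel R between the Bray-Curtis matrices of the complete
#' and subsampled data, and the PROTEST concordance between their 2-D NMDS
#' ordinations, together with the subsample's median sample size (the
#' x-coordinate on which all results are reported).
#'
#' @param complete,subsample [CommunityMatrix-class] objects over the same
#'   samples in the same order (the subsample may have fewer taxa).
#' @param settings from [analysisSettings()].
#' @param seed integer seed for the permutation tests and NMDS starts.
#' @param datasetId,proportion,replicate identifiers copied into the
#'   record.
#' @param completeD,completeOrd optional precomputed Bray-Curtis matrix and
#'   ordination of `complete` (cached across replicates by
#'   [runExperiment()]).
#' @return one-row data.frame: dataset_id, proportion, replicate,
#'   median_subsample_size, mantel_r, mantel_p, protest_concordance,
#'   protest_p, ok.
#' @export
compareOne <- function(complete, subsample, settings = analysisSettings(),
                       seed = NULL, datasetId = "dataset", proportion = NA,
                       replicate = NA_integer_, completeD = NULL,
                       completeOrd = NULL) {
  if (!identical(sampleIDs(complete), sampleIDs(subsample)))
    stop("complete and subsample must contain the same samples in the same order")
  med <- midMedian(rowSums(counts(subsample)))
  rec <- data.frame(dataset_id = datasetId, proportion = proportion,
                    replicate = replicate, median_subsample_size = med,
                    mantel_r = NA_real_, mantel_p = NA_real_,
                    protest_concordance = NA_real_, protest_p = NA_real_,
                    ok = TRUE)
  if (is.null(completeD)) completeD <- brayCurtis(complete)
  subD <- brayCurtis(subsample)
  if ("mantel" %in% settings$statistics) {
    mt <- mantelTest(completeD, subD,
                     nPermutations = settings$mantelPermutations,
                     seed = if (is.null(seed)) NULL else deriveSeed(seed, 1L))
    rec$mantel_r <- mt@r
    rec$mantel_p <- mt@pValue
  }
  if ("protest" %in% settings$statistics) {
    if (is.null(completeOrd))
      completeOrd <- nmdsOrdination(completeD, nStarts = settings$nmdsStarts,
                                    maxIter = settings$nmdsMaxIter,
                                    tol = settings$nmdsTol,
                                    seed = if (is.null(seed)) NULL else
                                      deriveSeed(seed, 2L))
    subOrd <- nmdsOrdination(subD, nStarts = settings$nmdsStarts,
                             maxIter = settings$nmdsMaxIter,
                             tol = settings$nmdsTol,
                             seed = if (is.null(seed)) NULL else
                               deriveSeed(seed, 3L))
    pt <- protestTest(completeOrd, subOrd,
                      nPermutations = settings$protestPermutations,
                      seed = if (is.null(seed)) NULL else
                        deriveSeed(seed, 4L))
    rec$protest_concordance <- pt@concordance
    rec$protest_p <- pt@pValue
  }
  rec
}

#' Run the full subsample-versus-complete experiment
#'
#' For every dataset, streams all (proportion, replicate) subsamples
#' through [compareOne()].  The complete dataset's Bray-Curtis matrix and
#' ordination are computed once and reused across its replicates.  A
#' failing replicate (e.g. a degenerate subsample) is recorded with
#' `ok = FALSE` rather than aborting the run.
#'
#' @param datasets named list of [CommunityMatrix-class] objects (names
#'   become dataset ids).
#' @param scheme a [SubsampleScheme-class].
#' @param settings from [analysisSettings()].
#' @param verbose print one line per dataset.
#' @return data.frame of comparison records (one row per dataset x
#'   proportion x replicate).
#' @export
runExperiment <- function(datasets, scheme, settings = analysisSettings(),
                          verbose = FALSE) {
  if (length(datasets) < 1L) stop("need at least one dataset")
  ids <- names(datasets)
  if (is.null(ids)) ids <- sprintf("dataset%02d", seq_along(datasets))
  grid <- replicateGrid(scheme)
  out <- vector("list", length(datasets))
  for (d in seq_along(datasets)) {
    cm <- datasets[[d]]
    t0 <- proc.time()[["elapsed"]]
    completeD <- brayCurtis(cm)
    completeOrd <- if ("protest" %in% settings$statistics)
      nmdsOrdination(completeD, nStarts = settings$nmdsStarts,
                     maxIter = settings$nmdsMaxIter, tol = settings$nmdsTol,
                     seed = deriveSeed(scheme@seed, d, 0L))
      else NULL
    recs <- vector("list", nrow(grid))
    for (i in seq_len(nrow(grid))) {
      cseed <- deriveSeed(grid$seed[i], d)
      recs[[i]] <- tryCatch({
        sub <- subsampleMatrix(cm, grid$proportion[i], seed = cseed)
        compareOne(cm, sub, settings = settings,
                   seed = deriveSeed(cseed, 99L), datasetId = ids[d],
                   proportion = grid$proportion[i],
                   replicate = grid$replicate[i],
                   completeD = completeD, completeOrd = completeOrd)
      }, error = function(e) {
        data.frame(dataset_id = ids[d], proportion = grid$proportion[i],
                   replicate = grid$replicate[i],
                   median_subsample_size = NA_real_, mantel_r = NA_real_,
                   mantel_p = NA_real_, protest_concordance = NA_real_,
                   protest_p = NA_real_, ok = FALSE)
      })
    }
    out[[d]] <- do.call(rbind, recs)
    if (verbose)
      message(sprintf("%s: %d records in %.1fs", ids[d], nrow(grid),
                      proc.time()[["elapsed"]] - t0))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Aggregate comparison records into goodness-of-fit curves
#'
#' Groups records by (dataset, proportion) and returns the mean and sample
#' standard deviation of each statistic and of the median subsample size
#' (the points of the statistic-versus-size curves).  Failed replicates
#' (`ok = FALSE`) are excluded; their counts are reported in
#' `n_failed`.
#'
#' @param records data.frame from [runExperiment()].
#' @return data.frame with one row per dataset x proportion: dataset_id,
#'   proportion, n_replicates, n_failed, median_size_mean, median_size_sd,
#'   mantel_mean, mantel_sd, protest_mean, protest_sd.
#' @export
aggregateCurves <- function(records) {
  if (nrow(records) == 0L) stop("no records to aggregate")
  key <- interaction(records$dataset_id, records$proportion, drop = TRUE)
  rows <- lapply(split(records, key), function(g) {
    ok <- g[g$ok, , drop = FALSE]
    data.frame(dataset_id = g$dataset_id[1L], proportion = g$proportion[1L],
               n_replicates = nrow(ok), n_failed = sum(!g$ok),
               median_size_mean = mean(ok$median_subsample_size),
               median_size_sd = stats::sd(ok$median_subsample_size),
               mantel_mean = mean(ok$mantel_r),
               mantel_sd = stats::sd(ok$mantel_r),
               protest_mean = mean(ok$protest_concordance),
               protest_sd = stats::sd(ok$protest_concordance))
  })
  res <- do.call(rbind, rows)
  res <- res[order(res$dataset_id, res$proportion), ]
  rownames(res) <- NULL
  res
}

#' Locate the plateau/decline breakpoint of a goodness-of-fit curve
#'
#' Pools the (mean statistic, mean median size) points of the curves and
#' fits a continuous two-segment piecewise-linear model of the statistic
#' against log10(size), grid-searching the breakpoint over the observed
#' sizes.  The plateau value is the mean fitted value over the right
#' (large-size) segment.  When the two-segment fit barely improves on a
#' single line, or the right segment is not flat (|slope| >
#' `plateauSlopeTol` per log10 unit), the result is flagged as having no
#' breakpoint and the plateau value falls back to the overall mean.
#'
#' @param curves data.frame from [aggregateCurves()].
#' @param statistic `"mantel"` or `"protest"`.
#' @param plateauSlopeTol flatness tolerance for the right segment
#'   (default 0.1).
#' @param minImprovement minimum relative residual-sum-of-squares
#'   improvement over a single line for a breakpoint to be declared
#'   (default 0.05).
#' @return a [ThresholdResult-class].
#' @export
detectThreshold <- function(curves, statistic = c("mantel", "protest"),
                            plateauSlopeTol = 0.1, minImprovement = 0.05) {
  statistic <- match.arg(statistic)
  y <- curves[[paste0(statistic, "_mean")]]
  x <- log10(curves$median_size_mean)
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(unique(round(x, 10))) < 4L)
    stop("need at least 4 distinct median sizes")
  rss1 <- sum(stats::lm.fit(cbind(1, x), y)$residuals^2)
  cand <- sort(unique(x))
  cand <- cand[cand > min(x) & cand < max(x)]
  cand <- cand[vapply(cand, function(cc)
    sum(x < cc) >= 2L && sum(x >= cc) >= 2L, logical(1))]
  best <- NULL
  for (cc in cand) {
    X <- cbind(1, pmin(x - cc, 0), pmax(x - cc, 0))
    fit <- stats::lm.fit(X, y)
    rss <- sum(fit$residuals^2)
    if (is.null(best) || rss < best$rss)
      best <- list(rss = rss, c = cc, coef = fit$coefficients)
  }
  if (is.null(best)) stop("no admissible breakpoint candidates")
  right <- x >= best$c
  plateau <- mean(best$coef[1L] + best$coef[3L] * (x[right] - best$c))
  # a breakpoint needs a clear rise on the left, a flat right segment, and
  # a real fit improvement over a single line
  hasBp <- rss1 > 1e-10 &&
    best$rss < (1 - minImprovement) * rss1 &&
    abs(best$coef[3L]) <= plateauSlopeTol &&
    best$coef[2L] > plateauSlopeTol
  if (!hasBp) plateau <- mean(y)
  new("ThresholdResult", statistic = statistic,
      breakpointSize = 10^best$c, plateauValue = plateau,
      hasBreakpoint = hasBp, method = "two-segment piecewise linear on log10 size")
}

setMethod("show", "ThresholdResult", function(object) {
  if (object@hasBreakpoint)
    cat(sprintf(
      "Threshold (%s): breakpoint at ~%.0f individuals, plateau %.3f\n",
      object@statistic, object@breakpointSize, object@plateauValue))
  else
    cat(sprintf("Threshold (%s): no breakpoint detected; overall mean %.3f\n",
                object@statistic, object@plateauValue))
})

#' Group-difference tests on per-dataset statistics
#'
#' Tests whether a goodness-of-fit statistic differs between dataset
#' groups at a fixed subsample size.  Two groups are compared by a Welch
#' two-sample t-test; three or more by one-way ANOVA followed by
#' Bonferroni-corrected pairwise Welch t-tests.
#'
#' @param values numeric vector of per-dataset statistic values (e.g. mean
#'   Mantel R at the proportion whose median size is nearest 50).
#' @param groups factor/character grouping of the same length.
#' @param alpha significance level recorded in the table (default 0.05).
#' @param alternative passed to the two-group Welch test (default
#'   "two.sided").
#' @return data.frame with columns test, groups, statistic, p_value,
#'   p_adjusted, significant.
#' @export
groupTests <- function(values, groups, alpha = 0.05,
                       alternative = "two.sided") {
  groups <- as.factor(groups)
  tab <- table(groups)
  if (length(tab) < 2L) stop("need at least 2 groups")
  if (any(tab < 2L)) warning("group with fewer than 2 values; flagged")
  lv <- levels(groups)
  rows <- list()
  safeT <- function(x, y, ...) {
    tryCatch(stats::t.test(x, y, ...),
             error = function(e) list(statistic = NA_real_,
                                      p.value = NA_real_))
  }
  if (length(lv) == 2L) {
    tt <- safeT(values[groups == lv[1L]], values[groups == lv[2L]],
                alternative = alternative)
    rows[[1L]] <- data.frame(test = "welch_t",
                             groups = paste(lv, collapse = " vs "),
                             statistic = unname(tt$statistic),
                             p_value = tt$p.value, p_adjusted = tt$p.value)
  } else {
    av <- stats::oneway.test(values ~ groups, var.equal = TRUE)  # one-way ANOVA
    rows[[1L]] <- data.frame(test = "anova",
                             groups = paste(lv, collapse = ", "),
                             statistic = unname(av$statistic),
                             p_value = av$p.value, p_adjusted = av$p.value)
    pairs <- utils::combn(lv, 2L, simplify = FALSE)
    praw <- vapply(pairs, function(pr) {
      safeT(values[groups == pr[1L]], values[groups == pr[2L]])$p.value
    }, numeric(1))
    padj <- stats::p.adjust(praw, method = "bonferroni")
    for (k in seq_along(pairs))
      rows[[k + 1L]] <- data.frame(
        test = "bonferroni_welch_t",
        groups = paste(pairs[[k]], collapse = " vs "),
        statistic = NA_real_, p_value = praw[k], p_adjusted = padj[k])
  }
  res <- do.call(rbind, rows)
  res$significant <- !is.na(res$p_adjusted) & res$p_adjusted < alpha
  res
}

#' Pick the proportion whose realised median size is nearest a target
#'
#' Convenience for fixed-size groupings (e.g. "subsample size 50", which
#' for 200-individual samples is the 25% proportion).
#'
#' @param curves data.frame from [aggregateCurves()].
#' @param size target median subsample size (default 50).
#' @return the proportion value nearest the target, per dataset pooled.
#' @export
proportionNearestSize <- function(curves, size = 50) {
  byP <- tapply(curves$median_size_mean, curves$proportion, mean)
  as.numeric(names(byP))[which.min(abs(byP - size))]
}

#' Export experiment outputs as CSV plus a JSON manifest
#'
#' Writes `curves.csv` (the figure-ready mean +/- SD table),
#' `thresholds.csv`, `group_tests.csv` and `manifest.json` (seeds,
#' settings, package version) under `outDir`.
#'
#' @param curves data.frame from [aggregateCurves()].
#' @param thresholds list of [ThresholdResult-class] (may be empty).
#' @param tests data.frame from [groupTests()] or `NULL`.
#' @param outDir output directory (created if missing).
#' @param manifest list of run parameters to serialise.
#' @return invisibly, the vector of files written.
#' @export
exportResults <- function(curves, thresholds = list(), tests = NULL,
                          outDir = ".", manifest = list()) {
  if (!dir.exists(outDir) && !dir.create(outDir, recursive = TRUE))
    stop("cannot create output directory: ", outDir)
  files <- character()
  f <- file.path(outDir, "curves.csv")
  utils::write.csv(curves, f, row.names = FALSE)
  files <- c(files, f)
  thr <- if (length(thresholds)) do.call(rbind, lapply(thresholds, function(t)
    data.frame(statistic = t@statistic, breakpoint_size = t@breakpointSize,
               plateau_value = t@plateauValue,
               has_breakpoint = t@hasBreakpoint, method = t@method)))
    else data.frame(statistic = character(), breakpoint_size = numeric(),
                    plateau_value = numeric(), has_breakpoint = logical(),
                    method = character())
  f <- file.path(outDir, "thresholds.csv")
  utils::write.csv(thr, f, row.names = FALSE)
  files <- c(files, f)
  if (!is.null(tests)) {
    f <- file.path(outDir, "group_tests.csv")
    utils::write.csv(tests, f, row.names = FALSE)
    files <- c(files, f)
  }
  manifest$package_version <- as.character(utils::packageVersion("commsize"))
  manifest$written <- format(Sys.time(), tz = "UTC")
  f <- file.path(outDir, "manifest.json")
  jsonlite::write_json(manifest, f, auto_unbox = TRUE, pretty = TRUE)
  files <- c(files, f)
  f <- file.path(outDir, "run.log")
  writeLines(c(sprintf("commsize %s | %s", manifest$package_version,
                       manifest$written),
               sprintf("curves: %d rows over %d datasets", nrow(curves),
                       length(unique(curves$dataset_id))),
               sprintf("thresholds: %d | group tests: %s", nrow(thr),
                       if (is.null(tests)) "none" else nrow(tests))), f)
  files <- c(files, f)
  invisible(files)
}
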