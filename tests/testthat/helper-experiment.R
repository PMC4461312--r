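# The desk-scale gradient experiment shared by the adequacy tests:
# one dataset per gradient design row (long gradients reduced to G = 100),
# five proportions x 100 replicates, Mantel with 199 permutations.
# Run once per test session and cached.

.experimentCache <- new.env(parent = emptyenv())

gradientExperimentCurves <- function() {
  if (!is.null(.experimentCache$curves)) return(.experimentCache$curves)
  design <- gradientDesignTable(replicates = 1L, maxG = 100)
  suite <- generateSuite(design, seed = 101, type = "gradient")
  scheme <- SubsampleScheme(nReplicates = 100L, seed = 1101L)
  settings <- analysisSettings(mantelPermutations = 199L,
                               protestPermutations = 0L, nmdsStarts = 0L)
  records <- runExperiment(suite, scheme, settings)
  .experimentCache$records <- records
  .experimentCache$curves <- aggregateCurves(records)
  .experimentCache$curves
}
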