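test_that("Gaussian response curve matches its closed form", {
  expect_equal(taxonResponse(50, 50, 10, 100), 100)
  expect_equal(taxonResponse(60, 50, 10, 100), 100 * exp(-0.5),
               tolerance = 1e-12)
  expect_lt(taxonResponse(1e6, 50, 10, 100), 1e-300)
  expect_error(taxonResponse(1, 1, 0, 10), "sigma")
})

test_that("gradient simulation rounds curve heights half-up", {
  spec <- new("GradientSpec", gradientLength = 100, nTaxa = 2L,
              nSamples = 2L, mu = c(50, 50), sigma = c(10, 10),
              peak = c(100, 100), positionMode = "unique-integer",
              seed = 1L)
  cm <- simulateGradientDataset(spec, positions = c(50, 60))
  expect_equal(unname(counts(cm)[1, 1]), 100)      # at the optimum
  expect_equal(unname(counts(cm)[2, 1]), 61)       # round(60.65...)
})

test_that("random specs are deterministic and respect their ranges", {
  s1 <- randomGradientSpec(20, 30, 100, seed = 5)
  s2 <- randomGradientSpec(20, 30, 100, seed = 5)
  expect_identical(s1@mu, s2@mu)
  expect_identical(s1@sigma, s2@sigma)
  big <- randomGradientSpec(10, 5000, 100, seed = 9)
  expect_true(all(big@mu >= 1 & big@mu <= 100))
  expect_true(all(big@sigma >= 5 & big@sigma <= 25))
  expect_true(all(big@peak >= 1 & big@peak <= 100))
  expect_error(randomGradientSpec(10, 5, 100, 1, sigmaRange = c(0.2, 0.1)),
               "sigmaRange")
})

test_that("gradient datasets have the designed shape and unimodal taxa", {
  spec <- randomGradientSpec(20, 20, 100, seed = 31)
  cm <- simulateGradientDataset(spec)
  expect_equal(nSamples(cm), 20L)
  expect_lte(nTaxa(cm), 20L)
  expect_true(all(counts(cm) >= 0))
  expect_identical(counts(simulateGradientDataset(spec)), counts(cm))
  # along the gradient every taxon rises then falls (up to rounding ties)
  ord <- order(cm@metadata$positions)
  for (t in seq_len(nTaxa(cm))) {
    y <- counts(cm)[ord, t]
    pk <- which.max(y)
    expect_true(all(diff(y[seq_len(pk)]) >= 0))
    expect_true(all(diff(y[seq(pk, length(y))]) <= 0))
  }
})

test_that("designs wider than the gradient need real-valued positions", {
  expect_error(new("GradientSpec", gradientLength = 100, nTaxa = 2L,
                   nSamples = 200L, mu = c(10, 20), sigma = c(5, 5),
                   peak = c(10, 10), positionMode = "unique-integer",
                   seed = 1L) |> validObject(),
               "uniform-real")
  spec <- randomGradientSpec(200, 20, 100, seed = 3)
  expect_equal(spec@positionMode, "uniform-real")
  expect_equal(nSamples(simulateGradientDataset(spec)), 200L)
})

test_that("default parameter ranges give median sample sizes of order hundreds", {
  meds <- vapply(1:10, function(i) {
    cm <- simulateGradientDataset(randomGradientSpec(20, 20, 100, seed = i))
    summarizeSamples(cm)@medianSampleSize
  }, numeric(1))
  expect_gt(median(meds), 50)
  expect_lt(median(meds), 2000)
})

test_that("selected datasets conserve 200 individuals and hit the J targets", {
  for (cls in c("low", "high")) {
    spec <- new("SelectedSpec", nSamples = 10L, richness = 20L,
                perSampleTotal = 200L, evennessClass = cls,
                targetJ = c(0.58, 0.79), structureId = 2L, seed = 1L)
    cm <- buildSelectedDataset(spec)
    expect_true(all(rowSums(counts(cm)) == 200))
    target <- if (cls == "low") 0.58 else 0.79
    expect_lt(abs(summarizeSamples(cm)@meanEvenness - target), 0.05)
  }
})

test_that("mixed datasets alternate low- and high-evenness communities", {
  spec <- new("SelectedSpec", nSamples = 10L, richness = 10L,
              perSampleTotal = 200L, evennessClass = "mixed",
              targetJ = c(0.58, 0.79), structureId = 2L, seed = 1L)
  ev <- summarizeSamples(buildSelectedDataset(spec))@evenness
  lowJ <- ev[seq(1, 10, 2)]
  highJ <- ev[seq(2, 10, 2)]
  expect_lt(abs(mean(lowJ) - 0.58), 0.05)
  expect_lt(abs(mean(highJ) - 0.79), 0.05)
  expect_gt(mean(highJ) - mean(lowJ), 0.15)  # two well-separated modes
})

test_that("a uniform series has J = 1 and impossible targets error", {
  expect_equal(pielouEvenness(commsize:::geometricAbundances(10, 200, 1)), 1)
  expect_error(commsize:::geometricAbundances(50, 200, 0.2), "attainable")
})

test_that("suite generation is manifest-reproducible and counts rows", {
  design <- gradientDesignTable(replicates = 1L, maxG = 100)
  expect_equal(nrow(design), 22L)
  suite <- generateSuite(design[1:4, ], seed = 7, type = "gradient")
  man <- attr(suite, "manifest")
  expect_equal(nrow(man), 4L)
  # any dataset can be rebuilt from its manifest seed
  i <- 3L
  rebuilt <- simulateGradientDataset(
    randomGradientSpec(design$n_samples[i], design$n_taxa[i],
                       design$gradient_size[i], seed = man$seed[i]))
  expect_identical(counts(rebuilt), counts(suite[[man$dataset_id[i]]]))
  # replicate multiplicity
  suite10 <- generateSuite(design[1:2, ] |>
                             transform(replicates = 5L), seed = 7,
                           type = "gradient")
  expect_equal(length(suite10), 10L)
  # selected suites carry their design labels
  sel <- generateSuite(selectedDesignTable(structures = 1),
                       seed = 3, type = "selected")
  expect_equal(nrow(attr(sel, "manifest")), 18L)
  expect_true(all(c("evenness_class", "richness") %in%
                    names(attr(sel, "manifest"))))
})
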