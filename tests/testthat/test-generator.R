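test_that("degenerate variance collapses all samples to one abundance", {
  cls <- data.frame(name = "Chrysophyceae", n_species = 1L,
                    abund_meanlog = log(1e4), abund_sdlog = 0,
                    vol_meanlog = log(300), vol_sdlog = 0,
                    primer_efficiency = 1)
  cfg <- generatorConfig(nStations = 3L, nYears = 2L, classes = cls,
                         yearEffectSd = 0, sampleNoiseSd = 0,
                         mapOneToOne = 1, mapMerged = 0, mapMetaOnly = 0,
                         heterotrophAsvCount = 0L, seed = 5L)
  tr <- generateTruth(cfg)
  expect_equal(dim(tr@trueAbundance), c(1L, 6L))
  expect_equal(length(unique(as.numeric(tr@trueAbundance))), 1L)
  expect_equal(unname(tr@trueAbundance[1, 1]), 1e4, tolerance = 1e-12)
})

test_that("identical config and seed reproduce identical outputs", {
  a <- generateDataset(smallConfig(seed = 3L))
  b <- generateDataset(smallConfig(seed = 3L))
  expect_identical(a$truth@trueAbundance, b$truth@trueAbundance)
  expect_identical(speciesData(a$species), speciesData(b$species))
  expect_identical(asvCounts(a$asv), asvCounts(b$asv))
  c <- generateDataset(smallConfig(seed = 4L))
  expect_false(identical(asvCounts(a$asv), asvCounts(c$asv)))
})

test_that("copy number follows the volume power law", {
  cls <- data.frame(name = c("A1", "A2"), n_species = c(1L, 1L),
                    abund_meanlog = log(1e4), abund_sdlog = 0,
                    vol_meanlog = log(c(10, 100)), vol_sdlog = 0,
                    primer_efficiency = 1)
  cfg <- generatorConfig(nStations = 2L, nYears = 1L, classes = cls,
                         copyNumberExponent = 1,
                         mapOneToOne = 1, mapMerged = 0, mapMetaOnly = 0,
                         heterotrophAsvCount = 0L, seed = 1L)
  tr <- generateTruth(cfg)
  cn <- sort(tr@copyNumber)
  expect_equal(unname(cn[2] / cn[1]), 10)
})

test_that("invalid configs fail with the offending field named", {
  expect_error(generatorConfig(readDepth = 10L), "readDepth")
  expect_error(generatorConfig(microscopyCountVolume = 0),
               "microscopyCountVolume")
  expect_error(generatorConfig(mapOneToOne = 0.5, mapMerged = 0.1,
                               mapMetaOnly = 0.1), "mapping fractions")
  cls <- defaultClassSpecs(); cls$primer_efficiency[1] <- 0
  expect_error(generatorConfig(classes = cls), "primer_efficiency")
})

test_that("microscopy totals land within 3 Poisson SD of the expectation", {
  cfg <- generatorConfig(seed = 9L)
  tr <- generateTruth(cfg)
  st <- simulateMicroscopy(tr, cfg)
  v <- cfg@microscopyCountVolume
  visible <- setdiff(rownames(tr@trueAbundance), tr@metaOnlySpecies)
  expMean <- sum(tr@trueAbundance[visible, ]) * v
  obs <- sum(speciesData(st)$abundance) * v
  expect_lt(abs(obs - expMean), 3 * sqrt(expMean))
})

test_that("metabarcoding-only species never appear in the microscopy table", {
  ds <- generateDataset(generatorConfig(seed = 2L))
  expect_gt(length(ds$truth@metaOnlySpecies), 0)
  expect_false(any(ds$truth@metaOnlySpecies %in% speciesData(ds$species)$species))
})

test_that("reads per sample sum exactly to the configured depth", {
  ds <- generateDataset(smallConfig(seed = 6L))
  expect_true(all(colSums(asvCounts(ds$asv)) == 5000L))
})

test_that("expected read ratios follow copy-number weights", {
  # two species, equal abundance, copy numbers 1 and 10 via b = 1
  cls <- data.frame(name = c("A1", "A2"), n_species = c(1L, 1L),
                    abund_meanlog = log(1e5), abund_sdlog = 0,
                    vol_meanlog = log(c(1, 10)), vol_sdlog = 0,
                    primer_efficiency = 1)
  cfg <- generatorConfig(nStations = 1L, nYears = 1L, classes = cls,
                         copyNumberExponent = 1, readDepth = 1000000L,
                         yearEffectSd = 0, sampleNoiseSd = 0,
                         mapOneToOne = 1, mapMerged = 0, mapMetaOnly = 0,
                         heterotrophAsvCount = 0L, seed = 8L)
  tr <- generateTruth(cfg)
  at <- simulateReads(tr, cfg)
  cts <- asvCounts(at)[, 1]
  ratio <- cts[["ASV_A2_sp01"]] / cts[["ASV_A1_sp01"]]
  expect_equal(ratio, 10, tolerance = 0.05)
})

test_that("species sharing an ASV pool their read weights", {
  cfg <- smallConfig(seed = 12L, mapOneToOne = 0.4, mapMerged = 0.6,
                     mapMetaOnly = 0, readDepth = 1000000L)
  ds <- generateDataset(cfg)
  map <- ds$truth@asvMap
  merged <- names(which(table(map$asv_id) > 1))
  expect_gt(length(merged), 0)
  # expected proportion of the merged ASV = sum of its species' weights
  tr <- ds$truth
  eff <- setNames(cfg@classes$primer_efficiency, cfg@classes$name)
  w <- tr@trueAbundance * tr@copyNumber[rownames(tr@trueAbundance)] *
    eff[tr@classOf[rownames(tr@trueAbundance)]]
  asvW <- rowsum(w[map$species, , drop = FALSE], group = map$asv_id)
  hetCts <- asvCounts(ds$asv)[tr@heterotrophAsvs, , drop = FALSE]
  phytoDepth <- colSums(asvCounts(ds$asv)) - colSums(hetCts)
  expProp <- sweep(asvW, 2, colSums(asvW), "/")
  obsProp <- sweep(asvCounts(ds$asv)[rownames(asvW), ], 2, phytoDepth, "/")
  expect_lt(max(abs(expProp[merged, ] - obsProp[merged, ])), 0.01)
})

test_that("unbiased regime read proportions converge to true proportions", {
  cfg <- unbiasedConfig(seed = 21L, readDepth = 1000000L)
  ds <- generateDataset(cfg)
  tr <- ds$truth
  trueProp <- sweep(tr@trueAbundance, 2, colSums(tr@trueAbundance), "/")
  map <- ds$truth@asvMap
  cts <- asvCounts(ds$asv)
  obsProp <- sweep(cts, 2, colSums(cts), "/")
  asvOf <- setNames(map$asv_id, map$species)
  dev <- abs(obsProp[asvOf[rownames(trueProp)], ] - trueProp)
  expect_lt(max(dev), 0.01)
})

test_that("class-structured bias leaves within-class proportions unbiased", {
  cfg <- classBiasConfig(seed = 31L, readDepth = 1000000L,
                         mapOneToOne = 1, mapMerged = 0, mapMetaOnly = 0,
                         heterotrophAsvCount = 0L)
  ds <- generateDataset(cfg)
  tr <- ds$truth
  cts <- asvCounts(ds$asv)
  asvOf <- setNames(tr@asvMap$asv_id, tr@asvMap$species)
  for (cc in unique(tr@classOf)) {
    sp <- names(tr@classOf)[tr@classOf == cc]
    trueProp <- sweep(tr@trueAbundance[sp, , drop = FALSE], 2,
                      colSums(tr@trueAbundance[sp, , drop = FALSE]), "/")
    sub <- cts[asvOf[sp], , drop = FALSE]
    obsProp <- sweep(sub, 2, colSums(sub), "/")
    expect_lt(max(abs(obsProp - trueProp)), 0.02)
  }
})

test_that("no heterotroph lineages appear when heterotrophAsvCount is 0", {
  ds <- generateDataset(smallConfig(seed = 13L, heterotrophAsvCount = 0L))
  expect_true(all(asvTrophic(ds$asv) == "phytoplankton"))
  expect_identical(sort(unique(speciesData(ds$species)$sample_id)),
                   sort(sampleIds(ds$asv)))
})
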