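# small paired fixture: 3 phyto ASVs in 2 classes over 3 samples
quantFixture <- function() {
  counts <- rbind(ASV_d1 = c(25L, 10L, 0L),
                  ASV_d2 = c(75L, 30L, 5L),
                  ASV_c1 = c(100L, 60L, 0L))
  colnames(counts) <- c("s1", "s2", "s3")
  lin <- setNames(c(
    paste("Eukaryota", "SG", "D", "S", "Bacillariophyceae", "O", "F", "G",
          "d1", sep = ";"),
    paste("Eukaryota", "SG", "D", "S", "Bacillariophyceae", "O", "F", "G",
          "d2", sep = ";"),
    paste("Eukaryota", "SG", "D", "S", "Chrysophyceae", "O", "F", "G",
          "c1", sep = ";")), rownames(counts))
  asv <- asvTable(counts, lineage = lin)
  sp <- speciesTable(data.frame(
    sample_id = c("s1", "s1", "s2", "s3", "s3"),
    species = c("diatomA", "chrysoA", "diatomA", "diatomA", "diatomB"),
    class_name = c("Bacillariophyceae", "Chrysophyceae",
                   "Bacillariophyceae", "Bacillariophyceae",
                   "Bacillariophyceae"),
    abundance = c(120e3, 40e3, 50e3, 10e3, 20e3),
    biomass = c(10, 4, 5, 1, 2)))
  list(asv = asv, species = sp, anchors = anchorTotals(sp))
}

test_that("total-scheme values are the anchored products and conserve totals", {
  fx <- quantFixture()
  R <- relativeAbundance(fx$asv)
  q <- absoluteByTotal(R, fx$anchors, "abundance")
  v <- quantValues(q)
  # R = 0.125 for ASV_d1 in s1; A_s1 = 160e3
  expect_equal(v["ASV_d1", "s1"], 0.125 * 160e3)
  expect_equal(unname(colSums(v)),
               unname(sampleTotals(fx$anchors, "abundance")[colnames(v)]),
               tolerance = 1e-12)
  qb <- absoluteByTotal(R, fx$anchors, "biomass")
  expect_equal(unname(colSums(quantValues(qb))),
               unname(sampleTotals(fx$anchors, "biomass")[colnames(v)]),
               tolerance = 1e-12)
  # rank preservation: multiplying by a positive anchor keeps sample order
  expect_equal(order(v[, "s1"]), order(relAbundance(R)[, "s1"]))
})

test_that("zero anchors give zero estimates; missing samples are errors", {
  fx <- quantFixture()
  sp0 <- speciesTable(rbind(speciesData(fx$species)[0, ],
    data.frame(sample_id = "s1", species = "x",
               class_name = "Bacillariophyceae", abundance = 0,
               biomass = 0)))
  anch0 <- anchorTotals(sp0, samples = c("s1", "s2", "s3"))
  R <- relativeAbundance(fx$asv)
  expect_true(all(quantValues(absoluteByTotal(R, anch0)) == 0))
  anchMissing <- anchorTotals(speciesTable(
    speciesData(fx$species)[speciesData(fx$species)$sample_id == "s1", ]))
  expect_error(absoluteByTotal(R, anchMissing), "s2")
})

test_that("class-scheme values use class anchors and mask impossible cells", {
  fx <- quantFixture()
  Rc <- classRelativeAbundance(fx$asv)
  q <- absoluteByClass(Rc, fx$anchors, "abundance")
  v <- quantValues(q)
  # within Bacillariophyceae in s1: R_d1 = 0.25, A_jc = 120e3
  expect_equal(v["ASV_d1", "s1"], 0.25 * 120e3)
  # Chrysophyceae has reads in s2 but no microscopy cells -> masked
  expect_true(is.na(v["ASV_c1", "s2"]))
  # Chrysophyceae has no reads in s3 -> undefined as well
  expect_true(is.na(v["ASV_c1", "s3"]))
  # single-ASV class equals the full class anchor where defined
  expect_equal(v["ASV_c1", "s1"],
               classTotals(fx$anchors)["Chrysophyceae", "s1"])
  # conservation within class wherever defined
  expect_equal(sum(v[c("ASV_d1", "ASV_d2"), "s1"]),
               classTotals(fx$anchors)["Bacillariophyceae", "s1"][[1]],
               tolerance = 1e-12)
})

test_that("proxy class mapping anchors orphan classes; unknown proxy errors", {
  fx <- quantFixture()
  counts <- rbind(ASV_n1 = c(10L, 5L, 2L))
  colnames(counts) <- c("s1", "s2", "s3")
  lin <- setNames(paste("Eukaryota", "SG", "D", "S", "Eustigmatophyceae",
                        "O", "F", "G", "n1", sep = ";"), "ASV_n1")
  orphan <- asvTable(counts, lineage = lin)
  Rc <- classRelativeAbundance(orphan)
  expect_error(absoluteByClass(Rc, fx$anchors), "proxy")
  pm <- proxyClassMap("Eustigmatophyceae", "Bacillariophyceae")
  q <- absoluteByClass(Rc, fx$anchors, proxy = pm)
  expect_equal(quantValues(q)["ASV_n1", "s1"],
               classTotals(fx$anchors)["Bacillariophyceae", "s1"][[1]])
  expect_error(absoluteByClass(Rc, fx$anchors,
                               proxy = proxyClassMap("Eustigmatophyceae",
                                                     "NoSuchClass")),
               "unknown proxy")
  # mapping a class to itself is identity behaviour
  RcD <- classRelativeAbundance(fx$asv)["Bacillariophyceae"]
  qSelf <- absoluteByClass(RcD, fx$anchors,
                           proxy = proxyClassMap("Bacillariophyceae",
                                                 "Bacillariophyceae"))
  qPlain <- absoluteByClass(RcD, fx$anchors)
  expect_identical(quantValues(qSelf), quantValues(qPlain))
})

test_that("schemes coincide when read and microscopy class shares agree", {
  # construct reads whose class shares equal the microscopy class shares
  sp <- speciesTable(data.frame(
    sample_id = c("s1", "s1"), species = c("diatomA", "chrysoA"),
    class_name = c("Bacillariophyceae", "Chrysophyceae"),
    abundance = c(60e3, 40e3), biomass = c(6, 4)))
  anch <- anchorTotals(sp)
  counts <- rbind(ASV_d1 = 30L, ASV_d2 = 30L, ASV_c1 = 40L)
  colnames(counts) <- "s1"
  lin <- setNames(c(
    paste("Eukaryota", "SG", "D", "S", "Bacillariophyceae", "O", "F", "G",
          "d1", sep = ";"),
    paste("Eukaryota", "SG", "D", "S", "Bacillariophyceae", "O", "F", "G",
          "d2", sep = ";"),
    paste("Eukaryota", "SG", "D", "S", "Chrysophyceae", "O", "F", "G",
          "c1", sep = ";")), rownames(counts))
  asv <- asvTable(counts, lineage = lin)
  qTot <- quantValues(absoluteByTotal(relativeAbundance(asv), anch))
  qCls <- quantValues(absoluteByClass(classRelativeAbundance(asv), anch))
  expect_equal(qTot[rownames(qCls), , drop = FALSE], qCls,
               tolerance = 1e-12)
})

test_that("conservation holds on random fixtures for both schemes", {
  set.seed(99)
  for (rep in 1:25) {
    nAsv <- sample(3:8, 1); nSm <- sample(3:6, 1)
    classes <- c("Bacillariophyceae", "Chrysophyceae", "Cryptophyceae")
    cls <- sample(classes, nAsv, replace = TRUE)
    counts <- matrix(rpois(nAsv * nSm, 40), nAsv, nSm,
                     dimnames = list(sprintf("ASV%02d", seq_len(nAsv)),
                                     paste0("s", seq_len(nSm))))
    storage.mode(counts) <- "integer"
    lin <- setNames(paste("Eukaryota", "SG", "D", "S", cls, "O", "F", "G",
                          rownames(counts), sep = ";"), rownames(counts))
    asv <- asvTable(counts, lineage = lin)
    spd <- expand.grid(sample_id = colnames(counts),
                       species = paste0("sp_", classes),
                       stringsAsFactors = FALSE)
    spd$class_name <- sub("sp_", "", spd$species)
    spd$abundance <- stats::runif(nrow(spd), 1e3, 1e5)
    spd$biomass <- stats::runif(nrow(spd), 0.1, 10)
    anch <- anchorTotals(speciesTable(spd))
    qT <- quantValues(absoluteByTotal(relativeAbundance(asv), anch))
    ok <- colSums(counts) > 0
    expect_equal(colSums(qT)[ok],
                 sampleTotals(anch, "abundance")[colnames(counts)][ok],
                 tolerance = 1e-9)
    Rc <- classRelativeAbundance(asv)
    qC <- quantValues(absoluteByClass(Rc, anch))
    clsOf <- asvClass(asv)
    for (cc in unique(cls)) {
      sub <- qC[names(clsOf)[clsOf == cc], , drop = FALSE]
      defined <- colSums(is.na(sub)) == 0
      expect_equal(colSums(sub)[defined],
                   classTotals(anch, "abundance")[cc, names(defined)][defined],
                   tolerance = 1e-9)
    }
  }
})
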