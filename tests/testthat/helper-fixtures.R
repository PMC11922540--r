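# in-code fixtures shared across test files

# toy ASV table: counts chosen so filtering rules have forced outcomes
toyAsvTable <- function() {
  counts <- rbind(
    ASV_a = c(1L, 1L, 0L),    # total 2 -> removed by read filter
    ASV_b = c(2L, 1L, 0L),    # total 3 -> kept
    ASV_c = c(50L, 30L, 20L), # kept
    ASV_d = c(9999L, 1L, 0L), # Metazoa -> removed
    ASV_e = c(5L, 5L, 5L),    # Streptophyta -> removed
    ASV_f = c(7L, 7L, 7L),    # nucleomorph -> removed
    ASV_g = c(4L, 4L, 4L),    # unclassified domain -> removed
    ASV_h = c(10L, 0L, 2L))   # heterotroph, kept by lineage filter
  colnames(counts) <- c("1_20", "2_20", "3_20")
  lin <- function(class, sp) paste("Eukaryota", "SG", "Div", "Sub", class,
                                   "Ord", "Fam", "Gen", sp, sep = ";")
  lineage <- c(
    ASV_a = lin("Chrysophyceae", "a"),
    ASV_b = lin("Chrysophyceae", "b"),
    ASV_c = lin("Bacillariophyceae", "c"),
    ASV_d = paste("Eukaryota", "Obazoa", "Opisthokonta", "Metazoa",
                  "Metazoa_X", "Ord", "Fam", "Gen", "d", sep = ";"),
    ASV_e = paste("Eukaryota", "Archaeplastida", "Streptophyta", "Sub",
                  "Embryophyceae", "Ord", "Fam", "Gen", "e", sep = ";"),
    ASV_f = paste("Eukaryota", "SG", "Div:nucl", "Sub", "Cryptophyceae",
                  "Ord", "Fam", "Gen", "f", sep = ";"),
    ASV_g = paste("unclassified", "SG", "Div", "Sub", "Cls",
                  "Ord", "Fam", "Gen", "g", sep = ";"),
    ASV_h = lin("Ciliophora", "h"))
  asvTable(counts, lineage = lineage)
}

# small species table: two classes over two samples
toySpeciesTable <- function() {
  speciesTable(data.frame(
    sample_id = c("1_20", "1_20", "1_20", "2_20", "2_20"),
    species = c("spA", "spB", "spC", "spA", "spC"),
    class_name = c("Bacillariophyceae", "Bacillariophyceae",
                   "Chrysophyceae", "Bacillariophyceae", "Chrysophyceae"),
    abundance = c(10e3, 20e3, 30e3, 5e3, 15e3),
    biomass = c(1, 2, 3, 0.5, 1.5),
    stringsAsFactors = FALSE))
}

# tiny generator config for fast property tests
smallConfig <- function(seed = 1L, readDepth = 5000L,
                        heterotrophAsvCount = 2L, ...) {
  cls <- data.frame(
    name = c("Bacillariophyceae", "Chrysophyceae"),
    n_species = c(3L, 3L),
    abund_meanlog = log(c(2e4, 1e4)),
    abund_sdlog = c(0.8, 0.8),
    vol_meanlog = log(c(800, 300)),
    vol_sdlog = c(0.4, 0.4),
    primer_efficiency = c(1, 1.5),
    stringsAsFactors = FALSE)
  generatorConfig(nStations = 3L, nYears = 2L, classes = cls,
                  readDepth = readDepth,
                  heterotrophAsvCount = heterotrophAsvCount,
                  seed = seed, ...)
}

# brute-force RV via the double-sum of squared covariances
bruteForceRV <- function(X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  covs2 <- function(A, B) {
    s <- 0
    for (i in seq_len(ncol(A)))
      for (j in seq_len(ncol(B)))
        s <- s + stats::cov(A[, i], B[, j])^2
    s
  }
  covs2(X, Y) / sqrt(covs2(X, X) * covs2(Y, Y))
}
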