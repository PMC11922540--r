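#' @include AllClasses.R accessors.R
NULL

# Lineage template: nine PR2-style ranks with the class at position 5.
.makeLineage <- function(class_name, genus, species) {
  paste("Eukaryota", "Supergroup_sim", "Division_sim", "Subdivision_sim",
        class_name, paste0("Order_", class_name), paste0("Family_", class_name),
        genus, species, sep = ";")
}

.heterotrophTaxa <- c("Ciliophora", "Cercozoa", "Bicoecea", "Rozellomycota")

#' Default class specifications for the community generator
#'
#' Six phytoplankton classes with lognormal abundance and cell-volume
#' parameters chosen to emulate a spring lake community: diatoms
#' (Bacillariophyceae, Mediophyceae) with mid-to-large cells, small-celled
#' Chrysophyceae/Cryptophyceae/Chlorophyceae, and large-celled Dinophyceae
#' with an elevated primer efficiency standing in for their high marker-gene
#' copy number. Abundances are cells per litre; volumes um^3.
#'
#' @return data.frame suitable for the \code{classes} slot of
#'   \linkS4class{GeneratorConfig}.
#' @export
defaultClassSpecs <- function() {
  data.frame(
    name = c("Bacillariophyceae", "Mediophyceae", "Chrysophyceae",
             "Cryptophyceae", "Dinophyceae", "Chlorophyceae"),
    n_species = c(4L, 3L, 5L, 4L, 3L, 5L),
    abund_meanlog = log(c(2e4, 1.5e4, 2.5e4, 1e4, 3e3, 1.5e4)),
    abund_sdlog = c(1, 1, 1, 1, 1, 1),
    vol_meanlog = log(c(800, 1200, 300, 400, 8000, 150)),
    vol_sdlog = c(0.6, 0.5, 0.5, 0.5, 0.7, 0.6),
    primer_efficiency = c(1.0, 1.1, 0.9, 1.2, 2.5, 0.8),
    stringsAsFactors = FALSE)
}

#' Build a generator configuration
#'
#' @param nStations,nYears sample grid (default 9 x 3 = 27 samples).
#' @param classes class specification data.frame; see
#'   \code{\link{defaultClassSpecs}}.
#' @param copyNumberExponent b in copy number = volume^b (default 0.6).
#' @param readDepth reads per sample (default 30000).
#' @param microscopyCountVolume effective counted volume in litres
#'   (default 0.01, i.e. 10 mL of concentrated sample).
#' @param yearEffectSd sd of the shared class-by-year lognormal effect
#'   (default 0.7; samples within a year are correlated).
#' @param sampleNoiseSd residual per-species-per-sample lognormal sd
#'   (default 0.4).
#' @param mapOneToOne,mapMerged,mapMetaOnly species-to-ASV mapping fractions
#'   (must sum to 1).
#' @param heterotrophAsvCount heterotroph ASVs mixed into the reads
#'   (default 22).
#' @param seed integer seed.
#' @return a validated \linkS4class{GeneratorConfig}.
#' @export
generatorConfig <- function(nStations = 9L, nYears = 3L,
                            classes = defaultClassSpecs(),
                            copyNumberExponent = 0.6,
                            readDepth = 30000L,
                            microscopyCountVolume = 0.01,
                            yearEffectSd = 0.7,
                            sampleNoiseSd = 0.4,
                            mapOneToOne = 0.7,
                            mapMerged = 0.2,
                            mapMetaOnly = 0.1,
                            heterotrophAsvCount = 22L,
                            seed = 1L) {
  cfg <- new("GeneratorConfig",
    nStations = as.integer(nStations), nYears = as.integer(nYears),
    classes = classes, copyNumberExponent = as.numeric(copyNumberExponent),
    readDepth = as.integer(readDepth),
    microscopyCountVolume = as.numeric(microscopyCountVolume),
    yearEffectSd = as.numeric(yearEffectSd),
    sampleNoiseSd = as.numeric(sampleNoiseSd),
    mapOneToOne = as.numeric(mapOneToOne), mapMerged = as.numeric(mapMerged),
    mapMetaOnly = as.numeric(mapMetaOnly),
    heterotrophAsvCount = as.integer(heterotrophAsvCount),
    seed = as.integer(seed))
  validObject(cfg)
  cfg
}

#' Configuration of the class-structured bias regime
#'
#' A variant of the default configuration in which amplification bias is
#' structured strictly at the class level: cell volumes (hence copy numbers)
#' are constant within each class and primer efficiencies differ between
#' classes. Under this regime within-class read proportions are unbiased
#' estimates of within-class true relative abundances, the premise that
#' makes class-specific anchoring more accurate than total anchoring.
#'
#' @param seed integer seed.
#' @param ... further arguments passed to \code{\link{generatorConfig}}.
#' @return a \linkS4class{GeneratorConfig}.
#' @export
classBiasConfig <- function(seed = 1L, ...) {
  cls <- defaultClassSpecs()
  cls$vol_sdlog <- 0
  generatorConfig(classes = cls, seed = seed, ...)
}

#' Configuration of the unbiased regime
#'
#' No copy-number scaling (b = 0), equal primer efficiencies, no
#' heterotroph reads and strict one-to-one species-ASV mapping: expected
#' read proportions equal true relative abundances.
#'
#' @param seed integer seed.
#' @param readDepth reads per sample (default 1e5).
#' @param ... further arguments passed to \code{\link{generatorConfig}}.
#' @return a \linkS4class{GeneratorConfig}.
#' @export
unbiasedConfig <- function(seed = 1L, readDepth = 100000L, ...) {
  cls <- defaultClassSpecs()
  cls$primer_efficiency <- 1
  generatorConfig(classes = cls, copyNumberExponent = 0,
                  readDepth = readDepth, heterotrophAsvCount = 0L,
                  mapOneToOne = 1, mapMerged = 0, mapMetaOnly = 0,
                  seed = seed, ...)
}

# Deterministic community-wide partition of species into mapping groups.
# Quotas are set on the whole community (per-class rounding would starve
# small classes), then handed out to the classes with most unassigned
# species first; merged species are taken in within-class pairs.
.partitionMapping <- function(classSizes, fracMerged, fracMeta) {
  N <- sum(classSizes)
  nMeta <- round(fracMeta * N)
  nMergedPairs <- floor(fracMerged * N / 2)
  remaining <- classSizes
  mergedAlloc <- metaAlloc <- integer(length(classSizes))
  for (p in seq_len(nMergedPairs)) {
    elig <- which(remaining >= 2)
    if (length(elig) == 0) break
    k <- elig[which.max(remaining[elig])]
    mergedAlloc[k] <- mergedAlloc[k] + 2L
    remaining[k] <- remaining[k] - 2L
  }
  for (p in seq_len(nMeta)) {
    elig <- which(remaining >= 1)
    if (length(elig) == 0) break
    k <- elig[which.max(remaining[elig])]
    metaAlloc[k] <- metaAlloc[k] + 1L
    remaining[k] <- remaining[k] - 1L
  }
  lapply(seq_along(classSizes), function(k)
    rep(c("one_to_one", "merged", "meta_only"),
        c(remaining[k], mergedAlloc[k], metaAlloc[k])))
}

#' Generate the ground truth of a simulated community
#'
#' Draws per-species lognormal abundances over an nStations x nYears sample
#' grid with a shared class-by-year random effect (samples within a year are
#' correlated, mirroring year-dominant community structure), lognormal cell
#' volumes, copy numbers = volume^b, and a species-to-ASV map with
#' one-to-one, merged (genus-level) and metabarcoding-only species.
#'
#' @param config a \linkS4class{GeneratorConfig}.
#' @return a \linkS4class{TruthRecord}.
#' @export
generateTruth <- function(config) {
  stopifnot(is(config, "GeneratorConfig"))
  validObject(config)
  set.seed(config@seed)
  cls <- config@classes
  yearSuffix <- as.character(20 + seq_len(config@nYears) - 1L)
  sampleIds <- as.vector(outer(seq_len(config@nStations), yearSuffix,
                               function(s, y) paste0(s, "_", y)))
  yearOf <- setNames(rep(yearSuffix, each = config@nStations), sampleIds)

  species <- character(0); classOf <- character(0)
  cellVolume <- numeric(0); speciesOffset <- numeric(0)
  mapping <- character(0)
  mappingAlloc <- .partitionMapping(cls$n_species, config@mapMerged,
                                    config@mapMetaOnly)
  for (k in seq_len(nrow(cls))) {
    n <- cls$n_species[k]
    sp <- sprintf("%s_sp%02d", cls$name[k], seq_len(n))
    species <- c(species, sp)
    classOf <- c(classOf, setNames(rep(cls$name[k], n), sp))
    cellVolume <- c(cellVolume,
      setNames(rlnorm(n, cls$vol_meanlog[k], cls$vol_sdlog[k]), sp))
    speciesOffset <- c(speciesOffset,
      setNames(rnorm(n, 0, cls$abund_sdlog[k]), sp))
    mapping <- c(mapping, setNames(mappingAlloc[[k]], sp))
  }

  # shared class-by-year effect, then residual species-by-sample noise
  yearEffect <- matrix(rnorm(nrow(cls) * config@nYears, 0, config@yearEffectSd),
                       nrow(cls), config@nYears,
                       dimnames = list(cls$name, yearSuffix))
  nSp <- length(species); nSm <- length(sampleIds)
  noise <- matrix(rnorm(nSp * nSm, 0, config@sampleNoiseSd), nSp, nSm)
  meanlog <- cls$abund_meanlog[match(classOf, cls$name)]
  logAbund <- matrix(meanlog + speciesOffset, nSp, nSm) +
    yearEffect[cbind(match(classOf, cls$name),
                     rep(match(yearOf, yearSuffix), each = nSp))] + noise
  trueAbundance <- exp(logAbund)
  dimnames(trueAbundance) <- list(species, sampleIds)

  copyNumber <- setNames(cellVolume ^ config@copyNumberExponent, species)

  # species -> ASV map; merged species pair up within their class
  asvMap <- do.call(rbind, lapply(seq_len(nrow(cls)), function(k) {
    sp <- species[classOf == cls$name[k]]
    grp <- mapping[sp]
    rows <- list()
    for (s in sp[grp != "merged"]) {
      rows[[s]] <- data.frame(species = s, asv_id = paste0("ASV_", s),
        lineage = .makeLineage(cls$name[k], paste0("Genus_", cls$name[k]), s),
        stringsAsFactors = FALSE)
    }
    merged <- sp[grp == "merged"]
    if (length(merged) > 0) {
      pair <- ceiling(seq_along(merged) / 2)
      for (g in unique(pair)) {
        gid <- sprintf("ASV_%s_genus%02d", cls$name[k], g)
        for (s in merged[pair == g]) {
          rows[[s]] <- data.frame(species = s, asv_id = gid,
            lineage = .makeLineage(cls$name[k],
                                   paste0("Genus_", cls$name[k]),
                                   paste0("Genus_", cls$name[k], "_sp")),
            stringsAsFactors = FALSE)
        }
      }
    }
    do.call(rbind, rows)
  }))
  rownames(asvMap) <- NULL

  hetAsvs <- character(0)
  if (config@heterotrophAsvCount > 0L)
    hetAsvs <- sprintf("ASV_het%02d", seq_len(config@heterotrophAsvCount))

  tr <- new("TruthRecord", trueAbundance = trueAbundance,
            cellVolume = cellVolume, classOf = classOf,
            copyNumber = copyNumber, asvMap = asvMap,
            heterotrophAsvs = hetAsvs,
            metaOnlySpecies = names(mapping)[mapping == "meta_only"],
            sampleIds = sampleIds, yearOf = yearOf)
  validObject(tr)
  tr
}

#' Simulate microscopy observation of a community
#'
#' Counted cells per species and sample are Poisson with mean
#' true abundance x counted volume, rescaled back to cells per litre;
#' biomass is abundance x cell volume x 1e-9 (um^3 cells L^-1 -> mg L^-1,
#' unit density). Species with zero counted cells, and species visible to
#' metabarcoding only, are absent from the table.
#'
#' @param truth a \linkS4class{TruthRecord}.
#' @param config the \linkS4class{GeneratorConfig} used to generate it.
#' @return a \linkS4class{SpeciesTable}.
#' @export
simulateMicroscopy <- function(truth, config) {
  stopifnot(is(truth, "TruthRecord"), is(config, "GeneratorConfig"))
  set.seed(config@seed + 1L)
  v <- config@microscopyCountVolume
  visible <- setdiff(rownames(truth@trueAbundance), truth@metaOnlySpecies)
  ab <- truth@trueAbundance[visible, , drop = FALSE]
  counted <- matrix(rpois(length(ab), ab * v), nrow(ab), ncol(ab),
                    dimnames = dimnames(ab))
  obs <- counted / v
  idx <- which(counted > 0, arr.ind = TRUE)
  sp <- rownames(obs)[idx[, 1]]
  d <- data.frame(
    sample_id = colnames(obs)[idx[, 2]],
    species = sp,
    class_name = unname(truth@classOf[sp]),
    abundance = obs[idx],
    biomass = speciesBiomass(obs[idx], truth@cellVolume[sp]),
    stringsAsFactors = FALSE)
  d <- d[order(d$sample_id, d$species), ]
  rownames(d) <- NULL
  st <- new("SpeciesTable", data = d)
  validObject(st)
  st
}

#' Simulate metabarcoding reads of a community
#'
#' Expected ASV weight per sample is proportional to true abundance x
#' copy number x class primer efficiency, summed over species sharing an
#' ASV; heterotroph ASVs get independent lognormal weights scaled to the
#' community; reads are multinomial at the configured depth.
#'
#' @param truth a \linkS4class{TruthRecord}.
#' @param config the \linkS4class{GeneratorConfig} used to generate it.
#' @return an \linkS4class{AsvTable} (unfiltered; includes heterotrophs).
#' @export
simulateReads <- function(truth, config) {
  stopifnot(is(truth, "TruthRecord"), is(config, "GeneratorConfig"))
  if (config@readDepth < 1L) stop("readDepth must be >= 1")
  set.seed(config@seed + 2L)
  cls <- config@classes
  eff <- setNames(cls$primer_efficiency, cls$name)
  sp <- rownames(truth@trueAbundance)
  w <- truth@trueAbundance * truth@copyNumber[sp] *
    eff[truth@classOf[sp]]

  asvIds <- unique(truth@asvMap$asv_id)
  agg <- rowsum(w[truth@asvMap$species, , drop = FALSE],
                group = truth@asvMap$asv_id, reorder = FALSE)
  agg <- agg[asvIds, , drop = FALSE]

  lineage <- setNames(truth@asvMap$lineage[!duplicated(truth@asvMap$asv_id)],
                      unique(truth@asvMap$asv_id))

  nHet <- length(truth@heterotrophAsvs)
  if (nHet > 0) {
    # heterotroph expected weights: lognormal around the mean phyto ASV weight
    base <- log(pmax(colMeans(agg), .Machine$double.eps))
    hw <- matrix(rlnorm(nHet * ncol(agg),
                        meanlog = rep(base, each = nHet), sdlog = 1),
                 nHet, ncol(agg),
                 dimnames = list(truth@heterotrophAsvs, colnames(agg)))
    hetTaxa <- sample(.heterotrophTaxa, nHet, replace = TRUE)
    hetLineage <- setNames(
      .makeLineage(hetTaxa, paste0("Genus_", hetTaxa), truth@heterotrophAsvs),
      truth@heterotrophAsvs)
    agg <- rbind(agg, hw)
    lineage <- c(lineage, hetLineage)
  }

  counts <- apply(agg, 2, function(col)
    rmultinom(1, config@readDepth, col / sum(col)))
  dimnames(counts) <- list(rownames(agg), colnames(agg))

  trophic <- ifelse(rownames(counts) %in% truth@heterotrophAsvs,
                    "heterotroph", "phytoplankton")
  asvTable(counts, lineage = lineage[rownames(counts)], trophic = trophic)
}

#' Generate a paired microscopy/metabarcoding dataset
#'
#' Composition of \code{\link{generateTruth}},
#' \code{\link{simulateMicroscopy}} and \code{\link{simulateReads}}; the
#' single config seed controls all randomness.
#'
#' @param config a \linkS4class{GeneratorConfig}.
#' @return list with elements \code{species} (\linkS4class{SpeciesTable}),
#'   \code{asv} (\linkS4class{AsvTable}) and \code{truth}
#'   (\linkS4class{TruthRecord}).
#' @export
generateDataset <- function(config) {
  truth <- generateTruth(config)
  list(species = simulateMicroscopy(truth, config),
       asv = simulateReads(truth, config),
       truth = truth)
}
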