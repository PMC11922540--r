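#' @include AllClasses.R accessors.R generator.R microscopy.R asv.R
#' @include quantification.R composition.R consistency.R
NULL

# row-normalise a samples x features matrix to proportions
.closeRows <- function(m) {
  rs <- rowSums(m)
  rs[rs == 0] <- NA
  m / rs
}

# aggregate the columns (features) of a samples x features matrix by class
.aggregateByClass <- function(m, classOf) {
  cls <- classOf[colnames(m)]
  keep <- !is.na(cls)
  t(rowsum(t(m[, keep, drop = FALSE]), group = cls[keep]))
}

#' Run the end-to-end microscopy/metabarcoding comparison
#'
#' Orchestrates the full analysis on either a synthetic dataset (from a
#' \linkS4class{GeneratorConfig}) or files on disk: ASV filtering,
#' relative-abundance matrices, total- and class-anchored quantification,
#' compositional transforms, class-level and species-by-ASV Spearman
#' correlation grids with BH adjustment, correlation-count summaries, RV
#' coefficients across the quantitative-data variants, and diversity
#' tables, with a provenance record of every filtering step.
#'
#' @param config list with components:
#'   \describe{
#'     \item{generator}{a \linkS4class{GeneratorConfig} (takes precedence),
#'       or \code{NULL} to read files;}
#'     \item{speciesPath, asvCountsPath, taxonomyPath}{input TSVs when no
#'       generator is given;}
#'     \item{transforms}{subset of \code{c("relative", "rank01", "clr",
#'       "absolute_total", "absolute_class")} (default: all);}
#'     \item{alpha}{significance level (default 0.05);}
#'     \item{minPrevalence}{prevalence threshold for correlation features
#'       (default 8);}
#'     \item{topN}{optional cap on the number of phytoplankton ASVs (by
#'       total reads, after the prevalence filter);}
#'     \item{proxy}{named proxy-class map for class-scheme anchoring;}
#'     \item{outputDir}{optional directory for TSV/JSON outputs.}
#'   }
#' @return (invisibly) a list: \code{grids} (class-level and species-level
#'   \linkS4class{CorrelationGrid}s), \code{counts} (significant-correlation
#'   summary), \code{rv} (RV table), \code{diversity}, \code{quantified},
#'   \code{provenance}.
#' @export
runComparison <- function(config) {
  stopifnot(is.list(config))
  transforms <- config$transforms %||%
    c("relative", "rank01", "clr", "absolute_total", "absolute_class")
  badTr <- setdiff(transforms,
    c("relative", "rank01", "clr", "absolute_total", "absolute_class"))
  if (length(badTr) > 0) stop("unknown transform(s): ",
                              paste(badTr, collapse = ", "))
  if (length(transforms) == 0) stop("at least one transform is required")
  alpha <- config$alpha %||% 0.05
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  minPrev <- config$minPrevalence %||% 8L

  prov <- list(package_version = as.character(packageVersion("phytoanchor")),
               alpha = alpha, min_prevalence = minPrev,
               transforms = transforms)

  if (!is.null(config$generator)) {
    gen <- config$generator
    if (!is(gen, "GeneratorConfig")) stop("generator must be a GeneratorConfig")
    ds <- generateDataset(gen)
    species <- ds$species; asvRaw <- ds$asv
    prov$seed <- gen@seed
    prov$input <- "synthetic"
  } else {
    species <- readSpeciesTable(config$speciesPath)
    asvRaw <- readAsvTable(config$asvCountsPath, config$taxonomyPath)
    prov$input <- list(species = config$speciesPath,
                       asv = config$asvCountsPath,
                       taxonomy = config$taxonomyPath)
  }

  unmatched <- c(setdiff(sampleIds(species), sampleIds(asvRaw)),
                 setdiff(sampleIds(asvRaw), sampleIds(species)))
  if (length(unmatched) > 0)
    stop("sample id(s) present in only one table: ",
         paste(unique(unmatched), collapse = ", "))

  filtered <- filterAsvs(asvRaw)
  phyto <- selectPhytoplankton(filtered)
  prov$asv_filter <- S4Vectors::metadata(filtered)$filter_log
  prov$trophic_filter <- S4Vectors::metadata(phyto)$filter_log

  phytoPrev <- prevalenceFilter(phyto, minSamples = minPrev)
  if (!is.null(config$topN)) phytoPrev <- topAsvs(phytoPrev, config$topN)
  prov$n_asv_correlation <- nrow(phytoPrev)

  # relative abundances are computed over ALL phytoplankton reads, then
  # restricted to the correlation feature set
  Rall <- relativeAbundance(phyto)
  Rclass <- classRelativeAbundance(phyto)
  anchors <- anchorTotals(species, samples = sampleIds(asvRaw))

  quantified <- list()
  if ("absolute_total" %in% transforms) {
    quantified$total_abundance <- absoluteByTotal(Rall, anchors, "abundance")
    quantified$total_biomass <- absoluteByTotal(Rall, anchors, "biomass")
  }
  if ("absolute_class" %in% transforms) {
    quantified$class_abundance <- absoluteByClass(Rclass, anchors,
                                                  "abundance",
                                                  proxy = config$proxy)
    quantified$class_biomass <- absoluteByClass(Rclass, anchors, "biomass",
                                                proxy = config$proxy)
    prov$masked_cells <- sum(is.na(quantValues(quantified$class_abundance)))
  }

  # sample x feature tables -------------------------------------------------
  keepAsv <- rownames(phytoPrev)
  spAb <- t(speciesMatrix(species, "abundance"))     # samples x species
  spBm <- t(speciesMatrix(species, "biomass"))
  spKeep <- colnames(spAb)[colSums(spAb > 0) >= minPrev]
  spRelAb <- .closeRows(spAb)[, spKeep, drop = FALSE]
  spRelBm <- .closeRows(spBm)[, spKeep, drop = FALSE]
  spAbsAb <- spAb[, spKeep, drop = FALSE]
  spAbsBm <- spBm[, spKeep, drop = FALSE]

  asvRel <- t(relAbundance(Rall))[, keepAsv, drop = FALSE]
  tables <- list()
  if ("relative" %in% transforms) {
    tables$relative_abundance <- list(mic = spRelAb, micBm = spRelBm,
                                      meta = asvRel)
  }
  if ("clr" %in% transforms) {
    tables$clr <- list(
      mic = transformedValues(clrTransform(spRelAb)),
      micBm = transformedValues(clrTransform(spRelBm)),
      meta = transformedValues(clrTransform(asvRel)))
  }
  if ("absolute_total" %in% transforms) {
    tables$absolute_total <- list(
      mic = spAbsAb, micBm = spAbsBm,
      meta = t(quantValues(quantified$total_abundance))[, keepAsv,
                                                        drop = FALSE],
      metaBm = t(quantValues(quantified$total_biomass))[, keepAsv,
                                                        drop = FALSE])
  }
  if ("absolute_class" %in% transforms) {
    qa <- t(quantValues(quantified$class_abundance))
    qb <- t(quantValues(quantified$class_biomass))
    ka <- intersect(keepAsv, colnames(qa))
    tables$absolute_class <- list(
      mic = spAbsAb, micBm = spAbsBm,
      meta = qa[, ka, drop = FALSE], metaBm = qb[, ka, drop = FALSE])
  }

  # species x ASV grids ------------------------------------------------------
  grids <- list()
  if ("relative" %in% transforms) {
    grids$relative_abundance <- spearmanGrid(tables$relative_abundance$mic,
                                             tables$relative_abundance$meta,
                                             alpha = alpha)
    grids$relative_biomass <- spearmanGrid(tables$relative_abundance$micBm,
                                           tables$relative_abundance$meta,
                                           alpha = alpha)
  }
  if ("clr" %in% transforms) {
    grids$clr_abundance <- spearmanGrid(tables$clr$mic, tables$clr$meta,
                                        alpha = alpha)
    grids$clr_biomass <- spearmanGrid(tables$clr$micBm, tables$clr$meta,
                                      alpha = alpha)
  }
  if ("absolute_total" %in% transforms) {
    grids$absolute_total_abundance <- spearmanGrid(
      tables$absolute_total$mic, tables$absolute_total$meta, alpha = alpha)
    grids$absolute_total_biomass <- spearmanGrid(
      tables$absolute_total$micBm, tables$absolute_total$metaBm,
      alpha = alpha)
  }
  if ("absolute_class" %in% transforms) {
    grids$absolute_class_abundance <- spearmanGrid(
      tables$absolute_class$mic, tables$absolute_class$meta, alpha = alpha)
    grids$absolute_class_biomass <- spearmanGrid(
      tables$absolute_class$micBm, tables$absolute_class$metaBm,
      alpha = alpha)
  }

  # class-level grids (six pairings) -----------------------------------------
  classGrids <- list()
  spClass <- speciesClassMap(species)
  asvClassMap <- asvClass(phyto)
  micClassAb <- .aggregateByClass(spAb, spClass)
  micClassBm <- .aggregateByClass(spBm, spClass)
  metaClassRel <- .aggregateByClass(t(relAbundance(Rall)), asvClassMap)
  if ("relative" %in% transforms) {
    classGrids$rel_abundance <- spearmanGrid(.closeRows(micClassAb),
                                             metaClassRel, alpha = alpha)
    classGrids$rel_biomass <- spearmanGrid(.closeRows(micClassBm),
                                           metaClassRel, alpha = alpha)
  }
  if ("clr" %in% transforms) {
    classGrids$clr_abundance <- spearmanGrid(
      transformedValues(clrTransform(.closeRows(micClassAb))),
      transformedValues(clrTransform(metaClassRel)), alpha = alpha)
    classGrids$clr_biomass <- spearmanGrid(
      transformedValues(clrTransform(.closeRows(micClassBm))),
      transformedValues(clrTransform(metaClassRel)), alpha = alpha)
  }
  if ("absolute_total" %in% transforms) {
    metaClassAbsAb <- .aggregateByClass(
      t(quantValues(quantified$total_abundance)), asvClassMap)
    metaClassAbsBm <- .aggregateByClass(
      t(quantValues(quantified$total_biomass)), asvClassMap)
    classGrids$abs_abundance <- spearmanGrid(micClassAb, metaClassAbsAb,
                                             alpha = alpha)
    classGrids$abs_biomass <- spearmanGrid(micClassBm, metaClassAbsBm,
                                           alpha = alpha)
  }

  counts <- do.call(rbind, lapply(names(grids), function(g) {
    ct <- countCorrelations(grids[[g]])
    data.frame(grid = g, n_negative = ct[["n_negative"]],
               n_positive = ct[["n_positive"]])
  }))

  # RV table across quantitative-data variants -------------------------------
  rvRow <- function(mic, meta, micBm, metaBm)
    c(abundance = rvCoefficient(mic, meta),
      biomass = rvCoefficient(micBm, metaBm))
  rv <- list()
  if ("relative" %in% transforms)
    rv$relative <- rvRow(spRelAb, asvRel, spRelBm, asvRel)
  if ("rank01" %in% transforms)
    rv$rank01 <- rvRow(transformedValues(rank01Transform(spRelAb)),
                       transformedValues(rank01Transform(asvRel)),
                       transformedValues(rank01Transform(spRelBm)),
                       transformedValues(rank01Transform(asvRel)))
  if ("clr" %in% transforms)
    rv$clr <- rvRow(tables$clr$mic, tables$clr$meta,
                    tables$clr$micBm, tables$clr$meta)
  if ("absolute_total" %in% transforms)
    rv$absolute <- rvRow(spAbsAb, tables$absolute_total$meta,
                         spAbsBm, tables$absolute_total$metaBm)
  rvTable <- if (length(rv) > 0)
    data.frame(variant = names(rv), do.call(rbind, rv), row.names = NULL)
  else data.frame()

  diversity <- rbind(
    cbind(method = "microscopy",
          diversityProfile(spAb, chao1 = FALSE)),
    cbind(method = "metabarcoding",
          diversityProfile(t(asvCounts(phyto)), chao1 = TRUE)))

  result <- list(grids = grids, classGrids = classGrids, counts = counts,
                 rv = rvTable, diversity = diversity,
                 quantified = quantified, anchors = anchors,
                 provenance = prov)
  if (!is.null(config$outputDir)) .writeBundle(result, config$outputDir)
  invisible(result)
}

.writeBundle <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(x, f) write.table(x, file.path(dir, f), sep = "\t",
                                   quote = FALSE, row.names = FALSE)
  wtm <- function(m, f) write.table(
    data.frame(feature = rownames(m), m, check.names = FALSE),
    file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  for (g in names(result$grids)) {
    wtm(gridMatrix(result$grids[[g]], "r"), paste0("grid_", g, "_r.tsv"))
    wtm(gridMatrix(result$grids[[g]], "q"), paste0("grid_", g, "_q.tsv"))
  }
  wt(result$counts, "correlation_counts.tsv")
  if (nrow(result$rv) > 0) wt(result$rv, "rv_table.tsv")
  wt(result$diversity, "diversity.tsv")
  for (qn in names(result$quantified)) {
    m <- quantValues(result$quantified[[qn]])
    wtm(m, paste0("quantified_", qn, ".tsv"))
  }
  jsonlite::write_json(result$provenance,
                       file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Validate input files for the comparison pipeline
#'
#' Schema check, sample-id cross-check, and a screen for negative or
#' non-finite values. Structural problems (missing columns, duplicate
#' species rows, ASVs without taxonomy) are errors; non-fatal issues are
#' returned as warnings.
#'
#' @param speciesPath long-format species TSV.
#' @param asvCountsPath ASV count TSV (samples as rows).
#' @param taxonomyPath two-column taxonomy TSV.
#' @return list with \code{ok = TRUE} and a character vector
#'   \code{warnings} (empty when the inputs are clean).
#' @export
validateInputs <- function(speciesPath, asvCountsPath, taxonomyPath) {
  for (p in c(speciesPath, asvCountsPath, taxonomyPath))
    if (!file.exists(p)) stop("file not found: ", p)
  warnings <- character(0)

  sp <- read.delim(speciesPath, stringsAsFactors = FALSE)
  req <- c("sample_id", "species", "class_name", "abundance", "biomass")
  if (!all(req %in% names(sp)))
    stop("species table is missing column(s): ",
         paste(setdiff(req, names(sp)), collapse = ", "))
  dup <- duplicated(sp[, c("sample_id", "species")])
  if (any(dup))
    stop("duplicate (sample_id, species) row(s) at line(s): ",
         paste(which(dup) + 1L, collapse = ", "))
  badVal <- !is.finite(sp$abundance) | !is.finite(sp$biomass) |
    sp$abundance < 0 | sp$biomass < 0
  if (any(badVal))
    stop("negative or non-finite abundance/biomass at line(s): ",
         paste(which(badVal) + 1L, collapse = ", "))

  cts <- read.delim(asvCountsPath, stringsAsFactors = FALSE,
                    check.names = FALSE)
  if (ncol(cts) < 2) stop("ASV count table has no ASV columns")
  m <- as.matrix(cts[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("ASV counts must be numeric")
  if (any(!is.finite(m)) || any(m < 0) || any(m != round(m)))
    stop("ASV counts must be non-negative integers")

  tax <- read.delim(taxonomyPath, stringsAsFactors = FALSE)
  if (ncol(tax) < 2) stop("taxonomy table needs (asv_id, lineage) columns")
  noTax <- setdiff(colnames(m), tax[[1]])
  if (length(noTax) > 0)
    stop("ASV(s) missing from taxonomy: ", paste(noTax, collapse = ", "))

  spSamples <- unique(sp$sample_id)
  asvSamples <- cts[[1]]
  onlySp <- setdiff(spSamples, asvSamples)
  onlyAsv <- setdiff(asvSamples, spSamples)
  if (length(onlySp) > 0)
    warnings <- c(warnings, paste("samples only in species table:",
                                  paste(onlySp, collapse = ", ")))
  if (length(onlyAsv) > 0)
    warnings <- c(warnings, paste("samples only in ASV table:",
                                  paste(onlyAsv, collapse = ", ")))
  extraTax <- setdiff(tax[[1]], colnames(m))
  if (length(extraTax) > 0)
    warnings <- c(warnings,
                  paste("taxonomy entries without counts:",
                        paste(extraTax, collapse = ", ")))
  list(ok = TRUE, warnings = warnings)
}
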