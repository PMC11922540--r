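#' @include AllClasses.R
NULL

#' Accessors for phytoanchor data classes
#'
#' Small accessor layer so downstream code never touches slots directly.
#'
#' @param x an object of one of the package's S4 classes.
#' @param ... unused.
#' @name accessors
NULL

#' @describeIn accessors sample identifiers of a table.
#' @export
setGeneric("sampleIds", function(x, ...) standardGeneric("sampleIds"))

#' @describeIn accessors the relative-abundance matrix (ASVs x samples).
#' @export
setGeneric("relAbundance", function(x, ...) standardGeneric("relAbundance"))

#' @describeIn accessors quantified values (ASVs x samples, NA = masked).
#' @export
setGeneric("quantValues", function(x, ...) standardGeneric("quantValues"))

#' @describeIn accessors transformed values (samples x features).
#' @export
setGeneric("transformedValues", function(x, ...)
  standardGeneric("transformedValues"))

setMethod("sampleIds", "SpeciesTable", function(x, ...)
  sort(unique(x@data$sample_id)))
setMethod("sampleIds", "AsvTable", function(x, ...) colnames(x))
setMethod("sampleIds", "RelAbundanceMatrix", function(x, ...) colnames(x@ra))
setMethod("sampleIds", "AnchorTotals", function(x, ...) names(x@abundance))
setMethod("sampleIds", "QuantifiedAsvTable", function(x, ...)
  colnames(x@values))
setMethod("sampleIds", "TruthRecord", function(x, ...) x@sampleIds)

setMethod("relAbundance", "RelAbundanceMatrix", function(x, ...) x@ra)
setMethod("quantValues", "QuantifiedAsvTable", function(x, ...) x@values)
setMethod("transformedValues", "TransformedMatrix", function(x, ...) x@values)

#' @describeIn accessors long-format data.frame of a SpeciesTable.
#' @export
speciesData <- function(x) {
  stopifnot(is(x, "SpeciesTable"))
  x@data
}

#' Wide abundance / biomass matrices of a SpeciesTable
#'
#' Species absent from a sample get 0 (microscopy observed no cells).
#'
#' @param x a \linkS4class{SpeciesTable}.
#' @param quantity \code{"abundance"} or \code{"biomass"}.
#' @return numeric matrix, species x samples.
#' @export
speciesMatrix <- function(x, quantity = c("abundance", "biomass")) {
  stopifnot(is(x, "SpeciesTable"))
  quantity <- match.arg(quantity)
  d <- x@data
  sp <- sort(unique(d$species))
  sm <- sort(unique(d$sample_id))
  m <- matrix(0, length(sp), length(sm), dimnames = list(sp, sm))
  m[cbind(match(d$species, sp), match(d$sample_id, sm))] <- d[[quantity]]
  m
}

#' Species -> class map of a SpeciesTable
#' @param x a \linkS4class{SpeciesTable}.
#' @return named character vector.
#' @export
speciesClassMap <- function(x) {
  stopifnot(is(x, "SpeciesTable"))
  d <- unique(x@data[, c("species", "class_name")])
  setNames(d$class_name, d$species)
}

#' @describeIn accessors read counts of an AsvTable (ASVs x samples).
#' @export
asvCounts <- function(x) {
  stopifnot(is(x, "AsvTable"))
  SummarizedExperiment::assay(x, "counts")
}

#' @describeIn accessors per-ASV lineage strings.
#' @export
asvLineage <- function(x) {
  stopifnot(is(x, "AsvTable"))
  setNames(SummarizedExperiment::rowData(x)$lineage, rownames(x))
}

#' @describeIn accessors per-ASV taxonomic class.
#' @export
asvClass <- function(x) {
  stopifnot(is(x, "AsvTable"))
  setNames(as.character(SummarizedExperiment::rowData(x)$class_name),
           rownames(x))
}

#' @describeIn accessors per-ASV trophic flag.
#' @export
asvTrophic <- function(x) {
  stopifnot(is(x, "AsvTable"))
  setNames(as.character(SummarizedExperiment::rowData(x)$trophic),
           rownames(x))
}

#' Anchor totals accessors
#'
#' @param x an \linkS4class{AnchorTotals}.
#' @param quantity \code{"abundance"} or \code{"biomass"}.
#' @return \code{sampleTotals}: named numeric per sample (A_j or M_j);
#'   \code{classTotals}: numeric matrix classes x samples (A_jc or M_jc).
#' @export
sampleTotals <- function(x, quantity = c("abundance", "biomass")) {
  stopifnot(is(x, "AnchorTotals"))
  quantity <- match.arg(quantity)
  if (quantity == "abundance") x@abundance else x@biomass
}

#' @rdname sampleTotals
#' @export
classTotals <- function(x, quantity = c("abundance", "biomass")) {
  stopifnot(is(x, "AnchorTotals"))
  quantity <- match.arg(quantity)
  if (quantity == "abundance") x@classAbundance else x@classBiomass
}

#' @describeIn accessors significance mask of a CorrelationGrid (q <= alpha).
#' @export
significanceMask <- function(x) {
  stopifnot(is(x, "CorrelationGrid"))
  m <- !is.na(x@q) & x@q <= x@alpha
  m
}

#' @describeIn accessors r / p / q matrices of a CorrelationGrid.
#' @param what one of "r", "p", "q", "n".
#' @export
gridMatrix <- function(x, what = c("r", "p", "q", "n")) {
  stopifnot(is(x, "CorrelationGrid"))
  switch(match.arg(what), r = x@r, p = x@p, q = x@q, n = x@nUsed)
}

#' @describeIn accessors the RV coefficient of a CoinertiaResult.
#' @export
rvValue <- function(x) {
  stopifnot(is(x, "CoinertiaResult"))
  x@rv
}

#' @describeIn accessors per-axis co-inertia of a CoinertiaResult.
#' @export
axisInertia <- function(x) {
  stopifnot(is(x, "CoinertiaResult"))
  x@axisInertia
}

setMethod("show", "SpeciesTable", function(object) {
  d <- object@data
  cat("SpeciesTable:", length(unique(d$species)), "species,",
      length(unique(d$sample_id)), "samples,",
      length(unique(d$class_name)), "classes\n")
})

setMethod("show", "RelAbundanceMatrix", function(object) {
  cat("RelAbundanceMatrix [", object@scope,
      if (object@scope == "within_class") paste0(": ", object@className),
      "] ", nrow(object@ra), " ASVs x ", ncol(object@ra), " samples (",
      sum(object@emptySamples), " empty)\n", sep = "")
})

setMethod("show", "AnchorTotals", function(object) {
  cat("AnchorTotals:", length(object@abundance), "samples,",
      nrow(object@classAbundance), "classes\n")
})

setMethod("show", "QuantifiedAsvTable", function(object) {
  cat("QuantifiedAsvTable [", object@method, ", ", object@quantity, "] ",
      nrow(object@values), " ASVs x ", ncol(object@values), " samples, ",
      sum(is.na(object@values)), " masked cells\n", sep = "")
})

setMethod("show", "CorrelationGrid", function(object) {
  m <- significanceMask(object)
  cat("CorrelationGrid:", nrow(object@r), "x", ncol(object@r),
      "pairs, alpha =", object@alpha, "->", sum(m), "significant\n")
})

setMethod("show", "CoinertiaResult", function(object) {
  cat("CoinertiaResult: RV =", format(object@rv, digits = 4),
      "(", object@nAxes, "axes )\n")
})

setMethod("show", "GeneratorConfig", function(object) {
  cat("GeneratorConfig:", object@nStations, "stations x", object@nYears,
      "years,", sum(object@classes$n_species), "species in",
      nrow(object@classes), "classes, depth", object@readDepth, "\n")
})

setMethod("show", "TruthRecord", function(object) {
  cat("TruthRecord:", nrow(object@trueAbundance), "species x",
      ncol(object@trueAbundance), "samples;",
      nrow(object@asvMap), "species-ASV links;",
      length(object@heterotrophAsvs), "heterotroph ASVs\n")
})
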