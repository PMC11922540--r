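#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment assay assayNames rowData
#' @importFrom S4Vectors DataFrame metadata 'metadata<-'
#' @importFrom stats rnorm rlnorm rpois rmultinom cor pt qt p.adjust dist
#'   hclust sd setNames
#' @importFrom utils read.delim write.table packageVersion
NULL

#' SpeciesTable: microscopy observations of phytoplankton species
#'
#' Long-format container for per-sample microscopy observations: species
#' identity, taxonomic class, absolute abundance (cells L^-1) and biomass
#' (mg L^-1). A species appears at most once per sample; species not observed
#' in a sample are simply absent from it.
#'
#' @slot data data.frame with columns \code{sample_id}, \code{species},
#'   \code{class_name}, \code{abundance}, \code{biomass}.
#' @export
setClass("SpeciesTable", slots = c(data = "data.frame"))

setValidity("SpeciesTable", function(object) {
  d <- object@data
  req <- c("sample_id", "species", "class_name", "abundance", "biomass")
  if (!all(req %in% names(d)))
    return(paste("missing columns:", paste(setdiff(req, names(d)), collapse = ", ")))
  if (nrow(d) == 0) return(TRUE)
  if (any(duplicated(d[, c("sample_id", "species")])))
    return("duplicate (sample_id, species) rows")
  if (any(!is.finite(d$abundance)) || any(d$abundance < 0))
    return("abundance must be finite and non-negative")
  if (any(!is.finite(d$biomass)) || any(d$biomass < 0))
    return("biomass must be finite and non-negative")
  if (any(is.na(d$class_name) | !nzchar(d$class_name)))
    return("class_name must be non-empty")
  TRUE
})

#' AsvTable: ASV read counts with taxonomy
#'
#' A \linkS4class{SummarizedExperiment} holding an integer read-count matrix
#' (ASVs in rows, samples in columns) in the \code{"counts"} assay, with
#' per-ASV metadata in \code{rowData}: \code{lineage} (semicolon-delimited
#' ranked taxonomy, PR2-style), \code{class_name} (taxonomic class extracted
#' from the lineage) and \code{trophic} (\code{"phytoplankton"} or
#' \code{"heterotroph"}, possibly \code{NA} before flagging).
#'
#' @export
setClass("AsvTable", contains = "SummarizedExperiment")

setValidity("AsvTable", function(object) {
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    return("assay 'counts' is required")
  cts <- SummarizedExperiment::assay(object, "counts")
  if (any(cts < 0) || any(cts != round(cts)))
    return("counts must be non-negative integers")
  if (!"lineage" %in% names(SummarizedExperiment::rowData(object)))
    return("rowData column 'lineage' is required")
  lin <- SummarizedExperiment::rowData(object)$lineage
  if (any(is.na(lin) | !nzchar(lin)))
    return("every ASV must have a lineage entry")
  TRUE
})

#' RelAbundanceMatrix: row-stochastic relative abundances
#'
#' Relative read abundances with an explicit scope: either all phytoplankton
#' reads of a sample (\code{scope = "all_phyto"}) or the reads of one
#' taxonomic class (\code{scope = "within_class"}). ASVs are rows, samples
#' are columns; each non-empty sample column sums to 1. Samples with zero
#' reads in the scope are flagged empty and carry \code{NA}.
#'
#' @slot ra numeric matrix, ASVs x samples.
#' @slot scope \code{"all_phyto"} or \code{"within_class"}.
#' @slot className the class for within-class scope, \code{NA} otherwise.
#' @slot emptySamples named logical, one per sample.
#' @export
setClass("RelAbundanceMatrix",
  slots = c(ra = "matrix", scope = "character", className = "character",
            emptySamples = "logical"))

setValidity("RelAbundanceMatrix", function(object) {
  if (!object@scope %in% c("all_phyto", "within_class"))
    return("scope must be 'all_phyto' or 'within_class'")
  ra <- object@ra
  ok <- !object@emptySamples
  if (length(ok) != ncol(ra))
    return("emptySamples must have one entry per sample column")
  if (any(ok)) {
    vals <- ra[, ok, drop = FALSE]
    if (any(is.na(vals)) || any(vals < -1e-12) || any(vals > 1 + 1e-12))
      return("entries of non-empty samples must lie in [0, 1]")
    s <- colSums(vals)
    if (any(abs(s - 1) > 1e-9))
      return("non-empty sample columns must sum to 1 (+/- 1e-9)")
  }
  TRUE
})

#' AnchorTotals: per-sample and per-class microscopy totals
#'
#' Per sample j the total phytoplankton abundance A_j (cells L^-1) and
#' biomass M_j (mg L^-1); per sample and class c the class totals A_jc and
#' M_jc. Class totals are additive: summing over classes recovers the
#' sample totals.
#'
#' @slot abundance named numeric, A_j per sample.
#' @slot biomass named numeric, M_j per sample.
#' @slot classAbundance numeric matrix, classes x samples (A_jc).
#' @slot classBiomass numeric matrix, classes x samples (M_jc).
#' @export
setClass("AnchorTotals",
  slots = c(abundance = "numeric", biomass = "numeric",
            classAbundance = "matrix", classBiomass = "matrix"))

setValidity("AnchorTotals", function(object) {
  if (any(object@abundance < 0) || any(object@biomass < 0) ||
      any(object@classAbundance < 0) || any(object@classBiomass < 0))
    return("anchor totals must be non-negative")
  tolOK <- function(colsum, tot) all(abs(colsum - tot) <= 1e-8 * pmax(tot, 1))
  if (!tolOK(colSums(object@classAbundance), object@abundance))
    return("class abundances must sum to the sample total")
  if (!tolOK(colSums(object@classBiomass), object@biomass))
    return("class biomasses must sum to the sample total")
  TRUE
})

#' QuantifiedAsvTable: anchored absolute abundances or biomasses
#'
#' Estimated absolute values per ASV and sample, obtained by multiplying
#' relative read abundances by microscopy anchors. Cells that cannot be
#' computed (class-anchored scheme where the class has reads but microscopy
#' recorded no cells of that class, or samples with no reads in scope) are
#' \code{NA} ("masked"), deliberately distinct from zero.
#'
#' @slot values numeric matrix, ASVs x samples, \code{NA} where masked.
#' @slot quantity \code{"abundance"} (cells L^-1) or \code{"biomass"} (mg L^-1).
#' @slot method \code{"asv_x_total"} or \code{"asv_x_class"}.
#' @slot className per-ASV anchoring class (\code{NA} for the total scheme).
#' @export
setClass("QuantifiedAsvTable",
  slots = c(values = "matrix", quantity = "character", method = "character",
            className = "character"))

setValidity("QuantifiedAsvTable", function(object) {
  if (!object@quantity %in% c("abundance", "biomass"))
    return("quantity must be 'abundance' or 'biomass'")
  if (!object@method %in% c("asv_x_total", "asv_x_class"))
    return("method must be 'asv_x_total' or 'asv_x_class'")
  v <- object@values
  if (any(v[!is.na(v)] < 0)) return("defined values must be non-negative")
  TRUE
})

#' TransformedMatrix: compositional or rank transform of a feature table
#'
#' @slot values numeric matrix, samples x features.
#' @slot transform one of \code{"clr"}, \code{"rank01"}, \code{"none"}.
#' @slot zeroRecord data.frame recording, per sample, the zero-replacement
#'   pseudo-value used before the clr transform (empty for other transforms).
#' @export
setClass("TransformedMatrix",
  slots = c(values = "matrix", transform = "character",
            zeroRecord = "data.frame"))

setValidity("TransformedMatrix", function(object) {
  if (!object@transform %in% c("clr", "rank01", "none"))
    return("transform must be 'clr', 'rank01' or 'none'")
  v <- object@values
  if (object@transform == "clr" && nrow(v) > 0) {
    if (any(abs(rowSums(v)) > 1e-9 * pmax(1, ncol(v))))
      return("clr rows must sum to 0 (+/- 1e-9)")
  }
  if (object@transform == "rank01" && length(v) > 0) {
    if (any(v < -1e-12 | v > 1 + 1e-12))
      return("rank01 entries must lie in [0, 1]")
  }
  TRUE
})

#' CorrelationGrid: Spearman correlations with BH-adjusted significance
#'
#' All-pairs Spearman correlations between the features of two tables that
#' share samples, with two-sided p-values from the t approximation and
#' q-values from Benjamini-Hochberg adjustment applied jointly over the
#' whole grid. Pairs with fewer than 4 pairwise-complete samples are
#' undefined (\code{NA}).
#'
#' @slot r,p,q numeric matrices, rows = features of X, columns = features of Y.
#' @slot nUsed integer matrix of pairwise-complete sample counts.
#' @slot alpha significance level used by the mask.
#' @export
setClass("CorrelationGrid",
  slots = c(r = "matrix", p = "matrix", q = "matrix", nUsed = "matrix",
            alpha = "numeric"))

setValidity("CorrelationGrid", function(object) {
  r <- object@r
  if (any(abs(r[!is.na(r)]) > 1 + 1e-12)) return("r must lie in [-1, 1]")
  if (object@alpha <= 0 || object@alpha >= 1) return("alpha must be in (0, 1)")
  qv <- object@q; pv <- object@p
  idx <- !is.na(qv) & !is.na(pv)
  if (any(qv[idx] < pv[idx] - 1e-12)) return("q must be >= p elementwise")
  TRUE
})

#' CoinertiaResult: co-inertia decomposition of two paired tables
#'
#' @slot rv the RV coefficient in [0, 1].
#' @slot axisInertia per-axis co-inertia (squared singular values of the
#'   cross-covariance), for the retained axes.
#' @slot totalCoinertia total co-inertia (sum over all axes).
#' @slot nAxes number of axes retained.
#' @slot rowScores,colScores sample scores of each table on the co-inertia axes.
#' @export
setClass("CoinertiaResult",
  slots = c(rv = "numeric", axisInertia = "numeric", totalCoinertia = "numeric",
            nAxes = "integer", rowScores = "matrix", colScores = "matrix"))

#' GeneratorConfig: parameters of the paired-community generator
#'
#' Defines the simulated study: a station-by-year sample grid, class-
#' structured lognormal species abundances and cell volumes, microscopy
#' counting effort, and the read-generation bias model (gene copy number
#' increasing with cell biovolume, class-level primer efficiency).
#'
#' @slot nStations,nYears grid dimensions (default 9 x 3 = 27 samples).
#' @slot classes data.frame with one row per class: \code{name},
#'   \code{n_species}, \code{abund_meanlog}, \code{abund_sdlog} (species-level
#'   spread of log abundance), \code{vol_meanlog}, \code{vol_sdlog} (log cell
#'   volume, um^3), \code{primer_efficiency} (> 0).
#' @slot copyNumberExponent b in copy number proportional to volume^b.
#' @slot readDepth reads per sample (>= 100).
#' @slot microscopyCountVolume effective counted volume, litres.
#' @slot yearEffectSd,sampleNoiseSd lognormal sd of the shared class-year
#'   effect and of residual per-sample noise.
#' @slot mapOneToOne,mapMerged,mapMetaOnly fractions of species mapped
#'   one-to-one to an ASV, merged into a shared genus-level ASV, or visible
#'   to metabarcoding only (absent from microscopy).
#' @slot heterotrophAsvCount number of heterotroph ASVs added to the reads.
#' @slot seed integer seed controlling all randomness.
#' @export
setClass("GeneratorConfig",
  slots = c(nStations = "integer", nYears = "integer", classes = "data.frame",
            copyNumberExponent = "numeric", readDepth = "integer",
            microscopyCountVolume = "numeric", yearEffectSd = "numeric",
            sampleNoiseSd = "numeric", mapOneToOne = "numeric",
            mapMerged = "numeric", mapMetaOnly = "numeric",
            heterotrophAsvCount = "integer", seed = "integer"))

setValidity("GeneratorConfig", function(object) {
  if (object@nStations < 1L) return("nStations must be >= 1")
  if (object@nYears < 1L) return("nYears must be >= 1")
  cls <- object@classes
  req <- c("name", "n_species", "abund_meanlog", "abund_sdlog",
           "vol_meanlog", "vol_sdlog", "primer_efficiency")
  if (!all(req %in% names(cls)))
    return(paste("classes is missing columns:",
                 paste(setdiff(req, names(cls)), collapse = ", ")))
  if (nrow(cls) < 1) return("at least one class is required")
  if (any(cls$n_species < 1)) return("n_species must be >= 1")
  if (any(cls$primer_efficiency <= 0)) return("primer_efficiency must be > 0")
  if (any(cls$abund_sdlog < 0) || any(cls$vol_sdlog < 0))
    return("log-sd parameters must be >= 0")
  if (object@readDepth < 100L) return("readDepth must be >= 100")
  if (object@microscopyCountVolume <= 0)
    return("microscopyCountVolume must be > 0")
  if (object@yearEffectSd < 0 || object@sampleNoiseSd < 0)
    return("effect sd parameters must be >= 0")
  fr <- c(object@mapOneToOne, object@mapMerged, object@mapMetaOnly)
  if (any(fr < 0) || any(fr > 1) || abs(sum(fr) - 1) > 1e-9)
    return("mapping fractions must lie in [0, 1] and sum to 1")
  if (object@heterotrophAsvCount < 0L)
    return("heterotrophAsvCount must be >= 0")
  TRUE
})

#' TruthRecord: ground truth of a simulated community
#'
#' @slot trueAbundance numeric matrix, species x samples, cells L^-1.
#' @slot cellVolume named numeric, um^3 per species.
#' @slot classOf named character, species -> class.
#' @slot copyNumber named numeric, relative marker-gene copies per cell.
#' @slot asvMap data.frame: \code{species}, \code{asv_id}, \code{lineage}.
#' @slot heterotrophAsvs character, ASV ids of heterotroph reads.
#' @slot metaOnlySpecies species visible to metabarcoding only.
#' @slot sampleIds sample identifiers "station_yearSuffix".
#' @slot yearOf named character, sample -> year suffix.
#' @export
setClass("TruthRecord",
  slots = c(trueAbundance = "matrix", cellVolume = "numeric",
            classOf = "character", copyNumber = "numeric",
            asvMap = "data.frame", heterotrophAsvs = "character",
            metaOnlySpecies = "character", sampleIds = "character",
            yearOf = "character"))

setValidity("TruthRecord", function(object) {
  if (any(object@trueAbundance < 0)) return("true abundance must be >= 0")
  if (any(object@cellVolume <= 0)) return("cell volumes must be > 0")
  sp <- rownames(object@trueAbundance)
  if (!all(sp %in% names(object@classOf)))
    return("every species must have a class")
  mapped <- setdiff(sp, object@metaOnlySpecies)
  if (!all(mapped %in% object@asvMap$species) ||
      !all(object@metaOnlySpecies %in% object@asvMap$species))
    return("asvMap must cover every species")
  TRUE
})
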