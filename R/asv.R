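#' @include AllClasses.R accessors.R
NULL

# lineage ranks are semicolon-delimited, PR2-style:
# domain;supergroup;division;subdivision;class;order;family;genus;species
.CLASS_RANK <- 5L

.lineageRank <- function(lineage, rank) {
  parts <- strsplit(lineage, ";", fixed = TRUE)
  vapply(parts, function(p) if (length(p) >= rank) p[rank] else NA_character_,
         character(1))
}

#' Extract the taxonomic class from PR2-style lineage strings
#'
#' @param lineage character vector of semicolon-delimited lineages.
#' @param rank position of the class rank (default 5, the PR2 convention).
#' @return character vector of class names (\code{NA} if the lineage is too
#'   short).
#' @export
lineageClass <- function(lineage, rank = .CLASS_RANK) {
  .lineageRank(lineage, rank)
}

#' Default class-to-trophic lookup
#'
#' Phytoplankton classes (autotrophs plus mixotroph classes such as
#' Chrysophyceae and Cryptophyceae) versus common heterotroph taxa.
#' Extend or replace when your taxonomy differs.
#'
#' @return named character vector: class -> "phytoplankton"/"heterotroph".
#' @export
defaultTrophicMap <- function() {
  phyto <- c("Bacillariophyceae", "Coscinodiscophyceae", "Mediophyceae",
             "Chrysophyceae", "Cryptophyceae", "Dinophyceae",
             "Chlorophyceae", "Trebouxiophyceae", "Prymnesiophyceae",
             "Eustigmatophyceae", "Dictyochophyceae", "Mamiellophyceae",
             "Synurophyceae", "Xanthophyceae")
  het <- c("Ciliophora", "Cercozoa", "Bicoecea", "Rozellomycota",
           "Aphelidiomycota", "Chytridiomycota", "Perkinsea",
           "Ichthyosporea", "Filosa-Thecofilosea")
  c(setNames(rep("phytoplankton", length(phyto)), phyto),
    setNames(rep("heterotroph", length(het)), het))
}

#' Construct an AsvTable
#'
#' @param counts integer matrix, ASVs x samples.
#' @param lineage named character vector (or vector in row order) of
#'   semicolon-delimited lineages, one per ASV.
#' @param trophic optional per-ASV trophic flag; if \code{NULL}, flags are
#'   derived from the class via \code{trophicMap} (unmatched classes get
#'   \code{NA}).
#' @param trophicMap class -> trophic lookup used when \code{trophic} is
#'   \code{NULL}.
#' @param classRank lineage position of the class rank.
#' @return a validated \linkS4class{AsvTable}.
#' @export
asvTable <- function(counts, lineage, trophic = NULL,
                     trophicMap = defaultTrophicMap(),
                     classRank = .CLASS_RANK) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  if (is.null(rownames(counts)))
    stop("counts must have ASV ids as rownames")
  if (!is.null(names(lineage))) {
    missing <- setdiff(rownames(counts), names(lineage))
    if (length(missing) > 0)
      stop("ASV(s) without lineage record: ", paste(missing, collapse = ", "))
    lineage <- lineage[rownames(counts)]
  } else if (length(lineage) != nrow(counts)) {
    stop("lineage must have one entry per ASV")
  }
  cls <- lineageClass(lineage, classRank)
  if (is.null(trophic)) trophic <- unname(trophicMap[cls])
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    rowData = S4Vectors::DataFrame(lineage = unname(lineage),
                                   class_name = cls,
                                   trophic = trophic,
                                   row.names = rownames(counts)))
  at <- new("AsvTable", se)
  validObject(at)
  at
}

#' Read an AsvTable from counts and taxonomy TSV files
#'
#' @param countsPath TSV with samples as rows and ASVs as columns (first
#'   column = sample id).
#' @param taxonomyPath two-column TSV: asv_id, lineage (semicolon-delimited
#'   ranks).
#' @param ... passed to \code{\link{asvTable}}.
#' @return an \linkS4class{AsvTable}.
#' @export
readAsvTable <- function(countsPath, taxonomyPath, ...) {
  cts <- read.delim(countsPath, stringsAsFactors = FALSE, check.names = FALSE)
  samples <- cts[[1]]
  m <- t(as.matrix(cts[, -1, drop = FALSE]))
  colnames(m) <- samples
  tax <- read.delim(taxonomyPath, stringsAsFactors = FALSE)
  lineage <- setNames(tax[[2]], tax[[1]])
  asvTable(m, lineage = lineage, ...)
}

#' @rdname readAsvTable
#' @param x an \linkS4class{AsvTable}.
#' @export
writeAsvTable <- function(x, countsPath, taxonomyPath) {
  stopifnot(is(x, "AsvTable"))
  cts <- asvCounts(x)
  out <- data.frame(sample_id = colnames(cts), t(cts), check.names = FALSE)
  write.table(out, countsPath, sep = "\t", quote = FALSE, row.names = FALSE)
  tax <- data.frame(asv_id = rownames(cts), lineage = unname(asvLineage(x)))
  write.table(tax, taxonomyPath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(countsPath, taxonomyPath))
}

.EXCLUDED_TAXA <- c("Metazoa", "Streptophyta", "Bacteria", "Archaea")

#' Filter raw ASVs by read support and lineage
#'
#' Removes ASVs with total reads <= 2 and ASVs whose lineage contains an
#' excluded taxon (Metazoa, Streptophyta, nucleomorph-derived ":nucl"
#' sequences, Bacteria, Archaea) or is unclassified at the domain level.
#' Order of the remaining ASVs is preserved; the removal counts are
#' attached as the \code{"filter_log"} element of the metadata.
#'
#' @param table an \linkS4class{AsvTable}.
#' @param minReads minimum total read count (exclusive threshold is
#'   \code{<= minReads - 1}; default keeps totals > 2).
#' @param excludedTaxa taxa whose presence anywhere in the lineage excludes
#'   the ASV.
#' @return the filtered \linkS4class{AsvTable}.
#' @export
filterAsvs <- function(table, minReads = 3L, excludedTaxa = .EXCLUDED_TAXA) {
  stopifnot(is(table, "AsvTable"))
  cts <- asvCounts(table)
  lin <- asvLineage(table)
  lowReads <- rowSums(cts) < minReads
  parts <- strsplit(lin, ";", fixed = TRUE)
  badTaxon <- vapply(parts, function(p)
    any(p %in% excludedTaxa) || any(grepl(":nucl", p, fixed = TRUE)),
    logical(1))
  domain <- vapply(parts, `[`, character(1), 1L)
  noDomain <- is.na(domain) | !nzchar(domain) |
    grepl("^unclassified|^unknown", domain, ignore.case = TRUE)
  keep <- !(lowReads | badTaxon | noDomain)
  out <- table[keep, ]
  S4Vectors::metadata(out)$filter_log <- list(
    n_in = nrow(cts), n_low_reads = sum(lowReads),
    n_excluded_lineage = sum(badTaxon & !lowReads),
    n_no_domain = sum(noDomain & !badTaxon & !lowReads),
    n_out = sum(keep))
  out
}

#' Keep only phytoplankton-flagged ASVs
#'
#' @param table an \linkS4class{AsvTable} with trophic flags set.
#' @return the phytoplankton subset.
#' @export
selectPhytoplankton <- function(table) {
  stopifnot(is(table, "AsvTable"))
  tro <- asvTrophic(table)
  if (any(is.na(tro)))
    stop("ASV(s) with missing trophic flag: ",
         paste(names(tro)[is.na(tro)], collapse = ", "))
  keep <- tro == "phytoplankton"
  if (!any(keep)) warning("no phytoplankton ASVs remain")
  out <- table[keep, ]
  S4Vectors::metadata(out)$filter_log <- list(
    n_in = length(tro), n_heterotroph = sum(!keep), n_out = sum(keep))
  out
}

#' Top-n ASVs by total read count
#'
#' Ties are broken by lexicographic ASV id, so the selection is
#' deterministic.
#'
#' @param table an \linkS4class{AsvTable}.
#' @param n number of ASVs to keep.
#' @return an \linkS4class{AsvTable} with at most \code{n} ASVs, in their
#'   original order.
#' @export
topAsvs <- function(table, n) {
  stopifnot(is(table, "AsvTable"), n >= 1)
  totals <- rowSums(asvCounts(table))
  if (n >= length(totals)) {
    if (n > length(totals))
      warning("n exceeds the number of ASVs; returning all ", length(totals))
    return(table)
  }
  ord <- order(-totals, rownames(table))
  keep <- sort(ord[seq_len(n)])
  table[keep, ]
}

#' Prevalence filter
#'
#' Retains features observed (nonzero) in at least \code{minSamples}
#' samples. Used before correlation analyses (default 8, the study's
#' threshold for 27 samples).
#'
#' @param x an \linkS4class{AsvTable}, or a numeric matrix with features in
#'   rows and samples in columns.
#' @param minSamples minimum number of samples with a nonzero value.
#' @return the filtered object, same type as the input.
#' @export
prevalenceFilter <- function(x, minSamples = 8L) {
  stopifnot(minSamples >= 1)
  m <- if (is(x, "AsvTable")) asvCounts(x) else as.matrix(x)
  keep <- rowSums(m != 0, na.rm = TRUE) >= minSamples
  x[keep, , drop = FALSE]
}

.mkRelAbundance <- function(cts, scope, className = NA_character_) {
  tot <- colSums(cts)
  empty <- tot == 0
  ra <- sweep(cts, 2, ifelse(empty, NA, tot), "/")
  ra[, empty] <- NA_real_
  new("RelAbundanceMatrix", ra = ra, scope = scope,
      className = className, emptySamples = setNames(empty, colnames(cts)))
}

#' Relative abundance over all phytoplankton reads
#'
#' R_ij = reads_ij / total phytoplankton reads of sample j. The denominator
#' is phytoplankton-only (apply \code{\link{selectPhytoplankton}} first),
#' which is what lets R_ij stand in for the ASV's share of total
#' phytoplankton abundance.
#'
#' @param table an \linkS4class{AsvTable} of phytoplankton ASVs.
#' @return a \linkS4class{RelAbundanceMatrix} with scope
#'   \code{"all_phyto"}.
#' @export
relativeAbundance <- function(table) {
  stopifnot(is(table, "AsvTable"))
  ra <- .mkRelAbundance(asvCounts(table) * 1.0, "all_phyto")
  validObject(ra)
  ra
}

#' Class-specific relative abundances
#'
#' For each taxonomic class c, R_ijc = reads_ij / total class-c reads of
#' sample j. ASVs whose class cannot be resolved from the lineage are
#' excluded (with a warning); they remain usable in total-scheme anchoring.
#'
#' @param table an \linkS4class{AsvTable} of phytoplankton ASVs.
#' @return named list of \linkS4class{RelAbundanceMatrix}, one per class,
#'   scope \code{"within_class"}.
#' @export
classRelativeAbundance <- function(table) {
  stopifnot(is(table, "AsvTable"))
  cls <- asvClass(table)
  if (any(is.na(cls))) {
    warning("ASV(s) with unresolved class excluded from class-specific ",
            "anchoring: ", paste(names(cls)[is.na(cls)], collapse = ", "))
  }
  cts <- asvCounts(table) * 1.0
  out <- lapply(sort(unique(cls[!is.na(cls)])), function(cc) {
    sub <- cts[which(cls == cc), , drop = FALSE]
    ra <- .mkRelAbundance(sub, "within_class", cc)
    validObject(ra)
    ra
  })
  names(out) <- sort(unique(cls[!is.na(cls)]))
  out
}
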