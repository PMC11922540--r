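#' @include AllClasses.R accessors.R
NULL

#' Construct a SpeciesTable
#'
#' @param data data.frame with columns \code{sample_id}, \code{species},
#'   \code{class_name}, \code{abundance} (cells L^-1), \code{biomass}
#'   (mg L^-1).
#' @param dropCyanobacteria drop rows whose class matches cyanobacteria
#'   (default TRUE): they are counted by light microscopy but are invisible
#'   to 18S rRNA metabarcoding, so they are excluded from all analyses.
#' @return a validated \linkS4class{SpeciesTable}.
#' @export
speciesTable <- function(data, dropCyanobacteria = TRUE) {
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  if (dropCyanobacteria && nrow(data) > 0) {
    cyano <- grepl("cyanobacteri|cyanophyce", data$class_name,
                   ignore.case = TRUE)
    data <- data[!cyano, , drop = FALSE]
  }
  rownames(data) <- NULL
  st <- new("SpeciesTable", data = data)
  validObject(st)
  st
}

#' Read / write a SpeciesTable as long-format TSV
#'
#' @param path file path.
#' @param ... passed to \code{\link{speciesTable}}.
#' @return \code{readSpeciesTable}: a \linkS4class{SpeciesTable}.
#' @export
readSpeciesTable <- function(path, ...) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  speciesTable(d, ...)
}

#' @rdname readSpeciesTable
#' @param x a \linkS4class{SpeciesTable}.
#' @export
writeSpeciesTable <- function(x, path) {
  stopifnot(is(x, "SpeciesTable"))
  write.table(x@data, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# shape -> (required dimensions, volume formula); dimensions in um
.shapeRegistry <- new.env(parent = emptyenv())

#' Register a cell-shape volume formula
#'
#' The seven standard hydrobiological shapes are pre-registered; additional
#' shapes can be added with this function.
#'
#' @param shape shape name.
#' @param dims character vector of required dimension names.
#' @param fun function(dims named list) -> volume in um^3.
#' @export
registerShape <- function(shape, dims, fun) {
  assign(shape, list(dims = dims, fun = fun), envir = .shapeRegistry)
  invisible(shape)
}

local({
  registerShape("sphere", "diameter",
    function(d) pi * d$diameter^3 / 6)
  registerShape("cylinder", c("diameter", "length"),
    function(d) pi * (d$diameter / 2)^2 * d$length)
  registerShape("prolate_spheroid", c("diameter", "length"),
    function(d) (pi / 6) * d$diameter^2 * d$length)
  registerShape("box", c("length", "width", "height"),
    function(d) d$length * d$width * d$height)
  registerShape("cone", c("diameter", "height"),
    function(d) (pi / 12) * d$diameter^2 * d$height)
  # h is the total length of the two joined cones
  registerShape("double_cone", c("diameter", "height"),
    function(d) (pi / 6) * d$diameter^2 * (d$height / 2) * 2)
  registerShape("ellipsoid", c("length", "width", "height"),
    function(d) (pi / 6) * d$length * d$width * d$height)
})

#' Cell biovolume from geometric shape
#'
#' Computes cell volume (um^3) from morphometric measurements (um) and an
#' assigned geometric shape, as done when converting microscopy counts to
#' biovolume and biomass.
#'
#' @param shape one of the registered shapes (\code{"sphere"},
#'   \code{"cylinder"}, \code{"prolate_spheroid"}, \code{"box"},
#'   \code{"cone"}, \code{"double_cone"}, \code{"ellipsoid"}, or any shape
#'   added via \code{\link{registerShape}}).
#' @param ... named dimensions in um (\code{diameter}, \code{length},
#'   \code{width}, \code{height} as the shape requires).
#' @return volume in um^3.
#' @examples
#' cellBiovolume("sphere", diameter = 10)       # 523.6 um^3
#' cellBiovolume("cylinder", diameter = 10, length = 100)
#' @export
cellBiovolume <- function(shape, ...) {
  if (!exists(shape, envir = .shapeRegistry, inherits = FALSE))
    stop("unknown shape: ", shape)
  reg <- get(shape, envir = .shapeRegistry, inherits = FALSE)
  dims <- list(...)
  missing <- setdiff(reg$dims, names(dims))
  if (length(missing) > 0)
    stop("shape '", shape, "' requires dimension(s): ",
         paste(missing, collapse = ", "))
  used <- dims[reg$dims]
  bad <- vapply(used, function(x) !is.numeric(x) || length(x) != 1 ||
                  !is.finite(x) || x <= 0, logical(1))
  if (any(bad))
    stop("dimension(s) must be positive finite numbers: ",
         paste(reg$dims[bad], collapse = ", "))
  reg$fun(used)
}

#' Species biomass from abundance and cell volume
#'
#' Biomass = abundance x mean cell volume x density x unit scale, with
#' phytoplankton density taken as 1 g cm^-3. The default unit scale 1e-9
#' converts um^3 x cells L^-1 to mg L^-1.
#'
#' @param abundance cells L^-1 (vectorised).
#' @param volume mean cell volume, um^3.
#' @param density g cm^-3 (default 1).
#' @param unitScale conversion factor (default 1e-9).
#' @return biomass in mg L^-1 (under the default scale).
#' @export
speciesBiomass <- function(abundance, volume, density = 1, unitScale = 1e-9) {
  if (any(abundance < 0) || any(volume < 0) || density < 0 || unitScale < 0)
    stop("all inputs must be non-negative")
  abundance * volume * density * unitScale
}

#' Split a cryptic species pair by SEM relative counts
#'
#' Light microscopy cannot separate some morphologically similar species
#' pairs; scanning electron microscopy counts of the two morphotypes are
#' used to split the pair's pooled abundance and biomass proportionally.
#'
#' @param pairCounts integer vector of length 2, SEM counts of the two
#'   species.
#' @param pairTotalAbundance pooled abundance, cells L^-1.
#' @param pairTotalBiomass pooled biomass, mg L^-1.
#' @return data.frame with one row per species: \code{fraction},
#'   \code{abundance}, \code{biomass}. The two abundances sum to the pooled
#'   total exactly.
#' @export
semSplitPair <- function(pairCounts, pairTotalAbundance, pairTotalBiomass) {
  stopifnot(length(pairCounts) == 2)
  if (any(pairCounts < 0) || any(pairCounts != round(pairCounts)))
    stop("pairCounts must be non-negative integers")
  tot <- sum(pairCounts)
  if (tot == 0) stop("pairCounts sum to zero; cannot split")
  if (tot < 100)
    warning("fewer than 100 cells counted (", tot,
            "); the split ratio may be imprecise")
  if (pairTotalAbundance < 0 || pairTotalBiomass < 0)
    stop("pair totals must be non-negative")
  frac <- pairCounts / tot
  data.frame(fraction = frac,
             abundance = frac * pairTotalAbundance,
             biomass = frac * pairTotalBiomass)
}

#' Per-sample and per-class anchor totals
#'
#' Sums microscopy abundances and biomasses per sample (A_j = sum_i a_ij,
#' M_j = sum_i m_ij) and per sample and class (A_jc, M_jc). Classes absent
#' from a sample get zero totals, so class totals always add up to the
#' sample totals.
#'
#' @param table a \linkS4class{SpeciesTable}.
#' @param samples optional character vector of sample ids to report; samples
#'   with no observed species get zero totals. Default: the samples present
#'   in the table.
#' @return an \linkS4class{AnchorTotals}.
#' @export
anchorTotals <- function(table, samples = NULL) {
  stopifnot(is(table, "SpeciesTable"))
  validObject(table)
  d <- table@data
  if (is.null(samples)) samples <- sort(unique(d$sample_id))
  else samples <- sort(unique(c(samples, d$sample_id)))
  classes <- sort(unique(d$class_name))
  zeroClass <- matrix(0, length(classes), length(samples),
                      dimnames = list(classes, samples))
  A <- setNames(numeric(length(samples)), samples)
  M <- A
  Ac <- zeroClass; Mc <- zeroClass
  if (nrow(d) > 0) {
    aj <- tapply(d$abundance, d$sample_id, sum)
    mj <- tapply(d$biomass, d$sample_id, sum)
    A[names(aj)] <- aj
    M[names(mj)] <- mj
    ac <- tapply(d$abundance, list(d$class_name, d$sample_id), sum)
    mc <- tapply(d$biomass, list(d$class_name, d$sample_id), sum)
    ac[is.na(ac)] <- 0; mc[is.na(mc)] <- 0
    Ac[rownames(ac), colnames(ac)] <- ac
    Mc[rownames(mc), colnames(mc)] <- mc
  }
  at <- new("AnchorTotals", abundance = A, biomass = M,
            classAbundance = Ac, classBiomass = Mc)
  validObject(at)
  at
}
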