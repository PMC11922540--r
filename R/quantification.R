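#' @include AllClasses.R accessors.R
NULL

#' Absolute abundance/biomass by total-phytoplankton anchoring
#'
#' The ASV x total scheme: each ASV's relative read abundance is multiplied
#' by the sample's total microscopy abundance (cells L^-1) or biomass
#' (mg L^-1): estimated value = R_ij x A_j (or R_ij x M_j). Per-sample sums
#' of the estimates reproduce the anchor exactly, so the scheme conserves
#' the microscopy total and preserves the within-sample ranking of the
#' relative abundances.
#'
#' @param R a \linkS4class{RelAbundanceMatrix} with scope
#'   \code{"all_phyto"}.
#' @param anchors an \linkS4class{AnchorTotals} covering the samples of
#'   \code{R}.
#' @param quantity \code{"abundance"} or \code{"biomass"}.
#' @return a \linkS4class{QuantifiedAsvTable}, method \code{"asv_x_total"}.
#'   Samples with no reads in scope are fully masked (\code{NA}).
#' @export
absoluteByTotal <- function(R, anchors, quantity = c("abundance", "biomass")) {
  stopifnot(is(R, "RelAbundanceMatrix"), is(anchors, "AnchorTotals"))
  if (R@scope != "all_phyto")
    stop("total-scheme anchoring requires an all_phyto relative-abundance matrix")
  quantity <- match.arg(quantity)
  ra <- relAbundance(R)
  missing <- setdiff(colnames(ra), sampleIds(anchors))
  if (length(missing) > 0)
    stop("sample(s) missing from anchors: ", paste(missing, collapse = ", "))
  anchor <- sampleTotals(anchors, quantity)[colnames(ra)]
  vals <- sweep(ra, 2, anchor, "*")
  q <- new("QuantifiedAsvTable", values = vals, quantity = quantity,
           method = "asv_x_total",
           className = setNames(rep(NA_character_, nrow(vals)),
                                rownames(vals)))
  validObject(q)
  q
}

#' Declare a proxy anchoring class
#'
#' Some classes are seen by metabarcoding only (e.g. small-celled
#' Eustigmatophyceae, Dictyochophyceae) and have no microscopy anchor of
#' their own; their ASVs are anchored with the class totals of a
#' morphologically similar, correlated class (e.g. Nannochloropsis with
#' Chlorophyceae, Pedinella with Trebouxiophyceae).
#'
#' @param asvClass class name as seen in the ASV lineages.
#' @param proxyClass microscopy class whose anchors to use.
#' @return a named character vector usable as (part of) the \code{proxy}
#'   argument of \code{\link{absoluteByClass}}; entries combine with
#'   \code{c()}.
#' @export
proxyClassMap <- function(asvClass, proxyClass) {
  stopifnot(is.character(asvClass), is.character(proxyClass),
            length(asvClass) == length(proxyClass))
  setNames(proxyClass, asvClass)
}

#' Absolute abundance/biomass by class-specific anchoring
#'
#' The ASV x class scheme: each ASV's within-class relative read abundance
#' is multiplied by the sample- and class-specific microscopy total:
#' estimated value = R_ijc x A_jc (or R_ijc x M_jc). Cells where the ASV's
#' class has reads but microscopy recorded no cells of that class
#' (A_jc = 0) cannot be computed and are masked \code{NA} — the scheme's
#' known disadvantage — as are samples where the class has no reads.
#'
#' @param Rc named list of within-class \linkS4class{RelAbundanceMatrix}
#'   objects, as returned by \code{\link{classRelativeAbundance}}.
#' @param anchors an \linkS4class{AnchorTotals}.
#' @param quantity \code{"abundance"} or \code{"biomass"}.
#' @param proxy optional named character vector mapping ASV classes without
#'   microscopy anchors to proxy anchor classes (see
#'   \code{\link{proxyClassMap}}). An unknown proxy class is a
#'   configuration error.
#' @return a \linkS4class{QuantifiedAsvTable}, method \code{"asv_x_class"},
#'   stacking the ASVs of all classes.
#' @export
absoluteByClass <- function(Rc, anchors, quantity = c("abundance", "biomass"),
                            proxy = NULL) {
  stopifnot(is.list(Rc), is(anchors, "AnchorTotals"))
  quantity <- match.arg(quantity)
  classAnchor <- classTotals(anchors, quantity)
  anchorClasses <- rownames(classAnchor)
  if (!is.null(proxy)) {
    unknown <- setdiff(proxy, anchorClasses)
    if (length(unknown) > 0)
      stop("unknown proxy class(es): ", paste(unknown, collapse = ", "))
  }
  pieces <- lapply(Rc, function(R) {
    stopifnot(is(R, "RelAbundanceMatrix"))
    if (R@scope != "within_class")
      stop("class-scheme anchoring requires within_class matrices")
    cc <- R@className
    anchorClass <- if (cc %in% anchorClasses) cc
      else if (!is.null(proxy) && cc %in% names(proxy)) proxy[[cc]]
      else stop("class '", cc, "' has no microscopy anchor and no proxy ",
                "mapping; supply one via proxyClassMap()")
    ra <- relAbundance(R)
    missing <- setdiff(colnames(ra), colnames(classAnchor))
    if (length(missing) > 0)
      stop("sample(s) missing from anchors: ", paste(missing, collapse = ", "))
    anchor <- classAnchor[anchorClass, colnames(ra)]
    vals <- sweep(ra, 2, anchor, "*")
    # reads present but no microscopy cells of the class: undefined, not 0
    hasReads <- !R@emptySamples[colnames(ra)]
    undef <- hasReads & anchor == 0
    vals[, undef] <- NA_real_
    list(vals = vals,
         className = setNames(rep(cc, nrow(vals)), rownames(vals)))
  })
  vals <- do.call(rbind, lapply(pieces, `[[`, "vals"))
  className <- do.call(c, lapply(pieces, `[[`, "className"))
  names(className) <- rownames(vals)
  q <- new("QuantifiedAsvTable", values = vals, quantity = quantity,
           method = "asv_x_class", className = className)
  validObject(q)
  q
}
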