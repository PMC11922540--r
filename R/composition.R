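#' @include AllClasses.R accessors.R
NULL

#' Centered log-ratio transform
#'
#' clr(x)_i = ln(x_i / g(x)) with g(x) the geometric mean of the row, so
#' every transformed row sums to zero. Rows are compositions (samples in
#' rows, features in columns); rows need not be closed beforehand — the clr
#' is invariant to a positive row scaling, and rows are closed internally.
#' Zeros are handled by multiplicative replacement: each zero becomes
#' \code{pseudoFraction} x the smallest nonzero proportion of that row and
#' the remaining entries are rescaled so the row still sums to 1. The
#' pseudo-value used per row is recorded in the result so runs are
#' reproducible.
#'
#' @param rel numeric matrix, samples x features, non-negative with at
#'   least one positive entry per row.
#' @param zeroStrategy \code{"multiplicative"} (default) or \code{"none"}
#'   (zeros cause an error).
#' @param pseudoFraction multiplier of the row's smallest nonzero
#'   proportion (default 0.5).
#' @return a \linkS4class{TransformedMatrix} with transform \code{"clr"}.
#' @examples
#' clrTransform(matrix(c(0.5, 0.25, 0.25), 1))  # (0.4621, -0.2310, -0.2310)
#' @export
clrTransform <- function(rel, zeroStrategy = c("multiplicative", "none"),
                         pseudoFraction = 0.5) {
  zeroStrategy <- match.arg(zeroStrategy)
  rel <- as.matrix(rel)
  if (any(is.na(rel)) || any(rel < 0))
    stop("rel must be non-negative with no missing values")
  rs <- rowSums(rel)
  zeroRows <- rs == 0
  if (any(zeroRows))
    stop("all-zero row(s): ",
         paste(rownames(rel)[zeroRows] %||% which(zeroRows), collapse = ", "))
  prop <- rel / rs
  zrec <- data.frame(sample = rownames(prop) %||% seq_len(nrow(prop)),
                     n_replaced = integer(nrow(prop)),
                     pseudo_value = NA_real_)
  for (i in seq_len(nrow(prop))) {
    z <- prop[i, ] == 0
    if (any(z)) {
      if (zeroStrategy == "none")
        stop("zero entries in row ", rownames(prop)[i] %||% i,
             " with zeroStrategy = 'none'")
      delta <- pseudoFraction * min(prop[i, !z])
      prop[i, z] <- delta
      prop[i, !z] <- prop[i, !z] * (1 - sum(z) * delta)
      zrec$n_replaced[i] <- sum(z)
      zrec$pseudo_value[i] <- delta
    }
  }
  lp <- log(prop)
  vals <- lp - rowMeans(lp)
  tm <- new("TransformedMatrix", values = vals, transform = "clr",
            zeroRecord = zrec)
  validObject(tm)
  tm
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Rank scaling to [0, 1]
#'
#' Per feature (column), values are replaced by (rank - 1)/(n - 1) across
#' samples, with average ranks for ties; a constant column maps to all 0.5.
#'
#' @param mat numeric matrix, samples x features, at least 2 samples.
#' @return a \linkS4class{TransformedMatrix} with transform \code{"rank01"}.
#' @export
rank01Transform <- function(mat) {
  mat <- as.matrix(mat)
  n <- nrow(mat)
  if (n < 2)
    stop("rank scaling is undefined for a single-sample matrix")
  vals <- apply(mat, 2, function(x) (rank(x, ties.method = "average") - 1) /
                  (n - 1))
  dimnames(vals) <- dimnames(mat)
  tm <- new("TransformedMatrix", values = vals, transform = "rank01",
            zeroRecord = data.frame())
  validObject(tm)
  tm
}

#' Diversity indices per sample
#'
#' Richness (count of positive features), Shannon H = -sum p ln p (nats),
#' Gini-Simpson 1 - sum p^2, and (for integer count data) the
#' bias-corrected Chao1 estimator S + F1(F1-1)/(2(F2+1)), where F1/F2 are
#' singleton/doubleton counts. Shannon, Simpson and Chao1 are delegated to
#' vegan.
#'
#' @param x numeric matrix, samples x features (or a single sample as a
#'   vector); counts or abundances.
#' @param chao1 compute Chao1 (requires integer counts; default TRUE).
#' @return data.frame: sample, richness, chao1, shannon, simpson.
#' @export
diversityProfile <- function(x, chao1 = TRUE) {
  if (is.null(dim(x))) x <- matrix(x, 1, dimnames = list("sample1", NULL))
  x <- as.matrix(x)
  if (any(x < 0)) stop("values must be non-negative")
  ch <- rep(NA_real_, nrow(x))
  if (chao1) {
    if (any(x != round(x)))
      stop("Chao1 requires integer counts")
    ch <- unname(suppressWarnings(vegan::estimateR(x))["S.chao1", ])
  }
  data.frame(
    sample = rownames(x) %||% paste0("sample", seq_len(nrow(x))),
    richness = rowSums(x > 0),
    chao1 = ch,
    shannon = unname(vegan::diversity(x, index = "shannon")),
    simpson = unname(vegan::diversity(x, index = "simpson")),
    row.names = NULL)
}

#' Analytic rarefaction curve
#'
#' Expected richness at subsample depth d under sampling without
#' replacement: E[S_d] = sum_i [1 - C(N - N_i, d)/C(N, d)] (hypergeometric
#' expectation, via \code{vegan::rarefy}).
#'
#' @param counts integer vector of feature counts for one sample.
#' @param depths subsample depths, each <= sum(counts).
#' @return data.frame: depth, expected_richness.
#' @export
rarefactionCurve <- function(counts, depths) {
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  N <- sum(counts)
  if (any(depths < 1) || any(depths > N))
    stop("depths must lie in [1, total reads = ", N, "]")
  er <- vapply(depths, function(d)
    as.numeric(vegan::rarefy(matrix(counts, 1), sample = d)), numeric(1))
  data.frame(depth = depths, expected_richness = er)
}
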