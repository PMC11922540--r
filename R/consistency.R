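#' @include AllClasses.R accessors.R
NULL

# Spearman r and t-approximation p for one pair of vectors with possible
# missing values; returns c(r, p, n). n < 4 complete pairs -> undefined.
.spearmanPair <- function(x, y, exact = FALSE) {
  ok <- is.finite(x) & is.finite(y)
  n <- sum(ok)
  if (n < 4) return(c(NA_real_, NA_real_, n))
  x <- x[ok]; y <- y[ok]
  if (sd(x) == 0 || sd(y) == 0) return(c(NA_real_, NA_real_, n))
  r <- cor(rank(x, ties.method = "average"), rank(y, ties.method = "average"))
  if (exact && n <= 12) {
    p <- suppressWarnings(
      stats::cor.test(x, y, method = "spearman", exact = TRUE)$p.value)
  } else if (abs(r) >= 1) {
    p <- 0
  } else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * pt(-abs(tstat), df = n - 2)
  }
  c(r, p, n)
}

#' Spearman correlation grid with BH adjustment
#'
#' All-pairs Spearman correlations between the features (columns) of two
#' sample-by-feature tables sharing samples. p-values use the two-sided t
#' approximation t = r sqrt((n-2)/(1-r^2)) on n-2 df; Benjamini-Hochberg
#' adjustment is applied jointly over every defined cell of the grid (one
#' family per grid). Masked (NA) values are excluded pairwise; pairs with
#' fewer than 4 complete samples, or with a constant feature, are undefined
#' rather than an error.
#'
#' @param X,Y numeric matrices, samples x features, with matching rownames
#'   (samples); Y defaults to X.
#' @param alpha significance level stored with the grid (default 0.05).
#' @param exact use the exact permutation distribution for p when a pair
#'   has n <= 12 complete samples (no ties; default FALSE).
#' @return a \linkS4class{CorrelationGrid}.
#' @export
spearmanGrid <- function(X, Y = X, alpha = 0.05, exact = FALSE) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (is.null(rownames(X)) || is.null(rownames(Y)))
    stop("X and Y must carry sample ids as rownames")
  shared <- intersect(rownames(X), rownames(Y))
  if (length(shared) < 4)
    stop("fewer than 4 shared samples")
  X <- X[shared, , drop = FALSE]; Y <- Y[shared, , drop = FALSE]
  nx <- ncol(X); ny <- ncol(Y)
  r <- p <- matrix(NA_real_, nx, ny,
                   dimnames = list(colnames(X), colnames(Y)))
  nUsed <- matrix(0L, nx, ny, dimnames = dimnames(r))
  for (i in seq_len(nx)) {
    for (j in seq_len(ny)) {
      res <- .spearmanPair(X[, i], Y[, j], exact = exact)
      r[i, j] <- res[1]; p[i, j] <- res[2]; nUsed[i, j] <- as.integer(res[3])
    }
  }
  q <- p
  def <- !is.na(p)
  q[def] <- p.adjust(p[def], method = "BH")
  grid <- new("CorrelationGrid", r = r, p = p, q = q, nUsed = nUsed,
              alpha = alpha)
  validObject(grid)
  grid
}

#' Critical Spearman r at a given sample size
#'
#' The smallest |r| whose two-sided t-approximate p-value is <= alpha:
#' r* = t_crit / sqrt(n - 2 + t_crit^2), with t_crit the (1 - alpha/2)
#' quantile of Student's t on n - 2 df. For the 27-sample design at
#' alpha = 0.05 this is 0.38 (2 dp), the "reliable value" threshold.
#'
#' @param n number of samples (>= 4).
#' @param alpha two-sided significance level (default 0.05).
#' @return the critical |r|.
#' @export
criticalR <- function(n, alpha = 0.05) {
  if (n < 4) stop("n must be >= 4")
  tcrit <- qt(1 - alpha / 2, df = n - 2)
  tcrit / sqrt(n - 2 + tcrit^2)
}

#' Count significant correlations by sign
#'
#' @param grid a \linkS4class{CorrelationGrid}.
#' @return named integer vector: \code{n_negative}, \code{n_positive}
#'   (cells with q <= alpha, split by the sign of r).
#' @export
countCorrelations <- function(grid) {
  stopifnot(is(grid, "CorrelationGrid"))
  m <- significanceMask(grid)
  r <- gridMatrix(grid, "r")
  c(n_negative = sum(m & r < 0, na.rm = TRUE),
    n_positive = sum(m & r >= 0, na.rm = TRUE))
}

.leafOrder <- function(m) {
  if (nrow(m) < 2) return(rownames(m))
  # sort by label first so the tree is invariant to input permutation
  m <- m[order(rownames(m)), , drop = FALSE]
  hc <- hclust(dist(m, method = "euclidean"), method = "complete")
  rownames(m)[hc$order]
}

#' Heatmap row/column order by complete-linkage clustering
#'
#' Hierarchical agglomerative clustering (Euclidean distance, complete
#' linkage) of the rows and of the columns of a correlation matrix, as
#' used to order correlation heat maps. Undefined cells are imputed as 0
#' for the distance computation (reported in the result); rows are sorted
#' by label before clustering so the leaf order is deterministic.
#'
#' @param r numeric matrix (e.g. the r matrix of a
#'   \linkS4class{CorrelationGrid}).
#' @return list with \code{rows}, \code{cols} (label orders) and
#'   \code{n_imputed} (count of NA cells treated as 0).
#' @export
heatmapOrder <- function(r) {
  r <- as.matrix(r)
  if (is.null(rownames(r))) rownames(r) <- paste0("R", seq_len(nrow(r)))
  if (is.null(colnames(r))) colnames(r) <- paste0("C", seq_len(ncol(r)))
  nImp <- sum(is.na(r))
  r[is.na(r)] <- 0
  list(rows = .leafOrder(r), cols = .leafOrder(t(r)), n_imputed = nImp)
}

.centerCols <- function(X) {
  X <- as.matrix(X)
  sweep(X, 2, colMeans(X), "-")
}

#' RV coefficient of two paired tables
#'
#' The matrix correlation RV = tr(X'Y Y'X) / sqrt(tr((X'X)^2) tr((Y'Y)^2))
#' on column-centered tables: a [0, 1] generalization of squared
#' correlation measuring the co-structure of two multivariate tables over
#' the same samples. RV = 1 iff one configuration is a rotation/dilation
#' of the other.
#'
#' @param X,Y numeric matrices, samples x features, same row (sample)
#'   order.
#' @return the RV coefficient.
#' @export
rvCoefficient <- function(X, Y) {
  Xc <- .centerCols(X); Yc <- .centerCols(Y)
  if (nrow(Xc) != nrow(Yc)) stop("X and Y must share samples")
  sx <- sum(crossprod(Xc)^2); sy <- sum(crossprod(Yc)^2)
  if (sx == 0 || sy == 0)
    stop("zero total variance in one of the tables")
  rv <- sum(crossprod(Xc, Yc)^2) / sqrt(sx * sy)
  min(max(rv, 0), 1)
}

#' Co-inertia analysis of two paired tables
#'
#' Decomposes the cross-covariance of two column-centered tables by SVD:
#' the singular vectors are the co-inertia axes, the squared singular
#' values the per-axis co-inertia. The global association is summarised by
#' the RV coefficient (identical to \code{\link{rvCoefficient}}).
#'
#' @param X,Y numeric matrices, samples x features, same sample order.
#' @param nAxes number of axes to retain (default 2; truncated to the rank
#'   of the cross-covariance with a warning if larger).
#' @return a \linkS4class{CoinertiaResult}.
#' @export
coinertia <- function(X, Y, nAxes = 2L) {
  Xc <- .centerCols(X); Yc <- .centerCols(Y)
  if (nrow(Xc) != nrow(Yc)) stop("X and Y must share samples")
  C <- crossprod(Xc, Yc) / (nrow(Xc) - 1)
  sv <- svd(C)
  tol <- max(dim(C)) * .Machine$double.eps * max(sv$d, 0)
  rnk <- sum(sv$d > tol)
  if (nAxes > rnk) {
    warning("nAxes (", nAxes, ") exceeds the rank (", rnk, "); truncating")
    nAxes <- rnk
  }
  nAxes <- max(1L, as.integer(nAxes))
  keep <- seq_len(nAxes)
  new("CoinertiaResult",
      rv = rvCoefficient(X, Y),
      axisInertia = sv$d[keep]^2,
      totalCoinertia = sum(sv$d^2),
      nAxes = nAxes,
      rowScores = Xc %*% sv$u[, keep, drop = FALSE],
      colScores = Yc %*% sv$v[, keep, drop = FALSE])
}
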