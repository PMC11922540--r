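test_that("critical r reproduces the 27-sample significance threshold", {
  # t_crit(25 df) = 2.0595 -> r* = 0.3809
  expect_equal(round(criticalR(27, 0.05), 2), 0.38)
  expect_equal(criticalR(27, 0.05), 0.3809, tolerance = 1e-4)
  expect_equal(criticalR(12, 0.05), 0.576, tolerance = 1e-3)
  ns <- 4:60
  expect_true(all(diff(vapply(ns, criticalR, numeric(1))) < 0))
  expect_error(criticalR(3), ">= 4")
})

test_that("spearman grid handles concordant, discordant and masked pairs", {
  set.seed(5)
  x <- stats::rnorm(27)
  X <- cbind(up = x, down = -x, noise = stats::rnorm(27))
  rownames(X) <- paste0("s", 1:27)
  g <- spearmanGrid(X, X[, "up", drop = FALSE])
  expect_equal(gridMatrix(g, "r")["up", "up"], 1)
  expect_equal(gridMatrix(g, "r")["down", "up"], -1)
  expect_equal(gridMatrix(g, "p")["up", "up"], 0)
  # the t-approximation p matches the closed form for an intermediate r
  r <- gridMatrix(g, "r")["noise", "up"]
  n <- 27
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  expect_equal(gridMatrix(g, "p")["noise", "up"],
               2 * pt(-abs(tstat), n - 2), tolerance = 1e-12)
  # masked values are excluded pairwise; < 4 complete pairs -> undefined
  Xna <- X; Xna[4:27, "noise"] <- NA
  g2 <- spearmanGrid(Xna, X[, "up", drop = FALSE])
  expect_true(is.na(gridMatrix(g2, "r")["noise", "up"]))
  expect_equal(gridMatrix(g2, "n")["noise", "up"], 3L)
  # with exactly 4 complete pairs the cell is defined
  Xna4 <- X; Xna4[5:27, "noise"] <- NA
  g3 <- spearmanGrid(Xna4, X[, "up", drop = FALSE])
  expect_false(is.na(gridMatrix(g3, "r")["noise", "up"]))
})

test_that("BH adjustment follows the step-up procedure over the grid", {
  # worked example: p = (0.001, 0.01, 0.03, 0.04, 0.2) at alpha 0.05
  # step-up: max k with p_(k) <= k/5 * 0.05 is k = 4
  p <- c(0.001, 0.01, 0.03, 0.04, 0.2)
  q <- p.adjust(p, "BH")
  expect_identical(q <= 0.05, c(TRUE, TRUE, TRUE, TRUE, FALSE))
  # same decisions inside a grid: build pairs hitting those p-values
  # (directly check that the grid's q equals p.adjust over defined cells)
  set.seed(11)
  X <- matrix(stats::rnorm(27 * 4), 27, 4,
              dimnames = list(paste0("s", 1:27), paste0("x", 1:4)))
  Y <- matrix(stats::rnorm(27 * 3), 27, 3,
              dimnames = list(paste0("s", 1:27), paste0("y", 1:3)))
  g <- spearmanGrid(X, Y)
  expect_equal(as.numeric(gridMatrix(g, "q")),
               p.adjust(as.numeric(gridMatrix(g, "p")), "BH"))
  # rejections are monotone non-decreasing in alpha
  masks <- vapply(c(0.01, 0.05, 0.1, 0.5),
                  function(a) sum(gridMatrix(g, "q") <= a), numeric(1))
  expect_true(all(diff(masks) >= 0))
})

test_that("independent noise yields ~alpha raw and ~0 BH-significant cells", {
  set.seed(123)
  X <- matrix(stats::rnorm(27 * 20), 27, 20,
              dimnames = list(paste0("s", 1:27), paste0("x", 1:20)))
  Y <- matrix(stats::rnorm(27 * 20), 27, 20,
              dimnames = list(paste0("s", 1:27), paste0("y", 1:20)))
  g <- spearmanGrid(X, Y, alpha = 0.05)
  rawFrac <- mean(gridMatrix(g, "p") <= 0.05)
  expect_lt(abs(rawFrac - 0.05), 0.03)
  ct <- countCorrelations(g)
  expect_lte(sum(ct), 2)  # essentially none survive BH under the null
})

test_that("correlation counts split significant cells by sign", {
  x <- sort(stats::rnorm(27))
  X <- cbind(a = x, b = -x)
  rownames(X) <- paste0("s", 1:27)
  g <- spearmanGrid(X, X[, "a", drop = FALSE])
  ct <- countCorrelations(g)
  expect_equal(ct[["n_positive"]], 1)
  expect_equal(ct[["n_negative"]], 1)
})

test_that("spearman r is invariant to monotone per-feature transforms", {
  set.seed(9)
  X <- matrix(stats::rlnorm(27 * 3), 27, 3,
              dimnames = list(paste0("s", 1:27), paste0("x", 1:3)))
  Y <- matrix(stats::rnorm(27 * 2), 27, 2,
              dimnames = list(paste0("s", 1:27), paste0("y", 1:2)))
  g1 <- spearmanGrid(X, Y)
  g2 <- spearmanGrid(X * 1000, Y)          # positive scaling
  g3 <- spearmanGrid(log(X), Y)            # strictly monotone transform
  expect_equal(gridMatrix(g1, "r"), gridMatrix(g2, "r"))
  expect_equal(gridMatrix(g1, "r"), gridMatrix(g3, "r"))
})

test_that("heatmap ordering clusters duplicate and block-structured rows", {
  set.seed(2)
  base <- matrix(stats::rnorm(24), 4, 6,
                 dimnames = list(paste0("r", 1:4), paste0("c", 1:6)))
  m <- rbind(base, twin = base["r2", ])
  ord <- heatmapOrder(m)$rows
  expect_equal(abs(which(ord == "twin") - which(ord == "r2")), 1)
  # block-diagonal structure: blocks stay contiguous in leaf order
  blockA <- matrix(0.9, 3, 3) + diag(0.1, 3)
  blockB <- matrix(0.8, 3, 3) + diag(0.2, 3)
  r <- rbind(cbind(blockA, matrix(-0.5, 3, 3)),
             cbind(matrix(-0.5, 3, 3), blockB))
  dimnames(r) <- list(c(paste0("a", 1:3), paste0("b", 1:3)),
                      paste0("c", 1:6))
  ordB <- heatmapOrder(r)$rows
  posA <- sort(match(paste0("a", 1:3), ordB))
  expect_equal(posA, seq(posA[1], posA[1] + 2))
  # permutation invariance of the tree: same merge heights, same order
  perm <- sample(nrow(r))
  ordP <- heatmapOrder(r[perm, ])$rows
  expect_identical(ordB, ordP)
  expect_identical(heatmapOrder(r[1, , drop = FALSE])$rows, "a1")
})

test_that("RV coefficient matches the brute-force double-sum oracle", {
  set.seed(31)
  for (i in 1:20) {
    X <- matrix(stats::rnorm(15), 5, 3)
    Y <- matrix(stats::rnorm(15), 5, 3)
    expect_equal(rvCoefficient(X, Y), bruteForceRV(X, Y),
                 tolerance = 1e-10)
  }
})

test_that("RV is 1 for identical or rotated tables and bounded in [0,1]", {
  set.seed(13)
  X <- matrix(stats::rnorm(27 * 5), 27, 5)
  expect_equal(rvCoefficient(X, X), 1, tolerance = 1e-12)
  Q <- qr.Q(qr(matrix(stats::rnorm(25), 5, 5)))  # random orthogonal
  expect_equal(rvCoefficient(X, X %*% Q), 1, tolerance = 1e-10)
  Y <- matrix(stats::rnorm(27 * 10), 27, 10)
  rv <- rvCoefficient(X, Y)
  expect_gte(rv, 0); expect_lte(rv, 1)
  expect_lt(rv, 0.5)  # independent noise has low co-structure
  expect_equal(rvCoefficient(Y, X), rv, tolerance = 1e-12)
  expect_error(rvCoefficient(matrix(1, 5, 2), Y[1:5, ]), "variance")
})

test_that("co-inertia axes decompose the cross-covariance", {
  set.seed(17)
  # rank-1 coupling: both tables driven by one latent gradient
  z <- stats::rnorm(20)
  X <- cbind(z, 2 * z, -z) + 0
  Y <- cbind(-3 * z, z)
  expect_warning(ci <- coinertia(X, Y, nAxes = 2), "rank")
  expect_equal(axisInertia(ci)[1], ci@totalCoinertia, tolerance = 1e-9)
  expect_equal(rvValue(ci), 1, tolerance = 1e-9)
  # general tables: contributions sum to the total; RV agrees with
  # rvCoefficient to near machine precision
  X2 <- matrix(stats::rnorm(20 * 4), 20, 4)
  Y2 <- matrix(stats::rnorm(20 * 3), 20, 3)
  ci2 <- coinertia(X2, Y2, nAxes = 3)
  expect_equal(sum(axisInertia(ci2)), ci2@totalCoinertia, tolerance = 1e-9)
  expect_equal(rvValue(ci2), rvCoefficient(X2, Y2), tolerance = 1e-10)
})
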