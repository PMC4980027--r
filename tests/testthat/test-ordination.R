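test_that("correlation-matrix PCA matches an independent decomposition", {
  m <- random_matrix(10, 6, seed = 21)
  pc <- ges_pca(m)
  ref <- prcomp(m, center = TRUE, scale. = TRUE)
  expect_equal(pc$eigenvalues, unname(ref$sdev^2), tolerance = 1e-8)
  expect_equal(pc$variance_share, unname(ref$sdev^2 / sum(ref$sdev^2)),
               tolerance = 1e-8)
  expect_equal(sum(pc$variance_share), 1, tolerance = 1e-12)
  expect_true(all(diff(pc$eigenvalues) <= 1e-12))
  # loadings orthonormal
  expect_equal(crossprod(pc$loadings), diag(6), tolerance = 1e-10,
               ignore_attr = TRUE)
  # scores reproduce the standardized data through the loadings
  expect_equal(pc$scores %*% t(pc$loadings), scale(m), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("PCA recognises degenerate structure", {
  set.seed(22)
  x <- rnorm(20)
  twin <- cbind(A = x, B = 2 * x + 5)  # perfectly correlated
  pc <- ges_pca(twin)
  expect_equal(pc$variance_share[1], 1, tolerance = 1e-12)

  m <- cbind(A = x, CONST = rep(1, 20))
  expect_error(ges_pca(m), "CONST")
})

test_that("RDA constrained share equals the regression oracle", {
  m <- random_matrix(10, 6, seed = 23)
  rda <- ges_rda(m, c("C01", "C04"))
  # hand-rolled oracle: per-response least squares, SS ratio
  Z <- scale(m)
  X <- Z[, c(1, 4)]
  Y <- Z[, -c(1, 4)]
  fitted <- apply(Y, 2, function(y) lm.fit(cbind(1, X), y)$fitted.values)
  expect_equal(rda$constrained_share, sum(fitted^2) / sum(Y^2),
               tolerance = 1e-8)
  expect_lte(rda$constrained_share, 1)
  expect_equal(sum(rda$variance_share), rda$constrained_share,
               tolerance = 1e-8)
})

test_that("RDA agrees with vegan on the constrained variance share", {
  m <- random_matrix(30, 8, seed = 24)
  cons <- c("C02", "C05", "C08")
  ours <- ges_rda(m, cons)$constrained_share
  Z <- scale(m)
  v <- vegan::rda(Z[, setdiff(colnames(m), cons)] ~ Z[, cons])
  expect_equal(ours, unname(v$CCA$tot.chi / v$tot.chi), tolerance = 1e-8)
})

test_that("RDA hits its exact boundary cases", {
  set.seed(25)
  x1 <- rnorm(30); x2 <- rnorm(30)
  # responses are exact linear maps of the constraints -> share 1
  m1 <- cbind(X1 = x1, X2 = x2, Y1 = 2 * x1 - x2, Y2 = x1 + 3 * x2)
  expect_equal(ges_rda(m1, c("X1", "X2"))$constrained_share, 1,
               tolerance = 1e-10)

  # constraint orthogonal (in sample) to every response -> share 0
  z <- rnorm(30)
  raw <- matrix(rnorm(60), 30, 2)
  resid <- apply(raw, 2, function(y) lm.fit(cbind(1, z), y)$residuals)
  m2 <- cbind(Z = z, R1 = resid[, 1], R2 = resid[, 2])
  expect_equal(ges_rda(m2, "Z")$constrained_share, 0, tolerance = 1e-8)

  # collinear constraints and all-column constraint sets are rejected
  m3 <- cbind(A = x1, B = 2 * x1, C = x2, D = rnorm(30))
  expect_error(ges_rda(m3, c("A", "B")), "collinear")
  expect_error(ges_rda(m3, c("A", "B", "C", "D")), "no responses")
  expect_error(ges_rda(m3, "NOPE"), "unknown constraint")
})

test_that("greedy selection is monotone and exhausts to full variance", {
  m <- random_matrix(10, 6, seed = 26)
  sel <- select_indicators(m, k_max = 6)
  expect_length(sel$selected, 6L)
  expect_true(all(diff(sel$share_trajectory) >= -1e-12))
  expect_equal(tail(sel$share_trajectory, 1), 1, tolerance = 1e-12)
  expect_warning(select_indicators(m, k_max = 10), "capped")

  # greedy first pick agrees with the exhaustive subset oracle
  ex <- select_indicators(m, k_max = 1, method = "exhaustive")
  expect_identical(sel$selected[1], ex$selected[1])
  expect_equal(sel$share_trajectory[1], ex$share_trajectory[1])
})

test_that("a duplicated column is never selected while it adds nothing", {
  set.seed(27)
  base <- matrix(rnorm(40 * 3), 40, 3)
  m <- cbind(A = base[, 1], Adup = base[, 1], B = base[, 2], C = base[, 3])
  sel <- select_indicators(m, k_max = 4)
  expect_identical(sel$selected[1], "A")       # tie with Adup -> column order
  expect_identical(sel$selected[4], "Adup")    # zero marginal gain until last
  # adding the twin never changed the explained share
  expect_equal(sel$share_trajectory[4], sel$share_trajectory[3],
               tolerance = 1e-12)
})

test_that("goal_share stops the selection early", {
  m <- random_matrix(20, 5, seed = 28)
  sel <- select_indicators(m, k_max = 5, goal_share = 0.5)
  expect_lt(length(sel$selected), 5L)
  expect_gte(tail(sel$share_trajectory, 1), 0.5)
})

test_that("partial correlations separate direct and mediated dependence", {
  set.seed(29)
  n <- 500
  x <- rnorm(n)
  # independent noise: nothing flagged
  m_null <- cbind(X = x, Y = rnorm(n), W = rnorm(n))
  scr <- independence_screen(m_null, threshold = 0.5)
  expect_false(any(scr$flagged))

  # near-duplicate: flagged
  m_dep <- cbind(X = x, Y = x + rnorm(n, sd = 0.2), W = rnorm(n))
  scr2 <- independence_screen(m_dep, threshold = 0.5)
  xy <- scr2[(scr2$a == "X" & scr2$b == "Y") |
             (scr2$a == "Y" & scr2$b == "X"), ]
  expect_true(xy$flagged)

  # chain X -> Z -> Y: X,Y marginally correlated, conditionally independent
  z <- x + rnorm(n, sd = 0.3)
  y <- z + rnorm(n, sd = 0.3)
  m_chain <- cbind(X = x, Z = z, Y = y)
  expect_gt(abs(cor(m_chain)["X", "Y"]), 0.5)  # marginal dependence is real
  scr3 <- independence_screen(m_chain, threshold = 0.5)
  xy3 <- scr3[(scr3$a == "X" & scr3$b == "Y") |
              (scr3$a == "Y" & scr3$b == "X"), ]
  expect_false(xy3$flagged)
  expect_lt(abs(xy3$partial_cor), 0.2)
})

test_that("under-determined screens fall back to shrinkage", {
  m <- random_matrix(5, 6, seed = 30)  # fewer rows than columns
  expect_warning(scr <- independence_screen(m, threshold = 0.9), "shrink")
  expect_identical(nrow(scr), 15L)
})

test_that("gap handling interpolates interior missing cells only", {
  m <- random_matrix(8, 3, seed = 31)
  m[4, 2] <- NA                       # interior gap: interpolated
  filled <- as_indicator_matrix(m)
  expect_equal(filled[4, 2], (m[3, 2] + m[5, 2]) / 2)
  expect_identical(nrow(filled), 8L)

  m[1, 3] <- NA                       # leading gap: row dropped
  expect_warning(trimmed <- as_indicator_matrix(m), "dropped 1")
  expect_identical(nrow(trimmed), 7L)
})
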