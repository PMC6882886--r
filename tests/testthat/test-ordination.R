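test_that("CA axis 1 matches a dense eigen-decomposition oracle", {
  set.seed(3)
  X <- matrix(rpois(20, 5), 5, 4,
              dimnames = list(paste0("s", 1:5), paste0("t", 1:4)))
  got <- ca_axis1(X, transform = "none")
  P <- X / sum(X); r <- rowSums(P); cc <- colSums(P)
  S <- (P - outer(r, cc)) / sqrt(outer(r, cc))
  ev <- eigen(t(S) %*% S, symmetric = TRUE)
  expect_equal(got$eigenvalue1, ev$values[1], tolerance = 1e-8)
  # scores proportional to D_r^{-1/2} u1 up to the fixed sign
  u1 <- (S %*% ev$vectors[, 1]) / sqrt(ev$values[1])
  oracle_scores <- unname(as.numeric(u1) / sqrt(r) * sqrt(ev$values[1]))
  if (sign(oracle_scores[1] - oracle_scores[5]) !=
      sign(got$axis1_scores[1] - got$axis1_scores[5]))
    oracle_scores <- -oracle_scores
  expect_equal(unname(got$axis1_scores), oracle_scores, tolerance = 1e-8)
  expect_gt(got$eigenvalue1, 0)
  expect_lte(got$eigenvalue1, 1)
})

test_that("CA axis 1 agrees with vegan's cca", {
  set.seed(19)
  X <- matrix(rpois(60, 6), 10, 6)
  got <- ca_axis1(X)
  v <- vegan::cca(X)
  expect_equal(got$eigenvalue1, unname(v$CA$eig[1]), tolerance = 1e-10)
  sc <- vegan::scores(v, display = "sites", choices = 1, scaling = "sites")[, 1]
  expect_equal(abs(cor(got$axis1_scores, sc)), 1, tolerance = 1e-8)
})

test_that("degenerate and transformed tables are handled per contract", {
  ident <- matrix(rep(c(3, 2, 1), each = 4), 4, 3, byrow = FALSE)
  expect_error(ca_axis1(ident), "non-trivial")
  expect_error(ca_axis1(matrix(1:2, 2, 1)), "rank-deficient")
  expect_error(ca_axis1(matrix(c(-1, 2, 3, 4), 2, 2)), "non-negative")

  set.seed(2)
  X <- matrix(rpois(30, 4), 6, 5)
  a <- ca_axis1(X)
  # scale invariance of CA (positive constant multiple)
  b <- ca_axis1(X * 7)
  expect_equal(a$axis1_scores, b$axis1_scores, tolerance = 1e-10)
  # row permutation permutes scores identically, up to the overall sign
  # (the sign convention is anchored to the first/last rows, which move)
  p <- c(3, 1, 6, 2, 5, 4)
  cp <- ca_axis1(X[p, ])
  ref <- unname(a$axis1_scores[p])
  got <- unname(cp$axis1_scores)
  expect_true(isTRUE(all.equal(got, ref, tolerance = 1e-10)) ||
                isTRUE(all.equal(got, -ref, tolerance = 1e-10)))
  # sqrt transform equals CA of the transformed matrix
  expect_equal(ca_axis1(X, "sqrt")$eigenvalue1,
               ca_axis1(sqrt(X), "none")$eigenvalue1)
})

test_that("detrending zeroes per-segment axis-2 means and keeps axis-1 ranks", {
  set.seed(10)
  x1 <- sort(runif(40, 0, 4))
  # an arch: axis 2 quadratic in axis 1, plus one already-centred case
  arch <- (x1 - 2)^2
  det <- detrend_by_segments(x1, arch, n_segments = 10)
  seg <- cut(x1, seq(min(x1), max(x1), length.out = 11),
             include.lowest = TRUE)
  expect_true(all(abs(tapply(det$axis2_detrended, seg, mean)) < 1e-12))
  expect_equal(det$axis1, x1 - min(x1), ignore_attr = TRUE) # no table: unchanged

  centred <- rnorm(40)
  centred <- centred - ave(centred, seg)
  det2 <- detrend_by_segments(x1, centred, n_segments = 10)
  expect_equal(unname(det2$axis2_detrended), centred, tolerance = 1e-12)

  u <- unimodal_table()
  ca <- ca_axis1(u$table)
  det3 <- detrend_by_segments(ca$axis1_scores, ca$axis2_scores_raw,
                              table = ca$table)
  expect_equal(rank(det3$axis1), rank(ca$axis1_scores)) # monotone rescaling
  expect_gte(det3$gradient_length, 0)
})

test_that("detrended axis 1 orders samples by the true gradient", {
  u <- unimodal_table()          # noise-free Gaussian responses
  ord <- dca_axis1(u$table, transform = "none")
  expect_equal(abs(cor(ord$axis1_scores, u$gradient, method = "spearman")), 1)
  expect_true(all(is.finite(ord$axis1_scores)))
  expect_gt(ord$gradient_length, 0)
})

test_that("time-constrained axis 1 matches oracles and limit cases", {
  # composition exactly linear in the constraint: chi-square matrix is
  # rank 1 with row space spanned by z, so constrained == unconstrained
  # (z and e chosen orthogonal to the margins so P's margins are exact)
  r <- c(0.2, 0.3, 0.5); cc <- c(0.3, 0.3, 0.2, 0.2)
  z <- c(-1, 0, 0.4)                 # sum(r * z) = 0
  e <- c(0.3, -0.1, -0.2, -0.1)      # sum(cc * e) = 0
  X <- 1000 * outer(r, cc) * (1 + outer(z, e))
  lim_u <- ca_axis1(X)
  lim_c <- constrained_axis1(X, z)
  expect_equal(lim_c$eigenvalue1, lim_u$eigenvalue1, tolerance = 1e-10)

  # brute-force projection-then-eigen oracle on a 5x4 table
  set.seed(23)
  X2 <- matrix(rpois(20, 8) + 1, 5, 4)
  z2 <- 1:5
  got <- constrained_axis1(X2, z2)
  P <- X2 / sum(X2); r2 <- rowSums(P); c2 <- colSums(P)
  S <- (P - outer(r2, c2)) / sqrt(outer(r2, c2))
  B <- sqrt(r2) * cbind(1, z2)
  H <- B %*% solve(crossprod(B)) %*% t(B)
  ev <- eigen(t(H %*% S) %*% (H %*% S), symmetric = TRUE)$values[1]
  expect_equal(got$eigenvalue1, ev, tolerance = 1e-10)
  # LC scores are linear in the constraint
  expect_lt(max(abs(residuals(lm(got$axis1_scores ~ z2)))), 1e-10)

  # vegan cross-check
  v <- vegan::cca(X2 ~ z2)
  expect_equal(got$eigenvalue1, unname(v$CCA$eig[1]), tolerance = 1e-10)

  # composition independent of time: permuting the labels of a strongly
  # time-structured series collapses the constrained eigenvalue
  set.seed(24)
  zt <- 1:20
  mu <- sapply(1:10, function(j) 40 * exp(-(zt - 2 * j)^2 / 18))
  Xt <- matrix(rpois(200, mu + 1), 20, 10)
  ev_true <- constrained_axis1(Xt, zt)$eigenvalue1
  evs <- replicate(30, constrained_axis1(Xt, sample(zt))$eigenvalue1)
  expect_lt(median(evs), 0.2 * ev_true)

  expect_error(constrained_axis1(X2, rep(1, 5)), "constant")
})
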