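test_that("PCA loadings are orthonormal and reconstruct the scaled data", {
  set.seed(21)
  x <- matrix(rnorm(15 * 6), 15, 6, dimnames = list(paste0("s", 1:15),
                                                    paste0("f", 1:6)))
  fit <- fit_pca(x, n_components = 5)
  G <- t(fit$loadings_all) %*% fit$loadings_all
  expect_equal(G, diag(ncol(G)), tolerance = 1e-8, ignore_attr = TRUE)
  xs <- sweep(sweep(x, 2, fit$center, "-"), 2, fit$scale, "/")
  expect_equal(fit$scores_all %*% t(fit$loadings_all), xs,
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(fit$scores_all, xs %*% fit$loadings_all, tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_true(all(diff(fit$explained) <= 1e-10))
})

test_that("duplicated samples share score coordinates and rank-1 data has one component", {
  set.seed(22)
  x <- matrix(rnorm(8 * 4), 8, 4)
  x[2, ] <- x[1, ]
  fit <- fit_pca(x, n_components = 2)
  expect_equal(fit$scores[1, ], fit$scores[2, ], tolerance = 1e-10)

  v <- rnorm(5); u <- rnorm(9)
  r1 <- outer(u, v)
  fit1 <- fit_pca(r1, n_components = 2, scaling = "none")
  expect_equal(fit1$explained[1], 100, tolerance = 1e-8)
  expect_equal(sum(fit1$explained[-1]), 0, tolerance = 1e-8)

  expect_error(fit_pca(x, n_components = 8), "exceeds")
})

test_that("Hotelling flags agree with an independent T2 computation", {
  set.seed(23)
  x <- matrix(rnorm(21 * 10), 21, 10)
  x[21, ] <- x[21, ] + 4  # one outlying sample
  fit <- fit_pca(x, n_components = 2)
  t2_ind <- t2_oracle(fit$scores)
  expect_equal(fit$t2, t2_ind, tolerance = 1e-8, ignore_attr = TRUE)
  n <- 21; a <- 2
  lim <- a * (n - 1) * (n + 1) / (n * (n - a)) * qf(0.95, a, n - a)
  expect_identical(fit$inside, fit$t2 <= lim, ignore_attr = TRUE)
  expect_false(all(fit$inside))
})

test_that("perfect linear association gives r = 1 with tier ***", {
  x <- matrix(seq_len(10), 10, 1, dimnames = list(paste0("s", 1:10), "t"))
  y <- matrix(2 * x + 1, 10, 1, dimnames = list(rownames(x), "g"))
  res <- correlate_traits_genes(x, y)
  expect_equal(res$r, 1, tolerance = 1e-12)
  expect_identical(res$tier, "***")
  expect_equal(res$n, 10)
})

test_that("independent pairs rarely reach significance", {
  hits <- 0
  for (seed in 1:200) {
    set.seed(seed)
    x <- matrix(rnorm(21), 21, 1, dimnames = list(paste0("s", 1:21), "t"))
    y <- matrix(rnorm(21), 21, 1, dimnames = list(rownames(x), "g"))
    res <- correlate_traits_genes(x, y)
    if (res$p <= 0.05) hits <- hits + 1
  }
  expect_lte(hits, 20)  # p > 0.05 in at least 90% of repeats
})

test_that("degenerate correlation inputs are handled", {
  x <- matrix(rep(1, 5), 5, 1, dimnames = list(paste0("s", 1:5), "t"))
  y <- matrix(rnorm(5), 5, 1, dimnames = list(rownames(x), "g"))
  res <- correlate_traits_genes(x, y)
  expect_true(is.na(res$r))
  expect_warning(
    correlate_traits_genes(x[1:2, , drop = FALSE], y[1:2, , drop = FALSE]),
    "skipped")
})

test_that("unregularized rCCA matches the classical CCA oracle", {
  set.seed(31)
  for (rep in 1:5) {
    X <- matrix(rnorm(40 * 4), 40, 4)
    Y <- matrix(rnorm(40 * 3), 40, 3)
    Y[, 1] <- Y[, 1] + 0.8 * X[, 1]
    colnames(X) <- paste0("x", 1:4); colnames(Y) <- paste0("y", 1:3)
    fit <- fit_rcca(X, Y, lambda1 = 0, lambda2 = 0, K = 3)
    expect_equal(fit$rho, cancor_oracle(X, Y)[1:3], tolerance = 1e-6,
                 ignore_attr = TRUE)
  }
})

test_that("identical blocks give canonical correlations of one", {
  set.seed(32)
  X <- matrix(rnorm(30 * 4), 30, 4, dimnames = list(NULL, paste0("x", 1:4)))
  fit <- fit_rcca(X, X, lambda1 = 0, lambda2 = 0, K = 4)
  expect_equal(fit$rho, rep(1, 4), tolerance = 1e-8)
})

test_that("canonical correlations are sorted and shrink with the penalty", {
  set.seed(33)
  X <- matrix(rnorm(25 * 6), 25, 6, dimnames = list(NULL, paste0("x", 1:6)))
  Y <- matrix(rnorm(25 * 5), 25, 5, dimnames = list(NULL, paste0("y", 1:5)))
  Y[, 1:2] <- Y[, 1:2] + X[, 1:2]
  rho1 <- c()
  for (lam in c(0, 0.05, 0.2, 1, 5)) {
    fit <- fit_rcca(X, Y, lam, lam, K = 4)
    expect_true(all(diff(fit$rho) <= 1e-10))
    rho1 <- c(rho1, fit$rho[1])
  }
  expect_true(all(diff(rho1) <= 1e-10))
})

test_that("rCCA at zero penalty is invariant to feature rescaling", {
  set.seed(34)
  X <- matrix(rnorm(30 * 4), 30, 4, dimnames = list(NULL, paste0("x", 1:4)))
  Y <- matrix(rnorm(30 * 3), 30, 3, dimnames = list(NULL, paste0("y", 1:3)))
  X2 <- sweep(X, 2, c(100, 0.01, 3, 42), "*")
  f1 <- fit_rcca(X, Y, 0, 0, K = 2)
  f2 <- fit_rcca(X2, Y, 0, 0, K = 2)
  expect_equal(f1$rho, f2$rho, tolerance = 1e-8)
})

test_that("ridge rCCA agrees with the reference mixOmics implementation", {
  skip_if_not_installed("mixOmics")
  set.seed(35)
  X <- matrix(rnorm(30 * 5), 30, 5, dimnames = list(NULL, paste0("x", 1:5)))
  Y <- matrix(rnorm(30 * 4), 30, 4, dimnames = list(NULL, paste0("y", 1:4)))
  Y[, 1] <- Y[, 1] + X[, 1]
  fit <- fit_rcca(X, Y, 0.05, 0.05, K = 3)
  ref <- mixOmics::rcc(X, Y, method = "ridge", lambda1 = 0.05,
                       lambda2 = 0.05)
  # covariance scaling conventions differ slightly between implementations
  expect_equal(fit$rho, ref$cor[1:3], tolerance = 0.02, ignore_attr = TRUE)
})

test_that("rCCA rejects invalid inputs", {
  X <- matrix(rnorm(20), 10, 2, dimnames = list(NULL, c("a", "b")))
  Y <- matrix(rnorm(20), 10, 2, dimnames = list(NULL, c("c", "d")))
  expect_error(fit_rcca(X, Y, lambda1 = -1), "non-negative")
  expect_error(fit_rcca(X, Y, K = 5), "K must be")
  Xna <- X; Xna[1, 1] <- NA
  expect_error(fit_rcca(Xna, Y), "complete")
})

test_that("hierarchical ordering groups identical and clustered rows", {
  m <- rbind(a = c(1, 1, 1), b = c(-1, -1, -1), c = c(1, 1, 1),
             d = c(5, 5, 5))
  colnames(m) <- c("p", "q", "r")
  ord <- cluster_order(m)
  pos <- match(c("a", "c"), ord$row_order)
  expect_equal(abs(diff(pos)), 1)  # identical rows adjacent

  # block sign structure stays contiguous
  set.seed(36)
  blk <- rbind(matrix(1 + rnorm(12, sd = 0.05), 4, 3),
               matrix(-1 + rnorm(12, sd = 0.05), 4, 3))
  rownames(blk) <- c(paste0("pos", 1:4), paste0("neg", 1:4))
  colnames(blk) <- c("x", "y", "z")
  ordb <- cluster_order(blk)
  first4 <- substr(ordb$row_order[1:4], 1, 3)
  expect_true(all(first4 == first4[1]))

  # permuting input rows leaves the leaf order unchanged
  perm <- sample(nrow(blk))
  ordp <- cluster_order(blk[perm, ])
  expect_identical(ordp$row_order, ordb$row_order)

  single <- m[1, , drop = FALSE]
  expect_identical(cluster_order(single)$row_order, "a")
})

test_that("the leave-one-out penalty search returns a grid cell", {
  set.seed(37)
  X <- matrix(rnorm(15 * 3), 15, 3, dimnames = list(NULL, paste0("x", 1:3)))
  Y <- matrix(X[, 1] + rnorm(15 * 2, sd = 0.5), 15, 2,
              dimnames = list(NULL, paste0("y", 1:2)))
  tuned <- tune_rcca(X, Y, grid = c(0.1, 1))
  expect_true(tuned$lambda1 %in% c(0.1, 1))
  expect_true(is.finite(tuned$score))
})
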