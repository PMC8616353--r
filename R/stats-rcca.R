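#' Regularized canonical correlation analysis
#'
#' Canonical correlation analysis between two blocks measured on the same
#' samples, with ridge regularization of the within-block covariance
#' matrices: the CCA eigenproblem is solved with \eqn{C_{xx} + \lambda_1 I}
#' and \eqn{C_{yy} + \lambda_2 I} in place of the within-block covariances,
#' which keeps the problem well-posed when features outnumber samples.
#' Columns of both blocks are standardized (zero mean, unit variance)
#' before fitting, so the covariance blocks are correlation matrices.
#' Canonical weight pairs are normalized to unit variance of the variate
#' under the regularized metric, and the sign of each X-weight vector is
#' fixed so that its largest-magnitude element is positive, with the
#' Y-weight flipped to keep the canonical correlation non-negative.
#'
#' The cross-block similarity matrix projects both blocks onto the first
#' \code{K} consensus variates \eqn{Z_d} (the average of the d-th X- and
#' Y-variates): \eqn{sim(i, j) = \sum_{d \le K} cor(X_i, Z_d)\,cor(Y_j,
#' Z_d)}.  Entries are reported unclipped; for \code{K > 1} their magnitude
#' can exceed 1, and heatmap color scales should saturate at plus/minus 1.
#'
#' @param X,Y complete numeric matrices, samples in rows (same rows in the
#'   same order or matched by row names), features in columns.
#' @param lambda1,lambda2 ridge penalties for the X and Y blocks
#'   (non-negative; defaults 0.1).
#' @param K number of canonical components (default 2).
#' @return object of class \code{glyco_rcca}: list with \code{rho}
#'   (canonical correlations, non-increasing, in [0, 1]), \code{xweights},
#'   \code{yweights} (features x K), \code{xvariates}, \code{yvariates}
#'   (samples x K), \code{similarity} (X-features x Y-features),
#'   \code{lambda1}, \code{lambda2}, \code{K}.
#' @export
fit_rcca <- function(X, Y, lambda1 = 0.1, lambda2 = 0.1, K = 2L) {
  stopifnot(is.matrix(X), is.matrix(Y))
  if (!is.null(rownames(X)) && !is.null(rownames(Y))) {
    shared <- intersect(rownames(X), rownames(Y))
    if (length(shared) < 3L) stop("fewer than 3 shared samples")
    X <- X[shared, , drop = FALSE]
    Y <- Y[shared, , drop = FALSE]
  } else if (nrow(X) != nrow(Y)) {
    stop("X and Y must have the same samples")
  }
  if (anyNA(X) || anyNA(Y) || any(!is.finite(X)) || any(!is.finite(Y)))
    stop("fit_rcca requires complete finite matrices")
  if (lambda1 < 0 || lambda2 < 0) stop("lambda must be non-negative")
  K <- as.integer(K)
  if (K < 1L || K > min(ncol(X), ncol(Y)))
    stop("K must be between 1 and min(ncol(X), ncol(Y))")
  Xs <- .standardize(X)
  Ys <- .standardize(Y)
  n <- nrow(Xs)
  Cxx <- crossprod(Xs) / (n - 1) + diag(lambda1, ncol(Xs))
  Cyy <- crossprod(Ys) / (n - 1) + diag(lambda2, ncol(Ys))
  Cxy <- crossprod(Xs, Ys) / (n - 1)
  Cxx_isqrt <- .inv_sqrt(Cxx)
  Cyy_inv <- .sym_solve(Cyy)
  M <- Cxx_isqrt %*% Cxy %*% Cyy_inv %*% t(Cxy) %*% Cxx_isqrt
  M <- (M + t(M)) / 2
  eg <- eigen(M, symmetric = TRUE)
  rho <- sqrt(pmax(eg$values[seq_len(K)], 0))
  rho <- pmin(rho, 1)
  A <- Cxx_isqrt %*% eg$vectors[, seq_len(K), drop = FALSE]
  B <- matrix(0, ncol(Ys), K)
  for (d in seq_len(K)) {
    b <- Cyy_inv %*% t(Cxy) %*% A[, d]
    nb <- sqrt(drop(t(b) %*% Cyy %*% b))
    if (nb > 0) b <- b / nb
    B[, d] <- b
  }
  # deterministic signs
  for (d in seq_len(K)) {
    a <- A[, d]
    s <- sign(a[which.max(abs(a))]); if (s == 0) s <- 1
    A[, d] <- A[, d] * s
    u <- Xs %*% A[, d]; v <- Ys %*% B[, d]
    if (drop(stats::cor(u, v)) < 0) B[, d] <- -B[, d]
  }
  U <- Xs %*% A
  V <- Ys %*% B
  Z <- (U + V) / 2
  Rx <- stats::cor(Xs, Z)
  Ry <- stats::cor(Ys, Z)
  sim <- Rx %*% t(Ry)
  dimnames(sim) <- list(colnames(X), colnames(Y))
  dimnames(A) <- list(colnames(X), paste0("CC", seq_len(K)))
  dimnames(B) <- list(colnames(Y), paste0("CC", seq_len(K)))
  dimnames(U) <- list(rownames(X), paste0("CC", seq_len(K)))
  dimnames(V) <- dimnames(U)
  structure(list(rho = rho, xweights = A, yweights = B,
                 xvariates = U, yvariates = V, similarity = sim,
                 lambda1 = lambda1, lambda2 = lambda2, K = K),
            class = "glyco_rcca")
}

.standardize <- function(m) {
  mu <- colMeans(m)
  sdev <- apply(m, 2, stats::sd)
  if (any(sdev == 0))
    stop("constant feature(s): ",
         paste(colnames(m)[sdev == 0], collapse = ", "))
  sweep(sweep(m, 2, mu, "-"), 2, sdev, "/")
}

.inv_sqrt <- function(S) {
  eg <- eigen((S + t(S)) / 2, symmetric = TRUE)
  vals <- pmax(eg$values, .Machine$double.eps)
  eg$vectors %*% diag(1 / sqrt(vals), length(vals)) %*% t(eg$vectors)
}

.sym_solve <- function(S) {
  eg <- eigen((S + t(S)) / 2, symmetric = TRUE)
  vals <- pmax(eg$values, .Machine$double.eps)
  eg$vectors %*% diag(1 / vals, length(vals)) %*% t(eg$vectors)
}

#' Leave-one-out grid search for the rCCA ridge penalties
#'
#' Scores each (lambda1, lambda2) pair on the grid by the first canonical
#' correlation evaluated on held-out samples: for each left-out sample, the
#' model is fitted on the rest and the held-out variate pair is recorded;
#' the score is the correlation between the held-out X- and Y-variates.
#'
#' @param X,Y as in [fit_rcca()].
#' @param grid numeric vector of candidate penalties (used for both blocks).
#' @return list with \code{lambda1}, \code{lambda2}, \code{score} (the best
#'   cell) and \code{scores} (the full grid matrix).
#' @export
tune_rcca <- function(X, Y, grid = c(0.01, 0.05, 0.1, 0.5, 1)) {
  n <- nrow(X)
  scores <- matrix(NA_real_, length(grid), length(grid),
                   dimnames = list(grid, grid))
  for (i in seq_along(grid)) for (j in seq_along(grid)) {
    u <- v <- numeric(n)
    ok <- TRUE
    for (s in seq_len(n)) {
      fit <- tryCatch(
        fit_rcca(X[-s, , drop = FALSE], Y[-s, , drop = FALSE],
                 lambda1 = grid[i], lambda2 = grid[j], K = 1L),
        error = function(e) NULL)
      if (is.null(fit)) { ok <- FALSE; break }
      xs <- (X[s, ] - colMeans(X[-s, , drop = FALSE])) /
        apply(X[-s, , drop = FALSE], 2, stats::sd)
      ys <- (Y[s, ] - colMeans(Y[-s, , drop = FALSE])) /
        apply(Y[-s, , drop = FALSE], 2, stats::sd)
      u[s] <- sum(xs * fit$xweights[, 1])
      v[s] <- sum(ys * fit$yweights[, 1])
    }
    if (ok) scores[i, j] <- stats::cor(u, v)
  }
  best <- which(scores == max(scores, na.rm = TRUE), arr.ind = TRUE)[1, ]
  list(lambda1 = grid[best[1]], lambda2 = grid[best[2]],
       score = max(scores, na.rm = TRUE), scores = scores)
}

#' Hierarchical ordering of a similarity matrix
#'
#' Orders the rows and columns of a (similarity) matrix by agglomerative
#' hierarchical clustering with Euclidean distance and complete linkage.
#' Rows (and columns) are pre-sorted by label so that tied merges resolve
#' deterministically; a single row or column returns the identity order.
#'
#' @param similarity finite numeric matrix with row and column names.
#' @return list with \code{row_order}, \code{col_order} (label vectors in
#'   leaf order) and \code{row_hclust}, \code{col_hclust} (\code{hclust}
#'   objects, \code{NULL} when the margin has a single element).
#' @export
cluster_order <- function(similarity) {
  stopifnot(is.matrix(similarity))
  if (any(!is.finite(similarity))) stop("similarity matrix must be finite")
  if (is.null(rownames(similarity)))
    rownames(similarity) <- paste0("r", seq_len(nrow(similarity)))
  if (is.null(colnames(similarity)))
    colnames(similarity) <- paste0("c", seq_len(ncol(similarity)))
  one_margin <- function(m) {
    if (nrow(m) < 2L)
      return(list(order = rownames(m), hclust = NULL))
    m <- m[order(rownames(m)), , drop = FALSE]
    hc <- stats::hclust(stats::dist(m, method = "euclidean"),
                        method = "complete")
    list(order = rownames(m)[hc$order], hclust = hc)
  }
  rows <- one_margin(similarity)
  cols <- one_margin(t(similarity))
  list(row_order = rows$order, col_order = cols$order,
       row_hclust = rows$hclust, col_hclust = cols$hclust)
}
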