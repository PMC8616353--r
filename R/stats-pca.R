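#' Principal component analysis with a Hotelling T-squared limit
#'
#' Mean-centers, scales each feature (unit variance by default, Pareto or
#' none selectable) and decomposes by singular values.  The sign of each
#' loading vector is fixed so that its largest-magnitude element is
#' positive.  The Hotelling T-squared statistic of each sample over the
#' first \code{n_components} scores, and its limit at level \code{alpha},
#' define the confidence ellipse used to flag outlying samples:
#' \deqn{T^2_{lim} = \frac{A(n-1)(n+1)}{n(n-A)} F_{1-\alpha;A,n-A}}
#' with \eqn{A} components and \eqn{n} samples.
#'
#' @param x complete numeric matrix, samples in rows, features in columns.
#' @param n_components number of components to retain (must be at most
#'   \code{min(nrow(x) - 1, ncol(x))}).
#' @param scaling \code{"uv"} (unit variance, default), \code{"pareto"}
#'   (divide by the square root of the standard deviation) or \code{"none"}.
#' @param alpha significance level of the Hotelling limit (default 0.05,
#'   the 95 percent ellipse).
#' @return object of class \code{glyco_pca}: list with \code{scores}
#'   (samples x components), \code{loadings} (features x components,
#'   orthonormal), \code{explained} (percent variance per component, all
#'   components), \code{center}, \code{scale}, \code{eigenvalues} (score
#'   variances of retained components), \code{t2} (per-sample Hotelling
#'   statistic), \code{t2_limit}, \code{inside} (logical, per sample),
#'   \code{n_components}, \code{alpha}.
#' @export
fit_pca <- function(x, n_components = 2L,
                    scaling = c("uv", "pareto", "none"), alpha = 0.05) {
  scaling <- match.arg(scaling)
  stopifnot(is.matrix(x))
  if (anyNA(x) || any(!is.finite(x)))
    stop("fit_pca requires a complete finite matrix (impute first)")
  n <- nrow(x); p <- ncol(x)
  if (n < 3L) stop("fit_pca needs at least 3 samples")
  max_comp <- min(n - 1L, p)
  if (n_components > max_comp)
    stop(sprintf("n_components = %d exceeds min(n - 1, features) = %d",
                 n_components, max_comp))
  ctr <- colMeans(x)
  sdev <- apply(x, 2, stats::sd)
  scl <- switch(scaling,
                uv = ifelse(sdev > 0, sdev, 1),
                pareto = ifelse(sdev > 0, sqrt(sdev), 1),
                none = rep(1, p))
  xs <- sweep(sweep(x, 2, ctr, "-"), 2, scl, "/")
  sv <- svd(xs)
  # fix loading signs: largest-magnitude element of each loading positive
  flip <- vapply(seq_len(ncol(sv$v)), function(j) {
    v <- sv$v[, j]
    sign(v[which.max(abs(v))])
  }, numeric(1))
  flip[flip == 0] <- 1
  loadings <- sweep(sv$v, 2, flip, "*")
  scores_all <- sweep(sv$u %*% diag(sv$d, length(sv$d)), 2, flip, "*")
  expl <- sv$d^2 / sum(sv$d^2) * 100
  scores <- scores_all[, seq_len(n_components), drop = FALSE]
  lambda <- sv$d[seq_len(n_components)]^2 / (n - 1)
  t2 <- rowSums(sweep(scores^2, 2, lambda, "/"))
  a <- n_components
  t2_limit <- a * (n - 1) * (n + 1) / (n * (n - a)) *
    stats::qf(1 - alpha, a, n - a)
  dimnames(loadings) <- list(colnames(x), paste0("PC", seq_len(ncol(loadings))))
  dimnames(scores_all) <- list(rownames(x), paste0("PC", seq_len(ncol(scores_all))))
  structure(list(scores = scores_all[, seq_len(n_components), drop = FALSE],
                 scores_all = scores_all,
                 loadings = loadings[, seq_len(n_components), drop = FALSE],
                 loadings_all = loadings,
                 explained = expl, center = ctr, scale = scl,
                 eigenvalues = lambda, t2 = t2, t2_limit = t2_limit,
                 inside = t2 <= t2_limit,
                 n_components = n_components, alpha = alpha,
                 scaling = scaling),
            class = "glyco_pca")
}

#' @export
print.glyco_pca <- function(x, ...) {
  cat(sprintf("<PCA> %d samples, %d retained components (%s scaling)\n",
              nrow(x$scores), x$n_components, x$scaling))
  cat(sprintf("  explained variance: %s\n",
              paste(sprintf("%.1f%%", x$explained[seq_len(x$n_components)]),
                    collapse = ", ")))
  cat(sprintf("  Hotelling T2 %.0f%% limit: %.3f (%d of %d samples inside)\n",
              100 * (1 - x$alpha), x$t2_limit, sum(x$inside),
              length(x$inside)))
  invisible(x)
}
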