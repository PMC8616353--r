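#' Pearson correlation of glycan traits with gene expression
#'
#' For each requested (trait, gene) pair, computes the Pearson correlation
#' over samples shared between the trait matrix and the expression matrix,
#' with a two-sided p-value from the t transform
#' \eqn{t = r\sqrt{(n-2)/(1-r^2)}} on \eqn{n-2} degrees of freedom, and the
#' conventional significance tiers (\code{"*"} for p <= 0.05, \code{"***"}
#' for p <= 0.001).  A Benjamini-Hochberg adjusted p-value column is
#' included for reference; the tiers themselves are on raw p-values.
#'
#' @param traits samples x traits matrix.
#' @param expr samples x genes matrix (log-scale expression).
#' @param pairs data frame with columns \code{trait} and \code{gene};
#'   default: all traits against all genes.
#' @return data frame with columns \code{trait}, \code{gene}, \code{r},
#'   \code{p}, \code{n}, \code{tier}, \code{p_adj}.  Pairs with fewer than
#'   3 shared samples are skipped with a warning; zero-variance vectors
#'   yield \code{NA} correlations.
#' @export
correlate_traits_genes <- function(traits, expr, pairs = NULL) {
  stopifnot(is.matrix(traits), is.matrix(expr))
  shared <- intersect(rownames(traits), rownames(expr))
  if (is.null(pairs))
    pairs <- expand.grid(trait = colnames(traits), gene = colnames(expr),
                         stringsAsFactors = FALSE)
  bad_t <- setdiff(unique(pairs$trait), colnames(traits))
  bad_g <- setdiff(unique(pairs$gene), colnames(expr))
  if (length(bad_t) || length(bad_g))
    stop("unknown pair member(s): ", paste(c(bad_t, bad_g), collapse = ", "))
  res <- lapply(seq_len(nrow(pairs)), function(i) {
    tr <- pairs$trait[i]; gn <- pairs$gene[i]
    x <- traits[shared, tr]; y <- expr[shared, gn]
    ok <- !is.na(x) & !is.na(y)
    n <- sum(ok)
    if (n < 3L) {
      warning(sprintf("pair (%s, %s): only %d shared samples, skipped",
                      tr, gn, n))
      return(NULL)
    }
    x <- x[ok]; y <- y[ok]
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
      return(data.frame(trait = tr, gene = gn, r = NA_real_, p = NA_real_,
                        n = n, stringsAsFactors = FALSE))
    r <- stats::cor(x, y)
    tt <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
    data.frame(trait = tr, gene = gn, r = r, p = p, n = n,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    return(data.frame(trait = character(0), gene = character(0),
                      r = numeric(0), p = numeric(0), n = integer(0),
                      tier = character(0), p_adj = numeric(0)))
  out$tier <- significance_tier(out$p)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out
}

#' Significance tier for a p-value
#'
#' @param p numeric vector of p-values.
#' @return \code{"***"} for p <= 0.001, \code{"*"} for p <= 0.05, otherwise
#'   \code{""} (and \code{NA} for missing p).
#' @export
significance_tier <- function(p) {
  ifelse(is.na(p), NA_character_,
         ifelse(p <= 0.001, "***", ifelse(p <= 0.05, "*", "")))
}
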