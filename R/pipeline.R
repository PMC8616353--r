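#' Read and write pipeline tables
#'
#' Strict readers/writers for the tables flowing through the pipeline.
#' The quant table is CSV with columns \code{sample}, \code{replicate},
#' \code{glycan}, \code{area}, \code{rt_match} (0/1), \code{idotp},
#' \code{snr}.  Expression and metadata are TSV; expression has samples in
#' rows (first column \code{sample}, remaining columns gene symbols),
#' metadata has columns \code{sample} and \code{fab}.  All files are UTF-8
#' with a header and decimal points.
#'
#' @param path file path.
#' @return the read object (\code{data.frame} or matrix); writers return
#'   \code{path} invisibly.
#' @name pipeline_tables
NULL

.check_cols <- function(df, required, path) {
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop(path, ": missing column(s) ", paste(missing, collapse = ", "))
  dup <- names(df)[duplicated(names(df))]
  if (length(dup))
    stop(path, ": duplicated column(s) ", paste(unique(dup), collapse = ", "))
  invisible(df)
}

#' @rdname pipeline_tables
#' @export
read_quant_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  .check_cols(df, c("sample", "replicate", "glycan", "area", "rt_match",
                    "idotp", "snr"), path)
  for (col in c("area", "idotp", "snr")) {
    if (!is.numeric(df[[col]]))
      stop(path, ": column '", col, "' is not numeric")
  }
  if (any(df$area < 0, na.rm = TRUE))
    stop(path, ": negative peak area")
  if (any(df$idotp < 0 | df$idotp > 1, na.rm = TRUE))
    stop(path, ": idotp outside [0, 1]")
  df$rt_match <- as.logical(df$rt_match)
  df
}

#' @rdname pipeline_tables
#' @param quant quant-table data frame.
#' @export
write_quant_table <- function(quant, path) {
  out <- quant
  out$rt_match <- as.integer(as.logical(out$rt_match))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname pipeline_tables
#' @export
read_expression_matrix <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  .check_cols(df, "sample", path)
  m <- as.matrix(df[, setdiff(names(df), "sample"), drop = FALSE])
  if (!is.numeric(m)) stop(path, ": non-numeric expression values")
  rownames(m) <- df$sample
  m
}

#' @rdname pipeline_tables
#' @param expr samples x genes matrix.
#' @export
write_expression_matrix <- function(expr, path) {
  df <- data.frame(sample = rownames(expr), as.data.frame(expr),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname pipeline_tables
#' @export
read_metadata <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  .check_cols(df, c("sample", "fab"), path)
  if (anyDuplicated(df$sample))
    stop(path, ": duplicated sample id(s)")
  df
}

#' @rdname pipeline_tables
#' @param metadata data frame with columns \code{sample}, \code{fab}.
#' @export
write_metadata <- function(metadata, path) {
  utils::write.table(metadata, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a simulated cohort to a directory
#'
#' Writes the quant table (\code{quant.csv}), annotation table
#' (\code{annotation.tsv}), expression matrix (\code{expression.tsv}),
#' sample metadata (\code{metadata.tsv}) and ground truth
#' (\code{ground_truth.json}) of a [simulate_cohort()] result.
#'
#' @param cohort result of [simulate_cohort()].
#' @param dir output directory (created if absent).
#' @return \code{dir}, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_quant_table(cohort$quant, file.path(dir, "quant.csv"))
  utils::write.table(cohort$annotation, file.path(dir, "annotation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_expression_matrix(cohort$expression,
                          file.path(dir, "expression.tsv"))
  write_metadata(cohort$metadata, file.path(dir, "metadata.tsv"))
  truth <- cohort$truth
  truth$true_traits <- unclass(truth$true_traits)
  attr(truth$true_traits, "trait_info") <- NULL
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       digits = NA, auto_unbox = TRUE, matrix = "rowmajor",
                       dataframe = "rows", force = TRUE)
  invisible(dir)
}

#' Run the integrated glycomics analysis pipeline
#'
#' Executes the full analysis in order: QC filtering of quantification
#' records, total-area normalization to fractional abundances per glycan
#' class, replicate precision (when technical replicates are present),
#' derived-trait computation, constant imputation of missing values, PCA
#' with the Hotelling T-squared limit, trait-gene Pearson correlation, and
#' regularized canonical correlation of traits against a transcription
#' factor panel with hierarchically ordered cross-block similarity.
#'
#' @param quant quant table (data frame) or path to a quant CSV.
#' @param library glycan library (named list of records) or path to an
#'   annotation table.
#' @param expression samples x genes matrix or path to an expression TSV
#'   (optional; correlation and rCCA stages are skipped without it).
#' @param metadata data frame with \code{sample}, \code{fab} or path
#'   (optional; used for group summaries).
#' @param idotp_min,snr_min,require_rt QC thresholds (defaults 0.85, 6,
#'   TRUE).
#' @param impute_value imputation constant (default 0.01).
#' @param n_components,scaling,alpha PCA settings (defaults 2, unit
#'   variance, 0.05).
#' @param cor_pairs data frame of \code{trait}, \code{gene} pairs for the
#'   correlation stage (default: every trait against every gene).
#' @param rcca_genes genes forming the rCCA Y block (default: all
#'   expression columns).
#' @param lambda1,lambda2,K rCCA settings (defaults 0.1, 0.1, 2).
#' @param verbose log stage progress to stderr (default FALSE).
#' @return object of class \code{glyco_pipeline}: list with \code{qc},
#'   \code{fractions} (replicate-level), \code{fractions_by_sample},
#'   \code{replicate_rsd}, \code{traits}, \code{traits_imputed},
#'   \code{group_means}, \code{pca}, \code{correlations}, \code{rcca},
#'   \code{cluster}, \code{params}.
#' @export
run_pipeline <- function(quant, library, expression = NULL, metadata = NULL,
                         idotp_min = 0.85, snr_min = 6, require_rt = TRUE,
                         impute_value = 0.01, n_components = 2L,
                         scaling = "uv", alpha = 0.05, cor_pairs = NULL,
                         rcca_genes = NULL, lambda1 = 0.1, lambda2 = 0.1,
                         K = 2L, verbose = FALSE) {
  say <- function(...) if (verbose) message("[glycofab] ", ...)
  if (is.character(quant)) quant <- read_quant_table(quant)
  if (is.character(library)) library <- read_annotation_table(library)
  if (is.character(expression) && length(expression) == 1L)
    expression <- read_expression_matrix(expression)
  if (is.character(metadata) && length(metadata) == 1L)
    metadata <- read_metadata(metadata)
  params <- list(idotp_min = idotp_min, snr_min = snr_min,
                 require_rt = require_rt, impute_value = impute_value,
                 n_components = n_components, scaling = scaling,
                 alpha = alpha, lambda1 = lambda1, lambda2 = lambda2, K = K)
  say("QC filter: idotp >= ", idotp_min, ", S/N >= ", snr_min,
      ", rt required: ", require_rt)
  qc <- qc_filter(quant, idotp_min = idotp_min, snr_min = snr_min,
                  require_rt = require_rt)
  if (nrow(qc$kept) == 0L)
    stop("no quantification record passes the QC thresholds (idotp >= ",
         idotp_min, ", S/N >= ", snr_min, ")")
  say(nrow(qc$kept), " of ", nrow(quant), " records pass QC")
  areas <- areas_from_records(qc$kept, library)
  fractions <- to_fractional(areas)
  rsd <- NULL
  sid <- attr(fractions, "sample_id")
  if (!is.null(sid) && anyDuplicated(unname(sid))) {
    rep_rows <- names(sid)[sid %in% sid[duplicated(unname(sid))]]
    rsd <- replicate_rsd(fractions[rep_rows, , drop = FALSE])
    say("replicate RSD (mean >= 1%): ",
        sprintf("%.1f%%", rsd$average_rsd))
  }
  frac_sample <- collapse_replicates(fractions)
  traits <- derive_traits(frac_sample, library)
  traits_imputed <- impute_missing(unclass(traits), value = impute_value)
  frac_imputed <- impute_missing(frac_sample, value = impute_value)
  group_means <- NULL
  if (!is.null(metadata)) {
    fab <- stats::setNames(metadata$fab, metadata$sample)
    group_means <- fab_group_summary(traits, fab[rownames(traits)])
  }
  say("PCA on ", nrow(frac_imputed), " samples x ",
      ncol(frac_imputed) + ncol(traits_imputed), " features")
  pca_x <- cbind(frac_imputed, traits_imputed)
  pca <- fit_pca(pca_x, n_components = n_components, scaling = scaling,
                 alpha = alpha)
  correlations <- NULL
  rcca <- NULL
  cluster <- NULL
  if (!is.null(expression)) {
    correlations <- correlate_traits_genes(traits_imputed, expression,
                                           pairs = cor_pairs)
    ygenes <- if (is.null(rcca_genes)) colnames(expression) else rcca_genes
    Y <- expression[, ygenes, drop = FALSE]
    shared <- intersect(rownames(traits_imputed), rownames(Y))
    X <- traits_imputed[shared, , drop = FALSE]
    Y <- Y[shared, , drop = FALSE]
    const <- apply(X, 2, stats::sd) == 0
    if (any(const)) {
      say("dropping constant trait(s) from rCCA: ",
          paste(colnames(X)[const], collapse = ", "))
      X <- X[, !const, drop = FALSE]
    }
    rcca <- fit_rcca(X, Y, lambda1 = lambda1, lambda2 = lambda2, K = K)
    cluster <- cluster_order(rcca$similarity)
  }
  structure(list(qc = qc, fractions = fractions,
                 fractions_by_sample = frac_sample,
                 replicate_rsd = rsd, traits = traits,
                 traits_imputed = traits_imputed,
                 group_means = group_means, pca = pca,
                 correlations = correlations, rcca = rcca,
                 cluster = cluster, params = params),
            class = "glyco_pipeline")
}

#' @export
print.glyco_pipeline <- function(x, ...) {
  cat("<glycofab pipeline result>\n")
  cat(sprintf("  QC: %d kept, %d rejected\n", nrow(x$qc$kept),
              nrow(x$qc$rejected)))
  cat(sprintf("  samples: %d, glycans: %d, traits: %d\n",
              nrow(x$fractions_by_sample), ncol(x$fractions_by_sample),
              ncol(x$traits)))
  if (!is.null(x$replicate_rsd))
    cat(sprintf("  replicate RSD: %.1f%%\n", x$replicate_rsd$average_rsd))
  print(x$pca)
  if (!is.null(x$rcca))
    cat(sprintf("  rCCA: rho = %s (lambda = %.2g/%.2g, K = %d)\n",
                paste(sprintf("%.3f", x$rcca$rho), collapse = ", "),
                x$rcca$lambda1, x$rcca$lambda2, x$rcca$K))
  invisible(x)
}
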