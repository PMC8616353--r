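#' Filter quantification records by quality criteria
#'
#' Keeps glycan quantification records that pass the standard quality
#' criteria: matching retention time, isotope dot product at or above
#' \code{idotp_min}, and signal-to-noise ratio at or above \code{snr_min}.
#' Both thresholds are inclusive.  Rejected records are returned with the
#' first failed criterion named.
#'
#' @param records data frame with columns \code{sample}, \code{replicate},
#'   \code{glycan}, \code{area}, \code{rt_match} (logical or 0/1),
#'   \code{idotp}, \code{snr}.
#' @param idotp_min minimum isotope dot product (default 0.85).
#' @param snr_min minimum signal-to-noise ratio (default 6).
#' @param require_rt require a matching retention time (default TRUE).
#' @return list with \code{kept} (passing records), \code{rejected}
#'   (failing records with a \code{reason} column: \code{"rt"},
#'   \code{"idotp"} or \code{"snr"}).
#' @export
qc_filter <- function(records, idotp_min = 0.85, snr_min = 6,
                      require_rt = TRUE) {
  required <- c("sample", "glycan", "area", "rt_match", "idotp", "snr")
  missing <- setdiff(required, names(records))
  if (length(missing))
    stop("quant records: missing column(s) ", paste(missing, collapse = ", "))
  rt_ok <- !require_rt | as.logical(records$rt_match)
  idotp_ok <- records$idotp >= idotp_min
  snr_ok <- records$snr >= snr_min
  keep <- rt_ok & idotp_ok & snr_ok
  reason <- rep(NA_character_, nrow(records))
  reason[!snr_ok] <- "snr"
  reason[!idotp_ok] <- "idotp"
  reason[!rt_ok] <- "rt"
  rejected <- records[!keep, , drop = FALSE]
  rejected$reason <- reason[!keep]
  list(kept = records[keep, , drop = FALSE], rejected = rejected)
}

#' Write a QC rejection log
#'
#' One rejected record per line, stating sample, glycan and the failed
#' criterion.
#'
#' @param rejected the \code{rejected} element of [qc_filter()].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_rejection_log <- function(rejected, path) {
  lines <- sprintf("sample=%s glycan=%s failed=%s idotp=%.3f snr=%.2f rt_match=%s",
                   rejected$sample, rejected$glycan, rejected$reason,
                   rejected$idotp, rejected$snr,
                   as.logical(rejected$rt_match))
  writeLines(lines, path)
  invisible(path)
}

#' Build a samples-by-glycans area matrix from long-format records
#'
#' @param records data frame as for [qc_filter()] (after filtering);
#'   replicates are kept as distinct rows named
#'   \code{"<sample>.<replicate>"} when more than one replicate is present.
#' @param library named list of \code{glycan_record}, used to attach the
#'   per-column glycan class.
#' @return numeric matrix (NA where a glycan was not quantified in a
#'   sample) with attribute \code{"glycan_class"}: named character vector
#'   over columns.
#' @export
areas_from_records <- function(records, library) {
  rep_id <- if ("replicate" %in% names(records) &&
                length(unique(records$replicate)) > 1L)
    paste(records$sample, records$replicate, sep = ".")
  else as.character(records$sample)
  samples <- unique(rep_id)
  glycans <- unique(as.character(records$glycan))
  unknown <- setdiff(glycans, names(library))
  if (length(unknown))
    stop("unknown glycan name(s) in quant records: ",
         paste(unknown, collapse = ", "))
  m <- matrix(NA_real_, length(samples), length(glycans),
              dimnames = list(samples, glycans))
  m[cbind(match(rep_id, samples), match(records$glycan, glycans))] <-
    records$area
  attr(m, "glycan_class") <- vapply(library[glycans], `[[`, character(1),
                                    "glycan_class")
  attr(m, "sample_id") <- stats::setNames(
    as.character(records$sample)[match(samples, rep_id)], samples)
  m
}

#' Average replicate rows down to one row per sample
#'
#' Collapses a matrix whose rows are replicate measurements (as produced by
#' [areas_from_records()] when replicates are present) to per-sample means,
#' ignoring missing cells.
#'
#' @param matrix numeric matrix with a \code{"sample_id"} attribute mapping
#'   row names to sample ids (rows lacking the attribute are taken as
#'   already sample-level).
#' @return matrix with one row per sample; \code{"glycan_class"} attribute
#'   preserved.
#' @export
collapse_replicates <- function(matrix) {
  sid <- attr(matrix, "sample_id")
  if (is.null(sid)) return(matrix)
  sid <- sid[rownames(matrix)]
  samples <- unique(unname(sid))
  out <- t(vapply(samples, function(s) {
    colMeans(matrix[sid == s, , drop = FALSE], na.rm = TRUE)
  }, numeric(ncol(matrix))))
  out[is.nan(out)] <- NA_real_
  dimnames(out) <- list(samples, colnames(matrix))
  attr(out, "glycan_class") <- attr(matrix, "glycan_class")
  out
}

.glycan_classes <- function(matrix, library = NULL) {
  cls <- attr(matrix, "glycan_class")
  if (is.null(cls)) {
    if (is.null(library))
      stop("matrix has no glycan_class attribute and no library was given")
    cls <- vapply(library[colnames(matrix)], `[[`, character(1),
                  "glycan_class")
  }
  cls[colnames(matrix)]
}

#' Convert peak areas to fractional abundances
#'
#' Normalizes each sample to total area within each glycan class
#' independently, so that observed N-glycans sum to 100 percent and observed
#' O-glycans sum to 100 percent per sample.  Cells that are \code{NA}
#' (not quantified) stay \code{NA} and are excluded from the class total.
#'
#' @param areas numeric matrix samples x glycans with a
#'   \code{"glycan_class"} attribute (see [areas_from_records()]).
#' @param library optional glycan library supplying classes when the
#'   attribute is absent.
#' @return matrix of fractional abundances in percent, same dimnames and
#'   \code{"glycan_class"} attribute.
#' @export
to_fractional <- function(areas, library = NULL) {
  stopifnot(is.matrix(areas))
  cls <- .glycan_classes(areas, library)
  out <- areas
  for (k in unique(cls)) {
    cols <- which(cls == k)
    tot <- rowSums(areas[, cols, drop = FALSE], na.rm = TRUE)
    zero <- tot <= 0
    if (any(zero))
      stop("sample(s) with no positive ", k, "-glycan area: ",
           paste(rownames(areas)[zero], collapse = ", "))
    out[, cols] <- sweep(areas[, cols, drop = FALSE], 1, tot, "/") * 100
  }
  attr(out, "glycan_class") <- cls
  out
}

#' Write and read an abundance matrix as TSV with a units header
#'
#' The matrix (samples in rows, glycans in columns, first column
#' \code{sample}) is written below a comment line stating the units; the
#' per-column glycan classes go to a JSON sidecar at
#' \code{paste0(path, ".meta.json")}.
#'
#' @param matrix abundance matrix (areas or percent) with an optional
#'   \code{"glycan_class"} attribute.
#' @param path output TSV path.
#' @param units units string recorded in the header line (default
#'   \code{"percent"}).
#' @return \code{path} (writer, invisibly) or the matrix with restored
#'   attributes (reader).
#' @export
write_abundance_matrix <- function(matrix, path, units = "percent") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# units: %s", units), con)
  df <- data.frame(sample = rownames(matrix), as.data.frame(matrix),
                   check.names = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  cls <- attr(matrix, "glycan_class")
  if (!is.null(cls))
    jsonlite::write_json(as.list(cls), paste0(path, ".meta.json"),
                         auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_abundance_matrix
#' @export
read_abundance_matrix <- function(path) {
  first <- readLines(path, n = 1L)
  if (!grepl("^# units:", first))
    stop(path, ": missing units header line")
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, setdiff(names(df), "sample"), drop = FALSE])
  rownames(m) <- df$sample
  attr(m, "units") <- sub("^# units: *", "", first)
  meta <- paste0(path, ".meta.json")
  if (file.exists(meta))
    attr(m, "glycan_class") <- unlist(jsonlite::read_json(meta))
  m
}

#' Impute missing values with a constant pseudo-abundance
#'
#' Replaces every missing (\code{NA}) cell of a percent-scale matrix by the
#' minimum positive constant (default 0.01), leaving observed cells
#' untouched and without renormalizing.  The imputation mask is attached as
#' attribute \code{"imputed"} (logical matrix).
#'
#' @param matrix fractional abundance or trait matrix in percent units.
#' @param value imputation constant (default 0.01).
#' @return the completed matrix with attribute \code{"imputed"}.
#' @export
impute_missing <- function(matrix, value = 0.01) {
  stopifnot(is.matrix(matrix))
  mask <- is.na(matrix)
  matrix[mask] <- value
  attr(matrix, "imputed") <- mask
  matrix
}

#' Replicate precision as relative standard deviation
#'
#' Computes the per-glycan relative standard deviation (sample standard
#' deviation divided by the mean, in percent) across replicate rows, and
#' the average RSD over glycans whose mean fractional abundance is at least
#' \code{min_mean} percent.  Grouping by technical or biological replicate
#' labels yields technical or biological precision respectively.
#'
#' @param matrix fractional abundance matrix whose rows are replicates of
#'   one sample.
#' @param min_mean minimum mean fractional abundance (percent) for a glycan
#'   to enter the average (default 1.0).
#' @return list with \code{per_glycan} (data frame: glycan, mean, sd, rsd,
#'   included) and \code{average_rsd}.
#' @export
replicate_rsd <- function(matrix, min_mean = 1.0) {
  stopifnot(is.matrix(matrix))
  if (nrow(matrix) < 2L)
    stop("replicate RSD needs at least 2 replicates")
  means <- colMeans(matrix, na.rm = TRUE)
  sds <- apply(matrix, 2, stats::sd, na.rm = TRUE)
  rsd <- ifelse(means > 0, sds / means * 100, NA_real_)
  included <- !is.na(rsd) & means >= min_mean
  list(per_glycan = data.frame(glycan = colnames(matrix), mean = means,
                               sd = sds, rsd = rsd, included = included,
                               row.names = NULL, stringsAsFactors = FALSE),
       average_rsd = mean(rsd[included]))
}

#' Z-transform each feature independently
#'
#' Centers and scales each column to mean 0 and standard deviation 1 across
#' samples.  Constant columns (zero standard deviation) are set to 0 with a
#' warning.
#'
#' @param matrix samples x features matrix.
#' @return z-scored matrix of the same shape.
#' @export
zscore_features <- function(matrix) {
  stopifnot(is.matrix(matrix), nrow(matrix) >= 2L)
  mu <- colMeans(matrix)
  sdev <- apply(matrix, 2, stats::sd)
  const <- sdev == 0 | is.na(sdev)
  if (any(const)) {
    warning("constant feature(s) set to zero: ",
            paste(colnames(matrix)[const], collapse = ", "))
    sdev[const] <- 1
  }
  z <- sweep(sweep(matrix, 2, mu, "-"), 2, sdev, "/")
  z[, const] <- 0
  z
}
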