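#' Define a derived glycan trait
#'
#' A trait definition names a derived glycan feature and states how it is
#' computed from per-glycan fractional abundances: which glycans carry the
#' trait (a pure predicate over the curated record), whether carriers are
#' weighted by presence or by occurrence count, which abundance set forms the
#' denominator, and whether the output is a percentage or a ratio.
#'
#' @param trait_name identifier for the trait.
#' @param glycan_class \code{"N"} or \code{"O"}.
#' @param predicate function taking a \code{glycan_record} and returning
#'   \code{TRUE} if the glycan carries the trait.  For \code{weight =
#'   "count"}, supply \code{count_fn} instead of or in addition.
#' @param weight \code{"presence"} (abundance of carrier glycans; default) or
#'   \code{"count"} (abundance multiplied by the occurrence count).
#' @param denominator \code{"total_class"} (all glycans of the class;
#'   default), \code{"complex_only"} or \code{"complex_hybrid"}.
#' @param output \code{"percentage"} (default) or \code{"ratio"}.
#' @param count_fn for count weighting: function from record to the
#'   occurrence count (e.g. the number of alpha-2,3-linked sialic acids).
#' @param ratio_predicate for ratio traits: predicate selecting the
#'   denominator glycans (the trait value is then carrier abundance divided
#'   by that set's abundance, unscaled).
#' @return an object of class \code{trait_definition}.
#' @export
trait_definition <- function(trait_name, glycan_class, predicate,
                             weight = c("presence", "count"),
                             denominator = c("total_class", "complex_only",
                                             "complex_hybrid"),
                             output = c("percentage", "ratio"),
                             count_fn = NULL, ratio_predicate = NULL) {
  weight <- match.arg(weight)
  denominator <- match.arg(denominator)
  output <- match.arg(output)
  glycan_class <- match.arg(glycan_class, c("N", "O"))
  if (weight == "count" && is.null(count_fn))
    stop("count weighting requires count_fn")
  if (output == "ratio" && is.null(ratio_predicate))
    stop("ratio traits require ratio_predicate")
  structure(list(trait_name = trait_name, glycan_class = glycan_class,
                 predicate = predicate, weight = weight,
                 denominator = denominator, output = output,
                 count_fn = count_fn, ratio_predicate = ratio_predicate),
            class = "trait_definition")
}

#' The built-in derived-trait panel
#'
#' Returns the default panel of derived glycan traits.  N-glycan traits:
#' the four glycan-type percentages (oligomannose, paucimannose, hybrid,
#' complex), phosphorylation, bisection, core fucosylation, (s)Lewis x/a
#' (sialylated and neutral antennary-fucosylated forms pooled), antennarity
#' (glycans with three or more antennae), total sialylation, alpha-2,3
#' sialylation and alpha-2,6 sialylation on terminal galactose.  O-glycan
#' traits: core 1 and core 2 percentages, the core1:core2 ratio, T antigen,
#' sialyl-T, disialyl-T, Lewis x/a, sialyl-Lewis x/a, H antigen, sulfation,
#' LacNAc extension, alpha-2,3 sialylation, alpha-2,6 sialylation on the
#' core GalNAc and alpha-2,8 sialylation.
#'
#' All percentage traits default to the within-class total as denominator.
#' Sialic acids of undetermined linkage count towards total sialylation but
#' towards no linkage-specific trait.
#'
#' @return named list of \code{trait_definition} (names are trait names).
#' @export
builtin_traits <- function() {
  defs <- list(
    # N-glycan types
    trait_definition("N_oligomannose", "N",
                     function(r) r$glycan_type == "oligomannose"),
    trait_definition("N_paucimannose", "N",
                     function(r) r$glycan_type == "paucimannose"),
    trait_definition("N_hybrid", "N",
                     function(r) r$glycan_type == "hybrid"),
    trait_definition("N_complex", "N",
                     function(r) r$glycan_type == "complex"),
    # N derived traits
    trait_definition("N_phosphorylation", "N",
                     function(r) r$composition[["phospho"]] >= 1L),
    trait_definition("N_bisection", "N", function(r) r$bisecting),
    trait_definition("N_core_fucosylation", "N",
                     function(r) r$core_fucose >= 1L),
    trait_definition("N_sLex_a", "N",
                     function(r) r$has_sLex_a || r$has_Lex_a),
    trait_definition("N_antennarity", "N", function(r) r$antennae >= 3L),
    trait_definition("N_sialylation", "N",
                     function(r) r$composition[["neuac"]] >= 1L),
    trait_definition("N_sia_a23", "N", function(r) r$sia_a23 >= 1L),
    trait_definition("N_sia_a26_gal", "N", function(r) r$sia_a26_gal >= 1L),
    # O-glycan cores
    trait_definition("O_core1", "O", function(r) r$glycan_type == "core1"),
    trait_definition("O_core2", "O", function(r) r$glycan_type == "core2"),
    trait_definition("O_core1_core2_ratio", "O",
                     function(r) r$glycan_type == "core1",
                     output = "ratio",
                     ratio_predicate = function(r) r$glycan_type == "core2"),
    # O derived traits
    trait_definition("O_T_antigen", "O", function(r) r$has_T_antigen),
    trait_definition("O_sialyl_T", "O", function(r) {
      r$glycan_type == "core1" && r$composition[["hex"]] == 1L &&
        r$composition[["hexnac"]] == 1L && r$composition[["neuac"]] == 1L
    }),
    trait_definition("O_disialyl_T", "O", function(r) {
      r$glycan_type == "core1" && r$composition[["hex"]] == 1L &&
        r$composition[["hexnac"]] == 1L && r$composition[["neuac"]] == 2L &&
        r$sia_a28 == 0L
    }),
    trait_definition("O_Lex_a", "O", function(r) r$has_Lex_a),
    trait_definition("O_sLex_a", "O", function(r) r$has_sLex_a),
    trait_definition("O_H_antigen", "O", function(r) r$has_H_antigen),
    trait_definition("O_sulfation", "O",
                     function(r) r$composition[["sulfo"]] >= 1L),
    trait_definition("O_LacNAc", "O", function(r) r$lacnac_repeats >= 1L),
    trait_definition("O_sia_a23", "O", function(r) r$sia_a23 >= 1L),
    trait_definition("O_sia_a26_core", "O", function(r) r$sia_a26_core >= 1L),
    trait_definition("O_sia_a28", "O", function(r) r$sia_a28 >= 1L)
  )
  names(defs) <- vapply(defs, `[[`, character(1), "trait_name")
  defs
}

#' Derive trait values from fractional abundances
#'
#' Computes the trait matrix from a samples-by-glycans matrix of fractional
#' abundances (percent, summing to 100 per sample within each glycan class)
#' and the curated glycan library.  For a percentage trait, the value is the
#' summed abundance of carrier glycans divided by the summed abundance of
#' the denominator set, times 100; with count weighting, carrier abundances
#' are multiplied by their occurrence counts.  Ratio traits divide carrier
#' abundance by the abundance of the ratio denominator set; a zero
#' denominator yields \code{NA}.  Glycans missing in a sample (\code{NA})
#' contribute zero.
#'
#' @param abundances numeric matrix, samples in rows, glycans in columns
#'   (column names must be library names), fractional abundances in percent.
#' @param library named list of \code{glycan_record} (see
#'   [builtin_glycan_library()]).
#' @param traits list of \code{trait_definition}; default [builtin_traits()].
#' @return a \code{trait_matrix}: numeric matrix samples x traits with a
#'   \code{"trait_info"} attribute (data frame of trait name, class,
#'   denominator, weight, output).
#' @examples
#' lib <- builtin_glycan_library()
#' ab <- matrix(c(60, 40), 1, dimnames = list("s1", c("H1N1S1a", "H2N2S2")))
#' tm <- derive_traits(ab, lib)
#' tm[, c("O_core1", "O_core2", "O_core1_core2_ratio")]
#' @export
derive_traits <- function(abundances, library, traits = builtin_traits()) {
  stopifnot(is.matrix(abundances), !is.null(colnames(abundances)))
  unknown <- setdiff(colnames(abundances), names(library))
  if (length(unknown))
    stop("unknown glycan name(s): ", paste(unknown, collapse = ", "))
  recs <- library[colnames(abundances)]
  classes <- vapply(recs, `[[`, character(1), "glycan_class")
  types <- vapply(recs, `[[`, character(1), "glycan_type")
  ab <- abundances
  ab[is.na(ab)] <- 0
  out <- matrix(NA_real_, nrow(ab), length(traits),
                dimnames = list(rownames(ab),
                                vapply(traits, `[[`, character(1),
                                       "trait_name")))
  for (td in traits) {
    in_class <- classes == td$glycan_class
    member <- in_class & vapply(recs, function(r) isTRUE(td$predicate(r)),
                                logical(1))
    w <- as.numeric(member)
    if (td$weight == "count")
      w <- w * vapply(recs, function(r) as.numeric(td$count_fn(r)),
                      numeric(1))
    num <- ab %*% w
    if (td$output == "ratio") {
      den_member <- in_class & vapply(recs, function(r)
        isTRUE(td$ratio_predicate(r)), logical(1))
      den <- ab %*% as.numeric(den_member)
      val <- ifelse(den > 0, num / den, NA_real_)
    } else {
      den_member <- switch(td$denominator,
        total_class = in_class,
        complex_only = in_class & types == "complex",
        complex_hybrid = in_class & types %in% c("complex", "hybrid"))
      den <- ab %*% as.numeric(den_member)
      val <- ifelse(den > 0, num / den * 100, NA_real_)
    }
    out[, td$trait_name] <- val
  }
  info <- data.frame(
    trait_name = vapply(traits, `[[`, character(1), "trait_name"),
    glycan_class = vapply(traits, `[[`, character(1), "glycan_class"),
    denominator = vapply(traits, `[[`, character(1), "denominator"),
    weight = vapply(traits, `[[`, character(1), "weight"),
    output = vapply(traits, `[[`, character(1), "output"),
    stringsAsFactors = FALSE)
  attr(out, "trait_info") <- info
  class(out) <- c("trait_matrix", class(out))
  out
}

#' Group trait values by FAB class
#'
#' Averages each trait within groups of samples defined by their FAB
#' (French-American-British) class labels.  Single-sample groups return
#' that sample's values; labels with no sample are dropped with a warning.
#'
#' @param traits a \code{trait_matrix} (or any samples x features matrix).
#' @param fab_labels character vector of group labels, one per sample (row).
#' @return matrix groups x traits of group means, rows ordered by label.
#' @export
fab_group_summary <- function(traits, fab_labels) {
  stopifnot(is.matrix(traits))
  if (length(fab_labels) != nrow(traits))
    stop("need one FAB label per sample (row)")
  if (anyNA(fab_labels))
    stop("every sample needs a FAB label")
  if (is.factor(fab_labels)) {
    empty <- setdiff(levels(fab_labels), unique(as.character(fab_labels)))
    if (length(empty))
      warning("dropping empty group(s): ", paste(empty, collapse = ", "))
  }
  fab_labels <- as.character(fab_labels)
  groups <- sort(unique(fab_labels))
  out <- t(vapply(groups, function(g) {
    colMeans(traits[fab_labels == g, , drop = FALSE], na.rm = TRUE)
  }, numeric(ncol(traits))))
  dimnames(out) <- list(groups, colnames(traits))
  out
}

#' Write and read a trait matrix as TSV with a metadata sidecar
#'
#' The trait matrix is written as a TSV (samples in rows, traits in
#' columns, first column \code{sample}); the trait metadata (class,
#' denominator, weight, output) goes to a JSON sidecar at
#' \code{paste0(path, ".meta.json")}.
#'
#' @param traits a \code{trait_matrix}.
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
write_trait_matrix <- function(traits, path) {
  df <- data.frame(sample = rownames(traits), as.data.frame(unclass(traits)),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  info <- attr(traits, "trait_info")
  if (!is.null(info))
    jsonlite::write_json(info, paste0(path, ".meta.json"), dataframe = "rows",
                         auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_trait_matrix
#' @export
read_trait_matrix <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (!"sample" %in% names(df))
    stop("trait matrix ", path, ": missing 'sample' column")
  m <- as.matrix(df[, setdiff(names(df), "sample"), drop = FALSE])
  rownames(m) <- df$sample
  meta_path <- paste0(path, ".meta.json")
  if (file.exists(meta_path))
    attr(m, "trait_info") <- as.data.frame(
      jsonlite::read_json(meta_path, simplifyVector = TRUE))
  class(m) <- c("trait_matrix", class(m))
  m
}
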