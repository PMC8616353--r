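#' Default glycan-type classification from composition
#'
#' Assigns the glycan type from composition alone, used when no curated
#' structural annotation is available.  For N-glycans the four canonical
#' types are distinguished: paucimannose (truncated, HexNAc 2, at most 3
#' hexoses, optional single core fucose, unsialylated), oligomannose
#' (HexNAc 2, 4-9 hexoses, no fucose or sialic acid), hybrid (HexNAc 3 with
#' at least 4 hexoses) and complex (everything else, i.e. HexNAc >= 4 or
#' HexNAc 3 with fewer than 4 hexoses).  For O-glycans, core 1 (single
#' HexNAc, the core GalNAc) versus core 2 (additional branching GlcNAc);
#' core 3/4 are not modelled.  Phosphorylated Hex(x)HexNAc2 species remain
#' oligomannose; phosphorylation is tracked as a derived trait, not a type.
#'
#' The paucimannose/oligomannose boundary is set at hex <= 3 for
#' paucimannose, so H4N2 (Man4) classifies as oligomannose.
#'
#' @param composition a \code{glycan_composition}.
#' @param glycan_class \code{"N"} or \code{"O"}.
#' @return the glycan type as a string: one of \code{"oligomannose"},
#'   \code{"paucimannose"}, \code{"hybrid"}, \code{"complex"} for class N;
#'   \code{"core1"} or \code{"core2"} for class O.
#' @examples
#' classify_by_composition(glycan_composition(hex = 9, hexnac = 2), "N")
#' classify_by_composition(glycan_composition(hex = 1, hexnac = 1, neuac = 1), "O")
#' @export
classify_by_composition <- function(composition, glycan_class) {
  stopifnot(inherits(composition, "glycan_composition"))
  glycan_class <- match.arg(glycan_class, c("N", "O"))
  hex <- composition[["hex"]]; hexnac <- composition[["hexnac"]]
  fuc <- composition[["fuc"]]; neuac <- composition[["neuac"]]
  if (hexnac < 1L)
    stop("invalid composition: hexnac must be >= 1 for a real glycan")
  if (glycan_class == "N") {
    if (hexnac < 2L)
      stop("invalid N-glycan composition: hexnac must be >= 2 (chitobiose core)")
    if (hexnac == 2L && hex <= 3L && fuc <= 1L && neuac == 0L)
      return("paucimannose")
    if (hexnac == 2L && hex >= 4L && hex <= 9L && fuc == 0L && neuac == 0L)
      return("oligomannose")
    if (hexnac == 3L && hex >= 4L)
      return("hybrid")
    return("complex")
  }
  if (hexnac == 1L) "core1" else "core2"
}

.annotation_cols <- c("glycan_type", "antennae", "bisecting", "core_fucose",
                      "antennary_fucose", "sia_a23", "sia_a26_gal",
                      "sia_a26_core", "sia_a28", "sia_unknown",
                      "lacnac_repeats", "sulfo_sites", "has_H_antigen",
                      "has_T_antigen", "has_sLex_a", "has_Lex_a")

#' Construct a curated glycan record
#'
#' A glycan record couples a composition (parsed from \code{name}) with its
#' glycan class and a structural annotation established from MS2 evidence:
#' antenna count, bisecting GlcNAc, the split of fucoses into core and
#' antennary positions, sialic acid linkage counts (alpha-2,3; alpha-2,6 on
#' terminal Gal for N-glycans; alpha-2,6 on the core GalNAc for O-glycans;
#' alpha-2,8 chain extension; undetermined), LacNAc repeats, sulfation sites
#' and epitope flags (H antigen, T antigen, Lewis x/a, sialyl-Lewis x/a).
#'
#' @param name composition string with optional isomer suffix.
#' @param glycan_class \code{"N"} or \code{"O"}.
#' @param glycan_type curated type; defaults to
#'   [classify_by_composition()] on the parsed composition.
#' @param antennae antenna count (N-glycans; 0 for O-glycans).
#' @param bisecting logical, bisecting GlcNAc present.
#' @param core_fucose,antennary_fucose fucose position counts; must sum to
#'   the composition fucose count.
#' @param sia_a23,sia_a26_gal,sia_a26_core,sia_a28,sia_unknown sialic acid
#'   linkage counts; must sum to the composition NeuAc count.
#' @param lacnac_repeats count of N-acetyllactosamine extension units.
#' @param sulfo_sites count of sulfated positions.
#' @param has_H_antigen,has_T_antigen,has_sLex_a,has_Lex_a epitope flags.
#' @param retention_order_key optional positive number ordering isomers of
#'   one composition by elution.
#' @return an object of class \code{glycan_record} (a list).
#' @export
glycan_record <- function(name, glycan_class,
                          glycan_type = NULL,
                          antennae = 0L, bisecting = FALSE,
                          core_fucose = 0L, antennary_fucose = 0L,
                          sia_a23 = 0L, sia_a26_gal = 0L, sia_a26_core = 0L,
                          sia_a28 = 0L, sia_unknown = 0L,
                          lacnac_repeats = 0L, sulfo_sites = 0L,
                          has_H_antigen = FALSE, has_T_antigen = FALSE,
                          has_sLex_a = FALSE, has_Lex_a = FALSE,
                          retention_order_key = NA_real_) {
  parsed <- parse_glycan_name(name)
  glycan_class <- match.arg(glycan_class, c("N", "O"))
  if (is.null(glycan_type))
    glycan_type <- classify_by_composition(parsed$composition, glycan_class)
  rec <- list(name = name, composition = parsed$composition,
              glycan_class = glycan_class, isomer = parsed$isomer,
              glycan_type = glycan_type,
              antennae = as.integer(antennae),
              bisecting = isTRUE(as.logical(bisecting)),
              core_fucose = as.integer(core_fucose),
              antennary_fucose = as.integer(antennary_fucose),
              sia_a23 = as.integer(sia_a23),
              sia_a26_gal = as.integer(sia_a26_gal),
              sia_a26_core = as.integer(sia_a26_core),
              sia_a28 = as.integer(sia_a28),
              sia_unknown = as.integer(sia_unknown),
              lacnac_repeats = as.integer(lacnac_repeats),
              sulfo_sites = as.integer(sulfo_sites),
              has_H_antigen = isTRUE(as.logical(has_H_antigen)),
              has_T_antigen = isTRUE(as.logical(has_T_antigen)),
              has_sLex_a = isTRUE(as.logical(has_sLex_a)),
              has_Lex_a = isTRUE(as.logical(has_Lex_a)),
              retention_order_key = as.numeric(retention_order_key))
  class(rec) <- "glycan_record"
  rec
}

.n_types <- c("oligomannose", "paucimannose", "hybrid", "complex")
.o_types <- c("core1", "core2")

#' Validate the structural annotation of a glycan record
#'
#' Checks the internal consistency of a curated record and returns all
#' violations found (an empty character vector means the record is
#' consistent).  Checked invariants: sialic linkage counts sum to the NeuAc
#' count; fucose position counts sum to the fucose count; O-glycans carry
#' neither bisection nor antennae; sialyl-Lewis x/a requires antennary
#' fucose and sialic acid; Lewis x/a requires antennary fucose; the T
#' antigen is a nonsialylated core 1 O-glycan; the glycan type belongs to
#' the class vocabulary.  Disagreement between the curated type and the
#' composition-based default classifier is reported as a warning-level
#' violation (prefix \code{"warning:"}), since curated assignments rest on
#' MS2 evidence the composition cannot encode and take precedence.
#'
#' @param record a \code{glycan_record}.
#' @return character vector of violation descriptions; empty if consistent.
#' @export
validate_annotation <- function(record) {
  stopifnot(inherits(record, "glycan_record"))
  v <- character(0)
  comp <- record$composition
  sia_sum <- record$sia_a23 + record$sia_a26_gal + record$sia_a26_core +
    record$sia_a28 + record$sia_unknown
  if (sia_sum != comp[["neuac"]])
    v <- c(v, sprintf("sialic linkage counts sum to %d but composition has %d NeuAc",
                      sia_sum, comp[["neuac"]]))
  fuc_sum <- record$core_fucose + record$antennary_fucose
  if (fuc_sum != comp[["fuc"]])
    v <- c(v, sprintf("fucose position counts sum to %d but composition has %d Fuc",
                      fuc_sum, comp[["fuc"]]))
  if (record$glycan_class == "O") {
    if (record$bisecting)
      v <- c(v, "O-glycan annotated as bisected")
    if (record$antennae > 0L)
      v <- c(v, "O-glycan annotated with antennae")
    if (!record$glycan_type %in% .o_types)
      v <- c(v, sprintf("O-glycan type '%s' not one of core1/core2",
                        record$glycan_type))
    if (record$sia_a26_gal > 0L)
      v <- c(v, "alpha-2,6 sialylation on terminal Gal annotated on an O-glycan")
  } else {
    if (!record$glycan_type %in% .n_types)
      v <- c(v, sprintf("N-glycan type '%s' not one of oligomannose/paucimannose/hybrid/complex",
                        record$glycan_type))
    if (record$sia_a26_core > 0L)
      v <- c(v, "alpha-2,6 sialylation on core GalNAc annotated on an N-glycan")
    if (record$has_T_antigen)
      v <- c(v, "T antigen annotated on an N-glycan")
  }
  if (record$has_sLex_a && (record$antennary_fucose < 1L || comp[["neuac"]] < 1L))
    v <- c(v, "sialyl-Lewis x/a requires antennary fucose and sialic acid")
  if (record$has_Lex_a && record$antennary_fucose < 1L)
    v <- c(v, "Lewis x/a requires antennary fucose")
  if (record$has_T_antigen &&
      (record$glycan_type != "core1" || comp[["neuac"]] > 0L))
    v <- c(v, "T antigen requires a nonsialylated core 1 glycan")
  if (any(c(record$antennae, record$core_fucose, record$antennary_fucose,
            record$sia_a23, record$sia_a26_gal, record$sia_a26_core,
            record$sia_a28, record$sia_unknown, record$lacnac_repeats,
            record$sulfo_sites) < 0L))
    v <- c(v, "negative annotation count")
  if (record$sulfo_sites != comp[["sulfo"]])
    v <- c(v, sprintf("sulfation sites (%d) disagree with composition Su count (%d)",
                      record$sulfo_sites, comp[["sulfo"]]))
  default_type <- tryCatch(
    classify_by_composition(comp, record$glycan_class),
    error = function(e) NA_character_)
  if (is.na(default_type)) {
    v <- c(v, "composition violates class invariants")
  } else if (.composition_decisive(comp, record$glycan_class) &&
             record$glycan_type != default_type) {
    v <- c(v, sprintf("warning: curated type '%s' differs from composition-based type '%s'",
                      record$glycan_type, default_type))
  }
  v
}

# TRUE when the composition admits only one sensible type: the default
# classifier is then treated as decisive.  Hybrid/complex assignment for
# HexNAc >= 3 can rest on MS2 evidence, so those are never decisive; O-glycan
# core assignment and the HexNAc 2 N-glycan families are.
.composition_decisive <- function(composition, glycan_class) {
  if (glycan_class == "O") return(TRUE)
  composition[["hexnac"]] == 2L
}

#' Read and write glycan annotation tables
#'
#' The annotation table is a tab- or comma-separated file with one row per
#' glycan record and columns \code{name}, \code{glycan_class},
#' \code{glycan_type}, \code{antennae}, \code{bisecting},
#' \code{core_fucose}, \code{antennary_fucose}, \code{sia_a23},
#' \code{sia_a26_gal}, \code{sia_a26_core}, \code{sia_a28},
#' \code{sia_unknown}, \code{lacnac_repeats}, \code{sulfo_sites},
#' \code{has_H_antigen}, \code{has_T_antigen}, \code{has_sLex_a},
#' \code{has_Lex_a}.  Booleans are encoded 0/1.
#'
#' @param path file path.
#' @param validate if \code{TRUE} (default), non-warning annotation
#'   violations raise an error.
#' @return \code{read_annotation_table}: a list of \code{glycan_record};
#'   \code{write_annotation_table}: \code{path}, invisibly.
#' @export
read_annotation_table <- function(path, validate = TRUE) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("name", "glycan_class", .annotation_cols)
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("annotation table ", path, ": missing column(s) ",
         paste(missing, collapse = ", "))
  if (anyDuplicated(df$name))
    stop("annotation table ", path, ": duplicated glycan name(s) ",
         paste(unique(df$name[duplicated(df$name)]), collapse = ", "))
  recs <- lapply(seq_len(nrow(df)), function(i) {
    r <- df[i, ]
    glycan_record(
      name = r$name, glycan_class = r$glycan_class,
      glycan_type = r$glycan_type, antennae = r$antennae,
      bisecting = r$bisecting == 1, core_fucose = r$core_fucose,
      antennary_fucose = r$antennary_fucose, sia_a23 = r$sia_a23,
      sia_a26_gal = r$sia_a26_gal, sia_a26_core = r$sia_a26_core,
      sia_a28 = r$sia_a28, sia_unknown = r$sia_unknown,
      lacnac_repeats = r$lacnac_repeats, sulfo_sites = r$sulfo_sites,
      has_H_antigen = r$has_H_antigen == 1,
      has_T_antigen = r$has_T_antigen == 1,
      has_sLex_a = r$has_sLex_a == 1, has_Lex_a = r$has_Lex_a == 1)
  })
  names(recs) <- df$name
  if (validate) {
    for (rec in recs) {
      viol <- validate_annotation(rec)
      hard <- viol[!startsWith(viol, "warning:")]
      if (length(hard))
        stop("annotation table ", path, ", glycan ", rec$name, ": ",
             paste(hard, collapse = "; "))
    }
  }
  recs
}

#' @rdname read_annotation_table
#' @param library list of \code{glycan_record}.
#' @export
write_annotation_table <- function(library, path) {
  df <- library_as_data_frame(library)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Flatten a glycan library to the annotation-table data frame
#' @param library list of \code{glycan_record}.
#' @return data frame in annotation-table column layout (booleans 0/1).
#' @export
library_as_data_frame <- function(library) {
  stopifnot(length(library) > 0)
  rows <- lapply(library, function(rec) {
    data.frame(name = rec$name, glycan_class = rec$glycan_class,
               glycan_type = rec$glycan_type, antennae = rec$antennae,
               bisecting = as.integer(rec$bisecting),
               core_fucose = rec$core_fucose,
               antennary_fucose = rec$antennary_fucose,
               sia_a23 = rec$sia_a23, sia_a26_gal = rec$sia_a26_gal,
               sia_a26_core = rec$sia_a26_core, sia_a28 = rec$sia_a28,
               sia_unknown = rec$sia_unknown,
               lacnac_repeats = rec$lacnac_repeats,
               sulfo_sites = rec$sulfo_sites,
               has_H_antigen = as.integer(rec$has_H_antigen),
               has_T_antigen = as.integer(rec$has_T_antigen),
               has_sLex_a = as.integer(rec$has_sLex_a),
               has_Lex_a = as.integer(rec$has_Lex_a),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' The packaged curated glycan library
#'
#' Loads the glycan library shipped with the package: curated N- and
#' O-glycan records spanning all four N-glycan types (including
#' phosphorylated oligomannose and bisected, antennary-fucosylated and
#' highly branched complex glycans) and core 1/core 2 O-glycans with
#' T antigen, sialyl-T, H antigen, Lewis-type, sulfated, LacNAc-extended
#' and alpha-2,8-sialylated representatives.
#'
#' @return named list of \code{glycan_record}.
#' @export
builtin_glycan_library <- function() {
  path <- system.file("extdata", "glycan_library.tsv", package = "glycofab",
                      mustWork = TRUE)
  read_annotation_table(path, validate = TRUE)
}

#' @export
print.glycan_record <- function(x, ...) {
  cat(sprintf("<glycan record> %s (%s-glycan, %s)\n",
              x$name, x$glycan_class, x$glycan_type))
  invisible(x)
}
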