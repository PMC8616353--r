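#' Monoisotopic residue masses used for glycan alditol mass computation
#'
#' Dehydrated (residue) monoisotopic masses in Da for the building blocks of
#' the composition shorthand: hexose (H), N-acetylhexosamine (N),
#' deoxyhexose/fucose (F), N-acetylneuraminic acid (S), phosphorylation (P,
#' as HPO3) and sulfation (Su, as SO3).
#' @keywords internal
.residue_masses <- c(
  hex    = 162.052824,
  hexnac = 203.079373,
  fuc    = 146.057909,
  neuac  = 291.095417,
  phospho = 79.966331,
  sulfo   = 79.956815
)

# water + 2H: mass of the free reduced (alditol) terminus
.alditol_terminus <- 18.010565 + 2.015650

.comp_slots <- c("hex", "hexnac", "fuc", "neuac", "phospho", "sulfo")
# token order used when formatting names; "Su" must be matched before "S"
.comp_tokens <- c(hex = "H", hexnac = "N", fuc = "F", neuac = "S",
                  phospho = "P", sulfo = "Su")

#' Construct a glycan composition
#'
#' A glycan composition counts the monosaccharides and modifications of a
#' glycan in the shorthand used throughout the package: hexose (H),
#' N-acetylhexosamine (N), fucose (F), N-acetylneuraminic acid (S),
#' phosphorylation (P) and sulfation (Su).
#'
#' @param hex,hexnac,fuc,neuac,phospho,sulfo non-negative integer counts.
#' @return an object of class \code{glycan_composition}: a named integer
#'   vector with elements \code{hex}, \code{hexnac}, \code{fuc},
#'   \code{neuac}, \code{phospho}, \code{sulfo}.
#' @examples
#' glycan_composition(hex = 5, hexnac = 4, neuac = 2)
#' @export
glycan_composition <- function(hex = 0L, hexnac = 0L, fuc = 0L, neuac = 0L,
                               phospho = 0L, sulfo = 0L) {
  x <- c(hex = hex, hexnac = hexnac, fuc = fuc, neuac = neuac,
         phospho = phospho, sulfo = sulfo)
  if (any(is.na(x)) || any(x < 0) || any(x != round(x)))
    stop("composition counts must be non-negative integers")
  x <- as.integer(round(x))
  names(x) <- .comp_slots
  class(x) <- "glycan_composition"
  x
}

#' Parse a glycan composition name
#'
#' Parses composition strings of the form \code{"H5N4F1S2a"}: letter-count
#' tokens drawn from H (hexose), N (HexNAc), F (fucose), S (NeuAc),
#' P (phosphate), Su (sulfate), in any order, each at most once, optionally
#' followed by a single lowercase isomer letter.  Isomer letters distinguish
#' structural isomers of one composition and encode elution order only.
#'
#' @param name composition string, e.g. \code{"H5N4S2a"} or \code{"H9N2"}.
#' @return a list with elements \code{name} (the input), \code{composition}
#'   (a \code{glycan_composition}) and \code{isomer} (single lowercase letter
#'   or \code{NA_character_}).
#' @seealso [format_glycan_name()] for the inverse operation.
#' @examples
#' parse_glycan_name("H5N4S2a")
#' parse_glycan_name("H9N2")
#' @export
parse_glycan_name <- function(name) {
  if (!is.character(name) || length(name) != 1L || is.na(name) ||
      !nzchar(name))
    stop("glycan name must be a single non-empty string")
  rest <- name
  counts <- stats::setNames(integer(length(.comp_slots)), .comp_slots)
  seen <- character(0)
  isomer <- NA_character_
  while (nzchar(rest)) {
    m <- regmatches(rest, regexec("^(Su|H|N|F|S|P)([0-9]+)", rest))[[1]]
    if (length(m)) {
      tok <- m[2]
      cnt <- suppressWarnings(as.integer(m[3]))
      slot <- names(.comp_tokens)[match(tok, .comp_tokens)]
      if (tok %in% seen)
        stop(sprintf("glycan name '%s': duplicated token '%s'", name, tok))
      if (is.na(cnt) || cnt < 1L)
        stop(sprintf("glycan name '%s': non-positive count for token '%s'",
                     name, tok))
      seen <- c(seen, tok)
      counts[slot] <- cnt
      rest <- substr(rest, nchar(m[1]) + 1L, nchar(rest))
    } else if (grepl("^[a-z]$", rest)) {
      isomer <- rest
      rest <- ""
    } else {
      bad <- regmatches(rest, regexpr("^[A-Za-z]+[0-9]*|^.", rest))
      stop(sprintf("glycan name '%s': unknown token '%s'", name, bad))
    }
  }
  if (length(seen) == 0L)
    stop(sprintf("glycan name '%s': no composition tokens found", name))
  comp <- do.call(glycan_composition, as.list(counts))
  list(name = name, composition = comp, isomer = isomer)
}

#' Format a glycan composition as a name
#'
#' Emits the canonical composition string (token order H, N, F, S, P, Su,
#' zero counts omitted), with the isomer suffix if given.  Formatting then
#' parsing is the identity on canonical names.
#'
#' @param composition a \code{glycan_composition}.
#' @param isomer optional single lowercase isomer letter.
#' @return the composition string.
#' @examples
#' format_glycan_name(glycan_composition(hex = 5, hexnac = 4, neuac = 2), "a")
#' @export
format_glycan_name <- function(composition, isomer = NA_character_) {
  stopifnot(inherits(composition, "glycan_composition"))
  parts <- vapply(.comp_slots, function(s) {
    if (composition[[s]] > 0L) paste0(.comp_tokens[[s]], composition[[s]])
    else ""
  }, character(1))
  nm <- paste0(paste(parts, collapse = ""),
               if (!is.na(isomer)) isomer else "")
  nm
}

#' Monoisotopic mass of a reduced (alditol) glycan
#'
#' Computes the neutral monoisotopic mass of the reducing-end-reduced glycan
#' alditol, the analyte form after borohydride reduction in porous graphitized
#' carbon LC-MS workflows: the sum of dehydrated residue masses plus the
#' reduced terminus (water + 2 H).
#'
#' @param composition a \code{glycan_composition}.
#' @return mass in Da.
#' @examples
#' alditol_mass(glycan_composition(hex = 9, hexnac = 2))  # Man9 alditol
#' @export
alditol_mass <- function(composition) {
  stopifnot(inherits(composition, "glycan_composition"))
  sum(as.numeric(composition) * .residue_masses[.comp_slots]) +
    .alditol_terminus
}

#' @export
print.glycan_composition <- function(x, ...) {
  cat("<glycan composition> ", format_glycan_name(x), "\n", sep = "")
  invisible(x)
}
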