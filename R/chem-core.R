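# Elemental compositions, peptide/glycan masses and SIL label arithmetic.

#' Create an elemental composition
#'
#' An elemental composition is a named integer vector over the supported
#' element symbols (`C`, `H`, `N`, `O`, `S` and the heavy-label
#' pseudo-elements `C13`, `N15`). All arithmetic on compositions is
#' element-wise.
#'
#' @param ... element counts, e.g. `elemental_composition(C = 6, H = 12, O = 6)`.
#' @return an object of class `elemental_composition`.
#' @export
elemental_composition <- function(...) {
  x <- c(...)
  counts <- stats::setNames(integer(length(.ELEMENTS)), .ELEMENTS)
  if (length(x)) {
    bad <- setdiff(names(x), .ELEMENTS)
    if (length(bad)) {
      stop("unknown element symbol(s): ", paste(bad, collapse = ", "))
    }
    if (any(x < 0)) stop("element counts must be non-negative")
    counts[names(x)] <- as.integer(x)
  }
  structure(counts, class = "elemental_composition")
}

.as_composition <- function(counts) {
  full <- stats::setNames(integer(length(.ELEMENTS)), .ELEMENTS)
  full[names(counts)] <- as.integer(counts)
  structure(full, class = "elemental_composition")
}

#' @export
print.elemental_composition <- function(x, ...) {
  nz <- x[x > 0]
  cat("<elemental composition> ",
      paste0(names(nz), unclass(nz), collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Add elemental compositions
#'
#' @param e1,e2 compositions.
#' @export
"+.elemental_composition" <- function(e1, e2) {
  .as_composition(unclass(e1) + unclass(e2))
}

#' Monoisotopic mass of an elemental composition
#'
#' @param comp an [elemental_composition()].
#' @return mass in Da.
#' @export
composition_mass <- function(comp) {
  sum(unclass(comp) * .MONO_MASS[names(comp)])
}

#' Elemental composition of a tryptic peptide backbone
#'
#' Sums standard residue compositions plus one water. For `label = "SIL"`
#' the C-terminal residue (which must be Lys or Arg, as produced by tryptic
#' cleavage of a 13C6,15N2-Lys / 13C6,15N4-Arg labeled protein) has 6 carbons
#' moved to the pure-13C pseudo-element and 2 (Lys) or 4 (Arg) nitrogens
#' moved to pure 15N.
#'
#' @param sequence one-letter amino-acid string.
#' @param label `"natural"` or `"SIL"`.
#' @return an [elemental_composition()].
#' @export
peptide_composition <- function(sequence, label = c("natural", "SIL")) {
  label <- match.arg(label)
  if (!is.character(sequence) || length(sequence) != 1L || !nzchar(sequence)) {
    stop("peptide sequence must be a non-empty string")
  }
  aa <- strsplit(sequence, "")[[1]]
  bad <- setdiff(aa, colnames(.RESIDUES))
  if (length(bad)) {
    stop("unknown residue(s) in sequence: ", paste(unique(bad), collapse = ", "))
  }
  counts <- .WATER
  counts[rownames(.RESIDUES)] <- counts[rownames(.RESIDUES)] +
    as.integer(rowSums(.RESIDUES[, aa, drop = FALSE]))
  if (label == "SIL") {
    cterm <- aa[length(aa)]
    if (!cterm %in% c("K", "R")) {
      stop("SIL peptides must end in K or R (tryptic); got '", cterm, "'")
    }
    n_heavy_n <- if (cterm == "K") 2L else 4L
    counts["C"] <- counts["C"] - 6L
    counts["C13"] <- counts["C13"] + 6L
    counts["N"] <- counts["N"] - n_heavy_n
    counts["N15"] <- counts["N15"] + n_heavy_n
  }
  .as_composition(counts)
}

#' Mass shift of one SIL-labeled residue
#'
#' Lys carries 13C6,15N2 (+8 neutrons), Arg 13C6,15N4 (+10 neutrons); the
#' exact shifts follow from the isotope mass differences.
#'
#' @param residue `"K"` or `"R"`.
#' @return shift in Da.
#' @export
sil_mass_shift <- function(residue) {
  if (!is.character(residue) || length(residue) != 1L ||
      !residue %in% c("K", "R")) {
    stop("SIL label shift is defined for residues K and R only")
  }
  d_c <- .ISOTOPES$C$mass[2] - .ISOTOPES$C$mass[1]
  d_n <- .ISOTOPES$N$mass[2] - .ISOTOPES$N$mass[1]
  n_n <- if (residue == "K") 2 else 4
  6 * d_c + n_n * d_n
}

#' Theoretical m/z of an analyte at a given charge
#'
#' m/z of the first (monoisotopic) isotopologue:
#' `(M + z * 1.007276) / z` where `M` is the monoisotopic neutral mass of
#' the peptide backbone (natural or SIL) plus any attached glycan.
#'
#' @param sequence peptide backbone (one-letter codes).
#' @param charge positive integer charge.
#' @param label `"natural"` or `"SIL"`.
#' @param glycan optional glycan short name (e.g. `"G0F"`) or
#'   [glycan_composition()]; `NULL` or `""` for non-glycosylated peptides.
#' @return m/z in Th.
#' @export
analyte_mz <- function(sequence, charge, label = "natural", glycan = NULL) {
  if (!is.numeric(charge) || length(charge) != 1L || charge < 1 ||
      charge != round(charge)) {
    stop("charge must be a positive integer")
  }
  (analyte_mass(sequence, label, glycan) + charge * PROTON_MASS) / charge
}

#' Monoisotopic neutral mass of a (glyco)peptide analyte
#'
#' @inheritParams analyte_mz
#' @return mass in Da.
#' @export
analyte_mass <- function(sequence, label = "natural", glycan = NULL) {
  composition_mass(analyte_composition(sequence, label, glycan))
}

#' Full elemental composition of a (glyco)peptide analyte
#'
#' @inheritParams analyte_mz
#' @return an [elemental_composition()].
#' @export
analyte_composition <- function(sequence, label = "natural", glycan = NULL) {
  comp <- peptide_composition(sequence, label)
  if (!is.null(glycan) && !(is.character(glycan) && !nzchar(glycan[1]))) {
    g <- if (inherits(glycan, "glycan_composition")) glycan else
      parse_glycan(glycan)
    comp <- comp + glycan_elemental(g)
  }
  comp
}
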