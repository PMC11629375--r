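# Glycan compositions and the short-name nomenclature used for IgG Fc
# N-glycans (G0F, G1FN, G2FS2, ...).

#' Create a glycan composition
#'
#' Monosaccharide counts of an N-glycan: hexoses (Hex), N-acetylhexosamines
#' (HexNAc), deoxyhexoses (Fuc) and N-acetylneuraminic acids (NeuAc).
#'
#' @param hex,hexnac,fuc,neuac non-negative integer counts.
#' @return an object of class `glycan_composition`.
#' @export
glycan_composition <- function(hex = 0, hexnac = 0, fuc = 0, neuac = 0) {
  x <- c(hex = hex, hexnac = hexnac, fuc = fuc, neuac = neuac)
  if (any(x < 0) || any(x != round(x))) {
    stop("monosaccharide counts must be non-negative integers")
  }
  structure(stats::setNames(as.integer(x), names(x)),
            class = "glycan_composition")
}

#' @export
print.glycan_composition <- function(x, ...) {
  nm <- glycan_name(x)
  cat("<glycan> hex", x[["hex"]], " hexnac", x[["hexnac"]],
      " fuc", x[["fuc"]], " neuac", x[["neuac"]],
      if (!is.na(nm)) paste0("  (", nm, ")") else "", "\n", sep = "")
  invisible(x)
}

#' Parse an IgG Fc glycan short name
#'
#' The short-name grammar for complex-type biantennary IgG Fc glycans:
#' `G<g>` with `g` galactoses (0-2) on a `Hex3HexNAc4` core, optional `F`
#' (core fucose), optional `N` (bisecting HexNAc), optional `S` or `S2`
#' (sialic acids). E.g. `"G0F"` is Hex3 HexNAc4 Fuc1; `"G2FS2"` is
#' Hex5 HexNAc4 Fuc1 NeuAc2. The mapping is bijective over the supported
#' name set ([glycan_name()] inverts it).
#'
#' @param name glycan short name.
#' @return a [glycan_composition()].
#' @export
parse_glycan <- function(name) {
  if (!is.character(name) || length(name) != 1L) {
    stop("glycan name must be a single string")
  }
  m <- regmatches(name, regexec("^G([0-2])(F?)(N?)(S([12])?)?$", name))[[1]]
  if (!length(m)) stop("unsupported glycan short name: '", name, "'")
  gal <- as.integer(m[2])
  sial <- if (!nzchar(m[5])) 0L else if (nzchar(m[6])) as.integer(m[6]) else 1L
  glycan_composition(
    hex = 3L + gal,
    hexnac = 4L + (m[4] == "N"),
    fuc = as.integer(m[3] == "F"),
    neuac = sial
  )
}

#' Short name of a glycan composition
#'
#' Inverse of [parse_glycan()]; returns `NA` for compositions outside the
#' supported complex-type biantennary name set.
#'
#' @param glycan a [glycan_composition()].
#' @return short name string or `NA`.
#' @export
glycan_name <- function(glycan) {
  g <- unclass(glycan)
  gal <- g[["hex"]] - 3L
  bis <- g[["hexnac"]] - 4L
  if (gal < 0 || gal > 2 || !bis %in% c(0L, 1L) || !g[["fuc"]] %in% c(0L, 1L) ||
      g[["neuac"]] < 0 || g[["neuac"]] > 2 || g[["neuac"]] > gal) {
    return(NA_character_)
  }
  paste0("G", gal,
         if (g[["fuc"]] == 1L) "F" else "",
         if (bis == 1L) "N" else "",
         if (g[["neuac"]] == 1L) "S" else if (g[["neuac"]] == 2L) "S2" else "")
}

#' Elemental composition of a glycan
#'
#' Monosaccharide residue compositions (condensation water removed); the
#' attachment to the peptide sequon asparagine is likewise anhydrous, so
#' glycopeptide composition is peptide + glycan.
#'
#' @param glycan a [glycan_composition()].
#' @return an [elemental_composition()].
#' @export
glycan_elemental <- function(glycan) {
  if (!inherits(glycan, "glycan_composition")) glycan <- parse_glycan(glycan)
  counts <- as.integer(.MONOSACCHARIDES %*% unclass(glycan))
  names(counts) <- rownames(.MONOSACCHARIDES)
  .as_composition(counts)
}

#' Monoisotopic residue mass of a glycan
#'
#' @param glycan a [glycan_composition()] or short name.
#' @return mass in Da (0 for the empty composition).
#' @export
glycan_mass <- function(glycan) {
  if (!inherits(glycan, "glycan_composition")) glycan <- parse_glycan(glycan)
  composition_mass(glycan_elemental(glycan))
}

#' Default glycoform panels
#'
#' `igg1_glycoforms()` returns the default 20-glycoform IgG1 Fc panel used
#' for quantitation and profiling; it is a documented stand-in covering the
#' common complex-type biantennary glycoforms and should be overridden with
#' a study-specific list where one exists. `igg3_glycoforms()` returns the
#' six glycoforms used for IgG3 quantitation. `sil_glycoforms()` returns the
#' three dominant glycoforms of the CHO-produced SIL IgG1 standard that are
#' quantified and used as calibrants.
#'
#' @return character vector of glycan short names.
#' @export
igg1_glycoforms <- function() {
  c("G0", "G0F", "G0N", "G0FN",
    "G1", "G1F", "G1N", "G1FN",
    "G2", "G2F", "G2N", "G2FN",
    "G1S", "G1FS", "G1FNS",
    "G2S", "G2FS", "G2FNS",
    "G2S2", "G2FS2")
}

#' @rdname igg1_glycoforms
#' @export
igg3_glycoforms <- function() {
  c("G0F", "G1F", "G1FS", "G1FN", "G2F", "G2FS")
}

#' @rdname igg1_glycoforms
#' @export
sil_glycoforms <- function() {
  c("G0", "G0F", "G1F")
}
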