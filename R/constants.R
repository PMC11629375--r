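# Physical constants and embedded isotope / residue tables.
#
# Isotope masses and abundances follow the IUPAC/CODATA recommended values
# commonly embedded in proteomics software. The pseudo-elements C13 and N15
# represent label atoms of the stable-isotope-labeled (SIL) standard and are
# treated as isotopically pure.

#' Mass of a proton in Da
#'
#' Used for all charge-state m/z arithmetic.
#' @export
PROTON_MASS <- 1.007276

# Supported element symbols, in canonical order. C13/N15 are pseudo-elements
# holding the heavy label atoms of SIL peptides.
.ELEMENTS <- c("C", "H", "N", "O", "S", "C13", "N15")

# Per element: isotope neutron offsets (relative to the lightest isotope),
# exact masses (Da) and relative abundances (fractions summing to 1).
.ISOTOPES <- list(
  C = list(offset = c(0L, 1L),
           mass = c(12.0, 13.0033548378),
           abundance = c(0.9893, 0.0107)),
  H = list(offset = c(0L, 1L),
           mass = c(1.00782503207, 2.0141017778),
           abundance = c(0.999885, 0.000115)),
  N = list(offset = c(0L, 1L),
           mass = c(14.0030740048, 15.0001088982),
           abundance = c(0.99636, 0.00364)),
  O = list(offset = c(0L, 1L, 2L),
           mass = c(15.9949146196, 16.9991317, 17.9991610),
           abundance = c(0.99757, 0.00038, 0.00205)),
  S = list(offset = c(0L, 1L, 2L, 4L),
           mass = c(31.97207100, 32.97145876, 33.96786690, 35.96708076),
           abundance = c(0.9499, 0.0075, 0.0425, 0.0001)),
  # label pseudo-elements: isotopically pure heavy atoms
  C13 = list(offset = 0L, mass = 13.0033548378, abundance = 1.0),
  N15 = list(offset = 0L, mass = 15.0001088982, abundance = 1.0)
)

# Monoisotopic mass of each element = mass of its lightest listed isotope
# (for the pseudo-elements, the heavy isotope itself).
.MONO_MASS <- vapply(.ISOTOPES, function(x) x$mass[1L], numeric(1))

# Amino-acid residue elemental compositions (residue = amino acid - H2O),
# canonical one-letter codes. Rows: C, H, N, O, S.
.RESIDUES <- {
  m <- rbind(
    #     G  A  S  P  V  T  C  L  I  N  D  Q  K  E  M  H  F  R  Y  W
    C = c(2, 3, 3, 5, 5, 4, 3, 6, 6, 4, 4, 5, 6, 5, 5, 6, 9, 6, 9, 11),
    H = c(3, 5, 5, 7, 9, 7, 5, 11, 11, 6, 5, 8, 12, 7, 9, 7, 9, 12, 9, 10),
    N = c(1, 1, 1, 1, 1, 1, 1, 1, 1, 2, 1, 2, 2, 1, 1, 3, 1, 4, 1, 2),
    O = c(1, 1, 2, 1, 1, 2, 1, 1, 1, 2, 3, 2, 1, 3, 1, 1, 1, 1, 2, 1),
    S = c(0, 0, 0, 0, 0, 0, 1, 0, 0, 0, 0, 0, 0, 0, 1, 0, 0, 0, 0, 0)
  )
  colnames(m) <- c("G", "A", "S", "P", "V", "T", "C", "L", "I", "N", "D",
                   "Q", "K", "E", "M", "H", "F", "R", "Y", "W")
  storage.mode(m) <- "integer"
  m
}

# Monosaccharide residue elemental compositions (as incorporated in a glycan,
# i.e. condensation water already removed). Rows: C, H, N, O, S.
.MONOSACCHARIDES <- {
  m <- rbind(
    C = c(hex = 6, hexnac = 8, fuc = 6, neuac = 11),
    H = c(10, 13, 10, 17),
    N = c(0, 1, 0, 1),
    O = c(5, 5, 4, 8),
    S = c(0, 0, 0, 0)
  )
  storage.mode(m) <- "integer"
  m
}

# Water, for peptide termini.
.WATER <- c(C = 0L, H = 2L, N = 0L, O = 1L, S = 0L, C13 = 0L, N15 = 0L)
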