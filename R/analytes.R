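# Analyte definition tables (panels).
#
# A panel is a plain data.frame, one row per analyte, with columns:
#   analyte_id  unique id, e.g. "IgG1-G0F" or "IgG1-G0F-SIL"
#   sequence    peptide backbone, one-letter codes
#   label       "natural" or "SIL"
#   glycan      glycan short name, or "" for non-glycosylated peptides
#   charges     comma-separated charge states, e.g. "2,3"
#   rt_start_s, rt_end_s  retention-time window (seconds) of the sum
#               spectrum the analyte is integrated from
#   role        "quantifier", "calibrant", "both" or "excluded"

.PANEL_COLS <- c("analyte_id", "sequence", "label", "glycan", "charges",
                 "rt_start_s", "rt_end_s", "role")

#' Default tryptic (glyco)peptide backbones
#'
#' The IgG1 Fc glycopeptide backbone `EEQYNSTYR`, the IgG3 backbone
#' `EEQYNSTFR`, and the IgG1 proteotypic peptides `GPSVFPLAPSSK` (GPS) and
#' `TTPPVLDSDGSFFLYSK` (TTP). All are configurable wherever a panel is
#' accepted.
#'
#' @return named character vector.
#' @export
default_backbones <- function() {
  c(IgG1 = "EEQYNSTYR", IgG3 = "EEQYNSTFR",
    GPS = "GPSVFPLAPSSK", TTP = "TTPPVLDSDGSFFLYSK")
}

#' Build the default analyte panel
#'
#' Natural IgG1 glycopeptides over the default 20-glycoform panel, the three
#' SIL standard glycopeptides (G0, G0F, G1F; also the mass calibrants), the
#' GPS and TTP proteotypic peptides in natural and SIL form, and optionally
#' the six natural IgG3 glycopeptides. Glycopeptides carry charges 2 and 3;
#' non-glycosylated peptides charge 2 only.
#'
#' @param include_igg3 add the IgG3 glycopeptide rows.
#' @param backbones named backbone overrides, see [default_backbones()].
#' @param rt_glyco,rt_gps,rt_ttp retention windows in seconds
#'   (instrument-specific; the defaults match the synthetic generator).
#' @return a panel data.frame.
#' @export
default_panel <- function(include_igg3 = FALSE,
                          backbones = default_backbones(),
                          rt_glyco = c(48, 62),
                          rt_gps = c(100, 114),
                          rt_ttp = c(120, 134)) {
  row <- function(id, seq, label, glycan, charges, rt, role) {
    data.frame(analyte_id = id, sequence = seq, label = label,
               glycan = glycan, charges = charges,
               rt_start_s = rt[1], rt_end_s = rt[2], role = role,
               stringsAsFactors = FALSE)
  }
  rows <- list()
  for (g in igg1_glycoforms()) {
    rows[[length(rows) + 1L]] <-
      row(paste0("IgG1-", g), backbones[["IgG1"]], "natural", g, "2,3",
          rt_glyco, "quantifier")
  }
  for (g in sil_glycoforms()) {
    rows[[length(rows) + 1L]] <-
      row(paste0("IgG1-", g, "-SIL"), backbones[["IgG1"]], "SIL", g, "2,3",
          rt_glyco, "both")
  }
  if (include_igg3) {
    for (g in igg3_glycoforms()) {
      rows[[length(rows) + 1L]] <-
        row(paste0("IgG3-", g), backbones[["IgG3"]], "natural", g, "2,3",
            rt_glyco, "quantifier")
    }
  }
  rows[[length(rows) + 1L]] <-
    row("GPS", backbones[["GPS"]], "natural", "", "2", rt_gps, "quantifier")
  rows[[length(rows) + 1L]] <-
    row("GPS-SIL", backbones[["GPS"]], "SIL", "", "2", rt_gps, "quantifier")
  rows[[length(rows) + 1L]] <-
    row("TTP", backbones[["TTP"]], "natural", "", "2", rt_ttp, "quantifier")
  rows[[length(rows) + 1L]] <-
    row("TTP-SIL", backbones[["TTP"]], "SIL", "", "2", rt_ttp, "quantifier")
  panel <- do.call(rbind, rows)
  validate_panel(panel)
  panel
}

#' Validate an analyte panel
#'
#' @param panel a panel data.frame.
#' @return the panel, invisibly; errors on structural problems.
#' @export
validate_panel <- function(panel) {
  miss <- setdiff(.PANEL_COLS, names(panel))
  if (length(miss)) stop("panel is missing column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(panel$analyte_id)) stop("panel analyte_id must be unique")
  if (!all(panel$label %in% c("natural", "SIL"))) {
    stop("panel label must be 'natural' or 'SIL'")
  }
  if (!all(panel$role %in% c("quantifier", "calibrant", "both", "excluded"))) {
    stop("unknown panel role")
  }
  for (i in seq_len(nrow(panel))) {
    ch <- panel_charges(panel$charges[i])
    if (!length(ch) || any(ch < 1)) {
      stop("analyte '", panel$analyte_id[i], "' has invalid charges")
    }
    if (panel$label[i] == "SIL") {
      # errors if not tryptic K/R terminal
      peptide_composition(panel$sequence[i], "SIL")
    }
    if (nzchar(panel$glycan[i])) parse_glycan(panel$glycan[i])
  }
  if (any(panel$rt_start_s >= panel$rt_end_s)) {
    stop("panel rt windows must have start < end")
  }
  invisible(panel)
}

#' @rdname validate_panel
#' @param charges comma-separated charge string, e.g. `"2,3"`.
#' @export
panel_charges <- function(charges) {
  as.integer(strsplit(as.character(charges), ",", fixed = TRUE)[[1]])
}

#' Read / write an analyte panel TSV
#'
#' @param path file path.
#' @return `read_analyte_panel` returns a validated panel data.frame.
#' @export
read_analyte_panel <- function(path) {
  panel <- utils::read.delim(path, comment.char = "#",
                             colClasses = "character")
  panel$rt_start_s <- as.numeric(panel$rt_start_s)
  panel$rt_end_s <- as.numeric(panel$rt_end_s)
  panel$glycan[is.na(panel$glycan)] <- ""
  validate_panel(panel)
  panel
}

#' @rdname read_analyte_panel
#' @param panel a panel data.frame.
#' @export
write_analyte_panel <- function(panel, path) {
  validate_panel(panel)
  write_result_table(panel, path, schema = "analyte-panel")
  invisible(path)
}
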