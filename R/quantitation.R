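# Absolute concentration from natural/SIL ratios.
#
# With a spike of `sil_mass_ng` into the eluate of `plasma_volume_ml` of
# plasma, and equal MS response of natural and SIL isotopologues, the
# plasma concentration of the natural protein is
#
#   conc [ng/mL] = (natural signal / SIL signal) * sil_mass_ng /
#                  plasma_volume_ml
#
# evaluated either on summed glycopeptide signals or on a single
# proteotypic peptide pair.

#' Concentration from summed glycopeptide signals
#'
#' @param nat_sum summed coverage-corrected, charge-state-merged natural
#'   glycopeptide signal over the consensus panel.
#' @param sil_sum summed signal over the SIL standard glycopeptides.
#' @param spike a [spike_config()].
#' @return concentration in ng/mL; `NA` (standard failure) when
#'   `sil_sum <= 0`.
#' @export
conc_from_glycopeptides <- function(nat_sum, sil_sum,
                                    spike = spike_config()) {
  if (is.na(sil_sum) || sil_sum <= 0) return(NA_real_)
  (nat_sum / sil_sum) * spike$sil_mass_ng / spike$plasma_volume_ml
}

#' Concentration from a proteotypic peptide pair
#'
#' Same ratio formula as [conc_from_glycopeptides()], applied to the
#' corrected intensities of one natural/SIL peptide pair (uncalibrated
#' charge-2 extraction).
#'
#' @param nat_intensity,sil_intensity corrected areas of the natural and
#'   SIL peptide.
#' @inheritParams conc_from_glycopeptides
#' @export
conc_from_peptide <- function(nat_intensity, sil_intensity,
                              spike = spike_config()) {
  conc_from_glycopeptides(nat_intensity, sil_intensity, spike)
}

#' Composite concentration
#'
#' Median of the available per-analyte-class concentrations (an even count
#' averages the central two). By default the composite uses the
#' glycopeptide- and GPS-derived values; TTP is excluded as
#' interference-prone.
#'
#' @param concs numeric vector of concentrations (NAs dropped).
#' @return median concentration; `NA` when no value is available.
#' @export
composite_concentration <- function(concs) {
  concs <- concs[!is.na(concs)]
  if (!length(concs)) return(NA_real_)
  stats::median(concs)
}

#' IgG3 concentration against the IgG1 SIL standard
#'
#' Applies the glycopeptide ratio formula with the summed natural IgG3
#' glycopeptide signal (six-glycoform panel) over the IgG1 SIL standard
#' sum. Tagged as cross-subclass: subclass-specific response differences
#' (e.g. ionization suppression at the IgG3 retention time) are not
#' corrected, so accuracy is lower than for IgG1.
#'
#' @param nat_igg3_sum summed natural IgG3 glycopeptide signal.
#' @param sil_igg1_sum summed IgG1 SIL glycopeptide signal.
#' @inheritParams conc_from_glycopeptides
#' @return concentration in ng/mL with attribute
#'   `standard = "cross-subclass"`.
#' @export
conc_igg3 <- function(nat_igg3_sum, sil_igg1_sum, spike = spike_config()) {
  out <- conc_from_glycopeptides(nat_igg3_sum, sil_igg1_sum, spike)
  attr(out, "standard") <- "cross-subclass"
  out
}

#' Quantify all samples of a cohort
#'
#' Sums charge-state-merged corrected areas over the configured panels per
#' sample and derives the glycopeptide, GPS, optional TTP and composite
#' concentrations, with LLOQ/ULOQ reporting flags.
#'
#' @param extractions cohort extraction results (per charge state).
#' @param curation a `curation_report` from [spectral_curation()].
#' @param nat_panel_ids consensus natural glycopeptide analyte ids.
#' @param sil_panel_ids SIL standard glycopeptide analyte ids.
#' @param spike a [spike_config()].
#' @param gps_pair,ttp_pair c(natural id, SIL id) of the peptide pairs.
#' @param igg3_panel_ids optional natural IgG3 glycopeptide ids; adds a
#'   `conc_igg3` column.
#' @return data.frame, one row per sample: `sample_id`, `conc_glyco`,
#'   `conc_gps`, `conc_ttp`, `conc_composite`, `conc_igg3` (optional),
#'   `below_lloq`, `above_uloq`, `curation_passed`.
#' @export
quantify_samples <- function(extractions, curation, nat_panel_ids,
                             sil_panel_ids, spike = spike_config(),
                             gps_pair = c("GPS", "GPS-SIL"),
                             ttp_pair = c("TTP", "TTP-SIL"),
                             igg3_panel_ids = NULL) {
  merged <- merge_charge_states(extractions)
  passed <- curation$per_sample$passed
  names(passed) <- curation$per_sample$sample_id
  area_of <- function(d, ids) sum(d$corrected_area[d$analyte_id %in% ids])
  rows <- lapply(split(merged, merged$sample_id), function(d) {
    sid <- d$sample_id[1]
    sil_sum <- area_of(d, sil_panel_ids)
    conc_glyco <- conc_from_glycopeptides(area_of(d, nat_panel_ids),
                                          sil_sum, spike)
    conc_gps <- conc_from_peptide(area_of(d, gps_pair[1]),
                                  area_of(d, gps_pair[2]), spike)
    conc_ttp <- conc_from_peptide(area_of(d, ttp_pair[1]),
                                  area_of(d, ttp_pair[2]), spike)
    comp <- composite_concentration(
      c(conc_glyco, conc_gps, if (isTRUE(spike$include_ttp)) conc_ttp))
    row <- data.frame(sample_id = sid,
                      conc_glyco = conc_glyco, conc_gps = conc_gps,
                      conc_ttp = conc_ttp, conc_composite = comp,
                      below_lloq = !is.na(comp) && comp < spike$lloq,
                      above_uloq = !is.na(comp) && comp > spike$uloq,
                      curation_passed = isTRUE(unname(passed[sid])))
    if (!is.null(igg3_panel_ids)) {
      row$conc_igg3 <- as.numeric(conc_igg3(area_of(d, igg3_panel_ids),
                                            sil_sum, spike))
    }
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
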