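# Processing configuration.

#' Processing configuration
#'
#' Defaults follow the glycopeptide-centered MS1 integration workflow:
#' glycopeptides are integrated in 0.04 Th windows covering at least 95% of
#' the theoretical isotopologue pattern with mass calibration applied;
#' non-glycosylated peptides in 0.065 Th windows covering at least 80%,
#' without calibration. Calibrants require S/N >= 9.
#'
#' @param glyco_window_th integration half-window around each glycopeptide
#'   isotopologue, Th.
#' @param glyco_min_fraction minimum integrated fraction of the theoretical
#'   glycopeptide isotopologue pattern.
#' @param pep_window_th integration half-window for non-glycosylated
#'   peptides, Th.
#' @param pep_min_fraction minimum integrated pattern fraction for
#'   non-glycosylated peptides.
#' @param calibrant_sn S/N cutoff for accepting a calibrant point.
#' @param ppm_search half-width of the calibrant search window, ppm.
#' @param noise_half_width_th half-width of the local background/noise
#'   estimation window, Th.
#' @param merge_grid_th m/z grid used when merging scan centroids into a sum
#'   spectrum, Th; an order of magnitude finer than the narrowest
#'   integration window.
#' @param qc_sn_min,qc_ppm_max,qc_ipq_max per-analyte QC thresholds used for
#'   the consensus list (applied after charge-state merging).
#' @param presence_cutoff fraction of curated spectra per biological group
#'   in which an analyte must pass QC to enter the consensus list.
#' @param consensus_all_groups require the presence cutoff in every listed
#'   group (`TRUE`, default) or in at least one group (`FALSE`).
#' @param negative_percentile percentile of negative-control
#'   natural-to-standard ratios used as the spectral curation cutoff.
#' @return a list of class `silglyco_config`.
#' @export
processing_config <- function(glyco_window_th = 0.04,
                              glyco_min_fraction = 0.95,
                              pep_window_th = 0.065,
                              pep_min_fraction = 0.8,
                              calibrant_sn = 9,
                              ppm_search = 30,
                              noise_half_width_th = 10,
                              merge_grid_th = 0.002,
                              qc_sn_min = 9,
                              qc_ppm_max = 20,
                              qc_ipq_max = 0.25,
                              presence_cutoff = 0.80,
                              consensus_all_groups = TRUE,
                              negative_percentile = 0.95) {
  cfg <- list(glyco_window_th = glyco_window_th,
              glyco_min_fraction = glyco_min_fraction,
              pep_window_th = pep_window_th,
              pep_min_fraction = pep_min_fraction,
              calibrant_sn = calibrant_sn,
              ppm_search = ppm_search,
              noise_half_width_th = noise_half_width_th,
              merge_grid_th = merge_grid_th,
              qc_sn_min = qc_sn_min,
              qc_ppm_max = qc_ppm_max,
              qc_ipq_max = qc_ipq_max,
              presence_cutoff = presence_cutoff,
              consensus_all_groups = consensus_all_groups,
              negative_percentile = negative_percentile)
  stopifnot(cfg$glyco_window_th > 0, cfg$pep_window_th > 0,
            cfg$glyco_min_fraction > 0, cfg$glyco_min_fraction <= 1,
            cfg$pep_min_fraction > 0, cfg$pep_min_fraction <= 1,
            cfg$merge_grid_th > 0)
  class(cfg) <- "silglyco_config"
  cfg
}

#' Spike configuration for ratio-based quantitation
#'
#' The SIL IgG1 standard is spiked into each immunosorbent eluate; with the
#' default 2 ng spike and 0.02 mL plasma input, a unit natural-to-standard
#' ratio corresponds to 100 ng/mL.
#'
#' @param sil_mass_ng spiked SIL standard mass per sample, ng.
#' @param plasma_volume_ml plasma volume captured per sample, mL.
#' @param lloq,uloq reporting limits of quantitation, ng/mL (flags only;
#'   values are never truncated).
#' @param include_ttp include the TTP peptide concentration in the composite
#'   (excluded by default; TTP is interference-prone).
#' @return a list of class `spike_config`.
#' @export
spike_config <- function(sil_mass_ng = 2,
                         plasma_volume_ml = 0.02,
                         lloq = 100,
                         uloq = 10000,
                         include_ttp = FALSE) {
  stopifnot(sil_mass_ng > 0, plasma_volume_ml > 0)
  structure(list(sil_mass_ng = sil_mass_ng,
                 plasma_volume_ml = plasma_volume_ml,
                 lloq = lloq, uloq = uloq,
                 include_ttp = include_ttp),
            class = "spike_config")
}
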