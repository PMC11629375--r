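# End-to-end pipeline: read -> sum -> calibrate -> integrate -> curate ->
# quantify -> profile, with per-sample fault isolation and provenance.

#' Run the full processing pipeline on a cohort
#'
#' Reads one spectrum file per sample (mzXML or TSV peak list), extracts
#' the panel, applies spectral curation against the negative controls,
#' builds the consensus analyte list, quantifies every sample against the
#' SIL spike and derives glycoform profiles and traits for curated
#' samples. A corrupt or unreadable sample file fails that sample only;
#' the run continues.
#'
#' @param files named character vector: `sample_id` -> spectrum file path.
#'   Alternatively a directory via `input_dir` where each file is named
#'   `<sample_id>.tsv` / `<sample_id>.mzXML`.
#' @param panel analyte panel data.frame or panel TSV path.
#' @param meta sample metadata data.frame or TSV path.
#' @param out_dir output directory for result tables; `NULL` to skip
#'   writing.
#' @param config a [processing_config()].
#' @param spike a [spike_config()].
#' @param input_dir directory scanned for sample files when `files` is
#'   `NULL`.
#' @param igg3 also quantify/profile IgG3 (requires IgG3 rows in the
#'   panel).
#' @param verbose emit one log line per sample.
#' @return list with `extractions`, `curation`, `consensus`, `quant`,
#'   `profiles`, `traits`, `failures` (data.frame sample_id, error) and
#'   `config`.
#' @export
run_pipeline <- function(files = NULL, panel, meta, out_dir = NULL,
                         config = processing_config(),
                         spike = spike_config(),
                         input_dir = NULL, igg3 = FALSE, verbose = TRUE) {
  if (is.character(panel) && length(panel) == 1L) {
    panel <- read_analyte_panel(panel)
  }
  validate_panel(panel)
  if (is.character(meta) && length(meta) == 1L) {
    meta <- read_sample_metadata(meta)
  }
  if (is.null(files)) {
    if (is.null(input_dir)) stop("provide either 'files' or 'input_dir'")
    cand <- list.files(input_dir, pattern = "\\.(tsv|mzXML|mzxml)$",
                       full.names = TRUE)
    ids <- tools::file_path_sans_ext(basename(cand))
    files <- stats::setNames(cand, ids)
    files <- files[names(files) %in% meta$sample_id]
  }
  if (is.null(names(files)) || any(!nzchar(names(files)))) {
    stop("'files' must be named by sample_id")
  }

  extractions <- list(); failures <- list()
  for (sid in names(files)) {
    res <- tryCatch({
      scans <- read_scans(files[[sid]])
      ext <- extract_sample(scans, panel, config, sample_id = sid)
      cal <- attr(ext, "calibration")
      if (verbose) {
        message(sprintf("sample %s: calibration %s (%d points)%s", sid,
                        if (is.null(cal)) "none" else cal$kind,
                        if (is.null(cal)) 0L else nrow(cal$points),
                        if (!is.null(cal) && isTRUE(cal$flagged))
                          " [uncalibrated]" else ""))
      }
      ext
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[sid]] <- data.frame(sample_id = sid,
                                    error = conditionMessage(res))
      if (verbose) message(sprintf("sample %s: FAILED (%s)", sid,
                                   conditionMessage(res)))
    } else {
      extractions[[sid]] <- res
    }
  }
  if (!length(extractions)) stop("no sample could be processed")
  extr <- do.call(rbind, c(extractions, list(make.row.names = FALSE)))
  meta_ok <- meta[meta$sample_id %in% names(extractions), , drop = FALSE]

  nat_ids <- panel$analyte_id[panel$label == "natural" &
                                nzchar(panel$glycan) &
                                startsWith(panel$analyte_id, "IgG1-")]
  sil_ids <- panel$analyte_id[panel$label == "SIL" & nzchar(panel$glycan)]

  curation <- spectral_curation(extr, meta_ok, nat_ids, sil_ids,
                                percentile = config$negative_percentile)
  consensus <- analyte_consensus(extr, meta_ok, curation, nat_ids,
                                 config = config)
  if (!length(consensus)) {
    warning("empty consensus list; falling back to the full natural panel")
    consensus <- sort(nat_ids)
  }

  igg3_ids <- NULL
  if (igg3) {
    igg3_ids <- panel$analyte_id[startsWith(panel$analyte_id, "IgG3-")]
    if (!length(igg3_ids)) stop("igg3 = TRUE but the panel has no IgG3 rows")
  }
  quant <- quantify_samples(extr, curation, consensus, sil_ids, spike,
                            igg3_panel_ids = igg3_ids)

  curated_ids <- curation$per_sample$sample_id[curation$per_sample$passed]
  prof <- profile_cohort(extr, consensus,
                         sample_ids = intersect(unique(extr$sample_id),
                                                curated_ids))
  profiles <- prof$profiles; traits <- prof$traits
  if (igg3) {
    prof3 <- profile_cohort(extr, igg3_ids,
                            sample_ids = intersect(unique(extr$sample_id),
                                                   curated_ids),
                            subclass = "IgG3")
    profiles <- rbind(profiles, prof3$profiles)
    traits <- rbind(traits, prof3$traits)
  }
  failures <- if (length(failures))
    do.call(rbind, c(failures, list(make.row.names = FALSE))) else
    data.frame(sample_id = character(0), error = character(0))

  out <- list(extractions = extr, curation = curation,
              consensus = consensus, quant = quant,
              profiles = profiles, traits = traits, failures = failures,
              config = config, spike = spike)
  if (!is.null(out_dir)) write_pipeline_outputs(out, out_dir)
  out
}

#' Write all pipeline result tables
#'
#' Writes `extraction.tsv`, `curation.tsv`, `curation_summary.json`,
#' `consensus.tsv`, `quantitation.tsv`, `profiles.tsv`, `traits.tsv`,
#' `failures.tsv` and the fully resolved configuration as `config.json`
#' (provenance).
#'
#' @param result a [run_pipeline()] result.
#' @param out_dir output directory (created if needed).
#' @export
write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_result_table(result$extractions, file.path(out_dir, "extraction.tsv"),
                     schema = "extraction")
  write_result_table(result$curation$per_sample,
                     file.path(out_dir, "curation.tsv"), schema = "curation")
  jsonlite::write_json(
    list(cutoff_ratio = result$curation$cutoff_ratio,
         percentile = result$curation$percentile,
         n_passed = sum(result$curation$per_sample$passed),
         n_excluded = sum(!result$curation$per_sample$passed)),
    file.path(out_dir, "curation_summary.json"), auto_unbox = TRUE,
    digits = NA)
  write_result_table(data.frame(analyte_id = result$consensus),
                     file.path(out_dir, "consensus.tsv"),
                     schema = "consensus")
  write_result_table(result$quant, file.path(out_dir, "quantitation.tsv"),
                     schema = "quantitation")
  if (!is.null(result$profiles)) {
    write_result_table(result$profiles, file.path(out_dir, "profiles.tsv"),
                       schema = "glyco-profile")
  }
  if (!is.null(result$traits)) {
    write_result_table(result$traits, file.path(out_dir, "traits.tsv"),
                       schema = "glyco-traits")
  }
  write_result_table(result$failures, file.path(out_dir, "failures.tsv"),
                     schema = "failures")
  jsonlite::write_json(
    list(processing = unclass(result$config),
         spike = unclass(result$spike)),
    file.path(out_dir, "config.json"), auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
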