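# Spectral curation against negative controls and consensus analyte
# selection.

#' Read / write sample metadata
#'
#' Metadata TSV columns: `sample_id`, `role` (`case`, `negative_control`,
#' `pool_replicate`), `group` (biological group label; may be empty for
#' negative controls) and `batch`.
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_sample_metadata <- function(path) {
  meta <- utils::read.delim(path, comment.char = "#",
                            colClasses = "character")
  need <- c("sample_id", "role", "group", "batch")
  miss <- setdiff(need, names(meta))
  if (length(miss)) stop("metadata missing column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(meta$sample_id)) stop("sample_id must be unique")
  bad <- setdiff(meta$role, c("case", "negative_control", "pool_replicate"))
  if (length(bad)) stop("unknown sample role(s): ", paste(bad, collapse = ", "))
  meta
}

#' Spectral curation by the negative-control ratio cutoff
#'
#' For every sample the ratio of total natural analyte signal to total SIL
#' standard signal (summed corrected areas over the given panels, all
#' charge states) is computed. The cutoff is the 95th percentile
#' (empirical definition, see [negative_control_cutoff()]) of this ratio over
#' the negative controls; samples at or below the cutoff fail. Negative
#' controls themselves always fail for downstream quantitation. Samples
#' without any SIL signal fail with reason `"standard absent"` (spike or
#' digestion failure).
#'
#' @param extractions extraction results for the whole cohort (per charge
#'   state; they are summed here).
#' @param meta sample metadata (see [read_sample_metadata()]); at least 3
#'   negative controls are required.
#' @param nat_panel_ids analyte ids of the natural signal panel.
#' @param sil_panel_ids analyte ids of the SIL standard panel.
#' @param percentile cutoff percentile, default 0.95.
#' @return list of class `curation_report`: `cutoff_ratio`, `per_sample`
#'   (data.frame `sample_id`, `role`, `nat_total`, `sil_total`, `ratio`,
#'   `passed`, `reason`), `percentile`.
#' @export
spectral_curation <- function(extractions, meta, nat_panel_ids,
                              sil_panel_ids, percentile = 0.95) {
  if (!length(nat_panel_ids) || !length(sil_panel_ids)) {
    stop("natural and SIL panels must be non-empty")
  }
  n_neg <- sum(meta$role == "negative_control")
  if (n_neg < 3) {
    stop("spectral curation requires at least 3 negative controls; got ",
         n_neg)
  }
  sum_panel <- function(d, ids) sum(d$corrected_area[d$analyte_id %in% ids])
  per <- lapply(split(extractions, extractions$sample_id), function(d) {
    data.frame(sample_id = d$sample_id[1],
               nat_total = sum_panel(d, nat_panel_ids),
               sil_total = sum_panel(d, sil_panel_ids))
  })
  per <- do.call(rbind, per)
  per <- merge(meta[, c("sample_id", "role")], per, by = "sample_id")
  per$ratio <- ifelse(per$sil_total > 0, per$nat_total / per$sil_total,
                      NA_real_)
  neg_ratios <- per$ratio[per$role == "negative_control" &
                            !is.na(per$ratio)]
  if (length(neg_ratios) < 3) {
    stop("fewer than 3 negative controls with measurable standard signal")
  }
  cutoff <- negative_control_cutoff(neg_ratios, percentile)
  per$passed <- !is.na(per$ratio) & per$ratio > cutoff &
    per$role != "negative_control"
  per$reason <- ifelse(per$passed, "",
                       ifelse(is.na(per$ratio), "standard absent",
                              ifelse(per$role == "negative_control",
                                     "negative control",
                                     "at or below background cutoff")))
  per <- per[order(per$sample_id), , drop = FALSE]
  rownames(per) <- NULL
  structure(list(cutoff_ratio = cutoff, per_sample = per,
                 percentile = percentile),
            class = "curation_report")
}

#' Negative-control ratio cutoff
#'
#' The empirical ("higher") percentile of the natural-to-standard ratios
#' observed in negative controls: the smallest observed ratio with at
#' least the requested fraction of negatives at or below it (quantile
#' type 1). With n negatives and the strict `ratio > cutoff` pass rule,
#' the expected false-pass rate among i.i.d. negatives is
#' `floor((1 - percentile) * n) / n`, i.e. at most 5% for the default
#' 95th percentile; an interpolating percentile definition would not
#' guarantee this bound (at n = 28 it would always let the top two
#' negatives through, 7.1%).
#'
#' @param neg_ratios numeric vector of negative-control ratios.
#' @param percentile percentile in (0, 1).
#' @param type quantile type passed to [stats::quantile()]; the default 1
#'   is the empirical percentile.
#' @return the cutoff ratio.
#' @export
negative_control_cutoff <- function(neg_ratios, percentile = 0.95,
                                    type = 1) {
  unname(stats::quantile(neg_ratios, probs = percentile, type = type,
                         names = FALSE))
}

#' @export
print.curation_report <- function(x, ...) {
  tab <- table(x$per_sample$role, x$per_sample$passed)
  cat(sprintf("<curation report> cutoff ratio %.5g (p%g of negatives)\n",
              x$cutoff_ratio, 100 * x$percentile))
  print(tab)
  invisible(x)
}

#' Consensus analyte list
#'
#' An analyte enters the consensus list iff, within every listed biological
#' group, it passes the QC rule (after charge-state merging: `sn >=
#' qc_sn_min`, `|ppm_error| <= qc_ppm_max`, `ipq <= qc_ipq_max`) in at least
#' `presence_cutoff` of that group's curated spectra (boundary inclusive).
#' With `all_groups = FALSE` passing the cutoff in any one group suffices.
#'
#' @param extractions cohort extraction results (per charge state).
#' @param meta sample metadata.
#' @param curation a `curation_report`; only samples that passed spectral
#'   curation are counted.
#' @param candidate_ids analyte ids eligible for the list (e.g. the natural
#'   glycopeptides).
#' @param groups biological group labels to require; default the (up to) 4
#'   largest groups among curated case samples.
#' @param config a [processing_config()] providing the QC thresholds,
#'   `presence_cutoff` and `consensus_all_groups`.
#' @return sorted character vector of consensus analyte ids.
#' @export
analyte_consensus <- function(extractions, meta, curation, candidate_ids,
                              groups = NULL,
                              config = processing_config()) {
  passed_ids <- curation$per_sample$sample_id[curation$per_sample$passed]
  curated <- meta[meta$sample_id %in% passed_ids & meta$role == "case", ,
                  drop = FALSE]
  if (is.null(groups)) {
    cnt <- sort(table(curated$group), decreasing = TRUE)
    groups <- names(cnt)[seq_len(min(4L, length(cnt)))]
  }
  if (!length(groups)) stop("no biological groups to build a consensus from")
  merged <- merge_charge_states(
    extractions[extractions$analyte_id %in% candidate_ids, , drop = FALSE])
  merged$qc_pass <- merged$sn >= config$qc_sn_min &
    !is.na(merged$ppm_error) & abs(merged$ppm_error) <= config$qc_ppm_max &
    !is.na(merged$ipq) & merged$ipq <= config$qc_ipq_max

  frac <- matrix(NA_real_, nrow = length(candidate_ids),
                 ncol = length(groups),
                 dimnames = list(candidate_ids, groups))
  for (g in groups) {
    ids_g <- curated$sample_id[curated$group == g]
    if (!length(ids_g)) stop("group '", g, "' has no curated spectra")
    mg <- merged[merged$sample_id %in% ids_g, , drop = FALSE]
    for (a in candidate_ids) {
      ma <- mg[mg$analyte_id == a, , drop = FALSE]
      frac[a, g] <- if (length(ids_g))
        sum(ma$qc_pass) / length(ids_g) else 0
    }
  }
  keep <- if (isTRUE(config$consensus_all_groups)) {
    apply(frac, 1L, function(x) all(x >= config$presence_cutoff))
  } else {
    apply(frac, 1L, function(x) any(x >= config$presence_cutoff))
  }
  sort(candidate_ids[keep])
}
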