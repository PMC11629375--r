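# Synthetic LC-MS cohorts with full ground truth.
#
# The generator emulates the measured structure of the assay: per sample,
# each panel analyte contributes its truncated isotopologue cluster at each
# charge state, distributed over the scans of its retention window by a
# fixed triangular chromatographic profile, m/z-shifted by a configurable
# miscalibration model and intensity-perturbed by multiplicative lognormal
# noise; random contaminant peaks and an additive noise floor complete the
# spectra. Intensity response is linear in analyte amount with a single
# response factor shared by natural and SIL species (the core assumption of
# ratio-based quantitation).

#' Default glycoform distributions for the generator
#'
#' `sim_igg1_profile()`: mean relative abundances of the 20 default IgG1
#' glycoforms (typical plasma-IgG1-like Fc profile, dominated by G0F/G1F).
#' `sim_sil_profile()`: the narrow CHO-type distribution of the SIL
#' standard over its three quantified glycoforms. `sim_igg3_profile()`:
#' means over the six-glycoform IgG3 panel.
#'
#' @return named numeric vector summing to 1.
#' @export
sim_igg1_profile <- function() {
  p <- c(G0 = 0.035, G0F = 0.27, G0N = 0.004, G0FN = 0.045,
         G1 = 0.022, G1F = 0.30, G1N = 0.003, G1FN = 0.035,
         G2 = 0.008, G2F = 0.12, G2N = 0.002, G2FN = 0.012,
         G1S = 0.004, G1FS = 0.035, G1FNS = 0.006,
         G2S = 0.004, G2FS = 0.055, G2FNS = 0.008,
         G2S2 = 0.002, G2FS2 = 0.03)
  p / sum(p)
}

#' @rdname sim_igg1_profile
#' @export
sim_sil_profile <- function() {
  c(G0 = 0.25, G0F = 0.45, G1F = 0.30)
}

#' @rdname sim_igg1_profile
#' @export
sim_igg3_profile <- function() {
  p <- c(G0F = 0.32, G1F = 0.33, G1FS = 0.08, G1FN = 0.07,
         G2F = 0.14, G2FS = 0.06)
  p / sum(p)
}

#' Simulation configuration
#'
#' @param seed RNG seed; identical seed and config give identical cohorts.
#' @param n_cases,n_negatives,n_pool_replicates cohort composition
#'   (defaults mirror a vaccination-cohort batch: cases in four biological
#'   groups, 28 antibody-deficient negative controls, 19 pooled-sample
#'   replicates).
#' @param conc_range true case concentrations are drawn log-uniformly from
#'   this range, ng/mL.
#' @param pool_conc true concentration of the sample pool, ng/mL.
#' @param profile,sil_profile,igg3_profile glycoform distributions (named,
#'   summing to 1).
#' @param profile_dispersion per-sample lognormal jitter (sdlog) applied to
#'   the glycoform means before renormalization.
#' @param spike a [spike_config()].
#' @param response_factor summed cluster intensity per ng of analyte.
#' @param charge_split fraction of a glycopeptide's signal in charge 2 vs 3.
#' @param noise_cv multiplicative intensity noise (lognormal sdlog)
#'   applied per isotopologue peak; integrating whole patterns averages
#'   part of it out, mirroring why the method integrates patterns.
#' @param noise_floor_density additive noise peaks per Th per scan.
#' @param noise_floor_mean mean intensity of noise-floor peaks
#'   (exponential).
#' @param miscal_ppm,miscal_ppm_per_th injected mass miscalibration:
#'   constant ppm offset plus a linear-in-m/z component (ppm per Th).
#' @param interference_rate expected contaminant peaks per retention
#'   window.
#' @param interference_intensity mean contaminant intensity (exponential).
#' @param negative_bg_meanlog,negative_bg_sdlog lognormal distribution of
#'   the residual natural/SIL ratio in negative controls (median
#'   `exp(meanlog)`, default 0.005 so the percentile cutoff exercise is
#'   non-degenerate).
#' @param include_igg3 also simulate (and panel) natural IgG3
#'   glycopeptides.
#' @param igg3_conc_factor IgG3 concentration as a fraction of the IgG1
#'   concentration.
#' @param n_scans_per_window scans per retention window (triangular
#'   elution profile).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_cases = 50L, n_negatives = 28L,
                       n_pool_replicates = 19L,
                       conc_range = c(100, 10000),
                       pool_conc = 5400,
                       profile = sim_igg1_profile(),
                       sil_profile = sim_sil_profile(),
                       igg3_profile = sim_igg3_profile(),
                       profile_dispersion = 0.1,
                       spike = spike_config(),
                       response_factor = 5e4,
                       charge_split = c(`2` = 0.6, `3` = 0.4),
                       noise_cv = 0.05,
                       noise_floor_density = 1,
                       noise_floor_mean = 30,
                       miscal_ppm = 8,
                       miscal_ppm_per_th = 0,
                       interference_rate = 5,
                       interference_intensity = 500,
                       negative_bg_meanlog = log(0.005),
                       negative_bg_sdlog = 0.5,
                       include_igg3 = FALSE,
                       igg3_conc_factor = 0.1,
                       n_scans_per_window = 10L) {
  stopifnot(abs(sum(profile) - 1) < 1e-6,
            conc_range[1] > 0, conc_range[1] < conc_range[2],
            noise_cv >= 0, noise_floor_density >= 0,
            interference_rate >= 0, n_scans_per_window >= 1)
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  cfg
}

# Triangular elution weights over n scans, normalized to sum 1.
.elution_weights <- function(n) {
  w <- pmin(seq_len(n), rev(seq_len(n)))
  w / sum(w)
}

# Apply the miscalibration model to theoretical m/z.
.miscalibrate <- function(mz, config) {
  mz * (1 + (config$miscal_ppm + config$miscal_ppm_per_th * mz) * 1e-6)
}

# Amount (ng) of each panel analyte for one sample truth record.
.analyte_amounts <- function(panel, truth, config) {
  vol <- config$spike$plasma_volume_ml
  amt <- numeric(nrow(panel))
  for (i in seq_len(nrow(panel))) {
    id <- panel$analyte_id[i]
    g <- panel$glycan[i]
    if (panel$label[i] == "SIL") {
      amt[i] <- if (nzchar(g))
        config$spike$sil_mass_ng * config$sil_profile[[g]] else
        config$spike$sil_mass_ng
    } else if (startsWith(id, "IgG1-")) {
      amt[i] <- truth$conc * vol * truth$profile[[g]]
    } else if (startsWith(id, "IgG3-")) {
      amt[i] <- truth$conc_igg3 * vol * truth$igg3_profile[[g]]
    } else {
      amt[i] <- truth$conc * vol   # proteotypic peptides track the protein
    }
  }
  amt
}

#' Simulate the scans of one sample
#'
#' @param truth list with `conc` (ng/mL), `profile` (named over the IgG1
#'   panel), and when IgG3 is simulated `conc_igg3`, `igg3_profile`.
#' @param panel analyte panel (default-panel id conventions).
#' @param config a [sim_config()]. Uses the current RNG state; seed
#'   upstream for reproducibility.
#' @return list of scans (see [scan()]).
#' @export
simulate_sample <- function(truth, panel, config = sim_config()) {
  amounts <- .analyte_amounts(panel, truth, config)
  w <- .elution_weights(config$n_scans_per_window)
  wkey <- paste(panel$rt_start_s, panel$rt_end_s)
  scans <- list()
  for (key in unique(wkey)) {
    idx <- which(wkey == key)
    rt0 <- panel$rt_start_s[idx[1]]; rt1 <- panel$rt_end_s[idx[1]]
    times <- seq(rt0, rt1, length.out = config$n_scans_per_window + 2L)
    times <- times[2:(config$n_scans_per_window + 1L)]
    # m/z extent of this window's analytes, padded for noise estimation
    mono <- unlist(lapply(idx, function(i) {
      vapply(panel_charges(panel$charges[i]), function(z)
        analyte_mz(panel$sequence[i], z, panel$label[i],
                   if (nzchar(panel$glycan[i])) panel$glycan[i] else NULL),
        numeric(1))
    }))
    mz_lo <- min(mono) - 15; mz_hi <- max(mono) + 15

    per_scan_mz <- vector("list", config$n_scans_per_window)
    per_scan_int <- vector("list", config$n_scans_per_window)
    add_cluster <- function(mz, intensity_total_per_iso) {
      for (s in seq_along(w)) {
        per_scan_mz[[s]] <<- c(per_scan_mz[[s]], mz)
        per_scan_int[[s]] <<- c(per_scan_int[[s]],
                                intensity_total_per_iso * w[s])
      }
    }
    for (i in idx) {
      if (amounts[i] <= 0) next
      is_glyco <- nzchar(panel$glycan[i])
      pat <- .cached_pattern(panel$sequence[i], panel$label[i],
                             if (is_glyco) panel$glycan[i] else NULL,
                             0.99999)
      for (z in panel_charges(panel$charges[i])) {
        split <- if (is_glyco)
          config$charge_split[[as.character(z)]] else 1
        cluster <- amounts[i] * config$response_factor * split
        iso <- cluster * pat$rel_abundance
        if (config$noise_cv > 0) {
          # multiplicative noise per observable isotopologue peak
          iso <- iso * exp(stats::rnorm(length(iso), 0, config$noise_cv))
        }
        mz <- .miscalibrate((pat$exact_mass + z * PROTON_MASS) / z, config)
        add_cluster(mz, iso)
      }
    }
    # contaminant peaks (chimeric interferences), eluting like analytes
    n_cont <- stats::rpois(1, config$interference_rate)
    if (n_cont > 0) {
      add_cluster(stats::runif(n_cont, mz_lo, mz_hi),
                  stats::rexp(n_cont, 1 / config$interference_intensity))
    }
    for (s in seq_along(times)) {
      mzs <- per_scan_mz[[s]]; ints <- per_scan_int[[s]]
      if (config$noise_floor_density > 0) {
        n_noise <- stats::rpois(1, config$noise_floor_density *
                                  (mz_hi - mz_lo))
        if (n_noise > 0) {
          mzs <- c(mzs, stats::runif(n_noise, mz_lo, mz_hi))
          ints <- c(ints, stats::rexp(n_noise, 1 / config$noise_floor_mean))
        }
      }
      if (length(mzs) == 0L) { mzs <- numeric(0); ints <- numeric(0) }
      scans[[length(scans) + 1L]] <- scan(times[s], mzs, ints)
    }
  }
  scans[order(vapply(scans, `[[`, numeric(1), "rt"))]
}

#' Simulate a full cohort with ground truth
#'
#' Draws per-sample truths (concentrations, glycoform profiles,
#' negative-control background ratios), simulates every sample and
#' optionally writes one spectrum file per sample plus metadata and truth
#' tables.
#'
#' @param config a [sim_config()].
#' @param dir output directory; `NULL` keeps scans in memory.
#' @param format `"tsv"` (peak-list dialect) or `"mzxml"`.
#' @return list with `panel`, `metadata`, `truth` (data.frame `sample_id`,
#'   `role`, `group`, `batch`, `true_conc`, `bg_ratio`, one
#'   `profile_<glycoform>` column per glycoform), `scans` (named list,
#'   `NULL` when written to disk) and `files` (named paths, `NULL` when in
#'   memory).
#' @export
simulate_cohort <- function(config = sim_config(), dir = NULL,
                            format = c("tsv", "mzxml")) {
  format <- match.arg(format)
  set.seed(config$seed)
  panel <- default_panel(include_igg3 = config$include_igg3)

  ids <- c(sprintf("S%03d", seq_len(config$n_cases)),
           sprintf("NEG%03d", seq_len(config$n_negatives)),
           sprintf("POOL%02d", seq_len(config$n_pool_replicates)))
  roles <- rep(c("case", "negative_control", "pool_replicate"),
               c(config$n_cases, config$n_negatives,
                 config$n_pool_replicates))
  groups <- character(length(ids))
  groups[roles == "case"] <- rep(c("groupA", "groupB", "groupC", "groupD"),
                                 length.out = config$n_cases)
  groups[roles == "pool_replicate"] <- "pool"
  batches <- paste0("batch", 1L + (seq_along(ids) %% 2L))
  meta <- data.frame(sample_id = ids, role = roles, group = groups,
                     batch = batches, stringsAsFactors = FALSE)

  # shared pool truth: one draw for all replicates
  pool_profile <- .jitter_profile(config$profile, config$profile_dispersion)
  vol <- config$spike$plasma_volume_ml
  truths <- list(); all_scans <- list(); files <- character(0)
  if (!is.null(dir)) dir.create(dir, showWarnings = FALSE, recursive = TRUE)

  for (j in seq_along(ids)) {
    role <- roles[j]
    if (role == "case") {
      conc <- exp(stats::runif(1, log(config$conc_range[1]),
                               log(config$conc_range[2])))
      prof <- .jitter_profile(config$profile, config$profile_dispersion)
      bg <- NA_real_
    } else if (role == "negative_control") {
      bg <- stats::rlnorm(1, config$negative_bg_meanlog,
                          config$negative_bg_sdlog)
      conc <- bg * config$spike$sil_mass_ng / vol
      prof <- .jitter_profile(config$profile, config$profile_dispersion)
    } else {
      conc <- config$pool_conc
      prof <- pool_profile
      bg <- NA_real_
    }
    truth <- list(conc = conc, profile = prof,
                  conc_igg3 = conc * config$igg3_conc_factor,
                  igg3_profile = config$igg3_profile)
    scans <- simulate_sample(truth, panel, config)
    rec <- data.frame(sample_id = ids[j], role = role, group = groups[j],
                      batch = batches[j], true_conc = conc, bg_ratio = bg)
    for (g in names(prof)) rec[[paste0("profile_", g)]] <- prof[[g]]
    truths[[j]] <- rec
    if (is.null(dir)) {
      all_scans[[ids[j]]] <- scans
    } else {
      path <- file.path(dir, paste0(ids[j],
                                    if (format == "tsv") ".tsv" else
                                      ".mzXML"))
      if (format == "tsv") write_peaklist_tsv(scans, path) else
        write_mzxml(scans, path)
      files[ids[j]] <- path
    }
  }
  truth <- do.call(rbind, truths)
  if (!is.null(dir)) {
    write_result_table(meta, file.path(dir, "metadata.tsv"),
                       schema = "sample-metadata")
    write_result_table(truth, file.path(dir, "truth.tsv"),
                       schema = "ground-truth")
    write_analyte_panel(panel, file.path(dir, "panel.tsv"))
  }
  list(panel = panel, metadata = meta, truth = truth,
       scans = if (is.null(dir)) all_scans else NULL,
       files = if (is.null(dir)) NULL else files)
}

.jitter_profile <- function(profile, sdlog) {
  if (sdlog <= 0) return(profile)
  p <- profile * exp(stats::rnorm(length(profile), 0, sdlog))
  p / sum(p)
}

#' Write scans to an mzXML file
#'
#' Minimal mzXML 3.2 writer for synthetic data: base64-encoded network-
#' byte-order peak arrays, 32- or 64-bit, optionally zlib-compressed.
#'
#' @param scans list of scans.
#' @param path output path.
#' @param precision 32 or 64 (bits per value).
#' @param compress zlib-compress the peak arrays.
#' @export
write_mzxml <- function(scans, path, precision = 32, compress = FALSE) {
  stopifnot(precision %in% c(32, 64))
  enc <- function(peaks) {
    v <- as.vector(t(peaks))
    raw <- writeBin(v, raw(), size = precision / 8, endian = "big")
    if (compress) raw <- memCompress(raw, type = "gzip")  # zlib stream
    gsub("\n", "", jsonlite::base64_enc(raw), fixed = TRUE)
  }
  body <- vapply(seq_along(scans), function(i) {
    s <- scans[[i]]
    sprintf(paste0(
      '  <scan num="%d" msLevel="%d" peaksCount="%d" ',
      'retentionTime="PT%.6fS">\n',
      '   <peaks precision="%d" byteOrder="network" contentType="m/z-int" ',
      'compressionType="%s"%s>%s</peaks>\n  </scan>'),
      i, s$ms_level, nrow(s$peaks), s$rt, precision,
      if (compress) "zlib" else "none",
      if (compress) sprintf(' compressedLen="%d"',
                            length(memCompress(writeBin(
                              as.vector(t(s$peaks)), raw(),
                              size = precision / 8, endian = "big"),
                              type = "gzip"))) else "",
      enc(s$peaks))
  }, character(1))
  ns <- "http://sashimi.sourceforge.net/schema_revision/mzXML_3.2"
  doc <- c('<?xml version="1.0" encoding="ISO-8859-1"?>',
           sprintf(paste0('<mzXML xmlns="%s" xmlns:xsi=',
                          '"http://www.w3.org/2001/XMLSchema-instance" ',
                          'xsi:schemaLocation="%s %s/mzXML_idx_3.2.xsd">'),
                   ns, ns, ns),
           sprintf(' <msRun scanCount="%d">', length(scans)),
           body, ' </msRun>', '</mzXML>')
  writeLines(doc, path)
  invisible(path)
}
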