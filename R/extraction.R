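# Mass calibration and targeted isotopologue-cluster integration with QC
# metrics, operating on sum spectra.

#' Local background and noise estimate
#'
#' Background is the mean, and noise the standard deviation, of the
#' lowest-intensity 20% of grid peaks within `half_width` Th of `center_mz`,
#' after excluding cells inside any targeted integration window passed in
#' `exclude`. If the window holds no usable cells the background is 0 and
#' the noise falls back to the smallest positive intensity in the spectrum
#' (result flagged).
#'
#' @param spectrum a [sum_spectra()] result.
#' @param center_mz window center, Th.
#' @param half_width window half-width, Th.
#' @param exclude optional two-column matrix of (lo, hi) m/z intervals to
#'   exclude (targeted analyte windows).
#' @param quantile_frac fraction of lowest-intensity cells used.
#' @return list with `background`, `noise`, `flagged`.
#' @export
estimate_background <- function(spectrum, center_mz, half_width = 10,
                                exclude = NULL, quantile_frac = 0.2) {
  pk <- spectrum$peaks
  sel <- pk$mz >= center_mz - half_width & pk$mz <= center_mz + half_width
  if (!is.null(exclude) && nrow(exclude) && any(sel)) {
    mz <- pk$mz
    inside <- rep(FALSE, nrow(pk))
    idx <- which(sel)
    for (j in seq_len(nrow(exclude))) {
      inside[idx] <- inside[idx] |
        (mz[idx] >= exclude[j, 1] & mz[idx] <= exclude[j, 2])
    }
    sel <- sel & !inside
  }
  vals <- pk$intensity[sel]
  if (!length(vals)) {
    pos <- pk$intensity[pk$intensity > 0]
    return(list(background = 0,
                noise = if (length(pos)) min(pos) else 1,
                flagged = TRUE))
  }
  n_low <- max(1L, ceiling(length(vals) * quantile_frac))
  low <- sort(vals, partial = n_low)[seq_len(n_low)]
  noise <- stats::sd(low)
  flagged <- FALSE
  if (!is.finite(noise) || noise <= 0) {
    pos <- pk$intensity[pk$intensity > 0]
    noise <- if (length(pos)) min(pos) else 1
    flagged <- TRUE
  }
  list(background = mean(low), noise = noise, flagged = flagged)
}

# Exclusion intervals around every (analyte, charge) monoisotopic m/z in the
# panel: the isotopologue cluster spans a few Th at most, so a fixed +-3 Th
# guard keeps analyte signal out of background estimates.
.panel_exclusion_windows <- function(panel, guard_th = 3) {
  rows <- list()
  for (i in seq_len(nrow(panel))) {
    for (z in panel_charges(panel$charges[i])) {
      mz <- analyte_mz(panel$sequence[i], z, panel$label[i],
                       if (nzchar(panel$glycan[i])) panel$glycan[i] else NULL)
      rows[[length(rows) + 1L]] <- c(mz - guard_th, mz + guard_th)
    }
  }
  do.call(rbind, rows)
}

#' Fit a mass calibration model from SIL calibrant glycopeptides
#'
#' For every calibrant (analyte, charge) the most intense peak within
#' `ppm_search` ppm of the theoretical monoisotopic m/z is matched; matches
#' with S/N at or above `sn_cutoff` become calibration points (observed ppm
#' error versus theoretical m/z). The model order degrades gracefully with
#' the number of points: >= 5 quadratic, 3-4 linear, 1-2 constant ppm, 0
#' none (spectrum flagged uncalibrated).
#'
#' @param spectrum a [sum_spectra()] result.
#' @param panel analyte panel; rows with role `calibrant` or `both` are
#'   used.
#' @param config a [processing_config()].
#' @return list of class `calibration_model` with `kind`, `coefficients`,
#'   `points` (data.frame analyte_id, charge, mz_theo, mz_obs, ppm, sn)
#'   and `flagged`.
#' @export
fit_calibration <- function(spectrum, panel, config = processing_config()) {
  cal <- panel[panel$role %in% c("calibrant", "both"), , drop = FALSE]
  exclude <- if (nrow(panel)) .panel_exclusion_windows(panel) else NULL
  pts <- list()
  pk <- spectrum$peaks
  for (i in seq_len(nrow(cal))) {
    for (z in panel_charges(cal$charges[i])) {
      mz_theo <- analyte_mz(cal$sequence[i], z, cal$label[i],
                            if (nzchar(cal$glycan[i])) cal$glycan[i] else NULL)
      tol <- mz_theo * config$ppm_search * 1e-6
      sel <- which(pk$mz >= mz_theo - tol & pk$mz <= mz_theo + tol)
      if (!length(sel)) next
      hit <- sel[which.max(pk$intensity[sel])]
      bg <- estimate_background(spectrum, mz_theo,
                                half_width = config$noise_half_width_th,
                                exclude = exclude)
      sn <- (pk$intensity[hit] - bg$background) / bg$noise
      if (sn < config$calibrant_sn) next
      pts[[length(pts) + 1L]] <- data.frame(
        analyte_id = cal$analyte_id[i], charge = z,
        mz_theo = mz_theo, mz_obs = pk$mz[hit],
        ppm = (pk$mz[hit] - mz_theo) / mz_theo * 1e6, sn = sn)
    }
  }
  points <- if (length(pts)) do.call(rbind, pts) else
    data.frame(analyte_id = character(0), charge = integer(0),
               mz_theo = numeric(0), mz_obs = numeric(0),
               ppm = numeric(0), sn = numeric(0))
  n <- nrow(points)
  if (n >= 5) {
    fit <- stats::lm(ppm ~ mz_theo + I(mz_theo^2), data = points)
    model <- list(kind = "quadratic", coefficients = stats::coef(fit))
  } else if (n >= 3) {
    fit <- stats::lm(ppm ~ mz_theo, data = points)
    model <- list(kind = "linear", coefficients = c(stats::coef(fit), 0))
  } else if (n >= 1) {
    model <- list(kind = "constant_ppm",
                  coefficients = c(mean(points$ppm), 0, 0))
  } else {
    warning("no calibrant passed the S/N cutoff; spectrum left uncalibrated")
    model <- list(kind = "none", coefficients = c(0, 0, 0))
  }
  names(model$coefficients) <- c("c0", "c1", "c2")
  model$points <- points
  model$flagged <- n == 0
  class(model) <- "calibration_model"
  model
}

# Predicted ppm error at (approximately observed) m/z.
.cal_ppm <- function(model, mz) {
  co <- unname(model$coefficients)
  co[1] + co[2] * mz + co[3] * mz^2
}

#' Apply or invert a calibration model
#'
#' `apply_calibration` maps observed to corrected m/z by removing the
#' modeled ppm error; `invert_calibration` maps corrected back to observed
#' (fixed-point iteration; round trip is identity to better than 1e-9
#' relative). `kind = "none"` leaves m/z unchanged.
#'
#' @param model a `calibration_model`.
#' @param mz m/z vector.
#' @return corrected (or restored) m/z vector.
#' @export
apply_calibration <- function(model, mz) {
  if (model$kind == "none") return(mz)
  mz / (1 + .cal_ppm(model, mz) * 1e-6)
}

#' @rdname apply_calibration
#' @export
invert_calibration <- function(model, mz) {
  if (model$kind == "none") return(mz)
  obs <- mz
  for (i in 1:12) obs <- mz * (1 + .cal_ppm(model, obs) * 1e-6)
  obs
}

#' @rdname apply_calibration
#' @param spectrum a [sum_spectra()] result.
#' @return `calibrate_spectrum` returns the spectrum with corrected m/z.
#' @export
calibrate_spectrum <- function(model, spectrum) {
  if (model$kind == "none") return(spectrum)
  spectrum$peaks$mz <- apply_calibration(model, spectrum$peaks$mz)
  spectrum
}

#' Integrate one analyte's isotopologue cluster
#'
#' The isotopologue subset is the most-abundant-first prefix of the
#' theoretical pattern reaching the configured minimum fraction. For each
#' selected isotopologue the spectrum intensity within `window_th` of its
#' theoretical m/z is summed and the local background (per occupied grid
#' cell) subtracted; negative per-isotopologue areas are clipped to 0.
#' `corrected_area` divides the summed area by the integrated theoretical
#' fraction (coverage correction). Glycopeptides are integrated on the
#' calibrated spectrum; non-glycosylated peptides bypass calibration.
#'
#' QC metrics: `sn` is the apex intensity of the most abundant isotopologue
#' over the local noise; `ppm_error` the theoretical-abundance-weighted mean
#' apex deviation; `ipq` the L1 distance between observed and theoretical
#' normalized isotopologue intensities (lower is better).
#'
#' @param spectrum a [sum_spectra()] result (uncalibrated).
#' @param analyte_row one panel row.
#' @param charge charge state.
#' @param calibration a `calibration_model` (used for glycopeptides only).
#' @param config a [processing_config()].
#' @param background optional precomputed [estimate_background()] result.
#' @param exclude optional exclusion windows for background estimation.
#' @return one-row data.frame: `analyte_id`, `charge`, `raw_area`,
#'   `coverage`, `corrected_area`, `sn`, `ppm_error`, `ipq`, `calibrated`.
#' @export
integrate_analyte <- function(spectrum, analyte_row, charge,
                              calibration = NULL,
                              config = processing_config(),
                              background = NULL, exclude = NULL) {
  is_glyco <- nzchar(analyte_row$glycan)
  window_th <- if (is_glyco) config$glyco_window_th else config$pep_window_th
  min_frac <- if (is_glyco) config$glyco_min_fraction else
    config$pep_min_fraction
  use_cal <- is_glyco && !is.null(calibration) && calibration$kind != "none"
  spec <- if (use_cal) calibrate_spectrum(calibration, spectrum) else spectrum

  pat <- .cached_pattern(analyte_row$sequence, analyte_row$label,
                         if (is_glyco) analyte_row$glycan else NULL, min_frac)
  mz_theo <- (pat$exact_mass + charge * PROTON_MASS) / charge
  theo <- pat$rel_abundance
  coverage <- attr(pat, "coverage")

  if (is.null(background)) {
    background <- estimate_background(
      spec, mz_theo[which.max(theo)],
      half_width = config$noise_half_width_th, exclude = exclude)
  }

  pk <- spec$peaks
  n_iso <- length(mz_theo)
  area <- numeric(n_iso)
  apex_dev <- rep(NA_real_, n_iso)
  apex_int <- numeric(n_iso)
  if (nrow(pk)) {
    lo <- findInterval(mz_theo - window_th, pk$mz) + 1L
    hi <- findInterval(mz_theo + window_th, pk$mz)
    for (k in seq_len(n_iso)) {
      if (hi[k] < lo[k]) next
      idx <- lo[k]:hi[k]
      ints <- pk$intensity[idx]
      area[k] <- max(0, sum(ints) - background$background * length(idx))
      top <- which(ints == max(ints))
      if (length(top) > 1L) {  # tie: smaller |delta m/z| wins
        top <- top[which.min(abs(pk$mz[idx[top]] - mz_theo[k]))]
      }
      apex_int[k] <- ints[top]
      apex_dev[k] <- (pk$mz[idx[top]] - mz_theo[k]) / mz_theo[k] * 1e6
    }
  }
  raw_area <- sum(area)
  k_top <- which.max(theo)
  sn <- if (apex_int[k_top] > 0)
    (apex_int[k_top] - background$background) / background$noise else 0
  seen <- !is.na(apex_dev)
  ppm_error <- if (any(seen))
    sum(apex_dev[seen] * theo[seen]) / sum(theo[seen]) else NA_real_
  ipq <- if (raw_area > 0)
    sum(abs(area / raw_area - theo / sum(theo))) else NA_real_

  data.frame(analyte_id = analyte_row$analyte_id, charge = as.integer(charge),
             raw_area = raw_area, coverage = coverage,
             corrected_area = raw_area / coverage,
             sn = max(0, sn), ppm_error = ppm_error, ipq = ipq,
             calibrated = use_cal)
}

#' Extract all panel analytes from one sample
#'
#' Builds one sum spectrum per distinct retention-time window in the panel,
#' fits the calibration on the window containing the calibrant analytes,
#' and integrates every (analyte, charge) pair. Results are ordered by
#' analyte id, then charge.
#'
#' @param scans list of scans (one sample).
#' @param panel analyte panel.
#' @param config a [processing_config()].
#' @param sample_id optional id prepended as a column.
#' @return data.frame of extraction results; attributes `calibration`
#'   (the fitted model) and `sample_id`.
#' @export
extract_sample <- function(scans, panel, config = processing_config(),
                           sample_id = NA_character_) {
  validate_panel(panel)
  if (!nrow(panel)) stop("empty analyte panel")
  wkey <- paste(panel$rt_start_s, panel$rt_end_s)
  spectra <- lapply(split(seq_len(nrow(panel)), wkey), function(idx) {
    sum_spectra(scans, c(panel$rt_start_s[idx[1]], panel$rt_end_s[idx[1]]),
                grid_th = config$merge_grid_th)
  })
  exclude <- .panel_exclusion_windows(panel)

  # calibrate on the window(s) holding calibrant analytes
  cal_rows <- which(panel$role %in% c("calibrant", "both"))
  calibration <- NULL
  if (length(cal_rows)) {
    cal_window <- wkey[cal_rows[1]]
    calibration <- withCallingHandlers(
      fit_calibration(spectra[[cal_window]], panel, config),
      warning = function(w) invokeRestart("muffleWarning"))
  }

  out <- list()
  for (i in seq_len(nrow(panel))) {
    spec <- spectra[[wkey[i]]]
    is_glyco <- nzchar(panel$glycan[i])
    use_cal <- is_glyco && !is.null(calibration) &&
      calibration$kind != "none"
    spec_used <- if (use_cal) calibrate_spectrum(calibration, spec) else spec
    for (z in panel_charges(panel$charges[i])) {
      min_frac <- if (is_glyco) config$glyco_min_fraction else
        config$pep_min_fraction
      pat <- .cached_pattern(panel$sequence[i], panel$label[i],
                             if (is_glyco) panel$glycan[i] else NULL, min_frac)
      center <- (pat$exact_mass[which.max(pat$rel_abundance)] +
                   z * PROTON_MASS) / z
      bg <- estimate_background(spec_used, center,
                                half_width = config$noise_half_width_th,
                                exclude = exclude)
      out[[length(out) + 1L]] <- integrate_analyte(
        spec, panel[i, , drop = FALSE], z, calibration, config,
        background = bg, exclude = exclude)
    }
  }
  res <- do.call(rbind, out)
  res <- res[order(res$analyte_id, res$charge), , drop = FALSE]
  rownames(res) <- NULL
  res <- cbind(sample_id = sample_id, res)
  attr(res, "calibration") <- calibration
  res
}

#' Merge extraction results across charge states
#'
#' Sums areas over charge states per (sample, analyte); `sn` is the maximum
#' over charges, `ppm_error` and `ipq` are corrected-area-weighted means.
#'
#' @param extractions extraction data.frame (possibly several samples).
#' @return merged data.frame, one row per (sample_id, analyte_id).
#' @export
merge_charge_states <- function(extractions) {
  key <- interaction(extractions$sample_id, extractions$analyte_id,
                     drop = TRUE, lex.order = TRUE)
  merged <- lapply(split(extractions, key), function(d) {
    w <- d$corrected_area
    wt <- if (sum(w) > 0) w / sum(w) else rep(1 / nrow(d), nrow(d))
    data.frame(sample_id = d$sample_id[1], analyte_id = d$analyte_id[1],
               raw_area = sum(d$raw_area),
               corrected_area = sum(d$corrected_area),
               sn = max(d$sn),
               ppm_error = if (all(is.na(d$ppm_error))) NA_real_ else
                 sum(wt * d$ppm_error, na.rm = TRUE),
               ipq = if (all(is.na(d$ipq))) NA_real_ else
                 sum(wt * d$ipq, na.rm = TRUE))
  })
  out <- do.call(rbind, merged)
  rownames(out) <- NULL
  out
}
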