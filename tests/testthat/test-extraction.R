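# Background estimation, mass calibration and targeted integration.

# A bare sum spectrum built directly from synthetic peak tables.
flat_noise_spectrum <- function(seed = 1, n = 2000, lo = 800, hi = 840) {
  set.seed(seed)
  scans <- list(scan(10, sort(runif(n, lo, hi)), rexp(n, 1 / 40)))
  sum_spectra(scans, c(9, 11))
}

test_that("background matches the bottom-quintile statistics directly", {
  spec <- flat_noise_spectrum()
  bg <- estimate_background(spec, 820, half_width = 10)
  vals <- spec$peaks$intensity[spec$peaks$mz >= 810 & spec$peaks$mz <= 830]
  low <- sort(vals)[seq_len(ceiling(length(vals) * 0.2))]
  expect_equal(bg$background, mean(low))
  expect_equal(bg$noise, sd(low))
  expect_gt(bg$noise, 0)
  expect_false(bg$flagged)
})

test_that("off-peak background is zero in a noiseless spectrum", {
  spec <- sum_spectra(list(scan(10, c(900.0, 900.5), c(1000, 500))),
                      c(9, 11))
  bg <- estimate_background(spec, 1200, half_width = 10)
  expect_equal(bg$background, 0)
  expect_true(bg$flagged)
  expect_equal(bg$noise, 500)  # smallest positive intensity fallback
})

test_that("targeted windows are excluded from background cells", {
  spec <- flat_noise_spectrum()
  # a huge cluster dominating the window
  spec$peaks <- rbind(spec$peaks,
                      data.frame(mz = c(819.9, 820.1), intensity = 1e7))
  spec$peaks <- spec$peaks[order(spec$peaks$mz), ]
  with_excl <- estimate_background(spec, 820, half_width = 10,
                                   exclude = rbind(c(817, 823)))
  no_excl <- estimate_background(flat_noise_spectrum(), 820,
                                 half_width = 10)
  expect_equal(with_excl$background, no_excl$background, tolerance = 0.15)
})

test_that("injected calibration drifts are recovered below 1 ppm residual", {
  pc <- processing_config()
  for (drift in list(c(10, 0), c(-20, 0), c(20, 0), c(5, 0.004))) {
    cfg <- sim_config(seed = 11, n_cases = 1, n_negatives = 3,
                      n_pool_replicates = 0, noise_cv = 0.02,
                      miscal_ppm = drift[1], miscal_ppm_per_th = drift[2])
    co <- simulate_cohort(cfg)
    spec <- sum_spectra(co$scans[["S001"]], c(48, 62))
    model <- fit_calibration(spec, co$panel, pc)
    expect_gte(nrow(model$points), 5)
    expect_identical(model$kind, "quadratic")
    if (drift[2] == 0) {
      expect_equal(mean(model$points$ppm), drift[1], tolerance = 0.5)
    }
    # residuals at calibrant positions after correction
    cal <- calibrate_spectrum(model, spec)
    resid <- vapply(seq_len(nrow(model$points)), function(i) {
      theo <- model$points$mz_theo[i]
      sel <- which(abs(cal$peaks$mz - theo) < theo * 5e-6)
      j <- sel[which.max(cal$peaks$intensity[sel])]
      (cal$peaks$mz[j] - theo) / theo * 1e6
    }, numeric(1))
    expect_lt(max(abs(resid)), 1)
  }
})

test_that("a perfectly calibrated spectrum yields a near-identity model", {
  cfg <- noiseless_config(seed = 5, n_cases = 1)
  co <- cached_cohort("noiseless_io", cfg)
  spec <- sum_spectra(co$scans[["S001"]], c(48, 62))
  model <- fit_calibration(spec, co$panel)
  expect_lt(max(abs(model$points$ppm)), 0.1)
  mz <- seq(830, 1410, by = 10)
  expect_lt(max(abs(apply_calibration(model, mz) / mz - 1)) * 1e6, 0.1)
})

test_that("calibration degrades to none and flags when all calibrants are dim", {
  # spectrum holds only noise, away from every calibrant m/z
  spec <- flat_noise_spectrum(lo = 900, hi = 920)
  panel <- default_panel()
  expect_warning(model <- fit_calibration(spec, panel), "uncalibrated")
  expect_identical(model$kind, "none")
  expect_true(model$flagged)
  expect_equal(apply_calibration(model, 1000), 1000)
})

test_that("calibration apply/invert round trip is identity", {
  model <- structure(list(kind = "quadratic",
                          coefficients = c(c0 = 12, c1 = -0.004,
                                           c2 = 1.5e-6)),
                     class = "calibration_model")
  mz <- seq(500, 1500, by = 13)
  expect_lt(max(abs(invert_calibration(model,
                                       apply_calibration(model, mz)) /
                      mz - 1)), 1e-9)
})

test_that("coverage-corrected integration is unbiased on noiseless clusters", {
  # single analyte cluster of known total intensity, no noise
  pat <- isotopologue_pattern(
    analyte_composition("EEQYNSTYR", "natural", "G0F"), 0.99999)
  total <- 1000
  mz <- (pat$exact_mass + 2 * PROTON_MASS) / 2
  spec <- sum_spectra(list(scan(10, mz, total * pat$rel_abundance)),
                      c(9, 11))
  panel <- default_panel()
  row <- panel[panel$analyte_id == "IgG1-G0F", ]
  for (frac in c(0.8, 0.9, 0.95, 1.0)) {
    pc <- processing_config(glyco_min_fraction = frac)
    res <- integrate_analyte(spec, row, 2, calibration = NULL, config = pc)
    expect_equal(res$corrected_area, total, tolerance = 5e-3)
    expect_gte(res$coverage, min(frac, 0.99999))
    expect_gte(res$corrected_area, res$raw_area)
  }
})

test_that("empty spectra integrate to zero without error", {
  spec <- sum_spectra(list(scan(10, 100.0, 1)), c(9, 11))
  panel <- default_panel()
  res <- integrate_analyte(spec, panel[panel$analyte_id == "IgG1-G0F", ], 2)
  expect_equal(res$raw_area, 0)
  expect_equal(res$corrected_area, 0)
  expect_equal(res$sn, 0)
})

test_that("ipq is small for clean clusters and grows under distortion", {
  pat <- isotopologue_pattern(
    analyte_composition("EEQYNSTYR", "natural", "G0F"), 0.99999)
  mz <- (pat$exact_mass + 2 * PROTON_MASS) / 2
  panel <- default_panel()
  row <- panel[panel$analyte_id == "IgG1-G0F", ]
  zero_bg <- list(background = 0, noise = 1, flagged = FALSE)
  clean <- sum_spectra(list(scan(10, mz, 1000 * pat$rel_abundance)),
                       c(9, 11))
  res_clean <- integrate_analyte(clean, row, 2, background = zero_bg)
  expect_lt(res_clean$ipq, 0.02)
  # hand-computed L1 deviation when isotopologue 2 is doubled
  distorted_int <- 1000 * pat$rel_abundance
  distorted_int[2] <- 2 * distorted_int[2]
  distorted <- sum_spectra(list(scan(10, mz, distorted_int)), c(9, 11))
  res_dist <- integrate_analyte(distorted, row, 2, background = zero_bg)
  pat95 <- isotopologue_pattern(
    analyte_composition("EEQYNSTYR", "natural", "G0F"), 0.95)
  obs <- 1000 * pat95$rel_abundance
  obs[2] <- 2 * obs[2]
  expected_ipq <- sum(abs(obs / sum(obs) -
                            pat95$rel_abundance /
                            sum(pat95$rel_abundance)))
  expect_equal(res_dist$ipq, expected_ipq, tolerance = 1e-6)
  expect_gt(res_dist$ipq, res_clean$ipq)
})

test_that("integration is additive in generated intensity", {
  pat <- isotopologue_pattern(
    analyte_composition("EEQYNSTYR", "natural", "G0F"), 0.99999)
  mz <- (pat$exact_mass + 2 * PROTON_MASS) / 2
  panel <- default_panel()
  row <- panel[panel$analyte_id == "IgG1-G0F", ]
  r1 <- integrate_analyte(
    sum_spectra(list(scan(10, mz, 500 * pat$rel_abundance)), c(9, 11)),
    row, 2)
  r2 <- integrate_analyte(
    sum_spectra(list(scan(10, mz, 1000 * pat$rel_abundance)), c(9, 11)),
    row, 2)
  expect_equal(r2$raw_area, 2 * r1$raw_area, tolerance = 1e-6)
})

test_that("non-glyco peptides bypass calibration even when a model exists", {
  model <- structure(list(kind = "constant_ppm",
                          coefficients = c(c0 = 100, c1 = 0, c2 = 0)),
                     class = "calibration_model")
  panel <- default_panel()
  row <- panel[panel$analyte_id == "GPS", ]
  pat <- isotopologue_pattern(peptide_composition("GPSVFPLAPSSK"), 0.99999)
  mz <- (pat$exact_mass + 2 * PROTON_MASS) / 2
  spec <- sum_spectra(list(scan(107, mz, 1000 * pat$rel_abundance)),
                      c(100, 114))
  res <- integrate_analyte(spec, row, 2, calibration = model)
  expect_false(res$calibrated)
  expect_equal(res$corrected_area, 1000, tolerance = 5e-3)
})

test_that("extract_sample is complete, ordered and order-invariant", {
  cfg <- noiseless_config(seed = 5, n_cases = 1)
  co <- cached_cohort("noiseless_io", cfg)
  pc <- processing_config()
  res <- extract_sample(co$scans[["S001"]], co$panel, pc, "S001")
  n_expected <- sum(vapply(co$panel$charges,
                           function(ch) length(panel_charges(ch)),
                           integer(1)))
  expect_equal(nrow(res), n_expected)
  expect_false(is.unsorted(res$analyte_id))
  perm <- co$panel[rev(seq_len(nrow(co$panel))), ]
  res2 <- extract_sample(co$scans[["S001"]], perm, pc, "S001")
  expect_equal(res, res2, ignore_attr = TRUE)
  # all truly present analytes exceed the calibrant S/N at this signal level
  present <- res$analyte_id %in%
    co$panel$analyte_id[co$panel$label == "SIL"]
  expect_true(all(res$sn[present] > 9))
})

test_that("heavy and light clusters of one glycoform never share windows", {
  # the separation property: the SIL-fucosylated cluster sits between the
  # natural fucosylated and afucosylated (one-more-hexose) clusters
  pc <- processing_config()
  windows <- function(seq, label, glycan, z) {
    pat <- isotopologue_pattern(analyte_composition(seq, label, glycan),
                                pc$glyco_min_fraction)
    mz <- (pat$exact_mass + z * PROTON_MASS) / z
    cbind(mz - pc$glyco_window_th, mz + pc$glyco_window_th)
  }
  overlap <- function(a, b) {
    any(outer(a[, 1], b[, 2], `<=`) & outer(a[, 2], b[, 1], `>=`))
  }
  for (z in c(2, 3)) {
    for (pair in list(c("G0F", "G0"), c("G1F", "G1"), c("G1F", "G2"))) {
      nat_f <- windows("EEQYNSTYR", "natural", pair[1], z)
      sil_f <- windows("EEQYNSTYR", "SIL", pair[1], z)
      nat_a <- windows("EEQYNSTYR", "natural", pair[2], z)
      expect_false(overlap(nat_f, sil_f))
      expect_false(overlap(sil_f, nat_a))
      expect_false(overlap(nat_f, nat_a))
    }
  }
})

test_that("charge-state merging aggregates areas and QC sensibly", {
  extr <- data.frame(
    sample_id = "S1", analyte_id = rep("A", 2), charge = c(2L, 3L),
    raw_area = c(90, 30), coverage = c(0.96, 0.96),
    corrected_area = c(100, 50), sn = c(40, 12),
    ppm_error = c(2, 5), ipq = c(0.02, 0.08), calibrated = TRUE)
  m <- merge_charge_states(extr)
  expect_equal(nrow(m), 1L)
  expect_equal(m$corrected_area, 150)
  expect_equal(m$sn, 40)
  expect_equal(m$ppm_error, (2 * 100 + 5 * 50) / 150)
  expect_equal(m$ipq, (0.02 * 100 + 0.08 * 50) / 150)
})
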