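# Independent oracles and small shared fixtures.

# Brute-force isotopologue distribution by exhaustive enumeration over
# heavy-isotope counts (binomial / multinomial per element), pruned at
# negligible probability. Independent of the convolution implementation.
enumerate_pattern <- function(comp, prune = 1e-13) {
  counts <- unclass(comp)
  iso_abund <- list(
    C = c(0.9893, 0.0107), H = c(0.999885, 0.000115),
    N = c(0.99636, 0.00364), O = c(0.99757, 0.00038, 0.00205),
    S = c(0.9499, 0.0075, 0.0425, 0.0001))
  iso_mass <- list(
    C = c(12.0, 13.0033548378), H = c(1.00782503207, 2.0141017778),
    N = c(14.0030740048, 15.0001088982),
    O = c(15.9949146196, 16.9991317, 17.9991610),
    S = c(31.97207100, 32.97145876, 33.96786690, 35.96708076))
  iso_offset <- list(C = 0:1, H = 0:1, N = 0:1, O = 0:2, S = c(0:2, 4))

  # per element: data.frame(offset, p, m) over heavy-isotope count vectors
  element_states <- function(el, n) {
    if (n == 0) return(data.frame(offset = 0L, p = 1, m = 0))
    ab <- iso_abund[[el]]; ms <- iso_mass[[el]]; off <- iso_offset[[el]]
    kmax <- vapply(ab[-1], function(a)
      min(n, stats::qbinom(1 - prune, n, a) + 2L), numeric(1))
    grids <- do.call(expand.grid, lapply(kmax, function(k) 0:k))
    keep <- rowSums(grids) <= n
    grids <- grids[keep, , drop = FALSE]
    out <- lapply(seq_len(nrow(grids)), function(r) {
      ks <- as.integer(grids[r, ])
      x <- c(n - sum(ks), ks)
      p <- stats::dmultinom(x, prob = ab)
      if (p < prune) return(NULL)
      data.frame(offset = sum(x * off), p = p, m = sum(x * ms))
    })
    do.call(rbind, out)
  }
  acc <- data.frame(offset = 0L, p = 1, m = 0)
  for (el in c("C", "H", "N", "O", "S")) {
    n <- counts[[el]]
    st <- element_states(el, n)
    cross <- merge(acc, st, by = NULL, suffixes = c("", ".el"))
    cross$offset <- cross$offset + cross$offset.el
    cross$pp <- cross$p * cross$p.el
    cross$mm <- cross$m + cross$m.el
    cross <- cross[cross$pp >= prune * 1e-3, , drop = FALSE]
    p <- tapply(cross$pp, cross$offset, sum)
    pm <- tapply(cross$pp * cross$mm, cross$offset, sum)
    acc <- data.frame(offset = as.integer(names(p)), p = as.numeric(p),
                      m = as.numeric(pm / p))
  }
  # label pseudo-elements: pure isotopes, offset 0, add mass only
  acc$m <- acc$m + counts[["C13"]] * 13.0033548378 +
    counts[["N15"]] * 15.0001088982
  acc[order(acc$offset), ]
}

# Small in-memory cohorts, memoized across tests within a run.
.cohort_cache <- new.env(parent = emptyenv())

cached_cohort <- function(tag, config) {
  co <- .cohort_cache[[tag]]
  if (is.null(co)) {
    co <- simulate_cohort(config)
    assign(tag, co, envir = .cohort_cache)
  }
  co
}

extract_cohort <- function(cohort, config = processing_config()) {
  do.call(rbind, c(lapply(names(cohort$scans), function(sid)
    extract_sample(cohort$scans[[sid]], cohort$panel, config,
                   sample_id = sid)),
    list(make.row.names = FALSE)))
}

nat_ids_of <- function(panel) {
  panel$analyte_id[panel$label == "natural" & nzchar(panel$glycan) &
                     startsWith(panel$analyte_id, "IgG1-")]
}

sil_ids_of <- function(panel) {
  panel$analyte_id[panel$label == "SIL" & nzchar(panel$glycan)]
}

noiseless_config <- function(seed = 3, n_cases = 3, n_pool_replicates = 0,
                             ...) {
  sim_config(seed = seed, n_cases = n_cases, n_negatives = 3,
             n_pool_replicates = n_pool_replicates, noise_cv = 0,
             noise_floor_density = 0, miscal_ppm = 0,
             interference_rate = 0, profile_dispersion = 0, ...)
}
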