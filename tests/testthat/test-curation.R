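# Negative-control spectral curation and consensus analyte selection.

# Minimal synthetic extraction table: one natural and one SIL analyte per
# sample, areas set directly.
ratio_extractions <- function(nat, sil, ids = names(nat)) {
  do.call(rbind, lapply(seq_along(ids), function(i) {
    data.frame(sample_id = ids[i],
               analyte_id = c("IgG1-G0F", "IgG1-G0F-SIL"),
               charge = 2L, raw_area = c(nat[i], sil[i]),
               coverage = 1, corrected_area = c(nat[i], sil[i]),
               sn = 50, ppm_error = 0, ipq = 0.01, calibrated = TRUE)
  }))
}

meta_for <- function(ids, roles, groups = "") {
  data.frame(sample_id = ids, role = roles,
             group = rep(groups, length.out = length(ids)),
             batch = "b1", stringsAsFactors = FALSE)
}

test_that("the cutoff is the empirical 95th percentile of negative ratios", {
  set.seed(101)
  neg_ratio <- rlnorm(28, log(0.005), 0.5)
  ids <- sprintf("N%02d", 1:28)
  extr <- ratio_extractions(nat = neg_ratio * 100, sil = rep(100, 28), ids)
  meta <- meta_for(ids, "negative_control")
  # need >= 3 negatives plus some case to curate
  extr <- rbind(extr, ratio_extractions(nat = 500, sil = 100, "C01"))
  meta <- rbind(meta, meta_for("C01", "case", "g1"))
  rep <- spectral_curation(extr, meta, "IgG1-G0F", "IgG1-G0F-SIL")
  # sort-based oracle: smallest order statistic covering 95% of negatives
  s <- sort(neg_ratio)
  oracle <- s[ceiling(0.95 * 28)]
  expect_equal(rep$cutoff_ratio, oracle, tolerance = 1e-12)
  expect_equal(rep$cutoff_ratio,
               negative_control_cutoff(neg_ratio), tolerance = 1e-12)
})

test_that("high cases pass, negatives fail, by the ratio cutoff", {
  set.seed(7)
  n_neg <- 28
  neg_ratio <- rlnorm(n_neg, log(0.005), 0.5)
  case_ratio <- neg_ratio[1:10] * 100  # 100x background
  ids <- c(sprintf("N%02d", 1:n_neg), sprintf("C%02d", 1:10))
  extr <- ratio_extractions(nat = c(neg_ratio, case_ratio) * 1000,
                            sil = rep(1000, n_neg + 10), ids)
  meta <- meta_for(ids, rep(c("negative_control", "case"), c(n_neg, 10)),
                   "g1")
  rep <- spectral_curation(extr, meta, "IgG1-G0F", "IgG1-G0F-SIL")
  ps <- rep$per_sample
  expect_true(all(!ps$passed[ps$role == "negative_control"]))
  expect_true(all(ps$passed[ps$role == "case"]))
})

test_that("identical ratios all fail under the <= boundary rule", {
  ids <- c(sprintf("N%d", 1:3), "C1")
  extr <- ratio_extractions(nat = rep(50, 4), sil = rep(100, 4), ids)
  meta <- meta_for(ids, c(rep("negative_control", 3), "case"), "g1")
  rep <- spectral_curation(extr, meta, "IgG1-G0F", "IgG1-G0F-SIL")
  expect_equal(rep$cutoff_ratio, 0.5)
  expect_false(any(rep$per_sample$passed))
})

test_that("fewer than 3 negative controls is an error", {
  ids <- c("N1", "N2", "C1")
  extr <- ratio_extractions(nat = c(1, 1, 100), sil = rep(100, 3), ids)
  meta <- meta_for(ids, c("negative_control", "negative_control", "case"))
  expect_error(spectral_curation(extr, meta, "IgG1-G0F", "IgG1-G0F-SIL"),
               "at least 3")
})

test_that("a sample without standard signal fails as standard absent", {
  ids <- c(sprintf("N%d", 1:3), "C1")
  extr <- ratio_extractions(nat = c(1, 2, 3, 500), sil = c(100, 100, 100, 0),
                            ids)
  meta <- meta_for(ids, c(rep("negative_control", 3), "case"), "g1")
  rep <- spectral_curation(extr, meta, "IgG1-G0F", "IgG1-G0F-SIL")
  c1 <- rep$per_sample[rep$per_sample$sample_id == "C1", ]
  expect_false(c1$passed)
  expect_identical(c1$reason, "standard absent")
})

test_that("curation is invariant to per-sample intensity scaling", {
  set.seed(13)
  ids <- c(sprintf("N%d", 1:5), "C1", "C2")
  nat <- c(rlnorm(5, log(1), 0.3), 400, 700)
  sil <- rep(100, 7)
  meta <- meta_for(ids, c(rep("negative_control", 5), "case", "case"), "g1")
  r1 <- spectral_curation(ratio_extractions(nat, sil, ids), meta,
                          "IgG1-G0F", "IgG1-G0F-SIL")
  scale <- c(1, 5, 0.2, 10, 1, 3, 0.5)
  r2 <- spectral_curation(ratio_extractions(nat * scale, sil * scale, ids),
                          meta, "IgG1-G0F", "IgG1-G0F-SIL")
  expect_equal(r1$per_sample$passed, r2$per_sample$passed)
  expect_equal(r1$cutoff_ratio, r2$cutoff_ratio, tolerance = 1e-12)
})

# ---- consensus -------------------------------------------------------------

consensus_fixture <- function(pass_by_group) {
  # pass_by_group: list group -> logical vector over samples of that group
  # (TRUE = analyte "A" passes QC in that sample). Analyte "B" always
  # passes; both are candidates.
  extr <- list(); meta <- list(); k <- 0
  for (g in names(pass_by_group)) {
    for (ok in pass_by_group[[g]]) {
      k <- k + 1
      sid <- sprintf("S%03d", k)
      extr[[length(extr) + 1L]] <- data.frame(
        sample_id = sid, analyte_id = c("A", "B", "NAT", "SIL"),
        charge = 2L, raw_area = 100, coverage = 1,
        corrected_area = c(100, 100, 1000, 100),
        sn = c(if (ok) 50 else 2, 50, 50, 50),
        ppm_error = 0, ipq = 0.01, calibrated = TRUE)
      meta[[length(meta) + 1L]] <- meta_for(sid, "case", g)
    }
  }
  # three negatives with tiny natural signal
  for (i in 1:3) {
    k <- k + 1
    sid <- sprintf("S%03d", k)
    extr[[length(extr) + 1L]] <- data.frame(
      sample_id = sid, analyte_id = c("A", "B", "NAT", "SIL"),
      charge = 2L, raw_area = 1, coverage = 1,
      corrected_area = c(0, 0, 0.01 * i, 100),
      sn = 1, ppm_error = 0, ipq = 0.01, calibrated = TRUE)
    meta[[length(meta) + 1L]] <- meta_for(sid, "negative_control")
  }
  extr <- do.call(rbind, extr)
  meta <- do.call(rbind, meta)
  cur <- spectral_curation(extr, meta, "NAT", "SIL")
  list(extr = extr, meta = meta, cur = cur)
}

test_that("an analyte passing everywhere is included", {
  fx <- consensus_fixture(list(g1 = rep(TRUE, 5), g2 = rep(TRUE, 5)))
  got <- analyte_consensus(fx$extr, fx$meta, fx$cur, c("A", "B"),
                           groups = c("g1", "g2"))
  expect_identical(got, c("A", "B"))
})

test_that("failing the cutoff in a single group excludes the analyte", {
  fx <- consensus_fixture(list(g1 = c(TRUE, TRUE, FALSE, FALSE),
                               g2 = rep(TRUE, 4)))
  got <- analyte_consensus(fx$extr, fx$meta, fx$cur, c("A", "B"),
                           groups = c("g1", "g2"))
  expect_identical(got, "B")
  # any-group mode re-admits it
  relaxed <- processing_config(consensus_all_groups = FALSE)
  got2 <- analyte_consensus(fx$extr, fx$meta, fx$cur, c("A", "B"),
                            groups = c("g1", "g2"), config = relaxed)
  expect_identical(got2, c("A", "B"))
})

test_that("the 80% presence boundary is inclusive (counting oracle)", {
  # exactly 4 of 5 passing = 0.80 in each group
  fx <- consensus_fixture(list(g1 = c(rep(TRUE, 4), FALSE),
                               g2 = c(rep(TRUE, 4), FALSE)))
  got <- analyte_consensus(fx$extr, fx$meta, fx$cur, c("A", "B"),
                           groups = c("g1", "g2"))
  expect_identical(got, c("A", "B"))
  # one sample fewer passing drops below the cutoff
  fx2 <- consensus_fixture(list(g1 = c(rep(TRUE, 3), FALSE, FALSE),
                                g2 = c(rep(TRUE, 4), FALSE)))
  got2 <- analyte_consensus(fx2$extr, fx2$meta, fx2$cur, c("A", "B"),
                            groups = c("g1", "g2"))
  expect_identical(got2, "B")
})

test_that("raising the presence cutoff never adds analytes", {
  fx <- consensus_fixture(list(g1 = c(rep(TRUE, 4), FALSE),
                               g2 = rep(TRUE, 5)))
  lists <- lapply(c(0.5, 0.8, 0.9, 1.0), function(cut)
    analyte_consensus(fx$extr, fx$meta, fx$cur, c("A", "B"),
                      groups = c("g1", "g2"),
                      config = processing_config(presence_cutoff = cut)))
  for (i in seq_along(lists)[-1]) {
    expect_true(all(lists[[i]] %in% lists[[i - 1]]))
  }
})

test_that("an empty group is reported by name", {
  fx <- consensus_fixture(list(g1 = rep(TRUE, 4)))
  expect_error(analyte_consensus(fx$extr, fx$meta, fx$cur, c("A", "B"),
                                 groups = c("g1", "ghost")),
               "ghost")
})

test_that("negative pass rate stays near or below 5% by percentile math", {
  # percentile-definition property at n = 28, many replicates: drawing
  # i.i.d. continuous ratios, the expected fraction of negatives above
  # their own type-7 95th percentile is <= 5%
  set.seed(2026)
  n <- 28
  frac <- replicate(1000, {
    r <- rlnorm(n, log(0.005), 0.5)
    mean(r > negative_control_cutoff(r))
  })
  expect_lte(mean(frac), 0.05)
})
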