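# Relative glycoform abundances and derived glycosylation traits.

#' Relative glycoform profile of one sample
#'
#' Normalizes charge-state-merged corrected areas of the natural
#' glycopeptides in the consensus panel to fractions summing to 1. SIL
#' analytes must not be part of `panel_ids`; they never enter the natural
#' profile.
#'
#' @param extractions extraction results of one sample (per charge state).
#' @param panel_ids consensus natural glycopeptide analyte ids; names map
#'   analyte id to glycoform short name, otherwise the suffix after the
#'   last `-` of the analyte id is used (e.g. `"IgG1-G0F"` -> `"G0F"`).
#' @param subclass profile label, `"IgG1"` or `"IgG3"`.
#' @return data.frame of class `glyco_profile` with columns `subclass`,
#'   `glycoform`, `rel_abundance`; attribute `flagged` is `TRUE` when the
#'   panel total was zero (profile undefined, all NA).
#' @export
relative_profile <- function(extractions, panel_ids, subclass = "IgG1") {
  if (!length(panel_ids)) stop("profile panel must be non-empty")
  merged <- merge_charge_states(
    extractions[extractions$analyte_id %in% panel_ids, , drop = FALSE])
  glycoform <- if (!is.null(names(panel_ids)) && all(nzchar(names(panel_ids))))
    stats::setNames(names(panel_ids), panel_ids) else
    stats::setNames(sub(".*-", "", panel_ids), panel_ids)
  area <- stats::setNames(rep(0, length(panel_ids)), panel_ids)
  area[merged$analyte_id] <- merged$corrected_area
  total <- sum(area)
  rel <- if (total > 0) area / total else rep(NA_real_, length(area))
  out <- data.frame(subclass = subclass,
                    glycoform = unname(glycoform[panel_ids]),
                    rel_abundance = unname(rel))
  attr(out, "flagged") <- !(total > 0)
  class(out) <- c("glyco_profile", "data.frame")
  out
}

#' Derived glycosylation traits
#'
#' Antenna-normalized IgG trait convention for complex-type biantennary Fc
#' glycans:
#' * fucosylation: summed abundance of core-fucosylated forms (Fuc >= 1);
#' * bisection: summed abundance of forms with a bisecting HexNAc
#'   (HexNAc >= 5);
#' * galactosylation: abundance-weighted galactoses per antenna,
#'   `sum((hex - 3, clipped to 0..2) / 2 * abundance)`;
#' * sialylation: abundance-weighted sialic acids per antenna,
#'   `sum(min(neuac, 2) / 2 * abundance)`.
#'
#' @param profile a [relative_profile()] result (or data.frame with
#'   `glycoform`, `rel_abundance`).
#' @return named numeric vector with `fucosylation`, `galactosylation`,
#'   `sialylation`, `bisection`, each in \[0, 1\].
#' @export
derived_traits <- function(profile) {
  rel <- profile$rel_abundance
  comps <- lapply(profile$glycoform, function(g) {
    tryCatch(parse_glycan(g), error = function(e)
      stop("cannot derive traits: unparseable glycoform '", g, "'",
           call. = FALSE))
  })
  hex <- vapply(comps, `[[`, integer(1), "hex")
  hexnac <- vapply(comps, `[[`, integer(1), "hexnac")
  fuc <- vapply(comps, `[[`, integer(1), "fuc")
  neuac <- vapply(comps, `[[`, integer(1), "neuac")
  gal <- pmin(pmax(hex - 3L, 0L), 2L)
  c(fucosylation = sum(rel[fuc >= 1]),
    galactosylation = sum(gal / 2 * rel),
    sialylation = sum(pmin(neuac, 2L) / 2 * rel),
    bisection = sum(rel[hexnac >= 5]))
}

#' Profiles and traits for a whole cohort
#'
#' @param extractions cohort extraction results.
#' @param panel_ids consensus natural glycopeptide ids (see
#'   [relative_profile()]).
#' @param sample_ids samples to profile; default all in `extractions`.
#' @param subclass profile label.
#' @return list with `profiles` (long data.frame `sample_id`, `subclass`,
#'   `glycoform`, `rel_abundance`) and `traits` (long data.frame
#'   `sample_id`, `subclass`, `trait`, `value`).
#' @export
profile_cohort <- function(extractions, panel_ids, sample_ids = NULL,
                           subclass = "IgG1") {
  if (is.null(sample_ids)) sample_ids <- unique(extractions$sample_id)
  profs <- list(); traits <- list()
  for (sid in sample_ids) {
    d <- extractions[extractions$sample_id == sid, , drop = FALSE]
    p <- relative_profile(d, panel_ids, subclass)
    profs[[sid]] <- cbind(sample_id = sid, as.data.frame(p))
    if (!isTRUE(attr(p, "flagged"))) {
      tr <- derived_traits(p)
      traits[[sid]] <- data.frame(sample_id = sid, subclass = subclass,
                                  trait = names(tr), value = unname(tr))
    }
  }
  list(profiles = do.call(rbind, c(profs, list(make.row.names = FALSE))),
       traits = do.call(rbind, c(traits, list(make.row.names = FALSE))))
}
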