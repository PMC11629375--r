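# Aggregated isotopologue patterns.
#
# Patterns are aggregated by neutron-count offset above the monoisotopic
# species (nominal aggregation), not by isotope fine structure: targeted
# integration uses mass windows of several hundredths of a Th, far wider
# than fine-structure splitting, so only the aggregated peaks are
# observable. Each aggregated entry carries the abundance-weighted mean
# exact mass of its fine-structure members.

# Offset distribution of n atoms of one element, as a pair of vectors:
# p[k]  = probability of total offset k-1,
# pm[k] = sum over fine structure of probability * mass (so pm/p is the
#         abundance-weighted mean mass at that offset).
# Computed by exponentiation-by-squaring of the single-atom distribution.
.element_offset_dist <- function(symbol, n, tail_cut = 1e-15) {
  iso <- .ISOTOPES[[symbol]]
  width <- max(iso$offset) + 1L
  base <- list(p = numeric(width), pm = numeric(width))
  base$p[iso$offset + 1L] <- iso$abundance
  base$pm[iso$offset + 1L] <- iso$abundance * iso$mass
  acc <- list(p = 1, pm = 0)  # zero atoms: offset 0, mass 0
  while (n > 0L) {
    if (n %% 2L == 1L) acc <- .conv_dist(acc, base, tail_cut)
    n <- n %/% 2L
    if (n > 0L) base <- .conv_dist(base, base, tail_cut)
  }
  acc
}

# Convolution of two (p, pm) offset distributions. For the mass moment of a
# sum of independent parts, E[p*m] at offset k is
# sum_i p1[i]*pm2[k-i] + pm1[i]*p2[k-i].
.conv_dist <- function(a, b, tail_cut = 1e-15) {
  p <- .conv_vec(a$p, b$p)
  pm <- .conv_vec(a$p, b$pm) + .conv_vec(a$pm, b$p)
  keep <- which(p > tail_cut)
  if (length(keep)) {
    last <- max(keep)
    p <- p[seq_len(last)]
    pm <- pm[seq_len(last)]
  }
  list(p = p, pm = pm)
}

.conv_vec <- function(x, y) {
  k <- length(x) + length(y) - 1L
  out <- numeric(k)
  for (i in seq_along(x)) {
    if (x[i] == 0) next
    idx <- i + seq_along(y) - 1L
    out[idx] <- out[idx] + x[i] * y
  }
  out
}

#' Aggregated isotopologue pattern of an elemental composition
#'
#' Computes the isotope distribution aggregated by neutron-count offset,
#' then selects the most-abundant-first subset of entries whose theoretical
#' fractions sum to at least `min_total_fraction`, returned in offset order.
#' Abundances are the untruncated theoretical fractions (they are not
#' renormalized); their sum is the pattern coverage used for
#' coverage-corrected integration.
#'
#' @param comp an [elemental_composition()].
#' @param min_total_fraction minimal summed theoretical fraction of the
#'   returned entries, in (0, 1].
#' @return a data.frame with columns `offset` (neutrons above monoisotopic),
#'   `exact_mass` (Da, abundance-weighted mean of the offset's fine
#'   structure) and `rel_abundance`; attribute `coverage` holds the summed
#'   fraction.
#' @export
isotopologue_pattern <- function(comp, min_total_fraction = 1) {
  if (!is.numeric(min_total_fraction) || length(min_total_fraction) != 1L ||
      min_total_fraction <= 0 || min_total_fraction > 1) {
    stop("min_total_fraction must be in (0, 1]")
  }
  counts <- unclass(comp)
  if (sum(counts) == 0L) stop("empty elemental composition")
  acc <- list(p = 1, pm = 0)
  for (el in names(counts)) {
    if (counts[[el]] > 0L) {
      acc <- .conv_dist(acc, .element_offset_dist(el, counts[[el]]))
    }
  }
  p <- acc$p
  mass <- acc$pm / ifelse(p > 0, p, 1)
  offset <- seq_along(p) - 1L
  keep <- p > 1e-14
  p <- p[keep]; mass <- mass[keep]; offset <- offset[keep]

  # most-abundant-first prefix reaching the requested total fraction
  ord <- order(p, decreasing = TRUE)
  csum <- cumsum(p[ord])
  n_keep <- which(csum >= min_total_fraction)[1]
  if (is.na(n_keep)) n_keep <- length(ord)  # fraction ~1: take everything
  sel <- sort(ord[seq_len(n_keep)])

  out <- data.frame(offset = offset[sel], exact_mass = mass[sel],
                    rel_abundance = p[sel])
  attr(out, "coverage") <- sum(p[sel])
  class(out) <- c("isotopologue_pattern", "data.frame")
  out
}

# Memoised pattern lookup for repeated extraction over cohorts. Keyed by
# analyte identity and fraction; patterns are deterministic so the cache is
# transparent.
.pattern_cache <- new.env(parent = emptyenv())

.cached_pattern <- function(sequence, label, glycan, min_fraction) {
  key <- paste(sequence, label,
               if (is.null(glycan) || is.na(glycan)) "" else glycan,
               format(min_fraction, digits = 12), sep = "|")
  pat <- .pattern_cache[[key]]
  if (is.null(pat)) {
    comp <- analyte_composition(sequence, label,
                                if (!is.null(glycan) && !is.na(glycan) &&
                                    nzchar(glycan)) glycan else NULL)
    pat <- isotopologue_pattern(comp, min_fraction)
    assign(key, pat, envir = .pattern_cache)
  }
  pat
}
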