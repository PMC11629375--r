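---
title: "silglyco: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{silglyco: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(silglyco)
```

This vignette is the package's own account of the science it implements:
the measurement model, the tunable parameters and why their defaults are
what they are, what the synthetic-data generator does and does not
emulate, and the numerical and design decisions taken where the problem
left room.

## Measurement model

The assay captures antigen-specific IgG from a known plasma volume
(default 0.02 mL), spikes a fixed mass of a stable-isotope-labeled (SIL)
recombinant IgG1 (default 2 ng) into the eluate, digests with trypsin and
acquires centroided MS1 LC-MS data. Every tryptic peptide of the SIL
standard carries one labeled C-terminal residue — ¹³C₆,¹⁵N₂-Lys (+8
neutrons, exact shift `r round(sil_mass_shift("K"), 4)` Da) or
¹³C₆,¹⁵N₄-Arg (+10 neutrons, `r round(sil_mass_shift("R"), 4)` Da) — so
each natural (glyco)peptide has a heavy twin a few Th away at charge 2–3.
Natural and SIL isotopologues are chemically identical, hence equal MS
response is assumed throughout; that assumption is the entire basis of the
quantitation and is also built into the synthetic generator (one shared
response factor).

Quantitation is ratio-based. Signals are summed over charge states and
integrated isotopologues, coverage-corrected (below), then

$$\mathrm{conc} = \frac{\sum \mathrm{natural}}{\sum \mathrm{SIL}}
  \cdot \frac{m_\mathrm{SIL}}{V_\mathrm{plasma}}$$

so a unit ratio corresponds to 100 ng/mL at the default spike. The formula
is evaluated twice — over the consensus natural glycopeptide panel against
the three quantified SIL glycoforms (G0, G0F, G1F), and over the GPS
proteotypic peptide pair — and the reported concentration is the median of
the two. TTP is extracted and reported but excluded from the composite by
default: it is interference-prone, and its inclusion is a single
`spike_config(include_ttp = TRUE)` switch. LLOQ/ULOQ (defaults 100 and
10000 ng/mL) are reporting flags, never truncation.

Relative glycoform abundances are corrected areas of the natural
glycopeptides normalized to the consensus panel; SIL analytes never enter
the profile. Traits follow the antenna-normalized IgG convention:
fucosylation and bisection are presence-weighted sums (Fuc ≥ 1,
HexNAc ≥ 5), galactosylation and sialylation count residues per antenna
(`(hex − 3)/2` clipped to [0, 1], `min(neuac, 2)/2`). Hybrid or
high-mannose compositions are not part of the supported short-name set; a
profile containing one stops trait derivation with an explicit error
rather than silently distorting antenna normalization.

## Isotopologue patterns and coverage correction

Patterns are computed from elemental compositions by convolution of
per-element neutron-offset distributions (exponentiation by squaring),
aggregated by nominal neutron count. Aggregation is deliberate: the
integration windows (0.04 / 0.065 Th) are far wider than isotope
fine-structure splitting, so only aggregated peaks are observable. Each
aggregated entry carries the abundance-weighted mean exact mass of its
fine structure. Label atoms are pseudo-elements of 100% isotopic purity —
impurity modeling would be unidentifiable from the data this package
targets. The integrated subset is the most-abundant-first prefix whose
theoretical fractions reach the configured minimum (0.95 for
glycopeptides, 0.8 for peptides); dividing the integrated area by the
subset's summed fraction makes integration unbiased regardless of the
chosen minimum, which the tests verify at 0.5% on noiseless clusters.
The implementation is cross-checked against an exhaustive per-isotope
enumeration oracle to total-variation distance below 1e-9.

## Extraction parameters

| parameter | default | unit | rationale |
|---|---|---|---|
| `glyco_window_th` | 0.04 | Th | integration half-window per isotopologue (glycopeptides) |
| `glyco_min_fraction` | 0.95 | – | integrated pattern coverage (glycopeptides) |
| `pep_window_th` | 0.065 | Th | peptide integration half-window |
| `pep_min_fraction` | 0.8 | – | peptide pattern coverage |
| `calibrant_sn` | 9 | – | S/N cutoff for accepting a calibrant point |
| `ppm_search` | 30 | ppm | calibrant match window |
| `noise_half_width_th` | 10 | Th | local background/noise window |
| `merge_grid_th` | 0.002 | Th | sum-spectrum merge grid |
| `qc_sn_min`, `qc_ppm_max`, `qc_ipq_max` | 9, 20, 0.25 | – | per-analyte QC for the consensus list |
| `presence_cutoff` | 0.80 | – | consensus presence fraction per group |

The merge grid is an order of magnitude finer than the narrowest
integration window, so merging centroids cannot move signal across
integration boundaries. Retention windows are per-analyte configuration,
not auto-detected: elution times are instrument facts, and the default
windows simply match the synthetic generator.

**Background and noise.** The S/N definition behind the cutoff of 9 is not
uniquely determined by the workflow this package re-implements, so the
estimator is explicit, configurable and used identically for calibrant
screening and QC: background is the mean, and noise the standard
deviation, of the lowest-intensity 20% of grid cells within ±10 Th of the
target, after excluding ±3 Th guard intervals around every panel analyte's
monoisotopic m/z at every charge. Anyone reproducing a LaCyTools-based
study bit-exactly should expect small S/N differences. Degenerate windows
(no usable cells) return zero background with the smallest positive
intensity as noise, flagged.

**Calibration.** The three SIL glycopeptides at two charges each give up
to six calibration points (observed ppm error vs theoretical m/z, matched
as the most intense peak within ±30 ppm, S/N ≥ 9). The model order
degrades with the point count — ≥5 quadratic, 3–4 linear, 1–2 constant
ppm, 0 none-and-flagged — so a partially failed spike still calibrates as
well as its evidence allows. Corrected m/z is `mz / (1 + e(mz)·1e-6)`;
inversion uses a short fixed-point iteration (round trip identity to
1e-9 relative). Non-glycosylated peptides are always integrated
uncalibrated, even when a model exists. Negative per-isotopologue areas
after background subtraction are clipped to zero; ppm-error apex ties
break toward the smaller |Δm/z|.

## Curation

Spectral curation compares each sample's total natural/SIL ratio with the
95th percentile of that ratio among ≥3 negative controls; samples at or
below the cutoff fail (the boundary is excluded — the source protocol does
not state the boundary, and excluding it makes the all-equal degenerate
case fail closed). The percentile is the *empirical* one (smallest
observed ratio covering 95% of negatives, quantile type 1). This is a
deliberate choice: with an interpolating definition at n = 28 negatives,
the cutoff always falls between the 26th and 27th order statistics, so
exactly the top two negatives pass — a guaranteed 7.1% false-pass rate.
The empirical percentile bounds the expected false-pass rate by
`floor(0.05 n)/n` ≤ 5%, which is the design goal of the control; the
definition remains an argument of `negative_control_cutoff()`. Negative
controls themselves always fail for downstream quantitation; a sample
with zero SIL signal fails as "standard absent" (spike or digestion
failure) rather than dividing by zero.

The consensus analyte list requires an analyte to pass QC (after
charge-state merging: max S/N, area-weighted ppm and IPQ) in at least 80%
of curated spectra *in every* listed biological group — the strictest
reading; `consensus_all_groups = FALSE` switches to any-group. The
boundary is inclusive. Groups default to the four largest among curated
cases.

## The synthetic-data generator

The generator is the test harness standing in for raw clinical data, and
its defaults are the study conditions: cohorts of cases in four biological
groups, 28 antibody-deficient negative controls, 19 pooled-sample
replicates at 5.4 µg/mL; true case concentrations log-uniform over
100–10000 ng/mL; 2 ng SIL spike against 0.02 mL plasma; 5% multiplicative
intensity noise; constant miscalibration of 8 ppm (injectable up to ±20
ppm, with an optional linear-in-m/z component); sporadic contaminant
peaks; an exponential noise floor; and negative-control natural/SIL
background ratios log-normal with median 0.005, so the percentile-cutoff
exercise is non-degenerate.

Multiplicative noise is applied per *isotopologue peak* — the observable
unit of a centroided spectrum. Pattern-integrated areas then average part
of it out, which is precisely the method's rationale for integrating whole
patterns; a per-cluster noise unit of the same magnitude would make
replicate glycoprofile scatter hinge on seed luck rather than on the
method. The elution profile is a fixed triangle over 10 scans: integration
operates on sum spectra, so peak shape is immaterial. The SIL standard's
signal is distributed over exactly its three quantified glycoforms
(G0/G0F/G1F summing to 1), matching the convention that their sum
*represents* the standard in the ratio.

What the generator does **not** emulate: realistic chromatography and
peak shapes, ionization suppression and matrix effects, label impurity,
digestion variability, MS2, detector saturation, and capture-efficiency
variation. Passing the recovery tests therefore demonstrates correctness
of the data processing under the method's own assumptions — not accuracy
against plasma reality, where capture efficiency (explicitly uncorrected
in this design) biases absolute values downward.

## Default panels

The 20-glycoform IgG1 panel is a documented stand-in covering the common
complex-type biantennary forms (G0–G2 × core-fucose × bisecting HexNAc ×
0–2 sialic acids); reproducing any specific study requires overriding it
with that study's analyte list. The IgG1/IgG3 glycopeptide backbones
default to `EEQYNSTYR`/`EEQYNSTFR` (both configurable). IgG3 is quantified
against the *IgG1* SIL standard over six glycoforms (G0F, G1F, G1FS, G1FN,
G2F, G2FS) and tagged cross-subclass: subclass-specific response
differences are not corrected.

## Known limitations

* **IgG3-G2F / IgG1-G1S near-isobar.** With these backbones, NeuAc − Hex −
  Fuc + O ≈ −1.0204 Da, so each IgG3-G2F isotopologue lies ~0.006–0.009 Th
  from the next IgG1-G1S isotopologue — inside the 0.04 Th windows at both
  charges. At equal subclass abundance the effect is negligible (<1% on
  the IgG3 sum); at a 10:1 IgG1 excess it inflates IgG3 by a few percent.
  The tests characterize both regimes.
* **SIL isotopologue tails near the LLOQ.** The +10 Da separation is
  imperfect for far tail isotopologues: near 100 ng/mL the SIL-G1F tail
  measurably perturbs the ~1%-abundance natural G2 form (~0.2 percentage
  points). At typical concentrations the profile is SIL-invariant to
  <0.1 pp, which is what the invariance test asserts on the pooled
  sample.
* Positive noise bias in negative controls: clipping negative
  background-subtracted areas at zero inflates near-zero signals summed
  over many analytes. Negative controls are excluded from quantitation
  anyway; the clipping is documented and tested.
* Only centroided MS1 mzXML (or the TSV peak-list dialect) is read;
  profile data must be centroided upstream. mzML and vendor formats are
  out of scope.

## Problem sizes used in the checks

The validation suites run cohorts of 3–12 samples for exactness
properties, the full default cohort (50 cases + 28 negatives + 19 pool
replicates) for rank-correlation and error-under-noise properties, 1000
replicates of 28 negative-control draws for the curation rate, and
compositions up to ~370 atoms for the isotope-pattern oracle — sizes at
which every property is decisive for the implementation while the whole
suite stays inside a coffee break on one CPU.
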