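---
title: "Methods: simulation, copy-number calling and concordance analysis for non-invasive chromosome screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulation, copy-number calling and concordance analysis for non-invasive chromosome screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nicscreen)
```

## The problem

Preimplantation genetic testing for aneuploidy (PGT-A) selects IVF embryos
for transfer by sequencing a trophectoderm (TE) biopsy of 3–5 cells.
Non-invasive chromosome screening (NICS) instead sequences the cell-free
DNA an embryo sheds into its spent culture medium, avoiding the biopsy.
Validating NICS requires comparing three assays of the same embryo — the
spent medium, the TE biopsy, and the disaggregated whole embryo as the
gold standard — on chromosome-level copy-number calls, and summarizing
agreement with diagnostic statistics.

`nicscreen` implements that entire validation workflow: a synthetic
trio-cohort generator, a copy-number caller for low-coverage binned
counts, a ploidy classifier, and the concordance engine. It also ships a
per-embryo transcription of a published 256-embryo validation cohort
(`published_embryo_calls()`), from which every group-level statistic of
that study re-derives exactly.

## Copy-number calling chain

Input is a table of read counts on a fixed 1 Mb bin grid
(`build_bin_grid()`, hg19-like chromosome lengths packaged). The chain in
`call_profile()` is:

1. **CV quality control.** The coefficient of variation of read density
   over usable autosomal bins gates every sample; `cv < 0.2` (strict) is a
   successful amplification. Two deliberate choices: sex chromosomes are
   excluded, so a male X does not read as noise; and each autosome's
   density is scaled by its own chromosome mean before taking `sd/mean`.
   The second choice makes the QC invariant to whole-chromosome
   aneuploidy: the CV gauges *amplification uniformity*, and an aneuploid
   genome amplified evenly is a successful amplification. Without this, a
   genome with many abnormal chromosomes adds up to ~0.05 to the squared
   CV and would be rejected for its biology rather than its data quality —
   embryos that demonstrably pass QC in real cohorts.
2. **GC normalization** (`gc_normalize()`). A robust lowess of density on
   GC fraction (span 0.3, 2 robustness iterations) is divided out. Bins
   beyond 5×/0.2× the median density are excluded from the *fit* (single
   amplification artifacts otherwise bend the curve in sparse GC ranges)
   but are still normalized. Degenerate GC (all equal) makes this a no-op.
3. **Reference normalization** (`reference_normalize()`). Density is
   divided by a panel's per-bin 10%-trimmed mean (rescaled to mean 1) and
   doubled, so the panel average sits at copy number 2. The default panel
   is 30 euploid XX samples generated by the package's own simulator from
   a fixed seed — fully reproducible, and replaceable by a user panel.
   With an XX panel the Y reference falls below the 0.1 floor and Y bins
   are masked; sex is instead inferred from the X level plus raw Y density
   (`infer_sex()`).
4. **Circular binary segmentation** (`cbs_segment()`). At each step the
   circular arc maximizing the pooled-variance two-sample t-statistic
   between arc and complement is found by exhaustive scan; the split is
   accepted if its permutation p-value is at most `alpha`, and the
   procedure recurses until nothing is accepted or pieces reach
   `2 * min_bins`. Adjacent segments closer than `merge_tol` in mean are
   re-merged.

### CBS numerical choices

- Scanning non-wrapping arcs covers all circular arcs because `|t|` is
  invariant under arc/complement exchange; arcs ending at the last bin
  with a non-zero left index are skipped as duplicates of the equivalent
  edge arc, so each distinct split is evaluated exactly once (this also
  makes the arg-max reproducible against an independent exhaustive
  search).
- Pooled variance is floored at 1e-9, so a perfect noiseless step gets a
  large finite t rather than a division by zero.
- The permutation p-value is `(1 + #{perm max |t| > observed}) /
  (1 + nperm)` with a *strictly greater* comparison: a permutation that
  merely reproduces a perfect step's statistic exactly does not count
  against the split. All-equal segments short-circuit to a single segment
  with p = 1. Permutations consume R's RNG, so profiles are reproducible
  under a seed; the test stops early once enough exceedances guarantee
  rejection.
- Ties in the scan resolve to the smallest left index, then the smallest
  right index.
- Defaults `alpha = 0.01`, `nperm = 1000`, `min_bins = 3`,
  `merge_tol = 0.3` resolve events of a few Mb at 2 million reads per
  sample while keeping false segments rare; all are `cnv_params()` keys.

## Ploidy classification

`classify_embryo()` reduces segments to per-chromosome calls against a
baseline of 2 (autosomes, female X) or 1 (male X/Y), using the scaled
deviation `d = (mean_cn − baseline) / (baseline / 2)`:

- `|d| ≥ 0.7`: full gain/loss; `0.3 ≤ |d| < 0.7`: mosaic, with the
  deviation itself as the mosaic-fraction estimate; below 0.3: euploid.
  The 0.3–0.7 band follows common PGT-A practice; both cutoffs are
  `ploidy_params()` keys, and none of the published-table statistics
  depend on them. Calls carry both the banded `level` and the continuous
  estimator `d_hat`.
- Deviating segments covering ≥ 80% of a chromosome merge into a
  whole-chromosome event; otherwise segments of at least 10 Mb are
  reported as segmental (the smallest arm event printed in the validation
  study's profiles is ~30 Mb, so 10 Mb leaves headroom without inviting
  noise calls). Arm labels use the chromosome midpoint as a nominal
  centromere — a simplification; real band coordinates are out of scope.
- An embryo is *euploid* with 0 abnormal chromosomes, *MAC* (multiple
  abnormal chromosomes) with ≥ 5, otherwise *abnormal*; the boundary is
  exact (4 never MAC, 5 always). These map to prioritization groups
  A/B/C. Segmental events count toward the MAC tally like whole-chromosome
  events, and Y is called but excluded from the tally and from all
  concordance sets (comparisons cover 22 autosomes + X). "Uncertain"
  (QC-failed) samples are a separate flag, not part of group C.
- Karyotype strings (`"[47, XX, +21]"`, `"[46, XX, -8mos]"`, …) are
  assembled in chromosome order; the parser accepts the typographic
  variants seen in clinical reports (en dash or minus sign for losses,
  `∼`/`→` in spans, optional space before `mos`) and the writer emits a
  canonical ASCII form that round-trips exactly.

## The synthetic cohort generator

`simulate_cohort()` draws, per embryo, a ground truth and three samples
(whole embryo, TE, medium). Per bin `b` the count is negative binomial
with mean proportional to `bin_length × (c_b / 2) × g(gc_b)`, scaled to
the target depth, where `c_b` is the copy number of the assay's cell
mixture and `g` a smooth GC-bias curve. Defaults, chosen once as the
study conditions the package emulates:

- **Depth** 2e6 reads/sample, 1 Mb bins — the regime of low-coverage
  MALBAC sequencing.
- **Dispersion** per assay `whole = 0.005 < TE = 0.015 < medium = 0.03`:
  many-cell input amplifies most evenly; cell-free medium DNA is the
  noisiest template. Baseline CVs land near 0.08 / 0.13 / 0.18 — below
  but not far from the 0.2 threshold, as in real MALBAC data. These are
  configuration, not claims about any particular chemistry.
- **Category mix** euploid 0.60, aneuploid 0.20, segmental 0.05, mosaic
  0.11, MAC 0.04, giving ~37% abnormal embryos and a few percent MAC, the
  rates observed in donated low-morphology cohorts.
- **Mosaicism** is lineage-aware: an event is shared by both lineages
  (p = 0.5), TE-restricted (0.3) or ICM-restricted (0.2), which is what
  makes TE biopsies disagree with whole embryos more often than medium
  does. Fractions are uniform on a configurable range.
- **Medium mixture**: 50% ICM / 50% TE embryonic DNA before
  contamination. The true origin of medium DNA is an open question in the
  field, so this stays a free parameter (`medium_icm_fraction`).
- **Maternal contamination** of the medium: a euploid 46,XX contaminant
  (cumulus cells have balanced chromosomes) at fraction
  `f ~ Beta(2, 18)` (mean 0.1, mirroring cohorts where rigorous rinsing
  keeps contamination low). The called level of a true aneuploidy in
  medium decreases monotonically in `f` — at `f = 1` the profile *is*
  euploid XX, which is exactly the false-negative mechanism contamination
  creates.
- **GC bias** `g(gc) = max(0.1, 1 − s·(gc − 0.42)²)` with strength
  `s = 8`: smooth, unimodal, and removable by lowess — by construction
  the normalization model is correctly specified, which is what makes the
  generator a *calibration* tool rather than a realism claim.
- **QC failures**: each sample independently fails amplification with
  probability 0.0114, drawn with dispersion 0.3 (CV ≈ 0.55). With three
  samples per embryo this reproduces a cohort yield of roughly 256
  fully-qualified embryos out of 265.

What the generator deliberately does **not** emulate: read-level errors,
mappability and blacklist structure of a real genome, segmental-duplication
artifacts, amplification dropout at single-bin scale, or chaotic/partial
ploidy states (triploidy, uniparental disomy). Passing tests therefore
demonstrate that the calling chain inverts the stated noise model and that
the statistics are computed correctly — not that the caller is validated
on real MALBAC data.

## Concordance statistics

"Positive" is *chromosomally abnormal* (aneuploid or mosaic; group B or
C). Against the gold standard the engine reports sensitivity,
specificity, NPV and PPV, each with a Wilson score 95% CI (exact 0/1
bounds at k = 0 / k = n); observed concordance with a Wilson CI; and
Cohen's kappa with the Fleiss–Cohen–Everitt asymptotic CI clipped to
[−1, 1]. Zero-denominator metrics are reported as undefined, never 0.
Paired assay comparisons use the exact McNemar test (doubled binomial
tail of the discordant counts, capped at 1); the pairing stratum is an
explicit argument because sensitivity comparisons pair only gold-positive
embryos. Chromosome-set agreement treats each autosome or X of each
non-MAC embryo as one set (23 per embryo); by default mosaic and full
events of the same direction count as the same ploidy class, mirroring
the "including mosaic" clause of karyotype-concordance conventions, and a
configurable switch tightens this to exact status. Reported percentages
round half-up to 1 decimal and kappas to 3, matching the conventions of
clinical validation reports.

The packaged cohort table is a single per-embryo joint fixture rather
than separate per-table transcriptions: the published pairwise 2×2
tables, group splits and secondary-validation cross-tabulations are
mutually consistent and determine a unique 17-cell joint distribution
over (whole-embryo status, NICS group, TE group) — including exactly one
embryo called MAC by both assays — so one table reproduces them all and
internal consistency is guaranteed by construction.

## Problem sizes and runtime choices

The test-suite simulations use sizes chosen to make the statistical
assertions sharp while keeping a full run inside a few minutes on one
CPU: 200 whole-embryo samples for event recall and mosaic-fraction
recovery (recall ≥ 95% asserted; observed mosaic-fraction error ~0.03),
100 replicates for CBS breakpoint recovery at noise σ = 0.1, 2,000
embryos for category-mix convergence, and a 265-embryo cohort for the QC
yield. `scripts/acceptance.R` recomputes the published-cohort statistics
and these recovery metrics from scratch under a caller-supplied seed.

## Known limitations

- The caller targets chromosome- and arm-scale events at 1 Mb resolution;
  sub-megabase CNVs, allele-frequency evidence (BAF), and genome-wide
  ploidy shifts (e.g. triploidy, which is invisible to depth-ratio
  methods) are out of scope.
- Mosaic-fraction estimates assume single-copy changes; a 2-copy mosaic
  gain is reported as a higher-fraction single-copy gain.
- The published-cohort fixture carries embryo-level binary/group calls
  only; per-chromosome identities of that cohort were not published, so
  chromosome-set and karyotype-level concordance run on synthetic cohorts
  or user data, not on the fixture.
- Printed p-values of paired diagnostic comparisons require the original
  per-embryo three-way pairing, which the group-level tables do not
  determine; the exact test is provided but those values are not
  reproduced.
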