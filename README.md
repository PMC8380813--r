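# nicscreen

Validation toolkit for **non-invasive chromosome screening (NICS)** of IVF
embryos.

PGT-A (preimplantation genetic testing for aneuploidy) selects embryos for
transfer by low-coverage sequencing of a 3–5-cell trophectoderm (TE)
biopsy. NICS replaces the invasive biopsy with the cell-free DNA an embryo
sheds into its spent culture medium. Validating NICS means comparing three
assays of the *same* embryo — spent medium, TE biopsy, and the whole
embryo as gold standard — on chromosome-level copy-number calls, then
summarizing agreement with diagnostic statistics. `nicscreen` implements
that full workflow for methodologists and embryology labs:

- **Synthetic trio cohorts** (`simulate_cohort()`): per-bin counts
  `~ NB(mean = depth · w_b · (c_b/2) · g(gc_b), size = 1/φ)` with
  assay-specific overdispersion φ (medium ≫ biopsy ≫ whole embryo),
  smooth GC bias `g`, lineage-restricted mosaicism (ICM vs TE), maternal
  euploid-XX contamination of the medium `f ~ Beta(a, b)`, and
  amplification failures.
- **Copy-number calling** (`call_profile()`): CV quality control
  (`sd/mean` of read density, pass iff `CV < 0.2`), robust lowess GC
  normalization, reference-panel normalization to relative copy number
  (euploid = 2), and in-house **circular binary segmentation** — max-t arc
  search with permutation testing, exact on noiseless steps and verified
  against exhaustive search.
- **Ploidy classification** (`classify_embryo()`): per-chromosome calls
  from the scaled deviation `d = (CN − baseline)/(baseline/2)` (`|d| ≥
  0.7` full, `0.3–0.7` mosaic with fraction `d`), embryo categories
  euploid / abnormal / **MAC** (≥ 5 abnormal chromosomes), prioritization
  groups A/B/C, and canonical karyotype strings (`"[46, XX, -8mos]"`).
- **Concordance engine** (`concordance_report()`): sensitivity,
  specificity, NPV, PPV with **Wilson score** 95% CIs, observed
  concordance, **Cohen's kappa** (Fleiss–Cohen–Everitt CI), the **exact
  McNemar** test for paired assays, 23-per-embryo chromosome-set Venn
  partitions, per-group accuracy and secondary-validation
  reclassification.

A per-embryo transcription of a published 256-embryo validation cohort is
packaged (`published_embryo_calls()`); every group-level statistic of that
study re-derives from it exactly.

## Worked example

Simulate three embryo trios, call copy number, and classify:

```r
library(nicscreen)
grid   <- build_bin_grid()                      # hg19-like 1 Mb bins
cfg    <- sim_config(n_embryos = 3, seed = 7)   # 2M reads/sample defaults
cohort <- simulate_cohort(cfg, grid)
called <- pipeline_call(cohort, grid, params = cnv_params(seed = 7))
called$calls[, c("embryo_id", "assay", "category", "group", "karyotype", "cv")]
#>   embryo_id assay category group                       karyotype         cv
#> 1     S0001 whole  euploid     A                        [46, XY] 0.08363403
#> 2     S0001    TE  euploid     A                        [46, XY] 0.13314053
#> 3     S0001  NICS  euploid     A                        [46, XY] 0.17562606
#> 4     S0002 whole  euploid     A                        [46, XX] 0.08243972
#> 5     S0002    TE abnormal     B [46, XX, +1q(q->qter, ~14M)mos] 0.13070422
#> 6     S0002  NICS  euploid     A                        [46, XX] 0.18129453
#> 7     S0003 whole abnormal     B                   [45, XX, -22] 0.08287972
#> 8     S0003    TE abnormal     B                   [45, XX, -22] 0.13051969
#> 9     S0003  NICS abnormal     B                   [45, XX, -22] 0.18288589
```

Each row is one assay of one embryo: the CV column is the amplification QC
metric (all pass `< 0.2`; medium is noisiest, as configured); S0003 is a
monosomy-22 embryo called concordantly by all three assays; S0002 shows an
assay discordance — a small mosaic arm-level gain reported in the TE
biopsy only, the kind of disagreement the concordance statistics quantify.

Running the engine on the packaged validation cohort:

```r
rep <- pipeline_concordance("published", gold = "whole")
rep$all$diagnostics$NICS$summary
#>        metric  estimate        lo        hi   k   n
#> 1 sensitivity 0.8645833 0.7819886 0.9191229  83  96
#> 2 specificity 0.7312500 0.6577316 0.7939245 117 160
#> 3         npv 0.9000000 0.8364142 0.9406245 117 130
#> 4         ppv 0.6587302 0.5723451 0.7357229  83 126
```

NICS detects 86.5% of abnormal embryos (sensitivity) and, most usefully
for a rule-in assay, 90.0% of embryos it calls normal really are normal
(NPV). `print(rep)` additionally reports the TE-biopsy summaries, kappa
agreement (0.665 TE, 0.561 NICS vs whole embryo), the prioritization-group
accuracies (90.0% / 72.2% / 27.8% for NICS groups A/B/C) and the
secondary-validation gains from adding a TE assay to NICS groups B and C.

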