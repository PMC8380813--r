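pub <- published_embryo_calls()
bin <- function(assay) {
  sub <- pub[pub$assay == assay, ]
  stats::setNames(sub$category != "euploid", sub$embryo_id)
}
grp <- function(assay) {
  sub <- pub[pub$assay == assay, ]
  stats::setNames(c(euploid = "A", abnormal = "B", MAC = "C")[sub$category],
                  sub$embryo_id)
}

test_that("Wilson intervals match the printed precision and behave", {
  expect_equal(round(wilson_ci(86, 96) * 100, 1), c(lo = 81.9, hi = 94.2))

  set.seed(8)
  for (r in 1:50) {
    n <- sample(5:500, 1)
    k <- sample(0:n, 1)
    ci <- wilson_ci(k, n)
    expect_true(ci[1] <= k / n && k / n <= ci[2])          # containment
    mir <- wilson_ci(n - k, n)
    expect_equal(unname(ci), unname(1 - rev(mir)))         # mirror symmetry
  }
  # width shrinks with n at fixed proportion
  widths <- vapply(c(10, 40, 160, 640), function(n)
    diff(wilson_ci(round(0.3 * n), n)), numeric(1))
  expect_true(all(diff(widths) < 0))
  expect_equal(unname(wilson_ci(0, 20)[1]), 0)
  expect_error(wilson_ci(5, 0))
})

test_that("confusion tables reproduce the published 2x2 counts", {
  te <- confusion(bin("TE"), bin("whole"))
  expect_equal(unlist(te[c("tp", "fp", "fn", "tn")]),
               c(tp = 86, fp = 32, fn = 10, tn = 128))
  ni <- confusion(bin("NICS"), bin("whole"))
  expect_equal(unlist(ni[c("tp", "fp", "fn", "tn")]),
               c(tp = 83, fp = 43, fn = 13, tn = 117))

  # swapping the rater flips fp/fn
  sw <- confusion(bin("whole"), bin("TE"))
  expect_equal(sw$fp, te$fn)
  expect_equal(sw$fn, te$fp)

  ident <- confusion(bin("TE"), bin("TE"))
  expect_equal(ident$fp + ident$fn, 0)
  expect_error(confusion(stats::setNames(TRUE, "zz"), bin("whole")),
               "no embryos")
})

test_that("diagnostic summaries carry Wilson CIs and handle emptiness", {
  d <- diagnostic_summary(confusion(bin("TE"), bin("whole")))
  sens <- d[d$metric == "sensitivity", ]
  expect_equal(round(100 * sens$estimate, 1), 89.6)
  expect_equal(round(100 * c(sens$lo, sens$hi), 1), c(81.9, 94.2))
  npv <- diagnostic_summary(confusion(bin("NICS"), bin("whole")))
  expect_equal(round(100 * npv$estimate[npv$metric == "npv"], 1), 90.0)

  none <- structure(list(tp = 0, fp = 0, fn = 10, tn = 5, n = 15,
                         n_excluded = 0), class = "confusion_table")
  ds <- diagnostic_summary(none)
  expect_true(is.na(ds$estimate[ds$metric == "ppv"]))   # undefined, not 0
  expect_equal(ds$estimate[ds$metric == "sensitivity"], 0)
})

test_that("exact paired test equals binomial enumeration up to b+c = 12", {
  a <- rep(TRUE, 4)
  expect_equal(exact_paired_test(a, a), 1)

  mk <- function(b, cc) {
    n <- b + cc + 3
    list(a = c(rep(TRUE, b), rep(FALSE, cc), rep(TRUE, 3)),
         b = c(rep(FALSE, b), rep(TRUE, cc), rep(TRUE, 3)))
  }
  expect_equal(exact_paired_test(mk(3, 1)$a, mk(3, 1)$b), 0.625)
  expect_equal(exact_paired_test(mk(10, 0)$a, mk(10, 0)$b), 2 / 1024)
  for (b in 0:12) for (cc in 0:(12 - b)) {
    v <- mk(b, cc)
    expect_equal(exact_paired_test(v$a, v$b), mcnemar_enum(b, cc),
                 info = paste(b, cc))
  }
})

test_that("Cohen's kappa matches the published agreement analysis", {
  te <- cohen_kappa(confusion(bin("TE"), bin("whole")))
  expect_equal(round(te$kappa, 3), 0.665)
  expect_equal(round(100 * te$po, 1), 83.6)
  ni <- cohen_kappa(confusion(bin("NICS"), bin("whole")))
  expect_equal(round(ni$kappa, 3), 0.561)
  nt <- cohen_kappa(confusion(bin("NICS"), bin("TE")))
  expect_equal(round(nt$kappa, 3), 0.484)

  perfect <- cohen_kappa(matrix(c(30, 0, 0, 70), 2))
  expect_equal(perfect$kappa, 1)

  chance <- cohen_kappa(matrix(c(24, 36, 16, 24), 2))  # po == pe
  expect_equal(chance$kappa, 0)
  expect_true(chance$kappa >= chance$kappa_ci[1] &&
                chance$kappa <= chance$kappa_ci[2])

  degen <- cohen_kappa(matrix(c(10, 0, 0, 0), 2))
  expect_true(is.na(degen$kappa))
})

test_that("chromosome-set Venn partitions 23 sets per non-MAC embryo", {
  g <- hg_grid
  mk_calls <- function(ids, means_by_id = list()) {
    calls_table(lapply(ids, function(id) {
      segs <- profile_segments(g, means_by_id[[id]] %||% list())
      cl <- classify_embryo(stub_profile(segs, g, sample_id = id))
      cl$embryo_id <- id
      cl
    }))
  }
  ids <- sprintf("V%02d", 1:6)
  same <- mk_calls(ids, list(V01 = list(`3` = 3)))
  venn <- chrom_set_venn(same, same, same)
  expect_equal(venn$n_sets, 6 * 23)
  expect_equal(unname(venn$regions["all_three"]), 6 * 23)
  expect_equal(sum(venn$regions), venn$n_sets)

  other <- mk_calls(ids, list(V01 = list(`3` = 1), V02 = list(`9` = 3)))
  venn2 <- chrom_set_venn(same, other, same)
  expect_equal(sum(venn2$regions), venn2$n_sets)
  # V01 chr3: gain vs loss vs gain -> TE/whole agree only; V02 chr9:
  # euploid vs gain vs euploid -> TE/whole agree only
  expect_equal(unname(venn2$regions["te_whole_only"]), 2)

  # mosaic vs full same direction counts as consistent by default
  mosa <- mk_calls(ids, list(V01 = list(`3` = 2.5)))
  venn3 <- chrom_set_venn(same, mosa, same)
  expect_equal(unname(venn3$regions["all_three"]), 6 * 23)

  mac <- mk_calls(ids, list(V01 = stats::setNames(as.list(rep(3, 5)),
                                                  as.character(1:5))))
  expect_error(chrom_set_venn(mac, same, same), "MAC")
})

test_that("karyotype concordance applies the full/partial/discordant rules", {
  expect_equal(karyotype_concordance("[46, XX]", "[46, XX]"), "full")
  expect_equal(karyotype_concordance("[48, XY, +6, +20]",
                                     "[46, XY, -6mos, +20]"), "full")
  expect_equal(karyotype_concordance("[48, XY, +6, +20]",
                                     "[48, XY, +20, +15]"), "partial")
  expect_equal(karyotype_concordance("[47, XX, +6]", "[46, XX]"),
               "discordant")
})

test_that("group tables reproduce the published prioritization fractions", {
  gt <- group_table(grp("NICS"), bin("whole"))
  expect_equal(gt$n, c(130, 108, 18))
  expect_equal(gt$consistent, c(117, 78, 5))
  expect_equal(round(100 * gt$consistent_frac, 1), c(90.0, 72.2, 27.8))
  expect_equal(gt$n_gold_normal + gt$n_gold_abnormal, gt$n)

  gt_te <- group_table(grp("TE"), bin("whole"))
  expect_equal(gt_te$n, c(138, 108, 10))
  expect_equal(round(100 * gt_te$consistent_frac, 1), c(92.8, 75.0, 50.0))

  allA <- group_table(stats::setNames(rep("A", 5), letters[1:5]),
                      stats::setNames(rep(FALSE, 5), letters[1:5]))
  expect_equal(allA$consistent_frac[1], 1)
})

test_that("secondary validation reproduces the published reclassification", {
  svC <- secondary_validation(grp("NICS"), bin("TE"), bin("whole"), "C")
  expect_equal(svC$n, 18)
  expect_equal(round(100 * svC$accuracy, 1), 83.3)
  expect_equal(svC$n_recategorized, 12)
  expect_equal(round(100 * svC$primary_accuracy, 1), 27.8)

  svB <- secondary_validation(grp("NICS"), bin("TE"), bin("whole"), "B")
  expect_equal(svB$n, 108)
  expect_equal(round(100 * svB$accuracy, 1), 84.3)
  expect_equal(svB$n_recategorized, 25)

  ident <- secondary_validation(grp("NICS"), bin("whole"), bin("whole"),
                                "C")
  expect_equal(ident$accuracy, 1)

  none <- secondary_validation(stats::setNames("A", "e1"),
                               stats::setNames(TRUE, "e1"),
                               stats::setNames(TRUE, "e1"), "C")
  expect_equal(none$n, 0)
})
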