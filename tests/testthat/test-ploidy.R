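test_that("chromosome calls follow the deviation thresholds", {
  g <- hg_grid
  seg <- function(mean_cn) flat_segments(g, stats::setNames(list(mean_cn),
                                                            "7"))
  full <- call_chromosome(seg(3.0), "7", baseline = 2)
  expect_equal(full$status, "gain")
  expect_equal(full$level, 1)

  mos <- call_chromosome(seg(1.5), "7", baseline = 2)
  expect_equal(mos$status, "mosaic_loss")
  expect_equal(mos$level, 0.5)

  eu <- call_chromosome(seg(2.2), "7", baseline = 2)
  expect_equal(nrow(eu), 0)

  # male X: thresholds scale with baseline 1
  xg <- call_chromosome(flat_segments(g, list(X = 1.5)), "X", baseline = 1)
  expect_equal(xg$status, "gain")     # |d| = 0.5 >= 0.7 * baseline / 2
  expect_equal(xg$level, 1)
  xm <- call_chromosome(flat_segments(g, list(X = 1.25)), "X", baseline = 1)
  expect_equal(xm$status, "mosaic_gain")
  expect_equal(xm$level, 0.5)
})

test_that("distal segments are reported as arm-level events with span", {
  g <- hg_grid
  len16 <- attr(g, "chrom_lengths")[["16"]]
  idx <- which(g$chrom == "16" & g$mask)  # usable (full-size) bins
  qstart <- g$start[idx[length(idx) - 46]]  # distal 47 usable bins
  qend <- g$end[idx[length(idx)]]
  segs <- data.frame(
    chrom = "16",
    start_bp = c(0, qstart), end_bp = c(qstart, qend),
    n_bins = c(length(idx) - 47, 47), mean_cn = c(2, 3), p = 0.001,
    stringsAsFactors = FALSE)
  ev <- call_chromosome(segs, "16", baseline = 2, chrom_length = len16)
  expect_equal(ev$status, "segmental_gain")
  expect_equal(ev$arm, "q")
  expect_equal(round(ev$span_mb), 47)

  k <- nicscreen:::events_to_karyotype(ev, "XY")
  expect_match(k, "\\+16q\\(.*~47M\\)")
  expect_match(k, "^\\[46, XY")

  # sub-threshold spans are not reported
  short <- segs
  short$n_bins <- c(length(idx) - 5, 5)
  short$start_bp[2] <- g$start[idx[length(idx) - 4]]
  expect_equal(nrow(call_chromosome(short, "16", baseline = 2,
                                    chrom_length = len16)), 0)
})

test_that("the MAC boundary at five abnormal chromosomes is exact", {
  g <- hg_grid
  gains <- function(k) stats::setNames(as.list(rep(3, k)),
                                       as.character(seq_len(k)))
  for (k in c(0, 1, 4, 5, 7)) {
    prof <- stub_profile(profile_segments(g, gains(k)), g, sex = "XX")
    cl <- classify_embryo(prof)
    expect_equal(cl$n_abnormal, k)
    expect_equal(cl$category,
                 if (k == 0) "euploid" else if (k >= 5) "MAC"
                 else "abnormal")
    expect_equal(cl$group,
                 if (k == 0) "A" else if (k >= 5) "C" else "B")
  }
})

test_that("embryo calls assemble karyotypes that round-trip", {
  g <- hg_grid
  prof <- stub_profile(profile_segments(g, list(`6` = 3, `20` = 3),
                                        sex = "XY"), g, sex = "XY")
  cl <- classify_embryo(prof)
  expect_equal(cl$karyotype, "[48, XY, +6, +20]")

  prof2 <- stub_profile(profile_segments(g, list(`8` = 1.5)), g,
                        sex = "XX")
  cl2 <- classify_embryo(prof2)
  expect_equal(cl2$karyotype, "[46, XX, -8mos]")

  for (cl_i in list(cl, cl2)) {
    parsed <- parse_karyotype(cl_i$karyotype)
    expect_setequal(parsed$events$chrom, unique(cl_i$events$chrom))
    expect_equal(parsed$events$mosaic,
                 cl_i$events$mosaic[match(parsed$events$chrom,
                                          cl_i$events$chrom)])
  }
})

test_that("sex inference uses the X level and Y density", {
  g <- hg_grid
  cfg <- sim_config(seed = 1)
  panel <- nicscreen:::default_reference_panel(g)
  prof_xy <- call_profile(simulate_counts(make_truth("xy", "XY"), "whole",
                                          g, cfg, seed = 21),
                          g, panel, cnv_params(seed = 1))
  expect_equal(as.character(prof_xy$sex), "XY")
  prof_xx <- call_profile(simulate_counts(make_truth("xx", "XX"), "whole",
                                          g, cfg, seed = 22),
                          g, panel, cnv_params(seed = 1))
  expect_equal(as.character(prof_xx$sex), "XX")

  # XX medium with 30% maternal contamination is still XX
  prof_con <- call_profile(simulate_counts(make_truth("c", "XX"), "medium",
                                           g, cfg, seed = 23,
                                           contamination = 0.3),
                           g, panel, cnv_params(seed = 1))
  expect_equal(as.character(prof_con$sex), "XX")
})

test_that("raising the true mosaic fraction never un-calls an abnormality", {
  g <- hg_grid
  cfg <- sim_config(seed = 1)
  panel <- nicscreen:::default_reference_panel(g)
  called <- vapply(c(0.35, 0.5, 0.65, 0.8, 1), function(f) {
    tr <- make_truth("m", "XX", whole_event("14", +1, fraction = f))
    ct <- simulate_counts(tr, "whole", g, cfg, seed = 99)
    cl <- classify_embryo(call_profile(ct, g, panel,
                                       cnv_params(seed = 99)))
    "14" %in% cl$events$chrom
  }, logical(1))
  expect_false(any(diff(called) < 0))  # abnormal never reverts to euploid
  expect_true(all(called[3:5]))
})
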