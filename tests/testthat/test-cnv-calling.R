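test_that("CV equals sd/mean of read density and gates QC strictly", {
  g <- toy_grid(c(`1` = 4e6))
  ct <- count_table(rep(120, 4), g)
  expect_equal(compute_cv(ct, g), 0)

  x <- c(100, 100, 100, 300)
  ct2 <- count_table(x, g)
  expect_equal(compute_cv(ct2, g), sd(x) / mean(x))  # hand oracle

  zero <- count_table(rep(0, 4), g)
  expect_equal(compute_cv(zero, g), Inf)

  # threshold is strict: cv == threshold fails QC
  cv0 <- sd(x) / mean(x)
  prof <- call_profile(ct2, g, panel = matrix(1, 4, 20),
                       params = cnv_params(cv_threshold = cv0))
  expect_false(prof$qc_pass)
  prof2 <- call_profile(ct2, g, panel = matrix(1, 4, 20),
                        params = cnv_params(cv_threshold = cv0 + 1e-9,
                                            nperm = 100))
  expect_true(prof2$qc_pass)
})

test_that("CV excludes sex chromosomes so a male X does not inflate it", {
  g <- toy_grid(c(`1` = 5e6, X = 5e6))
  ct <- count_table(c(rep(100, 5), rep(50, 5)), g)
  expect_equal(compute_cv(ct, g), 0)
})

test_that("lowess GC normalization removes a smooth GC-only trend", {
  set.seed(21)
  n <- 400
  gc <- pmin(0.6, pmax(0.3, rnorm(n, 0.42, 0.05)))
  g <- toy_grid(c(`1` = n * 1e6), gc = gc)
  trend <- 1 - 6 * (gc - 0.42)^2          # pure GC effect
  ct <- count_table(round(500 * trend), g)
  dens <- gc_normalize(ct, g)
  expect_lt(max(dens) / min(dens), 1.05)  # flat after normalization

  flat <- count_table(rep(500, n), g)
  expect_equal(gc_normalize(flat, g), rep(1, n))

  # single outlier barely moves everyone else (robust fit)
  out <- round(500 * trend)
  out[200] <- 5000
  d_out <- gc_normalize(count_table(out, g), g)
  rel <- abs(d_out[-200] / dens[-200] - mean(d_out[-200] / dens[-200]))
  expect_lt(max(rel), 0.01)

  # degenerate GC: normalization is a no-op up to scaling
  gflat <- toy_grid(c(`1` = 6e6))
  ctf <- count_table(c(100, 200, 100, 200, 100, 200), gflat)
  dflat <- gc_normalize(ctf, gflat)
  expect_equal(dflat / mean(dflat), ctf$count / mean(ctf$count))
})

test_that("reference normalization pins the panel mean at copy number 2", {
  g <- toy_grid(c(`1` = 6e6, `21` = 4e6))
  n <- nrow(g)
  panel <- matrix(1, n, 25)
  expect_equal(reference_normalize(rep(1, n), panel, g), rep(2, n))

  dens <- rep(1, n)
  dens[g$chrom == "21"] <- 1.5
  cn <- reference_normalize(dens, panel, g)
  expect_equal(unique(cn[g$chrom == "21"]), 3)
  expect_equal(unique(cn[g$chrom == "1"]), 2)

  dead <- panel
  dead[3, ] <- 0.001
  cn2 <- reference_normalize(rep(1, n), dead, g)
  expect_true(is.na(cn2[3]))
  expect_false(anyNA(cn2[-3]))

  expect_error(reference_normalize(dens, NULL, g), "empty reference panel")
})

test_that("copy number and segments are invariant to global scaling", {
  g <- toy_grid(c(`1` = 30e6))
  base <- rep(200, 30)
  base[11:20] <- 300
  p1 <- call_profile(count_table(base, g), g, panel = matrix(1, 30, 20),
                     params = cnv_params(min_bins = 3, nperm = 200,
                                         seed = 5))
  p2 <- call_profile(count_table(base * 7, g), g,
                     panel = matrix(1, 30, 20),
                     params = cnv_params(min_bins = 3, nperm = 200,
                                         seed = 5))
  expect_equal(p1$cv, p2$cv)
  expect_equal(p1$cn, p2$cn)
  expect_equal(p1$segments$mean_cn, p2$segments$mean_cn)
  expect_equal(p1$segments$start_bp, p2$segments$start_bp)
})

test_that("read-density CV rises monotonically with simulator dispersion", {
  g <- toy_grid(c(`1` = 40e6, `2` = 40e6))
  tr <- make_truth("cvm", "XX")
  cvs <- vapply(c(0.005, 0.02, 0.08, 0.3), function(phi) {
    cfg <- sim_config(seed = 1, dispersion = c(whole = phi, TE = phi,
                                               medium = phi, blank = phi))
    compute_cv(simulate_counts(tr, "whole", g, cfg, seed = 31), g)
  }, numeric(1))
  expect_true(all(diff(cvs) > 0))
})

test_that("QC failure yields a profile without segments", {
  g <- toy_grid(c(`1` = 4e6))
  prof <- call_profile(count_table(c(0, 0, 0, 0), g), g,
                       panel = matrix(1, 4, 20))
  expect_false(prof$qc_pass)
  expect_null(prof$segments)
  cl <- classify_embryo(prof)
  expect_false(cl$qc_pass)
  expect_true(is.na(cl$category))
})
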