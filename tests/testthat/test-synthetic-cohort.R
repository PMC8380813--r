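test_that("sim_config validates its inputs", {
  expect_error(sim_config(n_embryos = 5), "seed")
  expect_error(sim_config(seed = 1, category_mix = c(euploid = 0.5,
                                                     aneuploid = 0.4,
                                                     segmental = 0.2,
                                                     mosaic = 0, MAC = 0)),
               "category_mix")
  cfg <- sim_config(seed = 1)
  expect_s3_class(cfg, "sim_config")
  expect_equal(sum(cfg$category_mix), 1)
})

test_that("degenerate category mixes force the truth structure", {
  mix_e <- c(euploid = 1, aneuploid = 0, segmental = 0, mosaic = 0, MAC = 0)
  cfg <- sim_config(n_embryos = 20, seed = 3, category_mix = mix_e)
  truths <- simulate_truth(cfg)
  expect_true(all(vapply(truths, function(t) t$category, "") == "euploid"))
  expect_true(all(vapply(truths, function(t) nrow(t$events), 0L) == 0))

  mix_m <- c(euploid = 0, aneuploid = 0, segmental = 0, mosaic = 0, MAC = 1)
  cfg <- sim_config(n_embryos = 20, seed = 4, category_mix = mix_m)
  truths <- simulate_truth(cfg)
  n_abn <- vapply(truths, function(t) length(unique(t$events$chrom)), 0L)
  expect_true(all(n_abn >= 5))
})

test_that("category proportions converge to the configured mix", {
  cfg <- sim_config(n_embryos = 2000, seed = 5)
  truths <- simulate_truth(cfg)
  cats <- vapply(truths, function(t) t$category, "")
  for (nm in names(cfg$category_mix)) {
    p <- cfg$category_mix[[nm]]
    se <- sqrt(p * (1 - p) / 2000)
    expect_lt(abs(mean(cats == nm) - p), 3 * se + 1e-9)
  }
})

test_that("expected counts encode the copy-number mixture exactly", {
  g <- toy_grid(c(`1` = 10e6, `21` = 5e6, X = 6e6, Y = 3e6))
  cfg <- sim_config(seed = 1, gc_bias_strength = 0)

  eu <- make_truth("e1", "XY")
  mu <- expected_counts(eu, "whole", g, cfg)
  expect_equal(sum(mu), cfg$depth)
  aut <- g$chrom %in% c("1", "21")
  expect_equal(unname(mu[g$chrom == "X"][1] / mu[aut][1]), 0.5)
  expect_equal(length(unique(round(mu[aut], 9))), 1)  # flat autosomes

  t21 <- make_truth("t21", "XX", whole_event("21", +1))
  mu21 <- expected_counts(t21, "whole", g, cfg)
  expect_equal(unname(mu21[g$chrom == "21"][1] / mu21[g$chrom == "1"][1]),
               1.5)

  # pure maternal contamination makes the medium profile euploid XX
  mac <- make_truth("m", "XY", whole_event("21", +1))
  mu_f1 <- expected_counts(mac, "medium", g, cfg, contamination = 1)
  eu_xx <- expected_counts(make_truth("e2", "XX"), "medium", g, cfg,
                           contamination = 0)
  expect_equal(mu_f1, eu_xx)
})

test_that("count simulation is seed-deterministic and blank is near-empty", {
  g <- toy_grid()
  cfg <- sim_config(seed = 2)
  tr <- make_truth("d", "XX")
  a <- simulate_counts(tr, "medium", g, cfg, seed = 10)
  b <- simulate_counts(tr, "medium", g, cfg, seed = 10)
  expect_identical(a$count, b$count)
  expect_identical(attr(a, "contamination"), attr(b, "contamination"))

  blank <- simulate_counts(tr, "blank", g, cfg, seed = 10)
  expect_lt(sum(blank$count), cfg$depth * 0.01)
  expect_error(simulate_counts(tr, "plasma", g, cfg), "arg")
})

test_that("mean bin counts are unbiased for the relative copy number", {
  g <- toy_grid(c(`1` = 8e6, `2` = 8e6))
  cfg <- sim_config(seed = 6, gc_bias_strength = 0,
                    dispersion = c(whole = 0.02, TE = 0.05, medium = 0.1,
                                   blank = 0.02))
  tr <- make_truth("m", "XX", whole_event("2", +1, fraction = 0.5))
  sums <- 0
  with_seed <- nicscreen:::with_seed
  with_seed(77, {
    for (i in 1:200) sums <- sums + simulate_counts(tr, "whole", g, cfg)$count
  })
  mu <- sums / 200
  ratio <- mean(mu[g$chrom == "2"]) / mean(mu[g$chrom == "1"])
  expect_lt(abs(ratio - 2.5 / 2), 0.02)
})

test_that("maternal contamination dilutes the aneuploidy monotonically", {
  acn <- nicscreen:::assay_copy_number
  g <- toy_grid(c(`1` = 8e6, `21` = 5e6))
  cfg <- sim_config(seed = 1)
  tr <- make_truth("m", "XX", whole_event("21", -1))
  lvl <- vapply(c(0, 0.25, 0.5, 0.75, 1), function(f) {
    cn <- acn(tr, "medium", g, cfg, contamination = f)
    2 - mean(cn[g$chrom == "21"])  # apparent mosaic loss level
  }, numeric(1))
  expect_true(all(diff(lvl) < 0))
  expect_equal(lvl[1], 1)
  expect_equal(lvl[5], 0)
})

test_that("cohort simulation yields a trio per embryo and a manifest", {
  g <- toy_grid()
  cfg <- sim_config(n_embryos = 4, seed = 9, depth = 5e4)
  coh <- simulate_cohort(cfg, g)
  expect_equal(nrow(coh$manifest), 12)
  expect_equal(length(coh$counts), 12)
  expect_setequal(unique(coh$manifest$assay), c("whole", "TE", "medium"))
  expect_true(all(coh$manifest$seed == 9))

  empty <- simulate_cohort(sim_config(n_embryos = 0, seed = 9), g)
  expect_equal(nrow(empty$manifest), 0)
  expect_equal(length(empty$counts), 0)

  out <- file.path(tempdir(), "cohort-test")
  on.exit(unlink(out, recursive = TRUE))
  coh2 <- simulate_cohort(cfg, g, out_dir = out)
  expect_true(file.exists(file.path(out, "manifest.tsv")))
  expect_true(file.exists(file.path(out, "config.yaml")))
  expect_identical(coh2$counts[[1]]$count, coh$counts[[1]]$count)
})
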