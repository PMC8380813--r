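# Synthetic trio cohorts: ground-truth embryos (per-lineage integer copy
# states, mosaic fractions, category) and overdispersed MALBAC-like bin
# counts for the three assays (whole embryo, TE biopsy, spent medium) plus
# blank-medium controls.
#
# Noise model per bin b:  count_b ~ NegBin(mean = depth * w_b, size = 1/phi)
# with w_b proportional to bin_length * (c_b / 2) * g(gc_b), where c_b is the
# lineage-mixture copy number implied by the truth and g a smooth unimodal
# GC-bias curve. The spent-medium mixture adds a maternal euploid-XX fraction
# f ~ Beta(contamination_beta).

#' Simulation configuration
#'
#' Defaults encode the study conditions the package emulates: 2 million
#' reads per sample on a 1 Mb grid; dispersion ordered medium > TE > whole
#' (cell-free DNA is the noisiest template); a cohort mix with ~37% of
#' embryos chromosomally abnormal and a few percent MAC; a per-sample QC
#' failure rate calibrated so that roughly 9 embryos in 265 lack a fully
#' qualified trio.
#'
#' @param n_embryos Number of embryos to simulate.
#' @param seed RNG seed (mandatory; every derived artifact records it).
#' @param depth Sequencing reads per sample (default 2e6).
#' @param dispersion Named negative-binomial dispersion (phi) per assay.
#' @param gc_bias_strength Strength of the quadratic GC bias around GC 0.42.
#' @param contamination_beta Beta(a, b) parameters for the maternal fraction
#'   of spent-medium DNA.
#' @param medium_icm_fraction,whole_icm_fraction ICM share of the embryonic
#'   DNA in the medium / whole-embryo mixtures (the true medium origin is an
#'   open question; both are free parameters).
#' @param category_mix Probabilities of the five truth categories
#'   (euploid, aneuploid, segmental, mosaic, MAC); must sum to 1.
#' @param mosaic_fraction_range Uniform range for simulated mosaic fractions.
#' @param lineage_probs Probabilities that a mosaic event is shared by both
#'   lineages, restricted to TE, or restricted to ICM.
#' @param qc_fail_rate Per-sample probability of amplification failure.
#' @param qc_fail_dispersion Dispersion used for failed samples (drives the
#'   read-density CV above the 0.2 threshold).
#' @param blank_depth_fraction Blank-medium depth as a fraction of `depth`.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_embryos = 265L, seed = NULL, depth = 2e6,
                       dispersion = c(whole = 0.005, TE = 0.015,
                                      medium = 0.03, blank = 0.03),
                       gc_bias_strength = 8,
                       contamination_beta = c(2, 18),
                       medium_icm_fraction = 0.5,
                       whole_icm_fraction = 0.5,
                       category_mix = c(euploid = 0.60, aneuploid = 0.20,
                                        segmental = 0.05, mosaic = 0.11,
                                        MAC = 0.04),
                       mosaic_fraction_range = c(0.2, 0.8),
                       lineage_probs = c(both = 0.5, te_only = 0.3,
                                         icm_only = 0.2),
                       qc_fail_rate = 0.0114,
                       qc_fail_dispersion = 0.3,
                       blank_depth_fraction = 0.001) {
  if (is.null(seed)) stop("sim_config requires an explicit seed", call. = FALSE)
  stopifnot(n_embryos >= 0, depth > 0,
            all(c("whole", "TE", "medium", "blank") %in% names(dispersion)),
            all(dispersion >= 0),
            length(contamination_beta) == 2, all(contamination_beta > 0),
            medium_icm_fraction >= 0, medium_icm_fraction <= 1,
            qc_fail_rate >= 0, qc_fail_rate <= 1)
  nm <- c("euploid", "aneuploid", "segmental", "mosaic", "MAC")
  if (!all(nm %in% names(category_mix)) ||
      abs(sum(category_mix) - 1) > 1e-8 || any(category_mix < 0))
    stop("category_mix must be non-negative probabilities over ",
         paste(nm, collapse = "/"), " summing to 1", call. = FALSE)
  if (abs(sum(lineage_probs) - 1) > 1e-8)
    stop("lineage_probs must sum to 1", call. = FALSE)
  structure(list(n_embryos = as.integer(n_embryos), seed = as.integer(seed),
                 depth = depth, dispersion = dispersion,
                 gc_bias_strength = gc_bias_strength,
                 contamination_beta = contamination_beta,
                 medium_icm_fraction = medium_icm_fraction,
                 whole_icm_fraction = whole_icm_fraction,
                 category_mix = category_mix[nm],
                 mosaic_fraction_range = mosaic_fraction_range,
                 lineage_probs = lineage_probs,
                 qc_fail_rate = qc_fail_rate,
                 qc_fail_dispersion = qc_fail_dispersion,
                 blank_depth_fraction = blank_depth_fraction),
            class = "sim_config")
}

new_truth <- function(embryo_id, sex, category, events) {
  structure(list(embryo_id = embryo_id, sex = sex, category = category,
                 events = events), class = "embryo_truth")
}

empty_events <- function() {
  data.frame(chrom = character(), kind = character(), delta = integer(),
             fraction = numeric(), lineage = character(),
             start_mb = numeric(), end_mb = numeric(), arm = character(),
             stringsAsFactors = FALSE)
}

#' Simulate ground-truth embryos
#'
#' Draws embryo sex, category and copy-number events. Whole-chromosome and
#' segmental events live on autosomes; mosaic events carry a cell fraction
#' and may be restricted to one lineage (the source of TE-vs-whole-embryo
#' discordance). MAC embryos carry five or more abnormal chromosomes by
#' construction; non-MAC embryos never reach five.
#'
#' @param config A [sim_config()].
#' @param n Number of embryos (defaults to `config$n_embryos`).
#' @param seed Optional seed overriding `config$seed`.
#' @return List of `embryo_truth` objects.
#' @export
simulate_truth <- function(config, n = config$n_embryos, seed = config$seed) {
  with_seed(seed, lapply(seq_len(n), function(i) simulate_truth_one(config, i)))
}

simulate_truth_one <- function(config, i) {
  sex <- sample(c("XX", "XY"), 1)
  category <- sample(names(config$category_mix), 1,
                     prob = config$category_mix)
  fr <- function(n) stats::runif(n, config$mosaic_fraction_range[1],
                                 config$mosaic_fraction_range[2])
  ev <- empty_events()
  add_whole <- function(n, fraction, lineage) {
    chroms <- sample(AUTOSOMES, n)
    data.frame(chrom = chroms, kind = "whole",
               delta = sample(c(1L, -1L), n, replace = TRUE),
               fraction = fraction, lineage = lineage,
               start_mb = NA_real_, end_mb = NA_real_, arm = NA_character_,
               stringsAsFactors = FALSE)
  }
  if (category == "aneuploid") {
    ev <- add_whole(sample(1:3, 1, prob = c(0.6, 0.3, 0.1)), 1, "both")
  } else if (category == "MAC") {
    ev <- add_whole(sample(5:8, 1), 1, "both")
  } else if (category == "mosaic") {
    n_ev <- sample(1:2, 1, prob = c(0.8, 0.2))
    ev <- add_whole(n_ev, fr(n_ev),
                    sample(c("both", "te", "icm"), n_ev, replace = TRUE,
                           prob = config$lineage_probs))
  } else if (category == "segmental") {
    lens <- hg19_chrom_lengths()
    chrom <- sample(AUTOSOMES[1:12], 1)  # large autosomes carry visible arms
    clen_mb <- lens$length[lens$chrom == chrom] / 1e6
    span <- stats::runif(1, 30, min(100, clen_mb * 0.45))
    arm <- sample(c("p", "q"), 1)
    ev <- data.frame(chrom = chrom, kind = "segmental",
                     delta = sample(c(1L, -1L), 1), fraction = 1,
                     lineage = "both",
                     start_mb = if (arm == "p") 0 else clen_mb - span,
                     end_mb = if (arm == "p") span else clen_mb,
                     arm = arm, stringsAsFactors = FALSE)
  }
  new_truth(sprintf("S%04d", i), sex, category, ev)
}

# True copy-number vector for one lineage over the grid bins.
lineage_copy_number <- function(truth, lineage, grid) {
  cn <- ifelse(grid$chrom %in% AUTOSOMES, 2,
               ifelse(grid$chrom == "X", if (truth$sex == "XX") 2 else 1,
                      if (truth$sex == "XY") 1 else 0))
  ev <- truth$events
  if (nrow(ev) > 0) {
    keep <- ev$lineage == "both" | ev$lineage == lineage
    for (k in which(keep)) {
      on_chrom <- grid$chrom == ev$chrom[k]
      if (ev$kind[k] == "whole") sel <- on_chrom
      else sel <- on_chrom & grid$start >= ev$start_mb[k] * 1e6 &
        grid$start < ev$end_mb[k] * 1e6
      cn[sel] <- cn[sel] + ev$delta[k] * ev$fraction[k]
    }
  }
  pmax(cn, 0)
}

# Copy-number mixture seen by one assay; medium mixes in a maternal euploid
# XX contaminant at fraction f.
assay_copy_number <- function(truth, assay, grid, config, contamination = 0) {
  icm <- lineage_copy_number(truth, "icm", grid)
  te <- lineage_copy_number(truth, "te", grid)
  if (assay == "whole") {
    w <- config$whole_icm_fraction
    w * icm + (1 - w) * te
  } else if (assay == "TE") {
    te
  } else if (assay == "medium") {
    m <- config$medium_icm_fraction
    emb <- m * icm + (1 - m) * te
    maternal <- ifelse(grid$chrom == "Y", 0, 2)
    (1 - contamination) * emb + contamination * maternal
  } else stop("unknown assay label: ", assay, call. = FALSE)
}

gc_bias_curve <- function(gc, strength) {
  pmax(0.1, 1 - strength * (gc - 0.42)^2)
}

#' Expected (noise-free) bin counts for one sample
#'
#' The mean structure of the simulator: useful for noiseless-limit checks
#' and for verifying that normalization removes exactly the biases the
#' generator injects.
#'
#' @inheritParams simulate_counts
#' @param contamination Maternal fraction for `assay = "medium"` (fixed, not
#'   drawn).
#' @return Numeric vector of expected counts per grid bin (sums to `depth`).
#' @export
expected_counts <- function(truth, assay, grid, config, contamination = 0) {
  if (assay == "blank") {
    w <- (grid$end - grid$start)
    return(config$depth * config$blank_depth_fraction * w / sum(w))
  }
  cn <- assay_copy_number(truth, assay, grid, config, contamination)
  g <- gc_bias_curve(grid$gc, config$gc_bias_strength)
  w <- (grid$end - grid$start) / attr(grid, "bin_size") * (cn / 2) * g
  config$depth * w / sum(w)
}

#' Simulate one sample's binned read counts
#'
#' @param truth An `embryo_truth` from [simulate_truth()].
#' @param assay `"whole"`, `"TE"`, `"medium"` or `"blank"`.
#' @param grid A [build_bin_grid()] grid.
#' @param config A [sim_config()].
#' @param seed Optional seed for a self-contained deterministic draw; when
#'   `NULL` the current RNG stream is used (as inside [simulate_cohort()]).
#' @param dispersion Override of the assay's dispersion (used for QC-failure
#'   samples).
#' @param contamination Maternal fraction for medium; drawn from
#'   `Beta(contamination_beta)` when `NULL`.
#' @return A `count_table`; for medium the realized maternal fraction is in
#'   `attr(x, "contamination")`.
#' @export
simulate_counts <- function(truth, assay, grid, config, seed = NULL,
                            dispersion = NULL, contamination = NULL) {
  assay <- match.arg(assay, c("whole", "TE", "medium", "blank"))
  with_seed(seed, {
    if (assay == "medium" && is.null(contamination))
      contamination <- stats::rbeta(1, config$contamination_beta[1],
                                    config$contamination_beta[2])
    mu <- expected_counts(truth, assay, grid, config,
                          contamination = contamination %||% 0)
    phi <- dispersion %||% unname(config$dispersion[assay])
    counts <- if (phi <= 0) stats::rpois(length(mu), mu)
              else stats::rnbinom(length(mu), mu = mu, size = 1 / phi)
    ct <- count_table(counts, grid,
                      sample_id = paste(truth$embryo_id, assay, sep = "_"),
                      assay = assay, seed = seed)
    attr(ct, "contamination") <- if (assay == "medium") contamination else NA
    ct
  })
}

#' Karyotype string implied by a truth's events in one lineage
#'
#' @param truth An `embryo_truth`.
#' @param lineage `"icm"` or `"te"`.
#' @return Canonical karyotype string.
#' @export
truth_karyotype <- function(truth, lineage = "te") {
  ev <- truth$events
  ev <- ev[ev$lineage == "both" | ev$lineage == lineage, , drop = FALSE]
  count <- 46L
  events <- empty_events()
  if (nrow(ev) > 0) {
    full_whole <- ev$kind == "whole" & ev$fraction >= 1
    count <- count + sum(ev$delta[full_whole])
    events <- data.frame(
      chrom = ev$chrom, sign = ifelse(ev$delta > 0, "+", "-"),
      arm = ev$arm,
      band_from = ifelse(ev$kind == "segmental",
                         ifelse(ev$arm == "p", "pter", paste0(ev$arm, "11")),
                         NA_character_),
      band_to = ifelse(ev$kind == "segmental",
                       ifelse(ev$arm == "p", paste0(ev$arm, "11"), "qter"),
                       NA_character_),
      span_mb = ifelse(ev$kind == "segmental",
                       round(ev$end_mb - ev$start_mb), NA_real_),
      mosaic = ev$fraction < 1, stringsAsFactors = FALSE)
  }
  format_karyotype(structure(list(count = count, sex = truth$sex,
                                  events = events), class = "karyotype"))
}

#' Simulate a full trio cohort
#'
#' For each embryo, draws a truth and three samples (whole, TE, medium); a
#' random `qc_fail_rate` fraction of samples is drawn with inflated
#' dispersion so that their read-density CV exceeds the QC threshold,
#' emulating amplification failures.
#'
#' @param config A [sim_config()] (its `seed` drives everything).
#' @param grid A bin grid (default: packaged hg19-like 1 Mb grid).
#' @param out_dir Optional directory: count tables, the truth manifest and
#'   the resolved config (YAML) are written there.
#' @return List with `truths`, `counts` (named list of `count_table`s) and
#'   `manifest` (one row per sample: ids, assay, truth category, per-lineage
#'   karyotypes, contamination fraction, QC-failure flag, seed).
#' @export
simulate_cohort <- function(config, grid = build_bin_grid(), out_dir = NULL) {
  truths <- simulate_truth(config)
  counts <- list()
  rows <- list()
  with_seed(config$seed + 1L, {
    for (tr in truths) {
      for (assay in c("whole", "TE", "medium")) {
        fail <- stats::runif(1) < config$qc_fail_rate
        ct <- simulate_counts(tr, assay, grid, config,
                              dispersion = if (fail)
                                config$qc_fail_dispersion else NULL)
        sid <- attr(ct, "sample_id")
        counts[[sid]] <- ct
        rows[[length(rows) + 1]] <- data.frame(
          embryo_id = tr$embryo_id, sample_id = sid, assay = assay,
          sex = tr$sex, category = tr$category,
          karyotype_icm = truth_karyotype(tr, "icm"),
          karyotype_te = truth_karyotype(tr, "te"),
          contamination = attr(ct, "contamination"),
          qc_fail_truth = fail, seed = config$seed,
          stringsAsFactors = FALSE)
      }
    }
  })
  manifest <- if (length(rows)) do.call(rbind, rows) else
    data.frame(embryo_id = character(), sample_id = character(),
               assay = character(), sex = character(), category = character(),
               karyotype_icm = character(), karyotype_te = character(),
               contamination = numeric(), qc_fail_truth = logical(),
               seed = integer(), stringsAsFactors = FALSE)
  res <- list(truths = truths, counts = counts, manifest = manifest)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (sid in names(counts))
      write_count_table(counts[[sid]], file.path(out_dir,
                                                 paste0(sid, ".tsv")))
    utils::write.table(manifest, file.path(out_dir, "manifest.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    yaml::write_yaml(unclass(config), file.path(out_dir, "config.yaml"))
  }
  res
}
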