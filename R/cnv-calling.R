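# From raw bin counts to a QC-gated, segmented copy-number profile:
# CV quality control -> GC (lowess) normalization -> reference-panel
# normalization -> per-chromosome CBS.

#' Parameters of the copy-number calling chain
#'
#' @param cv_threshold QC: a sample passes iff its read-density CV is
#'   strictly below this (default 0.2).
#' @param alpha,nperm,min_bins,merge_tol CBS parameters, see
#'   [cbs_segment()]. Defaults resolve events of a few Mb at 2M reads.
#' @param lowess_span,lowess_iter Span and robustness iterations of the GC
#'   lowess fit.
#' @param ref_trim Trimming fraction of the panel trimmed mean.
#' @param ref_min Bins whose reference density falls below this are masked.
#' @param seed Seed for the CBS permutation tests.
#' @return A `cnv_params` list.
#' @export
cnv_params <- function(cv_threshold = 0.2, alpha = 0.01, nperm = 1000,
                       min_bins = 3, merge_tol = 0.3, lowess_span = 0.3,
                       lowess_iter = 2, ref_trim = 0.1, ref_min = 0.1,
                       seed = NULL) {
  structure(list(cv_threshold = cv_threshold, alpha = alpha, nperm = nperm,
                 min_bins = min_bins, merge_tol = merge_tol,
                 lowess_span = lowess_span, lowess_iter = lowess_iter,
                 ref_trim = ref_trim, ref_min = ref_min, seed = seed),
            class = "cnv_params")
}

# raw read density (counts per Mb-equivalent of bin length)
raw_density <- function(counts, grid) {
  counts / ((grid$end - grid$start) / attr(grid, "bin_size"))
}

#' Coefficient of variation of read density
#'
#' CV = sd(density) / mean(density) over usable autosomal bins, computed on
#' the raw (pre-normalization) density; sex chromosomes are excluded so a
#' male X does not inflate the CV. Because the CV gauges amplification
#' uniformity rather than biology, each autosome's density is scaled by its
#' chromosome mean first, which makes the measure invariant to
#' whole-chromosome aneuploidy (an aneuploid genome amplified evenly is a
#' successful amplification). A CV below the threshold (strictly) marks a
#' successful amplification; a zero total count, or a chromosome with no
#' reads at all, yields `Inf`.
#'
#' @param x A `count_table`.
#' @param grid The matching `bin_grid`.
#' @return The CV as a single number.
#' @export
compute_cv <- function(x, grid) {
  use <- grid$mask & grid$chrom %in% AUTOSOMES
  if (sum(use) < 2) stop("need at least 2 usable autosomal bins",
                         call. = FALSE)
  d <- raw_density(x$count, grid)[use]
  if (sum(d) <= 0) return(Inf)
  ch <- grid$chrom[use]
  means <- tapply(d, ch, mean)
  if (any(means <= 0)) return(Inf)
  scaled <- d / as.numeric(means[ch])
  stats::sd(scaled) / mean(scaled)
}

#' GC-normalize bin counts into a density vector
#'
#' Fits a robust lowess of raw density on GC fraction over usable bins,
#' rescales the fit to mean 1, and divides it out, removing any smooth
#' GC-only trend. Degenerate GC (all bins equal) makes this a no-op. The
#' result is rescaled to mean 1 over usable bins.
#'
#' @inheritParams compute_cv
#' @param params A [cnv_params()].
#' @return Numeric density per bin (masked bins are computed but carry no
#'   weight in the scaling).
#' @export
gc_normalize <- function(x, grid, params = cnv_params()) {
  d0 <- raw_density(x$count, grid)
  use <- grid$mask
  ghat <- rep(1, nrow(grid))
  # extreme bins (amplification artifacts, dead bins) are excluded from the
  # bias fit but still normalized
  med <- stats::median(d0[use])
  fit_use <- use & d0 <= 5 * med & d0 >= med / 5
  if (sum(fit_use) < 10) fit_use <- use
  if (stats::sd(grid$gc[use]) > 0) {
    fit <- stats::lowess(grid$gc[fit_use], d0[fit_use],
                         f = params$lowess_span,
                         iter = params$lowess_iter)
    pred <- stats::approx(fit$x, fit$y, xout = grid$gc, rule = 2,
                          ties = mean)$y
    pred <- pred / mean(pred[use])
    ghat <- pmax(pred, 0.1)
  }
  dens <- d0 / ghat
  dens / mean(dens[use])
}

#' Build a reference panel of euploid densities
#'
#' Simulates `n` euploid XX whole-embryo samples at the configured depth and
#' GC-normalizes each; the panel is the per-bin density matrix used by
#' [reference_normalize()]. A fixed seed makes the default panel fully
#' reproducible; users may substitute a panel built from their own euploid
#' samples.
#'
#' @param grid A `bin_grid`.
#' @param n Panel size (at least 20 recommended).
#' @param config A [sim_config()]; depth/dispersion/GC bias of the panel
#'   samples.
#' @param seed Seed of the panel simulation.
#' @return Numeric matrix, bins x samples.
#' @export
build_reference_panel <- function(grid, n = 30,
                                  config = sim_config(seed = 1L),
                                  seed = 20210101L) {
  truth <- new_truth("REF", "XX", "euploid", empty_events())
  with_seed(seed, {
    vapply(seq_len(n), function(i) {
      ct <- simulate_counts(truth, "whole", grid, config)
      gc_normalize(ct, grid)
    }, numeric(nrow(grid)))
  })
}

# memoized default panel (keyed by grid fingerprint)
.panel_cache <- new.env(parent = emptyenv())

default_reference_panel <- function(grid) {
  key <- paste0("p", nrow(grid), "_", sum(grid$mask))
  if (is.null(.panel_cache[[key]]))
    .panel_cache[[key]] <- build_reference_panel(grid)
  .panel_cache[[key]]
}

#' Normalize a density vector against a reference panel
#'
#' Divides by the panel's per-bin trimmed-mean density (rescaled to mean 1)
#' and doubles, so a sample identical to the panel mean sits at copy number
#' 2 everywhere. Bins whose reference density is below `ref_min` are masked
#' (`NA`), which removes dead bins and, with an XX panel, the Y chromosome.
#'
#' @param density Per-bin density from [gc_normalize()].
#' @param panel Bins x samples matrix from [build_reference_panel()], or a
#'   `bin_grid`-matched matrix of your own euploid samples.
#' @param grid The `bin_grid`.
#' @inheritParams gc_normalize
#' @return Per-bin relative copy number (euploid = 2), `NA` where masked.
#' @export
reference_normalize <- function(density, panel, grid,
                                params = cnv_params()) {
  if (is.null(panel) || length(panel) == 0 || NCOL(panel) == 0)
    stop("empty reference panel; use build_reference_panel() to generate ",
         "the packaged simulated euploid panel", call. = FALSE)
  panel <- as.matrix(panel)
  stopifnot(nrow(panel) == nrow(grid), length(density) == nrow(grid))
  ref <- apply(panel, 1, mean, trim = params$ref_trim)
  ref <- ref / mean(ref[grid$mask])
  cn <- 2 * density / ref
  cn[ref < params$ref_min | !grid$mask] <- NA_real_
  pmax(cn, 0)
}

#' Call a full copy-number profile from raw counts
#'
#' Runs the whole chain: CV QC, GC normalization, reference normalization
#' and per-chromosome CBS; then infers sex from the X level and Y density.
#' A QC failure yields a profile with `qc_pass = FALSE` and no segments.
#'
#' @inheritParams compute_cv
#' @param panel Reference panel matrix; `NULL` uses the packaged simulated
#'   euploid panel for this grid (built on first use from a fixed seed).
#' @param params A [cnv_params()].
#' @return A `cn_profile`: list with `cv`, `qc_pass`, `density`, `cn`,
#'   `segments` (chrom, start_bp, end_bp, n_bins, mean_cn, p), `sex`,
#'   `sample_id`, `assay`, `params`.
#' @export
call_profile <- function(x, grid, panel = NULL, params = cnv_params()) {
  cv <- compute_cv(x, grid)
  prof <- structure(list(grid = grid, cv = cv,
                         qc_pass = is.finite(cv) & cv < params$cv_threshold,
                         density = NULL, cn = NULL,
                         segments = NULL, sex = NA_character_,
                         sample_id = attr(x, "sample_id"),
                         assay = attr(x, "assay"), params = params),
                    class = "cn_profile")
  if (!prof$qc_pass) return(prof)
  if (is.null(panel)) panel <- default_reference_panel(grid)
  prof$density <- gc_normalize(x, grid, params)
  prof$cn <- reference_normalize(prof$density, panel, grid, params)
  segs <- lapply(unique(grid$chrom), function(ch) {
    idx <- which(grid$chrom == ch & !is.na(prof$cn))
    if (length(idx) < params$min_bins) return(NULL)
    s <- cbs_segment(prof$cn[idx], alpha = params$alpha,
                     nperm = params$nperm, min_bins = params$min_bins,
                     merge_tol = params$merge_tol, seed = params$seed)
    data.frame(chrom = ch, start_bp = grid$start[idx[s$start]],
               end_bp = grid$end[idx[s$end]], n_bins = s$n_bins,
               mean_cn = s$mean, p = s$p, stringsAsFactors = FALSE)
  })
  prof$segments <- do.call(rbind, segs)
  rownames(prof$segments) <- NULL
  prof$sex <- infer_sex(prof)
  prof
}

#' @export
print.cn_profile <- function(x, ...) {
  cat(sprintf("cn_profile %s [%s]: CV %.3f (%s)\n", x$sample_id, x$assay,
              x$cv, if (x$qc_pass) "QC pass" else "QC FAIL"))
  if (!is.null(x$segments)) {
    dev <- x$segments[abs(x$segments$mean_cn - 2) >= 0.3 &
                        x$segments$chrom %in% AUTOSOMES, ]
    cat(sprintf("  sex %s, %d segments (%d deviating autosomal)\n",
                x$sex, nrow(x$segments), nrow(dev)))
  }
  invisible(x)
}

#' Write a profile's segment table and QC sidecar
#'
#' Segments go to `<path>.tsv`, QC metadata (CV, pass flag, parameters,
#' seed) to `<path>.json`.
#'
#' @param prof A `cn_profile`.
#' @param path Output path stem.
#' @export
write_profile <- function(prof, path) {
  if (!is.null(prof$segments))
    utils::write.table(prof$segments, paste0(path, ".tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  meta <- list(sample_id = prof$sample_id, assay = prof$assay,
               cv = prof$cv, qc_pass = prof$qc_pass, sex = prof$sex,
               params = prof$params[c("cv_threshold", "alpha", "nperm",
                                      "min_bins", "merge_tol")],
               seed = prof$params$seed)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(path)
}
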