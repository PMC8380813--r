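# Ploidy classification: copy-number profile -> per-chromosome calls ->
# embryo category (euploid / abnormal / MAC), prioritization group (A/B/C)
# and karyotype string.

#' Classification thresholds
#'
#' Deviations are measured per segment as `d = mean_cn - baseline`, scaled
#' by `baseline / 2` so the male X uses the same bands. `|d|` at or above
#' `mosaic_high` is a full event, between `mosaic_low` and `mosaic_high` a
#' mosaic with estimated fraction `|d|` (single-copy change), below
#' `mosaic_low` euploid. Deviating segments covering at least `whole_cov`
#' of a chromosome make a whole-chromosome event; otherwise segments of at
#' least `min_seg_mb` are reported as segmental. An embryo with `mac_min`
#' or more abnormal chromosomes (autosomes + X) carries MAC.
#'
#' @param mosaic_low,mosaic_high Mosaic band on the scaled deviation.
#' @param whole_cov Coverage fraction distinguishing whole-chromosome from
#'   segmental events.
#' @param min_seg_mb Minimum reportable segmental span (Mb).
#' @param mac_min Abnormal-chromosome count defining MAC.
#' @return A `ploidy_params` list.
#' @export
ploidy_params <- function(mosaic_low = 0.3, mosaic_high = 0.7,
                          whole_cov = 0.8, min_seg_mb = 10, mac_min = 5L) {
  stopifnot(mosaic_low > 0, mosaic_low < mosaic_high, whole_cov > 0.5,
            mac_min >= 1)
  structure(list(mosaic_low = mosaic_low, mosaic_high = mosaic_high,
                 whole_cov = whole_cov, min_seg_mb = min_seg_mb,
                 mac_min = as.integer(mac_min)), class = "ploidy_params")
}

#' Infer embryo sex from a copy-number profile
#'
#' XY when the median X copy number is below 1.5 and the Y read density sits
#' above a blank-level floor; XX otherwise. When the X level is borderline
#' (1.4-1.6) and conflicts with the Y evidence, the result is flagged
#' ambiguous and the Y evidence decides.
#'
#' @param prof A `cn_profile` with `cn` and `density` filled in.
#' @param y_floor Median Y density (mean-1 scale) above which Y is present.
#' @return `"XX"` or `"XY"`, with attribute `ambiguous`.
#' @export
infer_sex <- function(prof, y_floor = 0.1) {
  grid <- prof$grid
  xi <- grid$chrom == "X" & !is.na(prof$cn)
  yi <- grid$chrom == "Y" & grid$mask
  if (!any(xi) || !any(yi)) return(NA_character_)
  x_cn <- stats::median(prof$cn[xi])
  y_present <- stats::median(prof$density[yi]) > y_floor
  sex <- if (y_present) "XY" else "XX"
  ambiguous <- (x_cn >= 1.4 && x_cn <= 1.6) &&
    ((x_cn < 1.5) != y_present)
  attr(sex, "ambiguous") <- ambiguous
  sex
}

#' Call one chromosome from its segments
#'
#' @param segs Segment rows of one chromosome (columns `start_bp`, `end_bp`,
#'   `n_bins`, `mean_cn`).
#' @param chrom Chromosome label.
#' @param baseline Expected copy number (2 for autosomes and female X, 1
#'   for male X/Y).
#' @param chrom_length Chromosome length in bp (arm assignment of
#'   segmental events).
#' @param params A [ploidy_params()].
#' @return Data.frame of events for the chromosome (zero rows = euploid):
#'   columns `chrom`, `status`, `sign`, `mosaic`, `level` (banded mosaic
#'   fraction; 1 = full), `d_hat` (continuous scaled deviation, the raw
#'   mosaic-fraction estimator), `span_mb`, `arm`.
#' @export
call_chromosome <- function(segs, chrom, baseline = 2,
                            chrom_length = NA_real_,
                            params = ploidy_params()) {
  no_event <- data.frame(chrom = character(), status = character(),
                         sign = character(), mosaic = logical(),
                         level = numeric(), d_hat = numeric(),
                         span_mb = numeric(), arm = character(),
                         stringsAsFactors = FALSE)
  if (is.null(segs) || nrow(segs) == 0) return(no_event)
  scale <- baseline / 2
  d <- segs$mean_cn - baseline
  dev <- abs(d) >= params$mosaic_low * scale
  if (!any(dev)) return(no_event)
  total_bins <- sum(segs$n_bins)
  out <- list()
  for (sgn in c(1, -1)) {
    grp <- dev & sign(d) == sgn
    if (!any(grp)) next
    coverage <- sum(segs$n_bins[grp]) / total_bins
    if (coverage >= params$whole_cov) {
      dd <- abs(stats::weighted.mean(d[grp], segs$n_bins[grp])) / scale
      mosaic <- dd < params$mosaic_high
      out[[length(out) + 1]] <- data.frame(
        chrom = chrom,
        status = paste0(if (mosaic) "mosaic_" else "",
                        if (sgn > 0) "gain" else "loss"),
        sign = if (sgn > 0) "+" else "-", mosaic = mosaic,
        level = if (mosaic) min(dd, 1) else 1, d_hat = min(dd, 1),
        span_mb = NA_real_, arm = NA_character_, stringsAsFactors = FALSE)
    } else {
      for (k in which(grp)) {
        span_mb <- (segs$end_bp[k] - segs$start_bp[k]) / 1e6
        if (span_mb < params$min_seg_mb) next
        dd <- abs(d[k]) / scale
        mosaic <- dd < params$mosaic_high
        mid <- (segs$start_bp[k] + segs$end_bp[k]) / 2
        out[[length(out) + 1]] <- data.frame(
          chrom = chrom,
          status = paste0("segmental_", if (sgn > 0) "gain" else "loss"),
          sign = if (sgn > 0) "+" else "-", mosaic = mosaic,
          level = if (mosaic) min(dd, 1) else 1, d_hat = min(dd, 1),
          span_mb = span_mb,
          arm = if (!is.na(chrom_length) && mid >= chrom_length / 2)
            "q" else "p",
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0) no_event else do.call(rbind, out)
}

#' Classify an embryo sample from its copy-number profile
#'
#' Calls every autosome and X (Y is called but report-only), counts
#' abnormal chromosomes, assigns the category (euploid / abnormal / MAC
#' when `>= mac_min` chromosomes are abnormal), the prioritization group
#' (A = euploid, B = abnormal, C = MAC) and assembles the karyotype string.
#'
#' @param prof A `cn_profile` from [call_profile()].
#' @param params A [ploidy_params()].
#' @param embryo_id Optional embryo identifier (defaults to the profile's
#'   sample id).
#' @return An `embryo_call`: list with `embryo_id`, `assay`, `sex`,
#'   `events` (all events incl. Y), `n_abnormal`, `category`, `group`,
#'   `karyotype`, `qc_pass`.
#' @export
classify_embryo <- function(prof, params = ploidy_params(),
                            embryo_id = NULL) {
  embryo_id <- embryo_id %||% sub("_(whole|TE|medium|blank)$", "",
                                  prof$sample_id %||% "embryo")
  out <- structure(list(embryo_id = embryo_id, assay = prof$assay,
                        sex = prof$sex, events = NULL,
                        n_abnormal = NA_integer_, category = NA_character_,
                        group = NA_character_, karyotype = NA_character_,
                        qc_pass = prof$qc_pass), class = "embryo_call")
  if (!prof$qc_pass) return(out)
  grid <- prof$grid
  lens <- attr(grid, "chrom_lengths")
  called <- unique(prof$segments$chrom)
  needed <- intersect(c(AUTOSOMES, "X"), unique(grid$chrom))
  if (!all(needed %in% called)) {  # no-call propagates as QC failure
    out$qc_pass <- FALSE
    return(out)
  }
  ev <- lapply(called, function(ch) {
    is_xy <- isTRUE(prof$sex == "XY")
    if (ch == "Y" && !is_xy) return(NULL)
    baseline <- 2
    if (ch %in% c("X", "Y") && is_xy) baseline <- 1
    call_chromosome(prof$segments[prof$segments$chrom == ch, , drop = FALSE],
                    ch, baseline, lens[[ch]] %||% NA_real_, params)
  })
  events <- do.call(rbind, ev)
  out$events <- events
  countable <- events$chrom %in% c(AUTOSOMES, "X")
  out$n_abnormal <- length(unique(events$chrom[countable]))
  out$category <- if (out$n_abnormal == 0) "euploid"
    else if (out$n_abnormal >= params$mac_min) "MAC" else "abnormal"
  out$group <- c(euploid = "A", abnormal = "B", MAC = "C")[[out$category]]
  out$karyotype <- events_to_karyotype(events, prof$sex %||% "XX")
  out
}

# Assemble a canonical karyotype string from an event table.
events_to_karyotype <- function(events, sex) {
  if (is.null(events)) events <- data.frame()
  if (nrow(events) == 0)
    return(format_karyotype(structure(list(count = 46L, sex = sex,
                                           events = empty_kary_events()),
                                      class = "karyotype")))
  whole <- is.na(events$span_mb)
  count <- 46L + sum(ifelse(whole & !events$mosaic,
                            ifelse(events$sign == "+", 1L, -1L), 0L))
  ke <- data.frame(
    chrom = events$chrom, sign = events$sign,
    arm = ifelse(whole, NA_character_, events$arm),
    band_from = ifelse(whole, NA_character_,
                       ifelse(events$arm == "q", "q", "pter")),
    band_to = ifelse(whole, NA_character_,
                     ifelse(events$arm == "q", "qter", "p")),
    span_mb = ifelse(whole, NA_real_, round(events$span_mb)),
    mosaic = events$mosaic, stringsAsFactors = FALSE)
  format_karyotype(structure(list(count = count, sex = sex, events = ke),
                             class = "karyotype"))
}

empty_kary_events <- function() {
  data.frame(chrom = character(), sign = character(), arm = character(),
             band_from = character(), band_to = character(),
             span_mb = numeric(), mosaic = logical(), stringsAsFactors = FALSE)
}

#' @export
print.embryo_call <- function(x, ...) {
  cat(sprintf("embryo_call %s [%s]: %s\n", x$embryo_id, x$assay,
              if (!x$qc_pass) "QC FAIL"
              else sprintf("%s (group %s, %d abnormal) %s", x$category,
                           x$group, x$n_abnormal, x$karyotype)))
  invisible(x)
}

#' Flatten embryo calls into the interchange calls table
#'
#' One row per sample with embryo id, assay, sex, QC flag, abnormal count,
#' category, group, karyotype and one status column per chromosome
#' (`chr1`..`chrX`, `chrY`), encoded as `status:level`.
#'
#' @param calls List of `embryo_call` objects.
#' @return A data.frame; the format consumed by the concordance engine.
#' @export
calls_table <- function(calls) {
  rows <- lapply(calls, function(cl) {
    row <- data.frame(embryo_id = cl$embryo_id, assay = cl$assay,
                      sex = cl$sex %||% NA_character_,
                      qc_pass = cl$qc_pass,
                      n_abnormal = cl$n_abnormal,
                      category = cl$category, group = cl$group,
                      karyotype = cl$karyotype, stringsAsFactors = FALSE)
    for (ch in c(AUTOSOMES, "X", "Y")) {
      ev <- if (!is.null(cl$events)) cl$events[cl$events$chrom == ch, ,
                                               drop = FALSE]
            else NULL
      row[[paste0("chr", ch)]] <- if (is.null(ev) || nrow(ev) == 0) "euploid"
        else paste(sprintf("%s:%.2f", ev$status, ev$level), collapse = ";")
    }
    row
  })
  do.call(rbind, rows)
}
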