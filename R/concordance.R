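# Diagnostic concordance engine: confusion tables vs the whole-embryo gold
# standard, Wilson score intervals, Cohen's kappa with its asymptotic CI,
# the exact McNemar test, chromosome-set Venn partitions, prioritization
# group tables and secondary-validation reclassification.

#' Wilson score confidence interval for a binomial proportion
#'
#' @param k Number of successes.
#' @param n Number of trials (>= 1).
#' @param conf Confidence level (default 0.95).
#' @return Named numeric `c(lo, hi)` in `[0, 1]`; the point estimate `k/n`
#'   always lies inside.
#' @export
#' @examples
#' round(wilson_ci(86, 96) * 100, 1)  # 81.9, 94.2
wilson_ci <- function(k, n, conf = 0.95) {
  stopifnot(n >= 1, k >= 0, k <= n)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- k / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  # at k = 0 / k = n the bound is exactly 0 / 1 analytically
  c(lo = if (k == 0) 0 else max(0, centre - half),
    hi = if (k == n) 1 else min(1, centre + half))
}

#' Cross-tabulate binary abnormal calls against a gold standard
#'
#' "Positive" means chromosomally abnormal. Embryos lacking either call are
#' dropped and counted in `n_excluded`.
#'
#' @param calls_assay,calls_gold Logical vectors (TRUE = abnormal) named by
#'   embryo id.
#' @return A `confusion_table`: list with `tp`, `fp`, `fn`, `tn`,
#'   `n`, `n_excluded`.
#' @export
confusion <- function(calls_assay, calls_gold) {
  stopifnot(is.logical(calls_assay), is.logical(calls_gold),
            !is.null(names(calls_assay)), !is.null(names(calls_gold)))
  ids <- intersect(names(calls_assay)[!is.na(calls_assay)],
                   names(calls_gold)[!is.na(calls_gold)])
  if (length(ids) == 0) stop("no embryos with both calls", call. = FALSE)
  a <- calls_assay[ids]
  g <- calls_gold[ids]
  structure(list(tp = sum(a & g), fp = sum(a & !g), fn = sum(!a & g),
                 tn = sum(!a & !g), n = length(ids),
                 n_excluded = length(union(names(calls_assay),
                                           names(calls_gold))) - length(ids)),
            class = "confusion_table")
}

#' @export
print.confusion_table <- function(x, ...) {
  cat(sprintf("confusion (n=%d): tp=%d fp=%d fn=%d tn=%d\n",
              x$n, x$tp, x$fp, x$fn, x$tn))
  invisible(x)
}

#' Diagnostic summary with Wilson intervals
#'
#' Sensitivity, specificity, NPV and PPV with Wilson score confidence
#' intervals. A metric with a zero denominator is reported as `NA`
#' (undefined), never as zero.
#'
#' @param ct A [confusion()] table.
#' @param conf Confidence level.
#' @return A `diagnostic_summary` data.frame: metric, estimate, lo, hi,
#'   k, n.
#' @export
diagnostic_summary <- function(ct, conf = 0.95) {
  stopifnot(inherits(ct, "confusion_table"))
  one <- function(k, n) {
    if (n == 0) return(c(NA_real_, NA_real_, NA_real_))
    c(k / n, wilson_ci(k, n, conf))
  }
  rows <- rbind(sensitivity = c(one(ct$tp, ct$tp + ct$fn), ct$tp,
                                ct$tp + ct$fn),
                specificity = c(one(ct$tn, ct$tn + ct$fp), ct$tn,
                                ct$tn + ct$fp),
                npv = c(one(ct$tn, ct$tn + ct$fn), ct$tn, ct$tn + ct$fn),
                ppv = c(one(ct$tp, ct$tp + ct$fp), ct$tp, ct$tp + ct$fp))
  out <- data.frame(metric = rownames(rows), estimate = rows[, 1],
                    lo = rows[, 2], hi = rows[, 3], k = rows[, 4],
                    n = rows[, 5], row.names = NULL,
                    stringsAsFactors = FALSE)
  class(out) <- c("diagnostic_summary", "data.frame")
  out
}

#' Exact test for paired binary data (exact McNemar)
#'
#' With `b` and `c` the two discordant counts, the two-sided p-value is
#' `min(1, 2 * P(X <= min(b, c)))` for `X ~ Binomial(b + c, 1/2)`; `b + c
#' = 0` gives p = 1. The stratum (which embryos are paired, e.g. the
#' gold-positive subset for a sensitivity comparison) is chosen by the
#' caller.
#'
#' @param outcomes_a,outcomes_b Paired logical vectors of equal length.
#' @return The exact two-sided p-value.
#' @export
exact_paired_test <- function(outcomes_a, outcomes_b) {
  stopifnot(length(outcomes_a) == length(outcomes_b),
            is.logical(outcomes_a), is.logical(outcomes_b))
  b <- sum(outcomes_a & !outcomes_b)
  cc <- sum(!outcomes_a & outcomes_b)
  if (b + cc == 0) return(1.0)
  min(1, 2 * stats::pbinom(min(b, cc), b + cc, 0.5))
}

#' Cohen's kappa with asymptotic confidence interval
#'
#' Observed agreement `po`, chance agreement `pe` from the marginals,
#' `kappa = (po - pe) / (1 - pe)`, and a 95% CI from the
#' Fleiss-Cohen-Everitt asymptotic variance, clipped to `[-1, 1]`.
#' Degenerate marginals (`pe = 1`) leave kappa undefined.
#'
#' @param x A [confusion()] table or a square agreement matrix (rows =
#'   rater 1, columns = rater 2).
#' @param conf Confidence level.
#' @return An `agreement_result`: list with `po`, `pe`, `kappa`,
#'   `kappa_ci`, `se`, `n`.
#' @export
cohen_kappa <- function(x, conf = 0.95) {
  tab <- if (inherits(x, "confusion_table"))
    matrix(c(x$tp, x$fp, x$fn, x$tn), 2, 2, byrow = TRUE,
           dimnames = list(c("+", "-"), c("+", "-")))
  else as.matrix(x)
  stopifnot(nrow(tab) == ncol(tab), all(tab >= 0))
  n <- sum(tab)
  stopifnot(n > 0)
  p <- tab / n
  po <- sum(diag(p))
  ri <- rowSums(p)
  cj <- colSums(p)
  pe <- sum(ri * cj)
  if (1 - pe < 1e-12)
    return(structure(list(po = po, pe = pe, kappa = NA_real_,
                          kappa_ci = c(NA_real_, NA_real_), se = NA_real_,
                          n = n), class = "agreement_result"))
  kappa <- (po - pe) / (1 - pe)
  # Fleiss, Cohen & Everitt asymptotic variance
  A <- sum(diag(p) * (1 - (ri + cj) * (1 - kappa))^2)
  off <- which(row(p) != col(p), arr.ind = TRUE)
  B <- (1 - kappa)^2 * sum(p[off] * (cj[off[, 1]] + ri[off[, 2]])^2)
  C <- (kappa - pe * (1 - kappa))^2
  se <- sqrt(max(0, (A + B - C) / (n * (1 - pe)^2)))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  ci <- pmax(-1, pmin(1, kappa + c(-1, 1) * z * se))
  structure(list(po = po, pe = pe, kappa = kappa,
                 kappa_ci = c(lo = ci[1], hi = ci[2]), se = se, n = n),
            class = "agreement_result")
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf("agreement: po=%.3f kappa=%.3f (%.3f-%.3f)\n", x$po,
              x$kappa, x$kappa_ci[1], x$kappa_ci[2]))
  invisible(x)
}

# map a per-chromosome status string onto an agreement class
status_class <- function(status, collapse_mosaic = TRUE) {
  s <- sub(":.*$", "", vapply(strsplit(status, ";"), `[`, character(1), 1))
  if (collapse_mosaic) {
    ifelse(grepl("gain", s), "gain", ifelse(grepl("loss", s), "loss", s))
  } else s
}

#' Three-way chromosome-set agreement (Venn partition)
#'
#' Treats each autosome or chromosome X of each embryo as one set and
#' counts, over `23 * n` sets, how the three assays agree pairwise on the
#' ploidy class. By default mosaic and full events of the same direction
#' count as consistent. MAC embryos must be pre-filtered by the caller and
#' are rejected here.
#'
#' @param calls_te,calls_nics,calls_whole Data.frames with `embryo_id` and
#'   `chr1`..`chr22`, `chrX` status columns (the [calls_table()] format).
#' @param collapse_mosaic Count mosaic and full events of the same sign as
#'   the same class?
#' @param mac_min Abnormal-chromosome count that defines MAC.
#' @return A `chrom_set_venn`: list with `n_embryos`, `n_sets` and
#'   `regions` (all_three, te_nics_only, nics_whole_only, te_whole_only,
#'   none), which partition `n_sets`.
#' @export
chrom_set_venn <- function(calls_te, calls_nics, calls_whole,
                           collapse_mosaic = TRUE, mac_min = 5L) {
  chroms <- paste0("chr", c(AUTOSOMES, "X"))
  ids <- Reduce(intersect, list(calls_te$embryo_id, calls_nics$embryo_id,
                                calls_whole$embryo_id))
  cls <- function(df) {
    df <- df[match(ids, df$embryo_id), chroms, drop = FALSE]
    m <- vapply(chroms, function(ch) status_class(df[[ch]], collapse_mosaic),
                character(length(ids)))
    matrix(m, nrow = length(ids), dimnames = list(ids, chroms))
  }
  te <- cls(calls_te)
  ni <- cls(calls_nics)
  wh <- cls(calls_whole)
  n_abn <- pmax(rowSums(te != "euploid"), rowSums(ni != "euploid"),
                rowSums(wh != "euploid"))
  if (any(n_abn >= mac_min))
    stop("MAC embryo(s) present; filter them out before the ",
         "chromosome-set comparison", call. = FALSE)
  tn <- te == ni
  nw <- ni == wh
  tw <- te == wh
  all3 <- tn & nw
  regions <- c(all_three = sum(all3),
               te_nics_only = sum(tn & !nw),
               nics_whole_only = sum(nw & !tn),
               te_whole_only = sum(tw & !tn & !nw),
               none = sum(!tn & !nw & !tw))
  structure(list(n_embryos = length(ids),
                 n_sets = length(ids) * length(chroms),
                 regions = regions), class = "chrom_set_venn")
}

#' @export
print.chrom_set_venn <- function(x, ...) {
  cat(sprintf("chromosome sets: %d (%d embryos x 23)\n", x$n_sets,
              x$n_embryos))
  print(x$regions)
  invisible(x)
}

#' Karyotype-level concordance of two embryo calls
#'
#' Full concordance when both samples are euploid or the same chromosomes
#' are abnormal (mosaic and/or reciprocal losses and gains count as
#' concordant); partial when at least one abnormal chromosome corresponds;
#' discordant otherwise.
#'
#' @param k1,k2 `embryo_call` objects, karyotype strings, or character
#'   vectors of abnormal chromosome labels.
#' @return `"full"`, `"partial"` or `"discordant"`.
#' @export
karyotype_concordance <- function(k1, k2) {
  set1 <- abnormal_chrom_set(k1)
  set2 <- abnormal_chrom_set(k2)
  if (setequal(set1, set2)) "full"
  else if (length(intersect(set1, set2)) > 0) "partial"
  else "discordant"
}

abnormal_chrom_set <- function(k) {
  if (inherits(k, "embryo_call")) {
    if (is.null(k$events)) character(0)
    else unique(k$events$chrom[k$events$chrom %in% c(AUTOSOMES, "X")])
  } else if (inherits(k, "karyotype")) {
    unique(k$events$chrom)
  } else if (is.character(k) && length(k) == 1 && grepl("^\\[", k)) {
    unique(parse_karyotype(k)$events$chrom)
  } else unique(as.character(k))
}

#' Per-group agreement with the gold standard
#'
#' For each prioritization group of an assay (A = normal, B = abnormal,
#' C = MAC), counts how many embryos the gold standard calls normal vs
#' abnormal, and the fraction consistent with the group's own claim
#' (gold-normal for A; gold-abnormal for B and C).
#'
#' @param groups Character vector of group labels (`"A"/"B"/"C"`) named by
#'   embryo id.
#' @param gold Logical vector (TRUE = abnormal) named by embryo id.
#' @return Data.frame: group, n, n_gold_normal, n_gold_abnormal,
#'   consistent, consistent_frac.
#' @export
group_table <- function(groups, gold) {
  ids <- intersect(names(groups), names(gold))
  groups <- groups[ids]
  gold <- gold[ids]
  rows <- lapply(c("A", "B", "C"), function(g) {
    sel <- groups == g
    n <- sum(sel)
    n_abn <- sum(gold[sel])
    cons <- if (g == "A") n - n_abn else n_abn
    data.frame(group = g, n = n, n_gold_normal = n - n_abn,
               n_gold_abnormal = n_abn, consistent = cons,
               consistent_frac = if (n > 0) cons / n else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Secondary-validation reclassification within one group
#'
#' Restricted to embryos the primary assay put in group B (abnormal) or C
#' (MAC), evaluates a secondary assay against the gold standard: its
#' accuracy in the stratum, the number of embryos it re-categorizes as
#' normal, and the full cross-tabulation by gold status.
#'
#' @param primary_groups Group labels of the primary assay, named by
#'   embryo id.
#' @param secondary Logical abnormal calls of the secondary assay, named
#'   by embryo id.
#' @param gold Logical abnormal calls of the gold standard, named by
#'   embryo id.
#' @param group `"B"` or `"C"`.
#' @return List with `group`, `n`, `accuracy`, `n_recategorized`,
#'   `primary_accuracy` (the stratum's gold-abnormal fraction, i.e. the
#'   primary assay's own accuracy there) and `table` (gold x secondary
#'   counts).
#' @export
secondary_validation <- function(primary_groups, secondary, gold,
                                 group = c("B", "C")) {
  group <- match.arg(group)
  ids <- Reduce(intersect, list(names(primary_groups), names(secondary),
                                names(gold)))
  ids <- ids[primary_groups[ids] == group]
  n <- length(ids)
  if (n == 0)
    return(list(group = group, n = 0, accuracy = NA_real_,
                n_recategorized = 0, primary_accuracy = NA_real_,
                table = NULL))
  s <- secondary[ids]
  g <- gold[ids]
  tab <- table(gold = factor(ifelse(g, "abnormal", "normal"),
                             c("abnormal", "normal")),
               secondary = factor(ifelse(s, "abnormal", "normal"),
                                  c("abnormal", "normal")))
  list(group = group, n = n, accuracy = mean(s == g),
       n_recategorized = sum(!s), primary_accuracy = mean(g),
       table = tab)
}

#' Published validation-cohort call table
#'
#' The packaged per-embryo call table of a 256-embryo trio validation
#' cohort (whole embryo, TE biopsy and spent-medium NICS for each embryo),
#' reconstructed from the published group-level contingency tables; the
#' three pairwise tables, the per-group splits and the secondary-validation
#' cross-tabulations all re-derive from it exactly.
#'
#' @return Long data.frame: `embryo_id`, `assay` (`whole`/`TE`/`NICS`),
#'   `category` (`euploid`/`abnormal`/`MAC`).
#' @export
published_embryo_calls <- function() {
  path <- system.file("extdata", "embryo_calls_published.tsv",
                      package = "nicscreen", mustWork = TRUE)
  utils::read.delim(path, colClasses = "character")
}
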