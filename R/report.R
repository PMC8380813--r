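# Cohort-level concordance report: ties the statistical primitives together
# over a long calls table (embryo_id, assay, category).

assay_binary <- function(calls, assay) {
  sub <- calls[calls$assay == assay & !is.na(calls$category), ]
  stats::setNames(sub$category != "euploid", sub$embryo_id)
}

assay_groups <- function(calls, assay) {
  sub <- calls[calls$assay == assay & !is.na(calls$category), ]
  stats::setNames(c(euploid = "A", abnormal = "B", MAC = "C")[sub$category],
                  sub$embryo_id)
}

#' Full concordance report against a gold-standard assay
#'
#' Computes, for every test assay versus the gold standard: the confusion
#' table and diagnostic summary (Wilson CIs), the observed concordance with
#' its Wilson CI, and Cohen's kappa with its CI; the same between pairs of
#' test assays; everything again on the subset excluding embryos called
#' MAC by any test assay; the per-group agreement tables; and the
#' secondary-validation reclassification for groups B and C of each
#' primary/secondary assay pair.
#'
#' @param calls Long data.frame with columns `embryo_id`, `assay` and
#'   `category` (`euploid`/`abnormal`/`MAC`), e.g. [published_embryo_calls()]
#'   or the output of [pipeline_call()].
#' @param gold Label of the gold-standard assay (default `"whole"`).
#' @param assays Test assays; default: all non-gold assays present.
#' @param conf Confidence level.
#' @return A `concordance_report` list with elements `all`, `mac_excluded`
#'   (each holding `diagnostics`, `agreement`), `groups`, `secondary`,
#'   `n_embryos`, `n_mac_excluded`, `n_chrom_sets`.
#' @export
concordance_report <- function(calls, gold = "whole", assays = NULL,
                               conf = 0.95) {
  stopifnot(all(c("embryo_id", "assay", "category") %in% names(calls)))
  if (!gold %in% calls$assay)
    stop("gold assay '", gold, "' absent from the calls table",
         call. = FALSE)
  assays <- assays %||% setdiff(unique(calls$assay), gold)
  if (length(assays) < 1)
    stop("need at least one test assay besides the gold standard",
         call. = FALSE)
  gold_bin <- assay_binary(calls, gold)

  stratum <- function(ids) {
    sub <- calls[calls$embryo_id %in% ids, ]
    diag <- lapply(stats::setNames(assays, assays), function(a) {
      ct <- confusion(assay_binary(sub, a), gold_bin[ids])
      list(confusion = ct, summary = diagnostic_summary(ct, conf))
    })
    pairs <- c(lapply(stats::setNames(assays, paste0(assays, "_vs_", gold)),
                      function(a) list(a = a, b = gold)),
               if (length(assays) >= 2)
                 stats::setNames(
                   apply(utils::combn(assays, 2), 2,
                         function(p) list(a = p[2], b = p[1]),
                         simplify = FALSE),
                   apply(utils::combn(assays, 2), 2,
                         function(p) paste0(p[2], "_vs_", p[1]))))
    agree <- lapply(pairs, function(p) {
      ct <- confusion(assay_binary(sub, p$a),
                      if (p$b == gold) gold_bin[ids]
                      else assay_binary(sub, p$b)[ids])
      kp <- cohen_kappa(ct, conf)
      n_agree <- ct$tp + ct$tn
      list(confusion = ct, po = kp$po,
           po_ci = wilson_ci(n_agree, ct$n, conf), kappa = kp)
    })
    list(diagnostics = diag, agreement = agree)
  }

  all_ids <- names(gold_bin)
  mac_by_assay <- lapply(assays, function(a) {
    grp <- assay_groups(calls, a)
    names(grp)[grp == "C"]
  })
  mac_ids <- unique(unlist(mac_by_assay))
  keep_ids <- setdiff(all_ids, mac_ids)

  groups <- lapply(stats::setNames(assays, assays), function(a)
    group_table(assay_groups(calls, a), gold_bin))

  secondary <- list()
  if (length(assays) >= 2) {
    for (prim in assays) for (sec in setdiff(assays, prim)) {
      for (g in c("B", "C")) {
        key <- sprintf("%s_group%s_by_%s", prim, g, sec)
        secondary[[key]] <- secondary_validation(
          assay_groups(calls, prim), assay_binary(calls, sec), gold_bin, g)
      }
    }
  }

  structure(list(gold = gold, assays = assays,
                 n_embryos = length(all_ids),
                 n_mac_excluded = length(keep_ids),
                 n_chrom_sets = 23L * length(keep_ids),
                 all = stratum(all_ids),
                 mac_excluded = stratum(keep_ids),
                 groups = groups, secondary = secondary),
            class = "concordance_report")
}

fmt_pct <- function(x, digits = 1) sprintf(paste0("%.", digits, "f"),
                                           round_half_up(100 * x, digits))

#' @export
print.concordance_report <- function(x, ...) {
  cat(sprintf("Concordance report: %d embryos, gold = %s\n", x$n_embryos,
              x$gold))
  show_stratum <- function(s, label) {
    cat(sprintf("\n== %s ==\n", label))
    for (a in names(s$diagnostics)) {
      d <- s$diagnostics[[a]]$summary
      cat(sprintf("%-7s", a))
      for (i in seq_len(nrow(d)))
        cat(sprintf(" %s %s (%s-%s)", d$metric[i], fmt_pct(d$estimate[i]),
                    fmt_pct(d$lo[i]), fmt_pct(d$hi[i])))
      cat("\n")
    }
    for (nm in names(s$agreement)) {
      g <- s$agreement[[nm]]
      cat(sprintf("%-18s concordance %s (%s-%s)  kappa %.3f (%.3f-%.3f)\n",
                  nm, fmt_pct(g$po), fmt_pct(g$po_ci[1]),
                  fmt_pct(g$po_ci[2]), g$kappa$kappa, g$kappa$kappa_ci[1],
                  g$kappa$kappa_ci[2]))
    }
  }
  show_stratum(x$all, "all embryos")
  show_stratum(x$mac_excluded,
               sprintf("MAC excluded (n=%d, %d chromosome sets)",
                       x$n_mac_excluded, x$n_chrom_sets))
  cat("\n== groups ==\n")
  for (a in names(x$groups)) {
    g <- x$groups[[a]]
    for (i in seq_len(nrow(g)))
      cat(sprintf("%-7s group %s: n=%3d  consistent %s%%\n", a, g$group[i],
                  g$n[i], fmt_pct(g$consistent_frac[i])))
  }
  cat("\n== secondary validation ==\n")
  for (nm in names(x$secondary)) {
    s <- x$secondary[[nm]]
    if (s$n == 0) next
    cat(sprintf("%-22s n=%3d  accuracy %s%% (primary %s%%), %d re-categorized normal\n",
                nm, s$n, fmt_pct(s$accuracy), fmt_pct(s$primary_accuracy),
                s$n_recategorized))
  }
  invisible(x)
}
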