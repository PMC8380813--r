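# Orchestration: simulate -> call -> classify -> score, with file-based
# provenance (every run writes its resolved configuration and seed).

ASSAY_LABELS <- c(whole = "whole", TE = "TE", medium = "NICS")

#' Simulate a cohort to disk
#'
#' Thin wrapper over [simulate_cohort()] that always writes count tables, a
#' truth manifest and the resolved config.
#'
#' @param n_embryos Number of embryos.
#' @param seed RNG seed.
#' @param out_dir Output directory (created if missing).
#' @param grid Bin grid (default packaged hg19-like 1 Mb grid).
#' @param ... Further [sim_config()] overrides.
#' @return The cohort list, invisibly.
#' @export
pipeline_simulate <- function(n_embryos, seed, out_dir,
                              grid = build_bin_grid(), ...) {
  config <- sim_config(n_embryos = n_embryos, seed = seed, ...)
  invisible(simulate_cohort(config, grid, out_dir = out_dir))
}

#' Call copy-number profiles and classify a cohort
#'
#' Accepts either an in-memory cohort from [simulate_cohort()] or a
#' directory of count-table TSVs. QC-failing samples are reported with
#' their CV and carried as no-calls; corrupted files are named and skipped.
#'
#' @param x Cohort list or directory path.
#' @param grid Bin grid matching the count tables.
#' @param panel Reference panel; `NULL` = packaged simulated euploid panel.
#' @param params A [cnv_params()].
#' @param ploidy A [ploidy_params()].
#' @param out_dir Optional directory for per-sample profiles and the merged
#'   calls table.
#' @param verbose Log progress and QC exclusions?
#' @return List with `calls` (long calls data.frame, assay `medium`
#'   relabelled `NICS`), `profiles`, `qc` (per-sample CV/pass table).
#' @export
pipeline_call <- function(x, grid = build_bin_grid(), panel = NULL,
                          params = cnv_params(), ploidy = ploidy_params(),
                          out_dir = NULL, verbose = FALSE) {
  tables <- if (is.character(x)) {
    paths <- setdiff(list.files(x, pattern = "\\.tsv$", full.names = TRUE),
                     file.path(x, "manifest.tsv"))
    tl <- list()
    for (p in paths) {
      ct <- tryCatch(read_count_table(p, grid), error = function(e) {
        warning("skipping unreadable count table ", basename(p), ": ",
                conditionMessage(e), call. = FALSE)
        NULL
      })
      if (!is.null(ct)) tl[[attr(ct, "sample_id")]] <- ct
    }
    tl
  } else x$counts
  if (is.null(panel)) panel <- default_reference_panel(grid)

  profiles <- list()
  qc_rows <- list()
  calls <- list()
  for (sid in names(tables)) {
    ct <- tables[[sid]]
    prof <- call_profile(ct, grid, panel, params)
    profiles[[sid]] <- prof
    qc_rows[[sid]] <- data.frame(sample_id = sid, assay = prof$assay,
                                 cv = prof$cv, qc_pass = prof$qc_pass,
                                 stringsAsFactors = FALSE)
    cl <- classify_embryo(prof, ploidy)
    calls[[sid]] <- data.frame(
      embryo_id = cl$embryo_id,
      assay = ASSAY_LABELS[[prof$assay]] %||% prof$assay,
      category = cl$category, group = cl$group, sex = cl$sex,
      n_abnormal = cl$n_abnormal, karyotype = cl$karyotype,
      qc_pass = cl$qc_pass, cv = prof$cv, stringsAsFactors = FALSE)
    if (verbose && !prof$qc_pass)
      message(sprintf("QC fail: %s (CV = %.3f)", sid, prof$cv))
  }
  calls <- do.call(rbind, calls)
  rownames(calls) <- NULL
  qc <- do.call(rbind, qc_rows)
  rownames(qc) <- NULL
  if (verbose)
    message(sprintf("%d/%d samples passed CV QC", sum(qc$qc_pass),
                    nrow(qc)))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(calls, file.path(out_dir, "calls.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(qc, file.path(out_dir, "qc.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    for (sid in names(profiles))
      write_profile(profiles[[sid]], file.path(out_dir, sid))
  }
  list(calls = calls, profiles = profiles, qc = qc)
}

#' Run the concordance engine on a calls table
#'
#' @param calls A long calls data.frame (or a path to one as TSV), or the
#'   string `"published"` to run on the packaged validation-cohort
#'   transcription. Rows with `qc_pass == FALSE` or `NA` categories are
#'   dropped; embryos are kept only when the gold assay and at least one
#'   test assay called them.
#' @param gold Gold-standard assay label.
#' @param out_dir Optional directory: report written as JSON and
#'   markdown-ish text.
#' @return A [concordance_report()].
#' @export
pipeline_concordance <- function(calls, gold = "whole", out_dir = NULL) {
  if (is.character(calls) && length(calls) == 1) {
    calls <- if (identical(calls, "published")) published_embryo_calls()
             else utils::read.delim(calls, colClasses = "character")
  }
  if ("qc_pass" %in% names(calls))
    calls <- calls[calls$qc_pass %in% c(TRUE, "TRUE"), ]
  calls <- calls[!is.na(calls$category), ]
  # keep embryos with a qualified gold call and a full assay complement
  n_assays <- length(unique(calls$assay))
  counts <- table(calls$embryo_id)
  qualified <- names(counts)[counts == n_assays]
  dropped <- length(counts) - length(qualified)
  if (dropped > 0)
    message(dropped, " embryo(s) lacked a fully qualified assay trio and ",
            "were excluded")
  rep <- concordance_report(calls[calls$embryo_id %in% qualified, ],
                            gold = gold)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(report_as_list(rep),
                         file.path(out_dir, "concordance.json"),
                         auto_unbox = TRUE, digits = NA)
    sink(file.path(out_dir, "concordance.txt"))
    print(rep)
    sink()
  }
  rep
}

# plain-list view of a report for JSON serialization
report_as_list <- function(rep) {
  strat <- function(s) list(
    diagnostics = lapply(s$diagnostics, function(d) {
      ct <- d$confusion
      list(tp = ct$tp, fp = ct$fp, fn = ct$fn, tn = ct$tn,
           summary = d$summary)
    }),
    agreement = lapply(s$agreement, function(g)
      list(po = g$po, po_ci = as.list(g$po_ci), kappa = g$kappa$kappa,
           kappa_ci = as.list(g$kappa$kappa_ci))))
  list(gold = rep$gold, n_embryos = rep$n_embryos,
       n_mac_excluded = rep$n_mac_excluded,
       n_chrom_sets = rep$n_chrom_sets,
       all = strat(rep$all), mac_excluded = strat(rep$mac_excluded),
       groups = rep$groups,
       secondary = lapply(rep$secondary, function(s)
         list(group = s$group, n = s$n, accuracy = s$accuracy,
              n_recategorized = s$n_recategorized)))
}

#' End-to-end pipeline: simulate, call, score
#'
#' @inheritParams pipeline_simulate
#' @param out_dir Output directory for all stages.
#' @param ... [sim_config()] overrides.
#' @return List with `cohort`, `called`, `report`.
#' @export
pipeline_all <- function(n_embryos, seed, out_dir = NULL, ...) {
  grid <- build_bin_grid()
  config <- sim_config(n_embryos = n_embryos, seed = seed, ...)
  cohort <- simulate_cohort(config, grid,
                            out_dir = if (!is.null(out_dir))
                              file.path(out_dir, "cohort"))
  called <- pipeline_call(cohort, grid,
                          params = cnv_params(seed = seed),
                          out_dir = if (!is.null(out_dir))
                            file.path(out_dir, "calls"))
  report <- pipeline_concordance(called$calls, gold = "whole",
                                 out_dir = out_dir)
  list(cohort = cohort, called = called, report = report)
}
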