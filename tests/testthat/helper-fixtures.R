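# Shared fixtures and independent oracles, built in code at test time.

# Full hg19-like 1 Mb grid and its default euploid reference panel are
# built once per test run (the panel is memoized inside the package).
hg_grid <- build_bin_grid()

# Small toy grid: two "chromosomes" with flat GC so normalization is inert.
toy_grid <- function(lengths = c(`1` = 10e6, `2` = 8e6), bin_size = 1e6,
                     gc = NULL) {
  spec <- data.frame(chrom = names(lengths), length = unname(lengths))
  n <- sum(ceiling(lengths / bin_size))
  build_bin_grid(spec, bin_size = bin_size,
                 gc = gc %||% rep(0.42, n))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# Truth-object constructor for targeted scenarios.
make_truth <- function(id, sex, events = NULL, category = "euploid") {
  ev <- if (is.null(events)) nicscreen:::empty_events() else events
  nicscreen:::new_truth(id, sex, category, ev)
}

whole_event <- function(chrom, delta, fraction = 1, lineage = "both") {
  data.frame(chrom = as.character(chrom), kind = "whole",
             delta = as.integer(delta), fraction = fraction,
             lineage = lineage, start_mb = NA_real_, end_mb = NA_real_,
             arm = NA_character_, stringsAsFactors = FALSE)
}

# Independent exhaustive oracle for the CBS arc scan: direct double loop
# over every valid circular arc, variance from deviations (not the
# cumulative-sum algebra the implementation uses).
exhaustive_best_arc <- function(x, min_bins) {
  m <- length(x)
  best <- list(t = -1, i = -1L, j = -1L)
  for (i in 0:(m - min_bins)) {
    if (i > 0 && i < min_bins) next
    for (j in (i + min_bins):m) {
      k <- j - i
      nc <- m - k
      if (nc < min_bins) next
      if (i > 0 && j == m) next  # same split as edge arc (0, i)
      if (j < m && m - j < min_bins) next
      arc <- x[(i + 1):j]
      comp <- x[-((i + 1):j)]
      ss <- sum((arc - mean(arc))^2) + sum((comp - mean(comp))^2)
      s2 <- max(ss / max(m - 2, 1), 1e-9)
      t <- abs((mean(arc) - mean(comp)) / sqrt(s2 * (1 / k + 1 / nc)))
      if (t > best$t) best <- list(t = t, i = i, j = j)
    }
  }
  best
}

# Enumeration oracle for the exact paired binomial test.
mcnemar_enum <- function(b, cc) {
  n <- b + cc
  if (n == 0) return(1)
  tail <- sum(vapply(0:min(b, cc), function(k) choose(n, k) * 0.5^n,
                     numeric(1)))
  min(1, 2 * tail)
}

# Minimal cn_profile stub so classification can be tested directly on
# constructed segment tables.
stub_profile <- function(segments, grid, sex = "XX", assay = "whole",
                         sample_id = "stub") {
  structure(list(grid = grid, cv = 0.05, qc_pass = TRUE, density = NULL,
                 cn = NULL, segments = segments, sex = sex,
                 sample_id = sample_id, assay = assay,
                 params = cnv_params()), class = "cn_profile")
}

# Segment table describing whole chromosomes at given mean copy numbers on
# the hg19-like grid.
flat_segments <- function(grid, means) {
  rows <- lapply(names(means), function(ch) {
    idx <- which(grid$chrom == ch & grid$mask)
    data.frame(chrom = ch, start_bp = grid$start[min(idx)],
               end_bp = grid$end[max(idx)], n_bins = length(idx),
               mean_cn = means[[ch]], p = 0.001, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# All-chromosome segment table: euploid baseline overridden by `means`.
profile_segments <- function(grid, means = list(), sex = "XX") {
  base <- stats::setNames(as.list(rep(2, 23)), c(as.character(1:22), "X"))
  if (sex == "XY") base$X <- 1
  for (ch in names(means)) base[[ch]] <- means[[ch]]
  flat_segments(grid, base)
}
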