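# Circular binary segmentation (recursion + merge; the arc scan and
# permutation test live in src/cbs.cpp).

#' Segment a copy-number vector by circular binary segmentation
#'
#' Recursively finds the circular arc maximizing the pooled-variance
#' two-sample t-statistic between arc and complement, accepts the split when
#' its permutation p-value is at most `alpha`, and recurses into the
#' resulting pieces until no split is accepted or a piece is shorter than
#' `2 * min_bins`. Adjacent segments whose means differ by less than
#' `merge_tol` are re-merged. An all-equal input yields a single segment
#' with p = 1. Ties in the arc scan resolve to the smallest left index,
#' then the smallest right index.
#'
#' @param x Numeric vector of per-bin copy number for one chromosome.
#' @param alpha Split acceptance level for the permutation test.
#' @param nperm Number of label permutations.
#' @param min_bins Minimum bins per segment.
#' @param merge_tol Adjacent segments closer than this in mean are merged.
#' @param seed Optional seed making the permutation test reproducible.
#' @return Data.frame with columns `start`, `end` (1-based bin indices into
#'   `x`, inclusive), `n_bins`, `mean`, `p` (p-value of the split that
#'   carved the segment; `NA` when the segment was never testable).
#' @export
#' @examples
#' cbs_segment(c(2, 2, 2, 3, 3, 3), min_bins = 2, nperm = 200, seed = 1)
cbs_segment <- function(x, alpha = 0.01, nperm = 1000, min_bins = 3,
                        merge_tol = 0.3, seed = NULL) {
  stopifnot(is.numeric(x), min_bins >= 1)
  m <- length(x)
  if (m == 0)
    return(data.frame(start = integer(), end = integer(),
                      n_bins = integer(), mean = numeric(), p = numeric()))
  with_seed(seed, {
    segs <- cbs_recurse(x, 1L, m, alpha, nperm, min_bins)
    segs <- cbs_merge(x, segs, merge_tol)
    segs$mean <- vapply(seq_len(nrow(segs)),
                        function(i) mean(x[segs$start[i]:segs$end[i]]),
                        numeric(1))
    segs$n_bins <- segs$end - segs$start + 1L
    segs[c("start", "end", "n_bins", "mean", "p")]
  })
}

cbs_recurse <- function(x, lo, hi, alpha, nperm, min_bins) {
  seg <- function(p) data.frame(start = lo, end = hi, p = p)
  m <- hi - lo + 1L
  if (m < 2L * min_bins) return(seg(NA_real_))
  xs <- x[lo:hi]
  if (max(xs) - min(xs) == 0) return(seg(1))
  best <- cbs_best_arc_cpp(xs, min_bins)
  if (!best$valid) return(seg(NA_real_))
  p <- cbs_perm_pvalue_cpp(xs, min_bins, best$t, nperm, alpha)
  if (p > alpha) return(seg(p))
  # cut after positions i and j (within-segment, 0-based boundaries)
  cuts <- c(best$i, best$j)
  cuts <- cuts[cuts > 0 & cuts < m]
  bounds <- c(lo - 1L, lo - 1L + cuts, hi)
  out <- lapply(seq_len(length(bounds) - 1L), function(k) {
    cbs_recurse(x, bounds[k] + 1L, bounds[k + 1L], alpha, nperm, min_bins)
  })
  res <- do.call(rbind, out)
  res$p[is.na(res$p)] <- p  # untestable pieces inherit the split's p
  res
}

cbs_merge <- function(x, segs, merge_tol) {
  if (merge_tol <= 0) return(segs)
  repeat {
    if (nrow(segs) < 2) return(segs)
    means <- vapply(seq_len(nrow(segs)),
                    function(i) mean(x[segs$start[i]:segs$end[i]]),
                    numeric(1))
    d <- abs(diff(means))
    if (all(d >= merge_tol)) return(segs)
    k <- which.min(d)  # merge the closest adjacent pair first
    segs$end[k] <- segs$end[k + 1]
    pp <- segs$p[c(k, k + 1)]
    segs$p[k] <- if (all(is.na(pp))) NA_real_ else max(pp, na.rm = TRUE)
    segs <- segs[-(k + 1), , drop = FALSE]
    rownames(segs) <- NULL
  }
}
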