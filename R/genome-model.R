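# Bin grid, count tables and read binning: the coordinate frame shared by the
# simulator, the copy-number caller and the concordance engine.

#' hg19-like chromosome lengths
#'
#' Integer lengths (bp) for chromosomes 1-22, X and Y, packaged so that no
#' download is ever required. Chromosome 1 is 249,250,621 bp.
#'
#' @return A data.frame with columns `chrom` and `length`.
#' @export
#' @examples
#' hg19_chrom_lengths()[1, ]
hg19_chrom_lengths <- function() {
  path <- system.file("extdata", "hg19_chrom_lengths.tsv",
                      package = "nicscreen", mustWork = TRUE)
  spec <- utils::read.delim(path, colClasses = c("character", "numeric"))
  spec$chrom <- as.character(spec$chrom)
  spec
}

#' Build an ordered genomic bin grid
#'
#' Tiles each chromosome with contiguous half-open `[start, end)` bins of
#' `bin_size` bp; the last bin of a chromosome keeps the remainder. Bins carry
#' a GC fraction (supplied, or generated by a deterministic synthetic GC
#' model) and a usability mask. Remainder bins shorter than half a bin are
#' masked out by default because their rescaled read density is unstable.
#'
#' @param genome_spec Data.frame with columns `chrom` (labels among 1-22, X,
#'   Y) and `length` (bp). Defaults to the packaged hg19-like table.
#' @param bin_size Bin width in bp (default 1 Mb).
#' @param gc Optional numeric vector of per-bin GC fractions in `[0, 1]`
#'   (recycled from a spec column `gc` if present). When absent, a smooth
#'   synthetic GC track is generated from a fixed internal seed, so the same
#'   spec and bin size always yield a bit-identical grid.
#' @param mask_short_bins Mask bins shorter than `bin_size / 2`? Default TRUE.
#' @return A `bin_grid`: data.frame with columns `chrom`, `start`, `end`,
#'   `gc`, `mask`, plus attributes `bin_size` and `chrom_lengths`.
#' @export
#' @examples
#' grid <- build_bin_grid(data.frame(chrom = "1", length = 3500000))
#' nrow(grid)        # 4 bins
#' grid$end - grid$start  # last bin is the 500 kb remainder
build_bin_grid <- function(genome_spec = hg19_chrom_lengths(),
                           bin_size = 1e6, gc = NULL,
                           mask_short_bins = TRUE) {
  stopifnot(is.data.frame(genome_spec),
            all(c("chrom", "length") %in% names(genome_spec)))
  if (!is.numeric(bin_size) || length(bin_size) != 1 || bin_size < 1)
    stop("bin_size must be a positive number of bp (>= 1)", call. = FALSE)
  if (any(genome_spec$length <= 0))
    stop("chromosome lengths must be positive", call. = FALSE)
  cf <- chrom_factor(genome_spec$chrom)
  genome_spec <- genome_spec[order(cf), , drop = FALSE]

  pieces <- lapply(seq_len(nrow(genome_spec)), function(i) {
    len <- genome_spec$length[i]
    starts <- seq(0, len - 1, by = bin_size)
    data.frame(chrom = genome_spec$chrom[i], start = starts,
               end = pmin(starts + bin_size, len),
               stringsAsFactors = FALSE)
  })
  grid <- do.call(rbind, pieces)
  rownames(grid) <- NULL
  grid$chrom <- as.character(grid$chrom)

  if (is.null(gc) && "gc" %in% names(genome_spec)) {
    # per-chromosome constant GC from the spec
    gc <- genome_spec$gc[match(grid$chrom, genome_spec$chrom)]
  }
  if (is.null(gc)) {
    gc <- synthetic_gc(nrow(grid))
  }
  stopifnot(length(gc) == nrow(grid))
  if (any(gc < 0 | gc > 1)) stop("gc fractions must lie in [0, 1]",
                                 call. = FALSE)
  grid$gc <- as.numeric(gc)
  grid$mask <- if (mask_short_bins) (grid$end - grid$start) >= bin_size / 2
               else rep(TRUE, nrow(grid))

  structure(grid, bin_size = bin_size,
            chrom_lengths = stats::setNames(genome_spec$length,
                                            genome_spec$chrom),
            class = c("bin_grid", "data.frame"))
}

# Smooth synthetic GC track: AR(1)-correlated noise around 0.42, clamped to a
# realistic range. Fixed seed => the default grid is fully deterministic.
synthetic_gc <- function(n, centre = 0.42, sd = 0.05, seed = 19910904L) {
  with_seed(seed, {
    z <- as.numeric(stats::filter(stats::rnorm(n), 0.8, "recursive"))
    z <- z * sqrt(1 - 0.8^2)  # back to unit marginal sd
    pmin(0.65, pmax(0.30, centre + sd * z))
  })
}

#' @export
print.bin_grid <- function(x, ...) {
  cat(sprintf("bin_grid: %d bins (%d usable), bin size %g bp, %d chromosomes\n",
              nrow(x), sum(x$mask), attr(x, "bin_size"),
              length(unique(x$chrom))))
  invisible(x)
}

n_bins <- function(grid, chrom = NULL) {
  if (is.null(chrom)) nrow(grid) else sum(grid$chrom == chrom)
}

#' Construct a per-bin count table
#'
#' @param counts Non-negative integer vector, one entry per grid bin.
#' @param grid A `bin_grid`.
#' @param sample_id Sample identifier.
#' @param assay One of `"whole"`, `"TE"`, `"medium"`, `"blank"`.
#' @param seed Optional seed recorded for provenance (written to file headers).
#' @return A `count_table` (data.frame chrom/start/end/count with metadata
#'   attributes).
#' @export
count_table <- function(counts, grid, sample_id = "sample",
                        assay = c("whole", "TE", "medium", "blank"),
                        seed = NULL) {
  assay <- match.arg(assay)
  counts <- as.numeric(counts)
  if (length(counts) != nrow(grid))
    stop("counts length (", length(counts), ") != grid length (",
         nrow(grid), ")", call. = FALSE)
  if (any(is.na(counts)) || any(counts < 0) || any(counts != floor(counts)))
    stop("counts must be non-negative integers", call. = FALSE)
  structure(data.frame(chrom = grid$chrom, start = grid$start,
                       end = grid$end, count = counts,
                       stringsAsFactors = FALSE),
            sample_id = sample_id, assay = assay, seed = seed,
            class = c("count_table", "data.frame"))
}

#' Write / read a count table as TSV
#'
#' The on-disk dialect is a plain TSV with columns chrom/start/end/count and
#' `#key=value` header comments recording sample id, assay and seed, so a
#' round trip is lossless.
#'
#' @param x A `count_table`.
#' @param path File path.
#' @export
write_count_table <- function(x, path) {
  stopifnot(inherits(x, "count_table"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("#sample_id=%s", attr(x, "sample_id")),
               sprintf("#assay=%s", attr(x, "assay")),
               sprintf("#seed=%s", attr(x, "seed") %||% "NA")), con)
  utils::write.table(as.data.frame(x), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_count_table
#' @param grid The `bin_grid` the table must match bin-for-bin.
#' @export
read_count_table <- function(path, grid) {
  hdr <- readLines(path, n = 10L)
  hdr <- hdr[startsWith(hdr, "#")]
  meta <- list()
  for (h in hdr) {
    kv <- strsplit(sub("^#", "", h), "=", fixed = TRUE)[[1]]
    if (length(kv) == 2) meta[[kv[1]]] <- kv[2]
  }
  df <- utils::read.delim(path, comment.char = "#",
                          colClasses = c("character", "numeric", "numeric",
                                         "numeric"))
  need <- c("chrom", "start", "end", "count")
  if (!all(need %in% names(df)))
    stop("count table must have columns chrom, start, end, count",
         call. = FALSE)
  if (nrow(df) != nrow(grid) ||
      !all(df$chrom == grid$chrom & df$start == grid$start &
           df$end == grid$end))
    stop("count table bins do not match the supplied grid", call. = FALSE)
  if (any(df$count < 0)) stop("negative counts are not allowed", call. = FALSE)
  seed <- meta$seed
  if (!is.null(seed) && identical(seed, "NA")) seed <- NULL
  count_table(df$count, grid, sample_id = meta$sample_id %||% "sample",
              assay = meta$assay %||% "whole", seed = seed)
}

#' Bin read positions onto a grid
#'
#' Assigns each read to exactly one bin by half-open containment, so a read
#' at exactly 1,000,000 falls in the second 1 Mb bin. Total count is
#' conserved.
#'
#' @param read_positions Data.frame with columns `chrom` and `pos` (0-based
#'   bp), e.g. parsed from 3-column BED starts.
#' @param grid A `bin_grid`.
#' @inheritParams count_table
#' @return A `count_table`.
#' @export
bin_reads <- function(read_positions, grid, sample_id = "sample",
                      assay = "whole") {
  stopifnot(all(c("chrom", "pos") %in% names(read_positions)))
  lens <- attr(grid, "chrom_lengths")
  chrom <- as.character(read_positions$chrom)
  bad_chrom <- !(chrom %in% names(lens))
  pos <- read_positions$pos
  oob <- bad_chrom | pos < 0 | pos >= lens[chrom]
  if (any(oob, na.rm = TRUE))
    stop(sum(oob | is.na(oob)), " read position(s) out of chromosome bounds",
         call. = FALSE)
  bs <- attr(grid, "bin_size")
  # bin index within chromosome, then offset by chromosome start in the grid
  offset <- c(0, cumsum(table(chrom_factor(grid$chrom))))
  names(offset) <- c(CHROM_LEVELS, "end")[seq_along(offset)]
  idx <- offset[chrom] + floor(pos / bs) + 1
  counts <- tabulate(idx, nbins = nrow(grid))
  count_table(counts, grid, sample_id = sample_id, assay = assay)
}
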