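# Internal helpers shared across modules.

CHROM_LEVELS <- c(as.character(1:22), "X", "Y")
AUTOSOMES <- as.character(1:22)

#' Evaluate an expression with a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards, so seeded simulations never
#' perturb the global random stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

#' Round half away from zero (the convention used for reported percentages)
#' @noRd
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Order chromosome labels as 1..22, X, Y
#' @noRd
chrom_factor <- function(chrom) {
  chrom <- as.character(chrom)
  bad <- setdiff(unique(chrom), CHROM_LEVELS)
  if (length(bad) > 0)
    stop("unknown chromosome label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  factor(chrom, levels = CHROM_LEVELS)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
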