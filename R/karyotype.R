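# Karyotype-string grammar.
#
# Strings look like "[46, XX]", "[48, XY, +6, +20]", "[46, XX, -8mos]" or
# "[46, XY, -7q(q31.33->qter, ~30M)mos, +18mos]". The parser accepts the
# typographic variants seen in clinical reports (en dash / minus sign for a
# loss, "∼" for "~", "→" for "->", optional spaces, optional space
# before "mos"); the writer always emits the canonical ASCII form.

normalize_karyotype_text <- function(text) {
  text <- gsub("–|−|—", "-", text)  # en/em dash, minus sign
  text <- gsub("∼", "~", text)                # tilde operator
  text <- gsub("→", "->", text)               # rightwards arrow
  text
}

EVENT_RE <- paste0(
  "^([+-])",                               # sign
  "(2[012]|1?[0-9]|X|Y)",                  # chromosome 1-22, X, Y
  "([pq])?",                               # optional arm
  "(?:\\s*\\(\\s*([^,()]*?)\\s*->\\s*([^,()]*?)\\s*,\\s*~\\s*",
  "([0-9.]+)\\s*M\\s*\\))?",               # optional (from->to, ~spanM)
  "\\s*(mos)?$")                           # optional mosaic flag

#' Parse a bracketed karyotype string
#'
#' @param text A karyotype string such as `"[48, XY, +6, +20]"`. Unicode
#'   dashes/tilde/arrow variants are accepted.
#' @return A `karyotype` object: list with `count` (modal chromosome number),
#'   `sex` (`"XX"`/`"XY"`), and `events`, a data.frame with columns `chrom`,
#'   `sign` (`"+"`/`"-"`), `arm` (`NA`, `"p"` or `"q"`), `band_from`,
#'   `band_to`, `span_mb` and `mosaic`.
#' @export
#' @examples
#' k <- parse_karyotype("[46, XY, –7q(q31.33 → qter, ∼30M) mos, +18mos]")
#' format_karyotype(k)
parse_karyotype <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  raw <- text
  text <- normalize_karyotype_text(trimws(text))
  if (!grepl("^\\[.*\\]$", text))
    stop("karyotype must be enclosed in brackets: ", raw, call. = FALSE)
  inner <- substr(text, 2, nchar(text) - 1)

  # split on commas not inside parentheses
  chars <- strsplit(inner, "")[[1]]
  depth <- cumsum((chars == "(") - (chars == ")"))
  cuts <- which(chars == "," & depth == 0)
  bounds <- c(0, cuts, length(chars) + 1)
  tokens <- vapply(seq_len(length(bounds) - 1), function(i) {
    trimws(paste(chars[seq(bounds[i] + 1, bounds[i + 1] - 1)], collapse = ""))
  }, character(1))
  tokens <- tokens[tokens != ""]
  if (length(tokens) < 2)
    stop("karyotype needs at least a count and a sex field: ", raw,
         call. = FALSE)

  if (!grepl("^[0-9]+$", tokens[1]))
    stop("malformed chromosome count token: '", tokens[1], "'", call. = FALSE)
  count <- as.integer(tokens[1])
  if (!tokens[2] %in% c("XX", "XY"))
    stop("malformed sex token: '", tokens[2], "'", call. = FALSE)
  sex <- tokens[2]

  ev <- lapply(tokens[-(1:2)], function(tok) {
    m <- regmatches(tok, regexec(EVENT_RE, tok))[[1]]
    if (length(m) == 0)
      stop("malformed karyotype event token: '", tok, "'", call. = FALSE)
    has_span <- nzchar(m[7])
    if (nzchar(m[4]) && !has_span)
      stop("arm-level event needs a (from->to, ~spanM) segment: '", tok, "'",
           call. = FALSE)
    data.frame(chrom = m[3], sign = m[2],
               arm = if (nzchar(m[4])) m[4] else NA_character_,
               band_from = if (has_span) m[5] else NA_character_,
               band_to = if (has_span) m[6] else NA_character_,
               span_mb = if (has_span) as.numeric(m[7]) else NA_real_,
               mosaic = nzchar(m[8]),
               stringsAsFactors = FALSE)
  })
  events <- if (length(ev)) do.call(rbind, ev) else
    data.frame(chrom = character(), sign = character(), arm = character(),
               band_from = character(), band_to = character(),
               span_mb = numeric(), mosaic = logical(),
               stringsAsFactors = FALSE)
  structure(list(count = count, sex = sex, events = events),
            class = "karyotype")
}

#' Format a karyotype object as its canonical string
#'
#' @param k A `karyotype` object (see [parse_karyotype()]).
#' @return A single canonical ASCII karyotype string; parsing it back yields
#'   an identical object.
#' @export
format_karyotype <- function(k) {
  stopifnot(inherits(k, "karyotype"))
  toks <- c(as.character(k$count), k$sex)
  if (nrow(k$events) > 0) {
    ev <- k$events[order(chrom_factor(k$events$chrom)), , drop = FALSE]
    toks <- c(toks, vapply(seq_len(nrow(ev)), function(i) {
      e <- ev[i, ]
      s <- paste0(e$sign, e$chrom, if (!is.na(e$arm)) e$arm else "")
      if (!is.na(e$span_mb))
        s <- paste0(s, "(", e$band_from, "->", e$band_to, ", ~",
                    format(e$span_mb, trim = TRUE), "M)")
      if (e$mosaic) s <- paste0(s, "mos")
      s
    }, character(1)))
  }
  paste0("[", paste(toks, collapse = ", "), "]")
}

#' @export
print.karyotype <- function(x, ...) {
  cat(format_karyotype(x), "\n")
  invisible(x)
}
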