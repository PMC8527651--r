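#' Construct a table of genomic intervals
#'
#' The elementary data unit of the package: 1-based coordinates with
#' inclusive printed ends, chromosome label attached. Interval length is
#' defined as `end - start` (see [span_length()]).
#'
#' @param chrom character vector of chromosome labels (non-empty).
#' @param start,end integer-like vectors, `1 <= start <= end`.
#' @return a `data.frame` with columns `chrom`, `start`, `end`.
#' @examples
#' genomic_interval("chr2", 31545815, 31547924)
#' @export
genomic_interval <- function(chrom, start, end) {
  chrom <- as.character(chrom)
  start <- as.numeric(start)
  end <- as.numeric(end)
  n <- max(length(chrom), length(start), length(end))
  chrom <- rep_len(chrom, n); start <- rep_len(start, n); end <- rep_len(end, n)
  if (any(is.na(chrom) | !nzchar(chrom)))
    stop_named("chromosome labels must be non-empty")
  if (any(!is.finite(start) | !is.finite(end)))
    stop_named("interval coordinates must be finite")
  if (any(start < 1)) stop_named("interval start must be >= 1")
  if (any(end < start)) stop_named("interval end must be >= start")
  if (any(end >= 2^31)) stop_named("coordinate overflow: end >= 2^31")
  data.frame(chrom = chrom, start = start, end = end,
             stringsAsFactors = FALSE)
}

#' Parse coordinate strings like "chr2:31,545,815-31,547,924"
#'
#' Accepts hyphen, en-dash or em-dash separators, optional thousands
#' separators and stray whitespace, as found in published probe tables.
#'
#' @param text character vector of `chrom:start-end` strings.
#' @return interval table as from [genomic_interval()].
#' @examples
#' parse_region("chr2:31,545,815–31,547,924")
#' @export
parse_region <- function(text) {
  text <- as.character(text)
  rx <- "^\\s*([^:[:space:]]+)\\s*:\\s*([0-9][0-9,]*)\\s*[-–—]\\s*([0-9][0-9,]*)\\s*$"
  m <- regexec(rx, text)
  parts <- regmatches(text, m)
  bad <- lengths(parts) != 4L
  if (any(bad))
    stop_named("malformed coordinate string: '%s'", text[which(bad)[1L]])
  chrom <- vapply(parts, `[[`, "", 2L)
  start <- as.numeric(gsub(",", "", vapply(parts, `[[`, "", 3L)))
  end <- as.numeric(gsub(",", "", vapply(parts, `[[`, "", 4L)))
  swap <- end < start
  if (any(swap))
    stop_named("malformed coordinate string (start > end): '%s'",
               text[which(swap)[1L]])
  genomic_interval(chrom, start, end)
}

#' Interval length under the domain-table convention
#'
#' Length is `end - start`: the convention under which each bracketed
#' domain length in the published probe table is recovered exactly from
#' the printed 1-based coordinates (e.g. chr2:31,545,815-31,571,269 gives
#' 25,454 bp). The alternative `end - start + 1` dialect, used for some
#' per-probe lengths in the original figures, is not used anywhere in this
#' package.
#'
#' @param x interval table with `start` and `end` columns.
#' @return numeric vector of lengths in bp.
#' @export
span_length <- function(x) {
  stopifnot(is.data.frame(x), all(c("start", "end") %in% names(x)))
  if (any(x$end < x$start)) stop_named("invalid interval: end < start")
  x$end - x$start
}

#' Gap between two ordered disjoint intervals
#'
#' `b$start - a$end` for same-chromosome intervals with `a` strictly
#' before `b`. The caller is responsible for sorting.
#'
#' @param a,b interval tables of equal row count.
#' @return numeric vector of gaps in bp.
#' @export
gap_between <- function(a, b) {
  stopifnot(is.data.frame(a), is.data.frame(b), nrow(a) == nrow(b))
  if (any(a$chrom != b$chrom))
    stop_named("gap_between: intervals on different chromosomes")
  if (any(a$end >= b$start))
    stop_named("gap_between: intervals overlap or are unordered")
  b$start - a$end
}

#' Smallest interval containing a set of same-chromosome intervals
#'
#' @param x interval table, all rows on one chromosome.
#' @return single-row interval table.
#' @export
interval_hull <- function(x) {
  stopifnot(is.data.frame(x), nrow(x) >= 1L)
  if (length(unique(x$chrom)) != 1L)
    stop_named("interval_hull: intervals span multiple chromosomes")
  genomic_interval(x$chrom[1L], min(x$start), max(x$end))
}

#' Format base pairs as a rounded kb string
#'
#' Half-up rounding to the printed number of decimals, reproducing the
#' report dialect of the domain tables (82,850 bp -> "82.9").
#'
#' @param bp numeric vector of lengths in bp.
#' @param digits decimals to keep (default 1).
#' @return character vector.
#' @examples
#' format_kb(82850)  # "82.9"
#' @export
format_kb <- function(bp, digits = 1) {
  sprintf(paste0("%.", digits, "f"), round_half_up(bp / 1000, digits))
}
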