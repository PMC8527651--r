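#' Read a single-copy probe table
#'
#' Tab-separated with a header; required columns `name`, `coordinates`
#' (strings such as `chr2:31,545,815-31,547,924`), `position_class`
#' (`genic`/`intergenic`) and `anchor` (logical). Optional columns
#' (`region`, `domain`, `call`, `gene`, ...) are carried through
#' unchanged. Coordinates are parsed with [parse_region()].
#'
#' @param path path to a TSV file.
#' @return `data.frame` with columns `name`, `chrom`, `start`, `end`,
#'   `position_class`, `anchor`, plus any extra input columns.
#' @seealso [scfish_probes()] for the packaged probe set.
#' @export
read_probe_table <- function(path) {
  raw <- read.delim(path, sep = "\t", header = TRUE,
                    colClasses = "character", check.names = FALSE,
                    na.strings = c("NA", ""))
  required <- c("name", "coordinates", "position_class", "anchor")
  missing <- setdiff(required, names(raw))
  if (length(missing))
    stop_named("probe table is missing column(s): %s",
               paste(missing, collapse = ", "))
  if (nrow(raw) == 0L) {
    out <- data.frame(name = character(), chrom = character(),
                      start = numeric(), end = numeric(),
                      position_class = character(), anchor = logical(),
                      stringsAsFactors = FALSE)
    return(out)
  }
  if (anyDuplicated(raw$name))
    stop_named("duplicate probe name(s): %s",
               paste(unique(raw$name[duplicated(raw$name)]), collapse = ", "))
  iv <- parse_region(raw$coordinates)
  pc <- tolower(raw$position_class)
  badpc <- !pc %in% c("genic", "intergenic")
  if (any(badpc))
    stop_named("unknown position_class '%s' for probe %s",
               raw$position_class[which(badpc)[1L]], raw$name[which(badpc)[1L]])
  anc <- tolower(raw$anchor)
  anchor <- anc %in% c("true", "t", "1", "yes")
  if (any(!anc %in% c("true", "t", "1", "yes", "false", "f", "0", "no")))
    stop_named("anchor column must be logical (TRUE/FALSE)")
  out <- data.frame(name = raw$name, chrom = iv$chrom, start = iv$start,
                    end = iv$end, position_class = pc, anchor = anchor,
                    stringsAsFactors = FALSE)
  extras <- setdiff(names(raw), c(required, "coordinates"))
  for (col in extras) out[[col]] <- raw[[col]]
  out
}

#' The packaged scFISH probe set (GRCh37)
#'
#' The 19-probe coordinate table used throughout the package: 18 probes
#' with differential accessibility (DA) across six chromosomal regions
#' plus the equivalent-accessibility (EA) control probe 3.3_1p36,
#' transcribed from the published probe table. Columns include the
#' chromosome band (`region`), the domain each probe belongs to
#' (`domain`, `NA` for probes outside domains), the accessibility call
#' (`call`), the anchor flag, and the nearest/containing gene.
#'
#' @return probe `data.frame` as from [read_probe_table()].
#' @examples
#' probes <- scfish_probes()
#' nrow(probes)  # 19
#' @export
scfish_probes <- function() {
  read_probe_table(system.file("extdata", "scfish_probes_grch37.tsv",
                               package = "dachroma", mustWork = TRUE))
}

.df_to_granges <- function(x, extra = NULL) {
  gr <- GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start, end = x$end))
  for (col in extra) {
    if (!is.null(x[[col]])) S4Vectors::mcols(gr)[[col]] <- x[[col]]
  }
  gr
}

#' Read a BED file into the internal 1-based convention
#'
#' BED is 0-based half-open on disk; rows come back as 1-based inclusive
#' intervals (the conversion is handled by `rtracklayer`). `name` and
#' `score` columns are kept when present.
#'
#' @param path path to a BED3/BED6 file.
#' @return interval `data.frame` (possibly with `name`, `score`).
#' @export
read_bed <- function(path) {
  if (file.info(path)$size == 0 ||
      length(readLines(path, n = 1L, warn = FALSE)) == 0L) {
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), stringsAsFactors = FALSE))
  }
  gr <- rtracklayer::import(path, format = "BED")
  out <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                    start = GenomicRanges::start(gr),
                    end = GenomicRanges::end(gr),
                    stringsAsFactors = FALSE)
  mc <- S4Vectors::mcols(gr)
  for (col in intersect(c("name", "score"), names(mc))) {
    v <- mc[[col]]
    if (!all(is.na(v))) out[[col]] <- v
  }
  if (any(out$end >= 2^31)) stop_named("coordinate overflow: end >= 2^31")
  out
}

#' Write intervals to BED (0-based half-open on disk)
#'
#' @param x interval table with `chrom`, `start`, `end` and optionally
#'   `name`, `score`; other columns are rejected so nothing is silently
#'   dropped.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  stopifnot(is.data.frame(x))
  unknown <- setdiff(names(x), c("chrom", "start", "end", "name", "score"))
  if (length(unknown))
    stop_named("write_bed: unknown column(s): %s",
               paste(unknown, collapse = ", "))
  if (nrow(x) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  genomic_interval(x$chrom, x$start, x$end)  # validates
  gr <- .df_to_granges(x, extra = c("name", "score"))
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read a bedGraph signal track
#'
#' Returns a piecewise-constant track: `chrom`, `start`, `end` (1-based
#' inclusive, converted from the 0-based half-open file) and `value`.
#'
#' @param path path to a bedGraph file.
#' @return track `data.frame` suitable for [integrate_track()].
#' @export
read_bedgraph <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr),
             value = S4Vectors::mcols(gr)$score,
             stringsAsFactors = FALSE)
}

#' Write a signal track to bedGraph
#'
#' @param x track table with `chrom`, `start`, `end`, `value`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(x, path) {
  stopifnot(is.data.frame(x), all(c("chrom", "start", "end", "value") %in%
                                    names(x)))
  gr <- .df_to_granges(x)
  S4Vectors::mcols(gr)$score <- x$value
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Read a RepeatMasker-style repeat annotation table
#'
#' Tab-separated with header columns `chrom`, `start`, `end`, `family`,
#' `divergence` (percent divergence from the family consensus, 0-100).
#' Coordinates are 1-based inclusive.
#'
#' @param path path to a TSV file.
#' @return repeat `data.frame`.
#' @export
read_repeat_table <- function(path) {
  x <- read.delim(path, sep = "\t", header = TRUE, check.names = FALSE)
  need <- c("chrom", "start", "end", "family", "divergence")
  missing <- setdiff(need, names(x))
  if (length(missing))
    stop_named("repeat table is missing column(s): %s",
               paste(missing, collapse = ", "))
  if (any(x$divergence < 0 | x$divergence > 100))
    stop_named("repeat divergence must lie in [0, 100]")
  x
}

#' Read a CNV table with population frequencies
#'
#' Tab-separated with header columns `chrom`, `start`, `end`,
#' `frequency` (population frequency as a fraction in [0, 1]).
#'
#' @param path path to a TSV file.
#' @return CNV `data.frame`.
#' @export
read_cnv_table <- function(path) {
  x <- read.delim(path, sep = "\t", header = TRUE, check.names = FALSE)
  need <- c("chrom", "start", "end", "frequency")
  missing <- setdiff(need, names(x))
  if (length(missing))
    stop_named("CNV table is missing column(s): %s",
               paste(missing, collapse = ", "))
  if (any(x$frequency < 0 | x$frequency > 1))
    stop_named("CNV frequency must lie in [0, 1]")
  x
}
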