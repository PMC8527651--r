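#' Find candidate single-copy intervals in a repeat landscape
#'
#' Single-copy FISH probes must avoid repetitive elements that
#' cross-hybridize genome-wide. Repeats diverged by less than
#' `max_divergence` percent from their family consensus mask the region;
#' highly divergent repeats behave as unique sequence and are ignored.
#' The maximal repeat-free runs inside `region` are returned; runs
#' shorter than `min_len` are dropped and runs longer than `max_len` are
#' kept whole but flagged `oversize` (they would be trimmed only at probe
#' synthesis time).
#'
#' @param repeats repeat table (`chrom`, `start`, `end`, `divergence`),
#'   all on the chromosome of `region`.
#' @param region single-row interval table.
#' @param min_len,max_len probe length window in bp (defaults 1400 and
#'   4000, the practical single-copy probe size range).
#' @param max_divergence masking threshold in percent (default 20).
#' @return interval `data.frame` with an `oversize` logical column.
#' @export
find_sc_intervals <- function(repeats, region, min_len = 1400,
                              max_len = 4000, max_divergence = 20) {
  stopifnot(is.data.frame(region), nrow(region) == 1L)
  if (min_len > max_len) stop_named("min_len must be <= max_len")
  empty <- data.frame(chrom = character(), start = numeric(),
                      end = numeric(), oversize = logical(),
                      stringsAsFactors = FALSE)
  if (nrow(repeats) > 0 && any(repeats$chrom != region$chrom))
    stop_named("find_sc_intervals: repeats on a different chromosome (%s) than the region (%s)",
               setdiff(repeats$chrom, region$chrom)[1L], region$chrom)
  reg <- IRanges::IRanges(region$start, region$end)
  low <- repeats[repeats$divergence < max_divergence, , drop = FALSE]
  if (nrow(low) == 0L) {
    mask <- IRanges::IRanges()
  } else {
    mask <- IRanges::reduce(IRanges::IRanges(low$start, low$end))
  }
  runs <- IRanges::setdiff(reg, mask)
  if (length(runs) == 0L) return(empty)
  out <- data.frame(chrom = region$chrom,
                    start = IRanges::start(runs),
                    end = IRanges::end(runs),
                    stringsAsFactors = FALSE)
  len <- span_length(out)
  out <- out[len >= min_len, , drop = FALSE]
  if (nrow(out) == 0L) return(empty)
  out$oversize <- span_length(out) > max_len
  rownames(out) <- NULL
  out
}

#' Drop candidates overlapping common copy-number variants
#'
#' A candidate interval overlapping (by one or more base) any CNV with a
#' population frequency at or above `freq_threshold` is excluded, since
#' copy number differences between homologs would confound accessibility
#' scoring.
#'
#' @param candidates interval table.
#' @param cnvs CNV table (`chrom`, `start`, `end`, `frequency`).
#' @param freq_threshold frequency cut-off as a fraction (default 0.01,
#'   i.e. 1 percent).
#' @return the surviving rows of `candidates`.
#' @export
filter_cnv <- function(candidates, cnvs, freq_threshold = 0.01) {
  stopifnot(is.data.frame(candidates), is.data.frame(cnvs))
  if (nrow(candidates) == 0L || nrow(cnvs) == 0L) return(candidates)
  hot <- cnvs[cnvs$frequency >= freq_threshold, , drop = FALSE]
  if (nrow(hot) == 0L) return(candidates)
  cgr <- .df_to_granges(candidates)
  hgr <- .df_to_granges(hot)
  hit <- GenomicRanges::countOverlaps(cgr, hgr, minoverlap = 1L) > 0L
  out <- candidates[!hit, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Keep probes whose gene is transcriptionally inert in all tissues
#'
#' For cross-tissue accessibility comparisons, probes within genes must
#' target loci with little to no expression (at most `max_tpm` TPM) in
#' every tissue of interest, so that tissue-specific transcription cannot
#' confound chromatin accessibility. Intergenic probes pass
#' unconditionally. A genic probe whose gene has no expression records is
#' an error, never a silent keep.
#'
#' @param probes probe table with `position_class` and `gene` columns.
#' @param expression `data.frame` with columns `gene`, `tissue`, `tpm`.
#' @param max_tpm TPM ceiling (default 5.0).
#' @return the surviving rows of `probes`.
#' @export
filter_expression <- function(probes, expression, max_tpm = 5.0) {
  stopifnot(is.data.frame(probes), is.data.frame(expression),
            all(c("gene", "tissue", "tpm") %in% names(expression)))
  if (any(expression$tpm < 0)) stop_named("tpm values must be >= 0")
  genic <- probes$position_class == "genic"
  if (any(genic)) {
    genes <- probes$gene[genic]
    missing <- setdiff(genes, expression$gene)
    if (length(missing))
      stop_named("no expression records for genic probe gene(s): %s",
                 paste(missing, collapse = ", "))
  }
  max_by_gene <- tapply(expression$tpm, expression$gene, max)
  keep <- !genic | max_by_gene[probes$gene] <= max_tpm
  out <- probes[as.logical(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}
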