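# Aggregation of concordant DA probes into chromosomal domains, with the
# span / gap / combined-target-length report dialect of the probe table.

#' Aggregate adjacent concordant DA probes into domains
#'
#' A DA domain is a maximal run of two or more consecutive probes all
#' classified `DA`, with no interspersed `EA` probe, within one analyzed
#' probe set. Probe sets are delimited by the `region` column (the
#' chromosome band of the locus) when present, else by chromosome — a
#' chromosome can carry several independently analyzed loci. Domain
#' boundaries are the smallest and largest coordinates of the maximally
#' separated member probes; the domain is inferred contiguous between
#' them. Single DA probes are reported separately, never as domains.
#'
#' @param probes probe table with `name`, `chrom`, `start`, `end`,
#'   `call` and optionally `region` and `domain` (a name carried into
#'   the built domain).
#' @param group_col column delimiting analyzed probe sets (default:
#'   `region` if present, else `chrom`).
#' @param max_gap optional bp; a warning is emitted for intra-domain
#'   gaps exceeding it (no gap ceiling is imposed otherwise).
#' @return object of class `da_domain_set`: list with `domains` (list of
#'   `da_domain`) and `singletons` (data.frame of isolated DA probes).
#' @examples
#' doms <- build_domains(scfish_probes())
#' length(doms$domains)  # 6
#' @export
build_domains <- function(probes, group_col = NULL, max_gap = NULL) {
  stopifnot(all(c("name", "chrom", "start", "end", "call") %in%
                  names(probes)))
  if (!all(probes$call %in% c("DA", "EA")))
    stop_named("probe calls must be 'DA' or 'EA'")
  group_col <- group_col %||% if ("region" %in% names(probes)) "region"
                              else "chrom"
  domains <- list()
  singles <- probes[0, , drop = FALSE]
  for (grp in unique(probes[[group_col]])) {
    sub <- probes[probes[[group_col]] == grp, , drop = FALSE]
    if (length(unique(sub$chrom)) != 1L)
      stop_named("probe set '%s' spans multiple chromosomes", grp)
    sub <- sub[order(sub$start), , drop = FALSE]
    if (nrow(sub) > 1L && any(sub$start[-1L] <= sub$end[-nrow(sub)]))
      stop_named("overlapping probes in probe set '%s'", grp)
    runs <- rle(sub$call == "DA")
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    for (i in seq_along(runs$lengths)) {
      if (!runs$values[i]) next
      members <- sub[starts[i]:ends[i], , drop = FALSE]
      if (nrow(members) < 2L) {
        singles <- rbind(singles, members)
        next
      }
      gaps <- gap_between(members[-nrow(members), , drop = FALSE],
                          members[-1L, , drop = FALSE])
      nm <- unique(members$domain[!is.na(members$domain)])
      nm <- if (length(nm) == 1L) nm else as.character(grp)
      if (!is.null(max_gap) && any(gaps > max_gap))
        warning(sprintf("domain %s has gap(s) above %d bp: %s", nm,
                        max_gap, paste(gaps[gaps > max_gap],
                                       collapse = ", ")),
                call. = FALSE)
      domains[[length(domains) + 1L]] <- structure(
        list(name = nm, probes = members,
             hull = interval_hull(members), gaps = gaps,
             combined_target_length = sum(span_length(members))),
        class = "da_domain")
    }
  }
  structure(list(domains = domains, singletons = singles),
            class = "da_domain_set")
}

#' @export
print.da_domain <- function(x, ...) {
  cat(sprintf("DA domain %s: %d probes, %s:%d-%d, span %s kb, target %s kb\n",
              x$name, nrow(x$probes), x$hull$chrom, x$hull$start,
              x$hull$end, format_kb(span_length(x$hull)),
              format_kb(x$combined_target_length)))
  invisible(x)
}

#' Span / gap / target-length report for DA domains
#'
#' One row per domain: the hull span (`end - start` over the maximally
#' separated probes), the successive inter-probe gaps, the combined
#' probe target length, and their half-up-rounded kb strings as printed
#' in domain tables.
#'
#' @param x a `da_domain`, a `da_domain_set`, or a list of domains.
#' @return `data.frame` with columns `name`, `chrom`, `start`, `end`,
#'   `n_probes`, `span_bp`, `span_kb`, `gaps_bp` (comma-joined),
#'   `max_gap_bp`, `min_gap_bp`, `target_bp`, `target_kb`.
#' @export
domain_report <- function(x) {
  if (inherits(x, "da_domain")) x <- list(x)
  if (inherits(x, "da_domain_set")) x <- x$domains
  out <- lapply(x, function(d) {
    span <- span_length(d$hull)
    data.frame(name = d$name, chrom = d$hull$chrom,
               start = d$hull$start, end = d$hull$end,
               n_probes = nrow(d$probes), span_bp = span,
               span_kb = format_kb(span),
               gaps_bp = paste(d$gaps, collapse = ","),
               max_gap_bp = max(d$gaps), min_gap_bp = min(d$gaps),
               target_bp = d$combined_target_length,
               target_kb = format_kb(d$combined_target_length),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Name a probe interval relative to its nearest or containing gene
#'
#' Probes inside a gene are named `GENE_IVSa-IVSb` from the introns they
#' span, listed in ascending genomic coordinate order as printed (so a
#' minus-strand gene yields descending intron numbers). Intergenic
#' probes are named `GENE_cen<d>` or `GENE_tel<d>` after the nearest
#' gene on the chromosome, where `cen`/`tel` says whether the probe lies
#' on the centromeric or telomeric side of that gene and `d` is the bp
#' distance between the gene boundary and the interval.
#'
#' @param interval single-row interval table.
#' @param genes gene table with `gene`, `chrom`, `start`, `end`.
#' @param introns optional intron table with `gene`, `intron`, `start`,
#'   `end` (required to name genic probes).
#' @param centromere centromere position (bp) of the chromosome,
#'   required for intergenic naming.
#' @return probe name string.
#' @export
name_probe <- function(interval, genes, introns = NULL,
                       centromere = NULL) {
  stopifnot(nrow(interval) == 1L,
            all(c("gene", "chrom", "start", "end") %in% names(genes)))
  genes <- genes[genes$chrom == interval$chrom, , drop = FALSE]
  if (nrow(genes) == 0L)
    stop_named("no gene annotation on chromosome %s", interval$chrom)
  inside <- genes$start <= interval$start & genes$end >= interval$end
  if (any(inside)) {
    g <- genes[which(inside)[1L], ]
    if (is.null(introns))
      stop_named("intron annotation required to name a genic probe")
    iv <- introns[introns$gene == g$gene, , drop = FALSE]
    hit <- iv[iv$start <= interval$end & iv$end >= interval$start, ,
              drop = FALSE]
    if (nrow(hit) == 0L)
      stop_named("probe overlaps no annotated intron of %s", g$gene)
    hit <- hit[order(hit$start), , drop = FALSE]
    first <- hit$intron[1L]; last <- hit$intron[nrow(hit)]
    lab <- if (first == last) sprintf("IVS%d", first)
           else sprintf("IVS%d-IVS%d", first, last)
    return(paste0(g$gene, "_", lab))
  }
  if (is.null(centromere))
    stop_named("centromere position required to name an intergenic probe")
  # nearest gene by gap distance (0 if abutting or overlapping partially)
  d_lo <- pmax(0, genes$start - interval$end)   # gene is downstream
  d_hi <- pmax(0, interval$start - genes$end)   # gene is upstream
  dist <- pmax(d_lo, d_hi)
  g <- genes[which.min(dist), ]
  d <- min(dist)
  probe_mid <- (interval$start + interval$end) / 2
  gene_mid <- (g$start + g$end) / 2
  side <- if (abs(probe_mid - centromere) < abs(gene_mid - centromere))
    "cen" else "tel"
  sprintf("%s_%s%d", g$gene, side, as.integer(d))
}

#' Construct a piecewise-constant genomic signal track
#'
#' @param chrom,start,end,value equal-length vectors; segments must not
#'   overlap within a chromosome (segments may share an endpoint, since
#'   lengths follow the package's `end - start` convention).
#' @return track `data.frame`.
#' @export
signal_track <- function(chrom, start, end, value) {
  x <- genomic_interval(chrom, start, end)
  x$value <- as.numeric(value)
  if (any(x$value < 0)) stop_named("track values must be >= 0")
  for (ch in unique(x$chrom)) {
    s <- x[x$chrom == ch, , drop = FALSE]
    s <- s[order(s$start), , drop = FALSE]
    if (nrow(s) > 1L && any(s$start[-1L] < s$end[-nrow(s)]))
      stop_named("overlapping track segments on %s", ch)
  }
  x
}

#' Integrate a signal track over an interval
#'
#' Cumulative signal is the sum over overlapping segments of
#' `value * overlap_bp`, with overlap measured as
#' `min(end) - max(start)` — the same `end - start` length convention
#' used for spans, which makes integration additive over partitions
#' sharing an endpoint. Uncovered bases contribute zero. The per-bp mean
#' divides by the interval span.
#'
#' @param track track `data.frame` (`chrom`, `start`, `end`, `value`).
#' @param interval single-row interval table.
#' @return list with `cumulative` and `per_bp`.
#' @export
integrate_track <- function(track, interval) {
  stopifnot(nrow(interval) == 1L,
            all(c("chrom", "start", "end", "value") %in% names(track)))
  seg <- track[track$chrom == interval$chrom, , drop = FALSE]
  ov <- pmax(0, pmin(seg$end, interval$end) - pmax(seg$start,
                                                   interval$start))
  cumulative <- sum(seg$value * ov)
  list(cumulative = cumulative,
       per_bp = cumulative / span_length(interval))
}

#' Compare integrated chromatin-mark intensities between DA and EA groups
#'
#' For each mark, Welch-tests the integrated intensities of DA intervals
#' against EA intervals. Values exceeding `outlier_factor` times their
#' group median are flagged (e.g. a probe sitting in a highly accessible
#' promoter); flagged values are removed from the test only when
#' `censor = TRUE`, and censored ids are always reported — censoring is
#' opt-in and logged, never silent.
#'
#' @param values `data.frame` with columns `mark`, `group`
#'   (`"DA"`/`"EA"`), `id`, `value`.
#' @param censor drop flagged outliers before testing (default FALSE).
#' @param outlier_factor flag threshold as a multiple of the group
#'   median (default 10).
#' @param alpha significance level (default 0.05).
#' @return `data.frame` with one row per mark: group means, Welch t and
#'   p, `flagged` and `censored` id strings.
#' @export
compare_marks <- function(values, censor = FALSE, outlier_factor = 10,
                          alpha = 0.05) {
  stopifnot(all(c("mark", "group", "id", "value") %in% names(values)),
            all(values$group %in% c("DA", "EA")))
  out <- lapply(split(values, values$mark), function(v) {
    med <- tapply(v$value, v$group, median)
    flag <- v$value > outlier_factor * med[v$group]
    used <- if (censor) v[!flag, , drop = FALSE] else v
    da <- used$value[used$group == "DA"]
    ea <- used$value[used$group == "EA"]
    if (length(da) < 2L || length(ea) < 2L)
      stop_named("mark %s: need >= 2 values per group", v$mark[1L])
    tst <- welch_t(da, ea, alpha = alpha)
    data.frame(mark = v$mark[1L], n_da = length(da), n_ea = length(ea),
               mean_da = mean(da), mean_ea = mean(ea),
               statistic = tst$statistic, p_value = tst$p_value,
               flagged = paste(v$id[flag], collapse = ","),
               censored = if (censor) paste(v$id[flag], collapse = ",")
                          else "",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Construct a set of topologically associated domains (TADs)
#'
#' @param chrom,start,end equal-length vectors of disjoint TAD
#'   intervals (sorted within chromosome after construction).
#' @param resolution contact-map resolution in bp that produced the
#'   TAD calls (default 25000); also the default boundary-proximity
#'   window for [classify_tad_overlap()].
#' @return object of class `tad_set` (a data.frame with a `resolution`
#'   attribute).
#' @export
tad_set <- function(chrom, start, end, resolution = 25000) {
  x <- genomic_interval(chrom, start, end)
  x <- x[order(x$chrom, x$start), , drop = FALSE]
  for (ch in unique(x$chrom)) {
    s <- x[x$chrom == ch, , drop = FALSE]
    if (nrow(s) > 1L && any(s$start[-1L] < s$end[-nrow(s)]))
      stop_named("overlapping TADs on %s", ch)
  }
  rownames(x) <- NULL
  attr(x, "resolution") <- resolution
  class(x) <- c("tad_set", "data.frame")
  x
}

#' Classify how a DA domain relates to the TAD partition
#'
#' Exactly one label per domain:
#' \describe{
#'   \item{within}{hull fully inside one TAD, more than
#'     `boundary_window` bp from both of its edges.}
#'   \item{within_boundary_proximal}{fully inside one TAD but within
#'     `boundary_window` of an edge (the domain approaches a TAD
#'     boundary).}
#'   \item{spans_boundary}{overlaps two or more TADs, or crosses a TAD
#'     edge.}
#'   \item{between_tads}{overlaps no TAD (sits in an inter-TAD gap).}
#' }
#'
#' @param domain a `da_domain` or a single-row interval table (the
#'   hull).
#' @param tads a [tad_set()].
#' @param boundary_window proximity window in bp (default: the TAD
#'   resolution, i.e. one contact-map bin).
#' @return one of the four labels above.
#' @export
classify_tad_overlap <- function(domain, tads,
                                 boundary_window = attr(tads,
                                                        "resolution")) {
  hull <- if (inherits(domain, "da_domain")) domain$hull else domain
  stopifnot(nrow(hull) == 1L, inherits(tads, "tad_set"))
  t <- tads[tads$chrom == hull$chrom, , drop = FALSE]
  ov <- pmax(0, pmin(t$end, hull$end) - pmax(t$start, hull$start)) > 0
  if (!any(ov)) return("between_tads")
  if (sum(ov) >= 2L) return("spans_boundary")
  tad <- t[ov, ]
  if (hull$start < tad$start || hull$end > tad$end)
    return("spans_boundary")
  margin <- min(hull$start - tad$start, tad$end - hull$end)
  if (margin > boundary_window) "within" else "within_boundary_proximal"
}
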