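# Primer-level sequence metrics: GC content, nearest-neighbor melting
# temperature, self-complementarity, and the pair-level constraint report.

.check_dna <- function(seq) {
  seq <- toupper(as.character(seq))
  if (any(!nzchar(seq))) stop_named("empty DNA sequence")
  bad <- regmatches(seq, regexpr("[^ACGT]", seq))
  if (length(unlist(bad)))
    stop_named("non-ACGT character '%s' in sequence", unlist(bad)[1L])
  seq
}

#' GC content of a DNA sequence
#'
#' @param seq character vector of DNA sequences (A/C/G/T).
#' @return fraction of G+C bases, in [0, 1].
#' @examples
#' gc_content(c("ATAT", "GCGC"))
#' @export
gc_content <- function(seq) {
  seq <- .check_dna(seq)
  gc <- nchar(gsub("[AT]", "", seq))
  gc / nchar(seq)
}

# SantaLucia (1998) unified nearest-neighbor parameters.
# dH in kcal/mol, dS in cal/(mol K); keys are 5'->3' dinucleotides.
.nn_dH <- c(AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2,
            CA = -8.5, TG = -8.5, GT = -8.4, AC = -8.4,
            CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
            CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0)
.nn_dS <- c(AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3,
            CA = -22.7, TG = -22.7, GT = -22.4, AC = -22.4,
            CT = -21.0, AG = -21.0, GA = -22.2, TC = -22.2,
            CG = -27.2, GC = -24.4, GG = -19.9, CC = -19.9)

#' Nearest-neighbor melting temperature
#'
#' Unified nearest-neighbor thermodynamics (SantaLucia 1998 parameter
#' set) with duplex initiation terms for the terminal base pairs, the
#' entropic monovalent-salt correction `0.368 (N-1) ln[Na+]`, and
#' `Tm = 1000 dH / (dS + R ln(Ct/4)) - 273.15` for non-self-complementary
#' duplexes at total strand concentration `Ct`.
#'
#' @param seq character vector of primer sequences (A/C/G/T).
#' @param Na monovalent cation concentration in mM (default 50).
#' @param conc total primer concentration in mol/L (default 5e-7,
#'   i.e. 500 nM).
#' @return melting temperature(s) in degrees Celsius.
#' @export
melting_temperature <- function(seq, Na = 50, conc = 5e-7) {
  seq <- .check_dna(seq)
  vapply(seq, function(s) {
    n <- nchar(s)
    if (n < 2L) stop_named("sequence too short for nearest-neighbor model")
    b <- strsplit(s, "")[[1L]]
    steps <- paste0(b[-n], b[-1L])
    dH <- sum(.nn_dH[steps])
    dS <- sum(.nn_dS[steps])
    for (term in b[c(1L, n)]) {
      if (term %in% c("G", "C")) { dH <- dH + 0.1; dS <- dS - 2.8 }
      else { dH <- dH + 2.3; dS <- dS + 4.1 }
    }
    dS <- dS + 0.368 * (n - 1L) * log(Na / 1000)
    1000 * dH / (dS + 1.987 * log(conc / 4)) - 273.15
  }, numeric(1L), USE.NAMES = FALSE)
}

.revcomp <- function(seq) {
  chartr("ACGT", "TGCA",
         vapply(seq, function(s) paste(rev(strsplit(s, "")[[1L]]),
                                       collapse = ""), "",
                USE.NAMES = FALSE))
}

#' Self-complementarity score of a primer
#'
#' Maximum number of Watson-Crick matches over all ungapped alignments
#' of the sequence against its own reverse complement. High scores mark
#' primers prone to hairpins and self-dimers.
#'
#' @param seq character vector of DNA sequences.
#' @return integer score(s); 0 means no self-pairing at any offset.
#' @examples
#' self_complementarity("ACGT")  # 4: a perfect palindrome
#' @export
self_complementarity <- function(seq) {
  seq <- .check_dna(seq)
  rc <- .revcomp(seq)
  vapply(seq_along(seq), function(i) {
    a <- strsplit(seq[i], "")[[1L]]
    b <- strsplit(rc[i], "")[[1L]]
    n <- length(a)
    best <- 0L
    for (off in (-(n - 1L)):(n - 1L)) {
      ia <- seq_len(n) + off
      ok <- ia >= 1L & ia <= n
      best <- max(best, sum(a[ia[ok]] == b[ok]))
    }
    as.integer(best)
  }, integer(1L), USE.NAMES = FALSE)
}

#' Construct a primer pair record
#'
#' Computes GC content, nearest-neighbor Tm and self-complementarity for
#' both primers; `product_length` is the expected PCR product size in bp.
#'
#' @param forward_seq,reverse_seq primer sequences (A/C/G/T).
#' @param product_length expected amplicon length in bp (> 0).
#' @param ... passed to [melting_temperature()].
#' @return a list of class `primer_pair`.
#' @export
primer_pair <- function(forward_seq, reverse_seq, product_length, ...) {
  forward_seq <- .check_dna(forward_seq)
  reverse_seq <- .check_dna(reverse_seq)
  stopifnot(length(product_length) == 1L, product_length > 0)
  structure(list(
    forward_seq = forward_seq, reverse_seq = reverse_seq,
    tm_forward = melting_temperature(forward_seq, ...),
    tm_reverse = melting_temperature(reverse_seq, ...),
    gc_forward = gc_content(forward_seq),
    gc_reverse = gc_content(reverse_seq),
    product_length = as.numeric(product_length),
    self_complementarity = max(self_complementarity(forward_seq),
                               self_complementarity(reverse_seq))),
    class = "primer_pair")
}

#' Evaluate a primer pair against the probe-production constraints
#'
#' Hard rules (any failure disqualifies): both Tm in `tm_range`, Tm
#' difference at most `max_tm_diff`, product no longer than the
#' single-copy interval and no shorter than the interval minus
#' `product_min_slack`. Soft rules (preferences that only affect
#' ranking): both GC contents in `gc_range`, both primers longer than
#' `min_primer_len` bases. Survivors are ordered by soft failures, then
#' self-complementarity, then Tm difference, then distance from the
#' optimal Tm — lower `rank_key` is better.
#'
#' @param pair a [primer_pair()].
#' @param sc_interval_length length of the single-copy interval in bp.
#' @param tm_range hard Tm window in Celsius (default `c(58, 65)`).
#' @param optimal_tm rank target Tm (default 62).
#' @param max_tm_diff hard ceiling on |Tm difference| (default 2).
#' @param gc_range soft GC window (default `c(0.40, 0.60)`).
#' @param min_primer_len soft primer length floor (default 25).
#' @param product_min_slack bp below the interval length still accepted
#'   for the product minimum (default 500).
#' @return list with `checks` (named logicals, TRUE = pass),
#'   `hard_pass`, `soft_failures` and `rank_key`.
#' @export
evaluate_primer_pair <- function(pair, sc_interval_length,
                                 tm_range = c(58, 65), optimal_tm = 62,
                                 max_tm_diff = 2, gc_range = c(0.40, 0.60),
                                 min_primer_len = 25,
                                 product_min_slack = 500) {
  stopifnot(inherits(pair, "primer_pair"), sc_interval_length > 0)
  dtm <- abs(pair$tm_forward - pair$tm_reverse)
  checks <- c(
    tm_window = pair$tm_forward >= tm_range[1] &&
      pair$tm_forward <= tm_range[2] &&
      pair$tm_reverse >= tm_range[1] && pair$tm_reverse <= tm_range[2],
    tm_difference = dtm <= max_tm_diff,
    product_max = pair$product_length <= sc_interval_length,
    product_min = pair$product_length >= sc_interval_length - product_min_slack,
    gc_window = pair$gc_forward >= gc_range[1] &&
      pair$gc_forward <= gc_range[2] &&
      pair$gc_reverse >= gc_range[1] && pair$gc_reverse <= gc_range[2],
    primer_length = nchar(pair$forward_seq) > min_primer_len &&
      nchar(pair$reverse_seq) > min_primer_len)
  hard <- c("tm_window", "tm_difference", "product_max", "product_min")
  soft <- c("gc_window", "primer_length")
  soft_failures <- sum(!checks[soft])
  rank_key <- soft_failures * 1e4 + pair$self_complementarity * 1e2 +
    dtm * 10 + abs(mean(c(pair$tm_forward, pair$tm_reverse)) - optimal_tm)
  list(checks = checks, hard_pass = all(checks[hard]),
       soft_failures = soft_failures, rank_key = rank_key)
}

#' Rank candidate primer pairs for one single-copy interval
#'
#' Disqualifies hard-rule failures and orders the survivors by
#' `rank_key` (see [evaluate_primer_pair()]). At most `max_candidates`
#' pairs are considered, mirroring the usual enumeration cap in primer
#' design.
#'
#' @param pairs list of [primer_pair()] objects.
#' @param sc_interval_length single-copy interval length in bp.
#' @param max_candidates cap on evaluated candidates (default 20).
#' @param ... passed to [evaluate_primer_pair()].
#' @return `data.frame` of surviving candidates sorted best-first, with
#'   their index into `pairs` and rank keys.
#' @export
rank_primer_pairs <- function(pairs, sc_interval_length,
                              max_candidates = 20, ...) {
  pairs <- head(pairs, max_candidates)
  reports <- lapply(pairs, evaluate_primer_pair,
                    sc_interval_length = sc_interval_length, ...)
  keep <- vapply(reports, `[[`, logical(1L), "hard_pass")
  out <- data.frame(
    index = seq_along(pairs),
    hard_pass = keep,
    soft_failures = vapply(reports, `[[`, numeric(1L), "soft_failures"),
    rank_key = vapply(reports, `[[`, numeric(1L), "rank_key"))
  out <- out[out$hard_pass, , drop = FALSE]
  out[order(out$rank_key), , drop = FALSE]
}
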