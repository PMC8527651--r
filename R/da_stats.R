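# DA/EA scoring of categorical homolog intensity calls and the
# statistical battery used to classify probes, compare samples, tissues
# and chromatin-mark groups.

.categories <- c("bright", "medium", "dim", "nil")

test_result <- function(statistic, p_value, method, alpha = 0.05, ...) {
  stopifnot(p_value >= 0, p_value <= 1 + 1e-12)
  structure(list(statistic = unname(statistic),
                 p_value = min(1, unname(p_value)),
                 method = method, alpha = alpha, ...),
            class = "da_test")
}

#' @export
print.da_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g (alpha = %g)\n",
              x$method, x$statistic, x$p_value, x$alpha))
  invisible(x)
}

#' Score one metaphase cell from its two homolog intensity categories
#'
#' Each homolog is graded `bright`, `medium`, `dim` or `nil`. A cell is
#' differentially accessible (`DA`) when the homologs are graded
#' differently (bright/medium, bright/dim, bright/nil, medium/dim,
#' medium/nil), equivalently accessible (`EA`) when both are bright or
#' both medium, and `EXCLUDED` for the uninformative pairs dim/dim,
#' nil/nil and dim/nil (in either order) or when the hybridized region
#' was involved in a chromosome overlap.
#'
#' @param cat1,cat2 character vectors of homolog intensity categories.
#' @param overlap logical vector: chromosome overlap at the target
#'   (forces exclusion).
#' @return `data.frame` with columns `call` (`DA`/`EA`/`EXCLUDED`) and
#'   `reason` (`NA` unless excluded).
#' @examples
#' score_cell("bright", "dim")     # DA
#' score_cell("medium", "medium")  # EA
#' score_cell("dim", "nil")        # EXCLUDED
#' @export
score_cell <- function(cat1, cat2, overlap = FALSE) {
  cat1 <- tolower(as.character(cat1)); cat2 <- tolower(as.character(cat2))
  n <- max(length(cat1), length(cat2))
  cat1 <- rep_len(cat1, n); cat2 <- rep_len(cat2, n)
  overlap <- rep_len(as.logical(overlap), n)
  bad <- !(cat1 %in% .categories) | !(cat2 %in% .categories)
  if (any(bad))
    stop_named("unknown intensity category '%s'",
               c(cat1, cat2)[!c(cat1, cat2) %in% .categories][1L])
  lo <- pmin(cat1, cat2); hi <- pmax(cat1, cat2)  # order-free pair key
  key <- paste(lo, hi)
  excluded_pairs <- c("dim dim", "nil nil", "dim nil")
  call <- ifelse(key %in% excluded_pairs, "EXCLUDED",
                 ifelse(cat1 == cat2, "EA", "DA"))
  reason <- ifelse(key %in% excluded_pairs, paste0(lo, "/", hi),
                   NA_character_)
  call[overlap] <- "EXCLUDED"
  reason[overlap] <- "chromosome overlap"
  data.frame(call = call, reason = reason, stringsAsFactors = FALSE)
}

#' Summarize cell scores per probe, sample and tissue
#'
#' @param scores `data.frame` with columns `probe`, `sample`, `tissue`,
#'   `cat1`, `cat2` and optionally `overlap`.
#' @return `data.frame` with one row per (probe, sample, tissue) and
#'   counts `n_da`, `n_ea`, `n_excluded`.
#' @export
summarize_scores <- function(scores) {
  stopifnot(all(c("probe", "sample", "tissue", "cat1", "cat2") %in%
                  names(scores)))
  ov <- scores$overlap %||% FALSE
  calls <- score_cell(scores$cat1, scores$cat2, ov)$call
  key <- interaction(scores$probe, scores$sample, scores$tissue,
                     drop = TRUE, lex.order = TRUE, sep = "\r")
  tab <- table(key, factor(calls, levels = c("DA", "EA", "EXCLUDED")))
  ids <- do.call(rbind, strsplit(rownames(tab), "\r", fixed = TRUE))
  data.frame(probe = ids[, 1L], sample = ids[, 2L], tissue = ids[, 3L],
             n_da = as.integer(tab[, "DA"]),
             n_ea = as.integer(tab[, "EA"]),
             n_excluded = as.integer(tab[, "EXCLUDED"]),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Two-tailed binomial test with normal approximation
#'
#' Tests whether `k` successes in `n` trials are compatible with success
#' probability `p0` using the normal approximation
#' `z = (k - n p0) / sqrt(n p0 (1 - p0))`, two-sided. The half-unit
#' continuity correction (default) keeps the approximate p within 0.002
#' of the exact two-sided binomial p at the cell counts used here
#' (n around 25); without it the gap reaches 0.16 near the null.
#'
#' @param k successes (0..n).
#' @param n trials (>= 1).
#' @param p0 null success probability (default 0.5: DA and EA calls
#'   equally likely under no accessibility bias).
#' @param correct apply the continuity correction (default TRUE).
#' @param alpha significance level carried in the result (default 0.05).
#' @return a `da_test` result (statistic is z).
#' @export
binomial_test_normal <- function(k, n, p0 = 0.5, correct = TRUE,
                                 alpha = 0.05) {
  stopifnot(length(k) == 1L, length(n) == 1L)
  if (n < 1) stop_named("binomial test requires n >= 1")
  if (k < 0 || k > n) stop_named("k must lie in 0..n")
  if (p0 <= 0 || p0 >= 1) stop_named("p0 must lie in (0, 1)")
  se <- sqrt(n * p0 * (1 - p0))
  dev <- abs(k - n * p0)
  if (correct) dev <- max(0, dev - 0.5)
  z <- sign(k - n * p0) * dev / se
  test_result(z, 2 * (1 - pnorm(abs(z))),
              "two-tailed binomial test (normal approximation)",
              alpha, k = k, n = n, p0 = p0)
}

#' Classify a probe as DA, EA or indeterminate
#'
#' Pools scored cells across a probe's samples, then calls the probe
#' `DA` when the DA fraction exceeds 1/2 and the binomial test against
#' 0.5 is significant at `alpha`; `EA` symmetrically; `indeterminate`
#' otherwise. The observational two-thirds landmark (more than 2/3 of
#' scored cells concordant) is reported as a flag, not used as a gate.
#' Pooling fewer than `min_cells` scored cells attaches a warning string
#' to the result rather than failing silently.
#'
#' @param summary `data.frame` rows for one probe with `n_da`, `n_ea`
#'   columns (as from [summarize_scores()]).
#' @param alpha significance level (default 0.05).
#' @param min_cells minimum pooled scored cells (default 25).
#' @return list with `call`, `p_value`, `frac_da`, `n_da`, `n_ea`,
#'   `two_thirds` flag and optional `warning`.
#' @export
classify_probe <- function(summary, alpha = 0.05, min_cells = 25) {
  stopifnot(all(c("n_da", "n_ea") %in% names(summary)))
  n_da <- sum(summary$n_da); n_ea <- sum(summary$n_ea)
  n <- n_da + n_ea
  if (n == 0L) stop_named("no scored cells to classify")
  tst <- binomial_test_normal(n_da, n, alpha = alpha)
  frac <- n_da / n
  call <- "indeterminate"
  if (tst$p_value < alpha) call <- if (frac > 0.5) "DA" else "EA"
  if (call == "EA" && n_ea / n <= 0.5) call <- "indeterminate"
  out <- list(call = call, p_value = tst$p_value, frac_da = frac,
              n_da = n_da, n_ea = n_ea,
              two_thirds = max(frac, 1 - frac) > 2 / 3)
  if (n < min_cells)
    out$warning <- sprintf("only %d scored cells (minimum %d)", n,
                           min_cells)
  out
}

#' Two-proportion z-test (pooled variance)
#'
#' Compares DA fractions between two samples with the pooled-variance
#' z statistic and a two-sided normal p-value; no continuity correction.
#'
#' @param k1,n1 successes and trials in sample 1.
#' @param k2,n2 successes and trials in sample 2.
#' @param alpha significance level (default 0.05).
#' @return a `da_test` result (statistic is z).
#' @export
two_proportion_z <- function(k1, n1, k2, n2, alpha = 0.05) {
  stopifnot(k1 >= 0, k1 <= n1, k2 >= 0, k2 <= n2, n1 >= 1, n2 >= 1)
  p_hat <- (k1 + k2) / (n1 + n2)
  if (p_hat == 0 || p_hat == 1)
    stop_named("degenerate pooled proportion (%g): zero variance", p_hat)
  z <- (k1 / n1 - k2 / n2) /
    sqrt(p_hat * (1 - p_hat) * (1 / n1 + 1 / n2))
  test_result(z, 2 * (1 - pnorm(abs(z))), "two-proportion z-test", alpha,
              p1 = k1 / n1, p2 = k2 / n2)
}

# Tie-corrected normal approximation variance of the Mann-Whitney U.
.mwu_var <- function(x, y) {
  m <- length(x); n <- length(y); N <- m + n
  ties <- table(c(x, y))
  m * n / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum test of a location shift between two samples of
#' intensity ratios. When both samples have at most `exact_max`
#' observations and there are no ties, the exact null distribution of U
#' is used; otherwise the normal approximation with mid-ranks and tie
#' correction. The continuity correction (default on) keeps the
#' approximate p within about 0.01 of the exact p at the sample sizes
#' used here; set `correct = FALSE` to obtain the uncorrected z whose
#' square equals the Kruskal-Wallis H for two groups.
#'
#' @param x,y numeric samples (non-empty).
#' @param exact force (`TRUE`) or forbid (`FALSE`) the exact null;
#'   `NULL` (default) decides by size and ties.
#' @param exact_max exact-mode size cap per sample (default 8).
#' @param correct continuity correction for the normal approximation.
#' @param alpha significance level (default 0.05).
#' @return a `da_test` result; `statistic` is U (for `x`), with `z`
#'   attached when the normal approximation is used.
#' @export
mann_whitney_u <- function(x, y, exact = NULL, exact_max = 8,
                           correct = TRUE, alpha = 0.05) {
  stopifnot(length(x) >= 1L, length(y) >= 1L)
  m <- length(x); n <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  has_ties <- anyDuplicated(c(x, y)) > 0L
  use_exact <- exact %||% (m <= exact_max && n <= exact_max && !has_ties)
  if (use_exact && has_ties)
    stop_named("exact Mann-Whitney null requires untied samples")
  if (use_exact) {
    p <- 2 * min(pwilcox(U, m, n), 1 - pwilcox(U - 1, m, n))
    return(test_result(U, min(1, p), "Mann-Whitney U test (exact)",
                       alpha, exact = TRUE))
  }
  mu <- m * n / 2
  s2 <- .mwu_var(x, y)
  if (s2 == 0) return(test_result(U, 1, "Mann-Whitney U test (normal approximation)",
                                  alpha, z = 0, exact = FALSE))
  dev <- abs(U - mu)
  if (correct) dev <- max(0, dev - 0.5)
  z <- sign(U - mu) * dev / sqrt(s2)
  test_result(U, 2 * (1 - pnorm(abs(z))),
              "Mann-Whitney U test (normal approximation)", alpha,
              z = z, exact = FALSE)
}

#' Kruskal-Wallis rank test across groups
#'
#' Tie-corrected H with a chi-square reference on k - 1 degrees of
#' freedom (via `stats::kruskal.test`); used to compare per-tissue DA
#' fractions across tissues. Identical observations across all groups
#' give H = 0, p = 1 rather than an error.
#'
#' @param groups list of numeric samples (>= 2 groups, each non-empty).
#' @param alpha significance level (default 0.05).
#' @return a `da_test` result (statistic is H).
#' @export
kruskal_wallis <- function(groups, alpha = 0.05) {
  stopifnot(is.list(groups), length(groups) >= 2L,
            all(lengths(groups) >= 1L))
  values <- unlist(groups, use.names = FALSE)
  if (length(unique(values)) == 1L)
    return(test_result(0, 1, "Kruskal-Wallis rank sum test", alpha,
                       df = length(groups) - 1L))
  g <- factor(rep(seq_along(groups), lengths(groups)))
  kt <- kruskal.test(values, g)
  test_result(kt$statistic, kt$p.value, "Kruskal-Wallis rank sum test",
              alpha, df = unname(kt$parameter))
}

#' Welch two-sample t-test
#'
#' Unpaired t-test with the Welch correction for unequal variances
#' (via `stats::t.test`); used for mean integrated chromatin-mark
#' intensities between DA and EA interval groups.
#'
#' @param x,y numeric samples, each of size >= 2; at least one with
#'   nonzero variance.
#' @param alpha significance level (default 0.05).
#' @return a `da_test` result with `df` attached.
#' @export
welch_t <- function(x, y, alpha = 0.05) {
  stopifnot(length(x) >= 2L, length(y) >= 2L)
  if (sd(x) == 0 && sd(y) == 0) {
    if (mean(x) == mean(y))
      return(test_result(0, 1, "Welch two-sample t-test", alpha,
                         df = length(x) + length(y) - 2))
    stop_named("both samples have zero variance")
  }
  tt <- t.test(x, y, var.equal = FALSE)
  test_result(tt$statistic, tt$p.value, "Welch two-sample t-test",
              alpha, df = unname(tt$parameter))
}
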