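# Synthetic inputs with known ground truth: two-spot metaphase FISH
# images, categorical score tables, repeat/CNV landscapes with planted
# single-copy runs, chromatin-mark signal tracks, and TAD partitions.
# Every generator is a pure function of its arguments and seed.

#' Generate a synthetic two-spot metaphase FISH image
#'
#' Two isotropic Gaussian-profile hybridization signals with exact
#' integrated photon sums `S` and `rho * S` are placed on a constant
#' background, with optional Poisson or Gaussian read noise. The ground
#' truth records the centers, the per-spot sums, and the true homolog
#' intensity ratio `(1 - rho) / (1 + rho)`. Chromosome morphology is not
#' modeled: the spot centers stand in for the expected probe target
#' location on each homolog.
#'
#' @param rho homolog intensity asymmetry in [0, 1]: the dim homolog
#'   carries `rho` times the bright homolog's integrated signal.
#' @param total integrated photon sum S of the bright homolog
#'   (default 30000).
#' @param shape image shape in px (default 64 x 64).
#' @param centers 2 x 2 matrix of spot centers (row, col); defaults to
#'   horizontally separated thirds of the image.
#' @param psf_sigma point-spread sigma in px (default 2).
#' @param background constant background level (default 20).
#' @param noise `"gaussian"` (default), `"poisson"` or `"none"`.
#' @param noise_sd Gaussian read-noise sd (default 3).
#' @param min_separation error if the centers are closer than this
#'   (default `6 * psf_sigma`): overlapping signals are unscorable by
#'   design.
#' @param seed RNG seed (generation is byte-reproducible given a seed).
#' @return object of class `fish_image`: list with `pixels` and
#'   `truth` (centers, sums, ratio).
#' @export
generate_fish_image <- function(rho, total = 30000, shape = c(64, 64),
                                centers = NULL, psf_sigma = 2,
                                background = 20,
                                noise = c("gaussian", "poisson", "none"),
                                noise_sd = 3,
                                min_separation = 6 * psf_sigma,
                                seed = NULL) {
  stopifnot(rho >= 0, rho <= 1, psf_sigma > 0, total > 0,
            background >= 0)
  noise <- match.arg(noise)
  if (is.null(centers))
    centers <- rbind(c(shape[1L] / 2, shape[2L] * 0.3),
                     c(shape[1L] / 2, shape[2L] * 0.7))
  centers <- as.matrix(centers)
  stopifnot(nrow(centers) == 2L, ncol(centers) == 2L)
  sep <- sqrt(sum((centers[1L, ] - centers[2L, ])^2))
  if (sep < min_separation)
    stop_named("spot centers %.1f px apart, below the %.1f px separation floor",
               sep, min_separation)
  sums <- c(total, rho * total)
  img <- matrix(background, shape[1L], shape[2L])
  for (i in 1:2) {
    py <- dnorm(seq_len(shape[1L]), centers[i, 1L], psf_sigma)
    px <- dnorm(seq_len(shape[2L]), centers[i, 2L], psf_sigma)
    img <- img + sums[i] * outer(py, px)
  }
  img <- local_seed(seed, {
    switch(noise,
           gaussian = matrix(pmax(0, img + rnorm(length(img),
                                                 sd = noise_sd)),
                             nrow(img)),
           poisson = matrix(rpois(length(img), img), nrow(img)),
           none = img)
  })
  structure(list(pixels = img,
                 truth = list(centers = centers, sums = sums,
                              ratio = if (sum(sums) > 0)
                                abs(diff(sums)) / sum(sums) else NA_real_)),
            class = "fish_image")
}

#' Generate a batch of synthetic cells in a DA or EA intensity regime
#'
#' Draws one image per cell with a per-cell true intensity ratio from a
#' normal distribution centred on `ratio_median` (truncated to [0, 1])
#' and the corresponding homolog asymmetry
#' `rho = (1 - ratio) / (1 + ratio)`. The default medians emulate the
#' scale of observed DA and EA ratio distributions (around 0.8 for
#' differentially accessible loci, 0.2 for equivalently accessible
#' ones), without claiming to reproduce any real image set.
#'
#' @param n cells in the batch (default 25, the per-probe quantification
#'   count).
#' @param regime `"DA"` or `"EA"`.
#' @param ratio_median target median true ratio (defaults 0.8 for DA,
#'   0.2 for EA).
#' @param ratio_sd per-cell spread of the true ratio (default 0.1).
#' @param seed RNG seed (per-cell image seeds are derived from it).
#' @param ... passed to [generate_fish_image()].
#' @return list with `images` (list of `fish_image`) and `true_ratios`.
#' @export
generate_fish_batch <- function(n = 25, regime = c("DA", "EA"),
                                ratio_median = NULL, ratio_sd = 0.1,
                                seed = NULL, ...) {
  regime <- match.arg(regime)
  ratio_median <- ratio_median %||% if (regime == "DA") 0.8 else 0.2
  local_seed(seed, {
    ratios <- pmin(1, pmax(0, rnorm(n, ratio_median, ratio_sd)))
    seeds <- sample.int(.Machine$integer.max - 1L, n)
    images <- lapply(seq_len(n), function(i) {
      rho <- (1 - ratios[i]) / (1 + ratios[i])
      generate_fish_image(rho, seed = seeds[i], ...)
    })
    list(images = images, true_ratios = ratios)
  })
}

.da_pairs <- rbind(c("bright", "medium"), c("bright", "dim"),
                   c("bright", "nil"), c("medium", "dim"),
                   c("medium", "nil"))
.ea_pairs <- rbind(c("bright", "bright"), c("medium", "medium"))
.excluded_pairs <- rbind(c("dim", "dim"), c("nil", "nil"),
                         c("dim", "nil"))

#' Generate a synthetic cell-score table
#'
#' Emulates analyst scoring of hybridized metaphase cells: each cell is
#' excluded with probability `p_excluded` (drawing one of the excluded
#' category pairs), otherwise scored with a DA-consistent category pair
#' with probability `p_da` or an EA-consistent pair otherwise. Pairs are
#' drawn uniformly within their class and homolog order is randomized,
#' so the generator and [score_cell()] agree by construction.
#'
#' @param probes character vector of probe names.
#' @param n_samples samples per probe (default 2, the validation
#'   minimum).
#' @param cells_per_sample cells scored per sample (default 25, the
#'   scoring minimum).
#' @param p_da per-cell probability of a DA-consistent score
#'   (default 0.8, the middle of the observed 73-89 percent range).
#' @param p_excluded per-cell exclusion probability (default 0.1).
#' @param tissue tissue label(s), recycled over samples
#'   (default "lymphocyte").
#' @param seed RNG seed.
#' @return `data.frame` with columns `probe`, `sample`, `tissue`,
#'   `cell_id`, `cat1`, `cat2`, `overlap`.
#' @export
generate_cell_scores <- function(probes = "probe1", n_samples = 2,
                                 cells_per_sample = 25, p_da = 0.8,
                                 p_excluded = 0.1,
                                 tissue = "lymphocyte", seed = NULL) {
  stopifnot(p_da >= 0, p_da <= 1, p_excluded >= 0, p_excluded <= 1)
  tissue <- rep_len(tissue, n_samples)
  local_seed(seed, {
    rows <- list()
    for (pr in probes) for (s in seq_len(n_samples)) {
      n <- cells_per_sample
      excl <- runif(n) < p_excluded
      da <- runif(n) < p_da
      pick <- function(pairs) pairs[sample.int(nrow(pairs), 1L), ]
      cats <- t(vapply(seq_len(n), function(i) {
        pair <- if (excl[i]) pick(.excluded_pairs)
                else if (da[i]) pick(.da_pairs) else pick(.ea_pairs)
        if (runif(1) < 0.5) rev(pair) else pair
      }, character(2L)))
      rows[[length(rows) + 1L]] <- data.frame(
        probe = pr, sample = sprintf("%s_s%d", pr, s),
        tissue = tissue[s], cell_id = seq_len(n),
        cat1 = cats[, 1L], cat2 = cats[, 2L], overlap = FALSE,
        stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
  })
}

#' Generate a repeat/CNV landscape with planted single-copy runs
#'
#' Plants repeat-free single-copy runs inside a region and tiles the
#' rest with repeat elements whose consensus divergence is drawn from a
#' two-component distribution (mass `1 - p_divergent` below 20 percent,
#' the masking regime; the rest in the 20-60 percent regime that behaves
#' as unique sequence). Tiles abut the planted run boundaries exactly,
#' and inter-tile gaps stay below the minimum probe length, so the
#' plantable single-copy intervals are exactly the planted runs (plus
#' any stretches uncovered because their tiles drew high divergence).
#' The ground truth lists those plantable intervals, computed from the
#' generator's own bookkeeping.
#'
#' @param region single-row interval table (default `chrSim:1-50000`).
#' @param sc_runs data.frame of planted runs (`start`, `end`); default:
#'   three 2 kb runs evenly placed.
#' @param p_divergent probability a tile draws divergence >= 20
#'   (default 0: all tiles mask).
#' @param tile_len mean repeat tile length in bp (default 600).
#' @param gap_max maximum inter-tile gap in bp (default 200; kept well
#'   below the 1400 bp probe minimum).
#' @param cnvs data.frame of planted CNVs (`start`, `end`,
#'   `frequency`); default: one common (2 percent) and one rare
#'   (0.5 percent) CNV in the first and last quarter.
#' @param min_len minimum plantable run length in bp used for the
#'   ground-truth list (default 1400, the probe minimum).
#' @param seed RNG seed.
#' @return list with `repeats`, `cnvs`, `sc_truth` (interval tables)
#'   and `region`.
#' @export
generate_repeat_landscape <- function(region = NULL, sc_runs = NULL,
                                      p_divergent = 0, tile_len = 600,
                                      gap_max = 200, cnvs = NULL,
                                      min_len = 1400, seed = NULL) {
  region <- region %||% genomic_interval("chrSim", 1, 50000)
  stopifnot(nrow(region) == 1L)
  L <- region$end - region$start + 1
  if (is.null(sc_runs)) {
    anchors <- region$start + round(L * c(0.2, 0.5, 0.8))
    sc_runs <- data.frame(start = anchors, end = anchors + 2000)
  }
  sc_runs <- sc_runs[order(sc_runs$start), , drop = FALSE]
  local_seed(seed, {
    # complement of the planted runs, to be tiled with repeats
    free <- IRanges::setdiff(IRanges::IRanges(region$start, region$end),
                             IRanges::IRanges(sc_runs$start, sc_runs$end))
    reps <- list()
    for (i in seq_len(length(free))) {
      pos <- IRanges::start(free)[i]
      seg_end <- IRanges::end(free)[i]
      while (pos <= seg_end) {
        len <- max(100, round(rnorm(1, tile_len, tile_len / 4)))
        tile_end <- min(pos + len - 1, seg_end)
        divergent <- runif(1) < p_divergent
        div <- if (divergent) runif(1, 20, 60) else runif(1, 1, 19.5)
        reps[[length(reps) + 1L]] <- data.frame(
          chrom = region$chrom, start = pos, end = tile_end,
          family = sprintf("SIM%d", length(reps) + 1L),
          divergence = div, stringsAsFactors = FALSE)
        if (tile_end >= seg_end) break
        # inter-tile gaps stay below probe length and never touch the
        # segment ends, so tiles abut the planted run boundaries exactly
        gap <- sample.int(gap_max + 1L, 1L) - 1L
        gap <- min(gap, seg_end - tile_end - 1L)
        pos <- tile_end + 1L + max(0L, gap)
      }
    }
    repeats <- if (length(reps)) do.call(rbind, reps)
               else data.frame(chrom = character(), start = numeric(),
                               end = numeric(), family = character(),
                               divergence = numeric(),
                               stringsAsFactors = FALSE)
    if (is.null(cnvs)) {
      cnvs <- data.frame(
        start = region$start + round(L * c(0.05, 0.9)),
        end = region$start + round(L * c(0.1, 0.95)),
        frequency = c(0.02, 0.005))
    }
    cnv_tab <- data.frame(chrom = region$chrom, start = cnvs$start,
                          end = cnvs$end, frequency = cnvs$frequency,
                          stringsAsFactors = FALSE)
    # plantable intervals: complement of the low-divergence mask
    low <- repeats[repeats$divergence < 20, , drop = FALSE]
    mask <- if (nrow(low)) IRanges::reduce(IRanges::IRanges(low$start,
                                                            low$end))
            else IRanges::IRanges()
    truth <- IRanges::setdiff(IRanges::IRanges(region$start, region$end),
                              mask)
    sc_truth <- data.frame(chrom = region$chrom,
                           start = IRanges::start(truth),
                           end = IRanges::end(truth),
                           stringsAsFactors = FALSE)
    # plantable means probe-sized: sub-minimum slivers (inter-tile gaps)
    # are not part of the ground truth
    sc_truth <- sc_truth[span_length(sc_truth) >= min_len, , drop = FALSE]
    rownames(sc_truth) <- NULL
    list(repeats = repeats, cnvs = cnv_tab, sc_truth = sc_truth,
         region = region)
  })
}

#' Generate a chromatin-mark signal track over DA and EA intervals
#'
#' One piecewise-constant segment per interval, with values drawn
#' normally around `mean_da` over DA intervals and `mean_ea` over EA
#' intervals (EA three-fold higher by default, emulating the depletion
#' of open-chromatin marks over differentially accessible loci),
#' truncated at zero. An optional planted outlier multiplies one DA
#' interval's value, emulating a probe landing in a highly accessible
#' promoter.
#'
#' @param da_intervals,ea_intervals interval tables.
#' @param mean_da,mean_ea group means (defaults 1 and 3).
#' @param noise_sd relative sd of segment values (default 0.25 of the
#'   group mean).
#' @param outlier index into `da_intervals` to inflate, or `NULL`.
#' @param outlier_factor inflation factor (default 20).
#' @param seed RNG seed.
#' @return track `data.frame` with an extra `group` column.
#' @export
generate_signal_track <- function(da_intervals, ea_intervals,
                                  mean_da = 1, mean_ea = 3,
                                  noise_sd = 0.25, outlier = NULL,
                                  outlier_factor = 20, seed = NULL) {
  local_seed(seed, {
    mk <- function(iv, mu, group) {
      v <- pmax(0, rnorm(nrow(iv), mu, noise_sd * mu))
      data.frame(chrom = iv$chrom, start = iv$start, end = iv$end,
                 value = v, group = group, stringsAsFactors = FALSE)
    }
    da <- mk(da_intervals, mean_da, "DA")
    if (!is.null(outlier)) da$value[outlier] <- da$value[outlier] *
        outlier_factor
    rbind(da, mk(ea_intervals, mean_ea, "EA"))
  })
}

#' Generate a TAD partition from boundary positions
#'
#' TADs fill the spans between successive boundaries; a positive
#' `gap_bp` shrinks interior TAD edges symmetrically to create
#' inter-TAD gaps (so the `between_tads` overlap class is exercisable).
#' With boundaries at multiples of the contact-map resolution and zero
#' gap, the TADs partition the chromosome with resolution-aligned
#' edges.
#'
#' @param chrom chromosome label.
#' @param boundaries increasing vector of boundary positions in bp
#'   (at least 2).
#' @param gap_bp inter-TAD gap in bp (default 0).
#' @param resolution contact-map resolution (default 25000).
#' @return a [tad_set()].
#' @export
generate_tads <- function(chrom, boundaries, gap_bp = 0,
                          resolution = 25000) {
  boundaries <- sort(as.numeric(boundaries))
  stopifnot(length(boundaries) >= 2L, gap_bp >= 0)
  k <- length(boundaries) - 1L
  start <- boundaries[-length(boundaries)]
  end <- boundaries[-1L]
  half <- gap_bp / 2
  start <- start + ifelse(seq_len(k) == 1L, 0, ceiling(half))
  end <- end - ifelse(seq_len(k) == k, 0, floor(half))
  tad_set(chrom, pmax(1, start), end, resolution = resolution)
}
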