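# Independent brute-force oracles. These deliberately avoid the code
# paths they check: per-base scans instead of interval algebra, full
# enumeration instead of distribution functions.

# Maximal repeat-free runs by per-base masking over the region.
oracle_sc_scan <- function(repeats, region, min_len = 1400,
                           max_len = 4000, max_divergence = 20) {
  bases <- region$start:region$end
  masked <- rep(FALSE, length(bases))
  low <- repeats[repeats$divergence < max_divergence, , drop = FALSE]
  for (i in seq_len(nrow(low))) {
    hit <- bases >= low$start[i] & bases <= low$end[i]
    masked[hit] <- TRUE
  }
  r <- rle(!masked)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- data.frame(chrom = character(), start = numeric(),
                    end = numeric(), oversize = logical())
  for (i in seq_along(r$lengths)) {
    if (!r$values[i]) next
    s <- bases[starts[i]]; e <- bases[ends[i]]
    if (e - s < min_len) next
    out <- rbind(out, data.frame(chrom = region$chrom, start = s, end = e,
                                 oversize = (e - s) > max_len))
  }
  rownames(out) <- NULL
  out
}

# Per-base track integration under the end - start length convention:
# base b contributes value of the segment with start <= b < end.
oracle_track_sum <- function(track, interval) {
  seg <- track[track$chrom == interval$chrom, , drop = FALSE]
  total <- 0
  for (b in seq(interval$start, interval$end - 1)) {
    hit <- seg$start <= b & seg$end > b
    if (any(hit)) total <- total + seg$value[which(hit)[1L]]
  }
  total
}

# Exact two-sided Mann-Whitney p by full enumeration of labelings.
oracle_mwu_exact <- function(x, y) {
  m <- length(x); n <- length(y)
  pool <- c(x, y)
  u_obs <- sum(rank(pool)[seq_len(m)]) - m * (m + 1) / 2
  combs <- utils::combn(m + n, m)
  u_all <- apply(combs, 2L, function(idx)
    sum(rank(pool)[idx]) - m * (m + 1) / 2)
  p <- 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs))
  min(1, p)
}

# Hand-formula Welch statistic, df and p.
oracle_welch <- function(x, y) {
  vx <- var(x) / length(x); vy <- var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# Run-length scan for DA domain construction over one sorted probe set.
oracle_domain_runs <- function(calls) {
  runs <- list()
  cur <- integer(0)
  for (i in seq_along(calls)) {
    if (calls[i] == "DA") cur <- c(cur, i)
    else { if (length(cur) >= 2) runs[[length(runs) + 1]] <- cur
           cur <- integer(0) }
  }
  if (length(cur) >= 2) runs[[length(runs) + 1]] <- cur
  runs
}

# Polygon circularity 4*pi*A/P^2 from a contour matrix (row, col).
polygon_circularity <- function(ct) {
  x <- ct[, 2]; y <- ct[, 1]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  area <- abs(sum(x * yn - xn * y)) / 2
  per <- sum(sqrt((xn - x)^2 + (yn - y)^2))
  4 * pi * area / per^2
}

# Disk mask helper for intensity tests.
disk_mask <- function(n, p, center, r) {
  yy <- matrix(seq_len(n), n, p)
  xx <- matrix(seq_len(p), n, p, byrow = TRUE)
  (yy - center[1])^2 + (xx - center[2])^2 <= r^2
}

table1_expected_spans <- c(XDH = 25454, HMGB1P5 = 39731, FGF6 = 16048,
                           TPM1 = 16034, COX5A = 109970,
                           HMGB1P1 = 129583)
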