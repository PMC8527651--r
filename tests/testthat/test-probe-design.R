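test_that("single-copy intervals avoid low-divergence repeats", {
  region <- genomic_interval("chrT", 1, 10000)
  one_rep <- data.frame(chrom = "chrT", start = 4001, end = 6000,
                        family = "L1", divergence = 5)
  got <- find_sc_intervals(one_rep, region)
  expect_equal(got$start, c(1, 6001))
  expect_equal(got$end, c(4000, 10000))

  # no repeats -> whole region (flagged oversize at 4 kb max)
  none <- one_rep[0, ]
  whole <- find_sc_intervals(none, region)
  expect_equal(whole[, c("start", "end")],
               data.frame(start = 1, end = 10000))
  expect_true(whole$oversize)

  # a highly divergent repeat behaves as unique sequence
  div <- data.frame(chrom = "chrT", start = 1, end = 10000,
                    family = "HERV", divergence = 35)
  expect_equal(find_sc_intervals(div, region)$start, 1)

  expect_error(find_sc_intervals(
    data.frame(chrom = "chrU", start = 1, end = 10, divergence = 1),
    region), "different chromosome")
})

test_that("interval finder matches the per-base brute-force scan", {
  set.seed(202)
  for (case in 1:100) {
    L <- sample(3000:20000, 1)
    region <- genomic_interval("chrT", 1, L)
    n_rep <- sample(0:12, 1)
    if (n_rep > 0) {
      s <- sort(sample.int(L, n_rep))
      reps <- data.frame(chrom = "chrT", start = s,
                         end = pmin(L, s + sample(50:3000, n_rep,
                                                  replace = TRUE)),
                         family = "R",
                         divergence = runif(n_rep, 0, 40))
    } else reps <- data.frame(chrom = character(), start = numeric(),
                              end = numeric(), family = character(),
                              divergence = numeric())
    min_len <- sample(c(500, 1400), 1)
    got <- find_sc_intervals(reps, region, min_len = min_len)
    want <- oracle_sc_scan(reps, region, min_len = min_len)
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
    expect_equal(got$oversize, want$oversize)
    # no returned interval overlaps a masking repeat
    low <- reps[reps$divergence < 20, , drop = FALSE]
    for (i in seq_len(nrow(got)))
      expect_false(any(low$start <= got$end[i] & low$end >= got$start[i]))
  }
})

test_that("CNV filter drops any candidate overlapping a common CNV", {
  cand <- data.frame(chrom = "chrT", start = c(100, 5000),
                     end = c(2000, 6000))
  common <- data.frame(chrom = "chrT", start = 1500, end = 1600,
                       frequency = 0.02)
  expect_equal(filter_cnv(cand, common)$start, 5000)
  rare <- data.frame(chrom = "chrT", start = 1500, end = 1600,
                     frequency = 0.005)
  expect_equal(nrow(filter_cnv(cand, rare)), 2)

  # planted design: 10 candidates, 3 hot CNVs hitting 3 of them
  set.seed(7)
  cand10 <- data.frame(chrom = "chrT", start = (0:9) * 10000 + 1,
                       end = (0:9) * 10000 + 3000)
  hot <- data.frame(chrom = "chrT",
                    start = cand10$start[c(2, 5, 9)] + 100,
                    end = cand10$start[c(2, 5, 9)] + 200,
                    frequency = 0.05)
  survivors <- filter_cnv(cand10, hot)
  expect_equal(nrow(survivors), 7)
  # brute-force overlap cross-check
  keep <- sapply(seq_len(10), function(i)
    !any(hot$start <= cand10$end[i] & hot$end >= cand10$start[i]))
  expect_equal(survivors$start, cand10$start[keep])
})

test_that("expression filter keeps only transcriptionally inert genes", {
  probes <- data.frame(name = c("g1_IVS1", "g2_IVS1", "ig_tel100"),
                       position_class = c("genic", "genic", "intergenic"),
                       gene = c("G1", "G2", NA))
  expr <- data.frame(gene = rep(c("G1", "G2"), each = 3),
                     tissue = rep(c("lymph", "marrow", "fibro"), 2),
                     tpm = c(1.2, 0.0, 4.9, 1.2, 7.0, 0.1))
  kept <- filter_expression(probes, expr)
  expect_equal(kept$name, c("g1_IVS1", "ig_tel100"))

  probes2 <- data.frame(name = "gX_IVS1", position_class = "genic",
                        gene = "GX")
  expect_error(filter_expression(probes2, expr), "GX")

  # randomized table against a brute-force max-per-gene filter
  set.seed(31)
  genes <- sprintf("G%02d", 1:20)
  tab <- expand.grid(gene = genes, tissue = c("a", "b", "c"),
                     stringsAsFactors = FALSE)
  tab$tpm <- rexp(nrow(tab), rate = 0.3)
  pr <- data.frame(name = paste0(genes, "_IVS1"),
                   position_class = "genic", gene = genes)
  kept <- filter_expression(pr, tab)
  want <- genes[tapply(tab$tpm, tab$gene, max)[genes] <= 5]
  expect_setequal(kept$gene, want)
})

test_that("GC content and nearest-neighbor Tm are computed correctly", {
  expect_equal(gc_content(c("ATAT", "GCGC")), c(0, 1))
  expect_equal(gc_content("ACGT"), 0.5)
  expect_error(gc_content("ACGN"), "non-ACGT.*N")

  # frozen reference values from an independent implementation of the
  # SantaLucia unified nearest-neighbor table (50 mM Na+, 500 nM primer)
  expect_equal(melting_temperature("ACGTGCTAGCTAGGCTAATCGATCG"),
               60.941244, tolerance = 1e-6)
  expect_equal(melting_temperature("ATGCATGCATGCATGCATGCATGCA"),
               64.220513, tolerance = 1e-6)
  expect_equal(melting_temperature("GGGCCCGGGCCCAAATTTGCGCGCA"),
               73.173058, tolerance = 1e-6)
})

test_that("self-complementarity equals the exhaustive offset scan", {
  expect_equal(self_complementarity("AAAA"), 0)
  expect_equal(self_complementarity("ACGT"), 4)

  scan_oracle <- function(s) {
    a <- strsplit(s, "")[[1]]
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    n <- length(a)
    best <- 0
    # all ungapped alignments of the sequence against its own reverse
    # complement, counted position by position
    rc <- rev(unname(comp[a]))
    for (off in -(n - 1):(n - 1)) {
      cnt <- 0
      for (i in seq_len(n)) {
        j <- i + off
        if (j >= 1 && j <= n && a[j] == rc[i]) cnt <- cnt + 1
      }
      best <- max(best, cnt)
    }
    best
  }
  set.seed(5)
  for (i in 1:25) {
    s <- paste(sample(c("A", "C", "G", "T"), 20, replace = TRUE),
               collapse = "")
    expect_equal(self_complementarity(s), scan_oracle(s), info = s)
  }
})

test_that("primer pair evaluation applies hard and soft rules", {
  mk <- function(tmf, tmr, gcf = 0.5, gcr = 0.52, prod = 2800,
                 len = 26) {
    p <- structure(list(
      forward_seq = strrep("A", len), reverse_seq = strrep("A", len),
      tm_forward = tmf, tm_reverse = tmr, gc_forward = gcf,
      gc_reverse = gcr, product_length = prod,
      self_complementarity = 0), class = "primer_pair")
    p
  }
  ok <- evaluate_primer_pair(mk(61, 62.5), 3000)
  expect_true(ok$hard_pass)
  expect_true(all(ok$checks[c("tm_window", "tm_difference",
                              "product_max", "product_min")]))

  dtm <- evaluate_primer_pair(mk(58, 61), 3000)
  expect_false(dtm$checks[["tm_difference"]])
  expect_false(dtm$hard_pass)

  short_prod <- evaluate_primer_pair(mk(61, 62, prod = 2300), 3000)
  expect_false(short_prod$checks[["product_min"]])

  # soft failures do not disqualify, only rank worse
  soft <- evaluate_primer_pair(mk(61, 62, gcf = 0.3), 3000)
  expect_true(soft$hard_pass)
  expect_gt(soft$rank_key, ok$rank_key)
})

test_that("worsening one primer metric never rescues a failing pair", {
  base <- list(tmf = 61, tmr = 62.5, prod = 2800)
  worsen <- list(
    function(b) { b$tmf <- b$tmf - 5; b },       # leaves Tm window
    function(b) { b$tmr <- b$tmr + 4; b },       # leaves window + dTm
    function(b) { b$prod <- b$prod + 500; b },   # exceeds interval
    function(b) { b$prod <- b$prod - 600; b })   # below the minimum
  mk <- function(b) structure(list(
    forward_seq = strrep("A", 26), reverse_seq = strrep("A", 26),
    tm_forward = b$tmf, tm_reverse = b$tmr, gc_forward = 0.5,
    gc_reverse = 0.5, product_length = b$prod,
    self_complementarity = 0), class = "primer_pair")
  for (w in worsen) {
    before <- evaluate_primer_pair(mk(base), 3000)
    after <- evaluate_primer_pair(mk(w(base)), 3000)
    expect_true(before$hard_pass)
    expect_false(after$hard_pass)
  }
})
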