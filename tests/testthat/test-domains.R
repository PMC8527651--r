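test_that("the packaged probe set yields the six published domains", {
  d <- build_domains(scfish_probes())
  expect_length(d$domains, 6)
  rep <- domain_report(d)
  expect_setequal(rep$name, names(table1_expected_spans))
  rep <- rep[match(names(table1_expected_spans), rep$name), ]
  expect_equal(rep$span_bp, unname(table1_expected_spans))
  expect_equal(rep$n_probes, c(3, 2, 2, 3, 3, 4))
  # every emitted domain member is DA; the EA control and the
  # tissue-study singleton stay out
  for (dom in d$domains) expect_true(all(dom$probes$call == "DA"))
  expect_equal(d$singletons$name, "DUOX1_IVS1-IVS3")

  # kb report dialect
  expect_equal(rep$target_kb[rep$name == "XDH"], "7.6")
  expect_equal(rep$target_kb[rep$name == "TPM1"], "8.0")
  expect_equal(rep$target_kb[rep$name == "HMGB1P1"], "12.2")
  hmgb1p1 <- d$domains[[which(sapply(d$domains, `[[`, "name") ==
                                "HMGB1P1")]]
  expect_true(82850 %in% hmgb1p1$gaps)
  expect_equal(format_kb(max(hmgb1p1$gaps)), "82.9")
})

test_that("an interspersed EA probe breaks a DA run", {
  probes <- data.frame(
    name = c("a", "b", "c"), chrom = "chr9",
    start = c(100, 5000, 9000), end = c(1000, 6000, 10000),
    call = c("DA", "EA", "DA"), domain = NA_character_)
  d <- build_domains(probes)
  expect_length(d$domains, 0)
  expect_equal(nrow(d$singletons), 2)

  probes$call <- c("DA", "DA", "DA")
  d2 <- build_domains(probes)
  expect_length(d2$domains, 1)
  expect_equal(nrow(d2$domains[[1]]$probes), 3)

  probes$end[1] <- 5500  # overlaps the second probe
  expect_error(build_domains(probes), "overlapping")
})

test_that("domain construction equals the run-length oracle on random calls", {
  set.seed(321)
  for (case in 1:50) {
    n <- sample(2:12, 1)
    starts <- cumsum(sample(2000:20000, n))
    probes <- data.frame(
      name = sprintf("p%02d", seq_len(n)), chrom = "chrQ",
      start = starts, end = starts + 1500,
      call = sample(c("DA", "EA"), n, replace = TRUE),
      domain = NA_character_)
    d <- build_domains(probes)
    want <- oracle_domain_runs(probes$call)
    expect_length(d$domains, length(want))
    for (i in seq_along(want))
      expect_equal(d$domains[[i]]$probes$name, probes$name[want[[i]]])
  }
})

test_that("a configurable max-gap warning is emitted, not enforced", {
  probes <- data.frame(
    name = c("a", "b"), chrom = "chr9",
    start = c(100, 90000), end = c(1000, 95000),
    call = "DA", domain = NA_character_)
  expect_warning(build_domains(probes, max_gap = 50000), "gap")
  expect_silent(d <- build_domains(probes))
  expect_length(d$domains, 1)
})

test_that("probes are named by intron span or nearest-gene side and distance", {
  genes <- data.frame(gene = c("FGF6", "CTCFL"),
                      chrom = c("chr12", "chr20"),
                      start = c(4543308, 56071021),
                      end = c(4555000, 56100000))
  # synthetic annotation: gene coordinates chosen to reproduce the
  # published naming distances
  # chr12p: centromere is at higher coordinates than the probe
  got <- name_probe(genomic_interval("chr12", 4537157, 4538816),
                    genes, centromere = 35800000)
  expect_equal(got, "FGF6_tel4492")
  # chr20q: centromere at lower coordinates; probe between it and gene
  got2 <- name_probe(genomic_interval("chr20", 56033167, 56036719),
                     genes, centromere = 28100000)
  expect_equal(got2, "CTCFL_cen34302")
  # abutting interval: distance 0, centromeric side
  got3 <- name_probe(genomic_interval("chr20", 56070000, 56071021),
                     genes, centromere = 28100000)
  expect_equal(got3, "CTCFL_cen0")

  introns <- data.frame(gene = "TPM1", intron = c(5, 6, 7, 8),
                        start = c(100, 300, 500, 700) + 63353000,
                        end = c(200, 400, 600, 800) + 63353000)
  genes_t <- data.frame(gene = "TPM1", chrom = "chr15",
                        start = 63352000, end = 63365000)
  got4 <- name_probe(genomic_interval("chr15", 63353150, 63353750),
                     genes_t, introns = introns)
  expect_equal(got4, "TPM1_IVS5-IVS8")

  expect_error(name_probe(genomic_interval("chrX", 1, 10), genes,
                          centromere = 1e6), "no gene annotation")
})

test_that("track integration is exact, additive, and matches per-base sums", {
  tr <- signal_track("chr1", 1, 10001, 2.5)
  iv <- genomic_interval("chr1", 1, 10001)
  got <- integrate_track(tr, iv)
  expect_equal(got$cumulative, 2.5 * 10000)
  expect_equal(got$per_bp, 2.5)

  # splitting at an internal point preserves the total
  left <- integrate_track(tr, genomic_interval("chr1", 1, 4000))
  right <- integrate_track(tr, genomic_interval("chr1", 4000, 10001))
  expect_equal(left$cumulative + right$cumulative, got$cumulative)

  set.seed(55)
  for (case in 1:100) {
    n_seg <- sample(1:6, 1)
    bounds <- sort(sample(1:500, n_seg + 1))
    track <- signal_track("chrP", bounds[-length(bounds)], bounds[-1],
                          runif(n_seg, 0, 10))
    s <- sample(1:400, 1); e <- s + sample(1:100, 1)
    iv <- genomic_interval("chrP", s, e)
    expect_equal(integrate_track(track, iv)$cumulative,
                 oracle_track_sum(track, iv), tolerance = 1e-9)
  }
})

test_that("mark comparison flags outliers and censors only on request", {
  vals <- data.frame(mark = "DNase",
                     group = rep(c("DA", "EA"), c(6, 6)),
                     id = sprintf("iv%02d", 1:12),
                     value = c(1, 1.1, 0.9, 1, 1.05, 0.95,
                               1, 1.1, 0.9, 1, 1.05, 0.95))
  same <- compare_marks(vals)
  expect_gt(same$p_value, 0.9)
  expect_equal(same$flagged, "")

  vals$value[3] <- 20  # a 20x promoter-like outlier in the DA group
  flagged <- compare_marks(vals)
  expect_equal(flagged$flagged, "iv03")
  expect_equal(flagged$censored, "")
  censored <- compare_marks(vals, censor = TRUE)
  expect_equal(censored$censored, "iv03")
  expect_lt(censored$mean_da, flagged$mean_da)
})

test_that("synthetic depleted DA tracks are detected at the study sizes", {
  da_iv <- genomic_interval("chrM", (0:17) * 10000 + 1,
                            (0:17) * 10000 + 3000)
  ea_iv <- genomic_interval("chrM", (0:58) * 10000 + 500001,
                            (0:58) * 10000 + 503000)
  hits <- 0
  for (mark in 1:6) {
    tr <- generate_signal_track(da_iv, ea_iv, seed = 600 + mark)
    vals <- data.frame(mark = sprintf("m%d", mark),
                       group = tr$group,
                       id = sprintf("iv%02d", seq_len(nrow(tr))),
                       value = sapply(seq_len(nrow(tr)), function(i)
                         integrate_track(tr,
                                         genomic_interval(tr$chrom[i],
                                                          tr$start[i],
                                                          tr$end[i]))$per_bp))
    res <- compare_marks(vals)
    if (res$mean_da < res$mean_ea && res$p_value < 0.05)
      hits <- hits + 1
  }
  expect_gte(hits, 5)
})

test_that("TAD overlap classification partitions all planted cases", {
  tads <- generate_tads("chrT", boundaries = c(0, 1e6, 2e6, 3e6))
  # strictly inside with wide margins
  expect_equal(classify_tad_overlap(
    genomic_interval("chrT", 1.4e6, 1.6e6), tads), "within")
  # inside but within one 25 kb bin of an edge
  expect_equal(classify_tad_overlap(
    genomic_interval("chrT", 1.01e6, 1.1e6), tads),
    "within_boundary_proximal")
  # crossing a planted boundary
  expect_equal(classify_tad_overlap(
    genomic_interval("chrT", 0.9e6, 1.1e6), tads), "spans_boundary")
  # planted inter-TAD gap
  gap_tads <- generate_tads("chrT", boundaries = c(0, 1e6, 2e6),
                            gap_bp = 100000)
  expect_equal(classify_tad_overlap(
    genomic_interval("chrT", 960000, 1040000), gap_tads),
    "between_tads")

  # exactly one label for arbitrary (domain, TadSet) pairs
  set.seed(42)
  labels <- c("within", "within_boundary_proximal", "spans_boundary",
              "between_tads")
  for (i in 1:50) {
    s <- sample.int(29e5, 1); e <- s + sample.int(5e5, 1)
    got <- classify_tad_overlap(genomic_interval("chrT", s, e), gap_tads)
    expect_true(got %in% labels)
  }
})
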