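test_that("assign_orf finds the longest ATG-initiated ORF and honours annotation", {
  # exhaustive-scan example: ATG GCG TAG at 0-based 2..11
  m <- models_from_widths(13, id = "t1")
  m$transcripts$evaluable <- NULL
  m2 <- assign_orf(m, c(t1 = "AAATGGCGTAGCC"))
  expect_equal(m2$transcripts$cds_start, 2)
  expect_equal(m2$transcripts$cds_end, 11)
  expect_true(m2$transcripts$evaluable)

  # no ATG -> not evaluable
  m3 <- models_from_widths(12, id = "t1")
  m3$transcripts$evaluable <- NULL
  m3 <- assign_orf(m3, c(t1 = "CCCCCCCCCCCC"))
  expect_false(m3$transcripts$evaluable)

  # annotated CDS wins over a longer unannotated ORF
  # seq has ORF ATG...TAA spanning 0..15, but annotation says 6..12
  seq <- paste0("ATGAAA", "ATGTAA", "TAAC")  # long ORF at 0, annotated at 6
  m4 <- models_from_widths(nchar(seq), cds_start = 6, cds_end = 12, id = "t1")
  m4$transcripts$evaluable <- NULL
  m4 <- assign_orf(m4, c(t1 = seq))
  expect_equal(m4$transcripts$cds_start, 6)
  expect_equal(m4$transcripts$cds_end, 12)
})

test_that("detect_dej matches hand-computed coordinate arithmetic", {
  cfg <- feature_config()
  # two exons (200, 100), stop ends at 123, junction at 200 -> distance 77
  m <- models_from_widths(c(200, 100), cds_start = 30, cds_end = 123)
  d <- detect_dej(m, cfg)
  expect_true(d$has_dej)
  expect_equal(d$dej_distance, 77)
  # same structure, stop ends at 160 -> distance 40 -> below threshold
  m2 <- models_from_widths(c(200, 100), cds_start = 31, cds_end = 160)
  d2 <- detect_dej(m2, cfg)
  expect_false(d2$has_dej)
  expect_equal(d2$dej_distance, 40)
  # single exon: no junction
  m3 <- models_from_widths(300, cds_start = 30, cds_end = 123)
  d3 <- detect_dej(m3, cfg)
  expect_false(d3$has_dej)
  expect_true(is.na(d3$dej_distance))
})

test_that("detect_uorfs applies the length and containment rules", {
  cfg <- feature_config()
  # 5'UTR with no ATG -> 0
  m <- models_from_widths(30, cds_start = 6, cds_end = 24, id = "t1")
  s <- c(t1 = paste0("CCCCCC", "ATG", rand_codons(4), "TAA", "CCCCCC"))
  expect_equal(detect_uorfs(m, s, cfg)$n_uorfs, 0L)
  # 2-codon uORF counted only when uorf_min_codons <= 2
  s2 <- c(t1 = paste0("ATGTAA", "ATG", rand_codons(4), "TAA", "CCCCCC"))
  expect_equal(detect_uorfs(m, s2, cfg)$n_uorfs, 0L)
  cfg2 <- feature_config(uorf_min_codons = 2)
  expect_equal(detect_uorfs(m, s2, cfg2)$n_uorfs, 1L)
  # two disjoint planted uORFs
  m2 <- models_from_widths(60, cds_start = 36, cds_end = 54, id = "t1")
  utr <- paste0("ATG", "AAACCC", "TAA", "CC", "ATG", "GGGCCC", "TGA",
                strrep("C", 10))
  s3 <- c(t1 = paste0(utr, "ATG", rand_codons(4), "TAA", "CCCCCC"))
  expect_equal(nchar(utr), 36)
  expect_equal(detect_uorfs(m2, s3, cfg)$n_uorfs, 2L)
})

test_that("measure_utr3 lengths and long-3'UTR rules", {
  cfg <- feature_config()
  # transcript 2000 nt, ORF ends at 500 -> 3'UTR 1500
  m <- models_from_widths(2000, cds_start = 200, cds_end = 500)
  expect_equal(measure_utr3(m, cfg)$utr3_length, 1500)
  # ORF ends at transcript end -> not evaluable (empty 3'UTR)
  m2 <- models_from_widths(500, cds_start = 200, cds_end = 500)
  m2$transcripts$evaluable <- m2$transcripts$cds_end < m2$transcripts$length
  expect_true(is.na(measure_utr3(m2, cfg)$utr3_length))
  # multiple-of-median rule: median 400, value 2 -> 900 is long
  u3 <- measure_utr3(m, cfg, utr3_median = 400)
  m$transcripts$cds_end <- 1100  # 3'UTR 900
  expect_true(measure_utr3(m, cfg, utr3_median = 400)$is_long_utr3)
  m$transcripts$cds_end <- 1400  # 3'UTR 600 < 800
  expect_false(measure_utr3(m, cfg, utr3_median = 400)$is_long_utr3)
  # absolute rule
  cfg_abs <- feature_config(long_utr3_rule = "absolute_nt", long_utr3_value = 700)
  m$transcripts$cds_end <- 1100
  expect_true(measure_utr3(m, cfg_abs)$is_long_utr3)
})

test_that("collapse_to_gene ORs features over evaluable transcripts", {
  f <- data.frame(
    transcript_id = c("a1", "a2", "b1", "c1"),
    gene_id = c("A", "A", "B", "C"),
    evaluable = c(TRUE, TRUE, TRUE, FALSE),
    has_dej = c(TRUE, FALSE, FALSE, NA),
    dej_distance = c(80, -10, -5, NA),
    n_uorfs = c(0L, 2L, 0L, NA), has_uorf = c(FALSE, TRUE, FALSE, NA),
    utr3_length = c(100, 200, 300, NA),
    is_long_utr3 = c(FALSE, FALSE, FALSE, NA))
  g <- collapse_to_gene(f)
  expect_true(g$has_dej[g$gene_id == "A"])      # any dEJ+ transcript
  expect_true(g$has_uorf[g$gene_id == "A"])
  expect_false(g$has_dej[g$gene_id == "B"])     # all negative -> negative
  expect_false(g$evaluable[g$gene_id == "C"])   # no evaluable transcript
  expect_true(is.na(g$has_dej[g$gene_id == "C"]))
})

test_that("detectors agree exactly with the nucleotide-level oracle on 500 random transcripts", {
  set.seed(77)
  cfg <- feature_config()
  for (i in 1:500) {
    rt <- random_transcript()
    d <- detect_dej(rt$models, cfg)
    o <- oracle_dej(rt$widths, rt$cds_end, cfg$dej_threshold)
    expect_identical(unname(d$has_dej), o$has)
    if (!is.na(d$dej_distance)) expect_equal(d$dej_distance, o$dist)
    u <- detect_uorfs(rt$models, stats::setNames(rt$seq, "tx"), cfg)
    expect_identical(u$n_uorfs, oracle_uorf(rt$seq, rt$cds_start,
                                            cfg$uorf_min_codons))
    u3 <- measure_utr3(rt$models, cfg)
    expect_equal(u3$utr3_length, oracle_utr3(rt$seq, rt$cds_end))
  }
})

test_that("feature calls are strand-invariant", {
  set.seed(99)
  cfg <- feature_config()
  for (i in 1:40) {
    rt_p <- random_transcript(strand = "+")
    # realize the identical transcript (same widths/CDS/seq) on the minus strand
    m_m <- models_from_widths(rt_p$widths, cds_start = rt_p$cds_start,
                              cds_end = rt_p$cds_end, strand = "-")
    d_p <- detect_dej(rt_p$models, cfg)
    d_m <- detect_dej(m_m, cfg)
    expect_identical(d_p$has_dej, d_m$has_dej)
    expect_identical(d_p$dej_distance, d_m$dej_distance)
    s <- stats::setNames(rt_p$seq, "tx")
    expect_identical(detect_uorfs(rt_p$models, s, cfg)$n_uorfs,
                     detect_uorfs(m_m, s, cfg)$n_uorfs)
  }
})

test_that("raising the dEJ threshold never turns has_dej from FALSE to TRUE", {
  set.seed(13)
  for (i in 1:60) {
    rt <- random_transcript()
    calls <- vapply(c(10, 50, 100, 200), function(th)
      isTRUE(detect_dej(rt$models, feature_config(dej_threshold = th))$has_dej),
      logical(1))
    expect_true(all(diff(as.integer(calls)) <= 0))
  }
})
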