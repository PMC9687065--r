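iso_quant_fixture <- function() {
  tpm <- rbind(
    gA.t1 = c(6, 6, 6, 6), gA.t2 = c(4, 4, 4, 4),
    gB.t1 = c(10, 10, 10, 10),
    gC.t1 = c(5, 0, 5, 5), gC.t2 = c(5, 0, 5, 5))
  colnames(tpm) <- sprintf("s%d", 1:4)
  map <- data.frame(isoform_id = rownames(tpm),
                    gene_id = sub("\\..*", "", rownames(tpm)))
  isoform_fractions(tpm, map)
}

test_that("isoform fractions: arithmetic, single-isoform genes, zero-TPM samples", {
  q <- iso_quant_fixture()
  expect_equal(unname(q$if_["gA.t1", ]), rep(0.6, 4))
  expect_equal(unname(q$if_["gA.t2", ]), rep(0.4, 4))
  expect_equal(unname(q$if_["gB.t1", ]), rep(1, 4))     # single isoform
  expect_true(is.na(q$if_["gC.t1", "s2"]))              # gene TPM 0
  # unknown gene errors
  expect_error(isoform_fractions(q$tpm,
                                 q$map[q$map$gene_id != "gB", ]), "unknown gene")
  # IFs sum to 1 per gene/sample where defined
  sums <- rowsum(q$if_, q$map$gene_id)
  expect_equal(unname(sums[!is.na(sums)]),
               rep(1, sum(!is.na(sums))))
})

test_that("filter_isoforms applies TPM, fraction and gene-size rules", {
  tpm <- rbind(
    gA.t1 = rep(10, 4), gA.t2 = rep(0.09, 4),      # t2: below 0.1 TPM
    gB.t1 = rep(96, 4), gB.t2 = rep(4, 4),         # t2: 4% of gene
    gC.t1 = rep(5, 4), gC.t2 = rep(5, 4))
  colnames(tpm) <- sprintf("s%d", 1:4)
  map <- data.frame(isoform_id = rownames(tpm),
                    gene_id = sub("\\..*", "", rownames(tpm)))
  fq <- filter_isoforms(isoform_fractions(tpm, map))
  # gA and gB reduced below two isoforms -> genes dropped entirely
  expect_setequal(fq$map$gene_id, "gC")
  # compositional closure after refiltering
  expect_equal(unname(colSums(fq$if_)), rep(1, 4))
})

test_that("dif_test: identity, symmetry and compositional identities", {
  set.seed(11)
  n_s <- 12
  gt <- rep(c("null", "control"), each = 6)
  base <- matrix(rgamma(6 * n_s, 20, 2), 6, n_s,
                 dimnames = list(c("gA.t1", "gA.t2", "gB.t1", "gB.t2",
                                   "gC.t1", "gC.t2"), sprintf("s%d", 1:n_s)))
  map <- data.frame(isoform_id = rownames(base),
                    gene_id = sub("\\..*", "", rownames(base)))
  q <- isoform_fractions(base, map)
  # identical groups -> dif 0, no calls
  q_eq <- isoform_fractions(cbind(base[, 1:6], base[, 1:6]), map)
  r_eq <- dif_test(q_eq, gt)
  expect_equal(r_eq$dif, rep(0, 6))
  expect_false(any(r_eq$called))
  # per-gene dIFs sum to ~0
  r <- dif_test(q, gt)
  expect_equal(as.numeric(tapply(r$dif, r$gene_id, sum)), rep(0, 3),
               tolerance = 1e-12)
  # label swap negates dIF and preserves p
  gt_swapped <- ifelse(gt == "null", "control", "null")
  r_sw <- dif_test(q, gt_swapped)
  expect_equal(r_sw$dif, -r$dif)
  expect_equal(r_sw$p, r$p)
  # constant IF in both groups -> p = 1
  const <- matrix(rep(c(6, 4), n_s), 2, n_s,
                  dimnames = list(c("gZ.t1", "gZ.t2"), sprintf("s%d", 1:n_s)))
  qc <- isoform_fractions(const, data.frame(isoform_id = rownames(const),
                                            gene_id = "gZ"))
  expect_equal(dif_test(qc, gt)$p, c(1, 1))
})

test_that("consequence classification matches constructed structural contrasts", {
  # gene with major isoform (2 exons, stop in last exon) and an
  # NMD-sensitive isoform adding a 3' exon after the stop
  tx <- data.frame(
    transcript_id = c("g.t1", "g.t2"), gene_id = "g", chrom = "chr1",
    strand = "+", cds_start = c(30, 30), cds_end = c(240, 240))
  ex <- data.frame(
    transcript_id = c("g.t1", "g.t1", "g.t2", "g.t2", "g.t2"),
    chrom = "chr1",
    start = c(0, 500, 0, 500, 1200),
    end = c(200, 800, 200, 800, 1400),
    strand = "+")
  m <- transcript_models(tx, ex)
  m$transcripts$evaluable <- TRUE
  feats <- cbind(detect_dej(m), utr3_length = m$transcripts$length -
                   m$transcripts$cds_end, has_uorf = FALSE)
  expect_false(feats$has_dej[1]); expect_true(feats$has_dej[2])
  sw <- data.frame(isoform_id = "g.t2", gene_id = "g", dif = 0.4,
                   p = 1e-5, q = 1e-4)
  tpm <- rbind(g.t1 = c(8, 8, 2, 2), g.t2 = c(2, 2, 8, 8))
  colnames(tpm) <- sprintf("s%d", 1:4)
  q <- isoform_fractions(tpm, data.frame(isoform_id = rownames(tpm),
                                         gene_id = "g"))
  gt <- c("control", "control", "null", "null")
  cons <- classify_consequences(m, feats, sw, q, gt)
  got <- cons$consequence
  expect_true(all(c("nmd_sensitivity_gain", "utr3_longer", "alt_tts",
                    "last_exon_change", "length_change",
                    "exon_number_change") %in% got))
  expect_false("alt_tss" %in% got)
  expect_false("intron_retention" %in% got)
  expect_equal(unique(cons$major_isoform), "g.t1")

  # intron retention: single exon spanning the major isoform's intron
  tx2 <- data.frame(transcript_id = c("h.t1", "h.t2"), gene_id = "h",
                    chrom = "chr1", strand = "+",
                    cds_start = c(30, 30), cds_end = c(150, 150))
  ex2 <- data.frame(transcript_id = c("h.t1", "h.t1", "h.t2"), chrom = "chr1",
                    start = c(0, 500, 0), end = c(200, 800, 800), strand = "+")
  m2 <- transcript_models(tx2, ex2)
  m2$transcripts$evaluable <- TRUE
  feats2 <- cbind(detect_dej(m2), utr3_length = m2$transcripts$length -
                    m2$transcripts$cds_end, has_uorf = FALSE)
  sw2 <- data.frame(isoform_id = "h.t2", gene_id = "h", dif = 0.3,
                    p = 1e-4, q = 1e-3)
  tpm2 <- rbind(h.t1 = c(9, 9, 4, 4), h.t2 = c(1, 1, 6, 6))
  colnames(tpm2) <- sprintf("s%d", 1:4)
  q2 <- isoform_fractions(tpm2, data.frame(isoform_id = rownames(tpm2),
                                           gene_id = "h"))
  cons2 <- classify_consequences(m2, feats2, sw2, q2, gt)
  expect_true("intron_retention" %in% cons2$consequence)

  # identical structures -> empty consequence set (NA row)
  sw3 <- data.frame(isoform_id = "g.t1", gene_id = "g", dif = 0.2,
                    p = 1e-4, q = 1e-3)
  ex_same <- ex[ex$transcript_id == "g.t1", ]
  ex_same2 <- ex_same; ex_same2$transcript_id <- "g.t2"
  m3 <- transcript_models(transform(tx, cds_end = c(240, 240)),
                          rbind(ex_same, ex_same2))
  m3$transcripts$evaluable <- TRUE
  feats3 <- cbind(detect_dej(m3), utr3_length = m3$transcripts$length -
                    m3$transcripts$cds_end, has_uorf = FALSE)
  cons3 <- classify_consequences(m3, feats3, sw3, q, gt)
  expect_true(all(is.na(cons3$consequence)))
})
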