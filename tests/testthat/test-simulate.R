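test_that("sim_params validates its invariants", {
  expect_error(sim_params(stabilization_factor = 1.2), "stabilization_factor")
  expect_error(sim_params(feedback_fraction = -0.1), "feedback_fraction")
  expect_error(sim_params(n_null = 1), "samples per genotype")
  expect_error(sim_params(n_genes = 50, n_targets = 100), "exceed")
  # impossible geometry: dEJ planting with single-exon-only transcripts
  expect_error(simulate_annotation(sim_params(exon_count_range = c(1, 1))),
               "impossible geometry")
})

test_that("generators are deterministic under a fixed seed", {
  p <- sim_params(n_genes = 40, n_targets = 5, n_switch_genes = 2,
                  n_factors = 2, seed = 5)
  f1 <- tempfile(fileext = ".gtf"); f2 <- tempfile(fileext = ".gtf")
  a1 <- tempfile(fileext = ".fa"); a2 <- tempfile(fileext = ".fa")
  s1 <- simulate_annotation(p); s2 <- simulate_annotation(p)
  write_gtf(s1$models, f1); write_gtf(s2$models, f2)
  write_transcript_fasta(s1$sequences, a1); write_transcript_fasta(s2$sequences, a2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(readLines(a1), readLines(a2))
  expect_identical(simulate_counts(s1)$exonic, simulate_counts(s2)$exonic)
  m1 <- simulate_stage_matrix(s1$truth, seed = 9)
  m2 <- simulate_stage_matrix(s2$truth, seed = 9)
  expect_identical(m1$matrix, m2$matrix)
})

test_that("nothing planted means nothing planted", {
  p <- sim_params(n_genes = 50, n_targets = 0, n_switch_genes = 0,
                  n_factors = 0, dej_rate_targets = 0, uorf_rate_targets = 0,
                  long_utr3_rate_targets = 0, background_dej_rate = 0,
                  background_uorf_rate = 0, background_long_utr3_rate = 0,
                  seed = 2)
  sim <- simulate_annotation(p)
  expect_false(any(sim$truth$planted_dej | sim$truth$planted_uorf |
                     sim$truth$planted_long3utr))
  f <- annotate_features(sim$models, sim$sequences)
  expect_false(any(f$has_dej[f$evaluable], na.rm = TRUE))
  expect_false(any(f$has_uorf[f$evaluable], na.rm = TRUE))
})

test_that("planted features are recovered and incidental features absent", {
  w <- small_world()
  f <- annotate_features(w$sim$models, w$sim$sequences)
  g <- collapse_to_gene(f)
  m <- merge(w$sim$truth, g, by = "gene_id")
  sw <- !is.na(m$planted_switch)
  expect_true(all(m$has_dej[m$planted_dej]))
  expect_true(all(m$has_uorf[m$planted_uorf]))
  expect_true(all(m$is_long_utr3[m$planted_long3utr]))
  # non-planted, non-switch genes are feature-negative by construction
  expect_false(any(m$has_dej[!m$planted_dej & !sw], na.rm = TRUE))
  expect_false(any(m$has_uorf[!m$planted_uorf], na.rm = TRUE))
  expect_false(any(m$is_long_utr3[!m$planted_long3utr], na.rm = TRUE))
  # the planted switch isoform itself carries a dEJ
  swiso <- stats::na.omit(w$sim$truth$planted_switch)
  expect_true(all(f$has_dej[match(swiso, f$transcript_id)]))
})

test_that("NB count marginals match (mu, mu + mu^2 * dispersion)", {
  set.seed(123)
  for (mu in c(8, 200)) {
    for (phi in c(0.05, 0.2)) {
      x <- nmdtargets:::rnb(10000, mu, phi)
      expect_equal(mean(x), mu, tolerance = 0.05)
      expect_equal(stats::var(x), mu + phi * mu^2, tolerance = 0.15)
    }
  }
})

test_that("count expectations follow the steady-state closed forms", {
  p <- sim_params(n_genes = 120, n_targets = 15, n_switch_genes = 0,
                  n_factors = 0, feedback_fraction = 0.3, seed = 31)
  sim <- simulate_annotation(p)
  ct <- simulate_counts(sim)
  tr <- sim$truth
  mu_n <- ct$expected$null; mu_c <- ct$expected$control
  pure <- tr$is_planted_target & !tr$has_feedback
  fb <- tr$has_feedback
  bg <- !tr$is_planted_target
  has_int <- ct$gene_lengths$intronic_length > 0
  # composition renormalization rescales all genes of a genotype equally;
  # remove the genotype-level scale (estimated on background genes) before
  # checking the per-gene closed forms
  scale_ex <- stats::median(mu_n$ex[bg] / mu_c$ex[bg])
  scale_in <- stats::median(mu_n$int[bg & has_int] / mu_c$int[bg & has_int])
  # planted (factor 0.5, no feedback): log2(exon/intron) exactly 1 higher in null
  i <- which(pure & has_int)
  expect_equal(log2(mu_n$ex[i] / mu_n$int[i]) - log2(mu_c$ex[i] / mu_c$int[i]) -
                 log2(scale_ex / scale_in),
               rep(1, length(i)), tolerance = 1e-8)
  # feedback: exonic expectation equal across genotypes, intronic halves
  j <- which(fb & has_int)
  expect_equal(mu_n$ex[j] / mu_c$ex[j] / scale_ex, rep(1, length(j)),
               tolerance = 1e-6)
  expect_equal(mu_n$int[j] / mu_c$int[j] / scale_in, rep(0.5, length(j)),
               tolerance = 1e-6)
  # stabilization_factor -> 1 removes all expected differences
  p1 <- sim_params(n_genes = 120, n_targets = 15, n_switch_genes = 0,
                   n_factors = 0, feedback_fraction = 0,
                   stabilization_factor = 1 - 1e-12, seed = 31)
  ct1 <- simulate_counts(simulate_annotation(p1))
  expect_equal(ct1$expected$null$ex, ct1$expected$control$ex, tolerance = 1e-6)
  # intron-less genes get zero intronic counts and are flagged
  single <- !has_int
  if (any(single)) {
    expect_true(all(ct$intronic[single, ] == 0))
    expect_false(any(ct$has_intron[rownames(ct$exonic)[single]]))
  }
})

test_that("stage matrix plants the dip where stated and nowhere else", {
  p <- sim_params(n_genes = 400, n_targets = 60, n_switch_genes = 0,
                  n_factors = 10, seed = 8)
  sim <- simulate_annotation(p)
  expect_error(simulate_stage_matrix(sim$truth, dip_depth = 0), "dip_depth")
  expect_error(simulate_stage_matrix(sim$truth, stages = c("E4.5", "E5.5")),
               "baseline")
  expr <- simulate_stage_matrix(sim$truth, dip_depth = 1, seed = 21)
  lfc <- lfc_vs_baseline(expr)
  tg <- sim$truth$gene_id[sim$truth$trajectory_class == "target"]
  grab <- function(stage, lin, genes)
    mean(lfc$lfc[lfc$stage == stage & lfc$lineage == lin &
                   lfc$gene_id %in% genes])
  # baseline stage: LFC identically 0
  expect_equal(lfc$lfc[lfc$stage == "E3.5" & lfc$lineage == "all"],
               rep(0, nrow(expr$matrix)))
  # targets: ~ -dip_depth at E5.5 in EPI, ~0 in TE, rebound at E6.5
  expect_equal(grab("E5.5", "EPI", tg), -1, tolerance = 0.12)
  expect_equal(grab("E5.5", "TE", tg), 0, tolerance = 0.12)
  expect_equal(grab("E6.5", "EPI", tg), 0, tolerance = 0.12)
})
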