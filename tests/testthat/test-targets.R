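# Exhaustive Boolean oracle for the integration rule.
canonical_rule <- function(up, stab, dej, prior) up & (stab | dej | prior)
ap_rule <- function(up_iso, dej, longer, prior) up_iso & (dej | longer | prior)

test_that("canonical calls match the Boolean rule on all evidence combinations", {
  combos <- expand.grid(up = c(TRUE, FALSE), stab = c(TRUE, FALSE),
                        dej = c(TRUE, FALSE), prior = c(TRUE, FALSE))
  gid <- sprintf("g%02d", seq_len(nrow(combos)))
  de <- data.frame(gene_id = gid,
                   log2fc = ifelse(combos$up, 1.5, 1.5),
                   q = ifelse(combos$up, 0.01, 0.5))
  stab <- data.frame(gene_id = gid, dss = ifelse(combos$stab, 0.8, 0),
                     stabilized = combos$stab)
  gf <- data.frame(gene_id = gid, evaluable = TRUE, has_dej = combos$dej,
                   has_uorf = FALSE, is_long_utr3 = FALSE,
                   max_utr3_length = 100)
  prior <- gid[combos$prior]
  calls <- call_canonical_targets(de, stab, gf, prior)
  expected <- gid[canonical_rule(combos$up, combos$stab, combos$dej,
                                 combos$prior)]
  expect_setequal(calls$gene_id, expected)
  # upregulated with no second criterion excluded; stabilized-not-up excluded
  expect_false(any(calls$gene_id %in%
                     gid[combos$up & !combos$stab & !combos$dej & !combos$prior]))
  expect_false(any(calls$gene_id %in% gid[!combos$up]))
  # negative fold change disqualifies even at small q
  de2 <- de; de2$log2fc <- -1
  expect_equal(nrow(call_canonical_targets(de2, stab, gf, prior)), 0)
})

test_that("AP calls match the Boolean rule including direction", {
  combos <- expand.grid(updir = c(1, -1), dej = c(TRUE, FALSE),
                        longer = c(TRUE, FALSE), prior = c(TRUE, FALSE))
  iso <- sprintf("g%02d.t2", seq_len(nrow(combos)))
  gid <- sub("\\.t2", "", iso)
  sw <- data.frame(isoform_id = iso, gene_id = gid,
                   dif = 0.4 * combos$updir, p = 1e-4, q = 1e-3)
  cons <- data.frame(isoform_id = iso[combos$longer], gene_id = gid[combos$longer],
                     major_isoform = "x", consequence = "utr3_longer")
  feats <- data.frame(transcript_id = iso, gene_id = gid, evaluable = TRUE,
                      has_dej = combos$dej, has_uorf = FALSE)
  calls <- call_ap_targets(sw, cons, feats, gid[combos$prior])
  expected <- gid[ap_rule(combos$updir > 0, combos$dej, combos$longer,
                          combos$prior)]
  expect_setequal(calls$gene_id, expected)
  # downregulated switch isoform with dEJ excluded
  expect_false(any(calls$gene_id %in% gid[combos$updir < 0]))
  # prior list alone qualifies an upregulated isoform
  only_prior <- gid[combos$updir > 0 & !combos$dej & !combos$longer &
                      combos$prior]
  expect_true(all(only_prior %in% calls$gene_id))
})

test_that("combine_targets takes the union with category 'both'", {
  canon <- data.frame(gene_id = c("a", "b", "c"))
  ap <- data.frame(gene_id = c("c", "d"))
  comb <- combine_targets(canon, ap)
  expect_equal(nrow(comb), 4)
  expect_equal(comb$category[comb$gene_id == "c"], "both")
  # disjoint lists add; empty ap leaves canonical unchanged
  comb2 <- combine_targets(canon, data.frame(gene_id = character(0)))
  expect_setequal(comb2$gene_id, canon$gene_id)
  expect_true(all(comb2$category == "canonical_high_confidence"))
})

test_that("feature enrichment uses the exact hypergeometric null", {
  # 2x2 table (9,1; 10,90): compare Fisher p with hypergeometric enumeration
  gf <- data.frame(
    gene_id = sprintf("g%03d", 1:110), evaluable = TRUE,
    has_dej = c(rep(TRUE, 9), rep(FALSE, 1), rep(TRUE, 10), rep(FALSE, 90)),
    has_uorf = FALSE, is_long_utr3 = FALSE, max_utr3_length = 100)
  set <- gf$gene_id[1:10]
  enr <- feature_enrichment(set, gf)
  p_impl <- enr$p[enr$feature == "has_dej"]
  # enumeration oracle: sum over tables as or more extreme under fixed margins
  m <- 19; nn <- 91; k <- 10   # feature+, feature-, set size
  probs <- stats::dhyper(0:min(k, m), m, nn, k)
  p_oracle <- sum(probs[probs <= stats::dhyper(9, m, nn, k) * (1 + 1e-7)])
  expect_equal(p_impl, p_oracle, tolerance = 1e-12)
  expect_equal(enr$prop_set[enr$feature == "has_dej"], 0.9)
  # set = all dEJ-positive genes -> proportion 1.0
  enr2 <- feature_enrichment(gf$gene_id[gf$has_dej], gf)
  expect_equal(enr2$prop_set[enr2$feature == "has_dej"], 1.0)
  expect_error(feature_enrichment(character(0), gf), "empty")
})

test_that("random sets show no enrichment", {
  set.seed(12)
  gf <- data.frame(gene_id = sprintf("g%04d", 1:1000), evaluable = TRUE,
                   has_dej = runif(1000) < 0.2, has_uorf = FALSE,
                   is_long_utr3 = FALSE, max_utr3_length = 100)
  ps <- replicate(50, {
    enr <- feature_enrichment(sample(gf$gene_id, 100), gf)
    enr$p[enr$feature == "has_dej"]
  })
  expect_gt(mean(ps > 0.05), 0.8)   # p roughly uniform: few false positives
})

test_that("overlap percentages are plain arithmetic", {
  expect_equal(overlap_with_prior(letters[1:5], letters[1:10]), 100)
  expect_equal(overlap_with_prior(letters[1:5], LETTERS[1:5]), 0)
  expect_equal(overlap_with_prior(sprintf("g%02d", 1:20),
                                  sprintf("g%02d", 14:20)), 35)
  expect_error(overlap_with_prior(character(0), letters), "empty")
})

test_that("list size is monotone in the q threshold", {
  w <- small_world()
  ct <- w$counts
  de5 <- de_test(filter_low_counts(ct$exonic), ct$samples$genotype,
                 q_threshold = 0.05)
  st <- infer_stability(ct)
  gf <- collapse_to_gene(annotate_features(w$sim$models, w$sim$sequences))
  prior <- w$sim$truth$gene_id[w$sim$truth$in_prior_list]
  n_strict <- nrow(call_canonical_targets(de5, st, gf, prior, q_threshold = 0.05))
  n_loose <- nrow(call_canonical_targets(de5, st, gf, prior, q_threshold = 0.2))
  expect_lte(n_strict, n_loose)
})
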