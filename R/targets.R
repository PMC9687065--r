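#' Call canonical high-confidence NMD targets
#'
#' A gene is a canonical high-confidence target when it is upregulated in
#' null samples (q below threshold and positive log2 fold change) and meets
#' at least one of: (1) stabilized (DSS above threshold), (2) encodes a
#' transcript with a dEJ, (3) present in the prior published target list.
#'
#' @param de A `de_result` data.frame from [de_test()].
#' @param stab A `stability_result` data.frame from [infer_stability()].
#' @param gene_features Gene-level feature table from [collapse_to_gene()].
#' @param prior_list Character vector of prior published target gene ids.
#' @param q_threshold DE significance threshold (default 0.1, the
#'   blastocyst value).
#' @return data.frame of class `target_calls`: `gene_id`, `category`
#'   (`"canonical_high_confidence"`), `evidence` (comma-separated), and the
#'   individual evidence flags.
#' @export
call_canonical_targets <- function(de, stab, gene_features, prior_list,
                                   q_threshold = 0.1) {
  up <- !is.na(de$q) & de$q < q_threshold & de$log2fc > 0
  st <- stab$stabilized[match(de$gene_id, stab$gene_id)] %in% TRUE
  dej <- gene_features$has_dej[match(de$gene_id, gene_features$gene_id)] %in% TRUE
  prior <- de$gene_id %in% prior_list
  call <- up & (st | dej | prior)
  k <- sum(call)
  out <- data.frame(gene_id = de$gene_id[call],
                    category = rep("canonical_high_confidence", k),
                    upregulated = rep(TRUE, k),
                    stabilized = st[call], dej = dej[call],
                    prior_list = prior[call],
                    stringsAsFactors = FALSE)
  ev <- cbind(upregulated = rep(TRUE, k), stabilized = st[call],
              dej = dej[call], prior_list = prior[call])
  out$evidence <- vapply(seq_len(k), function(i)
    paste(colnames(ev)[ev[i, ]], collapse = ","), character(1))
  rownames(out) <- NULL
  class(out) <- c("target_calls", "data.frame")
  out
}

#' Call alternatively-processed (AP) high-confidence NMD targets
#'
#' An isoform is an AP high-confidence target when it is significantly
#' upregulated in null samples (dif above 0, q below threshold) and either
#' carries a dEJ, has a 3' UTR longer than the gene's major isoform, or its
#' gene is on the prior target list. uORF evidence is computed upstream but
#' excluded from the default call (set `use_uorf = TRUE` to include it).
#'
#' @param switch A `switch_result` data.frame from [dif_test()].
#' @param consequences Consequence table from [classify_consequences()].
#' @param features Per-transcript feature table from [annotate_features()].
#' @param prior_list Character vector of prior target gene ids.
#' @param q_threshold Significance threshold (default 0.1).
#' @param use_uorf Include isoform uORF presence as qualifying evidence.
#' @return data.frame of class `target_calls` with `gene_id`, `category`
#'   (`"ap_high_confidence"`), `isoform_id` and evidence flags.
#' @export
call_ap_targets <- function(switch, consequences, features, prior_list,
                            q_threshold = 0.1, use_uorf = FALSE) {
  up <- switch[!is.na(switch$q) & switch$q < q_threshold & switch$dif > 0, ,
               drop = FALSE]
  f <- features[match(up$isoform_id, features$transcript_id), , drop = FALSE]
  dej <- f$has_dej %in% TRUE
  longer <- vapply(up$isoform_id, function(id)
    any(consequences$isoform_id == id &
          consequences$consequence %in% "utr3_longer"), logical(1))
  prior <- up$gene_id %in% prior_list
  uorf <- f$has_uorf %in% TRUE
  qual <- dej | longer | prior
  if (use_uorf) qual <- qual | uorf
  k <- sum(qual)
  out <- data.frame(gene_id = up$gene_id[qual],
                    category = rep("ap_high_confidence", k),
                    isoform_id = up$isoform_id[qual],
                    isoform_upregulated = rep(TRUE, k),
                    dej = dej[qual], utr3_longer = unname(longer[qual]),
                    prior_list = prior[qual], uorf = uorf[qual],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("target_calls", "data.frame")
  out
}

#' Combine canonical and AP target lists
#'
#' Union of gene ids; genes present in both lists receive category
#' `"both"`.
#'
#' @param canonical,ap `target_calls` data.frames.
#' @return data.frame `gene_id`, `category`.
#' @export
combine_targets <- function(canonical, ap) {
  cg <- unique(canonical$gene_id); ag <- unique(ap$gene_id)
  genes <- union(cg, ag)
  data.frame(gene_id = genes,
             category = ifelse(genes %in% cg & genes %in% ag, "both",
                               ifelse(genes %in% cg,
                                      "canonical_high_confidence",
                                      "ap_high_confidence")),
             stringsAsFactors = FALSE)
}

#' Feature enrichment of a gene set against the background
#'
#' For each feature flag, the proportion of set genes carrying the feature
#' versus the background (all evaluable genes), with a two-sided Fisher
#' exact test. The 3' UTR length comparison is reported as a ratio of means
#' with a Wilcoxon rank-sum test.
#'
#' @param gene_set Character vector of gene ids.
#' @param gene_features Gene-level feature table ([collapse_to_gene()]).
#' @return data.frame with one row per feature: `feature`, `prop_set`,
#'   `prop_background`, `odds_ratio`, `p`; plus attributes `utr3_ratio`
#'   and `utr3_p`.
#' @export
feature_enrichment <- function(gene_set, gene_features) {
  bg <- gene_features[gene_features$evaluable %in% TRUE, , drop = FALSE]
  inset <- bg$gene_id %in% gene_set
  if (!any(inset)) stop("empty gene set (no evaluable set genes)")
  one <- function(flag) {
    x <- bg[[flag]] %in% TRUE
    tab <- table(factor(inset, c(TRUE, FALSE)), factor(x, c(TRUE, FALSE)))
    ft <- stats::fisher.test(tab)
    data.frame(feature = flag, prop_set = mean(x[inset]),
               prop_background = mean(x),
               odds_ratio = unname(ft$estimate), p = ft$p.value)
  }
  out <- do.call(rbind, lapply(c("has_dej", "has_uorf", "is_long_utr3"), one))
  rownames(out) <- NULL
  u_set <- bg$max_utr3_length[inset]
  u_all <- bg$max_utr3_length
  attr(out, "utr3_ratio") <- mean(u_set, na.rm = TRUE) / mean(u_all, na.rm = TRUE)
  attr(out, "utr3_p") <- tryCatch(
    stats::wilcox.test(u_set, u_all[!inset])$p.value, error = function(e) NA_real_)
  out
}

#' Percent overlap of a gene set with a prior list
#'
#' @param gene_set Character vector (nonempty).
#' @param prior_list Character vector.
#' @return Percentage: 100 * |set intersect prior| / |set|.
#' @export
overlap_with_prior <- function(gene_set, prior_list) {
  gene_set <- unique(gene_set)
  if (length(gene_set) == 0L) stop("empty gene set")
  100 * length(intersect(gene_set, prior_list)) / length(gene_set)
}
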