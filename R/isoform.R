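#' Filtering thresholds for isoform-switch analysis
#'
#' Isoforms expressed below `min_tpm` mean TPM or contributing less than
#' `min_gene_fraction` of parent-gene expression are removed; after
#' filtering, only genes with at least `min_isoforms` surviving transcripts
#' are kept.
#'
#' @param min_tpm Minimum mean TPM (default 0.1).
#' @param min_gene_fraction Minimum mean isoform fraction (default 0.05).
#' @param min_isoforms Minimum surviving isoforms per gene (default 2).
#' @return A list of class `switch_filter_config`.
#' @export
switch_filter_config <- function(min_tpm = 0.1, min_gene_fraction = 0.05,
                                 min_isoforms = 2L) {
  if (min_tpm < 0 || min_gene_fraction < 0 || min_isoforms < 0)
    stop("thresholds must be >= 0")
  structure(list(min_tpm = min_tpm, min_gene_fraction = min_gene_fraction,
                 min_isoforms = min_isoforms), class = "switch_filter_config")
}

#' Compute isoform fractions from TPM
#'
#' The isoform fraction (IF) of a transcript in a sample is its TPM divided
#' by the summed TPM of the parent gene's isoforms; samples where the gene
#' TPM is zero get missing IFs and are excluded from testing.
#'
#' @param tpm Isoform x sample TPM matrix.
#' @param map data.frame mapping `isoform_id` to `gene_id`.
#' @return An `isoform_quant` object: list with `tpm`, `if_` (IF matrix),
#'   `map`.
#' @export
isoform_fractions <- function(tpm, map) {
  if (!all(rownames(tpm) %in% map$isoform_id))
    stop("isoform(s) in TPM matrix with unknown gene: ",
         paste(utils::head(setdiff(rownames(tpm), map$isoform_id), 3),
               collapse = ", "))
  map <- map[match(rownames(tpm), map$isoform_id), , drop = FALSE]
  gene_tpm <- rowsum(tpm, map$gene_id)
  gt <- gene_tpm[map$gene_id, , drop = FALSE]
  iff <- tpm / gt
  iff[gt == 0] <- NA_real_
  structure(list(tpm = tpm, if_ = iff, map = map), class = "isoform_quant")
}

#' Filter isoform quantifications
#'
#' Applies the [switch_filter_config()] thresholds and recomputes isoform
#' fractions over the surviving isoforms, so IFs still sum to one per gene
#' and sample.
#'
#' @param quant An `isoform_quant` object from [isoform_fractions()].
#' @param config A [switch_filter_config()].
#' @return A filtered `isoform_quant` object.
#' @export
filter_isoforms <- function(quant, config = switch_filter_config()) {
  mean_tpm <- rowMeans(quant$tpm)
  mean_if <- rowMeans(quant$if_, na.rm = TRUE)
  keep <- mean_tpm >= config$min_tpm & !is.na(mean_if) &
    mean_if >= config$min_gene_fraction
  map <- quant$map[keep, , drop = FALSE]
  n_iso <- table(map$gene_id)
  keep_gene <- names(n_iso)[n_iso >= config$min_isoforms]
  keep2 <- keep & quant$map$gene_id %in% keep_gene
  isoform_fractions(quant$tpm[keep2, , drop = FALSE],
                    quant$map[keep2, , drop = FALSE])
}

#' Test isoform-usage differences between genotypes
#'
#' Per isoform, a two-sample Welch t-test on arcsine-square-root-transformed
#' isoform fractions (null vs control), with Benjamini-Hochberg adjustment
#' across isoforms. `dif` is the difference of mean IF (null minus control)
#' on the raw scale. Isoforms with constant IF in both groups get p = 1 by
#' convention.
#'
#' @param quant A (filtered) `isoform_quant` object.
#' @param genotype Genotype vector over samples.
#' @param q_threshold Significance threshold for `called` (default 0.1).
#' @return data.frame of class `switch_result`: `isoform_id`, `gene_id`,
#'   `mean_if_null`, `mean_if_control`, `dif`, `p`, `q`, `direction`,
#'   `called`.
#' @export
dif_test <- function(quant, genotype, q_threshold = 0.1) {
  genotype <- as.character(genotype)
  iff <- quant$if_
  j1 <- genotype == "null"; j0 <- genotype == "control"
  if (sum(j1) < 2 || sum(j0) < 2) stop("need >= 2 samples per group")
  trans <- asin(sqrt(pmin(pmax(iff, 0), 1)))
  res <- lapply(seq_len(nrow(iff)), function(i) {
    x1 <- trans[i, j1]; x0 <- trans[i, j0]
    x1 <- x1[!is.na(x1)]; x0 <- x0[!is.na(x0)]
    m1 <- mean(iff[i, j1], na.rm = TRUE); m0 <- mean(iff[i, j0], na.rm = TRUE)
    if (length(x1) < 2 || length(x0) < 2) {
      p <- NA_real_
    } else if (stats::sd(x1) == 0 && stats::sd(x0) == 0) {
      p <- 1
    } else {
      p <- stats::t.test(x1, x0)$p.value
    }
    data.frame(mean_if_null = m1, mean_if_control = m0, dif = m1 - m0, p = p)
  })
  out <- do.call(rbind, res)
  out <- cbind(data.frame(isoform_id = rownames(iff),
                          gene_id = quant$map$gene_id,
                          stringsAsFactors = FALSE), out)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out$direction <- ifelse(out$dif > 0, "up", "down")
  out$called <- !is.na(out$q) & out$q < q_threshold
  rownames(out) <- NULL
  class(out) <- c("switch_result", "data.frame")
  out
}

# introns of a transcript as genomic intervals (0-based half-open)
tx_introns <- function(models, transcript_id) {
  e <- models$exons[models$exons$transcript_id == transcript_id, , drop = FALSE]
  if (nrow(e) < 2L) return(data.frame(start = integer(0), end = integer(0)))
  data.frame(start = e$end[-nrow(e)], end = e$start[-1])
}

# 5'/3' genomic end of a transcript, strand-aware
tx_ends <- function(models, transcript_id) {
  e <- models$exons[models$exons$transcript_id == transcript_id, , drop = FALSE]
  if (e$strand[1] == "+") c(tss = min(e$start), tts = max(e$end))
  else c(tss = max(e$end), tts = min(e$start))
}

# terminal (last, strand-aware) exon as c(start, end)
last_exon <- function(models, transcript_id) {
  e <- models$exons[models$exons$transcript_id == transcript_id, , drop = FALSE]
  k <- if (e$strand[1] == "+") nrow(e) else 1L
  c(e$start[k], e$end[k])
}

compare_isoform_pair <- function(models, features, up_id, major_id) {
  cons <- character(0)
  f_up <- features[features$transcript_id == up_id, , drop = FALSE]
  f_mj <- features[features$transcript_id == major_id, , drop = FALSE]
  if (nrow(f_up) == 1L && nrow(f_mj) == 1L &&
      !is.na(f_up$has_dej) && !is.na(f_mj$has_dej)) {
    if (f_up$has_dej && !f_mj$has_dej) cons <- c(cons, "nmd_sensitivity_gain")
    if (!f_up$has_dej && f_mj$has_dej) cons <- c(cons, "nmd_sensitivity_loss")
    if (!is.na(f_up$utr3_length) && !is.na(f_mj$utr3_length)) {
      if (f_up$utr3_length > f_mj$utr3_length) cons <- c(cons, "utr3_longer")
      if (f_up$utr3_length < f_mj$utr3_length) cons <- c(cons, "utr3_shorter")
    }
  }
  e_up <- models$exons[models$exons$transcript_id == up_id, , drop = FALSE]
  intr <- tx_introns(models, major_id)
  if (nrow(intr) && any(vapply(seq_len(nrow(intr)), function(i) {
    any(e_up$start <= intr$start[i] & e_up$end >= intr$end[i])
  }, logical(1)))) cons <- c(cons, "intron_retention")
  end_up <- tx_ends(models, up_id); end_mj <- tx_ends(models, major_id)
  if (end_up["tss"] != end_mj["tss"]) cons <- c(cons, "alt_tss")
  if (end_up["tts"] != end_mj["tts"]) cons <- c(cons, "alt_tts")
  if (!identical(last_exon(models, up_id), last_exon(models, major_id)))
    cons <- c(cons, "last_exon_change")
  tx <- models$transcripts
  if (tx$length[match(up_id, tx$transcript_id)] !=
      tx$length[match(major_id, tx$transcript_id)])
    cons <- c(cons, "length_change")
  if (nrow(e_up) != sum(models$exons$transcript_id == major_id))
    cons <- c(cons, "exon_number_change")
  cons
}

#' Classify consequences of significant isoform switches
#'
#' Each significantly upregulated isoform (in null samples) is compared
#' against its gene's major isoform - the isoform with the highest mean
#' control IF, ties broken by longer transcript then lexicographic id.
#' Emitted consequence classes: `nmd_sensitivity_gain`/`loss` (dEJ status
#' differs), `utr3_longer`/`shorter`, `intron_retention` (an exon of the up
#' isoform spans an intron of the major isoform), `alt_tss`, `alt_tts`,
#' `last_exon_change`, `length_change`, `exon_number_change`.
#'
#' @param models A [transcript_models] object.
#' @param features Per-transcript feature table from [annotate_features()].
#' @param switch A `switch_result` data.frame from [dif_test()].
#' @param quant The `isoform_quant` the switch test was run on.
#' @param genotype Genotype vector over samples.
#' @param q_threshold Significance threshold (default 0.1).
#' @return data.frame with one row per (isoform, consequence):
#'   `isoform_id`, `gene_id`, `major_isoform`, `consequence`. Upregulated
#'   significant isoforms with an empty consequence set appear with
#'   `consequence = NA`.
#' @export
classify_consequences <- function(models, features, switch, quant, genotype,
                                  q_threshold = 0.1) {
  up <- switch[!is.na(switch$q) & switch$q < q_threshold & switch$dif > 0, ,
               drop = FALSE]
  if (nrow(up) == 0L)
    return(data.frame(isoform_id = character(0), gene_id = character(0),
                      major_isoform = character(0), consequence = character(0),
                      stringsAsFactors = FALSE))
  ctrl_if <- rowMeans(quant$if_[, genotype == "control", drop = FALSE],
                      na.rm = TRUE)
  tx <- models$transcripts
  rows <- list()
  for (i in seq_len(nrow(up))) {
    g <- up$gene_id[i]
    members <- quant$map$isoform_id[quant$map$gene_id == g]
    cand <- setdiff(members, up$isoform_id[i])
    if (length(cand) == 0L) next
    ci <- ctrl_if[cand]
    if (all(is.nan(ci))) {
      message("no major isoform definable for gene ", g, "; skipped")
      next
    }
    len <- tx$length[match(cand, tx$transcript_id)]
    ord <- order(-ci, -len, cand)
    major <- cand[ord[1]]
    cons <- compare_isoform_pair(models, features, up$isoform_id[i], major)
    if (length(cons) == 0L) cons <- NA_character_
    rows[[length(rows) + 1L]] <- data.frame(
      isoform_id = up$isoform_id[i], gene_id = g, major_isoform = major,
      consequence = cons, stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(isoform_id = character(0), gene_id = character(0),
               major_isoform = character(0), consequence = character(0),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
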