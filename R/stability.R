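#' Configuration for stability inference
#'
#' @param pseudocount Added to normalized counts before log2 (default 1).
#' @param stringency Required fraction of samples with nonzero intronic
#'   signal for a gene to be quantifiable (default 0.99, the most stringent
#'   value: with 19 samples, every sample must be nonzero).
#' @param smoother_span Span of the local-regression bias smoother
#'   (default 0.3).
#' @param dss_threshold Differential stability score above which a gene is
#'   called stabilized (default 0.1).
#' @return A list of class `stability_config`.
#' @export
stability_config <- function(pseudocount = 1, stringency = 0.99,
                             smoother_span = 0.3, dss_threshold = 0.1) {
  if (pseudocount <= 0) stop("pseudocount must be > 0")
  if (!(stringency > 0 && stringency <= 1)) stop("stringency must be in (0, 1]")
  if (smoother_span <= 0) stop("smoother_span must be > 0")
  structure(list(pseudocount = pseudocount, stringency = stringency,
                 smoother_span = smoother_span, dss_threshold = dss_threshold),
            class = "stability_config")
}

#' Per-gene, per-sample stability proxy (delta)
#'
#' Exonic and intronic counts are normalized by their own median-of-ratios
#' size factors; delta is log2(normalized exonic + pseudocount) minus
#' log2(normalized intronic + pseudocount), a proxy for log mature over
#' pre-mRNA abundance and hence (inverse) decay rate. Genes without introns
#' are excluded (reason `no_intron`); genes whose intronic count is zero in
#' more than `1 - stringency` of samples are flagged unquantifiable
#' (reason `stringency`).
#'
#' @param ct A `count_tables` object (see [simulate_counts()] /
#'   [read_count_tables()]).
#' @param config A [stability_config()].
#' @return List with `delta` (matrix over quantifiable genes), `log_abund`
#'   (log2 normalized exonic abundance, same shape), `quantifiable`
#'   (logical over all genes), `reason` (character), `samples`.
#' @export
delta_matrix <- function(ct, config = stability_config()) {
  pc <- config$pseudocount
  reason <- rep("ok", nrow(ct$exonic))
  names(reason) <- rownames(ct$exonic)
  no_intron <- !ct$has_intron[rownames(ct$exonic)]
  reason[no_intron] <- "no_intron"
  frac_nonzero <- rowMeans(ct$intronic > 0)
  low <- !no_intron & frac_nonzero < config$stringency
  reason[low] <- "stringency"
  quantifiable <- reason == "ok"

  ex <- normalize_counts(ct$exonic)$normalized
  int <- normalize_counts(ct$intronic[quantifiable, , drop = FALSE])$normalized
  delta <- log2(ex[quantifiable, , drop = FALSE] + pc) - log2(int + pc)
  list(delta = delta,
       log_abund = log2(ex[quantifiable, , drop = FALSE] + pc),
       quantifiable = quantifiable, reason = reason,
       samples = ct$samples)
}

#' Fit and remove the gene-specific stability bias
#'
#' The raw exon/intron delta carries an expression-dependent bias (genes
#' that are abundant partly because they are stable show inflated deltas).
#' For each sample, a local (loess) regression of delta against the gene's
#' overall (across-sample mean) log exonic abundance estimates the sample's
#' bias curve. The curve is evaluated at the gene's mean abundance - not
#' its per-sample abundance - so that genotype-driven expression changes
#' cannot masquerade as bias and be subtracted from real stability signal.
#' Because loess is equivariant to additive shifts in the response,
#' sample-wide artifacts (library-size offsets) are absorbed exactly. The
#' residuals are then centered per gene over all samples combined, so each
#' gene's bias-corrected stability has zero mean and only between-sample
#' (e.g. genotype) structure remains. With fewer than 50 quantifiable genes
#' the smoother is unreliable and an error instructs the user to lower the
#' stringency.
#'
#' @param dm Output of [delta_matrix()], or a delta matrix (then
#'   `log_abund` must be supplied).
#' @param log_abund Log2 normalized exonic abundance matrix.
#' @param config A [stability_config()].
#' @return List with `stability` (bias-corrected matrix) and `bias`
#'   (fitted bias, `delta = stability + bias`).
#' @export
fit_bias <- function(dm, log_abund = NULL, config = stability_config()) {
  if (is.list(dm) && !is.null(dm$delta)) {
    delta <- dm$delta
    if (is.null(log_abund)) log_abund <- dm$log_abund
  } else delta <- dm
  if (is.null(log_abund)) stop("log_abund required")
  ng <- nrow(delta)
  if (ng < 50L)
    stop("too few quantifiable genes (", ng,
         ") to fit the bias smoother; lower the stringency")
  smooth <- matrix(0, ng, ncol(delta), dimnames = dimnames(delta))
  a <- rowMeans(log_abund)
  for (j in seq_len(ncol(delta))) {
    fit <- stats::loess(delta[, j] ~ a, span = config$smoother_span,
                        degree = 1, family = "gaussian")
    smooth[, j] <- fit$fitted
  }
  resid <- delta - smooth
  gene_mean <- rowMeans(resid)
  stability <- resid - gene_mean
  list(stability = stability, bias = smooth + gene_mean)
}

#' Differential stability score (DSS)
#'
#' The DSS of a gene is the difference in mean bias-corrected stability
#' between null and control samples (positive = more stable upon NMD loss).
#' Genes with DSS above `dss_threshold` are called stabilized; genes below
#' minus the threshold destabilized.
#'
#' @param stability Bias-corrected stability matrix from [fit_bias()].
#' @param genotype Genotype vector over samples (`"null"` / `"control"`).
#' @param config A [stability_config()].
#' @return data.frame `gene_id`, `dss`, `stabilized`, `destabilized`.
#' @export
differential_stability <- function(stability, genotype,
                                   config = stability_config()) {
  genotype <- as.character(genotype)
  if (!any(genotype == "null") || !any(genotype == "control"))
    stop("both genotypes required")
  dss <- rowMeans(stability[, genotype == "null", drop = FALSE]) -
    rowMeans(stability[, genotype == "control", drop = FALSE])
  data.frame(gene_id = rownames(stability), dss = dss,
             stabilized = dss > config$dss_threshold,
             destabilized = dss < -config$dss_threshold,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Full stability inference from count tables
#'
#' Convenience wrapper chaining [delta_matrix()], [fit_bias()] and
#' [differential_stability()]; returns one row per input gene with
#' unquantifiable genes carrying `NA` scores.
#'
#' @inheritParams delta_matrix
#' @return data.frame of class `stability_result`: `gene_id`, `dss`,
#'   `stabilized`, `destabilized`, `quantifiable`, `reason`.
#' @export
infer_stability <- function(ct, config = stability_config()) {
  dm <- delta_matrix(ct, config)
  fb <- fit_bias(dm, config = config)
  ds <- differential_stability(fb$stability, ct$samples$genotype, config)
  all_genes <- rownames(ct$exonic)
  out <- data.frame(gene_id = all_genes,
                    dss = ds$dss[match(all_genes, ds$gene_id)],
                    stringsAsFactors = FALSE)
  out$stabilized <- !is.na(out$dss) & out$dss > config$dss_threshold
  out$destabilized <- !is.na(out$dss) & out$dss < -config$dss_threshold
  out$quantifiable <- dm$quantifiable[all_genes]
  out$reason <- dm$reason[all_genes]
  rownames(out) <- NULL
  class(out) <- c("stability_result", "data.frame")
  out
}
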