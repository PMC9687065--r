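#' Remove genes with uniformly low counts
#'
#' A gene is kept when at least one sample has at least `min_reads` raw
#' reads.
#'
#' @param counts Integer gene x sample matrix of raw counts.
#' @param min_reads Minimum raw read count (default 10).
#' @return The filtered count matrix.
#' @export
filter_low_counts <- function(counts, min_reads = 10L) {
  if (is.null(dim(counts)) || nrow(counts) == 0L || ncol(counts) == 0L)
    stop("empty count matrix")
  if (any(counts < 0)) stop("counts must be non-negative")
  counts[apply(counts, 1, max) >= min_reads, , drop = FALSE]
}

#' Median-of-ratios size factors
#'
#' For each sample, the size factor is the median across genes of the ratio
#' of that sample's count to the across-sample geometric mean, computed over
#' genes with all-positive counts. Falls back to total-count scaling (with a
#' warning) when no gene is positive in every sample.
#'
#' @param counts Gene x sample count matrix.
#' @return Numeric vector of size factors (one per sample), scaled to have
#'   geometric mean 1.
#' @export
size_factors <- function(counts) {
  pos <- rowSums(counts <= 0) == 0
  if (!any(pos)) {
    warning("no gene with all-positive counts; falling back to total-count scaling")
    sf <- colSums(counts)
    return(sf / exp(mean(log(sf))))
  }
  lc <- log(counts[pos, , drop = FALSE])
  geo <- rowMeans(lc)
  sf <- apply(lc, 2, function(x) exp(stats::median(x - geo)))
  sf / exp(mean(log(sf)))
}

#' Normalize counts by size factors
#'
#' @inheritParams size_factors
#' @param sf Optional precomputed size factors.
#' @return List with `normalized` matrix and `size_factors`.
#' @export
normalize_counts <- function(counts, sf = NULL) {
  if (is.null(sf)) sf <- size_factors(counts)
  list(normalized = sweep(counts, 2, sf, "/"), size_factors = sf)
}

#' Transcripts per million
#'
#' Length-normalized rates scaled so that every column sums to one million.
#'
#' @inheritParams size_factors
#' @param lengths Feature lengths in nt, aligned with the matrix rows.
#' @return TPM matrix.
#' @export
tpm <- function(counts, lengths) {
  if (length(lengths) != nrow(counts)) stop("lengths must match rows of counts")
  rate <- counts / (lengths / 1000)
  sweep(rate, 2, colSums(rate), "/") * 1e6
}

# Moment estimate of NB dispersion per gene from normalized counts with
# group-mean centering, shrunk toward a 1/mean trend fitted across genes.
estimate_dispersion <- function(norm, genotype, weight = 0.5, floor = 1e-4) {
  groups <- split(seq_along(genotype), genotype)
  n <- ncol(norm)
  k <- length(groups)
  resid2 <- matrix(0, nrow(norm), n)
  for (g in groups) {
    m <- rowMeans(norm[, g, drop = FALSE])
    resid2[, g] <- (norm[, g, drop = FALSE] - m)^2
  }
  s2 <- rowSums(resid2) / (n - k)
  mbar <- rowMeans(norm)
  raw <- (s2 - mbar) / pmax(mbar, 1e-8)^2
  # trend: phi ~ a + b/mean, robust to the raw estimator's heavy tail
  ok <- mbar > 0 & is.finite(raw)
  fit <- try(stats::lm(raw[ok] ~ I(1 / mbar[ok])), silent = TRUE)
  if (inherits(fit, "try-error")) {
    trend <- rep(stats::median(pmax(raw[ok], 0)), length(mbar))
  } else {
    cf <- pmax(stats::coef(fit), 0)
    trend <- cf[1] + cf[2] / pmax(mbar, 1e-8)
  }
  pmax(weight * pmax(raw, 0) + (1 - weight) * trend, floor)
}

#' Negative binomial Wald test for differential expression
#'
#' A minimal DE engine: median-of-ratios normalization, per-gene
#' moment-based dispersion shrunk toward a mean-dispersion trend, a Wald
#' test on the log2 fold change of group means (null vs control), and
#' Benjamini-Hochberg adjustment. The default significance threshold is
#' Q < 0.1, the value used for the blastocyst contrasts; Q < 0.05 is the
#' conventional alternative.
#'
#' @param counts Raw gene x sample count matrix (filtered).
#' @param genotype Character vector over samples, values `"null"` /
#'   `"control"`.
#' @param sf Optional size factors.
#' @param q_threshold Adjusted p-value threshold for `called`.
#' @param shrink_weight Weight of the per-gene raw dispersion estimate
#'   against the trend (default 0.5).
#' @param dispersion_floor Lower bound for the working dispersion.
#' @return data.frame of class `de_result`: `gene_id`, `log2fc`, `p`, `q`,
#'   `mean_norm_expr`, `called`, `passed_filter`.
#' @export
de_test <- function(counts, genotype, sf = NULL, q_threshold = 0.1,
                    shrink_weight = 0.5, dispersion_floor = 1e-4) {
  genotype <- as.character(genotype)
  if (!all(genotype %in% c("null", "control")))
    stop("genotype must be 'null' or 'control'")
  if (min(table(genotype)) < 2) stop("need >= 2 samples per group")
  nm <- normalize_counts(counts, sf)
  y <- nm$normalized
  inv_sf <- 1 / nm$size_factors
  j1 <- genotype == "null"; j0 <- genotype == "control"
  n1 <- sum(j1); n0 <- sum(j0)
  m1 <- rowMeans(y[, j1, drop = FALSE])
  m0 <- rowMeans(y[, j0, drop = FALSE])
  phi <- estimate_dispersion(y, genotype, weight = shrink_weight,
                             floor = dispersion_floor)
  eps <- 0.25
  lfc <- log2((m1 + eps) / (m0 + eps))
  # var of a group mean of normalized NB counts: (mu * mean(1/sf) + phi mu^2)/n
  v1 <- (pmax(m1, eps) * mean(inv_sf[j1]) + phi * m1^2) / n1
  v0 <- (pmax(m0, eps) * mean(inv_sf[j0]) + phi * m0^2) / n0
  se <- sqrt(v1 / pmax(m1 + eps, eps)^2 + v0 / pmax(m0 + eps, eps)^2) / log(2)
  z <- lfc / se
  p <- 2 * stats::pnorm(-abs(z))
  p[m1 == m0] <- 1
  q <- stats::p.adjust(p, method = "BH")
  res <- data.frame(gene_id = rownames(counts), log2fc = lfc, p = p, q = q,
                    mean_norm_expr = rowMeans(y),
                    called = q < q_threshold,
                    passed_filter = TRUE,
                    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  class(res) <- c("de_result", "data.frame")
  res
}

#' Marker-set expression ratio between genotypes
#'
#' For each gene in a marker set, the ratio of mean normalized expression in
#' null over control samples; the set is summarized as mean +/- sem with a
#' two-tailed one-sample t-test against 1. Ratios below one indicate lower
#' expression in null samples. A two-set comparison variant tests the ratio
#' distributions of two sets against each other.
#'
#' @param norm Normalized gene x sample matrix.
#' @param gene_set Character vector of gene ids.
#' @param genotype Genotype vector over samples.
#' @param other_set Optional second gene set; when given, a two-sample
#'   t-test between the two sets' per-gene ratios is also reported.
#' @return List with `ratios` (per-gene), `mean`, `sem`, `p` (t-test vs 1),
#'   `n`, `excluded` (genes with control mean 0), and optionally
#'   `p_between`.
#' @export
marker_set_ratio <- function(norm, gene_set, genotype, other_set = NULL) {
  set_ratios <- function(genes) {
    genes <- intersect(genes, rownames(norm))
    if (length(genes) == 0L) stop("gene set has empty intersection with matrix")
    m1 <- rowMeans(norm[genes, genotype == "null", drop = FALSE])
    m0 <- rowMeans(norm[genes, genotype == "control", drop = FALSE])
    excluded <- genes[m0 == 0]
    if (length(excluded))
      message("excluding ", length(excluded), " gene(s) with zero control mean")
    keep <- m0 > 0
    list(r = (m1 / m0)[keep], excluded = excluded)
  }
  a <- set_ratios(gene_set)
  r <- a$r
  tt <- if (length(r) >= 2 && stats::sd(r) > 0)
    stats::t.test(r, mu = 1)$p.value else NA_real_
  out <- list(ratios = r, mean = mean(r),
              sem = stats::sd(r) / sqrt(length(r)),
              p = tt, n = length(r), excluded = a$excluded)
  if (!is.null(other_set)) {
    b <- set_ratios(other_set)
    out$p_between <- stats::t.test(r, b$r)$p.value
    out$other_mean <- mean(b$r)
  }
  out
}
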