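#' Per-gene log2 fold change versus the baseline stage
#'
#' LFC = log2((mean stage expression + eps) / (mean baseline expression +
#' eps)), computed from per-gene stage means over cells, pooled across
#' lineages (`lineage = "all"`) and per lineage. A lineage absent at a
#' stage yields missing values, not failure.
#'
#' @param expr A `stage_expression` object (see [simulate_stage_matrix()] /
#'   [read_stage_matrix()]).
#' @param baseline_stage Baseline stage (default the object's baseline).
#' @param eps Pseudo-value guarding zero means (default 1e-3).
#' @param by_lineage Also compute per-lineage LFCs (default TRUE).
#' @return Long data.frame: `gene_id`, `stage`, `lineage`, `lfc`.
#' @export
lfc_vs_baseline <- function(expr, baseline_stage = expr$baseline, eps = 1e-3,
                            by_lineage = TRUE) {
  cells <- expr$cells
  if (!(baseline_stage %in% cells$stage))
    stop("baseline stage absent from data: ", baseline_stage)
  lineages <- "all"
  if (by_lineage) lineages <- c("all", unique(cells$lineage))
  out <- list()
  for (lin in lineages) {
    sel_lin <- if (lin == "all") rep(TRUE, nrow(cells)) else cells$lineage == lin
    base_cells <- cells$cell_id[sel_lin & cells$stage == baseline_stage]
    if (length(base_cells) == 0L) next
    m0 <- rowMeans(expr$matrix[, base_cells, drop = FALSE])
    for (st in expr$stages) {
      sc <- cells$cell_id[sel_lin & cells$stage == st]
      if (length(sc) == 0L) next
      m <- rowMeans(expr$matrix[, sc, drop = FALSE])
      out[[length(out) + 1L]] <- data.frame(
        gene_id = rownames(expr$matrix), stage = st, lineage = lin,
        lfc = log2((m + eps) / (m0 + eps)), stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Gene-set LFC trajectory with stage-wise tests
#'
#' Summarizes a gene set's LFC distribution per stage and lineage (mean,
#' sem) and tests it against zero with a two-tailed one-sample t-test,
#' Bonferroni-adjusted over the non-baseline stages within each lineage.
#' Genes absent from the LFC table are dropped (and counted in `n_genes`).
#'
#' @param lfc Long LFC table from [lfc_vs_baseline()].
#' @param gene_set Character vector of gene ids.
#' @param set_name Label stored in the output.
#' @param baseline_stage Stage to treat as reference (tests are skipped
#'   there).
#' @param alpha Significance level applied to the Bonferroni-adjusted p.
#' @return data.frame of class `magnitude_result`: `set`, `stage`,
#'   `lineage`, `n_genes`, `mean_lfc`, `sem`, `p`, `p_adj`, `significant`.
#' @export
gene_set_trajectory <- function(lfc, gene_set, set_name = "set",
                                baseline_stage = NULL, alpha = 0.05) {
  sub <- lfc[lfc$gene_id %in% gene_set, , drop = FALSE]
  if (nrow(sub) == 0L) stop("gene set absent from LFC table")
  if (is.null(baseline_stage)) {
    # the baseline is the stage where every gene's pooled LFC is exactly 0
    agg <- stats::aggregate(lfc ~ stage, data = sub[sub$lineage == "all", ],
                            function(x) all(x == 0))
    baseline_stage <- if (any(agg$lfc)) agg$stage[which(agg$lfc)[1]] else NA
  }
  sp <- split(sub, list(sub$stage, sub$lineage), drop = TRUE)
  rows <- lapply(sp, function(d) {
    x <- d$lfc[is.finite(d$lfc)]
    p <- if (length(x) >= 2 && stats::sd(x) > 0 &&
             !identical(d$stage[1], baseline_stage))
      stats::t.test(x, mu = 0)$p.value else NA_real_
    data.frame(set = set_name, stage = d$stage[1], lineage = d$lineage[1],
               n_genes = length(x), mean_lfc = mean(x),
               sem = stats::sd(x) / sqrt(length(x)), p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  # Bonferroni family: tested (non-baseline) stages within each lineage
  out$p_adj <- NA_real_
  for (lin in unique(out$lineage)) {
    i <- out$lineage == lin & !is.na(out$p)
    out$p_adj[i] <- pmin(out$p[i] * sum(i), 1)
  }
  out$significant <- !is.na(out$p_adj) & out$p_adj < alpha
  out <- out[order(out$lineage, match(out$stage, unique(lfc$stage))), ]
  rownames(out) <- NULL
  class(out) <- c("magnitude_result", "data.frame")
  out
}

#' Two-sample Kolmogorov-Smirnov D statistic
#'
#' Supremum absolute difference between the two empirical CDFs, evaluated
#' at the pooled sample points (exact under ties).
#'
#' @param x,y Numeric samples.
#' @return D in `[0, 1]`.
#' @export
ks_d <- function(x, y) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (!length(x) || !length(y)) stop("empty sample")
  pts <- sort(unique(c(x, y)))
  Fx <- stats::ecdf(x)(pts)
  Fy <- stats::ecdf(y)(pts)
  max(abs(Fx - Fy))
}

#' Distribution shift of a gene set between a stage and baseline
#'
#' Computes the KS D statistic between the per-gene mean expression values
#' of a gene set at `stage` versus the baseline stage, the same for a
#' reference set (e.g. all RNA-binding proteins), and their ratio - the
#' differential D statistic D(set)/D(reference). Also returns the CDF table
#' for plotting.
#'
#' @param expr A `stage_expression` object.
#' @param gene_set,reference_set Character vectors of gene ids.
#' @param stage Stage to compare against baseline.
#' @param baseline_stage Baseline stage.
#' @param lineage Lineage restriction (`"all"` pools every cell).
#' @return List with `ks_d`, `ks_d_reference`, `differential_d` (`NA` with
#'   a flag when the reference D is 0), and `cdf` (long data.frame of
#'   values per set and stage).
#' @export
ks_shift <- function(expr, gene_set, reference_set, stage,
                     baseline_stage = expr$baseline, lineage = "all") {
  cells <- expr$cells
  sel <- if (lineage == "all") rep(TRUE, nrow(cells)) else
    cells$lineage == lineage
  vals <- function(genes, st) {
    genes <- intersect(genes, rownames(expr$matrix))
    if (!length(genes)) stop("gene set absent from matrix")
    cc <- cells$cell_id[sel & cells$stage == st]
    if (!length(cc)) stop("no cells at stage ", st)
    rowMeans(expr$matrix[genes, cc, drop = FALSE])
  }
  s1 <- vals(gene_set, stage); s0 <- vals(gene_set, baseline_stage)
  r1 <- vals(reference_set, stage); r0 <- vals(reference_set, baseline_stage)
  d_set <- ks_d(s1, s0)
  d_ref <- ks_d(r1, r0)
  dd <- if (d_ref == 0) NA_real_ else d_set / d_ref
  cdf <- rbind(
    data.frame(set = "gene_set", stage = stage, value = s1),
    data.frame(set = "gene_set", stage = baseline_stage, value = s0),
    data.frame(set = "reference", stage = stage, value = r1),
    data.frame(set = "reference", stage = baseline_stage, value = r0))
  rownames(cdf) <- NULL
  list(ks_d = d_set, ks_d_reference = d_ref, differential_d = dd,
       reference_d_zero = d_ref == 0, cdf = cdf)
}

#' Fraction of a gene set downregulated between two stages
#'
#' Fraction of set genes whose LFC decreases from `from_stage` to
#' `to_stage` (strictly negative change).
#'
#' @param lfc Long LFC table from [lfc_vs_baseline()].
#' @param gene_set Character vector of gene ids (nonempty intersection
#'   required).
#' @param from_stage,to_stage Stage window.
#' @param lineage Lineage (default `"all"`).
#' @return Fraction in `[0, 1]`.
#' @export
fraction_downregulated <- function(lfc, gene_set, from_stage, to_stage,
                                   lineage = "all") {
  a <- lfc[lfc$lineage == lineage & lfc$stage == from_stage &
             lfc$gene_id %in% gene_set, , drop = FALSE]
  b <- lfc[lfc$lineage == lineage & lfc$stage == to_stage &
             lfc$gene_id %in% gene_set, , drop = FALSE]
  if (nrow(a) == 0L || nrow(b) == 0L) stop("empty gene set or missing stage")
  d <- b$lfc[match(a$gene_id, b$gene_id)] - a$lfc
  mean(d < 0, na.rm = TRUE)
}

#' Dot-plot summary of a gene set
#'
#' Per gene and stage: mean expression and the fraction of cells with
#' detectable (nonzero) expression - the two aesthetics of a dot plot.
#'
#' @param expr A `stage_expression` object.
#' @param gene_set Character vector of gene ids.
#' @return data.frame: `gene_id`, `stage`, `mean_expr`, `fraction_detected`.
#' @export
dotplot_summary <- function(expr, gene_set) {
  genes <- intersect(gene_set, rownames(expr$matrix))
  rows <- list()
  for (st in expr$stages) {
    cc <- expr$cells$cell_id[expr$cells$stage == st]
    m <- expr$matrix[genes, cc, drop = FALSE]
    rows[[st]] <- data.frame(gene_id = genes, stage = st,
                             mean_expr = rowMeans(m),
                             fraction_detected = rowMeans(m > 0),
                             stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Gene-set trajectory on a protein time course
#'
#' Reuses the LFC/trajectory machinery with time points in place of stages
#' and replicates in place of cells. Proteins in the set but absent from
#' the matrix are skipped with a message.
#'
#' @param protein Matrix protein (rows, named by gene) x sample.
#' @param timepoint Vector over samples giving the ordered time point of
#'   each column; the first (baseline) time point must be present.
#' @param gene_set Character vector of gene ids.
#' @param baseline Baseline time point (default the first unique value).
#' @param set_name Label for the output.
#' @param alpha Significance level.
#' @return A `magnitude_result` data.frame (lineage fixed at `"all"`).
#' @export
protein_trajectory <- function(protein, timepoint, gene_set,
                               baseline = unique(timepoint)[1],
                               set_name = "protein_set", alpha = 0.05) {
  timepoint <- as.character(timepoint)
  missing <- setdiff(gene_set, rownames(protein))
  if (length(missing))
    message("skipping ", length(missing), " set gene(s) absent from matrix")
  expr <- structure(list(
    matrix = protein,
    cells = data.frame(cell_id = colnames(protein), stage = timepoint,
                       lineage = "all", stringsAsFactors = FALSE),
    stages = unique(timepoint), baseline = as.character(baseline)),
    class = "stage_expression")
  lfc <- lfc_vs_baseline(expr, by_lineage = FALSE)
  gene_set_trajectory(lfc, intersect(gene_set, rownames(protein)),
                      set_name = set_name,
                      baseline_stage = as.character(baseline), alpha = alpha)
}
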