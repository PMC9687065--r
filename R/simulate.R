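#' Simulation parameters for the synthetic blastocyst world
#'
#' Defines the stated world for the synthetic data generator: a two-genotype
#' bulk RNA-seq design (null vs control), per-gene transcription (`alpha`)
#' and decay (`beta`) rates under a steady-state model in which mature mRNA
#' abundance is `alpha/beta` and pre-mRNA abundance is `alpha/gamma`, with
#' planted decay-rate reductions (NMD targets), planted NMD-inducing
#' transcript features, planted isoform switches and a prior target list.
#'
#' @param n_genes Number of simulated genes.
#' @param n_targets Number of planted NMD targets (decay rate multiplied by
#'   `stabilization_factor` in null samples).
#' @param feedback_fraction Fraction of planted targets whose transcription
#'   rate is also reduced in null samples so the mature steady state is
#'   unchanged (transcriptional feedback: stabilized but not upregulated).
#' @param n_switch_genes Number of genes with a planted isoform switch
#'   toward an NMD-sensitive (dEJ-bearing) isoform in null samples.
#' @param n_factors Number of genes acting as NMD factors in the
#'   stage-trajectory world.
#' @param isoforms_per_gene,exon_count_range,exon_length_range,intron_length_range
#'   Integer ranges controlling transcript geometry (exon lengths are
#'   emergent for feature-planted genes; introns are drawn from
#'   `intron_length_range`).
#' @param utr5_length_range,utr3_length_range,long_utr3_length UTR geometry
#'   (nt); planted long-3'UTR genes receive `long_utr3_length`-scale 3'
#'   UTRs, well clear of twice the background median.
#' @param alpha_meanlog,alpha_sdlog Log-normal law of the transcription rate.
#' @param beta,beta_sdlog Baseline decay rate and its log-normal spread.
#' @param gamma Pre-mRNA processing rate (constant across genes).
#' @param stabilization_factor Multiplier applied to `beta` in null samples
#'   for planted targets; 0.5 halves decay, doubling mature abundance.
#' @param dispersion Negative binomial dispersion of simulated counts.
#' @param depth,intron_depth Expected total exonic / intronic library size
#'   per sample.
#' @param n_null,n_control Sample sizes (defaults 8 vs 11, the blastocyst
#'   design).
#' @param dej_rate_targets,uorf_rate_targets,long_utr3_rate_targets
#'   Per-feature planting probabilities for target genes.
#' @param background_dej_rate Fraction of background genes that carry a dEJ
#'   without being NMD-sensitive (default 0.17, the annotation-wide rate).
#' @param background_uorf_rate,background_long_utr3_rate Background feature
#'   rates.
#' @param prior_target_rate,prior_background_rate Probability that a target
#'   / background gene appears in the prior published target list.
#' @param seed RNG seed; all generators are deterministic given the seed.
#' @return A validated list of class `sim_params`.
#' @export
sim_params <- function(n_genes = 2000L,
                       n_targets = 100L,
                       feedback_fraction = 0.1,
                       n_switch_genes = 20L,
                       n_factors = 12L,
                       isoforms_per_gene = c(1L, 2L),
                       exon_count_range = c(1L, 6L),
                       exon_length_range = c(120L, 300L),
                       intron_length_range = c(300L, 1500L),
                       utr5_length_range = c(30L, 120L),
                       utr3_length_range = c(60L, 350L),
                       long_utr3_length = 1200L,
                       alpha_meanlog = log(20), alpha_sdlog = 0.7,
                       beta = 1, beta_sdlog = 0.3,
                       gamma = 5,
                       stabilization_factor = 0.5,
                       dispersion = 0.2,
                       depth = 2e6, intron_depth = 5e5,
                       n_null = 8L, n_control = 11L,
                       dej_rate_targets = 0.6,
                       uorf_rate_targets = 0.3,
                       long_utr3_rate_targets = 0.25,
                       background_dej_rate = 0.17,
                       background_uorf_rate = 0.05,
                       background_long_utr3_rate = 0.02,
                       prior_target_rate = 0.4,
                       prior_background_rate = 0.02,
                       seed = 1L) {
  p <- as.list(environment())
  if (p$n_genes < 1) stop("n_genes must be >= 1")
  if (p$n_targets + p$n_switch_genes + p$n_factors > p$n_genes)
    stop("planted gene classes exceed n_genes")
  if (!(p$stabilization_factor > 0 && p$stabilization_factor < 1))
    stop("stabilization_factor must be in (0, 1)")
  if (p$feedback_fraction < 0 || p$feedback_fraction > 1)
    stop("feedback_fraction must be in [0, 1]")
  if (p$beta <= 0 || p$gamma <= 0) stop("rates must be > 0")
  if (p$dispersion < 0) stop("dispersion must be >= 0")
  if (p$n_null < 2 || p$n_control < 2) stop("need >= 2 samples per genotype")
  structure(p, class = "sim_params")
}

rand_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Random coding codons (no stop); optionally no ATG either.
rand_codons <- function(n, no_atg = FALSE) {
  bases <- c("A", "C", "G", "T")
  all_codons <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  pool <- setdiff(all_codons, STOP_CODONS)
  if (no_atg) pool <- setdiff(pool, "ATG")
  paste(sample(pool, n, replace = TRUE), collapse = "")
}

scrub_atg <- function(s) gsub("ATG", "CTG", s, fixed = TRUE)

# sample() without the length-1 surprise
sample_vec <- function(x, k) x[sample.int(length(x), k)]

#' Simulate a toy transcript annotation with planted NMD features
#'
#' Emits multi- and single-exon gene models with transcript sequences and a
#' ground-truth table. Geometry guarantees every planted feature under the
#' package's detection rules (dEJ transcripts place the stop codon more than
#' 50 nt upstream of the last junction) and avoids incidental features in
#' background genes by construction: stop codons of non-dEJ transcripts lie
#' in the last exon, 5' UTRs of non-uORF transcripts are ATG-free, and
#' background 3' UTR lengths stay below twice the annotation median.
#' Planted isoform-switch genes receive a second, dEJ-bearing isoform
#' (extra 3' exon); a fraction of other genes receive an alternative-TSS
#' second isoform.
#'
#' @param params A [sim_params()] object.
#' @return A list with elements `models` ([transcript_models]), `sequences`
#'   (named [Biostrings::DNAStringSet] of transcript sequences) and `truth`
#'   (the ground-truth data.frame; one row per gene).
#' @export
simulate_annotation <- function(params = sim_params()) {
  stopifnot(inherits(params, "sim_params"))
  if (params$exon_count_range[2] < 2 &&
      (params$dej_rate_targets > 0 || params$background_dej_rate > 0 ||
       params$n_switch_genes > 0))
    stop("impossible geometry: a dEJ requires a multi-exon transcript, ",
         "but exon_count_range forbids more than one exon")
  set.seed(params$seed)
  n <- params$n_genes
  gid <- sprintf("g%04d", seq_len(n))

  idx <- sample(n)
  target_idx <- idx[seq_len(params$n_targets)]
  switch_idx <- idx[params$n_targets + seq_len(params$n_switch_genes)]
  factor_idx <- idx[params$n_targets + params$n_switch_genes +
                      seq_len(params$n_factors)]
  is_target <- seq_len(n) %in% target_idx
  is_switch <- seq_len(n) %in% switch_idx
  feedback <- is_target & (stats::runif(n) < params$feedback_fraction)

  p_dej <- ifelse(is_target, params$dej_rate_targets, params$background_dej_rate)
  p_uorf <- ifelse(is_target, params$uorf_rate_targets, params$background_uorf_rate)
  p_long <- ifelse(is_target, params$long_utr3_rate_targets,
                   params$background_long_utr3_rate)
  planted_dej <- stats::runif(n) < p_dej
  planted_dej[is_switch] <- FALSE      # switch genes keep a clean major isoform
  planted_uorf <- stats::runif(n) < p_uorf
  planted_long <- stats::runif(n) < p_long
  planted_long[is_switch] <- FALSE
  in_prior <- stats::runif(n) < ifelse(is_target, params$prior_target_rate,
                                       params$prior_background_rate)
  traj <- ifelse(is_target, "target",
                 ifelse(seq_len(n) %in% factor_idx, "factor", "background"))

  second_iso <- is_switch | (stats::runif(n) < 0.15)
  min_gap <- 30L

  tx_rows <- list(); ex_rows <- list(); seq_list <- list()
  for (g in seq_len(n)) {
    # --- transcript composition (transcript coordinates) ---
    u <- sample(params$utr5_length_range[1]:params$utr5_length_range[2], 1)
    if (planted_uorf[g]) u <- max(u, 60L)
    ncod <- sample(60:200, 1)
    orf_len <- 3L * ncod
    cds_start <- u; cds_end <- u + orf_len
    if (planted_long[g]) {
      t3 <- params$long_utr3_length + sample(0:200, 1)
    } else if (is_switch[g]) {
      t3 <- sample(60:120, 1)
    } else {
      t3 <- sample(params$utr3_length_range[1]:params$utr3_length_range[2], 1)
    }
    if (planted_dej[g]) t3 <- max(t3, 200L)
    L <- u + orf_len + t3

    # --- exon structure via junction positions ---
    if (planted_dej[g]) {
      n_ex <- sample(2:max(2, params$exon_count_range[2]), 1)
      d <- sample(60:min(150L, t3 - 50L), 1)
      last_j <- cds_end + d                      # stop sits d nt before last junction
      grid <- seq(2L * min_gap, cds_end - min_gap, by = min_gap)
      extra <- sort(sample_vec(grid, min(n_ex - 2L, length(grid))))
      junctions <- c(extra, last_j)
    } else {
      n_ex <- sample(params$exon_count_range[1]:params$exon_count_range[2], 1)
      grid <- seq(2L * min_gap, cds_end - min_gap, by = min_gap)
      junctions <- if (n_ex > 1L)
        sort(sample_vec(grid, min(n_ex - 1L, length(grid)))) else integer(0)
    }
    widths <- diff(c(0L, junctions, L))

    # --- genomic layout (one locus per gene) ---
    strand <- sample(c("+", "-"), 1)
    introns <- if (length(widths) > 1L)
      sample(params$intron_length_range[1]:params$intron_length_range[2],
             length(widths) - 1L, replace = TRUE) else integer(0)
    gstart <- 5000L   # leaves room for an upstream extra exon on '-' strands
    # transcript-order widths laid out 5'->3'; for '-' strand the first
    # transcript exon is the genomically last one
    w_geno <- if (strand == "-") rev(widths) else widths
    i_geno <- if (strand == "-") rev(introns) else introns
    starts <- gstart + cumsum(c(0L, utils::head(w_geno, -1L) + i_geno))
    ends <- starts + w_geno
    chrom <- paste0("chr_", gid[g])

    # --- sequence ---
    utr5 <- scrub_atg(rand_seq(u))
    if (planted_uorf[g]) {
      k <- sample(4:6, 1)                        # uORF codons incl. stop
      useq <- paste0("ATG", rand_codons(k - 2L, no_atg = TRUE),
                     sample(STOP_CODONS, 1))
      pos <- sample(0:(u - nchar(useq)), 1)      # 0-based insert offset
      utr5 <- paste0(substr(utr5, 1, pos), useq,
                     substr(utr5, pos + nchar(useq) + 1L, u))
    }
    orf <- paste0("ATG", rand_codons(ncod - 2L), sample(STOP_CODONS, 1))
    utr3 <- rand_seq(t3)
    seq1 <- paste0(utr5, orf, utr3)

    t1 <- paste0(gid[g], ".t1")
    tx_rows[[length(tx_rows) + 1L]] <- data.frame(
      transcript_id = t1, gene_id = gid[g], chrom = chrom, strand = strand,
      cds_start = cds_start, cds_end = cds_end, stringsAsFactors = FALSE)
    ex_rows[[length(ex_rows) + 1L]] <- data.frame(
      transcript_id = t1, chrom = chrom, start = starts, end = ends,
      strand = strand, stringsAsFactors = FALSE)
    seq_list[[t1]] <- seq1

    if (second_iso[g]) {
      t2 <- paste0(gid[g], ".t2")
      if (is_switch[g]) {
        # NMD-sensitive isoform: extra 3' exon places a junction >50 nt
        # downstream of the (unchanged) stop codon
        we <- sample(150:250, 1)
        gap <- sample(params$intron_length_range[1]:params$intron_length_range[2], 1)
        if (strand == "+") {
          s2 <- c(starts, max(ends) + gap); e2 <- c(ends, max(ends) + gap + we)
        } else {
          s2 <- c(min(starts) - gap - we, starts); e2 <- c(min(starts) - gap, ends)
        }
        seq2 <- paste0(seq1, rand_seq(we))
        cs2 <- cds_start; ce2 <- cds_end
      } else {
        # alternative TSS: first transcript exon shortened by k nt
        k <- sample(10:max(10L, min(u - 10L, 40L)), 1)
        s2 <- starts; e2 <- ends
        if (strand == "+") s2[1] <- s2[1] + k else e2[length(e2)] <- e2[length(e2)] - k
        seq2 <- substr(seq1, k + 1L, L)
        cs2 <- cds_start - k; ce2 <- cds_end - k
      }
      tx_rows[[length(tx_rows) + 1L]] <- data.frame(
        transcript_id = t2, gene_id = gid[g], chrom = chrom, strand = strand,
        cds_start = cs2, cds_end = ce2, stringsAsFactors = FALSE)
      ex_rows[[length(ex_rows) + 1L]] <- data.frame(
        transcript_id = t2, chrom = chrom, start = s2, end = e2,
        strand = strand, stringsAsFactors = FALSE)
      seq_list[[t2]] <- seq2
    }
  }

  models <- transcript_models(do.call(rbind, tx_rows), do.call(rbind, ex_rows))
  seqs <- Biostrings::DNAStringSet(unlist(seq_list))
  truth <- data.frame(
    gene_id = gid,
    is_planted_target = is_target,
    has_feedback = feedback,
    planted_dej = planted_dej,
    planted_uorf = planted_uorf,
    planted_long3utr = planted_long,
    planted_switch = ifelse(is_switch, paste0(gid, ".t2"), NA_character_),
    in_prior_list = in_prior,
    trajectory_class = traj,
    stringsAsFactors = FALSE)
  list(models = models, sequences = seqs, truth = truth, params = params)
}

rnb <- function(n, mu, dispersion) {
  if (dispersion <= 0) stats::rpois(n, mu) else
    stats::rnbinom(n, mu = mu, size = 1 / dispersion)
}

# Gene-level exonic length (union of exons over isoforms) and intronic
# length (gene span minus exonic union).
gene_lengths_from_models <- function(models) {
  ex <- models$exons
  gene_of <- models$transcripts$gene_id[match(ex$transcript_id,
                                              models$transcripts$transcript_id)]
  sp <- split(ex, gene_of)
  res <- lapply(sp, function(e) {
    ir <- IRanges::reduce(IRanges::IRanges(e$start + 1L, e$end))
    exl <- sum(IRanges::width(ir))
    span <- max(e$end) - min(e$start)
    data.frame(exonic_length = exl, intronic_length = span - exl)
  })
  out <- do.call(rbind, res)
  cbind(data.frame(gene_id = names(sp), stringsAsFactors = FALSE), out)
}

#' Simulate exonic and intronic count matrices
#'
#' Draws negative binomial counts under the steady-state model: mature mRNA
#' abundance is `alpha/beta`, pre-mRNA abundance `alpha/gamma`. Expected
#' exonic counts are proportional to mature abundance times exonic length,
#' expected intronic counts to pre-mRNA abundance times intronic length,
#' each scaled to its library depth. In null samples, planted targets have
#' `beta` multiplied by `stabilization_factor`; feedback targets also scale
#' `alpha` by the same factor so the mature steady state (hence exonic
#' counts) is unchanged while pre-mRNA drops. Intron-less genes receive
#' intronic count 0 and are flagged unusable for stability inference.
#'
#' @param sim Output of [simulate_annotation()], or a [transcript_models]
#'   object (then `truth` and `params` must be given).
#' @param truth,params Ground-truth table and [sim_params()]; defaulted from
#'   `sim`.
#' @return A `count_tables` object: list with integer matrices `exonic` and
#'   `intronic` (gene x sample), `samples` (data.frame `sample_id`,
#'   `genotype`), `gene_lengths`, and `has_intron`.
#' @export
simulate_counts <- function(sim, truth = sim$truth, params = sim$params) {
  models <- if (inherits(sim, "transcript_models")) sim else sim$models
  stopifnot(inherits(params, "sim_params"))
  gl <- gene_lengths_from_models(models)
  if (!all(gl$gene_id %in% truth$gene_id))
    stop("truth table does not cover all genes")
  gl <- gl[match(truth$gene_id, gl$gene_id), , drop = FALSE]
  set.seed(params$seed + 1L)
  n <- nrow(truth)
  alpha <- stats::rlnorm(n, params$alpha_meanlog, params$alpha_sdlog)
  beta <- params$beta * stats::rlnorm(n, 0, params$beta_sdlog)
  gamma <- rep(params$gamma, n)
  sf <- params$stabilization_factor

  group_expect <- function(genotype) {
    b <- beta; a <- alpha
    if (genotype == "null") {
      b[truth$is_planted_target] <- b[truth$is_planted_target] * sf
      a[truth$has_feedback] <- a[truth$has_feedback] * sf
    }
    mature <- a / b; pre <- a / gamma
    mu_ex <- params$depth * mature * gl$exonic_length /
      sum(mature * gl$exonic_length)
    w_in <- pre * gl$intronic_length
    mu_in <- ifelse(gl$intronic_length > 0,
                    params$intron_depth * w_in / sum(w_in), 0)
    list(ex = mu_ex, int = mu_in)
  }
  mu_null <- group_expect("null"); mu_ctrl <- group_expect("control")

  ids <- c(sprintf("null_%02d", seq_len(params$n_null)),
           sprintf("ctrl_%02d", seq_len(params$n_control)))
  genotype <- rep(c("null", "control"), c(params$n_null, params$n_control))
  draw <- function(mu_n, mu_c) {
    m <- vapply(seq_along(ids), function(j) {
      mu <- if (genotype[j] == "null") mu_n else mu_c
      rnb(n, mu, params$dispersion)
    }, numeric(n))
    dimnames(m) <- list(truth$gene_id, ids)
    storage.mode(m) <- "integer"
    m
  }
  structure(list(
    exonic = draw(mu_null$ex, mu_ctrl$ex),
    intronic = draw(mu_null$int, mu_ctrl$int),
    samples = data.frame(sample_id = ids, genotype = genotype,
                         stringsAsFactors = FALSE),
    gene_lengths = gl,
    has_intron = stats::setNames(gl$intronic_length > 0, gl$gene_id),
    expected = list(null = mu_null, control = mu_ctrl)),
    class = "count_tables")
}

#' @export
print.count_tables <- function(x, ...) {
  cat(sprintf("count_tables: %d genes x %d samples (%d null, %d control)\n",
              nrow(x$exonic), ncol(x$exonic),
              sum(x$samples$genotype == "null"),
              sum(x$samples$genotype == "control")))
  invisible(x)
}

#' Simulate per-isoform TPM quantifications
#'
#' Two-isoform genes have isoform fractions (0.8, 0.2) in both genotypes
#' except planted switch genes, whose NMD-sensitive second isoform rises
#' from IF 0.2 in control to 0.6 in null samples. Per-isoform reads are
#' drawn negative binomially around gene expression times isoform fraction
#' and converted to TPM.
#'
#' @inheritParams simulate_counts
#' @param switch_if Isoform fraction of the planted switch isoform in
#'   control and null samples (default `c(0.2, 0.6)`).
#' @param minor_if Isoform fraction of the second isoform in non-switch
#'   two-isoform genes.
#' @param iso_depth Expected reads per sample for the isoform layer.
#' @return A list with `tpm` (isoform x sample matrix), `map` (data.frame
#'   `isoform_id`, `gene_id`) and `samples`.
#' @export
simulate_isoform_tpm <- function(sim, truth = sim$truth, params = sim$params,
                                 switch_if = c(0.2, 0.6), minor_if = 0.2,
                                 iso_depth = 1e6) {
  models <- sim$models
  set.seed(params$seed + 2L)
  tx <- models$transcripts
  n_tx <- nrow(tx)
  gene_n_iso <- table(tx$gene_id)
  alpha <- stats::rlnorm(nrow(truth), params$alpha_meanlog, params$alpha_sdlog)
  gene_mu <- iso_depth * alpha / sum(alpha)
  names(gene_mu) <- truth$gene_id

  ids <- c(sprintf("null_%02d", seq_len(params$n_null)),
           sprintf("ctrl_%02d", seq_len(params$n_control)))
  genotype <- rep(c("null", "control"), c(params$n_null, params$n_control))

  if_of <- function(txrow, genotype) {
    g <- tx$gene_id[txrow]
    if (gene_n_iso[[g]] == 1L) return(1)
    sw <- truth$planted_switch[match(g, truth$gene_id)]
    second <- grepl("\\.t2$", tx$transcript_id[txrow])
    if (!is.na(sw)) {
      p2 <- if (genotype == "null") switch_if[2] else switch_if[1]
    } else p2 <- minor_if
    if (second) p2 else 1 - p2
  }
  tpm <- matrix(0, n_tx, length(ids),
                dimnames = list(tx$transcript_id, ids))
  for (j in seq_along(ids)) {
    ifs <- vapply(seq_len(n_tx), if_of, numeric(1), genotype = genotype[j])
    mu <- gene_mu[tx$gene_id] * ifs
    counts <- rnb(n_tx, mu, params$dispersion)
    rate <- counts / (tx$length / 1000)
    tpm[, j] <- rate / sum(rate) * 1e6
  }
  list(tpm = tpm,
       map = data.frame(isoform_id = tx$transcript_id, gene_id = tx$gene_id,
                        stringsAsFactors = FALSE),
       samples = data.frame(sample_id = ids, genotype = genotype,
                            stringsAsFactors = FALSE))
}

#' Simulate a stage-by-lineage single-cell expression matrix
#'
#' Generates normalized expression for cells across developmental stages
#' and lineages with log-normal cell-level noise. Background genes are flat
#' in expectation; genes of trajectory class `target` dip by `dip_depth`
#' log2 units at the dip stage (default E5.5) in the EPI lineage only and
#' rebound afterwards; genes of class `factor` rise by `dip_depth` at the
#' dip stage (all lineages) and fall back by the following stage.
#'
#' @param truth Ground-truth table from [simulate_annotation()] (only
#'   `gene_id` and `trajectory_class` are used).
#' @param stages Ordered character vector of stages; must contain
#'   `baseline_stage` and `dip_stage`.
#' @param lineages Lineages; must contain `"EPI"`, `"PrE"`, `"TE"`.
#' @param dip_depth Magnitude of the planted shift in log2 units; must be
#'   positive.
#' @param cells_per_group Cells per stage x lineage combination.
#' @param noise_sdlog Cell-level log-normal noise (natural-log sd).
#' @param baseline_stage,dip_stage Baseline and shifted stage.
#' @param seed RNG seed.
#' @return A `stage_expression` object: list with `matrix` (gene x cell),
#'   `cells` (data.frame `cell_id`, `stage`, `lineage`), `stages`,
#'   `baseline`.
#' @export
simulate_stage_matrix <- function(truth,
                                  stages = c("E3.5", "E4.5", "E5.5", "E6.5"),
                                  lineages = c("EPI", "PrE", "TE"),
                                  dip_depth = 1,
                                  cells_per_group = 30L,
                                  noise_sdlog = 0.5,
                                  baseline_stage = "E3.5",
                                  dip_stage = "E5.5",
                                  seed = 1L) {
  if (dip_depth <= 0) stop("dip_depth must be > 0")
  if (!(baseline_stage %in% stages)) stop("stages must include the baseline stage")
  if (!all(c("EPI", "PrE", "TE") %in% lineages))
    stop("lineages must include EPI, PrE and TE")
  set.seed(seed)
  genes <- truth$gene_id
  base <- stats::rlnorm(length(genes), log(5), 0.8)
  cls <- truth$trajectory_class

  cells <- expand.grid(rep_cell = seq_len(cells_per_group),
                       lineage = lineages, stage = stages,
                       stringsAsFactors = FALSE)
  cells$cell_id <- sprintf("%s_%s_c%03d", cells$stage, cells$lineage,
                           cells$rep_cell)
  m <- matrix(0, length(genes), nrow(cells),
              dimnames = list(genes, cells$cell_id))
  for (j in seq_len(nrow(cells))) {
    shift <- numeric(length(genes))
    if (cells$stage[j] == dip_stage) {
      if (cells$lineage[j] == "EPI") shift[cls == "target"] <- -dip_depth
      shift[cls == "factor"] <- dip_depth
    }
    m[, j] <- base * 2^shift * stats::rlnorm(length(genes), 0, noise_sdlog)
  }
  structure(list(matrix = m,
                 cells = cells[, c("cell_id", "stage", "lineage")],
                 stages = stages, baseline = baseline_stage),
            class = "stage_expression")
}

#' @export
print.stage_expression <- function(x, ...) {
  cat(sprintf("stage_expression: %d genes x %d cells; stages: %s\n",
              nrow(x$matrix), ncol(x$matrix), paste(x$stages, collapse = " < ")))
  invisible(x)
}
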