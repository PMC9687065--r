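#' Default pipeline configuration
#'
#' A single configuration object holding paths, module parameters and the
#' seed; accepted by [run_pipeline()] either as a list or as a path to a
#' JSON file with the same structure.
#'
#' @param outdir Output directory for all artifacts.
#' @param seed Seed for every stochastic stage.
#' @param sim A [sim_params()] object (or list of overrides).
#' @param feature A [feature_config()].
#' @param stability A [stability_config()].
#' @param switch_filter A [switch_filter_config()].
#' @param de_q,switch_q DE and switch significance thresholds.
#' @param dip_depth Planted shift for the simulated stage matrix.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(outdir = "nmd_out", seed = 1L,
                            sim = sim_params(seed = seed),
                            feature = feature_config(),
                            stability = stability_config(),
                            switch_filter = switch_filter_config(),
                            de_q = 0.1, switch_q = 0.1, dip_depth = 1) {
  structure(list(outdir = outdir, seed = seed, sim = sim, feature = feature,
                 stability = stability, switch_filter = switch_filter,
                 de_q = de_q, switch_q = switch_q, dip_depth = dip_depth),
            class = "pipeline_config")
}

load_config <- function(config) {
  if (is.character(config)) {
    raw <- jsonlite::read_json(config, simplifyVector = TRUE)
    cfg <- pipeline_config()
    for (nm in intersect(names(raw), c("outdir", "seed", "de_q", "switch_q",
                                       "dip_depth")))
      cfg[[nm]] <- raw[[nm]]
    if (!is.null(raw$sim)) cfg$sim <- do.call(sim_params, raw$sim)
    if (!is.null(raw$feature)) cfg$feature <- do.call(feature_config, raw$feature)
    if (!is.null(raw$stability))
      cfg$stability <- do.call(stability_config, raw$stability)
    if (!is.null(raw$switch_filter))
      cfg$switch_filter <- do.call(switch_filter_config, raw$switch_filter)
    cfg$sim$seed <- cfg$seed
    return(cfg)
  }
  if (!inherits(config, "pipeline_config")) stop("invalid config")
  config
}

need_file <- function(path, producer) {
  if (!file.exists(path))
    stop("missing input ", path, "; run the '", producer,
         "' stage first", call. = FALSE)
  path
}

#' Run the NMD target-calling pipeline
#'
#' Orchestrates the stages as subcommands sharing one configuration and
#' output directory. `"simulate"` writes the synthetic annotation, counts,
#' isoform TPMs, stage matrix, truth table and gene lists; downstream
#' stages read the artifacts they need and fail with an actionable message
#' when a dependency is missing. `"all"` runs everything and writes a
#' machine-readable `summary.json` with set sizes, enrichment and
#' trajectory statistics plus provenance (package version, seed,
#' configuration echo), and precision/recall against the planted truth.
#'
#' @param step One of `"simulate"`, `"annotate"`, `"de"`, `"stability"`,
#'   `"switch"`, `"integrate"`, `"magnitude"`, `"mendel"`, `"all"`.
#' @param config A [pipeline_config()] or path to a JSON config file.
#' @return For `"all"`, the summary list (invisibly the path otherwise).
#' @export
run_pipeline <- function(step = c("all", "simulate", "annotate", "de",
                                  "stability", "switch", "integrate",
                                  "magnitude", "mendel"),
                         config = pipeline_config()) {
  step <- match.arg(step)
  cfg <- load_config(config)
  out <- cfg$outdir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  pth <- function(...) file.path(out, ...)

  if (step %in% c("simulate", "all")) {
    sim <- simulate_annotation(cfg$sim)
    write_gtf(sim$models, pth("annotation.gtf"))
    write_transcript_fasta(sim$sequences, pth("transcripts.fa"))
    write_tsv(sim$truth, pth("truth.tsv"))
    ct <- simulate_counts(sim)
    write_count_tables(ct, pth("counts"))
    iso <- simulate_isoform_tpm(sim)
    write_matrix_tsv(iso$tpm, pth("isoform_tpm.tsv"), id_col = "isoform_id")
    write_tsv(iso$map, pth("isoform_map.tsv"))
    expr <- simulate_stage_matrix(sim$truth, dip_depth = cfg$dip_depth,
                                  seed = cfg$seed)
    write_stage_matrix(expr, pth("stage"))
    write_gene_list(sim$truth$gene_id[sim$truth$in_prior_list],
                    pth("prior_targets.tsv"))
    message("simulate: ", nrow(sim$truth), " genes, ",
            sum(sim$truth$is_planted_target), " planted targets")
  }

  if (step %in% c("annotate", "all")) {
    models <- read_gtf(need_file(pth("annotation.gtf"), "simulate"))
    seqs <- read_transcript_fasta(need_file(pth("transcripts.fa"), "simulate"))
    feats <- annotate_features(models, seqs, cfg$feature)
    write_tsv(feats, pth("features_transcript.tsv"))
    write_tsv(collapse_to_gene(feats), pth("features_gene.tsv"))
    message("annotate: ", sum(feats$evaluable), "/", nrow(feats),
            " transcripts evaluable")
  }

  if (step %in% c("de", "all")) {
    ct <- read_count_tables(need_file(pth("counts"), "simulate"))
    counts <- filter_low_counts(ct$exonic)
    message("de: ", nrow(counts), "/", nrow(ct$exonic),
            " genes pass the low-count filter")
    de <- de_test(counts, ct$samples$genotype, q_threshold = cfg$de_q)
    write_tsv(de, pth("de_results.tsv"))
  }

  if (step %in% c("stability", "all")) {
    ct <- read_count_tables(need_file(pth("counts"), "simulate"))
    stab <- infer_stability(ct, cfg$stability)
    message("stability: ", sum(stab$quantifiable), "/", nrow(stab),
            " genes quantifiable; ", sum(stab$stabilized), " stabilized")
    write_tsv(stab, pth("stability_results.tsv"))
  }

  if (step %in% c("switch", "all")) {
    tpm <- read_matrix_tsv(need_file(pth("isoform_tpm.tsv"), "simulate"))
    map <- read_tsv(need_file(pth("isoform_map.tsv"), "simulate"))
    ct <- read_count_tables(need_file(pth("counts"), "simulate"))
    quant <- filter_isoforms(isoform_fractions(tpm, map), cfg$switch_filter)
    message("switch: ", nrow(quant$map), "/", nrow(map),
            " isoforms pass filtering")
    sw <- dif_test(quant, ct$samples$genotype, q_threshold = cfg$switch_q)
    write_tsv(sw, pth("switch_results.tsv"))
    models <- read_gtf(need_file(pth("annotation.gtf"), "simulate"))
    feats <- read_tsv(need_file(pth("features_transcript.tsv"), "annotate"))
    cons <- classify_consequences(models, feats, sw, quant,
                                  ct$samples$genotype, cfg$switch_q)
    write_tsv(cons, pth("switch_consequences.tsv"))
  }

  if (step %in% c("integrate", "all")) {
    de <- read_tsv(need_file(pth("de_results.tsv"), "de"))
    stab <- read_tsv(need_file(pth("stability_results.tsv"), "stability"))
    gf <- read_tsv(need_file(pth("features_gene.tsv"), "annotate"))
    tf <- read_tsv(need_file(pth("features_transcript.tsv"), "annotate"))
    sw <- read_tsv(need_file(pth("switch_results.tsv"), "switch"))
    cons <- read_tsv(need_file(pth("switch_consequences.tsv"), "switch"))
    prior <- read_gene_list(need_file(pth("prior_targets.tsv"), "simulate"))
    canonical <- call_canonical_targets(de, stab, gf, prior, cfg$de_q)
    ap <- call_ap_targets(sw, cons, tf, prior, cfg$switch_q)
    combined <- combine_targets(canonical, ap)
    write_tsv(canonical, pth("targets_canonical.tsv"))
    write_tsv(ap, pth("targets_ap.tsv"))
    write_tsv(combined, pth("targets_combined.tsv"))
    message("integrate: ", nrow(canonical), " canonical, ",
            length(unique(ap$gene_id)), " AP genes, ",
            nrow(combined), " combined")
  }

  if (step %in% c("magnitude", "all")) {
    expr <- read_stage_matrix(need_file(pth("stage"), "simulate"))
    truth <- read_tsv(need_file(pth("truth.tsv"), "simulate"))
    lfc <- lfc_vs_baseline(expr)
    targets <- truth$gene_id[truth$trajectory_class == "target"]
    factors <- truth$gene_id[truth$trajectory_class == "factor"]
    background <- truth$gene_id[truth$trajectory_class == "background"]
    traj <- rbind(gene_set_trajectory(lfc, targets, "targets"),
                  gene_set_trajectory(lfc, factors, "factors"))
    write_tsv(traj, pth("trajectories.tsv"))
    ks <- ks_shift(expr, factors, background, stage = "E5.5")
    write_tsv(ks$cdf, pth("cdf.tsv"))
    write_tsv(dotplot_summary(expr, factors), pth("dotplot.tsv"))
  }

  if (step == "mendel") {
    er <- expected_ratios(cross_model(c("+/-", "+/-"),
                                      lethal_genotypes = "-/-"))
    jsonlite::write_json(lapply(er, as.list), pth("mendel.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  if (step == "all") {
    truth <- read_tsv(pth("truth.tsv"))
    combined <- read_tsv(pth("targets_combined.tsv"))
    gf <- read_tsv(pth("features_gene.tsv"))
    prior <- read_gene_list(pth("prior_targets.tsv"))
    planted <- truth$gene_id[truth$is_planted_target |
                               !is.na(truth$planted_switch)]
    called <- combined$gene_id
    tp <- length(intersect(called, planted))
    enr <- feature_enrichment(called, gf)
    traj <- read_tsv(pth("trajectories.tsv"))
    summary <- list(
      provenance = list(package = "nmdtargets",
                        version = as.character(utils::packageVersion("nmdtargets")),
                        seed = cfg$seed),
      config = list(de_q = cfg$de_q, switch_q = cfg$switch_q,
                    n_genes = cfg$sim$n_genes,
                    n_targets = cfg$sim$n_targets),
      sets = list(n_canonical = nrow(read_tsv(pth("targets_canonical.tsv"))),
                  n_ap_genes = length(unique(read_tsv(pth("targets_ap.tsv"))$gene_id)),
                  n_combined = nrow(combined)),
      truth_recovery = list(precision = tp / max(length(called), 1),
                            recall = tp / max(length(planted), 1)),
      prior_overlap_pct = overlap_with_prior(called, prior),
      dej_enrichment = list(
        prop_targets = enr$prop_set[enr$feature == "has_dej"],
        prop_background = enr$prop_background[enr$feature == "has_dej"]),
      trajectory = traj[traj$significant %in% TRUE,
                        c("set", "stage", "lineage", "mean_lfc", "p_adj")])
    jsonlite::write_json(summary, pth("summary.json"), auto_unbox = TRUE,
                         digits = NA, dataframe = "rows")
    return(invisible(summary))
  }
  invisible(out)
}
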