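# Table I/O for the pipeline artifacts. Every table carries a provenance
# comment line; readers skip comment lines.

prov_line <- function() {
  sprintf("# nmdtargets %s | %s",
          as.character(utils::packageVersion("nmdtargets")),
          format(Sys.time(), "%Y-%m-%d"))
}

write_tsv <- function(df, path, provenance = TRUE) {
  con <- file(path, "w")
  on.exit(close(con))
  if (provenance) writeLines(prov_line(), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE, ...)
}

write_matrix_tsv <- function(m, path, id_col = "gene_id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  write_tsv(df, path)
}

read_matrix_tsv <- function(path) {
  df <- read_tsv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Write / read count tables
#'
#' Persists the exonic and intronic count matrices, sample sheet and gene
#' lengths as TSV files in a directory, and reads them back into a
#' `count_tables` object.
#'
#' @param ct A `count_tables` object.
#' @param dir Directory (created if missing).
#' @return `dir` / a `count_tables` object.
#' @export
write_count_tables <- function(ct, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_matrix_tsv(ct$exonic, file.path(dir, "exonic_counts.tsv"))
  write_matrix_tsv(ct$intronic, file.path(dir, "intronic_counts.tsv"))
  write_tsv(ct$samples, file.path(dir, "samples.tsv"))
  write_tsv(ct$gene_lengths, file.path(dir, "gene_lengths.tsv"))
  invisible(dir)
}

#' @rdname write_count_tables
#' @export
read_count_tables <- function(dir) {
  ex <- read_matrix_tsv(file.path(dir, "exonic_counts.tsv"))
  int <- read_matrix_tsv(file.path(dir, "intronic_counts.tsv"))
  samples <- read_tsv(file.path(dir, "samples.tsv"))
  gl <- read_tsv(file.path(dir, "gene_lengths.tsv"))
  if (!identical(rownames(ex), rownames(int)) ||
      !identical(colnames(ex), colnames(int)))
    stop("exonic and intronic matrices disagree on genes or samples")
  storage.mode(ex) <- "integer"; storage.mode(int) <- "integer"
  structure(list(exonic = ex, intronic = int, samples = samples,
                 gene_lengths = gl,
                 has_intron = stats::setNames(
                   gl$intronic_length[match(rownames(ex), gl$gene_id)] > 0,
                   rownames(ex))),
            class = "count_tables")
}

#' Write / read a stage-by-lineage expression matrix
#'
#' @param expr A `stage_expression` object.
#' @param dir Directory.
#' @param baseline_stage Baseline stage used when reading back.
#' @return `dir` / a `stage_expression` object.
#' @export
write_stage_matrix <- function(expr, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_matrix_tsv(expr$matrix, file.path(dir, "stage_expression.tsv"))
  write_tsv(expr$cells, file.path(dir, "cells.tsv"))
  invisible(dir)
}

#' @rdname write_stage_matrix
#' @export
read_stage_matrix <- function(dir, baseline_stage = NULL) {
  m <- read_matrix_tsv(file.path(dir, "stage_expression.tsv"))
  cells <- read_tsv(file.path(dir, "cells.tsv"))
  stages <- unique(cells$stage)
  if (is.null(baseline_stage)) baseline_stage <- stages[1]
  structure(list(matrix = m, cells = cells, stages = stages,
                 baseline = baseline_stage), class = "stage_expression")
}

#' Write / read a plain gene list
#'
#' One gene id per line (TSV with a single `gene_id` column).
#'
#' @param genes Character vector.
#' @param path File path.
#' @return `path` / character vector.
#' @export
write_gene_list <- function(genes, path) {
  write_tsv(data.frame(gene_id = genes, stringsAsFactors = FALSE), path)
}

#' @rdname write_gene_list
#' @export
read_gene_list <- function(path) {
  read_tsv(path)$gene_id
}
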