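#' Read transcript models from a GTF file
#'
#' Reads gene/transcript/exon (and optional CDS) records in the Ensembl GTF
#' dialect (`gene_id` / `transcript_id` attributes, 1-based inclusive
#' coordinates) and converts them to the internal 0-based half-open
#' representation. Genomic CDS records are collapsed to transcript-coordinate
#' ORF bounds.
#'
#' @param path Path to a GTF file.
#' @return A [transcript_models] object.
#' @export
read_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  df <- as.data.frame(gr)
  if (!all(c("type", "gene_id", "transcript_id") %in% names(df)))
    stop("GTF lacks type/gene_id/transcript_id fields: ", path)
  ex <- df[df$type == "exon", , drop = FALSE]
  if (nrow(ex) == 0L) stop("GTF contains no exon records: ", path)
  exons <- data.frame(
    transcript_id = as.character(ex$transcript_id),
    chrom = as.character(ex$seqnames),
    start = ex$start - 1L,            # GTF 1-based inclusive -> 0-based half-open
    end = ex$end,
    strand = as.character(ex$strand),
    stringsAsFactors = FALSE)
  tx <- unique(data.frame(
    transcript_id = as.character(ex$transcript_id),
    gene_id = as.character(ex$gene_id),
    chrom = as.character(ex$seqnames),
    strand = as.character(ex$strand),
    stringsAsFactors = FALSE))
  if (anyDuplicated(tx$transcript_id))
    stop("transcript assigned to multiple genes/chroms/strands in ", path)
  tx$cds_start <- NA_integer_
  tx$cds_end <- NA_integer_
  models <- transcript_models(tx, exons)

  cds <- df[df$type == "CDS", , drop = FALSE]
  if (nrow(cds) > 0L) {
    for (id in unique(as.character(cds$transcript_id))) {
      ci <- cds[cds$transcript_id == id, , drop = FALSE]
      iv <- data.frame(start = ci$start - 1L, end = ci$end)
      b <- map_genome_to_tx(models, id, iv)
      i <- match(id, models$transcripts$transcript_id)
      models$transcripts$cds_start[i] <- b[1]
      models$transcripts$cds_end[i] <- b[2]
    }
    validate_models(models)
  }
  models
}

#' Write transcript models to a GTF file
#'
#' Emits gene, transcript, exon and (where ORF bounds are set) CDS records.
#' Round-trip stable with [read_gtf()].
#'
#' @param models A [transcript_models] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(models, path) {
  tx <- models$transcripts
  ex <- models$exons
  rows <- list()
  attr_str <- function(gene, txid = NULL) {
    s <- sprintf('gene_id "%s";', gene)
    if (!is.null(txid)) s <- paste0(s, sprintf(' transcript_id "%s";', txid))
    s
  }
  for (g in unique(tx$gene_id)) {
    txg <- tx[tx$gene_id == g, , drop = FALSE]
    exg <- ex[ex$transcript_id %in% txg$transcript_id, , drop = FALSE]
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = txg$chrom[1], source = "nmdtargets", type = "gene",
      start = min(exg$start) + 1L, end = max(exg$end), score = ".",
      strand = txg$strand[1], frame = ".", attr = attr_str(g))
    for (i in seq_len(nrow(txg))) {
      id <- txg$transcript_id[i]
      et <- exg[exg$transcript_id == id, , drop = FALSE]
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = txg$chrom[i], source = "nmdtargets", type = "transcript",
        start = min(et$start) + 1L, end = max(et$end), score = ".",
        strand = txg$strand[i], frame = ".", attr = attr_str(g, id))
      for (k in seq_len(nrow(et))) {
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = et$chrom[k], source = "nmdtargets", type = "exon",
          start = et$start[k] + 1L, end = et$end[k], score = ".",
          strand = et$strand[k], frame = ".", attr = attr_str(g, id))
      }
      if (!is.na(txg$cds_start[i])) {
        iv <- map_tx_to_genome(models, id, txg$cds_start[i], txg$cds_end[i])
        iv <- iv[order(iv$start), , drop = FALSE]
        for (k in seq_len(nrow(iv))) {
          rows[[length(rows) + 1L]] <- data.frame(
            chrom = txg$chrom[i], source = "nmdtargets", type = "CDS",
            start = iv$start[k] + 1L, end = iv$end[k], score = ".",
            strand = txg$strand[i], frame = ".", attr = attr_str(g, id))
        }
      }
    }
  }
  tab <- do.call(rbind, rows)
  lines <- sprintf("%s\t%s\t%s\t%d\t%d\t%s\t%s\t%s\t%s",
                   tab$chrom, tab$source, tab$type, tab$start, tab$end,
                   tab$score, tab$strand, tab$frame, tab$attr)
  writeLines(lines, path)
  invisible(path)
}

#' Read / write transcript sequences
#'
#' Thin wrappers around Biostrings FASTA I/O; sequences are keyed by
#' transcript id.
#'
#' @param path FASTA path.
#' @return `read_transcript_fasta` returns a [Biostrings::DNAStringSet].
#' @export
read_transcript_fasta <- function(path) {
  Biostrings::readDNAStringSet(path)
}

#' @rdname read_transcript_fasta
#' @param seqs A named [Biostrings::DNAStringSet] or named character vector.
#' @export
write_transcript_fasta <- function(seqs, path) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}
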