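#' Transcript model container
#'
#' Bundles per-transcript metadata with an exon table into a light-weight
#' container used throughout the package. Coordinates are internal 0-based,
#' half-open (`start` inclusive, `end` exclusive); GTF input/output converts
#' from/to the 1-based inclusive convention.
#'
#' @param transcripts data.frame with columns `transcript_id`, `gene_id`,
#'   `chrom`, `strand`, `cds_start`, `cds_end` (transcript-coordinate ORF
#'   bounds, `NA` if unannotated). `length` is recomputed from the exons.
#' @param exons data.frame with columns `transcript_id`, `chrom`, `start`,
#'   `end`, `strand`; one row per exon, 0-based half-open genomic intervals.
#' @return An object of class `transcript_models`.
#' @export
transcript_models <- function(transcripts, exons) {
  stopifnot(is.data.frame(transcripts), is.data.frame(exons))
  need_tx <- c("transcript_id", "gene_id", "chrom", "strand")
  if (!all(need_tx %in% names(transcripts)))
    stop("transcripts table must contain: ", paste(need_tx, collapse = ", "))
  need_ex <- c("transcript_id", "chrom", "start", "end", "strand")
  if (!all(need_ex %in% names(exons)))
    stop("exon table must contain: ", paste(need_ex, collapse = ", "))
  if (anyDuplicated(transcripts$transcript_id))
    stop("duplicated transcript_id in transcripts table")
  if (!all(exons$transcript_id %in% transcripts$transcript_id))
    stop("exon table references unknown transcript_id")
  if (!("cds_start" %in% names(transcripts))) transcripts$cds_start <- NA_integer_
  if (!("cds_end" %in% names(transcripts))) transcripts$cds_end <- NA_integer_

  exons <- exons[order(exons$transcript_id, exons$start), , drop = FALSE]
  rownames(exons) <- NULL
  obj <- structure(list(transcripts = transcripts, exons = exons),
                   class = "transcript_models")
  obj$transcripts$length <- vapply(
    split(exons$end - exons$start, exons$transcript_id)[transcripts$transcript_id],
    sum, numeric(1))
  validate_models(obj)
  obj
}

#' @export
print.transcript_models <- function(x, ...) {
  cat(sprintf("transcript_models: %d transcripts, %d genes, %d exons\n",
              nrow(x$transcripts), length(unique(x$transcripts$gene_id)),
              nrow(x$exons)))
  invisible(x)
}

validate_models <- function(m) {
  tx <- m$transcripts
  ex <- m$exons
  if (any(ex$start < 0) || any(ex$end <= ex$start))
    stop("invalid exon interval: require 0 <= start < end")
  if (!all(ex$strand %in% c("+", "-")) || !all(tx$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  for (id in tx$transcript_id) {
    e <- ex[ex$transcript_id == id, , drop = FALSE]
    if (nrow(e) == 0L) stop("transcript without exons: ", id)
    i <- match(id, tx$transcript_id)
    if (length(unique(e$strand)) != 1L || e$strand[1] != tx$strand[i])
      stop("mixed or inconsistent strands in transcript ", id)
    if (length(unique(e$chrom)) != 1L || e$chrom[1] != tx$chrom[i])
      stop("mixed chromosomes in transcript ", id)
    if (nrow(e) > 1L && any(e$start[-1] < e$end[-nrow(e)]))
      stop("overlapping exons in transcript ", id)
    cs <- tx$cds_start[i]; ce <- tx$cds_end[i]
    if (!is.na(cs) || !is.na(ce)) {
      len <- sum(e$end - e$start)
      if (is.na(cs) || is.na(ce) || cs < 0 || ce <= cs || ce > len)
        stop("invalid CDS bounds in transcript ", id)
      if ((ce - cs) %% 3L != 0L)
        stop("CDS length not divisible by 3 in transcript ", id)
    }
  }
  invisible(m)
}

# Exon widths of one transcript in transcript (5'->3') order.
exon_widths_tx <- function(models, transcript_id) {
  e <- models$exons[models$exons$transcript_id == transcript_id, , drop = FALSE]
  w <- e$end - e$start
  if (e$strand[1] == "-") rev(w) else w
}

n_exons <- function(models) {
  tab <- table(models$exons$transcript_id)
  as.integer(tab[models$transcripts$transcript_id])
}

# Map a transcript-coordinate interval [t0, t1) onto genomic intervals.
# Returns a data.frame(start, end) in genomic coordinates (0-based half-open).
map_tx_to_genome <- function(models, transcript_id, t0, t1) {
  e <- models$exons[models$exons$transcript_id == transcript_id, , drop = FALSE]
  minus <- e$strand[1] == "-"
  if (minus) e <- e[rev(seq_len(nrow(e))), , drop = FALSE]
  w <- e$end - e$start
  off <- cumsum(c(0, w[-length(w)]))
  out <- list()
  for (k in seq_len(nrow(e))) {
    a <- max(t0, off[k]); b <- min(t1, off[k] + w[k])
    if (a >= b) next
    if (minus) {
      # transcript coord x maps to genomic e$end[k] - 1 - (x - off[k])
      gs <- e$end[k] - (b - off[k]); ge <- e$end[k] - (a - off[k])
    } else {
      gs <- e$start[k] + (a - off[k]); ge <- e$start[k] + (b - off[k])
    }
    out[[length(out) + 1L]] <- data.frame(start = gs, end = ge)
  }
  do.call(rbind, out)
}

# Map genomic intervals (data.frame start/end) to transcript coordinate range.
# Returns c(t0, t1); errors if the intervals are not contiguous in the
# transcript (used to reconstruct CDS bounds from genomic CDS records).
map_genome_to_tx <- function(models, transcript_id, intervals) {
  e <- models$exons[models$exons$transcript_id == transcript_id, , drop = FALSE]
  minus <- e$strand[1] == "-"
  eo <- if (minus) e[rev(seq_len(nrow(e))), , drop = FALSE] else e
  w <- eo$end - eo$start
  off <- cumsum(c(0, w[-length(w)]))
  to_tx <- function(g) { # genomic base position -> transcript coordinate
    for (k in seq_len(nrow(eo))) {
      if (g >= eo$start[k] && g < eo$end[k]) {
        return(if (minus) off[k] + (eo$end[k] - 1 - g) else off[k] + (g - eo$start[k]))
      }
    }
    stop("genomic position ", g, " outside exons of ", transcript_id)
  }
  tc <- unlist(lapply(seq_len(nrow(intervals)), function(i) {
    c(to_tx(intervals$start[i]), to_tx(intervals$end[i] - 1L))
  }))
  t0 <- min(tc); t1 <- max(tc) + 1L
  if ((t1 - t0) != sum(intervals$end - intervals$start))
    stop("CDS intervals not contiguous in transcript ", transcript_id)
  c(t0, t1)
}
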