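#' Configuration for NMD feature detection
#'
#' @param dej_threshold Distance (nt) from the stop codon to the last
#'   exon-exon junction above which a transcript is called dEJ-positive
#'   (the "50-nt rule"; the call requires distance strictly greater than
#'   this value). Default 50.
#' @param uorf_min_codons Minimum upstream ORF length in codons, including
#'   the stop codon. Default 3.
#' @param long_utr3_rule Either `"multiple_of_annotation_median"` (default)
#'   or `"absolute_nt"`.
#' @param long_utr3_value Threshold for the chosen rule: a multiplier of the
#'   annotation-wide median 3' UTR length (default 2), or an absolute length
#'   in nt.
#' @return A list of class `feature_config`.
#' @export
feature_config <- function(dej_threshold = 50L, uorf_min_codons = 3L,
                           long_utr3_rule = c("multiple_of_annotation_median",
                                              "absolute_nt"),
                           long_utr3_value = 2) {
  long_utr3_rule <- match.arg(long_utr3_rule)
  if (dej_threshold <= 0) stop("dej_threshold must be > 0")
  if (uorf_min_codons < 1) stop("uorf_min_codons must be >= 1")
  if (long_utr3_value <= 0) stop("long_utr3_value must be > 0")
  structure(list(dej_threshold = dej_threshold,
                 uorf_min_codons = uorf_min_codons,
                 long_utr3_rule = long_utr3_rule,
                 long_utr3_value = long_utr3_value),
            class = "feature_config")
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

# All ATG-initiated, in-frame-stop-terminated ORFs in a sequence string.
# Returns data.frame(start, end) in 0-based half-open coordinates (end just
# past the stop codon); one row per initiating ATG.
# as.character() drops names on plain character vectors; keep them
prep_seqs <- function(seqs) {
  nm <- names(seqs)
  s <- as.character(seqs)
  names(s) <- nm
  s
}

find_orfs <- function(seq) {
  n <- nchar(seq)
  if (n < 6L) return(data.frame(start = integer(0), end = integer(0)))
  starts <- integer(0); ends <- integer(0)
  atg <- gregexpr("ATG", seq, fixed = TRUE)[[1]]
  if (atg[1] == -1L) return(data.frame(start = integer(0), end = integer(0)))
  for (p in as.integer(atg)) {        # p is 1-based
    q <- p + 3L
    while (q + 2L <= n) {
      if (substr(seq, q, q + 2L) %in% STOP_CODONS) {
        starts <- c(starts, p - 1L); ends <- c(ends, q + 2L)
        break
      }
      q <- q + 3L
    }
  }
  data.frame(start = starts, end = ends)
}

#' Assign an open reading frame to each transcript
#'
#' Keeps an annotated CDS where present; otherwise assigns the longest
#' ATG-initiated ORF terminating at an in-frame stop codon. Transcripts with
#' no ORF, or whose ORF leaves an empty 5' or 3' UTR, are marked not
#' evaluable (only transcripts with a detectable 5' UTR and 3' UTR enter
#' feature calling).
#'
#' @param models A [transcript_models] object.
#' @param seqs Named [Biostrings::DNAStringSet] (or character vector) of
#'   transcript sequences; names must cover all transcript ids, lengths must
#'   equal the transcript lengths.
#' @return `models` with `cds_start`/`cds_end` filled where assignable and a
#'   logical `evaluable` column added to the transcript table.
#' @export
assign_orf <- function(models, seqs) {
  seqs <- prep_seqs(seqs)
  tx <- models$transcripts
  miss <- setdiff(tx$transcript_id, names(seqs))
  if (length(miss)) stop("missing sequence for transcripts: ",
                         paste(utils::head(miss, 3), collapse = ", "))
  for (i in seq_len(nrow(tx))) {
    s <- seqs[[tx$transcript_id[i]]]
    if (nchar(s) != tx$length[i])
      stop("sequence length mismatch for transcript ", tx$transcript_id[i])
    if (is.na(tx$cds_start[i])) {
      orfs <- find_orfs(s)
      if (nrow(orfs)) {
        j <- which.max(orfs$end - orfs$start)   # ties: first (leftmost) ATG
        tx$cds_start[i] <- orfs$start[j]
        tx$cds_end[i] <- orfs$end[j]
      }
    }
  }
  tx$evaluable <- !is.na(tx$cds_start) & tx$cds_start > 0 &
    !is.na(tx$cds_end) & tx$cds_end < tx$length
  models$transcripts <- tx
  validate_models(models)
  models
}

#' Detect a downstream exon-exon junction (dEJ)
#'
#' A transcript carries a dEJ when its stop codon lies more than
#' `dej_threshold` nt upstream of the last exon-exon junction, the canonical
#' trigger of NMD (50-nt rule). The distance is signed: negative values mean
#' the stop codon is within the last exon.
#'
#' @param models A [transcript_models] object with ORFs assigned
#'   (see [assign_orf()]).
#' @param config A [feature_config()].
#' @return data.frame with `transcript_id`, `has_dej`, `dej_distance`
#'   (`NA` for single-exon or non-evaluable transcripts).
#' @export
detect_dej <- function(models, config = feature_config()) {
  tx <- models$transcripts
  ev <- if ("evaluable" %in% names(tx)) tx$evaluable else
    (!is.na(tx$cds_start) & tx$cds_start > 0 & tx$cds_end < tx$length)
  dist <- rep(NA_real_, nrow(tx))
  has <- rep(NA, nrow(tx))
  for (i in seq_len(nrow(tx))) {
    if (!isTRUE(ev[i])) next
    w <- exon_widths_tx(models, tx$transcript_id[i])
    if (length(w) < 2L) { has[i] <- FALSE; next }
    junction <- tx$length[i] - w[length(w)]   # transcript coord of last junction
    dist[i] <- junction - tx$cds_end[i]       # cds_end = position after stop
    has[i] <- dist[i] > config$dej_threshold
  }
  data.frame(transcript_id = tx$transcript_id, has_dej = has,
             dej_distance = dist, stringsAsFactors = FALSE)
}

#' Count upstream open reading frames (uORFs)
#'
#' Counts ATG-initiated ORFs of at least `uorf_min_codons` codons (stop
#' included) that start strictly within the 5' UTR and terminate at or
#' before the main start codon; ORFs overlapping the main ORF are not
#' counted.
#'
#' @inheritParams detect_dej
#' @param seqs Named transcript sequences.
#' @return data.frame with `transcript_id`, `n_uorfs`, `has_uorf`.
#' @export
detect_uorfs <- function(models, seqs, config = feature_config()) {
  seqs <- prep_seqs(seqs)
  tx <- models$transcripts
  ev <- tx$evaluable
  n <- rep(NA_integer_, nrow(tx))
  for (i in seq_len(nrow(tx))) {
    if (!isTRUE(ev[i])) next
    cs <- tx$cds_start[i]
    s <- seqs[[tx$transcript_id[i]]]
    orfs <- find_orfs(substr(s, 1L, cs + 2L))  # allow stop to end exactly at cs
    if (nrow(orfs) == 0L) { n[i] <- 0L; next }
    keep <- orfs$start < cs & orfs$end <= cs &
      (orfs$end - orfs$start) / 3L >= config$uorf_min_codons
    n[i] <- sum(keep)
  }
  data.frame(transcript_id = tx$transcript_id, n_uorfs = n,
             has_uorf = ifelse(is.na(n), NA, n > 0L), stringsAsFactors = FALSE)
}

#' Measure 3' UTR length and call long 3' UTRs
#'
#' The 3' UTR length is the transcript length minus the ORF end. Under the
#' default rule a transcript has a long 3' UTR when its 3' UTR is at least
#' `long_utr3_value` times the median 3' UTR length over all evaluable
#' transcripts in the annotation.
#'
#' @inheritParams detect_dej
#' @param utr3_median Optional pre-computed annotation-wide median 3' UTR
#'   length (nt); computed from `models` when `NULL`.
#' @return data.frame with `transcript_id`, `utr3_length`, `is_long_utr3`.
#' @export
measure_utr3 <- function(models, config = feature_config(), utr3_median = NULL) {
  tx <- models$transcripts
  ev <- tx$evaluable
  len <- ifelse(ev, tx$length - tx$cds_end, NA_real_)
  if (config$long_utr3_rule == "absolute_nt") {
    thr <- config$long_utr3_value
  } else {
    if (is.null(utr3_median)) utr3_median <- stats::median(len, na.rm = TRUE)
    thr <- config$long_utr3_value * utr3_median
  }
  data.frame(transcript_id = tx$transcript_id, utr3_length = len,
             is_long_utr3 = ifelse(is.na(len), NA, len >= thr),
             stringsAsFactors = FALSE)
}

#' Annotate all NMD-inducing features per transcript
#'
#' Runs [assign_orf()] (if ORFs are not yet assigned), [detect_dej()],
#' [detect_uorfs()] and [measure_utr3()] and combines them into one
#' per-transcript feature table.
#'
#' @inheritParams detect_uorfs
#' @return data.frame with columns `transcript_id`, `gene_id`, `evaluable`,
#'   `has_dej`, `dej_distance`, `utr3_length`, `is_long_utr3`, `n_uorfs`,
#'   `has_uorf`.
#' @export
annotate_features <- function(models, seqs, config = feature_config()) {
  if (!("evaluable" %in% names(models$transcripts)))
    models <- assign_orf(models, seqs)
  tx <- models$transcripts
  dej <- detect_dej(models, config)
  uo <- detect_uorfs(models, seqs, config)
  u3 <- measure_utr3(models, config)
  out <- data.frame(transcript_id = tx$transcript_id, gene_id = tx$gene_id,
                    evaluable = tx$evaluable, stringsAsFactors = FALSE)
  out <- merge(merge(merge(out, dej, by = "transcript_id"),
                     uo, by = "transcript_id"), u3, by = "transcript_id")
  out[match(tx$transcript_id, out$transcript_id), , drop = FALSE]
}

#' Collapse transcript-level features to gene level
#'
#' A gene is called positive for a feature if any of its evaluable
#' transcripts carries the feature. Genes with no evaluable transcript are
#' marked not evaluable with `NA` flags.
#'
#' @param features Per-transcript feature table from [annotate_features()].
#' @return data.frame with one row per gene: `gene_id`, `evaluable`,
#'   `has_dej`, `has_uorf`, `is_long_utr3`, `max_utr3_length`.
#' @export
collapse_to_gene <- function(features) {
  sp <- split(features, features$gene_id)
  rows <- lapply(sp, function(f) {
    f <- f[f$evaluable %in% TRUE, , drop = FALSE]
    if (nrow(f) == 0L)
      return(data.frame(evaluable = FALSE, has_dej = NA, has_uorf = NA,
                        is_long_utr3 = NA, max_utr3_length = NA_real_))
    data.frame(evaluable = TRUE,
               has_dej = any(f$has_dej, na.rm = TRUE),
               has_uorf = any(f$has_uorf, na.rm = TRUE),
               is_long_utr3 = any(f$is_long_utr3, na.rm = TRUE),
               max_utr3_length = suppressWarnings(max(f$utr3_length, na.rm = TRUE)))
  })
  out <- do.call(rbind, rows)
  out <- cbind(data.frame(gene_id = names(sp), stringsAsFactors = FALSE), out)
  rownames(out) <- NULL
  out
}
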