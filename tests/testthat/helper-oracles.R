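# Independent brute-force oracles. These deliberately avoid the package's
# internal coordinate machinery: structures are described as exon widths in
# transcript (5'->3') order plus transcript-coordinate CDS bounds, and every
# quantity is obtained by enumerating transcript nucleotides.

# Nucleotide-level dEJ oracle: walk the transcript base by base, note where
# the exon index changes (junctions), take the last junction.
oracle_dej <- function(widths, cds_end, threshold = 50) {
  exon_of_base <- rep(seq_along(widths), widths)   # exon index of base 1..L
  junctions <- integer(0)
  for (p in seq_len(length(exon_of_base) - 1)) {
    if (exon_of_base[p] != exon_of_base[p + 1]) junctions <- c(junctions, p)
  }
  if (length(junctions) == 0) return(list(has = FALSE, dist = NA_real_))
  d <- max(junctions) - cds_end
  list(has = d > threshold, dist = d)
}

# Scan every base of the 5' UTR for an ATG; extend codon by codon to the
# first stop; count if fully upstream of the main ORF and long enough.
oracle_uorf <- function(seq, cds_start, min_codons = 3) {
  n <- 0L
  stops <- c("TAA", "TAG", "TGA")
  for (p in seq_len(cds_start)) {                  # 1-based start positions
    if (p - 1 >= cds_start) break
    if (substr(seq, p, p + 2) != "ATG") next
    q <- p + 3
    while (q + 2 <= nchar(seq)) {
      if (substr(seq, q, q + 2) %in% stops) {
        if (q + 2 <= cds_start && (q + 2 - p + 1) / 3 >= min_codons)
          n <- n + 1L
        break
      }
      q <- q + 3
    }
  }
  n
}

oracle_utr3 <- function(seq, cds_end) nchar(seq) - cds_end

# Random toy transcript: widths in transcript order, CDS bounds, sequence,
# plus a realized transcript_models object on a random strand.
random_transcript <- function(id = "tx", strand = sample(c("+", "-"), 1)) {
  u <- sample(1:60, 1)
  ncod <- sample(4:60, 1)
  t3 <- sample(1:300, 1)
  L <- u + 3 * ncod + t3
  n_ex <- sample(1:5, 1)
  cuts <- if (n_ex > 1) sort(sample(seq_len(L - 1), n_ex - 1)) else integer(0)
  widths <- diff(c(0, cuts, L))
  seq <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
  introns <- if (n_ex > 1) sample(50:500, n_ex - 1, replace = TRUE) else integer(0)
  w_geno <- if (strand == "-") rev(widths) else widths
  i_geno <- if (strand == "-") rev(introns) else introns
  starts <- 1000 + cumsum(c(0, head(w_geno, -1) + i_geno))
  models <- transcript_models(
    data.frame(transcript_id = id, gene_id = paste0(id, "_g"), chrom = "chr1",
               strand = strand, cds_start = u, cds_end = u + 3 * ncod,
               stringsAsFactors = FALSE),
    data.frame(transcript_id = id, chrom = "chr1", start = starts,
               end = starts + w_geno, strand = strand,
               stringsAsFactors = FALSE))
  models$transcripts$evaluable <- TRUE
  list(models = models, widths = widths, seq = seq,
       cds_start = u, cds_end = u + 3 * ncod)
}

# Build a transcript_models object directly from transcript-order exon
# widths (plus strand), for hand-constructed cases.
models_from_widths <- function(widths, cds_start = NA, cds_end = NA,
                               strand = "+", id = "tx", gene = "g",
                               gap = 100) {
  w_geno <- if (strand == "-") rev(widths) else widths
  starts <- 1000 + cumsum(c(0, head(w_geno, -1) + rep(gap, length(w_geno) - 1)))
  m <- transcript_models(
    data.frame(transcript_id = id, gene_id = gene, chrom = "chr1",
               strand = strand, cds_start = cds_start, cds_end = cds_end,
               stringsAsFactors = FALSE),
    data.frame(transcript_id = id, chrom = "chr1", start = starts,
               end = starts + w_geno, strand = strand,
               stringsAsFactors = FALSE))
  m$transcripts$evaluable <- !is.na(cds_start)
  m
}

auroc <- function(score, label) {
  r <- rank(score)
  n1 <- sum(label); n0 <- sum(!label)
  (sum(r[label]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Small default world shared by several test files (cached per session).
small_world <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      p <- sim_params(n_genes = 300, n_targets = 20, n_switch_genes = 6,
                      n_factors = 5, seed = 101)
      sim <- simulate_annotation(p)
      cache <<- list(params = p, sim = sim, counts = simulate_counts(sim))
    }
    cache
  }
})
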