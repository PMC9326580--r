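# Fixture builders and independent brute-force oracles. The oracles work on
# plain character vectors and R loops, sharing no code with the package
# implementations they check.

toy_genome <- function(...) {
  seqs <- c(...)
  g <- Biostrings::DNAStringSet(unname(seqs))
  names(g) <- names(seqs)
  g
}

toy_gene <- function(gene_id = "g1", chrom = "chr1", strand = "+",
                     tx_start = 0L, tx_end = 100L,
                     isoform_id = paste0(gene_id, ".1")) {
  gene_models(gene_id, isoform_id, chrom, strand, tx_start, tx_end)
}

random_seq <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

toy_frags <- function(chrom, start, end, condition = "UNT",
                      total_mapped = NULL) {
  fragment_set(data.frame(chrom = chrom, start = start, end = end),
               condition = condition, total_mapped = total_mapped)
}

# --- oracles ----------------------------------------------------------------

# G+C percent of chr_str[start0, end0) (0-based half-open), N excluded from
# numerator and denominator; NA when >= half the bases are ambiguous.
bf_region_gc <- function(chr_str, start0, end0) {
  bases <- strsplit(substr(chr_str, start0 + 1, end0), "")[[1]]
  gc <- sum(bases %in% c("G", "C"))
  ok <- sum(bases %in% c("A", "C", "G", "T"))
  if (ok <= length(bases) / 2) return(NA_real_)
  gc / ok * 100
}

# per-window G+C along a gene, transcription orientation
bf_window_gc <- function(chr_str, tx_start, tx_end, strand, window = 100,
                         step = window) {
  len <- tx_end - tx_start
  if (len < window) return(numeric(0))
  offs <- seq(0, len - window, by = step)
  vapply(offs, function(o) {
    if (strand == "+") bf_region_gc(chr_str, tx_start + o, tx_start + o + window)
    else bf_region_gc(chr_str, tx_end - o - window, tx_end - o)
  }, 0)
}

# fragment midpoint assignment, one gene max per fragment
bf_count_fragments <- function(genes, frag_df) {
  counts <- stats::setNames(integer(nrow(genes)), genes$gene_id)
  for (i in seq_len(nrow(frag_df))) {
    m <- (frag_df$start[i] + frag_df$end[i]) %/% 2
    hit <- which(genes$chrom == frag_df$chrom[i] &
                   genes$tx_start <= m & m < genes$tx_end)
    if (length(hit) == 0) next
    if (length(hit) > 1) {
      hit <- hit[order(genes$tx_start[hit], genes$gene_id[hit])][1]
    }
    counts[hit] <- counts[hit] + 1L
  }
  counts
}

# midpoint histogram over [start0, end0) in `bin`-bp bins, 5'->3'
bf_bin_hist <- function(mids, start0, end0, strand, bin) {
  n_bins <- (end0 - start0) / bin
  counts <- integer(n_bins)
  for (m in mids) {
    if (m < start0 || m >= end0) next
    t_off <- if (strand == "+") m - start0 else end0 - 1 - m
    b <- t_off %/% bin + 1
    counts[b] <- counts[b] + 1L
  }
  counts
}

# linear-interpolation quantile between order statistics
bf_quantile <- function(x, p) {
  s <- sort(x)
  n <- length(s)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

# reverse complement on characters
bf_revcomp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

# overlapping dinucleotide count
bf_dinuc_count <- function(s, pat) {
  n <- nchar(s)
  if (n < 2) return(0L)
  sum(vapply(seq_len(n - 1), function(i) substr(s, i, i + 1) == pat, TRUE))
}
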