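# Windowed and whole-gene-body G+C content, mono- and dinucleotide
# frequencies, all in transcription orientation.
#
# G+C content is reverse-complement invariant, so windows are counted on the
# plus strand of the genome and only their ORDER depends on strand (5'->3'
# from the TSS). Ambiguous bases (N) are excluded from both numerator and
# denominator; a window with >= 50% ambiguous bases is reported NA.

chrom_of <- function(genome, chrom) {
  if (!chrom %in% names(genome)) stop("chromosome not in genome: ", chrom)
  genome[[chrom]]
}

check_span <- function(gene, genome) {
  chr <- chrom_of(genome, gene$chrom)
  if (gene$tx_start < 0 || gene$tx_end > length(chr)) {
    stop(sprintf("gene '%s' span [%d,%d) outside chromosome bounds (%d bp)",
                 gene$gene_id, gene$tx_start, gene$tx_end, length(chr)))
  }
  chr
}

#' Gene-body sequence in transcription orientation
#'
#' Returns the sense-strand sequence of the transcript span (exons and
#' introns): the plus-strand subsequence for `+` genes, its reverse
#' complement for `-` genes, so position 1 is always the TSS.
#'
#' @param gene a single-row `gene_models` table.
#' @param genome a named [Biostrings::DNAStringSet].
#' @return A [Biostrings::DNAString].
#' @export
gene_sequence <- function(gene, genome) {
  chr <- check_span(gene, genome)
  s <- Biostrings::subseq(chr, start = gene$tx_start + 1L, end = gene$tx_end)
  if (gene$strand == "-") s <- Biostrings::reverseComplement(s)
  s
}

# GC percent for a set of same-chromosome windows given as 0-based half-open
# genomic intervals; NA where >= half the bases are ambiguous.
gc_percent_views <- function(chr, starts0, ends0) {
  v <- Biostrings::Views(chr, start = starts0 + 1L, end = ends0)
  f <- Biostrings::letterFrequency(v, letters = c("GC", "AT"))
  gc <- f[, 1]
  ok <- f[, 1] + f[, 2]
  width <- ends0 - starts0
  out <- ifelse(ok > width / 2, gc / ok * 100, NA_real_)
  as.numeric(out)
}

#' G+C percent per window along a gene body
#'
#' Tiles the gene body (exons and introns) with fixed-width windows from the
#' TSS toward the TTS in transcription direction; for minus-strand genes the
#' windows advance leftward from `tx_end`. The trailing partial window is
#' dropped.
#'
#' @param gene a single-row `gene_models` table.
#' @param genome a named [Biostrings::DNAStringSet].
#' @param window,step window width and step in bp (non-overlapping tiling by
#'   default).
#' @return Numeric vector of percents, one per window, ordered 5' to 3';
#'   `NA` for windows with at least half ambiguous bases.
#' @export
window_gc <- function(gene, genome, window = 100L, step = window) {
  stopifnot(window >= 1, step >= 1)
  chr <- check_span(gene, genome)
  len <- gene$tx_end - gene$tx_start
  if (len < window) return(numeric(0))
  offsets <- seq.int(0L, len - window, by = step)
  if (gene$strand == "+") {
    starts0 <- gene$tx_start + offsets
  } else {
    starts0 <- gene$tx_end - window - offsets
  }
  gc_percent_views(chr, starts0, starts0 + window)
}

# Genomic interval of the body region from (TSS + skip) to the TTS,
# 0-based half-open; NA row where the gene is too short.
body_region <- function(genes, skip_5prime) {
  len <- gene_length(genes)
  ok <- len > skip_5prime
  start0 <- ifelse(genes$strand == "+", genes$tx_start + skip_5prime,
                   genes$tx_start)
  end0 <- ifelse(genes$strand == "+", genes$tx_end,
                 genes$tx_end - skip_5prime)
  data.frame(start0 = ifelse(ok, start0, NA_integer_),
             end0 = ifelse(ok, end0, NA_integer_), ok = ok)
}

#' Whole-gene-body G+C percent
#'
#' G+C percent over the gene body from `skip_5prime` bp downstream of the TSS
#' to the TTS. The first kilobase is excluded by default because it usually
#' contains a G+C-rich promoter region that would otherwise dominate short
#' genes. Genes no longer than `skip_5prime` are reported `NA` with a warning.
#'
#' @param genes a `gene_models` table (any number of rows).
#' @param genome a named [Biostrings::DNAStringSet].
#' @param skip_5prime bp excluded downstream of the TSS (default 1000).
#' @return Numeric vector of percents, one per gene.
#' @export
whole_gene_gc <- function(genes, genome, skip_5prime = 1000L) {
  reg <- body_region(genes, skip_5prime)
  if (any(!reg$ok)) {
    warning(sprintf("%d gene(s) no longer than %d bp excluded from gene-body G+C",
                    sum(!reg$ok), skip_5prime))
  }
  out <- rep(NA_real_, nrow(genes))
  for (chrom in unique(genes$chrom[reg$ok])) {
    idx <- which(reg$ok & genes$chrom == chrom)
    chr <- chrom_of(genome, chrom)
    if (any(genes$tx_start[idx] < 0 | genes$tx_end[idx] > length(chr))) {
      stop("gene span outside chromosome bounds on ", chrom)
    }
    out[idx] <- gc_percent_views(chr, reg$start0[idx], reg$end0[idx])
  }
  out
}

#' Mono- and dinucleotide frequencies over the gene body
#'
#' Computed over the same region as [whole_gene_gc()] (TSS + `skip_5prime` to
#' TTS). Mononucleotide percents are relative to unambiguous bases on the
#' requested strand; CpG and GpC percents are dinucleotide counts divided by
#' (region length - 1). `strand_mode = "template"` reports the template
#' (antisense) strand, which swaps A with T and C with G; CpG and GpC are
#' reverse-complement palindromes so their frequencies are strand-invariant.
#'
#' @param gene a single-row `gene_models` table.
#' @param genome a named [Biostrings::DNAStringSet].
#' @param skip_5prime bp excluded downstream of the TSS.
#' @param strand_mode `"sense"` (default) or `"template"`.
#' @return Named numeric vector with elements A, C, G, T, CpG, GpC (percent).
#' @export
dinucleotide_freq <- function(gene, genome, skip_5prime = 1000L,
                              strand_mode = c("sense", "template")) {
  strand_mode <- match.arg(strand_mode)
  reg <- body_region(gene, skip_5prime)
  if (!reg$ok) {
    warning(sprintf("gene '%s' no longer than %d bp: frequencies undefined",
                    gene$gene_id, skip_5prime))
    return(c(A = NA_real_, C = NA_real_, G = NA_real_, T = NA_real_,
             CpG = NA_real_, GpC = NA_real_))
  }
  chr <- check_span(gene, genome)
  s <- Biostrings::subseq(chr, start = reg$start0 + 1L, end = reg$end0)
  if (gene$strand == "-") s <- Biostrings::reverseComplement(s)
  if (strand_mode == "template") s <- Biostrings::reverseComplement(s)
  mono <- Biostrings::letterFrequency(s, letters = c("A", "C", "G", "T"))
  n_ok <- sum(mono)
  mono_pct <- if (n_ok > 0) as.numeric(mono) / n_ok * 100 else rep(NA_real_, 4)
  di <- Biostrings::dinucleotideFrequency(s)
  pairs <- length(s) - 1L
  c(A = mono_pct[1], C = mono_pct[2], G = mono_pct[3], T = mono_pct[4],
    CpG = as.numeric(di["CG"]) / pairs * 100,
    GpC = as.numeric(di["GC"]) / pairs * 100)
}

#' Per-gene G+C and nucleotide-frequency table
#'
#' Convenience wrapper producing one row per gene: length, whole-gene-body
#' G+C and sense-strand mono/dinucleotide frequencies.
#'
#' @inheritParams whole_gene_gc
#' @return data.frame with columns gene_id, gene_length, gc, A, C, G, T,
#'   CpG, GpC.
#' @export
gc_table <- function(genes, genome, skip_5prime = 1000L) {
  gc <- whole_gene_gc(genes, genome, skip_5prime = skip_5prime)
  freqs <- t(vapply(seq_len(nrow(genes)), function(i) {
    suppressWarnings(
      dinucleotide_freq(genes[i, , drop = FALSE], genome,
                        skip_5prime = skip_5prime)
    )
  }, numeric(6)))
  data.frame(gene_id = genes$gene_id, gene_length = gene_length(genes),
             gc = gc, freqs, stringsAsFactors = FALSE)
}

#' Windowed G+C matrix over the first part of each gene
#'
#' For heatmap display of G+C along genes ordered by the caller (typically by
#' ESKOR): row i holds the G+C percent of consecutive windows covering the
#' first `span` bp of gene i's body, starting at the TSS. Genes shorter than
#' `span` are excluded.
#'
#' @param genes a `gene_models` table in the desired row order.
#' @param genome a named [Biostrings::DNAStringSet].
#' @param span bp of gene body scanned from the TSS (default 10 kb).
#' @param window window width in bp (default 100; `span / window` columns).
#' @return Numeric matrix with `rownames` = gene ids of the retained genes.
#' @export
heatmap_matrix <- function(genes, genome, span = 10000L, window = 100L) {
  keep <- gene_length(genes) >= span
  genes <- genes[keep, , drop = FALSE]
  ncol_out <- span %/% window
  mat <- matrix(NA_real_, nrow = nrow(genes), ncol = ncol_out,
                dimnames = list(genes$gene_id, NULL))
  for (i in seq_len(nrow(genes))) {
    w <- window_gc(genes[i, , drop = FALSE], genome, window = window)
    mat[i, ] <- w[seq_len(ncol_out)]
  }
  mat
}
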