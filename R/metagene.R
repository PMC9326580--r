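# Scaled metagene coverage: each gene body divided into a fixed number of
# bins independently of length, with fixed-width flanking bins, so cohorts
# of genes of very different lengths can be averaged position-by-position.

#' Select the highest- and lowest-ESKOR gene sets
#'
#' Disjoint top-k and bottom-k records by ESKOR; ties at the boundary are
#' broken by gene id. If fewer than `2k` records are available, `k` is
#' shrunk to `floor(n/2)` with a warning.
#'
#' @param records filtered records carrying `eskor`.
#' @param k genes per set (default 2000).
#' @return List with `top` and `bottom` record subsets and the `k` used.
#' @export
select_extreme_eskor <- function(records, k = 2000L) {
  n <- nrow(records)
  if (2L * k > n) {
    k <- n %/% 2L
    warning(sprintf("fewer than 2k records; k shrunk to %d", k))
  }
  ord_hi <- order(-records$eskor, records$gene_id)
  ord_lo <- order(records$eskor, records$gene_id)
  list(top = records[ord_hi[seq_len(k)], , drop = FALSE],
       bottom = records[ord_lo[seq_len(k)], , drop = FALSE],
       k = k)
}

metagene_edges <- function(len, body_bins, flank, flank_bin) {
  c(seq.int(-flank, -flank_bin, by = flank_bin),
    round((0:body_bins) * len / body_bins),
    seq.int(len + flank_bin, len + flank, by = flank_bin))
}

#' Normalized coverage profile of one gene
#'
#' The gene body is divided, independently of gene length, into `body_bins`
#' bins (edges at `TSS + round(j*L/body_bins)` in transcription direction);
#' each 1 kb flank is divided into fixed `flank_bin`-bp bins. Per bin the
#' fragment-midpoint count is normalized to reads per million mapped per kb
#' of bin width (a density, so unequal bin widths are comparable).
#' Minus-strand profiles are reversed so index 1 is always the 5'-most
#' upstream flank bin. Flank bins truncated by a chromosome edge are `NA`.
#'
#' @param gene a single-row `gene_models` table; gene length must be at
#'   least `body_bins` bp.
#' @param frags a `fragment_set`.
#' @param body_bins number of gene-body bins (default 100).
#' @param flank flank span in bp on each side (default 1000).
#' @param flank_bin flank bin width in bp (default 25).
#' @param chrom_len chromosome length, used to flag truncated flank bins;
#'   `Inf` disables the check.
#' @return Numeric vector of `flank/flank_bin + body_bins + flank/flank_bin`
#'   densities with a `section` attribute
#'   (`"upstream"`/`"body"`/`"downstream"`).
#' @export
gene_profile <- function(gene, frags, body_bins = 100L, flank = 1000L,
                         flank_bin = 25L, chrom_len = Inf) {
  len <- gene$tx_end - gene$tx_start
  if (len < body_bins) {
    stop(sprintf("gene '%s' (%d bp) shorter than %d body bins",
                 gene$gene_id, len, body_bins))
  }
  f <- frags$fragments
  fi <- which(f$chrom == gene$chrom)
  mid <- (f$start[fi] + f$end[fi]) %/% 2L
  profile_from_mids(mid, gene$strand, gene$tx_start, gene$tx_end, len,
                    frags$total_mapped, body_bins, flank, flank_bin,
                    chrom_len)
}

profile_from_mids <- function(mid, strand, tx_start, tx_end, len,
                              total_mapped, body_bins, flank, flank_bin,
                              chrom_len) {
  edges <- metagene_edges(len, body_bins, flank, flank_bin)
  n_bins <- length(edges) - 1L
  t_off <- if (strand == "+") mid - tx_start else (tx_end - 1L) - mid
  t_off <- t_off[t_off >= -flank & t_off < len + flank]
  idx <- findInterval(t_off, edges)
  counts <- tabulate(idx, nbins = n_bins)
  width_kb <- diff(edges) / 1000
  out <- counts / (total_mapped / 1e6) / width_kb
  # flag bins whose genomic span falls outside the chromosome
  if (strand == "+") {
    span_lo <- tx_start + edges[-length(edges)]
    span_hi <- tx_start + edges[-1]
  } else {
    span_hi <- tx_end - edges[-length(edges)]
    span_lo <- tx_end - edges[-1]
  }
  out[span_lo < 0 | span_hi > chrom_len] <- NA_real_
  nf <- flank %/% flank_bin
  attr(out, "section") <- c(rep("upstream", nf), rep("body", body_bins),
                            rep("downstream", nf))
  out
}

#' Coverage profiles for a gene cohort
#'
#' [gene_profile()] for every gene in `genes`, sharing one pass over the
#' fragment set. Genes shorter than `body_bins` bp are dropped with a
#' warning.
#'
#' @inheritParams gene_profile
#' @param genes a `gene_models` table.
#' @param genome optional named [Biostrings::DNAStringSet]; supplies
#'   chromosome lengths for edge truncation.
#' @return Numeric matrix, one row per retained gene (rownames = gene ids),
#'   with the `section` attribute of [gene_profile()].
#' @export
metagene_profiles <- function(genes, frags, body_bins = 100L, flank = 1000L,
                              flank_bin = 25L, genome = NULL) {
  keep <- gene_length(genes) >= body_bins
  if (any(!keep)) {
    warning(sprintf("%d gene(s) shorter than %d bp excluded from metagene",
                    sum(!keep), body_bins))
  }
  genes <- genes[keep, , drop = FALSE]
  f <- frags$fragments
  n_bins <- 2L * (flank %/% flank_bin) + body_bins
  mat <- matrix(NA_real_, nrow = nrow(genes), ncol = n_bins,
                dimnames = list(genes$gene_id, NULL))
  section <- NULL
  for (chrom in unique(genes$chrom)) {
    gi <- which(genes$chrom == chrom)
    mids <- sort((f$start[f$chrom == chrom] + f$end[f$chrom == chrom]) %/% 2L)
    clen <- if (is.null(genome)) Inf else length(chrom_of(genome, chrom))
    for (i in gi) {
      lo <- genes$tx_start[i] - flank
      hi <- genes$tx_end[i] + flank
      sel <- mids[mids >= lo & mids < hi]
      p <- profile_from_mids(sel, genes$strand[i], genes$tx_start[i],
                             genes$tx_end[i],
                             genes$tx_end[i] - genes$tx_start[i],
                             frags$total_mapped, body_bins, flank,
                             flank_bin, clen)
      mat[i, ] <- p
      section <- attr(p, "section")
    }
  }
  attr(mat, "section") <- section
  mat
}

#' Aggregate per-gene profiles into a mean metagene profile
#'
#' Bin-wise mean across genes; missing bins (chromosome-edge truncation)
#' are skipped and the number of contributing genes is tracked per bin.
#'
#' @param profiles matrix from [metagene_profiles()] (genes x bins).
#' @return List with `mean` (bin-wise mean density), `n` (genes per bin)
#'   and `section`.
#' @export
aggregate_metagene <- function(profiles) {
  if (is.null(dim(profiles))) profiles <- matrix(profiles, nrow = 1)
  if (nrow(profiles) < 1) stop("need at least one profile")
  list(mean = colMeans(profiles, na.rm = TRUE),
       n = colSums(!is.na(profiles)),
       section = attr(profiles, "section"))
}
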