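# Per-gene 500 bp segmentation, extreme-G+C segment selection and
# 25 bp-binned normalized counts, contrasting knockdown vs untreated
# occupancy of each gene's most and least G+C-rich segment.

#' Tile a gene body with fixed-length segments
#'
#' Consecutive non-overlapping segments of `seg` bp starting `offset` bp 3'
#' of the TSS (in transcription direction; for minus-strand genes segments
#' advance leftward from `tx_end`). The trailing partial segment is dropped.
#'
#' @param gene a single-row `gene_models` table.
#' @param offset bp skipped downstream of the TSS (default 1000).
#' @param seg segment length in bp (default 500).
#' @return data.frame with `seg_index` (1 = 5'-most) and genomic 0-based
#'   half-open `start0`, `end0`; zero rows (with a warning) if the gene is
#'   too short to hold one full segment.
#' @export
segment_gene <- function(gene, offset = 1000L, seg = 500L) {
  len <- gene$tx_end - gene$tx_start
  n_seg <- (len - offset) %/% seg
  if (n_seg < 1) {
    warning(sprintf("gene '%s' (%d bp) too short for segmentation: excluded",
                    gene$gene_id, len))
    return(data.frame(seg_index = integer(0), start0 = integer(0),
                      end0 = integer(0)))
  }
  j <- seq_len(n_seg)
  if (gene$strand == "+") {
    start0 <- gene$tx_start + offset + (j - 1L) * seg
  } else {
    start0 <- gene$tx_end - offset - j * seg
  }
  data.frame(seg_index = j, start0 = as.integer(start0),
             end0 = as.integer(start0 + seg))
}

#' Select a gene's highest- and lowest-G+C segments
#'
#' Computes the G+C percent of each segment and returns the argmax and
#' argmin, ties broken by the 5'-most segment. A gene whose segments all
#' have identical G+C is flagged degenerate (highest = lowest); genes with
#' fewer than two segments cannot be contrasted.
#'
#' @param gene a single-row `gene_models` table.
#' @param segments data.frame from [segment_gene()].
#' @param genome a named [Biostrings::DNAStringSet].
#' @return List with `highest`, `lowest` (single-row segment data.frames
#'   with a `gc` column), and `degenerate`.
#' @export
pick_extreme_segments <- function(gene, segments, genome) {
  if (nrow(segments) < 2) {
    stop(sprintf("gene '%s' has %d segment(s); need >= 2 for a contrast",
                 gene$gene_id, nrow(segments)))
  }
  chr <- chrom_of(genome, gene$chrom)
  gc <- gc_percent_views(chr, segments$start0, segments$end0)
  segments$gc <- gc
  hi <- which.max(gc)  # first max = 5'-most
  lo <- which.min(gc)
  list(highest = segments[hi, , drop = FALSE],
       lowest = segments[lo, , drop = FALSE],
       degenerate = isTRUE(max(gc, na.rm = TRUE) == min(gc, na.rm = TRUE)))
}

#' Binned normalized fragment counts over a segment
#'
#' Splits the segment into `bin`-bp bins ordered 5' to 3' and counts fragment
#' midpoints per bin, normalized to reads per million mapped.
#'
#' @param gene the single-row `gene_models` table the segment belongs to
#'   (supplies chromosome and strand).
#' @param segment a single-row data.frame with `start0`, `end0`.
#' @param frags a `fragment_set`.
#' @param bin bin width in bp; must divide the segment length.
#' @return Numeric vector of length `(end0-start0)/bin`.
#' @export
binned_normalized_counts <- function(gene, segment, frags, bin = 25L) {
  width <- segment$end0 - segment$start0
  if (width %% bin != 0) stop("segment length must be divisible by bin width")
  n_bins <- width %/% bin
  f <- frags$fragments
  fi <- which(f$chrom == gene$chrom)
  counts <- numeric(n_bins)
  if (length(fi) > 0) {
    mid <- (f$start[fi] + f$end[fi]) %/% 2L
    mid <- mid[mid >= segment$start0 & mid < segment$end0]
    if (length(mid) > 0) {
      t_off <- if (gene$strand == "+") mid - segment$start0
               else segment$end0 - 1L - mid
      counts <- tabulate(t_off %/% bin + 1L, nbins = n_bins)
    }
  }
  counts / (frags$total_mapped / 1e6)
}

#' Extreme-G+C segment profiles for a gene cohort
#'
#' For every gene long enough to hold at least two segments, selects its
#' highest- and lowest-G+C segment and computes 25 bp-binned normalized
#' counts in both conditions. Degenerate genes (all segments at identical
#' G+C) are retained but flagged, and excluded from cohort contrasts.
#'
#' @param genes a `gene_models` table.
#' @param genome a named [Biostrings::DNAStringSet].
#' @param frags_unt,frags_kd `fragment_set`s.
#' @param offset,seg,bin see [segment_gene()] and
#'   [binned_normalized_counts()].
#' @return data.frame with one row per gene x role (`highest_gc` /
#'   `lowest_gc`): segment coordinates, `segment_gc`, `degenerate`,
#'   list-columns `bins_unt`, `bins_kd`, and per-segment totals
#'   `total_unt`, `total_kd` (reads per million mapped).
#' @export
segment_profiles <- function(genes, genome, frags_unt, frags_kd,
                             offset = 1000L, seg = 500L, bin = 25L) {
  rows <- vector("list", nrow(genes))
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, , drop = FALSE]
    segs <- suppressWarnings(segment_gene(g, offset = offset, seg = seg))
    if (nrow(segs) < 2) next
    ex <- pick_extreme_segments(g, segs, genome)
    one <- function(role, s) {
      bu <- binned_normalized_counts(g, s, frags_unt, bin = bin)
      bk <- binned_normalized_counts(g, s, frags_kd, bin = bin)
      data.frame(gene_id = g$gene_id, role = role,
                 start0 = s$start0, end0 = s$end0, segment_gc = s$gc,
                 degenerate = ex$degenerate,
                 bins_unt = I(list(bu)), bins_kd = I(list(bk)),
                 total_unt = sum(bu), total_kd = sum(bk),
                 stringsAsFactors = FALSE)
    }
    rows[[i]] <- rbind(one("highest_gc", ex$highest),
                       one("lowest_gc", ex$lowest))
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    stop("no gene held two or more segments")
  }
  rownames(out) <- NULL
  out
}

#' Cohort mean and SEM of per-segment totals
#'
#' Averages per-gene segment totals (sum of the 25 bp bins, reads per
#' million mapped) across genes for one segment role and condition.
#'
#' @param profiles data.frame from [segment_profiles()].
#' @param role `"highest_gc"` or `"lowest_gc"`.
#' @param condition `"UNT"` or `"KD"`.
#' @param drop_degenerate exclude genes whose segments all tie in G+C.
#' @return List with `mean`, `sem` (sample SD / sqrt(n)) and `n`.
#' @export
aggregate_cohort <- function(profiles, role = c("highest_gc", "lowest_gc"),
                             condition = c("UNT", "KD"),
                             drop_degenerate = TRUE) {
  role <- match.arg(role)
  condition <- match.arg(condition)
  p <- profiles[profiles$role == role, , drop = FALSE]
  if (drop_degenerate) p <- p[!p$degenerate, , drop = FALSE]
  totals <- if (condition == "UNT") p$total_unt else p$total_kd
  n <- length(totals)
  if (n < 2) stop("aggregate_cohort needs at least 2 genes (SEM undefined)")
  list(mean = mean(totals), sem = stats::sd(totals) / sqrt(n), n = n)
}

#' Two-sample equal-variance t-test
#'
#' Student's t-test, two samples assuming equal variances, two tails
#' (pooled variance, nx + ny - 2 degrees of freedom). With zero pooled
#' variance the p-value is defined as 1 when the means are equal and is an
#' error otherwise.
#'
#' @param x,y numeric samples of length >= 2.
#' @return List with `t`, `p` (two-tailed) and `df`.
#' @export
ttest_equal_var <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) stop("both samples need >= 2 values")
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    if (mean(x) == mean(y)) {
      return(list(t = 0, p = 1, df = length(x) + length(y) - 2L))
    }
    stop("zero pooled variance with unequal means: t undefined")
  }
  ht <- stats::t.test(x, y, var.equal = TRUE, alternative = "two.sided")
  list(t = unname(ht$statistic), p = ht$p.value,
       df = unname(ht$parameter))
}

#' Knockdown-vs-untreated contrast of extreme-G+C segment totals
#'
#' For each segment role, compares per-gene totals between conditions with
#' the equal-variance t-test and reports cohort means and SEMs.
#'
#' @param profiles data.frame from [segment_profiles()].
#' @return data.frame with one row per role: n, mean/sem per condition,
#'   `fold_unt_over_kd`, `t`, `p`.
#' @export
segment_contrast <- function(profiles) {
  do.call(rbind, lapply(c("highest_gc", "lowest_gc"), function(role) {
    p <- profiles[profiles$role == role & !profiles$degenerate, ,
                  drop = FALSE]
    agg_u <- aggregate_cohort(profiles, role, "UNT")
    agg_k <- aggregate_cohort(profiles, role, "KD")
    ht <- ttest_equal_var(p$total_unt, p$total_kd)
    data.frame(role = role, n = agg_u$n,
               mean_unt = agg_u$mean, sem_unt = agg_u$sem,
               mean_kd = agg_k$mean, sem_kd = agg_k$sem,
               t = ht$t, p = ht$p, stringsAsFactors = FALSE)
  }))
}
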