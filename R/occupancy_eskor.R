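# Fragment counting, FPKM, gene filters, the ESKOR statistic and its
# gene-level diagnostics (trendline slopes, ranked moving average, RNA fold
# change).
#
# ESKOR = log2(ChIP FPKM in knockdown / ChIP FPKM untreated) per gene.
# Zero means no occupancy difference; positive means more RNAPII-S2 occupancy
# after knockdown.

#' Count ChIP fragments per gene by midpoint assignment
#'
#' A fragment is assigned to a gene iff its midpoint, `floor((start+end)/2)`,
#' lies in the gene's transcript span `[tx_start, tx_end)`. Each fragment is
#' assigned to at most one gene; ties among overlapping genes are broken by
#' smallest `tx_start`, then by gene id. Fragments on chromosomes with no
#' genes contribute nothing.
#'
#' @param genes a `gene_models` table (one row per gene).
#' @param frags a `fragment_set`.
#' @return Integer vector of counts named by `gene_id`, in `genes` row order.
#' @export
count_fragments <- function(genes, frags) {
  counts <- integer(nrow(genes))
  names(counts) <- genes$gene_id
  f <- frags$fragments
  if (nrow(f) == 0) return(counts)
  mid <- (f$start + f$end) %/% 2L
  for (chrom in unique(genes$chrom)) {
    gi <- which(genes$chrom == chrom)
    fi <- which(f$chrom == chrom)
    if (length(fi) == 0) next
    q <- IRanges::IRanges(start = mid[fi] + 1L, width = 1L)
    s <- IRanges::IRanges(start = genes$tx_start[gi] + 1L,
                          end = genes$tx_end[gi])
    ov <- IRanges::findOverlaps(q, s)
    if (length(ov) == 0) next
    qh <- S4Vectors::queryHits(ov)
    sh <- S4Vectors::subjectHits(ov)
    # deterministic one-gene-per-fragment resolution
    prio <- order(genes$tx_start[gi], genes$gene_id[gi])
    rank_of <- integer(length(gi))
    rank_of[prio] <- seq_along(gi)
    ord <- order(qh, rank_of[sh])
    keep <- !duplicated(qh[ord])
    hit <- sh[ord][keep]
    tab <- tabulate(hit, nbins = length(gi))
    counts[gi] <- counts[gi] + tab
  }
  counts
}

#' Fragments per kilobase per million mapped
#'
#' Length- and depth-normalized occupancy, computed exactly as for RNA-seq:
#' `count / (gene_length/1000) / (total_mapped/1e6)`.
#'
#' @param count fragment count(s).
#' @param gene_length gene length(s) in bp (TSS to TTS, introns included).
#' @param total_mapped library size (total mapped fragments).
#' @return Numeric FPKM, vectorized over `count`/`gene_length`.
#' @export
fpkm <- function(count, gene_length, total_mapped) {
  if (any(total_mapped <= 0)) stop("total_mapped must be > 0")
  if (any(gene_length <= 0)) stop("gene_length must be > 0")
  count / (gene_length / 1000) / (total_mapped / 1e6)
}

#' Assemble per-gene occupancy records
#'
#' Counts fragments in both conditions, converts to FPKM, and attaches
#' whole-gene-body G+C and (optionally) the RNA log2 fold change. This is the
#' unfiltered record table; apply [filter_genes()] before computing ESKOR.
#'
#' @param genes a `gene_models` table (one row per gene).
#' @param frags_unt,frags_kd `fragment_set`s for the untreated and knockdown
#'   libraries.
#' @param genome a named [Biostrings::DNAStringSet] (used for G+C); pass
#'   `gc` directly to skip sequence work.
#' @param gc optional numeric vector of per-gene G+C percents.
#' @param expr optional expression table with `gene_id`, `rna_fpkm_unt`,
#'   `rna_fpkm_kd`.
#' @param skip_5prime bp excluded downstream of the TSS for gene-body G+C.
#' @return data.frame with one row per gene: gene_id, gene_length, gc,
#'   count_unt, count_kd, fpkm_unt, fpkm_kd and, if `expr` is given,
#'   rna_log2fc.
#' @export
occupancy_table <- function(genes, frags_unt, frags_kd, genome = NULL,
                            gc = NULL, expr = NULL, skip_5prime = 1000L) {
  stopifnot(frags_unt$condition == "UNT", frags_kd$condition == "KD")
  if (is.null(gc)) {
    if (is.null(genome)) stop("provide either `genome` or `gc`")
    gc <- suppressWarnings(whole_gene_gc(genes, genome,
                                         skip_5prime = skip_5prime))
  }
  len <- gene_length(genes)
  cu <- count_fragments(genes, frags_unt)
  ck <- count_fragments(genes, frags_kd)
  out <- data.frame(
    gene_id = genes$gene_id,
    gene_length = len,
    gc = gc,
    count_unt = as.integer(cu),
    count_kd = as.integer(ck),
    fpkm_unt = fpkm(cu, len, frags_unt$total_mapped),
    fpkm_kd = fpkm(ck, len, frags_kd$total_mapped),
    stringsAsFactors = FALSE
  )
  if (!is.null(expr)) {
    fc <- rna_log2fc(expr)
    out$rna_log2fc <- fc[out$gene_id]
  }
  rownames(out) <- NULL
  out
}

#' Gene inclusion filters for the ESKOR analysis
#'
#' Retains genes that (i) are at least `min_length` bp long (TSS to TTS,
#' introns included), (ii) have ChIP FPKM above `min_fpkm` in both
#' conditions, and (iii) are present in the RNA-seq gene list. The number of
#' genes surviving each stage is reported via `message()`.
#'
#' @param records data.frame from [occupancy_table()].
#' @param min_length minimum gene length in bp (default 5000).
#' @param min_fpkm FPKM threshold, exclusive, applied to both conditions
#'   (default 0.5).
#' @param expressed character vector of gene ids present in the RNA-seq
#'   list; `NULL` skips this stage.
#' @return The filtered records with an `eskor` column appended.
#' @export
filter_genes <- function(records, min_length = 5000L, min_fpkm = 0.5,
                         expressed = NULL) {
  n0 <- nrow(records)
  keep_len <- records$gene_length >= min_length & !is.na(records$gc)
  r <- records[keep_len, , drop = FALSE]
  n1 <- nrow(r)
  r <- r[r$fpkm_unt > min_fpkm & r$fpkm_kd > min_fpkm, , drop = FALSE]
  n2 <- nrow(r)
  if (!is.null(expressed)) r <- r[r$gene_id %in% expressed, , drop = FALSE]
  n3 <- nrow(r)
  message(sprintf(
    "filter_genes: %d genes -> %d (length >= %d) -> %d (FPKM > %g both) -> %d (in RNA-seq list)",
    n0, n1, min_length, n2, min_fpkm, n3))
  r$eskor <- eskor(r$fpkm_kd, r$fpkm_unt)
  rownames(r) <- NULL
  r
}

#' ESKOR: effect of knockdown on RNAPII occupancy
#'
#' `log2(fpkm_kd / fpkm_unt)` per gene. Positive values mean more RNAPII-S2
#' occupancy after Supt4h knockdown; zero means no difference.
#'
#' @param fpkm_kd,fpkm_unt positive ChIP FPKM values.
#' @return Numeric vector of log2 ratios.
#' @export
eskor <- function(fpkm_kd, fpkm_unt) {
  if (any(fpkm_kd <= 0) || any(fpkm_unt <= 0)) {
    stop("eskor requires positive FPKM in both conditions (filter first)")
  }
  log2(fpkm_kd / fpkm_unt)
}

#' Convert an ESKOR value to a percent occupancy shift
#'
#' `(2^eskor - 1) * 100`, rounded to the nearest integer percent: the
#' baseline-relative occupancy change implied by a log2 ratio (e.g. -0.25
#' is a -16% shift, +0.24 a +18% shift).
#'
#' @param eskor finite log2 ratio(s).
#' @return Integer percent shift(s).
#' @export
eskor_to_percent_shift <- function(eskor) {
  stopifnot(all(is.finite(eskor)))
  round((2^eskor - 1) * 100)
}

#' Linear trend of occupancy on G+C content
#'
#' Ordinary least squares of per-gene ChIP FPKM (y) on whole-gene-body G+C
#' percent (x) for one condition, as displayed as scatter-plot trendlines.
#'
#' @param records filtered records carrying `gc`, `fpkm_unt`, `fpkm_kd`.
#' @param condition `"UNT"` or `"KD"`.
#' @return List of class `trend_fit` with `slope` (FPKM per G+C percentage
#'   point), `intercept` (FPKM) and `condition`.
#' @export
fit_trend <- function(records, condition = c("UNT", "KD")) {
  condition <- match.arg(condition)
  y <- if (condition == "UNT") records$fpkm_unt else records$fpkm_kd
  x <- records$gc
  if (length(x) < 3) stop("fit_trend needs at least 3 records")
  if (stats::sd(x) == 0) stop("degenerate fit: all G+C values identical")
  co <- stats::coef(stats::lm(y ~ x))
  structure(list(slope = unname(co[2]), intercept = unname(co[1]),
                 condition = condition),
            class = "trend_fit")
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf("<trend_fit %s> FPKM = %.4f + %.4f * GC%%\n",
              x$condition, x$intercept, x$slope))
  invisible(x)
}

#' Percent drop of the occupancy-vs-G+C slope after knockdown
#'
#' `(slope_unt - slope_kd) / slope_unt * 100`, rounded to the nearest integer
#' (e.g. slopes 0.0502 and 0.0328 give a 35% drop).
#'
#' @param fit_unt,fit_kd `trend_fit` objects (or bare numeric slopes).
#' @return Integer percent.
#' @export
slope_drop_percent <- function(fit_unt, fit_kd) {
  s_unt <- if (inherits(fit_unt, "trend_fit")) fit_unt$slope else fit_unt
  s_kd <- if (inherits(fit_kd, "trend_fit")) fit_kd$slope else fit_kd
  if (s_unt == 0) stop("untreated slope is zero: percent drop undefined")
  round((s_unt - s_kd) / s_unt * 100)
}

#' Rank genes by ESKOR and smooth G+C along the ranking
#'
#' Sorts records by ESKOR from high to low and computes a centered moving
#' average of G+C over `window` neighboring genes (the window shrinks
#' symmetrically near the ends so every gene has a smoothed value). Also
#' reports the Pearson product-moment correlation between ESKOR and G+C.
#'
#' @param records filtered records carrying `eskor` and `gc`.
#' @param window number of neighboring genes to average (default 100).
#' @return List with `ranked` (records sorted by ESKOR, plus `eskor_rank`
#'   and `gc_moving_avg`) and `pearson_r`.
#' @export
rank_and_smooth <- function(records, window = 100L) {
  n <- nrow(records)
  if (n < window) {
    warning(sprintf("only %d genes; moving-average window shrunk from %d",
                    n, window))
  }
  ord <- order(-records$eskor, records$gene_id)
  r <- records[ord, , drop = FALSE]
  r$eskor_rank <- seq_len(n)
  half <- (min(window, n) - 1L) %/% 2L
  cs <- cumsum(c(0, r$gc))
  r$gc_moving_avg <- vapply(seq_len(n), function(i) {
    h <- min(half, i - 1L, n - i)
    (cs[i + h + 1L] - cs[i - h]) / (2 * h + 1)
  }, 0)
  if (stats::sd(records$gc) == 0 || stats::sd(records$eskor) == 0) {
    warning("Pearson r undefined: zero variance in ESKOR or G+C")
    pr <- NA_real_
  } else {
    pr <- stats::cor(records$eskor, records$gc, method = "pearson")
  }
  rownames(r) <- NULL
  list(ranked = r, pearson_r = pr)
}

#' RNA log2 fold change (knockdown vs untreated)
#'
#' Plain log2 ratio of RNA FPKM with a small pseudocount guarding zeros:
#' `log2((fpkm_kd + pseudocount) / (fpkm_unt + pseudocount))`.
#'
#' @param expr data.frame with `gene_id`, `rna_fpkm_unt`, `rna_fpkm_kd`.
#' @param pseudocount added to both FPKMs (default 0.01).
#' @return Numeric vector named by `gene_id`.
#' @export
rna_log2fc <- function(expr, pseudocount = 0.01) {
  out <- log2((expr$rna_fpkm_kd + pseudocount) /
                (expr$rna_fpkm_unt + pseudocount))
  names(out) <- expr$gene_id
  out
}
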