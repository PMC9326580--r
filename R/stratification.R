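# Gene-length x G+C stratification of ESKOR and G+C summaries of extreme
# RNA fold-change gene sets, exported as violin-plot-ready tables.

LENGTH_GROUPS <- data.frame(
  label = c("group1", "group2", "group3", "group4"),
  lo = c(5000L, 15000L, 30000L, 70000L),
  hi = c(15000L, 30000L, 70000L, 230000L)
)

GC_RANGES <- data.frame(
  label = c("range1", "range2", "range3"),
  lo = c(45, 50, 55),
  hi = c(50, 55, 60)
)

#' Assign genes to length groups
#'
#' Half-open bins: 5 kb <= group1 < 15 kb <= group2 < 30 kb <= group3 <
#' 70 kb <= group4 < 230 kb. Lengths outside 5-230 kb map to `NA`.
#'
#' @param gene_length gene length(s) in bp.
#' @return Character vector of group labels (or `NA`).
#' @export
assign_length_group <- function(gene_length) {
  idx <- findInterval(gene_length, c(LENGTH_GROUPS$lo, 230000L))
  out <- rep(NA_character_, length(gene_length))
  in_range <- idx >= 1 & idx <= nrow(LENGTH_GROUPS)
  out[in_range] <- LENGTH_GROUPS$label[idx[in_range]]
  out
}

#' Assign genes to G+C ranges
#'
#' Half-open bins: 45% <= range1 < 50% <= range2 < 55% <= range3 < 60%.
#' Values outside 45-60% map to `NA`.
#'
#' @param gc G+C percent value(s).
#' @return Character vector of range labels (or `NA`).
#' @export
assign_gc_range <- function(gc) {
  idx <- findInterval(gc, c(GC_RANGES$lo, 60))
  out <- rep(NA_character_, length(gc))
  in_range <- !is.na(gc) & idx >= 1 & idx <= nrow(GC_RANGES)
  out[in_range] <- GC_RANGES$label[idx[in_range]]
  out
}

stratum_stats <- function(values) {
  if (length(values) == 0) {
    return(list(n = 0L, median = NA_real_, q25 = NA_real_, q75 = NA_real_))
  }
  # type 7: linear interpolation between order statistics
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  list(n = length(values), median = q[2], q25 = q[1], q75 = q[3])
}

#' ESKOR summaries over length-group x G+C-range strata
#'
#' Each gene maps to at most one length group and one G+C range; per
#' stratum the median and quartiles of ESKOR are reported (linear
#' interpolation between order statistics, quantile type 7). Empty strata
#' are reported with `n = 0` and missing statistics. The member values are
#' retained as a list-column for violin rendering.
#'
#' @param records filtered records carrying `gene_length`, `gc`, `eskor`.
#' @return data.frame of 12 rows (4 length groups x 3 G+C ranges).
#' @export
summarize_strata <- function(records) {
  lg <- assign_length_group(records$gene_length)
  gr <- assign_gc_range(records$gc)
  out <- expand.grid(length_group = LENGTH_GROUPS$label,
                     gc_range = GC_RANGES$label,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  stats_list <- lapply(seq_len(nrow(out)), function(i) {
    vals <- records$eskor[!is.na(lg) & !is.na(gr) &
                            lg == out$length_group[i] &
                            gr == out$gc_range[i]]
    c(stratum_stats(vals), list(values = list(vals)))
  })
  out$n <- vapply(stats_list, function(s) s$n, 0L)
  out$median <- vapply(stats_list, function(s) s$median, 0)
  out$q25 <- vapply(stats_list, function(s) s$q25, 0)
  out$q75 <- vapply(stats_list, function(s) s$q75, 0)
  out$values <- I(lapply(stats_list, function(s) s$values[[1]]))
  out
}

#' G+C content of the most up- and down-regulated genes
#'
#' Ranks genes by RNA log2 fold change (ties broken by gene id), takes the
#' top and bottom `k`, and summarizes their G+C content as in
#' [summarize_strata()].
#'
#' @param records records carrying `rna_log2fc` and `gc`.
#' @param k genes per set (default 1000); shrunk to `floor(n/2)` with a
#'   warning when fewer than `2k` records are available.
#' @return data.frame with rows `upregulated` and `downregulated`: n,
#'   median, q25, q75 of G+C plus a `values` list-column.
#' @export
extreme_expression_gc <- function(records, k = 1000L) {
  n <- nrow(records)
  if (2L * k > n) {
    k <- n %/% 2L
    warning(sprintf("fewer than 2k records; k shrunk to %d", k))
  }
  ord_up <- order(-records$rna_log2fc, records$gene_id)
  ord_dn <- order(records$rna_log2fc, records$gene_id)
  sets <- list(upregulated = records$gc[ord_up[seq_len(k)]],
               downregulated = records$gc[ord_dn[seq_len(k)]])
  out <- do.call(rbind, lapply(names(sets), function(nm) {
    s <- stratum_stats(sets[[nm]])
    data.frame(set = nm, n = s$n, median = s$median, q25 = s$q25,
               q75 = s$q75, stringsAsFactors = FALSE)
  }))
  out$values <- I(unname(sets))
  out
}
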