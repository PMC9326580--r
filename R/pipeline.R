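# End-to-end driver: counts -> FPKM -> filters -> ESKOR -> trend fits and
# ranking diagnostics, so analyses and validations run one call.

#' Run the occupancy / ESKOR analysis end to end
#'
#' Builds per-gene occupancy records from the two fragment sets, applies the
#' gene filters, computes ESKOR, fits the occupancy-vs-G+C trendline in both
#' conditions and the percent slope drop, and ranks genes by ESKOR with the
#' smoothed G+C series and Pearson correlation.
#'
#' @param genes a `gene_models` table, one row per gene (after isoform
#'   selection).
#' @param genome a named [Biostrings::DNAStringSet].
#' @param frags_unt,frags_kd `fragment_set`s.
#' @param expr optional RNA table (`gene_id`, `rna_fpkm_unt`,
#'   `rna_fpkm_kd`); when given, its gene list is the RNA-seq inclusion
#'   filter and `rna_log2fc` is attached.
#' @param min_length,min_fpkm gene filters (see [filter_genes()]).
#' @param smooth_window moving-average window in genes.
#' @param skip_5prime bp excluded downstream of the TSS for gene-body G+C.
#' @return List with `records` (filtered, with `eskor`), `fit_unt`,
#'   `fit_kd`, `slope_drop` (percent), `ranked`, `pearson_r`.
#' @export
run_eskor_pipeline <- function(genes, genome, frags_unt, frags_kd,
                               expr = NULL, min_length = 5000L,
                               min_fpkm = 0.5, smooth_window = 100L,
                               skip_5prime = 1000L) {
  records <- occupancy_table(genes, frags_unt, frags_kd, genome = genome,
                             expr = expr, skip_5prime = skip_5prime)
  expressed <- if (is.null(expr)) NULL else expr$gene_id
  records <- filter_genes(records, min_length = min_length,
                          min_fpkm = min_fpkm, expressed = expressed)
  fit_unt <- fit_trend(records, "UNT")
  fit_kd <- fit_trend(records, "KD")
  rs <- rank_and_smooth(records, window = smooth_window)
  list(records = records,
       fit_unt = fit_unt, fit_kd = fit_kd,
       slope_drop = slope_drop_percent(fit_unt, fit_kd),
       ranked = rs$ranked, pearson_r = rs$pearson_r)
}
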