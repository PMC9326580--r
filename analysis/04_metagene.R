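#!/usr/bin/env Rscript
# Metagene profiles: scaled 100-bin gene-body coverage with 1 kb flanks for
# the highest- and lowest-ESKOR gene sets, per condition. Under the default
# simulation the knockdown removes occupancy progressively from TSS to TTS
# in the low-ESKOR (G+C-rich) set, so the knockdown/untreated body-bin
# ratio declines along the gene body.

source("analysis/00_common.R")

ds <- load_dataset()
rec <- utils::read.table(file.path(SIM_DIR, "eskor_records.tsv"),
                         sep = "\t", header = TRUE)
sets <- select_extreme_eskor(rec, k = 2000)
message(sprintf("gene sets: top/bottom %d by ESKOR", sets$k))

rows <- list()
for (set_name in c("high_eskor", "low_eskor")) {
  ids <- if (set_name == "high_eskor") sets$top$gene_id else
    sets$bottom$gene_id
  g <- ds$genes[match(ids, ds$genes$gene_id), ]
  for (cond in c("UNT", "KD")) {
    fr <- if (cond == "UNT") ds$frags_unt else ds$frags_kd
    agg <- aggregate_metagene(metagene_profiles(g, fr, genome = ds$genome))
    rows[[paste(set_name, cond)]] <- data.frame(
      gene_set = set_name, condition = cond,
      bin = seq_along(agg$mean), section = agg$section,
      mean_density = agg$mean, n_genes = agg$n)
  }
}
out <- do.call(rbind, rows)
rownames(out) <- NULL
write_tsv(out, "04_metagene_profiles.tsv")

trend <- function(set_name) {
  u <- out[out$gene_set == set_name & out$condition == "UNT" &
             out$section == "body", "mean_density"]
  k <- out[out$gene_set == set_name & out$condition == "KD" &
             out$section == "body", "mean_density"]
  ct <- suppressWarnings(cor.test(seq_along(u), k / u, method = "spearman"))
  message(sprintf("%s: KD/UNT body-bin ratio Spearman rho = %.3f (p = %.2g)",
                  set_name, ct$estimate, ct$p.value))
}
trend("low_eskor")
trend("high_eskor")
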