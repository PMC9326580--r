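#!/usr/bin/env Rscript
# Stratified views: ESKOR distributions across gene-length groups
# (5-15, 15-30, 30-70, 70-230 kb) within G+C ranges (45-50, 50-55,
# 55-60%), and the G+C content of the most up- and down-regulated genes by
# RNA fold change. With the default simulation's 5'->3' knockdown decay,
# longer G+C-rich genes lose more occupancy, so median ESKOR falls with
# length; RNA changes track occupancy changes, so down-regulated genes are
# G+C-rich.

source("analysis/00_common.R")

rec <- utils::read.table(file.path(SIM_DIR, "eskor_records.tsv"),
                         sep = "\t", header = TRUE)

strata <- summarize_strata(rec)
write_tsv(strata[, c("length_group", "gc_range", "n", "median",
                     "q25", "q75")], "05_eskor_strata.tsv")
for (rng in unique(strata$gc_range)) {
  s <- strata[strata$gc_range == rng, ]
  message(sprintf("G+C %s: median ESKOR by length group: %s",
                  rng, paste(sprintf("%.3f", s$median), collapse = " ")))
}

ext <- extreme_expression_gc(rec, k = 1000)
write_tsv(ext[, c("set", "n", "median", "q25", "q75")],
          "05_extreme_expression_gc.tsv")
message(sprintf(
  "median G+C: %.1f%% (most down-regulated) vs %.1f%% (most up-regulated)",
  ext$median[ext$set == "downregulated"],
  ext$median[ext$set == "upregulated"]))
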