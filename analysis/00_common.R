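# Shared setup for the numbered analysis scripts: paths and the dataset
# loader. Scripts are run from the repository root, in order; 01_simulate.R
# writes the synthetic dataset under scratch/sim/ and later scripts read it
# back through the package's format readers.

library(eskor)

SIM_DIR <- "scratch/sim"
RESULTS_DIR <- "results"
SIM_SEED <- 101L

dir.create(RESULTS_DIR, showWarnings = FALSE, recursive = TRUE)

load_dataset <- function() {
  stopifnot(dir.exists(SIM_DIR))
  genome <- read_genome(file.path(SIM_DIR, "genome.fa"))
  genes <- read_refflat(file.path(SIM_DIR, "genes.refflat"))
  depth <- sim_config(seed = SIM_SEED)$depth
  list(genome = genome,
       genes = genes,
       frags_unt = read_fragments(file.path(SIM_DIR, "unt.bed"), "UNT",
                                  total_mapped = depth),
       frags_kd = read_fragments(file.path(SIM_DIR, "kd.bed"), "KD",
                                 total_mapped = depth),
       expr = read_expression(file.path(SIM_DIR, "expression.tsv")),
       truth = utils::read.table(file.path(SIM_DIR, "truth.tsv"),
                                 sep = "\t", header = TRUE))
}

write_tsv <- function(x, name) {
  path <- file.path(RESULTS_DIR, name)
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  message("wrote ", path)
}
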