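# eskor

Genome-wide dependence of RNA polymerase II template occupancy on G+C
content when DSIF is impaired.

DSIF (the Supt4h–Supt5h heterodimer) clamps elongating RNA polymerase II
(RNAPII) onto the DNA template. This package implements, as a tested and
reusable pipeline, the analysis of how occupancy by the elongating,
Ser2-phosphorylated polymerase (RNAPII-S2, measured by ChIP-seq) depends on
template G+C content after Supt4h knockdown. It is aimed at computational
genomicists who want to run that analysis on their own annotation/fragment
data or to study its statistical behaviour on simulated data.

The per-gene statistic at the core is **ESKOR** (Effect of Supt4h Knockdown
on Occupancy by RNA polymerase):

```
ESKOR_g = log2( FPKM_ChIP[KD, g] / FPKM_ChIP[UNT, g] )
```

with FPKM = fragments per kilobase of gene body (TSS→TTS, introns included)
per million mapped fragments. Around it the package provides:

* **I/O**: refFlat/genePred gene models, BED fragment sets, FASTA genomes
  (via Biostrings), RNA abundance TSVs; most-abundant-isoform selection.
* **G+C profiling**: 100 bp windowed G+C along genes, whole-gene-body G+C
  excluding the first kilobase after the TSS, mono/dinucleotide (CpG, GpC)
  frequencies, and the ESKOR-ordered 10 kb G+C heatmap matrix.
* **Occupancy & ESKOR**: midpoint fragment counting, FPKM, the gene
  inclusion filters (length ≥ 5 kb, ChIP FPKM > 0.5 in both conditions,
  present in the RNA list), occupancy-vs-G+C trendlines and the percent
  slope drop, ESKOR ranking with a 100-gene moving average of G+C, RNA
  log2 fold change.
* **Segments**: per-gene 500 bp segmentation, highest/lowest-G+C segment
  selection, 25 bp-binned normalized counts, cohort means ± SEM and the
  equal-variance t-test.
* **Metagene**: 100-bin scaled gene-body profiles with 1 kb flanks for the
  extreme-ESKOR gene sets.
* **Stratification**: ESKOR distributions over gene-length groups × G+C
  ranges; G+C of the most up-/down-regulated genes.
* **Synthetic data**: a deterministic generator producing genome,
  annotation, paired UNT/KD fragment sets and an RNA table whose occupancy
  is linear in G+C at condition-specific trendline slopes (0.0502 vs
  0.0328 FPKM per G+C point by default), with optional 5′→3′ knockdown
  decay — so the whole pipeline runs and is validated without external
  sequencing data.

See `vignettes/eskor-methods.Rmd` for the model, conventions, parameter
choices and limitations.

## Worked example

Simulate the default study conditions (2000 genes of 5–230 kb, 2×10⁶
fragments per condition; ~30 s) and run the analysis end to end:

```r
library(eskor)

sim <- simulate_dataset(sim_config(seed = 101))
res <- run_eskor_pipeline(sim$genes, sim$genome, sim$frags_unt,
                          sim$frags_kd, expr = sim$expr)
#> filter_genes: 2000 genes -> 2000 (length >= 5000) -> 1935 (FPKM > 0.5 both)
#>   -> 1935 (in RNA-seq list)

res$fit_unt
#> <trend_fit UNT> FPKM = -1.2070 + 0.0497 * GC%
res$fit_kd
#> <trend_fit KD> FPKM = -0.3581 + 0.0326 * GC%
res$slope_drop
#> [1] 34
round(res$pearson_r, 3)
#> [1] -0.545
```

The untreated trendline slope (0.0497 FPKM per G+C percentage point)
recovers the generator's 0.0502; knockdown flattens it to 0.0326 (truth
0.0328), a 34% drop — occupancy gains from G+C-rich templates are lost
when DSIF is reduced. Ranking the 1935 filtered genes by ESKOR and
correlating with gene-body G+C gives Pearson r = −0.545: genes whose
occupancy falls most after knockdown are the G+C-rich ones. An ESKOR of
−0.25 or +0.24 corresponds to a −16% / +18% occupancy shift:

```r
eskor_to_percent_shift(c(-0.25, 0.24))
#> [1] -16  18
```

## Analysis workflow

The numbered scripts under `analysis/` run the complete study on synthetic
data, writing the simulated dataset to `scratch/sim/` (large; regenerated
on demand) and summary tables to `results/`:

```sh
Rscript analysis/01_simulate.R        # genome, annotation, fragments, RNA
Rscript analysis/02_occupancy_eskor.R # FPKM, filters, ESKOR, trendlines
Rscript analysis/03_segments.R        # extreme-G+C 500 bp segment contrast
Rscript analysis/04_metagene.R        # scaled metagene profiles
Rscript analysis/05_stratification.R  # length x G+C strata, RNA extremes
```

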