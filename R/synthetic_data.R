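# Synthetic genome / annotation / ChIP-fragment / expression generator.
#
# The generator emulates the signal structure the occupancy analysis
# assumes: per-gene expected ChIP FPKM linear in whole-gene-body G+C at a
# condition-specific slope, Poisson fragment counts at a stated library
# size, optional 5'->3' placement decay under knockdown for G+C-rich genes,
# optional within-gene attenuation of occupancy in locally G+C-rich blocks,
# and RNA fold changes coupled to the expected occupancy change.

#' Simulation configuration
#'
#' Defaults correspond to the desk-scale study conditions every
#' downstream validation uses. Key parameters:
#'
#' * `n_genes`, `length_range` (bp, log-uniform), `gc_range` (percent,
#'   uniform per gene).
#' * `block_bp`, `block_gc_sd`: within-gene G+C block structure; each gene's
#'   sequence is drawn per base with P(G or C) equal to its block's G+C,
#'   blocks jittered around the gene target so each gene has distinct
#'   highest/lowest 500 bp segments.
#' * `slope_unt` = 0.0502 and `slope_kd` = 0.0328 FPKM per G+C percentage
#'   point: the occupancy-vs-G+C trendline slopes being emulated.
#'   `intercept_kd` defaults so the two lines cross at `gc_pivot` (per
#'   -million library normalization cancels a global occupancy shift, so
#'   knockdown raises apparent FPKM below the pivot and lowers it above).
#' * `decay`: knockdown positional decay, per kb of transcription distance
#'   per G+C point above `gc_pivot`; redistributes fragments 5'->3' within
#'   a gene without changing its count.
#' * `kd_local_mult`: multiplier (< 1 to activate) on knockdown occupancy of
#'   blocks whose local G+C exceeds `local_gc_threshold`; unlike `decay`
#'   this removes fragments, lowering the gene's expected count.
#' * `depth`: total mapped fragments per condition (library size);
#'   `background_frac` of it is placed uniformly genome-wide.
#' * `rna_coupling`, `rna_noise_sd`: RNA fold change per gene is
#'   `2^(coupling * expected_eskor + noise)`.
#'
#' @param n_genes number of genes.
#' @param length_range gene length range in bp (log-uniform).
#' @param gc_range per-gene target G+C range in percent (uniform).
#' @param block_bp,block_gc_sd G+C block length and jitter SD.
#' @param slope_unt,slope_kd FPKM per G+C percentage point.
#' @param intercept_unt FPKM intercept of the untreated trend.
#' @param intercept_kd FPKM intercept of the knockdown trend; `NULL` places
#'   the crossing at `gc_pivot`.
#' @param gc_pivot G+C percent where the condition trends cross; also the
#'   pivot of the positional decay.
#' @param decay knockdown positional decay rate (per kb per G+C point).
#' @param kd_local_mult,local_gc_threshold within-gene knockdown
#'   attenuation of locally G+C-rich blocks (1 = off).
#' @param depth total mapped fragments per condition.
#' @param background_frac fraction of `depth` placed uniformly genome-wide.
#' @param fragment_bp fragment length (even).
#' @param fpkm_floor lower bound on expected FPKM.
#' @param rna_coupling,rna_noise_sd RNA fold-change coupling to expected
#'   ESKOR and its log2 noise SD.
#' @param rna_baseline_meanlog,rna_baseline_sdlog log-normal baseline RNA
#'   FPKM parameters.
#' @param rna_library RNA library size used to derive raw counts.
#' @param gap_bp minimum gap between genes and to chromosome ends.
#' @param chrom_target_bp approximate chromosome size before a new
#'   chromosome is started.
#' @param seed integer seed; identical configs give byte-identical outputs.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000L,
                       length_range = c(5000L, 230000L),
                       gc_range = c(35, 65),
                       block_bp = 500L,
                       block_gc_sd = 6,
                       slope_unt = 0.0502,
                       slope_kd = 0.0328,
                       intercept_unt = -1.4,
                       intercept_kd = NULL,
                       gc_pivot = 50,
                       decay = 0.002,
                       kd_local_mult = 1,
                       local_gc_threshold = 55,
                       depth = 2e6,
                       background_frac = 0.02,
                       fragment_bp = 200L,
                       fpkm_floor = 0.05,
                       rna_coupling = 1,
                       rna_noise_sd = 0.05,
                       rna_baseline_meanlog = log(20),
                       rna_baseline_sdlog = 1,
                       rna_library = 2e7,
                       gap_bp = 2000L,
                       chrom_target_bp = 3e7,
                       seed = 1L) {
  if (is.null(intercept_kd)) {
    intercept_kd <- intercept_unt + (slope_unt - slope_kd) * gc_pivot
  }
  cfg <- list(n_genes = as.integer(n_genes),
              length_range = as.numeric(length_range),
              gc_range = as.numeric(gc_range),
              block_bp = as.integer(block_bp), block_gc_sd = block_gc_sd,
              slope_unt = slope_unt, slope_kd = slope_kd,
              intercept_unt = intercept_unt, intercept_kd = intercept_kd,
              gc_pivot = gc_pivot, decay = decay,
              kd_local_mult = kd_local_mult,
              local_gc_threshold = local_gc_threshold,
              depth = depth, background_frac = background_frac,
              fragment_bp = as.integer(fragment_bp),
              fpkm_floor = fpkm_floor,
              rna_coupling = rna_coupling, rna_noise_sd = rna_noise_sd,
              rna_baseline_meanlog = rna_baseline_meanlog,
              rna_baseline_sdlog = rna_baseline_sdlog,
              rna_library = rna_library,
              gap_bp = as.integer(gap_bp),
              chrom_target_bp = chrom_target_bp,
              seed = as.integer(seed))
  stopifnot(cfg$n_genes >= 1,
            cfg$length_range[1] <= cfg$length_range[2],
            cfg$gc_range[1] <= cfg$gc_range[2],
            cfg$slope_unt >= 0, cfg$slope_kd >= 0,
            cfg$depth > 0, cfg$fragment_bp %% 2 == 0,
            cfg$kd_local_mult > 0, cfg$kd_local_mult <= 1)
  class(cfg) <- "sim_config"
  cfg
}

# one gene's sense-strand sequence from its per-block G+C percents
draw_gene_seq <- function(block_gc, block_bp, len) {
  p <- rep(block_gc / 100, each = block_bp)[seq_len(len)]
  u1 <- stats::runif(len)
  u2 <- stats::runif(len)
  lut <- charToRaw("ATGC")
  idx <- 1L + (u2 >= 0.5) + 2L * (u1 < p)
  rawToChar(lut[idx])
}

draw_uniform_seq <- function(len) {
  rawToChar(charToRaw("ACGT")[sample.int(4L, len, replace = TRUE)])
}

block_lengths <- function(len, block_bp) {
  n_blocks <- ceiling(len / block_bp)
  c(rep(block_bp, n_blocks - 1L), len - (n_blocks - 1L) * block_bp)
}

#' Simulate a genome and annotation
#'
#' Draws gene lengths (log-uniform), per-gene target G+C (uniform) and
#' per-block G+C (normal jitter around the target, clamped to 1-99%), then
#' generates each gene's sense-strand sequence per base and packs genes
#' onto chromosomes with at least `gap_bp` of uniform-composition spacer
#' between genes and at the ends. Strands are assigned at random; each gene
#' has a single isoform spanning its whole body.
#'
#' @param config a [sim_config()].
#' @return List with `genome` ([Biostrings::DNAStringSet]), `genes`
#'   (`gene_models`), `truth` (per-gene target and realized whole-gene-body
#'   G+C), `blocks` (per-gene block G+C, transcription order) and `config`.
#' @export
simulate_genome <- function(config) {
  set.seed(config$seed)
  n <- config$n_genes
  len <- as.integer(round(exp(stats::runif(
    n, log(config$length_range[1]), log(config$length_range[2])))))
  target_gc <- stats::runif(n, config$gc_range[1], config$gc_range[2])
  strand <- sample(c("+", "-"), n, replace = TRUE)
  blocks <- vector("list", n)
  seqs <- character(n)
  for (i in seq_len(n)) {
    n_blocks <- ceiling(len[i] / config$block_bp)
    bg <- target_gc[i] + stats::rnorm(n_blocks, 0, config$block_gc_sd)
    bg <- pmin(pmax(bg, 1), 99)
    blocks[[i]] <- bg
    seqs[i] <- draw_gene_seq(bg, config$block_bp, len[i])
  }
  # pack genes onto chromosomes
  gap <- config$gap_bp
  chrom_id <- integer(n)
  tx_start <- integer(n)
  cur_chrom <- 1L
  cur_pos <- gap
  chrom_parts <- list(list(draw_uniform_seq(gap)))
  for (i in seq_len(n)) {
    if (cur_pos + len[i] + gap > config$chrom_target_bp && cur_pos > gap) {
      cur_chrom <- cur_chrom + 1L
      cur_pos <- gap
      chrom_parts[[cur_chrom]] <- list(draw_uniform_seq(gap))
    }
    chrom_id[i] <- cur_chrom
    tx_start[i] <- cur_pos
    s <- seqs[i]
    if (strand[i] == "-") {
      s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    }
    chrom_parts[[cur_chrom]] <- c(chrom_parts[[cur_chrom]],
                                  list(s, draw_uniform_seq(gap)))
    cur_pos <- cur_pos + len[i] + gap
  }
  chrom_seq <- vapply(chrom_parts, function(p) paste0(unlist(p), collapse = ""),
                      "")
  genome <- Biostrings::DNAStringSet(chrom_seq)
  names(genome) <- paste0("chrS", seq_along(chrom_seq))
  gene_id <- sprintf("SG%04d", seq_len(n))
  genes <- gene_models(gene_id, paste0(gene_id, ".1"),
                       paste0("chrS", chrom_id), strand,
                       tx_start, tx_start + len)
  realized_gc <- whole_gene_gc(genes, genome)
  truth <- data.frame(gene_id = gene_id, strand = strand,
                      gene_length = len, target_gc = target_gc,
                      realized_gc = realized_gc, stringsAsFactors = FALSE)
  list(genome = genome, genes = genes, truth = truth, blocks = blocks,
       config = config)
}

expected_fpkm <- function(config, gc, condition) {
  slope <- if (condition == "UNT") config$slope_unt else config$slope_kd
  intercept <- if (condition == "UNT") config$intercept_unt else
    config$intercept_kd
  pmax(intercept + slope * gc, config$fpkm_floor)
}

# per-gene knockdown placement weights over blocks (transcription order)
# and the count multiplier from local attenuation
kd_block_weights <- function(config, gene_gc, block_gc, block_len) {
  x_kb <- (cumsum(block_len) - block_len / 2) / 1000
  rate <- config$decay * max(0, gene_gc - config$gc_pivot)
  w_pos <- exp(-rate * x_kb)
  w_local <- ifelse(block_gc > config$local_gc_threshold,
                    config$kd_local_mult, 1)
  list(placement = w_pos * w_local * block_len,
       count_mult = sum(w_local * block_len) / sum(block_len))
}

#' Expected per-gene occupancy under a configuration
#'
#' The noise-free per-gene expectations implied by a [sim_config()]:
#' expected FPKM per condition (knockdown including the local-attenuation
#' count multiplier) and the expected ESKOR.
#'
#' @param config a [sim_config()].
#' @param sim output of [simulate_genome()].
#' @return data.frame with gene_id, expected_fpkm_unt, expected_fpkm_kd,
#'   expected_eskor.
#' @export
expected_occupancy <- function(config, sim) {
  gc <- sim$truth$realized_gc
  fu <- expected_fpkm(config, gc, "UNT")
  fk <- expected_fpkm(config, gc, "KD")
  mult <- vapply(seq_len(nrow(sim$truth)), function(i) {
    bl <- block_lengths(sim$truth$gene_length[i], config$block_bp)
    kd_block_weights(config, gc[i], sim$blocks[[i]], bl)$count_mult
  }, 0)
  data.frame(gene_id = sim$truth$gene_id,
             expected_fpkm_unt = fu,
             expected_fpkm_kd = fk * mult,
             expected_eskor = log2(fk * mult / fu),
             stringsAsFactors = FALSE)
}

#' Simulate ChIP fragment sets for both conditions
#'
#' Per gene and condition the fragment count is Poisson with mean
#' `expected FPKM x length_kb x depth_millions` (knockdown additionally
#' multiplied by the local-attenuation factor). Untreated fragments are
#' placed with uniform midpoints along the gene body; knockdown midpoints
#' follow the block placement weights (positional decay times local
#' attenuation). A `background_frac` of `depth` is placed uniformly
#' genome-wide in each condition. `total_mapped` is set to `depth`.
#'
#' @param config a [sim_config()].
#' @param sim output of [simulate_genome()].
#' @return List with `unt` and `kd` `fragment_set`s.
#' @export
simulate_fragments <- function(config, sim) {
  set.seed(config$seed + 1L)
  genes <- sim$genes
  gc <- sim$truth$realized_gc
  len <- sim$truth$gene_length
  depth_m <- config$depth / 1e6
  half <- config$fragment_bp %/% 2L
  exp_occ <- expected_occupancy(config, sim)
  out <- list()
  for (condition in c("UNT", "KD")) {
    lambda <- if (condition == "UNT") exp_occ$expected_fpkm_unt else
      exp_occ$expected_fpkm_kd
    n_i <- stats::rpois(length(lambda), lambda * (len / 1000) * depth_m)
    mids <- vector("list", length(n_i) + 1L)
    for (i in seq_along(n_i)) {
      if (n_i[i] == 0) next
      if (condition == "UNT" ||
          (config$decay == 0 && config$kd_local_mult == 1)) {
        t_off <- floor(stats::runif(n_i[i]) * len[i])
      } else {
        bl <- block_lengths(len[i], config$block_bp)
        w <- kd_block_weights(config, gc[i], sim$blocks[[i]], bl)$placement
        b <- sample.int(length(bl), n_i[i], replace = TRUE, prob = w)
        t_off <- (b - 1L) * config$block_bp +
          floor(stats::runif(n_i[i]) * bl[b])
      }
      m <- if (genes$strand[i] == "+") genes$tx_start[i] + t_off else
        genes$tx_end[i] - 1L - t_off
      mids[[i]] <- data.frame(chrom = genes$chrom[i], start = m - half,
                              stringsAsFactors = FALSE)
    }
    # uniform genome-wide background
    n_bg <- stats::rpois(1, config$background_frac * config$depth)
    clens <- Biostrings::width(sim$genome)
    bchrom <- sample.int(length(clens), n_bg, replace = TRUE,
                         prob = clens)
    bpos <- floor(stats::runif(n_bg) * (clens[bchrom] - 2L * half)) + half
    mids[[length(n_i) + 1L]] <- data.frame(
      chrom = names(sim$genome)[bchrom], start = bpos - half,
      stringsAsFactors = FALSE)
    f <- do.call(rbind, mids)
    f$end <- f$start + config$fragment_bp
    out[[tolower(condition)]] <- fragment_set(
      f, condition = condition, total_mapped = config$depth)
  }
  out
}

#' Simulate an RNA abundance table
#'
#' Baseline untreated FPKM is log-normal; knockdown FPKM multiplies the
#' baseline by `2^(rna_coupling * expected_eskor + noise)` so expression
#' changes track the expected occupancy change. Raw counts are Poisson at
#' the stated RNA library size.
#'
#' @param config a [sim_config()].
#' @param sim output of [simulate_genome()].
#' @return data.frame with gene_id, isoform_id, rna_fpkm_unt, rna_fpkm_kd,
#'   count_unt, count_kd.
#' @export
simulate_expression <- function(config, sim) {
  set.seed(config$seed + 2L)
  exp_occ <- expected_occupancy(config, sim)
  n <- nrow(exp_occ)
  base <- stats::rlnorm(n, config$rna_baseline_meanlog,
                        config$rna_baseline_sdlog)
  noise <- stats::rnorm(n, 0, config$rna_noise_sd)
  fc <- 2^(config$rna_coupling * exp_occ$expected_eskor + noise)
  fpkm_kd <- base * fc
  len_kb <- sim$truth$gene_length / 1000
  lib_m <- config$rna_library / 1e6
  data.frame(gene_id = sim$truth$gene_id,
             isoform_id = sim$genes$isoform_id,
             rna_fpkm_unt = base, rna_fpkm_kd = fpkm_kd,
             count_unt = stats::rpois(n, base * len_kb * lib_m),
             count_kd = stats::rpois(n, fpkm_kd * len_kb * lib_m),
             stringsAsFactors = FALSE)
}

#' Simulate a complete dataset
#'
#' Genome and annotation, fragment sets for both conditions, RNA table, and
#' a per-gene truth table carrying the noise-free expectations for
#' parameter-recovery checks.
#'
#' @param config a [sim_config()].
#' @return List with `genome`, `genes`, `frags_unt`, `frags_kd`, `expr`,
#'   `truth` and `config`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  sim <- simulate_genome(config)
  frags <- simulate_fragments(config, sim)
  expr <- simulate_expression(config, sim)
  truth <- merge(sim$truth, expected_occupancy(config, sim), by = "gene_id",
                 sort = FALSE)
  list(genome = sim$genome, genes = sim$genes,
       frags_unt = frags$unt, frags_kd = frags$kd,
       expr = expr, truth = truth, blocks = sim$blocks, config = config)
}

#' Write a simulated dataset to plain-text files
#'
#' Emits `genome.fa`, `genes.refflat`, `unt.bed`, `kd.bed`,
#' `expression.tsv` and `truth.tsv` under `dir`.
#'
#' @param sim output of [simulate_dataset()].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_genome(sim$genome, file.path(dir, "genome.fa"))
  write_refflat(sim$genes, file.path(dir, "genes.refflat"))
  write_fragments(sim$frags_unt, file.path(dir, "unt.bed"))
  write_fragments(sim$frags_kd, file.path(dir, "kd.bed"))
  write_expression(sim$expr, file.path(dir, "expression.tsv"))
  utils::write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
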