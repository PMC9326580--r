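# 500 bp segmentation, extreme-G+C segment selection, binned counts and the
# equal-variance t-test.

test_that("segmentation tiles the body past the offset, strand aware", {
  g <- toy_gene(tx_end = 3000L)
  s <- segment_gene(g)
  expect_equal(nrow(s), 4)
  expect_equal(s$start0, c(1000L, 1500L, 2000L, 2500L))
  expect_equal(s$end0, c(1500L, 2000L, 2500L, 3000L))
  # too-short gene excluded with a warning
  expect_warning(s0 <- segment_gene(toy_gene(tx_end = 1499L)), "excluded")
  expect_equal(nrow(s0), 0)
  # minus strand: segments advance leftward from tx_end - offset
  gm <- toy_gene(strand = "-", tx_start = 0L, tx_end = 10000L)
  sm <- segment_gene(gm)
  expect_equal(sm$end0[1], 9000L)
  expect_equal(sm$start0[1], 8500L)
  expect_equal(nrow(sm), 18)
  expect_equal(sm$start0[18], 0L)
})

test_that("extreme segments are the G+C argmax/argmin, 5'-most on ties", {
  chr <- paste0(strrep("A", 1000),               # offset
                paste(rep(c("AT", "GC", "AG"), each = 250), collapse = ""))
  genome <- toy_genome(chr1 = chr)
  g <- toy_gene(tx_end = 2500L)
  segs <- segment_gene(g)
  ex <- pick_extreme_segments(g, segs, genome)
  expect_equal(ex$highest$seg_index, 2L)   # all-GC segment
  expect_equal(ex$lowest$seg_index, 1L)    # all-AT segment
  expect_false(ex$degenerate)
  # all segments equal: both picks are the 5'-most, flagged degenerate
  gu <- toy_gene(tx_end = 2500L)
  exu <- pick_extreme_segments(gu, segment_gene(gu),
                               toy_genome(chr1 = strrep("G", 2500)))
  expect_equal(exu$highest$seg_index, 1L)
  expect_equal(exu$lowest$seg_index, 1L)
  expect_true(exu$degenerate)
  expect_error(pick_extreme_segments(g, segs[1, ], genome), ">= 2")
})

test_that("segment G+C matches a brute-force recount on random genes", {
  set.seed(31)
  for (rep in 1:20) {
    chr <- random_seq(8000)
    genome <- toy_genome(chr1 = chr)
    strand <- sample(c("+", "-"), 1)
    g <- toy_gene(strand = strand, tx_start = 200L,
                  tx_end = 200L + sample(2000:7000, 1))
    segs <- segment_gene(g)
    ex <- pick_extreme_segments(g, segs, genome)
    gc_bf <- vapply(seq_len(nrow(segs)), function(i) {
      bf_region_gc(chr, segs$start0[i], segs$end0[i])
    }, 0)
    expect_equal(ex$highest$seg_index, which.max(gc_bf))
    expect_equal(ex$lowest$seg_index, which.min(gc_bf))
    expect_equal(ex$highest$gc, max(gc_bf))
  }
})

test_that("binned counts place midpoints and normalize per million", {
  g <- toy_gene(tx_end = 3000L)
  seg <- data.frame(start0 = 1000L, end0 = 1500L)
  # one fragment, midpoint 1060 -> bin 3 of 20
  fs <- toy_frags("chr1", 960L, 1160L, total_mapped = 1e6)
  b <- binned_normalized_counts(g, seg, fs)
  expect_equal(b[3], 1.0)
  expect_equal(sum(b), 1.0)
  # empty set
  empty <- fragment_set(data.frame(chrom = character(0), start = integer(0),
                                   end = integer(0)), "UNT", total_mapped = 1e6)
  expect_equal(binned_normalized_counts(g, seg, empty), rep(0, 20))
  expect_error(binned_normalized_counts(g, seg, fs, bin = 33), "divisible")
})

test_that("binned counts equal the brute-force midpoint histogram", {
  set.seed(32)
  for (rep in 1:20) {
    strand <- sample(c("+", "-"), 1)
    g <- toy_gene(strand = strand, tx_end = 5000L)
    start0 <- sample(seq(0L, 4500L, by = 25L), 1)
    seg <- data.frame(start0 = start0, end0 = start0 + 500L)
    fstart <- sample.int(5000, 500, replace = TRUE) - 1L
    fs <- toy_frags("chr1", fstart, fstart + 150L, total_mapped = 2e6)
    mids <- (2 * fstart + 150L) %/% 2
    bf <- bf_bin_hist(mids, seg$start0, seg$end0, strand, 25) / 2
    expect_equal(binned_normalized_counts(g, seg, fs), bf)
    # count conservation: totals recover the raw midpoint count
    expect_equal(sum(binned_normalized_counts(g, seg, fs)) * 2,
                 sum(mids >= seg$start0 & mids < seg$end0))
  }
})

test_that("cohort aggregation returns mean, SEM and n", {
  profiles <- data.frame(
    gene_id = c("a", "b"), role = "highest_gc", degenerate = FALSE,
    total_unt = c(1, 3), total_kd = c(2, 2))
  agg <- aggregate_cohort(profiles, "highest_gc", "UNT")
  expect_equal(agg$mean, 2)
  expect_equal(agg$sem, 1)
  expect_equal(agg$n, 2)
  expect_equal(aggregate_cohort(profiles, "highest_gc", "KD")$sem, 0)
  expect_error(aggregate_cohort(profiles[1, ], "highest_gc", "UNT"),
               "at least 2")
})

test_that("cohort means recover a known Poisson rate", {
  set.seed(33)
  lambda <- 4
  total <- 2e6
  n <- 400
  profiles <- data.frame(
    gene_id = sprintf("g%03d", 1:n), role = "highest_gc", degenerate = FALSE,
    total_unt = rpois(n, lambda) / (total / 1e6),
    total_kd = rpois(n, lambda) / (total / 1e6))
  agg <- aggregate_cohort(profiles, "highest_gc", "UNT")
  expect_lt(abs(agg$mean - lambda / (total / 1e6)), 3 * agg$sem)
})

test_that("the equal-variance t-test handles degenerate samples", {
  ht <- ttest_equal_var(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ht$t, 0)
  expect_equal(ht$p, 1)
  expect_error(ttest_equal_var(c(0, 0), c(10, 10)), "zero pooled variance")
  expect_equal(ttest_equal_var(c(5, 5), c(5, 5))$p, 1)
  expect_error(ttest_equal_var(1, c(1, 2)), ">= 2")
  # pooled t with nx + ny - 2 df on a hand-checked case
  ht2 <- ttest_equal_var(c(1, 2, 3, 4), c(3, 4, 5))
  expect_equal(ht2$df, 5)
  sp2 <- (3 * var(c(1, 2, 3, 4)) + 2 * var(c(3, 4, 5))) / 5
  t_manual <- (2.5 - 4) / sqrt(sp2 * (1 / 4 + 1 / 3))
  expect_equal(ht2$t, t_manual)
  expect_equal(ht2$p, 2 * pt(t_manual, 5))
})

test_that("segment profiles contrast high- vs low-G+C occupancy loss", {
  # knockdown confined to locally G+C-rich blocks: highest-G+C segments lose
  # occupancy, lowest-G+C segments do not
  cfg <- sim_config(n_genes = 150, length_range = c(6000, 20000),
                    slope_kd = 0.0502, decay = 0, kd_local_mult = 0.5,
                    local_gc_threshold = 55, depth = 1e6, seed = 34L)
  sim <- simulate_dataset(cfg)
  prof <- segment_profiles(sim$genes, sim$genome, sim$frags_unt, sim$frags_kd)
  expect_setequal(unique(prof$role), c("highest_gc", "lowest_gc"))
  hi <- prof[prof$role == "highest_gc", ]
  lo <- prof[prof$role == "lowest_gc", ]
  expect_true(all(hi$segment_gc >= lo$segment_gc))
  ctr <- segment_contrast(prof)
  hi_row <- ctr[ctr$role == "highest_gc", ]
  lo_row <- ctr[ctr$role == "lowest_gc", ]
  expect_gt(hi_row$mean_unt - hi_row$mean_kd,
            lo_row$mean_unt - lo_row$mean_kd)
})
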