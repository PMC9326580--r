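# Midpoint counting, FPKM, gene filters, ESKOR and its diagnostics.

test_that("fragments are assigned by midpoint with half-open bounds", {
  g <- toy_gene(tx_start = 100L, tx_end = 600L)
  # midpoint 250 inside; midpoint exactly at tx_end excluded; at tx_start in
  fs <- toy_frags("chr1", c(150L, 500L, 0L), c(350L, 700L, 200L))
  expect_equal(unname(count_fragments(g, fs)), 2L)
  # different chromosome contributes nothing; empty set gives zeros
  expect_equal(unname(count_fragments(g, toy_frags("chrX", 150L, 350L))), 0L)
  empty <- fragment_set(data.frame(chrom = character(0), start = integer(0),
                                   end = integer(0)), "UNT", total_mapped = 1)
  expect_equal(unname(count_fragments(g, empty)), 0L)
})

test_that("overlapping genes split fragments deterministically", {
  genes <- gene_models(c("b_gene", "a_gene"), c("b.1", "a.1"), "chr1", "+",
                       c(0L, 0L), c(1000L, 1000L))
  fs <- toy_frags("chr1", c(100L, 200L), c(300L, 400L))
  cts <- count_fragments(genes, fs)
  # same tx_start: gene id breaks the tie; every fragment counted once
  expect_equal(unname(cts[c("a_gene", "b_gene")]), c(2L, 0L))
  expect_equal(sum(cts), nrow(fs$fragments))
})

test_that("counting matches the brute-force per-fragment scan", {
  set.seed(21)
  for (rep in 1:20) {
    n_genes <- sample(3:10, 1)
    starts <- sort(sample.int(50000, n_genes))
    lens <- sample(500:5000, n_genes, replace = TRUE)
    genes <- gene_models(sprintf("g%02d", 1:n_genes),
                         sprintf("g%02d.1", 1:n_genes),
                         sample(c("c1", "c2"), n_genes, TRUE),
                         sample(c("+", "-"), n_genes, TRUE),
                         starts, starts + lens)
    fstart <- sample.int(60000, 1000, replace = TRUE)
    fr <- data.frame(chrom = sample(c("c1", "c2", "c3"), 1000, TRUE),
                     start = fstart, end = fstart + 200L)
    fs <- fragment_set(fr, "UNT")
    expect_equal(count_fragments(genes, fs), bf_count_fragments(genes, fr))
  }
})

test_that("count conservation holds against the fragment total", {
  set.seed(22)
  starts <- c(0L, 30000L)
  genes <- gene_models(c("g1", "g2"), c("g1.1", "g2.1"), "c1", "+",
                       starts, starts + 10000L)
  fstart <- sample.int(50000, 500, replace = TRUE)
  fs <- toy_frags("c1", fstart, fstart + 100L)
  cts <- count_fragments(genes, fs)
  mids <- (fstart + fstart + 100L) %/% 2
  inside <- sum((mids >= 0 & mids < 10000) | (mids >= 30000 & mids < 40000))
  expect_equal(sum(cts), inside)
  expect_lte(sum(cts), nrow(fs$fragments))
})

test_that("FPKM does the stated arithmetic and is scale invariant", {
  expect_equal(fpkm(10, 10000, 1e6), 1.0)
  expect_equal(fpkm(0, 10000, 1e6), 0.0)
  expect_equal(fpkm(66, 2500, 4e6), 6.6)   # 66 / 2.5 / 4
  expect_error(fpkm(10, 10000, 0), "total_mapped")
  k <- 7.5
  expect_equal(fpkm(66 * k, 2500, 4e6 * k), fpkm(66, 2500, 4e6))
})

test_that("gene filters apply the three predicates and log counts", {
  rec <- data.frame(
    gene_id = c("a", "b", "c", "d", "e"),
    gene_length = c(10000, 4999, 10000, 10000, 10000),
    gc = c(50, 50, 50, 50, 50),
    fpkm_unt = c(0.6, 2, 0.6, 0.4, 2),
    fpkm_kd = c(0.4, 2, 0.7, 0.6, 2)
  )
  expressed <- c("a", "b", "c", "d")
  msgs <- capture_messages(
    out <- filter_genes(rec, expressed = expressed))
  # a: KD FPKM below threshold; b: short; e: not in RNA list
  expect_equal(out$gene_id, "c")
  expect_match(msgs, "5 genes -> 4 .* -> 2 .* -> 1", all = FALSE)
  # brute-force predicate oracle on a random cohort
  set.seed(23)
  rec2 <- data.frame(gene_id = sprintf("g%03d", 1:200),
                     gene_length = sample(3000:8000, 200, TRUE),
                     gc = runif(200, 40, 60),
                     fpkm_unt = runif(200, 0, 2),
                     fpkm_kd = runif(200, 0, 2))
  expr_ids <- sample(rec2$gene_id, 150)
  out2 <- suppressMessages(filter_genes(rec2, expressed = expr_ids))
  manual <- rec2$gene_id[rec2$gene_length >= 5000 & rec2$fpkm_unt > 0.5 &
                           rec2$fpkm_kd > 0.5 & rec2$gene_id %in% expr_ids]
  expect_equal(out2$gene_id, manual)
})

test_that("ESKOR is the log2 FPKM ratio with guarded domain", {
  expect_equal(eskor(2, 1), 1)
  expect_equal(eskor(1, 1), 0)                       # no difference
  expect_equal(eskor(0.84, 1), log2(0.84))           # -0.2515388...
  expect_error(eskor(0, 1), "positive")
  # antisymmetry: swapping condition labels negates every value
  set.seed(24)
  a <- runif(50, 0.1, 5); b <- runif(50, 0.1, 5)
  expect_equal(eskor(a, b), -eskor(b, a))
})

test_that("percent shift reproduces the worked examples and is monotone", {
  expect_equal(eskor_to_percent_shift(-0.25), -16)
  expect_equal(eskor_to_percent_shift(0.24), 18)
  expect_equal(eskor_to_percent_shift(0), 0)
  x <- seq(-2, 2, by = 0.01)
  expect_true(all(diff(eskor_to_percent_shift(x)) >= 0))
})

test_that("trend fits recover exact lines and reject degenerate input", {
  rec <- data.frame(gc = c(40, 50, 60), fpkm_unt = c(1, 2, 3),
                    fpkm_kd = c(3, 3, 3))
  f <- fit_trend(rec, "UNT")
  expect_equal(f$slope, 0.1)
  expect_equal(f$intercept, -3)
  expect_equal(fit_trend(rec, "KD")$slope, 0)
  rec$gc <- 50
  expect_error(fit_trend(rec, "UNT"), "degenerate")
  expect_error(fit_trend(rec[1:2, ], "UNT"), "3 records")
})

test_that("slope drop percent matches the printed arithmetic", {
  expect_equal(slope_drop_percent(0.0502, 0.0328), 35)
  expect_equal(slope_drop_percent(0.1, 0.1), 0)
  expect_equal(slope_drop_percent(0.10, 0.05), 50)
  expect_error(slope_drop_percent(0, 0.1), "zero")
})

test_that("ranking smooths G+C over a centered shrinking window", {
  rec <- data.frame(gene_id = c("a", "b", "c"), gc = c(60, 50, 40),
                    eskor = c(3, 2, 1))
  rs <- suppressWarnings(rank_and_smooth(rec, window = 3))
  expect_equal(rs$ranked$gene_id, c("a", "b", "c"))
  expect_equal(rs$ranked$gc_moving_avg, c(60, 50, 40))  # edges shrink to 1
  expect_equal(rs$pearson_r, 1)
  # centered window of 3 genes averages the middle
  rec5 <- data.frame(gene_id = letters[1:5], gc = c(10, 20, 60, 40, 30),
                     eskor = 5:1)
  rs5 <- suppressWarnings(rank_and_smooth(rec5, window = 3))
  expect_equal(rs5$ranked$gc_moving_avg, c(10, 30, 40, 130 / 3, 30))
  # degenerate G+C: correlation undefined
  rec$gc <- 50
  expect_warning(rs0 <- rank_and_smooth(rec, window = 3), "undefined")
  expect_true(is.na(rs0$pearson_r))
})

test_that("RNA log2 fold change matches the printed knockdown example", {
  expr <- data.frame(gene_id = c("Supt4h", "flat", "silent"),
                     rna_fpkm_unt = c(66.78, 3, 0),
                     rna_fpkm_kd = c(12.05, 3, 0))
  fc <- rna_log2fc(expr)
  expect_equal(unname(fc["Supt4h"]), log2(12.06 / 66.79))
  expect_equal(unname(fc["flat"]), 0)
  expect_equal(unname(fc["silent"]), 0)  # pseudocount guards 0/0
  # the knockdown leaves 18% of the initial mRNA concentration
  expect_equal(round(12.05 / 66.78 * 100), 18)
})
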