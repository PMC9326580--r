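# Windowed and whole-gene-body G+C, nucleotide frequencies, heatmap matrix.

test_that("window G+C resolves homopolymer blocks and strand order", {
  chr <- paste0(strrep("G", 100), strrep("A", 100), strrep("C", 100))
  genome <- toy_genome(chr1 = chr)
  g_plus <- toy_gene(tx_end = 300L)
  expect_equal(window_gc(g_plus, genome), c(100, 0, 100))
  # palindromic G/A/C profile is unchanged under strand flip
  g_minus <- toy_gene(strand = "-", tx_end = 300L)
  expect_equal(window_gc(g_minus, genome), c(100, 0, 100))
  # non-palindromic blocks: minus-strand profile is the plus profile reversed
  chr2 <- paste0(strrep("G", 100), strrep("A", 100), strrep("T", 100))
  genome2 <- toy_genome(chr1 = chr2)
  expect_equal(window_gc(toy_gene(strand = "-", tx_end = 300L), genome2),
               rev(window_gc(toy_gene(tx_end = 300L), genome2)))
})

test_that("window G+C matches a brute-force recount on random genes", {
  set.seed(11)
  for (rep in 1:20) {
    chr <- random_seq(3000)
    genome <- toy_genome(chr1 = chr)
    strand <- sample(c("+", "-"), 1)
    tx_start <- sample(0:500, 1)
    len <- sample(450:2400, 1)
    g <- toy_gene(strand = strand, tx_start = tx_start,
                  tx_end = tx_start + len)
    expect_equal(window_gc(g, genome),
                 bf_window_gc(chr, tx_start, tx_start + len, strand))
  }
})

test_that("ambiguous bases are excluded and heavy-N windows are missing", {
  chr <- paste0(strrep("G", 60), strrep("N", 40),   # 40% N: still defined
                strrep("N", 50), strrep("A", 50))   # 50% N: missing
  genome <- toy_genome(chr1 = chr)
  w <- window_gc(toy_gene(tx_end = 200L), genome)
  expect_equal(w[1], 100)    # 60 G over 60 unambiguous
  expect_true(is.na(w[2]))
  expect_error(window_gc(toy_gene(tx_end = 500L), genome), "bounds")
})

test_that("whole-gene G+C skips the first kilobase after the TSS", {
  chr <- paste0(strrep("G", 1000), strrep("A", 1000))
  genome <- toy_genome(chr1 = chr)
  expect_equal(whole_gene_gc(toy_gene(tx_end = 2000L), genome), 0)
  # minus-strand gene on the same span reads 3'->5' of the plus strand:
  # its first kilobase is the A block, leaving the G block
  expect_equal(whole_gene_gc(toy_gene(strand = "-", tx_end = 2000L), genome),
               100)
  expect_warning(
    res <- whole_gene_gc(toy_gene(tx_end = 900L), genome), "excluded")
  expect_true(is.na(res))
})

test_that("whole-gene G+C equals a brute-force count and is strand-invariant", {
  set.seed(12)
  for (rep in 1:10) {
    chr <- random_seq(6000)
    genome <- toy_genome(chr1 = chr)
    g <- toy_gene(tx_start = 100L, tx_end = 5100L)
    expect_equal(whole_gene_gc(g, genome), bf_region_gc(chr, 1100, 5100))
    # G+C over a fixed span is reverse-complement invariant; for the minus
    # strand the excluded kilobase sits at the other end of the span
    g_m <- toy_gene(strand = "-", tx_start = 100L, tx_end = 5100L)
    expect_equal(whole_gene_gc(g_m, genome), bf_region_gc(chr, 100, 4100))
  }
})

test_that("mean of windows weighted by coverage equals regional G+C", {
  set.seed(13)
  chr <- random_seq(5050)
  genome <- toy_genome(chr1 = chr)
  g <- toy_gene(tx_end = 5050L)
  w <- window_gc(g, genome)          # 50 full windows; 50 bp tail dropped
  expect_length(w, 50)
  expect_equal(mean(w), bf_region_gc(chr, 0, 5000))
})

test_that("dinucleotide and mononucleotide frequencies are exact", {
  chr <- paste0(strrep("A", 1000), "CGCGCG")
  genome <- toy_genome(chr1 = chr)
  f <- dinucleotide_freq(toy_gene(tx_end = 1006L), genome)
  expect_equal(unname(f["CpG"]), 3 / 5 * 100)
  expect_equal(unname(f["GpC"]), 2 / 5 * 100)
  expect_equal(unname(f["C"] + f["G"]), 100)
  # all-A region: no dinucleotide signal
  f0 <- dinucleotide_freq(toy_gene(tx_end = 2000L),
                          toy_genome(chr1 = strrep("A", 2000)))
  expect_equal(unname(f0[c("CpG", "GpC")]), c(0, 0))
  expect_equal(unname(f0["A"]), 100)
})

test_that("frequencies match a brute-force scan, on both strands and modes", {
  set.seed(14)
  for (rep in 1:10) {
    chr <- random_seq(4000)
    genome <- toy_genome(chr1 = chr)
    strand <- sample(c("+", "-"), 1)
    g <- toy_gene(strand = strand, tx_start = 0L, tx_end = 4000L)
    region <- if (strand == "+") substr(chr, 1001, 4000) else
      bf_revcomp(substr(chr, 1, 3000))
    f <- dinucleotide_freq(g, genome)
    pairs <- nchar(region) - 1
    expect_equal(unname(f["CpG"]), bf_dinuc_count(region, "CG") / pairs * 100)
    expect_equal(unname(f["GpC"]), bf_dinuc_count(region, "GC") / pairs * 100)
    counts <- table(factor(strsplit(region, "")[[1]],
                           levels = c("A", "C", "G", "T")))
    expect_equal(unname(f[c("A", "C", "G", "T")]),
                 as.numeric(counts) / sum(counts) * 100)
    # template mode swaps A<->T and C<->G; CpG/GpC are palindromic
    ft <- dinucleotide_freq(g, genome, strand_mode = "template")
    expect_equal(unname(ft[c("A", "C", "G", "T")]),
                 unname(f[c("T", "G", "C", "A")]))
    expect_equal(unname(ft[c("CpG", "GpC")]), unname(f[c("CpG", "GpC")]))
  }
})

test_that("heatmap matrix keeps only genes spanning the scan and is ordered", {
  set.seed(15)
  chrs <- replicate(4, random_seq(12000))
  genome <- toy_genome(chr1 = chrs[1], chr2 = chrs[2], chr3 = chrs[3],
                       chr4 = chrs[4])
  genes <- gene_models(c("a", "b", "c", "d"), paste0(letters[1:4], ".1"),
                       paste0("chr", 1:4), "+", rep(0L, 4),
                       c(11000L, 10000L, 8000L, 10500L))
  m <- heatmap_matrix(genes, genome)
  expect_equal(rownames(m), c("a", "b", "d"))  # 8 kb gene excluded
  expect_equal(ncol(m), 100)
  expect_equal(m["b", ], bf_window_gc(chrs[2], 0, 10000, "+"))
  # an all-G gene gives a row of 100s
  gG <- toy_gene("gg", tx_end = 10000L)
  mg <- heatmap_matrix(gG, toy_genome(chr1 = strrep("G", 10000)))
  expect_equal(unname(mg[1, ]), rep(100, 100))
})

test_that("rows sorted by gene G+C have monotonically decreasing means", {
  set.seed(16)
  gcs <- seq(80, 20, length.out = 6)
  seqs <- vapply(gcs, function(p) {
    paste(sample(c("G", "C", "A", "T"), 10000, TRUE,
                 prob = c(p / 2, p / 2, (100 - p) / 2, (100 - p) / 2) / 100),
          collapse = "")
  }, "")
  genome <- do.call(toy_genome, stats::setNames(as.list(seqs),
                                                paste0("c", 1:6)))
  genes <- gene_models(paste0("g", 1:6), paste0("g", 1:6, ".1"),
                       paste0("c", 1:6), "+", 0L, 10000L)
  m <- heatmap_matrix(genes, genome)
  expect_true(all(diff(rowMeans(m)) < 0))
})
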