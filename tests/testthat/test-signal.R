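test_that("windowed counting matches a brute-force interval check", {
  genes <- data.frame(chrom = "chr1", start = c(10000L, 30000L), end = c(15000L, 36000L),
                      strand = c("+", "-"), gene_id = c("g1", "g2"))
  win <- gene_windows(genes, "tss_pm", 2000L)
  # plus-strand TSS at 10000, minus-strand TSS at 35999
  expect_equal(win$start, c(8000L, 33999L))
  expect_equal(win$end, c(12000L, 37999L))

  # tss_down extends into the gene, leftward for minus strand
  wd <- gene_windows(genes, "tss_down", 2000L)
  expect_equal(wd$start[1], 10000L); expect_equal(wd$end[1], 12000L)
  expect_equal(wd$start[2], 34000L); expect_equal(wd$end[2], 36000L)

  set.seed(61)
  reads <- data.frame(chrom = "chr1", start = sample(0:45000, 400))
  reads$end <- reads$start + 100L
  got <- count_in_window(reads, win)
  brute <- vapply(seq_len(nrow(win)), function(i)
    sum(reads$chrom == win$chrom[i] & reads$start < win$end[i] &
          win$start[i] < reads$end), 0L)
  expect_equal(got, brute)
  # a read straddling the window edge by 1 bp counts
  edge <- data.frame(chrom = "chr1", start = win$start[1] - 99L, end = win$start[1] + 1L)
  expect_equal(count_in_window(edge, win), c(1L, 0L))
})

test_that("metagene density: constant tracks, two-gene SEM, strand flip", {
  genes <- data.frame(chrom = "chr1", start = c(10000L, 40000L), end = c(20000L, 50000L),
                      strand = "+", gene_id = c("g1", "g2"))
  const <- data.frame(chrom = "chr1", start = 0L, end = 100000L, value = 3)
  prof <- metagene_density(const, genes, "tss", 2000L, 200L)
  expect_equal(prof$mean, rep(3, 20))
  expect_equal(prof$sem, rep(0, 20))

  # two genes with flat per-gene values a and b: mean (a+b)/2, SEM |a-b|/2
  track <- data.frame(chrom = "chr1", start = c(8000L, 38000L),
                      end = c(12000L, 42000L), value = c(4, 10))
  p2 <- metagene_density(track, genes, "tss", 2000L, 200L)
  expect_equal(p2$mean, rep(7, 20))
  expect_equal(p2$sem, rep(3, 20))

  # an asymmetric profile mirrors when all strands flip
  bump <- data.frame(chrom = "chr1", start = c(10000L, 40000L),
                     end = c(12000L, 42000L), value = 5)
  fwd <- metagene_density(bump, genes, "tss", 2000L, 200L)
  # minus-strand genes with the same TSS base: profile mirrors
  rev <- metagene_density(bump, transform(genes, strand = "-",
                                          start = start - 9999L, end = start + 1L),
                          "tss", 2000L, 200L)
  expect_equal(rev$mean, rev(fwd$mean), tolerance = 1e-9)

  # linearity through spike scaling
  p_scaled <- metagene_density(normalize_track(track, 0.5), genes, "tss", 2000L, 200L)
  expect_equal(p_scaled$mean, p2$mean * 0.5)
  expect_equal(p_scaled$sem, p2$sem * 0.5)

  expect_error(metagene_density(const, genes[1, ], "tss"), ">= 2 genes")
})

test_that("equal-size binning puts the remainder in the last bin", {
  b <- bin_average(c(6, 5, 4, 3, 2, 1), c(60, 50, 40, 30, 20, 10), genes_per_bin = 3)
  expect_equal(b$mean_x, c(2, 5))
  expect_equal(b$mean_y, c(20, 50))

  const <- bin_average(1:10, rep(7, 10), genes_per_bin = 4)
  expect_equal(const$mean_y, rep(7, 3))
  expect_equal(const$n, c(4L, 4L, 2L))

  # 14,085 records at 150 per bin: 94 bins, the last with 135
  big <- bin_average(seq_len(14085), seq_len(14085), genes_per_bin = 150)
  expect_equal(nrow(big), 94L)
  expect_equal(big$n[94], 135L)

  # bin size 1 is the identity on sorted data
  x <- c(3, 1, 2); y <- c(30, 10, 20)
  one <- bin_average(x, y, genes_per_bin = 1)
  expect_equal(one$mean_x, sort(x))
  expect_equal(one$mean_y, y[order(x)])

  expect_error(bin_average(1:3, 1:3, genes_per_bin = 4), "bin size")
})

test_that("reference-median normalization maps the reference median to 1", {
  ref <- c(1, 2, 3)
  expect_equal(median(normalize_to_reference(ref, ref)), 1)
  expect_equal(normalize_to_reference(c(2, 4, 6), c(0, 2, 100)), c(1, 2, 3))
  v <- runif(20)
  expect_equal(rank(normalize_to_reference(v, c(3, 4, 5))), rank(v))
  expect_error(normalize_to_reference(1:3, c(-1, 0, 1)), "positive")
})

test_that("binding-per-interaction ratio is scale-consistent", {
  expect_equal(binding_per_interaction(1000, 100), 10)
  expect_equal(binding_per_interaction(c(10, 20), c(1, 3)), 7.5)
  expect_equal(binding_per_interaction(2 * c(10, 20), 2 * c(1, 3)), 7.5)
  # a spike factor on the reads scales the ratio linearly
  f <- 0.37
  expect_equal(binding_per_interaction(f * c(10, 20), c(1, 3)),
               f * binding_per_interaction(c(10, 20), c(1, 3)))
  expect_equal(binding_per_interaction(c(4, 9), c(2, 3), per_window = TRUE), c(2, 3))
  expect_error(binding_per_interaction(c(1, 2), c(0, 0)), "zero interactions")
})

test_that("two-group comparisons: exact rank-sum and Welch t behave as expected", {
  expect_equal(group_compare(c(1, 2, 3), c(4, 5, 6), "ranksum")$p_value, 0.1)
  expect_equal(group_compare(c(1, 2, 3), c(1, 2, 3), "ranksum")$p_value, 1)
  w <- group_compare(c(1, 2, 3), c(1, 2, 3), "t_unpaired_unequal_var")
  expect_equal(w$p_value, 1)                     # t = 0
  # degenerate variance falls back to the rank test rather than erroring
  d <- suppressMessages(group_compare(c(2, 2, 2), c(2, 2, 2),
                                      "t_unpaired_unequal_var"))
  expect_true(is.finite(d$p_value))
  expect_error(group_compare(c(1, 2), c(1, 2, 3)), ">= 3")
})
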