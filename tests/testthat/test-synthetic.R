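test_that("generation is deterministic: same spec and seed, identical output", {
  spec <- tiny_spec(seed = 19L)
  a1 <- generate_annotations(spec)
  a2 <- generate_annotations(spec)
  expect_identical(a1$genes, a2$genes)
  expect_identical(a1$enhancers, a2$enhancers)
  l1 <- generate_loops(spec, a1)
  l2 <- generate_loops(spec, a2)
  expect_identical(l1$loops, l2$loops)
  expect_identical(l1$truth, l2$truth)
  # a different seed changes the draw
  l3 <- generate_loops(tiny_spec(seed = 20L), a1)
  expect_false(identical(l1$loops$startA, l3$loops$startA))
})

test_that("planted GATC sites appear exactly where requested, nowhere else", {
  spec <- synthetic_spec(chrom_sizes = c(chrP = 10000L), seed = 5L)
  g <- generate_genome(spec, planted_sites = list(chrP = c(100L, 500L)),
                       include_spike = FALSE)
  s <- as.character(g$genome[["chrP"]])
  occ <- gregexpr("GATC", s, fixed = TRUE)[[1]]
  expect_equal(as.integer(occ) - 1L, c(100L, 500L))
  expect_equal(g$fragmap$start, c(0L, 100L, 500L))

  expect_error(generate_genome(spec, planted_sites = list(chrP = c(10L, 12L)),
                               include_spike = FALSE), "4 bp apart")
})

test_that("random-mode GATC density matches the binomial expectation", {
  spec <- synthetic_spec(chrom_sizes = c(chrR = 100000L), gc = 0.5, seed = 23L)
  g <- generate_genome(spec, include_spike = FALSE)
  n_occ <- nrow(g$fragmap) - 1L      # cuts = fragments - 1
  p <- (1 / 4)^4                     # at gc = 0.5 every base is 1/4
  n_pos <- 100000 - 3
  expect_lt(abs(n_occ - n_pos * p), 3 * sqrt(n_pos * p * (1 - p)))
})

test_that("annotation truths hold by construction", {
  spec <- tiny_spec()
  ann <- tiny_annotations()
  expect_equal(nrow(ann$genes), spec$n_genes)
  # promoter truth: TSS +/- 500 of each gene
  catalog <- derive_catalog(ann$genes, ann$repeats, ann$histone)
  tss <- ifelse(ann$genes$strand == "-", ann$genes$end - 1L, ann$genes$start)
  expect_equal(catalog$promoter$start, pmax(0L, tss - 500L))
  expect_equal(catalog$promoter$end, tss + 500L)
  # every planted enhancer is covered by H3K4me1 and H3K27ac, never H3K4me3
  expect_true(all(overlaps_any(ann$enhancers, ann$histone$H3K4me1)))
  expect_true(all(overlaps_any(ann$enhancers, ann$histone$H3K27ac)))
  expect_false(any(overlaps_any(ann$enhancers, ann$histone$H3K4me3)))
  # zero requested repeats give empty tracks
  ann0 <- generate_annotations(tiny_spec(repeat_counts = c(SINE = 0L)))
  expect_equal(nrow(ann0$repeats$SINE), 0L)
})

test_that("single-class loop spec puts every anchor in that class", {
  spec <- tiny_spec(n_loops = 10L, n_decoys = 0L,
                    class_fractions = c("promoter-promoter" = 1.0))
  ann <- generate_annotations(spec)
  gl <- generate_loops(spec, ann)
  expect_equal(nrow(gl$loops), 10L)
  catalog <- derive_catalog(ann$genes, ann$repeats, ann$histone)
  al <- annotate_loops(gl$loops, catalog)
  expect_true(all(al$classA == "promoter" & al$classB == "promoter"))

  # requesting a class with an empty track errors
  bad <- tiny_spec(repeat_counts = c(SINE = 0L),
                   class_fractions = c("promoter-SINE" = 0.5))
  ann_bad <- generate_annotations(bad)
  expect_error(generate_loops(bad, ann_bad), "empty annotation track")
})

test_that("planted decoys fail the q-filter and true loops pass", {
  spec <- tiny_spec(n_loops = 95L, n_decoys = 5L)
  gl <- generate_loops(spec, tiny_annotations())
  expect_equal(sum(gl$truth$is_decoy), 5L)
  expect_true(all(gl$loops$qvalue[gl$truth$is_decoy] > 0.01))
  expect_true(all(gl$loops$qvalue[!gl$truth$is_decoy] <= 0.01))
  kept <- suppressMessages(filter_loops(gl$loops, 0.01))
  expect_equal(nrow(kept), 95L)
})

test_that("reads carry planted junctions and the spike mixture", {
  spec <- tiny_spec(seed = 29L, n_pets = 600L)
  g <- generate_genome(synthetic_spec(chrom_sizes = c(chr1 = 100000L),
                                      spike_chrom_size = 60000L, seed = 29L))
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  rr <- generate_reads(spec, g$genome, g$fragmap, f1, f2)
  reads1 <- Biostrings::readDNAStringSet(f1, format = "fastq")
  seqs1 <- as.character(reads1)
  names(seqs1) <- sub("\\s.*$", "", names(reads1))

  jt <- rr$truth[!is.na(rr$truth$junction_offset), ]
  expect_gt(nrow(jt), 0)
  for (i in seq_len(min(20, nrow(jt)))) {
    r <- seqs1[[jt$read_id[i]]]
    # bases after the planted prefix start with a ligation-site string
    post <- substr(r, jt$junction_offset[i] + 1L, nchar(r))
    expect_true(any(startsWith(post, hichipr:::LIGATION_SITES)))
    # the prefix matches the fragment-A end of the genome
    chrom_seq <- as.character(g$genome[[jt$chromA[i]]])
    expected <- if (jt$strandA[i] == "+")
      substr(chrom_seq, jt$posA[i] + 1L, jt$posA[i] + jt$junction_offset[i])
    else hichipr:::.revcomp_chr(substr(chrom_seq,
                                       jt$posA[i] - spec$read_length + 2L,
                                       jt$posA[i] + 1L)) |> substr(1L, jt$junction_offset[i])
    expect_equal(substr(r, 1L, jt$junction_offset[i]), expected)
  }

  # spike fraction within binomial 3 sigma
  n <- nrow(rr$truth); p <- spec$spike_fraction
  expect_lt(abs(sum(rr$truth$is_spike) - n * p), 3 * sqrt(n * p * (1 - p)))
  expect_true(all(grepl("^spike_", rr$truth$chromA[rr$truth$is_spike])))

  # zero junction fraction: no read contains a ligation-site string
  rr0 <- generate_reads(tiny_spec(seed = 29L, n_pets = 150L, junction_fraction = 0),
                        g$genome, g$fragmap, f1, f2)
  s0 <- as.character(Biostrings::readDNAStringSet(f1, format = "fastq"))
  hits <- vapply(hichipr:::LIGATION_SITES,
                 function(site) any(grepl(site, s0, fixed = TRUE)), TRUE)
  expect_false(any(hits))

  expect_error(synthetic_spec(read_length = 20L), "linker length")
})

test_that("expression strata have the requested sizes", {
  spec <- tiny_spec()
  expr <- generate_expression(spec, tiny_annotations()$genes)
  expect_equal(nrow(expr), spec$n_expressed)
  expect_equal(sum(expr$stratum == "down"), spec$n_down)
  expect_equal(sum(expr$stratum == "up"), spec$n_up)
  expect_true(all(expr$log2fc[expr$stratum == "down"] < 0))
  expect_true(all(expr$log2fc[expr$stratum == "up"] > 0))
})
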