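# Small synthetic specs used across tests (kept tiny so the suite is fast).

tiny_spec <- function(seed = 7L, ...) {
  defaults <- list(
    chrom_sizes = c(chr1 = 600000L, chr2 = 600000L),
    spike_chrom_size = 50000L,
    n_genes = 80L, n_enhancers = 40L, n_decoy_marks = 5L,
    repeat_counts = c(SINE = 60L, LINE = 10L, LTR = 8L, satellite = 2L,
                      tRNA = 6L, rRNA = 2L, miRNA = 3L, snRNA = 2L, snoRNA = 2L),
    n_intergenic_anchors = 150L,
    n_loops = 100L, n_decoys = 10L,
    n_pets = 400L,
    n_expressed = 80L, n_down = 5L, n_up = 8L,
    seed = seed
  )
  do.call(synthetic_spec, utils::modifyList(defaults, list(...)))
}

tiny_annotations <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_annotations(tiny_spec())
    cache
  }
})

random_loops <- function(n, chroms = c("chr1", "chr2"), span = 100000L,
                         width = 500L, prefix = "L") {
  chromA <- sample(chroms, n, replace = TRUE)
  sA <- sample.int(span, n)
  sB <- sample.int(span, n)
  .mk <- function(ch, s) list(ch = ch, s = as.integer(s), e = as.integer(s + width))
  loops <- data.frame(
    id = sprintf("%s_%d", prefix, seq_len(n)),
    chromA = chromA, startA = as.integer(sA), endA = as.integer(sA + width),
    chromB = chromA, startB = as.integer(sB), endB = as.integer(sB + width),
    pet = sample(1:10, n, replace = TRUE),
    pvalue = runif(n), qvalue = runif(n), sample_id = rep(prefix, n),
    stringsAsFactors = FALSE
  )
  canonicalize_loops(loops)
}
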