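# Synthetic-data generators. Every pipeline input can be generated with
# known planted truth: a toy genome with controllable restriction-site
# placement, gene/repeat/histone annotations whose derived enhancer set
# equals the planted one, loops with planted class composition, decoys and
# hubs, and chimeric read pairs with planted ligation junctions and a
# two-genome spike mixture. Identical spec + seed give identical output.

#' Evaluate code with a temporary RNG seed
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`; the caller's RNG state is restored afterwards.
#' @export
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Specification of a synthetic study
#'
#' Collects every knob of the generators. The defaults mirror the scale of a
#' single HiChIP study divided by ten (about 1,470 genes and 460 loops over a
#' 13.5 Mb three-chromosome toy genome; expression strata of 1,470 / 61 / 92
#' genes; a 1:20 spike mixture, i.e. 5% spike reads) so a full run stays
#' interactive.
#'
#' @param chrom_sizes named integer vector of chromosome lengths (>= 10 kb).
#' @param spike_chrom_size length of the single spike-genome chromosome.
#' @param gc GC content of random genome sequence.
#' @param n_genes number of genes to plant.
#' @param gene_length_range,intergenic_gap_range bp ranges for gene lengths
#'   and inter-gene gaps.
#' @param exons_per_gene range of exon counts per gene.
#' @param repeat_counts named integer vector: planted elements per repeat/RNA
#'   class.
#' @param repeat_lengths named integer vector: element length per class.
#' @param n_enhancers planted enhancers (H3K4me1+H3K27ac without H3K4me3).
#' @param n_decoy_marks planted triple-marked sites (also H3K4me3) that must
#'   NOT become enhancers.
#' @param n_intergenic_anchors pre-allocated intergenic anchor slots.
#' @param n_loops called-loop count (true loops; decoys come on top).
#' @param class_fractions named fractions per loop class (summing to <= 1;
#'   remainder is intergenic-intergenic).
#' @param pet_mean mean PET count (geometric distribution on 1, 2, ...).
#' @param n_decoys decoy loops planted with q > 0.01.
#' @param hubs list of planted hubs, each
#'   `list(n_promoters=, n_enhancers=, topology="tree"|"path")`.
#' @param anchor_width anchor width in bp.
#' @param n_pets synthetic read pairs.
#' @param read_length read length (must exceed linker length + 10).
#' @param junction_fraction fraction of valid PETs whose read 1 carries a
#'   ligation junction.
#' @param junction_offset 0-based offset of the junction in such reads.
#' @param invalid_fractions named fractions of dangling_end / self_circle /
#'   re_ligation PETs.
#' @param multimapped_fraction fraction of PETs flagged multi-mapped.
#' @param spike_fraction fraction of PETs drawn from the spike genome.
#' @param n_expressed,n_down,n_up expression stratum sizes.
#' @param seed integer master seed.
#' @return a list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(
    chrom_sizes = c(chr1 = 4500000L, chr2 = 4500000L, chr3 = 4500000L),
    spike_chrom_size = 200000L,
    gc = 0.5,
    n_genes = 1470L,
    gene_length_range = c(2000L, 6000L),
    intergenic_gap_range = c(2500L, 6000L),
    exons_per_gene = c(2L, 5L),
    repeat_counts = c(SINE = 600L, LINE = 150L, LTR = 100L, satellite = 30L,
                      tRNA = 60L, rRNA = 20L, miRNA = 30L, snRNA = 20L,
                      snoRNA = 20L),
    repeat_lengths = c(SINE = 300L, LINE = 1000L, LTR = 500L, satellite = 2000L,
                       tRNA = 80L, rRNA = 150L, miRNA = 80L, snRNA = 150L,
                       snoRNA = 100L),
    n_enhancers = 150L,
    n_decoy_marks = 30L,
    n_intergenic_anchors = 800L,
    n_loops = 460L,
    class_fractions = c("promoter-promoter" = 0.28,
                        "promoter-gene_body" = 0.19,
                        "promoter-SINE" = 0.14,
                        "promoter-enhancer" = 0.10),
    pet_mean = 4,
    n_decoys = 46L,
    hubs = list(),
    anchor_width = 500L,
    n_pets = 2000L,
    read_length = 75L,
    junction_fraction = 0.3,
    junction_offset = 40L,
    invalid_fractions = c(dangling_end = 0.08, self_circle = 0.04,
                          re_ligation = 0.06),
    multimapped_fraction = 0.05,
    spike_fraction = 0.05,
    n_expressed = 1470L,
    n_down = 61L,
    n_up = 92L,
    seed = 1L) {
  spec <- as.list(environment())
  if (any(spec$chrom_sizes < 10000L))
    stop("chromosome sizes must be >= 10 kb", call. = FALSE)
  if (sum(spec$class_fractions) > 1 + 1e-9)
    stop("class fractions must sum to <= 1", call. = FALSE)
  if (sum(spec$invalid_fractions) >= 1)
    stop("invalid-PET fractions must sum to < 1", call. = FALSE)
  if (spec$read_length < max(nchar(LIGATION_SITES)) + 10L)
    stop("read length must be at least linker length + 10", call. = FALSE)
  class(spec) <- "synthetic_spec"
  spec
}

.rand_seq <- function(L, gc) {
  paste(sample(c("A", "C", "G", "T"), L, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

.destroy_site <- function(seq, site = "GATC") {
  repeat {
    hits <- gregexpr(site, seq, fixed = TRUE)[[1]]
    if (hits[1] == -1L) return(seq)
    chars <- strsplit(seq, "", fixed = TRUE)[[1]]
    chars[hits + 1L] <- "C"                 # GATC -> GCTC
    seq <- paste(chars, collapse = "")
  }
}

# sample() treats a length-1 numeric vector as 1:x; these never do
.sample1 <- function(x) if (length(x) == 1L) x else sample(x, 1L)
.sample_n <- function(x, n) if (length(x) == 1L && n == 1L) x else sample(x, n)
.shuffle <- function(x) if (length(x) <= 1L) x else sample(x)

#' Generate the toy genome
#'
#' Random mode produces per-chromosome random sequence at the requested GC;
#' planted mode guarantees GATC occurs exactly at the given positions and
#' nowhere else. The spike genome is appended as one extra chromosome named
#' `spike_chr1`.
#'
#' @param spec a [synthetic_spec].
#' @param planted_sites optional named list (chromosome -> 0-based GATC
#'   positions); switches the named chromosomes to planted-site mode.
#'   Positions must be >= 4 bp apart.
#' @param include_spike append the spike chromosome (default TRUE).
#' @return list with `genome` (named `DNAStringSet`) and `fragmap` (the
#'   digestion truth from [digest_genome]).
#' @export
generate_genome <- function(spec, planted_sites = NULL, include_spike = TRUE) {
  with_seed(spec$seed + 101L, {
    sizes <- spec$chrom_sizes
    if (include_spike)
      sizes <- c(sizes, setNames(spec$spike_chrom_size, "spike_chr1"))
    seqs <- lapply(names(sizes), function(ch) {
      L <- sizes[[ch]]
      s <- .rand_seq(L, spec$gc)
      if (!is.null(planted_sites[[ch]])) {
        pos <- sort(as.integer(planted_sites[[ch]]))
        if (length(pos) > 1L && min(diff(pos)) < 4L)
          stop("planted GATC sites must be >= 4 bp apart", call. = FALSE)
        if (any(pos < 0L | pos + 4L > L))
          stop("planted site outside chromosome", call. = FALSE)
        s <- .destroy_site(s)
        for (p in pos) substr(s, p + 1L, p + 4L) <- "GATC"
      }
      s
    })
    genome <- Biostrings::DNAStringSet(unlist(seqs))
    names(genome) <- names(sizes)
    list(genome = genome, fragmap = digest_genome(genome))
  })
}

# Interval allocator over free space: place non-overlapping elements into a
# shrinking set of free segments.
.new_allocator <- function(free) {
  env <- new.env(parent = emptyenv())
  env$free <- free
  env
}

.alloc <- function(alloc, chrom = NULL, len, pad = 50L) {
  f <- alloc$free
  cand <- which(f$end - f$start >= len + 2L * pad &
                  (if (is.null(chrom)) TRUE else f$chrom == chrom))
  if (!length(cand)) return(NULL)
  wts <- (f$end - f$start)[cand]
  i <- if (length(cand) == 1L) cand else sample(cand, 1L, prob = wts)
  lo <- f$start[i] + pad
  hi <- f$end[i] - pad - len
  s <- if (hi > lo) lo + sample.int(hi - lo + 1L, 1L) - 1L else lo
  placed <- data.frame(chrom = f$chrom[i], start = s, end = s + len,
                       stringsAsFactors = FALSE)
  left <- data.frame(chrom = f$chrom[i], start = f$start[i], end = s - pad)
  right <- data.frame(chrom = f$chrom[i], start = s + len + pad, end = f$end[i])
  keep <- rbind(left, right)
  keep <- keep[keep$end - keep$start > 0L, , drop = FALSE]
  alloc$free <- rbind(f[-i, , drop = FALSE], keep)
  placed
}

#' Generate annotations with planted truth
#'
#' Plants non-overlapping gene models, repeat elements, enhancers and
#' histone-peak tracks such that the catalog derived by [derive_catalog]
#' recovers the planted classes exactly: H3K27ac peaks coincide with planted
#' enhancers, H3K4me1 peaks extend 200 bp beyond them, H3K4me3 marks
#' promoters and the planted decoy sites (which therefore never derive as
#' enhancers). Anchor pools per class (sub-intervals guaranteed to annotate
#' as that class and nothing higher-priority) are returned for the loop
#' generator.
#'
#' @param spec a [synthetic_spec].
#' @param config a [pipeline_config] (windows and priority).
#' @return list: `genes`, `exons`, `repeats` (named list), `histone` (named
#'   list), `enhancers` (planted truth), `anchor_pools` (named list of
#'   interval data.frames), `chrom_sizes`.
#' @export
generate_annotations <- function(spec, config = pipeline_config()) {
  with_seed(spec$seed + 202L, {
    sizes <- spec$chrom_sizes
    quota <- round(spec$n_genes * as.numeric(sizes) / sum(as.numeric(sizes)))
    names(quota) <- names(sizes)
    quota[length(quota)] <- spec$n_genes - sum(quota[-length(quota)])
    genes_parts <- list()
    gi <- 0L
    for (ch in names(sizes)) {
      L <- sizes[[ch]]
      cursor <- 2000L
      placed <- 0L
      while (placed < quota[[ch]]) {
        gap <- sample(spec$intergenic_gap_range[1]:spec$intergenic_gap_range[2], 1L)
        glen <- sample(spec$gene_length_range[1]:spec$gene_length_range[2], 1L)
        s <- cursor + gap
        if (s + glen + 2000L > L) break
        gi <- gi + 1L
        genes_parts[[gi]] <- data.frame(
          chrom = ch, start = s, end = s + glen,
          strand = sample(c("+", "-"), 1L),
          gene_id = sprintf("gene_%04d", gi), stringsAsFactors = FALSE)
        cursor <- s + glen
        placed <- placed + 1L
      }
    }
    genes <- do.call(rbind, genes_parts)
    if (is.null(genes) || nrow(genes) < spec$n_genes)
      stop("genome too small for the requested gene count", call. = FALSE)

    # exons: alternate exon/intron chunks inside each gene span
    exons <- do.call(rbind, lapply(seq_len(nrow(genes)), function(i) {
      k <- sample(spec$exons_per_gene[1]:spec$exons_per_gene[2], 1L)
      glen <- genes$end[i] - genes$start[i]
      if (k == 1L || glen < 4L * k)
        return(data.frame(chrom = genes$chrom[i], start = genes$start[i],
                          end = genes$end[i], gene_id = genes$gene_id[i]))
      cuts <- sort(sample(seq_len(glen - 1L), 2L * (k - 1L)))
      bounds <- c(0L, cuts, glen)
      s <- genes$start[i] + bounds[seq(1, length(bounds) - 1, by = 2)]
      e <- genes$start[i] + bounds[seq(2, length(bounds), by = 2)]
      data.frame(chrom = genes$chrom[i], start = s, end = e,
                 gene_id = genes$gene_id[i], stringsAsFactors = FALSE)
    }))

    # free intergenic space: chromosomes minus gene spans padded so that
    # promoter/TES windows never reach planted intergenic elements
    pad <- max(config$promoter_window, config$tes_window) + 100L
    chrom_df <- data.frame(chrom = names(sizes), start = 100L,
                           end = as.integer(sizes) - 100L)
    gene_pad <- data.frame(chrom = genes$chrom, start = pmax(0L, genes$start - pad),
                           end = genes$end + pad)
    alloc <- .new_allocator(interval_setdiff(chrom_df, gene_pad))

    place_many <- function(n, len, pad_el = 50L) {
      out <- vector("list", n)
      for (i in seq_len(n)) {
        p <- .alloc(alloc, len = len, pad = pad_el)
        if (is.null(p)) stop("ran out of intergenic space", call. = FALSE)
        out[[i]] <- p
      }
      do.call(rbind, out)
    }

    enhancers <- place_many(spec$n_enhancers, 800L, pad_el = 250L)
    decoy_marks <- if (spec$n_decoy_marks > 0L)
      place_many(spec$n_decoy_marks, 800L, pad_el = 250L) else NULL
    repeats <- list()
    for (cl in names(spec$repeat_counts)) {
      n <- spec$repeat_counts[[cl]]
      repeats[[cl]] <- if (n > 0L) place_many(n, spec$repeat_lengths[[cl]])
      else data.frame(chrom = character(0), start = integer(0), end = integer(0))
    }
    intergenic_pool <- place_many(spec$n_intergenic_anchors, spec$anchor_width)

    # histone peaks: K27ac == enhancer; K4me1 = enhancer +/- 200; K4me3 at
    # promoters and at the decoy triple-marked sites
    tss <- ifelse(genes$strand == "-", genes$end - 1L, genes$start)
    k4me3 <- rbind(
      data.frame(chrom = genes$chrom, start = pmax(0L, tss - 300L), end = tss + 300L),
      if (!is.null(decoy_marks)) decoy_marks[, c("chrom", "start", "end")]
    )
    k4me1 <- rbind(
      data.frame(chrom = enhancers$chrom, start = pmax(0L, enhancers$start - 200L),
                 end = enhancers$end + 200L),
      if (!is.null(decoy_marks)) decoy_marks[, c("chrom", "start", "end")]
    )
    k27ac <- rbind(enhancers[, c("chrom", "start", "end")],
                   if (!is.null(decoy_marks)) decoy_marks[, c("chrom", "start", "end")])
    histone <- list(H3K4me1 = k4me1, H3K27ac = k27ac, H3K4me3 = k4me3)

    if (any(overlaps_any(enhancers, k4me3)))
      stop("planted enhancer overlaps a planted H3K4me3 peak", call. = FALSE)

    # anchor pools: sub-intervals that annotate exactly as their class
    hw <- spec$anchor_width %/% 2L
    promoter_pool <- data.frame(chrom = genes$chrom,
                                start = pmax(0L, tss - hw), end = tss + hw,
                                stringsAsFactors = FALSE)
    interior_lo <- genes$start + config$promoter_window + 150L
    interior_hi <- genes$end - config$tes_window - 150L
    ok <- interior_hi - interior_lo >= spec$anchor_width
    mid <- (interior_lo + interior_hi) %/% 2L
    gene_body_pool <- data.frame(chrom = genes$chrom[ok],
                                 start = mid[ok] - hw, end = mid[ok] + hw,
                                 stringsAsFactors = FALSE)
    # promoters of minus-strand genes sit at the gene end; drop gene-body
    # slots whose window could touch a promoter of a neighbouring gene
    anchor_pools <- list(
      promoter = promoter_pool,
      gene_body = gene_body_pool,
      SINE = repeats$SINE,
      enhancer = enhancers[, c("chrom", "start", "end")],
      intergenic = intergenic_pool
    )
    list(genes = genes, exons = exons, repeats = repeats, histone = histone,
         enhancers = enhancers, anchor_pools = anchor_pools,
         chrom_sizes = sizes)
  })
}

# Draw `n` indices from a pool without replacement while it lasts, then
# recycle (logged by the caller via attr "recycled").
.pool_draw <- function(state, pool_name, n) {
  avail <- state[[pool_name]]
  if (length(avail) < n) {
    avail <- c(avail, .shuffle(state$full[[pool_name]]))
    state$recycled <- TRUE
  }
  take <- avail[seq_len(n)]
  state[[pool_name]] <- avail[-seq_len(n)]
  take
}

#' Generate loops with planted classes, decoys and hubs
#'
#' Loop classes are drawn multinomially from `spec$class_fractions` (the
#' remainder is intergenic-intergenic); every loop's anchors come from the
#' class-exclusive anchor pools, sampled without replacement while the pools
#' last. Planted-true loops get q-values uniform on (0, 0.01], decoys uniform
#' on (0.01, 1], so the q <= 0.01 filter separates them exactly. PET counts
#' are geometric on {1, 2, ...} with mean `pet_mean`. Each planted hub is
#' realized as a connected random tree (or path) over dedicated promoter and
#' enhancer anchors on one chromosome; hub anchors are never reused for
#' background loops.
#'
#' @param spec a [synthetic_spec].
#' @param ann annotations from [generate_annotations].
#' @return list: `loops` (canonical loop data.frame) and `truth`
#'   (`id, classA_true, classB_true, loop_class_true, is_decoy, hub_id`).
#' @export
generate_loops <- function(spec, ann) {
  with_seed(spec$seed + 303L, {
    pools <- ann$anchor_pools
    fr <- spec$class_fractions
    if (sum(fr) < 1 - 1e-9) fr <- c(fr, "intergenic-intergenic" = 1 - sum(fr))
    class_pair <- strsplit(names(fr), "-", fixed = TRUE)
    for (cp in unique(unlist(class_pair))) {
      if (is.null(pools[[cp]]) || nrow(pools[[cp]]) == 0L)
        stop("loop class requests empty annotation track: ", cp, call. = FALSE)
    }

    # reserve hub anchors first
    state <- new.env(parent = emptyenv())
    state$full <- lapply(pools, function(p) seq_len(nrow(p)))
    state$recycled <- FALSE
    hub_rows <- list(); hub_truth <- list()
    for (h in seq_along(spec$hubs)) {
      hub <- spec$hubs[[h]]
      # confine each hub to the chromosome with the most promoter slots
      avail_p <- state$full$promoter
      ch_tab <- sort(table(pools$promoter$chrom[avail_p]), decreasing = TRUE)
      ch <- names(ch_tab)[1]
      prom_idx <- .sample_n(intersect(which(pools$promoter$chrom == ch), avail_p),
                            hub$n_promoters)
      enh_idx <- .sample_n(intersect(which(pools$enhancer$chrom == ch),
                                     state$full$enhancer),
                           hub$n_enhancers)
      state$full$promoter <- setdiff(state$full$promoter, prom_idx)
      state$full$enhancer <- setdiff(state$full$enhancer, enh_idx)
      nodes <- rbind(cbind(pools$promoter[prom_idx, c("chrom", "start", "end")],
                           class = "promoter"),
                     cbind(pools$enhancer[enh_idx, c("chrom", "start", "end")],
                           class = "enhancer"))
      nodes <- nodes[sample(nrow(nodes)), , drop = FALSE]
      k <- nrow(nodes)
      topo <- if (!is.null(hub$topology)) hub$topology else "tree"
      parent <- if (topo == "path") seq_len(k - 1L)
                else vapply(2:k, function(i) sample.int(i - 1L, 1L), 1L)
      child <- 2:k
      hub_rows[[h]] <- data.frame(
        chromA = nodes$chrom[parent], startA = nodes$start[parent],
        endA = nodes$end[parent],
        chromB = nodes$chrom[child], startB = nodes$start[child],
        endB = nodes$end[child],
        classA = nodes$class[parent], classB = nodes$class[child],
        stringsAsFactors = FALSE)
      hub_truth[[h]] <- rep(h, k - 1L)
    }
    for (nm in names(state$full)) state[[nm]] <- .shuffle(state$full[[nm]])

    n <- spec$n_loops
    cls_idx <- sample(seq_along(fr), n, replace = TRUE, prob = fr)
    n_dec <- spec$n_decoys
    dec_idx <- sample(seq_along(fr), n_dec, replace = TRUE, prob = fr)
    all_idx <- c(cls_idx, dec_idx)
    is_decoy <- c(rep(FALSE, n), rep(TRUE, n_dec))

    draw_class <- function(ci) {
      cp <- class_pair[[ci]]
      ia <- .pool_draw(state, cp[1], 1L)
      # prefer an anchor on the same chromosome for the second end
      chA <- pools[[cp[1]]]$chrom[ia]
      availB <- state[[cp[2]]]
      same <- availB[pools[[cp[2]]]$chrom[availB] == chA &
                       !(cp[1] == cp[2] & availB == ia)]
      ib <- if (length(same)) same[1] else .pool_draw(state, cp[2], 1L)
      state[[cp[2]]] <- setdiff(state[[cp[2]]], ib)
      list(a = pools[[cp[1]]][ia, , drop = FALSE],
           b = pools[[cp[2]]][ib, , drop = FALSE],
           classA = cp[1], classB = cp[2])
    }
    picks <- lapply(all_idx, draw_class)

    bg <- data.frame(
      chromA = vapply(picks, function(p) p$a$chrom, ""),
      startA = vapply(picks, function(p) p$a$start, 0L),
      endA = vapply(picks, function(p) p$a$end, 0L),
      chromB = vapply(picks, function(p) p$b$chrom, ""),
      startB = vapply(picks, function(p) p$b$start, 0L),
      endB = vapply(picks, function(p) p$b$end, 0L),
      classA = vapply(picks, function(p) p$classA, ""),
      classB = vapply(picks, function(p) p$classB, ""),
      stringsAsFactors = FALSE)
    all_rows <- rbind(do.call(rbind, hub_rows), bg)
    n_hub <- sum(lengths(hub_truth))
    hub_id <- c(unlist(hub_truth), rep(NA_integer_, nrow(bg)))
    is_decoy <- c(rep(FALSE, n_hub), is_decoy)

    m <- nrow(all_rows)
    pet <- 1L + stats::rgeom(m, prob = 1 / spec$pet_mean)
    q <- ifelse(is_decoy, 0.01 + stats::runif(m) * 0.99, stats::runif(m) * 0.01)
    loops <- .new_loops(all_rows$chromA, all_rows$startA, all_rows$endA,
                        all_rows$chromB, all_rows$startB, all_rows$endB,
                        pet, pvalue = q / 2, qvalue = q, sample_id = "synthetic")
    truth <- data.frame(
      id = loops$id,
      classA_true = all_rows$classA, classB_true = all_rows$classB,
      loop_class_true = loop_class_label(all_rows$classA, all_rows$classB),
      is_decoy = is_decoy,
      hub_id = hub_id,
      stringsAsFactors = FALSE)
    if (state$recycled)
      .log_stage("generate", "anchor pools exhausted; anchors were reused")
    list(loops = loops, truth = truth)
  })
}

.revcomp_chr <- function(s)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))

#' Generate synthetic read pairs with planted PET truth
#'
#' Samples PETs over the restriction-fragment map: a configurable fraction
#' are dangling ends, self-circles or re-ligations (same / adjacent
#' fragments with the class-defining strand geometry); the rest are valid
#' pairs on non-adjacent fragments. A fraction of valid read-1 sequences
#' carry a ligation-site junction at a planted offset; a fraction of PETs
#' come from the spike genome; a fraction are flagged multi-mapped.
#'
#' @param spec a [synthetic_spec].
#' @param genome named `DNAStringSet` including the spike chromosome.
#' @param fragmap fragment map of that genome.
#' @param fastq1,fastq2 output FASTQ paths.
#' @return list: `truth` (read-level truth table) and the two paths.
#' @export
generate_reads <- function(spec, genome, fragmap, fastq1, fastq2) {
  with_seed(spec$seed + 404L, {
    rl <- spec$read_length
    n <- spec$n_pets
    classes <- c("valid", names(spec$invalid_fractions))
    probs <- c(1 - sum(spec$invalid_fractions), spec$invalid_fractions)
    cls <- sample(classes, n, replace = TRUE, prob = probs)
    is_spike <- stats::runif(n) < spec$spike_fraction
    multimapped <- stats::runif(n) < spec$multimapped_fraction
    junction <- cls == "valid" & stats::runif(n) < spec$junction_fraction

    chrom_len <- setNames(Biostrings::width(genome), names(genome))
    fm_by_chrom <- split(fragmap, fragmap$chrom)
    spike_chroms <- grep("^spike_", names(genome), value = TRUE)
    primary_chroms <- setdiff(names(genome), spike_chroms)

    pick_pos <- function(fm, L, idx) {
      lo <- max(fm$start[idx], rl - 1L)
      hi <- min(fm$end[idx] - 1L, L - rl)
      if (hi < lo) return(NA_integer_)
      lo + sample.int(hi - lo + 1L, 1L) - 1L
    }
    seq_cache <- lapply(genome, as.character)
    read_seq <- function(ch, pos, strand) {
      if (strand == "+") substr(seq_cache[[ch]], pos + 1L, pos + rl)
      else .revcomp_chr(substr(seq_cache[[ch]], pos - rl + 2L, pos + 1L))
    }

    truth <- vector("list", n)
    s1 <- character(n); s2 <- character(n)
    for (i in seq_len(n)) {
      chs <- if (is_spike[i]) spike_chroms else primary_chroms
      repeat {
        ch <- .sample1(chs)
        fm <- fm_by_chrom[[ch]]
        L <- chrom_len[[ch]]
        nf <- nrow(fm)
        if (nf < 4L) next
        if (cls[i] == "valid") {
          ia <- sample.int(nf - 3L, 1L) + 1L   # keep room for non-adjacency
          ib <- .sample1(setdiff(seq_len(nf), (ia - 1L):(ia + 1L)))
          sa <- sample(c("+", "-"), 1L); sb <- sample(c("+", "-"), 1L)
        } else if (cls[i] == "re_ligation") {
          ia <- sample.int(nf - 1L, 1L); ib <- ia + 1L
          sa <- sample(c("+", "-"), 1L); sb <- sample(c("+", "-"), 1L)
        } else {
          ia <- sample.int(nf, 1L); ib <- ia
          sa <- "+"; sb <- "-"
        }
        pa <- pick_pos(fm, L, ia); pb <- pick_pos(fm, L, ib)
        if (is.na(pa) || is.na(pb)) next
        if (ia == ib) {
          lohi <- range(pa, pb)
          if (lohi[1] == lohi[2]) next
          pa <- lohi[1]; pb <- lohi[2]
          # dangling end: inward (+ left, - right); self-circle: outward
          sa <- if (cls[i] == "dangling_end") "+" else "-"
          sb <- if (cls[i] == "dangling_end") "-" else "+"
        }
        break
      }
      r1 <- read_seq(ch, pa, sa)
      if (junction[i]) {
        site <- sample(LIGATION_SITES, 1L)
        fill <- read_seq(ch, pb, sb)
        r1 <- substr(paste0(substr(r1, 1L, spec$junction_offset), site, fill),
                     1L, rl)
      }
      s1[i] <- r1
      s2[i] <- read_seq(ch, pb, sb)
      truth[[i]] <- data.frame(
        read_id = sprintf("pet_%05d", i),
        chromA = ch, posA = pa, strandA = sa,
        chromB = ch, posB = pb, strandB = sb,
        class_true = cls[i], is_spike = is_spike[i],
        multimapped = multimapped[i],
        junction_offset = if (junction[i]) spec$junction_offset else NA_integer_,
        stringsAsFactors = FALSE)
    }
    truth <- do.call(rbind, truth)
    qual <- strrep("I", rl)
    writeLines(as.vector(rbind(paste0("@", truth$read_id), s1, "+", qual)), fastq1)
    writeLines(as.vector(rbind(paste0("@", truth$read_id), s2, "+", qual)), fastq2)
    list(truth = truth, fastq1 = fastq1, fastq2 = fastq2)
  })
}

#' Generate expression strata and fold changes
#'
#' Assigns `n_expressed` genes to the expressed universe and plants
#' `n_down` / `n_up` regulated genes with negative / positive log2 fold
#' changes; the remainder get small changes around zero.
#'
#' @param spec a [synthetic_spec].
#' @param genes gene data.frame from [generate_annotations].
#' @return data.frame `gene_id, stratum, log2fc`.
#' @export
generate_expression <- function(spec, genes) {
  with_seed(spec$seed + 505L, {
    expressed <- genes$gene_id[sample(nrow(genes), min(spec$n_expressed, nrow(genes)))]
    reg <- sample(expressed, spec$n_down + spec$n_up)
    down <- reg[seq_len(spec$n_down)]
    up <- reg[spec$n_down + seq_len(spec$n_up)]
    stratum <- ifelse(expressed %in% down, "down",
               ifelse(expressed %in% up, "up", "unchanged"))
    lfc <- stats::rnorm(length(expressed), 0, 0.2)
    lfc[stratum == "down"] <- -abs(stats::rnorm(sum(stratum == "down"), 1.5, 0.5))
    lfc[stratum == "up"] <- abs(stats::rnorm(sum(stratum == "up"), 1.5, 0.5))
    data.frame(gene_id = expressed, stratum = stratum, log2fc = lfc,
               stringsAsFactors = FALSE)
  })
}

#' Generate a per-sample spike count table
#'
#' @param spec a [synthetic_spec].
#' @param n_samples samples in the batch.
#' @return data.frame `sample_id, primary, spike` suitable for
#'   [chiprx_factors].
#' @export
generate_spike_table <- function(spec, n_samples = 2L) {
  with_seed(spec$seed + 606L, {
    primary <- round(stats::runif(n_samples, 5e5, 2e6))
    spike <- round(primary * spec$spike_fraction * stats::runif(n_samples, 0.6, 1.4))
    data.frame(sample_id = sprintf("sample_%d", seq_len(n_samples)),
               primary = primary, spike = spike, stringsAsFactors = FALSE)
  })
}
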