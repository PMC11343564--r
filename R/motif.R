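# PWM scanning with exact p-values. Scores are log2 odds against an order-0
# background; the null distribution of scores over background words is
# computed exactly by dynamic programming on a discretized (binned) score
# grid, so every reported p-value is P(background word scores >= observed)
# up to the documented discretization bound.

#' Read PWMs from a MEME minimal-format file
#'
#' Parses `MOTIF` blocks with `letter-probability matrix` sections
#' (alphabet ACGT).
#'
#' @param path MEME minimal format file.
#' @return named list of PWMs; each a list with `name` and `mat`
#'   (4 x w probability matrix, rows A,C,G,T).
#' @export
read_meme <- function(path) {
  lines <- readLines(path, warn = FALSE)
  motif_at <- grep("^MOTIF\\s+", lines)
  if (!length(motif_at)) stop("no MOTIF blocks in ", path, call. = FALSE)
  out <- list()
  for (k in seq_along(motif_at)) {
    name <- strsplit(trimws(lines[motif_at[k]]), "\\s+")[[1]][2]
    hdr <- grep("letter-probability matrix", lines)
    hdr <- hdr[hdr > motif_at[k]][1]
    w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[hdr]))
    rows <- lines[(hdr + 1):(hdr + w)]
    mat <- matrix(unlist(lapply(rows, function(r)
      as.numeric(strsplit(trimws(r), "\\s+")[[1]]))), nrow = 4)
    dimnames(mat) <- list(c("A", "C", "G", "T"), NULL)   # rows A C G T
    out[[name]] <- list(name = name, mat = mat)
  }
  out
}

#' Built-in synthetic PWMs (E-box, B-box, A-box)
#'
#' Consensus-anchored stand-in matrices shipped with the package
#' (`inst/extdata/motifs_synthetic.meme`): an E-box centred on CACGTG, and
#' B-box / A-box matrices built from the canonical internal RNA-polymerase-III
#' promoter consensi (GTTCGAANNC / TRGCNNARYNNG). They are synthetic
#' constructions for testing and demonstration, not curated database
#' matrices.
#'
#' @return named list of PWMs as in [read_meme].
#' @export
default_pwms <- function() {
  read_meme(system.file("extdata", "motifs_synthetic.meme", package = "hichipr",
                        mustWork = TRUE))
}

#' Fit an order-0 background from sequences
#'
#' Letter frequencies with a pseudocount; by default frequencies are
#' strand-symmetrized (counts pooled with the reverse complement, so
#' freq(A) = freq(T) and freq(C) = freq(G)), matching the default behaviour
#' of order-0 background fitting in motif toolkits.
#'
#' @param sequences character vector of DNA sequences.
#' @param pseudocount added per letter (default 1).
#' @param symmetrize pool counts with the reverse complement (default TRUE).
#' @return named numeric vector of A/C/G/T frequencies (> 0, sums to 1).
#' @export
fit_background <- function(sequences, pseudocount = 1, symmetrize = TRUE) {
  if (length(sequences) == 0L || sum(nchar(sequences)) == 0L)
    stop("empty input sequences", call. = FALSE)
  counts <- colSums(Biostrings::letterFrequency(
    Biostrings::DNAStringSet(sequences), c("A", "C", "G", "T")))
  if (symmetrize) counts <- counts + rev(counts)   # A<->T, C<->G
  counts <- counts + pseudocount
  counts / sum(counts)
}

# log2-odds matrix with FIMO-style background-proportional pseudocount
pwm_logodds <- function(pwm, background, pseudocount = 0.1) {
  p <- sweep(pwm$mat + pseudocount * background, 2,
             colSums(pwm$mat) + pseudocount, "/")
  log2(p / background)
}

.revcomp_mat <- function(m) {
  out <- m[4:1, ncol(m):1, drop = FALSE]
  rownames(out) <- rownames(m)
  out
}

#' Exact null distribution of PWM scores (discretized)
#'
#' Per-position log-odds are scaled to integers (`round(x / bin)`); the
#' distribution of the integer score of a random background word is built by
#' dynamic programming (one convolution per position). The absolute error of
#' any word's binned score is at most `w * bin / 2`.
#'
#' @param logodds 4 x w log2-odds matrix.
#' @param background A/C/G/T frequencies.
#' @param bin score bin width in bits (default 0.001).
#' @return list: `int_mat` (integer-scaled matrix), `min_score` (integer
#'   offset of the distribution), `tail` (tail[k] = P(score_int >= min_score
#'   + k - 1)), `bin`.
#' @export
motif_score_distribution <- function(logodds, background, bin = 0.001) {
  I <- matrix(as.integer(round(logodds / bin)), nrow = 4,
              dimnames = dimnames(logodds))
  w <- ncol(I)
  d <- 1
  base <- 0L
  for (j in seq_len(w)) {
    vals <- I[, j]
    lo <- min(vals)
    span <- max(vals) - lo
    new <- numeric(length(d) + span)
    for (b in 1:4) {
      sh <- vals[b] - lo
      idx <- seq_along(d) + sh
      new[idx] <- new[idx] + d * background[b]
    }
    d <- new
    base <- base + lo
  }
  tail <- rev(cumsum(rev(d)))
  list(int_mat = I, min_score = base, tail = tail, bin = bin)
}

# P(score_int >= s_int) under the distribution
.tail_p <- function(dist, s_int) {
  k <- s_int - dist$min_score + 1L
  k <- pmax(1L, k)
  ifelse(k > length(dist$tail), 0, dist$tail[pmax(1L, pmin(k, length(dist$tail)))])
}

.DNA_CODE <- c(A = 1L, C = 2L, G = 3L, T = 4L)

.scan_one_strand <- function(codes, I) {
  w <- ncol(I)
  n <- length(codes) - w + 1L
  if (n < 1L) return(integer(0))
  s <- integer(n)
  ok <- rep(TRUE, n)
  for (j in seq_len(w)) {
    cj <- codes[j:(n + j - 1L)]
    bad <- is.na(cj)
    ok <- ok & !bad
    cj[bad] <- 1L
    s <- s + I[cbind(cj, j)]
  }
  s[!ok] <- NA_integer_
  s
}

#' Scan a sequence with a PWM, reporting exact p-values
#'
#' Both strands are scanned; the score of a window is the sum of per-position
#' log2(p_motif / p_background); the p-value is the exact probability that a
#' random background word scores at least as high (from
#' [motif_score_distribution]). Windows containing non-ACGT letters are
#' skipped. A sequence shorter than the motif yields no hits.
#'
#' @param sequence a single DNA sequence (character).
#' @param pwm a PWM (list with `name`, `mat`).
#' @param background A/C/G/T frequencies (see [fit_background]).
#' @param p_max report hits with p-value <= this threshold (default 1e-4).
#' @param bin discretization bin width in bits.
#' @param pseudocount PWM pseudocount (see details in [motif_score_distribution]).
#' @return data.frame `motif, offset (0-based), strand, score, pvalue`.
#' @export
scan_pwm <- function(sequence, pwm, background, p_max = 1e-4, bin = 0.001,
                     pseudocount = 0.1) {
  lo <- pwm_logodds(pwm, background, pseudocount)
  w <- ncol(lo)
  codes <- unname(.DNA_CODE[strsplit(toupper(sequence), "")[[1]]])
  empty <- data.frame(motif = character(0), offset = integer(0),
                      strand = character(0), score = numeric(0), pvalue = numeric(0))
  if (length(codes) < w) return(empty)
  strands <- list(`+` = lo, `-` = .revcomp_mat(lo))
  out <- list()
  for (st in names(strands)) {
    dist <- motif_score_distribution(strands[[st]], background, bin)
    s_int <- .scan_one_strand(codes, dist$int_mat)
    p <- .tail_p(dist, s_int)
    keep <- which(!is.na(s_int) & p <= p_max)
    if (length(keep))
      out[[st]] <- data.frame(motif = pwm$name, offset = keep - 1L, strand = st,
                              score = s_int[keep] * bin, pvalue = p[keep],
                              stringsAsFactors = FALSE)
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$pvalue, res$offset), , drop = FALSE]
}

#' Extract anchor sequences from a genome
#' @param genome named `DNAStringSet` or FASTA path.
#' @param anchors interval data.frame (0-based half-open).
#' @return character vector of sequences, one per anchor.
#' @export
get_anchor_seqs <- function(genome, anchors) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  vapply(seq_len(nrow(anchors)), function(i) {
    as.character(Biostrings::subseq(genome[[anchors$chrom[i]]],
                                    anchors$start[i] + 1L, anchors$end[i]))
  }, "")
}

#' Scan many anchors with many PWMs
#'
#' @param seqs named character vector of anchor sequences (names = anchor ids).
#' @param pwms list of PWMs (e.g. [default_pwms()]).
#' @param background background frequencies; fitted from `seqs` when NULL.
#' @param p_max p-value threshold.
#' @return data.frame of hits with an `anchor` column.
#' @export
scan_anchors <- function(seqs, pwms, background = NULL, p_max = 1e-4) {
  if (is.null(background)) background <- fit_background(seqs)
  out <- list()
  for (a in names(seqs)) {
    for (pw in pwms) {
      h <- scan_pwm(seqs[[a]], pw, background, p_max = p_max)
      if (nrow(h)) out[[length(out) + 1L]] <- cbind(anchor = a, h,
                                                    stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(anchor = character(0), motif = character(0),
                      offset = integer(0), strand = character(0),
                      score = numeric(0), pvalue = numeric(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Deduplicate hits and label anchors by motif priority
#'
#' Per (anchor, motif) only the lowest-p hit is kept; each anchor is then
#' labelled with the highest-priority motif present (priority beats
#' p-value); anchors without any hit get `"no_motif"`.
#'
#' @param hits hit data.frame from [scan_anchors].
#' @param anchors character vector of all anchor ids (so hit-less anchors are
#'   labelled too).
#' @param priority motif names in decreasing priority.
#' @return list: `hits` (deduplicated) and `labels` (data.frame
#'   `anchor, label`).
#' @export
dedup_and_prioritize <- function(hits, anchors,
                                 priority = c("E-box", "B-box", "A-box")) {
  if (nrow(hits)) {
    ord <- order(hits$anchor, hits$motif, hits$pvalue)
    hits <- hits[ord, , drop = FALSE]
    hits <- hits[!duplicated(hits[, c("anchor", "motif")]), , drop = FALSE]
  }
  lab <- vapply(anchors, function(a) {
    mm <- hits$motif[hits$anchor == a]
    hit <- priority[priority %in% mm]
    if (length(hit)) hit[1] else "no_motif"
  }, "")
  list(hits = hits,
       labels = data.frame(anchor = anchors, label = unname(lab),
                           stringsAsFactors = FALSE))
}

#' Pairwise motif-label count matrix over loops
#'
#' @param loops loop data.frame.
#' @param labels data.frame `anchor, label` from [dedup_and_prioritize];
#'   anchors are keyed `chrom:start-end`.
#' @param levels label levels for the matrix axes.
#' @return symmetric count matrix; `sum(matrix) == nrow(loops)` (each loop
#'   contributes one unordered label pair, recorded in the upper triangle).
#' @export
pair_motif_table <- function(loops, labels,
                             levels = c("E-box", "B-box", "A-box", "no_motif")) {
  key <- stats::setNames(labels$label, labels$anchor)
  la <- key[sprintf("%s:%d-%d", loops$chromA, loops$startA, loops$endA)]
  lb <- key[sprintf("%s:%d-%d", loops$chromB, loops$startB, loops$endB)]
  la[is.na(la)] <- "no_motif"; lb[is.na(lb)] <- "no_motif"
  m <- matrix(0L, length(levels), length(levels), dimnames = list(levels, levels))
  ia <- match(la, levels); ib <- match(lb, levels)
  lo_i <- pmin(ia, ib); hi_i <- pmax(ia, ib)
  for (k in seq_along(lo_i)) m[lo_i[k], hi_i[k]] <- m[lo_i[k], hi_i[k]] + 1L
  m
}
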