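# Genomic intervals: plain data.frames in 0-based half-open coordinates
# (BED convention) with columns chrom, start, end and optionally name, score,
# strand. One convention everywhere; conversions to IRanges happen only
# inside overlap computations.

#' Construct a set of genomic intervals
#'
#' Intervals use the BED convention throughout the package: 0-based start,
#' exclusive end (`[start, end)`), strand one of `+`, `-`, `.`.
#'
#' @param chrom character vector of chromosome names (non-empty).
#' @param start integer vector, 0-based inclusive.
#' @param end integer vector, 0-based exclusive; must satisfy `end > start`.
#' @param strand strand per interval; recycled. Default `"."`.
#' @param name optional name per interval; recycled.
#' @param score optional numeric score; recycled.
#' @return A `data.frame` with class `genomic_intervals`.
#' @export
genomic_intervals <- function(chrom, start, end, strand = ".", name = NA_character_,
                              score = NA_real_) {
  n <- length(chrom)
  df <- data.frame(
    chrom = as.character(chrom),
    start = as.integer(start),
    end = as.integer(end),
    name = rep_len(as.character(name), n),
    score = rep_len(as.numeric(score), n),
    strand = rep_len(as.character(strand), n),
    stringsAsFactors = FALSE
  )
  validate_intervals(df)
  class(df) <- c("genomic_intervals", "data.frame")
  df
}

validate_intervals <- function(df) {
  if (nrow(df) == 0L) return(invisible(df))
  if (any(is.na(df$chrom) | !nzchar(df$chrom)))
    stop("interval with empty chromosome name", call. = FALSE)
  if (any(df$start < 0L))
    stop("interval with negative start", call. = FALSE)
  bad <- which(df$end <= df$start)
  if (length(bad))
    stop(sprintf("interval with end <= start (first at record %d: %s:%d-%d)",
                 bad[1], df$chrom[bad[1]], df$start[bad[1]], df$end[bad[1]]),
         call. = FALSE)
  ok <- df$strand %in% c("+", "-", ".")
  if (!all(ok))
    stop("strand must be one of '+', '-', '.'", call. = FALSE)
  invisible(df)
}

#' Natural ordering of chromosome names
#'
#' Orders `chr1 < chr2 < chr10 < chrX`: a numeric suffix sorts numerically,
#' everything else lexicographically after the numbered chromosomes.
#'
#' @param chroms character vector of chromosome names.
#' @return integer rank usable with `order()`.
#' @export
chrom_rank <- function(chroms) {
  u <- unique(chroms)
  num <- suppressWarnings(as.integer(sub("^chr", "", u)))
  ord <- order(is.na(num), num, u)
  match(chroms, u[ord])
}

# IRanges conversion (1-based closed) for overlap machinery. Returns a list
# keyed by chromosome so callers can do per-chromosome findOverlaps.
.as_iranges_by_chrom <- function(df) {
  split(seq_len(nrow(df)), df$chrom)
}

# findOverlaps between two interval data.frames (>= 1 bp overlap, strand
# ignored). Returns data.frame(query, subject) of row indices.
overlap_pairs <- function(query, subject) {
  if (nrow(query) == 0L || nrow(subject) == 0L)
    return(data.frame(query = integer(0), subject = integer(0)))
  out_q <- integer(0); out_s <- integer(0)
  for (ch in intersect(unique(query$chrom), unique(subject$chrom))) {
    qi <- which(query$chrom == ch)
    si <- which(subject$chrom == ch)
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(query$start[qi] + 1L, query$end[qi]),
      IRanges::IRanges(subject$start[si] + 1L, subject$end[si])
    )
    out_q <- c(out_q, qi[S4Vectors::queryHits(hits)])
    out_s <- c(out_s, si[S4Vectors::subjectHits(hits)])
  }
  data.frame(query = out_q, subject = out_s)
}

# TRUE for each query interval that overlaps any subject interval by >= 1 bp.
overlaps_any <- function(query, subject) {
  hit <- rep(FALSE, nrow(query))
  op <- overlap_pairs(query, subject)
  hit[unique(op$query)] <- TRUE
  hit
}

# Set operations on interval data.frames (union/intersection/difference of
# the covered base sets), chromosome-wise via IRanges.
interval_reduce <- function(df) {
  if (nrow(df) == 0L) return(df[, c("chrom", "start", "end")])
  parts <- lapply(split(df, df$chrom), function(d) {
    r <- IRanges::reduce(IRanges::IRanges(d$start + 1L, d$end))
    data.frame(chrom = d$chrom[1], start = IRanges::start(r) - 1L,
               end = IRanges::end(r), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out[order(chrom_rank(out$chrom), out$start), , drop = FALSE]
}

interval_intersect <- function(a, b) {
  chroms <- intersect(unique(a$chrom), unique(b$chrom))
  parts <- lapply(chroms, function(ch) {
    ra <- IRanges::reduce(IRanges::IRanges(a$start[a$chrom == ch] + 1L, a$end[a$chrom == ch]))
    rb <- IRanges::reduce(IRanges::IRanges(b$start[b$chrom == ch] + 1L, b$end[b$chrom == ch]))
    r <- IRanges::intersect(ra, rb)
    if (length(r) == 0L) return(NULL)
    data.frame(chrom = ch, start = IRanges::start(r) - 1L, end = IRanges::end(r),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, parts)
  if (is.null(out)) return(data.frame(chrom = character(0), start = integer(0), end = integer(0)))
  rownames(out) <- NULL
  out
}

interval_setdiff <- function(a, b) {
  if (nrow(a) == 0L) return(a[, c("chrom", "start", "end")])
  parts <- lapply(split(a, a$chrom), function(d) {
    ch <- d$chrom[1]
    ra <- IRanges::reduce(IRanges::IRanges(d$start + 1L, d$end))
    bi <- b[b$chrom == ch, , drop = FALSE]
    r <- if (nrow(bi)) {
      IRanges::setdiff(ra, IRanges::reduce(IRanges::IRanges(bi$start + 1L, bi$end)))
    } else ra
    if (length(r) == 0L) return(NULL)
    data.frame(chrom = ch, start = IRanges::start(r) - 1L, end = IRanges::end(r),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, parts)
  if (is.null(out)) return(data.frame(chrom = character(0), start = integer(0), end = integer(0)))
  rownames(out) <- NULL
  out[order(chrom_rank(out$chrom), out$start), , drop = FALSE]
}
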