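# Readers/writers for the tabular formats the pipeline touches. All
# coordinates are passed through in the 0-based half-open convention the
# files themselves use; no re-basing happens at IO boundaries.

.read_tab_lines <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines[nzchar(lines) & !startsWith(lines, "#") & !startsWith(lines, "track")]
}

#' Read a BED3/BED6 file
#'
#' @param path path to a tab-separated BED file (>= 3 columns). Column 4 is
#'   taken as name, 5 as score, 6 as strand when present.
#' @return a [genomic_intervals] data.frame.
#' @export
read_bed <- function(path) {
  lines <- .read_tab_lines(path)
  if (length(lines) == 0L)
    return(genomic_intervals(character(0), integer(0), integer(0)))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(fields)
  if (any(ncols < 3L))
    stop(sprintf("%s: malformed BED line %d (fewer than 3 columns)",
                 path, which(ncols < 3L)[1]), call. = FALSE)
  get <- function(i) vapply(fields, function(f) if (length(f) >= i) f[i] else NA_character_, "")
  start <- suppressWarnings(as.integer(get(2)))
  end <- suppressWarnings(as.integer(get(3)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad))
    stop(sprintf("%s: non-numeric coordinates at line %d", path, bad[1]), call. = FALSE)
  bad <- which(end <= start)
  if (length(bad))
    stop(sprintf("%s: end <= start at line %d", path, bad[1]), call. = FALSE)
  strand <- get(6); strand[is.na(strand)] <- "."
  score <- suppressWarnings(as.numeric(get(5)))
  genomic_intervals(get(1), start, end, strand = strand, name = get(4), score = score)
}

#' Write intervals as BED
#'
#' @param x a [genomic_intervals] data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  df <- as.data.frame(x)
  if (nrow(df)) {
    df <- df[order(chrom_rank(df$chrom), df$start), , drop = FALSE]
    df$name[is.na(df$name)] <- "."
    df$score[is.na(df$score)] <- 0
    out <- sprintf("%s\t%d\t%d\t%s\t%g\t%s", df$chrom, df$start, df$end,
                   df$name, df$score, df$strand)
  } else out <- character(0)
  writeLines(out, path)
  invisible(path)
}

#' Canonicalize a loop table
#'
#' Orders the two anchors of every loop so that
#' `(chromA, startA) <= (chromB, startB)` under natural chromosome order.
#' Idempotent; anchor swap never changes the canonical record.
#'
#' @param loops loop data.frame (columns `chromA,startA,endA,chromB,startB,endB`).
#' @return the canonicalized loop data.frame.
#' @export
canonicalize_loops <- function(loops) {
  if (nrow(loops) == 0L) return(loops)
  swap <- chrom_rank(loops$chromB) < chrom_rank(loops$chromA) |
    (loops$chromA == loops$chromB &
       (loops$startB < loops$startA |
          (loops$startB == loops$startA & loops$endB < loops$endA)))
  if (any(swap)) {
    a <- loops[swap, c("chromA", "startA", "endA")]
    loops[swap, c("chromA", "startA", "endA")] <- loops[swap, c("chromB", "startB", "endB")]
    loops[swap, c("chromB", "startB", "endB")] <- a
  }
  loops
}

.new_loops <- function(chromA, startA, endA, chromB, startB, endB, pet,
                       pvalue = NA_real_, qvalue = NA_real_, sample_id = NA_character_,
                       id = NULL) {
  n <- length(chromA)
  df <- data.frame(
    id = if (is.null(id)) sprintf("loop_%d", seq_len(n)) else as.character(id),
    chromA = as.character(chromA), startA = as.integer(startA), endA = as.integer(endA),
    chromB = as.character(chromB), startB = as.integer(startB), endB = as.integer(endB),
    pet = as.integer(pet),
    pvalue = rep_len(as.numeric(pvalue), n),
    qvalue = rep_len(as.numeric(qvalue), n),
    sample_id = rep_len(as.character(sample_id), n),
    stringsAsFactors = FALSE
  )
  if (any(df$pet < 0L, na.rm = TRUE)) stop("negative PET count", call. = FALSE)
  canonicalize_loops(df)
}

#' Read a mango-style loop table
#'
#' Accepts 8-10 tab-separated columns:
#' `chrA startA endA chrB startB endB petCount [pValue] [qValue]`
#' (a 10th column, if present, is kept as the record name). Anchors are
#' canonicalized on read; PET counts must be integers.
#'
#' @param path path to the loop table.
#' @param sample_id optional sample label attached to every loop.
#' @return a loop data.frame with columns
#'   `id, chromA, startA, endA, chromB, startB, endB, pet, pvalue, qvalue, sample_id`.
#' @export
read_loops_mango <- function(path, sample_id = NA_character_) {
  lines <- .read_tab_lines(path)
  if (length(lines) == 0L)
    return(.new_loops(character(0), integer(0), integer(0), character(0),
                      integer(0), integer(0), integer(0)))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(fields)
  if (any(ncols < 7L))
    stop(sprintf("%s: loop line %d has fewer than 7 columns", path,
                 which(ncols < 7L)[1]), call. = FALSE)
  get <- function(i) vapply(fields, function(f) if (length(f) >= i) f[i] else NA_character_, "")
  pet_chr <- get(7)
  pet <- suppressWarnings(as.numeric(pet_chr))
  bad <- which(is.na(pet) | pet != floor(pet))
  if (length(bad))
    stop(sprintf("%s: non-integer PET count '%s' at line %d", path,
                 pet_chr[bad[1]], bad[1]), call. = FALSE)
  for (col in c(2, 3, 5, 6)) {
    v <- suppressWarnings(as.integer(get(col)))
    if (anyNA(v))
      stop(sprintf("%s: non-numeric coordinate at line %d", path,
                   which(is.na(v))[1]), call. = FALSE)
  }
  name <- get(10)                       # optional 10th column: record name/id
  loops <- .new_loops(
    get(1), as.integer(get(2)), as.integer(get(3)),
    get(4), as.integer(get(5)), as.integer(get(6)),
    as.integer(pet),
    pvalue = suppressWarnings(as.numeric(get(8))),
    qvalue = suppressWarnings(as.numeric(get(9))),
    sample_id = sample_id,
    id = if (!anyNA(name) && !anyDuplicated(name)) name else NULL
  )
  validate_intervals(data.frame(chrom = loops$chromA, start = loops$startA,
                                end = loops$endA, strand = "."))
  validate_intervals(data.frame(chrom = loops$chromB, start = loops$startB,
                                end = loops$endB, strand = "."))
  loops
}

#' Write loops as BEDPE / mango-style table
#'
#' Emits `chrA startA endA chrB startB endB pet [pvalue] [qvalue]`; p/q
#' columns are written whenever any loop carries them, so
#' `read_loops_mango(write_bedpe(x))` round-trips canonical records.
#'
#' @param loops loop data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bedpe <- function(loops, path) {
  loops <- canonicalize_loops(loops)
  if (nrow(loops)) {
    loops <- loops[order(chrom_rank(loops$chromA), loops$startA,
                         chrom_rank(loops$chromB), loops$startB), , drop = FALSE]
    has_q <- any(!is.na(loops$qvalue)); has_p <- any(!is.na(loops$pvalue)) || has_q
    out <- sprintf("%s\t%d\t%d\t%s\t%d\t%d\t%d", loops$chromA, loops$startA,
                   loops$endA, loops$chromB, loops$startB, loops$endB, loops$pet)
    if (has_p) out <- paste(out, format_number(loops$pvalue), sep = "\t")
    if (has_q) {
      out <- paste(out, format_number(loops$qvalue), sep = "\t")
      out <- paste(out, loops$id, sep = "\t")   # 10th column: record id
    }
  } else out <- character(0)
  writeLines(out, path)
  invisible(path)
}

format_number <- function(x) {
  out <- vapply(x, function(v) if (is.na(v)) "NA" else format(v, digits = 17, scientific = FALSE), "")
  out
}

#' Write a coverage track as bedGraph
#'
#' @param track data.frame with columns `chrom, start, end, value`; spans
#'   must be disjoint within each chromosome (bedGraph requirement).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  if (nrow(track)) {
    track <- track[order(chrom_rank(track$chrom), track$start), , drop = FALSE]
    ov <- unlist(lapply(split(track, track$chrom), function(d)
      any(d$start[-1] < d$end[-nrow(d)])), use.names = FALSE)
    if (any(ov)) stop("bedGraph intervals must be disjoint within a chromosome",
                      call. = FALSE)
    out <- sprintf("%s\t%d\t%d\t%s", track$chrom, track$start, track$end,
                   format_number(track$value))
  } else out <- character(0)
  writeLines(out, path)
  invisible(path)
}

#' Read a bedGraph track
#'
#' @param path path to a 4-column bedGraph file.
#' @return data.frame `chrom, start, end, value`.
#' @export
read_bedgraph <- function(path) {
  lines <- .read_tab_lines(path)
  if (length(lines) == 0L)
    return(data.frame(chrom = character(0), start = integer(0), end = integer(0),
                      value = numeric(0)))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 4L))
    stop(sprintf("%s: bedGraph line %d has fewer than 4 columns", path,
                 which(lengths(fields) < 4L)[1]), call. = FALSE)
  df <- data.frame(
    chrom = vapply(fields, `[`, "", 1),
    start = as.integer(vapply(fields, `[`, "", 2)),
    end = as.integer(vapply(fields, `[`, "", 3)),
    value = as.numeric(vapply(fields, `[`, "", 4)),
    stringsAsFactors = FALSE
  )
  if (any(df$end <= df$start)) stop(path, ": bedGraph interval with end <= start",
                                    call. = FALSE)
  df
}

#' Write a generic TSV with a header
#' @param df data.frame to write.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_tsv]
#' @param path input path.
#' @return data.frame.
#' @export
read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE, comment.char = "")
}

.log_stage <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, sprintf(...)))
}
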