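# In-silico restriction digestion and PET (paired-end tag) processing: the
# computational core of ligation-based proximity data. DpnII cuts at GATC;
# fragments tile each chromosome; a read pair is a valid PET only when its
# two ends fall on different, non-adjacent fragments.

LIGATION_SITES <- c("GATCAGATTTGGGGATC", "GATCCCCAAATCTGATC")

#' In-silico restriction digestion
#'
#' Cuts every chromosome at the start of each exact occurrence of the
#' recognition site (default GATC, DpnII) and returns the resulting fragment
#' map. Fragments tile each chromosome exactly: sorted, disjoint, union equal
#' to `[0, length)`. A chromosome without sites yields a single fragment.
#'
#' @param genome a named `Biostrings::DNAStringSet`, or the path to a FASTA
#'   file.
#' @param site recognition sequence (default `"GATC"`).
#' @return a `fragment_map`: data.frame with columns
#'   `chrom, start, end, frag_index` (`frag_index` is per-chromosome, 1-based).
#' @export
digest_genome <- function(genome, site = "GATC") {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  parts <- lapply(seq_along(genome), function(i) {
    L <- Biostrings::width(genome)[i]
    m <- Biostrings::matchPattern(site, genome[[i]])
    cuts <- IRanges::start(m) - 1L          # 0-based cut positions
    bounds <- sort(unique(c(0L, cuts, L)))
    bounds <- bounds[bounds <= L]
    start <- bounds[-length(bounds)]
    end <- bounds[-1]
    keep <- end > start                      # drop empty leading fragment
    data.frame(chrom = names(genome)[i], start = start[keep], end = end[keep],
               frag_index = seq_len(sum(keep)), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  class(out) <- c("fragment_map", "data.frame")
  out
}

#' Trim a read at the ligation junction
#'
#' If either ligation-site string (the chimeric sequence formed where the
#' phosphorylated linker joins two fragment ends) occurs in the read, the
#' read is truncated to the prefix ending at the earliest occurrence plus
#' 4 bases, retaining the fragment-terminal GATC. Reads without a junction
#' are returned unchanged.
#'
#' @param reads character vector of read sequences.
#' @param sites ligation-site strings (defaults to the two linker junctions).
#' @return data.frame with columns `seq` (trimmed sequence) and
#'   `junction` (logical, junction found).
#' @export
trim_linker <- function(reads, sites = LIGATION_SITES) {
  offs <- rep(NA_integer_, length(reads))
  for (s in sites) {
    o <- regexpr(s, reads, fixed = TRUE)
    o <- ifelse(o < 0L, NA_integer_, as.integer(o) - 1L)   # 0-based offset
    offs <- pmin(offs, o, na.rm = TRUE)
  }
  found <- !is.na(offs)
  out <- reads
  out[found] <- substr(reads[found], 1L, offs[found] + 4L)
  data.frame(seq = out, junction = found, stringsAsFactors = FALSE)
}

#' Assign positions to restriction fragments
#'
#' Binary-search lookup of 0-based positions in the fragment tiling.
#'
#' @param fragmap a `fragment_map` from [digest_genome].
#' @param chrom,pos parallel vectors of chromosome names and 0-based positions.
#' @return integer vector of per-chromosome fragment indices.
#' @export
assign_fragment <- function(fragmap, chrom, pos) {
  out <- integer(length(chrom))
  for (ch in unique(chrom)) {
    fm <- fragmap[fragmap$chrom == ch, , drop = FALSE]
    if (nrow(fm) == 0L) stop("chromosome not in fragment map: ", ch, call. = FALSE)
    sel <- chrom == ch
    p <- pos[sel]
    if (any(p < 0L | p >= max(fm$end)))
      stop(sprintf("position out of range on %s (length %d)", ch, max(fm$end)),
           call. = FALSE)
    out[sel] <- fm$frag_index[findInterval(p, fm$start)]
  }
  out
}

#' Classify a PET from its two ends
#'
#' Standard Hi-C quality classes: ends on different non-adjacent fragments
#' are `valid`; same fragment with inward-facing strands is a `dangling_end`,
#' outward-facing a `self_circle`; adjacent fragments (|indexA - indexB| = 1
#' on the same chromosome) are `re_ligation`; a missing mate is `single_end`;
#' same fragment with equal strands is `unassigned`. Classification is
#' symmetric in the two ends. Ends on different chromosomes are always
#' `valid`.
#'
#' @param chromA,posA,strandA,fragA first end: chromosome, 0-based 5'
#'   position, strand, fragment index (vectors).
#' @param chromB,posB,strandB,fragB second end; `NA` marks a missing mate.
#' @return character vector of classifications.
#' @export
classify_pet <- function(chromA, posA, strandA, fragA,
                         chromB, posB, strandB, fragB) {
  n <- length(chromA)
  cls <- character(n)
  missing <- is.na(chromB) | is.na(posB) | is.na(fragB) | is.na(chromA) | is.na(fragA)
  cls[missing] <- "single_end"
  trans <- !missing & chromA != chromB
  cls[trans] <- "valid"
  cis <- !missing & !trans
  same <- cis & fragA == fragB
  adj <- cis & abs(fragA - fragB) == 1L
  far <- cis & !same & !adj
  cls[far] <- "valid"
  cls[adj] <- "re_ligation"
  # same fragment: orient by position; inward = left end on '+', right on '-'
  if (any(same)) {
    leftA <- posA[same] <= posB[same]
    s_left <- ifelse(leftA, strandA[same], strandB[same])
    s_right <- ifelse(leftA, strandB[same], strandA[same])
    cls[same] <- ifelse(s_left == "+" & s_right == "-", "dangling_end",
                 ifelse(s_left == "-" & s_right == "+", "self_circle", "unassigned"))
  }
  cls
}

#' Duplicate and multi-mapping policy
#'
#' Duplicates (identical end coordinates and strands) are retained in both
#' modes; records flagged multi-mapped are removed only in `plhichip` mode.
#'
#' @param pets PET table with columns
#'   `chromA,posA,strandA,chromB,posB,strandB` and optionally `multimapped`.
#' @param mode `"plhic"` (input material, multi-mapped kept) or `"plhichip"`
#'   (IP material, multi-mapped removed).
#' @return the filtered PET table.
#' @export
dedup_policy <- function(pets, mode) {
  if (!mode %in% c("plhic", "plhichip"))
    stop("unknown mode '", mode, "'; expected 'plhic' or 'plhichip'", call. = FALSE)
  n0 <- nrow(pets)
  if (mode == "plhichip" && "multimapped" %in% names(pets))
    pets <- pets[!pets$multimapped, , drop = FALSE]
  .log_stage("dedup", "mode=%s in=%d kept=%d (duplicates retained)", mode, n0, nrow(pets))
  pets
}

#' Extract and classify PETs from synthetic reads
#'
#' Trims ligation junctions, places each end by positional lookup of its
#' planted coordinates (no aligner: the synthetic truth supplies the mapping),
#' assigns restriction fragments and classifies each pair.
#'
#' @param fastq1,fastq2 FASTQ paths for the two read mates.
#' @param truth read-truth table from [generate_reads] (columns
#'   `read_id, chromA, posA, strandA, chromB, posB, strandB, is_spike,
#'   multimapped`).
#' @param fragmap fragment map of the combined primary+spike genome.
#' @param mode duplicate policy mode, see [dedup_policy].
#' @return list with `pets` (classified PET table) and `qc`
#'   (counts per class and percent valid).
#' @export
extract_pets <- function(fastq1, fastq2, truth, fragmap, mode = "plhichip") {
  r1 <- Biostrings::readDNAStringSet(fastq1, format = "fastq")
  r2 <- Biostrings::readDNAStringSet(fastq2, format = "fastq")
  ids <- sub("\\s.*$", "", names(r1))
  t1 <- trim_linker(as.character(r1))
  t2 <- trim_linker(as.character(r2))
  truth <- truth[match(ids, truth$read_id), , drop = FALSE]
  fragA <- assign_fragment(fragmap, truth$chromA, truth$posA)
  fragB <- rep(NA_integer_, nrow(truth))
  has_mate <- !is.na(truth$chromB)
  fragB[has_mate] <- assign_fragment(fragmap, truth$chromB[has_mate], truth$posB[has_mate])
  cls <- classify_pet(truth$chromA, truth$posA, truth$strandA, fragA,
                      truth$chromB, truth$posB, truth$strandB, fragB)
  pets <- data.frame(
    read_id = ids,
    chromA = truth$chromA, posA = truth$posA, strandA = truth$strandA, fragA = fragA,
    chromB = truth$chromB, posB = truth$posB, strandB = truth$strandB, fragB = fragB,
    junction = t1$junction | t2$junction,
    classification = cls,
    is_spike = truth$is_spike,
    multimapped = if ("multimapped" %in% names(truth)) truth$multimapped else FALSE,
    stringsAsFactors = FALSE
  )
  pets <- dedup_policy(pets, mode)
  list(pets = pets, qc = pet_qc(pets))
}

#' QC summary of a classified PET table
#' @param pets classified PET table.
#' @return data.frame of counts per classification plus percent valid.
#' @export
pet_qc <- function(pets) {
  classes <- c("valid", "dangling_end", "self_circle", "re_ligation",
               "single_end", "unassigned")
  counts <- vapply(classes, function(cl) sum(pets$classification == cl), 0L)
  data.frame(classification = classes, count = counts,
             percent = if (nrow(pets)) round(100 * counts / nrow(pets), 2) else 0,
             row.names = NULL, stringsAsFactors = FALSE)
}
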