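# Functional annotation of loop anchors. Each anchor gets exactly one class:
# the first class in the fixed priority order whose interval set overlaps the
# anchor by >= 1 bp, or "intergenic" when none does.

#' Derive the annotation catalog from primary inputs
#'
#' Builds the priority-ordered interval catalog the annotator consumes:
#' promoters are TSS +/- `promoter_window`, TES windows are TES +/-
#' `tes_window` (both strand-aware: the TSS of a minus-strand gene is its
#' right end), gene bodies are the union of exons and introns (the gene
#' span), and enhancers are the intervals covered by both H3K4me1 and
#' H3K27ac peaks but not overlapping any H3K4me3 peak.
#'
#' @param genes data.frame `chrom, start, end, strand, gene_id` (0-based
#'   half-open gene spans).
#' @param repeats named list of interval data.frames per repeat/RNA-gene
#'   class (tRNA, rRNA, miRNA, snRNA, snoRNA, SINE, LINE, LTR, satellite);
#'   missing classes become empty tracks.
#' @param histone named list with elements `H3K4me1`, `H3K27ac`, `H3K4me3`
#'   (interval data.frames).
#' @param config a [pipeline_config] supplying windows and priority order.
#' @return an `annotation_catalog`: a named list of interval data.frames in
#'   priority order.
#' @export
derive_catalog <- function(genes, repeats = list(), histone = list(),
                           config = pipeline_config()) {
  if (nrow(genes) && (anyNA(genes$start) || anyNA(genes$strand)))
    stop("gene records must carry coordinates and strand", call. = FALSE)
  tss <- ifelse(genes$strand == "-", genes$end - 1L, genes$start)
  tes <- ifelse(genes$strand == "-", genes$start, genes$end - 1L)
  pw <- config$promoter_window; tw <- config$tes_window
  mk <- function(center, w) data.frame(
    chrom = genes$chrom, start = pmax(0L, as.integer(center - w)),
    end = as.integer(center + w), gene_id = genes$gene_id,
    stringsAsFactors = FALSE)
  promoter <- mk(tss, pw)
  tes_win <- mk(tes, tw)
  gene_body <- data.frame(chrom = genes$chrom, start = genes$start,
                          end = genes$end, gene_id = genes$gene_id,
                          stringsAsFactors = FALSE)
  empty <- data.frame(chrom = character(0), start = integer(0), end = integer(0))
  h <- function(nm) if (!is.null(histone[[nm]])) histone[[nm]] else empty
  # co-marked sites (H3K4me1 AND H3K27ac); any such site overlapping an
  # H3K4me3 peak is excluded as a whole (promoter-like, not an enhancer)
  co <- interval_intersect(h("H3K4me1"), h("H3K27ac"))
  enhancer <- co[!overlaps_any(co, h("H3K4me3")), , drop = FALSE]
  enhancer <- enhancer[order(chrom_rank(enhancer$chrom), enhancer$start), ,
                       drop = FALSE]
  rownames(enhancer) <- NULL
  catalog <- list(enhancer = enhancer, promoter = promoter, TES = tes_win,
                  gene_body = gene_body)
  for (cl in setdiff(config$priority, names(catalog)))
    catalog[[cl]] <- if (!is.null(repeats[[cl]])) repeats[[cl]] else empty
  catalog <- catalog[config$priority]
  class(catalog) <- c("annotation_catalog", "list")
  attr(catalog, "priority") <- config$priority
  catalog
}

#' Filter loops on their q-value
#'
#' Retains loops with `qvalue <= q_max` (inclusive threshold) and logs the
#' number dropped.
#'
#' @param loops loop data.frame.
#' @param q_max inclusive q-value cutoff (default 0.01).
#' @param require_q error on absent q-values (default TRUE); with `FALSE`,
#'   loops without a q-value are kept.
#' @return the filtered loop data.frame.
#' @export
filter_loops <- function(loops, q_max = 0.01, require_q = TRUE) {
  if (anyNA(loops$qvalue)) {
    if (require_q) stop("loops without q-value; pass require_q = FALSE to keep them",
                        call. = FALSE)
    keep <- is.na(loops$qvalue) | loops$qvalue <= q_max
  } else keep <- loops$qvalue <= q_max
  .log_stage("filter", "q <= %g: %d in, %d dropped", q_max, nrow(loops), sum(!keep))
  loops[keep, , drop = FALSE]
}

#' Annotate anchors with their highest-priority class
#'
#' @param anchors interval data.frame (`chrom, start, end`).
#' @param catalog an `annotation_catalog` from [derive_catalog].
#' @return character vector: the first class in priority order overlapping
#'   each anchor by >= 1 bp, `"intergenic"` if none. Strand is ignored.
#' @export
annotate_anchor <- function(anchors, catalog) {
  cls <- rep("intergenic", nrow(anchors))
  open <- rep(TRUE, nrow(anchors))
  for (nm in attr(catalog, "priority")) {
    if (!any(open)) break
    track <- catalog[[nm]]
    if (is.null(track) || nrow(track) == 0L) next
    idx <- which(open)
    hit <- overlaps_any(anchors[idx, , drop = FALSE], track)
    cls[idx[hit]] <- nm
    open[idx[hit]] <- FALSE
  }
  cls
}

#' Annotate both anchors of every loop
#'
#' @param loops loop data.frame.
#' @param catalog an `annotation_catalog`.
#' @return loops with `classA`, `classB` and a symmetric `loop_class` label
#'   (classes joined by `"-"` in priority order, so anchor order never
#'   changes the label).
#' @export
annotate_loops <- function(loops, catalog) {
  anchorsA <- data.frame(chrom = loops$chromA, start = loops$startA, end = loops$endA)
  anchorsB <- data.frame(chrom = loops$chromB, start = loops$startB, end = loops$endB)
  loops$classA <- annotate_anchor(anchorsA, catalog)
  loops$classB <- annotate_anchor(anchorsB, catalog)
  loops$loop_class <- loop_class_label(loops$classA, loops$classB,
                                       attr(catalog, "priority"))
  loops
}

#' Symmetric loop-class label from two anchor classes
#' @param classA,classB anchor class labels.
#' @param priority the priority order used to fix label orientation;
#'   `"intergenic"` always sorts last.
#' @return character vector of `"classX-classY"` labels.
#' @export
loop_class_label <- function(classA, classB, priority = pipeline_config()$priority) {
  lev <- c(priority, "intergenic")
  ra <- match(classA, lev); rb <- match(classB, lev)
  ifelse(ra <= rb, paste(classA, classB, sep = "-"), paste(classB, classA, sep = "-"))
}

#' Round half away from zero
#' @param x numeric vector.
#' @return integer vector rounded half away from zero.
#' @export
round_half_up <- function(x) as.integer(sign(x) * floor(abs(x) + 0.5))

#' Tabulate loop classes
#'
#' Counts loops per unordered class pair and reports integer percentages
#' (`100 * count / total`, rounded half away from zero, the convention of
#' printed figures: 1277 of 4591 prints as 28%).
#'
#' @param loops annotated loop data.frame (needs `loop_class`), or a
#'   character vector of loop-class labels.
#' @param total denominator for percentages; defaults to the number of loops.
#' @return data.frame `loop_class, count, percent`, sorted by count.
#' @export
classify_loops <- function(loops, total = NULL) {
  labels <- if (is.data.frame(loops)) loops$loop_class else as.character(loops)
  if (is.null(total)) total <- length(labels)
  tab <- table(labels)
  nm <- names(tab)
  if (is.null(nm)) nm <- character(0)
  out <- data.frame(loop_class = nm, count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out$percent <- round_half_up(100 * out$count / total)
  out[order(-out$count, out$loop_class), , drop = FALSE]
}
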