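# Overlap classification between two loop sets with pairtopair semantics:
# "either" requires at least one anchor of a to overlap an anchor of b,
# "both" requires the two anchors of a to overlap the two anchors of b in
# one of the two pairing orientations. Strand is ignored; self-hits
# (identical record identity) are excluded; minimum anchor overlap is 1 bp.

.loop_anchors <- function(loops) {
  rbind(
    data.frame(loop = seq_len(nrow(loops)), side = 1L, chrom = loops$chromA,
               start = loops$startA, end = loops$endA, stringsAsFactors = FALSE),
    data.frame(loop = seq_len(nrow(loops)), side = 2L, chrom = loops$chromB,
               start = loops$startB, end = loops$endB, stringsAsFactors = FALSE)
  )
}

#' Match two loop sets pairtopair-style
#'
#' @param setA,setB loop data.frames (canonicalized; each with an `id`
#'   column used for self-hit exclusion).
#' @param type `"either"` (>= 1 shared anchor) or `"both"` (both anchors
#'   shared, in either pairing orientation).
#' @return data.frame `idA, idB` of matching loop pairs. Records with equal
#'   `id` (self-hits) never match; distinct records with identical
#'   coordinates do.
#' @export
pair_to_pair <- function(setA, setB, type = c("either", "both")) {
  type <- match.arg(type)
  if (nrow(setA) == 0L || nrow(setB) == 0L)
    return(data.frame(idA = character(0), idB = character(0)))
  ancA <- .loop_anchors(setA)
  ancB <- .loop_anchors(setB)
  hits <- overlap_pairs(ancA[, c("chrom", "start", "end")],
                        ancB[, c("chrom", "start", "end")])
  if (nrow(hits) == 0L) return(data.frame(idA = character(0), idB = character(0)))
  # per (loopA, loopB): which of the 4 anchor pairings overlap
  key <- data.frame(la = ancA$loop[hits$query], sa = ancA$side[hits$query],
                    lb = ancB$loop[hits$subject], sb = ancB$side[hits$subject])
  pair_id <- paste(key$la, key$lb)
  if (type == "either") {
    keep <- !duplicated(pair_id)
    out <- key[keep, c("la", "lb")]
  } else {
    combos <- split(paste0(key$sa, key$sb), pair_id)
    ok <- vapply(combos, function(cc) {
      (("11" %in% cc) && ("22" %in% cc)) || (("12" %in% cc) && ("21" %in% cc))
    }, TRUE)
    ids <- names(combos)[ok]
    if (!length(ids)) return(data.frame(idA = character(0), idB = character(0)))
    sp <- strsplit(ids, " ", fixed = TRUE)
    out <- data.frame(la = as.integer(vapply(sp, `[`, "", 1)),
                      lb = as.integer(vapply(sp, `[`, "", 2)))
  }
  res <- data.frame(idA = setA$id[out$la], idB = setB$id[out$lb],
                    stringsAsFactors = FALSE)
  res <- res[res$idA != res$idB, , drop = FALSE]   # prevent self-hits
  rownames(res) <- NULL
  res
}

#' A-centred overlap summary between two loop sets
#'
#' Loop-level counting: each loop of `setA` is classified once as sharing
#' `both` anchors with some loop of `setB`, exactly `one` anchor
#' (either-match without a both-match), or `none`. The one-anchor count is
#' the either count minus the both count.
#'
#' @param setA,setB loop data.frames.
#' @return list with `per_loop` (data.frame `id, overlap_type`) and `summary`
#'   (counts: `either`, `one`, `both`, `a_only`, `b_only`, `n_a`, `n_b`).
#' @export
venn_summary <- function(setA, setB) {
  m_either <- pair_to_pair(setA, setB, "either")
  m_both <- pair_to_pair(setA, setB, "both")
  either_ids <- unique(m_either$idA)
  both_ids <- unique(m_both$idA)
  otype <- ifelse(setA$id %in% both_ids, "both",
           ifelse(setA$id %in% either_ids, "one", "none"))
  summary <- data.frame(
    n_a = nrow(setA), n_b = nrow(setB),
    either = length(either_ids),
    both = length(both_ids),
    one = length(either_ids) - length(both_ids),
    a_only = nrow(setA) - length(either_ids),
    b_only = nrow(setB) - length(unique(m_either$idB))
  )
  list(per_loop = data.frame(id = setA$id, overlap_type = otype,
                             stringsAsFactors = FALSE),
       summary = summary)
}

#' Class tabulation per overlap stratum
#'
#' Splits `setA` into its `"A only"` and `"joint"` strata (per the A-centred
#' overlap report), takes the `"B only"` stratum from `setB`, and applies
#' [classify_loops] within each.
#'
#' @param setA,setB annotated loop data.frames (with `loop_class`).
#' @param report a [venn_summary] result for `setA` vs `setB`; computed when
#'   missing.
#' @return named list of class tabulations: `a_only`, `joint`, `b_only`.
#' @export
stratify_shared <- function(setA, setB, report = NULL) {
  if (is.null(report)) report <- venn_summary(setA, setB)
  shared_a <- report$per_loop$id[report$per_loop$overlap_type != "none"]
  rev_match <- pair_to_pair(setB, setA, "either")
  shared_b <- unique(rev_match$idA)
  list(
    a_only = classify_loops(setA[!setA$id %in% shared_a, , drop = FALSE]),
    joint = classify_loops(setA[setA$id %in% shared_a, , drop = FALSE]),
    b_only = classify_loops(setB[!setB$id %in% shared_b, , drop = FALSE])
  )
}
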