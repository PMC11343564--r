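# Promoter-hub networks: anchors are nodes (merged by exact coordinate
# identity), loops are edges weighted by PET count, clusters are connected
# components. The largest hubs connect tens of promoters and enhancers.

anchor_key <- function(chrom, start, end) sprintf("%s:%d-%d", chrom, start, end)

#' Build the interaction graph from annotated loops
#'
#' Nodes are distinct anchors (exact coordinate identity); each node carries
#' its functional class. Parallel loops between the same anchor pair are
#' merged into one edge with summed PET weight (merges are logged).
#'
#' @param loops annotated loop data.frame (with `classA`, `classB`).
#' @return an `igraph` graph with vertex attributes `name` (anchor key),
#'   `class`, `chrom`, `start`, `end`, and edge attribute `weight`
#'   (summed PETs).
#' @export
build_graph <- function(loops) {
  if (nrow(loops) == 0L)
    return(igraph::make_empty_graph(directed = FALSE))
  keyA <- anchor_key(loops$chromA, loops$startA, loops$endA)
  keyB <- anchor_key(loops$chromB, loops$startB, loops$endB)
  nodes <- data.frame(
    name = c(keyA, keyB),
    class = c(loops$classA, loops$classB),
    chrom = c(loops$chromA, loops$chromB),
    start = c(loops$startA, loops$startB),
    end = c(loops$endA, loops$endB),
    stringsAsFactors = FALSE
  )
  nodes <- nodes[!duplicated(nodes$name), , drop = FALSE]
  edges <- data.frame(from = keyA, to = keyB, weight = as.numeric(loops$pet),
                      stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE, vertices = nodes)
  n_par <- igraph::ecount(g) - igraph::ecount(igraph::simplify(g))
  if (n_par > 0) .log_stage("hubs", "merged %d parallel loop(s)", n_par)
  igraph::simplify(g, edge.attr.comb = list(weight = "sum"))
}

#' Cluster statistics from the interaction graph
#'
#' Clusters are the connected components of the graph. Per cluster the node
#' count, promoter-class and enhancer-class node counts, and total PET weight
#' are reported, sorted by node count (descending).
#'
#' @param graph an igraph from [build_graph].
#' @return data.frame
#'   `cluster_id, n_nodes, n_promoters, n_enhancers, total_pets`, plus the
#'   per-node membership as attribute `"membership"` (named integer vector).
#' @export
clusters <- function(graph) {
  if (igraph::vcount(graph) == 0L) {
    out <- data.frame(cluster_id = integer(0), n_nodes = integer(0),
                      n_promoters = integer(0), n_enhancers = integer(0),
                      total_pets = numeric(0))
    attr(out, "membership") <- integer(0)
    return(out)
  }
  comp <- igraph::components(graph)
  cls <- igraph::V(graph)$class
  if (is.null(cls)) cls <- rep(NA_character_, igraph::vcount(graph))
  ew <- igraph::E(graph)$weight
  e_ends <- igraph::ends(graph, igraph::E(graph), names = FALSE)
  e_comp <- comp$membership[e_ends[, 1]]
  out <- data.frame(
    cluster_id = seq_len(comp$no),
    n_nodes = as.integer(comp$csize),
    n_promoters = vapply(seq_len(comp$no), function(k)
      sum(comp$membership == k & cls == "promoter", na.rm = TRUE), 0L),
    n_enhancers = vapply(seq_len(comp$no), function(k)
      sum(comp$membership == k & cls == "enhancer", na.rm = TRUE), 0L),
    total_pets = vapply(seq_len(comp$no), function(k)
      sum(ew[e_comp == k]), 0)
  )
  out <- out[order(-out$n_nodes, out$cluster_id), , drop = FALSE]
  rownames(out) <- NULL
  membership <- comp$membership
  names(membership) <- igraph::V(graph)$name
  attr(out, "membership") <- membership
  out
}

#' Compare cluster sizes between two groups (Wilcoxon rank-sum)
#'
#' Two-sided rank-sum test on the numbers of nodes per cluster; exact for
#' small tie-free samples (<= 20 total), normal approximation with tie
#' correction otherwise.
#'
#' @param sizesA,sizesB numeric vectors of cluster sizes (>= 3 each).
#' @return list with `p_value` and the underlying `htest`.
#' @export
compare_cluster_sizes <- function(sizesA, sizesB) {
  if (length(sizesA) < 3L || length(sizesB) < 3L)
    stop("need >= 3 clusters per group; report descriptive sizes only",
         call. = FALSE)
  exact <- (length(sizesA) + length(sizesB)) <= 20L && !any(duplicated(c(sizesA, sizesB)))
  # no continuity correction in the approximate branch so that symmetric
  # data (identical size multisets) give p = 1 exactly
  ht <- suppressWarnings(stats::wilcox.test(sizesA, sizesB,
                                            alternative = "two.sided",
                                            exact = exact, correct = FALSE))
  p <- ht$p.value
  if (is.nan(p)) p <- 1   # complete ties: no evidence of a difference
  list(p_value = p, test = ht)
}

#' Map promoter-class nodes to genes
#'
#' A promoter node is assigned the gene whose promoter window contains the
#' anchor midpoint; ties are broken by nearest TSS.
#'
#' @param graph igraph from [build_graph].
#' @param genes gene data.frame (`chrom, start, end, strand, gene_id`).
#' @param promoter_window promoter half-width (bp).
#' @return data.frame `anchor, gene_id, cluster_id` for promoter-class nodes
#'   with a gene assignment.
#' @export
hub_genes <- function(graph, genes, promoter_window = 500L) {
  stats_df <- clusters(graph)
  membership <- attr(stats_df, "membership")
  v <- data.frame(name = igraph::V(graph)$name, class = igraph::V(graph)$class,
                  chrom = igraph::V(graph)$chrom,
                  mid = (igraph::V(graph)$start + igraph::V(graph)$end) %/% 2L,
                  stringsAsFactors = FALSE)
  v <- v[v$class == "promoter", , drop = FALSE]
  if (nrow(v) == 0L)
    return(data.frame(anchor = character(0), gene_id = character(0),
                      cluster_id = integer(0)))
  tss <- ifelse(genes$strand == "-", genes$end - 1L, genes$start)
  rows <- lapply(seq_len(nrow(v)), function(i) {
    cand <- which(genes$chrom == v$chrom[i] & abs(tss - v$mid[i]) <= promoter_window)
    if (!length(cand)) return(NULL)
    best <- cand[which.min(abs(tss[cand] - v$mid[i]))]
    data.frame(anchor = v$name[i], gene_id = genes$gene_id[best],
               cluster_id = unname(membership[v$name[i]]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(anchor = character(0), gene_id = character(0),
                                      cluster_id = integer(0))
  out
}

#' Merge duplicate gene entries by median PET count
#' @param genes character vector of gene ids.
#' @param pets numeric PET counts parallel to `genes`.
#' @return data.frame `gene_id, pets` with one row per gene (median PETs).
#' @export
merge_duplicate_genes <- function(genes, pets) {
  agg <- tapply(pets, genes, stats::median)
  data.frame(gene_id = names(agg), pets = as.numeric(agg),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Gene-set over-representation of hub genes (hypergeometric)
#'
#' Upper-tail hypergeometric test per gene set with Benjamini-Hochberg
#' correction; sets with q <= `q_max` are flagged. Hub genes absent from the
#' universe are dropped (logged).
#'
#' @param hub_genes character vector of genes of interest (duplicates allowed;
#'   merge with [merge_duplicate_genes] first when PETs matter).
#' @param gene_sets named list of character vectors (the sets).
#' @param universe character vector: the gene universe.
#' @param q_max significance threshold on BH-adjusted p (default 0.05).
#' @return data.frame
#'   `set, n_set, n_hub, overlap, p_value, q_value, significant`.
#' @export
hub_gene_enrichment <- function(hub_genes, gene_sets, universe, q_max = 0.05) {
  hub_genes <- unique(hub_genes)
  missing <- setdiff(hub_genes, universe)
  if (length(missing))
    .log_stage("enrich", "dropping %d hub gene(s) absent from universe",
               length(missing))
  hub <- intersect(hub_genes, universe)
  N <- length(unique(universe)); n <- length(hub)
  rows <- lapply(names(gene_sets), function(s) {
    set <- intersect(unique(gene_sets[[s]]), universe)
    K <- length(set); k <- length(intersect(hub, set))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set = s, n_set = K, n_hub = n, overlap = k, p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  out$significant <- out$q_value <= q_max
  out[order(out$p_value), , drop = FALSE]
}

#' Export the graph as SIF-style edge list and node table
#' @param graph igraph from [build_graph].
#' @param prefix path prefix; writes `<prefix>.sif` and `<prefix>_nodes.tsv`.
#' @return character vector of the two paths, invisibly.
#' @export
export_graph <- function(graph, prefix) {
  ends <- igraph::ends(graph, igraph::E(graph))
  sif <- sprintf("%s\tinteracts\t%s", ends[, 1], ends[, 2])
  writeLines(sif, paste0(prefix, ".sif"))
  nodes <- data.frame(name = igraph::V(graph)$name, class = igraph::V(graph)$class)
  write_tsv(nodes, paste0(prefix, "_nodes.tsv"))
  invisible(c(paste0(prefix, ".sif"), paste0(prefix, "_nodes.tsv")))
}
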