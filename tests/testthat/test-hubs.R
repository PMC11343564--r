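mk_loops <- function(pairs, classes = NULL, pet = 2L) {
  # pairs: list of c(anchorA, anchorB) keys "chrom:start-end"
  parse <- function(k) {
    m <- regmatches(k, regexec("^(.*):(\\d+)-(\\d+)$", k))[[1]]
    list(chrom = m[2], start = as.integer(m[3]), end = as.integer(m[4]))
  }
  rows <- lapply(seq_along(pairs), function(i) {
    a <- parse(pairs[[i]][1]); b <- parse(pairs[[i]][2])
    data.frame(id = sprintf("e%d", i),
               chromA = a$chrom, startA = a$start, endA = a$end,
               chromB = b$chrom, startB = b$start, endB = b$end,
               pet = pet, stringsAsFactors = FALSE)
  })
  loops <- do.call(rbind, rows)
  if (is.null(classes)) classes <- rep("promoter", 2 * nrow(loops))
  loops$classA <- classes[seq_len(nrow(loops))]
  loops$classB <- classes[nrow(loops) + seq_len(nrow(loops))]
  loops
}

test_that("graph construction merges anchors and parallel edges", {
  loops <- mk_loops(list(c("chr1:0-100", "chr1:500-600"),
                         c("chr1:500-600", "chr1:900-1000")))
  g <- build_graph(loops)
  expect_equal(igraph::vcount(g), 3L)
  expect_equal(igraph::ecount(g), 2L)
  expect_equal(igraph::components(g)$no, 1L)

  dup <- mk_loops(list(c("chr1:0-100", "chr1:500-600"),
                       c("chr1:0-100", "chr1:500-600")), pet = 3L)
  g2 <- suppressMessages(build_graph(dup))
  expect_equal(igraph::ecount(g2), 1L)
  expect_equal(igraph::E(g2)$weight, 6)          # summed PETs

  set.seed(99)
  g0 <- build_graph(random_loops(0))
  expect_equal(igraph::vcount(g0), 0L)
  expect_equal(nrow(clusters(g0)), 0L)
})

test_that("cluster statistics match a union-find oracle on random graphs", {
  set.seed(51)
  for (rep in 1:10) {
    n_nodes <- sample(10:40, 1)
    keys <- sprintf("chr1:%d-%d", (1:n_nodes) * 1000L, (1:n_nodes) * 1000L + 100L)
    n_edges <- sample(5:50, 1)
    ai <- sample(n_nodes, n_edges, replace = TRUE)
    bi <- sample(n_nodes, n_edges, replace = TRUE)
    keep <- ai != bi
    ai <- ai[keep]; bi <- bi[keep]
    if (!length(ai)) next
    loops <- mk_loops(Map(function(x, y) c(keys[x], keys[y]), ai, bi))
    g <- suppressMessages(build_graph(loops))
    st <- clusters(g)
    oracle <- uf_components(unique(c(keys[ai], keys[bi])), keys[ai], keys[bi])
    expect_equal(sum(st$n_nodes > 0), nrow(st))
    expect_equal(nrow(st), oracle$n)
    # membership partitions agree (same node sets per component)
    memb <- attr(st, "membership")
    split_got <- lapply(split(names(memb), memb), sort)
    split_want <- lapply(split(names(oracle$membership), oracle$membership), sort)
    expect_setequal(unname(lapply(split_got, paste, collapse = ",")),
                    unname(lapply(split_want, paste, collapse = ",")))
  }
})

test_that("planted disjoint hubs come back with their planted sizes", {
  spec <- tiny_spec(seed = 13L,
                    hubs = list(list(n_promoters = 8L, n_enhancers = 3L,
                                     topology = "path"),
                                list(n_promoters = 5L, n_enhancers = 2L)))
  ann <- generate_annotations(spec)
  gl <- generate_loops(spec, ann)
  catalog <- derive_catalog(ann$genes, ann$repeats, ann$histone)
  loops <- annotate_loops(suppressMessages(filter_loops(gl$loops, 0.01)), catalog)
  st <- clusters(suppressMessages(build_graph(loops)))
  top2 <- st[1:2, ]
  expect_setequal(top2$n_nodes, c(11L, 7L))
  expect_setequal(top2$n_promoters, c(8L, 5L))
  expect_setequal(top2$n_enhancers, c(3L, 2L))
  # a planted path of k anchors is one cluster of k nodes
  hub1_ids <- gl$truth$id[!is.na(gl$truth$hub_id) & gl$truth$hub_id == 1]
  sub <- loops[loops$id %in% hub1_ids, ]
  expect_equal(clusters(build_graph(sub))$n_nodes, 11L)
})

test_that("cluster-size comparison uses an exact two-sided rank-sum when possible", {
  expect_equal(compare_cluster_sizes(c(1, 2, 3), c(10, 11, 12))$p_value, 0.1)
  expect_equal(compare_cluster_sizes(c(5, 5, 5), c(5, 5, 5))$p_value, 1)
  # invariance under a monotone transform
  a <- c(2, 9, 4, 17); b <- c(30, 41, 58)
  expect_equal(compare_cluster_sizes(a, b)$p_value,
               compare_cluster_sizes(exp(a / 10), exp(b / 10))$p_value)
  expect_error(compare_cluster_sizes(c(1, 2), c(3, 4, 5)), "descriptive")
})

test_that("hypergeometric enrichment matches closed-form combinatorics", {
  universe <- sprintf("g%02d", 1:40)
  sets <- list(S1 = universe[1:10], S2 = universe[11:40])
  hub <- universe[1:10]                    # hub genes = entire set S1
  out <- suppressMessages(hub_gene_enrichment(hub, sets, universe))
  N <- 40; K <- 10; n <- 10; k <- 10
  p_closed <- choose(K, k) * choose(N - K, n - k) / choose(N, n)
  expect_equal(out$p_value[out$set == "S1"], p_closed, tolerance = 1e-12)
  # dhyper enumeration oracle
  p_enum <- sum(dhyper(k:min(K, n), K, N - K, n))
  expect_equal(out$p_value[out$set == "S1"], p_enum, tolerance = 1e-12)
  # zero overlap with the complement set covering the rest: p = 1
  expect_equal(out$p_value[out$set == "S2"], 1, tolerance = 1e-12)
  expect_equal(out$q_value, p.adjust(out$p_value[order(out$p_value)], "BH"))

  # genes absent from the universe are dropped, not counted
  out2 <- suppressMessages(hub_gene_enrichment(c(hub, "not_a_gene"), sets, universe))
  expect_equal(out2$overlap[out2$set == "S1"], 10L)
  expect_equal(out2$n_hub[1], 10L)
})

test_that("duplicate genes merge by the median of their PET counts", {
  m <- merge_duplicate_genes(c("A", "A", "B"), c(2, 6, 5))
  expect_equal(m$pets[m$gene_id == "A"], 4)
  expect_equal(m$pets[m$gene_id == "B"], 5)
})

test_that("promoter nodes map to the gene with the nearest TSS", {
  genes <- data.frame(chrom = "chr1", start = c(1000L, 2000L), end = c(1500L, 2600L),
                      strand = c("+", "+"), gene_id = c("gA", "gB"))
  loops <- mk_loops(list(c("chr1:900-1100", "chr1:1900-2100")),
                    classes = c("promoter", "promoter"))
  g <- build_graph(loops)
  hg <- hub_genes(g, genes)
  expect_equal(sort(hg$gene_id), c("gA", "gB"))
  expect_equal(unique(hg$cluster_id), 1L)
})
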