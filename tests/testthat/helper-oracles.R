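# Independent brute-force oracles kept deliberately naive.

# union-find over node keys; returns number of components and membership
uf_components <- function(nodes, edges_a, edges_b) {
  parent <- stats::setNames(nodes, nodes)
  find <- function(x) {
    while (parent[[x]] != x) x <- parent[[x]]
    x
  }
  for (k in seq_along(edges_a)) {
    ra <- find(edges_a[k]); rb <- find(edges_b[k])
    if (ra != rb) parent[[ra]] <- rb
  }
  roots <- vapply(nodes, find, "")
  list(n = length(unique(roots)), membership = roots)
}

# quadratic pairtopair over all loop pairs and all 2x2 anchor pairings
brute_pairtopair <- function(setA, setB, type) {
  ovl <- function(c1, s1, e1, c2, s2, e2) c1 == c2 && s1 < e2 && s2 < e1
  out <- list()
  for (i in seq_len(nrow(setA))) for (j in seq_len(nrow(setB))) {
    if (setA$id[i] == setB$id[j]) next
    m11 <- ovl(setA$chromA[i], setA$startA[i], setA$endA[i],
               setB$chromA[j], setB$startA[j], setB$endA[j])
    m12 <- ovl(setA$chromA[i], setA$startA[i], setA$endA[i],
               setB$chromB[j], setB$startB[j], setB$endB[j])
    m21 <- ovl(setA$chromB[i], setA$startB[i], setA$endB[i],
               setB$chromA[j], setB$startA[j], setB$endA[j])
    m22 <- ovl(setA$chromB[i], setA$startB[i], setA$endB[i],
               setB$chromB[j], setB$startB[j], setB$endB[j])
    hit <- if (type == "both") (m11 && m22) || (m12 && m21)
           else m11 || m12 || m21 || m22
    if (hit) out[[length(out) + 1L]] <- c(setA$id[i], setB$id[j])
  }
  if (!length(out)) return(data.frame(idA = character(0), idB = character(0)))
  m <- do.call(rbind, out)
  data.frame(idA = m[, 1], idB = m[, 2], stringsAsFactors = FALSE)
}

sort_pairs <- function(df) {
  df[order(df$idA, df$idB), , drop = FALSE]
}

# enumerate all 4^w words: float scores and exact tail probabilities
# (p_at(s, slack) = P(word score >= s - slack), slack may be negative)
brute_motif_p <- function(logodds, background) {
  w <- ncol(logodds)
  words <- as.matrix(expand.grid(rep(list(1:4), w)))
  n <- nrow(words)
  score <- numeric(n); prob <- rep(1, n)
  for (j in seq_len(w)) {
    score <- score + logodds[cbind(words[, j], j)]
    prob <- prob * background[words[, j]]
  }
  ord <- order(score)
  ss <- score[ord]; csa <- cumsum(prob[ord]); total <- sum(prob)
  p_at <- function(s, slack = 0) {
    k <- findInterval(s - slack - 1e-9, ss)
    total - ifelse(k == 0L, 0, csa[pmax(k, 1L)])
  }
  list(words = words, score = score, prob = prob, p_at = p_at)
}

random_pwm <- function(w, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(stats::rgamma(4 * w, 1), 4, w)
  m <- sweep(m, 2, colSums(m), "/")
  rownames(m) <- c("A", "C", "G", "T")
  list(name = sprintf("rand_w%d", w), mat = m)
}
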