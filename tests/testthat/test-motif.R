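test_that("the shipped MEME fixture parses into proper PWMs", {
  pwms <- default_pwms()
  expect_setequal(names(pwms), c("E-box", "B-box", "A-box"))
  expect_equal(ncol(pwms[["E-box"]]$mat), 10L)
  expect_equal(ncol(pwms[["A-box"]]$mat), 12L)
  for (pw in pwms)
    expect_equal(colSums(pw$mat), rep(1, ncol(pw$mat)), tolerance = 1e-6)
})

test_that("background fitting: degenerate, symmetric and random inputs", {
  # all-A input without symmetrization: A frequency near 1
  bg_a <- fit_background(strrep("A", 1000), symmetrize = FALSE)
  expect_equal(unname(bg_a["A"]), 1001 / 1004, tolerance = 1e-12)

  # symmetrization enforces A=T, C=G
  set.seed(41)
  s <- paste(sample(c("A", "C", "G", "T"), 5000, TRUE, prob = c(.4, .1, .2, .3)),
             collapse = "")
  bg <- fit_background(s)
  expect_equal(unname(bg["A"]), unname(bg["T"]))
  expect_equal(unname(bg["C"]), unname(bg["G"]))

  # uniform random sequence: each frequency within binomial 3 sigma of 0.25
  u <- paste(sample(c("A", "C", "G", "T"), 10000, TRUE), collapse = "")
  bgu <- fit_background(u)
  sigma <- sqrt(0.25 * 0.75 / 10000)
  expect_true(all(abs(bgu - 0.25) < 3 * sigma + 1e-3))

  expect_error(fit_background(character(0)), "empty")
})

test_that("consensus attains the maximal score and its exact p-value", {
  bg <- c(A = 0.3, C = 0.2, G = 0.2, T = 0.3)
  pw <- random_pwm(5, seed = 42)
  lo <- hichipr:::pwm_logodds(pw, bg)
  bf <- brute_motif_p(lo, bg)
  cons_codes <- apply(lo, 2, which.max)
  cons_score <- sum(lo[cbind(cons_codes, 1:5)])
  expect_equal(max(bf$score), cons_score, tolerance = 1e-12)
  # p-value of the max score = total background mass of maximum-scoring words
  expect_equal(bf$p_at(cons_score), prod(bg[cons_codes]), tolerance = 1e-12)
})

test_that("DP p-values agree with 4^w enumeration within the discretization bound", {
  bg <- c(A = 0.28, C = 0.22, G = 0.22, T = 0.28)
  bin <- 0.001
  for (w in c(4L, 6L, 8L)) {
    pw <- random_pwm(w, seed = 100 + w)
    lo <- hichipr:::pwm_logodds(pw, bg)
    dist <- motif_score_distribution(lo, bg, bin = bin)
    bf <- brute_motif_p(lo, bg)
    # evaluate at every achievable word score
    s_int <- numeric(nrow(bf$words))
    for (j in seq_len(w)) s_int <- s_int + dist$int_mat[cbind(bf$words[, j], j)]
    p_dp <- hichipr:::.tail_p(dist, s_int)
    p_bf <- bf$p_at(bf$score)
    # bracket: the DP answer lies between the brute-force tails at +/- w*bin
    p_loose <- bf$p_at(bf$score, slack = w * bin)
    p_strict <- bf$p_at(bf$score, slack = -w * bin)
    expect_true(all(p_dp <= p_loose + 1e-12), info = paste("w =", w))
    expect_true(all(p_dp >= p_strict - 1e-12), info = paste("w =", w))
    # deviation never exceeds the discretization bound
    expect_true(all(abs(p_dp - p_bf) <= (p_loose - p_strict) + 1e-12),
                info = paste("w =", w))
    # p-value is monotone non-increasing in score
    ord <- order(s_int)
    expect_true(all(diff(p_dp[ord]) <= 1e-15))
  }
})

test_that("scanning finds a planted consensus on both strands at p <= 1e-4", {
  pwms <- default_pwms()
  ebox <- pwms[["E-box"]]
  bg <- c(A = 0.3, C = 0.2, G = 0.2, T = 0.3)
  cons <- paste(rownames(ebox$mat)[apply(ebox$mat, 2, which.max)], collapse = "")
  set.seed(43)
  flank <- function(n) paste(sample(c("A", "T"), n, TRUE), collapse = "")
  seqp <- paste0(flank(60), cons, flank(60))
  hits <- scan_pwm(seqp, ebox, bg)
  expect_true(any(hits$offset == 60 & hits$strand == "+"))
  expect_true(all(hits$pvalue <= 1e-4))

  # a hit's reverse complement scores the same on the minus strand
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seqp)))
  hits_rc <- scan_pwm(rc, ebox, bg)
  plus <- hits[hits$strand == "+", ]
  minus <- hits_rc[hits_rc$strand == "-", ]
  expect_equal(sort(plus$score), sort(minus$score), tolerance = 1e-9)

  # sequence shorter than the motif: empty result, no error
  expect_equal(nrow(scan_pwm("ACGT", ebox, bg)), 0L)
})

test_that("per-anchor dedup keeps the lowest p-value and priority beats p", {
  hits <- data.frame(
    anchor = c("a1", "a1", "a1", "a2"),
    motif = c("E-box", "E-box", "A-box", "B-box"),
    offset = c(5L, 9L, 2L, 0L), strand = "+",
    score = c(8, 9, 12, 7),
    pvalue = c(1e-5, 1e-6, 1e-9, 1e-5),
    stringsAsFactors = FALSE)
  out <- dedup_and_prioritize(hits, anchors = c("a1", "a2", "a3"))
  e1 <- out$hits[out$hits$anchor == "a1" & out$hits$motif == "E-box", ]
  expect_equal(e1$pvalue, 1e-6)                 # duplicate E-box: keep min p
  labs <- stats::setNames(out$labels$label, out$labels$anchor)
  expect_equal(unname(labs["a1"]), "E-box")     # priority beats smaller A-box p
  expect_equal(unname(labs["a2"]), "B-box")
  expect_equal(unname(labs["a3"]), "no_motif")
})

test_that("pair motif table partitions loops and is anchor-order invariant", {
  loops <- data.frame(
    id = c("l1", "l2", "l3"),
    chromA = "chr1", startA = c(0L, 100L, 200L), endA = c(50L, 150L, 250L),
    chromB = "chr1", startB = c(1000L, 1100L, 1200L), endB = c(1050L, 1150L, 1250L),
    pet = 1L, stringsAsFactors = FALSE)
  labels <- data.frame(
    anchor = c("chr1:0-50", "chr1:100-150", "chr1:200-250",
               "chr1:1000-1050", "chr1:1100-1150", "chr1:1200-1250"),
    label = c("E-box", "E-box", "no_motif", "B-box", "B-box", "A-box"),
    stringsAsFactors = FALSE)
  m <- pair_motif_table(loops, labels)
  expect_equal(sum(m), nrow(loops))
  expect_equal(m["E-box", "B-box"], 2L)
  expect_equal(m["A-box", "no_motif"], 1L)
  # swapping anchors leaves the table unchanged
  sw <- loops
  sw[, c("chromA", "startA", "endA")] <- loops[, c("chromB", "startB", "endB")]
  sw[, c("chromB", "startB", "endB")] <- loops[, c("chromA", "startA", "endA")]
  expect_equal(pair_motif_table(sw, labels), m)
})
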