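# Signal-integration statistics: windowed read counting around gene
# landmarks, metagene density profiles (mean +/- SEM), equal-size binning of
# gene-level values, reference-median normalization, binding-per-interaction
# ratios, and two-group comparisons.

#' Strand-aware gene windows
#'
#' Window specs: `"tss_pm"` = TSS +/- w; `"tes_pm"` = TES +/- w;
#' `"tss_down"` = from the TSS w bp into the gene (downstream; extends
#' leftward for minus-strand genes). Windows are clipped at position 0 and,
#' when `chrom_sizes` is given, at the chromosome end (clipping is logged).
#'
#' @param genes gene data.frame (`chrom, start, end, strand, gene_id`).
#' @param spec one of `"tss_pm"`, `"tes_pm"`, `"tss_down"`.
#' @param w window parameter in bp (half-width for `*_pm`, width for
#'   `tss_down`).
#' @param chrom_sizes optional named vector of chromosome lengths.
#' @return interval data.frame with `gene_id` and `strand`.
#' @export
gene_windows <- function(genes, spec = c("tss_pm", "tes_pm", "tss_down"),
                         w = 2000L, chrom_sizes = NULL) {
  spec <- match.arg(spec)
  tss <- ifelse(genes$strand == "-", genes$end - 1L, genes$start)
  tes <- ifelse(genes$strand == "-", genes$start, genes$end - 1L)
  if (spec == "tss_pm") { s <- tss - w; e <- tss + w }
  else if (spec == "tes_pm") { s <- tes - w; e <- tes + w }
  else {
    s <- ifelse(genes$strand == "-", tss - w + 1L, tss)
    e <- ifelse(genes$strand == "-", tss + 1L, tss + w)
  }
  s2 <- pmax(0L, as.integer(s)); e2 <- as.integer(e)
  if (!is.null(chrom_sizes)) e2 <- pmin(e2, as.integer(chrom_sizes[genes$chrom]))
  if (any(s2 != s | e2 != e))
    .log_stage("windows", "%d window(s) clipped at chromosome bounds",
               sum(s2 != s | e2 != e))
  data.frame(chrom = genes$chrom, start = s2, end = e2,
             gene_id = genes$gene_id, strand = genes$strand,
             stringsAsFactors = FALSE)
}

#' Count reads overlapping gene windows
#'
#' Each read (interval) overlapping a window by >= 1 bp is counted once for
#' that window.
#'
#' @param reads interval data.frame of reads (`chrom, start, end`).
#' @param windows window data.frame from [gene_windows].
#' @return integer vector of counts, one per window row.
#' @export
count_in_window <- function(reads, windows) {
  counts <- integer(nrow(windows))
  op <- overlap_pairs(windows[, c("chrom", "start", "end")],
                      reads[, c("chrom", "start", "end")])
  if (nrow(op)) {
    tab <- table(op$query)
    counts[as.integer(names(tab))] <- as.integer(tab)
  }
  counts
}

# mean coverage value of a step-function track over [s, e)
.track_bin_means <- function(track_ch, bounds) {
  # bounds: vector of bin boundaries (0-based); returns mean value per bin,
  # missing track regions counting as 0.
  nb <- length(bounds) - 1L
  vals <- numeric(nb)
  if (nrow(track_ch) == 0L) return(vals)
  for (k in seq_len(nb)) {
    s <- bounds[k]; e <- bounds[k + 1L]
    ov <- track_ch[track_ch$start < e & track_ch$end > s, , drop = FALSE]
    if (nrow(ov) == 0L) next
    cov <- pmin(ov$end, e) - pmax(ov$start, s)
    vals[k] <- sum(cov * ov$value) / (e - s)
  }
  vals
}

#' Metagene density profile (mean and SEM per bin)
#'
#' Averages a (spike-scaled) coverage track over a gene set on a grid centred
#' at the TSS or TES. Minus-strand genes are flipped before averaging so the
#' profile reads 5' to 3'. Tracks are consumed as-is: scale them with
#' [normalize_track] beforehand; no further per-sample normalization happens
#' here.
#'
#' @param track bedGraph-style data.frame `chrom, start, end, value`.
#' @param genes gene data.frame; must have >= 2 rows.
#' @param centre `"tss"` or `"tes"`.
#' @param half_width half-width of the profile in bp (default 2000).
#' @param bin_width bin width in bp (must divide `2 * half_width`).
#' @return data.frame `position` (bin centre relative to the landmark),
#'   `mean`, `sem`, `n_genes`.
#' @export
metagene_density <- function(track, genes, centre = c("tss", "tes"),
                             half_width = 2000L, bin_width = 100L) {
  centre <- match.arg(centre)
  if (nrow(genes) < 2L) stop("need >= 2 genes for a density profile", call. = FALSE)
  if ((2L * half_width) %% bin_width != 0L)
    stop("bin_width must divide the profile width", call. = FALSE)
  nb <- as.integer(2L * half_width / bin_width)
  anchor <- if (centre == "tss") {
    ifelse(genes$strand == "-", genes$end - 1L, genes$start)
  } else {
    ifelse(genes$strand == "-", genes$start, genes$end - 1L)
  }
  by_chrom <- split(track, track$chrom)
  prof <- matrix(NA_real_, nrow(genes), nb)
  for (i in seq_len(nrow(genes))) {
    bounds <- anchor[i] - half_width + bin_width * (0:nb)
    tch <- by_chrom[[genes$chrom[i]]]
    if (is.null(tch)) tch <- track[0, , drop = FALSE]
    v <- .track_bin_means(tch, bounds)
    if (genes$strand[i] == "-") v <- rev(v)
    prof[i, ] <- v
  }
  mu <- colMeans(prof)
  sem <- apply(prof, 2, stats::sd) / sqrt(nrow(genes))
  data.frame(position = -half_width + bin_width * (seq_len(nb) - 0.5),
             mean = mu, sem = sem, n_genes = nrow(genes))
}

#' Equal-size binning of sorted gene-level values
#'
#' Sorts records by `x` and groups them into consecutive bins of
#' `genes_per_bin` records (the final bin holds the remainder: 14,085 genes
#' at 150 per bin give 94 bins, the last with 135). Alternatively `n_bins`
#' fixes the bin count and the bin size is `floor(n / n_bins)` with the
#' remainder again in the last bin.
#'
#' @param x,y numeric vectors (e.g. expression fold change and signal).
#' @param genes_per_bin records per bin.
#' @param n_bins alternative to `genes_per_bin`.
#' @return data.frame `bin, n, mean_x, mean_y`.
#' @export
bin_average <- function(x, y, genes_per_bin = NULL, n_bins = NULL) {
  n <- length(x)
  stopifnot(length(y) == n)
  if (is.null(genes_per_bin) == is.null(n_bins))
    stop("give exactly one of genes_per_bin or n_bins", call. = FALSE)
  k <- if (!is.null(genes_per_bin)) as.integer(genes_per_bin)
       else as.integer(floor(n / n_bins))
  if (k > n || k < 1L) stop("bin size exceeds the number of records", call. = FALSE)
  ord <- order(x)
  grp <- ceiling(seq_len(n) / k)
  if (!is.null(n_bins)) grp <- pmin(grp, as.integer(n_bins))
  xs <- x[ord]; ys <- y[ord]
  data.frame(
    bin = sort(unique(grp)),
    n = as.integer(table(grp)),
    mean_x = as.numeric(tapply(xs, grp, mean)),
    mean_y = as.numeric(tapply(ys, grp, mean))
  )
}

#' Normalize values to the median of a reference group
#'
#' @param values numeric vector to scale.
#' @param reference numeric vector whose median becomes 1 after scaling.
#' @return `values / median(reference)`.
#' @export
normalize_to_reference <- function(values, reference) {
  m <- stats::median(reference)
  if (!is.finite(m) || m <= 0)
    stop("reference median must be positive", call. = FALSE)
  values / m
}

#' Binding-per-interaction ratio
#'
#' Ratio of (spike-normalized) reads to interaction counts over a shared
#' window set, either as a global sum ratio (default) or per window.
#'
#' @param chip_counts numeric vector: reads per window.
#' @param loop_counts numeric vector: interactions per window.
#' @param per_window return per-window ratios instead of the global ratio.
#' @return a single ratio, or a vector when `per_window = TRUE`.
#' @export
binding_per_interaction <- function(chip_counts, loop_counts, per_window = FALSE) {
  stopifnot(length(chip_counts) == length(loop_counts))
  if (per_window) {
    if (any(loop_counts <= 0))
      stop("zero interactions in some window; cannot form per-window ratios",
           call. = FALSE)
    return(chip_counts / loop_counts)
  }
  tot <- sum(loop_counts)
  if (tot <= 0) stop("zero interactions overall; use per_window output", call. = FALSE)
  sum(chip_counts) / tot
}

#' Two-group comparison (Welch t or rank-sum)
#'
#' Two-sided tests: `"t_unpaired_unequal_var"` is Welch's t-test;
#' `"ranksum"` is the unpaired Wilcoxon rank-sum (exact when tie-free and
#' small). A degenerate-variance t-test falls back to the exact rank test
#' (logged).
#'
#' @param a,b numeric vectors (>= 3 values each).
#' @param test `"ranksum"` or `"t_unpaired_unequal_var"`.
#' @return list with `p_value` and the `htest` object.
#' @export
group_compare <- function(a, b, test = c("ranksum", "t_unpaired_unequal_var")) {
  test <- match.arg(test)
  if (length(a) < 3L || length(b) < 3L) stop("need >= 3 values per group", call. = FALSE)
  if (test == "t_unpaired_unequal_var") {
    if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      .log_stage("stats", "degenerate variance; falling back to exact rank-sum")
      test <- "ranksum"
    } else {
      ht <- stats::t.test(a, b, var.equal = FALSE)
      return(list(p_value = ht$p.value, test = ht))
    }
  }
  exact <- (length(a) + length(b)) <= 50L && !any(duplicated(c(a, b)))
  # correct = FALSE: symmetric data give p = 1 in the approximate branch
  ht <- suppressWarnings(stats::wilcox.test(a, b, alternative = "two.sided",
                                            exact = exact, correct = FALSE))
  p <- ht$p.value
  if (is.nan(p)) p <- 1   # complete ties
  list(p_value = p, test = ht)
}
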