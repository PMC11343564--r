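#' Pipeline configuration
#'
#' Collects the tunable constants of the pipeline. Defaults are the values
#' used throughout the analyses: promoters are TSS +/- 500 bp, transcription
#' end sites TES +/- 300 bp, loops are kept at q <= 0.01, motif hits at
#' p <= 1e-4, and loops may span at most 5 Mb.
#'
#' @param priority character vector: annotation classes in decreasing
#'   priority. The first class overlapping an anchor wins.
#' @param promoter_window half-width (bp) of the promoter window around TSS.
#' @param tes_window half-width (bp) of the TES window.
#' @param tss_count_window width (bp) of TSS windows used for read counting.
#' @param q_max loop q-value threshold (inclusive), in (0, 1].
#' @param motif_p_max motif p-value threshold, in (0, 1].
#' @param max_loop_dist maximum anchor separation (bp) for a called loop.
#' @param seed integer seed for stochastic stages.
#' @param spike_label chromosome-name prefix identifying the spike genome.
#' @return a named list of class `pipeline_config`.
#' @export
pipeline_config <- function(priority = c("enhancer", "promoter", "TES", "gene_body",
                                         "tRNA", "rRNA", "miRNA", "snRNA", "snoRNA",
                                         "SINE", "LINE", "LTR", "satellite"),
                            promoter_window = 500L,
                            tes_window = 300L,
                            tss_count_window = 2000L,
                            q_max = 0.01,
                            motif_p_max = 1e-4,
                            max_loop_dist = 5e6,
                            seed = 1L,
                            spike_label = "spike") {
  cfg <- list(priority = priority, promoter_window = as.integer(promoter_window),
              tes_window = as.integer(tes_window),
              tss_count_window = as.integer(tss_count_window),
              q_max = q_max, motif_p_max = motif_p_max,
              max_loop_dist = max_loop_dist, seed = as.integer(seed),
              spike_label = spike_label)
  if (anyDuplicated(cfg$priority)) stop("priority list has duplicate entries", call. = FALSE)
  for (th in c("q_max", "motif_p_max"))
    if (cfg[[th]] <= 0 || cfg[[th]] > 1) stop(th, " must be in (0, 1]", call. = FALSE)
  for (w in c("promoter_window", "tes_window", "tss_count_window", "max_loop_dist"))
    if (cfg[[w]] <= 0) stop(w, " must be positive", call. = FALSE)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a configuration file (YAML or flat `key: value`) over the defaults
#' @param path YAML file; keys override [pipeline_config] defaults.
#' @return a `pipeline_config`.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  base <- pipeline_config()
  known <- names(unclass(base))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) stop("unknown config keys: ", paste(unknown, collapse = ", "),
                            call. = FALSE)
  do.call(pipeline_config, utils::modifyList(as.list(unclass(base)), vals)[known])
}
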