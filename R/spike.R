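# Spike-in (reference-exogenous) normalization. Each sample's primary-genome
# signal is scaled by min(spike counts over the batch) / own spike count, so
# the sample with the smallest spike library keeps its raw counts and every
# other sample is scaled down onto the same exogenous yardstick.

#' ChIP-Rx spike-in scale factors
#'
#' For a batch of samples with counts of reads mapping exclusively to the
#' primary genome and exclusively to the spike genome, computes
#' `factor_i = min_j(spike_j) / spike_i` and
#' `normalized_i = primary_i * factor_i`. The sample attaining the minimum
#' spike count keeps its raw primary count.
#'
#' @param counts data.frame with columns `sample_id, primary, spike`
#'   (reads, or valid PETs for HiChIP use).
#' @return the input with `factor` and `normalized` columns added.
#' @export
chiprx_factors <- function(counts) {
  stopifnot(all(c("sample_id", "primary", "spike") %in% names(counts)))
  if (nrow(counts) < 1L) stop("need at least one sample", call. = FALSE)
  zero <- counts$spike <= 0
  if (any(zero))
    stop("spike count must be positive; offending sample(s): ",
         paste(counts$sample_id[zero], collapse = ", "), call. = FALSE)
  min_spike <- min(counts$spike)
  counts$factor <- min_spike / counts$spike
  counts$normalized <- counts$primary * counts$factor
  .log_stage("spike", "batch of %d sample(s), min spike = %g", nrow(counts), min_spike)
  counts
}

#' Spike-in factors for HiChIP PET counts
#'
#' Applies the same formula as [chiprx_factors] to valid-PET counts. Spike
#' PETs are removed from the primary PET set before counting when a
#' classified PET table is supplied; alternatively a pre-tabulated count
#' table can be passed straight through.
#'
#' @param x either a list of classified PET tables (one per sample, each with
#'   `classification` and `is_spike` columns) or a `sample_id/primary/spike`
#'   count data.frame.
#' @return count data.frame with `factor` and `normalized` columns.
#' @export
splhichip_factors <- function(x) {
  if (is.data.frame(x)) return(chiprx_factors(x))
  counts <- do.call(rbind, lapply(names(x), function(s) {
    pets <- x[[s]]
    valid <- pets[pets$classification == "valid", , drop = FALSE]
    data.frame(sample_id = s,
               primary = sum(!valid$is_spike),
               spike = sum(valid$is_spike),
               stringsAsFactors = FALSE)
  }))
  chiprx_factors(counts)
}

#' Rescale loop PET counts by a sample's spike factor
#' @param loops loop data.frame.
#' @param factor spike scale factor (> 0).
#' @return loops with a `pet_normalized` column.
#' @export
rescale_loop_pets <- function(loops, factor) {
  if (factor <= 0) stop("scale factor must be positive", call. = FALSE)
  loops$pet_normalized <- loops$pet * factor
  loops
}

#' Fold change of total interactions between two samples
#'
#' `(n_treated * f_treated) / (n_control * f_control)` where `n` are loop
#' counts (or total PETs) and `f` the spike factors.
#'
#' @param n_treated,n_control interaction counts.
#' @param f_treated,f_control spike factors.
#' @return the normalized fold change.
#' @export
interaction_fold_change <- function(n_treated, f_treated, n_control, f_control) {
  if (f_treated <= 0 || f_control <= 0) stop("factors must be positive", call. = FALSE)
  (n_treated * f_treated) / (n_control * f_control)
}

#' Scale a coverage track by a spike factor
#'
#' Multiplies every interval value by the factor; downstream density plots
#' consume the scaled values with no further per-sample normalization.
#'
#' @param track data.frame `chrom, start, end, value`.
#' @param factor positive scale factor.
#' @return the scaled track.
#' @export
normalize_track <- function(track, factor) {
  if (factor <= 0) stop("scale factor must be positive", call. = FALSE)
  track$value <- track$value * factor
  track
}
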