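#' Run the full offset-detection pipeline on paired reads
#'
#' Convenience wrapper chaining the stages of the screen analysis:
#' merge/filter reads, quantify per-adenosine editing, compute delta
#' editing versus the perfect-duplex reference, pool by signed distance to
#' each construct's disruption, LOESS-smooth and call the induction peak
#' and suppression trough.
#'
#' @param library List of barcoded `adar_construct` including the
#'   reference.
#' @param r1,r2 FASTQ paths (or read vectors).
#' @param arm Sequenced arm.
#' @param reference_id Id of the perfect-duplex construct.
#' @param span LOESS span.
#' @param peak_window,trough_window Extremum search windows.
#' @param min_reference_percent Reference-editing inclusion threshold.
#' @return List: `profiles`, `deltas`, `aggregate` (smoothed), `call`
#'   (an `offset_call`), `filter_report`.
#' @export
run_offset_pipeline <- function(library, r1, r2, arm = c("upper", "lower"),
                                reference_id = "perfect", span = 0.05,
                                peak_window = c(-45, -15),
                                trough_window = c(-5, 5),
                                min_reference_percent = 1.0) {
  arm <- match.arg(arm)
  merged <- merge_and_filter_reads(r1, r2, library, arm = arm)
  profiles <- quantify_editing(merged, library)
  if (!reference_id %in% names(profiles)) {
    stop("no reads recovered for the reference construct '", reference_id, "'")
  }
  ref <- profiles[[reference_id]]
  variant_ids <- setdiff(names(profiles), reference_id)
  deltas <- lapply(profiles[variant_ids], delta_profile,
    reference = ref, min_reference_percent = min_reference_percent
  )
  agg <- aggregate_by_distance(deltas, library, arm = arm)
  agg <- smooth_aggregate(agg, span = span)
  call <- detect_offset_extrema(agg,
    peak_window = peak_window,
    trough_window = trough_window
  )
  list(
    profiles = profiles, deltas = deltas, aggregate = agg,
    call = call, filter_report = merged$report
  )
}
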