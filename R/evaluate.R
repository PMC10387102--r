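# Ground-truth benchmarking of detection output against the simulator.

#' Greedy matching of detected to true event times
#'
#' One-to-one nearest-neighbour assignment: true events and detections are
#' scanned in time order and each true event consumes the nearest unused
#' detection within the tolerance.
#'
#' @param true_times,detected_times Sorted numeric vectors (s).
#' @param tol_s Matching tolerance (s).
#' @return Integer number of matched true events.
#' @export
match_events <- function(true_times, detected_times, tol_s = 1e-3) {
  if (!length(true_times) || !length(detected_times)) return(0L)
  used <- logical(length(detected_times))
  matched <- 0L
  for (t in true_times) {
    d <- abs(detected_times - t)
    d[used] <- Inf
    j <- which.min(d)
    if (d[j] <= tol_s) {
      used[j] <- TRUE
      matched <- matched + 1L
    }
  }
  matched
}

#' Detection recall and precision against simulator ground truth
#'
#' Recall is computed over ground-truth events whose programmed amplitude
#' is at least `min_amplitude_uV` and which fall after `settle_s` (the
#' filter settling window excluded from detection); precision over all
#' detections on electrodes carrying at least one true event, matched to
#' any true event of that electrode.
#'
#' @param truth An `mea_ground_truth`.
#' @param trains A `spike_trains` object detected from the matching
#'   recording.
#' @param tol_ms Matching tolerance, ms.
#' @param min_amplitude_uV Amplitude floor (absolute, microvolts) for the
#'   recall denominator.
#' @param settle_s Initial window excluded from scoring (s).
#' @return List with `recall`, `precision`, `n_true` (recall denominator),
#'   `n_detected` (precision denominator).
#' @export
detection_scores <- function(truth, trains, tol_ms = 1, min_amplitude_uV = 0,
                             settle_s = 0.1) {
  tol_s <- tol_ms * 1e-3
  ev <- truth$events
  n_true <- 0L; n_hit <- 0L; n_det <- 0L; n_det_hit <- 0L
  for (el in unique(ev$electrode)) {
    all_true <- ev$time_s[ev$electrode == el]
    sel_true <- ev$time_s[ev$electrode == el & ev$time_s > settle_s &
                            abs(ev$amplitude_uV) >= min_amplitude_uV]
    det <- trains$trains[[el]]
    n_true <- n_true + length(sel_true)
    n_hit <- n_hit + match_events(sel_true, det, tol_s)
    n_det <- n_det + length(det)
    n_det_hit <- n_det_hit + match_events(det, all_true, tol_s)
  }
  list(recall = if (n_true) n_hit / n_true else NA_real_,
       precision = if (n_det) n_det_hit / n_det else NA_real_,
       n_true = n_true, n_detected = n_det)
}

#' Effective template attenuation through a preprocessing filter
#'
#' Peak amplitude ratio of the simulator's unit spike template after the
#' given bandpass filter — the factor linking a programmed event amplitude
#' to the peak it reaches in the filtered trace.
#'
#' @param filt A [signal::Arma()] filter.
#' @param width_ms Template width parameter (ms).
#' @param sampling_rate Sampling rate, Hz.
#' @return Attenuation factor in (0, 1].
#' @export
template_attenuation <- function(filt, width_ms = 1, sampling_rate = 10000) {
  tm <- spike_template(-1, width_ms, sampling_rate)
  x <- numeric(length(tm$wave) + 2000L)
  x[1001:(1000 + length(tm$wave))] <- tm$wave
  y <- signal::filter(filt, x)
  max(abs(y))
}
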