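#' Detect spikes by robust amplitude thresholding
#'
#' Per electrode: estimates the noise scale over the whole (post-settle)
#' trace, sets thresholds at `+/- k_mad` times that scale, fixes the
#' polarity as the sign of the first threshold crossing encountered (the
#' first phase of the spike waveform; negative if the trace never crosses),
#' and collects the timestamps of threshold crossings of that polarity,
#' suppressing further crossings for `dead_time_ms` after each accepted
#' event. A crossing is the first sample beyond the threshold after a
#' sample within it.
#'
#' The noise scale (`mad_type`) is, by default, the scaled median absolute
#' deviation (`stats::mad`, consistent with a Gaussian s.d.); `"median"`
#' gives the unscaled median absolute deviation and `"mean"` the mean
#' absolute deviation. All-zero (zero-scale) electrodes are flagged
#' degenerate and emit no spikes.
#'
#' @param rec A filtered `mea_recording`.
#' @param k_mad Threshold multiplier (default 5).
#' @param dead_time_ms Post-spike dead time, ms (default 3).
#' @param mad_type One of `"normalized"`, `"median"`, `"mean"`.
#' @return A `spike_trains` object: `trains` (named list of timestamp
#'   vectors, seconds), `info` (per-electrode data.frame: spike count,
#'   rate, noise scale, threshold, polarity, degenerate flag),
#'   `duration_s`, `params`.
#' @export
detect_spikes <- function(rec, k_mad = 5, dead_time_ms = 3,
                          mad_type = c("normalized", "median", "mean")) {
  stopifnot(k_mad > 0, dead_time_ms > 0, rec$duration_s > 0)
  mad_type <- match.arg(mad_type)
  fs <- rec$sampling_rate
  settle_s <- rec$provenance$settle_s
  if (is.null(settle_s)) settle_s <- 0
  i0 <- as.integer(floor(settle_s * fs)) + 1L
  dead_samples <- dead_time_ms * 1e-3 * fs

  ids <- rec$channel_ids
  trains <- stats::setNames(vector("list", length(ids)), ids)
  info <- data.frame(electrode = ids, n_spikes = 0L, rate_hz = 0,
                     mad = NA_real_, threshold_uV = NA_real_,
                     polarity = NA_integer_, degenerate = FALSE,
                     stringsAsFactors = FALSE)
  for (j in seq_along(ids)) {
    x <- rec$traces[i0:nrow(rec$traces), j]
    m <- switch(mad_type,
                normalized = stats::mad(x),
                median = stats::median(abs(x - stats::median(x))),
                mean = mean(abs(x - mean(x))))
    info$mad[j] <- m
    if (m == 0) {
      info$degenerate[j] <- TRUE
      trains[[j]] <- numeric(0)
      next
    }
    thr <- k_mad * m
    info$threshold_uV[j] <- thr
    beyond <- which(abs(x) > thr)
    pol <- if (length(beyond)) sign(x[beyond[1]]) else -1L
    info$polarity[j] <- as.integer(pol)
    out <- if (pol < 0) x < -thr else x > thr
    crossings <- which(out & !c(FALSE, out[-length(out)]))
    accepted <- integer(0)
    last <- -Inf
    for (i in crossings) {
      if (i - last >= dead_samples - 1e-9) {
        accepted <- c(accepted, i)
        last <- i
      }
    }
    times <- (i0 - 1L + accepted - 1L) / fs
    trains[[j]] <- times
    info$n_spikes[j] <- length(times)
  }
  info$rate_hz <- info$n_spikes / rec$duration_s
  res <- structure(
    list(trains = trains, info = info, duration_s = rec$duration_s,
         params = list(k_mad = k_mad, dead_time_ms = dead_time_ms,
                       mad_type = mad_type, settle_s = settle_s)),
    class = "spike_trains"
  )
  # contract: strictly increasing timestamps, dead time respected, in range
  for (tr in res$trains) {
    if (length(tr) > 1) {
      stopifnot(all(diff(tr) >= dead_time_ms * 1e-3 - 1e-9))
    }
    stopifnot(all(tr >= 0 & tr <= rec$duration_s))
  }
  res
}

#' @export
print.spike_trains <- function(x, ...) {
  cat(sprintf("spike_trains: %d electrodes, %g s, %d spikes total (k_mad=%g, dead=%g ms, mad=%s)\n",
              length(x$trains), x$duration_s, sum(x$info$n_spikes),
              x$params$k_mad, x$params$dead_time_ms, x$params$mad_type))
  invisible(x)
}

#' Active-electrode gate
#'
#' Electrodes whose mean firing rate over the whole recording reaches
#' `min_rate` (inclusive; 5 spikes in 50 s passes the default 0.1 Hz).
#' Degenerate electrodes never qualify.
#'
#' @param trains A `spike_trains` object.
#' @param min_rate Minimum mean firing rate, Hz (default 0.1).
#' @return Character vector of active electrode ids.
#' @export
active_electrodes <- function(trains, min_rate = 0.1) {
  stopifnot(min_rate >= 0)
  info <- trains$info
  info$electrode[info$rate_hz >= min_rate & !info$degenerate]
}

#' Mean firing rate per electrode and over a subset
#'
#' @param trains A `spike_trains` object.
#' @param subset Electrode ids to average over (default: all).
#' @return List with `per_electrode` (data.frame electrode, rate_hz) and
#'   `mean_rate_hz` (arithmetic mean over the subset; `NA` with a warning
#'   if the subset is empty).
#' @export
mean_firing_rate <- function(trains, subset = NULL) {
  info <- trains$info
  if (is.null(subset)) subset <- info$electrode
  unknown <- setdiff(subset, info$electrode)
  if (length(unknown)) stop("unknown electrode id: ", paste(unknown, collapse = ", "))
  per <- info[match(subset, info$electrode), c("electrode", "rate_hz")]
  rownames(per) <- NULL
  if (!length(subset)) {
    warning("empty electrode subset: mean firing rate undefined")
    return(list(per_electrode = per, mean_rate_hz = NA_real_))
  }
  list(per_electrode = per, mean_rate_hz = mean(per$rate_hz))
}

#' Extract spike waveform cutouts and amplitude statistics
#'
#' Cuts a fixed window (`pre_ms` before to `post_ms` after each detection
#' timestamp) from the filtered trace of every electrode. Windows that
#' would extend past the trace boundary are flagged and excluded from the
#' statistics. Per electrode it reports the mean peak amplitude, the
#' amplitude coefficient of variation (CV; low for a single stereotyped
#' axonal waveform, high where several units of different amplitude mix, as
#' near somata), and a shape-dispersion index (RMS residual around the mean
#' waveform relative to the RMS of the mean waveform).
#'
#' @param rec The filtered `mea_recording` the spikes were detected on.
#' @param trains A `spike_trains` object.
#' @param pre_ms,post_ms Window before/after the timestamp, ms.
#' @return A `waveform_cutouts` object: `cutouts` (named list of
#'   spikes x samples matrices), `stats` (per-electrode data.frame:
#'   n, n_clipped, mean_amp_uV, amp_cv, shape_dispersion), window
#'   parameters.
#' @export
extract_cutouts <- function(rec, trains, pre_ms = 1, post_ms = 2) {
  stopifnot(pre_ms > 0, post_ms > 0)
  fs <- rec$sampling_rate
  npre <- as.integer(round(pre_ms * 1e-3 * fs))
  npost <- as.integer(round(post_ms * 1e-3 * fs))
  n <- nrow(rec$traces)
  ids <- names(trains$trains)
  cuts <- stats::setNames(vector("list", length(ids)), ids)
  st <- data.frame(electrode = ids, n = 0L, n_clipped = 0L,
                   mean_amp_uV = NA_real_, amp_cv = NA_real_,
                   shape_dispersion = NA_real_, stringsAsFactors = FALSE)
  for (j in seq_along(ids)) {
    tt <- trains$trains[[j]]
    if (!length(tt)) { cuts[[j]] <- matrix(0, 0, npre + npost + 1L); next }
    centers <- as.integer(round(tt * fs)) + 1L
    ok <- centers - npre >= 1L & centers + npost <= n
    st$n_clipped[j] <- sum(!ok)
    centers <- centers[ok]
    w <- t(vapply(centers, function(c0) {
      rec$traces[(c0 - npre):(c0 + npost), j]
    }, numeric(npre + npost + 1L)))
    cuts[[j]] <- w
    st$n[j] <- nrow(w)
    if (nrow(w)) {
      amps <- apply(abs(w), 1, max)
      st$mean_amp_uV[j] <- mean(amps)
      st$amp_cv[j] <- if (nrow(w) > 1) stats::sd(amps) / mean(amps) else 0
      mw <- colMeans(w)
      st$shape_dispersion[j] <- if (nrow(w) > 1) {
        sqrt(mean((sweep(w, 2, mw))^2)) / sqrt(mean(mw^2))
      } else 0
    }
  }
  structure(list(cutouts = cuts, stats = st,
                 pre_ms = pre_ms, post_ms = post_ms),
            class = "waveform_cutouts")
}
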