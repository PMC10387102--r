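#' Detect bursts by the interspike-interval rule
#'
#' A burst is a maximal run of consecutive spikes on one electrode whose
#' interspike intervals are all at most `max_isi_ms` (boundary inclusive),
#' with at least `min_spikes` spikes. Burst duration is last minus first
#' spike time.
#'
#' @param trains A `spike_trains` object.
#' @param max_isi_ms Maximum in-burst interspike interval, ms (default 100).
#' @param min_spikes Minimum spikes per burst (default 2).
#' @return A `burst_set`: `bursts` (data.frame electrode, t_start_s,
#'   t_end_s, n_spikes, duration_ms), `params`, `duration_s`, `electrodes`.
#' @export
detect_bursts <- function(trains, max_isi_ms = 100, min_spikes = 2L) {
  stopifnot(max_isi_ms > 0, min_spikes >= 2)
  max_isi_s <- max_isi_ms * 1e-3
  rows <- list()
  for (id in names(trains$trains)) {
    tt <- trains$trains[[id]]
    if (length(tt) < min_spikes) next
    # split at gaps strictly exceeding the ceiling (tolerance for the
    # sample-quantized timestamps)
    grp <- cumsum(c(0, diff(tt) > max_isi_s + 1e-9))
    for (g in split(tt, grp)) {
      if (length(g) < min_spikes) next
      rows[[length(rows) + 1L]] <- data.frame(
        electrode = id, t_start_s = g[1], t_end_s = g[length(g)],
        n_spikes = length(g), duration_ms = (g[length(g)] - g[1]) * 1000,
        stringsAsFactors = FALSE
      )
    }
  }
  bursts <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(electrode = character(0), t_start_s = numeric(0),
               t_end_s = numeric(0), n_spikes = integer(0),
               duration_ms = numeric(0))
  }
  rownames(bursts) <- NULL
  structure(list(bursts = bursts,
                 params = list(max_isi_ms = max_isi_ms,
                               min_spikes = as.integer(min_spikes)),
                 duration_s = trains$duration_s,
                 electrodes = names(trains$trains)),
            class = "burst_set")
}

#' Burst rate and duration statistics
#'
#' Per active electrode: burst rate (bursts per second of recording), mean
#' burst duration, and the intra-burst spike rate (spikes in bursts per
#' total time in bursts — the natural reading when "burst rate" is reported
#' in tens of Hz). Electrodes without bursts contribute a zero rate but are
#' excluded from the duration and intra-burst averages.
#'
#' @param bursts A `burst_set`.
#' @param active Electrode ids to aggregate over (e.g. from
#'   [active_electrodes()]); default all electrodes in the set.
#' @param duration_s Recording duration; default the burst set's.
#' @return List with `per_electrode` (data.frame electrode, n_bursts,
#'   burst_rate_hz, mean_duration_ms, intra_burst_rate_hz),
#'   `mean_burst_rate_hz`, `mean_burst_duration_ms`,
#'   `mean_intra_burst_rate_hz`.
#' @export
burst_stats <- function(bursts, active = NULL, duration_s = NULL) {
  if (is.null(active)) active <- bursts$electrodes
  unknown <- setdiff(active, bursts$electrodes)
  if (length(unknown)) stop("unknown electrode id: ", paste(unknown, collapse = ", "))
  if (is.null(duration_s)) duration_s <- bursts$duration_s
  b <- bursts$bursts
  per <- data.frame(electrode = active, n_bursts = 0L, burst_rate_hz = 0,
                    mean_duration_ms = NA_real_,
                    intra_burst_rate_hz = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_along(active)) {
    bi <- b[b$electrode == active[i], , drop = FALSE]
    per$n_bursts[i] <- nrow(bi)
    per$burst_rate_hz[i] <- nrow(bi) / duration_s
    if (nrow(bi)) {
      per$mean_duration_ms[i] <- mean(bi$duration_ms)
      tot_t <- sum(bi$duration_ms) / 1000
      per$intra_burst_rate_hz[i] <- if (tot_t > 0) sum(bi$n_spikes) / tot_t else NA_real_
    }
  }
  has <- per$n_bursts > 0
  if (any(!has)) {
    message(sum(!has), " electrode(s) without bursts: rate 0, excluded from duration average")
  }
  list(per_electrode = per,
       mean_burst_rate_hz = if (length(active)) mean(per$burst_rate_hz) else NA_real_,
       mean_burst_duration_ms = if (any(has)) mean(per$mean_duration_ms[has]) else NA_real_,
       mean_intra_burst_rate_hz = if (any(has)) mean(per$intra_burst_rate_hz[has], na.rm = TRUE) else NA_real_)
}
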