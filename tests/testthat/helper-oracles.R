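# Independent reference implementations and fixture builders used as
# oracles across the suite. These deliberately use plain per-sample /
# per-pair scans rather than the package's vectorized code paths.

# Exhaustive per-sample spike detector: state machine over the trace,
# applying the stated rule directly (threshold at k * noise scale,
# polarity = sign of first crossing, crossing = outside after inside,
# dead-time suppression after each accepted event).
ref_detect <- function(x, fs, k_mad = 5, dead_time_ms = 3,
                       mad_type = "normalized") {
  m <- switch(mad_type,
              normalized = 1.4826 * median(abs(x - median(x))),
              median = median(abs(x - median(x))),
              mean = mean(abs(x - mean(x))))
  if (m == 0) return(numeric(0))
  thr <- k_mad * m
  pol <- 0
  for (i in seq_along(x)) {
    if (x[i] > thr) { pol <- 1; break }
    if (x[i] < -thr) { pol <- -1; break }
  }
  if (pol == 0) pol <- -1
  dead <- dead_time_ms * 1e-3 * fs
  idx <- integer(0); last <- -Inf; prev_out <- FALSE
  for (i in seq_along(x)) {
    cur_out <- if (pol < 0) x[i] < -thr else x[i] > thr
    if (cur_out && !prev_out && (i - last >= dead - 1e-9)) {
      idx <- c(idx, i); last <- i
    }
    prev_out <- cur_out
  }
  (idx - 1) / fs
}

# Quadratic-flavoured burst grouper: for each spike, walk forward while
# the gap stays within the ceiling, then emit the run.
ref_bursts <- function(times, max_isi_ms = 100, min_spikes = 2) {
  n <- length(times)
  out <- list()
  i <- 1
  while (i <= n) {
    j <- i
    while (j < n && times[j + 1] - times[j] <= max_isi_ms * 1e-3 + 1e-9) j <- j + 1
    if (j - i + 1 >= min_spikes) {
      out[[length(out) + 1]] <- c(start = times[i], end = times[j],
                                  n = j - i + 1)
    }
    i <- j + 1
  }
  out
}

# Brute-force lagged Pearson correlation with overlap normalization.
ref_cc <- function(x, y, max_lag) {
  n <- length(x)
  sapply(-max_lag:max_lag, function(l) {
    if (l >= 0) { xa <- x[seq_len(n - l)]; yb <- y[seq_len(n - l) + l] }
    else { xa <- x[seq_len(n + l) - l]; yb <- y[seq_len(n + l)] }
    if (length(xa) < 2 || stats::sd(xa) == 0 || stats::sd(yb) == 0) 0
    else stats::cor(xa, yb)
  })
}

# Small layout configurations ---------------------------------------------

config_2x2 <- function() {
  list(grid = list(rows = 2L, cols = 2L, pitch_um = 100, excluded = list()),
       compartments = list(somatic_chamber_A = c(1L, 1L),
                           long_microchannel = c(2L, 2L)),
       references = list(R1 = 1:2))
}

config_3x3 <- function() {
  list(grid = list(rows = 3L, cols = 3L, pitch_um = 100, excluded = list()),
       compartments = list(somatic_chamber_A = c(1L, 1L),
                           short_microchannel = c(2L, 2L),
                           synaptic_chamber = c(3L, 3L)),
       references = list(R1 = 1:3))
}

# Recording / spike-train object builders ---------------------------------

make_rec <- function(traces, fs, settle_s = NULL) {
  if (is.null(dim(traces))) traces <- matrix(traces, ncol = 1,
                                             dimnames = list(NULL, "ch1"))
  prov <- if (is.null(settle_s)) NULL else list(settle_s = settle_s)
  structure(list(traces = traces, sampling_rate = fs,
                 channel_ids = colnames(traces),
                 duration_s = nrow(traces) / fs, provenance = prov),
            class = "mea_recording")
}

make_trains <- function(times_list, duration_s) {
  ids <- names(times_list)
  info <- data.frame(electrode = ids,
                     n_spikes = vapply(times_list, length, 0L),
                     rate_hz = vapply(times_list, length, 0L) / duration_s,
                     mad = 1, threshold_uV = 5, polarity = -1L,
                     degenerate = FALSE, stringsAsFactors = FALSE)
  structure(list(trains = times_list, info = info, duration_s = duration_s,
                 params = list(k_mad = 5, dead_time_ms = 3,
                               mad_type = "normalized", settle_s = 0)),
            class = "spike_trains")
}

# a biphasic deflection of given peak for hand-built traces
bump <- function(peak, fs = 10000, width_ms = 1) {
  w <- mfnet:::spike_template(1, width_ms, fs)
  peak * w$wave
}

insert_bump <- function(x, at_sample, peak, fs = 10000) {
  w <- mfnet:::spike_template(1, 1, fs)
  b <- peak * w$wave
  i0 <- at_sample - (w$peak_index - 1L)
  i1 <- max(1L, i0); i2 <- min(length(x), i0 + length(b) - 1L)
  x[i1:i2] <- x[i1:i2] + b[(i1 - i0 + 1):(i2 - i0 + 1)]
  x
}

edge_key <- function(d, from = "from", to = "to") paste(d[[from]], d[[to]])
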