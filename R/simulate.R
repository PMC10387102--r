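#' Spike source specification
#'
#' Describes one extracellular spike source: a Poisson background train
#' superposed with burst trains (Poisson burst onsets; fixed intra-burst
#' interspike interval plus multiplicative jitter), rendered at its home
#' electrode with a biphasic negative-leading waveform.
#'
#' @param id Source identifier (character, unique).
#' @param home_electrode Electrode id the source is recorded on.
#' @param baseline_rate Background firing rate, events/s.
#' @param burst_rate Burst onset rate, bursts/s.
#' @param spikes_per_burst Integer range `c(min, max)`; burst sizes drawn
#'   uniformly.
#' @param intra_burst_isi_ms Nominal interspike interval within a burst (ms).
#' @param isi_jitter Relative s.d. of the intra-burst ISI.
#' @param amp_uV Waveform peak amplitude in microvolts (negative-leading;
#'   sign is the polarity).
#' @param width_ms Waveform width parameter (ms); the biphasic template
#'   spans about 6 widths.
#' @param amplitude_jitter Relative s.d. of per-event amplitude.
#' @return A `source_spec` list.
#' @export
source_spec <- function(id, home_electrode, baseline_rate = 1,
                        burst_rate = 0, spikes_per_burst = c(4L, 6L),
                        intra_burst_isi_ms = 15, isi_jitter = 0.1,
                        amp_uV = -100, width_ms = 1,
                        amplitude_jitter = 0.02) {
  stopifnot(baseline_rate >= 0, burst_rate >= 0, intra_burst_isi_ms > 0,
            width_ms > 0, amplitude_jitter >= 0)
  structure(list(id = as.character(id),
                 home_electrode = as.character(home_electrode),
                 baseline_rate = baseline_rate, burst_rate = burst_rate,
                 spikes_per_burst = as.integer(spikes_per_burst),
                 intra_burst_isi_ms = intra_burst_isi_ms,
                 isi_jitter = isi_jitter, amp_uV = amp_uV,
                 width_ms = width_ms, amplitude_jitter = amplitude_jitter),
            class = "source_spec")
}

#' Propagation edge specification
#'
#' A directed projection from a source to a target electrode: every source
#' event is copied to the target after `delay_ms`, kept with probability
#' `transmission_prob`, with amplitude scaled by `amplitude_scale`
#' (microchannel sealing typically amplifies, so scales > 1 are common).
#'
#' @param from_source Source id.
#' @param to_electrode Target electrode id.
#' @param delay_ms Propagation delay, ms (>= 0).
#' @param transmission_prob Per-event transmission probability in \[0, 1\].
#' @param amplitude_scale Positive amplitude multiplier at the target.
#' @return A `propagation_edge` list.
#' @export
propagation_edge <- function(from_source, to_electrode, delay_ms,
                             transmission_prob = 1, amplitude_scale = 1) {
  stopifnot(delay_ms >= 0, transmission_prob >= 0, transmission_prob <= 1,
            amplitude_scale > 0)
  structure(list(from_source = as.character(from_source),
                 to_electrode = as.character(to_electrode),
                 delay_ms = delay_ms, transmission_prob = transmission_prob,
                 amplitude_scale = amplitude_scale),
            class = "propagation_edge")
}

# deterministic 31-bit string hash, used to give every source its own
# reproducible RNG stream independent of source ordering
stable_hash <- function(s) {
  h <- 0
  for (k in utf8ToInt(s)) h <- (h * 31 + k) %% 2147483647
  as.integer(h)
}

stream_seed <- function(seed, key) {
  as.integer((as.numeric(seed) %% 65521 * 32749 + stable_hash(key)) %% 2147483647)
}

# biphasic negative-leading spike template (difference of Gaussians),
# sampled at fs; returns the waveform and the index of its main peak.
# width_ms is the approximate total spike duration; the negative phase has
# s.d. width/5, fast enough to pass a 200-3500 Hz band mostly undistorted.
spike_template <- function(amp_uV, width_ms, sampling_rate) {
  s <- width_ms * 1e-3 / 5
  tt <- seq(-3 * s, 4.5 * s, by = 1 / sampling_rate)
  w <- exp(-tt^2 / (2 * s^2)) - 0.45 * exp(-(tt - 1.4 * s)^2 / (2 * (1.6 * s)^2))
  w <- amp_uV * w / max(abs(w))
  list(wave = w, peak_index = which.max(abs(w)))
}

# draws one source's event times with the current RNG state
source_events_core <- function(spec, duration_s) {
  n_base <- rpois(1L, spec$baseline_rate * duration_s)
  t_base <- runif(n_base, 0, duration_s)
  t_burst <- numeric(0)
  n_bursts <- 0L
  if (spec$burst_rate > 0) {
    n_bursts <- rpois(1L, spec$burst_rate * duration_s)
    if (n_bursts > 0) {
      onsets <- runif(n_bursts, 0, duration_s)
      spb <- spec$spikes_per_burst
      sizes <- spb[1] + floor(runif(n_bursts) * (spb[2] - spb[1] + 1L))
      t_burst <- unlist(lapply(seq_len(n_bursts), function(i) {
        isi <- spec$intra_burst_isi_ms * 1e-3 *
          pmax(0.2, 1 + spec$isi_jitter * rnorm(sizes[i] - 1L))
        onsets[i] + cumsum(c(0, isi))
      }))
    }
  }
  times <- sort(c(t_base, t_burst))
  list(times = times[times >= 0 & times <= duration_s], n_bursts = n_bursts)
}

#' Simulate one source's spike times
#'
#' Draws the event times of a single [source_spec()] over a given duration,
#' reproducibly from `seed`. Used for rate/burst calibration independently
#' of voltage rendering.
#'
#' @param spec A `source_spec`.
#' @param duration_s Duration in seconds.
#' @param seed Integer seed.
#' @return Numeric vector of event times (s), sorted.
#' @export
simulate_source_events <- function(spec, duration_s, seed) {
  set.seed(stream_seed(seed, spec$id))
  source_events_core(spec, duration_s)$times
}

#' Simulate a raw multi-channel MEA recording with ground truth
#'
#' Renders per-channel voltage traces as i.i.d. Gaussian noise plus
#' superposed biphasic spike templates: each source fires at its home
#' electrode, and each propagation edge copies the source events to a
#' target electrode after a fixed delay, thinned by the transmission
#' probability and rescaled in amplitude. Two extra reference channels
#' (noise only) named after the layout's reference ids are appended so that
#' the re-referencing stage can be exercised. Each source consumes its own
#' seeded RNG stream keyed by its id, so simulations are reproducible,
#' source-wise decomposable (event superposition is exactly linear) and
#' independent of source ordering.
#'
#' @param layout An `electrode_layout`.
#' @param sources List of [source_spec()] objects.
#' @param edges List of [propagation_edge()] objects.
#' @param noise_sd_uV Noise s.d. per channel, microvolts.
#' @param duration_s Recording length, seconds.
#' @param sampling_rate Sampling rate, Hz (default 10 kHz).
#' @param seed Integer master seed.
#' @return A list with `recording` (an `mea_recording`: `traces` matrix of
#'   samples x channels in microvolts, `sampling_rate`, `channel_ids`,
#'   `duration_s`) and `truth` (an `mea_ground_truth`: per-source and
#'   per-electrode event times, the edge list with true delays, realized
#'   per-electrode rates and per-source burst counts).
#' @export
simulate_recording <- function(layout, sources = list(), edges = list(),
                               noise_sd_uV = 3, duration_s = 50,
                               sampling_rate = 10000, seed = 1) {
  stopifnot(duration_s > 0, sampling_rate > 0)
  src_ids <- vapply(sources, `[[`, "", "id")
  if (anyDuplicated(src_ids)) stop("duplicate source ids")
  el_ids <- layout$electrodes$id
  for (s in sources) {
    if (!s$home_electrode %in% el_ids) stop("unknown home electrode: ", s$home_electrode)
    if (sampling_rate < 10 / (s$width_ms * 1e-3)) {
      stop("sampling_rate too low to render a ", s$width_ms, " ms template")
    }
  }
  for (e in edges) {
    if (!e$to_electrode %in% el_ids) {
      stop("unknown electrode in edges: ", e$to_electrode)
    }
    if (!e$from_source %in% src_ids) stop("unknown source in edges: ", e$from_source)
  }

  n_samples <- as.integer(round(duration_s * sampling_rate))
  channels <- c(el_ids, layout$reference_ids)

  ev_electrode <- character(0); ev_time <- numeric(0)
  ev_source <- character(0); ev_amp <- numeric(0)
  source_events <- stats::setNames(vector("list", length(sources)), src_ids)
  burst_counts <- integer(length(sources))
  templates <- stats::setNames(vector("list", length(sources)), src_ids)

  # draw all events first (one seeded RNG stream per source id, so the
  # superposition is linear across sources and independent of ordering)
  for (si in seq_along(sources)) {
    s <- sources[[si]]
    set.seed(stream_seed(seed, s$id))
    ev <- source_events_core(s, duration_s)
    times <- ev$times
    burst_counts[si] <- ev$n_bursts
    source_events[[s$id]] <- times
    templates[[s$id]] <- spike_template(1, s$width_ms, sampling_rate)
    amps <- s$amp_uV * (1 + s$amplitude_jitter * rnorm(length(times)))
    ev_electrode <- c(ev_electrode, rep(s$home_electrode, length(times)))
    ev_time <- c(ev_time, times)
    ev_source <- c(ev_source, rep(s$id, length(times)))
    ev_amp <- c(ev_amp, amps)
    for (e in edges) {
      if (e$from_source != s$id) next
      keep <- runif(length(times)) < e$transmission_prob
      tt <- times[keep] + e$delay_ms * 1e-3
      aa <- amps[keep] * e$amplitude_scale
      inside <- tt <= duration_s
      tt <- tt[inside]; aa <- aa[inside]
      ev_electrode <- c(ev_electrode, rep(e$to_electrode, length(tt)))
      ev_time <- c(ev_time, tt)
      ev_source <- c(ev_source, rep(s$id, length(tt)))
      ev_amp <- c(ev_amp, aa)
    }
  }

  if (noise_sd_uV > 0) {
    set.seed(stream_seed(seed, ".noise"))
    traces <- matrix(rnorm(n_samples * length(channels), sd = noise_sd_uV),
                     nrow = n_samples, ncol = length(channels),
                     dimnames = list(NULL, channels))
  } else {
    traces <- matrix(0, nrow = n_samples, ncol = length(channels),
                     dimnames = list(NULL, channels))
  }

  # render templates channel by channel (local vector keeps updates in place)
  for (ch in unique(ev_electrode)) {
    sel <- which(ev_electrode == ch)
    v <- traces[, ch]
    for (k in sel) {
      tmpl <- templates[[ev_source[k]]]
      idx0 <- as.integer(round(ev_time[k] * sampling_rate)) + 1L - (tmpl$peak_index - 1L)
      L <- length(tmpl$wave)
      i1 <- max(1L, idx0); i2 <- min(n_samples, idx0 + L - 1L)
      if (i2 < i1) next
      j1 <- i1 - idx0 + 1L
      v[i1:i2] <- v[i1:i2] + ev_amp[k] * tmpl$wave[j1:(j1 + i2 - i1)]
    }
    traces[, ch] <- v
  }

  events <- data.frame(electrode = ev_electrode, time_s = ev_time,
                       source = ev_source, amplitude_uV = ev_amp,
                       stringsAsFactors = FALSE)
  events <- events[order(events$electrode, events$time_s), , drop = FALSE]
  rownames(events) <- NULL
  rate_tab <- table(factor(events$electrode, levels = el_ids))
  edge_df <- if (length(edges)) {
    data.frame(
      from_source = vapply(edges, `[[`, "", "from_source"),
      from_electrode = vapply(edges, function(e) {
        sources[[match(e$from_source, src_ids)]]$home_electrode
      }, ""),
      to_electrode = vapply(edges, `[[`, "", "to_electrode"),
      delay_ms = vapply(edges, `[[`, 0, "delay_ms"),
      transmission_prob = vapply(edges, `[[`, 0, "transmission_prob"),
      amplitude_scale = vapply(edges, `[[`, 0, "amplitude_scale"),
      stringsAsFactors = FALSE
    )
  } else {
    data.frame(from_source = character(0), from_electrode = character(0),
               to_electrode = character(0), delay_ms = numeric(0),
               transmission_prob = numeric(0), amplitude_scale = numeric(0))
  }

  recording <- structure(
    list(traces = traces, sampling_rate = sampling_rate,
         channel_ids = channels, duration_s = duration_s),
    class = "mea_recording"
  )
  truth <- structure(
    list(source_events = source_events, events = events, edges = edge_df,
         sources = sources,
         electrode_rates = data.frame(electrode = names(rate_tab),
                                      rate_hz = as.numeric(rate_tab) / duration_s,
                                      stringsAsFactors = FALSE),
         burst_truth = data.frame(
           source = src_ids,
           home_electrode = vapply(sources, `[[`, "", "home_electrode"),
           n_bursts = burst_counts,
           burst_rate_hz = burst_counts / duration_s,
           stringsAsFactors = FALSE
         ),
         duration_s = duration_s, seed = seed),
    class = "mea_ground_truth"
  )
  list(recording = recording, truth = truth)
}

#' @export
print.mea_recording <- function(x, ...) {
  cat(sprintf("mea_recording: %d channels x %g s @ %g Hz (%d samples)\n",
              ncol(x$traces), x$duration_s, x$sampling_rate, nrow(x$traces)))
  invisible(x)
}

# per-source map electrode -> cumulative delay (home at 0 ms)
source_delay_maps <- function(truth) {
  lapply(truth$sources, function(s) {
    e <- truth$edges[truth$edges$from_source == s$id, , drop = FALSE]
    stats::setNames(c(0, e$delay_ms), c(s$home_electrode, e$to_electrode))
  })
}

pairwise_delay_implied <- function(truth, keep) {
  out <- list()
  for (dm in source_delay_maps(truth)) {
    if (length(dm) < 2) next
    cmb <- utils::combn(length(dm), 2)
    for (k in seq_len(ncol(cmb))) {
      i <- cmb[1, k]; j <- cmb[2, k]
      d <- dm[j] - dm[i]
      from <- names(dm)[i]; to <- names(dm)[j]
      if (d < 0) { d <- -d; tmp <- from; from <- to; to <- tmp }
      if (from == to || !keep(d)) next
      out[[paste(from, to)]] <- data.frame(from = from, to = to, delay_ms = d,
                                           stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(from = character(0), to = character(0),
                      delay_ms = numeric(0)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Ground-truth directed pairs with delays in a window
#'
#' Enumerates electrode pairs that share a source and whose cumulative
#' propagation delays differ by `min_ms` to `max_ms`; these are the pairs a
#' delayed-correlation analysis is expected to recover, oriented from the
#' leading to the lagging electrode.
#'
#' @param truth An `mea_ground_truth`.
#' @param min_ms,max_ms Delay-difference window (ms), inclusive.
#' @return data.frame with `from`, `to`, `delay_ms`.
#' @export
true_delayed_edges <- function(truth, min_ms = 5, max_ms = 25) {
  pairwise_delay_implied(truth, function(d) d >= min_ms & d <= max_ms)
}

#' Ground-truth synchronous (common-drive) pairs
#'
#' Electrode pairs sharing a source with cumulative delays differing by at
#' most `tol_ms`: the pairs a short-term (central-bin) correlation map is
#' expected to recover.
#'
#' @inheritParams true_delayed_edges
#' @param tol_ms Maximum delay difference (ms).
#' @return data.frame with `from`, `to`, `delay_ms` (unordered pairs,
#'   `from` < `to`).
#' @export
true_zero_delay_pairs <- function(truth, tol_ms = 2.5) {
  d <- pairwise_delay_implied(truth, function(x) x <= tol_ms)
  if (nrow(d)) {
    swap <- d$from > d$to
    tmp <- d$from[swap]; d$from[swap] <- d$to[swap]; d$to[swap] <- tmp
    d <- d[!duplicated(d[c("from", "to")]), , drop = FALSE]
    rownames(d) <- NULL
  }
  d
}

#' Canned dual-compartment scenario
#'
#' A complete test scenario on the default layout, emulating one soma
#' driving two geometrically defined pathways: a straight chain through a
#' short microchannel, the synaptic chamber and two long-microchannel
#' electrodes (cumulative delays 6-20 ms), and a second arbor spreading
#' synchronously across the synaptic chamber; three synaptic-chamber
#' sources each feed one somatic electrode back at 8 ms (afferent nodes);
#' a common-drive triplet in the short microchannels carries zero relative
#' delay; an unconnected control block (empty chamber plus two somatic
#' electrodes) fires independently. Somatic waveforms are small (-44 to
#' -60 uV) and microchannel/synaptic waveforms large (-80 to -100 uV),
#' reflecting microchannel sealing amplification. All true edge delays lie
#' in 6-20 ms, resolvable at 5 ms binning.
#'
#' The programmed somatic node roles are: one efferent electrode ("24"),
#' three afferent electrodes ("12", "15", "17"), all other active somatic
#' electrodes isolated.
#'
#' @param seed Integer seed.
#' @param duration_s Recording length, s (default 50).
#' @param sampling_rate Sampling rate, Hz (default 10 kHz).
#' @param noise_sd_uV Noise s.d., microvolts (default 3).
#' @return As [simulate_recording()]: list with `recording` and `truth`.
#' @export
scenario_dual_compartment <- function(seed, duration_s = 50,
                                      sampling_rate = 10000, noise_sd_uV = 3) {
  layout <- build_layout()
  mk_ctrl <- function(id, home, rate, amp, burst_rate, isi) {
    source_spec(id, home, baseline_rate = rate, burst_rate = burst_rate,
                spikes_per_burst = c(3L, 5L), intra_burst_isi_ms = isi,
                amp_uV = amp)
  }
  sources <- list(
    source_spec("S1", "24", baseline_rate = 2.0, burst_rate = 0.30,
                spikes_per_burst = c(5L, 7L), intra_burst_isi_ms = 15,
                amp_uV = -60, amplitude_jitter = 0.03),
    source_spec("S2", "24", baseline_rate = 1.8, burst_rate = 0.25,
                spikes_per_burst = c(5L, 7L), intra_burst_isi_ms = 15,
                amp_uV = -55, amplitude_jitter = 0.03),
    source_spec("F1", "52", baseline_rate = 2.2, burst_rate = 0.20,
                spikes_per_burst = c(4L, 6L), intra_burst_isi_ms = 20,
                amp_uV = -80),
    source_spec("F2", "55", baseline_rate = 2.2, burst_rate = 0.20,
                spikes_per_burst = c(4L, 6L), intra_burst_isi_ms = 20,
                amp_uV = -80),
    source_spec("F3", "57", baseline_rate = 2.2, burst_rate = 0.20,
                spikes_per_burst = c(4L, 6L), intra_burst_isi_ms = 20,
                amp_uV = -80),
    mk_ctrl("C1", "82", 1.2, -70, 0.10, 25), mk_ctrl("C2", "83", 1.2, -70, 0.10, 25),
    mk_ctrl("C3", "84", 1.2, -70, 0.10, 25), mk_ctrl("C4", "85", 1.2, -70, 0.10, 25),
    mk_ctrl("C5", "86", 1.2, -70, 0.10, 25), mk_ctrl("C6", "87", 1.2, -70, 0.10, 25),
    mk_ctrl("C7", "21", 1.5, -50, 0.15, 20), mk_ctrl("C8", "28", 1.5, -50, 0.15, 20)
  )
  pe <- function(src, to, d, scale) {
    propagation_edge(src, to, d, transmission_prob = 0.9, amplitude_scale = scale)
  }
  edges <- list(
    # S1: straight chain soma -> short channel(s) -> synaptic -> long channels
    pe("S1", "34", 6, 100 / 60), pe("S1", "33", 6, 100 / 60), pe("S1", "35", 6, 100 / 60),
    pe("S1", "44", 12, 90 / 60), pe("S1", "64", 18, 100 / 60), pe("S1", "74", 20, 100 / 60),
    # S2: arbor spreading synchronously over the synaptic chamber
    pe("S2", "36", 6, 100 / 55),
    pe("S2", "45", 12, 82 / 55), pe("S2", "46", 12, 82 / 55),
    pe("S2", "47", 12, 82 / 55), pe("S2", "56", 12, 82 / 55),
    # feeders: synaptic chamber -> somatic afferents + local synaptic spread
    pe("F1", "42", 6, 1.2), pe("F1", "12", 8, 0.55),
    pe("F2", "54", 6, 1.2), pe("F2", "15", 8, 0.55),
    pe("F3", "48", 6, 1.2), pe("F3", "17", 8, 0.55)
  )
  out <- simulate_recording(layout, sources, edges, noise_sd_uV = noise_sd_uV,
                            duration_s = duration_s,
                            sampling_rate = sampling_rate, seed = seed)
  out$truth$programmed_roles <- list(
    efferent = "24",
    afferent = c("12", "15", "17")
  )
  out$layout <- layout
  out
}
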