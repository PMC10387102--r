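#' Analysis configuration
#'
#' All stage parameters of the pipeline, at their standard defaults:
#' 200-3500 Hz 4th-order Bessel bandpass after column-group re-referencing,
#' +/-5 MAD threshold with 3 ms dead time, 0.1 Hz active-electrode gate,
#' 100 ms burst ISI ceiling with at least 2 spikes, 5 ms correlation bins
#' with a 5-bin (25 ms) lag window, 1000 jitter surrogates (+/-50 ms) at
#' alpha 0.01. A serialized configuration plus the input recording and the
#' seed fully determine every output.
#'
#' @param k_mad,dead_time_ms,mad_type Spike detection; see
#'   [detect_spikes()].
#' @param min_rate_hz Active-electrode gate; see [active_electrodes()].
#' @param max_isi_ms,min_spikes Burst detection; see [detect_bursts()].
#' @param bin_ms,max_lag_bins,n_surrogates,jitter_ms,alpha Correlation
#'   analysis; see [correlate_pairs()].
#' @param low_hz,high_hz,order,zero_phase,settle_ms Filtering; see
#'   [bandpass()].
#' @param seed Integer seed for all randomness.
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(k_mad = 5, dead_time_ms = 3,
                            mad_type = "normalized", min_rate_hz = 0.1,
                            max_isi_ms = 100, min_spikes = 2L, bin_ms = 5,
                            low_hz = 200, high_hz = 3500, order = 4L,
                            zero_phase = FALSE, settle_ms = 100,
                            max_lag_bins = 5L, n_surrogates = 1000L,
                            jitter_ms = 50, alpha = 0.01, seed = 1L) {
  structure(list(k_mad = k_mad, dead_time_ms = dead_time_ms,
                 mad_type = mad_type, min_rate_hz = min_rate_hz,
                 max_isi_ms = max_isi_ms, min_spikes = as.integer(min_spikes),
                 bin_ms = bin_ms, low_hz = low_hz, high_hz = high_hz,
                 order = as.integer(order), zero_phase = zero_phase,
                 settle_ms = settle_ms, max_lag_bins = as.integer(max_lag_bins),
                 n_surrogates = as.integer(n_surrogates),
                 jitter_ms = jitter_ms, alpha = alpha, seed = as.integer(seed)),
            class = "analysis_config")
}

#' Read / write an analysis configuration (flat YAML key-value file)
#'
#' @param path File path.
#' @param config An `analysis_config`.
#' @return `read_config` returns an `analysis_config` (unknown keys are an
#'   error); `write_config` returns `path` invisibly.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(analysis_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  do.call(analysis_config, vals)
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Stable hash of a configuration (32-bit polynomial hash)
#'
#' @param config An `analysis_config`.
#' @return 8-character hex string.
#' @export
config_hash <- function(config) {
  s <- paste(names(config), vapply(config, function(v) format(v, digits = 15), ""),
             sep = "=", collapse = ";")
  h <- 5381
  for (k in utf8ToInt(s)) h <- (h * 33 + k) %% 4294967296
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Run the full analysis pipeline
#'
#' Executes re-referencing, Bessel bandpass filtering, MAD-threshold spike
#' detection, the active-electrode gate, burst detection, pairwise
#' correlation with surrogate significance, and the short-term and delayed
#' connectivity graphs with node roles — in that order, logging each
#' stage's parameters and counts. All randomness derives from the
#' configuration seed, so identical inputs and configuration reproduce the
#' report byte-identically.
#'
#' @param rec An `mea_recording` or a path readable by [read_recording()].
#' @param layout An `electrode_layout` or a path to its JSON.
#' @param config An `analysis_config` or a path to its YAML.
#' @param out_dir Optional directory; when given, spike trains, bursts,
#'   correlations, both graphs (edge CSV + GraphML), node roles and the
#'   JSON report are written there. A failing stage leaves a
#'   `FAILED_<stage>` marker file.
#' @param verbose Emit per-stage log messages (default `TRUE`).
#' @return A `run_report` list (config echo with hash, per-stage
#'   summaries), with the stage objects attached in `$objects`.
#' @export
run_pipeline <- function(rec, layout, config = analysis_config(),
                         out_dir = NULL, verbose = TRUE) {
  if (is.character(rec)) rec <- read_recording(rec)
  if (is.character(layout)) layout <- read_layout_json(layout)
  if (is.character(config)) config <- read_config(config)
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  log <- function(...) if (verbose) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      if (!is.null(out_dir)) {
        writeLines(conditionMessage(e),
                   file.path(out_dir, paste0("FAILED_", name)))
      }
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  log("preprocess: re-reference + bessel bandpass %g-%g Hz order %d",
      config$low_hz, config$high_hz, config$order)
  filt <- stage("preprocess", {
    bandpass(rereference(rec, layout), low = config$low_hz,
             high = config$high_hz, order = config$order,
             zero_phase = config$zero_phase, settle_ms = config$settle_ms)
  })

  trains <- stage("detect", {
    detect_spikes(filt, k_mad = config$k_mad,
                  dead_time_ms = config$dead_time_ms,
                  mad_type = config$mad_type)
  })
  active <- active_electrodes(trains, config$min_rate_hz)
  log("detect: %d spikes on %d channels, %d active (>= %g Hz)",
      sum(trains$info$n_spikes), length(trains$trains), length(active),
      config$min_rate_hz)
  rates <- if (length(active)) mean_firing_rate(trains, active) else NULL

  bursts <- stage("bursts", {
    detect_bursts(trains, max_isi_ms = config$max_isi_ms,
                  min_spikes = config$min_spikes)
  })
  bstats <- if (length(active)) {
    suppressMessages(burst_stats(bursts, active))
  } else {
    NULL
  }
  log("bursts: %d bursts (max ISI %g ms, min %d spikes)",
      nrow(bursts$bursts), config$max_isi_ms, config$min_spikes)

  cc <- stage("correlate", {
    correlate_pairs(trains, electrodes = active, bin_ms = config$bin_ms,
                    max_lag_bins = config$max_lag_bins,
                    n_surrogates = config$n_surrogates,
                    jitter_ms = config$jitter_ms, alpha = config$alpha,
                    seed = config$seed)
  })
  log("correlate: %d pairs, %d significant at alpha=%g",
      nrow(cc), sum(cc$significant), config$alpha)

  gshort <- stage("graph", short_term_graph(cc, layout))
  gdel <- stage("graph", delayed_graph(cc, layout))
  roles <- node_roles(gdel, layout)
  log("graph: %d short-term edges, %d delayed edges", nrow(gshort), nrow(gdel))

  active_roles <- roles[roles$electrode %in% active, , drop = FALSE]
  report <- list(
    config = unclass(config),
    config_hash = config_hash(config),
    n_channels = length(rec$channel_ids),
    duration_s = rec$duration_s,
    n_active_electrodes = length(active),
    active_electrodes = sort(active),
    mean_firing_rate_hz = if (is.null(rates)) NULL else rates$mean_rate_hz,
    n_bursts = nrow(bursts$bursts),
    mean_burst_rate_hz = if (is.null(bstats)) NULL else bstats$mean_burst_rate_hz,
    mean_burst_duration_ms = if (is.null(bstats)) NULL else bstats$mean_burst_duration_ms,
    n_pairs = nrow(cc),
    n_significant_pairs = sum(cc$significant),
    short_term = list(n_edges = nrow(gshort),
                      class_counts = as.list(classify_edges(gshort, layout)$class_counts)),
    delayed = list(n_edges = nrow(gdel),
                   class_counts = as.list(classify_edges(gdel, layout)$class_counts)),
    node_roles = list(
      n_efferent = sum(active_roles$role == "efferent", na.rm = TRUE),
      n_afferent = sum(active_roles$role == "afferent", na.rm = TRUE),
      n_mixed = sum(active_roles$role == "mixed", na.rm = TRUE),
      efferent = sort(active_roles$electrode[which(active_roles$role == "efferent")]),
      afferent = sort(active_roles$electrode[which(active_roles$role == "afferent")])
    )
  )
  class(report) <- "run_report"
  report$objects <- list(filtered = filt, trains = trains, active = active,
                         bursts = bursts, correlations = cc,
                         short_term = gshort, delayed = gdel, roles = roles)

  if (!is.null(out_dir)) {
    write_spike_trains(trains, file.path(out_dir, "spikes.csv"))
    write_bursts(bursts, file.path(out_dir, "bursts.csv"))
    write_correlations(cc, file.path(out_dir, "correlations.csv"))
    utils::write.csv(gshort, file.path(out_dir, "short_term_edges.csv"),
                     row.names = FALSE)
    utils::write.csv(gdel, file.path(out_dir, "delayed_edges.csv"),
                     row.names = FALSE)
    utils::write.csv(roles, file.path(out_dir, "node_roles.csv"),
                     row.names = FALSE)
    if (nrow(gshort)) write_graphml(gshort, layout, file.path(out_dir, "short_term.graphml"))
    if (nrow(gdel)) write_graphml(gdel, layout, file.path(out_dir, "delayed.graphml"))
    write_config(config, file.path(out_dir, "config.yaml"))
    write_report(report, file.path(out_dir, "report.json"))
  }
  report
}

#' Write a run report as JSON
#'
#' Serializes the summary part of a `run_report` (not the attached stage
#' objects) deterministically, so identical runs give byte-identical
#' files.
#'
#' @param report A `run_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  r <- unclass(report)
  r$objects <- NULL
  jsonlite::write_json(r, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("mfnet run report (config %s)\n", x$config_hash))
  cat(sprintf("  channels: %d, duration: %g s\n", x$n_channels, x$duration_s))
  cat(sprintf("  active electrodes: %d", x$n_active_electrodes))
  if (!is.null(x$mean_firing_rate_hz)) {
    cat(sprintf(" (mean rate %.3g Hz)", x$mean_firing_rate_hz))
  }
  cat("\n")
  cat(sprintf("  bursts: %d", x$n_bursts))
  if (!is.null(x$mean_burst_rate_hz)) {
    cat(sprintf(" (%.3g bursts/s, mean duration %.3g ms)",
                x$mean_burst_rate_hz, x$mean_burst_duration_ms))
  }
  cat("\n")
  cat(sprintf("  pairs: %d, significant: %d\n", x$n_pairs, x$n_significant_pairs))
  cat(sprintf("  edges: %d short-term, %d delayed; efferent %d, afferent %d\n",
              x$short_term$n_edges, x$delayed$n_edges,
              x$node_roles$n_efferent, x$node_roles$n_afferent))
  invisible(x)
}
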