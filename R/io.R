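# Plain-text artifact formats. Every writer emits a small '#'-prefixed
# metadata header followed by CSV; every reader reconstructs the object.

meta_header <- function(kind, meta) {
  c(sprintf("# mfnet_%s v1", kind),
    vapply(names(meta), function(k) sprintf("# %s: %s", k, meta[[k]]), ""))
}

read_meta <- function(path) {
  lines <- readLines(path, n = 50)
  hdr <- lines[startsWith(lines, "#")]
  meta <- list()
  for (h in hdr[-1]) {
    kv <- sub("^# *", "", h)
    key <- sub(":.*$", "", kv)
    meta[[key]] <- trimws(sub("^[^:]*: *", "", kv))
  }
  list(meta = meta, skip = length(hdr))
}

#' Write / read a multi-channel recording as CSV
#'
#' Plain-text container: `#` metadata lines (sampling rate, duration)
#' followed by one CSV column per channel, in microvolts.
#'
#' @param rec An `mea_recording`.
#' @param path File path.
#' @return `write_recording` returns `path` invisibly; `read_recording`
#'   returns an `mea_recording`.
#' @export
write_recording <- function(rec, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(meta_header("recording", list(
    sampling_rate_hz = format(rec$sampling_rate, digits = 15),
    duration_s = format(rec$duration_s, digits = 15)
  )), con)
  utils::write.csv(as.data.frame(rec$traces), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  m <- read_meta(path)
  if (is.null(m$meta$sampling_rate_hz)) {
    stop("parse error in ", path, ": missing sampling_rate_hz header")
  }
  df <- utils::read.csv(path, skip = m$skip, check.names = FALSE)
  traces <- as.matrix(df)
  structure(list(traces = traces,
                 sampling_rate = as.numeric(m$meta$sampling_rate_hz),
                 channel_ids = colnames(traces),
                 duration_s = as.numeric(m$meta$duration_s)),
            class = "mea_recording")
}

#' Write / read a spike-train set as CSV
#'
#' Long-format CSV (`electrode_id`, `t_s`) with the electrode roster,
#' duration and detection parameters in the metadata header, so that
#' silent electrodes survive the round trip.
#'
#' @param trains A `spike_trains` object.
#' @param path File path.
#' @return `write_spike_trains` returns `path` invisibly;
#'   `read_spike_trains` returns a `spike_trains` object (detection
#'   thresholds are not persisted).
#' @export
write_spike_trains <- function(trains, path) {
  con <- file(path, "w")
  on.exit(close(con))
  p <- trains$params
  writeLines(meta_header("spike_trains", list(
    duration_s = format(trains$duration_s, digits = 15),
    electrodes = paste(names(trains$trains), collapse = " "),
    k_mad = p$k_mad, dead_time_ms = p$dead_time_ms,
    mad_type = p$mad_type, settle_s = p$settle_s
  )), con)
  df <- data.frame(
    electrode_id = rep(names(trains$trains),
                       vapply(trains$trains, length, 0L)),
    t_s = sprintf("%.12f", unlist(trains$trains, use.names = FALSE))
  )
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_spike_trains
#' @export
read_spike_trains <- function(path) {
  m <- read_meta(path)
  if (is.null(m$meta$electrodes)) {
    stop("parse error in ", path, ": missing electrodes header")
  }
  ids <- strsplit(m$meta$electrodes, " ")[[1]]
  df <- utils::read.csv(path, skip = m$skip,
                        colClasses = c("character", "numeric"))
  trains <- stats::setNames(
    lapply(ids, function(id) sort(df$t_s[df$electrode_id == id])), ids)
  duration_s <- as.numeric(m$meta$duration_s)
  info <- data.frame(electrode = ids,
                     n_spikes = vapply(trains, length, 0L),
                     rate_hz = vapply(trains, length, 0L) / duration_s,
                     mad = NA_real_, threshold_uV = NA_real_,
                     polarity = NA_integer_, degenerate = FALSE,
                     stringsAsFactors = FALSE)
  structure(list(trains = trains, info = info, duration_s = duration_s,
                 params = list(k_mad = as.numeric(m$meta$k_mad),
                               dead_time_ms = as.numeric(m$meta$dead_time_ms),
                               mad_type = m$meta$mad_type,
                               settle_s = as.numeric(m$meta$settle_s))),
            class = "spike_trains")
}

#' Write / read a burst set as CSV
#'
#' @param bursts A `burst_set`.
#' @param path File path.
#' @return `write_bursts` returns `path` invisibly; `read_bursts` a
#'   `burst_set`.
#' @export
write_bursts <- function(bursts, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(meta_header("bursts", list(
    duration_s = format(bursts$duration_s, digits = 15),
    electrodes = paste(bursts$electrodes, collapse = " "),
    max_isi_ms = bursts$params$max_isi_ms,
    min_spikes = bursts$params$min_spikes
  )), con)
  b <- bursts$bursts
  b$t_start_s <- sprintf("%.9f", b$t_start_s)
  b$t_end_s <- sprintf("%.9f", b$t_end_s)
  utils::write.csv(b, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_bursts
#' @export
read_bursts <- function(path) {
  m <- read_meta(path)
  df <- utils::read.csv(path, skip = m$skip,
                        colClasses = c("character", "numeric", "numeric",
                                       "integer", "numeric"))
  structure(list(bursts = df,
                 params = list(max_isi_ms = as.numeric(m$meta$max_isi_ms),
                               min_spikes = as.integer(m$meta$min_spikes)),
                 duration_s = as.numeric(m$meta$duration_s),
                 electrodes = strsplit(m$meta$electrodes, " ")[[1]]),
            class = "burst_set")
}

#' Write / read a pairwise correlation table as CSV
#'
#' @param cc A `correlation_result` from [correlate_pairs()].
#' @param path File path.
#' @return `write_correlations` returns `path` invisibly;
#'   `read_correlations` a `correlation_result`.
#' @export
write_correlations <- function(cc, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(meta_header("correlations", list(
    bin_ms = attr(cc, "bin_ms"), max_lag_bins = attr(cc, "max_lag_bins"),
    alpha = attr(cc, "alpha")
  )), con)
  utils::write.csv(as.data.frame(cc), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_correlations
#' @export
read_correlations <- function(path) {
  m <- read_meta(path)
  df <- utils::read.csv(path, skip = m$skip,
                        colClasses = c(a = "character", b = "character"))
  attr(df, "bin_ms") <- as.numeric(m$meta$bin_ms)
  attr(df, "max_lag_bins") <- as.integer(m$meta$max_lag_bins)
  attr(df, "alpha") <- as.numeric(m$meta$alpha)
  class(df) <- c("correlation_result", "data.frame")
  df
}
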