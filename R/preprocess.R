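#' Analog Bessel low-pass prototype
#'
#' Poles and gain of an order-`n` analog Bessel (Thomson) low-pass filter,
#' normalized so the magnitude response is -3 dB at angular frequency 1.
#' Poles are the roots of the reverse Bessel polynomial
#' `theta_n(s) = sum_k (2n-k)! / (2^(n-k) k! (n-k)!) s^k`, rescaled from
#' the unit-group-delay normalization to the magnitude normalization.
#'
#' @param n Filter order (positive integer).
#' @return List with `poles` (complex) and `gain` (real).
#' @export
bessel_prototype <- function(n) {
  stopifnot(n == round(n), n >= 1)
  k <- 0:n
  a <- factorial(2 * n - k) / (2^(n - k) * factorial(k) * factorial(n - k))
  poles <- polyroot(a)
  gain <- a[1]
  mag2 <- function(w) {
    th <- sum(a * (1i * w)^k)
    gain^2 / Mod(th)^2
  }
  w3 <- stats::uniroot(function(w) mag2(w) - 0.5, c(1e-6, 4 * n),
                       tol = 1e-13)$root
  list(poles = poles / w3, gain = gain / w3^n)
}

#' Digital Bessel bandpass filter design
#'
#' Designs a digital Bessel bandpass of the given order by the standard
#' route: analog low-pass prototype, low-pass-to-bandpass transform with
#' frequency pre-warping, then bilinear mapping (mirroring
#' [signal::butter()]'s internals, with the Bessel prototype of
#' [bessel_prototype()]).
#'
#' @param order Prototype order (the bandpass has `2 * order` poles).
#' @param low,high Cutoff frequencies, Hz.
#' @param sampling_rate Sampling rate, Hz.
#' @return A [signal::Arma()] filter (coefficients `b`, `a`).
#' @export
bessel_bandpass <- function(order = 4, low = 200, high = 3500,
                            sampling_rate = 10000) {
  if (!(low > 0 && high > low)) stop("need 0 < low < high")
  if (high >= sampling_rate / 2) {
    stop("high cutoff (", high, " Hz) must be below the Nyquist frequency (",
         sampling_rate / 2, " Hz): raise the sampling rate or lower the cutoff")
  }
  W <- c(low, high) / (sampling_rate / 2)
  T <- 2
  Wa <- 2 / T * tan(pi * W / T)
  p <- bessel_prototype(order)
  zpg <- signal::Zpg(zero = numeric(0), pole = p$poles, gain = p$gain)
  zpg <- signal::sftrans(zpg, W = Wa, stop = FALSE)
  zpg <- signal::bilinear(zpg, T = T)
  arma <- signal::as.Arma(zpg)
  signal::Arma(b = Re(arma$b), a = Re(arma$a))
}

#' Magnitude response of a digital filter
#'
#' @param filt A [signal::Arma()] filter.
#' @param freq_hz Frequencies at which to evaluate, Hz.
#' @param sampling_rate Sampling rate, Hz.
#' @return Magnitude |H| at each frequency.
#' @export
filter_magnitude <- function(filt, freq_hz, sampling_rate) {
  vapply(freq_hz, function(f) {
    z <- exp(-1i * 2 * pi * f / sampling_rate)
    Mod(sum(filt$b * z^(seq_along(filt$b) - 1)) /
          sum(filt$a * z^(seq_along(filt$a) - 1)))
  }, 0)
}

#' Re-reference analysis channels against their chamber reference
#'
#' Subtracts, sample-wise, each analysis electrode's assigned reference
#' channel (from the layout's reference map: by default columns 1-4 against
#' `R1`, columns 5-8 against `R2`), removing artifacts shared through the
#' resistive path to the reference. Reference channels are dropped from the
#' output.
#'
#' @param rec An `mea_recording`.
#' @param layout An `electrode_layout` whose electrodes are all present in
#'   `rec`.
#' @return An `mea_recording` containing only the analysis electrodes, with
#'   a `provenance` record of the reference map used.
#' @export
rereference <- function(rec, layout) {
  e <- layout$electrodes
  missing_el <- setdiff(e$id, rec$channel_ids)
  if (length(missing_el)) {
    stop("recording lacks electrode channel(s): ",
         paste(missing_el, collapse = ", "))
  }
  missing_ref <- setdiff(unique(e$reference), rec$channel_ids)
  if (length(missing_ref)) {
    stop("missing reference channel(s): ", paste(missing_ref, collapse = ", "))
  }
  out <- rec$traces[, e$id, drop = FALSE] -
    rec$traces[, e$reference, drop = FALSE]
  colnames(out) <- e$id
  structure(
    list(traces = out, sampling_rate = rec$sampling_rate,
         channel_ids = e$id, duration_s = rec$duration_s,
         provenance = c(rec$provenance,
                        list(reference_map = stats::setNames(e$reference, e$id)))),
    class = "mea_recording"
  )
}

#' Bessel bandpass filtering of a recording
#'
#' Filters every channel with a Bessel bandpass (defaults: 4th order,
#' 200-3500 Hz). The default application is single-pass causal, which
#' preserves the causal ordering of spike onsets that the delayed
#' correlation analysis depends on; `zero_phase = TRUE` applies the filter
#' forward and backward instead ([signal::filtfilt()]). An initial settling
#' window (`settle_ms`) is recorded in the provenance and excluded from
#' downstream detection, absorbing the filter's startup transient.
#'
#' @param rec An `mea_recording`.
#' @param low,high Cutoff frequencies, Hz.
#' @param order Filter order (default 4).
#' @param zero_phase Apply forward-backward instead of causal (default
#'   `FALSE`).
#' @param settle_ms Initial settling window excluded from analysis, ms.
#' @return A filtered `mea_recording` with complete filter provenance.
#' @export
bandpass <- function(rec, low = 200, high = 3500, order = 4,
                     zero_phase = FALSE, settle_ms = 100) {
  filt <- bessel_bandpass(order, low, high, rec$sampling_rate)
  out <- rec$traces
  for (j in seq_len(ncol(out))) {
    out[, j] <- if (zero_phase) {
      signal::filtfilt(filt, rec$traces[, j])
    } else {
      signal::filter(filt, rec$traces[, j])
    }
  }
  structure(
    list(traces = out, sampling_rate = rec$sampling_rate,
         channel_ids = rec$channel_ids, duration_s = rec$duration_s,
         provenance = c(rec$provenance,
                        list(filter = list(type = "bessel_bandpass",
                                           low_hz = low, high_hz = high,
                                           order = order,
                                           zero_phase = zero_phase),
                             settle_s = settle_ms / 1000))),
    class = "mea_recording"
  )
}
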