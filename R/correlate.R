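#' Bin spike trains into count vectors
#'
#' Counts spikes per half-open bin `[k*bin, (k+1)*bin)` from the recording
#' origin; all electrodes share the same bin grid. A spike exactly at the
#' recording end is counted in the last bin so that counts always sum to
#' the spike count.
#'
#' @param trains A `spike_trains` object.
#' @param bin_ms Bin width, ms (default 5).
#' @return A `binned_trains` object: `counts` (bins x electrodes matrix),
#'   `bin_ms`, `electrodes`, `duration_s`.
#' @export
bin_trains <- function(trains, bin_ms = 5) {
  stopifnot(bin_ms > 0)
  bin_s <- bin_ms / 1000
  n_bins <- max(1L, as.integer(ceiling(trains$duration_s / bin_s - 1e-9)))
  ids <- names(trains$trains)
  counts <- matrix(0L, nrow = n_bins, ncol = length(ids),
                   dimnames = list(NULL, ids))
  for (j in seq_along(ids)) {
    tt <- trains$trains[[j]]
    if (!length(tt)) next
    idx <- pmin(as.integer(floor(tt / bin_s)) + 1L, n_bins)
    counts[, j] <- tabulate(idx, nbins = n_bins)
  }
  structure(list(counts = counts, bin_ms = bin_ms, electrodes = ids,
                 duration_s = trains$duration_s),
            class = "binned_trains")
}

#' Lagged Pearson cross-correlation of two binned trains
#'
#' Pearson correlation coefficient of `x` against `y` shifted by each lag
#' in `[-max_lag_bins, +max_lag_bins]`, normalized over the overlapping
#' region of the shifted vectors. Positive lags pair `x[i]` with
#' `y[i + lag]`, i.e. a maximum at a positive lag means `x` leads `y`.
#' Lags whose overlap has zero variance (or fewer than two bins) are
#' defined as 0 and flagged.
#'
#' @param x,y Equal-length numeric count vectors.
#' @param max_lag_bins Maximum lag, in bins (default 5).
#' @return Numeric vector of coefficients named by lag, with attributes
#'   `lags` (integer vector) and `degenerate` (logical per lag).
#' @export
cross_correlate <- function(x, y, max_lag_bins = 5) {
  if (length(x) != length(y)) stop("length mismatch between binned trains")
  stopifnot(max_lag_bins >= 0)
  res <- cc_lags_cpp(as.numeric(x), as.numeric(y), as.integer(max_lag_bins))
  lags <- seq.int(-max_lag_bins, max_lag_bins)
  r <- stats::setNames(res$r, lags)
  attr(r, "lags") <- lags
  attr(r, "degenerate") <- as.logical(res$degenerate)
  r
}

# central-bin and maximum-bin extraction with the documented tie-break
# (smallest |lag| first, then the positive lag)
cc_extract <- function(r) {
  lags <- attr(r, "lags")
  ord <- order(-r, abs(lags), -lags)
  best <- ord[1]
  list(c0 = unname(r[lags == 0]), cmax = unname(r[best]),
       lag = lags[best])
}

#' Cross-correlation matrix of binned spike trains
#'
#' Symmetric matrix of lag-0 Pearson coefficients, rows and columns ordered
#' by microfluidic compartment (the layout's color-bar order) when a layout
#' is supplied. Electrodes with zero binned variance (silent) get zero
#' rows/columns and are flagged in the `silent` attribute; all other
#' diagonal entries are 1.
#'
#' @param binned A `binned_trains` object.
#' @param subset Electrode ids to include (default all).
#' @param layout Optional `electrode_layout` used for compartment ordering.
#' @return Correlation matrix with attributes `silent` and (if a layout is
#'   given) `compartment`.
#' @export
correlation_matrix <- function(binned, subset = NULL, layout = NULL) {
  ids <- binned$electrodes
  if (!is.null(subset)) ids <- ids[ids %in% subset]
  if (!length(ids)) stop("empty electrode subset")
  if (!is.null(layout)) {
    ord <- compartment_order(layout)
    ids <- ord[ord %in% ids]
  }
  m <- binned$counts[, ids, drop = FALSE]
  v <- apply(m, 2, stats::var)
  silent <- v == 0
  cc <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  if (any(!silent)) {
    cc[!silent, !silent] <- stats::cor(m[, !silent, drop = FALSE])
  }
  diag(cc)[silent] <- 0
  attr(cc, "silent") <- stats::setNames(silent, ids)
  if (!is.null(layout)) {
    attr(cc, "compartment") <-
      layout$electrodes$compartment[layout_lookup(layout, ids)]
  }
  cc
}

#' Surrogate significance of a pair's correlation
#'
#' Monte-Carlo p-values for the central-bin and maximum-bin coefficients of
#' one electrode pair against a jitter-surrogate null: the second train's
#' spike times are displaced uniformly by up to `jitter_ms` (wrapping at
#' the recording boundaries), which preserves firing rate and slow
#' structure while destroying millisecond-scale timing. p-values are
#' sequential Monte-Carlo estimates (early-stopped once `m_stop`
#' exceedances are seen, which cannot affect significance decisions at
#' levels below `m_stop / n_surrogates`).
#'
#' @param x_times,y_times Spike time vectors (s).
#' @param duration_s Recording duration (s).
#' @param bin_ms Bin width, ms.
#' @param max_lag_bins Maximum lag, bins.
#' @param n_surrogates Number of surrogates (default 1000).
#' @param jitter_ms Jitter half-width, ms (default 50).
#' @param seed Optional integer seed.
#' @param m_stop Early-stopping exceedance count (default 50).
#' @return List with `p_c0`, `p_cmax`, `observed` (c0, cmax, lag),
#'   `n_surrogates_used` and `undefined` (TRUE when either train has fewer
#'   than 2 spikes, in which case the p-values are `NA`).
#' @export
significance_by_surrogates <- function(x_times, y_times, duration_s,
                                       bin_ms = 5, max_lag_bins = 5,
                                       n_surrogates = 1000, jitter_ms = 50,
                                       seed = NULL, m_stop = 50) {
  stopifnot(n_surrogates >= 100)
  if (!is.null(seed)) set.seed(seed)
  if (length(x_times) < 2 || length(y_times) < 2) {
    return(list(p_c0 = NA_real_, p_cmax = NA_real_, observed = NULL,
                n_surrogates_used = 0L, undefined = TRUE))
  }
  bin_s <- bin_ms / 1000
  n_bins <- max(1L, as.integer(ceiling(duration_s / bin_s - 1e-9)))
  bin1 <- function(tt) tabulate(pmin(as.integer(floor(tt / bin_s)) + 1L, n_bins),
                                nbins = n_bins)
  xb <- as.numeric(bin1(x_times))
  yb <- as.numeric(bin1(y_times))
  r <- cross_correlate(xb, yb, max_lag_bins)
  obs <- cc_extract(r)
  sp <- surrogate_pvals_cpp(xb, as.numeric(y_times), bin_s, n_bins,
                            as.integer(max_lag_bins), jitter_ms / 1000,
                            duration_s, as.integer(n_surrogates),
                            as.integer(m_stop), obs$c0, obs$cmax)
  list(p_c0 = sp$p_c0, p_cmax = sp$p_cmax, observed = obs,
       n_surrogates_used = sp$n_surrogates_used, undefined = FALSE)
}

#' Pairwise correlation analysis of a spike-train set
#'
#' For every unordered pair of the selected electrodes: bins the trains,
#' extracts the central-bin coefficient `c0` and the maximum-bin
#' coefficient `cmax` with its signed delay (positive delay = `a` leads
#' `b`; ties broken toward the smallest |lag| then the positive lag), and
#' attaches a jitter-surrogate p-value for `cmax`. Pairs where either
#' train has fewer than 2 spikes are flagged `undefined` and never
#' significant. Swapping a pair's ordering negates the delay and preserves
#' the coefficients.
#'
#' @param trains A `spike_trains` object.
#' @param electrodes Electrode ids to analyse (default: all non-degenerate).
#' @param bin_ms,max_lag_bins,n_surrogates,jitter_ms,m_stop As in
#'   [significance_by_surrogates()].
#' @param alpha Significance level on `p_cmax` (default 0.01).
#' @param seed Integer seed for the surrogate draws.
#' @return A `correlation_result` data.frame: `a`, `b`, `c0`, `cmax`,
#'   `lag_bins`, `delay_ms`, `p`, `significant`, `undefined`, with
#'   `bin_ms`, `max_lag_bins` and `alpha` attributes.
#' @export
correlate_pairs <- function(trains, electrodes = NULL, bin_ms = 5,
                            max_lag_bins = 5, n_surrogates = 1000,
                            jitter_ms = 50, alpha = 0.01, seed = 1,
                            m_stop = 50) {
  info <- trains$info
  if (is.null(electrodes)) electrodes <- info$electrode[!info$degenerate]
  unknown <- setdiff(electrodes, info$electrode)
  if (length(unknown)) stop("unknown electrode id: ", paste(unknown, collapse = ", "))
  binned <- bin_trains(trains, bin_ms)
  set.seed(seed)
  n <- length(electrodes)
  res <- list()
  if (n >= 2) {
    cmb <- utils::combn(n, 2)
    bin_s <- bin_ms / 1000
    n_bins <- nrow(binned$counts)
    for (k in seq_len(ncol(cmb))) {
      a <- electrodes[cmb[1, k]]; b <- electrodes[cmb[2, k]]
      ta <- trains$trains[[a]]; tb <- trains$trains[[b]]
      if (length(ta) < 2 || length(tb) < 2) {
        res[[k]] <- data.frame(a = a, b = b, c0 = 0, cmax = 0,
                               lag_bins = NA_integer_, delay_ms = NA_real_,
                               p = NA_real_, significant = FALSE,
                               undefined = TRUE, stringsAsFactors = FALSE)
        next
      }
      xb <- as.numeric(binned$counts[, a])
      yb <- as.numeric(binned$counts[, b])
      r <- cross_correlate(xb, yb, max_lag_bins)
      ex <- cc_extract(r)
      sp <- surrogate_pvals_cpp(xb, as.numeric(tb), bin_s, n_bins,
                                as.integer(max_lag_bins), jitter_ms / 1000,
                                trains$duration_s, as.integer(n_surrogates),
                                as.integer(m_stop), ex$c0, ex$cmax)
      res[[k]] <- data.frame(a = a, b = b, c0 = ex$c0, cmax = ex$cmax,
                             lag_bins = ex$lag, delay_ms = ex$lag * bin_ms,
                             p = sp$p_cmax,
                             significant = sp$p_cmax <= alpha,
                             undefined = FALSE, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(res)) do.call(rbind, res) else {
    data.frame(a = character(0), b = character(0), c0 = numeric(0),
               cmax = numeric(0), lag_bins = integer(0),
               delay_ms = numeric(0), p = numeric(0),
               significant = logical(0), undefined = logical(0))
  }
  rownames(out) <- NULL
  ok <- !out$undefined
  stopifnot(all(out$cmax[ok] >= out$c0[ok] - 1e-12),
            all(abs(out$cmax[ok]) <= 1 + 1e-12),
            all(abs(out$c0[ok]) <= 1 + 1e-12))
  attr(out, "bin_ms") <- bin_ms
  attr(out, "max_lag_bins") <- max_lag_bins
  attr(out, "alpha") <- alpha
  class(out) <- c("correlation_result", "data.frame")
  out
}
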