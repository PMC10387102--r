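test_that("dead time suppresses the second of two close deflections", {
  fs <- 10000
  # baseline alternating +-2 uV -> unscaled median absolute deviation 2
  x <- rep(c(2, -2), 5000)
  x <- insert_bump(x, 4000, -15)
  x <- insert_bump(x, 4010, -15)  # 1 ms later
  tr <- detect_spikes(make_rec(x, fs), k_mad = 5, dead_time_ms = 3,
                      mad_type = "median")
  expect_equal(tr$info$polarity, -1L)
  expect_equal(tr$info$n_spikes, 1L)
  # second deflection accepted once the dead time has passed
  x2 <- rep(c(2, -2), 5000)
  x2 <- insert_bump(x2, 4000, -15)
  x2 <- insert_bump(x2, 4040, -15)  # 4 ms later
  tr2 <- detect_spikes(make_rec(x2, fs), mad_type = "median")
  expect_equal(tr2$info$n_spikes, 2L)
})

test_that("an all-zero trace is degenerate, not an error", {
  tr <- detect_spikes(make_rec(numeric(10000), 10000))
  expect_true(tr$info$degenerate)
  expect_length(tr$trains[[1]], 0)
  expect_false("ch1" %in% active_electrodes(tr))
})

test_that("polarity follows the first threshold crossing", {
  fs <- 10000
  x <- rep(c(2, -2), 5000)
  x <- insert_bump(x, 2000, 15)    # positive deflection first
  x <- insert_bump(x, 6000, -15)   # later negative one is ignored
  tr <- detect_spikes(make_rec(x, fs), mad_type = "median")
  expect_equal(tr$info$polarity, 1L)
  expect_equal(tr$info$n_spikes, 1L)
  expect_lt(abs(tr$trains[[1]] - 0.2), 1e-3)
})

test_that("detection matches the per-sample reference on random traces", {
  set.seed(7)
  fs <- 10000
  for (i in 1:10) {
    x <- rnorm(10000)
    for (k in sample(500:9500, 8)) x <- insert_bump(x, k, sample(c(-1, 1), 1) * runif(1, 8, 20))
    for (mt in c("normalized", "median", "mean")) {
      tr <- detect_spikes(make_rec(x, fs), mad_type = mt)
      expect_identical(tr$trains[[1]], ref_detect(x, fs, mad_type = mt))
    }
  }
})

test_that("raising the threshold never increases the spike count", {
  set.seed(8)
  fs <- 10000
  for (i in 1:5) {
    x <- rnorm(20000)
    for (k in sample(500:19500, 15)) x <- insert_bump(x, k, -runif(1, 4, 25))
    rec <- make_rec(x, fs)
    counts <- vapply(c(3, 4, 5, 6, 8),
                     function(k) detect_spikes(rec, k_mad = k)$info$n_spikes, 0L)
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("the dead-time invariant holds on every output", {
  sim <- scenario_dual_compartment(seed = 9, duration_s = 5)
  filt <- bandpass(rereference(sim$recording, sim$layout))
  tr <- detect_spikes(filt)
  for (t in tr$trains) {
    if (length(t) > 1) expect_gte(min(diff(t)), 3e-3 - 1e-9)
  }
})

test_that("the active gate is inclusive at the rate threshold", {
  tr <- make_trains(list(a = seq(0, 40, 10), b = seq(0, 30, 10),
                         c = numeric(0)), duration_s = 50)
  # 5 spikes / 50 s = 0.1 Hz -> active; 4 -> inactive; empty -> inactive
  expect_identical(active_electrodes(tr, 0.1), "a")
})

test_that("mean firing rate averages correctly and flags empty subsets", {
  tr <- make_trains(list(a = seq(0, 49.6, length.out = 125),
                         b = seq(0, 49, 1), d = seq(0, 49.9, length.out = 150)),
                    duration_s = 50)
  expect_equal(mean_firing_rate(tr, "a")$mean_rate_hz, 2.5)
  expect_equal(mean_firing_rate(tr, c("b", "d"))$mean_rate_hz, 2)
  expect_warning(res <- mean_firing_rate(tr, character(0)), "empty")
  expect_true(is.na(res$mean_rate_hz))
  expect_error(mean_firing_rate(tr, "zz"), "unknown electrode")
})

test_that("cutout amplitude CV separates stereotyped and mixed waveforms", {
  lay <- build_layout(config_2x2())
  # one axonal-like source, tight amplitude jitter
  ax <- source_spec("A", "21", baseline_rate = 6, amp_uV = -100,
                    amplitude_jitter = 0.02)
  # three somatic-like units of distinct amplitude on one electrode
  mix <- list(source_spec("M1", "11", baseline_rate = 3, amp_uV = -40),
              source_spec("M2", "11", baseline_rate = 3, amp_uV = -80),
              source_spec("M3", "11", baseline_rate = 3, amp_uV = -120))
  sim <- simulate_recording(lay, c(list(ax), mix), noise_sd_uV = 2,
                            duration_s = 20, seed = 4)
  filt <- bandpass(rereference(sim$recording, lay))
  tr <- detect_spikes(filt)
  cuts <- extract_cutouts(filt, tr)
  st <- cuts$stats
  expect_lt(st$amp_cv[st$electrode == "21"], 0.05)
  expect_gt(st$amp_cv[st$electrode == "11"], 0.2)
  # cutouts share length and counts match (minus boundary-clipped)
  w <- cuts$cutouts[["21"]]
  expect_equal(ncol(w), 31)  # 1 ms pre + 2 ms post at 10 kHz
  expect_equal(nrow(w) + st$n_clipped[st$electrode == "21"],
               tr$info$n_spikes[tr$info$electrode == "21"])
})

test_that("a single spike has zero amplitude CV", {
  fs <- 10000
  x <- rep(c(2, -2), 5000)
  x <- insert_bump(x, 5000, -20)
  tr <- detect_spikes(make_rec(x, fs), mad_type = "median")
  cuts <- extract_cutouts(make_rec(x, fs), tr)
  expect_equal(cuts$stats$amp_cv, 0)
  expect_equal(cuts$stats$shape_dispersion, 0)
})

test_that("simulated somatic rates in the physiological range are recovered", {
  lay <- build_layout(config_2x2())
  srcs <- list(source_spec("A", "11", baseline_rate = 0.9, amp_uV = -60),
               source_spec("B", "12", baseline_rate = 2.5, amp_uV = -60))
  sim <- simulate_recording(lay, srcs, noise_sd_uV = 3, duration_s = 50,
                            seed = 6)
  filt <- bandpass(rereference(sim$recording, lay))
  tr <- detect_spikes(filt)
  mr <- mean_firing_rate(tr, c("11", "12"))$mean_rate_hz
  truth <- mean(sim$truth$electrode_rates$rate_hz[
    sim$truth$electrode_rates$electrode %in% c("11", "12")])
  expect_lt(abs(mr - truth) / truth, 0.1)
})
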