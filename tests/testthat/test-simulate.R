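lay2 <- build_layout(config_2x2())

test_that("noise-only simulation has the requested per-channel s.d.", {
  sim <- simulate_recording(lay2, noise_sd_uV = 2, duration_s = 10,
                            sampling_rate = 10000, seed = 1)
  sds <- apply(sim$recording$traces, 2, sd)
  expect_true(all(abs(sds - 2) / 2 < 0.05))
  expect_equal(nrow(sim$truth$events), 0L)
  expect_equal(nrow(sim$truth$edges), 0L)
})

test_that("a 5 Hz Poisson source emits ~250 events in 50 s", {
  src <- source_spec("P", "11", baseline_rate = 5)
  sim <- simulate_recording(lay2, list(src), noise_sd_uV = 0,
                            duration_s = 50, seed = 7)
  n <- length(sim$truth$source_events$P)
  expect_true(abs(n - 250) <= 3 * sqrt(250))
})

test_that("propagated events are source events shifted by the edge delay", {
  src <- source_spec("A", "11", baseline_rate = 4)
  ed <- list(propagation_edge("A", "21", delay_ms = 10, transmission_prob = 1))
  sim <- simulate_recording(lay2, list(src), ed, noise_sd_uV = 0,
                            duration_s = 10, seed = 3)
  ev <- sim$truth$events
  t_src <- ev$time_s[ev$electrode == "11"]
  t_tgt <- ev$time_s[ev$electrode == "21"]
  # every target event is a source event + 10 ms (a few may fall off the end)
  expect_true(length(t_tgt) >= length(t_src) - 1)
  expect_true(all(vapply(t_tgt, function(t) any(abs(t_src + 0.01 - t) < 1e-12),
                         TRUE)))
})

test_that("event superposition is exactly linear across sources", {
  s1 <- source_spec("A", "11", baseline_rate = 3, amp_uV = -60)
  s2 <- source_spec("B", "12", baseline_rate = 2, burst_rate = 0.3,
                    amp_uV = -80)
  ed <- list(propagation_edge("A", "21", 10, 0.8, 1.5))
  m <- simulate_recording(lay2, list(s1, s2), ed, noise_sd_uV = 0,
                          duration_s = 5, seed = 3)
  m1 <- simulate_recording(lay2, list(s1), ed, noise_sd_uV = 0,
                           duration_s = 5, seed = 3)
  m2 <- simulate_recording(lay2, list(s2), list(), noise_sd_uV = 0,
                           duration_s = 5, seed = 3)
  expect_identical(m$recording$traces,
                   m1$recording$traces + m2$recording$traces)
})

test_that("identical seeds give byte-identical recordings", {
  a <- scenario_dual_compartment(seed = 5, duration_s = 2)
  b <- scenario_dual_compartment(seed = 5, duration_s = 2)
  expect_identical(a$recording$traces, b$recording$traces)
  expect_identical(a$truth$events, b$truth$events)
  c <- scenario_dual_compartment(seed = 6, duration_s = 2)
  expect_false(identical(a$recording$traces, c$recording$traces))
})

test_that("empirical source rate converges to the specification", {
  for (seed in 1:3) {
    tt <- simulate_source_events(source_spec("R", "11", baseline_rate = 4),
                                 500, seed)
    expect_lt(abs(length(tt) / 500 - 4) / 4, 0.05)
  }
})

test_that("the dual-compartment scenario honours its stated structure", {
  sim <- scenario_dual_compartment(seed = 2, duration_s = 2)
  tr <- sim$truth
  # all true edge delays resolvable by 5 ms binning
  expect_true(all(tr$edges$delay_ms >= 1 & tr$edges$delay_ms <= 25))
  # programmed somatic partition: efferent soma has outgoing edges only,
  # afferents incoming only
  eff <- tr$programmed_roles$efferent
  aff <- tr$programmed_roles$afferent
  expect_true(all(eff %in% tr$edges$from_electrode))
  expect_false(any(eff %in% tr$edges$to_electrode))
  expect_true(all(aff %in% tr$edges$to_electrode))
  expect_false(any(aff %in% tr$edges$from_electrode))
  # somatic compartment membership of the programmed roles
  e <- sim$layout$electrodes
  expect_true(all(e$compartment[match(c(eff, aff), e$id)] == "somatic_chamber_A"))
  # every electrode-level event traces back to a source event
  ev <- tr$events
  dm <- sapply(tr$sources, function(s) s$id)
  expect_true(all(ev$source %in% dm))
})

test_that("unknown electrodes and invalid rates are rejected", {
  expect_error(simulate_recording(lay2, list(source_spec("X", "99"))),
               "unknown home electrode")
  src <- source_spec("A", "11")
  expect_error(
    simulate_recording(lay2, list(src),
                       list(propagation_edge("A", "99", 5))),
    "unknown electrode in edges")
  expect_error(source_spec("A", "11", baseline_rate = -1))
})

test_that("true_delayed_edges and true_zero_delay_pairs partition by delay", {
  sim <- scenario_dual_compartment(seed = 3, duration_s = 2)
  de <- true_delayed_edges(sim$truth)
  zp <- true_zero_delay_pairs(sim$truth)
  expect_true(all(de$delay_ms >= 5 & de$delay_ms <= 25))
  expect_true(all(zp$delay_ms <= 2.5))
  expect_false(any(edge_key(de) %in% edge_key(zp, "from", "to")))
})
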