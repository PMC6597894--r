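# Envelope computation, cycle anchoring/segmentation and valve-event search.

test_that("envelope is flat for a tone and peaks at burst centres", {
  expect_equal(compute_envelope(numeric(400), 1000), numeric(400))
  env <- compute_envelope(make_tone(300, 2), 1000, 25)
  expect_equal(mean(interior(env)), 1, tolerance = 0.05)
  expect_lt(stats::sd(interior(env)), 0.05)
  # Gaussian-windowed bursts: envelope maxima at the burst centres
  t <- seq(0, 2 - 1e-3, by = 1e-3)
  centers <- c(0.4, 1.0, 1.6)
  x <- numeric(length(t))
  for (tc in centers)
    x <- x + exp(-(t - tc)^2 / (2 * 0.01^2)) * sin(2 * pi * 250 * (t - tc))
  env <- compute_envelope(x, 1000, 25)
  for (tc in centers) {
    win <- which(abs(t - tc) < 0.1)
    expect_lt(abs(t[win[which.max(env[win])]] - tc), 0.005)
  }
  expect_error(compute_envelope(x, 1000, 600), "smooth_cutoff_hz")
})

fake_decomp <- function(centers, energies) {
  comps <- lapply(seq_along(centers), function(k) {
    structure(list(samples = sqrt(energies[k] / 100) * rep(1, 100),
                   center_freq_hz = centers[k], iteration = k,
                   energy_fraction = NA_real_, preset_id = NULL),
              class = "oscillatory_component")
  })
  structure(list(components = comps, residual = numeric(100), fs = 1000,
                 input = numeric(100), label = "fake", t0 = 0,
                 calibration = NULL),
            class = "swd_decomposition")
}

test_that("valve component selection prefers energetic high-frequency OCs", {
  expect_equal(select_valve_component(fake_decomp(c(20, 250), c(5, 3))), 2)
  expect_equal(select_valve_component(fake_decomp(c(150, 300), c(2, 4))), 2)
  expect_equal(select_valve_component(fake_decomp(c(150, 300), c(4, 2))), 1)
  # nothing above the cut-off: fall back to the highest centre
  expect_equal(select_valve_component(fake_decomp(c(20, 60), c(9, 1))), 2)
  expect_error(select_valve_component(fake_decomp(numeric(0), numeric(0))),
               "no components")
})

test_that("cycle anchors recover the beat schedule on clean recordings", {
  d <- generate_dus(synth_config(duration_s = 10, snr_db = Inf), seed = 3)
  env <- compute_envelope(d$truth$valve_track, 1000)
  anchors <- detect_cycle_anchors(env, 1000)
  truth_idx <- round(d$truth$anchors_s * 1000) + 1
  expect_equal(length(anchors), length(truth_idx))
  expect_lt(max(abs(anchors - truth_idx)), 10)
  # ECG-reference mode passes externally supplied peaks through untouched
  expect_identical(detect_cycle_anchors(env, 1000, r_peaks_idx = truth_idx),
                   as.integer(truth_idx))
  expect_error(detect_cycle_anchors(env, 1000, r_peaks_idx = c(5, 5, 9)),
               "strictly increasing")
  expect_error(detect_cycle_anchors(rep(1, 3000), 1000), "insufficient")
  expect_error(detect_cycle_anchors(env[1:500], 1000), "2 s")
})

test_that("segments tile the anchored span with the right RR", {
  segs <- segment_cycles(1000, c(1, 401, 801), fs = 1000)
  expect_equal(nrow(segs), 2)
  expect_equal(segs$rr_ms, c(400, 400))
  expect_equal(segment_cycles(1000, c(10, 500), fs = 1000)$rr_ms, 490)
  anchors <- c(1, 350, 820, 999)
  segs <- segment_cycles(1000, anchors, fs = 1000)
  expect_equal(sum(segs$end_idx - segs$start_idx),
               anchors[length(anchors)] - anchors[1])
  expect_error(segment_cycles(1000, c(100, 50), fs = 1000), "increasing")
  expect_error(segment_cycles(1000, 5, fs = 1000), "2 anchors")
})

test_that("segment normalization is an exact z-score with n-1 denominator", {
  expect_equal(normalize_segment(c(1, 2, 3)), c(-1, 0, 1))
  set.seed(9)
  v <- normalize_segment(rnorm(200, 5, 3))
  expect_equal(mean(v), 0, tolerance = 1e-12)
  expect_equal(stats::sd(v), 1, tolerance = 1e-12)
  expect_error(normalize_segment(c(5, 5, 5)), "degenerate")
  expect_error(normalize_segment(3), "too short")
})

# normalized envelope segment with Gaussian humps at given times (ms)
segment_with_bumps <- function(at_ms, rr_ms = 400, fs = 1000, amp = NULL) {
  t <- seq(0, rr_ms - 1) / 1000
  if (is.null(amp)) amp <- rep(1, length(at_ms))
  v <- numeric(length(t))
  for (k in seq_along(at_ms))
    v <- v + amp[k] * exp(-(t - at_ms[k] / 1000)^2 / (2 * 0.008^2))
  normalize_segment(v)
}

test_that("valve events are located inside their windows", {
  seg <- segment_with_bumps(c(25, 75, 200, 290))
  ev <- detect_valve_events(seg, fs = 1000, rr_ms = 400)
  expect_false(anyNA(ev[1, 1:4]))
  expect_equal(ev$t_mc_ms, 25, tolerance = 5)
  expect_equal(ev$t_ao_ms, 75, tolerance = 5)
  expect_equal(ev$t_ac_ms, 200, tolerance = 5)
  expect_equal(ev$t_mo_ms, 290, tolerance = 5)
  expect_true(ev$ordered)
})

test_that("a lone aortic-opening burst leaves the other events missing", {
  seg <- segment_with_bumps(75)
  ev <- detect_valve_events(seg, fs = 1000, rr_ms = 400)
  expect_false(is.na(ev$t_ao_ms))
  expect_true(all(is.na(c(ev$t_mc_ms, ev$t_ac_ms, ev$t_mo_ms))))
  expect_true(is.na(ev$ordered))
})

test_that("windows clip to short cycles and detection still runs", {
  seg <- segment_with_bumps(c(25, 75, 200, 280), rr_ms = 300)
  ev <- detect_valve_events(seg, fs = 1000, rr_ms = 300)
  expect_equal(ev$t_mo_ms, 280, tolerance = 5)   # window clipped to [260,300)
  # every reported event lies inside its (clipped) window
  w <- default_event_windows()
  for (e in c("mc", "ao", "ac", "mo")) {
    t_ev <- ev[[paste0("t_", e, "_ms")]]
    if (!is.na(t_ev)) {
      expect_gte(t_ev, w[[e]][1])
      expect_lt(t_ev, min(w[[e]][2], 300))
    }
  }
})

test_that("the pipeline enforces minimum duration and event ordering", {
  expect_error(run_event_pipeline(
    signal_record(make_tone(100, 2), 1000)), "5 s")
  d <- generate_dus(synth_config(duration_s = 15, snr_db = 20), seed = 11)
  ev <- run_event_pipeline(d$signal)
  expect_s3_class(ev, "valve_events")
  expect_gt(nrow(ev$events), 20)
  ok <- ev$events$ordered
  expect_true(all(ok[!is.na(ok)]))
  w <- default_event_windows()
  for (e in c("mc", "ao", "ac", "mo")) {
    t_ev <- ev$events[[paste0("t_", e, "_ms")]]
    t_ev <- t_ev[!is.na(t_ev)]
    expect_true(all(t_ev >= w[[e]][1] & t_ev < w[[e]][2]))
  }
  expect_true(all(ev$events$rr_ms >= 250 & ev$events$rr_ms <= 700))
  # the selected component tracks the generated valve bursts best
  cors <- vapply(ev$decomposition$components, function(c)
    abs(cor(c$samples, d$truth$valve_track)), 0)
  expect_equal(ev$component, which.max(cors))
})
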