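# Synthetic Doppler generator: schedules, waveforms, ground truth, cohorts.

test_that("beat schedules are regular, correctly counted and deterministic", {
  cfg <- synth_config(duration_s = 4, rr_mean_ms = 400, rr_sd_ms = 0)
  expect_equal(generate_beat_schedule(cfg), seq(0, 3.6, by = 0.4))
  cfg60 <- synth_config(duration_s = 60, rr_mean_ms = 420, rr_sd_ms = 10)
  n <- length(generate_beat_schedule(cfg60, seed = 21))
  expect_lte(abs(n - floor(60000 / 420)), 2)
  expect_identical(generate_beat_schedule(cfg60, seed = 4),
                   generate_beat_schedule(cfg60, seed = 4))
  expect_error(synth_config(duration_s = 0.5), "two mean beats")
  expect_error(synth_config(event_offsets_ms = c(mc = 55, ao = 15,
                                                 ac = 195, mo = 270)),
               "ordered")
})

test_that("noiseless valve-track envelope peaks at the configured events", {
  cfg <- synth_config(duration_s = 2, snr_db = Inf, rr_sd_ms = 0,
                      event_offset_sd_ms = c(mc = 0, ao = 0, ac = 0, mo = 0))
  d <- generate_dus(cfg, seed = 1)
  env <- compute_envelope(d$truth$valve_track, cfg$fs)
  t_ms <- (seq_along(env) - 1)    # at 1 kHz one sample = 1 ms
  a0 <- d$truth$anchors_s[1] * 1000
  for (ev in c("mc", "ao", "ac", "mo")) {
    tc <- a0 + cfg$event_offsets_ms[[ev]]
    win <- which(abs(t_ms - tc) < 12)
    expect_lt(abs(t_ms[win[which.max(env[win])]] - tc), 2)
  }
})

test_that("the realised SNR matches the request and truth is self-consistent", {
  d <- generate_dus(synth_config(duration_s = 10, snr_db = 10), seed = 2)
  expect_lt(abs(d$truth$snr_db_realised - 10), 0.5)
  expect_equal(d$signal$samples,
               d$truth$noiseless + d$truth$noise, tolerance = 1e-12)
  expect_equal(d$truth$noiseless,
               d$truth$valve_track + d$truth$wall_track, tolerance = 1e-12)
  iv <- d$truth$intervals
  expect_equal(iv$pep_ms, 25 + iv$ict_ms, tolerance = 1e-9)
  expect_equal(iv$sti_ms, iv$pep_ms + iv$vet_ms, tolerance = 1e-9)
  pink <- generate_dus(synth_config(duration_s = 5, snr_db = 5,
                                    noise_type = "pink"), seed = 2)
  expect_lt(abs(pink$truth$snr_db_realised - 5), 0.5)
})

test_that("amplitude scaling leaves estimated event times unchanged", {
  d <- generate_dus(synth_config(duration_s = 12, snr_db = 15), seed = 13)
  ev1 <- run_event_pipeline(d$signal)
  doubled <- signal_record(2 * d$signal$samples, d$signal$fs)
  ev2 <- run_event_pipeline(doubled)
  expect_identical(ev1$events[c("t_mc_ms", "t_ao_ms", "t_ac_ms", "t_mo_ms")],
                   ev2$events[c("t_mc_ms", "t_ao_ms", "t_ac_ms", "t_mo_ms")])
})

test_that("the ECG surrogate puts its R peaks exactly on the schedule", {
  cfg <- synth_config(duration_s = 6)
  sched <- generate_beat_schedule(cfg, seed = 5)
  fecg <- generate_fecg(sched, cfg)
  sched_idx <- round(sched * cfg$fs) + 1
  # R-peak detection: tallest sample within +/- 100 ms of each beat
  for (i in seq_along(sched_idx)) {
    win <- max(1, sched_idx[i] - 100):min(length(fecg$samples),
                                          sched_idx[i] + 100)
    expect_equal(win[which.max(fecg$samples[win])], sched_idx[i])
  }
  expect_error(generate_fecg(numeric(0), cfg), "empty")
  # peak count is threshold-independent over a 10x range
  counts <- vapply(c(0.05, 0.1, 0.2, 0.5), function(th) {
    x <- fecg$samples
    pk <- which(x > th * max(x))
    pk <- pk[x[pk] >= x[pmax(pk - 1, 1)] & x[pk] >= x[pmin(pk + 1,
                                                           length(x))]]
    sum(diff(c(-1000, pk)) > 100)
  }, 0)
  expect_true(all(counts == length(sched)))
})

test_that("cohort generation emits every configured subject with truth", {
  spec <- default_cohort_spec(duration_s = 5, snr_db = 20)
  for (g in seq_along(spec)) spec[[g]]$n <- c(2, 2, 2)[g]
  coh <- generate_cohort(spec, seed = 6)
  expect_length(coh, 6)
  expect_equal(vapply(coh, function(s) s$group, ""),
               rep(c("early", "mid", "late"), each = 2))
  expect_s3_class(coh[[1]]$dus, "synthetic_dus")
  expect_true(all(diff(coh[[1]]$offset_mean_ms) > 0))
  # full-size cohort structure: 16/21/29 subjects
  spec66 <- default_cohort_spec(duration_s = 3, snr_db = 20)
  coh66 <- generate_cohort(spec66, seed = 6)
  expect_length(coh66, 66)
  expect_error(generate_cohort(list(list(n = 1)), seed = 1))
})

test_that("interval cohort simulation matches the reference layout", {
  coh <- simulate_cohort_intervals(seed = 77)
  expect_equal(nrow(coh), 66)
  expect_equal(unname(table(coh$group)[c("early", "mid", "late")]),
               c(16L, 21L, 29L), ignore_attr = TRUE)
  expect_identical(simulate_cohort_intervals(seed = 77), coh)
})
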