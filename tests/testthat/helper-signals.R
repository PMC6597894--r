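# shared fixtures: tones and small synthetic recordings built in code

make_tone <- function(freq_hz, duration_s = 2, fs = 1000, amp = 1) {
  t <- seq(0, duration_s - 1 / fs, by = 1 / fs)
  amp * sin(2 * pi * freq_hz * t)
}

# interior portion of a vector (both transients dropped)
interior <- function(x, frac = 0.2) {
  n <- length(x)
  x[seq.int(floor(n * frac) + 1L, ceiling(n * (1 - frac)))]
}

# default 1 kHz calibration (shipped table; cached by the package)
test_cal <- function() default_calibration(1000)

# match estimated beats to the nearest true anchors; returns per-event
# absolute timing errors (ms) and the all-four-events indicator
timing_errors <- function(events, truth) {
  mi <- vapply(events$anchor_time_s,
               function(a) which.min(abs(truth$anchors_s - a)), 0L)
  errs <- lapply(c("mc", "ao", "ac", "mo"), function(e) {
    col <- paste0("t_", e, "_ms")
    abs(events$anchor_time_s * 1000 + events[[col]] -
        truth$event_times_s[[col]][mi] * 1000)
  })
  names(errs) <- c("mc", "ao", "ac", "mo")
  all4 <- stats::complete.cases(
    events[c("t_mc_ms", "t_ao_ms", "t_ac_ms", "t_mo_ms")])
  list(errors = errs, all4 = all4, match = mi)
}
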