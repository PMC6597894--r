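# Synthetic Doppler ultrasound generator: quasi-periodic beats carrying four
# Gaussian-windowed high-frequency valve bursts, a beat-modulated
# low-frequency wall-motion tone, and additive noise at a requested SNR,
# with full ground truth (beat schedule, jittered event times, intervals).

# evaluate expr under a temporary RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Synthetic Doppler configuration
#'
#' Defaults emulate a 1-minute fetal Doppler recording at 1 kHz: RR around
#' 420 +/- 10 ms, valve bursts at 15/55/195/270 ms after the beat anchor
#' (mitral closing, aortic opening, aortic closing, mitral opening) with
#' beat-to-beat jitter of 3/4/5/4 ms, 250 Hz burst carriers in a Gaussian
#' window of 15 ms full width at half maximum (a click a few tens of ms
#' long), systolic events louder than diastolic ones, a 30 Hz
#' wall-motion tone amplitude-modulated at the beat rate, and white noise at
#' 10 dB SNR.
#'
#' @param duration_s Signal duration in seconds.
#' @param fs Sampling rate in Hz.
#' @param rr_mean_ms,rr_sd_ms Beat-to-beat RR distribution (normal, clipped
#'   to the physiologic range 250-700 ms).
#' @param event_offsets_ms Named means (mc, ao, ac, mo) of the event offsets
#'   from the beat anchor, in ms.
#' @param event_offset_sd_ms Beat-to-beat jitter SDs of the four offsets.
#' @param event_amplitude Relative burst amplitudes of the four events.
#' @param burst_freq_hz Burst carrier frequency per event (Hz).
#' @param burst_width_ms Burst width (full width at half maximum of the
#'   Gaussian window) in ms; the Gaussian SD is `burst_width_ms / 2.355`.
#' @param wall_freq_hz,wall_amplitude Wall-motion tone frequency/amplitude.
#' @param snr_db Signal-to-noise ratio in dB against the noiseless mixture;
#'   `Inf` disables noise.
#' @param noise_type `"white"` or `"pink"`.
#' @param seed Default RNG seed for the generators.
#' @param edt_ms Electromechanical delay used for ground-truth intervals.
#' @return A `synth_config` list.
#' @export
synth_config <- function(duration_s = 60, fs = 1000,
                         rr_mean_ms = 420, rr_sd_ms = 10,
                         event_offsets_ms = c(mc = 15, ao = 55,
                                              ac = 195, mo = 270),
                         event_offset_sd_ms = c(mc = 3, ao = 4,
                                                ac = 5, mo = 4),
                         event_amplitude = c(mc = 1, ao = 0.85,
                                             ac = 0.7, mo = 0.6),
                         burst_freq_hz = c(mc = 250, ao = 250,
                                           ac = 250, mo = 250),
                         burst_width_ms = 15,
                         wall_freq_hz = 30, wall_amplitude = 0.5,
                         snr_db = 10, noise_type = c("white", "pink"),
                         seed = 1, edt_ms = 25) {
  noise_type <- match.arg(noise_type)
  ev <- c("mc", "ao", "ac", "mo")
  event_offsets_ms <- event_offsets_ms[ev]
  event_offset_sd_ms <- event_offset_sd_ms[ev]
  event_amplitude <- event_amplitude[ev]
  burst_freq_hz <- burst_freq_hz[ev]
  if (anyNA(event_offsets_ms) || any(diff(event_offsets_ms) <= 0))
    stop("event offsets must be named mc, ao, ac, mo and ordered")
  if (rr_mean_ms <= event_offsets_ms["mo"] + burst_width_ms)
    stop("rr_mean_ms must exceed the mo offset plus the burst width")
  if (fs / 2 <= max(burst_freq_hz))
    stop("fs/2 must exceed the largest burst frequency")
  if (duration_s < 2 * rr_mean_ms / 1000)
    stop("duration must cover at least two mean beats")
  structure(list(duration_s = duration_s, fs = fs, rr_mean_ms = rr_mean_ms,
                 rr_sd_ms = rr_sd_ms, event_offsets_ms = event_offsets_ms,
                 event_offset_sd_ms = event_offset_sd_ms,
                 event_amplitude = event_amplitude,
                 burst_freq_hz = burst_freq_hz,
                 burst_width_ms = burst_width_ms,
                 wall_freq_hz = wall_freq_hz,
                 wall_amplitude = wall_amplitude, snr_db = snr_db,
                 noise_type = noise_type, seed = seed, edt_ms = edt_ms),
            class = "synth_config")
}

#' Generate a quasi-periodic beat schedule
#'
#' Anchors accumulate RR draws from a normal distribution clipped to the
#' physiologic range 250-700 ms, starting at time 0; generation is
#' deterministic given the seed.
#'
#' @param config A [synth_config()].
#' @param seed RNG seed; defaults to `config$seed`.
#' @return Numeric vector of anchor times in seconds, all `< duration_s`.
#' @export
generate_beat_schedule <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "synth_config"))
  with_seed(seed, {
    anchors <- 0
    repeat {
      rr <- min(700, max(250, stats::rnorm(1, config$rr_mean_ms,
                                           config$rr_sd_ms))) / 1000
      nxt <- anchors[length(anchors)] + rr
      if (nxt >= config$duration_s - 1e-9) break
      anchors <- c(anchors, nxt)
    }
    anchors
  })
}

gauss_burst <- function(t, tc, amp, f, sigma_s) {
  i0 <- max(1L, findInterval(tc - 4 * sigma_s, t))
  i1 <- min(length(t), findInterval(tc + 4 * sigma_s, t) + 1L)
  idx <- i0:i1
  tt <- t[idx] - tc
  list(idx = idx, y = amp * exp(-tt^2 / (2 * sigma_s^2)) * sin(2 * pi * f * tt))
}

#' Generate a synthetic Doppler recording with ground truth
#'
#' The waveform is the sum over beats and events of Gaussian-windowed tone
#' bursts at the jittered event times, a wall-motion tone amplitude-modulated
#' at the beat rate, and noise scaled to the requested SNR (measured against
#' the noiseless mixture). The ground truth records the beat schedule, every
#' jittered event time and the implied cardiac intervals.
#'
#' @param config A [synth_config()].
#' @param seed RNG seed; defaults to `config$seed`.
#' @return An object of class `synthetic_dus`: list with `signal`
#'   (a [signal_record()]) and `truth` (list: `anchors_s`, `events` -- data
#'   frame `beat_index, t_mc_ms, t_ao_ms, t_ac_ms, t_mo_ms, rr_ms` of true
#'   offsets (last beat's RR runs to the signal end), `event_times_s`,
#'   `intervals` from [compute_intervals()], `noiseless`, `valve_track`,
#'   `wall_track`, `noise`, `snr_db_realised`).
#' @export
generate_dus <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "synth_config"))
  anchors <- generate_beat_schedule(config, seed)
  fs <- config$fs
  t <- seq(0, config$duration_s - 1 / fs, by = 1 / fs)
  n_beats <- length(anchors)
  ev <- c("mc", "ao", "ac", "mo")
  offsets <- with_seed(seed + 1L, {
    m <- matrix(NA_real_, n_beats, 4, dimnames = list(NULL, ev))
    for (j in seq_along(ev))
      m[, j] <- stats::rnorm(n_beats, config$event_offsets_ms[j],
                             config$event_offset_sd_ms[j])
    m
  })
  valve <- numeric(length(t))
  sigma_s <- config$burst_width_ms / 2.355 / 1000
  for (b in seq_len(n_beats)) for (j in seq_along(ev)) {
    tc <- anchors[b] + offsets[b, j] / 1000
    if (tc < -4 * sigma_s || tc > config$duration_s + 4 * sigma_s) next
    g <- gauss_burst(t, tc, config$event_amplitude[j],
                     config$burst_freq_hz[j], sigma_s)
    valve[g$idx] <- valve[g$idx] + g$y
  }
  # wall motion: low-frequency tone, amplitude modulated over each beat
  bounds <- c(anchors, config$duration_s)
  seg <- findInterval(t, bounds, rightmost.closed = FALSE)
  seg[seg < 1L] <- 1L; seg[seg > n_beats] <- n_beats
  frac <- (t - bounds[seg]) / (bounds[seg + 1L] - bounds[seg])
  am <- 0.6 + 0.4 * sin(pi * pmin(pmax(frac, 0), 1))^2
  wall <- config$wall_amplitude * am * sin(2 * pi * config$wall_freq_hz * t)
  mix <- valve + wall
  noise <- numeric(length(t))
  snr_real <- Inf
  if (is.finite(config$snr_db)) {
    p_mix <- mean(mix^2)
    target <- p_mix / 10^(config$snr_db / 10)
    noise <- with_seed(seed + 2L, {
      w <- stats::rnorm(length(t))
      if (config$noise_type == "pink") {
        b <- c(0.049922035, -0.095993537, 0.050612699, -0.004408786)
        a <- c(1, -2.494956002, 2.017265875, -0.522189400)
        w <- as.numeric(signal::filter(b, a, w))
      }
      w * sqrt(target / mean(w^2))
    })
    snr_real <- 10 * log10(p_mix / mean(noise^2))
  }
  x <- mix + noise
  # normalise to audio range (peak 0.9) like a recorded waveform; the same
  # factor is applied to every stored track so truth stays self-consistent
  k <- 0.9 / max(abs(x))
  x <- k * x; mix <- k * mix; valve <- k * valve; wall <- k * wall
  noise <- k * noise
  rr_ms <- diff(c(anchors, config$duration_s)) * 1000
  events <- data.frame(beat_index = seq_len(n_beats),
                       t_mc_ms = offsets[, "mc"], t_ao_ms = offsets[, "ao"],
                       t_ac_ms = offsets[, "ac"], t_mo_ms = offsets[, "mo"],
                       rr_ms = rr_ms)
  event_times_s <- events
  for (j in c("t_mc_ms", "t_ao_ms", "t_ac_ms", "t_mo_ms"))
    event_times_s[[j]] <- anchors + events[[j]] / 1000
  truth <- list(anchors_s = anchors, events = events,
                event_times_s = event_times_s,
                intervals = compute_intervals(events, rr_ms = rr_ms,
                                              edt_ms = config$edt_ms),
                noiseless = mix, valve_track = valve, wall_track = wall,
                noise = noise, snr_db_realised = snr_real)
  structure(list(signal = signal_record(x, fs,
                                        label = sprintf("synthetic seed %s",
                                                        seed)),
                 truth = truth, config = config, seed = seed),
            class = "synthetic_dus")
}

#' @export
print.synthetic_dus <- function(x, ...) {
  cat(sprintf(
    "<synthetic_dus> %.3g s @ %g Hz, %d beats, SNR %.4g dB (seed %s)\n",
    x$config$duration_s, x$config$fs, length(x$truth$anchors_s),
    x$truth$snr_db_realised, x$seed))
  invisible(x)
}

#' Generate a synthetic fetal-ECG-like reference
#'
#' Places a QRS-shaped template (Gaussian R wave with small Q and S dips) at
#' every anchor of a beat schedule; the R-peak sample of each beat is exactly
#' the anchor sample. Used only to exercise ECG-reference mode.
#'
#' @param schedule_s Non-empty numeric vector of anchor times in seconds.
#' @param config A [synth_config()] (only `fs` and `duration_s` are used).
#' @return A [signal_record()].
#' @export
generate_fecg <- function(schedule_s, config) {
  stopifnot(inherits(config, "synth_config"))
  if (length(schedule_s) == 0L) stop("schedule is empty")
  fs <- config$fs
  n <- round(config$duration_s * fs)
  x <- numeric(n)
  t_rel <- seq(-0.04, 0.04, by = 1 / fs)
  template <- exp(-t_rel^2 / (2 * 0.004^2)) -
    0.15 * exp(-(t_rel + 0.012)^2 / (2 * 0.003^2)) -
    0.2 * exp(-(t_rel - 0.012)^2 / (2 * 0.003^2))
  half <- (length(template) - 1L) %/% 2L
  for (a in schedule_s) {
    c_idx <- round(a * fs) + 1L
    idx <- (c_idx - half):(c_idx + half)
    ok <- idx >= 1L & idx <= n
    x[idx[ok]] <- x[idx[ok]] + template[ok]
  }
  signal_record(x, fs, label = "synthetic fecg")
}

#' Default cohort specification
#'
#' Per-group sample sizes (16/21/29) and subject-level distributions of the
#' valve-event offsets, parameterised from [fetal_timing_reference()]:
#' subject mean offsets are drawn from a normal with the group mean and
#' between-subject sd `SE * sqrt(n)`.
#'
#' @param duration_s,snr_db Per-subject recording settings.
#' @return List of per-group specs (`label`, `n`, `offset_mean_ms`,
#'   `offset_sd_ms`, `rr_mean_ms`, `rr_between_sd_ms`, `duration_s`,
#'   `snr_db`).
#' @export
default_cohort_spec <- function(duration_s = 60, snr_db = 10) {
  ref <- fetal_timing_reference()
  lapply(c("early", "mid", "late"), function(g) {
    r <- function(m) ref[ref$measure == m & ref$group == g, ]
    n <- r("rr_ms")$n
    list(label = g, n = n,
         offset_mean_ms = c(mc = r("r_mc_ms")$mean, ao = r("r_ao_ms")$mean,
                            ac = r("r_ac_ms")$mean, mo = r("r_mo_ms")$mean),
         offset_sd_ms = c(mc = r("r_mc_ms")$se, ao = r("r_ao_ms")$se,
                          ac = r("r_ac_ms")$se,
                          mo = r("r_mo_ms")$se) * sqrt(n),
         rr_mean_ms = r("rr_ms")$mean,
         rr_between_sd_ms = r("rr_ms")$se * sqrt(n),
         duration_s = duration_s, snr_db = snr_db)
  })
}

#' Generate a cohort of synthetic subjects
#'
#' For every subject, subject-level event-offset means (and RR mean) are
#' drawn from the group distribution, then a recording is generated with
#' [generate_dus()]. Subject truth tables support testing of the statistics
#' stage without running the detection pipeline.
#'
#' @param group_specs As from [default_cohort_spec()].
#' @param seed RNG seed.
#' @return List of subjects, each a list with `subject_id`, `group`,
#'   `dus` (a `synthetic_dus`), `offset_mean_ms`.
#' @export
generate_cohort <- function(group_specs = default_cohort_spec(), seed = 1) {
  stopifnot(is.list(group_specs), length(group_specs) >= 1L)
  n_total <- sum(vapply(group_specs, function(g) g$n, 0))
  sub_seeds <- with_seed(seed, sample.int(2^31 - 2, n_total))
  subjects <- list()
  k <- 0L
  for (gs in group_specs) {
    stopifnot(!is.null(gs$label), gs$n >= 1L)
    for (i in seq_len(gs$n)) {
      k <- k + 1L
      draw <- with_seed(sub_seeds[k], {
        off <- stats::rnorm(4, gs$offset_mean_ms, gs$offset_sd_ms)
        names(off) <- c("mc", "ao", "ac", "mo")
        off <- sort(off)  # keep physiological ordering under extreme draws
        names(off) <- c("mc", "ao", "ac", "mo")
        rr <- max(320, stats::rnorm(1, gs$rr_mean_ms, gs$rr_between_sd_ms))
        list(off = off, rr = rr)
      })
      cfg <- synth_config(duration_s = gs$duration_s %||% 60,
                          rr_mean_ms = draw$rr,
                          event_offsets_ms = draw$off,
                          snr_db = gs$snr_db %||% 10,
                          seed = sub_seeds[k])
      subjects[[k]] <- list(subject_id = sprintf("%s_%02d", gs$label, i),
                            group = gs$label,
                            dus = generate_dus(cfg),
                            offset_mean_ms = draw$off)
    }
  }
  subjects
}

#' Simulate subject-level interval means for three age groups
#'
#' Draws per-subject mean intervals directly as normal variates with the
#' published group means and between-subject sd `SE * sqrt(n)` (the
#' dispersion implied by a standard error over `n` subjects). This is the
#' simulation surrogate used to study the power of the group comparisons.
#'
#' @param seed RNG seed.
#' @param measures Interval columns to simulate.
#' @param reference Reference table, default [fetal_timing_reference()].
#' @return Subject-summary data frame `subject_id, group, <measures>`.
#' @export
simulate_cohort_intervals <- function(seed,
                                      measures = c("sti_ms", "irt_ms",
                                                   "pep_ms"),
                                      reference = fetal_timing_reference()) {
  groups <- unique(reference$group)
  with_seed(seed, {
    rows <- list()
    for (g in groups) {
      n <- unique(reference$n[reference$group == g])
      df <- data.frame(subject_id = sprintf("%s_%02d", g, seq_len(n)),
                       group = g, stringsAsFactors = FALSE)
      for (m in measures) {
        r <- reference[reference$measure == m & reference$group == g, ]
        stopifnot(nrow(r) == 1L)
        df[[m]] <- stats::rnorm(n, r$mean, r$se * sqrt(r$n))
      }
      rows[[g]] <- df
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}
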