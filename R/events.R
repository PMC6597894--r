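# Cardiac event detection: valve-component envelope, per-beat cycle anchors,
# cycle segmentation/normalization, and localisation of the four valve events
# (Mc, Ao, Ac, Mo) inside physiological search windows.

#' Default valve-event search windows
#'
#' Search windows in ms relative to the beat anchor (R-peak or surrogate):
#' mitral closing 0-50, aortic opening 50-100, aortic closing 140-260,
#' mitral opening 260-330. Windows are treated as half-open `[start, end)`.
#'
#' @return Named list of two-element numeric vectors (`mc`, `ao`, `ac`,
#'   `mo`).
#' @export
default_event_windows <- function() {
  list(mc = c(0, 50), ao = c(50, 100), ac = c(140, 260), mo = c(260, 330))
}

validate_windows <- function(windows) {
  stopifnot(all(c("mc", "ao", "ac", "mo") %in% names(windows)))
  for (w in windows[c("mc", "ao", "ac", "mo")]) {
    if (length(w) != 2L || !all(is.finite(w)) || w[1] >= w[2])
      stop("each event window must satisfy start < end")
  }
  windows
}

#' Amplitude envelope of an oscillatory component
#'
#' Rectifies (absolute value), low-pass smooths with a zero-phase 4th-order
#' Butterworth filter at `smooth_cutoff_hz`, scales by pi/2 so that a pure
#' tone's envelope equals its amplitude (the mean of a rectified unit
#' sinusoid is 2/pi), and clips filter-induced negative excursions to 0.
#'
#' @param component Numeric vector or `oscillatory_component`.
#' @param fs Sampling rate in Hz.
#' @param smooth_cutoff_hz Low-pass cut-off in (0, fs/2).
#' @return Non-negative numeric vector, same length as the input.
#' @export
compute_envelope <- function(component, fs, smooth_cutoff_hz = 25) {
  x <- if (inherits(component, "oscillatory_component")) component$samples
       else as.numeric(component)
  if (smooth_cutoff_hz <= 0 || smooth_cutoff_hz >= fs / 2)
    stop("smooth_cutoff_hz must lie in (0, fs/2)")
  bf <- signal::butter(4, smooth_cutoff_hz / (fs / 2), type = "low")
  env <- signal::filtfilt(bf, abs(x)) * (pi / 2)
  pmax(env, 0)
}

#' Select the valve-motion component of a decomposition
#'
#' Valve clicks live in the high-frequency band of Doppler audio, wall
#' motion in the low band. Returns the index of the highest-energy component
#' whose centre frequency is at least `min_freq_hz`; if none qualifies, the
#' component with the highest centre frequency.
#'
#' @param decomp A `swd_decomposition`.
#' @param min_freq_hz Minimum centre frequency in Hz to qualify.
#' @return Integer component index.
#' @export
select_valve_component <- function(decomp, min_freq_hz = 100) {
  stopifnot(inherits(decomp, "swd_decomposition"))
  if (length(decomp$components) == 0L)
    stop("decomposition has no components")
  centers <- vapply(decomp$components, function(c) c$center_freq_hz, 0)
  energies <- vapply(decomp$components,
                     function(c) sum(c$samples^2), 0)
  ok <- !is.na(centers) & centers >= min_freq_hz
  if (any(ok)) {
    idx <- which(ok)
    idx[which.max(energies[idx])]
  } else {
    if (all(is.na(centers))) stop("no component has a defined frequency")
    which.max(centers)
  }
}

#' Detect per-beat cycle anchors from an envelope
#'
#' Finds the systolic envelope burst of each beat and anchors the cycle just
#' before its onset: local maxima above `median + threshold_k * MAD` with a
#' minimum separation of `min_rr_ms` are accepted greedily by height; each
#' accepted peak is then replaced by the earliest comparable peak
#' (>= `cluster_rel` of its height within `cluster_ms` before it), so the
#' anchor locks onto the first click of the S1 complex (mitral closure) even
#' when a later click is marginally taller; finally the peak is shifted to
#' the leading 50%-height crossing of its burst and advanced by
#' `anchor_lead_ms`. Mitral closure follows the R wave by roughly the
#' electromechanical delay, so the led burst onset approximates the R-peak.
#' When `r_peaks_idx` is supplied (ECG-reference mode) it is validated for
#' strict monotonicity and returned unchanged.
#'
#' @param envelope Non-negative numeric vector (valve-component envelope).
#' @param fs Sampling rate in Hz.
#' @param min_rr_ms Minimum beat separation in ms (250 ms caps the fetal
#'   heart rate at 240 bpm).
#' @param threshold_k MAD multiplier of the peak acceptance threshold.
#' @param r_peaks_idx Optional externally supplied R-peak sample indices
#'   (1-based).
#' @param max_edge_ms Furthest the leading-edge search walks left of a peak.
#' @param cluster_ms Look-back span for the cluster-onset rule.
#' @param cluster_rel Relative height an earlier peak must reach to be
#'   preferred as the cluster onset.
#' @param anchor_lead_ms Fixed lead subtracted from the burst onset so the
#'   anchor approximates the R wave (electromechanical delay minus envelope
#'   rise time).
#' @return Strictly increasing integer vector of anchor sample indices.
#' @export
detect_cycle_anchors <- function(envelope, fs, min_rr_ms = 250,
                                 threshold_k = 3, r_peaks_idx = NULL,
                                 max_edge_ms = 150, cluster_ms = 100,
                                 cluster_rel = 0.6, anchor_lead_ms = 8) {
  if (!is.null(r_peaks_idx)) {
    r_peaks_idx <- as.integer(r_peaks_idx)
    if (any(diff(r_peaks_idx) <= 0))
      stop("supplied R-peaks must be strictly increasing")
    return(r_peaks_idx)
  }
  env <- as.numeric(envelope)
  if (any(env < 0)) stop("envelope must be non-negative")
  if (length(env) / fs < 2) stop("envelope must cover at least 2 s")
  thr <- stats::median(env) + threshold_k * stats::mad(env)
  n <- length(env)
  cand <- which(env > thr)
  cand <- cand[cand > 1L & cand < n]
  cand <- cand[env[cand] > env[cand - 1L] & env[cand] >= env[cand + 1L]]
  if (length(cand) == 0L) stop("insufficient beats (no envelope bursts)")
  min_sep <- round(min_rr_ms / 1000 * fs)
  cand <- cand[order(env[cand], decreasing = TRUE)]
  keep <- integer(0)
  for (p in cand)
    if (all(abs(keep - p) >= min_sep)) keep <- c(keep, p)
  keep <- sort(keep)
  # a diastolic click at the very end of the recording has no following
  # systolic burst to suppress it; require accepted peaks to reach a
  # consistent systolic height
  keep <- keep[env[keep] >= 0.7 * stats::median(env[keep])]
  if (length(keep) < 2L) stop("insufficient beats")
  # cluster-onset rule: prefer the earliest comparable candidate peak so the
  # anchor tracks the first click of the systolic complex
  cl_back <- as.integer(round(cluster_ms / 1000 * fs))
  cand_sorted <- sort(cand)
  keep <- vapply(keep, function(p) {
    earlier <- cand_sorted[cand_sorted < p & cand_sorted >= p - cl_back &
                           env[cand_sorted] >= cluster_rel * env[p]]
    if (length(earlier)) earlier[1L] else p
  }, 0L)
  max_back <- as.integer(round(max_edge_ms / 1000 * fs))
  lead <- as.integer(round(anchor_lead_ms / 1000 * fs))
  anchors <- vapply(keep, function(p) {
    half <- env[p] / 2
    j <- p
    while (j > 1L && env[j - 1L] >= half && (p - j) < max_back) j <- j - 1L
    max(1L, j - lead)
  }, 0L)
  anchors <- unique(anchors)
  if (length(anchors) < 2L) stop("insufficient beats")
  anchors
}

#' Segment a signal into cardiac cycles
#'
#' `K` anchors yield `K - 1` half-open segments `[a_k, a_{k+1})`; samples
#' before the first and after the last anchor are discarded.
#'
#' @param signal_len Signal length in samples.
#' @param anchors Strictly increasing anchor sample indices (1-based).
#' @param fs Sampling rate in Hz (for `rr_ms`).
#' @return Data frame with `start_idx`, `end_idx` (half-open, 1-based) and
#'   `rr_ms`.
#' @export
segment_cycles <- function(signal_len, anchors, fs) {
  anchors <- as.integer(anchors)
  if (length(anchors) < 2L) stop("need at least 2 anchors")
  if (any(diff(anchors) <= 0)) stop("anchors must be strictly increasing")
  if (any(anchors < 1L) || any(anchors > signal_len))
    stop("anchors out of range")
  k <- length(anchors)
  data.frame(start_idx = anchors[-k], end_idx = anchors[-1L],
             rr_ms = diff(anchors) * 1000 / fs)
}

#' Z-normalize a cycle segment
#'
#' Subtracts the mean and divides by the sample standard deviation
#' (`n - 1` denominator).
#'
#' @param values Numeric vector of length >= 2.
#' @return Numeric vector with mean 0 and sd 1.
#' @export
normalize_segment <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L) stop("segment too short")
  s <- stats::sd(values)
  if (!is.finite(s) || s == 0) stop("degenerate segment (zero variance)")
  (values - mean(values)) / s
}

#' Locate the four valve events inside one cycle
#'
#' For each search window (clipped to `[0, rr_ms)`), peaks of the normalized
#' envelope are located as +/- sign changes of its first difference; the
#' highest peak above `noise_floor` is reported (ties break toward the
#' earlier peak). A window with no qualifying peak yields a missing event --
#' missingness is data, not an error.
#'
#' @param segment Normalized envelope samples of one cycle (see
#'   [normalize_segment()]).
#' @param fs Sampling rate in Hz.
#' @param windows Event windows as from [default_event_windows()].
#' @param noise_floor Minimum peak height in normalized units.
#' @param rr_ms Cycle length in ms; defaults to the segment duration.
#' @return One-row data frame `t_mc_ms, t_ao_ms, t_ac_ms, t_mo_ms` (NA =
#'   missing) plus logical `ordered` (TRUE when all four events are present
#'   in physiological order Mc < Ao < Ac < Mo, NA when any is missing).
#' @export
detect_valve_events <- function(segment, fs, windows = default_event_windows(),
                                noise_floor = 0.5, rr_ms = NULL) {
  v <- as.numeric(segment)
  windows <- validate_windows(windows)
  if (is.null(rr_ms)) rr_ms <- length(v) * 1000 / fs
  n <- length(v)
  # interior peaks: rising then non-rising first difference
  d <- diff(v)
  pk <- which(d[-length(d)] > 0 & d[-1L] <= 0) + 1L
  t_pk <- (pk - 1L) * 1000 / fs
  out <- list()
  for (ev in c("mc", "ao", "ac", "mo")) {
    w <- windows[[ev]]
    w0 <- max(w[1], 0); w1 <- min(w[2], rr_ms)
    t_ev <- NA_real_
    if (w1 > w0) {
      sel <- which(t_pk >= w0 & t_pk < w1)
      if (length(sel)) {
        h <- v[pk[sel]]
        best <- sel[which.max(h)]   # which.max -> earliest on ties
        if (v[pk[best]] >= noise_floor) t_ev <- t_pk[best]
      }
    }
    out[[paste0("t_", ev, "_ms")]] <- t_ev
  }
  df <- as.data.frame(out)
  df$ordered <- if (anyNA(df[1, 1:4])) NA else
    (df$t_mc_ms < df$t_ao_ms && df$t_ao_ms < df$t_ac_ms &&
     df$t_ac_ms < df$t_mo_ms)
  df
}

#' Run the full valve-timing pipeline on one recording
#'
#' Chains [swarm_decompose()] -> [select_valve_component()] ->
#' [compute_envelope()] -> [detect_cycle_anchors()] (or supplied R-peaks) ->
#' [segment_cycles()] -> [normalize_segment()] -> [detect_valve_events()].
#' Beats whose RR falls outside `rr_range_ms` are discarded as segmentation
#' faults.
#'
#' @param signal A [signal_record()] of at least 5 s.
#' @param config A configuration list as from [default_config()]; the
#'   `swd` and `events` blocks are used.
#' @param r_peaks Optional numeric vector of R-peak times in seconds
#'   (ECG-reference mode).
#' @param decomposition Optionally, a precomputed `swd_decomposition` of
#'   `signal` (skips the decomposition stage).
#' @param verbose Log beat and missing-event counts to stderr.
#' @return An object of class `valve_events`: list with `events` (data frame
#'   `beat_index, anchor_time_s, rr_ms, t_mc_ms, t_ao_ms, t_ac_ms, t_mo_ms,
#'   ordered`), `anchors_idx`, `component` (selected index),
#'   `decomposition`, `envelope`, `fs`, `mode`.
#' @export
run_event_pipeline <- function(signal, config = default_config(),
                               r_peaks = NULL, decomposition = NULL,
                               verbose = FALSE) {
  stopifnot(is_signal_record(signal))
  if (length(signal$samples) / signal$fs < 5)
    stop("signal must be at least 5 s long")
  sc <- config$swd; ec <- config$events
  if (is.null(decomposition)) {
    cal <- if (!is.null(sc$calibration_file))
      read_calibration_csv(sc$calibration_file) else NULL
    decomposition <- swarm_decompose(
      signal, calibration = cal,
      residual_threshold = sc$residual_threshold %||% 0.01,
      max_components = sc$max_components %||% 8)
  }
  comp_idx <- select_valve_component(decomposition,
                                     ec$min_component_freq_hz %||% 100)
  env <- compute_envelope(decomposition$components[[comp_idx]]$samples,
                          signal$fs, ec$envelope_cutoff_hz %||% 25)
  mode <- if (is.null(r_peaks)) "auto-anchor" else "ecg-ref"
  r_idx <- if (is.null(r_peaks)) NULL
           else as.integer(round((r_peaks - signal$t0) * signal$fs)) + 1L
  if (!is.null(r_idx))
    r_idx <- r_idx[r_idx >= 1L & r_idx <= length(env)]
  anchors <- detect_cycle_anchors(env, signal$fs,
                                  min_rr_ms = ec$min_rr_ms %||% 250,
                                  threshold_k = ec$threshold_k %||% 3,
                                  r_peaks_idx = r_idx,
                                  anchor_lead_ms = ec$anchor_lead_ms %||% 8)
  segs <- segment_cycles(length(env), anchors, signal$fs)
  rr_range <- ec$rr_range_ms %||% c(250, 700)
  windows <- ec$windows %||% default_event_windows()
  rows <- vector("list", nrow(segs))
  for (k in seq_len(nrow(segs))) {
    if (segs$rr_ms[k] < rr_range[1] || segs$rr_ms[k] > rr_range[2]) next
    vals <- env[segs$start_idx[k]:(segs$end_idx[k] - 1L)]
    norm <- tryCatch(normalize_segment(vals), error = function(e) NULL)
    if (is.null(norm)) next
    ev <- detect_valve_events(norm, signal$fs, windows = windows,
                              noise_floor = ec$noise_floor %||% 0.5,
                              rr_ms = segs$rr_ms[k])
    ev <- cbind(data.frame(
      beat_index = k,
      anchor_time_s = signal$t0 + (segs$start_idx[k] - 1L) / signal$fs,
      rr_ms = segs$rr_ms[k]), ev)
    rows[[k]] <- ev
  }
  rows <- rows[!vapply(rows, is.null, TRUE)]
  events <- if (length(rows)) do.call(rbind, rows) else
    data.frame(beat_index = integer(), anchor_time_s = numeric(),
               rr_ms = numeric(), t_mc_ms = numeric(), t_ao_ms = numeric(),
               t_ac_ms = numeric(), t_mo_ms = numeric(), ordered = logical())
  rownames(events) <- NULL
  n_missing <- sum(is.na(as.matrix(
    events[c("t_mc_ms", "t_ao_ms", "t_ac_ms", "t_mo_ms")])))
  if (verbose)
    message(sprintf("events: %d beats, %d missing events (%s mode)",
                    nrow(events), n_missing, mode))
  structure(list(events = events, anchors_idx = anchors,
                 component = comp_idx, decomposition = decomposition,
                 envelope = env, fs = signal$fs, mode = mode,
                 n_missing = n_missing),
            class = "valve_events")
}

#' @export
print.valve_events <- function(x, ...) {
  cat(sprintf(
    "<valve_events> %d beats (%s mode), valve component #%d, %d missing events\n",
    nrow(x$events), x$mode, x$component, x$n_missing))
  if (nrow(x$events)) {
    df <- x$events
    for (j in c("rr_ms", "t_mc_ms", "t_ao_ms", "t_ac_ms", "t_mo_ms"))
      df[[j]] <- round(df[[j]], 1)
    print(utils::head(df, 8), row.names = FALSE)
    if (nrow(df) > 8) cat(sprintf("... %d more beats\n", nrow(df) - 8))
  }
  invisible(x)
}
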