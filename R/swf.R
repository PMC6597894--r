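# Swarm filtering (SwF): band-selective filtering via a swarm-prey hunting
# model. Each swarm member carries a position/velocity state updated sample by
# sample; the prey is the input sequence; the filter output is the swarm-mean
# position. A preset (SwF parameter set) determines the passband; presets are
# characterised empirically by calibrate_swf().

#' SwF parameter set
#'
#' Parameters of one swarm filter. The driving force pulls every member
#' toward the current prey sample (`drive_gain`) with finite agility
#' (`drag`); the cohesion force pulls members toward the swarm mean
#' (`cohesion_gain`) and switches to a short-range repulsion when two members
#' come closer than `repulsion_scale` (collision avoidance). `delta` is the
#' virtual time step of the swarm dynamics and controls its flexibility.
#'
#' @param delta Positive time-step / flexibility parameter.
#' @param drive_gain Positive prey-attraction coefficient.
#' @param cohesion_gain Non-negative member-cohesion coefficient.
#' @param drag Non-negative velocity-damping coefficient of the driving
#'   force; zero gives an undamped (marginally stable) swarm.
#' @param repulsion_scale Non-negative distance below which cohesion turns
#'   repulsive; 0 disables repulsion (the default force model is then linear).
#' @param n_members Swarm size (>= 2).
#' @param n_passes Consecutive SwF applications used when an oscillatory
#'   component is extracted.
#' @param id Optional preset identifier.
#' @return An object of class `swf_params`.
#' @seealso [swf_preset()] to place the passband at a target frequency.
#' @export
swf_params <- function(delta, drive_gain, cohesion_gain = 1, drag = 0.5,
                       repulsion_scale = 0, n_members = 20L, n_passes = 2L,
                       id = NULL) {
  if (!is.finite(delta) || delta <= 0) stop("delta must be > 0")
  if (!is.finite(drive_gain) || drive_gain <= 0)
    stop("drive_gain must be > 0")
  if (cohesion_gain < 0 || repulsion_scale < 0 || drag < 0)
    stop("cohesion_gain, drag and repulsion_scale must be >= 0")
  n_members <- as.integer(n_members)
  n_passes <- as.integer(n_passes)
  if (n_members < 2L) stop("n_members must be >= 2")
  if (n_passes < 1L) stop("n_passes must be >= 1")
  structure(list(delta = delta, drive_gain = drive_gain,
                 cohesion_gain = cohesion_gain, drag = drag,
                 repulsion_scale = repulsion_scale, n_members = n_members,
                 n_passes = n_passes, id = id),
            class = "swf_params")
}

#' @export
print.swf_params <- function(x, ...) {
  cat(sprintf(paste0("<swf_params%s> delta=%.4g drive=%.4g cohesion=%.3g ",
                     "drag=%.4g members=%d passes=%d\n"),
              if (is.null(x$id)) "" else paste0(" ", x$id),
              x$delta, x$drive_gain, x$cohesion_gain, x$drag,
              x$n_members, x$n_passes), ...)
  invisible(x)
}

#' Build a preset targeting a centre frequency
#'
#' Places the swarm-mean resonance of the filter near `center_hz` by choosing
#' `drive_gain` and `drag` for the given `delta`. The pole radius is set to
#' `1 - pi*center_hz/(q*fs)`, floored at `r_min`, so the relative bandwidth
#' is roughly constant (quality factor `q`). Above `0.35*fs` the floor is
#' raised to 0.9 so the resonance peak stays above the response's rise
#' toward Nyquist and the passband keeps an interior maximum. The realised
#' response is always measured, not trusted: see [calibrate_swf()].
#'
#' @param center_hz Target centre frequency in Hz, in (0, fs/2).
#' @param fs Sampling rate in Hz.
#' @param q Approximate quality factor of the resonance.
#' @param r_min Floor on the pole radius.
#' @param delta,n_members,n_passes,cohesion_gain,repulsion_scale Passed to
#'   [swf_params()].
#' @param id Preset identifier.
#' @return An `swf_params` object with attribute `target_hz`.
#' @export
swf_preset <- function(center_hz, fs, q = 1.5, r_min = 0.5, delta = 0.5,
                       n_members = 20L, n_passes = 2L, cohesion_gain = 1,
                       repulsion_scale = 0, id = NULL) {
  if (center_hz <= 0 || center_hz >= fs / 2)
    stop("center_hz must lie in (0, fs/2)")
  w0 <- 2 * pi * center_hz / fs
  r <- max(if (center_hz > 0.35 * fs) max(r_min, 0.9) else r_min,
           1 - pi * center_hz / (q * fs))
  drag <- (1 - r^2) / delta
  drive <- (1 + r^2 - 2 * r * cos(w0)) / delta^2
  # member deviations from the swarm mean obey a resonator with stiffness
  # drive + cohesion; keep it inside its stability region (stay below the
  # z = -1 boundary (2 + 2 r^2)/delta^2 with 50% margin) so cohesion never
  # destabilises a preset placed near Nyquist
  c_max <- 0.5 * ((2 + 2 * r^2) / delta^2 - drive)
  cohesion_gain <- max(0, min(cohesion_gain, c_max))
  p <- swf_params(delta = delta, drive_gain = drive,
                  cohesion_gain = cohesion_gain, drag = drag,
                  repulsion_scale = repulsion_scale, n_members = n_members,
                  n_passes = n_passes, id = id)
  attr(p, "target_hz") <- center_hz
  p
}

#' Default SwF preset family
#'
#' Twelve presets log-spaced in target centre frequency over
#' `f_range = c(5, 450)` Hz at `fs = 1000` Hz, covering the wall-motion (low)
#' and valve-motion (high) bands of fetal Doppler audio.
#'
#' @param fs Sampling rate in Hz.
#' @param n Number of presets.
#' @param f_range Frequency span (Hz) of the family.
#' @param ... Passed to [swf_preset()].
#' @return A list of `swf_params`.
#' @export
default_presets <- function(fs = 1000, n = 12, f_range = c(5, 450), ...) {
  stopifnot(n >= 1, f_range[1] > 0, f_range[2] < fs / 2)
  centers <- exp(seq(log(f_range[1]), log(f_range[2]), length.out = n))
  lapply(seq_len(n), function(k)
    swf_preset(centers[k], fs, id = sprintf("p%02d", k), ...))
}

#' Apply one swarm filter to a signal
#'
#' Iterates the two-step swarm state update over all samples, the input
#' acting as the prey trajectory; the output is the mean member position.
#' Member positions start evenly spread over a symmetric 1e-6-scale interval
#' around the first sample with zero velocity, so the filter is fully
#' deterministic. By default the sweep is applied forward and then backward
#' (zero-phase), which cancels the swarm's phase lag and keeps event timing
#' unbiased; `direction = "forward"` gives the single causal hunt.
#'
#' The operator behaves as a band-pass-like resonator; its realised centre
#' frequency and bandwidth are characterised by [calibrate_swf()].
#'
#' @param signal A [signal_record()] or numeric vector.
#' @param params An [swf_params()] preset.
#' @param direction `"zero-phase"` (forward-backward, default) or
#'   `"forward"`.
#' @return Numeric vector, same length as the input.
#' @export
swarm_filter <- function(signal, params,
                         direction = c("zero-phase", "forward")) {
  direction <- match.arg(direction)
  x <- if (is_signal_record(signal)) signal$samples else as.numeric(signal)
  if (!all(is.finite(x))) stop("signal must be finite")
  stopifnot(inherits(params, "swf_params"))
  if (length(x) < 2L) return(x)
  swarm_sweep_cpp(x, params$n_members, params$delta, params$drive_gain,
                  params$cohesion_gain, params$drag, params$repulsion_scale,
                  zero_phase = direction == "zero-phase")
}

#' Measure the frequency response of SwF presets
#'
#' Drives each preset with unit-amplitude probe sinusoids swept over
#' (0, fs/2), measures the steady-state RMS gain (central portion of the
#' probe, edges discarded), and records the gain-maximising frequency and the
#' -3 dB bandwidth. The centre is refined on a local fine grid plus quadratic
#' interpolation. A preset whose gain maximum sits on the sweep boundary has
#' no interior passband and is rejected with a warning.
#'
#' @param preset_family Non-empty list of [swf_params()] presets.
#' @param fs Sampling rate in Hz.
#' @param n_probes Number of coarse log-spaced probe frequencies.
#' @param f_range Probe span in Hz; default `c(1, 0.48*fs)`.
#' @return A `swd_calibration` data frame (one row per accepted preset,
#'   sorted by measured centre frequency) with the preset parameters,
#'   `center_freq_hz`, `bandwidth_hz` and `peak_gain`; attribute `fs`.
#' @export
calibrate_swf <- function(preset_family, fs, n_probes = 40, f_range = NULL) {
  if (!is.list(preset_family) || length(preset_family) == 0L)
    stop("preset family must be a non-empty list of swf_params")
  if (inherits(preset_family, "swf_params"))
    preset_family <- list(preset_family)
  if (is.null(f_range)) f_range <- c(1, 0.48 * fs)
  coarse <- exp(seq(log(f_range[1]), log(f_range[2]),
                    length.out = n_probes))
  rows <- list()
  for (k in seq_along(preset_family)) {
    p <- preset_family[[k]]
    stopifnot(inherits(p, "swf_params"))
    grid <- coarse
    tgt <- attr(p, "target_hz")
    if (!is.null(tgt)) {
      extra <- tgt * c(0.85, 1, 1.15)
      grid <- sort(c(grid, extra[extra > f_range[1] & extra < f_range[2]]))
    }
    g <- vapply(grid, probe_gain, 0, params = p, fs = fs)
    imax <- which.max(g)
    if (imax == 1L || imax == length(g)) {
      warning(sprintf("preset %s has no interior gain maximum; rejected",
                      p$id %||% k))
      next
    }
    fine <- seq(grid[imax - 1L], grid[imax + 1L], length.out = 17)
    gf <- vapply(fine, probe_gain, 0, params = p, fs = fs)
    jf <- which.max(gf)
    center <- if (jf > 1L && jf < length(gf))
      quad_peak(fine[(jf - 1L):(jf + 1L)], gf[(jf - 1L):(jf + 1L)])
    else fine[jf]
    freqs <- c(grid, fine); gains <- c(g, gf)
    o <- order(freqs); freqs <- freqs[o]; gains <- gains[o]
    bw <- halfpower_bandwidth(freqs, gains, max(gains))
    rows[[length(rows) + 1L]] <- data.frame(
      preset_id = p$id %||% sprintf("p%02d", k), delta = p$delta,
      n_members = p$n_members, drive_gain = p$drive_gain,
      cohesion_gain = p$cohesion_gain, drag = p$drag,
      repulsion_scale = p$repulsion_scale, n_passes = p$n_passes,
      center_freq_hz = center, bandwidth_hz = bw,
      peak_gain = max(gains), stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) stop("no preset produced an interior passband")
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$center_freq_hz), , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "fs") <- fs
  class(tab) <- c("swd_calibration", "data.frame")
  tab
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# steady-state gain of one preset at one probe frequency: RMS of the middle
# 60% of the filtered probe over RMS of the probe
probe_gain <- function(f, params, fs) {
  dur <- max(1.5, 0.5 + 20 / f)
  t <- seq(0, dur, by = 1 / fs)
  y <- swarm_filter(sin(2 * pi * f * t), params)
  i <- seq.int(floor(length(t) * 0.2) + 1L, ceiling(length(t) * 0.8))
  sqrt(mean(y[i]^2) / mean(sin(2 * pi * f * t[i])^2))
}

quad_peak <- function(x3, y3) {
  d <- (y3[1] - 2 * y3[2] + y3[3])
  if (d >= 0) return(x3[2])
  x3[2] - 0.5 * (x3[3] - x3[1]) / 2 * (y3[3] - y3[1]) / d
}

halfpower_bandwidth <- function(freqs, gains, peak) {
  thr <- peak / sqrt(2)
  above <- gains >= thr
  imax <- which.max(gains)
  lo <- freqs[1]; hi <- freqs[length(freqs)]
  i <- imax
  while (i > 1L && above[i - 1L]) i <- i - 1L
  if (i > 1L)
    lo <- stats::approx(gains[c(i - 1L, i)], freqs[c(i - 1L, i)],
                        xout = thr)$y
  j <- imax
  while (j < length(gains) && above[j + 1L]) j <- j + 1L
  if (j < length(gains))
    hi <- stats::approx(gains[c(j + 1L, j)], freqs[c(j + 1L, j)],
                        xout = thr)$y
  hi - lo
}

#' @export
print.swd_calibration <- function(x, ...) {
  cat(sprintf("<swd_calibration> %d presets @ fs = %g Hz\n",
              nrow(x), attr(x, "fs")))
  df <- as.data.frame(x)[c("preset_id", "center_freq_hz", "bandwidth_hz",
                           "peak_gain")]
  df$center_freq_hz <- round(df$center_freq_hz, 2)
  df$bandwidth_hz <- round(df$bandwidth_hz, 2)
  df$peak_gain <- round(df$peak_gain, 2)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Serialize / read a calibration table as CSV
#'
#' Columns: `preset_id, delta, n_members, drive_gain, cohesion_gain, drag,
#' repulsion_scale, n_passes, center_freq_hz, bandwidth_hz, peak_gain, fs`.
#'
#' @param calibration A `swd_calibration` table from [calibrate_swf()].
#' @param path File path.
#' @return `path` (writer, invisibly) or a `swd_calibration` table (reader).
#' @export
write_calibration_csv <- function(calibration, path) {
  stopifnot(inherits(calibration, "swd_calibration"))
  df <- as.data.frame(calibration)
  df$fs <- attr(calibration, "fs")
  utils::write.csv(fmt_num_df(df), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_calibration_csv
#' @export
read_calibration_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  fs <- unique(as.numeric(df$fs))
  stopifnot(length(fs) == 1L)
  df$fs <- NULL
  num <- setdiff(names(df), "preset_id")
  for (j in num) df[[j]] <- as.numeric(df[[j]])
  df$n_members <- as.integer(df$n_members)
  df$n_passes <- as.integer(df$n_passes)
  attr(df, "fs") <- fs
  class(df) <- c("swd_calibration", "data.frame")
  df
}

calibration_params <- function(calibration, row) {
  r <- calibration[row, ]
  swf_params(delta = r$delta, drive_gain = r$drive_gain,
             cohesion_gain = r$cohesion_gain, drag = r$drag,
             repulsion_scale = r$repulsion_scale, n_members = r$n_members,
             n_passes = r$n_passes, id = r$preset_id)
}

# calibration cache: the default family is deterministic, so characterise it
# once per sampling rate and session
.swdus_cal_cache <- new.env(parent = emptyenv())

#' Default calibration table for a sampling rate
#'
#' Calibrates [default_presets()] at `fs`, caching the result for the
#' session. The shipped copy for 1 kHz lives in
#' `system.file("extdata", "swf_calibration_fs1000.csv", package = "swdus")`
#' and is regenerated by this function.
#'
#' @param fs Sampling rate in Hz.
#' @return A `swd_calibration` table.
#' @export
default_calibration <- function(fs = 1000) {
  key <- sprintf("fs%.6g", fs)
  if (!is.null(.swdus_cal_cache[[key]])) return(.swdus_cal_cache[[key]])
  shipped <- system.file("extdata", "swf_calibration_fs1000.csv",
                         package = "swdus")
  tab <- if (fs == 1000 && nzchar(shipped)) read_calibration_csv(shipped)
         else calibrate_swf(default_presets(fs = fs), fs = fs)
  .swdus_cal_cache[[key]] <- tab
  tab
}
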