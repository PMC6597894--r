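# Swarm decomposition (SWD): sifting-like loop that repeatedly guesses the
# dominant oscillatory band of the residual, extracts it with repeated swarm
# filtering, and subtracts it, yielding ordered oscillatory components (OCs)
# plus a residual that reconstructs the input exactly by construction.

#' Dominant frequency of a signal
#'
#' Frequency of the maximum of a smoothed periodogram of the mean-removed
#' signal (modified Daniell smoother, 10% cosine taper).
#'
#' @param signal A [signal_record()] or numeric vector (then `fs` required).
#' @param fs Sampling rate in Hz when `signal` is a bare vector.
#' @return Dominant frequency in Hz, in (0, fs/2).
#' @export
estimate_dominant_frequency <- function(signal, fs = NULL) {
  x <- if (is_signal_record(signal)) signal$samples else as.numeric(signal)
  if (is_signal_record(signal)) fs <- signal$fs
  if (is.null(fs)) stop("fs required")
  if (length(x) < 64L) stop("signal too short (need >= 64 samples)")
  x <- x - mean(x)
  if (diff(range(x)) == 0) stop("no oscillatory content")
  span <- max(3L, as.integer(2 * floor(length(x) * 1.5 / fs) + 1L))
  sp <- stats::spec.pgram(stats::ts(x, frequency = fs), spans = span,
                          taper = 0.1, detrend = FALSE, plot = FALSE)
  sp$freq[which.max(sp$spec)]
}

#' Extract one oscillatory component
#'
#' Applies [swarm_filter()] with `params$n_passes` consecutive passes (each
#' pass filtering the previous output), stopping early once two consecutive
#' passes correlate at >= `stop_corr`. The result is gain-equalised by its
#' least-squares projection onto the extraction input, so subtracting it from
#' the input always lowers the residual energy.
#'
#' @param signal A [signal_record()] or numeric vector (then `fs` required).
#' @param params An [swf_params()] preset.
#' @param fs Sampling rate when `signal` is a bare vector.
#' @param stop_corr Early-stop correlation between consecutive passes.
#' @param iteration Extraction order stored on the component.
#' @return An `oscillatory_component`: list with `samples`,
#'   `center_freq_hz`, `iteration`, `energy_fraction` (component energy over
#'   input energy), `preset_id`, `n_passes_used`.
#' @export
extract_oscillatory_component <- function(signal, params, fs = NULL,
                                          stop_corr = 0.999,
                                          iteration = 1L) {
  x <- if (is_signal_record(signal)) signal$samples else as.numeric(signal)
  if (is_signal_record(signal)) fs <- signal$fs
  if (is.null(fs)) stop("fs required")
  y <- x
  used <- 0L
  for (k in seq_len(params$n_passes)) {
    y_new <- swarm_filter(y, params)
    used <- k
    if (k > 1L && all(is.finite(y_new))) {
      denom <- sqrt(sum(y^2) * sum(y_new^2))
      if (denom > 0 && sum(y * y_new) / denom >= stop_corr) {
        y <- y_new
        break
      }
    }
    y <- y_new
  }
  e_y <- sum(y^2)
  beta <- if (e_y > 0) sum(x * y) / e_y else 0
  oc <- beta * y
  e_in <- sum(x^2)
  e_oc <- sum(oc^2)
  cf <- if (e_oc > 0 && length(oc) >= 64L && diff(range(oc)) > 0)
    estimate_dominant_frequency(oc, fs = fs) else NA_real_
  structure(list(samples = oc, center_freq_hz = cf,
                 iteration = as.integer(iteration),
                 energy_fraction = if (e_in > 0) e_oc / e_in else 0,
                 preset_id = params$id, n_passes_used = used),
            class = "oscillatory_component")
}

#' @export
print.oscillatory_component <- function(x, ...) {
  cat(sprintf(
    "<oscillatory_component #%d> center %.4g Hz, energy fraction %.3g (%s)\n",
    x$iteration, x$center_freq_hz, x$energy_fraction,
    x$preset_id %||% "custom"))
  invisible(x)
}

#' Decompose a signal into oscillatory components
#'
#' Sifting-like loop: estimate the dominant frequency of the current
#' residual, select the calibrated preset with the nearest centre frequency
#' (log-frequency distance), extract one oscillatory component, subtract it,
#' and repeat until the residual energy falls below
#' `residual_threshold * input energy`, `max_components` is reached, or an
#' extraction no longer removes energy. The components plus the final
#' residual reproduce the input exactly by construction.
#'
#' @param signal A [signal_record()] or numeric vector (then `fs` required).
#' @param fs Sampling rate when `signal` is a bare vector.
#' @param calibration A `swd_calibration` table; `NULL` uses
#'   [default_calibration()] when `auto_calibrate = TRUE`.
#' @param residual_threshold Stop when residual energy is below this fraction
#'   of the input energy.
#' @param max_components Maximum number of extracted components.
#' @param stop_corr Early-stop correlation for the inner pass loop.
#' @param auto_calibrate Calibrate the default preset family on the fly when
#'   no table is supplied.
#' @return An object of class `swd_decomposition` with elements
#'   `components` (list of `oscillatory_component`, extraction order),
#'   `residual`, `fs`, `input`, `label`, `calibration`.
#' @examples
#' t <- seq(0, 2, by = 1e-3)
#' x <- signal_record(sin(2 * pi * 50 * t) + sin(2 * pi * 300 * t), 1000)
#' d <- swarm_decompose(x)
#' d
#' @export
swarm_decompose <- function(signal, fs = NULL, calibration = NULL,
                            residual_threshold = 0.01, max_components = 8,
                            stop_corr = 0.999, auto_calibrate = TRUE) {
  rec <- if (is_signal_record(signal)) signal
         else as_signal_record(signal, fs)
  x <- rec$samples
  if (length(x) < 256L) stop("signal too short (need >= 256 samples)")
  if (is.null(calibration)) {
    if (!auto_calibrate)
      stop("no calibration table supplied and auto-calibration disabled")
    calibration <- default_calibration(rec$fs)
  }
  stopifnot(inherits(calibration, "swd_calibration"))
  if (any(diff(calibration$center_freq_hz) <= 0))
    stop("calibration table centre frequencies must be strictly increasing")
  e_in <- sum(x^2)
  residual <- x
  comps <- list()
  while (e_in > 0 && length(comps) < max_components &&
         sum(residual^2) >= residual_threshold * e_in) {
    if (diff(range(residual)) == 0) break
    f_dom <- estimate_dominant_frequency(residual, fs = rec$fs)
    row <- which.min(abs(log(calibration$center_freq_hz) - log(f_dom)))
    params <- calibration_params(calibration, row)
    oc <- extract_oscillatory_component(residual, params, fs = rec$fs,
                                        stop_corr = stop_corr,
                                        iteration = length(comps) + 1L)
    e_before <- sum(residual^2)
    new_res <- residual - oc$samples
    # abandon the loop once an extraction stops removing energy
    if (sum(oc$samples^2) == 0 ||
        (e_before - sum(new_res^2)) < 1e-6 * e_in) break
    oc$energy_fraction <- sum(oc$samples^2) / e_in
    comps[[length(comps) + 1L]] <- oc
    residual <- new_res
  }
  structure(list(components = comps, residual = residual, fs = rec$fs,
                 input = x, label = rec$label, t0 = rec$t0,
                 calibration = calibration),
            class = "swd_decomposition")
}

#' @export
print.swd_decomposition <- function(x, ...) {
  cat(sprintf("<swd_decomposition> '%s': %d components, fs = %g Hz\n",
              x$label, length(x$components), x$fs))
  if (length(x$components)) {
    df <- data.frame(
      component = seq_along(x$components),
      center_freq_hz = round(vapply(x$components,
                                    function(c) c$center_freq_hz, 0), 2),
      energy_fraction = signif(vapply(x$components,
                                      function(c) c$energy_fraction, 0), 3),
      preset = vapply(x$components,
                      function(c) c$preset_id %||% "custom", ""))
    print(df, row.names = FALSE)
  }
  cat(sprintf("residual energy: %.3g of input\n",
              sum(x$residual^2) / max(sum(x$input^2), .Machine$double.xmin)))
  invisible(x)
}

#' @export
summary.swd_decomposition <- function(object, ...) {
  print(object)
  rel <- sum((object$input - reconstruct(object))^2) /
    max(sum(object$input^2), .Machine$double.xmin)
  cat(sprintf("reconstruction relative L2 error: %.3g\n", sqrt(rel)))
  invisible(object)
}

#' Reconstruct the input from a decomposition
#'
#' @param object A `swd_decomposition`.
#' @return Numeric vector: sum of all components plus the residual.
#' @export
reconstruct <- function(object) {
  stopifnot(inherits(object, "swd_decomposition"))
  out <- object$residual
  for (c in object$components) out <- out + c$samples
  out
}

#' @export
residuals.swd_decomposition <- function(object, ...) object$residual

#' @export
fitted.swd_decomposition <- function(object, ...)
  object$input - object$residual

#' @export
as.data.frame.swd_decomposition <- function(x, ...) {
  df <- data.frame(time_s = x$t0 + (seq_along(x$input) - 1) / x$fs)
  for (k in seq_along(x$components))
    df[[sprintf("oc%d", k)]] <- x$components[[k]]$samples
  df$residual <- x$residual
  df
}

#' @export
plot.swd_decomposition <- function(x, max_seconds = 5, ...) {
  n <- min(length(x$input), round(max_seconds * x$fs))
  idx <- seq_len(n)
  tt <- (idx - 1) / x$fs
  k <- length(x$components)
  op <- graphics::par(mfrow = c(k + 2, 1), mar = c(2, 4, 1, 1))
  on.exit(graphics::par(op))
  graphics::plot(tt, x$input[idx], type = "l", ylab = "input", xlab = "")
  for (j in seq_len(k))
    graphics::plot(tt, x$components[[j]]$samples[idx], type = "l",
                   ylab = sprintf("OC%d", j), xlab = "")
  graphics::plot(tt, x$residual[idx], type = "l", ylab = "residual",
                 xlab = "time (s)")
  invisible(x)
}

#' Write decomposition components as CSV
#'
#' Multi-column CSV `time_s, oc1, ..., residual`.
#'
#' @param decomp A `swd_decomposition`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_components_csv <- function(decomp, path) {
  utils::write.csv(fmt_num_df(as.data.frame(decomp)), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Instantaneous energy of a component
#'
#' Squared envelope (see [compute_envelope()]) of an oscillatory component;
#' non-negative, same length as the component.
#'
#' @param component An `oscillatory_component` or numeric vector.
#' @param fs Sampling rate in Hz (required for bare vectors).
#' @param smooth_cutoff_hz Envelope smoothing cut-off in Hz.
#' @return Numeric vector of instantaneous energy.
#' @export
instantaneous_energy <- function(component, fs, smooth_cutoff_hz = 25) {
  x <- if (inherits(component, "oscillatory_component")) component$samples
       else as.numeric(component)
  if (length(x) == 0L) stop("component is empty")
  compute_envelope(x, fs, smooth_cutoff_hz)^2
}
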