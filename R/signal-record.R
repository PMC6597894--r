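#' Uniformly sampled waveform container
#'
#' A `signal_record` wraps a real-valued, uniformly sampled waveform together
#' with its sampling rate, a free-text provenance label and the start time.
#' It is the common input type of the decomposition and event-detection
#' stages.
#'
#' @param samples Numeric vector of at least two finite samples (arbitrary
#'   units).
#' @param fs Sampling rate in Hz (positive scalar).
#' @param label Free-text provenance label.
#' @param t0 Start time of the first sample in seconds.
#' @return An object of class `signal_record`: a list with elements
#'   `samples`, `fs`, `label`, `t0`.
#' @examples
#' x <- signal_record(sin(2 * pi * 5 * seq(0, 1, by = 1e-3)), fs = 1000)
#' x
#' @export
signal_record <- function(samples, fs, label = "signal", t0 = 0) {
  samples <- as.numeric(samples)
  if (length(samples) < 2L)
    stop("signal must contain at least 2 samples")
  if (!all(is.finite(samples)))
    stop("signal samples must all be finite")
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("fs must be a positive finite scalar")
  structure(list(samples = samples, fs = as.numeric(fs),
                 label = as.character(label)[1L], t0 = as.numeric(t0)[1L]),
            class = "signal_record")
}

#' @export
print.signal_record <- function(x, ...) {
  cat(sprintf("<signal_record> '%s': %d samples @ %g Hz (%.3f s), t0 = %g s\n",
              x$label, length(x$samples), x$fs,
              length(x$samples) / x$fs, x$t0))
  invisible(x)
}

#' @export
length.signal_record <- function(x) length(x$samples)

#' Sample times of a signal record
#'
#' @param x A [signal_record()].
#' @return Numeric vector of sample times in seconds.
#' @export
signal_times <- function(x) {
  stopifnot(inherits(x, "signal_record"))
  x$t0 + (seq_along(x$samples) - 1) / x$fs
}

is_signal_record <- function(x) inherits(x, "signal_record")

as_signal_record <- function(x, fs = NULL, label = "signal") {
  if (is_signal_record(x)) return(x)
  if (is.null(fs)) stop("fs required when input is a bare numeric vector")
  signal_record(x, fs, label = label)
}
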