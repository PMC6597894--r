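# Run configuration: YAML blocks `swd`, `events`, `stats`, `synthetic`
# merged over package defaults. Logging goes to stderr; results go to files.

#' Default run configuration
#'
#' @return Nested list with blocks `swd` (decomposition), `events`
#'   (envelope/anchor/window settings), `stats` (electromechanical delay and
#'   gestational-week group boundaries) and `synthetic` (generator
#'   defaults).
#' @export
default_config <- function() {
  list(
    swd = list(n_members = 20L, n_passes = 2L, residual_threshold = 0.01,
               max_components = 8L, calibration_file = NULL),
    events = list(windows = default_event_windows(), noise_floor = 0.5,
                  min_rr_ms = 250, envelope_cutoff_hz = 25, threshold_k = 3,
                  anchor_lead_ms = 8,
                  rr_range_ms = c(250, 700), min_component_freq_hz = 100),
    stats = list(edt_ms = 25,
                 group_weeks = list(early = c(16, 29), mid = c(30, 35),
                                    late = c(36, 41))),
    synthetic = unclass(synth_config()))
}

merge_config <- function(base, override) {
  if (is.null(override)) return(base)
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]) &&
        !is.null(names(override[[nm]])))
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' Read a YAML run configuration
#'
#' Values found in the file override the package defaults; unknown keys are
#' kept (and ignored by the stages that do not use them).
#'
#' @param path Path to a YAML file, or `NULL` for pure defaults.
#' @return Configuration list as in [default_config()].
#' @export
read_run_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  cfg <- merge_config(cfg, user)
  ev <- c("mc", "ao", "ac", "mo")
  for (e in ev)
    cfg$events$windows[[e]] <- as.numeric(cfg$events$windows[[e]])
  for (f in c("event_offsets_ms", "event_offset_sd_ms", "event_amplitude",
              "burst_freq_hz"))
    if (!is.null(cfg$synthetic[[f]]))
      cfg$synthetic[[f]] <- stats::setNames(
        as.numeric(unlist(cfg$synthetic[[f]])[ev]), ev)
  cfg
}

# 32-bit FNV-1a over a character scalar (config fingerprint for logs)
fnv1a <- function(x) {
  bytes <- as.integer(charToRaw(paste(x, collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), b)
    # 32-bit modular multiply in double precision (split at 2^16)
    h <- ((h %% 65536) * 16777619 +
          ((h %/% 65536) * 16777619 %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

config_hash <- function(cfg) fnv1a(yaml::as.yaml(cfg))

log_msg <- function(...) message(sprintf(...))
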