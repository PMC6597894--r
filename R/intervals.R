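# Cardiac intervals: convert per-beat valve-event times to ICT, VET, IRT,
# PEP and STI, aggregate to subjects, and summarise gestational-age groups
# with nonparametric tests.
#
# Interval conventions (ms): ICT = Ao - Mc, VET = Ac - Ao, IRT = Mo - Ac,
# PEP = EDT + ICT (EDT = electromechanical delay, default 25 ms),
# STI = PEP + VET.

#' Compute cardiac intervals from valve-event times
#'
#' Any interval with a missing operand is missing; a computed negative
#' interval (event-ordering violation) is set missing and flagged.
#'
#' @param events A `valve_events` object, a data frame with columns
#'   `t_mc_ms, t_ao_ms, t_ac_ms, t_mo_ms` (optionally `beat_index`,
#'   `rr_ms`), or a named numeric vector for a single beat.
#' @param rr_ms Per-beat RR in ms (recycled); taken from `events` when
#'   present.
#' @param edt_ms Electromechanical delay in ms added to ICT to form PEP.
#' @return A `beat_intervals` data frame: `beat_index, rr_ms, ict_ms,
#'   vet_ms, irt_ms, pep_ms, sti_ms, flag_ordering`.
#' @examples
#' compute_intervals(c(t_mc_ms = 14.51, t_ao_ms = 59.4,
#'                     t_ac_ms = 198.08, t_mo_ms = 275.57))
#' @export
compute_intervals <- function(events, rr_ms = NULL, edt_ms = 25) {
  if (edt_ms < 0) stop("edt_ms must be >= 0")
  if (inherits(events, "valve_events")) events <- events$events
  if (is.numeric(events) && !is.null(names(events)))
    events <- as.data.frame(as.list(events))
  stopifnot(is.data.frame(events))
  need <- c("t_mc_ms", "t_ao_ms", "t_ac_ms", "t_mo_ms")
  stopifnot(all(need %in% names(events)))
  n <- nrow(events)
  if (is.null(rr_ms)) rr_ms <- events$rr_ms %||% rep(NA_real_, n)
  ict <- events$t_ao_ms - events$t_mc_ms
  vet <- events$t_ac_ms - events$t_ao_ms
  irt <- events$t_mo_ms - events$t_ac_ms
  flag <- (!is.na(ict) & ict <= 0) | (!is.na(vet) & vet <= 0) |
    (!is.na(irt) & irt <= 0)
  ict[!is.na(ict) & ict <= 0] <- NA_real_
  vet[!is.na(vet) & vet <= 0] <- NA_real_
  irt[!is.na(irt) & irt <= 0] <- NA_real_
  pep <- edt_ms + ict
  sti <- pep + vet
  out <- data.frame(
    beat_index = events$beat_index %||% seq_len(n),
    rr_ms = rep_len(rr_ms, n),
    ict_ms = ict, vet_ms = vet, irt_ms = irt, pep_ms = pep, sti_ms = sti,
    flag_ordering = flag)
  class(out) <- c("beat_intervals", "data.frame")
  attr(out, "edt_ms") <- edt_ms
  out
}

#' @export
print.beat_intervals <- function(x, ...) {
  cat(sprintf("<beat_intervals> %d beats (EDT = %g ms)\n", nrow(x),
              attr(x, "edt_ms") %||% NA))
  df <- as.data.frame(x)
  for (j in intersect(names(df), c("rr_ms", "ict_ms", "vet_ms", "irt_ms",
                                   "pep_ms", "sti_ms")))
    df[[j]] <- round(df[[j]], 1)
  print(utils::head(df, 10), row.names = FALSE)
  if (nrow(df) > 10) cat(sprintf("... %d more beats\n", nrow(df) - 10))
  invisible(x)
}

#' Average a subject's beats
#'
#' Arithmetic mean of each interval over the beats where it is present;
#' an interval missing on every beat stays missing.
#'
#' @param beats A `beat_intervals` data frame.
#' @param subject_id Subject identifier.
#' @param group_label Gestational-age group label.
#' @return One-row data frame with `subject_id`, `group`, `n_beats` and the
#'   per-interval means (`rr_ms, ict_ms, vet_ms, irt_ms, pep_ms, sti_ms`).
#' @export
aggregate_subject <- function(beats, subject_id, group_label) {
  stopifnot(is.data.frame(beats))
  if (nrow(beats) == 0L) stop("subject has no beats")
  cols <- c("rr_ms", "ict_ms", "vet_ms", "irt_ms", "pep_ms", "sti_ms")
  means <- lapply(cols, function(j) {
    v <- beats[[j]]
    if (is.null(v) || all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  })
  names(means) <- cols
  cbind(data.frame(subject_id = as.character(subject_id),
                   group = as.character(group_label),
                   n_beats = nrow(beats), stringsAsFactors = FALSE),
        as.data.frame(means))
}

#' Group means and standard errors of subject-level intervals
#'
#' @param subjects Data frame of subject summaries (rows from
#'   [aggregate_subject()] or [simulate_cohort_intervals()]).
#' @param measures Interval columns to summarise.
#' @return Data frame `measure, group, n, mean, se` with
#'   `se = sd / sqrt(n)` (`n - 1` denominator); `se` is missing for groups
#'   with fewer than 2 subjects.
#' @export
group_summary <- function(subjects,
                          measures = c("rr_ms", "ict_ms", "vet_ms",
                                       "irt_ms", "pep_ms", "sti_ms")) {
  stopifnot(is.data.frame(subjects), "group" %in% names(subjects))
  measures <- intersect(measures, names(subjects))
  groups <- unique(subjects$group)
  rows <- list()
  for (m in measures) for (g in groups) {
    v <- subjects[[m]][subjects$group == g]
    v <- v[!is.na(v)]
    rows[[length(rows) + 1L]] <- data.frame(
      measure = m, group = g, n = length(v),
      mean = if (length(v)) mean(v) else NA_real_,
      se = if (length(v) >= 2L) stats::sd(v) / sqrt(length(v)) else NA_real_,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Kruskal-Wallis test across groups
#'
#' Rank-based H with tie correction and a chi-square approximation on
#' `k - 1` degrees of freedom. When every observation is identical the test
#' is degenerate and `H = 0, p = 1` is returned.
#'
#' @param groups List of >= 2 numeric vectors (each of length >= 2).
#' @return List with elements `H` and `p`.
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  lapply(groups, function(g) stopifnot(length(g) >= 2L))
  x <- unlist(groups, use.names = FALSE)
  if (diff(range(x)) == 0) return(list(H = 0, p = 1))
  g <- factor(rep(seq_along(groups), lengths(groups)))
  kt <- stats::kruskal.test(x, g)
  list(H = unname(kt$statistic), p = kt$p.value)
}

#' Pairwise Mann-Whitney-Wilcoxon tests
#'
#' Two-sided test for every pair of groups: exact when both samples have at
#' most 20 observations and no ties cross the pair, otherwise the normal
#' approximation with tie and continuity correction. P-values are reported
#' raw (no multiplicity adjustment).
#'
#' @param groups Named or unnamed list of >= 2 numeric vectors.
#' @return Data frame `pair, U, p` (U is the first group's Mann-Whitney
#'   statistic).
#' @export
pairwise_mannwhitney <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  nm <- names(groups) %||% paste0("g", seq_along(groups))
  if (is.null(names(groups))) names(groups) <- nm
  combs <- utils::combn(seq_along(groups), 2)
  rows <- apply(combs, 2, function(ij) {
    a <- groups[[ij[1]]]; b <- groups[[ij[2]]]
    exact <- length(a) <= 20L && length(b) <= 20L &&
      !any(duplicated(c(a, b)))
    wt <- suppressWarnings(
      stats::wilcox.test(a, b, exact = exact, correct = TRUE))
    data.frame(pair = paste(nm[ij[1]], "vs", nm[ij[2]]),
               U = unname(wt$statistic),
               p = if (diff(range(c(a, b))) == 0) 1 else wt$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Age correlation of an interval over adjacent groups
#'
#' Spearman rank correlation between age (group rank, or gestational weeks
#' when supplied) and the subject-level interval mean, pooled over two
#' adjacent gestational-age groups.
#'
#' @param subjects Subject-summary data frame with a `group` column.
#' @param measure Interval column name (e.g. `"sti_ms"`).
#' @param pair Character vector of the two group labels, ordered
#'   young -> old.
#' @param weeks Optional numeric vector (same length as `nrow(subjects)`)
#'   of gestational weeks used instead of group rank.
#' @return Spearman `r`, or `NA` when the interval is constant.
#' @export
age_correlation <- function(subjects, measure, pair, weeks = NULL) {
  stopifnot(length(pair) == 2L, measure %in% names(subjects))
  sel <- subjects$group %in% pair
  v <- subjects[[measure]][sel]
  age <- if (!is.null(weeks)) weeks[sel]
         else match(subjects$group[sel], pair)
  ok <- !is.na(v) & !is.na(age)
  if (sum(ok) < 3L) stop("need >= 3 subjects with the interval present")
  if (diff(range(v[ok])) == 0) return(NA_real_)
  stats::cor(age[ok], v[ok], method = "spearman")
}

#' Full group-level statistics table
#'
#' Combines [group_summary()] (mean +/- SE per group), a Kruskal-Wallis test
#' per interval, pairwise Mann-Whitney post hoc comparisons and Spearman age
#' correlations over adjacent groups into one report object.
#'
#' @param subjects Subject-summary data frame (`subject_id`, `group`,
#'   interval columns). `group` levels are ordered young -> old via
#'   `group_order`.
#' @param measures Interval columns to analyse.
#' @param group_order Ordering of the group labels; defaults to their order
#'   of appearance.
#' @return An object of class `gest_group_stats`: list with `summary`,
#'   `tests` (per-measure H, p), `pairwise` (per-measure data frame),
#'   `correlations` (adjacent-pair Spearman r), `group_order`.
#' @export
group_stats <- function(subjects,
                        measures = c("ict_ms", "irt_ms", "pep_ms",
                                     "sti_ms", "vet_ms"),
                        group_order = NULL) {
  stopifnot(is.data.frame(subjects), "group" %in% names(subjects))
  measures <- intersect(measures, names(subjects))
  if (is.null(group_order)) group_order <- unique(subjects$group)
  stopifnot(length(group_order) >= 2L)
  smry <- group_summary(subjects, measures)
  tests <- list(); pw <- list(); corr <- list()
  adj <- if (length(group_order) >= 2L)
    lapply(seq_len(length(group_order) - 1L),
           function(i) group_order[i:(i + 1L)]) else list()
  for (m in measures) {
    gl <- lapply(group_order, function(g) {
      v <- subjects[[m]][subjects$group == g]
      v[!is.na(v)]
    })
    names(gl) <- group_order
    usable <- all(lengths(gl) >= 2L)
    tests[[m]] <- if (usable) kruskal_wallis(gl)
                  else list(H = NA_real_, p = NA_real_)
    pw[[m]] <- if (usable) pairwise_mannwhitney(gl) else NULL
    corr[[m]] <- vapply(adj, function(pr)
      tryCatch(age_correlation(subjects, m, pr), error = function(e)
        NA_real_), 0)
    names(corr[[m]]) <- vapply(adj, paste, "", collapse = " to ")
  }
  structure(list(summary = smry, tests = tests, pairwise = pw,
                 correlations = corr, group_order = group_order,
                 measures = measures),
            class = "gest_group_stats")
}

#' @export
print.gest_group_stats <- function(x, digits = 1, ...) {
  cat("<gest_group_stats> groups:", paste(x$group_order, collapse = ", "),
      "\n\nMean +/- SE by group (ms):\n")
  wide <- NULL
  for (m in x$measures) {
    row <- data.frame(interval = m, stringsAsFactors = FALSE)
    for (g in x$group_order) {
      s <- x$summary[x$summary$measure == m & x$summary$group == g, ]
      row[[g]] <- if (nrow(s)) sprintf("%.*f +/- %.*f", digits, s$mean,
                                       digits + 1, s$se) else ""
    }
    wide <- rbind(wide, row)
  }
  print(wide, row.names = FALSE)
  cat("\nKruskal-Wallis (H, p) and adjacent-group Spearman r:\n")
  for (m in x$measures) {
    co <- paste(sprintf("%s: %.2f", names(x$correlations[[m]]),
                        x$correlations[[m]]), collapse = ", ")
    cat(sprintf("  %-7s H = %6.3f  p = %.6f   r(%s)\n", m,
                x$tests[[m]]$H, x$tests[[m]]$p, co))
  }
  cat("\nPairwise Mann-Whitney p-values (raw):\n")
  for (m in x$measures) {
    if (is.null(x$pairwise[[m]])) next
    cat(sprintf("  %-7s %s\n", m,
                paste(sprintf("%s: %.4f", x$pairwise[[m]]$pair,
                              x$pairwise[[m]]$p), collapse = "   ")))
  }
  invisible(x)
}

#' Write a group-statistics report
#'
#' CSV mirrors the mean +/- SE / test-table layout; the JSON carries full
#' precision.
#'
#' @param stats A `gest_group_stats` object.
#' @param csv_path,json_path Output paths (`NULL` skips that format).
#' @return Invisibly, the list written to JSON.
#' @export
write_stats_report <- function(stats, csv_path = NULL, json_path = NULL) {
  stopifnot(inherits(stats, "gest_group_stats"))
  tests <- data.frame(
    measure = names(stats$tests),
    H = vapply(stats$tests, function(t) t$H, 0),
    p = vapply(stats$tests, function(t) t$p, 0))
  if (!is.null(csv_path)) {
    smry <- stats$summary
    utils::write.csv(fmt_num_df(merge(smry, tests, by = "measure",
                                      all.x = TRUE)),
                     csv_path, row.names = FALSE, quote = FALSE)
  }
  payload <- list(summary = stats$summary, tests = stats$tests,
                  pairwise = stats$pairwise,
                  correlations = stats$correlations,
                  group_order = stats$group_order)
  if (!is.null(json_path))
    jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  invisible(payload)
}

#' Published reference timings for normal fetuses
#'
#' Group-level mean and standard error (ms) of the RR interval, the four
#' valve-event timings from the R peak, and the five cardiac intervals, for
#' normal fetuses in three gestational-age groups (early 16-29 weeks,
#' n = 16; mid 30-35 weeks, n = 21; late 36-41 weeks, n = 29). These values
#' parameterise the cohort simulators.
#'
#' @return Data frame `measure, group, n, mean, se`.
#' @export
fetal_timing_reference <- function() {
  g <- c("early", "mid", "late")
  n <- c(16L, 21L, 29L)
  ref <- list(
    rr_ms   = list(mean = c(404.56, 422.56, 421.98), se = c(11.97, 7.54, 6.8)),
    r_mc_ms = list(mean = c(14.51, 15.89, 15.17), se = c(1.27, 1, 0.76)),
    r_ao_ms = list(mean = c(59.4, 51.7, 53.2), se = c(3.86, 1.02, 0.84)),
    r_ac_ms = list(mean = c(198.08, 196.19, 187.61), se = c(3.72, 2.38, 2.87)),
    r_mo_ms = list(mean = c(275.57, 270.97, 266.39), se = c(3.65, 1.52, 1.5)),
    ict_ms  = list(mean = c(44.9, 35.8, 38), se = c(3.1, 1.2, 1)),
    irt_ms  = list(mean = c(77.5, 74.8, 78.8), se = c(2.18, 2.9, 3.2)),
    pep_ms  = list(mean = c(69.9, 60.8, 63), se = c(3.1, 1.2, 1)),
    sti_ms  = list(mean = c(208.6, 205.3, 197.4), se = c(3.19, 2.7, 3)),
    vet_ms  = list(mean = c(138.7, 144.5, 134.4), se = c(3.36, 2.7, 3.3)))
  out <- do.call(rbind, lapply(names(ref), function(m)
    data.frame(measure = m, group = g, n = n, mean = ref[[m]]$mean,
               se = ref[[m]]$se, stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out
}
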