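# Interval arithmetic and the nonparametric group-comparison machinery.

test_that("published group-mean event timings reproduce the interval rows", {
  # per-group mean timings (ms from the R peak) and the expected 1-dp rows
  groups <- list(
    early = list(ev = c(t_mc_ms = 14.51, t_ao_ms = 59.4, t_ac_ms = 198.08,
                        t_mo_ms = 275.57),
                 out = c(ict = 44.9, vet = 138.7, irt = 77.5,
                         pep = 69.9, sti = 208.6)),
    mid = list(ev = c(t_mc_ms = 15.89, t_ao_ms = 51.7, t_ac_ms = 196.19,
                      t_mo_ms = 270.97),
               out = c(ict = 35.8, vet = 144.5, irt = 74.8,
                       pep = 60.8, sti = 205.3)),
    late = list(ev = c(t_mc_ms = 15.17, t_ao_ms = 53.2, t_ac_ms = 187.61,
                       t_mo_ms = 266.39),
                out = c(ict = 38.0, vet = 134.4, irt = 78.8,
                        pep = 63.0, sti = 197.4)))
  for (g in groups) {
    iv <- compute_intervals(g$ev, edt_ms = 25)
    got <- round(c(iv$ict_ms, iv$vet_ms, iv$irt_ms, iv$pep_ms, iv$sti_ms), 1)
    expect_equal(got, unname(g$out))
  }
})

test_that("missing operands and ordering violations propagate correctly", {
  ev <- data.frame(t_mc_ms = 14, t_ao_ms = NA, t_ac_ms = 198, t_mo_ms = 275)
  iv <- compute_intervals(ev)
  expect_true(all(is.na(c(iv$ict_ms, iv$vet_ms, iv$pep_ms, iv$sti_ms))))
  expect_equal(iv$irt_ms, 77)
  bad <- compute_intervals(data.frame(t_mc_ms = 60, t_ao_ms = 50,
                                      t_ac_ms = 198, t_mo_ms = 275))
  expect_true(is.na(bad$ict_ms))
  expect_true(bad$flag_ordering)
  expect_false(is.na(bad$vet_ms))
  expect_error(compute_intervals(ev, edt_ms = -1), "edt_ms")
})

test_that("interval identities hold exactly on random beats", {
  set.seed(5)
  ev <- data.frame(t_mc_ms = runif(50, 5, 30), t_ao_ms = runif(50, 45, 70),
                   t_ac_ms = runif(50, 150, 240),
                   t_mo_ms = runif(50, 262, 320))
  iv <- compute_intervals(ev, edt_ms = 25)
  expect_equal(iv$pep_ms, 25 + iv$ict_ms, tolerance = 1e-9)
  expect_equal(iv$sti_ms, iv$pep_ms + iv$vet_ms, tolerance = 1e-9)
  expect_equal(iv$ict_ms, ev$t_ao_ms - ev$t_mc_ms, tolerance = 1e-9)
})

test_that("subject aggregation averages only the beats that carry an interval", {
  beats <- compute_intervals(data.frame(
    t_mc_ms = c(10, 12), t_ao_ms = c(50, 62),
    t_ac_ms = c(190, NA), t_mo_ms = c(270, 272)))
  s <- aggregate_subject(beats, "s1", "early")
  expect_equal(s$ict_ms, mean(c(40, 50)))
  expect_equal(s$vet_ms, 140)          # beat 2 excluded from VET only
  expect_true(is.na(s$sti_ms) || s$sti_ms == beats$sti_ms[1])
  expect_equal(s$n_beats, 2)
  none <- compute_intervals(data.frame(t_mc_ms = NA_real_, t_ao_ms = NA_real_,
                                       t_ac_ms = 190, t_mo_ms = 270))
  expect_true(is.na(aggregate_subject(none, "s2", "early")$ict_ms))
  expect_error(aggregate_subject(beats[0, ], "s3", "early"), "no beats")
})

test_that("group summary computes mean and SE over subject means", {
  subj <- data.frame(subject_id = c("a", "b", "c", "d"),
                     group = c("g1", "g1", "g1", "g2"),
                     sti_ms = c(10, 20, 30, 50))
  sm <- group_summary(subj, "sti_ms")
  g1 <- sm[sm$group == "g1", ]
  expect_equal(g1$mean, 20)
  expect_equal(g1$se, 10 / sqrt(3))
  g2 <- sm[sm$group == "g2", ]
  expect_equal(g2$mean, 50)
  expect_true(is.na(g2$se))
})

test_that("simulated cohorts recover the configured group means", {
  ref <- fetal_timing_reference()
  hits <- 0; total <- 0
  for (s in 1:20) {
    coh <- simulate_cohort_intervals(seed = 500 + s)
    sm <- group_summary(coh, c("sti_ms", "irt_ms", "pep_ms"))
    for (i in seq_len(nrow(sm))) {
      r <- ref[ref$measure == sm$measure[i] & ref$group == sm$group[i], ]
      total <- total + 1
      if (abs(sm$mean[i] - r$mean) <= 2 * r$se) hits <- hits + 1
    }
  }
  expect_gt(hits / total, 0.9)
})

test_that("Kruskal-Wallis matches the explicit rank formula", {
  g <- list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9))
  # oracle: H = 12/(N(N+1)) * sum(R_i^2/n_i) - 3(N+1), no ties
  ranks <- rank(unlist(g))
  Ri <- c(sum(ranks[1:3]), sum(ranks[4:6]), sum(ranks[7:9]))
  H_oracle <- 12 / (9 * 10) * sum(Ri^2 / 3) - 3 * 10
  kw <- kruskal_wallis(g)
  expect_equal(kw$H, H_oracle, tolerance = 1e-12)
  expect_equal(kw$p, stats::pchisq(H_oracle, 2, lower.tail = FALSE),
               tolerance = 1e-12)
  ident <- kruskal_wallis(list(rep(4, 5), rep(4, 6), rep(4, 4)))
  expect_equal(ident$H, 0)
  expect_equal(ident$p, 1)
  set.seed(2)
  a <- rnorm(20); b <- rnorm(20) + 10
  expect_lt(kruskal_wallis(list(a, b))$p, 0.01)
  expect_error(kruskal_wallis(list(1:3)), "2")
})

test_that("exact Mann-Whitney p matches full enumeration", {
  a <- c(1, 2, 3); b <- c(4, 5, 6)
  # oracle: enumerate all choose(6,3) = 20 assignments of the pooled ranks
  pooled <- c(a, b)
  obs_u <- sum(outer(a, b, ">")) # 0
  combos <- utils::combn(6, 3)
  us <- apply(combos, 2, function(idx)
    sum(outer(pooled[idx], pooled[-idx], ">")))
  # two-sided exact p: tail probability of as-extreme U on either side
  p_oracle <- mean(pmin(us, 9 - us) <= min(obs_u, 9 - obs_u))
  expect_equal(p_oracle, 0.1)
  pw <- pairwise_mannwhitney(list(a = a, b = b))
  expect_equal(pw$p, 0.1)
  expect_equal(pairwise_mannwhitney(list(rep(1, 4), rep(1, 5)))$p, 1)
  # U and its mirror always sum to n1*n2
  set.seed(8)
  x <- rnorm(7); y <- rnorm(9)
  u_xy <- pairwise_mannwhitney(list(x, y))$U
  u_yx <- pairwise_mannwhitney(list(y, x))$U
  expect_equal(u_xy + u_yx, 7 * 9)
})

test_that("age correlation is a signed Spearman over pooled adjacent groups", {
  subj <- data.frame(subject_id = letters[1:6],
                     group = rep(c("early", "mid"), each = 3),
                     sti_ms = c(1, 2, 3, 4, 5, 6))
  weeks <- c(20, 22, 24, 31, 33, 35)
  expect_equal(age_correlation(subj, "sti_ms", c("early", "mid"),
                               weeks = weeks), 1)
  expect_equal(age_correlation(subj, "sti_ms", c("mid", "early"),
                               weeks = max(weeks) - weeks), -1)
  # with group-rank ages the ties cap |r| below 1 but the sign flips exactly
  r_fwd <- age_correlation(subj, "sti_ms", c("early", "mid"))
  expect_gt(r_fwd, 0.8)
  expect_equal(age_correlation(subj, "sti_ms", c("mid", "early")), -r_fwd)
  subj$sti_ms <- rep(7, 6)
  expect_true(is.na(age_correlation(subj, "sti_ms", c("early", "mid"))))
  # under a null with no age effect the mean correlation stays near zero
  rs <- vapply(1:20, function(s) {
    set.seed(300 + s)
    d <- data.frame(subject_id = as.character(1:20),
                    group = rep(c("early", "mid"), each = 10),
                    sti_ms = rnorm(20))
    age_correlation(d, "sti_ms", c("early", "mid"))
  }, 0)
  expect_lt(abs(mean(rs)), 0.2)
})

test_that("the full group-statistics report assembles all pieces", {
  coh <- simulate_cohort_intervals(seed = 99)
  st <- group_stats(coh, measures = c("sti_ms", "irt_ms", "pep_ms"),
                    group_order = c("early", "mid", "late"))
  expect_s3_class(st, "gest_group_stats")
  expect_named(st$tests, c("sti_ms", "irt_ms", "pep_ms"))
  expect_true(all(vapply(st$tests, function(t) t$p >= 0 && t$p <= 1, TRUE)))
  expect_equal(nrow(st$pairwise$sti_ms), 3)
  expect_length(st$correlations$sti_ms, 2)
  out <- utils::capture.output(print(st))
  expect_true(any(grepl("Kruskal", out)))
})
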