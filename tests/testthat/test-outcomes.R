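test_that("time in range counts readings inclusively and matches a counting oracle", {
  expect_equal(time_in_range(rep(6, 288)), 100)
  expect_equal(time_in_range(c(rep(5, 3), rep(12, 9))), 25)
  set.seed(6)
  v <- round(runif(500, 1, 14), 1)
  expect_equal(time_in_range(v, 4, 8),
               sum(v >= 4 & v <= 8) / length(v) * 100)
  expect_equal(time_above(v, 10), sum(v > 10) / length(v) * 100)
  expect_equal(time_below(v, 2.6), sum(v < 2.6) / length(v) * 100)
  expect_error(time_in_range(numeric(0)), "empty")
})

test_that("band percentages partition an edge-free trace", {
  set.seed(7)
  v <- runif(1000, 0.5, 14)
  v <- v[abs(v - 4) > 0.01 & abs(v - 8) > 0.01 &
           abs(v - 10) > 0.01 & abs(v - 2.6) > 0.01]
  mid <- sum(v >= 2.6 & v < 4 | v > 8 & v <= 10) / length(v) * 100
  total <- time_in_range(v, 4, 8) + mid + time_above(v, 10) + time_below(v, 2.6)
  expect_equal(total, 100)
})

test_that("percent of window converts to (rounded) hours as trials report it", {
  h <- percent_to_hours(91, 24)
  expect_equal(unname(h["hours"]), 21.84)
  expect_equal(unname(h["hours_rounded"]), 22)
  expect_equal(unname(percent_to_hours(0, 24)["hours"]), 0)
  expect_equal(unname(percent_to_hours(100, 24)["hours"]), 24)
  expect_error(percent_to_hours(101, 24), "pct")
})

test_that("hypoglycaemia episodes follow run semantics with a duration floor", {
  t5 <- seq(0, 5 * 59, by = 5)
  v <- rep(5, 60)
  v[10:50] <- 2.2 # 41 consecutive readings -> 205 min
  eps <- episodes_below(data.frame(time = t5, value = v))
  expect_equal(nrow(eps), 1)
  expect_equal(eps$duration, 205)
  expect_equal(eps$nadir, 2.2)
  expect_equal(nrow(episodes_below(data.frame(time = t5, value = rep(5, 60)))), 0)
  # two runs separated by a single in-range reading are two episodes
  v2 <- rep(5, 60); v2[10:15] <- 2; v2[17:22] <- 2.3
  eps2 <- episodes_below(data.frame(time = t5, value = v2))
  expect_equal(nrow(eps2), 2)
  # a single low reading (5 min) is below the 10-min floor
  v3 <- rep(5, 60); v3[30] <- 2
  expect_equal(nrow(episodes_below(data.frame(time = t5, value = v3))), 0)
})

test_that("summary statistics match two-pass oracles", {
  s <- summary_stats(c(5, 6, 7))
  expect_equal(unname(s["mean"]), 6)
  expect_equal(unname(s["sd"]), 1)
  expect_equal(unname(summary_stats(rep(4.4, 10))["sd"]), 0)
  set.seed(8)
  v <- rnorm(200, 7, 2)
  s2 <- summary_stats(v)
  expect_equal(unname(s2["mean"]), sum(v) / length(v))
  expect_equal(unname(s2["sd"]),
               sqrt(sum((v - mean(v))^2) / (length(v) - 1)))
})

test_that("median and IQR use type-7 interpolation", {
  expect_equal(unname(median_iqr(1:5)), c(3, 2, 4))
  expect_equal(unname(median_iqr(7.3)), c(7.3, 7.3, 7.3))
  # n = 6 hand computation: h = (n-1)p, linear interpolation
  v <- c(2, 4, 5, 7, 8, 10)
  expect_equal(unname(median_iqr(v)), c(6, 4.25, 7.75))
  expect_error(median_iqr(numeric(0)), "empty")
})

test_that("Mann-Whitney exact path equals full permutation enumeration", {
  mw <- mann_whitney(c(1, 2), c(3, 4))
  expect_equal(mw$U, 0)
  expect_equal(mw$p, 1 / 3, tolerance = 1e-9)
  expect_equal(mw$method, "exact")
  expect_equal(mann_whitney(c(1, 2, 3), c(1, 2, 3))$p, 1)
  set.seed(9)
  for (i in 1:5) {
    nx <- sample(3:8, 1); ny <- sample(3:8, 1)
    x <- round(rnorm(nx, 5, 2), 3); y <- round(rnorm(ny, 6, 2), 3)
    expect_equal(mann_whitney(x, y)$p, perm_mw_p(x, y), tolerance = 1e-9)
  }
  # exact and normal approximation agree closely at n = 8 vs 8
  set.seed(10)
  x <- rnorm(8, 5); y <- rnorm(8, 6)
  exact_p <- mann_whitney(x, y)$p
  approx_p <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                                  correct = TRUE))$p.value
  expect_lt(abs(exact_p - approx_p), 0.02)
  expect_error(mann_whitney(numeric(0), 1), "empty")
})

test_that("pooled t test matches its algebraic closed form", {
  tt <- unpaired_t(c(4, 5, 6), c(1, 2, 3))
  expect_equal(tt$t, 3 / sqrt(2 / 3), tolerance = 1e-9) # pooled SD 1
  expect_equal(tt$df, 4)
  eq <- unpaired_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(eq$t, 0)
  expect_equal(eq$p, 1)
  deg <- unpaired_t(c(2, 2), c(2, 2))
  expect_equal(deg$p, 1)
  # n = 2 vs 2 algebraic oracle
  x <- c(1.2, 2.0); y <- c(3.1, 4.5)
  sp <- sqrt((var(x) + var(y)) / 2)
  t_hand <- (mean(x) - mean(y)) / (sp * sqrt(1 / 2 + 1 / 2))
  p_hand <- 2 * pt(-abs(t_hand), 2)
  res <- unpaired_t(x, y)
  expect_equal(res$t, t_hand, tolerance = 1e-12)
  expect_equal(res$p, p_hand, tolerance = 1e-12)
  expect_error(unpaired_t(1, c(1, 2)), "n >= 2")
})

test_that("outcome table slices the period, needs both arms, ignores infant order", {
  proto <- quiet_protocol(total_h = 76, start_h = 48, window_h = c(48, 72))
  ds <- run_trial(cohort_spec(n = 4), proto, seed = 12)
  tab <- outcome_table(ds, "intervention")
  expect_true(all(c("Time 4.0-8.0 mmol/L (%)", "Mean sensor glucose (mmol/L)")
                  %in% tab$outcome))
  per <- attr(tab, "per_infant")
  expect_equal(attr(tab, "period_h"), c(48, 72))
  # summaries are invariant to infant order
  ds_rev <- ds
  ds_rev$records <- rev(ds_rev$records)
  tab_rev <- outcome_table(ds_rev, "intervention")
  expect_equal(tab$median_closed_loop, tab_rev$median_closed_loop)
  expect_equal(tab$p, tab_rev$p)
  # single-arm dataset is rejected
  ds_one <- ds
  keep <- ds$assignment$id[ds$assignment$arm == "control"]
  ds_one$records <- ds$records[keep]
  expect_error(outcome_table(ds_one, "intervention"), "both arms")
  # post period slices beyond 72 h
  tab_post <- outcome_table(ds, "post")
  expect_equal(attr(tab_post, "period_h")[1], 72)
})

test_that("glycaemic summaries are invariant to a timestamp offset", {
  proto <- quiet_protocol(total_h = 52, start_h = 48, window_h = c(48, 52))
  rec <- run_arm(make_profile(), "closed_loop", proto, seed = 14)
  s1 <- glycaemic_summary(rec, c(48, 52))
  rec2 <- rec
  rec2$rows$time_min <- rec2$rows$time_min + 600
  s2 <- glycaemic_summary(rec2, c(58, 62))
  expect_equal(s1[-(1:2)], s2[-(1:2)], tolerance = 1e-12)
})
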