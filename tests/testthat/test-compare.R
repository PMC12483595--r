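test_that("analysis windows are anchored at induction and clipped with a warning", {
  day <- 86400
  rs <- recording_set(list(rep(1e-6, 10 * day / 60)),
                      acq = acquisition(60), induction_time = 7 * day)
  expect_equal(extract_segment(rs, segment_spec("before")),
               c(345600, 604800))
  expect_equal(extract_segment(rs, segment_spec("after")),
               c(604800, 864000))

  early <- recording_set(list(rep(1e-6, 10 * day / 60)),
                         acq = acquisition(60), induction_time = day)
  expect_warning(win <- extract_segment(early, segment_spec("before")),
                 "clipped")
  expect_equal(win, c(0, 86400))

  none <- recording_set(list(rep(1e-6, 100)))
  expect_error(extract_segment(none, segment_spec("before")), "induction_time")
  expect_equal(extract_segment(none, segment_spec("after", duration = 3,
                                                  reference = "recording_start")),
               c(0, 3))
})

test_that("shapiro_wilk matches the order-statistic correlation form and flags degeneracy", {
  # n = 3 equally spaced data are exactly linear in the normal order
  # statistic means, so W = 1
  res <- shapiro_wilk(c(1, 2, 3))
  expect_equal(res$W, 1, tolerance = 1e-6)

  expect_equal(shapiro_wilk(c(1, 2))$flag, "insufficient n")
  expect_equal(shapiro_wilk(rep(5, 10))$flag, "zero variance")

  # heavy-tailed data score lower than a same-size normal sample
  set.seed(101)
  heavy <- rt(10, df = 1)
  set.seed(101)
  gauss <- rnorm(10)
  expect_lt(shapiro_wilk(heavy)$W, shapiro_wilk(gauss)$W)
})

test_that("welch_t_test matches the direct formulas and their limits", {
  a <- c(1, 2, 3, 4); b <- c(2, 4, 6, 8)
  res <- welch_t_test(a, b)
  se2 <- var(a) / 4 + var(b) / 4
  t_hand <- (mean(a) - mean(b)) / sqrt(se2)
  df_hand <- se2^2 / ((var(a) / 4)^2 / 3 + (var(b) / 4)^2 / 3)
  p_hand <- 2 * pt(-abs(t_hand), df_hand)
  expect_equal(res$t, t_hand, tolerance = 1e-9)
  expect_equal(res$df, df_hand, tolerance = 1e-9)
  expect_equal(res$p, p_hand, tolerance = 1e-9)

  # equal n, equal variance: reduces to Student's df = n_a + n_b - 2
  x <- c(1, 2, 3, 4, 5); y <- c(11, 12, 13, 14, 15)
  expect_equal(welch_t_test(x, y)$df, 8, tolerance = 1e-9)

  # identical groups
  same <- welch_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  # antisymmetry
  fwd <- welch_t_test(a, b); rev <- welch_t_test(b, a)
  expect_equal(fwd$t, -rev$t)
  expect_equal(fwd$df, rev$df)
  expect_equal(fwd$p, rev$p)

  expect_error(welch_t_test(1, c(1, 2)), "at least 2")
  expect_error(welch_t_test(c(2, 2), c(3, 3)), "zero variance")
})

test_that("percent change follows (a/b - 1) * 100", {
  expect_equal(percent_change(5, 4), 25)
  expect_equal(percent_change(3, 3), 0)
  expect_equal(percent_change(1, 2), -50)
  expect_error(percent_change(1, 0), "> 0")
})

test_that("recomputed published percent changes agree within printed precision", {
  tab <- check_published_percent_change()
  expect_equal(nrow(tab), 9)
  # every row agrees once the 5-6 significant figures of the printed means
  # are accounted for
  expect_true(all(tab$within_tolerance))
  expect_true(all(abs(tab$difference) <= 0.005 + 1e-9))
  # the small-ratio rows agree to the printed 3 decimals outright
  small <- abs(tab$percent_change) < 500
  expect_true(all(abs(tab$difference[small]) <= 0.001 + 1e-9))
})

test_that("compare_conditions aggregates groups, tests, and keeps provenance", {
  cfg <- fast_scenario(n_inoculated = 4, n_control = 3, master_seed = 8)
  cl <- drop_missing(simulate_experiment(cfg))
  day <- cfg$day_seconds
  cmp <- suppressWarnings(compare_conditions(
    cl, a = inoculated, b = !inoculated,
    segment = segment_spec("before", duration = 3 * day)
  ))
  expect_s3_class(cmp, "myco_comparison")
  expect_equal(cmp$group_a$n, 4)
  expect_equal(cmp$group_b$n, 3)
  expect_equal(cmp$group_a$mean_power, mean(cmp$group_a$channel_powers))
  expect_equal(cmp$percent_change,
               (cmp$group_a$mean_power / cmp$group_b$mean_power - 1) * 100)
  expect_gt(cmp$percent_change, 0)
  expect_true(cmp$welch$df > 0)
  expect_true(cmp$welch$p >= 0 && cmp$welch$p <= 1)

  gl <- glance(cmp)
  expect_equal(gl$n_a, 4)
  td <- tidy(cmp)
  expect_equal(nrow(td), 2)
  expect_setequal(td$group, c("a", "b"))

  # channel-order invariance
  perm <- cl[rev(seq_len(nrow(cl))), ]
  cmp2 <- suppressWarnings(compare_conditions(
    perm, a = inoculated, b = !inoculated,
    segment = segment_spec("before", duration = 3 * day)
  ))
  expect_equal(cmp2$percent_change, cmp$percent_change)
  expect_equal(cmp2$welch$t, cmp$welch$t)

  expect_error(
    compare_conditions(cl, a = treatment == "cycloheximide", b = !inoculated,
                       segment = segment_spec("before", duration = 3 * day)),
    "empty group a"
  )
})

test_that("single-replicate groups report percent change with flagged tests", {
  cfg <- fast_scenario(n_inoculated = 1, n_control = 1, master_seed = 9)
  cl <- drop_missing(simulate_experiment(cfg))
  cmp <- compare_conditions(cl, a = inoculated, b = !inoculated,
                            segment = segment_spec("before",
                                                   duration = 3 * cfg$day_seconds))
  expect_null(cmp$welch)
  expect_equal(cmp$test_flag, "insufficient replicates")
  expect_true(is.finite(cmp$percent_change))
  expect_equal(cmp$group_a$shapiro$flag, "insufficient n")
})

test_that("comparison reports round-trip through csv and json", {
  cfg <- fast_scenario(master_seed = 10)
  cl <- drop_missing(simulate_experiment(cfg))
  cmp <- suppressWarnings(pool_pre_induction(
    cl, segment = segment_spec("before", duration = 3 * cfg$day_seconds)))
  csv <- withr::local_tempfile(fileext = ".csv")
  js <- withr::local_tempfile(fileext = ".json")
  rows <- write_comparison_report(cmp, csv, js)
  back <- readr::read_csv(csv, show_col_types = FALSE)
  expect_equal(back$percent_change, round(cmp$percent_change, 3))
  expect_equal(back$replicates, sprintf("%d vs %d", cmp$group_a$n, cmp$group_b$n))
  prov <- jsonlite::read_json(js)[[1]]
  expect_equal(prov$percent_change, cmp$percent_change, tolerance = 1e-12)
  expect_setequal(unlist(prov$groups[[1]]$channel_ids), cmp$group_a$channel_ids)
})
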