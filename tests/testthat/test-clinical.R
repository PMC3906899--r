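test_that("onset requires two consecutive days of disease", {
  expect_identical(onset_day(c(0, 0, 1, 1, 2)), 3L)
  expect_identical(onset_day(c(0, 1, 0, 1, 1)), 4L)
  expect_true(is.na(onset_day(rep(0, 30))))
})

test_that("mean day of onset substitutes T+1 for never-diseased mice", {
  mk <- function(s) clinical_course("m", "g", s)
  co <- list(mk(c(0, 0, 1, 1, 1)), mk(c(0, 0, 0, 0, 1)))
  # onsets 3 and none over T=5 -> (3 + 6) / 2
  expect_equal(mean_day_of_onset(co, 5), 4.5)
  ons <- list(mk(c(0, 0, 1, 1)), mk(c(0, 0, 0, 0)))
  expect_equal(mean_day_of_onset(ons, 30), (3 + 31) / 2)  # padded series
  all1 <- list(mk(c(1, 1, 2)), mk(c(1, 1, 1)))
  expect_equal(mean_day_of_onset(all1, 3), 1)
})

test_that("cohort summary matches hand-evaluated definitions", {
  one <- list(clinical_course("m1", "g", c(0, 0, 1, 2, 2)))
  s1 <- cohort_summary(one, 5)
  expect_equal(s1$mean_day_of_onset, 3)
  expect_equal(s1$disease_index, 5 / 3 * 100, tolerance = 1e-10)
  expect_equal(s1$mean_max_score, 2)
  expect_equal(s1$incidence, 1)

  two <- list(clinical_course("m1", "g", c(0, 1, 1, 2, 3, 3)),
              clinical_course("m2", "g", c(0, 0, 0, 1, 1, 2)))
  s2 <- cohort_summary(two, 6)
  expect_equal(s2$mean_day_of_onset, 3)
  expect_equal(s2$disease_index, 7 / 3 * 100, tolerance = 1e-10)
  expect_equal(s2$mean_max_score, 2.5)
  expect_equal(s2$incidence, 1)

  none <- lapply(1:3, function(i)
    clinical_course(paste0("m", i), "g", rep(0, 30)))
  s0 <- cohort_summary(none, 30)
  expect_equal(s0$incidence, 0)
  expect_equal(s0$mean_day_of_onset, 31)
  expect_equal(s0$disease_index, 0)
})

test_that("summary formulas agree with a spreadsheet-style oracle", {
  set.seed(99)
  for (rep in 1:10) {
    n <- sample(3:8, 1)
    t_days <- sample(8:15, 1)
    mat <- matrix(0L, n, t_days)
    for (i in seq_len(n)) {
      if (runif(1) < 0.8) {
        onset <- sample(2:(t_days - 1), 1)
        plateau <- sample(1:4, 1)
        for (d in onset:t_days)
          mat[i, d] <- min(plateau, d - onset + 1)
      }
    }
    if (all(mat == 0)) mat[1, (t_days - 1):t_days] <- 1L
    co <- lapply(seq_len(n), function(i)
      clinical_course(paste0("m", i), "g", mat[i, ]))
    s <- cohort_summary(co, t_days)
    o <- oracle_summary(mat, t_days)
    expect_equal(s$incidence, o$incidence)
    expect_equal(s$mean_day_of_onset, o$mdo)
    expect_equal(s$mean_max_score, o$mean_max)
    expect_equal(s$disease_index, o$di)
  }
})

test_that("ascending slope is fit from mean onset to the first maximum", {
  expect_equal(ascending_slope(c(0, 0, 1, 2, 3, 3, 3), 3), 1)
  expect_equal(ascending_slope(c(0, 0.5, 1.5, 2.5, 2.5), 2), 1)
  # flat after onset: degenerate window extended to 2 days, slope 0
  expect_equal(ascending_slope(c(0, 1, 1, 1), 2), 0)
  # no 2-day window inside the series
  expect_true(is.na(ascending_slope(c(0, 1), 2)))
})

test_that("severity test gives the exact small-sample Mann-Whitney p value", {
  st <- severity_test(c(1, 1, 1, 1), c(4, 4, 4, 4))
  expect_equal(st$p, 2 / choose(8, 4), tolerance = 1e-12)
  expect_identical(st$method, "exact enumeration")
  # symmetric inputs give p = 1
  expect_equal(severity_test(c(2, 3), c(2, 3))$p, 1)
  # large samples fall back to the normal approximation
  set.seed(1)
  big <- severity_test(rnorm(20), rnorm(20))
  expect_identical(big$method, "normal approximation")
  expect_gt(big$p, 0.05)
})

test_that("group comparison covers incidence, severity and onset", {
  mk_cohort <- function(g, onsets, plateau, t_days = 20) {
    lapply(seq_along(onsets), function(i) {
      s <- integer(t_days)
      if (!is.na(onsets[i]))
        for (d in onsets[i]:t_days) s[d] <- min(plateau, d - onsets[i] + 1)
      clinical_course(sprintf("%s%d", g, i), g, s)
    })
  }
  # identical groups: nothing significant
  a <- mk_cohort("a", c(8, 9, 10, 11), 3)
  b <- mk_cohort("b", c(8, 9, 10, 11), 3)
  cmp <- compare_clinical_groups(list(a = a, b = b), 20)
  expect_gt(cmp$incidence$p, 0.05)
  expect_true(all(cmp$severity$p > 0.05))
  expect_gt(cmp$onset$p, 0.05)
  # separated severities
  lo <- mk_cohort("lo", c(8, 9, 10, 11), 1)
  hi <- mk_cohort("hi", c(8, 9, 10, 11), 4)
  cmp2 <- compare_clinical_groups(list(lo = lo, hi = hi), 20)
  expect_lt(cmp2$severity$p[1], 0.05)
  # incidence 4/4 vs 0/4: exact test on the 2x2 table
  sick <- mk_cohort("s", c(5, 6, 7, 8), 2)
  well <- mk_cohort("w", c(NA, NA, NA, NA), 2)
  cmp3 <- compare_clinical_groups(list(s = sick, w = well), 20)
  # oracle: hypergeometric enumeration of the 2x2 table
  p_exact <- 2 * dhyper(4, 4, 4, 4)
  expect_equal(cmp3$incidence$p, p_exact, tolerance = 1e-10)
  expect_lt(cmp3$incidence$p, 0.05)
  expect_error(compare_clinical_groups(list(a = a), 20), "2 groups")
  expect_error(compare_clinical_groups(list(a = a, b = b[1]), 20), "2 mice")
})

test_that("score validation enforces the integer 0-5 scale and absorbing death", {
  expect_error(clinical_course("m", "g", c(0, 0.5, 1)), "integers")
  expect_error(clinical_course("m", "g", c(0, 6)), "0..5")
  expect_error(clinical_course("m", "g", c(0, 5, 4)), "absorbing")
  ok <- clinical_course("m", "g", c(0, 1, 5, 5))
  expect_s3_class(ok, "clinical_course")
})

test_that("simulated cohorts are seeded and reproduce the profile orderings", {
  a <- simulate_cohort("wt", 10, 30, seed = 5)
  b <- simulate_cohort("wt", 10, 30, seed = 5)
  expect_identical(lapply(a, `[[`, "scores"), lapply(b, `[[`, "scores"))
  wt <- cohort_summary(simulate_cohort("wt", 50, 30, seed = 2), 30)
  endo <- cohort_summary(simulate_cohort("endo_ko", 50, 30, seed = 2), 30)
  astro <- cohort_summary(simulate_cohort("astro_ko", 50, 30, seed = 2), 30)
  expect_gt(endo$mean_day_of_onset, wt$mean_day_of_onset)
  expect_lt(astro$mean_max_score, wt$mean_max_score)
})

test_that("long-format score CSVs are parsed into cohorts", {
  df <- data.frame(
    mouse_id = rep(c("m1", "m2"), each = 4),
    group = "wt",
    day = rep(1:4, 2),
    score = c(0, 1, 1, 2, 0, 0, 1, 1))
  f <- tempfile(fileext = ".csv")
  write.csv(df, f, row.names = FALSE)
  co <- read_scores_csv(f)
  expect_identical(names(co), "wt")
  expect_identical(length(co$wt), 2L)
  expect_identical(onset_day(co$wt[[1]]), 2L)
  unlink(f)
})
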