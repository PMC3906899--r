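#' A single mouse's EAE clinical course
#'
#' Daily clinical scores on the standard 0-5 EAE paralysis scale
#' (0 = normal, 1 = tail limpness, 2 = limp tail and hind-leg weakness,
#' 3 = complete hind-leg paralysis, 4 = partial front-leg paralysis,
#' 5 = death). Scores must be integers; once a score of 5 occurs all
#' later days must be 5 (death is absorbing).
#'
#' @param mouse_id,group labels.
#' @param scores integer vector of daily scores for days `1..T`.
#' @return an object of class `clinical_course`.
#' @export
clinical_course <- function(mouse_id, group, scores) {
  scores <- as.numeric(scores)
  if (length(scores) < 1L) stopf("scores must cover at least one day")
  if (any(scores != round(scores)))
    stopf("scores must be integers on the 0-5 scale (half points are not part of the scale)")
  if (any(scores < 0 | scores > 5)) stopf("scores must lie in 0..5")
  dead <- which(scores == 5)
  if (length(dead) && any(scores[dead[1]:length(scores)] != 5))
    stopf("death (score 5) is absorbing: later scores must remain 5")
  structure(list(mouse_id = as.character(mouse_id),
                 group = as.character(group),
                 scores = as.integer(scores)),
            class = "clinical_course")
}

#' Day of disease onset
#'
#' The first day on which a clinical score >= 1 is observed and
#' maintained on the following day (two consecutive days rule). An
#' isolated single day of disease does not count.
#'
#' @param course a [clinical_course()] or a bare score vector.
#' @return the onset day, or `NA` if the mouse never shows disease.
#' @export
onset_day <- function(course) {
  s <- if (inherits(course, "clinical_course")) course$scores else course
  n <- length(s)
  if (n < 2L) return(NA_integer_)
  hit <- which(s[-n] >= 1 & s[-1] >= 1)
  if (length(hit)) hit[1] else NA_integer_
}

#' Mean day of onset for a cohort
#'
#' Average onset day across mice. A mouse that never shows disease is
#' counted, by convention, as having onset one day after the last day of
#' the experiment (`last_day + 1`).
#'
#' @param cohort list of [clinical_course()] objects.
#' @param last_day last experimental day T.
#' @return mean day of onset.
#' @export
mean_day_of_onset <- function(cohort, last_day) {
  if (!length(cohort)) stopf("cohort is empty")
  onsets <- vapply(cohort, onset_day, integer(1))
  onsets[is.na(onsets)] <- last_day + 1L
  mean(onsets)
}

#' Ascending slope of the mean clinical curve
#'
#' Ordinary least-squares slope of the cohort's daily mean score versus
#' day, over the window from `ceiling(mean_onset)` through the first day
#' the series attains its maximum. If the maximum is already attained at
#' the window start, the window is extended to two days so a flat
#' post-onset course yields slope 0; if no 2-day window fits inside the
#' series the slope is undefined (`NA`).
#'
#' @param daily_mean_scores numeric vector of daily cohort-mean scores
#'   (day 1 first).
#' @param mean_onset mean day of onset (see [mean_day_of_onset()]).
#' @return slope in score/day, or `NA` if undefined.
#' @export
ascending_slope <- function(daily_mean_scores, mean_onset) {
  y <- as.numeric(daily_mean_scores)
  n <- length(y)
  start <- ceiling(mean_onset)
  if (start >= n || start < 1) return(NA_real_)
  end <- which.max(y)
  if (end <= start) end <- start + 1L
  if (end > n) return(NA_real_)
  days <- start:end
  unname(coef(lm(y[days] ~ days))[2])
}

#' Cohort summary of EAE clinical parameters
#'
#' Disease incidence (fraction of mice with an onset), mean day of onset
#' (never-diseased mice substituted at `last_day + 1`), mean maximum
#' clinical score (average of per-mouse maxima), disease index
#' (100 x sum of daily cohort-average scores / mean day of onset), and
#' the ascending slope of the mean clinical curve.
#'
#' @param cohort list of [clinical_course()] objects with equal-length
#'   score series.
#' @param last_day last experimental day T; defaults to the series
#'   length.
#' @return an object of class `cohort_summary`.
#' @export
cohort_summary <- function(cohort, last_day = NULL) {
  if (!length(cohort)) stopf("cohort is empty")
  lens <- vapply(cohort, function(cc) length(cc$scores), integer(1))
  if (length(unique(lens)) != 1L)
    stopf("all mice must have equal-length score series")
  t_days <- lens[1]
  if (is.null(last_day)) last_day <- t_days
  onsets <- vapply(cohort, onset_day, integer(1))
  incidence <- mean(!is.na(onsets))
  mdo <- mean_day_of_onset(cohort, last_day)
  maxima <- vapply(cohort, function(cc) max(cc$scores), integer(1))
  mat <- do.call(rbind, lapply(cohort, function(cc) cc$scores))
  daily_means <- colMeans(mat)
  structure(list(
    incidence = incidence,
    mean_day_of_onset = mdo,
    mean_max_score = mean(maxima),
    disease_index = 100 * sum(daily_means) / mdo,
    ascending_slope = ascending_slope(daily_means, mdo),
    daily_mean_scores = daily_means,
    n_mice = length(cohort),
    last_day = last_day), class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("<cohort_summary> n = %d mice, %d days\n", x$n_mice, x$last_day))
  cat(sprintf("  incidence          %.2f\n", x$incidence))
  cat(sprintf("  mean day of onset  %.2f\n", x$mean_day_of_onset))
  cat(sprintf("  mean max score     %.2f\n", x$mean_max_score))
  cat(sprintf("  disease index      %.2f\n", x$disease_index))
  cat(sprintf("  ascending slope    %.3f score/day\n", x$ascending_slope))
  invisible(x)
}

# Exact two-sided Mann-Whitney p value by full enumeration of group
# assignments (valid with ties); used for small samples.
mw_exact_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  rk <- rank(pooled)
  u_obs <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- combn(n1 + n2, n1)
  udist <- apply(combs, 2, function(ix) sum(rk[ix]) - n1 * (n1 + 1) / 2)
  lo <- min(u_obs, n1 * n2 - u_obs)
  hi <- max(u_obs, n1 * n2 - u_obs)
  min(1, mean(udist <= lo) + mean(udist >= hi))
}

#' Pairwise Mann-Whitney test on disease severity
#'
#' Compares per-mouse maximum clinical scores between two groups. With
#' at most 8 mice per group the two-sided p value is computed exactly by
#' enumerating all group assignments (ties handled by mid-ranks);
#' otherwise the normal approximation with tie correction is used.
#'
#' @param x,y numeric severity values (per-mouse maxima) per group.
#' @return list with `U`, `p`, `method`.
#' @export
severity_test <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  rk <- rank(c(x, y))
  u <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (n1 <= 8L && n2 <= 8L) {
    list(U = u, p = mw_exact_p(x, y), method = "exact enumeration")
  } else {
    wt <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = TRUE))
    list(U = u, p = wt$p.value, method = "normal approximation")
  }
}

#' Group comparison of clinical EAE parameters
#'
#' The conventional battery of tests: chi-squared on disease incidence
#' (2 x k contingency of diseased vs not; Fisher's exact test is used
#' when any expected count is below 5), pairwise Mann-Whitney on
#' per-mouse maximum scores (disease severity), and one-way ANOVA with
#' Bonferroni-adjusted pairwise t tests on onset days (never-diseased
#' mice substituted at `last_day + 1`). Significance is conventionally
#' read at p <= 0.05.
#'
#' @param cohorts named list mapping group label to a list of
#'   [clinical_course()] objects (>= 2 groups of >= 2 mice).
#' @param last_day last experimental day T.
#' @return an object of class `clinical_comparison`.
#' @export
compare_clinical_groups <- function(cohorts, last_day) {
  if (length(cohorts) < 2L) stopf("need at least 2 groups")
  sizes <- lengths(cohorts)
  if (any(sizes < 2L)) stopf("every group needs at least 2 mice")
  groups <- names(cohorts)

  diseased <- vapply(cohorts, function(co)
    sum(!is.na(vapply(co, onset_day, integer(1)))), numeric(1))
  tab <- rbind(diseased = diseased, healthy = sizes - diseased)
  expected_ok <- all(outer(rowSums(tab), colSums(tab)) / sum(tab) >= 5)
  if (all(rowSums(tab) > 0) && expected_ok) {
    ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
    incidence <- list(p = ct$p.value, statistic = unname(ct$statistic),
                      method = "chi-squared")
  } else {
    ft <- fisher.test(tab)
    incidence <- list(p = ft$p.value, statistic = NA_real_,
                      method = "Fisher exact")
  }

  maxima <- lapply(cohorts, function(co)
    vapply(co, function(cc) max(cc$scores), integer(1)))
  sev <- list()
  for (i in seq_along(groups)) for (j in seq_along(groups)) {
    if (j <= i) next
    st <- severity_test(maxima[[i]], maxima[[j]])
    sev[[length(sev) + 1L]] <- data.frame(
      group_a = groups[i], group_b = groups[j], U = st$U, p = st$p,
      method = st$method, stringsAsFactors = FALSE)
  }
  severity <- do.call(rbind, sev)

  onset_df <- do.call(rbind, lapply(groups, function(g) {
    on <- vapply(cohorts[[g]], onset_day, integer(1))
    on[is.na(on)] <- last_day + 1L
    data.frame(group = g, onset = on, stringsAsFactors = FALSE)
  }))
  onset_df$group <- factor(onset_df$group)
  fit <- aov(onset ~ group, data = onset_df)
  an <- summary(fit)[[1]]
  pw <- pairwise.t.test(onset_df$onset, onset_df$group,
                        p.adjust.method = "bonferroni", pool.sd = TRUE)
  structure(list(
    incidence = incidence,
    severity = severity,
    onset = list(F = an[["F value"]][1], df = unname(an[["Df"]]),
                 p = an[["Pr(>F)"]][1], pairwise = pw$p.value),
    alpha = 0.05), class = "clinical_comparison")
}

#' @export
print.clinical_comparison <- function(x, ...) {
  cat("Clinical group comparison\n")
  cat(sprintf("  incidence: %s p = %.4g\n", x$incidence$method, x$incidence$p))
  cat("  severity (Mann-Whitney on per-mouse maxima):\n")
  print(x$severity, row.names = FALSE)
  cat(sprintf("  onset: ANOVA F(%d, %d) = %.3f, p = %.4g\n",
              x$onset$df[1], x$onset$df[2], x$onset$F, x$onset$p))
  invisible(x)
}

#' Simulate an EAE cohort under a named disease profile
#'
#' Seeded stochastic score trajectories emulating the qualitative
#' phenotypes of wild-type and the two conditional CCL2-knockout
#' regimes: per-mouse onset day drawn from a profile-specific normal
#' distribution, scores ramping at a profile rate to a profile plateau.
#' The wild-type and endothelial-knockout profiles share plateau and
#' ramp rate but the latter has delayed onset; the astrocyte-knockout
#' profile has a lower plateau and a slower ramp. Induction is modelled
#' as fully penetrant (every mouse develops disease), matching the
#' near-complete incidence of active-immunisation EAE and keeping the
#' onset-window metrics undistorted by the never-diseased substitution
#' rule.
#'
#' @param profile `"wt"`, `"astro_ko"` or `"endo_ko"`.
#' @param n_mice number of mice (>= 1).
#' @param last_day last experimental day T.
#' @param seed integer seed.
#' @return a list of [clinical_course()] objects.
#' @export
simulate_cohort <- function(profile = c("wt", "astro_ko", "endo_ko"),
                            n_mice, last_day = 30L, seed = 1L) {
  profile <- match.arg(profile)
  if (n_mice < 1L) stopf("n_mice must be >= 1")
  par <- switch(profile,
    wt       = list(onset_mean = 11, onset_sd = 1.5, ramp = 0.6,
                    plateau = 3.5, plateau_sd = 0.5),
    astro_ko = list(onset_mean = 12, onset_sd = 1.5, ramp = 0.3,
                    plateau = 2.0, plateau_sd = 0.4),
    endo_ko  = list(onset_mean = 16, onset_sd = 1.5, ramp = 0.6,
                    plateau = 3.3, plateau_sd = 0.5))
  set.seed(seed)
  cohort <- vector("list", n_mice)
  for (i in seq_len(n_mice)) {
    scores <- integer(last_day)
    {
      onset <- max(2L, round(rnorm(1, par$onset_mean, par$onset_sd)))
      plateau <- min(4, max(1, rnorm(1, par$plateau, par$plateau_sd)))
      for (d in seq_len(last_day)) {
        if (d < onset) next
        latent <- min(plateau, par$ramp * (d - onset + 1))
        scores[d] <- max(1L, as.integer(round(latent)))
      }
    }
    cohort[[i]] <- clinical_course(sprintf("m%03d", i), profile, scores)
  }
  cohort
}

#' Read clinical scores from a long-format CSV
#'
#' Expects columns `mouse_id`, `group`, `day`, `score`. Scores must be
#' integers on the 0-5 scale; days must form a complete 1..T series per
#' mouse.
#'
#' @param path CSV path.
#' @return named list mapping group label to a list of
#'   [clinical_course()] objects.
#' @export
read_scores_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("mouse_id", "group", "day", "score")
  if (!all(need %in% names(df)))
    stopf("scores CSV needs columns %s", paste(need, collapse = ", "))
  out <- list()
  for (g in unique(df$group)) {
    sub <- df[df$group == g, ]
    courses <- lapply(split(sub, sub$mouse_id), function(mm) {
      mm <- mm[order(mm$day), ]
      if (!identical(as.integer(mm$day), seq_len(nrow(mm))))
        stopf("mouse '%s': days must form a complete 1..T series",
              mm$mouse_id[1])
      clinical_course(mm$mouse_id[1], g, mm$score)
    })
    out[[g]] <- unname(courses)
  }
  out
}
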