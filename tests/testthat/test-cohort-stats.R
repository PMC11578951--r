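# Exclusion cascade, improvement rate, summary-statistic tests,
# covariate-adjusted screening and outcome correlations.

make_candidates <- function(n = 50, flags = c(5, 2, 1, 3)) {
  df <- data.frame(subject_id = sprintf("c%02d", seq_len(n)),
                   excl_no_surgery = FALSE, excl_unilateral = FALSE,
                   excl_lesion = FALSE, excl_missing_data = FALSE)
  idx <- seq_len(sum(flags))
  df$excl_no_surgery[idx[1:flags[1]]] <- TRUE
  df$excl_unilateral[idx[flags[1] + 1:flags[2]]] <- TRUE
  df$excl_lesion[idx[flags[1] + flags[2] + 1:flags[3]]] <- TRUE
  df$excl_missing_data[idx[flags[1] + flags[2] + flags[3] + 1:flags[4]]] <- TRUE
  df
}

test_that("the exclusion cascade removes flagged candidates in order", {
  res <- cohort_filter(make_candidates())
  expect_equal(nrow(res$retained), 39)
  expect_equal(res$ledger$n_excluded, c(5L, 2L, 1L, 3L))

  clean <- cohort_filter(make_candidates(flags = c(0, 0, 0, 0)))
  expect_equal(nrow(clean$retained), 50)

  all_bad <- make_candidates(n = 4, flags = c(1, 1, 1, 1))
  res2 <- cohort_filter(all_bad)
  expect_equal(nrow(res2$retained), 0)
  expect_equal(sum(res2$ledger$n_excluded), 4)
})

test_that("improvement rate is the percent UPDRS-III reduction", {
  expect_equal(improvement_rate(40, 40), 0)
  expect_equal(improvement_rate(40, 0), 100)
  expect_equal(improvement_rate(40, 60), -50)  # worsening allowed
  expect_equal(round(improvement_rate(55.95, 17.54), 2), 68.65)
  expect_error(improvement_rate(0, 10), "positive")
})

test_that("pooled-variance t reproduces printed group comparisons", {
  expect_equal(pooled_t_from_summary(5, 1, 10, 5, 2, 12)$t, 0)

  # motor scores, surgical-target comparison (printed summaries as inputs)
  pre <- pooled_t_from_summary(56.08, 15.83, 24, 55.73, 17.76, 15)
  expect_equal(round(pre$abs_t, 3), 0.064)
  expect_equal(pre$df, 37)
  stim <- pooled_t_from_summary(16.96, 11.00, 24, 18.47, 9.32, 15)
  expect_equal(round(stim$abs_t, 3), 0.441)

  expect_error(pooled_t_from_summary(1, 0, 5, 2, 0, 5), "zero pooled")
  expect_equal(pooled_t_from_summary(3, 0, 5, 3, 0, 5)$t, 0)
})

test_that("2x2 chi-square without continuity correction matches hand values", {
  expect_equal(round(chisq_2x2(matrix(c(21, 8, 18, 21), 2))$chisq, 3), 4.689)
  expect_equal(round(chisq_2x2(matrix(c(12, 9, 12, 6), 2))$chisq, 3), 0.371)
  expect_equal(chisq_2x2(matrix(c(10, 10, 10, 10), 2))$chisq, 0)
  expect_error(chisq_2x2(matrix(c(0, 0, 5, 5), 2)), "margin")
})

test_that("covariate-adjusted group comparison behaves at the null and under confounding", {
  set.seed(31)
  v <- rnorm(20)
  same <- ancova_region(v, v)
  expect_lt(same$F, 1e-20)
  expect_equal(same$p, 1, tolerance = 1e-10)

  # group effect carried entirely by age vanishes after adjustment
  n <- 40
  age_pd <- rnorm(n, 65, 5); age_hc <- rnorm(n, 55, 5)
  y_pd <- 0.05 * age_pd + rnorm(n, sd = 0.1)
  y_hc <- 0.05 * age_hc + rnorm(n, sd = 0.1)
  sexes <- sample(c("male", "female"), n, replace = TRUE)
  unadj <- ancova_region(y_pd, y_hc)
  adj <- ancova_region(y_pd, y_hc,
                       data.frame(age = age_pd, sex = sexes),
                       data.frame(age = age_hc, sex = sexes))
  expect_gt(unadj$F, 10)
  expect_lt(adj$F, unadj$F / 5)

  shifted <- ancova_region(v + 1, v)
  expect_equal(shifted$direction, "+")
  expect_equal(ancova_region(v - 1, v)$direction, "-")
})

test_that("adjusted group test rejects at a rate matching analytic power", {
  set.seed(32)
  d <- 0.3; n1 <- 39; n2 <- 29
  reps <- 400
  rej <- mean(replicate(reps, {
    a <- ancova_region(rnorm(n1, d), rnorm(n2))
    a$p < 0.05
  }))
  ncp <- d^2 * n1 * n2 / (n1 + n2)
  power <- 1 - pf(qf(0.95, 1, n1 + n2 - 2), 1, n1 + n2 - 2, ncp)
  se <- sqrt(power * (1 - power) / reps)
  expect_lt(abs(rej - power), 3.5 * se)
})

test_that("paired medication test handles null, degenerate and shifted cases", {
  x <- rnorm(10)
  null <- paired_t_region(x, x)
  expect_equal(null$t, 0)
  expect_equal(null$p, 1)

  expect_error(paired_t_region(x + 2, x), "zero variance")
  expect_error(paired_t_region(x[1:2], x[1:2]), "3 pairs")

  # mean t over replicates approximates the noncentral-t expectation
  set.seed(33)
  n <- 30; reps <- 500
  ts <- replicate(reps, {
    d <- rnorm(n, 0.2, 1)
    paired_t_region(d, rep(0, n))$t
  })
  df <- n - 1
  expected <- 0.2 * sqrt(n) * sqrt(df / 2) * gamma((df - 1) / 2) / gamma(df / 2)
  expect_lt(abs(mean(ts) - expected), 3.5 * sd(ts) / sqrt(reps))
})

test_that("the intersection rule keeps only doubly significant regions", {
  scr <- data.frame(
    label = c("A.L", "B.L", "C.L", "D.L"), metric = "ac",
    group_F = c(9, 9, 1, 9), group_p = c(0.01, 0.01, 0.6, 0.2),
    direction = "-", med_t = c(3, 0.5, 3, 3),
    med_p = c(0.01, 0.7, 0.01, 0.01), n_pairs = 20)
  out <- select_responsive_regions(scr, alpha = 0.05)
  expect_equal(out$label, "A.L")  # B: paired ns; C: group ns; D: group ns
  expect_true(all(out$responsive))

  none <- scr; none$group_p <- 0.9
  expect_equal(nrow(select_responsive_regions(none)), 0)

  # FDR correction can only shrink the uncorrected list
  marginal <- scr
  marginal$group_p <- c(0.04, 0.045, 0.048, 0.049)
  marginal$med_p <- 0.01
  un <- select_responsive_regions(marginal)
  fdr <- select_responsive_regions(marginal, correction = "fdr")
  expect_equal(nrow(un), 4)
  expect_true(all(fdr$label %in% un$label))
})

test_that("delta-outcome correlations recover exact and null relations", {
  set.seed(34)
  subjects <- sprintf("s%02d", 1:12)
  labs <- c("THA.L", "THA.R")
  deltas <- expand.grid(subject_id = subjects, label = labs,
                        stringsAsFactors = FALSE)
  deltas$delta_ac <- rnorm(nrow(deltas))
  deltas$delta_mc <- rnorm(nrow(deltas))
  imp <- setNames(
    -3 * deltas$delta_ac[deltas$label == "THA.L"][
      match(subjects, deltas$subject_id[deltas$label == "THA.L"])] + 50,
    subjects)
  tab <- correlate_delta_outcome(deltas, imp, roi_labels = labs)
  row <- tab[tab$label == "THA.L" & tab$metric == "ac", ]
  expect_equal(row$r, -1, tolerance = 1e-10)
  expect_true(row$significant)

  # zero-variance delta is reported, not dropped
  deltas2 <- deltas
  deltas2$delta_mc[deltas2$label == "THA.R"] <- 0
  tab2 <- correlate_delta_outcome(deltas2, imp, roi_labels = labs)
  bad <- tab2[tab2$label == "THA.R" & tab2$metric == "mc", ]
  expect_false(bad$defined)

  expect_error(correlate_delta_outcome(deltas[deltas$subject_id %in%
                                                subjects[1:3], ], imp[1:3],
                                       roi_labels = labs), "5 subjects")
})

test_that("outcome-correlation type-I error is near nominal under independence", {
  set.seed(35)
  reps <- 300
  hits <- replicate(reps, {
    subjects <- sprintf("s%02d", 1:20)
    deltas <- data.frame(subject_id = subjects, label = "THA.L",
                         delta_ac = rnorm(20), delta_mc = rnorm(20))
    imp <- setNames(rnorm(20), subjects)
    tab <- suppressWarnings(
      correlate_delta_outcome(deltas, imp, roi_labels = "THA.L"))
    tab$p[tab$metric == "ac"] < 0.05
  })
  rate <- mean(hits)
  expect_lt(abs(rate - 0.05), 3.5 * sqrt(0.05 * 0.95 / reps))
})
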