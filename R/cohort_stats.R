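# Cohort-level statistics: exclusion cascade, clinical improvement rate,
# demographic comparisons from summary statistics, covariate-adjusted
# group screening, paired medication tests, the responsive-region
# intersection rule, and delta-controllability/outcome correlations.

#' Apply the recruitment exclusion cascade
#'
#' Removes flagged candidates in a fixed order (no surgery, unilateral
#' implantation, lesion procedure, missing imaging/clinical data) and
#' returns the retained records together with an exclusion ledger.
#'
#' @param candidates Data frame with logical columns `excl_no_surgery`,
#'   `excl_unilateral`, `excl_lesion`, `excl_missing_data` (missing
#'   columns are treated as all-FALSE).
#' @return List with `retained` (filtered data frame) and `ledger`
#'   (data frame of reason/count in exclusion order).
#' @export
cohort_filter <- function(candidates) {
  reasons <- c(excl_no_surgery = "no surgery",
               excl_unilateral = "unilateral implantation",
               excl_lesion = "radio-frequency lesion",
               excl_missing_data = "missing images or incomplete clinical data")
  kept <- candidates
  ledger <- data.frame(reason = unname(reasons),
                       n_excluded = 0L, stringsAsFactors = FALSE)
  for (i in seq_along(reasons)) {
    col <- names(reasons)[i]
    flag <- if (col %in% names(kept)) isTRUE_vec(kept[[col]]) else
      rep(FALSE, nrow(kept))
    ledger$n_excluded[i] <- sum(flag)
    kept <- kept[!flag, , drop = FALSE]
  }
  list(retained = kept, ledger = ledger)
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)

#' Percent motor improvement after stimulation
#'
#' `improvement = (pre - post) / pre * 100`, the percent reduction of
#' the UPDRS-III motor score from the preoperative medication-off state
#' to the postoperative medication-off/stimulation-on state. Negative
#' values (worsening) are allowed; the value cannot exceed 100 while
#' `post >= 0`.
#'
#' @param pre_off Preoperative medication-off score (> 0).
#' @param post_off_stim_on Postoperative off/stimulation-on score.
#' @return Improvement rate in percent.
#' @export
improvement_rate <- function(pre_off, post_off_stim_on) {
  if (any(pre_off <= 0)) stop("preoperative score must be positive")
  (pre_off - post_off_stim_on) / pre_off * 100
}

#' Pooled-variance two-sample t from summary statistics
#'
#' Classical equal-variance two-sample t computed from printed group
#' means, SDs and sizes, with `df = n1 + n2 - 2` and a two-sided p; the
#' absolute t is reported alongside the signed one to match unsigned
#' table conventions.
#'
#' @param m1,s1,n1 Mean, SD, size of group 1.
#' @param m2,s2,n2 Mean, SD, size of group 2.
#' @return List with `t`, `abs_t`, `df`, `p`.
#' @export
pooled_t_from_summary <- function(m1, s1, n1, m2, s2, n2) {
  if (n1 < 2 || n2 < 2) stop("both groups need n >= 2")
  if (s1 < 0 || s2 < 0) stop("SDs must be nonnegative")
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / df
  if (sp2 == 0) {
    if (m1 == m2) return(list(t = 0, abs_t = 0, df = df, p = 1))
    stop("zero pooled variance with unequal means: t undefined")
  }
  t <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = t, abs_t = abs(t), df = df,
       p = 2 * stats::pt(-abs(t), df))
}

#' Pearson chi-square for a 2x2 table, no continuity correction
#'
#' @param counts 2x2 matrix of nonnegative integer counts with positive
#'   margins.
#' @return List with `chisq`, `df` (1), `p`.
#' @export
chisq_2x2 <- function(counts) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(2, 2))) stop("counts must be a 2x2 table")
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be nonnegative integers")
  }
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    stop("all margins must be positive")
  }
  res <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  list(chisq = unname(res$statistic), df = 1L, p = res$p.value)
}

#' Covariate-adjusted group comparison for one region's controllability
#'
#' Linear-model analysis of covariance `value ~ group + age + sex`; the
#' F statistic and p value are the marginal (adjusted) test of the group
#' term, and the direction is the sign of the adjusted patient-minus-
#' control difference.
#'
#' @param pd_values,hc_values Controllability values per subject.
#' @param pd_covariates,hc_covariates Data frames with columns `age`
#'   and `sex` aligned with the value vectors; pass `NULL` for an
#'   unadjusted comparison.
#' @return List with `F`, `p`, `direction` (`"+"`/`"-"`), `n`.
#' @export
ancova_region <- function(pd_values, hc_values,
                          pd_covariates = NULL, hc_covariates = NULL) {
  y <- c(pd_values, hc_values)
  group <- factor(rep(c("patient", "control"),
                      c(length(pd_values), length(hc_values))),
                  levels = c("control", "patient"))
  dat <- data.frame(y = y, group = group)
  if (!is.null(pd_covariates)) {
    cov <- rbind(as.data.frame(pd_covariates), as.data.frame(hc_covariates))
    dat <- cbind(dat, cov)
    form <- y ~ group + age + sex
    if (length(unique(dat$sex)) < 2) form <- y ~ group + age
    fit <- stats::lm(form, data = dat)
  } else {
    fit <- stats::lm(y ~ group, data = dat)
  }
  dr <- stats::drop1(fit, scope = ~group, test = "F")
  Fv <- dr[["F value"]][2]
  pv <- dr[["Pr(>F)"]][2]
  direction <- if (stats::coef(fit)[["grouppatient"]] >= 0) "+" else "-"
  list(F = Fv, p = pv, direction = direction, n = length(y))
}

#' Paired t-test of medication-on vs medication-off controllability
#'
#' Standard paired t on `on - off` differences (two-sided). The
#' degenerate case of identical nonzero differences with zero variance
#' is rejected with a diagnostic rather than returning an infinite t.
#'
#' @param on_values,off_values Paired per-subject values.
#' @return List with `t`, `df`, `p`, `mean_diff`, `n`.
#' @export
paired_t_region <- function(on_values, off_values) {
  if (length(on_values) != length(off_values)) stop("pairs must align")
  d <- on_values - off_values
  n <- length(d)
  if (n < 3) stop("need at least 3 pairs")
  sdd <- stats::sd(d)
  md <- mean(d)
  if (sdd < 1e-12 * max(1, abs(md))) {
    if (md == 0) return(list(t = 0, df = n - 1, p = 1, mean_diff = 0, n = n))
    stop("all differences identical (", format(md),
         "): paired t undefined with zero variance")
  }
  t <- md / (sdd / sqrt(n))
  list(t = t, df = n - 1, p = 2 * stats::pt(-abs(t), n - 1),
       mean_diff = md, n = n)
}

#' Screen every region and metric of a cohort's controllability profiles
#'
#' Runs [ancova_region()] (patient-off vs control, age/sex adjusted) and
#' [paired_t_region()] (on vs off in patients with both sessions) for
#' every node and both metrics.
#'
#' @param profiles Data frame of stacked controllability profiles
#'   (columns `subject_id`, `session`, `label`, `ac`, `mc`).
#' @param records Clinical data frame with `subject_id`, `cohort`,
#'   `age`, `sex`.
#' @return Data frame with one row per label x metric: `group_F`,
#'   `group_p`, `direction`, `med_t`, `med_p`, `n_pairs`.
#' @export
screen_regions <- function(profiles, records) {
  labels <- unique(profiles$label)
  rec <- records[match(profiles$subject_id, records$subject_id), ]
  is_pat <- rec$cohort == "patient"
  out <- list()
  for (metric in c("ac", "mc")) {
    for (lab in labels) {
      sel <- profiles$label == lab
      pd_off <- sel & is_pat & profiles$session == "off"
      hc <- sel & !is_pat
      an <- ancova_region(
        profiles[[metric]][pd_off], profiles[[metric]][hc],
        data.frame(age = rec$age[pd_off], sex = rec$sex[pd_off]),
        data.frame(age = rec$age[hc], sex = rec$sex[hc]))
      on_rows <- profiles[sel & is_pat & profiles$session == "on", ]
      off_rows <- profiles[profiles$label == lab & is_pat &
                             profiles$session == "off", ]
      both <- intersect(on_rows$subject_id, off_rows$subject_id)
      pt <- if (length(both) >= 3) {
        paired_t_region(
          on_rows[[metric]][match(both, on_rows$subject_id)],
          off_rows[[metric]][match(both, off_rows$subject_id)])
      } else list(t = NA_real_, p = NA_real_, n = length(both))
      out[[length(out) + 1L]] <- data.frame(
        label = lab, metric = metric,
        group_F = an$F, group_p = an$p, direction = an$direction,
        med_t = pt$t, med_p = pt$p, n_pairs = pt$n,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Intersection rule for medication-responsive aberrant regions
#'
#' A region/metric is "responsive" when the covariate-adjusted group
#' difference (patient-off vs control) and the paired medication change
#' are both significant at `alpha` (uncorrected).
#'
#' @param screen A [screen_regions()] table (or separate ancova/paired
#'   tables sharing `label` and `metric` columns).
#' @param alpha Significance level (default 0.05).
#' @param correction `"none"` (default, matching the uncorrected
#'   convention of the clinical screening this mirrors) or `"fdr"`
#'   (Benjamini-Hochberg within each test family).
#' @return The subset of rows with `responsive = TRUE` added.
#' @export
select_responsive_regions <- function(screen, alpha = 0.05,
                                      correction = c("none", "fdr")) {
  correction <- match.arg(correction)
  gp <- screen$group_p
  mp <- screen$med_p
  if (correction == "fdr") {
    gp <- stats::p.adjust(gp, method = "BH")
    mp <- stats::p.adjust(mp, method = "BH")
  }
  resp <- !is.na(gp) & gp < alpha & !is.na(mp) & mp < alpha
  out <- screen[resp, , drop = FALSE]
  if (nrow(out) > 0) out$responsive <- TRUE
  out
}

#' Correlate delta controllability with motor improvement
#'
#' Pearson correlation, with two-sided p, between each selected
#' region/metric delta and the percent UPDRS-III improvement, across the
#' subjects of one surgical group. The default region set is the eight
#' a-priori motor structures (caudate, putamen, pallidum, thalamus,
#' precentral and postcentral gyri, supplementary motor area,
#' paracentral lobule), both hemispheres, both metrics.
#'
#' @param deltas Data frame of stacked delta profiles (columns
#'   `subject_id`, `label`, `delta_ac`, `delta_mc`).
#' @param improvements Named numeric vector of improvement rates
#'   (names = subject ids).
#' @param roi_labels Node labels to test; default the 16 motor-ROI
#'   labels.
#' @param alpha Flagging threshold (uncorrected).
#' @return Data frame with `label`, `metric`, `r`, `p`, `n`,
#'   `significant`, `defined`.
#' @export
correlate_delta_outcome <- function(deltas, improvements,
                                    roi_labels = NULL, alpha = 0.05) {
  if (is.null(roi_labels)) {
    atlas <- aal90_atlas()
    roi_labels <- atlas$label[atlas$region %in% .motor_roi_regions]
  }
  subjects <- intersect(unique(deltas$subject_id), names(improvements))
  if (length(subjects) < 5) stop("need at least 5 subjects with deltas and outcomes")
  y <- improvements[subjects]
  out <- list()
  for (metric in c("delta_ac", "delta_mc")) {
    for (lab in roi_labels) {
      sel <- deltas$label == lab
      x <- deltas[[metric]][sel][match(subjects, deltas$subject_id[sel])]
      defined <- stats::sd(x) > 0 && stats::sd(y) > 0
      if (defined) {
        ct <- stats::cor.test(x, y)
        r <- unname(ct$estimate); p <- ct$p.value
      } else {
        r <- NA_real_; p <- NA_real_
      }
      out[[length(out) + 1L]] <- data.frame(
        label = lab, metric = sub("delta_", "", metric),
        r = r, p = p, n = length(subjects),
        significant = defined && p < alpha, defined = defined,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
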