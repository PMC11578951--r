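# Designed simulation experiments used to validate the pipeline against
# its own synthetic ground truth: screening sensitivity / type-I error,
# and prediction calibration against planted outcome-link strength.

#' One screening-cascade replicate on a synthetic cohort
#'
#' Generates a cohort, runs the connectivity/controllability/screening
#' stages and summarizes recovery of the planted disease regions. Under
#' `null = TRUE` the perturbation is switched off (`perturbation_scale
#' = 1`), making every region/metric test a true null, and the
#' rejection rates estimate the cascade's type-I error.
#'
#' @param seed Replicate seed.
#' @param null Run under the global null instead of the planted
#'   alternative.
#' @param alpha Significance level of the intersection rule.
#' @return List with `sensitivity` (fraction of perturbed regions
#'   present in the responsive list, either metric; `NA` under the
#'   null), `effect_size_d` (realized patient-vs-control Cohen's d of
#'   average controllability averaged over perturbed regions),
#'   `group_reject_rate`, `med_reject_rate` (fraction of all
#'   region/metric tests below `alpha`), and `n_tests`.
#' @export
screening_experiment <- function(seed, null = FALSE, alpha = 0.05) {
  net <- make_base_network(perturbation_scale = if (null) 1 else 0.6,
                           seed = seed)
  co <- generate_cohort(cohort_config(seed = seed), net)
  prof <- cohort_profiles(co)
  scr <- screen_regions(prof, co$records)
  resp <- select_responsive_regions(scr, alpha = alpha)
  pert <- net$labels[net$perturbed_nodes]

  off <- prof[prof$session == "off", ]
  ctl <- prof[prof$session == "single", ]
  d_by_lab <- vapply(pert, function(lab) {
    a <- off$ac[off$label == lab]
    b <- ctl$ac[ctl$label == lab]
    sp <- sqrt(((length(a) - 1) * stats::var(a) +
                  (length(b) - 1) * stats::var(b)) /
                 (length(a) + length(b) - 2))
    abs(mean(a) - mean(b)) / sp
  }, numeric(1))

  list(
    sensitivity = if (null) NA_real_ else mean(pert %in% resp$label),
    effect_size_d = mean(d_by_lab),
    group_reject_rate = mean(scr$group_p < alpha, na.rm = TRUE),
    med_reject_rate = mean(scr$med_p < alpha, na.rm = TRUE),
    n_tests = sum(!is.na(scr$group_p)) + sum(!is.na(scr$med_p))
  )
}

#' Strong-plant cohort configuration for prediction calibration
#'
#' The designed experiment behind the prediction-calibration checks: a
#' tightly modular network (within-block covariance 0.9) whose disease
#' nodes are deeply attenuated as `strength` grows
#' (`perturbation_scale = 1 - 0.95 * strength`), a wide medication
#' response (mean 0.5, SD 0.3) driving a noise-free planted outcome
#' link, and no dropped sessions. At `strength = 0` the network is
#' unperturbed and delta controllability carries no outcome
#' information; at `strength = 1` the link is as strong as the
#' session-level connectivity sampling noise permits.
#'
#' @param strength Planted link strength in `[0, 1]`.
#' @param seed Replicate seed.
#' @param n_patients Size of the STN-like stratum (default 24).
#' @return List with `net` and `cfg` ready for [generate_cohort()].
#' @export
strong_plant_design <- function(strength, seed, n_patients = 24) {
  stopifnot(strength >= 0, strength <= 1)
  list(
    net = make_base_network(within_strength = 0.9, between_strength = 0.02,
                            perturbation_scale = 1 - 0.95 * strength,
                            seed = seed),
    cfg = cohort_config(n_patients_stn = n_patients, n_patients_gpi = 1,
                        n_controls = 1, medication_recovery_mean = 0.5,
                        recovery_sd = 0.3, outcome_noise_sd = 0,
                        n_drop_on = 0, n_drop_off = 0, seed = seed)
  )
}

#' One prediction-calibration replicate
#'
#' Generates a [strong_plant_design()] cohort at the given link
#' strength, runs the full pipeline up to delta controllability, and
#' evaluates LOOCV-SVR on the STN-like feature set (bilateral thalamic
#' delta average controllability).
#'
#' @inheritParams strong_plant_design
#' @param permute_labels Permute outcomes before the LOOCV (null
#'   calibration).
#' @return List with `r` (predicted-vs-actual Pearson correlation),
#'   `feature_cor` (in-sample correlation of the mean feature with the
#'   outcome) and `n`.
#' @export
prediction_experiment <- function(strength, seed, n_patients = 24,
                                  permute_labels = FALSE) {
  des <- strong_plant_design(strength, seed, n_patients)
  co <- generate_cohort(des$cfg, des$net)
  prof <- cohort_profiles(co)
  del <- cohort_deltas(prof)
  fx <- assemble_features(del, co$records, feature_spec("STN"))
  y <- fx$y
  if (permute_labels) {
    set.seed(seed + 500000L)
    y <- stats::setNames(sample(as.numeric(y)), names(y))
  }
  res <- svr_loocv(fx$X, y, seed = seed)
  list(r = res$r, feature_cor = stats::cor(rowMeans(fx$X), y),
       n = length(y))
}
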