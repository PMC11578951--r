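# Synthetic study generator: modular ground-truth covariance, disease
# perturbation at striato-pallido-thalamo-cortical nodes, partial
# normalization under medication, BOLD-like sessions, and clinical
# outcomes with a planted link from medication response to percent
# UPDRS-III improvement.

#' Build a modular ground-truth covariance network
#'
#' Constructs a block (community) covariance: unit variances,
#' `within_strength` covariance inside each of `n_modules` contiguous
#' communities and `between_strength` across communities, plus diagonal
#' loading when needed so the smallest eigenvalue is at least `min_eig`.
#'
#' @param n_nodes Number of nodes (default 90, atlas-labelled).
#' @param n_modules Number of equally sized contiguous communities;
#'   must divide `n_nodes`.
#' @param within_strength,between_strength Within-/between-community
#'   covariance; `within_strength > between_strength >= 0` required.
#' @param perturbed_nodes Indices of the "disease nodes" whose coupling
#'   is attenuated in the patient-off state; defaults to the bilateral
#'   caudate, putamen, pallidum, thalamus and postcentral gyrus slots
#'   when `n_nodes == 90`, empty otherwise.
#' @param perturbation_scale Factor in `[0, 1]` applied to off-diagonal
#'   entries touching a perturbed node in the patient-off state.
#' @param min_eig Lower bound enforced on the smallest eigenvalue.
#' @param seed Seed stored with the network and used for session
#'   simulation downstream.
#' @return Object of class `ground_truth_network`: `base_cov`,
#'   `module_assignment`, `perturbed_nodes`, `perturbation_scale`,
#'   `labels`, `seed`.
#' @export
make_base_network <- function(n_nodes = 90, n_modules = 6,
                              within_strength = 0.6,
                              between_strength = 0.1,
                              perturbed_nodes = NULL,
                              perturbation_scale = 0.6,
                              min_eig = 0.1, seed = 1L) {
  if (n_nodes %% n_modules != 0) {
    stop("n_modules = ", n_modules, " does not partition n_nodes = ", n_nodes)
  }
  if (!(within_strength > between_strength && between_strength >= 0)) {
    stop("need within_strength > between_strength >= 0")
  }
  if (perturbation_scale < 0 || perturbation_scale > 1) {
    stop("perturbation_scale must lie in [0, 1]")
  }
  modules <- rep(seq_len(n_modules), each = n_nodes / n_modules)
  same <- outer(modules, modules, "==")
  S <- ifelse(same, within_strength, between_strength)
  diag(S) <- 1
  ev_min <- min(eigen(S, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min < min_eig) {
    diag(S) <- diag(S) + (min_eig - ev_min)
    ev_min <- min(eigen(S, symmetric = TRUE, only.values = TRUE)$values)
  }
  if (ev_min <= 0) {
    stop("constructed covariance is not positive definite (min eigenvalue ",
         format(ev_min), ")")
  }
  labels <- if (n_nodes == 90) aal90_labels() else
    paste0("node", seq_len(n_nodes))
  dimnames(S) <- list(labels, labels)
  if (is.null(perturbed_nodes)) {
    perturbed_nodes <- if (n_nodes == 90)
      aal90_indices(.default_perturbed_regions) else integer(0)
  }
  if (length(perturbed_nodes) > 0 &&
      (min(perturbed_nodes) < 1 || max(perturbed_nodes) > n_nodes)) {
    stop("perturbed_nodes out of range")
  }
  structure(
    list(base_cov = S, module_assignment = modules,
         perturbed_nodes = as.integer(perturbed_nodes),
         perturbation_scale = perturbation_scale,
         labels = labels, seed = as.integer(seed)),
    class = "ground_truth_network"
  )
}

#' @export
print.ground_truth_network <- function(x, ...) {
  cat(sprintf(
    "<ground_truth_network> %d nodes, %d modules, %d perturbed nodes (scale %g)\n",
    nrow(x$base_cov), length(unique(x$module_assignment)),
    length(x$perturbed_nodes), x$perturbation_scale))
  invisible(x)
}

#' Generating covariance for a cohort/session combination
#'
#' Controls (and the `"single"` session) use the base covariance
#' unchanged. The patient medication-off state attenuates every
#' off-diagonal entry touching a perturbed node by the network's
#' `perturbation_scale`. The medication-on state is the convex
#' combination `(1 - recovery) * off + recovery * base`: `recovery = 1`
#' restores the base exactly, `recovery = 0` leaves the off-state
#' untouched. Positive definiteness is preserved (Schur product with a
#' PSD unit-diagonal mask) and asserted.
#'
#' @param net A [make_base_network()] result.
#' @param cohort `"patient"` or `"control"`.
#' @param session `"off"`, `"on"` or `"single"`.
#' @param recovery Fraction in `[0, 1]` of the way back to base.
#' @return Symmetric positive-definite covariance matrix.
#' @export
state_covariance <- function(net, cohort = c("patient", "control"),
                             session = c("off", "on", "single"),
                             recovery = 0) {
  cohort <- match.arg(cohort)
  session <- match.arg(session)
  if (recovery < 0 || recovery > 1) stop("recovery must lie in [0, 1]")
  base <- net$base_cov
  if (cohort == "control" || session == "single") return(base)
  n <- nrow(base)
  touch <- rep(FALSE, n)
  touch[net$perturbed_nodes] <- TRUE
  mask <- matrix(1, n, n)
  mask[touch, ] <- net$perturbation_scale
  mask[, touch] <- net$perturbation_scale
  diag(mask) <- 1
  off_state <- base * mask
  S <- if (session == "off") off_state else
    (1 - recovery) * off_state + recovery * base
  ev_min <- min(eigen(S, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min <= 0) {
    stop("state covariance lost positive definiteness (min eigenvalue ",
         format(ev_min), ")")
  }
  S
}

#' Simulate one BOLD-like session
#'
#' Draws `n_timepoints` samples from a stationary Gaussian process with
#' the given contemporaneous covariance and optional AR(1) temporal
#' autocorrelation: `x_t = ar * x_{t-1} + sqrt(1 - ar^2) * e_t` with
#' `e_t ~ N(0, cov)`, so the marginal covariance equals `cov` at every
#' lag-0 regardless of `ar`.
#'
#' @param cov Positive-definite node covariance.
#' @param n_timepoints Number of time points.
#' @param tr_seconds Sampling interval (s).
#' @param ar AR(1) coefficient in `[0, 1)` (default 0.3).
#' @param seed Integer seed; identical seeds give identical sessions.
#' @param subject_id,session Provenance for the returned object.
#' @return A [roi_timeseries].
#' @export
simulate_session <- function(cov, n_timepoints, tr_seconds = 2, ar = 0.3,
                             seed = 1L, subject_id = NA_character_,
                             session = NA_character_) {
  cov <- as.matrix(cov)
  n_nodes <- ncol(cov)
  if (ar < 0 || ar >= 1) stop("ar must lie in [0, 1)")
  L <- tryCatch(chol(cov), error = function(e)
    stop("covariance is not positive definite: ", conditionMessage(e)))
  if (n_timepoints < n_nodes + 2) {
    warning("n_timepoints = ", n_timepoints, " < n_nodes + 2 = ",
            n_nodes + 2, ": sample connectivity will be rank-deficient")
  }
  set.seed(as.integer(seed))
  E <- matrix(stats::rnorm(n_timepoints * n_nodes), n_timepoints) %*% L
  if (ar > 0) {
    X <- E
    s <- sqrt(1 - ar^2)
    X[1, ] <- E[1, ]
    for (t in 2:n_timepoints) X[t, ] <- ar * X[t - 1, ] + s * E[t, ]
  } else {
    X <- E
  }
  roi_timeseries(X, tr_seconds, node_labels = colnames(cov),
                 subject_id = subject_id, session = session)
}

#' Cohort configuration
#'
#' Assembles and validates the configuration of the synthetic study.
#' Defaults mirror the target study design: 24 STN-DBS and 15 GPi-DBS
#' patients, 29 healthy controls, 223 retained time points at TR 2 s,
#' and a mean medication recovery of 0.6 driving a planted linear
#' outcome link.
#'
#' @param n_patients_stn,n_patients_gpi,n_controls Stratum sizes.
#' @param n_timepoints Time points per session.
#' @param tr_seconds Repetition time (s).
#' @param medication_recovery_mean Mean per-subject recovery fraction.
#' @param recovery_sd SD of the truncated-normal recovery distribution.
#' @param outcome_intercept,outcome_slope Planted linear model
#'   `improvement = intercept + slope * recovery + noise` (percent).
#' @param outcome_noise_sd Outcome noise SD (percentage points).
#' @param ar AR(1) coefficient of the session simulator.
#' @param n_drop_on,n_drop_off Number of patient on-/off-sessions marked
#'   missing (scan-exclusion emulation).
#' @param seed Master seed.
#' @return Validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_patients_stn = 24, n_patients_gpi = 15,
                          n_controls = 29, n_timepoints = 223,
                          tr_seconds = 2, medication_recovery_mean = 0.6,
                          recovery_sd = 0.2, outcome_intercept = 38.65,
                          outcome_slope = 50, outcome_noise_sd = 8,
                          ar = 0.3, n_drop_on = 5, n_drop_off = 2,
                          seed = 1L) {
  cfg <- list(n_patients_stn = n_patients_stn, n_patients_gpi = n_patients_gpi,
              n_controls = n_controls, n_timepoints = n_timepoints,
              tr_seconds = tr_seconds,
              medication_recovery_mean = medication_recovery_mean,
              recovery_sd = recovery_sd,
              outcome_intercept = outcome_intercept,
              outcome_slope = outcome_slope,
              outcome_noise_sd = outcome_noise_sd, ar = ar,
              n_drop_on = n_drop_on, n_drop_off = n_drop_off,
              seed = as.integer(seed))
  errs <- character(0)
  for (f in c("n_patients_stn", "n_patients_gpi", "n_controls",
              "n_timepoints")) {
    if (cfg[[f]] < 1) errs <- c(errs, paste0(f, " must be positive"))
  }
  if (cfg$tr_seconds <= 0) errs <- c(errs, "tr_seconds must be > 0")
  if (cfg$medication_recovery_mean < 0 || cfg$medication_recovery_mean > 1) {
    errs <- c(errs, "medication_recovery_mean must lie in [0, 1]")
  }
  if (cfg$outcome_noise_sd < 0) errs <- c(errs, "outcome_noise_sd must be >= 0")
  if (length(errs) > 0) stop("invalid cohort config:\n  - ",
                             paste(errs, collapse = "\n  - "))
  class(cfg) <- "cohort_config"
  cfg
}

# deterministic per-subject/session sub-seed below 2^31
.sub_seed <- function(master, i, k) {
  (as.integer(master) %% 1000003L) * 2017L + i * 131L + k
}

#' Generate a full synthetic cohort
#'
#' Produces the clinical table, all session time series and a
#' ground-truth table. Each patient draws a recovery fraction from a
#' normal distribution truncated to `[0, 1]`; the planted improvement
#' rate is `intercept + slope * recovery + noise`, truncated to
#' `[0, 100]`, and the postoperative UPDRS-III score is backed out of
#' the improvement-rate formula
#' `improvement = (pre - post) / pre * 100`. Controls get one session.
#' A configurable number of patient on- and off-sessions is marked
#' missing to emulate scan exclusions.
#'
#' @param cfg A [cohort_config()].
#' @param net A [make_base_network()] result.
#' @return List with `records` (clinical data frame, one row per
#'   subject), `sessions` (named list of [roi_timeseries], names
#'   `"<subject_id>.<session>"`), and `truth` (per-subject recovery
#'   fractions and planted values).
#' @export
generate_cohort <- function(cfg = cohort_config(), net = make_base_network()) {
  stopifnot(inherits(cfg, "cohort_config"),
            inherits(net, "ground_truth_network"))
  n_pat <- cfg$n_patients_stn + cfg$n_patients_gpi
  n_all <- n_pat + cfg$n_controls
  set.seed(cfg$seed)

  target <- c(rep("STN", cfg$n_patients_stn), rep("GPi", cfg$n_patients_gpi),
              rep("none", cfg$n_controls))
  cohort <- c(rep("patient", n_pat), rep("control", cfg$n_controls))
  subject_id <- sprintf("%s%02d",
                        c(rep("PD", n_pat), rep("HC", cfg$n_controls)),
                        c(seq_len(n_pat), seq_len(cfg$n_controls)))

  # demographics in the magnitude range of the study population
  age <- round(ifelse(cohort == "patient",
                      stats::rnorm(n_all, 59.2, 9.6),
                      stats::rnorm(n_all, 53.5, 8.4)), 1)
  age <- pmin(pmax(age, 30), 85)
  sex <- ifelse(stats::runif(n_all) <
                  ifelse(cohort == "patient", 21 / 39, 8 / 29),
                "male", "female")

  # truncated-normal per-subject medication response
  recovery <- rep(NA_real_, n_all)
  for (i in seq_len(n_pat)) {
    r <- stats::rnorm(1, cfg$medication_recovery_mean, cfg$recovery_sd)
    while (r < 0 || r > 1) r <- stats::rnorm(1, cfg$medication_recovery_mean,
                                             cfg$recovery_sd)
    recovery[i] <- r
  }

  pre <- ifelse(cohort == "patient",
                pmax(stats::rnorm(n_all, 55.95, 16.37), 10), NA_real_)
  noise <- stats::rnorm(n_all, 0, cfg$outcome_noise_sd)
  improvement <- ifelse(
    cohort == "patient",
    pmin(pmax(cfg$outcome_intercept + cfg$outcome_slope * recovery + noise,
              0), 100),
    NA_real_)
  post <- ifelse(cohort == "patient", pre * (1 - improvement / 100), NA_real_)

  has_off <- cohort == "patient"
  has_on <- cohort == "patient"
  pat_idx <- seq_len(n_pat)
  if (cfg$n_drop_on > 0) {
    has_on[sample(pat_idx, min(cfg$n_drop_on, n_pat))] <- FALSE
  }
  if (cfg$n_drop_off > 0) {
    has_off[sample(pat_idx, min(cfg$n_drop_off, n_pat))] <- FALSE
  }

  records <- data.frame(
    subject_id = subject_id, cohort = cohort, target = target,
    age = age, sex = sex,
    updrs3_pre_off = round(pre, 2),
    updrs3_post_off_stim_on = round(post, 2),
    improvement_rate = round(improvement, 2),
    has_off_session = has_off, has_on_session = has_on,
    stringsAsFactors = FALSE
  )

  sessions <- list()
  for (i in seq_len(n_all)) {
    if (cohort[i] == "control") {
      S <- state_covariance(net, "control", "single")
      sessions[[paste0(subject_id[i], ".single")]] <-
        simulate_session(S, cfg$n_timepoints, cfg$tr_seconds, cfg$ar,
                         seed = .sub_seed(cfg$seed, i, 0L),
                         subject_id = subject_id[i], session = "single")
    } else {
      if (has_off[i]) {
        S <- state_covariance(net, "patient", "off")
        sessions[[paste0(subject_id[i], ".off")]] <-
          simulate_session(S, cfg$n_timepoints, cfg$tr_seconds, cfg$ar,
                           seed = .sub_seed(cfg$seed, i, 1L),
                           subject_id = subject_id[i], session = "off")
      }
      if (has_on[i]) {
        S <- state_covariance(net, "patient", "on", recovery = recovery[i])
        sessions[[paste0(subject_id[i], ".on")]] <-
          simulate_session(S, cfg$n_timepoints, cfg$tr_seconds, cfg$ar,
                           seed = .sub_seed(cfg$seed, i, 2L),
                           subject_id = subject_id[i], session = "on")
      }
    }
  }

  truth <- data.frame(
    subject_id = subject_id, recovery = recovery,
    planted_improvement = improvement,
    stringsAsFactors = FALSE
  )
  list(records = records, sessions = sessions, truth = truth,
       config = cfg, network = net)
}

#' Write a generated cohort to disk
#'
#' Sessions are written as tab-separated tables (rows = time points,
#' columns = node labels), the clinical and ground-truth tables as CSV,
#' and a JSON manifest listing every path, the seed and file checksums.
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest list.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(file.path(dir, "sessions"), recursive = TRUE,
             showWarnings = FALSE)
  paths <- character(0)
  for (nm in names(cohort$sessions)) {
    p <- file.path(dir, "sessions", paste0(nm, ".tsv"))
    utils::write.table(cohort$sessions[[nm]]$values, p, sep = "\t",
                       row.names = FALSE, quote = FALSE)
    paths <- c(paths, p)
  }
  clin <- file.path(dir, "clinical.csv")
  utils::write.csv(cohort$records, clin, row.names = FALSE)
  truth <- file.path(dir, "ground_truth.csv")
  utils::write.csv(cohort$truth, truth, row.names = FALSE)
  paths <- c(paths, clin, truth)
  manifest <- list(seed = cohort$config$seed,
                   files = as.list(setNames(unname(tools::md5sum(paths)),
                                            paths)))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Read a session time-series table written by [write_cohort()]
#'
#' @param path TSV path (rows = time points, columns = node labels).
#' @param tr_seconds Sampling interval.
#' @param subject_id,session Provenance.
#' @return A [roi_timeseries].
#' @export
read_session_tsv <- function(path, tr_seconds = 2,
                             subject_id = NA_character_,
                             session = NA_character_) {
  X <- as.matrix(utils::read.delim(path, check.names = FALSE))
  roi_timeseries(X, tr_seconds, subject_id = subject_id, session = session)
}
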