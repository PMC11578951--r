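# Outcome prediction: epsilon-SVR (libsvm via e1071) on
# delta-controllability features under leave-one-subject-out
# cross-validation, evaluated by the Pearson correlation between
# predicted and actual percent improvement.

#' Feature specification for one surgical group
#'
#' Defaults follow the regions selected for each target: STN uses
#' bilateral thalamic delta average controllability; GPi uses bilateral
#' postcentral delta average controllability plus left postcentral and
#' left caudate delta modal controllability.
#'
#' @param group `"STN"` or `"GPi"`.
#' @param features Data frame with columns `region`, `hemisphere`,
#'   `metric` (`"ac"`/`"mc"`); `NULL` selects the group default.
#' @return Object of class `feature_spec`.
#' @export
feature_spec <- function(group = c("STN", "GPi"), features = NULL) {
  group <- match.arg(group)
  if (is.null(features)) {
    features <- if (group == "STN") {
      data.frame(region = c("THA", "THA"), hemisphere = c("L", "R"),
                 metric = c("ac", "ac"), stringsAsFactors = FALSE)
    } else {
      data.frame(region = c("PoCG", "PoCG", "PoCG", "CAU"),
                 hemisphere = c("L", "R", "L", "L"),
                 metric = c("ac", "ac", "mc", "mc"),
                 stringsAsFactors = FALSE)
    }
  }
  if (nrow(features) == 0) stop("feature list must be nonempty")
  key <- paste(features$region, features$hemisphere, features$metric)
  if (anyDuplicated(key)) stop("feature triples must be unique")
  structure(list(group = group, features = features), class = "feature_spec")
}

#' Assemble the SVR design matrix from delta profiles
#'
#' @param deltas Data frame of stacked delta profiles (`subject_id`,
#'   `label`, `delta_ac`, `delta_mc`).
#' @param records Clinical data frame (`subject_id`, `target`,
#'   `improvement_rate`).
#' @param spec A [feature_spec()].
#' @return List with `X` (subject-by-feature matrix, rows ordered by
#'   subject id), `y` (improvement vector) and `dropped` (subjects of
#'   the group without a complete delta profile or outcome).
#' @export
assemble_features <- function(deltas, records, spec) {
  stopifnot(inherits(spec, "feature_spec"))
  grp <- records[records$target == spec$group &
                   !is.na(records$improvement_rate), ]
  cols <- paste(spec$features$region, spec$features$hemisphere, sep = ".")
  metric_col <- paste0("delta_", spec$features$metric)
  subjects <- sort(unique(grp$subject_id))
  have <- subjects %in% deltas$subject_id
  dropped <- subjects[!have]
  subjects <- subjects[have]
  if (length(subjects) == 0) stop("no subjects with deltas and outcomes")
  X <- matrix(NA_real_, length(subjects), nrow(spec$features),
              dimnames = list(subjects,
                              paste(cols, spec$features$metric, sep = ".")))
  for (j in seq_len(nrow(spec$features))) {
    sel <- deltas$label == cols[j]
    X[, j] <- deltas[[metric_col[j]]][sel][
      match(subjects, deltas$subject_id[sel])]
  }
  if (anyNA(X)) stop("missing delta features for some subjects")
  y <- grp$improvement_rate[match(subjects, grp$subject_id)]
  names(y) <- subjects
  list(X = X, y = y, dropped = dropped)
}

#' Leave-one-subject-out epsilon-SVR
#'
#' For each fold, features and the outcome are standardized with
#' training-fold statistics only (the toolbox's own scaling convention;
#' predictions are mapped back to the percent scale), an epsilon-SVR is
#' fitted on the remaining subjects and the held-out subject is
#' predicted. Defaults follow the libsvm conventions: RBF kernel,
#' `C = 1`, `epsilon = 0.1`, `gamma = 1 / n_features`.
#'
#' @param X Subject-by-feature numeric matrix.
#' @param y Outcome vector (percent improvement).
#' @param kernel `"radial"` or `"linear"`.
#' @param cost,epsilon,gamma SVR hyperparameters (`gamma = NULL` means
#'   `1 / ncol(X)`).
#' @param seed Stored for provenance (the fit itself is deterministic).
#' @param leak Internal switch used only by leakage regression tests.
#'   `"none"` (the default) is the honest procedure;
#'   `"standardization"` computes scaling statistics on the whole
#'   sample; `"training"` additionally keeps the held-out subject in
#'   the training fold. Keep `"none"`.
#' @return Object of class `prediction_result`: per-subject `actual`,
#'   `predicted`, `fold`, plus `r`, `p` (correlation t-test) and the
#'   hyperparameters used.
#' @export
svr_loocv <- function(X, y, kernel = c("radial", "linear"), cost = 1,
                      epsilon = 0.1, gamma = NULL, seed = 1L,
                      leak = c("none", "standardization", "training")) {
  kernel <- match.arg(kernel)
  leak <- match.arg(leak)
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 5) stop("need at least 5 subjects for LOOCV")
  if (length(y) != n) stop("y must match the rows of X")
  if (stats::sd(y) == 0) stop("constant outcome: LOOCV correlation undefined")
  if (is.null(gamma)) gamma <- 1 / ncol(X)
  pred <- numeric(n)
  for (i in seq_len(n)) {
    train <- if (leak == "training") seq_len(n) else setdiff(seq_len(n), i)
    Xtr <- X[train, , drop = FALSE]
    if (leak == "none") {
      mu <- colMeans(Xtr)
      sg <- apply(Xtr, 2, stats::sd)
    } else {
      mu <- colMeans(X)
      sg <- apply(X, 2, stats::sd)
    }
    sg[sg == 0] <- 1
    Ztr <- sweep(sweep(Xtr, 2, mu), 2, sg, "/")
    Zte <- sweep(sweep(X[i, , drop = FALSE], 2, mu), 2, sg, "/")
    ytr <- y[train]
    if (leak == "none") {
      y_mu <- mean(ytr)
      y_sg <- stats::sd(ytr)
    } else {
      y_mu <- mean(y); y_sg <- stats::sd(y)
    }
    if (y_sg == 0) y_sg <- 1
    fit <- e1071::svm(Ztr, (ytr - y_mu) / y_sg, type = "eps-regression",
                      kernel = kernel, cost = cost, epsilon = epsilon,
                      gamma = gamma, scale = FALSE)
    pred[i] <- stats::predict(fit, Zte) * y_sg + y_mu
  }
  r <- if (stats::sd(pred) > 0) stats::cor(pred, y) else NA_real_
  structure(
    list(subject = rownames(X), actual = as.numeric(y), predicted = pred,
         fold = seq_len(n), r = r,
         p = if (is.na(r)) NA_real_ else .cor_t_p(r, n),
         hyperparameters = list(kernel = kernel, cost = cost,
                                epsilon = epsilon, gamma = gamma),
         seed = seed),
    class = "prediction_result"
  )
}

.cor_t_p <- function(r, n) {
  t <- r * sqrt(n - 2) / sqrt(1 - r^2)
  2 * stats::pt(-abs(t), n - 2)
}

#' @export
print.prediction_result <- function(x, ...) {
  cat(sprintf(
    "<prediction_result> n = %d, predicted-vs-actual r = %.3f (p = %.4g)\n",
    length(x$actual), x$r, x$p))
  invisible(x)
}

#' @export
as.data.frame.prediction_result <- function(x, ...) {
  data.frame(subject = x$subject %||% seq_along(x$actual),
             actual = x$actual, predicted = x$predicted, fold = x$fold,
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate LOOCV predictions against actual outcomes
#'
#' Pearson correlation across folds, with the p value either from the
#' standard correlation t-test (`t = r sqrt(n-2) / sqrt(1-r^2)`,
#' `df = n - 2`) or from a label-permutation null with full LOOCV refits.
#'
#' @param result A [svr_loocv()] result, or a list holding `X`, `y`
#'   when `method = "permutation"` (refits need the features).
#' @param method `"t-test"` or `"permutation"`.
#' @param n_perm Number of permutations.
#' @param seed Permutation seed.
#' @param ... Passed to [svr_loocv()] for permutation refits.
#' @return List with `r`, `p`, `n`, `method`.
#' @export
evaluate_prediction <- function(result, method = c("t-test", "permutation"),
                                n_perm = 1000, seed = 1L, ...) {
  method <- match.arg(method)
  stopifnot(inherits(result, "prediction_result"))
  n <- length(result$actual)
  if (n < 5) stop("need at least 5 folds")
  if (stats::sd(result$predicted) == 0) {
    stop("zero variance in predictions: correlation undefined")
  }
  r <- stats::cor(result$predicted, result$actual)
  if (method == "t-test") {
    return(list(r = r, p = .cor_t_p(r, n), n = n, method = method))
  }
  extra <- list(...)
  X <- extra$X
  if (is.null(X)) stop("permutation evaluation needs the feature matrix X")
  set.seed(as.integer(seed))
  y <- result$actual
  hp <- result$hyperparameters
  exceed <- 0L
  for (b in seq_len(n_perm)) {
    rb <- svr_loocv(X, sample(y), kernel = hp$kernel, cost = hp$cost,
                    epsilon = hp$epsilon, gamma = hp$gamma)$r
    if (!is.na(rb) && abs(rb) >= abs(r)) exceed <- exceed + 1L
  }
  list(r = r, p = (1 + exceed) / (1 + n_perm), n = n, method = method)
}
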