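# Temporal cleaning of ROI time series and Pearson functional
# connectivity: band-pass filter, expanded 24-parameter motion model,
# nuisance regression, framewise displacement and scrubbing.

#' Construct an ROI time-series object
#'
#' @param values Numeric time-by-node matrix (rows are time points).
#' @param tr_seconds Repetition time (sampling interval) in seconds.
#' @param node_labels Node labels; defaults to `colnames(values)`.
#' @param subject_id,session Provenance.
#' @return Object of class `roi_timeseries`.
#' @export
roi_timeseries <- function(values, tr_seconds, node_labels = colnames(values),
                           subject_id = NA_character_,
                           session = NA_character_) {
  values <- as.matrix(values)
  if (is.null(node_labels)) node_labels <- paste0("node", seq_len(ncol(values)))
  if (length(node_labels) != ncol(values)) {
    stop("node count (", ncol(values), ") does not match label count (",
         length(node_labels), ")")
  }
  if (nrow(values) < 2L) stop("need at least 2 time points")
  if (anyNA(values)) stop("time series contains missing values")
  if (!is.numeric(tr_seconds) || tr_seconds <= 0) stop("tr_seconds must be > 0")
  colnames(values) <- node_labels
  structure(
    list(values = values, tr_seconds = tr_seconds, node_labels = node_labels,
         subject_id = subject_id, session = session),
    class = "roi_timeseries"
  )
}

#' @export
print.roi_timeseries <- function(x, ...) {
  cat(sprintf("<roi_timeseries> %d time points x %d nodes, TR = %gs (%s/%s)\n",
              nrow(x$values), ncol(x$values), x$tr_seconds,
              x$subject_id, x$session))
  invisible(x)
}

.replace_values <- function(ts, values) {
  ts$values <- values
  colnames(ts$values) <- ts$node_labels
  ts
}

#' Band-pass filter ROI time series
#'
#' Removes a per-node linear trend, then applies an ideal
#' frequency-domain filter that keeps Fourier bins with
#' `low_hz <= f <= high_hz` and zeroes the rest (the zero-frequency bin
#' is kept only if `low_hz == 0`). Output length equals input length.
#'
#' @param ts A [roi_timeseries].
#' @param low_hz,high_hz Pass-band edges in Hz; the resting-state default
#'   is 0.01-0.08 Hz.
#' @param detrend Remove a least-squares linear trend first (default TRUE).
#' @return Filtered [roi_timeseries].
#' @export
bandpass <- function(ts, low_hz = 0.01, high_hz = 0.08, detrend = TRUE) {
  stopifnot(inherits(ts, "roi_timeseries"))
  nyquist <- 1 / (2 * ts$tr_seconds)
  if (low_hz < 0 || low_hz >= high_hz) {
    stop("need 0 <= low_hz < high_hz (got ", low_hz, ", ", high_hz, ")")
  }
  if (high_hz > nyquist + 1e-12) {
    stop("high_hz = ", high_hz, " Hz exceeds the Nyquist frequency ",
         nyquist, " Hz at TR = ", ts$tr_seconds, " s")
  }
  X <- ts$values
  n <- nrow(X)
  if (detrend) {
    tt <- seq_len(n)
    X <- as.matrix(stats::lm.fit(cbind(1, tt), X)$residuals)
  }
  freq <- seq(0, n - 1) / (n * ts$tr_seconds)
  freq <- pmin(freq, 1 / ts$tr_seconds - freq)  # fold to [0, Nyquist]
  keep <- freq >= low_hz - 1e-12 & freq <= high_hz + 1e-12
  if (low_hz > 0) keep[1] <- FALSE
  Xf <- stats::mvfft(X)
  Xf[!keep, ] <- 0
  out <- Re(stats::mvfft(Xf, inverse = TRUE)) / n
  .replace_values(ts, out)
}

#' Construct a motion trace
#'
#' @param params Time-by-6 matrix of rigid-body realignment parameters:
#'   three translations (mm) then three rotations (radians).
#' @return Object of class `motion_trace`.
#' @export
motion_trace <- function(params) {
  params <- as.matrix(params)
  if (ncol(params) != 6L) stop("motion parameters must have 6 columns")
  if (nrow(params) < 2L) stop("need at least 2 time points")
  structure(list(params = params), class = "motion_trace")
}

#' Expanded 24-parameter motion confound model
#'
#' Expands the 6 rigid-body parameters into the standard 24-regressor
#' model: the parameters, their one-step-lagged versions (first row 0),
#' their squares, and the squared lagged versions, in that block order.
#'
#' @param motion A [motion_trace] or time-by-6 matrix.
#' @return Time-by-24 numeric matrix with descriptive column names.
#' @export
friston24 <- function(motion) {
  P <- if (inherits(motion, "motion_trace")) motion$params else as.matrix(motion)
  if (ncol(P) != 6L) stop("motion parameters must have 6 columns")
  if (nrow(P) < 2L) stop("need at least 2 time points")
  lagP <- rbind(0, P[-nrow(P), , drop = FALSE])
  out <- cbind(P, lagP, P^2, lagP^2)
  colnames(out) <- c(paste0("p", 1:6), paste0("p", 1:6, "_lag"),
                     paste0("p", 1:6, "_sq"), paste0("p", 1:6, "_lag_sq"))
  out
}

#' Regress confounds out of ROI time series
#'
#' Ordinary least-squares residualization of every node signal on the
#' confound columns plus an internally added intercept. Rank-deficient
#' confound sets are reduced to a full-rank basis with a warning; the
#' residuals are orthogonal to every retained confound column.
#'
#' @param ts A [roi_timeseries].
#' @param confounds Time-by-k numeric matrix (no intercept needed).
#' @return Residual [roi_timeseries].
#' @export
regress_confounds <- function(ts, confounds) {
  stopifnot(inherits(ts, "roi_timeseries"))
  X <- cbind(intercept = 1, as.matrix(confounds))
  if (nrow(X) != nrow(ts$values)) {
    stop("confounds have ", nrow(X), " rows but the series has ",
         nrow(ts$values), " time points")
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[-seq_len(qrX$rank)]]
    warning("dropping ", ncol(X) - qrX$rank,
            " linearly dependent confound column(s): ",
            paste(dropped, collapse = ", "))
  }
  res <- qr.resid(qrX, ts$values)
  .replace_values(ts, res)
}

#' Framewise displacement from rigid-body motion
#'
#' Scalar per-frame head-motion summary: the sum of absolute backward
#' differences of the three translations plus `head_radius_mm` times the
#' summed absolute rotation differences (small-angle arc length on a
#' spherical head). The first frame has no predecessor and gets FD 0.
#'
#' @param motion A [motion_trace] or time-by-6 matrix (translations mm,
#'   rotations radians).
#' @param head_radius_mm Head radius used to convert rotations to mm.
#' @return Numeric FD series (mm), one value per frame.
#' @export
framewise_displacement <- function(motion, head_radius_mm = 50) {
  P <- if (inherits(motion, "motion_trace")) motion$params else as.matrix(motion)
  if (ncol(P) != 6L) stop("motion parameters must have 6 columns")
  if (nrow(P) < 2L) stop("need at least 2 time points")
  d <- abs(diff(P))
  fd <- rowSums(d[, 1:3, drop = FALSE]) +
    head_radius_mm * rowSums(d[, 4:6, drop = FALSE])
  c(0, fd)
}

#' Motion scrubbing by framewise displacement
#'
#' Censors frames whose FD exceeds `threshold_mm` and, optionally, the
#' frame immediately following each such frame. A session losing more
#' than half its frames is flagged unusable.
#'
#' @param ts A [roi_timeseries].
#' @param fd FD series from [framewise_displacement()], same length as
#'   the series.
#' @param threshold_mm Censoring threshold (default 0.5 mm).
#' @param drop_following Also drop the frame after each supra-threshold
#'   frame (default TRUE).
#' @return List with `ts` (scrubbed series), `mask` (logical kept-frame
#'   vector), `frac_removed`, and `usable` (FALSE when more than 50% of
#'   frames were censored).
#' @export
scrub <- function(ts, fd, threshold_mm = 0.5, drop_following = TRUE) {
  stopifnot(inherits(ts, "roi_timeseries"))
  n <- nrow(ts$values)
  if (length(fd) != n) stop("FD length does not match the time series")
  bad <- fd > threshold_mm
  if (drop_following) bad <- bad | c(FALSE, bad[-n])
  mask <- !bad
  frac <- mean(bad)
  usable <- frac <= 0.5
  if (!usable) {
    warning(sprintf("session flagged unusable: %.0f%% of frames removed",
                    100 * frac))
  }
  list(ts = .replace_values(ts, ts$values[mask, , drop = FALSE]),
       mask = mask, frac_removed = frac, usable = usable)
}

#' Pearson functional connectivity
#'
#' Pairwise Pearson correlation across time between all node signals;
#' the diagonal is then set to zero so self-loops carry no weight into
#' the control model. Zero-variance nodes yield zero rows/columns with a
#' warning rather than an error.
#'
#' @param ts A [roi_timeseries] with at least 3 time points.
#' @return Object of class `connectivity_matrix`: list with the
#'   node-by-node `values` matrix, `node_labels` and `n_timepoints_used`.
#' @export
pearson_fc <- function(ts) {
  stopifnot(inherits(ts, "roi_timeseries"))
  X <- ts$values
  if (nrow(X) < 3L) stop("need at least 3 time points for correlation")
  sds <- apply(X, 2, stats::sd)
  flat <- sds == 0 | !is.finite(sds)
  if (any(flat)) {
    warning("zero-variance node(s): ",
            paste(ts$node_labels[flat], collapse = ", "),
            "; their correlations are set to 0")
  }
  R <- suppressWarnings(stats::cor(X))
  R[!is.finite(R)] <- 0
  R[flat, ] <- 0
  R[, flat] <- 0
  diag(R) <- 0
  R <- (R + t(R)) / 2
  dimnames(R) <- list(ts$node_labels, ts$node_labels)
  structure(
    list(values = R, node_labels = ts$node_labels,
         n_timepoints_used = nrow(ts$values),
         subject_id = ts$subject_id, session = ts$session),
    class = "connectivity_matrix"
  )
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(sprintf("<connectivity_matrix> %d nodes from %d time points (%s/%s)\n",
              length(x$node_labels), x$n_timepoints_used,
              x$subject_id, x$session))
  invisible(x)
}

#' Clean a session and compute its connectivity matrix
#'
#' Convenience wrapper applying the temporal pipeline in the order
#' band-pass -> confound regression -> scrubbing -> Pearson FC. Any step
#' can be disabled; confounds, when supplied together with filtering,
#' are band-pass filtered identically before regression so the
#' regression cannot reintroduce out-of-band noise.
#'
#' @param ts A [roi_timeseries].
#' @param band `NULL` to skip filtering, else `c(low_hz, high_hz)`.
#' @param confounds Optional time-by-k confound matrix.
#' @param motion Optional [motion_trace]; expanded with [friston24()]
#'   and appended to `confounds`, and used for scrubbing.
#' @param scrub_threshold_mm `NULL` to skip scrubbing.
#' @return A [pearson_fc()] connectivity matrix.
#' @export
session_fc <- function(ts, band = c(0.01, 0.08), confounds = NULL,
                       motion = NULL, scrub_threshold_mm = NULL) {
  conf <- confounds
  if (!is.null(motion)) {
    m24 <- friston24(motion)
    conf <- if (is.null(conf)) m24 else cbind(conf, m24)
  }
  if (!is.null(band)) {
    ts <- bandpass(ts, band[1], band[2])
    if (!is.null(conf)) {
      ctmp <- roi_timeseries(conf, ts$tr_seconds)
      conf <- bandpass(ctmp, band[1], band[2])$values
    }
  }
  if (!is.null(conf)) ts <- regress_confounds(ts, conf)
  if (!is.null(scrub_threshold_mm) && !is.null(motion)) {
    fd <- framewise_displacement(motion)
    ts <- scrub(ts, fd, scrub_threshold_mm)$ts
  }
  pearson_fc(ts)
}
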