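# Network-control core: stabilized linear dynamics on a functional
# connectivity matrix, node-wise average controllability (trace of the
# infinite-horizon controllability Gramian) and modal controllability.
#
# Model: x_{t+1} = A x_t + B_K u_K(t), with A the weighted symmetric
# adjacency scaled to Schur stability. For a single control node i
# (B = e_i) the Gramian is W = sum_{tau>=0} A^tau e_i e_i' A^tau, and
# AC_i = tr(W) = sum_j v_ij^2 / (1 - lambda_j^2) in the eigenbasis
# A = V diag(lambda) V'. Modal controllability is
# phi_i = sum_j (1 - lambda_j^2) v_ij^2.

#' Stabilize a connectivity matrix into Schur-stable linear dynamics
#'
#' Scales a symmetric, zero-diagonal connectivity matrix `C` as
#' `A = C / (c + sigma_max(C))` where `sigma_max` is the largest singular
#' value, so that the spectral radius of `A` is strictly below 1 and the
#' infinite-horizon controllability Gramian converges. The
#' eigendecomposition of `A` is computed once and cached for all
#' node-wise controllability evaluations.
#'
#' @param fc A [connectivity_matrix] or a plain symmetric numeric matrix
#'   with zero diagonal.
#' @param c Stabilization offset added to `sigma_max` in the denominator;
#'   the default `1` yields spectral radius `sigma_max / (1 + sigma_max) < 1`.
#' @param tol Symmetry tolerance; asymmetry beyond `tol` is an error,
#'   numerical asymmetry within it is removed by `(C + t(C)) / 2`.
#' @return An object of class `dynamics_matrix`: list with `A`, cached
#'   eigenvalues `values`, orthonormal eigenvectors `vectors`, `labels`
#'   and a `source` provenance note.
#' @export
#' @examples
#' A <- stabilize(matrix(c(0, 0.5, 0.5, 0), 2, 2))
#' A$values  # +- 1/3
stabilize <- function(fc, c = 1, tol = 1e-8) {
  C <- if (inherits(fc, "connectivity_matrix")) fc$values else as.matrix(fc)
  labels <- colnames(C)
  if (nrow(C) != ncol(C)) stop("connectivity matrix must be square")
  asym <- max(abs(C - t(C)))
  if (asym > tol) {
    stop("input matrix is asymmetric beyond tolerance (max |C - t(C)| = ",
         format(asym), ")")
  }
  if (asym > 0) C <- (C + t(C)) / 2
  if (c <= 0) stop("stabilization offset c must be positive")
  # for symmetric C the largest singular value is the largest |eigenvalue|
  eC <- eigen(C, symmetric = TRUE)
  sigma_max <- max(abs(eC$values))
  A <- C / (c + sigma_max)
  structure(
    list(
      A = A,
      values = eC$values / (c + sigma_max),
      vectors = eC$vectors,
      labels = labels,
      source = sprintf("stabilize(c=%g, sigma_max=%.6g)", c, sigma_max)
    ),
    class = "dynamics_matrix"
  )
}

#' @export
print.dynamics_matrix <- function(x, ...) {
  cat(sprintf("<dynamics_matrix> %d nodes, spectral radius %.4f\n  %s\n",
              nrow(x$A), max(abs(x$values)), x$source))
  invisible(x)
}

.check_dyn <- function(dyn) {
  if (!inherits(dyn, "dynamics_matrix")) stop("expected a dynamics_matrix")
  rho <- max(abs(dyn$values))
  if (rho >= 1) {
    stop("spectral radius ", format(rho),
         " >= 1: the infinite-horizon Gramian diverges")
  }
  rho
}

#' Average controllability of one node
#'
#' Trace of the infinite-horizon controllability Gramian
#' `W = sum_tau A^tau B B' (A^tau)'` for the single control node `node`
#' (`B` the canonical unit vector). Three routes are available and must
#' agree for a valid stable symmetric system: the closed form
#' `sum_j v_ij^2 / (1 - lambda_j^2)` from the cached eigendecomposition
#' (default), an independent Smith-doubling solve of the discrete
#' Lyapunov equation `A W A' - W = -B B'`, and the truncated power sum
#' with the truncation horizon chosen from the spectral-radius tail
#' bound.
#'
#' @param dyn A [stabilize()] result.
#' @param node Node index (1-based).
#' @param method `"closed_form"`, `"lyapunov"` or `"truncated"`.
#' @param tail_tol For `"truncated"`: bound on the neglected tail
#'   `rho^(2T) / (1 - rho^2)`.
#' @return Scalar average controllability (always `>= 1`).
#' @export
average_controllability <- function(dyn, node,
                                    method = c("closed_form", "lyapunov",
                                               "truncated"),
                                    tail_tol = 1e-10) {
  method <- match.arg(method)
  rho <- .check_dyn(dyn)
  n <- nrow(dyn$A)
  if (node < 1 || node > n) stop("node index out of range")
  switch(method,
    closed_form = sum(dyn$vectors[node, ]^2 / (1 - dyn$values^2)),
    lyapunov = {
      B <- numeric(n); B[node] <- 1
      sum(diag(lyapunov_gramian(dyn$A, B)))
    },
    truncated = {
      # rho^(2T) / (1 - rho^2) < tail_tol  =>  T > log(tail_tol (1-rho^2)) / (2 log rho)
      T_need <- if (rho == 0) 1L else
        ceiling(log(tail_tol * (1 - rho^2)) / (2 * log(rho)))
      T_need <- max(1L, min(T_need, 1e6))
      x <- numeric(n); x[node] <- 1
      acc <- 1  # tau = 0 term
      for (tau in seq_len(T_need)) {
        x <- dyn$A %*% x
        acc <- acc + sum(x^2)
      }
      acc
    }
  )
}

#' Solve the discrete Lyapunov equation for a controllability Gramian
#'
#' Computes `W = sum_{tau>=0} A^tau B B' (A^tau)'`, the solution of
#' `A W A' - W = -B B'`, by Smith squared iteration
#' (`W <- W + A W A'`, `A <- A A'` as in repeated squaring), which
#' converges doubly exponentially for Schur-stable `A`. Independent of
#' any eigendecomposition.
#'
#' @param A Schur-stable square matrix.
#' @param B Input matrix (or vector, one column).
#' @param tol Stop once `max|A_k|` falls below `tol`.
#' @return The Gramian matrix `W`.
#' @export
lyapunov_gramian <- function(A, B, tol = 1e-14) {
  A <- as.matrix(A)
  B <- as.matrix(B)
  W <- tcrossprod(B)
  Ak <- A
  for (iter in 1:200) {
    W <- W + Ak %*% W %*% t(Ak)
    Ak <- Ak %*% Ak
    if (max(abs(Ak)) < tol) break
    if (iter == 200) stop("Lyapunov iteration failed to converge; is A stable?")
  }
  W
}

#' Modal controllability of one node
#'
#' `phi_i = sum_j (1 - lambda_j^2) v_ij^2` over the eigenmodes of the
#' stabilized dynamics: large values mean node `i` projects strongly
#' onto fast-decaying (hard-to-reach) modes.
#'
#' @inheritParams average_controllability
#' @return Scalar in `(0, 1]` for any Schur-stable symmetric dynamics.
#' @export
modal_controllability <- function(dyn, node) {
  .check_dyn(dyn)
  if (node < 1 || node > nrow(dyn$A)) stop("node index out of range")
  sum((1 - dyn$values^2) * dyn$vectors[node, ]^2)
}

#' Node-wise controllability profile
#'
#' Evaluates average and modal controllability for every node of the
#' network, reusing the single cached eigendecomposition; each node in
#' turn is the sole control point.
#'
#' @inheritParams average_controllability
#' @param subject_id,session Provenance carried into the profile.
#' @return Object of class `controllability_profile`: data frame-like
#'   list with `label`, `ac`, `mc` vectors plus `subject_id`, `session`.
#' @export
controllability_profile <- function(dyn, subject_id = NA_character_,
                                    session = NA_character_) {
  .check_dyn(dyn)
  V2 <- dyn$vectors^2
  ac <- as.numeric(V2 %*% (1 / (1 - dyn$values^2)))
  mc <- as.numeric(V2 %*% (1 - dyn$values^2))
  labels <- dyn$labels
  if (is.null(labels)) labels <- paste0("node", seq_len(nrow(dyn$A)))
  structure(
    list(label = labels, ac = ac, mc = mc,
         subject_id = subject_id, session = session),
    class = "controllability_profile"
  )
}

#' @export
as.data.frame.controllability_profile <- function(x, ...) {
  data.frame(subject_id = x$subject_id, session = x$session,
             label = x$label, ac = x$ac, mc = x$mc,
             stringsAsFactors = FALSE)
}

#' @export
print.controllability_profile <- function(x, ...) {
  cat(sprintf("<controllability_profile> subject %s, session %s, %d nodes\n",
              x$subject_id, x$session, length(x$label)))
  print(head(as.data.frame(x)))
  invisible(x)
}

#' Delta controllability between medication states
#'
#' Per-node signed differences (on minus off) in average and modal
#' controllability for one subject scanned in both medication sessions.
#'
#' @param on,off [controllability_profile] objects for the same subject
#'   with identical node labels.
#' @return Object of class `delta_profile` with `label`, `delta_ac`,
#'   `delta_mc`, `subject_id`.
#' @export
delta_profile <- function(on, off) {
  stopifnot(inherits(on, "controllability_profile"),
            inherits(off, "controllability_profile"))
  if (!identical(on$subject_id, off$subject_id)) {
    stop("subject mismatch: '", on$subject_id, "' vs '", off$subject_id, "'")
  }
  if (!identical(on$label, off$label)) stop("node labels differ between sessions")
  structure(
    list(label = on$label,
         delta_ac = on$ac - off$ac,
         delta_mc = on$mc - off$mc,
         subject_id = on$subject_id),
    class = "delta_profile"
  )
}

#' @export
as.data.frame.delta_profile <- function(x, ...) {
  data.frame(subject_id = x$subject_id, label = x$label,
             delta_ac = x$delta_ac, delta_mc = x$delta_mc,
             stringsAsFactors = FALSE)
}
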