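# Shared fixture builders: everything is generated in code at test time.

# random symmetric zero-diagonal "connectivity" matrix
random_fc <- function(n, seed = NULL, scale = 1) {
  if (!is.null(seed)) set.seed(seed)
  M <- matrix(rnorm(n * n, sd = scale), n, n)
  M <- (M + t(M)) / 2
  diag(M) <- 0
  M
}

random_dyn <- function(n, seed = NULL) stabilize(random_fc(n, seed))

# a deliberately small cohort for structural tests (fast: 10 nodes)
tiny_cohort <- function(seed = 1) {
  net <- make_base_network(n_nodes = 10, n_modules = 2,
                           perturbed_nodes = c(1L, 2L),
                           perturbation_scale = 0.5, seed = seed)
  cfg <- cohort_config(n_patients_stn = 3, n_patients_gpi = 2,
                       n_controls = 3, n_timepoints = 40,
                       n_drop_on = 1, n_drop_off = 0, seed = seed)
  generate_cohort(cfg, net)
}

# sinusoidal ROI series at a single frequency
sinusoid_ts <- function(freq_hz, n = 200, tr = 2, nodes = 2) {
  tt <- seq_len(n) * tr
  X <- sapply(seq_len(nodes), function(j) sin(2 * pi * freq_hz * tt + j))
  roi_timeseries(X, tr)
}
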