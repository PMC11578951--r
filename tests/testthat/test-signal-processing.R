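# Band-pass, motion expansion, nuisance regression, FD, scrubbing, FC.

test_that("band-pass keeps in-band sinusoids and rejects out-of-band ones", {
  inband <- sinusoid_ts(0.05, n = 200, tr = 2)
  out <- bandpass(inband, 0.01, 0.08)
  expect_equal(nrow(out$values), 200)
  expect_gt(cor(out$values[10:190, 1], inband$values[10:190, 1]), 0.999)

  highf <- sinusoid_ts(0.2, n = 200, tr = 2)
  filt <- bandpass(highf, 0.01, 0.08, detrend = FALSE)
  expect_lt(max(abs(filt$values)), 0.01 * max(abs(highf$values)))

  expect_error(bandpass(inband, 0.01, 0.3), "Nyquist")
  expect_error(bandpass(inband, 0.08, 0.01), "low_hz")
})

test_that("band-passed white noise concentrates its power in the pass band", {
  set.seed(2)
  ts <- roi_timeseries(matrix(rnorm(400), 400, 1), tr_seconds = 2)
  filt <- bandpass(ts, 0.01, 0.08)
  spec <- Mod(fft(filt$values[, 1]))^2
  freq <- seq(0, 399) / (400 * 2)
  freq <- pmin(freq, 0.5 - freq)
  inband <- freq >= 0.01 & freq <= 0.08
  expect_gte(sum(spec[inband]) / sum(spec), 0.99)
})

test_that("24-parameter motion expansion has the documented block structure", {
  z <- motion_trace(matrix(0, 10, 6))
  expect_equal(friston24(z), matrix(0, 10, 24,
                                    dimnames = list(NULL, colnames(friston24(z)))))

  ones <- friston24(motion_trace(matrix(1, 5, 6)))
  expect_equal(unname(ones[, 1:6]), matrix(1, 5, 6))       # base block
  expect_equal(unname(ones[1, 7:12]), rep(0, 6))           # lag first row
  expect_equal(unname(ones[-1, 7:12]), matrix(1, 4, 6))
  expect_equal(ones[, 13:18], ones[, 1:6], ignore_attr = TRUE)

  ramp <- friston24(motion_trace(matrix(1:6, 6, 6)))
  expect_equal(unname(ramp[, 7]), c(0, 1:5))               # lagged ramp
  expect_equal(unname(ramp[, 13]), (1:6)^2)                # squared ramp
  expect_equal(unname(ramp[, 19]), c(0, 1:5)^2)            # squared lag
})

test_that("confound regression residualizes exactly and is orthogonal", {
  set.seed(3)
  n <- 60
  c1 <- rnorm(n)
  # series equal to a confound -> zero residual
  ts <- roi_timeseries(cbind(c1, 2 * c1), tr_seconds = 2)
  res <- regress_confounds(ts, cbind(c1))
  expect_lt(max(abs(res$values)), 1e-10)

  # intercept only -> mean centering
  x <- rnorm(n)
  ts2 <- roi_timeseries(cbind(x, x + 5), tr_seconds = 2)
  res2 <- regress_confounds(ts2, matrix(numeric(0), n, 0))
  expect_equal(res2$values[, 1], x - mean(x), ignore_attr = TRUE)

  # planted orthogonal component is recovered
  e <- as.numeric(residuals(lm(rnorm(n) ~ c1)))  # orthogonal to 1 and c1
  ts3 <- roi_timeseries(cbind(2 * c1 + e), tr_seconds = 2)
  res3 <- regress_confounds(ts3, cbind(c1))
  expect_equal(as.numeric(res3$values), e, tolerance = 1e-10)

  # residuals orthogonal to every confound column
  conf <- cbind(rnorm(n), rnorm(n), rnorm(n))
  ts4 <- roi_timeseries(matrix(rnorm(3 * n), n, 3), tr_seconds = 2)
  r4 <- regress_confounds(ts4, conf)$values
  for (k in 1:3) {
    u <- conf[, k] / sqrt(sum(conf[, k]^2))
    expect_lt(max(abs(crossprod(u, r4))), 1e-8)
  }

  expect_warning(regress_confounds(ts4, cbind(c1, c1)), "dependent")
})

test_that("framewise displacement combines translations and scaled rotations", {
  still <- matrix(0, 20, 6)
  expect_equal(framewise_displacement(still), rep(0, 20))

  tr <- still
  tr[10:20, 1] <- 1  # single 1 mm x-step at frame 10
  fd <- framewise_displacement(tr)
  expect_equal(fd[10], 1.0)
  expect_equal(sum(fd), 1.0)

  rot <- still
  rot[5:20, 5] <- 0.02  # single 0.02 rad step, radius 50 -> 1 mm
  expect_equal(framewise_displacement(rot)[5], 1.0)
  expect_equal(framewise_displacement(rot, head_radius_mm = 100)[5], 2.0)
})

test_that("scrubbing censors supra-threshold frames plus followers", {
  set.seed(4)
  ts <- roi_timeseries(matrix(rnorm(40), 20, 2), tr_seconds = 2)

  clean <- scrub(ts, rep(0, 20), threshold_mm = 0.5)
  expect_true(all(clean$mask))
  expect_equal(clean$ts$values, ts$values)
  expect_true(clean$usable)

  fd <- rep(0, 20); fd[8] <- 1
  one <- scrub(ts, fd, threshold_mm = 0.5)
  expect_equal(sum(!one$mask), 2)
  expect_equal(which(!one$mask), c(8, 9))

  alt <- rep(c(0, 1), 10)
  expect_warning(res <- scrub(ts, alt, threshold_mm = 0.5), "unusable")
  expect_false(res$usable)
  expect_gte(res$frac_removed, 0.5)
})

test_that("Pearson FC handles exact, degenerate and rescaled inputs", {
  n <- 100
  tt <- seq_len(n)
  x <- sin(2 * pi * tt / 20)
  y <- cos(2 * pi * tt / 20)
  set.seed(5)
  z <- rnorm(n)
  ts <- roi_timeseries(cbind(a = x, b = x, c = -x, d = y, e = z),
                       tr_seconds = 2)
  fc <- pearson_fc(ts)
  expect_equal(fc$values["a", "b"], 1.0)
  expect_equal(fc$values["a", "c"], -1.0)
  expect_lt(abs(fc$values["a", "d"]), 1e-10)  # sin vs cos over full cycles
  expect_equal(diag(fc$values), rep(0, 5), ignore_attr = TRUE)
  expect_equal(fc$values, t(fc$values))

  # invariance to per-node affine rescaling
  ts2 <- roi_timeseries(cbind(a = 3 * x + 7, b = x, c = -0.1 * x + 2,
                              d = 5 * y, e = z / 9), tr_seconds = 2)
  expect_equal(pearson_fc(ts2)$values, fc$values, tolerance = 1e-12)

  flat <- roi_timeseries(cbind(a = x, b = rep(1, n)), tr_seconds = 2)
  expect_warning(fcf <- pearson_fc(flat), "zero-variance")
  expect_equal(fcf$values["a", "b"], 0)
})

test_that("the session pipeline preserves node count and labels", {
  set.seed(6)
  ts <- roi_timeseries(matrix(rnorm(80 * 4), 80, 4,
                              dimnames = list(NULL, c("w", "x", "y", "z"))),
                       tr_seconds = 2)
  motion <- motion_trace(cbind(matrix(rnorm(80 * 3, sd = 0.01), 80, 3),
                               matrix(rnorm(80 * 3, sd = 0.0005), 80, 3)))
  # tiny squared-rotation regressors may be numerically collinear; the
  # regression drops them with a warning, which is the documented path
  fc <- suppressWarnings(session_fc(ts, band = c(0.01, 0.08), motion = motion,
                                    scrub_threshold_mm = 0.5))
  expect_equal(fc$node_labels, c("w", "x", "y", "z"))
  expect_equal(dim(fc$values), c(4, 4))
})
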