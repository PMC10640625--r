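test_that("initial-frame removal shortens series and aligned traces equally", {
  ts <- rand_ts(12, 3)
  out <- drop_initial_frames(ts, 4)
  expect_equal(nrow(out$values), 8L)
  expect_equal(out$values[1, ], ts$values[5, ])

  expect_identical(drop_initial_frames(ts, 0), ts)
  expect_error(drop_initial_frames(rand_ts(4, 2), 4), "cannot drop")

  mt <- motion_trace(matrix(rnorm(72), 12, 6))
  mt2 <- drop_initial_rows(mt, 4)
  expect_equal(nrow(mt2$params), 8L)
  expect_equal(mt2$params[1, ], mt$params[5, ])
})

test_that("framewise displacement follows the translation + 50 mm rotation rule", {
  p <- matrix(0, 5, 6)
  p[3, 1:3] <- 0.1                       # +0.1 mm on each translation axis
  fd <- compute_fd(p)
  expect_equal(fd[1], 0)
  expect_equal(fd[3], 0.3)
  expect_equal(fd[4], 0.3)               # moves back

  p2 <- matrix(0, 4, 6)
  p2[2:4, 4] <- 0.002                    # 0.002 rad rotation step
  expect_equal(compute_fd(p2)[2], 0.1)   # 50 * 0.002
  expect_equal(compute_fd(p2)[3], 0)

  expect_equal(compute_fd(matrix(1, 6, 6)), rep(0, 6))
  expect_error(compute_fd(matrix(c(Inf, rnorm(23)), 4, 6)), "non-finite")
})

test_that("DVARS matches closed form and brute force after median-1000 scaling", {
  v <- matrix(1000, 10, 4, dimnames = list(NULL, paste0("r", 1:4)))
  ts <- make_ts(v)
  expect_equal(compute_dvars(ts), rep(0, 10))

  d <- 8
  v2 <- v; v2[6, 2] <- 1000 + d          # single-ROI step at frame 6
  dv <- compute_dvars(make_ts(v2))
  expect_equal(dv[6], d / sqrt(4))
  expect_equal(dv[7], d / sqrt(4))

  set.seed(5)
  for (i in 1:5) {
    vals <- matrix(1000 + rnorm(60, sd = 20), 10, 6)
    expect_lt(max(abs(compute_dvars(make_ts(vals)) - bf_dvars(vals))), 1e-10)
  }

  expect_error(compute_dvars(make_ts(matrix(0, 5, 3))), "median")
})

test_that("frame flagging censors one before and two after each seed", {
  fd <- rep(0, 30); dvars <- rep(0, 30)
  fd[10] <- 0.25
  mask <- flag_frames(fd, dvars)
  expect_identical(which(mask), c(9L, 10L, 11L, 12L))

  expect_false(any(flag_frames(rep(0.1, 30), rep(10, 30))))

  fd0 <- rep(0, 30); fd0[1] <- 1
  expect_identical(which(flag_frames(fd0, dvars)), c(1L, 2L, 3L))

  dv <- rep(0, 30); dv[29] <- 60
  expect_identical(which(flag_frames(rep(0, 30), dv)), c(28L, 29L, 30L))

  # monotone in thresholds: lowering fd_thresh never shrinks the mask
  set.seed(6)
  fdr <- runif(40, 0, 0.5); dvr <- runif(40, 0, 80)
  m_hi <- flag_frames(fdr, dvr, fd_thresh = 0.3)
  m_lo <- flag_frames(fdr, dvr, fd_thresh = 0.15)
  expect_true(all(m_lo[m_hi]))
})

test_that("censored frames are linearly interpolated with edge carry-over", {
  v <- matrix(0, 8, 2, dimnames = list(NULL, c("a", "b")))
  v[, 1] <- c(9, 9, 9, 9, 1.0, 99, 3.0, 3)
  v[, 2] <- 1:8
  mask <- rep(FALSE, 8); mask[6] <- TRUE
  out <- interpolate_frames(make_ts(v), mask)
  expect_equal(unname(out$values[6, 1]), 2.0)   # midpoint of 1.0 and 3.0
  expect_equal(unname(out$values[6, 2]), 6)
  expect_false(out$frame_usable[6])

  mask2 <- c(TRUE, TRUE, rep(FALSE, 6))
  out2 <- interpolate_frames(make_ts(v), mask2)
  expect_equal(out2$values[1, 1], v[3, 1])  # nearest usable value copied

  expect_identical(interpolate_frames(make_ts(v), rep(FALSE, 8))$values, v)
  expect_error(interpolate_frames(make_ts(v), rep(TRUE, 8)), "all frames")
})

test_that("retention rule excludes strictly below half the frames", {
  mask <- rep(c(TRUE, FALSE), c(398, 398))
  expect_equal(retention_check(mask)$decision, "include")     # exactly 50%
  mask2 <- rep(c(TRUE, FALSE), c(399, 397))
  expect_equal(retention_check(mask2)$decision, "exclude")
  expect_equal(retention_check(rep(FALSE, 10))$decision, "include")
  expect_equal(retention_check(rep(FALSE, 10))$retained_fraction, 1)
})

test_that("nuisance regression produces residuals orthogonal to confounds", {
  set.seed(7)
  ts <- rand_ts(40, 4)
  conf <- matrix(rnorm(120), 40, 3,
                 dimnames = list(NULL, c("global_signal", "white_matter", "csf")))
  # confound equal to an ROI's own series wipes that ROI
  conf[, 1] <- ts$values[, 2]
  res <- nuisance_regress(ts, conf)
  expect_lt(max(abs(res$values[, 2])), 1e-10)
  for (k in 1:3)
    expect_lt(max(abs(crossprod(conf[, k], res$values))), 1e-8)

  expect_error(nuisance_regress(ts, matrix(0, 40, 2)), "collinear")
})

test_that("band-pass keeps in-band sinusoids, kills out-of-band and DC", {
  tr <- 0.719
  t <- (0:599) * tr
  mid <- 150:450
  keep <- make_ts(cbind(sin(2 * pi * 0.03 * t), cos(2 * pi * 0.02 * t)), tr = tr)
  out <- bandpass_filter(keep)
  expect_gt(max(abs(out$values[mid, 1])), 0.95)
  expect_lt(abs(max(abs(out$values[mid, 1])) - 1), 0.05)

  kill <- make_ts(cbind(sin(2 * pi * 0.3 * t), rep(5, 600)), tr = tr)
  out2 <- bandpass_filter(kill)
  expect_lt(max(abs(out2$values[mid, 1])), 0.1)   # >= 90% attenuation
  expect_lt(max(abs(out2$values[, 2])), 1e-6)     # constant -> ~0

  expect_error(bandpass_filter(keep, low = 0.009, high = 0.8), "Nyquist|band")
})

test_that("vectorized zero-phase filtering equals signal::filtfilt per column", {
  set.seed(8)
  bf <- signal::butter(4, c(0.009, 0.08) / (0.5 / 0.719), type = "pass")
  X <- matrix(rnorm(300 * 5), 300, 5)
  ours <- netreconf:::mat_filtfilt(bf$b, bf$a, X)
  ref <- apply(X, 2, function(x) signal::filtfilt(bf, x))
  expect_equal(ours, ref, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("the 12-parameter motion model appends backward differences", {
  p <- matrix(rnorm(30), 5, 6,
              dimnames = list(NULL, c("trans_x", "trans_y", "trans_z",
                                      "rot_x", "rot_y", "rot_z")))
  ex <- expand_motion_params(motion_trace(p))
  expect_equal(ncol(ex), 12L)
  expect_equal(ex[1, 7:12], setNames(rep(0, 6), colnames(ex)[7:12]))
  expect_equal(unname(ex[3, 7]), unname(p[3, 1] - p[2, 1]))
})
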