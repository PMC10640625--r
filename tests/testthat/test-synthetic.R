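test_that("cohorts match the configured shape and age range", {
  cfg <- sim_config()
  mf <- simulate_cohort(cfg, seed = 5)
  expect_equal(nrow(mf), 48L)
  expect_equal(sum(mf$group == "MBTI"), 25L)
  expect_equal(sum(mf$group == "SHEEP"), 23L)
  expect_true(all(mf$age >= 50 & mf$age <= 80))
  expect_true(all(mf$gender %in% c(0, 1)))
  expect_identical(mf, simulate_cohort(cfg, seed = 5))
  expect_false(identical(mf, simulate_cohort(cfg, seed = 6)))
})

test_that("simulated button logs hit their accuracy target in expectation", {
  log <- simulate_events(1, duration_seconds = 400, seed = 2)
  expect_equal(score_bct(log)$accuracy, 1)

  set.seed(43)
  accs <- replicate(200, {
    s <- score_bct(simulate_events(0.6, duration_seconds = 600,
                                   seed = sample.int(1e6, 1)))
    c(s$n_correct, s$n_cycles)
  })
  pooled <- sum(accs[1, ]) / sum(accs[2, ])
  expect_lt(abs(pooled - 0.6), 0.05)

  expect_identical(simulate_events(0.7, 300, seed = 9),
                   simulate_events(0.7, 300, seed = 9))
  expect_error(simulate_events(0.5, duration_seconds = 10), "too short")
  expect_error(simulate_events(1.5, 300), "accuracy_target")
})

test_that("FFMQ simulation stays on the 1-5 scale and plants the Observing shift", {
  cfg <- sim_config()
  r <- simulate_ffmq("MBTI", "post", cfg, seed = 3)
  expect_length(r, 39L)
  expect_true(all(r %in% 1:5))

  # planted interaction: MBTI post raises Observing items relative to pre
  obs_items <- ffmq_facets()$observing
  set.seed(44)
  d_mbti <- mean(replicate(150, {
    post <- simulate_ffmq("MBTI", "post", cfg, seed = sample.int(1e6, 1))
    pre <- simulate_ffmq("MBTI", "pre", cfg, seed = sample.int(1e6, 1))
    mean(post[obs_items]) - mean(pre[obs_items])
  }))
  d_sheep <- mean(replicate(150, {
    post <- simulate_ffmq("SHEEP", "post", cfg, seed = sample.int(1e6, 1))
    pre <- simulate_ffmq("SHEEP", "pre", cfg, seed = sample.int(1e6, 1))
    mean(post[obs_items]) - mean(pre[obs_items])
  }))
  expect_gt(d_mbti, d_sheep)

  # no planted effects: pre/post means close
  cfg0 <- sim_config(ffmq_time_effect = 0, ffmq_observing_interaction = 0)
  set.seed(45)
  d0 <- mean(replicate(150, {
    post <- simulate_ffmq("MBTI", "post", cfg0, seed = sample.int(1e6, 1))
    pre <- simulate_ffmq("MBTI", "pre", cfg0, seed = sample.int(1e6, 1))
    mean(post[obs_items]) - mean(pre[obs_items])
  }))
  expect_lt(abs(d0), 0.1)
})

test_that("simulated scans carry the planted structure and pass validation", {
  cfg <- sim_config(n_participants = 4, n_mbti = 2)
  struct <- sim_structure(cfg, seed = 8)
  mf <- simulate_cohort(cfg, seed = 8)
  sc <- simulate_timeseries(struct, mf, 1, "pre", "rest", seed = 8)
  expect_s3_class(sc$ts, "roi_timeseries")
  expect_equal(ncol(sc$ts$values), cfg$n_rois)
  expect_equal(nrow(sc$ts$values), cfg$frames)
  expect_true(all(is.finite(sc$ts$values)))
  # scaled near median 1000
  expect_lt(abs(median(sc$ts$values) - 1000), 50)
  expect_null(sc$events)

  tk <- simulate_timeseries(struct, mf, 1, "post", "task", seed = 8)
  expect_s3_class(tk$events, "button_log")
  expect_false(anyNA(tk$eta))

  # regenerable in isolation from the master seed
  tk2 <- simulate_timeseries(struct, mf, 1, "post", "task", seed = 8)
  expect_identical(tk$ts$values, tk2$ts$values)
})

test_that("a motion spike censors the step frame with 1-before/2-after expansion", {
  params <- matrix(0, 60, 6)
  k <- 25L
  params[k:60, 1] <- 0.5                 # 0.5 mm step at frame k
  fd <- compute_fd(motion_trace(params))
  mask <- flag_frames(fd, rep(0, 60))
  expect_identical(which(mask), c(k - 1L, k, k + 1L, k + 2L))
})

test_that("ground truth is complete, reproducible, and encodes the contrast", {
  cfg <- sim_config(n_participants = 6, n_mbti = 3)
  st <- generate_study(cfg, seed = 12)
  nets <- networks(st$map)
  expect_equal(nrow(st$truth), 6 * 2 * length(nets))

  st2 <- generate_study(cfg, seed = 12)
  expect_identical(st$truth, st2$truth)

  # planted networks move by -contrast/2 (MBTI) and +contrast/2 (SHEEP)
  tr <- st$truth
  for (net in cfg$planted_networks) {
    for (i in seq_len(nrow(st$manifest))) {
      pid <- st$manifest$participant_id[i]
      grp <- st$manifest$group[i]
      pre <- tr$eta[tr$participant_id == pid & tr$timepoint == "pre" &
                      tr$network == net]
      post <- tr$eta[tr$participant_id == pid & tr$timepoint == "post" &
                       tr$network == net]
      lat_b1 <- tr$b1[tr$participant_id == pid & tr$network == net][1]
      shift <- if (grp == "MBTI") -cfg$eta_contrast / 2 else cfg$eta_contrast / 2
      expect_equal(post - pre, lat_b1 + shift, tolerance = 1e-10)
    }
  }
})

test_that("written studies reload through the package readers without errors", {
  dir <- withr::local_tempdir()
  cfg <- sim_config(n_participants = 4, n_mbti = 2)
  simulate_study(dir, cfg = cfg, seed = 21)
  expect_true(file.exists(file.path(dir, "manifest.tsv")))
  loaded <- netreconf:::load_study_dir(dir)
  expect_equal(nrow(loaded$manifest), 4L)
  expect_length(loaded$scans, 4L)
  ts <- loaded$scans[[1]]$pre$rest$ts
  expect_equal(nrow(ts$values), cfg$frames)
  orig <- generate_study(cfg, seed = 21)
  expect_lt(max(abs(ts$values - orig$scans[[1]]$pre$rest$ts$values)), 1e-9)
  ev <- loaded$scans[[1]]$post$task$events
  expect_s3_class(ev, "button_log")
  expect_false(is.na(score_bct(ev)$accuracy))
})

test_that("zero perturbation maximizes similarity and eta ordering is recovered", {
  cfg0 <- sim_config(n_participants = 2, n_mbti = 1, eta_base = 0,
                     eta_contrast = 0, sd_intercept = 0, sd_slope = 0)
  cfg_lo <- sim_config(n_participants = 2, n_mbti = 1, eta_base = 0.1,
                       eta_contrast = 0, sd_intercept = 0, sd_slope = 0)
  cfg_hi <- sim_config(n_participants = 2, n_mbti = 1, eta_base = 0.4,
                       eta_contrast = 0, sd_intercept = 0, sd_slope = 0)
  sim_mean <- function(cfg, s) {
    struct <- sim_structure(cfg, s)
    mf <- simulate_cohort(cfg, s)
    rest <- simulate_timeseries(struct, mf, 1, "pre", "rest", s)
    task <- simulate_timeseries(struct, mf, 1, "pre", "task", s)
    fr <- compute_fc(rest$ts); ft <- compute_fc(task$ts, condition = "task")
    mean(sapply(networks(struct$map), function(nt)
      similarity(fr, ft, struct$map, nt, "intra")))
  }
  seeds <- 1:8
  m0 <- mean(sapply(seeds, function(s) sim_mean(cfg0, s)))
  m_lo <- mean(sapply(seeds, function(s) sim_mean(cfg_lo, s)))
  m_hi <- mean(sapply(seeds, function(s) sim_mean(cfg_hi, s)))
  expect_gt(m0, m_lo)
  expect_gt(m_lo, m_hi)
})
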