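test_that("time-series TSV round trip is lossless and preserves ROI order", {
  m <- matrix(c(1.5, 2, 3, -0.25, 5, 6), nrow = 3,
              dimnames = list(NULL, c("roiB", "roiA")))
  ts <- roi_timeseries(m, tr_seconds = 0.719, run_label = "rest")
  expect_equal(dim(ts$values), c(3L, 2L))
  expect_identical(ts$roi_ids, c("roiB", "roiA"))

  path <- withr::local_tempfile(fileext = ".tsv")
  write_timeseries(ts, path)
  back <- read_timeseries(path, tr_seconds = 0.719, run_label = "rest")
  expect_identical(back$roi_ids, ts$roi_ids)
  expect_lt(max(abs(back$values - ts$values)), 1e-12)
  expect_true(all(back$frame_usable))

  set.seed(4)
  ts2 <- rand_ts(17, 5)
  write_timeseries(ts2, path)
  back2 <- read_timeseries(path, tr_seconds = 0.719)
  expect_lt(max(abs(back2$values - ts2$values)), 1e-12)
})

test_that("readers reject blanks, non-numeric cells and ragged rows", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("a\tb", "1\t2", "\t4", "5\t6"), path)
  expect_error(read_timeseries(path, 0.719), "row 2.*column 'a'|column 'a'.*row 2")

  writeLines(c("a\tb", "1\tx", "3\t4"), path)
  expect_error(read_timeseries(path, 0.719), "non-numeric.*row 1.*column 'b'")

  writeLines(c("a\tb", "1\t2\t9", "3\t4"), path)
  expect_error(read_timeseries(path, 0.719))
})

test_that("time-series invariants: unique ROIs, >1 frame/ROI, finite values", {
  m <- matrix(1:6, 3, 2, dimnames = list(NULL, c("r1", "r1")))
  expect_error(roi_timeseries(m, 0.7), "duplicate")
  expect_error(roi_timeseries(matrix(1:4, 1, 4,
    dimnames = list(NULL, paste0("r", 1:4))), 0.7), "frame")
  expect_error(roi_timeseries(matrix(1:4, 4, 1,
    dimnames = list(NULL, "r1")), 0.7), "ROI")
  m2 <- matrix(c(1, NA, 3, 4, 5, 6), 3, 2,
               dimnames = list(NULL, c("r1", "r2")))
  expect_error(roi_timeseries(m2, 0.7), "missing")
})

test_that("network map reads, validates and defines ROI order", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("roi_id\tnetwork", "r1\tA", "r2\tA", "r3\tA",
               "r4\tB", "r5\tB", "r6\tB"), path)
  map <- read_network_map(path)
  expect_identical(networks(map), c("A", "B"))
  expect_identical(as.integer(table(map$network)), c(3L, 3L))

  writeLines(c("roi_id\tnetwork", "r1\tA", "r1\tB"), path)
  expect_error(read_network_map(path), "duplicate")

  # ROI in time series but absent from map
  map6 <- network_map(paste0("r", 1:6), rep(c("A", "B"), each = 3))
  ts <- make_ts(matrix(rnorm(12), 2, 6))
  expect_error(conform_timeseries(ts, map6), "absent from network map")

  ts2 <- roi_timeseries(matrix(rnorm(12), 2, 6), 0.7,
                        roi_ids = paste0("r", 6:1))
  conf <- conform_timeseries(ts2, map6)
  expect_identical(conf$roi_ids, map6$roi_id)
  expect_equal(conf$values[, "r3"], ts2$values[, "r3"])
})

test_that("default network map has 9 networks and 430 ROIs", {
  map <- default_network_map()
  expect_equal(nrow(map), 430L)
  expect_length(networks(map), 9L)
  expect_equal(sum(map$cortical), 400L)
  expect_equal(sum(map$network == "subcortical"), 30L)
  expect_true(all(table(map$network) > 0))
})

test_that("event logs read in onset order, map trial types and validate onsets", {
  path <- withr::local_tempfile(fileext = ".tsv")
  df <- data.frame(onset = c(1:8, 9) * 4, duration = 0,
                   trial_type = c(rep("count", 8), "nine"))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  log <- read_events(path, run_duration_seconds = 60)
  expect_length(log$button, 9L)
  expect_identical(log$button, c(rep("count", 8), "nine"))

  df2 <- df[c(3, 1, 2, 4:9), ]
  write.table(df2, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_warning(log2 <- read_events(path, 60), "sort")
  expect_identical(log2$onset_seconds, df$onset)

  expect_error(read_events(path, run_duration_seconds = 10), "run_duration")

  df3 <- transform(df, trial_type = sub("nine", "button2", trial_type))
  write.table(df3, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_events(path, 60), "button2")
  log3 <- read_events(path, 60,
                      trial_type_map = c(count = "count", button2 = "nine"))
  expect_identical(log3$button[9], "nine")
})

test_that("confounds and manifest readers validate required columns", {
  path <- withr::local_tempfile(fileext = ".tsv")
  conf <- data.frame(trans_x = rnorm(5), trans_y = rnorm(5), trans_z = rnorm(5),
                     rot_x = rnorm(5), rot_y = rnorm(5), rot_z = rnorm(5),
                     global_signal = rnorm(5), white_matter = rnorm(5),
                     csf = rnorm(5))
  write.table(conf, path, sep = "\t", quote = FALSE, row.names = FALSE)
  cc <- read_confounds(path)
  expect_s3_class(cc$motion, "motion_trace")
  expect_equal(ncol(cc$nuisance), 3L)

  write.table(conf[, -1], path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_confounds(path), "trans_x")

  mf <- data.frame(participant_id = c("s1", "s2"), group = c("MBTI", "SHEEP"),
                   age = c(61, 55), gender = c(1, 0))
  write.table(mf, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_identical(read_manifest(path)$group, c("MBTI", "SHEEP"))
  mf$group[2] <- "CTRL"
  write.table(mf, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_manifest(path), "CTRL")
})
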