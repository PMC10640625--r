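test_that("long tables validate coding and pairing", {
  lt <- make_lt(rnorm(6), rnorm(6), group = rep(c("MBTI", "SHEEP"), 3))
  out <- long_table(lt)
  expect_true(all(out$group %in% c(0, 1)))
  expect_equal(sum(out$group) / 2, 3)

  bad <- lt[-1, ]
  expect_error(long_table(bad), "exactly 2 rows")
  lt2 <- lt; lt2$group[1] <- "CTRL"
  expect_error(long_table(lt2), "CTRL")
})

test_that("an exact linear outcome is recovered without noise", {
  set.seed(30)
  n <- 12
  grp <- rep(c(0, 1), 6); age <- rnorm(n, 60, 5); gen <- rbinom(n, 1, 0.5)
  a <- 2.5; b <- 1.25
  lt <- make_lt(rep(a, n), rep(a + b, n), group = grp, age = age, gender = gen)
  fit <- fit_lmm(lt)
  expect_equal(unname(coef(fit)["timepoint"]), b, tolerance = 1e-8)
  expect_equal(unname(coef(fit)["group:timepoint"]), 0, tolerance = 1e-8)
  expect_equal(unname(coef(fit)["age"]), 0, tolerance = 1e-8)

  expect_error(fit_lmm(make_lt(rnorm(6), rnorm(6), group = rep(0, 6))),
               "both groups")
  expect_error(fit_lmm(make_lt(rnorm(3), rnorm(3), group = c(0, 1, 0))),
               "at least 4")
})

test_that("fixed effects match lme4 on simulated longitudinal data", {
  set.seed(31)
  worst <- 0
  for (i in 1:8) {
    n <- 24
    grp <- sample(rep(c(0, 1), 12))
    age <- rnorm(n, 60, 6); gen <- rbinom(n, 1, 0.5)
    b0 <- rnorm(n, 0, 0.6); b1 <- rnorm(n, 0, 0.3)
    ypre <- 1 + 0.02 * age + 0.3 * gen + 0.2 * grp + b0 + rnorm(n, 0, 0.5)
    ypost <- ypre - rnorm(n, 0, 0.5) + 0.4 + 0.3 * grp + b1 + rnorm(n, 0, 0.5)
    lt <- make_lt(ypre, ypost, group = grp, age = age, gender = gen)
    f_fast <- fit_lmm(lt, engine = "reml2")
    f_ref <- fit_lmm(lt, engine = "lmer")
    worst <- max(worst, max(abs(coef(f_fast) - coef(f_ref))))
  }
  expect_lt(worst, 5e-3)
})

test_that("simulation recovers a planted interaction without bias", {
  set.seed(32)
  gamma <- 0.6
  ests <- replicate(100, {
    n <- 200
    grp <- rep(c(0, 1), 100)
    b0 <- rnorm(n, 0, 0.5); b1 <- rnorm(n, 0, 0.2)
    ypre <- b0 + rnorm(n, 0, 0.4)
    ypost <- b0 + b1 + 0.3 + gamma * grp + rnorm(n, 0, 0.4)
    coef(fit_lmm(make_lt(ypre, ypost, group = grp)))["group:timepoint"]
  })
  mc_se <- sd(ests) / sqrt(length(ests))
  expect_lt(abs(mean(ests) - gamma), 2 * mc_se + 1e-8)
})

test_that("label permutation preserves participants and swaps half the pairs", {
  set.seed(33)
  lt <- long_table(make_lt(rnorm(10), rnorm(10), group = rep(c(0, 1), 5)))
  p1 <- permute_labels(lt)
  expect_equal(sort(unique(p1$participant_id)), sort(unique(lt$participant_id)))
  expect_equal(sum(p1$group), sum(lt$group))
  # age/gender ride with the participant
  expect_equal(p1$age[match(lt$participant_id, p1$participant_id)], lt$age)
  # outcome pairs are intact (possibly swapped within participant)
  for (pid in unique(lt$participant_id))
    expect_setequal(p1$value[p1$participant_id == pid],
                    lt$value[lt$participant_id == pid])

  set.seed(101); a <- permute_labels(lt)
  set.seed(101); b <- permute_labels(lt)
  expect_identical(a, b)

  # swap frequency ~ 0.5
  swaps <- 0; draws <- 1500
  set.seed(34)
  for (i in seq_len(draws)) {
    p <- permute_labels(lt)
    pre_vals <- p$value[p$timepoint == 0]
    swaps <- swaps + sum(pre_vals != lt$value[lt$timepoint == 0])
  }
  rate <- swaps / (draws * 10)
  expect_gt(rate, 0.48); expect_lt(rate, 0.52)
})

test_that("permutation p-values follow the fraction-of-iterations definition", {
  set.seed(35)
  lt <- make_lt(rnorm(16), rnorm(16), group = rep(c(0, 1), 8))
  pr <- permutation_tests(lt, terms = c("timepoint", "group:timepoint"),
                          n_perm = 59, seed = 42)
  for (tm in names(pr)) {
    x <- pr[[tm]]
    expect_equal(x$p_value, mean(abs(x$null) >= abs(x$observed)))
    expect_length(x$null, 59L)
    expect_gte(x$p_value, 0); expect_lte(x$p_value, 1)
  }
  # an observed beta of zero would make every permutation at least as
  # extreme: the formula then gives exactly 1
  expect_equal(mean(abs(pr[[1]]$null) >= 0), 1)

  # reproducible given the seed
  pr2 <- permutation_pvalue(lt, term = "group:timepoint", n_perm = 59, seed = 42)
  expect_identical(pr2$null, pr[["group:timepoint"]]$null)

  # invariant to outcome rescaling
  lt10 <- lt; lt10$value <- lt10$value * 10
  pr10 <- permutation_pvalue(lt10, term = "group:timepoint", n_perm = 59, seed = 42)
  expect_equal(pr10$p_value, pr[["group:timepoint"]]$p_value)

  # the (k+1)/(n+1) variant is available and never smaller
  pr_c <- permutation_pvalue(lt, term = "group:timepoint", n_perm = 59,
                             seed = 42, add_one = TRUE)
  expect_gte(pr_c$p_value, pr[["group:timepoint"]]$p_value)
})

test_that("a strong planted interaction is detected, a null one is not", {
  set.seed(36)
  n <- 48
  grp <- sample(rep(c(0, 1), 24))
  b0 <- rnorm(n, 0, 0.3)
  ypre <- b0 + rnorm(n, 0, 0.3)
  ypost <- b0 + rnorm(n, 0, 0.3) - 1.0 * grp      # 1 SD-scale interaction
  pr <- permutation_pvalue(make_lt(ypre, ypost, group = grp),
                           term = "group:timepoint", n_perm = 199, seed = 1)
  expect_lte(pr$p_value, 0.05)
  expect_lt(pr$observed, 0)
})

test_that("type-I error of the permutation interaction test is near nominal", {
  set.seed(37)
  rej <- replicate(80, {
    n <- 20
    grp <- sample(rep(c(0, 1), 10))
    b0 <- rnorm(n, 0, 0.5); b1 <- rnorm(n, 0, 0.3)
    lt <- make_lt(b0 + rnorm(n, 0, 0.4), b0 + b1 + rnorm(n, 0, 0.4),
                  group = grp)
    permutation_pvalue(lt, "group:timepoint", n_perm = 99,
                       seed = sample.int(1e6, 1))$p_value <= 0.05
  })
  # broad sanity band for 80 datasets; the acceptance suite runs the full
  # calibration at 500 datasets with the exact binomial interval
  expect_gte(mean(rej), 0.0)
  expect_lte(mean(rej), 0.15)
})

test_that("Cliff's delta enumerates pair dominance and is antisymmetric", {
  expect_equal(cliffs_delta(c(2, 3), c(0, 1))$cliffs_delta, 1)
  expect_equal(cliffs_delta(c(4, 1, 7), c(4, 1, 7))$cliffs_delta, 0)
  expect_equal(cliffs_delta(c(1, 2, 3), c(2, 2, 2))$cliffs_delta, 0)

  set.seed(38)
  for (i in 1:20) {
    x <- rnorm(sample(2:12, 1)); y <- rnorm(sample(2:12, 1))
    d <- cliffs_delta(x, y)$cliffs_delta
    expect_equal(d, bf_cliffs(x, y))
    expect_equal(cliffs_delta(y, x)$cliffs_delta, -d)
    expect_gte(d, -1); expect_lte(d, 1)
  }
  expect_error(cliffs_delta(numeric(0), 1), "nonempty")
})

test_that("Mann-Whitney U counts dominated pairs; exact and normal p agree", {
  mw <- mann_whitney(c(1, 2), c(3, 4))
  expect_equal(mw$U, 0)
  expect_equal(mw$method, "exact")

  mw2 <- mann_whitney(c(1, 2, 3), c(1, 2, 3))
  expect_equal(mw2$p_value, 1)

  set.seed(39)
  for (i in 1:10) {
    x <- rnorm(15); y <- rnorm(15, 0.2)
    pe <- mann_whitney(x, y)$p_value
    wa <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                              correct = TRUE))$p.value
    expect_lt(abs(pe - wa), 0.02)
  }
})

test_that("association models recover exact slopes and calibrate under the null", {
  set.seed(40)
  n <- 30
  ch <- data.frame(participant_id = sprintf("p%02d", 1:n),
                   group = sample(rep(c(0, 1), 15)),
                   age = rnorm(n, 60, 5), gender = rbinom(n, 1, 0.5),
                   d_similarity = rnorm(n))
  ch$d_behavior <- 2 * ch$d_similarity
  fa <- fit_association(ch, n_perm = 99, seed = 1)
  expect_equal(unname(fa$coefficients["d_similarity"]), 2, tolerance = 1e-10)
  expect_lte(fa$slope_p, 0.05)

  # null calibration: independent deltas reject near alpha
  rej <- replicate(60, {
    ch$d_behavior <- rnorm(n)
    fit_association(ch, n_perm = 99, seed = sample.int(1e6, 1))$slope_p <= 0.05
  })
  expect_lte(mean(rej), 0.15)

  ch$group <- 0
  expect_error(fit_association(ch, with_interaction = TRUE), "both groups")
  expect_error(fit_association(ch[1:5, ]), "at least 10")
})
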