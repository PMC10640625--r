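# Longitudinal inference: linear mixed models for the balanced
# two-timepoint design, the permutation scheme (group shuffle + 50%
# timepoint swap), and brain-behavior association models.
#
# Model: Y ~ Age + Gender + Group * Timepoint + (1 + Timepoint | Participant)
# Coding: Group 1 = SHEEP (control), 0 = MBTI; Timepoint 1 = post;
# Gender 1 = female. With an improvement concentrated in the mindfulness
# arm this convention yields a negative Group x Timepoint coefficient.

lmm_terms <- c("(Intercept)", "age", "gender", "group", "timepoint",
               "group:timepoint")

#' Validate and normalize a long outcome table
#'
#' One row per participant x timepoint, with binary dummy coding: `group`
#' (0 = MBTI, 1 = SHEEP), `timepoint` (0 = pre, 1 = post), `gender`
#' (0/1). Factor-style labels (`MBTI`/`SHEEP`, `pre`/`post`) are recoded.
#'
#' @param df Data frame with columns `participant_id`, `group`,
#'   `timepoint`, `age`, `gender`, `value`.
#' @return A validated data.frame of class `long_table`, ordered by
#'   participant then timepoint.
#' @export
long_table <- function(df) {
  need <- c("participant_id", "group", "timepoint", "age", "gender", "value")
  if (!all(need %in% names(df)))
    stop("long table must have columns ", paste(need, collapse = ", "), call. = FALSE)
  df <- as.data.frame(df)[need]
  df$participant_id <- as.character(df$participant_id)
  if (is.character(df$group) || is.factor(df$group)) {
    g <- as.character(df$group)
    bad <- setdiff(unique(g), c("MBTI", "SHEEP"))
    if (length(bad)) stop("unknown group label(s): ", paste(bad, collapse = ", "), call. = FALSE)
    df$group <- as.numeric(g == "SHEEP")
  }
  if (is.character(df$timepoint) || is.factor(df$timepoint)) {
    tp <- as.character(df$timepoint)
    bad <- setdiff(unique(tp), c("pre", "post"))
    if (length(bad)) stop("unknown timepoint label(s): ", paste(bad, collapse = ", "), call. = FALSE)
    df$timepoint <- as.numeric(tp == "post")
  }
  df$group <- as.numeric(df$group)
  df$timepoint <- as.numeric(df$timepoint)
  df$gender <- as.numeric(df$gender)
  df$age <- as.numeric(df$age)
  df$value <- as.numeric(df$value)
  if (!all(df$group %in% c(0, 1)) || !all(df$timepoint %in% c(0, 1)) ||
      !all(df$gender %in% c(0, 1)))
    stop("group, timepoint and gender must be binary 0/1 codes", call. = FALSE)
  if (anyNA(df$value) || anyNA(df$age))
    stop("missing values in outcome or age", call. = FALSE)
  cnt <- table(df$participant_id)
  if (any(cnt != 2))
    stop("each participant needs exactly 2 rows (pre and post); offending: ",
         paste(utils::head(names(cnt)[cnt != 2], 5), collapse = ", "), call. = FALSE)
  df <- df[order(df$participant_id, df$timepoint), ]
  both <- tapply(df$timepoint, df$participant_id, function(x) identical(sort(x), c(0, 1)))
  if (!all(both))
    stop("each participant needs one pre and one post row", call. = FALSE)
  rownames(df) <- NULL
  class(df) <- c("long_table", "data.frame")
  df
}

# Wide per-participant view: Y (m x 2), participant-level covariates.
lt_wide <- function(table) {
  pre <- table[table$timepoint == 0, ]
  post <- table[table$timepoint == 1, ]
  stopifnot(identical(pre$participant_id, post$participant_id))
  list(participant_id = pre$participant_id,
       Y = cbind(pre$value, post$value),
       age = pre$age, gender = pre$gender, group = pre$group)
}

# REML objective and GLS fixed effects for the balanced two-timepoint
# design with an unstructured 2x2 marginal covariance V (the marginal
# family induced by per-participant random intercept + timepoint slope).
reml2_engine <- function(w) {
  m <- length(w$age)
  Xpre <- cbind(1, w$age, w$gender, w$group, 0, 0)
  Xpost <- cbind(1, w$age, w$gender, w$group, 1, w$group)
  if (qr(rbind(Xpre, Xpost))$rank < 6)
    stop("fixed-effect design is rank deficient (constant covariate or group)",
         call. = FALSE)
  A11 <- crossprod(Xpre); A22 <- crossprod(Xpost)
  A12 <- crossprod(Xpre, Xpost); As <- A12 + t(A12)

  vpar <- function(th) {
    # clamp so V stays invertible: |rho| <= tanh(5) ~ 0.9999
    s1 <- exp(min(max(th[1], -15), 15))
    s2 <- exp(min(max(th[2], -15), 15))
    rho <- tanh(min(max(th[3], -5), 5))
    c(v11 = s1 * s1, v22 = s2 * s2, v12 = rho * s1 * s2)
  }

  fit_for_Y <- function(Y, maxit = 600, structure = c("full", "cs")) {
    structure <- match.arg(structure)
    b11 <- crossprod(Xpre, Y[, 1]); b22 <- crossprod(Xpost, Y[, 2])
    bs <- crossprod(Xpre, Y[, 2]) + crossprod(Xpost, Y[, 1])
    obj <- function(th) {
      v <- vpar(th)
      v11 <- v[[1]]; v22 <- v[[2]]; v12 <- v[[3]]
      dt <- v11 * v22 - v12 * v12
      w11 <- v22 / dt; w22 <- v11 / dt; w12 <- -v12 / dt
      XtWX <- w11 * A11 + w12 * As + w22 * A22
      ch <- tryCatch(chol(XtWX), error = function(e) NULL)
      if (is.null(ch)) return(1e10)
      beta <- backsolve(ch, forwardsolve(t(ch), w11 * b11 + w12 * bs + w22 * b22))
      r1 <- Y[, 1] - Xpre %*% beta; r2 <- Y[, 2] - Xpost %*% beta
      quad <- w11 * sum(r1 * r1) + 2 * w12 * sum(r1 * r2) + w22 * sum(r2 * r2)
      m * log(dt) + 2 * sum(log(diag(ch))) + quad
    }
    # warm start: OLS residual covariance
    Xall <- rbind(Xpre, Xpost)
    bo <- qr.coef(qr(Xall), c(Y[, 1], Y[, 2]))
    R <- cbind(Y[, 1] - Xpre %*% bo, Y[, 2] - Xpost %*% bo)
    if (max(abs(R)) < 1e-10 * max(1, max(abs(Y)))) {
      # outcome lies exactly in the fixed-effect span: GLS = OLS for any V
      beta <- stats::setNames(as.numeric(bo), lmm_terms)
      return(list(beta = beta, V = matrix(0, 2, 2,
                    dimnames = list(c("pre", "post"), c("pre", "post"))),
                  vcov_beta = matrix(0, 6, 6), converged = TRUE))
    }
    Sv <- crossprod(R) / m
    Sv <- Sv + diag(2) * (1e-10 * (max(diag(Sv)) + 1e-10))
    rho0 <- Sv[1, 2] / sqrt(Sv[1, 1] * Sv[2, 2])
    st <- c(0.5 * log(Sv[1, 1]), 0.5 * log(Sv[2, 2]),
            atanh(max(-0.99, min(0.99, rho0))))
    if (structure == "cs") {
      # random-intercept-only fallback: equal variances, rho in [0, 1)
      obj_cs <- function(th2) obj(c(th2[1], th2[1],
                                    max(0, th2[2])))
      st_cs <- c(mean(st[1:2]), max(0, st[3]))
      op2 <- stats::optim(st_cs, obj_cs, method = "Nelder-Mead",
                          control = list(maxit = maxit, reltol = 1e-9))
      op <- list(par = c(op2$par[1], op2$par[1], max(0, op2$par[2])),
                 convergence = op2$convergence, value = op2$value)
    } else {
      op <- stats::optim(st, obj, method = "Nelder-Mead",
                         control = list(maxit = maxit, reltol = 1e-9))
    }
    v <- vpar(op$par)
    v11 <- v[[1]]; v22 <- v[[2]]; v12 <- v[[3]]
    dt <- v11 * v22 - v12 * v12
    w11 <- v22 / dt; w22 <- v11 / dt; w12 <- -v12 / dt
    XtWX <- w11 * A11 + w12 * As + w22 * A22
    sol <- tryCatch({
      list(beta = drop(solve(XtWX, w11 * b11 + w12 * bs + w22 * b22)),
           vb = solve(XtWX))
    }, error = function(e) NULL)
    if (is.null(sol))
      return(list(beta = NULL, V = NULL, vcov_beta = NULL, converged = FALSE))
    beta <- sol$beta
    names(beta) <- lmm_terms
    list(beta = beta,
         V = matrix(c(v11, v12, v12, v22), 2,
                    dimnames = list(c("pre", "post"), c("pre", "post"))),
         vcov_beta = sol$vb,
         converged = op$convergence == 0 && is.finite(op$value) && op$value < 1e9)
  }
  fit_for_Y
}

#' Fit the longitudinal linear mixed model
#'
#' REML fit of `value ~ age + gender + group * timepoint` with
#' per-participant random intercept and timepoint slope. The default engine
#' (`"reml2"`) profiles the fixed effects over the unstructured 2x2
#' marginal covariance of the (pre, post) pair — the marginal family the
#' random intercept + slope structure induces at two timepoints — which is
#' fast and free of boundary issues. `engine = "lmer"` fits the literal
#' random-effects model through \pkg{lme4} (identifiability checks relaxed,
#' as two observations per participant sit at the edge of what the
#' random-slope parameterization identifies); it serves as the reference
#' implementation and agrees with `"reml2"` on fixed effects.
#'
#' @param table A [long_table()] (or coercible data.frame).
#' @param engine `"reml2"` (default) or `"lmer"`.
#' @return Object of class `lmm_fit`: `coefficients` (named vector:
#'   intercept, age, gender, group, timepoint, group:timepoint),
#'   `V` (marginal 2x2 covariance of a participant's pre/post pair),
#'   `varcomp` (random-effect variance components, `lmer` engine only),
#'   `converged`, `engine`.
#' @export
fit_lmm <- function(table, engine = c("reml2", "lmer")) {
  engine <- match.arg(engine)
  table <- long_table(table)
  w <- lt_wide(table)
  if (length(w$age) < 4) stop("need at least 4 participants", call. = FALSE)
  if (length(unique(w$group)) < 2)
    stop("both groups must be represented", call. = FALSE)
  if (engine == "reml2") {
    fitter <- reml2_engine(w)
    f <- fitter(w$Y)
    flagged <- FALSE
    if (!f$converged) f <- fitter(w$Y, maxit = 5000)
    if (!f$converged) {          # random-intercept-only fallback, flagged
      flagged <- TRUE
      f <- fitter(w$Y, maxit = 5000, structure = "cs")
    }
    if (!f$converged)
      stop("REML fit did not converge (full and random-intercept structures)",
           call. = FALSE)
    return(structure(list(coefficients = f$beta, V = f$V,
                          vcov_beta = f$vcov_beta, varcomp = NULL,
                          converged = !flagged, engine = "reml2"),
                     class = "lmm_fit"))
  }
  ctrl <- lme4::lmerControl(check.nobs.vs.nRE = "ignore",
                            check.conv.singular = "ignore",
                            check.conv.grad = "ignore",
                            check.conv.hess = "ignore",
                            calc.derivs = FALSE)
  d <- as.data.frame(table)
  fit <- tryCatch(
    suppressWarnings(suppressMessages(
      lme4::lmer(value ~ age + gender + group * timepoint +
                   (1 + timepoint | participant_id),
                 data = d, REML = TRUE, control = ctrl))),
    error = function(e) NULL)
  flagged <- FALSE
  if (is.null(fit)) {   # fall back to random intercept only
    flagged <- TRUE
    fit <- tryCatch(
      suppressWarnings(suppressMessages(
        lme4::lmer(value ~ age + gender + group * timepoint +
                     (1 | participant_id),
                   data = d, REML = TRUE, control = ctrl))),
      error = function(e) NULL)
    if (is.null(fit)) stop("lmer failed to fit even the random-intercept model",
                           call. = FALSE)
  }
  beta <- lme4::fixef(fit)
  names(beta) <- lmm_terms
  vc <- as.data.frame(lme4::VarCorr(fit))
  structure(list(coefficients = beta, V = NULL, vcov_beta = as.matrix(stats::vcov(fit)),
                 varcomp = vc, converged = !flagged, engine = "lmer"),
            class = "lmm_fit")
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat("<lmm_fit (", x$engine, ")>\n", sep = "")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @export
coef.lmm_fit <- function(object, ...) object$coefficients

#' Permute group and timepoint labels
#'
#' The permutation scheme for the longitudinal model: group labels are
#' shuffled as whole participants (both rows of a participant receive the
#' same permuted label, preserving group sizes), and independently each
#' participant's two timepoint labels are swapped with probability 0.5.
#' Age, gender and outcome values stay attached to their participant. Uses
#' the current R RNG state.
#'
#' @param table A [long_table()].
#' @return A permuted `long_table`.
#' @export
permute_labels <- function(table) {
  table <- long_table(table)
  w <- lt_wide(table)
  m <- length(w$group)
  gperm <- w$group[sample.int(m)]
  swap <- stats::runif(m) < 0.5
  Y <- w$Y
  Y[swap, ] <- Y[swap, 2:1, drop = FALSE]
  long_table(data.frame(
    participant_id = rep(w$participant_id, each = 2),
    group = rep(gperm, each = 2),
    timepoint = rep(c(0, 1), m),
    age = rep(w$age, each = 2),
    gender = rep(w$gender, each = 2),
    value = as.vector(t(Y))))
}

#' Permutation p-value for a fixed-effect term
#'
#' Fits the observed table, then `n_perm` permuted tables under the group
#' shuffle + 50% timepoint swap scheme, with identical fitting
#' configuration throughout. The two-sided p-value is the fraction of
#' permutations whose |beta| is at least |beta_observed| (no small-sample
#' +1 correction by default, matching the plain fraction-of-iterations
#' definition; `add_one = TRUE` gives the (k+1)/(n+1) variant).
#' Non-convergent permutation fits are redrawn; more than 10% redraws is an
#' error.
#'
#' @param table A [long_table()].
#' @param term One of `"timepoint"`, `"group:timepoint"`, `"group"`,
#'   `"age"`, `"gender"`.
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed for the permutation stream.
#' @param engine Fitting engine, as in [fit_lmm()].
#' @param add_one Apply the (k+1)/(n+1) correction (default `FALSE`).
#' @return Object of class `perm_result`: `term`, `observed`, `null`
#'   (length `n_perm`), `p_value`, `n_perm`, `seed`, `n_redrawn`.
#' @export
permutation_pvalue <- function(table, term = "group:timepoint", n_perm = 1000,
                               seed = 1L, engine = c("reml2", "lmer"),
                               add_one = FALSE) {
  term <- match.arg(term, lmm_terms[-1])
  permutation_tests(table, terms = term, n_perm = n_perm, seed = seed,
                    engine = engine, add_one = add_one)[[term]]
}

#' Permutation tests for several terms from one permutation stream
#'
#' Same scheme as [permutation_pvalue()] but each permuted dataset is fit
#' once and all requested terms' null betas are collected from it.
#'
#' @inheritParams permutation_pvalue
#' @param terms Character vector of fixed-effect terms.
#' @return Named list of `perm_result` objects, one per term.
#' @export
permutation_tests <- function(table, terms = c("timepoint", "group:timepoint"),
                              n_perm = 1000, seed = 1L,
                              engine = c("reml2", "lmer"), add_one = FALSE) {
  engine <- match.arg(engine)
  stopifnot(all(terms %in% lmm_terms[-1]))
  table <- long_table(table)
  obs_fit <- fit_lmm(table, engine = engine)
  obs <- obs_fit$coefficients[terms]
  w <- lt_wide(table)
  m <- length(w$group)
  nulls <- matrix(NA_real_, n_perm, length(terms),
                  dimnames = list(NULL, terms))
  n_redrawn <- 0L
  max_redraw <- max(10L, ceiling(0.1 * n_perm))
  set.seed(as.integer(seed))
  i <- 1L
  while (i <= n_perm) {
    gperm <- w$group[sample.int(m)]
    swap <- stats::runif(m) < 0.5
    Y <- w$Y
    Y[swap, ] <- Y[swap, 2:1, drop = FALSE]
    b <- if (engine == "reml2") {
      wp <- list(age = w$age, gender = w$gender, group = gperm)
      # a permuted group vector can coincide with gender (collinear
      # design); such draws are redrawn like non-convergent fits
      f <- tryCatch({
        fitter <- reml2_engine(wp)
        fp <- fitter(Y)
        if (!fp$converged) fp <- fitter(Y, maxit = 5000)
        if (!fp$converged) fp <- fitter(Y, maxit = 5000, structure = "cs")
        fp
      }, error = function(e) NULL)
      if (!is.null(f) && f$converged) f$beta[terms] else NULL
    } else {
      tb <- data.frame(participant_id = rep(w$participant_id, each = 2),
                       group = rep(gperm, each = 2), timepoint = rep(c(0, 1), m),
                       age = rep(w$age, each = 2), gender = rep(w$gender, each = 2),
                       value = as.vector(t(Y)))
      f <- tryCatch(fit_lmm(tb, engine = "lmer"), error = function(e) NULL)
      if (!is.null(f)) f$coefficients[terms] else NULL
    }
    if (is.null(b)) {
      n_redrawn <- n_redrawn + 1L
      if (n_redrawn > max_redraw)
        stop("more than 10% of permutation fits failed to converge", call. = FALSE)
      next
    }
    nulls[i, ] <- b
    i <- i + 1L
  }
  out <- list()
  for (tm in terms) {
    k <- sum(abs(nulls[, tm]) >= abs(obs[[tm]]))
    p <- if (add_one) (k + 1) / (n_perm + 1) else k / n_perm
    out[[tm]] <- structure(
      list(term = tm, observed = obs[[tm]], null = nulls[, tm], p_value = p,
           n_perm = n_perm, seed = as.integer(seed),
           n_redrawn = n_redrawn, engine = engine),
      class = "perm_result")
  }
  out
}

#' @export
print.perm_result <- function(x, ...) {
  cat(sprintf("<perm_result: %s beta = %.4f, p = %.4g (%d permutations, seed %d)>\n",
              x$term, x$observed, x$p_value, x$n_perm, x$seed))
  invisible(x)
}

#' Brain-behavior association model on change scores
#'
#' Ordinary linear model of behavioral change (post - pre) on FC-similarity
#' change with age and gender as covariates of no interest, optionally with
#' a group x similarity-change interaction. Inference by permutation:
#' group labels are shuffled across participants and the *outcome* change
#' score is sign-flipped per participant with probability 0.5 (the
#' change-score analogue of the timepoint swap, applied to the outcome so
#' the null of no brain-behavior association is exchangeable).
#'
#' @param changes Data frame with one row per participant: columns
#'   `participant_id`, `group` (0/1 or MBTI/SHEEP), `age`, `gender`,
#'   `d_behavior`, `d_similarity`.
#' @param with_interaction Include group main effect and
#'   group x similarity-change interaction (default `FALSE`).
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed.
#' @param alternative `"two.sided"` (default) or `"greater"` (positive
#'   association).
#' @return List: `coefficients`, `slope_p`, and when `with_interaction`,
#'   `interaction_p`; plus `n_perm`, `seed`.
#' @export
fit_association <- function(changes, with_interaction = FALSE, n_perm = 1000,
                            seed = 1L, alternative = c("two.sided", "greater")) {
  alternative <- match.arg(alternative)
  need <- c("group", "age", "gender", "d_behavior", "d_similarity")
  if (!all(need %in% names(changes)))
    stop("changes table must have columns ", paste(need, collapse = ", "), call. = FALSE)
  if (nrow(changes) < 10) stop("need at least 10 participants", call. = FALSE)
  g <- changes$group
  if (is.character(g) || is.factor(g)) g <- as.numeric(as.character(g) == "SHEEP")
  if (with_interaction && length(unique(g)) < 2)
    stop("interaction model needs both groups represented", call. = FALSE)
  build_X <- function(gv, ds) {
    if (with_interaction)
      cbind(1, ds, changes$age, changes$gender, gv, gv * ds)
    else cbind(1, ds, changes$age, changes$gender)
  }
  fit_beta <- function(y, X) qr.coef(qr(X), y)
  X <- build_X(g, changes$d_similarity)
  beta <- fit_beta(changes$d_behavior, X)
  names(beta) <- if (with_interaction)
    c("(Intercept)", "d_similarity", "age", "gender", "group", "group:d_similarity")
  else c("(Intercept)", "d_similarity", "age", "gender")
  n <- nrow(changes)
  null_slope <- numeric(n_perm)
  null_inter <- if (with_interaction) numeric(n_perm) else NULL
  set.seed(as.integer(seed))
  i <- 1L
  n_redrawn <- 0L
  while (i <= n_perm) {
    gp <- g[sample.int(n)]
    flip <- ifelse(stats::runif(n) < 0.5, -1, 1)
    bp <- fit_beta(flip * changes$d_behavior, build_X(gp, changes$d_similarity))
    if (anyNA(bp)) {              # collinear permuted design; redraw
      n_redrawn <- n_redrawn + 1L
      if (n_redrawn > max(10L, ceiling(0.1 * n_perm)))
        stop("too many degenerate permutation designs", call. = FALSE)
      next
    }
    null_slope[i] <- bp[2]
    if (with_interaction) null_inter[i] <- bp[6]
    i <- i + 1L
  }
  pval <- function(obs, null) {
    if (alternative == "greater") mean(null >= obs) else mean(abs(null) >= abs(obs))
  }
  out <- list(coefficients = beta,
              slope_p = pval(beta[["d_similarity"]], null_slope),
              n_perm = n_perm, seed = as.integer(seed),
              alternative = alternative)
  if (with_interaction)
    out$interaction_p <- pval(beta[["group:d_similarity"]], null_inter)
  out
}
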