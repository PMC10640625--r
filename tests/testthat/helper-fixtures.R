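# Shared fixtures and independent brute-force oracles. The oracles are
# deliberately naive (explicit loops, no shared code with the package
# internals) so they can serve as references.

make_ts <- function(values, tr = 0.719, run = "rest") {
  values <- as.matrix(values)
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("ROI_%03d", seq_len(ncol(values)))
  roi_timeseries(values, tr_seconds = tr, run_label = run)
}

rand_ts <- function(frames, rois, tr = 0.719, run = "rest") {
  make_ts(matrix(rnorm(frames * rois), frames, rois), tr = tr, run = run)
}

tiny_map <- function(sizes = c(alpha = 3, beta = 4, gamma = 3)) {
  net <- rep(names(sizes), sizes)
  network_map(sprintf("ROI_%03d", seq_along(net)), net)
}

press_log <- function(buttons, gap = 4, duration = NULL) {
  onsets <- seq_along(buttons) * gap
  if (is.null(duration)) duration <- max(onsets) + gap
  button_log(onsets, buttons, duration)
}

# --- brute-force oracles ---------------------------------------------------

bf_fd <- function(params, head_radius = 50) {
  n <- nrow(params)
  fd <- numeric(n)
  for (t in 2:n) {
    s <- 0
    for (j in 1:3) s <- s + abs(params[t, j] - params[t - 1, j])
    for (j in 4:6) s <- s + head_radius * abs(params[t, j] - params[t - 1, j])
    fd[t] <- s
  }
  fd
}

bf_dvars <- function(values, scale_to = 1000) {
  v <- values * (scale_to / median(values))
  n <- nrow(v); R <- ncol(v)
  dv <- numeric(n)
  for (t in 2:n) {
    s <- 0
    for (j in 1:R) s <- s + (v[t, j] - v[t - 1, j])^2
    dv[t] <- sqrt(s / R)
  }
  dv
}

bf_fc <- function(values, clip = 1 - 1e-7) {
  R <- ncol(values)
  z <- matrix(0, R, R)
  for (i in 1:R) for (j in 1:R) {
    if (i == j) next
    r <- cor(values[, i], values[, j])
    r <- max(min(r, clip), -clip)
    z[i, j] <- atanh(r)
  }
  z
}

bf_block_values <- function(z, idx, scope) {
  if (scope == "intra") {
    out <- c()
    n <- length(idx)
    for (a in 1:(n - 1)) for (b in (a + 1):n)
      out <- c(out, z[idx[a], idx[b]])
    out
  } else {
    other <- setdiff(seq_len(nrow(z)), idx)
    out <- c()
    for (j in other) for (i in idx) out <- c(out, z[i, j])
    out
  }
}

bf_similarity <- function(z_rest, z_task, idx, scope, clip = 1 - 1e-7) {
  a <- bf_block_values(z_rest, idx, scope)
  b <- bf_block_values(z_task, idx, scope)
  r <- cor(a, b)
  atanh(max(min(r, clip), -clip))
}

bf_cliffs <- function(x, y) {
  s <- 0
  for (xi in x) for (yj in y) {
    if (xi > yj) s <- s + 1
    if (xi < yj) s <- s - 1
  }
  s / (length(x) * length(y))
}

# Balanced two-timepoint long table from participant-level vectors.
make_lt <- function(ypre, ypost, group, age = NULL, gender = NULL) {
  n <- length(ypre)
  if (is.null(age)) age <- rnorm(n, 60, 6)
  if (is.null(gender)) gender <- rbinom(n, 1, 0.5)
  data.frame(participant_id = rep(sprintf("p%03d", seq_len(n)), each = 2),
             group = rep(group, each = 2),
             timepoint = rep(c(0, 1), n),
             age = rep(age, each = 2), gender = rep(gender, each = 2),
             value = as.vector(rbind(ypre, ypost)))
}
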