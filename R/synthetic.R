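# Synthetic study generator: cohorts, rest/task ROI time series with a
# planted rest-task reconfiguration effect, motion traces with spikes,
# breath-count button logs and FFMQ item responses, plus exported ground
# truth for every planted parameter.

# Deterministic substream seeds: any participant/scan is regenerable in
# isolation from the master seed. Kept below 2^31.
substream <- function(seed, ...) {
  x <- as.double(seed) %% 2147483647
  for (k in c(...)) x <- (x * 69069 + as.double(k) * 2654435761) %% 2147483647
  as.integer(x)
}

#' Nearest positive-definite correlation repair
#'
#' Deterministic eigenvalue clipping: eigenvalues below `eps` are raised to
#' `eps`, the matrix is reconstructed and rescaled to unit diagonal.
#'
#' @param S Symmetric matrix with unit diagonal (approximately).
#' @param eps Minimum eigenvalue (default 1e-6).
#' @return Positive-definite correlation matrix.
#' @export
nearest_pd_cor <- function(S, eps = 1e-6) {
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  if (min(e$values) < eps) {
    v <- pmax(e$values, eps)
    S <- e$vectors %*% (v * t(e$vectors))
  }
  d <- sqrt(diag(S))
  S <- S / tcrossprod(d)
  diag(S) <- 1
  (S + t(S)) / 2
}

#' Simulation configuration
#'
#' Defines the study conditions the generator emulates. Desk-scale defaults
#' (60 ROIs over 9 networks, 200 acquired frames) keep a full simulated
#' study tractable; `scale = "full"` switches to 430 ROIs / 834 frames
#' (a 10-minute run at TR 0.719 s).
#'
#' The task-condition perturbation parameter eta is the fraction of a
#' network's edge-pattern variance replaced by fresh structure in the task
#' state, so the expected rest-task pattern correlation is sqrt(1 - eta).
#' The planted group x time effect moves eta at post-intervention by
#' -`eta_contrast`/2 in the MBTI arm and +`eta_contrast`/2 in the SHEEP
#' arm for the networks in `planted_networks`.
#'
#' @param n_participants Cohort size (default 48).
#' @param n_mbti Participants in the MBTI arm (default 25; remainder SHEEP).
#' @param scale `"desk"` (60 ROIs, 200 frames) or `"full"` (430, 834).
#' @param tr_seconds Repetition time (default 0.719).
#' @param n_drop Initial frames the preprocessing drops (default 4;
#'   generated runs include them).
#' @param rho_in,rho_out Mean within-/between-network correlation level.
#' @param loading_halfwidth Half-width of the uniform network-factor
#'   loading distribution around `sqrt(rho_in)`; larger values give a more
#'   distinctive within-network edge pattern.
#' @param cross_loading_max Maximum secondary loading of an ROI on one
#'   other network's factor (between-network pattern variation).
#' @param global_halfwidth Half-width of the global-factor loading around
#'   `sqrt(rho_out)`.
#' @param secondary_halfwidth Half-width of the signed shared-factor
#'   loading adding within-network pattern variation.
#' @param eta_base Baseline reconfiguration magnitude in [0, 1).
#' @param eta_contrast Planted group x time contrast on eta (default 0.3).
#' @param planted_networks Networks carrying the planted effect.
#' @param sd_intercept,sd_slope Participant heterogeneity SDs on eta
#'   (random intercept / timepoint slope).
#' @param participant_jitter Half-width of participant-level edge jitter on
#'   the rest correlation structure.
#' @param spike_rate Per-frame probability of a motion spike.
#' @param spike_amp_mm Translation step amplitude of a spike (default 0.5).
#' @param bct_accuracy_mean,bct_accuracy_sd Distribution of per-participant
#'   breath-count cycle accuracy targets.
#' @param ffmq_time_effect Latent-SD time effect applied to all facets.
#' @param ffmq_observing_interaction Extra latent-SD shift of the Observing
#'   facet in the MBTI arm at post (planted interaction).
#' @param signal_amp BOLD fluctuation amplitude on the 1000-intensity scale.
#' @param task_activation_amp Amplitude of HRF-locked button-press
#'   activation added to task runs.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_participants = 48, n_mbti = 25,
                       scale = c("desk", "full"), tr_seconds = 0.719,
                       n_drop = 4, rho_in = 0.35, rho_out = 0.05,
                       loading_halfwidth = 0.35, cross_loading_max = 0.35,
                       global_halfwidth = 0.12, secondary_halfwidth = 0.35,
                       eta_base = 0.35, eta_contrast = 0.3,
                       planted_networks = c("executive_control",
                                            "default_mode", "salience"),
                       sd_intercept = 0.06, sd_slope = 0.04,
                       participant_jitter = 0.04,
                       spike_rate = 0.01, spike_amp_mm = 0.5,
                       bct_accuracy_mean = 0.85, bct_accuracy_sd = 0.08,
                       ffmq_time_effect = 0.2,
                       ffmq_observing_interaction = 0.5,
                       signal_amp = 10, task_activation_amp = 5) {
  scale <- match.arg(scale)
  dims <- if (scale == "desk") {
    list(n_rois = 60, frames = 200,
         net_sizes = c(executive_control = 12, default_mode = 14,
                       salience = 8, somatomotor = 6, visual = 4,
                       dorsal_attention = 4, limbic = 4,
                       temporal_parietal = 4, subcortical = 4))
  } else {
    m <- default_network_map()
    list(n_rois = 430, frames = 834,
         net_sizes = table(factor(m$network, levels = unique(m$network))))
  }
  cfg <- list(n_participants = n_participants, n_mbti = n_mbti, scale = scale,
              n_rois = dims$n_rois, frames = dims$frames,
              net_sizes = dims$net_sizes, tr_seconds = tr_seconds,
              n_drop = n_drop, rho_in = rho_in, rho_out = rho_out,
              loading_halfwidth = loading_halfwidth,
              cross_loading_max = cross_loading_max,
              global_halfwidth = global_halfwidth,
              secondary_halfwidth = secondary_halfwidth,
              eta_base = eta_base, eta_contrast = eta_contrast,
              planted_networks = planted_networks,
              sd_intercept = sd_intercept, sd_slope = sd_slope,
              participant_jitter = participant_jitter,
              spike_rate = spike_rate, spike_amp_mm = spike_amp_mm,
              bct_accuracy_mean = bct_accuracy_mean,
              bct_accuracy_sd = bct_accuracy_sd,
              ffmq_time_effect = ffmq_time_effect,
              ffmq_observing_interaction = ffmq_observing_interaction,
              signal_amp = signal_amp,
              task_activation_amp = task_activation_amp)
  if (eta_base < 0 || eta_contrast < 0) stop("eta parameters must be >= 0", call. = FALSE)
  structure(cfg, class = "sim_config")
}

sim_network_map <- function(cfg) {
  sizes <- cfg$net_sizes
  net <- rep(names(sizes), sizes)
  network_map(sprintf("ROI_%03d", seq_along(net)), net)
}

# Block-structured base correlation from a factor model, so the matrix is
# positive definite by construction while carrying a rich edge-level
# spatial pattern (the pattern the similarity measure correlates):
# each ROI loads on its network factor (loading ~ U around sqrt(rho_in)),
# on a global factor (~ U around sqrt(rho_out)) and on one random other
# network's factor (cross-network pattern variation).
sim_factor_sigma <- function(cfg, map) {
  R <- nrow(map)
  nets <- networks(map)
  K <- length(nets)
  l_c <- sqrt(cfg$rho_in); l_h <- cfg$loading_halfwidth
  g_c <- sqrt(max(cfg$rho_out, 0.01)); g_h <- cfg$global_halfwidth
  L <- matrix(0, R, K + 2)          # K network factors + global + secondary
  net_idx <- match(map$network, nets)
  for (i in seq_len(R)) {
    L[i, net_idx[i]] <- stats::runif(1, max(0.05, l_c - l_h), min(0.95, l_c + l_h))
    other <- sample(setdiff(seq_len(K), net_idx[i]), 1)
    L[i, other] <- stats::runif(1, 0, cfg$cross_loading_max)
    L[i, K + 1] <- stats::runif(1, max(0.02, g_c - g_h), g_c + g_h)
    L[i, K + 2] <- stats::runif(1, -cfg$secondary_halfwidth, cfg$secondary_halfwidth)
  }
  S <- tcrossprod(L)
  psi <- pmax(1 - diag(S), 0.05)
  S <- S + diag(psi)
  d <- sqrt(diag(S))
  S <- S / tcrossprod(d)
  diag(S) <- 1
  S
}

# Per-block (network-pair) mean of off-diagonal entries, expanded to a
# full matrix; used to separate block level from edge-pattern deviations.
block_means <- function(S, map) {
  nets <- networks(map)
  ni <- match(map$network, nets)
  M <- matrix(0, nrow(S), ncol(S))
  for (a in seq_along(nets)) for (b in seq_along(nets)) {
    ia <- which(ni == a); ib <- which(ni == b)
    blk <- S[ia, ib, drop = FALSE]
    mu <- if (a == b) {
      if (length(ia) < 2) 0 else mean(blk[row(blk) != col(blk)])
    } else mean(blk)
    M[ia, ib] <- mu
  }
  diag(M) <- 1
  M
}

#' Simulate a participant cohort
#'
#' Ages drawn Normal(60, 6) truncated to [50, 80]; genders Bernoulli(0.58
#' female = 1); groups assigned by simple randomization to the configured
#' 25/23-style split.
#'
#' @param cfg A [sim_config()].
#' @param seed Integer seed.
#' @return Manifest data.frame: `participant_id`, `group`, `age`, `gender`.
#' @export
simulate_cohort <- function(cfg, seed = 1L) {
  set.seed(substream(seed, 2))
  n <- cfg$n_participants
  age <- numeric(n)
  for (i in seq_len(n)) {
    a <- stats::rnorm(1, 60, 6)
    while (a < 50 || a > 80) a <- stats::rnorm(1, 60, 6)
    age[i] <- round(a, 1)
  }
  gender <- stats::rbinom(n, 1, 0.58)
  group <- sample(rep(c("MBTI", "SHEEP"), c(cfg$n_mbti, n - cfg$n_mbti)))
  data.frame(participant_id = sprintf("sub-%03d", seq_len(n)),
             group = group, age = age, gender = gender,
             stringsAsFactors = FALSE)
}

# Per-participant latent draws (random effects on eta, rest-structure
# jitter seed, behavioral targets), reproducible in isolation.
participant_latents <- function(cfg, i, seed) {
  set.seed(substream(seed, 100, i))
  list(b0 = stats::rnorm(1, 0, cfg$sd_intercept),
       b1 = stats::rnorm(1, 0, cfg$sd_slope),
       jitter_seed = substream(seed, 100, i, 7),
       bct_pre = min(0.98, max(0.55, stats::rnorm(1, cfg$bct_accuracy_mean, cfg$bct_accuracy_sd))),
       bct_post = min(0.98, max(0.55, stats::rnorm(1, cfg$bct_accuracy_mean, cfg$bct_accuracy_sd))))
}

# Effective eta per network for one participant scan cell.
effective_eta <- function(cfg, lat, group, timepoint, map) {
  nets <- networks(map)
  post <- as.numeric(timepoint == "post")
  eta <- rep(cfg$eta_base + lat$b0 + lat$b1 * post, length(nets))
  names(eta) <- nets
  if (post == 1) {
    half <- cfg$eta_contrast / 2
    shift <- if (group == "MBTI") -half else half
    pl <- intersect(cfg$planted_networks, nets)
    eta[pl] <- eta[pl] + shift
  }
  pmin(pmax(eta, 0.02), 0.95)
}

# AR(1) nuisance signal, unit variance.
ar1 <- function(n, phi = 0.9) {
  x <- as.numeric(stats::filter(stats::rnorm(n), phi, method = "recursive"))
  x / stats::sd(x)
}

#' Simulate one scan (ROI time series + motion + confounds + events)
#'
#' Rest runs are drawn from a participant-specific block-structured
#' correlation matrix; task runs from a perturbed matrix in which each
#' network's edge-pattern deviations are mixed with fresh structure at the
#' participant's effective eta (cross-network edges use the mean of the two
#' networks' etas). Motion is smooth drift plus step-like spikes; three
#' nuisance signals are generated and partially mixed into the ROI
#' signals; task runs additionally contain canonical-HRF button-press
#' activation. Signals are scaled to a run-wide median of 1000.
#'
#' @param struct List from [sim_structure()].
#' @param manifest Cohort manifest from [simulate_cohort()].
#' @param i Participant index (row of `manifest`).
#' @param timepoint `"pre"` or `"post"`.
#' @param condition `"rest"` or `"task"`.
#' @param seed Master seed of the study.
#' @return List: `ts` ([roi_timeseries()]), `motion` ([motion_trace()]),
#'   `nuisance` (frames x 3 matrix), `events` ([button_log()], task only),
#'   `eta` (named per-network ground truth; NA for rest).
#' @export
simulate_timeseries <- function(struct, manifest, i, timepoint, condition,
                                seed = 1L) {
  cfg <- struct$cfg
  map <- struct$map
  lat <- participant_latents(cfg, i, seed)
  group <- manifest$group[i]
  frames <- cfg$frames
  R <- cfg$n_rois

  # participant rest structure (same at both timepoints)
  set.seed(lat$jitter_seed)
  J <- matrix(0, R, R)
  J[upper.tri(J)] <- stats::runif(R * (R - 1) / 2, -cfg$participant_jitter,
                                  cfg$participant_jitter)
  J <- J + t(J)
  sigma_rest <- nearest_pd_cor(struct$sigma + J)

  tp_code <- as.integer(timepoint == "post")
  cond_code <- as.integer(condition == "task")
  set.seed(substream(seed, 200, i, tp_code * 2 + cond_code))

  if (condition == "task") {
    eta <- effective_eta(cfg, lat, group, timepoint, map)
    M <- block_means(sigma_rest, map)
    dev <- sigma_rest - M
    diag(dev) <- 0
    # fresh pattern from an independent factor-model draw
    sigma_f <- sim_factor_sigma(cfg, map)
    dev_f <- sigma_f - block_means(sigma_f, map)
    diag(dev_f) <- 0
    # within-network edges take the network's eta; cross-network edges the
    # mean of the two networks' etas (reduces to eta_k within a network)
    eta_roi <- eta[map$network]
    eta_edge <- (matrix(eta_roi, R, R) + matrix(eta_roi, R, R, byrow = TRUE)) / 2
    mixed <- sqrt(1 - eta_edge) * dev + sqrt(eta_edge) * dev_f
    diag(mixed) <- 0
    S <- M + mixed
    diag(S) <- 1
    sigma_use <- nearest_pd_cor(S)
  } else {
    eta <- stats::setNames(rep(NA_real_, length(networks(map))), networks(map))
    sigma_use <- sigma_rest
  }

  X <- matrix(stats::rnorm(frames * R), frames, R) %*% chol(sigma_use)

  # nuisance signals, partially mixed into the ROI signals
  g <- ar1(frames); wm <- ar1(frames); csf <- ar1(frames)
  load_g <- stats::runif(R, 0.1, 0.3)
  load_wm <- stats::runif(R, 0.05, 0.15)
  load_csf <- stats::runif(R, 0.05, 0.15)
  X <- X + outer(g, load_g) + outer(wm, load_wm) + outer(csf, load_csf)

  # motion: slow drift plus step spikes (a step moves FD above threshold at
  # the step frame only); spikes also shift the signal baseline
  drift_t <- sapply(1:3, function(k) cumsum(stats::rnorm(frames, 0, 0.005)))
  drift_r <- sapply(1:3, function(k) cumsum(stats::rnorm(frames, 0, 1e-4)))
  params <- cbind(drift_t, drift_r)
  colnames(params) <- c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z")
  spikes <- which(stats::runif(frames) < cfg$spike_rate)
  spikes <- spikes[spikes > cfg$n_drop + 2]
  for (k in spikes) {
    # the head moves and stays moved (FD exceedance at the step frame);
    # the signal artifact is transient and later censored + interpolated
    params[k:frames, 1] <- params[k:frames, 1] +
      cfg$spike_amp_mm * sample(c(-1, 1), 1)
    X[k, ] <- X[k, ] + stats::rnorm(R, 0, 3)
  }

  events <- NULL
  if (condition == "task") {
    events <- simulate_events(if (timepoint == "pre") lat$bct_pre else lat$bct_post,
                              duration_seconds = frames * cfg$tr_seconds,
                              seed = substream(seed, 300, i, tp_code))
    des <- build_design(events, frames, cfg$tr_seconds, collapse_buttons = TRUE)
    act_rois <- which(map$network == "somatomotor")
    if (length(act_rois) == 0) act_rois <- seq_len(min(5, R))
    amp <- cfg$task_activation_amp / max(abs(des$X[, 1]))
    X[, act_rois] <- X[, act_rois] + amp * des$X[, 1]
  }

  vals <- 1000 + cfg$signal_amp * X
  colnames(vals) <- map$roi_id
  list(ts = roi_timeseries(vals, tr_seconds = cfg$tr_seconds,
                           roi_ids = map$roi_id, run_label = condition),
       motion = motion_trace(params),
       nuisance = cbind(global_signal = g, white_matter = wm, csf = csf),
       events = events, eta = eta)
}

#' Build the shared simulation structure (map + base correlation pattern)
#'
#' @param cfg A [sim_config()].
#' @param seed Master seed.
#' @return List: `cfg`, `map` ([network_map()]), `sigma` (base rest
#'   correlation matrix).
#' @export
sim_structure <- function(cfg, seed = 1L) {
  map <- sim_network_map(cfg)
  set.seed(substream(seed, 1))
  list(cfg = cfg, map = map, sigma = sim_factor_sigma(cfg, map))
}

#' Simulate a breath-counting button log
#'
#' Breath intervals are Uniform(3.5, 6.0) s. Each cycle is independently
#' correct (8 count presses + the nine button) with probability
#' `accuracy_target`, otherwise corrupted (7 or 9 count presses, or a lost
#' press mid-cycle). The log truncates at the run end, possibly leaving a
#' trailing incomplete cycle.
#'
#' @param accuracy_target Probability a cycle is rendered correct, in [0, 1].
#' @param duration_seconds Run duration.
#' @param seed Integer seed.
#' @return A [button_log()].
#' @export
simulate_events <- function(accuracy_target, duration_seconds, seed = 1L) {
  if (accuracy_target < 0 || accuracy_target > 1)
    stop("accuracy_target must be in [0, 1]", call. = FALSE)
  if (duration_seconds < 9 * 3.5)
    stop("run too short for a single breath cycle", call. = FALSE)
  set.seed(as.integer(seed))
  t <- stats::runif(1, 2, 5)
  onset <- numeric(0); button <- character(0)
  repeat {
    correct <- stats::runif(1) < accuracy_target
    if (correct) {
      presses <- c(rep("count", 8), "nine")
    } else {
      mode <- sample(c("seven", "nine_press", "lost"), 1)
      presses <- switch(mode,
        seven = c(rep("count", 7), "nine"),
        nine_press = c(rep("count", 9), "nine"),
        lost = c(rep("count", sample(1:7, 1)), "lost"))
    }
    for (b in presses) {
      if (t >= duration_seconds) break
      onset <- c(onset, t); button <- c(button, b)
      t <- t + stats::runif(1, 3.5, 6.0)
    }
    if (t >= duration_seconds) break
  }
  button_log(onset, button, duration_seconds)
}

#' Simulate a 39-item FFMQ response
#'
#' Each item's latent score is Normal(facet mean + planted effects, 1),
#' cut at thresholds (-1.5, -0.5, 0.5, 1.5) into ratings 1-5. A time
#' effect applies to all facets; the planted group x time interaction
#' shifts the Observing facet in the MBTI arm at post.
#'
#' @param group `"MBTI"` or `"SHEEP"`.
#' @param timepoint `"pre"` or `"post"`.
#' @param cfg A [sim_config()].
#' @param seed Integer seed.
#' @return Integer vector of 39 ratings in 1-5.
#' @export
simulate_ffmq <- function(group, timepoint, cfg, seed = 1L) {
  set.seed(as.integer(seed))
  facets <- ffmq_facets()
  post <- as.numeric(timepoint == "post")
  mu <- numeric(39)
  for (fn in names(facets)) {
    eff <- cfg$ffmq_time_effect * post
    if (fn == "observing" && group == "MBTI")
      eff <- eff + cfg$ffmq_observing_interaction * post
    mu[facets[[fn]]] <- eff
  }
  latent <- stats::rnorm(39, mu, 1)
  as.integer(cut(latent, breaks = c(-Inf, -1.5, -0.5, 0.5, 1.5, Inf),
                 labels = FALSE))
}

#' Generate a complete in-memory synthetic study
#'
#' @param cfg A [sim_config()].
#' @param seed Master seed; every sub-draw streams deterministically from it.
#' @return List of class `sim_study`: `cfg`, `seed`, `map`, `manifest`,
#'   `scans` (per participant/timepoint/condition), `ffmq` (item table),
#'   `truth` (ground-truth data.frame from [export_ground_truth()]).
#' @export
generate_study <- function(cfg = sim_config(), seed = 1L) {
  struct <- sim_structure(cfg, seed)
  manifest <- simulate_cohort(cfg, seed)
  scans <- list()
  ffmq_rows <- list()
  for (i in seq_len(nrow(manifest))) {
    pid <- manifest$participant_id[i]
    scans[[pid]] <- list()
    for (tp in c("pre", "post")) {
      scans[[pid]][[tp]] <- list(
        rest = simulate_timeseries(struct, manifest, i, tp, "rest", seed),
        task = simulate_timeseries(struct, manifest, i, tp, "task", seed))
      resp <- simulate_ffmq(manifest$group[i], tp, cfg,
                            seed = substream(seed, 400, i, as.integer(tp == "post")))
      row <- data.frame(participant_id = pid, timepoint = tp,
                        stringsAsFactors = FALSE)
      row[sprintf("item_%02d", 1:39)] <- as.list(resp)
      ffmq_rows[[length(ffmq_rows) + 1L]] <- row
    }
  }
  study <- list(cfg = cfg, seed = as.integer(seed), map = struct$map,
                manifest = manifest, scans = scans,
                ffmq = do.call(rbind, ffmq_rows))
  study$truth <- export_ground_truth(study)
  class(study) <- "sim_study"
  study
}

#' Ground-truth table for a generated study
#'
#' One row per participant x timepoint x network with the effective eta
#' used in generation, the participant's random effects and the behavioral
#' targets (breath-count accuracy, planted FFMQ latent shifts).
#'
#' @param study A `sim_study` from [generate_study()].
#' @return Data frame.
#' @export
export_ground_truth <- function(study) {
  cfg <- study$cfg
  rows <- list()
  for (i in seq_len(nrow(study$manifest))) {
    pid <- study$manifest$participant_id[i]
    grp <- study$manifest$group[i]
    lat <- participant_latents(cfg, i, study$seed)
    for (tp in c("pre", "post")) {
      eta <- effective_eta(cfg, lat, grp, tp, study$map)
      obs_shift <- cfg$ffmq_time_effect * (tp == "post") +
        cfg$ffmq_observing_interaction * (tp == "post" && grp == "MBTI")
      rows[[length(rows) + 1L]] <- data.frame(
        participant_id = pid, group = grp, timepoint = tp,
        network = names(eta), eta = unname(eta),
        b0 = lat$b0, b1 = lat$b1,
        bct_accuracy_target = if (tp == "pre") lat$bct_pre else lat$bct_post,
        ffmq_observing_latent_shift = obs_shift,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Write a generated study to a directory of TSV files
#'
#' Layout: `manifest.tsv`, `network_map.tsv`, `ffmq.tsv`,
#' `ground_truth.tsv`, `config.tsv` (flat key=value snapshot) and
#' `scans/<pid>_<timepoint>_<condition>_{bold,confounds}.tsv` plus
#' `_events.tsv` for task runs.
#'
#' @param study A `sim_study`, or `NULL` to generate one from `cfg`/`seed`.
#' @param dir Output directory (created if missing).
#' @param cfg,seed Used when `study` is `NULL`.
#' @return The directory path, invisibly.
#' @export
simulate_study <- function(dir, study = NULL, cfg = sim_config(), seed = 1L) {
  if (is.null(study)) study <- generate_study(cfg, seed)
  dir.create(file.path(dir, "scans"), recursive = TRUE, showWarnings = FALSE)
  write_tsv(study$manifest, file.path(dir, "manifest.tsv"))
  write_network_map(study$map, file.path(dir, "network_map.tsv"))
  write_tsv(study$ffmq, file.path(dir, "ffmq.tsv"))
  write_tsv(study$truth, file.path(dir, "ground_truth.tsv"))
  cfgdf <- data.frame(key = c("seed", "n_participants", "n_mbti", "scale",
                              "n_rois", "frames", "tr_seconds", "eta_base",
                              "eta_contrast", "planted_networks"),
                      value = c(study$seed, study$cfg$n_participants,
                                study$cfg$n_mbti, study$cfg$scale,
                                study$cfg$n_rois, study$cfg$frames,
                                study$cfg$tr_seconds, study$cfg$eta_base,
                                study$cfg$eta_contrast,
                                paste(study$cfg$planted_networks, collapse = ",")),
                      stringsAsFactors = FALSE)
  write_tsv(cfgdf, file.path(dir, "config.tsv"))
  for (pid in names(study$scans)) for (tp in c("pre", "post"))
    for (cond in c("rest", "task")) {
      sc <- study$scans[[pid]][[tp]][[cond]]
      stem <- file.path(dir, "scans", paste(pid, tp, cond, sep = "_"))
      write_timeseries(sc$ts, paste0(stem, "_bold.tsv"))
      conf <- cbind(as.data.frame(sc$motion$params), as.data.frame(sc$nuisance))
      write_tsv(conf, paste0(stem, "_confounds.tsv"))
      if (!is.null(sc$events)) write_events(sc$events, paste0(stem, "_events.tsv"))
    }
  invisible(dir)
}
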