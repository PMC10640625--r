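# End-to-end study orchestration: behavioral scoring, exclusion cascade,
# preprocessing and QC, task regression, FC, similarity, outlier screen,
# mixed-model permutation inference, network-averaged-FC control analysis,
# baseline checks and association models, with a full exclusion ledger.

load_study_dir <- function(dir) {
  cfg_df <- read_tsv_strict(file.path(dir, "config.tsv"))
  cfgv <- stats::setNames(cfg_df$value, cfg_df$key)
  tr <- as.numeric(cfgv[["tr_seconds"]])
  manifest <- read_manifest(file.path(dir, "manifest.tsv"))
  map <- read_network_map(file.path(dir, "network_map.tsv"))
  ffmq <- read_tsv_strict(file.path(dir, "ffmq.tsv"))
  scans <- list()
  for (pid in manifest$participant_id) {
    scans[[pid]] <- list()
    for (tp in c("pre", "post")) {
      scans[[pid]][[tp]] <- list()
      for (cond in c("rest", "task")) {
        stem <- file.path(dir, "scans", paste(pid, tp, cond, sep = "_"))
        ts <- read_timeseries(paste0(stem, "_bold.tsv"), tr_seconds = tr,
                              run_label = cond)
        conf <- read_confounds(paste0(stem, "_confounds.tsv"))
        ev <- NULL
        if (cond == "task")
          ev <- read_events(paste0(stem, "_events.tsv"),
                            run_duration_seconds = nrow(ts$values) * tr)
        scans[[pid]][[tp]][[cond]] <- list(ts = ts, motion = conf$motion,
                                           nuisance = conf$nuisance,
                                           events = ev)
      }
    }
  }
  list(manifest = manifest, map = map, ffmq = ffmq, scans = scans,
       tr_seconds = tr)
}

score_behavior <- function(study) {
  rows <- list()
  for (pid in names(study$scans)) for (tp in c("pre", "post")) {
    ev <- study$scans[[pid]][[tp]]$task$events
    sc <- score_bct(ev)
    rows[[length(rows) + 1L]] <- data.frame(
      participant_id = pid, timepoint = tp, measure = "bct_accuracy",
      value = sc$accuracy, stringsAsFactors = FALSE)
    fr <- study$ffmq[study$ffmq$participant_id == pid &
                       study$ffmq$timepoint == tp, ]
    ratings <- as.numeric(fr[1, sprintf("item_%02d", 1:39)])
    fs <- score_ffmq(ratings)
    for (m in c("observing", "describing", "awareness", "nonjudging",
                "nonreactivity", "total"))
      rows[[length(rows) + 1L]] <- data.frame(
        participant_id = pid, timepoint = tp,
        measure = paste0("ffmq_", m), value = fs[[m]],
        stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Baseline group comparisons
#'
#' Two-sided Mann-Whitney U tests comparing the two intervention arms on
#' each supplied outcome at the pre-intervention timepoint.
#'
#' @param manifest Manifest data.frame (`participant_id`, `group`).
#' @param outcomes Long data.frame with columns `participant_id`,
#'   `timepoint`, `measure`, `value` (pre rows are used).
#' @return Data frame: `measure`, `U`, `p_value`, `n_mbti`, `n_sheep`.
#' @export
baseline_checks <- function(manifest, outcomes) {
  pre <- outcomes[outcomes$timepoint %in% c("pre", 0), ]
  grp <- manifest$group[match(pre$participant_id, manifest$participant_id)]
  out <- list()
  for (m in unique(pre$measure)) {
    sel <- pre$measure == m
    x <- pre$value[sel & grp == "MBTI"]
    y <- pre$value[sel & grp == "SHEEP"]
    mw <- mann_whitney(x, y)
    out[[length(out) + 1L]] <- data.frame(
      measure = m, U = mw$U, p_value = mw$p_value,
      n_mbti = length(x), n_sheep = length(y), stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

make_long <- function(values_df, manifest, measure) {
  sel <- values_df[values_df$measure == measure, ]
  idx <- match(sel$participant_id, manifest$participant_id)
  long_table(data.frame(
    participant_id = sel$participant_id,
    group = manifest$group[idx],
    timepoint = sel$timepoint,
    age = manifest$age[idx],
    gender = manifest$gender[idx],
    value = sel$value, stringsAsFactors = FALSE))
}

analyze_outcome <- function(values_df, manifest, measure, n_perm, seed) {
  lt <- make_long(values_df, manifest, measure)
  fit <- fit_lmm(lt)
  pr <- permutation_tests(lt, terms = c("timepoint", "group:timepoint"),
                          n_perm = n_perm,
                          seed = substream(seed, 500, sum(utf8ToInt(measure))))
  deltas <- vapply(c(0, 1), function(gc) {
    post <- lt$value[lt$group == gc & lt$timepoint == 1]
    pre <- lt$value[lt$group == gc & lt$timepoint == 0]
    cliffs_delta(post, pre)$cliffs_delta
  }, numeric(1))
  do.call(rbind, lapply(c("timepoint", "group:timepoint"), function(tm) {
    data.frame(outcome = measure, term = tm,
               beta = pr[[tm]]$observed, p_perm = pr[[tm]]$p_value,
               n_perm = n_perm, seed = pr[[tm]]$seed,
               cliffs_delta_MBTI = deltas[1], cliffs_delta_SHEEP = deltas[2],
               converged = fit$converged, stringsAsFactors = FALSE)
  }))
}

#' Run the full study analysis end to end
#'
#' Executes, in order: behavioral scoring; breath-count-accuracy exclusion;
#' per-scan preprocessing with frame-retention exclusion; task-activation
#' regression; FC matrices; the rest-task similarity table; the >3 SD
#' outlier screen on task performance and every reconfiguration measure;
#' linear-mixed-model permutation inference on every behavioral measure and
#' every network x scope similarity; the network-averaged-FC control
#' analysis; baseline Mann-Whitney checks; and association models for
#' measure pairs with significant time or interaction effects. Writes the
#' results bundle as TSVs when `out_dir` is given.
#'
#' @param study A study directory path (layout of [simulate_study()]) or an
#'   in-memory `sim_study` from [generate_study()].
#' @param out_dir Optional output directory for the results TSVs.
#' @param n_perm Permutations per outcome (default 1000).
#' @param seed Master analysis seed (drives every permutation stream).
#' @param alpha Significance level used to select measures for the
#'   association stage (default 0.05).
#' @return List of class `study_results`: `lmm` (main inference table),
#'   `network_fc` (control analysis), `similarity`, `behavioral`,
#'   `exclusions`, `qc`, `baseline`, `associations`, `included`, `seed`.
#' @export
run_study <- function(study, out_dir = NULL, n_perm = 1000, seed = 1L,
                      alpha = 0.05) {
  if (is.character(study)) study <- load_study_dir(study)
  manifest <- study$manifest
  map <- study$map
  excl <- list()
  note_excl <- function(pid, rule, stage, detail = "")
    data.frame(participant_id = pid, rule = rule, stage = stage,
               detail = detail, stringsAsFactors = FALSE)

  # stage 1: behavioral scoring + BCT exclusion
  behav <- score_behavior(study)
  included <- manifest$participant_id
  for (pid in manifest$participant_id) {
    acc <- behav$value[behav$participant_id == pid &
                         behav$measure == "bct_accuracy"]
    dec <- if (anyNA(acc)) list(decision = "exclude", reason = "no completed cycles")
      else if (min(acc) < 0.5) list(decision = "exclude",
                                    reason = sprintf("accuracy %.3f < 0.50", min(acc)))
      else list(decision = "include")
    if (dec$decision == "exclude") {
      included <- setdiff(included, pid)
      excl[[length(excl) + 1L]] <- note_excl(pid, "bct_accuracy", "behavioral",
                                             dec$reason)
    }
  }

  # stage 2: preprocessing + retention exclusion
  qc <- list()
  prep <- list()
  for (pid in included) {
    prep[[pid]] <- list()
    failed <- FALSE
    for (tp in c("pre", "post")) for (cond in c("rest", "task")) {
      sc <- study$scans[[pid]][[tp]][[cond]]
      pr <- preprocess_scan(sc$ts, sc$motion, sc$nuisance)
      qc[[length(qc) + 1L]] <- data.frame(
        participant_id = pid, timepoint = tp, run = cond,
        mean_fd = pr$mean_fd, n_censored = pr$n_censored,
        retained_fraction = pr$retained_fraction, decision = pr$decision,
        stringsAsFactors = FALSE)
      if (pr$decision == "exclude") failed <- TRUE
      prep[[pid]][[tp]][[cond]] <- pr
    }
    if (failed) {
      included <- setdiff(included, pid)
      excl[[length(excl) + 1L]] <- note_excl(pid, "frame_retention",
                                             "preprocessing")
      prep[[pid]] <- NULL
    }
  }

  # stage 3: task regression + FC + similarity
  n_drop <- 4
  fc_pairs <- list()
  for (pid in included) {
    fc_pairs[[pid]] <- list()
    for (tp in c("pre", "post")) {
      sc_task <- study$scans[[pid]][[tp]]$task
      frames_full <- nrow(sc_task$ts$values)
      des <- build_design(sc_task$events, frames_full, sc_task$ts$tr_seconds,
                          collapse_buttons = FALSE, drop_first = n_drop)
      ts_task <- regress_task_activations(prep[[pid]][[tp]]$task$ts, des)
      fc_pairs[[pid]][[tp]] <- list(
        rest = compute_fc(conform_timeseries(prep[[pid]][[tp]]$rest$ts, map)),
        task = compute_fc(conform_timeseries(ts_task, map), condition = "task"))
    }
  }
  simtab_full <- build_similarity_table(fc_pairs, map, manifest)
  simtab <- simtab_full$table

  # stage 4: >3 SD outlier screen (pooled), task performance + every
  # reconfiguration measure; flagged by any screened vector = excluded
  if (length(included) >= 3) {
    flagged <- character(0)
    for (tp in c("pre", "post")) {
      acc <- behav[behav$measure == "bct_accuracy" & behav$timepoint == tp &
                     behav$participant_id %in% included, ]
      keep <- outlier_filter(acc$value)
      flagged <- union(flagged, acc$participant_id[!keep])
    }
    for (tp in c("pre", "post")) for (net in networks(map))
      for (sc in c("intra", "inter")) {
        sel <- simtab$timepoint == tp & simtab$network == net &
          simtab$scope == sc & simtab$participant_id %in% included
        if (sum(sel) >= 3) {
          keep <- outlier_filter(simtab$similarity_z[sel])
          flagged <- union(flagged, simtab$participant_id[sel][!keep])
        }
      }
    for (pid in flagged) {
      included <- setdiff(included, pid)
      excl[[length(excl) + 1L]] <- note_excl(pid, "outlier_3sd", "outliers")
    }
  }
  simtab <- simtab[simtab$participant_id %in% included, ]
  behav_inc <- behav[behav$participant_id %in% included, ]

  # stage 5: network-averaged FC (control analysis outcomes)
  netfc <- list()
  for (pid in included) for (tp in c("pre", "post"))
    for (cond in c("rest", "task")) for (net in networks(map)) {
      netfc[[length(netfc) + 1L]] <- data.frame(
        participant_id = pid, timepoint = tp,
        measure = paste("netfc", cond, net, sep = "_"),
        value = network_mean_fc(fc_pairs[[pid]][[tp]][[cond]], map, net, "intra"),
        stringsAsFactors = FALSE)
    }
  netfc <- do.call(rbind, netfc)

  # stage 6: LMM + permutation on every outcome
  sim_long <- data.frame(participant_id = simtab$participant_id,
                         timepoint = simtab$timepoint,
                         measure = paste("similarity", simtab$scope,
                                         simtab$network, sep = "_"),
                         value = simtab$similarity_z, stringsAsFactors = FALSE)
  outcomes <- rbind(behav_inc, sim_long, netfc)
  results <- list()
  for (m in unique(outcomes$measure))
    results[[m]] <- analyze_outcome(outcomes, manifest, m, n_perm, seed)
  lmm_res <- do.call(rbind, results)
  rownames(lmm_res) <- NULL

  # stage 7: baseline checks on behavioral measures + significant networks
  sig <- lmm_res[lmm_res$p_perm <= alpha, ]
  base_measures <- unique(c(unique(behav_inc$measure),
                            intersect(unique(sim_long$measure), sig$outcome)))
  baseline <- baseline_checks(manifest,
                              outcomes[outcomes$measure %in% base_measures, ])

  # stage 8: association models for significant behavioral x similarity pairs
  sig_behav <- intersect(unique(behav_inc$measure), sig$outcome)
  sig_sim <- intersect(unique(sim_long$measure), sig$outcome)
  assoc <- list()
  delta_by_participant <- function(measure) {
    sub <- outcomes[outcomes$measure == measure, ]
    pre <- sub[sub$timepoint == "pre", ]
    post <- sub[sub$timepoint == "post", ]
    ids <- intersect(pre$participant_id, post$participant_id)
    stats::setNames(post$value[match(ids, post$participant_id)] -
                      pre$value[match(ids, pre$participant_id)], ids)
  }
  for (bm in sig_behav) for (sm in sig_sim) {
    d_beh <- delta_by_participant(bm)
    d_sim <- delta_by_participant(sm)
    ids <- intersect(names(d_beh), names(d_sim))
    if (length(ids) < 10) next
    idx <- match(ids, manifest$participant_id)
    ch <- data.frame(participant_id = ids, group = manifest$group[idx],
                     age = manifest$age[idx], gender = manifest$gender[idx],
                     d_behavior = unname(d_beh[ids]),
                     d_similarity = unname(d_sim[ids]),
                     stringsAsFactors = FALSE)
    for (wi in c(FALSE, TRUE)) {
      fa <- fit_association(ch, with_interaction = wi, n_perm = n_perm,
                            seed = substream(seed, 600,
                                             sum(utf8ToInt(paste(bm, sm)))))
      assoc[[length(assoc) + 1L]] <- data.frame(
        behavior = bm, similarity = sm, model = if (wi) "interaction" else "slope",
        slope = fa$coefficients[["d_similarity"]], slope_p = fa$slope_p,
        interaction_p = if (wi) fa$interaction_p else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  assoc <- if (length(assoc)) do.call(rbind, assoc) else
    data.frame(behavior = character(0), similarity = character(0),
               model = character(0), slope = numeric(0),
               slope_p = numeric(0), interaction_p = numeric(0))

  exclusions <- if (length(excl)) do.call(rbind, excl) else
    data.frame(participant_id = character(0), rule = character(0),
               stage = character(0), detail = character(0))
  stopifnot(length(included) + length(unique(exclusions$participant_id)) ==
              nrow(manifest))

  res <- structure(list(
    lmm = lmm_res, similarity = simtab, behavioral = behav_inc,
    network_fc = netfc, exclusions = exclusions,
    qc = do.call(rbind, qc), baseline = baseline, associations = assoc,
    included = included, skipped = simtab_full$skipped,
    seed = as.integer(seed), n_perm = n_perm), class = "study_results")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_tsv(res$lmm, file.path(out_dir, "lmm_results.tsv"))
    write_tsv(res$similarity, file.path(out_dir, "similarity.tsv"))
    write_tsv(res$behavioral, file.path(out_dir, "behavioral.tsv"))
    write_tsv(res$network_fc, file.path(out_dir, "network_fc.tsv"))
    write_tsv(res$exclusions, file.path(out_dir, "exclusions.tsv"))
    write_tsv(res$qc, file.path(out_dir, "qc.tsv"))
    write_tsv(res$baseline, file.path(out_dir, "baseline.tsv"))
    write_tsv(res$associations, file.path(out_dir, "associations.tsv"))
    write_tsv(data.frame(key = c("seed", "n_perm", "alpha", "n_included"),
                         value = c(seed, n_perm, alpha, length(included))),
              file.path(out_dir, "run_info.tsv"))
  }
  res
}

#' @export
print.study_results <- function(x, ...) {
  cat(sprintf("<study_results: %d participants included, %d excluded; %d outcomes tested (%d permutations)>\n",
              length(x$included), length(unique(x$exclusions$participant_id)),
              length(unique(x$lmm$outcome)), x$n_perm))
  sig <- x$lmm[x$lmm$p_perm <= 0.05, c("outcome", "term", "beta", "p_perm")]
  if (nrow(sig)) { cat("significant effects (p <= 0.05):\n"); print(sig, row.names = FALSE) }
  invisible(x)
}
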