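# netreconf

Rest-task brain-network **reconfiguration efficiency** analysis for
longitudinal two-arm intervention studies, with a synthetic multi-subject
fMRI study generator for validation.

## The scientific problem

Switching from rest to an attention-demanding task reorganizes the brain's
functional connectivity (FC). How much it must reorganize is behaviorally
meaningful: less reorganization (higher rest-task FC similarity) is read
as more efficient reconfiguration. This package implements that measure
and the full analysis around it for a design in which elderly participants
with sleep difficulties were randomized to a mindfulness-based therapy
(MBTI) or an active sleep-hygiene control (SHEEP), scanned at rest and
during a breath-counting task (BCT) before and after the intervention.

For participant *i*, network *k* and timepoint *t*, the measure is

> S_ikt = atanh( cor( z_rest(edges_k), z_task(edges_k) ) )

where `z_cond(edges_k)` are the Fisher-z FC values of network *k*'s edge
set (intranetwork: within-network pairs; internetwork: pairs linking the
network to all other ROIs), index-aligned between conditions. Task FC is
computed after regressing out canonical-HRF button-press activation.
Intervention effects are assessed with the linear mixed model

> Y ~ Age + Gender + Group * Timepoint + (1 + Timepoint | Participant)

with permutation p-values (group labels shuffled across participants,
timepoint labels swapped within participants 50% of the time), unpaired
Cliff's delta effect sizes per arm, and Mann-Whitney baseline checks.

## What is in the package

| Area | Functions |
| --- | --- |
| Data model & TSV I/O | `roi_timeseries()`, `read_timeseries()`, `read_network_map()`, `read_events()`, `read_confounds()`, `read_manifest()` |
| Preprocessing & motion QC | `drop_initial_frames()`, `compute_fd()`, `compute_dvars()`, `flag_frames()`, `interpolate_frames()`, `retention_check()`, `nuisance_regress()`, `bandpass_filter()`, `preprocess_scan()` |
| Task design | `canonical_hrf()`, `build_design()`, `regress_task_activations()` |
| Connectivity & similarity | `compute_fc()`, `network_mean_fc()`, `vectorize_block()`, `similarity()`, `build_similarity_table()` |
| Behavioral scoring | `parse_cycles()`, `score_bct()`, `bct_exclusion()`, `score_ffmq()`, `outlier_filter()` |
| Inference | `fit_lmm()`, `permute_labels()`, `permutation_pvalue()`, `permutation_tests()`, `cliffs_delta()`, `mann_whitney()`, `fit_association()` |
| Synthetic studies | `sim_config()`, `generate_study()`, `simulate_study()`, `simulate_cohort()`, `simulate_timeseries()`, `simulate_events()`, `simulate_ffmq()`, `export_ground_truth()` |
| Orchestration | `run_study()`, `baseline_checks()` |

## Worked example

Simulate a complete study at the trial's cohort shape (48 participants,
25/23 split) with the default planted effects — a group x time
reconfiguration contrast of 0.3 on the executive control, default mode and
salience networks, and an FFMQ Observing interaction — then analyze it end
to end:

```r
library(netreconf)

study <- generate_study(sim_config(), seed = 11)
res   <- run_study(study, n_perm = 499, seed = 5)
print(res)
```

```
<study_results: 38 participants included, 10 excluded; 43 outcomes tested (499 permutations)>
significant effects (p <= 0.05):
                      outcome            term       beta      p_perm
               ffmq_observing       timepoint  5.1578947 0.000000000
               ffmq_observing group:timepoint -5.0000000 0.006012024
              ffmq_nonjudging       timepoint  3.0000000 0.004008016
                   ffmq_total       timepoint 12.6315789 0.000000000
 similarity_intra_somatomotor       timepoint -0.2921034 0.024048096
 similarity_intra_subcortical group:timepoint -0.5351523 0.034068136
            netfc_task_visual group:timepoint -0.2010021 0.012024048
```

Reading the output: each outcome gets the mixed-model `timepoint` and
`group:timepoint` coefficients with permutation p-values. Group is coded
MBTI = 0 / SHEEP = 1, so a *negative* interaction coefficient means the
mindfulness arm improved relative to control (for FFMQ Observing the
planted interaction shows up as a negative beta with a small p). The
per-arm Cliff's deltas in `res$lmm` give the direction within each arm,
`res$exclusions` itemizes every participant removed by the BCT-accuracy,
frame-retention or 3-SD-outlier rules, and `res$similarity` holds the
participant-level similarity table. Note that 43 outcomes are tested at
alpha = 0.05 with no multiplicity correction (by design), so a couple of
significant rows in unplanted outcomes — as above in the somatomotor,
subcortical and visual entries — are the expected false-positive yield.
At desk scale (60 ROIs, 200 frames)
single-network FC similarity is noisy, so a contrast of 0.3 is not
reliably significant in any one network in a single simulated study — the
package's power analysis (see the methods vignette) quantifies exactly
this, and the test suite demonstrates >= 80% recovery power at a strong
contrast on the planted-network composite.

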