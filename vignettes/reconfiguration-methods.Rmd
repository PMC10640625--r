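---
title: "Rest-task network reconfiguration efficiency: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rest-task network reconfiguration efficiency: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The measure

When the brain switches from rest to an attention-demanding task, its
functional connectivity (FC) pattern reorganizes. **Rest-task FC
similarity** quantifies how much: for a participant and a brain network,
take every Fisher-z FC value of the network's edge set at rest, the same
(index-aligned) values during the task, and compute the Pearson correlation
between the two vectors, Fisher r-to-z transformed. High similarity means
the task state is reachable from the intrinsic configuration with little
reorganization — *efficient* reconfiguration. Two edge sets are used per
network: **intranetwork** (the n(n-1)/2 within-network pairs) and
**internetwork** (the n x (R-n) pairs linking the network to the rest of
the brain).

The package implements this measure inside a complete longitudinal analysis
for a two-arm intervention design (a mindfulness-based therapy arm, MBTI,
versus an active sleep-hygiene control arm, SHEEP, with pre- and
post-intervention scanning): ROI-level fMRI denoising and motion QC,
breath-counting-task (BCT) and Five Facet Mindfulness Questionnaire (FFMQ)
scoring, exclusion rules, and permutation inference on linear mixed models.

## Pipeline order and preprocessing choices

Each scan is processed in a fixed order:

1. drop the first 4 volumes (non-steady-state);
2. framewise displacement (FD) and DVARS computed on the *pre-interpolation*
   data — FD as the sum of absolute frame-to-frame translation changes plus
   50 mm times the absolute rotation changes (radians); DVARS as the RMS
   over ROIs of the temporal signal derivative after rescaling the run-wide
   median intensity to 1000, so the conventional threshold of 50 has its
   usual meaning;
3. frames with FD > 0.2 mm or DVARS > 50 are censored together with one
   frame before and two after, clipped to run bounds;
4. censored frames are replaced by per-ROI linear interpolation between the
   nearest usable neighbours (edge runs copy the nearest usable value); the
   usability mask records what was replaced. Spectral interpolation was
   considered and rejected for the default: with the tight censoring
   expansion the linear rule is transparent and adequate to stabilize the
   filter;
5. nuisance regression against an intercept, three tissue signals (global,
   white matter, CSF — supplied as columns, since the pipeline starts at
   ROI level) and the 12-parameter motion model (6 rigid-body parameters
   plus their first backward differences);
6. zero-phase 4th-order Butterworth band-pass, 0.009-0.08 Hz. The filter is
   applied to all ROIs at once with a vectorized forward-backward pass that
   is numerically identical to `signal::filtfilt` per column (asserted in
   the test suite).

A scan retaining fewer than 50% of its frames after censoring is excluded;
the boundary is inclusive (exactly 50% retained is kept), reading the
exclusion rule strictly. A participant failing any of the four scans is
excluded. FD/DVARS before nuisance regression, and retention of
interpolated frames in FC estimation, are the defaults; both orderings are
defensible and the choices are recorded here because the processing
literature does not fix them.

Task runs are additionally residualized against a task design built from
the logged button presses: each button type is a zero-duration impulse
train convolved with a canonical double-gamma HRF (response peak at 6 s,
undershoot at 16 s, peak:undershoot ratio 6, unit peak) and with its
temporal derivative. All columns are mean-centered; regressors that an
edge-truncated event renders degenerate are pivoted out with a warning.
Modeling the three buttons separately is the least lossy reading of
"button presses"; a config switch collapses them.

## Behavioral scoring

A BCT cycle is delimited purely by terminator presses: it ends at the first
press of the "ninth breath" button or the "lost count" button. A cycle is
correct iff it contains exactly eight count presses and ends with the nine
button. The trailing unterminated run of presses cannot be judged and is
excluded from numerator and denominator. Accuracy = correct / completed
cycles; with zero completed cycles the accuracy is undefined (`NA`), and
the participant is excluded. The exclusion threshold is strict:
accuracy < 0.5 excludes, exactly 0.5 is kept. Whether lost-count cycles
belong in the denominator is not fixed by the instrument description; they
are counted by default (`count_lost_cycles = TRUE`).

FFMQ: 39 items rated 1-5, summed into five facets (Observing, Describing,
Acting with awareness, Nonjudging, Nonreactivity; 8/8/8/8/7 items) and a
total in [39, 195]. Scoring defaults to plain sums; the published
reverse-key set ships as `ffmq_reverse_items()` for real survey data.

The >3 SD outlier screen computes mean and SD over the supplied pooled
vector (not per group — the rule's reference population is the analysis
sample) and is applied to task performance and to every reconfiguration
measure; a participant flagged by any screened vector is excluded. With
~74 screened vectors this union rule removes a noticeable fraction of a
synthetic cohort at desk scale; that is a property of the rule itself, and
the exclusion ledger makes each removal attributable.

## The mixed model and its permutation inference

Every outcome (BCT accuracy, six FFMQ scores, 18 network x scope similarity
measures, and the 18 network-averaged FC control outcomes) is analyzed
with

    value ~ age + gender + group * timepoint + (1 + timepoint | participant)

with binary dummies (group: MBTI = 0, SHEEP = 1; timepoint: post = 1;
gender: female = 1). Under this coding an improvement concentrated in the
mindfulness arm produces a **negative** group x timepoint coefficient.

With exactly two observations per participant, the random intercept +
slope structure is at the edge of identifiability: the marginal covariance
of a participant's (pre, post) pair is an unstructured 2x2 matrix, and the
four variance parameters map onto its three free entries plus an
unidentified direction. `lme4::lmer` declines the model outright (40
observations vs 40 random effects) unless its checks are relaxed, and then
routinely sits on the variance boundary. The default engine therefore
profiles the fixed effects by REML directly over the unstructured 2x2
marginal covariance — exactly the marginal family the random-effects
structure induces — via Nelder-Mead on (log sd_pre, log sd_post, atanh
correlation). This is fast (~4 ms per fit, which matters at tens of
thousands of permutation fits), has no boundary pathology, and agrees with
`lme4` fixed effects to ~1e-4 on simulated data (tested). `engine = "lmer"`
remains available as the reference path. Degenerate cases are handled
explicitly: an outcome lying exactly in the fixed-effect span returns the
OLS solution; non-convergence triggers a restart and then a flagged
random-intercept-only (compound-symmetry) fit.

Permutation inference follows the design's exchangeability: group labels
are shuffled across participants as whole participants, and independently
each participant's two timepoint labels are swapped with probability 0.5
(equivalently, the outcome pair is swapped while the design stays fixed).
p = #\{|beta_perm| >= |beta_obs|\} / n_perm, two-sided, with no +1
correction — the literal fraction-of-iterations definition; the
(k+1)/(n+1) variant is available. A permuted group vector occasionally
coincides with the gender vector, making the design collinear; such draws
are redrawn and counted, with an error if more than 10% of draws fail.
No multiple-testing correction is applied across networks by default,
matching the per-outcome permutation-p convention; Benjamini-Hochberg can
be applied downstream.

For the brain-behavior association stage (behavioral change regressed on
similarity change, age and gender, optionally with a group interaction),
the timepoint swap must act in the change-score domain. Swapping a
participant's timepoints flips *both* deltas jointly — but a joint flip
leaves the slope's cross-products invariant, so it cannot generate a null
for the association. The implemented null flips the sign of the *outcome*
delta only (with the group shuffle), which preserves exchangeability under
the hypothesis of no association; its calibration is verified by
simulation in the test suite.

Effect sizes are unpaired Cliff's delta of post versus pre within each arm,
and baseline group comparisons use two-sided Mann-Whitney U tests (exact
when n_x * n_y <= 400 and tie-free, tie-corrected normal approximation
otherwise).

## The synthetic study generator

No raw data accompany the design the package implements, so the generator
is a first-class module that emulates the study's conditions: 48
participants (25 MBTI / 23 SHEEP), ages Normal(60, 6) truncated to
[50, 80], 58% female; four scans per participant (rest/task x pre/post) at
TR = 0.719 s; button logs with Uniform(3.5, 6) s breath intervals; 39-item
FFMQ responses from a latent normal cut at (-1.5, -0.5, 0.5, 1.5).

**Connectivity structure.** The base rest correlation matrix comes from a
factor model: each ROI loads on its network's factor (loading ~ Uniform
around sqrt(rho_in) = 0.59), on a global factor (~ sqrt(rho_out)), on one
random other network's factor, and on a signed shared factor. This yields
a positive-definite matrix with block means near rho_in = 0.35 within and
rho_out = 0.05 between networks and — crucially — a rich, heterogeneous
edge-level pattern (within-network edge SD ~0.17), because the similarity
measure correlates exactly that pattern. (An earlier iid-spread
construction required so much positive-definite repair in 60 dimensions
that the repair destroyed the planted pattern; the factor model avoids
this by construction.) Participants get small edge-level jitter on top.

**The reconfiguration parameter.** For a task scan, each network's
edge-pattern deviations are mixed with a fresh factor-model draw:
`task_dev = sqrt(1 - eta) * rest_dev + sqrt(eta) * fresh_dev` (cross-network
edges use the mean of the two networks' etas), followed by an eigenvalue-
clipping positive-definite repair that is small by construction. Thus
**eta is the fraction of edge-pattern variance replaced in the task
state**, the expected rest-task pattern correlation is sqrt(1 - eta), and
expected similarity is strictly decreasing in eta — the generator's core
contract, tested over a Monte-Carlo grid. The planted group x time effect
moves eta at post-intervention by -contrast/2 (MBTI) and +contrast/2
(SHEEP) in the executive control, default mode and salience networks
(default contrast 0.3), on top of per-participant random intercepts
(SD 0.06) and slopes (SD 0.04) in eta units.

**Noise and artifacts.** Signals are scaled to a median-1000 intensity
with amplitude 10; three AR(1) nuisance signals are partially mixed into
the ROIs; task runs carry HRF-locked button-press activation in the
somatomotor ROIs (so task regression has real work to do). Motion is a
slow random walk plus step spikes of 0.5 mm (the head moves and stays
moved, so FD flags exactly the step frame, and the 1-before/2-after
expansion is observable); the step frame also carries a transient signal
artifact that censoring + interpolation removes.

**Desk scale.** Default dimensions are 60 ROIs over 9 networks and 200
acquired frames (the full 430 ROIs / 834 frames of a 10-minute run are one
config switch away); the desk-scale network sizes are 12/14/8/6/4/4/4/4/4
with the planted networks the largest, mirroring real parcellations where
default-mode and executive-control are the largest systems. Sizes below 4
ROIs were rejected: a 3-edge intranetwork block makes the spatial
correlation a 3-point Pearson r whose Fisher z explodes, which contaminates
the outlier screen.

**What desk scale can and cannot show.** A 200-frame run band-passed to
0.009-0.08 Hz retains roughly 2BT ~ 20 effective degrees of freedom per FC
estimate, so single-edge FC values are noisy (SE ~0.2 in z) and similarity
measures inherit substantial measurement noise. Power calculations on
these conditions show that a planted eta contrast of 0.3 at n = 48 sits
near 50% detection power for a single desk-scale network — an information
limit of short filtered runs, not a method defect; at full scale (834
frames, ~50-ROI networks) the same contrast is detected essentially
always. The recovery test therefore plants a strong contrast (0.6) and
reads out the mean intranetwork similarity over the three planted
networks; under those conditions the generate-analyze loop attains >= 80%
power with the interaction sign recovered in >= 95% of replicates. Passing
these tests demonstrates that the machinery recovers what was planted
under the stated conditions; it does not certify effect sizes in real
elderly cohorts, whose true reconfiguration magnitudes are unknown.

The generator does not model hemodynamic forward dynamics, scanner physics
or atlas geometry, and it simulates only in-scanner breath counting (the
out-of-scanner practice session of the original design is not emulated).
Every planted parameter is exported per participant x timepoint x network
(`export_ground_truth()`), and all randomness streams deterministically
from one master seed, so any single participant is regenerable in
isolation.

## Numerical conventions

* Correlations are clipped to |r| <= 1 - 1e-7 before atanh, keeping Fisher
  z finite on degenerate fixtures (identical matrices, duplicated ROIs).
* The canonical intranetwork vector order is the row-major upper triangle;
  internetwork vectors are the cross block flattened column-major with the
  network's ROIs as rows. The correlation is order-invariant; freezing the
  order makes vectors auditable and rest/task vectors index-aligned.
* The intranetwork correlation uses the unique triangle; on a symmetric
  block the duplicated-block correlation is identical, so nothing hinges
  on the choice.
* FC diagonals are stored as 0 and excluded from every vectorization.
* Positive-definite repair is deterministic eigenvalue clipping at 1e-6
  with unit-diagonal rescale.
* All tabular I/O is header-bearing TSV, UTF-8, decimal point; readers
  reject ragged rows, blanks and non-numeric cells with coordinates rather
  than imputing.

## Problem sizes used by the test suite

Module tests run on toy fixtures (<= 50 frames, <= 10 ROIs). The
calibration suites use 500 null datasets of 20 participants with 99
permutations (test size), 100 full generate-analyze replicates at n = 48
desk scale with 199 permutations (power and sign recovery), 20 seeds per
eta level (monotonicity), and a 10-participant study run twice end to end
(byte-identical determinism). These sizes were chosen so the entire suite
completes in well under half an hour on one core while keeping the
binomial error of every calibrated rate inside its test's tolerance.
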