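---
title: "Detecting task-independent signals with tensor decomposition and trial shuffling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting task-independent signals with tensor decomposition and trial shuffling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific question

In trial-structured population recordings -- here, two-photon calcium
imaging of mouse visual cortex during a visual behavior task -- neurons
respond both to the task events themselves (repeated familiar images, and
their unexpected omissions) and to *task-independent* influences: running,
arousal as indexed by pupil size, and other shared state fluctuations.
Condition-averaged responses cannot distinguish the two, because a shared
state signal that happens to co-occur with omissions looks exactly like an
omission response.

The key observation behind this package is that the two differ in their
*trial-to-trial covariance structure*: an omission-locked response is
reproduced (up to noise) on every omission trial, while a task-independent
signal fluctuates across trials coherently **across neurons**. Permuting
trial identities within each condition, independently for each neuron,
preserves every neuron's condition-locked response and its marginal
trial-to-trial variability, but destroys the across-neuron coherence. Any
statistic that drops after such a shuffle therefore measures shared,
condition-unrelated structure.

`tcashuffle` implements this program end to end:

1. `generate_session()` simulates a session with the task's statistical
   structure, including a controllable shared latent (ground truth).
2. `align_to_events()` builds the neurons x time x trials tensor.
3. `fit_cp_als()` / `run_tca_ensemble()` decompose it with a canonical
   polyadic (CP) model.
4. `classify_components()` labels components image-/omission-specific by
   their trial weights.
5. `shuffle_within_condition()` + `compare_real_vs_shuffled_weights()`
   perform the shuffle test.
6. `framewise_pair_correlation()` and friends provide the complementary
   pairwise noise-correlation view.

## The simulated task

The stimulus is a periodic stream: a 250 ms image followed by a 500 ms
gray screen, i.e. one flash per 750 ms. A small fraction of flashes change
the image identity (8 identities by default); each *non-change* flash is
independently replaced by a gray screen -- an omission -- with probability
0.05. Omissions are rare and unpredictable, so they violate the learned
temporal expectation.

Cell classes differ in their response kernels:

* **excitatory** and **SST** neurons respond to images with a
  difference-of-exponentials transient; SST neurons carry a small sustained
  *negative* omission response.
* **VIP** neurons show an anticipatory ramp starting 250 ms before each
  expected flash. An image truncates the ramp (suppression); an omission
  lets it grow into a sustained activation. This yields the characteristic
  pattern in which VIP activity peaks after omissions.

The shared latent multiplies each event response: the gain of neuron $n$
on trial $k$ is

$$ g_{nk} = 1 + s\,\ell_k\,u_n, $$

where $\ell_k$ is a standard-normal per-trial latent shared by all
neurons, $u_n \ge 0$ are half-normal per-neuron loadings drawn once per
session, and $s$ (`latent_strength`) sets the overall strength. The latent
can be linearly coupled to the per-trial mean running speed and pupil area
(themselves AR(1) processes), so that "state" is partially observable
through behavior, as in real data. Independent Gaussian noise is added per
frame and the traces are rectified at zero (they stand in for inferred
event rates); a slow dF/F-like variant is obtained by causal exponential
filtering.

### Default parameter choices

The defaults are fixed properties of the simulated study conditions, not
free knobs; they were chosen once, for realism, and are exercised
unchanged by the package's validation suite.

| parameter | default | rationale |
|---|---|---|
| frame rate | 10 Hz | typical multi-plane mesoscope rate; all windows are defined in seconds and mapped to frames by the alignment convention |
| session duration | 330 s | ~440 flashes: ~405 repeated images and ~20 omissions, a realistic per-session omission count |
| `omission_prob` | 0.05 | the task's omission rate |
| `change_prob` | 0.03 | occasional identity changes; change flashes are excluded from the repeated-image pool |
| `latent_strength` (fixture `"latent"`) | 0.5 | with $E|u| \approx 0.8$, typical gain excursions of ~±40%, consistent with state modulation of visual cortex |
| behavior coupling (fixture `"behavior-coupled"`) | wheel 1.0, pupil 0.35 | wheel-dominant coupling; both variables matter but locomotion more strongly |
| `noise_sd` | 0.1 | per-frame noise comparable to the kernel amplitudes (0.15-0.7) |
| AR(1) behavior | wheel: mean 5 cm/s, sd 3, ar 0.97; pupil: mean 300 a.u., sd 40, ar 0.98 | slow, smooth behavioral time series |

## Alignment conventions

Offset 0 of an aligned window is the first frame at or after the event
onset; windows are half-open $[t_0, t_1)$. At 10 Hz the default tensor
window $[-0.3, 0.6)$ s yields 9 frames. Because the stimulus period is
750 ms, aligning on omissions simultaneously aligns on the surrounding
images, which is how the correlation analysis reads image- and
baseline-window quantities off one omission-aligned $[-1, 2]$ s grid.

Evoked responses are quantified on class-specific windows: 350 ms
post-onset for excitatory/SST images; $[-250, 100)$ ms for VIP images (to
capture the anticipatory ramp); 500 ms post-onset for omissions in all
classes. Traces shown as population averages use the median across trials
followed by the mean across neurons; scalar quantifications use the
across-trial mean trace. Both stages are implemented
(`population_trace_summary()`, `quantify_evoked_response()`).

## The CP decomposition

`fit_cp_als()` implements unconstrained (signed) CP by alternating least
squares, written from first principles on the three mode unfoldings. Each
factor update is an exact least-squares solve against the Khatri-Rao
product of the other two factors, so the reconstruction error is
non-increasing across sweeps (asserted in the test suite on every
iteration). Numerical choices:

* initialization: standard-normal factors, seeded; `n_restarts` keeps the
  best of several starts (default 5 for single fits, 1 inside ensembles,
  whose members already sample initializations);
* convergence: stop when the normalized error changes by less than
  `tol = 1e-6` between sweeps, or after `max_iter = 500` sweeps;
* a tiny ridge (1e-10 relative) is added to a Gram matrix only if it is
  numerically singular;
* gauge fixing: factor columns are unit-norm, all scale is absorbed into
  $\lambda_r \ge 0$, signs are fixed by making the absolute peak of the
  temporal and neuron columns positive (compensated in the trial factor),
  and components are sorted by decreasing $\lambda$.

For magnitude comparisons, `component_weights(..., scaled = TRUE)`
redistributes the scale evenly across modes (each factor column times
$\lambda_r^{1/3}$, the balanced gauge), so "neuronal weights" carry the
component's size.

`model_similarity()` scores two fits by optimally matching components
(assignment problem on the product of absolute factor cosines) and is 1
for any gauge transformation of the same model; it is used to demonstrate
ensemble reproducibility.

## Component classification

`classify_components()` compares each component's trial weights between
image and omission trials with the two-sided Wilcoxon rank-sum test
(exact enumeration with average ranks for pooled n <= 20; tie-corrected
normal approximation otherwise -- see `rank_sum_test()`). Non-significant
components (alpha = 0.05) are nonspecific; significant ones go to the
condition with the larger mean absolute weight.

By default the rank-sum compares **absolute** trial weights. This was a
genuinely open design choice, and the deciding argument is invariance: the
CP sign gauge is arbitrary, so only weight magnitudes are well defined
across fits, and a component driven by a shared state signal on omission
trials has omission weights that are large in magnitude but roughly
symmetric about zero -- a signed test is structurally blind to exactly the
component class this analysis is designed to find. The signed variant
(`classify_on = "signed"`) is retained for comparison.

Depth 250 um is the superficial/deep boundary; exactly 250 um is assigned
to deep. No multiple-testing correction is applied across components or
groups, and alpha is fixed at 0.05 throughout.

## The shuffle test and its operating characteristics

`shuffle_within_condition()` permutes trial slices within image trials
and, separately, within omission trials, independently per neuron. Two
exact conservation laws are tested: per neuron and condition, the multiset
of trial slices (hence the condition-mean trace) is preserved bit-exactly.

`compare_real_vs_shuffled_weights()` pools the scaled absolute neuronal
weights of omission-specific components across each ensemble and reports,
per area x layer group and overall:

* the **pooled** rank-sum p (every weight from every ensemble member), the
  convention used for full-scale reporting. Because ensemble members
  re-fit the same tensor, pooled values are strongly dependent, so this p
  overstates its evidence; with small populations its usefulness lies in
  the *direction* of the difference combined with significance.
* a calibrated **iteration-level** rank-sum (one pooled-mean weight per
  ensemble member, two-sample across members), reported as
  `overall$p_value`.

The validation rule (`shuffle_comparison_detects()`) therefore requires
both significance and the correct direction (real above shuffled). At desk
scale this matters for a subtle reason: the 0.9 s tensor window is longer
than the 0.75 s stimulus period, so adjacent trials share one or two
frames. This duplication is a genuine across-trial structure that
shuffling destroys even without any latent, and it nudges the two
ensembles apart in the *opposite* direction (shuffled fits scatter their
omission-specific weight mass differently than real fits). Requiring the
real-above-shuffled direction makes the test specific to the latent while
remaining sensitive: on simulated sessions with `latent_strength = 0.5`
the detection rule fires in the large majority of replicates, and
essentially never on latent-free sessions. Sessions that happen to draw
few omission flashes (the omission count is binomial around ~21) are the
main source of misses -- with a dozen omission trials there is little
coherent variance for the decomposition to find, which is a faithful
property of the method, not an artifact of the implementation.

## Noise correlations

`remove_stimulus_signal()` subtracts, per neuron and frame, the mean
response of each image identity (omissions are their own category), and
`framewise_pair_correlation()` computes Spearman correlations across
trials at every frame (average ranks; a pair-frame where either neuron is
constant is excluded and counted). `correlation_shuffle_null()` permutes
each neuron's trial order independently (50 repeats by default) to
control for activity-level effects.

Two p-value flavors are reported by `aggregate_plane_pairs()`: the
asymptotic Spearman test per pair, and a one-sample t-test of the real
value against its shuffle null. A limitation worth knowing: with few
trials, signal removal centers both neurons of a *real* pair on the same
trial groups, which slightly widens the sampling spread of the real
correlation relative to its trial-permutation null; the t flavor is
therefore optimistic on null data at small n, while the rank-based flavor
is calibrated. The package reports both so the reader can see when they
disagree.

## What the simulations do and do not establish

The generator reproduces the task's timing statistics, class-specific
response shapes, a shared behavior-coupled latent, and independent
per-neuron noise. It deliberately omits: calcium-indicator biophysics and
spike inference (traces are event rates by construction), image pixel
content and stimulus-identity tuning beyond identity labels, reward and
licking structure, and slow drifts such as photobleaching or plane drift.
Passing the validation suite therefore establishes that the pipeline
recovers shared task-independent structure *when the generative
assumptions hold*; on real recordings, spike-inference artifacts,
non-multiplicative state effects and slow nonstationarities can all
modulate sensitivity, and the shuffle control addresses only trial-level
coherence, not within-trial temporal confounds.

## Problem sizes used in the validation suite

The full-scale convention is 100 ensemble iterations and 100 shuffle
repetitions per session. The package's own validation studies use
sessions of ~50 neurons with ~405 image and ~21 omission trials, ensembles
of 20 real and 20 shuffled fits, and 20 replicate sessions per condition
-- sizes at which the qualitative behavior of the full-scale procedure is
already stable while a complete run of the suite stays within minutes on
a single core.

## A worked example

```{r, eval = FALSE}
library(tcashuffle)

cfg <- fixture_config("latent", seed = 1)
session <- generate_session(cfg)
cmp <- run_shuffle_comparison(session, n_iterations = 20, seed = 1)
cmp$overall
#> $p_value      # iteration-level rank-sum
#> $p_pooled     # pooled rank-sum across all weights
#> $mean_real    # mean |scaled neuronal weight|, real fits
#> $mean_shuffled
#> $direction    # +1: shuffling decreased the weights
shuffle_comparison_detects(cmp)
```
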