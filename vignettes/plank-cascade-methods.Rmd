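---
title: "Methods: cascade classification of plank technique from IMU signals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cascade classification of plank technique from IMU signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plankcascade)
```

# The problem and the model

Five body-worn inertial sensors (occiput, C7, T3, sacrum, right forearm)
record a subject holding a plank for 10 s at 60 Hz. Each sensor reports
Euler orientation angles, acceleration, angular velocity and magnetic field
on three axes: 60 channels, 600 timestamps. The task is to decide whether
the hold is an acceptable plank (`PC`) or one of six deviations (`HTFN`,
`HTBN`, `HC`, `HTB`, `HD`, `BC`; see `technique_descriptions()`).

## Stable-window features

Subjects take a moment to settle into the hold and anticipate its end, so
the signal is non-stationary at both ends of the trial. Features are the
per-channel means over the middle stable window,
\[
X_{k,j} = \frac{1}{240}\sum_{t=181}^{420} x^{(k)}_{t,j},
\]
i.e. the 4th through 7th second. Both endpoints are inclusive — the
normalising constant 240 forces the closed interval \([181, 420]\), and
`window_spec()` implements exactly that. A `fractional` mode (30 %–70 % of
the trial) generalises to other trial lengths and reproduces the fixed
indices at \(T = 600\). Engineered features
\(\max(A, B)\) over pairs of channels that measure the same quantity at
different sensors (`add_max_features()`) encode *relative* segment
configuration — e.g. whether the mid-back sits above the sacrum — which no
single sensor channel sees.

## The cascade

Classification proceeds down a binary tree (`build_tree()`):

* **Root threshold node.** One deviation is separable by one feature alone
  (a backwards head tilt drives the first sensor's Euler-Y far below every
  other class). The fitted threshold is the midpoint between the two
  classes' nearest extremes; fitting *fails loudly* if the training classes
  overlap on the chosen variable, because a midpoint between overlapping
  classes is meaningless. With `threshold_first = "auto"` all
  (feature, class) pairs are scanned for perfect separation and the widest
  standardised gap wins; if none separates, the tree is built from
  two-stage nodes only.
* **Two-stage nodes.** Node \(i\) separates one deviation \(D_1\) from the
  remainder \(D_2 = C_i\), where \(C_i = C_{i-1} \setminus D_{1,i}\):
  first an aberrance filter \(F_i\), then a binary random forest
  \(RF_i\) over *all* features.
* **Terminal leaf.** An observation every node declines is `PC`. The
  acceptable class is deliberately never a node's \(D_1\): the cascade
  peels off deviations and what remains is acceptable.

**Node ordering.** The order in which deviations are peeled off is chosen
greedily: each candidate is fitted as a node and scored by its two-stage
training accuracy, with the forest part scored **out-of-bag** (OOB). Plain
training accuracy is degenerate for purity-grown forests (always ≈ 1), and
a further data split would waste subjects; OOB is the standard internal
estimate and costs nothing. Ties go to canonical technique order, which
makes greedy builds deterministic under a seed.

## The aberrance filter

For each filter variable at node \(i\), the \(D_2\) training values form an
empirical reference distribution. An observation \(x\) is flagged — and
classified as \(D_1\) without consulting the forest — if any variable's
empirical p-value falls below \(\alpha = 0.05\) (the union rule across
variables). `empirical_p_value()` supports two conventions:

* `add_one` (its own default):
  \(p_\text{left} = (\#\{v \le x\} + 1)/(m+1)\), never exactly zero;
* `none` (the filters' default): the raw proportion \(\#\{v \le x\}/m\),
  which is zero for a value outside the reference range.

The filters must use the uncorrected form: with the corrected one, the
smallest attainable two-sided p-value is \(2/(m+1)\), which already exceeds
0.05 for every \(m \le 39\) — at the final node the reference has only
\(m = 15\) training subjects, so a corrected filter could never flag
anything there, defeating its purpose. A useful side effect of the
uncorrected leave-in convention: a *training* \(D_2\) value compared
against its own reference always has \(p \ge 2/m\), so training
specificities are exact by construction, while genuinely extreme \(D_1\)
observations land outside the reference range at \(p = 0\).

Rows flagged during training are by default excluded from the forest's
training sample (`exclude_flagged = TRUE`): extremes sit in regions that
complicate the boundary, and flagged observations never reach the forest at
prediction time anyway. Exclusion is skipped if it would empty a class.

**Choosing filter variables.** The reference study hand-picked its filter
variables per node; this package does the analogous thing through
`designated_filter_variables()`, which names the channels the synthetic
hip-drop deviation is built on (plus their cross-sensor maxima). Only the
hip-drop class gets a filter by default: it is the only class with an
extreme subpopulation, and an empirical-tail filter false-flags in-range
observations at a rate of roughly \(\alpha\) per variable, so filtering
classes without extremes merely costs specificity. An `"auto"` mode
implements a selection rule — retain a candidate iff it flags at least one
\(D_1\) training observation while flagging at most
\(\lfloor \alpha |D_2| \rfloor\) of \(D_2\) — but with small references the
outside-the-range event is common enough (\(\approx 2/m\) per draw) that
auto mode over-retains; it is provided for experimentation, not as the
default.

## The random forest

No forest implementation is available in the target environment, so the
package carries its own (`rf_fit()`, Rcpp): bootstrap-aggregated CART trees
with Gini splitting, grown to purity (`nodesize = 1`), 500 trees,
\(\lfloor\sqrt{p}\rfloor\) candidate features per split, majority vote with
ties to the negative class, OOB votes retained, and mean-decrease-Gini
importances accumulated over splits. One deliberate detail follows
scikit-learn's splitter semantics: features that are constant within a node
do **not** count against `mtry` — the splitter keeps drawing until it has
examined `mtry` splittable features or exhausted them all. Without this, a
noise-free dataset (where most channels are globally constant) degenerates
to single-leaf trees. On noisy data the behaviour matches a reference
random forest (verified against an independent implementation during
development).

# The synthetic world

The study's recordings are not deposited, so every pipeline stage is
exercised against `generate_dataset()`. The signal model is the simplest
structure that exercises every stage:
\[
x_t = \mu_{c,j} + b_{k,j} + r_t + \varepsilon_t,
\]
with class/channel means \(\mu_{c,j}\), subject random effects
\(b_{k,j} \sim N(0, \texttt{subject\_sd}^2)\), i.i.d. noise
\(\varepsilon_t \sim N(0, \texttt{noise\_sd}^2)\) (an AR(1) option,
`ar1_phi`, exists but is off by default), and deterministic linear ramps of
amplitude `transient_amp` over the first and last `transient_len`
timestamps — the ramps make the stable window *matter* without touching it.

Defaults state the emulated world once:

| parameter | default | meaning |
|---|---|---|
| `n_subjects_per_technique` | 19 | cohort size of the emulated study |
| `n_timestamps`, `sample_rate` | 600, 60 | 10 s at 60 Hz |
| `subject_sd` | 1 | between-subject spread per channel (signal units) |
| `noise_sd` | 2 | within-trial sampling noise; feature-level SD ≈ \(2/\sqrt{240}\) |
| `class_shift` | 5 | offset of each non-HD deviation from `PC` on its designated channels, graded by multipliers (1, 0.8, 0.6) ≈ 5 combined feature SDs |
| `hd_base_shift` | 2 | hip-drop offset — deliberately only ≈ 2 SDs, so HD and PC overlap |
| `hd_extreme_fraction`, `hd_extreme_shift` | 8/19, 6 | the extreme hip-drop subpopulation |
| `htbn_margin` | 5 | guaranteed HTBN gap on `Euler-Y-S1`, *plus* a 6-SD allowance |
| `transient_len`, `transient_amp` | 180, 3 | settling ramps outside timestamps 181–420 |

Channel assignments: head deviations move S1–S2 Euler channels, hands-too-
close moves S5 channels, the two pelvis/back deviations move distinct S4
channels, and hip-drop moves `Euler-Z-S3`, `Acc-X-S3/S4`, `Mag-Z-S3/S4`.
Magnetometer baselines differ per sensor so cross-sensor maxima are
non-degenerate. The HTBN mean on `Euler-Y-S1` is placed below every other
class by `htbn_margin` plus six noise SDs, so the threshold node is
separable with probability ≈ 1, mirroring the perfectly separated
distribution the method exploits.

**What a green test establishes — and what it does not.** The generator
reproduces the *statistical geometry* the cascade exploits (separable
margins, partial overlap, an extreme mixture, subject effects,
non-stationary ends). It does not simulate biomechanics: channels are
independent given the class, there is no orientation-consistency between
Euler/gyro/acceleration channels, and real deviations surely move more
channels with correlated patterns. Green tests therefore certify the
*machinery* — windowing, thresholding, filtering, forests, the evaluation
protocol — not field performance on real athletes.

# Evaluation protocol

`stratified_split()` draws, per technique, \(\lfloor 0.8 n\rfloor\)
training subjects (19 → 15/4), seeded per repetition as `seed +
repetition`; `repeat_evaluation()` refits the full cascade on each of the
50 training sets and tabulates per-node confusion metrics on train and
test. \(D_2\) membership at node \(i\) follows the true-label chain
\(C_i\), so `n1`/`n2` per node are fixed across repetitions (the
alternative — only rows the cascade actually routes there — is available
via `routed = TRUE`). Metrics with zero denominators are reported `NA`,
never coerced to zero. Aggregates are plain means and SDs over repetitions
(SD 0 by convention for a single repetition, with a caveat flag).

# Numerical and design choices

* **Tie-breaks.** Forest vote ties go to the negative (continue) class;
  greedy-order score ties go to canonical technique order; split points are
  midpoints of adjacent distinct values.
* **Determinism.** All randomness flows through R's RNG (the C++ code draws
  via `unif_rand()`), so a seed fixes the dataset, every split, every
  forest and hence every reported number bit-identically.
* **Serialization.** Models are single JSON files with 17-significant-digit
  numbers; that is the precision at which doubles survive a decimal round
  trip, and the tests assert label-identical predictions after reload. A
  version stamp guards against format drift.
* **Derived features at prediction.** If a model needs `max(A, B)` columns
  that the new table lacks, they are recomputed from the base channels
  rather than erroring.
* **Criterion world for the sensitivity property.** The "separations ≥ 4
  combined SDs" recovery property is checked in a configuration where
  *every* designated channel reaches 4 combined feature SDs
  (`class_shift = 4·sd/0.6`, `hd_base_shift = 4·sd` with
  `sd = sqrt(subject_sd² + noise_sd²/240)`). With weaker worlds (a single
  ≥ 4 SD channel per class) a √p forest with 15 positive subjects can dip
  below 90 % sensitivity at one node — behaviour reproduced exactly by an
  independent reference forest, i.e. a small-sample property of the method,
  not of this implementation.

# Known limitations

* The study's exact threshold (−46.4 on `Euler-Y-S1`) is tied to its sensor
  mounting and units; the package reproduces the *rule* (midpoint between
  nearest class extremes), never the constant.
* The auto filter-selection rule over-retains on small samples (see above);
  hand-picked filter lists remain the recommended path, as in the original
  workflow.
* Channel units are treated as unitless reals; unit handling (degrees vs
  radians, g vs m/s²) is the caller's responsibility.
* With 19 subjects per class, test-set metrics at deep nodes rest on 4 + 4
  observations; their SDs across repetitions are accordingly large, which
  the report makes visible rather than smoothing over.
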