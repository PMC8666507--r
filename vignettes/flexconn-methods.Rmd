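---
title: "Methods: from reversal-learning errors to connectivity-mediated effects"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from reversal-learning errors to connectivity-mediated effects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flexconn)
```

flexconn chains five statistical stages: behavioral scoring, edgewise
connectivity statistics with permutation family-wise error control,
edge–behavior correlation, principal-component subnetwork construction, and
counterfactual causal mediation with a count outcome. This vignette explains
each model, its assumptions, the tunable parameters, and the design choices
made where the design was genuinely open. It states no empirical result
that the test suite and `scripts/acceptance.R` do not themselves compute.

## Behavioral scoring

**Conditioned approach.** A session log is a timestamped event stream
(`cs_onset`, `cs_offset`, `lever_press`, `receptacle_entry`,
`sucrose_delivery`). For each 30-s CS window `[onset, onset + 30)` we tally
presses and entries, take the latency from onset to the first response, and
compute the elevation score — entries during the CS minus entries in the
30 s immediately before it — summed over trials. Response probability is
the fraction of trials with at least one response. Per-subject summaries
average the last `k_last = 5` sessions (the training endpoint). Two open
points were resolved as follows and are configurable:

* *Censored latencies.* Trials with no response enter the mean latency at
  the 30-s censoring bound (`latency_mode = "censor"`). Censoring keeps the
  estimate bounded and deterministic and is directionally consistent with
  "slower"; `"exclude"` mode drops such trials instead.
* *Pre-CS windows.* The 30 s immediately preceding onset. At inter-trial
  intervals of 90–210 s a pre-CS window can never overlap the previous CS;
  if a malformed log violates this the scorer raises rather than truncates.

**Set-shift scoring.** A phase is an ordered outcome sequence over
`{correct, error, omission}`. The criterion is the first run of
`criterion_k = 6` consecutive correct choices; both errors and omissions
break the run (an omitted trial counts against the criterion), but
omissions are *not* active errors — they are non-choices and carry no
feedback. Errors strictly before the first correct choice are prepotent;
later errors are regressive, split by the immediately preceding
non-omission outcome (correct → initial, error → subsequent). Skipping
omissions in that look-back is a choice: an omission provides no feedback
that could re-anchor behavior. Both rules are arguments
(`criterion_k`, `skip_omissions`). Each contingency (acquisition,
reacquisitions, reversals, extradimensional shift) is scored as its own
sequence. The paper-level ambiguity of which phase ("Reversal-2
reacquisition" vs. "Reversal 2") supplies the mediation outcome is exposed
as `outcome_phase` in the pipeline config and never guessed.

## Inference kernels

* **Poisson GLM** (`fit_poisson_glm`): IRLS via the standard one-parameter
  exponential-family fit, deviance tolerance 1e-8, at most 100 iterations.
  Effects are reported as rate ratios `Exp(B)` with Wald 95% intervals
  `exp(b ± 1.96·SE)` — the Wald (not profile) form matches the reporting
  style of mainstream behavioral-statistics software. Separation (an
  all-zero group) is detected from boundary fitted rates and flagged as
  non-convergence instead of being reported silently. No overdispersion
  correction is applied by default; counts in this design are modeled as
  plain Poisson.
* **Two-way ANOVA** (`two_way_anova`): Type-II sums of squares, which
  coincide with the textbook decomposition in balanced designs and are the
  conventional default for main-effect-focused 2 × 2 layouts
  (`ss_type = 3` available). Fits with numerically zero residual variance
  return infinite F with a `degenerate` flag.
* **Beta correlation p-value** (`corr_pvalue_beta`): under independent
  bivariate-normal sampling the null Pearson correlation from `n`
  observations follows a symmetric beta on [−1, 1] with shapes
  `a = b = n/2 − 1`; the two-sided p is `2·min(F(r), 1 − F(r))`. This is
  algebraically the classical t-test on `t = r√((n−2)/(1−r²))`; the suite
  asserts agreement to 1e-10 over a grid. The identity assumes temporally
  independent samples — see the cleaning note below.
* **Multiplicity**: Benjamini–Hochberg for edge–behavior discovery,
  Bonferroni for post-hoc contrasts. Note the step-up BH *adjustment* is
  not idempotent as an operator (re-adjusting adjusted values changes
  them); the suite asserts its monotonicity and Bonferroni domination
  instead. Reports label p ≤ 0.05 as significant and p ≤ 0.10 as marginal.

## Connectivity

Cleaning regresses confounds (plus an intercept) out of each ROI signal by
least squares, then applies a zero-phase forward–backward 4th-order
Butterworth band-pass (default 0.01–0.15 Hz at TR = 2 s; Nyquist 0.25 Hz)
with reflective padding to suppress filter-edge transients. Regression
precedes filtering; a combined-projection mode is not needed for the white
synthetic signals but order matters in principle for real data, so the
band and order are explicit arguments and are recorded with the outputs.
Connectivity is the Pearson correlation matrix of the (cleaned) signals;
group statistics use Fisher z. `|r| = 1` is clamped to `1 − 1e-7` before
`atanh` with a warning, never silently.

Edges are unordered ROI pairs named `A-B` with A before B in the fixed ROI
order (PrL, IL, OFC, S1, NAc, CPu, HippD, Thal); the upper triangle in that
order is the canonical storage everywhere (28 edges for 8 ROIs).

In synthetic pipeline mode cleaning is **off** by default: the generator's
signals are white and confound-free, and band-passing white noise would
induce autocorrelation that violates the independent-samples assumption
behind the beta p-value. For file inputs cleaning defaults to on.

## Network-based statistics

The suprathreshold statistic is the pooled two-sample exposure *t* on each
edge's z values (sign convention: exposure minus control; tables report the
magnitude plus a direction column, since reduced connectivity is
conventionally printed with positive T). The link-based variant corrects
each edge by the permutation distribution of the maximum |t| over all
edges; the component variant thresholds |t| at the critical value for
`supra_p`, forms connected components on the ROI graph, and corrects by the
null maximum component size (in edges). Link-based is the default; the
component variant is the canonical alternative and useful for comparison.

Permutations shuffle exposure labels freely across sexes (the observed
labeling is included in the permutation null, so corrected p ≥ 1/n_perm and
p-values live on the k/n_perm grid); when `n_perm` reaches the number of
distinct label assignments the engine enumerates them exhaustively and the
p-values are exact. The "sparse matrix per subject" reading of
suprathresholding is not implementable as an FWE procedure; edge-level
suprathresholding of the group statistic — the standard NBS construction —
is used.

## Subnetwork mediator and causal mediation

Edges with uncorrected exposure p below `select_p = 0.1` (lenient by
design: weak univariate edges can still carry shared variance) are
column-centered — *not* standardized, since all columns are Fisher-z values
on a common scale; a standardized mode exists — and decomposed by SVD. PC1
loadings are sign-oriented so their mean is non-negative (the component
reads as a cohesive subnetwork); subject scores are the centered projection
and become the mediator M.

The mediator model is ordinary least squares with normal errors; the
outcome model is the Poisson GLM above. Without an exposure–mediator
interaction the natural effects are `RR_NIE = exp(a₁b₂)`,
`RR_NDE = exp(b₁)`, and `RR_total = RR_NDE·RR_NIE` exactly. With the
interaction term (off by default — a single mediated percentage with no
interaction is the conventional report) the conditional-at-mean-covariate
forms use the exact normal moment `E[exp(kM)] = exp(kμ + k²σ²/2)`, giving
`log NDE = b₁ + b₄(a₀ + a₂·C̄) + (b₂b₄ + b₄²/2)σ²`; the suite checks both
cases against a Monte-Carlo counterfactual oracle that integrates the
fitted models by simulation. Proportion mediated is reported on the log
scale, `PM_log = log RR_NIE / log RR_total` (natural for a log-link
decomposition), with the excess-rate-ratio version alongside; when direct
and indirect effects point in opposite directions the result is flagged
"inconsistent mediation" and the excess-RR measure is not interpreted as a
proportion.

Bootstrap inference resamples subjects with replacement, stratified by
exposure so both GLMs keep their group sizes (unstratified mode available);
intervals are percentile, and the indirect-effect p-value is the two-sided
bootstrap tail probability of `log RR_NIE` against zero. Degenerate
resamples are redrawn and counted.

## The synthetic study

The generator is the package's definition of the study conditions:

* **Design**: balanced 2 × 2 (sex × exposure), `n_per_cell = 10` — 40
  subjects, the scale of a rodent imaging subsample.
* **Scans**: `n_timepoints = 900` at TR = 2 s (a 30-min scan), zero-mean
  multivariate normal per subject. Signals are temporally white by default
  because the beta p-value's sampling theory assumes independent samples;
  an AR(1) option exists solely to probe robustness to that assumption.
* **Network**: exchangeable base correlation 0.35 across the 8 ROIs;
  exposure subtracts `delta = 0.3` on the five accumbens edges (PrL-NAc,
  S1-NAc, NAc-CPu, NAc-HippD, NAc-Thal), with eigenvalue clipping at 1e-6
  and diagonal renormalization repairing the reduced matrix to a valid
  correlation. The magnitude was fixed once, from power arithmetic: with
  the between-subject spread below, it makes the group effect detectable
  (standardized difference ≈ 1.3) in a 20-vs-20 design, emulating a study
  that *found* its network effect.
* **Between-subject variance**: each subject carries a stable shared
  subnetwork-strength offset on the affected edges (`subject_sd = 0.2`,
  Fisher-z scale) plus independent per-edge offsets on all edges
  (`edge_sd = 0.15`). This is essential realism, not decoration: with a
  fixed group correlation matrix the mediator would vary across subjects
  only by correlation-estimation noise (≈ 1/√(T−3) ≈ 0.03), exposure and
  mediator would be collinear, and neither cross-subject edge–behavior
  correlation nor the indirect effect would be estimable in principle. The
  shared factor also gives the selected edge set its dominant principal
  component, as observed in real connectivity data.
* **Behavior**: counts are Poisson with
  `log rate = b₀ + b₁X + b₂M + b₃C`, where M is the *measured* mean
  Fisher z over the planted edges, computed by the same connectivity module
  the analysis uses — the mediation path is real, not assumed. Defaults
  `b₀ = log 10`, `b₁ = 0.2`, `b₂ = −0.75`, `b₃ = 0.1`: reduced
  connectivity raises the error rate around a baseline of 10 active
  errors, and the implied planted proportion mediated on the log scale is
  ≈ 0.5.
* **Event logs**: homogeneous Poisson events (presses 0.10/s and entries
  0.15/s during the CS, baseline entries 0.05/s) over 15 trials per
  session with uniform 90–210-s inter-trial intervals; rates are desk
  picks of plausible conditioned-approach magnitudes, as no reference
  values exist.
* **Determinism**: every generator is a pure function of its configuration
  and seed; per-subject sub-seeds are `seed + subject index`, so adding or
  removing subjects never reshuffles other subjects' draws. The design
  table itself is a deterministic layout (cells in fixed order).

What the generator does **not** emulate: hemodynamics, physiological and
motion noise structure, spatial processing (registration, smoothing,
atlasing), unbalanced designs, or overdispersed behavior. Passing tests
therefore demonstrate the statistical machinery's correctness and
calibration under the stated sampling model, not robustness to real
acquisition artifacts.

## Numerical choices and degenerate inputs

* IRLS tolerance 1e-8 / 100 iterations; Wald z = 1.96.
* Eigenvalue floor 1e-6 for correlation repair; `atanh` clamp at 1e-7.
* Zero-variance ROI signals, constant behavior vectors, constant edge
  columns, rank-deficient design matrices, and empty sex × exposure cells
  raise typed errors naming the offender; zero within-cell ANOVA variance
  and separated GLMs are flagged, not fatal.
* PC1 sign ties (mean loading exactly 0) keep the SVD orientation; more
  edges than subjects is allowed but warned about.
* The NBS exceedance count uses a 1e-10 relative slack so that label
  assignments whose maximum statistic equals the observed one up to
  floating-point noise (e.g. the group-swapped assignment) are counted.

## Problem sizes used by the test suite

The calibration and recovery simulations run at deliberately scaled-down
sizes chosen to keep the whole suite comfortably reproducible on a single
CPU while retaining statistical resolution: 500 null datasets × 1000
permutations (family-wise calibration at T = 300), 200 replicates × 500
bootstrap draws at n = 200 (mediation recovery and coverage), and 50
end-to-end replicates at the full study conditions (n = 40, T = 900).

## Known limitations

* The ANOVA engine targets 2 × 2 between-subjects designs only.
* Bootstrap and permutation engines are single-threaded.
* Mediation assumes a single continuous mediator; no multi-mediator or
  sequential decomposition, and no sensitivity analysis for unmeasured
  mediator–outcome confounding.
* Graph-theoretic summaries (degree, modularity) are out of scope.
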