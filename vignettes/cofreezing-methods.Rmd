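---
title: "Quantifying dyadic co-freezing: models, null distributions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying dyadic co-freezing: models, null distributions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cofreezr)
```

This vignette explains the statistical machinery in `cofreezr`: what each
stage computes, the assumptions it rests on, the parameters that matter
and why their defaults are what they are, and what the synthetic-data
validation does and does not establish about real recordings.

## The experimental setting

The package targets a five-day dyadic fear-extinction paradigm. On day 1
both rats of a pair are fear-conditioned to a tone (5 CS of 20 s, 60 s
inter-trial intervals, after 120 s of habituation). On days 2–4 one animal
(the *partner*) undergoes extinction training (30 CS per session) while the
other (the *subject*) spends the same time in the experimental cage without
tones. On day 5 both are tested together (15 CS) separated by a wire mesh.
`make_schedule()` encodes these four protocols; the cage-exposure session
has no CS and inherits the extinction-training duration because the subject
spends the same amount of time in the cage.

## Freezing quantification

Freezing is operationalised as **at least 1 s of immobility**: maximal runs
of motion samples at or below a threshold, lasting ≥ 1.0 s (inclusive — a
run of exactly 1 s counts), become bouts (`detect_freezing()`). The motion
threshold is a free parameter: automated video scorers use calibrated
internal thresholds that are not portable across setups, so the package
leaves it to the caller and validates the detection logic on synthetic
traces with known bouts instead.

Per-CS freezing (`window_freezing()`) is the percentage of each
**CS + 20 s window** spent frozen, computed by continuous-time interval
intersection rather than sample counting; this makes the percentage
independent of the sampling rate and sidesteps boundary-sample ambiguity,
at the cost of exact equivalence with bin-counting scorers (differences are
at most one sample per window edge). The 20 s tail reflects the observation
that freezing initiated during a CS typically outlasts it. Session
summaries follow the field's conventions: the mean of the last two CS
(`last_k_cs_mean()`, the end-of-training fear level) and pre-CS freezing
over the 2-min habituation window (`pre_cs_freezing()`, contextual fear).

## The co-freezing recurrence analysis

Both freezing series are first down-sampled to 1 Hz (`downsample_1hz()`):
second *t* is frozen when at least 0.5 s of `[t, t+1)` is covered by a bout
(majority rule; the published description states only the 1 Hz rate, and
the majority rule is the natural unbiased choice).

For a dyad with subject series $S$ and partner series $P$, the
co-freezing profile is

$$\mathrm{prob}(\tau) \;=\; \frac{1}{T - |\tau|} \sum_{t} S(t+\tau)\,P(t),
\qquad \tau = -L, \dots, L \;(\text{default } L = 30\ \mathrm{s}),$$

the joint probability that both animals are frozen when the partner's
state is read $\tau$ seconds earlier — **positive lags mean the partner
leads**. Only overlapping indices contribute (no padding), so
`n_valid = T − |τ|` shrinks with the lag. A conditional variant
$P(S(t+\tau) = 1 \mid P(t) = 1)$ is available via `statistic =
"conditional"`; the joint form is the default because "probability of
co-occurrence" denotes a joint probability. Internally all lags are
computed at once by FFT cross-correlation on a padded 2-3-5-smooth length;
the counts are integers, so rounding removes floating-point noise, and the
unit tests compare the result against a literal double loop.

### The shuffled-partner null

Co-freezing can arise from matched marginal rates alone. The control
profile (`shuffled_control_profile()`) therefore permutes the partner's
1-Hz bins uniformly at random (default 100 shuffles), recomputes the
profile each time, and averages — destroying temporal alignment while
conserving the partner's marginal freezing rate exactly. The subject
series is never touched. A full permutation also destroys the partner's
bout structure; a circular-shift null (`null = "circular"`) that preserves
run lengths is provided as a sensitivity check but is not the default,
because the published procedure shuffles individual data points in time.

### Group inference

`group_lag_tests()` compares observed and control probabilities across the
dyads of a group with a **paired t test separately at each lag**, followed
by Benjamini–Hochberg FDR correction across the $2L+1$ lags (the step-up
procedure; the specific FDR variant is not stated in the source
literature, and BH is the standard choice). Lags with zero variance of the
differences are reported as degenerate rather than erroring: all-equal
profiles give $t = 0, P = 1$; a constant non-zero difference gives
infinite $t$. The paired t assumes approximate normality of the per-dyad
differences; with typical group sizes (6–12 dyads) it is the procedure
the field uses, not an optimal choice, and the type-I calibration of the
whole chain is checked by simulation (below).

## The inferential toolbox

* `perm_ttest()` / `perm_oneway_anova()` — classical pooled t / one-way F
  on the observed data; the P value is the add-one estimator
  $(1 + \#\{|T^\ast| \ge |T|\})/(1 + B)$ under random label reassignment,
  with $B = 10\,000$ by default (the add-one form bounds P below by
  $1/(B+1)$ and is valid for any $B$). The permutation scheme is free
  label exchange between groups; residual permutation is not implemented.
  The t-test permutation stream operates on the sorted pooled sample and
  draws the smaller group size, making the estimate invariant to argument
  order. Statistics and degrees of freedom are reported for reference
  only.
* `mixed_rm_anova()` — the classical univariate split-plot decomposition
  for one between-subjects factor and one within-subjects (trial) factor
  on a balanced time grid, allowing unequal group sizes: the group effect
  is tested against subject-within-group error, time and group × time
  against the within-subject residual. Sums of squares are computed from
  cell-mean projections, whose orthogonality makes the decomposition
  additive to machine precision (verified to 10 significant digits against
  an independent projection oracle and against `aov()` with an error
  stratum). Univariate F and P are reported uncorrected; the
  Greenhouse–Geisser epsilon is available (`gg_epsilon = TRUE`) for
  sphericity sensitivity checks but no correction is applied, matching the
  source analyses.
* `wilcoxon_signed_rank()` / `mann_whitney()` — W is the positive-rank
  sum after dropping zero differences (the standard signed-rank
  convention); U is the count of cross-pairs in rank-sum form. For untied
  small samples (n ≤ 25 paired, min(n) ≤ 20 unpaired) two-sided P values
  are **exact**, from the full enumeration null distributions ($2^n$ sign
  patterns, $\binom{n_1+n_2}{n_1}$ arrangements, evaluated through the
  exact distribution functions); ties fall back to the tie-corrected
  normal approximation with continuity correction. The unit tests verify
  the exact branch against literal enumeration.
* `pooled_t_summary()` / `welch_t_summary()` — unpaired t tests
  reconstructed from printed group means, SDs and sizes, used to check
  published statistics; Welch degrees of freedom follow
  Welch–Satterthwaite.
* `shapiro_wilk()` wraps the standard approximation algorithm;
  `bh_fdr()` wraps the Benjamini–Hochberg step-up adjustment. Both are
  thin surfaces over base R's well-tested implementations.

## The synthetic-data generator

No public raw data exist for this paradigm, so validation rests on a
generative model with known ground truth. Freezing is modelled as a
**two-state Markov chain** per animal at `fs` steps/s: onset probability
`p_on_base` (multiplied by `cs_gain` inside CS + 20 s windows), offset
probability `p_off_base`. The subject is coupled to the partner: when the
partner was frozen `lag_s` seconds earlier, the subject's onset
probability is multiplied by $(1 + \kappa)$ and its offset probability
divided by $(1 + \kappa)$, both clamped to $[0, 1]$ — so coupling raises
both entry into and persistence of co-freezing. The partner's state
before the session starts is defined as non-freezing, removing edge
ambiguity, and $\kappa = 0$ yields exactly independent chains.

This model is an assumption, not an empirical claim: it implies geometric
bout lengths, stationary dynamics within CS/no-CS segments, and purely
unidirectional influence. Real freezing has heavy-tailed bouts,
within-session extinction drift and bidirectional interaction. Passing
the synthetic validation therefore shows that the *analysis chain* is
correct and calibrated — not that the generative model describes real
rats.

### Default parameters

Defaults emulate a day-5 extinction-test session, the session the
recurrence analysis targets: `p_on_base = 0.005`/s, `p_off_base =
0.015`/s (mean bout ≈ 67 s, no-CS stationary freezing 25%) and `cs_gain =
15`, making freezing predominantly CS-evoked. On the 15-CS test schedule
these settings give session freezing around 60–85%, with the coupled
subject near the top of that range — the levels reported for
fear-conditioned rats in such tests. Long bouts matter: the co-freezing
elevation produced by coupling decays on the bout timescale, and bouts
shorter than the 30 s lag horizon could not sustain synchrony across the
full ±30 s window.

For coupling-**lag recovery**, the opposite regime is required: the
profile's argmax can only resolve a δ of a few seconds if the chains
switch state on a comparable timescale. The lag-recovery validation
therefore uses a fast-switching configuration (`p_on_base = 0.15`,
`p_off_base = 0.4`); with κ = 5 the subject then tracks the partner's
lagged state closely and the argmax identifies δ ∈ {1, …, 5} s reliably.
With the slow default dynamics the argmax is smeared upward by the
subject's geometric onset delay — an estimator property worth knowing
when interpreting peak lags in real data.

Auxiliary generators: `simulate_motion()` (two-level trace plus Gaussian
noise, exactly recoverable when the levels are ≥ 6 SDs apart),
`simulate_usv()` (two independent Poisson streams with uniform peak
frequencies inside the 22- and 50-kHz bands), `simulate_trajectory()`
(reflected Gaussian random walk in a 1 m × 1 m arena).

## Scoring conventions for auxiliary measures

* USV bands: `[18, 32)` kHz and `[35, 90)` kHz. The literature describes
  calls only as "around 22 kHz" and "around 50 kHz"; these cutoffs bracket
  the published band ranges and leave a deliberate gap — events between
  bands are counted as unclassified rather than force-assigned.
* Open field: the centre zone is the concentric square with half the
  arena's side length (25% of the area). An entry is an outside-to-inside
  transition; starting inside does not count as an entry (hence a rat
  placed in the centre and never leaving has zero entries but full centre
  time). Mean entry duration is centre time divided by entries, undefined
  at zero entries.
* Ethogram: interval durations are clipped to the session and summed per
  behaviour. Different behaviours may overlap (scoring conventions vary);
  overlap within one behaviour is an error because it double-counts time.

## Numerical choices and degenerate inputs

* Freezing percentages use exact interval arithmetic; bout edges are
  assumed to lie on the sampling grid (the binary and interval forms then
  interconvert losslessly).
* All-identical samples: permutation F is undefined, reported as P = 1 by
  convention and flagged; zero-variance paired differences are flagged
  degenerate rather than raising errors.
* Every stochastic routine takes an explicit integer seed and is exactly
  reproducible; simulation helpers reset the global RNG, so calling code
  that interleaves its own draws should draw data before running seeded
  tests.

## Validation scale

The test suite and the acceptance script validate calibration by
simulation at sizes chosen to complete in minutes on one CPU while
keeping Monte-Carlo error well inside the asserted bounds: 20-dyad null
experiments (1200 s sessions) with 100–200 replicate experiments for the
false-positive rate of the recurrence chain; 12 coupled dyads for signal
recovery; 100 replicates of 3600 s dyads for lag recovery; 1000 null
replicates at 1000 permutations for the type-I error of the permutation
tests; 50 random designs for the split-plot decomposition; 100 motion
fixtures for the freezing round trip.

## Known limitations

* The recurrence analysis assumes two animals and stationary marginal
  rates under the null; common slow drive (e.g. CS-locked freezing in
  both animals) registers as synchrony relative to the shuffle null, by
  design — the null calibration therefore uses CS-free sessions.
* The split-plot ANOVA requires a complete, balanced time grid; missing
  cells are rejected, not imputed.
* Exact rank tests require tie-free data; with ties the normal
  approximation is used regardless of sample size.
* The simulator does not model bout-length heavy tails, within-session
  extinction drift, bidirectional coupling, or ethogram co-occurrence
  structure beyond independent intervals.
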