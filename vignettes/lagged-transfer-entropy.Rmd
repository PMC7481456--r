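---
title: "Lagged Transfer Entropy: model, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lagged Transfer Entropy: model, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(telag)
```

## The measure

Transfer Entropy (TE) quantifies the information that the past of a source
process $X$ carries about the present of a target process $Y$ beyond what
the target's own past already provides. In conditional-entropy form,

$$TE_{X \to Y} = H(y_n \mid y^-_n) - H(y_n \mid x^-_n, y^-_n),$$

and, once the relevant past states have been collected into a conditioning
vector $V = [V^X, V^Y]$, as the four-term entropy combination

$$TE_{X \to Y} = H(y_n, V^Y) - H(V^Y) - H(y_n, V) + H(V).$$

TE is directed and model-free; it captures linear and nonlinear coupling
alike. Its classical limitation is that it is a single global number. The
*lagged* variant computed here shifts the target series by $\tau$ samples —
the design pairs the target sample $y_{n-\tau}$ with the source window
$x_{n-1}, \dots, x_{n-L_{max}}$ and the target past
$y_{n-\tau-1}, \dots, y_{n-\tau-L_{max}}$ — and scans $\tau$ over a grid
(default $0..15$). Because the source window stays anchored at the original
time index while the target shifts, source samples with absolute delay
below $\tau$ would lie *after* the target; these anti-causal candidates are
excluded from the pool. The contemporaneous sample (delay exactly $\tau$)
is kept: at $\tau = 1$ it is the source sample aligned with the shifted
target, and it is what carries the instantaneous pathway. Two consequences
follow that the validation study relies on: a coupling at source delay $d$
remains visible only while $\tau + d \le L_{max}$ (deep couplings drop out
of the window as the lag grows), and for $\tau > L_{max}$ no causal source
candidate exists at all, so the transfer is identically zero. Without the
anti-causal exclusion, the reverse direction of a strongly coupled pair
picks up large spurious "transfer" at $\tau \ge 2$ — the source sample
$y_{n-1}$ is then a deterministic function of the very target it is
supposed to predict — and the forward profile never decays to zero. The resulting profile resolves *when* the information
transfer happens: an instantaneous pathway shows up at small lags only, a
slow sustained one stays elevated across lags. In cardiorespiratory
analysis the two directions behave very differently (fast, quickly decaying
RESP→RR transfer versus slower, more stable RR→RESP transfer), which is
what makes the time-scale-resolved view informative about the autonomic
branches driving each pathway.

All series entering the estimator are z-normalized to zero mean and unit
population variance; values are reported in nats.

## Non-uniform embedding

Rather than a fixed uniform delay vector, the conditioning vector is built
greedily from the candidate pool
$\Omega = \{X_{n-1},..,X_{n-L_{max}}, Y_{n-1},..,Y_{n-L_{max}}\}$ with
$L_{max} = 10$: at each round the candidate with the largest conditional
mutual information (CMI) gain given the already-accepted candidates is
tested against a permutation null, and the first failure terminates
selection. Only informative past states enter the model, and the selection
*frequencies* across replicates are themselves a readout of the coupling
delays (see `candidate_frequency()`).

### The significance gate

The gate is the one genuinely open design point, and it matters: the tested
gain is the *maximum* over the $m$ remaining candidates, so comparing it to
the permutation null of a single candidate at the nominal level would
accept a spurious candidate in a large fraction of null runs (we measured
roughly 40% at $m = 20$, and still ~20% when the threshold is raised to
the maximum of 100 permuted gains). The package therefore:

1. permutes the winning candidate's column (`n_shuffles = 100` draws,
   shared permutations per round) to build its null gain sample;
2. applies a Šidák correction for the selection maximum — the per-candidate
   level is $\alpha_c = 1 - (1-\alpha)^{1/m}$;
3. evaluates that level on a moment fit of the null with a Cornish–Fisher
   skewness adjustment, because $\alpha_c \approx 0.0026$ cannot be
   resolved by the empirical quantiles of 100 draws and the null is mildly
   right-skewed.

With this gate the family-wise false-selection rate per round sits at its
nominal $\alpha = 0.05$ (the test suite checks that independent white-noise
pairs yield an empty embedding in well over 90% of runs and that false
source selections stay within the binomial envelope of $\alpha$). The
uncorrected per-candidate percentile gate remains available as
`selection_policy(gate = "percentile")` for comparison. Ties in the greedy
argmax resolve deterministically to the lowest delay, source before target.

## Nearest-neighbor estimation

All entropies are estimated with the Kozachenko–Leonenko nearest-neighbor
construction under the max-coordinate (Chebyshev) metric with digamma bias
correction; the CMI uses shared joint-space radii (the Frenzel–Pompe
construction), so the four entropy terms above combine to exactly the
pointwise digamma estimate — the decomposition identity holds to machine
precision, not merely asymptotically. Defaults: $k = 10$ neighbors,
exposed in `run_config()`. Raw CMI estimates can be slightly negative;
reported TE values are clipped at zero with the raw value retained.

Because the metric is a max over coordinates, tied distances would break
the neighbor-count logic; every entry point therefore adds a deterministic
jitter of amplitude $10^{-10}$ times the sample SD, derived from the run
seed, before any neighbor query.

## Surrogate significance

Each TE value is tested against `n_surrogates = 100` time-shift surrogates:
the source series is circularly shifted by an integer drawn uniformly from
$[1, \text{max\_shift} = 20]$ (forward only, with replacement), the
embedding selected on the original data is reused, and the observed raw TE
must exceed the empirical 95th percentile of the surrogate distribution
(strict inequality, no interpolation). Shifting only the source destroys
the directed alignment while preserving both marginals. With a fixed
embedding the observed statistic is exchangeable with its surrogates under
independence, so the test is exactly calibrated; re-selection bias is
deliberately excluded from the surrogate loop (selection is *not* re-run
per surrogate, which would also be computationally prohibitive).

## The validation system

The built-in generator realizes the coupled pair

$$X_n = a_1 X_{n-1} + a_2 X_{n-2} + 0.07\, Y_{n-1} + U_n, \qquad
  Y_n = C_1 X_{n-1} + C_2 X_{n-2} + C_3 X_{n-5} + V_n,$$

with unit-variance white noises: a strong, lasting $X \to Y$ coupling at
delays 1, 2 and 5 against a weak, transient $Y \to X$ coupling. $X$ is an
AR(2) stochastic oscillator; `ar_oscillator_coeffs(f = 0.1, rho = 0.95)`
places its complex pole pair at normalized frequency 0.1 with modulus 0.95,
giving $(a_1, a_2) = (1.5371, -0.9025)$. The cross-coupling strengths
$C_1 = C_2 = C_3 = 0.5$ were fixed once to realize the designed
strong/weak asymmetry against the printed 0.07 reverse coupling; all of
them are exposed in `ar_sim_spec()`. A 1,000-sample burn-in removes the
transient, and stationarity is enforced by checking the companion-matrix
spectral radius before generation.

The validation study runs 100 seeded replicates of $N = 300$ samples and
computes the lag profile for both directions. The expected signature, which
the test suite asserts, is stepwise: with $L_{max} = 10$, the delay-5
coupling leaves the candidate window when $\tau$ passes 5→6, the delay-2
coupling at 8→9, and the delay-1 coupling at 9→10, after which
$TE_{X \to Y}$ is indistinguishable from zero; $TE_{Y \to X}$ stays low and
flat throughout. A one-way ANOVA of TE against the 16-level lag factor
summarizes the lag effect per direction, with Bonferroni-adjusted pairwise
lag comparisons. Whether every pair inside the 6–10 transition block
separates at the adjusted level depends on the exact coupling strengths,
which the source of the design leaves open; the block boundaries (0–5
versus 6–15, 11–15 versus 0–10) are the robust part of the pattern.

## The synthetic cardiorespiratory generator

Real neonatal recordings are not redistributable, so end-to-end tests run
on `simulate_physio()`: R-peak event times whose inter-beat (RR) intervals
follow `mean_rr + rsa_gain * resp(t) + AR(1) noise`, and a 200 Hz
respiration waveform — a sinusoidal oscillator with alternating sleep-state
bouts (quiet-sleep bouts breathe at 85%, active-sleep bouts at 115% of the
baseline rate), slow bounded rate wander and additive noise. Defaults:
10-minute records, mean RR 0.45 s (inside the neonatal acceptance range
0.3–0.667 s), baseline breathing rate 0.8 Hz (respiratory period inside
0.5–2.5 s), RSA gain 0.01 s per unit respiration amplitude. The RSA gain
is sized so that clean beat-to-beat changes stay safely below the 10%
artifact rule — the generator's ground truth must round-trip exactly
through the artifact filter — while still leaving a clear spectral
signature of respiration in the RR series. Out-of-range artifact beats
(0.75 s) can be injected at known, isolated indices and are returned as
ground truth.

What the generator does *not* emulate: real R-peak detection error,
amplitude artifacts in the respiration belt signal, apneas and periodic
breathing, non-stationary state transitions inside a bout, or any
gestational-age physiology. Passing tests on this generator therefore
demonstrate the correctness of the pipeline's bookkeeping and the
calibration of its statistics, not clinical validity on real recordings.

## Preprocessing rules

* `RR(n)` is the interval from the n-th R peak to the next; the
  beat-aligned respiration series interpolates the band-passed waveform
  (zero-phase order-4 Butterworth, 0.05–3.5 Hz) linearly at each R-peak
  onset — respiration at 200 Hz is heavily oversampled relative to its
  band, so linear interpolation is adequate.
* Artifact rules: RR accepted in 0.3–0.667 s with at most 10% change
  against the previous *accepted* beat (so one outlier does not cascade);
  respiratory *cycle durations* (successive upward zero crossings of the
  filtered signal) accepted in 0.5–2.5 s with at most 40% change; a
  rejected cycle flags every beat inside it. The duration thresholds are
  stated in seconds, which can only refer to cycle durations, not belt
  amplitude.
* Segments: within each sleep-state bout, consecutive non-overlapping
  300-beat windows, earliest first; windows with more than 5% flagged
  samples are discarded whole (no beat editing or imputation); each
  emitted channel is z-normalized with the population (divide-by-n) SD.
* `breathing_rate()` takes the periodogram peak in 0.2–2.0 Hz over at
  least 60 s of signal and requires the peak to exceed 15 times the median
  in-band power — white noise produces peak-to-median ratios around 7–10,
  a genuine respiratory rhythm orders of magnitude more, so the rule
  cleanly separates "no dominant rhythm" from a usable estimate.

## Statistical designs

`validation_experiment()` implements the lag ANOVA described above.
`cohort_model()` fits the cohort-style design — TE against categorical lag,
group and their interaction with sex, mode of delivery and hours of life as
covariates — with Type-II sums of squares (`car::Anova`) and
Bonferroni-adjusted pairwise group contrasts on estimated marginal means
(`emmeans`). `sobel_mediation()` runs the three-regression mediation with
the Sobel z and reports the proportion mediated $(c - c')/c$. The synthetic
cohort generator (`simulate_cohort_table()`) injects known group shifts,
lag profiles and interactions so that recovery, null calibration and
interaction specificity can all be tested; multiple segments per subject
are treated as independent units, mirroring the analysis design this
reproduces — a known limitation, documented rather than corrected here.

## Reproducibility and problem sizes

One master seed expands into named substreams (`derive_seed()`) for
simulation noise, jitter, gate permutations and surrogate shifts, so every
result is bit-reproducible and adding one component never perturbs
another's stream. Selection is exact brute-force $O(n^2)$ per CMI
evaluation, which is the right trade-off at segment scale ($n \approx
300$); the package refuses selection on series beyond a few thousand
samples. The shipped analyses use 100 replicates for the validation study,
200 runs for the null-calibration checks, and $n = 10^4$ samples for
estimator-against-oracle comparisons — sizes at which the estimator
tolerances quoted in the tests (0.02–0.05 nats) hold comfortably.

## Known limitations

* Bivariate only: no multivariate conditioning on a third process, and no
  partial/conditional TE.
* The kNN estimator's neighbor count $k$, metric and bias correction are
  defensible defaults, not values fixed by the underlying study design;
  they are exposed in the configuration.
* Surrogate shifts are forward-only; backward shifts would be an equally
  valid null.
* Real-cohort quantities (group contrasts, mediation percentages) depend on
  data that cannot be shipped; the package reproduces those designs in
  form and verifies them on synthetic cohorts only.
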