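---
title: "Models and methods behind cas9smfret"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind cas9smfret}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cas9smfret)
```

# The kinetic model

The package analyses (and simulates) single-molecule FRET recordings of
Cas9 ribonucleoprotein (Cas9-RNA) binding to surface-immobilized DNA
targets. The generative model is a three-state continuous-time Markov
chain:

* `U` — unbound DNA, zero FRET;
* `S` — the *sampling* mode, a transient, sequence-nonspecific contact in
  which Cas9-RNA surveys the DNA for a PAM (mid FRET, mean 0.42);
* `H` — the RNA-DNA heteroduplex (R-loop) formed after PAM recognition
  (high FRET, mean 0.92).

Binding `U -> S` is bimolecular: its rate constant is in per molar per
second and is multiplied by the Cas9-RNA concentration (entries flagged
`conc_scaled` in a [kinetic_scheme()]). All other steps are first order.
The default scheme is strictly two-step (`U -> S -> H`); a direct `U -> H`
entry is representable (the rate matrix has the slot) so the one-step
hypothesis can be explored without code changes, but no preset uses it:
at 0.1 s frames a one-step and a two-step entry with a ~0.1 s intermediate
are experimentally indistinguishable, and the two-step scheme is the
mechanistically motivated choice.

Photobleaching is a single exponential clock per molecule, independent of
the state path, that silences both channels when it fires. This matches
how bleaching enters the analysis — as trace truncation — and deliberately
does not distinguish donor from acceptor loss; either ends the FRET
observable, and nothing downstream depends on which dye died.

## Target presets

Each DNA target (`cognate`, `x–y_mm` for a contiguous mismatch from
position `x` to `y` counted from the PAM, `no_PAM`, ...) is a
[target_preset()] wrapping a scheme. The preset values live in
`inst/extdata/target_presets.json` and encode literature-derived
single-molecule measurements of SpCas9:

* association: 6×10⁶ M⁻¹ s⁻¹ into the sampling mode for every target with
  a PAM, reduced (3×10⁶) without one;
* sampling-mode lifetime 0.1 s for every target — PAM surveillance does
  not read the protospacer;
* amplitude-weighted bound lifetimes of ~0.5 s (`5-20_mm`), ~8 s
  (`8-20_mm`) and ~16 s (`9-20_mm`), photobleach-limited (bound lifetime
  set to 1800 s against a 180 s bleach lifetime) for targets with nine or
  more PAM-proximal matches;
* roadblock targets (`9-12_mm`, `5-8_mm`) share the kinetics of their
  `x-20_mm` counterparts — dissociation is set by where heteroduplex
  extension stops, not by what lies beyond it.

Two scheme parameters are not printed in the source measurements and were
fixed once, before any recovery test was run: the branching fraction of
the sampling mode into the heteroduplex (`p_extend = 0.8` for targets
with a PAM and an extendable seed) and, per target, the heteroduplex exit
rate `k_HU`, chosen so that the mean bound dwell
`E = sampling_lifetime + p_extend / k_HU` equals the measured
amplitude-weighted lifetime exactly (for a survival curve
`A1*exp(-t/tau1) + A2*exp(-t/tau2)` with `A1 + A2 = 1`, the
amplitude-weighted lifetime *is* the distribution mean, so matching means
is matching the measurand). A high branching fraction is what makes
cognate binding look single-step at 0.1 s resolution — most sampling
dwells convert before a frame elapses. For `1-2_mm` the branching
fraction is 0.001 with a long-lived heteroduplex: seed mismatches almost
always abort R-loop extension, but the rare complete heteroduplex is
stable, which reproduces both the collapsed bound fraction and the
photobleach-limited high-state lifetime reported for that target.

## Emission model

Frames integrate the path: the true FRET of a frame is the
occupancy-time-weighted average of the state means over the frame (a
state visited for half a 0.1 s frame at FRET 0.92 contributes 0.46), so
dwells near the frame interval are blurred exactly as a camera blurs
them. Donor and acceptor counts are

```
donor    = I_tot * (1 - F) * f_emit + bg_D + noise
acceptor = I_tot * F * f_emit + leak * donor_signal + bg_A + noise
```

with `f_emit` the pre-bleach fraction of the frame. Defaults
(`total_intensity = 500`, `noise sd = 30` per channel, backgrounds 50,
`leakage = 0.07`, `frame_interval = 0.1 s`) give FRET clusters separable
but overlapping — a realistic TIRF regime, and the regime in which all
recovery tests must pass. The noise is Gaussian and state-independent;
dye photophysics (blinking, protein-induced enhancement) and
intra-dwell FRET diffusion are out of scope.

# Trace correction and histograms

`correct_trace()` inverts the emission model:
`I_D = raw_D - bg_D`, `I_A = raw_A - bg_A - leak * I_D`, and
`FRET = I_A / (I_D + I_A)`, clamped to `[-0.2, 1.2]` rather than `[0, 1]`
so noise-driven excursions stay visible in histograms (the clamp is
config-exposed). Backgrounds and leakage come from the dataset manifest
when analysing synthetic data; no automatic estimation from post-bleach
frames is attempted. Photobleaching is detected from the *total*
corrected intensity (either dye's loss ends the observable): the trace is
median-smoothed and the bleach frame is the start of the terminal run
below 30% of the trace's high quantile; traces dark from the start
resolve to frame 0 and constant traces to their final frame.

Histograms pool the first five valid (pre-bleach) frames per molecule
(ten as the alternate convention) in 0.05-wide bins, and the bound
fraction is the proportion of pooled points with FRET above 0.75. Frames
invalidated by bleaching inside the first five are excluded — the
convention is not stated in the source analyses; exclusion is this
package's choice and is applied consistently.

# HMM idealization

`fit_hmm()` fits a three-state Gaussian-emission hidden Markov model by
EM (initial means 0, 0.42, 0.92; stop at a log-likelihood improvement
below 1e-6 or 500 iterations), Viterbi-decodes the state path, and
relabels states in ascending mean order. Exact Viterbi ties go to the
lower state index so output is deterministic. Emission means are free by
default; `fix_means = TRUE` anchors them, a switch provided because the
source analyses do not say whether means were refined. Unoccupied states
are legal and flagged (`degenerate`), not an error.

Three methodological points deserve explanation.

**Pooled fits.** `fit_hmm_pooled()` shares one parameter set across all
molecules (per-trace E-step, pooled M-step) and then decodes each trace.
Per-molecule fits honor the aggregation rule for transition
probabilities, but they degenerate on weak-binding traces that contain
only a handful of sampling events: a three-state fit to ~10 informative
frames collapses its spare states onto single noisy frames. The pipeline
therefore uses pooled fits for idealization and state-mean estimation,
and per-molecule fits remain available where traces are information-rich.

**Tied variances.** By default the pooled fit shares one emission
standard deviation across states (`tie_sds = TRUE`). The detection noise
of the two-channel readout is state-independent, so homoscedastic
emissions match the generative physics; more importantly, with free
variances a state can inflate its variance to absorb camera-blurred
transition frames, which drags its mean toward the blur continuum and
pushes Viterbi boundaries far from the state midpoints. With tied
variances the decision boundaries sit near the midpoints between state
means — equivalent to majority-occupancy classification of blurred
frames, which is the least biased frame-labeling rule available at this
time resolution.

**Interior means.** Frames that straddle a transition average two states
and bias a state's fitted mean toward the neighbouring level; for states
visited in dwells of one or two frames (the sampling mode) the bias is
substantial. The fits therefore also report `means_interior`: state
means recomputed from dwell-interior frames only (first and last frame
of every decoded dwell dropped). Interior frames are fully occupied by
construction, so this estimator recovers the emission mean where the raw
EM mean reports the blurred value. The pipeline reports interior means
as the state-mean estimates.

Transition-probability aggregation follows the stated rule: the mean
probability for a state pair is the geometric mean, `exp(mean(log T_p))`,
over trajectories with a positive entry for that pair; zeros are excluded
from the log-mean and counted separately (the rule is silent on zeros),
and the rate is the mean probability times the sampling rate (10 s⁻¹ at
0.1 s frames). Note the `T_p × rate` conversion is a small-probability
approximation: for exit probabilities approaching 1 it saturates at the
sampling rate, which is why state *lifetimes* in this package come from
dwell-time fits rather than from converted transition probabilities.

# Dwell-time and survival analysis

`extract_dwells()` merges mid and high FRET into a single *bound* class
(threshold 0.2), the convention used for bound-state survival analysis,
and also emits per-state (`mid`, `high`) dwells with their exit
destinations. A dwell ended by the observation boundary (trace end or
detected bleach) is right-censored and carries no destination state. The
first run of a trace ends in an observed transition and is therefore not
right-censored; it is flagged `first_run` instead so steady-state
analyses can drop it, while flow-in experiments — where the first unbound
dwell genuinely starts at time zero — keep it.

`fit_survival()` fits exponential models to dwell durations by maximum
likelihood rather than least squares on the empirical survival curve:
MLE handles censoring principledly and uses every dwell. Durations are
integer frame counts, so the default analyses use the frame-quantized
likelihood (`discrete = TRUE`): each exponential component becomes a
geometric law with per-frame survival `exp(-dt/tau)`. For dwells much
longer than a frame this coincides with the continuous likelihood; for
dwells of a few frames it removes an up-to-half-frame upward bias. This
is the exact likelihood for quantized data, not a missed-event
correction — dwells shorter than one frame remain unrepresentable and no
blur correction is applied. Model choice (`auto`) takes the
double-exponential mixture when it improves BIC by at least 6, a
conventional strong-evidence threshold chosen because the source
analyses report the outcome (double for bound dwells, single for
unbound) but not a criterion.

## Photobleaching: two equivalent corrections, never stacked

Bleaching truncates dwells. Two routes are implemented:

1. `censoring = "mle"`: bleach-truncated dwells enter the likelihood as
   survival contributions. Nothing is subtracted afterwards.
2. `censoring = "observed"`: every duration is treated as an event, and
   the bleach rate (fitted from the detected bleach times of the same
   dataset, censoring-aware) is subtracted from the fitted rate:
   `k_actual = k_observed - k_photobleach`, floored at zero with a flag.
   Because the bleach clock is exponential and memoryless, each observed
   dwell is the minimum of the true dwell and an exponential bleach time,
   so `k_observed = k_true + k_photobleach` holds exactly and the
   subtraction is the correct inverse — this is the classical correction
   arithmetic, reproduced as stated.

The two routes estimate the same quantity and a test verifies they agree;
the pipeline uses route 2 for bound-state lifetimes. They must not be
combined: subtracting the bleach rate from a censoring-aware fit removes
the bleach hazard twice and overestimates lifetimes by roughly
`k_photobleach / k_true`.

Association kinetics: unbound-dwell decay rates are fitted per
concentration and `estimate_kon()` takes the weighted least-squares slope
through the origin (zero binding at zero concentration; an
intercept-allowed variant is available as a diagnostic). With a single
concentration the slope reduces to `rate / concentration`.

# Dataset initialization

`simulate_state_path()` starts in `U`. `generate_dataset()` adds two
experiment-level modes: `"flow_in"` (all molecules start unbound —
association measurements, where Cas9-RNA enters the chamber as
acquisition starts) and `"equilibrium"` (each molecule's initial state is
drawn from the occupancy after a 600 s pre-imaging incubation, computed
by matrix exponential of the generator). A 10-minute incubation is a
typical bench protocol; true stationarity is deliberately not used
because slowly accumulating targets (e.g. `1-2_mm`, whose heteroduplex is
stable but almost never forms) would otherwise reach unrealistically
high bound fractions.

One tension in the encoded values is worth recording: with association
at 6×10⁶ M⁻¹ s⁻¹ and a 16 s bound lifetime, the equilibrium bound
fraction of `9-20_mm` at 20 nM is ~0.65, visibly below the cognate
plateau, whereas the source measurements report indistinguishable bound
fractions through 12 distal mismatches. Both numbers cannot hold at
simple two-state equilibrium; the package keeps the kinetic values (they
are the quantities under test) and the qualitative bound-fraction
profile — plateau for distal mismatches, collapse for seed mismatches —
is what the acceptance checks assert.

# What passing tests do and do not show

The simulator emulates: exponential state dwells from the configured
rates, concentration-scaled binding, camera integration at 0.1 s,
Gaussian channel noise, leakage, backgrounds and exponential bleaching.
It does not emulate dye blinking, intensity heterogeneity between
molecules, baseline drift, multi-step bleaching, spatial/optical
artifacts, or non-exponential (multi-state) dissociation within a
target. Parameter recovery on these simulations therefore validates the
estimator chain — correction, idealization, dwell statistics,
censoring/bleach handling — under the stated noise model; it does not
certify performance on real recordings with artifacts outside that
model.

Known resolution limits, visible in the recovery tolerances: sampling
dwells (~1 frame) are measured with a positive bias of a few tens of
percent even with the discrete likelihood, because thresholded/decoded
run lengths are extended by blurred edge frames — hence the wide (30%)
tolerance on the sampling lifetime, mirroring its resolution-limited
status. Sub-half-frame bound dwells are invisible, which slightly
depletes the short component of bound-dwell mixtures and biases
amplitude-weighted lifetimes of strongly two-component targets upward by
up to ~10%; the real measurement shares this limit.

# Problem sizes

Acceptance recomputations use 200–500 molecules per target with trace
lengths of 60–600 s at 0.1 s frames (the trace length is matched to the
lifetime being measured: ~25 bound-dwell lifetimes or ~3 bleach
lifetimes per trace). The test suite uses the same generator at
somewhat smaller sizes chosen so that sampling error stays well inside
each stated tolerance. All randomness is seeded; datasets are
byte-reproducible given the seed.
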