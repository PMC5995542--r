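---
title: "Models and methods behind termfret"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind termfret}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(termfret)
```

## The measurement this package models

Bacterial translation termination is driven by release factors: RF1 and RF2
hydrolyze the peptidyl-tRNA at stop codons, and the GTPase RF3 recycles
them. Single-molecule FRET on surface-immobilized ribosome termination
complexes reports two kinds of signal:

* **Conformational dye pairs** (small-subunit S6 vs large-subunit L9 for
  subunit rotation; P-site tRNA vs protein L1 for the L1 stalk) fluoresce
  continuously and hop between discrete FRET levels — about 0.73 for the
  non-rotated (N) and 0.52 for the rotated (R) ribosome, and 0.32 (open) /
  0.74 (closed) for the L1–tRNA pair.
* **Binding dye pairs** (a Cy5-labelled factor against Cy3-labelled L11)
  show FRET only while the factor is bound; binding events appear and
  disappear, and the exponential rate of event durations is the factor's
  dissociation rate, bounded from above by dye photobleaching.

Two-channel traces are recorded at 30 frames/s. The analysis chain is:
trace quality control and bleed-through correction, hidden-Markov
idealization of the FRET series, Gaussian-mixture population analysis,
dwell-time kinetics with censoring, and post-synchronized density maps.
No public trace data accompany the measurements this models, so the package
carries a simulator whose named scenarios encode the published state means
and rate constants as ground truth: every stage of the pipeline is then
validated by parameter recovery, which is also what the test suite does.

## The simulator (and what it deliberately leaves out)

`sample_state_path()` draws exact continuous-time Markov paths (Gillespie:
exponential sojourns at the state's total exit rate, next state
proportional to the outgoing rates). `render_trace()` integrates the state
path over each camera frame *exactly*, so frames spanning a transition
carry the occupancy-weighted mean FRET — the averaging blur a real camera
produces and the idealization must tolerate. Emission is then

```
donor    = I_tot (1 - E) + bg_D + noise
acceptor = I_tot E + beta I_tot (1 - E) + bg_A + noise
```

with Gaussian channel noise, bleed-through `beta = 0.13`, and independent
exponential single-step photobleaching of each dye. After acceptor bleach
the full intensity returns to the donor; after donor bleach both channels
fall to background. Dark states (unbound factor) emit `E = 0`.

Defaults: `I_tot = 1000` counts/frame and channel noise 70 counts/frame,
chosen so the per-state FRET spread is about 0.05, matching the Gaussian
widths of the published histograms; dye-pair bleach rate 0.1 1/s (donor and
acceptor 0.05 each), inside the experimentally reported 0.07–0.19 1/s;
traces 20 s at 30 frames/s.

Not modelled: Poisson shot noise and EMCCD gain statistics, triplet
blinking, baseline drift, spot detection from raw movies. Passing recovery
tests therefore demonstrates correctness of the estimators under Gaussian
noise and ideal backgrounds, not robustness to every artifact of real
recordings.

Where a rate is not an experimentally printed quantity the fixture value is
a documented design choice (flagged in `scenario_fixture()$design_values`):
the PreHC baseline exchange (0.1 / 0.4 1/s, giving the observed N-dominant
slow exchange; a symmetric 0.1/0.1 choice would contradict N dominance),
the PostHC exchange (1.0 / 1.5 1/s inside the reported 0.5–2.6 band),
`k_N_to_R = 4.4` for the RF3-bound PreHC (making R dominant at 2/3),
`k_open_to_closed = 2.0` for the L1 pair, and `k_on = 0.5 1/s` for all
binding scenarios (events well separated at 10 nM-like conditions). These
were fixed once, before any recovery measurement, and are not tuned.

## Trace quality control

`select_traces()` applies the standard selection rules: Pearson
correlation of the smoothed channels over the pre-bleach window below 0.1
(anticorrelated or static traces pass — static RF1 traces are analyzable
on purpose), a single photobleaching step per channel, and pre-bleach
total intensity within 0.5–1.5 times the set median (rejecting
multi-fluorophore aggregates). The step detector is a penalized
least-squares changepoint segmentation (binary segmentation, SIC-type
penalty `10 sigma^2 log T` with `sigma` from the median absolute
first difference). A downward step counts as a bleach step only if the
drop is at least 40% of the pre-step level, the signal never recovers, the
trace ultimately decays to the bleached floor, and the pre-step level
itself stands clear of that floor — so reversible FRET transitions and the
loss of residual bleed-through at a later donor bleach are not counted,
while the staircase of a two-dye aggregate counts twice.

Bleed-through is calibrated by `estimate_bleedthrough()` as the median of
`acceptor/donor` over frames where the acceptor has bleached but the donor
is alive — the only frames where the acceptor channel contains nothing but
bleed-through.

For binding experiments the acceptor arrives and leaves with the factor,
so only the donor channel is scanned for bleach steps and only donor
bleach masks the trace; the loss of a bound factor's acceptor dye is
physically indistinguishable from dissociation and is handled in the
kinetics instead (below).

## Idealization

`fit_hmm()` is a Gaussian-emission HMM fitted by EM with quantile-based
deterministic initialization plus seeded restarts; convergence at relative
log-likelihood change `1e-6`, 200 iterations cap, best of 4 starts;
emission sds floored at `1e-3`. `select_K()` chooses the state number by
BIC. `viterbi_decode()` returns the MAP path with ties broken toward the
lower-mean state (tested against exhaustive path enumeration for short
traces). The variational-Bayes machinery some smFRET packages use is
intentionally not reproduced: downstream analysis consumes only the
idealized paths, and maximum-likelihood EM plus explicit BIC model
selection exposes the same surface with fewer moving parts.

One deliberate deviation from common practice: although all series are
smoothed over three points for selection, histograms and display, the HMM
runs on *unsmoothed* FRET. The moving average correlates noise across
frames and hides one-to-two-frame dwells; on simulated truth this inflates
dwell times by 15–25% at the rates of interest. Unsmoothed decoding with
the dead-time correction below recovers rates to within a few percent.

Before kinetics, `exclude_for_kinetics()` applies the exclusion rules:
states whose fitted means differ by less than 0.1 FRET are merged
(occupancy-weighted, idempotent), and traces with at most one surviving
transition are excluded from kinetics while remaining in the population
histograms. The ambiguous reading of this rule (merge sub-0.1 states vs
drop sub-0.1 transitions) is resolved as merging; both thresholds are
configurable. Binding scenarios use a one-transition eligibility threshold
instead: a single binding event is a valid residence-time observation.

## Dwell-time kinetics

`fit_dwell_exponential()` fits one or two exponentials by maximum
likelihood. Right-censored dwells (ended by photobleaching or the end of
the recording) contribute survival terms; left-censored first dwells are
dropped. All terms are conditioned on the dwell exceeding the minimum
detectable dwell `t_min` (one frame), giving the closed form
`k = n_uncensored / sum(d - t_min)` for a single component. The
censoring-aware fit is verified against `survival::survreg` and shown
unbiased where the naive mean-of-uncensored is ~25% off.

Frame sampling introduces a second, subtler bias: sojourns shorter than
about one frame are not just truncated, they are *missed*, and a missed
excursion merges the two flanking dwells of the partner state. The
first-order dead-time correction (`correct_missed_events()`) inverts this:
with dead time `theta`, a partner sojourn is missed with probability
`q = 1 - exp(-k_partner theta)`, each observed dwell contains
`m = q/(1-q)` merged interruptions on average, so
`1/k_raw = (1+m)/k + m E[tau_partner | tau < theta]`; the two-state system
is solved by fixed-point iteration. With `theta` equal to one frame this
recovers simulated exit rates to within about 3% across the regimes the
scenarios span (1–6 1/s at 30 frames/s), where the uncorrected estimates
are up to 20% low. The calibration target here is generator truth, never a
published number.

Two-exponential fits on frame-quantized dwells have a lattice degeneracy
(an unbounded-rate spike component can absorb the one-frame dwells), so
mixture rates are capped at `0.8/t_min` and a biphasic call additionally
requires both fractions at least 0.05 and a rate ratio of at least 2.

**Biphasic populations.** When dwell distributions are biphasic, the
quantity of interest is the fraction of *molecules* in the fast class, not
the fraction of dwells — fast molecules contribute several-fold more
dwells, so pooled amplitudes overshoot (about 0.9 where the molecule
fraction is 0.7). `fit_dwell_mixture_traces()` therefore runs a two-level
EM in which whole traces carry the class and dwells within a trace share
one rate. The pipeline goes one step further with
`fit_dwell_mixture_joint()`: a molecule's class governs the exit rates of
*both* states, so both states' dwells contribute classification evidence;
this cuts the misclassification of slow molecules with few dwells from
~30% to a few percent and brings the recovered fraction within a few
hundredths of truth. The residual upward drift (~0.03) comes from the
eligibility rule, which removes slightly more slow than fast traces.

**Photobleaching and binding.** In a binding trace, dissociation, acceptor
bleach and donor bleach all end the FRET event indistinguishably, so bound
dwells are censored only when the trace ends unbleached, and the observed
decay is `k_obs = k_off + k_bleach(pair)`. `estimate_photobleach_rate()`
calibrates the pair bleach rate from non-fluctuating traces (signal
duration to the first bleach step of either dye, censoring-aware), and
`correct_koff()` subtracts it with propagated uncertainty. When `k_obs`
lies within two standard deviations of the bleach rate no point estimate
is resolvable and an upper bound at the detection limit (0.2 1/s by
default) is reported — this is how the slow RF1 dissociation is handled.
Both corrected and uncorrected values appear in the rate table. The
association rate `k_on` is reported uncorrected and is biased low whenever
the acceptor bleaches mid-trace (subsequent dark time is unobservable);
it backs no reported result.

## Populations and density maps

`fit_gmm()` fits Gaussian mixtures by EM on the raw pooled values
(quantile initialization, seeded restarts, components sorted by mean), so
the reported populations are independent of any histogram bin width; a
binned least-squares mode exists for fidelity and agrees on clean data
(display bins are 0.02 FRET units on [-0.1, 1.1]). Conformational
scenarios pool all unmasked frames of the *smoothed* series — smoothing
narrows the state peaks from ~0.05 to ~0.03 and stabilizes the minor
component. Binding scenarios pool the first 10–30 frames (default 20)
after synchronization to the FRET event start, restricted to frames
decoded as bound and eroded by one frame at segment edges, because frames
spanning the binding or release event blend with the dark level.

`density_map()` compiles aligned traces into per-frame FRET probability
columns; each populated column is normalized over the traces contributing
at that time (survivor normalization — a deliberate choice, the
alternative whole-set normalization would make columns decay with
photobleaching), which is what the column-sum invariant tests. Alignment
modes: start of the FRET event (binding), first transition into a target
state, and first high-to-low transition (N-to-R rotation).

## The pipeline and replicates

`run_pipeline()` chains the stages per scenario over three independently
seeded replicate simulations — the stand-in for three independent
experimental datasets — and reports every quantity as mean ± sample sd
across replicates (`aggregate_replicates()`; any detection-limit bound
among replicates makes the aggregate a bound, using the largest limit so
the bound holds for every replicate). Everything derives deterministically
from one configuration seed via a counter. Default problem sizes (300
traces x 3 replicates x 20 s) were chosen as the desk-scale regime in
which the recovery tolerances of the test suite (2% on FRET means, 15% on
rates) sit several standard errors away from the estimator noise.

## Known limitations

* The dead-time correction is first order; at rates approaching a third of
  the frame rate it under-corrects and a shorter frame time (or an HMM
  with explicit missed-event likelihood) would be needed.
* The Gaussian channel-noise model understates the heavy tails of real
  EMCCD data; QC thresholds may need retuning on real traces.
* `k_on` estimates are systematically low in binding scenarios whenever
  the acceptor bleaches mid-trace (see above).
* Population weights (areas) for strongly overlapping components absorb
  frame-averaged transition density and carry a few-percent bias in
  fast-exchange scenarios; the component means are unaffected.
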