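# termfret

Simulation and kinetic analysis of single-molecule FRET (smFRET) traces
from bacterial ribosome **translation termination** complexes.

During termination, release factors RF1/RF2 hydrolyze the peptidyl-tRNA and
the GTPase RF3 recycles them, while the ribosome fluctuates between its
non-rotated (N) and rotated (R) conformations. TIRF smFRET experiments
follow this with two kinds of dye pairs recorded at 30 frames/s:

* **conformational pairs** (S6/L9 for subunit rotation, L1/tRNA for the L1
  stalk) hop between discrete FRET levels (N ≈ 0.73, R ≈ 0.52; closed ≈
  0.74, open ≈ 0.32), and the exponential rates of the state dwell times
  are the conformational rate constants;
* **binding pairs** (Cy5-labelled factor vs Cy3-labelled ribosomal protein
  L11) show FRET only while the factor is bound, so the decay rate of
  event durations is the dissociation rate `k_off`, observable only up to
  the photobleaching ceiling (~0.2 s⁻¹).

`termfret` implements the complete analysis chain for such data, plus a
ground-truth simulator so every estimator is testable by parameter
recovery:

| stage | functions |
|---|---|
| trace simulation (Gillespie CTMC + camera emission model) | `simulate_scenario()`, `sample_state_path()`, `render_trace()` |
| trace QC: anticorrelation, bleach-step counting, intensity band, bleed-through | `select_traces()`, `detect_bleach_steps()`, `estimate_bleedthrough()`, `correct_bleedthrough()`, `compute_fret()`, `smooth3()` |
| idealization: Gaussian HMM + Viterbi, exclusion rules, dwell tables | `fit_hmm()`, `select_K()`, `viterbi_decode()`, `exclude_for_kinetics()`, `extract_dwells()` |
| FRET populations: Gaussian mixtures, dynamic-trace fraction | `fit_gmm()`, `collect_fret_samples()`, `dynamic_fraction()` |
| dwell kinetics: censored/truncated exponential MLE, dead-time correction, biphasic trace-level mixtures, photobleach correction | `fit_dwell_exponential()`, `select_exp_model()`, `correct_missed_events()`, `fit_dwell_mixture_joint()`, `estimate_photobleach_rate()`, `correct_koff()`, `aggregate_replicates()` |
| synchronized contour plots | `synchronize_traces()`, `density_map()` |
| orchestration over replicate datasets | `run_pipeline()`, `validate_config()` |

The dwell-time likelihood handles right-censoring (photobleaching, trace
end), a one-frame minimum-detectable-dwell truncation, and a first-order
missed-event (dead time) correction for sub-frame sojourns: for a dwell in
state A interrupted by state B,
`1/k_raw = (1 + m)/k_A + m·E[τ_B | τ_B < θ]` with
`m = q/(1−q)`, `q = 1 − exp(−k_B θ)` and θ = one frame; the two-state
system is solved by fixed-point iteration. Without this correction,
recovered rates are up to 20% low at the rates these complexes exhibit
(1–6 s⁻¹ at 30 frames/s).

## Worked example

Simulate the "RF3–GTP on the pre-hydrolysis complex" scenario (truth:
FRET states 0.52/0.73, `k_R→N` = 2.2 s⁻¹, `k_N→R` = 4.4 s⁻¹) and run the
full pipeline over three replicate datasets:

```r
library(termfret)
res <- run_pipeline(list(scenario = "rf3_prehc_rotation",
                         n_traces = 100, seed = 7))
print(res)
#> Pipeline result for scenario 'rf3_prehc_rotation' (3 replicates x 100 traces)
#>
#> FRET populations (mean over replicates):
#>  component      mean      mean_sd      width         p        p_sd
#>          1 0.5276218 0.0004119309 0.03657596 0.6521848 0.006457383
#>          2 0.7084716 0.0009737716 0.04640626 0.3478152 0.006457383
#>
#> Rate constants:
#>  quantity     mean         sd corrected bound limit n_replicates
#>  k_R_to_N 2.164230 0.02564302     FALSE FALSE    NA            3
#>  k_N_to_R 4.185924 0.02210245     FALSE FALSE    NA            3
#>
#> Dynamic traces: 0.99
```

Reading the output: the two Gaussian components sit at the rotated
(0.528) and non-rotated (0.708) FRET levels with the R state dominant
(p = 0.65, generator truth 2/3); the dwell-time fits recover the
rotation rates within a few percent of the 2.2 / 4.4 s⁻¹ ground truth
(`sd` is the spread over the three replicate datasets); and essentially
every trace is dynamic, as expected for this complex. Available
scenarios: `list_scenarios()`; their ground truth and which values are
design choices: `scenario_fixture("name")`.

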