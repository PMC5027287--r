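# cas9smfret

Kinetic analysis of CRISPR-Cas9 target recognition and rejection from
single-molecule FRET (smFRET) trajectories, paired with a trajectory
simulator so that every stage of the analysis is verifiable by parameter
recovery.

## The problem

Cas9 in complex with its guide RNA (Cas9-RNA) finds a 20-bp DNA target next
to a PAM (5'-NGG-3'). How quickly a correct target is recognized — and an
off-target rejected — is a kinetic question: smFRET reports it directly as
per-frame FRET efficiency between a donor dye on the DNA and an acceptor on
the guide RNA. Trajectories show an unbound state (FRET 0), a transient
sequence-nonspecific *sampling* mode (FRET ≈ 0.42) interpreted as PAM
surveillance, and a stable RNA–DNA heteroduplex (FRET ≈ 0.92). The package
implements the full analysis chain for such recordings:

* **Simulation** — exact Gillespie sampling of a three-state kinetic scheme
  (unbound → sampling → heteroduplex), camera-frame integration at 0.1 s,
  Gaussian channel noise, donor→acceptor leakage, backgrounds and
  exponential photobleaching. Per-target presets encode literature-derived
  SpCas9 kinetics (`cognate`, `9-20_mm`, `5-20_mm`, roadblock targets,
  `no_PAM`, ...).
* **Trace correction** — `FRET = I_A / (I_D + I_A)` from background- and
  leakage-corrected intensities, photobleach detection, FRET histograms and
  the bound fraction (FRET > 0.75 over the first five frames per molecule).
* **HMM idealization** — three-state Gaussian-emission hidden Markov model
  (per-molecule or pooled across molecules), Viterbi decoding, transition
  density plots, and transition rates via
  `k(A→B) = T_p(A→B) × sampling rate`.
* **Dwell kinetics** — bound/unbound dwell extraction (bound = FRET > 0.2,
  mid and high merged), censoring-aware maximum-likelihood survival fits
  (`A1 e^{-t/τ1} + A2 e^{-t/τ2}`), the amplitude-weighted lifetime
  `τ_avg = A1 τ1 + A2 τ2`, photobleach correction
  `k_actual = k_observed − k_photobleach`, and the bimolecular association
  constant `k_on` from the concentration dependence of the unbound decay
  rate.
* **Genome counting** — occurrences of a PAM-plus-seed query (IUPAC `N` as
  wildcard) in any FASTA genome on both strands, against the
  random-sequence expectation `(1/4)^n × L`.

## A worked example

Simulate a target with 16 PAM-distal mismatches (`5-20_mm`, mean bound
lifetime 0.5 s), recover its kinetics, and print the per-target summary:

```r
library(cas9smfret)

rep <- run_pipeline(run_config(presets = "5-20_mm", n_molecules = 120,
                               duration = 120, seed = 6, idealize = FALSE))
rep$summary[, c("target", "bound_fraction", "tau_avg_s", "k_on_M_s")]
#>    target bound_fraction tau_avg_s k_on_M_s
#> 1 5-20_mm     0.05714286 0.5556831  5455761
```

The bound fraction (~0.05) is the equilibrium occupancy of this weak
binder at 20 nM; `tau_avg_s` recovers the preset's 0.5 s bound lifetime
from ~1,000 dwells after photobleach correction; `k_on` recovers the
6×10⁶ M⁻¹s⁻¹ association constant from the unbound-state decay rate. Run
`vignette("cas9-smfret-methods")` for the model, the estimator choices and
their biases at the 0.1 s resolution limit.

Counting a PAM-plus-seed query in a genome:

```r
count_matches("genome.fa", seed_query("GTCACCTCNGG"))
```

A thin command-line wrapper over the same functions ships in
`inst/scripts/cas9smfret.R` (subcommands `simulate`, `count`, `report`).

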