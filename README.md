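# plinet — Phase Lag Index functional networks and spanning-tree topology for EEG

`plinet` builds weighted functional brain networks from multichannel scalp
EEG and quantifies how their topology changes between recording conditions
and differs between groups. It implements the analysis chain used to study
whether sleep deprivation reorganizes the interictal functional network in
children with suspected focal epilepsy — a clinical setting where a routine
EEG and a sleep-deprived EEG (SD-EEG) exist for every subject — and ships a
synthetic coupled-oscillator cohort generator with known ground-truth
coupling topology, so the entire pipeline is testable without any clinical
data.

## The method

1. **Preprocess** — 21-electrode 10-20 montage; Fp1, Fp2, A1, A2 excluded
   (17 network nodes); common average reference; four contiguous epochs of
   4096 samples at 512 Hz; zero-phase Butterworth band-pass per band
   (delta 0.5–4, theta 4–8, alpha 8–13, beta 13–30 Hz).
2. **Connectivity** — the Phase Lag Index between every electrode pair,

   PLI = | ⟨ sign Δφ(t_k) ⟩ |,  Δφ ∈ (−π, π],

   from analytic-signal (Hilbert) phases, averaged over epochs: 1 for a
   perfectly consistent nonzero phase lag, 0 for none — and, by the
   sign(0) = 0 convention, blind to zero-lag (volume-conducted) coupling.
   Plus relative spectral power in five bands (alpha split 8–10 / 10–13 Hz).
3. **Network measures** — weighted clustering coefficient
   C_i = Σ w_ik w_il w_kl / Σ w_ik w_il (segregation) and Dijkstra path
   length on reciprocal weights l_ij = 1/w_ij (integration), each normalized
   by the mean of 50 weight-shuffle surrogate networks.
4. **Spanning tree** — Kruskal's algorithm keeps the N−1 strongest-PLI
   acyclic connections; **leaf number** (degree-1 nodes: 2 for a path, 16
   for a 17-node star) and hop-count **diameter** (bounded by
   m − leaves + 2) summarize tree shape on the path-like ↔ star-like axis,
   with density held identical across subjects by construction.
5. **Statistics** — paired t per group and band; the group × condition
   interaction from the 2×2 repeated-measures design, computed exactly as
   the squared difference-score t with df = (1, n₁ + n₂ − 2); per-band
   Benjamini–Hochberg FDR at q = 0.05; tables for the full cohort and for
   the added-diagnostic-value patient subset with all controls.

See `vignettes/pli-mst-networks.Rmd` for the full methods account,
including the synthetic generator's design and its parameter defaults.

## Worked example

Generate a synthetic cohort in which patients shift toward a path-like
backbone after sleep deprivation while controls shift toward a star-like
one, then run the full pipeline on the alpha band:

```r
library(plinet)

spec <- cohort_spec(n_patients = 8, n_controls = 8, seed = 42)
co   <- generate_cohort(spec)
res  <- run_pipeline(co, out_dir = "demo_out",
                     bands = eeg_bands()["alpha"], power_bands = NULL,
                     n_surrogates = 50, seed = 42)
it <- res$tables$interaction
it[it$scope == "all", c("measure", "band", "statistic", "df1", "df2",
                        "p", "fdr_significant",
                        "mean_diff_patient", "mean_diff_control")]
```

```
                measure  band statistic df1 df2        p fdr_significant
 clustering_coefficient alpha     9.897   1  14 7.15e-03            TRUE
            path_length alpha     0.177   1  14 6.80e-01           FALSE
            leaf_number alpha    85.172   1  14 2.50e-07            TRUE
               diameter alpha    74.599   1  14 5.55e-07            TRUE
 mean_diff_patient mean_diff_control
           -0.0293             0.046
            0.2805             0.226
           -5.3750             5.750
            6.1250            -4.625
```

Reading the leaf-number row: after sleep deprivation patients lose on
average 5.4 leaves (toward a path) while controls gain 5.8 (toward a star);
the interaction F(1, 14) = 85.2 survives the per-band FDR correction, and
the diameter mirrors it with opposite signs — the programmed topology
contrast, recovered from raw simulated signals through filtering, phase
estimation, PLI matrices and tree construction. `demo_out/` also receives
`measures.csv` (one row per subject × condition × band × measure), the
paired and interaction tables as CSV, and `run_log.txt` with the
configuration hash and seeds.

File-based cohorts work the same way: point `run_pipeline()` at a
`manifest.csv` (subject_id, group, condition, file, added_value) whose files
are tab-separated samples × channels ASCII matrices; `make_fixtures(dir)`
writes a small complete example.

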