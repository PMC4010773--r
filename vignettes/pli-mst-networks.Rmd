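---
title: "Phase-lag functional networks and spanning-tree topology: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phase-lag functional networks and spanning-tree topology: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plinet)
```

`plinet` turns multichannel scalp EEG into weighted functional networks and
asks how their topology differs between two groups recorded under two
conditions — the design used clinically when a routine EEG and a
sleep-deprived EEG (SD-EEG) are compared between children with suspected
focal epilepsy and children in whom epilepsy was excluded. This vignette
explains the model behind every stage, the parameters that matter, and the
choices made where the design was genuinely open.

## From samples to networks

**Montage.** Recordings use the 21-electrode international 10-20 layout. The
four most artifact-prone electrodes (Fp1, Fp2, A1, A2 — frontopolar and
ear) are dropped and the remaining 17 channels are re-referenced to their
common average, which `apply_montage()` performs per sample. Seventeen
electrodes are therefore the nodes of every network.

**Epochs.** Four contiguous artifact-free epochs of 4096 samples at 512 Hz
are taken from the start of each recording (`select_epochs()`). A note on
units: 4096 samples at 512 Hz is 8.0 s, although such epochs are often
described as 8.19 s (4096/500); `plinet` treats the *sample count* as
authoritative and derives duration from it — both values are printed by the
record summaries so the discrepancy is never silent.

**Band-pass.** Analysis is per frequency band: delta (0.5–4 Hz), theta
(4–8 Hz), alpha (8–13 Hz), beta (13–30 Hz). `bandpass()` applies a 4th-order
Butterworth forward and backward (`signal::filtfilt`), giving an 8th-order
magnitude response with exactly zero phase. Zero-phase filtering is not
cosmetic here: any frequency-dependent delay would masquerade as a phase lag
and bias the connectivity estimator directly. The half-power points sit at
the band edges, so "in-band" statements in the tests refer to the passband
interior.

## Phase Lag Index

For channels $a, b$ with instantaneous phases $\phi_a(t_k), \phi_b(t_k)$
(arguments of the FFT-based analytic signal, `instantaneous_phase()`):

$$\mathrm{PLI} = \left| \left\langle \mathrm{sign}\,\Delta\phi(t_k)
\right\rangle \right|, \qquad \Delta\phi \in (-\pi, \pi].$$

PLI is 0 when the phase difference is symmetric around $0$ or $\pm\pi$ and 1
when its sign is perfectly consistent; it is blind to signal amplitude and —
by the $\mathrm{sign}(0) = 0$ convention — to exactly zero-lag coupling, the
signature of volume conduction at the scalp. Numerical conventions, all of
which the estimator's value can depend on, are fixed as:

* the phase difference is wrapped to $(-\pi, \pi]$ before taking the sign;
* $\mathrm{sign}(0)$ contributes 0 (excluded mass, not a positive or
  negative vote);
* the analytic signal is distorted near record ends, so
  $\lceil f_s / f_{low} \rceil$ samples per end — capped at 10% of the epoch
  — are excluded from the average (one cycle of the slowest in-band
  component; at 8-s alpha epochs this is 64 of 4096 samples).

`pli_matrix()` computes all pairwise PLIs per epoch and averages the
matrices arithmetically over epochs, yielding the symmetric, zero-diagonal
weight matrix $W$ with $w_{ij} \in [0, 1]$.

**Relative power** (`relative_power()`) uses a Hann-windowed,
50%-overlapping Welch periodogram per epoch and channel; band power over
half-open intervals $[f_1, f_2)$ — delta, theta, alpha1 (8–10), alpha2
(10–13), beta — is divided by power over the 0.5–30 Hz union. The
denominator is configurable because analyses in this literature do not
always state it; with the default, the five fractions tile the total and sum
to 1.

## Classical weighted measures and surrogate normalization

The weighted clustering coefficient of node $i$ is

$$C_i = \frac{\sum_{k \ne l,\, k,l \ne i} w_{ik} w_{il} w_{kl}}
             {\sum_{k \ne l,\, k,l \ne i} w_{ik} w_{il}},$$

evaluated as $\mathrm{diag}(W^3)_i / (s_i^2 - q_i)$ with $s_i = \sum_k
w_{ik}$, $q_i = \sum_k w_{ik}^2$ — an identity the test suite verifies
against the explicit triple sum. Ordered pairs $(k,l)$ and $(l,k)$ are both
counted; the ratio is identical either way. A node with fewer than two
weighted neighbours has an empty sum and gets $C_i = 0$. For 0/1 weights the
formula reduces to the unweighted clustering coefficient.

Path length uses reciprocal weights as edge lengths, $l_{ij} = 1/w_{ij}$
(strong synchronization = short functional distance; $w = 0$ means no edge,
not an overflowing one), Dijkstra shortest paths (via `igraph::distances`,
checked against a Floyd–Warshall oracle), and
$L_i = \frac{1}{N-1}\sum_{j \ne i} d_{ij}$. A disconnected graph is a hard
error naming the stray component: with 17-channel PLI matrices every weight
is almost surely positive, so disconnection signals corrupted input rather
than a value to propagate.

Because both measures depend on the overall weight level, they are
normalized by surrogate networks: each surrogate permutes the upper-triangle
weights at random and mirrors them back (`surrogate_networks()`), preserving
the weight multiset while destroying the topology. The reported quantities
are $C / \langle C_{surr} \rangle$ and $L / \langle L_{surr} \rangle$ over
an ensemble of 50 — an ensemble size at which the batch-to-batch coefficient
of variation of the surrogate means stays well below 1% on 17-node matrices
(the acceptance script measures ≈0.1%). A surrogate whose positive-weight
graph is disconnected is redrawn (bounded retries) because the normalization
needs finite surrogate path lengths; on dense PLI matrices this essentially
never triggers. The cited literature leaves the exact surrogate unclear
(weight shuffle vs degree-preserving rewiring); the weight shuffle is
implemented because it is the construction that preserves exactly what the
normalization divides by — the weight distribution.

## Maximum spanning tree

Comparing weighted graph measures across groups is confounded by network
density; the spanning tree avoids thresholds entirely by keeping, of all
$N-1$-edge loopless subnetworks, the one with the strongest total
connectivity. `maximum_spanning_tree()` runs Kruskal's algorithm on edges
sorted by *descending* PLI, skipping any edge that closes a cycle.
Descending order is deliberate: strong PLI means a strong connection, and
maximizing total PLI is equivalent to the minimum spanning tree under the
reciprocal lengths $1/w$ (cross-checked against `igraph::mst` in the
tests). The result depends only on the weight *order* — any monotone
transform of $W$ yields the same tree — and ties are broken by
lexicographic label pair so degenerate synthetic inputs reproduce exactly.

Two shape measures summarize each 17-node, 16-edge tree
(`tree_measures()`):

* **leaf number** — count of degree-1 nodes; 2 for a path, $m = N - 1$ for
  a star;
* **diameter** — the largest hop distance between any node pair, found by a
  double breadth-first sweep (exact on trees); it satisfies
  $\mathrm{diameter} \le m - \mathrm{leaves} + 2$.

The diameter is counted in hops, not in summed reciprocal weights, because
the bound above — and the path/star limiting values 16 and 2 — only hold
for hop counts. Both measures are also reported normalized by $m$, mapping
them into $(0, 1]$; the alternative normalization $(x - x_{min})/(x_{max} -
x_{min})$ would change the scale but not the sign of any group contrast, so
the simpler convention is used.

A path-like tree (few leaves, long diameter) reflects a chain of locally
linked regions; a star-like tree (many leaves, diameter 2) reflects a
hub-dominated, integrated organization. These are the two ends of the axis
along which the group-by-condition contrast is tested.

## Statistics

Within each group, routine and sleep-deprived values of every measure are
compared per band with a classical paired $t$ (df $= n - 1$). Identical
conditions return $t = 0, p = 1$; a constant nonzero difference is an
error, since the statistic is undefined.

The group-by-condition interaction uses the exact algebra of the 2×2
repeated-measures design: the interaction $F$ equals the square of the
pooled two-sample $t$ comparing per-subject difference scores between
groups, with df $= (1, n_1 + n_2 - 2)$. `rm_anova_interaction()` computes it
that way — dependency-light and exact — and the test suite verifies the
identity against a full `aov` error-stratum fit. The direction of each
group's mean difference is returned alongside, because the scientific claim
is a *sign pattern* (one group toward path-like, the other toward
star-like), not just a p-value.

Multiple testing is controlled per frequency band with Benjamini–Hochberg at
$q = 0.05$ (`stats::p.adjust`): each band is associated with distinct
networks and functions, so the correction family is the set of measures
tested within one band (the four network/tree measures for the network
tables; the five band fractions form one family per group in the power
table). The data do not pin this family definition uniquely; the per-band
reading is implemented and documented here as the package's convention.
`build_tables()` emits the paired tables per group, and the interaction
table on two scopes: the full cohort, and the subset of patients whose
sleep-deprived recording carried added diagnostic value together with *all*
controls.

## The synthetic cohort generator

No clinical recordings ship with the package; instead `generate_cohort()`
produces cohorts whose ground truth is known exactly, so every pipeline
stage is testable end to end.

**Signal model.** Each channel is a narrowband-centred oscillator: carrier
at the band centre plus a mean-reverting Ornstein–Uhlenbeck phase deviation
(stationary SD `phase_dev_sd`, correlation time `phase_tau`), all channels
of an epoch sharing one uniform epoch-start phase. Coupling mixes core
phases directionally in index order, $p_j = (1 - s)\,\theta_j + \sum_{i<j}
c_{ij}\, p_i$, and the imposed pairwise lags are added as per-channel
emission offsets propagated over the coupling backbone's spanning forest.
The emitted signal is $\cos(p_j + \delta_j)$ plus white Gaussian noise.
This architecture is the product of three deliberate decisions:

1. *Directional realization of symmetric coupling.* Two mutually and
   symmetrically phase-mixed channels meet at a zero-centred difference —
   no consistent lag, hence no PLI. Driving each channel only from its
   lower-indexed neighbours is what lets a fully coupled pair carry a
   constant nonzero lag (coupling 1, lag $\pi/2$, no noise gives PLI $= 1$
   exactly).
2. *Lags as emission offsets, not mixture terms.* Mixing
   $(\mathrm{neighbour} + \mathrm{lag})$ directly compounds the lag along
   chains and leaks it back through the own-phase term, driving deep-chain
   adjacent lags toward zero (the accumulated offset converges to
   $c\,\mathrm{lag}/(1-c)$ and re-enters at rate $1-c$). Propagating
   offsets over the backbone instead gives every backbone edge exactly its
   specified lag, while channels that merely share a driver meet at a
   difference centred on zero — which PLI suppresses, exactly as it
   suppresses volume conduction. Ground-truth detectability is therefore
   *direct coupling*, not common drive.
3. *Mean-reverting (not free) phase random walks.* A pure random walk's
   sign has arcsine-law persistence: even a zero-centred difference spends
   most of one epoch on a single side, inflating per-epoch PLI of indirect
   pairs. The OU deviation decorrelates within `phase_tau`, so an epoch
   holds $\approx n/(f_s \tau)$ independent phase observations and
   uncoupled-pair PLI decays toward zero as epochs lengthen.

**Defaults and the narrowbandness trade-off.** The defaults — coupling
strength 0.85, lag $\pi/2$, `phase_dev_sd = 3` rad, `phase_tau = 0.25` s,
`noise_sd = 0.25`, 17 channels, 4 epochs of 4096 samples at 512 Hz, alpha
carrier — were chosen to make the generator's ground truth *identifiable by
the estimator it feeds*: with them, a pure chain backbone is recovered as
the spanning tree with leaf number 2 and a pure star with diameter 2,
reliably across seeds, and estimated PLI is monotone in coupling strength.
The large phase deviation is what buys hop-distance discrimination (each
coupling hop adds independent phase wiggle, so PLI decays with backbone
distance), and it comes at a price stated openly: the instantaneous
frequency excursions are wide, so the raw signal is a broad spectral hump
around the carrier rather than a strictly band-limited tone, and the
band-pass stage analyzes its in-band component. Narrow-deviation regimes
(e.g. `phase_dev_sd` ≈ 0.4) give textbook-clean constant-lag examples and
are used for exactly those tests.

**Cohort design.** A cohort holds 21 patients and 17 controls, two
conditions each, with 15 of 21 patients flagged "added value" — the sample
sizes of the study design being emulated. Each subject-condition draws a
backbone tree by sequential attachment: node $j$ attaches to the hub with
probability `star_frac`, else to node $j-1$; `star_frac = 0` is the path,
`1` the star, and the expected leaf number interpolates linearly between.
(A convex combination of chain and star *matrices* was considered and
rejected: its dominant-backbone forest flips discontinuously at the
midpoint, producing a cliff rather than a smooth topology axis; the
deterministic interpolation is still available as
`interpolate_topology()`.) The programmed contrast — `topology_shift()` —
starts both groups at `star_frac = 0.5` under the routine condition and
moves patients to 0.1 and controls to 0.9 after sleep deprivation, with
subject-level jitter (SD 0.08): patients shift toward the path (leaf number
falls, diameter rises), controls toward the star (the reverse). The
magnitude of this shift is a free parameter of the synthetic design — the
emulated study reports no effect size — so power and significance obtained
on synthetic cohorts characterize the pipeline, not any clinical
population. One global seed fans out deterministically to per-subject
substreams, so cohorts are reproducible while subjects stay independent.

**What the generator does not emulate:** epileptiform transients, sleep
staging, volume-conduction forward models, per-channel amplitude
heterogeneity, or 1/f background spectra. Passing tests demonstrate that
the pipeline recovers phase-lag network structure it was designed to
detect; they are not evidence about artifact robustness on clinical
recordings.

## Problem sizes used by the tests

The unit tests run the full study geometry where it is cheap (17 channels,
4 × 4096 samples for backbone recovery and the cohort recovery check) and
reduced geometries elsewhere (6–10 channels, 1–2 epochs of 512–2048
samples) to keep the suite fast. Oracle comparisons use exhaustive
enumeration at ≤ 7 nodes (spanning trees), ≤ 8 nodes (clustering,
Floyd–Warshall), 1000 random trees for the leaf/diameter bounds, and 500–
1000 label permutations for type-I-error calibration. The acceptance script
regenerates its quantities from scratch at the full 17-node scale.

## Known limitations

* EDF input is not implemented; records enter as tab-separated ASCII sample
  matrices (the interchange format clinical review stations export) plus a
  CSV manifest.
* Artifact rejection is out of scope: epochs are taken as given (clinical
  practice performs visual inspection; synthetic epochs are clean by
  construction). A per-epoch inclusion decision therefore happens upstream
  of this package.
* The surrogate construction and the FDR family definition follow one
  defensible reading each of an under-specified convention; both are
  isolated behind single functions (`surrogate_networks()`,
  `fdr_correct()`) so alternatives can be swapped in.
* PLI cannot distinguish a direct connection from an indirect chain whose
  accumulated lag happens to be consistent; the generator's default regime
  avoids this by making phase wiggle grow with hop distance, but on real
  data the spanning tree should be read as "strongest consistent phase-lag
  relations", not anatomical connectivity.
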