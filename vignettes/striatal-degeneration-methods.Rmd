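---
title: "Modeling striatal network degeneration: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling striatal network degeneration: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(striatnet)
```

# The scientific problem

Chronic dopamine depletion, as in Parkinson's disease (PD), changes the
morphology of striatal neurons: the dendritic arbors of the projection
neurons (dSPN and iSPN, ~95% of striatal neurons) atrophy progressively,
while fast-spiking (FS) interneuron axons sprout, growing over 60%
longer and forming new synapses preferentially onto iSPNs. `striatnet`
asks two questions about these single-cell changes:

1. How do they restructure the *local network*? Pairwise connection
   probabilities tell only part of the story, so the package counts
   **directed cliques** — feedforward motifs of all-to-all connected
   neurons with a consistent ordering — across disease stages.
2. How must the *corticostriatal drive* change to restore SPN output
   once dendrites (and with them glutamatergic synapses) are lost? Two
   compensation strategies are compared: strengthening the surviving
   synapses and rewiring lost synapses onto surviving dendrites.

The package is a self-contained reimplementation of this pipeline on
synthetic morphologies: no proprietary reconstructions are required,
and every stage is seeded and reproducible.

# Morphologies and their transforms

Morphologies are rooted trees of typed 3-D points with SWC semantics
(`read_swc()`, `write_swc()`, `morphometry()`). Two transforms model
the disease:

* **Stepwise dendritic truncation** (`degenerate_step()`,
  `degenerate()`). After resampling dendrites at 3 µm, each step
  removes one 3 µm segment at *every* dendritic terminal. Stages PD1,
  PD2, PD3 correspond to 10, 20 and 30 steps. Three rules resolve
  cases the stepwise description leaves open, chosen to keep the
  per-step loss bounded by 3 µm per terminal:
  * a terminal branch shorter than the step is removed entirely and
    truncation stops at the branch point (no borrowing from the parent
    section within the same step);
  * a branch point whose children are all consumed becomes a terminal
    and is truncated from the next step onward (one truncation event
    per terminal per step);
  * a primary dendrite consumed to the soma is deleted, so the
    primary-dendrite count can decline, as observed in lesioned animals.

  Surviving nodes keep their identities (a truncated terminal moves
  toward its parent), which is what lets synapses anchored to a node be
  followed across stages.

* **Axonal terminal extension** (`grow_axon_terminals()`). Every FS
  axonal terminal is extended by exactly 61 µm of path length — the
  value implied by the reported 25,572 → 41,249 µm total (a 161.3%
  ratio; note 41,249 − 25,572 = 257 × 61 exactly, fixing the terminal
  count at 257). The experimental observation is that arbors grow in
  no preferred direction and become *denser*, with an unchanged
  maximal radius. We therefore implement growth as a persistent random
  walk (3 µm steps, heading = `tortuosity` × previous heading plus an
  isotropic perturbation, default tortuosity 0.8) that *reflects* at a
  radius cap. `stage_morphologies()` defaults the cap to each arbor's
  initial axonal radius, reproducing the "denser, same envelope"
  phenotype: Sholl crossings rise at intermediate radii while the
  maximal distance from the soma stays put.

# The synthetic morphology generator

The original reconstructions are not redistributable, so
`generate_morphology()` draws stand-ins whose population means are
calibrated to the published morphometrics (dSPN 3,997.9 µm over 8
primaries; iSPN 3,116.7 µm over 6; FS axon 25,572 µm with 257
terminals). Design of the generator:

* **Topology first.** A section tree is grown by random binary
  branching from `n_primary` stems until the target terminal count is
  reached. SPN terminal counts are not printed anywhere, but they are
  implied by the stage-to-stage length losses: with 3 µm removed per
  terminal per step, the first-stage loss fixes the mean effective
  terminal count (`calibrate_terminal_count()`: 37 for dSPN, 25 for
  iSPN). This makes the first-stage percentage loss correct *by
  construction*, while the later stages remain genuine tests of how the
  branch structure decays.
* **Section lengths.** Gamma-distributed, with terminal sections drawn
  three times longer than internal ones (shape 4 vs 3) — reflecting
  the long unbranched distal segments of these cells — then rescaled so
  each draw's total length is exact. The resulting populations lose
  length under 20 truncation steps to ≈49.5% (dSPN) and ≈55% (iSPN) of
  healthy, against printed values of 50% and 57%.
* **Geometry.** Sections are persistent random walks in ≤3 µm steps
  (so the truncation precondition holds without resampling),
  reflecting at a per-type radial extent. The extents are the one
  genuinely free spatial choice; we use field-typical values — SPN
  dendritic field radius 150 µm, SPN axon collaterals 250 µm, FS
  dendrites 120 µm and FS axonal plexus 200 µm. Dense, *local* FS
  axons matter: they are what lets capped sprouting densify the
  territory that iSPN dendrites actually occupy. (The sum of axonal
  and dendritic extents, ~400-550 µm, matches the reported maximal
  distance between connected neurons.)
* SPN axon collaterals and interneuron dendrites carry generic
  parameters (documented in `morphgen_spec()`); only their
  connectivity role matters downstream. A `scale_jitter` option adds
  per-draw log-normal size variability and is off by default.

What the generator does **not** emulate: diameter tapering, spines,
per-reconstruction idiosyncrasies, and the spatial correlation between
branching and target location of real axons. Tests passing on these
morphologies show that the *pipeline* behaves correctly under the
published summary statistics, not that real reconstructions would give
identical clique counts.

# Network construction

`place_neurons()` distributes neurons uniformly in a cube at the
striatal density of 80,500 neurons/mm³: 47.5% dSPN, 47.5% iSPN, and
3.2% modeled interneurons. The published total does not break down the
interneuron share, so FS 1.3%, ChIN 1.1%, LTS 0.8% is a documented
assumption; the remaining 1.8% is placed as unmodeled filler that
makes no synapses. Orientations are uniform random rotations.

`touch_detect()` records a putative synapse wherever a presynaptic
axonal segment passes within `max_distance` (default 3 µm) of a
postsynaptic dendritic segment or soma (the soma is treated as a
sphere of its radius, not a point). A voxel grid (10 µm) accelerates
the search; the result is provably independent of the voxel size, and
`touch_detect_bruteforce()` exists purely as the all-pairs oracle for
that property.

`prune()` thins the over-complete touch set with per-ordered-type-pair
rules applied in a fixed order: random keep; distance-dependent keep;
per-pair soft cap; all-or-none removal of weakly coupled pairs (more
likely the fewer synapses); all-or-none pair removal at a flat
probability. Functional forms for the distance dependence are not
published, so the defaults encode the standard physiology: FS synapses
are perisomatic (keep ∝ exp(−d/40 µm)), LTS synapses distal
(1 − exp(−d/120 µm)). The per-pair removal probabilities in
`default_pruning_rules()` are set so that a full-density build lands
near published pairwise connection probabilities (sparse, asymmetric
SPN collaterals — iSPN output well connected, dSPN output weak — and
high FS→SPN connectivity); `calibrate_keep_fraction()` re-fits the
random-keep stage by bisection against any target.

Three routes produce a disease-stage network (`build_pd_network()`):
the **degeneration** method keeps PD0 synapses whose postsynaptic
anchor survives atrophy (a strict subset — no sprouting contribution);
the **de novo** method re-runs touch detection and pruning on the
stage morphologies; the **hybrid** method keeps degeneration-route
synapses in place and tops up each ordered type pair from the de novo
set until the de novo counts are matched exactly, reporting the
per-pair remapping fraction as an attribute (it is an emergent
quantity, not an input).

# Topology

`digraph_from_synapses()` collapses synapse multiplicity onto weighted
edges (at most one edge per ordered pair, no self-loops).
`count_directed_cliques()` counts the simplices of the **directed flag
complex**: ordered tuples (v0, …, vn) of distinct vertices with an
edge vi→vj for every i < j. This ordered-tuple convention is the one
used by flag-complex counting software; it differs from the
set-with-unique-source-and-sink reading exactly when reciprocal edges
occur inside a clique, and the set-based variant is available via
`convention = "set"` for sensitivity analysis. The counter is exact
recursive enumeration (C++), with an independent subset-permutation
oracle (`brute_force_cliques()`) asserted equal on dozens of random
graphs in the test suite. Counts at dimensions 0 and 1 must equal the
vertex and edge counts on every run — this is asserted in tests rather
than assumed.

Edge effects are handled kernel-first: `select_kernel_core()` picks
the 8 most central neurons (4 dSPN + 4 iSPN, ties by lower id), takes
all their synaptic partners as the core, and clique counting keeps
only cliques that intersect the kernel.

`classify_cliques()` partitions cliques into all-dSPN, all-iSPN,
contains-interneuron (precedence) and mixed; `synapse_count_histogram()`
totals edge weights inside each clique, including reciprocal edges;
`erosion_curves()` compares random synapse removal (whole-network or
SPN-only) against interneuron ablation.

# Input drive and compensation

Correlated inputs use a mother-child construction
(`correlated_spike_trains()`): a mother Poisson train at rate f is
thinned once with transfer probability p = c; the surviving spikes are
shared by all children, each of which adds an independent Poisson
train at (1 − p)·f. Every child has rate f and the expected pairwise
spike-count correlation is exactly c (shared variance p·f out of f).
We chose the *shared* transfer reading because it is the one that
makes the correlation parameter equal the grid value c; copying mother
spikes independently per child would give correlation c² instead. The
estimator is Pearson correlation of 25 ms-binned counts averaged over
distinct pairs — the bin size is this package's declared choice, as no
estimator is standard for this protocol.

`place_synapses()` spreads input synapses uniformly per unit dendritic
arc length; `surviving_fraction()` evaluates which sites outlive
degeneration (dSPN ≈ 47%, iSPN ≈ 52% at stage PD2 on calibrated
populations, against reported estimates of 47.5% and 53.25%).
Compensation follows the published formulas exactly: strengthening at
level x adds (cond_PD0 − cond_PD2)·x/100/n_syn_PD2 to every surviving
synapse (total conductance restored exactly at x = 100); rewiring adds
round(x/100·(n_syn_PD0 − n_syn_PD2)) base-conductance synapses on the
surviving dendrites (count restored exactly at x = 100).

The postsynaptic cell is deliberately **not** a multicompartment
conductance model: `surrogate_neuron()` is an adaptive leaky
integrate-and-fire point neuron (C = 100 pF, gL = 5 nS, threshold
−50 mV, spike-triggered adaptation 60 pA with 300 ms decay) with
depressing Tsodyks–Markram synapses (utilization 0.3, recovery 800 ms,
2 ms conductance decay — standard glutamatergic values, as the
formalism is cited without parameters upstream). Disease presets shift
leak and threshold distance by ±15%: dSPN more excitable in PD, iSPN
less, implementing the reported direction of excitability change
without claiming to reproduce current-frequency curves. The healthy
input count is calibrated per morphology by bisection
(`calibrate_input_count()`) to 10 Hz output under 5 Hz uncorrelated
drive, landing at roughly 7,000-8,000 synapses. Integration uses a
fixed 0.1 ms step; synaptic events are folded in event-wise, so runs
are deterministic given the trains.

`protocol_grid("full")` enumerates the complete experiment — 12
scenarios (PD0, PD2, five strengthening and five rewiring levels) × 10
rates (0.5-5 Hz) × 6 correlations (0-0.5) = 720 sets;
`protocol_grid("desk")` keeps the endpoints of each axis (4 × 3 × 3)
for routine runs.

# Problem sizes, tolerances, degenerate inputs

* The bundled experiments run at *desk scale*: a 150 µm cube at full
  density (≈270 neurons, two morphology variants per type) for network
  questions, 20-draw populations for morphometric means, 200 trains ×
  100 s for correlation estimates, 3-4 s simulations for drive
  experiments. These sizes were chosen so that each qualitative
  comparison is reproducible in minutes; absolute clique counts at
  this scale are three to four orders of magnitude below a
  100,000-neuron build and are compared only *between* conditions.
* Touch detection treats segment pairs within 1e-12 of the threshold
  as touching; degeneration uses the same guard for "consumed"
  segments. Zero-length sections are forbidden by the generator
  (minimum 1 µm before rescaling).
* Empty inputs degrade gracefully: an empty synapse table yields a
  vertex-only digraph; a soma-only morphology reports zero lengths; a
  morphology without axon makes growth a warning no-op; an empty
  Sholl structure reports zero crossings.
* Known limitations: no gap junctions, no dopamine neuromodulation, no
  afferent axon geometry inside the volume (drive is abstract), no
  persistent homology, and the surrogate neuron is not an
  electrophysiological model — directional drive results (deficit,
  rescue, dSPN needing less compensation than iSPN) are the claims it
  supports.

# Reproducing a full run

```{r, eval = FALSE}
cfg <- pipeline_config(cube_side = 150, stages = c("PD0", "PD2"),
                       run_drive = TRUE, seed = 1)
man <- run_pipeline(cfg, "striatnet_run")
report("striatnet_run")
```

Every artifact is a CSV/TSV with an MD5 recorded in `manifest.json`;
rerunning with the same configuration and seed reproduces the files
byte for byte.
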