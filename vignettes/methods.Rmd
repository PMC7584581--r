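---
title: "Surrogate connectomes and simulated segregation-integration dynamics: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surrogate connectomes and simulated segregation-integration dynamics: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The question and the approach

Resting-state functional connectivity (FC) fluctuates over tens of seconds
between *segregated* patterns, dominated by within-community coupling, and
*integrated* patterns with strong between-community coupling. `connfluct`
implements a generative analysis of which structural features of the
connectome shape the magnitude of those fluctuations. The logic is a
constrained-null-model experiment run through a forward simulation:

1. build surrogate connectomes by permuting structural connection weights
   under constraints that preserve selected features — nothing (`R`), the
   weight-length relationship (`G`), communities plus the weighted rich
   club (`T`), or all of them (`GT`), plus main/control pairs that localize
   permutation to edges incident (or not) to one resting-state network;
2. simulate neural activity on each surrogate with delay-coupled phase
   oscillators, selecting the coupling constant so every surrogate reaches
   the same global synchrony level as the reference connectome;
3. convert to BOLD with the Balloon/Windkessel model, compute tapered
   sliding-window FC, and track three global measures per window: signed
   modularity Q\* (segregation), mean participation coefficient (PC) and
   mean temporal participation coefficient (TPC) (integration);
4. quantify each run's fluctuation magnitude as the SD of a measure across
   windows and compare magnitudes between surrogate families
   (Mann-Whitney U, Benjamini-Hochberg FDR, Cliff's delta).

If a preserved feature carries the fluctuation-generating structure, its
family's magnitudes exceed the unconstrained family's.

# The synthetic connectome generator

All pipeline stages run on seeded synthetic connectomes, so the analysis is
reproducible end to end without imaging data. The generator emulates the
statistical structure of a consensus-thresholded group connectome, not any
particular dataset:

- **Geometry.** Node coordinates are sampled on two mirrored hemispheric
  ellipsoidal shells (semi-axes 30, 80, 55 mm, shell thickness 25% of the
  radius, 2 mm interhemispheric margin). Mirroring gives the broad,
  bimodal-ish mix of within- and between-hemisphere distances that the
  length-binned constraint needs.
- **Weights.** Candidate weights follow
  `w = exp(-L / decay_scale) * community_boost^within *
  hub_boost^(hubs/2) * lognormal(0, sdlog)` with `decay_scale = 60` mm,
  `community_boost = 2`, `hub_boost = 5`, `sdlog = 0.8`, and streamline
  length `L` = Euclidean distance times tortuosity 1.2. Communities are
  spatially contiguous k-means clusters (4 by default); hubs are a random
  15% of nodes.
- **Density.** The weakest candidates are thresholded away to hit the
  target density 0.19; maximum-weight bridging candidates are re-added if
  the binarized graph disconnects.
- **Length support.** Candidates longer than `max_length = 120` mm are
  excluded. Without this cap, isolated extreme-length edges leave empty
  top-length bins and the descending bin-count scan has no admissible
  count for many seeds; with it, the scan selects 20-50 bins at the
  114-node scale, bracketing the 30 bins typical of group connectomes.
- **RSN labels.** The seven canonical labels are assigned in spatially
  contiguous blocks along the posterior-anterior axis with a 2 mm jitter;
  the visual network takes the posterior pole, which makes it the most
  compact block and gives it the highest within-RSN edge density — the
  configuration whose local contribution the RSN analysis probes.

What the generator does *not* emulate: subject-level variability,
tractography biases, hemispheric asymmetries, and the empirical length
*distribution* beyond its compact support. Passing tests therefore show
that the pipeline's machinery behaves as specified on data with the right
coarse structure; they are not evidence about any empirical connectome.

# Surrogate families

Weight permutation operates on disjoint *cells* of the non-zero edge set;
weights are shuffled uniformly within each cell of two or more edges.
`R` uses one global cell. `G` uses equal-width streamline-length bins,
with the bin count chosen by scanning 100, 90, ..., 10 and accepting the
first count at which at most 10% of bins hold three or fewer edges and
every bin holds at least two. `T` intersects community blocks (within each
community, or the single between-communities block; communities frozen
from one 100-restart Louvain maximization on the parent) with rich-club
degree categories `d = min(deg_i, deg_j)` on the binarized graph —
permuting within those categories preserves the weighted rich-club curve
exactly. `GT` intersects all three partitions. The permuted-edge fraction
of a family is the fraction of edges lying in cells of size two or more
(the permutation pool), which is 1 for `R` by construction and shrinks
monotonically under refinement.

RSN main surrogates restrict the `GT` cells to edges incident to the RSN
of interest; control surrogates to non-incident edges, with random extra
edges frozen until the two permutation pools match in size (exactly when
the cell-size arithmetic permits; the residual mismatch averages below
1e-4 of the edge set).

After permutation, node strengths are restored by iterative multiplicative
correction: each weight is repeatedly rescaled by the geometric mean of
its endpoints' target/current strength ratios until the maximum relative
strength error drops below 1e-3 (cap 100 iterations; non-convergence is a
warning that reports the achieved error). An earlier variant that re-sorted
the adjusted values onto the permuted rank order each iteration cannot
converge — freezing the global rank order on a fixed support leaves too few
degrees of freedom to realize an arbitrary strength sequence — so the
correction deliberately lets individual values move smoothly. On this
synthetic family the correction shifts per-bin mean weights by ~10%
(the hub boost makes strengths strongly heterogeneous), while the
bin-mean profile and the negative weight-length relationship survive; the
tests assert that qualitative preservation.

# Simulation model

Phases follow `dtheta_i/dt = 2*pi*f + k * sum_j c_ij *
sin(theta_j(t - tau_ij) - theta_i(t))` with natural frequency `f = 60` Hz,
coupling `c` normalized to unit mean over non-zero edges, and delays
`tau_ij = L_ij / v` where `v = mean(L) / tau_bar` and `tau_bar = 12` ms.
Integration is Heun's predictor-corrector at `dt = 0.2` ms with delays
rounded to the nearest step (sub-step error at most 0.1 ms, far below the
16.7 ms oscillation period) and realized as lookups into a circular
sin/cos history; the stage-two delayed sums of one step are reused as the
stage-one sums of the next, and zero-lag edges read the predictor slot,
which is exactly what the two-stage scheme requires. The initial history
is the uncoupled backward rotation over the maximum delay (the length of
this uncoupled lead-in is not prescribed anywhere, so the shortest
sufficient history was chosen); initial phases are uniform on `[0, 2*pi)`.
The first 20 s are discarded. Global synchrony is the time-mean Kuramoto
order parameter `r(t)`.

Amplitudes `sin(theta)` are recorded at 1 kHz and drive the standard
four-state Balloon/Windkessel model (vasodilatory signal, inflow, volume,
deoxyhemoglobin; `kappa = 0.65 1/s`, `gamma = 0.41 1/s`, `tau = 0.98 s`,
`alpha = 0.32`, `rho = 0.34`, `V0 = 0.02`), integrated per node with Heun
at 1 ms. These hemodynamic constants are the standard published set; since
absolute BOLD scale never enters the correlation-based measures, only the
dynamics matter and `input_gain` stays at 1.

BOLD post-processing downsamples to TR = 0.72 s through staged zero-phase
FIR decimation (each stage's low-pass normalized to exact unit DC gain),
band-passes 0.021-0.1 Hz with a zero-phase 2nd-order Butterworth at the TR
rate, and regresses out the global mean signal with intercept. The
band-pass runs *after* downsampling: at 1 kHz the normalized low cut would
be ~4e-5, where IIR coefficients are numerically meaningless in double
precision, whereas at the TR rate the design is well conditioned; since
decimation and filtering are linear and the passband sits far below the
decimation cutoffs, the operator is equivalent where it matters. When the
sliding-window width changes, the low cut moves to 1/width.

# Time-resolved FC and network measures

Windows are a 66-TR rectangle convolved with a sigma = 9 TR Gaussian
truncated at 3 sigma (support 120 TRs), advanced in 3-TR steps, last
partial window dropped. The taper acts as observation weights in a
weighted Pearson correlation — with a uniform taper this is exactly plain
Pearson on the window slice, which the tests assert to 1e-12. Correlations
are Fisher z-transformed with `|r|` clamped at `1 - 1e-15`; both signs are
kept, nothing is thresholded. Windows with a zero-variance node set that
node's entries to zero and warn.

Q\* is the signed-network modularity with positive and negative null terms
`e± = s±_i s±_j / v±`, the negative term weighted by `1/(v+ + v-)` and
dropped for all-positive input; the resolution parameter (default 1)
scales the null terms only. Maximization is Louvain with hierarchical
aggregation, 100 restarts randomized through the node visiting order, ties
to the first encountered best community; on every signed network with at
most 8 nodes in the test suite it attains the exhaustively enumerated
optimum. Degenerate all-singleton or all-in-one partitions are accepted as
valid outputs. PC uses positive strengths only; a node with zero positive
strength gets PC 0 with a warning. TPC averages the community-concentration
sum over all windows' partitions and reduces to PC when partitions are
constant. The fluctuation magnitude of a run is the sample SD of each
measure across its windows.

# Coupling selection and the comparison protocol

Surrogate dynamics are made comparable by matching global synchrony: the
reference level is the mean time-mean `r` over 8 seeded runs of the parent
at `k = 55`. Each surrogate sample is simulated
once per grid value `k = 2.5, 5, ..., 70` (RSN families: 50 to 60) at
fixed `tau_bar`, the closest `k` is selected, and samples whose closest
synchrony still misses by more than a rejection radius are discarded and
regenerated (retry cap 5 per accepted sample). `build_sync_reference()`
reports the reference ensemble's own radius (the maximum deviation of any
reference run from the mean), but the pipeline's default rejection
threshold is the canonical operating value 0.085: on a 57-node connectome
whose parent dynamics settle into a single attractor, the ensemble radius
can collapse below 1e-3, which would reject surrogates matching the
reference synchrony to a fraction of a percent and starve the ensemble.
Both values are logged; setting `search$radius` to `NULL` restores the
computed radius. Matching runs use a shortened 10 s transient + 10 s
measurement profile — 600 oscillation cycles, enough to rank grid
points — while accepted samples are re-run at full length for the
analysis itself.

Group comparisons use the Mann-Whitney U test (exact enumeration up to 12
combined observations, tie-corrected normal approximation with continuity
correction above), Benjamini-Hochberg adjustment across the comparison
plan, and Cliff's delta as effect size.

# Desk-scale profile and problem sizes

The default `run_pipeline()` profile uses 57 nodes, 140 s runs (120 s
retained; 166 TRs; 16 windows) and 8 accepted samples per family, with the
full 114-node generator available through configuration. These sizes were
chosen so a complete directional analysis — the sign pattern
`SD(G) > SD(R)`, `SD(T) > SD(R)`, `SD(actual) > SD(GT)` — runs on a single
CPU in well under an hour while each stage still operates in its intended
regime (the synchrony transition of the 57-node connectome spans incoherent
to near-synchronized over the coupling grid). With 8 samples per family the
comparison is a sign check on medians, not a powered hypothesis test; the
full-scale protocol (50 samples per family, 100 per RSN arm, 14.4-min
runs) is a configuration change, not a code change.

# Numerical choices and degenerate inputs

- Delays shorter than half an integration step round to zero lag and are
  handled exactly (the predictor slot); a warning flags `dt` larger than
  the smallest positive delay.
- Phase blow-up (non-finite values) aborts with the failing step; the
  hemodynamic integrator aborts if flow, volume or deoxyhemoglobin leave
  the positive domain.
- The Fisher-z clamp keeps perfectly correlated pairs finite
  (`z ~ 17.6`).
- Zero-variance windows, zero-positive-strength nodes, and Louvain
  degeneracies warn-and-continue rather than fail, since they occur
  naturally in permuted or toy inputs.
- Equal-width length bins use half-open intervals with a closed last bin,
  so every edge lands in exactly one bin.
- `Q*` sums run over ordered pairs including the diagonal null terms;
  with that convention the single-community partition scores exactly 0 on
  any network, which the tests pin.

# Known limitations

- The two-stage empirical parameter fit is represented by its stage-one
  criteria functions (`stage1_fit_criteria()`); running the full fit
  requires empirical FC, which is out of scope.
- Simulated BOLD carries no physiological noise, so absolute fluctuation
  magnitudes are not comparable to empirical values — only between
  conditions of the same simulation protocol.
- The strength correction distorts per-bin mean weights by ~10% on this
  synthetic family (see above); analyses that need exact bin-mean
  preservation should use the pre-adjustment surrogates.
- The number of sliding windows per empirical-length run depends on a
  placement convention the sliding-window literature leaves open; this
  implementation starts at the first TR and drops the final partial
  window.
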