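# connfluct

Structural determinants of dynamic fluctuations between segregation and
integration on the connectome.

Resting-state functional connectivity drifts back and forth between
*segregated* patterns (strong within-community coupling) and *integrated*
patterns (strong between-community coupling) on a time scale of tens of
seconds. `connfluct` asks which features of the structural connectome are
responsible for the *magnitude* of those fluctuations, and answers it with
a constrained-null-model experiment run through a forward simulation:

1. **Surrogate connectomes.** Non-zero structural weights are randomly
   permuted under constraints that preserve chosen features of the parent:
   nothing (`R`), the weight–length relationship via equal-width length
   bins (`G`), community blocks intersected with rich-club degree
   categories (`T`), or all of them (`GT`); plus RSN-localized main/control
   pairs built on top of `GT` with equalized permutation pools. Node
   strengths are restored afterwards by iterative multiplicative
   correction.
2. **Simulation.** Delay-coupled Kuramoto phase oscillators
   (`dθ_i/dt = 2πf + k Σ_j c_ij sin(θ_j(t − τ_ij) − θ_i(t))`, `f` = 60 Hz,
   `τ_ij = L_ij/v`, Heun at 0.2 ms) run on each surrogate, with the global
   coupling `k` selected per sample so that global synchrony — the time
   mean of the Kuramoto order parameter `r(t)` — matches the parent
   connectome's reference level; unmatched samples are rejected and
   regenerated.
3. **BOLD and time-resolved FC.** Amplitudes `sin θ` drive the
   Balloon/Windkessel hemodynamic model; BOLD is downsampled to
   TR = 0.72 s, band-passed 0.021–0.1 Hz, global-signal regressed, and
   windowed with a tapered sliding window (66 TR rectangle ⊛ σ = 9 TR
   Gaussian, step 3 TR) into signed Fisher-z correlation matrices.
4. **Network measures and statistics.** Per window: signed modularity Q\*
   maximized by 100-restart Louvain (segregation), mean participation
   coefficient and mean temporal participation coefficient (integration).
   The fluctuation magnitude of a run is the SD of each measure across
   windows; families are compared with Mann-Whitney U tests,
   Benjamini-Hochberg FDR and Cliff's delta.

Everything runs on seeded synthetic connectomes (spatially embedded,
modular, rich-club-bearing, density 0.19, seven RSN labels), so the whole
analysis is reproducible on one machine with no imaging data. The package
is aimed at researchers in network neuroscience and computational
modelling who want to run or extend constrained-surrogate experiments on
connectome-shaped data.

## Worked example

```r
library(connfluct)

conn <- synthetic_connectome(n_nodes = 57, seed = 1)
conn
#> <connectome> 57 nodes, 303 edges, density 0.190
#>   RSN counts: CON=8 DMN=12 LIM=5 DAN=6 VAN=6 SMN=8 VIS=12

# constrained surrogate: geometry + topology preserved
part  <- detect_structural_communities(conn, seed = 2)
bins  <- select_length_bins(conn)
cells <- build_cells(conn, "GT", bins = bins, partition = part)
cells$permutable_fraction        # fraction of edges free to permute
#> [1] 0.689769
smp <- make_surrogate(conn, cells, seed = 3)

# simulate, convert to BOLD, measure fluctuations
cfg  <- sim_config(k = 55, duration = 140, transient = 20, seed = 4)
traj <- simulate_phases(conn, cfg)
traj$r_mean                      # global synchrony level
#> [1] 0.1414846
bold <- postprocess_bold(balloon_windkessel(phases_to_neural(traj)))
fc   <- sliding_window_fc(bold, build_taper(), step = 3)
ms   <- measure_series(fc, seed = 5)
head(ms, 3)
#>   window     qstar   mean_pc  mean_tpc
#> 1      1 0.4195523 0.4454579 0.5233960
#> 2      2 0.4236868 0.4533062 0.5166143
#> 3      3 0.4232939 0.4456196 0.5109380
fluctuation_magnitude(ms)$sd_mean_pc
#> [1] 0.02939944
```

`qstar` high / `mean_pc` low marks a segregated window; the SD of
`mean_pc` across windows is the run's fluctuation magnitude — the quantity
compared between surrogate families. The full protocol (all families,
synchrony-matched coupling per sample, group comparisons) is one call:

```r
res <- run_pipeline(default_config(), seed = 7, outdir = "out")
res$comparisons   # U, p, FDR-adjusted p, Cliff's delta per family pair
```

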