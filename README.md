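# agetr

Reverse-engineering gene regulatory networks (GRNs) in tissues where
patterning and morphogenesis happen at the same time — such as the zebrafish
presomitic mesoderm (PSM) — requires gene expression dynamics in *moving*
single cells, which no current experiment measures directly. `agetr`
implements the AGET approach: combine quantitative fixed-sample imaging with
live cell tracking to build **Approximated Gene Expression Trajectories**
(AGETs) for every tracked cell, then fit a per-cell dynamical GRN model to
those trajectories.

The package is aimed at quantitative developmental biologists and systems
biologists who have (a) cell-tracking tables from a time lapse and (b)
processed 3D expression point clouds from fixed samples (e.g. HCR), and want
candidate network topologies plus in-silico perturbation predictions.

## What it does

1. **Expression processing** — background thresholding, posterior-to-anterior
   (A–P) axis normalization, per-experiment channel normalization by
   Savitzky–Golay-smoothed profile maxima.
2. **Registration** — isotropic A–P length rescaling followed by
   point-to-plane ICP, with a numeric quality gate (RMS residual + inlier
   fraction) replacing visual inspection.
3. **AGET construction** — for every tracked cell at every frame, the median
   (default) of its 5 nearest neighbours in each aligned source cloud,
   combined across sources as a median of medians.
4. **Live-modelling** — a connectionist GRN ODE simulated independently in
   each cell. For gene *a* with mRNA level *g\_a*:

   dg_a/dt = R_a φ(u_a) − λ_a g_a,  φ(u) = ½(u/√(u²+1) + 1),
   u_a = Σ_b W_ba g_b + Σ_s E_sa g_s + h_a

   with genes G = {tbxta, tbx16, tbx6} and signals S = {Wnt, FGF} read
   per-cell from the AGET (the system is non-autonomous); 24 free
   parameters: W (3×3), E (2×3), R, λ, h (3 each).
5. **Inference** — affine-invariant ensemble MCMC (stretch move) on a
   Gaussian likelihood with per-gene σ (0.2, 0.2, 0.1), uniform priors
   ±200 (R, λ restricted positive), Kolmogorov–Smirnov convergence
   diagnostics, overall-likelihood recomputation, MAP selection.
6. **Post-processing** — likelihood (−15000) and weight-magnitude (±100)
   filters, z-scaled k-means topology clustering with 5 % cluster pruning,
   interaction-sign consensus, and signal-clamp perturbation experiments
   (Wnt → 1.5 over-expression, FGF → 0.01 loss of function).
7. **Synthetic embryo generator** — tapered-cylinder PSM point clouds with
   logistic A–P expression profiles, advecting cell tracks with posterior
   mixing, and exact forward-simulated ground-truth AGETs, so the entire
   pipeline is testable without any imaging data.

## Worked example

```r
library(agetr)

# synthetic embryo: 61-frame lapse, ground-truth sparse network
cfg    <- synthetic_config(n_tracks = 40, n_cells_per_cloud = 100, seed = 11)
tracks <- generate_tracks(cfg)
truth  <- ground_truth_grn()
agets  <- forward_simulate_agets(tracks, truth)
grid   <- time_grid(61)

# fit 24 randomly selected cells with ensemble MCMC
fit_set <- select_fitting_agets(agets, tracks, 24, seed = 5)
ens <- run_mcmc(fit_set,
                config = mcmc_config(n_walkers = 64, n_steps = 2500,
                                     max_extensions = 0, seed = 42),
                grid = grid)
map <- select_map(ens)
print(map)
#> GRN parameter set (24 parameters)
#> W (gene -> gene, regulator rows):  ... W[tbx16, tbx6] = 8.22 (truth 8)
#> E (signal -> gene):                ... E[wnt, tbx16] = 10.29 (truth 8),
#>                                        E[fgf, tbxta] = -9.61 (truth -6)

# goodness of fit of the MAP network, per gene
sim <- live_model(fit_set, map, grid)
sapply(1:3, function(a) sqrt(mean((sim$values[,,a] - fit_set$values[,,a])^2)))
#> [1] 0.0143 0.0059 0.0051    # RMS error in expression units (all < 0.05)

# in-silico FGF loss of function: tbxta expands, as expected for repression
run_perturbation(agets, truth$params, perturbation_spec("fgf", 0.01), grid)$mean_delta
#>      tbxta      tbx16       tbx6
#>  0.2718564 -0.1616539 -0.2778194
```

The MAP network recovers the sign of every strong ground-truth interaction,
its live-model error is about an order of magnitude below the likelihood σ,
and clamping FGF to 0.01 raises mean final-frame *tbxta* by ≈ 0.27 (FGF
represses *tbxta* in the generator network).

A command-line wrapper for the whole pipeline is installed as
`exec/agetkit` (subcommands `synth`, `process`, `align`, `build`,
`simulate`, `fit`, `cluster`, `perturb`, `report`).

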