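---
title: "AGET construction and GRN reverse-engineering: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{AGET construction and GRN reverse-engineering: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

In the zebrafish presomitic mesoderm (PSM), the T-box genes *tbxta*,
*tbx16* and *tbx6* are expressed in a posterior-to-anterior (A–P) sequence
while the cells carrying them move extensively — mixing in the tailbud,
then streaming anteriorly toward the forming somites. Classical GRN
inference needs per-cell expression dynamics, but live multi-gene reporters
at this scale do not exist. The AGET approach approximates those dynamics
by combining what each modality does measure:

* **live imaging** gives cell positions over time (tracks), but no
  multiplexed expression;
* **fixed samples** (e.g. HCR) give quantitative expression plus nuclear
  positions, but only at one instant.

Registering every fixed-sample point cloud onto every time-lapse frame and
reading each tracked cell's expression from its spatial neighbours yields
an *approximated gene expression trajectory* (AGET) per cell: five channels
(three genes, two signalling inputs — Wnt and FGF) at every frame.

# AGET construction

For each frame *i* and each accepted source cloud *j*, the source is
rescaled to the target's A–P length and aligned by point-to-plane ICP. Each
tracked cell *k* then receives, per channel, the median of its `n = 5`
nearest source points, and these per-source medians are combined across
sources as a median of medians. Choices and their rationale:

* **Isotropic rescaling.** The A–P extents are matched with a single scale
  factor applied to all three axes, preserving local nuclear-neighbourhood
  geometry. Rescaling about the source centroid makes the operation
  idempotent.
* **Initial alignment.** Centroid matching plus rotation of the source's
  first principal axis onto the target's (signs chosen so both point
  anteriorly), deliberately without roll about that axis: a tapered,
  approximately cylindrical tissue gives unstable second/third principal
  axes, and an arbitrary roll would seed ICP badly.
* **Quality gate.** Alignment quality is assessed numerically rather than
  visually: accepted iff RMS correspondence residual ≤ 5 % of the target
  A–P extent and ≥ 50 % of source points find a correspondence within the
  distance gate (default 10 % of A–P extent). Reproducibility requires an
  objective criterion; the thresholds are configurable.
* **Tie-breaking.** Distance ties at the n-th neighbour break by lowest
  source-point index — deterministic and matched exactly by the brute-force
  oracle used in the tests. Even-count medians are the midpoint of the two
  central values.
* **Per-frame transforms.** Each source is re-aligned to every frame
  independently; sources failing the gate for a frame are dropped from that
  frame's median, with a configurable minimum (default 3) below which the
  build aborts rather than silently thinning.

AGET channels live in [0, 1] after processing: thresholding (values below a
per-channel floor set to 0), A–P normalization (x divided by its maximum),
and per-experiment channel normalization (division by the maximum of the
Savitzky–Golay-smoothed A–P profile; window 11 bins, polynomial order 3, 50
bins by default). Normalization is per source cloud, never pooled across
experiments. Raw points exceeding the smoothed maximum are capped at 1;
where noise saturates the peak this can leave the recomputed smoothed
maximum marginally below 1 — accepted, since the cap is what keeps the
channel-range invariant. Smoothing operates on binned profiles (bin means
along the normalized A–P axis); isolated empty bins are linearly
interpolated, runs longer than 5 bins abort with an error.

# The dynamical model

Each cell runs an independent copy of a connectionist gene-circuit model.
For gene $a$ with mRNA level $g_a(t)$:

$$\frac{dg_a}{dt} = R_a\,\phi(u_a) - \lambda_a g_a, \qquad
\phi(u) = \tfrac12\!\left(\frac{u}{\sqrt{u^2+1}} + 1\right), \qquad
u_a = \sum_{b \in G} W_{ba} g_b + \sum_{s \in S} E_{sa} g_s + h_a,$$

with $G$ the three T-box genes and $S$ = {Wnt, FGF}. The signal levels
$g_s(t)$ are read from the cell's AGET and linearly interpolated between
frames, making the system non-autonomous; they are inputs, not state. The
initial condition $g_a(0)$ is the AGET's first-frame gene value. The 24
parameters are the 9 gene–gene weights $W$, 6 signal–gene weights $E$, and
per-gene production rates $R$, decay rates $\lambda$ and basal thresholds
$h$. Positive weights are activations, negative repressions. The model is
deterministic, has no cell–cell coupling, and does not model Wnt/FGF
dynamics themselves; the known somite-derived repression of anterior
*tbx6* is outside the model on purpose.

**Time units.** Model time is dimensionless: the lapse spans 1 unit (the
convention that 1 is the time the fastest cell needs to cross the PSM),
divided evenly over the frames. Units cancel in parameter-recovery
experiments as long as generator and fitter share the grid; the span is
configurable.

**Integration.** Classical fixed-step RK4 with 10 sub-steps per frame
interval. Against a 1000-steps-per-frame explicit-Euler oracle on random
parameter draws the frame-sampled error is below $10^{-4}$; halving the
sub-step changes endpoints by under $10^{-6}$. A fixed-step method keeps
the likelihood a smooth deterministic function of the parameters (adaptive
step-size control would introduce evaluation-order noise into the MCMC).
States are not clipped during integration: with $g_0 \ge 0$, $R \ge 0$,
$\lambda > 0$ the trajectory stays within $[\min(g_0, 0),\,
\max(g_0, R/\lambda)]$, which the tests assert rather than enforce.
Non-finite states (possible under extreme prior draws) make the likelihood
$-\infty$.

# Likelihood, priors and sampling

The likelihood is Gaussian with fixed per-gene standard deviations
$\sigma_{tbxta} = \sigma_{tbx16} = 0.2$, $\sigma_{tbx6} = 0.1$:

$$L = -\tfrac12 \sum_a \sum_c \sum_t
\frac{(T_{atc} - S_{atc})^2}{\sigma_a^2}.$$

The residual is squared: part of the literature prints this formula without
the exponent, but the accompanying description ("squared distance") and the
role of $\sigma^2$ make the quadratic form the only consistent reading, so
that is what is implemented.

Priors are uniform on $[-200, 200]$ per parameter, with $R$ and $\lambda$
restricted to non-negative values (production and degradation rates; the
restricted set is configurable because reasonable people could also
restrict $h$). Walkers initialize uniformly in a small region of support —
weights and thresholds in $[-1, 1]$, rates in $[0.1, 2]$ — to avoid
starting at $\lambda \le 0$ where the likelihood is $-\infty$.

Sampling uses the Goodman–Weare stretch move (the affine-invariant ensemble
scheme) with scale $a = 2$, implemented generically so the sampler can be
validated against closed-form targets (a 2-d Gaussian and a flat box)
independently of the GRN likelihood. **Walker count:** stretch-move
proposals lie in the affine span of the current ensemble, so a 24-parameter
fit needs comfortably more than 48 walkers; the configuration enforces
$\ge 50$ and defaults to 96. Reference-scale fits use 96 walkers × 10000
steps with 10000-step extensions; scaled-down recovery experiments (below)
use 64 × 2500.

**Convergence** is declared by two-sample Kolmogorov–Smirnov tests per
parameter between an early window (steps $L-10000$ to $L-8000$ at
reference scale; the first fifth for shorter chains) and the final window
(last 5000 steps; the last half for shorter chains): converged when at
least 20 of 24 parameters show *no* distributional shift at
$\alpha = 0.001$. The source description of this rule reads
"distinguishable", which would invert the purpose of a convergence check;
indistinguishability is implemented.

After sampling, the likelihood of the final 2000 retained samples is
recomputed on *all* AGETs so runs fitted to different cell counts are
comparable; the MAP network is the retained sample with the highest score
(ties by earliest index).

# Filtering, clustering, perturbations

Retained samples must come from converged runs, have every interaction
weight within ±100, and score at least −15000 on the full AGET set.
Survivors are z-scaled per parameter (zero-variance parameters get scale 1,
logged) and clustered with k-means (fixed seed, 10 restarts); k is chosen
at the maximum-curvature point of the within-cluster-sum-of-squares curve
over k = 2..15 unless overridden; clusters holding under 5 % of networks
are masked, never relabelled, so provenance indices survive the whole
filter–cluster–prune pipeline. Sign consensus reports, per interaction
parameter, the fraction of networks with value strictly above 0 (exact
zeros count as non-positive).

Perturbations clamp one signal channel to a constant (Wnt → 1.5 emulating
over-expression, FGF → 0.01 emulating loss of function) over the whole
simulation and report per-cell final-frame expression differences and
their per-gene means. Clamp values may exceed 1 by design.

# The synthetic embryo generator

The generator provides study conditions for every test, emulating:

* **Source clouds** — points uniform in a tapered cylinder (default length
  200 µm, anterior radius 40 µm, tapering ~30 % toward the posterior tip;
  the real tissue's shape is not parameterized anywhere, so a
  phenomenological stand-in is used), channels logistic in normalized A–P
  position (tbxta, tbx16, Wnt, FGF posterior-high with increasing
  midpoints; tbx6 anterior-high) plus Gaussian noise (sd 0.05), clipped to
  [0, 1]. Pooled developmental stages are emulated by jittering profile
  midpoints (±0.02 by default).
* **Tracks** — 61 frames at 2-minute intervals (a 2-hour lapse). Cells
  advect posteriorly→anteriorly with per-cell speeds uniform between 50 %
  and 100 % of the fastest-crossing speed; positional Gaussian noise
  (0.5 µm/frame) is tripled in the posterior 30 % of the axis to mimic
  tailbud mixing. No published mixing statistics or speed distributions
  exist for calibration, so these are order-of-magnitude choices, fixed
  once. No cell division or ingression.
* **Ground truth** — a sparse network (Wnt→tbx16 +8, FGF→tbx16 +8,
  FGF→tbxta −6, tbx16→tbx6 +8, $R = \lambda = 2$, $h$ = (2, −6, −4)) whose
  four strong interactions are all recoverable in sign, with signal inputs
  and initial conditions generated from each cell's A–P position by the
  same logistic rules.

What the generator does *not* emulate — segmentation errors, uneven
staining, anisotropic imaging resolution, track breakage and identity
swaps, real tissue deformation — bounds what passing tests show: they
validate the algorithms under clean geometry and known dynamics, not
robustness to every imaging artefact.

# Scaled experiment sizes

Recovery and registration experiments are sized for a desk-scale run while
keeping the statistical structure of the full problem: 24 fitting cells
(within the 10–200 range used at reference scale), 64 walkers × 2500 steps
for the recovery fit, 500-point clouds and 100 random rigid perturbations
for registration, brute-force oracles on ≤ 100-cell instances. The MAP
network from the scaled fit recovers every strong interaction sign and
reaches per-gene live-model RMS well under 0.05 — about an order of
magnitude below the likelihood σ.

# Known limitations

* AGETs inherit the assumption that expression is a smooth function of
  position pooled across fixed samples; genuinely cell-autonomous
  heterogeneity is averaged away by the neighbour median.
* The numeric ICP gate replaces visual QC with two thresholds; badly
  deformed but low-residual alignments would pass it.
* The K-S window rule is a pragmatic stationarity check, not a guarantee of
  mixing; multimodal posteriors can pass it within one mode. Independent
  replicate runs (the `replicates` config field) are the defence.
* Parameter identifiability is partial: genes whose inputs barely vary
  across the fitted cells constrain their incoming weights weakly, which is
  why only strong-interaction signs (|weight| ≥ 5) are asserted in
  recovery experiments.
* The posterior is multimodal (notably sign-swapped modes between the two
  correlated signal inputs), and an ensemble initialized in a small region
  can collapse into one local mode that stretch moves never leave —
  extending such a chain does not help. Independent replicate chains with
  fresh initializations, keeping the best-scoring mode, are the practical
  defence; the reproduction script runs two.
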