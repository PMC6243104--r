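---
title: "Markov state models of loop dynamics: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Markov state models of loop dynamics: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(loopmsm)
```

`loopmsm` estimates discrete-state kinetic models of protein loop
conformational dynamics — the kind of analysis used to ask whether a flexible
receptor loop (for instance the hypervariable CDR3 loops of a T cell
receptor) interconverts between a small number of long-lived, crystal-like
conformational states in solution. This vignette explains the model behind
each stage, the tunable parameters and their defaults, the synthetic world
used for validation, and the numerical choices that were genuinely open.

## The model

The input is an ensemble of molecular dynamics trajectories, treated as
independent realizations of a stationary stochastic process, and a loop
selection. The analysis chain is:

1. **Featurization.** Backbone torsions φ and ψ of the loop residues,
   computed per frame. Torsions are the natural internal coordinates for
   loop conformational change: they are invariant to rigid-body motion and
   capture backbone rearrangement directly.
2. **tICA.** Time-lagged independent component analysis finds the linear
   combinations of features with the slowest autocorrelation: it solves the
   generalized eigenproblem $C_\tau v = \lambda C_0 v$, where $C_0$ is the
   instantaneous covariance of the (mean-centered) features and
   $C_\tau = \tfrac12 (\hat C_\tau + \hat C_\tau^{\mathsf T})$ is the
   symmetrized lagged covariance. Eigenvalues are autocorrelations of the
   projected coordinates at the lag; eigenvectors are $C_0$-orthonormal so
   every component has unit variance at lag zero.
3. **Density landscape.** Gaussian kernel density estimates of the leading
   tICA coordinates, with the full-covariance Scott's-Rule bandwidth
   $H = n^{-2/(d+4)}\,\hat\Sigma$. Local maxima of the 2-D density are the
   visual signature of metastable conformational islands.
4. **Microstates.** K-medoids (PAM) clustering under the Euclidean metric
   in the retained tICA space discretizes the frames into microstates.
5. **Microstate MSM.** Transitions between microstates are counted with a
   sliding window at lag τ, strictly within trajectories. The reversible
   maximum-likelihood transition matrix maximizes
   $\prod_{ij} T_{ij}^{c_{ij}}$ subject to detailed balance
   $\pi_i T_{ij} = \pi_j T_{ji}$, via the standard fixed-point iteration on
   unnormalized edge weights. Reversibility is the default because the
   equilibrium populations reported downstream presuppose a real spectrum
   and a meaningful stationary distribution.
6. **Lag selection.** Implied timescales $t_i(\tau) = -\tau / \ln
   \lambda_i(\tau)$ are scanned over a lag grid; the model lag is the
   smallest lag beyond which the slowest timescales are lag-stable (relative
   change below 10% between successive grid points, through the end of the
   grid). If no lag qualifies the pipeline *reports* non-convergence and
   stops the kinetic analysis — the honest outcome when the slowest motion
   exceeds the sampled timescales, as happens for very slow loops.
7. **Macrostates.** PCCA+ groups microstates into $m$ metastable
   macrostates using the $m$ dominant right eigenvectors, which for a
   reversible chain form a simplex whose vertices are the metastable
   aggregates. The inner simplex algorithm picks the vertex microstates;
   memberships are the linear map sending those vertices to unit vectors,
   clipped to the probability simplex; crisp states are row argmax. The
   macrostate count is read off the timescale spectrum: $m$ = 1 + the
   number of slow timescales before the largest relative gap.
8. **Macrostate MSM.** Micro labels are mapped through the crisp
   assignment and a second MLE model is estimated at an independent,
   longer lag; its off-diagonal entries are the jump probabilities between
   macrostates within one macro lag, and its stationary distribution gives
   the equilibrium populations. Both the eigen-analysis populations and the
   membership-aggregated micro populations ($\chi^{\mathsf T}\pi_{micro}$)
   are emitted, since the two conventions differ slightly in general.
9. **Structural characterization.** Per-macrostate: centroid frames (the
   member minimizing summed tICA-space distance to the rest of its state),
   φ/ψ tables in degrees, hydrogen-bond occupancies, and Shrake–Rupley
   solvent-accessible surface area of the loop. External conformations
   (e.g. bound crystal structures) are projected into the trained tICA
   space with `project_external()` for overlay on the density landscape,
   and `nearest_frame_by_rmsd()` finds the closest simulated frame after
   Kabsch superposition of a stable domain.

## Parameters that matter

| parameter | default | units | notes |
|---|---|---|---|
| `frame_interval` | required | ns | time between saved frames; never stored in trajectory files, so it must be supplied |
| `tica_lag_ns` | 5 | ns | lag of the tICA covariance pair |
| `n_components` | 16 | — | retained tICA components (`"var90"` picks the smallest k with ≥90% cumulative eigenvalue fraction) |
| `n_clusters` | 32 | — | k-medoids microstates; 16 suits a simpler loop |
| `micro_lag_ns` | 8 | ns | microstate MSM lag (`"auto"` = implied-timescale choice) |
| `macro_lag_ns` | 115 | ns | macrostate MSM lag, deliberately independent of the micro lag |
| `its_tolerance` | 0.10 | — | relative change defining timescale convergence |
| `hbond_dist`, `hbond_angle` | 3.2, 20 | Å, deg | donor–acceptor distance; D–H···A deviation from linearity |
| `sasa_probe`, `sasa_points` | 1.4, 960 | Å, — | probe radius; fixed golden-section sphere points |
| `mode_prominence` | 0.05 | — | density-mode threshold as a fraction of the global maximum |
| `seed` | 2018 | — | governs every stochastic stage (k-medoids seeding, synthetic generation) |

All lags are specified in ns and converted once through `frame_interval`
(non-integer ratios are rounded with a warning). Internally angles are
radians on $(-\pi, \pi]$, frames are indexed from 1 (R convention), and
coordinates are Å.

## Circular embedding: a deliberate deviation

Raw dihedral angles have a branch cut at ±π where a small physical motion
appears as a jump of 2π, which makes linear covariance analysis ill-defined
for angles that visit that neighborhood. The default pipeline therefore
embeds each angle as the pair (sin θ, cos θ) before tICA; the embedding is
invertible up to angle identity and doubles the feature dimension. A
config switch (`embed = "raw"`) restores analysis on raw angles for
loops that provably stay away from the cut.

## The synthetic world, and what a green test establishes

`default_4state_spec()` defines the stated validation world: a hidden
Markov chain over K = 4 metastable states at the frame level with

- transition matrix (frame lag, `frame_interval` 1 ns):
  self-transition probabilities 0.9865–0.995; implied timescales 128, 107
  and 55 frames (three slow processes, well separated from frame-level
  noise); stationary distribution (0.07, 0.17, 0.30, 0.47), i.e. one
  dominant state and one sparsely populated state;
- a hub-like state 2, the only state exchanging directly with all others;
- independent von Mises emissions per angle (κ = 25, circular sd ≈ 11.5°,
  a realistic within-basin backbone fluctuation) around four backbone
  conformations that differ in most of the 12 φ/ψ angles of a six-residue
  loop;
- 10 trajectories × 30,000 frames, all randomness from one seed.

The frame interval of 1 ns was chosen so the default analysis lags
(5/8/115 ns) probe the same regimes relative to the slow timescales as in
a real loop analysis; this is what makes the default config testable
end-to-end without modification.

What the generator does **not** emulate: intra-state correlations between
angles (emissions are independent given the hidden state), non-Markovian
memory within states, Cartesian geometry (no loop closure — synthetic data
are dihedral-only, so structural stages are exercised separately on
constructed Cartesian fixtures), and sampling non-stationarity. A green
end-to-end test therefore establishes that the estimator chain recovers
the kinetic structure it assumes, not that the assumptions hold for any
particular force field or loop.

## Numerical choices

- **Covariance estimation** uses the symmetric estimator (statistics of
  the leading and trailing frame sets averaged), which together with
  symmetrizing $C_\tau$ keeps the spectrum real; $C_0$ receives diagonal
  shrinkage $10^{-6}\,\mathrm{tr}(C_0)/d$ before the Cholesky-based solve.
  Eigenvector signs are fixed by making the largest-magnitude loading
  positive.
- **K-medoids**: k-means++-style seeding on medoids under the config seed;
  PAM alternation to a label fixed point or 100 sweeps; assignment ties go
  to the lowest medoid index and medoid-update ties to the earliest
  (trajectory, frame) — stated so tests can be exact. Empty clusters keep
  their medoid.
- **Reversible MLE** iterates to an elementwise change in T below 1e-12
  (cap 10⁶ iterations); states outside the largest strongly connected
  component of the count graph are trimmed first and reported.
- **PCCA+** refuses degenerate spectra (eigenvalue tie at the cut within
  1e-10) with an error suggesting a different m, rather than silently
  picking an arbitrary rotation. Macrostates are renumbered by decreasing
  population so labels are deterministic.
- **Mode finding** uses strict 8-neighborhood maxima with a height
  threshold relative to the global maximum ("prominence" in the simple
  height sense); the KDE grid spans the data range ± 3 marginal bandwidths
  at 128 nodes per axis.
- **SASA** uses Bondi radii and 960 deterministic golden-section sphere
  points; absolute values can differ by a few percent from tools with
  different internal radii, which is why cross-state *differences* are the
  meaningful readout.
- **Desk-scale controls**: when stacked data exceed `max_cluster_frames`
  (20,000), clustering runs on an evenly strided subset and all frames are
  then assigned to the fitted medoids; KDE and centroid searches have
  analogous caps. The underlying functions are exact on whatever data they
  are handed — subsampling is purely a pipeline/config concern.
- **Serialization**: the tICA archive stores doubles as `%.17g` strings,
  which round-trips IEEE 754 exactly; plain JSON numbers (15 significant
  digits) do not.

## Known limitations

- No Bayesian error bars on transition matrices, no hidden-Markov MSMs,
  no transition-path-theory fluxes; jump probabilities are reported
  instead of committor-based rates.
- The relationship between the microstate lag (8 ns) and the much longer
  macrostate lag (115 ns) is treated as two independent config values;
  no attempt is made to reconcile them.
- XTC and Amber NetCDF trajectory formats are not read (no suitable
  reader available in the target environment); PDB and DCD are.
- Hydrogen-bond detection requires explicit hydrogens; there is no
  heavy-atom-only fallback.
- Cluster-count sensitivity is real (re-clustering can change per-residue
  detail); the pipeline exposes `n_clusters` and `seed` sweeps but
  prescribes no selection criterion.
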