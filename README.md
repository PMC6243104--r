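# loopmsm

Markov state model (MSM) analysis of protein loop conformational dynamics
in R.

Flexible receptor loops — the canonical example being the hypervariable
CDR3 loops of αβ T cell receptors — may interconvert between a small number
of long-lived conformational states in solution, a question central to
conformational-selection vs induced-fit pictures of molecular recognition.
`loopmsm` turns an ensemble of molecular dynamics trajectories of such a
loop into a discrete-state kinetic model and per-state structural report:

1. backbone φ/ψ dihedral featurization of a selected loop, with a
   (sin, cos) circular embedding;
2. time-lagged independent component analysis (tICA): the generalized
   eigenproblem `C_tau v = lambda C0 v` between instantaneous and
   lag-τ feature covariances, yielding the slowest collective coordinates;
3. Gaussian KDE landscapes (Scott's-Rule bandwidth) of the leading tICs
   and detection of metastable density islands;
4. k-medoids microstate clustering in tICA space;
5. reversible maximum-likelihood transition matrices
   (`pi_i T_ij = pi_j T_ji`), implied timescales
   `t_i(tau) = -tau / ln lambda_i(tau)` with convergence-based lag
   selection;
6. PCCA+ coarse-graining into metastable macrostates, with equilibrium
   populations and inter-state jump probabilities;
7. per-macrostate structure: centroid conformations, φ/ψ tables,
   hydrogen-bond occupancy (3.2 Å / 20° criterion), Shrake–Rupley SASA
   (1.4 Å probe), and projection of external (e.g. bound crystal)
   conformations onto the simulation landscape.

A hidden-Markov von Mises generator of synthetic dihedral trajectories
(`default_4state_spec()`, `generate_hmm_trajectories()`) provides a stated
validation world with known metastable structure, so the entire pipeline is
tested by parameter recovery without any external data.

## Worked example

Recover a four-state loop from the built-in synthetic world (10
trajectories × 30,000 frames at 1 ns/frame):

```r
library(loopmsm)

cfg <- analysis_config(
  input = list(type = "synthetic", spec = default_4state_spec(2018)),
  seed  = 2018
)
man <- run_pipeline(cfg, "run_4state")

man$status$n_macrostates
#> [1] 4
man$status$n_modes_tic12          # modes of the tIC1-tIC2 density landscape
#> [1] 4
round(man$status$recovery$ari, 3) # agreement with the true hidden states
#> [1] 0.988
read.csv("run_4state/macrostate_populations.csv")
#>   macrostate   pi_eigen pi_membership
#> 1          1 0.47174568    0.47135430
#> 2          2 0.29842842    0.29560585
#> 3          3 0.16036857    0.16237732
#> 4          4 0.06945734    0.07066253
render_reports("run_4state")      # density, macrostate-network, phi/psi figures
```

The four estimated equilibrium populations match the generator chain's
stationary distribution (0.47, 0.30, 0.16, 0.07) to within an L1 error of
0.015 (macrostates are numbered by decreasing population; exact digits vary
with the seed). For real data, replace `input` with
`list(type = "trajectories", paths = <DCD files>, topology = <PDB>,
frame_interval = <ns>)` and give a loop selection such as
`selection = "92-97,205-210"` (contiguous residue numbering across chains)
or `"A:92-97,B:205-210"` (author numbering per chain).

A command-line driver with the same capabilities is installed at
`system.file("cli/loopmsm", package = "loopmsm")`
(subcommands `run`, `synth`, `report`, and stage-limited runs;
`--config`, `--outdir`, `--seed`).

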