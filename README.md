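# tetradyn

Multi-scale rigidity and flexibility analysis of oligomeric proteins from
molecular dynamics trajectories.

## What it is for

Comparing homologous proteins — the canonical case being a mesophilic
versus a thermophilic tetrameric malate dehydrogenase, simulated at two
temperatures in monomeric and tetrameric form — requires quantifying
"rigidity" at several length- and time-scales at once. `tetradyn` takes a
topology (PDB) plus a coordinate trajectory (DCD, multi-model PDB, or XYZ)
and computes, per system:

* **Windowed RMSF** — per-atom fluctuations from a double time average over
  non-overlapping blocks of length τ_w (0.1–5 ns sweep), with block-to-block
  variability, temperature derivatives, and the monomer→tetramer stiffening
  pattern (residues whose relative RMSF drop exceeds a threshold).
* **Conformational substates** — leader-algorithm clustering of frames on
  pairwise superposed all-heavy-atom RMSD, and an exponential saturation
  fit `n(t) = N∞ (1 − exp(−t/τ))` giving the number of reachable substates
  and their saturation time.
* **Collective variables** — radius of gyration, RMSD to a reference,
  fraction of native contacts `Q = ⟨m_i/n_i⟩` (5 Å side-chain heavy-atom
  contacts, > 3 residues apart in sequence), fraction of native φ/ψ
  torsions, and catalytic-pocket RMSD to apo/holo reference states.
* **Internal diffusion** — `D = ⟨δξ²⟩ / τ_ξ` for any CV under the harmonic
  approximation, with τ_ξ from a single-exponential fit to the
  autocorrelation function.
* **Interfaces** — decomposition of a tetramer into the m/d/c interface
  classes, interdomain ion-pair and hydrogen-bond timelines (mean ± sd
  counts, per-pair occupancies), occupancy-weighted salt-bridge networks,
  hydrophobic/hydrophilic/mixed interface-surface fractions from radical
  Voronoi facets, and a hydrophobic proximity census.
* **Volumetrics** — per-atom volumes by radical Voronoi tessellation
  (exact convex-cell clipping; periodic boxes partition exactly, open
  domains are closed by a generated solvent-probe shell) and intrinsic
  compressibility `β_T = ⟨δV²⟩ / (k_B T ⟨V⟩)` in 10⁻² GPa⁻¹.

A synthetic-trajectory generator (Ornstein–Uhlenbeck fluctuations,
conformer hopping, telegraph contacts, toy tetramers with designed
interfaces) provides exactly known ground truth, and the entire test suite
validates every estimator against it or against brute-force oracles.

## Worked example

Two synthetic systems with designed rigidity contrast — a two-state
"rigid" system and a five-state "flexible" one — run through the
comparative pipeline:

```r
library(tetradyn)
set.seed(1)
s <- make_toy_structure(n_chains = 1, n_res = 6)
deform <- function(amp) set_coords(s, s$xyz +
  matrix(rnorm(n_atoms(s) * 3, 0, amp), ncol = 3))
rigid <- make_hopping_trajectory(list(s, deform(2)),
  rbind(c(0.8, 0.2), c(0.2, 0.8)), jitter = 0.05, n_frames = 150, seed = 2)
flexible <- make_hopping_trajectory(c(list(s), lapply(1:4, function(i)
  deform(3))), matrix(0.2, 5, 5), jitter = 0.05, n_frames = 150, seed = 3)

reps <- run_pipeline(list(
  output_dir = file.path(tempdir(), "demo"),
  systems = list(list(label = "rigid", trajectory_object = rigid),
                 list(label = "flexible", trajectory_object = flexible)),
  analyses = list(cluster = list(cutoff = 1.3))))
compare_systems(reps)
#>       metric       rigid    flexible ratio_flexible
#> 1 n_clusters 2.000000000 5.000000000       2.500000
#> 2      n_inf 2.003024701 5.004542366       2.498493
#> 3    tau_sat 0.002751073 0.003481661       1.265564
```

The cluster counts recover the designed numbers of conformers exactly and
the `N∞` ratio (2.5) quantifies the rigidity contrast. Ground-truth
recovery on an OU trajectory (σ = 0.5 Å per coordinate, τ_c = 20 ps):

```r
traj <- make_ou_trajectory(s, sigma = 0.5, tau_c = 20, n_frames = 20000,
                           dt = 1, seed = 4)
prof <- rmsf_windowed(traj, "calpha", window = 5000, fit = FALSE)
mean(prof$rmsf) / sqrt(3)   # per-coordinate amplitude: 0.501 A
cv <- new_cv_series("x", traj$xyz[, 1], traj$times, "A")
diffusion_coefficient(cv, skip = 0)
#> <DiffusionEstimate 'x'> <dxi^2> = 0.2389, tau = 0.01926 ns, D = 12.4 /ns
```

against the analytic truth σ² = 0.25 Å², τ = 20 ps, D = σ²/τ_c = 12.5 Å²/ns.

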