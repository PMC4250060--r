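---
title: "Multi-scale rigidity analysis of oligomeric proteins"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-scale rigidity analysis of oligomeric proteins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tetradyn)
```

## The scientific problem

Thermophilic enzymes are often assumed to be mechanically more rigid than
their mesophilic homologues at ambient temperature — the *corresponding
states* picture, in which the flexibility required for catalysis is only
recovered near the organism's working temperature. For oligomeric enzymes
such as tetrameric malate dehydrogenase (a dimer of dimers with chains A, B,
C, D), rigidity is a multi-scale property: atomistic fluctuations, the size
of the explored conformational-substate network, the kinetics of collective
motions, and the packing and electrostatics of the monomer–monomer
interfaces can each tell a different story. `tetradyn` implements the
post-processing side of such a comparison: it takes a topology (PDB) plus a
coordinate trajectory and quantifies rigidity at every one of those levels,
for any pair (or larger set) of systems one wishes to compare — e.g. a
mesophilic versus a thermophilic tetramer at two temperatures, in monomeric
and tetrameric form.

The package deliberately does **not** run molecular dynamics. Simulations
of solvated tetramers at the hundred-nanosecond scale are an external input;
everything here operates on their frames. Because such trajectories are
rarely shippable, the package also contains a synthetic-trajectory generator
with exactly known statistical ground truth, and its whole test suite runs
against that generator.

## Observables and models

### Collective variables

Four scalar CVs summarize a conformation:

* **Radius of gyration** `Rg = sqrt(mean_i |r_i - rbar|^2)` with the
  *unweighted* mean position `rbar` — no mass weighting.
* **RMSD to a reference** after least-squares superposition of the selected
  atoms (Kabsch algorithm via SVD with reflection correction, so the fitted
  rotation is always proper).
* **Fraction of native contacts Q**: for every side-chain heavy atom, its
  native partners are the side-chain heavy atoms within 5 Å in the
  reference structure and more than 3 residues away in sequence;
  `Q = mean_i m_i / n_i` over atoms with `n_i > 0`, where `m_i` counts
  partners still within the same cutoff at time *t*. No hysteresis: the
  5 Å criterion is reused verbatim at analysis time.
* **Fraction of native torsions A**: the share of backbone φ/ψ dihedrals
  within a circular tolerance of their reference values, counted per angle.
  The tolerance defaults to 60°, a standard native-dihedral window, and is
  configurable; deviations always use the shorter arc.

Both Q and A equal 1 on the reference configuration by construction, and
both are invariant under global rotation and translation — properties the
test suite asserts directly.

### Windowed RMSF

Atomistic flexibility is measured as a double time average: the trajectory
is cut into non-overlapping blocks of length τ~w~; within each block the
squared deviation of each atom from its block-mean position is averaged,
then the outer average runs over blocks and RMSF is the square root. The
window length (default sweep 0.1–5 ns) sets the timescale probed: an
atom whose motion decorrelates over τ~c~ contributes its full stationary
variance only once τ~w~ ≫ τ~c~, so RMSF(τ~w~) is monotone nondecreasing.
The block-to-block standard deviation is reported as the long-timescale
variability.

Each block is superposed onto its own mean structure before deviations are
measured (two fit iterations), so only internal motion within the window is
counted. This fitting deliberately becomes optional (`fit = FALSE`):
on synthetic trajectories whose fluctuations are stationary in the lab
frame and carry no rigid-body component, fitting is not only unnecessary
but slightly biased — a rigid-body fit on N atoms absorbs about 6/(3N) of
the true variance into the removed degrees of freedom, which matters for
the small test systems. The ground-truth recovery runs therefore use
`fit = FALSE`; real trajectories should keep the default.

A note on conventions: the generator's `sigma` is the stationary standard
deviation *per Cartesian coordinate*, so the three-dimensional per-atom
RMSF converges to `sqrt(3) * sigma`. Recovery checks compare
`RMSF/sqrt(3)` against `sigma`.

### Conformational substates: leader clustering

The number of distinct conformational substates visited, n(t), is counted
with the classic single-pass leader algorithm on pairwise superposed RMSD
(all heavy atoms by default; a Cα metric and per-chain clustering are
provided for robustness checks). A frame joins the first leader within the
cutoff, in leader-creation order — the textbook tie-break, chosen for
determinism. The default cutoff is 1.3 Å and a sweep utility documents
how the count responds to the cutoff (it is monotone nonincreasing).

The growth curve is summarized by a nonlinear least-squares fit of
`n(t) = N_inf * (1 - exp(-t/tau))`, giving the extrapolated number of
substates and their saturation time. Initialization uses
`N_inf0 = max n(t)` and `tau0` = time to half of that; when the
Levenberg–Marquardt fit degenerates (near-step growth curves make the
Jacobian singular) the implementation falls back to profiled least squares —
`N_inf` is linear given `tau`, leaving a robust 1-D minimization. A
constant n(t) is flagged (`tau` undefined) rather than fitted.

### Internal diffusion of a CV

Under the harmonic approximation, the internal diffusion coefficient of a
CV is `D = <delta xi^2> / tau_xi`: the stationary variance divided by the
decorrelation time from a single-exponential fit to the normalized
autocorrelation function. Numerical choices: the ACF is computed (mean
removed, variance normalized) to a maximum lag of 10 % of the series — long
lags are variance-dominated; the exponential is fitted without an additive
offset over lags up to the first crossing of e^-2, beyond which noise
dominates; an RMS-residual diagnostic flags oscillating or nonmonotone
ACFs. A transient stretch (default 10 ns) is discarded before everything.
D is invariant under shifting the CV and quadratic under scaling it, and on
OU-generated series (σ², τ~c~) the triple (variance, τ, D) recovers
(σ², τ~c~, σ²/τ~c~) — both verified in the tests.

### Interfaces of a tetramer

A dimer-of-dimers tetramer has three interface classes, each the sum of two
chain pairs: the intra-dimer interface m = {A–B, D–C} and two cross-dimer
classes covering {A–D, B–C} and {A–C, B–D}. Which of the two cross-dimer
pairings is called *d* and which *c* is a geometric convention of the
particular assembly (it is defined pictorially, not algebraically), so the
mapping is a configuration option recorded on the result, never hard-coded.

Per frame and per interface the package counts:

* **Ion pairs** — any basic side-chain nitrogen (Arg NE/NH1/NH2, Lys NZ,
  His optionally when protonated) within 4.0 Å of any acidic carboxylate
  oxygen (Asp OD1/OD2, Glu OE1/OE2), across chains, counted once per
  residue pair. 4.0 Å N–O is the common salt-bridge convention; the cutoff
  is exposed as a parameter.
* **Hydrogen bonds** — donor/acceptor heavy atoms within 3.5 Å plus an
  angular criterion: D–H···A ≥ 150° with explicit hydrogens, or the
  antecedent–donor–acceptor angle ≥ 120° as a heavy-atom proxy. Donors and
  acceptors come from residue templates (backbone amide/carbonyl plus polar
  side chains); unknown residue types are skipped with a warning.

Timelines aggregate per-frame counts (mean ± sd for table-style reporting;
the per-frame mean is reported alongside a distinct-pair census, since a
time average and a pair census answer different questions), per-pair
occupancies, and an occupancy-weighted salt-bridge network (nodes =
charged residues weighted by the time they form any interdomain ion pair,
edges weighted by pair occupancy, built on igraph).

**Interface surface classes.** The interfacial area is decomposed by the
chemistry of the facing atoms using the facets of a radical (power) Voronoi
tessellation: every facet separating two atoms of different chains that are
within solvent-probe contact (distance ≤ r_i + r_j + 2·1.4 Å) contributes
its area as hydrophobic–hydrophobic (both atoms C or S),
hydrophilic–hydrophilic (both N or O) or mixed. Fractions are normalized
to sum to exactly 1 per interface, which makes systems with different total
interface areas comparable; absolute areas are also returned. The method
("voronoi-facets") is recorded in the output, since contact-area
approximations would give slightly different numbers.

### Volumetrics and intrinsic compressibility

Per-atom volumes come from the same radical Voronoi construction: each
atom's cell is the intersection of half-spaces against its neighbors'
power-weighted bisector planes, built by direct convex-polyhedron clipping
(nearest neighbors first, stopping when the next bisector lies beyond the
farthest remaining vertex). In a periodic box the cells partition the box
exactly — the tessellation-closure test holds to 10^-6 relative — and in an
open domain a generated solvent-probe shell at 2.8 Å offset from the
molecular surface closes the outer cells; a still-unbounded cell is a hard
error rather than a silently wrong volume.

The intrinsic compressibility uses the standard equilibrium-fluctuation
formula `beta_T = <dV^2> / (k_B T <V>)`, reported in 10^-2 GPa^-1. The
formula and unit convention are embedded in the output metadata because
different volumetric tools apply different boundary corrections; the value
scales as stated with T and the moments (halving with doubled temperature
at fixed fluctuations), and a constant series returns 0 with a warning.

## The synthetic-data generator

The generator produces the three statistical archetypes the estimators
assume, with the ground truth attached to every trajectory (and exportable
as a JSON sidecar):

* `make_ou_trajectory()` — independent, exactly discretized stationary
  Ornstein–Uhlenbeck motion per coordinate about the reference positions:
  `x(t+dt) = x(t) e^(-dt/tau_c) + eta`,
  `eta ~ N(0, sigma^2 (1 - e^(-2 dt/tau_c)))`, initialized from the
  stationary law. This is the ground truth for RMSF and diffusion.
* `make_hopping_trajectory()` — a discrete Markov chain over K conformers
  plus Gaussian jitter; conformers must be separated by more than 3× the
  jitter. Ground truth for clustering.
* `make_contact_telegraph()` — designed interfacial contacts toggling
  between bound and unbound geometry as independent two-state chains with
  stationary occupancy `p_on/(p_on + p_off)`. Ground truth for timelines.

`make_toy_structure()` builds the chains these run on: zig-zag backbones
folded into two antiparallel strands 4.8 Å apart (so sequence-distant
residues are spatial neighbors and the native-contact CV has real
contacts), minimal but chemically resolvable side chains, four chains on a
2×2 grid with 20 Å axis separation, and designed interfacial contacts whose
functional tip atoms are placed at exact distances. Each charged residue
carries exactly one charged atom group, so ion-pair criteria are
unambiguous.

What the generator does *not* emulate: excluded volume, solvent, bonded
geometry under deformation (an "unbound" side chain is translated, not
re-built), correlated inter-atom motion, and anharmonicity. Passing the
recovery tests therefore demonstrates estimator correctness — that the
implementations measure what they claim on data whose truth is known — not
force-field-level realism. Conclusions about real proteins still require
real trajectories.

Reproducibility: one seeded generator per trajectory, consumed in a
documented order; the same seed gives bit-identical output.

## Validation conditions and problem sizes

The recovery runs use, as the package's standard validation conditions:
OU with σ = 0.5 Å, τ~c~ = 20 frames, 10^5 frames × 20 seeds (σ within 5 %,
τ within 10 %, D within 15 %); hopping with K ∈ {2, 5, 10} conformers over
200 frames checked frame-by-frame against a brute-force leader oracle built
on an independent RMSD routine; saturation fits exact to 10^-6 on noiseless
curves and within 10 % median error across 50 replicates at 5 %
multiplicative noise; interface detectors checked against O(N²)
enumeration oracles on random charged decoys (~10³ atoms) and telegraph
occupancies within 3σ binomial bounds (the telegraph runs use
`p_on + p_off = 1`, which makes the chain memoryless so the binomial bound
is exact); tessellation closure to 10^-6; CV identities exactly.
These sizes keep the whole suite and the acceptance script within a few
minutes on one CPU while leaving comfortable statistical margins.

## Design decisions on genuinely open points

* **Torsion criterion**: per-angle counting with a configurable 60°
  circular tolerance. Per-residue counting (both φ and ψ native) is a
  stricter alternative; per-angle was chosen as the more granular and more
  common convention.
* **Native contacts** are intrachain by default ("referring to the whole
  chain"); an interchain mode exists but is off by default.
* **Clustering cutoff** defaults to 1.3 Å with a sweep utility, since the
  appropriate value depends on system size and metric selection.
* **ACF fit offset**: the exponential is fitted without an additive offset;
  an offset can mask slow drift as a baseline, and the residual diagnostic
  reports when a plain exponential is inadequate.
* **d/c labeling** of the cross-dimer interfaces is configurable (see
  above).
* **Waters/het groups** are excluded from all protein selection classes by
  default; the `all` class keeps them reachable.
* **Command-line interface**: the package is an R analysis library in the
  bio3d tradition; its users drive it from R via `run_pipeline()` /
  `compare_systems()` and the exported stage functions, so no shell
  subcommand binary is shipped.

## Worked example

```{r example}
set.seed(1)
# a rigid two-state system vs a flexible five-state system
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
```

The substate count and its ratio quantify exactly the kind of
rigidity contrast the comparative workflow is built to expose.

## Known limitations

* The leader algorithm is order-dependent by definition; cluster counts
  from trajectory reorderings differ. This matches its standard use for
  n(t) growth curves, not a limitation introduced here.
* The Voronoi construction is exact but pure R; per-frame volumetrics on
  systems beyond a few thousand atoms is the slowest stage. Restrict the
  selection or subsample frames for long trajectories.
* The heavy-atom hydrogen-bond proxy (120° antecedent angle) is more
  permissive than the explicit-hydrogen criterion; counts from the two
  modes should not be mixed in one comparison.
* DCD reading is delegated to bio3d and inherits its dialect support;
  frame times always come from the user-supplied `dt`.
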