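Package: tetradyn
Title: Rigidity and Flexibility Analysis of Oligomeric Proteins from
    Molecular Dynamics Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Post-processing toolkit for comparing the mechanical rigidity of
    homologous oligomeric proteins (e.g. mesophilic versus thermophilic
    tetrameric malate dehydrogenase) from molecular dynamics trajectories.
    Implements windowed root mean square fluctuations across timescales,
    leader-algorithm conformational clustering with exponential saturation
    fits, internal diffusion coefficients of collective variables under the
    harmonic approximation (fraction of native contacts, native torsions,
    radius of gyration, RMSD), tetramer interface decomposition with ion-pair
    and hydrogen-bond timelines and occupancy networks, Voronoi volumetrics
    with intrinsic compressibility, and a synthetic-trajectory generator
    (Ornstein-Uhlenbeck fluctuations, conformer hopping, telegraph contacts)
    with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    igraph,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
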