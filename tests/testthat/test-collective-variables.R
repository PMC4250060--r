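test_that("radius of gyration matches exact geometry", {
  expect_equal(radius_of_gyration(matrix(c(1, 2, 3), 1, 3)), 0)
  cube <- as.matrix(expand.grid(c(-0.5, 0.5), c(-0.5, 0.5), c(-0.5, 0.5)))
  expect_equal(radius_of_gyration(cube), sqrt(0.75), tolerance = 1e-12)
  expect_error(radius_of_gyration(cube, integer(0)), "empty selection")
})

test_that("superposition is exact on rigid transforms and degenerate input errors", {
  set.seed(21)
  x <- matrix(rnorm(30), 10, 3)
  expect_equal(rmsd_fit(x, x), 0, tolerance = 1e-10)
  th <- 37 * pi / 180
  ax <- c(1, 2, 2) / 3
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0), 3, 3,
              byrow = TRUE)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
  y <- x %*% t(R) + matrix(rep(c(3, -1, 2), each = 10), 10, 3)
  expect_lt(rmsd_fit(y, x), 1e-10)
  fit <- superpose(y, x)
  expect_equal(det(fit$R), 1, tolerance = 1e-10)  # proper rotation
  expect_error(superpose(x[1:2, ], x[1:2, ]), "at least 3")
  line <- cbind(1:5, 2 * (1:5), 3 * (1:5))
  expect_error(superpose(line, line + 1), "collinear")
})

test_that("fitted RMSD matches the brute-force rotation-grid oracle", {
  set.seed(31)
  x <- matrix(rnorm(30), 10, 3)
  y <- matrix(rnorm(30), 10, 3)
  fitted <- rmsd_fit(x, y)
  grid_min <- oracle_grid_rmsd(x, y)
  expect_lte(fitted, grid_min + 1e-9)   # optimum can only improve on the grid
  expect_lt(grid_min - fitted, 0.05)    # and the grid comes close to it
})

test_that("rmsd_series removes rigid-body motion", {
  s <- make_toy_structure(n_chains = 1, n_res = 8)
  flat <- as.vector(t(s$xyz))
  xyz <- rbind(flat, flat + rep(c(5, 0, 0), n_atoms(s)), flat)
  traj <- new_trajectory(xyz, dt = 1, topology = s)
  rs <- rmsd_series(traj, s)
  expect_lt(max(rs$values), 1e-10)
})

test_that("hand-built frame RMSD equals the oracle fit", {
  set.seed(41)
  ref <- matrix(rnorm(12), 4, 3)
  frm <- ref + matrix(rnorm(12, 0, 0.6), 4, 3)
  s <- new_structure(
    data.frame(name = "CA", element = "C", resid = "ALA", resno = 1:4,
               chain = "A", occ = 1), ref)
  traj <- new_trajectory(matrix(as.vector(t(frm)), 1), 1, s)
  got <- rmsd_series(traj, s, selection = 1:4)$values
  expect_equal(got, oracle_grid_rmsd(frm, ref), tolerance = 0.02)
})

test_that("contact reference obeys cutoff and sequence-separation rules", {
  mk <- function(d_space, d_seq) {
    lines <- unlist(lapply(c(1, 1 + d_seq), function(r) {
      b <- (r == 1) * 0 + (r != 1) * 5
      x <- if (r == 1) 0 else d_space
      c(pdb_atom_line(b + 1, "N", "SER", "A", r, x - 1.2, 0.4, 0),
        pdb_atom_line(b + 2, "CA", "SER", "A", r, x, 0.6, 0),
        pdb_atom_line(b + 3, "C", "SER", "A", r, x + 1.2, 0.4, 0),
        pdb_atom_line(b + 4, "O", "SER", "A", r, x + 1.3, 1.4, 0.9),
        pdb_atom_line(b + 5, "OG", "SER", "A", r, x, 0.6, 1.5))
    }))
    read_structure(write_pdb_fixture(lines))
  }
  near_far <- build_contact_reference(mk(4.9, 5))   # 4.9 A apart, 5 residues
  og <- which(near_far$n > 0)
  expect_length(og, 2)                              # the two OG atoms pair up
  near_close <- build_contact_reference(mk(4.9, 2)) # only 2 residues apart
  expect_true(all(near_close$n == 0))
})

test_that("contact reference equals the O(N^2) oracle on a toy peptide", {
  s <- make_toy_structure(n_chains = 1, n_res = 12)
  ref <- build_contact_reference(s)
  orc <- oracle_contacts(s)
  expect_equal(ref$atoms, orc$atoms)
  expect_equal(ref$partners, orc$partners)
  # symmetry of partner lists
  for (i in seq_along(ref$partners)) {
    for (j in ref$partners[[i]]) expect_true(i %in% ref$partners[[j]])
  }
})

test_that("Q is 1 on the reference, 0 when exploded, and rotation-invariant", {
  s <- make_toy_structure(n_chains = 1, n_res = 12)
  ref <- build_contact_reference(s)
  expect_equal(fraction_native_contacts(s$xyz, ref), 1)
  far <- s$xyz + cbind(seq(0, 1e4, length.out = n_atoms(s)), 0, 0)
  expect_equal(fraction_native_contacts(far, ref), 0)
  th <- 1.1
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  expect_equal(fraction_native_contacts(s$xyz %*% R + 7, ref), 1)
})

test_that("torsion fraction identities hold and perturbations count per angle", {
  s <- make_toy_structure(n_chains = 1, n_res = 10)
  tref <- build_torsion_reference(s, tolerance = 60)
  expect_equal(fraction_native_torsions(s$xyz, tref), 1)
  # rotation invariance
  th <- 0.8
  R <- matrix(c(1, 0, 0, 0, cos(th), -sin(th), 0, sin(th), cos(th)), 3, 3)
  expect_equal(fraction_native_torsions(s$xyz %*% R - 3, tref), 1)
  expect_error(build_torsion_reference(s, tolerance = 0), "tolerance")
  expect_error(build_torsion_reference(s, tolerance = 200), "tolerance")
})

test_that("circular deviation uses the shorter arc", {
  # 179 vs -179 degrees differ by 2, not 358
  expect_equal(tetradyn:::.circ_dev(179, -179), 2)
  expect_equal(tetradyn:::.circ_dev(-170, 170), 20)
})

test_that("pocket RMSD is zero on its own reference and tracks two states", {
  s <- make_toy_structure(n_chains = 1, n_res = 10)
  # a genuinely deformed holo: pocket strand bent in z
  holo_xyz <- s$xyz
  pocket_atoms <- resolve_selection(s, "resno 3:6")
  holo_xyz[pocket_atoms, 3] <- holo_xyz[pocket_atoms, 3] +
    seq(0.5, 2, length.out = length(pocket_atoms))
  holo <- set_coords(s, holo_xyz)
  xyz <- rbind(as.vector(t(s$xyz)), as.vector(t(holo_xyz)))
  traj <- new_trajectory(xyz, 1, s)
  pr <- pocket_rmsd_to_references(traj, s, holo, "resno 3:6")
  expect_lt(pr$apo$values[1], 1e-10)
  expect_lt(pr$holo$values[2], 1e-10)
  expect_gt(pr$apo$values[2], 0.1)
  # apo<->holo symmetry: frame at holo has apo-RMSD equal to the
  # pocket-backbone RMSD between the two references
  ref_rmsd <- rmsd_fit(holo$xyz, s$xyz,
                       resolve_selection(s, "resno 3:6 and backbone"))
  expect_equal(pr$apo$values[2], ref_rmsd, tolerance = 1e-8)
  expect_error(pocket_rmsd_to_references(traj, s, holo, "resno 9:10"),
               NA)
})

test_that("unmappable pocket residues raise an error listing them", {
  s <- make_toy_structure(n_chains = 1, n_res = 10)
  short <- make_toy_structure(n_chains = 1, n_res = 6)
  traj <- make_ou_trajectory(s, 0.1, 5, n_frames = 3, dt = 1, seed = 2)
  expect_error(pocket_rmsd_to_references(traj, short, short, "resno 7:9"),
               "not mappable")
})
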