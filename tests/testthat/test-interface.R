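tetramer_with_contacts <- function(n_res = 12) {
  make_toy_structure(
    n_chains = 4, n_res = n_res,
    contacts = list(
      list(type = "ip", chain1 = "A", res1 = 3, chain2 = "B", res2 = 3),
      list(type = "ip", chain1 = "A", res1 = 7, chain2 = "B", res2 = 7),
      list(type = "ip", chain1 = "D", res1 = 5, chain2 = "C", res2 = 5),
      list(type = "hb", chain1 = "A", res1 = 9, chain2 = "B", res2 = 9),
      list(type = "phobic", chain1 = "A", res1 = 11, chain2 = "D",
           res2 = 11)))
}

test_that("interface decomposition covers all six chain pairs once", {
  s <- tetramer_with_contacts()
  ifs <- define_interfaces(s)
  expect_named(ifs, c("m", "d", "c"))
  all_pairs <- unlist(lapply(ifs, function(x) {
    vapply(x$pairs, function(p) paste(sort(p), collapse = ""), character(1))
  }), use.names = FALSE)
  expect_setequal(all_pairs, c("AB", "CD", "AD", "BC", "AC", "BD"))
  expect_equal(length(unique(all_pairs)), 6)
  # m is fixed; d/c mapping is configurable
  expect_true(all(c("AB", "CD") %in% all_pairs[1:2]))
  ifs2 <- define_interfaces(s, d_pairing = "AC")
  d2 <- vapply(ifs2$d$pairs, function(p) paste(sort(p), collapse = ""),
               character(1))
  expect_setequal(d2, c("AC", "BD"))
})

test_that("interface decomposition rejects non-tetramers", {
  s <- make_toy_structure(n_chains = 2, n_res = 5)
  expect_error(define_interfaces(s), "4 chains")
})

test_that("designed ion pairs are found and distant chains give zero", {
  s <- tetramer_with_contacts()
  ifs <- define_interfaces(s)
  ip_m <- detect_ion_pairs(s, ifs$m)
  expect_equal(nrow(ip_m), 3)              # A-B x2 plus D-C x1
  expect_setequal(
    ip_m$pair_id,
    c("A:3ARG-B:3GLU", "A:7ARG-B:7GLU", "C:5GLU-D:5ARG"))
  expect_true(all(abs(ip_m$min_dist - 3.0) < 1e-6))
  # the c interface (diagonal chains) has no designed IPs
  expect_equal(nrow(detect_ion_pairs(s, ifs$c)), 0)
})

test_that("ion-pair detection equals the O(N^2) oracle on a random decoy", {
  # random charged decoy: Arg/Lys vs Asp/Glu tips scattered in a box
  set.seed(73)
  n_per <- 60
  mk_rows <- function(chain, types, names_by_type, x0) {
    rows <- list(); xyz <- list(); serial <- 0
    for (r in seq_len(n_per)) {
      res <- sample(types, 1)
      base <- c(x0 + runif(1, 0, 25), runif(1, 0, 25), runif(1, 0, 25))
      for (nm in c("CA", names_by_type[[res]])) {
        serial <- serial + 1
        rows[[serial]] <- data.frame(
          name = nm, element = substr(nm, 1, 1), resid = res, resno = r,
          chain = chain, occ = 1)
        xyz[[serial]] <- base + runif(3, -0.8, 0.8)
      }
    }
    list(atoms = do.call(rbind, rows), xyz = do.call(rbind, xyz))
  }
  tips <- list(ARG = c("NE", "NH1", "NH2"), LYS = "NZ",
               ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))
  a <- mk_rows("A", names(tips), tips, 0)
  b <- mk_rows("B", names(tips), tips, 12)   # overlapping slabs -> contacts
  s <- new_structure(rbind(a$atoms, b$atoms), rbind(a$xyz, b$xyz))
  expect_lte(n_atoms(s), 2000)
  got <- detect_ion_pairs(s, list(c("A", "B")))
  want <- oracle_ion_pairs(s, list(c("A", "B")))
  expect_gt(length(want), 0)              # decoy genuinely has contacts
  expect_equal(pair_keys(got), want)
})

test_that("ion-pair counts are invariant under global rigid motion", {
  s <- tetramer_with_contacts()
  ifs <- define_interfaces(s)
  th <- 0.7
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  s_rot <- set_coords(s, s$xyz %*% R + 11)
  for (lab in names(ifs)) {
    expect_equal(nrow(detect_ion_pairs(s_rot, ifs[[lab]])),
                 nrow(detect_ion_pairs(s, ifs[[lab]])))
  }
})

test_that("hydrogen-bond geometry criteria gate distance and angle", {
  # designed cross-chain donor/acceptor at 2.9 A with a linear antecedent
  mk <- function(d_oo) {
    atoms <- data.frame(
      name = c("CA", "CB", "OG", "CA", "CB", "OG"),
      element = c("C", "C", "O", "C", "C", "O"),
      resid = "SER", resno = c(1, 1, 1, 1, 1, 1),
      chain = c("A", "A", "A", "B", "B", "B"), occ = 1)
    xyz <- rbind(c(-3, 0, 0), c(-1.5, 0, 0), c(0, 0, 0),
                 c(d_oo + 3, 0, 0), c(d_oo + 1.5, 0, 0), c(d_oo, 0, 0))
    new_structure(atoms, xyz)
  }
  expect_equal(nrow(detect_hydrogen_bonds(mk(2.9), list(c("A", "B")))), 1)
  expect_equal(nrow(detect_hydrogen_bonds(mk(4.2), list(c("A", "B")))), 0)
  # bent antecedent geometry (acceptor behind the donor) is rejected;
  # the acceptor side is a bare backbone carbonyl so no reverse H-bond exists
  mk2 <- function(cb_pos) {
    atoms <- data.frame(
      name = c("CB", "OG", "CA", "C", "O"),
      element = c("C", "O", "C", "C", "O"),
      resid = c("SER", "SER", "ALA", "ALA", "ALA"), resno = 1,
      chain = c("A", "A", "B", "B", "B"), occ = 1)
    xyz <- rbind(cb_pos, c(0, 0, 0),
                 c(6.4, 0, 0), c(4.4, 0, 0), c(2.9, 0, 0))
    new_structure(atoms, xyz)
  }
  straight <- mk2(c(-1.5, 0, 0))   # CB-OG...O angle 180 deg
  expect_equal(nrow(detect_hydrogen_bonds(straight, list(c("A", "B")))), 1)
  bent <- mk2(c(1.0, 0.5, 0))      # CB ahead of OG -> angle < 120 deg
  expect_equal(nrow(detect_hydrogen_bonds(bent, list(c("A", "B")))), 0)
})

test_that("explicit-hydrogen D-H...A angle test is honored", {
  atoms <- data.frame(
    name = c("CA", "CB", "OG", "HG", "CA", "CB", "OG"),
    element = c("C", "C", "O", "H", "C", "C", "O"),
    resid = "SER", resno = 1,
    chain = c("A", "A", "A", "A", "B", "B", "B"), occ = 1)
  lin <- rbind(c(-3, 0, 0), c(-1.5, 0, 0), c(0, 0, 0), c(1.0, 0, 0),
               c(5.9, 0, 0), c(4.4, 0, 0), c(2.9, 0, 0))
  expect_equal(nrow(detect_hydrogen_bonds(new_structure(atoms, lin),
                                          list(c("A", "B")))), 1)
  # hydrogen pointing away: D-H...A angle ~ 0
  away <- lin; away[4, ] <- c(-1.0, 0, 0)
  expect_equal(nrow(detect_hydrogen_bonds(new_structure(atoms, away),
                                          list(c("A", "B")))), 0)
})

test_that("timelines report exact occupancies for designed static contacts", {
  s <- tetramer_with_contacts()
  ifs <- define_interfaces(s)
  flat <- as.vector(t(s$xyz))
  traj <- new_trajectory(matrix(rep(flat, 6), 6, byrow = TRUE), 1, s)
  tl <- contact_timelines(traj, ifs$m, type = "ip")
  expect_equal(unname(tl$occupancy), rep(1, 3))
  expect_equal(tl$mean_count, 3)
  expect_equal(tl$sd_count, 0)
})

test_that("telegraph contacts recover the stationary occupancy", {
  s <- make_toy_structure(
    n_chains = 4, n_res = 10,
    contacts = list(
      list(type = "ip", chain1 = "A", res1 = 3, chain2 = "B", res2 = 3),
      list(type = "ip", chain1 = "A", res1 = 7, chain2 = "B", res2 = 7)))
  # memoryless switching (p_on + p_off = 1): stationary occupancy 2/3
  traj <- make_contact_telegraph(s, p_on = 2 / 3, p_off = 1 / 3,
                                 n_frames = 1500, seed = 79)
  ifs <- define_interfaces(s)
  tl <- contact_timelines(traj, ifs$m, type = "ip")
  gt <- attr(traj, "ground_truth")
  # detector reproduces the generator's bound states exactly
  expect_equal(sort(unname(tl$occupancy)), sort(colMeans(gt$bound)))
  # and the sample occupancy sits within 3 sigma binomial of 2/3
  band <- 3 * sqrt(2 / 3 * 1 / 3 / 1500)
  expect_true(all(abs(tl$occupancy - 2 / 3) < band))
  # per-frame count mean ~ sum of occupancies
  expect_equal(tl$mean_count, sum(tl$occupancy), tolerance = 1e-10)
})

test_that("surface classification is normalized and matches designed chemistry", {
  # all-carbon interface -> purely hydrophobic
  s_phob <- make_toy_structure(
    n_chains = 4, n_res = 8, frac_charged = 0, frac_hydrophobic = 1,
    contacts = list(
      list(type = "phobic", chain1 = "A", res1 = 3, chain2 = "B", res2 = 3),
      list(type = "phobic", chain1 = "A", res1 = 6, chain2 = "B", res2 = 6)))
  ifs <- define_interfaces(s_phob)
  sc <- classify_interface_surface(s_phob, ifs$m)
  expect_equal(sum(sc$fractions), 1, tolerance = 1e-6)
  expect_equal(unname(sc$fractions["hydrophobic"]), 1, tolerance = 1e-9)
  # carbon face against oxygen face -> mixed
  atoms <- data.frame(
    name = c("CB", "CB", "OG", "OG"), element = c("C", "C", "O", "O"),
    resid = c("ALA", "ALA", "SER", "SER"), resno = c(1, 2, 1, 2),
    chain = c("A", "A", "B", "B"), occ = 1)
  xyz <- rbind(c(0, 0, 0), c(0, 3, 0), c(4, 0, 0), c(4, 3, 0))
  sm <- classify_interface_surface(new_structure(atoms, xyz),
                                   list(c("A", "B")))
  expect_equal(unname(sm$fractions["mixed"]), 1, tolerance = 1e-9)
  # empty interface errors
  far <- make_toy_structure(n_chains = 4, n_res = 5, gap = 80)
  expect_error(classify_interface_surface(far, define_interfaces(far)$m),
               "interface empty")
})

test_that("surface fractions equal a facet-by-facet tally", {
  s <- tetramer_with_contacts()
  ifs <- define_interfaces(s)
  sc <- classify_interface_surface(s, ifs$m)
  expect_equal(sum(sc$fractions), 1, tolerance = 1e-6)
  expect_equal(sum(sc$areas), sc$total_area, tolerance = 1e-9)
  expect_true(all(sc$areas >= 0))
})

test_that("ion-pair network carries occupancy-weighted nodes and edges", {
  s <- make_toy_structure(
    n_chains = 4, n_res = 10,
    contacts = list(
      list(type = "ip", chain1 = "A", res1 = 3, chain2 = "B", res2 = 3)))
  flat <- as.vector(t(s$xyz))
  traj <- new_trajectory(matrix(rep(flat, 5), 5, byrow = TRUE), 1, s)
  tl <- contact_timelines(traj, define_interfaces(s)$m, type = "ip")
  g <- build_ip_network(tl)
  expect_equal(igraph::vcount(g), 2)
  expect_equal(igraph::ecount(g), 1)
  expect_equal(igraph::E(g)$occupancy, 1)
  expect_equal(unname(igraph::V(g)$occupancy), c(1, 1))
  # node weight >= max incident edge weight by construction
  for (v in igraph::V(g)) {
    inc <- igraph::incident(g, v)
    expect_gte(igraph::vertex_attr(g, "occupancy", v),
               max(igraph::edge_attr(g, "occupancy", inc)))
  }
})

test_that("multi-partner networks resolve partner-specific occupancies", {
  s <- make_toy_structure(
    n_chains = 4, n_res = 12,
    contacts = list(
      list(type = "ip", chain1 = "A", res1 = 3, chain2 = "B", res2 = 3),
      list(type = "ip", chain1 = "A", res1 = 7, chain2 = "B", res2 = 7)))
  traj <- make_contact_telegraph(s, p_on = c(0.6, 0.4), p_off = c(0.4, 0.6),
                                 n_frames = 800, seed = 83)
  tl <- contact_timelines(traj, define_interfaces(s)$m, type = "ip")
  g <- build_ip_network(tl, display_threshold = 0.5)
  expect_equal(igraph::vcount(g), 4)
  expect_equal(igraph::ecount(g), 2)
  gt <- attr(traj, "ground_truth")
  expect_setequal(round(igraph::E(g)$occupancy, 10),
                  round(colMeans(gt$bound), 10))
  expect_equal(sort(unique(igraph::V(g)$chain)), c("A", "B"))
})

test_that("hydrophobic census counts designed patches and equals brute force", {
  s <- make_toy_structure(
    n_chains = 4, n_res = 12,
    contacts = list(
      list(type = "phobic", chain1 = "A", res1 = 3, chain2 = "D", res2 = 3),
      list(type = "phobic", chain1 = "A", res1 = 7, chain2 = "D", res2 = 7)))
  ifs <- define_interfaces(s)
  cen <- hydrophobic_proximity_census(s, ifs$d)
  a_row <- cen[cen$chain == "A" & cen$partner_chain == "D", ]
  expect_equal(a_row$n_hydrophobic, 2)
  # brute-force recount
  a <- s$atoms
  side <- which(a$element != "H" & !(a$name %in% c("N", "CA", "C", "O")) &
                  a$resid %in% c("ALA", "VAL", "LEU", "ILE", "PRO", "PHE",
                                 "MET", "TRP"))
  brute <- length(unique(a$resno[side[vapply(side, function(i) {
    if (a$chain[i] != "A") return(FALSE)
    js <- side[a$chain[side] == "D"]
    any(sqrt(rowSums(sweep(s$xyz[js, , drop = FALSE], 2,
                           s$xyz[i, ])^2)) <= 4.5)
  }, logical(1))]]))
  expect_equal(a_row$n_hydrophobic, brute)
  # distant chains: zero
  far <- cen[cen$chain == "B" & cen$partner_chain == "C", ]
  expect_equal(far$n_hydrophobic, 0)
})
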