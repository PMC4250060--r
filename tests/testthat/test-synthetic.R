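test_that("toy structures expose the requested chains, residues and atoms", {
  s <- make_toy_structure(n_chains = 4, n_res = 30)
  expect_setequal(unique(s$atoms$chain), c("A", "B", "C", "D"))
  expect_length(resolve_selection(s, "name CA"), 120)
  expect_equal(max(s$atoms$resno), 30)
  # impossible composition errors
  expect_error(make_toy_structure(frac_charged = 0.8,
                                  frac_hydrophobic = 0.5),
               "impossible composition")
})

test_that("zero-charge compositions yield no ion pairs anywhere", {
  s <- make_toy_structure(n_chains = 4, n_res = 10, frac_charged = 0)
  ifs <- define_interfaces(s)
  for (lab in names(ifs)) {
    expect_equal(nrow(detect_ion_pairs(s, ifs[[lab]])), 0)
  }
})

test_that("designed contacts are placed at their exact distances", {
  s <- make_toy_structure(
    n_chains = 4, n_res = 10,
    contacts = list(
      list(type = "ip", chain1 = "A", res1 = 2, chain2 = "B", res2 = 2,
           dist = 3.4),
      list(type = "ip", chain1 = "A", res1 = 6, chain2 = "B", res2 = 9)))
  ip <- detect_ion_pairs(s, list(c("A", "B")))
  expect_equal(nrow(ip), 2)
  expect_setequal(round(ip$min_dist, 6), c(3.4, 3.0))
  # conflicting designs are rejected
  expect_error(make_toy_structure(
    n_chains = 4, n_res = 10,
    contacts = list(
      list(type = "ip", chain1 = "A", res1 = 2, chain2 = "B", res2 = 2),
      list(type = "hb", chain1 = "A", res1 = 2, chain2 = "B", res2 = 5))),
    "conflict")
})

test_that("the same seed reproduces trajectories bit-identically", {
  s <- make_toy_structure(n_chains = 1, n_res = 5)
  a <- make_ou_trajectory(s, 0.5, 10, n_frames = 50, dt = 1, seed = 33)
  b <- make_ou_trajectory(s, 0.5, 10, n_frames = 50, dt = 1, seed = 33)
  expect_identical(a$xyz, b$xyz)
  c2 <- make_ou_trajectory(s, 0.5, 10, n_frames = 50, dt = 1, seed = 34)
  expect_false(identical(a$xyz, c2$xyz))
  set.seed(201)
  confs <- list(s, set_coords(s, s$xyz + matrix(rnorm(n_atoms(s) * 3, 0, 2),
                                                ncol = 3)))
  h1 <- make_hopping_trajectory(confs, matrix(0.5, 2, 2), 0.1, 40, seed = 3)
  h2 <- make_hopping_trajectory(confs, matrix(0.5, 2, 2), 0.1, 40, seed = 3)
  expect_identical(h1$xyz, h2$xyz)
})

test_that("OU trajectories realize the stationary law and ACF time", {
  s <- make_toy_structure(n_chains = 1, n_res = 4)
  sigma <- 0.5; tau_c <- 20
  traj <- make_ou_trajectory(s, sigma, tau_c, n_frames = 5e4, dt = 1,
                             seed = 101)
  dev <- sweep(traj$xyz, 2, as.vector(t(s$xyz)))
  expect_equal(mean(dev^2), sigma^2, tolerance = 0.05)
  ft <- fit_correlation_time(cv_autocorrelation(dev[, 1]))
  expect_equal(ft$tau, tau_c, tolerance = 0.10)
  # sigma = 0 gives a static trajectory
  st <- make_ou_trajectory(s, 0, 10, n_frames = 5, dt = 1, seed = 1)
  expect_true(all(st$xyz == rep(as.vector(t(s$xyz)), each = 5)))
})

test_that("hopping trajectories obey the Markov chain ground truth", {
  s <- make_toy_structure(n_chains = 1, n_res = 6)
  confs <- list(s, set_coords(s, s$xyz + matrix(rnorm(n_atoms(s) * 3, 0, 2),
                                                ncol = 3)))
  # rates 2:1 -> stationary occupancy of state 1 is 2/3
  P <- rbind(c(2 / 3, 1 / 3), c(2 / 3, 1 / 3))
  traj <- make_hopping_trajectory(confs, P, jitter = 0.05, n_frames = 3000,
                                  seed = 103)
  gt <- attr(traj, "ground_truth")
  occ1 <- mean(gt$states == 1)
  expect_equal(occ1, 2 / 3, tolerance = 3 * sqrt(2 / 9 / 3000) / (2 / 3))
  # degenerate conformers are rejected
  expect_error(make_hopping_trajectory(list(s, s), P, jitter = 0.05,
                                       n_frames = 10),
               "degenerate")
  expect_error(make_hopping_trajectory(confs, matrix(1, 2, 2), 0.05, 10),
               "sum to 1")
})

test_that("an absorbing state stops cluster growth at states visited", {
  s <- make_toy_structure(n_chains = 1, n_res = 6)
  set.seed(207)
  confs <- list(s, set_coords(s, s$xyz + matrix(rnorm(n_atoms(s) * 3, 0, 2),
                                                ncol = 3)))
  P <- rbind(c(0, 1), c(0, 1))    # state 2 absorbing
  traj <- make_hopping_trajectory(confs, P, jitter = 0.05, n_frames = 50,
                                  seed = 107)
  gr <- leader_cluster(traj, cutoff = 1.0)
  expect_equal(length(gr$leaders), length(unique(attr(traj,
                                                      "ground_truth")$states)))
})

test_that("telegraph occupancy limits: k_off = 0 binds permanently", {
  s <- make_toy_structure(
    n_chains = 4, n_res = 8,
    contacts = list(
      list(type = "ip", chain1 = "A", res1 = 3, chain2 = "B", res2 = 3)))
  traj <- make_contact_telegraph(s, p_on = 0.5, p_off = 0, n_frames = 200,
                                 seed = 109)
  tl <- contact_timelines(traj, define_interfaces(s)$m, type = "ip")
  expect_equal(unname(tl$occupancy), 1)
  expect_error(make_contact_telegraph(make_toy_structure(n_chains = 2,
                                                         n_res = 4)),
               "no designed contacts")
})

test_that("ground truth sidecar files round-trip through JSON", {
  s <- make_toy_structure(n_chains = 1, n_res = 5)
  traj <- make_ou_trajectory(s, 0.5, 10, n_frames = 10, dt = 1, seed = 3)
  p <- tempfile(fileext = ".json")
  write_ground_truth(traj, p)
  gt <- jsonlite::read_json(p, simplifyVector = TRUE)
  expect_equal(gt$model, "ou")
  expect_equal(gt$tau_c, 10)
  expect_equal(gt$sigma, rep(0.5, n_atoms(s)))
})
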