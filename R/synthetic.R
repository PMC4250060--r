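# Minimal side-chain templates for the toy builder: enough chemistry for
# selections, torsions, donors/acceptors and charge classes to resolve.
# Each entry: atom names from CB outward; `tip` is the functional atom placed
# at a designed contact point; `branch` atoms sit off-axis near the tip.
.TOY_SIDECHAINS <- list(
  ALA = list(atoms = "CB", tip = "CB", branch = character(0)),
  LEU = list(atoms = c("CB", "CG", "CD1", "CD2"), tip = "CD1",
             branch = "CD2"),
  SER = list(atoms = c("CB", "OG"), tip = "OG", branch = character(0)),
  ARG = list(atoms = c("CB", "CG", "CD", "NE", "CZ", "NH1", "NH2"),
             tip = "NH1", branch = "NH2"),
  LYS = list(atoms = c("CB", "CG", "CD", "CE", "NZ"), tip = "NZ",
             branch = character(0)),
  ASP = list(atoms = c("CB", "CG", "OD1", "OD2"), tip = "OD1",
             branch = "OD2"),
  GLU = list(atoms = c("CB", "CG", "CD", "OE1", "OE2"), tip = "OE1",
             branch = "OE2"),
  GLY = list(atoms = character(0), tip = NA_character_,
             branch = character(0))
)
.TOY_ELEMENT <- function(name) substr(name, 1, 1)

#' Build a toy multi-chain protein structure with designed interfaces
#'
#' Generates an idealized protein: chains labeled A, B, ... laid out as
#' straight zig-zag rods (3.8 A Calpha spacing) on a 2 x 2 grid (tetramer
#' layout: A and B face each other across one axis, A and D across the
#' other, A and C diagonally), each residue carrying a full backbone
#' (N, CA, C, O) and a minimal side chain so that selections, phi/psi
#' torsions, H-bond donors/acceptors and charge classes all resolve.
#' Residue types follow the composition fractions (charged residues
#' alternate Arg/Glu/Lys/Asp so both charge signs occur) unless overridden
#' by a designed contact, which forces the needed types and places the two
#' functional tip atoms at an exact separation across the interface.
#'
#' @param n_chains number of chains (1, 2 or 4).
#' @param n_res residues per chain.
#' @param frac_charged,frac_hydrophobic composition fractions; the remainder
#'   is polar (Ser). Hydrophobic residues are Leu, polar Ser.
#' @param contacts optional list of designed interfacial contacts, each a
#'   list with `type` ("ip", "hb" or "phobic"), `chain1`, `res1`, `chain2`,
#'   `res2`, and optional `dist` (tip-tip distance, A; defaults 3.0 / 2.9 /
#'   4.0 by type).
#' @param gap chain-chain axis separation (A), default 20.
#' @param fold `"hairpin"` (default) folds each chain into two antiparallel
#'   strands 4.8 A apart, so residues distant in sequence are close in space
#'   and the chain has native side-chain contacts; `"rod"` keeps a straight
#'   chain (no intrachain contacts beyond nearest neighbors).
#' @param seed integer seed fixing the (deterministic) composition layout.
#' @return a `Structure` with attribute `design` describing every designed
#'   contact (atom indices, tip positions, direction) for downstream
#'   generators.
#' @export
make_toy_structure <- function(n_chains = 4, n_res = 30,
                               frac_charged = 0.25, frac_hydrophobic = 0.4,
                               contacts = NULL, gap = 20,
                               fold = c("hairpin", "rod"), seed = 1) {
  fold <- match.arg(fold)
  if (!n_chains %in% c(1, 2, 4)) stop("n_chains must be 1, 2 or 4")
  if (frac_charged + frac_hydrophobic > 1 + 1e-9) {
    stop("impossible composition: fractions exceed 1")
  }
  chains <- LETTERS[seq_len(n_chains)]
  # chain origins and outward (default side-chain) directions in the y-z plane
  origin <- list(A = c(0, 0, 0), B = c(0, gap, 0),
                 D = c(0, 0, gap), C = c(0, gap, gap))
  outward <- list(A = c(0, -1, -1), B = c(0, 1, -1),
                  D = c(0, -1, 1), C = c(0, 1, 1))
  outward <- lapply(outward, function(v) v / sqrt(sum(v^2)))
  set.seed(seed)
  n_charged <- round(frac_charged * n_res)
  n_phob <- round(frac_hydrophobic * n_res)
  base_seq <- c(rep(c("ARG", "GLU", "LYS", "ASP"),
                    length.out = n_charged),
                rep("LEU", n_phob),
                rep("SER", n_res - n_charged - n_phob))
  # deterministic interleave so charge/phobic residues spread along the chain
  ord <- order(rep(seq_len(ceiling(n_res / 4)), each = 4,
                   length.out = n_res))
  sequences <- setNames(lapply(chains, function(ch) base_seq[ord]), chains)

  # designed contacts override residue types
  contacts <- lapply(contacts, function(ct) {
    ct$dist <- ct$dist %||% switch(ct$type, ip = 3.0, hb = 2.9, phobic = 4.0)
    ct
  })
  res_key <- function(ch, r) paste0(ch, ":", r)
  used <- character(0)
  for (ct in contacts) {
    k1 <- res_key(ct$chain1, ct$res1); k2 <- res_key(ct$chain2, ct$res2)
    if (k1 %in% used || k2 %in% used) {
      stop("geometric conflict: residue used by two designed contacts")
    }
    used <- c(used, k1, k2)
    types <- switch(ct$type, ip = c("ARG", "GLU"), hb = c("SER", "SER"),
                    phobic = c("LEU", "LEU"),
                    stop("unknown contact type: ", ct$type))
    sequences[[ct$chain1]][ct$res1] <- types[1]
    sequences[[ct$chain2]][ct$res2] <- types[2]
  }

  rows <- list(); xyz <- list()
  add_atom <- function(ch, rn, res, nm, p) {
    rows[[length(rows) + 1]] <<- data.frame(
      name = nm, element = .TOY_ELEMENT(nm), resid = res, resno = rn,
      chain = ch, occ = 1)
    xyz[[length(xyz) + 1]] <<- p
  }
  # local backbone frame: hairpin = strand out along +x, turn, strand back
  # along -x at 4.8 A z-offset, so sequence-distant residues are spatial
  # neighbors; rod = single straight strand
  half <- ceiling(n_res / 2)
  res_local <- function(r) {
    if (fold == "rod" || r <= half) {
      list(x = 3.8 * (r - 1), z = 0, dir = 1)
    } else {
      list(x = 3.8 * (n_res - r), z = 4.8, dir = -1)
    }
  }
  ca_pos <- function(ch, r) {
    lc <- res_local(r)
    origin[[ch]] + c(lc$x, 0.6 * (-1)^r, lc$z)
  }
  tip_target <- list()   # res_key -> designed tip position
  dirs <- list()         # res_key -> forced side-chain direction
  for (ct in contacts) {
    ca1 <- ca_pos(ct$chain1, ct$res1); ca2 <- ca_pos(ct$chain2, ct$res2)
    u <- (ca2 - ca1) / sqrt(sum((ca2 - ca1)^2))
    mid <- (ca1 + ca2) / 2
    tip_target[[res_key(ct$chain1, ct$res1)]] <- mid - (ct$dist / 2) * u
    tip_target[[res_key(ct$chain2, ct$res2)]] <- mid + (ct$dist / 2) * u
    dirs[[res_key(ct$chain1, ct$res1)]] <- u
    dirs[[res_key(ct$chain2, ct$res2)]] <- -u
  }

  for (ch in chains) {
    o <- origin[[ch]]
    for (r in seq_len(n_res)) {
      res <- sequences[[ch]][r]
      p <- (-1)^r
      lc <- res_local(r)
      ca <- ca_pos(ch, r)
      add_atom(ch, r, res, "N",
               o + c(lc$x - 1.25 * lc$dir, 0.4 * p, lc$z - 0.35))
      add_atom(ch, r, res, "CA", ca)
      add_atom(ch, r, res, "C",
               o + c(lc$x + 1.25 * lc$dir, 0.4 * p, lc$z + 0.35))
      add_atom(ch, r, res, "O",
               o + c(lc$x + 1.35 * lc$dir, 1.45 * p, lc$z + 0.85))
      sc <- .TOY_SIDECHAINS[[res]]
      if (length(sc$atoms) == 0) next
      key <- res_key(ch, r)
      u <- dirs[[key]] %||% outward[[ch]]
      target <- tip_target[[key]]
      main <- setdiff(sc$atoms, sc$branch)
      k <- length(main)
      tip_dist <- if (!is.null(target)) sqrt(sum((target - ca)^2))
                  else 1.5 + 1.3 * (k - 1)
      # main-axis atoms from CB (1.5 A) out to the tip, linearly spaced
      dists <- if (k == 1) tip_dist else seq(1.5, tip_dist, length.out = k)
      vperp <- .perp_unit(u)
      for (j in seq_len(k)) {
        add_atom(ch, r, res, main[j], ca + dists[j] * u)
      }
      for (bn in sc$branch) {
        add_atom(ch, r, res, bn, ca + tip_dist * u + 0.9 * vperp)
      }
    }
  }
  atoms <- do.call(rbind, rows)
  s <- new_structure(atoms, do.call(rbind, xyz), source = "toy-generator",
                     title = sprintf("toy %d x %d", n_chains, n_res))
  design <- lapply(contacts, function(ct) {
    a <- s$atoms
    sc1 <- which(a$chain == ct$chain1 & a$resno == ct$res1 &
                   !(a$name %in% .BACKBONE_NAMES))
    sc2 <- which(a$chain == ct$chain2 & a$resno == ct$res2 &
                   !(a$name %in% .BACKBONE_NAMES))
    c(ct, list(sidechain1 = sc1, sidechain2 = sc2,
               u = dirs[[res_key(ct$chain1, ct$res1)]]))
  })
  attr(s, "design") <- design
  s
}

.perp_unit <- function(u) {
  v <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  w <- v - sum(v * u) * u
  w / sqrt(sum(w^2))
}

#' Ornstein-Uhlenbeck synthetic trajectory
#'
#' Every atom fluctuates about its reference position as an independent,
#' exactly discretized stationary OU process per Cartesian coordinate:
#' x(t + dt) = x(t) e^(-dt/tau_c) + eta, eta ~ N(0, sigma^2 (1 - e^(-2 dt/tau_c))),
#' initialized from the stationary law N(0, sigma^2). The stationary per-
#' coordinate sd is sigma and the autocorrelation time is tau_c, which is the
#' ground truth for RMSF and diffusion estimators.
#'
#' @param structure reference `Structure`.
#' @param sigma stationary sd (A), scalar or per atom.
#' @param tau_c correlation time (ps).
#' @param n_frames number of frames.
#' @param dt frame spacing (ps), default 1.
#' @param seed integer seed; same seed gives bit-identical output.
#' @param temperature optional temperature (K) recorded on the trajectory.
#' @return a `Trajectory` with attribute `ground_truth` (sigma, tau_c, dt).
#' @export
make_ou_trajectory <- function(structure, sigma, tau_c, n_frames, dt = 1,
                               seed = 1, temperature = NULL) {
  if (any(sigma < 0) || tau_c <= 0) stop("sigma and tau_c must be positive")
  nat <- n_atoms(structure)
  sigma <- rep(sigma, length.out = nat)
  sig3 <- rep(sigma, each = 3)
  phi <- exp(-dt / tau_c)
  set.seed(seed)
  if (all(sigma == 0)) {
    dev <- matrix(0, n_frames, 3 * nat)
  } else {
    innov_sd <- sig3 * sqrt(1 - phi^2)
    x0 <- rnorm(3 * nat, 0, sig3)
    eps <- matrix(rnorm(n_frames * 3 * nat), n_frames, 3 * nat)
    eps <- sweep(eps, 2, innov_sd, "*")
    dev <- vapply(seq_len(3 * nat), function(j) {
      as.numeric(stats::filter(eps[, j], phi, method = "recursive",
                               init = x0[j]))
    }, numeric(n_frames))
  }
  ref_flat <- as.vector(t(structure$xyz))
  xyz <- sweep(dev, 2, ref_flat, "+")
  traj <- new_trajectory(xyz, dt = dt, topology = structure,
                         temperature = temperature)
  attr(traj, "ground_truth") <- list(model = "ou", sigma = sigma,
                                     tau_c = tau_c, dt = dt, seed = seed)
  traj
}

#' Conformer-hopping synthetic trajectory
#'
#' Discrete Markov chain over K conformers plus isotropic Gaussian jitter:
#' the ground truth for conformational clustering (the number of reachable
#' states and their occupancies are known by construction).
#'
#' @param conformers list of K >= 2 `Structure`s (or n x 3 matrices) sharing
#'   one atom order; pairwise superposed RMSD must exceed 3 x `jitter`.
#' @param transition K x K row-stochastic transition matrix.
#' @param jitter per-coordinate Gaussian sd (A) added to every frame.
#' @param n_frames number of frames.
#' @param dt frame spacing (ps), default 1.
#' @param seed integer seed.
#' @param topology `Structure` used as topology; defaults to the first
#'   conformer when conformers are `Structure`s.
#' @return a `Trajectory` with attribute `ground_truth` (states, matrix).
#' @export
make_hopping_trajectory <- function(conformers, transition, jitter = 0.1,
                                    n_frames = 1000, dt = 1, seed = 1,
                                    topology = NULL) {
  K <- length(conformers)
  if (K < 2) stop("need at least 2 conformers")
  coords <- lapply(conformers, function(cf) {
    if (inherits(cf, "Structure")) cf$xyz else as.matrix(cf)
  })
  if (is.null(topology)) {
    if (!inherits(conformers[[1]], "Structure")) {
      stop("supply `topology` when conformers are bare matrices")
    }
    topology <- conformers[[1]]
  }
  for (i in seq_len(K - 1)) for (j in (i + 1):K) {
    if (rmsd_fit(coords[[i]], coords[[j]]) <= 3 * jitter) {
      stop(sprintf(
        "degenerate conformers %d/%d: RMSD must exceed 3 x jitter", i, j))
    }
  }
  transition <- as.matrix(transition)
  if (any(abs(rowSums(transition) - 1) > 1e-8)) {
    stop("transition matrix rows must sum to 1")
  }
  set.seed(seed)
  states <- integer(n_frames)
  states[1] <- 1L
  for (f in 2:n_frames) {
    states[f] <- sample.int(K, 1, prob = transition[states[f - 1], ])
  }
  nat <- nrow(coords[[1]])
  xyz <- matrix(NA_real_, n_frames, 3 * nat)
  for (f in seq_len(n_frames)) {
    xyz[f, ] <- as.vector(t(coords[[states[f]]])) +
      rnorm(3 * nat, 0, jitter)
  }
  traj <- new_trajectory(xyz, dt = dt, topology = topology)
  attr(traj, "ground_truth") <- list(model = "hopping", states = states,
                                     transition = transition,
                                     jitter = jitter, seed = seed)
  traj
}

#' Telegraph (two-state) interfacial contact trajectory
#'
#' Each designed contact of a [make_toy_structure()] design toggles between
#' its bound geometry (tips at the designed distance) and an unbound
#' geometry (the first residue's side chain retracted along the contact
#' axis) as an independent two-state Markov chain with per-frame switching
#' probabilities `p_on` (unbound -> bound) and `p_off` (bound -> unbound).
#' The stationary bound probability is p_on / (p_on + p_off), the ground
#' truth for occupancy estimators.
#'
#' @param structure a `Structure` from [make_toy_structure()] with designed
#'   contacts.
#' @param p_on,p_off per-frame switching probabilities, scalar or one per
#'   contact.
#' @param n_frames number of frames.
#' @param dt frame spacing (ps), default 1.
#' @param seed integer seed.
#' @param unbound_shift retraction distance (A) separating an unbound
#'   contact, default 6.
#' @return a `Trajectory` with attribute `ground_truth` (per-contact bound
#'   state matrix and stationary occupancies).
#' @export
make_contact_telegraph <- function(structure, p_on = 0.1, p_off = 0.1,
                                   n_frames = 1000, dt = 1, seed = 1,
                                   unbound_shift = 6) {
  design <- attr(structure, "design")
  if (is.null(design) || length(design) == 0) {
    stop("structure carries no designed contacts")
  }
  nc <- length(design)
  p_on <- rep(p_on, length.out = nc)
  p_off <- rep(p_off, length.out = nc)
  set.seed(seed)
  bound <- matrix(NA, n_frames, nc)
  for (k in seq_len(nc)) {
    st <- logical(n_frames)
    st[1] <- runif(1) < p_on[k] / (p_on[k] + p_off[k])  # stationary start
    for (f in 2:n_frames) {
      st[f] <- if (st[f - 1]) runif(1) >= p_off[k] else runif(1) < p_on[k]
    }
    bound[, k] <- st
  }
  ref <- as.vector(t(structure$xyz))
  xyz <- matrix(rep(ref, each = n_frames), n_frames, length(ref))
  for (k in seq_len(nc)) {
    sc <- design[[k]]$sidechain1
    u <- design[[k]]$u
    cols <- as.vector(rbind(3 * sc - 2, 3 * sc - 1, 3 * sc))
    shift <- rep(-unbound_shift * u, times = length(sc))
    unb <- which(!bound[, k])
    if (length(unb) > 0) {
      xyz[unb, cols] <- sweep(xyz[unb, cols, drop = FALSE], 2, shift, "+")
    }
  }
  traj <- new_trajectory(xyz, dt = dt, topology = structure)
  attr(traj, "ground_truth") <- list(
    model = "telegraph", bound = bound,
    occupancy = p_on / (p_on + p_off),
    contacts = vapply(design, function(ct) {
      paste0(ct$chain1, ":", ct$res1, "-", ct$chain2, ":", ct$res2)
    }, character(1)),
    seed = seed)
  traj
}

#' Write a generator's ground truth to a JSON sidecar
#'
#' @param traj a synthetic `Trajectory` carrying a `ground_truth` attribute.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(traj, path) {
  gt <- attr(traj, "ground_truth")
  if (is.null(gt)) stop("trajectory carries no ground truth")
  jsonlite::write_json(gt, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}
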