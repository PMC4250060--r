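# Fixtures are built in code: PDB text written at test time, plus the
# independent brute-force oracles the analysis implementations are checked
# against.

pdb_atom_line <- function(serial, name, resn, chain, resno, x, y, z,
                          occ = 1, alt = " ", elem = substr(name, 1, 1)) {
  nm <- if (nchar(name) < 4) sprintf(" %-3s", name) else name
  sprintf("ATOM  %5d %4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, nm, alt, resn, chain, resno, x, y, z, occ, 0, elem)
}

write_pdb_fixture <- function(lines, path = tempfile(fileext = ".pdb")) {
  writeLines(c(lines, "END"), path)
  path
}

# 3-atom, single-chain minimal structure
mini_pdb <- function() {
  write_pdb_fixture(c(
    pdb_atom_line(1, "N", "ALA", "A", 1, 0, 0, 0),
    pdb_atom_line(2, "CA", "ALA", "A", 1, 1.45, 0, 0),
    pdb_atom_line(3, "C", "ALA", "A", 1, 2.4, 1.0, 0)
  ))
}

# CA with altloc A (occ 0.4) and B (occ 0.6): B must be kept
altloc_pdb <- function() {
  write_pdb_fixture(c(
    pdb_atom_line(1, "N", "SER", "A", 1, 0, 0, 0),
    pdb_atom_line(2, "CA", "SER", "A", 1, 1.45, 0, 0, occ = 0.4, alt = "A"),
    pdb_atom_line(3, "CA", "SER", "A", 1, 1.55, 0, 0, occ = 0.6, alt = "B"),
    pdb_atom_line(4, "C", "SER", "A", 1, 2.4, 1.0, 0)
  ))
}

# two-chain dipeptide (backbone + CB), for selection tests
dipeptide_pdb <- function() {
  mk <- function(serial0, chain, z) {
    unlist(lapply(1:2, function(r) {
      b <- serial0 + (r - 1) * 5
      x <- (r - 1) * 3.8
      c(pdb_atom_line(b + 0, "N", "ALA", chain, r, x - 1.2, 0.4, z),
        pdb_atom_line(b + 1, "CA", "ALA", chain, r, x, 0.6, z),
        pdb_atom_line(b + 2, "C", "ALA", chain, r, x + 1.2, 0.4, z),
        pdb_atom_line(b + 3, "O", "ALA", chain, r, x + 1.3, 1.4, z + 0.9),
        pdb_atom_line(b + 4, "CB", "ALA", chain, r, x, 0.8, z + 1.4))
    }))
  }
  write_pdb_fixture(c(mk(1, "A", 0), mk(11, "B", 8)))
}

# ---- independent oracles ---------------------------------------------------

# brute-force selection: plain logical filter over the atom table
oracle_select <- function(structure, chain = NULL, name = NULL,
                          sideheavy = FALSE) {
  a <- structure$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(chain)) keep <- keep & a$chain %in% chain
  if (!is.null(name)) keep <- keep & a$name %in% name
  if (sideheavy) {
    keep <- keep & a$element != "H" &
      !(a$name %in% c("N", "CA", "C", "O", "OXT"))
  }
  which(keep)
}

# rotation-grid RMSD oracle: exhaustive search over Euler angles after
# centering both point sets (translation handled by centroid alignment)
oracle_grid_rmsd <- function(x, y, step_deg = 9) {
  xc <- sweep(x, 2, colMeans(x))
  yc <- sweep(y, 2, colMeans(y))
  best <- Inf
  ga <- seq(0, 360 - step_deg, by = step_deg) * pi / 180
  gb <- seq(0, 180, by = step_deg) * pi / 180
  for (a in ga) for (b in gb) for (g in ga) {
    ca <- cos(a); sa <- sin(a); cb <- cos(b); sb <- sin(b)
    cg <- cos(g); sg <- sin(g)
    R <- matrix(c(
      ca * cb * cg - sa * sg, -ca * cb * sg - sa * cg, ca * sb,
      sa * cb * cg + ca * sg, -sa * cb * sg + ca * cg, sa * sb,
      -sb * cg, sb * sg, cb), 3, 3, byrow = TRUE)
    r <- sqrt(mean(rowSums((xc %*% t(R) - yc)^2)))
    if (r < best) best <- r
  }
  best
}

# O(N^2) native-contact oracle: double loop over all side-chain heavy pairs
oracle_contacts <- function(structure, cutoff = 5, min_sep = 3) {
  a <- structure$atoms
  idx <- oracle_select(structure, sideheavy = TRUE)
  partners <- lapply(seq_along(idx), function(i) integer(0))
  for (i in seq_along(idx)) for (j in seq_along(idx)) {
    if (i == j) next
    ii <- idx[i]; jj <- idx[j]
    if (a$chain[ii] != a$chain[jj]) next
    if (abs(a$resno[ii] - a$resno[jj]) <= min_sep) next
    if (sqrt(sum((structure$xyz[ii, ] - structure$xyz[jj, ])^2)) <= cutoff) {
      partners[[i]] <- c(partners[[i]], j)
    }
  }
  list(atoms = idx, partners = partners)
}

# O(N^2) interdomain ion-pair oracle over a set of chain pairs
oracle_ion_pairs <- function(structure, chain_pairs, cutoff = 4.0) {
  a <- structure$atoms
  basic <- list(ARG = c("NE", "NH1", "NH2"), LYS = "NZ")
  acidic <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))
  is_basic <- mapply(function(res, nm) {
    res %in% names(basic) && nm %in% basic[[res]]
  }, a$resid, a$name)
  is_acidic <- mapply(function(res, nm) {
    res %in% names(acidic) && nm %in% acidic[[res]]
  }, a$resid, a$name)
  found <- character(0)
  for (pr in chain_pairs) {
    for (i in which(is_basic)) for (j in which(is_acidic)) {
      ok <- (a$chain[i] == pr[1] && a$chain[j] == pr[2]) ||
        (a$chain[i] == pr[2] && a$chain[j] == pr[1])
      if (!ok) next
      if (sqrt(sum((structure$xyz[i, ] - structure$xyz[j, ])^2)) <= cutoff) {
        e1 <- paste0(a$chain[i], ":", a$resno[i])
        e2 <- paste0(a$chain[j], ":", a$resno[j])
        found <- c(found, paste(sort(c(e1, e2)), collapse = "-"))
      }
    }
  }
  sort(unique(found))
}

# reduce a detector result to the oracle's pair-key format
pair_keys <- function(contacts) {
  if (nrow(contacts) == 0) return(character(0))
  sort(vapply(seq_len(nrow(contacts)), function(r) {
    paste(sort(c(paste0(contacts$chain1[r], ":", contacts$resno1[r]),
                 paste0(contacts$chain2[r], ":", contacts$resno2[r]))),
          collapse = "-")
  }, character(1)))
}

# brute-force leader clustering using bio3d's independent fit/RMSD routine
oracle_leader <- function(traj, idx, cutoff) {
  nfr <- n_frames(traj)
  leaders <- integer(0)
  assignment <- integer(nfr)
  get <- function(f) frame_coords(traj, f)[idx, , drop = FALSE]
  for (f in seq_len(nfr)) {
    hit <- 0L
    for (k in leaders) {
      r <- bio3d::rmsd(as.vector(t(get(k))), as.vector(t(get(f))),
                       fit = TRUE)
      if (r <= cutoff) { hit <- which(leaders == k); break }
    }
    if (hit == 0L) { leaders <- c(leaders, f); hit <- length(leaders) }
    assignment[f] <- hit
  }
  list(leaders = leaders, assignment = assignment)
}
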