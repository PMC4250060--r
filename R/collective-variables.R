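#' Construct a collective-variable time series
#'
#' @param name CV identifier (e.g. "rg", "qnative").
#' @param values numeric vector, one value per frame.
#' @param times frame times (ps).
#' @param units "A" or "fraction" (dimensionless).
#' @return an object of class `CVSeries`.
#' @export
new_cv_series <- function(name, values, times, units = "A") {
  if (length(values) != length(times)) stop("values/times length mismatch")
  if (units == "fraction" &&
      any(values < -1e-9 | values > 1 + 1e-9, na.rm = TRUE)) {
    stop("fractional CV outside [0, 1]")
  }
  structure(list(name = name, values = as.numeric(values),
                 times = as.numeric(times), units = units),
            class = "CVSeries")
}

#' @export
print.CVSeries <- function(x, ...) {
  cat(sprintf("<CVSeries '%s'> %d frames, mean %.4g %s\n",
              x$name, length(x$values), mean(x$values), x$units))
  invisible(x)
}

#' Radius of gyration of a coordinate frame
#'
#' Rg = sqrt(mean_i |r_i - rbar|^2) over the selected atoms, where rbar is the
#' unweighted mean position (no mass weighting).
#'
#' @param coords n_atoms x 3 coordinate matrix (A).
#' @param selection atom indices; default all.
#' @return radius of gyration (A).
#' @export
radius_of_gyration <- function(coords, selection = NULL) {
  coords <- as.matrix(coords)
  if (!is.null(selection)) coords <- coords[selection, , drop = FALSE]
  if (nrow(coords) == 0) stop("empty selection for radius of gyration")
  ctr <- colMeans(coords)
  sqrt(mean(rowSums(sweep(coords, 2, ctr)^2)))
}

#' Radius-of-gyration time series
#'
#' @param traj a `Trajectory`.
#' @param selection selection expression or index vector; default "calpha".
#' @return a `CVSeries` in A.
#' @export
rg_series <- function(traj, selection = "calpha") {
  idx <- .as_indices(traj$topology, selection)
  vals <- vapply(seq_len(n_frames(traj)), function(f) {
    radius_of_gyration(frame_coords(traj, f), idx)
  }, numeric(1))
  new_cv_series("rg", vals, traj$times, "A")
}

.as_indices <- function(structure, selection) {
  if (is.character(selection)) resolve_selection(structure, selection)
  else as.integer(selection)
}

#' Per-frame RMSD to a reference structure
#'
#' For each frame, rigid-body motion is removed by superposing the selected
#' atoms onto the same atoms of the reference; the post-fit RMSD over that
#' selection is reported.
#'
#' @param traj a `Trajectory`.
#' @param reference a `Structure` (e.g. the crystallographic configuration).
#' @param selection selection expression or indices; default "calpha".
#' @return a `CVSeries` in A.
#' @export
rmsd_series <- function(traj, reference, selection = "calpha") {
  idx <- .as_indices(traj$topology, selection)
  ref <- reference$xyz
  vals <- vapply(seq_len(n_frames(traj)), function(f) {
    rmsd_fit(frame_coords(traj, f), ref, idx)
  }, numeric(1))
  new_cv_series("rmsd", vals, traj$times, "A")
}

#' Build the native side-chain contact reference
#'
#' For every side-chain heavy atom, its native partners are the side-chain
#' heavy atoms within `cutoff` in the reference configuration that belong to
#' residues more than `min_sep` apart in sequence (same chain by default).
#' The per-atom native contact counts n_i feed the fraction-of-native-contacts
#' CV.
#'
#' @param structure reference `Structure`.
#' @param cutoff contact distance (A), default 5.
#' @param min_sep minimum sequence separation in residues, default 3
#'   (partners must be MORE than `min_sep` apart).
#' @param interchain if TRUE, pairs on different chains also count as
#'   contacts (always satisfying the sequence-separation rule); default FALSE.
#' @return an object of class `ContactReference`.
#' @export
build_contact_reference <- function(structure, cutoff = 5, min_sep = 3,
                                    interchain = FALSE) {
  idx <- resolve_selection(structure, "sideheavy")
  if (length(idx) == 0) {
    warning("structure has no side-chain heavy atoms; empty contact reference")
    return(structure(list(atoms = integer(0), partners = list(),
                          n = integer(0), cutoff = cutoff, min_sep = min_sep),
                     class = "ContactReference"))
  }
  xyz <- structure$xyz[idx, , drop = FALSE]
  resno <- structure$atoms$resno[idx]
  chain <- structure$atoms$chain[idx]
  d <- as.matrix(dist(xyz))
  sep_ok <- abs(outer(resno, resno, "-")) > min_sep
  same_chain <- outer(chain, chain, "==")
  eligible <- (same_chain & sep_ok) | (!same_chain & interchain)
  adj <- d <= cutoff & eligible
  diag(adj) <- FALSE
  partners <- lapply(seq_along(idx),
                     function(i) as.integer(which(adj[i, ])))
  structure(
    list(atoms = idx, partners = partners,
         n = vapply(partners, length, integer(1)),
         cutoff = cutoff, min_sep = min_sep),
    class = "ContactReference"
  )
}

#' Fraction of native contacts of one frame
#'
#' Q = (1/N) * sum_i m_i/n_i over the N side-chain heavy atoms with n_i > 0
#' native partners, where m_i is how many of atom i's native partners are
#' still within the native cutoff in this frame. Q is 1 on the reference
#' configuration and lies in [0, 1] always.
#'
#' @param coords full n_atoms x 3 frame (A).
#' @param reference a `ContactReference`.
#' @return Q in [0, 1].
#' @export
fraction_native_contacts <- function(coords, reference) {
  if (length(reference$atoms) == 0) stop("empty contact reference")
  active <- which(reference$n > 0)
  if (length(active) == 0) stop("contact reference has no contacts")
  xyz <- as.matrix(coords)[reference$atoms, , drop = FALSE]
  ratio <- vapply(active, function(i) {
    p <- reference$partners[[i]]
    dv <- sweep(xyz[p, , drop = FALSE], 2, xyz[i, ])
    sum(sqrt(rowSums(dv^2)) <= reference$cutoff) / length(p)
  }, numeric(1))
  mean(ratio)
}

#' Fraction-of-native-contacts time series
#' @param traj a `Trajectory`.
#' @param reference a `ContactReference` built on the reference structure.
#' @return a `CVSeries` (dimensionless fraction).
#' @export
qnative_series <- function(traj, reference) {
  vals <- vapply(seq_len(n_frames(traj)), function(f) {
    fraction_native_contacts(frame_coords(traj, f), reference)
  }, numeric(1))
  new_cv_series("qnative", vals, traj$times, "fraction")
}

# Dihedral angle (degrees, in (-180, 180]) defined by four points.
.dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
          n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2^2))
  ang <- atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

# Index table of all phi/psi dihedrals resolvable on a structure:
# phi(i) = C(i-1)-N(i)-CA(i)-C(i); psi(i) = N(i)-CA(i)-C(i)-N(i+1).
.backbone_torsion_table <- function(structure) {
  a <- structure$atoms
  rows <- list()
  for (ch in unique(a$chain)) {
    in_ch <- which(a$chain == ch & a$resid %in% .PROTEIN_RESIDUES)
    if (length(in_ch) == 0) next
    resnos <- sort(unique(a$resno[in_ch]))
    find <- function(rn, nm) {
      i <- in_ch[a$resno[in_ch] == rn & a$name[in_ch] == nm]
      if (length(i) == 1) i else NA_integer_
    }
    for (k in seq_along(resnos)) {
      rn <- resnos[k]
      Ni <- find(rn, "N"); CAi <- find(rn, "CA"); Ci <- find(rn, "C")
      if (k > 1 && resnos[k - 1] == rn - 1) {
        Cm <- find(rn - 1, "C")
        if (!anyNA(c(Cm, Ni, CAi, Ci))) {
          rows[[length(rows) + 1]] <-
            data.frame(chain = ch, resno = rn, angle = "phi",
                       i1 = Cm, i2 = Ni, i3 = CAi, i4 = Ci)
        }
      }
      if (k < length(resnos) && resnos[k + 1] == rn + 1) {
        Np <- find(rn + 1, "N")
        if (!anyNA(c(Ni, CAi, Ci, Np))) {
          rows[[length(rows) + 1]] <-
            data.frame(chain = ch, resno = rn, angle = "psi",
                       i1 = Ni, i2 = CAi, i3 = Ci, i4 = Np)
        }
      }
    }
  }
  if (length(rows) == 0) return(NULL)
  do.call(rbind, rows)
}

#' Build the native backbone-torsion reference
#'
#' Records the native phi and psi dihedral values of every residue (where all
#' four defining atoms exist) together with the circular tolerance used to
#' call a torsion "native" at analysis time.
#'
#' @param structure reference `Structure`.
#' @param tolerance circular tolerance in degrees (default 60); a frame
#'   torsion is native when its shorter-arc deviation from the reference
#'   value is within this window.
#' @return an object of class `TorsionReference`.
#' @export
build_torsion_reference <- function(structure, tolerance = 60) {
  if (tolerance <= 0 || tolerance >= 180) stop("tolerance must be in (0, 180)")
  tab <- .backbone_torsion_table(structure)
  if (is.null(tab)) stop("no resolvable phi/psi torsions in structure")
  tab$native <- vapply(seq_len(nrow(tab)), function(r) {
    .dihedral(structure$xyz[tab$i1[r], ], structure$xyz[tab$i2[r], ],
              structure$xyz[tab$i3[r], ], structure$xyz[tab$i4[r], ])
  }, numeric(1))
  structure(list(table = tab, tolerance = tolerance),
            class = "TorsionReference")
}

# shorter-arc circular deviation in degrees
.circ_dev <- function(a, b) {
  d <- (a - b) %% 360
  pmin(d, 360 - d)
}

#' Fraction of native torsion angles of one frame
#'
#' The fraction of phi/psi dihedrals whose circular (shorter-arc) deviation
#' from the native value is within the reference tolerance. Counted per
#' angle, not per residue.
#'
#' @param coords full n_atoms x 3 frame (A).
#' @param reference a `TorsionReference`.
#' @return fraction in [0, 1].
#' @export
fraction_native_torsions <- function(coords, reference) {
  tab <- reference$table
  if (is.null(tab) || nrow(tab) == 0) stop("empty torsion reference")
  coords <- as.matrix(coords)
  cur <- vapply(seq_len(nrow(tab)), function(r) {
    .dihedral(coords[tab$i1[r], ], coords[tab$i2[r], ],
              coords[tab$i3[r], ], coords[tab$i4[r], ])
  }, numeric(1))
  mean(.circ_dev(cur, tab$native) <= reference$tolerance)
}

#' Fraction-of-native-torsions time series
#' @param traj a `Trajectory`.
#' @param reference a `TorsionReference`.
#' @return a `CVSeries` (dimensionless fraction).
#' @export
torsion_series <- function(traj, reference) {
  vals <- vapply(seq_len(n_frames(traj)), function(f) {
    fraction_native_torsions(frame_coords(traj, f), reference)
  }, numeric(1))
  new_cv_series("torsions", vals, traj$times, "fraction")
}

#' Catalytic-pocket RMSD to open (apo) and closed (holo) references
#'
#' Tracks the conformational state of a binding-site region (e.g. the loop
#' gating the catalytic pocket) by computing, per frame, the backbone RMSD of
#' the pocket residues to two reference structures after superposing on the
#' pocket backbone itself. Mapping between trajectory and reference is by
#' (chain, residue number, atom name); residues of the pocket selection that
#' cannot be mapped onto a reference are an error.
#'
#' @param traj a `Trajectory`.
#' @param apo_ref,holo_ref reference `Structure`s (ligand-free / ligand-bound).
#' @param pocket_selection selection expression on the trajectory topology
#'   restricting to the pocket residues; combined with backbone atoms.
#' @return list of two `CVSeries`: `apo` and `holo` (A).
#' @export
pocket_rmsd_to_references <- function(traj, apo_ref, holo_ref,
                                      pocket_selection) {
  top <- traj$topology
  idx <- resolve_selection(top, paste(pocket_selection, "and backbone"))
  if (length(idx) < 3) stop("pocket backbone selection has fewer than 3 atoms")
  key <- function(s, i) paste(s$atoms$chain[i], s$atoms$resno[i],
                              s$atoms$name[i], sep = "|")
  traj_keys <- key(top, idx)
  map_onto <- function(ref, label) {
    ref_keys <- key(ref, seq_len(n_atoms(ref)))
    pos <- match(traj_keys, ref_keys)
    if (anyNA(pos)) {
      bad <- unique(paste(top$atoms$chain[idx[is.na(pos)]],
                          top$atoms$resno[idx[is.na(pos)]]))
      stop("pocket residues not mappable onto ", label, " reference: ",
           paste(bad, collapse = ", "))
    }
    ref$xyz[pos, , drop = FALSE]
  }
  apo_xyz <- map_onto(apo_ref, "apo")
  holo_xyz <- map_onto(holo_ref, "holo")
  one <- function(refc) {
    vapply(seq_len(n_frames(traj)), function(f) {
      crd <- frame_coords(traj, f)[idx, , drop = FALSE]
      rmsd_fit(crd, refc)
    }, numeric(1))
  }
  list(apo = new_cv_series("pocket_rmsd_apo", one(apo_xyz), traj$times, "A"),
       holo = new_cv_series("pocket_rmsd_holo", one(holo_xyz), traj$times, "A"))
}
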