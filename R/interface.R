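# Residue chemistry tables used by the interface detectors. Charged-group
# atoms follow the common salt-bridge convention: basic side-chain nitrogens
# vs acidic carboxylate oxygens.
.BASIC_N <- list(
  ARG = c("NE", "NH1", "NH2"), LYS = "NZ",
  HIS = c("ND1", "NE2"), HSP = c("ND1", "NE2")
)
.ACIDIC_O <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))

.HYDROPHOBIC_RES <- c("ALA", "VAL", "LEU", "ILE", "PRO", "PHE", "MET", "TRP")

# Heavy-atom H-bond donors with their antecedent atom (for the heavy-atom
# angle proxy) and acceptors, per residue template. Backbone N/O handled
# separately.
.HB_DONORS <- list(
  SER = list(c("OG", "CB")), THR = list(c("OG1", "CB")),
  TYR = list(c("OH", "CZ")), ASN = list(c("ND2", "CG")),
  GLN = list(c("NE2", "CD")), TRP = list(c("NE1", "CE2")),
  HIS = list(c("ND1", "CG"), c("NE2", "CD2")),
  LYS = list(c("NZ", "CE")),
  ARG = list(c("NE", "CD"), c("NH1", "CZ"), c("NH2", "CZ"))
)
.HB_ACCEPTORS <- list(
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"), ASN = "OD1", GLN = "OE1",
  SER = "OG", THR = "OG1", TYR = "OH", HIS = c("ND1", "NE2"), MET = "SD"
)

#' Decompose a tetramer into its three interface classes
#'
#' A homotetramer built as a dimer of dimers (AB + CD) has three classes of
#' monomer-monomer interface, each the sum of two symmetry-equivalent chain
#' pairs: the intra-dimer interface m = \{A-B, D-C\}, and the two cross-dimer
#' classes d and c covering \{A-D, B-C\} and \{A-C, B-D\}. Which cross-dimer
#' pairing carries the label "d" is a geometric convention of the particular
#' assembly, so it is configurable (and recorded on the result) rather than
#' hard-coded.
#'
#' @param structure a `Structure` with exactly four chains.
#' @param d_pairing `"AD"` (default: d = \{A-D, B-C\}) or `"AC"`
#'   (d = \{A-C, B-D\}).
#' @return named list of three `InterfaceSpec` objects (`m`, `d`, `c`), each
#'   a list with `label` and `pairs` (list of two chain-id pairs).
#' @export
define_interfaces <- function(structure, d_pairing = c("AD", "AC")) {
  d_pairing <- match.arg(d_pairing)
  chains <- unique(structure$atoms$chain)
  if (length(chains) != 4) {
    stop("interface decomposition needs exactly 4 chains, found ",
         length(chains))
  }
  if (anyDuplicated(chains)) stop("duplicate chain ids")
  if (!all(c("A", "B", "C", "D") %in% chains)) {
    stop("chains must be labeled A, B, C, D")
  }
  mk <- function(label, p1, p2) {
    structure(list(label = label, pairs = list(p1, p2)),
              class = "InterfaceSpec")
  }
  if (d_pairing == "AD") {
    list(m = mk("m", c("A", "B"), c("D", "C")),
         d = mk("d", c("A", "D"), c("B", "C")),
         c = mk("c", c("A", "C"), c("B", "D")))
  } else {
    list(m = mk("m", c("A", "B"), c("D", "C")),
         d = mk("d", c("A", "C"), c("B", "D")),
         c = mk("c", c("A", "D"), c("B", "C")))
  }
}

# rows of atoms of one charge class in one chain: index, resno, resid
.charged_atoms <- function(structure, chain, table) {
  a <- structure$atoms
  hits <- integer(0)
  for (res in names(table)) {
    hits <- c(hits, which(a$chain == chain & a$resid == res &
                            a$name %in% table[[res]]))
  }
  hits
}

#' Detect interdomain ion pairs in one frame
#'
#' An ion pair (salt bridge) is counted when any basic side-chain nitrogen
#' (Arg NE/NH1/NH2, Lys NZ, His ND1/NE2 if `protonated_his`) lies within
#' `cutoff` of any acidic carboxylate oxygen (Asp OD1/OD2, Glu OE1/OE2) with
#' the two residues on the two chains of one of the interface's chain pairs.
#' Counted once per residue pair per frame regardless of how many atom pairs
#' satisfy the criterion.
#'
#' @param structure a `Structure` carrying the frame coordinates.
#' @param interface an `InterfaceSpec` from [define_interfaces()], or a list
#'   of chain pairs like `list(c("A","B"))`.
#' @param cutoff N-O distance cutoff (A), default 4.0.
#' @param protonated_his count His as basic (default FALSE).
#' @return data.frame, one row per residue pair: `chain1`, `resno1`,
#'   `resid1`, `chain2`, `resno2`, `resid2`, `min_dist`, `pair_id`. Zero rows
#'   when no ion pair exists.
#' @export
detect_ion_pairs <- function(structure, interface, cutoff = 4.0,
                             protonated_his = FALSE) {
  basic <- .BASIC_N
  if (!protonated_his) basic <- basic[setdiff(names(basic), c("HIS", "HSP"))]
  pairs <- if (inherits(interface, "InterfaceSpec")) interface$pairs
           else interface
  out <- list()
  for (pr in pairs) {
    for (ori in list(pr, rev(pr))) {
      bi <- .charged_atoms(structure, ori[1], basic)
      ai <- .charged_atoms(structure, ori[2], .ACIDIC_O)
      if (length(bi) == 0 || length(ai) == 0) next
      d <- .cross_dist(structure$xyz[bi, , drop = FALSE],
                       structure$xyz[ai, , drop = FALSE])
      hit <- which(d <= cutoff, arr.ind = TRUE)
      if (nrow(hit) == 0) next
      a <- structure$atoms
      df <- data.frame(
        chain1 = ori[1], resno1 = a$resno[bi[hit[, 1]]],
        resid1 = a$resid[bi[hit[, 1]]],
        chain2 = ori[2], resno2 = a$resno[ai[hit[, 2]]],
        resid2 = a$resid[ai[hit[, 2]]],
        min_dist = d[hit]
      )
      out[[length(out) + 1]] <- df
    }
  }
  .collapse_contacts(out)
}

# cross pairwise distance matrix between two coordinate sets
.cross_dist <- function(x, y) {
  x2 <- rowSums(x^2); y2 <- rowSums(y^2)
  d2 <- outer(x2, y2, "+") - 2 * tcrossprod(x, y)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

# reduce atom-level hits to one row per residue pair with the minimum distance
.collapse_contacts <- function(dfs) {
  empty <- data.frame(chain1 = character(0), resno1 = integer(0),
                      resid1 = character(0), chain2 = character(0),
                      resno2 = integer(0), resid2 = character(0),
                      min_dist = numeric(0), pair_id = character(0))
  if (length(dfs) == 0) return(empty)
  df <- do.call(rbind, dfs)
  if (nrow(df) == 0) return(empty)
  # canonical residue-pair orientation so A:1-B:2 and B:2-A:1 collapse
  flip <- df$chain1 > df$chain2 |
    (df$chain1 == df$chain2 & df$resno1 > df$resno2)
  if (any(flip)) {
    tmp <- df[flip, c("chain1", "resno1", "resid1")]
    df[flip, c("chain1", "resno1", "resid1")] <-
      df[flip, c("chain2", "resno2", "resid2")]
    df[flip, c("chain2", "resno2", "resid2")] <- tmp
  }
  df$pair_id <- paste0(df$chain1, ":", df$resno1, df$resid1, "-",
                       df$chain2, ":", df$resno2, df$resid2)
  agg <- df[order(df$pair_id, df$min_dist), ]
  agg <- agg[!duplicated(agg$pair_id), ]
  rownames(agg) <- NULL
  agg
}

# donor rows: atom index + antecedent index (NA if missing) for one chain
.hb_donor_atoms <- function(structure, chain) {
  a <- structure$atoms
  rows <- list()
  in_ch <- a$chain == chain
  # backbone amide N, antecedent CA (Pro N has no H: excluded)
  nb <- which(in_ch & a$name == "N" & a$resid %in% .PROTEIN_RESIDUES &
                a$resid != "PRO")
  for (i in nb) {
    ca <- which(in_ch & a$name == "CA" & a$resno == a$resno[i])
    rows[[length(rows) + 1]] <- c(i, if (length(ca) == 1) ca else NA)
  }
  for (res in names(.HB_DONORS)) {
    for (da in .HB_DONORS[[res]]) {
      di <- which(in_ch & a$resid == res & a$name == da[1])
      for (i in di) {
        ante <- which(in_ch & a$resno == a$resno[i] & a$name == da[2])
        rows[[length(rows) + 1]] <- c(i, if (length(ante) == 1) ante else NA)
      }
    }
  }
  if (length(rows) == 0) return(matrix(integer(0), ncol = 2))
  do.call(rbind, rows)
}

.hb_acceptor_atoms <- function(structure, chain) {
  a <- structure$atoms
  in_ch <- a$chain == chain
  hits <- which(in_ch & a$name == "O" & a$resid %in% .PROTEIN_RESIDUES)
  for (res in names(.HB_ACCEPTORS)) {
    hits <- c(hits, which(in_ch & a$resid == res &
                            a$name %in% .HB_ACCEPTORS[[res]]))
  }
  sort(unique(hits))
}

.angle_deg <- function(a, b, c) {
  v1 <- a - b; v2 <- c - b
  cs <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
  acos(pmin(1, pmax(-1, cs))) * 180 / pi
}

#' Detect interdomain hydrogen bonds in one frame
#'
#' Geometric criterion: donor and acceptor heavy atoms within `dist_cutoff`,
#' plus an angular test. With explicit hydrogens bonded to the donor, the
#' D-H...A angle must be at least `angle_h`; without hydrogens the proxy is
#' the antecedent-donor-acceptor angle (e.g. CA-N...O) of at least
#' `angle_proxy`, which screens out geometries where the acceptor sits behind
#' the donor. Donors/acceptors come from residue templates (backbone amide
#' N/carbonyl O plus polar side chains); residue types outside the templates
#' are skipped with a warning.
#'
#' @param structure a `Structure` carrying the frame coordinates.
#' @param interface an `InterfaceSpec` or list of chain pairs.
#' @param dist_cutoff donor-acceptor heavy-atom cutoff (A), default 3.5.
#' @param angle_h D-H...A angle threshold with hydrogens (deg), default 150.
#' @param angle_proxy antecedent-D...A threshold without hydrogens (deg),
#'   default 120.
#' @return data.frame as in [detect_ion_pairs()].
#' @export
detect_hydrogen_bonds <- function(structure, interface, dist_cutoff = 3.5,
                                  angle_h = 150, angle_proxy = 120) {
  pairs <- if (inherits(interface, "InterfaceSpec")) interface$pairs
           else interface
  a <- structure$atoms
  xyz <- structure$xyz
  unknown <- setdiff(unique(a$resid),
                     c(.PROTEIN_RESIDUES, "HOH", "WAT"))
  if (length(unknown) > 0) {
    warning("unknown residue type(s) skipped for H-bonds: ",
            paste(unknown, collapse = ", "))
  }
  has_h <- any(a$element == "H")
  out <- list()
  for (pr in pairs) {
    for (ori in list(pr, rev(pr))) {
      don <- .hb_donor_atoms(structure, ori[1])
      acc <- .hb_acceptor_atoms(structure, ori[2])
      if (nrow(don) == 0 || length(acc) == 0) next
      d <- .cross_dist(xyz[don[, 1], , drop = FALSE],
                       xyz[acc, , drop = FALSE])
      cand <- which(d <= dist_cutoff, arr.ind = TRUE)
      if (nrow(cand) == 0) next
      ok <- logical(nrow(cand))
      for (r in seq_len(nrow(cand))) {
        di <- don[cand[r, 1], 1]; ante <- don[cand[r, 1], 2]
        ai <- acc[cand[r, 2]]
        if (has_h) {
          # hydrogens bonded to this donor: same residue, element H, within 1.3 A
          hs <- which(a$chain == ori[1] & a$resno == a$resno[di] &
                        a$element == "H")
          hs <- hs[sqrt(rowSums(sweep(xyz[hs, , drop = FALSE], 2,
                                      xyz[di, ])^2)) < 1.3]
          ok[r] <- length(hs) > 0 && any(vapply(hs, function(h) {
            .angle_deg(xyz[di, ], xyz[h, ], xyz[ai, ]) >= angle_h
          }, logical(1)))
        } else {
          ok[r] <- is.na(ante) ||
            .angle_deg(xyz[ante, ], xyz[di, ], xyz[ai, ]) >= angle_proxy
        }
      }
      cand <- cand[ok, , drop = FALSE]
      if (nrow(cand) == 0) next
      out[[length(out) + 1]] <- data.frame(
        chain1 = ori[1], resno1 = a$resno[don[cand[, 1], 1]],
        resid1 = a$resid[don[cand[, 1], 1]],
        chain2 = ori[2], resno2 = a$resno[acc[cand[, 2]]],
        resid2 = a$resid[acc[cand[, 2]]],
        min_dist = d[cand]
      )
    }
  }
  .collapse_contacts(out)
}

#' Contact timelines over a trajectory
#'
#' Runs the ion-pair or hydrogen-bond detector on every frame of a trajectory
#' for one interface and aggregates: the per-frame contact count (the Fig
#' 5-style timeline), the occupancy of every distinct residue pair (fraction
#' of frames present), and the mean +/- sd count for Table-style reporting.
#'
#' @param traj a `Trajectory`.
#' @param interface an `InterfaceSpec` or list of chain pairs.
#' @param type `"ip"` or `"hb"`.
#' @param ... passed to the detector ([detect_ion_pairs()] or
#'   [detect_hydrogen_bonds()]).
#' @return an object of class `ContactTimeline`: list with `type`, `counts`
#'   (per frame), `times` (ps), `occupancy` (named vector per pair),
#'   `presence` (frames x pairs logical matrix), `mean_count`, `sd_count`,
#'   `n_distinct_pairs`.
#' @export
contact_timelines <- function(traj, interface, type = c("ip", "hb"), ...) {
  type <- match.arg(type)
  detector <- if (type == "ip") detect_ion_pairs else detect_hydrogen_bonds
  nfr <- n_frames(traj)
  per_frame <- vector("list", nfr)
  top <- traj$topology
  for (f in seq_len(nfr)) {
    s <- set_coords(top, frame_coords(traj, f))
    per_frame[[f]] <- detector(s, interface, ...)$pair_id
  }
  all_pairs <- sort(unique(unlist(per_frame)))
  presence <- matrix(FALSE, nfr, length(all_pairs),
                     dimnames = list(NULL, all_pairs))
  for (f in seq_len(nfr)) presence[f, per_frame[[f]]] <- TRUE
  counts <- rowSums(presence)
  structure(
    list(type = type, counts = counts, times = traj$times,
         occupancy = colMeans(presence), presence = presence,
         mean_count = mean(counts), sd_count = sd(counts),
         n_distinct_pairs = length(all_pairs),
         label = if (inherits(interface, "InterfaceSpec")) interface$label
                 else NA_character_),
    class = "ContactTimeline"
  )
}

#' @export
print.ContactTimeline <- function(x, ...) {
  cat(sprintf(
    "<ContactTimeline %s%s> %d frames, mean count %.2f +/- %.2f, %d distinct pairs\n",
    toupper(x$type), if (is.na(x$label)) "" else paste0(" (", x$label, ")"),
    length(x$counts), x$mean_count, x$sd_count, x$n_distinct_pairs))
  invisible(x)
}

#' Classify interfacial surface into hydrophobic / hydrophilic / mixed
#'
#' Builds the power (radical Voronoi) tessellation of the heavy atoms around
#' an interface and collects the facet areas separating atoms that belong to
#' the two different chains of each pair, keeping only facets between atoms
#' in solvent-probe contact (distance <= r_i + r_j + 2 * probe). Each facet
#' is classed by the elements of its two atoms: C/S vs C/S is
#' hydrophobic-hydrophobic, N/O vs N/O hydrophilic-hydrophilic, anything
#' else mixed. Fractions are normalized to sum to 1 per interface.
#'
#' @param structure a `Structure` carrying the frame coordinates.
#' @param interface an `InterfaceSpec` or list of chain pairs.
#' @param probe solvent probe radius (A), default 1.4.
#' @return an object of class `SurfaceClassification`: list with `fractions`
#'   (named: hydrophobic, hydrophilic, mixed; sums to 1), `areas` (A^2),
#'   `total_area`, `method` ("voronoi-facets").
#' @export
classify_interface_surface <- function(structure, interface, probe = 1.4) {
  pairs <- if (inherits(interface, "InterfaceSpec")) interface$pairs
           else interface
  a <- structure$atoms
  heavy <- which(a$element != "H")
  xyz <- structure$xyz[heavy, , drop = FALSE]
  elem <- a$element[heavy]
  chain <- a$chain[heavy]
  radii <- .vdw_radius(elem)
  phob <- elem %in% c("C", "S")
  areas <- c(hydrophobic = 0, hydrophilic = 0, mixed = 0)
  for (pr in pairs) {
    i1 <- which(chain == pr[1]); i2 <- which(chain == pr[2])
    if (length(i1) == 0 || length(i2) == 0) next
    d <- .cross_dist(xyz[i1, , drop = FALSE], xyz[i2, , drop = FALSE])
    contact <- d <= outer(radii[i1], radii[i2], "+") + 2 * probe
    touching1 <- i1[rowSums(contact) > 0]
    if (length(touching1) == 0) next
    # context set: all heavy atoms near any touching atom, to bound the cells
    near <- unique(unlist(lapply(touching1, function(i) {
      which(sqrt(colSums((t(xyz) - xyz[i, ])^2)) < 10)
    })))
    sub <- sort(unique(c(touching1, near)))
    pos <- xyz[sub, , drop = FALSE]
    rad <- radii[sub]
    for (i in touching1) {
      self <- match(i, sub)
      cell <- .voronoi_cell(pos, rad, self, bound = 20)
      if (is.null(cell)) next
      for (k in seq_along(cell$neighbor)) {
        j <- sub[cell$neighbor[k]]
        if (chain[j] != pr[2]) next
        dij <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
        if (dij > radii[i] + radii[j] + 2 * probe) next
        cls <- if (phob[i] && phob[j]) "hydrophobic"
               else if (!phob[i] && !phob[j]) "hydrophilic"
               else "mixed"
        areas[cls] <- areas[cls] + cell$face_area[k]
      }
    }
  }
  total <- sum(areas)
  if (total <= 0) stop("interface empty: no interfacial contact found")
  structure(
    list(fractions = areas / total, areas = areas, total_area = total,
         method = "voronoi-facets", probe = probe,
         label = if (inherits(interface, "InterfaceSpec")) interface$label
                 else NA_character_),
    class = "SurfaceClassification"
  )
}

.vdw_radius <- function(elem) {
  tbl <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20, P = 1.80)
  r <- tbl[elem]
  r[is.na(r)] <- 1.70
  unname(r)
}

#' Ion-pair occupancy network
#'
#' Builds the salt-bridge network across all supplied interface timelines:
#' nodes are charged residues (labeled chain:resno resid, colored by chain)
#' weighted by the fraction of frames in which the residue forms at least one
#' interdomain ion pair; edges are residue pairs weighted by their pair
#' occupancy. Edges below `display_threshold` are kept in the data but
#' flagged for display filtering.
#'
#' @param timelines list of `ContactTimeline` objects (type "ip").
#' @param display_threshold occupancy below which an edge is flagged
#'   (default 0.1).
#' @return an `igraph` graph with vertex attributes `occupancy`, `chain` and
#'   edge attributes `occupancy`, `display`.
#' @export
build_ip_network <- function(timelines, display_threshold = 0.1) {
  if (inherits(timelines, "ContactTimeline")) timelines <- list(timelines)
  if (length(timelines) == 0) stop("no timelines supplied")
  edges <- list(); node_frames <- list(); nfr_total <- 0
  for (tl in timelines) {
    pairs <- colnames(tl$presence)
    nfr <- nrow(tl$presence)
    nfr_total <- max(nfr_total, nfr)
    for (p in pairs) {
      ends <- strsplit(p, "-", fixed = TRUE)[[1]]
      edges[[length(edges) + 1]] <-
        data.frame(from = ends[1], to = ends[2],
                   occupancy = unname(tl$occupancy[p]))
      for (e in ends) {
        prev <- node_frames[[e]]
        node_frames[[e]] <- if (is.null(prev)) tl$presence[, p]
                            else prev | tl$presence[, p]
      }
    }
  }
  if (length(edges) == 0) {
    return(igraph::make_empty_graph(directed = FALSE))
  }
  ed <- do.call(rbind, edges)
  # merge duplicate edges across timelines by max occupancy
  key <- paste(ed$from, ed$to)
  ed <- ed[order(key, -ed$occupancy), ]
  ed <- ed[!duplicated(paste(ed$from, ed$to)), ]
  g <- igraph::graph_from_data_frame(ed, directed = FALSE)
  node_occ <- vapply(igraph::V(g)$name,
                     function(v) mean(node_frames[[v]]), numeric(1))
  igraph::V(g)$occupancy <- node_occ
  igraph::V(g)$chain <- sub(":.*$", "", igraph::V(g)$name)
  igraph::E(g)$display <- igraph::E(g)$occupancy >= display_threshold
  g
}

#' Census of interfacial hydrophobic residues
#'
#' Counts, per chain of each pair, the hydrophobic residues (Ala, Val, Leu,
#' Ile, Pro, Phe, Met, Trp) having any side-chain heavy atom within `cutoff`
#' of a side-chain heavy atom of a hydrophobic residue on the opposite chain.
#'
#' @param structure a `Structure`.
#' @param interface an `InterfaceSpec` or list of chain pairs.
#' @param cutoff distance cutoff (A), default 4.5.
#' @return data.frame `chain`, `partner_chain`, `n_hydrophobic`.
#' @export
hydrophobic_proximity_census <- function(structure, interface, cutoff = 4.5) {
  pairs <- if (inherits(interface, "InterfaceSpec")) interface$pairs
           else interface
  a <- structure$atoms
  side_heavy <- a$element != "H" & !(a$name %in% .BACKBONE_NAMES) &
    a$resid %in% .HYDROPHOBIC_RES
  out <- list()
  for (pr in pairs) {
    for (ori in list(pr, rev(pr))) {
      i1 <- which(side_heavy & a$chain == ori[1])
      i2 <- which(side_heavy & a$chain == ori[2])
      n <- 0L
      if (length(i1) > 0 && length(i2) > 0) {
        d <- .cross_dist(structure$xyz[i1, , drop = FALSE],
                         structure$xyz[i2, , drop = FALSE])
        close_atom <- rowSums(d <= cutoff) > 0
        n <- length(unique(a$resno[i1[close_atom]]))
      }
      out[[length(out) + 1]] <- data.frame(
        chain = ori[1], partner_chain = ori[2], n_hydrophobic = n)
    }
  }
  do.call(rbind, out)
}
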