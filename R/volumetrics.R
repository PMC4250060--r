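# ---- radical (power) Voronoi cell by half-space clipping -------------------
#
# The cell of generator i is the intersection of the half-spaces
#   { x : |x - p_i|^2 - r_i^2 <= |x - p_j|^2 - r_j^2 }  for all j != i,
# i.e. 2 (p_j - p_i) . x <= |p_j|^2 - |p_i|^2 + r_i^2 - r_j^2.
# The polyhedron starts as a bounding cube and is clipped plane by plane
# (voro++ style), nearest generators first, stopping once the next bisector
# lies beyond the farthest remaining vertex. No 3-D tessellation library
# exists in the R stack, so the construction is done here directly.

# Clip convex polyhedron (verts, faces, face_nb) by half-space a.x <= b.
# Returns NULL when nothing remains. `nb` tags the new cap face.
.clip_poly <- function(poly, a, b, nb, tol) {
  s <- as.vector(poly$verts %*% a) - b
  if (all(s <= tol)) return(poly)          # plane does not cut
  if (all(s >= -tol)) return(NULL)         # cell entirely outside
  verts <- poly$verts
  new_faces <- list(); new_nb <- integer(0)
  edge_cache <- new.env(hash = TRUE, parent = emptyenv())
  cap <- integer(0)
  cut_edge <- function(v1, v2) {
    key <- paste(min(v1, v2), max(v1, v2))
    hit <- edge_cache[[key]]
    if (!is.null(hit)) return(hit)
    t <- s[v1] / (s[v1] - s[v2])
    p <- verts[v1, ] + t * (verts[v2, ] - verts[v1, ])
    verts <<- rbind(verts, p)
    idx <- nrow(verts)
    edge_cache[[key]] <- idx
    idx
  }
  for (fi in seq_along(poly$faces)) {
    loop <- poly$faces[[fi]]
    nl <- length(loop)
    out <- integer(0)
    for (k in seq_len(nl)) {
      v1 <- loop[k]; v2 <- loop[if (k == nl) 1 else k + 1]
      in1 <- s[v1] <= tol; in2 <- s[v2] <= tol
      if (in1) out <- c(out, v1)
      if ((s[v1] > tol && s[v2] < -tol) || (s[v1] < -tol && s[v2] > tol)) {
        out <- c(out, cut_edge(v1, v2))
      }
    }
    out <- out[c(TRUE, out[-1] != out[-length(out)])]
    if (length(out) > 1 && out[1] == out[length(out)]) {
      out <- out[-length(out)]
    }
    if (length(out) >= 3) {
      new_faces[[length(new_faces) + 1]] <- out
      new_nb <- c(new_nb, poly$face_nb[fi])
      on_plane <- out[abs(s[out]) <= tol | out > length(s)]
      cap <- c(cap, on_plane)
    }
  }
  cap <- unique(cap)
  if (length(cap) >= 3) {
    # order cap vertices around the clip plane
    nrm <- a / sqrt(sum(a^2))
    u <- if (abs(nrm[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    e1 <- u - sum(u * nrm) * nrm; e1 <- e1 / sqrt(sum(e1^2))
    e2 <- c(nrm[2] * e1[3] - nrm[3] * e1[2],
            nrm[3] * e1[1] - nrm[1] * e1[3],
            nrm[1] * e1[2] - nrm[2] * e1[1])
    pts <- verts[cap, , drop = FALSE]
    ctr <- colMeans(pts)
    ang <- atan2((pts - rep(ctr, each = nrow(pts))) %*% e2,
                 (pts - rep(ctr, each = nrow(pts))) %*% e1)
    new_faces[[length(new_faces) + 1]] <- cap[order(ang)]
    new_nb <- c(new_nb, nb)
  }
  if (length(new_faces) < 4) return(NULL)
  list(verts = verts, faces = new_faces, face_nb = new_nb)
}

# Volume and per-face areas of a convex polyhedron via fan decomposition
# about the vertex centroid (interior for convex bodies).
.poly_measure <- function(poly) {
  used <- unique(unlist(poly$faces))
  O <- colMeans(poly$verts[used, , drop = FALSE])
  vol <- 0
  areas <- numeric(length(poly$faces))
  for (fi in seq_along(poly$faces)) {
    loop <- poly$faces[[fi]]
    v1 <- poly$verts[loop[1], ] - O
    area <- 0
    for (k in 2:(length(loop) - 1)) {
      va <- poly$verts[loop[k], ] - O
      vb <- poly$verts[loop[k + 1], ] - O
      cx <- c(va[2] * vb[3] - va[3] * vb[2],
              va[3] * vb[1] - va[1] * vb[3],
              va[1] * vb[2] - va[2] * vb[1])
      vol <- vol + abs(sum(v1 * cx)) / 6
      e1 <- poly$verts[loop[k], ] - poly$verts[loop[1], ]
      e2 <- poly$verts[loop[k + 1], ] - poly$verts[loop[1], ]
      cr <- c(e1[2] * e2[3] - e1[3] * e2[2],
              e1[3] * e2[1] - e1[1] * e2[3],
              e1[1] * e2[2] - e1[2] * e2[1])
      area <- area + sqrt(sum(cr^2)) / 2
    }
    areas[fi] <- area
  }
  list(volume = vol, face_area = areas)
}

# Power-Voronoi cell of points[self, ]. `box`: c(Lx, Ly, Lz) for a periodic
# domain (periodic images generated internally); `bound`: half-size of the
# initial bounding cube for open domains. Returns volume, generating
# neighbors of the kept faces, their facet areas, and whether any bounding-
# cube face survived (an unbounded cell in the open-domain sense).
.voronoi_cell <- function(points, radii, self, box = NULL, bound = 30) {
  p0 <- points[self, ]
  if (is.null(radii)) radii <- rep(0, nrow(points))
  if (!is.null(box)) {
    shifts <- as.matrix(expand.grid(x = c(-1, 0, 1) * box[1],
                                    y = c(-1, 0, 1) * box[2],
                                    z = c(-1, 0, 1) * box[3]))
    nb_pos <- do.call(rbind, lapply(seq_len(nrow(shifts)), function(s) {
      sweep(points, 2, as.numeric(shifts[s, ]), "+")
    }))
    nb_rad <- rep(radii, nrow(shifts))
    nb_id <- rep(seq_len(nrow(points)), nrow(shifts))
    central <- which(rowSums(abs(shifts)) == 0)
    self_row <- (central - 1) * nrow(points) + self
    keep <- seq_len(nrow(nb_pos)) != self_row
    nb_pos <- nb_pos[keep, , drop = FALSE]
    nb_rad <- nb_rad[keep]; nb_id <- nb_id[keep]
    bound <- max(box)
  } else {
    keep <- seq_len(nrow(points)) != self
    nb_pos <- points[keep, , drop = FALSE]
    nb_rad <- radii[keep]
    nb_id <- which(keep)
  }
  tol <- 1e-9 * bound
  # initial bounding cube centered on the generator, faces tagged NA
  h <- bound
  cv <- as.matrix(expand.grid(c(-h, h), c(-h, h), c(-h, h)))
  verts <- sweep(cv, 2, p0, "+")
  faces <- list(c(1, 2, 4, 3), c(5, 7, 8, 6), c(1, 5, 6, 2),
                c(3, 4, 8, 7), c(1, 3, 7, 5), c(2, 6, 8, 4))
  poly <- list(verts = verts, faces = faces,
               face_nb = rep(NA_integer_, 6))
  dvec <- sweep(nb_pos, 2, p0)
  power_d <- rowSums(dvec^2) - nb_rad^2
  ord <- order(power_d)
  for (j in ord) {
    a <- 2 * (nb_pos[j, ] - p0)
    b <- sum(nb_pos[j, ]^2) - sum(p0^2) + radii[self]^2 - nb_rad[j]^2
    # early exit: plane distance from generator beyond farthest vertex
    an <- sqrt(sum(a^2))
    if (an < 1e-12) next
    plane_d <- (b - sum(a * p0)) / an
    used <- unique(unlist(poly$faces))
    rmax <- sqrt(max(rowSums(sweep(poly$verts[used, , drop = FALSE],
                                   2, p0)^2)))
    if (plane_d > rmax) break
    poly <- .clip_poly(poly, a, b, j, tol)
    if (is.null(poly)) return(NULL)
  }
  meas <- .poly_measure(poly)
  nbset <- poly$face_nb
  real <- !is.na(nbset)
  list(volume = meas$volume,
       neighbor = nb_id[nbset[real]],
       face_area = meas$face_area[real],
       unbounded = any(!real))
}

#' Per-atom volumes by radical Voronoi tessellation
#'
#' Partitions space among atoms (generators weighted by their van der Waals
#' radii, i.e. a power diagram) and returns the cell volume of each
#' requested generator. In a periodic box the tessellation partitions the
#' box exactly, so cell volumes sum to the box volume. In an open domain a
#' set of boundary generators must enclose the atoms of interest so their
#' cells are bounded; if none is supplied a solvent-probe shell is generated
#' at 2.8 A offset from the molecular surface. Detecting a still-unbounded
#' cell is an error instructing to supply a boundary.
#'
#' @param coords n x 3 generator coordinates (A).
#' @param radii per-generator radii (A); NULL for an unweighted tessellation.
#' @param box `c(Lx, Ly, Lz)` of a periodic box, or NULL for an open domain.
#' @param boundary matrix of extra boundary generator coordinates, TRUE to
#'   auto-generate a probe shell (default for open domains), or FALSE/NULL
#'   for none.
#' @param subset indices of the generators whose volumes to return
#'   (default all rows of `coords`).
#' @return list with `volumes` (per subset generator, A^3), `subset`,
#'   `boundary_points` (the shell used, if any).
#' @export
tessellate_volumes <- function(coords, radii = NULL, box = NULL,
                               boundary = NULL, subset = NULL) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (is.null(subset)) subset <- seq_len(n)
  if (!is.null(box)) {
    vols <- vapply(subset, function(i) {
      cell <- .voronoi_cell(coords, radii, i, box = box)
      if (is.null(cell)) 0 else cell$volume
    }, numeric(1))
    return(list(volumes = vols, subset = subset, boundary_points = NULL))
  }
  shell <- NULL
  if (is.null(boundary) || isTRUE(boundary)) {
    shell <- .probe_shell(coords, radii)
  } else if (is.matrix(boundary)) {
    shell <- boundary
  }
  all_pts <- if (is.null(shell)) coords else rbind(coords, shell)
  all_rad <- if (is.null(radii)) NULL
             else c(radii, rep(1.4, if (is.null(shell)) 0 else nrow(shell)))
  span <- max(apply(all_pts, 2, function(v) diff(range(v)))) + 10
  vols <- numeric(length(subset))
  for (k in seq_along(subset)) {
    cell <- .voronoi_cell(all_pts, all_rad, subset[k], bound = span)
    if (is.null(cell) || cell$unbounded) {
      stop("unbounded Voronoi cell for generator ", subset[k],
           "; supply boundary generators enclosing the atoms")
    }
    vols[k] <- cell$volume
  }
  list(volumes = vols, subset = subset, boundary_points = shell)
}

# Solvent-probe shell: candidate points on each atom at vdW radius + 2.8 A
# along icosahedral directions, kept when outside every atom's probe-contact
# surface, thinned on a 1.5 A grid.
.probe_shell <- function(coords, radii = NULL, offset = 2.8) {
  if (is.null(radii)) radii <- rep(0, nrow(coords))
  phi <- (1 + sqrt(5)) / 2
  dirs <- rbind(
    cbind(0, c(-1, -1, 1, 1), c(-phi, phi, -phi, phi)),
    cbind(c(-1, -1, 1, 1), c(-phi, phi, -phi, phi), 0),
    cbind(c(-phi, phi, -phi, phi), 0, c(-1, -1, 1, 1))
  )
  dirs <- dirs / sqrt(rowSums(dirs^2))
  cand <- do.call(rbind, lapply(seq_len(nrow(coords)), function(i) {
    sweep(dirs * (radii[i] + offset), 2, coords[i, ], "+")
  }))
  # drop candidates that intrude into another atom's offset sphere
  min_clear <- radii + offset - 0.5
  ok <- vapply(seq_len(nrow(cand)), function(k) {
    d <- sqrt(rowSums(sweep(coords, 2, cand[k, ])^2))
    all(d >= min_clear - 1e-9)
  }, logical(1))
  cand <- cand[ok, , drop = FALSE]
  if (nrow(cand) == 0) return(cand)
  key <- paste(round(cand[, 1] / 1.5), round(cand[, 2] / 1.5),
               round(cand[, 3] / 1.5))
  cand[!duplicated(key), , drop = FALSE]
}

#' Per-frame protein volume series
#'
#' Runs the tessellation on every frame of a trajectory and records the total
#' volume of the selected atoms plus the per-atom mean.
#'
#' @param traj a `Trajectory`.
#' @param selection selection expression or indices; default "heavy".
#' @param temperature temperature (K) attached to the series; defaults to
#'   the trajectory's.
#' @return an object of class `VolumeSeries`: list with `total` (per-frame
#'   A^3), `per_atom` (per-frame total / atom count), `n_atoms`, `times`,
#'   `temperature`.
#' @export
volume_series <- function(traj, selection = "heavy", temperature = NULL) {
  idx <- .as_indices(traj$topology, selection)
  if (length(idx) == 0) stop("empty selection for volumetrics")
  radii <- .vdw_radius(traj$topology$atoms$element[idx])
  tot <- vapply(seq_len(n_frames(traj)), function(f) {
    crd <- frame_coords(traj, f)[idx, , drop = FALSE]
    sum(tessellate_volumes(crd, radii)$volumes)
  }, numeric(1))
  new_volume_series(tot, length(idx), traj$times,
                    temperature %||% traj$temperature)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct a VolumeSeries directly
#' @param total per-frame total volume (A^3).
#' @param n_atoms atom count the totals refer to.
#' @param times frame times (ps).
#' @param temperature temperature (K), optional.
#' @return an object of class `VolumeSeries`.
#' @export
new_volume_series <- function(total, n_atoms, times = seq_along(total),
                              temperature = NULL) {
  if (any(total <= 0)) stop("volumes must be positive")
  structure(list(total = as.numeric(total), per_atom = total / n_atoms,
                 n_atoms = n_atoms, times = times,
                 temperature = temperature),
            class = "VolumeSeries")
}

#' Mean volume per atom of a volume series
#' @param series a `VolumeSeries`.
#' @return list with `mean` and `sd` of the per-frame volume per atom (A^3).
#' @export
volume_per_atom <- function(series) {
  if (length(series$total) < 2) stop("need at least 2 frames")
  list(mean = mean(series$per_atom), sd = sd(series$per_atom))
}

# Boltzmann constant in GPa * A^3 / K (1.380649e-23 J/K, 1 GPa A^3 = 1e-21 J)
.KB_GPA_A3 <- 1.380649e-2

#' Intrinsic compressibility from volume fluctuations
#'
#' Equilibrium fluctuation estimate of the isothermal compressibility of the
#' protein interior, beta_T = <delta V^2> / (k_B T <V>), reported in
#' 10^-2 GPa^-1. Doubling the temperature at fixed fluctuations halves
#' beta_T; a constant volume series gives 0 with a warning.
#'
#' @param series a `VolumeSeries`.
#' @param temperature temperature in K; defaults to the series temperature.
#' @return list with `beta_T` (10^-2 GPa^-1), `mean_volume` (A^3),
#'   `var_volume` (A^6), `temperature` (K), `formula`.
#' @export
intrinsic_compressibility <- function(series, temperature = NULL) {
  temperature <- temperature %||% series$temperature
  if (is.null(temperature) || temperature <= 0) {
    stop("a positive temperature (K) is required")
  }
  v <- series$total
  mv <- mean(v)
  vv <- mean((v - mv)^2)
  if (vv == 0) {
    warning("zero volume variance: compressibility is 0")
  }
  beta_gpa <- vv / (.KB_GPA_A3 * temperature * mv)
  list(beta_T = beta_gpa * 100, mean_volume = mv, var_volume = vv,
       temperature = temperature,
       formula = "<dV^2>/(kB T <V>), units 1e-2 GPa^-1")
}
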