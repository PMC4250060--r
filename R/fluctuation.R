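#' Windowed root mean square fluctuations
#'
#' Multi-timescale RMSF: the trajectory is cut into non-overlapping blocks of
#' length `window` (ps). Within each block the squared deviation of every
#' selected atom from its block-mean position is averaged (inner average);
#' the outer average runs over blocks, and RMSF = sqrt of the double average.
#' The block-to-block standard deviation of the per-block RMS deviation is
#' returned as the long-timescale variability. By default every block is
#' first superposed onto its own mean structure (two fit iterations, fitting
#' on the analysis selection) so only internal motion within the window is
#' counted; set `fit = FALSE` when the trajectory carries no rigid-body
#' component (e.g. synthetic stationary fluctuations in the lab frame).
#'
#' @param traj a `Trajectory`.
#' @param selection selection expression or indices; default "calpha".
#' @param window inner window length tau_w in ps.
#' @param fit superpose each block onto its own mean before measuring
#'   deviations (default TRUE).
#' @return an object of class `RMSFProfile`: data.frame of `atom`, `chain`,
#'   `resno`, `rmsf` (A), `variability` (A) plus attributes `window` (ps) and
#'   `selection`.
#' @export
rmsf_windowed <- function(traj, selection = "calpha", window, fit = TRUE) {
  idx <- .as_indices(traj$topology, selection)
  if (length(idx) == 0) stop("empty selection for RMSF")
  wlen <- floor(window / traj$dt)
  if (wlen < 2) stop("window must span at least 2 frames")
  nfr <- n_frames(traj)
  nblocks <- nfr %/% wlen
  if (nblocks < 2) {
    stop(sprintf(
      "window (%g ps) longer than half the trajectory (%g ps); need >= 2 blocks",
      window, nfr * traj$dt))
  }
  cols <- as.vector(rbind(3 * idx - 2, 3 * idx - 1, 3 * idx))
  n_at <- length(idx)
  block_msd <- matrix(NA_real_, nblocks, n_at)   # per-block mean squared dev
  for (b in seq_len(nblocks)) {
    rows <- ((b - 1) * wlen + 1):(b * wlen)
    X <- traj$xyz[rows, cols, drop = FALSE]      # wlen x 3*n_at
    if (fit) X <- .fit_block_to_mean(X, n_at)
    mu <- colMeans(X)
    dev2 <- sweep(X, 2, mu)^2
    # sum x,y,z components per atom, average over frames
    per_atom <- colMeans(dev2)
    block_msd[b, ] <- per_atom[c(TRUE, FALSE, FALSE)] +
      per_atom[c(FALSE, TRUE, FALSE)] + per_atom[c(FALSE, FALSE, TRUE)]
  }
  rmsf <- sqrt(colMeans(block_msd))
  variability <- apply(sqrt(block_msd), 2, sd)
  out <- data.frame(
    atom = idx,
    chain = traj$topology$atoms$chain[idx],
    resno = traj$topology$atoms$resno[idx],
    rmsf = rmsf, variability = variability
  )
  attr(out, "window") <- window
  attr(out, "selection") <- if (is.character(selection)) selection else "indices"
  class(out) <- c("RMSFProfile", "data.frame")
  out
}

# Iteratively superpose every frame of a block (rows of X, coords flattened
# x1 y1 z1 x2 ...) onto the running block-mean structure. Two passes are
# enough for the small displacements RMSF operates on.
.fit_block_to_mean <- function(X, n_at) {
  to_mat <- function(v) matrix(v, ncol = 3, byrow = TRUE)
  ref <- to_mat(X[1, ])
  for (pass in 1:2) {
    for (f in seq_len(nrow(X))) {
      fit <- superpose(to_mat(X[f, ]), ref)
      X[f, ] <- as.vector(t(fit$coords))
    }
    ref <- to_mat(colMeans(X))
  }
  X
}

#' Average RMSF over atoms (and chains)
#'
#' Scalar flexibility summary per (system, temperature, window): the plain
#' mean RMSF over all selected atoms; for tetramers pass a profile computed
#' on all four chains so every chain contributes.
#'
#' @param profile an `RMSFProfile` (or a list of them, pooled with equal
#'   atom weight).
#' @return mean RMSF (A).
#' @export
rmsf_average <- function(profile) {
  if (inherits(profile, "RMSFProfile")) profile <- list(profile)
  vals <- unlist(lapply(profile, function(p) p$rmsf))
  if (length(vals) == 0) stop("empty RMSF profile")
  mean(vals)
}

#' Temperature derivative of an RMSF profile
#'
#' Finite-difference response of per-atom RMSF to temperature,
#' (RMSF(T2) - RMSF(T1)) / (T2 - T1), requiring the two profiles to cover the
#' same atoms with the same window.
#'
#' @param profile_T1,profile_T2 `RMSFProfile`s at temperatures T1 < T2.
#' @param T1,T2 the temperatures (K).
#' @return data.frame `atom`, `chain`, `resno`, `slope` (A/K).
#' @export
rmsf_temperature_derivative <- function(profile_T1, profile_T2, T1, T2) {
  if (T2 <= T1) stop("T2 must exceed T1")
  if (!identical(profile_T1$atom, profile_T2$atom)) {
    stop("profiles cover different atoms")
  }
  if (!isTRUE(all.equal(attr(profile_T1, "window"),
                        attr(profile_T2, "window")))) {
    stop("profiles use different windows")
  }
  data.frame(atom = profile_T1$atom, chain = profile_T1$chain,
             resno = profile_T1$resno,
             slope = (profile_T2$rmsf - profile_T1$rmsf) / (T2 - T1))
}

#' Stiffening pattern upon oligomerization
#'
#' Relative RMSF drop per residue between the isolated monomer and the same
#' chain inside the assembled oligomer:
#' change = (RMSF_mono - RMSF_tetra) / RMSF_mono, so positive values mean
#' stiffening upon assembly. Residues are matched by residue number;
#' residues with zero monomer RMSF are skipped with a warning. Returns the
#' residues whose change exceeds `threshold`.
#'
#' @param rmsf_monomer `RMSFProfile` of the isolated chain.
#' @param rmsf_oligomer `RMSFProfile` of the same chain in the assembly.
#' @param threshold relative-change threshold (default 0.30).
#' @return an object of class `RigidityPattern`: data.frame of `resno`,
#'   `rmsf_mono`, `rmsf_tetra`, `change` for residues above threshold, with
#'   the full per-residue table in attribute `all`.
#' @export
rigidity_pattern <- function(rmsf_monomer, rmsf_oligomer, threshold = 0.30) {
  mono <- rmsf_monomer[order(rmsf_monomer$resno), ]
  tet <- rmsf_oligomer[order(rmsf_oligomer$resno), ]
  common <- intersect(mono$resno, tet$resno)
  if (length(common) == 0) stop("no residue correspondence between profiles")
  mono <- mono[match(common, mono$resno), ]
  tet <- tet[match(common, tet$resno), ]
  zero <- mono$rmsf <= 0
  if (any(zero)) {
    warning(sum(zero), " residue(s) with zero monomer RMSF skipped")
  }
  tab <- data.frame(resno = common,
                    rmsf_mono = mono$rmsf, rmsf_tetra = tet$rmsf)
  tab$change <- ifelse(zero, NA_real_,
                       (tab$rmsf_mono - tab$rmsf_tetra) / tab$rmsf_mono)
  out <- tab[!is.na(tab$change) & tab$change > threshold, ]
  rownames(out) <- NULL
  attr(out, "threshold") <- threshold
  attr(out, "all") <- tab
  class(out) <- c("RigidityPattern", "data.frame")
  out
}
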