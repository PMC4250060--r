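#' Leader-algorithm conformational clustering
#'
#' Single-pass clustering of trajectory frames by pairwise superposed RMSD:
#' frames are scanned in time order; a frame joins the first existing cluster
#' whose leader frame lies within `cutoff` RMSD (leaders tried in creation
#' order), otherwise it founds a new cluster and becomes its leader. The
#' cumulative number of distinct clusters n(t) measures how fast the system
#' explores its conformational substates.
#'
#' @param traj a `Trajectory`.
#' @param selection RMSD metric selection; default "heavy" (all heavy atoms).
#'   Use e.g. `"chain A and heavy"` to cluster a single chain of a multimer.
#' @param cutoff RMSD cutoff in A (default 1.3).
#' @return an object of class `ClusterGrowth`: list with `assignment`
#'   (per-frame cluster id), `leaders` (frame indices of leaders), `n_t`
#'   (cumulative distinct clusters per frame), `times` (ps), `cutoff`,
#'   `selection`.
#' @export
leader_cluster <- function(traj, selection = "heavy", cutoff = 1.3) {
  if (cutoff <= 0) stop("cutoff must be positive")
  idx <- .as_indices(traj$topology, selection)
  if (length(idx) == 0) stop("empty selection for clustering")
  nfr <- n_frames(traj)
  leaders <- integer(0)
  leader_coords <- list()
  assignment <- integer(nfr)
  n_t <- integer(nfr)
  for (f in seq_len(nfr)) {
    crd <- frame_coords(traj, f)[idx, , drop = FALSE]
    hit <- 0L
    for (k in seq_along(leaders)) {
      if (rmsd_fit(crd, leader_coords[[k]]) <= cutoff) { hit <- k; break }
    }
    if (hit == 0L) {
      leaders <- c(leaders, f)
      leader_coords[[length(leaders)]] <- crd
      hit <- length(leaders)
    }
    assignment[f] <- hit
    n_t[f] <- length(leaders)
  }
  structure(
    list(assignment = assignment, leaders = leaders, n_t = n_t,
         times = traj$times, cutoff = cutoff,
         selection = if (is.character(selection)) selection else "indices"),
    class = "ClusterGrowth"
  )
}

#' @export
print.ClusterGrowth <- function(x, ...) {
  cat(sprintf("<ClusterGrowth> %d frames -> %d clusters (cutoff %g A, %s)\n",
              length(x$assignment), length(x$leaders), x$cutoff, x$selection))
  invisible(x)
}

#' Exponential saturation fit of cluster-count growth
#'
#' Fits n(t) = Ninf * (1 - exp(-t / tau)) to the cumulative cluster count by
#' nonlinear least squares, giving the extrapolated maximum number of
#' conformational substates Ninf and their characteristic saturation time
#' tau. Initialization: Ninf0 = max n(t), tau0 = time at which n(t) first
#' reaches half of Ninf0.
#'
#' @param growth a `ClusterGrowth`, or a list with numeric `n_t` and `times`.
#' @param time_unit divisor applied to `times` before fitting (default 1000,
#'   i.e. ps -> ns so tau is reported in ns).
#' @return list with `n_inf`, `tau` (in the fitted time unit), `residual`
#'   (residual norm), `constant` (TRUE when n(t) never grew; then
#'   `n_inf` = n, `tau` = NA).
#' @export
fit_saturation <- function(growth, time_unit = 1000) {
  n_t <- as.numeric(growth$n_t)
  t_raw <- as.numeric(growth$times)
  if (length(n_t) < 5) stop("need at least 5 time points for the fit")
  # real cluster growth is nondecreasing by construction; raw samples (e.g.
  # noisy synthetic growth curves) are fitted as-is
  if (inherits(growth, "ClusterGrowth") && any(diff(n_t) < 0)) {
    stop("n(t) must be nondecreasing")
  }
  tt <- t_raw / time_unit
  if (max(n_t) == min(n_t)) {
    return(list(n_inf = n_t[1], tau = NA_real_, residual = 0,
                constant = TRUE))
  }
  n_inf0 <- max(n_t)
  tau0 <- tt[which(n_t >= n_inf0 / 2)[1]]
  if (!is.finite(tau0) || tau0 <= 0) tau0 <- max(tt) / 4
  df <- data.frame(t = tt, n = n_t)
  fit <- tryCatch(
    minpack.lm::nlsLM(n ~ n_inf * (1 - exp(-t / tau)), data = df,
                      start = list(n_inf = n_inf0, tau = tau0),
                      lower = c(1e-9, 1e-9),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL
  )
  if (!is.null(fit)) {
    cf <- coef(fit)
    return(list(n_inf = unname(cf["n_inf"]), tau = unname(cf["tau"]),
                residual = sqrt(sum(stats::residuals(fit)^2)),
                constant = FALSE))
  }
  # fallback for degenerate (near-step) growth where the Jacobian is
  # singular: profile least squares -- for fixed tau the optimal N_inf is
  # linear, leaving a 1-D minimization over tau
  prof <- function(tau) {
    f <- 1 - exp(-tt / tau)
    n_inf <- sum(n_t * f) / sum(f^2)
    sum((n_t - n_inf * f)^2)
  }
  tmax <- max(tt[tt > 0], 1)
  opt <- optimize(prof, interval = c(tmax * 1e-6, tmax * 10), tol = 1e-12)
  tau_hat <- opt$minimum
  f <- 1 - exp(-tt / tau_hat)
  n_inf_hat <- sum(n_t * f) / sum(f^2)
  if (!is.finite(n_inf_hat) || n_inf_hat <= 0) {
    stop("saturation fit did not converge: degenerate growth curve")
  }
  list(n_inf = n_inf_hat, tau = tau_hat, residual = sqrt(opt$objective),
       constant = FALSE)
}

#' Export cluster leader frames as a multi-model PDB
#'
#' @param growth a `ClusterGrowth` from [leader_cluster()].
#' @param traj the clustered `Trajectory`.
#' @param path output PDB path.
#' @return `path`, invisibly.
#' @export
cluster_leaders_export <- function(growth, traj, path) {
  xyz <- traj$xyz[growth$leaders, , drop = FALSE]
  write_structure(traj$topology, path, xyz = xyz)
  invisible(path)
}

#' Cluster-count robustness sweep over RMSD cutoffs
#'
#' Reruns [leader_cluster()] across cutoffs and reports the final cluster
#' count per cutoff; the count is monotone nonincreasing in the cutoff.
#'
#' @param traj a `Trajectory`.
#' @param cutoffs numeric vector of cutoffs (A).
#' @param selection metric selection, as in [leader_cluster()].
#' @return data.frame `cutoff`, `n_clusters`.
#' @export
cluster_cutoff_sweep <- function(traj, cutoffs, selection = "heavy") {
  data.frame(
    cutoff = cutoffs,
    n_clusters = vapply(cutoffs, function(cf) {
      length(leader_cluster(traj, selection, cf)$leaders)
    }, integer(1))
  )
}
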