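#' Run the comparative rigidity analysis pipeline
#'
#' Orchestrates the full workflow over a set of systems (e.g. two homologues
#' x two temperatures x monomer/tetramer): for each system it loads topology
#' and trajectory (or accepts in-memory `Trajectory` objects), runs the
#' enabled stages — windowed RMSF, leader clustering with saturation fit,
#' CV diffusion coefficients, interface ion-pair/H-bond timelines and
#' surface classes, volumetrics — and writes per-stage CSV/JSON outputs
#' plus a parameter log. Any stage failure aborts with the stage and system
#' named.
#'
#' @param config configuration list (or path to a YAML file readable by
#'   [read_run_config()]). Keys: `output_dir`; `seed` (optional); `systems`:
#'   list of entries with `label`, `form` ("monomer"/"tetramer"),
#'   `temperature`, and either `trajectory_object` (a `Trajectory`) or
#'   `topology`/`trajectory`/`dt` file paths; `analyses`: named list of
#'   stage settings — `rmsf` (window, selection), `cluster` (cutoff,
#'   selection), `diffusion` (cvs, skip), `interface` (types, d_pairing),
#'   `volumetrics` (selection, enabled).
#' @return named list of per-system report lists (class `RigidityReport`),
#'   invisibly; outputs are written under `output_dir/<label>/`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  req <- c("output_dir", "systems")
  missing_keys <- setdiff(req, names(config))
  if (length(missing_keys) > 0) {
    stop("config lacks required key(s): ", paste(missing_keys, collapse = ", "))
  }
  if (length(config$systems) == 0) stop("config lists no systems")
  labels <- vapply(config$systems, function(s) s$label %||% "", character(1))
  if (any(labels == "") || anyDuplicated(labels)) {
    stop("every system needs a unique label")
  }
  an <- config$analyses %||% list()
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$output_dir, "run.log")
  logf <- function(...) cat(sprintf(...), "\n", sep = "", file = log_path,
                            append = TRUE)
  cat("", file = log_path)
  logf("pipeline run %s; seed=%s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
       config$seed %||% "none")

  reports <- list()
  for (sys in config$systems) {
    lab <- sys$label
    outdir <- file.path(config$output_dir, lab)
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    stage <- "load"
    rep <- tryCatch({
      traj <- if (!is.null(sys$trajectory_object)) {
        sys$trajectory_object
      } else {
        top <- read_structure(sys$topology)
        read_trajectory(sys$trajectory, top, dt = sys$dt,
                        temperature = sys$temperature)
      }
      ref <- sys$reference_object %||% set_coords(traj$topology,
                                                  frame_coords(traj, 1))
      out <- list(label = lab, form = sys$form %||% NA_character_,
                  temperature = sys$temperature %||% traj$temperature)

      if (!is.null(an$rmsf)) {
        stage <- "rmsf"
        w <- an$rmsf$window %||% (n_frames(traj) * traj$dt / 4)
        selc <- an$rmsf$selection %||% "calpha"
        prof <- rmsf_windowed(traj, selc, window = w,
                              fit = an$rmsf$fit %||% TRUE)
        write.csv(prof, file.path(outdir, "rmsf.csv"), row.names = FALSE)
        logf("[%s] rmsf: window=%g ps selection=%s fit=%s", lab, w, selc,
             an$rmsf$fit %||% TRUE)
        out$rmsf_mean <- rmsf_average(prof)
        out$rmsf_profile <- prof
      }
      if (!is.null(an$cluster)) {
        stage <- "cluster"
        cf <- an$cluster$cutoff %||% 1.3
        selc <- an$cluster$selection %||% "heavy"
        gr <- leader_cluster(traj, selc, cutoff = cf)
        fit <- fit_saturation(gr)
        write.csv(data.frame(time_ps = gr$times, n_clusters = gr$n_t),
                  file.path(outdir, "cluster_growth.csv"), row.names = FALSE)
        jsonlite::write_json(fit, file.path(outdir, "cluster_fit.json"),
                             auto_unbox = TRUE, digits = NA)
        logf("[%s] cluster: cutoff=%g A selection=%s -> %d clusters",
             lab, cf, selc, length(gr$leaders))
        out$n_clusters <- length(gr$leaders)
        out$n_inf <- fit$n_inf
        out$tau_sat <- fit$tau
      }
      if (!is.null(an$diffusion)) {
        stage <- "diffusion"
        skip <- an$diffusion$skip %||% 0
        cvs <- an$diffusion$cvs %||% c("rg")
        out$diffusion <- list()
        for (cv in cvs) {
          series <- switch(cv,
            rg = rg_series(traj),
            rmsd = rmsd_series(traj, ref),
            qnative = qnative_series(traj, build_contact_reference(ref)),
            torsions = torsion_series(traj, build_torsion_reference(ref)),
            stop("unknown CV: ", cv))
          est <- diffusion_coefficient(series, skip = skip)
          out$diffusion[[cv]] <- est
          logf("[%s] diffusion %s: fluct=%.4g tau=%.4g ns D=%.4g",
               lab, cv, est$fluctuation, est$tau, est$D)
        }
        jsonlite::write_json(
          lapply(out$diffusion, function(e) e[c("fluctuation", "tau", "D")]),
          file.path(outdir, "diffusion.json"), auto_unbox = TRUE, digits = NA)
      }
      if (!is.null(an$interface)) {
        stage <- "interface"
        ifs <- define_interfaces(traj$topology,
                                 d_pairing = an$interface$d_pairing %||% "AD")
        types <- an$interface$types %||% c("ip")
        out$interface <- list()
        for (lab_if in names(ifs)) {
          entry <- list()
          for (ty in types) {
            tl <- contact_timelines(traj, ifs[[lab_if]], type = ty)
            write.csv(data.frame(time_ps = tl$times, count = tl$counts),
                      file.path(outdir, sprintf("interface_%s_%s.csv",
                                                lab_if, ty)),
                      row.names = FALSE)
            entry[[ty]] <- list(mean = tl$mean_count, sd = tl$sd_count,
                                n_pairs = tl$n_distinct_pairs,
                                occupancy = as.list(tl$occupancy))
            logf("[%s] interface %s %s: mean=%.2f sd=%.2f pairs=%d",
                 lab, lab_if, ty, tl$mean_count, tl$sd_count,
                 tl$n_distinct_pairs)
          }
          if (isTRUE(an$interface$surface)) {
            sc <- classify_interface_surface(
              set_coords(traj$topology, frame_coords(traj, 1)), ifs[[lab_if]])
            entry$surface <- as.list(sc$fractions)
            logf("[%s] interface %s surface: phob=%.2f phil=%.2f mixed=%.2f",
                 lab, lab_if, sc$fractions["hydrophobic"],
                 sc$fractions["hydrophilic"], sc$fractions["mixed"])
          }
          out$interface[[lab_if]] <- entry
        }
        jsonlite::write_json(out$interface,
                             file.path(outdir, "interface_summary.json"),
                             auto_unbox = TRUE, digits = NA)
      }
      if (!is.null(an$volumetrics) && !isFALSE(an$volumetrics$enabled)) {
        stage <- "volumetrics"
        vs <- volume_series(traj, an$volumetrics$selection %||% "heavy",
                            temperature = out$temperature)
        vpa <- volume_per_atom(vs)
        bt <- intrinsic_compressibility(vs)
        write.csv(data.frame(time_ps = vs$times, volume_A3 = vs$total),
                  file.path(outdir, "volume.csv"), row.names = FALSE)
        jsonlite::write_json(
          list(volume_per_atom_A3 = vpa, compressibility = bt),
          file.path(outdir, "volumetrics.json"), auto_unbox = TRUE,
          digits = NA)
        logf("[%s] volumetrics: V/atom=%.3f A^3, beta_T=%.3g e-2/GPa",
             lab, vpa$mean, bt$beta_T)
        out$volume_per_atom <- vpa$mean
        out$beta_T <- bt$beta_T
      }
      class(out) <- "RigidityReport"
      out
    }, error = function(e) {
      stop(sprintf("stage '%s' failed for system '%s': %s", stage, lab,
                   conditionMessage(e)), call. = FALSE)
    })
    reports[[lab]] <- rep
  }
  invisible(reports)
}

#' Align reports from several systems into a comparison table
#'
#' Tabulates the scalar metrics shared by all reports side by side and adds
#' the ratio of each system to the first (e.g. the conformational-substate
#' ratio N_inf(A)/N_inf(B) that quantifies relative rigidity).
#'
#' @param reports list of `RigidityReport`s from [run_pipeline()].
#' @return data.frame with one row per metric: `metric`, one value column
#'   per system, one `ratio_<label>` column per non-reference system.
#' @export
compare_systems <- function(reports) {
  if (length(reports) < 2) stop("need at least 2 reports to compare")
  scalars <- function(rep) {
    out <- list()
    for (m in c("rmsf_mean", "n_clusters", "n_inf", "tau_sat",
                "volume_per_atom", "beta_T")) {
      if (!is.null(rep[[m]])) out[[m]] <- rep[[m]]
    }
    for (cv in names(rep$diffusion %||% list())) {
      out[[paste0("D_", cv)]] <- rep$diffusion[[cv]]$D
      out[[paste0("tau_", cv)]] <- rep$diffusion[[cv]]$tau
    }
    out
  }
  per_sys <- lapply(reports, scalars)
  shared <- Reduce(intersect, lapply(per_sys, names))
  if (length(shared) == 0) stop("reports share no comparable stages")
  labels <- names(reports)
  tab <- data.frame(metric = shared)
  for (l in labels) {
    tab[[l]] <- vapply(shared, function(m) per_sys[[l]][[m]], numeric(1))
  }
  for (l in labels[-1]) {
    tab[[paste0("ratio_", l)]] <- tab[[l]] / tab[[labels[1]]]
  }
  rownames(tab) <- NULL
  tab
}
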