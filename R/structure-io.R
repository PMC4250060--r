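#' @importFrom stats sd var setNames filter acf rnorm runif optimize coef
#' @importFrom utils head tail write.csv combn
NULL

# Standard protein residues, used for the "protein" selection class and as
# the default analysis universe (crystallographic waters/het groups excluded).
.PROTEIN_RESIDUES <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "HSD",
  "HSE", "HSP", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR",
  "TRP", "TYR", "VAL"
)

.BACKBONE_NAMES <- c("N", "CA", "C", "O", "OXT")

#' Construct a Structure object
#'
#' A `Structure` is the shared static data model of the package: an atom
#' table plus one set of coordinates in Angstrom. It is what every analysis
#' stage receives as topology and what reference (crystallographic)
#' configurations are stored in.
#'
#' @param atoms data.frame with columns `name` (atom name, e.g. "CA"),
#'   `element` (element symbol), `resid` (residue name), `resno` (residue
#'   number, author numbering preserved), `chain` (chain id), `occ`
#'   (occupancy).
#' @param xyz numeric matrix with one row per atom and columns x, y, z (A).
#' @param source optional identifier of the originating file/accession.
#' @param title optional free-text title.
#' @return an object of class `Structure`.
#' @export
new_structure <- function(atoms, xyz, source = NA_character_, title = NA_character_) {
  atoms <- as.data.frame(atoms)
  needed <- c("name", "element", "resid", "resno", "chain", "occ")
  missing_cols <- setdiff(needed, names(atoms))
  if (length(missing_cols) > 0) {
    stop("atoms table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  xyz <- as.matrix(xyz)
  if (nrow(xyz) != nrow(atoms) || ncol(xyz) != 3) {
    stop("xyz must be an n_atoms x 3 matrix matching the atom table")
  }
  if (nrow(atoms) == 0) stop("empty structure")
  if (!all(is.finite(xyz))) stop("non-finite coordinates in structure")
  rownames(xyz) <- NULL
  structure(
    list(atoms = atoms, xyz = xyz,
         metadata = list(source = source, title = title)),
    class = "Structure"
  )
}

#' @export
print.Structure <- function(x, ...) {
  cat(sprintf("<Structure> %d atoms, %d chain(s): %s\n",
              nrow(x$atoms), length(unique(x$atoms$chain)),
              paste(sort(unique(x$atoms$chain)), collapse = " ")))
  invisible(x)
}

#' Number of atoms in a Structure
#' @param structure a `Structure`.
#' @return integer atom count.
#' @export
n_atoms <- function(structure) nrow(structure$atoms)

# Derive an element symbol from a PDB atom name when the element column is
# blank. Digit-prefixed hydrogen names (1HB2) and two-letter metals are the
# usual traps; protein work only needs C/N/O/S/H/P to be right.
.element_from_name <- function(name) {
  nm <- gsub("[0-9']", "", trimws(name))
  first <- toupper(substr(nm, 1, 1))
  ifelse(first %in% c("C", "N", "O", "S", "H", "P"), first,
         toupper(substr(trimws(name), 1, 1)))
}

#' Read a PDB structure file
#'
#' Parses a PDB file into a [new_structure()] object. Alternate locations are
#' resolved to a single conformer by keeping, per (chain, residue, atom name),
#' the altloc with the highest occupancy (first record on ties). Author
#' residue numbering is preserved. Hydrogens are retained if present.
#'
#' @param path path to a PDB file.
#' @param model model number to extract from multi-model files (default 1).
#' @return a `Structure`.
#' @export
read_structure <- function(path, model = 1) {
  if (!file.exists(path)) stop("no such file: ", path)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) stop("failed to parse PDB '", path, "': ",
                             conditionMessage(e))
  )
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0) stop("empty structure in ", path)
  occ <- suppressWarnings(as.numeric(at$o))
  occ[is.na(occ)] <- 1
  keep <- rep(TRUE, nrow(at))
  alt <- at$alt
  alt[is.na(alt)] <- ""
  has_alt <- alt != ""
  if (any(has_alt)) {
    key <- paste(at$chain, at$resno, at$insert, at$elety, sep = "|")
    for (k in unique(key[has_alt])) {
      idx <- which(key == k)
      if (length(idx) > 1) {
        best <- idx[which.max(occ[idx])]   # highest occupancy, first on tie
        keep[setdiff(idx, best)] <- FALSE
      }
    }
  }
  at <- at[keep, , drop = FALSE]
  occ <- occ[keep]
  elem <- at$elesy
  if (is.null(elem)) elem <- rep("", nrow(at))
  elem <- trimws(elem)
  blank <- is.na(elem) | elem == ""
  elem[blank] <- .element_from_name(at$elety[blank])
  chain <- at$chain
  chain[is.na(chain) | chain == ""] <- "A"
  atoms <- data.frame(
    name = trimws(at$elety), element = toupper(elem),
    resid = trimws(at$resid), resno = at$resno, chain = chain,
    occ = occ, stringsAsFactors = FALSE
  )
  new_structure(atoms, cbind(at$x, at$y, at$z), source = path)
}

#' Write a Structure to a PDB file
#'
#' @param structure a `Structure`.
#' @param path output path.
#' @param xyz optional replacement coordinates: an n_atoms x 3 matrix, or a
#'   multi-row frames x 3*n_atoms matrix to write a multi-model PDB.
#' @return `path`, invisibly.
#' @export
write_structure <- function(structure, path, xyz = NULL) {
  a <- structure$atoms
  if (is.null(xyz)) xyz <- structure$xyz
  if (is.matrix(xyz) && ncol(xyz) == 3) {
    xyz <- matrix(t(xyz), nrow = 1)
  }
  if (ncol(xyz) != 3 * nrow(a)) {
    stop("coordinate width does not match atom count")
  }
  bio3d::write.pdb(file = path, xyz = xyz,
                   resno = a$resno, resid = a$resid, chain = a$chain,
                   elety = a$name, o = a$occ, elesy = a$element)
  invisible(path)
}

#' Construct a Trajectory object
#'
#' A `Trajectory` is a time-ordered stack of coordinate frames bound to a
#' topology `Structure`. Coordinates are stored bio3d-style as a
#' frames x 3*n_atoms matrix (x1, y1, z1, x2, ...), in Angstrom.
#'
#' @param xyz frames x 3*n_atoms coordinate matrix (A).
#' @param dt frame spacing in ps; must be > 0.
#' @param topology the `Structure` the frames refer to.
#' @param temperature optional simulation temperature (K).
#' @param times optional per-frame times (ps); default `(0:(n-1)) * dt`.
#' @return an object of class `Trajectory`.
#' @export
new_trajectory <- function(xyz, dt, topology, temperature = NULL, times = NULL) {
  xyz <- as.matrix(xyz)
  if (nrow(xyz) == 0) stop("trajectory has zero frames")
  if (!inherits(topology, "Structure")) stop("topology must be a Structure")
  if (ncol(xyz) != 3 * n_atoms(topology)) {
    stop(sprintf("frame atom count (%d) does not match topology (%d)",
                 ncol(xyz) / 3, n_atoms(topology)))
  }
  if (is.null(dt) || !is.finite(dt) || dt <= 0) {
    stop("dt must be a positive frame spacing in ps")
  }
  if (is.null(times)) times <- (seq_len(nrow(xyz)) - 1) * dt
  if (any(diff(times) <= 0)) stop("frame times must be strictly increasing")
  structure(
    list(xyz = xyz, dt = dt, times = times, temperature = temperature,
         topology = topology),
    class = "Trajectory"
  )
}

#' @export
print.Trajectory <- function(x, ...) {
  cat(sprintf("<Trajectory> %d frames x %d atoms, dt = %g ps (%.3g ns total)\n",
              n_frames(x), ncol(x$xyz) / 3, x$dt,
              n_frames(x) * x$dt / 1000))
  invisible(x)
}

#' Number of frames in a Trajectory
#' @param traj a `Trajectory`.
#' @return integer frame count.
#' @export
n_frames <- function(traj) nrow(traj$xyz)

#' Extract one frame of a Trajectory as an n_atoms x 3 matrix
#' @param traj a `Trajectory`.
#' @param i frame index.
#' @return n_atoms x 3 coordinate matrix (A).
#' @export
frame_coords <- function(traj, i) {
  matrix(traj$xyz[i, ], ncol = 3, byrow = TRUE)
}

#' Replace the coordinates of a Structure
#' @param structure a `Structure`.
#' @param coords n_atoms x 3 matrix (A).
#' @return the updated `Structure`.
#' @export
set_coords <- function(structure, coords) {
  coords <- as.matrix(coords)
  if (nrow(coords) != n_atoms(structure) || ncol(coords) != 3) {
    stop("coords must be n_atoms x 3")
  }
  structure$xyz <- coords
  structure
}

#' Read a coordinate trajectory
#'
#' Reads a trajectory in DCD (binary), multi-model PDB, or plain XYZ format,
#' dispatching on the file extension. The atom count must match `topology`.
#' Frame spacing is taken from `dt`; multi-model PDB and XYZ carry no time
#' information, so omitting `dt` is an error.
#'
#' @param path trajectory file (.dcd, .pdb, .xyz).
#' @param topology `Structure` describing the atoms.
#' @param dt frame spacing in ps.
#' @param temperature optional temperature (K) recorded on the trajectory.
#' @return a `Trajectory`.
#' @export
read_trajectory <- function(path, topology, dt = NULL, temperature = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(dt)) {
    stop("dt is not derivable from the trajectory file; supply dt (ps)")
  }
  ext <- tolower(tools::file_ext(path))
  xyz <- switch(ext,
    dcd = bio3d::read.dcd(path, verbose = FALSE),
    pdb = {
      pdb <- suppressWarnings(bio3d::read.pdb(path, multi = TRUE,
                                              verbose = FALSE))
      pdb$xyz
    },
    xyz = .read_xyz(path),
    stop("unsupported trajectory format: .", ext)
  )
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3 * n_atoms(topology)) {
    stop(sprintf(
      "trajectory atom count (%d) does not match topology atom count (%d)",
      ncol(xyz) / 3, n_atoms(topology)))
  }
  new_trajectory(xyz, dt = dt, topology = topology, temperature = temperature)
}

#' Write a Trajectory
#'
#' Writes a multi-model PDB (`.pdb`) or plain XYZ (`.xyz`) depending on the
#' extension of `path`.
#'
#' @param traj a `Trajectory`.
#' @param path output file (.pdb or .xyz).
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "pdb") {
    write_structure(traj$topology, path, xyz = traj$xyz)
  } else if (ext == "xyz") {
    .write_xyz(traj, path)
  } else {
    stop("unsupported trajectory output format: .", ext)
  }
  invisible(path)
}

# Plain XYZ: "n_atoms\ncomment\nElem x y z" repeated per frame.
.read_xyz <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 3) stop("malformed XYZ file: ", path)
  nat <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(nat) || nat <= 0) stop("malformed XYZ header in ", path)
  block <- nat + 2
  if (length(lines) %% block != 0) {
    stop("XYZ file length not a multiple of frame block in ", path)
  }
  nfr <- length(lines) %/% block
  out <- matrix(NA_real_, nfr, 3 * nat)
  for (f in seq_len(nfr)) {
    body <- lines[((f - 1) * block + 3):((f - 1) * block + 2 + nat)]
    parts <- strsplit(trimws(body), "\\s+")
    coords <- vapply(parts, function(p) as.numeric(p[2:4]), numeric(3))
    out[f, ] <- as.vector(coords)
  }
  out
}

.write_xyz <- function(traj, path) {
  nat <- n_atoms(traj$topology)
  elem <- traj$topology$atoms$element
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(n_frames(traj))) {
    crd <- frame_coords(traj, f)
    writeLines(as.character(nat), con)
    writeLines(sprintf("frame %d t= %.4f ps", f, traj$times[f]), con)
    writeLines(sprintf("%-2s %12.6f %12.6f %12.6f",
                       elem, crd[, 1], crd[, 2], crd[, 3]), con)
  }
}

#' Resolve an atom selection expression
#'
#' Small deterministic selection grammar: clauses joined by `and`, each one of
#' `chain <id>...`, `resno <a>:<b>` (or a list of numbers), `name <nm>...`,
#' `resid <res>...`, or a bare class keyword: `all`, `protein`, `calpha`
#' (alias `CA`), `backbone`, `heavy`, `sidechain-heavy` (alias `sideheavy`).
#' All class keywords except `all` restrict to standard protein residues;
#' `heavy` classes exclude element H. "sidechain-heavy" excludes backbone
#' N/CA/C/O (and OXT) and hydrogens, so glycine contributes nothing.
#'
#' The result is a sorted (file-order) integer index vector, identical across
#' repeated calls. An empty result is returned with a warning; an unknown
#' chain or residue raises an error.
#'
#' @param structure a `Structure`.
#' @param spec selection expression string.
#' @return sorted integer vector of atom indices.
#' @export
resolve_selection <- function(structure, spec) {
  a <- structure$atoms
  keep <- rep(TRUE, nrow(a))
  is_protein <- a$resid %in% .PROTEIN_RESIDUES
  clauses <- strsplit(trimws(spec), "\\s+and\\s+")[[1]]
  if (length(clauses) == 0 || !nzchar(trimws(spec))) {
    stop("empty selection expression")
  }
  for (cl in clauses) {
    toks <- strsplit(trimws(cl), "\\s+")[[1]]
    kw <- tolower(toks[1])
    args <- toks[-1]
    mask <- switch(kw,
      all = rep(TRUE, nrow(a)),
      protein = is_protein,
      calpha = , ca = is_protein & a$name == "CA",
      backbone = is_protein & a$name %in% .BACKBONE_NAMES & a$element != "H",
      heavy = is_protein & a$element != "H",
      `sidechain-heavy` = , sideheavy =
        is_protein & a$element != "H" & !(a$name %in% .BACKBONE_NAMES),
      chain = {
        if (length(args) == 0) stop("'chain' needs at least one id")
        unknown <- setdiff(args, unique(a$chain))
        if (length(unknown) > 0) {
          stop("unknown chain id(s): ", paste(unknown, collapse = ", "))
        }
        a$chain %in% args
      },
      resno = {
        if (length(args) == 0) stop("'resno' needs a range or numbers")
        nums <- unlist(lapply(args, function(s) {
          if (grepl(":", s, fixed = TRUE)) {
            ab <- as.integer(strsplit(s, ":", fixed = TRUE)[[1]])
            seq(ab[1], ab[2])
          } else as.integer(s)
        }))
        if (anyNA(nums)) stop("unparseable residue numbers in: ", cl)
        unknown <- setdiff(nums, unique(a$resno))
        if (length(unknown) == length(nums)) {
          stop("no such residue number(s): ", paste(unknown, collapse = ", "))
        }
        a$resno %in% nums
      },
      resid = {
        if (length(args) == 0) stop("'resid' needs at least one residue name")
        a$resid %in% toupper(args)
      },
      name = {
        if (length(args) == 0) stop("'name' needs at least one atom name")
        a$name %in% args
      },
      stop("unknown selection keyword: '", toks[1], "'")
    )
    keep <- keep & mask
  }
  idx <- sort(which(keep))
  if (length(idx) == 0) warning("selection '", spec, "' matched no atoms")
  idx
}

#' Read a run configuration file
#'
#' YAML key/value configuration naming topology, trajectory, dt, temperature,
#' selections and stage parameters; consumed by [run_pipeline()].
#'
#' @param path YAML file.
#' @return named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg) || length(cfg) == 0) stop("empty configuration: ", path)
  cfg
}
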