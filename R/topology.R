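#' @title Core trajectory data model
#' @description S3 containers for topologies, single coordinate frames and
#'   trajectories. Internal units are nanometres (lengths) and picoseconds
#'   (times) throughout; nanoseconds appear only in user-facing arguments
#'   that are explicitly suffixed `_ns`.
#' @name trajectory-model
NULL

#' Construct a topology
#'
#' A topology holds atom and residue identity: one row per atom with its
#' name, element, residue name, author residue number and chain identifier.
#' Atom order defines the atom index (1-based in R; the `index` column holds
#' the equivalent 0-based serial for interoperability with trajectory file
#' formats).
#'
#' @param atoms data.frame with columns `name`, `element`, `resname`,
#'   `resid` (integer, author numbering), `chain` (character). Extra columns
#'   are retained.
#' @param bonds optional two-column integer matrix of 1-based atom indices.
#' @return object of class `vw_topology`
#' @export
vw_topology <- function(atoms, bonds = NULL) {
  stopifnot(is.data.frame(atoms))
  required <- c("name", "element", "resname", "resid", "chain")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols) > 0L) {
    stop("topology atoms table lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (nrow(atoms) == 0L) stop("topology must contain at least one atom")
  atoms$resid <- as.integer(atoms$resid)
  atoms$index <- seq_len(nrow(atoms)) - 1L
  # residue numbering must be unique within a chain: the same (chain, resid)
  # pair must always carry the same residue name
  key <- paste(atoms$chain, atoms$resid)
  resname_per_key <- tapply(atoms$resname, key, function(x) length(unique(x)))
  if (any(resname_per_key > 1L)) {
    stop("residue numbering not unique within chain: ",
         names(resname_per_key)[which(resname_per_key > 1L)[1L]])
  }
  if (!is.null(bonds)) {
    bonds <- as.matrix(bonds)
    if (ncol(bonds) != 2L) stop("bonds must be a two-column matrix")
    if (any(bonds < 1L | bonds > nrow(atoms))) {
      stop("bond atom indices out of range")
    }
  }
  structure(list(atoms = atoms, bonds = bonds, n_atoms = nrow(atoms)),
            class = "vw_topology")
}

#' @export
print.vw_topology <- function(x, ...) {
  cat("<vw_topology> ", x$n_atoms, " atoms, ",
      length(unique(paste(x$atoms$chain, x$atoms$resid))), " residues, ",
      length(unique(x$atoms$chain)), " chain(s)\n", sep = "")
  invisible(x)
}

#' Construct a single coordinate frame
#'
#' @param xyz numeric matrix, one row per atom, columns x/y/z in nm.
#' @param box length-3 numeric, orthorhombic box edge lengths in nm.
#' @param time frame time in ps (nonnegative).
#' @return object of class `vw_frame`
#' @export
vw_frame <- function(xyz, box, time = 0) {
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3L) stop("frame coordinates must be an n x 3 matrix")
  box <- as.numeric(box)
  if (length(box) == 9L) {
    m <- matrix(box, 3, 3)
    if (any(abs(m[upper.tri(m) | lower.tri(m)]) > 1e-9)) {
      stop("triclinic boxes are not supported; box must be orthorhombic")
    }
    box <- diag(m)
  }
  if (length(box) != 3L) stop("box must be three orthorhombic edge lengths")
  if (any(!is.finite(box)) || any(box <= 0)) {
    stop("box edge lengths must be strictly positive")
  }
  if (!is.finite(time) || time < 0) stop("frame time must be nonnegative")
  structure(list(xyz = xyz, box = box, time = as.numeric(time)),
            class = "vw_frame")
}

#' Construct a trajectory
#'
#' Coordinates are stored densely as an `n_atoms x 3 x n_frames` array;
#' at the problem sizes this package targets (thousands of frames of a few
#' thousand particles) this comfortably fits in memory while keeping frame
#' access O(1).
#'
#' @param topology a `vw_topology`
#' @param coords `n_atoms x 3 x n_frames` array (nm) or a list of per-frame
#'   coordinate matrices.
#' @param box per-frame box: either length-3 (constant) or `n_frames x 3`
#'   matrix (nm).
#' @param times frame times in ps, strictly increasing.
#' @param spacing_tol relative tolerance on constancy of frame spacing.
#' @return object of class `vw_trajectory` with element `spacing` (ps).
#' @export
vw_trajectory <- function(topology, coords, box, times,
                          spacing_tol = 1e-4) {
  stopifnot(inherits(topology, "vw_topology"))
  if (is.list(coords)) {
    coords <- array(unlist(coords),
                    dim = c(nrow(coords[[1L]]), 3L, length(coords)))
  }
  if (length(dim(coords)) != 3L || dim(coords)[2L] != 3L) {
    stop("coords must be an n_atoms x 3 x n_frames array")
  }
  if (dim(coords)[1L] != topology$n_atoms) {
    stop("coordinate count (", dim(coords)[1L],
         ") does not match topology atom count (", topology$n_atoms, ")")
  }
  n_frames <- dim(coords)[3L]
  times <- as.numeric(times)
  if (length(times) != n_frames) stop("one time per frame required")
  if (n_frames > 1L && any(diff(times) <= 0)) {
    stop("frame times must be strictly increasing")
  }
  if (any(times < 0)) stop("frame times must be nonnegative")
  if (is.null(dim(box))) box <- matrix(box, n_frames, 3L, byrow = TRUE)
  box <- as.matrix(box)
  if (nrow(box) != n_frames || ncol(box) != 3L) {
    stop("box must be length-3 or an n_frames x 3 matrix")
  }
  if (any(box <= 0)) stop("box edge lengths must be strictly positive")
  spacing <- NA_real_
  if (n_frames > 1L) {
    d <- diff(times)
    spacing <- stats::median(d)
    if (any(abs(d - spacing) > spacing_tol * spacing)) {
      stop("frame spacing is not constant (tolerance ", spacing_tol, ")")
    }
  }
  structure(list(topology = topology, coords = coords, box = box,
                 times = times, n_frames = n_frames, spacing = spacing),
            class = "vw_trajectory")
}

#' @export
print.vw_trajectory <- function(x, ...) {
  cat("<vw_trajectory> ", x$n_frames, " frames x ", x$topology$n_atoms,
      " atoms, spacing ", x$spacing, " ps, span ",
      if (x$n_frames > 0) sprintf("%.4g-%.4g ps", x$times[1L],
                                  x$times[x$n_frames]) else "empty",
      "\n", sep = "")
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a `vw_trajectory`
#' @return integer frame count
#' @export
n_frames <- function(traj) traj$n_frames

#' Extract one frame of a trajectory
#' @param traj a `vw_trajectory`
#' @param i frame number (1-based)
#' @return a `vw_frame`
#' @export
get_frame <- function(traj, i) {
  if (i < 1L || i > traj$n_frames) stop("frame index out of range")
  vw_frame(traj$coords[, , i, drop = TRUE], traj$box[i, ], traj$times[i])
}

#' Minimum-image distance under orthorhombic periodic boundaries
#'
#' @param a,b 3-vectors or n x 3 matrices of positions (nm)
#' @param box length-3 orthorhombic box (nm)
#' @return nonnegative distance(s) in nm; each displacement component is at
#'   most half the corresponding box length.
#' @export
minimum_image_distance <- function(a, b, box) {
  box <- as.numeric(box)
  if (length(box) != 3L || any(!is.finite(box)) || any(box <= 0)) {
    stop("box edge lengths must be strictly positive")
  }
  if (is.null(dim(a))) a <- matrix(a, ncol = 3L)
  if (is.null(dim(b))) b <- matrix(b, ncol = 3L)
  d <- minimum_image_displacement(a, b, box)
  sqrt(rowSums(d * d))
}

#' Minimum-image displacement vectors (b - a, wrapped)
#' @inheritParams minimum_image_distance
#' @return n x 3 matrix of wrapped displacement components (nm)
#' @export
minimum_image_displacement <- function(a, b, box) {
  if (is.null(dim(a))) a <- matrix(a, ncol = 3L)
  if (is.null(dim(b))) b <- matrix(b, ncol = 3L)
  d <- b - a
  for (k in 1:3) d[, k] <- d[, k] - box[k] * round(d[, k] / box[k])
  d
}

#' Remove the equilibration segment of a trajectory
#'
#' Frames with time earlier than `t_start_ns` are discarded so that
#' downstream analyses see production frames only. The conventional choice
#' for the ABCG2 systems this package targets is 25 ns, leaving 150 ns of a
#' 175-ns mutant run and 500 ns of a 525-ns wild-type run.
#'
#' @param traj a `vw_trajectory`
#' @param t_start_ns equilibration span to drop, in ns
#' @return trimmed `vw_trajectory`
#' @export
trim_equilibration <- function(traj, t_start_ns) {
  stopifnot(inherits(traj, "vw_trajectory"))
  t_start_ps <- t_start_ns * 1000
  if (t_start_ps > traj$times[traj$n_frames]) {
    stop("equilibration cutoff ", t_start_ns,
         " ns lies beyond the last frame (",
         traj$times[traj$n_frames] / 1000, " ns)")
  }
  keep <- traj$times >= t_start_ps
  vw_trajectory(traj$topology,
                traj$coords[, , keep, drop = FALSE],
                traj$box[keep, , drop = FALSE],
                traj$times[keep])
}

#' Trajectory time span in ps
#' @param traj a `vw_trajectory`
#' @return last time minus first time (ps)
#' @export
time_span_ps <- function(traj) {
  traj$times[traj$n_frames] - traj$times[1L]
}
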