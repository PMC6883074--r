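#' @title Synthetic trajectory generators with logged ground truth
#' @description Every generator is seeded and reproducible, and returns both
#'   a `vw_trajectory` and a ground-truth record, so downstream analyses
#'   (flux counting, density maps, RMSF, distance statistics) can be tested
#'   against exactly known answers without running molecular dynamics.
#'   Physical realism is not attempted: no electrostatics, no lipids, one
#'   particle per water molecule.
#' @name synthetic-data
NULL

#' Parameters for the semi-permeable barrier system
#'
#' The system emulates the statistical structure of a hydrophobic valve
#' separating two aqueous compartments: point "waters" perform reflected
#' Brownian motion in an orthorhombic box split by a planar slab barrier at
#' `barrier_z`. A Brownian step that would carry a particle across the
#' barrier plane is an attempt; attempts succeed with probability
#' `crossing_probability` (the particle passes through), otherwise the
#' particle reflects off the slab face. A static 8-atom scaffold (L554/L555
#' CA and CB of two chains) marks the valve location so the standard
#' valve-anchored selections run unchanged on synthetic systems.
#'
#' @param n_waters number of solvent particles
#' @param box orthorhombic box edge lengths (nm)
#' @param barrier_z axial position of the barrier plane (nm)
#' @param barrier_half_thickness half thickness of the excluded slab (nm)
#' @param crossing_probability probability an attempted crossing succeeds
#' @param step_sigma per-coordinate Brownian step standard deviation per
#'   frame (nm)
#' @param n_frames number of frames
#' @param spacing_ps frame spacing (ps)
#' @param seed RNG seed
#' @return a named list of validated parameters
#' @export
barrier_params <- function(n_waters = 400, box = c(6, 6, 12),
                           barrier_z = 6, barrier_half_thickness = 0.15,
                           crossing_probability = 0.1, step_sigma = 0.05,
                           n_frames = 1000, spacing_ps = 10, seed = 1) {
  if (crossing_probability < 0 || crossing_probability > 1) {
    stop("crossing_probability must lie in [0, 1]")
  }
  if (step_sigma <= 0) stop("step_sigma must be positive")
  if (barrier_half_thickness < 0) stop("barrier_half_thickness must be >= 0")
  if (barrier_z - barrier_half_thickness <= 0 ||
      barrier_z + barrier_half_thickness >= box[3L]) {
    stop("barrier slab must lie strictly inside the box")
  }
  if (n_waters < 1 || n_frames < 2) stop("need >= 1 water and >= 2 frames")
  list(n_waters = n_waters, box = as.numeric(box), barrier_z = barrier_z,
       barrier_half_thickness = barrier_half_thickness,
       crossing_probability = crossing_probability,
       step_sigma = step_sigma, n_frames = as.integer(n_frames),
       spacing_ps = spacing_ps, seed = as.integer(seed))
}

valve_scaffold_atoms <- function() {
  data.frame(
    name = rep(c("CA", "CB"), 4L),
    element = "C",
    resname = "LEU",
    resid = rep(c(554L, 555L, 554L, 555L), each = 2L)[c(1, 2, 3, 4, 5, 6, 7, 8)],
    chain = rep(c("A", "A", "B", "B"), each = 2L),
    stringsAsFactors = FALSE
  )
}

valve_scaffold_xyz <- function(center, radius = 0.5) {
  # 8 atoms on a ring in the barrier plane: CA on the ring, CB slightly
  # inward, two residues per chain, chains facing each other
  ang <- c(0, 0.25, 1, 1.25, 2, 2.25, 3, 3.25) * pi / 2
  r <- rep(c(radius, radius * 0.7), 4L)
  cbind(center[1L] + r * cos(ang),
        center[2L] + r * sin(ang),
        rep(center[3L], 8L))
}

#' Generate a barrier-partitioned Brownian solvent system
#'
#' @param params list from [barrier_params()]
#' @return list with `trajectory` (`vw_trajectory`) and `ground_truth`,
#'   where `ground_truth$events` is a data.frame (`frame` — index of the
#'   frame after the crossing, `water` — water number, `atom` — atom index,
#'   `direction` — `"up"` or `"down"`) containing exactly the sign changes
#'   of `z - barrier_z` between consecutive emitted frames.
#' @export
generate_barrier_system <- function(params = barrier_params()) {
  set.seed(params$seed)
  n <- params$n_waters
  box <- params$box
  z0 <- params$barrier_z
  h <- params$barrier_half_thickness
  p <- params$crossing_probability
  sig <- params$step_sigma
  nfr <- params$n_frames

  scaffold <- valve_scaffold_atoms()
  n_scaf <- nrow(scaffold)
  waters <- data.frame(name = "OW", element = "O", resname = "SOL",
                       resid = seq_len(n) + 1000L, chain = "W",
                       stringsAsFactors = FALSE)
  topology <- vw_topology(rbind(scaffold, waters))
  scaf_xyz <- valve_scaffold_xyz(c(box[1L] / 2, box[2L] / 2, z0))

  # initial water positions: uniform in the box, outside the slab
  pos <- cbind(stats::runif(n, 0, box[1L]), stats::runif(n, 0, box[2L]),
               stats::runif(n, 0, box[3L]))
  inside <- abs(pos[, 3L] - z0) < h
  while (any(inside)) {
    pos[inside, 3L] <- stats::runif(sum(inside), 0, box[3L])
    inside <- abs(pos[, 3L] - z0) < h
  }

  reflect_wall <- function(v, L) {
    v <- ifelse(v < 0, -v, v)
    v <- ifelse(v > L, 2 * L - v, v)
    pmin(pmax(v, 1e-9), L - 1e-9)
  }

  coords <- array(NA_real_, dim = c(n_scaf + n, 3L, nfr))
  for (f in seq_len(nfr)) {
    if (f > 1L) {
      prop <- pos + matrix(stats::rnorm(3L * n, 0, sig), n, 3L)
      up <- pos[, 3L] > z0
      znew <- prop[, 3L]
      attempt <- (up & znew < z0 + h) | (!up & znew > z0 - h)
      accept <- attempt & (stats::runif(n) < p)
      reject <- attempt & !accept
      # accepted: pass through the slab; penetration depth carried to the
      # far face (reduces to free diffusion when h = 0)
      pen_up <- (z0 + h) - znew    # coming from above
      pen_dn <- znew - (z0 - h)    # coming from below
      z_acc <- ifelse(up,
                      ifelse(znew < z0 - h, znew, (z0 - h) - pen_up),
                      ifelse(znew > z0 + h, znew, (z0 + h) + pen_dn))
      # rejected: reflect off the near slab face, staying on the same side
      z_rej <- ifelse(up, 2 * (z0 + h) - znew, 2 * (z0 - h) - znew)
      znew[accept] <- z_acc[accept]
      znew[reject] <- z_rej[reject]
      prop[, 3L] <- znew
      prop[, 1L] <- reflect_wall(prop[, 1L], box[1L])
      prop[, 2L] <- reflect_wall(prop[, 2L], box[2L])
      prop[, 3L] <- reflect_wall(prop[, 3L], box[3L])
      pos <- prop
    }
    coords[seq_len(n_scaf), , f] <- scaf_xyz
    coords[n_scaf + seq_len(n), , f] <- pos
  }

  # ground-truth event log derived from the emitted frames: a logged event
  # is exactly a sign change of (z - barrier_z) between consecutive frames
  zs <- coords[n_scaf + seq_len(n), 3L, , drop = TRUE]
  if (n == 1L) zs <- matrix(zs, nrow = 1L)
  side <- zs > z0
  events <- NULL
  if (nfr > 1L) {
    changed <- side[, -1L, drop = FALSE] != side[, -nfr, drop = FALSE]
    idx <- which(changed, arr.ind = TRUE)
    if (nrow(idx) > 0L) {
      events <- data.frame(
        frame = idx[, 2L] + 1L,
        water = idx[, 1L],
        atom = n_scaf + idx[, 1L],
        direction = ifelse(side[cbind(idx[, 1L], idx[, 2L] + 1L)],
                           "up", "down"),
        stringsAsFactors = FALSE
      )
      events <- events[order(events$frame, events$water), , drop = FALSE]
      rownames(events) <- NULL
    }
  }
  if (is.null(events)) {
    events <- data.frame(frame = integer(0), water = integer(0),
                         atom = integer(0), direction = character(0))
  }
  times <- (seq_len(nfr) - 1L) * params$spacing_ps
  traj <- vw_trajectory(topology, coords, box, times)
  list(trajectory = traj,
       ground_truth = list(kind = "barrier", events = events,
                           params = params))
}

#' Calibrate the crossing probability to a target event interval
#'
#' For the zero-thickness barrier, the expected number of counted crossing
#' events per frame inside a flux-box footprint of area `A` is
#' `p * rho * A * sigma * sqrt(2/pi)`: `rho * A * sigma * sqrt(2/pi)` is the
#' rate at which free Brownian particles of step `sigma` and number density
#' `rho` propose a plane crossing within the footprint, and each proposal
#' succeeds with probability `p`. Inverting gives the `p` that emulates a
#' prescribed mean interval between single-water transitions (e.g. one
#' event per ~5 ns for a wild-type-like seal).
#'
#' @param params list from [barrier_params()] (with
#'   `barrier_half_thickness = 0`)
#' @param target_interval_ns desired mean time between counted events (ns)
#' @param footprint_area lateral area of the flux box (nm^2), default 4
#'   (2 x 2 nm)
#' @return crossing probability in (0, 1]
#' @export
calibrate_crossing_probability <- function(params, target_interval_ns,
                                           footprint_area = 4) {
  rho <- params$n_waters / prod(params$box)
  rate_per_frame <- params$spacing_ps / (target_interval_ns * 1000)
  p <- rate_per_frame /
    (rho * footprint_area * params$step_sigma * sqrt(2 / pi))
  if (p > 1) {
    stop("target rate unreachable: calibrated probability ", signif(p, 3),
         " exceeds 1; increase n_waters or step_sigma")
  }
  p
}

#' Generate a harmonically tethered particle system
#'
#' Particle i is drawn independently each frame from an isotropic Gaussian
#' of per-coordinate standard deviation `sigmas[i]` about a fixed anchor;
#' anchors sit on a grid 2 nm apart so particles never interact. A 4-atom
#' static scaffold (resname `SCF`) is included so superposition-based
#' analyses have a rigid reference.
#'
#' @param sigmas per-particle per-coordinate standard deviation (nm), all > 0
#'   (use 0 for rigid particles)
#' @param n_frames number of frames
#' @param spacing_ps frame spacing (ps)
#' @param seed RNG seed
#' @return list with `trajectory` and `ground_truth` (`$sigmas`, `$anchors`)
#' @export
generate_tethered_system <- function(sigmas, n_frames = 5000,
                                     spacing_ps = 10, seed = 1) {
  if (length(sigmas) < 1L || any(sigmas < 0)) {
    stop("sigmas must be nonnegative")
  }
  if (n_frames < 2L) stop("need at least 2 frames")
  set.seed(seed)
  n <- length(sigmas)
  anchors <- cbind(2 * (seq_len(n) - 1L) + 2, rep(2, n), rep(2, n))
  box <- c(max(anchors[, 1L]) + 2, 4, 4)
  scaffold <- data.frame(name = "CA", element = "C", resname = "SCF",
                         resid = 9001:9004, chain = "S",
                         stringsAsFactors = FALSE)
  scaf_xyz <- cbind(c(0.5, box[1L] - 0.5, 0.5, box[1L] - 0.5),
                    c(0.5, 0.5, 3.5, 3.5), c(0.5, 0.5, 3.5, 3.5))
  particles <- data.frame(name = "CA", element = "C", resname = "ALA",
                          resid = seq_len(n), chain = "A",
                          stringsAsFactors = FALSE)
  topology <- vw_topology(rbind(scaffold, particles))
  coords <- array(NA_real_, dim = c(4L + n, 3L, n_frames))
  for (f in seq_len(n_frames)) {
    coords[1:4, , f] <- scaf_xyz
    coords[4L + seq_len(n), , f] <-
      anchors + matrix(stats::rnorm(3L * n, 0, rep(sigmas, 3L)), n, 3L)
  }
  times <- (seq_len(n_frames) - 1L) * spacing_ps
  list(trajectory = vw_trajectory(topology, coords, box, times),
       ground_truth = list(kind = "tethered", sigmas = sigmas,
                           anchors = anchors, seed = seed))
}

#' Generate an atom pair with a prescribed separation distribution
#'
#' Each frame the two atoms are placed at a separation drawn from a one- or
#' two-component Gaussian mixture (samples truncated at > 0 by resampling),
#' along a uniformly random direction about the box centre. The default atom
#' metadata mimics the valve Calpha pair (LEU 554, chains A and B) so the
#' standard pair specifications resolve on synthetic systems.
#'
#' @param means,sds,weights mixture component parameters (1 or 2 components);
#'   `weights` normalized internally
#' @param n_frames number of frames
#' @param spacing_ps frame spacing (ps)
#' @param seed RNG seed
#' @param atoms optional 2-row atom metadata data.frame (columns `name`,
#'   `element`, `resname`, `resid`, `chain`)
#' @return list with `trajectory` and `ground_truth` (`$means`, `$sds`,
#'   `$weights`, `$separations` — the exact sampled distances)
#' @export
generate_distance_pair_system <- function(means, sds, weights = NULL,
                                          n_frames = 5000, spacing_ps = 10,
                                          seed = 1, atoms = NULL) {
  k <- length(means)
  if (k < 1L || k > 2L) stop("mixture must have one or two components")
  if (length(sds) != k || any(sds < 0)) stop("one nonnegative sd per component")
  if (any(means <= 0)) stop("component means must be positive")
  if (is.null(weights)) weights <- rep(1 / k, k)
  weights <- weights / sum(weights)
  if (n_frames < 1L) stop("need at least 1 frame")
  set.seed(seed)
  comp <- sample.int(k, n_frames, replace = TRUE, prob = weights)
  r <- stats::rnorm(n_frames, means[comp], sds[comp])
  bad <- r <= 0
  while (any(bad)) {
    r[bad] <- stats::rnorm(sum(bad), means[comp[bad]], sds[comp[bad]])
    bad <- r <= 0
  }
  # uniform random directions
  u <- stats::rnorm(n_frames); v <- stats::rnorm(n_frames)
  w <- stats::rnorm(n_frames)
  norm <- sqrt(u^2 + v^2 + w^2)
  dir <- cbind(u, v, w) / norm
  box <- c(1, 1, 1) * max(4, 2 * max(means + 4 * sds) + 1)
  center <- box / 2
  if (is.null(atoms)) {
    atoms <- data.frame(name = "CA", element = "C", resname = "LEU",
                        resid = c(554L, 554L), chain = c("A", "B"),
                        stringsAsFactors = FALSE)
  }
  topology <- vw_topology(atoms)
  coords <- array(NA_real_, dim = c(2L, 3L, n_frames))
  for (f in seq_len(n_frames)) {
    coords[1L, , f] <- center - dir[f, ] * r[f] / 2
    coords[2L, , f] <- center + dir[f, ] * r[f] / 2
  }
  times <- (seq_len(n_frames) - 1L) * spacing_ps
  list(trajectory = vw_trajectory(topology, coords, box, times),
       ground_truth = list(kind = "distance_pair", means = means, sds = sds,
                           weights = weights, separations = r, seed = seed))
}

#' Generate a rigidly shifted copy of a structure
#'
#' @param topology a `vw_topology`
#' @param frame a `vw_frame`
#' @param shift_vector length-3 translation (nm)
#' @param selection optional `vw_selection`: shift only these atoms (e.g.
#'   the valve) leaving the rest fixed; default shifts every atom
#' @return list with `frame_a` (original), `frame_b` (shifted) and
#'   `ground_truth` (`$shift`)
#' @export
generate_shifted_pair <- function(topology, frame, shift_vector,
                                  selection = NULL) {
  stopifnot(inherits(frame, "vw_frame"), length(shift_vector) == 3L)
  xyz <- frame$xyz
  if (is.null(selection)) {
    xyz <- sweep(xyz, 2L, shift_vector, "+")
  } else {
    idx <- selection$indices
    xyz[idx, ] <- sweep(xyz[idx, , drop = FALSE], 2L, shift_vector, "+")
  }
  list(frame_a = frame,
       frame_b = vw_frame(xyz, frame$box, frame$time),
       ground_truth = list(kind = "shifted_pair",
                           shift = as.numeric(shift_vector)))
}

#' Build a miniature two-chain transporter model (synthetic)
#'
#' A hand-constructed stand-in with the residue identities the analyses
#' expect: per chain, valve residues 553-559 with backbone atoms (CB on the
#' leucines), roof residues R426 (CA/CZ/NH1/NH2), E585 (CA/CD/OE1/OE2),
#' K417 and K500 (CA/NZ), and a block of transmembrane-core CA atoms
#' (residues 400-410) usable as an alignment reference. Cross-dimer
#' L554/L555 CA distances are ~1.00-1.05 nm in the inward-facing geometry
#' and ~1.3 / 0.9 nm in the outward-facing one; the outward geometry also
#' raises the valve by 0.3 nm. This object is entirely synthetic — it is a
#' geometric caricature for exercising analysis code, not a model of any
#' experimental structure.
#'
#' @param state `"inward"` or `"outward"`
#' @param salt_bridge_distance distance (nm) between the R426 guanidinium
#'   nitrogens and the E585 carboxylate oxygens across the roof
#' @return list with `topology` and `frame`
#' @export
make_synthetic_transporter <- function(state = c("inward", "outward"),
                                       salt_bridge_distance = 0.30) {
  state <- match.arg(state)
  box <- c(10, 10, 12)
  cx <- 5; cy <- 5
  valve_z <- if (state == "inward") 6.0 else 6.3
  d554 <- if (state == "inward") 1.05 else 1.30
  d555 <- if (state == "inward") 1.00 else 0.90

  rows <- list(); xyz <- list()
  add <- function(name, element, resname, resid, chain, pos) {
    rows[[length(rows) + 1L]] <<- data.frame(
      name = name, element = element, resname = resname,
      resid = as.integer(resid), chain = chain, stringsAsFactors = FALSE)
    xyz[[length(xyz) + 1L]] <<- pos
  }

  for (ci in 1:2) {
    chain <- c("A", "B")[ci]
    side <- c(-1, 1)[ci]
    # valve stretch G553-T559 (residue names are a caricature anchored on
    # the glycine/leucines/threonine of the real constriction): backbone
    # along y, chains offset in x
    stretch <- c("GLY", "LEU", "LEU", "SER", "ALA", "VAL", "THR")
    for (j in 0:6) {
      resid <- 553L + j
      resname <- stretch[j + 1L]
      y <- cy + (j - 3) * 0.35
      half <- if (resid == 554L) d554 / 2 else if (resid == 555L) d555 / 2
              else 0.55
      xca <- cx + side * half
      add("N", "N", resname, resid, chain, c(xca - 0.12, y - 0.12, valve_z))
      add("CA", "C", resname, resid, chain, c(xca, y, valve_z))
      add("C", "C", resname, resid, chain, c(xca + 0.12, y + 0.12, valve_z))
      add("O", "O", resname, resid, chain, c(xca + 0.12, y + 0.24, valve_z))
      if (resid %in% c(554L, 555L)) {
        add("CB", "C", resname, resid, chain,
            c(xca - side * 0.15, y, valve_z + 0.1))
      }
    }
    # transmembrane-core CA block, residues 400-410 (alignment reference)
    for (j in 0:10) {
      add("CA", "C", "VAL", 400L + j, chain,
          c(cx + side * 1.8, cy - 1.5 + j * 0.3, 3.5))
    }
    # roof: R426 (ECL1) and E585 (re-entry helix) face each other; the
    # guanidinium N -- carboxylate O gap is salt_bridge_distance
    zroof <- 9.0
    gap <- salt_bridge_distance
    xr <- cx + side * (0.5 + gap / 2)
    xe <- cx + side * (0.5 - gap / 2)
    add("CA", "C", "ARG", 426L, chain, c(xr + side * 0.4, cy - 0.5, zroof))
    add("CZ", "C", "ARG", 426L, chain, c(xr + side * 0.1, cy - 0.5, zroof))
    add("NH1", "N", "ARG", 426L, chain, c(xr, cy - 0.55, zroof))
    add("NH2", "N", "ARG", 426L, chain, c(xr, cy - 0.45, zroof))
    add("CA", "C", "GLU", 585L, chain, c(xe - side * 0.4, cy - 0.5, zroof))
    add("CD", "C", "GLU", 585L, chain, c(xe - side * 0.1, cy - 0.5, zroof))
    add("OE1", "O", "GLU", 585L, chain, c(xe, cy - 0.55, zroof))
    add("OE2", "O", "GLU", 585L, chain, c(xe, cy - 0.45, zroof))
    # K417 on ECL1 and K500 on ECL2
    add("CA", "C", "LYS", 417L, chain, c(xr + side * 0.6, cy + 0.4, zroof))
    add("NZ", "N", "LYS", 417L, chain, c(xr + side * 0.4, cy + 0.5, zroof))
    add("CA", "C", "LYS", 500L, chain, c(xe - side * 0.6, cy + 0.6, zroof))
    add("NZ", "N", "LYS", 500L, chain, c(xe - side * 0.4, cy + 0.7, zroof))
  }
  atoms <- do.call(rbind, rows)
  list(topology = vw_topology(atoms),
       frame = vw_frame(do.call(rbind, xyz), box))
}

#' Write a synthetic system (topology, trajectory, ground truth) to disk
#'
#' Writes `<prefix>.pdb` (topology + first frame), `<prefix>.gro`
#' (multi-frame trajectory, or `.dcd` when `format = "dcd"`) and
#' `<prefix>_truth.json` (ground-truth sidecar).
#'
#' @param system list with `trajectory` and `ground_truth` as returned by
#'   the generators
#' @param prefix output path prefix
#' @param format trajectory format, `"gro"` or `"dcd"`
#' @return named character vector of the written paths
#' @export
write_synthetic_system <- function(system, prefix, format = "gro") {
  traj <- system$trajectory
  pdb_path <- paste0(prefix, ".pdb")
  trj_path <- paste0(prefix, ".", format)
  json_path <- paste0(prefix, "_truth.json")
  write_pdb_structure(traj$topology, get_frame(traj, 1L), pdb_path)
  write_trajectory(traj, trj_path, format = format)
  gt <- system$ground_truth
  jsonlite::write_json(gt, json_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  c(topology = pdb_path, trajectory = trj_path, ground_truth = json_path)
}
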