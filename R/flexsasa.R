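#' @title Per-residue flexibility and hydrophobic surface area
#' @description Root mean square fluctuations after least-squares removal of
#'   rigid-body motion, residue polarity classification, and
#'   solvent-accessible surface area by the Shrake-Rupley sphere-point
#'   method with a 0.14 nm probe, plus 1-ns running-average smoothing of
#'   SASA time series.
#' @name flexibility-sasa
NULL

#' Per-residue RMSF profile
#'
#' Each frame is superposed onto the trajectory mean structure by
#' least-squares fit on `fit_selection` (two-pass: fit to the first frame,
#' compute the mean, refit to the mean); pass `fit_selection = NULL` when
#' the trajectory carries no rigid-body motion (e.g. tethered synthetic
#' systems). RMSF of atom i is `sqrt(mean |r_i - <r_i>|^2)` over frames,
#' reported per residue of `target_selection` (conventionally the Calpha
#' atoms).
#'
#' @param traj a `vw_trajectory` with at least 2 frames (equilibration
#'   trimmed)
#' @param fit_selection `vw_selection` for the superposition, or `NULL`
#' @param target_selection `vw_selection` of atoms to report (default
#'   protein Calpha)
#' @return data.frame with columns `chain`, `resid`, `rmsf_nm` (one row per
#'   selected atom; for Calpha selections, one per residue)
#' @export
rmsf_profile <- function(traj, fit_selection = NULL,
                         target_selection = NULL) {
  stopifnot(inherits(traj, "vw_trajectory"))
  if (traj$n_frames < 2L) stop("RMSF requires at least 2 frames")
  if (is.null(target_selection)) {
    target_selection <- select_atoms(traj$topology, "protein and name CA")
  }
  n_at <- traj$topology$n_atoms
  coords <- traj$coords
  if (!is.null(fit_selection)) {
    fidx <- fit_selection$indices
    if (length(fidx) < 3L) stop("fit selection needs >= 3 atoms")
    aligned <- coords
    ref <- coords[fidx, , 1L]
    for (f in seq_len(traj$n_frames)) {
      fit <- kabsch(coords[fidx, , f], ref)
      aligned[, , f] <- fit$apply(coords[, , f])
    }
    mean_xyz <- apply(aligned, c(1, 2), mean)
    for (f in seq_len(traj$n_frames)) {
      fit <- kabsch(aligned[fidx, , f], mean_xyz[fidx, ])
      aligned[, , f] <- fit$apply(aligned[, , f])
    }
    coords <- aligned
  }
  mean_xyz <- apply(coords, c(1, 2), mean)
  dev2 <- array(0, dim = c(n_at, traj$n_frames))
  for (f in seq_len(traj$n_frames)) {
    d <- coords[, , f] - mean_xyz
    dev2[, f] <- rowSums(d * d)
  }
  rmsf <- sqrt(rowMeans(dev2))
  tidx <- target_selection$indices
  at <- traj$topology$atoms
  data.frame(chain = at$chain[tidx], resid = at$resid[tidx],
             rmsf_nm = rmsf[tidx], stringsAsFactors = FALSE)
}

#' Average RMSF profiles over replicates
#'
#' @param profiles list of data.frames from [rmsf_profile()] over the same
#'   residues
#' @return data.frame `chain`, `resid`, `rmsf_nm` (replicate mean), `n`
#' @export
rmsf_average <- function(profiles) {
  stopifnot(is.list(profiles), length(profiles) >= 1L)
  base <- profiles[[1L]][, c("chain", "resid")]
  for (p in profiles[-1L]) {
    if (!identical(p$resid, profiles[[1L]]$resid) ||
        !identical(p$chain, profiles[[1L]]$chain)) {
      stop("replicate profiles cover different residues")
    }
  }
  vals <- vapply(profiles, function(p) p$rmsf_nm,
                 numeric(nrow(base)))
  if (is.null(dim(vals))) vals <- matrix(vals, nrow = nrow(base))
  base$rmsf_nm <- rowMeans(vals)
  base$n <- length(profiles)
  base
}

POLARITY_TABLE <- c(
  ALA = "hydrophobic", VAL = "hydrophobic", LEU = "hydrophobic",
  ILE = "hydrophobic", PHE = "hydrophobic", MET = "hydrophobic",
  TRP = "hydrophobic", PRO = "hydrophobic",
  SER = "polar", THR = "polar", ASN = "polar", GLN = "polar",
  TYR = "polar", CYS = "polar", GLY = "polar",
  ARG = "positive", LYS = "positive", HIS = "positive",
  ASP = "negative", GLU = "negative"
)

#' Classify a residue by side-chain polarity
#'
#' Classes: hydrophobic (ALA VAL LEU ILE PHE MET TRP PRO), polar (SER THR
#' ASN GLN TYR CYS GLY), positive (ARG LYS HIS), negative (ASP GLU). GLY and
#' CYS are assigned polar; override by passing a modified `table`.
#'
#' @param resname three-letter residue name
#' @param table named character vector mapping residue names to classes
#' @return one of `"hydrophobic"`, `"polar"`, `"positive"`, `"negative"`
#' @export
classify_polarity <- function(resname, table = POLARITY_TABLE) {
  key <- toupper(resname)
  out <- unname(table[key])
  if (any(is.na(out))) {
    stop("non-standard residue name(s): ",
         paste(unique(key[is.na(out)]), collapse = ", "))
  }
  out
}

#' Van der Waals radii (nm) used for SASA
#' @export
VDW_RADII <- c(H = 0.120, C = 0.170, N = 0.155, O = 0.152, S = 0.180,
               P = 0.180)

vdw_radius <- function(element) {
  r <- VDW_RADII[toupper(element)]
  r[is.na(r)] <- 0.170
  unname(r)
}

# deterministic quasi-uniform points on the unit sphere (golden spiral)
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Per-atom solvent-accessible surface area (Shrake-Rupley)
#'
#' Each atom's accessible sphere (van der Waals radius + probe radius) is
#' sampled with `n_points` quasi-uniform test points; points buried inside
#' any neighbour's accessible sphere are discarded and the exposed fraction
#' scales the sphere area.
#'
#' @param xyz n x 3 coordinate matrix (nm)
#' @param radii per-atom van der Waals radii (nm)
#' @param probe probe radius (nm), default 0.14 (water)
#' @param n_points sphere sample points per atom, default 960
#' @return numeric vector of per-atom SASA (nm^2)
#' @export
shrake_rupley <- function(xyz, radii, probe = 0.14, n_points = 960L) {
  xyz <- as.matrix(xyz)
  n <- nrow(xyz)
  if (length(radii) != n) stop("one radius per atom required")
  pts <- sphere_points(n_points)
  racc <- radii + probe
  out <- numeric(n)
  max_r <- max(racc)
  # an atom exactly coincident with an earlier identical atom adds no
  # surface: it gets zero area and does not occlude
  dup <- duplicated(cbind(round(xyz, 9), round(racc, 9)))
  live <- which(!dup)
  xyz_l <- xyz[live, , drop = FALSE]
  racc_l <- racc[live]
  for (i in live) {
    d2 <- rowSums(sweep(xyz_l, 2L, xyz[i, ])^2)
    nb <- which(d2 > 0 & d2 < (racc[i] + max_r)^2)
    nb <- nb[sqrt(d2[nb]) < racc[i] + racc_l[nb]]
    surf <- sweep(pts * racc[i], 2L, xyz[i, ], "+")
    exposed <- rep(TRUE, n_points)
    for (j in nb) {
      dj <- sweep(surf, 2L, xyz_l[j, ])
      exposed <- exposed & (rowSums(dj * dj) >= racc_l[j]^2)
      if (!any(exposed)) break
    }
    out[i] <- 4 * pi * racc[i]^2 * mean(exposed)
  }
  out
}

#' Default upper-cavity residue list
#'
#' Editorial reconstruction of the cavity-facing residues of the valve
#' stretch, re-entry helix and extracellular loops used for upper-cavity
#' surface accounting (the exact set is a configuration input; this default
#' collects the residues named in the analyses: the G553-T559 valve
#' stretch, F431, the R426/E585 salt-bridge partners, K417, K500 and the
#' disulfide cysteines C592/C603/C608).
#' @export
UPPER_CAVITY_RESIDUES <- c(553:559, 431L, 426L, 585L, 417L, 500L,
                           592L, 603L, 608L)

#' Hydrophobic SASA time series of a residue set
#'
#' Per analyzed frame, the summed SASA of atoms belonging to the cavity
#' residues whose residue class matches `class_filter`, computed against
#' all atoms of `context_selection` (default: the whole protein). The raw
#' series is smoothed with a centered running average (default window 1 ns).
#'
#' @param traj a `vw_trajectory` (equilibration trimmed)
#' @param cavity_residues integer vector of residue numbers (both chains are
#'   included); see [UPPER_CAVITY_RESIDUES]
#' @param class_filter polarity class to keep (`"hydrophobic"` by default)
#'   or `NULL` for all cavity atoms
#' @param probe probe radius (nm)
#' @param stride_ps sampling stride (ps)
#' @param window_ps smoothing window (ps), default 1000 (1 ns)
#' @param n_points Shrake-Rupley sphere points per atom
#' @param context_selection `vw_selection` defining the occluding atom set;
#'   default all protein atoms
#' @return object of class `vw_sasa_series`: `times_ps`, `raw_nm2`,
#'   `smoothed_nm2`, `residues`, `probe_nm`, `stride_ps`
#' @export
sasa_series <- function(traj, cavity_residues = UPPER_CAVITY_RESIDUES,
                        class_filter = "hydrophobic", probe = 0.14,
                        stride_ps = 10, window_ps = 1000, n_points = 960L,
                        context_selection = NULL) {
  stopifnot(inherits(traj, "vw_trajectory"))
  if (length(cavity_residues) == 0L) stop("cavity residue list is empty")
  if (is.null(context_selection)) {
    context_selection <- select_atoms(traj$topology, "protein")
  }
  at <- traj$topology$atoms
  cidx <- context_selection$indices
  in_cavity <- at$resid[cidx] %in% cavity_residues
  if (!is.null(class_filter)) {
    cls <- classify_polarity(at$resname[cidx])
    in_cavity <- in_cavity & cls == class_filter
  }
  if (!any(in_cavity)) {
    stop("no cavity atoms match the class filter")
  }
  radii <- vdw_radius(at$element[cidx])
  k <- stride_ps / traj$spacing
  if (abs(k - round(k)) > 1e-9 || k < 1) {
    stop("stride is not a multiple of the frame spacing")
  }
  frames <- seq(1L, traj$n_frames, by = as.integer(round(k)))
  raw <- vapply(frames, function(fi) {
    a <- shrake_rupley(traj$coords[cidx, , fi], radii, probe, n_points)
    sum(a[in_cavity])
  }, numeric(1))
  smoothed <- running_average(raw, window_ps = window_ps,
                              spacing_ps = stride_ps)
  structure(list(times_ps = traj$times[frames], raw_nm2 = raw,
                 smoothed_nm2 = smoothed, residues = cavity_residues,
                 probe_nm = probe, stride_ps = stride_ps),
            class = "vw_sasa_series")
}

#' @export
print.vw_sasa_series <- function(x, ...) {
  cat("<vw_sasa_series> ", length(x$raw_nm2), " samples at ", x$stride_ps,
      " ps; mean ", signif(mean(x$raw_nm2), 4), " nm^2\n", sep = "")
  invisible(x)
}

#' Centered running average
#'
#' Moving mean over a window of `window_ps / spacing_ps` samples, centered
#' on each point; windows shrink near the series edges.
#'
#' @param x numeric series
#' @param window_ps window length in ps
#' @param spacing_ps sample spacing in ps
#' @return smoothed series, same length as `x`
#' @export
running_average <- function(x, window_ps = 1000, spacing_ps = 10) {
  n <- length(x)
  if (n == 0L) stop("empty series")
  if (window_ps < spacing_ps) stop("window shorter than the sampling interval")
  n_win <- max(1L, as.integer(round(window_ps / spacing_ps)))
  hl <- (n_win - 1L) %/% 2L
  hr <- n_win - 1L - hl
  cs <- c(0, cumsum(x))
  lo <- pmax(1L, seq_len(n) - hl)
  hi <- pmin(n, seq_len(n) + hr)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}
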