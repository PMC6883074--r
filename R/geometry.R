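#' @title Salt-bridge and valve geometry
#' @description Minimum-image distance time series between named atom pairs,
#'   boxplot statistics using the mean-as-centre convention, pooled distance
#'   probability distributions, salt-bridge detection and the axial shift of
#'   the valve between conformational states.
#' @name geometry
NULL

#' Parse a pair specification
#'
#' Mini-language: `"585:CD-426:CZ"` means the CD atom of residue 585 against
#' the CZ atom of residue 426. An optional leading chain qualifier is
#' allowed on either side (`"A/585:CD-A/426:CZ"`). Without a chain, one
#' series per chain is produced ("both transporter halves"), iterating
#' chains in topology order.
#'
#' @param spec specification string
#' @return list of two endpoints, each `list(chain, resid, name)`
#' @export
parse_pair_spec <- function(spec) {
  sides <- strsplit(spec, "-", fixed = TRUE)[[1L]]
  if (length(sides) != 2L) stop("pair spec must be '<res>:<atom>-<res>:<atom>'")
  parse_side <- function(s) {
    chain <- NA_character_
    if (grepl("/", s, fixed = TRUE)) {
      parts <- strsplit(s, "/", fixed = TRUE)[[1L]]
      chain <- parts[1L]
      s <- parts[2L]
    }
    parts <- strsplit(s, ":", fixed = TRUE)[[1L]]
    if (length(parts) != 2L || !grepl("^[0-9]+$", parts[1L])) {
      stop("malformed pair spec endpoint '", s, "'")
    }
    list(chain = chain, resid = as.integer(parts[1L]), name = parts[2L])
  }
  lapply(sides, parse_side)
}

resolve_endpoint <- function(topology, ep, chain) {
  at <- topology$atoms
  use_chain <- if (is.na(ep$chain)) chain else ep$chain
  hit <- which(at$resid == ep$resid & toupper(at$name) == toupper(ep$name) &
               at$chain == use_chain)
  if (length(hit) == 0L) {
    stop("atom ", ep$name, " of residue ", ep$resid, " (chain ", use_chain,
         ") not found; for mutated residues the requested side-chain atom ",
         "may not exist")
  }
  hit[1L]
}

#' Distance time series for an atom pair
#'
#' One series per chain (transporter half) unless the spec pins chains.
#' Distances are minimum-image; default sampling is one point per ns, the
#' convention used for the roof salt-bridge statistics.
#'
#' @param traj a `vw_trajectory`
#' @param pair_spec specification string, see [parse_pair_spec()]
#' @param stride_ns sampling stride (ns); must be a multiple of the frame
#'   spacing
#' @param construct free-text construct label carried into the output
#' @return list of data.frames (one per half) with columns `time_ps`,
#'   `distance_nm`, `half`, `label`, `construct`
#' @export
distance_series <- function(traj, pair_spec, stride_ns = 1,
                            construct = "WT") {
  stopifnot(inherits(traj, "vw_trajectory"))
  eps <- parse_pair_spec(pair_spec)
  stride_ps <- stride_ns * 1000
  k <- stride_ps / traj$spacing
  if (abs(k - round(k)) > 1e-9 || k < 1) {
    stop("stride ", stride_ns, " ns is not a multiple of the frame spacing")
  }
  k <- as.integer(round(k))
  frames <- seq(1L, traj$n_frames, by = k)
  chains <- if (is.na(eps[[1L]]$chain) && is.na(eps[[2L]]$chain)) {
    unique(traj$topology$atoms$chain)
  } else NA_character_
  out <- list()
  for (ch in chains) {
    i <- resolve_endpoint(traj$topology, eps[[1L]], ch)
    j <- resolve_endpoint(traj$topology, eps[[2L]], ch)
    d <- vapply(frames, function(fi) {
      minimum_image_distance(traj$coords[i, , fi], traj$coords[j, , fi],
                             traj$box[fi, ])
    }, numeric(1))
    out[[length(out) + 1L]] <- data.frame(
      time_ps = traj$times[frames], distance_nm = d,
      half = if (is.na(ch)) "pinned" else ch,
      label = pair_spec, construct = construct,
      stringsAsFactors = FALSE)
  }
  out
}

#' Boxplot statistics with the mean as centre line
#'
#' Quartiles use inclusive linear interpolation (`stats::quantile` type 7);
#' the centre is the arithmetic mean — not the median — matching the
#' convention "the center line shows the mean, the whiskers reach the
#' extremes".
#'
#' @param x numeric vector (distances, nm), n >= 1
#' @return list with `mean`, `q1`, `q3`, `min`, `max`, `n`
#' @export
boxplot_stats <- function(x) {
  x <- as.numeric(x)
  if (length(x) == 0L || any(!is.finite(x))) {
    stop("series must be nonempty and finite")
  }
  q <- stats::quantile(x, c(0.25, 0.75), names = FALSE, type = 7)
  list(mean = mean(x), q1 = q[1L], q3 = q[2L],
       min = min(x), max = max(x), n = length(x))
}

#' Pooled distance probability distribution
#'
#' Replicate (and half) series are pooled into one normalized histogram;
#' per-series histograms are retained so the composition is auditable.
#'
#' @param series_list list of numeric vectors (or of data.frames with a
#'   `distance_nm` column)
#' @param bin_width histogram bin width (nm)
#' @return list with `breaks`, `mids`, `prob` (sums to 1), `n`,
#'   `per_series` (list of per-input probability vectors on the same bins)
#' @export
distance_probability <- function(series_list, bin_width = 0.05) {
  if (bin_width <= 0) stop("bin width must be positive")
  vecs <- lapply(series_list, function(s) {
    if (is.data.frame(s)) s$distance_nm else as.numeric(s)
  })
  all_d <- unlist(vecs)
  if (length(all_d) == 0L) stop("no distances supplied")
  lo <- floor(min(all_d) / bin_width) * bin_width
  hi <- ceiling(max(all_d) / bin_width) * bin_width
  if (hi <= lo) hi <- lo + bin_width
  breaks <- seq(lo, hi, by = bin_width)
  counts <- hist(all_d, breaks = breaks, plot = FALSE)$counts
  per_series <- lapply(vecs, function(v) {
    cts <- hist(v, breaks = breaks, plot = FALSE)$counts
    cts / sum(cts)
  })
  list(breaks = breaks, mids = breaks[-length(breaks)] + bin_width / 2,
       prob = counts / sum(counts), n = length(all_d),
       per_series = per_series)
}

CHARGED_GROUP_ATOMS <- list(
  ARG = c("NE", "NH1", "NH2"),
  LYS = c("NZ"),
  HIS = c("ND1", "NE2"),
  GLU = c("OE1", "OE2"),
  ASP = c("OD1", "OD2")
)

charged_group_indices <- function(topology, resid, chain) {
  at <- topology$atoms
  rows <- which(at$resid == resid & at$chain == chain)
  if (length(rows) == 0L) {
    stop("residue ", resid, " (chain ", chain, ") not in topology")
  }
  resname <- toupper(at$resname[rows[1L]])
  grp <- CHARGED_GROUP_ATOMS[[resname]]
  if (is.null(grp)) {
    stop("residue ", resname, " ", resid,
         " is not a charged residue type (Arg/Lys/His/Glu/Asp)")
  }
  idx <- rows[toupper(at$name[rows]) %in% grp]
  if (length(idx) == 0L) {
    stop("no charged-group heavy atoms found for ", resname, " ", resid)
  }
  idx
}

#' Detect a salt bridge between two residues
#'
#' Bridged iff the minimum cross distance between the side-chain charged
#' heavy atoms (guanidinium/amine N of Arg/Lys/His; carboxylate O of
#' Glu/Asp) is below `cutoff_nm` (default 0.4 nm, the conventional
#' criterion). Symmetric in residue order.
#'
#' @param traj a `vw_trajectory` (a single `vw_frame` also works if wrapped
#'   in a one-frame trajectory)
#' @param residue_a,residue_b residue numbers
#' @param chain_a,chain_b chain ids (default `"A"`)
#' @param cutoff_nm bridge distance cutoff (nm)
#' @return list with `fraction` of frames bridged, `min_distance_nm` series,
#'   `times_ps`, `cutoff_nm`
#' @export
detect_salt_bridge <- function(traj, residue_a, residue_b,
                               chain_a = "A", chain_b = "A",
                               cutoff_nm = 0.4) {
  stopifnot(inherits(traj, "vw_trajectory"))
  ia <- charged_group_indices(traj$topology, residue_a, chain_a)
  ib <- charged_group_indices(traj$topology, residue_b, chain_b)
  mind <- vapply(seq_len(traj$n_frames), function(fi) {
    pa <- matrix(traj$coords[ia, , fi], ncol = 3L)
    pb <- matrix(traj$coords[ib, , fi], ncol = 3L)
    grid <- expand.grid(u = seq_len(nrow(pa)), v = seq_len(nrow(pb)))
    min(minimum_image_distance(pa[grid$u, , drop = FALSE],
                               pb[grid$v, , drop = FALSE], traj$box[fi, ]))
  }, numeric(1))
  list(fraction = mean(mind < cutoff_nm), min_distance_nm = mind,
       times_ps = traj$times, cutoff_nm = cutoff_nm)
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Returns the rotation and translation mapping `mobile` onto `ref` in the
#' least-squares sense.
#'
#' @param mobile,ref n x 3 coordinate matrices (paired rows)
#' @return list with `R` (3 x 3 rotation), `t` (translation), and
#'   `apply(x)` helper transforming an m x 3 matrix
#' @export
kabsch <- function(mobile, ref) {
  stopifnot(nrow(mobile) == nrow(ref), nrow(mobile) >= 3L)
  cm <- colMeans(mobile); cr <- colMeans(ref)
  A <- sweep(mobile, 2L, cm)
  B <- sweep(ref, 2L, cr)
  H <- t(A) %*% B
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$v %*% D %*% t(s$u)
  t_vec <- cr - as.numeric(R %*% cm)
  list(R = R, t = t_vec,
       apply = function(x) sweep(x %*% t(R), 2L, t_vec, "+"))
}

#' Axial shift of the valve between two structures
#'
#' The signed difference, along the membrane normal, of the valve-selection
#' centroid between structure B and structure A. Structures are assumed
#' pre-aligned on a common reference; supply `align_selection` (e.g. the
#' transmembrane-core Calpha atoms) to superpose B onto A first.
#'
#' @param frame_a,frame_b `vw_frame`s sharing one topology
#' @param valve_selection a `vw_selection`
#' @param axis 1, 2 or 3 (default 3, the z membrane normal)
#' @param align_selection optional `vw_selection` used for least-squares
#'   superposition of B onto A before measuring
#' @return signed shift in nm (positive = B displaced toward +axis)
#' @export
valve_axial_shift <- function(frame_a, frame_b, valve_selection,
                              axis = 3L, align_selection = NULL) {
  stopifnot(inherits(frame_a, "vw_frame"), inherits(frame_b, "vw_frame"))
  if (nrow(frame_a$xyz) != nrow(frame_b$xyz)) {
    stop("structures have different atom counts")
  }
  xyz_b <- frame_b$xyz
  if (!is.null(align_selection)) {
    fit <- kabsch(selection_xyz(frame_b, align_selection),
                  selection_xyz(frame_a, align_selection))
    xyz_b <- fit$apply(xyz_b)
  }
  ca <- colMeans(selection_xyz(frame_a, valve_selection))
  cb <- colMeans(xyz_b[valve_selection$indices, , drop = FALSE])
  (cb - ca)[axis]
}

#' Cross-dimer valve Calpha distances
#'
#' Distances between the Calpha atoms of the same valve residue on the two
#' chains (one value per residue), the quantity used to characterize the
#' valve geometry of inward- and outward-facing states.
#'
#' @param topology a `vw_topology`
#' @param frame a `vw_frame`
#' @param resids valve residue numbers (default 554 and 555)
#' @param chains the two chain ids (default first two chains in topology)
#' @return named numeric vector of distances (nm), names like `"L554"`
#' @export
valve_calpha_distances <- function(topology, frame, resids = c(554L, 555L),
                                   chains = NULL) {
  at <- topology$atoms
  if (is.null(chains)) chains <- unique(at$chain)[1:2]
  if (length(chains) != 2L || any(is.na(chains))) {
    stop("two chains are required")
  }
  out <- numeric(0)
  for (r in resids) {
    i <- which(at$resid == r & toupper(at$name) == "CA" &
               at$chain == chains[1L])
    j <- which(at$resid == r & toupper(at$name) == "CA" &
               at$chain == chains[2L])
    if (length(i) == 0L || length(j) == 0L) {
      stop("Calpha of residue ", r, " missing in one chain")
    }
    d <- minimum_image_distance(frame$xyz[i[1L], ], frame$xyz[j[1L], ],
                                frame$box)
    nm <- paste0(substr(at$resname[i[1L]], 1L, 1L), r)
    out[nm] <- d
  }
  out
}

#' Cross-dimer valve backbone distance
#'
#' Distance between the per-chain centroids of the backbone atoms
#' (N, CA, C, O) of the valve residues; the conventional "distance between
#' the backbones at the valve" (about 0.9 nm in both conformational states
#' of ABCG2). The residue set is configurable.
#'
#' @inheritParams valve_calpha_distances
#' @param resids valve residues pooled into each chain's centroid
#' @return distance in nm
#' @export
valve_backbone_distance <- function(topology, frame,
                                    resids = c(554L, 555L), chains = NULL) {
  at <- topology$atoms
  if (is.null(chains)) chains <- unique(at$chain)[1:2]
  bb <- c("N", "CA", "C", "O")
  cents <- lapply(chains, function(ch) {
    idx <- which(at$resid %in% resids & toupper(at$name) %in% bb &
                 at$chain == ch)
    if (length(idx) == 0L) stop("no backbone atoms for chain ", ch)
    colMeans(frame$xyz[idx, , drop = FALSE])
  })
  minimum_image_distance(cents[[1L]], cents[[2L]], frame$box)
}
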