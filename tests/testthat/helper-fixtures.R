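# Shared fixture builders. All synthetic, generated in code at test time.

tiny_topology <- function() {
  vw_topology(data.frame(
    name = c("CA", "CA", "OW"),
    element = c("C", "C", "O"),
    resname = c("LEU", "LEU", "SOL"),
    resid = c(554L, 554L, 1L),
    chain = c("A", "B", "W"),
    stringsAsFactors = FALSE))
}

# static trajectory: every frame identical to `xyz`
static_trajectory <- function(topology, xyz, box, n_frames = 5,
                              spacing_ps = 10) {
  coords <- array(rep(xyz, n_frames),
                  dim = c(nrow(xyz), 3L, n_frames))
  vw_trajectory(topology, coords, box,
                (seq_len(n_frames) - 1L) * spacing_ps)
}

# a hand-written 3-atom PDB with coordinates at exactly 10 A = 1.0 nm scale
write_tiny_pdb <- function(path) {
  writeLines(c(
    "CRYST1  100.000  100.000  100.000  90.00  90.00  90.00 P 1           1",
    "ATOM      1  CA  LEU A 554      10.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CA  LEU B 554       0.000  10.000   0.000  1.00  0.00           C",
    "ATOM      3  OW  SOL W   1       0.000   0.000  10.000  1.00  0.00           O",
    "END"), path)
  path
}

# independent sort-based quartile oracle (inclusive linear interpolation):
# h = (n - 1) p + 1, value = x[floor(h)] + (h - floor(h)) (x[floor(h)+1] - x[floor(h)])
oracle_quartile <- function(x, p) {
  xs <- sort(x)
  n <- length(xs)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  if (lo >= n) return(xs[n])
  xs[lo] + (h - lo) * (xs[lo + 1] - xs[lo])
}

# Monte-Carlo surface-point SASA oracle for a small set of spheres
mc_sasa <- function(xyz, radii, probe = 0.14, n_points = 40000L, seed = 99) {
  set.seed(seed)
  n <- nrow(xyz)
  racc <- radii + probe
  out <- numeric(n)
  for (i in seq_len(n)) {
    v <- matrix(stats::rnorm(3L * n_points), ncol = 3L)
    v <- v / sqrt(rowSums(v * v))
    pts <- sweep(v * racc[i], 2L, xyz[i, ], "+")
    exposed <- rep(TRUE, n_points)
    for (j in seq_len(n)[-i]) {
      d2 <- rowSums(sweep(pts, 2L, xyz[j, ])^2)
      exposed <- exposed & d2 >= racc[j]^2
    }
    out[i] <- 4 * pi * racc[i]^2 * mean(exposed)
  }
  out
}

# filter a barrier-system ground-truth log to events visible in the flux
# boxes: the water must be labelled in one sub-box at the frame before the
# crossing and in the other at the crossing frame
filter_ground_truth <- function(system, boxes, stringent = TRUE) {
  traj <- system$trajectory
  gt <- system$ground_truth$events
  if (nrow(gt) == 0L) return(gt)
  wsel <- select_atoms(traj$topology, "water")
  labels <- vapply(seq_len(traj$n_frames), function(f) {
    classify_waters(get_frame(traj, f), boxes, wsel)
  }, character(length(wsel$indices)))
  if (is.null(dim(labels))) labels <- matrix(labels, nrow = 1L)
  keep <- vapply(seq_len(nrow(gt)), function(r) {
    f <- gt$frame[r]; w <- gt$water[r]
    (labels[w, f - 1L] == "central" && labels[w, f] == "upper") ||
      (labels[w, f - 1L] == "upper" && labels[w, f] == "central")
  }, logical(1))
  gt[keep, , drop = FALSE]
}

# ring of hydrophobic residues whose radius expands over time (cavity
# opening fixture)
cavity_opening_trajectory <- function(n_res = 8, r0 = 0.25, r1 = 0.60,
                                      n_frames = 40, spacing_ps = 10) {
  atoms <- data.frame(name = "CA", element = "C", resname = "LEU",
                      resid = seq_len(n_res), chain = "A",
                      stringsAsFactors = FALSE)
  topo <- vw_topology(atoms)
  ang <- 2 * pi * (seq_len(n_res) - 1L) / n_res
  coords <- array(NA_real_, dim = c(n_res, 3L, n_frames))
  for (f in seq_len(n_frames)) {
    r <- r0 + (r1 - r0) * (f - 1) / (n_frames - 1)
    coords[, , f] <- cbind(3 + r * cos(ang), 3 + r * sin(ang), rep(3, n_res))
  }
  vw_trajectory(topo, coords, c(6, 6, 6),
                (seq_len(n_frames) - 1L) * spacing_ps)
}
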