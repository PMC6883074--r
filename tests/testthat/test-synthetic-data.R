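test_that("a sealed barrier produces no crossings and no logged events", {
  sys <- generate_barrier_system(barrier_params(
    n_waters = 40, crossing_probability = 0, n_frames = 500, seed = 3))
  expect_equal(nrow(sys$ground_truth$events), 0L)
  z <- sys$trajectory$coords[-(1:8), 3L, ]
  side <- z > 6
  expect_true(all(side[, 1L] == side[, ncol(side)]))
})

test_that("every logged event is a sign change of z - barrier_z", {
  sys <- generate_barrier_system(barrier_params(
    n_waters = 60, crossing_probability = 0.4, n_frames = 400, seed = 9))
  gt <- sys$ground_truth$events
  expect_gt(nrow(gt), 0L)
  z0 <- sys$ground_truth$params$barrier_z
  z <- sys$trajectory$coords[, 3L, ]
  for (r in seq_len(nrow(gt))) {
    za <- z[gt$atom[r], gt$frame[r] - 1L]
    zb <- z[gt$atom[r], gt$frame[r]]
    expect_true((za - z0) * (zb - z0) < 0)
    expect_equal(gt$direction[r], if (zb > z0) "up" else "down")
  }
  # and conversely: no unlogged sign changes
  side <- z[-(1:8), , drop = FALSE] > z0
  n_changes <- sum(side[, -1L] != side[, -ncol(side)])
  expect_equal(n_changes, nrow(gt))
})

test_that("with p=1 and zero thickness the barrier system matches free diffusion", {
  pp <- barrier_params(n_waters = 150, crossing_probability = 1,
                       barrier_half_thickness = 0, step_sigma = 0.05,
                       n_frames = 1500, seed = 21)
  sys <- generate_barrier_system(pp)
  gt_frames <- sys$ground_truth$events$frame
  # independent brute-force oracle: free Brownian particles with the same
  # wall reflection, no barrier logic at all
  set.seed(777)
  box <- pp$box
  pos <- cbind(runif(pp$n_waters, 0, box[1L]), runif(pp$n_waters, 0, box[2L]),
               runif(pp$n_waters, 0, box[3L]))
  oracle_frames <- integer(0)
  for (f in 2:pp$n_frames) {
    nxt <- pos + matrix(rnorm(3 * pp$n_waters, 0, pp$step_sigma),
                        ncol = 3L)
    for (k in 1:3) {
      v <- nxt[, k]
      v <- ifelse(v < 0, -v, v)
      v <- ifelse(v > box[k], 2 * box[k] - v, v)
      nxt[, k] <- v
    }
    n_cross <- sum((pos[, 3L] > pp$barrier_z) != (nxt[, 3L] > pp$barrier_z))
    oracle_frames <- c(oracle_frames, rep(f, n_cross))
    pos <- nxt
  }
  # successive recrossings make raw counts overdispersed relative to
  # Poisson, so compare windowed rates with their empirical variances
  brk <- seq(1, pp$n_frames + 1, length.out = 21)
  c_gen <- as.numeric(table(cut(gt_frames, brk)))
  c_ora <- as.numeric(table(cut(oracle_frames, brk)))
  se <- sqrt(stats::var(c_gen) / 20 + stats::var(c_ora) / 20)
  expect_lt(abs(mean(c_gen) - mean(c_ora)), 3 * se)
})

test_that("generators are bit-reproducible from their seeds", {
  p <- barrier_params(n_waters = 20, n_frames = 50, seed = 12)
  a <- generate_barrier_system(p)
  b <- generate_barrier_system(p)
  expect_identical(a$trajectory$coords, b$trajectory$coords)
  expect_identical(a$ground_truth$events, b$ground_truth$events)
  t1 <- generate_tethered_system(c(0.02, 0.05), n_frames = 100, seed = 4)
  t2 <- generate_tethered_system(c(0.02, 0.05), n_frames = 100, seed = 4)
  expect_identical(t1$trajectory$coords, t2$trajectory$coords)
  d1 <- generate_distance_pair_system(1, 0.05, n_frames = 50, seed = 8)
  d2 <- generate_distance_pair_system(1, 0.05, n_frames = 50, seed = 8)
  expect_identical(d1$ground_truth$separations, d2$ground_truth$separations)
})

test_that("per-window barrier event counts are Poisson-like", {
  # in the rare-crossing regime a hydrophobic seal emulates; at high
  # crossing probability recrossing bursts overdisperse the counts
  sys <- generate_barrier_system(barrier_params(
    n_waters = 300, crossing_probability = 0.05, n_frames = 4000, seed = 31))
  gt <- sys$ground_truth$events
  windows <- cut(gt$frame, breaks = seq(1, 4001, length.out = 21))
  counts <- as.numeric(table(windows))
  ratio <- stats::var(counts) / mean(counts)
  expect_gte(ratio, 0.5)
  expect_lte(ratio, 2)
})

test_that("tethered fluctuations match the prescribed sigmas", {
  sig <- c(0.02, 0.05, 0.10)
  sys <- generate_tethered_system(sig, n_frames = 5000, seed = 2)
  idx <- select_atoms(sys$trajectory$topology, "resname ALA and name CA")$indices
  for (i in seq_along(sig)) {
    per_coord_sd <- apply(sys$trajectory$coords[idx[i], , ], 1L, stats::sd)
    expect_lt(max(abs(per_coord_sd - sig[i]) / sig[i]), 0.05)
  }
  rigid <- generate_tethered_system(c(0, 0), n_frames = 10, seed = 1)
  expect_equal(max(abs(rigid$trajectory$coords[, , 1] -
                       rigid$trajectory$coords[, , 10])), 0)
})

test_that("distance-pair separations follow the prescribed mixture", {
  one <- generate_distance_pair_system(1.0, 0.05, n_frames = 5000, seed = 4)
  d <- sqrt(colSums((one$trajectory$coords[1, , ] -
                     one$trajectory$coords[2, , ])^2))
  expect_equal(d, one$ground_truth$separations, tolerance = 1e-12)
  expect_lt(abs(mean(d) - 1.0), 0.01)
  two <- generate_distance_pair_system(c(0.9, 1.3), c(0.04, 0.04),
                                       n_frames = 6000, seed = 5)
  h <- hist(two$ground_truth$separations, breaks = seq(0.6, 1.6, 0.05),
            plot = FALSE)
  # modes at the component means
  dens <- h$counts
  mids <- h$mids
  expect_lt(abs(mids[which.max(dens * (mids < 1.1))] - 0.9), 0.051)
  expect_lt(abs(mids[which.max(dens * (mids > 1.1))] - 1.3), 0.051)
  single <- generate_distance_pair_system(1.0, 0.05, n_frames = 1, seed = 6)
  d1 <- sqrt(sum((single$trajectory$coords[1, , 1] -
                  single$trajectory$coords[2, , 1])^2))
  expect_equal(d1, single$ground_truth$separations[1L])
})

test_that("shifted pairs recover the prescribed translation", {
  st <- make_synthetic_transporter("inward")
  same <- generate_shifted_pair(st$topology, st$frame, c(0, 0, 0))
  expect_identical(same$frame_a$xyz, same$frame_b$xyz)
  sp <- generate_shifted_pair(st$topology, st$frame, c(0, 0, 0.3))
  expect_equal(max(abs(sp$frame_b$xyz - sp$frame_a$xyz -
                       matrix(c(0, 0, 0.3), nrow(sp$frame_a$xyz), 3L,
                              byrow = TRUE))), 0)
})

test_that("synthetic systems survive a full write/read cycle with sidecar", {
  sys <- generate_barrier_system(barrier_params(n_waters = 10, n_frames = 6,
                                                seed = 14))
  prefix <- file.path(tempdir(), "synthsys")
  paths <- write_synthetic_system(sys, prefix)
  expect_true(all(file.exists(paths)))
  st <- load_structure(paths[["topology"]])
  expect_equal(st$topology$n_atoms, sys$trajectory$topology$n_atoms)
  back <- load_trajectory(st$topology, paths[["trajectory"]])
  expect_equal(back$n_frames, 6L)
  gt <- jsonlite::read_json(paths[["ground_truth"]], simplifyVector = TRUE)
  expect_equal(gt$params$crossing_probability,
               sys$ground_truth$params$crossing_probability)
})
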