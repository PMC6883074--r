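test_that("distance series are constant for fixed pairs and track mixtures", {
  st <- make_synthetic_transporter("inward")
  # constant-geometry trajectory: every frame identical
  traj <- static_trajectory(st$topology, st$frame$xyz, st$frame$box,
                            n_frames = 5, spacing_ps = 1000)
  d0 <- minimum_image_distance(
    st$frame$xyz[select_atoms(st$topology, "chain A and resid 554 and name CA")$indices, ],
    st$frame$xyz[select_atoms(st$topology, "chain B and resid 554 and name CA")$indices, ],
    st$frame$box)
  ser <- distance_series(traj, "A/554:CA-B/554:CA", stride_ns = 1)
  expect_length(ser, 1L)
  expect_true(all(abs(ser[[1L]]$distance_nm - d0) < 1e-12))

  sys <- generate_distance_pair_system(1.0, 0.05, n_frames = 5000, seed = 4)
  ds <- distance_series(sys$trajectory, "A/554:CA-B/554:CA",
                        stride_ns = 0.01)
  expect_lt(abs(mean(ds[[1L]]$distance_nm) - 1.0), 0.01)
})

test_that("unpinned pair specs produce one series per transporter half", {
  st <- make_synthetic_transporter("inward")
  # 150 frames at 1 ns: 150 points per half, 900 over 3 replicates x 2 halves
  traj <- static_trajectory(st$topology, st$frame$xyz, st$frame$box,
                            n_frames = 150, spacing_ps = 1000)
  halves <- distance_series(traj, "585:CD-426:CZ", stride_ns = 1)
  expect_length(halves, 2L)
  expect_setequal(vapply(halves, function(h) h$half[1L], character(1)),
                  c("A", "B"))
  total <- 3 * sum(vapply(halves, nrow, integer(1)))
  expect_equal(total, 900L)
})

test_that("missing side-chain atoms of mutated residues fail loudly", {
  # an alanine at 585 has no CD: the spec must not silently fall back
  atoms <- data.frame(
    name = c("CA", "CB", "CA", "CZ"), element = "C",
    resname = c("ALA", "ALA", "ARG", "ARG"),
    resid = c(585L, 585L, 426L, 426L), chain = "A",
    stringsAsFactors = FALSE)
  topo <- vw_topology(atoms)
  traj <- static_trajectory(topo, matrix(runif(12, 1, 3), 4L, 3L),
                            c(5, 5, 5), n_frames = 2, spacing_ps = 1000)
  expect_error(distance_series(traj, "585:CD-426:CZ", stride_ns = 1),
               "585")
})

test_that("boxplot statistics agree with a sort-based oracle", {
  s <- boxplot_stats(c(1, 2, 3, 4, 5))
  expect_equal(s$mean, 3)
  expect_equal(s$q1, 2)
  expect_equal(s$q3, 4)
  expect_equal(s$min, 1)
  expect_equal(s$max, 5)
  cc <- boxplot_stats(rep(2.5, 7))
  expect_true(all(unlist(cc[c("mean", "q1", "q3", "min", "max")]) == 2.5))
  set.seed(101)
  for (i in 1:100) {
    x <- stats::rnorm(sample(1:40, 1L))
    got <- boxplot_stats(x)
    expect_equal(got$q1, oracle_quartile(x, 0.25), tolerance = 1e-12)
    expect_equal(got$q3, oracle_quartile(x, 0.75), tolerance = 1e-12)
    expect_equal(got$mean, sum(x) / length(x), tolerance = 1e-12)
    expect_equal(got$min, sort(x)[1L])
  }
  expect_error(boxplot_stats(numeric(0)), "nonempty")
})

test_that("distance distributions normalize, localize modes and pool stably", {
  inward <- generate_distance_pair_system(1.05, 0.02, n_frames = 4000,
                                          seed = 7)
  d_in <- inward$ground_truth$separations
  dist_in <- distance_probability(list(d_in), bin_width = 0.1)
  expect_equal(sum(dist_in$prob), 1)
  mode_bin <- dist_in$mids[which.max(dist_in$prob)]
  expect_gte(mode_bin, 1.0)
  expect_lte(mode_bin, 1.1)

  outward <- generate_distance_pair_system(c(1.1, 1.5), c(0.04, 0.04),
                                           n_frames = 4000, seed = 8)
  d_out <- outward$ground_truth$separations
  dist_out <- distance_probability(list(d_out), bin_width = 0.05)
  support <- range(dist_out$mids[dist_out$prob > 0.01])
  expect_lt(support[1L], 1.2)
  expect_gt(support[2L], 1.4)

  # invariance to replicate concatenation order
  a <- d_in[1:2000]; b <- d_in[2001:4000]
  p1 <- distance_probability(list(a, b), bin_width = 0.05)
  p2 <- distance_probability(list(b, a), bin_width = 0.05)
  expect_equal(p1$prob, p2$prob)
  expect_error(distance_probability(list(a), bin_width = 0), "positive")
})

test_that("salt-bridge detection uses charged heavy atoms and a 0.4 nm cutoff", {
  near <- make_synthetic_transporter("inward", salt_bridge_distance = 0.30)
  far <- make_synthetic_transporter("inward", salt_bridge_distance = 0.80)
  tr_near <- static_trajectory(near$topology, near$frame$xyz,
                               near$frame$box, n_frames = 2)
  tr_far <- static_trajectory(far$topology, far$frame$xyz, far$frame$box,
                              n_frames = 2)
  expect_equal(detect_salt_bridge(tr_near, 426, 585)$fraction, 1)
  expect_equal(detect_salt_bridge(tr_far, 426, 585)$fraction, 0)
  # symmetry in residue order
  expect_equal(detect_salt_bridge(tr_near, 426, 585)$min_distance_nm,
               detect_salt_bridge(tr_near, 585, 426)$min_distance_nm)
  expect_error(detect_salt_bridge(tr_near, 554, 585), "charged")
})

test_that("scheduled bridge openings give the exact dwell fraction", {
  st <- make_synthetic_transporter("inward", salt_bridge_distance = 0.30)
  open <- make_synthetic_transporter("inward", salt_bridge_distance = 0.70)
  nfr <- 20L
  bridged_frames <- c(rep(TRUE, 13L), rep(FALSE, 7L))
  coords <- array(NA_real_, dim = c(st$topology$n_atoms, 3L, nfr))
  for (f in seq_len(nfr)) {
    coords[, , f] <- if (bridged_frames[f]) st$frame$xyz else open$frame$xyz
  }
  traj <- vw_trajectory(st$topology, coords, st$frame$box,
                        (0:(nfr - 1)) * 10)
  res <- detect_salt_bridge(traj, 426, 585)
  expect_equal(res$fraction, 13 / 20)
})

test_that("the valve axial shift is recovered exactly on rigid shifts", {
  st <- make_synthetic_transporter("inward")
  vsel <- select_atoms(st$topology, VALVE_SELECTION)
  expect_equal(valve_axial_shift(st$frame, st$frame, vsel), 0)
  pure <- generate_shifted_pair(st$topology, st$frame, c(0, 0, 0.3))
  expect_equal(valve_axial_shift(pure$frame_a, pure$frame_b, vsel), 0.3,
               tolerance = 1e-12)
  mixed <- generate_shifted_pair(st$topology, st$frame, c(0.1, 0, 0.3))
  expect_equal(valve_axial_shift(mixed$frame_a, mixed$frame_b, vsel), 0.3,
               tolerance = 1e-12)
})

test_that("alignment on the TM core isolates a valve-only shift", {
  st <- make_synthetic_transporter("inward")
  vsel <- select_atoms(st$topology, VALVE_SELECTION)
  core <- select_atoms(st$topology, "resid 400-410 and name CA")
  valve_all <- select_atoms(st$topology, "resid 553-559")
  moved <- generate_shifted_pair(st$topology, st$frame, c(0, 0, 0.3),
                                 selection = valve_all)
  # whole-body nuisance transform on top: translate everything
  nuis <- vw_frame(sweep(moved$frame_b$xyz, 2L, c(0.5, -0.2, 0.4), "+"),
                   moved$frame_b$box)
  got <- valve_axial_shift(moved$frame_a, nuis, vsel,
                           align_selection = core)
  expect_equal(got, 0.3, tolerance = 1e-9)
})

test_that("cross-dimer valve distances distinguish the two states", {
  inw <- make_synthetic_transporter("inward")
  out <- make_synthetic_transporter("outward")
  d_in <- valve_calpha_distances(inw$topology, inw$frame)
  d_out <- valve_calpha_distances(out$topology, out$frame)
  expect_true(all(d_in >= 1.0 & d_in <= 1.1))
  expect_equal(unname(d_out["L554"]), 1.3, tolerance = 1e-9)
  expect_equal(unname(d_out["L555"]), 0.9, tolerance = 1e-9)
  expect_gt(valve_backbone_distance(inw$topology, inw$frame), 0.5)
})

test_that("pair-system parameter recovery stays within 3 standard errors", {
  mu <- 0.95; sdv <- 0.06; n <- 4000L
  sys <- generate_distance_pair_system(mu, sdv, n_frames = n, seed = 13)
  ds <- distance_series(sys$trajectory, "A/554:CA-B/554:CA",
                        stride_ns = 0.01)[[1L]]$distance_nm
  se_mean <- sdv / sqrt(n)
  expect_lt(abs(mean(ds) - mu), 3 * se_mean)
  se_sd <- sdv / sqrt(2 * (n - 1))
  expect_lt(abs(stats::sd(ds) - sdv), 3 * se_sd)
})
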