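scaffold_with_waters <- function(water_xyz_list, box = c(6, 6, 12),
                                 n_frames = length(water_xyz_list),
                                 center = c(3, 3, 6)) {
  n_w <- nrow(water_xyz_list[[1L]])
  scaffold <- valvewatch:::valve_scaffold_atoms()
  waters <- data.frame(name = "OW", element = "O", resname = "SOL",
                       resid = 1000L + seq_len(n_w), chain = "W",
                       stringsAsFactors = FALSE)
  topo <- vw_topology(rbind(scaffold, waters))
  scaf <- valvewatch:::valve_scaffold_xyz(center)
  coords <- array(NA_real_, dim = c(8L + n_w, 3L, n_frames))
  for (f in seq_len(n_frames)) {
    coords[1:8, , f] <- scaf
    coords[8L + seq_len(n_w), , f] <- water_xyz_list[[f]]
  }
  vw_trajectory(topo, coords, box, (seq_len(n_frames) - 1L) * 10)
}

boxes_of <- function(traj) {
  anchor_boxes(get_frame(traj, 1L),
               select_atoms(traj$topology, VALVE_SELECTION))
}

test_that("a single static water fills exactly its voxel at 1/voxel_volume", {
  w <- matrix(c(3.25, 3.25, 6.75), 1L, 3L)
  traj <- scaffold_with_waters(rep(list(w), 100L))
  g <- density_grid(traj, boxes_of(traj), voxel_edge = 0.5)
  expect_equal(sum(g$values > 0), 1L)
  expect_equal(max(g$values), 1 / 0.5^3)
  expect_equal(dim(g$values), c(8L, 8L, 12L))
  expect_error(density_grid(traj, boxes_of(traj), voxel_edge = 7), "exceeds")
  expect_error(density_grid(traj, boxes_of(traj), voxel_edge = 0.7),
               "divide")
})

test_that("density mass equals the time-averaged in-box water count exactly", {
  sys <- generate_barrier_system(barrier_params(n_waters = 120,
                                                n_frames = 60, seed = 8))
  traj <- sys$trajectory
  b <- boxes_of(traj)
  g <- density_grid(traj, b, voxel_edge = 0.2)
  wsel <- select_atoms(traj$topology, "water")
  geom <- valvewatch:::grid_geometry(b, 0.2)
  inbox <- vapply(seq_len(traj$n_frames), function(f) {
    idx <- valvewatch:::voxel_indices(
      selection_xyz(get_frame(traj, f), wsel), b, geom, traj$box[f, ])
    sum(!is.na(idx[, 1L]))
  }, numeric(1))
  expect_equal(sum(g$values) * 0.2^3, mean(inbox), tolerance = 1e-12)
})

test_that("a uniform ideal-gas fixture is flat to within counting noise", {
  set.seed(123)
  n_w <- 1000L; n_f <- 150L
  frames <- lapply(seq_len(n_f), function(f) {
    cbind(runif(n_w, 0, 6), runif(n_w, 0, 6), runif(n_w, 0, 12))
  })
  traj <- scaffold_with_waters(frames)
  g <- density_grid(traj, boxes_of(traj), voxel_edge = 0.5)
  rho <- n_w / (6 * 6 * 12)
  # per voxel: Binomial(n_w * n_f, v/V); compare density to N/V at 3 sigma
  p_vox <- 0.5^3 / (6 * 6 * 12)
  sd_density <- sqrt(n_w * n_f * p_vox * (1 - p_vox)) / (n_f * 0.5^3)
  frac_ok <- mean(abs(g$values - rho) <= 3 * sd_density)
  expect_gte(frac_ok, 0.95)
})

test_that("voxels inside an impermeable slab are empty", {
  sys <- generate_barrier_system(barrier_params(
    n_waters = 150, crossing_probability = 0, barrier_half_thickness = 0.3,
    n_frames = 120, seed = 19))
  g <- density_grid(sys$trajectory, boxes_of(sys$trajectory),
                    voxel_edge = 0.2)
  # slab z in [5.7, 6.3]; grid z starts at 3: voxels 15 and 16 lie fully
  # inside the slab
  expect_equal(max(g$values[, , 15:16]), 0)
})

test_that("displacement grids recover static, ballistic and Brownian motion", {
  w0 <- matrix(c(3.2, 3.2, 6.6), 1L, 3L)
  static <- scaffold_with_waters(rep(list(w0), 30L))
  b <- boxes_of(static)
  g0 <- displacement_grid(static, b, voxel_edge = 0.5, dt_ps = 10)
  expect_equal(max(g0$values, na.rm = TRUE), 0)

  drift <- scaffold_with_waters(lapply(0:29, function(f) {
    w0 + matrix(c(0, 0, 0.05 * f), 1L, 3L)
  }))
  g1 <- displacement_grid(drift, boxes_of(drift), voxel_edge = 0.5,
                          dt_ps = 10)
  expect_equal(mean(g1$values, na.rm = TRUE), 0.05, tolerance = 1e-9)

  # Brownian: mean |dr| over lag dt is the chi(3) mean sigma*2*sqrt(2/pi)
  set.seed(55)
  sig <- 0.04
  n_w <- 300L; n_f <- 80L
  pos <- cbind(runif(n_w, 2, 4), runif(n_w, 2, 4), runif(n_w, 4.5, 7.5))
  frames <- vector("list", n_f)
  frames[[1L]] <- pos
  for (f in 2:n_f) {
    pos <- pos + matrix(rnorm(3 * n_w, 0, sig), ncol = 3L)
    frames[[f]] <- pos
  }
  brown <- scaffold_with_waters(frames)
  g2 <- displacement_grid(brown, boxes_of(brown), voxel_edge = 1,
                          dt_ps = 10)
  chi3_mean <- sig * 2 * sqrt(2) / sqrt(pi)
  expect_lt(abs(mean(g2$values, na.rm = TRUE) - chi3_mean) / chi3_mean,
            0.05)
  expect_error(displacement_grid(static, b, voxel_edge = 0.5, dt_ps = 500),
               "span")
})

test_that("slices pick the right plane and commute with averaging", {
  w <- matrix(c(3.25, 3.25, 6.75), 1L, 3L)
  traj <- scaffold_with_waters(rep(list(w), 10L))
  b <- boxes_of(traj)
  g <- density_grid(traj, b, voxel_edge = 0.5)
  sl <- grid_slice(g, 3L, 6.75)
  expect_equal(sum(sl > 0), 1L)
  expect_error(grid_slice(g, 3L, 20), "outside")
  g2 <- g; g2$values <- g$values * 3
  avg <- average_grids(list(g, g2))
  expect_equal(grid_slice(avg, 3L, 6.75),
               (grid_slice(g, 3L, 6.75) + grid_slice(g2, 3L, 6.75)) / 2)
})

test_that("the sealed-slab density shows an empty band at the valve plane", {
  sys <- generate_barrier_system(barrier_params(
    n_waters = 150, crossing_probability = 0, barrier_half_thickness = 0.3,
    n_frames = 100, seed = 23))
  g <- density_grid(sys$trajectory, boxes_of(sys$trajectory),
                    voxel_edge = 0.2)
  valve_band <- mean(g$values[, , 15:16])
  bulk <- mean(g$values[, , c(1:5, 26:30)])
  expect_equal(valve_band, 0)
  expect_gt(bulk, 0)
})

test_that("grid averaging is idempotent, linear and variance-reducing", {
  sys <- function(s) generate_barrier_system(barrier_params(
    n_waters = 100, n_frames = 40, seed = s))
  t1 <- sys(1)$trajectory
  b <- boxes_of(t1)
  g1 <- density_grid(t1, b, voxel_edge = 0.5)
  expect_equal(average_grids(list(g1, g1))$values, g1$values)
  z <- g1; z$values <- g1$values * 0
  doubled <- g1; doubled$values <- g1$values * 2
  expect_equal(average_grids(list(z, doubled))$values, g1$values)
  g2 <- density_grid(sys(2)$trajectory, b, voxel_edge = 0.5)
  g3 <- density_grid(sys(3)$trajectory, b, voxel_edge = 0.5)
  avg <- average_grids(list(g1, g2, g3))
  pooled_sd <- stats::sd(c(g1$values, g2$values, g3$values))
  expect_lt(stats::sd(avg$values), pooled_sd / sqrt(2))
  bad <- g2; bad$voxel_edge <- 0.25
  expect_error(average_grids(list(g1, bad)), "mismatch")
})

test_that("density grids survive the OpenDX round trip metadata-wise", {
  sys <- generate_barrier_system(barrier_params(n_waters = 30, n_frames = 10,
                                                seed = 2))
  g <- density_grid(sys$trajectory, boxes_of(sys$trajectory),
                    voxel_edge = 0.5)
  path <- tempfile(fileext = ".dx")
  write_dx(g, path)
  lines <- readLines(path)
  expect_true(any(grepl("gridpositions counts 8 8 12", lines)))
  items <- as.integer(sub(".*items ([0-9]+).*", "\\1",
                          grep("items", lines, value = TRUE)))
  expect_equal(items, length(g$values))
})
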