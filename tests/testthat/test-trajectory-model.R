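test_that("PDB structures load with Angstrom-to-nm conversion and box", {
  path <- write_tiny_pdb(tempfile(fileext = ".pdb"))
  st <- load_structure(path)
  expect_equal(st$topology$n_atoms, 3L)
  expect_equal(st$frame$xyz[1L, ], c(1, 0, 0))
  expect_equal(st$frame$xyz[3L, ], c(0, 0, 1))
  expect_equal(st$frame$box, c(10, 10, 10))
  expect_equal(st$topology$atoms$index, 0:2)
})

test_that("degenerate structure files are rejected", {
  empty <- tempfile(fileext = ".pdb")
  file.create(empty)
  expect_error(load_structure(empty), "empty")
  expect_error(load_structure(tempfile(fileext = ".pdb")), "not found")
  garbled <- tempfile(fileext = ".gro")
  writeLines(c("title", "not_a_number", "junk"), garbled)
  expect_error(load_structure(garbled), "malformed|GRO")
})

test_that("GRO trajectory round-trip preserves frames, spacing and positions", {
  sys <- generate_barrier_system(barrier_params(n_waters = 20, n_frames = 11,
                                                seed = 5))
  traj <- sys$trajectory
  expect_equal(traj$n_frames, 11L)
  expect_equal(traj$spacing, 10)
  path <- tempfile(fileext = ".gro")
  write_trajectory(traj, path)
  back <- load_trajectory(traj$topology, path)
  expect_equal(back$n_frames, traj$n_frames)
  expect_equal(back$spacing, traj$spacing)
  expect_equal(back$times, traj$times)
  # GRO stores 3 decimals in nm
  expect_lt(max(abs(back$coords - traj$coords)), 5.1e-4)
  expect_equal(back$box, traj$box, tolerance = 1e-4)
})

test_that("DCD round-trip through the independent bio3d reader agrees", {
  sys <- generate_barrier_system(barrier_params(n_waters = 15, n_frames = 7,
                                                seed = 6))
  traj <- sys$trajectory
  path <- tempfile(fileext = ".dcd")
  write_trajectory(traj, path, format = "dcd")
  back <- load_trajectory(traj$topology, path, spacing_ps = 10)
  expect_equal(back$n_frames, 7L)
  expect_lt(max(abs(back$coords - traj$coords)), 1e-5) # float32 precision
  expect_equal(back$box, traj$box, tolerance = 1e-5,
               ignore_attr = TRUE)
})

test_that("non-monotonic frame times are rejected", {
  sys <- generate_barrier_system(barrier_params(n_waters = 5, n_frames = 3,
                                                seed = 1))
  path <- tempfile(fileext = ".gro")
  write_trajectory(sys$trajectory, path)
  lines <- readLines(path)
  # swap the time stamps of frames 2 and 3
  heads <- grep("t=", lines)
  tmp <- lines[heads[2L]]
  lines[heads[2L]] <- lines[heads[3L]]
  lines[heads[3L]] <- tmp
  writeLines(lines, path)
  expect_error(load_trajectory(sys$trajectory$topology, path),
               "strictly increasing")
  expect_error(load_trajectory(sys$trajectory$topology, path,
                               format = "xtc"), "not supported")
})

test_that("atom count mismatches between topology and trajectory error", {
  sys <- generate_barrier_system(barrier_params(n_waters = 5, n_frames = 3,
                                                seed = 1))
  path <- tempfile(fileext = ".gro")
  write_trajectory(sys$trajectory, path)
  expect_error(load_trajectory(tiny_topology(), path), "atoms")
})

test_that("minimum-image distances obey wrap, symmetry and the triangle inequality", {
  expect_equal(minimum_image_distance(c(0, 0, 0), c(0, 0, 0.9),
                                      c(10, 10, 10)), 0.9)
  expect_equal(minimum_image_distance(c(0.05, 0, 0), c(0.95, 0, 0),
                                      c(1, 1, 1)), 0.10)
  expect_error(minimum_image_distance(c(0, 0, 0), c(1, 1, 1), c(0, 1, 1)),
               "positive")
  set.seed(42)
  box <- c(4, 5, 6)
  for (rep in 1:25) {
    pts <- matrix(stats::runif(9, 0, 0.8), 3L, 3L)  # pairwise < half box
    dab <- minimum_image_distance(pts[1L, ], pts[2L, ], box)
    dba <- minimum_image_distance(pts[2L, ], pts[1L, ], box)
    dbc <- minimum_image_distance(pts[2L, ], pts[3L, ], box)
    dac <- minimum_image_distance(pts[1L, ], pts[3L, ], box)
    expect_equal(dab, dba)
    expect_lte(dac, dab + dbc + 1e-12)
  }
  # each wrapped component is at most half the box length
  a <- matrix(stats::runif(30, 0, 4), ncol = 3L)
  b <- matrix(stats::runif(30, 0, 4), ncol = 3L)
  d <- minimum_image_displacement(a, b, c(4, 4, 4))
  expect_true(all(abs(d) <= 2 + 1e-12))
})

test_that("equilibration trimming keeps the production window", {
  # 175-ns-equivalent trajectory at 1-ns spacing
  topo <- tiny_topology()
  nfr <- 176L
  coords <- array(stats::runif(3 * 3 * nfr, 1, 9), dim = c(3L, 3L, nfr))
  traj <- vw_trajectory(topo, coords, c(10, 10, 10), (0:175) * 1000)
  trimmed <- trim_equilibration(traj, 25)
  expect_equal(time_span_ps(trimmed), 150000)  # 150 ns retained
  expect_identical(trim_equilibration(traj, 0)$coords, traj$coords)
  # 525-ns-equivalent wild-type-like run keeps 500 ns
  nfr_wt <- 526L
  coords_wt <- array(stats::runif(3 * 3 * nfr_wt, 1, 9),
                     dim = c(3L, 3L, nfr_wt))
  traj_wt <- vw_trajectory(topo, coords_wt, c(10, 10, 10), (0:525) * 1000)
  expect_equal(time_span_ps(trim_equilibration(traj_wt, 25)), 500000)
  expect_error(trim_equilibration(traj, 200), "beyond")
})

test_that("triclinic boxes are rejected everywhere", {
  m <- diag(c(5, 5, 5)); m[1, 2] <- 0.5
  expect_error(vw_frame(matrix(0, 1, 3), as.numeric(m)), "triclinic")
})

test_that("selection grammar resolves the standard analyses' selections", {
  st <- make_synthetic_transporter("inward")
  topo <- st$topology
  s1 <- select_atoms(topo, "chain A and resid 554 and name CA")
  expect_length(s1$indices, 1L)
  s2 <- select_atoms(topo, "resid 553-559")
  picked <- topo$atoms[s2$indices, ]
  expect_equal(nrow(unique(picked[, c("chain", "resid")])), 14L)
  expect_warning(select_atoms(topo, "name ZZ9", empty_ok = TRUE),
                 "no atoms")
  expect_error(select_atoms(topo, "name ZZ9"), "no atoms")
  expect_error(select_atoms(topo, "frobnicate CA"), "unknown")
  # boolean combinations and stability
  s3 <- select_atoms(topo, "(resid 554 or resid 555) and name CA and not chain B")
  expect_equal(length(s3$indices), 2L)
  s3b <- select_atoms(topo, "(resid 554 or resid 555) and name CA and not chain B")
  expect_identical(s3$indices, s3b$indices)
  expect_false(any(duplicated(s3$indices)))
})
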