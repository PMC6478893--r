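cfg <- analysis_config()

make_spinning_traj <- function(nf = 12, theta_per_frame = pi / 6) {
  # protein triangle plus one ligand head, rotated about the box centre z
  base <- rbind(c(55, 50, 30), c(50, 56, 30), c(45, 47, 32),
                c(70, 50, 30))
  centre <- c(50, 50, 0)
  frames <- lapply(seq_len(nf) - 1L, function(f) {
    th <- f * theta_per_frame
    p <- sweep(base, 2, centre)
    p[, 1:2] <- p[, 1:2] %*% t(matrix(c(cos(th), sin(th),
                                        -sin(th), cos(th)), 2, 2))
    sweep(p, 2, centre, "+")
  })
  traj_from_frames(frames, box = c(100, 100, 60),
                   particle_names = c("BB", "BB", "BB", "AM1"),
                   residue_ids = c(1L, 2L, 3L, 101L),
                   residue_names = c("ALA", "ALA", "ALA", "CER"))
}

test_that("in-plane alignment undoes per-frame z rotations exactly", {
  traj <- make_spinning_traj()
  al <- align_protein_xy(traj)
  prot <- which(traj$topology$role == "protein")
  for (f in seq_len(n_frames(traj))) {
    expect_lt(max(abs(al$coords[f, prot, ] - al$coords[1, prot, ])), 1e-6)
  }
  # z coordinates are never touched
  expect_equal(al$coords[, , 3], traj$coords[, , 3])
})

test_that("alignment is idempotent and leaves aligned trajectories unchanged", {
  traj <- make_spinning_traj()
  al1 <- align_protein_xy(traj)
  al2 <- align_protein_xy(al1)
  expect_lt(max(abs(al2$coords - al1$coords)), 1e-6)
})

test_that("pure z drift leaves xy untouched and z unchanged by alignment", {
  base <- rbind(c(55, 50, 30), c(50, 56, 30), c(45, 47, 32))
  frames <- lapply(0:5, function(f) sweep(base, 2, c(0, 0, f * 0.5), "+"))
  traj <- traj_from_frames(frames, box = c(100, 100, 60))
  al <- align_protein_xy(traj)
  expect_equal(al$coords[, , 1:2], traj$coords[, , 1:2], tolerance = 1e-12)
  expect_equal(al$coords[, , 3], traj$coords[, , 3])
})

test_that("alignment needs at least three protein particles", {
  frames <- list(matrix(runif(6, 0, 50), 2, 3))
  traj <- traj_from_frames(frames, box = c(50, 50, 50),
                           particle_names = c("BB", "BB"))
  expect_error(align_protein_xy(traj), "degenerate")
})

test_that("occupancy volumes count distinct occupied cells per frame", {
  # one stationary head inside one cell
  traj <- mixed_traj(rep(list(c(18.2, 10.4, 10.9)), 20))
  g <- occupancy_volume(traj, "ceramide", cfg)
  expect_equal(max(g$values), 1.0)
  expect_equal(grid_total(g), 1.0)

  # 50/50 between two cells
  frames <- c(rep(list(c(18, 10, 10)), 50), rep(list(c(33, 10, 10)), 50))
  g2 <- occupancy_volume(mixed_traj(frames), "ceramide", cfg)
  expect_equal(sort(g2$values[g2$values > 0]), c(0.5, 0.5))

  # three stationary heads in three distinct cells
  three <- rbind(c(7, 7, 7), c(22, 22, 22), c(41, 41, 41))
  g3 <- occupancy_volume(mixed_traj(rep(list(three), 10)), "ceramide", cfg)
  expect_equal(grid_total(g3), 3.0)
  expect_true(all(g3$values >= 0 & g3$values <= 1))

  # two heads sharing a cell count once
  two <- rbind(c(7, 7, 7), c(8, 8, 8))
  g4 <- occupancy_volume(mixed_traj(rep(list(two), 10)), "ceramide", cfg)
  expect_equal(grid_total(g4), 1.0)
})

test_that("grid totals match a brute-force cell count on random fixtures", {
  set.seed(77)
  for (rep_i in 1:5) {
    nf <- 20
    frames <- lapply(seq_len(nf), function(f)
      matrix(runif(9, 0, 49.9), 3, 3))
    traj <- mixed_traj(frames)
    g <- occupancy_volume(traj, "ceramide", cfg)
    # oracle: per frame, count distinct cells holding a head
    heads <- which(traj$topology$is_head)
    tot <- 0
    for (f in seq_len(nf)) {
      p <- matrix(traj$coords[f, heads, ], ncol = 3)
      cells <- unique(apply(p, 1, function(v)
        paste(floor(v / 5), collapse = ",")))
      tot <- tot + length(cells)
    }
    expect_equal(grid_total(g), tot / nf, tolerance = 1e-12)
  }
})

test_that("iso thresholds follow the configured per-species levels", {
  expect_equal(iso_threshold("ceramide", cfg), 0.10)
  expect_equal(iso_threshold("cholesterol", cfg), 0.20)
  expect_equal(iso_threshold("ceramide", cfg, 16, 16, compensate = TRUE),
               0.10)
  expect_equal(iso_threshold("ceramide", cfg, 32, 16, compensate = TRUE),
               0.20)
  expect_error(iso_threshold("ceramide", cfg, 0, 16, compensate = TRUE),
               "> 0")
})

test_that("site-cell occupancy mass converges to the stationary bound fraction", {
  spec <- kinetics_spec(k_on = 400, k_off = 400, n_frames = 1e4, seed = 29)
  res <- generate_synthetic_trajectory(spec)
  g <- occupancy_volume(res$trajectory, "ceramide", cfg)
  # cells within 12 A of site residue 74 hold the bound head and nothing
  # else; the occupancy mass there is exactly the realized bound fraction
  topo <- res$trajectory$topology
  p74 <- res$trajectory$coords[1, topo$role == "protein" &
                                 topo$residue_id == 74L, ]
  centers <- expand.grid(x = seq_len(g$shape[1]) - 0.5,
                         y = seq_len(g$shape[2]) - 0.5,
                         z = seq_len(g$shape[3]) - 0.5) * g$spacing
  near <- sqrt((centers$x - p74[1])^2 + (centers$y - p74[2])^2 +
                 (centers$z - p74[3])^2) <= 12
  site_mass <- sum(as.numeric(g$values)[near])
  expect_equal(site_mass, mean(res$site_series), tolerance = 1e-12)
  expect_equal(site_mass, 0.5, tolerance = 0.03)
})

test_that("occupancy grids round-trip through OpenDX", {
  traj <- mixed_traj(rep(list(rbind(c(7, 7, 7), c(22, 22, 22))), 8))
  g <- occupancy_volume(traj, "ceramide", cfg)
  path <- tempfile(fileext = ".dx")
  export_grid(g, path)
  back <- read_dx(path)
  expect_equal(back$shape, g$shape)
  expect_equal(back$origin, g$origin)
  expect_equal(back$spacing, g$spacing)
  expect_lt(max(abs(back$values - g$values)), 1e-6)
  expect_error(export_grid(list(values = numeric(0)), tempfile()), "empty")
})
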