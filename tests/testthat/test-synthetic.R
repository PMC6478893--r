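test_that("kinetics specifications enforce their validity bounds", {
  expect_error(kinetics_spec(k_on = -1), "non-negative")
  expect_error(kinetics_spec(k_on = 0, k_off = 0), "not both zero")
  expect_error(kinetics_spec(k_off = 1000), "below 0.5")
  expect_error(kinetics_spec(n_frames = 5), ">= 10")
})

test_that("analytic ground truth follows the telegraph stationary law", {
  s <- ground_truth_summary(kinetics_spec(k_on = 2, k_off = 2))
  expect_equal(s$stationary_bound_fraction, 0.5)
  expect_equal(ground_truth_summary(kinetics_spec(k_on = 1, k_off = 1)
               )$analytic_time_weighted_mean_us, 2)
  # bound fraction depends only on the rate ratio
  a <- ground_truth_summary(kinetics_spec(k_on = 1, k_off = 3))
  b <- ground_truth_summary(kinetics_spec(k_on = 2, k_off = 6))
  expect_equal(a$stationary_bound_fraction, b$stationary_bound_fraction)
})

test_that("telegraph limits and determinism behave as scheduled", {
  z <- generate_telegraph_series(kinetics_spec(k_on = 0, k_off = 1,
                                               n_frames = 50, n_ligands = 2,
                                               seed = 9))
  expect_true(all(z$series == 0L))
  expect_equal(nrow(z$ground_truth), 0L)

  f <- generate_telegraph_series(kinetics_spec(k_on = 1, k_off = 0,
                                               n_frames = 50, n_ligands = 1,
                                               seed = 9))
  expect_true(all(f$series == 1L))
  expect_equal(nrow(f$ground_truth), 1L)
  expect_true(f$ground_truth$end_censored)

  s1 <- generate_telegraph_series(kinetics_spec(seed = 4, n_frames = 500))
  s2 <- generate_telegraph_series(kinetics_spec(seed = 4, n_frames = 500))
  expect_identical(s1$series, s2$series)
})

test_that("empirical transition frequencies match the scheduled probabilities", {
  # plain chain (min_run = 1) so per-frame hazards are directly observable
  spec <- kinetics_spec(k_on = 100, k_off = 200, n_frames = 1e5,
                        n_ligands = 1, seed = 13, min_run = 1)
  s <- generate_telegraph_series(spec)$series[, 1]
  dt <- 600e-6
  from0 <- which(s[-length(s)] == 0L)
  from1 <- which(s[-length(s)] == 1L)
  p_bind_hat <- mean(s[from0 + 1L] == 1L)
  p_unbind_hat <- mean(s[from1 + 1L] == 0L)
  se0 <- sqrt(spec$k_on * dt * (1 - spec$k_on * dt) / length(from0))
  se1 <- sqrt(spec$k_off * dt * (1 - spec$k_off * dt) / length(from1))
  expect_lt(abs(p_bind_hat - spec$k_on * dt), 3 * se0)
  expect_lt(abs(p_unbind_hat - spec$k_off * dt), 3 * se1)
})

test_that("ground-truth runs are consistent with the emitted series", {
  gen <- generate_telegraph_series(kinetics_spec(k_on = 40, k_off = 40,
                                                 n_frames = 2000,
                                                 n_ligands = 4, seed = 6))
  for (l in 1:4) {
    gt <- gen$ground_truth[gen$ground_truth$ligand_id == l, ]
    rebuilt <- integer(2000)
    for (i in seq_len(nrow(gt))) {
      rebuilt[gt$start_frame[i] + seq_len(gt$n_frames[i])] <- 1L
    }
    expect_identical(rebuilt, gen$series[, l])
    expect_true(all(gt$n_frames >= 3L))  # smoothing-neutral construction
  }
})

test_that("synthetic trajectories honour the geometric ground-truth invariant", {
  spec <- kinetics_spec(k_on = 200, k_off = 200, n_frames = 120,
                        n_ligands = 5, seed = 21)
  res <- generate_synthetic_trajectory(spec)
  expect_true(isTRUE(validate_trajectory_geometry(res)))
})

test_that("the event pipeline recovers scheduled events exactly", {
  spec <- kinetics_spec(k_on = 150, k_off = 150, n_frames = 600,
                        n_ligands = 6, seed = 31)
  res <- generate_synthetic_trajectory(spec)
  traj <- res$trajectory
  cfg <- analysis_config()
  site <- site_definition()
  ligs <- sort(unique(traj$topology$molecule_id[traj$topology$role ==
                                                  "ligand"]))
  rec <- do.call(rbind, lapply(ligs, function(l) {
    s <- majority_smooth(raw_contact_series(traj, site, l),
                         cfg$smoothing_window, cfg$smoothing_min_true)
    extract_events(s, traj$frame_interval, ligand_id = l)$events
  }))
  gt <- res$ground_truth[!res$ground_truth$end_censored, ]
  gt <- gt[order(gt$ligand_id, gt$start_frame), ]
  rec <- rec[order(rec$ligand_id, rec$start_frame), ]
  expect_equal(nrow(rec), nrow(gt))
  expect_equal(rec$ligand_id, gt$ligand_id)
  expect_equal(rec$start_frame, gt$start_frame)
  expect_equal(rec$n_frames, gt$n_frames)
})

test_that("written fixture files load back with matching frame counts", {
  spec <- kinetics_spec(k_on = 100, k_off = 100, n_frames = 100,
                        n_ligands = 3, seed = 17)
  dir <- tempfile("fix")
  res <- generate_synthetic_trajectory(spec, dir = dir)
  expect_no_warning(traj <- load_trajectory(res$files$topology,
                                            res$files$trajectory))
  expect_equal(n_frames(traj), 100L)
  expect_equal(n_particles(traj), n_particles(res$trajectory))
  gt <- read.delim(res$files$ground_truth)
  expect_equal(nrow(gt), nrow(res$ground_truth))
  echo <- yaml::read_yaml(res$files$spec)
  expect_equal(echo$seed, 17L)
  expect_equal(echo$n_frames, 100L)
})

test_that("site-residue occupancy converges to the stationary bound fraction", {
  # fast symmetric switching decorrelates the chain well within the run
  spec <- kinetics_spec(k_on = 400, k_off = 400, n_frames = 1e4, seed = 23)
  res <- generate_synthetic_trajectory(spec)
  cm <- residue_contact_occupancy(res$trajectory, analysis_config(),
                                  "ceramide")
  # residue 74 sits at the site anchor, always within the contact cutoff
  # of a bound head
  occ <- cm$occupancy[cm$residue_id == 74]
  expect_equal(occ, 0.5, tolerance = 0.02)
  expect_equal(occ, mean(res$site_series), tolerance = 1e-12)
})
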