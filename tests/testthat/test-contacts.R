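cfg <- analysis_config()

test_that("always-bound and never-bound residues get occupancy 1 and 0", {
  # ligand head fixed 3 A from residue 3 (at x=15), far from the rest
  head <- c(18, 10, 10)
  traj <- mixed_traj(rep(list(head), 5))
  cm <- residue_contact_occupancy(traj, cfg, "ceramide")
  expect_equal(cm$occupancy[cm$residue_id == 3], 1.0)
  far <- abs(c(5, 10, 15, 20, 25) - 18) > 10
  expect_equal(cm$occupancy[far], rep(0, sum(far)))
  expect_equal(attr(cm, "n_frames"), 5L)
})

test_that("occupancy counts in-contact frames and unions over molecules", {
  near <- c(18, 10, 10); far <- c(40, 40, 25)
  frames <- c(rep(list(near), 3), rep(list(far), 7))
  cm <- residue_contact_occupancy(mixed_traj(frames), cfg, "ceramide")
  expect_equal(cm$occupancy[cm$residue_id == 3], 0.3)

  # two ligands alternate at the residue on complementary frames -> union 1
  frames2 <- lapply(1:10, function(f) {
    if (f %% 2) rbind(near, far) else rbind(far, near)
  })
  cm2 <- residue_contact_occupancy(mixed_traj(frames2), cfg, "ceramide")
  expect_equal(cm2$occupancy[cm2$residue_id == 3], 1.0)
})

test_that("occupancy matches the brute-force oracle on random small systems", {
  set.seed(101)
  for (rep_i in 1:8) {
    nf <- sample(5:50, 1)
    nlig <- sample(1:3, 1)
    frames <- lapply(seq_len(nf), function(f)
      matrix(runif(nlig * 3, 0, 50), nlig, 3))
    traj <- mixed_traj(frames)
    cm <- residue_contact_occupancy(traj, cfg, "ceramide")
    oracle <- brute_occupancy(traj, cfg$contact_cutoff, "ceramide")
    expect_identical(cm$occupancy, unname(oracle))
  }
})

test_that("occupancy is monotone in the cutoff and invariant to rigid motion and frame order", {
  set.seed(55)
  frames <- lapply(1:30, function(f) matrix(runif(6, 0, 50), 2, 3))
  traj <- mixed_traj(frames)
  occ7 <- residue_contact_occupancy(traj, cfg, "ceramide")$occupancy
  occ5 <- residue_contact_occupancy(
    traj, analysis_config(contact_cutoff = 5), "ceramide")$occupancy
  occ9 <- residue_contact_occupancy(
    traj, analysis_config(contact_cutoff = 9), "ceramide")$occupancy
  expect_true(all(occ5 <= occ7))
  expect_true(all(occ7 <= occ9))

  # global rigid transform applied uniformly to all frames (box-preserving
  # axis permutation + translation keeps periodic wrapping consistent)
  tr2 <- traj
  tr2$coords <- tr2$coords[, , c(2, 3, 1), drop = FALSE]
  tr2$coords <- sweep(tr2$coords, 3, c(3, -7, 11), "+")
  occ_rigid <- residue_contact_occupancy(tr2, cfg, "ceramide")$occupancy
  expect_equal(occ_rigid, occ7, tolerance = 1e-12)

  perm <- sample(30)
  tr3 <- traj
  tr3$coords <- tr3$coords[perm, , , drop = FALSE]
  tr3$box <- tr3$box[perm, , drop = FALSE]
  occ_perm <- residue_contact_occupancy(tr3, cfg, "ceramide")$occupancy
  expect_identical(occ_perm, occ7)
})

test_that("binding-site calls use a strict threshold", {
  cm <- data.frame(residue_id = c(57L, 58L, 59L, 60L),
                   residue_name = "ALA", species = "ceramide",
                   occupancy = c(0.10, 0.16, 0.40, 0.15))
  class(cm) <- c("contact_map", "data.frame")
  expect_equal(call_binding_site(cm, cfg), c(58L, 59L))
  cm$occupancy <- rep(0, 4)
  expect_equal(call_binding_site(cm, cfg), integer(0))
  expect_error(call_binding_site(cm[0, ], cfg), "empty")
})

test_that("contact tables round-trip through TSV", {
  traj <- mixed_traj(rep(list(c(18, 10, 10)), 4))
  cm <- residue_contact_occupancy(traj, cfg, "ceramide")
  path <- tempfile(fileext = ".tsv")
  write_contact_table(cm, path)
  back <- read_contact_table(path)
  expect_equal(nrow(back), nrow(cm))
  expect_equal(back$occupancy, round(cm$occupancy, 6))
  empty <- cm[0, ]
  class(empty) <- c("contact_map", "data.frame")
  expect_error(write_contact_table(empty, path), "empty")
})

test_that("unknown species and proteinless systems are rejected", {
  traj <- mixed_traj(rep(list(c(18, 10, 10)), 2))
  expect_error(residue_contact_occupancy(traj, cfg, "cardiolipin"),
               "head particles")
})
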