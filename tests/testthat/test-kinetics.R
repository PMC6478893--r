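test_that("site contact requires the configured number of groups in range", {
  # protein: three groups of one residue each on a small triangle
  prot <- rbind(c(10, 10, 10), c(20, 10, 10), c(10, 20, 10))
  mk <- function(head) {
    traj_from_frames(
      list(rbind(prot, head)), box = c(60, 60, 60),
      particle_names = c("BB", "BB", "BB", "AM1"),
      residue_ids = c(58L, 73L, 81L, 101L),
      residue_names = c("GLU", "GLU", "GLU", "CER"))
  }
  site <- site_definition(list(58L, 73L, 81L), event_cutoff = 8,
                          min_groups = 2L)
  expect_true(raw_contact_series(mk(c(15, 10, 10)), site, 1))   # groups 1+2
  expect_false(raw_contact_series(mk(c(10, 27, 10)), site, 1))  # group 3 only
  expect_true(raw_contact_series(mk(c(14, 14, 10)), site, 1))   # all three
  expect_error(raw_contact_series(mk(c(15, 10, 10)),
                                  site_definition(list(1L, 2L, 3L)), 1),
               "no residues")
})

test_that("majority smoothing votes over an edge-replicated window", {
  expect_equal(majority_smooth(c(1, 1, 1, 1, 1)), rep(TRUE, 5))
  expect_equal(majority_smooth(c(0, 0, 0, 0, 0)), rep(FALSE, 5))
  expect_equal(majority_smooth(c(0, 0, 1, 0, 0)), rep(FALSE, 5))
  expect_equal(majority_smooth(c(1, 1, 0, 1, 1)), rep(TRUE, 5))
  expect_error(majority_smooth(c(0, 1), window = 4), "odd")
  expect_error(majority_smooth(c(0, 1), window = 3, min_true = 4), "min_true")
})

test_that("smoothing matches the brute-force vote exhaustively up to length 12", {
  for (len in 1:12) {
    m <- all_binary_series(len)
    for (i in seq_len(nrow(m))) {
      s <- m[i, ]
      expect_identical(majority_smooth(s), brute_vote(s))
    }
  }
})

test_that("smoothing removes short features and fills short gaps in constant series", {
  # isolated features of <= window - min_true frames vanish; same for gaps
  for (flen in 1:2) {
    s <- c(rep(0, 6), rep(1, flen), rep(0, 6))
    expect_false(any(majority_smooth(s)))
    g <- c(rep(1, 6), rep(0, flen), rep(1, 6))
    expect_true(all(majority_smooth(g)))
  }
  # 3-frame features survive
  s3 <- c(rep(0, 6), rep(1, 3), rep(0, 6))
  expect_equal(sum(majority_smooth(s3)), 3)
})

test_that("event extraction censors runs touching the final frame", {
  ev <- extract_events(c(0, 1, 1, 1, 0, 1, 1), 600)
  expect_equal(nrow(ev$events), 1L)
  expect_equal(ev$events$duration, 1800)
  expect_equal(ev$events$start_frame, 1L)
  expect_equal(ev$n_discarded_end_censored, 1L)
  expect_equal(ev$total_time, 7 * 600)

  expect_equal(nrow(extract_events(rep(0, 5), 600)$events), 0L)

  allb <- extract_events(c(1, 1, 1), 600)
  expect_equal(nrow(allb$events), 0L)
  expect_equal(allb$n_discarded_end_censored, 1L)

  st <- extract_events(c(1, 1, 0, 1, 0), 600, drop_start_censored = TRUE)
  expect_equal(nrow(st$events), 1L)
  expect_equal(st$n_discarded_start_censored, 1L)
})

test_that("event extraction matches the brute-force scanner on random series", {
  set.seed(202)
  for (i in 1:300) {
    s <- rbinom(sample(1:200, 1), 1, runif(1, 0.1, 0.9))
    ev <- extract_events(s, 600)
    or <- brute_events(s)
    expect_identical(ev$events$start_frame, or$start_frame)
    expect_identical(ev$events$n_frames, or$n_frames)
    expect_identical(ev$n_discarded_end_censored, or$n_censored)
  }
})

test_that("residence histograms are duration-weighted and conserve bound time", {
  ev <- extract_events(c(0, 1, 1, 0, 1, 1, 1, 0, 0, 0), 600)
  h <- residence_time_distribution(ev)
  expect_equal(sum(h$y), 0.5, tolerance = 1e-12)  # (2+3)/10 frames bound

  h0 <- residence_time_distribution(extract_events(rep(0, 10), 600))
  expect_true(all(h0$y == 0))

  # single event falls in exactly one bin and carries all the weight
  ev1 <- extract_events(c(0, rep(1, 4), 0), 600)
  h1 <- residence_time_distribution(ev1)
  expect_equal(sum(h1$y > 0), 1L)
  expect_equal(max(h1$y), 2400 / 3600, tolerance = 1e-12)

  set.seed(303)
  for (i in 1:200) {
    s <- rbinom(sample(10:150, 1), 1, runif(1, 0.2, 0.8))
    ev <- extract_events(s, 600)
    h <- residence_time_distribution(ev)
    expect_equal(sum(h$y), sum(ev$events$duration) / ev$total_time,
                 tolerance = 1e-12)
  }
})

test_that("histogram bins reject events outside their range", {
  ev <- extract_events(c(0, 1, 1, 1, 1, 1, 1, 0), 600)
  expect_error(residence_time_distribution(ev, bins = c(100, 200, 300)),
               "outside the bin range")
  expect_error(residence_time_distribution(ev, total_time = 1000), "longest")
})

test_that("time-weighted mean weights events by their own duration", {
  expect_equal(time_weighted_mean(c(1, 1, 1)), 1)
  expect_equal(time_weighted_mean(c(1, 3)), 2.5)
  expect_equal(time_weighted_mean(5), 5)
  expect_error(time_weighted_mean(numeric(0)), "durations")
})

test_that("per-run normalization then duration-weighted pooling conserves pooled time", {
  set.seed(404)
  bins <- log_bins(600, 200 * 600)
  hs <- list(); tt <- numeric(3)
  bound <- numeric(3)
  for (r in 1:3) {
    s <- rbinom(80 + 40 * r, 1, 0.5)
    ev <- extract_events(s, 600)
    hs[[r]] <- residence_time_distribution(ev, bins = bins)
    tt[r] <- ev$total_time
    bound[r] <- sum(ev$events$duration)
  }
  pooled <- pool_residence_histograms(hs)
  expect_equal(sum(pooled$y), sum(bound) / sum(tt), tolerance = 1e-12)
})

test_that("recovered time-weighted residence matches 2/k_off on long runs", {
  # exponential residence with k_off = 1/us sampled every 600 ps; runs long
  # enough (120 us per ligand) that end-censoring bias is negligible
  hits <- 0L
  for (seed in 1:10) {
    spec <- kinetics_spec(k_on = 1, k_off = 1, n_frames = 2e5,
                          n_ligands = 8, seed = seed)
    gen <- generate_telegraph_series(spec)
    durs_us <- unlist(lapply(seq_len(spec$n_ligands), function(l) {
      extract_events(gen$series[, l], spec$frame_interval)$events$duration
    })) * 1e-6
    bs <- bootstrap_time_weighted_mean(durs_us, n_resamples = 2000,
                                       seed = seed)
    if (bs$ci_low <= 2 && 2 <= bs$ci_high) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})
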