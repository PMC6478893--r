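#!/usr/bin/env Rscript
# Stage 3: per-ligand binding events and residence-time statistics.
#
# Raw 8 A / 2-of-3-group contact series per ligand, 5-frame/3-vote
# majority smoothing, censored event extraction, the duration-weighted
# log-histogram, and the bootstrap CI of the time-weighted mean. The
# recovered events are compared against the generator's schedule.

source("analysis/00_common.R")
dir.create("results", showWarnings = FALSE)

res <- load_study_system()
traj <- res$trajectory
cfg <- analysis_config()
site <- site_definition()

topo <- traj$topology
ligs <- sort(unique(topo$molecule_id[topo$role == "ligand"]))
sets <- lapply(ligs, function(l) {
  s <- raw_contact_series(traj, site, l)
  s <- majority_smooth(s, cfg$smoothing_window, cfg$smoothing_min_true)
  extract_events(s, traj$frame_interval, ligand_id = l)
})
events <- combine_events(sets)
write_event_table(events, "results/binding_events.tsv")

hist <- residence_time_distribution(events)
write_histogram_table(hist, "results/residence_histogram.tsv")

gt <- res$ground_truth[!res$ground_truth$end_censored, ]
exact_match <- nrow(events$events) == nrow(gt) &&
  all(sort(events$events$start_frame) == sort(gt$start_frame))

bs <- bootstrap_time_weighted_mean(events$events$duration / 1e3,
                                   n_resamples = 10000, seed = 1)
stats <- list(
  n_events = nrow(events$events),
  n_end_censored = events$n_discarded_end_censored,
  bound_time_fraction = sum(hist$y),
  time_weighted_mean_ns = bs$point_estimate,
  ci95_ns = c(bs$ci_low, bs$ci_high),
  ground_truth_recovered_exactly = exact_match
)
jsonlite::write_json(stats, "results/residence_stats.json",
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)

cat(sprintf("retained events: %d (+%d end-censored discarded)\n",
            stats$n_events, stats$n_end_censored))
cat(sprintf("pipeline recovered the scheduled events exactly: %s\n",
            exact_match))
cat(sprintf("fraction of system time bound (sum of histogram y): %.3f\n",
            stats$bound_time_fraction))
cat(sprintf("time-weighted mean residence: %.1f ns, 95%% CI [%.1f, %.1f]\n",
            bs$point_estimate, bs$ci_low, bs$ci_high))
cat("wrote results/binding_events.tsv, residence_histogram.tsv, residence_stats.json\n")
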