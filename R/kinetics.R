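#' Raw per-frame site-contact series for one ligand
#'
#' A frame is in-contact when at least `min_groups` of the site's three
#' residue groups each have at least one particle within `event_cutoff`
#' (minimum image) of at least one head-group particle of the ligand. The
#' multi-group criterion deliberately tolerates brief drifts past a single
#' sharp cutoff, which would otherwise fragment long binding events.
#'
#' @param traj A `cg_trajectory`.
#' @param site A [site_definition()].
#' @param ligand Molecule id of the ligand (see the trajectory topology).
#' @param head_names Head particle names to use; defaults to the head beads
#'   recorded in the topology for that molecule.
#' @return Logical vector, one element per frame.
#' @export
raw_contact_series <- function(traj, site, ligand, head_names = NULL) {
  topo <- traj$topology
  lig <- which(topo$molecule_id == ligand & topo$role == "ligand")
  if (!length(lig)) stop("no ligand with molecule id ", ligand, call. = FALSE)
  heads <- if (is.null(head_names)) lig[topo$is_head[lig]] else
    lig[topo$particle_name[lig] %in% head_names]
  if (!length(heads)) {
    stop("ligand ", ligand, " has no head particles", call. = FALSE)
  }
  nf <- n_frames(traj)
  cut2 <- site$event_cutoff^2
  prot <- which(topo$role == "protein")
  n_in <- matrix(FALSE, nf, 3L)
  for (g in 1:3) {
    gp <- prot[topo$residue_id[prot] %in% site$groups[[g]]]
    if (!length(gp)) {
      stop("site group ", g, " maps to no residues in the topology",
           call. = FALSE)
    }
    hit <- rep(FALSE, nf)
    for (h in heads) {
      a <- traj$coords[, h, , drop = FALSE]
      dim(a) <- c(nf, 3L)
      d2 <- min_image_sq(a, traj$coords[, gp, , drop = FALSE], traj$box)
      hit <- hit | (rowSums(d2 <= cut2) > 0L)
    }
    n_in[, g] <- hit
  }
  rowSums(n_in) >= site$min_groups
}

#' Majority-vote smoothing of a binary contact series
#'
#' Filters spuriously brief contacts and spuriously brief losses of
#' contact: each output frame is set in-contact when at least `min_true` of
#' the `window` frames centred on it are in-contact, otherwise
#' not-in-contact. The series is padded by edge replication
#' (`(window-1)/2` frames each side) so both ends are treated symmetrically
#' and constant series pass through unchanged.
#'
#' @param series Logical or 0/1 vector.
#' @param window Odd window width in frames (default 5).
#' @param min_true Votes needed for in-contact (default 3).
#' @return Logical vector of the same length.
#' @export
majority_smooth <- function(series, window = 5L, min_true = 3L) {
  window <- as.integer(window); min_true <- as.integer(min_true)
  if (window %% 2L == 0L) stop("smoothing window must be odd", call. = FALSE)
  if (min_true > window) stop("min_true must be <= window", call. = FALSE)
  n <- length(series)
  if (!n) stop("empty series", call. = FALSE)
  s <- as.integer(as.logical(series))
  half <- (window - 1L) %/% 2L
  padded <- c(rep(s[1], half), s, rep(s[n], half))
  cs <- c(0L, cumsum(padded))
  votes <- cs[(window + 1L):(n + window)] - cs[1:n]
  votes >= min_true
}

#' Extract binding events from a smoothed contact series
#'
#' Maximal runs of in-contact frames become events; an event's duration is
#' its frame count times the frame interval (a 1-frame event lasts one
#' interval). A run that is still in contact at the final frame has an
#' unknown true duration and is disregarded, counted in
#' `n_discarded_end_censored`. Events in contact at frame 0 (whose true
#' start predates the run) are kept by default, matching the published
#' censoring rule; set `drop_start_censored = TRUE` to discard them too
#' when studying that bias.
#'
#' @param series Logical or 0/1 vector (after [majority_smooth()] for
#'   binding-duration analysis).
#' @param frame_interval Frame spacing (time units of your choice; ps for
#'   native trajectories).
#' @param ligand_id Identifier recorded in the event table.
#' @param drop_start_censored Also discard an event in contact at frame 0.
#' @return A `binding_events` object: list with `events` (data frame:
#'   `ligand_id`, `start_frame` 0-based, `n_frames`, `duration`),
#'   `n_discarded_end_censored`, `n_discarded_start_censored`,
#'   `total_time`, `frame_interval`.
#' @export
extract_events <- function(series, frame_interval, ligand_id = 0L,
                           drop_start_censored = FALSE) {
  if (!length(series)) stop("empty series", call. = FALSE)
  if (frame_interval <= 0) stop("frame_interval must be > 0", call. = FALSE)
  s <- as.logical(series)
  r <- rle(s)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  bound <- which(r$values)
  end_cens <- bound[ends[bound] == length(s)]
  start_cens <- if (drop_start_censored) bound[starts[bound] == 1L] else
    integer()
  keep <- setdiff(bound, union(end_cens, start_cens))
  ev <- data.frame(
    ligand_id = rep(ligand_id, length(keep)),
    start_frame = starts[keep] - 1L,
    n_frames = r$lengths[keep],
    duration = r$lengths[keep] * frame_interval
  )
  structure(list(
    events = ev,
    n_discarded_end_censored = length(end_cens),
    n_discarded_start_censored = length(start_cens),
    total_time = length(s) * frame_interval,
    frame_interval = frame_interval
  ), class = "binding_events")
}

#' Merge per-ligand event sets from one trajectory
#'
#' Concatenates the event tables and sums the censoring counts. The total
#' time stays that of the single trajectory (events of different ligands
#' share the same clock), matching the convention that summed histogram
#' fractions read as "fraction of total system time bound".
#'
#' @param ... `binding_events` objects, or a single list of them.
#' @return A combined `binding_events`.
#' @export
combine_events <- function(...) {
  sets <- list(...)
  if (length(sets) == 1L && !inherits(sets[[1]], "binding_events")) {
    sets <- sets[[1]]
  }
  stopifnot(length(sets) > 0L)
  ti <- vapply(sets, function(s) s$total_time, 0)
  if (length(unique(ti)) != 1L) {
    stop("event sets cover different total times; pool histograms instead",
         call. = FALSE)
  }
  structure(list(
    events = do.call(rbind, lapply(sets, function(s) s$events)),
    n_discarded_end_censored =
      sum(vapply(sets, function(s) s$n_discarded_end_censored, 0L)),
    n_discarded_start_censored =
      sum(vapply(sets, function(s) s$n_discarded_start_censored, 0L)),
    total_time = ti[1],
    frame_interval = sets[[1]]$frame_interval
  ), class = "binding_events")
}

#' Logarithmically spaced histogram bin edges
#'
#' @param lo,hi Positive range limits (lo < hi).
#' @param per_decade Bins per factor of 10 (default 8).
#' @return Numeric vector of strictly increasing edges covering `[lo, hi]`.
#' @export
log_bins <- function(lo, hi, per_decade = 8) {
  stopifnot(lo > 0, hi > lo)
  k <- ceiling(per_decade * log10(hi / lo))
  edges <- lo * 10^(seq(0, k) / per_decade)
  edges[length(edges)] <- max(edges[length(edges)], hi)
  edges
}

#' Time-weighted residence-time distribution
#'
#' Logarithmic histogram of binding-event durations in which each event
#' contributes its duration (not a count), normalized by the total
#' simulation time: the y-value of a bin is the fraction of total system
#' time spent in binding events of that duration, so summing all y-values
#' gives the fraction of time the ligand was bound. Long-term events are
#' thereby conveyed with their true time impact.
#'
#' @param events A `binding_events` object.
#' @param total_time Total simulation time (defaults to the event set's).
#' @param bins Increasing bin edges; default [log_bins()] from one frame
#'   interval to `total_time`, 8 bins per decade.
#' @return A `residence_histogram`: data frame with `bin_lo`, `bin_hi`, `y`.
#' @export
residence_time_distribution <- function(events, total_time = NULL,
                                        bins = NULL) {
  if (is.null(total_time)) total_time <- events$total_time
  d <- events$events$duration
  if (length(d) && total_time < max(d)) {
    stop("total_time is smaller than the longest event", call. = FALSE)
  }
  if (is.null(bins)) {
    bins <- log_bins(events$frame_interval, total_time)
  }
  if (any(diff(bins) <= 0)) stop("bin edges must be strictly increasing",
                                 call. = FALSE)
  nb <- length(bins) - 1L
  y <- numeric(nb)
  if (length(d)) {
    idx <- findInterval(d, bins, rightmost.closed = TRUE)
    bad <- which(idx < 1L | idx > nb)
    if (length(bad)) {
      stop(sprintf("event %d (duration %g) lies outside the bin range",
                   bad[1], d[bad[1]]), call. = FALSE)
    }
    y <- vapply(seq_len(nb), function(b) sum(d[idx == b]), 0) / total_time
  }
  out <- data.frame(bin_lo = bins[-length(bins)], bin_hi = bins[-1], y = y)
  attr(out, "total_time") <- total_time
  class(out) <- c("residence_histogram", "data.frame")
  out
}

#' Pool per-run residence histograms
#'
#' Each run is first normalized by its own total time (so runs of different
#' lengths are comparable), then pooled with duration weights: the pooled
#' y is the time-weighted average of the per-run fractions,
#' sum(y_i * T_i) / sum(T_i). Set `mode = "pool_events"` to instead merge
#' event durations before a single normalization by the summed time; the
#' two agree when runs share bins.
#'
#' @param histograms List of `residence_histogram`s on identical bins.
#' @param total_times Per-run total times (defaults to each histogram's).
#' @param mode `"per_run"` (default) or `"pool_events"` (kept for
#'   comparison; identical bins make them equal by construction).
#' @return A pooled `residence_histogram`.
#' @export
pool_residence_histograms <- function(histograms, total_times = NULL,
                                      mode = c("per_run", "pool_events")) {
  mode <- match.arg(mode)
  stopifnot(length(histograms) > 0L)
  if (is.null(total_times)) {
    total_times <- vapply(histograms, function(h) attr(h, "total_time"), 0)
  }
  b0 <- histograms[[1]]$bin_lo
  for (h in histograms[-1]) {
    if (!isTRUE(all.equal(h$bin_lo, b0))) {
      stop("histograms must share bin edges to be pooled", call. = FALSE)
    }
  }
  ys <- vapply(histograms, function(h) h$y, numeric(length(b0)))
  if (is.null(dim(ys))) ys <- matrix(ys, nrow = 1)
  y <- as.numeric(ys %*% total_times) / sum(total_times)
  out <- histograms[[1]]
  out$y <- y
  attr(out, "total_time") <- sum(total_times)
  out
}

#' Time-weighted mean of event durations
#'
#' `sum(d^2) / sum(d)`: each event weighted by its own length, so the value
#' reads as the expected duration of the event in progress at a random
#' bound instant. For exponentially distributed durations with rate
#' `k_off` this equals `2 / k_off`.
#'
#' @param durations Positive event durations.
#' @return The time-weighted mean, in the units of `durations`.
#' @export
time_weighted_mean <- function(durations) {
  if (!length(durations)) stop("no durations", call. = FALSE)
  if (any(durations <= 0)) stop("durations must be > 0", call. = FALSE)
  sum(durations^2) / sum(durations)
}

#' Write a binding-event table
#'
#' TSV columns: `ligand_id`, `start_frame`, `n_frames`, `duration_ns`.
#'
#' @param events A `binding_events` object (durations in ps).
#' @param path Output path.
#' @export
write_event_table <- function(events, path) {
  ev <- events$events
  df <- data.frame(ligand_id = ev$ligand_id, start_frame = ev$start_frame,
                   n_frames = ev$n_frames, duration_ns = ev$duration / 1e3)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a residence histogram table
#'
#' TSV columns: `bin_lo_ns`, `bin_hi_ns`, `y` (times read in ps).
#'
#' @param hist A `residence_histogram` (bin edges in ps).
#' @param path Output path.
#' @export
write_histogram_table <- function(hist, path) {
  df <- data.frame(bin_lo_ns = hist$bin_lo / 1e3,
                   bin_hi_ns = hist$bin_hi / 1e3, y = hist$y)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
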