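#' Ground-truth kinetics specification for synthetic trajectories
#'
#' Describes a two-state (telegraph) binding process used to drive
#' synthetic coarse-grain trajectories: per-frame transition probabilities
#' are `p_bind = k_on * dt` and `p_unbind = k_off * dt`. The defaults match
#' the emulated study system: 16 ligands, frames every 600 ps, and
#' micro-second-scale binding kinetics.
#'
#' @param k_on,k_off Site binding/unbinding rates in 1/us. Zero is allowed
#'   to express limits (a zero rate freezes the corresponding transition);
#'   at least one rate must be positive.
#' @param n_frames Number of saved frames (>= 10).
#' @param frame_interval Frame spacing in ps (default 600).
#' @param n_ligands Number of ligand molecules (default 16).
#' @param seed Integer seed driving all generator randomness.
#' @param min_run Minimum bound/unbound run length in frames (default 3).
#'   With runs of at least 3 frames the 5-frame/3-vote majority filter is
#'   the identity, so pipelines can be tested against exact ground truth;
#'   run durations are shifted-geometric, and with symmetric rates the
#'   stationary bound fraction remains exactly `k_on / (k_on + k_off)`.
#' @return A validated `kinetics_spec`.
#' @export
kinetics_spec <- function(k_on = 1, k_off = 1, n_frames = 10000L,
                          frame_interval = 600, n_ligands = 16L,
                          seed = 1L, min_run = 3L) {
  spec <- list(k_on = k_on, k_off = k_off, n_frames = as.integer(n_frames),
               frame_interval = frame_interval,
               n_ligands = as.integer(n_ligands), seed = as.integer(seed),
               min_run = as.integer(min_run))
  dt_us <- frame_interval * 1e-6
  if (k_on < 0 || k_off < 0 || (k_on == 0 && k_off == 0)) {
    stop("rates must be non-negative and not both zero", call. = FALSE)
  }
  if (k_off * dt_us >= 0.5 || k_on * dt_us >= 0.5) {
    stop("rate * frame_interval must stay below 0.5 for the discrete-time ",
         "approximation to hold", call. = FALSE)
  }
  if (spec$n_frames < 10L) stop("n_frames must be >= 10", call. = FALSE)
  if (spec$frame_interval <= 0) stop("frame_interval must be > 0",
                                     call. = FALSE)
  if (spec$n_ligands < 1L) stop("n_ligands must be >= 1", call. = FALSE)
  if (spec$min_run < 1L) stop("min_run must be >= 1", call. = FALSE)
  class(spec) <- "kinetics_spec"
  spec
}

#' Analytic ground-truth summary of a kinetics specification
#'
#' @param spec A [kinetics_spec()].
#' @return List with `stationary_bound_fraction` = `k_on / (k_on + k_off)`,
#'   `analytic_time_weighted_mean_us` = `2 / k_off` (the time-weighted mean
#'   `E[T^2]/E[T]` of the exponential residence law), and
#'   `mean_duration_us` = `1 / k_off`.
#' @export
ground_truth_summary <- function(spec) {
  list(
    stationary_bound_fraction = spec$k_on / (spec$k_on + spec$k_off),
    analytic_time_weighted_mean_us = if (spec$k_off > 0) 2 / spec$k_off
      else Inf,
    mean_duration_us = if (spec$k_off > 0) 1 / spec$k_off else Inf
  )
}

# One telegraph chain as run lengths: states alternate; each run lasts
# (min_run - 1) + Geometric(p) frames. A zero exit probability freezes the
# chain in its current state.
telegraph_chain <- function(n_frames, p_on, p_off, min_run,
                            init_state = NULL) {
  f <- if (p_on + p_off > 0) p_on / (p_on + p_off) else 0.5
  state <- if (is.null(init_state)) stats::rbinom(1L, 1L, f) else init_state
  s <- integer(n_frames)
  i <- 1L
  while (i <= n_frames) {
    p_exit <- if (state == 1L) p_off else p_on
    run <- if (p_exit <= 0) n_frames else
      (min_run - 1L) + stats::rgeom(1L, p_exit) + 1L
    j <- min(n_frames, i + run - 1L)
    if (state == 1L) s[i:j] <- 1L
    i <- j + 1L
    state <- 1L - state
  }
  s
}

# Maximal bound runs of a 0/1 series, flagging the end-censored run.
series_runs <- function(s, ligand_id = 0L) {
  r <- rle(as.integer(s))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  b <- which(r$values == 1L)
  data.frame(ligand_id = rep(ligand_id, length(b)),
             start_frame = starts[b] - 1L,
             n_frames = r$lengths[b],
             end_censored = ends[b] == length(s))
}

#' Generate telegraph binding series with exact ground truth
#'
#' One independent two-state chain per ligand, each started from the
#' stationary distribution, with per-frame transition probabilities
#' `k_on * dt` and `k_off * dt`. Ground-truth events are the maximal bound
#' runs, including the end-censored ones (flagged). Bit-reproducible under
#' the spec seed.
#'
#' @param spec A [kinetics_spec()].
#' @return List with `series` (n_frames x n_ligands 0/1 matrix),
#'   `ground_truth` (event data frame: `ligand_id`, `start_frame` 0-based,
#'   `n_frames`, `end_censored`), and `spec`.
#' @export
generate_telegraph_series <- function(spec) {
  stopifnot(inherits(spec, "kinetics_spec"))
  set.seed(spec$seed)
  dt <- spec$frame_interval * 1e-6
  p_on <- spec$k_on * dt
  p_off <- spec$k_off * dt
  series <- matrix(0L, spec$n_frames, spec$n_ligands)
  gt <- vector("list", spec$n_ligands)
  for (l in seq_len(spec$n_ligands)) {
    s <- telegraph_chain(spec$n_frames, p_on, p_off, spec$min_run)
    series[, l] <- s
    gt[[l]] <- series_runs(s, ligand_id = l)
  }
  list(series = series, ground_truth = do.call(rbind, gt), spec = spec)
}

#' Geometry of the synthetic barrel-in-bilayer system
#'
#' A static pseudo-barrel of single-bead residues on a cylinder: 19
#' three-residue columns stand in for beta-strands, with the three
#' binding-site residue groups (ids 58-60, 73-75, 81-83) placed on three
#' adjacent columns so a ligand head at the site face is within the event
#' cutoff of all of them. Ligand head particles live in the membrane
#' plane; unbound ones random-walk outside an exclusion radius that keeps
#' them well clear of the site.
#'
#' @param box Box edge lengths in Angstrom (orthorhombic).
#' @param barrel_radius Cylinder radius (Angstrom).
#' @param n_columns Number of residue columns (default 19).
#' @param z_spacing Vertical spacing of the 3 residues per column.
#' @param site_offset Radial distance beyond the barrel wall at which a
#'   bound head sits.
#' @param exclusion_radius Minimum axial (xy) distance of unbound ligands
#'   from the barrel axis.
#' @param step_sd Random-walk step standard deviation per axis per frame.
#' @return A `barrel_geometry` list.
#' @export
barrel_geometry <- function(box = c(100, 100, 60), barrel_radius = 12,
                            n_columns = 19L, z_spacing = 5,
                            site_offset = 4, exclusion_radius = 35,
                            step_sd = 2) {
  g <- list(box = box, barrel_radius = barrel_radius,
            n_columns = as.integer(n_columns), z_spacing = z_spacing,
            site_offset = site_offset, exclusion_radius = exclusion_radius,
            step_sd = step_sd, center = c(box[1] / 2, box[2] / 2, box[3] / 2))
  if (g$exclusion_radius + 3 * g$step_sd >= min(box[1], box[2]) / 2) {
    stop("box too small to keep unbound ligands clear of the site",
         call. = FALSE)
  }
  class(g) <- "barrel_geometry"
  g
}

# Residue ids and 3-D positions of the pseudo-barrel. The nine site
# residues occupy the first three (adjacent) columns; the remaining ids in
# 27..83 fill the other columns. One "BB" particle per residue.
barrel_layout <- function(geom) {
  site_ids <- c(58:60, 73:75, 81:83)
  other_ids <- setdiff(27:83, site_ids)
  n_res <- geom$n_columns * 3L
  stopifnot(length(site_ids) + length(other_ids) == n_res)
  col_of <- integer(0); lev_of <- integer(0); ids <- integer(0)
  for (k in 0:2) {  # site columns 1..3
    col_of <- c(col_of, rep(k + 1L, 3L))
    lev_of <- c(lev_of, 1:3)
    ids <- c(ids, site_ids[(3 * k + 1):(3 * k + 3)])
  }
  for (k in seq_along(other_ids)) {
    col_of <- c(col_of, 4L + (k - 1L) %/% 3L)
    lev_of <- c(lev_of, 1L + (k - 1L) %% 3L)
    ids <- c(ids, other_ids[k])
  }
  ord <- order(ids)
  theta <- 2 * pi * (col_of - 1) / geom$n_columns
  x <- geom$center[1] + geom$barrel_radius * cos(theta)
  y <- geom$center[2] + geom$barrel_radius * sin(theta)
  z <- geom$center[3] + (lev_of - 2) * geom$z_spacing
  data.frame(residue_id = ids, x = x, y = y, z = z,
             site = ids %in% site_ids)[ord, ]
}

# Anchor point where a bound ligand head sits: radially out from the
# middle site column.
site_anchor <- function(geom) {
  theta <- 2 * pi * 1 / geom$n_columns  # middle of columns 1..3
  r <- geom$barrel_radius + geom$site_offset
  c(geom$center[1] + r * cos(theta), geom$center[2] + r * sin(theta),
    geom$center[3])
}

#' Generate a synthetic coarse-grain trajectory with known binding kinetics
#'
#' Builds a static pseudo-barrel in a bilayer-plane box plus `n_ligands`
#' ceramide-like head particles (named `AM1`, residue `CER`). Site
#' occupation follows a single telegraph chain (one site, at most one
#' ligand bound per frame, so ground truth is unambiguous); bound runs are
#' assigned to ligands round-robin. During a bound run the scheduled
#' ligand sits at the site face with sub-Angstrom jitter - within the
#' event cutoff of at least two site groups on every bound frame; unbound
#' ligands random-walk in the membrane plane outside the exclusion radius,
#' always farther than `event_cutoff + 4` Angstrom from every site group.
#' Because all runs last at least `min_run` frames (default 3), the
#' majority filter leaves the contact series untouched and the event
#' pipeline recovers the ground truth exactly.
#'
#' @param spec A [kinetics_spec()].
#' @param geom A [barrel_geometry()].
#' @param dir Optional output directory; when given, writes
#'   `<basename>.gro` (multi-frame trajectory), `<basename>_topology.gro`
#'   (first frame), `<basename>_ground_truth.tsv` and `<basename>.yaml`
#'   (spec echo).
#' @param basename File basename (default `"synthetic"`).
#' @return List with `trajectory` (a `cg_trajectory`), `ground_truth`
#'   (event data frame incl. `end_censored`), `site_series` (the site
#'   chain), `spec`, `geom`, `summary` ([ground_truth_summary()]) and
#'   `files` (paths written, if any).
#' @export
generate_synthetic_trajectory <- function(spec, geom = barrel_geometry(),
                                          dir = NULL,
                                          basename = "synthetic") {
  stopifnot(inherits(spec, "kinetics_spec"))
  set.seed(spec$seed)
  dt <- spec$frame_interval * 1e-6
  s <- telegraph_chain(spec$n_frames, spec$k_on * dt, spec$k_off * dt,
                       spec$min_run)
  runs <- series_runs(s)
  nruns <- nrow(runs)
  runs$ligand_id <- if (nruns) ((seq_len(nruns) - 1L) %% spec$n_ligands) + 1L
    else integer(0)

  lay <- barrel_layout(geom)
  n_prot <- nrow(lay)
  nl <- spec$n_ligands
  n_part <- n_prot + nl
  nf <- spec$n_frames
  anchor <- site_anchor(geom)

  coords <- array(NA_real_, c(nf, n_part, 3L))
  coords[, seq_len(n_prot), 1] <- matrix(lay$x, nf, n_prot, byrow = TRUE)
  coords[, seq_len(n_prot), 2] <- matrix(lay$y, nf, n_prot, byrow = TRUE)
  coords[, seq_len(n_prot), 3] <- matrix(lay$z, nf, n_prot, byrow = TRUE)

  # bound schedule per frame: 0 = free, else ligand id
  bound_lig <- integer(nf)
  for (i in seq_len(nruns)) {
    idx <- runs$start_frame[i] + seq_len(runs$n_frames[i])
    bound_lig[idx] <- runs$ligand_id[i]
  }

  rand_free_xy <- function(n) {
    out <- matrix(NA_real_, n, 2)
    need <- seq_len(n)
    while (length(need)) {
      cand <- cbind(stats::runif(length(need), 0, geom$box[1]),
                    stats::runif(length(need), 0, geom$box[2]))
      r <- sqrt((cand[, 1] - geom$center[1])^2 +
                  (cand[, 2] - geom$center[2])^2)
      ok <- r >= geom$exclusion_radius + 3 * geom$step_sd
      out[need[ok], ] <- cand[ok, , drop = FALSE]
      need <- need[!ok]
    }
    out
  }

  pos <- cbind(rand_free_xy(nl), rep(geom$center[3], nl))
  for (f in seq_len(nf)) {
    step <- matrix(stats::rnorm(2 * nl, 0, geom$step_sd), nl, 2)
    newxy <- pos[, 1:2] + step
    newxy[, 1] <- newxy[, 1] %% geom$box[1]
    newxy[, 2] <- newxy[, 2] %% geom$box[2]
    r <- sqrt((newxy[, 1] - geom$center[1])^2 +
                (newxy[, 2] - geom$center[2])^2)
    stuck <- r < geom$exclusion_radius
    newxy[stuck, ] <- pos[stuck, 1:2, drop = FALSE]  # reject into the site
    pos[, 1:2] <- newxy
    if (bound_lig[f] > 0L) {
      l <- bound_lig[f]
      coords[f, n_prot + l, ] <- anchor + stats::runif(3, -0.45, 0.45)
      free <- setdiff(seq_len(nl), l)
    } else {
      free <- seq_len(nl)
    }
    for (l in free) coords[f, n_prot + l, ] <- pos[l, ]
    # a ligand leaving the site teleports back to a fresh free position
    if (f < nf && bound_lig[f] > 0L && bound_lig[f + 1L] != bound_lig[f]) {
      pos[bound_lig[f], 1:2] <- rand_free_xy(1L)
    }
  }

  topo <- build_topology(
    residue_id = c(lay$residue_id, 100L + seq_len(nl)),
    residue_name = c(ifelse(lay$site, "GLU", "ALA"), rep("CER", nl)),
    particle_name = c(rep("BB", n_prot), rep("AM1", nl))
  )
  traj <- new_cg_trajectory(coords,
                            matrix(geom$box, nf, 3, byrow = TRUE),
                            spec$frame_interval, topo)
  gt <- runs[, c("ligand_id", "start_frame", "n_frames", "end_censored")]
  files <- NULL
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    files <- list(
      trajectory = file.path(dir, paste0(basename, ".gro")),
      topology = file.path(dir, paste0(basename, "_topology.gro")),
      ground_truth = file.path(dir, paste0(basename, "_ground_truth.tsv")),
      spec = file.path(dir, paste0(basename, ".yaml"))
    )
    write_gro(traj, files$trajectory)
    one <- new_cg_trajectory(coords[1, , , drop = FALSE],
                             traj$box[1, , drop = FALSE],
                             spec$frame_interval, topo)
    write_gro(one, files$topology)
    utils::write.table(gt, files$ground_truth, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    yaml::write_yaml(unclass(spec), files$spec)
  }
  list(trajectory = traj, ground_truth = gt, site_series = s, spec = spec,
       geom = geom, summary = ground_truth_summary(spec), files = files)
}

#' Independently validate the geometric ground-truth invariant
#'
#' Frame-by-frame brute-force check (straight loops over frames, ligands
#' and site particles, no shared code with the contact pipeline) that a
#' generated trajectory honours its schedule: on every bound frame the
#' scheduled ligand's head is within `event_cutoff` of at least
#' `min_groups` site groups, and every unbound ligand stays farther than
#' `event_cutoff + 4` Angstrom from all site-group particles.
#'
#' @param result A [generate_synthetic_trajectory()] result.
#' @param site A [site_definition()] (defaults match the generator).
#' @return TRUE, or a character vector of violations.
#' @export
validate_trajectory_geometry <- function(result,
                                         site = site_definition()) {
  traj <- result$trajectory
  topo <- traj$topology
  heads <- which(topo$is_head)
  lig_of_head <- topo$molecule_id[heads]
  prot <- which(topo$role == "protein")
  groups <- lapply(site$groups, function(g)
    prot[topo$residue_id[prot] %in% g])
  bound_lig <- integer(n_frames(traj))
  for (i in seq_len(nrow(result$ground_truth))) {
    idx <- result$ground_truth$start_frame[i] +
      seq_len(result$ground_truth$n_frames[i])
    bound_lig[idx] <- result$ground_truth$ligand_id[i]
  }
  bad <- character()
  for (f in seq_len(n_frames(traj))) {
    for (hi in seq_along(heads)) {
      h <- heads[hi]
      p <- traj$coords[f, h, ]
      dmin <- vapply(groups, function(gp) {
        min(vapply(gp, function(q)
          min_image_distance(p, traj$coords[f, q, ], traj$box[f, ]), 0))
      }, 0)
      if (bound_lig[f] == lig_of_head[hi]) {
        if (sum(dmin <= site$event_cutoff) < site$min_groups) {
          bad <- c(bad, sprintf("frame %d: bound ligand %d not at site",
                                f - 1L, lig_of_head[hi]))
        }
      } else if (any(dmin <= site$event_cutoff + 4)) {
        bad <- c(bad, sprintf("frame %d: unbound ligand %d too close",
                              f - 1L, lig_of_head[hi]))
      }
    }
  }
  if (length(bad)) bad else TRUE
}
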