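#' Validate a pipeline configuration file
#'
#' Reads a YAML configuration, applies defaults, and checks every
#' invariant, collecting all violations rather than stopping at the first.
#'
#' Recognised keys: `topology` (required path), `trajectory` (optional
#' path), `frame_interval` (ps), `output_dir`, `species` (one or two
#' labels; the first drives event/occupancy analysis, a second enables the
#' duration comparison), `analysis` (overrides for [analysis_config()]
#' fields), `site` (`groups`, `event_cutoff`, `min_groups`), `stats`
#' (`resamples`, `ci_level`, `seed`, `alternative`). An empty override
#' section reproduces the published analysis settings exactly.
#'
#' @param path YAML file path.
#' @return A validated `pipeline_config` list; errors with the full list
#'   of violations otherwise.
#' @export
validate_config <- function(path) {
  raw <- tryCatch(yaml::read_yaml(path), error = function(e)
    stop("cannot parse YAML config: ", conditionMessage(e), call. = FALSE))
  problems <- character()
  need <- function(cond, msg) if (!isTRUE(cond)) problems <<- c(problems, msg)

  need(is.character(raw$topology) && length(raw$topology) == 1L,
       "topology path is required")
  if (is.character(raw$topology) && !file.exists(raw$topology)) {
    problems <- c(problems, paste0("topology file not found: ",
                                   raw$topology))
  }
  if (!is.null(raw$trajectory) && !file.exists(raw$trajectory)) {
    problems <- c(problems, paste0("trajectory file not found: ",
                                   raw$trajectory))
  }
  frame_interval <- raw$frame_interval %||% 600
  need(is.numeric(frame_interval) && frame_interval > 0,
       "frame_interval must be > 0")
  species <- as.character(raw$species %||% "ceramide")
  need(length(species) >= 1L, "at least one species label is required")

  acfg_args <- raw$analysis %||% list()
  acfg <- tryCatch(do.call(analysis_config, acfg_args), error = function(e) {
    problems <<- c(problems, sub("^invalid analysis configuration: ", "",
                                 conditionMessage(e)))
    NULL
  })
  site_raw <- raw$site %||% list()
  groups <- if (is.null(site_raw$groups)) list(58:60, 73:75, 81:83) else
    lapply(site_raw$groups, function(g) seq.int(g[[1]], g[[2]]))
  site <- tryCatch(
    site_definition(groups,
                    event_cutoff = site_raw$event_cutoff %||% 8,
                    min_groups = site_raw$min_groups %||% 2L),
    error = function(e) {
      problems <<- c(problems, conditionMessage(e)); NULL
    })
  st <- raw$stats %||% list()
  stats_opts <- list(resamples = as.integer(st$resamples %||% 10000L),
                     ci_level = st$ci_level %||% 0.95,
                     seed = as.integer(st$seed %||% 1L),
                     alternative = st$alternative %||% "a_greater")
  need(stats_opts$resamples >= 1L, "stats resamples must be >= 1")
  need(stats_opts$ci_level > 0 && stats_opts$ci_level < 1,
       "stats ci_level must be a fraction in (0,1)")
  need(stats_opts$alternative %in% c("a_greater", "b_greater"),
       "stats alternative must be a_greater or b_greater")

  if (length(problems)) {
    stop("invalid pipeline configuration:\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  }
  structure(list(topology = raw$topology, trajectory = raw$trajectory,
                 frame_interval = frame_interval,
                 output_dir = raw$output_dir %||% "cglipidsite_out",
                 species = species, analysis = acfg, site = site,
                 stats = stats_opts),
            class = "pipeline_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full contact / kinetics / occupancy / statistics pipeline
#'
#' Fixed stage order: load, residue contact occupancy (unsmoothed), then
#' per-ligand event detection (raw series, majority smoothing, censored
#' event extraction), residence histogram and bootstrap statistics, then
#' in-plane alignment and occupancy gridding. Writes `contacts.tsv`,
#' `events.tsv`, `hist.tsv`, one `<species>.dx` per species, `stats.json`
#' and `manifest.json` into the configured output directory. A stage
#' failure aborts with the stage name; partial outputs are flagged in the
#' manifest. Reruns with the same inputs and seed are byte-identical.
#'
#' @param config A `pipeline_config` from [validate_config()], or the path
#'   to a YAML configuration.
#' @return The report list (manifest contents plus in-memory results),
#'   invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- validate_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$output_dir
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("cglipidsite")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    config = unclass(config)[c("topology", "trajectory", "frame_interval",
                               "species")],
    seed = config$stats$seed,
    outputs = list(), warnings = character(), errors = character()
  )
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      manifest$errors <<- c(manifest$errors,
                            sprintf("stage '%s': %s", name,
                                    conditionMessage(e)))
      write_manifest(manifest, out)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  traj <- stage("load", load_trajectory(config$topology, config$trajectory,
                                        config$frame_interval))
  manifest$n_frames <- n_frames(traj)
  manifest$n_particles <- n_particles(traj)
  acfg <- config$analysis

  cmaps <- stage("contacts", {
    maps <- lapply(config$species, function(sp)
      residue_contact_occupancy(traj, acfg, sp))
    tab <- do.call(rbind, lapply(maps, as.data.frame))
    class(tab) <- c("contact_map", "data.frame")
    write_contact_table(tab, file.path(out, "contacts.tsv"))
    manifest$outputs$contacts <- "contacts.tsv"
    names(maps) <- config$species
    maps
  })

  events_by_species <- stage("events", {
    res <- lapply(config$species, function(sp) {
      topo <- traj$topology
      ligs <- unique(topo$molecule_id[!is.na(topo$species) &
                                        topo$species == sp])
      sets <- lapply(ligs, function(l) {
        s <- raw_contact_series(traj, config$site, l)
        s <- majority_smooth(s, acfg$smoothing_window,
                             acfg$smoothing_min_true)
        extract_events(s, traj$frame_interval, ligand_id = l)
      })
      combine_events(sets)
    })
    names(res) <- config$species
    write_event_table(res[[1]], file.path(out, "events.tsv"))
    manifest$outputs$events <- "events.tsv"
    res
  })

  hist <- stage("histogram", {
    h <- residence_time_distribution(events_by_species[[1]])
    write_histogram_table(h, file.path(out, "hist.tsv"))
    manifest$outputs$histogram <- "hist.tsv"
    h
  })

  grids <- stage("occupancy", {
    aligned <- align_protein_xy(traj)
    gs <- lapply(config$species, function(sp) {
      g <- occupancy_volume(aligned, sp, acfg)
      fn <- paste0(sp, ".dx")
      export_grid(g, file.path(out, fn))
      manifest$outputs[[paste0("grid_", sp)]] <<- fn
      g
    })
    names(gs) <- config$species
    gs
  })

  stats_report <- stage("stats", {
    ev1 <- events_by_species[[1]]$events$duration
    sr <- list(species = config$species[1],
               n_events = length(ev1),
               n_end_censored =
                 events_by_species[[1]]$n_discarded_end_censored,
               bound_fraction = sum(hist$y),
               seed = config$stats$seed)
    if (length(ev1)) {
      bs <- bootstrap_time_weighted_mean(
        ev1, config$stats$resamples, config$stats$ci_level,
        seed = config$stats$seed)
      sr$time_weighted_mean_ps <- bs$point_estimate
      sr$ci_ps <- c(bs$ci_low, bs$ci_high)
    }
    if (length(config$species) >= 2L) {
      ev2 <- events_by_species[[2]]$events$duration
      if (length(ev2)) {
        sr$comparison <- list(
          a = config$species[1], b = config$species[2],
          alternative = config$stats$alternative,
          p_value = compare_durations(ev1, ev2, config$stats$alternative))
      }
    }
    jsonlite::write_json(sr, file.path(out, "stats.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    manifest$outputs$stats <- "stats.json"
    sr
  })

  write_manifest(manifest, out)
  invisible(list(manifest = manifest, contacts = cmaps,
                 events = events_by_species, histogram = hist,
                 grids = grids, stats = stats_report))
}

write_manifest <- function(manifest, out) {
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}
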