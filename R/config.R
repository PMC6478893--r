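#' Analysis configuration
#'
#' Bundles every numeric parameter of the contact, binding-kinetics and
#' space-occupation analyses. The defaults are the published analysis
#' settings for the VDAC/ceramide system: head-group beads within 7 Angstrom
#' of any residue particle count as a residue contact; a binding event
#' requires the head group within 8 Angstrom of at least two of the three
#' residue groups on the beta-strands forming the site (residues 58-60,
#' 73-75 and 81-83); spuriously brief contacts or losses of contact are
#' majority-filtered over a 5-frame window with a 3-vote threshold; binding
#' site residues are called above 15% occupancy; occupancy volumes are
#' gridded at 5 Angstrom and contoured at 10% (ceramide) or 20%
#' (cholesterol); confidence intervals use a 10,000-resample bootstrap at
#' the 95% level.
#'
#' @param contact_cutoff Residue-contact distance cutoff in Angstrom.
#' @param event_cutoff Binding-event distance cutoff in Angstrom.
#' @param min_groups_in_contact Minimum number of site groups (out of three)
#'   simultaneously within `event_cutoff` for a frame to count as bound.
#' @param site_groups List of exactly three integer vectors of residue ids.
#' @param smoothing_window Odd window width (frames) for the majority filter.
#' @param smoothing_min_true Votes required to set the centre frame bound.
#' @param occupancy_threshold Occupancy fraction above which (strictly) a
#'   residue is called part of the binding site.
#' @param grid_spacing Occupancy-grid cell edge in Angstrom.
#' @param iso_threshold_ceramide,iso_threshold_cholesterol Iso-occupancy
#'   contour levels per species.
#' @param bootstrap_resamples Number of bootstrap resamples.
#' @param ci_level Two-sided confidence level, in (0,1).
#' @return An object of class `analysis_config` (a validated list).
#' @export
analysis_config <- function(contact_cutoff = 7,
                            event_cutoff = 8,
                            min_groups_in_contact = 2L,
                            site_groups = list(58:60, 73:75, 81:83),
                            smoothing_window = 5L,
                            smoothing_min_true = 3L,
                            occupancy_threshold = 0.15,
                            grid_spacing = 5,
                            iso_threshold_ceramide = 0.10,
                            iso_threshold_cholesterol = 0.20,
                            bootstrap_resamples = 10000L,
                            ci_level = 0.95) {
  cfg <- list(
    contact_cutoff = contact_cutoff,
    event_cutoff = event_cutoff,
    min_groups_in_contact = as.integer(min_groups_in_contact),
    site_groups = lapply(site_groups, as.integer),
    smoothing_window = as.integer(smoothing_window),
    smoothing_min_true = as.integer(smoothing_min_true),
    occupancy_threshold = occupancy_threshold,
    grid_spacing = grid_spacing,
    iso_threshold_ceramide = iso_threshold_ceramide,
    iso_threshold_cholesterol = iso_threshold_cholesterol,
    bootstrap_resamples = as.integer(bootstrap_resamples),
    ci_level = ci_level
  )
  problems <- config_violations(cfg)
  if (length(problems)) {
    stop("invalid analysis configuration: ", paste(problems, collapse = "; "),
         call. = FALSE)
  }
  class(cfg) <- "analysis_config"
  cfg
}

#' List every invariant violation in a configuration
#'
#' Returns all problems, not just the first, so a configuration file can be
#' fixed in one pass.
#'
#' @param cfg A list with `analysis_config` fields.
#' @return Character vector of violation messages (length zero when valid).
#' @export
config_violations <- function(cfg) {
  p <- character()
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  for (f in c("contact_cutoff", "event_cutoff", "grid_spacing")) {
    if (!num1(cfg[[f]]) || cfg[[f]] <= 0) {
      p <- c(p, sprintf("%s must be a single positive length", f))
    }
  }
  for (f in c("occupancy_threshold", "iso_threshold_ceramide",
              "iso_threshold_cholesterol", "ci_level")) {
    if (!num1(cfg[[f]]) || cfg[[f]] <= 0 || cfg[[f]] >= 1) {
      p <- c(p, sprintf("%s must be a fraction in (0,1)", f))
    }
  }
  if (!num1(cfg$smoothing_window) || cfg$smoothing_window < 1 ||
      cfg$smoothing_window %% 2 == 0) {
    p <- c(p, "smoothing_window must be odd")
  }
  if (!num1(cfg$smoothing_min_true) || cfg$smoothing_min_true < 1 ||
      (num1(cfg$smoothing_window) &&
       cfg$smoothing_min_true > cfg$smoothing_window)) {
    p <- c(p, "smoothing_min_true must be in 1..smoothing_window")
  }
  if (!num1(cfg$min_groups_in_contact) ||
      !cfg$min_groups_in_contact %in% 1:3) {
    p <- c(p, "min_groups_in_contact must be 1, 2 or 3")
  }
  if (!is.list(cfg$site_groups) || length(cfg$site_groups) != 3L ||
      any(!vapply(cfg$site_groups, length, 1L))) {
    p <- c(p, "site_groups must be three non-empty residue-id ranges")
  } else if (anyDuplicated(unlist(cfg$site_groups))) {
    p <- c(p, "site_groups must be mutually disjoint")
  }
  if (!num1(cfg$bootstrap_resamples) || cfg$bootstrap_resamples < 1) {
    p <- c(p, "bootstrap_resamples must be >= 1")
  }
  p
}

#' Binding-site definition for event detection
#'
#' A site is three disjoint groups of residues (here, short stretches on the
#' three beta-strands that line the lipid site); a ligand is in contact on a
#' frame when its head-group particles come within `event_cutoff` of at
#' least `min_groups` of the groups.
#'
#' @param groups List of exactly three non-empty, disjoint integer vectors
#'   of residue ids.
#' @param event_cutoff Contact cutoff in Angstrom.
#' @param min_groups Number of groups (1-3) that must be within cutoff.
#' @return An object of class `site_definition`.
#' @export
site_definition <- function(groups = list(58:60, 73:75, 81:83),
                            event_cutoff = 8,
                            min_groups = 2L) {
  groups <- lapply(groups, as.integer)
  if (length(groups) != 3L || any(lengths(groups) == 0L)) {
    stop("a site needs exactly three non-empty residue groups", call. = FALSE)
  }
  if (anyDuplicated(unlist(groups))) {
    stop("site groups must be mutually disjoint", call. = FALSE)
  }
  min_groups <- as.integer(min_groups)
  if (!min_groups %in% 1:3) stop("min_groups must be 1, 2 or 3", call. = FALSE)
  if (!is.numeric(event_cutoff) || event_cutoff <= 0) {
    stop("event_cutoff must be positive", call. = FALSE)
  }
  structure(list(groups = groups, event_cutoff = event_cutoff,
                 min_groups = min_groups),
            class = "site_definition")
}

#' @export
print.analysis_config <- function(x, ...) {
  cat("Analysis configuration\n")
  cat(sprintf("  contact cutoff       : %g A\n", x$contact_cutoff))
  cat(sprintf("  event cutoff         : %g A (>= %d of 3 groups)\n",
              x$event_cutoff, x$min_groups_in_contact))
  cat(sprintf("  site groups          : %s\n",
              paste(vapply(x$site_groups, function(g)
                paste0(min(g), "-", max(g)), ""), collapse = ", ")))
  cat(sprintf("  smoothing            : %d-frame window, %d votes\n",
              x$smoothing_window, x$smoothing_min_true))
  cat(sprintf("  occupancy threshold  : %g\n", x$occupancy_threshold))
  cat(sprintf("  grid spacing         : %g A\n", x$grid_spacing))
  cat(sprintf("  iso thresholds       : ceramide %g, cholesterol %g\n",
              x$iso_threshold_ceramide, x$iso_threshold_cholesterol))
  cat(sprintf("  bootstrap            : %d resamples, %g%% CI\n",
              x$bootstrap_resamples, 100 * x$ci_level))
  invisible(x)
}
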