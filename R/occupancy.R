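#' Align the protein in the membrane plane across frames
#'
#' Applies, per frame, the z-axis rotation plus xy translation that
#' minimizes the protein-particle RMSD to a reference frame; z coordinates
#' are untouched, preserving the membrane normal, and all particles
#' (protein and lipids) are co-transformed. The in-plane restriction is
#' what makes occupancy volumes meaningful relative to a bilayer-embedded
#' protein; a full 3-D superposition would tilt the membrane frame.
#'
#' The protein is assumed whole (not split across the periodic boundary),
#' which holds for a membrane protein kept near the box centre.
#'
#' @param traj A `cg_trajectory` with protein particles.
#' @param ref_frame 0-based reference frame index (default 0).
#' @return The aligned `cg_trajectory`.
#' @export
align_protein_xy <- function(traj, ref_frame = 0L) {
  topo <- traj$topology
  prot <- which(topo$role == "protein")
  if (length(prot) < 3L) {
    stop("fewer than 3 protein particles: alignment is degenerate",
         call. = FALSE)
  }
  nf <- n_frames(traj)
  rf <- as.integer(ref_frame) + 1L
  if (rf < 1L || rf > nf) stop("ref_frame out of range", call. = FALSE)
  ref <- traj$coords[rf, prot, 1:2, drop = FALSE]
  dim(ref) <- c(length(prot), 2L)
  ref_c <- colMeans(ref)
  refc <- sweep(ref, 2, ref_c)
  out <- traj$coords
  for (f in seq_len(nf)) {
    mob <- traj$coords[f, prot, 1:2, drop = FALSE]
    dim(mob) <- c(length(prot), 2L)
    mob_c <- colMeans(mob)
    mobc <- sweep(mob, 2, mob_c)
    # closed-form optimal in-plane rotation (2-D Kabsch)
    num <- sum(mobc[, 1] * refc[, 2] - mobc[, 2] * refc[, 1])
    den <- sum(mobc[, 1] * refc[, 1] + mobc[, 2] * refc[, 2])
    th <- atan2(num, den)
    ct <- cos(th); st <- sin(th)
    x <- out[f, , 1] - mob_c[1]
    y <- out[f, , 2] - mob_c[2]
    out[f, , 1] <- ct * x - st * y + ref_c[1]
    out[f, , 2] <- st * x + ct * y + ref_c[2]
  }
  new_cg_trajectory(out, traj$box, traj$frame_interval, topo)
}

#' Three-dimensional occupancy volume of a lipid species
#'
#' Grids the box at `grid_spacing` and, for every cell, records the
#' fraction of frames in which at least one head-group particle of the
#' species lies inside it (several particles in one cell still count as
#' one, keeping values in `[0, 1]`: 0 means never present, 1 always
#' present). Cells are half-open `[lo, hi)` in each axis and anchored at
#' the origin corner; particles are wrapped into the periodic box before
#' gridding, and the grid covers the maximal box extent across frames.
#' Align the trajectory with [align_protein_xy()] first so the volume is
#' meaningful relative to the protein.
#'
#' @param traj An aligned `cg_trajectory`.
#' @param species Ligand species label.
#' @param config An [analysis_config()]; `grid_spacing` is used.
#' @return An `occupancy_grid`: list with `origin`, `spacing`, `shape`,
#'   `values` (3-D array of occupancy fractions), `species`, `n_frames`.
#' @export
occupancy_volume <- function(traj, species, config = analysis_config()) {
  topo <- traj$topology
  heads <- which(!is.na(topo$species) & topo$species == species &
                   topo$is_head)
  if (!length(heads)) {
    stop("no head particles of species '", species, "' in the topology",
         call. = FALSE)
  }
  sp <- config$grid_spacing
  nf <- n_frames(traj)
  extent <- apply(traj$box, 2, max)
  shape <- pmax(as.integer(ceiling(extent / sp - 1e-9)), 1L)
  counts <- array(0L, shape)
  nh <- length(heads)
  for (f in seq_len(nf)) {
    p <- traj$coords[f, heads, , drop = FALSE]
    dim(p) <- c(nh, 3L)
    b <- traj$box[f, ]
    p <- p - rep(b, each = nh) * floor(p / rep(b, each = nh))  # wrap [0,box)
    ix <- pmin(floor(p[, 1] / sp), shape[1] - 1L)
    iy <- pmin(floor(p[, 2] / sp), shape[2] - 1L)
    iz <- pmin(floor(p[, 3] / sp), shape[3] - 1L)
    cells <- unique(ix + shape[1] * (iy + shape[2] * iz)) + 1L
    counts[cells] <- counts[cells] + 1L
  }
  structure(list(origin = c(0, 0, 0), spacing = sp, shape = shape,
                 values = counts / nf, species = species, n_frames = nf),
            class = "occupancy_grid")
}

#' Sum of an occupancy grid
#'
#' Equals the time-averaged number of distinct occupied cells per frame - a
#' useful conservation check.
#' @param grid An `occupancy_grid`.
#' @export
grid_total <- function(grid) sum(grid$values)

#' Iso-occupancy contour threshold for a species
#'
#' Returns the configured per-species contour level (10% for ceramide, 20%
#' for cholesterol by default). The optional compensation mode scales the
#' base threshold linearly by the molecule-count ratio
#' `n_species_molecules / n_reference_molecules` (clipped to (0,1)) to
#' compare species present in different copy numbers; it is off by default
#' because the published per-species levels are taken as authoritative and
#' linear scaling is only one reading of count compensation.
#'
#' @param species `"ceramide"` or `"cholesterol"` (other labels fall back
#'   to the ceramide level).
#' @param config An [analysis_config()].
#' @param n_species_molecules,n_reference_molecules Copy numbers used by
#'   the compensation mode; must be positive.
#' @param compensate Enable linear molecule-count compensation.
#' @return The threshold fraction.
#' @export
iso_threshold <- function(species, config = analysis_config(),
                          n_species_molecules = 1L,
                          n_reference_molecules = 1L,
                          compensate = FALSE) {
  if (n_species_molecules <= 0 || n_reference_molecules <= 0) {
    stop("molecule counts must be > 0", call. = FALSE)
  }
  base <- if (identical(species, "cholesterol")) {
    config$iso_threshold_cholesterol
  } else {
    config$iso_threshold_ceramide
  }
  if (compensate) {
    base <- base * n_species_molecules / n_reference_molecules
    eps <- .Machine$double.eps
    base <- min(max(base, eps), 1 - eps)
  }
  base
}

#' Export an occupancy grid as an OpenDX scalar field
#'
#' Standard DX regular-grid format, loadable by VMD and ChimeraX for
#' drawing iso-occupancy surfaces. Values are written z-fastest with full
#' precision and round-trip through [read_dx()] to better than 1e-6.
#'
#' @param grid An `occupancy_grid`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_grid <- function(grid, path) {
  if (is.null(grid$values) || !length(grid$values)) {
    stop("empty occupancy grid", call. = FALSE)
  }
  s <- grid$shape
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(
    "# occupancy volume written by cglipidsite",
    sprintf("object 1 class gridpositions counts %d %d %d", s[1], s[2], s[3]),
    sprintf("origin %.6f %.6f %.6f",
            grid$origin[1], grid$origin[2], grid$origin[3]),
    sprintf("delta %.6f 0.000000 0.000000", grid$spacing),
    sprintf("delta 0.000000 %.6f 0.000000", grid$spacing),
    sprintf("delta 0.000000 0.000000 %.6f", grid$spacing),
    sprintf("object 2 class gridconnections counts %d %d %d",
            s[1], s[2], s[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows",
            prod(s))
  ), con)
  # DX stores x slowest, z fastest
  v <- aperm(grid$values, c(3, 2, 1))
  v <- as.numeric(v)
  pad <- (-length(v)) %% 3L
  if (pad) v <- c(v, rep(NA_real_, pad))
  m <- matrix(v, ncol = 3L, byrow = TRUE)
  rows <- apply(m, 1, function(r)
    paste(sprintf("%.9g", r[!is.na(r)]), collapse = " "))
  writeLines(rows, con)
  writeLines(c('attribute "dep" string "positions"',
               'object "occupancy" class field',
               'component "positions" value 1',
               'component "connections" value 2',
               'component "data" value 3'), con)
  invisible(path)
}

#' Read an OpenDX scalar field written by [export_grid()]
#'
#' @param path DX file path.
#' @return An `occupancy_grid` (species/frames metadata unset).
#' @export
read_dx <- function(path) {
  lines <- readLines(path)
  gp <- grep("class gridpositions counts", lines, value = TRUE)[1]
  shape <- as.integer(strsplit(trimws(sub(".*counts", "", gp)),
                               "\\s+")[[1]])
  org <- as.numeric(strsplit(trimws(sub("^origin", "",
                                        grep("^origin", lines,
                                             value = TRUE)[1])), "\\s+")[[1]])
  deltas <- grep("^delta", lines, value = TRUE)
  dmat <- t(vapply(deltas, function(l)
    as.numeric(strsplit(trimws(sub("^delta", "", l)), "\\s+")[[1]]),
    numeric(3)))
  spacing <- unname(dmat[1, 1])
  start <- grep("data follows", lines)[1] + 1L
  n <- prod(shape)
  vals <- numeric(0)
  i <- start
  while (length(vals) < n && i <= length(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln) || grepl("^(attribute|object)", ln)) break
    vals <- c(vals, as.numeric(strsplit(ln, "\\s+")[[1]]))
    i <- i + 1L
  }
  if (length(vals) != n) stop("DX data block has ", length(vals),
                              " values, expected ", n, call. = FALSE)
  arr <- aperm(array(vals, dim = rev(shape)), c(3, 2, 1))
  structure(list(origin = org, spacing = spacing, shape = shape,
                 values = arr, species = NA_character_,
                 n_frames = NA_integer_),
            class = "occupancy_grid")
}
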