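#' Default particle/residue name mapping
#'
#' Maps coarse-grain bead and residue names to roles and ligand species.
#' Defaults follow Martini conventions: the protein backbone bead is `BB`
#' (side chains `SC1`-`SC4`); ceramide head-group beads are `AM1`/`AM2`,
#' the cholesterol hydroxyl is `ROH`, and the phosphocholine head beads are
#' `PO4`/`NC3`. Bead naming varies across force-field versions, so the
#' mapping is user-editable: pass a modified copy to [load_trajectory()].
#'
#' @return A list with elements `protein_particles` (bead names implying a
#'   protein particle), `protein_resnames` (residue names implying protein),
#'   `species_resnames` (named character vector, residue name -> species
#'   label) and `head_particles` (named list, species label -> head bead
#'   names).
#' @export
default_name_map <- function() {
  aa3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
           "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
           "TYR", "VAL")
  list(
    protein_particles = c("BB", "SC1", "SC2", "SC3", "SC4",
                          "N", "CA", "C", "O", "CB"),
    protein_resnames = aa3,
    species_resnames = c(CER = "ceramide", XNCE = "ceramide",
                         CHOL = "cholesterol",
                         POPC = "phosphatidylcholine",
                         DMPC = "phosphatidylcholine",
                         DPPC = "phosphatidylcholine"),
    head_particles = list(ceramide = c("AM1", "AM2"),
                          cholesterol = "ROH",
                          phosphatidylcholine = c("PO4", "NC3"))
  )
}

# Build the topology data frame from parsed particle records.
# Roles come from the name map; molecules are one block for the protein and
# one molecule per residue for every non-protein residue (coarse-grain lipid
# molecules are single residues in GRO files).
build_topology <- function(residue_id, residue_name, particle_name,
                           name_map = default_name_map()) {
  n <- length(particle_name)
  residue_name <- trimws(residue_name)
  particle_name <- trimws(particle_name)
  is_protein <- residue_name %in% name_map$protein_resnames |
    particle_name %in% name_map$protein_particles
  species <- unname(name_map$species_resnames[residue_name])
  role <- ifelse(is_protein, "protein",
                 ifelse(!is.na(species), "ligand", "other"))
  # molecule ids: protein particles share molecule 0; each other residue
  # (identified by a change of residue id or name) is its own molecule
  res_block <- cumsum(c(TRUE, residue_id[-1] != residue_id[-n] |
                          residue_name[-1] != residue_name[-n]))
  mol <- integer(n)
  nonprot <- !is_protein
  if (any(is_protein)) {
    mol[is_protein] <- 0L
    mol[nonprot] <- as.integer(factor(res_block[nonprot]))
  } else {
    mol <- as.integer(factor(res_block))
  }
  head <- rep(FALSE, n)
  for (sp in names(name_map$head_particles)) {
    sel <- !is.na(species) & species == sp &
      particle_name %in% name_map$head_particles[[sp]]
    head[sel] <- TRUE
  }
  data.frame(
    particle_id = seq_len(n) - 1L,
    particle_name = particle_name,
    residue_id = as.integer(residue_id),
    residue_name = residue_name,
    molecule_id = mol,
    role = role,
    species = species,
    is_head = head,
    stringsAsFactors = FALSE
  )
}

#' Construct a trajectory from coordinate arrays
#'
#' @param coords Numeric array, frames x particles x 3, in Angstrom.
#' @param box Per-frame orthorhombic box lengths: a 3-vector (constant box)
#'   or a frames x 3 matrix, in Angstrom.
#' @param frame_interval Frame spacing in ps (default 600).
#' @param topology Topology data frame as produced by the readers; if
#'   `NULL`, a minimal topology is built from `particle_names` and
#'   `residue_ids`.
#' @param particle_names,residue_ids,residue_names Used only when
#'   `topology` is `NULL`.
#' @return A `cg_trajectory`.
#' @export
cg_trajectory <- function(coords, box, frame_interval = 600,
                          topology = NULL, particle_names = NULL,
                          residue_ids = NULL, residue_names = NULL) {
  if (is.null(topology)) {
    np <- dim(coords)[2]
    if (is.null(particle_names)) particle_names <- rep("BB", np)
    if (is.null(residue_ids)) residue_ids <- seq_len(np)
    if (is.null(residue_names)) residue_names <- rep("ALA", np)
    topology <- build_topology(residue_ids, residue_names, particle_names)
  }
  new_cg_trajectory(coords, box, frame_interval, topology)
}

new_cg_trajectory <- function(coords, box, frame_interval, topology) {
  stopifnot(length(dim(coords)) == 3L, dim(coords)[3] == 3L)
  if (!is.matrix(box)) box <- matrix(box, nrow = dim(coords)[1], ncol = 3,
                                     byrow = TRUE)
  if (nrow(box) != dim(coords)[1]) {
    stop("box record count (", nrow(box), ") does not match frame count (",
         dim(coords)[1], ")", call. = FALSE)
  }
  if (any(box <= 0)) stop("box lengths must be > 0 in every frame",
                          call. = FALSE)
  if (!is.numeric(frame_interval) || frame_interval <= 0) {
    stop("frame_interval must be > 0", call. = FALSE)
  }
  if (nrow(topology) != dim(coords)[2]) {
    stop("topology has ", nrow(topology), " particles but coordinates have ",
         dim(coords)[2], call. = FALSE)
  }
  structure(list(coords = coords, box = box,
                 frame_interval = frame_interval, topology = topology),
            class = "cg_trajectory")
}

#' Number of frames / particles in a trajectory
#' @param traj A `cg_trajectory`.
#' @return Integer count.
#' @export
n_frames <- function(traj) dim(traj$coords)[1]

#' @rdname n_frames
#' @export
n_particles <- function(traj) dim(traj$coords)[2]

#' Time of frame i (0-based) in ps
#' @param traj A `cg_trajectory`.
#' @param i 0-based frame index or indices.
#' @export
frame_time <- function(traj, i) i * traj$frame_interval

#' @export
print.cg_trajectory <- function(x, ...) {
  cat(sprintf("Coarse-grain trajectory: %d frames x %d particles, %g ps/frame\n",
              n_frames(x), n_particles(x), x$frame_interval))
  tab <- table(x$topology$role)
  cat("  roles:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  sp <- unique(stats::na.omit(x$topology$species))
  if (length(sp)) cat("  ligand species:", paste(sp, collapse = ", "), "\n")
  invisible(x)
}

# ---- GRO (GROMACS coordinate) reading and writing -------------------------
#
# Fixed-column format, positions in nm (converted to Angstrom internally).
# Multiple concatenated frames (as written by `gmx trjconv -o traj.gro`)
# are supported; only orthorhombic boxes are accepted.

parse_gro_box <- function(line, frame) {
  v <- suppressWarnings(as.numeric(strsplit(trimws(line), "\\s+")[[1]]))
  if (anyNA(v) || !length(v) %in% c(3L, 9L)) {
    stop("malformed GRO box line at frame ", frame, call. = FALSE)
  }
  if (length(v) == 9L && any(v[4:9] != 0)) {
    stop("triclinic boxes are not supported (frame ", frame, ")",
         call. = FALSE)
  }
  if (any(v[1:3] <= 0)) {
    stop("non-positive box at frame ", frame, call. = FALSE)
  }
  v[1:3] * 10  # nm -> Angstrom
}

#' Read a (possibly multi-frame) GRO file
#'
#' @param path Path to a GRO file. Positions are converted from nm to
#'   Angstrom. Concatenated frames are read as a trajectory.
#' @param frame_interval Time between saved frames in ps.
#' @param name_map Name mapping, see [default_name_map()].
#' @return A `cg_trajectory`.
#' @export
read_gro <- function(path, frame_interval = 600, name_map = default_name_map()) {
  lines <- readLines(path)
  if (length(lines) < 3L) stop("truncated GRO file: ", path, call. = FALSE)
  natoms <- suppressWarnings(as.integer(trimws(lines[2])))
  if (is.na(natoms) || natoms < 1L) {
    stop("unreadable particle count in GRO file: ", path, call. = FALSE)
  }
  block <- natoms + 3L
  nframes <- length(lines) %/% block
  if (nframes < 1L || length(lines) %% block != 0L) {
    # allow trailing blank lines
    while (length(lines) && !nzchar(trimws(lines[length(lines)]))) {
      lines <- lines[-length(lines)]
    }
    nframes <- length(lines) %/% block
    if (nframes < 1L || length(lines) %% block != 0L) {
      stop("truncated GRO file at frame ", nframes, ": ", path, call. = FALSE)
    }
  }
  coords <- array(NA_real_, c(nframes, natoms, 3L))
  box <- matrix(NA_real_, nframes, 3L)
  for (f in seq_len(nframes)) {
    off <- (f - 1L) * block
    nat_f <- suppressWarnings(as.integer(trimws(lines[off + 2L])))
    if (is.na(nat_f) || nat_f != natoms) {
      stop("particle count changes at frame ", f - 1L, " of ", path,
           call. = FALSE)
    }
    atom_lines <- lines[(off + 3L):(off + 2L + natoms)]
    x <- suppressWarnings(as.numeric(substr(atom_lines, 21, 28)))
    y <- suppressWarnings(as.numeric(substr(atom_lines, 29, 36)))
    z <- suppressWarnings(as.numeric(substr(atom_lines, 37, 44)))
    if (anyNA(x) || anyNA(y) || anyNA(z)) {
      stop("unreadable coordinates at frame ", f - 1L, " of ", path,
           call. = FALSE)
    }
    coords[f, , 1] <- x * 10
    coords[f, , 2] <- y * 10
    coords[f, , 3] <- z * 10
    box[f, ] <- parse_gro_box(lines[off + 3L + natoms], f - 1L)
  }
  first <- lines[3:(2L + natoms)]
  topo <- build_topology(
    residue_id = as.integer(substr(first, 1, 5)),
    residue_name = substr(first, 6, 10),
    particle_name = substr(first, 11, 15),
    name_map = name_map
  )
  new_cg_trajectory(coords, box, frame_interval, topo)
}

#' Write a trajectory as a (multi-frame) GRO file
#'
#' @param traj A `cg_trajectory` (coordinates in Angstrom; written in nm).
#' @param path Output path.
#' @param title Title line for each frame.
#' @return `path`, invisibly.
#' @export
write_gro <- function(traj, path, title = "cglipidsite trajectory") {
  topo <- traj$topology
  nat <- n_particles(traj)
  con <- file(path, open = "wt")
  on.exit(close(con))
  hdr <- sprintf("%5d%-5s%5s%5d",
                 topo$residue_id %% 100000L,
                 substr(topo$residue_name, 1, 5),
                 substr(topo$particle_name, 1, 5),
                 seq_len(nat) %% 100000L)
  for (f in seq_len(n_frames(traj))) {
    writeLines(c(sprintf("%s, t= %.3f", title, (f - 1) * traj$frame_interval),
                 sprintf("%5d", nat),
                 paste0(hdr, sprintf("%8.3f%8.3f%8.3f",
                                     traj$coords[f, , 1] / 10,
                                     traj$coords[f, , 2] / 10,
                                     traj$coords[f, , 3] / 10)),
                 sprintf("%10.5f%10.5f%10.5f",
                         traj$box[f, 1] / 10, traj$box[f, 2] / 10,
                         traj$box[f, 3] / 10)),
               con)
  }
  invisible(path)
}

# ---- DCD trajectory support ----------------------------------------------

# Minimal CHARMM-style DCD writer (native endianness, single precision,
# orthorhombic unit-cell records). bio3d::read.dcd reads these back, which
# also serves as an independent check on the writer.
write_dcd <- function(traj, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  nf <- n_frames(traj)
  nat <- n_particles(traj)
  wint <- function(x) writeBin(as.integer(x), con, size = 4L)
  # header record: 'CORD' + 20 control integers (icntrl)
  wint(84L)
  writeChar("CORD", con, nchars = 4L, eos = NULL)
  icntrl <- integer(20)
  icntrl[1] <- nf          # number of frames
  icntrl[2] <- 1L          # first step
  icntrl[3] <- 1L          # save interval
  icntrl[4] <- nf          # last step
  icntrl[11] <- 1L         # unit-cell records present
  icntrl[20] <- 24L        # CHARMM version stamp
  wint(icntrl)
  wint(84L)
  # title record
  title <- sprintf("%-80s", "written by cglipidsite")
  wint(4L + 80L)
  wint(1L)
  writeChar(title, con, nchars = 80L, eos = NULL)
  wint(4L + 80L)
  # natom record
  wint(4L); wint(nat); wint(4L)
  for (f in seq_len(nf)) {
    # unit cell: a, cos(gamma), b, cos(beta), cos(alpha), c
    wint(48L)
    writeBin(as.double(c(traj$box[f, 1], 0, traj$box[f, 2], 0, 0,
                         traj$box[f, 3])), con, size = 8L)
    wint(48L)
    for (d in 1:3) {
      wint(4L * nat)
      writeBin(as.numeric(traj$coords[f, , d]), con, size = 4L)
      wint(4L * nat)
    }
  }
  invisible(path)
}

read_dcd_coords <- function(path) {
  xyz <- bio3d::read.dcd(path, verbose = FALSE)
  cell <- attr(xyz, "cell")
  nf <- nrow(xyz)
  nat <- ncol(xyz) / 3L
  coords <- array(NA_real_, c(nf, nat, 3L))
  coords[, , 1] <- xyz[, seq(1, 3 * nat, by = 3), drop = FALSE]
  coords[, , 2] <- xyz[, seq(2, 3 * nat, by = 3), drop = FALSE]
  coords[, , 3] <- xyz[, seq(3, 3 * nat, by = 3), drop = FALSE]
  box <- if (!is.null(cell)) cell[, c(1, 3, 6), drop = FALSE] else NULL
  list(coords = coords, box = box)
}

# ---- top-level loader -----------------------------------------------------

#' Load a topology plus (optionally) a trajectory
#'
#' Reads particle/residue structure from a GRO or PDB file and, when given,
#' frame coordinates from a multi-frame GRO or a DCD trajectory. Particle
#' roles (protein / ligand / other) are inferred from the name mapping.
#' Coordinates are stored in Angstrom; nm-based formats are converted.
#'
#' @param coords_path GRO or PDB file providing the topology (and, for a
#'   single-frame file with no `traj_path`, the single frame).
#' @param traj_path Optional trajectory file (`.gro` multi-frame or `.dcd`).
#'   Its particle count must match the topology.
#' @param frame_interval Time between saved frames in ps (default 600).
#' @param name_map Role/species mapping, see [default_name_map()].
#' @return A `cg_trajectory`.
#' @export
load_trajectory <- function(coords_path, traj_path = NULL,
                            frame_interval = 600,
                            name_map = default_name_map()) {
  ext <- tolower(tools::file_ext(coords_path))
  base <- switch(ext,
    gro = read_gro(coords_path, frame_interval, name_map),
    pdb = read_pdb_structure(coords_path, frame_interval, name_map),
    stop("unsupported topology format '", ext, "' (use GRO or PDB)",
         call. = FALSE)
  )
  if (is.null(traj_path)) return(base)
  text <- tolower(tools::file_ext(traj_path))
  if (text == "gro") {
    tr <- read_gro(traj_path, frame_interval, name_map)
    if (n_particles(tr) != n_particles(base)) {
      stop("trajectory has ", n_particles(tr),
           " particles but topology has ", n_particles(base), call. = FALSE)
    }
    return(new_cg_trajectory(tr$coords, tr$box, frame_interval,
                             base$topology))
  }
  if (text == "dcd") {
    dc <- read_dcd_coords(traj_path)
    if (dim(dc$coords)[2] != n_particles(base)) {
      stop("trajectory has ", dim(dc$coords)[2],
           " particles but topology has ", n_particles(base), call. = FALSE)
    }
    box <- if (is.null(dc$box)) {
      matrix(base$box[1, ], dim(dc$coords)[1], 3, byrow = TRUE)
    } else dc$box
    return(new_cg_trajectory(dc$coords, box, frame_interval, base$topology))
  }
  stop("unsupported trajectory format '", text, "' (use GRO or DCD)",
       call. = FALSE)
}

# Single-structure PDB reader (topology + one frame), via bio3d.
read_pdb_structure <- function(path, frame_interval = 600,
                               name_map = default_name_map()) {
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  topo <- build_topology(at$resno, at$resid, at$elety, name_map)
  coords <- array(NA_real_, c(1L, nrow(at), 3L))
  coords[1, , 1] <- at$x
  coords[1, , 2] <- at$y
  coords[1, , 3] <- at$z
  span <- apply(coords[1, , , drop = FALSE], 3, function(v) diff(range(v)))
  box <- matrix(pmax(span * 2, 1), 1, 3)  # PDB files carry no box; bound it
  new_cg_trajectory(coords, box, frame_interval, topo)
}
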