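# Fixtures and independent brute-force oracles used across the suite.
# Oracles are written as plain loops with no code shared with the package
# internals they check.

# Build a trajectory from a list of per-frame particle coordinate matrices.
traj_from_frames <- function(frames, box = c(50, 50, 50),
                             frame_interval = 600, particle_names = NULL,
                             residue_ids = NULL, residue_names = NULL) {
  np <- nrow(frames[[1]])
  coords <- array(NA_real_, c(length(frames), np, 3))
  for (f in seq_along(frames)) coords[f, , ] <- frames[[f]]
  cg_trajectory(coords, box, frame_interval,
                particle_names = particle_names,
                residue_ids = residue_ids, residue_names = residue_names)
}

# A tiny mixed protein/ligand system: n_res single-bead protein residues on
# a line, plus ceramide AM1 heads at caller-given positions per frame.
mixed_traj <- function(head_positions, prot_positions = NULL,
                       box = c(50, 50, 50), frame_interval = 600) {
  if (is.null(prot_positions)) {
    prot_positions <- cbind(seq(5, 25, by = 5), 10, 10)
  }
  npro <- nrow(prot_positions)
  frames <- lapply(head_positions, function(hp) {
    rbind(prot_positions, matrix(hp, ncol = 3))
  })
  nlig <- nrow(matrix(head_positions[[1]], ncol = 3))
  traj_from_frames(
    frames, box = box, frame_interval = frame_interval,
    particle_names = c(rep("BB", npro), rep("AM1", nlig)),
    residue_ids = c(seq_len(npro), 100L + seq_len(nlig)),
    residue_names = c(rep("ALA", npro), rep("CER", nlig))
  )
}

# Brute-force per-residue occupancy: triple loop over frames, heads and
# residue particles with scalar minimum-image distances.
brute_occupancy <- function(traj, cutoff, species = "ceramide") {
  topo <- traj$topology
  heads <- which(!is.na(topo$species) & topo$species == species &
                   topo$is_head)
  prot <- which(topo$role == "protein")
  res_ids <- unique(topo$residue_id[prot])
  occ <- numeric(length(res_ids))
  for (r in seq_along(res_ids)) {
    parts <- prot[topo$residue_id[prot] == res_ids[r]]
    nhit <- 0L
    for (f in seq_len(n_frames(traj))) {
      hit <- FALSE
      for (h in heads) {
        for (p in parts) {
          d <- 0
          for (k in 1:3) {
            dd <- traj$coords[f, h, k] - traj$coords[f, p, k]
            bb <- traj$box[f, k]
            dd <- dd - bb * round(dd / bb)
            d <- d + dd * dd
          }
          if (sqrt(d) <= cutoff) { hit <- TRUE; break }
        }
        if (hit) break
      }
      if (hit) nhit <- nhit + 1L
    }
    occ[r] <- nhit / n_frames(traj)
  }
  names(occ) <- res_ids
  occ
}

# Brute-force run-length event scanner with end censoring.
brute_events <- function(series) {
  s <- as.integer(as.logical(series))
  n <- length(s)
  starts <- integer(0); lens <- integer(0)
  i <- 1L
  censored <- 0L
  while (i <= n) {
    if (s[i] == 1L) {
      j <- i
      while (j < n && s[j + 1L] == 1L) j <- j + 1L
      if (j == n) censored <- censored + 1L
      else { starts <- c(starts, i - 1L); lens <- c(lens, j - i + 1L) }
      i <- j + 1L
    } else i <- i + 1L
  }
  list(start_frame = starts, n_frames = lens, n_censored = censored)
}

# Brute-force majority vote with edge replication.
brute_vote <- function(series, window = 5L, min_true = 3L) {
  s <- as.integer(as.logical(series))
  n <- length(s)
  half <- (window - 1L) %/% 2L
  out <- logical(n)
  for (i in seq_len(n)) {
    v <- 0L
    for (k in (i - half):(i + half)) {
      kk <- min(max(k, 1L), n)
      v <- v + s[kk]
    }
    out[i] <- v >= min_true
  }
  out
}

# All binary series of a given length, as rows.
all_binary_series <- function(len) {
  m <- as.matrix(expand.grid(rep(list(0:1), len)))
  dimnames(m) <- NULL
  m
}

# Minimal 9-particle single-frame GRO fixture, written as raw text so the
# reader is exercised independently of the package writer.
write_fixture_gro <- function(path) {
  lines <- c(
    "test system",
    "    9",
    "    1ALA    BB    1   0.500   1.000   1.000",
    "    2ALA    BB    2   1.000   1.000   1.000",
    "    3GLU    BB    3   1.500   1.000   1.000",
    "    4GLU    BB    4   2.000   1.000   1.000",
    "    5GLU    BB    5   2.500   1.000   1.000",
    "  101CER   AM1    6   1.600   1.200   1.000",
    "  101CER   AM2    7   1.700   1.200   1.000",
    "  102CER   AM1    8   4.000   4.000   1.000",
    "  103CHOL  ROH    9   0.200   4.000   1.000",
    "   5.00000   5.00000   5.00000"
  )
  writeLines(lines, path)
  path
}

# 3-D rigid transformation helpers for invariance checks.
rot_z <- function(theta) {
  matrix(c(cos(theta), sin(theta), 0,
           -sin(theta), cos(theta), 0,
           0, 0, 1), 3, 3)
}

random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]  # proper rotation only
  q
}
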