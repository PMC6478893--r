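#' Residue-resolved head-group contact occupancy
#'
#' For every protein residue, the fraction of trajectory frames in which at
#' least one head-group particle of any molecule of the given lipid species
#' lies within `contact_cutoff` (minimum image) of at least one particle of
#' that residue. An occupancy of 1.0 means a contact during the entire
#' analyzed time; counting is any-molecule (union over ligand copies), so
#' values never exceed 1. No smoothing is applied here - the majority
#' filter belongs to binding-duration analysis only.
#'
#' @param traj A `cg_trajectory`.
#' @param config An [analysis_config()]; `contact_cutoff` is used.
#' @param species Ligand species label present in the topology (e.g.
#'   `"ceramide"`).
#' @return A `contact_map`: data frame with columns `residue_id`,
#'   `residue_name`, `species`, `occupancy`, plus attributes `n_frames` and
#'   `head_particles`.
#' @export
residue_contact_occupancy <- function(traj, config = analysis_config(),
                                      species) {
  topo <- traj$topology
  heads <- which(!is.na(topo$species) & topo$species == species &
                   topo$is_head)
  if (!length(heads)) {
    stop("no head particles of species '", species, "' in the topology",
         call. = FALSE)
  }
  prot <- which(topo$role == "protein")
  if (!length(prot)) stop("no protein residues in the topology",
                          call. = FALSE)
  res_ids <- unique(topo$residue_id[prot])
  nf <- n_frames(traj)
  cut2 <- config$contact_cutoff^2
  # contact[f, r]: any head within cutoff of any particle of residue r
  contact <- matrix(FALSE, nf, length(res_ids))
  res_index <- split(prot, factor(topo$residue_id[prot], levels = res_ids))
  for (h in heads) {
    a <- traj$coords[, h, , drop = FALSE]
    dim(a) <- c(nf, 3L)
    d2 <- min_image_sq(a, traj$coords[, prot, , drop = FALSE], traj$box)
    within <- d2 <= cut2
    for (r in seq_along(res_ids)) {
      cols <- match(res_index[[r]], prot)
      contact[, r] <- contact[, r] |
        (rowSums(within[, cols, drop = FALSE]) > 0L)
    }
  }
  out <- data.frame(
    residue_id = res_ids,
    residue_name = topo$residue_name[match(res_ids, topo$residue_id)],
    species = species,
    occupancy = colMeans(contact),
    stringsAsFactors = FALSE
  )
  attr(out, "n_frames") <- nf
  attr(out, "head_particles") <- unique(topo$particle_name[heads])
  class(out) <- c("contact_map", "data.frame")
  out
}

#' Call binding-site residues from a contact map
#'
#' Residues whose occupancy is strictly greater than the threshold, in
#' residue order. The threshold marks the background level of non-site
#' residues, so ties at background are not called.
#'
#' @param cmap A `contact_map` from [residue_contact_occupancy()].
#' @param config An [analysis_config()]; `occupancy_threshold` is used.
#' @return Integer vector of residue ids.
#' @export
call_binding_site <- function(cmap, config = analysis_config()) {
  if (!nrow(cmap)) stop("empty contact map", call. = FALSE)
  cmap$residue_id[cmap$occupancy > config$occupancy_threshold]
}

#' Write / read a contact-occupancy table
#'
#' Tab-separated with columns `residue_id`, `residue_name`, `species`,
#' `occupancy` (6 decimals, round-trip safe at that precision).
#'
#' @param cmap A `contact_map`.
#' @param path Output path.
#' @return `path` invisibly (`write`); a `contact_map` (`read`).
#' @export
write_contact_table <- function(cmap, path) {
  if (!nrow(cmap)) stop("empty contact map", call. = FALSE)
  df <- as.data.frame(cmap)
  df$occupancy <- sprintf("%.6f", df$occupancy)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_contact_table
#' @export
read_contact_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  class(df) <- c("contact_map", "data.frame")
  df
}
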