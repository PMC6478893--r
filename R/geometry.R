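#' Minimum-image distance under orthorhombic periodic boundaries
#'
#' @param p,q Numeric 3-vectors or n x 3 matrices of positions (Angstrom).
#' @param box Positive 3-vector of box edge lengths (Angstrom).
#' @return Euclidean distance(s) to the nearest periodic image.
#' @export
min_image_distance <- function(p, q, box) {
  if (any(box <= 0)) stop("box lengths must be > 0", call. = FALSE)
  if (is.null(dim(p))) p <- matrix(p, ncol = 3, byrow = FALSE)
  if (is.null(dim(q))) q <- matrix(q, ncol = 3, byrow = FALSE)
  d <- p - q
  d <- d - rep(box, each = nrow(d)) * round(d / rep(box, each = nrow(d)))
  out <- sqrt(rowSums(d * d))
  if (length(out) == 1L) out[[1]] else out
}

# Squared minimum-image distances between one particle and a set of
# particles, vectorized across frames.
# a: frames x 3 coordinates of one particle; b: frames x m x 3 (or m x 3
# static); box: frames x 3. Returns frames x m matrix.
min_image_sq <- function(a, b, box) {
  nf <- nrow(a)
  if (length(dim(b)) == 2L) {
    m <- nrow(b)
    acc <- matrix(0, nf, m)
    for (d in 1:3) {
      dd <- outer(a[, d], b[, d], "-")
      dd <- dd - box[, d] * round(dd / box[, d])
      acc <- acc + dd * dd
    }
  } else {
    m <- dim(b)[2]
    acc <- matrix(0, nf, m)
    for (d in 1:3) {
      dd <- b[, , d] - a[, d]
      dd <- dd - box[, d] * round(dd / box[, d])
      acc <- acc + dd * dd
    }
  }
  acc
}

#' RMSD after optimal rigid-body superposition
#'
#' Root-mean-square deviation over explicitly paired particles after the
#' translation + rotation that minimizes it (Kabsch superposition, via
#' bio3d). The pairing is always supplied by the caller - typically from
#' [pairing_from_alignment()] - so the operation never guesses
#' correspondences.
#'
#' @param struct_a,struct_b Numeric n x 3 coordinate matrices (Angstrom).
#' @param pairing Two-column integer matrix/data.frame of 1-based particle
#'   indices, column 1 into `struct_a`, column 2 into `struct_b`. At least
#'   3 pairs are required for a non-degenerate superposition.
#' @return The RMSD in Angstrom.
#' @export
barrel_rmsd <- function(struct_a, struct_b, pairing) {
  pairing <- as.matrix(pairing)
  if (is.null(dim(pairing)) || ncol(pairing) != 2L || nrow(pairing) < 3L) {
    stop("pairing must supply at least 3 index pairs", call. = FALSE)
  }
  ia <- as.integer(pairing[, 1]); ib <- as.integer(pairing[, 2])
  if (any(ia < 1L) || any(ia > nrow(struct_a)) ||
      any(ib < 1L) || any(ib > nrow(struct_b))) {
    stop("pairing indices out of range", call. = FALSE)
  }
  a <- as.numeric(t(struct_a[ia, , drop = FALSE]))
  b <- as.numeric(t(struct_b[ib, , drop = FALSE]))
  bio3d::rmsd(a, b, fit = TRUE)
}

#' Residue pairing from a pairwise sequence alignment
#'
#' Builds the index pairing for [barrel_rmsd()] from a global pairwise
#' alignment (Needleman-Wunsch, via Biostrings) of two one-letter residue
#' sequences: every aligned, non-gap column yields one index pair.
#'
#' @param seq_a,seq_b One-letter residue sequences (single strings or
#'   character vectors of single letters).
#' @param gap_opening,gap_extension Alignment gap penalties.
#' @return Two-column integer matrix of paired residue positions.
#' @export
pairing_from_alignment <- function(seq_a, seq_b, gap_opening = 10,
                                   gap_extension = 0.5) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    stop("Biostrings is required for pairing_from_alignment()", call. = FALSE)
  }
  if (length(seq_a) > 1L) seq_a <- paste(seq_a, collapse = "")
  if (length(seq_b) > 1L) seq_b <- paste(seq_b, collapse = "")
  aln <- Biostrings::pairwiseAlignment(
    seq_a, seq_b, type = "global",
    substitutionMatrix = NULL,
    gapOpening = gap_opening, gapExtension = gap_extension
  )
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  pb <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  ia <- cumsum(pa != "-")
  ib <- cumsum(pb != "-")
  keep <- pa != "-" & pb != "-"
  cbind(a = ia[keep], b = ib[keep])
}
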