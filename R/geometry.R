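# Pore geometry: site centers, opposite-subunit (diagonal) distances,
# SF backbone RMSD, per-frame distance tables.

#' Center of a binding site
#'
#' The center of a binding site is the unweighted mean position of the eight
#' oxygen atoms delineating it (two rings of four).
#'
#' @param topology a [build_topology()] result.
#' @param site site label (`"S0"`..`"S4"`) or index 1-5.
#' @param frame an `n_atoms x 3` coordinate matrix (e.g. [frame_coords()]).
#' @return numeric 3-vector (Angstrom).
#' @export
site_center <- function(topology, site, frame) {
  stopifnot(inherits(topology, "channel_topology"))
  sd <- if (is.character(site)) topology$sites[[site]]
        else topology$sites[[as.integer(site)]]
  if (is.null(sd)) stop("unknown site: ", site)
  idx <- sd$atoms
  if (any(idx > nrow(frame)))
    stop("site atoms cannot be resolved in the supplied frame")
  colMeans(frame[idx, , drop = FALSE])
}

# Farthest-neighbour perfect matching of 4 points into the two diagonal
# pairs: pair point 1 with the farthest of the other three; the remaining
# two points form the second pair. For a (near-)square this selects the two
# diagonals; it needs no chain-label convention and works on arbitrarily
# labelled assemblies.
.diagonal_pairs <- function(p) {
  stopifnot(nrow(p) == 4L)
  d1 <- which.max(colSums((t(p[2:4, , drop = FALSE]) - p[1, ])^2)) + 1L
  rest <- setdiff(2:4, d1)
  list(c(1L, d1), rest)
}

#' Opposite-subunit distance of an atom
#'
#' For the four copies of one atom (one per subunit), identifies the two
#' diagonal subunit pairs by farthest-neighbour matching and reports both
#' diagonal distances and their mean. For a perfectly four-fold symmetric
#' ring the mean equals twice the radial distance from the pore axis.
#'
#' @param fs a [frame_set()].
#' @param resno residue number.
#' @param elety atom name (e.g. `"CA"`, `"O"`).
#' @param frame frame index (default 1).
#' @return object of class `distance_record`: list with `resno`, `elety`,
#'   `pairwise_distances` (the two diagonals, Angstrom) and `mean`.
#' @export
opposite_distance <- function(fs, resno, elety, frame = 1L) {
  stopifnot(inherits(fs, "frame_set"))
  idx <- .resolve_ring(fs$atoms, resno, elety, "opposite-distance")
  p <- frame_coords(fs, frame)[idx, , drop = FALSE]
  pr <- .diagonal_pairs(p)
  d <- vapply(pr, function(ij) sqrt(sum((p[ij[1], ] - p[ij[2], ])^2)),
              numeric(1))
  structure(list(resno = resno, elety = elety,
                 pairwise_distances = d, mean = mean(d)),
            class = "distance_record")
}

#' @export
print.distance_record <- function(x, ...) {
  cat(sprintf("residue %d %s: diagonals %.2f / %.2f A, mean %.2f A\n",
              x$resno, x$elety, x$pairwise_distances[1],
              x$pairwise_distances[2], x$mean))
  invisible(x)
}

#' Opposite-distance statistics over frames
#'
#' Computes, for each requested (residue, atom) row, the arithmetic mean and
#' standard deviation over frames of the per-frame mean diagonal distance.
#' This is the table layout conventionally used to report carbonyl-oxygen
#' diameters at the binding-site boundaries.
#'
#' @param fs a [frame_set()] with at least one frame.
#' @param rows data.frame or two-column matrix with columns `resno`, `elety`.
#' @return data.frame with columns `resno`, `elety`, `mean`, `sd`,
#'   `n_frames` (distances in Angstrom at full precision; round to one
#'   decimal for display).
#' @export
distance_table <- function(fs, rows) {
  stopifnot(inherits(fs, "frame_set"))
  if (n_frames(fs) < 1L) stop("frame set is empty")
  if (is.matrix(rows)) rows <- as.data.frame(rows)
  if (!all(c("resno", "elety") %in% names(rows)))
    stop("`rows` must have columns resno and elety")
  nf <- n_frames(fs)
  out <- lapply(seq_len(nrow(rows)), function(i) {
    idx <- .resolve_ring(fs$atoms, rows$resno[i], rows$elety[i],
                         "distance-table")
    # vectorised over frames: the two diagonals from farthest matching per frame
    m <- vapply(seq_len(nf), function(f) {
      p <- fs$coords[idx, , f]
      pr <- .diagonal_pairs(p)
      mean(vapply(pr, function(ij) sqrt(sum((p[ij[1], ] - p[ij[2], ])^2)),
                  numeric(1)))
    }, numeric(1))
    data.frame(resno = rows$resno[i], elety = rows$elety[i],
               mean = mean(m), sd = if (nf > 1L) stats::sd(m) else 0,
               n_frames = nf)
  })
  do.call(rbind, out)
}

# Gather mapped backbone coordinates in a fixed, reproducible order:
# residue pair, then subunit 0..3, then backbone atom name.
.mapped_coords <- function(fs, frame, resnos, map, column) {
  at <- fs$atoms
  rows <- list()
  for (i in seq_len(nrow(map$pairs))) {
    rn <- map$pairs[i, column]
    for (su in 0:3) {
      for (nm in map$backbone_atom_names) {
        hit <- which(!is.na(at$subunit) & at$subunit == su &
                       at$resno == rn & at$elety == nm)
        if (length(hit) == 0L)
          stop(sprintf("mapped atom missing: residue %d atom '%s' subunit %d",
                       rn, nm, su))
        rows[[length(rows) + 1L]] <- hit[1L]
      }
    }
  }
  frame[unlist(rows), , drop = FALSE]
}

#' SF backbone RMSD against a reference structure
#'
#' Root-mean-square deviation of the mapped backbone atoms (all four
#' subunits) of the selectivity filter from the corresponding atoms of a
#' reference structure. With `superpose = TRUE` (the default) an optimal
#' rigid-body least-squares (Kabsch) superposition onto the reference is
#' applied first; with `superpose = FALSE` the deviation is computed in the
#' common axis-aligned frame, so a uniform translation by `t` yields
#' RMSD `|t|`.
#'
#' @param query a [frame_set()]; the RMSD is computed for every frame.
#' @param reference a [frame_set()] (its frame `ref_frame` is used).
#' @param map a [map_reference()] result.
#' @param superpose apply Kabsch superposition first (default TRUE).
#' @param ref_frame reference frame index (default 1).
#' @return numeric vector, one RMSD (Angstrom) per query frame.
#' @export
sf_rmsd <- function(query, reference, map, superpose = TRUE, ref_frame = 1L) {
  stopifnot(inherits(query, "frame_set"), inherits(reference, "frame_set"),
            inherits(map, "residue_map"))
  ref <- .mapped_coords(reference, frame_coords(reference, ref_frame),
                        NULL, map, 2L)
  vapply(seq_len(n_frames(query)), function(f) {
    q <- .mapped_coords(query, frame_coords(query, f), NULL, map, 1L)
    if (nrow(q) != nrow(ref))
      stop(sprintf("mapped atom count mismatch: %d (query) vs %d (reference)",
                   nrow(q), nrow(ref)))
    if (superpose) {
      fitted <- bio3d::fit.xyz(fixed = as.vector(t(ref)),
                               mobile = as.vector(t(q)),
                               fixed.inds = seq_len(3L * nrow(ref)),
                               mobile.inds = seq_len(3L * nrow(q)))
      q <- matrix(fitted, ncol = 3L, byrow = TRUE)
    }
    sqrt(mean(rowSums((q - ref)^2)))
  }, numeric(1))
}
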