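# Channel topology: site definitions, atom selections, cavity probe and
# residue correspondence for RMSD.

#' Built-in site boundary schemes
#'
#' Loads a named K+ binding-site boundary scheme from the package's YAML
#' configuration (`herg` and `kcsa` ship with the package), or reads an
#' arbitrary scheme file of the same layout. A scheme lists six oxygen rings
#' (residue number + atom name, applied to all four subunits) ordered from
#' the extracellular to the intracellular side; consecutive ring pairs bound
#' binding sites S0-S4.
#'
#' @param name `"herg"` or `"kcsa"`, or a name present in `file`.
#' @param file optional YAML file with the same structure as the shipped
#'   `site_schemes.yaml`.
#' @return list with `sf_range` (inclusive residue interval) and `rings`
#'   (list of `list(resno, elety)`).
#' @export
sf_scheme <- function(name = "herg", file = NULL) {
  if (is.null(file))
    file <- system.file("extdata", "site_schemes.yaml", package = "sfstate",
                        mustWork = TRUE)
  cfg <- yaml::read_yaml(file)
  if (!name %in% names(cfg))
    stop(sprintf("no site scheme '%s' in %s (available: %s)", name, file,
                 paste(setdiff(names(cfg), "residue_maps"), collapse = ", ")))
  sc <- cfg[[name]]
  sc$rings <- lapply(sc$rings, function(r)
    list(resno = as.integer(r$resno), elety = as.character(r$elety)))
  sc$sf_range <- as.integer(unlist(sc$sf_range))
  sc
}

# Resolve one (resno, elety) ring across the four subunits; returns atom-table
# row indices ordered by subunit 0..3.
.resolve_ring <- function(atoms, resno, elety, context = "ring") {
  idx <- integer(4L)
  for (su in 0:3) {
    hit <- which(!is.na(atoms$subunit) & atoms$subunit == su &
                   atoms$resno == resno & atoms$elety == elety)
    if (length(hit) == 0L)
      stop(sprintf("cannot resolve %s atom: residue %d, atom '%s', subunit %d",
                   context, resno, elety, su))
    idx[su + 1L] <- hit[1L]
  }
  idx
}

#' Build the channel topology
#'
#' Resolves a site boundary scheme against a structure, producing the five
#' binding-site definitions S0-S4 (8 delineating oxygen atoms each), the
#' potassium and oxygen atom selections, and the intracellular cavity probe
#' segment (a pore-axis segment starting 2 Angstrom below the lower boundary
#' of S4 and extending 20 Angstrom toward the intracellular side).
#'
#' @param fs a [frame_set()] with four assigned subunits.
#' @param scheme a scheme from [sf_scheme()], or a scheme name string.
#' @param pore_axis unit 3-vector of the pore axis, pointing extracellular;
#'   default the z axis (trajectories are assumed axis-aligned).
#' @param cavity_offset distance below the lower boundary of S4 at which the
#'   cavity probe segment starts (Angstrom, default 2).
#' @param cavity_length length of the cavity probe segment (Angstrom,
#'   default 20).
#' @param cavity_spacing spacing of probe points along the segment
#'   (Angstrom, default 0.5, i.e. 41 points over 20 Angstrom).
#' @param k_cutoff,oxygen_cutoff switching-function cutoffs in Angstrom for
#'   K+ occupancy (default 1.4) and oxygen coordination/hydration
#'   (default 3.2).
#' @return object of class `channel_topology` with elements `sites` (list of
#'   five site definitions, each `list(label, ring_upper, ring_lower, atoms)`),
#'   `sf_range`, `pore_axis`, `potassium`, `oxygen` (atom index selections),
#'   `cavity` and the cutoffs.
#' @export
build_topology <- function(fs, scheme = "herg", pore_axis = c(0, 0, 1),
                           cavity_offset = 2, cavity_length = 20,
                           cavity_spacing = 0.5,
                           k_cutoff = 1.4, oxygen_cutoff = 3.2) {
  stopifnot(inherits(fs, "frame_set"))
  if (is.character(scheme)) scheme <- sf_scheme(scheme)
  rings <- scheme$rings
  if (length(rings) != 6L)
    stop("a site scheme must define exactly 6 oxygen rings (5 sites)")
  pore_axis <- as.numeric(pore_axis)
  if (length(pore_axis) != 3L || sum(pore_axis^2) == 0)
    stop("`pore_axis` must be a non-zero 3-vector")
  pore_axis <- pore_axis / sqrt(sum(pore_axis^2))

  at <- fs$atoms
  ring_idx <- lapply(rings, function(r)
    .resolve_ring(at, r$resno, r$elety, "site-scheme"))
  sites <- lapply(0:4, function(s) {
    list(label = paste0("S", s),
         ring_upper = rings[[s + 1L]],
         ring_lower = rings[[s + 2L]],
         atoms = c(ring_idx[[s + 1L]], ring_idx[[s + 2L]]))
  })
  names(sites) <- vapply(sites, `[[`, "", "label")

  potassium <- which(at$element == "K")
  oxygen <- which(at$element == "O")
  if (length(intersect(potassium, oxygen)))
    stop("potassium and oxygen selections overlap")

  structure(list(
    sf_range = if (!is.null(scheme$sf_range)) scheme$sf_range
               else range(vapply(rings, `[[`, 1L, "resno")),
    pore_axis = pore_axis,
    sites = sites,
    bottom_ring = ring_idx[[6L]],
    sf_atoms = unique(unlist(ring_idx)),
    potassium = potassium,
    oxygen = oxygen,
    cavity = list(offset = cavity_offset, length = cavity_length,
                  spacing = cavity_spacing),
    k_cutoff = k_cutoff, oxygen_cutoff = oxygen_cutoff),
    class = "channel_topology")
}

#' @export
print.channel_topology <- function(x, ...) {
  cat(sprintf("channel_topology: SF residues %d-%d, sites %s\n",
              x$sf_range[1], x$sf_range[2],
              paste(names(x$sites), collapse = " ")))
  cat(sprintf("  %d K+ ions, %d oxygen atoms; cavity probe %g+%g A, %g A spacing\n",
              length(x$potassium), length(x$oxygen),
              x$cavity$offset, x$cavity$length, x$cavity$spacing))
  cat(sprintf("  cutoffs: K+ %g A, oxygen %g A\n", x$k_cutoff, x$oxygen_cutoff))
  invisible(x)
}

#' Map residues between a query and a reference structure
#'
#' Builds the residue correspondence used by [sf_rmsd()]: a bijective list of
#' (query residue, reference residue) pairs plus the set of backbone atom
#' names compared. Every mapped residue must resolve in all four subunits of
#' both structures.
#'
#' The default backbone atom set is N, CA, C, O; it is user-overridable since
#' "backbone atoms" is convention-dependent.
#'
#' @param query,reference [frame_set()] objects.
#' @param pairs two-column matrix or data.frame (query resno, reference
#'   resno), or a list with elements `query` and `reference`.
#' @param backbone_atom_names atom names used for the RMSD.
#' @return object of class `residue_map`.
#' @export
map_reference <- function(query, reference, pairs,
                          backbone_atom_names = c("N", "CA", "C", "O")) {
  stopifnot(inherits(query, "frame_set"), inherits(reference, "frame_set"))
  if (is.list(pairs) && !is.data.frame(pairs) &&
      all(c("query", "reference") %in% names(pairs)))
    pairs <- cbind(pairs$query, pairs$reference)
  pairs <- as.matrix(pairs)
  if (ncol(pairs) != 2L) stop("`pairs` must have two columns")
  storage.mode(pairs) <- "integer"
  if (anyDuplicated(pairs[, 1]) || anyDuplicated(pairs[, 2]))
    stop("residue pairs must form a bijection: duplicated residue number")
  for (i in seq_len(nrow(pairs))) {
    for (nm in backbone_atom_names) {
      for (su in 0:3) {
        qh <- any(!is.na(query$atoms$subunit) & query$atoms$subunit == su &
                    query$atoms$resno == pairs[i, 1] & query$atoms$elety == nm)
        rh <- any(!is.na(reference$atoms$subunit) &
                    reference$atoms$subunit == su &
                    reference$atoms$resno == pairs[i, 2] &
                    reference$atoms$elety == nm)
        if (!qh || !rh)
          stop(sprintf(
            "unmappable residue pair (%d, %d): atom '%s' missing in subunit %d of the %s",
            pairs[i, 1], pairs[i, 2], nm, su,
            if (!qh) "query" else "reference"))
      }
    }
  }
  structure(list(pairs = pairs, backbone_atom_names = backbone_atom_names),
            class = "residue_map")
}

#' @export
print.residue_map <- function(x, ...) {
  cat(sprintf("residue_map: %d residue pairs x 4 subunits, backbone atoms {%s}\n",
              nrow(x$pairs), paste(x$backbone_atom_names, collapse = ", ")))
  invisible(x)
}
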