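# Per-frame occupancy features: K+ occupancy and oxygen coordination of
# binding sites S0-S4, cavity ion presence and hydration along the pore
# axis, and cavity dwell events.
#
# All routines are vectorised over frames (each atom contributes one
# length-n_frames distance vector), so feature extraction is strictly
# per-frame and commutes exactly with frame striding.

# Axis geometry shared by the cavity routines. Returns the axis direction,
# the per-frame foot point of the axis (projection of the SF centroid onto
# the plane t = 0) and the per-frame axial position of the lower boundary of
# S4 (mean projection of the bottom oxygen ring).
.axis_geometry <- function(fs, topology) {
  a <- topology$pore_axis
  ct <- .center_track(fs, topology$sf_atoms)          # 3 x nf
  t_c <- colSums(ct * a)
  o_perp <- ct - outer(a, t_c)                         # 3 x nf
  tb <- colMeans(do.call(rbind, lapply(topology$bottom_ring, function(j)
    colSums(.atom_track(fs, j) * a))))                 # length-nf vector
  list(a = a, o_perp = o_perp, t_bottom = tb)
}

# Sum of switching contributions from a selection at a moving probe track.
# probe: 3 x nf matrix. Returns length-nf vector.
.coord_track <- function(fs, selection, probe, d_c) {
  acc <- numeric(ncol(probe))
  for (j in selection) {
    p <- .atom_track(fs, j)
    d <- sqrt(colSums((p - probe)^2))
    acc <- acc + .sw(d, d_c)
  }
  acc
}

# n_sites x ... per-site coordination over frames for an atom selection.
.site_coordination_matrix <- function(fs, topology, selection, d_c) {
  nf <- n_frames(fs)
  out <- matrix(0, nrow = nf, ncol = 5L,
                dimnames = list(NULL, names(topology$sites)))
  for (s in seq_along(topology$sites)) {
    center <- .center_track(fs, topology$sites[[s]]$atoms)
    out[, s] <- .coord_track(fs, selection, center, d_c)
  }
  out
}

#' K+ occupancy of binding sites S0-S4
#'
#' For every frame, evaluates the coordination number of all potassium ions
#' at each binding-site center with the K+ cutoff (default 1.4 Angstrom).
#' The value tends to 1 when an ion sits at the site center and to 0 for an
#' empty site; it is invariant under relabeling of the ions.
#'
#' @param fs a [frame_set()].
#' @param topology a [build_topology()] result.
#' @return `n_frames x 5` matrix with columns `S0`..`S4`.
#' @export
site_k_occupancy <- function(fs, topology) {
  stopifnot(inherits(fs, "frame_set"), inherits(topology, "channel_topology"))
  .site_coordination_matrix(fs, topology, topology$potassium,
                            topology$k_cutoff)
}

#' Oxygen coordination of binding sites S0-S4
#'
#' For every frame, evaluates the coordination number of all oxygen atoms in
#' the system (protein and water) at each binding-site center with the
#' hydration-shell cutoff (default 3.2 Angstrom). Values above ~5 at every
#' site are characteristic of a structurally intact, conductive filter;
#' widening of the extracellular sites pushes S0/S1 below 5.
#'
#' @inheritParams site_k_occupancy
#' @return `n_frames x 5` matrix with columns `S0`..`S4`.
#' @export
site_oxygen_coordination <- function(fs, topology) {
  stopifnot(inherits(fs, "frame_set"), inherits(topology, "channel_topology"))
  .site_coordination_matrix(fs, topology, topology$oxygen,
                            topology$oxygen_cutoff)
}

# n_points x nf coordination profile along the cavity axis segment.
.cavity_profile_matrix <- function(fs, topology, selection, d_c) {
  g <- .axis_geometry(fs, topology)
  cav <- topology$cavity
  npts <- as.integer(round(cav$length / cav$spacing)) + 1L
  nf <- n_frames(fs)
  out <- matrix(0, nrow = npts, ncol = nf)
  for (k in seq_len(npts)) {
    t_k <- g$t_bottom - cav$offset - (k - 1L) * cav$spacing
    probe <- g$o_perp + outer(g$a, t_k)
    out[k, ] <- .coord_track(fs, selection, probe, d_c)
  }
  out
}

#' Coordination-number profile along the cavity axis
#'
#' Evaluates the coordination number at equally spaced points along the pore
#' axis, starting 2 Angstrom below the lower boundary of S4 and extending 20
#' Angstrom toward the intracellular compartment (both configurable in the
#' topology). `species = "potassium"` profiles K+ with the 1.4 Angstrom
#' cutoff; `species = "oxygen"` profiles all oxygen atoms with the 3.2
#' Angstrom cutoff.
#'
#' @inheritParams site_k_occupancy
#' @param species `"potassium"` or `"oxygen"`.
#' @param frame frame index (default 1).
#' @return object of class `axis_profile`: list with `points`
#'   (`n_points x 3` matrix), `spacing` and `values`.
#' @export
cavity_axis_profile <- function(fs, topology,
                                species = c("potassium", "oxygen"),
                                frame = 1L) {
  stopifnot(inherits(fs, "frame_set"), inherits(topology, "channel_topology"))
  species <- match.arg(species)
  sel <- if (species == "potassium") topology$potassium else topology$oxygen
  d_c <- if (species == "potassium") topology$k_cutoff else
    topology$oxygen_cutoff
  one <- subset_frames(fs, frame)
  vals <- .cavity_profile_matrix(one, topology, sel, d_c)[, 1L]
  g <- .axis_geometry(one, topology)
  cav <- topology$cavity
  npts <- length(vals)
  t_k <- g$t_bottom[1L] - cav$offset - (seq_len(npts) - 1L) * cav$spacing
  pts <- t(g$o_perp[, 1L] + outer(topology$pore_axis, t_k))
  structure(list(points = pts, spacing = cav$spacing, values = vals,
                 species = species),
            class = "axis_profile")
}

#' @export
print.axis_profile <- function(x, ...) {
  cat(sprintf("axis_profile (%s): %d points, %.2f A spacing, range [%.3f, %.3f]\n",
              x$species, length(x$values), x$spacing,
              min(x$values), max(x$values)))
  invisible(x)
}

#' Presence of K+ in the intracellular cavity
#'
#' The maximum of the potassium coordination profile along the cavity axis
#' segment, per frame. Using the maximum makes the estimate independent of
#' where along the axis the ion sits, so it reports the presence of K+ in
#' the cavity regardless of the exact ion position.
#'
#' @inheritParams site_k_occupancy
#' @return numeric vector, one value per frame.
#' @export
cavity_k_presence <- function(fs, topology) {
  stopifnot(inherits(fs, "frame_set"), inherits(topology, "channel_topology"))
  prof <- .cavity_profile_matrix(fs, topology, topology$potassium,
                                 topology$k_cutoff)
  apply(prof, 2L, max)
}

#' Hydration of the intracellular cavity
#'
#' The minimum of the oxygen coordination profile along the cavity axis
#' segment, per frame. The minimum flags stretches of the axis that lack
#' nearby water oxygens (a hydration gap), which can oppose ion conduction.
#'
#' @inheritParams site_k_occupancy
#' @return numeric vector, one value per frame.
#' @export
cavity_hydration <- function(fs, topology) {
  stopifnot(inherits(fs, "frame_set"), inherits(topology, "channel_topology"))
  prof <- .cavity_profile_matrix(fs, topology, topology$oxygen,
                                 topology$oxygen_cutoff)
  apply(prof, 2L, min)
}

#' Full per-frame feature table
#'
#' Computes the twelve per-frame features in one pass: K+ occupancy of
#' S0-S4 (`s0_k`..`s4_k`), oxygen coordination of S0-S4 (`s0_oxy`..`s4_oxy`),
#' cavity K+ presence (`cavity_k`) and cavity hydration (`cavity_w`).
#'
#' @inheritParams site_k_occupancy
#' @return data.frame with a `frame` column followed by the 12 features.
#' @export
frame_features <- function(fs, topology) {
  stopifnot(inherits(fs, "frame_set"), inherits(topology, "channel_topology"))
  kocc <- site_k_occupancy(fs, topology)
  oxy <- site_oxygen_coordination(fs, topology)
  out <- data.frame(frame = seq_len(n_frames(fs)))
  for (s in 0:4) out[[paste0("s", s, "_k")]] <- kocc[, s + 1L]
  for (s in 0:4) out[[paste0("s", s, "_oxy")]] <- oxy[, s + 1L]
  out$cavity_k <- cavity_k_presence(fs, topology)
  out$cavity_w <- cavity_hydration(fs, topology)
  out
}

#' Write / read a feature table as CSV
#'
#' One row per frame; reloadable without trajectory access.
#' @param features a [frame_features()] data.frame.
#' @param path CSV file path.
#' @return `path` (write) or the features data.frame (read).
#' @export
write_features <- function(features, path) {
  utils::write.csv(features, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  if (!file.exists(path)) stop("features file not found: ", path)
  utils::read.csv(path)
}

#' Cavity ion dwell events
#'
#' Detects, for every potassium ion, contiguous intervals during which the
#' ion resides inside the cavity probe segment: its axial projection lies
#' within the segment and its radial distance from the pore axis is at most
#' the K+ cutoff (1.4 Angstrom). Interruptions of at most `gap_tolerance`
#' frames (default 2) do not split an event, tolerating saving-interval
#' jitter. `exit_frame` is exclusive (the first frame after the ion has
#' left), so `duration = (exit_frame - entry_frame) * frame_interval`.
#'
#' @inheritParams site_k_occupancy
#' @param threshold_ns durations strictly greater than this count as stable
#'   binding (default 10 ns).
#' @param gap_tolerance maximum number of consecutive outside frames that do
#'   not terminate an event.
#' @return list with `events` (data.frame: `ion_id`, `entry_frame`,
#'   `exit_frame`, `duration_ns`) and `any_stable` (logical).
#' @export
dwell_events <- function(fs, topology, threshold_ns = 10, gap_tolerance = 2L) {
  stopifnot(inherits(fs, "frame_set"), inherits(topology, "channel_topology"))
  if (is.null(fs$frame_interval) || !is.finite(fs$frame_interval))
    stop("frame_interval is not configured on this frame set")
  g <- .axis_geometry(fs, topology)
  cav <- topology$cavity
  t_hi <- g$t_bottom - cav$offset
  t_lo <- g$t_bottom - cav$offset - cav$length
  ev <- list()
  for (j in topology$potassium) {
    p <- .atom_track(fs, j)
    tt <- colSums(p * g$a)
    radial <- sqrt(colSums((p - g$o_perp - outer(g$a, tt))^2))
    inside <- tt <= t_hi & tt >= t_lo & radial <= topology$k_cutoff
    runs <- rle(inside)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    iv <- cbind(starts[runs$values], ends[runs$values])
    if (nrow(iv) == 0L) next
    # merge runs separated by short gaps
    merged <- iv[1L, , drop = FALSE]
    if (nrow(iv) > 1L) for (r in 2:nrow(iv)) {
      if (iv[r, 1] - merged[nrow(merged), 2] - 1L <= gap_tolerance)
        merged[nrow(merged), 2] <- iv[r, 2]
      else merged <- rbind(merged, iv[r, , drop = FALSE])
    }
    for (r in seq_len(nrow(merged))) {
      ev[[length(ev) + 1L]] <- data.frame(
        ion_id = fs$atoms$eleno[j],
        entry_frame = merged[r, 1],
        exit_frame = merged[r, 2] + 1L,
        duration_ns = (merged[r, 2] + 1L - merged[r, 1]) * fs$frame_interval)
    }
  }
  events <- if (length(ev)) do.call(rbind, ev) else
    data.frame(ion_id = integer(), entry_frame = integer(),
               exit_frame = integer(), duration_ns = numeric())
  list(events = events, any_stable = any(events$duration_ns > threshold_ns))
}
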