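# Synthetic tetrameric selectivity-filter ensembles with planted ground
# truth: six stacked rings of four carbonyl-oxygen pseudo-atoms (defining
# binding sites S0-S4), Calpha pseudo-atoms on wider rings, K+ ions placed
# at chosen site centers per frame, a water column filling the intracellular
# cavity (with optional hydration gap), cavity-ion dwell schedules, and
# isotropic Gaussian thermal noise.
#
# The generator produces a pseudo-atom filter rather than a full protein:
# every metric implemented by the package only sees the site-delineating
# oxygens, ions and water oxygens, so this is sufficient ground truth while
# keeping generation trivial and fast.

.ring_tables <- list(
  herg = list(resno = c(628L, 627L, 626L, 625L, 624L, 624L),
              elety = c("O", "O", "O", "O", "O", "OG"),
              resid = c("GLY", "PHE", "GLY", "VAL", "SER", "SER")),
  kcsa = list(resno = c(79L, 78L, 77L, 76L, 75L, 75L),
              elety = c("O", "O", "O", "O", "O", "OG1"),
              resid = c("GLY", "TYR", "GLY", "VAL", "THR", "THR")))

# Conductive boundary-ring diameters (Angstrom), top (extracellular) to
# bottom: S0 upper ring, then the four site boundaries (Y78/G77/V76/T75-like
# rings at 5.1/4.7/4.7/4.5, the crystallographic conductive-filter values),
# then the threonine-hydroxyl ring capping S4.
.conductive_diameters <- c(5.1, 5.1, 4.7, 4.7, 4.5, 4.5)

#' Specify a synthetic SF ensemble
#'
#' Builds the full parameterisation of a synthetic selectivity-filter
#' ensemble. Three geometry states are available: `"conductive"`
#' (crystallographic conductive-filter ring diameters), `"widened"` (the
#' S0/S1 boundary ring inflated by +4 Angstrom diameter, emulating
#' extracellular widening), and `"constricted"` (the two S2-bounding rings
#' scaled by 5.5/8.1, emulating the pinched, hour-glass closed filter whose
#' Gly-ring Calpha diagonal drops from 8.1 to 5.5 Angstrom).
#'
#' Calpha pseudo-atoms are placed on each carbonyl ring at a diameter
#' `ca_offset` larger than the oxygen ring (default +3.4 Angstrom, so the
#' conductive Gly-ring Calpha diagonal is 8.1 Angstrom); state transforms
#' apply to oxygen and Calpha rings alike.
#'
#' @param n_frames number of frames (default 1000).
#' @param frame_interval ns between frames (default 0.01, i.e. 10 ps).
#' @param geometry_state `"conductive"`, `"widened"` or `"constricted"`.
#' @param naming residue naming/numbering scheme for the emitted atoms,
#'   `"herg"` (623-629) or `"kcsa"` (74-80); matches the corresponding
#'   [sf_scheme()].
#' @param ring_diameters optional 6-vector of oxygen-ring diameters
#'   (Angstrom, top to bottom) overriding the state defaults.
#' @param ring_sep axial separation between consecutive rings (Angstrom,
#'   default 2.8: one binding site spans about 2.8 Angstrom, twice the K+
#'   occupancy cutoff).
#' @param ca_offset Calpha ring diameter minus oxygen ring diameter.
#' @param configurations list of planted ion configurations; each is an
#'   integer vector of occupied site ids in 0:4 (0 = S0). May include an
#'   empty vector for an ion-free filter.
#' @param config_weights sampling weights over `configurations` (default
#'   uniform).
#' @param config_schedule optional explicit per-frame configuration index
#'   (length `n_frames`); overrides random sampling.
#' @param water_column fill the cavity with a column of water oxygens
#'   (default TRUE).
#' @param water_spacing axial spacing of water oxygens (Angstrom,
#'   default 1.4).
#' @param water_gap optional `c(zlo, zhi)`: waters with ideal z inside this
#'   interval are removed, planting a hydration gap.
#' @param cavity_ion_frames list of integer frame-index vectors; each
#'   element adds one K+ ion that resides mid-cavity on the listed frames
#'   (see [plant_ion_dwell()]).
#' @param noise_sigma isotropic Gaussian noise per atom per frame
#'   (Angstrom, default 0.1).
#' @param seed RNG seed (reproducible generation).
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_frames = 1000L, frame_interval = 0.01,
                           geometry_state = c("conductive", "widened",
                                              "constricted"),
                           naming = c("herg", "kcsa"),
                           ring_diameters = NULL, ring_sep = 2.8,
                           ca_offset = 3.4,
                           configurations = list(c(2L, 4L)),
                           config_weights = NULL, config_schedule = NULL,
                           water_column = TRUE, water_spacing = 1.4,
                           water_gap = NULL, cavity_ion_frames = list(),
                           noise_sigma = 0.1, seed = 1L) {
  geometry_state <- match.arg(geometry_state)
  naming <- match.arg(naming)
  n_frames <- as.integer(n_frames)
  if (n_frames < 1L) stop("`n_frames` must be >= 1")
  if (noise_sigma < 0) stop("`noise_sigma` must be >= 0")
  if (frame_interval <= 0) stop("`frame_interval` must be > 0 (ns)")

  o_diam <- if (!is.null(ring_diameters)) {
    if (length(ring_diameters) != 6L)
      stop("`ring_diameters` must have 6 entries (top to bottom)")
    as.numeric(ring_diameters)
  } else .conductive_diameters
  ca_diam <- o_diam[1:5] + ca_offset
  if (is.null(ring_diameters)) {
    if (geometry_state == "widened") {
      o_diam[2] <- o_diam[2] + 4
      ca_diam[2] <- ca_diam[2] + 4
    } else if (geometry_state == "constricted") {
      ratio <- 5.5 / 8.1
      o_diam[3:4] <- o_diam[3:4] * ratio
      ca_diam[3:4] <- ca_diam[3:4] * ratio
    }
  }
  ring_z <- ring_sep * seq(2.5, -2.5, by = -1)  # strictly decreasing

  if (!length(configurations)) stop("`configurations` must be non-empty")
  configurations <- lapply(configurations, function(cc) {
    cc <- as.integer(cc)
    if (length(cc) && (any(cc < 0L) || any(cc > 4L) || anyDuplicated(cc)))
      stop("configurations are vectors of distinct site ids in 0:4")
    cc
  })
  if (!is.null(config_schedule)) {
    config_schedule <- as.integer(config_schedule)
    if (length(config_schedule) != n_frames)
      stop(sprintf("`config_schedule` length %d does not match n_frames %d",
                   length(config_schedule), n_frames))
    if (any(config_schedule < 1L) ||
        any(config_schedule > length(configurations)))
      stop("`config_schedule` indexes outside `configurations`")
  }
  cavity_ion_frames <- lapply(cavity_ion_frames, function(fr) {
    fr <- as.integer(fr)
    if (length(fr) && (any(fr < 1L) || any(fr > n_frames)))
      stop("cavity ion frames outside [1, n_frames]")
    fr
  })

  structure(list(n_frames = n_frames, frame_interval = frame_interval,
                 geometry_state = geometry_state, naming = naming,
                 ring_diameters = o_diam, ca_diameters = ca_diam,
                 ring_z = ring_z, ring_sep = ring_sep,
                 configurations = configurations,
                 config_weights = config_weights,
                 config_schedule = config_schedule,
                 water_column = isTRUE(water_column),
                 water_spacing = water_spacing, water_gap = water_gap,
                 cavity_ion_frames = cavity_ion_frames,
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat(sprintf("synthetic_spec: %d frames (%g ns/frame), %s geometry, %s naming\n",
              x$n_frames, x$frame_interval, x$geometry_state, x$naming))
  cat(sprintf("  ring diameters: %s A; sigma = %g A; seed = %d\n",
              paste(sprintf("%.2f", x$ring_diameters), collapse = " "),
              x$noise_sigma, x$seed))
  cat(sprintf("  %d ion configuration(s), %d cavity ion(s)\n",
              length(x$configurations), length(x$cavity_ion_frames)))
  invisible(x)
}

#' Plant a cavity dwell event
#'
#' Adds one K+ ion that occupies the intracellular cavity for exactly
#' `ceiling(duration_ns / frame_interval)` consecutive frames starting at
#' `start_frame`; on all other frames the ion is parked far outside the
#' cavity. A planted duration of 0 adds no event.
#'
#' @param spec a [synthetic_spec()].
#' @param duration_ns planted residence time in ns.
#' @param start_frame first frame of the residence (default 1).
#' @return the updated `synthetic_spec`.
#' @export
plant_ion_dwell <- function(spec, duration_ns, start_frame = 1L) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (duration_ns < 0) stop("`duration_ns` must be >= 0")
  total <- spec$n_frames * spec$frame_interval
  if (duration_ns > total + 1e-9)
    stop(sprintf("planted duration %.4g ns exceeds the ensemble length %.4g ns",
                 duration_ns, total))
  nfr <- as.integer(ceiling(duration_ns / spec$frame_interval - 1e-9))
  if (nfr == 0L) return(spec)
  start_frame <- as.integer(start_frame)
  if (start_frame < 1L || start_frame + nfr - 1L > spec$n_frames)
    stop("planted dwell does not fit in [1, n_frames]")
  spec$cavity_ion_frames <-
    c(spec$cavity_ion_frames, list(seq(start_frame, start_frame + nfr - 1L)))
  spec
}

# Ideal (noise-free) atom table and template coordinates for a spec.
.synthetic_template <- function(spec) {
  rt <- .ring_tables[[spec$naming]]
  res_order <- unique(rt$resno)  # top to bottom
  atoms <- list(); xyz <- list()
  eleno <- 0L
  for (su in 0:3) {
    theta <- su * pi / 2
    ch <- LETTERS[su + 1L]
    for (rn in res_order) {
      rings_here <- which(rt$resno == rn)
      resid3 <- rt$resid[rings_here[1L]]
      # Calpha from the carbonyl ring of this residue
      oring <- rings_here[rt$elety[rings_here] == "O"][1L]
      r_ca <- spec$ca_diameters[oring] / 2
      eleno <- eleno + 1L
      atoms[[length(atoms) + 1L]] <- data.frame(
        eleno = eleno, elety = "CA", resid = resid3, resno = rn, chain = ch,
        subunit = su, element = "C", stringsAsFactors = FALSE)
      xyz[[length(xyz) + 1L]] <-
        c(r_ca * cos(theta), r_ca * sin(theta), spec$ring_z[oring])
      for (rg in rings_here) {
        r_o <- spec$ring_diameters[rg] / 2
        eleno <- eleno + 1L
        atoms[[length(atoms) + 1L]] <- data.frame(
          eleno = eleno, elety = rt$elety[rg], resid = resid3, resno = rn,
          chain = ch, subunit = su, element = "O", stringsAsFactors = FALSE)
        xyz[[length(xyz) + 1L]] <-
          c(r_o * cos(theta), r_o * sin(theta), spec$ring_z[rg])
      }
    }
  }
  z_bot <- min(spec$ring_z)
  # water column through the cavity probe segment (z_bot-2 .. z_bot-22),
  # extended a few Angstrom past both ends so every probe point sees a
  # two-sided column (the physical cavity connects to bulk water below)
  if (spec$water_column) {
    zw <- seq(z_bot - 1.5, z_bot - 26, by = -spec$water_spacing)
    if (!is.null(spec$water_gap))
      zw <- zw[zw < min(spec$water_gap) | zw > max(spec$water_gap)]
    for (i in seq_along(zw)) {
      eleno <- eleno + 1L
      atoms[[length(atoms) + 1L]] <- data.frame(
        eleno = eleno, elety = "O", resid = "HOH", resno = 1000L + i,
        chain = "W", subunit = NA_integer_, element = "O",
        stringsAsFactors = FALSE)
      xyz[[length(xyz) + 1L]] <- c(0, 0, zw[i])
    }
  }
  # ion slots: max configuration size + one per cavity ion
  n_cfg_ions <- max(vapply(spec$configurations, length, 1L))
  n_ions <- n_cfg_ions + length(spec$cavity_ion_frames)
  park <- function(slot) c(60 + 10 * slot, 0, 60)
  for (s in seq_len(n_ions)) {
    eleno <- eleno + 1L
    atoms[[length(atoms) + 1L]] <- data.frame(
      eleno = eleno, elety = "K", resid = "K", resno = 2000L + s,
      chain = "I", subunit = NA_integer_, element = "K",
      stringsAsFactors = FALSE)
    xyz[[length(xyz) + 1L]] <- park(s)
  }
  at <- do.call(rbind, atoms)
  template <- do.call(rbind, xyz)
  # ideal site centers: on the axis, midway between consecutive rings
  site_z <- (spec$ring_z[1:5] + spec$ring_z[2:6]) / 2
  list(atoms = at, template = template,
       ion_rows = which(at$element == "K"),
       n_cfg_ions = n_cfg_ions,
       site_centers = cbind(0, 0, site_z),
       cavity_pos = c(0, 0, z_bot - 12),
       park = park)
}

#' Generate a synthetic ensemble
#'
#' Realises a [synthetic_spec()]: builds the pseudo-atom filter, draws (or
#' takes) the per-frame ion configuration schedule, places ions at the ideal
#' site centers and cavity ions mid-cavity, fills the water column, and adds
#' isotropic Gaussian noise to every atom in every frame. Generation is
#' bit-reproducible for a fixed seed, and exactly four-fold symmetric at
#' `noise_sigma = 0`.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `frames` (a [frame_set()]) and `truth` (planted ground
#'   truth: `config_index` and exact `occupancy` 0/1 matrix per frame, the
#'   `geometry_state`, and planted cavity `dwell` events with exclusive exit
#'   frames).
#' @export
generate_ensemble <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  tpl <- .synthetic_template(spec)
  nf <- spec$n_frames
  nat <- nrow(tpl$atoms)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(spec$seed)

  sched <- spec$config_schedule
  if (is.null(sched)) {
    sched <- if (length(spec$configurations) == 1L) rep(1L, nf)
    else sample.int(length(spec$configurations), nf, replace = TRUE,
                    prob = spec$config_weights)
  }

  coords <- array(rep(as.numeric(tpl$template), nf) , dim = c(nat, 3L, nf))
  occupancy <- matrix(0L, nrow = nf, ncol = 5L,
                      dimnames = list(NULL, paste0("S", 0:4)))
  for (f in seq_len(nf)) {
    cfg <- spec$configurations[[sched[f]]]
    if (length(cfg)) {
      occupancy[f, cfg + 1L] <- 1L
      for (i in seq_along(cfg))
        coords[tpl$ion_rows[i], , f] <- tpl$site_centers[cfg[i] + 1L, ]
    }
  }
  if (length(spec$cavity_ion_frames)) {
    for (ci in seq_along(spec$cavity_ion_frames)) {
      row <- tpl$ion_rows[tpl$n_cfg_ions + ci]
      for (f in spec$cavity_ion_frames[[ci]])
        coords[row, , f] <- tpl$cavity_pos
    }
  }
  if (spec$noise_sigma > 0)
    coords <- coords + array(stats::rnorm(nat * 3L * nf, 0, spec$noise_sigma),
                             dim = c(nat, 3L, nf))

  dwell <- do.call(rbind, lapply(seq_along(spec$cavity_ion_frames),
    function(ci) {
      fr <- sort(spec$cavity_ion_frames[[ci]])
      if (!length(fr)) return(NULL)
      data.frame(ion_id = tpl$atoms$eleno[tpl$ion_rows[tpl$n_cfg_ions + ci]],
                 entry_frame = fr[1L], exit_frame = fr[length(fr)] + 1L,
                 duration_ns = length(fr) * spec$frame_interval)
    }))
  if (is.null(dwell))
    dwell <- data.frame(ion_id = integer(), entry_frame = integer(),
                        exit_frame = integer(), duration_ns = numeric())

  list(frames = frame_set(tpl$atoms, coords,
                          frame_interval = spec$frame_interval),
       truth = list(config_index = sched, occupancy = occupancy,
                    geometry_state = spec$geometry_state, dwell = dwell))
}

#' Paired ideal reference structures
#'
#' Returns noise-free, single-frame conductive and constricted filter
#' structures (KcsA residue naming by default), differing only at the two
#' S2-bounding rings. These are synthetic idealisations built from published
#' conductive/closed filter dimensions (boundary-ring diameters
#' 5.1/4.7/4.7/4.5 Angstrom; Gly-ring Calpha diagonal 8.1 vs 5.5 Angstrom),
#' not deposited experimental coordinates.
#'
#' @param naming `"kcsa"` (default) or `"herg"`.
#' @return list with `conductive` and `constricted` single-frame
#'   [frame_set()] objects.
#' @export
reference_structures <- function(naming = "kcsa") {
  mk <- function(state) {
    sp <- synthetic_spec(n_frames = 1L, geometry_state = state,
                         naming = naming, configurations = list(integer()),
                         water_column = FALSE, noise_sigma = 0, seed = 1L)
    generate_ensemble(sp)$frames
  }
  list(conductive = mk("conductive"), constricted = mk("constricted"))
}
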