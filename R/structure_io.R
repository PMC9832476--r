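# Structure and trajectory input/output, built on bio3d.
#
# Subunit assignment convention: chain identifiers (not segment names) define
# the four pore subunits, in order of first appearance in the file. Solvent
# and ion atoms carry NA as a sentinel subunit. Author residue numbering is
# kept as-is; no renumbering is ever applied.

.infer_element <- function(elety, elesy = NULL, resid = NULL) {
  elety <- trimws(elety)
  out <- character(length(elety))
  if (!is.null(elesy)) {
    elesy <- trimws(elesy)
    ok <- !is.na(elesy) & nzchar(elesy)
    out[ok] <- paste0(toupper(substr(elesy[ok], 1, 1)),
                      tolower(substr(elesy[ok], 2, 2)))
  }
  todo <- !nzchar(out)
  if (any(todo)) {
    # strip leading digits (e.g. "1HG1"), take first letter of the name
    nm <- sub("^[0-9]+", "", elety)
    out[todo] <- toupper(substr(nm, 1, 1))[todo]
  }
  # potassium ions are commonly named K/K+ in residues K/K+/POT/KP
  if (!is.null(resid)) {
    kmask <- toupper(trimws(resid)) %in% c("K", "K+", "POT", "KP") &
      toupper(elety) %in% c("K", "K+", "POT")
    out[kmask] <- "K"
  }
  out
}

.standard_aa <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                  "HIS", "HSD", "HSE", "HSP", "ILE", "LEU", "LYS", "MET",
                  "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL")

# Build the package atom table from a bio3d pdb object.
.atoms_from_pdb <- function(pdb) {
  at <- pdb$atom
  element <- .infer_element(at$elety, at$elesy, at$resid)
  chain <- as.character(at$chain)
  chain[is.na(chain)] <- ""
  is_protein <- toupper(trimws(at$resid)) %in% .standard_aa
  prot_chains <- unique(chain[is_protein])
  subunit <- rep(NA_integer_, nrow(at))
  subunit[is_protein] <- match(chain[is_protein], prot_chains) - 1L
  list(atoms = data.frame(eleno = as.integer(at$eleno),
                          elety = trimws(at$elety),
                          resid = trimws(at$resid),
                          resno = as.integer(at$resno),
                          chain = chain,
                          subunit = subunit,
                          element = element,
                          stringsAsFactors = FALSE),
       n_protein_chains = length(prot_chains))
}

#' Read a single structure (PDB)
#'
#' Parses a PDB file into a single-frame [frame_set()]. Multi-MODEL files are
#' accepted and returned with one frame per model. The four pore subunits are
#' assigned from chain identifiers in file order; a warning is raised if the
#' number of protein chains differs from four (e.g. an asymmetric unit that
#' stores a single channel chain: expansion to the biological assembly is the
#' caller's responsibility, since opposite-subunit distances are meaningless
#' on a monomer).
#'
#' @param path path to a PDB file.
#' @param format input format; only `"PDB"` is supported.
#' @param frame_interval time between models in ns for multi-model files.
#' @return a [frame_set()].
#' @export
read_structure <- function(path, format = "PDB", frame_interval = 0.01) {
  format <- toupper(format)
  if (format != "PDB") stop("unsupported structure format: ", format)
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- tryCatch(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE),
                  error = function(e)
                    stop(sprintf("failed to parse PDB file '%s': %s",
                                 path, conditionMessage(e)), call. = FALSE),
                  warning = function(w)
                    stop(sprintf("failed to parse PDB file '%s': %s",
                                 path, conditionMessage(w)), call. = FALSE))
  if (is.null(pdb$atom) || nrow(pdb$atom) == 0L)
    stop(sprintf("failed to parse PDB file '%s': no atom records found",
                 path), call. = FALSE)
  parsed <- .atoms_from_pdb(pdb)
  if (parsed$n_protein_chains != 4L)
    warning(sprintf("expected 4 protein chains, found %d in '%s'",
                    parsed$n_protein_chains, path))
  xyz <- pdb$xyz
  if (!is.matrix(xyz)) xyz <- matrix(xyz, nrow = 1L)
  nat <- nrow(parsed$atoms)
  nf <- nrow(xyz)
  coords <- array(NA_real_, dim = c(nat, 3L, nf))
  for (f in seq_len(nf))
    coords[, , f] <- matrix(xyz[f, ], ncol = 3L, byrow = TRUE)
  frame_set(parsed$atoms, coords, frame_interval = frame_interval)
}

#' Read a trajectory
#'
#' Reads a coordinate trajectory against a PDB topology. DCD trajectories are
#' read with bio3d; a multi-model PDB may also serve as the trajectory file
#' (useful for small text fixtures). The format is chosen by file extension
#' and can be forced with `format`.
#'
#' @param topology_path PDB file defining atoms (names, residues, chains).
#' @param trajectory_path DCD or multi-model PDB file with the frames.
#' @param stride keep every `stride`-th frame (default 1); the stored
#'   `frame_interval` is scaled by `stride`.
#' @param frame_interval time between frames in the trajectory file, in ns;
#'   default 0.01 ns.
#' @param format `"auto"` (by extension), `"DCD"` or `"PDB"`.
#' @return a [frame_set()].
#' @export
read_trajectory <- function(topology_path, trajectory_path, stride = 1L,
                            frame_interval = 0.01, format = "auto") {
  top <- read_structure(topology_path, frame_interval = frame_interval)
  format <- toupper(format)
  if (format == "AUTO") {
    ext <- toupper(tools::file_ext(trajectory_path))
    format <- if (ext %in% c("DCD")) "DCD" else if (ext %in% c("PDB", "ENT"))
      "PDB" else stop("cannot infer trajectory format from extension '.",
                      ext, "'; pass `format`")
  }
  xyz <- switch(format,
    DCD = tryCatch(bio3d::read.dcd(trajectory_path, verbose = FALSE),
                   error = function(e)
                     stop(sprintf("failed to parse DCD file '%s': %s",
                                  trajectory_path, conditionMessage(e)),
                          call. = FALSE)),
    PDB = {
      p <- bio3d::read.pdb(trajectory_path, multi = TRUE, verbose = FALSE)
      m <- p$xyz
      if (!is.matrix(m)) m <- matrix(m, nrow = 1L)
      m
    },
    stop("unsupported trajectory format: ", format))
  if (!is.matrix(xyz)) xyz <- matrix(xyz, nrow = 1L)
  nat_top <- n_atoms(top)
  nat_trj <- ncol(xyz) / 3L
  if (nat_trj != nat_top)
    stop(sprintf(
      "atom-count mismatch: topology '%s' has %d atoms but trajectory '%s' has %g",
      topology_path, nat_top, trajectory_path, nat_trj))
  keep <- seq(1L, nrow(xyz), by = as.integer(stride))
  coords <- array(NA_real_, dim = c(nat_top, 3L, length(keep)))
  for (i in seq_along(keep))
    coords[, , i] <- matrix(xyz[keep[i], ], ncol = 3L, byrow = TRUE)
  frame_set(top$atoms, coords,
            frame_interval = frame_interval * as.integer(stride))
}

#' Write a frame set to PDB
#'
#' Writes one or more frames as a (multi-MODEL) PDB file, preserving atom
#' names, residue numbering and chain identifiers. Coordinates are written at
#' the format's precision (3 decimals).
#'
#' @param fs a [frame_set()].
#' @param path output file path.
#' @param frames frame indices to write (default: all).
#' @return `path`, invisibly.
#' @export
write_structure <- function(fs, path, frames = NULL) {
  stopifnot(inherits(fs, "frame_set"))
  if (is.null(frames)) frames <- seq_len(n_frames(fs))
  xyz <- t(vapply(frames, function(f) as.vector(t(frame_coords(fs, f))),
                  numeric(3L * n_atoms(fs))))
  ch <- fs$atoms$chain
  ch[!nzchar(ch)] <- " "
  bio3d::write.pdb(file = path, xyz = xyz,
                   resno = fs$atoms$resno, resid = fs$atoms$resid,
                   eleno = fs$atoms$eleno, elety = fs$atoms$elety,
                   chain = ch)
  invisible(path)
}
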