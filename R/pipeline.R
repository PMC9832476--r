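# High-level pipeline entry points: configuration handling, the feature
# extraction run, the clustering run, and the opposite-distance table.
# These back the command-line interface (inst/cli/sfstate) and are the
# programmatic surface most analyses go through.

#' Assemble a run configuration
#'
#' Merges user settings over the package defaults (which reproduce the
#' standard analysis parameters exactly: K+ cutoff 1.4 Angstrom, oxygen
#' cutoff 3.2 Angstrom, cavity probe starting 2 Angstrom below S4's lower
#' boundary and extending 20 Angstrom with 0.5 Angstrom spacing, candidate
#' cluster counts 2-15, stride 1). Settings may come from a YAML file, an
#' override list, or both; precedence is overrides > file > defaults.
#'
#' @param file optional YAML configuration file.
#' @param overrides named list of settings taking precedence over the file.
#' @return named list of class `run_config`.
#' @export
run_config <- function(file = NULL, overrides = list()) {
  cfg <- list(scheme = "herg", k_cutoff = 1.4, oxygen_cutoff = 3.2,
              cavity_offset = 2, cavity_length = 20, cavity_spacing = 0.5,
              k_candidates = 2:15, stride = 1L, seed = 1L,
              pore_axis = c(0, 0, 1), dwell_threshold_ns = 10,
              output_dir = ".")
  if (!is.null(file)) {
    if (!file.exists(file)) stop("config file not found: ", file)
    fromfile <- yaml::read_yaml(file)
    cfg[names(fromfile)] <- fromfile
  }
  cfg[names(overrides)] <- overrides
  structure(cfg, class = "run_config")
}

.provenance <- function(cfg, seed = NULL) {
  list(package = "sfstate",
       version = as.character(utils::packageVersion("sfstate")),
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
       seed = if (!is.null(seed)) seed else cfg$seed,
       config = cfg[setdiff(names(cfg), "pore_axis")],
       pore_axis = as.numeric(cfg$pore_axis))
}

#' Run feature extraction
#'
#' Computes the per-frame feature table for a trajectory (or an in-memory
#' [frame_set()]) and writes it as CSV together with a JSON provenance
#' record (package version, seed, full configuration) sufficient to
#' reproduce the output.
#'
#' @param config a [run_config()].
#' @param frames a [frame_set()], or `NULL` to read from
#'   `config$topology_path` / `config$trajectory_path`.
#' @param output_csv output CSV path (default
#'   `<output_dir>/features.csv`).
#' @return the feature data.frame, invisibly; side effects: CSV +
#'   `<output_csv>.provenance.json`.
#' @export
run_features <- function(config, frames = NULL, output_csv = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(frames)) {
    if (is.null(config$topology_path))
      stop("no input: supply `frames` or set topology_path/trajectory_path")
    frames <- if (is.null(config$trajectory_path))
      read_structure(config$topology_path)
    else read_trajectory(config$topology_path, config$trajectory_path,
                         stride = config$stride)
  } else if (config$stride > 1L) {
    frames <- stride_frames(frames, config$stride)
  }
  topo <- build_topology(frames, scheme = config$scheme,
                         pore_axis = config$pore_axis,
                         cavity_offset = config$cavity_offset,
                         cavity_length = config$cavity_length,
                         cavity_spacing = config$cavity_spacing,
                         k_cutoff = config$k_cutoff,
                         oxygen_cutoff = config$oxygen_cutoff)
  feats <- frame_features(frames, topo)
  if (is.null(output_csv))
    output_csv <- file.path(config$output_dir, "features.csv")
  dir.create(dirname(output_csv), recursive = TRUE, showWarnings = FALSE)
  write_features(feats, output_csv)
  jsonlite::write_json(.provenance(config),
                       paste0(output_csv, ".provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(feats)
}

#' Run clustering on a feature table
#'
#' Selects the number of clusters by silhouette maximum over the configured
#' candidates, then writes the model JSON, the per-frame labels CSV, the
#' silhouette curve CSV and the cluster summary CSVs to the output
#' directory.
#'
#' @param config a [run_config()].
#' @param features a feature data.frame ([frame_features()] layout) or the
#'   path of a features CSV.
#' @param output_dir output directory (default `config$output_dir`).
#' @return the [select_k()] model, invisibly.
#' @export
run_cluster <- function(config, features, output_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (is.character(features)) features <- read_features(features)
  if (!nrow(features)) stop("empty feature table")
  if (is.null(output_dir)) output_dir <- config$output_dir
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  kc <- config$k_candidates
  model <- if (length(kc) == 1L) {
    labels <- cluster_frames(features, kc)
    structure(list(k_candidates = as.integer(kc), silhouette_by_k = NA_real_,
                   selected_k = as.integer(kc), labels = labels,
                   probabilities = as.numeric(table(labels)) / length(labels),
                   features = .occupancy_matrix(features),
                   provenance = data.frame(
                     replica = if (!is.null(features$replica))
                       features$replica else rep(1L, length(labels)),
                     frame = seq_along(labels))),
              class = "cluster_model")
  } else {
    select_k(features, k_candidates = kc, replica = features$replica,
             seed = config$seed)
  }
  summ <- summarize_clusters(model, features)
  utils::write.csv(data.frame(k = model$k_candidates,
                              silhouette = model$silhouette_by_k),
                   file.path(output_dir, "silhouette.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(row = seq_along(model$labels),
                              cluster = model$labels),
                   file.path(output_dir, "labels.csv"), row.names = FALSE)
  jsonlite::write_json(list(selected_k = model$selected_k,
                            k_candidates = model$k_candidates,
                            silhouette_by_k = model$silhouette_by_k,
                            probabilities = model$probabilities,
                            provenance = .provenance(config)),
                       file.path(output_dir, "model.json"),
                       auto_unbox = TRUE, digits = NA)
  export_cluster_report(summ, output_dir)
  invisible(model)
}

#' Opposite-distance table across systems
#'
#' Computes the opposite-subunit carbonyl-oxygen distance table for one or
#' more systems and writes it in the conventional layout: one row per
#' residue, one `mean +/- sd` column pair per system.
#'
#' @param inputs named list of [frame_set()] objects (or PDB paths), one
#'   per system (column).
#' @param rows data.frame with columns `resno`, `elety`; may carry
#'   per-system residue numbers as a list-column alternative, in which case
#'   supply one `rows` per input as a named list.
#' @param output_tsv optional output TSV path.
#' @return data.frame: `resno`, `elety`, then `<system>_mean`,
#'   `<system>_sd` per system.
#' @export
run_table1 <- function(inputs, rows, output_tsv = NULL) {
  if (inherits(inputs, "frame_set")) inputs <- list(system = inputs)
  if (is.null(names(inputs)) || any(!nzchar(names(inputs))))
    names(inputs) <- paste0("system", seq_along(inputs))
  per_system_rows <- if (is.data.frame(rows))
    stats::setNames(rep(list(rows), length(inputs)), names(inputs))
  else rows
  out <- NULL
  for (nm in names(inputs)) {
    fs <- inputs[[nm]]
    if (is.character(fs)) fs <- read_structure(fs)
    tb <- distance_table(fs, per_system_rows[[nm]])
    block <- data.frame(tb$mean, tb$sd)
    names(block) <- paste0(nm, c("_mean", "_sd"))
    out <- if (is.null(out))
      cbind(data.frame(resno = tb$resno, elety = tb$elety), block)
    else cbind(out, block)
  }
  if (!is.null(output_tsv)) {
    dir.create(dirname(output_tsv), recursive = TRUE, showWarnings = FALSE)
    utils::write.table(out, output_tsv, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  }
  out
}
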