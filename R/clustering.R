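# Frame clustering by ion configuration: Ward-linkage agglomerative
# clustering on the S0-S4 K+ occupancies, silhouette-based selection of the
# number of clusters, and cluster characterisation.

# Extract the 5 occupancy columns used as clustering features. Accepts a
# frame_features() data.frame, a bare matrix/data.frame with 5 columns, or a
# site_k_occupancy() matrix.
.occupancy_matrix <- function(features) {
  occ_cols <- paste0("s", 0:4, "_k")
  if (is.data.frame(features) && all(occ_cols %in% names(features)))
    features <- features[, occ_cols]
  m <- as.matrix(features)
  if (ncol(m) != 5L)
    stop("clustering features must be the 5 S0-S4 K+ occupancy columns ",
         "(s0_k..s4_k); got ", ncol(m), " columns")
  if (any(!is.finite(m)) || any(m < 0))
    stop("occupancy features must be finite and non-negative")
  storage.mode(m) <- "double"
  m
}

#' Cluster frames by ion configuration
#'
#' Partitions frames into `k` clusters by agglomerative clustering of the
#' S0-S4 K+ occupancy vectors, with Euclidean distance and the Ward linkage
#' criterion (`stats::hclust(method = "ward.D2")`, the Ward implementation
#' appropriate for unsquared Euclidean distances).
#'
#' @param features a [frame_features()] data.frame (the `s0_k`..`s4_k`
#'   columns are used), a [site_k_occupancy()] matrix, or any n x 5 matrix.
#' @param k number of clusters, `2 <= k <= n`.
#' @return integer vector of cluster labels (1..k), one per row.
#' @export
cluster_frames <- function(features, k) {
  m <- .occupancy_matrix(features)
  k <- as.integer(k)
  if (is.na(k) || k < 1L || k > nrow(m))
    stop(sprintf("`k` must be in [1, %d], got %d", nrow(m), k))
  hc <- stats::hclust(stats::dist(m), method = "ward.D2")
  stats::cutree(hc, k = k)
}

#' Select the number of clusters by silhouette maximum
#'
#' Builds the Ward dendrogram once, cuts it at every candidate `k`, scores
#' each partition with the mean silhouette width, and selects the candidate
#' with the maximal score (ties broken toward the smaller k, for parsimony).
#' The silhouette score lies in `[-1, 1]` and is maximal for the partition
#' that best separates homogeneous clusters; a flat, low curve
#' (max < `low_confidence`) triggers a warning since it indicates weak
#' cluster structure.
#'
#' For large frame counts the silhouette (which is quadratic in the number
#' of rows) is evaluated on a random subsample (default cap 20000 rows,
#' fixed by `seed`, stratified by replica when `replica` is given); the
#' dendrogram and the returned labels always cover all rows up to
#' `max_fit_rows`, beyond which remaining rows are assigned to the nearest
#' cluster centroid.
#'
#' @inheritParams cluster_frames
#' @param k_candidates integer vector of candidate cluster counts
#'   (default 2:15).
#' @param replica optional per-row replica/trajectory id, retained as row
#'   provenance and used to stratify the silhouette subsample.
#' @param subsample maximum number of rows used for silhouette scoring.
#' @param max_fit_rows maximum number of rows clustered hierarchically.
#' @param seed seed for the subsampling draw (only used when subsampling).
#' @param low_confidence silhouette level below which selection is flagged
#'   as low-confidence.
#' @return object of class `cluster_model`: list with `k_candidates`,
#'   `silhouette_by_k`, `selected_k`, `labels`, `probabilities`, `features`
#'   (the occupancy matrix) and `provenance` (replica, frame).
#' @export
select_k <- function(features, k_candidates = 2:15, replica = NULL,
                     subsample = 20000L, max_fit_rows = 20000L,
                     seed = 1L, low_confidence = 0.25) {
  m <- .occupancy_matrix(features)
  n <- nrow(m)
  k_candidates <- sort(unique(as.integer(k_candidates)))
  if (length(k_candidates) == 0L) stop("`k_candidates` must be non-empty")
  if (any(k_candidates < 2L) || any(k_candidates > n - 1L))
    stop(sprintf("candidate k must lie in [2, %d]", n - 1L))
  if (is.null(replica)) replica <- rep(1L, n)
  if (length(replica) != n) stop("`replica` must have one entry per row")

  fit_rows <- seq_len(n)
  if (n > max_fit_rows) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    fit_rows <- sort(.stratified_sample(replica, max_fit_rows))
  }
  d <- stats::dist(m[fit_rows, , drop = FALSE])
  hc <- stats::hclust(d, method = "ward.D2")

  sil_rows_local <- seq_along(fit_rows)
  use_sub <- length(fit_rows) > subsample
  if (use_sub) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed + 1L)
    sil_rows_local <- sort(.stratified_sample(replica[fit_rows], subsample))
    d_sil <- stats::dist(m[fit_rows[sil_rows_local], , drop = FALSE])
  } else d_sil <- d

  sil <- vapply(k_candidates, function(k) {
    lab <- stats::cutree(hc, k = k)[sil_rows_local]
    if (length(unique(lab)) < 2L) return(NA_real_)
    mean(cluster::silhouette(lab, d_sil)[, "sil_width"])
  }, numeric(1))

  best <- k_candidates[which.max(sil)]   # ties: first (smallest) candidate
  if (max(sil, na.rm = TRUE) < low_confidence)
    warning(sprintf(
      "low-confidence selection: maximal silhouette %.3f < %.2f (weak cluster structure)",
      max(sil, na.rm = TRUE), low_confidence))

  lab_fit <- stats::cutree(hc, k = best)
  labels <- integer(n)
  labels[fit_rows] <- lab_fit
  if (length(fit_rows) < n) {
    centroids <- t(vapply(sort(unique(lab_fit)), function(cl)
      colMeans(m[fit_rows[lab_fit == cl], , drop = FALSE]), numeric(5L)))
    rest <- setdiff(seq_len(n), fit_rows)
    for (i in rest) {
      dd <- rowSums((centroids - matrix(m[i, ], nrow(centroids), 5L,
                                        byrow = TRUE))^2)
      labels[i] <- which.min(dd)
    }
  }
  tab <- table(labels)
  probabilities <- as.numeric(tab) / n
  structure(list(k_candidates = k_candidates, silhouette_by_k = sil,
                 selected_k = best, labels = labels,
                 probabilities = probabilities, features = m,
                 provenance = data.frame(replica = replica,
                                         frame = seq_len(n))),
            class = "cluster_model")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
.stratified_sample <- function(strata, size) {
  n <- length(strata)
  if (size >= n) return(seq_len(n))
  idx <- unlist(lapply(split(seq_len(n), strata), function(ix)
    sample(ix, max(1L, round(length(ix) * size / n)))))
  if (length(idx) > size) idx <- sample(idx, size)
  idx
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("cluster_model: %d rows, selected k = %d (silhouette %.3f)\n",
              nrow(x$features), x$selected_k,
              x$silhouette_by_k[match(x$selected_k, x$k_candidates)]))
  cat("  candidates:", paste(x$k_candidates, collapse = " "), "\n")
  cat("  probabilities:",
      paste(sprintf("%.3f", x$probabilities), collapse = " "), "\n")
  invisible(x)
}

#' Characterise clusters
#'
#' Per cluster: mean and first/third quartiles (linear-interpolation
#' quantiles, `stats::quantile` type 7) of each of the 12 per-frame
#' features, the cluster probability (fraction of frames), and a
#' representative frame chosen as the medoid in the 5-dimensional occupancy
#' feature space (the member minimising the summed Euclidean distance to
#' its cluster).
#'
#' @param model a [select_k()] result (or a list with `labels`,
#'   `probabilities`, `features`, `provenance`).
#' @param features the full per-frame feature table ([frame_features()]
#'   layout); must align row-by-row with the model's labels.
#' @return object of class `cluster_summary`: list with `clusters`
#'   (data.frame: cluster, n, probability, representative replica/frame) and
#'   `stats` (long data.frame: cluster, feature, mean, q1, q3).
#' @export
summarize_clusters <- function(model, features) {
  stopifnot(inherits(model, "cluster_model"))
  labels <- model$labels
  if (is.data.frame(features) && "frame" %in% names(features))
    feat <- features[, setdiff(names(features), c("frame", "replica")),
                     drop = FALSE]
  else feat <- as.data.frame(features)
  if (nrow(feat) != length(labels))
    stop(sprintf("feature rows (%d) do not align with cluster labels (%d)",
                 nrow(feat), length(labels)))
  cls <- sort(unique(labels))
  stats_rows <- list()
  cl_rows <- list()
  for (cl in cls) {
    sel <- which(labels == cl)
    sub <- feat[sel, , drop = FALSE]
    for (fn in names(sub)) {
      v <- sub[[fn]]
      q <- stats::quantile(v, probs = c(0.25, 0.75), type = 7, names = FALSE)
      stats_rows[[length(stats_rows) + 1L]] <-
        data.frame(cluster = cl, feature = fn, mean = mean(v),
                   q1 = q[1], q3 = q[2])
    }
    # medoid in the occupancy feature space
    fm <- model$features[sel, , drop = FALSE]
    dmat <- as.matrix(stats::dist(fm))
    med <- sel[which.min(rowSums(dmat))]
    cl_rows[[length(cl_rows) + 1L]] <- data.frame(
      cluster = cl, n = length(sel),
      probability = length(sel) / length(labels),
      representative_replica = model$provenance$replica[med],
      representative_frame = model$provenance$frame[med])
  }
  structure(list(clusters = do.call(rbind, cl_rows),
                 stats = do.call(rbind, stats_rows)),
            class = "cluster_summary")
}

#' @export
print.cluster_summary <- function(x, ...) {
  cat(sprintf("cluster_summary: %d clusters\n", nrow(x$clusters)))
  print(x$clusters, row.names = FALSE)
  invisible(x)
}

#' Export / re-import a cluster report
#'
#' Writes the cluster summary as JSON (`clusters.json`: per-cluster records
#' with probabilities and representatives, plus the per-feature statistics)
#' and CSV (`cluster_stats.csv`, `clusters.csv`). `read_cluster_report()`
#' reconstructs an identical `cluster_summary` from the CSV files.
#'
#' @param summary a [summarize_clusters()] result.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
export_cluster_report <- function(summary, dir) {
  stopifnot(inherits(summary, "cluster_summary"))
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE)
  if (!ok || file.access(dir, 2L) != 0L)
    stop("cannot write to directory: ", dir)
  utils::write.csv(summary$clusters, file.path(dir, "clusters.csv"),
                   row.names = FALSE)
  utils::write.csv(summary$stats, file.path(dir, "cluster_stats.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(clusters = summary$clusters, stats = summary$stats),
    file.path(dir, "clusters.json"),
    dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname export_cluster_report
#' @export
read_cluster_report <- function(dir) {
  cl <- utils::read.csv(file.path(dir, "clusters.csv"))
  st <- utils::read.csv(file.path(dir, "cluster_stats.csv"))
  structure(list(clusters = cl, stats = st), class = "cluster_summary")
}
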