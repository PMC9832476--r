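# Independent oracles and small utilities shared across tests.

# Brute-force coordination number: per-atom loop over the defining rational
# form (1 - x^6) / (1 - x^12), evaluated with the removable singularity
# handled explicitly. Kept deliberately naive and independent of the
# package's vectorised path.
bf_coordination <- function(probe, coords, d_c) {
  if (is.null(dim(coords))) coords <- matrix(coords, ncol = 3, byrow = FALSE)
  total <- 0
  for (j in seq_len(nrow(coords))) {
    d <- sqrt(sum((coords[j, ] - probe)^2))
    x <- d / d_c
    total <- total + if (abs(x - 1) < 1e-12) 0.5 else (1 - x^6) / (1 - x^12)
  }
  total
}

# Silhouette score by definition (mean over points of (b-a)/max(a,b);
# singletons score 0).
bf_silhouette <- function(X, labels) {
  X <- as.matrix(X)
  n <- nrow(X)
  dmat <- as.matrix(dist(X))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i])
    if (length(own) == 1L) { s[i] <- 0; next }
    a <- mean(dmat[i, setdiff(own, i)])
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(cl)
      mean(dmat[i, labels == cl]), numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# All partitions of 1..n into exactly k non-empty blocks (n small).
all_partitions <- function(n, k) {
  out <- list()
  assign_next <- function(labels, i, used) {
    if (i > n) {
      if (used == k) out[[length(out) + 1L]] <<- labels
      return(invisible(NULL))
    }
    for (cl in seq_len(min(used + 1L, k))) {
      labels[i] <- cl
      assign_next(labels, i + 1L, max(used, cl))
    }
  }
  assign_next(integer(n), 1L, 0L)
  out
}

within_ss <- function(X, labels) {
  X <- as.matrix(X)
  sum(vapply(unique(labels), function(cl) {
    sub <- X[labels == cl, , drop = FALSE]
    sum(sweep(sub, 2, colMeans(sub))^2)
  }, numeric(1)))
}

# Rigid-body helpers.
rot_z <- function(theta) {
  matrix(c(cos(theta), -sin(theta), 0,
           sin(theta),  cos(theta), 0,
           0,           0,          1), 3, 3, byrow = TRUE)
}

random_rotation <- function() {
  qr.Q(qr(matrix(rnorm(9), 3)))
}

transform_frames <- function(fs, R = diag(3), t = c(0, 0, 0)) {
  for (f in seq_len(n_frames(fs)))
    fs$coords[, , f] <- fs$coords[, , f] %*% t(R) +
      matrix(t, n_atoms(fs), 3, byrow = TRUE)
  fs
}

# Best-permutation label agreement between two hard partitions.
label_agreement <- function(a, b) {
  tab <- table(a, b)
  sum(apply(tab, 1, max)) / length(a)
}

# Small conductive synthetic ensemble shared by several tests.
make_conductive <- function(n_frames = 20, sigma = 0, seed = 7,
                            configurations = list(c(2L, 4L)), ...) {
  generate_ensemble(synthetic_spec(n_frames = n_frames, noise_sigma = sigma,
                                   seed = seed,
                                   configurations = configurations, ...))
}

# Pool of well-separated planted ion configurations (pairwise Euclidean
# feature distance >= 1).
config_pool <- list(c(2L, 4L), c(1L, 3L), c(0L, 2L, 4L),
                    c(1L, 4L), c(0L, 3L), c(2L))
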