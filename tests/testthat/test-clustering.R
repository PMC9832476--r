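test_that("two repeated feature values separate perfectly at k = 2", {
  x <- rbind(matrix(rep(c(1, 0, 1, 0, 0), 50), ncol = 5, byrow = TRUE),
             matrix(rep(c(0, 0, 0, 1, 1), 50), ncol = 5, byrow = TRUE))
  lab <- cluster_frames(x, 2)
  expect_equal(within_ss(x, lab), 0)
  expect_length(unique(lab), 2L)
  m <- select_k(x, k_candidates = 2:4)
  expect_equal(m$selected_k, 2L)
  expect_equal(m$silhouette_by_k[1], 1)
  expect_true(all(m$silhouette_by_k >= -1 & m$silhouette_by_k <= 1,
                  na.rm = TRUE))
})

test_that("silhouette scores agree with the by-definition oracle", {
  set.seed(19)
  x <- matrix(runif(200, 0, 1), ncol = 5)
  m <- select_k(x, k_candidates = 2:5)
  for (i in seq_along(m$k_candidates)) {
    lab <- cluster_frames(x, m$k_candidates[i])
    expect_equal(m$silhouette_by_k[i], bf_silhouette(x, lab),
                 tolerance = 1e-9)
  }
})

test_that("Ward clustering matches brute-force partition enumeration", {
  # small 1-D instances: the optimal k=2 split is at the largest gap
  set.seed(3)
  for (rep in 1:10) {
    pts <- sort(runif(3, 0, 10))
    x <- cbind(pts, 0, 0, 0, 0)
    lab <- cluster_frames(x, 2)
    best <- min(vapply(all_partitions(3, 2), function(p) within_ss(x, p),
                       numeric(1)))
    expect_equal(within_ss(x, lab), best, tolerance = 1e-9)
  }
})

test_that("planted configurations are recovered with high label agreement", {
  sp <- synthetic_spec(n_frames = 400, noise_sigma = 0.05,
                       configurations = config_pool[1:3], seed = 101)
  ens <- generate_ensemble(sp)
  topo <- build_topology(ens$frames, "herg")
  occ <- site_k_occupancy(ens$frames, topo)
  lab <- cluster_frames(occ, 3)
  expect_gte(label_agreement(ens$truth$config_index, lab), 0.99)
})

test_that("k equal to the row count yields singleton clusters", {
  set.seed(4)
  x <- matrix(runif(50), ncol = 5)
  lab <- cluster_frames(x, nrow(x))
  expect_equal(sort(unique(lab)), 1:10)
  expect_error(cluster_frames(x, 11), "k")
})

test_that("silhouette maximum recovers the planted number of configurations", {
  sp <- synthetic_spec(n_frames = 600, noise_sigma = 0.05,
                       configurations = config_pool[1:4], seed = 55)
  ens <- generate_ensemble(sp)
  topo <- build_topology(ens$frames, "herg")
  occ <- site_k_occupancy(ens$frames, topo)
  m <- select_k(occ, k_candidates = 2:10)
  expect_equal(m$selected_k, 4L)
  # the invariant selected_k = argmax (smallest k on ties)
  mx <- max(m$silhouette_by_k, na.rm = TRUE)
  expect_equal(m$selected_k,
               m$k_candidates[which(m$silhouette_by_k == mx)][1])
  expect_equal(sum(m$probabilities), 1, tolerance = 1e-9)
})

test_that("structureless features trigger a low-confidence warning", {
  # uniform noise has no cluster structure: the silhouette curve stays low
  set.seed(19)
  x <- matrix(runif(600), ncol = 5)
  expect_warning(m <- select_k(x, k_candidates = 2:6), "low-confidence")
  expect_lt(max(m$silhouette_by_k), 0.25)
})

test_that("empty or malformed candidate lists are rejected", {
  x <- matrix(runif(50), ncol = 5)
  expect_error(select_k(x, k_candidates = integer()), "non-empty")
  expect_error(select_k(x, k_candidates = c(1, 2)), "candidate k")
  expect_error(select_k(x, k_candidates = 2:20), "candidate k")
})

test_that("cluster probabilities are invariant to row order", {
  sp <- synthetic_spec(n_frames = 300, noise_sigma = 0.05,
                       configurations = config_pool[1:2],
                       config_weights = c(0.7, 0.3), seed = 77)
  ens <- generate_ensemble(sp)
  topo <- build_topology(ens$frames, "herg")
  occ <- site_k_occupancy(ens$frames, topo)
  set.seed(1)
  perm <- sample(nrow(occ))
  m1 <- select_k(occ, k_candidates = 2:4)
  m2 <- select_k(occ[perm, ], k_candidates = 2:4)
  expect_equal(sort(m1$probabilities), sort(m2$probabilities),
               tolerance = 1e-12)
  expect_equal(m1$selected_k, m2$selected_k)
})

test_that("cluster summaries report quartiles, probabilities and medoids", {
  # one cluster of identical rows: Q1 = Q3 = mean
  x <- matrix(rep(c(0, 1, 0, 1, 0), 30), ncol = 5, byrow = TRUE)
  y <- matrix(rep(c(1, 0, 1, 0, 1), 30), ncol = 5, byrow = TRUE)
  m <- select_k(rbind(x, y), k_candidates = 2:3)
  feats <- as.data.frame(rbind(x, y))
  names(feats) <- paste0("s", 0:4, "_k")
  s <- summarize_clusters(m, feats)
  expect_equal(s$clusters$probability, c(0.5, 0.5))
  expect_true(all(s$stats$q1 == s$stats$q3))
  expect_true(all(s$stats$q1 == s$stats$mean))
  expect_true(all(s$stats$q1 <= s$stats$q3))
  expect_true(all(s$clusters$representative_frame %in% 1:60))
  expect_error(summarize_clusters(m, feats[1:10, ]), "align")
})

test_that("a planted conductive cluster shows > 5 coordinating oxygens", {
  ens <- make_conductive(n_frames = 150, sigma = 0.05, seed = 15,
                         configurations = config_pool[1:2])
  topo <- build_topology(ens$frames, "herg")
  feats <- frame_features(ens$frames, topo)
  m <- select_k(feats, k_candidates = 2:4)
  s <- summarize_clusters(m, feats)
  oxy <- s$stats[grepl("_oxy$", s$stats$feature), ]
  expect_true(all(oxy$mean > 5))
})

test_that("cluster reports round-trip through export and re-import", {
  ens <- make_conductive(n_frames = 120, sigma = 0.05, seed = 8,
                         configurations = config_pool[1:4],
                         config_schedule = rep(1:4, each = 30))
  topo <- build_topology(ens$frames, "herg")
  feats <- frame_features(ens$frames, topo)
  m <- select_k(feats, k_candidates = 2:6)
  s <- summarize_clusters(m, feats)
  dir <- withr::local_tempdir()
  export_cluster_report(s, dir)
  expect_true(all(file.exists(file.path(dir,
    c("clusters.csv", "cluster_stats.csv", "clusters.json")))))
  js <- jsonlite::read_json(file.path(dir, "clusters.json"))
  expect_equal(sum(vapply(js$clusters, `[[`, 1, "probability")), 1,
               tolerance = 1e-9)
  back <- read_cluster_report(dir)
  expect_equal(back$clusters, s$clusters, tolerance = 1e-12)
  expect_equal(back$stats, s$stats, tolerance = 1e-12)
})
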