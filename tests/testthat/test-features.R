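test_that("site K+ occupancy reads out planted ions", {
  # one ion exactly at the S2 center, no noise
  ens <- make_conductive(n_frames = 1, sigma = 0,
                         configurations = list(2L))
  topo <- build_topology(ens$frames, "herg")
  occ <- site_k_occupancy(ens$frames, topo)[1, ]
  expect_equal(unname(occ["S2"]), 1, tolerance = 1e-9)
  # sites >= 3.4 A away barely register (S0 and S4 are 5.6 A from S2)
  expect_lt(occ["S0"], 0.02)
  expect_lt(occ["S4"], 0.02)

  # no ions at all -> zero vector
  empty <- make_conductive(n_frames = 1, sigma = 0,
                           configurations = list(integer()))
  topo0 <- build_topology(empty$frames, "herg")
  expect_equal(unname(site_k_occupancy(empty$frames, topo0)[1, ]), rep(0, 5))

  # ion displaced to exactly the cutoff distance from the S0 center -> 0.5
  fs <- ens$frames
  ion <- topo$potassium[1]
  s0 <- site_center(topo, "S0", frame_coords(fs))
  fs$coords[ion, , 1] <- s0 + c(1.4, 0, 0)
  expect_equal(unname(site_k_occupancy(fs, topo)[1, "S0"]), 0.5,
               tolerance = 1e-9)
})

test_that("occupancy is invariant under ion relabeling", {
  ens <- make_conductive(n_frames = 5, sigma = 0.05,
                         configurations = list(c(1L, 3L)))
  topo <- build_topology(ens$frames, "herg")
  base <- site_k_occupancy(ens$frames, topo)
  fs <- ens$frames
  ions <- topo$potassium
  fs$coords[ions, , ] <- fs$coords[rev(ions), , ]
  expect_equal(site_k_occupancy(fs, topo), base, tolerance = 1e-12)
})

test_that("oxygen coordination separates conductive from widened filters", {
  for (state in c("conductive", "widened")) {
    ens <- generate_ensemble(synthetic_spec(
      n_frames = 1, geometry_state = state, noise_sigma = 0,
      configurations = list(integer()), seed = 1))
    topo <- build_topology(ens$frames, "herg")
    oxy <- site_oxygen_coordination(ens$frames, topo)[1, ]
    # independent oracle: brute-force sum over all oxygen atoms at the
    # analytic site centers (on-axis midpoints of consecutive rings)
    site_z <- (2.8 * seq(2.5, -2.5, -1))
    centers <- cbind(0, 0, (site_z[1:5] + site_z[2:6]) / 2)
    ocoords <- frame_coords(ens$frames)[topo$oxygen, ]
    oracle <- vapply(1:5, function(s)
      bf_coordination(centers[s, ], ocoords, 3.2), numeric(1))
    expect_equal(unname(oxy), oracle, tolerance = 1e-9)
    if (state == "conductive") expect_true(all(oxy > 5))
    else {
      expect_lt(oxy["S0"], 5); expect_lt(oxy["S1"], 5)
    }
  }
  # widened leaves the intracellular sites untouched (< 5% change)
  get_oxy <- function(state) {
    e <- generate_ensemble(synthetic_spec(n_frames = 1,
      geometry_state = state, noise_sigma = 0,
      configurations = list(integer()), seed = 1))
    site_oxygen_coordination(e$frames, build_topology(e$frames, "herg"))[1, ]
  }
  rel <- abs(get_oxy("widened") - get_oxy("conductive")) /
    get_oxy("conductive")
  expect_lt(max(rel[c("S3", "S4")]), 0.05)
})

test_that("oxygen coordination of an oxygen-free system is zero", {
  ens <- make_conductive(n_frames = 1)
  topo <- build_topology(ens$frames, "herg")
  topo$oxygen <- integer(0)
  expect_equal(unname(site_oxygen_coordination(ens$frames, topo)[1, ]),
               rep(0, 5))
})

test_that("cavity axis profiles cover the configured segment", {
  ens <- make_conductive(n_frames = 1, sigma = 0,
                         configurations = list(integer()),
                         water_column = FALSE)
  topo <- build_topology(ens$frames, "herg")
  prof <- cavity_axis_profile(ens$frames, topo, "potassium")
  expect_length(prof$values, 41L)
  expect_equal(prof$spacing, 0.5)
  # segment: 2 A below the bottom ring (z = -7), extending 20 A down
  expect_equal(prof$points[1, 3], -9, tolerance = 1e-9)
  expect_equal(prof$points[41, 3], -29, tolerance = 1e-9)
  # vacuum cavity: no ions -> exactly zero; hydration limited to the
  # vanishing tail of the filter oxygens two Angstrom above the segment
  expect_equal(prof$values, rep(0, 41))
  expect_equal(cavity_k_presence(ens$frames, topo), 0)
  expect_lt(cavity_hydration(ens$frames, topo), 1e-3)
})

test_that("cavity K+ presence is independent of the ion's axial position", {
  ens <- make_conductive(n_frames = 1, sigma = 0,
                         configurations = list(integer()),
                         water_column = FALSE)
  sp <- plant_ion_dwell(synthetic_spec(n_frames = 1, noise_sigma = 0,
                                       configurations = list(integer()),
                                       water_column = FALSE, seed = 1),
                        0.01)
  ens <- generate_ensemble(sp)
  topo <- build_topology(ens$frames, "herg")
  ion <- topo$potassium[length(topo$potassium)]
  vals <- vapply(c(0, 3, 6, -3, -7.9), function(dz) {
    fs <- ens$frames
    fs$coords[ion, 3, 1] <- fs$coords[ion, 3, 1] + dz
    cavity_k_presence(fs, topo)
  }, numeric(1))
  expect_equal(vals, rep(1, 5), tolerance = 0.01)
  # a radially displaced ion scores the switching value of its offset
  fs <- ens$frames
  fs$coords[ion, 1, 1] <- fs$coords[ion, 1, 1] + 1.4
  expect_equal(cavity_k_presence(fs, topo), 0.5, tolerance = 1e-6)
})

test_that("hydration minimum flags a planted water gap", {
  cont <- make_conductive(n_frames = 1, sigma = 0,
                          configurations = list(integer()))
  topo <- build_topology(cont$frames, "herg")
  h_cont <- cavity_hydration(cont$frames, topo)
  # continuous column: >= 2 oxygens within 3.2 A of every point
  expect_gt(h_cont, 1)
  expect_gt(h_cont, 4)

  gap <- generate_ensemble(synthetic_spec(
    n_frames = 1, noise_sigma = 0, configurations = list(integer()),
    water_gap = c(-22.5, -15.5), seed = 1))
  h_gap <- cavity_hydration(gap$frames, build_topology(gap$frames, "herg"))
  expect_lt(h_gap, 4)
  expect_lt(h_gap, h_cont)
  # oracle: brute-force oxygen coordination minimised over the probe points
  gtopo <- build_topology(gap$frames, "herg")
  ocoords <- frame_coords(gap$frames)[gtopo$oxygen, ]
  oracle <- min(vapply(seq(-9, -29, by = -0.5), function(z)
    bf_coordination(c(0, 0, z), ocoords, 3.2), numeric(1)))
  expect_equal(h_gap, oracle, tolerance = 1e-9)
})

test_that("feature extraction commutes exactly with frame striding", {
  ens <- make_conductive(n_frames = 30, sigma = 0.1, seed = 17)
  topo <- build_topology(ens$frames, "herg")
  full <- frame_features(ens$frames, topo)
  strided <- frame_features(stride_frames(ens$frames, 3), topo)
  keep <- seq(1, 30, by = 3)
  expect_identical(unname(as.matrix(strided[, -1])),
                   unname(as.matrix(full[keep, -1])))
})

test_that("features are invariant under four-fold rotation about the axis", {
  ens <- make_conductive(n_frames = 4, sigma = 0.1, seed = 23)
  topo <- build_topology(ens$frames, "herg")
  rot <- transform_frames(ens$frames, rot_z(pi / 2))
  f0 <- frame_features(ens$frames, topo)
  f1 <- frame_features(rot, topo)
  expect_equal(as.matrix(f1[, -1]), as.matrix(f0[, -1]), tolerance = 1e-6)
})

test_that("dwell events are detected, merged over short gaps, and timed", {
  # 500 consecutive frames at 0.01 ns -> one 5 ns event, not stable
  sp <- plant_ion_dwell(synthetic_spec(n_frames = 600, noise_sigma = 0,
                                       configurations = list(integer()),
                                       seed = 1), 5, start_frame = 51)
  ens <- generate_ensemble(sp)
  topo <- build_topology(ens$frames, "herg")
  dw <- dwell_events(ens$frames, topo)
  expect_equal(nrow(dw$events), 1L)
  expect_equal(dw$events$duration_ns, 5)
  expect_equal(dw$events$entry_frame, 51L)
  expect_equal(dw$events$exit_frame, 551L)
  expect_false(dw$any_stable)

  # no ions -> empty result
  none <- make_conductive(n_frames = 10, configurations = list(integer()),
                          sigma = 0)
  t0 <- build_topology(none$frames, "herg")
  dw0 <- dwell_events(none$frames, t0)
  expect_equal(nrow(dw0$events), 0L)
  expect_false(dw0$any_stable)

  # a <= 2 frame excursion does not split an event; 3 frames does
  sp2 <- plant_ion_dwell(synthetic_spec(n_frames = 100, noise_sigma = 0,
                                        configurations = list(integer()),
                                        seed = 1), 0.5, start_frame = 1)
  ens2 <- generate_ensemble(sp2)
  topo2 <- build_topology(ens2$frames, "herg")
  ion <- topo2$potassium[length(topo2$potassium)]
  out <- ens2$frames
  out$coords[ion, , 21:22] <- matrix(c(90, 0, 90), 2, 3, byrow = TRUE)
  dw2 <- dwell_events(out, topo2)
  expect_equal(nrow(dw2$events), 1L)
  out$coords[ion, , 23] <- c(90, 0, 90)
  dw3 <- dwell_events(out, topo2)
  expect_equal(nrow(dw3$events), 2L)
})
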