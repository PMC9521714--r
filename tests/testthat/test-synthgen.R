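test_that("SMLM generator honors zero, count, and placement contracts", {
  # zero case: nothing requested, nothing produced
  empty <- simulate_smlm_synapse(background_density = 0, n_hdrs = 0,
                                 psd_density = 0, psd_background_density = 0,
                                 seed = 1)
  expect_equal(nrow(empty$akap_field$locs), 0)
  expect_equal(nrow(empty$psd_field$locs), 0)

  # Poisson count oracle: 1000/um^2 over a 1 um^2 ROI, no blinking
  sim <- simulate_smlm_synapse(roi_width = 1000, roi_height = 1000,
                               background_density = 1000, n_hdrs = 0,
                               psd_density = 0, psd_background_density = 0,
                               blink_factor = 1, loc_uncertainty = 0, seed = 2)
  expect_lt(abs(nrow(sim$akap_field$locs) - 1000), 3 * sqrt(1000))

  # peripheral placement: centroids outside the PSD disc, within 100 nm of it
  per <- simulate_smlm_synapse(n_hdrs = 3, hdr_placement = "peripheral", seed = 3)
  r <- sqrt(rowSums(sweep(per$truth$hdr_centroids, 2, per$truth$psd_center)^2))
  expect_true(all(r > per$truth$psd_radius & r <= per$truth$psd_radius + 100))

  # guards
  expect_error(simulate_smlm_synapse(roi_width = -1, seed = 1), "ROI")
  expect_error(simulate_smlm_synapse(background_density = 1e7, seed = 1), "1e7")
  expect_error(simulate_smlm_synapse(), "seed")
})

test_that("identical seeds give bit-identical generator output", {
  a <- simulate_smlm_synapse(seed = 99)
  b <- simulate_smlm_synapse(seed = 99)
  expect_identical(a$akap_field$locs, b$akap_field$locs)
  e1 <- simulate_em_spine(seed = 42)
  e2 <- simulate_em_spine(seed = 42)
  expect_identical(e1$annotation$particles, e2$annotation$particles)
  t1 <- simulate_tracks(D = c(0.02, 0.4), A = build_transition_matrix(c(0.3, 0.7), c(0.8, NA)),
                        n_tracks = 50, seed = 5)
  t2 <- simulate_tracks(D = c(0.02, 0.4), A = build_transition_matrix(c(0.3, 0.7), c(0.8, NA)),
                        n_tracks = 50, seed = 5)
  expect_identical(as.data.frame(t1$tracks), as.data.frame(t2$tracks))
})

test_that("EM spine generator places particles per the zone offset models", {
  # zero counts: contour and PSD only
  bare <- simulate_em_spine(zone_counts = c(synaptic = 0, extrasynaptic = 0),
                            organelle_count = 0, seed = 1)
  expect_equal(nrow(bare$annotation$particles), 0)
  expect_false(is.null(bare$annotation$psd))

  # truncated-normal moment oracle for the synaptic offset model
  sim <- simulate_em_spine(zone_counts = c(synaptic = 500, extrasynaptic = 0),
                           head_width = 1200, head_height = 900,
                           psd_arc_length = 400, seed = 7)
  offs <- sim$truth$offset_nm
  mu <- truncnorm_mean_oracle(34, 18, 0, 100)
  se <- sd(offs) / sqrt(length(offs))
  expect_lt(abs(mean(offs) - mu), 3 * se)
  expect_true(all(offs >= 0 & offs <= 100))

  # exact per-zone tallies
  wt <- simulate_em_spine(zone_counts = c(synaptic = 180, extrasynaptic = 309),
                          seed = 11)
  expect_equal(as.numeric(table(wt$truth$zone)[c("synaptic", "extrasynaptic")]),
               c(180, 309))

  expect_error(simulate_em_spine(psd_arc_length = 1e6, seed = 1), "exceeds")
})

test_that("track generator obeys its displacement statistics", {
  # D = 0 and no noise: all tracks stationary
  still <- simulate_tracks(D = 0, n_tracks = 30, seed = 1)
  expect_equal(diff(still$tracks$x_um), rep(0, nrow(still$tracks) - 1))

  # single state: mean squared jump = 4 D dt within 1% at 1e5 jumps
  one <- simulate_tracks(D = 0.1, n_tracks = 20000, mean_track_len = 6,
                         loc_error = 0, seed = 2)
  j <- compute_jumps(one$tracks)
  expect_gt(j$n_jumps, 1e5)
  expect_equal(mean(j$magnitudes^2), 4 * 0.1 * 0.022, tolerance = 0.01)

  # localization error adds 4 sigma^2 to the mean squared jump
  noisy <- simulate_tracks(D = 0.1, n_tracks = 20000, mean_track_len = 6,
                           loc_error = 0.03, seed = 3)
  jn <- compute_jumps(noisy$tracks)
  expect_equal(mean(jn$magnitudes^2), 4 * 0.1 * 0.022 + 4 * 0.03^2,
               tolerance = 0.01)

  # three-state occupancies match the stationary distribution
  ref <- reference_hmm("WT")
  sim <- simulate_tracks(D = ref$D, A = ref$A, n_tracks = 20000,
                         mean_track_len = 6, seed = 4)
  occ <- as.numeric(table(sim$truth$state)) / nrow(sim$truth)
  expect_lt(max(abs(occ - ref$pi)), 0.01)

  # counts conservation
  expect_equal(length(unique(sim$tracks$track_id)), 20000)

  expect_error(simulate_tracks(D = c(0.1, -0.2), A = diag(2), n_tracks = 5, seed = 1),
               ">= 0")
  expect_error(simulate_tracks(D = c(0.1, 0.2), A = matrix(c(1, 0.5, 0, 0.6), 2),
                               n_tracks = 5, seed = 1), "sum to 1")
})

test_that("detailed-balance transition construction matches flow algebra", {
  # 2 states: fully determined by flow balance
  A <- build_transition_matrix(c(0.3, 0.7), c(0.9, NA))
  expect_equal(A[1, 2], 0.1)
  expect_equal(A[2, 1], 0.3 * 0.1 / 0.7)

  # stationary distribution of any valid output equals pi (power iteration)
  for (case in list(list(pi = c(0.2, 0.8), stay = c(0.7, NA)),
                    list(pi = c(0.11, 0.62, 0.28) / 1.01,
                         stay = c(0.85, 0.81, 0.59)))) {
    A <- suppressMessages(build_transition_matrix(case$pi, case$stay))
    expect_equal(rowSums(A), rep(1, length(case$pi)))
    pival <- case$pi / sum(case$pi)
    expect_lt(max(abs(power_stationary(A) - pival)), 1e-8)
  }

  # uniform pi with equal stays is symmetric
  A <- build_transition_matrix(rep(1 / 3, 3), rep(0.8, 3))
  expect_equal(A, t(A))
  expect_equal(unique(A[upper.tri(A)]), A[1, 2])

  # infeasible combination: state 3 sheds more flow than 1 and 2 can absorb
  expect_error(build_transition_matrix(c(0.45, 0.45, 0.1), c(0.99, 0.99, 0.1)),
               "infeasible")
})

test_that("reference models reproduce the published state parameters", {
  wt <- reference_hmm("WT")
  expect_equal(wt$D, c(0.02, 0.12, 0.47))
  expect_equal(wt$pi, c(0.11, 0.62, 0.28) / 1.01)
  expect_equal(wt$A[1, 2], 0.10, tolerance = 1e-12)
  expect_equal(wt$A[1, 3], 0.05, tolerance = 1e-12)
  expect_equal(wt$A[3, 2], 0.39, tolerance = 1e-10)
  expect_equal(as.numeric(stationary_distribution(wt$A)), wt$pi, tolerance = 1e-9)
  cs <- reference_hmm("CS")
  expect_equal(cs$A[1, 2], 0.24, tolerance = 1e-12)
  expect_equal(as.numeric(stationary_distribution(cs$A)), cs$pi, tolerance = 1e-9)
})
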