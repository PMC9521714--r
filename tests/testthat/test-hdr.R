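# well-separated planted nanocluster layout reused across tests
planted_centers <- rbind(c(500, 500), c(1500, 500), c(1000, 1500))

planted_sim <- function(seed, hdr_sigma = 40, hdr_points = 200,
                        background_density = 100) {
  simulate_smlm_synapse(n_hdrs = 3, hdr_centers = planted_centers,
                        hdr_sigma = hdr_sigma, hdr_points = hdr_points,
                        background_density = background_density,
                        psd_density = 0, psd_background_density = 0,
                        loc_uncertainty = 0, seed = seed)
}

test_that("uniform fields yield no HDRs", {
  sim <- simulate_smlm_synapse(n_hdrs = 0, psd_density = 0,
                               psd_background_density = 0, seed = 17)
  dens <- randomization_null(sim$akap_field, seed = 18, n_reps = 100)
  hdrs <- delineate_hdrs(sim$akap_field, dens)
  expect_equal(nrow(hdrs$regions), 0)
})

test_that("planted Gaussian clusters are recovered with accurate centroids", {
  sim <- planted_sim(seed = 23)
  dens <- randomization_null(sim$akap_field, seed = 24, n_reps = 100)
  hdrs <- delineate_hdrs(sim$akap_field, dens)
  expect_equal(nrow(hdrs$regions), 3)
  got <- as.matrix(hdrs$regions[c("centroid_x_nm", "centroid_y_nm")])
  err <- sapply(seq_len(3), function(k)
    min(sqrt(rowSums(sweep(got, 2, planted_centers[k, ])^2))))
  expect_lt(max(err), 25)
  # HDR members are disjoint and all supra-cutoff
  all_members <- unlist(hdrs$members)
  expect_equal(anyDuplicated(all_members), 0)
  expect_true(all(dens$counts[all_members] > dens$cutoff))
})

test_that("cluster effective diameters fall in the nanocluster size range", {
  diams <- unlist(lapply(1:3, function(s) {
    sim <- planted_sim(seed = s, hdr_sigma = 50)
    dens <- randomization_null(sim$akap_field, seed = s + 50, n_reps = 50)
    delineate_hdrs(sim$akap_field, dens)$regions$diameter_nm
  }))
  expect_true(all(diams >= 100 & diams <= 300))
})

test_that("HDR delineation is permutation invariant up to region order", {
  sim <- planted_sim(seed = 29)
  locs <- sim$akap_field$locs
  dens <- randomization_null(sim$akap_field, seed = 30, n_reps = 50)
  hdrs <- delineate_hdrs(sim$akap_field, dens)
  perm <- sample(nrow(locs))
  fp <- localization_field(locs$x_nm[perm], locs$y_nm[perm], roi = sim$akap_field$roi)
  densp <- randomization_null(fp, seed = 30, n_reps = 50)
  hdrsp <- delineate_hdrs(fp, densp)
  o1 <- order(hdrs$regions$centroid_x_nm)
  o2 <- order(hdrsp$regions$centroid_x_nm)
  expect_equal(hdrs$regions$centroid_x_nm[o1], hdrsp$regions$centroid_x_nm[o2])
  expect_equal(hdrs$regions$diameter_nm[o1], hdrsp$regions$diameter_nm[o2])
})

test_that("PSD outline recovers a dense disc on faint background", {
  disc_field <- function(seed, ctr, disc_density = 4000, bg = 400) {
    set.seed(seed)
    n_d <- rpois(1, disc_density * pi * 150^2 / 1e6)
    th <- runif(n_d, 0, 2 * pi); rr <- 150 * sqrt(runif(n_d))
    n_b <- rpois(1, bg * 9)
    localization_field(c(ctr[1] + rr * cos(th), runif(n_b, 0, 3000)),
                       c(ctr[2] + rr * sin(th), runif(n_b, 0, 3000)),
                       channel = "PSD95",
                       roi = matrix(c(0, 0, 3000, 0, 3000, 3000, 0, 3000),
                                    ncol = 2, byrow = TRUE))
  }
  for (s in 1:3) {
    p <- delineate_psd(disc_field(s, c(1500, 1500)))
    expect_equal(p$area_nm2, pi * 150^2, tolerance = 0.2)
  }
  # two discs, one much denser: outline encloses only the denser component
  set.seed(9)
  mk_disc <- function(n, ctr) {
    th <- runif(n, 0, 2 * pi); rr <- 150 * sqrt(runif(n))
    cbind(ctr[1] + rr * cos(th), ctr[2] + rr * sin(th))
  }
  dense <- mk_disc(600, c(800, 1500))
  faint <- mk_disc(60, c(2300, 1500))
  bg <- cbind(runif(3000, 0, 3000), runif(3000, 0, 3000))
  f2 <- localization_field(c(dense[, 1], faint[, 1], bg[, 1]),
                           c(dense[, 2], faint[, 2], bg[, 2]),
                           roi = matrix(c(0, 0, 3000, 0, 3000, 3000, 0, 3000),
                                        ncol = 2, byrow = TRUE))
  p2 <- delineate_psd(f2)
  expect_true(all(point_in_polygon(dense[, 1], dense[, 2], p2$polygon) |
                    as.numeric(point_to_contour_distance(dense, p2$polygon)) < 160))
  expect_false(any(point_in_polygon(faint[, 1], faint[, 2], p2$polygon)))

  empty <- localization_field(numeric(0), numeric(0),
                              roi = matrix(c(0, 0, 1, 0, 1, 1, 0, 1), ncol = 2,
                                           byrow = TRUE))
  expect_error(delineate_psd(empty), "empty")
})

test_that("HDR positional classes follow the PSD-band geometry", {
  square <- rbind(c(0, 0), c(200, 0), c(200, 200), c(0, 200))
  fake_hdrs <- structure(list(
    regions = data.frame(id = 1:3,
                         centroid_x_nm = c(100, 250, 500),
                         centroid_y_nm = c(100, 100, 100),
                         diameter_nm = 50, n_points = 20,
                         class = NA_character_),
    members = list(1L, 2L, 3L), link_radius = 50, min_points = 10,
    cutoff = 1), class = "hdr_set")
  got <- classify_hdr_positions(fake_hdrs, square, peri_band = 100)
  expect_equal(got$regions$class, c("psd-overlapping", "peri-synaptic", "distal"))
})

test_that("peripherally placed nanoclusters classify as peri-synaptic", {
  classes <- unlist(lapply(1:4, function(s) {
    sim <- simulate_smlm_synapse(seed = s)
    psd <- delineate_psd(sim$psd_field)
    dens <- randomization_null(sim$akap_field, seed = s + 200, n_reps = 50)
    hdrs <- classify_hdr_positions(delineate_hdrs(sim$akap_field, dens), psd)
    hdrs$regions$class
  }))
  expect_gt(mean(classes == "peri-synaptic"), 0.5)
})
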