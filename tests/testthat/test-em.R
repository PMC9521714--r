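test_that("zone assignment follows the membrane-distance rules", {
  ann <- make_box_annotation(particles = data.frame(
    x_nm = c(500, 100, 500, 2000),
    y_nm = c(570, 590, 450, 300)))
  za <- assign_zone(ann, depth = 100)
  # 30 nm beneath the PSD arc midpoint; 10 nm beneath off-PSD membrane
  # 200 nm along the contour from the PSD edge; 150 nm deep; outside
  expect_equal(za$zone, c("synaptic", "extrasynaptic", "cytoplasm", "outside"))
  expect_equal(za$distance_nm, c(30, 10, 150, 1000))

  # shaft compartment uses the nonsynaptic-shaft label
  shaft <- make_box_annotation(particles = data.frame(x_nm = 100, y_nm = 590),
                               compartment = "dendrite-shaft")
  expect_equal(assign_zone(shaft)$zone, "nonsynaptic-shaft")

  # membrane-proximal particles without a PSD cannot be zoned
  nopsd <- make_box_annotation(particles = data.frame(x_nm = 500, y_nm = 570),
                               psd = FALSE)
  expect_error(assign_zone(nopsd), "PSD")
})

test_that("every in-contour particle receives exactly one zone", {
  sim <- simulate_em_spine(zone_counts = c(synaptic = 60, extrasynaptic = 120),
                           seed = 19)
  za <- assign_zone(sim$annotation)
  expect_equal(nrow(za), 180)
  expect_true(all(za$zone %in% c("synaptic", "extrasynaptic", "cytoplasm")))
  tot <- sum(za$zone %in% c("synaptic", "extrasynaptic", "cytoplasm"))
  expect_equal(tot, sum(point_in_polygon(sim$annotation$particles$x_nm,
                                         sim$annotation$particles$y_nm,
                                         unclass(sim$annotation$contour))))
})

test_that("generator zone offsets are recovered by the distance pipeline", {
  sim <- simulate_em_spine(zone_counts = c(synaptic = 400, extrasynaptic = 600),
                           head_width = 1400, head_height = 1000,
                           psd_arc_length = 500, seed = 37)
  za <- assign_zone(sim$annotation)
  for (z in c("synaptic", "extrasynaptic")) {
    truth <- sim$truth$offset_nm[sim$truth$zone == z]
    got <- za$distance_nm[za$zone == z]
    se <- sd(truth) / sqrt(length(truth))
    expect_lt(abs(mean(got) - mean(truth)), 3 * se)
  }
})

test_that("nearest-neighbor distances match forced geometry and Poisson theory", {
  expect_equal(nearest_neighbor_distances(cbind(c(0, 30), c(0, 0))), c(30, 30))
  tri <- 50 * rbind(c(0, 0), c(1, 0), c(0.5, sqrt(3) / 2))
  expect_equal(nearest_neighbor_distances(tri), rep(50, 3))
  expect_error(nearest_neighbor_distances(cbind(1, 1)), "2 points")

  # mean NND of a Poisson process ~ 0.5 / sqrt(lambda), within 5%
  set.seed(3)
  lambda <- 500 / 1e6            # 500 points per 1000x1000 box
  pts <- cbind(runif(500, 0, 1000), runif(500, 0, 1000))
  expect_equal(mean(nearest_neighbor_distances(pts)), 0.5 / sqrt(lambda),
               tolerance = 0.05)

  # multiset invariant under point reordering
  perm <- sample(500)
  expect_equal(sort(nearest_neighbor_distances(pts[perm, ])),
               sort(nearest_neighbor_distances(pts)))
})

test_that("hard-core generation respects the minimum spacing", {
  sim <- simulate_em_spine(zone_counts = c(synaptic = 8, extrasynaptic = 20),
                           head_width = 900, head_height = 700,
                           min_nnd = 30, seed = 8)
  nnd <- nearest_neighbor_distances(sim$annotation$particles)
  expect_gte(min(nnd), 30)
})

test_that("gold-cluster detection sizes components correctly", {
  expect_equal(nrow(detect_gold_clusters(cbind(0, 0), min_size = 3)), 0)
  two <- rbind(cbind(rnorm(5, 0, 10), rnorm(5, 0, 10)),
               cbind(rnorm(5, 1000, 10), rnorm(5, 1000, 10)))
  set.seed(1)
  got <- detect_gold_clusters(two, link_distance = 60, min_size = 3)
  expect_equal(nrow(got), 2)

  # uniform-disc clusters of 200 nm diameter measure within 100-300 nm
  set.seed(14)
  mk <- function(ctr) {
    th <- runif(40, 0, 2 * pi); rr <- 100 * sqrt(runif(40))
    cbind(ctr[1] + rr * cos(th), ctr[2] + rr * sin(th))
  }
  parts <- rbind(mk(c(0, 0)), mk(c(2000, 0)), mk(c(0, 2000)))
  cl <- detect_gold_clusters(parts, link_distance = 60, min_size = 4)
  expect_equal(nrow(cl), 3)
  expect_true(all(cl$diameter_nm >= 100 & cl$diameter_nm <= 300))
})

test_that("distance summaries report the published CV convention", {
  # mean 34, SD 18 -> CV 0.53 at two decimals
  set.seed(2)
  x <- rnorm(5000)
  x <- (x - mean(x)) / sd(x) * 18 + 34
  s <- summarize_distances(x)
  expect_equal(round(s$cv, 2), 0.53)
  expect_equal(s$mean, 34)
  expect_equal(s$sd, 18)

  const <- summarize_distances(rep(7, 10))
  expect_equal(const$sd, 0)
  expect_equal(const$cv, 0)
  expect_true(const$p25 <= const$median && const$median <= const$p75)

  # truncated-normal sample summary within 3 SE of the oracle mean
  sim <- simulate_em_spine(zone_counts = c(synaptic = 10000, extrasynaptic = 0),
                           head_width = 2000, head_height = 1600,
                           psd_arc_length = 700, seed = 4)
  s2 <- summarize_distances(sim$truth$offset_nm)
  mu <- truncnorm_mean_oracle(34, 18, 0, 100)
  expect_lt(abs(s2$mean - mu), 3 * s2$sd / sqrt(s2$n))

  expect_error(summarize_distances(numeric(0)), "empty")
})

test_that("zone label fractions reproduce the published percentages", {
  wt <- zone_label_fractions(c(synaptic = 180, extrasynaptic = 309))
  expect_equal(wt$percent, c(37, 63))
  cs <- zone_label_fractions(c(synaptic = 222, extrasynaptic = 403))
  expect_equal(cs$percent, c(36, 64))
  expect_equal(cs$percent_raw, c(100 * 222 / 625, 100 * 403 / 625))
  edge <- zone_label_fractions(c(a = 0, b = 10))
  expect_equal(edge$percent, c(0, 100))
  expect_error(zone_label_fractions(c(0, 0)), "zero total")
})

test_that("endosome label fractions recover the generator labeling rates", {
  one <- endosome_label_fraction(list(
    spine_annotation(rbind(c(0, 0), c(100, 0), c(50, 100)),
                     organelles = data.frame(kind = rep("large vesicle", 7),
                                             labeled = c(rep(TRUE, 6), FALSE)))))
  expect_equal(one$per_spine, 600 / 7, tolerance = 1e-9)

  cohort <- function(n_spines, frac, seed0) {
    lapply(seq_len(n_spines), function(i)
      simulate_em_spine(zone_counts = c(synaptic = 0, extrasynaptic = 0),
                        organelle_count = 7, organelle_labeled_fraction = frac,
                        seed = seed0 + i)$annotation)
  }
  wt <- endosome_label_fraction(cohort(27, 0.86, 100))
  expect_lt(abs(wt$mean - 86), 3 * wt$sd / sqrt(wt$n) + 1e-9)
  cs <- endosome_label_fraction(cohort(20, 0.45, 200))
  expect_lt(abs(cs$mean - 45), 3 * cs$sd / sqrt(cs$n) + 1e-9)
})

test_that("group comparisons match exact enumeration and published calls", {
  same <- compare_groups(c(1, 2, 3, 4), c(1, 2, 3, 4), test = "rank-sum")
  expect_gte(same$p_value, 0.99)

  # full-permutation oracle: groups (1,2,3) vs (4,5,6), 20 arrangements,
  # the observed split is the most extreme both ways -> two-sided p = 2/20
  ex <- compare_groups(c(1, 2, 3), c(4, 5, 6), test = "rank-sum")
  expect_equal(ex$p_value, 0.1)

  # synaptic-zone distance models are reliably separated; at these sample
  # sizes the rank-sum power at the 1e-4 level is ~0.85 (analytic normal
  # approximation), so every replicate is expected below 0.01 and the
  # majority below 1e-4
  reps <- sapply(1:20, function(s) {
    set.seed(s)
    a <- qnorm(pnorm(0, 34, 18) + runif(180) * (pnorm(100, 34, 18) - pnorm(0, 34, 18)), 34, 18)
    b <- qnorm(pnorm(0, 45, 25) + runif(222) * (pnorm(100, 45, 25) - pnorm(0, 45, 25)), 45, 25)
    compare_groups(a, b, test = "rank-sum")$p_value
  })
  expect_gte(mean(reps < 0.01), 0.95)
  expect_gte(mean(reps < 1e-4), 0.6)

  # multi-group paths return adjusted pairwise p-values
  set.seed(6)
  g <- list(a = rnorm(30, 10), b = rnorm(30, 10), c = rnorm(30, 14))
  kw <- compare_groups(g, test = "kruskal-wallis")
  expect_equal(nrow(kw$pairwise), 3)
  tk <- compare_groups(g, test = "anova-tukey")
  expect_equal(nrow(tk$pairwise), 3)
  expect_lt(tk$p_value, 0.01)

  expect_error(compare_groups(1, c(1, 2), test = "rank-sum"), "n >= 2")
})

test_that("conformation classification reproduces the published calls", {
  psd <- classify_conformation(list(mean = 11, sd = 3, n = 275),
                               list(mean = 20, sd = 8, n = 212))
  expect_equal(psd$call, "vertical-extended")
  extra <- classify_conformation(list(mean = 16, sd = 5, n = 301),
                                 list(mean = 15, sd = 5, n = 175))
  expect_equal(extra$call, "parallel-or-compact")
  eq <- classify_conformation(list(mean = 15, sd = 5, n = 100),
                              list(mean = 15, sd = 5, n = 100))
  expect_equal(eq$call, "parallel-or-compact")
  expect_error(classify_conformation(list(mean = 0, sd = 1, n = 50),
                                     list(mean = 10, sd = 1, n = 50)), "mean")
  expect_error(classify_conformation(list(mean = 10, sd = 1, n = 5),
                                     list(mean = 10, sd = 1, n = 50)), "n >= 10")
})
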