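## Seeded synthetic-data generators. Every generator takes an explicit seed
## and returns ground truth alongside the simulated data, so downstream
## recovery can always be scored.

#' Simulate a two-channel SMLM synapse
#'
#' Generates a PSD-marker channel (uniform localizations in a PSD disc) and
#' a scaffold-protein channel (uniform Poisson background plus isotropic
#' Gaussian nanocluster HDRs) over a rectangular ROI, emulating a
#' two-color localization map of one spine synapse. With
#' `hdr_placement = "peripheral"` the HDR centers are placed just outside
#' the PSD disc, within 100 nm of its boundary, reproducing peri-synaptic
#' nanocluster placement; `"uniform"` scatters them over the ROI.
#'
#' Each emitter can be duplicated to emulate fluorophore re-blinking:
#' a localization appears `1 + Poisson(blink_factor - 1)` times, each copy
#' jittered by the localization uncertainty. The default `blink_factor = 1`
#' disables duplication.
#'
#' @param roi_width,roi_height ROI extent in nm.
#' @param psd_center PSD disc center (nm); defaults to the ROI center.
#' @param psd_radius PSD disc radius in nm.
#' @param psd_density PSD-channel density in localizations/um^2.
#' @param n_hdrs number of scaffold nanoclusters.
#' @param hdr_sigma isotropic Gaussian spread of each nanocluster, nm.
#' @param hdr_points localizations per nanocluster.
#' @param hdr_placement `"peripheral"` or `"uniform"`.
#' @param hdr_centers optional n_hdrs x 2 matrix of explicit nanocluster
#'   centers (nm), overriding `hdr_placement`.
#' @param background_density scaffold-channel background density,
#'   localizations/um^2.
#' @param psd_background_density PSD-channel background density,
#'   localizations/um^2 (default: same as `background_density`).
#' @param loc_uncertainty per-coordinate localization jitter SD, nm.
#' @param blink_factor mean localizations per emitter (>= 1).
#' @param seed integer seed (mandatory).
#' @return List of class `smlm_synapse_sim`: `psd_field` and `akap_field`
#'   ([localization_field()]s), and `truth` (list with `hdr_centroids`
#'   matrix, `psd_center`, `psd_radius`, counts).
#' @export
simulate_smlm_synapse <- function(roi_width = 2000, roi_height = 2000,
                                  psd_center = NULL, psd_radius = 150,
                                  psd_density = 3000, n_hdrs = 3,
                                  hdr_sigma = 40, hdr_points = 200,
                                  hdr_placement = c("peripheral", "uniform"),
                                  hdr_centers = NULL,
                                  background_density = 300,
                                  psd_background_density = 2 * background_density,
                                  loc_uncertainty = 10, blink_factor = 1,
                                  seed) {
  if (missing(seed)) stop("seed is mandatory")
  hdr_placement <- match.arg(hdr_placement)
  if (roi_width <= 0 || roi_height <= 0) stop("non-positive ROI")
  if (psd_radius <= 0) stop("psd_radius must be > 0")
  if (any(c(psd_density, background_density, n_hdrs, hdr_points,
            loc_uncertainty) < 0) || blink_factor < 1)
    stop("densities/counts must be >= 0 and blink_factor >= 1")
  if (is.null(psd_center)) psd_center <- c(roi_width / 2, roi_height / 2)
  roi_area_um2 <- roi_width * roi_height / 1e6
  exp_total <- psd_density * pi * psd_radius^2 / 1e6 +
    background_density * roi_area_um2 + n_hdrs * hdr_points
  if (exp_total * blink_factor > 1e7) stop("parameters would generate > 1e7 points")
  set.seed(seed)
  roi <- matrix(c(0, 0, roi_width, 0, roi_width, roi_height, 0, roi_height),
                ncol = 2, byrow = TRUE)

  # PSD channel: uniform in disc at psd_density over its own uniform
  # background (the PSD-marker channel carries scattered off-PSD
  # localizations too; without them a self-thresholded delineation has no
  # contrast to work against)
  n_psd <- rpois(1, psd_density * pi * psd_radius^2 / 1e6)
  th <- runif(n_psd, 0, 2 * pi)
  rr <- psd_radius * sqrt(runif(n_psd))
  n_psd_bg <- rpois(1, psd_background_density * roi_area_um2)
  psd_xy <- rbind(cbind(psd_center[1] + rr * cos(th), psd_center[2] + rr * sin(th)),
                  cbind(runif(n_psd_bg, 0, roi_width), runif(n_psd_bg, 0, roi_height)))

  # scaffold channel: Poisson background + Gaussian clusters
  n_bg <- rpois(1, background_density * roi_area_um2)
  bg_xy <- cbind(runif(n_bg, 0, roi_width), runif(n_bg, 0, roi_height))
  centroids <- matrix(numeric(0), 0, 2)
  hdr_xy <- matrix(numeric(0), 0, 2)
  if (n_hdrs > 0) {
    if (!is.null(hdr_centers)) {
      centroids <- as.matrix(hdr_centers)
      if (nrow(centroids) != n_hdrs) stop("hdr_centers must have n_hdrs rows")
    } else if (hdr_placement == "peripheral") {
      ang <- runif(n_hdrs, 0, 2 * pi)
      rad <- psd_radius + runif(n_hdrs, 0, 100)
      centroids <- cbind(psd_center[1] + rad * cos(ang),
                         psd_center[2] + rad * sin(ang))
    } else {
      centroids <- cbind(runif(n_hdrs, 0, roi_width),
                         runif(n_hdrs, 0, roi_height))
    }
    for (k in seq_len(n_hdrs)) {
      hdr_xy <- rbind(hdr_xy, cbind(rnorm(hdr_points, centroids[k, 1], hdr_sigma),
                                    rnorm(hdr_points, centroids[k, 2], hdr_sigma)))
    }
  }
  akap_xy <- rbind(bg_xy, hdr_xy)

  blink <- function(xy) {
    if (nrow(xy) == 0L) return(xy)
    copies <- 1L + if (blink_factor > 1) rpois(nrow(xy), blink_factor - 1) else 0L
    xy <- xy[rep(seq_len(nrow(xy)), copies), , drop = FALSE]
    if (loc_uncertainty > 0)
      xy <- xy + matrix(rnorm(length(xy), 0, loc_uncertainty), ncol = 2)
    xy
  }
  psd_xy <- blink(psd_xy)
  akap_xy <- blink(akap_xy)
  clamp <- function(xy) {
    # jitter may push points marginally past the ROI edge; keep them in-field
    xy[, 1] <- pmin(pmax(xy[, 1], 0), roi_width)
    xy[, 2] <- pmin(pmax(xy[, 2], 0), roi_height)
    xy
  }
  psd_xy <- clamp(psd_xy); akap_xy <- clamp(akap_xy)
  structure(list(
    psd_field = localization_field(psd_xy[, 1], psd_xy[, 2], channel = "PSD95",
                                   uncertainty = loc_uncertainty, roi = roi),
    akap_field = localization_field(akap_xy[, 1], akap_xy[, 2], channel = "AKAP",
                                    uncertainty = loc_uncertainty, roi = roi),
    truth = list(hdr_centroids = centroids, psd_center = psd_center,
                 psd_radius = psd_radius, n_psd_disc = n_psd,
                 n_background = n_bg, n_hdr_points = nrow(hdr_xy)),
    seed = seed), class = "smlm_synapse_sim")
}

# truncated normal sampler by inverse CDF; bounds may be +/-Inf
rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd <= 0) return(rep(pmin(pmax(mean, lower), upper), n))
  pl <- pnorm(lower, mean, sd)
  pu <- pnorm(upper, mean, sd)
  qnorm(pl + runif(n) * (pu - pl), mean, sd)
}

# mean of a truncated normal (used by tests as the moment oracle)
truncnorm_mean <- function(mean, sd, lower = -Inf, upper = Inf) {
  a <- (lower - mean) / sd
  b <- (upper - mean) / sd
  mean + sd * (dnorm(a) - dnorm(b)) / (pnorm(b) - pnorm(a))
}

#' Simulate an annotated EM spine cross-section
#'
#' Builds a closed elliptical spine-head membrane contour with a PSD arc at
#' its top, then places immunogold particles at signed inward normal
#' offsets from the membrane. Each zone (synaptic = under the PSD arc,
#' extrasynaptic = under the rest of the contour) has its own truncated
#' normal offset model; lateral positions are uniform along the zone's
#' arc. Organelle records carry Bernoulli labeled/unlabeled flags.
#'
#' @param head_width,head_height spine-head ellipse axes, nm.
#' @param n_vertices vertices in the contour polygon.
#' @param psd_arc_length PSD arc length along the contour, nm.
#' @param zone_models named list (`synaptic`, `extrasynaptic`) of numeric
#'   vectors `c(mean, sd, lower, upper)`: truncated normal offset model in
#'   nm. Defaults are the wild-type models (34 +/- 18 truncated to
#'   \[0, 100\] synaptic; 13 +/- 5 truncated to \[0, 100\] extrasynaptic).
#' @param zone_counts named integer vector: particles per zone.
#' @param organelle_count number of organelle records.
#' @param organelle_labeled_fraction Bernoulli probability an organelle is
#'   labeled.
#' @param compartment `"spine"` or `"dendrite-shaft"`.
#' @param min_nnd optional hard-core minimum nearest-neighbor distance in
#'   nm: placements closer than this to an accepted particle are re-drawn.
#' @param seed integer seed (mandatory).
#' @return List of class `em_spine_sim`: `annotation`
#'   ([spine_annotation()]) and `truth` (data.frame: particle `zone` and
#'   generated `offset_nm`).
#' @export
simulate_em_spine <- function(head_width = 600, head_height = 500,
                              n_vertices = 200, psd_arc_length = 300,
                              zone_models = list(
                                synaptic = c(mean = 34, sd = 18, lower = 0, upper = 100),
                                extrasynaptic = c(mean = 13, sd = 5, lower = 0, upper = 100)),
                              zone_counts = c(synaptic = 20, extrasynaptic = 35),
                              organelle_count = 7,
                              organelle_labeled_fraction = 0.86,
                              compartment = c("spine", "dendrite-shaft"),
                              min_nnd = NULL, seed) {
  if (missing(seed)) stop("seed is mandatory")
  compartment <- match.arg(compartment)
  for (zm in zone_models) {
    if (zm[["mean"]] < 0 || zm[["lower"]] < 0) stop("distance means and truncation lower bounds must be >= 0")
  }
  if (any(zone_counts < 0)) stop("zone_counts must be >= 0")
  set.seed(seed)

  # contour: ellipse sampled at equal angles, oriented counter-clockwise;
  # interior (cytoplasm) is to the left of the direction of travel
  ang <- pi / 2 + seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
  verts <- cbind(head_width / 2 * cos(ang), head_height / 2 * sin(ang))
  contour <- membrane_contour(verts, closed = TRUE)
  total_len <- max(attr(contour, "arc_length"))
  if (psd_arc_length >= total_len) stop("psd_arc_length exceeds contour length")

  # PSD arc: contiguous vertex range starting at the first vertex
  arc0 <- attr(contour, "arc_length")[seq_len(n_vertices)]
  psd_range <- c(1L, max(which(arc0 <= psd_arc_length)))

  segs <- contour_segments(unclass(contour), TRUE)
  seg_norm <- sqrt((segs$x1 - segs$x0)^2 + (segs$y1 - segs$y0)^2)
  arc <- attr(contour, "arc_length")

  # place a batch of particles at arc positions s with inward normal
  # offsets off; the inward normal of a CCW polygon is the left-rotated
  # tangent (-dy, dx)
  place_at <- function(s, off) {
    seg <- findInterval(s, arc, rightmost.closed = TRUE)
    seg <- pmin(pmax(seg, 1L), n_vertices)
    dx <- segs$x1[seg] - segs$x0[seg]; dy <- segs$y1[seg] - segs$y0[seg]
    t <- (s - arc[seg]) / seg_norm[seg]
    cbind(segs$x0[seg] + t * dx - off * dy / seg_norm[seg],
          segs$y0[seg] + t * dy + off * dx / seg_norm[seg])
  }

  # lateral placements keep a margin of ~1.5 segments from the zone
  # boundaries so that nearest-point attribution (which can shift by one
  # segment through polygon discretization) never flips a truth label
  margin <- 1.5 * total_len / n_vertices
  place_zone <- function(zone, n) {
    if (n == 0L) return(NULL)
    if (zone == "synaptic" && psd_arc_length <= 2 * margin)
      stop("psd_arc_length too short for synaptic placement")
    zm <- zone_models[[zone]]
    draw_s <- function(m) if (zone == "synaptic")
      runif(m, margin, psd_arc_length - margin)
    else runif(m, psd_arc_length + margin, total_len - margin)
    if (is.null(min_nnd)) {
      s <- draw_s(n)
      offs <- rtruncnorm(n, zm[["mean"]], zm[["sd"]], zm[["lower"]], zm[["upper"]])
      return(list(pts = place_at(s, offs), offs = offs))
    }
    # hard-core placement: accept sequentially, re-draw on conflict;
    # bounded attempts so an over-packed zone fails loudly
    pts <- matrix(NA_real_, 0, 2); offs <- numeric(0)
    attempts <- 0L
    while (nrow(pts) < n) {
      attempts <- attempts + 1L
      if (attempts > 200L * n)
        stop(sprintf("cannot place %d '%s' particles with min_nnd = %g nm (zone too crowded)",
                     n, zone, min_nnd))
      off <- rtruncnorm(1, zm[["mean"]], zm[["sd"]], zm[["lower"]], zm[["upper"]])
      p <- place_at(draw_s(1), off)
      if (nrow(pts) > 0 &&
          min(sqrt((pts[, 1] - p[1])^2 + (pts[, 2] - p[2])^2)) < min_nnd) next
      pts <- rbind(pts, p); offs <- c(offs, off)
    }
    list(pts = pts, offs = offs)
  }

  zones <- names(zone_counts)
  all_pts <- matrix(numeric(0), 0, 2); truth <- NULL
  for (z in zones) {
    pl <- place_zone(z, zone_counts[[z]])
    if (is.null(pl)) next
    all_pts <- rbind(all_pts, pl$pts)
    truth <- rbind(truth, data.frame(zone = z, offset_nm = pl$offs,
                                     stringsAsFactors = FALSE))
  }
  particles <- if (nrow(all_pts) > 0)
    data.frame(id = seq_len(nrow(all_pts)), x_nm = all_pts[, 1], y_nm = all_pts[, 2])
  else data.frame(id = integer(), x_nm = numeric(), y_nm = numeric())

  kinds <- c("large vesicle", "coated vesicle", "amorphous cistern",
             "tubular cistern", "MVB-tubule", "other")
  organelles <- if (organelle_count > 0)
    data.frame(id = seq_len(organelle_count),
               kind = sample(kinds, organelle_count, replace = TRUE),
               labeled = rbinom(organelle_count, 1, organelle_labeled_fraction) == 1,
               stringsAsFactors = FALSE)
  else data.frame(id = integer(), kind = character(), labeled = logical())

  ann <- spine_annotation(contour = contour, psd = psd_range,
                          particles = particles, organelles = organelles,
                          compartment = compartment)
  structure(list(annotation = ann, truth = truth, seed = seed),
            class = "em_spine_sim")
}

#' Build a transition matrix from occupancies and stay probabilities
#'
#' Constructs a row-stochastic per-time-step transition matrix whose
#' stationary distribution equals `pi` and whose diagonal equals `stay`,
#' by solving for symmetric probability flows under detailed balance
#' (`pi_i A_ij = pi_j A_ji`). For two states one `stay` entry may be `NA`
#' and is solved from flow balance. Occupancies that sum to 1 within
#' +/- 0.02 (as printed rounded values often do) are renormalized with a
#' message.
#'
#' @param pi occupancy vector (positive, summing to ~1).
#' @param stay per-state stay probabilities in \[0, 1); `NA` allowed for
#'   one entry when `length(pi) == 2`.
#' @return K x K row-stochastic matrix with `diag == stay` and stationary
#'   distribution `pi`.
#' @examples
#' A <- build_transition_matrix(c(0.3, 0.7), c(0.9, NA))
#' A[2, 1]  # 0.3 * 0.1 / 0.7
#' @export
build_transition_matrix <- function(pi, stay) {
  K <- length(pi)
  if (any(pi <= 0)) stop("pi must be > 0")
  s <- sum(pi)
  if (abs(s - 1) > 0.02) stop("pi must sum to 1 (within 0.02)")
  if (abs(s - 1) > 1e-12) {
    message(sprintf("build_transition_matrix: renormalizing pi (sum %.4f)", s))
    pi <- pi / s
  }
  if (length(stay) != K) stop("stay must match pi in length")
  if (K == 2L && sum(is.na(stay)) == 1L) {
    i <- which(is.na(stay)); j <- 3L - i
    # flow balance: pi_j (1 - stay_j) = pi_i (1 - stay_i)
    stay[i] <- 1 - pi[j] * (1 - stay[j]) / pi[i]
    if (stay[i] < 0) stop("infeasible (pi, stay) combination")
  }
  if (anyNA(stay) || any(stay < 0) || any(stay >= 1))
    stop("stay probabilities must be in [0, 1)")
  b <- pi * (1 - stay)  # total outgoing flow per state
  Fm <- matrix(0, K, K)
  if (K == 1L) {
    # single state: nothing to solve
  } else if (K == 2L) {
    if (abs(b[1] - b[2]) > 1e-12) stop("infeasible (pi, stay) combination")
    Fm[1, 2] <- Fm[2, 1] <- b[1]
  } else if (K == 3L) {
    # F12 + F13 = b1; F12 + F23 = b2; F13 + F23 = b3
    F12 <- (b[1] + b[2] - b[3]) / 2
    F13 <- (b[1] + b[3] - b[2]) / 2
    F23 <- (b[2] + b[3] - b[1]) / 2
    if (min(F12, F13, F23) < -1e-12) stop("infeasible (pi, stay) combination")
    Fm[1, 2] <- Fm[2, 1] <- max(F12, 0)
    Fm[1, 3] <- Fm[3, 1] <- max(F13, 0)
    Fm[2, 3] <- Fm[3, 2] <- max(F23, 0)
  } else stop("K <= 3 supported")
  A <- Fm / pi
  diag(A) <- stay
  # guard: rounding noise
  A <- A / rowSums(A)
  A
}

#' Simulate switching-state Brownian trajectories
#'
#' Generates single-molecule tracks from a K-state diffusion hidden Markov
#' model: the initial state of each track is drawn from the stationary
#' distribution of `A`, the state evolves by `A` at every time step, and
#' each per-coordinate displacement is Gaussian with variance
#' `2 * D[state] * dt`. Observed positions optionally add independent
#' Gaussian localization error per coordinate. Track lengths follow a
#' geometric law (photobleaching-limited): the number of jumps per track is
#' `1 + Geometric`, with mean `mean_track_len` jumps, so every track has at
#' least two positions.
#'
#' @param D per-state diffusion coefficients, um^2/s (>= 0).
#' @param A K x K per-time-step transition matrix (row-stochastic). For a
#'   single state, omit or pass `matrix(1)`.
#' @param dt frame interval in s (default 0.022).
#' @param loc_error per-coordinate localization error SD, um (default 0).
#' @param n_tracks number of tracks.
#' @param mean_track_len mean jumps per track (>= 1; default 6).
#' @param confinement_radius optional reflecting circular boundary radius,
#'   um (default `NULL`, unconfined).
#' @param seed integer seed (mandatory).
#' @return List of class `track_sim`: `tracks` (data.frame `track_id`,
#'   `frame`, `x_um`, `y_um` of class `track_set` with a `dt` attribute)
#'   and `truth` (data.frame `track_id`, `frame`, `state`, one row per
#'   position).
#' @export
simulate_tracks <- function(D, A = NULL, dt = 0.022, loc_error = 0,
                            n_tracks = 1000, mean_track_len = 6,
                            confinement_radius = NULL, seed) {
  if (missing(seed)) stop("seed is mandatory")
  K <- length(D)
  if (any(D < 0)) stop("D must be >= 0 elementwise")
  if (dt <= 0) stop("dt must be > 0")
  if (mean_track_len < 1) stop("mean_track_len must be >= 1")
  if (is.null(A)) {
    if (K != 1L) stop("A required for more than one state")
    A <- matrix(1, 1, 1)
  }
  A <- as.matrix(A)
  if (nrow(A) != K || ncol(A) != K) stop("A must be K x K")
  if (any(abs(rowSums(A) - 1) > 1e-12)) stop("A rows must sum to 1 (within 1e-12)")
  pi0 <- stationary_distribution(A)
  set.seed(seed)
  n_jumps_per <- 1L + rgeom(n_tracks, prob = 1 / mean_track_len)
  total_pos <- sum(n_jumps_per) + n_tracks
  track_id <- rep.int(seq_len(n_tracks), n_jumps_per + 1L)
  frame <- unlist(lapply(n_jumps_per + 1L, seq_len), use.names = FALSE)
  sigma <- sqrt(2 * D * dt)  # per-coordinate displacement SD by state
  n_pos <- n_jumps_per + 1L
  starts <- cumsum(c(1L, n_pos[-n_tracks]))
  is_last <- logical(total_pos)
  is_last[starts + n_pos - 1L] <- TRUE

  # state chains, vectorized across tracks by step index
  st <- integer(total_pos)
  st[starts] <- sample.int(K, n_tracks, replace = TRUE, prob = pi0)
  if (K > 1L) {
    cumA <- t(apply(A, 1L, cumsum))
    for (t in 2:max(n_pos)) {
      act <- which(n_pos >= t)
      if (length(act) == 0L) break
      cur <- st[starts[act] + t - 2L]
      u <- runif(length(act))
      st[starts[act] + t - 1L] <-
        1L + rowSums(u > cumA[cur, , drop = FALSE])
    }
  }

  # displacements from the state at the jump origin; per-track cumsum
  origin_state <- st[!is_last]
  dx <- rnorm(total_pos - n_tracks, 0, sigma[origin_state])
  dy <- rnorm(total_pos - n_tracks, 0, sigma[origin_state])
  step_x <- numeric(total_pos); step_y <- numeric(total_pos)
  step_x[!c(TRUE, is_last[-total_pos])] <- dx   # zero at each track start
  step_y[!c(TRUE, is_last[-total_pos])] <- dy
  cx <- cumsum(step_x); cy <- cumsum(step_y)
  x <- cx - rep.int(cx[starts], n_pos)
  y <- cy - rep.int(cy[starts], n_pos)
  if (!is.null(confinement_radius)) {
    # reflect at a circular boundary centered at each track's origin
    r <- sqrt(x^2 + y^2)
    out <- r > confinement_radius
    f <- (2 * confinement_radius - r[out]) / r[out]
    x[out] <- x[out] * f; y[out] <- y[out] * f
  }
  if (loc_error > 0) {
    x <- x + rnorm(total_pos, 0, loc_error)
    y <- y + rnorm(total_pos, 0, loc_error)
  }
  tracks <- track_set(data.frame(track_id = track_id, frame = frame,
                                 x_um = x, y_um = y), dt = dt)
  structure(list(tracks = tracks,
                 truth = data.frame(track_id = track_id, frame = frame,
                                    state = st)),
            seed = seed, class = "track_sim")
}

#' Reference diffusion models for AKAP79 single-molecule tracking
#'
#' Returns the published three-state diffusion model for wild-type (WT) or
#' palmitoylation-deficient (CS) AKAP79 in spines: per-state apparent
#' diffusion coefficients, stationary occupancies, and a full per-time-step
#' transition matrix. Only some transition entries were reported
#' (bound-to-slow, bound-to-fast, fast-to-slow); the remaining entries are
#' completed by detailed balance against the occupancies via
#' [build_transition_matrix()], so the matrix reproduces the reported
#' entries, occupancies, and bound-state dwell time but is a model
#' completion, not itself a reported quantity. Occupancies are renormalized
#' to sum to 1 (the printed WT values sum to 1.01).
#'
#' @param variant `"WT"` or `"CS"`.
#' @return List with `D` (um^2/s, ascending), `pi` (stationary
#'   occupancies), `A` (3 x 3 transition matrix per 22 ms time step),
#'   `dt` (0.022 s), `variant`.
#' @export
reference_hmm <- function(variant = c("WT", "CS")) {
  variant <- match.arg(variant)
  dt <- 0.022
  if (variant == "WT") {
    D <- c(0.02, 0.12, 0.47)
    pi_raw <- c(0.11, 0.62, 0.28)          # printed; sum 1.01
    a12 <- 0.10; a13 <- 0.05; a32 <- 0.39  # printed per-time-step entries
  } else {
    D <- c(0.02, 0.15, 0.52)               # bound-state D taken equal to WT
    pi_raw <- c(0.11, 0.55, 0.34)
    a12 <- 0.24; a13 <- 0.05; a32 <- 0.27
  }
  p <- pi_raw / sum(pi_raw)
  # complete the matrix by detailed balance: flows F_ij = pi_i A_ij symmetric
  F12 <- p[1] * a12
  F13 <- p[1] * a13
  F23 <- p[3] * a32
  stay <- c(1 - a12 - a13,
            1 - (F12 + F23) / p[2],
            1 - a32 - F13 / p[3])
  A <- suppressMessages(build_transition_matrix(p, stay))
  list(D = D, pi = p, A = A, dt = dt, variant = variant)
}
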