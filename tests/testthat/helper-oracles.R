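# Independent oracles used across tests. These deliberately avoid the
# package's own code paths: brute force, enumeration, numerical
# integration, and power iteration.

# O(n^2) all-pairs fixed-radius neighbor counts
brute_density <- function(x, y, radius) {
  n <- length(x)
  counts <- integer(n)
  for (i in seq_len(n)) {
    d2 <- (x - x[i])^2 + (y - y[i])^2
    counts[i] <- sum(d2 <= radius^2) - 1L
  }
  counts
}

# minimum point-to-polyline distance by dense resampling of the contour
# (step nm between samples)
brute_contour_distance <- function(px, py, vertices, closed = TRUE, step = 0.1) {
  v <- as.matrix(vertices)
  if (closed) v <- rbind(v, v[1, ])
  samp <- NULL
  for (i in seq_len(nrow(v) - 1L)) {
    len <- sqrt(sum((v[i + 1L, ] - v[i, ])^2))
    t <- seq(0, 1, by = step / len)
    samp <- rbind(samp, cbind(v[i, 1] + t * (v[i + 1L, 1] - v[i, 1]),
                              v[i, 2] + t * (v[i + 1L, 2] - v[i, 2])))
  }
  vapply(seq_along(px), function(i)
    sqrt(min((samp[, 1] - px[i])^2 + (samp[, 2] - py[i])^2)), numeric(1))
}

# stationary distribution by power iteration
power_stationary <- function(A, iter = 10000) {
  p <- rep(1 / nrow(A), nrow(A))
  for (i in seq_len(iter)) p <- as.numeric(p %*% A)
  p / sum(p)
}

# mean of a truncated normal by numerical integration
truncnorm_mean_oracle <- function(mean, sd, lower, upper) {
  z <- integrate(function(x) dnorm(x, mean, sd), lower, upper)$value
  integrate(function(x) x * dnorm(x, mean, sd), lower, upper)$value / z
}

# rigid motion of a 2D point matrix
rigid_motion <- function(xy, angle, shift) {
  R <- matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2, 2)
  sweep(as.matrix(xy) %*% t(R), 2, -shift)
}

# a small annotated synapse with a flat PSD membrane segment for
# hand-checkable zone geometry: rectangle 1000 x 600 nm, PSD along the top
# edge between x = 300 and x = 700 (top edge runs right-to-left so the
# interior is left of travel)
make_box_annotation <- function(particles = data.frame(x_nm = numeric(),
                                                       y_nm = numeric()),
                                compartment = "spine", psd = TRUE) {
  xs <- seq(1000, 0, by = -25)          # top edge, right to left
  top <- cbind(xs, 600)
  verts <- rbind(top,
                 c(0, 300),
                 c(0, 0), c(500, 0), c(1000, 0),
                 c(1000, 300))
  psd_idx <- if (psd) c(which(xs == 700), which(xs == 300)) else NULL
  spine_annotation(membrane_contour(verts, closed = TRUE), psd = psd_idx,
                   particles = particles, compartment = compartment)
}
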