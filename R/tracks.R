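#' Construct a track set
#'
#' A track set holds single-molecule trajectories sampled at a fixed frame
#' interval: one row per localization with `track_id`, `frame`, `x_um`,
#' `y_um`. Within a track, frames must be strictly increasing; tracks with
#' frame gaps should be split before construction (as [read_tracks()]
#' does). Tracks with fewer than 2 positions are retained but contribute no
#' jumps.
#'
#' @param df data.frame with columns `track_id`, `frame`, `x_um`, `y_um`.
#' @param dt frame interval in seconds (default 0.022).
#' @return The data.frame, sorted by track and frame, of class
#'   `track_set` with attribute `dt`.
#' @export
track_set <- function(df, dt = 0.022) {
  req <- c("track_id", "frame", "x_um", "y_um")
  if (!all(req %in% names(df))) stop("need columns: ", paste(req, collapse = ", "))
  if (dt <= 0) stop("dt must be > 0")
  df <- df[order(df$track_id, df$frame), , drop = FALSE]
  if (anyDuplicated(df[c("track_id", "frame")]))
    stop("duplicate (track_id, frame) pairs")
  rownames(df) <- NULL
  structure(df, dt = dt, class = c("track_set", "data.frame"))
}

#' @export
print.track_set <- function(x, ...) {
  cat(sprintf("Track set: %d tracks, %d localizations, dt = %g s\n",
              length(unique(x$track_id)), nrow(x), attr(x, "dt")))
  invisible(x)
}

#' Pool single-step displacements
#'
#' Euclidean magnitudes of consecutive-frame displacements, pooled across
#' all tracks. Displacements are only taken between positions one frame
#' apart; tracks with fewer than 2 positions contribute nothing.
#'
#' @param tracks a [track_set()] (or a conforming data.frame).
#' @return Object of class `jump_set`: list with `magnitudes` (um), `dx`,
#'   `dy` (signed per-coordinate displacements), `dt`, `n_tracks`,
#'   `n_jumps`, and `track_id` (the track of each jump).
#' @export
compute_jumps <- function(tracks) {
  if (!inherits(tracks, "track_set")) tracks <- track_set(tracks)
  dt <- attr(tracks, "dt")
  same <- c(tracks$track_id[-1] == tracks$track_id[-nrow(tracks)], FALSE)
  consec <- c(diff(tracks$frame) == 1L, FALSE)
  i <- which(same & consec)
  if (length(i) == 0L) stop("no track with >= 2 consecutive positions")
  dx <- tracks$x_um[i + 1L] - tracks$x_um[i]
  dy <- tracks$y_um[i + 1L] - tracks$y_um[i]
  structure(list(magnitudes = sqrt(dx^2 + dy^2), dx = dx, dy = dy, dt = dt,
                 n_tracks = length(unique(tracks$track_id)),
                 n_jumps = length(i), track_id = tracks$track_id[i]),
            class = "jump_set")
}

#' @export
print.jump_set <- function(x, ...) {
  cat(sprintf("Jump set: %d jumps from %d tracks (dt = %g s); median %.3f um\n",
              x$n_jumps, x$n_tracks, x$dt, median(x$magnitudes)))
  invisible(x)
}

#' Jump-length summary statistics
#'
#' Median and quartiles of the pooled jump magnitudes (linear-interpolation
#' quantiles) plus the fractions of short and long jumps at fixed
#' thresholds.
#'
#' @param jumps a [compute_jumps()] result.
#' @param short short-jump threshold in um: fraction of jumps strictly
#'   below it (default 0.1).
#' @param long long-jump threshold in um: fraction of jumps at or above it
#'   (default 0.2).
#' @return Object of class `jump_stats`: list with `median`, `p25`, `p75`
#'   (um), `frac_short`, `frac_long`, `n_jumps`.
#' @export
jump_stats <- function(jumps, short = 0.1, long = 0.2) {
  stopifnot(inherits(jumps, "jump_set"))
  r <- jumps$magnitudes
  if (length(r) == 0L) stop("empty jump set")
  q <- quantile(r, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  structure(list(median = q[2], p25 = q[1], p75 = q[3],
                 frac_short = mean(r < short), frac_long = mean(r >= long),
                 short = short, long = long, n_jumps = length(r)),
            class = "jump_stats")
}

#' @export
print.jump_stats <- function(x, ...) {
  cat(sprintf("Jumps (n = %d): median %.3f um [%.3f, %.3f]; %.0f%% < %g um, %.0f%% >= %g um\n",
              x$n_jumps, x$median, x$p25, x$p75,
              100 * x$frac_short, x$short, 100 * x$frac_long, x$long))
  invisible(x)
}

#' Closed-form jump-magnitude mixture CDF
#'
#' Cumulative distribution of the single-step 2D displacement magnitude
#' under a K-state diffusion mixture: each state contributes a Rayleigh
#' component with mean squared magnitude `4 * D_k * dt + 4 * loc_error^2`,
#' weighted by occupancy. Serves as the analytic oracle for simulated jump
#' statistics.
#'
#' @param r jump magnitude(s), um.
#' @param D per-state diffusion coefficients, um^2/s.
#' @param pi state occupancies (summing to 1).
#' @param dt frame interval, s.
#' @param loc_error per-coordinate localization error SD, um (default 0).
#' @return `P(jump <= r)`, vectorized over `r`.
#' @export
mixture_cdf <- function(r, D, pi, dt, loc_error = 0) {
  if (length(D) != length(pi)) stop("D and pi lengths differ")
  if (abs(sum(pi) - 1) > 1e-6) stop("pi must sum to 1")
  v <- 4 * D * dt + 4 * loc_error^2   # mean squared magnitude per state
  sapply(r, function(ri) {
    if (ri <= 0) return(0)
    term <- ifelse(v > 0, exp(-ri^2 / v), 0)
    sum(pi * (1 - term))
  })
}

#' Per-state mean dwell times
#'
#' Mean residence time of each state of a discrete-time chain:
#' `dwell_k = dt / (1 - A_kk)`. States with `A_kk = 1` are absorbing and
#' get an infinite dwell time.
#'
#' @param A row-stochastic transition matrix.
#' @param dt time step, s.
#' @return Numeric vector of dwell times (s); attribute `absorbing` flags
#'   states with stay probability 1.
#' @export
dwell_times <- function(A, dt) {
  A <- as.matrix(A)
  if (any(abs(rowSums(A) - 1) > 1e-8) || any(A < 0)) stop("A must be row-stochastic")
  stay <- diag(A)
  structure(ifelse(stay >= 1, Inf, dt / (1 - stay)), absorbing = stay >= 1)
}

#' Stationary distribution of a transition matrix
#'
#' Left eigenvector of `A` for eigenvalue 1, normalized to sum to 1. The
#' chain must be irreducible and aperiodic (a unique eigenvalue on the
#' unit circle); otherwise an error is raised.
#'
#' @param A row-stochastic transition matrix.
#' @return Stationary occupancy vector.
#' @export
stationary_distribution <- function(A) {
  A <- as.matrix(A)
  if (any(abs(rowSums(A) - 1) > 1e-8) || any(A < 0)) stop("A must be row-stochastic")
  if (nrow(A) == 1L) return(1)
  e <- eigen(t(A))
  mod <- Mod(e$values)
  if (sum(mod > 1 - 1e-9) != 1L)
    stop("chain is reducible or periodic (non-unique unit eigenvalue)")
  v <- Re(e$vectors[, which.max(mod)])
  v <- v / sum(v)
  if (any(v < -1e-10)) stop("chain is reducible (negative stationary entries)")
  pmax(v, 0) / sum(pmax(v, 0))
}
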