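#' Local density of a localization field
#'
#' For each localization, counts the other localizations within a fixed
#' search radius (self excluded). This fixed-radius neighbor count is the
#' local-density statistic thresholded by the randomization null to
#' delineate high-density regions (HDRs).
#'
#' @param field a [localization_field()].
#' @param radius search radius in nm (default 50).
#' @return Integer vector of neighbor counts, one per localization.
#' @seealso [randomization_null()], [delineate_hdrs()]
#' @export
local_density <- function(field, radius = 50) {
  stopifnot(inherits(field, "localization_field"))
  if (radius <= 0) stop("radius must be > 0")
  if (nrow(field$locs) == 0L) stop("empty localization field")
  .count_within_radius(field$locs$x_nm, field$locs$y_nm, radius)
}

#' Randomization null for local density
#'
#' Estimates the local-density distribution expected if the same number of
#' localizations were scattered uniformly over the field's ROI. For each
#' replicate the localizations are re-drawn uniformly over the ROI polygon
#' and their neighbor counts computed; the null mean and SD are taken over
#' the pooled per-localization counts of all replicates. The HDR cutoff is
#' set 2.5 standard deviations above the null mean.
#'
#' No edge correction is applied: the same naive neighbor count is used for
#' the data and the null, so the ROI-edge deficit affects both identically.
#'
#' @inheritParams local_density
#' @param n_reps number of uniform randomization replicates (default 100).
#' @param seed integer seed (mandatory; every stochastic step in this
#'   package takes an explicit seed).
#' @param sd_multiplier multiplier on the null SD for the cutoff
#'   (default 2.5).
#' @return An object of class `density_result`: list with `radius`,
#'   `counts` (observed per-localization counts), `null_mean`, `null_sd`,
#'   `cutoff`, `n_reps`, `sd_multiplier`, `seed`.
#' @export
randomization_null <- function(field, radius = 50, n_reps = 100, seed,
                               sd_multiplier = 2.5) {
  stopifnot(inherits(field, "localization_field"))
  if (missing(seed)) stop("seed is mandatory")
  if (n_reps < 1) stop("n_reps must be >= 1")
  if (polygon_area(field$roi) <= 0) stop("degenerate ROI (area 0)")
  counts <- local_density(field, radius)
  n <- nrow(field$locs)
  set.seed(seed)
  null_counts <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    p <- runif_in_polygon(n, field$roi)
    null_counts[[r]] <- .count_within_radius(p[, 1], p[, 2], radius)
  }
  pooled <- unlist(null_counts)
  null_mean <- mean(pooled)
  null_sd <- if (length(pooled) > 1L) sd(pooled) else 0
  if (!is.finite(null_sd)) null_sd <- 0
  structure(list(radius = radius, counts = counts,
                 null_mean = null_mean, null_sd = null_sd,
                 cutoff = null_mean + sd_multiplier * null_sd,
                 n_reps = n_reps, sd_multiplier = sd_multiplier, seed = seed),
            class = "density_result")
}

#' @export
print.density_result <- function(x, ...) {
  cat(sprintf("Local-density null (radius %g nm, %d reps, seed %d):\n",
              x$radius, x$n_reps, x$seed))
  cat(sprintf("  null mean %.3f, SD %.3f -> cutoff %.3f (mean + %.1f SD)\n",
              x$null_mean, x$null_sd, x$cutoff, x$sd_multiplier))
  cat(sprintf("  %d / %d localizations above cutoff\n",
              sum(x$counts > x$cutoff), length(x$counts)))
  invisible(x)
}
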