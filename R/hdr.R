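#' Delineate high-density regions (HDRs)
#'
#' Links supra-cutoff localizations (local density above the randomization
#' null cutoff) into connected components by single linkage at
#' `link_radius`; components with at least `min_points` members become
#' HDRs. Each HDR gets a centroid and an effective diameter, defined as the
#' diameter of the circle whose area equals the convex hull area of the
#' member localizations.
#'
#' @param field a [localization_field()].
#' @param density a [randomization_null()] result computed on `field`.
#' @param link_radius linking distance in nm; defaults to the density
#'   radius.
#' @param min_points minimum member count for an HDR (default 10).
#' @return An object of class `hdr_set`: list with `regions` (data.frame:
#'   `id`, `centroid_x_nm`, `centroid_y_nm`, `diameter_nm`, `n_points`,
#'   `class`), `members` (list of member index vectors into the field), and
#'   the parameters used. `class` is `NA` until
#'   [classify_hdr_positions()] is applied.
#' @export
delineate_hdrs <- function(field, density, link_radius = density$radius,
                           min_points = 10) {
  stopifnot(inherits(field, "localization_field"),
            inherits(density, "density_result"))
  if (length(density$counts) != nrow(field$locs))
    stop("density was not computed on this field")
  supra <- which(density$counts > density$cutoff)
  regions <- data.frame(id = integer(), centroid_x_nm = numeric(),
                        centroid_y_nm = numeric(), diameter_nm = numeric(),
                        n_points = integer(), class = character(),
                        stringsAsFactors = FALSE)
  members <- list()
  if (length(supra) > 0L) {
    comp <- .link_components(field$locs$x_nm[supra], field$locs$y_nm[supra],
                             link_radius)
    for (cid in seq_len(max(comp))) {
      idx <- supra[comp == cid]
      if (length(idx) < min_points) next
      xs <- field$locs$x_nm[idx]; ys <- field$locs$y_nm[idx]
      members[[length(members) + 1L]] <- idx
      regions <- rbind(regions, data.frame(
        id = length(members),
        centroid_x_nm = mean(xs), centroid_y_nm = mean(ys),
        diameter_nm = effective_diameter(xs, ys),
        n_points = length(idx), class = NA_character_,
        stringsAsFactors = FALSE))
    }
  }
  structure(list(regions = regions, members = members,
                 link_radius = link_radius, min_points = min_points,
                 cutoff = density$cutoff),
            class = "hdr_set")
}

#' @export
print.hdr_set <- function(x, ...) {
  cat(sprintf("HDR set: %d region(s) (link radius %g nm, min %d points, cutoff %.2f)\n",
              nrow(x$regions), x$link_radius, x$min_points, x$cutoff))
  if (nrow(x$regions) > 0) print(x$regions, row.names = FALSE)
  invisible(x)
}

#' Density-based PSD delineation
#'
#' Outlines the postsynaptic density (PSD) from the PSD-marker channel
#' (e.g. PSD-95): localizations whose local density exceeds the channel's
#' own mean + `density_sd_cutoff` x SD are linked into components, and the
#' convex hull of the largest component is returned as the PSD polygon.
#'
#' Unlike HDR delineation, the cutoff here is taken from the channel's own
#' density distribution, not from a randomization null: within a synaptic
#' ROI the PSD marker concentrates in one compact disc, so its empirical
#' density distribution separates the PSD from the off-PSD background
#' directly.
#'
#' Because a localization near the PSD edge has about half its counting
#' disc outside the dense region, the supra-cutoff point set is eroded by
#' roughly half the counting radius relative to the true outline; the hull
#' is therefore dilated radially outward from its centroid by `radius / 2`
#' to compensate.
#'
#' @param psd_field a [localization_field()] holding the PSD-marker channel.
#' @param density_sd_cutoff SD multiplier above the channel mean density
#'   (default 2.0).
#' @param radius density radius in nm (default 50).
#' @param link_radius component linking radius, defaults to `radius`.
#' @return Object of class `psd_outline`: list with `polygon` (matrix, nm),
#'   `channel`, `cutoff`, `area_nm2`.
#' @export
delineate_psd <- function(psd_field, density_sd_cutoff = 2.0, radius = 50,
                          link_radius = radius) {
  stopifnot(inherits(psd_field, "localization_field"))
  if (nrow(psd_field$locs) == 0L) stop("empty PSD channel")
  counts <- local_density(psd_field, radius)
  cutoff <- mean(counts) + density_sd_cutoff * sd(counts)
  supra <- which(counts > cutoff)
  if (length(supra) < 3L) stop("no supra-cutoff PSD localizations")
  comp <- .link_components(psd_field$locs$x_nm[supra],
                           psd_field$locs$y_nm[supra], link_radius)
  biggest <- which.max(tabulate(comp))
  idx <- supra[comp == biggest]
  poly <- convex_hull_polygon(psd_field$locs$x_nm[idx], psd_field$locs$y_nm[idx])
  if (polygon_area(poly) <= 0) stop("degenerate PSD outline (zero area)")
  # edge compensation: dilate the hull outward by half the counting radius
  ctr <- colMeans(poly)
  rad <- sqrt((poly[, 1] - ctr[1])^2 + (poly[, 2] - ctr[2])^2)
  poly <- cbind(ctr[1] + (poly[, 1] - ctr[1]) * (1 + (radius / 2) / rad),
                ctr[2] + (poly[, 2] - ctr[2]) * (1 + (radius / 2) / rad))
  structure(list(polygon = poly,
                 channel = unique(psd_field$locs$channel)[1],
                 cutoff = cutoff,
                 area_nm2 = polygon_area(poly)),
            class = "psd_outline")
}

#' @export
print.psd_outline <- function(x, ...) {
  cat(sprintf("PSD outline from channel '%s': %d vertices, area %.4g um^2 (density cutoff %.2f)\n",
              x$channel, nrow(x$polygon), x$area_nm2 / 1e6, x$cutoff))
  invisible(x)
}

#' Classify HDR positions relative to the PSD
#'
#' Assigns each HDR a positional class from its centroid: inside the PSD
#' polygon is `psd-overlapping`; outside but within `peri_band` nm of the
#' PSD boundary is `peri-synaptic`; farther away is `distal`.
#'
#' @param hdrs an [delineate_hdrs()] result.
#' @param psd a [delineate_psd()] outline (or any polygon matrix).
#' @param peri_band peri-synaptic band width in nm (default 100).
#' @return The `hdr_set` with the `class` column filled in.
#' @export
classify_hdr_positions <- function(hdrs, psd, peri_band = 100) {
  stopifnot(inherits(hdrs, "hdr_set"))
  poly <- if (inherits(psd, "psd_outline")) psd$polygon else as.matrix(psd)
  if (polygon_area(poly) <= 0) stop("invalid PSD polygon")
  if (nrow(hdrs$regions) == 0L) return(hdrs)
  cx <- hdrs$regions$centroid_x_nm
  cy <- hdrs$regions$centroid_y_nm
  inside <- point_in_polygon(cx, cy, poly)
  d <- as.numeric(point_to_contour_distance(cbind(cx, cy), poly))
  cls <- ifelse(inside, "psd-overlapping",
                ifelse(d <= peri_band, "peri-synaptic", "distal"))
  hdrs$regions$class <- cls
  hdrs
}
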