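#' Construct a localization field
#'
#' A localization field is an ordered set of 2D single-molecule localizations
#' (nm) together with the analysis region of interest (ROI), typically the
#' synaptic region of one spine. Localizations falling outside the ROI are
#' rejected at construction, counted, and reported via the `n_rejected`
#' attribute (mirroring how off-ROI localizations are excluded at load).
#'
#' @param x,y localization coordinates in nm.
#' @param channel channel label (e.g. `"AKAP"`, `"PSD95"`); recycled.
#' @param frame acquisition frame index; recycled (default 1).
#' @param uncertainty localization uncertainty in nm; recycled (default NA).
#' @param roi ROI polygon as an n x 2 matrix (nm). When `NULL` the convex
#'   hull of the localizations is used and this fallback is recorded in the
#'   `roi_source` attribute.
#' @return An object of class `localization_field`: a list with elements
#'   `locs` (data.frame: `x_nm`, `y_nm`, `frame`, `channel`,
#'   `uncertainty_nm`) and `roi` (polygon matrix).
#' @export
localization_field <- function(x, y, channel = "default", frame = 1L,
                               uncertainty = NA_real_, roi = NULL) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y lengths differ")
  bad <- !is.finite(x) | !is.finite(y)
  n_nonfinite <- sum(bad)
  locs <- data.frame(x_nm = x, y_nm = y,
                     frame = as.integer(rep_len(frame, length(x))),
                     channel = rep_len(as.character(channel), length(x)),
                     uncertainty_nm = rep_len(as.numeric(uncertainty), length(x)),
                     stringsAsFactors = FALSE)[!bad, , drop = FALSE]
  roi_source <- "supplied"
  if (is.null(roi)) {
    if (nrow(locs) >= 3L) {
      roi <- convex_hull_polygon(locs$x_nm, locs$y_nm)
      roi_source <- "convex-hull"
    } else {
      roi <- matrix(c(0, 0, 1, 0, 1, 1, 0, 1), ncol = 2, byrow = TRUE)
      roi_source <- "degenerate"
    }
  }
  roi <- as.matrix(roi)
  if (ncol(roi) != 2L || nrow(roi) < 3L) stop("roi must be an n x 2 polygon, n >= 3")
  inside <- point_in_polygon(locs$x_nm, locs$y_nm, roi) |
    (point_to_contour_distance(cbind(locs$x_nm, locs$y_nm), roi) < 1e-9)
  n_outside <- sum(!inside)
  if (n_outside > 0 && roi_source == "supplied")
    message(sprintf("localization_field: rejected %d localization(s) outside the ROI", n_outside))
  structure(list(locs = locs[inside, , drop = FALSE], roi = roi),
            n_rejected = n_nonfinite + n_outside,
            roi_source = roi_source,
            class = "localization_field")
}

#' @export
print.localization_field <- function(x, ...) {
  cat("Localization field:", nrow(x$locs), "localizations,",
      length(unique(x$locs$channel)), "channel(s)\n")
  cat("  ROI polygon:", nrow(x$roi), "vertices, area",
      format(polygon_area(x$roi) / 1e6, digits = 4), "um^2\n")
  if (attr(x, "n_rejected") > 0)
    cat("  rejected at load:", attr(x, "n_rejected"), "\n")
  invisible(x)
}

# subset a field by channel, keeping the ROI
field_channel <- function(field, channel) {
  keep <- field$locs$channel == channel
  out <- field
  out$locs <- field$locs[keep, , drop = FALSE]
  out
}
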