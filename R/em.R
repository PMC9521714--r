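#' Construct an annotated spine cross-section
#'
#' Bundles one spine (or dendrite-shaft) annotation: the membrane contour,
#' the PSD segment along it, the immunogold particle coordinates, and
#' organelle records with labeled/unlabeled flags. All coordinates are nm.
#'
#' @param contour a [membrane_contour()] (or n x 2 matrix, treated as
#'   closed).
#' @param psd integer vector `c(start_idx, end_idx)`: contiguous contour
#'   vertex range covered by the PSD, or `NULL` for annotations without a
#'   PSD (synaptic-zone analyses then error).
#' @param particles data.frame with columns `x_nm`, `y_nm` (and optionally
#'   `id`).
#' @param organelles data.frame with columns `kind` (see
#'   [organelle_kinds()]) and `labeled` (logical), optionally `id`.
#' @param compartment `"spine"` or `"dendrite-shaft"`.
#' @return Object of class `spine_annotation`.
#' @export
spine_annotation <- function(contour, psd = NULL,
                             particles = data.frame(x_nm = numeric(), y_nm = numeric()),
                             organelles = data.frame(kind = character(), labeled = logical()),
                             compartment = c("spine", "dendrite-shaft")) {
  compartment <- match.arg(compartment)
  if (!inherits(contour, "membrane_contour"))
    contour <- membrane_contour(as.matrix(contour), closed = TRUE)
  n <- nrow(contour)
  if (!is.null(psd)) {
    psd <- as.integer(psd)
    if (length(psd) != 2L || psd[1] < 1L || psd[2] > n || psd[1] >= psd[2])
      stop("psd must be c(start_idx, end_idx) within the contour, start < end")
  }
  stopifnot(all(c("x_nm", "y_nm") %in% names(particles)))
  if (nrow(particles) > 0 && !all(is.finite(particles$x_nm) & is.finite(particles$y_nm)))
    stop("particle coordinates must be finite")
  if (is.null(particles$id)) particles$id <- seq_len(nrow(particles))
  if (nrow(organelles) > 0) {
    stopifnot(all(c("kind", "labeled") %in% names(organelles)))
    bad <- setdiff(unique(organelles$kind), organelle_kinds())
    if (length(bad)) stop("unknown organelle kind(s): ", paste(bad, collapse = ", "))
  }
  if (is.null(organelles$id)) organelles$id <- seq_len(nrow(organelles))
  structure(list(contour = contour, psd = psd, particles = particles,
                 organelles = organelles, compartment = compartment),
            class = "spine_annotation")
}

#' Controlled vocabulary of organelle kinds
#' @return Character vector of recognized organelle kinds.
#' @export
organelle_kinds <- function() {
  c("large vesicle", "coated vesicle", "amorphous cistern",
    "tubular cistern", "MVB-tubule", "other")
}

#' @export
print.spine_annotation <- function(x, ...) {
  cat(sprintf("Spine annotation (%s): contour %d vertices%s, %d particle(s), %d organelle(s)\n",
              x$compartment, nrow(x$contour),
              if (is.null(x$psd)) ", no PSD"
              else sprintf(", PSD vertices %d-%d", x$psd[1], x$psd[2]),
              nrow(x$particles), nrow(x$organelles)))
  invisible(x)
}

# arc-length interval [lo, hi] covered by the PSD vertex range
psd_arc_interval <- function(annotation) {
  arc <- attr(annotation$contour, "arc_length")
  c(arc[annotation$psd[1]], arc[annotation$psd[2]])
}

#' Assign particles to membrane zones
#'
#' Assigns each immunogold particle to a zone following the
#' membrane-distance rules: *synaptic* if the particle lies inside the
#' contour, its nearest contour point is on the PSD arc, and its membrane
#' distance is at most `depth` (100 nm default); *extrasynaptic* if the
#' nearest contour point is off the PSD arc within `depth` (for spine
#' annotations; *nonsynaptic-shaft* for dendrite-shaft annotations);
#' *cytoplasm* if deeper than `depth`; *outside* if not inside the contour.
#'
#' @param annotation a [spine_annotation()]; `psd` is required unless every
#'   particle is off-PSD by construction.
#' @param depth zone depth beneath the membrane, nm (default 100).
#' @return data.frame with one row per particle: `id`, `distance_nm`
#'   (minimum distance to the membrane contour) and `zone`.
#' @export
assign_zone <- function(annotation, depth = 100) {
  stopifnot(inherits(annotation, "spine_annotation"))
  p <- annotation$particles
  if (nrow(p) == 0L)
    return(data.frame(id = integer(), distance_nm = numeric(), zone = character()))
  pts <- cbind(p$x_nm, p$y_nm)
  d <- point_to_contour_distance(pts, annotation$contour)
  inside <- point_in_polygon(p$x_nm, p$y_nm, unclass(annotation$contour)) |
    (as.numeric(d) < 1e-9)
  arc_pos <- attr(d, "arc_position")
  membrane_zone <- if (annotation$compartment == "spine") "extrasynaptic" else "nonsynaptic-shaft"
  if (is.null(annotation$psd)) {
    on_psd <- rep(FALSE, nrow(p))
    if (any(inside & as.numeric(d) <= depth))
      stop("synaptic assignment requires a PSD segment; annotation has none")
  } else {
    iv <- psd_arc_interval(annotation)
    on_psd <- arc_pos >= iv[1] & arc_pos <= iv[2]
  }
  zone <- ifelse(!inside, "outside",
          ifelse(as.numeric(d) > depth, "cytoplasm",
          ifelse(on_psd, "synaptic", membrane_zone)))
  data.frame(id = p$id, distance_nm = as.numeric(d), zone = zone,
             stringsAsFactors = FALSE)
}

#' Nearest-neighbor distances within a point set
#'
#' For each point, the Euclidean distance to its nearest other point in the
#' same subset.
#'
#' @param points data.frame with `x_nm`, `y_nm`, or an n x 2 matrix.
#' @param subset optional logical or integer index selecting the subset to
#'   analyze (default: all points).
#' @return Numeric vector of nearest-neighbor distances (nm), one per
#'   point of the subset.
#' @export
nearest_neighbor_distances <- function(points, subset = NULL) {
  if (is.data.frame(points)) points <- cbind(points$x_nm, points$y_nm)
  points <- as.matrix(points)
  if (!is.null(subset)) points <- points[subset, , drop = FALSE]
  n <- nrow(points)
  if (n < 2L) stop("need at least 2 points")
  dm <- as.matrix(stats::dist(points))
  diag(dm) <- Inf
  unname(apply(dm, 1L, min))
}

#' Detect gold-particle clusters
#'
#' Single-linkage connected components of particles at `link_distance`;
#' components smaller than `min_size` are discarded. The cluster diameter
#' is the maximum pairwise member distance. The defaults (60 nm linking,
#' about twice the ~30 nm minimum observed nearest-neighbor spacing of
#' membrane labels, and 4 members) target the dense 100-300 nm gold
#' clusters seen in projection images.
#'
#' @param particles data.frame with `x_nm`, `y_nm` or an n x 2 matrix.
#' @param link_distance linking distance, nm (default 60).
#' @param min_size minimum cluster membership (default 4).
#' @return data.frame: `cluster`, `n_particles`, `centroid_x_nm`,
#'   `centroid_y_nm`, `diameter_nm`; attribute `members` lists member row
#'   indices per cluster.
#' @export
detect_gold_clusters <- function(particles, link_distance = 60, min_size = 4) {
  if (link_distance <= 0) stop("link_distance must be > 0")
  if (is.data.frame(particles)) particles <- cbind(particles$x_nm, particles$y_nm)
  particles <- as.matrix(particles)
  out <- data.frame(cluster = integer(), n_particles = integer(),
                    centroid_x_nm = numeric(), centroid_y_nm = numeric(),
                    diameter_nm = numeric())
  members <- list()
  if (nrow(particles) > 0L) {
    comp <- .link_components(particles[, 1], particles[, 2], link_distance)
    for (cid in seq_len(max(comp))) {
      idx <- which(comp == cid)
      if (length(idx) < min_size) next
      xy <- particles[idx, , drop = FALSE]
      members[[length(members) + 1L]] <- idx
      out <- rbind(out, data.frame(
        cluster = length(members), n_particles = length(idx),
        centroid_x_nm = mean(xy[, 1]), centroid_y_nm = mean(xy[, 2]),
        diameter_nm = max(stats::dist(xy))))
    }
  }
  attr(out, "members") <- members
  out
}

#' Summarize a distance sample
#'
#' Mean, SD (n-1 denominator), median, quartiles (linear-interpolation
#' quantiles), and coefficient of variation (SD/mean) of a distance
#' sample.
#'
#' @param distances numeric vector, nm (or any consistent unit).
#' @return Object of class `distance_summary`: list with `n`, `mean`,
#'   `sd`, `median`, `p25`, `p75`, `cv`.
#' @export
summarize_distances <- function(distances) {
  distances <- as.numeric(distances)
  distances <- distances[is.finite(distances)]
  n <- length(distances)
  if (n < 1L) stop("empty distance sample")
  m <- mean(distances)
  s <- if (n > 1L) sd(distances) else 0
  q <- quantile(distances, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  structure(list(n = n, mean = m, sd = s, median = q[2], p25 = q[1], p75 = q[3],
                 cv = if (m > 0) s / m else NA_real_),
            class = "distance_summary")
}

#' @export
print.distance_summary <- function(x, ...) {
  cat(sprintf("n = %d: mean %.3g +/- %.3g (CV %.2f), median %.3g [%.3g, %.3g]\n",
              x$n, x$mean, x$sd, x$cv, x$median, x$p25, x$p75))
  invisible(x)
}

# round half away from zero at `digits` decimals (report convention;
# base round() rounds half to even)
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Zone label-count fractions
#'
#' Converts per-zone label counts to percentages of the total. Reported
#' percentages are rounded half-up to the nearest integer; the raw values
#' are retained.
#'
#' @param counts named numeric vector of per-zone label counts.
#' @return data.frame: `zone`, `count`, `percent_raw`, `percent`.
#' @examples
#' zone_label_fractions(c(synaptic = 180, extrasynaptic = 309))
#' @export
zone_label_fractions <- function(counts) {
  total <- sum(counts)
  if (total <= 0) stop("zero total label count")
  raw <- 100 * counts / total
  data.frame(zone = names(counts), count = as.numeric(counts),
             percent_raw = as.numeric(raw),
             percent = as.numeric(round_half_up(raw)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Fraction of labeled endosomal structures per spine
#'
#' For each spine, the percentage of labeled membrane structures out of
#' all membrane structures in that spine; spines with no organelle records
#' are excluded (and counted in the `n_excluded` attribute). The group
#' summary is the mean +/- SD over spines.
#'
#' @param annotations list of [spine_annotation()]s (one per spine).
#' @return List of class `endosome_fraction`: `per_spine` (numeric %),
#'   `mean`, `sd`, `n`; attribute `n_excluded`.
#' @export
endosome_label_fraction <- function(annotations) {
  pct <- vapply(annotations, function(a) {
    n <- nrow(a$organelles)
    if (n == 0L) NA_real_ else 100 * sum(a$organelles$labeled) / n
  }, numeric(1))
  excl <- sum(is.na(pct))
  pct <- pct[!is.na(pct)]
  if (length(pct) == 0L) stop("all spines have empty organelle records")
  if (excl > 0)
    message(sprintf("endosome_label_fraction: excluded %d spine(s) with no organelles", excl))
  structure(list(per_spine = pct, mean = mean(pct),
                 sd = if (length(pct) > 1) sd(pct) else 0, n = length(pct)),
            n_excluded = excl, class = "endosome_fraction")
}

#' @export
print.endosome_fraction <- function(x, ...) {
  cat(sprintf("Labeled endosomal structures: %.1f%% +/- %.1f%% (N = %d spines)\n",
              x$mean, x$sd, x$n))
  invisible(x)
}

#' Compare distance samples between groups
#'
#' Two-sided group comparisons matching the tests used for immunogold
#' distance data: `rank-sum` (Mann-Whitney/Wilcoxon, exact when sample
#' sizes permit), `kruskal-wallis` (with pairwise Wilcoxon post hoc,
#' Holm-adjusted), or `anova-tukey` (one-way ANOVA with Tukey HSD).
#'
#' @param ... two or more numeric vectors, or a single named list of them.
#' @param test one of `"rank-sum"`, `"kruskal-wallis"`, `"anova-tukey"`.
#' @return List of class `group_comparison`: `test`, `statistic`,
#'   `p_value`, and for multi-group tests `pairwise` (data.frame of
#'   adjusted pairwise p-values).
#' @export
compare_groups <- function(..., test = c("rank-sum", "kruskal-wallis", "anova-tukey")) {
  test <- match.arg(test)
  groups <- list(...)
  if (length(groups) == 1L && is.list(groups[[1]])) groups <- groups[[1]]
  if (is.null(names(groups)) || any(names(groups) == ""))
    names(groups) <- paste0("group", seq_along(groups))
  if (any(vapply(groups, length, 1L) < 2L)) stop("each group needs n >= 2")
  if (test == "rank-sum") {
    if (length(groups) != 2L) stop("rank-sum compares exactly 2 groups")
    w <- suppressWarnings(wilcox.test(groups[[1]], groups[[2]],
                                      alternative = "two.sided"))
    out <- list(test = test, statistic = unname(w$statistic),
                p_value = w$p.value, pairwise = NULL)
  } else {
    values <- unlist(groups, use.names = FALSE)
    g <- factor(rep(names(groups), vapply(groups, length, 1L)),
                levels = names(groups))
    if (test == "kruskal-wallis") {
      k <- kruskal.test(values, g)
      pw <- suppressWarnings(pairwise.wilcox.test(values, g, p.adjust.method = "holm"))
      tab <- as.data.frame(as.table(pw$p.value), stringsAsFactors = FALSE)
      tab <- tab[!is.na(tab$Freq), ]
      names(tab) <- c("group_a", "group_b", "p_adj")
      out <- list(test = test, statistic = unname(k$statistic),
                  p_value = k$p.value, pairwise = tab)
    } else {
      fit <- aov(values ~ g)
      an <- summary(fit)[[1]]
      tk <- TukeyHSD(fit)$g
      out <- list(test = test, statistic = an[["F value"]][1],
                  p_value = an[["Pr(>F)"]][1],
                  pairwise = data.frame(pair = rownames(tk),
                                        p_adj = tk[, "p adj"],
                                        row.names = NULL))
    }
  }
  structure(out, class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s: statistic %.4g, p = %.4g\n", x$test, x$statistic, x$p_value))
  if (!is.null(x$pairwise)) print(x$pairwise, row.names = FALSE)
  invisible(x)
}

# Welch two-sample t test from summary statistics
welch_from_summary <- function(m1, s1, n1, m2, s2, n2) {
  se2 <- s1^2 / n1 + s2^2 / n2
  t <- (m2 - m1) / sqrt(se2)
  df <- se2^2 / ((s1^2 / n1)^2 / (n1 - 1) + (s2^2 / n2)^2 / (n2 - 1))
  p <- 2 * pt(-abs(t), df)
  list(t = t, df = df, p = p)
}

#' Classify scaffold conformation from terminus-to-membrane distances
#'
#' Compares the membrane distances of N- and C-terminal tags of a membrane
#' scaffold to call its orientation: a C-terminus about twice as far from
#' the membrane as the N-terminus (ratio >= 1.5 with Welch p < 0.01)
#' indicates a vertical, extended configuration; near-equal distances
#' (ratio within 1.25-fold, or no significant difference at p >= 0.05)
#' indicate a compact or membrane-parallel configuration; anything in
#' between is indeterminate.
#'
#' @param n_stats,c_stats N-/C-terminus distance summaries: a
#'   [summarize_distances()] object or a list/vector with `mean`, `sd`,
#'   `n`.
#' @return List of class `conformation_call`: `call` (one of
#'   `"vertical-extended"`, `"parallel-or-compact"`, `"indeterminate"`),
#'   `ratio` (mean C / mean N), `p_value` (Welch two-sided).
#' @examples
#' classify_conformation(list(mean = 11, sd = 3, n = 275),
#'                       list(mean = 20, sd = 8, n = 212))
#' @export
classify_conformation <- function(n_stats, c_stats) {
  getv <- function(s, f) as.numeric(s[[f]])
  mN <- getv(n_stats, "mean"); sN <- getv(n_stats, "sd"); nN <- getv(n_stats, "n")
  mC <- getv(c_stats, "mean"); sC <- getv(c_stats, "sd"); nC <- getv(c_stats, "n")
  if (nN < 10 || nC < 10) stop("need n >= 10 per terminus")
  if (mN <= 0 || mC <= 0) stop("zero or negative mean distance")
  ratio <- mC / mN
  p <- if (sN == 0 && sC == 0) {
    if (mN == mC) 1 else 0
  } else welch_from_summary(mN, sN, nN, mC, sC, nC)$p
  call <- if (ratio >= 1.5 && p < 0.01) "vertical-extended"
    else if ((ratio >= 1 / 1.25 && ratio <= 1.25) || p >= 0.05) "parallel-or-compact"
    else "indeterminate"
  structure(list(call = call, ratio = ratio, p_value = p),
            class = "conformation_call")
}

#' @export
print.conformation_call <- function(x, ...) {
  cat(sprintf("Conformation: %s (C/N distance ratio %.2f, Welch p = %.3g)\n",
              x$call, x$ratio, x$p_value))
  invisible(x)
}
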