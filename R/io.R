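## File formats: localization CSV (native and ThunderSTORM-style headers),
## track CSV, spine annotation JSON, ROI polygon JSON. Localization and EM
## coordinates are nm; track coordinates are um (each community's
## convention); the unit is part of the column name so files are
## self-describing.

#' Read a localization table
#'
#' Reads a localization CSV in the native dialect (`x_nm`, `y_nm`,
#' optional `frame`, `channel`, `uncertainty_nm`) or the ThunderSTORM
#' export dialect (`"x [nm]"`, `"y [nm]"`, `"frame"`,
#' `"uncertainty [nm]"`). Rows with non-finite coordinates are rejected
#' and counted in the field's `n_rejected` attribute.
#'
#' @param path CSV file path.
#' @param dialect `"auto"` (default), `"native"`, or `"thunderstorm"`.
#' @param roi ROI polygon (n x 2 matrix, nm) or path to a polygon JSON
#'   (object with `vertices_nm`); `NULL` uses the convex hull of the
#'   localizations.
#' @param channel optional channel label overriding the file's channel
#'   column.
#' @return A [localization_field()].
#' @export
read_localizations <- function(path, dialect = c("auto", "native", "thunderstorm"),
                               roi = NULL, channel = NULL) {
  dialect <- match.arg(dialect)
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  nm <- names(df)
  has_native <- all(c("x_nm", "y_nm") %in% nm)
  has_ts <- all(c("x [nm]", "y [nm]") %in% nm)
  if (dialect == "auto") dialect <- if (has_native) "native" else "thunderstorm"
  if (dialect == "native" && !has_native)
    stop("missing required columns x_nm, y_nm")
  if (dialect == "thunderstorm" && !has_ts)
    stop("missing required columns 'x [nm]', 'y [nm]'")
  if (dialect == "thunderstorm") {
    x <- df[["x [nm]"]]; y <- df[["y [nm]"]]
    unc <- if ("uncertainty [nm]" %in% nm) df[["uncertainty [nm]"]] else NA_real_
  } else {
    x <- df$x_nm; y <- df$y_nm
    unc <- if ("uncertainty_nm" %in% nm) df$uncertainty_nm else NA_real_
  }
  if (!is.numeric(x) || !is.numeric(y)) stop("non-numeric coordinates")
  if (is.character(roi) && length(roi) == 1L) {
    roi <- matrix(unlist(jsonlite::read_json(roi)$vertices_nm), ncol = 2,
                  byrow = TRUE)
  }
  localization_field(
    x, y,
    channel = if (!is.null(channel)) channel
              else if ("channel" %in% nm) df$channel else "default",
    frame = if ("frame" %in% nm) df$frame else 1L,
    uncertainty = unc, roi = roi)
}

#' Write a localization table (native dialect)
#' @param field a [localization_field()].
#' @param path output CSV path.
#' @param roi_path optional path for the ROI polygon JSON.
#' @return `path`, invisibly.
#' @export
write_localizations <- function(field, path, roi_path = NULL) {
  write.csv(field$locs, path, row.names = FALSE)
  if (!is.null(roi_path))
    jsonlite::write_json(list(schema = "roi-polygon/1",
                              vertices_nm = apply(field$roi, 1, as.numeric,
                                                  simplify = FALSE)),
                         roi_path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a trajectory table
#'
#' Reads a track CSV (`track_id`, `frame`, `x_um`, `y_um`), sorts by
#' frame, and splits tracks at frame gaps: a track with frames 1, 2, 4, 5
#' becomes two two-point tracks with suffixed ids (`"7.1"`, `"7.2"`).
#' Duplicate (track_id, frame) pairs are an error.
#'
#' @param path CSV file path.
#' @param dt frame interval in seconds (default 0.022).
#' @return A [track_set()]; attribute `n_split` counts tracks split at
#'   gaps.
#' @export
read_tracks <- function(path, dt = 0.022) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("track_id", "frame", "x_um", "y_um")
  if (!all(req %in% names(df))) stop("need columns: ", paste(req, collapse = ", "))
  if (anyDuplicated(df[c("track_id", "frame")]))
    stop("duplicate (track_id, frame) pairs")
  df <- df[order(df$track_id, df$frame), ]
  pieces <- split(df, df$track_id)
  n_split <- 0L
  out <- lapply(pieces, function(p) {
    brk <- cumsum(c(0L, diff(p$frame) != 1L))
    if (max(brk) > 0L) {
      n_split <<- n_split + 1L
      p$track_id <- paste0(p$track_id, ".", brk + 1L)
    }
    p
  })
  ts <- track_set(do.call(rbind, out), dt = dt)
  attr(ts, "n_split") <- n_split
  ts
}

#' Write a trajectory table
#' @param tracks a [track_set()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(tracks, path) {
  write.csv(as.data.frame(tracks), path, row.names = FALSE)
  invisible(path)
}

#' Read a spine annotation (JSON)
#'
#' Schema (version `spine-annotation/1`): `contour_nm` (list of
#' `[x, y]`), `closed`, `psd_idx` (`[start, end]`, 1-based, or absent),
#' `particles_nm` (list of `[x, y]`), `organelles` (list of
#' `{kind, labeled}`), `compartment`.
#'
#' @param path JSON file path.
#' @return A [spine_annotation()].
#' @export
read_spine_annotation <- function(path) {
  j <- jsonlite::read_json(path)
  contour <- matrix(unlist(j$contour_nm), ncol = 2, byrow = TRUE)
  particles <- if (length(j$particles_nm))
    data.frame(x_nm = vapply(j$particles_nm, function(p) p[[1]], 1),
               y_nm = vapply(j$particles_nm, function(p) p[[2]], 1))
  else data.frame(x_nm = numeric(), y_nm = numeric())
  organelles <- if (length(j$organelles))
    data.frame(kind = vapply(j$organelles, `[[`, "", "kind"),
               labeled = vapply(j$organelles, `[[`, TRUE, "labeled"),
               stringsAsFactors = FALSE)
  else data.frame(kind = character(), labeled = logical())
  spine_annotation(
    contour = membrane_contour(contour,
                               closed = if (is.null(j$closed)) TRUE else j$closed),
    psd = if (length(j$psd_idx)) unlist(j$psd_idx) else NULL,
    particles = particles, organelles = organelles,
    compartment = if (is.null(j$compartment)) "spine" else j$compartment)
}

#' Write a spine annotation (JSON)
#' @param annotation a [spine_annotation()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_spine_annotation <- function(annotation, path) {
  contour <- unclass(annotation$contour)
  jsonlite::write_json(list(
    schema = "spine-annotation/1",
    contour_nm = apply(contour, 1, as.numeric, simplify = FALSE),
    closed = attr(annotation$contour, "closed"),
    psd_idx = annotation$psd,
    particles_nm = if (nrow(annotation$particles))
      apply(annotation$particles[c("x_nm", "y_nm")], 1, as.numeric,
            simplify = FALSE) else list(),
    organelles = if (nrow(annotation$organelles))
      lapply(seq_len(nrow(annotation$organelles)), function(i)
        list(kind = annotation$organelles$kind[i],
             labeled = annotation$organelles$labeled[i])) else list(),
    compartment = annotation$compartment),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Run analysis stages from a configuration
#'
#' Executes the requested stages in dependency order with explicit seeds
#' and writes every stage's outputs plus a reproducible run report.
#' Identical configuration, inputs, and seeds give identical outputs.
#'
#' Supported stages: `"simulate-smlm"`, `"hdr"` (density null + HDR
#' delineation + PSD outline + positional classes), `"simulate-em"`,
#' `"em-dist"` (zone assignment + distance summaries + zone fractions),
#' `"simulate-tracks"`, `"jumps"`, `"hmm"`.
#'
#' @param config named list (or path to a JSON file) with elements
#'   `stages` (character vector), `seed` (integer), and optional per-stage
#'   parameter lists (`smlm`, `hdr`, `em`, `tracks`, `hmm`) whose entries
#'   override the corresponding function defaults. Input files can be
#'   given as `inputs$tracks_csv`, `inputs$localizations_csv`,
#'   `inputs$roi_json`, `inputs$annotation_json`.
#' @param outdir output directory (created if missing); `NULL` disables
#'   file output.
#' @return Object of class `run_report`: list with `config` (parameter
#'   echo), `results` (per-stage result objects), `outputs` (written file
#'   paths), `warnings`, `version`.
#' @export
run_pipeline <- function(config, outdir = NULL) {
  if (is.character(config) && length(config) == 1L)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  stages <- config$stages
  if (is.null(config$seed) && length(stages) > 0L)
    stop("config$seed is mandatory")
  seed <- config$seed
  if (!is.null(outdir) && !dir.exists(outdir))
    dir.create(outdir, recursive = TRUE)
  results <- list(); outputs <- character(0); warns <- character(0)
  emit <- function(name, writer) {
    if (is.null(outdir)) return(invisible(NULL))
    p <- file.path(outdir, name)
    writer(p)
    outputs <<- c(outputs, p)
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
           call. = FALSE))
  }
  ovr <- function(defaults, over) utils::modifyList(defaults, over %||% list())
  `%||%` <- function(a, b) if (is.null(a)) b else a

  for (stage in stages) {
    if (stage == "simulate-smlm") {
      run_stage(stage, {
        args <- ovr(list(seed = seed), as.list(config$smlm))
        sim <- do.call(simulate_smlm_synapse, args)
        results$smlm_sim <- sim
        emit("akap_localizations.csv", function(p) write_localizations(sim$akap_field, p))
        emit("psd_localizations.csv", function(p) write_localizations(sim$psd_field, p))
      })
    } else if (stage == "hdr") {
      run_stage(stage, {
        akap <- results$smlm_sim$akap_field %||%
          read_localizations(config$inputs$localizations_csv,
                             roi = config$inputs$roi_json)
        psd_field <- results$smlm_sim$psd_field
        pars <- ovr(list(radius = 50, n_reps = 100, link_radius = NULL,
                         min_points = 10, peri_band = 100), as.list(config$hdr))
        dens <- randomization_null(akap, radius = pars$radius,
                                   n_reps = pars$n_reps, seed = seed)
        hdrs <- delineate_hdrs(akap, dens,
                               link_radius = pars$link_radius %||% pars$radius,
                               min_points = pars$min_points)
        if (!is.null(psd_field)) {
          psd <- delineate_psd(psd_field, radius = pars$radius)
          hdrs <- classify_hdr_positions(hdrs, psd, peri_band = pars$peri_band)
          results$psd_outline <- psd
          emit("psd_outline.json", function(p)
            jsonlite::write_json(list(schema = "roi-polygon/1",
                                      vertices_nm = apply(psd$polygon, 1,
                                                          as.numeric,
                                                          simplify = FALSE)),
                                 p, auto_unbox = TRUE, digits = NA))
        }
        results$density <- dens
        results$hdrs <- hdrs
        emit("density.csv", function(p)
          write.csv(data.frame(x_nm = akap$locs$x_nm, y_nm = akap$locs$y_nm,
                               count = dens$counts,
                               above_cutoff = dens$counts > dens$cutoff),
                    p, row.names = FALSE))
        emit("hdr_table.csv", function(p)
          write.csv(hdrs$regions, p, row.names = FALSE))
      })
    } else if (stage == "simulate-em") {
      run_stage(stage, {
        args <- ovr(list(seed = seed), as.list(config$em))
        sim <- simulate_em_spine_from_config(args)
        results$em_sim <- sim
        emit("spine_annotation.json", function(p)
          write_spine_annotation(sim$annotation, p))
      })
    } else if (stage == "em-dist") {
      run_stage(stage, {
        ann <- results$em_sim$annotation %||%
          read_spine_annotation(config$inputs$annotation_json)
        za <- assign_zone(ann)
        counts <- table(factor(za$zone, levels = c("synaptic", "extrasynaptic",
                                                   "nonsynaptic-shaft",
                                                   "cytoplasm", "outside")))
        counts <- counts[counts > 0]
        results$zones <- za
        results$zone_fractions <- zone_label_fractions(
          setNames(as.numeric(counts), names(counts)))
        results$zone_summaries <- lapply(split(za$distance_nm, za$zone),
                                          summarize_distances)
        emit("particle_zones.csv", function(p) write.csv(za, p, row.names = FALSE))
        emit("zone_fractions.csv", function(p)
          write.csv(results$zone_fractions, p, row.names = FALSE))
      })
    } else if (stage == "simulate-tracks") {
      run_stage(stage, {
        args <- ovr(list(seed = seed), as.list(config$tracks))
        if (!is.null(args$reference)) {
          ref <- reference_hmm(args$reference)
          args$reference <- NULL
          args <- ovr(list(D = ref$D, A = ref$A, dt = ref$dt), args)
        }
        sim <- do.call(simulate_tracks, args)
        results$track_sim <- sim
        emit("tracks.csv", function(p) write_tracks(sim$tracks, p))
        emit("track_truth.csv", function(p)
          write.csv(sim$truth, p, row.names = FALSE))
      })
    } else if (stage == "jumps") {
      run_stage(stage, {
        tr <- results$track_sim$tracks %||%
          read_tracks(config$inputs$tracks_csv)
        jumps <- compute_jumps(tr)
        results$jumps <- jumps
        results$jump_stats <- jump_stats(jumps)
        emit("jump_stats.json", function(p)
          jsonlite::write_json(unclass(results$jump_stats), p,
                               auto_unbox = TRUE, digits = NA))
      })
    } else if (stage == "hmm") {
      run_stage(stage, {
        tr <- results$track_sim$tracks %||%
          read_tracks(config$inputs$tracks_csv)
        pars <- ovr(list(k_max = 3, n_restarts = 10, tol = 1e-8,
                         max_iter = 1000), as.list(config$hmm))
        fit <- fit_diffusion_hmm(tr, k_max = pars$k_max,
                                 n_restarts = pars$n_restarts,
                                 tol = pars$tol, max_iter = pars$max_iter,
                                 seed = seed)
        results$hmm <- fit
        emit("hmm_fit.json", function(p)
          jsonlite::write_json(list(K = fit$K, D = fit$D, A = fit$A,
                                    pi = fit$pi, dwell = fit$dwell,
                                    loglik = fit$loglik, bic = fit$bic,
                                    seed = fit$seed),
                               p, auto_unbox = TRUE, digits = NA))
      })
    } else stop("unknown stage: ", stage)
  }
  structure(list(config = config, results = results, outputs = outputs,
                 warnings = warns,
                 version = as.character(packageVersion("nanospine"))),
            class = "run_report")
}

# simulate_em_spine takes structured list arguments (zone_models as a list
# of numeric vectors); JSON configs arrive as nested lists, so coerce
simulate_em_spine_from_config <- function(args) {
  if (!is.null(args$zone_models))
    args$zone_models <- lapply(args$zone_models, function(z)
      setNames(as.numeric(z), c("mean", "sd", "lower", "upper")))
  if (!is.null(args$zone_counts)) args$zone_counts <- unlist(args$zone_counts)
  do.call(simulate_em_spine, args)
}

#' @export
print.run_report <- function(x, ...) {
  cat("Pipeline run (nanospine", x$version, ")\n")
  cat("  stages:", paste(x$config$stages, collapse = ", "), "\n")
  cat("  seed:", x$config$seed, "\n")
  if (length(x$outputs)) cat("  outputs:\n   ", paste(x$outputs, collapse = "\n    "), "\n")
  invisible(x)
}
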