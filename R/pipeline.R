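#' Run the full analysis pipeline on one movie
#'
#' Segmentation, wound tracking, phase detection, patch motion estimation,
#' distance maps (frozen at the last pre-closure wound once the wound is
#' gone, so post-closure speeds are still indexed by distance from the
#' former wound), velocity magnitude map, toward-wound decomposition,
#' displacement/velocity profiles, LBP texture series and descriptor
#' vectors. Deterministic: the same movie and configuration always produce
#' identical results.
#'
#' @param movie a [movie_stack()].
#' @param config a [run_config()].
#' @param phases optional `phase_partition` (or list with `t_contact`,
#'   `t_closure`) overriding automatic detection.
#' @param anchors_um anchor distances for displacement/velocity profiles.
#' @param texture compute the LBP texture series (default `TRUE`).
#' @param out_dir if non-`NULL`, write per-stage outputs (CSV, PNG
#'   heatmap, JSON manifest) into this directory.
#' @return list of class `wound_run` with elements `segmentation`,
#'   `phases`, `fields`, `toward_fields`, `dist_maps`, `map`,
#'   `displacement`, `profiles`, `lbp`, `descriptors`, `config`,
#'   `manifest`.
#' @export
run_experiment <- function(movie, config = run_config(), phases = NULL,
                           anchors_um = c(25, 50, 75), texture = TRUE,
                           out_dir = NULL) {
  stopifnot(inherits(movie, "movie_stack"))
  validate_run_config(config)
  px <- movie$pixel_size_um
  dt_hr <- frame_interval_hr(movie)
  nf <- n_frames(movie)

  seg <- segment_movie(movie, config)
  if (is.null(phases))
    phases <- detect_phases(seg$wound_masks, config$closure_area_fraction)

  ps_px <- max(8L, round(config$patch_size_um / px))
  grid <- patch_grid(frame_dim(movie), ps_px)
  radius <- search_radius_px(config, px, movie$frame_interval_min)
  vfloor <- config$variance_floor_frac * median_patch_variance(movie, grid)

  # distance reference: the live wound while open, frozen afterwards
  dist_maps <- vector("list", nf)
  ref <- NULL
  frozen <- logical(nf)
  for (k in seq_len(nf)) {
    w <- seg$wound_masks[[k]]
    if (any(w)) ref <- w else frozen[k] <- TRUE
    dist_maps[[k]] <- if (is.null(ref))
      distance_map(seg$cellular_masks[[k]],
                   matrix(FALSE, nrow(w), ncol(w)), px)
    else distance_map(seg$cellular_masks[[k]], ref, px)
  }

  fields <- vector("list", nf - 1L)
  toward <- vector("list", nf - 1L)
  for (k in seq_len(nf - 1L)) {
    f <- estimate_field(movie$frames[[k]], movie$frames[[k + 1L]], grid,
                        radius, px, movie$frame_interval_min,
                        cellular_mask = seg$cellular_masks[[k]],
                        min_ncc = config$min_ncc, variance_floor = vfloor)
    fields[[k]] <- f
    toward[[k]] <- toward_wound_components(f, dist_maps[[k]], px)
  }

  map <- build_velocity_map(toward, dist_maps[seq_len(nf - 1L)],
                            strip_width_um = config$strip_width_um)

  t_stop <- if (!is.na(phases$t_closure)) phases$t_closure - 1L else nf - 1L
  displacement <- average_cell_displacement(
    toward, anchors_um, dt_hr, strip_width_um = config$strip_width_um,
    t_stop = t_stop, mode = config$anchor_mode)
  profiles <- velocity_toward_profile(
    toward, anchors_um, strip_width_um = config$strip_width_um,
    smooth_frames = config$profile_smooth_frames)

  lbp <- if (texture) lbp_series(movie, seg$cellular_masks) else NULL

  descriptors <- list()
  if (!is.na(phases$t_contact)) {
    phases_used <- if (!is.na(phases$t_closure)) 3L else 2L
    desc <- velocity_descriptor(map, phases, config$n_distance_intervals,
                                phases_used = phases_used,
                                max_distance_um = config$max_distance_um)
    descriptors$velocity <- desc
    descriptors$velocity_normalized <- normalize_descriptor(desc)
    if (texture && !is.na(phases$t_closure) &&
        phases$t_contact < phases$t_closure)
      descriptors$texture_phase2 <- phase_texture_descriptor(lbp, phases, 2L)
  }

  run <- structure(
    list(segmentation = seg, phases = phases, fields = fields,
         toward_fields = toward, dist_maps = dist_maps,
         dist_frozen = frozen, map = map, displacement = displacement,
         profiles = profiles, lbp = lbp, descriptors = descriptors,
         grid = grid, config = config, movie_name = movie$name),
    class = "wound_run")

  if (!is.null(out_dir)) run$manifest <- write_run_outputs(run, out_dir)
  run
}

#' @export
print.wound_run <- function(x, ...) {
  cat(sprintf("wound_run '%s': %d frame pairs, map %d x %d bins\n",
              x$movie_name, length(x$fields), nrow(x$map), ncol(x$map)))
  print(x$phases)
  invisible(x)
}

write_run_outputs <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  paths$velocity_map <- file.path(out_dir, "velocity_map.csv")
  write_matrix(unclass(run$map), paths$velocity_map,
               row_labels = sprintf("t%03d", seq_len(nrow(run$map))),
               col_labels = sprintf("d%.1fum", attr(run$map, "bin_centers_um")))
  paths$heatmap <- file.path(out_dir, "velocity_map.png")
  plot_velocity_map(run$map, run$phases, file = paths$heatmap)
  paths$wound_area <- file.path(out_dir, "wound_area.csv")
  utils::write.csv(data.frame(frame = seq_along(run$segmentation$wound_area_um2),
                              wound_area_um2 = run$segmentation$wound_area_um2),
                   paths$wound_area, row.names = FALSE)
  if (!is.null(run$lbp)) {
    paths$lbp <- file.path(out_dir, "lbp_series.csv")
    write_matrix(unclass(run$lbp), paths$lbp,
                 row_labels = sprintf("f%03d", seq_len(nrow(run$lbp))),
                 col_labels = paste0("lbp", 0:9))
  }
  if (!is.null(run$descriptors$velocity)) {
    paths$descriptors <- file.path(out_dir, "descriptors.csv")
    dmat <- rbind(velocity = run$descriptors$velocity,
                  velocity_normalized = run$descriptors$velocity_normalized)
    utils::write.csv(dmat, paths$descriptors)
  }
  manifest <- list(
    movie = run$movie_name,
    config = unclass(run$config),
    phases = list(t_contact = run$phases$t_contact,
                  t_closure = run$phases$t_closure),
    outputs = lapply(paths, function(p)
      list(path = p, md5 = unname(tools::md5sum(p)))),
    package_version = as.character(utils::packageVersion("woundkinetics")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  manifest
}

#' Render a velocity magnitude map heatmap
#'
#' Time on the x axis, distance from the wound on the y axis, mean speed
#' as colour; vertical lines mark the phase boundaries (first contact,
#' closure).
#'
#' @param map a [build_velocity_map()] result.
#' @param phases optional `phase_partition` for the boundary lines.
#' @param file if non-`NULL`, write a PNG there instead of drawing on the
#'   current device.
#' @param ... passed to [graphics::image()].
#' @return `file` (or `NULL`) invisibly.
#' @export
plot_velocity_map <- function(map, phases = NULL, file = NULL, ...) {
  draw <- function() {
    graphics::image(x = seq_len(nrow(map)), y = attr(map, "bin_centers_um"),
                    z = unclass(map), col = grDevices::hcl.colors(64, "Inferno"),
                    xlab = "frame", ylab = "distance from wound edge (um)",
                    main = "velocity magnitude map (um/hr)", ...)
    if (!is.null(phases)) {
      if (!is.na(phases$t_contact))
        graphics::abline(v = phases$t_contact, col = "white", lwd = 2)
      if (!is.na(phases$t_closure))
        graphics::abline(v = phases$t_closure, col = "white", lwd = 2, lty = 2)
    }
  }
  if (!is.null(file)) {
    grDevices::png(file, width = 800, height = 500)
    on.exit(grDevices::dev.off())
    draw()
    invisible(file)
  } else {
    draw()
    invisible(NULL)
  }
}

#' Standard synthetic validation cohort
#'
#' Scenario list for a two-condition cohort mirroring the study design:
#' `n_untreated` untreated and `n_treated` HGF/SF-like treated movies with
#' distinct seeds and identical geometry.
#'
#' @param n_untreated,n_treated movies per condition (defaults 6 and 5).
#' @param base_seed integer; movie `i` uses seed `base_seed * 1000 + i`.
#' @param ... overrides passed to [synthetic_scenario()].
#' @return list with `scenarios` (list) and `labels` (character vector).
#' @export
cohort_scenarios <- function(n_untreated = 6L, n_treated = 5L,
                             base_seed = 0L, ...) {
  regimes <- c(rep("untreated", n_untreated), rep("treated", n_treated))
  scenarios <- lapply(seq_along(regimes), function(i)
    synthetic_scenario(regimes[i],
                       rng_seed = (base_seed %% 1000000L) * 1000L + i, ...))
  list(scenarios = scenarios, labels = regimes)
}

#' Configuration matched to the synthetic cohort geometry
#'
#' Distance intervals of 16 um over 0-96 um (six intervals), strip width
#' equal to one interval, suited to the 128 x 256 px, 2 um/px synthetic
#' frames where each monolayer spans roughly 100 um at scratch time.
#'
#' @param ... overrides passed to [run_config()].
#' @return a [run_config()].
#' @export
cohort_config <- function(...) {
  run_config(strip_width_um = 16, max_distance_um = 96,
             seg_window_um = 14, expected_max_speed_um_hr = 40, ...)
}

#' Run a labelled cohort end to end and classify treatment
#'
#' Computes one descriptor vector per movie (3 phases when every movie
#' closes, otherwise Phases 1-2 only), then leave-one-out SVM accuracy on
#' raw and norm-1 descriptors, the exact rank-sum p-value of the held-out
#' SVM decision scores between conditions, and 2-component PCA of the
#' normalized descriptors.
#'
#' @param movies list of [movie_stack()]s, or a `cohort_scenarios()` list
#'   (scenarios are then rendered on the fly).
#' @param labels condition label per movie (ignored when `movies` carries
#'   its own labels).
#' @param config a [run_config()].
#' @param texture also classify on Phase-2 LBP descriptors when every
#'   movie closes (default `TRUE`).
#' @param progress print one line per movie.
#' @return list of class `cohort_report`: `descriptors` (matrix),
#'   `labels`, `loocv_raw`, `loocv_normalized`, `ranksum`, `pca`,
#'   `phases_used`, and optionally `texture_descriptors`/`loocv_texture`.
#' @export
run_cohort <- function(movies, labels = NULL, config = cohort_config(),
                       texture = TRUE, progress = FALSE) {
  if (is.list(movies) && !is.null(movies$scenarios)) {
    labels <- movies$labels
    movies <- movies$scenarios
  }
  if (is.null(labels)) stop("labels required")
  if (length(movies) != length(labels))
    stop("one label per movie required")
  if (length(unique(labels)) < 2)
    stop("need at least 2 conditions for classification")
  if (any(table(labels) < 2))
    stop("need at least 2 movies per condition for leave-one-out")

  runs <- vector("list", length(movies))
  for (i in seq_along(movies)) {
    m <- movies[[i]]
    if (inherits(m, "synthetic_scenario")) m <- generate_movie(m)$movie
    if (progress) message("movie ", i, "/", length(movies), ": ", m$name)
    runs[[i]] <- run_experiment(m, config, texture = texture)
  }

  closures <- vapply(runs, function(r) r$phases$t_closure %||% NA_integer_,
                     integer(1))
  phases_used <- if (any(is.na(closures))) 2L else 3L
  desc <- t(vapply(runs, function(r)
    velocity_descriptor(r$map, r$phases, config$n_distance_intervals,
                        phases_used = phases_used,
                        max_distance_um = config$max_distance_um),
    numeric(config$n_distance_intervals * phases_used)))
  rownames(desc) <- vapply(runs, function(r) r$movie_name, character(1))
  desc_norm <- t(apply(desc, 1, normalize_descriptor))

  res_raw <- loocv_svm(desc, labels, cost = config$svm_cost,
                       standardize = config$svm_standardize)
  res_norm <- loocv_svm(desc_norm, labels, cost = config$svm_cost,
                        standardize = config$svm_standardize)
  lv <- levels(factor(labels))
  ranksum <- exact_ranksum(res_norm$decision_values[labels == lv[1]],
                           res_norm$decision_values[labels == lv[2]])
  out <- list(descriptors = desc, normalized_descriptors = desc_norm,
              labels = labels, phases_used = phases_used,
              loocv_raw = res_raw, loocv_normalized = res_norm,
              ranksum = ranksum, pca = pca2(desc_norm), runs = runs)
  if (texture && phases_used == 3L) {
    tex <- t(vapply(runs, function(r)
      r$descriptors$texture_phase2 %||% rep(NA_real_, 10), numeric(10)))
    if (!anyNA(tex)) {
      out$texture_descriptors <- tex
      out$loocv_texture <- loocv_svm(tex, labels, cost = config$svm_cost,
                                     standardize = config$svm_standardize)
    }
  }
  class(out) <- "cohort_report"
  out
}

#' @export
print.cohort_report <- function(x, ...) {
  cat(sprintf("cohort of %d movies (%s)\n", length(x$labels),
              paste(sprintf("%s: %d", names(table(x$labels)),
                            table(x$labels)), collapse = ", ")))
  cat(sprintf("  descriptors: length %d (%d phases x %d intervals)\n",
              ncol(x$descriptors), x$phases_used,
              ncol(x$descriptors) / x$phases_used))
  cat(sprintf("  LOOCV accuracy: raw %.1f%%, normalized %.1f%%\n",
              100 * x$loocv_raw$accuracy, 100 * x$loocv_normalized$accuracy))
  cat(sprintf("  rank-sum p (decision scores): %.4g%s\n",
              x$ranksum$p_value, if (x$ranksum$exact) " (exact)" else ""))
  if (!is.null(x$loocv_texture))
    cat(sprintf("  LOOCV accuracy (phase-2 texture): %.1f%%\n",
                100 * x$loocv_texture$accuracy))
  invisible(x)
}
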