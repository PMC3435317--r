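#' Movie stack: an ordered grayscale time-lapse plus acquisition metadata
#'
#' The raw input of every analysis: a sequence of single-channel frames of
#' identical size, the physical pixel size and the frame interval.
#' Intensities are rescaled internally to \[0, 1\] by a single min-max
#' transform over the *whole movie* (not per frame), so that texture codes
#' and segmentation thresholds are comparable across frames while pixel
#' ordering is preserved.
#'
#' @param frames list of numeric matrices (identical dimensions) or a 3-d
#'   array with frames along the third dimension.
#' @param pixel_size_um physical size of one pixel, micrometres (> 0).
#' @param frame_interval_min time between consecutive frames, minutes (> 0).
#' @param name identifier used in reports and file names.
#' @param normalize rescale intensities to \[0, 1\] by movie-wide min-max
#'   (default `TRUE`; a constant movie maps to all zeros).
#'
#' @return An object of class `movie_stack`: a list with elements `frames`
#'   (list of matrices in \[0, 1\]), `pixel_size_um`, `frame_interval_min`,
#'   `name`.
#' @examples
#' frs <- replicate(3, matrix(runif(64), 8, 8), simplify = FALSE)
#' mv <- movie_stack(frs, pixel_size_um = 1, frame_interval_min = 10)
#' n_frames(mv)
#' @export
movie_stack <- function(frames, pixel_size_um, frame_interval_min,
                        name = "movie", normalize = TRUE) {
  if (is.array(frames) && length(dim(frames)) == 3L)
    frames <- lapply(seq_len(dim(frames)[3]), function(i) frames[, , i])
  stopifnot(is.list(frames))
  if (length(frames) < 2L)
    stop("a movie needs at least 2 frames, got ", length(frames))
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all frames must share the same height and width")
  if (!is.numeric(pixel_size_um) || !is.finite(pixel_size_um) || pixel_size_um <= 0)
    stop("pixel_size_um must be finite and positive")
  if (!is.numeric(frame_interval_min) || !is.finite(frame_interval_min) ||
      frame_interval_min <= 0)
    stop("frame_interval_min must be finite and positive")
  frames <- lapply(frames, function(f) {
    storage.mode(f) <- "double"
    f
  })
  if (any(!vapply(frames, function(f) all(is.finite(f)), logical(1))))
    stop("frames contain non-finite intensities")
  if (normalize) {
    rng <- range(unlist(lapply(frames, range)))
    span <- rng[2] - rng[1]
    frames <- if (span > 0)
      lapply(frames, function(f) (f - rng[1]) / span)
    else
      lapply(frames, function(f) f * 0)
  }
  structure(
    list(frames = frames, pixel_size_um = pixel_size_um,
         frame_interval_min = frame_interval_min, name = name),
    class = "movie_stack")
}

#' @export
print.movie_stack <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("movie_stack '%s': %d frames of %d x %d px, %.3g um/px, %.3g min/frame\n",
              x$name, length(x$frames), d[1], d[2],
              x$pixel_size_um, x$frame_interval_min))
  invisible(x)
}

#' Number of frames / frame dimensions of a movie
#' @param movie a [movie_stack()].
#' @return `n_frames`: integer count; `frame_dim`: integer `c(rows, cols)`.
#' @export
n_frames <- function(movie) length(movie$frames)

#' @rdname n_frames
#' @export
frame_dim <- function(movie) dim(movie$frames[[1]])

#' Hours elapsed between consecutive frames
#' @param movie a [movie_stack()].
#' @return numeric scalar, hours.
#' @export
frame_interval_hr <- function(movie) movie$frame_interval_min / 60

read_one_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: ", path))
  if (length(dim(img)) == 3L) {
    if (dim(img)[3] > 1L)
      stop("multi-channel image not supported (single bright-field channel expected): ",
           path)
    img <- img[, , 1]
  }
  img
}

#' Read a time-lapse movie from disk
#'
#' Accepts either a multi-page TIFF or a directory of same-shaped
#' single-channel PNG/TIFF images; directory frames are ordered
#' lexicographically by file name. 8- and 16-bit input are supported
#' (values are rescaled movie-wide to \[0, 1\]); multi-channel images are
#' rejected.
#'
#' @param path multi-page TIFF file or directory of per-frame images.
#' @inheritParams movie_stack
#' @return A [movie_stack()].
#' @export
read_movie <- function(path, pixel_size_um, frame_interval_min,
                       name = basename(path)) {
  if (!file.exists(path)) stop("no such file or directory: ", path)
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.(png|tif|tiff)$",
                             ignore.case = TRUE, full.names = TRUE))
    if (length(files) < 2L) stop("fewer than 2 image files in ", path)
    frames <- lapply(files, read_one_image)
  } else {
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    if (length(pages) < 2L) stop("fewer than 2 pages in ", path)
    frames <- lapply(pages, function(img) {
      if (length(dim(img)) == 3L) {
        if (dim(img)[3] > 1L) stop("multi-channel TIFF not supported: ", path)
        img <- img[, , 1]
      }
      img
    })
  }
  movie_stack(frames, pixel_size_um, frame_interval_min, name = name)
}

#' Write a movie as a multi-page 16-bit TIFF
#'
#' @param movie a [movie_stack()].
#' @param path output file (`.tif`).
#' @param bits 16 (default) or 32 (IEEE float pages, lossless).
#' @return `path`, invisibly.
#' @export
write_movie <- function(movie, path, bits = 16L) {
  stopifnot(inherits(movie, "movie_stack"))
  frames <- movie$frames
  if (bits == 32L)
    tiff::writeTIFF(frames, path, bits.per.sample = 32L)
  else
    tiff::writeTIFF(frames, path, bits.per.sample = 16L)
  invisible(path)
}

#' Write / read a labelled numeric matrix as CSV
#'
#' Values round-trip at full double precision (`read_matrix(write_matrix(m))`
#' recovers `m` up to 1e-9). Non-finite entries are rejected with the
#' offending (row, col) indices.
#'
#' @param m numeric matrix, all entries finite.
#' @param path output CSV path.
#' @param row_labels,col_labels axis labels; default the dimnames or indices.
#' @return `path` invisibly (`write_matrix`); a numeric matrix with dimnames
#'   (`read_matrix`).
#' @export
write_matrix <- function(m, path, row_labels = NULL, col_labels = NULL) {
  stopifnot(is.matrix(m), is.numeric(m))
  bad <- which(is.nan(m) | is.infinite(m), arr.ind = TRUE)  # NA = missing bin
  if (nrow(bad))
    stop("non-finite entries at (row,col): ",
         paste(sprintf("(%d,%d)", bad[, 1], bad[, 2]), collapse = " "))
  rownames(m) <- row_labels %||% rownames(m) %||% as.character(seq_len(nrow(m)))
  colnames(m) <- col_labels %||% colnames(m) %||% as.character(seq_len(ncol(m)))
  utils::write.csv(format(as.data.frame(m), digits = 15, trim = TRUE,
                          scientific = FALSE),
                   path, row.names = TRUE, quote = FALSE)
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path) {
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  as.matrix(df)
}

#' Analysis run configuration
#'
#' Bundles every tunable of the pipeline with validated defaults. Lengths
#' are in micrometres so the same configuration applies across
#' magnifications.
#'
#' @param patch_size_um side of the square sub-cellular motion-estimation
#'   patch (default 18.5).
#' @param search_radius_um block-matching search radius; `NULL` (default)
#'   auto-sizes to the largest per-frame displacement expected from
#'   `expected_max_speed_um_hr` plus a 2-pixel margin.
#' @param expected_max_speed_um_hr upper bound on cell speed used to
#'   auto-size the search radius (default 40).
#' @param strip_width_um width of one distance bin of the velocity
#'   magnitude map; default = `patch_size_um`.
#' @param n_distance_intervals number of distance intervals of the
#'   descriptor vector (default 6).
#' @param max_distance_um largest distance from the wound edge entering the
#'   descriptor (default 350).
#' @param closure_area_fraction wound is "fully closed" when its area drops
#'   below this fraction of the initial area (default 0.01).
#' @param seg_window_um side of the local-variance window of the segmenter;
#'   default = `patch_size_um / 2`.
#' @param variance_threshold fixed threshold on the local standard
#'   deviation image; `NULL` (default) selects it automatically by Otsu.
#' @param min_ncc minimum normalized cross-correlation for a patch
#'   displacement to be trusted (default 0.5).
#' @param variance_floor_frac patches whose intensity variance is below
#'   this fraction of the movie's median patch variance are flagged
#'   invalid (default 0.1).
#' @param profile_smooth_frames width (frames) of the centred moving
#'   average applied to velocity-toward-wound profiles (default 5).
#' @param anchor_mode `"advect"` (default): displacement anchors are
#'   re-binned by their remaining distance to the wound as they advance;
#'   `"fixed"`: anchors stay in their initial strip.
#' @param svm_cost linear SVM cost parameter (default 1).
#' @param svm_standardize standardize features on each training fold
#'   (default `TRUE`).
#' @param packing_fraction fraction of the monolayer area covered by cells,
#'   used to convert mean cell area to density (default 0.9).
#' @param seed RNG seed recorded with every run.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(patch_size_um = 18.5,
                       search_radius_um = NULL,
                       expected_max_speed_um_hr = 40,
                       strip_width_um = patch_size_um,
                       n_distance_intervals = 6L,
                       max_distance_um = 350,
                       closure_area_fraction = 0.01,
                       seg_window_um = patch_size_um / 2,
                       variance_threshold = NULL,
                       min_ncc = 0.5,
                       variance_floor_frac = 0.1,
                       profile_smooth_frames = 5L,
                       anchor_mode = c("advect", "fixed"),
                       svm_cost = 1,
                       svm_standardize = TRUE,
                       packing_fraction = 0.9,
                       seed = 1L) {
  anchor_mode <- match.arg(anchor_mode)
  cfg <- list(patch_size_um = patch_size_um,
              search_radius_um = search_radius_um,
              expected_max_speed_um_hr = expected_max_speed_um_hr,
              strip_width_um = strip_width_um,
              n_distance_intervals = as.integer(n_distance_intervals),
              max_distance_um = max_distance_um,
              closure_area_fraction = closure_area_fraction,
              seg_window_um = seg_window_um,
              variance_threshold = variance_threshold,
              min_ncc = min_ncc,
              variance_floor_frac = variance_floor_frac,
              profile_smooth_frames = as.integer(profile_smooth_frames),
              anchor_mode = anchor_mode,
              svm_cost = svm_cost,
              svm_standardize = isTRUE(svm_standardize),
              packing_fraction = packing_fraction,
              seed = as.integer(seed))
  validate_run_config(cfg)
  class(cfg) <- "run_config"
  cfg
}

validate_run_config <- function(cfg) {
  pos <- c("patch_size_um", "strip_width_um", "max_distance_um",
           "seg_window_um", "expected_max_speed_um_hr")
  for (nm in pos)
    if (!is.numeric(cfg[[nm]]) || !is.finite(cfg[[nm]]) || cfg[[nm]] <= 0)
      stop(nm, " must be finite and positive")
  if (!is.null(cfg$search_radius_um) &&
      (!is.finite(cfg$search_radius_um) || cfg$search_radius_um <= 0))
    stop("search_radius_um must be finite and positive (or NULL for auto)")
  if (cfg$n_distance_intervals < 1L)
    stop("n_distance_intervals must be >= 1")
  if (cfg$closure_area_fraction <= 0 || cfg$closure_area_fraction >= 1)
    stop("closure_area_fraction must be in (0, 1)")
  if (cfg$min_ncc < 0 || cfg$min_ncc > 1) stop("min_ncc must be in [0, 1]")
  if (cfg$packing_fraction <= 0 || cfg$packing_fraction > 1)
    stop("packing_fraction must be in (0, 1]")
  invisible(cfg)
}

#' Serialize / restore a run configuration as JSON
#' @param cfg a [run_config()].
#' @param path JSON file path.
#' @return `write_run_config`: `path` invisibly; `read_run_config`: a
#'   `run_config`.
#' @export
write_run_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, x)
}
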