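#' Sub-cellular patch grid
#'
#' Non-overlapping square patches tiling the frame, the unit at which local
#' motion is estimated. The leftover border is split evenly so the grid is
#' centred.
#'
#' @param frame_dim integer `c(rows, cols)` of the frame.
#' @param patch_size_px patch side in pixels (>= 8).
#' @return list of class `patch_grid`: `patch_size_px`, `n_rows`, `n_cols`,
#'   `r0`, `c0` (1-based top-left corner per patch, length
#'   `n_rows * n_cols`, row-major) and `center_r`, `center_c` (patch centre
#'   coordinates, possibly half-integer).
#' @export
patch_grid <- function(frame_dim, patch_size_px) {
  ps <- as.integer(patch_size_px)
  if (ps < 8L) stop("patch_size_px must be >= 8, got ", ps)
  nr <- frame_dim[1] %/% ps
  nc <- frame_dim[2] %/% ps
  if (nr < 1L || nc < 1L) stop("frame smaller than one patch")
  offr <- (frame_dim[1] - nr * ps) %/% 2
  offc <- (frame_dim[2] - nc * ps) %/% 2
  idx <- expand.grid(i = seq_len(nr), j = seq_len(nc))
  r0 <- offr + (idx$i - 1L) * ps + 1L
  c0 <- offc + (idx$j - 1L) * ps + 1L
  structure(list(patch_size_px = ps, n_rows = nr, n_cols = nc,
                 r0 = r0, c0 = c0,
                 center_r = r0 + (ps - 1) / 2,
                 center_c = c0 + (ps - 1) / 2),
            class = "patch_grid")
}

#' Estimate the local velocity field between two consecutive frames
#'
#' Each patch of `frame_t` whose centre is cellular and whose intensity
#' variance clears the floor is matched against a search window in
#' `frame_t1` by normalized cross-correlation (NCC); the arg-max
#' displacement (ties broken toward stillness) is refined to sub-pixel
#' precision by 1-D parabolic fits, then converted to um/hr. Patches with
#' best NCC below `min_ncc`, sub-floor variance, non-cellular centres or
#' search windows fully outside the frame are flagged invalid (never an
#' error).
#'
#' @param frame_t,frame_t1 consecutive frames (numeric matrices, same
#'   shape).
#' @param grid a [patch_grid()].
#' @param search_radius_px integer search radius (>= 1).
#' @param pixel_size_um,frame_interval_min acquisition metadata for the
#'   um/hr conversion.
#' @param cellular_mask logical matrix; patches centred on background are
#'   invalid. `NULL` accepts all centres.
#' @param min_ncc minimum acceptable NCC score (default 0.5).
#' @param variance_floor absolute variance floor; default 10% of the median
#'   patch variance of `frame_t`.
#' @return A data frame of class `velocity_field` with one row per patch:
#'   `r`, `c` (patch centre, px), `vr`, `vc` (velocity along rows/cols,
#'   um/hr), `speed_um_hr`, `score`, `n_cellular` (cellular pixels in the
#'   patch), `valid`.
#' @export
estimate_field <- function(frame_t, frame_t1, grid, search_radius_px,
                           pixel_size_um, frame_interval_min,
                           cellular_mask = NULL, min_ncc = 0.5,
                           variance_floor = NULL) {
  stopifnot(identical(dim(frame_t), dim(frame_t1)),
            inherits(grid, "patch_grid"), search_radius_px >= 1)
  if (is.null(variance_floor))
    variance_floor <- 0.1 * median_patch_variance(frame_t, grid)
  res <- ncc_block_match(frame_t, frame_t1,
                         as.integer(grid$r0 - 1L), as.integer(grid$c0 - 1L),
                         grid$patch_size_px, as.integer(search_radius_px),
                         min_ncc, variance_floor)
  valid <- res[, 4] > 0
  if (!is.null(cellular_mask)) {
    ctr <- cbind(pmin(nrow(frame_t), pmax(1, round(grid$center_r))),
                 pmin(ncol(frame_t), pmax(1, round(grid$center_c))))
    valid <- valid & cellular_mask[ctr]
    n_cell <- patch_cellular_counts(cellular_mask, grid)
  } else {
    n_cell <- rep(grid$patch_size_px^2, length(grid$r0))
  }
  scale <- pixel_size_um * 60 / frame_interval_min  # px/frame -> um/hr
  vr <- ifelse(valid, res[, 1] * scale, NA_real_)
  vc <- ifelse(valid, res[, 2] * scale, NA_real_)
  out <- data.frame(r = grid$center_r, c = grid$center_c,
                    vr = vr, vc = vc,
                    speed_um_hr = sqrt(vr^2 + vc^2),
                    score = res[, 3], n_cellular = n_cell, valid = valid)
  attr(out, "grid") <- grid
  attr(out, "pixel_size_um") <- pixel_size_um
  attr(out, "frame_interval_min") <- frame_interval_min
  class(out) <- c("velocity_field", class(out))
  out
}

patch_cellular_counts <- function(mask, grid) {
  ps <- grid$patch_size_px
  vapply(seq_along(grid$r0), function(k)
    sum(mask[grid$r0[k]:(grid$r0[k] + ps - 1L),
             grid$c0[k]:(grid$c0[k] + ps - 1L)]),
    numeric(1))
}

#' Median patch-intensity variance of a frame or movie
#'
#' Used to set the absolute variance floor below which a patch is
#' considered textureless. For a movie the median is taken over up to ten
#' evenly spaced frames.
#'
#' @param x a numeric frame or a [movie_stack()].
#' @param grid a [patch_grid()].
#' @return numeric scalar.
#' @export
median_patch_variance <- function(x, grid) {
  frame_vars <- function(f) {
    ps <- grid$patch_size_px
    vapply(seq_along(grid$r0), function(k) {
      p <- f[grid$r0[k]:(grid$r0[k] + ps - 1L),
             grid$c0[k]:(grid$c0[k] + ps - 1L)]
      mean(p^2) - mean(p)^2
    }, numeric(1))
  }
  if (inherits(x, "movie_stack")) {
    ks <- unique(round(seq(1, n_frames(x), length.out = min(10, n_frames(x)))))
    stats::median(unlist(lapply(x$frames[ks], frame_vars)))
  } else {
    stats::median(frame_vars(x))
  }
}

#' Default search radius in pixels
#'
#' The largest expected per-frame displacement plus a two-pixel margin.
#'
#' @param config a [run_config()].
#' @param pixel_size_um,frame_interval_min acquisition metadata.
#' @return integer radius >= 1.
#' @export
search_radius_px <- function(config, pixel_size_um, frame_interval_min) {
  if (!is.null(config$search_radius_um))
    return(max(1L, as.integer(ceiling(config$search_radius_um / pixel_size_um))))
  disp <- config$expected_max_speed_um_hr * frame_interval_min / 60 /
    pixel_size_um
  max(1L, as.integer(ceiling(disp)) + 2L)
}

#' Decompose patch velocities into toward-wound and parallel components
#'
#' At each patch centre the distance-map gradient gives the local
#' away-from-wound direction; the toward-wound component is
#' `dy = -(v . grad D) / |grad D|` (positive = moving toward the wound,
#' down-gradient) and `dx` the signed orthogonal (parallel) component, so
#' `dx^2 + dy^2` preserves the original squared speed. Patches on distance
#' plateaus (`|grad D|` ~ 0) are flagged invalid.
#'
#' @param field a `velocity_field` from [estimate_field()].
#' @param dist_map distance map (um) for the earlier frame, see
#'   [distance_map()].
#' @param pixel_size_um micrometres per pixel.
#' @return The field with columns `d_um` (distance of the patch centre from
#'   the wound), `dy` (toward-wound, um/hr) and `dx` (parallel, um/hr)
#'   added; `valid` is updated.
#' @export
toward_wound_components <- function(field, dist_map, pixel_size_um) {
  stopifnot(inherits(field, "velocity_field"))
  n <- nrow(field)
  r <- pmin(nrow(dist_map), pmax(1, round(field$r)))
  c <- pmin(ncol(dist_map), pmax(1, round(field$c)))
  gr <- gc <- d <- rep(NA_real_, n)
  rp <- pmin(nrow(dist_map), r + 1L); rm <- pmax(1L, r - 1L)
  cp <- pmin(ncol(dist_map), c + 1L); cm <- pmax(1L, c - 1L)
  d <- dist_map[cbind(r, c)]
  gr <- (dist_map[cbind(rp, c)] - dist_map[cbind(rm, c)]) /
    ((rp - rm) * pixel_size_um)
  gc <- (dist_map[cbind(r, cp)] - dist_map[cbind(r, cm)]) /
    ((cp - cm) * pixel_size_um)
  gn <- sqrt(gr^2 + gc^2)
  ok <- field$valid & is.finite(gn) & gn > 1e-6 & is.finite(d)
  dy <- dx <- rep(NA_real_, n)
  dy[ok] <- -(field$vr[ok] * gr[ok] + field$vc[ok] * gc[ok]) / gn[ok]
  dx[ok] <- (-field$vr[ok] * gc[ok] + field$vc[ok] * gr[ok]) / gn[ok]
  field$d_um <- d
  field$dy <- dy
  field$dx <- dx
  field$valid <- ok
  field
}

#' Export a velocity field as CSV
#' @param field a `velocity_field`.
#' @param path output path.
#' @return `path` invisibly.
#' @export
write_field <- function(field, path) {
  utils::write.csv(as.data.frame(field), path, row.names = FALSE)
  invisible(path)
}
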