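#' Estimate a single-cell trajectory by integrating patch velocity fields
#'
#' Forward Euler integration of the per-frame velocity fields: the
#' velocity at the current position is bilinearly interpolated between the
#' four surrounding patch centres; invalid patches are replaced by the
#' nearest valid patch within one patch radius, and the track terminates
#' (with a status flag) if none is available. This is the fully automated
#' substitute for manual single-cell tracking.
#'
#' @param fields list of `velocity_field`s (consecutive frame pairs).
#' @param start_um numeric `c(row_um, col_um)` start position.
#' @param pixel_size_um micrometres per pixel.
#' @param dt_hr hours per frame.
#' @param start_frame,end_frame 1-based frame range (default whole movie).
#' @return data frame of class `cell_track`: `frame`, `t_hr`, `row_um`,
#'   `col_um`, with attribute `status` (`"complete"` or
#'   `"terminated:no-valid-patch"`).
#' @export
estimate_trajectory <- function(fields, start_um, pixel_size_um, dt_hr,
                                start_frame = 1L,
                                end_frame = length(fields) + 1L) {
  grid <- attr(fields[[1]], "grid")
  ps_um <- grid$patch_size_px * pixel_size_um
  pos <- start_um
  n <- end_frame - start_frame + 1L
  out <- matrix(NA_real_, n, 2)
  out[1, ] <- pos
  status <- "complete"
  for (k in seq_len(n - 1L)) {
    f <- fields[[start_frame + k - 1L]]
    v <- interp_field(f, grid, pos, pixel_size_um, ps_um)
    if (any(!is.finite(v))) {
      status <- "terminated:no-valid-patch"
      break
    }
    pos <- pos + v * dt_hr
    out[k + 1L, ] <- pos
  }
  frames <- seq.int(start_frame, end_frame)
  res <- data.frame(frame = frames, t_hr = (frames - 1) * dt_hr,
                    row_um = out[, 1], col_um = out[, 2])
  attr(res, "status") <- status
  class(res) <- c("cell_track", class(res))
  res
}

# bilinear interpolation of (vr, vc) at position (row_um, col_um); invalid
# grid nodes are filled from the nearest valid node within one patch radius
interp_field <- function(field, grid, pos_um, pixel_size_um, ps_um) {
  vr <- matrix(field$vr, grid$n_rows, grid$n_cols)
  vc <- matrix(field$vc, grid$n_rows, grid$n_cols)
  cr <- matrix(field$r, grid$n_rows, grid$n_cols)[, 1] * pixel_size_um
  cc <- matrix(field$c, grid$n_rows, grid$n_cols)[1, ] * pixel_size_um
  gi <- findInterval(pos_um[1], cr, all.inside = TRUE)
  gj <- findInterval(pos_um[2], cc, all.inside = TRUE)
  fi <- (pos_um[1] - cr[gi]) / (cr[gi + 1] - cr[gi])
  fj <- (pos_um[2] - cc[gj]) / (cc[gj + 1] - cc[gj])
  fi <- min(1, max(0, fi)); fj <- min(1, max(0, fj))
  val <- function(V) {
    v <- c(V[gi, gj], V[gi + 1, gj], V[gi, gj + 1], V[gi + 1, gj + 1])
    if (any(!is.finite(v))) {
      for (idx in which(!is.finite(v))) {
        ii <- gi + (idx - 1) %% 2; jj <- gj + (idx - 1) %/% 2
        v[idx] <- nearest_valid(V, cr, cc, ii, jj, ps_um)
      }
    }
    if (any(!is.finite(v))) return(NA_real_)
    (1 - fi) * (1 - fj) * v[1] + fi * (1 - fj) * v[2] +
      (1 - fi) * fj * v[3] + fi * fj * v[4]
  }
  c(val(vr), val(vc))
}

nearest_valid <- function(V, cr, cc, i, j, ps_um) {
  ri <- max(1, i - 1):min(nrow(V), i + 1)
  cj <- max(1, j - 1):min(ncol(V), j + 1)
  sub <- V[ri, cj, drop = FALSE]
  dr <- outer(cr[ri] - cr[i], cc[cj] - cc[j], function(a, b) sqrt(a^2 + b^2))
  ok <- is.finite(sub) & dr <= ps_um + 1e-9
  if (!any(ok)) return(NA_real_)
  sub[ok][which.min(dr[ok])]
}

#' Area and eccentricity of a single-cell mask
#'
#' Area is the pixel count scaled to um^2. Eccentricity comes from the
#' ellipse with the same central second moments as the mask:
#' `sqrt(1 - (b/a)^2)` with `a >= b` the semi-axes, so 0 is a circle and
#' values near 1 a line segment.
#'
#' @param cell_mask logical/binary matrix of one cell.
#' @param pixel_size_um micrometres per pixel.
#' @return list: `area_um2`, `eccentricity`, `centroid_px` (row, col),
#'   `major_axis_um`, `minor_axis_um`.
#' @export
cell_shape_measures <- function(cell_mask, pixel_size_um = 1) {
  idx <- which(cell_mask != 0, arr.ind = TRUE)
  if (!nrow(idx)) stop("empty cell mask")
  n <- nrow(idx)
  mr <- mean(idx[, 1]); mc <- mean(idx[, 2])
  # +1/12: variance of the unit pixel footprint, stabilises 1-px-thin masks
  mu20 <- mean((idx[, 1] - mr)^2) + 1 / 12
  mu02 <- mean((idx[, 2] - mc)^2) + 1 / 12
  mu11 <- mean((idx[, 1] - mr) * (idx[, 2] - mc))
  common <- sqrt((mu20 - mu02)^2 + 4 * mu11^2)
  l1 <- (mu20 + mu02 + common) / 2
  l2 <- (mu20 + mu02 - common) / 2
  ecc <- sqrt(max(0, 1 - l2 / l1))
  list(area_um2 = n * pixel_size_um^2,
       eccentricity = ecc,
       centroid_px = c(mr, mc),
       major_axis_um = 4 * sqrt(l1) * pixel_size_um,
       minor_axis_um = 4 * sqrt(l2) * pixel_size_um)
}

#' Shape measures for every cell of a labelled image
#'
#' @param label_image integer matrix; 0 = background, k = cell k.
#' @param pixel_size_um micrometres per pixel.
#' @return data frame with one row per label: `label`, `area_um2`,
#'   `eccentricity`, `centroid_row_px`, `centroid_col_px`.
#' @export
label_shape_table <- function(label_image, pixel_size_um = 1) {
  labs <- sort(unique(label_image[label_image > 0]))
  rows <- lapply(labs, function(l) {
    m <- cell_shape_measures(label_image == l, pixel_size_um)
    data.frame(label = l, area_um2 = m$area_um2,
               eccentricity = m$eccentricity,
               centroid_row_px = m$centroid_px[1],
               centroid_col_px = m$centroid_px[2])
  })
  do.call(rbind, rows)
}

#' Cell density from mean cell area
#'
#' A confluent monolayer packs `packing_fraction` of its area with cells,
#' so density = packing_fraction / mean area; reported per 1000 um^2.
#'
#' @param mean_cell_area_um2 mean single-cell area (> 0).
#' @param packing_fraction fraction of area covered by cells, in (0, 1\]
#'   (default 0.9).
#' @return density in cells per 1000 um^2.
#' @export
density_from_area <- function(mean_cell_area_um2, packing_fraction = 0.9) {
  if (any(mean_cell_area_um2 <= 0)) stop("mean cell area must be positive")
  if (packing_fraction <= 0 || packing_fraction > 1)
    stop("packing_fraction must be in (0, 1]")
  1000 * packing_fraction / mean_cell_area_um2
}

#' Spearman correlation between density and speed
#'
#' Spearman's rank correlation with average ranks for ties; the two-sided
#' p-value is computed by exact enumeration of all permutations for
#' `n <= 8` and by the t approximation otherwise.
#'
#' @param density,speed paired numeric vectors (n >= 5).
#' @return list: `rho`, `p_value`, `n`, `method`; `rho` is `NA` (flagged)
#'   for constant input.
#' @export
density_speed_correlation <- function(density, speed) {
  stopifnot(length(density) == length(speed))
  ok <- is.finite(density) & is.finite(speed)
  x <- density[ok]; y <- speed[ok]
  n <- length(x)
  if (n < 5) stop("need at least 5 paired finite observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(rho = NA_real_, p_value = NA_real_, n = n,
                method = "undefined (constant series)"))
  rho <- stats::cor(x, y, method = "spearman")
  if (n <= 8) {
    perms <- permutations_of(n)
    rx <- rank(x); ry <- rank(y)
    rhos <- apply(perms, 1, function(p) stats::cor(rx, ry[p]))
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
    method <- "exact permutation"
  } else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
    method <- "t approximation"
  }
  list(rho = rho, p_value = p, n = n, method = method)
}

permutations_of <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- permutations_of(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k)
    cbind(k, sub + (sub >= k))))
}
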