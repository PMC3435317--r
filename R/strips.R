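#' Euclidean distance map from the wound edge
#'
#' Exact Euclidean distance (um) of every cellular pixel to the nearest
#' wound pixel; `NA` on background. An empty wound yields an all-`NA` map
#' flagged `undefined`.
#'
#' @param cellular_mask logical matrix (`TRUE` = cellular).
#' @param wound_mask logical matrix of the wound region.
#' @param pixel_size_um micrometres per pixel.
#' @return numeric matrix of class `distance_map` with attribute
#'   `undefined` (logical).
#' @export
distance_map <- function(cellular_mask, wound_mask, pixel_size_um) {
  stopifnot(identical(dim(cellular_mask), dim(wound_mask)))
  if (!any(wound_mask)) {
    m <- matrix(NA_real_, nrow(wound_mask), ncol(wound_mask))
    return(structure(m, class = c("distance_map", class(m)), undefined = TRUE))
  }
  d <- EBImage::distmap(matrix(as.numeric(!wound_mask), nrow(wound_mask)))
  d <- as.matrix(d) * pixel_size_um
  d[!cellular_mask] <- NA_real_
  structure(d, class = c("distance_map", class(d)), undefined = FALSE)
}

#' Velocity magnitude map
#'
#' The central kinetic summary `M[t, d]`: mean speed (um/hr) of the
#' monolayer at distance bin `d` from the wound edge at frame-pair `t`.
#' Each valid patch contributes its speed to the half-open bin
#' `[d, d + w)` containing its centre's distance, weighted by the number
#' of cellular pixels it covers; bins with no contributing patch are
#' missing (`NA`), not zero.
#'
#' @param fields list of `velocity_field`s (one per consecutive frame
#'   pair).
#' @param dist_maps list of [distance_map()]s aligned with `fields`
#'   (distance at the earlier frame of each pair).
#' @param strip_width_um width of one distance bin (default 18.5).
#' @param max_distance_um upper edge of the last bin; default the largest
#'   patch distance observed.
#' @return numeric matrix `[n_pairs, n_bins]` of class
#'   `velocity_magnitude_map` with attributes `strip_width_um` and
#'   `bin_centers_um`.
#' @export
build_velocity_map <- function(fields, dist_maps, strip_width_um = 18.5,
                               max_distance_um = NULL) {
  stopifnot(length(fields) == length(dist_maps))
  nt <- length(fields)
  dmax <- max_distance_um
  if (is.null(dmax)) {
    dmax <- 0
    for (i in seq_len(nt)) {
      f <- fields[[i]]
      d <- patch_distances(f, dist_maps[[i]])
      if (any(is.finite(d))) dmax <- max(dmax, max(d, na.rm = TRUE))
    }
    if (dmax <= 0) stop("no valid patch distances in any frame")
  }
  nb <- max(1L, as.integer(ceiling(dmax / strip_width_um)))
  M <- matrix(NA_real_, nt, nb)
  warned <- FALSE
  for (i in seq_len(nt)) {
    f <- fields[[i]]
    d <- patch_distances(f, dist_maps[[i]])
    ok <- f$valid & is.finite(d) & is.finite(f$speed_um_hr) & d < nb * strip_width_um
    if (!any(ok)) {
      if (!warned) warning("frame pair ", i, ": no valid patches; column missing")
      warned <- TRUE
      next
    }
    bin <- pmin(nb, floor(d[ok] / strip_width_um) + 1L)
    w <- f$n_cellular[ok]
    sp <- f$speed_um_hr[ok]
    num <- tapply(sp * w, bin, sum)
    den <- tapply(w, bin, sum)
    M[i, as.integer(names(num))] <- num / den
  }
  structure(M, class = c("velocity_magnitude_map", class(M)),
            strip_width_um = strip_width_um,
            bin_centers_um = (seq_len(nb) - 0.5) * strip_width_um)
}

patch_distances <- function(field, dist_map) {
  if (!is.null(field$d_um)) return(field$d_um)
  r <- pmin(nrow(dist_map), pmax(1, round(field$r)))
  c <- pmin(ncol(dist_map), pmax(1, round(field$c)))
  dist_map[cbind(r, c)]
}

#' Detect the three healing phases
#'
#' *Phase 1* runs from the scratch until first contact between cells from
#' the opposing wound edges, *Phase 2* until full closure, *Phase 3* after.
#' Contact is detected as loss of separation: the wound no longer spans
#' the frame along the wound axis (by planar duality, an 8-connected
#' cellular path then links the two fronts iff no 4-connected wound
#' component touches both of the borders the initial wound spanned).
#' Closure is the first frame whose wound area falls below
#' `closure_area_fraction` of the initial area.
#'
#' @param wound_masks per-frame wound masks (list of logical matrices),
#'   from frame 1 onward.
#' @param closure_area_fraction closure threshold (default 0.01).
#' @return list of class `phase_partition`: `t_contact`, `t_closure`
#'   (1-based first frame of contact / closure, `NA_integer_` if never
#'   reached), `n_frames`.
#' @export
detect_phases <- function(wound_masks, closure_area_fraction = 0.01) {
  n <- length(wound_masks)
  area0 <- sum(wound_masks[[1]])
  if (area0 == 0)                      # starts already closed
    return(structure(list(t_contact = 1L, t_closure = 1L, n_frames = n),
                     class = "phase_partition"))
  axis <- spanning_axis(wound_masks[[1]])
  t_contact <- NA_integer_
  t_closure <- NA_integer_
  for (k in seq_len(n)) {
    w <- wound_masks[[k]]
    if (is.na(t_contact) && !wound_spans(w, axis)) t_contact <- k
    if (is.na(t_closure) && sum(w) < closure_area_fraction * area0) {
      t_closure <- k
      break
    }
  }
  if (!is.na(t_closure) && is.na(t_contact)) t_contact <- t_closure
  structure(list(t_contact = t_contact, t_closure = t_closure, n_frames = n),
            class = "phase_partition")
}

#' @export
print.phase_partition <- function(x, ...) {
  cat(sprintf("phases: contact at frame %s, closure at frame %s (of %d)\n",
              x$t_contact, x$t_closure, x$n_frames))
  invisible(x)
}

spanning_axis <- function(wound) {
  if (any(wound[1, ]) && any(wound[nrow(wound), ])) "rows"
  else if (any(wound[, 1]) && any(wound[, ncol(wound)])) "cols"
  else "rows"
}

wound_spans <- function(wound, axis) {
  if (!any(wound)) return(FALSE)
  lab <- EBImage::bwlabel(wound * 1)   # 4-connected components
  first <- if (axis == "rows") lab[1, ] else lab[, 1]
  last <- if (axis == "rows") lab[nrow(lab), ] else lab[, ncol(lab)]
  length(intersect(first[first > 0], last[last > 0])) > 0
}

# frame windows (over map rows = frame pairs) of the three phases
phase_windows <- function(phases, n_pairs, phases_used = 3L) {
  tc <- phases$t_contact
  tz <- phases$t_closure
  if (is.na(tc)) stop("t_contact undefined; supply phase frames manually")
  if (phases_used >= 3L && is.na(tz))
    stop("t_closure undefined; supply phase frames manually or use 2 phases")
  if (is.na(tz)) tz <- n_pairs + 1L
  w <- list(`1` = seq_len(min(tc - 1L, n_pairs)),
            `2` = seq.int(tc, min(tz - 1L, n_pairs)))
  w$`2` <- w$`2`[w$`2` >= 1 & w$`2` <= n_pairs]
  if (phases_used >= 3L)
    w$`3` <- if (tz <= n_pairs) seq.int(tz, n_pairs) else integer(0)
  w
}

#' "Average-cell" cumulative displacement toward the wound
#'
#' For each anchor distance the strip-mean toward-wound velocity is
#' accumulated over frames (up to closure) into a displacement curve
#' `R(t)`. In the default `"advect"` mode the anchor's strip is relabelled
#' every frame by its remaining distance `d0 - R(t)` (floored at 0), i.e.
#' the anchor is tracked as it approaches the wound; `"fixed"` keeps the
#' initial strip.
#'
#' @param toward_fields list of fields from [toward_wound_components()].
#' @param anchors_um initial anchor distances (um).
#' @param dt_hr hours per frame.
#' @param strip_width_um distance-bin width.
#' @param t_stop last frame pair to accumulate (e.g. closure frame - 1);
#'   default all.
#' @param mode `"advect"` (default) or `"fixed"`.
#' @return matrix `[n_times + 1, n_anchors]` of class
#'   `displacement_series`; row 1 is `R(0) = 0`.
#' @export
average_cell_displacement <- function(toward_fields, anchors_um, dt_hr,
                                      strip_width_um = 18.5,
                                      t_stop = length(toward_fields),
                                      mode = c("advect", "fixed")) {
  mode <- match.arg(mode)
  nt <- min(t_stop, length(toward_fields))
  R <- matrix(0, nt + 1L, length(anchors_um))
  colnames(R) <- paste0("d", anchors_um)
  for (a in seq_along(anchors_um)) {
    r <- 0
    for (k in seq_len(nt)) {
      d_now <- if (mode == "advect") max(0, anchors_um[a] - r) else anchors_um[a]
      v <- strip_mean_dy(toward_fields[[k]], d_now, strip_width_um)
      if (is.finite(v)) r <- r + v * dt_hr
      R[k + 1L, a] <- r
    }
  }
  structure(R, class = c("displacement_series", class(R)),
            anchors_um = anchors_um, dt_hr = dt_hr)
}

strip_mean_dy <- function(field, d_um, strip_width_um) {
  bin <- floor(d_um / strip_width_um)
  lo <- bin * strip_width_um
  hi <- lo + strip_width_um
  ok <- field$valid & is.finite(field$d_um) & is.finite(field$dy) &
    field$d_um >= lo & field$d_um < hi
  if (!any(ok)) return(NA_real_)
  stats::weighted.mean(field$dy[ok], field$n_cellular[ok])
}

#' Velocity-toward-wound profiles at fixed anchor strips
#'
#' Per-frame strip-mean of the toward-wound velocity component at each
#' anchor's (fixed) distance bin, smoothed by a centred moving average.
#'
#' @inheritParams average_cell_displacement
#' @param smooth_frames moving-average width in frames (default 5; 1
#'   disables smoothing).
#' @return matrix `[n_times, n_anchors]` (um/hr).
#' @export
velocity_toward_profile <- function(toward_fields, anchors_um,
                                    strip_width_um = 18.5,
                                    smooth_frames = 5L) {
  nt <- length(toward_fields)
  P <- matrix(NA_real_, nt, length(anchors_um))
  colnames(P) <- paste0("d", anchors_um)
  for (a in seq_along(anchors_um))
    P[, a] <- vapply(toward_fields, strip_mean_dy, numeric(1),
                     anchors_um[a], strip_width_um)
  if (smooth_frames > 1L)
    P <- apply(P, 2, moving_average, w = smooth_frames)
  structure(P, anchors_um = anchors_um)
}

moving_average <- function(x, w) {
  h <- w %/% 2
  n <- length(x)
  vapply(seq_len(n), function(i) {
    j <- max(1, i - h):min(n, i + h)
    mean(x[j], na.rm = TRUE)
  }, numeric(1))
}
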