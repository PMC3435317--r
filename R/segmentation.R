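#' Segment a frame into cellular and background (wound) regions
#'
#' Bright-field monolayers carry high local texture while the wound void is
#' nearly flat, so the partition is driven by a local-variance image: the
#' standard deviation of intensities in a sliding square window. The
#' threshold is picked automatically by Otsu's method on that image unless
#' fixed in the configuration. The binary mask is then cleaned by
#' morphological closing, removal of cellular specks smaller than one
#' motion-estimation patch, and filling of intra-monolayer holes below the
#' same cutoff. The procedure is deterministic and invariant to affine
#' intensity changes of the frame up to the automatic threshold.
#'
#' @param frame numeric matrix, intensities in \[0, 1\].
#' @param pixel_size_um micrometres per pixel.
#' @param window_um side of the local-variance window (default half a
#'   patch, 9.25 um).
#' @param threshold fixed threshold on local standard deviation, or `NULL`
#'   (default) for automatic Otsu selection.
#' @param min_area_um2 components (cellular specks or holes) smaller than
#'   this are removed (default one patch area, 18.5^2 um^2).
#' @return Logical matrix (`TRUE` = cellular) of class `cellular_mask` with
#'   attributes `threshold` (the value used) and `flat` (`TRUE` when the
#'   frame was constant, in which case everything is background and a
#'   warning flag is raised rather than an error).
#' @export
segment_frame <- function(frame, pixel_size_um, window_um = 9.25,
                          threshold = NULL, min_area_um2 = 18.5^2) {
  stopifnot(is.matrix(frame), window_um > 0)
  win <- max(3L, round(window_um / pixel_size_um))
  sdimg <- local_sd(frame, win)
  flat <- max(sdimg) <= 1e-12
  if (flat) {
    mask <- matrix(FALSE, nrow(frame), ncol(frame))
    return(structure(mask, class = c("cellular_mask", class(mask)),
                     threshold = NA_real_, flat = TRUE))
  }
  if (is.null(threshold)) {
    scaled <- sdimg / max(sdimg)
    threshold <- EBImage::otsu(EBImage::as.Image(scaled)) * max(sdimg)
  }
  mask <- sdimg > threshold
  # close small gaps between textured blobs; a conservative brush keeps
  # the wound edge from creeping into the void
  brush <- EBImage::makeBrush(odd(max(3L, win %/% 2)), shape = "disc")
  mask <- EBImage::closing(mask * 1, brush) > 0
  min_px <- max(1L, round(min_area_um2 / pixel_size_um^2))
  mask <- drop_small(mask, min_px)          # cellular specks
  mask <- !drop_small(!mask, min_px, keep_border_touching = TRUE)  # holes
  structure(mask, class = c("cellular_mask", class(mask)),
            threshold = threshold, flat = FALSE)
}

odd <- function(n) if (n %% 2 == 0) n + 1L else as.integer(n)

# sliding-window standard deviation via cumulative-sum box filtering
local_sd <- function(x, win) {
  s1 <- box_sum(x, win)
  s2 <- box_sum(x * x, win)
  n <- box_sum(matrix(1, nrow(x), ncol(x)), win)
  v <- (s2 - s1^2 / n) / n
  v[v < 0] <- 0
  sqrt(v)
}

box_sum <- function(x, win) {
  h <- win %/% 2
  nr <- nrow(x); nc <- ncol(x)
  cs <- matrix(0, nr + 1, nc + 1)
  cs[-1, -1] <- apply(apply(x, 2, cumsum), 1, cumsum) |> t()
  r0 <- pmax(seq_len(nr) - h - 1, 0); r1 <- pmin(seq_len(nr) + h, nr)
  c0 <- pmax(seq_len(nc) - h - 1, 0); c1 <- pmin(seq_len(nc) + h, nc)
  cs[r1 + 1, c1 + 1, drop = FALSE] - cs[r0 + 1, c1 + 1, drop = FALSE] -
    cs[r1 + 1, c0 + 1, drop = FALSE] + cs[r0 + 1, c0 + 1, drop = FALSE]
}

# remove connected components smaller than min_px pixels
drop_small <- function(mask, min_px, keep_border_touching = FALSE) {
  if (!any(mask)) return(mask)
  lab <- EBImage::bwlabel(mask * 1)
  sizes <- tabulate(lab[lab > 0])
  small <- which(sizes < min_px)
  if (keep_border_touching && length(small)) {
    border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
    small <- setdiff(small, border[border > 0])
  }
  if (length(small)) mask[lab %in% small] <- FALSE
  mask
}

#' Extract the wound region from a cellular mask
#'
#' The wound is the background component that corresponds to the scratch:
#' at the first frame, the largest background connected component; at later
#' frames, every background component overlapping the previous wound.
#' Small intra-monolayer holes (below one patch area) never qualify. An
#' empty wound (post-closure) is a valid result, not an error.
#'
#' @param cellular_mask logical matrix from [segment_frame()].
#' @param pixel_size_um micrometres per pixel.
#' @param prior_wound wound mask of the previous frame, or `NULL` for the
#'   first frame.
#' @param min_area_um2 holes smaller than this are never wound.
#' @return Logical matrix of class `wound_mask` with attribute
#'   `area_um2`.
#' @export
extract_wound <- function(cellular_mask, pixel_size_um, prior_wound = NULL,
                          min_area_um2 = 18.5^2) {
  bg <- !cellular_mask
  min_px <- max(1L, round(min_area_um2 / pixel_size_um^2))
  wound <- matrix(FALSE, nrow(bg), ncol(bg))
  if (any(bg)) {
    lab <- EBImage::bwlabel(bg * 1)
    sizes <- tabulate(lab[lab > 0])
    keep <- integer(0)
    if (is.null(prior_wound)) {
      big <- which.max(sizes)
      if (sizes[big] >= min_px) keep <- big
    } else if (any(prior_wound)) {
      hit <- unique(lab[prior_wound & lab > 0])
      keep <- hit[sizes[hit] >= min_px]
    }
    if (length(keep)) wound <- matrix(lab %in% keep, nrow(bg), ncol(bg))
  }
  structure(wound, class = c("wound_mask", class(wound)),
            area_um2 = sum(wound) * pixel_size_um^2)
}

#' Segment a whole movie and track the wound
#'
#' Applies [segment_frame()] per frame and [extract_wound()] with
#' frame-to-frame wound tracking (overlap with the previous wound prevents
#' re-labelling noise once first contact splits the wound into fragments).
#'
#' @param movie a [movie_stack()].
#' @param config a [run_config()].
#' @return list with `cellular_masks` and `wound_masks` (lists of masks)
#'   and `wound_area_um2` (numeric vector).
#' @export
segment_movie <- function(movie, config = run_config()) {
  px <- movie$pixel_size_um
  min_area <- config$patch_size_um^2
  threshold <- config$variance_threshold
  if (is.null(threshold)) {
    # anchor the automatic threshold on frame 1, where wound and
    # monolayer are both present; late frames may have no low-variance
    # class left for Otsu to find
    first <- segment_frame(movie$frames[[1]], px,
                           window_um = config$seg_window_um,
                           min_area_um2 = min_area)
    threshold <- attr(first, "threshold")
    if (!is.finite(threshold)) threshold <- NULL
  }
  cellular <- lapply(movie$frames, segment_frame, pixel_size_um = px,
                     window_um = config$seg_window_um,
                     threshold = threshold,
                     min_area_um2 = min_area)
  wounds <- vector("list", length(cellular))
  prior <- NULL
  for (i in seq_along(cellular)) {
    wounds[[i]] <- extract_wound(cellular[[i]], px, prior_wound = prior,
                                 min_area_um2 = min_area)
    if (any(wounds[[i]])) prior <- wounds[[i]]
  }
  list(cellular_masks = cellular, wound_masks = wounds,
       wound_area_um2 = vapply(wounds, attr, numeric(1), "area_um2"))
}
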