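#' Rotation-invariant uniform LBP code of one pixel
#'
#' Compares the centre intensity with its 8 ring neighbours (radius 1,
#' neighbours ordered around the circle): bit `i` is 1 when
#' `neighbor_i >= center`. If the circular bit pattern is *uniform* (at
#' most two 0/1 transitions) the code is the number of ones (0..8);
#' otherwise the code is 9. With 8 neighbours exactly ten codes are
#' achievable, and a constant neighbourhood maps to code 8 (ties count as
#' "not lower").
#'
#' @param center scalar centre intensity.
#' @param neighbors numeric vector of 8 neighbour intensities in circular
#'   order.
#' @return integer code in 0..9.
#' @export
lbp_code <- function(center, neighbors) {
  stopifnot(length(neighbors) == 8L)
  b <- as.integer(neighbors >= center)
  transitions <- sum(abs(b - b[c(2:8, 1)]))
  if (transitions <= 2L) sum(b) else 9L
}

# shift a matrix by (dr, dc), replicating nothing: callers only read the
# interior so the padded border value is irrelevant
shift_mat <- function(x, dr, dc) {
  nr <- nrow(x); nc <- ncol(x)
  out <- matrix(0, nr, nc)
  rs <- max(1, 1 - dr):min(nr, nr - dr)
  cs <- max(1, 1 - dc):min(nc, nc - dc)
  out[rs, cs] <- x[rs + dr, cs + dc]
  out
}

# neighbour intensity images at radius 1: axis-aligned direct, diagonals
# bilinearly interpolated at (+-1/sqrt2, +-1/sqrt2)
lbp_neighbor_images <- function(frame) {
  f <- 1 / sqrt(2)
  w00 <- (1 - f)^2; w01 <- f * (1 - f); w11 <- f^2
  diag_img <- function(sr, sc) {
    w00 * frame +
      w01 * shift_mat(frame, sr, 0) +
      w01 * shift_mat(frame, 0, sc) +
      w11 * shift_mat(frame, sr, sc)
  }
  list(shift_mat(frame, 0, 1),    # east
       diag_img(-1, 1),           # north-east
       shift_mat(frame, -1, 0),   # north
       diag_img(-1, -1),          # north-west
       shift_mat(frame, 0, -1),   # west
       diag_img(1, -1),           # south-west
       shift_mat(frame, 1, 0),    # south
       diag_img(1, 1))            # south-east
}

# LBP code image; border pixels (incomplete neighbourhood) are NA
lbp_code_image <- function(frame) {
  nb <- lbp_neighbor_images(frame)
  bits <- lapply(nb, function(n) n >= frame)
  ones <- Reduce(`+`, bits)
  trans <- Reduce(`+`, lapply(seq_len(8), function(i) {
    j <- if (i == 8L) 1L else i + 1L
    abs(bits[[i]] - bits[[j]])
  }))
  code <- ifelse(trans <= 2L, ones, 9L)
  code[c(1, nrow(code)), ] <- NA
  code[, c(1, ncol(code))] <- NA
  code
}

#' Normalized 10-bin LBP histogram over cellular pixels
#'
#' Frequencies of the ten rotation-invariant uniform LBP codes over the
#' cellular pixels of one frame (border pixels excluded), L1-normalized.
#' Gray-scale invariant: any monotone affine intensity transform with
#' positive scale leaves the histogram unchanged.
#'
#' @param frame numeric matrix.
#' @param cellular_mask logical matrix; `NULL` uses every interior pixel.
#' @return numeric vector of length 10 (names `lbp0`..`lbp9`) summing to
#'   1, or all-`NA` with attribute `undefined = TRUE` when no cellular
#'   pixel is available.
#' @export
lbp_histogram <- function(frame, cellular_mask = NULL) {
  code <- lbp_code_image(frame)
  if (!is.null(cellular_mask)) code[!cellular_mask] <- NA
  counts <- tabulate(code + 1L, nbins = 10L)
  names(counts) <- paste0("lbp", 0:9)
  tot <- sum(counts)
  if (tot == 0)
    return(structure(rep(NA_real_, 10), names = paste0("lbp", 0:9),
                     undefined = TRUE))
  counts / tot
}

#' Per-frame LBP histogram series of a movie
#'
#' @param movie a [movie_stack()].
#' @param cellular_masks per-frame masks (list), or `NULL`.
#' @return matrix `[n_frames, 10]` of class `lbp_series`; rows sum to 1.
#' @export
lbp_series <- function(movie, cellular_masks = NULL) {
  H <- t(vapply(seq_len(n_frames(movie)), function(k)
    lbp_histogram(movie$frames[[k]],
                  if (is.null(cellular_masks)) NULL else cellular_masks[[k]]),
    numeric(10)))
  structure(H, class = c("lbp_series", class(H)))
}

#' Phase-averaged texture descriptor
#'
#' Mean LBP histogram over the frames of one healing phase (default Phase
#' 2, first contact to full closure, where most morphological change
#' happens); still a probability vector.
#'
#' @param H an [lbp_series()] matrix.
#' @param phases a `phase_partition` from [detect_phases()].
#' @param phase which phase to average (1, 2 or 3; default 2).
#' @return numeric vector of length 10.
#' @export
phase_texture_descriptor <- function(H, phases, phase = 2L) {
  w <- phase_windows(phases, nrow(H), phases_used = if (phase >= 2L) 3L else 2L)
  idx <- w[[as.character(phase)]]
  if (!length(idx)) stop("phase ", phase, " window is empty")
  colMeans(H[idx, , drop = FALSE], na.rm = FALSE)
}
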