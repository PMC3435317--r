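#' Synthetic wound-healing scenario
#'
#' Describes a simulated scratch assay: a confluent textured monolayer with
#' a vertical wound band of prescribed width, imaged at fixed pixel size and
#' frame interval, healing under one of three motility regimes:
#'
#' * `"untreated"`: cells move toward the wound with speed
#'   `v_front * exp(-d / decay_length)` at distance `d` from the wound edge,
#'   constant in time until closure; after closure all cells decelerate
#'   together.
#' * `"treated"` (HGF/SF-like): same initial decay, but an activation wave
#'   travels backward from the wound edge at `wave_speed`; cells joined by
#'   the wave accelerate toward `wave_boost * v_front`, so distant cells end
#'   up at least as fast as front cells before closure. After closure the
#'   front stops first and distant cells decay gradually.
#' * `"inhibited"` (Met-inhibited + HGF/SF): as untreated with lower peak
#'   speed and steeper spatial decay, maximising the front/distant speed
#'   ratio.
#'
#' The wound is a vertical band centred in the frame whose half-width
#' profile is perturbed by a smooth sinusoid of amplitude
#' `edge_ruggedness_um`, so first contact between the opposing fronts
#' precedes full closure. Both edges advance at `v_front`, giving
#' analytically known contact and closure times.
#'
#' @param regime `"untreated"`, `"treated"` or `"inhibited"`.
#' @param height_px,width_px frame size in pixels (wound axis is vertical,
#'   motion horizontal).
#' @param pixel_size_um,frame_interval_min acquisition metadata.
#' @param n_frames number of frames (>= 3).
#' @param wound_width_um initial scratch width (default 300).
#' @param v_front_um_hr peak speed at the wound edge; regime default.
#' @param decay_length_um spatial decay length of speed; regime default.
#' @param wave_speed_um_hr backward speed of the activation wave
#'   (treated regime).
#' @param wave_onset_hr,wave_ramp_hr midpoint delay and rise time (hours)
#'   of the logistic activation at the wound edge.
#' @param wave_boost plateau speed of activated cells, as a multiple of
#'   `v_front_um_hr` (treated regime).
#' @param relax_time_hr deceleration time constant after closure.
#' @param edge_ruggedness_um amplitude of the wound-edge perturbation.
#' @param texture_cell_diameter_um diameter of one textured pseudo-cell.
#' @param noise_sd standard deviation of the (static) sensor noise field.
#' @param morphology list: `front_spread`, `distant_growth`, `elongation` -
#'   dimensionless amplitudes of the pseudo-cell size/shape program.
#' @param rng_seed integer seed making the rendered movie a pure function
#'   of the scenario.
#' @return Object of class `synthetic_scenario` with derived fields
#'   `t_contact_hr` and `t_closure_hr` (`NA` when healing never happens).
#' @export
synthetic_scenario <- function(regime = c("untreated", "treated", "inhibited"),
                               height_px = 128L, width_px = 256L,
                               pixel_size_um = 2,
                               frame_interval_min = 14.5,
                               n_frames = 60L,
                               wound_width_um = 300,
                               v_front_um_hr = NULL,
                               decay_length_um = NULL,
                               wave_speed_um_hr = 50,
                               wave_onset_hr = 0.5,
                               wave_ramp_hr = 0.5,
                               wave_boost = 1.25,
                               relax_time_hr = NULL,
                               edge_ruggedness_um = 20,
                               texture_cell_diameter_um = 16,
                               noise_sd = 0.02,
                               morphology = list(front_spread = 0.25,
                                                 distant_growth = 0.3,
                                                 elongation = 0.4),
                               rng_seed = 1L) {
  regime <- match.arg(regime)
  defaults <- switch(regime,
    untreated = list(v = 20, lambda = 50, relax = 1.5),
    treated   = list(v = 30, lambda = 40, relax = 0.75),
    inhibited = list(v = 10, lambda = 25, relax = 1.5))
  v_front_um_hr <- v_front_um_hr %||% defaults$v
  decay_length_um <- decay_length_um %||% defaults$lambda
  relax_time_hr <- relax_time_hr %||% defaults$relax

  if (n_frames < 3L) stop("n_frames must be >= 3")
  rates <- c(v_front_um_hr, decay_length_um, wave_speed_um_hr, relax_time_hr)
  if (any(!is.finite(rates)) || any(rates < 0))
    stop("all rates must be finite and non-negative")
  width_um <- width_px * pixel_size_um
  height_um <- height_px * pixel_size_um
  if (wound_width_um + 2 * edge_ruggedness_um >= width_um)
    stop("wound (plus edge ruggedness) does not fit inside the frame width")

  # smooth ragged edges: random phases drawn once from the scenario seed
  phases <- with_seed(rng_seed, stats::runif(2, 0, 2 * pi))
  sc <- list(regime = regime,
             height_px = as.integer(height_px), width_px = as.integer(width_px),
             pixel_size_um = pixel_size_um,
             frame_interval_min = frame_interval_min,
             n_frames = as.integer(n_frames),
             wound_width_um = wound_width_um,
             v_front_um_hr = v_front_um_hr,
             decay_length_um = decay_length_um,
             wave_speed_um_hr = wave_speed_um_hr,
             wave_onset_hr = wave_onset_hr, wave_ramp_hr = wave_ramp_hr,
             wave_boost = wave_boost,
             relax_time_hr = relax_time_hr,
             edge_ruggedness_um = edge_ruggedness_um,
             texture_cell_diameter_um = texture_cell_diameter_um,
             noise_sd = noise_sd,
             morphology = morphology,
             rng_seed = as.integer(rng_seed),
             width_um = width_um, height_um = height_um,
             edge_phase_left = phases[1], edge_phase_right = phases[2])
  class(sc) <- "synthetic_scenario"

  # contact/closure: both edges advance at v_front, so the local gap
  # h_L(y) + h_R(y) shrinks at 2*v_front
  gaps <- edge_gap_profile(sc, seq(0.5, height_px - 0.5) * pixel_size_um)
  if (v_front_um_hr > 0) {
    sc$t_contact_hr <- min(gaps$total) / (2 * v_front_um_hr)
    sc$t_closure_hr <- max(gaps$total) / (2 * v_front_um_hr)
  } else {
    sc$t_contact_hr <- NA_real_
    sc$t_closure_hr <- NA_real_
  }
  sc
}

#' @export
print.synthetic_scenario <- function(x, ...) {
  cat(sprintf(paste0("synthetic_scenario: %s regime, %d x %d px, %d frames, ",
                     "%.3g um/px\n  wound %.0f um, v_front %.3g um/hr, ",
                     "decay %.3g um, contact %.2f hr, closure %.2f hr\n"),
              x$regime, x$height_px, x$width_px, x$n_frames, x$pixel_size_um,
              x$wound_width_um, x$v_front_um_hr, x$decay_length_um,
              x$t_contact_hr, x$t_closure_hr))
  invisible(x)
}

# Initial half-width of the wound on each side of the centreline, as a
# smooth function of the along-wound coordinate y (um).
edge_gap_profile <- function(sc, y_um) {
  # different spatial frequencies per side guarantee the gap profile
  # varies by at least 2 * edge_ruggedness_um whatever the random phases,
  # so first contact strictly precedes full closure
  w <- 2 * pi / sc$height_um
  hl <- sc$wound_width_um / 2 +
    sc$edge_ruggedness_um * sin(w * y_um + sc$edge_phase_left)
  hr <- sc$wound_width_um / 2 +
    sc$edge_ruggedness_um * sin(2 * w * y_um + sc$edge_phase_right)
  list(left = hl, right = hr, total = hl + hr)
}

# Signed wound interval at time t (hours): for each y returns the left and
# right wound borders (um from the left of the frame); the interval is
# empty where left >= right.
wound_interval <- function(sc, y_um, t_hr) {
  g <- edge_gap_profile(sc, y_um)
  adv <- sc$v_front_um_hr * t_hr
  mid <- sc$width_um / 2
  list(left = mid - (g$left - adv), right = mid + (g$right - adv))
}

# logistic activation of the treated-regime backward wave
wave_activation <- function(sc, d_um, t_hr) {
  lag <- if (sc$wave_speed_um_hr > 0) d_um / sc$wave_speed_um_hr else
    ifelse(d_um > 0, Inf, 0)
  stats::plogis((t_hr - lag - sc$wave_onset_hr) / sc$wave_ramp_hr)
}

#' Prescribed speed toward the wound
#'
#' The ground-truth speed (um/hr, toward the wound) of a cell at distance
#' `d_um` from the wound edge at time `t_hr`, for the scenario's regime.
#' This is the quantity a velocity magnitude map should recover.
#'
#' @param scenario a [synthetic_scenario()].
#' @param d_um distance from the wound edge, micrometres (>= 0); vectorised.
#' @param t_hr time since scratch, hours (>= 0); vectorised (recycled
#'   against `d_um`).
#' @return numeric vector of speeds, um/hr.
#' @export
prescribed_velocity <- function(scenario, d_um, t_hr) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  if (any(d_um < 0)) stop("negative distance")
  if (any(t_hr < 0)) stop("negative time")
  sc <- scenario
  decay <- exp(-d_um / sc$decay_length_um)
  v <- if (sc$regime == "treated") {
    s <- wave_activation(sc, d_um, t_hr)
    alpha <- 1 + (sc$wave_boost - 1) * (1 - decay)
    sc$v_front_um_hr * (decay + (alpha - decay) * s)
  } else {
    sc$v_front_um_hr * decay + 0 * t_hr
  }
  # post-closure relaxation; treated distant cells decay more slowly
  if (is.finite(sc$t_closure_hr)) {
    dt <- pmax(0, t_hr - sc$t_closure_hr)
    tau <- if (sc$regime == "treated")
      sc$relax_time_hr * (1 + d_um / sc$decay_length_um)
    else sc$relax_time_hr
    v <- v * exp(-dt / tau)
  }
  v
}

# pseudo-cell size multiplier of the morphology program (dimensionless)
morph_scale <- function(sc, d_um, t_hr) {
  m <- sc$morphology
  decay <- exp(-d_um / sc$decay_length_um)
  base <- if (sc$regime == "treated") {
    s <- wave_activation(sc, d_um, t_hr)
    1 + m$front_spread * decay * (1 - s) +
      m$distant_growth * (1 - decay) * s
  } else {
    1 + m$front_spread * decay
  }
  if (is.finite(sc$t_closure_hr)) {
    dt <- pmax(0, t_hr - sc$t_closure_hr)
    base <- 1 + (base - 1) * exp(-dt / sc$relax_time_hr)
  }
  base
}

# Edge sample points (um) of the open wound at time t: one point per pixel
# row and side where the wound interval is non-empty and inside the frame.
edge_points <- function(sc, t_hr) {
  y <- seq(0.5, sc$height_px - 0.5) * sc$pixel_size_um
  wi <- wound_interval(sc, y, t_hr)
  open <- wi$left < wi$right
  if (!any(open)) return(NULL)
  cbind(x = c(wi$left[open], wi$right[open]), y = c(y[open], y[open]))
}

# Advect particle positions (um) one frame forward; pts is a 2-col matrix
# (x, y); edge is the (possibly frozen) wound edge point set.
advect_step <- function(sc, pts, edge, t_hr, dt_hr) {
  if (is.null(edge) || nrow(pts) == 0L) return(pts)
  d2 <- outer(pts[, 1], edge[, 1], "-")^2 + outer(pts[, 2], edge[, 2], "-")^2
  j <- max.col(-d2, ties.method = "first")
  nearest <- edge[j, , drop = FALSE]
  dx <- nearest[, 1] - pts[, 1]
  dy <- nearest[, 2] - pts[, 2]
  d <- sqrt(dx^2 + dy^2)
  v <- prescribed_velocity(sc, d, t_hr)
  step <- v * dt_hr
  nz <- d > 1e-9
  out <- pts
  out[nz, 1] <- pts[nz, 1] + step[nz] * dx[nz] / d[nz]
  out[nz, 2] <- pts[nz, 2] + step[nz] * dy[nz] / d[nz]
  # never step across the edge into the open wound
  overshoot <- nz & step > d
  out[overshoot, 1] <- nearest[overshoot, 1]
  out[overshoot, 2] <- nearest[overshoot, 2]
  out
}

# TRUE where (x, y) [um] lies in the open wound at time t
in_wound <- function(sc, x_um, y_um, t_hr) {
  wi <- wound_interval(sc, y_um, t_hr)
  x_um > wi$left & x_um < wi$right & wi$left < wi$right
}

# logical wound mask over pixel centres at time t (rows = y, cols = x)
wound_mask_at <- function(sc, t_hr) {
  xs <- seq(0.5, sc$width_px - 0.5) * sc$pixel_size_um
  ys <- seq(0.5, sc$height_px - 0.5) * sc$pixel_size_um
  wi <- wound_interval(sc, ys, t_hr)
  m <- matrix(FALSE, sc$height_px, sc$width_px)
  open <- wi$left < wi$right
  for (i in which(open))
    m[i, xs > wi$left[i] & xs < wi$right[i]] <- TRUE
  m
}

seed_particle_grid <- function(sc, pad_um, t_hr = 0) {
  sp <- 0.7 * sc$texture_cell_diameter_um
  gx <- seq(-pad_um, sc$width_um + pad_um, by = sp)
  gy <- seq(-pad_um, sc$height_um + pad_um, by = sp)
  g <- expand.grid(ix = seq_along(gx), iy = seq_along(gy))
  jit <- matrix(stats::runif(2 * nrow(g), -0.35 * sp, 0.35 * sp), ncol = 2)
  pts <- cbind(gx[g$ix] + jit[, 1], gy[g$iy] + jit[, 2])
  # checkerboard bright/dark pseudo-cells: avoids both same-sign plateaus
  # and opposite-sign cancellation pools, keeping local variance uniform
  sign <- ifelse((g$ix + g$iy) %% 2 == 0, 1, -1)
  keep <- !in_wound(sc, pts[, 1], pts[, 2], t_hr)
  list(pts = pts[keep, , drop = FALSE], sign = sign[keep])
}

render_frame <- function(sc, pts, amp, t_hr, noise_field, wound_level = 0.5) {
  h <- sc$height_px; w <- sc$width_px; px <- sc$pixel_size_um
  img <- matrix(0, h, w)
  # distance of each particle to the (frozen-at-closure) wound edge drives
  # the morphology program
  t_geom <- t_hr
  if (is.finite(sc$t_closure_hr)) t_geom <- min(t_hr, sc$t_closure_hr)
  edge <- edge_points(sc, t_geom)
  if (!is.null(edge) && nrow(pts)) {
    d2 <- outer(pts[, 1], edge[, 1], "-")^2 + outer(pts[, 2], edge[, 2], "-")^2
    d <- sqrt(apply(d2, 1, min))
  } else d <- rep(0, nrow(pts))
  scale <- morph_scale(sc, d, t_hr)
  aspect <- 1 + sc$morphology$elongation * (scale - 1)
  sig0 <- sc$texture_cell_diameter_um / 3
  sx <- sig0 * scale * sqrt(aspect) / px   # along motion (x), px units
  sy <- sig0 * scale / sqrt(aspect) / px
  cx <- pts[, 1] / px + 0.5  # to pixel coordinates (col, row), 1-based centres
  cy <- pts[, 2] / px + 0.5
  for (i in seq_len(nrow(pts))) {
    r0 <- max(1L, floor(cy[i] - 3 * sy[i])); r1 <- min(h, ceiling(cy[i] + 3 * sy[i]))
    c0 <- max(1L, floor(cx[i] - 3 * sx[i])); c1 <- min(w, ceiling(cx[i] + 3 * sx[i]))
    if (r0 > r1 || c0 > c1) next
    gy <- exp(-((r0:r1 - cy[i])^2) / (2 * sy[i]^2))
    gx <- exp(-((c0:c1 - cx[i])^2) / (2 * sx[i]^2))
    img[r0:r1, c0:c1] <- img[r0:r1, c0:c1] + amp[i] * tcrossprod(gy, gx)
  }
  cellular <- !wound_mask_at(sc, t_hr)
  out <- wound_level + noise_field
  out[cellular] <- out[cellular] + img[cellular]
  pmin(pmax(out, 0), 1)
}

#' Render a synthetic wound-healing movie with full ground truth
#'
#' The cellular region is textured with Gaussian-blob pseudo-cells on a
#' jittered grid; blobs are advected every frame by the prescribed velocity
#' field (toward the nearest wound-edge point), the wound band shrinks at
#' the prescribed front speed, and under-covered monolayer areas are
#' re-seeded so the sheet stays confluent. The wound region carries only a
#' static low-amplitude sensor-noise field, so local texture energy is far
#' higher inside the monolayer than in the wound. The result is a pure
#' function of the scenario (including its `rng_seed`).
#'
#' @param scenario a [synthetic_scenario()].
#' @return A list with elements
#'   * `movie`: a [movie_stack()];
#'   * `truth`: list with `wound_masks` / `cellular_masks` (logical, per
#'     frame), `wound_area_um2`, `t_contact_frame`, `t_closure_frame`
#'     (1-based first frame of contact / closure, `NA` if never reached),
#'     `t_contact_hr`, `t_closure_hr`, `v_fun(d_um, t_hr)` and the scenario.
#' @export
generate_movie <- function(scenario) {
  sc <- scenario
  stopifnot(inherits(sc, "synthetic_scenario"))
  dt_hr <- sc$frame_interval_min / 60
  max_v <- sc$v_front_um_hr * max(1, sc$wave_boost)
  max_disp_px <- max_v * dt_hr / sc$pixel_size_um
  if (max_disp_px > min(sc$height_px, sc$width_px) / 2)
    stop("per-frame displacement (", round(max_disp_px, 1),
         " px) exceeds half the frame")

  with_seed(sc$rng_seed + 1L, {
    pad <- 2 * sc$texture_cell_diameter_um
    seeded <- seed_particle_grid(sc, pad)
    pts <- seeded$pts
    amp <- seeded$sign * stats::runif(nrow(pts), 0.25, 0.5)
    noise_field <- matrix(stats::rnorm(sc$height_px * sc$width_px, 0, sc$noise_sd),
                          sc$height_px, sc$width_px)
    sp <- 0.7 * sc$texture_cell_diameter_um
    # fill jitter-induced gaps along the wound boundary before the first
    # frame, so a zero-velocity scenario renders identical frames
    res0 <- reseed_holes(sc, pts, sp, pad, 0)
    if (nrow(res0)) {
      pts <- rbind(pts, res0)
      amp <- c(amp, sample(c(-1, 1), nrow(res0), replace = TRUE) *
                 stats::runif(nrow(res0), 0.25, 0.5))
    }

    frames <- vector("list", sc$n_frames)
    wound_masks <- vector("list", sc$n_frames)
    last_edge <- edge_points(sc, 0)
    for (k in seq_len(sc$n_frames)) {
      t_hr <- (k - 1) * dt_hr
      frames[[k]] <- render_frame(sc, pts, amp, t_hr, noise_field)
      wound_masks[[k]] <- wound_mask_at(sc, t_hr)
      if (k < sc$n_frames) {
        edge <- edge_points(sc, t_hr)
        if (!is.null(edge)) last_edge <- edge
        pts <- advect_step(sc, pts, edge %||% last_edge, t_hr, dt_hr)
        t_next <- k * dt_hr
        # pull any particle that ended up inside the shrinking wound back out
        inside <- in_wound(sc, pts[, 1], pts[, 2], t_next)
        if (any(inside)) {
          wi <- wound_interval(sc, pts[inside, 2], t_next)
          mid <- sc$width_um / 2
          pts[inside, 1] <- ifelse(pts[inside, 1] < mid, wi$left, wi$right)
        }
        # re-seed holes opened by the stretching flow (pseudo-proliferation)
        res <- reseed_holes(sc, pts, sp, pad, t_next)
        if (nrow(res)) {
          pts <- rbind(pts, res)
          amp <- c(amp, sample(c(-1, 1), nrow(res), replace = TRUE) *
                     stats::runif(nrow(res), 0.25, 0.5))
        }
      }
    }
  })

  movie <- movie_stack(frames, sc$pixel_size_um, sc$frame_interval_min,
                       name = paste0("synthetic-", sc$regime, "-seed",
                                     sc$rng_seed),
                       normalize = FALSE)
  area <- vapply(wound_masks, sum, numeric(1)) * sc$pixel_size_um^2
  # closure frame uses the same area criterion as detect_phases (area
  # below 1% of the initial wound)
  closure_frame <- if (area[1] > 0 && any(area < 0.01 * area[1]))
    which(area < 0.01 * area[1])[1] else NA_integer_
  truth <- list(
    wound_masks = wound_masks,
    cellular_masks = lapply(wound_masks, `!`),
    wound_area_um2 = area,
    t_contact_frame = hr_to_frame(sc$t_contact_hr, dt_hr, sc$n_frames),
    t_closure_frame = closure_frame,
    t_contact_hr = sc$t_contact_hr, t_closure_hr = sc$t_closure_hr,
    v_fun = function(d_um, t_hr) prescribed_velocity(sc, d_um, t_hr),
    scenario = sc)
  list(movie = movie, truth = truth)
}

hr_to_frame <- function(t_hr, dt_hr, n_frames) {
  if (!is.finite(t_hr)) return(NA_integer_)
  k <- 1L + as.integer(ceiling(t_hr / dt_hr - 1e-9))
  if (k > n_frames) NA_integer_ else k
}

reseed_holes <- function(sc, pts, sp, pad_um, t_hr) {
  # spawn a particle at any cellular grid node whose nearest particle is
  # farther than one grid step, keeping the sheet confluent where the
  # stretching flow thins it (pseudo-proliferation)
  gx <- seq(-pad_um, sc$width_um + pad_um, by = sp)
  gy <- seq(-pad_um, sc$height_um + pad_um, by = sp)
  g <- expand.grid(x = gx, y = gy)
  keep <- !in_wound(sc, g$x, g$y, t_hr)
  g <- g[keep, , drop = FALSE]
  if (!nrow(g) || !nrow(pts)) return(matrix(numeric(0), 0, 2))
  d2 <- outer(g$x, pts[, 1], "-")^2 + outer(g$y, pts[, 2], "-")^2
  mind <- sqrt(do.call(pmin, as.data.frame(d2)))
  hole <- mind > sp
  if (!any(hole)) return(matrix(numeric(0), 0, 2))
  n <- sum(hole)
  jit <- matrix(stats::runif(2 * n, -0.25 * sp, 0.25 * sp), ncol = 2)
  cbind(g$x[hole] + jit[, 1], g$y[hole] + jit[, 2])
}

#' Ground-truth cell trajectories under the prescribed velocity field
#'
#' Integrates the scenario's velocity law from random cellular start points
#' using the same advection rule as the renderer, producing the reference
#' tracks against which DIC-based trajectory estimation is validated.
#'
#' @param scenario a [synthetic_scenario()].
#' @param n_cells number of tracks (>= 1).
#' @param rng_seed seed for the start positions (default: scenario seed).
#' @return A list of `n_cells` data frames with columns `frame`, `t_hr`,
#'   `x_um`, `y_um`.
#' @export
seed_tracks <- function(scenario, n_cells, rng_seed = scenario$rng_seed) {
  sc <- scenario
  stopifnot(inherits(sc, "synthetic_scenario"), n_cells >= 1)
  dt_hr <- sc$frame_interval_min / 60
  margin <- sc$texture_cell_diameter_um
  cap <- (sc$width_um - sc$wound_width_um) * sc$height_um /
    sc$texture_cell_diameter_um^2
  if (n_cells > cap)
    stop("n_cells exceeds the available cellular area at cell-size spacing")
  pts <- with_seed(rng_seed + 2L, {
    out <- matrix(numeric(0), 0, 2)
    while (nrow(out) < n_cells) {
      cand <- cbind(stats::runif(4 * n_cells, margin, sc$width_um - margin),
                    stats::runif(4 * n_cells, margin, sc$height_um - margin))
      cand <- cand[!in_wound(sc, cand[, 1], cand[, 2], 0), , drop = FALSE]
      out <- rbind(out, cand)
    }
    out[seq_len(n_cells), , drop = FALSE]
  })
  pos <- array(NA_real_, c(sc$n_frames, n_cells, 2))
  pos[1, , ] <- pts
  last_edge <- edge_points(sc, 0)
  for (k in seq_len(sc$n_frames - 1L)) {
    t_hr <- (k - 1) * dt_hr
    edge <- edge_points(sc, t_hr)
    if (!is.null(edge)) last_edge <- edge
    pts <- advect_step(sc, pts, edge %||% last_edge, t_hr, dt_hr)
    pos[k + 1, , ] <- pts
  }
  lapply(seq_len(n_cells), function(i)
    data.frame(frame = seq_len(sc$n_frames),
               t_hr = (seq_len(sc$n_frames) - 1) * dt_hr,
               x_um = pos[, i, 1], y_um = pos[, i, 2]))
}
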