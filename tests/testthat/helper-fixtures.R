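# Shared fixtures, built once per test run and cached.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixture_env))
    assign(name, force(expr), envir = .fixture_env)
  get(name, envir = .fixture_env)
}

# one rendered movie + full pipeline run per regime
fx_untreated <- function() fixture("untreated", {
  gm <- generate_movie(synthetic_scenario("untreated", rng_seed = 11))
  run <- run_experiment(gm$movie, cohort_config(), texture = TRUE)
  list(gm = gm, run = run, scenario = gm$truth$scenario)
})

fx_treated <- function() fixture("treated", {
  gm <- generate_movie(synthetic_scenario("treated", rng_seed = 12))
  run <- run_experiment(gm$movie, cohort_config(), texture = TRUE)
  list(gm = gm, run = run, scenario = gm$truth$scenario)
})

# smooth random texture with displacement structure for motion tests
smooth_texture <- function(nr, nc, seed = 1, blur = 2) {
  set.seed(seed)
  x <- matrix(stats::rnorm(nr * nc), nr, nc)
  k <- stats::dnorm(seq(-3, 3, length.out = 2 * blur + 1))
  k <- k / sum(k)
  x <- apply(x, 2, stats::filter, filter = k, circular = TRUE)
  x <- t(apply(x, 1, stats::filter, filter = k, circular = TRUE))
  (x - min(x)) / (max(x) - min(x))
}

circ_shift <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  m[((seq_len(nr) - 1 - dr) %% nr) + 1, ((seq_len(nc) - 1 - dc) %% nc) + 1]
}

# hand-built velocity field on a grid, for strip/trajectory unit tests
make_field <- function(grid, vr, vc, valid = TRUE, d_um = NULL, dy = NULL,
                       dx = NULL, n_cellular = NULL) {
  n <- length(grid$r0)
  f <- data.frame(r = grid$center_r, c = grid$center_c,
                  vr = rep_len(vr, n), vc = rep_len(vc, n))
  f$speed_um_hr <- sqrt(f$vr^2 + f$vc^2)
  f$score <- 1
  f$n_cellular <- rep_len(n_cellular %||% grid$patch_size_px^2, n)
  f$valid <- rep_len(valid, n)
  f$vr[!f$valid] <- NA_real_
  f$vc[!f$valid] <- NA_real_
  if (!is.null(d_um)) f$d_um <- rep_len(d_um, n)
  if (!is.null(dy)) f$dy <- rep_len(dy, n)
  if (!is.null(dx)) f$dx <- rep_len(dx, n)
  attr(f, "grid") <- grid
  class(f) <- c("velocity_field", class(f))
  f
}

`%||%` <- function(a, b) if (is.null(a)) b else a

manual_phases <- function(t_contact, t_closure, n_frames = 60L) {
  structure(list(t_contact = t_contact, t_closure = t_closure,
                 n_frames = n_frames), class = "phase_partition")
}

# ground-truth-driven toward-wound fields: patch distances and dy taken
# from the prescribed velocity law, bypassing rendering and NCC
truth_toward_fields <- function(scenario, strip_width_um = 16,
                                n_bins = 12, n_frames = scenario$n_frames) {
  dt_hr <- scenario$frame_interval_min / 60
  grid <- patch_grid(c(scenario$height_px, scenario$width_px), 8L)
  ds <- (seq_len(n_bins) - 0.5) * strip_width_um
  lapply(seq_len(n_frames - 1L), function(k) {
    t_hr <- (k - 0.5) * dt_hr
    d <- rep_len(ds, length(grid$r0))
    make_field(grid, 0, 0, d_um = d,
               dy = prescribed_velocity(scenario, d, t_hr), dx = 0)
  })
}
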