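test_that("prescribed velocity follows the exponential decay law", {
  sc <- synthetic_scenario("untreated", rng_seed = 1)
  t_pre <- 0.5  # well before closure
  expect_equal(prescribed_velocity(sc, 0, t_pre), sc$v_front_um_hr)
  expect_equal(prescribed_velocity(sc, sc$decay_length_um, t_pre),
               sc$v_front_um_hr / exp(1))
  expect_error(prescribed_velocity(sc, -1, 0), "negative distance")
  expect_error(prescribed_velocity(sc, 0, -1), "negative time")
  # time-constant before closure, decaying to ~0 for all d afterwards
  expect_equal(prescribed_velocity(sc, 40, 0.1),
               prescribed_velocity(sc, 40, sc$t_closure_hr - 0.1))
  late <- sc$t_closure_hr + 6 * sc$relax_time_hr
  expect_lt(max(prescribed_velocity(sc, c(0, 50, 100), late)),
            0.05 * sc$v_front_um_hr)
})

test_that("treated regime: distant cells accelerate monotonically and pass front cells", {
  sc <- synthetic_scenario("treated", rng_seed = 1)
  d_far <- 100
  ts <- seq(0, sc$t_contact_hr, length.out = 25)
  v <- prescribed_velocity(sc, rep(d_far, length(ts)), ts)
  expect_true(all(diff(v) >= -1e-9))
  # after the wave has passed, distant speed exceeds the front's
  t2 <- (sc$t_contact_hr + sc$t_closure_hr) / 2
  expect_gt(prescribed_velocity(sc, d_far, t2),
            prescribed_velocity(sc, 0, t2))
})

test_that("inhibited regime maximises the front/distant speed ratio", {
  t <- 1
  d <- 80
  ratio <- function(reg) {
    sc <- synthetic_scenario(reg, rng_seed = 1)
    prescribed_velocity(sc, 0, t) / prescribed_velocity(sc, d, t)
  }
  expect_gt(ratio("inhibited"), ratio("untreated"))
  expect_gt(ratio("untreated"), ratio("treated"))
})

test_that("zero-motion scenario yields identical frames and no healing", {
  sc <- synthetic_scenario("untreated", v_front_um_hr = 0, n_frames = 4,
                           rng_seed = 5)
  gm <- generate_movie(sc)
  expect_true(is.na(gm$truth$t_contact_frame))
  expect_true(is.na(gm$truth$t_closure_frame))
  expect_equal(length(unique(gm$truth$wound_area_um2)), 1L)
  for (k in 2:4)
    expect_identical(gm$movie$frames[[k]], gm$movie$frames[[1]])
})

test_that("movie generation is a pure function of scenario and seed", {
  sc <- synthetic_scenario("treated", n_frames = 6, rng_seed = 21)
  a <- generate_movie(sc)
  b <- generate_movie(sc)
  expect_identical(a$movie$frames, b$movie$frames)
  expect_identical(a$truth$wound_area_um2, b$truth$wound_area_um2)
  c <- generate_movie(synthetic_scenario("treated", n_frames = 6,
                                         rng_seed = 22))
  expect_false(identical(a$movie$frames[[1]], c$movie$frames[[1]]))
})

test_that("scenario validation rejects impossible geometry and rates", {
  expect_error(synthetic_scenario("untreated", n_frames = 2), "n_frames")
  expect_error(synthetic_scenario("untreated", wound_width_um = 600),
               "does not fit")
  expect_error(synthetic_scenario("untreated", v_front_um_hr = -3),
               "non-negative")
  expect_error(
    generate_movie(synthetic_scenario("untreated", v_front_um_hr = 4000)),
    "exceeds half the frame")
})

test_that("ground-truth wound area is non-increasing until closure, then zero", {
  gm <- fx_untreated()$gm
  area <- gm$truth$wound_area_um2
  expect_true(all(diff(area) <= 0))
  geom_closed <- which(area == 0)[1]
  expect_false(is.na(geom_closed))
  expect_true(all(area[geom_closed:length(area)] == 0))
  expect_lte(gm$truth$t_contact_frame, gm$truth$t_closure_frame)
})

test_that("cellular texture energy dominates the wound by at least 3x", {
  gm <- fx_untreated()$gm
  for (k in c(1, 15, 28)) {
    f <- gm$movie$frames[[k]]
    w <- gm$truth$wound_masks[[k]]
    # interior of each region, away from the boundary
    d <- distance_map(!w, w, 1)
    cellular_core <- !w & is.finite(d) & d > 6
    expect_gt(stats::var(f[cellular_core]), 3 * stats::var(f[w]))
  }
})

test_that("seed_tracks: stationary limit, closed form, and wave property", {
  still <- synthetic_scenario("untreated", v_front_um_hr = 0, n_frames = 5,
                              rng_seed = 2)
  trk <- seed_tracks(still, 3)
  for (tr in trk) {
    expect_equal(stats::sd(tr$x_um), 0)
    expect_equal(stats::sd(tr$y_um), 0)
  }
  # near-uniform field (huge decay length, straight edge): displacement
  # ~ v * t exactly
  unif <- synthetic_scenario("untreated", v_front_um_hr = 10,
                             decay_length_um = 1e9, n_frames = 10,
                             edge_ruggedness_um = 0, rng_seed = 3)
  trk <- seed_tracks(unif, 4)
  dt_hr <- unif$frame_interval_min / 60
  horizon <- min(8, unif$t_contact_hr %/% dt_hr)
  for (tr in trk) {
    disp <- sqrt((tr$x_um[horizon] - tr$x_um[1])^2 +
                 (tr$y_um[horizon] - tr$y_um[1])^2)
    expect_equal(disp, 10 * (horizon - 1) * dt_hr, tolerance = 0.02)
  }
  expect_error(seed_tracks(unif, 1e7), "exceeds")
  # treated: a distant cell is faster in Phase 2 than in Phase 1
  sc <- fx_treated()$scenario
  trk <- seed_tracks(sc, 6, rng_seed = 4)
  dt_hr <- sc$frame_interval_min / 60
  tc <- ceiling(sc$t_contact_hr / dt_hr)
  tz <- floor(sc$t_closure_hr / dt_hr)
  for (tr in trk) {
    step <- sqrt(diff(tr$x_um)^2 + diff(tr$y_um)^2) / dt_hr
    v1 <- mean(step[1:(tc - 1)])
    v2 <- mean(step[tc:tz])
    expect_gte(v2, v1)
  }
  # reproducible by seed
  expect_identical(seed_tracks(sc, 2, rng_seed = 9),
                   seed_tracks(sc, 2, rng_seed = 9))
})
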