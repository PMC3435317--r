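test_that("distance map matches closed forms for simple wounds", {
  # vertical wound band, 1 um pixels
  cm <- matrix(TRUE, 20, 30); wm <- matrix(FALSE, 20, 30)
  wm[, 15:20] <- TRUE
  d <- distance_map(cm & !wm, wm, 1)
  for (c in 1:14) expect_equal(unname(d[10, c]), 15 - c)
  # single-pixel wound: radial Euclidean distance
  wm2 <- matrix(FALSE, 21, 21); wm2[11, 11] <- TRUE
  d2 <- distance_map(!wm2, wm2, 1)
  for (p in list(c(1, 11), c(11, 1), c(5, 5)))
    expect_equal(unname(d2[p[1], p[2]]),
                 sqrt((p[1] - 11)^2 + (p[2] - 11)^2), tolerance = 1e-6)
  # empty wound: flagged undefined
  d3 <- distance_map(cm, matrix(FALSE, 20, 30), 1)
  expect_true(attr(d3, "undefined"))
  expect_true(all(is.na(d3)))
})

test_that("distance transform equals brute force on random masks", {
  set.seed(10)
  for (rep in 1:5) {
    wm <- matrix(runif(32 * 32) < 0.05, 32, 32)
    if (!any(wm)) next
    d <- distance_map(matrix(TRUE, 32, 32) & !wm, wm, 1.5)
    wp <- which(wm, arr.ind = TRUE)
    idx <- which(!wm, arr.ind = TRUE)[seq(1, sum(!wm), by = 17), , drop = FALSE]
    for (i in seq_len(nrow(idx))) {
      bf <- min(sqrt((idx[i, 1] - wp[, 1])^2 + (idx[i, 2] - wp[, 2])^2)) * 1.5
      expect_equal(unname(d[idx[i, 1], idx[i, 2]]), bf, tolerance = 1e-6)
    }
  }
})

test_that("velocity map of uniform/zero fields is constant on defined bins", {
  cm <- matrix(TRUE, 64, 64); wm <- matrix(FALSE, 64, 64)
  wm[, 57:64] <- TRUE
  dm <- distance_map(cm & !wm, wm, 1)
  g <- patch_grid(c(64, 64), 8L)
  zero <- replicate(3, make_field(g, 0, 0), simplify = FALSE)
  M0 <- build_velocity_map(zero, replicate(3, dm, simplify = FALSE),
                           strip_width_um = 8)
  expect_true(all(M0[!is.na(M0)] == 0))
  unif <- replicate(3, make_field(g, 3, 4), simplify = FALSE)  # speed 5
  M1 <- build_velocity_map(unif, replicate(3, dm, simplify = FALSE),
                           strip_width_um = 8)
  expect_true(all(abs(M1[!is.na(M1)] - 5) < 1e-9))
})

test_that("every valid patch lands in exactly one strip bin", {
  fx <- fx_untreated()
  f <- fx$run$fields[[5]]
  dmap <- fx$run$dist_maps[[5]]
  M <- build_velocity_map(list(f), list(dmap), strip_width_um = 16)
  d <- f$d_um %||% dmap[cbind(round(f$r), round(f$c))]
  ok <- f$valid & is.finite(d)
  bins <- floor(d[ok] / 16) + 1
  expect_true(all(bins >= 1 & bins <= ncol(M)))
  # bins holding at least one patch are defined, others are missing
  expect_true(all(!is.na(M[1, sort(unique(pmin(bins, ncol(M))))])))
})

test_that("velocity map is covariant under vertical flips of the geometry", {
  fx <- fx_untreated()
  ks <- 4:6
  fields <- fx$run$fields[ks]          # raw fields: distances looked up per map
  dmaps <- lapply(fx$run$dist_maps[ks], function(d) matrix(d, nrow(d)))
  M <- build_velocity_map(fields, dmaps, strip_width_um = 16)
  H <- nrow(dmaps[[1]])
  flip <- lapply(fields, function(f) {
    f$r <- H + 1 - f$r
    f$vr <- -f$vr
    f
  })
  fdm <- lapply(dmaps, function(d) d[nrow(d):1, ])
  Mf <- build_velocity_map(flip, fdm, strip_width_um = 16)
  expect_equal(unclass(M), unclass(Mf), tolerance = 1e-9)
})

test_that("phase detection handles degenerate and synthetic movies", {
  # wound never shrinks
  wm <- matrix(FALSE, 20, 20); wm[, 9:12] <- TRUE
  ph <- detect_phases(replicate(4, wm, simplify = FALSE))
  expect_true(is.na(ph$t_contact) && is.na(ph$t_closure))
  # already closed at frame 1
  ph0 <- detect_phases(replicate(3, matrix(FALSE, 8, 8), simplify = FALSE))
  expect_equal(ph0$t_contact, 1L)
  expect_equal(ph0$t_closure, 1L)
  # synthetic: within 2 frames of ground truth closure
  fx <- fx_untreated()
  expect_lte(abs(fx$run$phases$t_closure - fx$gm$truth$t_closure_frame), 2)
  expect_lte(abs(fx$run$phases$t_contact - fx$gm$truth$t_contact_frame), 3)
  expect_lte(fx$run$phases$t_contact, fx$run$phases$t_closure)
})

test_that("displacement of a constant uniform toward-flow is exactly v*t", {
  g <- patch_grid(c(64, 64), 8L)
  flds <- replicate(10, make_field(g, 0, 0, d_um = 40, dy = 6, dx = 0),
                    simplify = FALSE)
  R <- average_cell_displacement(flds, anchors_um = 40, dt_hr = 0.25,
                                 strip_width_um = 16, mode = "fixed")
  expect_equal(unname(R[, 1]), 6 * 0.25 * (0:10))
})

test_that("untreated displacement gap grows; treated Phase-2 gap does not", {
  # ground-truth-driven fields isolate the regime property from NCC noise
  scu <- synthetic_scenario("untreated", rng_seed = 31)
  dtu <- scu$frame_interval_min / 60
  tfu <- truth_toward_fields(scu)
  stopu <- floor(scu$t_closure_hr / dtu)
  Ru <- average_cell_displacement(tfu, anchors_um = c(8, 88), dt_hr = dtu,
                                  strip_width_um = 16, t_stop = stopu)
  gap <- Ru[, 1] - Ru[, 2]
  expect_true(all(diff(gap) >= -1e-9))

  sct <- synthetic_scenario("treated", rng_seed = 32)
  dtt <- sct$frame_interval_min / 60
  tft <- truth_toward_fields(sct)
  tc <- ceiling(sct$t_contact_hr / dtt)
  tz <- floor(sct$t_closure_hr / dtt)
  Rt <- average_cell_displacement(tft, anchors_um = c(8, 104), dt_hr = dtt,
                                  strip_width_um = 16, t_stop = tz)
  gap2 <- (Rt[, 1] - Rt[, 2])[(tc + 1):(tz + 1)]
  expect_true(all(diff(gap2) <= 1e-9))
})

test_that("velocity-toward profiles reflect the regime laws", {
  g <- patch_grid(c(64, 64), 8L)
  zero <- replicate(6, make_field(g, 0, 0, d_um = 20, dy = 0, dx = 0),
                    simplify = FALSE)
  P0 <- velocity_toward_profile(zero, anchors_um = 20, strip_width_um = 16)
  expect_true(all(P0 == 0))

  scu <- synthetic_scenario("untreated", rng_seed = 33)
  dtu <- scu$frame_interval_min / 60
  tfu <- truth_toward_fields(scu)
  stopu <- floor(scu$t_closure_hr / dtu)
  P <- velocity_toward_profile(tfu[1:stopu], anchors_um = c(8, 56),
                               strip_width_um = 16, smooth_frames = 5)
  for (a in 1:2)
    expect_lt(max(abs(P[, a] - mean(P[, a]))), 0.2 * mean(P[, a]))

  sct <- synthetic_scenario("treated", rng_seed = 34)
  dtt <- sct$frame_interval_min / 60
  tft <- truth_toward_fields(sct)
  tc <- ceiling(sct$t_contact_hr / dtt)
  Pt <- velocity_toward_profile(tft[1:(tc - 1)], anchors_um = 104,
                                strip_width_um = 16, smooth_frames = 1)
  expect_true(all(diff(Pt[, 1]) >= -1e-9))
})
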