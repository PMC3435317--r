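test_that("trajectories integrate simple fields exactly", {
  g <- patch_grid(c(64, 64), 8L)
  zero <- replicate(5, make_field(g, 0, 0), simplify = FALSE)
  tr <- estimate_trajectory(zero, c(30, 30), pixel_size_um = 1, dt_hr = 0.5)
  expect_equal(attr(tr, "status"), "complete")
  expect_true(all(tr$row_um == 30 & tr$col_um == 30))
  unif <- replicate(5, make_field(g, 2, -1), simplify = FALSE)
  tr2 <- estimate_trajectory(unif, c(30, 30), 1, 0.5)
  expect_equal(tr2$row_um[6] - 30, 2 * 5 * 0.5, tolerance = 1e-6)
  expect_equal(tr2$col_um[6] - 30, -1 * 5 * 0.5, tolerance = 1e-6)
})

test_that("tracks terminate gracefully in invalid regions", {
  g <- patch_grid(c(64, 64), 8L)
  f <- make_field(g, 1, 1, valid = FALSE)
  tr <- estimate_trajectory(list(f, f), c(30, 30), 1, 0.5)
  expect_match(attr(tr, "status"), "terminated")
})

test_that("DIC-based trajectories stay within one patch of ground truth", {
  fx <- fx_untreated()
  sc <- fx$scenario
  dt_hr <- sc$frame_interval_min / 60
  tz <- fx$gm$truth$t_closure_frame
  tracks <- seed_tracks(sc, 4, rng_seed = 77)
  for (tr in tracks) {
    est <- estimate_trajectory(fx$run$fields, c(tr$y_um[1], tr$x_um[1]),
                               pixel_size_um = 2, dt_hr = dt_hr,
                               end_frame = tz)
    ok <- seq_len(min(tz, sum(!is.na(est$row_um))))
    err <- sqrt((est$row_um[ok] - tr$y_um[ok])^2 +
                (est$col_um[ok] - tr$x_um[ok])^2)
    expect_lte(mean(err), 18.5)
  }
})

test_that("trajectory estimation is bit-reproducible on identical fields", {
  fx <- fx_untreated()
  a <- estimate_trajectory(fx$run$fields, c(100, 100), 2, 14.5 / 60)
  b <- estimate_trajectory(fx$run$fields, c(100, 100), 2, 14.5 / 60)
  expect_identical(a, b)
})

test_that("shape measures reproduce the degenerate and analytic cases", {
  # rasterized disk: eccentricity ~ 0
  rr <- row(matrix(0, 51, 51)) - 26; cc <- col(matrix(0, 51, 51)) - 26
  disk <- rr^2 + cc^2 <= 20^2
  m <- cell_shape_measures(disk, 1)
  expect_lte(m$eccentricity, 0.1)
  expect_equal(m$area_um2, sum(disk))
  # a 1 x 50 line of pixels: eccentricity ~ 1
  line <- matrix(FALSE, 10, 60); line[5, 6:55] <- TRUE
  expect_gte(cell_shape_measures(line, 1)$eccentricity, 0.99)
  # ellipse a=40, b=20 px: ecc = sqrt(1 - 0.25)
  big <- matrix(0, 101, 101)
  rr <- row(big) - 51; cc <- col(big) - 51
  ell <- (cc / 40)^2 + (rr / 20)^2 <= 1
  expect_equal(cell_shape_measures(ell, 1)$eccentricity, sqrt(0.75),
               tolerance = 0.02)
  expect_error(cell_shape_measures(matrix(FALSE, 4, 4)), "empty")
})

test_that("eccentricity is scale- and rotation-invariant", {
  big <- matrix(0, 61, 61)
  rr <- row(big) - 31; cc <- col(big) - 31
  ell <- (cc / 25)^2 + (rr / 12)^2 <= 1
  e1 <- cell_shape_measures(ell, 1)$eccentricity
  up <- ell[rep(seq_len(61), each = 2), rep(seq_len(61), each = 2)]
  expect_lt(abs(cell_shape_measures(up, 1)$eccentricity - e1), 0.01)
  rot <- t(ell)
  expect_lt(abs(cell_shape_measures(rot, 1)$eccentricity - e1), 1e-9)
})

test_that("label images yield one measurement per cell", {
  lab <- matrix(0L, 20, 20)
  lab[2:5, 2:5] <- 1L
  lab[10:18, 10:12] <- 2L
  tab <- label_shape_table(lab, 2)
  expect_equal(tab$label, c(1L, 2L))
  expect_equal(tab$area_um2, c(16, 27) * 4)
  expect_gt(tab$eccentricity[2], tab$eccentricity[1])
})

test_that("density follows inverse proportionality to mean cell area", {
  expect_equal(density_from_area(200, 1.0), 5)
  expect_equal(density_from_area(400, 1.0), 2.5)
  expect_equal(density_from_area(200, 0.9), 4.5)
  expect_error(density_from_area(0), "positive")
  # packed label image with a known cell count: density recovered via the
  # measured mean cell area
  lab <- matrix(0L, 60, 60)
  k <- 0L
  for (i in seq(1, 51, by = 10)) for (j in seq(1, 51, by = 10)) {
    k <- k + 1L
    lab[i:(i + 8), j:(j + 8)] <- k   # 9x9 cells, 1 px gaps
  }
  tab <- label_shape_table(lab, pixel_size_um = 1)
  true_density <- 1000 * k / (60 * 60)
  est <- density_from_area(mean(tab$area_um2),
                           packing_fraction = sum(lab > 0) / (60 * 60))
  expect_lt(abs(est - true_density) / true_density, 0.2)
})

test_that("Spearman correlation: exact small-n p-values and flags", {
  r <- density_speed_correlation(5:1, c(10, 20, 30, 40, 50))
  expect_equal(r$rho, -1)
  expect_equal(r$p_value, 2 / 120, tolerance = 1e-12)
  flat <- density_speed_correlation(rep(1, 6), 1:6)
  expect_true(is.na(flat$rho))
  expect_error(density_speed_correlation(1:3, 3:1), "at least 5")
  set.seed(11)
  big <- density_speed_correlation(rnorm(30), rnorm(30))
  expect_equal(big$method, "t approximation")
  expect_true(big$p_value > 0 && big$p_value <= 1)
})

test_that("sparser strips move faster in the untreated regime (rho < 0)", {
  fx <- fx_untreated()
  sc <- fx$scenario
  M <- fx$run$map
  tc <- fx$run$phases$t_contact
  speeds <- colMeans(M[seq_len(tc - 1), 1:6], na.rm = TRUE)
  # morphology program: cells near the wound are more spread -> lower density
  d <- (1:6 - 0.5) * 16
  areas <- (sc$texture_cell_diameter_um *
              woundkinetics:::morph_scale(sc, d, 1))^2
  dens <- density_from_area(areas)
  r <- density_speed_correlation(c(dens, dens), c(speeds, speeds))
  expect_lt(r$rho, 0)
  expect_lt(r$p_value, 0.05)
})
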