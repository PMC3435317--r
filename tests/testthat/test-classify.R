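toy_map <- function(values, n_bins = 12, n_t = 30, strip = 16) {
  M <- matrix(values, n_t, n_bins)
  structure(M, class = c("velocity_magnitude_map", "matrix", "array"),
            strip_width_um = strip,
            bin_centers_um = (seq_len(n_bins) - 0.5) * strip)
}

test_that("descriptor geometry: 6 intervals x phases gives lengths 18 and 12", {
  M <- toy_map(7)
  ph <- manual_phases(10L, 20L, 31L)
  v18 <- velocity_descriptor(M, ph, n_intervals = 6, phases_used = 3,
                             max_distance_um = 96)
  expect_length(v18, 18L)
  v12 <- velocity_descriptor(M, ph, n_intervals = 6, phases_used = 2,
                             max_distance_um = 96)
  expect_length(v12, 12L)
  # constant map -> all entries equal that constant
  expect_true(all(v18 == 7))
  # ordering is phase-major and stable
  expect_equal(names(v18)[1:7],
               c(paste0("p1.i", 1:6), "p2.i1"))
})

test_that("wholly-missing descriptor cells raise an error naming the cell", {
  M <- toy_map(5)
  M[, 3] <- NA  # interval 3 only covered by bin 3 when aligned 16um bins
  ph <- manual_phases(10L, 20L, 31L)
  expect_error(velocity_descriptor(M, ph, 6, 3, max_distance_um = 96),
               "phase 1, interval 3")
})

test_that("norm-1 normalization removes scale exactly", {
  expect_equal(as.vector(normalize_descriptor(c(3, 4))), c(0.6, 0.8),
               ignore_attr = TRUE)
  set.seed(13)
  for (i in 1:10) {
    v <- rnorm(18)
    n1 <- normalize_descriptor(v)
    expect_equal(sqrt(sum(n1^2)), 1, tolerance = 1e-12)
    expect_equal(n1, normalize_descriptor(7.3 * v), tolerance = 1e-12)
  }
  expect_error(normalize_descriptor(rep(0, 5)), "zero")
})

test_that("LOOCV SVM is perfect on separable data and chance on shuffled labels", {
  set.seed(14)
  x <- rbind(matrix(rnorm(60, 1, 0.05), 6), matrix(rnorm(50, -1, 0.05), 5))
  y <- rep(c("a", "b"), c(6, 5))
  res <- loocv_svm(x, y)
  expect_equal(res$accuracy, 1.0)
  expect_equal(res$predictions, y)
  # decision scores separate the groups completely
  dv <- res$decision_values
  expect_true(max(dv[7:11]) < min(dv[1:6]) || max(dv[1:6]) < min(dv[7:11]))
  # permutation baseline
  accs <- replicate(100, loocv_svm(x, sample(y))$accuracy)
  expect_lt(abs(mean(accs) - 0.5), 0.15)
  expect_error(loocv_svm(x, rep("a", 11)), "two classes")
  expect_error(loocv_svm(x[1:3, ], c("a", "a", "b")), "at least 2")
})

test_that("LOOCV accuracy is invariant to consistent feature scaling", {
  set.seed(15)
  x <- rbind(matrix(rnorm(60, 1, 0.4), 6), matrix(rnorm(50, -1, 0.4), 5))
  y <- rep(c("a", "b"), c(6, 5))
  s <- diag(c(100, rep(0.01, 9)))
  expect_equal(loocv_svm(x, y)$accuracy, loocv_svm(x %*% s, y)$accuracy)
})

test_that("exact rank-sum p-values match the printed complete-separation bounds", {
  r65 <- exact_ranksum(1:6, 7:11)
  expect_true(r65$exact)
  expect_equal(r65$p_value, 2 / 462, tolerance = 1e-12)
  expect_equal(round(r65$p_value, 4), 0.0043)
  r66 <- exact_ranksum(7:12, 1:6)
  expect_equal(r66$p_value, 2 / 924, tolerance = 1e-12)
  expect_equal(round(r66$p_value, 4), 0.0022)
  expect_equal(exact_ranksum(rep(2, 5), rep(2, 4))$p_value, 1)
  expect_error(exact_ranksum(numeric(0), 1:3), "non-empty")
})

test_that("rank-sum null matches brute-force enumeration, ties included", {
  brute_p <- function(a, b) {
    n <- length(a) + length(b)
    r <- rank(c(a, b))
    combos <- utils::combn(n, length(a))
    ws <- apply(combos, 2, function(idx) sum(r[idx]))
    w <- sum(r[seq_along(a)])
    min(1, 2 * min(mean(ws <= w + 1e-9), mean(ws >= w - 1e-9)))
  }
  set.seed(16)
  for (i in 1:8) {
    na <- sample(2:6, 1); nb <- sample(2:6, 1)
    a <- sample(1:4, na, replace = TRUE)   # heavy ties
    b <- sample(2:6, nb, replace = TRUE)
    expect_equal(exact_ranksum(a, b)$p_value, brute_p(a, b),
                 tolerance = 1e-12)
  }
})

test_that("large samples fall back to a flagged normal approximation", {
  set.seed(17)
  r <- exact_ranksum(rnorm(15), rnorm(15, 1))
  expect_false(r$exact)
  expect_true(r$p_value > 0 && r$p_value <= 1)
})

test_that("2-component PCA preserves planar geometry and ranks variance", {
  set.seed(18)
  basis <- qr.Q(qr(matrix(rnorm(18 * 2), 18, 2)))
  plane <- matrix(rnorm(20), 10, 2) %*% t(basis)
  p <- pca2(plane)
  expect_equal(as.vector(dist(p$scores)), as.vector(dist(plane)),
               tolerance = 1e-9)
  expect_true(all(diff(p$var_explained) <= 1e-12))
  expect_lte(sum(p$var_explained), 1 + 1e-12)
  # deterministic sign: largest loading positive
  for (j in 1:2) expect_gt(p$loadings[which.max(abs(p$loadings[, j])), j], 0)
  # isotropic data spreads variance ~ evenly
  iso <- matrix(rnorm(5000 * 4), 5000, 4)
  expect_lt(abs(pca2(iso)$var_explained[1] - 0.25), 0.03)
  expect_error(pca2(plane[1:2, ]), "at least 3")
  expect_error(pca2(matrix(1, 5, 3)), "distinct")
})
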