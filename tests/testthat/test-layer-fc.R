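test_that("zero-phase filter preserves passband and kills stopband", {
  # 0.05 Hz sinusoid at TR = 4 passes nearly untouched
  t4 <- seq(0, 4000, by = 4)
  s <- sin(2 * pi * 0.05 * t4)
  f <- bandpass_filter(s, c(0.01, 0.1), TR = 4)
  mid <- 200:800 # interior, away from filter edge transients
  ratio <- sqrt(mean(f[mid]^2) / mean(s[mid]^2))
  expect_gt(ratio, 0.95)
  expect_lt(ratio, 1.05)

  # 0.2 Hz component (sampled at TR = 1) attenuated below 10%
  t1 <- seq(0, 2000, by = 1)
  s2 <- sin(2 * pi * 0.2 * t1)
  f2 <- bandpass_filter(s2, c(0.01, 0.1), TR = 1)
  expect_lt(sqrt(mean(f2[300:1700]^2) / mean(s2[300:1700]^2)), 0.1)

  # high-pass removes the mean
  const <- rep(5, 200)
  expect_lt(max(abs(bandpass_filter(const, c(0.01, NA), TR = 4))), 1e-6)

  # band outside Nyquist rejected, message names the Nyquist
  expect_error(bandpass_filter(s, c(0.01, 0.2), TR = 4), "0.125")
})

test_that("fisher_z is odd, monotone, clipped at the ceiling", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), 0.5493, tolerance = 1e-4)
  r <- seq(-0.99, 0.99, by = 0.01)
  expect_equal(fisher_z(-r), -fisher_z(r))
  expect_true(all(diff(fisher_z(r)) > 0))
  expect_equal(fisher_z(1), fisher_z_ceiling())
  expect_error(fisher_z(1.2), "\\[-1, 1\\]")
})

test_that("layer seed time courses select the right depths and units", {
  g <- small_grid(10)
  set.seed(12)
  mag <- array(rnorm(6 * 10 * 40, mean = 100), dim = c(6, 10, 40))
  ds <- laminar_dataset(mag, TR = 4, grid = g, roi = rep(c("M1", "S1"), each = 3))
  # full range equals the whole-ROI mean
  expect_equal(layer_seed_timecourse(ds, "M1", c(-0.2, 1.1)),
               apply(mag[1:3, , ], 3, mean))
  # single-unit ROI returns that unit's series
  one <- laminar_dataset(mag[1, , , drop = FALSE], TR = 4, grid = g)
  expect_equal(layer_seed_timecourse(one, 1, c(-0.2, 1.1)),
               apply(mag[1, , , drop = FALSE], 3, mean))
  expect_error(layer_seed_timecourse(ds, "V1"), "selects no units")
  expect_error(layer_seed_timecourse(ds, "M1", c(2, 3)), "no layers")
})

test_that("disjoint deep/superficial seeds recover their planted sources", {
  g <- depth_grid()
  deep_l <- which(g$mid >= 0.1 & g$mid <= 0.15)
  sup_l <- which(g$mid >= 0.85 & g$mid <= 0.9)
  n_t <- 300
  hits <- 0
  for (k in 1:20) {
    set.seed(800 + k)
    src_deep <- as.numeric(arima.sim(list(ar = 0.3), n_t))
    src_sup <- as.numeric(arima.sim(list(ar = 0.3), n_t))
    mag <- array(rnorm(4 * 20 * n_t, sd = 0.7), dim = c(4, 20, n_t))
    for (u in 1:4) {
      for (l in deep_l) mag[u, l, ] <- mag[u, l, ] + src_deep
      for (l in sup_l) mag[u, l, ] <- mag[u, l, ] + src_sup
    }
    ds <- laminar_dataset(100 + mag, TR = 4, grid = g)
    seed_deep <- layer_seed_timecourse(ds, projection = c(0.1, 0.15))
    seed_sup <- layer_seed_timecourse(ds, projection = c(0.85, 0.9))
    if (cor(seed_deep, src_deep) > 0.9 && cor(seed_sup, src_sup) > 0.9 &&
        cor(seed_deep, src_sup) < 0.5) {
      hits <- hits + 1
    }
  }
  expect_gte(hits, 19)
})

test_that("seed FC maps equal Fisher-z Pearson correlations with NA on flats", {
  g <- small_grid(4)
  set.seed(14)
  mag <- array(rnorm(3 * 4 * 100, mean = 100), dim = c(3, 4, 100))
  mag[2, 3, ] <- 50 # constant series
  ds <- laminar_dataset(mag, TR = 4, grid = g)
  seed <- mag[1, 1, ]
  expect_warning(m <- seed_fc_map(seed, ds), "zero-variance")
  # seed against itself sits at the clip ceiling
  expect_equal(m$z[m$unit == 1 & m$layer == 1], fisher_z_ceiling())
  expect_true(is.na(m$z[m$unit == 2 & m$layer == 3]))
  expect_equal(m$z[m$unit == 3 & m$layer == 2],
               fisher_z(cor(seed, mag[3, 2, ])))
  # independent noise: small average |z|
  others <- m$z[!(m$unit == 1 & m$layer == 1)]
  expect_lt(mean(abs(others), na.rm = TRUE), 3 / sqrt(100 - 3))
  # depth-range averaging path
  mr <- seed_fc_map(seed, ds, depth_ranges = list(deep = c(0, 0.5)))
  lay <- which(g$mid >= 0 & g$mid <= 0.5)
  expect_equal(mr$z[mr$unit == 3],
               fisher_z(cor(seed, apply(mag[3, lay, ], 2, mean))))
})

test_that("intracortical matrices are symmetric and track shared signal", {
  g <- small_grid(5)
  n_t <- 150
  # perfectly shared signal: every off-diagonal at the clip ceiling
  set.seed(15)
  shared <- rnorm(n_t)
  mag <- array(rep(shared, each = 2 * 5), dim = c(2, 5, n_t)) + 100
  ds <- laminar_dataset(mag, TR = 4, grid = g)
  M <- intracortical_depth_matrix(ds)
  expect_equal(max(abs(unclass(M) - t(unclass(M)))), 0, tolerance = 1e-12)
  expect_equal(M[upper.tri(M)], rep(fisher_z_ceiling(), 10))

  # independent signals: mean |z| below the sampling bound
  mag2 <- array(rnorm(6 * 5 * n_t, mean = 100), dim = c(6, 5, n_t))
  M2 <- intracortical_depth_matrix(laminar_dataset(mag2, TR = 4, grid = g))
  expect_lt(mean(abs(M2[upper.tri(M2)])), 3 / sqrt(n_t - 3))

  # constant-depth units are skipped with a message
  mag3 <- mag2
  mag3[1, 2, ] <- 7
  expect_message(
    M3 <- intracortical_depth_matrix(laminar_dataset(mag3, TR = 4, grid = g)),
    "skipped 1"
  )
  expect_equal(attr(M3, "n_units_used"), 5L)
})

test_that("drainage inflates superficial coupling and VN deflates it", {
  g <- depth_grid()
  op <- build_leakage_operator(g, alpha = 0.3)
  ret <- b7_retentions()
  rest <- simulate_rest_run(g, roi_count = 5, n_volumes = 200, seed = 31)
  none <- intracortical_depth_matrix(rest)
  b0 <- intracortical_depth_matrix(drain_dataset(rest, op, 1, 1))
  vn <- intracortical_depth_matrix(drain_dataset(rest, op, ret$vein, ret$cap))
  sup <- which(g$mid > 2 / 3)
  blk <- function(M) mean(M[sup, sup][upper.tri(diag(length(sup)))])
  expect_gt(blk(b0), blk(none))
  expect_lt(blk(vn), blk(b0))
})

test_that("ROI-pair depth FC finds planted couplings and matches its oracle", {
  g <- small_grid(6)
  # A = B gives a symmetric matrix with the diagonal at the ceiling
  rest <- simulate_rest_run(g, roi_count = 2, n_volumes = 150, seed = 41)
  fc <- roi_pair_depth_fc(rest)
  self_m <- pair_matrix(fc, 1, 1)
  expect_equal(unclass(self_m), t(unclass(self_m)), tolerance = 1e-12)
  expect_equal(diag(self_m), rep(fisher_z_ceiling(), 6))
  # direct oracle for one cross cell
  a2 <- rest$magnitude[1, 2, ]
  b4 <- rest$magnitude[2, 4, ]
  cell <- dplyr::filter(fc, roi_a == 1, roi_b == 2, depth_a == 2, depth_b == 4)
  expect_equal(cell$z, fisher_z(cor(a2, b4)))
  # independent ROIs: everything within the sampling bound on average
  cross <- dplyr::filter(fc, roi_a == 1, roi_b == 2)
  expect_lt(mean(abs(cross$z)), 3 / sqrt(150 * (0.09 / 0.125)))
  expect_error(roi_pair_depth_fc(rest, rois = c(1, 9)), "absent.*9")
})

test_that("planted deep-A to middle-B coupling is localised by the matrix argmax", {
  g <- small_grid(6)
  n_ch <- 12
  S <- diag(n_ch)
  S[2, 6 + 3] <- S[6 + 3, 2] <- 0.6 # deep-A (layer 2) <-> middle-B (layer 3)
  hits <- 0
  for (k in 1:50) {
    rest <- simulate_rest_run(g, roi_count = 2, target_covariance = S,
                              n_volumes = 300, seed = 900 + k)
    fc <- roi_pair_depth_fc(rest)
    cross <- dplyr::filter(fc, roi_a == 1, roi_b == 2)
    top <- cross[which.max(cross$z), ]
    if (top$depth_a == 2 && top$depth_b == 3) hits <- hits + 1
  }
  expect_gte(hits / 50, 0.9)
})

test_that("group tests control FDR and detect planted shifts", {
  # all-zero matrices: nothing significant
  zeros <- replicate(5, matrix(0, 4, 4), simplify = FALSE)
  gt <- group_matrix_test(zeros)
  expect_equal(sum(gt$significant), 0L)
  expect_error(group_matrix_test(zeros[1:2]), "at least 3")

  # planted 0.5-z shift in one cell, N = 14, subject sd 0.1
  detect <- 0
  for (k in 1:100) {
    set.seed(600 + k)
    ms <- lapply(1:14, function(i) {
      m <- matrix(rnorm(36, sd = 0.1), 6, 6)
      m <- (m + t(m)) / 2
      m[2, 5] <- m[5, 2] <- 0.5 + rnorm(1, sd = 0.1)
      m
    })
    g2 <- group_matrix_test(ms)
    hit <- any(g2$significant & g2$row == 2 & g2$col == 5)
    detect <- detect + hit
  }
  expect_gte(detect / 100, 0.95)

  # q monotone non-decreasing in the p rank, q >= p
  expect_true(all(g2$q >= g2$p))
  ord <- order(g2$p)
  expect_true(all(diff(g2$q[ord]) >= -1e-15))
})

test_that("BH keeps the false-discovery fraction at bay under the global null", {
  n_sims <- 500
  fdp <- numeric(n_sims)
  for (k in seq_len(n_sims)) {
    set.seed(10000 + k)
    ms <- lapply(1:8, function(i) matrix(rnorm(25, sd = 0.2), 5, 5))
    g0 <- group_matrix_test(ms) # asymmetric: all off-diag cells tested
    fdp[k] <- mean(g0$significant)
  }
  expect_lte(mean(fdp), 0.05)
})

test_that("paired comparison flags VN-induced reduction and no spurious one", {
  g <- small_grid(8)
  op <- build_leakage_operator(g, alpha = 0.3)
  ret <- b7_retentions()
  mats_b0 <- list()
  mats_vn <- list()
  mats_null_a <- list()
  mats_null_b <- list()
  for (s in 1:10) {
    rest <- simulate_rest_run(g, roi_count = 4, n_volumes = 150,
                              seed = 1200 + s)
    mats_b0[[s]] <- intracortical_depth_matrix(drain_dataset(rest, op, 1, 1))
    mats_vn[[s]] <- intracortical_depth_matrix(
      drain_dataset(rest, op, ret$vein, ret$cap))
    # two independent sessions without any drainage in either
    mats_null_a[[s]] <- intracortical_depth_matrix(
      simulate_rest_run(g, roi_count = 4, n_volumes = 150, seed = 4200 + s))
    mats_null_b[[s]] <- intracortical_depth_matrix(
      simulate_rest_run(g, roi_count = 4, n_volumes = 150, seed = 5200 + s))
  }
  test <- group_matrix_test(mats_b0, mats_vn, mode = "paired")
  sup <- which(g$mid > 2 / 3)
  sup_cells <- test$row %in% sup & test$col %in% sup
  expect_true(any(test$significant[sup_cells] & test$estimate[sup_cells] > 0))

  # drainage absent in both conditions: no spurious difference survives FDR
  null_test <- group_matrix_test(mats_null_a, mats_null_b, mode = "paired")
  expect_equal(sum(null_test$significant), 0L)
})
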