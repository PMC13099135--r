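test_that("double-gamma HRF vanishes at 0, peaks at 1 within 4-7 s", {
  tt <- seq(0, 30, by = 0.01)
  h <- double_gamma_hrf(tt)
  expect_equal(h[1], 0)
  expect_equal(max(h), 1)
  t_peak <- tt[which.max(h)]
  expect_gte(t_peak, 4)
  expect_lte(t_peak, 7)
  expect_error(double_gamma_hrf(1, peak_delay = -1), "peak_delay")
})

test_that("neural profiles realise the requested depth structure", {
  g <- small_grid(20)
  flat <- make_neural_profile("flat", g)
  expect_equal(flat$amplitude, rep(1, 20))

  dp <- make_neural_profile("double_peak", g, peak_depths = c(0.25, 0.8))
  a <- dp$amplitude
  local_max <- which(diff(sign(diff(a))) == -2) + 1
  expect_length(local_max, 2)
  expect_equal(sort(dp$depth[local_max]),
               sort(g$mid[c(which.min(abs(g$mid - 0.25)),
                            which.min(abs(g$mid - 0.8)))]))

  sup <- make_neural_profile("superficial_only", g, peak_depths = 0.9)
  expect_gte(which.max(sup$amplitude), ceiling(2 * 20 / 3))
  expect_error(
    make_neural_profile("double_peak", g, peak_depths = c(0.2, 0.8),
                        amplitudes = 1:3),
    "match"
  )
  expect_error(make_neural_profile("double_peak", g, peak_depths = c(0.2, 5)),
               "depth range")
})

test_that("leakage operator is lower-triangular with identity at alpha = 0", {
  g <- small_grid(8)
  expect_equal(build_leakage_operator(g, 0)$K, diag(8))
  op <- build_leakage_operator(g, 0.4)
  K <- op$K
  # signal flows deep -> superficial only: nothing above the diagonal
  expect_true(all((K - diag(8))[upper.tri(K)] == 0))
  expect_true(all(K >= 0))
  # vein density increases linearly toward the surface, mean 1
  expect_equal(mean(op$vein_density), 1)
  expect_true(all(diff(op$vein_density) > 0))
  expect_equal(diff(op$vein_density), rep(diff(op$vein_density)[1], 7))
  expect_error(build_leakage_operator(g, -0.1), "alpha")
})

test_that("drainage biases flat profiles upward and spares the deepest layer", {
  g <- small_grid(8)
  op <- build_leakage_operator(g, 0.3)
  flat <- make_neural_profile("flat", g)
  out <- apply_drainage(flat, op)
  # direct matrix-vector oracle
  expect_equal(out$amplitude, (op$K %*% rep(1, 8))[, 1])
  expect_true(all(diff(out$amplitude) > 0))
  expect_equal(out$amplitude[1], flat$amplitude[1])
})

test_that("velocity-nulling retentions undo the superficial drainage bias", {
  g <- depth_grid()
  op <- build_leakage_operator(g, 0.3)
  p <- make_neural_profile("double_peak", g)
  ret <- b7_retentions()
  sup <- which.min(abs(g$mid - 0.8))
  deep <- which.min(abs(g$mid - 0.25))
  ratio <- function(prof) prof$amplitude[sup] / prof$amplitude[deep]

  no_vn <- apply_drainage(p, op, 1, 1)
  vn <- apply_drainage(p, op, ret$vein, ret$cap)
  # drainage inflates the superficial/deep peak ratio; VN reduces it
  expect_gt(ratio(no_vn), ratio(p))
  expect_lt(ratio(vn), ratio(no_vn))
  # vein retention 0+ recovers the capillary profile shape
  near0 <- apply_drainage(p, op, 1e-12, 1)
  expect_equal(near0$amplitude, p$amplitude, tolerance = 1e-9)
  # measured-vs-true correlation is strictly higher under VN
  expect_gt(cor(vn$amplitude, p$amplitude), cor(no_vn$amplitude, p$amplitude))
  expect_error(apply_drainage(p$amplitude[1:5], op), "layers")
})

test_that("task simulator is seed-deterministic and recovers truth noiselessly", {
  g <- small_grid(6)
  p <- make_neural_profile("double_peak", g, peak_depths = c(0.2, 0.8))
  des <- task_design(n_blocks = 3)
  a <- simulate_task_run(des, p, n_units = 3, noise_sd = 0.5,
                         phase_gain = 0.01, phase_noise_sd = 0.01, seed = 42)
  b <- simulate_task_run(des, p, n_units = 3, noise_sd = 0.5,
                         phase_gain = 0.01, phase_noise_sd = 0.01, seed = 42)
  expect_identical(a$magnitude, b$magnitude)
  expect_identical(a$phase, b$phase)
  c2 <- simulate_task_run(des, p, n_units = 3, noise_sd = 0.5, seed = 43)
  expect_false(identical(a$magnitude, c2$magnitude))

  clean <- simulate_task_run(des, p, n_units = 1, noise_sd = 0, seed = 1)
  prof <- suppressWarnings(glm_depth_profile(layer_timeseries(clean), des, g))
  expect_equal(prof$beta, p$amplitude, tolerance = 1e-6)
  expect_error(simulate_task_run(des, p, noise_sd = -1, seed = 1), "noise_sd")
  expect_error(simulate_task_run(des, p), "seed")
})

test_that("noisy GLM betas are unbiased against the simulated truth", {
  g <- small_grid(5)
  p <- make_neural_profile("double_peak", g, peak_depths = c(0.2, 0.8))
  des <- task_design(n_blocks = 4)
  n_rep <- 100
  betas <- ses <- matrix(NA_real_, n_rep, g$n_layers)
  for (k in seq_len(n_rep)) {
    run <- simulate_task_run(des, p, n_units = 1, noise_sd = 0.6, seed = 1000 + k)
    prof <- glm_depth_profile(layer_timeseries(run), des, g)
    betas[k, ] <- prof$beta
    ses[k, ] <- prof$se
  }
  bias <- colMeans(betas) - p$amplitude
  se_of_mean <- apply(betas, 2, sd) / sqrt(n_rep)
  # bias negligible against a single fit's own standard error
  expect_true(all(abs(bias) < 2 * colMeans(ses)))
  # joint unbiasedness: layer-wise z-scores consistent with zero true bias
  expect_lt(sum((bias / se_of_mean)^2), qchisq(0.999, df = g$n_layers))
})

test_that("rest simulator hits its target covariance and band", {
  g <- small_grid(4)
  # identity target: off-diagonal z stays within the sampling bound
  rest <- simulate_rest_run(g, roi_count = 2, n_volumes = 300, seed = 7)
  M <- intracortical_depth_matrix(rest)
  off <- M[upper.tri(M)]
  # effective dof is reduced by band-limiting: band fraction of n
  eff_dof <- 300 * (0.1 - 0.01) / 0.125
  expect_lt(mean(abs(off)), 3 / sqrt(eff_dof))

  # identical seeds give identical outputs
  r2 <- simulate_rest_run(g, roi_count = 2, n_volumes = 300, seed = 7)
  expect_identical(rest$magnitude, r2$magnitude)

  # non-PSD covariance rejected with the offending eigenvalue reported
  bad <- matrix(0.9, 8, 8); diag(bad) <- 1; bad[1, 2] <- bad[2, 1] <- -0.9
  expect_error(simulate_rest_run(g, roi_count = 2, target_covariance = bad,
                                 seed = 1),
               "eigenvalue")
})

test_that("rest simulator recovers a planted r = 0.6 coupling across seeds", {
  g <- depth_grid(n_layers = 2)
  S <- matrix(c(1, 0.6, 0.6, 1), 2)
  n_seeds <- 200
  z <- numeric(n_seeds)
  for (k in seq_len(n_seeds)) {
    rest <- simulate_rest_run(g, roi_count = 1, target_covariance = S,
                              n_volumes = 300, TR = 4, seed = k)
    z[k] <- fisher_z(cor(rest$magnitude[1, 1, ], rest$magnitude[1, 2, ]))
  }
  expect_gte(mean(abs(z - atanh(0.6)) <= 0.15), 0.95)
})

test_that("empirical rest correlations converge to the target with run length", {
  g <- small_grid(3)
  S <- block_cov(3, 2, 0.5)
  frob <- function(nv) {
    d <- numeric(20)
    for (k in 1:20) {
      rest <- simulate_rest_run(g, roi_count = 1, target_covariance = S,
                                n_volumes = nv, seed = 300 + k)
      emp <- cor(t(rest$magnitude[1, , ]))
      d[k] <- sqrt(sum((emp - S)^2))
    }
    mean(d)
  }
  expect_lt(frob(400), frob(50))
})
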