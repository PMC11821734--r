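test_that("objective is zero iff the curves interpolate the data", {
  lay <- ascending_membrane()
  ds <- gen_biaxial(lay, noise = "none")
  expect_equal(biaxial_objective(ds, c(61.31, 2.09)), 0)
  expect_gt(biaxial_objective(ds, c(67, 2.09)), 0)
  expect_gt(biaxial_objective(ds, c(61.31, 2.3)), 0)
  # single point composed from the forward model
  tt <- membrane_tensions_single(0.2, 0.2, lay)
  d1 <- data.frame(protocol = "p", E11 = 0.2, E22 = 0.2, E12 = 0,
                   T11 = tt$T11, T22 = tt$T22, T12 = 0)
  ds1 <- biaxial_dataset(rbind(d1, d1, d1), 0.002)
  expect_equal(biaxial_objective(ds1, c(61.31, 2.09)), 0, tolerance = 1e-12)
  expect_error(biaxial_objective(ds, c(-1, 2)), "positive")
})

test_that("objective is invariant to data shuffling", {
  lay <- ascending_membrane()
  ds <- gen_biaxial(lay, noise = "multiplicative", sigma = 0.1, seed = 3)
  set.seed(4)
  perm <- sample(nrow(ds$data))
  ds_shuf <- biaxial_dataset(ds$data[perm, ], ds$sample_thickness)
  expect_equal(biaxial_objective(ds_shuf, c(55, 2.2)),
               biaxial_objective(ds, c(55, 2.2)), tolerance = 1e-12)
})

test_that("one-layer fit recovers the generating parameters", {
  ref <- porcine_reference_data()$one_layer
  # noiseless nine-protocol data from each region's tabulated truth
  for (i in seq_len(nrow(ref))) {
    truth <- c(ref$mu[i], ref$beta[i])
    lay <- membrane_layer_params(truth[1], truth[2], 0.002)
    ds <- gen_biaxial(lay, noise = "none")
    fit <- fit_one_layer(ds)
    expect_lt(max(abs(fit$params / truth - 1)), 1e-3)
    expect_equal(fit$r2_fd, 1, tolerance = 1e-8)
    expect_equal(fit$r2_xd, 1, tolerance = 1e-8)
  }
  expect_error(
    fit_one_layer(biaxial_dataset(
      data.frame(protocol = "p", E11 = 0.1, E22 = 0.1, E12 = 0,
                 T11 = 1, T22 = 1, T12 = 0), 0.002)),
    "independent strain states")
})

test_that("noisy recovery is within tolerance and unbiased across seeds", {
  truth <- c(61.31, 2.09)
  lay <- membrane_layer_params(truth[1], truth[2], 0.002)
  rel_err <- matrix(NA_real_, 20, 2)
  for (s in 1:20) {
    ds <- gen_biaxial(lay, noise = "multiplicative", sigma = 0.05, seed = s)
    fit <- fit_one_layer(ds)
    rel_err[s, ] <- fit$params / truth - 1
    expect_lt(max(abs(rel_err[s, ])), 0.10)
  }
  expect_lt(max(abs(colMeans(rel_err))), 0.05)
})

test_that("two-layer fit recovers a bilayer truth and splits tensions", {
  H_M <- 0.00175; H_A <- 0.00025
  r <- 0.5
  mu_M <- 40; beta_M <- 2.7; beta_A <- 1.4
  mu_A <- r * mu_M  # membrane-scale ratio (default)
  med <- membrane_layer_params(mu_M, beta_M, H_M)
  adv <- membrane_layer_params(mu_A, beta_A, H_A)
  ds <- gen_biaxial(list(media = med, adventitia = adv), noise = "none")
  fit <- fit_two_layer(ds, H_M, H_A, r)
  expect_lt(max(abs(fit$params / c(mu_M, beta_M, beta_A) - 1)), 0.01)
  expect_false(fit$beta_A_boundary)
  # split property: layer tensions sum to the fitted total at every point
  tm <- membrane_tensions_single(ds$data$E11, ds$data$E22, fit$media)
  ta <- membrane_tensions_single(ds$data$E11, ds$data$E22, fit$adventitia)
  expect_equal(tm$T11 + ta$T11, fit$predicted$T11, tolerance = 1e-12)
  expect_error(fit_two_layer(ds, H_M, H_A * 2, r), "sample thickness")
})

test_that("r = 1 with equal beta degenerates to a one-layer response", {
  lay <- membrane_layer_params(60, 2.0, 0.002)
  ds <- gen_biaxial(lay, noise = "none")
  # r = 1 with equal beta: layers share the membrane modulus, so
  # mu_M + mu_A = 2 mu_M must equal the one-layer modulus
  H_M <- 0.0015; H_A <- 0.0005
  obj <- biaxial_objective(ds, c(30, 2.0, 2.0), layers = 2,
                           r = 1, H_M = H_M, H_A = H_A)
  expect_equal(obj, 0, tolerance = 1e-9)
})

test_that("two-layer r sweep on one-layer data shows the identifiability
           degeneracy", {
  lay <- membrane_layer_params(60, 2.0, 0.002)
  ds <- gen_biaxial(lay, noise = "multiplicative", sigma = 0.02, seed = 9)
  H_M <- 0.0015; H_A <- 0.0005
  objs <- vapply(c(0.5, 1, 2), function(r)
    fit_two_layer(ds, H_M, H_A, r)$objective_value, numeric(1))
  expect_lt(diff(range(objs)) / min(objs), 0.05)
})

test_that("Pearson R^2 behaves as a squared correlation", {
  set.seed(8)
  exp_d <- data.frame(T11 = stats::runif(50, 0, 10),
                      T22 = stats::runif(50, 0, 10))
  expect_equal(unname(pearson_r2_by_direction(exp_d, exp_d)),
               c(1, 1))
  aff <- data.frame(T11 = 3 * exp_d$T11 + 2, T22 = 0.5 * exp_d$T22 - 1)
  expect_equal(unname(pearson_r2_by_direction(aff, exp_d)), c(1, 1))
  noise <- data.frame(T11 = stats::rnorm(5000), T22 = stats::rnorm(5000))
  sig <- data.frame(T11 = stats::runif(5000), T22 = stats::runif(5000))
  expect_lt(max(pearson_r2_by_direction(noise, sig)), 0.01)
  expect_error(pearson_r2_by_direction(exp_d[1:2, ], exp_d[1:2, ]),
               ">= 3")
  flat <- data.frame(T11 = rep(1, 10), T22 = rep(2, 10))
  expect_error(pearson_r2_by_direction(flat, exp_d[1:10, ]),
               "zero variance")
})

test_that("bootstrap confidence intervals are seeded and scale with noise", {
  lay <- ascending_membrane()
  # noiseless data: CI halfwidths collapse
  ds0 <- gen_biaxial(lay, noise = "none", E_step = 0.05)
  fit0 <- fit_one_layer(ds0)
  ci0 <- confidence_intervals(ds0, fit0, n_boot = 60, seed = 1)
  expect_lt(max(ci0 / c(61.31, 2.09)), 1e-4)
  # determinism under the seed
  ds <- gen_biaxial(lay, noise = "additive", sigma = 1, seed = 2,
                    E_step = 0.05)
  fit <- fit_one_layer(ds)
  ci_a <- confidence_intervals(ds, fit, n_boot = 60, seed = 7)
  ci_b <- confidence_intervals(ds, fit, n_boot = 60, seed = 7)
  expect_identical(ci_a, ci_b)
  # doubling the noise SD roughly doubles the halfwidths
  ds2 <- gen_biaxial(lay, noise = "additive", sigma = 2, seed = 2,
                     E_step = 0.05)
  fit2 <- fit_one_layer(ds2)
  ci2 <- confidence_intervals(ds2, fit2, n_boot = 60, seed = 7)
  ratio <- ci2 / ci_a
  expect_true(all(ratio > 1.2 & ratio < 3.5))
  expect_warning(confidence_intervals(ds, fit, n_boot = 20, seed = 1),
                 "n_boot")
})

test_that("fit results serialize to JSON", {
  lay <- ascending_membrane()
  ds <- gen_biaxial(lay, noise = "none", E_step = 0.1)
  fit <- fit_one_layer(ds)
  path <- tempfile(fileext = ".json")
  on.exit(unlink(path))
  write_fit_json(fit, path, ci = c(mu = 1.4, beta = 0.06))
  x <- jsonlite::read_json(path)
  expect_equal(x$layers, 1)
  expect_equal(x$params$mu, 61.31, tolerance = 1e-4)
  expect_equal(x$ci_halfwidth$beta, 0.06)
})
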