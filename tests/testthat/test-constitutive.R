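test_that("Donnan pressure matches the closed form and its limits", {
  env <- donnan_environment()  # T = 298.15 K, 300 mosM, phi = 1
  expect_equal(donnan_pressure(0, env), 0)
  # direct evaluation at the innermost ascending FCD magnitude
  expect_equal(donnan_pressure(35.3, env),
               8.314462618 * 298.15 * (sqrt(35.3^2 + 300^2) - 300),
               tolerance = 1e-12)
  expect_equal(donnan_pressure(35.3, env), 5130.64, tolerance = 1e-4)
  # van 't Hoff limit for a dilute bath
  env0 <- donnan_environment(bath_osm = 0)
  expect_equal(donnan_pressure(12, env0), 8.314462618 * 298.15 * 12,
               tolerance = 1e-12)
  # nonnegative, monotone and convex in cF
  cf <- seq(0, 200, by = 0.5)
  p <- donnan_pressure(cf, env)
  expect_true(all(p >= 0))
  expect_true(all(diff(p) > 0))
  expect_true(all(diff(diff(p)) > -1e-9))
  expect_error(donnan_environment(T_K = -1), "invalid environment")
  expect_error(donnan_environment(bath_osm = -5), "invalid environment")
})

test_that("current FCD follows the fluid-fraction dilution rule", {
  env <- donnan_environment()
  expect_equal(fcd_current(35.3, 1, env), 35.3)
  expect_equal(fcd_current(10, 1.3, env), 0.7 * 10, tolerance = 1e-14)
  expect_equal(fcd_current(10, 1e9, env), 0, tolerance = 1e-6)
  # exact algebraic identity cF * (J - 1 + phi0) = c0F * phi0
  for (J in c(0.8, 1, 1.1, 1.7, 3)) {
    expect_equal(fcd_current(24, J, env) * (J - 1 + 0.7), 24 * 0.7,
                 tolerance = 1e-14)
  }
  # strictly decreasing in J
  J <- seq(0.5, 2, by = 0.01)
  expect_true(all(diff(fcd_current(30, J, env)) < 0))
  expect_error(fcd_current(10, 0.2, env), "degenerate compaction")
})

test_that("Holmes-Mow energy is zero at identity and isotropic", {
  mat <- holmes_mow_material(30660, 2.09)
  expect_equal(hm_energy(deformation_state(diag(3)), mat), 0)
  # hand evaluation at an isotropic stretch
  Fh <- 1.1 * diag(3)
  Q <- 2.09 * (3 * 1.21 - 3 - 2 * log(1.1^3))
  expect_equal(hm_energy(deformation_state(Fh), mat),
               30660 / (2 * 2.09) * (exp(Q) - 1), tolerance = 1e-12)
  set.seed(11)
  for (i in 1:10) {
    F <- random_F()
    R <- random_rotation()
    expect_equal(hm_energy(deformation_state(R %*% F), mat),
                 hm_energy(deformation_state(F), mat), tolerance = 1e-10)
  }
})

test_that("Cauchy stress equals the finite-difference derivative of the energy", {
  set.seed(21)
  for (mat in list(holmes_mow_material(30660, 2.09),
                   holmes_mow_material(20000, 1.3, lam = 8000))) {
    worst <- 0
    for (i in 1:100) {
      F <- random_F(0.7, 1.5)
      sig <- hm_cauchy_stress(deformation_state(F), mat)
      sig_fd <- fd_cauchy_stress(F, mat)
      worst <- max(worst, max(abs(sig - sig_fd)) / max(abs(sig), 1))
    }
    expect_lt(worst, 1e-6)
  }
})

test_that("lambda = 0 stress reduces to the closed form (mu/J) e^Q (B - I)", {
  mat <- holmes_mow_material(30660, 2.09)
  st <- deformation_state(1.1 * diag(3))
  expect_equal(hm_cauchy_stress(st, mat)[1, 1], 5462.4, tolerance = 1e-4)
  set.seed(31)
  for (i in 1:25) {
    st <- deformation_state(random_F())
    Q <- mat$beta * (sum(diag(st$C)) - 3 - 2 * log(st$J))
    closed <- mat$mu_vol / st$J * exp(Q) * (st$B - diag(3))
    expect_equal(hm_cauchy_stress(st, mat), closed, tolerance = 1e-12)
  }
  # objectivity: sigma(RF) = R sigma(F) R^T
  for (i in 1:10) {
    F <- random_F(); R <- random_rotation()
    s1 <- hm_cauchy_stress(deformation_state(R %*% F), mat)
    s2 <- R %*% hm_cauchy_stress(deformation_state(F), mat) %*% t(R)
    expect_equal(s1, s2, tolerance = 1e-9)
  }
  expect_equal(hm_cauchy_stress(deformation_state(diag(3)), mat),
               matrix(0, 3, 3))
})

test_that("mixture stress composes pressure and elastic parts", {
  env <- donnan_environment()
  mat <- holmes_mow_material(30660, 2.09)
  st <- deformation_state(diag(3))
  ms <- mixture_stress(st, mat, 35.3, env)
  expect_equal(ms$sigma_total, -donnan_pressure(35.3, env) * diag(3))
  # zero FCD: total equals elastic
  st2 <- deformation_state(random_F())
  ms2 <- mixture_stress(st2, mat, 0, env)
  expect_equal(ms2$sigma_total, ms2$sigma_e)
  # trace identity
  ms3 <- mixture_stress(st2, mat, 20, env)
  expect_equal(sum(diag(ms3$sigma_total)),
               sum(diag(ms3$sigma_e)) - 3 * ms3$pi, tolerance = 1e-9)
})

test_that("membrane tensions match the derivative of the reduced energy", {
  lay <- ascending_membrane()
  expect_equal(unlist(membrane_tensions_single(0, 0, lay)),
               c(T11 = 0, T22 = 0, T12 = 0))
  expect_equal(membrane_tensions_single(0.2, 0.2, lay)$T11, 74.5175,
               tolerance = 1e-5)
  set.seed(41)
  worst <- 0
  for (i in 1:100) {
    E11 <- stats::runif(1, -0.2, 0.6)
    E22 <- stats::runif(1, -0.2, 0.6)
    tt <- membrane_tensions_single(E11, E22, lay)
    fd <- fd_membrane_tensions(E11, E22, lay)
    worst <- max(worst,
                 abs(tt$T11 - fd[["T11"]]) / max(abs(fd[["T11"]]), 1),
                 abs(tt$T22 - fd[["T22"]]) / max(abs(fd[["T22"]]), 1))
  }
  expect_lt(worst, 1e-6)
  # equibiaxial symmetry is exact
  tt <- membrane_tensions_single(0.37, 0.37, lay)
  expect_identical(tt$T11, tt$T22)
  expect_error(membrane_tensions_single(-0.6, 0.1, lay), "invalid strain")
})

test_that("bilayer tensions are the sum of the layer tensions", {
  med <- membrane_layer_params(50, 2.0, 0.0015)
  adv <- membrane_layer_params(20, 3.1, 0.0005)
  E11 <- c(0, 0.1, 0.3, 0.45)
  E22 <- c(0, 0.25, 0.05, 0.45)
  tb <- membrane_tensions_bilayer(E11, E22, med, adv)
  t1 <- membrane_tensions_single(E11, E22, med)
  t2 <- membrane_tensions_single(E11, E22, adv)
  expect_equal(tb$T11, t1$T11 + t2$T11)
  expect_equal(tb$T22, t1$T22 + t2$T22)
  expect_equal(tb$T12, rep(0, 4))
  # equal beta degenerates to a single layer with summed modulus
  adv2 <- membrane_layer_params(20, 2.0, 0.0005)
  tb2 <- membrane_tensions_bilayer(E11, E22, med, adv2)
  merged <- membrane_layer_params(70, 2.0, 0.002)
  expect_equal(tb2$T11, membrane_tensions_single(E11, E22, merged)$T11,
               tolerance = 1e-12)
})

test_that("material JSON files round-trip", {
  path <- tempfile(fileext = ".json")
  on.exit(unlink(path))
  layers <- list(membrane_layer_params(55.65, 2.0, 0.00175),
                 membrane_layer_params(5.565, 2.77, 0.00025))
  env <- donnan_environment(T_K = 310)
  write_material_json("ascending", layers, env, path)
  back <- read_material_json(path)
  expect_equal(back$region, "ascending")
  expect_equal(back$layers[[1]]$mu_memb, 55.65)
  expect_equal(back$layers[[2]]$beta, 2.77)
  expect_equal(back$donnan$T_K, 310)
  expect_equal(back$donnan$bath_osm, 300)
})
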