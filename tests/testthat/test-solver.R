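test_that("zero FCD returns the reference configuration exactly", {
  mesh <- build_quarter_ring(porcine_ring_geometry("ascending"), c(4, 10, 1))
  fields <- assign_fields(mesh, fcd_domain_profile("z", rep(0, 8)),
                          ascending_volumetric())
  sol <- solve_swelling_equilibrium(mesh, fields,
                                    config = simulation_config(ramp_steps = 1))
  expect_lt(max(abs(sol$u)),
            1e-10 * porcine_ring_geometry("ascending")$outer_diameter / 2)
  expect_equal(sol$opening_angle, 0)
})

test_that("uniform FCD with a homogeneous matrix swells without bending", {
  geom <- porcine_ring_geometry("ascending")
  mesh <- build_quarter_ring(geom, c(4, 10, 1))
  env <- donnan_environment()
  mat <- ascending_volumetric()
  f_uni <- assign_fields(mesh, fcd_domain_profile("u", rep(-20, 8)), mat)
  sol_uni <- solve_swelling_equilibrium(mesh, f_uni, env, quick_config())
  expect_lt(abs(sol_uni$opening_angle), 0.5)
  # J is near-uniform and matches the scalar free-swelling equilibrium
  J_ref <- uniform_swelling_J(mat$mu_vol, mat$beta, 20, env)
  expect_lt(max(abs(sol_uni$elem_J / J_ref - 1)), 1e-6)
  # interior stress is a tiny fraction of the graded case's peak stress
  f_grad <- assign_fields(mesh, porcine_fcd("ascending"), mat)
  sol_grad <- solve_swelling_equilibrium(mesh, f_grad, env, quick_config())
  expect_lt(max(abs(sol_uni$elem_sigma)), 0.01 * max(abs(sol_grad$elem_sigma)))
})

test_that("a single free element reproduces the scalar swelling equilibrium", {
  env <- donnan_environment()
  J_fe <- single_element_swelling(30655, 2.09, 35.3, env)
  J_ref <- uniform_swelling_J(30655, 2.09, 35.3, env)
  expect_lt(abs(J_fe / J_ref - 1), 1e-6)
})

test_that("the swelling solve is deterministic and in global equilibrium", {
  mesh <- build_quarter_ring(porcine_ring_geometry("descending"), c(4, 8, 1))
  fields <- assign_fields(mesh, porcine_fcd("descending"),
                          ascending_volumetric())
  s1 <- solve_swelling_equilibrium(mesh, fields, config = quick_config())
  s2 <- solve_swelling_equilibrium(mesh, fields, config = quick_config())
  expect_identical(s1$u, s2$u)
  # converged free residual
  expect_lt(s1$residual_norm, 1e-6)
  # reactions balance: internal forces sum to zero componentwise
  env <- donnan_environment()
  sys <- gagring:::.hex20_system(mesh$nodes, mesh$conn, s1$u,
                                 fields$mu, fields$beta, fields$c0F,
                                 env$R_gas * env$T_K, env$bath_osm, 0.7,
                                 FALSE, FALSE)
  fmat <- matrix(sys$f, ncol = 3, byrow = TRUE)
  expect_lt(max(abs(colSums(fmat))), 1e-10 * max(abs(sys$f)) + 1e-14)
})

test_that("opening angle measurement follows the opened-sector convention", {
  geom <- porcine_ring_geometry("ascending")
  mesh <- build_quarter_ring(geom, c(2, 8, 1))
  rad <- sqrt(rowSums(mesh$nodes[, 1:2]^2))
  th <- atan2(mesh$nodes[, 2], mesh$nodes[, 1])

  # closed ring: no deformation
  expect_equal(measure_opening_angle(list(mesh = mesh,
                                          u = 0 * mesh$nodes)), 0)

  # circular sector with central half-angle k*pi: chord construction must
  # give 180 (1 - k) degrees, e.g. 30 deg at k = 5/6
  for (alpha_true in c(30, 90, -20)) {
    k <- 1 - alpha_true / 180
    def <- cbind(rad * cos(k * th), rad * sin(k * th), mesh$nodes[, 3])
    got <- measure_opening_angle(list(mesh = mesh, u = def - mesh$nodes))
    expect_equal(got, alpha_true, tolerance = 1e-10)
  }

  # ring straightened into a strip perpendicular to the symmetry plane
  rbar <- mean(range(rad))
  def <- cbind(rad, rbar * th, mesh$nodes[, 3])
  got <- measure_opening_angle(list(mesh = mesh, u = def - mesh$nodes))
  expect_equal(got, 180, tolerance = 1e-10)
})

test_that("solver rejects materials with nonzero first Lame parameter", {
  mesh <- build_quarter_ring(porcine_ring_geometry("arch"), c(2, 4, 1))
  fields <- assign_fields(mesh, porcine_fcd("arch"),
                          holmes_mow_material(30000, 2, lam = 1000))
  expect_error(solve_swelling_equilibrium(mesh, fields), "lambda = 0")
})

test_that("reference one-layer rings swell open to positive angles", {
  # coarse-mesh spot check of the end-to-end pipeline (the acceptance tests
  # run the reference resolutions)
  sol <- simulate_opening_angle("ascending", layers = 1,
                                resolution = c(4, 10, 1))
  expect_gt(sol$opening_angle, 20)
  expect_lt(sol$opening_angle, 60)
  expect_true(all(sol$elem_J > 1))
})
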