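test_that("quarter-ring mesh matches the reference geometry", {
  geom <- porcine_ring_geometry("ascending")
  mesh <- build_quarter_ring(geom)  # default 8 x 20 x 8
  expect_equal(nrow(mesh$conn), 1280L)
  rad <- sqrt(rowSums(mesh$nodes[, 1:2]^2))
  # inner radius 25.5/2 - 2.68 = 10.07 mm
  expect_equal(min(rad), 0.01007, tolerance = 1e-10)
  expect_equal(max(rad), 0.01275, tolerance = 1e-10)
  expect_equal(max(mesh$nodes[, 3]), 4.5e-3 / 2, tolerance = 1e-12)
  expect_true(all(mesh$nodes[, 2] > -1e-15))
})

test_that("mesh volume matches the analytic half-annulus half-height volume", {
  geom <- porcine_ring_geometry("arch")
  mesh <- build_quarter_ring(geom, c(8, 20, 2))
  Ro <- geom$outer_diameter / 2
  Ri <- Ro - geom$thickness
  v_exact <- pi / 2 * (Ro^2 - Ri^2) * geom$height / 2
  expect_lt(abs(sum(mesh_element_volumes(mesh)) / v_exact - 1), 1e-3)
  # all element Jacobians positive
  expect_true(all(mesh_element_volumes(mesh) > 0))
})

test_that("node sets and boundary conditions are consistent", {
  mesh <- build_quarter_ring(porcine_ring_geometry("descending"),
                             c(4, 8, 2))
  s <- mesh$sets
  # plane A is the y = 0, x > 0 face; cut face has x < 0
  expect_true(all(abs(mesh$nodes[s$planeA, 2]) < 1e-15))
  expect_true(all(mesh$nodes[s$planeA, 1] > 0))
  expect_true(all(mesh$nodes[s$cut_face, 1] < 0))
  expect_true(all(abs(mesh$nodes[s$planeB, 3]) < 1e-15))
  expect_true(s$fixed_node %in% s$planeA && s$fixed_node %in% s$planeB)

  bc <- apply_boundary_conditions(mesh)
  expect_equal(length(bc$fixed_dofs),
               length(s$planeA) + length(s$planeB) + 1L)
  # the cut face is traction-free: none of its nodes carries an in-plane
  # (x or y) constraint; only its mid-height edge shares the z-symmetry of
  # plane B
  in_plane <- bc$constraints$node[bc$constraints$comp != 3L]
  expect_false(any(s$cut_face %in% in_plane))
})

test_that("constrained tangent at identity has no rigid-body modes", {
  mesh <- build_quarter_ring(porcine_ring_geometry("ascending"),
                             c(2, 4, 1))
  mat <- ascending_volumetric()
  fields <- assign_fields(mesh, fcd_domain_profile("z", rep(0, 8)), mat)
  env <- donnan_environment()
  sys <- gagring:::.hex20_system(mesh$nodes, mesh$conn,
                                 matrix(0, nrow(mesh$nodes), 3),
                                 fields$mu, fields$beta, fields$c0F,
                                 env$R_gas * env$T_K, env$bath_osm, 0.7,
                                 TRUE, FALSE)
  bc <- apply_boundary_conditions(mesh)
  free <- setdiff(seq_len(3L * nrow(mesh$nodes)), bc$fixed_dofs)
  K <- as.matrix(sys$K[free, free])
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), 0)
  # unconstrained tangent has exactly 6 near-zero modes
  K_full <- as.matrix(sys$K)
  ev_full <- eigen(K_full, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(sum(abs(ev_full) < 1e-7 * max(ev_full)), 6L)
})

test_that("field assignment maps FCD domains and layer split by radius", {
  mesh <- build_quarter_ring(porcine_ring_geometry("ascending"),
                             c(8, 4, 1))
  fcd <- porcine_fcd("ascending")
  # one layer: all media, FCD by radial index
  f1 <- assign_fields(mesh, fcd, ascending_volumetric())
  expect_true(all(f1$layer == "media"))
  expect_equal(f1$c0F[mesh$elem_radial == 1], rep(35.3, 4))
  expect_equal(f1$c0F[mesh$elem_radial == 8], rep(15.0, 4))
  # two layers, ascending: radial elements 1-7 media, 8 adventitia
  mats <- list(media = holmes_mow_material(30000, 2),
               adventitia = holmes_mow_material(3000, 2.8))
  f2 <- assign_fields(mesh, fcd, mats, n_media_elements = 7)
  expect_true(all(f2$layer[mesh$elem_radial <= 7] == "media"))
  expect_true(all(f2$layer[mesh$elem_radial == 8] == "adventitia"))
  expect_equal(unique(f2$mu[mesh$elem_radial == 8]), 3000)
  # descending split: 5 media + 3 adventitia
  f3 <- assign_fields(mesh, porcine_fcd("descending"), mats,
                      n_media_elements = 5)
  expect_equal(sum(f3$layer == "adventitia") / 4L, 3L)
  # refined radial resolution maps two elements per domain
  mesh16 <- build_quarter_ring(porcine_ring_geometry("ascending"),
                               c(16, 2, 1))
  f4 <- assign_fields(mesh16, fcd, ascending_volumetric())
  expect_equal(f4$domain[mesh16$elem_radial == 3],
               rep(2L, 2))
  expect_error(assign_fields(mesh, fcd, mats, n_media_elements = 9),
               "n_media_elements")
})
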