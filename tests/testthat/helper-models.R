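# shared fixtures built in code

ascending_membrane <- function() membrane_layer_params(61.31, 2.09, 0.002)

ascending_volumetric <- function() {
  membrane_to_volumetric(ascending_membrane())
}

# random deformation gradient with J in (J_lo, J_hi); rejection sampled
random_F <- function(J_lo = 0.7, J_hi = 1.5, spread = 0.15) {
  repeat {
    F <- diag(3) + matrix(stats::rnorm(9, 0, spread), 3, 3)
    J <- det(F)
    if (J > J_lo && J < J_hi) return(F)
  }
}

random_rotation <- function() {
  qr_d <- qr(matrix(stats::rnorm(9), 3, 3))
  R <- qr.Q(qr_d)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

# central finite difference of the energy wrt F -> first P-K stress,
# pushed to a Cauchy stress; the independent oracle for hm_cauchy_stress
fd_cauchy_stress <- function(F, mat, h = 1e-6) {
  P <- matrix(0, 3, 3)
  for (a in 1:3) for (b in 1:3) {
    Fp <- F; Fp[a, b] <- Fp[a, b] + h
    Fm <- F; Fm[a, b] <- Fm[a, b] - h
    P[a, b] <- (hm_energy(deformation_state(Fp), mat) -
                  hm_energy(deformation_state(Fm), mat)) / (2 * h)
  }
  P %*% t(F) / det(F)
}

# reduced membrane energy w = H * What(E11, E22); oracle for the tension
# formulas via central differences
reduced_membrane_energy <- function(E11, E22, layer) {
  Delta <- (2 * E11 + 1) * (2 * E22 + 1)
  Q <- 2 * layer$beta * (E11 + E22 + 0.5 * (1 / Delta - 1))
  layer$mu_memb / (2 * layer$beta) * (exp(Q) - 1)
}

fd_membrane_tensions <- function(E11, E22, layer, h = 1e-7) {
  c(T11 = (reduced_membrane_energy(E11 + h, E22, layer) -
             reduced_membrane_energy(E11 - h, E22, layer)) / (2 * h),
    T22 = (reduced_membrane_energy(E11, E22 + h, layer) -
             reduced_membrane_energy(E11, E22 - h, layer)) / (2 * h))
}

# scalar equilibrium of a freely swelling homogeneous block:
# (mu/J) e^Q (J^(2/3) - 1) = pi(J); oracle for the single-element solve
uniform_swelling_J <- function(mu, beta, c0F, env) {
  f <- function(J) {
    l2 <- J^(2 / 3)
    Q <- beta * (3 * l2 - 3 - 2 * log(J))
    mu / J * exp(Q) * (l2 - 1) -
      donnan_pressure(abs(fcd_current(c0F, J, env)), env)
  }
  stats::uniroot(f, c(1 + 1e-12, 3), tol = 1e-15)$root
}

# single free 20-node hex (unit cube, edge L) under uniform FCD with
# statically determinate supports; returns the solved mean J
single_element_swelling <- function(mu, beta, c0F, env, L = 1e-3) {
  grid_pts <- expand.grid(i = 0:2, j = 0:2, k = 0:2)
  keep <- rowSums(cbind(grid_pts$i %% 2, grid_pts$j %% 2,
                        grid_pts$k %% 2)) <= 1
  gp <- grid_pts[keep, ]
  gp <- gp[order(gp$k, gp$j, gp$i), ]
  nodes <- as.matrix(gp[, c("i", "j", "k")]) * L / 2
  id_of <- function(i, j, k) which(gp$i == i & gp$j == j & gp$k == k)
  loc <- rbind(c(0, 0, 0), c(2, 0, 0), c(2, 2, 0), c(0, 2, 0),
               c(0, 0, 2), c(2, 0, 2), c(2, 2, 2), c(0, 2, 2),
               c(1, 0, 0), c(2, 1, 0), c(1, 2, 0), c(0, 1, 0),
               c(1, 0, 2), c(2, 1, 2), c(1, 2, 2), c(0, 1, 2),
               c(0, 0, 1), c(2, 0, 1), c(2, 2, 1), c(0, 2, 1))
  conn <- matrix(vapply(1:20, function(a)
    id_of(loc[a, 1], loc[a, 2], loc[a, 3]), integer(1)), 1, 20)
  mesh <- structure(list(nodes = unname(nodes), conn = conn,
                         elem_radial = 1L, elem_circ = 1L, elem_axial = 1L,
                         resolution = c(nr = 1L, nc = 1L, nz = 1L),
                         sets = list()),
                    class = "quarter_ring_mesh")
  dof <- function(n, c) 3L * (n - 1L) + c
  bc <- list(fixed_dofs = sort(c(dof(id_of(0, 0, 0), 1:3),
                                 dof(id_of(2, 0, 0), 2:3),
                                 dof(id_of(0, 2, 0), 3))))
  fields <- list(mu = mu, beta = beta, lam = 0, c0F = c0F,
                 layer = "media", domain = 1L)
  sol <- solve_swelling_equilibrium(
    mesh, fields, env,
    simulation_config(ramp_steps = 5, newton_tol_rel = 1e-12), bc = bc)
  sol$elem_J
}

# small, fast solver settings for tests
quick_config <- function() simulation_config(ramp_steps = 5)
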