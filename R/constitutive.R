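#' Holmes-Mow solid-matrix material (volumetric scale)
#'
#' Isotropic exponential hyperelastic law widely used for cartilage and other
#' hydrated soft tissues. The strain energy is
#' \deqn{W = \frac{c}{2}(e^Q - 1), \quad c = \frac{\lambda + 2\mu}{2\beta},}
#' \deqn{Q = \frac{\beta}{\lambda+2\mu}\left[(2\mu-\lambda)(I_1-3) +
#'   \lambda(I_2-3) - (\lambda+2\mu)\ln J^2\right],}
#' with \eqn{I_1, I_2} the invariants of the right Cauchy-Green tensor and
#' \eqn{J = \det F}. Setting \code{lam = 0} gives a zero Poisson's ratio,
#' appropriate for the drained solid skeleton of a biphasic mixture; all ring
#' simulations in this package use \code{lam = 0}.
#'
#' @param mu_vol Shear-like modulus \eqn{\mu} in Pa (> 0).
#' @param beta Dimensionless exponential stiffening coefficient (> 0).
#' @param lam First Lame parameter \eqn{\lambda} in Pa (default 0).
#' @return An object of class \code{holmes_mow_material}.
#' @seealso [membrane_layer_params()], [hm_energy()], [hm_cauchy_stress()]
#' @export
holmes_mow_material <- function(mu_vol, beta, lam = 0) {
  stopifnot(is.numeric(mu_vol), length(mu_vol) == 1L, mu_vol > 0)
  stopifnot(is.numeric(beta), length(beta) == 1L, beta > 0)
  stopifnot(is.numeric(lam), length(lam) == 1L, lam >= 0)
  structure(list(mu_vol = mu_vol, beta = beta, lam = lam),
            class = "holmes_mow_material")
}

#' Holmes-Mow membrane layer parameters (tension scale)
#'
#' Parameters of the incompressibility-reduced Holmes-Mow membrane energy
#' \eqn{w = H\hat W} used to model planar biaxial tension data. \code{mu_memb}
#' is the membrane modulus in N/m (the volumetric modulus integrated through
#' the undeformed layer thickness \code{thickness_ref}).
#'
#' @param mu_memb Membrane modulus in N/m (> 0).
#' @param beta Dimensionless stiffening coefficient (> 0).
#' @param thickness_ref Undeformed layer thickness H in m (> 0).
#' @return An object of class \code{membrane_layer_params}.
#' @export
membrane_layer_params <- function(mu_memb, beta, thickness_ref) {
  stopifnot(mu_memb > 0, beta > 0, thickness_ref > 0)
  structure(list(mu_memb = mu_memb, beta = beta, thickness_ref = thickness_ref),
            class = "membrane_layer_params")
}

#' Convert membrane-scale parameters to a volumetric Holmes-Mow material
#'
#' Divides the membrane modulus (N/m) by the undeformed thickness to recover
#' the volumetric modulus (Pa) needed by the 3D mixture model.
#'
#' @param layer A [membrane_layer_params()] object.
#' @param lam First Lame parameter, Pa (default 0).
#' @return A [holmes_mow_material()] object.
#' @export
membrane_to_volumetric <- function(layer, lam = 0) {
  stopifnot(inherits(layer, "membrane_layer_params"))
  holmes_mow_material(mu_vol = layer$mu_memb / layer$thickness_ref,
                      beta = layer$beta, lam = lam)
}

#' Donnan swelling environment
#'
#' Chemistry of the external bath and reference tissue hydration governing
#' Donnan osmotic swelling.
#'
#' @param T_K Absolute temperature in K (> 0). Default 298.15 K (room
#'   temperature, matching ex vivo ring experiments); the Donnan pressure
#'   scales linearly in T.
#' @param phi_osm Osmotic coefficient \eqn{\Phi}; 1 for an ideal system.
#' @param bath_osm External bath osmolarity \eqn{\bar c^*} in mol/m^3
#'   (numerically equal to mosM); physiological default 300.
#' @param fluid_fraction_ref Reference fluid volume fraction
#'   \eqn{\varphi_0^\omega} in (0, 1); default 0.7 (70\% water content).
#' @param R_gas Universal gas constant, J/(mol K).
#' @return An object of class \code{donnan_environment}.
#' @export
donnan_environment <- function(T_K = 298.15, phi_osm = 1, bath_osm = 300,
                               fluid_fraction_ref = 0.7,
                               R_gas = 8.314462618) {
  if (!is.numeric(T_K) || T_K <= 0) stop("invalid environment: T_K must be > 0")
  if (!is.numeric(bath_osm) || bath_osm < 0)
    stop("invalid environment: bath_osm must be >= 0")
  stopifnot(phi_osm > 0, fluid_fraction_ref > 0, fluid_fraction_ref < 1,
            R_gas > 0)
  structure(list(T_K = T_K, phi_osm = phi_osm, bath_osm = bath_osm,
                 fluid_fraction_ref = fluid_fraction_ref, R_gas = R_gas),
            class = "donnan_environment")
}

#' Donnan osmotic pressure
#'
#' Equilibrium osmotic pressure generated by a fixed charge density against an
#' external bath:
#' \deqn{\pi = R T \Phi \left(\sqrt{(c^F)^2 + (\bar c^*)^2} - \bar c^*\right).}
#' The expression is even in \eqn{c^F}; magnitudes of signed FCD values may be
#' passed directly.
#'
#' @param c_fcd Current-configuration fixed charge density magnitude, mol/m^3
#'   (numerically mEq/L for monovalent charges). Vectorized.
#' @param env A [donnan_environment()].
#' @return Osmotic pressure(s) in Pa (>= 0).
#' @export
donnan_pressure <- function(c_fcd, env) {
  stopifnot(inherits(env, "donnan_environment"))
  if (any(c_fcd < 0)) stop("c_fcd must be a magnitude (>= 0)")
  with(env, R_gas * T_K * phi_osm * (sqrt(c_fcd^2 + bath_osm^2) - bath_osm))
}

#' Current-configuration fixed charge density
#'
#' Maps the reference FCD to the current configuration through the relative
#' volume J, accounting for the change in fluid volume:
#' \deqn{c^F = \frac{\varphi_0^\omega}{J - 1 + \varphi_0^\omega}\, c_0^F.}
#'
#' @param c0F Reference-configuration FCD, mol/m^3. Vectorized.
#' @param J Relative volume \eqn{\det F}; must exceed
#'   \eqn{1 - \varphi_0^\omega} (all fluid expelled). Vectorized.
#' @param env A [donnan_environment()].
#' @return Current FCD, mol/m^3 (same sign as \code{c0F}).
#' @export
fcd_current <- function(c0F, J, env) {
  stopifnot(inherits(env, "donnan_environment"))
  phi0 <- env$fluid_fraction_ref
  if (any(J <= 1 - phi0))
    stop("degenerate compaction: J <= 1 - fluid_fraction_ref")
  phi0 / (J - 1 + phi0) * c0F
}

#' Deformation state from a deformation gradient
#'
#' Bundles the kinematic quantities used by the constitutive laws: the
#' deformation gradient F, its determinant J, the right/left Cauchy-Green
#' tensors C and B, and the Green strain E = (C - I)/2.
#'
#' @param F 3x3 deformation gradient with \eqn{\det F > 0}.
#' @return An object of class \code{deformation_state}.
#' @export
deformation_state <- function(F) {
  F <- as.matrix(F)
  stopifnot(all(dim(F) == c(3L, 3L)))
  J <- det(F)
  if (J <= 0) stop("deformation gradient must have positive determinant")
  C <- crossprod(F)          # F^T F
  B <- tcrossprod(F)         # F F^T
  structure(list(F = F, J = J, C = C, B = B, E = (C - diag(3)) / 2),
            class = "deformation_state")
}

# Q exponent of the general Holmes-Mow law (volumetric form)
hm_Q <- function(state, mat) {
  C <- state$C
  I1 <- sum(diag(C))
  I2 <- (I1^2 - sum(C * C)) / 2
  lp2m <- mat$lam + 2 * mat$mu_vol
  mat$beta / lp2m * ((2 * mat$mu_vol - mat$lam) * (I1 - 3) +
                       mat$lam * (I2 - 3) - lp2m * 2 * log(state$J))
}

#' Holmes-Mow strain energy density
#'
#' @param state A [deformation_state()].
#' @param mat A [holmes_mow_material()].
#' @return Strain energy density, J/m^3.
#' @export
hm_energy <- function(state, mat) {
  stopifnot(inherits(state, "deformation_state"),
            inherits(mat, "holmes_mow_material"))
  cc <- (mat$lam + 2 * mat$mu_vol) / (2 * mat$beta)
  cc / 2 * (exp(hm_Q(state, mat)) - 1)
}

#' Elastic Cauchy stress of the Holmes-Mow solid matrix
#'
#' Pushes forward the second Piola-Kirchhoff stress
#' \eqn{T^S = 2\,\partial W/\partial C}:
#' \deqn{\sigma^e = \frac{2}{J} F \frac{\partial W}{\partial C} F^T.}
#' For \eqn{\lambda = 0} this reduces to the closed form
#' \eqn{\sigma^e = (\mu/J)\, e^Q (B - I)}.
#'
#' @param state A [deformation_state()].
#' @param mat A [holmes_mow_material()].
#' @return Symmetric 3x3 Cauchy stress, Pa.
#' @export
hm_cauchy_stress <- function(state, mat) {
  stopifnot(inherits(state, "deformation_state"),
            inherits(mat, "holmes_mow_material"))
  C <- state$C
  I1 <- sum(diag(C))
  lp2m <- mat$lam + 2 * mat$mu_vol
  cc <- lp2m / (2 * mat$beta)
  Q <- hm_Q(state, mat)
  # dQ/dC = beta/(lam+2mu) [ (2mu-lam) I + lam (I1 I - C) - (lam+2mu) C^{-1} ]
  dQdC <- mat$beta / lp2m *
    ((2 * mat$mu_vol - mat$lam) * diag(3) +
       mat$lam * (I1 * diag(3) - C) - lp2m * solve(C))
  dWdC <- cc / 2 * exp(Q) * dQdC
  sig <- 2 / state$J * state$F %*% dWdC %*% t(state$F)
  (sig + t(sig)) / 2
}

#' Total mixture Cauchy stress
#'
#' Combines the Donnan fluid pressure with the elastic stress of the solid
#' matrix: \eqn{\sigma = -\pi I + \sigma^e}. The current FCD is obtained from
#' the reference FCD via the relative volume J.
#'
#' @param state A [deformation_state()].
#' @param mat A [holmes_mow_material()].
#' @param c0F Reference FCD magnitude (mol/m^3); signed values are allowed and
#'   their magnitude is used (the pressure is even in the FCD).
#' @param env A [donnan_environment()].
#' @return A list of class \code{mixture_stress} with elements \code{sigma_e}
#'   (Pa), \code{pi} (Pa), and \code{sigma_total} (Pa).
#' @export
mixture_stress <- function(state, mat, c0F, env) {
  sig_e <- hm_cauchy_stress(state, mat)
  cF <- abs(fcd_current(c0F, state$J, env))
  pp <- donnan_pressure(cF, env)
  structure(list(sigma_e = sig_e, pi = pp,
                 sigma_total = -pp * diag(3) + sig_e),
            class = "mixture_stress")
}

# Exponent of the incompressibility-reduced membrane energy
membrane_Q <- function(E11, E22, beta) {
  Delta <- (2 * E11 + 1) * (2 * E22 + 1)
  2 * beta * (E11 + E22 + 0.5 * (1 / Delta - 1))
}

#' Second Piola-Kirchhoff membrane tensions, single layer
#'
#' Theoretical membrane tensions of the incompressibility-reduced Holmes-Mow
#' membrane under planar biaxial stretch (shear neglected):
#' \deqn{T_{11} = \mu\left[1 - \frac{1}{\Delta(2E_{11}+1)}\right] e^Q,\quad
#'       T_{22} = \mu\left[1 - \frac{1}{\Delta(2E_{22}+1)}\right] e^Q,\quad
#'       T_{12} = 0,}
#' with \eqn{Q = 2\beta\,(E_{11}+E_{22}+\tfrac12[1/\Delta - 1])} and
#' \eqn{\Delta = (2E_{11}+1)(2E_{22}+1)}. \eqn{\mu} here is the membrane
#' modulus in N/m.
#'
#' @param E11,E22 In-plane Green strains (vectorized; must keep
#'   \eqn{2E+1 > 0}).
#' @param layer A [membrane_layer_params()].
#' @return A data.frame with columns T11, T22, T12 in N/m.
#' @export
membrane_tensions_single <- function(E11, E22, layer) {
  stopifnot(inherits(layer, "membrane_layer_params"))
  if (any(2 * E11 + 1 <= 0) || any(2 * E22 + 1 <= 0))
    stop("invalid strain: requires 2*E11 + 1 > 0 and 2*E22 + 1 > 0")
  Delta <- (2 * E11 + 1) * (2 * E22 + 1)
  eQ <- exp(membrane_Q(E11, E22, layer$beta))
  mu <- layer$mu_memb
  data.frame(T11 = mu * (1 - 1 / (Delta * (2 * E11 + 1))) * eQ,
             T22 = mu * (1 - 1 / (Delta * (2 * E22 + 1))) * eQ,
             T12 = 0 * E11)
}

#' Second Piola-Kirchhoff membrane tensions, two-layer wall
#'
#' Tensions of a bilayer membrane (intima-media + adventitia) sharing the same
#' in-plane strain; layer tensions are additive:
#' \eqn{T = T_M(\mu_M, \beta_M) + T_A(\mu_A, \beta_A)}.
#'
#' @param E11,E22 In-plane Green strains (vectorized).
#' @param media,adventitia [membrane_layer_params()] for each layer.
#' @return A data.frame with columns T11, T22, T12 in N/m.
#' @export
membrane_tensions_bilayer <- function(E11, E22, media, adventitia) {
  tm <- membrane_tensions_single(E11, E22, media)
  ta <- membrane_tensions_single(E11, E22, adventitia)
  data.frame(T11 = tm$T11 + ta$T11, T22 = tm$T22 + ta$T22,
             T12 = tm$T12 + ta$T12)
}

#' Read a wall material description from JSON
#'
#' Expected shape:
#' \preformatted{{"region": "...",
#'   "layers": [{"mu_memb_N_per_m": ..., "beta": ..., "thickness_m": ...}],
#'   "donnan": {"T_K": ..., "bath_mosM": ..., "phi": ..., "fluid_fraction": ...}}}
#'
#' @param path JSON file path.
#' @return List with \code{region}, \code{layers} (list of
#'   [membrane_layer_params()]) and \code{donnan} ([donnan_environment()]).
#' @export
read_material_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  layers <- lapply(x$layers, function(l)
    membrane_layer_params(l$mu_memb_N_per_m, l$beta, l$thickness_m))
  d <- x$donnan
  env <- donnan_environment(T_K = d$T_K %||% 298.15,
                            phi_osm = d$phi %||% 1,
                            bath_osm = d$bath_mosM %||% 300,
                            fluid_fraction_ref = d$fluid_fraction %||% 0.7)
  list(region = x$region, layers = layers, donnan = env)
}

#' Write a wall material description to JSON
#'
#' @param region Region label.
#' @param layers List of [membrane_layer_params()].
#' @param env A [donnan_environment()].
#' @param path Output file path.
#' @return Invisibly, \code{path}.
#' @export
write_material_json <- function(region, layers, env, path) {
  x <- list(region = region,
            layers = lapply(layers, function(l)
              list(mu_memb_N_per_m = l$mu_memb, beta = l$beta,
                   thickness_m = l$thickness_ref)),
            donnan = list(T_K = env$T_K, bath_mosM = env$bath_osm,
                          phi = env$phi_osm,
                          fluid_fraction = env$fluid_fraction_ref))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
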