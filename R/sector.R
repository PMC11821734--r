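#' Opened-sector swelling oracle (reduced 1D model)
#'
#' Independent verification model for the ring solver: assumes the swollen
#' cut ring deforms as an axisymmetric opened sector with uniform axial
#' stretch, \eqn{r = r(\rho)}, \eqn{\varphi = k\theta}, \eqn{z' = \lambda_z
#' z}, so \eqn{F = \mathrm{diag}(r', k r/\rho, \lambda_z)}. Radial
#' equilibrium \eqn{d\sigma_{rr}/dr + (\sigma_{rr}-\sigma_{\theta\theta})/r
#' = 0} is integrated through the wall (fixed-grid Runge-Kutta per FCD
#' domain, so integration never crosses a property jump), and the three
#' scalars \eqn{(r(R_i), k, \lambda_z)} are found by enforcing zero radial
#' traction at both surfaces, zero net axial force, and zero net bending
#' moment of the circumferential stress on the cut. The net circumferential
#' force \eqn{\int \sigma_{\theta\theta} dr = [r \sigma_{rr}]} vanishes
#' identically once both surface tractions vanish (so the moment is
#' independent of its reference point); it is returned as a consistency
#' check. The opening angle follows from the sector parameter:
#' \eqn{\alpha = 180^\circ (1 - k)}.
#'
#' @param geom A [ring_geometry()].
#' @param fcd An [fcd_domain_profile()] (signed; magnitudes used).
#' @param materials A single [holmes_mow_material()] or
#'   \code{list(media = ..., adventitia = ...)}.
#' @param n_media_elements Intima-media slots out of \code{fcd$n_domains}
#'   (two-layer walls only).
#' @param env A [donnan_environment()].
#' @param steps_per_domain Radial RK4 steps per FCD domain (default 12).
#' @return List with \code{opening_angle} (signed degrees), \code{k},
#'   \code{lambda_z}, \code{r_inner}, \code{net_circ_force} (should be ~0 by
#'   construction), and the residual norm.
#' @export
sector_oracle <- function(geom, fcd, materials, n_media_elements = NULL,
                          env = donnan_environment(),
                          steps_per_domain = 12L) {
  stopifnot(inherits(geom, "ring_geometry"),
            inherits(fcd, "fcd_domain_profile"))
  Ro <- geom$outer_diameter / 2
  Ri <- Ro - geom$thickness
  nd <- fcd$n_domains
  c0 <- abs(fcd$c0F)
  one_layer <- inherits(materials, "holmes_mow_material")
  if (!one_layer && is.null(n_media_elements))
    stop("two-layer sector model needs n_media_elements")
  if (!one_layer && any(c(materials$media$lam, materials$adventitia$lam) != 0)
      || (one_layer && materials$lam != 0))
    stop("sector oracle implements the lambda = 0 matrix")

  prop_at <- function(rho) {
    frac <- (rho - Ri) / (Ro - Ri)
    dom <- pmin(nd, floor(frac * nd) + 1L)
    if (one_layer) {
      list(mu = materials$mu_vol, beta = materials$beta, c0F = c0[dom])
    } else {
      m <- if (frac <= n_media_elements / nd) materials$media else
        materials$adventitia
      list(mu = m$mu_vol, beta = m$beta, c0F = c0[dom])
    }
  }

  RTphi <- env$R_gas * env$T_K * env$phi_osm
  cstar <- env$bath_osm
  phi0 <- env$fluid_fraction_ref
  P0 <- max(RTphi * (sqrt(max(c0)^2 + cstar^2) - cstar), 1)  # stress scale

  stress_radial <- function(lr, lt, lz, p) {
    J <- lr * lt * lz
    if (J <= 1 - phi0 + 1e-9) return(Inf)
    cF <- phi0 / (J - 1 + phi0) * p$c0F
    pp <- RTphi * (sqrt(cF^2 + cstar^2) - cstar)
    eQ <- exp(p$beta * (lr^2 + lt^2 + lz^2 - 3 - 2 * log(J)))
    -pp + p$mu / J * eQ * (lr^2 - 1)
  }
  all_stresses <- function(lr, lt, lz, p) {
    J <- lr * lt * lz
    cF <- phi0 / (J - 1 + phi0) * p$c0F
    pp <- RTphi * (sqrt(cF^2 + cstar^2) - cstar)
    eQ <- exp(p$beta * (lr^2 + lt^2 + lz^2 - 3 - 2 * log(J)))
    c(srr = -pp + p$mu / J * eQ * (lr^2 - 1),
      stt = -pp + p$mu / J * eQ * (lt^2 - 1),
      szz = -pp + p$mu / J * eQ * (lz^2 - 1))
  }
  lr_from_srr <- function(srr, lt, lz, p) {
    lo <- (1 - phi0 + 1e-6) / (lt * lz)
    lo <- max(lo, 0.2)
    f <- function(lr) stress_radial(lr, lt, lz, p) - srr
    hi <- 4
    while (f(hi) < 0 && hi < 64) hi <- hi * 2
    stats::uniroot(f, c(lo, hi), tol = 1e-13)$root
  }

  # ODE state: (r, srr, Ftheta, M, Fz); independent variable rho
  rhs <- function(rho, y, parms) {
    p <- prop_at(rho)
    lt <- parms$k * y[1] / rho
    lr <- lr_from_srr(y[2], lt, parms$lz, p)
    s <- all_stresses(lr, lt, parms$lz, p)
    list(c(lr,
           -(s[["srr"]] - s[["stt"]]) / y[1] * lr,
           s[["stt"]] * lr,
           s[["stt"]] * y[1] * lr,
           s[["szz"]] * y[1] * lr))
  }
  edges <- Ri + (Ro - Ri) * (0:nd) / nd

  shoot <- function(a, k, lz) {
    # returns (srr(Ro), Ftheta, M, Fz) scaled by the pressure scale
    if (k <= 0 || lz <= 0 || a <= 0) return(rep(1e6, 4))
    y <- c(a, 0, 0, 0, 0)
    for (d in seq_len(nd)) {
      times <- seq(edges[d] + 1e-12 * (Ro - Ri), edges[d + 1],
                   length.out = steps_per_domain + 1L)
      out <- deSolve::ode(y, times, rhs, parms = list(k = k, lz = lz),
                          method = "rk4")
      y <- as.numeric(out[nrow(out), -1])
      if (!all(is.finite(y))) return(rep(1e6, 4))
    }
    c(y[2] / P0,
      y[3] / (P0 * (Ro - Ri)),
      y[4] / (P0 * (Ro - Ri) * Ro),
      y[5] / (P0 * (Ro - Ri) * Ro))
  }

  # nested solve: for fixed k, a 2x2 Newton drives the surface traction and
  # net axial force to zero in (a, lambda_z); the outer scalar root in k
  # zeroes the bending moment (monotone in k).
  inner_state <- c(Ri * 1.03, 1.02)   # warm start across outer iterations
  inner_solve <- function(k) {
    x <- inner_state
    f2 <- function(x) shoot(x[1], k, x[2])[c(1, 4)]
    f0 <- f2(x)
    for (it in 1:50) {
      if (max(abs(f0)) < 1e-10) break
      Jn <- matrix(0, 2, 2)
      for (j in 1:2) {
        h <- 1e-6 * max(abs(x[j]), 1e-4)
        xp <- x; xp[j] <- xp[j] + h
        Jn[, j] <- (f2(xp) - f0) / h
      }
      dx <- tryCatch(solve(Jn, f0), error = function(e) NULL)
      if (is.null(dx)) break
      alpha <- 1
      repeat {
        fn <- f2(x - alpha * dx)
        if (sum(fn^2) < sum(f0^2) || alpha < 1 / 64) break
        alpha <- alpha / 2
      }
      x <- x - alpha * dx
      f0 <- fn
    }
    if (max(abs(f0)) > 1e-8) stop("sector inner solve did not converge")
    inner_state <<- x
    x
  }
  moment_of <- function(k) {
    x <- inner_solve(k)
    shoot(x[1], k, x[2])[3]
  }
  root <- tryCatch(
    stats::uniroot(moment_of, c(0.6, 1.05), extendInt = "yes",
                   tol = 1e-10, maxiter = 80),
    error = function(e) stop("sector shooting did not converge: ",
                             conditionMessage(e)))
  k <- root$root
  x <- inner_solve(k)
  final <- shoot(x[1], k, x[2])
  list(opening_angle = 180 * (1 - k), k = k, lambda_z = x[2],
       r_inner = x[1], net_circ_force = final[2] * P0 * (Ro - Ri),
       residual = max(abs(final[c(1, 3, 4)])))
}
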