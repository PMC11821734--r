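#' Default nine biaxial stretching protocols
#'
#' Green-strain ratio pairs (direction 1 : direction 2) emulating a standard
#' nine-protocol equibiaxial / non-equibiaxial test battery. These ratios are
#' a package stand-in for unpublished rig protocols, not a measured value.
#'
#' @return A list of length-2 numeric vectors.
#' @export
default_protocol_ratios <- function() {
  list(c(1, 1), c(1, 0.75), c(0.75, 1), c(1, 0.5), c(0.5, 1),
       c(1, 0.25), c(0.25, 1), c(1, 0), c(0, 1))
}

with_seed <- function(seed, code) {
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  set.seed(seed)
  force(code)
}

#' Generate a synthetic planar biaxial dataset
#'
#' Computes membrane tensions from known one- or two-layer Holmes-Mow
#' parameters on a grid of Green strains along each protocol's strain-ratio
#' path, then applies optional noise. With \code{noise = "none"} the fitting
#' objective evaluated at the true parameters is exactly zero.
#'
#' @param layer A [membrane_layer_params()] (one-layer truth), or a list
#'   \code{list(media = ..., adventitia = ...)} for a bilayer truth.
#' @param protocols List of strain-ratio pairs; default
#'   [default_protocol_ratios()].
#' @param E_max,E_step Strain grid: the dominant arm runs from \code{E_step}
#'   to \code{E_max} in steps of \code{E_step}.
#' @param noise \code{"none"}, \code{"additive"} (N(0, sigma) N/m), or
#'   \code{"multiplicative"} (tension scaled by N(1, sigma)).
#' @param sigma Noise scale (>= 0).
#' @param seed Integer seed; fixes the output exactly.
#' @return A [biaxial_dataset()].
#' @export
gen_biaxial <- function(layer, protocols = default_protocol_ratios(),
                        E_max = 0.5, E_step = 0.025,
                        noise = c("none", "additive", "multiplicative"),
                        sigma = 0.05, seed = 1) {
  noise <- match.arg(noise)
  stopifnot(sigma >= 0)
  bilayer <- !inherits(layer, "membrane_layer_params")
  thickness <- if (bilayer) {
    layer$media$thickness_ref + layer$adventitia$thickness_ref
  } else {
    layer$thickness_ref
  }
  s <- seq(E_step, E_max, by = E_step)
  rows <- lapply(seq_along(protocols), function(i) {
    ab <- protocols[[i]]
    data.frame(protocol = sprintf("P%d_%g:%g", i, ab[1], ab[2]),
               E11 = s * ab[1], E22 = s * ab[2], E12 = 0)
  })
  d <- do.call(rbind, rows)
  tens <- if (bilayer) {
    membrane_tensions_bilayer(d$E11, d$E22, layer$media, layer$adventitia)
  } else {
    membrane_tensions_single(d$E11, d$E22, layer)
  }
  d <- cbind(d, tens)
  if (noise != "none") {
    d <- with_seed(seed, {
      n <- nrow(d)
      if (noise == "additive") {
        d$T11 <- d$T11 + stats::rnorm(n, 0, sigma)
        d$T22 <- d$T22 + stats::rnorm(n, 0, sigma)
      } else {
        d$T11 <- d$T11 * stats::rnorm(n, 1, sigma)
        d$T22 <- d$T22 * stats::rnorm(n, 1, sigma)
      }
      d
    })
  }
  biaxial_dataset(d, thickness)
}

#' Generate a synthetic mural sGAG profile
#'
#' Monotonically decreasing intima-to-adventitia concentration profile
#' sampled at slice centers, with optional additive Gaussian noise (clipped
#' at zero).
#'
#' @param inner,outer Concentrations at the luminal and adventitial walls,
#'   g/L (inner >= outer >= 0 for a decreasing gradient).
#' @param shape \code{"linear"} or \code{"exponential"} decay in normalized
#'   depth.
#' @param n_slices Number of equal-thickness slices (samples at slice
#'   centers).
#' @param sigma Additive noise SD, g/L.
#' @param seed Integer seed.
#' @return An [sgag_profile()].
#' @export
gen_sgag_profile <- function(inner = 9.054, outer = 3.85,
                             shape = c("linear", "exponential"),
                             n_slices = 8, sigma = 0, seed = 1) {
  shape <- match.arg(shape)
  stopifnot(inner >= 0, outer >= 0, sigma >= 0, n_slices >= 2)
  x <- (seq_len(n_slices) - 0.5) / n_slices
  conc <- if (shape == "linear") {
    inner + (outer - inner) * x
  } else {
    if (inner <= 0 || outer <= 0)
      stop("exponential shape requires positive concentrations")
    inner * (outer / inner)^x
  }
  if (sigma > 0) {
    conc <- with_seed(seed, pmax(0, conc + stats::rnorm(n_slices, 0, sigma)))
  }
  sgag_profile(x, conc)
}
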