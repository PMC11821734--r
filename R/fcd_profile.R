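#' Mural sulfated-GAG profile
#'
#' Sulfated-GAG concentration as a function of normalized mural depth
#' (0 = luminal/intimal side, 1 = adventitial side). Concentrations are
#' expressed per water volume (g/L); measurements reported per wet tissue
#' mass can be converted with [sgag_per_wet_mass_to_per_water()].
#'
#' @param depth Numeric vector of normalized depths in [0, 1], strictly
#'   increasing.
#' @param conc_per_water sGAG mass per water volume, g/L (>= 0).
#' @return An object of class \code{sgag_profile}.
#' @export
sgag_profile <- function(depth, conc_per_water) {
  stopifnot(length(depth) == length(conc_per_water))
  if (length(depth) < 1L) stop("empty profile")
  if (any(diff(depth) <= 0)) stop("depths must be strictly increasing")
  if (any(depth < 0 | depth > 1)) stop("depths must lie in [0, 1]")
  if (any(conc_per_water < 0)) stop("concentrations must be >= 0")
  structure(list(depth = depth, conc_per_water = conc_per_water),
            class = "sgag_profile")
}

#' Convert per-wet-mass sGAG to per-water-volume concentration
#'
#' @param conc_per_wet_mass sGAG mass per wet tissue mass, g/g.
#' @param water_fraction Tissue water mass fraction (default 0.7).
#' @param tissue_density Wet tissue density, g/L (default 1000, i.e. water
#'   density; adequate for highly hydrated soft tissue).
#' @return Concentration per water volume, g/L.
#' @export
sgag_per_wet_mass_to_per_water <- function(conc_per_wet_mass,
                                           water_fraction = 0.7,
                                           tissue_density = 1000) {
  stopifnot(water_fraction > 0, water_fraction <= 1, tissue_density > 0)
  conc_per_wet_mass * tissue_density / water_fraction
}

#' Fixed charge density from sGAG concentration
#'
#' Converts a sulfated-GAG concentration (mass per water volume) to a fixed
#' charge density, assuming chondroitin-sulfate disaccharide units:
#' \deqn{c^F = \frac{\mathrm{charge\ number}}{\mathrm{molecular\ weight}}
#'   \times \frac{\mathrm{GAG\ mass}}{\mathrm{water\ volume}}.}
#' Default: molecular weight 513 g/mol carrying two negative charges.
#'
#' @param conc_per_water sGAG concentration, g/L (vectorized, >= 0).
#' @param charge_number Charges per disaccharide, eq/mol (default 2).
#' @param molecular_weight Disaccharide molecular weight, g/mol (default 513).
#' @return FCD magnitude in mEq/L (numerically mol/m^3 of monovalent charge).
#' @export
sgag_to_fcd <- function(conc_per_water, charge_number = 2,
                        molecular_weight = 513) {
  if (molecular_weight <= 0) stop("molecular_weight must be > 0")
  if (charge_number <= 0) stop("charge_number must be > 0")
  if (any(conc_per_water < 0)) stop("concentration must be >= 0")
  # g/L / (g/mol) * eq/mol = eq/L; *1000 -> mEq/L
  charge_number / molecular_weight * conc_per_water * 1000
}

#' Average a mural profile over equal-width depth domains
#'
#' Interpolates the profile piecewise-linearly in normalized depth (constant
#' extrapolation beyond the measured range) and averages it over
#' \code{n_domains} equal-width bins; alternatively evaluates the interpolant
#' at bin midpoints (\code{method = "midpoint"}).
#'
#' @param profile An [sgag_profile()] (or any list with \code{depth} and
#'   \code{conc_per_water}).
#' @param n_domains Number of equal-width depth bins (default 8).
#' @param method \code{"bin_average"} (default) or \code{"midpoint"}.
#' @return Numeric vector of length \code{n_domains}, innermost bin first.
#' @export
interpolate_to_domains <- function(profile, n_domains = 8,
                                   method = c("bin_average", "midpoint")) {
  method <- match.arg(method)
  stopifnot(n_domains >= 1)
  x <- profile$depth
  y <- profile$conc_per_water
  if (length(x) < 2L) stop("profile must have at least 2 points")
  f <- stats::approxfun(x, y, rule = 2)
  edges <- seq(0, 1, length.out = n_domains + 1)
  if (method == "midpoint") {
    f((edges[-1] + edges[-(n_domains + 1)]) / 2)
  } else {
    vapply(seq_len(n_domains), function(k) {
      stats::integrate(f, edges[k], edges[k + 1],
                       subdivisions = 400L, rel.tol = 1e-10)$value /
        (edges[k + 1] - edges[k])
    }, numeric(1))
  }
}

#' Per-domain reference fixed charge densities
#'
#' @param region Region label.
#' @param c0F Signed per-domain FCD values, mEq/L (innermost domain first;
#'   negative for GAG).
#' @return An object of class \code{fcd_domain_profile} with fields
#'   \code{region}, \code{n_domains}, \code{c0F}.
#' @export
fcd_domain_profile <- function(region, c0F) {
  stopifnot(is.numeric(c0F), length(c0F) >= 1)
  structure(list(region = region, n_domains = length(c0F), c0F = c0F),
            class = "fcd_domain_profile")
}

#' Build a per-domain FCD profile from a mural sGAG profile
#'
#' Pipeline: interpolate/average the sGAG profile over equal-width domains,
#' then convert each domain concentration to FCD. Values are returned signed
#' negative (GAG charges).
#'
#' @inheritParams interpolate_to_domains
#' @inheritParams sgag_to_fcd
#' @param region Region label attached to the result.
#' @return An [fcd_domain_profile()].
#' @export
sgag_profile_to_fcd_domains <- function(profile, n_domains = 8,
                                        region = "custom",
                                        charge_number = 2,
                                        molecular_weight = 513,
                                        method = "bin_average") {
  conc <- interpolate_to_domains(profile, n_domains, method)
  fcd_domain_profile(region, -sgag_to_fcd(conc, charge_number,
                                          molecular_weight))
}

#' Reference porcine per-domain FCD values
#'
#' Signed FCD values (mEq/L) in 8 equal mural domains (1 = innermost) derived
#' from mural sGAG measurements on porcine thoracic aortas.
#'
#' @param region One of \code{"ascending"}, \code{"arch"},
#'   \code{"descending"}.
#' @return An [fcd_domain_profile()] with 8 signed values.
#' @export
porcine_fcd <- function(region) {
  region <- match_region(region)
  fcd_domain_profile(region, porcine_reference_data()$fcd[[region]])
}

#' Read a mural sGAG profile from CSV
#'
#' Expects columns \code{depth} and \code{conc}; an optional \code{units}
#' column (\code{"g_per_L"} or \code{"g_per_g_wet"}) selects the conversion,
#' defaulting to g/L per water volume.
#'
#' @param path CSV file path.
#' @param water_fraction Water mass fraction used for per-wet-mass inputs.
#' @return An [sgag_profile()].
#' @export
read_sgag_csv <- function(path, water_fraction = 0.7) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("depth", "conc") %in% names(d)))
  conc <- d$conc
  if ("units" %in% names(d) && any(d$units == "g_per_g_wet")) {
    wet <- d$units == "g_per_g_wet"
    conc[wet] <- sgag_per_wet_mass_to_per_water(conc[wet], water_fraction)
  }
  sgag_profile(d$depth, conc)
}

#' Write a per-domain FCD profile to CSV
#'
#' @param fcd An [fcd_domain_profile()].
#' @param path Output CSV path.
#' @return Invisibly, \code{path}.
#' @export
write_fcd_csv <- function(fcd, path) {
  utils::write.csv(data.frame(domain = seq_len(fcd$n_domains),
                              c0F_mEq_per_L = fcd$c0F),
                   path, row.names = FALSE)
  invisible(path)
}

#' Write / read a per-domain FCD profile as JSON
#'
#' Values round-trip exactly (full double precision).
#'
#' @param fcd An [fcd_domain_profile()].
#' @param path JSON file path.
#' @return \code{write_fcd_json}: invisibly, \code{path};
#'   \code{read_fcd_json}: an [fcd_domain_profile()].
#' @export
write_fcd_json <- function(fcd, path) {
  jsonlite::write_json(list(region = fcd$region, c0F_mEq_per_L = fcd$c0F),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_fcd_json
#' @export
read_fcd_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  fcd_domain_profile(x$region, as.numeric(x$c0F_mEq_per_L))
}
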