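#' Planar biaxial dataset
#'
#' Protocol-wise Green strain / second Piola-Kirchhoff membrane tension
#' records from planar biaxial tensile tests. Direction 1 is the fiber
#' direction (FD), direction 2 the cross-fiber direction (XD).
#'
#' @param data data.frame with columns \code{protocol}, \code{E11},
#'   \code{E22}, \code{E12} (dimensionless) and \code{T11}, \code{T22},
#'   \code{T12} (N/m).
#' @param sample_thickness Undeformed sample thickness, m.
#' @param region Optional region label.
#' @return An object of class \code{biaxial_dataset}.
#' @export
biaxial_dataset <- function(data, sample_thickness, region = "custom") {
  need <- c("protocol", "E11", "E22", "E12", "T11", "T22", "T12")
  stopifnot(is.data.frame(data), all(need %in% names(data)),
            sample_thickness > 0)
  structure(list(data = data[need], sample_thickness = sample_thickness,
                 region = region),
            class = "biaxial_dataset")
}

#' Read a biaxial dataset from CSV
#'
#' @param path CSV with columns protocol, E11, E22, E12, T11, T22, T12.
#' @param sample_thickness Undeformed sample thickness, m.
#' @param region Region label.
#' @return A [biaxial_dataset()].
#' @export
read_biaxial_csv <- function(path, sample_thickness, region = "custom") {
  biaxial_dataset(utils::read.csv(path, stringsAsFactors = FALSE),
                  sample_thickness, region)
}

#' Write a biaxial dataset to CSV
#' @param dataset A [biaxial_dataset()].
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_biaxial_csv <- function(dataset, path) {
  utils::write.csv(dataset$data, path, row.names = FALSE)
  invisible(path)
}

# membrane moduli of the two layers under the r constraint.
# r_scale = "membrane" (default): r ties the fitted membrane moduli,
#   mu_A_memb = r * mu_M_memb (each layer is later converted to volumetric
#   scale by its own thickness);
# r_scale = "volumetric": r ties the volumetric moduli, so
#   mu_A_memb = r * (mu_M_memb / H_M) * H_A.
bilayer_membrane_moduli <- function(mu_M, r, H_M, H_A,
                                    r_scale = c("membrane", "volumetric")) {
  r_scale <- match.arg(r_scale)
  mu_A <- if (r_scale == "volumetric") r * mu_M * H_A / H_M else r * mu_M
  c(mu_M = mu_M, mu_A = mu_A)
}

predicted_tensions <- function(dataset, params, layers = 1, r = NULL,
                               H_M = NULL, H_A = NULL,
                               r_scale = "membrane") {
  d <- dataset$data
  if (layers == 1) {
    lay <- membrane_layer_params(params[1], params[2],
                                 dataset$sample_thickness)
    membrane_tensions_single(d$E11, d$E22, lay)
  } else {
    stopifnot(!is.null(r), !is.null(H_M), !is.null(H_A))
    mus <- bilayer_membrane_moduli(params[1], r, H_M, H_A, r_scale)
    media <- membrane_layer_params(mus[["mu_M"]], params[2], H_M)
    adv <- membrane_layer_params(mus[["mu_A"]], params[3], H_A)
    membrane_tensions_bilayer(d$E11, d$E22, media, adv)
  }
}

#' L1 objective between experimental and theoretical membrane tensions
#'
#' Sum over all points and protocols of
#' \eqn{|T_{11,exp}-T_{11,theo}| + |T_{22,exp}-T_{22,theo}| +
#' |T_{12,exp}-T_{12,theo}|}. Zero iff the theoretical curves interpolate the
#' data exactly.
#'
#' @param dataset A [biaxial_dataset()].
#' @param params Numeric: \code{c(mu, beta)} (N/m, -) for one layer;
#'   \code{c(mu_M, beta_M, beta_A)} for two layers.
#' @param layers 1 or 2.
#' @param r Adventitia/media stiffness ratio (two-layer only).
#' @param H_M,H_A Undeformed layer thicknesses, m (two-layer only).
#' @param r_scale Whether \code{r} ties the fitted membrane moduli
#'   (\code{"membrane"}, default, so \eqn{\mu_A = r\,\mu_M} in N/m) or the
#'   volumetric moduli (\code{"volumetric"},
#'   \eqn{\hat\mu_A = r\,\hat\mu_M} in Pa).
#' @param aggregate \code{"sum"} (default) or \code{"rms"} of the per-point
#'   L1 errors.
#' @return Nonnegative scalar.
#' @export
biaxial_objective <- function(dataset, params, layers = 1, r = NULL,
                              H_M = NULL, H_A = NULL,
                              r_scale = "membrane",
                              aggregate = c("sum", "rms")) {
  aggregate <- match.arg(aggregate)
  if (any(params <= 0)) stop("parameters must be positive")
  d <- dataset$data
  th <- predicted_tensions(dataset, params, layers, r, H_M, H_A, r_scale)
  l1 <- abs(d$T11 - th$T11) + abs(d$T22 - th$T22) + abs(d$T12 - th$T12)
  if (aggregate == "sum") sum(l1) else sqrt(mean(l1^2))
}

#' Squared Pearson correlation by loading direction
#'
#' Squared Pearson correlation between pooled predicted and experimental
#' membrane tensions, separately for direction 1 (fiber, FD) and direction 2
#' (cross-fiber, XD).
#'
#' @param pred,exp data.frames with columns T11 and T22 (pooled over
#'   protocols, matching rows).
#' @return Named numeric \code{c(r2_fd, r2_xd)}.
#' @export
pearson_r2_by_direction <- function(pred, exp) {
  if (nrow(pred) < 3L || nrow(exp) != nrow(pred))
    stop("need >= 3 matching points")
  if (stats::sd(exp$T11) == 0 || stats::sd(exp$T22) == 0 ||
      stats::sd(pred$T11) == 0 || stats::sd(pred$T22) == 0)
    stop("zero variance: Pearson correlation undefined")
  c(r2_fd = stats::cor(exp$T11, pred$T11)^2,
    r2_xd = stats::cor(exp$T22, pred$T22)^2)
}

# deterministic multi-start grid (log-space lattice over the bounds)
start_grid <- function(lower, upper, n_per_dim = 3L) {
  axes <- lapply(seq_along(lower), function(i)
    seq(log(lower[i]), log(upper[i]), length.out = n_per_dim + 2L)[
      2:(n_per_dim + 1L)])
  m <- as.matrix(expand.grid(axes))
  dimnames(m) <- NULL
  m
}

run_nm <- function(obj_log, start, maxit = 2000) {
  o1 <- stats::optim(start, obj_log, method = "Nelder-Mead",
                     control = list(maxit = maxit, reltol = 1e-12))
  # restart from the incumbent to escape collapsed simplices
  stats::optim(o1$par, obj_log, method = "Nelder-Mead",
               control = list(maxit = maxit, reltol = 1e-14))
}

#' Fit one-layer Holmes-Mow membrane parameters
#'
#' Minimizes the L1 tension objective over \eqn{(\mu, \beta)} with a
#' derivative-free simplex search, multi-started from a deterministic
#' log-space lattice over the bounds; positivity is enforced by optimizing in
#' log space. Ties are broken on lowest objective, then lowest \eqn{\beta}.
#'
#' @param dataset A [biaxial_dataset()].
#' @param init Optional starting values \code{c(mu, beta)} added to the
#'   start lattice.
#' @param bounds List with \code{lower} and \code{upper} bounds for
#'   \code{c(mu, beta)}; defaults \code{c(1, 0.05)} / \code{c(1000, 20)}.
#' @param aggregate Objective aggregation, see [biaxial_objective()].
#' @return A list of class \code{fit_result}: \code{layer}
#'   ([membrane_layer_params()]), \code{params}, \code{objective_value},
#'   \code{r2_fd}, \code{r2_xd}, \code{predicted}, \code{layers = 1}.
#' @export
fit_one_layer <- function(dataset, init = NULL,
                          bounds = list(lower = c(1, 0.05),
                                        upper = c(1000, 20)),
                          aggregate = "sum") {
  d <- dataset$data
  if (nrow(unique(d[c("E11", "E22")])) < 2L)
    stop("need at least 2 independent strain states")
  obj_log <- function(p) biaxial_objective(dataset, exp(p), layers = 1,
                                           aggregate = aggregate)
  starts <- start_grid(bounds$lower, bounds$upper)
  if (!is.null(init)) starts <- rbind(starts, log(init))
  fits <- apply(starts, 1L, function(s) run_nm(obj_log, s), simplify = FALSE)
  vals <- vapply(fits, `[[`, numeric(1), "value")
  betas <- vapply(fits, function(f) exp(f$par[2]), numeric(1))
  best <- fits[[order(vals, betas)[1L]]]
  params <- unname(exp(best$par))
  pred <- predicted_tensions(dataset, params, layers = 1)
  r2 <- pearson_r2_by_direction(pred, d)
  structure(list(layer = membrane_layer_params(params[1], params[2],
                                               dataset$sample_thickness),
                 params = c(mu = params[1], beta = params[2]),
                 objective_value = best$value,
                 r2_fd = unname(r2["r2_fd"]), r2_xd = unname(r2["r2_xd"]),
                 predicted = pred, layers = 1L, aggregate = aggregate),
            class = "fit_result")
}

#' Fit two-layer Holmes-Mow membrane parameters under a stiffness-ratio
#' constraint
#'
#' Optimizes \eqn{(\mu_M, \beta_M, \beta_A)} with the adventitial modulus
#' tied to the medial one by the ratio \code{r} (\eqn{r = \mu_A/\mu_M});
#' layer tensions are additive. \eqn{\beta_A} is allowed to collapse to its
#' lower bound (a near-linear adventitia), in which case
#' \code{beta_A_boundary} is flagged.
#'
#' @param dataset A [biaxial_dataset()].
#' @param H_M,H_A Undeformed intima-media and adventitia thicknesses, m;
#'   must sum to the dataset sample thickness.
#' @param r Adventitia/media stiffness ratio (> 0).
#' @param init Optional start \code{c(mu_M, beta_M, beta_A)}.
#' @param bounds List with lower/upper bounds on
#'   \code{c(mu_M, beta_M, beta_A)}.
#' @param r_scale See [biaxial_objective()].
#' @param aggregate Objective aggregation.
#' @return A \code{fit_result} with \code{media}, \code{adventitia}
#'   ([membrane_layer_params()]), \code{r}, \code{params},
#'   \code{beta_A_boundary}, objective and R^2 fields.
#' @export
fit_two_layer <- function(dataset, H_M, H_A, r, init = NULL,
                          bounds = list(lower = c(1, 0.05, 1e-4),
                                        upper = c(1000, 20, 20)),
                          r_scale = "membrane", aggregate = "sum") {
  stopifnot(r > 0, H_M > 0, H_A > 0)
  if (abs(H_M + H_A - dataset$sample_thickness) >
      1e-9 * dataset$sample_thickness)
    stop("H_M + H_A must equal the dataset sample thickness")
  d <- dataset$data
  obj_log <- function(p) biaxial_objective(dataset, exp(p), layers = 2,
                                           r = r, H_M = H_M, H_A = H_A,
                                           r_scale = r_scale,
                                           aggregate = aggregate)
  starts <- start_grid(bounds$lower, bounds$upper, n_per_dim = 2L)
  if (!is.null(init)) starts <- rbind(starts, log(init))
  fits <- apply(starts, 1L, function(s) run_nm(obj_log, s), simplify = FALSE)
  vals <- vapply(fits, `[[`, numeric(1), "value")
  betas <- vapply(fits, function(f) exp(f$par[2]), numeric(1))
  best <- fits[[order(vals, betas)[1L]]]
  params <- unname(exp(best$par))
  mus <- bilayer_membrane_moduli(params[1], r, H_M, H_A, r_scale)
  pred <- predicted_tensions(dataset, params, layers = 2, r = r,
                             H_M = H_M, H_A = H_A, r_scale = r_scale)
  r2 <- pearson_r2_by_direction(pred, d)
  structure(list(media = membrane_layer_params(mus[["mu_M"]], params[2], H_M),
                 adventitia = membrane_layer_params(mus[["mu_A"]], params[3],
                                                    H_A),
                 r = r, r_scale = r_scale,
                 params = c(mu_M = params[1], beta_M = params[2],
                            beta_A = params[3]),
                 beta_A_boundary = params[3] <= bounds$lower[3] * 10,
                 objective_value = best$value,
                 r2_fd = unname(r2["r2_fd"]), r2_xd = unname(r2["r2_xd"]),
                 predicted = pred, layers = 2L, aggregate = aggregate,
                 H_M = H_M, H_A = H_A),
            class = "fit_result")
}

#' Bootstrap confidence intervals for fitted membrane parameters
#'
#' Nonparametric residual bootstrap: tension residuals are resampled with
#' replacement (per component, pooled over protocols), added back to the
#' fitted curves, and the model is refitted from the incumbent estimate.
#' Halfwidths are half the central 95\% percentile range.
#'
#' @param dataset A [biaxial_dataset()].
#' @param fit A \code{fit_result} from [fit_one_layer()] or
#'   [fit_two_layer()].
#' @param n_boot Number of bootstrap resamples (default 1000; < 50 warns).
#' @param seed Integer seed; same seed gives identical intervals.
#' @return Named numeric vector of 95\% (2-tailed) CI halfwidths, one per
#'   fitted parameter.
#' @export
confidence_intervals <- function(dataset, fit, n_boot = 1000, seed = 1) {
  if (n_boot < 50) warning("n_boot < 50: intervals will be unstable")
  d <- dataset$data
  res <- data.frame(T11 = d$T11 - fit$predicted$T11,
                    T22 = d$T22 - fit$predicted$T22,
                    T12 = d$T12 - fit$predicted$T12)
  n <- nrow(d)
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  set.seed(seed)
  boots <- replicate(n_boot, {
    db <- d
    db$T11 <- fit$predicted$T11 + sample(res$T11, n, replace = TRUE)
    db$T22 <- fit$predicted$T22 + sample(res$T22, n, replace = TRUE)
    db$T12 <- fit$predicted$T12 + sample(res$T12, n, replace = TRUE)
    dsb <- biaxial_dataset(db, dataset$sample_thickness, dataset$region)
    if (fit$layers == 1L) {
      obj <- function(p) biaxial_objective(dsb, exp(p), layers = 1,
                                           aggregate = fit$aggregate)
    } else {
      obj <- function(p) biaxial_objective(dsb, exp(p), layers = 2,
                                           r = fit$r, H_M = fit$H_M,
                                           H_A = fit$H_A,
                                           r_scale = fit$r_scale,
                                           aggregate = fit$aggregate)
    }
    exp(stats::optim(log(unname(fit$params)), obj, method = "Nelder-Mead",
                     control = list(maxit = 600, reltol = 1e-10))$par)
  })
  boots <- matrix(boots, nrow = length(fit$params))
  hw <- apply(boots, 1L, function(x)
    diff(stats::quantile(x, c(0.025, 0.975), names = FALSE)) / 2)
  stats::setNames(hw, names(fit$params))
}

#' Write a fit result to JSON
#'
#' @param fit A \code{fit_result}.
#' @param path Output path.
#' @param ci Optional named CI halfwidths from [confidence_intervals()].
#' @return Invisibly, \code{path}.
#' @export
write_fit_json <- function(fit, path, ci = NULL) {
  x <- list(layers = fit$layers, params = as.list(fit$params),
            objective_value = fit$objective_value,
            r2_fd = fit$r2_fd, r2_xd = fit$r2_xd)
  if (fit$layers == 2L) {
    x$r <- fit$r
    x$mu_A <- fit$adventitia$mu_memb
    x$beta_A_boundary <- fit$beta_A_boundary
  }
  if (!is.null(ci)) x$ci_halfwidth <- as.list(ci)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
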