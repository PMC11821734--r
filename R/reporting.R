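#' Round half away from zero to the nearest integer
#'
#' Percentages in the evaluation tables are rounded half-up (27.59 -> 28,
#' 32.46 -> 32), unlike base R's round-half-to-even.
#'
#' @param x Numeric vector.
#' @return Integer-valued numeric vector.
#' @export
round_half_up <- function(x) floor(x + 0.5)

#' Percent error of a simulated angle against a reference decrease
#'
#' \eqn{|sim - ref| / ref \times 100}, rounded half-up to an integer, the
#' convention used when scoring simulated opening angles against the
#' experimental GAG-depletion decrease.
#'
#' @param sim_deg Simulated opening angle, degrees.
#' @param ref_deg Reference (experimental delta) angle, degrees; nonzero.
#' @return Integer percent error (>= 0).
#' @export
percent_error <- function(sim_deg, ref_deg) {
  if (any(ref_deg == 0)) stop("reference angle must be nonzero")
  round_half_up(abs(sim_deg - ref_deg) / abs(ref_deg) * 100)
}

#' Simulated angle as a fraction of the control opening angle
#'
#' \eqn{sim / control \times 100}, rounded half-up to an integer.
#'
#' @param sim_deg Simulated opening angle, degrees.
#' @param control_deg Experimental control opening angle, degrees (> 0).
#' @return Integer percentage.
#' @export
fraction_of_control <- function(sim_deg, control_deg) {
  if (any(control_deg <= 0)) stop("control angle must be positive")
  round_half_up(sim_deg / control_deg * 100)
}

#' Summary of intima-media wall proportions
#'
#' Mean and standard deviation of the per-animal intima-media proportion in
#' each region, from the reference histology measurements.
#'
#' @return data.frame with region, mean_pct, sd_pct, n.
#' @export
intima_media_summary <- function() {
  lp <- porcine_reference_data()$layer_proportions
  regions <- setdiff(names(lp), "animal")
  data.frame(region = regions,
             mean_pct = vapply(lp[regions], mean, numeric(1)),
             sd_pct = vapply(lp[regions], stats::sd, numeric(1)),
             n = nrow(lp), row.names = NULL)
}

#' Build the opening-angle evaluation report
#'
#' Scores simulated opening angles against the experimental decrease in
#' opening angle caused by enzymatic GAG depletion ("delta") and against the
#' control opening angle. Configurations whose underlying biaxial fit had a
#' Pearson R^2 below 0.93 in either direction are flagged unacceptable, and
#' negative simulated angles are excluded from evaluation (not observed
#' experimentally); excluded cells report NA errors.
#'
#' @param angles Optional data.frame with columns \code{region},
#'   \code{layers}, \code{r} (NA for one layer) and \code{angle_deg}. In the
#'   default arithmetic mode the tabulated reference simulation angles are
#'   used, decoupling the report arithmetic from the FE solver.
#' @param mode \code{"arithmetic"} (default; reference angles) or
#'   \code{"simulated"} (\code{angles} required).
#' @return data.frame of class \code{evaluation_report} with per-row angle,
#'   delta and control references, acceptability flags, integer
#'   \code{percent_error} and \code{fraction_of_control}.
#' @export
build_report <- function(angles = NULL,
                         mode = c("arithmetic", "simulated")) {
  mode <- match.arg(mode)
  ref <- porcine_reference_data()
  if (mode == "arithmetic") {
    one <- data.frame(region = ref$angles$region, layers = 1L, r = NA_real_,
                      angle_deg = ref$angles$sim1_deg)
    two <- data.frame(region = ref$two_layer_angles$region, layers = 2L,
                      r = ref$two_layer_angles$r,
                      angle_deg = ref$two_layer_angles$angle_deg)
    angles <- rbind(one, two)
  } else if (is.null(angles)) {
    stop("simulated mode requires an angles data.frame")
  }
  stopifnot(all(c("region", "layers", "r", "angle_deg") %in% names(angles)))

  rows <- lapply(seq_len(nrow(angles)), function(i) {
    a <- angles[i, ]
    exp_ref <- ref$angles[ref$angles$region == a$region, ]
    if (nrow(exp_ref) == 0L)
      stop("unknown region in angles: ", a$region)
    fit_ok <- if (a$layers == 1L) {
      ol <- ref$one_layer[ref$one_layer$region == a$region, ]
      ol$r2_fd >= 0.93 && ol$r2_xd >= 0.93
    } else {
      tl <- ref$two_layer
      row <- tl[tl$region == a$region & abs(tl$r - a$r) < 1e-9, ]
      nrow(row) == 1L && row$fit_ok
    }
    excluded <- !fit_ok || a$angle_deg < 0
    data.frame(region = a$region, layers = a$layers, r = a$r,
               angle_deg = a$angle_deg,
               delta_deg = exp_ref$delta_deg,
               control_deg = exp_ref$control_deg,
               fit_ok = fit_ok, excluded = excluded,
               percent_error = if (excluded) NA_real_ else
                 percent_error(a$angle_deg, exp_ref$delta_deg),
               fraction_of_control = if (excluded) NA_real_ else
                 fraction_of_control(a$angle_deg, exp_ref$control_deg))
  })
  rep <- do.call(rbind, rows)
  class(rep) <- c("evaluation_report", "data.frame")
  rep
}

#' Smallest two-layer percent error per region
#'
#' @param report An \code{evaluation_report} from [build_report()].
#' @return data.frame with region, best r and smallest percent error among
#'   non-excluded two-layer configurations.
#' @export
smallest_two_layer_errors <- function(report) {
  tw <- report[report$layers == 2L & !report$excluded, ]
  do.call(rbind, lapply(split(tw, tw$region), function(d) {
    b <- d[which.min(d$percent_error), ]
    data.frame(region = b$region, r = b$r, percent_error = b$percent_error)
  }))
}

#' Write an evaluation report to JSON (and optionally CSV)
#'
#' @param report An \code{evaluation_report}.
#' @param path Output JSON path.
#' @param csv Optional CSV path.
#' @return Invisibly, \code{path}.
#' @export
write_report <- function(report, path, csv = NULL) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", na = "null")
  if (!is.null(csv)) utils::write.csv(report, csv, row.names = FALSE)
  invisible(path)
}
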