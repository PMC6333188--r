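#' Distance-to-agreement at the 50% penumbra level
#'
#' Locates the 50%-of-maximum crossing on each side of the peak of both
#' profiles by linear interpolation (each profile relative to its own
#' maximum within the analysis window) and reports the per-side and
#' average distance between the reference and evaluated crossings.
#'
#' @param reference,evaluated `fluence_profile` objects.
#' @param window Optional `c(y_min, y_max)` analysis window (mm).
#' @return Named numeric `c(left, right, avg)` in mm.
#' @examples
#' y <- seq(-5, 5, 0.1)
#' p <- fluence_profile(y, exp(-y^2 / 2))
#' q <- fluence_profile(y, exp(-(y - 0.5)^2 / 2))
#' dta_at_half_max(p, q)   # 0.5 on both sides
#' @export
dta_at_half_max <- function(reference, evaluated, window = NULL) {
  r <- half_max_crossings(reference, window)
  e <- half_max_crossings(evaluated, window)
  left <- abs(r["left"] - e["left"])
  right <- abs(r["right"] - e["right"])
  c(left = unname(left), right = unname(right),
    avg = unname((left + right) / 2))
}

half_max_crossings <- function(profile, window = NULL) {
  y <- profile$y_grid; v <- profile$values
  if (!is.null(window)) {
    keep <- y >= window[1] & y <= window[2]
    y <- y[keep]; v <- v[keep]
  }
  ipk <- which.max(v)
  half <- v[ipk] / 2
  cross <- function(idx, side) {
    if (length(idx) == 0)
      stop(sprintf("no 50%% crossing on the %s side of the peak", side),
           call. = FALSE)
    i <- if (side == "left") max(idx) else min(idx)
    ## linear interpolation between samples i and i+1
    y[i] + (half - v[i]) / (v[i + 1] - v[i]) * (y[i + 1] - y[i])
  }
  left <- cross(which(v[seq_len(ipk - 1)] < half &
                        v[seq_len(ipk - 1) + 1] >= half), "left")
  right_candidates <- which(v >= half & c(v[-1], -Inf) < half)
  right <- cross(right_candidates[right_candidates >= ipk], "right")
  c(left = left, right = right)
}

#' Gamma analysis criteria
#'
#' @param dose_tol Dose tolerance as percent of the reference maximum
#'   (global normalization).
#' @param dist_tol Distance tolerance (mm).
#' @return Object of class `gamma_criteria`.
#' @export
gamma_criteria <- function(dose_tol = 2, dist_tol = 1) {
  stopifnot(dose_tol > 0, dist_tol > 0)
  structure(list(dose_tol = dose_tol, dist_tol = dist_tol),
            class = "gamma_criteria")
}

#' One-dimensional global gamma analysis
#'
#' For every reference point, the gamma index is the minimum over the
#' evaluated profile of `sqrt((dD / (dose_tol% * max_ref))^2 +
#' (dy / dist_tol)^2)`; dose differences are normalized globally to the
#' reference maximum.  The search is exhaustive over evaluated samples
#' and, when `refine = TRUE`, refined by the closed-form minimum of the
#' quadratic gamma-squared along each linearly interpolated segment.
#'
#' @param reference,evaluated `fluence_profile` objects; the evaluated
#'   positions must overlap the reference range.
#' @param criteria A [gamma_criteria()].
#' @param refine Refine between evaluated samples?
#' @return List with `gamma` (per reference point), `pass_rate` (percent
#'   of points with gamma <= 1) and `criteria`.
#' @export
gamma_1d <- function(reference, evaluated, criteria = gamma_criteria(),
                     refine = TRUE) {
  yr <- reference$y_grid; dr <- reference$values
  ye <- evaluated$y_grid; de <- evaluated$values
  if (max(ye) < min(yr) || min(ye) > max(yr))
    stop("reference and evaluated profiles do not overlap", call. = FALSE)
  dmax <- max(dr)
  if (dmax <= 0) stop("reference maximum must be positive", call. = FALSE)
  dden <- criteria$dose_tol / 100 * dmax
  g2 <- vapply(seq_along(yr), function(i) {
    dy <- (ye - yr[i]) / criteria$dist_tol
    dd <- (de - dr[i]) / dden
    best <- min(dy^2 + dd^2)
    if (refine && length(ye) > 1) {
      ## on segment j..j+1: dy(t) = a1 + b1 t, dd(t) = a2 + b2 t, t in [0,1]
      a1 <- dy[-length(dy)]; b1 <- diff(dy)
      a2 <- dd[-length(dd)]; b2 <- diff(dd)
      t <- pmin(1, pmax(0, -(a1 * b1 + a2 * b2) / (b1^2 + b2^2)))
      t[!is.finite(t)] <- 0
      best <- min(best, (a1 + b1 * t)^2 + (a2 + b2 * t)^2)
    }
    best
  }, 0)
  gamma <- sqrt(g2)
  list(gamma = gamma, pass_rate = 100 * mean(gamma <= 1 + 1e-12),
       criteria = criteria)
}

#' Percent difference relative to a reference value
#'
#' @param reference_value Reference (non-zero).
#' @param test_value Test value.
#' @return `100 * (test - reference) / reference`.
#' @export
percent_difference <- function(reference_value, test_value) {
  if (any(reference_value == 0))
    stop("reference value must be non-zero", call. = FALSE)
  100 * (test_value - reference_value) / reference_value
}

#' Calibration context for absolute-dose conversion
#'
#' Converts a simulated dose-per-incident-particle into absolute dose
#' through a reference calibration simulation (10 x 10 cm^2 field,
#' SSD 100 cm, dose at 10 cm depth, 1 cGy/MU at reference conditions).
#'
#' @param dose_per_particle_individual Dose per incident particle of the
#'   individual simulation.
#' @param dose_per_particle_calibration Same for the calibration
#'   simulation (must be > 0).
#' @param mu_delivered Monitor units delivered.
#' @param cgy_per_mu Calibration dose rate (cGy/MU), 1 at reference
#'   conditions.
#' @return Object of class `calibration_context`.
#' @export
calibration_context <- function(dose_per_particle_individual,
                                dose_per_particle_calibration,
                                mu_delivered, cgy_per_mu = 1) {
  if (dose_per_particle_calibration <= 0)
    stop("calibration denominator must be > 0", call. = FALSE)
  structure(list(individual = dose_per_particle_individual,
                 calibration = dose_per_particle_calibration,
                 mu_delivered = mu_delivered, cgy_per_mu = cgy_per_mu),
            class = "calibration_context")
}

#' Absolute dose from a calibration context
#'
#' @param ctx A [calibration_context()].
#' @return Dose in cGy:
#'   `(individual / calibration) * cgy_per_mu * mu_delivered`.
#' @examples
#' absolute_dose(calibration_context(2e-17, 2e-17, 100))   # 100 cGy
#' @export
absolute_dose <- function(ctx) {
  ctx$individual / ctx$calibration * ctx$cgy_per_mu * ctx$mu_delivered
}

#' Full comparison report between two profiles
#'
#' @param reference,evaluated `fluence_profile` objects.
#' @param criteria A list of [gamma_criteria()] (default 1%/1 mm and
#'   2%/1 mm).
#' @param window Optional DTA analysis window (mm).
#' @return Object of class `metric_report` with the evaluated profile's
#'   maximum and integral, per-side/average DTA, gamma pass rates and the
#'   per-point percent differences (of the evaluated against the
#'   reference, as percent of the reference value at each point).
#' @export
metric_report <- function(reference, evaluated,
                          criteria = list(gamma_criteria(1, 1),
                                          gamma_criteria(2, 1)),
                          window = NULL) {
  dta <- dta_at_half_max(reference, evaluated, window)
  rates <- vapply(criteria, function(cr)
    gamma_1d(reference, evaluated, cr)$pass_rate, 0)
  names(rates) <- vapply(criteria, function(cr)
    sprintf("%g%%/%gmm", cr$dose_tol, cr$dist_tol), "")
  common <- reference$y_grid %in% evaluated$y_grid
  pd <- if (any(common)) {
    ev <- evaluated$values[match(reference$y_grid[common],
                                 evaluated$y_grid)]
    rv <- reference$values[common]
    ok <- rv != 0
    percent_difference(rv[ok], ev[ok])
  } else numeric(0)
  structure(list(max_value = profile_max(evaluated),
                 integral = profile_integral(evaluated),
                 dta_left = dta[["left"]], dta_right = dta[["right"]],
                 dta_avg = dta[["avg"]], gamma_pass_rate = rates,
                 point_diffs = pd),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat("Profile comparison report\n")
  cat(sprintf("  evaluated max %.4g, integral %.4g\n", x$max_value,
              x$integral))
  cat(sprintf("  DTA at 50%%: left %.3g mm, right %.3g mm, avg %.3g mm\n",
              x$dta_left, x$dta_right, x$dta_avg))
  for (nm in names(x$gamma_pass_rate))
    cat(sprintf("  gamma %s pass rate: %.1f%%\n", nm,
                x$gamma_pass_rate[[nm]]))
  if (length(x$point_diffs))
    cat(sprintf("  point differences: mean %.2f%%, range [%.2f, %.2f]%%\n",
                mean(x$point_diffs), min(x$point_diffs),
                max(x$point_diffs)))
  invisible(x)
}

#' Summarize profile differences at the extrema of an alternating field
#'
#' For a profile with several local maxima (open leaves) and minima
#' (closed leaves), reports the mean and sample standard deviation of the
#' percent differences at the extremum positions, one window per leaf.
#'
#' @param reference,evaluated `fluence_profile` objects on a common grid.
#' @param centers Leaf-center positions at the isocenter plane (mm).
#' @param half_width Half-width of each per-leaf window (mm).
#' @param type `"maxima"` or `"minima"`.
#' @return List with `diffs`, `mean` and `sd`.
#' @export
extrema_differences <- function(reference, evaluated, centers,
                                half_width = 2.5,
                                type = c("maxima", "minima")) {
  type <- match.arg(type)
  pick <- if (type == "maxima") which.max else which.min
  diffs <- vapply(centers, function(cc) {
    keep <- abs(reference$y_grid - cc) <= half_width
    if (!any(keep)) stop("window contains no grid points", call. = FALSE)
    i <- pick(reference$values[keep])
    rv <- reference$values[keep][i]
    ev <- evaluated$values[keep][i]
    percent_difference(rv, ev)
  }, 0)
  list(diffs = diffs, mean = mean(diffs),
       sd = if (length(diffs) > 1) stats::sd(diffs) else NA_real_)
}
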