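# Age-40 adjustment of AMH and BMI. A local-linear median (check-loss)
# smoother estimates the population median of the covariate versus age; each
# subject's value is shifted by the median difference between her age and the
# reference age 40, which yields per-subject age-40 adjusted values.

#' Fit a local-linear median curve of a covariate versus age
#'
#' At each point of a 0.1-year grid, fits intercept and slope minimizing the
#' median check loss \eqn{\sum \rho_{0.5}(y - a - b(age - t))} over a box
#' kernel window of half-width \code{bandwidth}. Windows holding fewer than 5
#' points are widened (doubling the bandwidth) with a warning.
#'
#' @param values covariate values (e.g. AMH in ng/mL, or BMI).
#' @param ages ages (years) at which the values were measured.
#' @param bandwidth box-kernel half-width in years (default 2).
#' @param grid optional evaluation grid; default covers the data range and at
#'   least [35, 48] in steps of 0.1 year.
#' @return object of class \code{"median_curve"}: \code{grid}, \code{fit},
#'   \code{bandwidth}.
#' @export
fit_median_curve <- function(values, ages, bandwidth = 2, grid = NULL) {
  stopifnot(length(values) == length(ages))
  ok <- is.finite(values) & is.finite(ages)
  values <- values[ok]; ages <- ages[ok]
  if (length(values) < 20) stop("need at least 20 points to fit a median curve")
  if (bandwidth <= 0) stop("bandwidth must be positive")
  if (is.null(grid)) {
    lo <- min(35, floor(min(ages) * 10) / 10)
    hi <- max(48, ceiling(max(ages) * 10) / 10)
    grid <- seq(lo, hi, by = 0.1)
  }
  # tau = 0.5 check loss reduces to half the absolute deviation
  check_loss <- function(par, y, dx) 0.5 * sum(abs(y - par[1] - par[2] * dx))
  widened <- FALSE
  fit <- vapply(grid, function(t0) {
    bw <- bandwidth
    idx <- which(abs(ages - t0) <= bw)
    while (length(idx) < 5 && bw < diff(range(ages)) + bandwidth) {
      bw <- bw * 2
      idx <- which(abs(ages - t0) <= bw)
      widened <<- TRUE
    }
    y <- values[idx]; dx <- ages[idx] - t0
    start <- stats::coef(stats::lsfit(dx, y))       # LS start (exact for noiseless linear data)
    if (any(!is.finite(start))) start <- c(stats::median(y), 0)
    opt <- stats::optim(start, check_loss, y = y, dx = dx,
                        method = "Nelder-Mead",
                        control = list(reltol = 1e-12, maxit = 500))
    opt$par[1]
  }, numeric(1))
  if (widened) warning("some windows held < 5 points; bandwidth widened locally")
  structure(list(grid = grid, fit = fit, bandwidth = bandwidth),
            class = "median_curve")
}

#' @export
predict.median_curve <- function(object, newage, ...) {
  out <- numeric(length(newage))
  oob <- newage < min(object$grid) | newage > max(object$grid)
  if (any(oob)) {
    warning("age outside curve grid; using nearest grid value")
    newage <- pmin(pmax(newage, min(object$grid)), max(object$grid))
  }
  stats::approx(object$grid, object$fit, xout = newage, rule = 2)$y
}

#' @export
print.median_curve <- function(x, ...) {
  cat(sprintf("Local-linear median curve on [%.1f, %.1f], bandwidth %.2f y, value at 40: %.3f\n",
              min(x$grid), max(x$grid), x$bandwidth,
              predict(x, 40)))
  invisible(x)
}

#' Adjust covariate values to a reference age
#'
#' Additive median-shift adjustment:
#' \eqn{y_i - curve(age_i) + curve(ref)}, so a subject measured at the
#' reference age is returned unchanged and within-age ordering is preserved.
#'
#' @param y_i covariate values.
#' @param age_i measurement ages.
#' @param curve a fitted \code{\link{fit_median_curve}}.
#' @param ref reference age (default 40).
#' @return adjusted values.
#' @export
adjust_to_reference <- function(y_i, age_i, curve, ref = 40) {
  stopifnot(inherits(curve, "median_curve"))
  y_i - predict(curve, age_i) + predict(curve, ref)
}

#' Discretize adjusted AMH
#'
#' Quartile mode cuts at empirical quartiles (or supplied cutpoints);
#' two-level mode uses the 0.83 ng/mL cutoff. Ties at a cutpoint fall in the
#' lower bin (a value equal to 0.83 is "low").
#'
#' @param values adjusted AMH values (ng/mL).
#' @param mode \code{"quartiles"} or \code{"two_level"}.
#' @param cutpoints optional: 3 interior cutpoints (quartiles) or 1 cutoff
#'   (two_level, default 0.83).
#' @return integer codes: 1-4 for quartiles, 0/1 (low/high) for two_level.
#' @examples
#' bin_amh(c(0.54, 0.83, 1.52), cutpoints = c(0.54, 0.83, 1.51))
#' bin_amh(c(0.83, 0.84), mode = "two_level")
#' @export
bin_amh <- function(values, mode = c("quartiles", "two_level"),
                    cutpoints = NULL) {
  mode <- match.arg(mode)
  if (any(!is.finite(values))) stop("AMH values must be finite")
  if (mode == "quartiles") {
    if (is.null(cutpoints))
      cutpoints <- as.numeric(stats::quantile(values, c(0.25, 0.5, 0.75),
                                              names = FALSE))
    if (length(cutpoints) != 3 || is.unsorted(cutpoints))
      stop("quartile mode needs 3 increasing cutpoints")
    1L + (values > cutpoints[1]) + (values > cutpoints[2]) +
      (values > cutpoints[3])
  } else {
    cut <- if (is.null(cutpoints)) 0.83 else cutpoints[1]
    as.integer(values > cut)
  }
}
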