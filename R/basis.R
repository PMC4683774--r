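# Truncated-power cubic spline basis over age, with exact analytic first
# derivatives. The penalized block (hinge terms) is shrunk toward zero in the
# sampler, so redundant knots are smoothed away rather than being harmful.

#' Build a penalized cubic spline basis over age
#'
#' Constructs a truncated-power cubic basis: a polynomial part
#' \eqn{(1, t, t^2, t^3)} plus one hinge term \eqn{(t - \kappa_m)_+^3} per
#' interior knot. Knots are placed at equally spaced empirical quantiles of the
#' supplied ages; the boundary is the data range. This parameterization keeps
#' the smoothing penalty a simple exchangeable shrinkage on the hinge
#' coefficients and makes the first derivative analytic.
#'
#' @param ages numeric vector of ages (years) observed in the data; at least
#'   two distinct values.
#' @param n_interior_knots number of interior knots (>= 0); default 10.
#' @param center,scale optional affine reparameterization of the time axis:
#'   the polynomial and hinge terms are evaluated in \code{(t - center) /
#'   scale}. The defaults (0, 1) give the plain \eqn{(1, t, t^2, t^3,
#'   (t-\kappa)_+^3)} rows; the model fitter uses \code{center = 40, scale =
#'   10} for numerical conditioning of the cross-products. The spanned
#'   function space is identical.
#' @return an object of class \code{"fmp_basis"} with fields \code{degree}
#'   (always 3), \code{knots} (interior knots in years, strictly increasing),
#'   \code{boundary} (data range), and \code{dim} (\code{4 + length(knots)}).
#' @examples
#' b <- fmp_basis(seq(35, 60, by = 1), n_interior_knots = 4)
#' basis_row(b, 42)
#' @export
fmp_basis <- function(ages, n_interior_knots = 10, center = 0, scale = 1) {
  if (any(is.na(ages)) || any(!is.finite(ages)))
    stop("ages contain NA or non-finite values")
  ua <- sort(unique(ages))
  if (length(ua) < 2) stop("need at least 2 distinct ages")
  if (n_interior_knots < 0) stop("n_interior_knots must be >= 0")
  if (length(ua) < n_interior_knots)
    stop("fewer distinct ages than requested knots (degenerate knots)")
  boundary <- range(ages)
  knots <- numeric(0)
  if (n_interior_knots > 0) {
    probs <- seq_len(n_interior_knots) / (n_interior_knots + 1)
    knots <- as.numeric(stats::quantile(ages, probs = probs, names = FALSE))
    knots <- knots[knots > boundary[1] & knots < boundary[2]]
    if (anyDuplicated(knots))
      stop("degenerate (tied) knots; reduce n_interior_knots")
  }
  if (scale <= 0) stop("scale must be positive")
  structure(list(degree = 3L, knots = knots, boundary = boundary,
                 dim = 4L + length(knots), center = center, scale = scale),
            class = "fmp_basis")
}

#' @export
print.fmp_basis <- function(x, ...) {
  cat(sprintf("Cubic truncated-power basis: %d interior knot(s), boundary [%.2f, %.2f], dim %d\n",
              length(x$knots), x$boundary[1], x$boundary[2], x$dim))
  invisible(x)
}

#' Design row(s) of a spline basis at given ages
#'
#' @param basis an \code{\link{fmp_basis}}.
#' @param t ages (years); values outside the boundary are extrapolated with the
#'   polynomial + active-hinge form and flagged via the \code{"extrapolated"}
#'   attribute (features at reference ages 40/45 must be computable for every
#'   subject).
#' @param deriv 0 for the level basis, 1 for its analytic first derivative.
#' @return a \code{length(t) x basis$dim} matrix; attribute
#'   \code{"extrapolated"} is \code{TRUE} if any age fell outside the boundary.
#' @export
basis_row <- function(basis, t, deriv = 0) {
  stopifnot(inherits(basis, "fmp_basis"), deriv %in% c(0, 1))
  if (any(!is.finite(t))) stop("non-finite age")
  extra <- any(t < basis$boundary[1] | t > basis$boundary[2])
  sc <- if (is.null(basis$scale)) 1 else basis$scale
  ce <- if (is.null(basis$center)) 0 else basis$center
  u <- (t - ce) / sc
  k <- (basis$knots - ce) / sc
  if (deriv == 0) {
    poly <- cbind(1, u, u^2, u^3)
    hinge <- if (length(k)) outer(u, k, function(a, b) pmax(a - b, 0)^3) else NULL
  } else {
    # d/dt = (1/scale) d/du
    poly <- cbind(0, 1, 2 * u, 3 * u^2) / sc
    hinge <- if (length(k)) outer(u, k, function(a, b) 3 * pmax(a - b, 0)^2) / sc else NULL
  }
  m <- if (is.null(hinge)) poly else cbind(poly, hinge)
  dimnames(m) <- NULL
  attr(m, "extrapolated") <- extra
  m
}

#' Evaluate a spline curve (mean hormone level) at given ages
#'
#' @inheritParams basis_row
#' @param coefs coefficient vector of length \code{basis$dim}.
#' @return numeric vector of curve values; carries the \code{"extrapolated"}
#'   attribute when any age was outside the basis boundary.
#' @export
eval_level <- function(basis, coefs, t) {
  if (length(coefs) != basis$dim)
    stop(sprintf("coefficient length %d does not match basis dimension %d",
                 length(coefs), basis$dim))
  m <- basis_row(basis, t, deriv = 0)
  out <- drop(m %*% coefs)
  attr(out, "extrapolated") <- attr(m, "extrapolated")
  out
}

#' Evaluate the rate of change (analytic first derivative) at given ages
#'
#' The rate of change of the smoothed mean level is the exact derivative of
#' the truncated-power expansion: \eqn{(0, 1, 2t, 3t^2, 3(t-\kappa_m)_+^2)}.
#'
#' @inheritParams eval_level
#' @return numeric vector of derivative values.
#' @export
eval_rate <- function(basis, coefs, t) {
  if (length(coefs) != basis$dim)
    stop(sprintf("coefficient length %d does not match basis dimension %d",
                 length(coefs), basis$dim))
  m <- basis_row(basis, t, deriv = 1)
  out <- drop(m %*% coefs)
  attr(out, "extrapolated") <- attr(m, "extrapolated")
  out
}
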