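# Internal numeric helpers shared across the sampler and likelihood code.

#' Log-sum-exp with max subtraction
#'
#' Numerically stable \code{log(sum(exp(x)))}; safe for log-likelihood
#' differences up to several hundred.
#'
#' @param x numeric vector, may contain \code{-Inf}.
#' @return scalar \code{log(sum(exp(x)))}.
#' @keywords internal
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# inverse-gamma draw parameterized by shape a, rate b (density ~ x^-(a+1) e^(-b/x))
rinvgamma1 <- function(n, shape, rate) 1 / stats::rgamma(n, shape = shape, rate = rate)

#' Student-t log density with location and scale
#'
#' @param x numeric vector of evaluation points.
#' @param mu location.
#' @param sigma scale (> 0).
#' @param df degrees of freedom (default 4, the fixed residual df of the
#'   longitudinal model).
#' @return vector of log densities.
#' @keywords internal
dt_ls <- function(x, mu, sigma, df = 4) {
  stats::dt((x - mu) / sigma, df = df, log = TRUE) - log(sigma)
}

#' Draw from a normal distribution truncated below
#'
#' Samples \code{N(mean, sd^2)} conditional on exceeding \code{lower}.
#' Uses inverse-CDF sampling in the body of the distribution and switches to
#' an exponential-proposal rejection sampler (Robert 1995) when the
#' standardized truncation point exceeds 5, where the inverse CDF loses
#' accuracy.
#'
#' @param n number of draws.
#' @param mean,sd normal parameters (vectors recycled to length \code{n}).
#' @param lower lower truncation point(s).
#' @return numeric vector of \code{n} draws, all \code{> lower}.
#' @export
rtnorm_lower <- function(n, mean = 0, sd = 1, lower = -Inf) {
  mean <- rep_len(mean, n); sd <- rep_len(sd, n); lower <- rep_len(lower, n)
  if (any(!is.finite(mean)) || any(!is.finite(sd)) || any(sd <= 0))
    stop("non-finite mean or non-positive sd in truncated-normal draw")
  a <- (lower - mean) / sd           # standardized truncation point
  out <- numeric(n)
  easy <- a <= 5 | !is.finite(a)
  if (any(easy)) {
    ae <- a[easy]
    p0 <- stats::pnorm(ae)
    u <- stats::runif(sum(easy), p0, 1)
    z <- stats::qnorm(u)
    # guard against u -> 1 rounding
    z <- pmax(z, ae)
    out[easy] <- z
  }
  if (any(!easy)) {
    idx <- which(!easy)
    for (j in idx) {
      aj <- a[j]
      if (!is.finite(aj)) stop("non-finite truncation point")
      # Robert (1995) translated-exponential rejection for the far tail
      alpha <- (aj + sqrt(aj^2 + 4)) / 2
      repeat {
        z <- aj + stats::rexp(1, rate = alpha)
        if (stats::runif(1) <= exp(-(z - alpha)^2 / 2)) break
      }
      out[j] <- z
    }
  }
  mean + sd * out
}

# mean of a lower-truncated normal: m + sd * phi(a*)/(1 - Phi(a*))
tnorm_lower_mean <- function(mean, sd, lower) {
  a <- (lower - mean) / sd
  mean + sd * exp(stats::dnorm(a, log = TRUE) -
                    stats::pnorm(a, lower.tail = FALSE, log.p = TRUE))
}

# simple named-list override, erroring on unknown keys (config hygiene)
merge_config <- function(defaults, user, what = "config") {
  if (is.null(user)) return(defaults)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop(sprintf("unknown %s field(s): %s", what, paste(unknown, collapse = ", ")))
  defaults[names(user)] <- user
  defaults
}
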