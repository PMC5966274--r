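#' Wrap angles to the canonical interval
#'
#' Maps any finite angle (in degrees) to the canonical interval (-180, 180].
#' All directions in the package are expressed relative to the session's
#' reference direction, which sits at 0 degrees.
#'
#' @param x Numeric vector of angles in degrees.
#' @return Numeric vector of the same length, each element in (-180, 180].
#'   Wrapping is idempotent and periodic: `wrap_angle(x + 360) == wrap_angle(x)`.
#' @examples
#' wrap_angle(c(361, -180, 750))
#' @export
wrap_angle <- function(x) {
  if (!is.numeric(x) || any(!is.finite(x))) {
    stop("wrap_angle() requires finite numeric input")
  }
  x - 360 * ceiling((x - 180) / 360)
}

#' Convert between von Mises concentration and dispersion in degrees
#'
#' The package parameterizes all noise sources by a von Mises concentration
#' `kappa` internally, but reports dispersions `sigma` in degrees using
#' `sigma = sqrt(1/kappa)` converted from radians. A `kappa` of 0 corresponds
#' to a uniform distribution (`sigma = Inf`). The alternative convention,
#' the circular standard deviation `sqrt(-2*log(A1(kappa)))` where
#' `A1 = I1/I0`, is available via `method = "circular-sd"`; the two agree to
#' within a few percent for sigma below about 30 degrees.
#'
#' @param kappa Nonnegative concentration parameter(s).
#' @param sigma Dispersion(s) in degrees, positive.
#' @param method Dispersion convention, `"sqrt-inverse"` (default) or
#'   `"circular-sd"`.
#' @return `kappa_to_sigma` returns dispersions in degrees; `sigma_to_kappa`
#'   returns concentrations. The default conversions round-trip exactly.
#' @export
kappa_to_sigma <- function(kappa, method = c("sqrt-inverse", "circular-sd")) {
  method <- match.arg(method)
  if (any(kappa < 0)) stop("kappa must be >= 0")
  out <- numeric(length(kappa))
  pos <- kappa > 0
  out[!pos] <- Inf
  if (method == "sqrt-inverse") {
    out[pos] <- sqrt(1 / kappa[pos]) * 180 / pi
  } else {
    a1 <- besselI(kappa[pos], 1, expon.scaled = TRUE) /
      besselI(kappa[pos], 0, expon.scaled = TRUE)
    out[pos] <- sqrt(-2 * log(a1)) * 180 / pi
  }
  out
}

#' @rdname kappa_to_sigma
#' @export
sigma_to_kappa <- function(sigma) {
  if (any(sigma <= 0)) stop("sigma must be > 0 (degrees)")
  ifelse(is.infinite(sigma), 0, (180 / (pi * sigma))^2)
}

#' von Mises probability density over directions in degrees
#'
#' Density per degree of the von Mises (circular normal) distribution,
#' normalized over the circle (-180, 180]. At `kappa = 0` it reduces to the
#' uniform density 1/360.
#'
#' @param theta Angle(s) in degrees at which to evaluate the density.
#' @param mu Mean direction in degrees.
#' @param kappa Concentration, >= 0. Evaluated with exponentially scaled
#'   Bessel functions so large concentrations stay finite.
#' @return Density values per degree (nonnegative, integrating to 1).
#' @examples
#' vm_pdf(0, 0, 5)
#' integrate(function(t) vm_pdf(t, 10, 2), -180, 180)
#' @export
vm_pdf <- function(theta, mu = 0, kappa) {
  if (length(kappa) != 1 || !is.finite(kappa) || kappa < 0) {
    stop("kappa must be a single finite value >= 0")
  }
  x <- (theta - mu) * pi / 180
  exp(kappa * (cos(x) - 1)) / (360 * besselI(kappa, 0, expon.scaled = TRUE))
}

#' Draw from a von Mises distribution (degrees)
#'
#' Best-Fisher rejection sampler; exact for any concentration, including the
#' uniform limit `kappa = 0`.
#'
#' @param n Number of draws.
#' @param mu Mean direction in degrees.
#' @param kappa Concentration, >= 0.
#' @return `n` angles in (-180, 180].
#' @export
rvm <- function(n, mu = 0, kappa) {
  if (kappa < 0) stop("kappa must be >= 0")
  if (kappa == 0) {
    return(wrap_angle(stats::runif(n, -180, 180)))
  }
  tau <- 1 + sqrt(1 + 4 * kappa^2)
  rho <- (tau - sqrt(2 * tau)) / (2 * kappa)
  r <- (1 + rho^2) / (2 * rho)
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need)) {
    m <- length(need)
    u1 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    c0 <- kappa * (r - f)
    u2 <- stats::runif(m)
    ok <- (c0 * (2 - c0) - u2 > 0) | (log(c0 / u2) + 1 - c0 >= 0)
    th <- sign(stats::runif(m) - 0.5) * acos(pmin(pmax(f, -1), 1))
    out[need[ok]] <- th[ok]
    need <- need[!ok]
  }
  wrap_angle(mu + out * 180 / pi)
}

#' Circular (resultant-vector) mean of angles
#'
#' Weighted circular mean in degrees. When the resultant length is
#' numerically zero (perfectly symmetric input) the mean direction is
#' undefined; the caller chooses whether that yields `NA` or an error.
#'
#' @param angles Angles in degrees.
#' @param weights Optional nonnegative weights, not all zero.
#' @param undefined What to do when the resultant length vanishes:
#'   return `NA` (default) or raise an error.
#' @return The mean direction in (-180, 180], or `NA` if undefined.
#' @export
circ_mean <- function(angles, weights = NULL, undefined = c("NA", "error")) {
  undefined <- match.arg(undefined)
  r <- circ_resultant(angles, weights)
  if (r$R < 1e-10) {
    if (undefined == "error") stop("circular mean undefined: zero resultant length")
    return(NA_real_)
  }
  r$mean
}

# resultant vector: mean direction and mean resultant length
circ_resultant <- function(angles, weights = NULL) {
  if (is.null(weights)) weights <- rep(1, length(angles))
  if (any(weights < 0) || sum(weights) == 0) {
    stop("weights must be nonnegative and not all zero")
  }
  rad <- angles * pi / 180
  z <- sum(weights * exp(1i * rad)) / sum(weights)
  list(mean = wrap_angle(Arg(z) * 180 / pi), R = Mod(z))
}

#' Circular distance, standard deviation and RMSE
#'
#' `circ_dist` is the signed shortest-arc difference `a - b` in (-180, 180].
#' `circ_sd` is the circular standard deviation `sqrt(-2*log(R))` in degrees.
#' `circ_rmse` is the root mean square of wrapped errors, used for the
#' high-contrast inclusion criterion (a uniform random estimator has
#' `circ_rmse` of 180/sqrt(3), about 103.9 degrees).
#'
#' @param a,b Angles in degrees.
#' @param angles Angles in degrees.
#' @param errors Signed angular errors in degrees (already wrapped).
#' @return Degrees.
#' @export
circ_dist <- function(a, b) wrap_angle(a - b)

#' @rdname circ_dist
#' @export
circ_sd <- function(angles) {
  R <- circ_resultant(angles)$R
  sqrt(-2 * log(max(R, .Machine$double.xmin))) * 180 / pi
}

#' @rdname circ_dist
#' @export
circ_rmse <- function(errors) sqrt(mean(wrap_angle(errors)^2))
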