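# Model-free description of estimation responses: a lapse-contaminated von
# Mises is fitted per presented angle, giving per-angle bias and
# variability curves.

# inverse of A1(kappa) = I1/I0 (Fisher 1993 approximation)
a1inv <- function(R) {
  R <- min(max(R, 0), 1 - 1e-12)
  k <- if (R < 0.53) {
    2 * R + R^3 + 5 * R^5 / 6
  } else if (R < 0.85) {
    -0.4 + 1.39 * R + 0.43 / (1 - R)
  } else {
    1 / (R^3 - 4 * R^2 + 3 * R)
  }
  min(max(k, 0), 1e6)
}

#' Per-angle lapse-mixture fit of estimation responses
#'
#' For each presented design angle, fits the estimate distribution
#' `(1 - alpha) * V(theta | mu, kappa) + alpha / 360` by maximum
#' likelihood (EM), with the lapse fraction `alpha` shared across angles
#' within a subject. The per-angle bias is `wrap_angle(mu - theta_act)` and
#' the per-angle variability is the dispersion of the fitted `kappa`.
#'
#' @param trials Filtered low-contrast trials of one subject.
#' @param min_per_angle Angles with fewer trials are skipped (warning).
#' @param max_iter,tol EM iteration cap and log-likelihood tolerance.
#' @return List with `per_angle` (data.frame: `angle`, `n`, `mu`, `kappa`,
#'   `sigma`, `bias`, `sd`) and `alpha` (shared lapse estimate).
#' @export
per_angle_mixture_fit <- function(trials, min_per_angle = 10,
                                  max_iter = 300, tol = 1e-9) {
  cnt <- table(trials$theta_act_deg)
  keep <- names(cnt)[cnt >= min_per_angle]
  if (length(keep) < length(cnt)) {
    warning("skipping angles with < ", min_per_angle, " trials: ",
            paste(setdiff(names(cnt), keep), collapse = ", "))
  }
  if (length(keep) == 0) stop("no angle has enough trials")
  angles <- sort(as.numeric(keep))
  sub <- trials[trials$theta_act_deg %in% angles, ]
  grp <- match(sub$theta_act_deg, angles)
  th <- sub$theta_est_deg
  rad <- th * pi / 180
  # init: per-angle circular moments, small lapse
  mu <- vapply(seq_along(angles), function(a) circ_mean(th[grp == a]), numeric(1))
  kap <- vapply(seq_along(angles), function(a) {
    a1inv(circ_resultant(th[grp == a])$R)
  }, numeric(1))
  alpha <- 0.05
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    dens_vm <- exp(kap[grp] * (cos(rad - mu[grp] * pi / 180) - 1)) /
      (360 * besselI(kap[grp], 0, expon.scaled = TRUE))
    dens <- (1 - alpha) * dens_vm + alpha / 360
    ll <- sum(log(pmax(dens, 1e-300)))
    gam <- (alpha / 360) / pmax(dens, 1e-300)   # lapse responsibility
    alpha <- mean(gam)
    wts <- 1 - gam
    for (a in seq_along(angles)) {
      ii <- grp == a
      z <- sum(wts[ii] * exp(1i * rad[ii]))
      sw <- sum(wts[ii])
      if (sw <= 0 || Mod(z) < 1e-12) next
      mu[a] <- wrap_angle(Arg(z) * 180 / pi)
      kap[a] <- a1inv(Mod(z) / sw)
    }
    if (is.finite(ll_old) && abs(ll - ll_old) < tol) break
    ll_old <- ll
  }
  per_angle <- data.frame(
    angle = angles,
    n = as.integer(cnt[as.character(angles)]),
    mu = mu,
    kappa = kap,
    sigma = kappa_to_sigma(kap),
    bias = wrap_angle(mu - angles),
    sd = kappa_to_sigma(kap))
  list(per_angle = per_angle, alpha = alpha, loglik = ll)
}
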