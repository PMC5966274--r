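# Generative response distributions p(theta_est | theta_act; M).
#
# The Bayesian observer: the true direction theta_act is corrupted in two
# cascaded von Mises stages with the same concentration kappa_sens
# (theta_act -> theta_t -> theta_sens); the observer combines the learned
# bimodal prior with the single-stage likelihood V(theta_sens | theta,
# kappa_sens) and reads out the circular mean of the posterior
# (theta_perc); motor noise (kappa_m) and a uniform lapse (alpha) produce
# the reported estimate. All distributions are evaluated as densities per
# degree on a regular grid; convolutions use the FFT.

#' Learned prior over motion directions
#'
#' The acquired expectation is a symmetric sum of two von Mises components
#' centered at +/-`theta_exp`, each with width `sigma_exp`:
#' `0.5 * (V(-theta_exp, kappa_exp) + V(+theta_exp, kappa_exp))`.
#'
#' @param theta Angle(s) in degrees.
#' @param params An [observer_params()] object.
#' @return Density per degree; normalized over the circle and symmetric
#'   about 0.
#' @export
prior_density <- function(theta, params) {
  ke <- sigma_to_kappa(params$sigma_exp)
  0.5 * (vm_pdf(theta, -params$theta_exp, ke) +
         vm_pdf(theta,  params$theta_exp, ke))
}

#' Distribution of the internal measurement
#'
#' Density of the noisy sensory measurement `theta_sens` given the true
#' direction. With `stages = 2` (default) the corruption is the literal
#' two-stage cascade (trial-varying direction `theta_t` around `theta_act`,
#' then measurement noise around `theta_t`, both with `kappa_sens`),
#' computed by circular self-convolution; `stages = 1` collapses to a
#' single von Mises.
#'
#' @param theta_sens Measurement angle(s) in degrees.
#' @param theta_act True direction in degrees (scalar).
#' @param params An [observer_params()] object.
#' @param stages 2 (cascade, default) or 1.
#' @param grid_step Evaluation grid spacing in degrees.
#' @return Density per degree at `theta_sens` (linear interpolation from the
#'   grid when `stages = 2`).
#' @export
measurement_pdf <- function(theta_sens, theta_act, params, stages = 2,
                            grid_step = 0.5) {
  ks <- sigma_to_kappa(sigma_sens_for(params, theta_act))
  if (stages == 1) return(vm_pdf(theta_sens, theta_act, ks))
  grid <- angle_grid(grid_step)
  kern <- vm_pdf(grid$disp, 0, ks)
  m0 <- circ_conv_fft(kern, stats::fft(kern), grid$step)
  m0 <- m0 / (sum(m0) * grid$step)
  grid_interp(rotate_kernel(m0, theta_act, grid), theta_sens, grid)
}

#' Posterior-mean percept
#'
#' The perceived direction for a given internal measurement: the circular
#' (resultant-vector) mean of the posterior `p(theta | theta_sens)
#' proportional to prior(theta) * V(theta_sens | theta, kappa_sens)`,
#' evaluated by quadrature on the grid. When the posterior is symmetric
#' (measurement exactly at 0 or 180 under a bimodal prior) the resultant
#' vanishes and the percept is defined as `theta_sens` itself (tie-break).
#'
#' @param theta_sens Measurement angle(s) in degrees.
#' @param params An [observer_params()] object.
#' @param theta_act Optional true direction used only to resolve a
#'   per-direction `sigma_sens`; defaults to the first element.
#' @param grid_step Quadrature grid spacing in degrees (0.01 gives a
#'   brute-force reference).
#' @return Percept angle(s) in (-180, 180].
#' @export
posterior_mean <- function(theta_sens, params, theta_act = NULL,
                           grid_step = 0.5) {
  ks <- if (is.null(theta_act)) {
    sigma_to_kappa(params$sigma_sens[1])
  } else {
    sigma_to_kappa(sigma_sens_for(params, theta_act))
  }
  grid <- angle_grid(grid_step)
  pr <- prior_density(grid$points, params)
  erad <- exp(1i * grid$points * pi / 180)
  vapply(theta_sens, function(ts) {
    post <- pr * vm_pdf(ts, grid$points, ks)
    z <- sum(post * erad)
    if (Mod(z) / max(sum(post), .Machine$double.xmin) < 1e-10) {
      return(wrap_angle(ts))
    }
    wrap_angle(Arg(z) * 180 / pi)
  }, numeric(1))
}

# FFT percept map: theta_perc at every grid point, for one kappa_sens.
# z(theta_sens) = sum_theta prior(theta) e^{i theta} L(theta_sens - theta)
# is a circular convolution; Arg(z) is the posterior circular mean.
percept_map <- function(prior_vec, lik_fft, grid) {
  f <- prior_vec * exp(1i * grid$points * pi / 180)
  z <- circ_conv_fft_c(f, lik_fft, grid$step)
  tp <- wrap_angle(Arg(z) * 180 / pi)
  tie <- Mod(z) < 1e-12
  tp[tie] <- grid$points[tie]
  tp
}

# Response-distribution curves for any family: a grid$n x length(theta_acts)
# matrix of densities per degree, one column per true direction.
response_curves <- function(spec, params, theta_acts, grid = angle_grid(0.5),
                            stages = 2) {
  if (spec$bayesian) {
    bayes_curves(params, theta_acts, grid, stages)
  } else {
    add_curves(spec, params, theta_acts, grid)
  }
}

bayes_curves <- function(params, theta_acts, grid, stages = 2) {
  n <- grid$n
  km <- sigma_to_kappa(params$sigma_m)
  motor_fft <- stats::fft(vm_pdf(grid$disp, 0, km))
  sig_s <- sigma_sens_for(params, theta_acts)
  pr <- prior_density(grid$points, params)
  out <- matrix(0, n, length(theta_acts))
  for (s in unique(sig_s)) {
    cols <- which(sig_s == s)
    ks <- sigma_to_kappa(s)
    kern <- vm_pdf(grid$disp, 0, ks)
    lik_fft <- stats::fft(kern)
    m0 <- if (stages == 2) {
      circ_conv_fft(kern, lik_fft, grid$step)
    } else {
      kern
    }
    m0 <- pmax(m0, 0)
    m0 <- m0 / (sum(m0) * grid$step)
    tp <- percept_map(pr, lik_fft, grid)
    # scatter the measurement mass onto percept positions, then blur by motor
    idx <- grid_interp_index(tp, grid)
    sh <- as.integer(round((theta_acts[cols] + 180) / grid$step))
    rot <- outer(seq_len(n), sh, function(a, b) ((a - b) %% n) + 1L)
    W <- matrix(m0[rot], n, length(cols)) * grid$step
    Q <- matrix(0, n, length(cols))
    s1 <- rowsum(W * (1 - idx$w), idx$i1, reorder = FALSE)
    Q[as.integer(rownames(s1)), ] <- s1
    s2 <- rowsum(W * idx$w, idx$i2, reorder = FALSE)
    Q[as.integer(rownames(s2)), ] <- Q[as.integer(rownames(s2)), ] + s2
    R <- Re(stats::mvfft(stats::mvfft(Q / grid$step) * c(motor_fft),
                         inverse = TRUE)) / n * grid$step
    R <- pmax(R, 0)
    R <- sweep(R, 2, colSums(R) * grid$step, "/")
    out[, cols] <- (1 - params$alpha) * R + params$alpha / 360
  }
  out
}

add_curves <- function(spec, params, theta_acts, grid) {
  n <- grid$n
  km <- sigma_to_kappa(params$sigma_m)
  ks <- sigma_to_kappa(params$sigma_sens[1])
  w <- params$w
  if (is.null(w)) stop("response-strategy models require the mixing weight w")
  # unbiased branch: sensory and motor noise combined by convolution,
  # centered on the true direction
  kern_s <- vm_pdf(grid$disp, 0, ks)
  u0 <- circ_conv_fft(kern_s, stats::fft(vm_pdf(grid$disp, 0, km)), grid$step)
  u0 <- pmax(u0, 0)
  u0 <- u0 / (sum(u0) * grid$step)
  # expectation branch
  side <- ifelse(wrap_angle(theta_acts) >= 0, 1, -1)  # 0 assigned positive
  qcol <- switch(spec$family,
    ADD1 = {
      matrix(prior_density(grid$points, params), n, length(theta_acts))
    },
    ADD2 = {
      pr <- prior_density(grid$points, params)
      qp <- pr * (grid$points > 0); qp <- qp / (sum(qp) * grid$step)
      qn <- pr * (grid$points < 0); qn <- qn / (sum(qn) * grid$step)
      sapply(side, function(s) if (s > 0) qp else qn)
    },
    ADD1_m = {
      q <- 0.5 * (vm_pdf(grid$points, -params$theta_exp, km) +
                  vm_pdf(grid$points,  params$theta_exp, km))
      matrix(q, n, length(theta_acts))
    },
    ADD2_m = {
      qp <- vm_pdf(grid$points,  params$theta_exp, km)
      qn <- vm_pdf(grid$points, -params$theta_exp, km)
      sapply(side, function(s) if (s > 0) qp else qn)
    },
    stop("not a response-strategy family"))
  ucol <- sapply(theta_acts, function(a) rotate_kernel(u0, a, grid))
  w * qcol + (1 - w) * ((1 - params$alpha) * ucol + params$alpha / 360)
}

#' Response distribution of the Bayesian observer
#'
#' Density per degree of the reported estimate given the true direction,
#' for the Bayesian families: the measurement distribution is marginalized
#' over, each measurement is mapped to its posterior-mean percept, motor
#' noise is convolved in, and a uniform lapse of weight `alpha` is mixed.
#'
#' @param theta_est Estimate angle(s) in degrees.
#' @param theta_act True direction in degrees (scalar).
#' @param spec A Bayesian-family [model_spec()].
#' @param params An [observer_params()] object.
#' @param grid_step Grid spacing in degrees.
#' @param stages Measurement cascade stages (2 default, 1 collapses).
#' @return Density per degree at `theta_est` (integrates to 1 over the circle).
#' @export
response_pdf <- function(theta_est, theta_act, spec = model_spec("BAYES"),
                         params, grid_step = 0.5, stages = 2) {
  if (!spec$bayesian) stop("use add_response_pdf() for response-strategy models")
  grid <- angle_grid(grid_step)
  cur <- response_curves(spec, params, theta_act, grid, stages)
  grid_interp(cur[, 1], theta_est, grid)
}

#' Response distribution of the response-strategy models
#'
#' Density per degree of the reported estimate for the ADD family: with
#' probability `w` the response is drawn from the expectation distribution
#' (the full prior for `ADD1`; the prior truncated to the stimulus side and
#' renormalized for `ADD2`; the prior mode(s) blurred only by motor noise
#' for `ADD1_m`/`ADD2_m`), otherwise it is an unbiased estimate centered on
#' the stimulus with sensory-plus-motor noise and a uniform lapse `alpha`.
#' A true direction of exactly 0 is assigned to the positive side.
#'
#' @inheritParams response_pdf
#' @param spec An ADD-family [model_spec()].
#' @return Density per degree at `theta_est`.
#' @export
add_response_pdf <- function(theta_est, theta_act, spec, params,
                             grid_step = 0.5) {
  if (spec$bayesian) stop("use response_pdf() for Bayesian models")
  grid <- angle_grid(grid_step)
  cur <- response_curves(spec, params, theta_act, grid)
  grid_interp(cur[, 1], theta_est, grid)
}
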