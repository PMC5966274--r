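# Shared fixtures: canonical observer parameters (the group means reported
# for the task) and small builders for synthetic trial tables.

group_mean_params <- function(w = NULL) {
  observer_params(theta_exp = 40, sigma_exp = 15, sigma_sens = 10,
                  alpha = 0.06, sigma_m = 10, w = w)
}

# estimation-only trial table from the generative chain
make_est_trials <- function(params, n = 200, seed = 1,
                            spec = model_spec("BAYES"), angles = NULL) {
  th <- if (is.null(angles)) {
    visprior:::recovery_angles(n, seed)
  } else {
    rep_len(angles, n)
  }
  e <- visprior:::with_seed(seed, visprior:::sample_estimates(params, th, spec))
  data.frame(theta_act_deg = th, theta_est_deg = e)
}

# independent O(n^2) Kendall tau-b oracle (no package code)
tau_b_oracle <- function(x, y) {
  n <- length(x)
  C <- D <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    s <- sign(x[j] - x[i]) * sign(y[j] - y[i])
    if (s > 0) C <- C + 1 else if (s < 0) D <- D + 1
  }
  tx <- table(x); ty <- table(y)
  n0 <- choose(n, 2)
  (C - D) / sqrt((n0 - sum(choose(tx[tx > 1], 2))) *
                 (n0 - sum(choose(ty[ty > 1], 2))))
}

# independent von Mises density (degrees), for plug-in oracles
vm_oracle <- function(theta, mu, kappa) {
  exp(kappa * (cos((theta - mu) * pi / 180) - 1)) /
    (360 * besselI(kappa, 0, expon.scaled = TRUE))
}
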