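make_session <- function(params, seed, ...) {
  simulate_observer(params, make_schedule(seed), seed = seed, ...)
}

test_that("inclusion criteria separate competent from degenerate observers", {
  # low-lapse observer: clearly inside both high-contrast benchmarks
  pgood <- observer_params(40, 15, 10, 0.01, 8)
  p <- group_mean_params()
  inc <- apply_inclusion(make_session(pgood, 21))
  expect_true(inc$included)
  expect_identical(inc$reason, "")
  # analysis set: post-convergence, staircased, validated and detected only
  expect_true(all(inc$trials$trial_index > 170))
  expect_true(all(inc$trials$condition %in% c("low41", "low21")))
  expect_true(all(inc$trials$detected & inc$trials$validated))
  # uniform random estimator: circular RMSE ~ 103.9 >> 30
  tr <- make_session(p, 22)
  tr$theta_est_deg <- wrap_angle(runif(nrow(tr), -180, 180))
  inc2 <- apply_inclusion(tr)
  expect_false(inc2$included)
  expect_match(inc2$reason, "RMSE")
  expect_gt(inc2$rmse, 80)
  # detection below the 80% threshold
  tr3 <- make_session(p, 23)
  hi <- which(tr3$condition == "high")
  tr3$detected[hi] <- rep(c(TRUE, FALSE), c(ceiling(0.79 * length(hi)),
                                            floor(0.21 * length(hi)) + 1))[seq_along(hi)]
  inc3 <- apply_inclusion(tr3)
  expect_false(inc3$included)
  expect_match(inc3$reason, "detection")
  expect_error(apply_inclusion(tr3[tr3$condition != "high", ]), "high-contrast")
})

test_that("motor pre-fit recovers the motor dispersion and lapse rate", {
  set.seed(31)
  n <- 4000
  th <- runif(n, -180, 180)
  alpha <- 0.05
  lapse <- runif(n) < alpha
  est <- wrap_angle(th + rvm(n, 0, sigma_to_kappa(10)))
  est[lapse] <- runif(sum(lapse), -180, 180)
  hi <- data.frame(theta_act_deg = th, theta_est_deg = est)
  m <- fit_motor(hi)
  expect_lt(abs(m$sigma_m - 10), 0.5)
  expect_lt(abs(m$alpha - alpha), 0.02)
  expect_error(fit_motor(hi[1:10, ]), ">= 20")
  # zero-error responses drive the dispersion to its lower bound
  m0 <- fit_motor(data.frame(theta_act_deg = th[1:200], theta_est_deg = th[1:200]))
  expect_lt(m0$sigma_m, 1)
  expect_lt(m0$alpha, 0.01)
  # pure-uniform responses are all lapse
  mu <- fit_motor(data.frame(theta_act_deg = th[1:2000],
                             theta_est_deg = runif(2000, -180, 180)))
  expect_gt(mu$alpha, 0.8)
})

test_that("model fitting recovers generating parameters and satisfies the BIC identity", {
  p <- group_mean_params()
  tr <- make_est_trials(p, n = 1000, seed = 41)
  f <- fit_model(tr, model_spec("BAYES"), sigma_m = 10)
  expect_equal(f$bic, -2 * f$loglik + f$k * log(f$n), tolerance = 1e-12)
  expect_equal(f$n, 1000)
  expect_equal(f$k, 4)
  expect_lt(abs(f$estimates[["theta_exp"]] - 40), 6)
  expect_lt(abs(f$estimates[["sigma_exp"]] - 15), 5)
  expect_lt(abs(f$estimates[["sigma_sens"]] - 10), 2)
  expect_lt(abs(f$estimates[["alpha"]] - 0.06), 0.03)
  # stationarity: restarting the simplex at the solution does not improve it
  b <- visprior:::param_bounds(f$spec)
  nll0 <- -f$loglik
  refit <- optim(visprior:::to_unbounded(unname(f$estimates), b$lb, b$ub),
                 function(t) {
                   x <- visprior:::to_bounded(t, b$lb, b$ub)
                   pp <- visprior:::unpack_params(x, f$spec, 10)
                   g <- angle_grid(0.5)
                   ua <- sort(unique(tr$theta_act_deg))
                   cur <- visprior:::response_curves(f$spec, pp, ua, g)
                   idx <- visprior:::grid_interp_index(tr$theta_est_deg, g)
                   grp <- match(tr$theta_act_deg, ua)
                   d <- cur[cbind(idx$i1, grp)] * (1 - idx$w) +
                     cur[cbind(idx$i2, grp)] * idx$w
                   -sum(log(pmax(d, 1e-300)))
                 }, method = "Nelder-Mead",
                 control = list(maxit = 300, reltol = 1e-10))
  expect_gt(refit$value, nll0 - 0.01)
})

test_that("nested likelihood ordering holds across the Bayesian families", {
  p <- group_mean_params()
  tr <- make_est_trials(p, n = 300, seed = 42)
  fb <- fit_model(tr, model_spec("BAYES"), sigma_m = 10)
  fvm <- fit_model(tr, model_spec("BAYES_varmin"), sigma_m = 10)
  fv <- fit_model(tr, model_spec("BAYES_var"), sigma_m = 10, n_polish = 2)
  expect_gte(fvm$loglik, fb$loglik - 1e-3)
  expect_gte(fv$loglik, fvm$loglik - 0.05)  # 8-par simplex tolerance
  expect_error(fit_model(tr[1:5, ], model_spec("BAYES"), sigma_m = 10),
               "too few")
})

test_that("per-angle lapse mixture fit recovers bias, dispersion and shared lapse", {
  set.seed(51)
  # one angle, known offset: mu = 38 at theta_act = 32 -> bias 6
  n <- 1e4
  est <- wrap_angle(rvm(n, 38, sigma_to_kappa(12)))
  tr <- data.frame(theta_act_deg = rep(32, n), theta_est_deg = est)
  fit <- per_angle_mixture_fit(tr)
  expect_lt(abs(fit$per_angle$bias - 6), 0.5)
  expect_lt(abs(fit$per_angle$sd - 12), 0.6)
  # shared lapse across two angles
  n2 <- 5000
  mk <- function(mu) {
    e <- wrap_angle(rvm(n2, mu, sigma_to_kappa(10)))
    lapse <- runif(n2) < 0.5
    e[lapse] <- runif(sum(lapse), -180, 180)
    e
  }
  tr2 <- data.frame(theta_act_deg = rep(c(-32, 32), each = n2),
                    theta_est_deg = c(mk(-32), mk(32)))
  fit2 <- per_angle_mixture_fit(tr2)
  expect_lt(abs(fit2$alpha - 0.5), 0.05)
  # zero-noise data
  tr0 <- data.frame(theta_act_deg = rep(16, 50), theta_est_deg = rep(16, 50))
  fit0 <- per_angle_mixture_fit(tr0)
  expect_lt(abs(fit0$per_angle$bias), 0.01)
  expect_lt(fit0$per_angle$sd, 0.5)
  # sparse angles skipped with a warning
  tr3 <- rbind(tr0, data.frame(theta_act_deg = rep(48, 3),
                               theta_est_deg = rep(48, 3)))
  expect_warning(per_angle_mixture_fit(tr3), "skipping")
})
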