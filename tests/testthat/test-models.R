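test_that("the learned prior is a normalized, symmetric bimodal mixture", {
  p <- group_mean_params()
  g <- seq(-180 + 0.1, 180, by = 0.1)
  expect_lt(abs(sum(prior_density(g, p)) * 0.1 - 1), 1e-6)
  expect_equal(prior_density(32, p), prior_density(-32, p))
  # uniform limit
  pflat <- observer_params(40, Inf, 10, 0.06, 10)
  expect_equal(prior_density(c(-90, 0, 45), pflat), rep(1 / 360, 3))
  # plug-in oracle for the mixture at theta_exp = 32, sigma_exp = 15
  p32 <- observer_params(32, 15, 10, 0, 10)
  ke <- (180 / (pi * 15))^2
  oracle <- 0.5 * (vm_oracle(c(0, 32), -32, ke) + vm_oracle(c(0, 32), 32, ke))
  expect_equal(prior_density(c(0, 32), p32), oracle, tolerance = 1e-12)
})

test_that("posterior-mean percept matches a fine-grid quadrature oracle", {
  p <- observer_params(32, 15, 10, 0, 10)
  # independent 0.01-degree oracle
  gf <- seq(-180 + 0.01, 180, by = 0.01)
  ke <- (180 / (pi * 15))^2
  ks <- (180 / (pi * 10))^2
  oracle <- function(ts) {
    post <- 0.5 * (vm_oracle(gf, -32, ke) + vm_oracle(gf, 32, ke)) *
      vm_oracle(ts, gf, ks)
    z <- sum(post * exp(1i * gf * pi / 180))
    Arg(z) * 180 / pi
  }
  for (ts in c(-150, -60, -20, 5, 20, 45, 90)) {
    expect_equal(posterior_mean(ts, p), oracle(ts), tolerance = 0.02)
  }
  # flat prior: percept equals the measurement
  pflat <- observer_params(40, Inf, 10, 0, 10)
  expect_equal(posterior_mean(c(-120, -15, 33), pflat), c(-120, -15, 33),
               tolerance = 1e-6)
  # symmetric posterior at 0: tie resolved to the measurement
  expect_equal(posterior_mean(0, p), 0, tolerance = 1e-8)
})

test_that("percept map attracts measurements toward the nearer prior mode", {
  p <- observer_params(32, 15, 10, 0, 10)
  for (ts in c(5, 16, 20, 45, 60)) {
    tp <- posterior_mean(ts, p)
    lo <- min(ts, 32); hi <- max(ts, 32)
    expect_gte(tp, lo)
    expect_lte(tp, hi)
    if (ts != 32) expect_gt(abs(tp - ts), 0)  # strict pull
  }
})

test_that("every model family's response distribution integrates to 1", {
  g <- angle_grid(0.5)
  set.seed(7)
  for (fam in c("BAYES", "BAYES_varmin", "BAYES_var",
                "ADD1", "ADD2", "ADD1_m", "ADD2_m")) {
    sp <- model_spec(fam)
    for (rep in 1:3) {
      ss <- switch(fam, BAYES_varmin = runif(2, 5, 30),
                   BAYES_var = runif(5, 5, 30), runif(1, 5, 30))
      pp <- observer_params(runif(1, 20, 60), runif(1, 6, 26), ss,
                            runif(1, 0, 0.3), runif(1, 5, 20),
                            w = if (sp$bayesian) NULL else runif(1))
      cur <- visprior:::response_curves(sp, pp, c(-32, 0, 16), g)
      expect_lt(max(abs(colSums(cur) * g$step - 1)), 1e-4)
      expect_true(all(cur >= 0))
    }
  }
})

test_that("lapse-only and noiseless limits behave as expected", {
  sp <- model_spec("BAYES")
  p1 <- observer_params(40, 15, 10, 1, 10)
  expect_equal(response_pdf(c(-90, 0, 77), 16, sp, p1), rep(1 / 360, 3),
               tolerance = 1e-9)
  # near-noiseless: mass concentrates at theta_act
  p0 <- observer_params(40, Inf, 0.5, 0, 0.5)
  g <- angle_grid(0.5)
  cur <- response_pdf(g$points, 16, sp, p0)
  inside <- abs(wrap_angle(g$points - 16)) <= 2.5
  expect_gt(sum(cur[inside]) * g$step, 0.99)
})

test_that("response distribution matches a Monte-Carlo simulation of the generative chain", {
  p <- group_mean_params()
  sp <- model_spec("BAYES")
  set.seed(99)
  draws <- visprior:::sample_estimates(p, rep(16, 2e5), sp)
  br <- seq(-180, 180, by = 8)
  h <- hist(draws, breaks = br, plot = FALSE)
  mids <- h$mids
  pdfv <- response_pdf(mids, 16, sp, p)
  pbin <- pdfv * 8
  se <- sqrt(pbin * (1 - pbin) / 2e5) / 8
  expect_lt(max(abs(h$density - pdfv) / pmax(se, 1e-9)), 4)
})

test_that("tied sensory noise collapses the variable-likelihood families onto BAYES", {
  g <- angle_grid(0.5)
  base <- observer_params(40, 15, 10, 0.06, 10)
  v2 <- observer_params(40, 15, c(10, 10), 0.06, 10)
  v5 <- observer_params(40, 15, rep(10, 5), 0.06, 10)
  angs <- design_angles()
  c0 <- visprior:::response_curves(model_spec("BAYES"), base, angs, g)
  expect_equal(visprior:::response_curves(model_spec("BAYES_varmin"), v2, angs, g),
               c0, tolerance = 1e-12)
  expect_equal(visprior:::response_curves(model_spec("BAYES_var"), v5, angs, g),
               c0, tolerance = 1e-12)
})

test_that("model-implied bias is attractive and antisymmetric; SD dips at the modes", {
  p <- observer_params(32, 15, 12, 0, 8)
  g <- angle_grid(0.5)
  sp <- model_spec("BAYES")
  angs <- design_angles()
  cur <- visprior:::response_curves(sp, p, angs, g)
  stat <- sapply(seq_along(angs), function(j) {
    z <- sum(cur[, j] * exp(1i * g$points * pi / 180)) * g$step
    mu <- Arg(z) * 180 / pi
    c(bias = wrap_angle(mu - angs[j]), sd = sqrt(-2 * log(Mod(z))) * 180 / pi)
  })
  bias <- stat["bias", ]; sdv <- stat["sd", ]
  names(bias) <- names(sdv) <- angs
  # attraction toward +/-32
  expect_gt(bias[["16"]], 0.5)
  expect_lt(bias[["48"]], -0.5)
  expect_lt(bias[["64"]], -0.5)
  # antisymmetry under reflection
  expect_equal(bias[["-16"]], -bias[["16"]], tolerance = 1e-6)
  expect_equal(bias[["-48"]], -bias[["48"]], tolerance = 1e-6)
  # reduced variability at the frequent directions relative to the
  # non-mode average (percepts near +/-16 split across the prior trough,
  # inflating SD there; beyond the modes one-sided compression keeps SD low)
  expect_lte(sdv[["32"]], sdv[["16"]])
  expect_lt(sdv[["32"]], mean(sdv[names(sdv) %in% c("-64", "-48", "-16", "0",
                                                    "16", "48", "64")]))
})

test_that("response-strategy mixtures: limits, truncation and mode readout", {
  g <- angle_grid(0.5)
  # w = 0: identical to the unbiased sensory branch for every ADD family
  p0 <- observer_params(40, 15, 10, 0.06, 10, w = 0)
  u <- visprior:::response_curves(model_spec("ADD1"), p0, 16, g)
  for (fam in c("ADD2", "ADD1_m", "ADD2_m")) {
    expect_equal(visprior:::response_curves(model_spec(fam), p0, 16, g), u,
                 tolerance = 1e-12)
  }
  # ADD2 truncation: expectation branch lives on the stimulus side only
  p1 <- observer_params(40, 15, 10, 0, 10, w = 1)
  q <- visprior:::response_curves(model_spec("ADD2"), p1, 16, g)[, 1]
  expect_lt(sum(q[g$points <= 0]) * g$step, 1e-9)
  expect_equal(sum(q[g$points > 0]) * g$step, 1, tolerance = 1e-6)
  # theta_act = 0 is assigned to the positive side
  q0 <- visprior:::response_curves(model_spec("ADD2"), p1, 0, g)[, 1]
  expect_equal(q, q0, tolerance = 1e-12)
  # ADD2_m, w = 1, small motor noise: mass near the stimulus-side mode
  pm <- observer_params(40, 15, 10, 0, 2, w = 1)
  qm <- visprior:::response_curves(model_spec("ADD2_m"), pm, 16, g)[, 1]
  expect_gt(sum(qm[abs(g$points - 40) <= 8]) * g$step, 0.99)
  # ADD1_m splits mass between both modes
  q1m <- visprior:::response_curves(model_spec("ADD1_m"), pm, 16, g)[, 1]
  expect_equal(sum(q1m[abs(g$points - 40) <= 8]) * g$step, 0.5, tolerance = 1e-3)
  expect_equal(sum(q1m[abs(g$points + 40) <= 8]) * g$step, 0.5, tolerance = 1e-3)
})

test_that("free-parameter counts follow the family definitions", {
  ks <- vapply(c("BAYES", "BAYES_varmin", "BAYES_var", "ADD1", "ADD2",
                 "ADD1_m", "ADD2_m"), function(f) model_spec(f)$k, numeric(1))
  expect_equal(unname(ks), c(4, 5, 8, 5, 5, 4, 4))
})
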