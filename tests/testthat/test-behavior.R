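test_that("p_rel is calibrated to 1 under uniform responding and 11.25 at the modes", {
  u <- seq(-180 + 0.05, 180, by = 0.1)
  expect_equal(p_rel(u), 1, tolerance = 0.01)
  expect_equal(p_rel(rep(32, 50)), 11.25)
  expect_equal(p_rel(rep(-32, 50)), 11.25)
  # mass fully inside both 8-degree windows also attains the maximum
  expect_equal(p_rel(c(rep(-30, 10), rep(35, 10))), 11.25)
  # sign-flip invariance
  set.seed(1)
  x <- runif(500, -180, 180)
  expect_equal(p_rel(x), p_rel(-x))
  expect_error(p_rel(numeric(0)), "empty")
})

test_that("hallucination window fractions are monotone and match the window measure", {
  expect_equal(unname(hallucination_windows(rep(32, 9))), c(1, 1, 1))
  u <- seq(-180 + 0.05, 180, by = 0.1)
  expect_equal(unname(hallucination_windows(u)),
               c(32, 64, 96) / 360, tolerance = 0.01)
  set.seed(2)
  w <- hallucination_windows(runif(2000, -180, 180))
  expect_true(all(diff(w) >= 0))
})

test_that("window fractions of prior-distributed hallucinations match quadrature", {
  # draws from the bimodal expectation with sigma_exp = 15 vs numeric
  # integrals of the same density over the windows
  p <- observer_params(32, 15, 10, 0, 10)
  set.seed(3)
  n <- 2e4
  draws <- wrap_angle(rvm(n, 0, sigma_to_kappa(15)) +
                      sample(c(-32, 32), n, TRUE))
  w <- hallucination_windows(draws)
  quad <- vapply(c(8, 16, 24), function(win) {
    f <- function(t) prior_density(t, p)
    integrate(f, 32 - win, 32 + win)$value +
      integrate(f, -32 - win, -32 + win)$value
  }, numeric(1))
  se <- sqrt(quad * (1 - quad) / n)
  expect_true(all(abs(w - quad) < 3 * se + 1e-3))
})

test_that("no-stimulus summaries count hallucinations correctly", {
  p <- group_mean_params()
  tr <- simulate_observer(p, make_schedule(7), seed = 7, p_hallucinate = 0.2)
  ns <- nostim_summary(tr)
  manual <- sum(tr$condition == "none" & tr$detected & tr$validated &
                !is.na(tr$theta_est_deg))
  expect_equal(ns$n_hallucinations, manual)
  expect_equal(length(ns$estimate_angles), manual)
  expect_true(ns$p_rel >= 0)
})

test_that("group curves flag reduced variability at the frequent directions", {
  # small synthetic cohort at the group-mean parameters
  p <- group_mean_params()
  per_subject <- lapply(1:12, function(i) {
    tr <- make_est_trials(p, n = 230, seed = 200 + i)
    per_angle_mixture_fit(tr, min_per_angle = 5)
  })
  grp <- group_bias_variability(per_subject)
  expect_equal(grp$angles, design_angles())
  expect_lt(mean(grp$sd_at_modes), mean(grp$sd_elsewhere))
  # attraction: positive bias below +32, negative beyond it (mirror image)
  expect_gt(grp$bias_mean[grp$angles == 16], 0)
  expect_lt(grp$bias_mean[grp$angles == -16], 0)
  expect_lt(grp$bias_mean[grp$angles == 64], 0)
  expect_gt(grp$bias_mean[grp$angles == -64], 0)
  expect_error(group_bias_variability(per_subject[1]), "2 subjects")
})

test_that("within-subject standard errors vanish for identical subjects", {
  mat <- matrix(rep(c(1, 3, 5, 4), each = 6), nrow = 6)
  expect_equal(unname(visprior:::within_subject_se(mat)), rep(0, 4))
})
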