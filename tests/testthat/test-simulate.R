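test_that("lapse-only observers respond uniformly", {
  p <- observer_params(40, 15, 10, 1, 10)
  set.seed(1)
  e <- visprior:::sample_estimates(p, rep(32, 2e4))
  h <- hist(e, breaks = seq(-180, 180, by = 20), plot = FALSE)
  expect_gt(chisq.test(h$counts)$p.value, 0.01)
})

test_that("near-noiseless observers reproduce the stimulus direction", {
  p <- observer_params(40, Inf, 0.5, 0, 0.5)
  set.seed(2)
  th <- rep(design_angles(), 5)
  e <- visprior:::sample_estimates(p, th)
  expect_lt(max(abs(wrap_angle(e - th))), 4)
})

test_that("simulated estimates agree with the analytic response distribution", {
  p <- group_mean_params()
  set.seed(3)
  for (fam in c("BAYES", "ADD2")) {
    sp <- model_spec(fam)
    pp <- if (sp$bayesian) p else group_mean_params(w = 0.4)
    e <- visprior:::sample_estimates(pp, rep(-32, 1e5), sp)
    br <- seq(-180, 180, by = 10)
    h <- hist(e, breaks = br, plot = FALSE)
    pdfv <- if (sp$bayesian) {
      response_pdf(h$mids, -32, sp, pp)
    } else {
      add_response_pdf(h$mids, -32, sp, pp)
    }
    pbin <- pdfv * 10
    se <- sqrt(pbin * (1 - pbin) / 1e5) / 10
    expect_lt(max(abs(h$density - pdfv) / pmax(se, 1e-9)), 4.5)
  }
})

test_that("a simulated session carries well-formed trial records", {
  p <- group_mean_params()
  tr <- simulate_observer(p, make_schedule(4), seed = 4, p_miss_validate = 0.1)
  expect_equal(nrow(tr), 567)
  expect_true(all(is.na(tr$theta_est_deg[!tr$validated])))
  expect_true(all(!is.na(tr$theta_est_deg[tr$validated])))
  expect_true(all(!is.na(tr$detected)))
  expect_true(any(!tr$validated))
  # high-contrast detection is near ceiling; no-stimulus detection is rare
  expect_gt(mean(tr$detected[tr$condition == "high"]), 0.95)
  expect_lt(mean(tr$detected[tr$condition == "none"]), 0.35)
  # determinism
  expect_identical(tr, simulate_observer(p, make_schedule(4), seed = 4,
                                         p_miss_validate = 0.1))
})

test_that("hallucinated estimates cluster near the prior modes", {
  p <- group_mean_params()
  est <- unlist(lapply(1:8, function(i) {
    tr <- simulate_observer(p, make_schedule(i), seed = 100 + i,
                            p_hallucinate = 0.3)
    ns <- tr[tr$condition == "none" & tr$detected & tr$validated, ]
    ns$theta_est_deg
  }))
  expect_gt(length(est), 200)
  frac24 <- hallucination_windows(est)[["within_24"]]
  expect_gt(frac24, 2 * 96 / 360)  # far above the uniform measure
})

test_that("cohorts honor degenerate spreads and trait links", {
  sds0 <- c(theta_exp = 0, sigma_exp = 0, sigma_sens = 0, alpha = 0, sigma_m = 0)
  cs <- cohort_spec(3, sds = sds0)
  truth <- visprior:::sample_cohort_params(cs, 1)
  expect_equal(truth$sigma_sens, rep(10, 3))
  expect_equal(truth$theta_exp, rep(40, 3))
  expect_error(cohort_spec(0), "n_subjects")
  # trait link: configured latent correlation is recovered in a large sample
  cs2 <- cohort_spec(600, trait_model = list(target = "sigma_sens", rho = -0.3))
  t2 <- visprior:::sample_cohort_params(cs2, 5)
  expect_true("AQ" %in% names(t2))
  expect_lt(abs(cor(t2$AQ, t2$sigma_sens) - (-0.3)), 0.1)
})

test_that("low-trial cohort simulation yields the requested trial counts", {
  cs <- cohort_spec(3)
  sim <- simulate_cohort(cs, seed = 9, trials = "low", n_trials = 120)
  expect_equal(nrow(sim$trials), 3 * 120)
  expect_equal(sort(unique(sim$trials$subject_id)), 1:3)
  expect_true(all(sim$trials$theta_act_deg %in% design_angles()))
  expect_equal(nrow(sim$truth), 3)
})
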