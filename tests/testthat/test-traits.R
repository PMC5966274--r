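test_that("robust correlation equals 1 on exact linear data and resists outliers", {
  x <- 1:30
  rc <- robust_corr(x, 2 * x + 5)
  expect_equal(rc$robust_r, 1, tolerance = 1e-6)
  expect_lt(rc$p, 1e-10)
  # near-noiseless data: matches Pearson's r
  set.seed(4)
  y <- x + rnorm(30, sd = 1e-4)
  expect_equal(robust_corr(x, y)$robust_r, cor(x, y), tolerance = 1e-4)
  # one gross outlier: the robust slope stays much closer to 1 than OLS
  set.seed(5)
  x2 <- rnorm(50); y2 <- x2
  y2[7] <- 40
  rc2 <- robust_corr(x2, y2)
  expect_lt(abs(rc2$robust_r - 1), abs(cor(x2, y2) - 1))
  expect_error(robust_corr(rep(1, 20), rnorm(20)), "variance")
  expect_error(robust_corr(1:5, 1:5), "n >= 10")
})

test_that("tau-b matches the brute-force pair-counting oracle, with ties", {
  expect_equal(kendall_tau_b(c(1, 2, 2, 3), c(1, 2, 3, 3))$tau_b,
               tau_b_oracle(c(1, 2, 2, 3), c(1, 2, 3, 3)),
               tolerance = 1e-12)
  set.seed(6)
  for (i in 1:100) {
    n <- sample(5:30, 1)
    x <- sample(1:6, n, replace = TRUE)
    y <- sample(1:6, n, replace = TRUE)
    if (length(unique(x)) < 2 || length(unique(y)) < 2) next
    expect_equal(kendall_tau_b(x, y)$tau_b, tau_b_oracle(x, y),
                 tolerance = 1e-12)
  }
  # perfectly concordant and reversal antisymmetry
  expect_equal(kendall_tau_b(1:10, (1:10)^2)$tau_b, 1)
  x <- rnorm(20); y <- rnorm(20)
  expect_equal(kendall_tau_b(x, -y)$tau_b, -kendall_tau_b(x, y)$tau_b)
  expect_error(kendall_tau_b(rep(2, 8), 1:8), "tied")
})

test_that("tau-b p-values agree with the standard reference implementation", {
  set.seed(7)
  # exact small-sample case, no ties
  x <- rnorm(9); y <- rnorm(9)
  kt <- kendall_tau_b(x, y)
  ref <- cor.test(x, y, method = "kendall", exact = TRUE)
  expect_equal(kt$p, ref$p.value, tolerance = 1e-10)
  expect_equal(kt$tau_b, unname(ref$estimate), tolerance = 1e-12)
  # tied case: normal approximation with tie-corrected variance
  x2 <- sample(1:5, 40, replace = TRUE)
  y2 <- sample(1:5, 40, replace = TRUE)
  ref2 <- cor.test(x2, y2, method = "kendall", exact = FALSE)
  expect_equal(kendall_tau_b(x2, y2)$p, ref2$p.value, tolerance = 1e-8)
})

test_that("the trait battery detects a built-in trait link and not a null one", {
  cs <- cohort_spec(300, trait_model = list(target = "sigma_sens", rho = -0.45))
  truth <- visprior:::sample_cohort_params(cs, 8)
  measures <- truth[, c("subject_id", "theta_exp", "sigma_exp", "sigma_sens",
                        "alpha", "sigma_m")]
  traits <- truth[, c("subject_id", "AQ")]
  bat <- trait_battery(measures, traits)
  row_s <- bat[bat$measure == "sigma_sens" & bat$trait == "AQ", ]
  row_e <- bat[bat$measure == "sigma_exp" & bat$trait == "AQ", ]
  expect_lt(row_s$robust_r, -0.3)
  expect_lt(row_s$bonferroni_adjusted_p, 0.05)
  expect_gt(row_e$robust_p, 0.05)
  # Bonferroni factor 4, primary rows only
  expect_equal(row_s$bonferroni_adjusted_p, min(1, 4 * row_s$robust_p))
  expect_true(is.na(bat$bonferroni_adjusted_p[bat$measure == "alpha"][1]))
  # shuffled traits: association vanishes
  set.seed(9)
  traits$AQ <- sample(traits$AQ)
  bat2 <- trait_battery(measures, traits)
  expect_lt(max(abs(bat2$robust_r)), 0.3)
})

test_that("measure collection assembles behavioral and model summaries by subject", {
  p <- group_mean_params()
  trials <- do.call(rbind, lapply(1:2, function(i) {
    tr <- simulate_observer(p, make_schedule(i), seed = 300 + i)
    tr$subject_id <- i
    tr
  }))
  per_angle <- lapply(1:2, function(i) {
    inc <- apply_inclusion(trials[trials$subject_id == i, ])
    per_angle_mixture_fit(inc$trials, min_per_angle = 5)
  })
  names(per_angle) <- c("1", "2")
  m <- collect_measures(per_angle = per_angle, trials = trials)
  expect_equal(nrow(m), 2)
  expect_true(all(c("mean_abs_bias", "mean_sd", "n_hallucinations") %in% names(m)))
  expect_true(all(is.finite(m$mean_sd)))
})
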