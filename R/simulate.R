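# Simulated observers and cohorts.

# Draw estimates from a model's generative chain for a vector of true
# directions. Sampling follows the chain literally, so the empirical
# distribution converges on response_curves().
sample_estimates <- function(params, theta_acts, spec = model_spec("BAYES"),
                             stages = 2, grid_step = 0.5) {
  n <- length(theta_acts)
  if (n == 0) return(numeric(0))
  km <- sigma_to_kappa(params$sigma_m)
  if (spec$bayesian) {
    grid <- angle_grid(grid_step)
    pr <- prior_density(grid$points, params)
    sig_s <- sigma_sens_for(params, theta_acts)
    est <- numeric(n)
    for (s in unique(sig_s)) {
      ii <- which(sig_s == s)
      ks <- sigma_to_kappa(s)
      lik_fft <- stats::fft(vm_pdf(grid$disp, 0, ks))
      zn <- percept_map_z(pr, lik_fft, grid)
      theta_t <- wrap_angle(theta_acts[ii] + rvm(length(ii), 0, ks))
      theta_sens <- if (stages == 2) {
        wrap_angle(theta_t + rvm(length(ii), 0, ks))
      } else {
        theta_t
      }
      theta_perc <- interp_percept(zn, theta_sens, grid)
      est[ii] <- wrap_angle(theta_perc + rvm(length(ii), 0, km))
    }
  } else {
    w <- params$w
    ks <- sigma_to_kappa(params$sigma_sens[1])
    ke <- sigma_to_kappa(params$sigma_exp)
    side <- ifelse(wrap_angle(theta_acts) >= 0, 1, -1)
    from_prior <- stats::runif(n) < w
    est <- numeric(n)
    np <- sum(from_prior)
    if (np > 0) {
      est[from_prior] <- switch(spec$family,
        ADD1 = rvm(np, 0, ke) + sample(c(-1, 1), np, TRUE) * params$theta_exp,
        ADD2 = {
          # prior truncated to the stimulus side: rejection on the sign
          s <- side[from_prior]
          x <- numeric(np)
          todo <- seq_len(np)
          while (length(todo)) {
            cand <- wrap_angle(rvm(length(todo), 0, ke) +
                               sample(c(-1, 1), length(todo), TRUE) * params$theta_exp)
            ok <- sign(cand) == s[todo] | (cand == 180 & s[todo] > 0)
            x[todo[ok]] <- cand[ok]
            todo <- todo[!ok]
          }
          x
        },
        ADD1_m = sample(c(-1, 1), np, TRUE) * params$theta_exp + rvm(np, 0, km),
        ADD2_m = side[from_prior] * params$theta_exp + rvm(np, 0, km))
      est[from_prior] <- wrap_angle(est[from_prior])
    }
    ns <- sum(!from_prior)
    if (ns > 0) {
      est[!from_prior] <- wrap_angle(theta_acts[!from_prior] +
                                     rvm(ns, 0, ks) + rvm(ns, 0, km))
    }
    # lapse applies to the sensory branch only (see add_response_pdf)
    lapse <- !from_prior & stats::runif(n) < params$alpha
    est[lapse] <- wrap_angle(stats::runif(sum(lapse), -180, 180))
    return(est)
  }
  lapse <- stats::runif(n) < params$alpha
  est[lapse] <- wrap_angle(stats::runif(sum(lapse), -180, 180))
  est
}

# unit-modulus complex percept map (NA modulus ties resolved to theta_sens)
percept_map_z <- function(prior_vec, lik_fft, grid) {
  f <- prior_vec * exp(1i * grid$points * pi / 180)
  z <- circ_conv_fft_c(f, lik_fft, grid$step)
  m <- Mod(z)
  tie <- m < 1e-12
  zn <- z
  zn[!tie] <- z[!tie] / m[!tie]
  zn[tie] <- exp(1i * grid$points[tie] * pi / 180)
  zn
}

# circularly safe interpolation of the percept map at arbitrary measurements
interp_percept <- function(zn, theta_sens, grid) {
  idx <- grid_interp_index(theta_sens, grid)
  z <- zn[idx$i1] * (1 - idx$w) + zn[idx$i2] * idx$w
  small <- Mod(z) < 1e-6
  out <- wrap_angle(Arg(z) * 180 / pi)
  out[small] <- wrap_angle(theta_sens[small])
  out
}

#' Simulate one observer through a session
#'
#' Plays a schedule through a generative observer. Stimulus-present
#' estimates are i.i.d. draws from the model's response distribution
#' (Bayesian chain or response-strategy chain). Detection on staircased
#' trials comes from the staircase simulation; on high-contrast trials from
#' `detect_model(high contrast)`. On no-stimulus trials the observer
#' hallucinates (reports detection) with probability `p_hallucinate`; a
#' hallucinated direction is generated by drawing the measurement from the
#' observer's own prior and passing it through the usual
#' posterior/motor/lapse chain, which clusters hallucinations near the
#' prior modes. Estimates on undetected no-stimulus trials are uniform.
#'
#' @param params An [observer_params()] object.
#' @param schedule Schedule data.frame; if it has no `contrast` column the
#'   staircases are run first (seed derived from `seed`).
#' @param spec A [model_spec()]; default BAYES.
#' @param seed Integer seed.
#' @param detect_model Detection model used for staircases/high trials.
#' @param p_hallucinate Per-trial probability of a false detection on
#'   no-stimulus trials.
#' @param p_miss_validate Probability that an estimate is not validated in
#'   time (dropout), default 0.
#' @param stages Measurement cascade stages for the Bayesian chain.
#' @param grid_step Grid spacing in degrees.
#' @return A trial data.frame with columns `trial_index`, `condition`,
#'   `theta_act_deg`, `contrast`, `theta_est_deg`, `validated`, `detected`,
#'   `rt_ms`. `theta_est_deg` is present iff `validated`.
#' @export
simulate_observer <- function(params, schedule = make_schedule(seed),
                              spec = model_spec("BAYES"), seed = 1,
                              detect_model = logistic_detect_model(),
                              p_hallucinate = 0.12, p_miss_validate = 0,
                              stages = 2, grid_step = 0.5) {
  if (is.null(schedule$contrast)) {
    schedule <- run_staircases(schedule, detect_model,
                               seed = subject_seed(seed, 1L))
  }
  n <- nrow(schedule)
  cond <- as.character(schedule$condition)
  with_seed(seed, {
    est <- rep(NA_real_, n)
    det <- schedule$detected
    is_high <- cond == "high"
    is_low <- cond %in% c("low41", "low21")
    is_none <- cond == "none"
    km <- sigma_to_kappa(params$sigma_m)
    # high contrast: sensory uncertainty near zero; motor noise plus lapse
    nh <- sum(is_high)
    if (nh > 0) {
      e <- wrap_angle(schedule$theta_act_deg[is_high] + rvm(nh, 0, km))
      lapse <- stats::runif(nh) < params$alpha
      e[lapse] <- wrap_angle(stats::runif(sum(lapse), -180, 180))
      est[is_high] <- e
      det[is_high] <- stats::runif(nh) < detect_model(schedule$contrast[is_high])
    }
    if (any(is_low)) {
      est[is_low] <- sample_estimates(params, schedule$theta_act_deg[is_low],
                                      spec, stages, grid_step)
    }
    nn <- sum(is_none)
    if (nn > 0) {
      det[is_none] <- stats::runif(nn) < p_hallucinate
      e <- wrap_angle(stats::runif(nn, -180, 180))
      hal <- which(is_none)[det[is_none]]
      if (length(hal) > 0) {
        # measurement drawn from the observer's own prior, then the
        # standard posterior-mean / motor / lapse chain
        grid <- angle_grid(grid_step)
        pr <- prior_density(grid$points, params)
        lik_fft <- stats::fft(vm_pdf(grid$disp, 0,
                                     sigma_to_kappa(params$sigma_sens[1])))
        zn <- percept_map_z(pr, lik_fft, grid)
        ts <- rvm(length(hal), 0, sigma_to_kappa(params$sigma_exp)) +
          sample(c(-1, 1), length(hal), TRUE) * params$theta_exp
        tp <- interp_percept(zn, wrap_angle(ts), grid)
        he <- wrap_angle(tp + rvm(length(hal), 0, km))
        lapse <- stats::runif(length(hal)) < params$alpha
        he[lapse] <- wrap_angle(stats::runif(sum(lapse), -180, 180))
        e[match(hal, which(is_none))] <- he
      }
      est[is_none] <- e
    }
    validated <- stats::runif(n) >= p_miss_validate
    est[!validated] <- NA_real_
    data.frame(
      trial_index = schedule$trial_index,
      condition = cond,
      theta_act_deg = schedule$theta_act_deg,
      contrast = schedule$contrast,
      theta_est_deg = est,
      validated = validated,
      detected = det,
      rt_ms = round(stats::rlnorm(n, log(600), 0.25), 1))
  })
}

#' Cohort specification
#'
#' Population parameters for simulated cohorts. Defaults follow the
#' parameter-recovery protocol: Gaussian means (40, 15, 10, 0.06, 10) for
#' (`theta_exp`, `sigma_exp`, `sigma_sens`, `alpha`, `sigma_m`), with
#' spreads (10, 6, 3, 0.08, 3), truncated to the identifiable regime of
#' the task: prior modes inside the probed direction range (20-64
#' degrees), prior width 6-26 degrees (a broader prior leaves no
#' measurable footprint in a session's trials), sensory and motor
#' dispersions 5-20 degrees and lapse rate at most 0.25. An optional trait
#' model induces a population correlation `rho` between a latent trait
#' score and one parameter.
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param means,sds Named numeric vectors over `theta_exp`, `sigma_exp`,
#'   `sigma_sens`, `alpha`, `sigma_m`. `sds` may contain zeros (all
#'   subjects identical in that parameter) but must be nonnegative.
#' @param limits Named list of `c(lower, upper)` truncation ranges.
#' @param trait_model Optional list with `target` (parameter name), `rho`
#'   (latent correlation), `trait` (score name, default `"AQ"`),
#'   `trait_mean`, `trait_sd`.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects,
                        means = c(theta_exp = 40, sigma_exp = 15,
                                  sigma_sens = 10, alpha = 0.06, sigma_m = 10),
                        sds = c(theta_exp = 10, sigma_exp = 6,
                                sigma_sens = 3, alpha = 0.08, sigma_m = 3),
                        limits = list(theta_exp = c(20, 64),
                                      sigma_exp = c(6, 26),
                                      sigma_sens = c(5, 20),
                                      alpha = c(0, 0.25),
                                      sigma_m = c(5, 20)),
                        trait_model = NULL) {
  if (n_subjects < 1) stop("n_subjects must be >= 1")
  nm <- c("theta_exp", "sigma_exp", "sigma_sens", "alpha", "sigma_m")
  if (!all(nm %in% names(means)) || !all(nm %in% names(sds))) {
    stop("means and sds must be named over ", paste(nm, collapse = ", "))
  }
  if (!all(nm %in% names(limits))) {
    stop("limits must cover ", paste(nm, collapse = ", "))
  }
  if (any(sds[nm] < 0)) stop("sds must be nonnegative")
  structure(list(n_subjects = as.integer(n_subjects), means = means[nm],
                 sds = sds[nm], limits = limits[nm],
                 trait_model = trait_model),
            class = "cohort_spec")
}

# truncated-normal draw by rejection (falls back to clamping for extreme
# truncation, e.g. sd = 0)
rtrunc_norm <- function(n, mean, sd, lower, upper) {
  if (sd == 0) return(pmin(pmax(rep(mean, n), lower), upper))
  out <- stats::rnorm(n, mean, sd)
  for (it in 1:1000) {
    bad <- out < lower | out > upper
    if (!any(bad)) break
    out[bad] <- stats::rnorm(sum(bad), mean, sd)
  }
  pmin(pmax(out, lower), upper)
}

# sample per-subject true parameters (and trait scores) from a cohort spec
sample_cohort_params <- function(cohort, seed) {
  with_seed(seed, {
    n <- cohort$n_subjects
    m <- cohort$means; s <- cohort$sds; lim <- cohort$limits
    draw <- function(nm) rtrunc_norm(n, m[nm], s[nm], lim[[nm]][1], lim[[nm]][2])
    tab <- data.frame(
      subject_id = seq_len(n),
      theta_exp = draw("theta_exp"),
      sigma_exp = draw("sigma_exp"),
      sigma_sens = draw("sigma_sens"),
      alpha = draw("alpha"),
      sigma_m = draw("sigma_m"))
    tm <- cohort$trait_model
    if (!is.null(tm)) {
      t_lat <- stats::rnorm(n)
      eps <- stats::rnorm(n)
      target <- tm$target
      tab[[target]] <- m[target] + s[target] *
        (tm$rho * t_lat + sqrt(max(0, 1 - tm$rho^2)) * eps)
      tab[[target]] <- pmin(pmax(tab[[target]], lim[[target]][1]),
                            lim[[target]][2])
      trait_mean <- if (is.null(tm$trait_mean)) 20.3 else tm$trait_mean
      trait_sd <- if (is.null(tm$trait_sd)) 8.3 else tm$trait_sd
      trait <- if (is.null(tm$trait)) "AQ" else tm$trait
      tab[[trait]] <- as.integer(round(pmin(pmax(
        trait_mean + trait_sd * t_lat, 0), 50)))
    }
    tab
  })
}

#' Simulate a cohort of observers
#'
#' Samples per-subject parameters from a [cohort_spec()] and simulates each
#' subject through the task. With `trials = "full"` every subject runs the
#' complete 567-trial schedule (independent schedule per subject); with
#' `trials = "low"` each subject contributes `n_trials` staircase-contrast
#' estimation trials drawn from the post-convergence part of a session, as
#' in the parameter-recovery protocol.
#'
#' @param cohort A [cohort_spec()].
#' @param seed Master integer seed; per-subject streams are derived from it.
#' @param trials `"full"` or `"low"`.
#' @param n_trials Number of low-contrast trials per subject when
#'   `trials = "low"`.
#' @param spec Generating [model_spec()].
#' @param w_true Mixing weight given to every subject when `spec` is a
#'   response-strategy family (the cohort spec has no `w` population).
#' @param ... Passed to [simulate_observer()].
#' @return List with `trials` (row-bound trial data.frame with
#'   `subject_id`), `truth` (true parameter table) and, when a trait model
#'   is active, trait scores as extra columns of `truth`.
#' @export
simulate_cohort <- function(cohort, seed = 1, trials = c("full", "low"),
                            n_trials = 200, spec = model_spec("BAYES"),
                            w_true = 0.5, ...) {
  trials <- match.arg(trials)
  truth <- sample_cohort_params(cohort, seed)
  out <- vector("list", cohort$n_subjects)
  for (i in seq_len(cohort$n_subjects)) {
    p <- observer_params(truth$theta_exp[i], truth$sigma_exp[i],
                         truth$sigma_sens[i], truth$alpha[i], truth$sigma_m[i],
                         w = if (spec$bayesian) NULL else w_true)
    sseed <- subject_seed(seed, i)
    if (trials == "full") {
      tr <- simulate_observer(params = p, schedule = make_schedule(sseed),
                              spec = spec, seed = sseed, ...)
    } else {
      th <- recovery_angles(n_trials, sseed)
      e <- with_seed(sseed, sample_estimates(p, th, spec))
      tr <- data.frame(trial_index = seq_along(th), condition = "low41",
                       theta_act_deg = th, contrast = NA_real_,
                       theta_est_deg = e, validated = TRUE, detected = TRUE,
                       rt_ms = NA_real_)
    }
    tr$subject_id <- i
    out[[i]] <- tr
  }
  trials_df <- do.call(rbind, out)
  trials_df <- trials_df[, c("subject_id", setdiff(names(trials_df), "subject_id"))]
  list(trials = trials_df, truth = truth)
}

# true directions of n post-convergence staircased trials of a session
recovery_angles <- function(n_trials, seed) {
  sch <- make_schedule(seed)
  low <- sch[sch$condition %in% c("low41", "low21") & sch$trial_index > 170, ]
  th <- low$theta_act_deg
  if (length(th) < n_trials) {
    th <- rep_len(th, n_trials)
  }
  th[seq_len(n_trials)]
}
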