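# Pipeline commands binding the stages together. Each command is a thin,
# idempotent wrapper: given a configuration (which carries the seed) and
# input CSVs it produces output CSVs, logging exclusions and warnings to
# stderr. These functions back the command-line script in
# inst/scripts/visprior.

vp_log <- function(verbose, ...) if (verbose) message(sprintf(...))

#' Simulate a cohort and write trial + ground-truth CSVs
#'
#' @param config Configuration from [default_config()].
#' @param n_subjects Number of subjects (>= 1).
#' @param out_trials,out_truth Output CSV paths.
#' @param spec Generating [model_spec()].
#' @param trait_model Optional trait model (see [cohort_spec()]).
#' @param verbose Log to stderr.
#' @return Invisibly, the [simulate_cohort()] result.
#' @export
cmd_simulate <- function(config = default_config(), n_subjects = 1,
                         out_trials = "trials.csv", out_truth = "truth.csv",
                         spec = model_spec("BAYES"), trait_model = NULL,
                         verbose = TRUE) {
  if (n_subjects < 1) stop("n_subjects must be >= 1")
  cohort <- cohort_spec(n_subjects, config$recovery$means, config$recovery$sds,
                        trait_model = trait_model)
  sim <- simulate_cohort(cohort, seed = config$seed, trials = "full",
                         spec = spec,
                         p_hallucinate = config$simulate$p_hallucinate,
                         p_miss_validate = config$simulate$p_miss_validate,
                         detect_model = logistic_detect_model(
                           config$detect$threshold_log10, config$detect$slope))
  write_trials(sim$trials, out_trials, config, config$seed)
  write_csv_prov(sim$truth, out_truth, config, config$seed)
  vp_log(verbose, "simulated %d subjects x %d trials -> %s", n_subjects,
         nrow(sim$trials) / n_subjects, out_trials)
  invisible(sim)
}

# shared front half of fitting commands: inclusion + motor pre-fit
prepare_subjects <- function(trials, config, verbose = TRUE) {
  ids <- unique(trials$subject_id)
  out <- list()
  for (id in ids) {
    tr <- trials[trials$subject_id == id, ]
    inc <- apply_inclusion(tr)
    if (!inc$included) {
      vp_log(verbose, "subject %s excluded: %s", id, inc$reason)
      next
    }
    motor <- fit_motor(inc$high_trials, config$fit$min_motor_trials)
    out[[as.character(id)]] <- list(id = id, inclusion = inc, motor = motor)
  }
  if (length(out) == 0) stop("no subject passed the inclusion criteria")
  out
}

#' Fit a model per subject and write the fitted-parameter CSV
#'
#' Applies the inclusion criteria and trial filter, pre-fits motor
#' precision on high-contrast trials, fits the requested family on the
#' filtered low-contrast trials and writes one row per included subject.
#'
#' @param config Configuration.
#' @param trials_csv Input trial CSV (or a trial data.frame).
#' @param out_csv Output parameter CSV path (NULL to skip writing).
#' @param model Family name, see [model_spec()].
#' @param verbose Log exclusions to stderr.
#' @return Invisibly, a list with `fits` (per subject), `motor`, `table`.
#' @export
cmd_fit <- function(config = default_config(), trials_csv, out_csv = "params.csv",
                    model = "BAYES", verbose = TRUE) {
  trials <- if (is.character(trials_csv)) read_trials(trials_csv) else trials_csv
  spec <- model_spec(model)
  prep <- prepare_subjects(trials, config, verbose)
  fits <- list()
  rows <- list()
  for (s in prep) {
    f <- fit_model(s$inclusion$trials, spec, sigma_m = s$motor$sigma_m,
                   grid_step = config$grid_step, stages = config$simulate$stages,
                   n_polish = config$fit$n_polish, maxit = config$fit$maxit)
    fits[[as.character(s$id)]] <- f
    rows[[as.character(s$id)]] <- data.frame(
      subject_id = s$id, t(f$estimates), sigma_m = s$motor$sigma_m,
      loglik = f$loglik, k = f$k, n = f$n, bic = f$bic)
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  if (!is.null(out_csv)) write_params_table(tab, out_csv, config, config$seed)
  vp_log(verbose, "fitted %s for %d subjects", model, nrow(tab))
  invisible(list(fits = fits, motor = lapply(prep, `[[`, "motor"), table = tab,
                 prep = prep))
}

#' Fit several families and write the model-comparison table
#'
#' @param config Configuration.
#' @param trials_csv Input trial CSV (or data.frame).
#' @param out_csv Output CSV for the per-model summary.
#' @param models Families to compare (reference first).
#' @param verbose Log to stderr.
#' @return Invisibly, the [compare_models()] result.
#' @export
cmd_compare <- function(config = default_config(), trials_csv,
                        out_csv = "comparison.csv",
                        models = c("BAYES", "BAYES_varmin", "BAYES_var",
                                   "ADD1", "ADD2", "ADD1_m", "ADD2_m"),
                        verbose = TRUE) {
  trials <- if (is.character(trials_csv)) read_trials(trials_csv) else trials_csv
  prep <- prepare_subjects(trials, config, verbose)
  fits <- list()
  for (m in models) {
    spec <- model_spec(m)
    fits[[m]] <- lapply(prep, function(s) {
      fit_model(s$inclusion$trials, spec, sigma_m = s$motor$sigma_m,
                grid_step = config$grid_step, stages = config$simulate$stages,
                n_polish = config$fit$n_polish, maxit = config$fit$maxit)
    })
    vp_log(verbose, "fitted %s for %d subjects", m, length(fits[[m]]))
  }
  cmp <- compare_models(fits, reference = models[1])
  if (!is.null(out_csv)) write_csv_prov(cmp$summary, out_csv, config, config$seed)
  invisible(cmp)
}

#' Behavioral statistics per subject and for the group
#'
#' Per-angle bias/variability mixture fits, group curves with
#' within-subject standard errors, and no-stimulus summaries (p_rel,
#' hallucination window fractions).
#'
#' @param config Configuration.
#' @param trials_csv Input trial CSV (or data.frame).
#' @param out_csv Output CSV for the group per-angle curves.
#' @param verbose Log to stderr.
#' @return Invisibly, a list with `per_subject`, `group`, `nostim`.
#' @export
cmd_behavior <- function(config = default_config(), trials_csv,
                         out_csv = "behavior.csv", verbose = TRUE) {
  trials <- if (is.character(trials_csv)) read_trials(trials_csv) else trials_csv
  prep <- prepare_subjects(trials, config, verbose)
  per_subject <- lapply(prep, function(s) {
    per_angle_mixture_fit(s$inclusion$trials, config$fit$min_per_angle)
  })
  group <- group_bias_variability(per_subject)
  nostim <- lapply(prep, function(s) {
    nostim_summary(trials[trials$subject_id == s$id, ])
  })
  tab <- data.frame(angle = group$angles, bias_mean = group$bias_mean,
                    bias_se = group$bias_se, sd_mean = group$sd_mean,
                    sd_se = group$sd_se)
  if (!is.null(out_csv)) write_csv_prov(tab, out_csv, config, config$seed)
  vp_log(verbose, "behavior summarized for %d subjects (SD at modes p = %.4g)",
         length(per_subject), group$p_sd_modes)
  invisible(list(per_subject = per_subject, group = group, nostim = nostim))
}

#' Run the parameter-recovery experiment and write the report
#'
#' @param config Configuration (recovery protocol under `config$recovery`).
#' @param out_csv Output CSV of actual vs recovered values.
#' @param verbose Log to stderr.
#' @return Invisibly, the [run_recovery()] report.
#' @export
cmd_recover <- function(config = default_config(), out_csv = "recovery.csv",
                        verbose = TRUE) {
  rep <- run_recovery(n_subjects = config$recovery$n_subjects,
                      n_trials = config$recovery$n_trials,
                      means = config$recovery$means, sds = config$recovery$sds,
                      seed = config$seed, n_polish = config$fit$n_polish,
                      grid_step = config$grid_step)
  tab <- merge(rep$actual, rep$recovered, by = "subject_id",
               suffixes = c("_actual", "_recovered"))
  if (!is.null(out_csv)) write_csv_prov(tab, out_csv, config, config$seed)
  vp_log(verbose, "recovery r: %s",
         paste(sprintf("%s=%.3f", names(rep$pearson_r), rep$pearson_r),
               collapse = ", "))
  invisible(rep)
}

#' Correlate fitted parameters and behavior with trait scores
#'
#' @param config Configuration.
#' @param params_csv Fitted-parameter CSV (or data.frame) from [cmd_fit()].
#' @param traits_csv Trait CSV (or data.frame), native dialect.
#' @param out_csv Output CSV of correlation results.
#' @param measures_df Optional extra behavioral measures keyed by
#'   `subject_id`, merged in.
#' @param verbose Log to stderr.
#' @return Invisibly, the [trait_battery()] data.frame.
#' @export
cmd_traits <- function(config = default_config(), params_csv, traits_csv,
                       out_csv = "trait_correlations.csv", measures_df = NULL,
                       verbose = TRUE) {
  params <- if (is.character(params_csv)) read_params_table(params_csv) else params_csv
  traits <- if (is.character(traits_csv)) read_traits(traits_csv) else traits_csv
  keep <- intersect(c("subject_id", "mean_abs_bias", "mean_sd",
                      "n_hallucinations", "theta_exp", "sigma_exp",
                      "sigma_sens", "alpha", "sigma_m"), names(params))
  measures <- params[, keep, drop = FALSE]
  if (!is.null(measures_df)) measures <- merge(measures, measures_df,
                                               by = "subject_id", all = TRUE)
  bat <- trait_battery(measures, traits)
  if (!is.null(out_csv)) write_csv_prov(bat, out_csv, config, config$seed)
  vp_log(verbose, "computed %d trait correlations", nrow(bat))
  invisible(bat)
}
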