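# Configuration and CSV interchange. CSV is the single data format:
# headers mandatory, UTF-8, '.' decimal, angles in degrees with a _deg
# suffix. Every file written carries a comment header line recording the
# seed and a hash of the configuration for provenance.

#' Default run configuration
#'
#' All tunable constants of the pipeline in one serializable list: the
#' trial-schedule counts, detection/staircase simulation settings, the
#' evaluation grid, fitting controls and the recovery protocol.
#'
#' @param seed Master seed.
#' @return A named list (class `visprior_config`).
#' @export
default_config <- function(seed = 1) {
  structure(list(
    seed = as.integer(seed),
    grid_step = 0.5,
    schedule = list(n_trials = 567, n_none = 167, n_low41 = 243, n_low21 = 90,
                    n_high = 67, n_low41_modes = 173, n_high_modes = 34,
                    design_angles = design_angles(), modes = c(-32, 32)),
    detect = list(threshold_log10 = -2, slope = 6),
    staircase = list(start_log10 = -1, step_init = 0.1, step_min = 0.02,
                     range_log10 = c(-4, 0), high_contrast = 1),
    simulate = list(p_hallucinate = 0.12, p_miss_validate = 0, stages = 2),
    fit = list(sigma_init = c(4, 8, 16, 32, 64), n_polish = 3, maxit = 400,
               min_motor_trials = 20, min_per_angle = 10),
    recovery = list(n_subjects = 80, n_trials = 200,
                    means = c(theta_exp = 40, sigma_exp = 15, sigma_sens = 10,
                              alpha = 0.06, sigma_m = 10),
                    sds = c(theta_exp = 10, sigma_exp = 6, sigma_sens = 3,
                            alpha = 0.08, sigma_m = 3))),
    class = "visprior_config")
}

#' Serialize and restore a configuration
#'
#' JSON round-trip is lossless for the default configuration.
#'
#' @param config A configuration list.
#' @param path File path.
#' @return `read_config` returns the configuration list.
#' @export
write_config <- function(config, path) {
  cfg <- unclass(config)
  # named vectors must travel as JSON objects to keep their names
  for (nm in c("means", "sds")) {
    cfg$recovery[[nm]] <- as.list(cfg$recovery[[nm]])
  }
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg$seed <- as.integer(cfg$seed)
  for (nm in c("means", "sds")) {
    cfg$recovery[[nm]] <- unlist(cfg$recovery[[nm]])
  }
  structure(cfg, class = "visprior_config")
}

#' Configuration hash
#'
#' Stable hash of a configuration, recorded in output file headers.
#' Computed on the canonical JSON serialization, so it is invariant to
#' integer-vs-double storage differences introduced by a round trip.
#'
#' @param config A configuration list.
#' @return Character scalar.
#' @export
config_hash <- function(config) {
  cfg <- unclass(config)
  for (nm in c("means", "sds")) {
    cfg$recovery[[nm]] <- as.list(cfg$recovery[[nm]])
  }
  rlang::hash(as.character(jsonlite::toJSON(cfg, auto_unbox = TRUE,
                                            digits = NA)))
}

# write a data.frame as CSV with a provenance comment line
write_csv_prov <- function(df, path, config = NULL, seed = NULL) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  hash <- if (is.null(config)) "none" else config_hash(config)
  writeLines(sprintf("# visprior config_hash=%s seed=%s", hash,
                     if (is.null(seed)) "NA" else seed), con)
  utils::write.table(df, con, sep = ",", row.names = FALSE, qmethod = "double")
  invisible(path)
}

read_csv_prov <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Read and write trial tables
#'
#' One row per trial with columns `subject_id`, `trial_index`, `condition`,
#' `theta_act_deg`, `contrast`, `theta_est_deg`, `validated`, `detected`,
#' `rt_ms`.
#'
#' @param trials Trial data.frame.
#' @param path File path.
#' @param config,seed Optional provenance recorded in the header line.
#' @return `read_trials` returns the trial data.frame.
#' @export
write_trials <- function(trials, path, config = NULL, seed = NULL) {
  write_csv_prov(trials, path, config, seed)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  df <- read_csv_prov(path)
  need <- c("subject_id", "trial_index", "condition", "theta_act_deg",
            "theta_est_deg", "validated", "detected")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("malformed trial CSV ", path, ": missing column(s) ",
         paste(miss, collapse = ", "))
  }
  df
}

#' Read and write fitted-parameter tables
#'
#' Keyed by `subject_id` with columns `theta_exp`, `sigma_exp`,
#' `sigma_sens` (plus per-angle columns for the variable-likelihood
#' families), `alpha`, `sigma_m`, `loglik`, `bic`.
#'
#' @param params_df Parameter data.frame.
#' @param path File path.
#' @param config,seed Optional provenance.
#' @return `read_params_table` returns the data.frame.
#' @export
write_params_table <- function(params_df, path, config = NULL, seed = NULL) {
  write_csv_prov(params_df, path, config, seed)
}

#' @rdname write_params_table
#' @export
read_params_table <- function(path) read_csv_prov(path)

#' Read a trait-score table
#'
#' The native dialect is a header CSV with `subject_id` and score columns
#' (`AQ`, `RISC`, `SPQ`, ...). The supplementary dialect is headerless
#' with the AQ score in column 3; remaining columns are kept as `V`
#' columns.
#'
#' @param path File path.
#' @param dialect `"native"` or `"supplementary"`.
#' @return data.frame with `subject_id` and trait columns.
#' @export
read_traits <- function(path, dialect = c("native", "supplementary")) {
  dialect <- match.arg(dialect)
  if (dialect == "native") {
    df <- read_csv_prov(path)
    if (!"subject_id" %in% names(df)) {
      stop("malformed trait CSV: missing subject_id column")
    }
    return(df)
  }
  df <- utils::read.csv(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 3) stop("supplementary trait CSV needs >= 3 columns")
  out <- data.frame(subject_id = seq_len(nrow(df)), AQ = df[[3]])
  extra <- df[, -3, drop = FALSE]
  names(extra) <- paste0("V", seq_len(ncol(extra)))
  cbind(out, extra)
}
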