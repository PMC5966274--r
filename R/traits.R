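# Trait-correlation analyses: robust (Huber IRLS) regression and
# Kendall's tau-b, with Bonferroni correction over the four primary
# hypotheses (two trait spectra x prior precision / sensory precision).

#' Robust correlation via Huber IRLS regression
#'
#' Both variables are z-scored and `y` is regressed on `x` by iteratively
#' reweighted least squares with the Huber loss (tuning constant 1.345,
#' 95% efficiency relative to least squares; MAD scale estimate). The
#' reported `robust_r` is the standardized regression slope, which equals
#' the Pearson correlation exactly when no observation is downweighted;
#' the p-value comes from the slope's t statistic on n - 2 degrees of
#' freedom.
#'
#' @param x,y Finite numeric vectors, length >= 10, nonzero variance.
#' @param k Huber tuning constant (default 1.345).
#' @return List with `robust_r`, `p`, `t`, `n`.
#' @export
robust_corr <- function(x, y, k = 1.345) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 10) stop("robust_corr needs n >= 10 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero variance input")
  xs <- as.numeric(scale(x)); ys <- as.numeric(scale(y))
  fit <- MASS::rlm(ys ~ xs, psi = MASS::psi.huber, k = k, maxit = 100)
  co <- summary(fit)$coefficients
  tval <- co["xs", "t value"]
  list(robust_r = unname(co["xs", "Value"]),
       p = 2 * stats::pt(-abs(tval), df = n - 2),
       t = unname(tval), n = n)
}

# exact null distribution of the Kendall S statistic (no ties): counts of
# permutations by number of inversions, built by convolution
kendall_exact_p <- function(S, n) {
  f <- 1
  for (m in 2:n) f <- stats::convolve(f, rep(1, m), type = "open")
  inv_obs <- (choose(n, 2) - S) / 2   # S = n(n-1)/2 - 2*inversions
  probs <- f / sum(f)
  inv_vals <- seq_along(probs) - 1
  s_vals <- choose(n, 2) - 2 * inv_vals
  min(1, sum(probs[abs(s_vals) >= abs(S) - 1e-9]))
}

#' Kendall's tau-b with tie correction
#'
#' Tie-corrected rank correlation. The two-sided p-value uses the exact
#' null distribution of the S statistic for n <= 12 without ties, and the
#' normal approximation with the standard tie-corrected variance
#' otherwise.
#'
#' @param x,y Numeric vectors of equal length >= 5.
#' @return List with `tau_b`, `p`, `S`, `n`.
#' @export
kendall_tau_b <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4) stop("kendall_tau_b needs n >= 4")
  dx <- sign(outer(x, x, "-"))
  dy <- sign(outer(y, y, "-"))
  up <- upper.tri(dx)
  S <- sum(dx[up] * dy[up])
  tx <- table(x); ty <- table(y)
  n0 <- choose(n, 2)
  n1 <- sum(choose(tx[tx > 1], 2))
  n2 <- sum(choose(ty[ty > 1], 2))
  denom <- sqrt((n0 - n1) * (n0 - n2))
  if (denom == 0) stop("tau-b undefined: all values tied in x or y")
  tau <- S / denom
  has_ties <- n1 > 0 || n2 > 0
  p <- if (!has_ties && n <= 12) {
    kendall_exact_p(S, n)
  } else {
    v0 <- n * (n - 1) * (2 * n + 5)
    vt <- sum(tx * (tx - 1) * (2 * tx + 5))
    vu <- sum(ty * (ty - 1) * (2 * ty + 5))
    v1 <- sum(tx * (tx - 1)) * sum(ty * (ty - 1)) / (2 * n * (n - 1))
    v2 <- sum(tx * (tx - 1) * (tx - 2)) * sum(ty * (ty - 1) * (ty - 2)) /
      (9 * n * (n - 1) * (n - 2))
    v <- (v0 - vt - vu) / 18 + v1 + v2
    if (S == 0) 1 else 2 * stats::pnorm(-abs(S) / sqrt(v))
  }
  list(tau_b = tau, p = min(1, p), S = S, n = n)
}

#' Collect per-subject measures for trait analysis
#'
#' Builds the measure table correlated with trait scores: mean absolute
#' estimation bias and mean estimation SD over the design angles (from the
#' per-angle mixture fits), the hallucination count (from no-stimulus
#' trials), and the fitted model parameters.
#'
#' @param fits Named-by-subject list of `fit_result` objects (or `NULL`).
#' @param per_angle Named-by-subject list of [per_angle_mixture_fit()]
#'   results (or `NULL`).
#' @param trials Trial data.frame with `subject_id` (or `NULL`).
#' @param sigma_m Optional named-by-subject vector of motor dispersions.
#' @return data.frame keyed by `subject_id`.
#' @export
collect_measures <- function(fits = NULL, per_angle = NULL, trials = NULL,
                             sigma_m = NULL) {
  ids <- unique(c(names(fits), names(per_angle),
                  if (!is.null(trials)) as.character(unique(trials$subject_id)),
                  names(sigma_m)))
  out <- data.frame(subject_id = ids, stringsAsFactors = FALSE)
  if (!is.null(per_angle)) {
    out$mean_abs_bias <- vapply(ids, function(i) {
      if (is.null(per_angle[[i]])) return(NA_real_)
      mean(abs(per_angle[[i]]$per_angle$bias))
    }, numeric(1))
    out$mean_sd <- vapply(ids, function(i) {
      if (is.null(per_angle[[i]])) return(NA_real_)
      mean(per_angle[[i]]$per_angle$sd)
    }, numeric(1))
  }
  if (!is.null(trials)) {
    out$n_hallucinations <- vapply(ids, function(i) {
      tr <- trials[trials$subject_id == i, ]
      if (nrow(tr) == 0) return(NA_real_)
      as.numeric(nostim_summary(tr)$n_hallucinations)
    }, numeric(1))
  }
  if (!is.null(fits)) {
    for (p in c("theta_exp", "sigma_exp", "sigma_sens", "alpha")) {
      out[[p]] <- vapply(ids, function(i) {
        f <- fits[[i]]
        if (is.null(f) || !p %in% names(f$estimates)) return(NA_real_)
        unname(f$estimates[p])
      }, numeric(1))
    }
  }
  if (!is.null(sigma_m)) {
    out$sigma_m <- unname(sigma_m[ids])
  }
  out
}

#' Trait-correlation battery
#'
#' Correlates every measure column with every trait column using both the
#' robust Huber regression and Kendall's tau-b, with pairwise deletion of
#' missing values. The Bonferroni factor 4 (the four primary, independent
#' hypotheses: each trait spectrum vs prior precision and vs sensory
#' precision) is applied only to the rows where trait is AQ or RISC and
#' measure is `sigma_exp` or `sigma_sens`.
#'
#' @param measures data.frame with `subject_id` and measure columns.
#' @param traits data.frame with `subject_id` and trait score columns
#'   (e.g. `AQ`, `RISC`, `SPQ`).
#' @return data.frame with one row per measure x trait pair: `measure`,
#'   `trait`, `robust_r`, `robust_p`, `tau_b`, `kendall_p`,
#'   `bonferroni_adjusted_p` (`NA` for non-primary rows), `n`.
#' @export
trait_battery <- function(measures, traits) {
  m <- merge(measures, traits, by = "subject_id")
  measure_cols <- setdiff(names(measures), "subject_id")
  trait_cols <- setdiff(names(traits), "subject_id")
  rows <- expand.grid(measure = measure_cols, trait = trait_cols,
                      stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(rows)), function(i) {
    x <- m[[rows$trait[i]]]; y <- m[[rows$measure[i]]]
    ok <- is.finite(x) & is.finite(y)
    n <- sum(ok)
    rc <- tryCatch(robust_corr(x[ok], y[ok]), error = function(e) NULL)
    kt <- tryCatch(kendall_tau_b(x[ok], y[ok]), error = function(e) NULL)
    primary <- rows$trait[i] %in% c("AQ", "RISC") &&
      rows$measure[i] %in% c("sigma_exp", "sigma_sens")
    data.frame(
      measure = rows$measure[i], trait = rows$trait[i],
      robust_r = if (is.null(rc)) NA_real_ else rc$robust_r,
      robust_p = if (is.null(rc)) NA_real_ else rc$p,
      tau_b = if (is.null(kt)) NA_real_ else kt$tau_b,
      kendall_p = if (is.null(kt)) NA_real_ else kt$p,
      bonferroni_adjusted_p = if (primary && !is.null(rc)) min(1, 4 * rc$p)
                              else NA_real_,
      n = n)
  })
  do.call(rbind, res)
}
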