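# Group-level behavioral statistics: estimation bias/variability curves and
# the distribution of no-stimulus estimates (hallucinations).

#' Clustering ratio of no-stimulus estimates near the frequent directions
#'
#' The probability that an estimate falls within 8 degrees (shortest arc)
#' of either +32 or -32, scaled so that uniform responding yields exactly
#' 1: the probability is divided by the measure of the two windows on the
#' circle (2 x 16/360). Responses concentrated entirely inside the windows
#' give the maximum, 360/32 = 11.25. The ratio is invariant under a sign
#' flip of all estimates.
#'
#' @param estimates Angles in degrees (nonempty).
#' @param window Half-width of the window in degrees (default 8).
#' @param modes Frequent directions (default +/-32).
#' @return Nonnegative scalar ratio.
#' @export
p_rel <- function(estimates, window = 8, modes = c(-32, 32)) {
  if (length(estimates) == 0) stop("p_rel is undefined for an empty estimate list")
  dist <- pmin(abs(circ_dist(estimates, modes[1])),
               abs(circ_dist(estimates, modes[2])))
  mean(dist <= window) / (2 * (2 * window) / 360)
}

#' Fraction of hallucinations near the frequent directions
#'
#' Fractions of estimates within 8, 16 and 24 degrees of either +/-32
#' (shortest-arc distance); monotone nondecreasing in the window size.
#'
#' @param estimates Angles in degrees (nonempty).
#' @param windows Window half-widths in degrees.
#' @param modes Frequent directions.
#' @return Named numeric vector of fractions in \code{[0, 1]}.
#' @export
hallucination_windows <- function(estimates, windows = c(8, 16, 24),
                                  modes = c(-32, 32)) {
  if (length(estimates) == 0) stop("empty estimate list")
  dist <- pmin(abs(circ_dist(estimates, modes[1])),
               abs(circ_dist(estimates, modes[2])))
  out <- vapply(windows, function(w) mean(dist <= w), numeric(1))
  names(out) <- paste0("within_", windows)
  out
}

#' Summary of no-stimulus trials for one subject
#'
#' @param trials One subject's trial data.frame.
#' @return List with `n_hallucinations` (no-stimulus trials with a
#'   detection response and a validated estimate), `estimate_angles`,
#'   `p_rel` and `window_fractions` (`NA` when there are no hallucinations).
#' @export
nostim_summary <- function(trials) {
  ns <- trials[trials$condition == "none" & trials$validated, ]
  hal <- ns[ns$detected & !is.na(ns$theta_est_deg), ]
  n <- nrow(hal)
  list(
    n_hallucinations = n,
    estimate_angles = hal$theta_est_deg,
    p_rel = if (n > 0) p_rel(hal$theta_est_deg) else NA_real_,
    window_fractions = if (n > 0) hallucination_windows(hal$theta_est_deg)
                       else stats::setNames(rep(NA_real_, 3),
                                            c("within_8", "within_16", "within_24")))
}

# Cousineau-Morey within-subject standard error: subject-mean-centered
# values, bias-corrected by sqrt(m/(m-1)) for m conditions
within_subject_se <- function(mat) {
  m <- ncol(mat)
  centered <- mat - rowMeans(mat) + mean(mat)
  apply(centered, 2, stats::sd) / sqrt(nrow(mat)) * sqrt(m / (m - 1))
}

#' Group bias and variability curves across design angles
#'
#' Aggregates per-subject per-angle mixture fits (see
#' [per_angle_mixture_fit()]) into group mean bias and estimation-SD
#' curves with Cousineau-Morey within-subject standard errors, and tests
#' the hallmark of an acquired prior: estimation SD at the +/-32 modes
#' (per-subject mean of the two) against the mean SD over all other design
#' angles, by two-sided Wilcoxon signed-rank test.
#'
#' @param per_subject A list (one element per subject) of
#'   [per_angle_mixture_fit()] results, each covering the same angles.
#' @return List with `angles`, `bias_mean`, `bias_se`, `sd_mean`, `sd_se`
#'   (per-angle group curves), `sd_at_modes`, `sd_elsewhere` (per-subject
#'   summaries) and `p_sd_modes` (signed-rank p-value).
#' @export
group_bias_variability <- function(per_subject) {
  if (length(per_subject) < 2) stop("need at least 2 subjects")
  angles <- sort(Reduce(intersect, lapply(per_subject,
                                          function(s) s$per_angle$angle)))
  if (length(angles) < 3 || !all(c(-32, 32) %in% angles)) {
    stop("subjects share too few design angles (the +/-32 modes are required)")
  }
  pick <- function(s, col) s$per_angle[[col]][match(angles, s$per_angle$angle)]
  bias <- t(vapply(per_subject, pick, numeric(length(angles)), col = "bias"))
  sds <- t(vapply(per_subject, pick, numeric(length(angles)), col = "sd"))
  is_mode <- angles %in% c(-32, 32)
  sd_modes <- rowMeans(sds[, is_mode, drop = FALSE])
  sd_other <- rowMeans(sds[, !is_mode, drop = FALSE])
  list(
    angles = angles,
    bias_mean = colMeans(bias),
    bias_se = within_subject_se(bias),
    sd_mean = colMeans(sds),
    sd_se = within_subject_se(sds),
    sd_at_modes = sd_modes,
    sd_elsewhere = sd_other,
    p_sd_modes = signed_rank_p(sd_modes - sd_other))
}
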