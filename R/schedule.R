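# The experiment's trial schedule and adaptive contrast staircases.

# run code under a temporary RNG state seeded deterministically
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed %% 2147483647L))
  force(code)
}

# deterministic per-subject seed stream derived from a master seed
subject_seed <- function(seed, i) as.integer((seed + 7919 * i) %% 2147483647)

#' Generate the session's trial schedule
#'
#' One session of 567 trials with four randomly interleaved contrast
#' conditions: 167 no-stimulus trials; 243 trials at the 4/1-staircased
#' contrast, of which 173 move at +/-32 degrees and 70 are spread equally
#' over the seven other design angles; 90 trials at the 2/1-staircased
#' contrast, uniform over the nine design angles; and 67 high-contrast
#' trials, 34 at +/-32 degrees and 33 at continuous-uniform random
#' directions.
#'
#' @param seed Integer seed; the same seed yields an identical schedule.
#' @return A data.frame with columns `trial_index`, `condition` (factor with
#'   levels `none`, `low41`, `low21`, `high`) and `theta_act_deg` (`NA` on
#'   no-stimulus trials).
#' @export
make_schedule <- function(seed = 1) {
  other <- setdiff(design_angles(), c(-32, 32))
  with_seed(seed, {
    modes41 <- sample(rep(c(-32, 32), c(86, 87)))
    low41 <- c(modes41, rep(other, each = 10))
    low21 <- rep(design_angles(), each = 10)
    high <- c(rep(c(-32, 32), each = 17),
              round(wrap_angle(stats::runif(33, -180, 180)), 2))
    df <- data.frame(
      condition = c(rep("none", 167),
                    rep("low41", length(low41)),
                    rep("low21", length(low21)),
                    rep("high", length(high))),
      theta_act_deg = c(rep(NA_real_, 167), low41, low21, high))
    df <- df[sample(nrow(df)), ]
    df$trial_index <- seq_len(nrow(df))
    rownames(df) <- NULL
    df[, c("trial_index", "condition", "theta_act_deg")]
  })
}

#' Logistic detection model
#'
#' A simple psychometric detection model: probability of detecting the
#' stimulus as a logistic function of log10 contrast. Used only to drive
#' simulated staircases and simulated detection responses, never for
#' fitting.
#'
#' @param threshold_log10 log10 contrast of 50% detection.
#' @param slope Logistic slope per log10 unit.
#' @return A function `contrast -> P(detect)`.
#' @export
logistic_detect_model <- function(threshold_log10 = -2, slope = 6) {
  function(contrast) stats::plogis(slope * (log10(contrast) - threshold_log10))
}

# check monotonicity of a detection model on a probe grid
assert_monotone_detect <- function(detect_model) {
  p <- detect_model(10^seq(-4, 0, length.out = 41))
  if (any(diff(p) < -1e-12)) stop("detect_model must be monotone increasing in contrast")
  invisible(TRUE)
}

#' Run the adaptive contrast staircases over a schedule
#'
#' Assigns a contrast to every trial and simulates the detection outcome on
#' staircased trials. The 4/1 staircase lowers contrast after 4 consecutive
#' detections and raises it after any miss, converging where detection
#' probability is 0.5^(1/4), about 84%; the 2/1 staircase converges near
#' 71%. Steps are taken in log10 contrast, starting at `step_init` and
#' halving after each reversal down to `step_min`.
#'
#' @param schedule A schedule data.frame from [make_schedule()] (only the
#'   `condition` column is required).
#' @param detect_model A monotone function `contrast -> P(detect)`.
#' @param seed Integer seed for the simulated detection outcomes.
#' @param start_log10 Starting log10 contrast for both staircases.
#' @param step_init,step_min Initial and minimum step size (log10 units).
#' @param range_log10 Contrast floor and ceiling (log10 units).
#' @param high_contrast Fixed contrast of high-contrast trials.
#' @return The schedule with columns `contrast` and, on staircased trials,
#'   `detected` (logical; `NA` elsewhere -- those outcomes are simulated by
#'   [simulate_observer()]).
#' @export
run_staircases <- function(schedule, detect_model = logistic_detect_model(),
                           seed = 1, start_log10 = -1, step_init = 0.1,
                           step_min = 0.02, range_log10 = c(-4, 0),
                           high_contrast = 1) {
  assert_monotone_detect(detect_model)
  st <- list(
    low41 = list(logc = start_log10, step = step_init, streak = 0L, last = 0L, k = 4L),
    low21 = list(logc = start_log10, step = step_init, streak = 0L, last = 0L, k = 2L))
  n <- nrow(schedule)
  contrast <- rep(NA_real_, n)
  detected <- rep(NA, n)
  with_seed(seed, {
    u <- stats::runif(n)
    for (i in seq_len(n)) {
      cond <- as.character(schedule$condition[i])
      if (cond == "high") {
        contrast[i] <- high_contrast
      } else if (cond == "none") {
        contrast[i] <- 0
      } else {
        s <- st[[cond]]
        contrast[i] <- 10^s$logc
        hit <- u[i] < detect_model(contrast[i])
        detected[i] <- hit
        if (!hit) {
          # any miss: one step up; a reversal if the last move was down
          if (s$last == -1L) s$step <- max(s$step / 2, step_min)
          s$logc <- min(s$logc + s$step, range_log10[2])
          s$streak <- 0L
          s$last <- 1L
        } else {
          s$streak <- s$streak + 1L
          if (s$streak >= s$k) {
            if (s$last == 1L) s$step <- max(s$step / 2, step_min)
            s$logc <- max(s$logc - s$step, range_log10[1])
            s$streak <- 0L
            s$last <- -1L
          }
        }
        st[[cond]] <- s
      }
    }
  })
  schedule$contrast <- contrast
  schedule$detected <- detected
  schedule
}
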