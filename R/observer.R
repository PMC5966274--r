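#' Design angles of the estimation task
#'
#' The nine predetermined low-contrast motion directions, in degrees relative
#' to the reference direction: 0, +/-16, +/-32, +/-48, +/-64. The two most
#' frequent directions are +/-32.
#'
#' @return Numeric vector of length 9, ascending.
#' @export
design_angles <- function() c(-64, -48, -32, -16, 0, 16, 32, 48, 64)

#' Observer parameters
#'
#' Bundles the parameters of the generative observer: the location
#' `theta_exp` and width `sigma_exp` of the learned bimodal prior (modes at
#' +/-`theta_exp`), the sensory noise `sigma_sens` (a scalar, or one value
#' for the +/-32 modes and one for the remaining directions, or five values
#' indexed by absolute direction 0, 16, 32, 48, 64), the lapse rate `alpha`
#' (fraction of uniformly random estimates), the motor noise `sigma_m`, and
#' for the response-strategy models the mixing weight `w` (fraction of
#' trials answered from expectations alone). All dispersions are in degrees;
#' concentration duals are available through [sigma_to_kappa()].
#'
#' @param theta_exp Prior mode location in degrees, in (0, 180].
#' @param sigma_exp Prior width in degrees, > 0 (may be `Inf` for a flat prior).
#' @param sigma_sens Sensory noise in degrees; length 1, 2 (mode, other) or 5
#'   (|direction| = 0, 16, 32, 48, 64).
#' @param alpha Lapse probability in \code{[0, 1]}.
#' @param sigma_m Motor noise in degrees, > 0.
#' @param w Optional expectation-strategy mixing weight in \code{[0, 1]}
#'   (response-strategy models only).
#' @return An object of class `observer_params`.
#' @examples
#' observer_params(theta_exp = 40, sigma_exp = 15, sigma_sens = 10,
#'                 alpha = 0.06, sigma_m = 10)
#' @export
observer_params <- function(theta_exp, sigma_exp, sigma_sens, alpha, sigma_m,
                            w = NULL) {
  stopifnot(length(theta_exp) == 1, length(sigma_exp) == 1,
            length(alpha) == 1, length(sigma_m) == 1)
  if (!(theta_exp > 0 && theta_exp <= 180)) stop("theta_exp must be in (0, 180]")
  if (sigma_exp <= 0) stop("sigma_exp must be > 0")
  if (!length(sigma_sens) %in% c(1, 2, 5)) {
    stop("sigma_sens must have length 1, 2 or 5")
  }
  if (any(sigma_sens <= 0)) stop("sigma_sens must be > 0")
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]")
  if (sigma_m <= 0) stop("sigma_m must be > 0")
  if (!is.null(w) && (w < 0 || w > 1)) stop("w must be in [0, 1]")
  structure(
    list(theta_exp = theta_exp, sigma_exp = sigma_exp,
         sigma_sens = unname(sigma_sens), alpha = alpha, sigma_m = sigma_m,
         w = w),
    class = "observer_params")
}

#' @export
print.observer_params <- function(x, ...) {
  cat("Observer parameters (degrees):\n")
  cat(sprintf("  theta_exp  %.2f\n  sigma_exp  %.2f\n", x$theta_exp, x$sigma_exp))
  cat("  sigma_sens", paste(sprintf("%.2f", x$sigma_sens), collapse = ", "), "\n")
  cat(sprintf("  alpha      %.3f\n  sigma_m    %.2f\n", x$alpha, x$sigma_m))
  if (!is.null(x$w)) cat(sprintf("  w          %.3f\n", x$w))
  invisible(x)
}

# resolve the sensory sigma applying to a given true direction
sigma_sens_for <- function(params, theta_act) {
  s <- params$sigma_sens
  a <- abs(round(wrap_angle(theta_act)))
  if (length(s) == 1) return(rep(s, length(theta_act)))
  if (length(s) == 2) return(ifelse(a == 32, s[1], s[2]))
  idx <- match(a, c(0, 16, 32, 48, 64))
  if (any(is.na(idx))) {
    stop("per-angle sigma_sens requires directions on the design angles")
  }
  s[idx]
}

#' Model family specification
#'
#' The seven model families. The Bayesian family combines prior and
#' likelihood on every trial: `BAYES` (common sensory noise; 4 free
#' parameters), `BAYES_varmin` (separate sensory noise at the +/-32 modes;
#' 5), `BAYES_var` (sensory noise free per absolute direction; 8). The
#' response-strategy family answers from the prior alone on a fraction `w`
#' of trials and from the stimulus alone otherwise: `ADD1` (samples the full
#' prior; 5), `ADD2` (samples the prior truncated to the stimulus side; 5),
#' and `ADD1_m` / `ADD2_m` (prior width taken to zero, so expectation-driven
#' responses sit at the mode(s); 4 each). Motor noise is always fixed from
#' the high-contrast pre-fit and is not counted as free.
#'
#' @param family One of `"BAYES"`, `"BAYES_varmin"`, `"BAYES_var"`,
#'   `"ADD1"`, `"ADD2"`, `"ADD1_m"`, `"ADD2_m"`.
#' @return An object of class `model_spec` with elements `family`, `k`
#'   (free-parameter count), `par_names`, and `bayesian` (logical).
#' @export
model_spec <- function(family = c("BAYES", "BAYES_varmin", "BAYES_var",
                                  "ADD1", "ADD2", "ADD1_m", "ADD2_m")) {
  family <- match.arg(family)
  info <- switch(family,
    BAYES = list(
      par_names = c("theta_exp", "sigma_exp", "sigma_sens", "alpha"),
      bayesian = TRUE),
    BAYES_varmin = list(
      par_names = c("theta_exp", "sigma_exp", "sigma_sens_mode",
                    "sigma_sens_other", "alpha"),
      bayesian = TRUE),
    BAYES_var = list(
      par_names = c("theta_exp", "sigma_exp", paste0("sigma_sens_", c(0, 16, 32, 48, 64)),
                    "alpha"),
      bayesian = TRUE),
    ADD1 = ,
    ADD2 = list(
      par_names = c("theta_exp", "sigma_exp", "sigma_sens", "alpha", "w"),
      bayesian = FALSE),
    ADD1_m = ,
    ADD2_m = list(
      par_names = c("theta_exp", "sigma_sens", "alpha", "w"),
      bayesian = FALSE))
  structure(list(family = family, k = length(info$par_names),
                 par_names = info$par_names, bayesian = info$bayesian),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("Model family %s (%s, %d free parameters)\n", x$family,
              if (x$bayesian) "Bayesian" else "response strategy", x$k))
  cat("  free:", paste(x$par_names, collapse = ", "), "\n")
  invisible(x)
}

# pack/unpack the free-parameter vector of a family from/to observer_params
pack_params <- function(params, spec) {
  switch(spec$family,
    BAYES = c(params$theta_exp, params$sigma_exp, params$sigma_sens[1], params$alpha),
    BAYES_varmin = c(params$theta_exp, params$sigma_exp, params$sigma_sens[1:2],
                     params$alpha),
    BAYES_var = c(params$theta_exp, params$sigma_exp, params$sigma_sens[1:5],
                  params$alpha),
    ADD1 = ,
    ADD2 = c(params$theta_exp, params$sigma_exp, params$sigma_sens[1],
             params$alpha, params$w),
    ADD1_m = ,
    ADD2_m = c(params$theta_exp, params$sigma_sens[1], params$alpha, params$w))
}

unpack_params <- function(x, spec, sigma_m) {
  switch(spec$family,
    BAYES = observer_params(x[1], x[2], x[3], x[4], sigma_m),
    BAYES_varmin = observer_params(x[1], x[2], x[3:4], x[5], sigma_m),
    BAYES_var = observer_params(x[1], x[2], x[3:7], x[8], sigma_m),
    ADD1 = ,
    ADD2 = observer_params(x[1], x[2], x[3], x[4], sigma_m, w = x[5]),
    # the _m variants have no prior width; carry a placeholder that the
    # response distribution never reads (modes only)
    ADD1_m = ,
    ADD2_m = observer_params(x[1], 1e-6, x[2], x[3], sigma_m, w = x[4]))
}
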