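# Random-effects model comparison from per-subject BICs.

# two-sided Wilcoxon signed-rank p for paired differences; zero
# differences dropped (Wilcoxon convention); exact distribution for small
# samples, normal approximation with continuity correction otherwise
signed_rank_p <- function(d, exact_max = 25) {
  d <- d[d != 0]
  if (length(d) == 0) return(1)
  suppressWarnings(
    stats::wilcox.test(d, exact = length(d) <= exact_max,
                       correct = TRUE)$p.value)
}

#' Compare fitted models across subjects via per-subject BIC
#'
#' Uses each subject's BIC as a summary statistic and tests, per model, the
#' paired BIC differences against the reference model with a two-sided
#' Wilcoxon signed-rank test (a random-effects comparison that preserves
#' individual variability). Positive `delta_bic` means the reference model
#' fits better.
#'
#' @param fits A named list of per-model lists of `fit_result` objects
#'   (`fits[[model]][[subject]]`), or a subjects x models matrix/data.frame
#'   of BIC values.
#' @param reference Reference model name, default `"BAYES"`.
#' @return An object of class `comparison_table`: `bic` (subjects x models
#'   matrix), `delta_bic` (relative to the reference; the reference column
#'   is identically 0), and `summary` (per model: median and quartiles of
#'   `delta_bic`, signed-rank p-value vs the reference).
#' @export
compare_models <- function(fits, reference = "BAYES") {
  if (is.list(fits) && !is.data.frame(fits) && !is.matrix(fits)) {
    models <- names(fits)
    ns <- vapply(fits, length, integer(1))
    if (length(unique(ns)) != 1) {
      warning("subjects without a fit for every model are dropped")
    }
    nsub <- min(ns)
    bic <- sapply(models, function(m) {
      vapply(fits[[m]][seq_len(nsub)], function(f) f$bic, numeric(1))
    })
  } else {
    bic <- as.matrix(fits)
  }
  if (!reference %in% colnames(bic)) stop("reference model not present: ", reference)
  delta <- bic - bic[, reference]
  summ <- data.frame(
    model = colnames(bic),
    median_delta_bic = apply(delta, 2, stats::median),
    q25 = apply(delta, 2, stats::quantile, 0.25),
    q75 = apply(delta, 2, stats::quantile, 0.75),
    p_signed_rank = vapply(colnames(bic), function(m) {
      if (m == reference) return(NA_real_)
      signed_rank_p(delta[, m])
    }, numeric(1)),
    row.names = NULL)
  structure(list(bic = bic, delta_bic = delta, reference = reference,
                 summary = summ), class = "comparison_table")
}

#' @export
print.comparison_table <- function(x, ...) {
  cat(sprintf("Model comparison (n = %d subjects, reference %s):\n",
              nrow(x$bic), x$reference))
  print(transform(x$summary,
                  median_delta_bic = round(median_delta_bic, 2),
                  q25 = round(q25, 2), q75 = round(q75, 2),
                  p_signed_rank = signif(p_signed_rank, 3)))
  invisible(x)
}
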