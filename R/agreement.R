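# Absolute-value agreement: repeated-measures Bland-Altman and percentage
# error.

#' Bland-Altman analysis for repeated measurements
#'
#' Computes bias, the SD of device-minus-reference differences, 95% limits of
#' agreement and percentage error for paired stroke-volume readings, where
#' each subject contributes several pairs over a range of induced stroke
#' volumes.
#'
#' With `method = "repeated_varying"` (the default) the SD of differences is
#' obtained from a one-way variance-component decomposition of the
#' differences grouped by subject (the multiple-observations-per-individual
#' method for a measurand that varies): the within-subject mean square `MSW`
#' and between-subject mean square `MSB` of a one-way ANOVA give
#' `sd_diff^2 = MSW + max(0, (MSB - MSW) / n0)` with
#' `n0 = (N^2 - sum(n_i^2)) / (N (k - 1))`. When every subject contributes a
#' single pair this reduces exactly to the plain SD of the differences.
#' `method = "pooled_naive"` always uses the plain SD of all differences.
#'
#' Proportional bias is summarised by the least-squares slope of the
#' differences on the pair means with its two-sided p-value; see
#' \code{\link{suppress_loa_if_proportional}}.
#'
#' @param pairs Data frame with columns `subject_id`, `sv_ref`, `sv_dev`
#'   (ml). Rows with a missing reading are dropped (per-device missingness is
#'   expected) and the retained pair count is reported.
#' @param method Variance model for the limits of agreement (see Details).
#' @return An object of class `sv_agreement`: `n_pairs`, `n_subjects`,
#'   `bias`, `sd_diff`, `loa_low`, `loa_high`, `mean_ref`,
#'   `percentage_error`, `proportional_bias_slope`, `proportional_bias_p`,
#'   `method` (the method actually used), `suppressed` and a character vector
#'   of structured `warnings` codes.
#' @export
bland_altman_repeated <- function(pairs,
                                  method = c("repeated_varying", "pooled_naive")) {
  method <- match.arg(method)
  need <- c("subject_id", "sv_ref", "sv_dev")
  if (!is.data.frame(pairs) || !all(need %in% names(pairs))) {
    stop("`pairs` must be a data frame with columns subject_id, sv_ref, sv_dev",
         call. = FALSE)
  }
  keep <- stats::complete.cases(pairs[, c("sv_ref", "sv_dev")])
  pairs <- pairs[keep, , drop = FALSE]
  if (nrow(pairs) < 2L) stop("need at least 2 complete pairs", call. = FALSE)
  if (any(pairs$sv_ref <= 0) || any(pairs$sv_dev <= 0)) {
    stop("all stroke volumes must be positive", call. = FALSE)
  }

  d <- pairs$sv_dev - pairs$sv_ref
  m <- (pairs$sv_dev + pairs$sv_ref) / 2
  subj <- factor(pairs$subject_id)
  k <- nlevels(subj)
  N <- length(d)
  warn <- character()

  eff <- method
  if (method == "repeated_varying" && k < 2L) {
    eff <- "pooled_naive"
    warn <- c(warn, "FELL_BACK_TO_POOLED_SINGLE_SUBJECT")
  }

  bias <- mean(d)
  if (eff == "pooled_naive") {
    sd_diff <- stats::sd(d)
  } else {
    ni <- tabulate(subj)
    dbar <- tapply(d, subj, mean)
    msw <- if (N > k) sum((d - dbar[as.integer(subj)])^2) / (N - k) else 0
    msb <- sum(ni * (dbar - bias)^2) / (k - 1)
    n0 <- (N^2 - sum(ni^2)) / (N * (k - 1))
    sigma2_between <- if (n0 > 0) max(0, (msb - msw) / n0) else 0
    sd_diff <- sqrt(msw + sigma2_between)
  }
  if (any(tabulate(subj) == 1L)) {
    warn <- c(warn, "SUBJECTS_WITH_SINGLE_OBSERVATION")
  }

  if (stats::var(m) == 0) {
    slope <- NA_real_
    slope_p <- NA_real_
  } else if (stats::var(d) == 0) {
    slope <- 0
    slope_p <- NA_real_
  } else {
    # summary.lm warns on an essentially perfect fit (e.g. constant
    # reference); the coefficients are still the ones we report
    cf <- suppressWarnings(summary(stats::lm(d ~ m)))$coefficients
    slope <- cf[2L, 1L]
    slope_p <- cf[2L, 4L]
  }

  mean_ref <- mean(pairs$sv_ref)
  structure(list(n_pairs = N,
                 n_subjects = k,
                 bias = bias,
                 sd_diff = sd_diff,
                 loa_low = bias - 1.96 * sd_diff,
                 loa_high = bias + 1.96 * sd_diff,
                 mean_ref = mean_ref,
                 percentage_error = percentage_error(sd_diff, mean_ref),
                 proportional_bias_slope = slope,
                 proportional_bias_p = slope_p,
                 method = eff,
                 suppressed = FALSE,
                 warnings = warn),
            class = "sv_agreement")
}

#' Percentage error of a monitor
#'
#' The half-width of the 95% limits of agreement expressed as a percentage of
#' the mean reference stroke volume: `100 * 1.96 * sd_diff / mean_ref`. A
#' value of 30% is the conventional upper limit of clinical acceptability.
#'
#' @param sd_diff SD (ml) of the device-minus-reference differences (>= 0).
#' @param mean_ref Mean reference stroke volume (ml, > 0).
#' @return Percentage error (percent).
#' @export
percentage_error <- function(sd_diff, mean_ref) {
  stop_if_not_number(sd_diff, "sd_diff", lo = 0)
  stop_if_not_number(mean_ref, "mean_ref", lo = 0, strict_lo = TRUE)
  100 * (1.96 * sd_diff) / mean_ref
}

#' Suppress limits of agreement under proportional bias
#'
#' When the slope of the differences on the pair means is statistically
#' significant, a single pair of limits of agreement (and hence the
#' percentage error) misrepresents the error structure; this helper marks
#' them not-reportable, mirroring the usual editorial treatment of strongly
#' proportional bias.
#'
#' @param summary An `sv_agreement` object.
#' @param slope_p_threshold Two-sided p-value threshold (default 0.05); the
#'   limits are suppressed when `proportional_bias_p` is below it.
#' @return The (possibly modified) `sv_agreement`.
#' @export
suppress_loa_if_proportional <- function(summary, slope_p_threshold = 0.05) {
  if (!inherits(summary, "sv_agreement")) {
    stop("`summary` must be an `sv_agreement` object", call. = FALSE)
  }
  stop_if_not_number(slope_p_threshold, "slope_p_threshold", lo = 0)
  p <- summary$proportional_bias_p
  if (is.finite(p) && p < slope_p_threshold) {
    summary$loa_low <- NA_real_
    summary$loa_high <- NA_real_
    summary$percentage_error <- NA_real_
    summary$suppressed <- TRUE
    summary$warnings <- c(summary$warnings,
                          "LOA_SUPPRESSED_PROPORTIONAL_BIAS")
  }
  summary
}

#' @export
print.sv_agreement <- function(x, ...) {
  cat("Bland-Altman agreement (", x$method, ")\n", sep = "")
  cat(sprintf("  pairs: %d over %d subjects\n", x$n_pairs, x$n_subjects))
  cat(sprintf("  bias: %.2f ml (SD of differences %.2f ml)\n",
              x$bias, x$sd_diff))
  if (x$suppressed) {
    cat("  limits of agreement / percentage error: suppressed",
        "(proportional bias)\n")
  } else {
    cat(sprintf("  95%% limits of agreement: [%.2f, %.2f] ml\n",
                x$loa_low, x$loa_high))
    cat(sprintf("  percentage error: %.1f%% (mean reference %.1f ml)\n",
                x$percentage_error, x$mean_ref))
  }
  if (is.finite(x$proportional_bias_slope)) {
    cat(sprintf("  difference-vs-mean slope: %.3f (p = %.3g)\n",
                x$proportional_bias_slope, x$proportional_bias_p))
  }
  if (length(x$warnings)) {
    cat("  codes:", paste(x$warnings, collapse = ", "), "\n")
  }
  invisible(x)
}
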