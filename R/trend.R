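# Trend (change-from-baseline) agreement: delta computation, four-quadrant
# concordance with a central exclusion zone, and Pearson correlation.

#' Percent change from baseline for reference and device readings
#'
#' For each subject, the reading at the baseline step defines that subject's
#' baseline separately for the reference and for the device; every later step
#' contributes `100 * (value - baseline) / baseline` for each. Proportional
#' device bias therefore cancels: a device reading half the true SV still
#' reports the correct percent change.
#'
#' @param records Cohort data frame (see \code{\link{simulate_cohort}}) with
#'   columns `subject_id`, `step_index`, `sv_ref` and the device column.
#' @param device Device identifier; the column `sv_<device>` (or a column
#'   named exactly `device`) is used.
#' @param baseline_index Step index of the baseline record; defaults to the
#'   smallest `step_index` present.
#' @return A data frame of delta pairs (`subject_id`, `strand`, `step_index`,
#'   `step_label`, `delta_ref`, `delta_dev`), excluding the baseline step
#'   itself. Subjects lacking a usable baseline are skipped and listed in the
#'   `skipped_subjects` attribute. Negative deltas are reductions.
#' @export
compute_deltas <- function(records, device, baseline_index = NULL) {
  col <- if (device %in% names(records)) device else paste0("sv_", device)
  need <- c("subject_id", "step_index", "sv_ref")
  if (!is.data.frame(records) || !all(need %in% names(records)) ||
      !col %in% names(records)) {
    stop("`records` must contain subject_id, step_index, sv_ref and a `",
         col, "` column", call. = FALSE)
  }
  if (is.null(baseline_index)) baseline_index <- min(records$step_index)
  if (is.null(records$strand)) records$strand <- NA_character_
  if (is.null(records$step_label)) records$step_label <- NA_character_

  out <- vector("list", length(unique(records$subject_id)))
  skipped <- character()
  i <- 0L
  for (sid in unique(records$subject_id)) {
    i <- i + 1L
    sub <- records[records$subject_id == sid, , drop = FALSE]
    base <- sub[sub$step_index == baseline_index, , drop = FALSE]
    if (nrow(base) != 1L || is.na(base$sv_ref) || is.na(base[[col]])) {
      skipped <- c(skipped, sid)
      next
    }
    if (base$sv_ref <= 0 || base[[col]] <= 0) {
      stop("non-positive baseline reading for subject ", sid, call. = FALSE)
    }
    rest <- sub[sub$step_index != baseline_index, , drop = FALSE]
    rest <- rest[!is.na(rest$sv_ref) & !is.na(rest[[col]]), , drop = FALSE]
    if (!nrow(rest)) next
    out[[i]] <- data.frame(
      subject_id = rest$subject_id,
      strand = rest$strand,
      step_index = rest$step_index,
      step_label = rest$step_label,
      delta_ref = 100 * (rest$sv_ref - base$sv_ref) / base$sv_ref,
      delta_dev = 100 * (rest[[col]] - base[[col]]) / base[[col]],
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  if (is.null(res)) {
    res <- data.frame(subject_id = character(), strand = character(),
                      step_index = integer(), step_label = character(),
                      delta_ref = numeric(), delta_dev = numeric(),
                      stringsAsFactors = FALSE)
  }
  rownames(res) <- NULL
  if (length(skipped)) {
    warning("subjects skipped for missing baseline: ",
            paste(skipped, collapse = ", "), call. = FALSE)
  }
  attr(res, "skipped_subjects") <- skipped
  res
}

#' Four-quadrant concordance of paired percent changes
#'
#' A pair is excluded when it falls inside the central exclusion zone
#' (default: both `|delta| < 15`, the "central square" rule); among the
#' remaining pairs, a pair is concordant when both deltas have the same
#' strict sign. Pairs with a delta of exactly zero outside the zone carry no
#' direction and are removed from the denominator. The Pearson correlation
#' is computed over *all* pairs, without exclusion.
#'
#' @param deltas Data frame with columns `delta_ref`, `delta_dev` (percent).
#' @param exclusion_threshold Half-width of the central zone in percent
#'   (default 15).
#' @param rule Exclusion-zone membership: `"and"` (central square, default),
#'   `"or"`, or `"ref_only"` (`|delta_ref| < threshold`).
#' @return An object of class `sv_concordance`: counts (`n_total`,
#'   `n_excluded`, `n_zero`, `n_concordant`), `concordance_rate` (percent,
#'   `NA` when no pair remains), `pearson_r`, `pearson_p`,
#'   `exclusion_threshold`, `rule`, and a `points` data frame with per-pair
#'   `included` / `concordant` flags for plotting.
#' @export
four_quadrant <- function(deltas, exclusion_threshold = 15,
                          rule = c("and", "or", "ref_only")) {
  rule <- match.arg(rule)
  if (!is.data.frame(deltas) ||
      !all(c("delta_ref", "delta_dev") %in% names(deltas))) {
    stop("`deltas` must contain delta_ref and delta_dev", call. = FALSE)
  }
  if (!nrow(deltas)) stop("need at least one delta pair", call. = FALSE)
  stop_if_not_number(exclusion_threshold, "exclusion_threshold", lo = 0)
  dr <- deltas$delta_ref
  dd <- deltas$delta_dev
  th <- exclusion_threshold
  inside <- switch(rule,
                   and = abs(dr) < th & abs(dd) < th,
                   or = abs(dr) < th | abs(dd) < th,
                   ref_only = abs(dr) < th)
  zero <- !inside & (dr == 0 | dd == 0)
  included <- !inside & !zero
  concordant <- included & sign(dr) == sign(dd)
  denom <- sum(included)

  r <- NA_real_
  p <- NA_real_
  if (length(dr) >= 3L && stats::var(dr) > 0 && stats::var(dd) > 0) {
    ct <- stats::cor.test(dr, dd)
    r <- unname(ct$estimate)
    p <- ct$p.value
  }
  structure(list(n_total = length(dr),
                 n_excluded = sum(inside),
                 n_zero = sum(zero),
                 n_concordant = sum(concordant),
                 concordance_rate = if (denom > 0) 100 * sum(concordant) / denom else NA_real_,
                 pearson_r = r,
                 pearson_p = p,
                 exclusion_threshold = th,
                 rule = rule,
                 points = data.frame(delta_ref = dr, delta_dev = dd,
                                     included = included,
                                     concordant = concordant)),
            class = "sv_concordance")
}

#' Pearson correlation of paired percent changes
#'
#' Standard product-moment correlation of `delta_ref` against `delta_dev`
#' with a two-sided p-value, over all pairs.
#'
#' @param deltas Data frame with columns `delta_ref`, `delta_dev`; at least
#'   3 pairs with non-zero variance in both coordinates.
#' @return A list with elements `r` and `p`.
#' @export
delta_correlation <- function(deltas) {
  if (!is.data.frame(deltas) ||
      !all(c("delta_ref", "delta_dev") %in% names(deltas))) {
    stop("`deltas` must contain delta_ref and delta_dev", call. = FALSE)
  }
  if (nrow(deltas) < 3L) stop("need at least 3 pairs", call. = FALSE)
  if (stats::var(deltas$delta_ref) == 0 || stats::var(deltas$delta_dev) == 0) {
    stop("zero variance in one coordinate; correlation undefined",
         call. = FALSE)
  }
  ct <- stats::cor.test(deltas$delta_ref, deltas$delta_dev)
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' @export
print.sv_concordance <- function(x, ...) {
  cat("Four-quadrant concordance (", x$rule, " rule, +/-",
      x$exclusion_threshold, "% zone)\n", sep = "")
  cat(sprintf("  pairs: %d (excluded %d, zero-direction %d)\n",
              x$n_total, x$n_excluded, x$n_zero))
  if (is.na(x$concordance_rate)) {
    cat("  concordance: undefined (no pair outside the exclusion zone)\n")
  } else {
    cat(sprintf("  concordance: %d/%d = %.1f%%\n", x$n_concordant,
                x$n_total - x$n_excluded - x$n_zero, x$concordance_rate))
  }
  if (is.finite(x$pearson_r)) {
    cat(sprintf("  Pearson r = %.2f (p = %.3g)\n", x$pearson_r, x$pearson_p))
  }
  invisible(x)
}
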