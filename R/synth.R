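# Synthetic LBNP cohort and expert-questionnaire generators.
#
# The cohort simulator is phenomenological: it reproduces the statistical
# structure that the downstream agreement / trending / error-grid analyses
# assume (a graded, targeted fall in stroke volume per subject, a noisy
# reference reading, and device readings with configurable gain, offset and
# noise), not the underlying cardiovascular physiology.

#' LBNP protocol configuration
#'
#' Describes one simulated lower body negative pressure (LBNP) session: a
#' baseline measurement, fixed initial suction steps, suction steps titrated
#' to target fractions of baseline stroke volume, and a recovery step.
#'
#' @param n_subjects Number of volunteers in the cohort.
#' @param strand Study arm label: LBNP alone (`"no_tourniquet"`) or LBNP with
#'   bilateral thigh tourniquets inflated (`"tourniquet"`). The strand is a
#'   label only; by default it does not modify simulated stroke volume,
#'   mirroring the near-identical haemodynamic behaviour of the two arms.
#' @param baseline_sv_mean,baseline_sv_sd Population mean and SD (ml) of the
#'   per-subject baseline stroke volume.
#' @param step_targets Ordered fractional SV targets (of baseline), one per
#'   protocol step. The first entry must be 1 (baseline). Defaults to a
#'   seven-step protocol: baseline, two fixed suction steps (0.92, 0.85),
#'   three titrated steps (0.80, 0.675, 0.595 -- the last two are midpoints of
#'   the 65-70% and 55-64% target bands), and recovery back to 1.
#' @param step_labels Optional character labels, one per step. Defaults to
#'   `baseline`, `LBNP1..k`, `recovery`.
#' @param band_draw If `TRUE`, steps listed in `target_bands` draw their
#'   target uniformly within the band instead of using the midpoint.
#' @param target_bands Named list mapping step index (as character) to a
#'   `c(lo, hi)` fractional band, used when `band_draw = TRUE`.
#' @param within_step_cv Coefficient of variation of the achieved true SV
#'   around its target at each step (titration imprecision).
#' @param ref_cv Coefficient of variation of the reference (echocardiographic)
#'   reading around the true SV.
#' @param seed Integer seed controlling all randomness for this protocol.
#' @return An object of class `protocol_config`.
#' @export
protocol_config <- function(n_subjects = 21,
                            strand = c("no_tourniquet", "tourniquet"),
                            baseline_sv_mean = 100,
                            baseline_sv_sd = 15,
                            step_targets = c(1.00, 0.92, 0.85, 0.80, 0.675, 0.595, 1.00),
                            step_labels = NULL,
                            band_draw = FALSE,
                            target_bands = list(`5` = c(0.65, 0.70),
                                                `6` = c(0.55, 0.64)),
                            within_step_cv = 0.05,
                            ref_cv = 0.10,
                            seed = 1L) {
  strand <- match.arg(strand)
  stop_if_not_number(n_subjects, "n_subjects", lo = 1)
  stop_if_not_number(baseline_sv_mean, "baseline_sv_mean", lo = 0, strict_lo = TRUE)
  stop_if_not_number(baseline_sv_sd, "baseline_sv_sd", lo = 0)
  stop_if_not_number(within_step_cv, "within_step_cv", lo = 0)
  stop_if_not_number(ref_cv, "ref_cv", lo = 0)
  if (length(step_targets) < 2L) {
    stop("`step_targets` must contain a baseline and at least one further step",
         call. = FALSE)
  }
  if (any(!is.finite(step_targets)) || any(step_targets <= 0) ||
      any(step_targets > 1.1)) {
    stop("`step_targets` must all lie in (0, 1.1]", call. = FALSE)
  }
  if (abs(step_targets[1L] - 1) > .Machine$double.eps^0.5) {
    stop("the first entry of `step_targets` is the baseline and must be 1",
         call. = FALSE)
  }
  k <- length(step_targets)
  if (step_targets[k] < min(step_targets[-k])) {
    stop("the final step is a recovery step and must not fall below the ",
         "preceding minimum", call. = FALSE)
  }
  if (is.null(step_labels)) {
    step_labels <- c("baseline",
                     if (k > 2L) paste0("LBNP", seq_len(k - 2L)),
                     if (step_targets[k] >= 0.99) "recovery" else paste0("LBNP", k - 1L))
  }
  if (length(step_labels) != k) {
    stop("`step_labels` must have one label per step", call. = FALSE)
  }
  structure(list(n_subjects = as.integer(n_subjects),
                 strand = strand,
                 baseline_sv_mean = baseline_sv_mean,
                 baseline_sv_sd = baseline_sv_sd,
                 step_targets = step_targets,
                 step_labels = step_labels,
                 band_draw = isTRUE(band_draw),
                 target_bands = target_bands,
                 within_step_cv = within_step_cv,
                 ref_cv = ref_cv,
                 seed = as.integer(seed)),
            class = "protocol_config")
}

#' Device error model
#'
#' A candidate monitor reads `slope * sv_true * (1 + e_m) + offset + e_a`,
#' where `e_m ~ N(0, trend_noise_sd)` is multiplicative (proportional) noise
#' and `e_a ~ N(0, noise_sd)` is additive noise in ml. Readings are truncated
#' below at 1 ml so that percent-change arithmetic stays defined.
#'
#' @param name Device identifier; the cohort table gains a `sv_<name>` column.
#' @param slope Multiplicative gain on true SV (> 0).
#' @param offset Additive bias in ml.
#' @param noise_sd SD (ml) of zero-mean additive measurement noise.
#' @param trend_noise_sd SD of zero-mean multiplicative noise, which carries
#'   through unchanged into percent-change (trend) readings.
#' @return An object of class `device_model`.
#' @export
device_model <- function(name, slope = 1, offset = 0, noise_sd = 0,
                         trend_noise_sd = 0) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    stop("`name` must be a non-empty string", call. = FALSE)
  }
  stop_if_not_number(slope, "slope", lo = 0, strict_lo = TRUE)
  stop_if_not_number(offset, "offset")
  stop_if_not_number(noise_sd, "noise_sd", lo = 0)
  stop_if_not_number(trend_noise_sd, "trend_noise_sd", lo = 0)
  structure(list(name = name, slope = slope, offset = offset,
                 noise_sd = noise_sd, trend_noise_sd = trend_noise_sd),
            class = "device_model")
}

#' Default thoracic-bioimpedance-like device model
#'
#' A device with a large proportional under-reading (gain 0.5) so that its
#' bias grows with stroke volume, plus moderate additive noise. Its percent
#' changes track the truth well because the gain cancels in ratios.
#' @return A `device_model`.
#' @export
device_teb <- function() {
  device_model("teb", slope = 0.5, offset = 5, noise_sd = 6,
               trend_noise_sd = 0.05)
}

#' Default suprasternal-Doppler-like device model
#'
#' A device with no systematic gain or offset but wide random error, split
#' between a proportional component and a small additive component.
#' @return A `device_model`.
#' @export
device_ssd <- function() {
  device_model("ssd", slope = 1, offset = 0, noise_sd = 4,
               trend_noise_sd = 0.10)
}

#' Simulate a paired-measurement LBNP cohort
#'
#' For each subject a baseline SV is drawn from
#' `N(baseline_sv_mean, baseline_sv_sd)`; at each protocol step the true SV is
#' `baseline * target * (1 + N(0, within_step_cv))`, the reference reading is
#' `sv_true * (1 + N(0, ref_cv))`, and each device reads according to its
#' \code{\link{device_model}}. All readings are truncated below at 1 ml.
#' Device noise streams are seeded per device name, so removing a device from
#' `devices` leaves every other column bit-identical.
#'
#' @param config A \code{\link{protocol_config}}.
#' @param devices A list of \code{\link{device_model}} objects (non-empty,
#'   unique names).
#' @return A data frame with one row per subject and step: `subject_id`,
#'   `strand`, `step_index`, `step_label`, `sv_true`, `sv_ref`, and one
#'   `sv_<name>` column per device.
#' @export
simulate_cohort <- function(config, devices = list(device_teb(), device_ssd())) {
  if (!inherits(config, "protocol_config")) {
    stop("`config` must be a `protocol_config`", call. = FALSE)
  }
  if (inherits(devices, "device_model")) devices <- list(devices)
  if (length(devices) == 0L ||
      !all(vapply(devices, inherits, TRUE, "device_model"))) {
    stop("`devices` must be a non-empty list of `device_model` objects",
         call. = FALSE)
  }
  dev_names <- vapply(devices, `[[`, "", "name")
  if (anyDuplicated(dev_names)) stop("device names must be unique", call. = FALSE)

  ns <- config$n_subjects
  nt <- length(config$step_targets)
  set.seed(config$seed)
  baseline <- pmax(stats::rnorm(ns, config$baseline_sv_mean, config$baseline_sv_sd), 1)
  targets <- matrix(rep(config$step_targets, each = ns), ns, nt)
  if (config$band_draw && length(config$target_bands)) {
    for (s in names(config$target_bands)) {
      i <- as.integer(s)
      if (is.na(i) || i < 1L || i > nt) next
      b <- config$target_bands[[s]]
      targets[, i] <- stats::runif(ns, b[1L], b[2L])
    }
  }
  sv_true <- pmax(baseline * targets *
                    (1 + matrix(stats::rnorm(ns * nt, 0, config$within_step_cv), ns, nt)),
                  1)
  sv_ref <- pmax(sv_true *
                   (1 + matrix(stats::rnorm(ns * nt, 0, config$ref_cv), ns, nt)),
                 1)

  out <- data.frame(
    subject_id = rep(sprintf("S%02d", seq_len(ns)), each = nt),
    strand = config$strand,
    step_index = rep(seq_len(nt), times = ns),
    step_label = rep(config$step_labels, times = ns),
    sv_true = as.vector(t(sv_true)),
    sv_ref = as.vector(t(sv_ref)),
    stringsAsFactors = FALSE
  )
  for (d in devices) {
    set.seed(device_seed(config$seed, d$name))
    mult <- 1 + matrix(stats::rnorm(ns * nt, 0, d$trend_noise_sd), ns, nt)
    addn <- matrix(stats::rnorm(ns * nt, 0, d$noise_sd), ns, nt)
    reading <- pmax(d$slope * sv_true * mult + d$offset + addn, 1)
    out[[paste0("sv_", d$name)]] <- as.vector(t(reading))
  }
  out
}

#' Write / read a cohort table as CSV
#'
#' @param cohort A cohort data frame as produced by
#'   \code{\link{simulate_cohort}}.
#' @param path File path.
#' @return `read_cohort_csv` returns the cohort data frame;
#'   `write_cohort_csv` returns `path` invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "step_index", "sv_ref")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("cohort CSV is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(df$strand)) df$strand <- "no_tourniquet"
  df
}

# ---------------------------------------------------------------------------
# Expert questionnaire
# ---------------------------------------------------------------------------

#' Generate synthetic expert respondent profiles
#'
#' Each respondent is characterised by two action thresholds on the percent
#' fall in SV: the fall at which treatment is *indicated* and the fall at
#' which it is *essential*, plus a probability of +/-1-category rating jitter.
#'
#' @param n_respondents Number of experts.
#' @param rating_noise Probability that an off-diagonal rating is jittered by
#'   one category.
#' @param seed Optional seed; when `NULL` the current RNG stream is used.
#' @return A data frame with columns `respondent_id`,
#'   `threshold_action_indicated`, `threshold_action_essential`,
#'   `rating_noise`.
#' @export
respondent_profiles <- function(n_respondents, rating_noise = 0, seed = NULL) {
  stop_if_not_number(n_respondents, "n_respondents", lo = 1)
  stop_if_not_number(rating_noise, "rating_noise", lo = 0)
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n_respondents)
  t_ind <- sample(c(10, 15, 20, 25), n, replace = TRUE)
  t_ess <- pmin(t_ind + sample(c(15, 20, 25), n, replace = TRUE), 60)
  data.frame(respondent_id = sprintf("R%02d", seq_len(n)),
             threshold_action_indicated = t_ind,
             threshold_action_essential = t_ess,
             rating_noise = rating_noise,
             stringsAsFactors = FALSE)
}

#' Harm rating implied by a respondent's action thresholds
#'
#' Falls in SV are binned into action categories (none / indicated /
#' essential) by the respondent's thresholds. A cell's harm rating depends on
#' the mismatch between the category of the actual fall and that of the
#' measured fall: no mismatch (or actual == measured) is `none`; a
#' one-category mismatch is `mild`, except that under-reading a fall that
#' made action essential is `moderate`; a two-category mismatch is `severe`.
#'
#' @param actual,measured Percent falls in SV (non-negative), recycled.
#' @param t_indicated,t_essential Action thresholds, with
#'   `0 < t_indicated < t_essential <= 60`; recycled.
#' @return A factor with levels none < mild < moderate < severe.
#' @export
harm_rating <- function(actual, measured, t_indicated, t_essential) {
  n <- max(length(actual), length(measured), length(t_indicated),
           length(t_essential))
  actual <- rep_len(actual, n); measured <- rep_len(measured, n)
  t1 <- rep_len(t_indicated, n); t2 <- rep_len(t_essential, n)
  if (any(!(t1 > 0 & t1 < t2 & t2 <= 60))) {
    stop("thresholds must satisfy 0 < indicated < essential <= 60",
         call. = FALSE)
  }
  ca <- (actual >= t1) + (actual >= t2)
  cm <- (measured >= t1) + (measured >= t2)
  gap <- abs(cm - ca)
  r <- rep("none", n)
  over <- measured > actual   # device overstates the fall (overtreatment risk)
  r[gap == 1L & over] <- "mild"
  r[gap == 1L & !over & ca == 2L] <- "moderate"
  r[gap == 1L & !over & ca != 2L] <- "mild"
  r[gap >= 2L] <- "severe"
  r[actual == measured] <- "none"
  factor(r, levels = harm_levels())
}

#' Simulate expert-questionnaire returns
#'
#' Generates one complete rating over the `grid_steps x grid_steps`
#' (actual fall x measured fall) grid per respondent, using
#' \code{\link{harm_rating}} under each respondent's thresholds and then
#' applying +/-1-category jitter with probability `rating_noise` to
#' off-diagonal cells. Diagonal cells are always `none`.
#'
#' @param n_respondents Number of experts (>= 1).
#' @param grid_steps Strictly increasing percent-reduction values starting at
#'   0; defaults to 0, 10, ..., 60.
#' @param profiles Optional data frame as from
#'   \code{\link{respondent_profiles}}; when `NULL` profiles are drawn.
#' @param rating_noise Jitter probability used when `profiles` is `NULL`.
#' @param seed Integer seed.
#' @return A long-form data frame (`respondent_id`, `actual_reduction_pct`,
#'   `measured_reduction_pct`, `rating`) with attribute `grid_steps`.
#' @export
simulate_questionnaire <- function(n_respondents = 15,
                                   grid_steps = seq(0, 60, by = 10),
                                   profiles = NULL,
                                   rating_noise = 0,
                                   seed = 1L) {
  stop_if_not_number(n_respondents, "n_respondents", lo = 1)
  if (length(grid_steps) < 2L || grid_steps[1L] != 0 ||
      any(diff(grid_steps) <= 0)) {
    stop("`grid_steps` must be strictly increasing and start at 0",
         call. = FALSE)
  }
  set.seed(seed)
  if (is.null(profiles)) {
    profiles <- respondent_profiles(n_respondents, rating_noise)
  } else {
    need <- c("respondent_id", "threshold_action_indicated",
              "threshold_action_essential")
    if (!all(need %in% names(profiles))) {
      stop("`profiles` must contain columns ",
           paste(need, collapse = ", "), call. = FALSE)
    }
    if (is.null(profiles$rating_noise)) profiles$rating_noise <- rating_noise
    if (nrow(profiles) != n_respondents) {
      stop("`profiles` must have one row per respondent", call. = FALSE)
    }
  }
  cells <- expand.grid(measured_reduction_pct = grid_steps,
                       actual_reduction_pct = grid_steps,
                       KEEP.OUT.ATTRS = FALSE)
  nc <- nrow(cells)
  n <- nrow(profiles)
  df <- data.frame(
    respondent_id = rep(profiles$respondent_id, each = nc),
    actual_reduction_pct = rep(cells$actual_reduction_pct, times = n),
    measured_reduction_pct = rep(cells$measured_reduction_pct, times = n),
    stringsAsFactors = FALSE
  )
  t1 <- rep(profiles$threshold_action_indicated, each = nc)
  t2 <- rep(profiles$threshold_action_essential, each = nc)
  noise <- rep(profiles$rating_noise, each = nc)
  df$rating <- harm_rating(df$actual_reduction_pct, df$measured_reduction_pct,
                           t1, t2)
  # jitter: draw for every cell to keep the RNG stream independent of which
  # cells happen to be eligible
  u <- stats::runif(nrow(df))
  dir <- sample(c(-1L, 1L), nrow(df), replace = TRUE)
  jit <- df$actual_reduction_pct != df$measured_reduction_pct & u < noise
  ri <- as.integer(df$rating)
  ri[jit] <- clamp(ri[jit] + dir[jit], 1L, 4L)
  df$rating <- factor(harm_levels()[ri], levels = harm_levels())
  attr(df, "grid_steps") <- grid_steps
  df
}

#' Write / read questionnaire returns as long-form CSV
#'
#' @param returns A long-form returns data frame as produced by
#'   \code{\link{simulate_questionnaire}}.
#' @param path File path.
#' @return `read_questionnaire_csv` returns the returns data frame;
#'   `write_questionnaire_csv` returns `path` invisibly.
#' @export
write_questionnaire_csv <- function(returns, path) {
  utils::write.csv(returns, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_questionnaire_csv
#' @export
read_questionnaire_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("respondent_id", "actual_reduction_pct", "measured_reduction_pct",
            "rating")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("questionnaire CSV is missing columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  bad <- setdiff(unique(df$rating), harm_levels())
  if (length(bad)) {
    stop("unknown rating values: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  df$rating <- factor(df$rating, levels = harm_levels())
  attr(df, "grid_steps") <- sort(unique(df$actual_reduction_pct))
  df
}
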