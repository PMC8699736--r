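# End-to-end orchestration: simulate or load a cohort, run agreement,
# trending and error-grid analyses per device and strand, and write
# deterministic CSV/JSON outputs.

#' Pipeline run configuration
#'
#' @param mode `"simulate"` (generate a cohort and questionnaire) or
#'   `"load"` (read a cohort CSV; zones from file or a questionnaire CSV).
#' @param protocol A \code{\link{protocol_config}} used in simulate mode;
#'   its `strand` and `seed` are overridden per strand from `strands` and
#'   `seed`.
#' @param devices In simulate mode, a list of \code{\link{device_model}}s;
#'   in load mode, optionally a character vector of device names (defaults
#'   to every `sv_<name>` column except `sv_true` / `sv_ref`).
#' @param strands Strand labels to analyse.
#' @param cohort_csv,questionnaire_csv,zones_file Input paths (load mode /
#'   optional overrides). When `zones_file` is given it bypasses grid
#'   derivation.
#' @param n_respondents,grid_steps,rating_noise Questionnaire simulation
#'   settings used when no questionnaire or zones file is supplied.
#' @param exclusion_threshold Four-quadrant central exclusion half-width, %.
#' @param pct_thresholds Zone banding thresholds, see
#'   \code{\link{derive_zones}}.
#' @param slope_p_threshold Proportional-bias suppression threshold, see
#'   \code{\link{suppress_loa_if_proportional}}.
#' @param seed Master integer seed; all stage seeds derive from it.
#' @param out_dir Output directory; when `NULL` nothing is written.
#' @return An object of class `sv_run_config`.
#' @export
run_config <- function(mode = c("simulate", "load"),
                       protocol = protocol_config(),
                       devices = list(device_teb(), device_ssd()),
                       strands = c("no_tourniquet", "tourniquet"),
                       cohort_csv = NULL,
                       questionnaire_csv = NULL,
                       zones_file = NULL,
                       n_respondents = 15,
                       grid_steps = seq(0, 60, by = 10),
                       rating_noise = 0.05,
                       exclusion_threshold = 15,
                       pct_thresholds = c(mild = 13.3, moderate = 35, severe = 75),
                       slope_p_threshold = 0.05,
                       seed = 1L,
                       out_dir = NULL) {
  mode <- match.arg(mode)
  if (mode == "load" && is.null(cohort_csv)) {
    stop("load mode requires `cohort_csv`", call. = FALSE)
  }
  if (mode == "simulate" && !inherits(protocol, "protocol_config")) {
    stop("simulate mode requires a `protocol_config`", call. = FALSE)
  }
  structure(list(mode = mode, protocol = protocol, devices = devices,
                 strands = strands, cohort_csv = cohort_csv,
                 questionnaire_csv = questionnaire_csv,
                 zones_file = zones_file, n_respondents = n_respondents,
                 grid_steps = grid_steps, rating_noise = rating_noise,
                 exclusion_threshold = exclusion_threshold,
                 pct_thresholds = pct_thresholds,
                 slope_p_threshold = slope_p_threshold,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "sv_run_config")
}

#' Run the full comparison pipeline
#'
#' Simulates (or loads) the paired-measurement cohort, obtains risk zones
#' (from file, from a questionnaire CSV, or by simulating a questionnaire
#' and deriving zones), and for every device x strand combination computes
#' the repeated-measures Bland-Altman summary (with proportional-bias
#' suppression), the four-quadrant concordance and the error-grid zone
#' summary. Per-device combined severe-harm rates are added when exactly two
#' strands are analysed. Stage failures are isolated per combination and
#' reported, not silently dropped. Re-running with an identical
#' configuration reproduces all outputs byte for byte.
#'
#' @param config An \code{\link{run_config}} object.
#' @return An object of class `sv_run_report` (also written as
#'   `report.json` / `report.txt` plus intermediate CSVs when
#'   `config$out_dir` is set).
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "sv_run_config")) {
    stop("`config` must come from run_config()", call. = FALSE)
  }

  questionnaire <- NULL
  harm_grid <- NULL

  if (config$mode == "simulate") {
    dev_names <- vapply(config$devices, `[[`, "", "name")
    cohort <- do.call(rbind, lapply(config$strands, function(st) {
      p <- config$protocol
      p$strand <- st
      p$seed <- strand_seed(config$seed, st)
      simulate_cohort(p, config$devices)
    }))
  } else {
    cohort <- read_cohort_csv(config$cohort_csv)
    sv_cols <- sub("^sv_", "", grep("^sv_", names(cohort), value = TRUE))
    dev_names <- if (is.character(config$devices)) config$devices
                 else setdiff(sv_cols, c("true", "ref"))
  }
  strands <- intersect(config$strands, unique(cohort$strand))
  if (!length(strands)) stop("no requested strand present in the cohort",
                             call. = FALSE)

  if (!is.null(config$zones_file)) {
    zones <- read_zones_json(config$zones_file)
  } else {
    questionnaire <- if (!is.null(config$questionnaire_csv)) {
      read_questionnaire_csv(config$questionnaire_csv)
    } else {
      simulate_questionnaire(config$n_respondents, config$grid_steps,
                             rating_noise = config$rating_noise,
                             seed = device_seed(config$seed, "questionnaire"))
    }
    harm_grid <- build_harm_grid(questionnaire)
    zones <- derive_zones(harm_grid, config$pct_thresholds)
  }

  results <- list()
  for (dev in dev_names) {
    results[[dev]] <- list()
    col <- paste0("sv_", dev)
    for (st in strands) {
      results[[dev]][[st]] <- tryCatch({
        sub <- cohort[cohort$strand == st, , drop = FALSE]
        pairs <- data.frame(subject_id = sub$subject_id,
                            sv_ref = sub$sv_ref,
                            sv_dev = sub[[col]],
                            stringsAsFactors = FALSE)
        agr <- suppress_loa_if_proportional(bland_altman_repeated(pairs),
                                            config$slope_p_threshold)
        ok <- stats::complete.cases(pairs[, c("sv_ref", "sv_dev")])
        ba_points <- data.frame(
          subject_id = pairs$subject_id[ok],
          mean = (pairs$sv_ref[ok] + pairs$sv_dev[ok]) / 2,
          difference = pairs$sv_dev[ok] - pairs$sv_ref[ok],
          stringsAsFactors = FALSE)
        deltas <- compute_deltas(sub, dev)
        trend <- four_quadrant(deltas, config$exclusion_threshold)
        classified <- classify_points(deltas, zones)
        list(failed = FALSE, agreement = agr, ba_points = ba_points,
             trend = trend, zone = zone_summary(classified), deltas = deltas,
             classified = classified)
      }, error = function(e) {
        list(failed = TRUE, reason = conditionMessage(e))
      })
    }
    if (length(strands) == 2L) {
      a <- results[[dev]][[strands[1L]]]
      b <- results[[dev]][[strands[2L]]]
      if (!a$failed && !b$failed) {
        results[[dev]]$combined <- zone_summary(a$classified, b$classified)
      }
    }
  }

  report <- structure(list(
    provenance = list(
      package = "svagree",
      version = as.character(utils::packageVersion("svagree")),
      mode = config$mode,
      seed = config$seed,
      devices = dev_names,
      strands = strands,
      exclusion_threshold = config$exclusion_threshold,
      pct_thresholds = unname(config$pct_thresholds),
      slope_p_threshold = config$slope_p_threshold,
      zones_provenance = zones$provenance
    ),
    results = results
  ), class = "sv_run_report")

  if (!is.null(config$out_dir)) {
    write_run_outputs(report, config, cohort, questionnaire, harm_grid, zones)
  }
  report
}

# Flatten an sv_agreement / sv_concordance / zone_summary into plain lists
# and one-row data frames for serialisation.
agreement_row <- function(dev, st, a) {
  data.frame(device = dev, strand = st, n_pairs = a$n_pairs,
             n_subjects = a$n_subjects, bias = a$bias, sd_diff = a$sd_diff,
             loa_low = a$loa_low, loa_high = a$loa_high,
             percentage_error = a$percentage_error,
             proportional_bias_slope = a$proportional_bias_slope,
             proportional_bias_p = a$proportional_bias_p,
             method = a$method, suppressed = a$suppressed,
             warnings = paste(a$warnings, collapse = ";"),
             stringsAsFactors = FALSE)
}

trend_row <- function(dev, st, t) {
  data.frame(device = dev, strand = st, n_total = t$n_total,
             n_excluded = t$n_excluded, n_zero = t$n_zero,
             n_concordant = t$n_concordant,
             concordance_rate = t$concordance_rate,
             pearson_r = t$pearson_r, pearson_p = t$pearson_p,
             exclusion_threshold = t$exclusion_threshold, rule = t$rule,
             stringsAsFactors = FALSE)
}

zone_row <- function(dev, st, z) {
  cbind(data.frame(device = dev, strand = st, n_points = z$n_points,
                   stringsAsFactors = FALSE),
        as.data.frame(as.list(z$counts)),
        stats::setNames(as.data.frame(as.list(z$percentages)),
                        paste0(harm_levels(), "_pct")))
}

write_run_outputs <- function(report, config, cohort, questionnaire,
                              harm_grid, zones) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)
  utils::write.csv(cohort, out("cohort.csv"), row.names = FALSE)
  if (!is.null(questionnaire)) {
    utils::write.csv(questionnaire, out("questionnaire.csv"), row.names = FALSE)
  }
  if (!is.null(harm_grid)) {
    utils::write.csv(as.data.frame(harm_grid), out("harm_grid.csv"),
                     row.names = FALSE)
  }
  write_zones_json(zones, out("zones.json"))

  arows <- list(); trows <- list(); zrows <- list()
  for (dev in names(report$results)) {
    for (st in setdiff(names(report$results[[dev]]), "combined")) {
      res <- report$results[[dev]][[st]]
      if (isTRUE(res$failed)) next
      tag <- paste0(dev, "_", st)
      utils::write.csv(res$ba_points,
                       out(paste0("ba_points_", tag, ".csv")),
                       row.names = FALSE)
      utils::write.csv(res$trend$points,
                       out(paste0("fourquad_points_", tag, ".csv")),
                       row.names = FALSE)
      utils::write.csv(res$classified,
                       out(paste0("classified_points_", tag, ".csv")),
                       row.names = FALSE)
      arows[[tag]] <- agreement_row(dev, st, res$agreement)
      trows[[tag]] <- trend_row(dev, st, res$trend)
      zrows[[tag]] <- zone_row(dev, st, res$zone)
    }
  }
  if (length(arows)) {
    utils::write.csv(do.call(rbind, arows), out("agreement_summary.csv"),
                     row.names = FALSE)
    utils::write.csv(do.call(rbind, trows), out("trend_summary.csv"),
                     row.names = FALSE)
    utils::write.csv(do.call(rbind, zrows), out("zone_summary.csv"),
                     row.names = FALSE)
  }

  jsonlite::write_json(report_as_list(report), out("report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  writeLines(utils::capture.output(print(report)), out("report.txt"))
  invisible(config$out_dir)
}

report_as_list <- function(report) {
  res <- lapply(report$results, function(by_strand) {
    lapply(by_strand, function(r) {
      if (inherits(r, "zone_summary")) {
        return(list(combined_severe_pct = r$combined_severe_pct,
                    n_pooled = r$n_pooled))
      }
      if (isTRUE(r$failed)) return(list(failed = TRUE, reason = r$reason))
      list(failed = FALSE,
           agreement = unclass(r$agreement),
           trend = unclass(r$trend)[setdiff(names(unclass(r$trend)), "points")],
           zones = list(counts = as.list(r$zone$counts),
                        percentages = as.list(r$zone$percentages),
                        n_points = r$zone$n_points))
    })
  })
  list(provenance = report$provenance, results = res)
}

#' @export
print.sv_run_report <- function(x, ...) {
  cat("Stroke-volume monitor comparison run\n")
  cat("  mode:", x$provenance$mode, " seed:", x$provenance$seed,
      " zones:", x$provenance$zones_provenance, "\n")
  for (dev in names(x$results)) {
    for (st in names(x$results[[dev]])) {
      r <- x$results[[dev]][[st]]
      cat("\n== device:", dev, "| strand:", st, "==\n")
      if (inherits(r, "zone_summary")) {
        cat(sprintf("  combined severe-harm rate: %.1f%% of %d points\n",
                    r$combined_severe_pct, r$n_pooled))
        next
      }
      if (isTRUE(r$failed)) {
        cat("  FAILED:", r$reason, "\n")
        next
      }
      print(r$agreement)
      print(r$trend)
      print(r$zone)
    }
  }
  invisible(x)
}
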