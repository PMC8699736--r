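# Expert-opinion error grid: harm scoring, risk-zone polygons, point
# classification and zone summaries.
#
# Coordinates throughout are *reductions*: percent falls in stroke volume,
# with the actual fall on the x axis and the device-measured fall on the y
# axis. The grid is deliberately not symmetrised: overestimating blood loss
# (unnecessary transfusion) and underestimating it (withheld treatment) harm
# differently.

#' Numerical harm weights
#'
#' The weight attached to each harm category when aggregating questionnaire
#' ratings; defaults None 0, Mild 2, Moderate 5, Severe 10.
#'
#' @param none,mild,moderate,severe Strictly increasing weights with
#'   `none = 0`.
#' @return A named numeric vector of class `harm_weights`.
#' @export
harm_weights <- function(none = 0, mild = 2, moderate = 5, severe = 10) {
  w <- c(none = none, mild = mild, moderate = moderate, severe = severe)
  if (w[["none"]] != 0) stop("the `none` weight must be 0", call. = FALSE)
  if (any(diff(w) <= 0)) stop("weights must be strictly increasing", call. = FALSE)
  structure(w, class = "harm_weights")
}

#' Build the combined harm grid from questionnaire returns
#'
#' Each cell's raw score is the sum over respondents of the weight of that
#' respondent's rating, giving a range from 0 (every respondent saw no
#' potential for harm) to `severe_weight * n_respondents` (every respondent
#' saw severe harm; 150 for 15 respondents under the default weights). Scores
#' are also expressed as a percentage of that maximum.
#'
#' @param returns Long-form returns (`respondent_id`, `actual_reduction_pct`,
#'   `measured_reduction_pct`, `rating`), e.g. from
#'   \code{\link{simulate_questionnaire}} or
#'   \code{\link{read_questionnaire_csv}}. Every respondent must rate every
#'   cell of the same grid exactly once.
#' @param weights A \code{\link{harm_weights}} vector.
#' @return An object of class `harm_grid`: `grid_steps`, `raw` and `pct`
#'   matrices (rows = actual reduction, columns = measured reduction),
#'   `n_respondents`, `max_score`, `weights`.
#' @export
build_harm_grid <- function(returns, weights = harm_weights()) {
  need <- c("respondent_id", "actual_reduction_pct", "measured_reduction_pct",
            "rating")
  if (!is.data.frame(returns) || !all(need %in% names(returns))) {
    stop("`returns` must contain ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (!nrow(returns)) stop("`returns` is empty", call. = FALSE)
  if (!inherits(weights, "harm_weights")) weights <- do.call(harm_weights, as.list(weights))
  steps <- sort(unique(returns$actual_reduction_pct))
  if (!setequal(steps, unique(returns$measured_reduction_pct))) {
    stop("actual and measured grid steps differ", call. = FALSE)
  }
  resp <- unique(returns$respondent_id)
  nc <- length(steps)^2
  tab <- table(returns$respondent_id,
               factor(returns$actual_reduction_pct, steps),
               factor(returns$measured_reduction_pct, steps))
  if (any(tab != 1L)) {
    stop("every respondent must rate every (actual, measured) cell exactly ",
         "once on a common grid", call. = FALSE)
  }
  rating <- as.character(returns$rating)
  bad <- setdiff(unique(rating), names(weights))
  if (length(bad)) stop("unknown ratings: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  w <- unclass(weights)[rating]
  raw <- tapply(w,
                list(factor(returns$actual_reduction_pct, steps),
                     factor(returns$measured_reduction_pct, steps)),
                sum)
  raw <- matrix(raw, length(steps), length(steps),
                dimnames = list(actual = steps, measured = steps))
  max_score <- unname(unclass(weights)[["severe"]] * length(resp))
  structure(list(grid_steps = steps,
                 raw = raw,
                 pct = 100 * raw / max_score,
                 n_respondents = length(resp),
                 max_score = max_score,
                 weights = weights),
            class = "harm_grid")
}

#' @export
print.harm_grid <- function(x, ...) {
  cat(sprintf("Harm grid: %d x %d cells, %d respondents, max score %d\n",
              length(x$grid_steps), length(x$grid_steps), x$n_respondents,
              x$max_score))
  print(round(x$pct, 1))
  invisible(x)
}

#' Export the percentage harm grid as a long-form data frame
#'
#' @param x A `harm_grid`.
#' @param ... Unused.
#' @return Data frame with `actual_reduction_pct`, `measured_reduction_pct`,
#'   `raw_score`, `pct_score`.
#' @export
as.data.frame.harm_grid <- function(x, ...) {
  g <- expand.grid(actual_reduction_pct = x$grid_steps,
                   measured_reduction_pct = x$grid_steps,
                   KEEP.OUT.ATTRS = FALSE)
  i <- match(g$actual_reduction_pct, x$grid_steps)
  j <- match(g$measured_reduction_pct, x$grid_steps)
  g$raw_score <- x$raw[cbind(i, j)]
  g$pct_score <- x$pct[cbind(i, j)]
  g
}

# Cell edges: grid points are cell centres; interior edges fall midway
# between adjacent points and the outer edges coincide with the domain
# limits.
grid_edges <- function(steps) {
  c(steps[1L], (steps[-1L] + steps[-length(steps)]) / 2, steps[length(steps)])
}

band_of_pct <- function(pct, thresholds) {
  1L + (pct >= thresholds[1L]) + (pct >= thresholds[2L]) + (pct >= thresholds[3L])
}

#' Derive risk-zone polygons from a harm grid
#'
#' Cells are banded by thresholding their percentage score, and contiguous
#' runs of same-band cells are merged into rectilinear polygons (no
#' smoothing). The four zones jointly tile the grid domain.
#'
#' @param grid A \code{\link{build_harm_grid}} result.
#' @param pct_thresholds Increasing percentage thresholds
#'   `(mild, moderate, severe)` in (0, 100]; a cell is `none` below the first
#'   threshold, `severe` at or above the last. The defaults (13.3, 35, 75)
#'   place the band edges below a uniformly-Mild panel, midway between
#'   uniformly-Mild and uniformly-Moderate, and at a Severe-dominant score.
#' @return An object of class `zone_set`: `zones` (named list of lists of
#'   polygon vertex matrices, in harm order), `domain`, `provenance`
#'   (`"derived_from_grid"`), plus the banded cells and edges for
#'   diagnostics.
#' @export
derive_zones <- function(grid, pct_thresholds = c(mild = 13.3, moderate = 35,
                                                  severe = 75)) {
  if (!inherits(grid, "harm_grid")) stop("`grid` must be a `harm_grid`",
                                         call. = FALSE)
  th <- unname(pct_thresholds)
  if (length(th) != 3L || any(!is.finite(th)) || any(diff(th) <= 0) ||
      th[1L] <= 0 || th[3L] > 100) {
    stop("`pct_thresholds` must be three increasing values in (0, 100]",
         call. = FALSE)
  }
  steps <- grid$grid_steps
  edges <- grid_edges(steps)
  bands <- band_of_pct(grid$pct, th)   # matrix [actual, measured]
  ncell <- length(steps)
  zones <- stats::setNames(vector("list", 4L), harm_levels())
  for (z in seq_len(4L)) {
    polys <- list()
    for (j in seq_len(ncell)) {          # rows of constant measured (y)
      in_band <- bands[, j] == z
      if (!any(in_band)) next
      r <- rle(in_band)
      stops <- cumsum(r$lengths)
      starts <- stops - r$lengths + 1L
      for (q in which(r$values)) {
        x0 <- edges[starts[q]]
        x1 <- edges[stops[q] + 1L]
        y0 <- edges[j]
        y1 <- edges[j + 1L]
        polys[[length(polys) + 1L]] <-
          matrix(c(x0, y0, x1, y0, x1, y1, x0, y1), ncol = 2L, byrow = TRUE)
      }
    }
    zones[[z]] <- polys
  }
  structure(list(zones = zones,
                 domain = range(edges),
                 provenance = "derived_from_grid",
                 grid_steps = steps,
                 edges = edges,
                 bands = bands,
                 pct_thresholds = th),
            class = "zone_set")
}

#' Construct a zone set from explicit polygons
#'
#' @param zones Named list (`none`, `mild`, `moderate`, `severe`), each
#'   either a single polygon (n x 2 vertex matrix / list of `[x, y]` pairs)
#'   or a list of polygons; empty zones may be omitted or `NULL`.
#' @param domain Numeric `c(lo, hi)`, the square plotting domain in percent
#'   reduction (default `c(0, 60)`).
#' @param provenance Provenance tag.
#' @return A `zone_set`.
#' @export
zone_set <- function(zones, domain = c(0, 60),
                     provenance = "loaded_from_file") {
  if (!is.list(zones) || !all(names(zones) %in% harm_levels())) {
    stop("`zones` must be a named list with names among ",
         paste(harm_levels(), collapse = ", "), call. = FALSE)
  }
  norm_poly <- function(p) {
    if (is.list(p)) p <- do.call(rbind, lapply(p, function(v) unlist(v)))
    p <- as.matrix(p)
    storage.mode(p) <- "double"
    if (ncol(p) != 2L || nrow(p) < 3L || any(!is.finite(p))) {
      stop("each polygon needs >= 3 finite (x, y) vertices", call. = FALSE)
    }
    # drop a repeated closing vertex
    if (all(p[1L, ] == p[nrow(p), ])) p <- p[-nrow(p), , drop = FALSE]
    if (nrow(p) < 3L) stop("degenerate polygon", call. = FALSE)
    p
  }
  out <- stats::setNames(vector("list", 4L), harm_levels())
  for (z in harm_levels()) {
    entry <- zones[[z]]
    if (is.null(entry) || !length(entry)) { out[[z]] <- list(); next }
    # a bare polygon is a list of coordinate pairs or a matrix
    is_single <- is.matrix(entry) ||
      (is.list(entry) && length(entry[[1L]]) == 2L && is.numeric(unlist(entry[[1L]])))
    out[[z]] <- if (is_single) list(norm_poly(entry)) else lapply(entry, norm_poly)
  }
  if (length(domain) != 2L || domain[1L] >= domain[2L]) {
    stop("`domain` must be c(lo, hi) with lo < hi", call. = FALSE)
  }
  structure(list(zones = out, domain = as.numeric(domain),
                 provenance = provenance),
            class = "zone_set")
}

#' Read / write a zone set as JSON
#'
#' The JSON layout is `{"zones": {"none": [...], ...}, "domain": [0, 60]}`
#' where each zone is a polygon (list of `[x, y]` vertices) or a list of
#' such polygons.
#'
#' @param path File path.
#' @param zones A `zone_set` (for writing).
#' @return `read_zones_json` returns a `zone_set`; `write_zones_json`
#'   returns `path` invisibly.
#' @export
read_zones_json <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(obj$zones)) stop("zones JSON must contain a `zones` object",
                               call. = FALSE)
  domain <- if (!is.null(obj$domain)) unlist(obj$domain) else c(0, 60)
  zone_set(obj$zones, domain = domain, provenance = "loaded_from_file")
}

#' @rdname read_zones_json
#' @export
write_zones_json <- function(zones, path) {
  if (!inherits(zones, "zone_set")) stop("`zones` must be a `zone_set`",
                                         call. = FALSE)
  ser <- lapply(zones$zones, function(polys) {
    lapply(polys, function(p) lapply(seq_len(nrow(p)), function(i) p[i, ]))
  })
  jsonlite::write_json(list(zones = ser, domain = zones$domain), path,
                       auto_unbox = FALSE, digits = NA)
  invisible(path)
}

# Point-in-polygon, boundary inclusive. Axis-aligned rectangles (the output
# of derive_zones) take a fast bounding-box path; general simple polygons use
# an even-odd ray cast with an explicit on-edge test.
point_in_polygon <- function(px, py, poly, tol = 1e-9) {
  n <- nrow(poly)
  if (n == 4L &&
      length(unique(poly[, 1L])) == 2L && length(unique(poly[, 2L])) == 2L) {
    return(px >= min(poly[, 1L]) - tol && px <= max(poly[, 1L]) + tol &&
           py >= min(poly[, 2L]) - tol && py <= max(poly[, 2L]) + tol)
  }
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1L]; yi <- poly[i, 2L]
    xj <- poly[j, 1L]; yj <- poly[j, 2L]
    if (abs((px - xi) * (yj - yi) - (py - yi) * (xj - xi)) <= tol *
          max(1, abs(xj - xi), abs(yj - yi)) &&
        px >= min(xi, xj) - tol && px <= max(xi, xj) + tol &&
        py >= min(yi, yj) - tol && py <= max(yi, yj) + tol) {
      return(TRUE)
    }
    if ((yi > py) != (yj > py)) {
      xint <- xi + (py - yi) * (xj - xi) / (yj - yi)
      if (px < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

#' Classify measurement pairs into risk zones
#'
#' Delta pairs (signed percent changes; negative = reduction) are converted
#' to reduction coordinates (`x = -delta_ref`, `y = -delta_dev`), clamped to
#' the zone domain, and assigned by point-in-polygon test. Zones are tested
#' from severe down to none, so a point on a shared boundary is assigned to
#' the higher-harm zone (conservative tie-break).
#'
#' @param deltas Data frame with `delta_ref`, `delta_dev` columns (e.g. from
#'   \code{\link{compute_deltas}}).
#' @param zones A `zone_set`.
#' @return `deltas` with added columns `reduction_ref`, `reduction_dev` and
#'   `zone` (factor none < mild < moderate < severe; `NA` with a warning for
#'   points no zone covers).
#' @export
classify_points <- function(deltas, zones) {
  if (!inherits(zones, "zone_set")) stop("`zones` must be a `zone_set`",
                                         call. = FALSE)
  if (!is.data.frame(deltas) ||
      !all(c("delta_ref", "delta_dev") %in% names(deltas))) {
    stop("`deltas` must contain delta_ref and delta_dev", call. = FALSE)
  }
  dom <- zones$domain
  x <- clamp(-deltas$delta_ref, dom[1L], dom[2L])
  y <- clamp(-deltas$delta_dev, dom[1L], dom[2L])
  order_hi <- rev(harm_levels())
  lab <- rep(NA_character_, length(x))
  for (k in seq_along(x)) {
    for (z in order_hi) {
      hit <- FALSE
      for (p in zones$zones[[z]]) {
        if (point_in_polygon(x[k], y[k], p)) { hit <- TRUE; break }
      }
      if (hit) { lab[k] <- z; break }
    }
  }
  if (anyNA(lab)) {
    warning(sum(is.na(lab)), " point(s) not covered by any zone", call. = FALSE)
  }
  out <- deltas
  out$reduction_ref <- x
  out$reduction_dev <- y
  out$zone <- factor(lab, levels = harm_levels())
  out
}

# Band lookup by cell membership; used as the independent cross-check of the
# polygon classification for points strictly inside cells.
band_for_point <- function(zones, x, y) {
  if (!identical(zones$provenance, "derived_from_grid")) {
    stop("band lookup requires zones derived from a grid", call. = FALSE)
  }
  e <- zones$edges
  g <- length(zones$grid_steps)
  i <- clamp(findInterval(x, e), 1L, g)
  j <- clamp(findInterval(y, e), 1L, g)
  harm_levels()[zones$bands[cbind(i, j)]]
}

#' Summarise zone membership
#'
#' Counts and integer-rounded percentages of points per risk zone; when a
#' second classified set is supplied (the other study strand), the combined
#' severe-harm rate over both is reported to one decimal place.
#'
#' @param classified Data frame with a `zone` column, as returned by
#'   \code{\link{classify_points}}.
#' @param pooled Optional second classified data frame to pool with.
#' @return An object of class `zone_summary`: `counts`, `percentages`,
#'   `n_points`, and (when pooled) `combined_severe_pct` and `n_pooled`.
#' @export
zone_summary <- function(classified, pooled = NULL) {
  if (!is.data.frame(classified) || is.null(classified$zone) ||
      !nrow(classified)) {
    stop("`classified` must be a non-empty data frame with a `zone` column",
         call. = FALSE)
  }
  counts <- table(factor(classified$zone, harm_levels()))
  n <- nrow(classified)
  out <- list(counts = stats::setNames(as.integer(counts), harm_levels()),
              percentages = stats::setNames(
                as.integer(round(100 * as.integer(counts) / n)),
                harm_levels()),
              n_points = n)
  if (!is.null(pooled)) {
    if (!is.data.frame(pooled) || is.null(pooled$zone) || !nrow(pooled)) {
      stop("`pooled` must be a non-empty data frame with a `zone` column",
           call. = FALSE)
    }
    c2 <- table(factor(pooled$zone, harm_levels()))
    n2 <- nrow(pooled)
    out$combined_severe_pct <- round(
      100 * (out$counts[["severe"]] + as.integer(c2[["severe"]])) / (n + n2), 1)
    out$n_pooled <- n + n2
  }
  structure(out, class = "zone_summary")
}

#' @export
print.zone_summary <- function(x, ...) {
  cat("Risk-zone summary (", x$n_points, " points)\n", sep = "")
  for (z in harm_levels()) {
    cat(sprintf("  %-8s %4d (%d%%)\n", z, x$counts[[z]], x$percentages[[z]]))
  }
  if (!is.null(x$combined_severe_pct)) {
    cat(sprintf("  combined severe over %d points: %.1f%%\n",
                x$n_pooled, x$combined_severe_pct))
  }
  invisible(x)
}
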