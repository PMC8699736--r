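test_that("harm grid aggregation sums weighted ratings per cell", {
  q <- simulate_questionnaire(15, profiles = consensus_panel(15), seed = 5)
  g <- build_harm_grid(q)
  expect_equal(g$max_score, 150)
  # the essential-fall-read-as-no-action corner is unanimously severe
  expect_equal(g$raw["50", "0"], 150)
  expect_equal(g$pct["50", "0"], 100)
  expect_true(all(diag(g$raw) == 0))
  expect_true(all(g$raw >= 0 & g$raw <= 150))

  # 5 None + 5 Mild + 5 Severe -> 0 + 10 + 50 = 60 raw, 40%
  ratings <- rep(c("none", "mild", "severe"), each = 5)
  ret <- do.call(rbind, lapply(1:15, function(i) {
    cells <- expand.grid(measured_reduction_pct = c(0, 30),
                         actual_reduction_pct = c(0, 30))
    cells$respondent_id <- sprintf("R%02d", i)
    cells$rating <- ifelse(
      cells$actual_reduction_pct == 30 & cells$measured_reduction_pct == 0,
      ratings[i], "none")
    cells
  }))
  g2 <- build_harm_grid(ret)
  expect_equal(g2$raw["30", "0"], 60)
  expect_equal(g2$pct["30", "0"], 40)
})

test_that("grids with missing or mismatched cells are rejected", {
  q <- simulate_questionnaire(3, seed = 2)
  expect_error(build_harm_grid(q[-1, ]), "exactly")
  q2 <- q
  q2$actual_reduction_pct[1] <- 65
  expect_error(build_harm_grid(q2), "differ|exactly")
})

test_that("upgrading one rating never lowers a cell score", {
  q <- simulate_questionnaire(6, seed = 10)
  g <- build_harm_grid(q)
  idx <- which(q$rating == "mild")[1]
  q$rating[idx] <- "severe"
  g2 <- build_harm_grid(q)
  expect_true(all(g2$raw >= g$raw))
})

test_that("zone derivation bands cells by threshold", {
  pct <- matrix(c(0, 50, 15, 90), 2, 2,
                dimnames = list(actual = c(0, 30), measured = c(0, 30)))
  g <- grid_from_pct(c(0, 30), pct)
  z <- derive_zones(g, c(10, 35, 75))
  expect_equal(svagree:::harm_levels()[z$bands],
               c("none", "moderate", "mild", "severe"))
  expect_length(z$zones$none, 1)
  expect_length(z$zones$severe, 1)
  expect_identical(z$provenance, "derived_from_grid")
  # an all-zero grid is a single none zone
  g0 <- grid_from_pct(c(0, 30), pct * 0)
  z0 <- derive_zones(g0)
  expect_length(z0$zones$mild, 0)
  expect_length(z0$zones$severe, 0)
  expect_true(length(z0$zones$none) >= 1)
  expect_error(derive_zones(g, c(35, 10, 75)), "increasing")
})

test_that("the grid is not symmetrised: over- and under-reading differ", {
  q <- simulate_questionnaire(15, profiles = consensus_panel(15), seed = 5)
  g <- build_harm_grid(q)
  # under-reading an essential fall (50 read as 30) is moderate for all,
  # over-reading (30 read as 50) is mild for all
  expect_equal(g$raw["50", "30"], 15 * 5)
  expect_equal(g$raw["30", "50"], 15 * 2)
  expect_false(isTRUE(all.equal(g$raw, t(g$raw))))
})

test_that("consensus-panel zones reproduce the category-mismatch bands", {
  q <- simulate_questionnaire(15, profiles = consensus_panel(15), seed = 5)
  z <- derive_zones(build_harm_grid(q))
  steps <- z$grid_steps
  for (i in seq_along(steps)) {
    for (j in seq_along(steps)) {
      expected <- as.character(harm_rating(steps[i], steps[j], 20, 40))
      expect_identical(svagree:::harm_levels()[z$bands[i, j]], expected)
    }
  }
})

test_that("identity points classify as none; boundaries go to higher harm", {
  q <- simulate_questionnaire(15, profiles = consensus_panel(15), seed = 5)
  z <- derive_zones(build_harm_grid(q))
  diag_pts <- data.frame(delta_ref = c(0, -20, -40, -60),
                         delta_dev = c(0, -20, -40, -60))
  expect_true(all(classify_points(diag_pts, z)$zone == "none"))

  # (actual 20, measured 0) cells: for the consensus panel actual >= 20 is
  # action-indicated, so the cell at (20, 0) is mild; the cell edge at
  # x = 15 is shared with the none zone and must classify as mild
  pt_edge <- data.frame(delta_ref = -15, delta_dev = -10)
  expect_equal(as.character(classify_points(pt_edge, z)$zone), "mild")

  # out-of-domain points are clamped to the domain edge, not dropped
  far <- data.frame(delta_ref = c(-120, 30), delta_dev = c(-130, 40))
  cf <- classify_points(far, z)
  expect_equal(cf$reduction_ref, c(60, 0))
  expect_false(anyNA(cf$zone))
})

test_that("polygon classification equals cell-band lookup for interior points", {
  set.seed(77)
  steps <- seq(0, 60, by = 10)
  for (rep in 1:10) {
    pct <- matrix(sample(0:150, 49, replace = TRUE) / 1.5, 7, 7,
                  dimnames = list(actual = steps, measured = steps))
    z <- derive_zones(grid_from_pct(steps, pct))
    e <- z$edges
    i <- sample(7, 200, replace = TRUE)
    j <- sample(7, 200, replace = TRUE)
    margin <- 0.1
    x <- runif(200, e[i] + margin, e[i + 1] - margin)
    y <- runif(200, e[j] + margin, e[j + 1] - margin)
    got <- classify_points(data.frame(delta_ref = -x, delta_dev = -y), z)$zone
    want <- svagree:::band_for_point(z, x, y)
    expect_identical(as.character(got), want)
  }
})

test_that("zone summaries report counts, rounded percentages and pooling", {
  mk <- function(counts) {
    data.frame(zone = factor(rep(svagree:::harm_levels(), counts),
                             svagree:::harm_levels()))
  }
  zs <- zone_summary(mk(c(75, 18, 22, 6)))
  expect_equal(unname(zs$counts), c(75, 18, 22, 6))
  expect_equal(unname(zs$percentages), c(62, 15, 18, 5))
  expect_equal(zs$n_points, 121)

  pooled <- zone_summary(mk(c(75, 18, 22, 6)), mk(c(80, 17, 16, 0)))
  expect_equal(pooled$combined_severe_pct, 2.6)
  expect_equal(pooled$n_pooled, 234)

  one <- zone_summary(mk(c(0, 0, 9, 0)))
  expect_equal(unname(one$percentages), c(0, 0, 100, 0))

  # invariance to point order; pooling is symmetric in the severe rate
  shuffled <- mk(c(75, 18, 22, 6))
  shuffled <- shuffled[sample(nrow(shuffled)), , drop = FALSE]
  expect_equal(zone_summary(shuffled)$counts, zs$counts)
  swapped <- zone_summary(mk(c(80, 17, 16, 0)), mk(c(75, 18, 22, 6)))
  expect_equal(swapped$combined_severe_pct, pooled$combined_severe_pct)
  expect_error(zone_summary(mk(c(0, 0, 0, 0))[0, , drop = FALSE]), "non-empty")
})

test_that("zone sets round-trip through JSON and keep provenance", {
  q <- simulate_questionnaire(10, seed = 3, rating_noise = 0.1)
  z <- derive_zones(build_harm_grid(q))
  path <- tempfile(fileext = ".json")
  on.exit(unlink(path), add = TRUE)
  write_zones_json(z, path)
  z2 <- read_zones_json(path)
  expect_identical(z2$provenance, "loaded_from_file")
  expect_equal(z2$domain, z$domain)
  # classification is preserved for random interior-ish points
  set.seed(4)
  pts <- data.frame(delta_ref = -runif(100, 0.2, 59.8),
                    delta_dev = -runif(100, 0.2, 59.8))
  expect_equal(as.character(classify_points(pts, z2)$zone),
               as.character(classify_points(pts, z)$zone))
})
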