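# Shared fixtures built in code.

# A panel of identical experts: everyone treats a 20% fall as action
# indicated and a 40% fall as action essential, with no rating jitter.
consensus_panel <- function(n = 15, indicated = 20, essential = 40) {
  data.frame(respondent_id = sprintf("R%02d", seq_len(n)),
             threshold_action_indicated = indicated,
             threshold_action_essential = essential,
             rating_noise = 0,
             stringsAsFactors = FALSE)
}

# Four-row, two-subject toy cohort with hand-computable statistics:
# differences (0, -10, 0, +9); deltas A (-20, -30), B (-40, -30).
toy_cohort <- function() {
  data.frame(subject_id = c("A", "A", "B", "B"),
             strand = "no_tourniquet",
             step_index = c(1L, 2L, 1L, 2L),
             step_label = c("baseline", "LBNP1", "baseline", "LBNP1"),
             sv_ref = c(100, 80, 90, 54),
             sv_probe = c(100, 70, 90, 63),
             stringsAsFactors = FALSE)
}

# Brute-force double-loop reimplementation of the four-quadrant rules,
# independent of the vectorised implementation.
four_quadrant_oracle <- function(dr, dd, th) {
  n_exc <- 0L; n_zero <- 0L; n_conc <- 0L
  for (i in seq_along(dr)) {
    if (abs(dr[i]) < th && abs(dd[i]) < th) {
      n_exc <- n_exc + 1L
    } else if (dr[i] == 0 || dd[i] == 0) {
      n_zero <- n_zero + 1L
    } else if (sign(dr[i]) == sign(dd[i])) {
      n_conc <- n_conc + 1L
    }
  }
  list(n_excluded = n_exc, n_zero = n_zero, n_concordant = n_conc)
}

# A harm grid with prescribed percentage scores (for zone-derivation tests).
grid_from_pct <- function(steps, pct) {
  raw <- pct * 1.5   # 15 respondents, severe weight 10 -> max 150
  structure(list(grid_steps = steps,
                 raw = raw,
                 pct = pct,
                 n_respondents = 15L,
                 max_score = 150,
                 weights = harm_weights()),
            class = "harm_grid")
}
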