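# Independent brute-force oracles and shared fixtures. The oracles are kept
# deliberately naive (literal double loops over the rule text) so they share
# no code path with the package implementations they check.

# literal scan of the plateau rule: first j (never the last point) whose value
# reaches frac of the plain average of the strictly more distal values
bf_plateau <- function(positions, values, frac = 0.95) {
  n <- length(values)
  for (j in seq_len(n - 1)) {
    rest <- values[(j + 1):n]
    avg <- sum(rest) / length(rest)
    if (values[j] >= frac * avg) return(positions[j])
  }
  NA_real_ # the rule never fired
}

# literal scan of the cell-length doubling rule
bf_elongation_onset <- function(lengths) {
  n <- length(lengths)
  if (n < 3) return(NA_integer_)
  for (i in 2:(n - 1)) {
    if (lengths[i] >= 2 * lengths[i - 1] && lengths[i + 1] > lengths[i]) {
      return(i)
    }
  }
  NA_integer_
}

# literal scan of the maturation rule with the five-remaining-cells guard
bf_maturation_onset <- function(lengths, onset, tol = 0.05) {
  n <- length(lengths)
  i <- as.integer(onset) + 1L
  while (i <= n - 4L) {
    if (lengths[i + 1L] <= (1 + tol) * lengths[i]) return(i)
    i <- i + 1L
  }
  NA_integer_
}

# the reference growth zone used throughout: 50 meristem cells of 10 um,
# P = 2 cells/h, V = 300 um/h, mature length 150 um, growth zone 900 um
ref_spec <- function(bump = "raised_cosine") {
  growth_zone_spec(
    meristem_length = 500, initial_cell_length = 10,
    meristem_strain_rate = 0.04, elongation_zone_length = 400,
    elongation_strain_integral = 280, bump_shape = bump
  )
}

# the matched slow-producing cohort: P = 1.5 cells/h, mature length 180 um,
# same cell-cycle duration (37.5 meristem cells)
mutant_spec <- function() {
  growth_zone_spec(
    meristem_length = 375, initial_cell_length = 10,
    meristem_strain_rate = 0.04, elongation_zone_length = 400,
    elongation_strain_integral = 255, bump_shape = "raised_cosine"
  )
}

# hand-built profile with a genuine sharp meristem/elongation transition, the
# regime the doubling rule was designed for: 50 cells of 10 um, a doubling
# step, a short elongation ramp, then mature cells of exactly 150 um
sharp_profile <- function(n_meristem = 50, l0 = 10, mature = 150) {
  c(rep(l0, n_meristem), 2.1 * l0, 4.5 * l0, 9.5 * l0, 14 * l0,
    rep(mature, 8))
}

# a bare velocity_profile object from known grid values, for closed-form
# checks of the profile-consuming operations
fake_profile <- function(x, v) {
  structure(
    list(
      data = tibble::tibble(x_um = x, v_um_per_h = v, v_fit_um_per_h = v),
      points = tibble::tibble(mid_um = numeric(0), v_um_per_h = numeric(0)),
      bandwidth = NA_real_, grid_step = unique(diff(x))[1], monotonized = FALSE,
      support = c(min(x), max(x))
    ),
    class = "velocity_profile"
  )
}

# random length sequences exercising both detector outcomes: flat and noisy
# profiles (usually no onset) and ramped profiles with an inserted doubling
random_length_sequence <- function(n = NULL) {
  if (is.null(n)) n <- sample(8:40, 1)
  kind <- sample(3, 1)
  if (kind == 1) {
    stats::runif(n, 5, 60)
  } else if (kind == 2) {
    stats::runif(n, 9, 11)
  } else {
    base <- c(rep(10, max(3, n %/% 3)),
              10 * cumprod(stats::runif(n %/% 3 + 2, 1.4, 2.3)))
    out <- c(base, rep(max(base) * stats::runif(1, 1, 1.04),
                       n - length(base)))
    pmax(out[seq_len(n)], 1)
  }
}
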