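# Kinematic analysis: boundary rules on velocity/flux profiles and the
# derived scalar quantities (cell production, cell-cycle duration, REGR
# profile, elongation-zone transit time).

#' Cell flux from velocity and cell length
#'
#' Flux (cells per hour past a position) is the velocity divided by the cell
#' length at the same position. In a steady-state root it is constant beyond
#' the meristem and equal to the cell production rate.
#'
#' @param v Velocity, um/h.
#' @param l Cell length, um (same length as `v`, all > 0).
#' @return Flux in 1/h, elementwise.
#' @export
compute_flux <- function(v, l) {
  if (length(v) != length(l)) {
    stop_rootkin("`v` and `l` must have the same length", "rootkin_error_parameter")
  }
  if (any(!is.na(l) & l <= 0)) {
    stop_rootkin("cell length must be > 0 wherever flux is evaluated",
                 "rootkin_error_domain")
  }
  v / l
}

#' Locate a plateau by the 95% rule
#'
#' Scans shootward for the first point whose value reaches at least
#' `plateau_frac` (default 95%) of the average of the remaining, more distal
#' points. The candidate itself is excluded from the "remaining" average by
#' default. The last point is never a valid answer: if no interior point
#' qualifies the series has not plateaued and an error is raised.
#'
#' @param positions Ascending positions, um.
#' @param values Series evaluated at `positions` (velocity or flux).
#' @param plateau_frac Plateau threshold fraction (default 0.95).
#' @param include_candidate Include the candidate point in the remaining
#'   average (default `FALSE`).
#' @return The boundary position (um).
#' @export
plateau_boundary <- function(positions, values, plateau_frac = 0.95,
                             include_candidate = FALSE) {
  n <- length(values)
  if (length(positions) != n) {
    stop_rootkin("`positions` and `values` must have the same length",
                 "rootkin_error_parameter")
  }
  if (n < 3L) {
    stop_rootkin("at least 3 points are required", "rootkin_error_insufficient_data")
  }
  if (is.unsorted(positions, strictly = TRUE)) {
    stop_rootkin("`positions` must be strictly increasing", "rootkin_error_parameter")
  }
  for (j in 1:(n - 1L)) {
    rest <- if (include_candidate) values[j:n] else values[(j + 1L):n]
    if (values[j] >= plateau_frac * mean(rest)) {
      return(positions[j])
    }
  }
  stop_rootkin(
    sprintf("series never reaches %g%% of the remaining mean: no plateau found",
            100 * plateau_frac),
    "rootkin_error_boundary"
  )
}

# scan window for the plateau rules: the occupied grid (within one bandwidth
# of the data), restricted to everything below 99% of the maximum velocity
# plus one plateau point (so the "remaining" mean always contains plateau
# values). Returns indices into the profile grid.
plateau_scan_region <- function(profile) {
  grid <- profile$data$x_um
  v <- profile$data$v_um_per_h
  occ <- which(grid >= profile$support[1] & grid <= profile$support[2])
  vo <- v[occ]
  below <- which(vo < 0.99 * max(vo))
  if (length(below) == 0) return(occ)
  occ[seq_len(min(max(below) + 1L, length(occ)))]
}

#' Growth-zone boundary and final velocity
#'
#' The growth zone ends at the first grid point where the smoothed velocity
#' reaches 95% of the average of the remaining velocity values in the scan
#' window (the region below 99% of the maximum velocity, plus one plateau
#' point). The final (plateau) velocity is the mean of the smoothed velocity
#' at and beyond that boundary.
#'
#' @param profile A [estimate_velocity_profile()] fit.
#' @param plateau_frac Plateau threshold fraction.
#' @return A list with `growth_zone_length_um` and `final_velocity_um_per_h`.
#' @export
growth_zone_boundary <- function(profile, plateau_frac = 0.95) {
  stopifnot(inherits(profile, "velocity_profile"))
  grid <- profile$data$x_um
  v <- profile$data$v_um_per_h
  region <- plateau_scan_region(profile)
  lg <- plateau_boundary(grid[region], v[region], plateau_frac)
  list(
    growth_zone_length_um = lg,
    final_velocity_um_per_h = mean(v[grid >= lg & grid <= profile$support[2]])
  )
}

#' Meristem boundary from the flux plateau
#'
#' Flux is the smoothed velocity divided by the cell-length field
#' interpolated from a paired cortical cell file ([cell_length_on_grid()]);
#' the meristem ends at the first grid point where the flux reaches 95% of
#' the average of the remaining flux values in the scan window. Grid points
#' without cell-length coverage are excluded.
#'
#' @inheritParams growth_zone_boundary
#' @param cell_lengths Cell length (um) at each grid position of the profile;
#'   `NA` outside coverage.
#' @return The meristem length estimate (um).
#' @export
meristem_boundary <- function(profile, cell_lengths, plateau_frac = 0.95) {
  stopifnot(inherits(profile, "velocity_profile"))
  grid <- profile$data$x_um
  v <- profile$data$v_um_per_h
  if (length(cell_lengths) != length(grid)) {
    stop_rootkin("`cell_lengths` must align with the profile grid",
                 "rootkin_error_parameter")
  }
  region <- plateau_scan_region(profile)
  # degenerate root: every observed velocity is already at the plateau, so
  # the meristem (where the flux rises) is not in view at all
  if (all(v[region] >= 0.99 * max(v[region]))) {
    stop_rootkin("velocity shows no rise within the observed region: meristem not in view",
                 "rootkin_error_boundary")
  }
  ok <- region[!is.na(cell_lengths[region])]
  if (length(ok) < 3L) {
    stop_rootkin("fewer than 3 grid points with cell-length coverage in the scan window",
                 "rootkin_error_insufficient_data")
  }
  flux <- compute_flux(v[ok], cell_lengths[ok])
  plateau_boundary(grid[ok], flux, plateau_frac)
}

#' Cell production rate
#'
#' Final velocity divided by mature cell length: the number of cells a file
#' delivers to the mature zone per hour, which under steady state equals the
#' meristem's cell production.
#'
#' @param final_velocity um/h.
#' @param mature_length um (> 0).
#' @return Cells per hour.
#' @export
cell_production_rate <- function(final_velocity, mature_length) {
  if (!is.numeric(mature_length) || is.na(mature_length) || mature_length <= 0) {
    stop_rootkin("`mature_length` must be > 0", "rootkin_error_domain")
  }
  final_velocity / mature_length
}

#' Average cell-cycle duration
#'
#' Under steady exponential proliferation of `n_meristem` cells producing
#' `production` cells per hour, the average cycle takes
#' `ln(2) * n_meristem / production` hours. The formula comes from the
#' standard kinematic framework for growth-zone analysis.
#'
#' @param n_meristem Number of meristematic cells in the file (>= 1).
#' @param production Cell production, cells/h (> 0).
#' @return Hours.
#' @export
cell_cycle_duration <- function(n_meristem, production) {
  if (!is.numeric(production) || is.na(production) || production <= 0) {
    stop_rootkin("`production` must be > 0", "rootkin_error_domain")
  }
  if (!is.numeric(n_meristem) || is.na(n_meristem) || n_meristem < 1) {
    stop_rootkin("`n_meristem` must be >= 1", "rootkin_error_domain")
  }
  log(2) * n_meristem / production
}

#' REGR (strain-rate) profile of a velocity fit
#'
#' The derivative of the smoothed velocity with respect to position, by
#' central differences on the uniform grid (one-sided at the ends), clamped
#' at zero.
#'
#' @inheritParams growth_zone_boundary
#' @return A tibble with `x_um` and `regr_per_h`.
#' @export
strain_rate_profile <- function(profile) {
  stopifnot(inherits(profile, "velocity_profile"))
  grid <- profile$data$x_um
  v <- profile$data$v_um_per_h
  n <- length(grid)
  if (n < 3L) {
    stop_rootkin("grid must have at least 3 points", "rootkin_error_insufficient_data")
  }
  r <- numeric(n)
  r[1] <- (v[2] - v[1]) / (grid[2] - grid[1])
  r[n] <- (v[n] - v[n - 1]) / (grid[n] - grid[n - 1])
  r[2:(n - 1)] <- (v[3:n] - v[1:(n - 2)]) / (grid[3:n] - grid[1:(n - 2)])
  tibble::tibble(x_um = grid, regr_per_h = pmax(r, 0))
}

#' Elongation-zone transit time
#'
#' The average time a cell spends traversing the elongation zone: the
#' integral of `1/v(x)` from the meristem boundary to the growth-zone
#' boundary. The smoothed profile is piecewise linear on its grid, so the
#' integral is evaluated in closed form segment by segment
#' (`dx/(v1-v0) * log(v1/v0)` per linear segment), which is exact rather
#' than merely within a quadrature tolerance.
#'
#' @inheritParams growth_zone_boundary
#' @param meristem_length_um,growth_zone_length_um Integration limits, um.
#' @return Hours.
#' @export
elongation_transit_time <- function(profile, meristem_length_um,
                                    growth_zone_length_um) {
  stopifnot(inherits(profile, "velocity_profile"))
  if (!is.finite(meristem_length_um) || !is.finite(growth_zone_length_um) ||
      meristem_length_um >= growth_zone_length_um) {
    stop_rootkin("need meristem boundary < growth-zone boundary",
                 "rootkin_error_domain")
  }
  grid <- profile$data$x_um
  v <- profile$data$v_um_per_h
  vf <- stats::approxfun(grid, v, rule = 2)
  inner <- grid[grid > meristem_length_um & grid < growth_zone_length_um]
  xs <- c(meristem_length_um, inner, growth_zone_length_um)
  vs <- vf(xs)
  if (any(vs <= 0)) {
    stop_rootkin("velocity must be positive throughout the elongation zone",
                 "rootkin_error_domain")
  }
  dx <- diff(xs)
  v0 <- head(vs, -1)
  v1 <- tail(vs, -1)
  seg <- ifelse(abs(v1 - v0) < 1e-12 * pmax(v0, v1),
                dx / v0,
                dx * log(v1 / v0) / (v1 - v0))
  sum(seg)
}
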