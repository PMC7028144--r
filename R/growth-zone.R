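#' Specify a steady-state root growth zone
#'
#' A growth zone is described in the frame of the quiescent centre (QC), with
#' positions `x` in micrometres increasing shootward. Cells proliferate in the
#' meristem (`0 <= x <= meristem_length`), where the relative elemental growth
#' rate (REGR, or strain rate) is a constant `meristem_strain_rate` and cell
#' length is held at `initial_cell_length` by ongoing division. Beyond the
#' meristem, cells stop dividing and pass through a rapid-elongation zone of
#' length `elongation_zone_length` whose strain-rate "bump" integrates to
#' `elongation_strain_integral` (um/h). Past the growth zone the tissue moves
#' at the constant final velocity `V = r_m * Lm + A_e` and cells are at their
#' mature length.
#'
#' Derived steady-state quantities (see [glance.growth_zone_spec()]):
#' cell production `P = r_m * Lm / l0` (cells/h per file), mature cell length
#' `V / P`, meristem cell number `N = Lm / l0`, cell-cycle duration
#' `Tc = ln(2) * N / P` (exponential doubling), and the elongation-zone
#' transit time `integral of 1/v(x)` across the elongation zone.
#'
#' @param meristem_length Meristem length `Lm` in um (> 0).
#' @param initial_cell_length Meristematic cell length `l0` in um (> 0).
#' @param meristem_strain_rate Meristem strain rate `r_m` in 1/h (> 0).
#' @param elongation_zone_length Elongation-zone length `Le` in um (> 0).
#' @param elongation_strain_integral Integral `A_e` (um/h, >= 0) of the
#'   elongation-zone strain-rate bump; equals the velocity gained across the
#'   elongation zone.
#' @param bump_shape Shape of the elongation-zone strain-rate bump:
#'   `"raised_cosine"` (smooth, unimodal; the default) or `"rectangular"`
#'   (constant; convenient for closed-form checks).
#' @param domain_extent Extent `X_max` of the simulated domain in um. Must
#'   exceed the growth-zone length `Lg = Lm + Le`; the default leaves room for
#'   six mature cells beyond the growth zone.
#'
#' @return An object of class `growth_zone_spec`.
#' @examples
#' spec <- growth_zone_spec(500, 10, 0.04, 400, 280, "rectangular")
#' glance(spec)
#' @export
growth_zone_spec <- function(meristem_length,
                             initial_cell_length,
                             meristem_strain_rate,
                             elongation_zone_length,
                             elongation_strain_integral,
                             bump_shape = c("raised_cosine", "rectangular"),
                             domain_extent = NULL) {
  bump_shape <- match.arg(bump_shape)
  check_scalar <- function(x, name) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
      stop_rootkin(paste0("`", name, "` must be a finite numeric scalar"),
                   "rootkin_error_spec")
    }
  }
  for (nm in c("meristem_length", "initial_cell_length", "meristem_strain_rate",
               "elongation_zone_length", "elongation_strain_integral")) {
    check_scalar(get(nm), nm)
  }
  if (meristem_length <= 0) {
    stop_rootkin("invalid spec: meristem_length Lm must be > 0", "rootkin_error_spec")
  }
  if (initial_cell_length <= 0) {
    stop_rootkin("invalid spec: initial_cell_length l0 must be > 0", "rootkin_error_spec")
  }
  if (meristem_strain_rate <= 0) {
    stop_rootkin("invalid spec: meristem_strain_rate r_m must be > 0", "rootkin_error_spec")
  }
  if (elongation_zone_length <= 0) {
    stop_rootkin("invalid spec: elongation_zone_length Le must be > 0", "rootkin_error_spec")
  }
  if (elongation_strain_integral < 0) {
    stop_rootkin("invalid spec: elongation_strain_integral A_e must be >= 0", "rootkin_error_spec")
  }

  growth_zone_length <- meristem_length + elongation_zone_length
  final_velocity <- meristem_strain_rate * meristem_length + elongation_strain_integral
  cell_production <- meristem_strain_rate * meristem_length / initial_cell_length
  mature_cell_length <- final_velocity / cell_production

  if (is.null(domain_extent)) {
    domain_extent <- growth_zone_length + 6 * mature_cell_length
  }
  check_scalar(domain_extent, "domain_extent")
  if (domain_extent <= growth_zone_length) {
    stop_rootkin("invalid spec: domain_extent X_max must exceed Lg = Lm + Le",
                 "rootkin_error_spec")
  }

  structure(
    list(
      meristem_length = meristem_length,
      initial_cell_length = initial_cell_length,
      meristem_strain_rate = meristem_strain_rate,
      elongation_zone_length = elongation_zone_length,
      elongation_strain_integral = elongation_strain_integral,
      bump_shape = bump_shape,
      domain_extent = domain_extent,
      growth_zone_length = growth_zone_length,
      final_velocity = final_velocity,
      cell_production = cell_production,
      mature_cell_length = mature_cell_length
    ),
    class = "growth_zone_spec"
  )
}

#' @export
print.growth_zone_spec <- function(x, ...) {
  cat("<growth_zone_spec>\n")
  cat(sprintf("  meristem:    Lm = %g um, l0 = %g um, r_m = %g /h\n",
              x$meristem_length, x$initial_cell_length, x$meristem_strain_rate))
  cat(sprintf("  elongation:  Le = %g um, A_e = %g um/h (%s bump)\n",
              x$elongation_zone_length, x$elongation_strain_integral, x$bump_shape))
  cat(sprintf("  derived:     V = %g um/h, P = %g cells/h, mature length = %g um\n",
              x$final_velocity, x$cell_production, x$mature_cell_length))
  cat(sprintf("  domain:      [0, %g] um (growth zone ends at %g um)\n",
              x$domain_extent, x$growth_zone_length))
  invisible(x)
}

#' Ground-truth summary of a growth-zone specification
#'
#' One-row tibble of the steady-state quantities implied by the spec: the
#' values a kinematic analysis of perfect data should recover.
#'
#' @param x A [growth_zone_spec()].
#' @param ... Unused.
#' @return A one-row tibble with the zone lengths, final velocity, cell
#'   production, mature cell length, meristem cell number, cell-cycle duration
#'   and elongation-zone transit time.
#' @export
glance.growth_zone_spec <- function(x, ...) {
  n_meristem <- x$meristem_length / x$initial_cell_length
  tibble::tibble(
    meristem_length_um = x$meristem_length,
    growth_zone_length_um = x$growth_zone_length,
    final_velocity_um_per_h = x$final_velocity,
    cell_production_cells_per_h = x$cell_production,
    mature_cell_length_um = x$mature_cell_length,
    meristem_cell_count = n_meristem,
    cell_cycle_h = log(2) * n_meristem / x$cell_production,
    transit_h = transit_time_true(x)
  )
}

# field accessors ---------------------------------------------------------

#' Velocity and strain-rate fields of a growth-zone specification
#'
#' `velocity_field()` returns the closed-form steady-state velocity `v(x)`
#' (um/h); `strain_rate_field()` its derivative, the REGR field `r(x)` (1/h);
#' `cell_length_field()` the steady-state cortical cell length `l(x)` (um);
#' and `flux_field()` the cell flux `F(x) = v(x)/l(x)` (cells/h). Each takes a
#' spec and returns a vectorised function of position (um from the QC).
#' Positions are clamped to `[0, X_max]`.
#'
#' @param spec A [growth_zone_spec()].
#' @return A function of position `x` (um).
#' @examples
#' v <- velocity_field(growth_zone_spec(500, 10, 0.04, 400, 280, "rectangular"))
#' v(c(500, 700, 900)) # 20, 160, 300 um/h
#' @export
velocity_field <- function(spec) {
  stopifnot(inherits(spec, "growth_zone_spec"))
  Lm <- spec$meristem_length
  Le <- spec$elongation_zone_length
  Ae <- spec$elongation_strain_integral
  rm_ <- spec$meristem_strain_rate
  rect <- spec$bump_shape == "rectangular"
  function(x) {
    x <- pmin(pmax(x, 0), spec$domain_extent)
    u <- pmin(pmax(x - Lm, 0), Le)
    base <- rm_ * pmin(x, Lm)
    bump <- if (rect) {
      (Ae / Le) * u
    } else {
      (Ae / Le) * (u - (Le / (2 * pi)) * sin(2 * pi * u / Le))
    }
    base + bump
  }
}

#' @rdname velocity_field
#' @export
strain_rate_field <- function(spec) {
  stopifnot(inherits(spec, "growth_zone_spec"))
  Lm <- spec$meristem_length
  Lg <- spec$growth_zone_length
  Le <- spec$elongation_zone_length
  Ae <- spec$elongation_strain_integral
  rect <- spec$bump_shape == "rectangular"
  function(x) {
    out <- numeric(length(x))
    mer <- x >= 0 & x <= Lm
    elo <- x > Lm & x <= Lg
    out[mer] <- spec$meristem_strain_rate
    u <- x[elo] - Lm
    out[elo] <- if (rect) Ae / Le else (Ae / Le) * (1 - cos(2 * pi * u / Le))
    out
  }
}

#' @rdname velocity_field
#' @export
cell_length_field <- function(spec) {
  stopifnot(inherits(spec, "growth_zone_spec"))
  v <- velocity_field(spec)
  function(x) {
    ifelse(x <= spec$meristem_length,
           spec$initial_cell_length,
           ifelse(x < spec$growth_zone_length,
                  v(x) / spec$cell_production,
                  spec$mature_cell_length))
  }
}

#' @rdname velocity_field
#' @export
flux_field <- function(spec) {
  v <- velocity_field(spec)
  l <- cell_length_field(spec)
  function(x) v(x) / l(x)
}

# ground-truth elongation-zone transit time (integral of 1/v over [Lm, Lg]);
# closed form for the rectangular bump, adaptive quadrature otherwise
transit_time_true <- function(spec) {
  v0 <- spec$meristem_strain_rate * spec$meristem_length
  if (spec$elongation_strain_integral == 0) {
    return(spec$elongation_zone_length / v0)
  }
  if (spec$bump_shape == "rectangular") {
    slope <- spec$elongation_strain_integral / spec$elongation_zone_length
    return(log(spec$final_velocity / v0) / slope)
  }
  v <- velocity_field(spec)
  stats::integrate(function(x) 1 / v(x),
                   spec$meristem_length, spec$growth_zone_length,
                   rel.tol = 1e-10, subdivisions = 1000L)$value
}
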