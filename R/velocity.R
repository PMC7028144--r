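#' Estimate the tissue velocity profile from particle displacements
#'
#' Raw velocity points are formed as displacement over elapsed time, placed at
#' the displacement midpoint. The profile is then smoothed by local quadratic
#' kernel regression (Gaussian kernel scaled so `+/- bandwidth` holds about
#' 95% of the kernel mass) on
#' a uniform grid from the QC, projected onto the nearest non-decreasing
#' sequence (pool-adjacent-violators, via [stats::isoreg()]) and clamped at
#' zero: tissue in a steady-state growth zone can only speed up shootward.
#'
#' The raw value `(x_end - x_start)/dt` is the particle's *secant* velocity:
#' because `dt = integral of dx/v` along the path, it equals the harmonic
#' spatial mean of `v` over the traversed interval, not `v` at the interval
#' midpoint. Over a one-hour interval a fast particle traverses a large part
#' of the elongation zone, so the plain midpoint assignment is biased
#' wherever the velocity curves. The fit therefore iterates a secant
#' correction (`refine_iterations` times, default 2): each working value is
#' rescaled by the ratio of its observed secant velocity to the secant
#' velocity the current fit predicts over the same interval, and the fit is
#' repeated. A fit that predicts every observed secant exactly -- in
#' particular the true velocity field on noiseless data -- is a fixed point.
#'
#' @param particles A data frame with columns `x_start_um`, `x_end_um`,
#'   `dt_h` (one root's worth of records).
#' @param bandwidth Kernel standard deviation, um.
#' @param grid_step Grid spacing, um.
#' @param refine_iterations Secant-correction passes (0 keeps the plain
#'   displacement-midpoint fit).
#' @return An object of class `velocity_profile`: grid positions, smoothed
#'   monotone velocity, the raw midpoint/velocity points and fit metadata.
#'   `tidy()` returns the per-grid-point tibble.
#' @export
estimate_velocity_profile <- function(particles, bandwidth = 50, grid_step = 1,
                                      refine_iterations = 2L) {
  req <- c("x_start_um", "x_end_um", "dt_h")
  missing_cols <- setdiff(req, names(particles))
  if (length(missing_cols) > 0) {
    stop_rootkin(paste0("`particles` is missing column(s): ",
                        paste(missing_cols, collapse = ", ")),
                 "rootkin_error_schema")
  }
  if (nrow(particles) == 0) {
    stop_rootkin("no particle records", "rootkin_error_estimation")
  }
  if (!is.numeric(bandwidth) || bandwidth <= 0) {
    stop_rootkin("`bandwidth` must be > 0", "rootkin_error_parameter")
  }
  if (any(particles$dt_h <= 0)) {
    stop_rootkin("all `dt_h` must be > 0", "rootkin_error_domain")
  }
  mid <- (particles$x_start_um + particles$x_end_um) / 2
  vel <- (particles$x_end_um - particles$x_start_um) / particles$dt_h
  keep <- is.finite(mid) & is.finite(vel)
  mid <- mid[keep]
  vel <- vel[keep]
  # a quadratic fit needs at least 3 distinct abscissae; the Gaussian kernel
  # has unbounded support, so coverage is a global rather than per-window check
  if (length(unique(mid)) < 3L) {
    stop_rootkin("need at least 3 distinct particle midpoints to fit a velocity profile",
                 "rootkin_error_estimation")
  }
  grid <- seq(0, max(mid), by = grid_step)
  x0 <- pmin(particles$x_start_um, particles$x_end_um)[keep]
  x1 <- pmax(particles$x_start_um, particles$x_end_um)[keep]
  work <- vel
  for (iter in seq_len(1L + refine_iterations)) {
    raw_fit <- local_quadratic(mid, work, grid, bandwidth)
    v <- pmax(stats::isoreg(grid, raw_fit)$yf, 0)
    if (iter <= refine_iterations) {
      pred <- secant_velocity(grid, v, x0, x1)
      v_mid <- stats::approx(grid, v, xout = mid, rule = 2)$y
      ratio <- vel / pred
      usable <- is.finite(ratio) & ratio > 0 & v_mid > 0
      work <- ifelse(usable, v_mid * ratio, vel)
    }
  }
  structure(
    list(
      data = tibble::tibble(x_um = grid, v_um_per_h = v, v_fit_um_per_h = raw_fit),
      points = tibble::tibble(mid_um = mid, v_um_per_h = vel,
                              v_corrected_um_per_h = work),
      bandwidth = bandwidth,
      grid_step = grid_step,
      monotonized = TRUE,
      refine_iterations = refine_iterations,
      # the occupied grid: positions within one bandwidth of the data, the
      # only region where boundary scans are meaningful
      support = c(max(0, min(mid) - bandwidth), max(mid))
    ),
    class = "velocity_profile"
  )
}

# Local quadratic kernel regression, vectorised over the grid: for each grid
# point solve the 3x3 weighted normal equations by Cramer's rule, with the
# abscissa scaled by the bandwidth for conditioning. The intercept of the
# local fit is the estimate. The bandwidth is widened locally to the distance
# of the 3rd-nearest distinct midpoint (a nearest-neighbour floor), so the
# quadratic fit stays determined across gaps in particle coverage; weights
# are normalised per grid point to avoid underflow far from the data (the
# intercept is invariant to rescaling a grid point's weights).
local_quadratic <- function(x, y, grid, bandwidth) {
  ux <- unique(x)
  d3 <- apply(abs(outer(grid, ux, "-")), 1L,
              function(z) sort.int(z, partial = 3L)[3L])
  # kernel sd = bandwidth/2, so +/- bandwidth holds ~95% of the kernel mass
  h <- pmax(bandwidth / 2, d3)
  u <- outer(grid, x, "-") * (-1 / h) # (x_i - g) / h_g, n_grid x n
  w <- exp(-0.5 * u^2)
  w <- w / pmax(apply(w, 1L, max), .Machine$double.xmin)
  s0 <- rowSums(w)
  s1 <- rowSums(w * u)
  s2 <- rowSums(w * u^2)
  s3 <- rowSums(w * u^3)
  s4 <- rowSums(w * u^4)
  t0 <- as.vector(w %*% y)
  t1 <- as.vector((w * u) %*% y)
  t2 <- as.vector((w * u^2) %*% y)
  det <- s0 * (s2 * s4 - s3^2) - s1 * (s1 * s4 - s2 * s3) + s2 * (s1 * s3 - s2^2)
  if (any(!is.finite(det)) || any(abs(det) < 1e-10)) {
    stop_rootkin("singular local fit: too few points within the bandwidth somewhere on the grid",
                 "rootkin_error_estimation")
  }
  # Cramer: replace the first column of the moment matrix by the response moments
  num <- t0 * (s2 * s4 - s3^2) - s1 * (t1 * s4 - t2 * s3) + s2 * (t1 * s3 - t2 * s2)
  num / det
}

# model-predicted secant velocity over each traversed interval:
# (x1 - x0) / integral(dx / v) with the exact segment-wise integral of the
# piecewise-linear profile; NA where the interval is degenerate or v <= 0
secant_velocity <- function(grid, v, x0, x1) {
  vf <- stats::approxfun(grid, v, rule = 2)
  vapply(seq_along(x0), function(i) {
    width <- x1[i] - x0[i]
    if (width <= 0) return(vf(x0[i]))
    inner <- grid[grid > x0[i] & grid < x1[i]]
    xs <- c(x0[i], inner, x1[i])
    vs <- vf(xs)
    if (any(vs <= 0)) return(NA_real_)
    dx <- diff(xs)
    va <- head(vs, -1)
    vb <- tail(vs, -1)
    tt <- sum(ifelse(abs(vb - va) < 1e-12 * pmax(va, vb),
                     dx / va, dx * log(vb / va) / (vb - va)))
    width / tt
  }, numeric(1))
}

#' @export
print.velocity_profile <- function(x, ...) {
  cat("<velocity_profile>\n")
  cat(sprintf("  %d raw points, grid [0, %g] um (step %g), bandwidth %g um\n",
              nrow(x$points), max(x$data$x_um), x$grid_step, x$bandwidth))
  cat(sprintf("  plateau velocity (grid max): %.3g um/h\n", max(x$data$v_um_per_h)))
  invisible(x)
}

#' @rdname estimate_velocity_profile
#' @param x A `velocity_profile`.
#' @param ... Unused.
#' @export
tidy.velocity_profile <- function(x, ...) x$data

#' Interpolate cortical cell lengths onto a position grid
#'
#' Cell lengths are attached to the midpoints of the cells as laid end-to-end
#' from the QC (plus the QC offset) and linearly interpolated between
#' midpoints. Grid positions outside the span of the file get `NA`: flux is
#' only computable where cell-length coverage exists.
#'
#' @param cell_file A data frame for one file: columns `cell_index`,
#'   `length_um`, optionally `qc_offset_um`.
#' @param grid Positions (um) to interpolate at.
#' @param qc_offset Offset used when the table has no `qc_offset_um` column.
#' @return Numeric vector of cell lengths (um) along `grid`, `NA` outside
#'   coverage.
#' @export
cell_length_on_grid <- function(cell_file, grid, qc_offset = 0) {
  cell_file <- dplyr::arrange(cell_file, .data$cell_index)
  len <- cell_file$length_um
  if (length(len) < 2L) {
    stop_rootkin("need at least 2 cells to interpolate a cell-length field",
                 "rootkin_error_insufficient_data")
  }
  offset <- if ("qc_offset_um" %in% names(cell_file)) cell_file$qc_offset_um[1] else qc_offset
  mids <- offset + cumsum(len) - len / 2
  stats::approx(mids, len, xout = grid, method = "linear", rule = 1)$y
}
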