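# Synthetic observations from a steady-state growth zone. All simulators are
# deterministic under a fixed integer seed (RNG state is restored on exit).

# derive a reproducible sub-seed (kept below 2^31) for per-root substreams
sub_seed <- function(seed, index, stream = 0L) {
  as.integer((as.numeric(seed) * 1009 + index * 97 + stream * 31013) %% 2147483647)
}

#' Simulate toner-particle displacement observations
#'
#' Emulates the velocity-measurement step of a kinematic experiment: particles
#' sprinkled on the root surface at positions drawn uniformly over the domain
#' are carried by the tissue velocity field for `dt` hours, and both endpoint
#' positions are read off with additive Gaussian measurement error.
#' Trajectories integrate `dx/dt = v(x)` with a classical 4th-order
#' Runge-Kutta scheme (100 steps per observation interval).
#'
#' @param spec A [growth_zone_spec()].
#' @param n_particles Number of particles (>= 1).
#' @param dt Elapsed time between the two images, hours (> 0).
#' @param position_noise_sd Gaussian measurement noise on each recorded
#'   position, um.
#' @param seed Integer seed; `NULL` leaves the RNG state alone.
#' @param root_id Label for the root.
#' @return A tibble with columns `root_id`, `x_start_um`, `x_end_um`, `dt_h`.
#' @export
simulate_particles <- function(spec, n_particles, dt = 1,
                               position_noise_sd = 0, seed = NULL,
                               root_id = "root1") {
  stopifnot(inherits(spec, "growth_zone_spec"))
  if (!is.numeric(n_particles) || n_particles < 1) {
    stop_rootkin("`n_particles` must be >= 1", "rootkin_error_parameter")
  }
  if (!is.numeric(dt) || dt <= 0) {
    stop_rootkin("`dt` must be > 0", "rootkin_error_parameter")
  }
  upper <- spec$domain_extent - spec$final_velocity * dt
  if (upper <= 0) {
    stop_rootkin(
      "`dt` is so large that trajectories exit the simulated domain",
      "rootkin_error_domain"
    )
  }
  v <- velocity_field(spec)
  draw <- function() {
    x0 <- runif(n_particles, 0, upper)
    x1 <- integrate_trajectory(v, x0, dt, n_steps = 100L)
    if (position_noise_sd > 0) {
      x0 <- x0 + rnorm(n_particles, 0, position_noise_sd)
      x1 <- x1 + rnorm(n_particles, 0, position_noise_sd)
    }
    tibble::tibble(
      root_id = root_id,
      x_start_um = x0,
      x_end_um = x1,
      dt_h = dt
    )
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

# vectorised RK4 for dx/dt = v(x); autonomous, so stages need no time argument
integrate_trajectory <- function(v, x0, dt, n_steps = 100L) {
  h <- dt / n_steps
  x <- x0
  for (i in seq_len(n_steps)) {
    k1 <- v(x)
    k2 <- v(x + h / 2 * k1)
    k3 <- v(x + h / 2 * k2)
    k4 <- v(x + h * k3)
    x <- x + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  x
}

#' Simulate an ordered cortical cell-length profile
#'
#' Lays cells end-to-end from the quiescent-centre end outward. Cell `k`
#' starting at `x_k` receives the steady-state length consistent with the
#' length field at its own midpoint (the solution of
#' `l = l_field(x_k + l/2)`), so that a noiseless file conserves flux:
#' `v/l` evaluated at cell midpoints equals the cell production rate
#' everywhere beyond the meristem. The length is then perturbed by
#' multiplicative lognormal noise with coefficient of variation `length_cv`
#' (log-scale deviates truncated at three standard deviations).
#' Generation continues until at least six cells lie wholly beyond the growth
#' zone, so the file always reaches well into the mature zone.
#'
#' @inheritParams simulate_particles
#' @param length_cv Coefficient of variation of cell length (0 <= cv < 0.5).
#' @param file_side `"left"`, `"right"` or `"single"`: which cortical file of
#'   the root the profile represents.
#' @param qc_offset Distance (um) from the QC to the proximal end of cell 1.
#' @return A tibble with columns `root_id`, `file_side`, `cell_index`,
#'   `length_um`, `qc_offset_um`, ordered from the first cell after the
#'   cortex/endodermis initial outward.
#' @export
simulate_cell_file <- function(spec, length_cv = 0, seed = NULL,
                               root_id = "root1", file_side = "single",
                               qc_offset = 0) {
  stopifnot(inherits(spec, "growth_zone_spec"))
  if (!is.numeric(length_cv) || length_cv < 0 || length_cv >= 0.5) {
    stop_rootkin("`length_cv` must satisfy 0 <= length_cv < 0.5",
                 "rootkin_error_parameter")
  }
  file_side <- match.arg(file_side, c("left", "right", "single"))
  l <- cell_length_field(spec)
  Lg <- spec$growth_zone_length
  sdlog <- sqrt(log(1 + length_cv^2))

  run <- function() {
    x <- qc_offset
    lengths <- numeric(0)
    starts <- numeric(0)
    n_mature <- 0L
    while (n_mature < 6L) {
      # midpoint-consistent cell length: fixed point of l = l_field(x + l/2)
      len <- l(x)
      for (it in 1:100) {
        new_len <- l(x + len / 2)
        if (abs(new_len - len) < 1e-12) break
        len <- new_len
      }
      if (sdlog > 0) {
        eps <- max(min(rnorm(1, 0, sdlog), 3 * sdlog), -3 * sdlog)
        len <- len * exp(eps)
      }
      starts <- c(starts, x)
      lengths <- c(lengths, len)
      x <- x + len
      if (starts[length(starts)] >= Lg) n_mature <- n_mature + 1L
    }
    tibble::tibble(
      root_id = root_id,
      file_side = file_side,
      cell_index = seq_along(lengths),
      length_um = lengths,
      qc_offset_um = qc_offset
    )
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Simulate a matched cohort of roots
#'
#' Convenience wrapper producing, for each of `n_roots` roots, one particle
#' table and a left and right cortical cell file, with per-root random
#' substreams derived deterministically from `seed` (so root `i` is unchanged
#' when `n_roots` grows).
#'
#' @inheritParams simulate_particles
#' @inheritParams simulate_cell_file
#' @param n_roots Number of roots.
#' @param particles_per_root Particles observed per root.
#' @param genotype Label attached to every record.
#' @return A list with tibbles `particles` and `cell_files`.
#' @export
simulate_cohort <- function(spec, n_roots = 10, particles_per_root = 40,
                            dt = 1, position_noise_sd = 5, length_cv = 0.05,
                            qc_offset = 0, seed = 1, genotype = "WT") {
  parts <- vector("list", n_roots)
  files <- vector("list", n_roots)
  for (i in seq_len(n_roots)) {
    id <- sprintf("%s_root%02d", genotype, i)
    parts[[i]] <- simulate_particles(
      spec, particles_per_root, dt, position_noise_sd,
      seed = sub_seed(seed, i, 1L), root_id = id
    )
    files[[i]] <- dplyr::bind_rows(
      simulate_cell_file(spec, length_cv, seed = sub_seed(seed, i, 2L),
                         root_id = id, file_side = "left", qc_offset = qc_offset),
      simulate_cell_file(spec, length_cv, seed = sub_seed(seed, i, 3L),
                         root_id = id, file_side = "right", qc_offset = qc_offset)
    )
  }
  list(
    particles = dplyr::mutate(dplyr::bind_rows(parts), genotype = genotype),
    cell_files = dplyr::mutate(dplyr::bind_rows(files), genotype = genotype)
  )
}

#' Simulate per-nucleus DNA-content fluorescence intensities
#'
#' Each nucleus is assigned a ploidy class with the given probabilities; its
#' fluorescence intensity is the class DNA content times `anchor/2` (so a 2C
#' nucleus centres on `anchor`), perturbed by multiplicative lognormal noise
#' with coefficient of variation `cv`.
#'
#' @param proportions Named numeric vector of class proportions over
#'   `c("2C","4C","8C","16C","32C")` (subset allowed); must sum to 1.
#' @param n Number of nuclei (>= 1).
#' @param anchor Intensity of the 2C peak centre (> 0).
#' @param cv Coefficient of variation of intensity within a class
#'   (0 <= cv < 0.25; 0 gives the exact geometric ladder).
#' @param seed Integer seed; `NULL` leaves the RNG state alone.
#' @param sample_id,genotype Labels attached to every nucleus.
#' @return A tibble with columns `sample_id`, `genotype`, `intensity`,
#'   `class_true`.
#' @export
simulate_ploidy <- function(proportions, n, anchor = 100, cv = 0.05,
                            seed = NULL, sample_id = "s1", genotype = "WT") {
  classes <- ploidy_classes()
  p <- unlist(proportions)
  if (is.null(names(p)) || !all(names(p) %in% classes)) {
    stop_rootkin("`proportions` must be named with classes among 2C,4C,8C,16C,32C",
                 "rootkin_error_parameter")
  }
  if (abs(sum(p) - 1) > 1e-9) {
    stop_rootkin("`proportions` must sum to 1 (within 1e-9)",
                 "rootkin_error_parameter")
  }
  if (!is.numeric(n) || n < 1) {
    stop_rootkin("`n` must be >= 1", "rootkin_error_parameter")
  }
  if (anchor <= 0) stop_rootkin("`anchor` must be > 0", "rootkin_error_parameter")
  if (cv < 0 || cv >= 0.25) {
    stop_rootkin("`cv` must satisfy 0 <= cv < 0.25", "rootkin_error_parameter")
  }
  full <- setNames(numeric(length(classes)), classes)
  full[names(p)] <- p
  dna <- c(`2C` = 2, `4C` = 4, `8C` = 8, `16C` = 16, `32C` = 32)
  sdlog <- sqrt(log(1 + cv^2))
  run <- function() {
    cls <- sample(classes, n, replace = TRUE, prob = full)
    intensity <- anchor * (dna[cls] / 2) * exp(rnorm(n, 0, sdlog))
    tibble::tibble(
      sample_id = sample_id,
      genotype = genotype,
      intensity = unname(intensity),
      class_true = factor(cls, levels = classes)
    )
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Write simulated observations to plain-text files
#'
#' Writes `particles.csv`, `cellfile.csv` and (optionally) `ploidy.csv` plus a
#' `truth.json` carrying the generating spec and its derived quantities.
#'
#' @param cohort A list as returned by [simulate_cohort()].
#' @param spec The generating [growth_zone_spec()].
#' @param dir Output directory (created if needed).
#' @param ploidy Optional tibble from [simulate_ploidy()].
#' @return Invisibly, the paths written.
#' @export
write_simulation <- function(cohort, spec, dir, ploidy = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    particles = file.path(dir, "particles.csv"),
    cellfile = file.path(dir, "cellfile.csv"),
    truth = file.path(dir, "truth.json")
  )
  readr::write_csv(
    dplyr::select(cohort$particles, "root_id", "x_start_um", "x_end_um", "dt_h"),
    paths[["particles"]]
  )
  readr::write_csv(
    dplyr::select(cohort$cell_files, "root_id", "file_side", "cell_index",
                  "length_um", "qc_offset_um"),
    paths[["cellfile"]]
  )
  truth <- c(unclass(spec), as.list(glance(spec)))
  jsonlite::write_json(truth, paths[["truth"]], auto_unbox = TRUE, digits = NA)
  if (!is.null(ploidy)) {
    paths <- c(paths, ploidy = file.path(dir, "ploidy.csv"))
    readr::write_csv(
      dplyr::select(ploidy, "sample_id", "genotype", "intensity"),
      paths[["ploidy"]]
    )
  }
  invisible(paths)
}
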