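test_that("the plateau rule matches hand-worked examples", {
  expect_equal(plateau_boundary(c(0, 100, 200, 300, 400, 500),
                                c(1, 2, 10, 10, 10, 10)), 200)
  expect_equal(plateau_boundary(c(0, 10, 20, 30), c(5, 5, 5, 5)), 0)
  expect_error(plateau_boundary(c(0, 10, 20, 30, 40), 1:5),
               class = "rootkin_error_boundary")
  expect_error(plateau_boundary(c(0, 10), c(1, 1)),
               class = "rootkin_error_insufficient_data")
})

test_that("the plateau rule agrees exactly with a brute-force scan", {
  withr::with_seed(77, {
    for (rep in 1:1000) {
      n <- sample(3:60, 1)
      values <- switch(sample(3, 1),
                       stats::runif(n, 0, 10),
                       cumsum(stats::runif(n)),            # rising series
                       c(cumsum(stats::runif(n %/% 2 + 1)),
                         rep(n, n - n %/% 2 - 1) + stats::rnorm(n - n %/% 2 - 1, 0, 0.1)))
      pos <- sort(stats::runif(n, 0, 1000))
      pos <- pos + seq_len(n) * 1e-6 # guarantee strictly increasing
      bf <- bf_plateau(pos, values)
      got <- tryCatch(plateau_boundary(pos, values), error = function(e) NA_real_)
      expect_identical(got, bf)
    }
  })
})

test_that("flux is velocity over cell length, with positivity enforced", {
  expect_equal(compute_flux(300, 150), 2)
  expect_equal(compute_flux(c(0, 100), c(10, 50)), c(0, 2))
  expect_error(compute_flux(10, 0), class = "rootkin_error_domain")
})

test_that("scalar kinematic formulas are exact", {
  expect_equal(cell_production_rate(300, 150), 2)
  expect_equal(cell_production_rate(0, 150), 0)
  expect_error(cell_production_rate(300, 0), class = "rootkin_error_domain")
  expect_equal(cell_cycle_duration(1, log(2)), 1)
  expect_equal(cell_cycle_duration(50, 2), log(2) * 25)
  expect_error(cell_cycle_duration(50, 0), class = "rootkin_error_domain")
})

test_that("strain-rate profiles differentiate the velocity grid", {
  x <- 0:100
  lin <- fake_profile(x, 0.5 * x)
  expect_equal(strain_rate_profile(lin)$regr_per_h, rep(0.5, 101))
  flat <- fake_profile(x, rep(42, 101))
  expect_equal(strain_rate_profile(flat)$regr_per_h, rep(0, 101))
})

test_that("transit times reproduce closed-form integrals", {
  x <- seq(0, 1200, by = 1)
  const <- fake_profile(x, rep(300, length(x)))
  expect_equal(elongation_transit_time(const, 500, 800), 1, tolerance = 1e-9)
  ident <- fake_profile(seq(0, 1000, by = 1), seq(0, 1000, by = 1))
  expect_equal(elongation_transit_time(ident, 100, 1000), log(10),
               tolerance = 1e-6)
  # scaling all velocities up strictly reduces the transit time
  faster <- fake_profile(x, 1.7 * pmax(x, 1) / 4)
  slower <- fake_profile(x, pmax(x, 1) / 4)
  expect_lt(elongation_transit_time(faster, 100, 900),
            elongation_transit_time(slower, 100, 900))
  zero <- fake_profile(x, c(0, 0, rep(10, length(x) - 2)))
  expect_error(elongation_transit_time(zero, 0, 500),
               class = "rootkin_error_domain")
})

test_that("constant-velocity data give a flat profile and an immediate plateau", {
  particles <- tibble::tibble(
    x_start_um = seq(950, 1400, length.out = 25),
    x_end_um = seq(950, 1400, length.out = 25) + 300,
    dt_h = 1
  )
  prof <- estimate_velocity_profile(particles)
  expect_equal(prof$data$v_um_per_h, rep(300, nrow(prof$data)), tolerance = 1e-6)
  gz <- growth_zone_boundary(prof)
  # a constant series plateaus at the very first occupied grid point
  expect_equal(gz$growth_zone_length_um, prof$support[1])
  expect_equal(gz$final_velocity_um_per_h, 300, tolerance = 1e-6)
})

test_that("duplicate midpoints are retained and jointly weighted", {
  particles <- tibble::tibble(
    x_start_um = c(95, 90, 0, 50, 150, 200),
    x_end_um = c(105, 110, 4, 56, 162, 214),
    dt_h = 1
  )
  prof <- estimate_velocity_profile(particles, bandwidth = 50)
  expect_identical(nrow(prof$points), 6L)
  expect_identical(sum(prof$points$mid_um == 100), 2L)
})

test_that("degenerate particle input raises estimation errors", {
  expect_error(estimate_velocity_profile(
    tibble::tibble(x_start_um = numeric(0), x_end_um = numeric(0),
                   dt_h = numeric(0))),
    class = "rootkin_error_estimation")
  expect_error(estimate_velocity_profile(
    tibble::tibble(x_start_um = c(10, 10, 10), x_end_um = c(20, 20, 20),
                   dt_h = 1)),
    class = "rootkin_error_estimation")
})

test_that("a noiseless simulation is recovered to within the fit tolerance", {
  spec <- ref_spec()
  v_true <- velocity_field(spec)
  obs <- simulate_particles(spec, 150, dt = 1, position_noise_sd = 0, seed = 21)
  prof <- estimate_velocity_profile(obs, bandwidth = 50)
  on_grid <- v_true(prof$data$x_um)
  rmse <- sqrt(mean((prof$data$v_um_per_h - on_grid)^2))
  expect_lt(rmse, 0.02 * spec$final_velocity)
})

test_that("noiseless profiles conserve flux and integrate REGR back to V", {
  spec <- ref_spec()
  sim <- simulate_cohort(spec, 1, 150, dt = 1, position_noise_sd = 0,
                         length_cv = 0, seed = 31)
  fit <- analyze_root_kinematics(sim$particles, sim$cell_files)
  s <- fit$summary

  expect_equal(s$V_um_per_h, 300, tolerance = 0.005)
  # the 95% rule returns the 95%-of-plateau crossing, biased tipward of the
  # true boundaries; the recovered values sit within 10% of truth
  expect_lt(abs(s$Lm_um - 500), 50)
  expect_lt(abs(s$Lg_um - 900), 110)

  # flux conservation beyond the estimated meristem boundary
  gd <- fit$grid_data
  flux <- gd$flux_per_h[!is.na(gd$flux_per_h) & gd$x_um >= s$Lm_um]
  expect_lt(sd(flux) / mean(flux), 0.02)

  # fundamental-theorem check: trapezoid integral of REGR over the measured
  # grid recovers the plateau velocity
  r <- gd$regr_per_h
  integral <- sum((r[-1] + r[-length(r)]) / 2 * diff(gd$x_um))
  expect_equal(integral, s$V_um_per_h, tolerance = 0.01)

  # transit estimate matches the analytic integral of the true field over
  # the same (estimated) interval
  v <- velocity_field(spec)
  analytic <- stats::integrate(function(x) 1 / v(x), s$Lm_um, s$Lg_um,
                               rel.tol = 1e-10)$value
  expect_equal(s$transit_h, analytic, tolerance = 0.01)
})

test_that("plateau-only roots yield V but no meristem boundary", {
  spec <- ref_spec()
  particles <- tibble::tibble(
    root_id = "p1",
    x_start_um = seq(1000, 1400, length.out = 20),
    x_end_um = seq(1000, 1400, length.out = 20) + 300,
    dt_h = 1
  )
  cf <- simulate_cell_file(spec, 0, seed = 1, root_id = "p1")
  fit <- analyze_root_kinematics(particles, cf)
  expect_equal(fit$summary$V_um_per_h, 300, tolerance = 1e-6)
  # the meristem is not in view: boundary-not-found is reported as a note,
  # not an abort
  expect_true(is.na(fit$summary$Lm_um))
  expect_match(paste(fit$notes, collapse = "; "), "meristem")
})

test_that("a lower-production, longer-celled cohort is ranked correctly", {
  wt <- ref_spec()
  mut <- mutant_spec()
  expect_equal(glance(mut)$cell_cycle_h, glance(wt)$cell_cycle_h) # same Tc
  ok <- vapply(1:5, function(s) {
    a <- simulate_cohort(wt, 4, 40, 1, 5, 0.05, seed = s, genotype = "WT")
    b <- simulate_cohort(mut, 4, 40, 1, 5, 0.05, seed = 1000 + s, genotype = "mut")
    ka <- analyze_kinematics(a$particles, a$cell_files)
    kb <- analyze_kinematics(b$particles, b$cell_files)
    mean(kb$P_cells_per_h, na.rm = TRUE) < mean(ka$P_cells_per_h, na.rm = TRUE) &&
      mean(kb$mature_len_um, na.rm = TRUE) > mean(ka$mature_len_um, na.rm = TRUE)
  }, logical(1))
  expect_true(all(ok))
})
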