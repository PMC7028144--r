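test_that("plateau particles move at exactly the final velocity", {
  spec <- ref_spec()
  withr::with_seed(7, {
    obs <- simulate_particles(spec, 200, dt = 1, position_noise_sd = 0, seed = 11)
    plateau <- obs$x_start_um >= spec$growth_zone_length
    expect_gt(sum(plateau), 0)
    expect_equal(obs$x_end_um[plateau],
                 obs$x_start_um[plateau] + spec$final_velocity,
                 tolerance = 1e-9)
  })
})

test_that("the trajectory integrator matches the exponential closed form", {
  # inside the meristem r is constant, so x(t) = x0 * exp(r_m t)
  spec <- ref_spec()
  small_dt_spec <- ref_spec() # dt = 1 keeps x0 * e^0.04 well inside the meristem
  obs <- simulate_particles(small_dt_spec, 50, dt = 1, position_noise_sd = 0,
                            seed = 3)
  meristem <- obs$x_start_um > 1 &
    obs$x_end_um < spec$meristem_length # whole trajectory inside
  expect_gt(sum(meristem), 0)
  expect_equal(obs$x_end_um[meristem],
               obs$x_start_um[meristem] * exp(spec$meristem_strain_rate),
               tolerance = 1e-4)
})

test_that("short-interval displacement rates converge to the local velocity", {
  spec <- ref_spec()
  v <- velocity_field(spec)
  obs <- simulate_particles(spec, 100, dt = 0.01, position_noise_sd = 0, seed = 5)
  rate <- (obs$x_end_um - obs$x_start_um) / obs$dt_h
  expect_equal(rate, v(obs$x_start_um), tolerance = 1e-3)
})

test_that("simulations are byte-identical under a fixed seed", {
  spec <- ref_spec()
  a <- simulate_particles(spec, 30, 1, 5, seed = 42)
  b <- simulate_particles(spec, 30, 1, 5, seed = 42)
  expect_identical(a, b)
  fa <- simulate_cell_file(spec, 0.05, seed = 42)
  fb <- simulate_cell_file(spec, 0.05, seed = 42)
  expect_identical(fa, fb)
  pa <- simulate_ploidy(c(`2C` = 0.6, `4C` = 0.4), 500, seed = 42)
  pb <- simulate_ploidy(c(`2C` = 0.6, `4C` = 0.4), 500, seed = 42)
  expect_identical(pa, pb)
  ca <- simulate_cohort(spec, 2, 10, seed = 9)
  cb <- simulate_cohort(spec, 2, 10, seed = 9)
  expect_identical(ca, cb)
})

test_that("observation intervals that overrun the domain are rejected", {
  spec <- ref_spec() # X_max = 1800, V = 300
  expect_error(simulate_particles(spec, 10, dt = 7),
               class = "rootkin_error_domain")
})

test_that("noiseless cell files tile the true zones exactly", {
  spec <- ref_spec()
  cf <- simulate_cell_file(spec, length_cv = 0, seed = 1)
  starts <- cumsum(cf$length_um) - cf$length_um
  # deterministic tiling: exactly Lm/l0 = 50 cells lie wholly in the meristem
  expect_identical(sum(starts + cf$length_um <= spec$meristem_length + 1e-9), 50L)
  expect_equal(cf$length_um[seq_len(50)], rep(10, 50))
  # every cell wholly beyond the growth zone has exactly the mature length
  beyond <- starts >= spec$growth_zone_length
  expect_gte(sum(beyond), 6)
  expect_equal(cf$length_um[beyond], rep(spec$mature_cell_length, sum(beyond)))
})

test_that("lognormal length noise is unbiased to within 1%", {
  spec <- ref_spec()
  # 200 files x 50 meristem cells = 10^4 draws around l0 = 10 um
  lens <- unlist(lapply(1:200, function(i) {
    simulate_cell_file(spec, length_cv = 0.05, seed = i)$length_um[1:50]
  }))
  expect_equal(mean(lens), 10, tolerance = 0.01)
})

test_that("ploidy class draws respect their probabilities", {
  p <- c(`2C` = 0.5, `4C` = 0.3, `8C` = 0.15, `16C` = 0.05)
  s <- simulate_ploidy(p, 10000, anchor = 100, cv = 0.05, seed = 12)
  counts <- table(s$class_true)[names(p)]
  expected <- 10000 * p
  # 99% binomial bounds
  bound <- stats::qnorm(0.995) * sqrt(10000 * p * (1 - p))
  expect_true(all(abs(counts - expected) <= bound))
})

test_that("a noise-free ploidy sample is the exact geometric ladder", {
  p <- rep(0.2, 5)
  names(p) <- c("2C", "4C", "8C", "16C", "32C")
  s <- simulate_ploidy(p, 2000, anchor = 80, cv = 0, seed = 2)
  vals <- sort(unique(s$intensity))
  expect_equal(vals, 80 * c(1, 2, 4, 8, 16))
  one <- simulate_ploidy(c(`2C` = 1), 100, anchor = 55, cv = 0, seed = 2)
  expect_equal(one$intensity, rep(55, 100))
})

test_that("malformed ploidy proportions are rejected", {
  expect_error(simulate_ploidy(c(`2C` = 0.5, `4C` = 0.4), 100),
               class = "rootkin_error_parameter")
  expect_error(simulate_ploidy(c(`3C` = 1), 100),
               class = "rootkin_error_parameter")
  expect_error(simulate_ploidy(c(`2C` = 1), 100, cv = 0.5),
               class = "rootkin_error_parameter")
})

test_that("simulation files round-trip through the plain-text writers", {
  spec <- ref_spec()
  dir <- withr::local_tempdir()
  sim <- simulate_cohort(spec, 2, 10, seed = 4)
  paths <- write_simulation(sim, spec, dir,
                            ploidy = simulate_ploidy(c(`2C` = 1), 120, seed = 1))
  expect_true(all(file.exists(paths)))
  back <- readr::read_csv(paths[["particles"]], show_col_types = FALSE)
  expect_equal(nrow(back), 20)
  expect_named(back, c("root_id", "x_start_um", "x_end_um", "dt_h"))
  truth <- jsonlite::read_json(paths[["truth"]])
  expect_equal(truth$final_velocity, 300)
})
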