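test_that("half-sine excitation matches its defining profile", {
  spec <- excitation_spec()
  expect_identical(half_sine_excitation(0, spec), 0)
  expect_equal(half_sine_excitation(125e-6, spec), 20e-6)
  expect_equal(half_sine_excitation(250e-6, spec), 0, tolerance = 1e-20)
  expect_identical(half_sine_excitation(300e-6, spec), 0)
  expect_error(half_sine_excitation(-1e-6, spec), "t")
  expect_error(excitation_spec(amplitude = 0), "amplitude")
})

test_that("zero excitation amplitude limit: tiny drive gives a tiny field", {
  m <- tendon_mesh(small_mesh_config())
  a <- beam_assembly(m, table1_params(), coupling_coeff = 0)
  a <- set_assembly_loads(a, uniform_case(m, 5e6))
  maps <- simulate_coupled_beams(a, excitation_spec(amplitude = 1e-30),
                                 refine = 1)
  expect_lt(max(abs(maps$LG$u)), 1e-29)
})

test_that("unstable explicit steps are rejected with the computed bound", {
  m <- tendon_mesh(small_mesh_config())
  a <- set_assembly_loads(beam_assembly(m, table1_params(), coupling_coeff = 0),
                          uniform_case(m, 30e6))
  expect_error(simulate_coupled_beams(a, dt = 1e-3), "bound")
  expect_error(simulate_coupled_beams(set_assembly_loads(
    beam_assembly(m, table1_params()),
    c(LG = -10e6, MG = 1e6, S = 1e6)), NULL), "tension")
})

test_that("decoupled beams propagate at the closed-form speed", {
  m <- tendon_mesh(mesh_config())
  p <- table1_params()
  a <- beam_assembly(m, p, coupling_coeff = 0)
  sigma <- 5e6
  maps <- simulate_coupled_beams(set_assembly_loads(a, uniform_case(m, sigma)))
  cexp <- closed_form_wave_speed(sigma, 1, p$mu, p$rho)
  # leading-edge arrival oracle at the far node (1% amplitude threshold)
  u <- maps$LG$u
  far <- nrow(u)
  amp <- max(abs(u))
  thr <- 0.01 * amp
  k <- which(abs(u[far, ]) > thr)[1]
  row <- abs(u[far, ])
  t_arr <- (k - 2 + (thr - row[k - 1]) / (row[k] - row[k - 1])) * maps$LG$dt
  d <- (far - 1) * maps$LG$dx
  t_onset <- asin(0.01) / pi * 250e-6     # drive crosses 1% amplitude
  expect_equal(d / (t_arr - t_onset), cexp, tolerance = 0.02)
  # Radon estimate agrees too
  for (l in c("LG", "MG", "S"))
    expect_equal(measure_wave_speed(maps[[l]])$speed, cexp, tolerance = 0.03)
})

test_that("rigid coupling drives all subtendons to the composite speed", {
  m <- tendon_mesh(mesh_config())
  p <- table1_params()
  a <- beam_assembly(m, p, coupling_coeff = 100)
  areas <- distal_areas(m)
  lc <- partition_cohort_forces(3300, areas, ratio = 2)
  maps <- simulate_coupled_beams(set_assembly_loads(a, lc))
  ccomp <- sqrt((sum(lc$stress * areas) / sum(areas) + p$mu) / p$rho)
  for (l in c("LG", "MG", "S"))
    expect_equal(measure_wave_speed(maps[[l]])$speed, ccomp, tolerance = 0.02)
})

test_that("discrete energy is conserved once the drive has ended", {
  m <- tendon_mesh(mesh_config(twist_deg = 60))
  a <- beam_assembly(m, table1_params(), coupling_coeff = 0.1)
  lc <- partition_cohort_forces(3300, distal_areas(m), ratio = 2)
  maps <- simulate_coupled_beams(set_assembly_loads(a, lc),
                                 return_energy = TRUE)
  en <- attr(maps, "energy")
  post <- en[30:length(en)]               # drive ends at 250 us (sample 26)
  expect_lt((max(post) - min(post)) / max(post), 0.01)
  expect_gt(min(post), 0)
})

test_that("zero twist and uniform load give three matching speeds", {
  m <- tendon_mesh(mesh_config())
  a <- beam_assembly(m, table1_params(), coupling_coeff = 0.1)
  maps <- simulate_coupled_beams(set_assembly_loads(a, uniform_case(m, 10e6)))
  sp <- vapply(c("LG", "MG", "S"),
               function(l) measure_wave_speed(maps[[l]])$speed, 0)
  expect_lt(diff(range(sp)) / mean(sp), 0.01)
})

test_that("coupling monotonicity: gastrocnemius speed non-decreasing in kappa", {
  m <- tendon_mesh(mesh_config())
  p <- table1_params()
  lc <- partition_cohort_forces(3300, distal_areas(m), ratio = 2)
  speeds <- vapply(c(0, 0.05, 0.2, 1), function(co) {
    a <- set_assembly_loads(beam_assembly(m, p, coupling_coeff = co), lc)
    measure_wave_speed(simulate_coupled_beams(a)$LG)$speed
  }, 0)
  expect_true(all(diff(speeds) > -1e-6 * speeds[-1]))
  expect_gt(speeds[4], speeds[1])
})

test_that("reflective-plus-filter agrees with absorbing-boundary estimates", {
  m <- tendon_mesh(mesh_config())
  a <- beam_assembly(m, table1_params(), coupling_coeff = 0)
  a <- set_assembly_loads(a, uniform_case(m, 10e6))
  refl <- measure_wave_speed(simulate_coupled_beams(a)$LG)$speed
  absb <- radon_speed(simulate_coupled_beams(a, proximal_bc = "absorbing")$LG,
                      filtered = TRUE)$speed
  expect_lt(abs(refl - absb) / absb, 0.03)
})

test_that("decoupling limit recovers slope 1/rho across a load sweep", {
  m <- tendon_mesh(mesh_config())
  p <- table1_params()
  a <- beam_assembly(m, p, coupling_coeff = 0)
  sig <- seq(4e6, 28e6, length.out = 7)
  sp <- vapply(sig, function(s) {
    maps <- simulate_coupled_beams(set_assembly_loads(a, uniform_case(m, s)))
    measure_wave_speed(maps$LG)$speed
  }, 0)
  r <- fit_wave_speed_stress(sp, sig)
  expect_lt(abs(r$slope - p$rho) / p$rho, 0.10)
  expect_gt(r$r_squared, 0.99)
})
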