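params <- physical_params()

test_that("Langmuir rate evaluates the printed kinetics", {
  expect_equal(langmuir_rate(1e-7, 0, params),
               1e3 * 1e-7 * 3.3e-8, tolerance = 1e-12)   # 3.3e-12 mol/m^2/s
  expect_equal(langmuir_rate(5, params$R_T, params), -1e-3 * 3.3e-8)
  kc <- params$k_on * params$C0 + params$k_off
  B_eq <- params$k_on * params$C0 * params$R_T / kc
  expect_equal(langmuir_rate(params$C0, B_eq, params), 0, tolerance = 1e-25)
  expect_error(langmuir_rate(1e-7, 2 * params$R_T, params), "R_T")
  expect_error(langmuir_rate(-1, 0, params), "C_w")
})

test_that("well-mixed closed form has the right limits", {
  expect_equal(well_mixed_binding(0, params), 0)
  expect_equal(well_mixed_binding(1e9, params), 3.0e-9, tolerance = 1e-3)
  p_irr <- physical_params(k_off = 1e-300)
  expect_equal(well_mixed_binding(1e12, p_irr), p_irr$R_T, tolerance = 1e-6)
  # cross-check against an independent ODE integration
  tt <- c(10, 50, 100)
  f <- function(t, B) params$k_on * params$C0 * (params$R_T - B) -
    params$k_off * B
  B <- 0; t <- 0; h <- 0.01
  num <- numeric(length(tt))
  for (i in seq_along(tt)) {
    while (t < tt[i] - 1e-12) {
      k1 <- f(t, B); k2 <- f(t + h / 2, B + h / 2 * k1)
      k3 <- f(t + h / 2, B + h / 2 * k2); k4 <- f(t + h, B + h * k3)
      B <- B + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4); t <- t + h
    }
    num[i] <- B
  }
  expect_equal(well_mixed_binding(tt, params), num, tolerance = 1e-8)
})

test_that("no reaction means no binding and an untouched bulk", {
  p0 <- physical_params(k_on = 0)
  m <- build_mesh(channel_geometry(), resolution = 0.35)
  b <- simulate_binding(m, NULL, p0, t_end = 10, dt = 1)
  expect_true(all(b$curve$B_avg == 0))
  expect_equal(b$state$C, rep(p0$C0, length(b$state$C)), tolerance = 1e-12)
})

test_that("time step must resolve the reaction timescale", {
  pfast <- physical_params(k_on = 1e6)
  m <- build_mesh(channel_geometry(), resolution = 0.35)
  expect_error(simulate_binding(m, NULL, pfast, t_end = 10, dt = 1),
               "use dt <=")
})

test_that("quiescent binding matches an independent 1D oracle", {
  # near-1D configuration: functionalized strip spanning (almost) the whole
  # bottom of a 200 um tall cavity; compare the bound density far from the
  # strip ends with a 1D finite-volume diffusion-reaction solution
  g <- channel_geometry(length = 200e-6, height = 200e-6,
                        gate_width = 190e-6, gate_height = 2e-7,
                        gate_center_x = 100e-6,
                        functionalized_span = c(5e-6, 195e-6))
  m <- build_mesh(g, resolution = 0.5)
  b2d <- simulate_binding(m, NULL, params, t_end = 100, dt = 0.5)
  xb <- m$nodes[b2d$state$nodes, 1]
  mid <- which.min(abs(xb - 100e-6))
  b1d <- oracle_binding_1d(params, H = 200e-6, t_end = 100, dt = 0.5)
  expect_equal(b2d$state$B[mid], b1d$B_final, tolerance = 0.10)
})

test_that("with fast diffusion the coupling reduces to well-mixed Langmuir", {
  # depletion kept negligible (small R_T) so the constant-C0 closed form is
  # the correct reference; D x 1e4 makes the 200 um cavity well mixed
  pwm <- physical_params(D_antigen = 1e-7, R_T = 1e-9)
  m <- build_mesh(channel_geometry(), resolution = 0.35)
  b <- simulate_binding(m, NULL, pwm, t_end = 50, dt = 0.5)
  keep <- b$curve$time > 0
  expect_equal(b$curve$B_avg[keep],
               well_mixed_binding(b$curve$time[keep], pwm),
               tolerance = 0.02)
})

test_that("closed chamber conserves total antigen; B stays in range", {
  sc <- make_scenario("static_chamber")
  m <- build_mesh(sc$geometry, resolution = 0.5)
  pot <- solve_potential_phasor(m, sc$params, sc$drive)
  fl <- solve_stokes(m, timeavg_slip(pot, m, sc$params))
  b <- simulate_binding(m, fl, sc$params, t_end = 100, dt = 0.5)
  drift <- max(abs(b$mass$total - b$mass$total[1])) / b$mass$total[1]
  expect_lt(drift, 1e-3)
  expect_true(all(b$state$B >= 0 & b$state$B <= sc$params$R_T))
  expect_true(all(b$curve$B_norm >= 0 & b$curve$B_norm <= 1))
  expect_gt(min(b$state$C), -0.02 * sc$params$C0)
  # binding curve is monotone while the wall stays below equilibrium
  expect_true(all(diff(b$curve$B_avg) >= -1e-20))
  # stirring beats pure diffusion
  b0 <- simulate_binding(m, NULL, sc$params, t_end = 100, dt = 0.5)
  expect_gt(binding_at(b, 100), binding_at(b0, 100))
})

test_that("halving the time step moves B(t_end) by less than 1%", {
  sc <- make_scenario("static_chamber")
  m <- build_mesh(sc$geometry, resolution = 0.35)
  pot <- solve_potential_phasor(m, sc$params, sc$drive)
  fl <- solve_stokes(m, timeavg_slip(pot, m, sc$params))
  b1 <- simulate_binding(m, fl, sc$params, t_end = 40, dt = 0.5)
  b2 <- simulate_binding(m, fl, sc$params, t_end = 40, dt = 0.25)
  expect_equal(binding_at(b2, 40), binding_at(b1, 40), tolerance = 0.01)
})

test_that("continuous flow holds the inlet at C0 and binds less than static", {
  sc <- make_scenario("continuous_flow")
  m <- build_mesh(sc$geometry, resolution = 0.5)
  fl <- solve_stokes(m, zero_slip(m), inlet_mean_velocity = 50e-6)
  b <- simulate_binding(m, fl, sc$params, t_end = 17, dt = 0.25)
  inlet <- tagged_nodes(m, "left_electrode")
  expect_equal(b$state$C[inlet], rep(sc$params$C0, length(inlet)))
  expect_true(all(b$curve$B_avg >= 0))
  expect_gt(min(b$state$C), -0.02 * sc$params$C0)
})
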