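params <- physical_params()
mesh <- build_mesh(channel_geometry(), resolution = RES_COARSE)
f_rc <- rc_frequency(params, 25e-6)
pot10 <- solve_potential_phasor(mesh, params, drive_signal(4, 10))
slip10 <- timeavg_slip(pot10, mesh, params)

test_that("induced zeta is the scaled gate-to-bulk potential drop", {
  z0 <- induced_zeta(pot10, mesh, params)
  p2 <- physical_params(delta = 1)
  z1 <- induced_zeta(pot10, mesh, p2)
  expect_equal(z1$zeta, z0$zeta / 2)
  # DC limit on the flat gate: zeta = E0 x / (1 + delta), slope E0 = 4000 V/m
  x <- z0$s - 25e-6
  fit <- stats::lm(Re(z0$zeta) ~ x)
  expect_equal(unname(stats::coef(fit)[2]), 4000, tolerance = 0.01)
  expect_equal(Re(z0$zeta[which.max(z0$s)]),
               4000 * max(x) / (1 + params$delta), tolerance = 0.02)
})

test_that("numerical low-frequency slip matches the DC closed form", {
  x <- slip10$s - 25e-6
  exact <- dc_limit_slip(x, 4000, params)
  central <- abs(x) <= 0.8 * 25e-6
  expect_lt(max(abs(slip10$slip[central] - exact[central]) /
                  abs(exact[central])), 0.10)
})

test_that("DC closed form evaluates as printed", {
  u <- dc_limit_slip(25e-6, 4000, params)
  expect_equal(abs(u), 1.42e-4, tolerance = 5e-3)
  expect_lt(u, 0)  # directed toward the gate center at the right edge
  expect_equal(dc_limit_slip(0, 4000, params), 0)
  expect_equal(dc_limit_slip(10e-6, 8000, params),
               4 * dc_limit_slip(10e-6, 4000, params))
  expect_error(dc_limit_slip(30e-6, 4000, params), "half-width")
})

test_that("slip is quadratic in drive amplitude, exactly", {
  pot8 <- solve_potential_phasor(mesh, params, drive_signal(8, 10))
  slip8 <- timeavg_slip(pot8, mesh, params)
  expect_equal(slip8$slip, 4 * slip10$slip, tolerance = 1e-12)
  expect_equal(surface_avg_slip(slip8) / surface_avg_slip(slip10), 4,
               tolerance = 1e-12)
  # holds at every frequency (product of two linearly scaling fields)
  potA <- solve_potential_phasor(mesh, params, drive_signal(4, 2000))
  potB <- solve_potential_phasor(mesh, params, drive_signal(8, 2000))
  expect_equal(timeavg_slip(potB, mesh, params)$slip,
               4 * timeavg_slip(potA, mesh, params)$slip, tolerance = 1e-12)
})

test_that("slip profile is odd about the gate center and vanishes at V0 = 0", {
  expect_equal(slip10$slip, -rev(slip10$slip), tolerance = 1e-10)
  # the two facets straddling the symmetry point carry equal and opposite
  # slip, so the interpolated slip at the gate center is zero
  ord <- order(abs(slip10$s - 25e-6))[1:2]
  expect_lt(abs(sum(slip10$slip[ord])), 1e-6 * max(abs(slip10$slip)))
  expect_true(all(zero_slip(mesh)$slip == 0))
})

test_that("surface averaging is a length-weighted mean of |slip|", {
  prof <- zero_slip(mesh)
  expect_equal(surface_avg_slip(prof), 0)
  prof$slip <- rep(3e-5, length(prof$slip))
  expect_equal(surface_avg_slip(prof), 3e-5)
  # linear (DC-limit) profile with edge value u_e averages to u_e/2
  prof$slip <- (prof$s - 25e-6) / 25e-6 * 1e-4
  expect_equal(surface_avg_slip(prof), 0.5e-4, tolerance = 0.01)
})

test_that("reduced RC response is Lorentzian with 50% at f_c", {
  expect_equal(reduced_rc_response(500, 500, 1e-4), 0.5e-4)
  expect_equal(reduced_rc_response(1e-3, 500, 1e-4), 1e-4, tolerance = 1e-8)
  expect_equal(reduced_rc_response(1500, 500, 1e-4), 1e-5)
})

test_that("slip frequency response is monotone and near-Lorentzian", {
  freqs <- 10^seq(1, 4.5, by = 0.5)
  us <- vapply(freqs, function(fr) {
    pot <- solve_potential_phasor(mesh, params, drive_signal(4, fr))
    surface_avg_slip(timeavg_slip(pot, mesh, params))
  }, 1)
  expect_true(all(diff(us) < 0))
  fc <- relaxation_frequency_from_sweep(data.frame(value = freqs, slip_avg = us))
  pred <- reduced_rc_response(freqs, fc, us[1])
  expect_lt(sqrt(mean(((us - pred) / us[1])^2)), 0.15)
})

test_that("raised gate carries slip on top and sidewalls", {
  m5 <- build_mesh(channel_geometry(gate_height = 5e-6), RES_COARSE)
  pot <- solve_potential_phasor(m5, params, drive_signal(4, 10))
  sl <- timeavg_slip(pot, m5, params)
  expect_true(any(abs(sl$slip[sl$side == 1L]) > 0))
  expect_true(any(abs(sl$slip[sl$side == 3L]) > 0))
  # taller gate intensifies the surface-averaged slip vs the flat gate
  expect_gt(surface_avg_slip(sl), surface_avg_slip(slip10))
})
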