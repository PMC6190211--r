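params <- physical_params()
mesh <- build_mesh(channel_geometry(), resolution = RES_COARSE)
f_rc <- rc_frequency(params, 25e-6)

test_that("a flat insulating bottom gives the 1D capacitor field", {
  # in the low-frequency/insulator limit the flat gate is indistinguishable
  # from the wall, so the potential is linear in x: |grad phi| = V0/L
  d <- drive_signal(4, 10)
  ins <- solve_potential_limit(mesh, d, "insulator")
  phi_exact <- 4 * (1 - mesh$nodes[, 1] / 1e-3)
  expect_equal(Re(ins$phi), phi_exact, tolerance = 1e-10)
  sf_phi <- structure(list(phi = ins$phi, V0g = 0 + 0i, drive = d),
                      class = "iceo_potential")
  sf <- surface_fields(sf_phi, mesh)
  expect_equal(Re(sf$Et), rep(4000, length(sf$Et)), tolerance = 1e-8)
  expect_equal(Mod(sf$En), rep(0, length(sf$En)), tolerance = 1e-6)
})

test_that("gate floating potential sits at V0/2 by symmetry", {
  sol <- solve_potential_phasor(mesh, params, drive_signal(4, 100))
  expect_equal(Re(sol$V0g), 2, tolerance = 1e-10)
  expect_lt(abs(Im(sol$V0g)), 1e-10)
})

test_that("gate charge is conserved and the maximum principle holds", {
  for (fr in c(10, f_rc, 1e4)) {
    sol <- solve_potential_phasor(mesh, params, drive_signal(4, fr))
    w <- 2 * pi * fr * params$C_D / (1 + params$delta)
    expect_lt(sol$charge_residual, 1e-8 * (w * 4 * 50e-6))
    expect_lte(max(Mod(sol$phi)), 4 * (1 + 1e-9))
  }
})

test_that("low and high frequency solutions approach the limit solves", {
  d <- drive_signal(4, 1)
  lo <- solve_potential_phasor(mesh, params,
                               drive_signal(4, f_rc / 100))
  ins <- solve_potential_limit(mesh, d, "insulator")
  expect_lt(max(Mod(lo$phi - ins$phi)), 0.02 * 4)
  # insulator limit: net normal flux magnitude over the gate is small
  sf <- surface_fields(lo, mesh)
  gate_flux <- sum(Mod(sf$En) * sf$length)
  expect_lt(gate_flux, 0.01 * 4000 * 50e-6)

  hi <- solve_potential_phasor(mesh, params,
                               drive_signal(4, 100 * f_rc))
  con <- solve_potential_limit(mesh, d, "conductor")
  expect_lt(max(Mod(hi$phi - con$phi)), 0.02 * 4)
  # conductor limit: tangential field vanishes at the gate center
  sfh <- surface_fields(hi, mesh)
  ic <- which.min(abs(sfh$s - 25e-6))
  expect_lt(Mod(sfh$Et[ic]), 0.02 * 4000)
})

test_that("solution scales linearly with the drive amplitude", {
  a <- solve_potential_phasor(mesh, params, drive_signal(4, 200))
  b <- solve_potential_phasor(mesh, params, drive_signal(10, 200))
  expect_equal(b$phi, 2.5 * a$phi, tolerance = 1e-9)
  expect_equal(b$V0g, 2.5 * a$V0g, tolerance = 1e-9)
})

test_that("the DC limit is routed to the analytic path", {
  d <- drive_signal(4, 1)
  d$omega <- 0
  expect_error(solve_potential_phasor(mesh, params, d), "DC limit")
})

test_that("RC relaxation frequency follows the printed formula", {
  p <- physical_params()  # lambda_D = 3.763e-8 m at 1 mS/m
  expect_equal(rc_frequency(p, 25e-6), 339, tolerance = 0.01)
  p2 <- physical_params(delta = 1)
  expect_equal(rc_frequency(p2, 25e-6), 2 * rc_frequency(p, 25e-6))
  expect_equal(rc_frequency(p, 50e-6), rc_frequency(p, 25e-6) / 2)
})
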