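params <- physical_params()
mesh <- build_mesh(channel_geometry(), resolution = RES_COARSE)
pot <- solve_potential_phasor(mesh, params, drive_signal(4, 10))
slip <- timeavg_slip(pot, mesh, params)
flow <- solve_stokes(mesh, slip)

test_that("no forcing gives a fluid at rest", {
  f0 <- solve_stokes(mesh, zero_slip(mesh))
  expect_equal(max(abs(c(f0$ux, f0$uy))), 0, tolerance = 1e-20)
})

test_that("pure inlet flow reproduces Poiseuille", {
  mcf <- build_mesh(make_scenario("continuous_flow")$geometry, RES_COARSE)
  fp <- solve_stokes(mcf, zero_slip(mcf), inlet_mean_velocity = 50e-6)
  H <- 50e-6
  # centerline maximum = 1.5 x mean
  expect_equal(max(fp$ux), 75e-6, tolerance = 0.02)
  # parabolic profile at a mid-channel section
  sel <- which(abs(mcf$nodes[, 1] - 500e-6) < 1e-9)
  y <- mcf$nodes[sel, 2]
  exact <- 1.5 * 50e-6 * (1 - (2 * y / H - 1)^2)
  expect_lt(max(abs(fp$ux[sel] - exact)), 0.02 * 75e-6)
  expect_lt(max(abs(fp$uy[sel])), 0.02 * 75e-6)
  # inlet and outlet fluxes balance
  expect_equal(section_flux(fp, mcf, 0), section_flux(fp, mcf, 1e-3),
               tolerance = 1e-8)
})

test_that("slip-driven chamber flow makes a counter-rotating vortex pair", {
  expect_equal(vortex_sign_changes(flow, mesh), 2)
  # closed chamber: no net volumetric flux through any vertical section
  umax <- max(abs(c(flow$ux, flow$uy)))
  for (x0 in c(250e-6, 500e-6, 750e-6)) {
    expect_lt(abs(section_flux(flow, mesh, x0)), 1e-6 * umax * 200e-6)
  }
  # the jets rise over the gate center: upward velocity at midline
  ic <- which.min((mesh$nodes[, 1] - 500e-6)^2 + (mesh$nodes[, 2] - 30e-6)^2)
  expect_gt(flow$uy[ic], 0)
})

test_that("velocity traces match the boundary data", {
  wall <- tagged_nodes(mesh, "wall")
  expect_equal(max(abs(c(flow$ux[wall], flow$uy[wall]))), 0)
  gb <- iceobind:::slip_nodal_velocity(mesh, slip)
  inner <- setdiff(gb$nodes, wall)
  expect_equal(flow$ux[inner], gb$ux[match(inner, gb$nodes)], tolerance = 1e-12)
  expect_equal(flow$uy[inner], rep(0, length(inner)), tolerance = 1e-12)
})

test_that("discrete continuity is satisfied to solver precision", {
  umax <- max(abs(c(flow$ux, flow$uy)))
  expect_lt(flow$continuity_residual, 1e-8 * umax / 200e-6)
})

test_that("Stokes solution is exactly linear in the slip amplitude", {
  chk <- flow_linearity_check(mesh, slip, alpha = c(2, 0, -1))
  expect_true(all(chk$rel_error < 1e-10))
})

test_that("ICEO chamber flow and Poiseuille superpose", {
  mcf <- build_mesh(make_scenario("continuous_flow")$geometry, RES_COARSE)
  potc <- solve_potential_phasor(mcf, params, drive_signal(8, 10))
  slipc <- timeavg_slip(potc, mcf, params)
  fa <- solve_stokes(mcf, slipc, inlet_mean_velocity = 0, open_ends = TRUE)
  fb <- solve_stokes(mcf, zero_slip(mcf), inlet_mean_velocity = 50e-6)
  fab <- solve_stokes(mcf, slipc, inlet_mean_velocity = 50e-6)
  scale <- max(abs(c(fab$ux, fab$uy)))
  expect_lt(max(abs(fab$ux - fa$ux - fb$ux)), 1e-9 * scale)
  expect_lt(max(abs(fab$uy - fa$uy - fb$uy)), 1e-9 * scale)
  # at 8 V the slip-driven speed over the gate dwarfs the 50 um/s base flow
  expect_gt(max(abs(c(fa$ux, fa$uy))), 50e-6)
})

test_that("mismatched slip/mesh pairs are rejected", {
  m2 <- build_mesh(channel_geometry(), resolution = 2 * RES_COARSE)
  expect_error(solve_stokes(m2, slip), "does not match")
})
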