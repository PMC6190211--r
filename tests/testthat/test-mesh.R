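mesh_flat <- build_mesh(channel_geometry(), resolution = RES_COARSE)

test_that("boundary tags partition the boundary and sit where they should", {
  m <- mesh_flat
  tol <- 1e-12
  # every boundary facet carries exactly one tag (edge_tag is one per facet)
  expect_length(m$edge_tag, nrow(m$edges))
  expect_true(all(m$edge_tag %in% c("left_electrode", "right_electrode",
                                    "gate", "functionalized", "wall")))
  # tagged facets tile the full boundary: total tagged length = perimeter
  # ("gate" already includes its functionalized subset)
  g <- m$geometry
  perim <- 2 * (g$length + g$height)
  total <- sum(vapply(c("left_electrode", "right_electrode", "gate", "wall"),
                      function(tg) boundary_arclength(m, tg), 1))
  expect_equal(total, perim, tolerance = 1e-9)
  # gate occupies [475, 525] um on the bottom, functionalized its left half
  gsel <- m$edge_tag %in% c("gate", "functionalized")
  gx <- m$nodes[unique(as.vector(m$edges[gsel, ])), 1]
  expect_equal(range(gx), c(475e-6, 525e-6), tolerance = 1e-12)
  fsel <- m$edge_tag == "functionalized"
  fx <- m$nodes[unique(as.vector(m$edges[fsel, ])), 1]
  expect_equal(range(fx), c(475e-6, 500e-6), tolerance = 1e-12)
  # end walls are the driving electrodes
  lx <- m$nodes[tagged_nodes(m, "left_electrode"), 1]
  expect_true(all(lx == 0))
})

test_that("boundary arclengths match the geometry", {
  expect_equal(boundary_arclength(mesh_flat, "gate"), 50e-6, tolerance = 1e-12)
  expect_equal(boundary_arclength(mesh_flat, "functionalized"), 25e-6,
               tolerance = 1e-12)
  m5 <- build_mesh(channel_geometry(gate_height = 5e-6), RES_COARSE)
  expect_equal(boundary_arclength(m5, "gate"), 60e-6, tolerance = 1e-12)
  expect_error(boundary_arclength(mesh_flat, "porch"), "unknown tag")
})

test_that("raised gates grow sidewall facets; short gates collapse flat", {
  m5 <- build_mesh(channel_geometry(gate_height = 5e-6), RES_COARSE)
  expect_true(m5$raised)
  expect_setequal(unique(m5$gate$side), c(1L, 2L, 3L))
  # flat: 200 nm is below the collapse threshold
  expect_false(mesh_flat$raised)
  expect_setequal(unique(mesh_flat$gate$side), 2L)
})

test_that("element quality stays above the angle floor on all presets", {
  expect_gt(mesh_min_angle(mesh_flat), 15)
  for (hg in c(1e-6, 2e-6, 5e-6)) {
    m <- build_mesh(channel_geometry(gate_height = hg), RES_COARSE)
    expect_gt(mesh_min_angle(m), 15)
  }
  mcf <- build_mesh(make_scenario("continuous_flow")$geometry, RES_COARSE)
  expect_gt(mesh_min_angle(mcf), 15)
})

test_that("doubling the resolution at least doubles gate facet count", {
  m1 <- build_mesh(channel_geometry(), resolution = 1)
  n1 <- sum(m1$edge_tag %in% c("gate", "functionalized"))
  m2 <- build_mesh(channel_geometry(), resolution = 2)
  n2 <- sum(m2$edge_tag %in% c("gate", "functionalized"))
  expect_gte(n2, 2 * n1)
})

test_that("local element size at the gate corners is fine enough", {
  m <- build_mesh(channel_geometry(), resolution = 1)
  g <- m$geometry
  for (xe in g$gate_center_x + c(-1, 1) * g$gate_width / 2) {
    near <- abs(m$gate$s - (xe - (g$gate_center_x - g$gate_width / 2))) <
      2 * min(m$gate$length)
    expect_lte(min(m$gate$length[near]), g$gate_width / 20)
  }
  # corner facets at graded minimum ~ gate_width/25 at resolution 1; the
  # gate_width/50 target is met from resolution ~2.5 upward
  m2 <- build_mesh(channel_geometry(), resolution = 2.5)
  expect_lte(min(m2$gate$length), g$gate_width / 50)
})

test_that("degenerate geometries are rejected", {
  expect_error(channel_geometry(length = 0), "degenerate")
  expect_error(channel_geometry(height = -1), "degenerate")
  expect_error(build_mesh(channel_geometry(), resolution = 0), "resolution")
})

test_that("mesh round-trips through Gmsh export", {
  f <- withr::local_tempfile(fileext = ".msh")
  write_mesh_msh(mesh_flat, f)
  txt <- readLines(f)
  expect_true("$MeshFormat" %in% txt)
  n_declared <- as.integer(txt[which(txt == "$Nodes") + 1])
  expect_equal(n_declared, nrow(mesh_flat$nodes))
})
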