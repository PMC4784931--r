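# Pore mechanics: resting equilibration against the intrinsic pressure
# profile and the response to local bending.  Resting states are computed
# once per fixture and shared across the tests in this file.

ch <- closed_channel()
rests <- lapply(fixture_bilayers(), function(bl) equilibrate_resting(bl, ch))

test_that("zero pressure leaves the reference pore untouched", {
  bl <- make_bilayer("di-16:0")
  st <- equilibrate_resting(bl, ch, profile = zero_profile(bl))
  H2 <- ch$d_p_nm / 2 + bl$h_head_nm
  r0 <- pore_radius_ref(ch, st$mesh$nodes[st$mesh$node_id[, 1], 2], H2)
  expect_lt(max(abs(st$pore$r_nm - r0)), 1e-9)
  expect_equal(constriction_radius(st$pore), ch$pore_constriction_radius_nm,
               tolerance = 1e-9)
})

test_that("resting equilibration narrows the hydrophobic constriction", {
  r_ref <- ch$pore_constriction_radius_nm
  gates <- vapply(rests, function(st) gate_radius(st$pore), 0)
  # thin-bilayer tail pressure squeezes the lock
  expect_lt(gates[["di-10:0"]], r_ref)
  expect_lt(gates[["di-16:0"]], r_ref)
  # thickest bilayer (flattest profile) deforms the channel least
  dev <- abs(gates - r_ref)
  expect_lt(dev[["di-24:1"]], dev[["di-10:0"]])
  expect_lt(dev[["di-24:1"]], dev[["di-16:0"]])
  # pore widens away from the core (headgroup/interfacial pull)
  st <- rests[["di-10:0"]]
  wall <- st$mesh$node_id[, 1]
  top <- which.max(st$mesh$nodes[wall, 2])
  H2 <- ch$d_p_nm / 2 + st$bilayer$h_head_nm
  expect_gt(st$pore$r_nm[top],
            pore_radius_ref(ch, st$mesh$nodes[wall[top], 2], H2))
})

test_that("inward bending opens the lock, outward bending closes it, oddly", {
  for (lb in fixture_labels) {
    bin <- bend_and_extract(NULL, NULL, -0.04, resting = rests[[lb]])
    bout <- bend_and_extract(NULL, NULL, +0.04, resting = rests[[lb]])
    expect_gt(bin$delta_r_constriction_nm, 0)
    expect_lt(bout$delta_r_constriction_nm, 0)
    expect_lt(abs(bin$delta_r_constriction_nm + bout$delta_r_constriction_nm),
              1e-10)
    expect_true(all(bin$pore$r_nm > 0))
  }
  b0 <- bend_and_extract(NULL, NULL, 0, resting = rests[["di-16:0"]])
  expect_equal(b0$delta_r_constriction_nm, 0)
})

test_that("thicker bilayers transmit more opening than thinner ones", {
  dr <- vapply(fixture_labels, function(lb)
    bend_and_extract(NULL, NULL, -0.04, resting = rests[[lb]])$delta_r_constriction_nm, 0)
  # the flexural-transmission leg of the mismatch comparison: negative
  # mismatch (thick) opens the lock more than positive mismatch (thin)
  expect_gt(dr[["di-24:1"]], dr[["di-10:0"]])
  expect_gt(dr[["di-16:0"]], dr[["di-10:0"]])
})

test_that("pore response converges with mesh refinement", {
  bl <- make_bilayer("di-16:0")
  dr <- vapply(c(0.5, 0.25), function(h) {
    st <- equilibrate_resting(bl, ch, h_target_nm = h)
    bend_and_extract(NULL, NULL, -0.04, resting = st)$delta_r_constriction_nm
  }, 0)
  expect_lt(abs(dr[2] - dr[1]) / abs(dr[2]), 0.1)
})

test_that("leaflet area difference vanishes flat, flips with direction, and
           matches the shallow-cap closed form on a homogeneous plate", {
  # an undeformed membrane has congruent leaflets
  bl16 <- make_bilayer("di-16:0")
  st0 <- equilibrate_resting(bl16, ch, profile = zero_profile(bl16))
  expect_equal(leaflet_area_difference(st0$field, st0$mesh), 0)
  st <- rests[["di-16:0"]]
  bin <- bend_and_extract(NULL, NULL, -0.04, resting = st)
  bout <- bend_and_extract(NULL, NULL, +0.04, resting = st)
  b0 <- bend_and_extract(NULL, NULL, 0, resting = st)
  expect_equal(b0$area_difference_A2, 0)
  expect_lt(bin$area_difference_A2, 0)     # inward shrinks the outer leaflet
  expect_gt(bout$area_difference_A2, 0)
  # odd to leading order (the area functional is quadratic in the field,
  # so the antisymmetry is exact only in the linearised limit)
  expect_equal(bin$area_difference_A2, -bout$area_difference_A2,
               tolerance = 1e-3)
  # homogeneous plate oracle: dA ~ 2 C s A over the lipid annulus
  geom <- st$geom; mesh <- st$mesh
  mats <- material_map(geom); mats$protein <- mats$core
  ld <- impose_curvature(load_case(mesh), mesh, 0.04)
  u <- solve_equilibrium(mesh, mats, ld)
  s <- st$bilayer$t_nm + st$bilayer$h_head_nm
  A <- pi * (geom$R_out_nm^2 - geom$R_wall_nm^2)
  expect_equal(leaflet_area_difference(u, mesh), 2 * 0.04 * s * A * 100,
               tolerance = 0.05)
})

test_that("fields and pore profiles export to VTK and CSV", {
  st <- rests[["di-10:0"]]
  vtk <- withr::local_tempfile(fileext = ".vtk")
  write_vtk_field(st$field, vtk, st$mesh)
  head <- readLines(vtk, n = 5)
  expect_identical(head[1], "# vtk DataFile Version 3.0")
  expect_match(head[5], "^POINTS [0-9]+ double$")
  expect_true(any(grepl("VECTORS displacement double", readLines(vtk), fixed = TRUE)))
  csv <- withr::local_tempfile(fileext = ".csv")
  write_pore_csv(st$pore, csv)
  back <- utils::read.csv(csv)
  expect_equal(back$r_nm, st$pore$r_nm)
})
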