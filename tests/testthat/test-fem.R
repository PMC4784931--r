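# Analytic solver benchmarks: patch test, thick-walled cylinder, linearity.

test_that("zero load produces zero displacement", {
  m <- annulus_mesh(1, 5, 0, 1, 4, 2)
  ld <- load_case(m)
  ld <- add_dirichlet(ld, m$node_id[, 1], 1:2, 0)
  u <- solve_equilibrium(m, list(plate = list(E = 1e7, nu = 0.3)), ld)
  expect_equal(max(abs(u)), 0)
})

test_that("patch test: uniform strain is reproduced exactly", {
  m <- annulus_mesh(1, 5, 0, 1, 6, 3)
  eps_r <- 1e-3; eps_z <- -2e-3
  bnd <- which(m$nodes[, 1] %in% range(m$nodes[, 1]) |
               m$nodes[, 2] %in% range(m$nodes[, 2]))
  ld <- load_case(m)
  ld <- add_dirichlet(ld, bnd, 1L, eps_r * m$nodes[bnd, 1])
  ld <- add_dirichlet(ld, bnd, 2L, eps_z * m$nodes[bnd, 2])
  u <- solve_equilibrium(m, list(plate = list(E = 1e7, nu = 0.3)), ld)
  err <- max(abs(u[, 1] - eps_r * m$nodes[, 1]),
             abs(u[, 2] - eps_z * m$nodes[, 2]))
  expect_lt(err, 1e-9 * max(abs(eps_r) * m$nodes[, 1]))
})

test_that("Lame thick-walled cylinder converges below 1% at fine mesh", {
  errs <- vapply(c(5, 10, 20, 40), lame_error, 0)
  expect_lt(errs[4], 0.01)          # h = 0.1 nm
  expect_true(all(diff(errs) < 0))  # monotone convergence under refinement
})

test_that("solutions superpose to solver tolerance", {
  m <- annulus_mesh(2, 6, 0, 1, 10, 4)
  mats <- list(plate = list(E = 1e7, nu = 0.45))
  clamp <- function(ld) add_dirichlet(ld, m$node_id[, m$n_col], 1:2, 0)
  ld1 <- clamp(add_edge_pressure(load_case(m), m, m$node_id[, 1], 2e5))
  ld2 <- clamp(load_case(m))
  ld2$sigma_fns <- list(function(r, z, region) -3e5 + 0 * r)
  ld12 <- clamp(add_edge_pressure(load_case(m), m, m$node_id[, 1], 2e5))
  ld12$sigma_fns <- ld2$sigma_fns
  ctx <- fe_context(m, mats, ld1)
  u1 <- solve_equilibrium(m, mats, ld1, ctx)
  u2 <- solve_equilibrium(m, mats, ld2, ctx)
  u12 <- solve_equilibrium(m, mats, ld12, ctx)
  expect_lt(max(abs(u12 - (u1 + u2))), 1e-10 * max(abs(u12)))
})

test_that("near-incompressible materials do not lock", {
  # selective reduced integration keeps the Lame benchmark accurate at nu -> 0.5
  err <- lame_error(20, nu = 0.499)
  expect_lt(err, 0.02)
})

test_that("unconstrained systems are rejected with a diagnostic", {
  m <- annulus_mesh(1, 5, 0, 1, 4, 2)
  ld <- add_edge_pressure(load_case(m), m, m$node_id[, 1], 1e5)
  expect_error(solve_equilibrium(m, list(plate = list(E = 1e7, nu = 0.3)), ld),
               class = "mscbend_singular_system")
})

test_that("imposed spherical curvature reproduces plate bending", {
  # mirror symmetry: C and -C give opposite displacement fields on a
  # homogeneous laminate (no protein contrast)
  geom <- build_geometry(make_bilayer("di-16:0"), closed_channel())
  mesh <- generate_mesh(geom, 0.35)
  mats <- material_map(geom)
  mats$protein <- mats$core
  mk <- function(C) impose_curvature(load_case(mesh), mesh, C)
  ctx <- fe_context(mesh, mats, mk(0))
  up <- solve_equilibrium(mesh, mats, mk(0.04), ctx)
  um <- solve_equilibrium(mesh, mats, mk(-0.04), ctx)
  expect_lt(max(abs(up + um)), 1e-9 * max(abs(up)))
  # achieved midplane curvature matches the imposed sphere 1/C within 10%
  mid <- mesh$node_id[mesh$n_h + mesh$n_c / 2 + 1L, (mesh$n_pr + 2):mesh$n_col]
  r <- mesh$nodes[mid, 1]; w <- up[mid, 2]
  fit <- stats::lm(w ~ I(r^2))
  expect_equal(-2 * unname(stats::coef(fit)[2]), 0.04, tolerance = 0.1)
  expect_warning(impose_curvature(load_case(mesh), mesh, 0.2),
                 class = "mscbend_curvature_warning")
})
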