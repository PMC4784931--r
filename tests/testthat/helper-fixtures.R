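# Shared fixtures for the test suite.  Everything is generated in code.

fixture_labels <- c("di-10:0", "di-16:0", "di-24:1")

fixture_bilayers <- function() {
  bls <- lapply(fixture_labels, make_bilayer)
  names(bls) <- fixture_labels
  bls
}

closed_channel <- function() make_channel("closed")

# A hand-built piecewise-constant profile, independent of the package's
# calibration: P = +c on [-a, 0), zero elsewhere.
rectangle_profile <- function(c_Pa, a_nm) {
  structure(list(
    z_breaks_nm = c(-a_nm, 0, a_nm),
    P_Pa = c(c_Pa, 0),
    provenance = "intrinsic",
    C_L_per_nm = 0,
    spec = NULL
  ), class = "pressure_profile")
}

# Zero-pressure variant of a bilayer's profile (same bands, P = 0).
zero_profile <- function(bilayer) {
  pr <- build_pressure_profile(bilayer)
  pr$P_Pa[] <- 0
  pr
}

# Plane-strain thick-walled cylinder: analytic radial displacement under
# internal pressure p, outer boundary free.
lame_solution <- function(r, a, b, p, E, nu) {
  p * a^2 / (E * (b^2 - a^2)) * ((1 + nu) * (1 - 2 * nu) * r + (1 + nu) * b^2 / r)
}

# Relative error of the FE Lame benchmark at nr radial elements.
lame_error <- function(nr, a = 2, b = 6, p = 1e5, E = 1e7, nu = 0.3) {
  m <- annulus_mesh(a, b, 0, 0.5, nr, 2)
  ld <- load_case(m)
  ld <- add_dirichlet(ld, seq_len(nrow(m$nodes)), 2L, 0)
  ld <- add_edge_pressure(ld, m, m$node_id[, 1], p)
  u <- solve_equilibrium(m, list(plate = list(E = E, nu = nu)), ld)
  ua <- lame_solution(m$nodes[, 1], a, b, p, E, nu)
  max(abs(u[, 1] - ua)) / max(abs(ua))
}
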