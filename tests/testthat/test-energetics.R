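# Frozen expected values below were computed by independent unit-tracked
# closed-form evaluation (SI throughout) before the implementation:
#   G_H = 2 (K_A^3 K_B / t^6)^(1/4) u0^2 2 pi R_ave
#       = 2 * 1.1805e8 J/m^3 * (4.5e-10 m)^2 * 2 pi * 2.5e-9 m = 7.509e-19 J
#   G_B = K/2 (C_L - C_P)^2, K = K_B pi R_ave^2 = 1.669e-36 J m^2 -> 1.335e-21 J
#   W   = K_B A_0 / (2 R^2) = 0.85e-19 * 1256 / 1250 = 8.541e-20 J

test_that("mismatch energy reproduces the closed-form worked example", {
  G_H <- mismatch_energy(0.24, 0.85e-19, 1.35, 2.7, 1.8, 2.5)
  expect_equal(G_H, 7.509092e-19, tolerance = 1e-6)
  expect_equal(G_H / kBT_298(), 182.5, tolerance = 1e-3)
})

test_that("mismatch energy vanishes only at zero mismatch and is even", {
  expect_identical(mismatch_energy(0.24, 0.85e-19, 1.35, 2.7, 2.7, 2.5), 0)
  up <- mismatch_energy(0.24, 0.85e-19, 1.35, 2.7 + 0.9, 2.7, 2.5)
  dn <- mismatch_energy(0.24, 0.85e-19, 1.35, 2.7 - 0.9, 2.7, 2.5)
  expect_equal(up, dn)
  expect_gt(up, 0)
  expect_error(mismatch_energy(-0.24, 0.85e-19, 1.35, 2.7, 1.8, 2.5),
               class = "mscbend_invalid_scenario")
})

test_that("bending energy reproduces the worked example and its limits", {
  K <- 0.85e-19 * pi * 2.5^2
  expect_equal(bending_energy(K, K, curvature_state(0.04), 0), 1.335177e-21,
               tolerance = 1e-6)
  expect_identical(bending_energy(K, K, curvature_state(0.04), 0.04), 0)
  # anisotropic term cancels when the protein deviator matches the membrane's
  st <- curvature_state(0.06, 0.02, theta_rad = 0)   # C_L* = 0.02
  expect_equal(bending_energy(K, K, st, C_P_per_nm = 0.04, C_P_star_per_nm = 0.02),
               0)
  # spherical + isotropic reduces to the pure quadratic
  st_sph <- curvature_state(0.03)
  expect_equal(bending_energy(K, 5 * K, st_sph, 0.01),
               K / 2 * (0.03 - 0.01)^2)
})

test_that("bending modulus thickness scaling behaves algebraically", {
  expect_identical(bending_modulus_from_thickness(1.35, 0.85e-19, 1.35), 0.85e-19)
  expect_equal(bending_modulus_from_thickness(1, 1e-19, 2, exponent = 3), 8e-19)
  expect_equal(bending_modulus_from_thickness(1, 1e-19, 2, exponent = 2), 4e-19)
  expect_error(bending_modulus_from_thickness(1, 1e-19, 2, exponent = 4),
               class = "mscbend_invalid_scenario")
  # with K_B ~ t^3 the mismatch prefactor scales exactly as t^(-3/4)
  pref <- function(t_nm) {
    K_B <- bending_modulus_from_thickness(1.35, 0.85e-19, t_nm)
    (0.24^3 * K_B / (t_nm * 1e-9)^6)^(1 / 4)
  }
  expect_equal(pref(1.8) / pref(0.9), (1.8 / 0.9)^(-3 / 4))
  expect_true(all(diff(vapply(c(0.9, 1.35, 1.8), pref, 0)) < 0))
})

test_that("total energy is the exact sum of its parts", {
  bl <- make_bilayer("di-24:1"); ch <- closed_channel()
  br <- total_energy(bl, ch, curvature_state(-0.04))
  expect_identical(br$G_J, br$G_H_J + br$G_B_J)
  expect_equal(br$G_kBT, br$G_J / kBT_298())
  expect_equal(br$K_J_nm2, bl$K_B_J * pi * ch$R_ave_nm^2)
  expect_identical(br$K_prime_J_nm2, br$K_J_nm2)   # K'/K = 1
  # zero mismatch + curvature at the protein's intrinsic value -> G = 0
  br0 <- total_energy(make_bilayer("di-16:0"), ch, curvature_state(ch$C_P_per_nm))
  expect_identical(br0$G_J, 0)
})

test_that("energy landscape is minimal at C_P and ordered by mismatch", {
  bls <- fixture_bilayers(); ch <- closed_channel()
  ls <- energy_landscape(bls, ch)
  am <- landscape_argmin(ls)
  expect_equal(am$C_L_argmin_per_nm, rep(ch$C_P_per_nm, 3))
  g <- split(ls, ls$acyl_label)
  off <- g[["di-16:0"]]$C_L_per_nm != ch$C_P_per_nm
  expect_true(all(g[["di-16:0"]]$G_J[off] < g[["di-24:1"]]$G_J[off]))
  expect_true(all(g[["di-24:1"]]$G_J < g[["di-10:0"]]$G_J))
  # parabolic symmetry about the minimum
  for (df in g) {
    expect_equal(df$G_J, rev(df$G_J))
    expect_true(all(df$G_H_J >= 0) && all(df$G_B_J >= 0))
  }
})

test_that("bending work follows K_B A0 / (2 R^2)", {
  w <- bending_work(0.85e-19, 1256, 25)
  expect_equal(w$W_J, 8.5408e-20, tolerance = 1e-6)
  expect_equal(bending_work(0.85e-19, 1256, 50)$W_J, w$W_J / 4)
  expect_equal(bending_work(0.85e-19, 2 * 1256, 25)$W_J, 2 * w$W_J)
  expect_equal(bending_work(2 * 0.85e-19, 1256, 25)$W_J, 2 * w$W_J)
  expect_lt(bending_work(0.85e-19, 1256, 1e6)$W_J, 1e-28)
  # thicker fixtures absorb more work at equal target curvature
  Ws <- vapply(fixture_bilayers(), function(bl) bending_work(bl$K_B_J, 1256, 25)$W_J, 0)
  expect_true(Ws[["di-24:1"]] > Ws[["di-16:0"]] && Ws[["di-16:0"]] > Ws[["di-10:0"]])
})
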