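test_that("bilayer fixtures carry the study geometry", {
  bls <- fixture_bilayers()
  expect_equal(vapply(bls, `[[`, 0, "d_l_nm"), c("di-10:0" = 1.8, "di-16:0" = 2.7,
                                                 "di-24:1" = 3.6))
  for (bl in bls) {
    expect_identical(bl$t_nm, bl$d_l_nm / 2)
    expect_gt(bl$h_head_nm, 0)
    expect_gt(bl$K_A_N_per_m, 0)
    expect_gt(bl$K_B_J, 0)
  }
  # mismatch signs against the closed channel's hydrophobic length
  ch <- closed_channel()
  expect_lt(bls[["di-10:0"]]$d_l_nm, ch$d_p_nm)   # positive mismatch
  expect_identical(bls[["di-16:0"]]$d_l_nm, ch$d_p_nm)
  expect_gt(bls[["di-24:1"]]$d_l_nm, ch$d_p_nm)   # negative mismatch
  # K_B scales with t^3 across the fixtures
  expect_equal(bls[["di-24:1"]]$K_B_J / bls[["di-16:0"]]$K_B_J, (1.8 / 1.35)^3)
})

test_that("unknown or invalid bilayer specifications are rejected", {
  expect_error(make_bilayer("di-48:0"), class = "mscbend_invalid_scenario")
  expect_error(bilayer_spec(d_l_nm = -1), class = "mscbend_invalid_scenario")
  expect_error(bilayer_spec(d_l_nm = 2.7, K_A_N_per_m = 0),
               class = "mscbend_invalid_scenario")
})

test_that("intrinsic profiles are tension-free, symmetric, three-regime", {
  peaks <- numeric(0)
  for (bl in fixture_bilayers()) {
    pr <- build_pressure_profile(bl)
    thick <- diff(range(pr$z_breaks_nm))
    net <- leaflet_tension(pr, "inner") + leaflet_tension(pr, "outer")
    expect_lt(abs(net), 1e-12 * max(abs(pr$P_Pa)) * thick * 1e-9)
    # mirror symmetry about the midplane
    z <- seq(min(pr$z_breaks_nm) + 1e-6, max(pr$z_breaks_nm) - 1e-6, length.out = 301)
    expect_equal(profile_pressure_at(pr, z), profile_pressure_at(pr, -z))
    # headgroup repulsion > 0, interfacial < 0, tail repulsion > 0
    t <- bl$t_nm; h <- bl$h_head_nm
    expect_gt(profile_pressure_at(pr, t + h / 2), 0)
    expect_lt(profile_pressure_at(pr, t - 0.01), 0)
    expect_gt(profile_pressure_at(pr, 0), 0)
    peaks <- c(peaks, max(abs(pr$P_Pa)))
  }
  # thicker bilayers have flatter profiles
  expect_true(peaks[1] > peaks[2] && peaks[2] > peaks[3])
})

test_that("leaflet tension is the exact band integral", {
  # rectangle oracle: P = +c over [-a, 0) gives gamma_inner = c * a
  c_Pa <- 3e7; a_nm <- 1.2
  pr <- rectangle_profile(c_Pa, a_nm)
  expect_equal(leaflet_tension(pr, "inner"), c_Pa * a_nm * 1e-9)
  expect_equal(leaflet_tension(pr, "outer"), 0)
  # intrinsic symmetric profile: equal leaflet tensions
  pr16 <- build_pressure_profile(make_bilayer("di-16:0"))
  expect_equal(leaflet_tension(pr16, "inner"), leaflet_tension(pr16, "outer"))
})

test_that("bending skews leaflet tensions oddly and monotonically", {
  for (bl in fixture_bilayers()) {
    pr <- build_pressure_profile(bl)
    dgamma <- function(C) {
      b <- suppressWarnings(apply_bending_to_profile(pr, C, bl))
      leaflet_tension(b, "inner") - leaflet_tension(b, "outer")
    }
    expect_identical(apply_bending_to_profile(pr, 0, bl), pr)
    expect_gt(dgamma(-0.04), 0)            # inward: inner leaflet tension higher
    expect_lt(dgamma(0.04), 0)             # outward: outer higher
    # oddness and monotone decrease over the valid strain range
    Cs <- seq(-0.08, 0.08, by = 0.01)
    d <- vapply(Cs, dgamma, 0)
    expect_equal(d, -rev(d))
    expect_true(all(diff(d) < 0))
  }
})

test_that("excessive bending strain warns instead of failing", {
  bl <- make_bilayer("di-16:0")
  pr <- build_pressure_profile(bl)
  expect_warning(apply_bending_to_profile(pr, 0.15, bl),
                 class = "mscbend_strain_warning")
})

test_that("profiles round-trip through CSV", {
  pr <- build_pressure_profile(make_bilayer("di-10:0"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_profile_csv(pr, path)
  back <- read_profile_csv(path)
  expect_equal(back$z_breaks_nm, pr$z_breaks_nm)
  expect_equal(back$P_Pa, pr$P_Pa)
  bad <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(a = 1), bad, row.names = FALSE)
  expect_error(read_profile_csv(bad), class = "mscbend_schema_error")
})
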