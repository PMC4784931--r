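test_that("the default scenario set is the 3 x 3 study design", {
  sc <- default_scenarios()
  expect_length(sc, 9)
  C <- vapply(sc, function(s) s$curvature$C_L_per_nm, 0)
  expect_true(all(abs(C) %in% c(0, 0.04)))
  expect_setequal(unique(vapply(sc, function(s) s$bilayer$acyl_label, "")),
                  fixture_labels)
  z16 <- sc[["di-16:0_resting"]]
  expect_identical(z16$bilayer$d_l_nm, z16$channel$d_p_nm)  # zero mismatch
  # purity
  expect_identical(default_scenarios(), sc)
})

test_that("scenarios round-trip losslessly through YAML", {
  sc <- default_scenarios()[["di-24:1_inward"]]
  sc$amphipath <- amphipath_spec("LPC", leaflet = "inner")
  path <- withr::local_tempfile(fileext = ".yaml")
  write_scenario(sc, path)
  back <- read_scenario(path)
  expect_equal(back$bilayer, sc$bilayer, tolerance = 1e-12)
  expect_equal(back$channel, sc$channel, tolerance = 1e-12)
  expect_equal(back$curvature, sc$curvature, tolerance = 1e-12)
  expect_equal(back$solver, sc$solver, tolerance = 1e-12)
  expect_identical(back$amphipath$name, "LPC")
  expect_identical(back$id, sc$id)
})

test_that("schema violations are reported naming the offending field", {
  sc <- default_scenarios()[[1]]
  path <- withr::local_tempfile(fileext = ".yaml")
  write_scenario(sc, path)
  y <- yaml::read_yaml(path)
  y$bilayer$K_A_N_per_m <- NULL
  yaml::write_yaml(y, path)
  err <- tryCatch(read_scenario(path), condition = identity)
  expect_s3_class(err, "mscbend_schema_error")
  expect_match(conditionMessage(err), "K_A_N_per_m")
  # invariant violations surface from the constructors
  y2 <- yaml::read_yaml(path)
  y2$bilayer$K_A_N_per_m <- 0.24
  y2$bilayer$d_l_nm <- -2
  yaml::write_yaml(y2, path)
  expect_error(read_scenario(path), class = "mscbend_invalid_scenario")
})

test_that("the shipped example scenario files load and match the defaults", {
  dir <- system.file("extdata", "scenarios", package = "mscbend")
  files <- list.files(dir, pattern = "\\.yaml$", full.names = TRUE)
  expect_length(files, 9)
  sc <- default_scenarios()
  for (f in files) {
    s <- read_scenario(f)
    expect_equal(s$bilayer, sc[[s$id]]$bilayer, tolerance = 1e-9)
    expect_equal(s$curvature, sc[[s$id]]$curvature, tolerance = 1e-9)
  }
})

test_that("perturbation is deterministic, bounded and invariant-preserving", {
  base <- default_scenarios()[["di-16:0_inward"]]
  expect_identical(perturb_scenario(base, 7, cv = 0), base)
  p1 <- perturb_scenario(base, 7, cv = 0.05)
  p2 <- perturb_scenario(base, 7, cv = 0.05)
  expect_equal(p1$bilayer, p2$bilayer)
  p3 <- perturb_scenario(base, 8, cv = 0.05)
  expect_false(identical(p1$bilayer$d_l_nm, p3$bilayer$d_l_nm))
  expect_error(perturb_scenario(base, 7, cv = 0.5),
               class = "mscbend_invalid_scenario")
  # perturbed parameters stay positive and within plausible lognormal range
  facs <- replicate(25, {
    p <- perturb_scenario(base, sample.int(1e6, 1), cv = 0.05)
    p$bilayer$d_l_nm / base$bilayer$d_l_nm
  })
  expect_true(all(facs > 0.7 & facs < 1.4))
  # the global RNG stream is not disturbed
  set.seed(123); before <- runif(3)
  set.seed(123); invisible(perturb_scenario(base, 99, cv = 0.05))
  expect_identical(runif(3), before)
})
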