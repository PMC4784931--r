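# Scenario fixtures: self-contained parameter sets describing one
# bilayer/channel/curvature case, serialisable to YAML with explicit units
# in every field name so the pipeline is testable without any downloads.

#' Construct a scenario
#'
#' @param id scenario identifier.
#' @param bilayer a [bilayer_spec()].
#' @param channel a [channel_spec()].
#' @param curvature a [curvature_state()].
#' @param amphipath optional [amphipath_spec()].
#' @param R_out_nm,lambda_nm,h_target_nm solver settings.
#' @param rng_seed integer seed attached to the scenario.
#' @return An object of class `scenario`.
#' @export
scenario <- function(id, bilayer, channel, curvature, amphipath = NULL,
                     R_out_nm = 20, lambda_nm = 2, h_target_nm = 0.25,
                     rng_seed = 1L) {
  stopifnot(inherits(bilayer, "bilayer_spec"), inherits(channel, "channel_spec"),
            inherits(curvature, "curvature_state"))
  if (!is.null(amphipath)) stopifnot(inherits(amphipath, "amphipath_spec"))
  structure(list(
    id = as.character(id), bilayer = bilayer, channel = channel,
    curvature = curvature, amphipath = amphipath,
    solver = list(R_out_nm = R_out_nm, lambda_nm = lambda_nm,
                  h_target_nm = h_target_nm),
    rng_seed = as.integer(rng_seed)
  ), class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf("Scenario '%s': %s bilayer, %s channel, C_L = %+.3g 1/nm\n",
              x$id, x$bilayer$acyl_label, x$channel$state,
              x$curvature$C_L_per_nm))
  invisible(x)
}

#' The nine default study scenarios
#'
#' The 3 x 3 design of the study: three bilayers (di-10:0, di-16:0,
#' di-24:1 — positive, zero and negative mismatch against the closed
#' channel) each at rest, under inward spherical bending
#' (`C_L = -0.04` 1/nm) and under outward bending (`+0.04` 1/nm).  Pure:
#' returns the same list on every call.
#'
#' @return A list of 9 [scenario()] objects.
#' @export
default_scenarios <- function() {
  labels <- c("di-10:0", "di-16:0", "di-24:1")
  loads <- c(resting = 0, inward = -0.04, outward = 0.04)
  ch <- make_channel("closed")
  out <- list()
  for (lb in labels) for (ln in names(loads)) {
    id <- paste0(lb, "_", ln)
    out[[id]] <- scenario(id, make_bilayer(lb), ch,
                          curvature_state(loads[[ln]]))
  }
  out
}

# Fields perturbed by perturb_scenario(): strictly positive continuous
# physical parameters.  Signed quantities (curvatures, the constriction
# z-position) are left untouched.
.PERTURB_FIELDS <- list(
  bilayer = c("d_l_nm", "h_head_nm", "K_A_N_per_m", "K_B_J"),
  channel = c("d_p_nm", "R_ave_nm", "pore_outer_radius_nm",
              "pore_constriction_radius_nm", "E_Pa")
)

with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Perturb a scenario's physical parameters
#'
#' Multiplies each strictly positive continuous parameter by an independent
#' lognormal factor with unit mean and the requested coefficient of
#' variation.  Deterministic given the seed; invariants are re-validated by
#' rebuilding the component specs, with bounded resampling on violation.
#'
#' @param scn a [scenario()].
#' @param rng_seed integer seed.
#' @param cv relative standard deviation of the lognormal factors, in
#'   `[0, 0.2]`.
#' @return A perturbed `scenario` (id suffixed with the seed).
#' @export
perturb_scenario <- function(scn, rng_seed, cv = 0.05) {
  stopifnot(inherits(scn, "scenario"))
  if (cv < 0 || cv > 0.2)
    stop_invalid("perturbation cv must lie in [0, 0.2]")
  if (cv == 0) return(scn)
  sdlog <- sqrt(log(1 + cv^2))
  n_fac <- sum(lengths(.PERTURB_FIELDS))
  with_seed(rng_seed, {
    for (try in 1:10) {
      fac <- stats::rlnorm(n_fac, meanlog = -sdlog^2 / 2, sdlog = sdlog)
      k <- 0
      bl <- scn$bilayer; chn <- scn$channel
      for (f in .PERTURB_FIELDS$bilayer) { k <- k + 1; bl[[f]] <- bl[[f]] * fac[k] }
      for (f in .PERTURB_FIELDS$channel) { k <- k + 1; chn[[f]] <- chn[[f]] * fac[k] }
      ok <- tryCatch({
        bl2 <- bilayer_spec(bl$acyl_label, d_l_nm = bl$d_l_nm, h_head_nm = bl$h_head_nm,
                            K_A_N_per_m = bl$K_A_N_per_m, K_B_J = bl$K_B_J)
        ch2 <- channel_spec(chn$state, d_p_nm = chn$d_p_nm, R_ave_nm = chn$R_ave_nm,
                            pore_outer_radius_nm = chn$pore_outer_radius_nm,
                            pore_constriction_radius_nm = chn$pore_constriction_radius_nm,
                            constriction_z_nm = chn$constriction_z_nm,
                            taper_exponent = chn$taper_exponent,
                            wall_radius_nm = chn$wall_radius_nm,
                            E_Pa = chn$E_Pa, nu = chn$nu,
                            C_P_per_nm = chn$C_P_per_nm,
                            C_P_star_per_nm = chn$C_P_star_per_nm)
        TRUE
      }, mscbend_error = function(e) FALSE)
      if (ok)
        return(scenario(paste0(scn$id, "_seed", rng_seed), bl2, ch2,
                        scn$curvature, scn$amphipath,
                        scn$solver$R_out_nm, scn$solver$lambda_nm,
                        scn$solver$h_target_nm, rng_seed))
    }
    stop_invalid("perturbation repeatedly violated scenario invariants")
  })
}

# Scenario (de)serialisation -------------------------------------------------

.SCENARIO_SCHEMA <- list(
  bilayer = c("acyl_label", "d_l_nm", "h_head_nm", "K_A_N_per_m", "K_B_J"),
  channel = c("state", "d_p_nm", "R_ave_nm", "pore_outer_radius_nm",
              "pore_constriction_radius_nm", "constriction_z_nm",
              "taper_exponent", "wall_radius_nm", "E_Pa", "nu",
              "C_P_per_nm", "C_P_star_per_nm"),
  curvature = c("C1_per_nm", "C2_per_nm", "theta_rad"),
  solver = c("R_out_nm", "lambda_nm", "h_target_nm")
)

#' Write a scenario to a YAML file
#'
#' Field names carry explicit units (`d_l_nm`, `K_A_N_per_m`, ...); the
#' round trip through [read_scenario()] is lossless to 15 significant
#' digits.
#'
#' @param scn a [scenario()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_scenario <- function(scn, path) {
  stopifnot(inherits(scn, "scenario"))
  x <- list(
    id = scn$id,
    bilayer = unclass(scn$bilayer)[.SCENARIO_SCHEMA$bilayer],
    channel = unclass(scn$channel)[.SCENARIO_SCHEMA$channel],
    curvature = unclass(scn$curvature)[.SCENARIO_SCHEMA$curvature],
    solver = scn$solver,
    rng_seed = scn$rng_seed
  )
  if (!is.null(scn$amphipath))
    x$amphipath <- unclass(scn$amphipath)[c("name", "a_mol_A2", "leaflet")]
  writeLines(yaml::as.yaml(x, precision = 15), path)
  invisible(path)
}

#' Read a scenario from a YAML file
#'
#' Schema-validated: a missing or non-numeric field raises a
#' `mscbend_schema_error` naming the offending field; invariant violations
#' (e.g. a negative thickness) surface as `mscbend_invalid_scenario`
#' conditions from the component constructors.
#'
#' @param path YAML file written by [write_scenario()].
#' @return A [scenario()].
#' @export
read_scenario <- function(path) {
  x <- yaml::read_yaml(path)
  for (block in names(.SCENARIO_SCHEMA)) {
    if (is.null(x[[block]]))
      stop_invalid(sprintf("scenario file missing block '%s'", block),
                   class = "mscbend_schema_error")
    for (f in .SCENARIO_SCHEMA[[block]]) {
      v <- x[[block]][[f]]
      if (is.null(v))
        stop_invalid(sprintf("scenario file missing field '%s' in block '%s'", f, block),
                     class = "mscbend_schema_error")
      if (!f %in% c("acyl_label", "state") && !is.numeric(v))
        stop_invalid(sprintf("scenario field '%s' must be numeric", f),
                     class = "mscbend_schema_error")
    }
  }
  bl <- x$bilayer
  bilayer <- bilayer_spec(bl$acyl_label, d_l_nm = bl$d_l_nm,
                          h_head_nm = bl$h_head_nm,
                          K_A_N_per_m = bl$K_A_N_per_m, K_B_J = bl$K_B_J)
  chn <- x$channel
  channel <- channel_spec(chn$state, d_p_nm = chn$d_p_nm, R_ave_nm = chn$R_ave_nm,
                          pore_outer_radius_nm = chn$pore_outer_radius_nm,
                          pore_constriction_radius_nm = chn$pore_constriction_radius_nm,
                          constriction_z_nm = chn$constriction_z_nm,
                          taper_exponent = chn$taper_exponent,
                          wall_radius_nm = chn$wall_radius_nm,
                          E_Pa = chn$E_Pa, nu = chn$nu,
                          C_P_per_nm = chn$C_P_per_nm,
                          C_P_star_per_nm = chn$C_P_star_per_nm)
  curv <- curvature_state(x$curvature$C1_per_nm, x$curvature$C2_per_nm,
                          x$curvature$theta_rad)
  amph <- if (!is.null(x$amphipath))
    amphipath_spec(x$amphipath$name, x$amphipath$a_mol_A2, x$amphipath$leaflet)
  scenario(x$id %||% "unnamed", bilayer, channel, curv, amph,
           x$solver$R_out_nm, x$solver$lambda_nm, x$solver$h_target_nm,
           x$rng_seed %||% 1L)
}
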