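# Channel (MscL) representative-volume-element specification.
#
# The protein is a continuum annulus with effective elastic constants
# (E = 40 MPa, nu = 0.5 in the reference parameterisation).  Its inner
# boundary is an hourglass-shaped pore with a narrow hydrophobic
# constriction on the cytoplasmic side (the L19/V23 hydrophobic lock);
# the outer boundary is a cylinder bonded to the annular lipid.

#' Construct a channel specification
#'
#' @param state `"closed"` or `"open"`.
#' @param d_p_nm protein hydrophobic length, nm.
#' @param R_ave_nm average channel radius, nm.
#' @param pore_outer_radius_nm pore radius at the membrane surfaces, nm.
#' @param pore_constriction_radius_nm narrowest pore radius, nm.
#' @param constriction_z_nm axial position of the constriction relative to
#'   the bilayer midplane, nm (negative = cytoplasmic side).
#' @param taper_exponent exponent of the hourglass taper (2 = parabolic).
#' @param wall_radius_nm outer (lipid-facing) protein radius, nm.
#' @param E_Pa Young's modulus of the protein RVE, Pa.
#' @param nu Poisson's ratio (0.5 = incompressible; the solver maps it to
#'   0.499 with locking mitigation).
#' @param C_P_per_nm mean intrinsic protein curvature, 1/nm (0 for the
#'   cylindrical closed state).
#' @param C_P_star_per_nm protein curvature deviator; 0 for an isotropic
#'   inclusion.
#' @return An object of class `channel_spec`.
#' @export
channel_spec <- function(state = c("closed", "open"),
                         d_p_nm = 2.7, R_ave_nm = 2.5,
                         pore_outer_radius_nm = 2.5,
                         pore_constriction_radius_nm = 0.25,
                         constriction_z_nm = -0.45,
                         taper_exponent = 2,
                         wall_radius_nm = 3.5,
                         E_Pa = 40e6, nu = 0.5,
                         C_P_per_nm = 0, C_P_star_per_nm = 0) {
  state <- match.arg(state)
  for (f in c("d_p_nm", "R_ave_nm", "pore_outer_radius_nm",
              "pore_constriction_radius_nm", "taper_exponent",
              "wall_radius_nm", "E_Pa")) {
    v <- get(f)
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0)
      stop_invalid(sprintf("channel field '%s' must be a positive number", f))
  }
  if (pore_constriction_radius_nm >= pore_outer_radius_nm)
    stop_invalid("channel constriction radius must be smaller than the pore outer radius")
  if (pore_outer_radius_nm > 2 * R_ave_nm)
    stop_invalid("channel pore outer radius must not exceed 2 * R_ave")
  if (wall_radius_nm <= pore_outer_radius_nm)
    stop_invalid("channel wall radius must exceed the pore outer radius")
  if (nu <= 0 || nu > 0.5)
    stop_invalid("channel Poisson ratio must lie in (0, 0.5]")
  if (abs(constriction_z_nm) >= d_p_nm / 2)
    stop_invalid("channel constriction must lie inside the hydrophobic core")
  structure(list(
    state = state, d_p_nm = d_p_nm, R_ave_nm = R_ave_nm,
    pore_outer_radius_nm = pore_outer_radius_nm,
    pore_constriction_radius_nm = pore_constriction_radius_nm,
    constriction_z_nm = constriction_z_nm,
    taper_exponent = taper_exponent,
    wall_radius_nm = wall_radius_nm,
    E_Pa = E_Pa, nu = nu,
    C_P_per_nm = C_P_per_nm, C_P1_per_nm = C_P_per_nm,
    C_P2_per_nm = C_P_per_nm, C_P_star_per_nm = C_P_star_per_nm
  ), class = "channel_spec")
}

#' Channel state fixtures
#'
#' `closed`: cylindrical inclusion (`C_P = 0`) with a 0.25 nm hydrophobic
#' constriction; `open`: conical inclusion (`C_P = -0.08` 1/nm) with a
#' widened 1.3 nm pore.  Both share the 2.7 nm hydrophobic length of the
#' closed crystal conformation.
#'
#' @param state `"closed"` or `"open"`.
#' @param ... overrides passed to [channel_spec()].
#' @return A `channel_spec`.
#' @export
make_channel <- function(state = c("closed", "open"), ...) {
  state <- match.arg(state)
  if (state == "closed")
    channel_spec("closed", ...)
  else
    channel_spec("open", pore_constriction_radius_nm = 1.3,
                 C_P_per_nm = -0.08, ...)
}

#' @export
print.channel_spec <- function(x, ...) {
  cat(sprintf("MscL RVE (%s): d_p = %.3g nm, R_ave = %.3g nm, wall %.3g nm\n",
              x$state, x$d_p_nm, x$R_ave_nm, x$wall_radius_nm))
  cat(sprintf("  pore %.3g -> %.3g nm at z = %.3g nm; E = %.3g MPa, nu = %.3g, C_P = %.3g 1/nm\n",
              x$pore_outer_radius_nm, x$pore_constriction_radius_nm,
              x$constriction_z_nm, x$E_Pa / 1e6, x$nu, x$C_P_per_nm))
  invisible(x)
}

#' Reference (undeformed) pore radius r0(z)
#'
#' Hourglass parameterisation of the pore wall: radius
#' `pore_outer_radius_nm` at the protein ends, tapering with the given
#' exponent to `pore_constriction_radius_nm` at `constriction_z_nm`.
#'
#' @param channel a [channel_spec()].
#' @param z_nm axial positions (vectorised), nm.
#' @param half_height_nm protein half-height, nm (hydrophobic half-length
#'   plus the headgroup band it spans).
#' @return Pore radii, nm (always > 0).
#' @export
pore_radius_ref <- function(channel, z_nm, half_height_nm) {
  rc <- channel$pore_constriction_radius_nm
  ro <- channel$pore_outer_radius_nm
  zc <- channel$constriction_z_nm
  p <- channel$taper_exponent
  z <- pmax(-half_height_nm, pmin(half_height_nm, z_nm))
  span <- ifelse(z >= zc, half_height_nm - zc, half_height_nm + zc)
  rc + (ro - rc) * (abs(z - zc) / span)^p
}
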