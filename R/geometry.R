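# Axisymmetric r-z computational domain: protein annulus embedded in the
# three-layer laminate membrane, with hydrophobic matching.  Far from the
# protein the core has the bilayer thickness d_l; within a morph annulus of
# width lambda next to the protein wall it transitions linearly to the
# protein hydrophobic length d_p (the hydrophobic coupling condition), and
# the protein-lipid interface is fully bonded.

#' Build the axisymmetric solver geometry
#'
#' @param bilayer a [bilayer_spec()].
#' @param channel a [channel_spec()].
#' @param R_out_nm patch outer radius, nm; must be at least 4 times the
#'   protein wall radius so the far field is unperturbed.
#' @param lambda_nm width of the morph annulus accommodating the
#'   hydrophobic mismatch, nm.
#' @return An object of class `geometry2d`.
#' @export
build_geometry <- function(bilayer, channel, R_out_nm = 20, lambda_nm = 2) {
  stopifnot(inherits(bilayer, "bilayer_spec"), inherits(channel, "channel_spec"))
  if (R_out_nm < 4 * channel$wall_radius_nm)
    stop_invalid(sprintf(
      "patch radius R_out = %.3g nm too small: need at least 4 x wall radius (%.3g nm)",
      R_out_nm, 4 * channel$wall_radius_nm))
  if (lambda_nm <= 0)
    stop_invalid("morph annulus width lambda must be positive")
  if (channel$wall_radius_nm + lambda_nm >= R_out_nm)
    stop_invalid("morph annulus extends beyond the patch outer radius")
  half_height <- channel$d_p_nm / 2 + bilayer$h_head_nm
  structure(list(
    bilayer = bilayer, channel = channel,
    R_out_nm = R_out_nm, lambda_nm = lambda_nm,
    R_wall_nm = channel$wall_radius_nm,
    protein_half_height_nm = half_height
  ), class = "geometry2d")
}

#' @export
print.geometry2d <- function(x, ...) {
  cat(sprintf(
    "Axisymmetric domain: pore wall -> R_out = %.3g nm; morph width %.3g nm\n",
    x$R_out_nm, x$lambda_nm))
  cat(sprintf("  core half-thickness %.3g nm at interface -> %.3g nm far field\n",
              x$channel$d_p_nm / 2, x$bilayer$t_nm))
  invisible(x)
}

#' Local core half-thickness of the laminate
#'
#' Equals `d_p/2` at the protein interface, morphing linearly over the
#' morph annulus to the bilayer value `d_l/2` in the far field.
#'
#' @param geom a `geometry2d`.
#' @param r_nm radial positions, nm (vectorised).
#' @return Half-thicknesses, nm.
#' @export
core_half_thickness <- function(geom, r_nm) {
  s <- pmin(1, pmax(0, (r_nm - geom$R_wall_nm) / geom$lambda_nm))
  geom$channel$d_p_nm / 2 + s * (geom$bilayer$t_nm - geom$channel$d_p_nm / 2)
}
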