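# High-level solver workflow: equilibrate the channel against the intrinsic
# pressure profile, then superpose local bending and extract the deformed
# pore profile and leaflet area difference.

#' Deformed pore profile from a solution field
#'
#' Traces the pore-wall node column of the mesh and adds its displacement
#' to the reference hourglass radius.  Besides the overall minimum radius,
#' the profile records the pore radius at the hydrophobic-lock material
#' point (the constriction site, a pinned mesh row): under load the
#' location of the shape minimum can slide along the hourglass, so the
#' gate-site radius is the mesh-stable readout of constriction gating.
#'
#' @param field a `solution_field`.
#' @param mesh the `fe_mesh` (defaults to the one attached to the field).
#' @return An object of class `pore_profile`: a data frame with columns
#'   `z_nm`, `r_nm` and attributes `constriction_radius_nm` (minimum over
#'   the profile) and `gate_radius_nm` (radius at the lock site).
#' @export
pore_profile_from_field <- function(field, mesh = attr(field, "mesh")) {
  wall <- mesh$node_id[, 1]
  r <- mesh$nodes[wall, 1] + field[wall, 1]
  z <- mesh$nodes[wall, 2] + field[wall, 2]
  if (any(r <= 0))
    stop_invalid("deformed pore radius is non-positive: pore wall self-intersects",
                 class = "mscbend_solver_error")
  out <- data.frame(z_nm = z, r_nm = r)
  class(out) <- c("pore_profile", "data.frame")
  attr(out, "constriction_radius_nm") <- min(r)
  attr(out, "gate_radius_nm") <- if (!is.null(mesh$gate_row)) r[mesh$gate_row] else min(r)
  out
}

#' Pore radius at the hydrophobic lock
#'
#' @param pore a `pore_profile`.
#' @return Radius at the constriction material site, nm.
#' @export
gate_radius <- function(pore) {
  attr(pore, "gate_radius_nm") %||% min(pore$r_nm)
}

#' Constriction radius of a pore profile
#'
#' @param pore a `pore_profile` (or any data frame with `r_nm`).
#' @return The minimum pore radius, nm.
#' @export
constriction_radius <- function(pore) {
  attr(pore, "constriction_radius_nm") %||% min(pore$r_nm)
}

#' Equilibrate the channel against the intrinsic pressure profile
#'
#' Builds the geometry, mesh and materials for a bilayer/channel pair,
#' loads the lipid with the bilayer's intrinsic lateral pressure profile
#' under the resting far-field clamp, and solves for the reference
#' (resting) state.  In thin bilayers the strong tail-pressure regime
#' narrows the hydrophobic constriction relative to the crystal-shape
#' reference, while the pore widens near the headgroup bands.
#'
#' @param bilayer a [bilayer_spec()].
#' @param channel a [channel_spec()].
#' @param R_out_nm,lambda_nm,h_target_nm solver geometry settings.
#' @param profile optional `pressure_profile` override (e.g. a zero
#'   profile); defaults to [build_pressure_profile()] of the bilayer.
#' @return An object of class `resting_state`: list with `field`, `pore`,
#'   `mesh`, `materials`, `context`, `profile`, and the input specs.
#' @export
equilibrate_resting <- function(bilayer, channel, R_out_nm = 20, lambda_nm = 2,
                                h_target_nm = 0.25, profile = NULL) {
  geom <- build_geometry(bilayer, channel, R_out_nm, lambda_nm)
  mesh <- generate_mesh(geom, h_target_nm)
  materials <- material_map(geom)
  if (is.null(profile)) profile <- build_pressure_profile(bilayer)
  load <- load_case(mesh)
  if (!is.null(profile)) load <- load_from_profile(load, mesh, profile, geom)
  load <- impose_curvature(load, mesh, 0)
  context <- fe_context(mesh, materials, load)
  field <- solve_equilibrium(mesh, materials, load, context)
  structure(list(
    bilayer = bilayer, channel = channel, geom = geom, mesh = mesh,
    materials = materials, profile = profile, context = context,
    field = field, pore = pore_profile_from_field(field, mesh)
  ), class = "resting_state")
}

#' Bend the membrane and extract the pore response
#'
#' Solves the bent state: intrinsic pressure profile plus the prescribed
#' far-field spherical deflection (Kirchhoff clamp band).  Returns the
#' bent pore profile together with the change in pore radius at the
#' hydrophobic lock relative to the resting state,
#' `delta_r = r_gate(bent) - r_gate(resting)`: positive for inward
#' (cytoplasmic, `C_L < 0`) bending, negative for outward bending, and
#' exactly odd in `C_L`.
#'
#' @param bilayer a [bilayer_spec()].
#' @param channel a [channel_spec()].
#' @param C_L_per_nm signed curvature, 1/nm.
#' @param ... geometry settings passed to [equilibrate_resting()] when no
#'   resting state is supplied.
#' @param resting optional precomputed [equilibrate_resting()] state; its
#'   stiffness factorisation is reused.
#' @return A list of class `bend_result`: `pore`, `resting_pore`,
#'   `delta_r_constriction_nm`, `area_difference_A2`, `field`, `C_L_per_nm`,
#'   `resting`.
#' @export
bend_and_extract <- function(bilayer, channel, C_L_per_nm, ..., resting = NULL) {
  if (is.null(resting)) resting <- equilibrate_resting(bilayer, channel, ...)
  mesh <- resting$mesh
  load <- load_case(mesh)
  if (!is.null(resting$profile))
    load <- load_from_profile(load, mesh, resting$profile, resting$geom)
  load <- impose_curvature(load, mesh, C_L_per_nm)
  field <- solve_equilibrium(mesh, resting$materials, load, resting$context)
  pore <- pore_profile_from_field(field, mesh)
  structure(list(
    pore = pore, resting_pore = resting$pore,
    delta_r_constriction_nm = gate_radius(pore) - gate_radius(resting$pore),
    area_difference_A2 = leaflet_area_difference(field, mesh) -
      leaflet_area_difference(resting$field, mesh),
    field = field, C_L_per_nm = C_L_per_nm, resting = resting
  ), class = "bend_result")
}

#' @export
print.bend_result <- function(x, ...) {
  cat(sprintf(
    "Bend C_L = %+.3g 1/nm: lock radius %.4g -> %.4g nm (delta %+.4g nm); dA = %+.4g A^2\n",
    x$C_L_per_nm, gate_radius(x$resting_pore), gate_radius(x$pore),
    x$delta_r_constriction_nm, x$area_difference_A2))
  invisible(x)
}

#' Monolayer area difference from a solution field
#'
#' Areas of the two deformed leaflet midsurfaces over the lipid annulus,
#' computed by surface-of-revolution quadrature of the displaced material
#' lines at `z = +-(t_loc + h)/2`, returned as outer minus inner in
#' Angstrom^2.  Vanishes in any unbent state and is odd in the bending
#' direction; for a homogeneous plate under shallow spherical bending it
#' approaches the closed form `2 C s A`.
#'
#' @param field a `solution_field`.
#' @param mesh the `fe_mesh` (defaults to the field's attribute).
#' @return Area difference, Angstrom^2.
#' @export
leaflet_area_difference <- function(field, mesh = attr(field, "mesh")) {
  h <- mesh$geom$bilayer$h_head_nm
  cols <- which(seq_len(mesh$n_col) > mesh$n_pr)   # lipid columns incl. interface
  surf <- function(sgn) {
    pts_r <- numeric(length(cols)); pts_z <- numeric(length(cols))
    for (k in seq_along(cols)) {
      ci <- cols[k]
      ids <- mesh$node_id[, ci]
      z_col <- mesh$nodes[ids, 2]
      z_mid <- sgn * (mesh$col_t_loc[ci] + h) / 2
      ur <- stats::approx(z_col, field[ids, 1], xout = z_mid, rule = 2)$y
      uz <- stats::approx(z_col, field[ids, 2], xout = z_mid, rule = 2)$y
      pts_r[k] <- mesh$nodes[ids[1], 1] + ur
      pts_z[k] <- z_mid + uz
    }
    sum(pi * (pts_r[-1] + pts_r[-length(pts_r)]) *
          sqrt(diff(pts_r)^2 + diff(pts_z)^2))
  }
  (surf(+1) - surf(-1)) * 100   # nm^2 -> A^2
}

#' Export a solution field as legacy ASCII VTK
#'
#' Writes the mesh as an unstructured grid of quads with the nodal
#' displacement vector attached, viewable in ParaView.
#'
#' @param field a `solution_field`.
#' @param path output file path.
#' @param mesh the `fe_mesh`.
#' @return `path`, invisibly.
#' @export
write_vtk_field <- function(field, path, mesh = attr(field, "mesh")) {
  n <- nrow(mesh$nodes); nel <- nrow(mesh$elem)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "mscbend axisymmetric solution", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", n)), con)
  writeLines(sprintf("%.9g %.9g 0", mesh$nodes[, 1], mesh$nodes[, 2]), con)
  writeLines(sprintf("CELLS %d %d", nel, 5 * nel), con)
  writeLines(sprintf("4 %d %d %d %d", mesh$elem[, 1] - 1L, mesh$elem[, 2] - 1L,
                     mesh$elem[, 3] - 1L, mesh$elem[, 4] - 1L), con)
  writeLines(sprintf("CELL_TYPES %d", nel), con)
  writeLines(rep("9", nel), con)
  writeLines(sprintf("POINT_DATA %d", n), con)
  writeLines("VECTORS displacement double", con)
  writeLines(sprintf("%.9g %.9g 0", field[, 1], field[, 2]), con)
  invisible(path)
}

#' Export a pore profile as CSV
#'
#' @param pore a `pore_profile`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pore_csv <- function(pore, path) {
  utils::write.csv(data.frame(z_nm = pore$z_nm, r_nm = pore$r_nm), path,
                   row.names = FALSE)
  invisible(path)
}
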