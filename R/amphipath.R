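# Amphipath (lysolipid) insertion, monolayer area difference and induced
# local curvature.  Asymmetric insertion of a conical lysolipid such as LPC
# into one leaflet expands that leaflet's area; the tension imbalance
# between the monolayers then bends the membrane locally.

# Worked-example fixtures: LPC headgroup projection in a POPC bilayer, the
# host (POPC) per-lipid area, and the patch over which the area difference
# is accumulated.  The patch area and leaflet separation are calibration
# values chosen so the closed-form shallow-cap formula reproduces the
# reference area difference of ~511 A^2 at C = 0.04 1/nm; they are
# fixtures, not derived quantities.
.LPC_AREA_A2 <- 101.35
.HOST_LIPID_AREA_A2 <- 68.3
.HOST_LEAFLET_AREA_A2 <- 10040
.CAL_PATCH_AREA_NM2 <- 25.15
.CAL_LEAFLET_SEP_NM <- 2.54

#' Amphipath specification
#'
#' @param name text label, e.g. `"LPC"`.
#' @param a_mol_A2 projected headgroup area per molecule, Angstrom^2.
#' @param leaflet `"inner"` or `"outer"` — the leaflet the amphipath
#'   partitions into.
#' @return An object of class `amphipath_spec`.
#' @export
amphipath_spec <- function(name = "LPC", a_mol_A2 = .LPC_AREA_A2,
                           leaflet = c("inner", "outer")) {
  leaflet <- match.arg(leaflet)
  if (!is.numeric(a_mol_A2) || a_mol_A2 <= 0)
    stop_invalid("amphipath field 'a_mol_A2' must be a positive number")
  structure(list(name = name, a_mol_A2 = a_mol_A2, leaflet = leaflet),
            class = "amphipath_spec")
}

#' Number of amphipath molecules for a leaflet area difference
#'
#' `round(delta_area / a_mol)` with ties rounded to even, matching the
#' reference worked example 511 / 101.35 = 5.04 -> 5 molecules.
#'
#' @param delta_area_A2 monolayer area difference, Angstrom^2 (>= 0).
#' @param spec an [amphipath_spec()].
#' @return Integer molecule count.
#' @export
amphipath_count <- function(delta_area_A2, spec = amphipath_spec()) {
  stopifnot(inherits(spec, "amphipath_spec"))
  if (!is.numeric(delta_area_A2) || delta_area_A2 < 0)
    stop_invalid("delta_area_A2 must be non-negative")
  as.integer(round(delta_area_A2 / spec$a_mol_A2))
}

#' Amphipath molar percentage relative to host lipids
#'
#' @param n amphipath molecule count.
#' @param n_host_lipids host lipid count in the same leaflet; defaults to
#'   the fixture leaflet area divided by the host per-lipid area
#'   (10040 / 68.3 -> 147 lipids).
#' @return Molar ratio in percent, `100 n / n_host`.
#' @export
molar_percent <- function(n, n_host_lipids = host_lipid_count()) {
  if (n_host_lipids <= 0)
    stop_invalid("host lipid count must be positive")
  if (n < 0) stop_invalid("molecule count must be non-negative")
  100 * n / n_host_lipids
}

#' @rdname molar_percent
#' @param leaflet_area_A2 leaflet area, Angstrom^2.
#' @param a_host_A2 area per host lipid, Angstrom^2.
#' @export
host_lipid_count <- function(leaflet_area_A2 = .HOST_LEAFLET_AREA_A2,
                             a_host_A2 = .HOST_LIPID_AREA_A2) {
  if (leaflet_area_A2 <= 0 || a_host_A2 <= 0)
    stop_invalid("leaflet and per-lipid areas must be positive")
  as.integer(round(leaflet_area_A2 / a_host_A2))
}

#' Radius of curvature from curvature
#'
#' @param C_per_nm curvature, 1/nm.  A flat membrane (`C = 0`) signals a
#'   `mscbend_flat_membrane` warning and returns `Inf`.
#' @return Radius `1/|C|` in nm.
#' @export
curvature_radius <- function(C_per_nm) {
  if (C_per_nm == 0) {
    warn_mscbend("flat membrane: curvature is zero, radius is infinite",
                 class = "mscbend_flat_membrane")
    return(Inf)
  }
  1 / abs(C_per_nm)
}

#' Classify a radius of curvature as local or global
#'
#' Local bending (radius < 100 nm, the caveolae / coated-pit scale)
#' modulates mechanosensitive channels; global curvature (radius > 200 nm)
#' has a negligible effect on the bilayer pressure profile and therefore on
#' channel activity, and is flagged with a warning.
#'
#' @param R_nm radius of curvature, nm (> 0).
#' @return `"local"`, `"global"` or `"intermediate"`.
#' @export
classify_curvature_scale <- function(R_nm) {
  if (!is.numeric(R_nm) || R_nm <= 0)
    stop_invalid("radius of curvature must be positive")
  if (R_nm < 100) return("local")
  if (R_nm > 200) {
    warn_mscbend(sprintf(
      "radius %.3g nm is global-scale curvature: channel modulation is negligible", R_nm),
      class = "mscbend_global_curvature")
    return("global")
  }
  "intermediate"
}

#' Monolayer area difference produced by spherical bending
#'
#' Shallow spherical cap, both principal curvatures equal to `C`: offsetting
#' the two leaflet midsurfaces by `+-s/2` from the bent midplane gives
#' \deqn{\Delta A = 2\,C\,s\,A,} signed with the curvature (outward bending
#' grows the outer leaflet).
#'
#' @param patch_area_nm2 patch area, nm^2.
#' @param leaflet_separation_nm distance between leaflet midsurfaces, nm.
#' @param C_per_nm signed curvature, 1/nm.
#' @return Area difference in Angstrom^2.
#' @export
area_difference_for_curvature <- function(patch_area_nm2 = .CAL_PATCH_AREA_NM2,
                                          leaflet_separation_nm = .CAL_LEAFLET_SEP_NM,
                                          C_per_nm = 0.04) {
  if (patch_area_nm2 <= 0 || leaflet_separation_nm <= 0)
    stop_invalid("patch area and leaflet separation must be positive")
  2 * C_per_nm * leaflet_separation_nm * patch_area_nm2 * 100  # nm^2 -> A^2
}

#' Lysolipid dose for a target local curvature
#'
#' Combines [area_difference_for_curvature()], [amphipath_count()],
#' [molar_percent()] and [curvature_radius()] into a single dose record:
#' how many amphipath molecules must insert asymmetrically into one leaflet
#' to produce a given local curvature, and what molar ratio against the
#' host lipid that represents.
#'
#' @param C_per_nm target curvature magnitude, 1/nm.
#' @param spec an [amphipath_spec()].
#' @param patch_area_nm2,leaflet_separation_nm patch geometry for the
#'   closed-form area difference.
#' @param n_host_lipids host lipid count for the molar ratio.
#' @return An object of class `dose_result` with fields `delta_area_A2`,
#'   `n_molecules`, `molar_percent`, `curvature_per_nm`, `radius_nm`,
#'   `scale`.
#' @examples
#' lpc_dose(0.04)  # ~511 A^2, 5 molecules, 3.4 %
#' @export
lpc_dose <- function(C_per_nm = 0.04, spec = amphipath_spec(),
                     patch_area_nm2 = .CAL_PATCH_AREA_NM2,
                     leaflet_separation_nm = .CAL_LEAFLET_SEP_NM,
                     n_host_lipids = host_lipid_count()) {
  dA <- abs(area_difference_for_curvature(patch_area_nm2, leaflet_separation_nm,
                                          C_per_nm))
  n <- amphipath_count(dA, spec)
  R <- if (C_per_nm == 0) Inf else 1 / abs(C_per_nm)
  structure(list(
    delta_area_A2 = dA,
    n_molecules = n,
    molar_percent = molar_percent(n, n_host_lipids),
    curvature_per_nm = C_per_nm,
    radius_nm = R,
    scale = if (is.finite(R)) suppressWarnings(classify_curvature_scale(R)) else "flat"
  ), class = "dose_result")
}

#' @export
print.dose_result <- function(x, ...) {
  cat(sprintf(
    "Amphipath dose: dA = %.4g A^2 -> %d molecules (%.3g%% molar); C = %.3g 1/nm, R = %.4g nm (%s)\n",
    x$delta_area_A2, x$n_molecules, x$molar_percent, x$curvature_per_nm,
    x$radius_nm, x$scale))
  invisible(x)
}
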