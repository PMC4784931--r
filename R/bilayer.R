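# Bilayer specifications and mean-field lateral pressure profiles.
#
# The bilayer is a three-layer laminate: two headgroup bands of thickness
# h_head sandwiching a hydrophobic core of thickness d_l.  The lateral
# pressure profile P(z) is piecewise constant with, per leaflet, a repulsive
# headgroup band, a negative interfacial-tension band at the head/tail
# boundary and a repulsive tail band; it integrates to zero net tension for
# an unloaded membrane.

# Calibration constants for the mean-field profile.  All band magnitudes
# scale as 1/d_l so that thicker bilayers have both flatter profiles and
# weaker integrated band tensions, hence deform the embedded channel less.
.PROFILE_GAMMA_IF_REF <- 0.035  # per-leaflet interfacial tension at d_l = 2.7 nm, N/m
.PROFILE_D_REF <- 2.7           # reference core thickness, nm
.PROFILE_W_FRAC <- 0.3          # interfacial band width as fraction of d_l
.PROFILE_C_HEAD <- 0.009        # headgroup peak coefficient, N/m (peak = c/d_l)

# Reference bending modulus and monolayer half-thickness used to scale K_B
# across fixtures (K_B proportional to t^3).
.KB_REF_J <- 0.85e-19
.T_REF_NM <- 1.35

#' Construct a bilayer specification
#'
#' A `bilayer_spec` holds the geometric and elastic description of a lipid
#' bilayer: hydrophobic core thickness `d_l` (nm), monolayer half-thickness
#' `t = d_l/2`, headgroup layer thickness `h_head` per side (nm), areal
#' expansion modulus `K_A` (N/m) and bending modulus `K_B` (J).
#'
#' When `K_B_J` is omitted it is scaled from the di-16:0 reference value
#' (0.85e-19 J at t = 1.35 nm) with the cubic thickness law of
#' [bending_modulus_from_thickness()].  `K_A` defaults to 0.24 N/m for all
#' thicknesses, since the areal elasticity of bilayers changes negligibly
#' with acyl-chain length.
#'
#' @param acyl_label text tag, e.g. `"di-16:0"` or `"custom"`.
#' @param d_l_nm hydrophobic core thickness, nm.
#' @param h_head_nm headgroup layer thickness per side, nm.
#' @param K_A_N_per_m areal expansion modulus, N/m.
#' @param K_B_J bending modulus, J; defaults to the t^3-scaled reference.
#' @return An object of class `bilayer_spec`.
#' @seealso [make_bilayer()] for the named fixtures.
#' @export
bilayer_spec <- function(acyl_label = "custom", d_l_nm, h_head_nm = 0.8,
                         K_A_N_per_m = 0.24, K_B_J = NULL) {
  if (!is.numeric(d_l_nm) || length(d_l_nm) != 1 || !is.finite(d_l_nm) || d_l_nm <= 0)
    stop_invalid("bilayer field 'd_l_nm' must be a positive number")
  if (!is.numeric(h_head_nm) || h_head_nm <= 0)
    stop_invalid("bilayer field 'h_head_nm' must be a positive number")
  if (!is.numeric(K_A_N_per_m) || K_A_N_per_m <= 0)
    stop_invalid("bilayer field 'K_A_N_per_m' must be a positive number")
  t_nm <- d_l_nm / 2
  if (is.null(K_B_J))
    K_B_J <- bending_modulus_from_thickness(.T_REF_NM, .KB_REF_J, t_nm, exponent = 3)
  if (!is.numeric(K_B_J) || K_B_J <= 0)
    stop_invalid("bilayer field 'K_B_J' must be a positive number")
  structure(list(
    acyl_label = as.character(acyl_label),
    d_l_nm = d_l_nm,
    t_nm = t_nm,
    h_head_nm = h_head_nm,
    K_A_N_per_m = K_A_N_per_m,
    K_B_J = K_B_J
  ), class = "bilayer_spec")
}

#' Named bilayer fixtures
#'
#' Returns the parameter set for one of the three study bilayers: `di-10:0`
#' (thin, positive mismatch against the default channel), `di-16:0` (zero
#' mismatch) and `di-24:1` (thick, negative mismatch).  Core thicknesses are
#' 1.8 / 2.7 / 3.6 nm so the mismatch magnitudes against the 2.7 nm channel
#' hydrophobic length are symmetric (+-0.9 nm).
#'
#' @param acyl_label one of `"di-10:0"`, `"di-16:0"`, `"di-24:1"`, or
#'   `"custom"` with the remaining fields supplied via `...`.
#' @param ... passed to [bilayer_spec()] for `"custom"`.
#' @return A `bilayer_spec`.
#' @examples
#' make_bilayer("di-16:0")$d_l_nm  # 2.7
#' @export
make_bilayer <- function(acyl_label, ...) {
  fixtures <- c("di-10:0" = 1.8, "di-16:0" = 2.7, "di-24:1" = 3.6)
  if (acyl_label %in% names(fixtures))
    return(bilayer_spec(acyl_label, d_l_nm = unname(fixtures[acyl_label]), ...))
  if (identical(acyl_label, "custom"))
    return(bilayer_spec("custom", ...))
  stop_invalid(sprintf(
    "unknown acyl label '%s' (known: %s, or 'custom')",
    acyl_label, paste(names(fixtures), collapse = ", ")))
}

#' @export
print.bilayer_spec <- function(x, ...) {
  cat(sprintf("Bilayer '%s': d_l = %.3g nm (t = %.3g), h_head = %.3g nm\n",
              x$acyl_label, x$d_l_nm, x$t_nm, x$h_head_nm))
  cat(sprintf("  K_A = %.3g N/m, K_B = %.3g J\n", x$K_A_N_per_m, x$K_B_J))
  invisible(x)
}

#' Build the intrinsic lateral pressure profile of a bilayer
#'
#' Constructs the mean-field piecewise-constant profile \eqn{P(z)} for an
#' unloaded bilayer: per leaflet a repulsive headgroup band, a negative
#' interfacial band at the head/tail boundary, and a repulsive tail band.
#' The profile is mirror-symmetric about the midplane `z = 0` (positive z
#' toward the extracellular side) and integrates to exactly zero net
#' tension.  Peak magnitude decreases with core thickness, so thicker
#' bilayers have flatter profiles.
#'
#' @param spec a [bilayer_spec()].
#' @return An object of class `pressure_profile` with fields `z_breaks_nm`
#'   (band boundaries, nm), `P_Pa` (pressure per band, positive = repulsive),
#'   and `provenance` (`"intrinsic"`).
#' @export
build_pressure_profile <- function(spec) {
  stopifnot(inherits(spec, "bilayer_spec"))
  t <- spec$t_nm; h <- spec$h_head_nm; d_l <- spec$d_l_nm
  w <- .PROFILE_W_FRAC * d_l                               # interfacial band width, nm
  gamma_if <- .PROFILE_GAMMA_IF_REF * .PROFILE_D_REF / d_l  # N/m per leaflet
  P_head <- .PROFILE_C_HEAD / d_l            # N/m per nm
  P_int <- -gamma_if / w
  # zero net tension per leaflet: P_head*h + P_int*w + P_tail*(t - w) = 0
  P_tail <- (gamma_if - P_head * h) / (t - w)
  if (P_tail <= 0)
    stop_invalid("pressure-profile calibration failed: non-positive tail peak")
  # bands split at z = 0 so each band lies in a single leaflet
  z_breaks <- c(-t - h, -t, -t + w, 0, t - w, t, t + h)
  P_nm <- c(P_head, P_int, P_tail, P_tail, P_int, P_head)  # N/m per nm
  structure(list(
    z_breaks_nm = z_breaks,
    P_Pa = P_nm * 1e9,          # (N/m)/nm -> Pa
    provenance = "intrinsic",
    C_L_per_nm = 0,
    spec = spec
  ), class = "pressure_profile")
}

#' @export
print.pressure_profile <- function(x, ...) {
  cat(sprintf("Pressure profile (%s), %d bands over [%.3g, %.3g] nm\n",
              x$provenance, length(x$P_Pa), min(x$z_breaks_nm), max(x$z_breaks_nm)))
  cat(sprintf("  peak |P| = %.3g MPa; net tension = %.3g N/m\n",
              max(abs(x$P_Pa)) / 1e6, profile_integral(x, min(x$z_breaks_nm), max(x$z_breaks_nm))))
  invisible(x)
}

# Integral of P(z) dz (z in nm, P in Pa) over [lo, hi] nm -> N/m.
profile_integral <- function(profile, lo_nm, hi_nm) {
  zb <- profile$z_breaks_nm
  b_lo <- zb[-length(zb)]; b_hi <- zb[-1]
  ov <- pmax(0, pmin(b_hi, hi_nm) - pmax(b_lo, lo_nm))
  sum(profile$P_Pa * ov) * 1e-9
}

#' Evaluate a piecewise-constant pressure profile
#'
#' @param profile a `pressure_profile`.
#' @param z_nm positions, nm (vectorised).  Outside the covered range the
#'   pressure is zero.
#' @return Pressure values in Pa.
#' @export
profile_pressure_at <- function(profile, z_nm) {
  zb <- profile$z_breaks_nm
  idx <- findInterval(z_nm, zb, left.open = FALSE, rightmost.closed = TRUE)
  out <- rep(0, length(z_nm))
  inside <- idx >= 1 & idx <= length(profile$P_Pa) & z_nm >= zb[1] & z_nm <= zb[length(zb)]
  out[inside] <- profile$P_Pa[idx[inside]]
  out
}

#' Leaflet tension
#'
#' Integrates the lateral pressure profile over one leaflet including its
#' headgroup band: inner means `z < 0` (cytoplasmic side), outer `z > 0`.
#' The integral is exact for piecewise-constant profiles.  For an intrinsic
#' symmetric profile the two leaflet tensions are equal (and zero for the
#' mean-field calibration used here).
#'
#' @param profile a `pressure_profile`.
#' @param leaflet `"inner"` or `"outer"`.
#' @return Signed tension \eqn{\gamma = \int P(z)\,dz} in N/m.
#' @export
leaflet_tension <- function(profile, leaflet = c("inner", "outer")) {
  leaflet <- match.arg(leaflet)
  zb <- profile$z_breaks_nm
  if (leaflet == "inner") profile_integral(profile, zb[1], 0)
  else profile_integral(profile, 0, zb[length(zb)])
}

#' Superpose bending stress on a pressure profile
#'
#' Imposes the pressure-profile asymmetry caused by local membrane bending.
#' The membrane strain at depth z is \eqn{\epsilon(z) = C_L z} with the sign
#' convention `C_L > 0` = outward bending (outer leaflet stretched) and
#' `C_L < 0` = inward, cytoplasmic bending (inner leaflet stretched).  Each
#' band is shifted by \eqn{\Delta\sigma = K_A/(2 T)\,\epsilon(\bar z)}
#' evaluated at the band midpoint, where `T` is the total laminate
#' thickness; the resulting leaflet-tension difference is exactly odd in
#' `C_L`, and inward bending raises the inner-leaflet tension.
#'
#' @param profile an intrinsic `pressure_profile`.
#' @param C_L_per_nm signed mean curvature, 1/nm.
#' @param spec the [bilayer_spec()] the profile belongs to (defaults to the
#'   one stored in the profile).
#' @return A new `pressure_profile` with provenance `"bent"`.
#' @export
apply_bending_to_profile <- function(profile, C_L_per_nm, spec = profile$spec) {
  stopifnot(inherits(profile, "pressure_profile"), inherits(spec, "bilayer_spec"))
  if (C_L_per_nm == 0) return(profile)
  t <- spec$t_nm; h <- spec$h_head_nm
  strain_edge <- abs(C_L_per_nm) * (t + h)
  if (strain_edge > 0.2)
    warn_mscbend(sprintf(
      "edge membrane strain |C_L|(t+h) = %.3g exceeds 0.2; small-strain assumption dubious",
      strain_edge), class = "mscbend_strain_warning")
  T_m <- (spec$d_l_nm + 2 * h) * 1e-9          # laminate thickness, m
  zb <- profile$z_breaks_nm
  z_mid <- (zb[-1] + zb[-length(zb)]) / 2
  dsigma <- spec$K_A_N_per_m / (2 * T_m) * (C_L_per_nm * z_mid)  # Pa
  out <- profile
  out$P_Pa <- profile$P_Pa + dsigma
  out$provenance <- "bent"
  out$C_L_per_nm <- C_L_per_nm
  out
}

#' Export or import a pressure profile as CSV
#'
#' Columns are `z_lo_nm`, `z_hi_nm`, `P_Pa`, one row per band.
#'
#' @param profile a `pressure_profile`.
#' @param path file path.
#' @return `write_profile_csv()` returns `path` invisibly;
#'   `read_profile_csv()` returns a `pressure_profile` (with `"imported"`
#'   spec slot unset).
#' @export
write_profile_csv <- function(profile, path) {
  zb <- profile$z_breaks_nm
  df <- data.frame(z_lo_nm = zb[-length(zb)], z_hi_nm = zb[-1], P_Pa = profile$P_Pa)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profile_csv
#' @export
read_profile_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("z_lo_nm", "z_hi_nm", "P_Pa")
  if (!all(need %in% names(df)))
    stop_invalid(sprintf("profile CSV must have columns %s", paste(need, collapse = ", ")),
                 class = "mscbend_schema_error")
  if (any(abs(df$z_lo_nm[-1] - df$z_hi_nm[-nrow(df)]) > 1e-12))
    stop_invalid("profile bands must be contiguous", class = "mscbend_schema_error")
  structure(list(
    z_breaks_nm = c(df$z_lo_nm, df$z_hi_nm[nrow(df)]),
    P_Pa = df$P_Pa,
    provenance = "imported",
    C_L_per_nm = NA_real_,
    spec = NULL
  ), class = "pressure_profile")
}
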