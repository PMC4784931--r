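# Closed-form gating free energy: G = G_H + G_B.
#
# G_H is the hydrophobic-mismatch deformation energy of the annular lipid,
# G_B the Helfrich-type bending energy of the protein-membrane composite.
# Lengths enter in nm, moduli in SI (K_A in N/m, K_B in J); energies are
# returned in joules, with k_BT conversions at 298 K.

#' Principal-curvature state of the membrane
#'
#' Bundles the two principal curvatures into the mean `C_L = (C1 + C2)/2`
#' and deviator `C_L* = (C1 - C2)/2`.  Spherical bending corresponds to
#' `C1 = C2`, i.e. a vanishing deviator.  `theta` is the angle between the
#' protein's and the membrane's principal axes (zero for MscL in a POPC
#' bilayer, where the inclusion is isotropic).
#'
#' @param C1_per_nm,C2_per_nm principal curvatures, 1/nm.
#' @param theta_rad axis angle, radians.
#' @return An object of class `curvature_state`.
#' @export
curvature_state <- function(C1_per_nm, C2_per_nm = C1_per_nm, theta_rad = 0) {
  stopifnot(is.numeric(C1_per_nm), is.numeric(C2_per_nm), is.numeric(theta_rad))
  structure(list(
    C1_per_nm = C1_per_nm,
    C2_per_nm = C2_per_nm,
    C_L_per_nm = (C1_per_nm + C2_per_nm) / 2,
    C_L_star_per_nm = (C1_per_nm - C2_per_nm) / 2,
    theta_rad = theta_rad
  ), class = "curvature_state")
}

#' Hydrophobic-mismatch energy
#'
#' Deformation energy of the annular lipid accommodating a mismatch between
#' the protein hydrophobic length `d_p` and the bilayer core thickness
#' `d_l`:
#' \deqn{G_H = 2\,(K_A^3 K_B / t^6)^{1/4}\, u_0^2 \cdot 2\pi R_{ave},}
#' with monolayer deformation \eqn{u_0 = (d_p - d_l)/2}.  The prefactor is
#' the boundary spring constant of a monolayer with areal modulus `K_A`,
#' bending modulus `K_B` and half-thickness `t`; the energy is strictly
#' positive unless the mismatch vanishes, and even in the sign of the
#' mismatch.
#'
#' @param K_A_N_per_m areal expansion modulus, N/m.
#' @param K_B_J monolayer/bilayer bending modulus, J.
#' @param t_nm monolayer half-thickness, nm.
#' @param d_p_nm,d_l_nm protein and bilayer hydrophobic lengths, nm.
#' @param R_ave_nm average channel radius, nm.
#' @return Energy in joules.
#' @export
mismatch_energy <- function(K_A_N_per_m, K_B_J, t_nm, d_p_nm, d_l_nm, R_ave_nm) {
  vals <- c(K_A_N_per_m, K_B_J, t_nm, d_p_nm, d_l_nm, R_ave_nm)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop_invalid("mismatch_energy requires all parameters > 0")
  t_m <- t_nm * 1e-9
  u0_m <- (d_p_nm - d_l_nm) / 2 * 1e-9
  pref <- (K_A_N_per_m^3 * K_B_J / t_m^6)^(1 / 4)   # J/m^3
  2 * pref * u0_m^2 * 2 * pi * (R_ave_nm * 1e-9)
}

#' Bending energy of the protein-membrane composite
#'
#' \deqn{G_B = \frac{K}{2}(C_L - C_P)^2 +
#'   K' (C_L^{*2} - 2 C_L^* C_P^* \cos 2\theta + C_P^{*2}).}
#' Under spherical bending (`C_L* = 0`) of an isotropic inclusion
#' (`C_P* = 0`) this reduces to the first, quadratic term, minimised exactly
#' where the imposed mean curvature matches the protein's intrinsic
#' curvature.
#'
#' @param K_J_nm2,K_prime_J_nm2 protein-lipid interaction coefficients,
#'   J nm^2.  The package default elsewhere is `K = K' = K_B pi R_ave^2`
#'   (Helfrich density over the protein footprint), honouring K'/K = 1.
#' @param state a [curvature_state()].
#' @param C_P_per_nm protein mean intrinsic curvature, 1/nm.
#' @param C_P_star_per_nm protein curvature deviator, 1/nm (0 = isotropic).
#' @return Energy in joules.
#' @export
bending_energy <- function(K_J_nm2, K_prime_J_nm2, state, C_P_per_nm,
                           C_P_star_per_nm = 0) {
  stopifnot(inherits(state, "curvature_state"))
  if (K_J_nm2 <= 0 || K_prime_J_nm2 <= 0)
    stop_invalid("bending_energy requires K, K' > 0")
  iso <- K_J_nm2 / 2 * (state$C_L_per_nm - C_P_per_nm)^2
  aniso <- K_prime_J_nm2 * (state$C_L_star_per_nm^2 -
    2 * state$C_L_star_per_nm * C_P_star_per_nm * cos(2 * state$theta_rad) +
    C_P_star_per_nm^2)
  iso + aniso
}

#' Total gating free energy G = G_H + G_B
#'
#' Combines [mismatch_energy()] and [bending_energy()] for a bilayer,
#' channel and curvature state, echoing all parameters that produced the
#' breakdown.  `K` and `K'` default to `K_B * pi * R_ave^2`.
#'
#' @param bilayer a [bilayer_spec()].
#' @param channel a [channel_spec()].
#' @param state a [curvature_state()].
#' @param K_J_nm2,K_prime_J_nm2 optional overrides of the interaction
#'   coefficients.
#' @return An object of class `energy_breakdown` with fields `G_H_J`,
#'   `G_B_J`, `G_J`, `G_kBT` and an `inputs` echo.
#' @export
total_energy <- function(bilayer, channel, state,
                         K_J_nm2 = NULL, K_prime_J_nm2 = NULL) {
  stopifnot(inherits(bilayer, "bilayer_spec"), inherits(channel, "channel_spec"),
            inherits(state, "curvature_state"))
  K_default <- bilayer$K_B_J * pi * channel$R_ave_nm^2
  K <- K_J_nm2 %||% K_default
  Kp <- K_prime_J_nm2 %||% K
  G_H <- if (channel$d_p_nm == bilayer$d_l_nm) 0 else
    mismatch_energy(bilayer$K_A_N_per_m, bilayer$K_B_J, bilayer$t_nm,
                    channel$d_p_nm, bilayer$d_l_nm, channel$R_ave_nm)
  G_B <- bending_energy(K, Kp, state, channel$C_P_per_nm, channel$C_P_star_per_nm)
  structure(list(
    G_H_J = G_H, G_B_J = G_B, G_J = G_H + G_B,
    G_H_kBT = G_H / .kBT, G_B_kBT = G_B / .kBT, G_kBT = (G_H + G_B) / .kBT,
    K_J_nm2 = K, K_prime_J_nm2 = Kp,
    inputs = list(
      K_A_N_per_m = bilayer$K_A_N_per_m, K_B_J = bilayer$K_B_J,
      t_nm = bilayer$t_nm, d_p_nm = channel$d_p_nm, d_l_nm = bilayer$d_l_nm,
      R_ave_nm = channel$R_ave_nm, C_P_per_nm = channel$C_P_per_nm,
      C_L_per_nm = state$C_L_per_nm, C_L_star_per_nm = state$C_L_star_per_nm,
      theta_rad = state$theta_rad)
  ), class = "energy_breakdown")
}

#' @export
print.energy_breakdown <- function(x, ...) {
  cat(sprintf("G = %.4g J (%.3g kBT) = G_H %.4g J + G_B %.4g J\n",
              x$G_J, x$G_kBT, x$G_H_J, x$G_B_J))
  invisible(x)
}

#' Scale a bending modulus with bilayer thickness
#'
#' Membrane bending rigidity grows with the second or third power of the
#' (half-)thickness; this helper applies
#' \eqn{K_B = K_{B,ref} (t/t_{ref})^{e}} with `e` 2 or 3 (default 3).
#'
#' @param t_ref_nm,K_B_ref_J reference half-thickness (nm) and modulus (J).
#' @param t_nm target half-thickness, nm.
#' @param exponent 2 or 3.
#' @return Scaled bending modulus, J.
#' @export
bending_modulus_from_thickness <- function(t_ref_nm, K_B_ref_J, t_nm, exponent = 3) {
  if (!exponent %in% c(2, 3))
    stop_invalid("thickness-scaling exponent must be 2 or 3")
  if (t_ref_nm <= 0 || K_B_ref_J <= 0 || any(t_nm <= 0))
    stop_invalid("bending_modulus_from_thickness requires positive arguments")
  K_B_ref_J * (t_nm / t_ref_nm)^exponent
}

#' Gating free-energy landscape over membrane curvature
#'
#' Evaluates [total_energy()] on a grid of mean curvatures for each bilayer,
#' under spherical bending of an isotropic inclusion.  Each curve is a
#' parabola in `C_L - C_P` sitting on the mismatch offset `G_H`, so its
#' minimum lies exactly at `C_L = C_P`; with the cubic thickness scaling of
#' `K_B` and symmetric mismatch magnitudes the curves order
#' zero < negative < positive mismatch at every grid curvature.
#'
#' @param bilayers a list of [bilayer_spec()] objects.
#' @param channel a [channel_spec()].
#' @param C_L_grid_per_nm curvature grid, 1/nm; defaults to 201 points
#'   spanning `C_P` symmetrically, `C_P +- 0.1`.
#' @return A data frame with columns `acyl_label`, `C_L_per_nm`, `G_H_J`,
#'   `G_B_J`, `G_J`, `G_kBT`, sorted by label then curvature.
#' @export
energy_landscape <- function(bilayers, channel, C_L_grid_per_nm = NULL) {
  stopifnot(inherits(channel, "channel_spec"))
  if (inherits(bilayers, "bilayer_spec")) bilayers <- list(bilayers)
  if (is.null(C_L_grid_per_nm))
    C_L_grid_per_nm <- seq(channel$C_P_per_nm - 0.1, channel$C_P_per_nm + 0.1,
                           length.out = 201)
  C_L_grid_per_nm <- sort(C_L_grid_per_nm)
  rows <- lapply(bilayers, function(bl) {
    e <- vapply(C_L_grid_per_nm, function(cl) {
      br <- total_energy(bl, channel, curvature_state(cl))
      c(br$G_H_J, br$G_B_J, br$G_J)
    }, numeric(3))
    data.frame(acyl_label = bl$acyl_label, C_L_per_nm = C_L_grid_per_nm,
               G_H_J = e[1, ], G_B_J = e[2, ], G_J = e[3, ],
               G_kBT = e[3, ] / .kBT)
  })
  do.call(rbind, rows)
}

#' Locate the minimum of each landscape curve
#'
#' @param landscape output of [energy_landscape()].
#' @return A data frame with one row per bilayer: `acyl_label`,
#'   `C_L_argmin_per_nm`, `G_min_J`.
#' @export
landscape_argmin <- function(landscape) {
  sp <- split(landscape, landscape$acyl_label)
  out <- lapply(sp, function(df) {
    i <- which.min(df$G_J)
    data.frame(acyl_label = df$acyl_label[1],
               C_L_argmin_per_nm = df$C_L_per_nm[i], G_min_J = df$G_J[i])
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Work done to bend a membrane patch
#'
#' \deqn{W = K_B A_0 / (2 R^2)} — the strain energy spent curving a patch of
#' initial area `A_0` to a sphere of radius `R`.  `W` is linear in `A_0` and
#' `K_B` and falls off as `1/R^2`, so thicker (stiffer) bilayers absorb more
#' work at the same target curvature.
#'
#' @param K_B_J bending modulus, J.
#' @param A_0_nm2 initial patch area, nm^2.
#' @param R_nm target radius of curvature, nm.
#' @return An object of class `bending_work` with fields `W_J`, `A_0_nm2`,
#'   `R_nm`, `K_B_J`.
#' @export
bending_work <- function(K_B_J, A_0_nm2, R_nm) {
  if (K_B_J <= 0 || A_0_nm2 <= 0 || R_nm <= 0)
    stop_invalid("bending_work requires K_B, A_0, R > 0")
  structure(list(W_J = K_B_J * A_0_nm2 / (2 * R_nm^2),
                 A_0_nm2 = A_0_nm2, R_nm = R_nm, K_B_J = K_B_J),
            class = "bending_work")
}

#' @export
print.bending_work <- function(x, ...) {
  cat(sprintf("W = %.4g J to bend A0 = %.4g nm^2 to R = %.4g nm (K_B = %.3g J)\n",
              x$W_J, x$A_0_nm2, x$R_nm, x$K_B_J))
  invisible(x)
}
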