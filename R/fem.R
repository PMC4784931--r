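# Axisymmetric small-strain linear elastostatics on bilinear quads with
# selective reduced integration (SRI): the shear/deviatoric part of the
# constitutive tensor is integrated with 2x2 Gauss quadrature, the
# volumetric (lambda) part with a single centre point.  This keeps the
# displacement formulation usable at near-incompressible Poisson ratios
# (the protein's nu = 0.5 is mapped to 0.499).
#
# Strain ordering: (e_rr, e_zz, e_thth, gamma_rz).  Coordinates in nm,
# moduli in Pa, so stiffness entries carry Pa*nm and displacements come out
# in nm.

.NU_CAP <- 0.499
.NU_LIPID <- 0.47
.E_LIPID <- 50e6   # effective Young's modulus of the fluid lipid laminate, Pa

#' Material map for a solver geometry
#'
#' Per-region Young's modulus and Poisson ratio.  The protein uses the
#' channel's `E` with `nu` capped at 0.499 (locking mitigation for the
#' incompressible limit).  The lipid laminate gets a single effective
#' modulus, 50 MPa by default, shared by all bilayers: the three study
#' membranes are the same hydrocarbon at different chain lengths, so
#' thickness is the only thing that distinguishes them mechanically.  At
#' the reference thickness this reproduces the areal-modulus scale
#' (`E T / (2(1-nu))` of about 0.2 N/m against the nominal 0.24 N/m), and
#' it makes the laminate's bending stiffness grow as the third power of
#' thickness, the accepted scaling of membrane bending rigidity.
#'
#' @param geom a `geometry2d`.
#' @param E_lipid_Pa effective lipid modulus, Pa.
#' @param nu_lipid lipid Poisson ratio.
#' @return A named list of regions, each with fields `E` (Pa) and `nu`.
#' @export
material_map <- function(geom, E_lipid_Pa = .E_LIPID, nu_lipid = .NU_LIPID) {
  stopifnot(inherits(geom, "geometry2d"))
  ch <- geom$channel
  list(protein = list(E = ch$E_Pa, nu = min(ch$nu, .NU_CAP)),
       core = list(E = E_lipid_Pa, nu = nu_lipid),
       head = list(E = E_lipid_Pa, nu = nu_lipid))
}

#' Create an empty load case
#'
#' A load case bundles (i) an initial in-plane stress field
#' `sigma_lat(r, z, region)` applied as `sigma_rr = sigma_thth` (Pa,
#' tension-positive), (ii) Dirichlet constraints, and (iii) boundary edge
#' tractions.  Helpers: [load_from_profile()], [impose_curvature()],
#' [add_bending_stress()], [add_edge_pressure()], [add_dirichlet()].
#'
#' @param mesh an `fe_mesh`.
#' @return An object of class `load_case`.
#' @export
load_case <- function(mesh) {
  structure(list(
    mesh_nel = nrow(mesh$elem),
    sigma_fns = list(),
    dirichlet = data.frame(node = integer(), dof = integer(), value = numeric()),
    tractions = list(),
    C_L_per_nm = 0
  ), class = "load_case")
}

#' Add a Dirichlet constraint set to a load case
#'
#' @param load a `load_case`.
#' @param node node indices.
#' @param dof 1 = radial, 2 = axial displacement.
#' @param value prescribed displacement, nm (recycled).
#' @return The updated `load_case`.  Later constraints on the same
#'   node/dof override earlier ones.
#' @export
add_dirichlet <- function(load, node, dof, value) {
  n <- max(length(node), length(dof), length(value))
  load$dirichlet <- rbind(load$dirichlet,
                          data.frame(node = rep_len(as.integer(node), n),
                                     dof = rep_len(as.integer(dof), n),
                                     value = rep_len(value, n)))
  load
}

#' Load a mesh with a lateral pressure profile
#'
#' Maps the bilayer's piecewise pressure profile onto the lipid elements as
#' an initial in-plane stress `sigma_rr = sigma_thth = -P(z')` (repulsive
#' pressure pushes; the protein carries no intrinsic stress).  In the morph
#' annulus the profile is evaluated in locally scaled coordinates so the
#' head, interfacial and tail regimes follow the deformed laminate layers.
#'
#' @param load a `load_case`.
#' @param mesh the `fe_mesh` the load belongs to.
#' @param profile a `pressure_profile`.
#' @param geom the `geometry2d` (defaults to the one in the mesh).
#' @return The updated `load_case`.
#' @export
load_from_profile <- function(load, mesh, profile, geom = mesh$geom) {
  t_ref <- profile$spec$t_nm
  force(profile); force(geom)
  f <- function(r, z, region) {
    out <- numeric(length(r))
    lip <- region != "protein"
    if (any(lip)) {
      t_loc <- core_half_thickness(geom, r[lip])
      zl <- z[lip]
      z_ref <- ifelse(abs(zl) <= t_loc, zl * t_ref / t_loc,
                      sign(zl) * (t_ref + (abs(zl) - t_loc)))
      out[lip] <- -profile_pressure_at(profile, z_ref)
    }
    out
  }
  load$sigma_fns <- c(load$sigma_fns, list(f))
  load
}

#' Add the bending-induced in-plane stress to a load case
#'
#' Local bending strains the laminate by `eps(z) = C_L z`; the associated
#' in-plane stress, with the areal modulus spread over the local laminate
#' thickness `T(r)`, is `sigma(z) = K_A C_L z / (2 T(r))`
#' (tension-positive).  In the morph annulus and at the protein wall the
#' local thickness follows the hydrophobically matched section, so the
#' near-field drive is set by the protein's hydrophobic length while the
#' far field carries the bilayer's own thickness.  Under inward bending
#' (`C_L < 0`) the cytoplasmic half of the lipid goes into tension and
#' pulls the pore wall open near the constriction.
#'
#' @param load a `load_case`.
#' @param mesh the `fe_mesh`.
#' @param C_L_per_nm signed curvature, 1/nm.
#' @param bilayer the `bilayer_spec` (defaults to the mesh geometry's).
#' @return The updated `load_case`.
#' @export
add_bending_stress <- function(load, mesh, C_L_per_nm, bilayer = mesh$geom$bilayer) {
  if (C_L_per_nm == 0) return(load)
  geom <- mesh$geom
  h <- bilayer$h_head_nm
  K_A <- bilayer$K_A_N_per_m
  f <- function(r, z, region) {
    T_loc_m <- if (is.null(geom)) (bilayer$d_l_nm + 2 * h) * 1e-9
               else 2 * (core_half_thickness(geom, r) + h) * 1e-9
    out <- K_A / (2 * T_loc_m) * C_L_per_nm * z
    out[region == "protein"] <- 0
    out
  }
  load$sigma_fns <- c(load$sigma_fns, list(f))
  load
}

#' Impose spherical curvature through the far-field boundary
#'
#' Prescribes the paraboloidal midplane deflection
#' `w(r) = -(C_L / 2) r^2` (the shallow approximation of a sphere of
#' radius `1/C_L`) as an axial displacement on all nodes of the outer 10%
#' annulus of the patch, and pins the radial displacement of the outermost
#' column.  `C_L > 0` bends the membrane outward (dome toward the
#' extracellular side, outer leaflet stretched).  With `C_L = 0` this
#' reduces to the resting far-field clamp, so resting and bent states share
#' one constrained dof set and superpose cleanly.
#'
#' @param load a `load_case`.
#' @param mesh the `fe_mesh`.
#' @param C_L_per_nm signed curvature, 1/nm.  Magnitudes above 0.1 warn
#'   (small-deflection validity).
#' @param band_fraction radial fraction of the patch used as the clamp
#'   band.
#' @return The updated `load_case`.
#' @export
impose_curvature <- function(load, mesh, C_L_per_nm = 0, band_fraction = 0.1) {
  if (abs(C_L_per_nm) > 0.1)
    warn_mscbend(sprintf("|C_L| = %.3g 1/nm exceeds the small-deflection bound 0.1",
                         abs(C_L_per_nm)), class = "mscbend_curvature_warning")
  R_out <- max(mesh$nodes[, 1])
  band <- which(mesh$nodes[, 1] >= (1 - band_fraction) * R_out - 1e-9)
  r_b <- mesh$nodes[band, 1]; z_b <- mesh$nodes[band, 2]
  # Kirchhoff plate-bending field: transverse paraboloid plus the fibre
  # rotation u_r = -z dw/dr, which carries the bending strain eps = C_L z
  # into the patch.
  load <- add_dirichlet(load, band, 2L, -(C_L_per_nm / 2) * r_b^2)
  load <- add_dirichlet(load, band, 1L, C_L_per_nm * r_b * z_b)
  load$C_L_per_nm <- C_L_per_nm
  load
}

#' Add a pressure traction along a node column
#'
#' Consistent nodal forces for a constant pressure acting in the radial
#' direction on the (vertical) boundary edge through the given ordered
#' nodes; positive pressure pushes toward +r.  Used by the thick-walled
#' cylinder benchmark.
#'
#' @param load a `load_case`.
#' @param mesh the `fe_mesh`.
#' @param nodes ordered node indices along the edge.
#' @param p_Pa pressure, Pa.
#' @return The updated `load_case`.
#' @export
add_edge_pressure <- function(load, mesh, nodes, p_Pa) {
  load$tractions <- c(load$tractions, list(list(nodes = as.integer(nodes), p = p_Pa)))
  load
}

# Lame parameters per element from the material map.
.element_moduli <- function(mesh, materials) {
  E <- numeric(nrow(mesh$elem)); nu <- numeric(nrow(mesh$elem))
  for (rg in unique(mesh$region)) {
    mat <- materials[[rg]]
    if (is.null(mat)) stop_invalid(sprintf("no material for region '%s'", rg))
    sel <- mesh$region == rg
    E[sel] <- mat$E; nu[sel] <- min(mat$nu, .NU_CAP)
  }
  mu <- E / (2 * (1 + nu))
  lambda <- E * nu / ((1 + nu) * (1 - 2 * nu))
  list(mu = mu, lambda = lambda)
}

#' Assemble the global stiffness matrix
#'
#' @param mesh an `fe_mesh`.
#' @param materials a [material_map()]-style list.
#' @return A sparse symmetric stiffness matrix (2 dof per node).
#' @export
assemble_stiffness <- function(mesh, materials) {
  nel <- nrow(mesh$elem)
  X <- matrix(mesh$nodes[mesh$elem, 1], ncol = 4)
  Y <- matrix(mesh$nodes[mesh$elem, 2], ncol = 4)
  mod <- .element_moduli(mesh, materials)
  mu <- mod$mu; lambda <- mod$lambda

  Ke <- matrix(0, nel, 64)   # element stiffness, column (p-1)*8+q
  gp <- 1 / sqrt(3)

  add_gp <- function(Ke, xi, eta, wgt, part) {
    N <- quad_N(xi, eta); dN <- quad_dN(xi, eta)
    J11 <- drop(X %*% dN[, 1]); J12 <- drop(Y %*% dN[, 1])
    J21 <- drop(X %*% dN[, 2]); J22 <- drop(Y %*% dN[, 2])
    detJ <- J11 * J22 - J12 * J21
    rg <- drop(X %*% N)
    dNx <- matrix(0, nel, 4); dNy <- matrix(0, nel, 4)
    for (a in 1:4) {
      dNx[, a] <- (dN[a, 1] * J22 - dN[a, 2] * J12) / detJ
      dNy[, a] <- (-dN[a, 1] * J21 + dN[a, 2] * J11) / detJ
    }
    Nr <- sweep(1 / matrix(rg, nel, 4), 2, N, "*")   # N_a / r
    scale <- 2 * pi * rg * detJ * wgt
    if (part == "mu") {
      c2 <- 2 * mu * scale; c1 <- mu * scale
      for (a in 1:4) for (b in 1:4) {
        pr <- 2 * a - 1; pz <- 2 * a; qr <- 2 * b - 1; qz <- 2 * b
        Ke[, (pr - 1) * 8 + qr] <- Ke[, (pr - 1) * 8 + qr] +
          c2 * (dNx[, a] * dNx[, b] + Nr[, a] * Nr[, b]) + c1 * dNy[, a] * dNy[, b]
        Ke[, (pz - 1) * 8 + qz] <- Ke[, (pz - 1) * 8 + qz] +
          c2 * dNy[, a] * dNy[, b] + c1 * dNx[, a] * dNx[, b]
        Ke[, (pr - 1) * 8 + qz] <- Ke[, (pr - 1) * 8 + qz] + c1 * dNy[, a] * dNx[, b]
        Ke[, (pz - 1) * 8 + qr] <- Ke[, (pz - 1) * 8 + qr] + c1 * dNx[, a] * dNy[, b]
      }
    } else {
      cl <- lambda * scale
      v <- matrix(0, nel, 8)
      for (a in 1:4) {
        v[, 2 * a - 1] <- dNx[, a] + Nr[, a]
        v[, 2 * a] <- dNy[, a]
      }
      for (p in 1:8) for (q in 1:8)
        Ke[, (p - 1) * 8 + q] <- Ke[, (p - 1) * 8 + q] + cl * v[, p] * v[, q]
    }
    Ke
  }

  for (xi in c(-gp, gp)) for (eta in c(-gp, gp))
    Ke <- add_gp(Ke, xi, eta, 1, "mu")
  Ke <- add_gp(Ke, 0, 0, 4, "lambda")

  eldof <- matrix(0L, nel, 8)
  eldof[, seq(1, 8, 2)] <- 2L * mesh$elem - 1L
  eldof[, seq(2, 8, 2)] <- 2L * mesh$elem

  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  ii <- rep(0L, nel * 64); jj <- ii; xx <- numeric(nel * 64)
  k <- 0L
  for (p in 1:8) for (q in 1:8) {
    idx <- k * nel + seq_len(nel)
    ii[idx] <- eldof[, p]; jj[idx] <- eldof[, q]
    xx[idx] <- Ke[, (p - 1) * 8 + q]
    k <- k + 1L
  }
  ndof <- 2L * nrow(mesh$nodes)
  K <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(ndof, ndof))
  Matrix::forceSymmetric((K + Matrix::t(K)) / 2)
}

# Consistent load vector from initial stresses and edge tractions.
.load_vector <- function(mesh, load) {
  nel <- nrow(mesh$elem)
  ndof <- 2L * nrow(mesh$nodes)
  f <- numeric(ndof)
  if (length(load$sigma_fns)) {
    X <- matrix(mesh$nodes[mesh$elem, 1], ncol = 4)
    Y <- matrix(mesh$nodes[mesh$elem, 2], ncol = 4)
    gp <- 1 / sqrt(3)
    for (xi in c(-gp, gp)) for (eta in c(-gp, gp)) {
      N <- quad_N(xi, eta); dN <- quad_dN(xi, eta)
      J11 <- drop(X %*% dN[, 1]); J12 <- drop(Y %*% dN[, 1])
      J21 <- drop(X %*% dN[, 2]); J22 <- drop(Y %*% dN[, 2])
      detJ <- J11 * J22 - J12 * J21
      rg <- drop(X %*% N); zg <- drop(Y %*% N)
      sig <- numeric(nel)
      for (fn in load$sigma_fns) sig <- sig + fn(rg, zg, mesh$region)
      scale <- 2 * pi * rg * detJ
      for (a in 1:4) {
        dNx <- (dN[a, 1] * J22 - dN[a, 2] * J12) / detJ
        # f_int = + B^T sigma0; equilibrium K u = -f_int
        contrib <- -(dNx + N[a] / rg) * sig * scale
        dofs <- 2L * mesh$elem[, a] - 1L
        f[dofs] <- f[dofs] + contrib
      }
    }
  }
  for (tr in load$tractions) {
    nd <- tr$nodes
    for (k in seq_len(length(nd) - 1L)) {
      n1 <- nd[k]; n2 <- nd[k + 1L]
      r1 <- mesh$nodes[n1, 1]; r2 <- mesh$nodes[n2, 1]
      L <- sqrt(sum((mesh$nodes[n2, ] - mesh$nodes[n1, ])^2))
      f[2L * n1 - 1L] <- f[2L * n1 - 1L] + tr$p * 2 * pi * L * (2 * r1 + r2) / 6
      f[2L * n2 - 1L] <- f[2L * n2 - 1L] + tr$p * 2 * pi * L * (r1 + 2 * r2) / 6
    }
  }
  f
}

# Resolved Dirichlet set: last writer wins per (node, dof).
.dirichlet_resolved <- function(load) {
  d <- load$dirichlet
  if (!nrow(d)) return(d)
  key <- paste(d$node, d$dof)
  d[!duplicated(key, fromLast = TRUE), , drop = FALSE]
}

#' Pre-factorised solver context
#'
#' Assembles and Cholesky-factorises the constrained stiffness matrix for a
#' fixed set of constrained dofs, so several load cases sharing one
#' constraint pattern (e.g. resting and bent states) can be solved against
#' a single factorisation.
#'
#' @param mesh an `fe_mesh`.
#' @param materials a material map.
#' @param load a `load_case` whose Dirichlet pattern defines the
#'   constrained dofs.
#' @return An object of class `fe_context`.
#' @export
fe_context <- function(mesh, materials, load) {
  K <- assemble_stiffness(mesh, materials)
  d <- .dirichlet_resolved(load)
  fixed <- sort(unique(2L * d$node - 2L + d$dof))
  ndof <- nrow(K)
  if (length(fixed) == 0)
    stop_invalid("no Dirichlet constraints: rigid-body mode (axial translation) unconstrained",
                 class = "mscbend_singular_system")
  free <- setdiff(seq_len(ndof), fixed)
  Kff <- K[free, free, drop = FALSE]
  fact <- tryCatch(Matrix::Cholesky(Matrix::forceSymmetric(Kff), LDL = FALSE),
                   error = function(e)
                     stop_invalid(paste0("singular stiffness system: ", conditionMessage(e),
                                         " (check rigid-body constraints)"),
                                  class = "mscbend_singular_system"))
  structure(list(K = K, fact = fact, fixed = fixed, free = free,
                 mesh = mesh, materials = materials),
            class = "fe_context")
}

#' Solve the axisymmetric elastostatic problem
#'
#' Direct sparse-Cholesky solution of `K u = f` under the load case's
#' Dirichlet constraints.  The constrained-system residual is verified to
#' be below `1e-10` times the load norm.
#'
#' @param mesh an `fe_mesh`.
#' @param materials a material map ([material_map()] or a hand-built list).
#' @param load a `load_case`.
#' @param context optional [fe_context()] (must share the mesh and
#'   constraint pattern); reused across load cases for speed.
#' @return An object of class `solution_field`: an n x 2 matrix of nodal
#'   displacements (u_r, u_z) in nm, with the mesh attached as an
#'   attribute.
#' @export
solve_equilibrium <- function(mesh, materials, load, context = NULL) {
  if (is.null(context)) context <- fe_context(mesh, materials, load)
  d <- .dirichlet_resolved(load)
  dofs <- 2L * d$node - 2L + d$dof
  if (!setequal(dofs, context$fixed))
    stop_invalid("load case constraint pattern does not match solver context")
  ndof <- nrow(context$K)
  u <- numeric(ndof)
  u[dofs] <- d$value
  f <- .load_vector(mesh, load)
  rhs <- f[context$free] - as.numeric(context$K[context$free, context$fixed, drop = FALSE] %*%
                                        u[context$fixed])
  u[context$free] <- as.numeric(Matrix::solve(context$fact, rhs))
  res <- as.numeric(context$K[context$free, , drop = FALSE] %*% u) - f[context$free]
  load_norm <- max(sqrt(sum(rhs^2)), sqrt(sum(f^2)), 1e-300)
  if (sqrt(sum(res^2)) > 1e-10 * load_norm && sqrt(sum(res^2)) > 1e-12)
    stop_invalid(sprintf("solver residual %.3g exceeds tolerance (load norm %.3g)",
                         sqrt(sum(res^2)), load_norm),
                 class = "mscbend_solver_error")
  field <- cbind(u_r = u[seq(1, ndof, 2)], u_z = u[seq(2, ndof, 2)])
  structure(field, class = c("solution_field", "matrix"),
            mesh = mesh, C_L_per_nm = load$C_L_per_nm)
}
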