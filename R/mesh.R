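# Structured conforming quadrilateral meshes for the axisymmetric solver.
#
# The domain is meshed as a logically rectangular grid of bilinear quads:
# radial "columns" run from the pore wall through the protein annulus and
# the lipid patch to R_out; vertical "rows" follow the laminate layers,
# scaling with the local core half-thickness so layer boundaries are always
# mesh lines.  Protein columns track the hourglass pore wall.

#' Generate the solver mesh
#'
#' Builds a conforming structured quad mesh for a [build_geometry()] domain
#' with at least 3 elements through each laminate layer and radial grading
#' away from the protein.
#'
#' @param geom a `geometry2d`.
#' @param h_target_nm target element size near the protein, nm.
#' @return An object of class `fe_mesh` with fields `nodes` (n x 2 matrix,
#'   r and z in nm), `elem` (nel x 4 node indices, counter-clockwise),
#'   `region` (per-element: `"protein"`, `"core"`, `"head"`), plus column /
#'   row bookkeeping used by the load and post-processing helpers.
#' @export
generate_mesh <- function(geom, h_target_nm = 0.25) {
  stopifnot(inherits(geom, "geometry2d"))
  if (!is.numeric(h_target_nm) || h_target_nm <= 0)
    stop_invalid("mesh target size h_target must be positive", class = "mscbend_mesh_error")
  bl <- geom$bilayer; ch <- geom$channel
  h <- bl$h_head_nm
  n_h <- max(3L, as.integer(ceiling(h / h_target_nm)))
  core_max <- max(bl$d_l_nm, ch$d_p_nm)
  n_c <- max(4L, 2L * as.integer(ceiling(core_max / (2 * h_target_nm))))

  # radial stations: protein columns (uniform in the wall-to-pore fraction),
  # then lipid columns graded geometrically out to R_out
  n_pr <- max(3L, as.integer(ceiling((ch$wall_radius_nm - ch$pore_outer_radius_nm) /
                                       h_target_nm)))
  xi <- seq(0, 1, length.out = n_pr + 1L)        # 0 = pore wall, 1 = protein wall
  r_band <- 0.9 * geom$R_out_nm       # clamp-band edge: always a mesh line
  r_lip <- geom$R_wall_nm
  w <- h_target_nm
  repeat {
    nxt <- r_lip[length(r_lip)] + w
    if (nxt >= r_band - 0.5 * w) break
    r_lip <- c(r_lip, nxt)
    w <- min(w * 1.2, 3 * h_target_nm)
  }
  n_band <- max(2L, ceiling((geom$R_out_nm - r_band) / (3 * h_target_nm)))
  r_lip <- c(r_lip, seq(r_band, geom$R_out_nm, length.out = n_band + 1L))

  n_col <- n_pr + length(r_lip)                  # protein cols + lipid cols
  n_row <- 2L * n_h + n_c + 1L

  # normalized through-core coordinate grid, with a grid line pinned at the
  # channel's constriction height so the gate is always a mesh node
  eta <- seq(-1, 1, length.out = n_c + 1L)
  eta_gate <- ch$constriction_z_nm / (ch$d_p_nm / 2)
  if (abs(eta_gate) < 1 && eta_gate != 0) {
    # pin the gate height, and its mirror image so the row layout stays
    # symmetric about the midplane
    i_gate <- which.min(abs(eta[-c(1L, n_c + 1L)] - eta_gate)) + 1L
    eta[i_gate] <- eta_gate
    eta[n_c + 2L - i_gate] <- -eta_gate
  }
  z_rows_for <- function(t_loc) {
    c(seq(-t_loc - h, -t_loc, length.out = n_h + 1L),
      (eta * t_loc)[-1L],
      seq(t_loc, t_loc + h, length.out = n_h + 1L)[-1L])
  }

  t_half_p <- ch$d_p_nm / 2
  z_protein <- z_rows_for(t_half_p)
  H2 <- geom$protein_half_height_nm

  nodes_r <- matrix(0, n_row, n_col)
  nodes_z <- matrix(0, n_row, n_col)
  col_t_loc <- numeric(n_col)
  for (ci in seq_len(n_col)) {
    if (ci <= n_pr) {
      r0 <- pore_radius_ref(ch, z_protein, H2)
      nodes_z[, ci] <- z_protein
      nodes_r[, ci] <- r0 + xi[ci] * (geom$R_wall_nm - r0)
      col_t_loc[ci] <- t_half_p
    } else {
      r_c <- r_lip[ci - n_pr]
      t_loc <- core_half_thickness(geom, r_c)
      nodes_z[, ci] <- z_rows_for(t_loc)
      nodes_r[, ci] <- r_c
      col_t_loc[ci] <- t_loc
    }
  }

  node_id <- matrix(seq_len(n_row * n_col), n_row, n_col)
  nodes <- cbind(r = as.vector(nodes_r), z = as.vector(nodes_z))

  nel <- (n_col - 1L) * (n_row - 1L)
  elem <- matrix(0L, nel, 4L)
  region <- character(nel)
  e <- 0L
  for (ci in seq_len(n_col - 1L)) {
    for (rj in seq_len(n_row - 1L)) {
      e <- e + 1L
      elem[e, ] <- c(node_id[rj, ci], node_id[rj, ci + 1L],
                     node_id[rj + 1L, ci + 1L], node_id[rj + 1L, ci])
      region[e] <- if (ci <= n_pr) "protein"
        else if (rj <= n_h || rj > n_h + n_c) "head" else "core"
    }
  }

  wall_ids <- node_id[, 1L]
  gate_row <- which.min(abs(z_protein - ch$constriction_z_nm))
  m <- structure(list(
    nodes = nodes, elem = elem, region = region,
    n_col = n_col, n_row = n_row, n_pr = n_pr, n_h = n_h, n_c = n_c,
    node_id = node_id, col_t_loc = col_t_loc,
    col_r = c(rep(NA_real_, n_pr), r_lip),
    gate_row = gate_row, gate_node = wall_ids[gate_row],
    geom = geom, h_target_nm = h_target_nm
  ), class = "fe_mesh")
  q <- mesh_quality(m)
  if (q$min_detJ <= 0)
    stop_invalid("unmeshable geometry: inverted element detected (non-positive Jacobian)",
                 class = "mscbend_mesh_error")
  m$quality <- q
  m
}

#' @export
print.fe_mesh <- function(x, ...) {
  cat(sprintf("FE mesh: %d nodes, %d bilinear quads (%d protein cols, %d x %d grid)\n",
              nrow(x$nodes), nrow(x$elem), x$n_pr, x$n_col, x$n_row))
  invisible(x)
}

# Corner-Jacobian and aspect-ratio summary, used to reject degenerate meshes.
mesh_quality <- function(mesh) {
  X <- matrix(mesh$nodes[mesh$elem, 1], ncol = 4)
  Y <- matrix(mesh$nodes[mesh$elem, 2], ncol = 4)
  gp <- 1 / sqrt(3)
  min_detJ <- Inf
  for (xi in c(-gp, gp)) for (eta in c(-gp, gp)) {
    dN <- quad_dN(xi, eta)
    J11 <- X %*% dN[, 1]; J12 <- Y %*% dN[, 1]
    J21 <- X %*% dN[, 2]; J22 <- Y %*% dN[, 2]
    min_detJ <- min(min_detJ, J11 * J22 - J12 * J21)
  }
  e1 <- sqrt((X[, 2] - X[, 1])^2 + (Y[, 2] - Y[, 1])^2)
  e2 <- sqrt((X[, 4] - X[, 1])^2 + (Y[, 4] - Y[, 1])^2)
  aspect <- pmax(e1, e2) / pmin(e1, e2)
  list(min_detJ = min_detJ, max_aspect = max(aspect))
}

# Bilinear quad shape functions and parent-space derivatives.
quad_N <- function(xi, eta) {
  c((1 - xi) * (1 - eta), (1 + xi) * (1 - eta),
    (1 + xi) * (1 + eta), (1 - xi) * (1 + eta)) / 4
}
quad_dN <- function(xi, eta) {
  cbind(c(-(1 - eta), (1 - eta), (1 + eta), -(1 + eta)) / 4,
        c(-(1 - xi), -(1 + xi), (1 + xi), (1 - xi)) / 4)
}

#' Structured rectangular annulus mesh
#'
#' A plain single-material mesh of the axisymmetric rectangle
#' `[r0, r1] x [z0, z1]`, used by the analytic solver benchmarks (patch
#' test, thick-walled cylinder) and available for ad-hoc experiments.
#'
#' @param r0_nm,r1_nm,z0_nm,z1_nm rectangle bounds, nm (`r0 > 0`).
#' @param nr,nz element counts.
#' @param region material tag for all elements.
#' @return An `fe_mesh`.
#' @export
annulus_mesh <- function(r0_nm, r1_nm, z0_nm, z1_nm, nr, nz, region = "plate") {
  stopifnot(r0_nm > 0, r1_nm > r0_nm, z1_nm > z0_nm, nr >= 1, nz >= 1)
  r <- seq(r0_nm, r1_nm, length.out = nr + 1L)
  z <- seq(z0_nm, z1_nm, length.out = nz + 1L)
  n_row <- nz + 1L; n_col <- nr + 1L
  node_id <- matrix(seq_len(n_row * n_col), n_row, n_col)
  nodes <- cbind(r = rep(r, each = n_row), z = rep(z, n_col))
  nel <- nr * nz
  elem <- matrix(0L, nel, 4L)
  e <- 0L
  for (ci in seq_len(nr)) for (rj in seq_len(nz)) {
    e <- e + 1L
    elem[e, ] <- c(node_id[rj, ci], node_id[rj, ci + 1L],
                   node_id[rj + 1L, ci + 1L], node_id[rj + 1L, ci])
  }
  structure(list(
    nodes = nodes, elem = elem, region = rep(region, nel),
    n_col = n_col, n_row = n_row, n_pr = 0L, n_h = 0L, n_c = nz,
    node_id = node_id, col_t_loc = rep((z1_nm - z0_nm) / 2, n_col),
    col_r = r, geom = NULL, h_target_nm = (r1_nm - r0_nm) / nr
  ), class = "fe_mesh")
}
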