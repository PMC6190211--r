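#' Steady incompressible Stokes flow with ICEO slip on the gate
#'
#' Solves \code{eta * laplacian(u) = grad(p)}, \code{div(u) = 0} with equal-order
#' P1/P1 elements stabilized by a Brezzi-Pitkaranta pressure term (an
#' inf-sup-stable formulation free of spurious pressure modes). Boundary
#' conditions: the prescribed tangential slip with zero normal velocity on
#' the gate, no slip on walls, and either a fully closed chamber (pressure
#' gauged to zero mean via a Lagrange multiplier) or, when
#' \code{inlet_mean_velocity > 0} (or \code{open_ends = TRUE}), a parabolic
#' profile of the stated mean on the left end wall and zero-traction outflow
#' on the right end wall. Inertia is neglected (Re << 1) and the flow driven
#' by the time-averaged slip is steady; the oscillatory 2-omega component is
#' ignored.
#'
#' @param mesh tagged \code{iceo_mesh}.
#' @param slip an \code{iceo_slip} computed on this same mesh (use
#'   \code{\link{zero_slip}} for an unenergized drive).
#' @param inlet_mean_velocity mean inlet velocity (m/s); 0 for a closed
#'   chamber.
#' @param open_ends force inlet/outlet-type end walls even at zero inlet
#'   velocity (used for superposition checks); default opens them only when
#'   \code{inlet_mean_velocity > 0}.
#' @param stab_gamma stabilization constant (dimensionless, default 0.05).
#' @return Object of class \code{iceo_flow}: nodal \code{ux}, \code{uy}
#'   (m/s), nodal \code{p} (Pa), \code{continuity_residual} (norm of the
#'   discrete continuity equations), \code{inlet_mean_velocity}.
#' @export
solve_stokes <- function(mesh, slip, inlet_mean_velocity = 0,
                         open_ends = NULL, stab_gamma = 0.05) {
  stopifnot(inherits(mesh, "iceo_mesh"), inherits(slip, "iceo_slip"))
  if (length(slip$s) != length(mesh$gate$s) ||
      any(abs(slip$s - mesh$gate$s) > 1e-12 + 1e-9 * mesh$geometry$length)) {
    stop("solve_stokes: slip profile does not match this mesh's gate facets")
  }
  if (is.null(open_ends)) open_ends <- inlet_mean_velocity > 0
  n <- nrow(mesh$nodes)
  geom <- tri_geom(mesh)
  K <- fem_stiffness(mesh, geom)
  Dv <- fem_divergence(mesh, geom)
  eta <- if (!is.null(slip$params)) slip$params$eta else 1e-3
  # pressure stabilization: gamma * h_K^2 / eta weighted stiffness
  hK2 <- 4 * abs(geom$area) / sqrt(3)
  t <- mesh$tri
  ii <- jj <- vv <- vector("list", 9L)
  k <- 0L
  for (a in 1:3) for (b in 1:3) {
    k <- k + 1L
    ii[[k]] <- t[, a]; jj[[k]] <- t[, b]
    vv[[k]] <- stab_gamma * hK2 / eta * geom$area *
      (geom$bx[, a] * geom$bx[, b] + geom$by[, a] * geom$by[, b])
  }
  Cs <- assemble_triplets(unlist(ii), unlist(jj), unlist(vv), n)

  A <- eta * K
  Z <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                            dims = c(n, n))
  closed <- !open_ends
  # unknown layout: [ux (n), uy (n), p (n), (lambda)]
  big <- rbind(cbind(A, Z, -Matrix::t(Dv$Dx)),
               cbind(Z, A, -Matrix::t(Dv$Dy)),
               cbind(-Dv$Dx, -Dv$Dy, -Cs))
  rhs <- numeric(3 * n)
  if (closed) {
    # gauge: integral of p over the domain = 0
    mvol <- as.numeric(Matrix::colSums(fem_mass(mesh, geom, lumped = TRUE)))
    col <- Matrix::sparseMatrix(i = 2 * n + seq_len(n), j = rep(1, n),
                                x = mvol, dims = c(3 * n, 1))
    big <- rbind(cbind(big, col),
                 cbind(Matrix::t(col), Matrix::sparseMatrix(
                   i = integer(0), j = integer(0), x = numeric(0),
                   dims = c(1, 1))))
    rhs <- c(rhs, 0)
  }

  # Dirichlet velocity data
  uval_x <- uval_y <- numeric(n)
  fixed <- rep(FALSE, n)
  wall_nodes <- tagged_nodes(mesh, "wall")
  fixed[wall_nodes] <- TRUE
  gate_bc <- slip_nodal_velocity(mesh, slip)
  fixed[gate_bc$nodes] <- TRUE
  uval_x[gate_bc$nodes] <- gate_bc$ux
  uval_y[gate_bc$nodes] <- gate_bc$uy
  # gate endpoints shared with no-slip boundary stay at rest
  uval_x[wall_nodes] <- 0; uval_y[wall_nodes] <- 0
  left <- tagged_nodes(mesh, c("left_electrode", "inlet"))
  right <- tagged_nodes(mesh, c("right_electrode", "outlet"))
  if (closed) {
    fixed[c(left, right)] <- TRUE
  } else {
    fixed[left] <- TRUE
    H <- mesh$geometry$height
    yy <- mesh$nodes[left, 2]
    uval_x[left] <- 1.5 * inlet_mean_velocity * (1 - (2 * yy / H - 1)^2)
    uval_y[left] <- 0
    corner <- left[yy < 1e-12 | yy > H - 1e-12]
    uval_x[corner] <- 0
    # right end: zero-traction outflow (natural), velocity free
  }

  ndof <- nrow(big)
  fix_idx <- c(which(fixed), n + which(fixed))
  fix_val <- c(uval_x[fixed], uval_y[fixed])
  free <- setdiff(seq_len(ndof), fix_idx)
  rhs_f <- rhs[free] - as.numeric(big[free, fix_idx, drop = FALSE] %*% fix_val)
  sol <- numeric(ndof)
  sol[fix_idx] <- fix_val
  sol[free] <- as.numeric(Matrix::solve(big[free, free, drop = FALSE], rhs_f))
  ux <- sol[seq_len(n)]; uy <- sol[n + seq_len(n)]; p <- sol[2 * n + seq_len(n)]

  cont_res <- as.numeric(-Dv$Dx %*% ux - Dv$Dy %*% uy - Cs %*% p)
  if (closed) cont_res <- cont_res + as.numeric(mvol * sol[3 * n + 1])
  structure(list(ux = ux, uy = uy, p = p,
                 continuity_residual = sqrt(sum(cont_res^2)),
                 inlet_mean_velocity = inlet_mean_velocity,
                 open_ends = open_ends, eta = eta),
            class = "iceo_flow")
}

# nodal Dirichlet velocity on the gate from a facet slip profile: each gate
# node takes the average of its adjacent facets' slip vectors; this is the
# mesh-size-limited regularization of the corner singularities (corner nodes
# shared with the no-slip wall are overridden to zero by the caller).
slip_nodal_velocity <- function(mesh, slip) {
  nodes <- unique(as.vector(slip$nodes))
  vx <- vy <- wt <- numeric(length(nodes))
  id <- match(as.vector(slip$nodes), nodes)
  sx <- rep(slip$slip * slip$tangent[, 1], 2L)
  sy <- rep(slip$slip * slip$tangent[, 2], 2L)
  for (k in seq_along(id)) {
    vx[id[k]] <- vx[id[k]] + sx[k]
    vy[id[k]] <- vy[id[k]] + sy[k]
    wt[id[k]] <- wt[id[k]] + 1
  }
  list(nodes = nodes, ux = vx / wt, uy = vy / wt)
}

#' Verify linear scaling of the Stokes solution in the slip amplitude
#'
#' Stokes flow is linear: scaling the slip boundary data by \code{alpha}
#' must scale the whole velocity field by \code{alpha}. This re-solves with a
#' scaled profile and reports the relative mismatch.
#'
#' @param mesh tagged \code{iceo_mesh}.
#' @param slip base \code{iceo_slip}.
#' @param alpha scale factors to test.
#' @return List with \code{alpha}, \code{rel_error} (per factor), and the
#'   base flow.
#' @export
flow_linearity_check <- function(mesh, slip, alpha = c(2, -1)) {
  base <- solve_stokes(mesh, slip)
  umax <- max(abs(c(base$ux, base$uy)))
  rel <- vapply(alpha, function(a) {
    s2 <- slip
    s2$slip <- a * slip$slip
    f2 <- solve_stokes(mesh, s2)
    max(abs(c(f2$ux - a * base$ux, f2$uy - a * base$uy))) /
      max(abs(a) * umax, .Machine$double.eps)
  }, numeric(1))
  list(alpha = alpha, rel_error = rel, base = base)
}

#' Volumetric flux through a vertical cross-section
#'
#' Trapezoidal integral of \code{ux} over the mesh nodes nearest to
#' \code{x = x0} (per unit channel width, m^2/s).
#'
#' @param flow an \code{iceo_flow}.
#' @param mesh the mesh it was solved on.
#' @param x0 axial position (m).
#' @return Net flux (m^2/s).
#' @export
section_flux <- function(flow, mesh, x0) {
  xs <- sort(unique(mesh$nodes[, 1]))
  xcol <- xs[which.min(abs(xs - x0))]
  sel <- which(abs(mesh$nodes[, 1] - xcol) < 1e-12 + 1e-9 * mesh$geometry$length)
  ord <- order(mesh$nodes[sel, 2])
  y <- mesh$nodes[sel[ord], 2]; u <- flow$ux[sel[ord]]
  sum(diff(y) * (u[-1] + u[-length(u)]) / 2)
}

#' Count vortices above the gate
#'
#' Samples the vertical velocity along a horizontal line just above the gate
#' and counts sign changes; a counter-rotating pair (down at the gate edges,
#' up over the center) shows two sign changes.
#'
#' @param flow an \code{iceo_flow}.
#' @param mesh the mesh it was solved on.
#' @param y0 sampling height (m); default one gate half-width above the gate.
#' @return Number of sign changes of \code{uy} across the gate span.
#' @export
vortex_sign_changes <- function(flow, mesh, y0 = NULL) {
  g <- mesh$geometry
  if (is.null(y0)) y0 <- g$gate_height + g$gate_width / 4
  ys <- sort(unique(mesh$nodes[, 2]))
  yrow <- ys[which.min(abs(ys - y0))]
  x0 <- g$gate_center_x - g$gate_width / 2
  x1 <- g$gate_center_x + g$gate_width / 2
  sel <- which(abs(mesh$nodes[, 2] - yrow) < 1e-12 + 1e-9 * g$height &
                 mesh$nodes[, 1] >= x0 & mesh$nodes[, 1] <= x1)
  ord <- order(mesh$nodes[sel, 1])
  v <- flow$uy[sel[ord]]
  v <- v[abs(v) > 1e-3 * max(abs(v))]
  sum(diff(sign(v)) != 0)
}
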