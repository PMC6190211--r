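#' Solve the quasi-static potential phasor with RC double-layer charging
#'
#' Solves \code{laplacian(phi) = 0} for the complex potential phasor in the
#' bulk, with Dirichlet data \code{V0} on the left driving electrode and 0 on
#' the right, insulation on the other walls, and the thin-double-layer RC
#' charging condition on the gate surface:
#' \deqn{-\sigma_f (n \cdot \nabla \phi) = j \omega C_D/(1+\delta) (V_0^g - \phi),}
#' with \code{n} pointing from the electrode into the bulk and
#' \code{C_D = eps_f / lambda_D} the Debye capacitance. The floating gate
#' potential phasor \code{V0g} is an additional unknown closed by charge
#' conservation (the integral of the charging current over the whole gate
#' surface vanishes); both are solved simultaneously in one bordered linear
#' system.
#'
#' @param mesh tagged \code{iceo_mesh}.
#' @param params \code{\link{physical_params}}.
#' @param drive \code{\link{drive_signal}} (\code{freq > 0}; the exact DC
#'   limit is served by the closed forms in \code{\link{dc_limit_slip}}).
#' @return Object of class \code{iceo_potential}: \code{phi} (complex nodal
#'   phasor, V), \code{V0g} (complex gate potential phasor, V),
#'   \code{charge_residual} (modulus of the net complex gate charging
#'   current, A/m per unit depth), plus \code{drive} and \code{params}.
#' @export
solve_potential_phasor <- function(mesh, params, drive) {
  stopifnot(inherits(mesh, "iceo_mesh"), inherits(params, "iceo_params"),
            inherits(drive, "iceo_drive"))
  if (!is.finite(drive$omega) || drive$omega <= 0) {
    stop("solve_potential_phasor: omega must be > 0; for the DC limit use ",
         "the analytic closed forms (dc_limit_slip)")
  }
  n <- nrow(mesh$nodes)
  K <- fem_stiffness(mesh)
  gate_rows <- which(mesh$edge_tag %in% c("gate", "functionalized"))
  Mg <- fem_boundary_mass(mesh, gate_rows)
  mg <- fem_boundary_load(mesh, gate_rows)
  Lg <- sum(mg)
  w <- drive$omega * params$C_D / (1 + params$delta)  # admittance density / j

  left <- tagged_nodes(mesh, "left_electrode")
  right <- tagged_nodes(mesh, "right_electrode")
  fixed <- c(left, right)
  phi_d <- numeric(n)
  phi_d[left] <- drive$V0
  free <- setdiff(seq_len(n), fixed)
  nf <- length(free)

  S <- params$sigma_f * K[free, free, drop = FALSE]
  Tm <- w * Mg[free, free, drop = FALSE]
  rhs_re <- as.numeric(-params$sigma_f * (K[free, fixed, drop = FALSE] %*%
                                            phi_d[fixed]))
  mgf <- mg[free]
  # complex system (S + jT) phi - j w mg V0g = rhs;  mg.phi - Lg V0g = 0
  # real block ordering: [Re(phi), Im(phi), Re(V0g), Im(V0g)]
  zc <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                             dims = c(nf, 1))
  col_re <- Matrix::Matrix(matrix(mgf * w, ncol = 1), sparse = TRUE)
  A <- rbind(
    cbind(S, -Tm, zc, col_re),
    cbind(Tm, S, -col_re, zc),
    cbind(Matrix::Matrix(matrix(mgf, nrow = 1), sparse = TRUE),
          Matrix::Matrix(matrix(0, 1, nf), sparse = TRUE),
          -Lg, 0),
    cbind(Matrix::Matrix(matrix(0, 1, nf), sparse = TRUE),
          Matrix::Matrix(matrix(mgf, nrow = 1), sparse = TRUE),
          0, -Lg))
  b <- c(rhs_re, numeric(nf), 0, 0)
  sol <- as.numeric(Matrix::solve(A, b))
  phi <- complex(real = phi_d, imaginary = 0)
  phi[free] <- complex(real = sol[seq_len(nf)],
                       imaginary = sol[nf + seq_len(nf)])
  V0g <- complex(real = sol[2 * nf + 1], imaginary = sol[2 * nf + 2])
  # net complex charging current over the gate (should vanish)
  cur <- 1i * w * (V0g * Lg - sum(as.numeric(mg) * phi))
  structure(list(phi = phi, V0g = V0g, charge_residual = Mod(cur),
                 drive = drive, params = params),
            class = "iceo_potential")
}

#' Limit solves of the gate boundary condition (analysis oracles)
#'
#' Solves the same Laplace problem with the gate replaced by its
#' low-frequency limit (a perfect insulator: zero normal flux) or its
#' high-frequency limit (an unscreened equipotential conductor whose floating
#' potential is fixed by zero net current). These serve as independent
#' references for the RC solution at \code{f << f_RC} and \code{f >> f_RC}.
#'
#' @param mesh tagged \code{iceo_mesh}.
#' @param drive \code{\link{drive_signal}}; only \code{V0} is used.
#' @param type \code{"insulator"} or \code{"conductor"}.
#' @return \code{iceo_potential} with a real-valued \code{phi}.
#' @export
solve_potential_limit <- function(mesh, drive, type = c("insulator", "conductor")) {
  type <- match.arg(type)
  n <- nrow(mesh$nodes)
  K <- fem_stiffness(mesh)
  left <- tagged_nodes(mesh, "left_electrode")
  right <- tagged_nodes(mesh, "right_electrode")
  fixed <- c(left, right)
  phi_d <- numeric(n)
  phi_d[left] <- drive$V0

  if (type == "insulator") {
    free <- setdiff(seq_len(n), fixed)
    phi <- phi_d
    rhs <- as.numeric(-K[free, fixed, drop = FALSE] %*% phi_d[fixed])
    phi[free] <- as.numeric(Matrix::solve(K[free, free, drop = FALSE], rhs))
    V0g <- NA_real_
  } else {
    # tie all gate nodes to one unknown; Galerkin reduction enforces zero
    # total current through the gate automatically
    gn <- tagged_nodes(mesh, c("gate", "functionalized"))
    free <- setdiff(seq_len(n), c(fixed, gn))
    nf <- length(free)
    map <- integer(n)
    map[free] <- seq_len(nf)
    map[gn] <- nf + 1L
    keep <- which(map > 0)
    P <- Matrix::sparseMatrix(i = keep, j = map[keep], x = 1,
                              dims = c(n, nf + 1L))
    Kr <- Matrix::t(P) %*% K %*% P
    rhs <- as.numeric(-Matrix::t(P) %*% (K[, fixed, drop = FALSE] %*% phi_d[fixed]))
    z <- as.numeric(Matrix::solve(Kr, rhs))
    phi <- phi_d
    phi[free] <- z[seq_len(nf)]
    phi[gn] <- z[nf + 1L]
    V0g <- z[nf + 1L]
  }
  structure(list(phi = complex(real = phi), V0g = complex(real = V0g),
                 charge_residual = 0, drive = drive, params = NULL,
                 limit = type),
            class = "iceo_potential")
}

#' Tangential and normal field phasors on the gate surface
#'
#' Traces \code{E = -grad(phi)} onto the gate facets: the tangential
#' component from the arclength derivative of the boundary potential
#' (tangent oriented with increasing gate arclength), the normal component
#' from the gradient in each facet's adjacent triangle (normal pointing out
#' of the fluid).
#'
#' @param field \code{iceo_potential} from \code{\link{solve_potential_phasor}}.
#' @param mesh the mesh the field was solved on.
#' @return List of class \code{iceo_surface_field}: \code{s} (facet midpoint
#'   arclength, m), \code{Et}, \code{En} (complex phasors, V/m),
#'   \code{length}, \code{tangent}.
#' @export
surface_fields <- function(field, mesh) {
  stopifnot(inherits(field, "iceo_potential"), inherits(mesh, "iceo_mesh"))
  gp <- mesh$gate
  phi <- field$phi
  Et <- -(phi[gp$nodes[, 2]] - phi[gp$nodes[, 1]]) / gp$length
  tri_id <- facet_triangles(mesh, gp$nodes)
  geom <- tri_geom(mesh)
  t <- mesh$tri
  gphi_x <- gphi_y <- complex(length(tri_id))
  for (a in 1:3) {
    gphi_x <- gphi_x + phi[t[tri_id, a]] * geom$bx[tri_id, a]
    gphi_y <- gphi_y + phi[t[tri_id, a]] * geom$by[tri_id, a]
  }
  # fluid-outward normal: tangent rotated -90 deg (boundary traversed with
  # the fluid on the left)
  nx <- gp$tangent[, 2]; ny <- -gp$tangent[, 1]
  En <- -(gphi_x * nx + gphi_y * ny)
  structure(list(s = gp$s, Et = Et, En = En, length = gp$length,
                 tangent = gp$tangent, functionalized = gp$functionalized),
            class = "iceo_surface_field")
}

# adjacent triangle of each boundary facet (row per facet node pair)
facet_triangles <- function(mesh, enodes) {
  t <- mesh$tri
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  tk <- c(key(t[, 1], t[, 2]), key(t[, 2], t[, 3]), key(t[, 3], t[, 1]))
  tid <- rep(seq_len(nrow(t)), 3L)
  m <- match(key(enodes[, 1], enodes[, 2]), tk)
  if (anyNA(m)) stop("facet_triangles: facet not found in triangulation")
  tid[m]
}

#' Double-layer RC relaxation frequency
#'
#' \code{f_RC = (1 + delta) * sigma_f / (2 * pi * C_D * R)} with
#' \code{C_D = eps_f / lambda_D}: the frequency at which the induced double
#' layer on a polarizable surface of macroscopic length scale \code{R}
#' charges. Below it the gate behaves as an insulator, above it as an
#' equipotential conductor.
#'
#' @param params \code{\link{physical_params}}.
#' @param R_length characteristic macroscopic length (m); the gate half-width
#'   is the conventional choice here.
#' @return Frequency in Hz.
#' @examples
#' rc_frequency(physical_params(), 25e-6)  # ~339 Hz at 1 mS/m
#' @export
rc_frequency <- function(params, R_length) {
  stopifnot(R_length > 0)
  (1 + params$delta) * params$sigma_f * params$lambda_D /
    (2 * pi * params$eps_f * R_length)
}
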