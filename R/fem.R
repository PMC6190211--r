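# Linear (P1) finite-element assembly on iceo_mesh triangulations.
# All matrices are Matrix::sparseMatrix ("dgCMatrix"); element loops are
# vectorized over all triangles at once.

# per-element geometry: areas and barycentric gradients
tri_geom <- function(mesh) {
  p <- mesh$nodes; t <- mesh$tri
  x1 <- p[t[, 1], 1]; y1 <- p[t[, 1], 2]
  x2 <- p[t[, 2], 1]; y2 <- p[t[, 2], 2]
  x3 <- p[t[, 3], 1]; y3 <- p[t[, 3], 2]
  det <- (x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1)
  area <- det / 2
  # grad of barycentric basis: b_i = (y_{i+1} - y_{i+2}, x_{i+2} - x_{i+1})/det
  bx <- cbind(y2 - y3, y3 - y1, y1 - y2) / det
  by <- cbind(x3 - x2, x1 - x3, x2 - x1) / det
  list(area = area, bx = bx, by = by)
}

assemble_triplets <- function(ii, jj, vv, n) {
  Matrix::sparseMatrix(i = as.vector(ii), j = as.vector(jj),
                       x = as.vector(vv), dims = c(n, n))
}

# stiffness K_ij = int grad(phi_i) . grad(phi_j)
fem_stiffness <- function(mesh, geom = tri_geom(mesh)) {
  t <- mesh$tri; n <- nrow(mesh$nodes)
  ii <- jj <- vv <- vector("list", 9L)
  k <- 0L
  for (a in 1:3) for (b in 1:3) {
    k <- k + 1L
    ii[[k]] <- t[, a]; jj[[k]] <- t[, b]
    vv[[k]] <- geom$area * (geom$bx[, a] * geom$bx[, b] +
                            geom$by[, a] * geom$by[, b])
  }
  assemble_triplets(unlist(ii), unlist(jj), unlist(vv), n)
}

# consistent mass M_ij = int phi_i phi_j  (area/12 off-diag, area/6 diag)
fem_mass <- function(mesh, geom = tri_geom(mesh), lumped = FALSE) {
  t <- mesh$tri; n <- nrow(mesh$nodes)
  if (lumped) {
    v <- rep(geom$area / 3, 3L)
    return(Matrix::sparseMatrix(i = as.vector(t), j = as.vector(t), x = v,
                                dims = c(n, n)))
  }
  ii <- jj <- vv <- vector("list", 9L)
  k <- 0L
  for (a in 1:3) for (b in 1:3) {
    k <- k + 1L
    ii[[k]] <- t[, a]; jj[[k]] <- t[, b]
    vv[[k]] <- geom$area * (if (a == b) 1 / 6 else 1 / 12)
  }
  assemble_triplets(unlist(ii), unlist(jj), unlist(vv), n)
}

# advection operators with SUPG (streamline upwinding) stabilization for the
# advection-dominated regime. ux, uy are nodal velocities; elementwise means
# are used. Returns:
#   G  - Galerkin advection, G_ij = int phi_i (u . grad phi_j)
#   S  - SUPG streamline stiffness, int tau (u.grad phi_i)(u.grad phi_j)
#   Ms - SUPG mass correction, int tau (u.grad phi_i) phi_j
fem_advection_supg <- function(mesh, ux, uy, D, geom = tri_geom(mesh),
                               supg = TRUE) {
  t <- mesh$tri; n <- nrow(mesh$nodes)
  uex <- (ux[t[, 1]] + ux[t[, 2]] + ux[t[, 3]]) / 3
  uey <- (uy[t[, 1]] + uy[t[, 2]] + uy[t[, 3]]) / 3
  speed <- sqrt(uex^2 + uey^2)
  hK <- sqrt(4 * abs(geom$area) / sqrt(3))   # nominal element size
  if (supg) {
    pe <- speed * hK / (2 * D)
    xi <- ifelse(pe > 1e-8, 1 / tanh(pe) - 1 / pe, pe / 3)
    tau <- ifelse(speed > 0, hK / (2 * pmax(speed, 1e-300)) * xi, 0)
  } else {
    tau <- numeric(nrow(t))
  }
  # u . grad(phi_a) per element, each basis
  ug <- lapply(1:3, function(a) uex * geom$bx[, a] + uey * geom$by[, a])
  iiN <- jjN <- vvG <- vvS <- vvM <- vector("list", 9L)
  k <- 0L
  for (a in 1:3) for (b in 1:3) {
    k <- k + 1L
    iiN[[k]] <- t[, a]; jjN[[k]] <- t[, b]
    vvG[[k]] <- geom$area * ug[[b]] / 3
    vvS[[k]] <- geom$area * tau * ug[[a]] * ug[[b]]
    vvM[[k]] <- geom$area * tau * ug[[a]] / 3
  }
  ii <- unlist(iiN); jj <- unlist(jjN)
  list(G = assemble_triplets(ii, jj, unlist(vvG), n),
       S = assemble_triplets(ii, jj, unlist(vvS), n),
       Ms = assemble_triplets(ii, jj, unlist(vvM), n))
}

# boundary mass matrix over a facet subset (rows of mesh$edges):
# int_Gamma phi_i phi_j ds ; lumped puts len/2 on each endpoint's diagonal
fem_boundary_mass <- function(mesh, edge_rows, lumped = FALSE) {
  n <- nrow(mesh$nodes)
  e <- mesh$edges[edge_rows, , drop = FALSE]
  d <- mesh$nodes[e[, 1], , drop = FALSE] - mesh$nodes[e[, 2], , drop = FALSE]
  len <- sqrt(rowSums(d^2))
  if (lumped) {
    return(Matrix::sparseMatrix(i = c(e[, 1], e[, 2]), j = c(e[, 1], e[, 2]),
                                x = c(len, len) / 2, dims = c(n, n)))
  }
  ii <- c(e[, 1], e[, 2], e[, 1], e[, 2])
  jj <- c(e[, 1], e[, 2], e[, 2], e[, 1])
  vv <- c(len / 3, len / 3, len / 6, len / 6)
  assemble_triplets(ii, jj, vv, n)
}

# boundary load vector: int_Gamma phi_i ds
fem_boundary_load <- function(mesh, edge_rows) {
  n <- nrow(mesh$nodes)
  e <- mesh$edges[edge_rows, , drop = FALSE]
  d <- mesh$nodes[e[, 1], , drop = FALSE] - mesh$nodes[e[, 2], , drop = FALSE]
  len <- sqrt(rowSums(d^2))
  v <- numeric(n)
  for (k in 1:2) {
    acc <- tapply(len / 2, e[, k], sum)
    v[as.integer(names(acc))] <- v[as.integer(names(acc))] + as.numeric(acc)
  }
  v
}

# nodes lying on facets with any of the given tags
tagged_nodes <- function(mesh, tags) {
  sel <- mesh$edge_tag %in% tags
  sort(unique(as.vector(mesh$edges[sel, , drop = FALSE])))
}

# divergence matrices for Stokes: Dx_ij = int q_i d(phi_j)/dx etc.
fem_divergence <- function(mesh, geom = tri_geom(mesh)) {
  t <- mesh$tri; n <- nrow(mesh$nodes)
  ii <- jj <- vx <- vy <- vector("list", 9L)
  k <- 0L
  for (a in 1:3) for (b in 1:3) {
    k <- k + 1L
    ii[[k]] <- t[, a]; jj[[k]] <- t[, b]
    vx[[k]] <- geom$area / 3 * geom$bx[, b]
    vy[[k]] <- geom$area / 3 * geom$by[, b]
  }
  list(Dx = assemble_triplets(unlist(ii), unlist(jj), unlist(vx), n),
       Dy = assemble_triplets(unlist(ii), unlist(jj), unlist(vy), n))
}
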