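#' @title Graded triangular meshes for the channel geometry
#' @description Internal helpers build tensor-product graded triangulations;
#'   the exported entry point is \code{\link{build_mesh}}.
#' @name mesh-internal
#' @keywords internal
NULL

# Base element sizes (m) at mesh_resolution = 1. Fine cells sit at the gate
# corners and along the bottom wall; the 3:1 cap on the local dx:dy ratio
# keeps every triangle's minimum angle above atan(1/3) ~ 18.4 deg.
MESH_H_MIN <- 2e-6
MESH_H_MAX <- 5e-6
FLAT_GATE_THRESHOLD <- 1e-6

# Node distribution on [a, b] with target size ha at a, hb at b, capped at
# hmax, growing linearly with distance from the refined ends. The base cell
# count is computed once from the size field; `res` rescales it so that
# doubling the resolution exactly doubles the cell count.
graded_nodes <- function(a, b, ha, hb, hmax, res = 1, slope = 0.35) {
  L <- b - a
  stopifnot(L > 0)
  tt <- seq(a, b, length.out = 512L)
  h <- pmin(hmax, pmin(ha + slope * (tt - a), hb + slope * (b - tt)))
  rho <- 1 / h
  cdf <- c(0, cumsum((rho[-1] + rho[-length(rho)]) / 2 * diff(tt)))
  n_base <- max(1L, as.integer(ceiling(cdf[length(cdf)] - 1e-9)))
  n <- max(1L, as.integer(ceiling(n_base * res - 1e-9)))
  q <- seq(0, cdf[length(cdf)], length.out = n + 1L)
  x <- stats::approx(cdf, tt, xout = q, ties = "ordered")$y
  x[1] <- a; x[n + 1L] <- b
  x
}

#' Build a tagged 2D mesh for a channel geometry
#'
#' Constructs a conforming triangulation of the rectangular channel, graded
#' toward the gate-electrode corners and the bottom wall. A gate shorter than
#' 1 um is collapsed to a flat segment of the bottom boundary; a taller gate
#' is meshed as a raised rectangular obstacle whose top and both sidewalls
#' carry the gate boundary condition. For a gate centered in the channel the
#' mesh (including triangle diagonals) is exactly mirror-symmetric about the
#' gate centerline, so discrete solutions inherit the continuous
#' (anti)symmetries.
#'
#' Boundary facets are tagged \code{left_electrode}, \code{right_electrode}
#' (the channel end walls, which double as flow inlet/outlet in flow-through
#' scenarios), \code{gate}, \code{functionalized} (the antibody-coated subset
#' of the gate), and \code{wall}.
#'
#' @param geometry an \code{\link{channel_geometry}} object.
#' @param resolution positive scale factor for mesh density; cell counts
#'   scale linearly, so doubling it doubles the facet count on every
#'   boundary.
#' @return An object of class \code{iceo_mesh}: list with \code{nodes}
#'   (n x 2 coordinates, m), \code{tri} (m x 3 counterclockwise
#'   connectivity), \code{edges} (boundary facets, 2 node indices each,
#'   ordered along the boundary path), \code{edge_tag}, \code{gate} (ordered
#'   gate-path facet table with arclength, tangents and functionalized flag),
#'   and the generating \code{geometry}/\code{resolution}.
#' @examples
#' m <- build_mesh(channel_geometry(), resolution = 0.5)
#' boundary_arclength(m, "gate")            # 50 um
#' boundary_arclength(m, "functionalized")  # 25 um
#' @export
build_mesh <- function(geometry, resolution = 1) {
  stopifnot(inherits(geometry, "iceo_geometry"))
  if (resolution <= 0) stop("build_mesh: resolution must be > 0")
  g <- geometry
  if (g$length <= 0 || g$height <= 0) stop("build_mesh: degenerate geometry")
  hmin <- MESH_H_MIN
  hmax <- MESH_H_MAX
  x0 <- g$gate_center_x - g$gate_width / 2
  x1 <- g$gate_center_x + g$gate_width / 2
  xc <- g$gate_center_x
  raised <- g$gate_height >= FLAT_GATE_THRESHOLD
  hg <- if (raised) g$gate_height else 0

  if (raised) {
    # keep the gate-layer cells near hmin and cap the global size at 2.5x
    # the realized layer cell height so the anisotropy bound (and with it
    # the angle floor) survives at any resolution
    ncell_g <- max(1L, round(hg / hmin))
    hgc_r <- hg / max(1L, as.integer(ceiling(ncell_g * resolution - 1e-9)))
    hmax <- min(hmax, 2.5 * hgc_r * resolution)
  }
  symmetric <- isTRUE(all.equal(xc, g$length / 2))
  xg_half <- c(graded_nodes(0, x0, hmax, hmin, hmax, resolution),
               graded_nodes(x0, xc, hmin, hmin, hmax, resolution)[-1])
  if (symmetric) {
    xs <- c(xg_half, 2 * xc - rev(xg_half)[-1])
  } else {
    xs <- c(xg_half,
            graded_nodes(xc, x1, hmin, hmin, hmax, resolution)[-1],
            graded_nodes(x1, g$length, hmin, hmax, hmax, resolution)[-1])
  }
  if (raised) {
    ys <- c(seq(0, hg, length.out = max(1L, as.integer(ceiling(ncell_g *
             resolution - 1e-9))) + 1L),
            graded_nodes(hg, g$height, hmin, hmax, hmax, resolution)[-1])
  } else {
    ys <- graded_nodes(0, g$height, hmin, hmax, hmax, resolution)
  }

  nx <- length(xs); ny <- length(ys)
  idx <- function(i, j) (j - 1L) * nx + i
  # cells (i, j) span [xs[i], xs[i+1]] x [ys[j], ys[j+1]]
  ci <- rep(seq_len(nx - 1L), times = ny - 1L)
  cj <- rep(seq_len(ny - 1L), each = nx - 1L)
  xmid <- (xs[ci] + xs[ci + 1L]) / 2
  ymid <- (ys[cj] + ys[cj + 1L]) / 2
  keep <- !(raised & xmid > x0 & xmid < x1 & ymid < hg)
  ci <- ci[keep]; cj <- cj[keep]
  xmid <- xmid[keep]
  a <- idx(ci, cj); b <- idx(ci + 1L, cj)
  cc <- idx(ci + 1L, cj + 1L); d <- idx(ci, cj + 1L)
  left <- xmid < xc
  # mirror-symmetric diagonal choice: "\" on the left, "/" on the right
  t1 <- ifelse(left, a, a); t2 <- ifelse(left, b, b)
  t3 <- ifelse(left, d, cc)
  s1 <- ifelse(left, b, a); s2 <- ifelse(left, cc, cc)
  s3 <- ifelse(left, d, d)
  tri <- rbind(cbind(t1, t2, t3), cbind(s1, s2, s3))

  nodes <- cbind(rep(xs, times = ny), rep(ys, each = nx))
  used <- sort(unique(as.vector(tri)))
  renum <- integer(nx * ny); renum[used] <- seq_along(used)
  tri <- matrix(renum[tri], ncol = 3L)
  nodes <- nodes[used, , drop = FALSE]

  # enforce counterclockwise orientation
  ax <- nodes[tri[, 1], 1]; ay <- nodes[tri[, 1], 2]
  bx <- nodes[tri[, 2], 1]; by <- nodes[tri[, 2], 2]
  cx <- nodes[tri[, 3], 1]; cy <- nodes[tri[, 3], 2]
  det2 <- (bx - ax) * (cy - ay) - (cx - ax) * (by - ay)
  flip <- det2 < 0
  if (any(flip)) tri[flip, c(2, 3)] <- tri[flip, c(3, 2)]

  edges <- boundary_edges(tri)
  mesh <- structure(list(nodes = nodes, tri = tri, edges = edges,
                         geometry = g, resolution = resolution,
                         raised = raised), class = "iceo_mesh")
  mesh$edge_tag <- tag_edges(mesh)
  mesh$gate <- gate_path(mesh)
  mesh
}

# undirected edges used by exactly one triangle
boundary_edges <- function(tri) {
  e <- rbind(tri[, c(1, 2)], tri[, c(2, 3)], tri[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  cnt <- table(key)
  single <- names(cnt)[cnt == 1L]
  e[key %in% single, , drop = FALSE]
}

tag_edges <- function(mesh) {
  g <- mesh$geometry
  n <- mesh$nodes
  x0 <- g$gate_center_x - g$gate_width / 2
  x1 <- g$gate_center_x + g$gate_width / 2
  hg <- if (mesh$raised) g$gate_height else 0
  tol <- 1e-12 + 1e-9 * g$length
  mx <- (n[mesh$edges[, 1], 1] + n[mesh$edges[, 2], 1]) / 2
  my <- (n[mesh$edges[, 1], 2] + n[mesh$edges[, 2], 2]) / 2
  tag <- rep("wall", nrow(mesh$edges))
  tag[mx < tol] <- "left_electrode"
  tag[mx > g$length - tol] <- "right_electrode"
  on_gate <- if (mesh$raised) {
    (my < hg + tol & my > tol & (abs(mx - x0) < tol | abs(mx - x1) < tol)) |
      (abs(my - hg) < tol & mx > x0 - tol & mx < x1 + tol)
  } else {
    my < tol & mx > x0 - tol & mx < x1 + tol
  }
  tag[on_gate] <- "gate"
  fs <- g$functionalized_span
  on_top <- if (mesh$raised) abs(my - hg) < tol else my < tol
  tag[on_gate & on_top & mx > fs[1] - tol & mx < fs[2] + tol] <- "functionalized"
  tag
}

# Ordered traversal of the gate boundary (arclength s increasing: up the left
# sidewall, across the top left-to-right, down the right sidewall; for a flat
# gate simply left-to-right). Tangent points along increasing s.
gate_path <- function(mesh) {
  g <- mesh$geometry
  is_g <- mesh$edge_tag %in% c("gate", "functionalized")
  eid <- which(is_g)
  if (length(eid) == 0) stop("gate_path: mesh has no gate facets")
  n <- mesh$nodes
  e <- mesh$edges[eid, , drop = FALSE]
  p1 <- n[e[, 1], , drop = FALSE]; p2 <- n[e[, 2], , drop = FALSE]
  mx <- (p1[, 1] + p2[, 1]) / 2; my <- (p1[, 2] + p2[, 2]) / 2
  x0 <- g$gate_center_x - g$gate_width / 2
  x1 <- g$gate_center_x + g$gate_width / 2
  tol <- 1e-9 * g$length
  side <- rep(2L, length(eid))              # top
  if (mesh$raised) {
    side[abs(mx - x0) < tol] <- 1L          # left sidewall
    side[abs(mx - x1) < tol] <- 3L          # right sidewall
  }
  ord <- order(side, ifelse(side == 1L, my, ifelse(side == 2L, mx, -my)))
  eid <- eid[ord]; side <- side[ord]
  e <- mesh$edges[eid, , drop = FALSE]
  p1 <- n[e[, 1], , drop = FALSE]; p2 <- n[e[, 2], , drop = FALSE]
  dx <- p2[, 1] - p1[, 1]; dy <- p2[, 2] - p1[, 2]
  len <- sqrt(dx^2 + dy^2)
  # orient each facet's node pair along increasing arclength
  want_dx <- ifelse(side == 2L, 1, 0)
  want_dy <- ifelse(side == 1L, 1, ifelse(side == 3L, -1, 0))
  flip <- dx * want_dx + dy * want_dy < 0
  e[flip, ] <- e[flip, c(2, 1)]
  dx[flip] <- -dx[flip]; dy[flip] <- -dy[flip]
  s_end <- cumsum(len)
  list(edge_id = eid,
       nodes = e,
       length = len,
       s = s_end - len / 2,
       tangent = cbind(dx / len, dy / len),
       functionalized = mesh$edge_tag[eid] == "functionalized",
       side = side)
}

#' Total arclength of a tagged boundary
#'
#' @param mesh an \code{iceo_mesh}.
#' @param tag boundary tag; \code{"gate"} includes the functionalized subset.
#' @return Summed facet length (m).
#' @export
boundary_arclength <- function(mesh, tag) {
  valid <- c("left_electrode", "right_electrode", "gate", "functionalized",
             "wall", "inlet", "outlet")
  if (!tag %in% valid) {
    stop("boundary_arclength: unknown tag '", tag, "'; valid: ",
         paste(valid, collapse = ", "))
  }
  sel <- if (tag == "gate") mesh$edge_tag %in% c("gate", "functionalized")
         else mesh$edge_tag == tag
  e <- mesh$edges[sel, , drop = FALSE]
  if (nrow(e) == 0) return(0)
  d <- mesh$nodes[e[, 1], , drop = FALSE] - mesh$nodes[e[, 2], , drop = FALSE]
  sum(sqrt(rowSums(d^2)))
}

#' Minimum interior angle over all mesh triangles (degrees)
#'
#' @param mesh an \code{iceo_mesh}.
#' @return Smallest triangle angle in degrees.
#' @export
mesh_min_angle <- function(mesh) {
  p <- mesh$nodes; t <- mesh$tri
  ang <- function(a, b, c) {
    u <- p[b, , drop = FALSE] - p[a, , drop = FALSE]
    v <- p[c, , drop = FALSE] - p[a, , drop = FALSE]
    num <- rowSums(u * v)
    den <- sqrt(rowSums(u^2) * rowSums(v^2))
    acos(pmax(-1, pmin(1, num / den)))
  }
  a1 <- ang(t[, 1], t[, 2], t[, 3])
  a2 <- ang(t[, 2], t[, 3], t[, 1])
  a3 <- ang(t[, 3], t[, 1], t[, 2])
  min(c(a1, a2, a3)) * 180 / pi
}

#' Export a mesh in Gmsh 2.2 ASCII format
#'
#' Writes nodes, boundary lines (physical tag = boundary tag index), and
#' triangles for inspection in standard mesh viewers.
#'
#' @param mesh an \code{iceo_mesh}.
#' @param path output file path (conventionally \code{.msh}).
#' @return \code{path}, invisibly.
#' @export
write_mesh_msh <- function(mesh, path) {
  tags <- c("left_electrode", "right_electrode", "gate", "functionalized",
            "wall", "inlet", "outlet")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("$MeshFormat", "2.2 0 8", "$EndMeshFormat"), con)
  writeLines(c("$PhysicalNames", as.character(length(tags) + 1L)), con)
  for (i in seq_along(tags)) {
    writeLines(sprintf('1 %d "%s"', i, tags[i]), con)
  }
  writeLines(sprintf('2 %d "fluid"', length(tags) + 1L), con)
  writeLines("$EndPhysicalNames", con)
  n <- nrow(mesh$nodes)
  writeLines(c("$Nodes", as.character(n)), con)
  writeLines(sprintf("%d %.12g %.12g 0", seq_len(n),
                     mesh$nodes[, 1], mesh$nodes[, 2]), con)
  writeLines("$EndNodes", con)
  ne <- nrow(mesh$edges); nt <- nrow(mesh$tri)
  writeLines(c("$Elements", as.character(ne + nt)), con)
  etag <- match(mesh$edge_tag, tags)
  writeLines(sprintf("%d 1 2 %d %d %d %d", seq_len(ne), etag, etag,
                     mesh$edges[, 1], mesh$edges[, 2]), con)
  ft <- length(tags) + 1L
  writeLines(sprintf("%d 2 2 %d %d %d %d %d", ne + seq_len(nt), ft, ft,
                     mesh$tri[, 1], mesh$tri[, 2], mesh$tri[, 3]), con)
  writeLines("$EndElements", con)
  invisible(path)
}

#' Grid-independence check for a scalar quantity of interest
#'
#' Recomputes a quantity at successive mesh resolutions and reports the
#' relative change between the last two levels; results are conventionally
#' accepted when that change is below 2 percent.
#'
#' @param scenario an \code{iceo_scenario}.
#' @param qoi function of a scenario returning one number (it should build
#'   its own mesh from \code{scenario$mesh_resolution}).
#' @param resolutions increasing vector of resolutions to test.
#' @param tol acceptance threshold on the relative change (default 0.02).
#' @return List with \code{resolutions}, \code{values}, \code{rel_change},
#'   \code{converged}.
#' @export
grid_independence <- function(scenario, qoi, resolutions = c(1, 1.5),
                              tol = 0.02) {
  stopifnot(length(resolutions) >= 2, all(diff(resolutions) > 0))
  vals <- vapply(resolutions, function(r) {
    sc <- scenario
    sc$mesh_resolution <- r
    qoi(sc)
  }, numeric(1))
  k <- length(vals)
  rel <- abs(vals[k] - vals[k - 1]) / max(abs(vals[k]), .Machine$double.eps)
  list(resolutions = resolutions, values = vals, rel_change = rel,
       converged = rel < tol)
}

#' @export
print.iceo_mesh <- function(x, ...) {
  cat(sprintf("iceo_mesh: %d nodes, %d triangles, %d boundary facets (%s gate)\n",
              nrow(x$nodes), nrow(x$tri), nrow(x$edges),
              if (x$raised) "raised" else "flat"))
  cat("  boundary tags:", paste(sprintf("%s=%d", names(table(x$edge_tag)),
                                        table(x$edge_tag)), collapse = ", "), "\n")
  invisible(x)
}
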