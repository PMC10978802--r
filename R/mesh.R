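#' Structured hexahedral mesh of the layered cylinder
#'
#' Discretizes a [build_geometry()] cylinder into 8-node hexahedra using an
#' O-grid cross-section (square core, radial transition to the pseudocoelom
#' boundary, then one structured ring per annular compartment) extruded along
#' the cylinder axis. Two mirror symmetries are exploited: the axial-vertical
#' plane through the contact point (x = 0) and the transverse-vertical plane
#' at mid-length (y = 0), so the mesh covers a quarter of the body (half the
#' cross-section, half the length). Circumferential and axial spacings are
#' graded towards the contact pole (top generator, +z) and the support pole
#' (-z) so that the minimum edge near the indenter is at most 0.4 um at the
#' default refinement.
#'
#' @param geometry a `worm_geometry` from [build_geometry()].
#' @param refinement integer refinement level, >= 0. Level 0 is a coarse mesh
#'   for calibration searches, level 1 (default) resolves a 0.4 um minimum
#'   contact edge, level 2 is used for convergence checks.
#' @param max_edge_contact_um edge-size contract at the contact zone for
#'   refinement >= 1; an error reports the achieved minimum edge if violated.
#' @param params optional named list overriding individual discretization
#'   parameters of the refinement level (`n`, `nr_core`, `h_ring`,
#'   `pole_arc`, `ax_first`, `ax_ratio`) for mesh-sensitivity studies.
#' @return An object of class `hex_mesh`: `nodes` (N x 3, um; axis = y,
#'   indentation = -z), `elems` (E x 8 connectivity, 1-based), `compartment`
#'   (character per element), `node_sets` (`symmetry_x`, `symmetry_y`,
#'   `contact_surface`, `base_support`, `outer_surface`), `node_area_um2`
#'   (tributary outer-surface area per node), `min_edge_contact_um`,
#'   `refinement`, and the originating `geometry`.
#' @examples
#' mesh <- generate_mesh(build_geometry(), refinement = 0)
#' mesh
#' @export
generate_mesh <- function(geometry, refinement = 1L,
                          max_edge_contact_um = 0.4, params = NULL) {
  stopifnot(inherits(geometry, "worm_geometry"))
  if (!is.numeric(refinement) || length(refinement) != 1 || refinement < 0)
    stop("'refinement' must be a single integer >= 0", call. = FALSE)
  p <- mesh_params(as.integer(refinement))
  if (!is.null(params)) p <- modifyList(p, params)

  comp <- geometry$compartments
  r1 <- comp$r_outer[1]
  r_out <- geometry$radius_um

  phi <- phi_distribution(p$n, p$pole_arc / r_out)
  m <- length(phi) - 1                      # circumferential intervals (= 4n)

  sec <- cross_section(phi, p, comp)
  nn2 <- nrow(sec$nodes)

  y <- axial_stations(geometry$length_um / 2, p$ax_first, p$ax_ratio)
  nlay <- length(y) - 1

  nodes <- matrix(0, nn2 * length(y), 3)
  for (k in seq_along(y)) {
    idx <- (k - 1L) * nn2 + seq_len(nn2)
    nodes[idx, 1] <- sec$nodes[, 1]
    nodes[idx, 2] <- y[k]
    nodes[idx, 3] <- sec$nodes[, 2]
  }

  nq <- nrow(sec$quads)
  elems <- matrix(0L, nq * nlay, 8)
  compartment <- character(nq * nlay)
  for (k in seq_len(nlay)) {
    off_lo <- (k - 1L) * nn2
    off_hi <- k * nn2
    rows <- (k - 1L) * nq + seq_len(nq)
    # zeta = -1 face on the larger-y section keeps reference Jacobians positive
    elems[rows, ] <- cbind(sec$quads + off_hi, sec$quads + off_lo)
    compartment[rows] <- sec$quad_comp
  }

  detJ <- mesh_jacobians_cpp(nodes, elems)
  if (any(detJ <= 0)) {
    bad <- which(apply(detJ <= 0, 1, any))
    stop(sprintf("mesh generation produced %d element(s) with non-positive Jacobian (first: %d)",
                 length(bad), bad[1]), call. = FALSE)
  }

  tol <- 1e-9
  r2d <- sqrt(nodes[, 1]^2 + nodes[, 3]^2)
  on_outer <- abs(r2d - r_out) < 1e-6 * r_out
  node_sets <- list(
    symmetry_x = which(abs(nodes[, 1]) < tol),
    symmetry_y = which(abs(nodes[, 2]) < tol),
    contact_surface = which(on_outer & nodes[, 3] > 0),
    base_support = which(on_outer & nodes[, 3] < 0),
    outer_surface = which(on_outer)
  )

  mesh <- structure(list(nodes = nodes, elems = elems,
                         compartment = compartment,
                         node_sets = node_sets,
                         refinement = as.integer(refinement),
                         geometry = geometry,
                         cache = new.env(parent = emptyenv())),
                    class = "hex_mesh")
  mesh$node_area_um2 <- outer_surface_areas(mesh, m, length(y))
  mesh$min_edge_contact_um <- contact_min_edge(mesh)
  if (refinement >= 1 && mesh$min_edge_contact_um > max_edge_contact_um)
    stop(sprintf("contact-zone minimum edge %.3f um exceeds the %.2f um contract",
                 mesh$min_edge_contact_um, max_edge_contact_um), call. = FALSE)
  mesh
}

# Per-level discretization parameters. Levels beyond 2 continue halving.
mesh_params <- function(level) {
  if (level <= 2L) {
    list(n = c(5L, 8L, 12L)[level + 1L],
         nr_core = c(3L, 4L, 6L)[level + 1L],
         h_ring = c(1.0, 0.5, 0.35)[level + 1L],
         pole_arc = c(0.6, 0.2, 0.1)[level + 1L],
         ax_first = c(0.6, 0.35, 0.15)[level + 1L],
         ax_ratio = c(1.7, 1.5, 1.35)[level + 1L])
  } else {
    f <- 2^(level - 2L)
    list(n = 12L * f, nr_core = 6L * f, h_ring = 0.35 / f,
         pole_arc = 0.1 / f, ax_first = 0.15 / f, ax_ratio = 1.35)
  }
}

# Circumferential node angles on [-pi/2, pi/2] (x >= 0 half-section),
# geometrically clustered at both poles with a target pole spacing (radians).
phi_distribution <- function(n, dphi_min) {
  half <- 2L * n                      # intervals per quadrant pair
  target <- pi / 2
  if (dphi_min * half >= target) {
    sizes <- rep(target / half, half)
  } else {
    f <- function(g) dphi_min * (g^half - 1) / (g - 1) - target
    g <- uniroot(f, c(1 + 1e-9, 10), tol = 1e-12)$root
    sizes <- dphi_min * g^(seq_len(half) - 1)
    sizes <- sizes * target / sum(sizes)
  }
  upper <- pi / 2 - rev(cumsum(c(0, sizes)))   # 0 .. pi/2, clustered at pi/2
  upper[1] <- 0
  upper[length(upper)] <- pi / 2
  c(-rev(upper[-1]), upper)
}

# Graded axial stations 0 .. half_length, fine at the contact plane y = 0.
axial_stations <- function(half_length, first, ratio) {
  h <- first
  inc <- c()
  while (sum(inc) < half_length) {
    inc <- c(inc, h)
    h <- h * ratio
  }
  inc <- inc * half_length / sum(inc)
  c(0, cumsum(inc))
}

# Half-disc cross-section in the (x, z) plane: square core (transfinite
# interpolation), radial transition to the first interface, then structured
# rings for each annular compartment. Quads are counter-clockwise in (x, z).
cross_section <- function(phi, p, comp) {
  n <- p$n
  m <- length(phi) - 1                      # = 4n
  r1 <- comp$r_outer[1]
  a <- 0.5 * r1

  # square-boundary point in the direction of angle phi (ray from origin)
  sq_pt <- function(ph) {
    cph <- cos(ph); sph <- sin(ph)
    if (abs(sph) <= cph) c(a, a * sph / cph) else c(a * cph / abs(sph), sign(sph) * a)
  }
  q <- t(vapply(phi, sq_pt, numeric(2)))
  q[1, ] <- c(0, -a); q[m + 1, ] <- c(0, a)

  # core grid (i = 0..n, j = 0..2n) by transfinite interpolation; outer
  # boundary (bottom, right, top) carries the path nodes q_k
  ni <- n + 1L; nj <- 2L * n + 1L
  core_x <- matrix(0, ni, nj); core_z <- matrix(0, ni, nj)
  left <- cbind(0, seq(-a, a, length.out = nj))
  bottom <- q[1:(n + 1L), , drop = FALSE]              # i = 0..n at j = 0
  right <- q[(n + 1L):(3L * n + 1L), , drop = FALSE]   # j = 0..2n at i = n
  top <- q[(4L * n + 1L):(3L * n + 1L), , drop = FALSE] # i = 0..n at j = 2n
  P00 <- bottom[1, ]; P10 <- bottom[n + 1L, ]
  P01 <- top[1, ]; P11 <- top[n + 1L, ]
  for (i in seq_len(ni)) {
    u <- (i - 1) / n
    for (j in seq_len(nj)) {
      v <- (j - 1) / (2 * n)
      pt <- (1 - u) * left[j, ] + u * right[j, ] +
        (1 - v) * bottom[i, ] + v * top[i, ] -
        ((1 - u) * (1 - v) * P00 + u * (1 - v) * P10 +
           (1 - u) * v * P01 + u * v * P11)
      core_x[i, j] <- pt[1]; core_z[i, j] <- pt[2]
    }
  }

  nodes <- cbind(as.vector(core_x), as.vector(core_z))
  core_id <- matrix(seq_len(ni * nj), ni, nj)

  # boundary path ids k = 0..4n (bottom edge, right edge, top edge reversed)
  path_id <- c(core_id[, 1], core_id[ni, 2:nj], core_id[n:1, nj])

  add_nodes <- function(nodes, xy) {
    ids <- nrow(nodes) + seq_len(nrow(xy))
    list(nodes = rbind(nodes, xy), ids = ids)
  }

  quads <- NULL; quad_comp <- NULL
  ring_quads <- function(inner_ids, outer_ids) {
    k <- seq_len(m)
    cbind(inner_ids[k], outer_ids[k], outer_ids[k + 1], inner_ids[k + 1])
  }

  # core quads (CCW in (x, z))
  qi <- rep(seq_len(n), 2 * n); qj <- rep(seq_len(2 * n), each = n)
  quads <- cbind(core_id[cbind(qi, qj)], core_id[cbind(qi + 1, qj)],
                 core_id[cbind(qi + 1, qj + 1)], core_id[cbind(qi, qj + 1)])
  quad_comp <- rep(comp$name[1], nrow(quads))

  # transition layers: square boundary -> circle r1 along rays, graded so
  # the outermost layer (under the contact) is the thinnest
  circ <- cbind(cos(phi), sin(phi))
  prev_ids <- path_id
  sizes <- 1.7^rev(seq_len(p$nr_core) - 1)
  tseq <- cumsum(sizes) / sum(sizes)
  for (l in seq_len(p$nr_core)) {
    t <- tseq[l]
    xy <- (1 - t) * q + t * r1 * circ
    xy[1, 1] <- 0; xy[m + 1, 1] <- 0
    res <- add_nodes(nodes, xy)
    nodes <- res$nodes
    quads <- rbind(quads, ring_quads(prev_ids, res$ids))
    quad_comp <- c(quad_comp, rep(comp$name[1], m))
    prev_ids <- res$ids
  }

  # annular compartments
  if (nrow(comp) > 1) {
    for (ci in 2:nrow(comp)) {
      width <- comp$r_outer[ci] - comp$r_inner[ci]
      nr <- max(1L, ceiling(width / p$h_ring))
      for (l in seq_len(nr)) {
        r <- comp$r_inner[ci] + width * l / nr
        xy <- r * circ
        xy[1, 1] <- 0; xy[m + 1, 1] <- 0
        res <- add_nodes(nodes, xy)
        nodes <- res$nodes
        quads <- rbind(quads, ring_quads(prev_ids, res$ids))
        quad_comp <- c(quad_comp, rep(comp$name[ci], m))
        prev_ids <- res$ids
      }
    }
  }

  list(nodes = nodes, quads = quads, quad_comp = quad_comp,
       outer_ids = prev_ids)
}

# Tributary areas of the outer-surface facets, accumulated per node.
outer_surface_areas <- function(mesh, ...) {
  out <- mesh$node_sets$outer_surface
  area <- numeric(nrow(mesh$nodes))
  # order outer nodes per axial station by angle
  nod <- mesh$nodes
  yv <- round(nod[out, 2], 9)
  ring <- lapply(sort(unique(yv)), function(y) {
    ids <- out[yv == y]
    ids[order(atan2(nod[ids, 3], nod[ids, 1]))]
  })
  # rings are identically ordered copies; consecutive stations form facets
  for (k in seq_len(length(ring) - 1)) {
    r1 <- ring[[k]]; r2 <- ring[[k + 1]]
    for (kk in seq_len(length(r1) - 1)) {
      idx <- c(r1[kk], r1[kk + 1], r2[kk + 1], r2[kk])
      a1 <- tri_area(nod[idx[1], ], nod[idx[2], ], nod[idx[3], ])
      a2 <- tri_area(nod[idx[1], ], nod[idx[3], ], nod[idx[4], ])
      area[idx] <- area[idx] + (a1 + a2) / 4
    }
  }
  area
}

tri_area <- function(p1, p2, p3) {
  v1 <- p2 - p1; v2 <- p3 - p1
  cr <- c(v1[2] * v2[3] - v1[3] * v2[2],
          v1[3] * v2[1] - v1[1] * v2[3],
          v1[1] * v2[2] - v1[2] * v2[1])
  0.5 * sqrt(sum(cr^2))
}

# Minimum element edge length among elements near the contact pole.
contact_min_edge <- function(mesh) {
  r_out <- mesh$geometry$radius_um
  cand <- which(mesh$nodes[, 3] > 0.95 * r_out & mesh$nodes[, 2] < 0.1 * r_out)
  if (!length(cand)) return(NA_real_)
  touch <- which(matrix(mesh$elems %in% cand, nrow(mesh$elems)) |> rowSums() > 0)
  edges <- rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 1),
                 c(5, 6), c(6, 7), c(7, 8), c(8, 5),
                 c(1, 5), c(2, 6), c(3, 7), c(4, 8))
  min_e <- Inf
  for (e in touch) {
    xe <- mesh$nodes[mesh$elems[e, ], ]
    d <- sqrt(rowSums((xe[edges[, 1], ] - xe[edges[, 2], ])^2))
    min_e <- min(min_e, d)
  }
  min_e
}

#' @export
print.hex_mesh <- function(x, ...) {
  cat("Hexahedral mesh (quarter-symmetric layered cylinder)\n")
  cat(sprintf("  %d nodes, %d elements, refinement level %d\n",
              nrow(x$nodes), nrow(x$elems), x$refinement))
  tab <- table(x$compartment)
  for (nm in names(tab)) cat(sprintf("    %-20s %d elements\n", nm, tab[[nm]]))
  cat(sprintf("  min contact-zone edge: %.3f um\n", x$min_edge_contact_um))
  invisible(x)
}

#' Assemble a `hex_mesh` from raw arrays
#'
#' Low-level constructor for hand-built meshes (single-element benchmarks,
#' patch tests). No symmetry sets or surface areas are attached unless given.
#'
#' @param nodes N x 3 coordinates (um).
#' @param elems E x 8 connectivity (1-based).
#' @param compartment compartment label per element (recycled).
#' @param node_sets optional named list of node-index sets.
#' @param node_area_um2 optional tributary surface area per node (um^2).
#' @return A `hex_mesh`.
#' @export
hex_mesh <- function(nodes, elems, compartment = "bulk",
                     node_sets = list(), node_area_um2 = NULL) {
  nodes <- as.matrix(nodes); storage.mode(nodes) <- "double"
  elems <- as.matrix(elems); storage.mode(elems) <- "integer"
  defaults <- list(symmetry_x = integer(0), symmetry_y = integer(0),
                   contact_surface = integer(0), base_support = integer(0),
                   outer_surface = integer(0))
  node_sets <- modifyList(defaults, node_sets)
  structure(list(nodes = nodes, elems = elems,
                 compartment = rep(compartment, length.out = nrow(elems)),
                 node_sets = node_sets,
                 node_area_um2 = node_area_um2 %||% numeric(nrow(nodes)),
                 min_edge_contact_um = NA_real_,
                 refinement = NA_integer_, geometry = NULL,
                 cache = new.env(parent = emptyenv())),
            class = "hex_mesh")
}

#' Mesh quality summary
#'
#' Reports reference-configuration Jacobian determinants at all quadrature
#' points, element aspect ratios (longest/shortest edge), element counts per
#' compartment, and lists any inverted (non-positive Jacobian) elements.
#'
#' @param mesh a `hex_mesh` (or any list with `nodes`, `elems` and optionally
#'   `compartment`).
#' @return An object of class `mesh_quality`: list with `min_jacobian`,
#'   `max_jacobian`, `aspect_ratio` (per element), `inverted` (element
#'   indices), `n_elements`, `per_compartment`.
#' @export
mesh_quality_report <- function(mesh) {
  detJ <- mesh_jacobians_cpp(mesh$nodes, mesh$elems)
  edges <- rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 1),
                 c(5, 6), c(6, 7), c(7, 8), c(8, 5),
                 c(1, 5), c(2, 6), c(3, 7), c(4, 8))
  ar <- apply(mesh$elems, 1, function(conn) {
    xe <- mesh$nodes[conn, ]
    d <- sqrt(rowSums((xe[edges[, 1], ] - xe[edges[, 2], ])^2))
    max(d) / min(d)
  })
  inverted <- which(apply(detJ <= 0, 1, any))
  per_comp <- if (!is.null(mesh$compartment)) table(mesh$compartment) else NULL
  structure(list(min_jacobian = min(detJ), max_jacobian = max(detJ),
                 jacobian = detJ, aspect_ratio = ar, inverted = inverted,
                 n_elements = nrow(mesh$elems), per_compartment = per_comp),
            class = "mesh_quality")
}

#' @export
print.mesh_quality <- function(x, ...) {
  cat("Mesh quality report\n")
  cat(sprintf("  elements: %d; Jacobian range [%.4g, %.4g]\n",
              x$n_elements, x$min_jacobian, x$max_jacobian))
  cat(sprintf("  aspect ratio: max %.2f (median %.2f)\n",
              max(x$aspect_ratio), median(x$aspect_ratio)))
  if (length(x$inverted))
    cat("  INVERTED elements:", paste(x$inverted, collapse = ", "), "\n")
  else cat("  no inverted elements\n")
  invisible(x)
}

#' Export a mesh (and optional nodal fields) as legacy-ASCII VTK
#'
#' Writes an unstructured-grid `.vtk` file (cell type 12, hexahedron) for
#' visualization in ParaView. Optional point data (e.g. a displacement field)
#' is appended as vectors or scalars.
#'
#' @param mesh a `hex_mesh`.
#' @param path output file path.
#' @param point_data named list of nodal fields: each a vector (scalar field)
#'   or N x 3 matrix (vector field).
#' @return `path`, invisibly.
#' @export
write_mesh_vtk <- function(mesh, path, point_data = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  n <- nrow(mesh$nodes); e <- nrow(mesh$elems)
  writeLines(c("# vtk DataFile Version 3.0",
               "nemaindent hexahedral mesh", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", n)), con)
  write.table(format(mesh$nodes, digits = 10, scientific = FALSE,
                     trim = TRUE),
              con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  writeLines(sprintf("CELLS %d %d", e, 9 * e), con)
  write.table(cbind(8L, mesh$elems - 1L), con, row.names = FALSE,
              col.names = FALSE, quote = FALSE)
  writeLines(sprintf("CELL_TYPES %d", e), con)
  writeLines(as.character(rep(12L, e)), con)
  writeLines(sprintf("CELL_DATA %d", e), con)
  writeLines(c("SCALARS compartment int 1", "LOOKUP_TABLE default"), con)
  writeLines(as.character(as.integer(factor(mesh$compartment))), con)
  if (!is.null(point_data) && length(point_data)) {
    writeLines(sprintf("POINT_DATA %d", n), con)
    for (nm in names(point_data)) {
      fld <- point_data[[nm]]
      if (is.matrix(fld) && ncol(fld) == 3) {
        writeLines(sprintf("VECTORS %s double", nm), con)
        write.table(format(fld, digits = 10, scientific = FALSE, trim = TRUE),
                    con, row.names = FALSE, col.names = FALSE, quote = FALSE)
      } else {
        writeLines(c(sprintf("SCALARS %s double 1", nm),
                     "LOOKUP_TABLE default"), con)
        writeLines(format(fld, digits = 10, trim = TRUE), con)
      }
    }
  }
  invisible(path)
}

#' Save or restore solver state
#'
#' Round-trips internal state (mesh, displacement field, solution history) via
#' R's native serialization.
#'
#' @param state any R object (typically the result of [newton_solve()] or
#'   [run_afm_indentation()] together with its mesh).
#' @param path file path.
#' @return `save_state` returns `path` invisibly; `load_state` returns the
#'   restored object.
#' @export
save_state <- function(state, path) {
  saveRDS(state, path)
  invisible(path)
}

#' @rdname save_state
#' @export
load_state <- function(path) readRDS(path)
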