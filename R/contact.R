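#' Analytic rigid contact surfaces
#'
#' The indenter is a rigid sphere (default radius 5 um, the 10 um glass bead
#' of the AFM probe); the support is a rigid frictionless plane (the agarose
#' bed the animal rests on). Both are represented analytically; contact is
#' enforced by a node-to-rigid-surface penalty.
#'
#' @param radius_um sphere radius in um (> 0).
#' @param center sphere center, length-3 (um).
#' @return An object of class `rigid_sphere` / `rigid_plane`.
#' @examples
#' s <- rigid_sphere(5, c(0, 0, 20))
#' contact_gap(c(0, 0, 14), s)   # 1 um outside
#' @export
rigid_sphere <- function(radius_um = 5, center = c(0, 0, 0)) {
  check_positive(radius_um, "radius_um")
  stopifnot(length(center) == 3)
  structure(list(radius = radius_um, center = as.numeric(center)),
            class = c("rigid_sphere", "rigid_surface"))
}

#' @param z_um plane height: the plane is `z = z_um` with outward normal +z
#'   (material is expected above the plane).
#' @rdname rigid_sphere
#' @export
rigid_plane <- function(z_um) {
  structure(list(z = z_um), class = c("rigid_plane", "rigid_surface"))
}

#' Signed gap between nodes and a rigid surface
#'
#' Positive outside the surface, zero on it, negative when penetrating. The
#' gradient of the gap with respect to the nodal position is the unit outward
#' normal of the surface.
#'
#' @param x numeric length-3 position or an n x 3 matrix of positions (um).
#' @param surface a `rigid_sphere` or `rigid_plane`.
#' @return Numeric vector of signed distances (um).
#' @export
contact_gap <- function(x, surface) {
  if (!is.matrix(x)) x <- matrix(x, 1)
  if (inherits(surface, "rigid_sphere")) {
    d <- sqrt((x[, 1] - surface$center[1])^2 +
                (x[, 2] - surface$center[2])^2 +
                (x[, 3] - surface$center[3])^2)
    d - surface$radius
  } else if (inherits(surface, "rigid_plane")) {
    x[, 3] - surface$z
  } else stop("unknown rigid surface", call. = FALSE)
}

#' Penalty contact residual and tangent contributions
#'
#' For every candidate node with non-positive gap the penalty law applies a
#' purely normal (frictionless) force `penalty * |gap|` directed along the
#' outward surface normal, together with its consistent tangent (including
#' the curvature term for spherical surfaces).
#'
#' @param x n x 3 matrix of current nodal positions (um).
#' @param surface a `rigid_sphere` or `rigid_plane`.
#' @param penalty penalty stiffness per node, nN/um; scalar or length-n
#'   vector (typically a pressure-type penalty times the tributary area).
#' @param curvature if `TRUE`, include the surface-curvature term of the
#'   exact contact linearization. The default `FALSE` keeps only the
#'   normal-direction dyad, which is positive semidefinite: for shallow
#'   penetrations (|gap| well below the sphere radius) the omitted term is a
#'   percent-level perturbation, and a definite tangent lets the sparse
#'   Cholesky solver run without indefinite-matrix fallbacks.
#' @return List with `gaps` (um), `active` (logical), `force` (n x 3, nN, the
#'   force exerted on each node), `K` (3 x 3 x n tangent blocks to be added
#'   to the stiffness), and `total_force` (nN, the reaction transmitted to
#'   the rigid surface along the indentation axis z).
#' @export
contact_contribution <- function(x, surface, penalty, curvature = FALSE) {
  if (!is.matrix(x)) x <- matrix(x, 1)
  n <- nrow(x)
  if (length(penalty) == 1) penalty <- rep(penalty, n)
  stopifnot(all(penalty > 0), length(penalty) == n)
  g <- contact_gap(x, surface)
  active <- g <= 0
  force <- matrix(0, n, 3)
  K <- array(0, c(3, 3, n))
  if (any(active)) {
    if (inherits(surface, "rigid_sphere")) {
      for (idx in which(active)) {
        dx <- x[idx, ] - surface$center
        d <- sqrt(sum(dx^2))
        nrm <- dx / d
        k <- penalty[idx]
        force[idx, ] <- -k * g[idx] * nrm
        K[, , idx] <- k * tcrossprod(nrm)
        if (curvature)
          K[, , idx] <- K[, , idx] +
            k * g[idx] / d * (diag(3) - tcrossprod(nrm))
      }
      if (any(g[active] < -0.1 * surface$radius))
        warning("contact penetration exceeds 10% of the sphere radius; increase the penalty")
    } else {
      for (idx in which(active)) {
        force[idx, 3] <- -penalty[idx] * g[idx]
        K[3, 3, idx] <- penalty[idx]
      }
    }
  }
  list(gaps = g, active = active, force = force, K = K,
       total_force = -sum(force[, 3]))
}
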