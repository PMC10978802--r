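#' Force-displacement curve container
#'
#' A processed (or simulated) indentation record: tip-sample indentation
#' depth in nm against force in nN, plus acquisition metadata.
#'
#' @param displacement_nm non-negative, strictly increasing depths (nm).
#' @param force_nN forces (nN), same length (>= 2 samples).
#' @param meta named list of metadata (`source` one of
#'   `"simulated" | "measured" | "synthetic"`, `set_force_nN`, `treatment`,
#'   `moduli_kPa`, ...).
#' @return An object of class `fd_curve` (a data.frame with a `meta`
#'   attribute).
#' @export
fd_curve <- function(displacement_nm, force_nN, meta = list()) {
  stopifnot(length(displacement_nm) == length(force_nN),
            length(displacement_nm) >= 2)
  if (any(displacement_nm < 0))
    stop("displacement must be non-negative", call. = FALSE)
  if (any(diff(displacement_nm) <= 0))
    stop("displacement must be strictly increasing", call. = FALSE)
  out <- data.frame(displacement_nm = as.numeric(displacement_nm),
                    force_nN = as.numeric(force_nN))
  attr(out, "meta") <- meta
  class(out) <- c("fd_curve", "data.frame")
  out
}

#' @export
print.fd_curve <- function(x, ...) {
  m <- attr(x, "meta")
  cat(sprintf("F-D curve (%s): %d samples, depth %.1f-%.1f nm, force up to %.2f nN\n",
              m$source %||% "unknown", nrow(x), min(x$displacement_nm),
              max(x$displacement_nm), max(x$force_nN)))
  if (!is.null(m$moduli_kPa))
    cat(sprintf("  moduli (cuticle, muscle, pseudocoelom): %s kPa\n",
                paste(signif(m$moduli_kPa, 4), collapse = ", ")))
  invisible(x)
}

#' @export
plot.fd_curve <- function(x, ..., xlab = "indentation depth (nm)",
                          ylab = "force (nN)", type = "l") {
  plot(x$displacement_nm, x$force_nN, xlab = xlab, ylab = ylab,
       type = type, ...)
}

#' Simulate an AFM indentation into a force-displacement curve
#'
#' Runs the three-compartment finite-element model under displacement-
#' controlled descent of the rigid spherical indenter (placed at mid-length
#' on the top generator of the cylinder) and records the reaction force at
#' every converged load step. The simulation terminates either when the
#' reaction reaches `set_force_nN` (AFM set-force protocol; the terminal
#' point is interpolated to the set force exactly) or at `max_depth_nm`.
#' Indentation depth is the rigid-sphere descent after first touch; the
#' cantilever-compliance correction belongs to the processing pipeline, not
#' to the simulator.
#'
#' @param geometry a [build_geometry()] object.
#' @param moduli Young's moduli in kPa: either a length-3 vector in the order
#'   (cuticle+hypodermis, muscle, pseudocoelom), a named vector keyed by
#'   compartment, or a single value for homogeneous geometries.
#' @param protocol list with exactly one of `set_force_nN` (default
#'   `list(set_force_nN = 450)`) or `max_depth_nm`.
#' @param refinement mesh refinement level (see [generate_mesh()]); ignored
#'   when `mesh` is supplied.
#' @param mesh optional precomputed `hex_mesh` (saves meshing time across
#'   repeated simulations).
#' @param nu Poisson ratio (near-incompressible default 0.49).
#' @param indenter_radius_um rigid-sphere radius (default 5 um, the 10 um
#'   AFM bead).
#' @param step_depth_nm descent increment per load step (nm).
#' @param config a [solver_config()].
#' @param penalty_factor contact penalty scaling, see [fe_model()].
#' @param treatment optional label stored in the curve metadata.
#' @param keep_state if `TRUE`, attach the final displacement field and mesh
#'   to the result (attribute `"sim"`).
#' @return An [fd_curve()] with `meta$source = "simulated"`. The attribute
#'   `"sim"` carries diagnostics: strain/penalty energy (nN um), external
#'   work, convergence flag, and (optionally) the final state.
#' @examples
#' \donttest{
#' crv <- run_afm_indentation(moduli = c(150, 1200, 840), refinement = 0)
#' depth_at_force(crv, 450)
#' }
#' @export
run_afm_indentation <- function(geometry = build_geometry(),
                                moduli,
                                protocol = list(set_force_nN = 450),
                                refinement = 1L,
                                mesh = NULL,
                                nu = 0.49,
                                indenter_radius_um = 5,
                                step_depth_nm = 50,
                                config = solver_config(),
                                penalty_factor = 50,
                                treatment = NULL,
                                keep_state = FALSE) {
  if (sum(c("set_force_nN", "max_depth_nm") %in% names(protocol)) != 1)
    stop("protocol must specify exactly one of 'set_force_nN' or 'max_depth_nm'",
         call. = FALSE)
  if (is.null(mesh)) mesh <- generate_mesh(geometry, refinement)
  E <- normalize_moduli(moduli, mesh)
  if (any(E <= 0)) stop("moduli must be positive", call. = FALSE)
  model <- fe_model(mesh, E, nu = nu, penalty_factor = penalty_factor)

  r_out <- max(sqrt(mesh$nodes[, 1]^2 + mesh$nodes[, 3]^2))
  z0 <- r_out + indenter_radius_um
  plane <- rigid_plane(-r_out)
  cand_top <- mesh$node_sets$contact_surface
  cand_bot <- mesh$node_sets$base_support
  sym_factor <- 4  # two mirror planes -> quarter model

  set_force <- protocol$set_force_nN
  max_depth_um <- if (is.null(protocol$max_depth_nm)) {
    0.9 * geometry$radius_um  # safety cap
  } else protocol$max_depth_nm / .nm_per_um

  u <- matrix(0, nrow(mesh$nodes), 3)
  depth <- 0
  step0 <- step_depth_nm / .nm_per_um
  step <- step0
  dep <- 0; frc <- 0
  work <- 0
  cutbacks <- 0
  failed <- FALSE
  last <- NULL
  while (TRUE) {
    d_try <- min(depth + step, max_depth_um)
    contacts <- list(
      list(surface = rigid_sphere(indenter_radius_um,
                                  c(0, 0, z0 - d_try)),
           candidates = cand_top),
      list(surface = plane, candidates = cand_bot))
    st <- newton_step(model, u, contacts, config)
    if (!st$converged) {
      cutbacks <- cutbacks + 1
      if (cutbacks > config$max_cutbacks) { failed <- TRUE; break }
      step <- step * config$step_cutback
      next
    }
    cutbacks <- 0
    u <- st$u
    f_new <- sym_factor * st$reactions[1]
    work <- work + 0.5 * (tail(frc, 1) + f_new) * (d_try - depth)
    depth <- d_try
    dep <- c(dep, depth)
    frc <- c(frc, f_new)
    last <- st
    step <- min(step * 1.3, step0)
    if (!is.null(set_force) && f_new >= set_force) break
    if (depth >= max_depth_um - 1e-12) break
  }

  if (length(dep) < 2)
    stop("indentation solver failed before completing a single load step",
         call. = FALSE)
  dep_nm <- dep * .nm_per_um
  if (!failed && !is.null(set_force) && tail(frc, 1) >= set_force &&
      length(frc) >= 2) {
    n <- length(frc)
    f1 <- frc[n - 1]; f2 <- frc[n]
    d_star <- dep_nm[n - 1] + (set_force - f1) / (f2 - f1) *
      (dep_nm[n] - dep_nm[n - 1])
    dep_nm <- c(dep_nm[seq_len(n - 1)], d_star)
    frc <- c(frc[seq_len(n - 1)], set_force)
  }

  meta <- list(source = "simulated", moduli_kPa = E, nu = nu,
               set_force_nN = set_force, treatment = treatment,
               refinement = mesh$refinement,
               indenter_radius_um = indenter_radius_um)
  crv <- fd_curve(dep_nm, frc, meta)
  attr(crv, "sim") <- list(
    converged = !failed,
    # totals for the full body (quarter-model values times the symmetry factor)
    energy_nNum = if (is.null(last)) NA else sym_factor * last$energy,
    pen_energy_nNum = if (is.null(last)) NA else sym_factor * last$pen_energy,
    work_nNum = work,
    state = if (keep_state) list(u = u, mesh = mesh) else NULL)
  if (failed)
    warning(sprintf("solver failed at depth %.0f nm; returning partial curve",
                    depth * .nm_per_um))
  crv
}

# map user moduli to a named per-compartment vector
normalize_moduli <- function(moduli, mesh) {
  comps <- unique(mesh$compartment)
  if (!is.null(names(moduli)) && all(comps %in% names(moduli)))
    return(unlist(moduli)[comps])
  if (length(moduli) == 1)
    return(setNames(rep(as.numeric(moduli), length(comps)), comps))
  if (length(moduli) == 3 &&
      all(sort(comps) == sort(c("cuticle_hypodermis", "muscle", "pseudocoelom"))))
    return(c(cuticle_hypodermis = as.numeric(moduli[1]),
             muscle = as.numeric(moduli[2]),
             pseudocoelom = as.numeric(moduli[3]))[comps])
  stop("cannot map 'moduli' onto mesh compartments: ",
       paste(comps, collapse = ", "), call. = FALSE)
}

#' Interpolate the indentation depth at a given force
#'
#' Monotone piecewise-linear interpolation of depth against force.
#'
#' @param curve an [fd_curve()].
#' @param force_nN force at which to read off the depth; must lie within the
#'   curve's force range.
#' @return Depth in nm.
#' @examples
#' crv <- fd_curve(c(0, 100, 200), c(0, 10, 40))
#' depth_at_force(crv, 25)  # 150 nm
#' @export
depth_at_force <- function(curve, force_nN) {
  stopifnot(inherits(curve, "fd_curve"), length(force_nN) == 1)
  f <- curve$force_nN
  if (force_nN < min(f) || force_nN > max(f))
    stop(sprintf("force %.3g nN outside curve range [%.3g, %.3g]",
                 force_nN, min(f), max(f)), call. = FALSE)
  approx(f, curve$displacement_nm, xout = force_nN, ties = "ordered")$y
}
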