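#' Quasi-static solver configuration
#'
#' @param n_load_steps number of load increments over the loading path.
#' @param newton_tol relative residual-norm tolerance for Newton convergence.
#' @param max_newton_iters Newton iteration cap per load step.
#' @param step_cutback multiplicative cutback factor applied to the load
#'   increment when a step fails to converge, in (0, 1).
#' @param max_cutbacks number of successive cutbacks before giving up.
#' @return An object of class `solver_config`.
#' @export
solver_config <- function(n_load_steps = 25, newton_tol = 1e-8,
                          max_newton_iters = 20, step_cutback = 0.5,
                          max_cutbacks = 8) {
  stopifnot(n_load_steps >= 1, newton_tol > 0,
            step_cutback > 0, step_cutback < 1, max_newton_iters >= 1)
  structure(list(n_load_steps = n_load_steps, newton_tol = newton_tol,
                 max_newton_iters = max_newton_iters,
                 step_cutback = step_cutback, max_cutbacks = max_cutbacks),
            class = "solver_config")
}

#' Assemble a finite-element model from a mesh and per-compartment moduli
#'
#' Precomputes everything the Newton solver needs: per-element hyperelastic
#' constants, the sparse-stiffness pattern, the symmetry-plane constraints
#' and the contact penalty per candidate node.
#'
#' @param mesh a `hex_mesh`.
#' @param E named vector of Young's moduli (kPa), one entry per compartment
#'   name appearing in the mesh, or a single value for homogeneous models.
#' @param nu Poisson ratio shared by all compartments (near-incompressible
#'   default 0.49).
#' @param penalty_factor dimensionless scaling of the pressure-type contact
#'   penalty `penalty_factor * max(E) / h_contact` (per area), converted to a
#'   nodal stiffness through the tributary surface area. The default is set
#'   so that doubling it changes the indenter force by well under 1%.
#' @param extra_fixed additional global dof indices (`3*(node-1)+component`)
#'   to treat as prescribed; their values are supplied per load step through
#'   the `dirichlet` argument of [newton_solve()].
#' @return An object of class `fe_model`.
#' @export
fe_model <- function(mesh, E, nu = 0.49, penalty_factor = 50,
                     extra_fixed = integer(0)) {
  stopifnot(inherits(mesh, "hex_mesh"))
  comps <- unique(mesh$compartment)
  if (length(E) == 1 && is.null(names(E)))
    E <- setNames(rep(E, length(comps)), comps)
  if (!all(comps %in% names(E)))
    stop("E must name every compartment: ", paste(comps, collapse = ", "),
         call. = FALSE)
  mats <- lapply(E[comps], neo_hookean, nu = nu)
  C10 <- vapply(mats[mesh$compartment], `[[`, 0, "C10")
  D1 <- vapply(mats[mesh$compartment], `[[`, 0, "D1")

  nn <- nrow(mesh$nodes)
  ndof <- 3L * nn
  fixed <- c(3L * (mesh$node_sets$symmetry_x - 1L) + 1L,   # u_x = 0
             3L * (mesh$node_sets$symmetry_y - 1L) + 2L,   # u_y = 0
             as.integer(extra_fixed))
  fixed <- sort(unique(fixed))
  free <- setdiff(seq_len(ndof), fixed)
  dofmap <- integer(ndof)
  dofmap[free] <- seq_along(free)

  # the sparsity pattern and slot mapping depend only on the mesh and the
  # constraint set; cache them on the mesh so repeated model builds (e.g.
  # inside a calibration loop) skip the expensive matching
  cache <- mesh$cache
  cache_key <- paste(length(extra_fixed), sum(extra_fixed), sep = "_")
  if (is.environment(cache) && identical(cache$key, cache_key)) {
    keep <- cache$keep; Ktpl <- cache$Ktpl; slots <- cache$slots
    contact_slots <- cache$contact_slots
  } else {
    pat <- fe_pattern_cpp(mesh$elems)
    keep <- dofmap[pat$i] > 0L & dofmap[pat$j] > 0L
    ri <- dofmap[pat$i[keep]]
    rj <- dofmap[pat$j[keep]]
    nfree <- length(free)

    # fixed sparsity template + slot mapping: assembly only rewrites @x
    Ktpl <- Matrix::sparseMatrix(i = ri, j = rj, x = 0,
                                 dims = c(nfree, nfree))
    keyP <- (rep.int(seq_len(nfree), diff(Ktpl@p)) - 1) * as.double(nfree) +
      (Ktpl@i + 1)
    slots <- match((rj - 1) * as.double(nfree) + ri, keyP)

    # slots for the 3x3 contact blocks of every contact-candidate node
    cand_all <- sort(unique(c(mesh$node_sets$contact_surface,
                              mesh$node_sets$base_support)))
    cs_i <- integer(0); cs_j <- integer(0); cs_node <- integer(0)
    cs_row <- integer(0); cs_col <- integer(0)
    for (n in cand_all) {
      rd <- dofmap[3L * (n - 1L) + 1:3]
      for (a in 1:3) for (b in 1:3) {
        if (rd[a] > 0L && rd[b] > 0L) {
          cs_i <- c(cs_i, rd[a]); cs_j <- c(cs_j, rd[b])
          cs_node <- c(cs_node, n); cs_row <- c(cs_row, a)
          cs_col <- c(cs_col, b)
        }
      }
    }
    cs_slot <- match((cs_j - 1) * as.double(nfree) + cs_i, keyP)
    contact_slots <- list(node = cs_node, row = cs_row, col = cs_col,
                          slot = cs_slot)
    if (is.environment(cache)) {
      cache$key <- cache_key; cache$keep <- keep; cache$Ktpl <- Ktpl
      cache$slots <- slots; cache$contact_slots <- contact_slots
    }
  }

  h <- mesh$min_edge_contact_um
  if (!is.finite(h)) h <- 0.4
  p_area <- penalty_factor * max(vapply(mats, `[[`, 0, "E")) / h  # nN/um^3
  penalty <- p_area * mesh$node_area_um2                          # nN/um per node

  structure(list(mesh = mesh, E = E, nu = nu, C10 = C10, D1 = D1,
                 fixed = fixed, free = free, dofmap = dofmap,
                 pattern_keep = keep, Ktpl = Ktpl, nnz = length(Ktpl@x),
                 slots = slots, contact_slots = contact_slots,
                 penalty = penalty, penalty_factor = penalty_factor,
                 solver_state = new.env(parent = emptyenv())),
            class = "fe_model")
}

# One Newton solve at fixed boundary data.
#   u: nn x 3 initial displacement (um), already satisfying Dirichlet data
#   contacts: list of list(surface, candidates); penalty taken from the model
# Returns u, convergence flag, residual history, per-contact reactions (nN),
# bulk strain energy and penalty energy.
newton_step <- function(model, u, contacts, config,
                        fixed_values = NULL) {
  mesh <- model$mesh
  nn <- nrow(mesh$nodes)
  free <- model$free
  res_hist <- numeric(0)
  converged <- FALSE
  reactions <- NULL
  energy <- NA_real_
  pen_energy <- NA_real_

  if (!is.null(fixed_values)) {
    uv <- as.vector(t(u))
    uv[fixed_values$dofs] <- fixed_values$values
    u <- matrix(uv, nn, 3, byrow = TRUE)
  }

  for (it in seq_len(config$max_newton_iters + 1L)) {
    asm <- fe_assemble_cpp(mesh$nodes, mesh$elems, u, model$C10, model$D1,
                           want_tangent = TRUE)
    if (!asm$ok)
      return(list(u = u, converged = FALSE, res_hist = res_hist,
                  error = sprintf("element %d inverted", asm$bad_elem)))
    r <- asm$fint
    cK <- list()   # per-contact tangent blocks, added at the slot level
    reactions <- numeric(length(contacts))
    pen_energy <- 0
    for (s in seq_along(contacts)) {
      cand <- contacts[[s]]$candidates
      xc <- mesh$nodes[cand, , drop = FALSE] + u[cand, , drop = FALSE]
      cc <- contact_contribution(xc, contacts[[s]]$surface,
                                 model$penalty[cand])
      act <- which(cc$active)
      if (length(act)) {
        for (a in act) {
          dofs <- 3L * (cand[a] - 1L) + 1:3
          r[dofs] <- r[dofs] - cc$force[a, ]
        }
        pen_energy <- pen_energy +
          0.5 * sum(model$penalty[cand][act] * cc$gaps[act]^2)
        cK[[s]] <- list(nodes = cand[act], K = cc$K[, , act, drop = FALSE])
      }
      reactions[s] <- cc$total_force
    }
    energy <- asm$energy

    rfree <- r[free]
    rnorm <- sqrt(sum(rfree^2))
    res_hist <- c(res_hist, rnorm)
    # converged relative to the external force scale or to the step's own
    # initial out-of-balance (whichever is larger), or absolutely tiny
    ref <- max(1, sqrt(sum((r - asm$fint)[free]^2)), abs(reactions),
               res_hist[1])
    if (rnorm <= config$newton_tol * ref || rnorm < 1e-12) {
      converged <- TRUE
      break
    }
    if (it > config$max_newton_iters) break

    x <- accumulate_slots_cpp(model$nnz, model$slots,
                              asm$Kx[model$pattern_keep])
    cs <- model$contact_slots
    for (blk in cK) {
      if (is.null(blk)) next
      for (a in seq_along(blk$nodes)) {
        sel <- which(cs$node == blk$nodes[a])
        if (length(sel))
          x[cs$slot[sel]] <- x[cs$slot[sel]] +
            blk$K[cbind(cs$row[sel], cs$col[sel], a)]
      }
    }
    K <- model$Ktpl
    K@x <- x
    du <- solve_spd_system(K, -rfree, rnorm, state = model$solver_state)
    if (is.null(du))
      return(list(u = u, converged = FALSE, res_hist = res_hist,
                  error = "singular tangent"))
    uv <- as.vector(t(u))
    uv[free] <- uv[free] + du
    u <- matrix(uv, nn, 3, byrow = TRUE)
  }
  list(u = u, converged = converged, res_hist = res_hist,
       reactions = reactions, energy = energy, pen_energy = pen_energy)
}

#' Quasi-static Newton-Raphson continuation
#'
#' Advances a load parameter `t` from 0 to 1 in `n_load_steps` increments.
#' At each step the Dirichlet data and the rigid-surface positions are
#' evaluated at `t` and the equilibrium is solved by a full Newton iteration
#' with consistent tangent; on non-convergence the increment is cut back by
#' `step_cutback` (repeatedly, up to `max_cutbacks`). The solver contains no
#' randomness: repeated runs are bit-identical.
#'
#' @param model an [fe_model()].
#' @param dirichlet optional function `t -> list(dofs, values)` of prescribed
#'   displacement dofs (global dof indices `3*(node-1)+component`) beyond the
#'   built-in symmetry constraints.
#' @param contacts optional function `t -> list(list(surface, candidates))`
#'   returning the rigid surfaces and their candidate node sets at load `t`.
#' @param config a [solver_config()].
#' @return An object of class `fe_solution`: list of per-step states, each
#'   with `t`, `u` (N x 3, um), `converged`, `res_hist`, `reactions` (nN),
#'   `energy` and `pen_energy` (nN um), plus a top-level `converged` flag.
#' @export
newton_solve <- function(model, dirichlet = NULL, contacts = NULL,
                         config = solver_config()) {
  u <- matrix(0, nrow(model$mesh$nodes), 3)
  states <- list()
  t_cur <- 0
  dt <- 1 / config$n_load_steps
  cutbacks <- 0
  while (t_cur < 1 - 1e-12) {
    t_try <- min(1, t_cur + dt)
    fx <- if (is.null(dirichlet)) NULL else dirichlet(t_try)
    ct <- if (is.null(contacts)) list() else contacts(t_try)
    st <- newton_step(model, u, ct, config, fixed_values = fx)
    if (!st$converged) {
      cutbacks <- cutbacks + 1
      if (cutbacks > config$max_cutbacks) {
        return(structure(list(states = states, converged = FALSE,
                              error = st$error %||% "Newton failed"),
                         class = "fe_solution"))
      }
      dt <- dt * config$step_cutback
      next
    }
    cutbacks <- 0
    t_cur <- t_try
    u <- st$u
    st$t <- t_cur
    states[[length(states) + 1L]] <- st
  }
  structure(list(states = states, converged = TRUE),
            class = "fe_solution")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Solve K du = b for the (symmetric) Newton system. Supernodal Cholesky
# first; CHOLMOD keeps going with a warning on indefinite matrices, so the
# direction is verified by its linear residual. Fallbacks: simplicial LDLt
# (which handles indefiniteness), then escalating Tikhonov-regularized
# Cholesky (a damped Newton direction). A small state environment remembers
# which factorization last succeeded so indefinite phases do not pay for a
# doomed supernodal attempt at every iteration.
solve_spd_system <- function(K, b, rnorm, state = NULL) {
  Ks <- Matrix::forceSymmetric(K)
  # CHOLMOD factor memory lives outside R's heap, so the garbage collector
  # feels no pressure from it; collect eagerly after every factorization
  try_solve <- function(A, check = TRUE, ...) {
    du <- tryCatch(suppressWarnings({
      ch <- Matrix::Cholesky(A, ...)
      res <- as.numeric(Matrix::solve(ch, b))
      rm(ch)
      res
    }), error = function(e) NULL)
    gc(verbose = FALSE)
    if (is.null(du) || !all(is.finite(du))) return(NULL)
    if (check) {
      lin_res <- sqrt(sum((as.numeric(K %*% du) - b)^2))
      if (!is.finite(lin_res) || lin_res > 1e-6 * max(rnorm, 1)) return(NULL)
    }
    du
  }
  prefer_ldl <- is.environment(state) && isTRUE(state$prefer_ldl)
  if (!prefer_ldl) {
    du <- try_solve(Ks, LDL = FALSE, super = TRUE)
    if (!is.null(du)) return(du)
    if (is.environment(state)) state$prefer_ldl <- TRUE
  }
  du <- try_solve(Ks, LDL = TRUE, super = FALSE)
  if (!is.null(du)) return(du)
  if (prefer_ldl) {
    du <- try_solve(Ks, LDL = FALSE, super = TRUE)
    if (!is.null(du)) {
      if (is.environment(state)) state$prefer_ldl <- FALSE
      return(du)
    }
  }
  # damped Newton direction from a Tikhonov-regularized tangent
  dscale <- max(abs(K@x))
  for (tau in 10^c(-8, -6, -4, -2)) {
    Kreg <- Ks + Matrix::Diagonal(nrow(K), tau * dscale)
    du <- try_solve(Kreg, check = FALSE, LDL = FALSE, super = TRUE)
    if (!is.null(du)) return(du)
  }
  NULL
}

#' @export
print.fe_solution <- function(x, ...) {
  cat(sprintf("FE solution: %d load steps, %s\n", length(x$states),
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}
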