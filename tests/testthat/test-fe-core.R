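fe_el <- function(...) nemaindent:::fe_element_cpp(...)

test_that("element internal force vanishes for zero and rigid motion", {
  mesh <- single_hex_mesh()
  m <- neo_hookean(100, 0.49)
  r0 <- fe_el(mesh$nodes, matrix(0, 8, 3), m$C10, m$D1)
  expect_equal(max(abs(r0$f)), 0)
  expect_equal(r0$volume, 1, tolerance = 1e-12)
  # rigid translation
  ut <- matrix(rep(c(0.4, -0.2, 0.7), each = 8), 8)
  expect_lt(max(abs(fe_el(mesh$nodes, ut, m$C10, m$D1)$f)), 1e-12)
})

test_that("element tangent is the exact derivative of the internal force", {
  mesh <- single_hex_mesh()
  m <- neo_hookean(100, 0.49)
  set.seed(2)
  u <- 0.05 * matrix(rnorm(24), 8, 3)
  r <- fe_el(mesh$nodes, u, m$C10, m$D1)
  h <- 1e-6
  Kfd <- matrix(0, 24, 24)
  for (n in 1:8) for (c in 1:3) {
    up <- u; um <- u
    up[n, c] <- up[n, c] + h; um[n, c] <- um[n, c] - h
    Kfd[, 3 * (n - 1) + c] <-
      (fe_el(mesh$nodes, up, m$C10, m$D1)$f -
         fe_el(mesh$nodes, um, m$C10, m$D1)$f) / (2 * h)
  }
  expect_lt(norm(r$K - Kfd, "F") / norm(Kfd, "F"), 1e-5)
  expect_lt(norm(r$K - t(r$K), "F") / norm(r$K, "F"), 1e-12)
})

test_that("inverted elements are flagged", {
  mesh <- single_hex_mesh()
  u <- matrix(0, 8, 3)
  u[c(3, 4, 7, 8), 3] <- -1.5     # push the top face through the bottom
  expect_false(fe_el(mesh$nodes, u, neo_hookean(10, 0.3)$C10,
                     neo_hookean(10, 0.3)$D1)$ok)
})

# stretch a single element along z with traction-free lateral faces and
# compare against the closed-form homogeneous solution (lateral stretch from
# radial equilibrium via uniroot -- an independent R-side oracle)
test_that("uniaxial stretch matches the closed-form neo-Hookean response", {
  E <- 200; nu <- 0.49
  mesh <- single_hex_mesh()
  fix <- c(gdof(c(1, 4, 5, 8), 1),      # u_x = 0 on x = 0
           gdof(5:8, 2),                # u_y = 0 on y = 0
           gdof(c(1, 2, 5, 6), 3),      # u_z = 0 on z = 0
           gdof(c(3, 4, 7, 8), 3))      # prescribed top face
  model <- fe_model(mesh, E, nu = nu, extra_fixed = fix)
  for (lam in c(1.15, 0.9)) {
    sol <- newton_solve(model, dirichlet = function(t) {
      list(dofs = gdof(c(3, 4, 7, 8), 3), values = rep(t * (lam - 1), 4))
    }, config = solver_config(n_load_steps = 4))
    expect_true(sol$converged)
    u <- sol$states[[length(sol$states)]]$u
    # oracle: lateral stretch solving sigma_lat = 0
    lat <- uniroot(function(l) nh_principal_stress(c(l, l, lam), E, nu)[1],
                   c(0.5, 2), tol = 1e-12)$root
    expect_equal(1 + u[2, 1], lat, tolerance = 5e-3)
    # axial reaction = P_zz * ref area = J sigma_zz / lambda
    szz <- nh_principal_stress(c(lat, lat, lam), E, nu)[3]
    m <- neo_hookean(E, nu)
    asm <- nemaindent:::fe_assemble_cpp(mesh$nodes, mesh$elems, u,
                                        m$C10, m$D1, FALSE)
    react <- sum(asm$fint[gdof(c(3, 4, 7, 8), 3)])
    expect_equal(react, lat^2 * lam * szz / lam, tolerance = 5e-3)
  }
})

test_that("confined compression matches the closed form exactly", {
  E <- 150; nu <- 0.49
  mesh <- single_hex_mesh()
  lam <- 0.95
  fix <- c(gdof(1:8, 1), gdof(1:8, 2), gdof(c(1, 2, 5, 6), 3),
           gdof(c(3, 4, 7, 8), 3))
  model <- fe_model(mesh, E, nu = nu, extra_fixed = fix)
  sol <- newton_solve(model, dirichlet = function(t) {
    list(dofs = fix, values = c(rep(0, 20), rep(t * (lam - 1), 4)))
  }, config = solver_config(n_load_steps = 3))
  expect_true(sol$converged)
  u <- sol$states[[length(sol$states)]]$u
  m <- neo_hookean(E, nu)
  asm <- nemaindent:::fe_assemble_cpp(mesh$nodes, mesh$elems, u,
                                      m$C10, m$D1, FALSE)
  react <- sum(asm$fint[gdof(c(3, 4, 7, 8), 3)])
  szz <- nh_principal_stress(c(1, 1, lam), E, nu)[3]
  expect_equal(react, lam * szz / lam, tolerance = 1e-6)
})

test_that("patch test: affine boundary data gives the affine solution", {
  # 2 x 2 x 2 block with a perturbed interior node
  g <- expand.grid(x = 0:2, z = 0:2, y = 0:2) / 2
  nodes <- as.matrix(g[, c("x", "y", "z")])
  nid <- function(ix, iy, iz) ix + 3 * iz + 9 * iy + 1  # 0-based indices
  elems <- NULL
  for (iy in 0:1) for (iz in 0:1) for (ix in 0:1) {
    q <- c(nid(ix, 0, iz), nid(ix + 1, 0, iz),
           nid(ix + 1, 0, iz + 1), nid(ix, 0, iz + 1)) + 9 * iy
    elems <- rbind(elems, c(q + 9, q))
  }
  centre <- nid(1, 1, 1)
  nodes[centre, ] <- nodes[centre, ] + c(0.07, -0.05, 0.04)
  mesh <- hex_mesh(nodes, elems)
  boundary <- setdiff(seq_len(nrow(nodes)), centre)
  A <- matrix(c(1.2, 0.3, -0.2, 0.1, 2.1, 0.4, -0.3, 0.2, 1.5), 3) * 1e-3
  ub <- nodes %*% t(A)
  fix <- as.vector(vapply(boundary, function(n) gdof(n, 1:3), integer(3)))
  model <- fe_model(mesh, 100, nu = 0.49, extra_fixed = fix)
  sol <- newton_solve(model, dirichlet = function(t) {
    list(dofs = fix, values = t * as.vector(t(ub[boundary, ])))
  }, config = solver_config(n_load_steps = 1))
  expect_true(sol$converged)
  u <- sol$states[[1]]$u
  # interior node follows the affine field; strain (hence energy density)
  # is homogeneous across all elements
  expect_equal(u[centre, ], as.vector(A %*% nodes[centre, ]),
               tolerance = 1e-8)
  m <- neo_hookean(100, 0.49)
  w <- vapply(seq_len(nrow(elems)), function(e) {
    r <- fe_el(nodes[elems[e, ], ], u[elems[e, ], ], m$C10, m$D1)
    r$energy / r$volume
  }, 0)
  expect_lt(diff(range(w)) / mean(w), 1e-8)
})

test_that("Newton iterations converge quadratically on the full model", {
  mesh <- cached("mesh_l0", generate_mesh(build_geometry(), 0))
  model <- fe_model(mesh, c(cuticle_hypodermis = 150, muscle = 1200,
                            pseudocoelom = 840))
  r_out <- mesh$geometry$radius_um
  contacts <- list(
    list(surface = rigid_sphere(5, c(0, 0, r_out + 5 - 0.15)),
         candidates = mesh$node_sets$contact_surface),
    list(surface = rigid_plane(-r_out),
         candidates = mesh$node_sets$base_support))
  st <- nemaindent:::newton_step(model, matrix(0, nrow(mesh$nodes), 3),
                                 contacts, solver_config())
  expect_true(st$converged)
  rh <- st$res_hist
  n <- length(rh)
  # deep overall reduction and a superlinear final contraction (the first
  # iterations may wander while the contact active set settles)
  expect_lt(rh[n] / rh[1], 1e-6)
  expect_lt(rh[n] / rh[n - 1], 0.05)
})
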