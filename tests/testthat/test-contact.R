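test_that("signed gap against the spherical indenter is exact geometry", {
  s <- rigid_sphere(5, c(0, 0, 0))
  expect_equal(contact_gap(c(6, 0, 0), s), 1)
  expect_equal(contact_gap(c(0, 5, 0), s), 0)
  expect_equal(contact_gap(c(0, 0, 4.9), s), -0.1)
  # gradient of the gap is the unit outward normal
  x <- c(1, 2, 3)
  h <- 1e-7
  g <- vapply(1:3, function(i) {
    e <- numeric(3); e[i] <- h
    (contact_gap(x + e, s) - contact_gap(x - e, s)) / (2 * h)
  }, 0)
  expect_equal(g, x / sqrt(sum(x^2)), tolerance = 1e-8)
})

test_that("penalty force follows the penalty law and is frictionless", {
  s <- rigid_sphere(5, c(0, 0, 0))
  # single node penetrating by 0.01 um with nodal penalty 1e4 nN/um
  x <- matrix(c(0, 0, 4.99), 1)
  cc <- contact_contribution(x, s, 1e4)
  expect_true(cc$active[1])
  expect_equal(sqrt(sum(cc$force[1, ]^2)), 100)
  # force is purely normal (frictionless): parallel to the outward radial
  nrm <- x[1, ] / sqrt(sum(x[1, ]^2))
  expect_equal(cc$force[1, ] / sqrt(sum(cc$force[1, ]^2)), nrm,
               tolerance = 1e-12)
  # non-penetrating nodes carry exactly zero force
  cc2 <- contact_contribution(matrix(c(0, 0, 5.5), 1), s, 1e4)
  expect_false(cc2$active[1])
  expect_equal(cc2$force[1, ], c(0, 0, 0))
})

test_that("contact tangent matches the derivative of the contact force", {
  s <- rigid_sphere(5, c(1, -2, 10))
  x0 <- c(1.4, -1.1, 5.6)    # inside the sphere
  stopifnot(contact_gap(x0, s) < 0)
  k <- 2e3
  cc <- contact_contribution(matrix(x0, 1), s, k, curvature = TRUE)
  h <- 1e-7
  Kfd <- matrix(0, 3, 3)
  for (i in 1:3) {
    e <- numeric(3); e[i] <- h
    fp <- contact_contribution(matrix(x0 + e, 1), s, k)$force[1, ]
    fm <- contact_contribution(matrix(x0 - e, 1), s, k)$force[1, ]
    Kfd[, i] <- -(fp - fm) / (2 * h)   # K adds -d f_ext / d x
  }
  expect_equal(cc$K[, , 1], Kfd, tolerance = 1e-6)
  # default tangent keeps the (semidefinite) normal dyad only
  cc0 <- contact_contribution(matrix(x0, 1), s, k)
  nrm <- (x0 - s$center) / sqrt(sum((x0 - s$center)^2))
  expect_equal(cc0$K[, , 1], k * tcrossprod(nrm), tolerance = 1e-12)
  expect_true(all(eigen(cc0$K[, , 1], symmetric = TRUE,
                        only.values = TRUE)$values > -1e-9))
})

test_that("support-plane contact resists only normal penetration", {
  p <- rigid_plane(-2)
  x <- matrix(c(0.3, 9, -2.05), 1)
  cc <- contact_contribution(x, p, 500)
  expect_equal(cc$force[1, ], c(0, 0, 500 * 0.05))
  expect_equal(cc$K[, , 1], diag(c(0, 0, 500)))
  expect_equal(contact_gap(c(1, 1, -1.5), p), 0.5)
})

test_that("converged indentation satisfies complementarity and force balance", {
  crv <- bdm_200_curve()
  st <- attr(crv, "sim")$state
  mesh <- st$mesh
  model <- fe_model(mesh, c(cuticle_hypodermis = 150, muscle = 1200,
                            pseudocoelom = 840))
  r_out <- mesh$geometry$radius_um
  d <- max(crv$displacement_nm) / 1000
  sph <- rigid_sphere(5, c(0, 0, r_out + 5 - d))
  cand <- mesh$node_sets$contact_surface
  xc <- mesh$nodes[cand, ] + st$u[cand, ]
  cc <- contact_contribution(xc, sph, model$penalty[cand])
  # complementarity: positive gap -> exactly zero force
  expect_true(all(cc$force[!cc$active, ] == 0))
  expect_true(all(cc$gaps[rowSums(abs(cc$force)) > 0] <= 0))
  # the reported indenter reaction is the symmetry factor times the sum of
  # axial nodal contact forces
  f_curve <- approx(crv$displacement_nm, crv$force_nN,
                    max(crv$displacement_nm))$y
  expect_equal(4 * cc$total_force, f_curve, tolerance = 1e-9)
  # frictionless: every nodal force is parallel to its surface normal
  act <- which(cc$active)
  for (a in act) {
    nrm <- (xc[a, ] - sph$center) / sqrt(sum((xc[a, ] - sph$center)^2))
    f <- cc$force[a, ]
    tang <- f - sum(f * nrm) * nrm
    expect_lt(sqrt(sum(tang^2)), 1e-9 * max(1, sqrt(sum(f^2))))
  }
})

test_that("rigid surfaces validate their parameters", {
  expect_error(rigid_sphere(-1), "radius_um")
  expect_error(contact_contribution(matrix(0, 1, 3), rigid_plane(0), -5))
})
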