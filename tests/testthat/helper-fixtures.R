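# Shared fixtures. Forward FE simulations are expensive, so every curve that
# more than one test needs is computed once per session and cached here.
# All cached runs use the coarse (level 0) mesh; the methods vignette states
# the problem sizes used by the test suite.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# forward simulation of the worm model at the coarse test resolution
worm_curve <- function(label, moduli, protocol = list(set_force_nN = 450),
                      refinement = 0, ...) {
  key <- paste0("sim_", label)
  cached(key, run_afm_indentation(moduli = moduli, protocol = protocol,
                                  refinement = refinement, ...))
}

bdm_mean_curve <- function() worm_curve("bdm_mean", c(150, 1200, 840))

# shared 200 nm BDM-mean run (with final state) reused by the contact,
# scaling and path-independence tests
bdm_200_curve <- function() {
  cached("sim_bdm_200",
         run_afm_indentation(moduli = c(150, 1200, 840),
                             protocol = list(max_depth_nm = 200),
                             refinement = 0, keep_state = TRUE))
}
salt_control_curve <- function() worm_curve("salt_control", c(105, 390, 880))
high_salt_curve <- function() worm_curve("high_salt", c(90, 650, 76))
aldicarb_curve <- function() worm_curve("aldicarb", c(140, 950, 94))

# single regular hexahedron (unit cube scaled), oriented like the mesher
# output: nodes 1-4 on the larger-y face, counter-clockwise in (x, z)
single_hex_mesh <- function(lx = 1, ly = 1, lz = 1) {
  quad <- rbind(c(0, 0), c(lx, 0), c(lx, lz), c(0, lz))
  nodes <- rbind(cbind(quad[, 1], ly, quad[, 2]),
                 cbind(quad[, 1], 0, quad[, 2]))
  hex_mesh(nodes, matrix(1:8, 1))
}

# analytic decoupled neo-Hookean Cauchy stress for a principal stretch state
# (independent R-side oracle used against the C++ kernels)
nh_principal_stress <- function(lambda, E, nu) {
  mu <- E / (2 * (1 + nu)); kappa <- E / (3 * (1 - 2 * nu))
  J <- prod(lambda)
  b <- lambda^2
  dev <- mu * J^(-5 / 3) * (b - mean(b))
  p <- kappa * (J - 1)
  dev + p
}

# global dof helper matching the solver's layout
gdof <- function(node, comp) 3L * (node - 1L) + comp
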