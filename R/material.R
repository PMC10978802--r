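#' Nearly incompressible neo-Hookean material from engineering constants
#'
#' Converts a Young's modulus and Poisson ratio into the constants of the
#' decoupled neo-Hookean strain energy
#' \deqn{W = C_{10}(\bar I_1 - 3) + \frac{1}{D_1}(J - 1)^2,}
#' with \eqn{C_{10} = \mu/2} and \eqn{D_1 = 2/\kappa}, where
#' \eqn{\mu = E/(2(1+\nu))} and \eqn{\kappa = E/(3(1-2\nu))}. Tissue
#' incompressibility is imposed in the near-incompressible sense: the default
#' \eqn{\nu = 0.49} keeps the volumetric stiffness finite (exact
#' incompressibility with displacement elements locks); values up to 0.499
#' are supported by the element technology.
#'
#' @param E Young's modulus in kPa (> 0).
#' @param nu Poisson ratio in `[0, 0.5)`; `nu = 0.5` exactly is rejected.
#' @return An object of class `neo_hookean`: list with `C10` (kPa), `D1`
#'   (1/kPa), `mu`, `kappa`, `E`, `nu`.
#' @examples
#' neo_hookean(150, 0.49)
#' @export
neo_hookean <- function(E, nu = 0.49) {
  check_positive(E, "E")
  if (!is.numeric(nu) || length(nu) != 1 || nu < 0 || nu >= 0.5)
    stop("'nu' must lie in [0, 0.5); use near-incompressibility (e.g. 0.49) instead of 0.5",
         call. = FALSE)
  mu <- E / (2 * (1 + nu))
  kappa <- E / (3 * (1 - 2 * nu))
  structure(list(C10 = mu / 2, D1 = 2 / kappa, mu = mu, kappa = kappa,
                 E = E, nu = nu), class = "neo_hookean")
}

#' @export
print.neo_hookean <- function(x, ...) {
  cat(sprintf("neo-Hookean material: E = %.4g kPa, nu = %.4g\n", x$E, x$nu))
  cat(sprintf("  C10 = %.6g kPa, D1 = %.6g 1/kPa (mu = %.6g, kappa = %.6g kPa)\n",
              x$C10, x$D1, x$mu, x$kappa))
  invisible(x)
}

#' Recover engineering constants from hyperelastic parameters
#'
#' Inverse of [neo_hookean()]: given `C10` and `D1`, returns the Young's
#' modulus and Poisson ratio via \eqn{E = 9\kappa\mu/(3\kappa+\mu)} and
#' \eqn{\nu = (3\kappa - 2\mu)/(2(3\kappa+\mu))}.
#'
#' @param params a `neo_hookean` object, or a list with `C10` and `D1`.
#' @return Named numeric vector `c(E, nu)`.
#' @export
engineering_constants <- function(params) {
  mu <- 2 * params$C10
  kappa <- 2 / params$D1
  c(E = 9 * kappa * mu / (3 * kappa + mu),
    nu = (3 * kappa - 2 * mu) / (2 * (3 * kappa + mu)))
}

#' Stress and tangent of the neo-Hookean law at a deformation gradient
#'
#' Evaluates the strain-energy density, second Piola-Kirchhoff and Cauchy
#' stress, and the material tangent \eqn{2\,\partial S/\partial C} for the
#' decoupled nearly incompressible neo-Hookean model.
#'
#' @param F_grad 3 x 3 deformation gradient with positive determinant.
#' @param params a `neo_hookean` object.
#' @return List with `energy` (kPa), `S` (PK2 stress, kPa), `sigma` (Cauchy
#'   stress, kPa), `tangent` (3 x 3 x 3 x 3 material tangent), `J`.
#' @examples
#' m <- neo_hookean(100, 0.49)
#' stress_and_tangent(diag(3), m)$sigma   # stress-free reference
#' @export
stress_and_tangent <- function(F_grad, params) {
  stopifnot(is.matrix(F_grad), all(dim(F_grad) == c(3, 3)))
  if (det(F_grad) <= 0)
    stop("element inversion: det(F) <= 0", call. = FALSE)
  nh_point_cpp(F_grad, params$C10, params$D1)
}
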