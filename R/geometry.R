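#' Idealized layered-cylinder geometry of the nematode body
#'
#' Builds the concentric three-compartment cylinder used by the indentation
#' model: a pseudocoelom core, a muscle annulus, and an outer annulus merging
#' cuticle and hypodermis (the two are too thin to resolve separately and are
#' parameterized by a single Young's modulus). Defaults correspond to an adult
#' animal: pseudocoelom diameter 26.3 um, muscle 1.0 um, hypodermis 0.1 um and
#' cuticle 0.6 um, giving interface radii 13.15 / 14.15 / 14.85 um.
#'
#' Compartments with zero width are dropped, so setting all widths to zero
#' yields a homogeneous cylinder (useful for Hertz-theory benchmarks).
#'
#' @param pseudocoelom_diameter_um diameter of the pseudocoelom core (um).
#' @param muscle_width_um width of the muscle annulus (um).
#' @param hypodermis_width_um width of the hypodermis layer (um); merged with
#'   the cuticle into one outer compartment.
#' @param cuticle_width_um width of the cuticle (um).
#' @param length_um total cylinder length (um). The default, about three outer
#'   diameters, makes end effects at the central contact negligible.
#' @return An object of class `worm_geometry`: list with `compartments`
#'   (data.frame `name`, `r_inner`, `r_outer` in um, ordered inside-out),
#'   `radius_um`, `length_um`, and `symmetry` (the two mirror planes the
#'   quarter model exploits).
#' @examples
#' geo <- build_geometry()
#' geo$compartments
#' @export
build_geometry <- function(pseudocoelom_diameter_um = 26.3,
                           muscle_width_um = 1.0,
                           hypodermis_width_um = 0.1,
                           cuticle_width_um = 0.6,
                           length_um = 90) {
  check_positive(pseudocoelom_diameter_um, "pseudocoelom_diameter_um")
  check_nonnegative(muscle_width_um, "muscle_width_um")
  check_nonnegative(hypodermis_width_um, "hypodermis_width_um")
  check_nonnegative(cuticle_width_um, "cuticle_width_um")
  check_positive(length_um, "length_um")

  r0 <- pseudocoelom_diameter_um / 2
  widths <- c(pseudocoelom = r0,
              muscle = muscle_width_um,
              cuticle_hypodermis = hypodermis_width_um + cuticle_width_um)
  r_outer <- cumsum(widths)
  r_inner <- c(0, r_outer[-length(r_outer)])
  keep <- widths > 0
  comp <- data.frame(name = names(widths)[keep],
                     r_inner = unname(r_inner[keep]),
                     r_outer = unname(r_outer[keep]),
                     stringsAsFactors = FALSE)
  structure(list(compartments = comp,
                 radius_um = unname(r_outer[length(r_outer)]),
                 length_um = length_um,
                 symmetry = c("x", "y")),
            class = "worm_geometry")
}

#' @export
print.worm_geometry <- function(x, ...) {
  cat("Layered-cylinder nematode geometry\n")
  cat(sprintf("  outer radius: %.3f um, length: %.1f um\n",
              x$radius_um, x$length_um))
  cat(sprintf("  compartments (inside-out):\n"))
  for (i in seq_len(nrow(x$compartments))) {
    c_i <- x$compartments[i, ]
    cat(sprintf("    %-20s r in [%.3f, %.3f] um\n",
                c_i$name, c_i$r_inner, c_i$r_outer))
  }
  invisible(x)
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x <= 0)
    stop(sprintf("'%s' must be a single positive finite number", name),
         call. = FALSE)
  invisible(TRUE)
}

check_nonnegative <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < 0)
    stop(sprintf("'%s' must be a single non-negative finite number", name),
         call. = FALSE)
  invisible(TRUE)
}
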