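#' Calibrated scenario presets
#'
#' The per-compartment Young's-modulus triples calibrated for each
#' experimental condition, used to generate scenario fixtures and to drive
#' forward simulations: `BDM_mean` is the BDM-immobilized wild-type mean,
#' `BDM_salt_control` the BDM control arm of the hyperosmotic-shock
#' comparison, `high_salt` the 0.5 M NaCl osmotic-shock condition and
#' `aldicarb` the 1 mM aldicarb treatment. All use the 450 nN AFM set force.
#'
#' @return A data.frame with columns `name`, `E_cuticle_kPa`,
#'   `E_muscle_kPa`, `E_pseudocoelom_kPa`, `set_force_nN`.
#' @export
scenario_presets <- function() {
  data.frame(
    name = c("BDM_mean", "BDM_salt_control", "high_salt", "aldicarb"),
    E_cuticle_kPa = c(150, 105, 90, 140),
    E_muscle_kPa = c(1200, 390, 650, 950),
    E_pseudocoelom_kPa = c(840, 880, 76, 94),
    set_force_nN = c(450, 450, 450, 450),
    stringsAsFactors = FALSE)
}

#' Acquisition-noise model for synthetic AFM records
#'
#' Gaussian force noise plus a constant baseline offset and a linear
#' baseline drift, seeded for exact reproducibility.
#'
#' @param sigma_force_nN standard deviation of additive force noise (nN).
#' @param baseline_offset_nN constant force offset (nN).
#' @param baseline_drift_nN_per_nm linear drift of the baseline with piezo
#'   position (nN per nm).
#' @param seed integer RNG seed; identical seeds give bit-identical curves.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(sigma_force_nN = 0, baseline_offset_nN = 0,
                        baseline_drift_nN_per_nm = 0, seed = 1L) {
  stopifnot(sigma_force_nN >= 0)
  structure(list(sigma_force_nN = sigma_force_nN,
                 baseline_offset_nN = baseline_offset_nN,
                 baseline_drift_nN_per_nm = baseline_drift_nN_per_nm,
                 seed = as.integer(seed)), class = "noise_model")
}

#' Generate a synthetic raw AFM record with known ground truth
#'
#' Emulates force-spectroscopy acquisition: a flat pre-contact baseline, a
#' contact point, a post-contact force rise from either the closed-form
#' Hertz model or a finite-element forward simulation, cantilever compliance
#' coupling piezo position to tip-sample displacement (`piezo = delta +
#' F/k`), and configurable noise. The exact ground truth (contact sample,
#' moduli, stiffness, seed) rides along in the metadata so recovery can be
#' asserted bit-exactly in tests.
#'
#' @param source forward model: `list(hertz_E_kPa = E)` for the analytic
#'   sphere-on-half-space law, or `list(moduli_kPa = c(cuticle, muscle,
#'   pseudocoelom))` for the FE model.
#' @param protocol `list(set_force_nN = ...)` (default 450) or
#'   `list(max_depth_nm = ...)`.
#' @param noise a [noise_model()].
#' @param cantilever_k_N_per_m cantilever stiffness; `Inf` for an ideally
#'   rigid cantilever.
#' @param R_um indenter radius (um).
#' @param nu_hertz Poisson ratio for the Hertz source.
#' @param pre_contact_nm length of the pre-contact baseline segment (nm).
#' @param sample_interval_nm piezo sampling density (nm).
#' @param geometry,refinement FE forward-model settings (only for the
#'   `moduli_kPa` source).
#' @param treatment optional label.
#' @return A [raw_fd_curve()] whose `meta$ground_truth` holds
#'   `contact_index`, `contact_piezo_nm`, the source parameters and the
#'   noise seed.
#' @examples
#' raw <- make_raw_curve(list(hertz_E_kPa = 577),
#'                       noise = noise_model(sigma_force_nN = 2, seed = 7))
#' hertz_sneddon_fit(process_fd_curve(raw))
#' @export
make_raw_curve <- function(source,
                           protocol = list(set_force_nN = 450),
                           noise = noise_model(),
                           cantilever_k_N_per_m = 7.5,
                           R_um = 5, nu_hertz = 0.5,
                           pre_contact_nm = 500,
                           sample_interval_nm = 1,
                           geometry = build_geometry(),
                           refinement = 0L,
                           treatment = NULL) {
  stopifnot(inherits(noise, "noise_model"))
  if (!xor(is.null(source$hertz_E_kPa), is.null(source$moduli_kPa)))
    stop("source must give exactly one of 'hertz_E_kPa' or 'moduli_kPa'",
         call. = FALSE)

  if (!is.null(source$hertz_E_kPa)) {
    E <- source$hertz_E_kPa
    check_positive(E, "hertz_E_kPa")
    pref <- (4 / 3) * E / (1 - nu_hertz^2) * sqrt(R_um)   # nN at delta um^1.5
    dmax_um <- if (!is.null(protocol$set_force_nN)) {
      (protocol$set_force_nN / pref)^(2 / 3)
    } else protocol$max_depth_nm / .nm_per_um
    d_um <- seq(0, dmax_um, length.out = 2048)
    f_true <- pref * d_um^1.5
  } else {
    crv <- run_afm_indentation(geometry = geometry,
                               moduli = source$moduli_kPa,
                               protocol = protocol,
                               refinement = refinement)
    d_um <- crv$displacement_nm / .nm_per_um
    f_true <- crv$force_nN
  }

  # piezo position past contact includes the cantilever deflection F/k
  k <- cantilever_k_N_per_m
  defl_nm <- if (is.finite(k)) f_true / k else 0
  piezo_post <- d_um * .nm_per_um + defl_nm
  piezo <- seq(-pre_contact_nm, max(piezo_post), by = sample_interval_nm)
  force <- numeric(length(piezo))
  pos <- piezo > 0
  force[pos] <- approx(piezo_post, f_true, xout = piezo[pos],
                       ties = "ordered")$y
  contact_index <- max(which(piezo <= 0))

  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  set.seed(noise$seed)
  force <- force + noise$baseline_offset_nN +
    noise$baseline_drift_nN_per_nm * (piezo - piezo[1]) +
    rnorm(length(force), 0, noise$sigma_force_nN)
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv)

  gt <- list(contact_index = contact_index,
             contact_piezo_nm = piezo[contact_index],
             cantilever_k_N_per_m = k,
             hertz_E_kPa = source$hertz_E_kPa,
             moduli_kPa = source$moduli_kPa,
             max_depth_nm = max(d_um) * .nm_per_um,
             noise = unclass(noise))
  raw_fd_curve(piezo, force, cantilever_k_N_per_m = k,
               meta = list(source = "synthetic", treatment = treatment,
                           set_force_nN = protocol$set_force_nN,
                           ground_truth = gt))
}

#' Generate the raw AFM record of a named scenario preset
#'
#' Runs the finite-element forward model with the preset's calibrated
#' moduli and wraps the result in a synthetic acquisition record.
#'
#' @param preset one of the names in [scenario_presets()].
#' @param noise a [noise_model()].
#' @param ... further arguments passed to [make_raw_curve()].
#' @return A [raw_fd_curve()].
#' @export
make_scenario_curves <- function(preset, noise = noise_model(), ...) {
  tab <- scenario_presets()
  row <- tab[tab$name == preset, ]
  if (nrow(row) != 1)
    stop("unknown preset '", preset, "'; available: ",
         paste(tab$name, collapse = ", "), call. = FALSE)
  make_raw_curve(source = list(moduli_kPa = c(row$E_cuticle_kPa,
                                              row$E_muscle_kPa,
                                              row$E_pseudocoelom_kPa)),
                 protocol = list(set_force_nN = row$set_force_nN),
                 noise = noise, treatment = preset, ...)
}
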