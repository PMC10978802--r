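test_that("percent changes reproduce the printed condition comparisons", {
  # high-salt vs its BDM control: 14% and 91% drops, ~67% muscle increase
  rep <- percent_change(c(105, 390, 880), c(90, 650, 76))
  expect_equal(round(rep$change_pct[["cuticle_hypodermis"]]), 14)
  expect_equal(round(rep$change_pct[["pseudocoelom"]]), 91)
  expect_equal(round(rep$change_pct[["muscle"]]), -67)  # an increase
  expect_equal(rep$change_pct[["pseudocoelom"]], (880 - 76) / 880 * 100,
               tolerance = 1e-12)
  expect_error(percent_change(c(0, 1, 1), c(1, 1, 1)))
})

test_that("objective is near zero at the generating moduli and positive off them", {
  tgt <- bdm_mean_curve()
  prob <- cached("prob_bdm", calibration_problem(tgt, refinement = 0))
  # self-consistency: re-simulating the generating moduli reproduces the
  # target up to the load-step interpolation floor (a tiny fraction of the
  # 450 nN force scale)
  obj_true <- fd_objective(c(150, 1200, 840), prob)
  expect_lt(obj_true, 0.5)
  # a rescaled target cannot be matched
  tgt15 <- fd_curve(tgt$displacement_nm, 1.5 * tgt$force_nN)
  obj_off <- fd_objective(c(150, 1200, 840),
                          calibration_problem(tgt15, refinement = 0))
  expect_gt(obj_off, 10)
  # the alternative triple with softened muscle / stiffened pseudocoelom
  # fits the true curve strictly worse
  obj_alt <- fd_objective(c(150, 900, 1400), prob)
  expect_gt(obj_alt, obj_true)
})

test_that("collapsed bounds return that point after one evaluation", {
  tgt <- bdm_mean_curve()
  prob <- calibration_problem(tgt, refinement = 0,
                              bounds = cbind(c(150, 1200, 840),
                                             c(150, 1200, 840)))
  fit <- fit_moduli(prob)
  expect_equal(unname(coef(fit)), c(150, 1200, 840))
  expect_equal(fit$n_evaluations, 1)
  expect_true(fit$converged)
  expect_gte(fit$objective, 0)
})

test_that("optimization is deterministic and never worse than its start", {
  tgt <- cached("short_target",
                run_afm_indentation(moduli = c(150, 1200, 840),
                                    protocol = list(max_depth_nm = 150),
                                    refinement = 0))
  prob <- calibration_problem(tgt, refinement = 0)
  f1 <- fit_moduli(prob, max_evaluations = 6, seed = 7)
  f2 <- fit_moduli(prob, max_evaluations = 6, seed = 7)
  expect_identical(f1$trace, f2$trace)
  expect_identical(coef(f1), coef(f2))
  # never worse than the initial simplex point
  expect_lte(f1$objective, f1$trace[1, "objective"])
  expect_lte(f1$objective, min(f1$trace[, "objective"]) + 1e-12)
})

test_that("envelope fits report ranges in conventional compartment order", {
  hz <- function(d, E) 4 / 3 * E / 0.75 * sqrt(5) * (d / 1000)^1.5
  d <- seq(0, 300, by = 10)
  targets <- list(min = fd_curve(d, hz(d, 300)),
                  mean = fd_curve(d, hz(d, 500)),
                  max = fd_curve(d, hz(d, 800)))
  # collapsed bounds make the three sub-fits trivial and fast
  env <- fit_envelope(targets, refinement = 0,
                      bounds = cbind(c(150, 1200, 840), c(150, 1200, 840)))
  expect_true(env$complete)
  expect_equal(rownames(env$ranges),
               c("cuticle_hypodermis", "muscle", "pseudocoelom"))
  expect_equal(colnames(env$ranges), c("min", "mean", "max"))
  expect_equal(unname(env$ranges["muscle", ]), rep(1200, 3),
               tolerance = 1e-9)
})

test_that("identifiability: pseudocoelom sensitivity exceeds muscle sensitivity", {
  tgt <- bdm_mean_curve()
  prob <- cached("prob_bdm", calibration_problem(tgt, refinement = 0))
  fit <- nemaindent:::new_calibration(c(150, 1200, 840), 0, 1, TRUE,
                                      NULL, prob, 1)
  s <- cached("sens_bdm", calibration_sensitivity(fit))
  expect_gt(s[["pseudocoelom"]], s[["muscle"]])
})

test_that("calibration objects support the modelling-idiom methods", {
  tgt <- bdm_mean_curve()
  prob <- calibration_problem(tgt, refinement = 0,
                              bounds = cbind(c(150, 1200, 840),
                                             c(150, 1200, 840)))
  fit <- fit_moduli(prob)
  expect_named(coef(fit), c("cuticle_hypodermis", "muscle", "pseudocoelom"))
  expect_output(print(fit), "RMS misfit")
  expect_output(print(summary(fit)), "moduli")
  pred <- predict(fit)
  expect_s3_class(pred, "fd_curve")
  expect_equal(max(pred$displacement_nm), max(tgt$displacement_nm),
               tolerance = 1e-6)
  path <- withr::local_tempfile(fileext = ".png")
  grDevices::png(path)
  expect_silent(plot(fit))
  grDevices::dev.off()
  expect_true(file.exists(path))
})
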