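hertz_force <- function(d_nm, E = 577, nu = 0.5, R = 5) {
  4 / 3 * E / (1 - nu^2) * sqrt(R) * (d_nm / 1000)^1.5
}

test_that("baseline zeroing removes offsets and linear drift", {
  raw <- make_raw_curve(list(hertz_E_kPa = 577),
                        noise = noise_model(baseline_offset_nN = 3, seed = 1))
  expect_equal(mean(raw$force_nN[1:400]), 3, tolerance = 1e-9)
  z <- zero_baseline(raw)
  expect_lt(abs(mean(z$force_nN[1:400])), 0.01)
  # drift fixture: slope and offset both removed
  rawd <- make_raw_curve(list(hertz_E_kPa = 577),
                         noise = noise_model(sigma_force_nN = 0.3,
                                             baseline_offset_nN = -2,
                                             baseline_drift_nN_per_nm = 0.004,
                                             seed = 8))
  zd <- zero_baseline(rawd)
  pre <- 1:400
  expect_lt(abs(mean(zd$force_nN[pre])), 0.05)
  expect_lt(abs(unname(coef(lm(zd$force_nN[pre] ~ zd$piezo_nm[pre]))[2])),
            1e-3)
  # idempotence within noise
  z2 <- zero_baseline(zd)
  expect_equal(z2$force_nN, zd$force_nN, tolerance = 0.02)
})

test_that("baseline zeroing refuses curves without a flat region", {
  d <- seq(0, 300, by = 1)
  raw <- raw_fd_curve(d, hertz_force(d), 7.5)  # contact at the first sample
  expect_error(zero_baseline(raw), "baseline")
})

test_that("contact detection is exact without noise and robust with it", {
  raw <- make_raw_curve(list(hertz_E_kPa = 577), noise = noise_model())
  gt <- attr(raw, "meta")$ground_truth
  det <- detect_contact_point(zero_baseline(raw))
  idx <- attr(det, "meta")$contact_index
  expect_lte(abs(idx - gt$contact_index), 1)
  # piezo re-referenced so that contact sits at zero
  expect_equal(det$piezo_nm[idx], 0)
  # sigma = 0.5 nN: recovered within 5 samples
  for (seed in c(3, 11, 21)) {
    rawn <- make_raw_curve(list(hertz_E_kPa = 577),
                           noise = noise_model(0.5, seed = seed))
    detn <- detect_contact_point(zero_baseline(rawn))
    expect_lte(abs(attr(detn, "meta")$contact_index - gt$contact_index), 5)
  }
})

test_that("pure noise never yields a contact point", {
  set.seed(9)
  raw <- raw_fd_curve(seq_len(1000), rnorm(1000, 0, 0.5), 7.5)
  expect_error(detect_contact_point(zero_baseline(raw)), "contact")
})

test_that("contact detection requires a zeroed baseline first", {
  raw <- make_raw_curve(list(hertz_E_kPa = 577), noise = noise_model())
  expect_error(detect_contact_point(raw), "baseline")
})

test_that("cantilever bending correction subtracts F/k in nm", {
  # linear ramp: F = 0.5 nN per nm of piezo past contact, k = 7.5 N/m
  p <- seq(-300, 900, by = 1)
  f <- pmax(p, 0) * 0.5
  raw <- raw_fd_curve(p, f, 7.5)
  crv <- correct_cantilever_bending(
    detect_contact_point(zero_baseline(raw), refine = FALSE))
  # at F = 450 nN the deflection is 60 nm: piezo 900 -> depth 840
  expect_equal(max(crv$force_nN), 450, tolerance = 1e-6)
  expect_equal(max(crv$displacement_nm), 900 - 60, tolerance = 0.5)
  # rigid cantilever leaves the curve unchanged
  raw_inf <- raw_fd_curve(p, f, Inf)
  crv_inf <- correct_cantilever_bending(
    detect_contact_point(zero_baseline(raw_inf), refine = FALSE))
  expect_equal(max(crv_inf$displacement_nm), 900, tolerance = 0.5)
})

test_that("compliance round trip recovers the generator's indentation", {
  raw <- make_raw_curve(list(hertz_E_kPa = 577), noise = noise_model(),
                        cantilever_k_N_per_m = 7.5)
  crv <- process_fd_curve(raw)
  gt <- attr(raw, "meta")$ground_truth
  # corrected depth maxes out at the generator's true maximum depth up to
  # the one-sample (1 nm) floor of contact detection on a sampled record
  expect_lt(abs(max(crv$displacement_nm) - gt$max_depth_nm), 1.5)
  # and the forces on the corrected grid reproduce the Hertz law
  sel <- crv$displacement_nm > 50
  expect_equal(crv$force_nN[sel], hertz_force(crv$displacement_nm[sel]),
               tolerance = 0.01)
  # with a rigid cantilever the detection is exact; the remaining
  # discrepancy is only the 1 nm truncation of the sampling grid
  raw_inf <- make_raw_curve(list(hertz_E_kPa = 577), noise = noise_model(),
                            cantilever_k_N_per_m = Inf)
  crv_inf <- process_fd_curve(raw_inf)
  gt_inf <- attr(raw_inf, "meta")$ground_truth
  expect_lt(abs(max(crv_inf$displacement_nm) - gt_inf$max_depth_nm), 1.1)
})

test_that("Hertz/Sneddon fitting is exact on its own model and linear in E", {
  d <- seq(0, 338, by = 2)
  crv <- fd_curve(d, hertz_force(d, E = 577))
  fit <- hertz_sneddon_fit(crv)
  expect_equal(fit$E_kPa, 577, tolerance = 1e-3)
  expect_lt(fit$rms_residual_nN, 1e-9)
  # scaling all forces x2 doubles the fitted modulus
  crv2 <- fd_curve(d, 2 * hertz_force(d, E = 577))
  expect_equal(hertz_sneddon_fit(crv2)$E_kPa, 2 * 577, tolerance = 1e-6)
  # log-log slope of the noise-free fixture is 3/2
  sel <- d > 0
  sl <- unname(coef(lm(log(hertz_force(d[sel])) ~ log(d[sel])))[2])
  expect_equal(sl, 1.5, tolerance = 0.01)
})

test_that("full pipeline recovers the modulus within 3% at sigma = 2 nN", {
  raw <- make_raw_curve(list(hertz_E_kPa = 577),
                        noise = noise_model(2, 3, 0.002, seed = 42),
                        cantilever_k_N_per_m = 7.5)
  fit <- hertz_sneddon_fit(process_fd_curve(raw))
  expect_equal(fit$E_kPa, 577, tolerance = 0.03)
})

test_that("processing chain is idempotent", {
  raw <- make_raw_curve(list(hertz_E_kPa = 577),
                        noise = noise_model(1, seed = 2))
  once <- process_fd_curve(raw)
  twice <- process_fd_curve(once)
  expect_identical(once$displacement_nm, twice$displacement_nm)
  expect_identical(once$force_nN, twice$force_nN)
})

test_that("bulk stiffness regresses over the upper displacement half", {
  d <- seq(0, 400, by = 1)
  crv <- fd_curve(d, 0.1 * d)
  bs <- bulk_stiffness(crv)
  expect_equal(bs$slope_nN_per_nm, 0.1, tolerance = 1e-12)
  expect_equal(bs$intercept_nN, 0, tolerance = 1e-9)
  expect_equal(bs$window_nm, c(200, 400))
  expect_equal(bs$n_points, sum(d >= 200))
  # window correctness: points below 0.5 dmax are excluded -> for a curve
  # that kinks at 150 nm the early slope does not contaminate the fit
  f_kink <- ifelse(d < 150, 0.5 * d, 75 + 0.1 * (d - 150))
  expect_equal(bulk_stiffness(fd_curve(d, f_kink))$slope_nN_per_nm, 0.1,
               tolerance = 1e-9)
})

test_that("bulk stiffness of a Hertz curve matches a dense-grid oracle", {
  d <- seq(0, 338, by = 2)
  bs <- bulk_stiffness(fd_curve(d, hertz_force(d)))
  # brute-force oracle: OLS on a 0.01 nm grid over [169, 338] nm
  dd <- seq(169, 338, by = 0.01)
  oracle <- unname(coef(lm(hertz_force(dd) ~ dd))[2])
  expect_equal(bs$slope_nN_per_nm, oracle, tolerance = 0.005)
})

test_that("normalized stiffness behaves like a ratio", {
  d <- seq(0, 400, by = 1)
  ctrl <- bulk_stiffness(fd_curve(d, 0.1 * d))
  trt <- bulk_stiffness(fd_curve(d, 0.034 * d))
  expect_equal(normalize_stiffness(ctrl, ctrl), 1)
  # 0.034 / 0.1 = 0.34: the scale of a 66% stiffness decrease
  expect_equal(normalize_stiffness(trt, ctrl), 0.34, tolerance = 1e-9)
  # invariant to a common force rescaling
  ctrl2 <- bulk_stiffness(fd_curve(d, 5 * 0.1 * d))
  trt2 <- bulk_stiffness(fd_curve(d, 5 * 0.034 * d))
  expect_equal(normalize_stiffness(trt2, ctrl2),
               normalize_stiffness(trt, ctrl), tolerance = 1e-12)
})

test_that("annotated CSV round trip preserves data and metadata", {
  d <- seq(0, 100, by = 5)
  crv <- fd_curve(d, 0.3 * d, meta = list(source = "simulated",
                                          set_force_nN = 450,
                                          treatment = "BDM_mean"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_fd_curve(crv, path)
  back <- read_fd_curve(path)
  expect_equal(back$displacement_nm, crv$displacement_nm)
  expect_equal(back$force_nN, crv$force_nN)
  expect_identical(attr(back, "meta")$treatment, "BDM_mean")
  # raw record round trip
  raw <- make_raw_curve(list(hertz_E_kPa = 100), noise = noise_model(1))
  write_fd_curve(raw, path)
  rback <- read_fd_curve(path)
  expect_s3_class(rback, "raw_fd_curve")
  expect_equal(rback$piezo_nm, raw$piezo_nm)
  expect_equal(attr(rback, "meta")$cantilever_k_N_per_m, 7.5)
})
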