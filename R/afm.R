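#' Raw AFM force record
#'
#' An unprocessed force-spectroscopy record: force against piezo position
#' (including the cantilever's own deflection), with a pre-contact baseline
#' segment. The processing chain ([zero_baseline()],
#' [detect_contact_point()], [correct_cantilever_bending()] — or
#' [process_fd_curve()] for all three) turns it into an [fd_curve()].
#'
#' @param piezo_nm piezo positions (nm), strictly increasing.
#' @param force_nN measured forces (nN).
#' @param cantilever_k_N_per_m cantilever spring constant (N/m); the AFM
#'   probes used for this kind of measurement span about 5.8-10.8 N/m.
#' @param meta named list of metadata.
#' @return An object of class `raw_fd_curve`.
#' @export
raw_fd_curve <- function(piezo_nm, force_nN, cantilever_k_N_per_m,
                         meta = list()) {
  stopifnot(length(piezo_nm) == length(force_nN), length(piezo_nm) >= 10)
  if (any(diff(piezo_nm) <= 0))
    stop("piezo position must be strictly increasing", call. = FALSE)
  if (!is.numeric(cantilever_k_N_per_m) || is.na(cantilever_k_N_per_m) ||
      cantilever_k_N_per_m <= 0)
    stop("'cantilever_k_N_per_m' must be positive (Inf = rigid cantilever)",
         call. = FALSE)
  out <- data.frame(piezo_nm = as.numeric(piezo_nm),
                    force_nN = as.numeric(force_nN))
  meta$cantilever_k_N_per_m <- cantilever_k_N_per_m
  attr(out, "meta") <- meta
  class(out) <- c("raw_fd_curve", "data.frame")
  out
}

#' @export
print.raw_fd_curve <- function(x, ...) {
  m <- attr(x, "meta")
  cat(sprintf("raw AFM record: %d samples, piezo %.0f..%.0f nm, k = %.3g N/m\n",
              nrow(x), min(x$piezo_nm), max(x$piezo_nm),
              m$cantilever_k_N_per_m))
  invisible(x)
}

raw_meta <- function(x) attr(x, "meta")

set_raw_meta <- function(x, ...) {
  m <- modifyList(attr(x, "meta") %||% list(), list(...))
  attr(x, "meta") <- m
  x
}

#' Zero the pre-contact baseline
#'
#' Identifies the flat pre-contact segment, fits a straight line to it
#' (removing both a constant offset and a linear drift) and subtracts the
#' extrapolated line from the whole record. Idempotent: re-applying to an
#' already zeroed record changes nothing beyond the noise level.
#'
#' @param raw a [raw_fd_curve()].
#' @param min_pre_fraction minimum fraction of samples that must precede
#'   contact for the baseline to be identifiable (default 0.2).
#' @param rough_threshold_sd multiple of the baseline noise level used for
#'   the rough contact guess delimiting the baseline region.
#' @return The record with zeroed baseline (`meta$baselined = TRUE`,
#'   `meta$baseline_coef` holding the removed offset and slope).
#' @export
zero_baseline <- function(raw, min_pre_fraction = 0.2,
                          rough_threshold_sd = 8) {
  stopifnot(inherits(raw, "raw_fd_curve"))
  n <- nrow(raw)
  i0 <- max(10L, floor(min_pre_fraction * n))
  fit0 <- lm(force_nN ~ piezo_nm, data = raw[seq_len(i0), ])
  # noise level from first differences of the early-segment residuals:
  # robust against the smooth curvature of a record that has no flat
  # pre-contact region at all (which must be refused, not fitted)
  sigma0 <- stats::mad(diff(residuals(fit0))) / sqrt(2)
  thr <- max(rough_threshold_sd * sigma0, 1e-9)
  excess <- raw$force_nN - predict(fit0, raw)
  above <- which(excess > thr)
  rough <- if (length(above)) above[1] else n + 1L
  pre_end <- floor(0.95 * (rough - 1L))
  if (pre_end < max(10L, floor(min_pre_fraction * n)))
    stop("no identifiable flat pre-contact baseline region", call. = FALSE)
  fit <- lm(force_nN ~ piezo_nm, data = raw[seq_len(pre_end), ])
  out <- raw
  out$force_nN <- raw$force_nN - predict(fit, raw)
  set_raw_meta(out, baselined = TRUE,
               baseline_coef = unname(coef(fit)),
               baseline_region = c(1L, pre_end))
}

#' Detect the tip-sample contact point
#'
#' After baseline zeroing, the contact point is the first sample whose force
#' exceeds `threshold_sd` times the pre-contact noise level and stays above
#' it for `persistence` consecutive samples. Piezo positions are
#' re-referenced so that contact sits at zero. The rule (c = 5, m = 10 by
#' default) is configurable; vendor software keeps its own undocumented
#' variant.
#'
#' @param raw a baselined [raw_fd_curve()].
#' @param threshold_sd detection threshold in units of baseline noise sd.
#' @param persistence number of consecutive supra-threshold samples
#'   required.
#' @param refine if `TRUE` (default), the thresholded estimate is refined by
#'   a least-squares scan: candidate contact positions around the crossing
#'   are scored by fitting a 3/2-power force rise, which removes the late
#'   bias of pure thresholding at realistic noise levels.
#' @return The record with piezo re-referenced to contact and
#'   `meta$contact_index` / `meta$contact_piezo_nm` set.
#' @export
detect_contact_point <- function(raw, threshold_sd = 5, persistence = 10,
                                 refine = TRUE) {
  stopifnot(inherits(raw, "raw_fd_curve"))
  m <- raw_meta(raw)
  if (!isTRUE(m$baselined))
    stop("baseline must be zeroed first (see zero_baseline)", call. = FALSE)
  n <- nrow(raw)
  pre <- m$baseline_region[2]
  sigma <- sd(raw$force_nN[seq_len(pre)])
  thr <- max(threshold_sd * sigma, 1e-9)
  above <- raw$force_nN > thr
  run <- rle(above)
  ends <- cumsum(run$lengths)
  starts <- ends - run$lengths + 1L
  hit <- which(run$values &
                 (run$lengths >= persistence | ends == n))
  if (!length(hit))
    stop("no contact point: force never exceeds the detection threshold",
         call. = FALSE)
  # refine: step back from the sustained crossing to the last sample at or
  # below zero force -- unbiased for vanishing noise
  i_cross <- starts[hit[1]]
  below <- which(raw$force_nN[seq_len(max(1L, i_cross - 1L))] <= 0)
  idx <- if (length(below)) max(below) else max(1L, i_cross - 1L)
  if (refine) {
    # score candidate contact points by a one-parameter 3/2-power fit
    span <- max(3L * persistence, 30L)
    cand <- max(1L, idx - span):min(n - 5L, idx + span)
    # short scoring window: far past contact the force-vs-piezo record
    # flattens through cantilever compliance, which would bias the fit
    fit_end <- min(n, i_cross + 3L * span)
    p <- raw$piezo_nm[seq_len(fit_end)]
    f <- raw$force_nN[seq_len(fit_end)]
    sse <- vapply(cand, function(i0) {
      x <- pmax(p - p[i0], 0)^1.5
      a <- sum(f * x) / sum(x^2)
      if (!is.finite(a) || a <= 0) return(Inf)
      sum((f - a * x)^2)
    }, 0)
    if (any(is.finite(sse))) idx <- cand[which.min(sse)]
  }
  out <- raw
  contact_piezo <- raw$piezo_nm[idx]
  out$piezo_nm <- raw$piezo_nm - contact_piezo
  set_raw_meta(out, contact_index = idx, contact_piezo_nm = contact_piezo)
}

#' Subtract the cantilever bending from the piezo travel
#'
#' The piezo travel past contact splits into true tip-sample indentation and
#' the deflection of the cantilever itself, `F / k` (force in nN over
#' stiffness in N/m gives nm directly). Subtracting the deflection yields
#' the tip-sample F-D curve. A warning is issued if the corrected
#' displacements lose monotonicity beyond what noise explains (offending
#' samples are dropped).
#'
#' @param raw a baselined, contact-referenced [raw_fd_curve()].
#' @return An [fd_curve()] (`meta$compliance_corrected = TRUE`).
#' @export
correct_cantilever_bending <- function(raw) {
  stopifnot(inherits(raw, "raw_fd_curve"))
  m <- raw_meta(raw)
  if (is.null(m$contact_index))
    stop("contact point must be detected first (see detect_contact_point)",
         call. = FALSE)
  k <- m$cantilever_k_N_per_m
  post <- raw[raw$piezo_nm >= 0, ]
  delta <- post$piezo_nm - post$force_nN / k    # nN / (N/m) = nm
  force <- post$force_nN
  # enforce strict monotonicity: drop samples that backtrack
  ord_keep <- logical(length(delta))
  dmax <- 0
  for (i in seq_along(delta)) {
    if (delta[i] > dmax) { ord_keep[i] <- TRUE; dmax <- delta[i] }
  }
  if (mean(ord_keep) < 0.9)
    warning("corrected displacement strongly non-monotonic; check cantilever stiffness")
  delta <- c(0, delta[ord_keep])
  force <- c(0, force[ord_keep])
  meta <- m
  meta$compliance_corrected <- TRUE
  meta$source <- m$source %||% "measured"
  fd_curve(delta, force, meta)
}

#' Full raw-to-analysis processing chain
#'
#' Applies baseline zeroing, contact-point detection and cantilever-bending
#' correction in their fixed order. Already-processed curves pass through
#' unchanged, so the chain is idempotent.
#'
#' @param raw a [raw_fd_curve()] (or an already processed [fd_curve()]).
#' @param threshold_sd,persistence contact-detection parameters, see
#'   [detect_contact_point()].
#' @return An [fd_curve()].
#' @export
process_fd_curve <- function(raw, threshold_sd = 5, persistence = 10) {
  if (inherits(raw, "fd_curve")) return(raw)
  raw |>
    zero_baseline() |>
    detect_contact_point(threshold_sd = threshold_sd,
                         persistence = persistence) |>
    correct_cantilever_bending()
}

#' Fit the Hertz/Sneddon spherical contact model
#'
#' Least-squares fit of \deqn{F = \frac{4}{3}\,\frac{E}{1-\nu^2}\sqrt{R}\,
#' \delta^{3/2}} for the overall Young's modulus `E`, with the indenter
#' radius `R` taken into account. `F` is linear in `E`, so the least-squares
#' solution is closed-form. The default Poisson ratio 0.5 matches the
#' incompressibility assumption for soft tissue; the fit range defaults to
#' the entire curve from contact to maximum depth.
#'
#' @param curve an [fd_curve()].
#' @param R_um indenter radius (um).
#' @param nu assumed Poisson ratio.
#' @param range_nm length-2 fit window in nm, default the whole curve.
#' @return An object of class `hertz_fit`: `E_kPa`, `R_um`, `nu`,
#'   `range_nm`, `rms_residual_nN`, `n`.
#' @examples
#' d <- seq(0, 338, by = 2)
#' f <- 4 / 3 * (577 / (1 - 0.25)) * sqrt(5) * (d / 1000)^1.5
#' hertz_sneddon_fit(fd_curve(d, f))$E_kPa   # 577
#' @export
hertz_sneddon_fit <- function(curve, R_um = 5, nu = 0.5, range_nm = NULL) {
  stopifnot(inherits(curve, "fd_curve"))
  if (is.null(range_nm)) range_nm <- range(curve$displacement_nm)
  sel <- curve$displacement_nm >= range_nm[1] &
    curve$displacement_nm <= range_nm[2]
  d_um <- curve$displacement_nm[sel] / .nm_per_um
  f <- curve$force_nN[sel]
  x <- (4 / 3) * sqrt(R_um) * d_um^1.5 / (1 - nu^2)
  E <- sum(f * x) / sum(x^2)
  if (!is.finite(E) || E <= 0)
    stop("Hertz/Sneddon fit produced a non-positive modulus", call. = FALSE)
  structure(list(E_kPa = E, R_um = R_um, nu = nu, range_nm = range_nm,
                 rms_residual_nN = sqrt(mean((f - E * x)^2)),
                 n = sum(sel)),
            class = "hertz_fit")
}

#' @export
print.hertz_fit <- function(x, ...) {
  cat(sprintf("Hertz/Sneddon fit: E = %.4g kPa (R = %g um, nu = %g)\n",
              x$E_kPa, x$R_um, x$nu))
  cat(sprintf("  fit range %.0f-%.0f nm, %d points, rms residual %.3g nN\n",
              x$range_nm[1], x$range_nm[2], x$n, x$rms_residual_nN))
  invisible(x)
}

#' Bulk stiffness: linear regression over the upper displacement half
#'
#' Ordinary least-squares slope of force against displacement over the
#' window `[0.5 delta_max, delta_max]`, the standard summary for moderate-
#' to-deep indentation.
#'
#' @param curve an [fd_curve()].
#' @return An object of class `bulk_stiffness`: `slope_nN_per_nm`,
#'   `intercept_nN`, `window_nm`, `n_points`.
#' @export
bulk_stiffness <- function(curve) {
  stopifnot(inherits(curve, "fd_curve"))
  dmax <- max(curve$displacement_nm)
  win <- c(0.5 * dmax, dmax)
  sel <- curve$displacement_nm >= win[1] & curve$displacement_nm <= win[2]
  if (sum(sel) < 2)
    stop("fewer than 2 samples in the [0.5 dmax, dmax] window", call. = FALSE)
  fit <- lm(force_nN ~ displacement_nm, data = curve[sel, ])
  structure(list(slope_nN_per_nm = unname(coef(fit)[2]),
                 intercept_nN = unname(coef(fit)[1]),
                 window_nm = win, n_points = sum(sel)),
            class = "bulk_stiffness")
}

#' @export
print.bulk_stiffness <- function(x, ...) {
  cat(sprintf("bulk stiffness: %.4g nN/nm over [%.0f, %.0f] nm (%d points)\n",
              x$slope_nN_per_nm, x$window_nm[1], x$window_nm[2], x$n_points))
  invisible(x)
}

#' Normalized bulk stiffness of a treated condition against its control
#'
#' @param treated,control [bulk_stiffness()] results.
#' @return The ratio `treated$slope / control$slope` (dimensionless).
#' @examples
#' # a ratio of 0.34 corresponds to a 66% stiffness decrease
#' @export
normalize_stiffness <- function(treated, control) {
  stopifnot(inherits(treated, "bulk_stiffness"),
            inherits(control, "bulk_stiffness"))
  if (control$slope_nN_per_nm <= 0)
    stop("control slope must be positive", call. = FALSE)
  treated$slope_nN_per_nm / control$slope_nN_per_nm
}

#' Read and write force-displacement curves as annotated CSV
#'
#' The on-disk format is plain CSV with two columns, `displacement_nm` and
#' `force_nN`, preceded by `#`-prefixed metadata header lines
#' (`k_N_per_m`, `set_force_nN`, `treatment`, `source`). Raw records
#' (`source: raw`) store piezo position in the displacement column and read
#' back as `raw_fd_curve`.
#'
#' @param curve an [fd_curve()] or [raw_fd_curve()].
#' @param path file path.
#' @return `write_fd_curve` returns `path` invisibly; `read_fd_curve`
#'   returns the curve object.
#' @export
write_fd_curve <- function(curve, path) {
  m <- attr(curve, "meta") %||% list()
  is_raw <- inherits(curve, "raw_fd_curve")
  hdr <- c(
    sprintf("# source: %s", if (is_raw) "raw" else m$source %||% "measured"),
    sprintf("# k_N_per_m: %s", m$cantilever_k_N_per_m %||% "NA"),
    sprintf("# set_force_nN: %s", m$set_force_nN %||% "NA"),
    sprintf("# treatment: %s", m$treatment %||% "NA"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines("displacement_nm,force_nN", con)
  disp <- if (is_raw) curve$piezo_nm else curve$displacement_nm
  writeLines(sprintf("%.10g,%.10g", disp, curve$force_nN), con)
  invisible(path)
}

#' @rdname write_fd_curve
#' @export
read_fd_curve <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (h in hdr) {
    kv <- sub("^#\\s*", "", h)
    key <- sub(":.*$", "", kv)
    val <- trimws(sub("^[^:]*:\\s*", "", kv))
    meta[[key]] <- if (val == "NA") NULL else val
  }
  dat <- read.table(text = lines[!grepl("^#", lines)], sep = ",",
                    header = TRUE)
  if (!all(c("displacement_nm", "force_nN") == names(dat)[1:2]))
    stop("expected columns 'displacement_nm, force_nN'", call. = FALSE)
  k <- suppressWarnings(as.numeric(meta$k_N_per_m))
  sf <- suppressWarnings(as.numeric(meta$set_force_nN))
  if (identical(meta$source, "raw")) {
    raw_fd_curve(dat$displacement_nm, dat$force_nN, k,
                 meta = list(treatment = meta$treatment,
                             set_force_nN = sf, source = "measured"))
  } else {
    fd_curve(dat$displacement_nm, dat$force_nN,
             meta = list(source = meta$source %||% "measured",
                         cantilever_k_N_per_m = k,
                         set_force_nN = sf, treatment = meta$treatment))
  }
}
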