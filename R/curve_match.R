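#' Matching configuration
#'
#' Grid and acceptance parameters for registering the reference curve to a
#' determinative curve by time-axis scaling and shifting.
#'
#' @param s_min,s_max Bounds of the scale-factor grid (`0 < s_min < s_max`).
#' @param s_steps Number of log-spaced scale values.
#' @param tau_min_s,tau_max_s,tau_step_s Shift grid in seconds; shifts are
#'   snapped to the determinative curve's sample grid so a shift is an
#'   exact index offset.
#' @param accept_threshold Minimum agreement for a fit to be accepted;
#'   determinative curves agreeing less than 85% with the adapted
#'   reference are rejected.
#' @param objective `"l1_area"` (default; L1 area disagreement normalized
#'   by the determinative curve area) or `"ncc"` (normalized
#'   cross-correlation, clipped to `[0, 1]`).
#' @param refine_tol Termination width (relative, in scale) of the
#'   golden-section refinement around the best grid cell.
#' @return A `match_config` object.
#' @export
match_config <- function(s_min = 0.25, s_max = 4, s_steps = 121L,
                         tau_min_s = -60, tau_max_s = 60, tau_step_s = 0.5,
                         accept_threshold = 0.85,
                         objective = c("l1_area", "ncc"),
                         refine_tol = 1e-3) {
  if (!(s_min > 0 && s_min < s_max)) stop_validation("need 0 < s_min < s_max")
  if (s_steps < 1L || tau_max_s < tau_min_s || tau_step_s <= 0) {
    stop_validation("empty matching grid")
  }
  if (accept_threshold <= 0 || accept_threshold >= 1) {
    stop_validation("accept_threshold must be in (0, 1)")
  }
  structure(
    list(s_min = s_min, s_max = s_max, s_steps = as.integer(s_steps),
         tau_min_s = tau_min_s, tau_max_s = tau_max_s, tau_step_s = tau_step_s,
         accept_threshold = accept_threshold,
         objective = match.arg(objective), refine_tol = refine_tol),
    class = "match_config"
  )
}

#' Patient reference perfusion profile
#'
#' The preprocessed baseline curve reflecting the patient's normal bowel
#' circulation under anaesthesia. Fits are only meaningful within one
#' bowel type, so the segment type travels with the profile.
#'
#' @param curve Preprocessed (normalized) [perfusion_curve()] with
#'   `source = "reference"`.
#' @param segment_type `"large_bowel"` or `"small_bowel"`.
#' @param patient_id Identifier.
#' @return A `reference_profile` object.
#' @export
reference_profile <- function(curve, segment_type = c("large_bowel", "small_bowel"),
                              patient_id = "patient") {
  segment_type <- match.arg(segment_type)
  r <- range(curve$intensities)
  if (r[1L] < -1e-9 || abs(r[2L] - 1) > 1e-6) {
    stop_validation("reference curve must be normalized to [0, 1] with max 1")
  }
  structure(
    list(curve = curve, segment_type = segment_type,
         patient_id = as.character(patient_id)),
    class = "reference_profile"
  )
}

as_ref_curve <- function(ref) {
  if (inherits(ref, "reference_profile")) ref$curve else ref
}

fitted_reference_values <- function(ref, det, s, tau) {
  u <- (det$times_s - tau) / s
  stats::approx(ref$times_s, ref$intensities, xout = u,
                yleft = 0, yright = 0)$y
}

#' Agreement between a scaled/shifted reference and a determinative curve
#'
#' The adapted reference is `ref((t - tau) / s)`, taken as 0 outside the
#' reference domain. For the default `"l1_area"` objective the agreement is
#' `1 - integral(|adapted_ref - det|) / integral(det)` over the
#' determinative grid, clipped to `[0, 1]`.
#'
#' @param ref Reference [perfusion_curve()] or [reference_profile()],
#'   normalized, on a uniform grid.
#' @param det Determinative [perfusion_curve()], normalized, uniform grid.
#' @param s Time-axis scale factor (> 0).
#' @param tau Time shift in seconds.
#' @param objective `"l1_area"` or `"ncc"`.
#' @return Agreement fraction in `[0, 1]`.
#' @export
agreement <- function(ref, det, s, tau, objective = "l1_area") {
  ref <- as_ref_curve(ref)
  dt <- curve_dt(det)
  det_area <- sum(det$intensities) * dt
  if (det_area <= 0) {
    stop(errorCondition("unquantifiable determinative curve (zero area)",
                        class = c("qicgfa_unquantifiable", "error")))
  }
  fit <- fitted_reference_values(ref, det, s, tau)
  a <- if (objective == "ncc") {
    if (stats::sd(fit) == 0 || stats::sd(det$intensities) == 0) 0
    else stats::cor(fit, det$intensities)
  } else {
    1 - sum(abs(fit - det$intensities)) * dt / det_area
  }
  min(max(a, 0), 1)
}

golden_max <- function(f, lo, hi, tol) {
  gr <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  x1 <- b - gr * (b - a); x2 <- a + gr * (b - a)
  f1 <- f(x1); f2 <- f(x2)
  while (b - a > tol) {
    if (f1 < f2) {
      a <- x1; x1 <- x2; f1 <- f2
      x2 <- a + gr * (b - a); f2 <- f(x2)
    } else {
      b <- x2; x2 <- x1; f2 <- f1
      x1 <- b - gr * (b - a); f1 <- f(x1)
    }
  }
  x <- (a + b) / 2
  list(x = x, value = f(x))
}

#' Fit the reference profile to a determinative curve
#'
#' Grid search over time-axis scale and shift (log-spaced scale grid,
#' grid-snapped shifts), followed by golden-section refinement of scale and
#' shift around the best cell. The reference curve is the one adapted: a
#' scale below 1 narrows it (the determinative perfusion is brisker than
#' baseline), above 1 broadens it (slower). Amplitude is never fitted.
#'
#' @param profile A [reference_profile()] (or bare normalized reference
#'   curve).
#' @param det Preprocessed determinative [perfusion_curve()].
#' @param cfg A [match_config()].
#' @param search_decim Temporal decimation factor applied to both curves
#'   during the grid-search stage only (the refinement always runs at full
#'   resolution). `NULL` picks the factor bringing the search grid to
#'   roughly 600 samples; 1 disables decimation.
#' @return A `curve_fit` object: `scale_s`, `shift_tau_s`, `agreement`
#'   (the "fit peak"), `diff_curve_area`, `accepted`, `briskness`
#'   (`1/scale_s`), plus the ROI identity of `det`. Grid-cell ties are
#'   broken by the smallest `|tau|`, then the scale nearest 1.
#' @export
fit_reference <- function(profile, det, cfg = match_config(),
                          search_decim = NULL) {
  ref <- as_ref_curve(profile)
  if (!is_uniform_grid(ref) || !is_uniform_grid(det)) {
    stop_validation("fit_reference requires uniform time grids; resample first")
  }
  det_dt <- curve_dt(det)
  n_det <- length(det$times_s)
  if (is.null(search_decim)) search_decim <- max(1L, n_det %/% 600L)
  dec_idx <- seq(1L, n_det, by = search_decim)
  det_s <- det$intensities[dec_idx]
  dt_s <- det_dt * search_decim

  s_grid <- exp(seq(log(cfg$s_min), log(cfg$s_max), length.out = cfg$s_steps))
  k_step <- max(1L, as.integer(round(cfg$tau_step_s / dt_s)))
  k_grid <- seq(as.integer(floor(cfg$tau_min_s / dt_s)),
                as.integer(ceiling(cfg$tau_max_s / dt_s)), by = k_step)
  if (!length(s_grid) || !length(k_grid)) stop_validation("empty matching grid")
  tau_grid <- k_grid * dt_s

  if (cfg$objective == "l1_area") {
    A <- agreement_grid_cpp(ref$intensities, ref$times_s[1L], curve_dt(ref),
                            det_s, det$times_s[1L], dt_s,
                            s_grid, as.integer(k_grid))
  } else {
    A <- outer(seq_along(s_grid), seq_along(tau_grid),
               Vectorize(function(i, j) {
                 agreement(ref, det, s_grid[i], tau_grid[j], cfg$objective)
               }))
  }

  best <- max(A)
  cand <- which(A >= best - 1e-12, arr.ind = TRUE)
  ord <- order(abs(tau_grid[cand[, 2L]]), abs(s_grid[cand[, 1L]] - 1))
  si <- cand[ord[1L], 1L]; ti <- cand[ord[1L], 2L]
  s0 <- s_grid[si]; tau0 <- tau_grid[ti]

  obj <- if (cfg$objective == "l1_area") {
    function(s, tau) {
      agreement_point_cpp(ref$intensities, ref$times_s[1L], curve_dt(ref),
                          det$intensities, det$times_s[1L], det_dt, s, tau)
    }
  } else {
    function(s, tau) agreement(ref, det, s, tau, cfg$objective)
  }
  s_lo <- s_grid[max(si - 2L, 1L)]; s_hi <- s_grid[min(si + 2L, length(s_grid))]
  tau_lo <- tau_grid[max(ti - 2L, 1L)]; tau_hi <- tau_grid[min(ti + 2L, length(tau_grid))]
  s_best <- s0; tau_best <- tau0
  s_rad <- (s_hi - s_lo) / 2; tau_rad <- max((tau_hi - tau_lo) / 2, cfg$refine_tol)
  for (round_i in 1:8) {
    s_prev <- s_best; tau_prev <- tau_best
    r <- golden_max(function(s) obj(s, tau_best),
                    max(s_best - s_rad, cfg$s_min / 2),
                    s_best + s_rad, tol = cfg$refine_tol * s_best / 4)
    s_best <- r$x
    r <- golden_max(function(tau) obj(s_best, tau),
                    tau_best - tau_rad, tau_best + tau_rad,
                    tol = cfg$refine_tol / 4)
    tau_best <- r$x
    s_rad <- max(s_rad / 2, 8 * cfg$refine_tol * s_best)
    tau_rad <- max(tau_rad / 2, 8 * cfg$refine_tol)
    if (abs(s_best - s_prev) < cfg$refine_tol * s_best / 2 &&
        abs(tau_best - tau_prev) < cfg$refine_tol / 2) break
  }
  a_best <- obj(s_best, tau_best)
  a0 <- obj(s0, tau0)  # full-resolution value at the winning grid cell
  if (a_best < a0) { s_best <- s0; tau_best <- tau0; a_best <- a0 }

  fit_vals <- fitted_reference_values(ref, det, s_best, tau_best)
  a_fit <- sum(fit_vals) * det_dt
  a_det <- sum(det$intensities) * det_dt
  res <- structure(
    list(
      roi_id = det$roi_id,
      position_index = det$position_index,
      scale_s = s_best,
      shift_tau_s = tau_best,
      agreement = a_best,
      diff_curve_area = abs(a_fit - a_det) / a_det,
      briskness = 1 / s_best,
      accepted = NA
    ),
    class = "curve_fit"
  )
  res$accepted <- accept_fit(res, cfg)
  res
}

#' Fit acceptance rule
#'
#' A determinative curve is accepted when its maximized agreement with the
#' adapted reference reaches the threshold (default 85%); fits below it
#' are rejected and never contribute to a recommendation.
#'
#' @param result A `curve_fit` from [fit_reference()].
#' @param cfg A [match_config()].
#' @return Logical: `TRUE` iff `agreement >= cfg$accept_threshold`.
#' @export
accept_fit <- function(result, cfg = match_config()) {
  isTRUE(result$agreement >= cfg$accept_threshold)
}

#' Interpret a fitted scale factor
#'
#' Narrowing the reference (`s < 1`) means the determinative perfusion is
#' brisker than the patient's baseline; broadening it (`s > 1`) means
#' slower perfusion.
#'
#' @param result An accepted `curve_fit`.
#' @param tol Half-width of the "equal" band around `s = 1`.
#' @return One of `"brisker"`, `"slower"`, `"equal"`.
#' @export
interpret_scale <- function(result, tol = 0.02) {
  s <- result$scale_s
  if (abs(s - 1) <= tol) "equal" else if (s < 1) "brisker" else "slower"
}

#' @export
print.curve_fit <- function(x, ...) {
  cat(sprintf(
    "<curve_fit> %s (pos %d): s = %.4f (briskness %.4f), tau = %.2f s,\n  agreement = %.4f, area diff = %.4f, %s\n",
    x$roi_id, x$position_index, x$scale_s, x$briskness, x$shift_tau_s,
    x$agreement, x$diff_curve_area,
    if (isTRUE(x$accepted)) "ACCEPTED" else "rejected"
  ))
  invisible(x)
}

#' Tabulate curve fits
#'
#' @param fits List of `curve_fit` objects.
#' @return `data.frame` with one row per ROI.
#' @export
fits_table <- function(fits) {
  do.call(rbind, lapply(fits, function(f) {
    data.frame(
      roi_id = f$roi_id, position_index = f$position_index,
      scale_s = f$scale_s, shift_tau_s = f$shift_tau_s,
      agreement = f$agreement, diff_curve_area = f$diff_curve_area,
      briskness = f$briskness, accepted = f$accepted,
      stringsAsFactors = FALSE
    )
  }))
}

#' Serialize curve fits
#'
#' Writes a list of fits as JSON (array of per-ROI objects) or CSV (one
#' row per ROI).
#'
#' @param fits List of `curve_fit` objects.
#' @param path Output path.
#' @param format `"json"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_fit_results <- function(fits, path, format = c("json", "csv")) {
  format <- match.arg(format)
  tab <- fits_table(fits)
  if (format == "json") {
    jsonlite::write_json(tab, path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA)
  } else {
    utils::write.csv(tab, path, row.names = FALSE)
  }
  invisible(path)
}
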