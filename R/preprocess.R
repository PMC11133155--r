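#' Preprocessing configuration
#'
#' Parameters for converting a raw fluorescence intensity series into a
#' background-free, uniformly sampled, smoothed and normalized curve.
#'
#' @param baseline_window_s Seconds at the start of the recording used to
#'   estimate background fluorescence (median); default 5 s, i.e. before
#'   dye inflow can plausibly arrive.
#' @param sg_window_s Savitzky-Golay window length in seconds. The window
#'   in samples is `2*floor(sg_window_s*resample_hz/2)+1`, i.e. rounded to
#'   the nearest odd count (31 samples at 30 Hz, 11 at the default 10 Hz).
#' @param sg_polyorder Savitzky-Golay polynomial order; must be smaller
#'   than the window length in samples.
#' @param resample_hz Common uniform grid frequency for matching.
#' @return A `preprocess_config` object.
#' @export
preprocess_config <- function(baseline_window_s = 5, sg_window_s = 1.0,
                              sg_polyorder = 3L, resample_hz = 10) {
  if (baseline_window_s < 0) stop_validation("baseline_window_s must be >= 0")
  if (resample_hz <= 0) stop_validation("resample_hz must be > 0")
  w <- sg_window_samples(sg_window_s, resample_hz)
  if (w <= sg_polyorder) {
    stop_validation("Savitzky-Golay window (%d samples) must exceed polyorder %d",
                    w, sg_polyorder)
  }
  structure(
    list(baseline_window_s = baseline_window_s, sg_window_s = sg_window_s,
         sg_polyorder = as.integer(sg_polyorder), resample_hz = resample_hz),
    class = "preprocess_config"
  )
}

sg_window_samples <- function(sg_window_s, hz) {
  2L * as.integer(floor(sg_window_s * hz / 2)) + 1L
}

#' Subtract background fluorescence
#'
#' Estimates background as the median intensity over the initial baseline
#' window and subtracts it, flooring the result at zero. Residual
#' fluorescence from earlier dye doses appears as a constant pedestal,
#' which this removes.
#'
#' @param curve A [perfusion_curve()] spanning at least
#'   `cfg$baseline_window_s` seconds.
#' @param cfg A [preprocess_config()].
#' @return Background-subtracted [perfusion_curve()].
#' @export
subtract_background <- function(curve, cfg = preprocess_config()) {
  span <- diff(range(curve$times_s))
  if (span < cfg$baseline_window_s) {
    stop_validation("baseline window (%g s) longer than curve (%g s)",
                    cfg$baseline_window_s, span)
  }
  in_win <- curve$times_s <= curve$times_s[1L] + cfg$baseline_window_s
  bg <- stats::median(curve$intensities[in_win])
  replace_intensities(curve, pmax(curve$intensities - bg, 0))
}

#' Resample a curve onto a uniform grid
#'
#' Linear interpolation onto a grid at `cfg$resample_hz` spanning
#' `[0, duration]` where duration is the last sample time.
#'
#' @inheritParams subtract_background
#' @return Resampled [perfusion_curve()].
#' @export
resample_curve <- function(curve, cfg = preprocess_config()) {
  if (length(curve$times_s) < 2L) stop_validation("resample needs >= 2 samples")
  duration <- curve$times_s[length(curve$times_s)]
  grid <- seq(0, by = 1 / cfg$resample_hz,
              length.out = floor(duration * cfg$resample_hz + 1e-9) + 1L)
  vals <- stats::approx(curve$times_s, curve$intensities, xout = grid,
                        rule = 2)$y
  replace_intensities(curve, vals, times = grid)
}

# Savitzky-Golay hat matrix for a window of w samples, polynomial order p.
sg_hat <- function(w, p) {
  x <- seq_len(w) - (w + 1) / 2
  X <- outer(x, 0:p, `^`)
  X %*% solve(crossprod(X), t(X))
}

#' Savitzky-Golay smoothing
#'
#' Local least-squares polynomial smoothing on a uniform grid. Interior
#' points use the standard convolution weights; edge points are fitted by
#' the polynomial of the first/last full window evaluated at their
#' positions, so polynomials up to `sg_polyorder` are reproduced exactly
#' everywhere.
#'
#' @inheritParams subtract_background
#' @return Smoothed [perfusion_curve()] of identical length.
#' @export
smooth_curve <- function(curve, cfg = preprocess_config()) {
  if (!is_uniform_grid(curve)) {
    stop_validation("smooth_curve requires a uniform time grid; resample first")
  }
  n <- length(curve$times_s)
  hz <- 1 / curve_dt(curve)
  w <- sg_window_samples(cfg$sg_window_s, hz)
  if (w <= cfg$sg_polyorder) {
    stop_validation("Savitzky-Golay window (%d) must exceed polyorder %d",
                    w, cfg$sg_polyorder)
  }
  if (w > n) stop_validation("Savitzky-Golay window (%d) exceeds curve length (%d)", w, n)
  H <- sg_hat(w, cfg$sg_polyorder)
  half <- (w - 1L) %/% 2L
  y <- curve$intensities
  sm <- stats::filter(y, H[half + 1L, ], sides = 2)
  sm <- as.numeric(sm)
  sm[seq_len(half)] <- H[seq_len(half), , drop = FALSE] %*% y[seq_len(w)]
  sm[(n - half + 1L):n] <- H[(half + 2L):w, , drop = FALSE] %*% y[(n - w + 1L):n]
  replace_intensities(curve, sm)
}

#' Min-max normalize a curve to [0, 1]
#'
#' Affine map of intensities sending the minimum to 0 and the maximum to 1.
#' The matching stage works on curve timing, not absolute brightness, so
#' all downstream analysis is invariant to positive affine intensity
#' transforms of the raw signal.
#'
#' @param curve A [perfusion_curve()] with `max > min`.
#' @return Normalized [perfusion_curve()].
#' @export
normalize_curve <- function(curve) {
  r <- range(curve$intensities)
  if (r[1L] == r[2L]) {
    stop(errorCondition(
      sprintf("unquantifiable ROI '%s': constant intensity", curve$roi_id),
      class = c("qicgfa_unquantifiable", "error")
    ))
  }
  replace_intensities(curve, (curve$intensities - r[1L]) / (r[2L] - r[1L]))
}

#' Full preprocessing pipeline
#'
#' Applies, in fixed order: background subtraction, resampling to the
#' common grid, Savitzky-Golay smoothing, min-max normalization. The order
#' is recorded in the result's `provenance` attribute.
#'
#' @inheritParams subtract_background
#' @return Preprocessed [perfusion_curve()] with intensities in `[0, 1]`.
#' @export
preprocess_curve <- function(curve, cfg = preprocess_config()) {
  out <- subtract_background(curve, cfg)
  out <- resample_curve(out, cfg)
  out <- smooth_curve(out, cfg)
  out <- normalize_curve(out)
  out$intensities <- pmin(pmax(out$intensities, 0), 1)
  attr(out, "provenance") <- list(
    steps = c("subtract_background", "resample", "savitzky_golay", "normalize"),
    config = unclass(cfg)
  )
  out
}
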