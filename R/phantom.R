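#' Gamma-variate bolus kinetic parameters
#'
#' Standard dye-bolus transit model: a gamma-variate inflow rising from
#' `onset_t0_s` to a peak at `peak_tp_s`, followed by an exponential
#' washout decaying towards a residual plateau (ICG is not fully cleared
#' within a 4-minute angiogram).
#'
#' @param onset_t0_s Inflow start time (s).
#' @param peak_tp_s Time of peak (s); must exceed `onset_t0_s`.
#' @param alpha Gamma-variate shape parameter (> 0).
#' @param amplitude Peak intensity before normalization.
#' @param washout_tau_s Post-peak exponential decay constant (s).
#' @param plateau Residual fraction of peak retained at late times
#'   (`0 <= plateau < 1`).
#' @return A `kinetic_params` object.
#' @export
kinetic_params <- function(onset_t0_s = 15, peak_tp_s = 45, alpha = 2.5,
                           amplitude = 1, washout_tau_s = 90, plateau = 0.35) {
  if (peak_tp_s <= onset_t0_s) stop_validation("peak_tp_s must exceed onset_t0_s")
  if (alpha <= 0) stop_validation("alpha must be > 0")
  if (plateau < 0 || plateau >= 1) stop_validation("plateau must be in [0, 1)")
  if (washout_tau_s <= 0 || amplitude <= 0) {
    stop_validation("washout_tau_s and amplitude must be > 0")
  }
  structure(
    list(onset_t0_s = onset_t0_s, peak_tp_s = peak_tp_s, alpha = alpha,
         amplitude = amplitude, washout_tau_s = washout_tau_s,
         plateau = plateau),
    class = "kinetic_params"
  )
}

# Multiply every time parameter by `d`: a pure time dilation about t = 0,
# exactly the transformation the matcher's scale factor models.
dilate_params <- function(params, d) {
  params$onset_t0_s <- params$onset_t0_s * d
  params$peak_tp_s <- params$peak_tp_s * d
  params$washout_tau_s <- params$washout_tau_s * d
  params
}

#' Evaluate a gamma-variate perfusion curve
#'
#' `f(t) = 0` before onset; `A * x^alpha * exp(alpha * (1 - x))` with
#' `x = (t - t0)/(tp - t0)` on the rise (peaking at exactly `A` at `tp`);
#' `A * ((1 - plateau) * exp(-(t - tp)/washout_tau) + plateau)` afterwards.
#' The pieces join continuously at the peak. Multiplying `t0`, `tp` and
#' `washout_tau` by `d` time-dilates the curve exactly by `d` about 0.
#'
#' @param params A [kinetic_params()].
#' @param times Numeric vector of sample times (s), uniform.
#' @param roi_id,position_index,source Passed to [perfusion_curve()].
#' @return A [perfusion_curve()].
#' @export
gamma_variate <- function(params, times, roi_id = "roi", position_index = 0L,
                          source = "determinative") {
  t0 <- params$onset_t0_s; tp <- params$peak_tp_s
  a <- params$alpha; A <- params$amplitude
  x <- (times - t0) / (tp - t0)
  y <- numeric(length(times))
  rise <- times >= t0 & times <= tp
  y[rise] <- A * x[rise]^a * exp(a * (1 - x[rise]))
  fall <- times > tp
  y[fall] <- A * ((1 - params$plateau) *
                    exp(-(times[fall] - tp) / params$washout_tau_s) +
                    params$plateau)
  perfusion_curve(times, y, roi_id = roi_id, position_index = position_index,
                  source = source)
}

#' Phantom specification
#'
#' Describes a synthetic bowel segment: `n_rois` sampling positions at
#' `spacing_cm` intervals, normally perfused up to `ischemia_start_index`
#' and progressively compromised beyond it. Ischemia is modeled as a joint
#' per-position time dilation (carrying the recoverable timing signal) and
#' amplitude attenuation (the "dim" appearance, which normalization
#' removes).
#'
#' @param n_rois Number of ROI positions (default 11, the granularity of a
#'   typical validation judgment series).
#' @param spacing_cm Physical ROI spacing (default 2 cm markings).
#' @param ischemia_start_index First compromised position (0-based);
#'   `n_rois` means no ischemia anywhere.
#' @param dilation_gradient Time-scale multiplier applied per position
#'   beyond the boundary (`>= 1`).
#' @param attenuation_gradient Amplitude multiplier per position beyond
#'   the boundary (`0 <` ... `<= 1`).
#' @param noise_sigma Gaussian noise SD in intensity units (amplitude 1).
#' @param background Constant background fluorescence added to all curves.
#' @param duration_s Recording length (4-minute angiogram).
#' @param rate_hz Sampling rate (30 fps video).
#' @param baseline A [kinetic_params()] for the healthy curve.
#' @param seed Integer seed; same seed, bit-identical phantom.
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(n_rois = 11L, spacing_cm = 2,
                         ischemia_start_index = 6L, dilation_gradient = 1.3,
                         attenuation_gradient = 0.8, noise_sigma = 0.02,
                         background = 0.05, duration_s = 240, rate_hz = 30,
                         baseline = kinetic_params(), seed = 1L) {
  if (ischemia_start_index < 0L || ischemia_start_index > n_rois) {
    stop_validation("ischemia_start_index must be in [0, n_rois]")
  }
  if (dilation_gradient < 1) stop_validation("dilation_gradient must be >= 1")
  if (attenuation_gradient <= 0 || attenuation_gradient > 1) {
    stop_validation("attenuation_gradient must be in (0, 1]")
  }
  structure(
    list(n_rois = as.integer(n_rois), spacing_cm = spacing_cm,
         ischemia_start_index = as.integer(ischemia_start_index),
         dilation_gradient = dilation_gradient,
         attenuation_gradient = attenuation_gradient,
         noise_sigma = noise_sigma, background = background,
         duration_s = duration_s, rate_hz = rate_hz, baseline = baseline,
         seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

ischemia_power <- function(spec, i) max(0L, i - spec$ischemia_start_index + 1L)

phantom_position_params <- function(spec, i) {
  p <- ischemia_power(spec, i)
  params <- dilate_params(spec$baseline, spec$dilation_gradient^p)
  params$amplitude <- params$amplitude * spec$attenuation_gradient^p
  params
}

#' Generate a synthetic bowel perfusion phantom
#'
#' Produces a reference curve from the baseline kinetics and one
#' determinative curve per ROI position, with positions at and beyond
#' `ischemia_start_index` progressively time-dilated and attenuated.
#' Gaussian noise and a constant background are added, and ground truth is
#' returned for recovery testing.
#'
#' @param spec A [phantom_spec()].
#' @return List with `reference` (a [perfusion_curve()]),
#'   `determinative` (list of curves), and `truth` (a
#'   `phantom_ground_truth`: per-position [kinetic_params()], dilation
#'   factors, `true_sufficient_set`, `true_boundary_index`).
#' @export
make_phantom <- function(spec = phantom_spec()) {
  times <- seq(0, spec$duration_s, by = 1 / spec$rate_hz)
  rng <- make_rng(spec$seed)
  noisy <- function(curve) {
    replace_intensities(
      curve,
      pmax(curve$intensities + spec$background +
             rng$rnorm(length(curve$intensities), sd = spec$noise_sigma), 0)
    )
  }
  reference <- noisy(gamma_variate(spec$baseline, times, roi_id = "ref",
                                   source = "reference"))
  per_position <- lapply(seq_len(spec$n_rois) - 1L, function(i) {
    phantom_position_params(spec, i)
  })
  determinative <- lapply(seq_len(spec$n_rois) - 1L, function(i) {
    noisy(gamma_variate(per_position[[i + 1L]], times,
                        roi_id = sprintf("roi_%02d", i), position_index = i,
                        source = "determinative"))
  })
  truth <- structure(
    list(
      params = per_position,
      dilation = vapply(seq_len(spec$n_rois) - 1L, function(i) {
        spec$dilation_gradient^ischemia_power(spec, i)
      }, numeric(1L)),
      true_boundary_index = spec$ischemia_start_index,
      true_sufficient_set = seq_len(spec$ischemia_start_index) - 1L
    ),
    class = "phantom_ground_truth"
  )
  list(reference = reference, determinative = determinative, truth = truth)
}

#' Render a phantom as a fluorescence video
#'
#' The bowel is a horizontal band across the frame; each pixel column
#' follows the kinetic curve of its (linearly interpolated) position along
#' the bowel, scaled to 8-bit, plus per-pixel Gaussian noise over a low
#' constant background. Proximal is at the left edge (column 0).
#'
#' @param spec A [phantom_spec()]; `rate_hz` also sets the video frame
#'   rate (use a reduced rate to bound memory).
#' @param width,height Frame dimensions in pixels (`>= 16`).
#' @param band_fraction Fraction of the frame height covered by the bowel
#'   band.
#' @param peak_intensity 8-bit value the healthy peak maps to.
#' @param background_level Constant background grey level.
#' @return List with `video` (a [video_stack()] including a synthetic
#'   white-light frame), `mask` (logical band mask), `truth` (ground truth
#'   with `boundary_col`, the first compromised pixel column).
#' @export
make_phantom_video <- function(spec = phantom_spec(), width = 256L,
                               height = 64L, band_fraction = 0.5,
                               peak_intensity = 200, background_level = 10) {
  if (width < 16L || height < 16L) stop_validation("video must be >= 16x16")
  times <- seq(0, spec$duration_s, by = 1 / spec$rate_hz)
  nt <- length(times)
  rng <- make_rng(spec$seed + 7919L)
  # columns take the kinetics of their nearest ROI position, so zone
  # boundaries in the video are sharp (matching the ROI phantom)
  col_pos <- (seq_len(width) - 1L) / (width - 1L) * (spec$n_rois - 1L)
  pos_idx <- pmin(as.integer(round(col_pos)), spec$n_rois - 1L)
  pos_curves <- vapply(seq_len(spec$n_rois) - 1L, function(i) {
    gamma_variate(phantom_position_params(spec, i), times)$intensities
  }, numeric(nt))
  col_curves <- pos_curves[, pos_idx + 1L, drop = FALSE]
  band_h <- max(1L, as.integer(round(height * band_fraction)))
  r0 <- (height - band_h) %/% 2L + 1L
  band_rows <- r0:(r0 + band_h - 1L)
  mask <- matrix(FALSE, height, width)
  mask[band_rows, ] <- TRUE
  frames <- array(background_level, dim = c(height, width, nt))
  for (k in seq_len(nt)) {
    sig <- background_level + peak_intensity * col_curves[k, ]
    frames[band_rows, , k] <- matrix(sig, nrow = band_h, ncol = width,
                                     byrow = TRUE)
  }
  frames <- frames + array(rng$rnorm(length(frames),
                                     sd = spec$noise_sigma * peak_intensity),
                           dim = dim(frames))
  frames <- pmin(pmax(frames, 0), 255)
  wl <- array(0.2, dim = c(height, width, 3L))
  wl[, , 1L][mask] <- 0.8; wl[, , 2L][mask] <- 0.55; wl[, , 3L][mask] <- 0.5
  video <- video_stack(frames, frame_rate = spec$rate_hz, white_light_frame = wl)
  boundary_col <- if (spec$ischemia_start_index >= spec$n_rois) width else {
    which(pos_idx >= spec$ischemia_start_index)[1L] - 1L  # 0-based
  }
  truth <- list(boundary_col = boundary_col, col_position_index = pos_idx,
                band_rows = band_rows)
  list(video = video, mask = mask, truth = truth)
}

#' Simulate per-position tissue lactate
#'
#' Serosal-incision lactate rises with ischemic burden:
#' `lactate_i = base + slope * (dilation_i - 1) + noise`, with ratios
#' taken against the most proximal position.
#'
#' @param truth A `phantom_ground_truth` from [make_phantom()].
#' @param base_mgdl Baseline lactate (healthy bowel), mg/dl.
#' @param slope_mgdl Increase per unit of excess dilation, mg/dl.
#' @param noise_sigma Measurement noise SD, mg/dl.
#' @param seed Integer seed.
#' @return `data.frame` with `position_index`, `lactate_mgdl`,
#'   `lactate_ratio`.
#' @export
make_lactate <- function(truth, base_mgdl = 1.2, slope_mgdl = 2.0,
                         noise_sigma = 0.1, seed = 1L) {
  rng <- make_rng(seed)
  lact <- base_mgdl + slope_mgdl * (truth$dilation - 1) +
    rng$rnorm(length(truth$dilation), sd = noise_sigma)
  lact <- pmax(lact, 0.05)
  data.frame(
    position_index = seq_along(lact) - 1L,
    lactate_mgdl = lact,
    lactate_ratio = lact / lact[1L]
  )
}

# Seeded RNG stream that never touches the caller's .Random.seed.
make_rng <- function(seed) {
  env <- new.env()
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed))
  env$state <- get(".Random.seed", globalenv())
  if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, globalenv())
  env$rnorm <- function(n, sd = 1) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, globalenv())
    out <- stats::rnorm(n, sd = sd)
    env$state <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, globalenv())
    out
  }
  env
}
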