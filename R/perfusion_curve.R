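#' Perfusion time-intensity curve
#'
#' The elementary data object of the package: one fluorescence
#' time-intensity series extracted from a region of interest (ROI) or a
#' pixel block of an ICG fluorescence angiogram.
#'
#' @param times_s Numeric vector of sample times in seconds from the start
#'   of the recording; must be strictly increasing.
#' @param intensities Numeric vector of fluorescence intensities (arbitrary
#'   units, or `[0, 1]` after [normalize_curve()]); same length as `times_s`.
#' @param roi_id Character identifier of the ROI.
#' @param position_index Integer ordinal along the bowel; 0 is the most
#'   proximal position and indices increase distally.
#' @param source Either `"reference"` (baseline angiogram acquired before
#'   dissection) or `"determinative"` (perianastomotic angiogram on which
#'   the transection decision is made).
#' @return An object of class `perfusion_curve`.
#' @examples
#' pc <- perfusion_curve(0:9, c(0, 0, 1, 4, 8, 10, 9, 7, 6, 5), roi_id = "r1")
#' pc
#' @export
perfusion_curve <- function(times_s, intensities, roi_id = "roi",
                            position_index = 0L, source = "determinative") {
  times_s <- as.numeric(times_s)
  intensities <- as.numeric(intensities)
  if (length(times_s) != length(intensities)) {
    stop("times_s and intensities must have equal length", call. = FALSE)
  }
  if (length(times_s) > 1L && any(diff(times_s) <= 0)) {
    stop("times_s must be strictly increasing", call. = FALSE)
  }
  source <- match.arg(source, c("reference", "determinative"))
  structure(
    list(
      times_s = times_s,
      intensities = intensities,
      roi_id = as.character(roi_id),
      position_index = as.integer(position_index),
      source = source
    ),
    class = "perfusion_curve"
  )
}

#' @export
print.perfusion_curve <- function(x, ...) {
  n <- length(x$times_s)
  span <- if (n) sprintf("%.1f-%.1f s", x$times_s[1L], x$times_s[n]) else "empty"
  cat(sprintf(
    "<perfusion_curve> %s (%s, position %d): %d samples, %s\n",
    x$roi_id, x$source, x$position_index, n, span
  ))
  if (n) {
    cat(sprintf(
      "  intensity range [%.4g, %.4g]\n",
      min(x$intensities), max(x$intensities)
    ))
  }
  invisible(x)
}

#' @export
length.perfusion_curve <- function(x) length(x$times_s)

#' @export
as.data.frame.perfusion_curve <- function(x, ...) {
  data.frame(
    time_s = x$times_s,
    roi_id = x$roi_id,
    position_index = x$position_index,
    source = x$source,
    intensity = x$intensities,
    stringsAsFactors = FALSE
  )
}

# TRUE when the curve sits on a uniform grid (within 1e-6 of the median step)
is_uniform_grid <- function(curve, tol = 1e-6) {
  dt <- diff(curve$times_s)
  length(dt) == 0L || all(abs(dt - stats::median(dt)) <= tol * max(stats::median(dt), 1))
}

curve_dt <- function(curve) {
  if (length(curve$times_s) < 2L) stop("curve has fewer than 2 samples", call. = FALSE)
  stats::median(diff(curve$times_s))
}

replace_intensities <- function(curve, values, times = curve$times_s) {
  out <- curve
  out$times_s <- times
  out$intensities <- values
  out
}
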