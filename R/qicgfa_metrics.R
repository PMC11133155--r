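#' Detect dye inflow onset (end of latency)
#'
#' The pre-inflow latency ends at the first time the normalized curve
#' reaches the onset threshold and stays at or above it for at least
#' `sustain_s` seconds, which guards against isolated noise spikes.
#'
#' @param curve Normalized [perfusion_curve()] on a uniform grid.
#' @param threshold Onset intensity threshold (default 0.10 of peak).
#' @param sustain_s Minimum time the curve must remain above threshold.
#' @return Onset time in seconds (equals the latency).
#' @export
detect_onset <- function(curve, threshold = 0.10, sustain_s = 1) {
  n <- length(curve$times_s)
  dt <- curve_dt(curve)
  need <- max(1L, as.integer(ceiling(sustain_s / dt)))
  above <- curve$intensities >= threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ok <- which(r$values & (r$lengths >= need | ends == n))
  if (!length(ok)) {
    stop(errorCondition("no inflow detected (curve never sustains threshold)",
                        class = c("qicgfa_no_inflow", "error")))
  }
  curve$times_s[starts[ok[1L]]]
}

ls_slope <- function(t, y) {
  if (length(t) < 2L) return(NA_real_)
  stats::cov(t, y) / stats::var(t)
}

interp_at <- function(curve, t) {
  stats::approx(curve$times_s, curve$intensities, xout = t, rule = 1)$y
}

# first time >= from where curve crosses `level` going up, linear interp
first_crossing <- function(curve, level, from) {
  idx <- which(curve$times_s >= from)
  tt <- curve$times_s[idx]; yy <- curve$intensities[idx]
  hit <- which(yy >= level)
  if (!length(hit)) return(NA_real_)
  i <- hit[1L]
  if (i == 1L || yy[i] == level) return(tt[i])
  t0 <- tt[i - 1L]; t1 <- tt[i]; y0 <- yy[i - 1L]; y1 <- yy[i]
  t0 + (level - y0) / (y1 - y0) * (t1 - t0)
}

#' Conventional QICGFA time-intensity descriptors
#'
#' Computes the descriptor set used by earlier quantitative ICGFA work:
#' latency (pre-inflow period), peak intensity `Fmax`, time to peak from
#' onset `Tmax`, time to half-peak `T1/2`, inflow `upslope` and overall
#' `downslope` (least-squares gradients), intensity and local gradient at
#' 50 and 100 s post peak (`F50/D50`, `F100/D100`), the time ratio
#' `TR = T1/2 : Tmax`, and the intensity-weighted centre of mass of the
#' whole recording. Quantities falling beyond the recording are `NA` and
#' listed in the `flags` field.
#'
#' @param curve Normalized [perfusion_curve()] on a uniform grid.
#' @param onset_threshold,sustain_s Passed to [detect_onset()].
#' @param slope_halfwindow_s Half-width of the window for the local D50 /
#'   D100 gradients.
#' @return An object of class `qicgfa_metrics` (a named list).
#' @export
compute_metrics <- function(curve, onset_threshold = 0.10, sustain_s = 1,
                            slope_halfwindow_s = 5) {
  onset <- detect_onset(curve, onset_threshold, sustain_s)
  tt <- curve$times_s; yy <- curve$intensities
  n <- length(tt)
  peak_i <- which.max(yy)
  t_peak <- tt[peak_i]
  fmax <- yy[peak_i]
  if (t_peak <= onset) stop_validation("peak not after onset")
  flags <- character(0)

  tmax <- t_peak - onset
  t_half_abs <- first_crossing(curve, fmax / 2, onset)
  t_half <- if (is.na(t_half_abs)) NA_real_ else t_half_abs - onset

  rise <- tt >= onset & tt <= t_peak
  upslope <- ls_slope(tt[rise], yy[rise])
  if (peak_i == n) {
    downslope <- NA_real_
    flags <- c(flags, "downslope_undefined_peak_at_end")
  } else {
    fall <- tt >= t_peak
    downslope <- ls_slope(tt[fall], yy[fall])
  }

  post <- function(delta) {
    tp <- t_peak + delta
    if (tp > tt[n]) {
      flags <<- c(flags, sprintf("t%d_beyond_recording", delta))
      return(list(t = NA_real_, f = NA_real_, d = NA_real_))
    }
    win <- tt >= tp - slope_halfwindow_s & tt <= tp + slope_halfwindow_s
    list(t = tp, f = interp_at(curve, tp), d = ls_slope(tt[win], yy[win]))
  }
  p50 <- post(50); p100 <- post(100)

  structure(
    list(
      roi_id = curve$roi_id, position_index = curve$position_index,
      latency_s = onset, fmax = fmax, tmax_s = tmax, t_half_s = t_half,
      upslope = upslope, downslope = downslope,
      t50_s = p50$t, f50 = p50$f, d50 = p50$d,
      t100_s = p100$t, f100 = p100$f, d100 = p100$d,
      tr = if (is.na(t_half)) NA_real_ else t_half / tmax,
      centre_of_mass_s = sum(tt * yy) / sum(yy),
      flags = flags
    ),
    class = "qicgfa_metrics"
  )
}

#' @export
print.qicgfa_metrics <- function(x, ...) {
  cat(sprintf(
    "<qicgfa_metrics> %s: latency %.1f s, Fmax %.3f at Tmax %.1f s, T1/2 %.1f s (TR %.2f),\n  upslope %.4g/s, downslope %.4g/s, C.M. %.1f s\n",
    x$roi_id, x$latency_s, x$fmax, x$tmax_s, x$t_half_s, x$tr,
    x$upslope, x$downslope, x$centre_of_mass_s
  ))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Per-ROI metrics table
#'
#' One row per curve with all conventional descriptors, optionally merged
#' with the curve-fit outputs (scale factor, area difference, fit peak,
#' acceptance) for the same positions. Undefined quantities are `NA`.
#'
#' @param curves List of normalized [perfusion_curve()]s.
#' @param fits Optional list of `curve_fit` objects matched by
#'   `position_index`.
#' @param ... Passed to [compute_metrics()].
#' @return `data.frame`, one row per ROI.
#' @export
metrics_table <- function(curves, fits = NULL, ...) {
  rows <- lapply(curves, function(cv) {
    m <- tryCatch(compute_metrics(cv, ...), qicgfa_no_inflow = function(e) NULL)
    base <- data.frame(roi_id = cv$roi_id, position_index = cv$position_index,
                       stringsAsFactors = FALSE)
    cols <- c("latency_s", "fmax", "tmax_s", "t_half_s", "upslope", "downslope",
              "t50_s", "f50", "d50", "t100_s", "f100", "d100", "tr",
              "centre_of_mass_s")
    for (cn in cols) base[[cn]] <- if (is.null(m)) NA_real_ else m[[cn]]
    base
  })
  tab <- do.call(rbind, rows)
  if (!is.null(fits)) {
    ft <- fits_table(fits)
    ft$roi_id <- NULL
    tab <- merge(tab, ft, by = "position_index", all.x = TRUE, sort = TRUE)
  }
  tab[order(tab$position_index), , drop = FALSE]
}
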