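#' Per-pixel (block) curve fitting over an annotated region
#'
#' Applies the reference-matching fit to the perfusion curve of every
#' `bin x bin` pixel block inside the annotated antimesenteric region.
#' Blocks whose curve is unquantifiable (constant / zero area) are marked
#' rejected rather than erroring the whole field.
#'
#' @param profile A [reference_profile()].
#' @param video A [video_stack()].
#' @param mask Logical matrix, same size as a frame.
#' @param bin Block edge length in pixels.
#' @param preprocess_cfg A [preprocess_config()].
#' @param match_cfg A [match_config()]; the default uses a lighter grid
#'   (61 scale steps, shifts in `[-30, 30]` s) than the ROI path because
#'   hundreds of blocks are fitted per frame.
#' @return A `scale_field`: matrices `scale_s`, `agreement`, `briskness`,
#'   `accepted` in block coordinates (`NA` outside the mask), plus `bin`,
#'   `mask` and the frame dimensions.
#' @export
fit_all_pixels <- function(profile, video, mask, bin = 4L,
                           preprocess_cfg = preprocess_config(),
                           match_cfg = match_config(s_steps = 61L,
                                                    tau_min_s = -30,
                                                    tau_max_s = 30)) {
  curves <- extract_pixel_curves(video, mask, bin = bin)
  d <- dim(video$frames)
  nbr <- (d[1L] + bin - 1L) %/% bin
  nbc <- (d[2L] + bin - 1L) %/% bin
  empty <- matrix(NA_real_, nbr, nbc)
  field <- structure(
    list(scale_s = empty, agreement = empty, briskness = empty,
         accepted = matrix(NA, nbr, nbc), bin = as.integer(bin),
         mask = mask, frame_dim = d[1:2]),
    class = "scale_field"
  )
  for (cv in curves) {
    r <- attr(cv, "block_row") + 1L
    cc <- attr(cv, "block_col") + 1L
    fit <- tryCatch({
      pc <- preprocess_curve(cv, preprocess_cfg)
      fit_reference(profile, pc, match_cfg)
    }, qicgfa_unquantifiable = function(e) NULL)
    if (is.null(fit)) {
      field$accepted[r, cc] <- FALSE
      next
    }
    field$scale_s[r, cc] <- fit$scale_s
    field$agreement[r, cc] <- fit$agreement
    field$briskness[r, cc] <- fit$briskness
    field$accepted[r, cc] <- fit$accepted
  }
  field
}

#' @export
print.scale_field <- function(x, ...) {
  n_blocks <- sum(!is.na(x$accepted))
  n_acc <- sum(x$accepted, na.rm = TRUE)
  cat(sprintf(
    "<scale_field> %dx%d blocks (bin %d): %d fitted, %d accepted\n",
    nrow(x$scale_s), ncol(x$scale_s), x$bin, n_blocks, n_acc
  ))
  invisible(x)
}

#' Three-colour sufficiency classification of a scale field
#'
#' Per accepted block, briskness `b = 1/scale_s` is pooled into a
#' histogram and its 75th percentile `q75` taken as the working
#' "well-perfused" level (allowing parts of the bowel to beat the
#' reference itself). Labels: sufficient (green) for `b >= 0.75 * q75`;
#' insufficient (red) for `b < 0.25 * q75` or any rejected block;
#' borderline (orange) in between. An alternative percentile-rank rule
#' (red below the 25th percentile of `b`, green above the 75th) is
#' available via `rule_mode = "percentile_rank"`.
#'
#' @param field A `scale_field` from [fit_all_pixels()].
#' @param rule_mode `"fraction_of_q75"` (default) or `"percentile_rank"`.
#' @param green_frac,red_frac Thresholds as fractions of `q75`
#'   (fraction-of-q75 mode).
#' @return A `pixel_classification`: integer label matrix in block
#'   coordinates (0 = outside, 1 = insufficient, 2 = borderline,
#'   3 = sufficient) plus `q75_briskness` and the rule parameters.
#' @export
classify_field <- function(field, rule_mode = c("fraction_of_q75", "percentile_rank"),
                           green_frac = 0.75, red_frac = 0.25) {
  rule_mode <- match.arg(rule_mode)
  inside <- !is.na(field$accepted)
  labels <- matrix(0L, nrow(field$accepted), ncol(field$accepted))
  acc <- inside & !is.na(field$accepted) & field$accepted
  b <- field$briskness
  if (!any(acc)) {
    warning("no accepted blocks: whole region classified insufficient")
    labels[inside] <- 1L
    return(structure(
      list(labels = labels, q75_briskness = NA_real_, rule_mode = rule_mode,
           green_frac = green_frac, red_frac = red_frac, bin = field$bin,
           frame_dim = field$frame_dim, mask = field$mask),
      class = "pixel_classification"
    ))
  }
  bv <- b[acc]
  q75 <- stats::quantile(bv, 0.75, names = FALSE)  # linear interpolation
  labels[inside] <- 1L  # rejected blocks stay insufficient
  if (rule_mode == "fraction_of_q75") {
    hi <- green_frac * q75
    lo <- red_frac * q75
  } else {
    hi <- stats::quantile(bv, 0.75, names = FALSE)
    lo <- stats::quantile(bv, 0.25, names = FALSE)
  }
  labels[acc & b >= hi] <- 3L
  labels[acc & b < hi & b >= lo] <- 2L
  labels[acc & b < lo] <- 1L
  structure(
    list(labels = labels, q75_briskness = q75, rule_mode = rule_mode,
         green_frac = green_frac, red_frac = red_frac, bin = field$bin,
         frame_dim = field$frame_dim, mask = field$mask),
    class = "pixel_classification"
  )
}

#' @export
print.pixel_classification <- function(x, ...) {
  tb <- table(factor(x$labels[x$labels > 0L], levels = 1:3,
                     labels = c("insufficient", "borderline", "sufficient")))
  cat(sprintf("<pixel_classification> q75 briskness %.3f (%s rule)\n",
              x$q75_briskness, x$rule_mode))
  print(tb)
  invisible(x)
}

expand_blocks <- function(block_mat, frame_dim, bin) {
  big <- block_mat[rep(seq_len(nrow(block_mat)), each = bin),
                   rep(seq_len(ncol(block_mat)), each = bin), drop = FALSE]
  big[seq_len(frame_dim[1L]), seq_len(frame_dim[2L]), drop = FALSE]
}

ensure_rgb <- function(frame_dim, white_light_frame) {
  if (!is.null(white_light_frame)) return(white_light_frame[, , 1:3, drop = FALSE])
  array(0.3, dim = c(frame_dim, 3L))
}

#' Render a continuous-metric heatmap overlay
#'
#' Colour-codes a per-pixel (or per-block) metric grid with a perceptually
#' uniform scale (purple = lowest value, yellow = highest) and
#' alpha-blends it over the white-light frame. Missing cells leave the
#' frame untouched.
#'
#' @param metric_grid Numeric matrix of metric values (`NA` = missing),
#'   either at frame resolution or in block coordinates (then upscaled by
#'   `bin`).
#' @param white_light_frame RGB array `(h, w, 3)` in `[0, 1]`, or `NULL`
#'   for a neutral grey canvas.
#' @param legend_title Character label for the legend.
#' @param frame_dim Frame dimensions `(h, w)`; required when
#'   `white_light_frame` is `NULL`.
#' @param bin Upscaling factor when `metric_grid` is in block coordinates.
#' @param alpha Overlay opacity.
#' @return A `heatmap_overlay`: `rgb` array `(h, w, 3)` and a `legend`
#'   list (`title`, `min`, `max`, `colors`).
#' @export
render_metric_heatmap <- function(metric_grid, white_light_frame = NULL,
                                  legend_title = "metric", frame_dim = NULL,
                                  bin = 1L, alpha = 0.45) {
  if (is.null(frame_dim)) {
    frame_dim <- if (!is.null(white_light_frame)) dim(white_light_frame)[1:2]
                 else dim(metric_grid) * bin
  }
  base <- ensure_rgb(frame_dim, white_light_frame)
  grid <- if (bin > 1L) expand_blocks(metric_grid, frame_dim, bin) else metric_grid
  if (!all(dim(grid) == frame_dim)) stop_validation("metric grid not co-registered with frame")
  rng <- suppressWarnings(range(grid, na.rm = TRUE))
  if (!all(is.finite(rng))) {
    return(structure(list(rgb = base,
                          legend = list(title = legend_title, min = NA, max = NA,
                                        colors = character(0))),
                     class = "heatmap_overlay"))
  }
  ncol_map <- 256L
  pal <- viridisLite::viridis(ncol_map)  # purple (low) to yellow (high)
  span <- if (rng[2L] > rng[1L]) rng[2L] - rng[1L] else 1
  idx <- pmin(pmax(as.integer(round((grid - rng[1L]) / span * (ncol_map - 1L))) + 1L,
                   1L), ncol_map)
  colmat <- grDevices::col2rgb(pal[idx]) / 255
  out <- base
  present <- !is.na(grid)
  for (ch in 1:3) {
    layer <- out[, , ch]
    overlay <- matrix(colmat[ch, ], frame_dim[1L], frame_dim[2L])
    layer[present] <- (1 - alpha) * layer[present] + alpha * overlay[present]
    out[, , ch] <- layer
  }
  structure(
    list(rgb = out,
         legend = list(title = legend_title, min = rng[1L], max = rng[2L],
                       colors = pal)),
    class = "heatmap_overlay"
  )
}

#' Render the three-colour recommendation overlay
#'
#' Green = sufficient, orange = borderline, red = insufficient, blended
#' over the white-light frame inside the annotated region; pixels outside
#' the mask are left untouched.
#'
#' @param classification A `pixel_classification` from [classify_field()].
#' @param white_light_frame RGB array or `NULL`.
#' @param alpha Overlay opacity.
#' @return A `heatmap_overlay` with a categorical legend.
#' @export
render_recommendation_overlay <- function(classification,
                                          white_light_frame = NULL,
                                          alpha = 0.45) {
  frame_dim <- classification$frame_dim
  base <- ensure_rgb(frame_dim, white_light_frame)
  labels <- expand_blocks(classification$labels, frame_dim, classification$bin)
  labels[!classification$mask] <- 0L
  cols <- rbind(
    insufficient = c(0.85, 0.10, 0.10),
    borderline   = c(1.00, 0.60, 0.00),
    sufficient   = c(0.10, 0.70, 0.15)
  )
  out <- base
  for (lab in 1:3) {
    sel <- labels == lab
    if (!any(sel)) next
    for (ch in 1:3) {
      layer <- out[, , ch]
      layer[sel] <- (1 - alpha) * layer[sel] + alpha * cols[lab, ch]
      out[, , ch] <- layer
    }
  }
  structure(
    list(rgb = out,
         legend = list(title = "perfusion",
                       labels = c("sufficient", "borderline", "insufficient"),
                       colors = grDevices::rgb(cols[3:1, 1], cols[3:1, 2],
                                               cols[3:1, 3]))),
    class = "heatmap_overlay"
  )
}

#' Write a heatmap overlay as PNG
#'
#' @param overlay A `heatmap_overlay`.
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_overlay_png <- function(overlay, path) {
  png::writePNG(pmin(pmax(overlay$rgb, 0), 1), path)
  invisible(path)
}

#' Write a classification label grid as PNG + JSON sidecar
#'
#' The label image encodes 0 = outside, 1 = insufficient (red),
#' 2 = borderline (orange), 3 = sufficient (green) at frame resolution;
#' the JSON sidecar records `q75_briskness` and the rule parameters.
#'
#' @param classification A `pixel_classification`.
#' @param path Output PNG path (`.json` sidecar written next to it).
#' @return `path`, invisibly.
#' @export
write_classification <- function(classification, path) {
  labels <- expand_blocks(classification$labels, classification$frame_dim,
                          classification$bin)
  labels[!classification$mask] <- 0L
  png::writePNG(labels / 3, path)
  meta <- list(
    q75_briskness = classification$q75_briskness,
    rule_mode = classification$rule_mode,
    green_frac = classification$green_frac,
    red_frac = classification$red_frac,
    encoding = c(outside = 0, insufficient = 1, borderline = 2, sufficient = 3)
  )
  jsonlite::write_json(meta, paste0(sub("\\.png$", "", path), ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
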