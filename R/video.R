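#' Fluorescence video stack
#'
#' Container for a near-infrared (NIR) fluorescence recording: a stack of
#' co-registered grayscale frames plus acquisition metadata and an optional
#' white-light frame co-registered with frame 1.
#'
#' @param frames Numeric array `(height, width, n_frames)` or a list of
#'   equally sized matrices.
#' @param frame_rate Frames per second (> 0); surgical NIR stacks record at
#'   30 fps.
#' @param white_light_frame Optional RGB array `(height, width, 3)` with
#'   values in `[0, 1]`.
#' @return An object of class `video_stack` with fields `frames`,
#'   `frame_rate`, `duration_s` and `white_light_frame`.
#' @export
video_stack <- function(frames, frame_rate = 30, white_light_frame = NULL) {
  if (is.list(frames)) {
    dims <- unique(lapply(frames, dim))
    if (length(dims) != 1L) stop_validation("frames have mismatched dimensions")
    frames <- array(unlist(frames), dim = c(dims[[1]], length(frames)))
  }
  if (length(dim(frames)) == 2L) frames <- array(frames, dim = c(dim(frames), 1L))
  if (length(dim(frames)) != 3L) stop_validation("frames must be (height, width, n)")
  if (!is.numeric(frame_rate) || frame_rate <= 0) {
    stop_validation("frame_rate must be > 0")
  }
  if (!is.null(white_light_frame) &&
      !all(dim(white_light_frame)[1:2] == dim(frames)[1:2])) {
    stop_validation("white_light_frame dimensions differ from video frames")
  }
  structure(
    list(
      frames = frames,
      frame_rate = frame_rate,
      duration_s = dim(frames)[3L] / frame_rate,
      white_light_frame = white_light_frame
    ),
    class = "video_stack"
  )
}

#' @export
print.video_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf(
    "<video_stack> %d frames of %dx%d at %g fps (%.2f s)%s\n",
    d[3L], d[1L], d[2L], x$frame_rate, x$duration_s,
    if (is.null(x$white_light_frame)) "" else ", with white-light frame"
  ))
  invisible(x)
}

n_frames <- function(video) dim(video$frames)[3L]

frame_times <- function(video) (seq_len(n_frames(video)) - 1L) / video$frame_rate

#' Read a fluorescence video from disk
#'
#' Reads a multi-frame grayscale TIFF. Acquisition metadata comes from a
#' YAML sidecar (`<stem>.yaml` or `<path>.yaml`) with keys `frame_rate`
#' (default 30) and optionally `white_light` (a PNG filename relative to
#' the video). A white-light PNG named `<stem>_whitelight.png` is also
#' picked up automatically.
#'
#' @param path Path to a multi-frame grayscale TIFF file.
#' @return A [video_stack()].
#' @export
read_video <- function(path) {
  frames <- read_tiff_frames(path)
  dims <- unique(lapply(frames, dim))
  if (length(dims) != 1L) stop_validation("video frames have mismatched shapes")
  stem <- sub("\\.[^.]+$", "", path)
  sidecars <- c(paste0(stem, ".yaml"), paste0(path, ".yaml"))
  meta <- list()
  for (sc in sidecars) {
    if (file.exists(sc)) { meta <- yaml::read_yaml(sc); break }
  }
  frame_rate <- meta$frame_rate %||% 30
  wl <- NULL
  wl_path <- if (!is.null(meta$white_light)) {
    file.path(dirname(path), meta$white_light)
  } else {
    paste0(stem, "_whitelight.png")
  }
  if (file.exists(wl_path)) {
    img <- png::readPNG(wl_path)
    if (length(dim(img)) == 2L) img <- array(rep(img, 3L), dim = c(dim(img), 3L))
    wl <- img[, , 1:3, drop = FALSE]
  }
  video_stack(frames, frame_rate = frame_rate, white_light_frame = wl)
}

#' Write a fluorescence video to disk
#'
#' Writes the stack as an uncompressed multi-frame grayscale TIFF with a
#' YAML metadata sidecar, and the white-light frame (if any) as PNG.
#'
#' @param video A [video_stack()].
#' @param path Output TIFF path.
#' @param bits Bit depth, 8 or 16.
#' @return `path`, invisibly.
#' @export
write_video <- function(video, path, bits = 8L) {
  frames <- lapply(seq_len(n_frames(video)), function(k) video$frames[, , k])
  write_tiff_frames(frames, path, bits = as.integer(bits))
  stem <- sub("\\.[^.]+$", "", path)
  meta <- list(frame_rate = video$frame_rate)
  if (!is.null(video$white_light_frame)) {
    wl_name <- paste0(basename(stem), "_whitelight.png")
    png::writePNG(video$white_light_frame, file.path(dirname(path), wl_name))
    meta$white_light <- wl_name
  }
  yaml::write_yaml(meta, paste0(stem, ".yaml"))
  invisible(path)
}

# Integer translation aligning `frame` to `target` by FFT cross-correlation.
# Returns c(dy, dx): the shift to APPLY to `frame` so it matches `target`.
translation_offset <- function(target, frame) {
  if (stats::sd(frame) == 0 || stats::sd(target) == 0) return(c(0L, 0L))
  a <- target - mean(target)
  b <- frame - mean(frame)
  cc <- Re(stats::fft(stats::fft(a) * Conj(stats::fft(b)), inverse = TRUE))
  idx <- which.max(cc)
  h <- nrow(a); w <- ncol(a)
  dy <- (idx - 1L) %% h
  dx <- (idx - 1L) %/% h
  if (dy > h / 2) dy <- dy - h
  if (dx > w / 2) dx <- dx - w
  c(dy, dx)
}

shift_frame <- function(frame, dy, dx, fill = 0) {
  h <- nrow(frame); w <- ncol(frame)
  out <- matrix(fill, h, w)
  src_r <- seq_len(h) - dy
  src_c <- seq_len(w) - dx
  ok_r <- src_r >= 1L & src_r <= h
  ok_c <- src_c >= 1L & src_c <= w
  out[which(ok_r), which(ok_c)] <- frame[src_r[ok_r], src_c[ok_c], drop = FALSE]
  out
}

#' Stabilize a video by whole-frame translation
#'
#' Registers every frame to frame 1 with an integer translation found by
#' FFT cross-correlation (no rotation or deformation). The applied offsets
#' are retrievable via `attr(out, "offsets")`, an `n x 2` matrix of
#' `(dy, dx)` shifts. Frame 1 is never moved; featureless (constant)
#' frames get a zero offset and a warning.
#'
#' @param video A [video_stack()] with at least 2 frames.
#' @return A stabilized [video_stack()] with an `offsets` attribute.
#' @export
stabilize <- function(video) {
  nf <- n_frames(video)
  if (nf < 2L) stop_validation("stabilize needs at least 2 frames")
  target <- video$frames[, , 1L]
  offsets <- matrix(0L, nrow = nf, ncol = 2L,
                    dimnames = list(NULL, c("dy", "dx")))
  out <- video$frames
  degenerate <- FALSE
  for (k in 2:nf) {
    fr <- video$frames[, , k]
    if (stats::sd(fr) == 0 || stats::sd(target) == 0) {
      degenerate <- TRUE
      next
    }
    off <- translation_offset(target, fr)
    offsets[k, ] <- off
    if (any(off != 0L)) out[, , k] <- shift_frame(fr, off[1L], off[2L])
  }
  if (degenerate) warning("uniform-intensity frame(s): no registration applied")
  res <- video_stack(out, frame_rate = video$frame_rate,
                     white_light_frame = video$white_light_frame)
  attr(res, "offsets") <- offsets
  res
}

#' ROI annotation line along the bowel
#'
#' A polyline drawn on the bowel serosa from which sampling ROIs are
#' generated at fixed arc-length spacing, emulating serosal markings at
#' regular intervals along the antimesenteric border.
#'
#' @param vertices `n x 2` matrix of `(row, col)` pixel coordinates
#'   (0-based, origin top-left), ordered proximal to distal; `n >= 2`.
#' @param spacing_px Arc-length spacing between ROI centres, in pixels.
#' @param roi_radius_px Radius of the disc averaged for each ROI.
#' @return An object of class `roi_line`.
#' @export
roi_line <- function(vertices, spacing_px, roi_radius_px = 8) {
  vertices <- as.matrix(vertices)
  if (nrow(vertices) < 2L) stop_validation("roi_line needs at least 2 vertices")
  if (spacing_px <= 0) stop_validation("spacing_px must be > 0")
  structure(
    list(vertices = vertices, spacing_px = spacing_px,
         roi_radius_px = roi_radius_px),
    class = "roi_line"
  )
}

# Equally spaced points along a polyline, by arc length, starting at the
# first vertex. Always returns at least the start point.
polyline_points <- function(vertices, spacing) {
  seg <- diff(vertices)
  seg_len <- sqrt(rowSums(seg^2))
  cum <- c(0, cumsum(seg_len))
  total <- cum[length(cum)]
  s <- seq(0, total, by = spacing)
  t(vapply(s, function(si) {
    j <- max(which(cum <= si + 1e-9))
    if (j >= nrow(vertices)) return(vertices[nrow(vertices), ])
    frac <- (si - cum[j]) / seg_len[j]
    vertices[j, ] + frac * seg[j, ]
  }, numeric(2L)))
}

disc_indices <- function(centre, radius, h, w) {
  r0 <- centre[1L]; c0 <- centre[2L]  # 0-based
  rows <- max(0, floor(r0 - radius)):min(h - 1L, ceiling(r0 + radius))
  cols <- max(0, floor(c0 - radius)):min(w - 1L, ceiling(c0 + radius))
  g <- expand.grid(r = rows, c = cols)
  g <- g[(g$r - r0)^2 + (g$c - c0)^2 <= radius^2, , drop = FALSE]
  g$r + 1L + g$c * h  # linear indices into column-major matrix
}

#' Extract per-ROI perfusion curves from a video
#'
#' Places ROI centres at equal arc-length intervals along the annotated
#' line (starting at its proximal end) and averages pixel intensity within
#' a disc of `roi_radius_px` around each centre, frame by frame.
#'
#' @param video A [video_stack()].
#' @param line An [roi_line()] lying inside the frame bounds.
#' @param source Curve source label, `"reference"` or `"determinative"`.
#' @return List of [perfusion_curve()]s ordered proximal to distal
#'   (`position_index` 0, 1, ...). ROIs whose disc falls entirely outside
#'   the frame are dropped with a warning.
#' @export
extract_roi_curves <- function(video, line, source = "determinative") {
  d <- dim(video$frames)
  h <- d[1L]; w <- d[2L]; nf <- d[3L]
  centres <- polyline_points(line$vertices, line$spacing_px)
  times <- frame_times(video)
  flat <- matrix(video$frames, nrow = h * w, ncol = nf)
  curves <- list()
  pos <- 0L
  for (i in seq_len(nrow(centres))) {
    idx <- disc_indices(centres[i, ], line$roi_radius_px, h, w)
    if (!length(idx)) {
      warning(sprintf("ROI %d outside frame bounds; dropped", i - 1L))
      next
    }
    vals <- if (length(idx) == 1L) flat[idx, ] else colMeans(flat[idx, , drop = FALSE])
    curves[[length(curves) + 1L]] <- perfusion_curve(
      times, vals, roi_id = sprintf("roi_%02d", pos),
      position_index = pos, source = source
    )
    pos <- pos + 1L
  }
  curves
}

#' Extract per-pixel (binned) perfusion curves
#'
#' Groups masked pixels into `bin x bin` blocks and returns one curve per
#' block (mean over the block's masked pixels). Block coordinates are
#' row-major and 0-based with block `(0,0)` at the image top-left; the
#' curve names are `"row,col"` in block units.
#'
#' @param video A [video_stack()].
#' @param mask Logical matrix with the same dimensions as a frame.
#' @param bin Block edge length in pixels (`>= 1`); `bin = 1` quantifies
#'   literally every pixel.
#' @return Named list of [perfusion_curve()]s; each carries attributes
#'   `block_row` and `block_col`. Empty mask gives an empty list.
#' @export
extract_pixel_curves <- function(video, mask, bin = 4L) {
  d <- dim(video$frames)
  if (!all(dim(mask) == d[1:2])) stop_validation("mask shape differs from frames")
  if (bin < 1L) stop_validation("bin must be >= 1")
  if (!any(mask)) return(list())
  h <- d[1L]; w <- d[2L]; nf <- d[3L]
  flat <- matrix(video$frames, nrow = h * w, ncol = nf)
  times <- frame_times(video)
  which_in <- which(mask)  # column-major linear indices
  px_row <- (which_in - 1L) %% h          # 0-based
  px_col <- (which_in - 1L) %/% h
  br <- px_row %/% bin
  bc <- px_col %/% bin
  key <- br * (w %/% bin + 1L) + bc
  groups <- split(which_in, key)
  out <- list()
  for (g in groups) {
    r <- (g[1L] - 1L) %% h %/% bin
    cc <- (g[1L] - 1L) %/% h %/% bin
    vals <- if (length(g) == 1L) flat[g, ] else colMeans(flat[g, , drop = FALSE])
    nm <- sprintf("%d,%d", r, cc)
    curve <- perfusion_curve(times, vals, roi_id = sprintf("blk_%s", nm))
    attr(curve, "block_row") <- as.integer(r)
    attr(curve, "block_col") <- as.integer(cc)
    out[[nm]] <- curve
  }
  # deterministic row-major order
  ord <- order(vapply(out, function(x) attr(x, "block_row"), integer(1L)),
               vapply(out, function(x) attr(x, "block_col"), integer(1L)))
  out[ord]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
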