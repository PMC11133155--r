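test_that("TIFF video round-trips with metadata and honours frame counts", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "clip.tiff")

  # a 4-minute recording at 30 fps has 7200 frames; keep frames tiny
  set.seed(11)
  frames <- array(sample(0:255, 16 * 16 * 60, replace = TRUE) + 0,
                  dim = c(16, 16, 60))
  v <- video_stack(frames, frame_rate = 30)
  expect_equal(v$duration_s, 2)
  expect_equal(video_stack(frames[, , 1, drop = FALSE], 30)$duration_s, 1 / 30)

  write_video(v, path)
  back <- read_video(path)
  expect_equal(back$frame_rate, 30)
  expect_equal(back$duration_s, v$duration_s)
  expect_equal(back$frames, frames)

  # 16-bit depth preserved
  frames16 <- array(c(0, 300, 40000, 65535), dim = c(2, 2, 1))
  write_video(video_stack(frames16, 30), file.path(dir, "deep.tiff"), bits = 16)
  expect_equal(read_video(file.path(dir, "deep.tiff"))$frames, frames16)

  # sidecar frame rate respected; duration = n / rate
  yaml::write_yaml(list(frame_rate = 15), file.path(dir, "clip.yaml"))
  expect_equal(read_video(path)$duration_s, 4)
})

test_that("malformed TIFF input raises format errors", {
  dir <- withr::local_tempdir()
  bad <- file.path(dir, "bad.tiff")
  writeBin(as.raw(1:5), bad)
  expect_error(read_video(bad), class = "qicgfa_format_error")

  # truncate a valid file mid-data
  path <- file.path(dir, "clip.tiff")
  write_video(video_stack(array(7, dim = c(8, 8, 3)), 30), path)
  full <- readBin(path, "raw", file.info(path)$size)
  writeBin(full[1:40], bad)
  expect_error(read_video(bad), class = "qicgfa_format_error")

  expect_error(video_stack(list(matrix(0, 4, 4), matrix(0, 5, 4))),
               class = "qicgfa_validation_error")
})

test_that("stabilize recovers known integer shifts and is idempotent", {
  set.seed(21)
  base <- matrix(stats::runif(64 * 64), 64, 64)
  base <- base + outer(sin(seq_len(64) / 5), cos(seq_len(64) / 7))  # texture
  shifts <- cbind(dy = c(0, 1, 3, -2), dx = c(0, 0, -1, 4))
  frames <- vapply(seq_len(4), function(k) {
    qicgfa:::shift_frame(base, shifts[k, 1], shifts[k, 2])
  }, matrix(0, 64, 64))
  v <- video_stack(frames, 30)
  st <- stabilize(v)
  off <- attr(st, "offsets")
  for (k in 2:4) {
    expect_lte(max(abs(off[k, ] - (-shifts[k, ]))), 1)
  }
  # idempotence: a second pass finds (0,0) everywhere (within 1 px)
  st2 <- stabilize(st)
  expect_lte(max(abs(attr(st2, "offsets"))), 1)

  # identical frames: all offsets zero
  same <- video_stack(array(rep(base, 3), dim = c(64, 64, 3)), 30)
  expect_equal(unname(attr(stabilize(same), "offsets")),
               matrix(0L, 3, 2))

  # uniform frames: zero offsets and a warning
  flat <- video_stack(array(5, dim = c(8, 8, 2)), 30)
  expect_warning(stf <- stabilize(flat), "uniform")
  expect_equal(unname(attr(stf, "offsets")), matrix(0L, 2, 2))
})

test_that("ROI extraction follows the annotated line and scales linearly", {
  # constant field -> every curve constant at 50
  v <- video_stack(array(50, dim = c(32, 64, 5)), 30)
  line <- roi_line(rbind(c(16, 4), c(16, 60)), spacing_px = 10, roi_radius_px = 3)
  curves <- extract_roi_curves(v, line)
  expect_length(curves, 6)  # arc length 56 -> centres at 0,10,...,50
  for (cv in curves) expect_equal(cv$intensities, rep(50, 5))
  expect_equal(vapply(curves, function(x) x$position_index, integer(1)), 0:5)

  # line shorter than spacing -> exactly one ROI at the line start
  short <- roi_line(rbind(c(16, 10), c(16, 14)), spacing_px = 100, roi_radius_px = 2)
  expect_length(extract_roi_curves(v, short), 1)

  # intensity scaling commutes with extraction
  set.seed(3)
  noisy <- array(stats::runif(32 * 64 * 5, 0, 100), dim = c(32, 64, 5))
  v1 <- video_stack(noisy, 30)
  v3 <- video_stack(noisy * 3, 30)
  c1 <- extract_roi_curves(v1, line)
  c3 <- extract_roi_curves(v3, line)
  for (k in seq_along(c1)) {
    expect_equal(c3[[k]]$intensities, 3 * c1[[k]]$intensities, tolerance = 1e-12)
  }
})

test_that("ROI curves recover phantom kinetics within noise", {
  spec <- phantom_spec(n_rois = 5, ischemia_start_index = 3L, rate_hz = 5,
                       duration_s = 120, noise_sigma = 0.02, seed = 9)
  pv <- make_phantom_video(spec, width = 100, height = 32)
  line <- roi_line(rbind(c(16, 2), c(16, 97)), spacing_px = 23.75,
                   roi_radius_px = 4)
  curves <- extract_roi_curves(pv$video, line)
  expect_length(curves, 5)
  times <- seq(0, spec$duration_s, by = 1 / spec$rate_hz)
  for (i in seq_along(curves)) {
    true_curve <- 10 + 200 * gamma_variate(
      qicgfa:::phantom_position_params(spec, i - 1L), times)$intensities
    rmse <- sqrt(mean((curves[[i]]$intensities - true_curve)^2))
    expect_lt(rmse, 2 * 0.02 * 200)
  }
})

test_that("pixel-block extraction bins, masks and averages correctly", {
  set.seed(5)
  frames <- array(stats::runif(8 * 8 * 4, 0, 10), dim = c(8, 8, 4))
  v <- video_stack(frames, 30)
  mask <- matrix(TRUE, 8, 8)

  expect_length(extract_pixel_curves(v, mask, bin = 4), 4)
  expect_length(extract_pixel_curves(v, matrix(FALSE, 8, 8), bin = 2), 0)

  # bin = 1 returns the raw per-pixel series
  c1 <- extract_pixel_curves(v, mask, bin = 1)
  expect_length(c1, 64)
  expect_equal(c1[["2,3"]]$intensities, frames[3, 4, ])

  # masking excludes a region entirely
  half <- mask; half[, 5:8] <- FALSE
  ch <- extract_pixel_curves(v, half, bin = 2)
  cols <- vapply(ch, function(x) attr(x, "block_col"), integer(1))
  expect_true(all(cols <= 1))

  # weighted block means reconstruct the masked-region mean curve
  cb <- extract_pixel_curves(v, half, bin = 4)
  wts <- vapply(names(cb), function(nm) {
    rc <- as.integer(strsplit(nm, ",")[[1]])
    sum(half[rc[1] * 4 + 1:4, rc[2] * 4 + 1:4])
  }, numeric(1))
  recon <- Reduce(`+`, Map(function(cv, w) cv$intensities * w, cb, wts)) / sum(wts)
  direct <- apply(frames, 3, function(f) mean(f[half]))
  expect_equal(recon, direct, tolerance = 1e-6)
})

test_that("curve CSV round-trips and validates its schema", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "curves.csv")
  curves <- list(
    perfusion_curve(c(0, 0.5, 1), c(0.1, 0.7, 0.3), "a", 0L, "reference"),
    perfusion_curve(c(0, 0.5, 1), c(0.2, 0.9, 0.4), "b", 1L),
    perfusion_curve(c(0, 1, 2), c(1.23456789, 2.3456789, 3), "c", 2L)
  )
  write_curves(curves, path)
  back <- read_curves(path)
  expect_length(back, 3)
  for (k in 1:3) {
    expect_equal(back[[k]]$intensities, curves[[k]]$intensities, tolerance = 1e-9)
    expect_equal(back[[k]]$times_s, curves[[k]]$times_s, tolerance = 1e-9)
    expect_equal(back[[k]]$source, curves[[k]]$source)
  }

  write_curves(list(), path)
  expect_equal(readLines(path), "time_s,roi_id,position_index,source,intensity")
  expect_length(read_curves(path), 0)

  writeLines(c("time_s,roi_id,intensity", "0,a,1"), path)
  expect_error(read_curves(path), "position_index",
               class = "qicgfa_format_error")

  # unsorted rows are re-sorted with a warning
  writeLines(c("time_s,roi_id,position_index,source,intensity",
               "1,a,0,determinative,5", "0,a,0,determinative,3"), path)
  expect_warning(sorted <- read_curves(path), "re-sorting")
  expect_equal(sorted[[1]]$times_s, c(0, 1))
})
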