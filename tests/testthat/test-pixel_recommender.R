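# A compact two-zone phantom video shared across the pixel-path tests:
# left half normal kinetics, right half time-dilated x2.
two_zone <- function(seed = 3, width = 64, height = 32, noise = 0.02) {
  spec <- phantom_spec(n_rois = 2, ischemia_start_index = 1L,
                       dilation_gradient = 2, noise_sigma = noise,
                       rate_hz = 5, duration_s = 120, seed = seed)
  pv <- make_phantom_video(spec, width = width, height = height)
  ref <- preprocess_curve(
    make_phantom(spec)$reference,
    preprocess_config()
  )
  list(pv = pv, profile = reference_profile(ref), spec = spec)
}

test_that("fit_all_pixels grids block fits with spatial structure", {
  tz <- two_zone()
  field <- fit_all_pixels(tz$profile, tz$pv$video, tz$pv$mask, bin = 8,
                          match_cfg = fast_match_cfg())
  fitted <- !is.na(field$scale_s)
  expect_equal(sum(fitted), 2 * 8)  # 16 band rows x 64 cols in 8x8 blocks

  scales <- field$scale_s
  left <- scales[, 1:4][!is.na(scales[, 1:4])]
  right <- scales[, 5:8][!is.na(scales[, 5:8])]
  expect_lt(abs(stats::median(left) - 1), 0.1)
  expect_lt(abs(stats::median(right) - 2), 0.2)

  # empty mask -> empty map
  empty <- fit_all_pixels(tz$profile, tz$pv$video,
                          matrix(FALSE, 32, 64), bin = 8)
  expect_equal(sum(!is.na(empty$accepted)), 0)
})

test_that("spatially uniform kinetics give uniform accepted scales", {
  spec <- phantom_spec(n_rois = 2, ischemia_start_index = 2L,
                       noise_sigma = 0.01, rate_hz = 5, duration_s = 120,
                       seed = 11)
  pv <- make_phantom_video(spec, width = 32, height = 32)
  ref <- preprocess_curve(make_phantom(spec)$reference)
  field <- fit_all_pixels(reference_profile(ref), pv$video, pv$mask, bin = 8,
                          match_cfg = fast_match_cfg())
  sc <- field$scale_s[!is.na(field$scale_s)]
  expect_gt(length(sc), 0)
  expect_lt(max(sc) / min(sc), 1.05)
})

test_that("classify_field applies the histogram rule arithmetic", {
  # hand-checkable: briskness {1.0 x 40, 0.5 x 40, 0.1 x 20}; q75 = 1.0
  b <- c(rep(1, 40), rep(0.5, 40), rep(0.1, 20))
  field <- structure(
    list(scale_s = matrix(1 / b, 10, 10), agreement = matrix(0.95, 10, 10),
         briskness = matrix(b, 10, 10), accepted = matrix(TRUE, 10, 10),
         bin = 1L, mask = matrix(TRUE, 10, 10), frame_dim = c(10L, 10L)),
    class = "scale_field"
  )
  cls <- classify_field(field)
  expect_equal(cls$q75_briskness, 1.0)
  expect_equal(as.integer(table(cls$labels)[c("1", "2", "3")]),
               c(20L, 40L, 40L))
  expect_equal(cls$labels[matrix(b, 10, 10) == 1], rep(3L, 40))
  expect_equal(cls$labels[matrix(b, 10, 10) == 0.5], rep(2L, 40))
  expect_equal(cls$labels[matrix(b, 10, 10) == 0.1], rep(1L, 20))

  # identical briskness everywhere -> everything sufficient
  same <- field
  same$briskness[] <- 0.8; same$scale_s[] <- 1.25
  expect_true(all(classify_field(same)$labels == 3L))

  # all rejected -> all insufficient, with a warning
  rej <- field
  rej$accepted[] <- FALSE
  expect_warning(crej <- classify_field(rej), "no accepted")
  expect_true(all(crej$labels == 1L))

  # rejected blocks never influence q75
  mixed <- field
  mixed$accepted[matrix(b, 10, 10) == 0.1] <- FALSE
  cm <- classify_field(mixed)
  expect_equal(cm$q75_briskness,
               stats::quantile(b[b > 0.1], 0.75, names = FALSE))

  # labels partition the masked area; deterministic
  expect_true(all(cls$labels[field$mask] %in% 1:3))
  expect_identical(classify_field(field), cls)
})

test_that("the two-zone phantom classifies with a sharp boundary", {
  tz <- two_zone()
  field <- fit_all_pixels(tz$profile, tz$pv$video, tz$pv$mask, bin = 8,
                          match_cfg = fast_match_cfg())
  cls <- classify_field(field)
  inside <- cls$labels[!is.na(field$accepted)]
  expect_true(all(inside %in% 1:3))

  lab <- cls$labels
  for (r in which(rowSums(!is.na(field$accepted)) > 0)) {
    expect_true(all(lab[r, 1:4] == 3L))        # normal zone: sufficient
    expect_true(all(lab[r, 5:8] %in% 1:2))     # dilated zone: not sufficient
  }
})

test_that("overlay rendering respects geometry and colour coding", {
  tz <- two_zone()
  wl <- tz$pv$video$white_light_frame

  # constant metric grid on a uniform canvas -> one overlay colour
  const_grid <- matrix(5, 32, 64)
  ov <- render_metric_heatmap(const_grid, NULL, legend_title = "const",
                              frame_dim = c(32L, 64L))
  expect_equal(dim(ov$rgb), c(32, 64, 3))
  expect_equal(nrow(unique(round(matrix(ov$rgb, ncol = 3), 9))), 1)

  # all-missing grid -> frame unchanged, empty legend
  ovna <- render_metric_heatmap(matrix(NA_real_, 32, 64), wl)
  expect_equal(ovna$rgb, wl)
  expect_length(ovna$legend$colors, 0)

  # Tmax heatmap: the ischemic (dilated) half renders at the slow end
  curves <- extract_pixel_curves(tz$pv$video, tz$pv$mask, bin = 8)
  tgrid <- matrix(NA_real_, 4, 8)
  for (cv in curves) {
    m <- compute_metrics(preprocess_curve(cv))
    tgrid[attr(cv, "block_row") + 1, attr(cv, "block_col") + 1] <- m$tmax_s
  }
  expect_gt(min(tgrid[, 5:8], na.rm = TRUE), max(tgrid[, 1:4], na.rm = TRUE))
  ovt <- render_metric_heatmap(tgrid, wl, frame_dim = c(32L, 64L), bin = 8)
  expect_equal(dim(ovt$rgb), c(32, 64, 3))

  # recommendation overlay: green left, untouched outside the mask
  field <- fit_all_pixels(tz$profile, tz$pv$video, tz$pv$mask, bin = 8,
                          match_cfg = fast_match_cfg())
  cls <- classify_field(field)
  rec_ov <- render_recommendation_overlay(cls, wl)
  expect_equal(dim(rec_ov$rgb), dim(wl))
  outside <- !tz$pv$mask
  for (ch in 1:3) {
    expect_equal(rec_ov$rgb[, , ch][outside], wl[, , ch][outside])
  }
  # green channel dominates in the sufficient zone
  rows <- tz$pv$truth$band_rows
  green <- rec_ov$rgb[rows, 1:16, 2]
  red <- rec_ov$rgb[rows, 1:16, 1]
  expect_true(mean(green) > mean(red))

  # PNG round-trip preserves dimensions
  dir <- withr::local_tempdir()
  write_overlay_png(rec_ov, file.path(dir, "ov.png"))
  img <- png::readPNG(file.path(dir, "ov.png"))
  expect_equal(dim(img)[1:2], dim(wl)[1:2])
  write_classification(cls, file.path(dir, "cls.png"))
  meta <- jsonlite::read_json(file.path(dir, "cls.json"))
  expect_equal(meta$q75_briskness, cls$q75_briskness, tolerance = 1e-9)
})
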