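test_that("agreement behaves as the L1-area definition requires", {
  f <- test_bump()
  expect_equal(agreement(f, f, 1, 0), 1)

  zero <- perfusion_curve(f$times_s, rep(0, length(f$times_s)))
  expect_error(agreement(f, zero, 1, 0), class = "qicgfa_unquantifiable")

  # a delayed copy is matched better by the true delay than by none
  tt <- seq(0, 120, by = 0.1)
  tri <- function(peak) pmax(1 - abs(tt - peak) / 30, 0)
  ref <- perfusion_curve(tt, tri(60))
  det <- perfusion_curve(tt, tri(70))
  expect_gt(agreement(ref, det, 1, 10), agreement(ref, det, 1, 0))

  # matches the independent oracle across a few (s, tau)
  for (s in c(0.7, 1, 1.8)) {
    for (tau in c(-5, 0, 12)) {
      expect_equal(agreement(ref, det, s, tau),
                   oracle_agreement(ref$times_s, ref$intensities,
                                    det$times_s, det$intensities, s, tau),
                   tolerance = 1e-12)
    }
  }
})

test_that("fit_reference self-match returns the identity fit", {
  f <- test_bump()
  fit <- fit_reference(f, f, fast_match_cfg())
  expect_gte(fit$agreement, 0.999)
  expect_lt(abs(log(fit$scale_s)), log(4 / 0.25) / 60)  # within one grid step
  expect_lt(abs(fit$shift_tau_s), 0.5)
  expect_true(fit$accepted)
  expect_equal(fit$briskness * fit$scale_s, 1)
})

test_that("fit_reference recovers known time dilations against the dense oracle", {
  # decaying washout: a residual plateau biases s < 1 fits through the
  # zero-outside-domain convention (documented limitation)
  ref <- test_bump(washout = 35, plateau = 0)
  for (s0 in c(0.75, 1.5)) {
    det <- test_bump(washout = 35, plateau = 0, dilate = s0)
    fit <- fit_reference(ref, det, fast_match_cfg())
    oracle <- oracle_dense_fit(ref$times_s, ref$intensities,
                               det$times_s, det$intensities,
                               s_values = seq(s0 * 0.9, s0 * 1.1, by = 0.002),
                               tau_values = c(-1, -0.5, 0, 0.5, 1))
    expect_equal(fit$scale_s, unname(oracle["s"]), tolerance = 0.01)
    expect_lt(abs(fit$scale_s - s0), 0.01 * s0)
    expect_gte(fit$agreement, unname(oracle["a"]) - 1e-3)
  }
})

test_that("noise-dominated determinative curves are rejected", {
  ref <- test_bump()
  set.seed(31)
  flat <- perfusion_curve(ref$times_s,
                          pmax(stats::rnorm(length(ref$times_s), 0.05, 0.02), 0))
  fit <- fit_reference(ref, flat, fast_match_cfg())
  expect_lt(fit$agreement, 0.85)
  expect_false(fit$accepted)
})

test_that("acceptance threshold uses >= at the 85% boundary", {
  cfg <- match_config()
  mk <- function(a) structure(list(agreement = a), class = "curve_fit")
  expect_true(accept_fit(mk(0.86), cfg))
  expect_true(accept_fit(mk(0.85), cfg))
  expect_false(accept_fit(mk(0.10), cfg))
})

test_that("scale interpretation maps narrowing to brisker perfusion", {
  mk <- function(s) structure(list(scale_s = s), class = "curve_fit")
  expect_equal(interpret_scale(mk(0.8)), "brisker")
  expect_equal(interpret_scale(mk(1.0)), "equal")
  expect_equal(interpret_scale(mk(1.015)), "equal")
  expect_equal(interpret_scale(mk(2.0)), "slower")
})

test_that("fits are invariant to amplitude and degrade monotonically with noise", {
  ref <- test_bump()
  det_raw <- test_bump(dilate = 1.3)

  # multiplying by c in (0,1) before normalization changes nothing
  cheap <- normalize_curve(perfusion_curve(det_raw$times_s,
                                           0.4 * det_raw$intensities))
  f1 <- fit_reference(ref, det_raw, fast_match_cfg())
  f2 <- fit_reference(ref, cheap, fast_match_cfg())
  expect_equal(f1$scale_s, f2$scale_s, tolerance = 1e-9)
  expect_equal(f1$agreement, f2$agreement, tolerance = 1e-9)

  # increasing noise strictly decreases median agreement (seeded replicates)
  cfg <- preprocess_config()
  med_agree <- vapply(c(0.01, 0.08, 0.3), function(sigma) {
    stats::median(vapply(1:15, function(seed) {
      set.seed(seed)
      noisy <- perfusion_curve(
        det_raw$times_s,
        pmax(det_raw$intensities + stats::rnorm(length(det_raw$times_s),
                                                sd = sigma), 0))
      fit_reference(ref, preprocess_curve(noisy, cfg), fast_match_cfg())$agreement
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(med_agree) < 0))
})

test_that("fit_reference is deterministic and serializes faithfully", {
  ref <- test_bump()
  det <- test_bump(dilate = 1.4)
  f1 <- fit_reference(ref, det, fast_match_cfg())
  f2 <- fit_reference(ref, det, fast_match_cfg())
  expect_identical(f1, f2)

  dir <- withr::local_tempdir()
  write_fit_results(list(f1), file.path(dir, "fits.json"))
  back <- jsonlite::read_json(file.path(dir, "fits.json"))
  expect_equal(back[[1]]$scale_s, f1$scale_s, tolerance = 1e-12)
  write_fit_results(list(f1), file.path(dir, "fits.csv"), format = "csv")
  tab <- utils::read.csv(file.path(dir, "fits.csv"))
  expect_equal(tab$agreement, f1$agreement, tolerance = 1e-6)
})

test_that("the normalized-cross-correlation objective is available", {
  ref <- test_bump()
  det <- test_bump(dilate = 1.5)
  cfg <- match_config(s_steps = 31L, tau_min_s = -10, tau_max_s = 10,
                      tau_step_s = 2, objective = "ncc")
  fit <- fit_reference(ref, det, cfg)
  expect_lt(abs(fit$scale_s - 1.5), 0.15)
  expect_gt(fit$agreement, 0.99)
})
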