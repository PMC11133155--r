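#' @useDynLib qicgfa, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' End-to-end ROI recommendation pipeline
#'
#' Preprocesses the reference and determinative curves, fits every
#' determinative curve against the patient's reference profile, and turns
#' the fits into a transection recommendation. Determinative curves that
#' cannot be quantified (constant signal) become rejected fits with zero
#' agreement instead of aborting the run.
#'
#' @param reference Raw reference [perfusion_curve()].
#' @param determinative List of raw determinative curves, ordered proximal
#'   to distal.
#' @param preprocess_cfg A [preprocess_config()].
#' @param match_cfg A [match_config()].
#' @param rel_threshold Sufficiency threshold on relative briskness.
#' @param segment_type Bowel type of all curves.
#' @return List with `profile` (the [reference_profile()]), `curves`
#'   (preprocessed determinative curves), `fits` (list of `curve_fit`)
#'   and `recommendation`.
#' @export
recommend_transection <- function(reference, determinative,
                                  preprocess_cfg = preprocess_config(),
                                  match_cfg = match_config(),
                                  rel_threshold = 0.95,
                                  segment_type = "large_bowel") {
  profile <- reference_profile(preprocess_curve(reference, preprocess_cfg),
                               segment_type = segment_type)
  pre <- vector("list", length(determinative))
  fits <- vector("list", length(determinative))
  for (i in seq_along(determinative)) {
    det <- determinative[[i]]
    fit <- tryCatch({
      pre[[i]] <- preprocess_curve(det, preprocess_cfg)
      fit_reference(profile, pre[[i]], match_cfg)
    }, qicgfa_unquantifiable = function(e) NULL)
    if (is.null(fit)) {
      fit <- structure(
        list(roi_id = det$roi_id, position_index = det$position_index,
             scale_s = NA_real_, shift_tau_s = NA_real_, agreement = 0,
             diff_curve_area = NA_real_, briskness = NA_real_,
             accepted = FALSE),
        class = "curve_fit"
      )
    }
    fits[[i]] <- fit
  }
  rec <- classify_sufficiency(roi_series(fits), rel_threshold = rel_threshold)
  list(profile = profile, curves = pre, fits = fits, recommendation = rec)
}
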