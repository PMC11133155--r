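#' Ordered series of per-ROI curve fits
#'
#' @param fits List of `curve_fit` objects ordered proximal to distal
#'   (strictly increasing `position_index`).
#' @param spacing_cm Physical spacing between ROI centres; serosal
#'   markings are placed at 2 cm intervals along the antimesenteric
#'   border.
#' @return An `roi_series` object.
#' @export
roi_series <- function(fits, spacing_cm = 2) {
  if (!length(fits)) stop_validation("empty ROI series")
  pos <- vapply(fits, function(f) f$position_index, integer(1L))
  if (any(diff(pos) <= 0)) stop_validation("position indices must be strictly increasing")
  if (spacing_cm <= 0) stop_validation("spacing_cm must be > 0")
  structure(list(fits = fits, spacing_cm = spacing_cm), class = "roi_series")
}

#' Classify perfusion sufficiency and recommend a transection site
#'
#' Among accepted fits, perfusion sufficiency is assumed at the briskest
#' determinative curves or those at least `rel_threshold` (default 95%) as
#' fast as the briskest, where briskness is `1/scale_s`. The transection
#' recommendation is the most distal sufficiently perfused ROI. If no fit
#' is accepted the result is an explicit no-recommendation — a valid
#' clinical outcome, not an error.
#'
#' @param series An [roi_series()].
#' @param rel_threshold Fraction of the maximum briskness still deemed
#'   sufficient.
#' @return A `recommendation` object with fields `status`
#'   (`"recommended"` or `"no_recommendation"`), `sufficient_set`
#'   (position indices), `recommended_index`, `max_briskness` and the
#'   per-ROI fit table.
#' @export
classify_sufficiency <- function(series, rel_threshold = 0.95) {
  fits <- series$fits
  acc <- Filter(function(f) isTRUE(f$accepted), fits)
  per_roi <- fits_table(fits)
  if (!length(acc)) {
    return(structure(
      list(status = "no_recommendation", sufficient_set = integer(0),
           recommended_index = NA_integer_, max_briskness = NA_real_,
           rel_threshold = rel_threshold, per_roi = per_roi),
      class = "recommendation"
    ))
  }
  brisk <- vapply(acc, function(f) f$briskness, numeric(1L))
  pos <- vapply(acc, function(f) f$position_index, integer(1L))
  max_b <- max(brisk)
  suff <- pos[brisk >= rel_threshold * max_b]
  structure(
    list(status = "recommended", sufficient_set = sort(suff),
         recommended_index = max(suff), max_briskness = max_b,
         rel_threshold = rel_threshold, per_roi = per_roi),
    class = "recommendation"
  )
}

#' @export
print.recommendation <- function(x, ...) {
  if (x$status == "no_recommendation") {
    cat("<recommendation> NO suitable transection site (all fits rejected)\n")
  } else {
    cat(sprintf(
      "<recommendation> transect at ROI %d (sufficient set: %s; max briskness %.3f)\n",
      x$recommended_index, paste(x$sufficient_set, collapse = ", "),
      x$max_briskness
    ))
  }
  invisible(x)
}

#' Jaccard similarity index between two zones
#'
#' `|A intersect B| / |A union B|`, with the convention that two empty
#' zones agree perfectly (index 1).
#'
#' @param zone_a,zone_b Integer sets of position indices.
#' @return Fraction in `[0, 1]`.
#' @export
jaccard_index <- function(zone_a, zone_b) {
  zone_a <- unique(zone_a); zone_b <- unique(zone_b)
  u <- length(union(zone_a, zone_b))
  if (u == 0L) return(1)
  length(intersect(zone_a, zone_b)) / u
}

#' Build the expert's transection zone
#'
#' The expert marks a single transection ROI. For zone comparison the
#' expert zone is either that point alone (`"point"`) or the marked ROI
#' plus everything proximal to it (`"proximal_run"`, the default: the
#' surgeon transecting at k implicitly certifies all more proximal bowel).
#'
#' @param expert_position Position index the expert selected.
#' @param mode `"proximal_run"` or `"point"`.
#' @return Integer vector of position indices.
#' @export
expert_zone <- function(expert_position, mode = c("proximal_run", "point")) {
  mode <- match.arg(mode)
  if (mode == "point") as.integer(expert_position) else 0:as.integer(expert_position)
}

#' Compare a recommendation to the expert-selected site
#'
#' @param rec A `recommendation` from [classify_sufficiency()].
#' @param expert_position Position index of the expert's transection site.
#' @return List with `contained` (the expert site lies in the sufficient
#'   zone) and `distal_alternative` (the tool recommends a safe site
#'   distal to the expert's).
#' @export
evaluate_against_expert <- function(rec, expert_position) {
  list(
    contained = expert_position %in% rec$sufficient_set,
    distal_alternative = rec$status == "recommended" &&
      rec$recommended_index > expert_position
  )
}

#' Write a recommendation report as JSON
#'
#' A no-recommendation outcome is serialized like any other (it is a valid
#' result, not a failure).
#'
#' @param rec A `recommendation`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_recommendation <- function(rec, path) {
  payload <- list(
    status = rec$status,
    recommended_index = if (is.na(rec$recommended_index)) NULL else rec$recommended_index,
    sufficient_set = rec$sufficient_set,
    max_briskness = if (is.na(rec$max_briskness)) NULL else rec$max_briskness,
    rel_threshold = rec$rel_threshold,
    per_roi = rec$per_roi
  )
  jsonlite::write_json(payload, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
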