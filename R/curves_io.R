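#' Write perfusion curves to CSV
#'
#' Serializes a list of curves into the package's CSV dialect with columns
#' `time_s, roi_id, position_index, source, intensity`. Values round-trip
#' losslessly well beyond 6 significant digits.
#'
#' @param curves List of [perfusion_curve()]s (possibly empty).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_curves <- function(curves, path) {
  cols <- c("time_s", "roi_id", "position_index", "source", "intensity")
  if (!length(curves)) {
    writeLines(paste(cols, collapse = ","), path)
    return(invisible(path))
  }
  df <- do.call(rbind, lapply(curves, as.data.frame))
  df$time_s <- formatC(df$time_s, digits = 15, format = "g")
  df$intensity <- formatC(df$intensity, digits = 15, format = "g")
  utils::write.csv(df[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read perfusion curves from CSV
#'
#' Inverse of [write_curves()]. Rows are grouped by `roi_id`; if a group's
#' times are out of order they are re-sorted with a warning.
#'
#' @param path CSV path with columns `time_s, roi_id, position_index,
#'   source, intensity`.
#' @return List of [perfusion_curve()]s ordered by `position_index`.
#' @export
read_curves <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("time_s", "roi_id", "position_index", "source", "intensity")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop_format("curve CSV missing column(s): %s", paste(missing, collapse = ", "))
  }
  if (!nrow(df)) return(list())
  out <- lapply(split(df, df$roi_id), function(g) {
    if (is.unsorted(g$time_s, strictly = TRUE)) {
      warning(sprintf("times for roi '%s' not sorted; re-sorting", g$roi_id[1L]))
      g <- g[order(g$time_s), ]
    }
    perfusion_curve(g$time_s, g$intensity, roi_id = g$roi_id[1L],
                    position_index = g$position_index[1L], source = g$source[1L])
  })
  names(out) <- NULL
  out[order(vapply(out, function(x) x$position_index, integer(1L)))]
}
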