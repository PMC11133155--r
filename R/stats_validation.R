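#' Spearman rank correlation matrix with interpretation bands
#'
#' Pairwise-complete Spearman correlations over the numeric columns of a
#' per-ROI variable table, with two-tailed p-values and the customary
#' verbal interpretation of `|rho|`: negligible `[0, 0.1)`, weak
#' `[0.1, 0.4)`, moderate `[0.4, 0.7)`, strong `[0.7, 0.9)`, very strong
#' `[0.9, 1]` (half-open intervals close the 0.39-0.4 and 0.69-0.7 gaps of
#' the verbal rule). Ties get average ranks. Exact p-values are used for
#' `n <= 10` without ties (full null distribution of the rank statistic);
#' otherwise the t approximation. Constant columns yield `NA` and are
#' flagged.
#'
#' @param table `data.frame`; non-numeric columns are dropped.
#' @param p_threshold Significance level for the `significant` flag.
#' @return A `correlation_report` with matrices `rho`, `p`, `n`,
#'   `significant`, label matrix `interpretation`, and `flagged`
#'   (constant-variable names).
#' @export
spearman_matrix <- function(table, p_threshold = 0.05) {
  num <- table[vapply(table, is.numeric, logical(1L))]
  vars <- names(num)
  k <- length(vars)
  if (k < 2L) stop_validation("need at least 2 numeric variables")
  rho <- p <- matrix(NA_real_, k, k, dimnames = list(vars, vars))
  n <- matrix(0L, k, k, dimnames = list(vars, vars))
  flagged <- character(0)
  for (i in seq_len(k)) {
    for (j in i:k) {
      x <- num[[i]]; y <- num[[j]]
      ok <- stats::complete.cases(x, y)
      nn <- sum(ok)
      n[i, j] <- n[j, i] <- nn
      if (i == j) { rho[i, j] <- 1; p[i, j] <- 0; next }
      if (nn < 3L) next
      xs <- x[ok]; ys <- y[ok]
      if (length(unique(xs)) < 2L || length(unique(ys)) < 2L) {
        flagged <- unique(c(flagged, vars[i][length(unique(xs)) < 2L],
                            vars[j][length(unique(ys)) < 2L]))
        next
      }
      r <- stats::cor(rank(xs), rank(ys), method = "pearson")
      has_ties <- anyDuplicated(xs) || anyDuplicated(ys)
      pv <- if (nn <= 10L && !has_ties) {
        stats::cor.test(xs, ys, method = "spearman", exact = TRUE)$p.value
      } else {
        tstat <- r * sqrt((nn - 2) / max(1 - r^2, .Machine$double.eps))
        2 * stats::pt(-abs(tstat), df = nn - 2)
      }
      rho[i, j] <- rho[j, i] <- r
      p[i, j] <- p[j, i] <- min(pv, 1)
    }
  }
  structure(
    list(rho = rho, p = p, n = n, significant = p < p_threshold,
         interpretation = apply(rho, c(1, 2), interpret_rho),
         p_threshold = p_threshold, flagged = flagged),
    class = "correlation_report"
  )
}

interpret_rho <- function(rho) {
  if (is.na(rho)) return(NA_character_)
  a <- abs(rho)
  if (a < 0.1) "negligible"
  else if (a < 0.4) "weak"
  else if (a < 0.7) "moderate"
  else if (a < 0.9) "strong"
  else "very strong"
}

#' @export
print.correlation_report <- function(x, ...) {
  cat(sprintf("<correlation_report> %d variables\n", nrow(x$rho)))
  out <- round(x$rho, 2)
  star <- ifelse(!is.na(x$significant) & x$significant & row(x$rho) != col(x$rho),
                 "*", "")
  disp <- matrix(paste0(format(out), star), nrow(out),
                 dimnames = dimnames(out))
  print(disp, quote = FALSE)
  if (length(x$flagged)) {
    cat("constant (undefined) variables:", paste(x$flagged, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write a correlation report
#'
#' CSV layout mirrors a square published correlation table: variables as
#' rows and columns, a trailing `*` marking `p < 0.05`; JSON carries the
#' full numeric matrices.
#'
#' @param report A `correlation_report`.
#' @param path Output path.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_correlation_report <- function(report, path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(
      list(rho = report$rho, p = report$p, n = report$n,
           interpretation = report$interpretation, flagged = report$flagged),
      path, matrix = "rowmajor", digits = NA, auto_unbox = TRUE
    )
  } else {
    star <- ifelse(!is.na(report$significant) & report$significant &
                     row(report$rho) != col(report$rho), "*", "")
    cells <- matrix(paste0(formatC(report$rho, digits = 2, format = "f"), star),
                    nrow(report$rho), dimnames = dimnames(report$rho))
    cells[is.na(report$rho)] <- "NA"
    df <- data.frame(variable = rownames(cells), cells, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}

# Canonical variable order mirroring the published correlation layout:
# metabolic, fit outputs, conventional descriptors.
validation_variable_order <- function() {
  c("lactate_mgdl", "lactate_ratio",
    "scale_s", "diff_curve_area", "agreement", "accepted",
    "upslope", "t_half_s", "fmax", "tmax_s", "downslope",
    "t50_s", "f50", "d50", "t100_s", "f100", "d100", "tr",
    "centre_of_mass_s")
}

#' Cross-correlate fit outputs, conventional descriptors and lactate
#'
#' Assembles the full per-ROI variable table (fit outputs, conventional
#' descriptors, simulated lactate) in the canonical order and computes the
#' Spearman matrix, summarizing the pairs reaching at least moderate
#' correlation (`|rho| >= 0.4`).
#'
#' @param metrics A [metrics_table()] that includes fit columns.
#' @param lactate Output of [make_lactate()] for the same positions.
#' @return List with `report` (a `correlation_report`), `table` (the
#'   merged variable table) and `summary` (data.frame of at-least-moderate
#'   pairs).
#' @export
validation_run <- function(metrics, lactate) {
  tab <- merge(lactate, metrics, by = "position_index", sort = TRUE)
  tab$accepted <- as.numeric(tab$accepted)
  keep <- intersect(validation_variable_order(), names(tab))
  report <- spearman_matrix(tab[keep])
  rr <- report$rho
  ut <- upper.tri(rr)
  idx <- which(ut & !is.na(rr) & abs(rr) >= 0.4, arr.ind = TRUE)
  summary <- data.frame(
    var_a = rownames(rr)[idx[, 1L]],
    var_b = colnames(rr)[idx[, 2L]],
    rho = rr[idx],
    p = report$p[idx],
    interpretation = report$interpretation[idx],
    stringsAsFactors = FALSE
  )
  summary <- summary[order(-abs(summary$rho)), , drop = FALSE]
  list(report = report, table = tab[c("position_index", keep)], summary = summary)
}
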