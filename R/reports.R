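#' Summarize evaluation runs grouped by experimental condition
#'
#' Computes, per condition, the arithmetic mean of macro precision/recall/F
#' and the population standard deviation of macro-F over the contributing
#' runs (each line an average over fold x repeat experiments). When a
#' `baseline` condition is named, a Welch two-sample t-test compares every
#' other condition's macro-F against it and the p-value is reported (not
#' asserted).
#'
#' @param runs A data frame with columns `condition`, `macro_precision`,
#'   `macro_recall`, `macro_f` -- one row per experiment (e.g. rows of
#'   `tidy(cross_validate(...))` tagged with a condition).
#' @param baseline Optional condition name to test the others against.
#' @return An object of class `experiment_summary`: a tibble with one row per
#'   condition (`mean_p`, `mean_r`, `mean_f`, `sd_f`, `n`, and `p_value`
#'   against the baseline when requested).
#' @export
summarize_experiments <- function(runs, baseline = NULL) {
  runs <- tibble::as_tibble(runs)
  stopifnot(all(c("condition", "macro_f") %in% names(runs)))
  if (!nrow(runs)) stop("no runs to summarize")
  counts <- table(runs$condition)
  if (any(counts < 1L)) stop("empty condition")
  out <- runs |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(
      mean_p = if ("macro_precision" %in% names(runs))
        mean(.data$macro_precision) else NA_real_,
      mean_r = if ("macro_recall" %in% names(runs))
        mean(.data$macro_recall) else NA_real_,
      mean_f = mean(.data$macro_f),
      sd_f = sd_pop(.data$macro_f),
      n = dplyr::n(),
      .groups = "drop")
  if (!is.null(baseline)) {
    if (!baseline %in% runs$condition) stop(sprintf("unknown baseline '%s'", baseline))
    base_f <- runs$macro_f[runs$condition == baseline]
    out$p_value <- vapply(out$condition, function(cond) {
      if (cond == baseline) return(NA_real_)
      other <- runs$macro_f[runs$condition == cond]
      if (length(other) < 2L || length(base_f) < 2L ||
          (sd_pop(other) == 0 && sd_pop(base_f) == 0)) return(NA_real_)
      stats::t.test(other, base_f)$p.value
    }, 0)
  }
  class(out) <- c("experiment_summary", class(out))
  out
}

#' Render an experiment or similarity summary as a Markdown table
#'
#' @param x An `experiment_summary` tibble (or any data frame).
#' @param digits Number of digits for numeric cells.
#' @return A character vector of Markdown lines.
#' @export
render_markdown_table <- function(x, digits = 1L) {
  df <- as.data.frame(x)
  fmt <- vapply(seq_along(df), function(j) {
    col <- df[[j]]
    if (is.numeric(col)) formatC(col, format = "f", digits = digits)
    else as.character(col)
  }, character(nrow(df)))
  if (nrow(df) == 1L) fmt <- matrix(fmt, nrow = 1L)
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  rows <- apply(fmt, 1L, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  c(header, sep, rows)
}
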