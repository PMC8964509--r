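# Cohort-level statistics: paired pre/post comparisons (two-tailed paired t or
# Wilcoxon matched-pairs signed rank) and assembly of instrument/metric report
# tables with deterministic ordering.

#' Paired pre/post comparison of one variable
#'
#' Two-sided paired test on patient-aligned pre/post values. Instrument scores
#' (ranked data) are conventionally compared by the Wilcoxon matched-pairs
#' signed rank test and summarized as median (IQR); metric values by the
#' paired t test and summarized as mean +/- SD.
#'
#' @param pre,post Equal-length numeric vectors (>= 3 pairs), aligned by
#'   patient.
#' @param method `"paired_t"` or `"wilcoxon_signed_rank"`.
#' @param variable Variable name carried into the result.
#' @return A `paired_comparison` list: `variable`, `method`, `statistic`,
#'   `p_value`, `n`, and `pre`/`post` summary lists matching the method's
#'   summary style.
#' @export
paired_compare <- function(pre, post,
                           method = c("paired_t", "wilcoxon_signed_rank"),
                           variable = "value") {
  method <- match.arg(method)
  if (length(pre) != length(post)) stop("pre and post must align", call. = FALSE)
  keep <- is.finite(pre) & is.finite(post)
  pre <- pre[keep]; post <- post[keep]
  if (length(pre) < 3) stop("need at least 3 complete pairs", call. = FALSE)
  d <- post - pre
  if (method == "paired_t") {
    if (stats::sd(d) == 0)
      stop("zero-variance differences: paired t test undefined", call. = FALSE)
    ht <- stats::t.test(post, pre, paired = TRUE)
    summ <- function(x) list(mean = mean(x), sd = stats::sd(x))
  } else {
    if (all(d == 0))
      stop("all paired differences tie at zero: signed-rank test undefined",
           call. = FALSE)
    ht <- suppressWarnings(stats::wilcox.test(post, pre, paired = TRUE))
    summ <- function(x) list(median = stats::median(x),
                             iqr = unname(stats::quantile(x, 0.75) -
                                          stats::quantile(x, 0.25)))
  }
  structure(list(variable = variable, method = method,
                 statistic = unname(ht$statistic), p_value = ht$p.value,
                 n = length(pre), pre = summ(pre), post = summ(post)),
            class = "paired_comparison")
}

#' @method print paired_comparison
#' @export
print.paired_comparison <- function(x, ...) {
  fmt <- function(s) {
    if (!is.null(s$mean)) sprintf("%.2f +/- %.2f", s$mean, s$sd)
    else sprintf("%.2f (%.2f)", s$median, s$iqr)
  }
  cat(sprintf("%s [%s, n=%d]: pre %s -> post %s, p = %.4g\n",
              x$variable, x$method, x$n, fmt(x$pre), fmt(x$post), x$p_value))
  invisible(x)
}

.summary_cell <- function(x, style) {
  x <- x[is.finite(x)]
  if (length(x) == 0) return(NA_character_)
  if (style == "median_iqr") {
    sprintf("%.2f (%.2f)", stats::median(x),
            unname(stats::quantile(x, 0.75) - stats::quantile(x, 0.25)))
  } else {
    sprintf("%.2f +/- %.2f", mean(x), stats::sd(x))
  }
}

# one report row: summaries per timepoint plus the paired p-value
.report_row <- function(df, col, label, method) {
  wide <- merge(df[df$timepoint == "pre", c("patient_id", col)],
                df[df$timepoint == "post", c("patient_id", col)],
                by = "patient_id", suffixes = c("_pre", "_post"))
  style <- if (method == "wilcoxon_signed_rank") "median_iqr" else "mean_sd"
  p <- tryCatch(
    paired_compare(wide[[paste0(col, "_pre")]], wide[[paste0(col, "_post")]],
                   method = method, variable = label)$p_value,
    error = function(e) NA_real_)
  data.frame(variable = label,
             preoperative = .summary_cell(df[[col]][df$timepoint == "pre"], style),
             postoperative = .summary_cell(df[[col]][df$timepoint == "post"], style),
             p_value = p, method = method, stringsAsFactors = FALSE)
}

#' Assemble a cohort report of instrument scores and symmetry metrics
#'
#' Builds a deterministic pre/post summary table: instrument rows (FNGS2.0,
#' Sunnybrook, FaCE) as median (IQR) with Wilcoxon signed-rank p-values,
#' symmetry-metric rows as mean +/- SD with paired t p-values (overridable per
#' variable via `methods`). Re-running on identical inputs is byte-identical.
#'
#' @param metrics Data.frame from [symmetry_metrics()] rows, with `patient_id`
#'   and `timepoint` columns; or `NULL`.
#' @param scores Named list of score tables (e.g. from
#'   [score_instrument_table()]), each with `patient_id`/`timepoint`; or
#'   `NULL`.
#' @param methods Optional named character vector mapping variable names to
#'   `"paired_t"` or `"wilcoxon_signed_rank"`.
#' @return A data.frame report, one row per variable.
#' @export
build_report <- function(metrics = NULL, scores = NULL, methods = NULL) {
  rows <- list()
  add_block <- function(df, default_method, prefix = "") {
    if (is.null(df) || nrow(df) == 0) return(invisible(NULL))
    ids_pre <- df$patient_id[df$timepoint == "pre"]
    ids_post <- df$patient_id[df$timepoint == "post"]
    unmatched <- union(setdiff(ids_pre, ids_post), setdiff(ids_post, ids_pre))
    if (length(unmatched) > 0)
      stop(sprintf("unmatched patient id(s): %s",
                   paste(utils::head(sort(unmatched), 10), collapse = ", ")),
           call. = FALSE)
    num_cols <- names(df)[vapply(df, is.numeric, logical(1))]
    for (col in num_cols) {
      label <- paste0(prefix, col)
      m <- if (!is.null(methods) && label %in% names(methods)) methods[[label]]
           else default_method
      rows[[length(rows) + 1L]] <<- .report_row(df, col, label, m)
    }
  }
  if (!is.null(scores)) {
    for (nm in names(scores))
      add_block(scores[[nm]], "wilcoxon_signed_rank", paste0(nm, "."))
  }
  if (!is.null(metrics)) add_block(metrics, "paired_t")
  if (length(rows) == 0) stop("empty cohort: nothing to report", call. = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a report as CSV and Markdown
#'
#' @param report A [build_report()] data.frame.
#' @param path Output path without extension; `.csv` and `.md` are written.
#' @return The two paths, invisibly.
#' @export
write_report <- function(report, path) {
  csv <- paste0(path, ".csv"); md <- paste0(path, ".md")
  utils::write.csv(report, csv, row.names = FALSE)
  lines <- c("| Variable | Preoperative | Postoperative | P value |",
             "|---|---|---|---|",
             sprintf("| %s | %s | %s | %.4g |", report$variable,
                     report$preoperative, report$postoperative, report$p_value))
  writeLines(lines, md)
  invisible(c(csv, md))
}
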