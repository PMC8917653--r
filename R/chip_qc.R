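#' Composite ChIP-seq quality score table
#'
#' Seven sample-level quality metrics are binned and each bin maps to an
#' integer score in -2..2; a sample's total score is the sum over metrics
#' and samples with total >= the retention threshold (default -3) are
#' kept. The default bins are:
#'
#' | metric | -2 | -1 | 0 | 1 | 2 |
#' |---|---|---|---|---|---|
#' | uniq_reads_pct | <20 | 20-40 | 40-60 | 60-80 | >=80 |
#' | nsc | <0.9 | 0.9-1 | 1-1.1 | 1.1-1.2 | >=1.2 |
#' | rsc | <0.8 | 0.8-0.9 | 0.9-1 | 1-1.1 | >=1.1 |
#' | auc | >=0.4 | 0.3-0.4 | 0.2-0.3 | 0.1-0.2 | <0.1 |
#' | x_intercept | >=0.3 | 0.2-0.3 | 0.15-0.2 | 0.1-0.15 | <0.1 |
#' | elbow_point | <0.65 | 0.65-0.75 | 0.75-0.85 | 0.85-0.95 | >=0.95 |
#' | peak_number | <e-10000 | e-10000..e-5000 | e-5000..e-2000 | e-2000..e | >=e |
#'
#' All ranges are lower-inclusive/upper-exclusive. AUC and X-intercept
#' score in descending order (smaller is better). The peak-number bins
#' are relative to an expected peak count `e` for the cell type, which
#' must be supplied; counts at or beyond e+25000 (outside the printed
#' right edge) still score 2, with a warning.
#'
#' @param expected_peaks reference peak count e for the cell type
#'   (mandatory, > 0).
#' @param retention_threshold minimum total score to retain a sample
#'   (default -3).
#' @return A `qc_score_table` object: per-metric breakpoints plus scores.
#' @export
qc_score_table <- function(expected_peaks, retention_threshold = -3L) {
  if (missing(expected_peaks) || !is.numeric(expected_peaks) ||
      expected_peaks <= 0)
    stop("qc_score_table: expected_peaks (e) must be supplied and > 0")
  e <- expected_peaks
  # breaks are the inner cut points; bins are [lower, upper); scores run
  # in bin order. ascending = FALSE marks metrics where smaller is better.
  tab <- list(
    uniq_reads_pct = list(breaks = c(20, 40, 60, 80),
                          scores = -2:2, ascending = TRUE),
    nsc = list(breaks = c(0.9, 1, 1.1, 1.2), scores = -2:2, ascending = TRUE),
    rsc = list(breaks = c(0.8, 0.9, 1, 1.1), scores = -2:2, ascending = TRUE),
    auc = list(breaks = c(0.1, 0.2, 0.3, 0.4), scores = 2:-2,
               ascending = FALSE),
    x_intercept = list(breaks = c(0.1, 0.15, 0.2, 0.3), scores = 2:-2,
                       ascending = FALSE),
    elbow_point = list(breaks = c(0.65, 0.75, 0.85, 0.95),
                       scores = -2:2, ascending = TRUE),
    peak_number = list(breaks = c(e - 10000, e - 5000, e - 2000, e),
                       scores = -2:2, ascending = TRUE,
                       right_edge = e + 25000)
  )
  structure(list(metrics = tab, expected_peaks = e,
                 retention_threshold = as.integer(retention_threshold)),
            class = "qc_score_table")
}

#' Score one quality metric
#'
#' Looks up the score of the bin containing `value` for `metric_name`;
#' bins are lower-inclusive and upper-exclusive.
#'
#' @param metric_name one of uniq_reads_pct, nsc, rsc, auc, x_intercept,
#'   elbow_point, peak_number.
#' @param value the metric value.
#' @param table a [qc_score_table()].
#' @return integer score in -2..2.
#' @export
score_metric <- function(metric_name, value, table) {
  stopifnot(inherits(table, "qc_score_table"))
  spec <- table$metrics[[metric_name]]
  if (is.null(spec))
    stop("score_metric: unknown metric '", metric_name, "'")
  if (!is.null(spec$right_edge) && value >= spec$right_edge)
    warning("peak_number ", value, " is at or beyond the table's right ",
            "edge (e + 25000); scoring 2")
  # findInterval with left-closed intervals: index 0 = below first break
  idx <- findInterval(value, spec$breaks, left.open = FALSE) + 1L
  as.integer(spec$scores[idx])
}

#' Total quality score of a ChIP sample
#'
#' Sums the per-metric scores over the seven quality metrics.
#'
#' @param metrics named list or vector with entries uniq_reads_pct, nsc,
#'   rsc, auc, x_intercept, elbow_point, peak_number.
#' @param table a [qc_score_table()].
#' @return list with `total` (integer in -14..14) and named `per_metric`
#'   scores.
#' @export
total_score <- function(metrics, table) {
  stopifnot(inherits(table, "qc_score_table"))
  need <- names(table$metrics)
  metrics <- as.list(metrics)
  absent <- setdiff(need, names(metrics))
  if (length(absent) > 0)
    stop("total_score: missing metric(s): ", paste(absent, collapse = ", "))
  per <- vapply(need, function(m) score_metric(m, metrics[[m]], table),
                integer(1))
  list(total = sum(per), per_metric = per)
}

#' Sample retention decision
#'
#' A sample passes when its total score is at or above the retention
#' threshold (default -3; higher scores indicate better quality).
#'
#' @param total integer total score in -14..14.
#' @param table a [qc_score_table()].
#' @return logical.
#' @export
passes_qc <- function(total, table) {
  stopifnot(inherits(table, "qc_score_table"),
            total >= -14, total <= 14)
  total >= table$retention_threshold
}

#' Fraction of reads in peaks (FRiP)
#'
#' @param reads_in_peaks mapped reads falling in called peaks.
#' @param total_mapped total mapped reads; must be > 0 and >=
#'   `reads_in_peaks`.
#' @return FRiP in \[0, 1\].
#' @export
frip <- function(reads_in_peaks, total_mapped) {
  if (any(total_mapped <= 0))
    stop("frip: total_mapped must be > 0")
  if (any(reads_in_peaks < 0) || any(reads_in_peaks > total_mapped))
    stop("frip: need 0 <= reads_in_peaks <= total_mapped")
  reads_in_peaks / total_mapped
}

#' Score a table of ChIP samples
#'
#' Convenience wrapper applying [total_score()] and [passes_qc()] to each
#' row of a metrics data frame (one row per sample, columns named after
#' the seven metrics).
#'
#' @param metrics_df data frame with the seven metric columns and
#'   optionally `sample_id`.
#' @param table a [qc_score_table()].
#' @return data frame with per-metric scores, `total`, and `pass`.
#' @export
score_qc_table <- function(metrics_df, table) {
  need <- names(table$metrics)
  out <- lapply(seq_len(nrow(metrics_df)), function(i) {
    ts <- total_score(as.list(metrics_df[i, need, drop = FALSE]), table)
    c(ts$per_metric, total = ts$total)
  })
  res <- as.data.frame(do.call(rbind, out))
  names(res) <- c(paste0("score_", need), "total")
  res$pass <- vapply(res$total, passes_qc, logical(1), table = table)
  if ("sample_id" %in% names(metrics_df))
    res <- cbind(sample_id = metrics_df$sample_id, res)
  res
}
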