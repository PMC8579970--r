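# Core inference: copy-number correction, genome-level aggregation,
# relative abundances, anomaly series, critical-time-point detection, SSP
# candidate ranking, absolute SSP cell abundance, and Tukey-fence outlier
# flagging.

#' Correct a count table for 16S rRNA gene copy number
#'
#' Divides each taxon's counts by its annotated 16S copy number, turning
#' read abundances into genome (cell) abundances. Refuses to run twice:
#' the input must be flagged raw and the output is flagged corrected.
#'
#' @param counts A raw [count_table].
#' @param annotations Annotation data frame with `taxon_id` and
#'   `copy_number` covering every taxon in the table.
#' @return A corrected [count_table].
#' @export
correct_copy_number <- function(counts, annotations) {
  if (!inherits(counts, "count_table")) counts <- count_table(counts)
  if (counts$corrected) {
    validation_error("count table is already copy-number corrected")
  }
  idx <- match(colnames(counts$abund), annotations$taxon_id)
  if (anyNA(idx)) {
    validation_error("no copy-number annotation for taxon '%s'",
                     colnames(counts$abund)[is.na(idx)][1])
  }
  cn <- annotations$copy_number[idx]
  if (any(!is.finite(cn)) || any(cn <= 0)) {
    validation_error("copy_number must be > 0 for every taxon")
  }
  count_table(sweep(counts$abund, 2, cn, "/"), corrected = TRUE)
}

#' Aggregate taxa to genome-level populations
#'
#' Sums the (corrected) abundances of all unique sequence variants
#' assigned to the same closest-genome label. Total abundance per sample
#' is conserved.
#'
#' @param counts A corrected [count_table] keyed by taxon id.
#' @param annotations Annotation data frame with `taxon_id` and
#'   `genome_label`.
#' @return A [count_table] keyed by genome label.
#' @export
aggregate_to_genomes <- function(counts, annotations) {
  if (!inherits(counts, "count_table")) counts <- count_table(counts)
  if (!counts$corrected) {
    validation_error("aggregate_to_genomes expects a copy-number corrected table")
  }
  idx <- match(colnames(counts$abund), annotations$taxon_id)
  if (anyNA(idx)) {
    validation_error("unannotated taxon '%s'",
                     colnames(counts$abund)[is.na(idx)][1])
  }
  labels <- annotations$genome_label[idx]
  agg <- t(rowsum(t(counts$abund), group = labels))
  count_table(agg, corrected = TRUE)
}

#' Relative abundances in percent
#'
#' Rescales every sample (row) to sum to 100.
#'
#' @param counts A [count_table] (raw or corrected).
#' @return A [count_table] of percentages; the corrected flag is carried
#'   through.
#' @export
relative_abundance <- function(counts) {
  if (!inherits(counts, "count_table")) counts <- count_table(counts)
  totals <- rowSums(counts$abund)
  if (any(totals <= 0)) {
    domain_error("sample '%s' has zero total abundance",
                 rownames(counts$abund)[which(totals <= 0)[1]])
  }
  count_table(sweep(counts$abund, 1, totals, "/") * 100,
              corrected = counts$corrected)
}

#' Relative-abundance anomaly series
#'
#' The dimensionless anomaly `a_t = (x_t - m) / m`, with `m` the mean of
#' the signal over the averaging window (by default the column's whole
#' observed effluent series). Anomalies over the window sum to zero by
#' construction.
#'
#' @param x Numeric signal (relative abundance, %), one value per time
#'   point.
#' @param days Integer day offsets, same length as `x` (default
#'   `seq_along(x)`).
#' @param window Day offsets forming the averaging window (default: all of
#'   `days`).
#' @param signal Signal name recorded in the output (e.g. an SSP genome
#'   label or `"DSR"`).
#' @param column_id Column identifier recorded in the output.
#' @return Data frame `column_id`, `signal`, `day`, `value`, `anomaly`,
#'   `window_mean`.
#' @export
anomaly_series <- function(x, days = seq_along(x), window = days,
                           signal = NA_character_,
                           column_id = NA_character_) {
  if (length(x) != length(days)) {
    validation_error("x and days must have equal length")
  }
  if (length(window) == 0) validation_error("averaging window is empty")
  in_win <- days %in% window
  if (!any(in_win)) validation_error("window shares no days with the series")
  m <- mean(x[in_win])
  if (!is.finite(m) || m <= 0) {
    domain_error("window mean is not positive; signal absent from column")
  }
  data.frame(column_id = column_id, signal = signal,
             day = as.integer(days), value = x,
             anomaly = (x - m) / m, window_mean = m,
             stringsAsFactors = FALSE)
}

#' Detect critical time points
#'
#' A critical time point is a TM-phase time point whose signal (SSP
#' relative abundance) is strictly greater than the TM-phase mean of that
#' signal; it is read as a biofilm-dispersal pulse into the effluent.
#' Ties with the mean are not critical.
#'
#' @param series Data frame with columns `day` and `value` for one column.
#' @param phases Phase assignment for the same column (`day`, `phase`).
#' @return Integer vector of critical days (empty, with a warning, when
#'   the column has no TM phase).
#' @export
detect_critical_time_points <- function(series, phases) {
  stopifnot_columns(series, c("day", "value"), "series")
  stopifnot_columns(phases, c("day", "phase"), "phases")
  tm_days <- phases$day[phases$phase == "TM"]
  if (length(tm_days) == 0) {
    warning("column has no TM phase; no critical time points")
    return(integer(0))
  }
  tm <- series[series$day %in% tm_days, ]
  if (nrow(tm) == 0) {
    validation_error("series has no observations on TM-phase days")
  }
  sort(as.integer(tm$day[tm$value > mean(tm$value)]))
}

#' Rank SSP candidates for one column
#'
#' Ranks SRB-flagged genome populations by their mean relative abundance
#' over the column's TM phase, descending (ties broken lexicographically).
#' All candidates at or above `floor` are returned, so columns carrying
#' more than one surging SRB population report multiple candidates.
#'
#' @param genome_rel Matrix of relative abundances (%) for one column's
#'   effluent samples: rows named by day offset, columns by genome label.
#' @param annotations Annotation data frame (`genome_label`, `is_srb`).
#' @param tm_days Day offsets of the column's TM phase.
#' @param floor Minimum TM-phase mean (%) for a candidate to be reported
#'   (default 0: report all SRB genomes).
#' @return Data frame `genome_label`, `tm_mean_pct`, `rank`.
#' @export
select_ssp_candidates <- function(genome_rel, annotations, tm_days,
                                  floor = 0) {
  srb <- unique(annotations$genome_label[annotations$is_srb])
  srb <- intersect(colnames(genome_rel), srb)
  if (length(srb) == 0) {
    validation_error("no SRB-flagged genomes present in the abundance table")
  }
  if (length(tm_days) == 0) validation_error("tm_days is empty")
  rows <- rownames(genome_rel) %in% as.character(tm_days)
  if (!any(rows)) {
    validation_error("no abundance rows on the given TM days")
  }
  means <- colMeans(genome_rel[rows, srb, drop = FALSE])
  ord <- order(-means, names(means))
  out <- data.frame(genome_label = names(means)[ord],
                    tm_mean_pct = unname(means[ord]),
                    stringsAsFactors = FALSE)
  out <- out[out$tm_mean_pct >= floor, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Absolute SSP cell abundance
#'
#' Scales a relative abundance (%) by the flow-cytometry total cell count:
#' `cells/ml = rel_pct / 100 * total_cells_per_ml`.
#'
#' @param rel_pct Relative abundance in percent, in `[0, 100]`.
#' @param total_cells_per_ml Total cell count (> 0).
#' @return SSP cell abundance in cells/ml.
#' @export
ssp_cell_abundance <- function(rel_pct, total_cells_per_ml) {
  if (any(rel_pct < 0 | rel_pct > 100)) {
    domain_error("relative abundance must be within [0, 100] percent")
  }
  if (any(total_cells_per_ml <= 0)) {
    domain_error("total cell count must be positive")
  }
  rel_pct / 100 * total_cells_per_ml
}

#' Flag outliers by Tukey's fences
#'
#' Flags values outside `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]`, with quartiles by
#' linear interpolation between order statistics at positions
#' `1 + (n - 1) q` (the default quantile convention of R). With fewer than
#' four values nothing is flagged and a warning is issued.
#'
#' @param values Numeric vector (non-empty).
#' @return Logical vector: `TRUE` marks an outlier.
#' @export
flag_tukey_outliers <- function(values) {
  if (length(values) == 0) domain_error("cannot flag outliers of an empty vector")
  if (any(!is.finite(values))) domain_error("values must be finite")
  if (length(values) < 4) {
    warning("fewer than 4 values; no outliers flagged")
    return(rep(FALSE, length(values)))
  }
  q <- stats::quantile(values, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  values < q[1] - 1.5 * iqr | values > q[2] + 1.5 * iqr
}
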