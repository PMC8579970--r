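# Predicted dissimilatory sulfate reduction (DSR) pathway abundance, its
# cross-column average anomaly, and a penalized-spline trend.

#' Predicted DSR pathway relative abundance per sample
#'
#' Sums genome-level relative abundances over the genomes annotated as
#' carrying the dissimilatory sulfate reduction I (to hydrogen sulfide)
#' pathway. Pathway presence is binary, so the result is the community
#' fraction (in percent, bounded by 100) predicted to encode the pathway.
#'
#' @param genome_rel Matrix of relative abundances (%): rows are samples,
#'   columns are genome labels.
#' @param annotations Annotation data frame with `genome_label` and
#'   `has_dsr` covering every genome in the table.
#' @return Named numeric vector, one DSR percentage per sample row.
#' @export
dsr_relative_abundance <- function(genome_rel, annotations) {
  ann <- unique(annotations[, c("genome_label", "has_dsr")])
  idx <- match(colnames(genome_rel), ann$genome_label)
  if (anyNA(idx) || anyNA(ann$has_dsr[idx])) {
    bad <- colnames(genome_rel)[is.na(idx) | is.na(ann$has_dsr[idx])][1]
    validation_error("genome '%s' has no has_dsr annotation", bad)
  }
  dsr_cols <- ann$has_dsr[idx]
  rowSums(genome_rel[, dsr_cols, drop = FALSE])
}

#' Cross-column average anomaly per time point
#'
#' Unweighted mean and standard deviation of per-column anomalies at each
#' time point; columns not observed at a time point are omitted from that
#' point (their count is reported). Time points observed in no column are
#' dropped with a warning.
#'
#' @param anomalies Long data frame with columns `column_id`, `day`,
#'   `anomaly` (one row per column and time point).
#' @param grid Optional day offsets at which to evaluate; defaults to all
#'   days present.
#' @return Data frame `day`, `mean_anomaly`, `sd_anomaly`, `n_columns`
#'   (SD is 0 when a single column is observed).
#' @export
average_anomaly <- function(anomalies, grid = NULL) {
  stopifnot_columns(anomalies, c("column_id", "day", "anomaly"), "anomalies")
  if (is.null(grid)) grid <- sort(unique(anomalies$day))
  rows <- lapply(grid, function(d) {
    v <- anomalies$anomaly[anomalies$day == d]
    if (length(v) == 0) return(NULL)
    data.frame(day = as.integer(d), mean_anomaly = mean(v),
               sd_anomaly = if (length(v) > 1) stats::sd(v) else 0,
               n_columns = length(v))
  })
  dropped <- sum(vapply(rows, is.null, TRUE))
  if (dropped > 0) {
    warning(sprintf("%d requested time point(s) observed in no column; omitted",
                    dropped))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Smooth a trend with a penalized spline (GAM)
#'
#' Fits a penalized cubic regression spline with smoothness chosen by
#' generalized cross-validation and returns the fit with a +- 2 standard
#' error band. The basis dimension defaults to `min(10, n/4)` knots
#' (bounded below so the basis stays valid).
#'
#' @param times Numeric predictor (day offsets); at least 5 distinct
#'   values.
#' @param values Response, same length as `times`.
#' @param k Optional basis dimension override.
#' @return Data frame `day`, `fit`, `se`, `lo`, `hi` evaluated at the
#'   sorted distinct input times (`lo`/`hi` are `fit -+ 2 se`).
#' @export
smooth_trend <- function(times, values, k = NULL) {
  if (length(times) != length(values)) {
    validation_error("times and values must have equal length")
  }
  ut <- sort(unique(times))
  if (length(ut) < 5) {
    validation_error("need at least 5 distinct time points (got %d)",
                     length(ut))
  }
  if (is.null(k)) k <- min(10, max(4, floor(length(times) / 4)))
  k <- min(k, length(ut))
  d <- data.frame(t = times, y = values)
  fit <- mgcv::gam(y ~ s(t, k = k, bs = "cr"), data = d, method = "GCV.Cp")
  pr <- mgcv::predict.gam(fit, newdata = data.frame(t = ut), se.fit = TRUE)
  data.frame(day = ut, fit = as.numeric(pr$fit), se = as.numeric(pr$se.fit),
             lo = as.numeric(pr$fit - 2 * pr$se.fit),
             hi = as.numeric(pr$fit + 2 * pr$se.fit))
}
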