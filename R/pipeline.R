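# End-to-end orchestration: generate or load a bundle, run every stage in
# order, and emit the indicator report plus flat per-stage tables.

#' Pipeline configuration
#'
#' @param mode `"synthetic"` (generate a bundle from `generator`) or
#'   `"files"` (load the six TSVs from `paths`).
#' @param generator A [generator_config()] (synthetic mode).
#' @param paths Directory or named paths for [load_bundle()] (files mode).
#' @param threshold_mm Sulfide threshold for phase segmentation (mM).
#' @param shannon_base Logarithm base for the Shannon index.
#' @param simpson_variant `"gini"` or `"dominance"`.
#' @param ssp_floor Minimum TM-phase mean (%) for reported SSP candidates.
#' @param gam_k Optional basis dimension for the DSR trend smoother.
#' @param ordination Compute the Bray-Curtis PCoA (the most expensive
#'   stage; disable for batch recovery experiments).
#' @param out_dir Optional output directory; when set, the report and all
#'   stage TSVs are written there.
#' @param seed Optional override of the generator seed.
#' @param quiet Suppress per-stage log messages.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(mode = c("synthetic", "files"),
                            generator = generator_config(),
                            paths = NULL,
                            threshold_mm = 1,
                            shannon_base = exp(1),
                            simpson_variant = "gini",
                            ssp_floor = 0,
                            gam_k = NULL,
                            ordination = TRUE,
                            out_dir = NULL,
                            seed = NULL,
                            quiet = FALSE) {
  mode <- match.arg(mode)
  if (mode == "files" && is.null(paths)) {
    config_error("files mode requires 'paths'")
  }
  structure(list(mode = mode, generator = generator, paths = paths,
                 threshold_mm = threshold_mm, shannon_base = shannon_base,
                 simpson_variant = simpson_variant, ssp_floor = ssp_floor,
                 gam_k = gam_k, ordination = isTRUE(ordination),
                 out_dir = out_dir, seed = seed, quiet = isTRUE(quiet)),
            class = "pipeline_config")
}

pipe_msg <- function(quiet, fmt, ...) {
  if (!quiet) message(sprintf(paste0("[soursentinel] ", fmt), ...))
}

# Per-treated-column indicator analysis. Returns NULL (with a warning)
# when the column never enters a TM phase.
analyze_column <- function(cid, rel_genome, samples, phases, cells,
                           annotations, floor = 0) {
  smp <- samples[samples$column_id == cid &
                   samples$sample_type == "effluent", ]
  smp <- smp[order(smp$day), ]
  mat <- rel_genome$abund[smp$sample_id, , drop = FALSE]
  rownames(mat) <- as.character(smp$day)
  ph <- phases[phases$column_id == cid, ]
  tm_days <- ph$day[ph$phase == "TM"]
  if (length(tm_days) == 0) {
    warning(sprintf("column %s has no TM phase; skipped in indicator report",
                    cid))
    return(NULL)
  }
  cand <- select_ssp_candidates(mat, annotations, tm_days, floor = floor)
  ssp <- cand$genome_label[1]
  series <- data.frame(day = smp$day, value = mat[, ssp])
  anom <- anomaly_series(series$value, series$day,
                         signal = ssp, column_id = cid)
  ct <- detect_critical_time_points(series, ph)

  # Tukey outlier flagging of total cell counts, per phase of this column,
  # before any absolute-abundance summary
  cc <- cells[cells$column_id == cid, ]
  cc$phase <- as.character(ph$phase[match(cc$day, ph$day)])
  cc$outlier <- FALSE
  for (p in unique(cc$phase[!is.na(cc$phase)])) {
    sel <- which(cc$phase %in% p)
    if (length(sel) >= 4) {
      cc$outlier[sel] <- flag_tukey_outliers(cc$cells_per_ml[sel])
    }
  }

  keep <- !cc$outlier & cc$day %in% series$day & !is.na(cc$phase)
  use <- cc[keep, ]
  rel <- series$value[match(use$day, series$day)]
  use$ssp_cells_per_ml <- ssp_cell_abundance(rel, use$cells_per_ml)
  use$group <- ifelse(use$day %in% ct, "CT", use$phase)

  groups <- c("S", "CT", "TM", "M", "R")
  summ <- do.call(rbind, lapply(groups, function(g) {
    v <- use$ssp_cells_per_ml[use$group == g]
    if (length(v) == 0) return(NULL)
    data.frame(group = g, n = length(v), median_cells_per_ml = stats::median(v),
               stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL

  kw <- NULL
  vals <- split(use$ssp_cells_per_ml, use$group)
  vals <- vals[vapply(vals, length, 0L) > 0]
  if (length(vals) >= 2) kw <- group_compare(vals, "kruskal_wallis")

  list(column_id = cid, ssp = cand, ssp_genome = ssp,
       critical_days = ct, anomalies = anom, phase_summary = summ,
       kruskal = kw, cells = cc)
}

#' Run the full indicator pipeline
#'
#' Executes, in order: bundle generation or loading, copy-number
#' correction, genome aggregation, relative abundances, phase
#' segmentation, alpha diversity (and optionally Bray-Curtis PCoA), SSP
#' candidate ranking and anomaly series per treated column, critical
#' time-point detection, Tukey-flagged absolute SSP cell-abundance
#' summaries, and the DSR pathway anomaly with its cross-column average
#' and GAM trend. When `out_dir` is set, the report, all stage TSVs and a
#' run manifest are written there.
#'
#' @param config A [pipeline_config()].
#' @return An object of class `indicator_report`, invisibly.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  q <- config$quiet
  truth <- NULL
  if (config$mode == "synthetic") {
    gen <- config$generator
    if (!is.null(config$seed)) gen$seed <- as.integer(config$seed)
    pipe_msg(q, "generating synthetic experiment (seed %d)", gen$seed)
    ge <- generate_experiment(gen)
    bundle <- ge$bundle
    truth <- ge$truth
  } else {
    pipe_msg(q, "loading bundle from files")
    bundle <- load_bundle(config$paths, quiet = q)
  }
  pipe_msg(q, "bundle: %d samples, %d taxa", nrow(bundle$samples),
           ncol(bundle$counts$abund))

  corrected <- correct_copy_number(bundle$counts, bundle$annotations)
  genome <- aggregate_to_genomes(corrected, bundle$annotations)
  rel_genome <- relative_abundance(genome)
  rel_asv <- relative_abundance(corrected)
  pipe_msg(q, "copy-number corrected and aggregated to %d genomes",
           ncol(genome$abund))

  grid <- unique(rbind(bundle$samples[, c("column_id", "day")],
                       bundle$sulfide[, c("column_id", "day")],
                       bundle$cells[, c("column_id", "day")]))
  phases <- assign_phases(bundle$sulfide, bundle$schedule,
                          threshold_mm = config$threshold_mm, times = grid)
  pipe_msg(q, "phase segmentation: %s",
           paste(sprintf("%s=%d", levels(phases$phase),
                         tabulate(phases$phase, 4)), collapse = " "))

  div <- data.frame(
    sample_id = rownames(corrected$abund),
    shannon = apply(corrected$abund, 1, shannon, base = config$shannon_base),
    simpson = apply(corrected$abund, 1, simpson,
                    variant = config$simpson_variant),
    stringsAsFactors = FALSE)
  ord <- NULL
  if (config$ordination) {
    bc <- vegan::vegdist(rel_asv$abund, method = "bray")
    ord <- pcoa(as.matrix(bc), k = 2)
    pipe_msg(q, "PCoA axes explain %.1f%% of positive inertia",
             100 * sum(ord$prop_explained))
  }

  treated_cols <- bundle$schedule$column_id[!is.na(bundle$schedule$nitrate_start)]
  col_results <- list()
  for (cid in treated_cols) {
    res <- analyze_column(cid, rel_genome, bundle$samples, phases,
                          bundle$cells, bundle$annotations,
                          floor = config$ssp_floor)
    if (!is.null(res)) col_results[[cid]] <- res
  }
  pipe_msg(q, "indicator analysis: %d treated columns, %d critical time points",
           length(col_results),
           sum(vapply(col_results, function(r) length(r$critical_days), 0L)))

  # DSR pathway anomaly for every column (treated and nontreated)
  eff <- bundle$samples[bundle$samples$sample_type == "effluent", ]
  dsr_pct <- dsr_relative_abundance(
    rel_genome$abund[eff$sample_id, , drop = FALSE], bundle$annotations)
  dsr <- data.frame(sample_id = eff$sample_id, column_id = eff$column_id,
                    day = eff$day, treatment = eff$treatment,
                    dsr_pct = as.numeric(dsr_pct), stringsAsFactors = FALSE)
  dsr_anom <- do.call(rbind, lapply(split(dsr, dsr$column_id), function(d) {
    d <- d[order(d$day), ]
    anomaly_series(d$dsr_pct, d$day, signal = "DSR",
                   column_id = d$column_id[1])
  }))
  rownames(dsr_anom) <- NULL
  treatment_of <- function(cids) {
    eff$treatment[match(cids, eff$column_id)]
  }
  dsr_anom$treatment <- treatment_of(dsr_anom$column_id)
  avg <- lapply(c("treated", "nontreated"), function(tr) {
    d <- dsr_anom[dsr_anom$treatment == tr, ]
    if (nrow(d) == 0) return(NULL)
    a <- average_anomaly(d)
    a$treatment <- tr
    a
  })
  dsr_average <- do.call(rbind, avg)

  trend <- NULL
  tr_avg <- dsr_average[dsr_average$treatment == "treated", ]
  if (!is.null(tr_avg) && length(unique(tr_avg$day)) >= 5) {
    trend <- smooth_trend(tr_avg$day, tr_avg$mean_anomaly, k = config$gam_k)
    pipe_msg(q, "GAM trend fitted on %d time points", nrow(trend))
  }

  anomalies <- rbind(
    do.call(rbind, lapply(col_results, function(r) r$anomalies)),
    dsr_anom[, c("column_id", "signal", "day", "value", "anomaly",
                 "window_mean")])
  rownames(anomalies) <- NULL
  cells_flagged <- do.call(rbind, lapply(col_results, function(r) r$cells))
  if (!is.null(cells_flagged)) rownames(cells_flagged) <- NULL

  report <- structure(list(
    columns = lapply(col_results, function(r) {
      r[c("column_id", "ssp", "ssp_genome", "critical_days",
          "phase_summary", "kruskal")]
    }),
    anomalies = anomalies,
    diversity = div,
    ordination = ord,
    dsr = dsr,
    dsr_average = dsr_average,
    trend = trend,
    cells_flagged = cells_flagged,
    phases = data.frame(phases[, c("column_id", "day")],
                        phase = as.character(phases$phase),
                        stringsAsFactors = FALSE),
    schedule = bundle$schedule,
    params = list(threshold_mm = config$threshold_mm,
                  ssp_floor = config$ssp_floor,
                  mode = config$mode,
                  seed = if (config$mode == "synthetic") {
                    if (is.null(config$seed)) config$generator$seed
                    else as.integer(config$seed)
                  } else {
                    NULL
                  }),
    truth = truth), class = "indicator_report")

  if (!is.null(config$out_dir)) {
    write_report(report, config$out_dir)
    pipe_msg(q, "report written to %s", config$out_dir)
  }
  invisible(report)
}

#' @export
print.indicator_report <- function(x, ...) {
  cat(sprintf("<indicator_report> %d treated columns\n", length(x$columns)))
  for (r in x$columns) {
    cat(sprintf("  %s: SSP %s; critical days {%s}\n", r$column_id,
                r$ssp_genome, paste(r$critical_days, collapse = ", ")))
  }
  invisible(x)
}

report_json_payload <- function(report) {
  cols <- lapply(report$columns, function(r) {
    list(column_id = r$column_id, ssp = r$ssp, ssp_genome = r$ssp_genome,
         critical_days = as.integer(r$critical_days),
         phase_summary = r$phase_summary,
         kruskal = if (is.null(r$kruskal)) NULL else
           r$kruskal[c("statistic", "p_value", "n")])
  })
  list(columns = cols,
       anomalies = report$anomalies,
       diversity = report$diversity,
       dsr = report$dsr,
       dsr_average = report$dsr_average,
       trend = report$trend,
       cells_flagged = report$cells_flagged,
       phases = report$phases,
       schedule = report$schedule,
       params = report$params)
}

#' Write an indicator report
#'
#' Emits a machine-readable `report.json` plus flat TSVs (anomalies per
#' column and time point, critical time points, SSP candidate ranks,
#' flagged cell counts, diversity, DSR series and trend). The JSON is
#' re-loadable losslessly via [read_report()].
#'
#' @param report An `indicator_report`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_report <- function(report, dir) {
  ok <- dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir)) io_error("cannot create output directory %s", dir)
  jsonlite::write_json(report_json_payload(report),
                       file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  ct <- do.call(rbind, lapply(report$columns, function(r) {
    if (length(r$critical_days) == 0) return(NULL)
    data.frame(column_id = r$column_id, day = r$critical_days,
               ssp_genome = r$ssp_genome, stringsAsFactors = FALSE)
  }))
  if (is.null(ct)) {
    ct <- data.frame(column_id = character(0), day = integer(0),
                     ssp_genome = character(0))
  }
  ranks <- do.call(rbind, lapply(report$columns, function(r) {
    data.frame(column_id = r$column_id, r$ssp, stringsAsFactors = FALSE)
  }))
  if (is.null(ranks)) {
    ranks <- data.frame(column_id = character(0), genome_label = character(0),
                        tm_mean_pct = numeric(0), rank = integer(0))
  }
  write_tsv(report$anomalies %||%
              data.frame(column_id = character(0)), file.path(dir, "anomalies.tsv"))
  write_tsv(ct, file.path(dir, "critical_points.tsv"))
  write_tsv(ranks, file.path(dir, "ssp_rank.tsv"))
  write_tsv(report$diversity, file.path(dir, "diversity.tsv"))
  write_tsv(report$dsr, file.path(dir, "dsr.tsv"))
  write_tsv(report$anomalies[report$anomalies$signal == "DSR", ],
            file.path(dir, "dsr_anomaly.tsv"))
  if (!is.null(report$trend)) write_tsv(report$trend, file.path(dir, "trend.tsv"))
  if (!is.null(report$cells_flagged)) {
    write_tsv(report$cells_flagged, file.path(dir, "cells_flagged.tsv"))
  }
  write_tsv(report$phases, file.path(dir, "phases.tsv"))
  manifest <- list(package = "soursentinel",
                   version = as.character(utils::packageVersion("soursentinel")),
                   params = report$params)
  jsonlite::write_json(manifest, file.path(dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Read an indicator report back from disk
#'
#' Reconstructs the `indicator_report` from `report.json` (the ordination
#' and generator ground truth, which are session objects, are not part of
#' the on-disk report).
#'
#' @param dir Directory written by [write_report()].
#' @return An `indicator_report`.
#' @export
read_report <- function(dir) {
  path <- file.path(dir, "report.json")
  if (!file.exists(path)) io_error("no report.json under %s", dir)
  x <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                          simplifyDataFrame = TRUE)
  x$columns <- lapply(x$columns, function(r) {
    r$critical_days <- as.integer(unlist(r$critical_days))
    r
  })
  structure(x, class = "indicator_report")
}
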