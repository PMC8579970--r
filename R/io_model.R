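# Data model and tabular interchange: count tables, experiment bundles,
# TSV/CSV readers and writers, cross-table validation, and the packaged
# study-design bookkeeping table.

#' Construct a count table
#'
#' A count table holds per-sample abundances (raw reads or copy-number
#' corrected values) for unique sequence variants or, after aggregation,
#' for genome-level populations. Rows are samples, columns are taxa.
#'
#' @param abund Numeric matrix (or data frame coercible to one) with sample
#'   ids as row names and taxon ids as column names. Values must be
#'   non-negative and finite; fractional values are allowed because 16S
#'   copy-number correction produces non-integers.
#' @param corrected Logical flag recording whether copy-number correction
#'   has already been applied. The flag exists to prevent double
#'   correction.
#' @return An object of class `count_table`.
#' @export
count_table <- function(abund, corrected = FALSE) {
  if (is.data.frame(abund)) abund <- as.matrix(abund)
  if (!is.matrix(abund) || !is.numeric(abund)) {
    validation_error("count table must be a numeric matrix (samples x taxa)")
  }
  if ((nrow(abund) > 0 && is.null(rownames(abund))) ||
      (ncol(abund) > 0 && is.null(colnames(abund)))) {
    validation_error("count table needs sample ids as row names and taxon ids as column names")
  }
  if (anyDuplicated(rownames(abund)) > 0) {
    validation_error("duplicated sample id in count table: '%s'",
                     rownames(abund)[anyDuplicated(rownames(abund))])
  }
  if (anyDuplicated(colnames(abund)) > 0) {
    validation_error("duplicated taxon id in count table: '%s'",
                     colnames(abund)[anyDuplicated(colnames(abund))])
  }
  if (any(!is.finite(abund))) {
    validation_error("count table contains non-finite values")
  }
  if (any(abund < 0)) {
    bad <- which(abund < 0, arr.ind = TRUE)[1, ]
    validation_error("negative abundance for sample '%s', taxon '%s'",
                     rownames(abund)[bad[1]], colnames(abund)[bad[2]])
  }
  structure(list(abund = abund, corrected = isTRUE(corrected)),
            class = "count_table")
}

#' @export
as.matrix.count_table <- function(x, ...) x$abund

#' @export
dim.count_table <- function(x) dim(x$abund)

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("<count_table> %d samples x %d taxa (%s)\n",
              nrow(x$abund), ncol(x$abund),
              if (x$corrected) "copy-number corrected" else "raw"))
  invisible(x)
}

#' Assemble an experiment bundle
#'
#' The bundle is the joined data model for one bioreactor experiment:
#' amplicon counts, taxon annotations, sample metadata, sulfide series,
#' nitrate treatment schedule, and flow-cytometry cell counts. Time is
#' stored everywhere as integer day offsets from experiment start.
#'
#' @param counts A [count_table].
#' @param annotations Data frame with columns `taxon_id`, `genome_label`,
#'   `is_srb`, `copy_number`, `has_dsr`.
#' @param samples Data frame with columns `sample_id`, `column_id`, `day`,
#'   `sample_type` (`effluent`/`sessile`), `section`
#'   (`top`/`middle`/`bottom`/`none`), `treatment`
#'   (`treated`/`nontreated`), `temperature_c`.
#' @param sulfide Data frame with columns `column_id`, `day`, `sulfide_mm`.
#' @param schedule Data frame with columns `column_id`, `nitrate_start`,
#'   `nitrate_stop`, `nitrate_mm` (`NA` start/stop for nontreated columns).
#' @param cells Data frame with columns `column_id`, `day`, `cells_per_ml`
#'   and optionally `outlier` (filled downstream by Tukey flagging).
#' @param validate Run [validate_bundle()] on the result (default `TRUE`).
#' @return An object of class `experiment_bundle`.
#' @export
experiment_bundle <- function(counts, annotations, samples, sulfide,
                              schedule, cells, validate = TRUE) {
  if (!inherits(counts, "count_table")) counts <- count_table(counts)
  if (!"outlier" %in% names(cells)) cells$outlier <- FALSE
  b <- structure(list(counts = counts,
                      annotations = as.data.frame(annotations),
                      samples = as.data.frame(samples),
                      sulfide = as.data.frame(sulfide),
                      schedule = as.data.frame(schedule),
                      cells = as.data.frame(cells)),
                 class = "experiment_bundle")
  if (validate) validate_bundle(b)
  b
}

#' @export
print.experiment_bundle <- function(x, ...) {
  cat("<experiment_bundle>\n")
  cat(sprintf("  samples:     %d (%d effluent, %d sessile)\n",
              nrow(x$samples),
              sum(x$samples$sample_type == "effluent"),
              sum(x$samples$sample_type == "sessile")))
  cat(sprintf("  taxa:        %d (%d annotated SRB)\n",
              ncol(x$counts$abund), sum(x$annotations$is_srb)))
  cat(sprintf("  columns:     %d (%d treated)\n",
              length(unique(x$samples$column_id)),
              sum(!is.na(x$schedule$nitrate_start))))
  cat(sprintf("  sulfide obs: %d, cell-count obs: %d\n",
              nrow(x$sulfide), nrow(x$cells)))
  invisible(x)
}

#' Validate cross-table consistency of a bundle
#'
#' Checks referential integrity and the type invariants of every member
#' table; raises a typed validation error naming the first offending
#' record, never silently passing malformed input.
#'
#' @param bundle An [experiment_bundle].
#' @return The bundle, invisibly.
#' @export
validate_bundle <- function(bundle) {
  counts <- bundle$counts
  ann <- stopifnot_columns(bundle$annotations,
                           c("taxon_id", "genome_label", "is_srb",
                             "copy_number", "has_dsr"), "annotations")
  smp <- stopifnot_columns(bundle$samples,
                           c("sample_id", "column_id", "day", "sample_type",
                             "section", "treatment", "temperature_c"),
                           "sample metadata")
  sul <- stopifnot_columns(bundle$sulfide,
                           c("column_id", "day", "sulfide_mm"), "sulfide")
  sch <- stopifnot_columns(bundle$schedule,
                           c("column_id", "nitrate_start", "nitrate_stop",
                             "nitrate_mm"), "schedule")
  cel <- stopifnot_columns(bundle$cells,
                           c("column_id", "day", "cells_per_ml"),
                           "cell counts")

  if (anyDuplicated(ann$taxon_id) > 0) {
    validation_error("duplicated taxon_id in annotations: '%s'",
                     ann$taxon_id[anyDuplicated(ann$taxon_id)])
  }
  if (any(!is.finite(ann$copy_number)) || any(ann$copy_number <= 0)) {
    validation_error("annotation copy_number must be > 0 (taxon '%s')",
                     ann$taxon_id[which(!(ann$copy_number > 0))[1]])
  }
  missing_tax <- setdiff(colnames(counts$abund), ann$taxon_id)
  if (length(missing_tax) > 0) {
    validation_error("taxon '%s' in counts has no annotation", missing_tax[1])
  }

  if (anyDuplicated(smp$sample_id) > 0) {
    validation_error("duplicated sample_id in metadata: '%s'",
                     smp$sample_id[anyDuplicated(smp$sample_id)])
  }
  orphan <- setdiff(rownames(counts$abund), smp$sample_id)
  if (length(orphan) > 0) {
    validation_error("sample '%s' in counts is absent from metadata", orphan[1])
  }
  bad_type <- !smp$sample_type %in% c("effluent", "sessile")
  if (any(bad_type)) {
    validation_error("sample '%s' has unknown sample_type '%s'",
                     smp$sample_id[bad_type][1], smp$sample_type[bad_type][1])
  }
  # sessile <=> a real section
  mismatch <- (smp$sample_type == "sessile") != (smp$section != "none")
  if (any(mismatch)) {
    validation_error("sample '%s' violates sessile <=> section rule",
                     smp$sample_id[mismatch][1])
  }
  if (any(!smp$treatment %in% c("treated", "nontreated"))) {
    validation_error("treatment must be 'treated' or 'nontreated'")
  }

  # sulfide: unique, strictly increasing times within a column
  key <- paste(sul$column_id, sul$day)
  if (anyDuplicated(key) > 0) {
    validation_error("duplicate sulfide observation at (%s)",
                     key[anyDuplicated(key)])
  }
  if (any(sul$sulfide_mm < 0, na.rm = TRUE)) {
    validation_error("negative sulfide concentration in column '%s'",
                     sul$column_id[which(sul$sulfide_mm < 0)[1]])
  }

  if (anyDuplicated(sch$column_id) > 0) {
    validation_error("duplicated schedule row for column '%s'",
                     sch$column_id[anyDuplicated(sch$column_id)])
  }
  both <- !is.na(sch$nitrate_start) & !is.na(sch$nitrate_stop)
  if (any(both & sch$nitrate_start >= sch$nitrate_stop)) {
    validation_error("nitrate_start must precede nitrate_stop (column '%s')",
                     sch$column_id[both & sch$nitrate_start >= sch$nitrate_stop][1])
  }
  treated_cols <- unique(smp$column_id[smp$treatment == "treated"])
  no_sched <- setdiff(treated_cols,
                      sch$column_id[!is.na(sch$nitrate_start)])
  if (length(no_sched) > 0) {
    validation_error("treated column '%s' has no nitrate_start in schedule",
                     no_sched[1])
  }

  if (any(!is.finite(cel$cells_per_ml)) || any(cel$cells_per_ml <= 0)) {
    validation_error("cells_per_ml must be positive (column '%s')",
                     cel$column_id[which(!(cel$cells_per_ml > 0))[1]])
  }
  invisible(bundle)
}

# ---- readers / writers ------------------------------------------------------

bundle_files <- c(counts = "counts.tsv", annotations = "annotations.tsv",
                  metadata = "metadata.tsv", sulfide = "sulfide.tsv",
                  schedule = "schedule.tsv", cells = "cells.tsv")

# Sniff the field separator from the header line; TSV is canonical,
# comma-separated files are accepted on read.
read_table_auto <- function(path) {
  if (!file.exists(path)) io_error("file not found: %s", path)
  first <- readLines(path, n = 2L)
  first <- first[!startsWith(first, "#")]
  sep <- if (length(first) > 0 && grepl("\t", first[1])) "\t" else ","
  utils::read.delim(path, sep = sep, comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

# Calendar dates in inputs are converted to integer day offsets from the
# earliest date seen in the bundle; integer inputs pass through unchanged.
as_day <- function(x, origin = NULL) {
  if (is.numeric(x)) return(as.integer(round(x)))
  d <- as.Date(as.character(x),
               tryFormats = c("%m/%d/%Y", "%Y-%m-%d", "%m/%d/%y"))
  if (any(is.na(d) & !is.na(x) & nzchar(as.character(x)))) {
    validation_error("unparseable time point '%s'",
                     as.character(x)[is.na(d)][1])
  }
  if (is.null(origin)) origin <- min(d, na.rm = TRUE)
  as.integer(d - origin)
}

time_col <- function(df) {
  nm <- intersect(c("day", "time_point"), names(df))
  if (length(nm) == 0) validation_error("table has no 'day' or 'time_point' column")
  nm[1]
}

#' Load an experiment bundle from TSV/CSV files
#'
#' Reads the six interchange tables, converts any calendar dates to integer
#' day offsets from the earliest date present, validates referential
#' integrity, and reports per-table record counts.
#'
#' @param paths Either a directory containing the canonical file names
#'   (`counts.tsv`, `annotations.tsv`, `metadata.tsv`, `sulfide.tsv`,
#'   `schedule.tsv`, `cells.tsv`) or a named character vector/list with
#'   those six names pointing at arbitrary files.
#' @param quiet Suppress the per-table record-count messages.
#' @return A validated [experiment_bundle].
#' @export
load_bundle <- function(paths, quiet = FALSE) {
  if (length(paths) == 1 && is.character(paths) && dir.exists(paths)) {
    paths <- file.path(paths, bundle_files)
    names(paths) <- names(bundle_files)
  }
  paths <- as.list(paths)
  need <- setdiff(names(bundle_files), names(paths))
  if (length(need) > 0) {
    io_error("missing path(s) for: %s", paste(need, collapse = ", "))
  }

  # corrected flag is carried as a '# corrected=' comment in counts.tsv
  counts_head <- readLines(paths$counts, n = 1L)
  corrected <- grepl("corrected=true", counts_head, fixed = TRUE)

  raw <- lapply(paths[names(bundle_files)], read_table_auto)

  cdf <- raw$counts
  if (nrow(cdf) == 0) {
    warning("counts file has a header but no samples; empty bundle")
    mat <- matrix(numeric(0), nrow = 0, ncol = max(ncol(cdf) - 1, 0),
                  dimnames = list(character(0),
                                  if (ncol(cdf) > 1) names(cdf)[-1] else character(0)))
  } else {
    mat <- as.matrix(cdf[, -1, drop = FALSE])
    rownames(mat) <- as.character(cdf[[1]])
  }

  # shared date origin across all time-bearing tables
  origin <- NULL
  tcols <- list(metadata = time_col(raw$metadata),
                sulfide = time_col(raw$sulfide),
                cells = time_col(raw$cells))
  dates <- unlist(lapply(names(tcols), function(nm) {
    v <- raw[[nm]][[tcols[[nm]]]]
    if (!is.numeric(v)) as.character(v) else character(0)
  }), use.names = FALSE)
  sch <- raw$schedule
  for (cc in c("nitrate_start", "nitrate_stop")) {
    if (cc %in% names(sch) && !is.numeric(sch[[cc]])) {
      v <- as.character(sch[[cc]])
      dates <- c(dates, v[!is.na(v) & nzchar(v)])
    }
  }
  if (length(dates) > 0) {
    origin <- min(as.Date(dates,
                          tryFormats = c("%m/%d/%Y", "%Y-%m-%d", "%m/%d/%y")),
                  na.rm = TRUE)
  }

  smp <- raw$metadata
  smp$day <- as_day(smp[[tcols$metadata]], origin)
  smp <- smp[, c("sample_id", "column_id", "day", "sample_type", "section",
                 "treatment", "temperature_c")]
  sul <- raw$sulfide
  sul$day <- as_day(sul[[tcols$sulfide]], origin)
  sul <- sul[, c("column_id", "day", "sulfide_mm")]
  cel <- raw$cells
  cel$day <- as_day(cel[[tcols$cells]], origin)
  if (!"outlier" %in% names(cel)) cel$outlier <- FALSE
  cel$outlier <- as.logical(cel$outlier)
  cel <- cel[, c("column_id", "day", "cells_per_ml", "outlier")]
  for (cc in c("nitrate_start", "nitrate_stop")) {
    if (!is.numeric(sch[[cc]])) {
      v <- as.character(sch[[cc]])
      v[!nzchar(v)] <- NA
      sch[[cc]] <- ifelse(is.na(v), NA_integer_, as_day(v, origin))
    } else {
      sch[[cc]] <- as.integer(round(sch[[cc]]))
    }
  }
  ann <- raw$annotations
  ann$is_srb <- as.logical(ann$is_srb)
  ann$has_dsr <- as.logical(ann$has_dsr)

  b <- experiment_bundle(count_table(mat, corrected = corrected),
                         ann, smp, sul, sch, cel)
  if (!quiet) {
    message(sprintf(
      "loaded bundle: %d samples, %d taxa, %d sulfide obs, %d schedules, %d cell counts",
      nrow(b$samples), ncol(b$counts$abund), nrow(b$sulfide),
      nrow(b$schedule), nrow(b$cells)))
  }
  b
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
}

#' Write an experiment bundle as the six canonical TSV files
#'
#' The inverse of [load_bundle()]: `load_bundle(write_bundle(b, dir))`
#' reproduces `b` field by field.
#'
#' @param bundle An [experiment_bundle].
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mat <- bundle$counts$abund
  con <- file(file.path(dir, "counts.tsv"), "w")
  writeLines(sprintf("# corrected=%s",
                     if (bundle$counts$corrected) "true" else "false"), con)
  cdf <- data.frame(sample_id = rownames(mat), mat,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(cdf, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  write_tsv(bundle$annotations, file.path(dir, "annotations.tsv"))
  smp <- bundle$samples
  names(smp)[names(smp) == "day"] <- "time_point"
  write_tsv(smp, file.path(dir, "metadata.tsv"))
  sul <- bundle$sulfide
  names(sul)[names(sul) == "day"] <- "time_point"
  write_tsv(sul, file.path(dir, "sulfide.tsv"))
  write_tsv(bundle$schedule, file.path(dir, "schedule.tsv"))
  cel <- bundle$cells
  names(cel)[names(cel) == "day"] <- "time_point"
  write_tsv(cel, file.path(dir, "cells.tsv"))
  invisible(dir)
}

# ---- packaged study-design bookkeeping --------------------------------------

#' Per-column design table of the 20-column bioreactor study
#'
#' Returns the packaged bookkeeping table: one row per column with its
#' treatment, operating temperature, sacrifice stage, harvest day and
#' per-column sample counts (674 effluent + 57 sessile = 731 samples in
#' total). Day offsets are counted from experiment start; nitrate
#' treatment begins on day 43.
#'
#' @return Data frame with one row per column.
#' @export
table1_design <- function() {
  path <- system.file("extdata", "table1_columns.tsv",
                      package = "soursentinel", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Expand the study-design table into per-sample metadata
#'
#' Generates the full 731-row sample metadata table implied by the design
#' bookkeeping: per column, its effluent samples on an evenly spaced day
#' grid ending at the column's sacrifice day, plus three sessile samples
#' (top/middle/bottom sections) at the harvest day for the 19 harvested
#' columns.
#'
#' @return Data frame in the bundle `samples` layout.
#' @export
table1_metadata <- function() {
  des <- table1_design()
  rows <- lapply(seq_len(nrow(des)), function(i) {
    d <- des[i, ]
    end_day <- if (is.na(d$harvest_day)) 148L else d$harvest_day
    days <- unique(as.integer(round(seq(0, end_day,
                                        length.out = d$n_effluent))))
    eff <- data.frame(
      sample_id = sprintf("%s_E%03d", d$column_id, seq_along(days)),
      column_id = d$column_id, day = days,
      sample_type = "effluent", section = "none",
      treatment = d$treatment, temperature_c = d$temperature_c,
      stringsAsFactors = FALSE)
    if (is.na(d$harvest_day)) return(eff)
    ses <- data.frame(
      sample_id = sprintf("%s_S_%s", d$column_id, c("top", "middle", "bottom")),
      column_id = d$column_id, day = d$harvest_day,
      sample_type = "sessile", section = c("top", "middle", "bottom"),
      treatment = d$treatment, temperature_c = d$temperature_c,
      stringsAsFactors = FALSE)
    rbind(eff, ses)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
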