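# Phase segmentation: sulfidogenesis (S), transition-to-mitigation (TM),
# mitigation (M), rebound sulfidogenesis (R) from sulfide series plus the
# nitrate treatment schedule.

phase_levels <- c("S", "TM", "M", "R")

# Core rule for one column. TM requires sulfide strictly above the
# threshold; once M is entered it is not revoked by a later blip above the
# threshold before nitrate_stop (the transition windows are contiguous).
phase_rule <- function(days, sulfide, nitrate_start, nitrate_stop,
                       threshold = 1) {
  n <- length(days)
  if (is.na(nitrate_start)) return(rep("S", n))
  phase <- character(n)
  in_m <- FALSE
  for (k in seq_len(n)) {
    t <- days[k]
    if (t < nitrate_start) {
      phase[k] <- "S"
    } else if (!is.na(nitrate_stop) && t >= nitrate_stop) {
      phase[k] <- "R"
    } else if (in_m) {
      phase[k] <- "M"
    } else if (sulfide[k] > threshold) {
      phase[k] <- "TM"
    } else {
      in_m <- TRUE
      phase[k] <- "M"
    }
  }
  phase
}

#' Assign S/TM/M/R phases to column time points
#'
#' Applies the treatment-window rule per column: time points before
#' `nitrate_start` are sulfidogenesis (S); from `nitrate_start`, points
#' remain transition-to-mitigation (TM) while sulfide is strictly above
#' `threshold_mm`; the first treated point at or below the threshold
#' enters mitigation (M), which persists (regardless of later sulfide
#' blips) until `nitrate_stop`; points from `nitrate_stop` on are rebound
#' (R). Columns with a null schedule (nontreated) are S throughout.
#'
#' Sulfide missing at a requested time point is carried forward from the
#' last observation; a requested point before the first observation is an
#' error.
#'
#' @param sulfide Data frame `column_id`, `day`, `sulfide_mm`.
#' @param schedule Data frame `column_id`, `nitrate_start`, `nitrate_stop`.
#' @param threshold_mm Sulfide threshold in mM separating TM from M
#'   (default 1, the ">1 mM" transition criterion). May be a single value
#'   or a named vector keyed by column id for per-column thresholds.
#' @param times Optional data frame `column_id`, `day` of time points to
#'   label; defaults to the sulfide observation times.
#' @return Data frame `column_id`, `day`, `phase` (factor S/TM/M/R).
#' @export
assign_phases <- function(sulfide, schedule, threshold_mm = 1, times = NULL) {
  stopifnot_columns(sulfide, c("column_id", "day", "sulfide_mm"), "sulfide")
  stopifnot_columns(schedule, c("column_id", "nitrate_start", "nitrate_stop"),
                    "schedule")
  cols <- unique(sulfide$column_id)
  missing_sched <- setdiff(cols, schedule$column_id)
  if (length(missing_sched) > 0) {
    validation_error("column '%s' has sulfide data but no schedule row",
                     missing_sched[1])
  }
  out <- lapply(cols, function(cid) {
    s <- sulfide[sulfide$column_id == cid, ]
    s <- s[order(s$day), ]
    sch <- schedule[schedule$column_id == cid, ][1, ]
    tt <- if (is.null(times)) s$day else
      sort(unique(times$day[times$column_id == cid]))
    if (length(tt) == 0) return(NULL)
    if (min(tt) < min(s$day)) {
      validation_error(
        "column '%s': time point %s precedes the first sulfide observation",
        cid, min(tt))
    }
    # last-observation-carried-forward interpolation onto the target grid
    smm <- stats::approx(s$day, s$sulfide_mm, xout = tt,
                         method = "constant", f = 0, rule = 2)$y
    thr <- if (!is.null(names(threshold_mm)) && cid %in% names(threshold_mm)) {
      threshold_mm[[cid]]
    } else {
      threshold_mm[[1]]
    }
    data.frame(column_id = cid, day = as.integer(tt),
               phase = phase_rule(tt, smm, sch$nitrate_start,
                                  sch$nitrate_stop, thr),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res$phase <- factor(res$phase, levels = phase_levels)
  rownames(res) <- NULL
  res
}
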