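# Synthetic bioreactor experiment generator. Emulates the 20-column,
# 148-day nitrate-mitigation study design with known ground truth: a
# sulfide phase structure (S -> TM -> M -> R), a biofilm-dispersal pulse of
# a specific SRB population (SSP) injected into the effluent 2-4 days
# after nitrate initiation, multinomial read sampling at realistic depth,
# and noisy flow-cytometry cell counts with occasional outliers.

srb_genome_pool <- c(
  "Desulfobacula toluolica Tol2",
  "Desulfarculus baarsii DSM 2075",
  "Desulfococcus multivorans",
  "Desulfovibrio vulgaris Hildenborough",
  "Desulfotignum balticum DSM 7044",
  "Desulfobacterium autotrophicum HRM2",
  "Desulfotalea psychrophila LSv54",
  "Desulfomicrobium baculatum DSM 4028")

#' Generator configuration
#'
#' Defaults reproduce the emulated study design: 20 columns (10 treated),
#' 148-day timeline, nitrate treatment from day 43 to day 115, an SSP
#' dispersal pulse 2 and 4 days after nitrate initiation, mean sequencing
#' depth 40,709 reads (SD 10,527), and 19 of 20 columns sacrificed for
#' sessile sampling (3 sections each, 57 sessile samples).
#'
#' @param n_columns Number of bioreactor columns.
#' @param n_treated Number of nitrate-treated columns (`<= n_columns`).
#' @param duration_days Experiment length in days.
#' @param sampling_interval_days Base effluent sampling interval; the
#'   nitrate start day and the dispersal days are always added to the grid.
#' @param nitrate_start_day,nitrate_stop_day Treatment window (treated
#'   columns only); `nitrate_stop_day = NA` means treatment never stops.
#' @param nitrate_mm Nitrate dose recorded in the schedule (mM).
#' @param n_background_taxa,n_srb_taxa Number of non-SRB background genomes
#'   and of SRB genomes (max 8 SRB genome labels are built in).
#' @param ssp_dispersal_day_offsets Day offsets after `nitrate_start_day` at
#'   which the sessile community is mixed into the effluent.
#' @param dispersal_fold Multiplier on the SSP's TM-baseline planktonic
#'   fraction at dispersal days; `1` disables injection (negative control).
#' @param mean_depth,sd_depth,min_depth Per-sample read depth: normal,
#'   truncated at `min_depth`, rounded.
#' @param sulfide_params List with `plateau_mm`, `rise_rate` (1/day),
#'   `decay_lag_days` (lag between nitrate start and sulfide decay),
#'   `decay_rate` (1/day), `rebound_rate` (1/day), `noise_sd_mm`.
#' @param srb_effluent_total Summed latent effluent fraction of all SRB
#'   genomes during sulfidogenesis.
#' @param sessile_ssp_frac Latent fraction of the SSP in the sessile
#'   community (free parameter; sessile composition is not quantified in
#'   the emulated study).
#' @param sessile_srb_other Summed sessile fraction of the non-SSP SRBs.
#' @param comp_jitter_sdlog Per-(taxon, day) lognormal jitter on latent
#'   compositions (overdispersion beyond multinomial noise).
#' @param nrb_bloom_fold Growth multiplier of the nitrate-reducing bloom
#'   genome during the M phase of treated columns.
#' @param cell_count_mean_log,cell_count_sd_log Lognormal (natural-log
#'   scale) parameters of total cell counts (cells/ml).
#' @param outlier_rate Probability that a cell count is replaced by an
#'   extreme value (`outlier_fold` times the drawn value).
#' @param outlier_fold Multiplier defining an outlying cell count.
#' @param harvest_scheme `"study"` sacrifices all but the last column at
#'   one of four harvest days as in the emulated design; `"none"` keeps
#'   every column running for the full duration with no sessile samples.
#' @param seed Integer master seed; per-column substreams are derived from
#'   it so columns are independently reproducible.
#' @return Object of class `generator_config`.
#' @export
generator_config <- function(n_columns = 20L,
                             n_treated = 10L,
                             duration_days = 148L,
                             sampling_interval_days = 3L,
                             nitrate_start_day = 43L,
                             nitrate_stop_day = 115L,
                             nitrate_mm = 3.3,
                             n_background_taxa = 40L,
                             n_srb_taxa = 5L,
                             ssp_dispersal_day_offsets = c(2L, 4L),
                             dispersal_fold = 8,
                             mean_depth = 40709,
                             sd_depth = 10527,
                             min_depth = 1000,
                             sulfide_params = list(plateau_mm = 4,
                                                   rise_rate = 0.1,
                                                   decay_lag_days = 6,
                                                   decay_rate = 0.6,
                                                   rebound_rate = 0.08,
                                                   noise_sd_mm = 0.05),
                             srb_effluent_total = 0.03,
                             sessile_ssp_frac = 0.45,
                             sessile_srb_other = 0.10,
                             comp_jitter_sdlog = 0.3,
                             nrb_bloom_fold = 5,
                             cell_count_mean_log = log(1e7),
                             cell_count_sd_log = 0.4,
                             outlier_rate = 0.02,
                             outlier_fold = 100,
                             harvest_scheme = c("study", "none"),
                             seed = 1L) {
  cfg <- list(n_columns = as.integer(n_columns),
              n_treated = as.integer(n_treated),
              duration_days = as.integer(duration_days),
              sampling_interval_days = as.integer(sampling_interval_days),
              nitrate_start_day = as.integer(nitrate_start_day),
              nitrate_stop_day = if (is.na(nitrate_stop_day)) NA_integer_ else as.integer(nitrate_stop_day),
              nitrate_mm = nitrate_mm,
              n_background_taxa = as.integer(n_background_taxa),
              n_srb_taxa = as.integer(n_srb_taxa),
              ssp_dispersal_day_offsets = as.integer(ssp_dispersal_day_offsets),
              dispersal_fold = dispersal_fold,
              mean_depth = mean_depth, sd_depth = sd_depth,
              min_depth = min_depth,
              sulfide_params = sulfide_params,
              srb_effluent_total = srb_effluent_total,
              sessile_ssp_frac = sessile_ssp_frac,
              sessile_srb_other = sessile_srb_other,
              comp_jitter_sdlog = comp_jitter_sdlog,
              nrb_bloom_fold = nrb_bloom_fold,
              cell_count_mean_log = cell_count_mean_log,
              cell_count_sd_log = cell_count_sd_log,
              outlier_rate = outlier_rate,
              outlier_fold = outlier_fold,
              harvest_scheme = match.arg(harvest_scheme),
              seed = as.integer(seed))
  class(cfg) <- "generator_config"
  validate_generator_config(cfg)
  cfg
}

#' Validate a generator configuration
#'
#' Collects every violated constraint and raises a single config error
#' listing all of them.
#'
#' @param config A `generator_config` (or plain list with the same fields).
#' @return The config, invisibly.
#' @export
validate_generator_config <- function(config) {
  v <- character(0)
  chk <- function(ok, msg) if (!isTRUE(ok)) v <<- c(v, msg)
  chk(config$n_columns >= 1, "n_columns must be >= 1")
  chk(config$n_treated >= 0 && config$n_treated <= config$n_columns,
      "n_treated must be in [0, n_columns]")
  chk(config$duration_days >= 1, "duration_days must be >= 1")
  chk(config$sampling_interval_days >= 1, "sampling_interval_days must be >= 1")
  chk(config$nitrate_start_day >= 0 &&
        config$nitrate_start_day <= config$duration_days,
      "nitrate_start_day must lie within the experiment")
  chk(is.na(config$nitrate_stop_day) ||
        config$nitrate_stop_day > config$nitrate_start_day,
      "nitrate_stop_day must follow nitrate_start_day")
  chk(config$n_background_taxa >= 2, "n_background_taxa must be >= 2")
  chk(config$n_srb_taxa >= 1 && config$n_srb_taxa <= length(srb_genome_pool),
      sprintf("n_srb_taxa must be in [1, %d]", length(srb_genome_pool)))
  chk(config$dispersal_fold >= 1, "dispersal_fold must be >= 1")
  chk(config$mean_depth > 0 && config$sd_depth >= 0,
      "mean_depth must be > 0 and sd_depth >= 0")
  chk(config$outlier_rate >= 0 && config$outlier_rate <= 1,
      "outlier_rate must be a probability in [0, 1]")
  chk(config$srb_effluent_total > 0 && config$srb_effluent_total < 1,
      "srb_effluent_total must be in (0, 1)")
  chk(config$sessile_ssp_frac > 0 && config$sessile_srb_other >= 0 &&
        config$sessile_ssp_frac + config$sessile_srb_other < 1,
      "sessile SRB fractions must leave room for the background community")
  chk(config$comp_jitter_sdlog >= 0, "comp_jitter_sdlog must be >= 0")
  if (length(v) > 0) {
    config_error("invalid generator config:\n  - %s",
                 paste(v, collapse = "\n  - "))
  }
  invisible(config)
}

#' Influent concentration after in-line dilution
#'
#' Concentration of a stock solution after mixing with a diluent stream:
#' `stock_mm * stock_rate / (stock_rate + diluent_rate)`. In the emulated
#' design, 33 mM volatile fatty acids fed at 100 ul/h into 1 ml/h seawater
#' give a 3 mM column influent.
#'
#' @param stock_mm Stock concentration (mM).
#' @param stock_rate,diluent_rate Flow rates in the same volume/time unit.
#' @return Influent concentration in mM.
#' @export
influent_concentration <- function(stock_mm, stock_rate, diluent_rate) {
  if (stock_rate < 0 || diluent_rate < 0) {
    domain_error("flow rates must be non-negative")
  }
  if (stock_rate + diluent_rate == 0) {
    domain_error("at least one flow rate must be positive")
  }
  stock_mm * stock_rate / (stock_rate + diluent_rate)
}

# Noise-free sulfide trajectory (mM). Shared by the generator and by the
# ground-truth phase boundaries.
sulfide_latent <- function(times, params, treated,
                           nitrate_start = NA, nitrate_stop = NA) {
  s <- params$plateau_mm * (1 - exp(-params$rise_rate * times))
  if (treated && !is.na(nitrate_start)) {
    t0 <- nitrate_start + params$decay_lag_days
    dec <- times >= t0
    s[dec] <- s[dec] * exp(-params$decay_rate * (times[dec] - t0))
    if (!is.na(nitrate_stop)) {
      reb <- times >= nitrate_stop
      s[reb] <- s[reb] +
        params$plateau_mm * (1 - exp(-params$rebound_rate *
                                       (times[reb] - nitrate_stop)))
    }
  }
  s
}

#' Simulate a sulfide concentration series
#'
#' Nontreated columns rise monotonically to a plateau (plus measurement
#' noise). Treated columns rise, decay after `nitrate_start` with a
#' configurable lag (so a transition-to-mitigation window with sulfide
#' above 1 mM exists), and rebound after `nitrate_stop`; with
#' `nitrate_stop = NA` the series stays suppressed after the decay.
#'
#' @param config A [generator_config()].
#' @param treatment `"treated"` or `"nontreated"`.
#' @param times Sorted day offsets.
#' @param nitrate_start,nitrate_stop Treatment window; default from config.
#' @param noise_sd_mm Measurement noise SD; default from config.
#' @return Data frame with columns `day` and `sulfide_mm` (all values >= 0).
#' @export
sulfide_curve <- function(config, treatment = c("treated", "nontreated"),
                          times,
                          nitrate_start = config$nitrate_start_day,
                          nitrate_stop = config$nitrate_stop_day,
                          noise_sd_mm = config$sulfide_params$noise_sd_mm) {
  treatment <- match.arg(treatment)
  if (is.unsorted(times)) validation_error("times must be sorted")
  s <- sulfide_latent(times, config$sulfide_params,
                      treated = treatment == "treated",
                      nitrate_start = nitrate_start,
                      nitrate_stop = nitrate_stop)
  if (noise_sd_mm > 0) s <- s + stats::rnorm(length(s), 0, noise_sd_mm)
  data.frame(day = as.integer(times), sulfide_mm = pmax(s, 0))
}

#' Multinomial read sampling
#'
#' Draws a read-count vector from a taxon composition at a fixed total
#' depth, modeling amplicon sequencing of one sample.
#'
#' @param composition Probability vector summing to 1 (+- 1e-9).
#' @param depth Total reads (non-negative integer).
#' @param seed Optional seed for a reproducible isolated draw.
#' @return Integer count vector with `sum == depth`, named like
#'   `composition`.
#' @export
sample_reads <- function(composition, depth, seed = NULL) {
  if (any(composition < 0)) domain_error("composition has negative entries")
  if (abs(sum(composition) - 1) > 1e-9) {
    domain_error("composition must sum to 1 (got %.12f)", sum(composition))
  }
  if (depth < 0) domain_error("depth must be >= 0")
  draw <- function() as.vector(stats::rmultinom(1, size = depth,
                                                prob = composition))
  counts <- if (is.null(seed)) draw() else with_seed(seed, draw())
  names(counts) <- names(composition)
  counts
}

# Column layout (treatment, temperature, harvest day). The default
# 20-column configuration reuses the packaged study design; other sizes
# fall back to a generic layout with the same shape.
generator_design <- function(config) {
  if (config$harvest_scheme == "study" && config$n_columns == 20 &&
      config$n_treated == 10) {
    des <- table1_design()
    return(data.frame(column_id = des$column_id,
                      treatment = des$treatment,
                      temperature_c = des$temperature_c,
                      harvest_day = des$harvest_day,
                      stringsAsFactors = FALSE))
  }
  ids <- sprintf("C%02d", seq_len(config$n_columns))
  treatment <- rep("nontreated", config$n_columns)
  if (config$n_treated > 0) treatment[seq_len(config$n_treated)] <- "treated"
  harvest <- rep(NA_integer_, config$n_columns)
  if (config$harvest_scheme == "study" && config$n_columns > 1) {
    hdays <- unique(pmin(config$duration_days,
                         round(config$duration_days * c(0.46, 0.49, 0.76, 1))))
    idx <- seq_len(config$n_columns - 1)   # last column is never harvested
    harvest[idx] <- hdays[((idx - 1) %% length(hdays)) + 1]
  }
  data.frame(column_id = ids, treatment = treatment, temperature_c = 30,
             harvest_day = harvest, stringsAsFactors = FALSE)
}

#' Generate a complete synthetic experiment with ground truth
#'
#' Builds an [experiment_bundle] (counts, annotations, metadata, sulfide,
#' schedule, cell counts) plus a `synthetic_truth` object recording, per
#' treated column, the true SSP genome, the injected dispersal days, the
#' noise-free phase boundaries, and the latent planktonic and sessile
#' composition trajectories.
#'
#' Latent compositions are cell fractions; read probabilities are weighted
#' by 16S copy number, so copy-number correction of the resulting counts
#' recovers the latent fractions. At each dispersal day of a treated
#' column the sessile composition is mixed into the effluent with a weight
#' chosen so that the SSP's latent planktonic fraction equals
#' `dispersal_fold` times its (pre-injection) TM-phase mean fraction;
#' `dispersal_fold = 1` disables the injection entirely.
#'
#' @param config A [generator_config()].
#' @return List with elements `bundle` ([experiment_bundle]) and `truth`
#'   (`synthetic_truth`).
#' @export
generate_experiment <- function(config = generator_config()) {
  validate_generator_config(config)
  set.seed(config$seed)
  des <- generator_design(config)
  nb <- config$n_background_taxa
  ns <- config$n_srb_taxa
  sp <- config$sulfide_params

  # ---- taxa and annotations
  bg_genomes <- c("Thauera sp. NRB-1",
                  sprintf("Bacterium sp. SYN-%02d", seq_len(nb - 1)))
  srb_genomes <- srb_genome_pool[seq_len(ns)]
  genomes <- c(bg_genomes, srb_genomes)
  is_srb_genome <- c(rep(FALSE, nb), rep(TRUE, ns))
  # background genomes: one sequence variant each; SRB genomes: two each
  ann <- data.frame(
    taxon_id = c(sprintf("ASV_B%03d", seq_len(nb)),
                 sprintf("ASV_S%03d", seq_len(2 * ns))),
    genome_label = c(bg_genomes, rep(srb_genomes, each = 2)),
    is_srb = c(rep(FALSE, nb), rep(TRUE, 2 * ns)),
    copy_number = c(sample(1:7, nb, replace = TRUE),
                    sample(1:4, 2 * ns, replace = TRUE)),
    has_dsr = c(rep(FALSE, nb), rep(TRUE, 2 * ns)),
    stringsAsFactors = FALSE)
  # within-genome split of each SRB genome over its two variants
  srb_split <- stats::runif(ns, 0.3, 0.7)
  # map genome-level composition -> taxon-level composition
  genome_of_taxon <- match(ann$genome_label, genomes)
  taxon_share <- rep(1, nrow(ann))
  for (j in seq_len(ns)) {
    idx <- which(ann$genome_label == srb_genomes[j])
    taxon_share[idx] <- c(srb_split[j], 1 - srb_split[j])
  }

  col_seeds <- sample.int(1e8, config$n_columns)
  start <- config$nitrate_start_day
  stop_ <- config$nitrate_stop_day
  disp_days <- start + config$ssp_dispersal_day_offsets
  base_grid <- sort(unique(c(seq(0, config$duration_days,
                                 by = config$sampling_interval_days),
                             start, disp_days)))
  base_grid <- base_grid[base_grid <= config$duration_days]

  samples <- list(); counts <- list(); sulfide <- list(); cells <- list()
  schedule <- list(); truth_cols <- list(); truth_disp <- list()
  truth_bounds <- list(); latent_eff <- list(); latent_ses <- list()

  for (i in seq_len(config$n_columns)) {
    set.seed(col_seeds[i])
    cid <- des$column_id[i]
    treated <- des$treatment[i] == "treated"
    end_day <- if (is.na(des$harvest_day[i])) config$duration_days else des$harvest_day[i]
    days <- base_grid[base_grid <= end_day]

    # base latent effluent composition (genome level)
    bg_w <- stats::rgamma(nb, shape = 0.8)
    srb_w <- stats::rgamma(ns, shape = 1)
    base <- c(bg_w / sum(bg_w) * (1 - config$srb_effluent_total),
              srb_w / sum(srb_w) * config$srb_effluent_total)
    ssp_idx <- nb + which.max(srb_w)

    # sessile composition: SSP-dominated SRB community over a jittered
    # version of the same background
    bg_s <- bg_w * stats::rlnorm(nb, 0, 0.5)
    other <- setdiff(nb + seq_len(ns), ssp_idx)
    sess <- numeric(nb + ns)
    sess[seq_len(nb)] <- bg_s / sum(bg_s) *
      (1 - config$sessile_ssp_frac - config$sessile_srb_other)
    sess[ssp_idx] <- config$sessile_ssp_frac
    if (length(other) > 0) {
      w_o <- srb_w[other - nb]
      sess[other] <- w_o / sum(w_o) * config$sessile_srb_other
    }

    # true phases from the noise-free sulfide trajectory
    lat_sulf <- sulfide_latent(days, sp, treated, start,
                               if (treated) stop_ else NA)
    phase <- phase_rule(days, lat_sulf,
                        if (treated) start else NA,
                        if (treated) stop_ else NA, threshold = 1)
    tm_days <- days[phase == "TM"]

    # phase multipliers: SRB suppression + NRB bloom under nitrate
    mult <- matrix(1, nrow = length(days), ncol = nb + ns)
    if (treated) {
      srb_cols <- nb + seq_len(ns)
      mult[phase == "TM", 1] <- 1.5
      mult[phase == "M", 1] <- config$nrb_bloom_fold
      mult[phase == "M", srb_cols] <- 0.15
      mult[phase == "R", 1] <- 2
      mult[phase == "R", srb_cols] <- 0.8
    }
    w <- sweep(mult, 2, base, "*") *
      matrix(stats::rlnorm(length(days) * (nb + ns), 0,
                           config$comp_jitter_sdlog),
             nrow = length(days))
    comp <- w / rowSums(w)
    dimnames(comp) <- list(days, genomes)

    # dispersal injection: mix sessile community into the effluent at the
    # dispersal days so the SSP hits dispersal_fold x its TM baseline
    col_disp <- integer(0)
    tm_baseline <- NA_real_
    target <- NA_real_
    if (treated && length(tm_days) > 0) {
      tm_baseline <- mean(comp[as.character(tm_days), ssp_idx])
      if (config$dispersal_fold > 1) {
        col_disp <- intersect(disp_days, tm_days)
        target <- config$dispersal_fold * tm_baseline
        for (d in col_disp) {
          x <- comp[as.character(d), ]
          if (sess[ssp_idx] <= target) {
            warning(sprintf(
              "column %s: dispersal target %.3f exceeds sessile SSP fraction %.3f; capping",
              cid, target, sess[ssp_idx]))
            wd <- 0.95
          } else {
            wd <- (target - x[ssp_idx]) / (sess[ssp_idx] - x[ssp_idx])
            wd <- min(max(wd, 0), 0.95)
          }
          comp[as.character(d), ] <- (1 - wd) * x + wd * sess
        }
      }
    }

    # effluent counts: copy-number weighted multinomial reads
    depth <- pmax(config$min_depth,
                  round(stats::rnorm(length(days), config$mean_depth,
                                     config$sd_depth)))
    eff_ids <- sprintf("%s_E%03d", cid, seq_along(days))
    cmat <- matrix(0L, nrow = length(days), ncol = nrow(ann),
                   dimnames = list(eff_ids, ann$taxon_id))
    for (k in seq_along(days)) {
      taxon_comp <- comp[k, genome_of_taxon] * taxon_share
      prob <- taxon_comp * ann$copy_number
      cmat[k, ] <- sample_reads(prob / sum(prob), depth[k])
    }

    smp <- data.frame(sample_id = eff_ids, column_id = cid,
                      day = as.integer(days), sample_type = "effluent",
                      section = "none", treatment = des$treatment[i],
                      temperature_c = des$temperature_c[i],
                      stringsAsFactors = FALSE)

    # sessile samples at the harvest day (three sections)
    ses_mat <- NULL
    if (!is.na(des$harvest_day[i])) {
      secs <- c("top", "middle", "bottom")
      ses_ids <- sprintf("%s_S_%s", cid, secs)
      ses_mat <- matrix(0L, nrow = 3, ncol = nrow(ann),
                        dimnames = list(ses_ids, ann$taxon_id))
      sdepth <- pmax(config$min_depth,
                     round(stats::rnorm(3, config$mean_depth,
                                        config$sd_depth)))
      for (k in 1:3) {
        g <- sess * stats::rlnorm(nb + ns, 0, 0.2)
        g <- g / sum(g)
        taxon_comp <- g[genome_of_taxon] * taxon_share
        prob <- taxon_comp * ann$copy_number
        ses_mat[k, ] <- sample_reads(prob / sum(prob), sdepth[k])
      }
      smp <- rbind(smp, data.frame(
        sample_id = ses_ids, column_id = cid,
        day = as.integer(des$harvest_day[i]), sample_type = "sessile",
        section = secs, treatment = des$treatment[i],
        temperature_c = des$temperature_c[i], stringsAsFactors = FALSE))
    }

    sul <- sulfide_curve(config, if (treated) "treated" else "nontreated",
                         days,
                         nitrate_start = if (treated) start else NA,
                         nitrate_stop = if (treated) stop_ else NA)
    sul <- data.frame(column_id = cid, sul, stringsAsFactors = FALSE)

    cc <- exp(stats::rnorm(length(days), config$cell_count_mean_log,
                           config$cell_count_sd_log))
    is_out <- stats::runif(length(days)) < config$outlier_rate
    cc[is_out] <- cc[is_out] * config$outlier_fold
    cel <- data.frame(column_id = cid, day = as.integer(days),
                      cells_per_ml = cc, outlier = FALSE,
                      stringsAsFactors = FALSE)

    schedule[[i]] <- data.frame(
      column_id = cid,
      nitrate_start = if (treated) start else NA_integer_,
      nitrate_stop = if (treated) stop_ else NA_integer_,
      nitrate_mm = if (treated) config$nitrate_mm else NA_real_,
      stringsAsFactors = FALSE)

    samples[[i]] <- smp
    counts[[i]] <- rbind(cmat, ses_mat)
    sulfide[[i]] <- sul
    cells[[i]] <- cel

    ph_runs <- unique(phase)
    truth_bounds[[i]] <- data.frame(
      column_id = cid, phase = ph_runs,
      start_day = vapply(ph_runs, function(p) min(days[phase == p]), 0),
      end_day = vapply(ph_runs, function(p) max(days[phase == p]), 0),
      stringsAsFactors = FALSE)
    truth_cols[[i]] <- data.frame(
      column_id = cid, treatment = des$treatment[i],
      true_ssp_genome = if (treated) genomes[ssp_idx] else NA_character_,
      baseline_tm_fraction = tm_baseline,
      target_fraction = target,
      end_day = as.integer(end_day),
      harvest_day = des$harvest_day[i],
      stringsAsFactors = FALSE)
    truth_disp[[cid]] <- as.integer(col_disp)
    latent_eff[[cid]] <- comp
    latent_ses[[cid]] <- stats::setNames(sess, genomes)
  }

  bundle <- experiment_bundle(
    count_table(do.call(rbind, counts), corrected = FALSE),
    ann,
    do.call(rbind, samples),
    do.call(rbind, sulfide),
    do.call(rbind, schedule),
    do.call(rbind, cells))
  truth <- structure(list(
    columns = do.call(rbind, truth_cols),
    dispersal_days = truth_disp,
    phase_boundaries = do.call(rbind, truth_bounds),
    latent = list(effluent = latent_eff, sessile = latent_ses),
    config = config), class = "synthetic_truth")
  list(bundle = bundle, truth = truth)
}

#' @export
print.synthetic_truth <- function(x, ...) {
  tr <- x$columns[x$columns$treatment == "treated", ]
  cat(sprintf("<synthetic_truth> %d columns (%d treated)\n",
              nrow(x$columns), nrow(tr)))
  if (nrow(tr) > 0) {
    cat(sprintf("  dispersal days: %s\n",
                paste(unique(unlist(x$dispersal_days)), collapse = ", ")))
  }
  invisible(x)
}
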