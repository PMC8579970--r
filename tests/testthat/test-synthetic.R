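test_that("influent dilution arithmetic matches the bench setup", {
  # 33 mM stock at 100 ul/h into 1 ml/h (= 1000 ul/h) diluent -> 3 mM
  expect_equal(influent_concentration(33, 100, 1000), 3.0)
  expect_equal(influent_concentration(5, 0, 2), 0)
  expect_equal(influent_concentration(10, 7, 7), 5)
  expect_error(influent_concentration(10, 0, 0),
               class = "soursentinel_domain_error")
  expect_error(influent_concentration(10, -1, 1),
               class = "soursentinel_domain_error")
})

test_that("sulfide curves produce the intended phase structure", {
  cfg <- generator_config()
  days <- seq(0, 148, by = 1)

  # treated: the decay lag leaves >= 2 post-treatment points above 1 mM
  s <- sulfide_curve(cfg, "treated", days, noise_sd_mm = 0)
  post <- s$sulfide_mm[s$day >= cfg$nitrate_start_day &
                         s$day < cfg$nitrate_stop_day]
  expect_gte(sum(post > 1), 2)
  # ... and sulfide is eventually suppressed below threshold before rebound
  expect_lt(min(post), 1)
  # rebound after nitrate stop
  expect_gt(s$sulfide_mm[s$day == 148], 1)

  # noise-free nontreated series is non-decreasing
  s0 <- sulfide_curve(cfg, "nontreated", days, noise_sd_mm = 0)
  expect_true(all(diff(s0$sulfide_mm) >= 0))

  # treated with no nitrate stop: stays suppressed after the decay
  s2 <- sulfide_curve(cfg, "treated", days, nitrate_stop = NA,
                      noise_sd_mm = 0)
  tail_vals <- s2$sulfide_mm[s2$day >= 80]
  expect_true(all(tail_vals <= 1))

  expect_true(all(sulfide_curve(cfg, "treated", days)$sulfide_mm >= 0))
  expect_error(sulfide_curve(cfg, "treated", c(3, 1)),
               class = "soursentinel_validation_error")
})

test_that("multinomial read sampling is exact at the edges and reproducible", {
  expect_equal(sample_reads(c(a = 1), 100), c(a = 100))
  expect_equal(unname(sample_reads(c(0.3, 0.7), 0)), c(0, 0))
  expect_error(sample_reads(c(0.5, 0.6), 10),
               class = "soursentinel_domain_error")
  expect_error(sample_reads(c(-0.1, 1.1), 10),
               class = "soursentinel_domain_error")
  expect_identical(sample_reads(c(0.2, 0.8), 1000, seed = 9),
                   sample_reads(c(0.2, 0.8), 1000, seed = 9))
  x <- sample_reads(rep(0.25, 4), 1234, seed = 1)
  expect_equal(sum(x), 1234)
})

test_that("deep draws concentrate near the composition (binomial tail)", {
  # P(|p_hat - 0.5| > 0.002) at depth 1e6 is ~6e-5, so >= 19/20 seeds
  # must land inside [0.498, 0.502]
  frac <- vapply(1:20, function(s) {
    sample_reads(c(0.5, 0.5), 1e6, seed = s)[1] / 1e6
  }, 0)
  expect_gte(sum(frac >= 0.498 & frac <= 0.502), 19)
})

test_that("generation is deterministic and matches the study layout", {
  cfg <- generator_config(seed = 21)
  r1 <- generate_experiment(cfg)
  r2 <- generate_experiment(cfg)
  expect_identical(r1$bundle$counts$abund, r2$bundle$counts$abund)
  expect_identical(r1$bundle$cells, r2$bundle$cells)
  expect_identical(r1$truth$latent$effluent, r2$truth$latent$effluent)

  b <- r1$bundle
  cols <- unique(b$samples[, c("column_id", "treatment")])
  expect_equal(sum(cols$treatment == "treated"), 10)
  expect_equal(nrow(cols), 20)
  expect_equal(sum(b$samples$sample_type == "sessile"), 57)
  expect_silent(validate_bundle(b))
})

test_that("realized read depth is consistent with the configured depth model", {
  b <- generate_experiment(generator_config(seed = 5))$bundle
  depth <- rowSums(b$counts$abund)
  se <- generator_config()$sd_depth / sqrt(length(depth))
  expect_lt(abs(mean(depth) - 40709), 2 * se)
})

test_that("latent compositions are simplex trajectories with the promised dispersal signal", {
  res <- generate_experiment(generator_config(seed = 13))
  tr <- res$truth
  for (cid in names(tr$latent$effluent)) {
    comp <- tr$latent$effluent[[cid]]
    expect_true(all(abs(rowSums(comp) - 1) < 1e-9))
  }
  trt <- tr$columns[tr$columns$treatment == "treated", ]
  for (i in seq_len(nrow(trt))) {
    cid <- trt$column_id[i]
    comp <- tr$latent$effluent[[cid]]
    ssp <- trt$true_ssp_genome[i]
    disp <- tr$dispersal_days[[cid]]
    expect_gt(length(disp), 0)
    # injected fraction equals dispersal_fold x pre-injection TM baseline
    expect_equal(unname(comp[as.character(disp), ssp]),
                 rep(trt$target_fraction[i], length(disp)),
                 tolerance = 1e-9)
    # and strictly exceeds the (post-injection) TM-phase mean
    pb <- tr$phase_boundaries
    tmb <- pb[pb$column_id == cid & pb$phase == "TM", ]
    tm_days <- intersect(as.integer(rownames(comp)),
                         seq(tmb$start_day, tmb$end_day))
    tm_mean <- mean(comp[as.character(tm_days), ssp])
    expect_true(all(comp[as.character(disp), ssp] > tm_mean))
  }
})

test_that("dispersal_fold = 1 is a clean negative control", {
  res <- generate_experiment(generator_config(seed = 13, dispersal_fold = 1))
  expect_true(all(lengths(res$truth$dispersal_days) == 0))
  # no column carries an injected spike at the would-be dispersal days
  cfg <- res$truth$config
  disp <- cfg$nitrate_start_day + cfg$ssp_dispersal_day_offsets
  trt <- res$truth$columns[res$truth$columns$treatment == "treated", ]
  for (i in seq_len(nrow(trt))) {
    comp <- res$truth$latent$effluent[[trt$column_id[i]]]
    ssp <- trt$true_ssp_genome[i]
    expect_lt(max(comp[as.character(disp), ssp]),
              5 * trt$baseline_tm_fraction[i])
  }
})

test_that("invalid generator configs report every violation at once", {
  err <- tryCatch(generator_config(n_treated = 30, dispersal_fold = 0.5,
                                   outlier_rate = 2),
                  error = function(e) e)
  expect_s3_class(err, "soursentinel_config_error")
  expect_match(conditionMessage(err), "n_treated")
  expect_match(conditionMessage(err), "dispersal_fold")
  expect_match(conditionMessage(err), "outlier_rate")
})
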