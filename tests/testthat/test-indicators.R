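mk_ct <- function(m, corrected = FALSE) {
  if (is.null(dimnames(m))) {
    dimnames(m) <- list(sprintf("s%d", seq_len(nrow(m))),
                        sprintf("t%d", seq_len(ncol(m))))
  }
  count_table(m, corrected = corrected)
}

test_that("copy-number correction divides by copies, once and only once", {
  ct <- mk_ct(matrix(c(10, 9), 1))
  ann <- data.frame(taxon_id = c("t1", "t2"), copy_number = c(2, 3))
  cc <- correct_copy_number(ct, ann)
  expect_equal(unname(cc$abund[1, ]), c(5, 3))
  expect_true(cc$corrected)
  expect_error(correct_copy_number(cc, ann),
               class = "soursentinel_validation_error")

  ann1 <- data.frame(taxon_id = c("t1", "t2"), copy_number = c(1, 1))
  expect_equal(correct_copy_number(ct, ann1)$abund, ct$abund)

  expect_error(correct_copy_number(ct, ann[1, , drop = FALSE]),
               class = "soursentinel_validation_error")

  # inverse check on a random table
  set.seed(1)
  m <- matrix(rpois(60, 20), 6, dimnames = list(letters[1:6], LETTERS[1:10]))
  annr <- data.frame(taxon_id = LETTERS[1:10],
                     copy_number = sample(1:7, 10, TRUE))
  cc2 <- correct_copy_number(count_table(m), annr)
  back <- sweep(cc2$abund, 2, annr$copy_number, "*")
  expect_lt(max(abs(back - m)), 1e-12)
})

test_that("genome aggregation sums member variants and conserves sample totals", {
  ct <- mk_ct(matrix(c(3, 4, 5), 1), corrected = TRUE)
  ann <- data.frame(taxon_id = c("t1", "t2", "t3"),
                    genome_label = c("G1", "G1", "G2"))
  ag <- aggregate_to_genomes(ct, ann)
  expect_equal(ag$abund[1, "G1"], 7)
  expect_equal(ag$abund[1, "G2"], 5)

  # one variant per genome is a pure relabeling
  ann2 <- data.frame(taxon_id = c("t1", "t2", "t3"),
                     genome_label = c("A", "B", "C"))
  ag2 <- aggregate_to_genomes(ct, ann2)
  expect_equal(unname(ag2$abund[1, c("A", "B", "C")]), c(3, 4, 5))

  set.seed(2)
  m <- matrix(runif(80, 0, 50), 8,
              dimnames = list(sprintf("s%d", 1:8), sprintf("t%d", 1:10)))
  annr <- data.frame(taxon_id = sprintf("t%d", 1:10),
                     genome_label = sample(c("G1", "G2", "G3"), 10, TRUE))
  agr <- aggregate_to_genomes(count_table(m, corrected = TRUE), annr)
  expect_equal(rowSums(agr$abund), rowSums(m))

  expect_error(aggregate_to_genomes(ct, ann[1:2, ]),
               class = "soursentinel_validation_error")
  expect_error(aggregate_to_genomes(mk_ct(matrix(1, 1)), ann),
               class = "soursentinel_validation_error")  # raw table refused
})

test_that("relative abundances sum to 100 and are scale invariant", {
  ct <- mk_ct(matrix(c(1, 3), 1))
  expect_equal(unname(relative_abundance(ct)$abund[1, ]), c(25, 75))
  expect_equal(unname(relative_abundance(mk_ct(matrix(42, 1)))$abund[1, 1]),
               100)
  m <- matrix(c(2, 5, 13, 1, 1, 2), 2, byrow = TRUE,
              dimnames = list(c("a", "b"), c("x", "y", "z")))
  r1 <- relative_abundance(count_table(m))
  r2 <- relative_abundance(count_table(m * c(7, 0.3)))
  expect_equal(r1$abund, r2$abund, tolerance = 1e-12)
  expect_true(all(abs(rowSums(r1$abund) - 100) < 1e-9))
  zero <- mk_ct(matrix(c(1, 1, 0, 0), 2, byrow = TRUE))
  err <- tryCatch(relative_abundance(zero), error = function(e) e)
  expect_s3_class(err, "soursentinel_domain_error")
  expect_match(conditionMessage(err), "s2")
})

test_that("anomaly series match the direct formula and sum to zero over the window", {
  a <- anomaly_series(c(2, 4, 6))
  expect_equal(a$anomaly, c(-0.5, 0, 0.5))
  expect_equal(a$window_mean, rep(4, 3))
  expect_equal(anomaly_series(rep(3.3, 5))$anomaly, rep(0, 5))
  expect_error(anomaly_series(c(0, 0, 0)),
               class = "soursentinel_domain_error")

  set.seed(9)
  for (i in 1:50) {
    n <- sample(3:40, 1)
    x <- rlnorm(n)
    win <- sort(sample(n, sample(2:n, 1)))
    a <- anomaly_series(x, seq_len(n), window = win)
    expect_lt(abs(sum(a$anomaly[a$day %in% win])), 1e-9 * n)
  }
})

test_that("critical time points are the TM points strictly above the TM mean", {
  series <- data.frame(day = c(1, 2, 3), value = c(1, 5, 3))
  phases <- data.frame(day = c(1, 2, 3), phase = "TM")
  expect_equal(detect_critical_time_points(series, phases), 2L)

  # constant TM signal: nothing strictly exceeds the mean
  flat <- data.frame(day = 1:4, value = rep(2, 4))
  expect_length(detect_critical_time_points(flat, data.frame(day = 1:4,
                                                             phase = "TM")), 0)

  # no TM phase: empty set with a warning
  expect_warning(
    out <- detect_critical_time_points(series,
                                       data.frame(day = 1:3, phase = "S")),
    "no TM phase")
  expect_length(out, 0)

  # only TM-phase days are eligible
  mixed <- data.frame(day = 1:4, phase = c("S", "TM", "TM", "M"))
  s2 <- data.frame(day = 1:4, value = c(100, 1, 3, 100))
  expect_equal(detect_critical_time_points(s2, mixed), 3L)
})

test_that("SSP candidates are SRB genomes ranked by TM-phase mean", {
  rel <- matrix(c(4, 2, 90, 4,
                  4, 2, 90, 4,
                  6, 2, 88, 4), 3, byrow = TRUE,
                dimnames = list(c(10, 12, 14),
                                c("SRB-A", "SRB-B", "BG-1", "SRB-C")))
  ann <- data.frame(genome_label = c("SRB-A", "SRB-B", "BG-1", "SRB-C"),
                    is_srb = c(TRUE, TRUE, FALSE, TRUE))
  cand <- select_ssp_candidates(rel, ann, tm_days = c(10, 12))
  expect_equal(cand$genome_label, c("SRB-A", "SRB-C", "SRB-B"))
  expect_equal(cand$tm_mean_pct, c(4, 4, 2))        # tie broken by label
  expect_equal(cand$rank, 1:3)

  # floor removes weak candidates
  cand2 <- select_ssp_candidates(rel, ann, tm_days = c(10, 12), floor = 3)
  expect_equal(cand2$genome_label, c("SRB-A", "SRB-C"))

  ann_none <- data.frame(genome_label = "BG-1", is_srb = FALSE)
  expect_error(select_ssp_candidates(rel, ann_none, tm_days = 10),
               class = "soursentinel_validation_error")
})

test_that("absolute SSP abundance is a plain percentage scaling", {
  expect_equal(ssp_cell_abundance(2, 1e6), 2e4)
  expect_equal(ssp_cell_abundance(0, 123), 0)
  expect_equal(ssp_cell_abundance(100, 5e6), 5e6)
  expect_error(ssp_cell_abundance(101, 1e6),
               class = "soursentinel_domain_error")
  expect_error(ssp_cell_abundance(50, 0), class = "soursentinel_domain_error")
})

test_that("Tukey fences flag exactly the points outside [Q1-1.5IQR, Q3+1.5IQR]", {
  expect_equal(flag_tukey_outliers(c(1, 2, 3, 4, 100)),
               c(FALSE, FALSE, FALSE, FALSE, TRUE))
  expect_equal(flag_tukey_outliers(rep(5, 6)), rep(FALSE, 6))
  expect_warning(out <- flag_tukey_outliers(c(1, 2, 1e6)), "fewer than 4")
  expect_equal(out, rep(FALSE, 3))
  expect_error(flag_tukey_outliers(numeric(0)),
               class = "soursentinel_domain_error")

  set.seed(3)
  for (i in 1:200) {
    n <- sample(4:12, 1)
    x <- if (i %% 3 == 0) sample(1:5, n, TRUE) else rlnorm(n, 0, 1.5)
    expect_identical(flag_tukey_outliers(x), oracle_tukey(x))
  }
})
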