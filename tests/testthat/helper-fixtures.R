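# Shared fixtures, all built in code.

mini_fixture_dir <- function() {
  system.file("extdata", "mini", package = "soursentinel", mustWork = TRUE)
}

# A scaled-down generator configuration for fast unit tests (fewer taxa,
# shorter experiment). Study-scale defaults are exercised in
# test-acceptance.R.
small_config <- function(...) {
  generator_config(n_columns = 4, n_treated = 2, duration_days = 80,
                   nitrate_start_day = 30, nitrate_stop_day = 64,
                   n_background_taxa = 10, n_srb_taxa = 3,
                   mean_depth = 5000, sd_depth = 1000, ...)
}

# Independently coded quartile (linear interpolation at 1 + (n-1) q) and
# Tukey fences, used as the oracle for flag_tukey_outliers.
oracle_quartile <- function(x, q) {
  s <- sort(x)
  h <- 1 + (length(x) - 1) * q
  lo <- floor(h)
  hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

oracle_tukey <- function(x) {
  q1 <- oracle_quartile(x, 0.25)
  q3 <- oracle_quartile(x, 0.75)
  x < q1 - 1.5 * (q3 - q1) | x > q3 + 1.5 * (q3 - q1)
}
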