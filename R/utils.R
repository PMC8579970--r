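# Typed condition helpers. Every user-facing failure is raised through one of
# these so callers (and the test suite) can distinguish validation problems
# from domain errors and I/O errors.

ss_condition <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "soursentinel_error")))
}

validation_error <- function(msg, ...) {
  ss_condition(sprintf(msg, ...), "soursentinel_validation_error")
}

domain_error <- function(msg, ...) {
  ss_condition(sprintf(msg, ...), "soursentinel_domain_error")
}

io_error <- function(msg, ...) {
  ss_condition(sprintf(msg, ...), "soursentinel_io_error")
}

config_error <- function(msg, ...) {
  ss_condition(sprintf(msg, ...), "soursentinel_config_error")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so library code never clobbers the
# user's stream.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

stopifnot_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    validation_error("%s is missing required column(s): %s",
                     what, paste(missing, collapse = ", "))
  }
  invisible(df)
}
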