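`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic per-stage seeds derived from one master seed, so changing
# e.g. forest settings never perturbs the generated data. Kept < 2^31.
substream_seed <- function(master, stream) {
  offsets <- c(generate = 1L, score = 2L, analyze = 3L, relate = 4L)
  if (!stream %in% names(offsets)) {
    stop("unknown RNG substream: ", stream, call. = FALSE)
  }
  (as.integer(master) + offsets[[stream]] * 100003L) %% 2147483647L
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("stage '%s': %s", stage, conditionMessage(e)), call. = FALSE)
  })
}

assert_columns <- function(records, vars, context = "records") {
  missing <- setdiff(vars, names(records))
  if (length(missing)) {
    stop(sprintf("%s lack required variable(s): %s", context,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(records)
}
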