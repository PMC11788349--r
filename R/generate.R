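#' Trial design
#'
#' Describes the randomized design: an ordered set of treatment codes,
#' a common replicate count, and an optional seed for the random stream.
#' The defaults mirror a 3-treatment (CK control, CS corn-straw return,
#' CB straw-biochar return) triplicate-plot field trial.
#'
#' @param treatments ordered character vector of treatment codes.
#' @param replicates positive integer, plots per treatment.
#' @param seed optional non-negative integer seed.
#' @return A list of class `trial_design`.
#' @export
trial_design <- function(treatments = c("CK", "CS", "CB"),
                         replicates = 3, seed = NULL) {
  treatments <- as.character(treatments)
  if (length(treatments) < 2 || anyDuplicated(treatments)) {
    stop("need at least 2 distinct treatments", call. = FALSE)
  }
  if (!is.numeric(replicates) || length(replicates) != 1 ||
      is.na(replicates) || replicates < 1 || replicates != round(replicates)) {
    stop("replicates must be a positive integer", call. = FALSE)
  }
  if (!is.null(seed)) {
    if (!is.numeric(seed) || length(seed) != 1 || is.na(seed) || seed < 0) {
      stop("seed must be a single non-negative integer", call. = FALSE)
    }
    seed <- as.integer(seed)
  }
  structure(list(treatments = treatments,
                 replicates = as.integer(replicates),
                 seed = seed),
            class = "trial_design")
}

#' Generate plot-level trial data
#'
#' Draws one record per plot of the design. Each variable is drawn from
#' Normal(mean = baseline_mean x multiplier, sd = cv x mean), truncated at
#' zero by redrawing negatives, so all emitted values are non-negative and
#' zero-noise (`cv = 0`) generation reproduces the treatment true means
#' exactly. Given a seed the output is fully deterministic.
#'
#' @param design a [trial_design()].
#' @param specs property specification data.frame (see [property_specs()]).
#' @param effects effect-multiplier data.frame (see [effect_table()]);
#'   missing (treatment, property) pairs resolve to multiplier 1.
#' @param cv optional single value overriding the per-variable `cv` column.
#' @param seed seed for the random stream; defaults to `design$seed`.
#' @return A data.frame with columns `treatment`, `replicate`, then one
#'   column per variable, `replicates x treatments` rows.
#' @examples
#' cal <- default_calibration()
#' trial <- generate_trial(trial_design(seed = 1), cal$specs, cal$effects)
#' head(trial[, 1:5])
#' @export
generate_trial <- function(design,
                           specs = default_calibration()$specs,
                           effects = default_calibration()$effects,
                           cv = NULL, seed = design$seed) {
  if (!inherits(design, "trial_design")) {
    design <- do.call(trial_design, as.list(design))
  }
  validate_effects(effects)
  if (!is.null(cv)) {
    if (!is.numeric(cv) || length(cv) != 1 || is.na(cv) || cv < 0) {
      stop("cv must be a single non-negative number", call. = FALSE)
    }
    specs$cv <- cv
  }
  if (any(specs$cv < 0)) stop("negative cv in property specs", call. = FALSE)
  if (any(!is.finite(specs$baseline_mean)) || any(specs$baseline_mean <= 0)) {
    stop("calibration error: baseline_mean must be positive for every property",
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(as.integer(seed))

  r <- design$replicates
  out <- data.frame(
    treatment = rep(design$treatments, each = r),
    replicate = rep(seq_len(r), times = length(design$treatments)),
    stringsAsFactors = FALSE
  )
  for (i in seq_len(nrow(specs))) {
    col <- numeric(0)
    for (tr in design$treatments) {
      m <- specs$baseline_mean[i] * effect_multiplier(effects, tr, specs$name[i])
      s <- specs$cv[i] * m
      x <- stats::rnorm(r, mean = m, sd = s)
      while (any(x < 0)) {
        x[x < 0] <- stats::rnorm(sum(x < 0), mean = m, sd = s)
      }
      col <- c(col, x)
    }
    out[[specs$name[i]]] <- col
  }
  out
}

#' Write plot records to CSV
#'
#' Plain RFC-4180 CSV with a header row (`treatment`, `replicate`, one
#' column per variable), "." decimal, full double precision (15
#' significant digits) so a round trip through [read_records()] is
#' lossless for practical purposes.
#'
#' @param records data.frame of plot records.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path) {
  assert_columns(records, c("treatment", "replicate"))
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read plot records from CSV
#'
#' Inverse of [write_records()]. Validates the header and every cell;
#' a missing required column or a non-numeric measurement raises a parse
#' error naming the offending row and column.
#'
#' @param path CSV file path.
#' @return A data.frame of plot records.
#' @export
read_records <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         check.names = FALSE, colClasses = "character")
  for (col in c("treatment", "replicate")) {
    if (!col %in% names(raw)) {
      stop(sprintf("parse error: required column '%s' missing from %s",
                   col, path), call. = FALSE)
    }
  }
  for (col in setdiff(names(raw), "treatment")) {
    num <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(num) & !is.na(raw[[col]]) & raw[[col]] != "NA")
    if (length(bad)) {
      stop(sprintf("parse error: non-numeric value '%s' in column '%s', row %d",
                   raw[[col]][bad[1]], col, bad[1]), call. = FALSE)
    }
    raw[[col]] <- num
  }
  raw$replicate <- as.integer(raw$replicate)
  raw
}
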