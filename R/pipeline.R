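#' Pipeline run configuration
#'
#' Collects every knob of a full generate -> score -> analyze -> relate
#' run into one serializable object. A config plus its seed reproduces all
#' outputs bit-identically (up to documented float formatting). The master
#' seed is split into named substreams per stage, so e.g. changing forest
#' settings never perturbs the generated data.
#'
#' @param seed master seed (non-negative integer).
#' @param treatments,replicates trial design (see [trial_design()]).
#' @param cv optional override of the within-treatment coefficient of
#'   variation for every variable.
#' @param specs,effects optional calibration overrides; defaults to
#'   [default_calibration()].
#' @param sqi_properties,emf_enzymes,sqi_variant scoring settings (see
#'   [score_dataset()]).
#' @param alpha significance level for ANOVA / LSD letters.
#' @param reference reference treatment for percent changes.
#' @param protected protected LSD (gate pairwise tests on the omnibus F).
#' @param rf_trees,rf_mtry forest settings for [rf_importance()].
#' @param rf_features feature names for the yield-driver forest; default
#'   the physicochemical panel.
#' @param input optional CSV of plot records; when NULL a synthetic trial
#'   is generated.
#' @param out_dir optional output directory for CSV/JSON artifacts.
#' @return A list of class `soilqual_config`.
#' @export
run_config <- function(seed = 1,
                       treatments = c("CK", "CS", "CB"), replicates = 3,
                       cv = NULL, specs = NULL, effects = NULL,
                       sqi_properties = default_sqi_properties(),
                       emf_enzymes = default_emf_enzymes(),
                       sqi_variant = "printed",
                       alpha = 0.05, reference = "CK", protected = FALSE,
                       rf_trees = 500, rf_mtry = NULL,
                       rf_features = c("salt", "pH", "soluble_Na", "TN",
                                       "avN", "avP", "avK", "SOC"),
                       input = NULL, out_dir = NULL) {
  structure(list(seed = as.integer(seed), treatments = treatments,
                 replicates = replicates, cv = cv,
                 specs = specs, effects = effects,
                 sqi_properties = sqi_properties,
                 emf_enzymes = emf_enzymes, sqi_variant = sqi_variant,
                 alpha = alpha, reference = reference, protected = protected,
                 rf_trees = rf_trees, rf_mtry = rf_mtry,
                 rf_features = rf_features,
                 input = input, out_dir = out_dir),
            class = "soilqual_config")
}

#' Read a run configuration from YAML
#'
#' Scalar settings map directly onto [run_config()] arguments. Calibration
#' overrides use `baselines` (a `name: value` map patching baseline means)
#' and `multipliers` (a list of `{treatment, property, multiplier}`
#' records patching or extending the effect table).
#'
#' @param path YAML file.
#' @return A `soilqual_config`.
#' @export
config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  cal <- default_calibration()
  specs <- cal$specs
  effects <- cal$effects
  if (!is.null(y$baselines)) {
    for (nm in names(y$baselines)) {
      hit <- match(nm, specs$name)
      if (is.na(hit)) stop(sprintf("baseline override for unknown property '%s'", nm),
                           call. = FALSE)
      specs$baseline_mean[hit] <- y$baselines[[nm]]
    }
  }
  if (!is.null(y$multipliers)) {
    for (m in y$multipliers) {
      hit <- which(effects$treatment == m$treatment & effects$property == m$property)
      if (length(hit)) {
        effects$multiplier[hit] <- m$multiplier
      } else {
        effects <- rbind(effects, data.frame(treatment = m$treatment,
                                             property = m$property,
                                             multiplier = m$multiplier))
      }
    }
  }
  args <- y[intersect(names(y), names(formals(run_config)))]
  args$specs <- specs
  args$effects <- effects
  do.call(run_config, args)
}

#' Write a run configuration to YAML
#'
#' @param config a `soilqual_config`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
config_to_yaml <- function(config, path) {
  y <- unclass(config)
  y$specs <- NULL
  y$effects <- NULL
  y <- y[!vapply(y, is.null, logical(1))]
  yaml::write_yaml(y, path)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Executes generate (or read) -> score -> analyze -> relate and collects
#' a machine-readable summary: per-variable treatment comparison (means,
#' SE, LSD letters, percent change vs the reference, ANOVA F/p), the
#' SQI/EMF comparisons, the pairwise correlation panel, the linear fits
#' among SQI, EMF and yield, the random-forest yield-driver importances,
#' and provenance (config hash, seed, package version). Errors from any
#' stage propagate prefixed with the stage name.
#'
#' @param config a [run_config()].
#' @return An object of class `soilqual_run`: list with `records`,
#'   `scores`, `comparisons`, `correlations`, `regressions`, `importance`,
#'   `provenance`. When `config$out_dir` is set, CSV and JSON artifacts
#'   are written there as a side effect.
#' @examples
#' \donttest{
#' run <- run_all(run_config(seed = 1, rf_trees = 100))
#' subset(run$comparisons, variable == "SQI")
#' }
#' @export
run_all <- function(config = run_config()) {
  stopifnot(inherits(config, "soilqual_config"))
  cal <- default_calibration()
  specs <- config$specs %||% cal$specs
  effects <- config$effects %||% cal$effects

  records <- with_stage("generate", {
    if (!is.null(config$input)) {
      read_records(config$input)
    } else {
      design <- trial_design(config$treatments, config$replicates,
                             seed = substream_seed(config$seed, "generate"))
      generate_trial(design, specs, effects, cv = config$cv)
    }
  })

  sc <- with_stage("scoring", {
    score_dataset(records, config$sqi_properties, config$emf_enzymes,
                  specs = specs, sqi_variant = config$sqi_variant)
  })

  full <- cbind(records, SQI = sc$scores$SQI, EMF = sc$scores$EMF)
  vars <- c(setdiff(names(records), c("treatment", "replicate")), "SQI", "EMF")

  comparisons <- with_stage("analyze", {
    rows <- lapply(vars, function(v) {
      an <- oneway_anova(full[[v]], full$treatment, variable = v)
      lsd <- fisher_lsd(an, alpha = config$alpha, protected = config$protected)
      pc <- percent_changes(full, v, reference = config$reference)
      data.frame(variable = v, treatment = names(an$means),
                 mean = as.numeric(an$means), se = as.numeric(an$se),
                 letter = as.character(lsd$letters[names(an$means)]),
                 pct_vs_ref = pc$value[match(names(an$means), pc$treatment)],
                 pct_undefined = pc$undefined[match(names(an$means), pc$treatment)],
                 F = an$F, p = an$p, row.names = NULL,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })

  corr_vars <- intersect(c("salt", "TN", "avN", "avP", "avK", "SOC",
                           "BG", "CE", "NAG", "LAP"), names(full))
  correlations <- with_stage("analyze", correlation_panel(full, corr_vars))

  relate_seed <- substream_seed(config$seed, "relate")
  regressions <- with_stage("relate", {
    fits <- list(linear_fit(full$SQI, full$yield, "SQI", "yield"),
                 linear_fit(full$EMF, full$yield, "EMF", "yield"),
                 linear_fit(full$SQI, full$EMF, "SQI", "EMF"))
    do.call(rbind, lapply(fits, function(f) {
      data.frame(response = f$response, predictor = f$predictor,
                 slope = f$slope, intercept = f$intercept,
                 r_squared = f$r_squared, p_slope = f$p_slope, n = f$n,
                 stringsAsFactors = FALSE)
    }))
  })

  rf_feat <- intersect(config$rf_features, names(full))
  importance <- with_stage("relate", {
    rf_importance(full[rf_feat], full$yield, n_trees = config$rf_trees,
                  seed = relate_seed, mtry = config$rf_mtry)
  })

  provenance <- list(config_hash = rlang::hash(unclass(config)),
                     seed = config$seed,
                     version = as.character(utils::packageVersion("soilqual")))

  run <- structure(list(records = records, scores = sc$scores,
                        comparisons = comparisons,
                        correlations = correlations$table,
                        regressions = regressions,
                        importance = importance$table,
                        rf_settings = importance$settings,
                        provenance = provenance),
                   class = "soilqual_run")

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    out <- function(f) file.path(config$out_dir, f)
    write_records(records, out("records.csv"))
    utils::write.csv(run$scores, out("scores.csv"), row.names = FALSE)
    utils::write.csv(run$comparisons, out("comparison.csv"), row.names = FALSE)
    utils::write.csv(run$correlations, out("correlations.csv"), row.names = FALSE)
    utils::write.csv(run$regressions, out("regressions.csv"), row.names = FALSE)
    utils::write.csv(run$importance, out("importance.csv"), row.names = FALSE)
    config_to_yaml(config, out("config.yaml"))
    jsonlite::write_json(
      list(schema = "soilqual-run/1",
           provenance = provenance,
           comparisons = run$comparisons,
           correlations = run$correlations,
           regressions = run$regressions,
           importance = run$importance),
      out("summary.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE,
      na = "null")
  }
  run
}

#' @export
print.soilqual_run <- function(x, ...) {
  cat(sprintf("soilqual run (seed %d, config %s)\n",
              x$provenance$seed, x$provenance$config_hash))
  cat("\nSQI / EMF / yield comparison:\n")
  print(x$comparisons[x$comparisons$variable %in% c("SQI", "EMF", "yield"), ],
        ...)
  cat("\nTop yield drivers (%IncMSE):\n")
  print(utils::head(x$importance, 4), ...)
  invisible(x)
}
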