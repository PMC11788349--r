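#' Built-in property specifications
#'
#' Returns the panel of measured variables for a coastal saline-soil
#' amendment trial: for each variable its units, scoring direction
#' (`more_is_better`, `less_is_better`, or `not_scored`), the control
#' (baseline) mean, and the within-treatment coefficient of variation used
#' by the synthetic generator.
#'
#' Physicochemical baselines are the pre-trial 0--20 cm panel of the study
#' site (salt 1.88 g/kg with soluble Na+ 1.52 g/kg dominating, pH 8.46,
#' SOC 7.6 g/kg, total N 1.01 g/kg, available N/P/K 50.41/34.98/393.71
#' mg/kg). Enzyme-activity and yield baselines are free positive scales:
#' every downstream quantity (percent change, Z-score, min-max score) is
#' invariant to them.
#'
#' Only salt (and, optionally, the soluble ions) is scored "less is
#' better"; the nutrient pools and SOC are "more is better"; pH, enzymes
#' and yield never enter the SQI.
#'
#' @param cv coefficient of variation of within-treatment noise applied to
#'   every variable (default 0.05).
#' @return A data.frame with columns `name`, `units`, `direction`,
#'   `baseline_mean`, `cv`.
#' @seealso [effect_table()], [default_calibration()]
#' @export
property_specs <- function(cv = 0.05) {
  if (!is.numeric(cv) || length(cv) != 1 || is.na(cv) || cv < 0) {
    stop("cv must be a single non-negative number", call. = FALSE)
  }
  spec <- function(name, units, direction, baseline) {
    data.frame(name = name, units = units, direction = direction,
               baseline_mean = baseline, cv = cv,
               stringsAsFactors = FALSE)
  }
  rbind(
    spec("salt",         "g/kg",       "less_is_better", 1.88),
    spec("pH",           "",           "not_scored",     8.46),
    spec("soluble_K",    "g/kg",       "less_is_better", 0.03),
    spec("soluble_Ca",   "g/kg",       "less_is_better", 0.13),
    spec("soluble_Na",   "g/kg",       "less_is_better", 1.52),
    spec("soluble_Mg",   "g/kg",       "less_is_better", 0.10),
    spec("soluble_Cl",   "g/kg",       "less_is_better", 0.05),
    spec("soluble_SO4",  "g/kg",       "less_is_better", 0.45),
    spec("soluble_HCO3", "g/kg",       "less_is_better", 0.03),
    spec("TN",           "g/kg",       "more_is_better", 1.01),
    spec("avN",          "mg/kg",      "more_is_better", 50.41),
    spec("avP",          "mg/kg",      "more_is_better", 34.98),
    spec("avK",          "mg/kg",      "more_is_better", 393.71),
    spec("SOC",          "g/kg",       "more_is_better", 7.6),
    spec("BG",           "nmol/g/h",   "not_scored",     50),
    spec("CE",           "nmol/g/h",   "not_scored",     20),
    spec("NAG",          "nmol/g/h",   "not_scored",     30),
    spec("LAP",          "nmol/g/h",   "not_scored",     15),
    spec("yield",        "t/ha",       "not_scored",     9.0)
  )
}

#' Built-in treatment effect multipliers
#'
#' Long table mapping (treatment, property) to the multiplier applied to
#' the baseline mean to give that treatment's true mean. The control CK is
#' the implicit reference: any (treatment, property) pair absent from the
#' table resolves to 1.0, so CK needs no rows and non-significant shifts
#' are modelled as no change.
#'
#' Corn-straw return (CS): salt x0.78, available N x1.91, available P
#' x1.49, available K x1.25, yield x1.22, BG x1.33, NAG x1.32, LAP x1.13.
#' Straw-biochar return (CB): salt x0.82, CE x1.22, NAG x1.11; its BG and
#' LAP multipliers are pinned by the reported CS-vs-CB ratios
#' (BG 1.33/1.70, LAP 1.13/1.15) rather than direct CB-vs-CK contrasts.
#'
#' @return A data.frame with columns `treatment`, `property`, `multiplier`.
#' @export
effect_table <- function() {
  eff <- function(treatment, property, multiplier) {
    data.frame(treatment = treatment, property = property,
               multiplier = multiplier, stringsAsFactors = FALSE)
  }
  rbind(
    eff("CS", "salt",  0.78),
    eff("CS", "avN",   1.91),
    eff("CS", "avP",   1.49),
    eff("CS", "avK",   1.25),
    eff("CS", "yield", 1.22),
    eff("CS", "BG",    1.33),
    eff("CS", "NAG",   1.32),
    eff("CS", "LAP",   1.13),
    eff("CB", "salt",  0.82),
    eff("CB", "CE",    1.22),
    eff("CB", "NAG",   1.11),
    eff("CB", "BG",    1.33 / 1.70),
    eff("CB", "LAP",   1.13 / 1.15)
  )
}

#' Default trial calibration
#'
#' Bundles [property_specs()] and [effect_table()] into the calibration
#' used throughout the package when none is supplied.
#'
#' @param cv within-treatment coefficient of variation passed to
#'   [property_specs()].
#' @return A list with elements `specs` and `effects`.
#' @examples
#' cal <- default_calibration()
#' effect_multiplier(cal$effects, "CS", "salt")   # 0.78
#' effect_multiplier(cal$effects, "CK", "salt")   # 1.0 (reference)
#' @export
default_calibration <- function(cv = 0.05) {
  list(specs = property_specs(cv = cv), effects = effect_table())
}

#' Resolve an effect multiplier
#'
#' Looks up the multiplier for a (treatment, property) pair in an effect
#' table; missing pairs resolve to 1.0 (the reference level).
#'
#' @param effects data.frame as returned by [effect_table()].
#' @param treatment,property single character identifiers.
#' @return A single positive number.
#' @export
effect_multiplier <- function(effects, treatment, property) {
  validate_effects(effects)
  hit <- effects$treatment == treatment & effects$property == property
  if (!any(hit)) return(1.0)
  effects$multiplier[which(hit)[1]]
}

validate_effects <- function(effects, reference = NULL) {
  need <- c("treatment", "property", "multiplier")
  if (!is.data.frame(effects) || !all(need %in% names(effects))) {
    stop("effects must be a data.frame with columns treatment, property, multiplier",
         call. = FALSE)
  }
  if (any(!is.finite(effects$multiplier)) || any(effects$multiplier <= 0)) {
    stop("all effect multipliers must be positive", call. = FALSE)
  }
  if (!is.null(reference)) {
    ref <- effects[effects$treatment == reference, ]
    if (nrow(ref) && any(ref$multiplier != 1)) {
      stop(sprintf("reference treatment '%s' must have multiplier 1 for every property",
                   reference), call. = FALSE)
    }
  }
  invisible(effects)
}

#' Default SQI property set
#'
#' The six-property minimum data set scored into the soil quality index:
#' salt (less is better) plus total N, available N, P, K and SOC (more is
#' better). The soluble ions are excluded by default but may be added via
#' the `sqi_properties` argument of [score_dataset()].
#'
#' @return Character vector of property names.
#' @export
default_sqi_properties <- function() {
  c("salt", "TN", "avN", "avP", "avK", "SOC")
}

#' Default EMF enzyme set
#'
#' The four extracellular enzymes averaged (after Z-standardisation) into
#' ecosystem multifunctionality: 1,4-beta-glucosidase (BG), cellobiosidase
#' (CE), beta-1,4-N-acetyl-glucosaminidase (NAG) and leucine
#' aminopeptidase (LAP).
#'
#' @return Character vector of enzyme names.
#' @export
default_emf_enzymes <- function() {
  c("BG", "CE", "NAG", "LAP")
}
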