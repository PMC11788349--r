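#' Directional linear (min-max) scores
#'
#' Transforms one property's values over a scoring set into linear scores
#' Li in (0, 1]. For "more is better" properties Li = v / v_max; for
#' "less is better" properties Li = v_min / v, where v_max and v_min are
#' taken over the supplied values. A constant column scores 1 everywhere
#' (the favourable extreme is attained by every plot).
#'
#' @param values numeric vector, one value per plot (the scoring set).
#' @param direction `"more_is_better"` or `"less_is_better"`.
#' @return Numeric vector of scores in (0, 1], same length as `values`.
#' @examples
#' linear_scores(c(5, 10), "more_is_better")          # 0.5 1.0
#' linear_scores(c(1.4664, 1.88), "less_is_better")   # 1.0 0.78
#' @export
linear_scores <- function(values, direction = c("more_is_better", "less_is_better")) {
  direction <- match.arg(direction)
  if (length(values) == 0) stop("empty scoring set", call. = FALSE)
  if (any(!is.finite(values))) stop("non-finite value in scoring set", call. = FALSE)
  if (any(values < 0)) stop("negative value in scoring set", call. = FALSE)
  if (direction == "more_is_better") {
    vmax <- max(values)
    if (vmax <= 0) stop("all values zero: more-is-better score undefined", call. = FALSE)
    values / vmax
  } else {
    if (any(values == 0)) {
      stop("zero value: less-is-better score v_min/v undefined", call. = FALSE)
    }
    min(values) / values
  }
}

#' Radar-area soil quality index
#'
#' Aggregates per-plot linear scores over n >= 3 properties into the SQI,
#' the area of the radar polygon spanned by the scores:
#' SQI = 0.5 * sin(2*pi/n) * sum(Li^2) (the `"printed"` form). The
#' `"adjacent"` variant uses the conventional radar-chart area with
#' adjacent-spoke products, 0.5 * sin(2*pi/n) * sum(Li * L(i+1)) taken
#' cyclically, and is provided for sensitivity analysis.
#'
#' Either way 0 < SQI <= 0.5 * n * sin(2*pi/n), with the upper bound
#' attained iff every score is 1.
#'
#' @param scores numeric matrix or data.frame, plots x properties, every
#'   entry in (0, 1].
#' @param variant `"printed"` (default) or `"adjacent"`.
#' @return Numeric vector of per-plot SQI values.
#' @examples
#' sqi(matrix(1, 1, 6))   # upper bound 3*sin(pi/3) ~ 2.598
#' @export
sqi <- function(scores, variant = c("printed", "adjacent")) {
  variant <- match.arg(variant)
  scores <- as.matrix(scores)
  n <- ncol(scores)
  if (n < 3) stop("radar area undefined for fewer than 3 properties", call. = FALSE)
  if (any(!is.finite(scores)) || any(scores <= 0) || any(scores > 1)) {
    stop("all linear scores must lie in (0, 1]", call. = FALSE)
  }
  half_sin <- 0.5 * sin(2 * pi / n)
  if (variant == "printed") {
    half_sin * rowSums(scores^2)
  } else {
    half_sin * rowSums(scores * scores[, c(2:n, 1), drop = FALSE])
  }
}

#' Upper bound of the SQI for n properties
#'
#' @param n number of scored properties (>= 3).
#' @return `0.5 * n * sin(2*pi/n)`.
#' @export
sqi_bound <- function(n) {
  if (n < 3) stop("radar area undefined for fewer than 3 properties", call. = FALSE)
  0.5 * n * sin(2 * pi / n)
}

#' Z-score ecosystem multifunctionality
#'
#' Standardises each enzyme-activity column to a Z-score (sample standard
#' deviation, denominator N-1) over the scoring set, then averages the
#' Z-scores within each plot. The resulting EMF has grand mean zero over
#' the scoring set and is invariant to affine rescaling of any single
#' enzyme column.
#'
#' @param enzyme_matrix numeric matrix or data.frame, plots x enzymes,
#'   at least 2 plots.
#' @return Numeric vector of per-plot EMF values.
#' @export
emf <- function(enzyme_matrix) {
  m <- as.matrix(enzyme_matrix)
  if (nrow(m) < 2) stop("need at least 2 plots to standardise", call. = FALSE)
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0)) {
    bad <- colnames(m)[which(sds == 0)[1]] %||% which(sds == 0)[1]
    stop(sprintf("enzyme '%s' has zero variance: Z-score undefined", bad),
         call. = FALSE)
  }
  z <- scale(m, center = TRUE, scale = TRUE)
  rowMeans(z)
}

#' Score a plot dataset: SQI and EMF
#'
#' Applies directional min-max scoring and the radar-area SQI to the
#' named soil properties, and Z-score EMF to the named enzymes, for every
#' plot. Scoring extremes (v_max/v_min) and enzyme means/sds are pooled
#' over ALL supplied plots, so treatment contrasts of SQI and EMF are
#' defined within the analysed dataset rather than against an external
#' reference.
#'
#' @param records plot-record data.frame (see [generate_trial()]).
#' @param sqi_properties ordered names of properties entering the SQI
#'   (default [default_sqi_properties()], n = 6).
#' @param emf_enzymes ordered names of enzymes entering the EMF
#'   (default [default_emf_enzymes()]); an empty vector skips the EMF
#'   columns (useful when enzyme columns are constant or absent).
#' @param specs property specification table supplying scoring directions.
#' @param sqi_variant `"printed"` or `"adjacent"`, see [sqi()].
#' @return An object of class `soilqual_scores`: a list with `scores`
#'   (data.frame: treatment, replicate, `L_<property>` columns, `SQI`,
#'   `Z_<enzyme>` columns, `EMF`), `n_properties`, `bound` (the SQI upper
#'   bound for that n) and `variant`.
#' @examples
#' cal <- default_calibration(cv = 0)
#' trial <- generate_trial(trial_design(seed = 1), cal$specs, cal$effects)
#' sc <- score_dataset(trial)
#' aggregate(SQI ~ treatment, sc$scores, mean)
#' @export
score_dataset <- function(records,
                          sqi_properties = default_sqi_properties(),
                          emf_enzymes = default_emf_enzymes(),
                          specs = default_calibration()$specs,
                          sqi_variant = c("printed", "adjacent")) {
  sqi_variant <- match.arg(sqi_variant)
  assert_columns(records, c("treatment", "replicate", sqi_properties, emf_enzymes))

  dir_of <- function(p) {
    hit <- match(p, specs$name)
    if (is.na(hit)) stop(sprintf("no scoring direction known for '%s'", p),
                         call. = FALSE)
    d <- specs$direction[hit]
    if (d == "not_scored") {
      stop(sprintf("property '%s' is not scoreable (direction not_scored)", p),
           call. = FALSE)
    }
    d
  }

  L <- sapply(sqi_properties, function(p) linear_scores(records[[p]], dir_of(p)))
  L <- matrix(L, nrow = nrow(records),
              dimnames = list(NULL, sqi_properties))
  sqi_vals <- sqi(L, variant = sqi_variant)

  scores <- data.frame(treatment = records$treatment,
                       replicate = records$replicate,
                       stringsAsFactors = FALSE)
  for (p in sqi_properties) scores[[paste0("L_", p)]] <- L[, p]
  scores$SQI <- sqi_vals
  if (length(emf_enzymes)) {
    emf_vals <- emf(records[emf_enzymes])
    Z <- scale(as.matrix(records[emf_enzymes]))
    for (e in emf_enzymes) scores[[paste0("Z_", e)]] <- Z[, e]
    scores$EMF <- emf_vals
  }

  structure(list(scores = scores,
                 n_properties = length(sqi_properties),
                 bound = sqi_bound(length(sqi_properties)),
                 variant = sqi_variant),
            class = "soilqual_scores")
}

#' @export
print.soilqual_scores <- function(x, ...) {
  cat(sprintf("Soil quality scores: %d plots, %d properties (SQI bound %.4f, %s variant)\n",
              nrow(x$scores), x$n_properties, x$bound, x$variant))
  print(utils::head(x$scores), ...)
  invisible(x)
}
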