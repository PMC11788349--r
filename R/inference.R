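#' One-way fixed-effects ANOVA
#'
#' Classical one-way decomposition (via [stats::lm()]) of a single
#' response over treatment groups: F = MS_between / MS_within with
#' df = (k - 1, N - k), p from the upper tail of the F distribution.
#' Degenerate cases are resolved explicitly: equal sample means give
#' F = 0; zero within-group variance with unequal means gives F = Inf,
#' p = 0.
#'
#' @param values numeric response vector.
#' @param groups treatment labels, same length; group order follows first
#'   appearance.
#' @param variable optional name carried into the result.
#' @return An object of class `soilqual_anova`: list with `variable`, `F`,
#'   `p`, `df_between`, `df_within`, `mse_within`, and named vectors
#'   `means`, `se`, `sd`, `n` per group (in design order).
#' @examples
#' oneway_anova(c(1, 2, 3, 2, 3, 4, 3, 4, 5), rep(c("A", "B", "C"), each = 3))
#' @export
oneway_anova <- function(values, groups, variable = NULL) {
  if (length(values) != length(groups)) {
    stop("values and groups must have equal length", call. = FALSE)
  }
  g <- factor(as.character(groups), levels = unique(as.character(groups)))
  n <- tapply(values, g, length)
  if (nlevels(g) < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(n < 2)) {
    stop(sprintf("group '%s' has fewer than 2 observations",
                 names(n)[which(n < 2)[1]]), call. = FALSE)
  }
  means <- c(tapply(values, g, mean))
  sds <- c(tapply(values, g, stats::sd))
  n <- c(n)

  # degenerate (zero-residual) fits are resolved explicitly below, so the
  # "essentially perfect fit" warning carries no information here
  tab <- suppressWarnings(stats::anova(stats::lm(values ~ g)))
  mse <- tab["Residuals", "Mean Sq"]
  df_between <- tab[1, "Df"]
  df_within <- tab["Residuals", "Df"]

  if (all(sds == 0)) {
    # zero within-group variance: F degenerates exactly
    mse <- 0
    if (max(means) == min(means)) { Fval <- 0; p <- 1 } else { Fval <- Inf; p <- 0 }
  } else if (max(means) == min(means)) {
    # exactly equal sample means: no between-group signal by definition
    Fval <- 0; p <- 1
  } else {
    Fval <- tab[1, "F value"]
    p <- tab[1, "Pr(>F)"]
  }

  structure(list(variable = variable, F = Fval, p = p,
                 df_between = df_between, df_within = df_within,
                 mse_within = mse,
                 means = means, sd = sds, se = sds / sqrt(n), n = n),
            class = "soilqual_anova")
}

#' @export
print.soilqual_anova <- function(x, ...) {
  cat(sprintf("One-way ANOVA%s: F(%d, %d) = %.4g, p = %.4g\n",
              if (is.null(x$variable)) "" else paste0(" [", x$variable, "]"),
              x$df_between, x$df_within, x$F, x$p))
  print(data.frame(mean = x$means, se = x$se, n = as.integer(x$n)), ...)
  invisible(x)
}

#' Fisher's LSD multiple comparison with compact letters
#'
#' Pairwise least-significant-difference tests using the ANOVA pooled
#' error: LSD_ij = t(1 - alpha/2, df_within) * sqrt(MSE * (1/n_i + 1/n_j)),
#' a pair differing when |mean_i - mean_j| exceeds its LSD (equivalently
#' the pairwise t-test p < alpha). Letters summarise the result via
#' insert-and-absorb compact letter display, assigned in descending-mean
#' order starting at "a" (ties broken by design order). Unprotected by
#' default: pairwise tests run regardless of the omnibus F; with
#' `protected = TRUE` all pairs are declared non-significant unless the
#' ANOVA p-value is below alpha.
#'
#' @param anova a [oneway_anova()] result.
#' @param alpha significance level (default 0.05).
#' @param protected gate the pairwise tests on the omnibus test.
#' @return An object of class `soilqual_lsd`: list with `alpha`,
#'   `lsd_value` (scalar for balanced designs, else NA), `lsd_matrix`,
#'   `p_matrix`, `significant` (logical matrix), and `letters` (named
#'   character vector).
#' @export
fisher_lsd <- function(anova, alpha = 0.05, protected = FALSE) {
  stopifnot(inherits(anova, "soilqual_anova"))
  if (anova$df_within < 1) stop("df_within must be >= 1", call. = FALSE)
  lev <- names(anova$means)
  k <- length(lev)
  tcrit <- stats::qt(1 - alpha / 2, anova$df_within)

  lsd_m <- p_m <- matrix(NA_real_, k, k, dimnames = list(lev, lev))
  sig <- matrix(FALSE, k, k, dimnames = list(lev, lev))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      se_ij <- sqrt(anova$mse_within * (1 / anova$n[i] + 1 / anova$n[j]))
      d <- anova$means[i] - anova$means[j]
      lsd_m[i, j] <- lsd_m[j, i] <- tcrit * se_ij
      if (se_ij == 0) {
        p_m[i, j] <- p_m[j, i] <- if (d == 0) 1 else 0
      } else {
        tstat <- d / se_ij
        p_m[i, j] <- p_m[j, i] <- 2 * stats::pt(-abs(tstat), anova$df_within)
      }
      sig[i, j] <- sig[j, i] <- p_m[i, j] < alpha
    }
  }
  if (protected && anova$p >= alpha) sig[] <- FALSE

  letters_out <- compact_letters(sig, anova$means)
  balanced <- length(unique(anova$n)) == 1
  structure(list(alpha = alpha,
                 lsd_value = if (balanced) unname(tcrit * sqrt(2 * anova$mse_within / anova$n[1])) else NA_real_,
                 lsd_matrix = lsd_m, p_matrix = p_m,
                 significant = sig, letters = letters_out,
                 protected = protected),
            class = "soilqual_lsd")
}

#' @export
print.soilqual_lsd <- function(x, ...) {
  cat(sprintf("Fisher's LSD (alpha = %g%s)\n", x$alpha,
              if (x$protected) ", protected" else ""))
  print(x$letters, ...)
  invisible(x)
}

#' Compact letter display from a significance matrix
#'
#' Insert-and-absorb algorithm: starting from a single letter class
#' holding every group, each significantly different pair splits any class
#' containing both; classes that become subsets of others are absorbed.
#' Letters are assigned so that the group with the largest mean carries
#' "a". Two groups share a letter iff their pair is non-significant.
#'
#' @param significant symmetric logical matrix of pairwise significance,
#'   dimnames giving the group labels.
#' @param means named numeric vector of group means (for letter ordering;
#'   ties keep the order of `names(means)`).
#' @return Named character vector of letter strings.
#' @export
compact_letters <- function(significant, means) {
  labs <- names(means)
  stopifnot(!is.null(labs), all(labs %in% rownames(significant)))
  classes <- list(labs)
  for (i in seq_len(length(labs) - 1)) {
    for (j in (i + 1):length(labs)) {
      if (!significant[labs[i], labs[j]]) next
      touched <- vapply(classes, function(cl) all(c(labs[i], labs[j]) %in% cl),
                        logical(1))
      if (!any(touched)) next
      new_classes <- list()
      for (idx in seq_along(classes)) {
        cl <- classes[[idx]]
        if (touched[idx]) {
          new_classes <- c(new_classes, list(setdiff(cl, labs[i])),
                           list(setdiff(cl, labs[j])))
        } else {
          new_classes <- c(new_classes, list(cl))
        }
      }
      # absorb: drop classes contained in another class (and duplicates)
      keep <- rep(TRUE, length(new_classes))
      for (a in seq_along(new_classes)) {
        for (b in seq_along(new_classes)) {
          if (a == b || !keep[a]) next
          if (all(new_classes[[a]] %in% new_classes[[b]]) &&
              (length(new_classes[[a]]) < length(new_classes[[b]]) || a > b)) {
            keep[a] <- FALSE
          }
        }
      }
      classes <- new_classes[keep]
    }
  }
  # order classes by the rank (descending mean, design-order ties) of their
  # best member, then assign letters a, b, c, ...
  ord <- order(-means)  # stable: ties keep design order
  rank_of <- stats::setNames(seq_along(labs), labs[ord])
  best <- vapply(classes, function(cl) min(rank_of[cl]), numeric(1))
  classes <- classes[order(best)]
  out <- stats::setNames(rep("", length(labs)), labs)
  for (c_idx in seq_along(classes)) {
    for (lab in classes[[c_idx]]) {
      out[lab] <- paste0(out[lab], letters[c_idx])
    }
  }
  out
}

#' Percent change of treatment means versus a reference
#'
#' 100 * (mean_t - mean_ref) / mean_ref for every treatment, computed from
#' treatment means of the raw variable. The reference-vs-itself change is
#' 0. When the reference mean is non-positive (as for the mean-zero EMF
#' composite) the percent form is undefined: the result is flagged and no
#' number is emitted.
#'
#' @param records plot-record data.frame containing `treatment` and the
#'   variable.
#' @param variable column name to contrast.
#' @param reference reference treatment code (default `"CK"`).
#' @return data.frame with columns `variable`, `treatment`, `reference`,
#'   `value` (percent, NA when undefined), `undefined`.
#' @examples
#' cal <- default_calibration(cv = 0)
#' trial <- generate_trial(trial_design(seed = 1), cal$specs, cal$effects)
#' percent_changes(trial, "salt")   # CS -22, CB -18
#' @export
percent_changes <- function(records, variable, reference = "CK") {
  assert_columns(records, c("treatment", variable))
  if (!reference %in% records$treatment) {
    stop(sprintf("reference treatment '%s' not present", reference), call. = FALSE)
  }
  g <- factor(records$treatment, levels = unique(records$treatment))
  means <- tapply(records[[variable]], g, mean)
  ref_mean <- means[[reference]]
  undefined <- ref_mean <= 0
  value <- if (undefined) rep(NA_real_, length(means)) else {
    100 * (means - ref_mean) / ref_mean
  }
  data.frame(variable = variable, treatment = names(means),
             reference = reference, value = as.numeric(value),
             undefined = undefined, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Pairwise Pearson correlation panel
#'
#' Pearson r with two-sided t-test p-value for every pair of the named
#' variables, with significance stars (* p < 0.05, ** p < 0.01). Constant
#' variables yield undefined correlations: their pairs are NA and the
#' variable is listed under `flagged`.
#'
#' @param records plot-record data.frame.
#' @param variables character vector (>= 2) of column names.
#' @return An object of class `soilqual_corr`: list with symmetric
#'   matrices `r` and `p` (diagonal r = 1, p = NA), a long `table`
#'   (var1, var2, r, p, stars), and `flagged`.
#' @export
correlation_panel <- function(records, variables) {
  assert_columns(records, variables)
  if (length(variables) < 2) stop("need at least 2 variables", call. = FALSE)
  if (nrow(records) < 3) stop("need at least 3 paired observations", call. = FALSE)
  X <- records[variables]
  k <- length(variables)
  r <- p <- matrix(NA_real_, k, k, dimnames = list(variables, variables))
  diag(r) <- 1
  flagged <- variables[vapply(X, function(v) stats::sd(v) == 0, logical(1))]
  rows <- list()
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      ok <- !(variables[i] %in% flagged || variables[j] %in% flagged)
      if (ok) {
        ct <- stats::cor.test(X[[i]], X[[j]], method = "pearson")
        r[i, j] <- r[j, i] <- unname(ct$estimate)
        p[i, j] <- p[j, i] <- ct$p.value
      }
      stars <- if (!ok || is.na(p[i, j])) "" else if (p[i, j] < 0.01) "**" else if (p[i, j] < 0.05) "*" else ""
      rows[[length(rows) + 1]] <- data.frame(
        var1 = variables[i], var2 = variables[j],
        r = r[i, j], p = p[i, j], stars = stars,
        stringsAsFactors = FALSE)
    }
  }
  structure(list(r = r, p = p, table = do.call(rbind, rows), flagged = flagged),
            class = "soilqual_corr")
}

#' @export
print.soilqual_corr <- function(x, ...) {
  cat("Pairwise Pearson correlations (* p<0.05, ** p<0.01)\n")
  print(x$table, ...)
  if (length(x$flagged)) cat("flagged constant:", paste(x$flagged, collapse = ", "), "\n")
  invisible(x)
}
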