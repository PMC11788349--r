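test_that("one-way ANOVA matches hand-computed sums of squares", {
  # groups (1,2,3),(2,3,4),(3,4,5): SSB = 6, SSW = 6, F = 3 on (2, 6) df
  an <- oneway_anova(c(1, 2, 3, 2, 3, 4, 3, 4, 5), rep(c("A", "B", "C"), each = 3))
  expect_equal(an$F, 3, tolerance = 1e-10)
  expect_equal(an$df_between, 2)
  expect_equal(an$df_within, 6)
  expect_equal(an$mse_within, 1, tolerance = 1e-10)
  expect_equal(an$p, pf(3, 2, 6, lower.tail = FALSE), tolerance = 1e-10)
  expect_equal(unname(an$means), c(2, 3, 4))
  expect_equal(unname(an$se), rep(1 / sqrt(3), 3), tolerance = 1e-10)
})

test_that("ANOVA degenerate cases are well-defined", {
  expect_equal(oneway_anova(rep(c(1, 2, 3), 3), rep(c("A", "B", "C"), each = 3))$F, 0)
  an <- oneway_anova(rep(c(1, 2), each = 3), rep(c("A", "B"), each = 3))
  expect_identical(an$F, Inf)
  expect_identical(an$p, 0)
  expect_error(oneway_anova(1:4, c("A", "A", "A", "B")), "fewer than 2")
  expect_error(oneway_anova(1:4, rep("A", 4)), "at least 2 groups")
})

test_that("ANOVA is exchangeable under joint permutation and equals t^2 at k = 2", {
  set.seed(10)
  y <- rnorm(12)
  g <- rep(c("A", "B", "C"), each = 4)
  perm <- sample(12)
  a1 <- oneway_anova(y, g)
  a2 <- oneway_anova(y[perm], g[perm])
  expect_equal(a1$F, a2$F, tolerance = 1e-12)
  expect_equal(a1$means[sort(names(a1$means))], a2$means[sort(names(a2$means))])

  for (i in 1:10) {
    y2 <- rnorm(10, mean = rep(c(0, i / 5), each = 5))
    g2 <- rep(c("A", "B"), each = 5)
    an <- oneway_anova(y2, g2)
    tt <- t.test(y2[g2 == "A"], y2[g2 == "B"], var.equal = TRUE)
    expect_equal(an$F, unname(tt$statistic)^2, tolerance = 1e-10)
    expect_equal(an$p, tt$p.value, tolerance = 1e-10)
  }
})

test_that("Fisher's LSD letters agree with brute-force pairwise t tests", {
  # means (10, 5, 4.9) with small error: only the 10-vs-5 and 10-vs-4.9
  # pairs separate
  y <- c(10, 10.1, 9.9, 5, 5.1, 4.9, 4.9, 5.0, 4.8)
  g <- rep(c("T1", "T2", "T3"), each = 3)
  an <- oneway_anova(y, g)
  lsd <- fisher_lsd(an, alpha = 0.05)

  # oracle: pooled-error pairwise t tests
  mse <- an$mse_within
  for (pair in list(c("T1", "T2"), c("T1", "T3"), c("T2", "T3"))) {
    d <- an$means[pair[1]] - an$means[pair[2]]
    tstat <- d / sqrt(mse * (2 / 3))
    p_hand <- 2 * pt(-abs(tstat), an$df_within)
    expect_equal(lsd$p_matrix[pair[1], pair[2]], unname(p_hand), tolerance = 1e-12)
    expect_identical(lsd$significant[pair[1], pair[2]], unname(p_hand < 0.05))
  }
  expect_identical(unname(lsd$letters), c("a", "b", "b"))
  expect_equal(lsd$lsd_value,
               qt(0.975, 6) * sqrt(2 * mse / 3), tolerance = 1e-12)
})

test_that("LSD letter extremes: no separation and total separation", {
  set.seed(21)
  y_null <- rnorm(9, 5, 10)
  g <- rep(c("T1", "T2", "T3"), each = 3)
  lsd_null <- fisher_lsd(oneway_anova(y_null, g))
  expect_identical(unname(lsd_null$letters), c("a", "a", "a"))

  y_sep <- c(30, 30.1, 29.9, 20, 20.1, 19.9, 10, 10.1, 9.9)
  lsd_sep <- fisher_lsd(oneway_anova(y_sep, g))
  expect_identical(unname(lsd_sep$letters), c("a", "b", "c"))

  # protected LSD suppresses pairwise differences when the omnibus F is ns
  an <- oneway_anova(y_null, g)
  expect_identical(unname(fisher_lsd(an, protected = TRUE)$letters),
                   c("a", "a", "a"))
})

test_that("compact letters are a valid CLD for every 3-group pattern", {
  labs <- c("A", "B", "C")
  means <- setNames(c(3, 2, 1), labs)
  pairs <- list(c(1, 2), c(1, 3), c(2, 3))
  for (mask in 0:7) {
    sig <- matrix(FALSE, 3, 3, dimnames = list(labs, labs))
    for (b in 1:3) {
      if (bitwAnd(mask, bitwShiftL(1L, b - 1L))) {
        i <- pairs[[b]][1]; j <- pairs[[b]][2]
        sig[i, j] <- sig[j, i] <- TRUE
      }
    }
    lets <- compact_letters(sig, means)
    for (b in 1:3) {
      i <- pairs[[b]][1]; j <- pairs[[b]][2]
      share <- any(strsplit(lets[i], "")[[1]] %in% strsplit(lets[j], "")[[1]])
      expect_identical(share, !sig[i, j],
                       info = sprintf("pattern %d pair %s-%s", mask, labs[i], labs[j]))
    }
    # highest mean always carries "a"
    expect_match(lets[["A"]], "a")
  }
})

test_that("percent changes reproduce calibrated effects and flag bad references", {
  trial <- zero_noise_trial()
  pc <- percent_changes(trial, "salt")
  expect_equal(pc$value[pc$treatment == "CS"], -22, tolerance = 1e-9)
  expect_equal(pc$value[pc$treatment == "CB"], -18, tolerance = 1e-9)
  expect_equal(pc$value[pc$treatment == "CK"], 0)
  expect_equal(percent_changes(trial, "avN")$value[2], 91, tolerance = 1e-9)

  sc <- score_dataset(trial)$scores
  pc_emf <- percent_changes(sc, "EMF")
  expect_true(all(pc_emf$undefined))
  expect_true(all(is.na(pc_emf$value)))

  expect_error(percent_changes(trial, "salt", reference = "XX"), "XX")
})

test_that("correlation panel gives Pearson r, stars and symmetry", {
  d <- data.frame(x = c(1, 2, 3), y = c(2, 4, 7), z = c(3, 2, 1), w = c(5, 5, 5))
  cp <- correlation_panel(d, c("x", "y", "z", "w"))
  # hand oracle: r = 5 / sqrt(2 * 114/9)
  expect_equal(cp$r["x", "y"], 5 / sqrt(2 * 114 / 9), tolerance = 1e-10)
  expect_equal(cp$r["x", "y"], 0.99339927, tolerance = 1e-7)
  expect_equal(cp$r["x", "z"], -1, tolerance = 1e-12)
  expect_identical(cp$r, t(cp$r))
  expect_equal(unname(diag(cp$r)), rep(1, 4))
  expect_identical(cp$flagged, "w")
  expect_true(all(is.na(cp$r["w", c("x", "y", "z")])))

  set.seed(30)
  d2 <- data.frame(a = rnorm(20))
  d2$b <- d2$a + rnorm(20, sd = 0.01)
  cp2 <- correlation_panel(d2, c("a", "b"))
  expect_identical(cp2$table$stars, "**")
})
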