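test_that("directional linear scores follow v/v_max and v_min/v", {
  expect_equal(linear_scores(c(5, 10), "more_is_better"), c(0.5, 1.0))
  # hand oracle: v_min = 1.4664, so scores are 1, 1.4664/1.88, 1.4664/1.5416
  expect_equal(linear_scores(c(1.4664, 1.88, 1.5416), "less_is_better"),
               c(1, 0.78, 1.4664 / 1.5416), tolerance = 1e-12)
  # constant columns attain the favourable extreme everywhere
  expect_equal(linear_scores(c(3, 3, 3), "more_is_better"), c(1, 1, 1))
  expect_equal(linear_scores(c(3, 3, 3), "less_is_better"), c(1, 1, 1))
  expect_error(linear_scores(numeric(0), "more_is_better"), "empty")
  expect_error(linear_scores(c(0, 1), "less_is_better"), "zero")
})

test_that("radar-area SQI matches closed forms and the printed formula", {
  expect_equal(sqi(matrix(1, 1, 6)), 3 * sin(pi / 3), tolerance = 1e-12)
  expect_equal(sqi(matrix(1, 1, 4)), 2, tolerance = 1e-12)
  # hand-calculator evaluation of 0.5*sin(pi/3)*sum(Li^2)
  L <- matrix(c(0.78, 0.5236, 0.6712, 0.8, 1, 1), 1, 6)
  expect_equal(sqi(L), 1.7203881, tolerance = 1e-6)
  expect_error(sqi(matrix(1, 1, 2)), "fewer than 3")
  expect_error(sqi(matrix(c(1, 1.2, 1), 1, 3)), "\\(0, 1\\]")
  # adjacent-product variant agrees at the all-ones bound, differs inside
  expect_equal(sqi(matrix(1, 1, 6), variant = "adjacent"), 3 * sin(pi / 3))
  expect_lt(sqi(L, variant = "adjacent"), sqi(L))
})

test_that("SQI equals an independent transcription and respects its bounds", {
  set.seed(101)
  direct_area <- function(L) {
    out <- numeric(nrow(L))
    n <- ncol(L)
    for (r in seq_len(nrow(L))) {
      acc <- 0
      for (i in seq_len(n)) acc <- acc + L[r, i]^2
      out[r] <- 0.5 * acc * sin(2 * pi / n)
    }
    out
  }
  for (rep in 1:25) {
    n_plots <- sample(2:5, 1)
    n_props <- sample(3:6, 1)
    L <- matrix(runif(n_plots * n_props, 0.05, 1), n_plots, n_props)
    s <- sqi(L)
    expect_equal(s, direct_area(L), tolerance = 1e-12)
    expect_true(all(s > 0))
    expect_true(all(s <= sqi_bound(n_props) + 1e-12))
  }
  # bound attained iff all scores are 1
  expect_equal(sqi(matrix(1, 3, 5)), rep(sqi_bound(5), 3), tolerance = 1e-12)
  L <- matrix(1, 2, 5); L[2, 3] <- 0.999
  s <- sqi(L)
  expect_equal(s[1], sqi_bound(5), tolerance = 1e-12)
  expect_lt(s[2], sqi_bound(5))
})

test_that("raising the max-holder's value never hurts it or helps others", {
  set.seed(202)
  for (rep in 1:20) {
    vals <- matrix(runif(4 * 4, 1, 10), 4, 4)
    L0 <- apply(vals, 2, linear_scores, direction = "more_is_better")
    s0 <- sqi(L0)
    j <- sample(4, 1)
    holder <- which.max(vals[, j])
    vals2 <- vals
    vals2[holder, j] <- vals2[holder, j] * 1.5
    L1 <- apply(vals2, 2, linear_scores, direction = "more_is_better")
    s1 <- sqi(L1)
    expect_gte(s1[holder], s0[holder] - 1e-12)
    expect_true(all(s1[-holder] <= s0[-holder] + 1e-12))
  }
})

test_that("EMF is a centred row mean of per-enzyme Z-scores", {
  # two plots, one enzyme: Z-scores with sample sd are -sqrt(2)/2, +sqrt(2)/2
  expect_equal(emf(matrix(c(3, 9), 2, 1, dimnames = list(NULL, "BG"))),
               c(-sqrt(2) / 2, sqrt(2) / 2), tolerance = 1e-12)
  set.seed(303)
  m <- matrix(rexp(8 * 4, 0.1), 8, 4, dimnames = list(NULL, c("BG", "CE", "NAG", "LAP")))
  e <- emf(m)
  expect_equal(mean(e), 0, tolerance = 1e-10)
  z <- scale(m)
  expect_equal(unname(colMeans(z)), rep(0, 4), tolerance = 1e-10)
  expect_equal(unname(apply(z, 2, sd)), rep(1, 4), tolerance = 1e-10)
  # affine invariance of a single column
  m2 <- m
  m2[, 2] <- m2[, 2] * 10 + 5
  expect_equal(emf(m2), e, tolerance = 1e-10)
  m3 <- m
  m3[, 3] <- 7
  expect_error(emf(m3), "NAG")
})

test_that("score_dataset reproduces the hand-computed calibrated SQI", {
  trial <- zero_noise_trial()
  sc <- score_dataset(trial)
  m <- tapply(sc$scores$SQI, sc$scores$treatment, mean)
  expect_equal(unname(m[["CS"]]), SQI_CS_EXPECTED, tolerance = 1e-9)
  expect_equal(unname(m[["CK"]]), SQI_CK_EXPECTED, tolerance = 1e-9)
  expect_equal(sc$bound, sqi_bound(6))
  expect_equal(sc$n_properties, 6)
})

test_that("score_dataset is order-invariant and validates its inputs", {
  trial <- noisy_trial(seed = 5)
  sc <- score_dataset(trial)$scores
  perm <- sample(nrow(trial))
  sc_perm <- score_dataset(trial[perm, ])$scores
  key <- paste(sc$treatment, sc$replicate)
  key_perm <- paste(sc_perm$treatment, sc_perm$replicate)
  expect_equal(sc_perm$SQI, sc$SQI[match(key_perm, key)], tolerance = 1e-12)
  expect_equal(sc_perm$EMF, sc$EMF[match(key_perm, key)], tolerance = 1e-12)

  # single-treatment zero-noise data: every column constant, SQI at the bound
  cal <- default_calibration(cv = 0)
  solo <- generate_trial(trial_design(treatments = c("CK", "CK2"), seed = 1),
                         cal$specs, cal$effects)
  expect_equal(score_dataset(solo, emf_enzymes = character(0))$scores$SQI,
               rep(sqi_bound(6), 6), tolerance = 1e-12)

  expect_error(score_dataset(trial, sqi_properties = c("salt", "TN", "unobtanium")),
               "unobtanium")
  expect_error(score_dataset(trial, sqi_properties = c("salt", "TN", "pH")),
               "not_scored")
})
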