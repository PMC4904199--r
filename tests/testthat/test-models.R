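test_that("intercept-only fixed model recovers the grand mean", {
  set.seed(1)
  d <- data.frame(rt_ms = rnorm(100, 500, 50))
  fit <- fitMixed(modelSpec("rt_ms", character(0)), d)
  expect_equal(fit$coefficients$estimate, mean(d$rt_ms))
})

test_that("zero random-effect variance reproduces OLS fixed estimates", {
  set.seed(5)
  n <- 400
  d <- data.frame(participant_id = rep(1:20, each = n / 20),
                  x = rnorm(n))
  d$rt_ms <- 300 + 25 * d$x + rnorm(n, 0, 10)  # no subject effects
  ols <- coef(lm(rt_ms ~ x, d))
  fit <- fitMixed(modelSpec("rt_ms", "x", "(1 | participant_id)"), d)
  est <- setNames(fit$coefficients$estimate, fit$coefficients$term)
  expect_equal(unname(est["(Intercept)"]), unname(ols[1]),
               tolerance = 1e-6)
  expect_equal(unname(est["x"]), unname(ols[2]), tolerance = 1e-6)
})

test_that("rank-deficient fixed designs error with the aliased terms", {
  d <- data.frame(rt_ms = rnorm(20), x = 1:20)
  d$y <- 2 * d$x
  expect_error(fitMixed(modelSpec("rt_ms", c("x", "y")), d),
               "aliased.*y")
  expect_error(fitMixed(modelSpec("bogus", "x"), d), "not found")
})

test_that("likelihood-ratio bookkeeping is correct", {
  set.seed(3)
  d <- data.frame(g = factor(rep(letters[1:3], each = 30)),
                  y = rnorm(90))
  full <- fitMixed(modelSpec("y", "g"), d)
  red <- fitMixed(modelSpec("y", character(0)), d)
  lrt <- lrTest(full, red)
  expect_equal(lrt$df, 2L)            # dropping a 3-level factor
  expect_gte(lrt$chi_square, 0)
  self <- lrTest(full, full)
  expect_equal(self$chi_square, 0)
  expect_equal(self$p_value, 1)
  expect_error(lrTest(red, full), "not nested")
  sub <- d[c(1:20, 31:50, 61:80), ]     # all levels, fewer rows
  d2 <- fitMixed(modelSpec("y", "g"), sub)
  expect_error(lrTest(full, d2), "different numbers")
})

test_that("LRT chi-squares are invariant to shifting the outcome", {
  d <- screenedStudy(n = 4, seed = 5)
  spec1 <- modelSpec("rt_ms", c("light_condition", "tnorm"),
                     "(1 | participant_id)")
  spec0 <- modelSpec("rt_ms", "tnorm", "(1 | participant_id)")
  l1 <- lrTest(fitMixed(spec1, d), fitMixed(spec0, d))
  d$rt_ms <- d$rt_ms + 123.456
  l2 <- lrTest(fitMixed(spec1, d), fitMixed(spec0, d))
  expect_equal(l1$chi_square, l2$chi_square, tolerance = 1e-6)
})

test_that("random-structure pruning keeps real slopes and drops null ones", {
  ## genuine by-subject hemifield slope, no subject tnorm slope
  p <- generatorParams(subject_sd = c(intercept = 25, hemifield = 15,
                                      alpha = 0))
  d <- screenedStudy(p, n = 24, seed = 31)
  base <- modelSpec("rt_ms", c("light_condition * hemifield", "tnorm"),
                    "(1 | participant_id)")
  pr <- pruneRandomStructure(
    base, d, candidates = c("(0 + hemi_left | participant_id)",
                            "(0 + tnorm | participant_id)"))
  expect_true("(0 + hemi_left | participant_id)" %in% pr$spec$random)
  expect_false("(0 + tnorm | participant_id)" %in% pr$spec$random)
  expect_equal(nrow(pr$audit), 2L)
  expect_true(all(c("chi_square", "p_value", "converged", "retained")
                  %in% names(pr$audit)))
  ## empty candidate list returns the spec unchanged
  pr0 <- pruneRandomStructure(base, d, character(0))
  expect_identical(pr0$spec$random, base$random)
})

test_that("pruning under a null random structure keeps intercepts only", {
  p <- generatorParams(subject_sd = c(intercept = 20, hemifield = 0,
                                      alpha = 0))
  d <- screenedStudy(p, n = 12, seed = 77)
  base <- modelSpec("rt_ms", c("light_condition * hemifield", "tnorm"),
                    "(1 | participant_id)")
  pr <- pruneRandomStructure(
    base, d, candidates = c("(0 + hemi_left | participant_id)",
                            "(0 + tnorm | participant_id)"))
  expect_identical(pr$spec$random, "(1 | participant_id)")
})

test_that("pairwise contrasts follow the fitted coefficients", {
  set.seed(11)
  d <- data.frame(grp = factor(rep(c("a", "b"), each = 40)))
  d$y <- 2 + 3 * (d$grp == "b") + rnorm(80)
  fit <- fitMixed(modelSpec("y", "grp"), d)
  ct <- pairwiseContrasts(fit, "grp")
  expect_equal(nrow(ct), 1L)
  expect_equal(ct$estimate,
               fit$coefficients$estimate[fit$coefficients$term == "grpb"])
  expect_equal(ct$p_adj, ct$p_raw)     # single contrast: no adjustment
})

test_that("contrast adjustment is monotone and antisymmetric", {
  set.seed(12)
  d <- data.frame(grp = factor(rep(c("a", "b", "c"), each = 30)))
  d$y <- rnorm(90) + 0.5 * (d$grp == "c")
  fit <- fitMixed(modelSpec("y", "grp"), d)
  ct <- pairwiseContrasts(fit, "grp")
  expect_equal(nrow(ct), 3L)
  expect_true(all(ct$p_adj >= ct$p_raw))
  ## reversing the level order flips contrast signs exactly
  d$grp <- factor(d$grp, levels = c("c", "b", "a"))
  ctr <- pairwiseContrasts(fitMixed(modelSpec("y", "grp"), d), "grp")
  expect_equal(ctr$estimate[ctr$contrast == "a - c"],
               -ct$estimate[ct$contrast == "c - a"])
  expect_error(pairwiseContrasts(fit, "nothere"), "not a factor")
})

test_that("single-step adjustment dominates Bonferroni", {
  wins <- 0L; total <- 0L
  for (s in 1:12) {
    set.seed(100 + s)
    d <- data.frame(grp = factor(rep(c("a", "b", "c"), each = 15)),
                    y = rnorm(45))
    fit <- fitMixed(modelSpec("y", "grp"), d)
    ss <- pairwiseContrasts(fit, "grp", "single-step")
    bf <- pairwiseContrasts(fit, "grp", "bonferroni")
    wins <- wins + sum(ss$p_adj <= bf$p_adj + 1e-10)
    total <- total + nrow(ss)
  }
  expect_gte(wins / total, 0.99)
})

test_that("Yuen-Welch bootstrap test matches its contracts", {
  set.seed(21)
  x <- rnorm(12)
  ## identical samples: zero statistic, p near 1
  r <- yuenWelchBoot(x, x, seed = 2)
  expect_equal(r$statistic, 0)
  expect_gt(r$p_value, 0.9)
  ## 20% trimming at n = 12 ignores the largest observation entirely
  x2 <- x; x2[which.max(x2)] <- 10 * max(x2)
  expect_equal(mean(x, trim = 0.2), mean(x2, trim = 0.2))
  ## detects a large shift
  set.seed(22)
  r2 <- yuenWelchBoot(rnorm(15), rnorm(15) + 3, seed = 3)
  expect_lt(r2$p_value, 0.01)
  expect_error(yuenWelchBoot(rnorm(12), rnorm(12), trim = 0.5), "trim")
  expect_error(yuenWelchBoot(rnorm(3), rnorm(12)), "at least 5")
})
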