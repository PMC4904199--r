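test_that("response-time rules remove the constructed offenders", {
  tr <- data.frame(responded = TRUE,
                   rt_ms = c(150, 150, 1100, rep(500, 7)))
  out <- filterTrials(tr, NULL)
  expect_equal(unname(out$report$removed[["rt_low"]]), 2L)
  expect_equal(unname(out$report$removed[["rt_high"]]), 1L)
  expect_equal(out$report$surviving, 7L)
  expect_equal(out$report$n_input - sum(out$report$removed),
               out$report$surviving)
  expect_error(filterTrials(tr, NULL, "nonsense"))
})

test_that("the artifact screen removes exactly the contaminated trials", {
  ses <- tinySession(seed = 41, params = quietParams(noise_sd_uv = 5))
  inj <- injectArtifacts(ses$epochs, 0.3, 150, seed = 9)
  out <- filterTrials(ses$trials, inj$epochs, "pretarget")
  expect_equal(which(!out$kept), inj$contaminated)
})

test_that("desync-window screening keys on the response-locked window", {
  ## place a transient at -450 ms: inside the pretarget window but
  ## outside -100..RT+100
  es <- rawEpochs(array(0, c(1, 1, 950)))
  tt <- sampleTimes(es)
  es@voltages[1, 1, which(tt >= -460 & tt <= -440)] <- 200
  tr <- data.frame(responded = TRUE, rt_ms = 400)
  expect_false(filterTrials(tr, es, "pretarget")$kept)
  expect_true(filterTrials(tr, es, "desync")$kept)
})

test_that("RT and artifact screening is idempotent", {
  ses <- tinySession(seed = 43, params = generatorParams())
  out1 <- filterTrials(ses$trials, ses$epochs, "pretarget")
  sub <- ses$epochs[which(out1$kept), ]
  out2 <- filterTrials(out1$trials, sub, "pretarget")
  expect_equal(sum(out2$report$removed), 0L)
  expect_equal(out2$report$surviving, out1$report$surviving)
})

test_that("log transform behaves and flags non-positive trials", {
  expect_equal(as.numeric(transformAlpha(1)), 0)
  expect_equal(as.numeric(transformAlpha(exp(1))), 1)
  expect_equal(attr(transformAlpha(2), "transform"), "log")
  expect_error(transformAlpha(c(1, 0, 3)), "trial\\(s\\): 2")
  ## lognormal skew is removed by the transform
  set.seed(6)
  x <- rlnorm(10000, 0, 0.8)
  lx <- transformAlpha(x)
  g1 <- function(v) mean((v - mean(v))^3) / sd(v)^3
  expect_gt(abs(g1(x)), 1)
  expect_lt(abs(g1(lx)), 0.1)
})

test_that("outlier rule matches the normal-tail oracle", {
  ## degenerate group: all equal -> nothing removed
  expect_length(removeOutliers(rep(3, 10), rep("a", 10))$removed, 0L)
  ## planted outlier is the only removal
  set.seed(8)
  x <- c(rnorm(1000), 10)
  out <- removeOutliers(x, rep("a", 1001))
  expect_true(1001 %in% out$removed)
  expect_lte(length(out$removed), 4L)   # ~0.27% false removals expected
  ## tail mass ~ 2 Phi(-3) at large n
  set.seed(9)
  y <- rnorm(100000)
  frac <- length(removeOutliers(y, rep("a", length(y)))$removed) / 1e5
  bounds <- qbinom(c(0.005, 0.995), 1e5, 2 * pnorm(-3)) / 1e5
  expect_gte(frac, bounds[1])
  expect_lte(frac, bounds[2])
})

test_that("outlier removal respects the grouping structure", {
  ## a value normal for group b but extreme for group a
  x <- c(rnorm(50, 0, 0.1), rnorm(50, 10, 0.1), 10)
  g <- c(rep("a", 50), rep("b", 50), "a")
  out <- removeOutliers(x, g)
  expect_equal(out$removed, 101L)
})
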