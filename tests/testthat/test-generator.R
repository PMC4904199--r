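test_that("identical seeds give bit-identical sessions", {
  a <- tinySession(seed = 99, params = generatorParams())
  b <- tinySession(seed = 99, params = generatorParams())
  expect_identical(a$trials, b$trials)
  expect_identical(a$epochs@voltages, b$epochs@voltages)
})

test_that("noise-free alpha yields the rectified-sine envelope 2A/pi", {
  p <- quietParams(alpha_base = 10)
  ses <- tinySession(seed = 5, params = p)
  env <- alphaEnvelope(bandpassAlpha(baselineEpochs(ses$epochs)))
  expected <- 2 * 10 / pi
  full <- env@values[, match("PO7", env@channelLabels), ]  # weight 1.0
  expect_true(all(abs(full / expected - 1) < 0.03))
  half <- env@values[, match("PO3", env@channelLabels), ]  # weight 0.5
  expect_true(all(abs(half / (expected / 2) - 1) < 0.03))
})

test_that("generated RTs recover the alpha coupling slope at n = 10,000", {
  sch <- makeSchedule(scheduleConfig(n_blocks = 209), seed = 2) # 10032 trials
  ses <- simulateSession(list(participant_id = 1, light_condition = "low",
                              condition_order = 1, seed = 12),
                         generatorParams(), sch, render_eeg = FALSE)
  d <- ses$trials
  dev <- d$log_alpha_pooled_true - mean(d$log_alpha_pooled_true)
  fit <- lm(rt_ms ~ dev + hemifield, data = d)
  est <- coef(summary(fit))["dev", ]
  true <- generatorParams()$alpha_rt_slope_ms[1]
  expect_lt(abs(est["Estimate"] - true), 3 * est["Std. Error"])
})

test_that("right-hemisphere envelope is monotone in light level", {
  d <- simulateStudy(n_participants = 6, seed = 8)
  m <- tapply(d$env_right_true, factor(d$light_condition,
                                       c("low", "medium", "high")), mean)
  expect_true(m[["low"]] <= m[["medium"]])
  expect_true(m[["medium"]] <= m[["high"]])
})

test_that("artifact injection matches its contract", {
  ses <- tinySession(seed = 3)
  ## rate 0: identity
  out0 <- injectArtifacts(ses$epochs, 0, 150, seed = 1)
  expect_identical(out0$epochs@voltages, ses$epochs@voltages)
  expect_length(out0$contaminated, 0L)
  ## rate 1, amplitude 150: every trial trips the +/-100 uV screen
  out1 <- injectArtifacts(ses$epochs, 1, 150, seed = 1)
  expect_equal(out1$contaminated, seq_len(nTrials(ses$epochs)))
  scr <- filterTrials(ses$trials, out1$epochs, "pretarget")
  expect_equal(unname(scr$report$removed[["artifact"]]),
               nTrials(ses$epochs))
  ## sub-threshold amplitude is flagged
  expect_warning(injectArtifacts(ses$epochs, 0.5, 90, seed = 1),
                 "100 microvolt")
})

test_that("contamination count at rate 0.1 sits in the binomial band", {
  ## 1000 silent trials, 2 channels
  es <- rawEpochs(array(0, c(1000, 2, 950)), c("O1", "O2"))
  out <- injectArtifacts(es, 0.1, 150, seed = 21)
  bounds <- qbinom(c(0.005, 0.995), 1000, 0.1)
  expect_gte(length(out$contaminated), bounds[1])
  expect_lte(length(out$contaminated), bounds[2])
  ## transients land inside the pre-target screen window
  tt <- sampleTimes(es)
  pre <- which(tt >= -500 & tt <= 0)
  hit <- apply(abs(out$epochs@voltages[out$contaminated, , pre]) > 100,
               1, any)
  expect_true(all(hit))
})

test_that("generator parameter invariants are enforced", {
  expect_error(generatorParams(artifact_rate = 1.2), "artifact_rate")
  expect_error(generatorParams(light_gain_right = c(1, -1, 1)),
               "positive")
  expect_error(generatorParams(resid_sd_ms = -1), "non-negative")
  expect_error(generatorParams(alpha_rt_slope_ms = c(1, 2)), "length 3")
})
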