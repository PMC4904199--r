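test_that("baselining zeroes window means and is idempotent", {
  ## constant epoch -> all zeros
  es <- rawEpochs(array(7, c(2, 1, 950)))
  expect_true(all(baselineEpochs(es)@voltages == 0))
  ## random epoch -> post-hoc window means vanish
  set.seed(4)
  es <- rawEpochs(array(rnorm(3 * 2 * 950), c(3, 2, 950)), c("O1", "O2"))
  b1 <- baselineEpochs(es)
  tt <- sampleTimes(b1)
  idx <- which(tt >= -100 & tt < 0)
  mu <- rowMeans(b1@voltages[, , idx, drop = FALSE], dims = 2)
  expect_true(all(abs(mu) < 1e-9))
  ## second application is a numerical no-op
  b2 <- baselineEpochs(b1)
  expect_equal(b2@voltages, b1@voltages, tolerance = 1e-12)
  expect_error(baselineEpochs(es, c(-2000, -1900)), "outside")
})

test_that("alpha band-pass passes 10 Hz, rejects DC and band edges", {
  tt <- seq(-700, 1198, by = 2)
  for (method in c("spectral", "filtfilt")) {
    sine <- rawEpochs(array(sin(2 * pi * 10 * tt / 1000),
                            c(1, 1, length(tt))))
    f <- bandpassAlpha(sine, method = method)
    keep <- tt >= -500 & tt <= 998     # discard 200 ms edges
    rms <- function(x) sqrt(mean(x^2))
    expect_lt(abs(rms(f@voltages[1, 1, keep]) /
                    rms(sine@voltages[1, 1, keep]) - 1), 0.05)
    dc <- rawEpochs(array(1, c(1, 1, length(tt))))
    fdc <- bandpassAlpha(dc, method = method)
    expect_lt(rms(fdc@voltages[1, 1, keep]), 0.01)
  }
  expect_error(bandpassAlpha(rawEpochs(array(0, c(1, 1, 950))),
                             band = c(13, 8)), "low < high")
  expect_error(bandpassAlpha(rawEpochs(array(0, c(1, 1, 950))),
                             band = c(8, 300)), "Nyquist")
})

test_that("white-noise transfer at 2 and 30 Hz is below -20 dB (DFT oracle)", {
  set.seed(9)
  n <- 950
  es <- rawEpochs(array(rnorm(20 * n), c(20, 1, n)))
  f <- bandpassAlpha(es, method = "spectral")
  freqs <- (seq_len(n) - 1) * 500 / n
  gainAt <- function(hz) {
    bin <- which.min(abs(freqs - hz))
    num <- den <- 0
    for (i in 1:20) {
      X <- fft(es@voltages[i, 1, ]); Y <- fft(f@voltages[i, 1, ])
      num <- num + Mod(Y[bin])^2; den <- den + Mod(X[bin])^2
    }
    10 * log10(num / den)
  }
  expect_lt(gainAt(2), -20)
  expect_lt(gainAt(30), -20)
  expect_gt(gainAt(10.5), -1)
})

test_that("spectral and filtfilt band-pass agree away from the edges", {
  set.seed(12)
  es <- rawEpochs(array(rnorm(4 * 950), c(4, 1, 950)))
  e1 <- alphaEnvelope(bandpassAlpha(es, method = "spectral"))
  e2 <- alphaEnvelope(bandpassAlpha(es, method = "filtfilt"))
  g <- e1@gridTimesMs
  mid <- g >= -100 & g <= 600     # deep interior
  expect_lt(max(abs(e1@values[, , mid] - e2@values[, , mid])) /
              mean(e2@values[, , mid]), 0.05)
})

test_that("envelope equals the closed form for a pure sinusoid", {
  tt <- seq(-700, 1198, by = 2)
  A <- 5
  es <- rawEpochs(array(A * sin(2 * pi * 10 * tt / 1000),
                        c(1, 1, length(tt))))
  env <- alphaEnvelope(bandpassAlpha(es))
  expect_true(all(abs(env@values / (2 * A / pi) - 1) < 0.03))
  ## trimmed support: -500..1000 ms, no window within 200 ms of an edge
  expect_equal(range(env@gridTimesMs), c(-450, 950))
  expect_true(all(env@gridTimesMs - 50 >= -500))
  expect_true(all(env@gridTimesMs + 50 <= 1000))
})

test_that("envelope matches a brute-force windowed-mean oracle", {
  set.seed(31)
  es <- rawEpochs(array(rnorm(2 * 2 * 950), c(2, 2, 950)),
                  c("O1", "O2"))
  ## oracle on the rectified raw signal (no filtering)
  env <- alphaEnvelope(es)
  tt <- sampleTimes(es)
  for (k in seq_along(env@gridTimesMs)) {
    s <- env@gridTimesMs[k] - 50
    idx <- which(tt >= s & tt < s + 100)
    for (i in 1:2) for (j in 1:2)
      expect_equal(env@values[i, j, k],
                   mean(abs(es@voltages[i, j, idx])), tolerance = 1e-12)
  }
})

test_that("envelope scales exactly with the voltages", {
  set.seed(7)
  es <- rawEpochs(array(rnorm(950), c(1, 1, 950)))
  k <- 3.7
  esk <- rawEpochs(k * es@voltages)
  e1 <- alphaEnvelope(bandpassAlpha(es))
  e2 <- alphaEnvelope(bandpassAlpha(esk))
  expect_equal(e2@values, k * e1@values, tolerance = 1e-10)
})

test_that("pre-target summary pools windows and electrodes correctly", {
  labs <- c("P3", "PO3", "P4", "PO4")
  pools <- list(left = c("P3", "PO3"), right = c("P4", "PO4"))
  ## constant envelope c -> every summary equals c
  sc <- handSeries(array(2.5, c(3, 4, 29)), labs)
  out <- pretargetAlpha(sc, pools)
  expect_true(all(out$alpha_left == 2.5 & out$alpha_right == 2.5 &
                    out$alpha_pooled == 2.5))
  ## left pool 2, right pool 4 -> (2, 4, 3)
  v <- array(0, c(1, 4, 29)); v[, 1:2, ] <- 2; v[, 3:4, ] <- 4
  out <- pretargetAlpha(handSeries(v, labs), pools)
  expect_equal(unlist(out[1, 1:3], use.names = FALSE), c(2, 4, 3))
  ## random series match a nested-loop oracle
  set.seed(17)
  v <- array(abs(rnorm(2 * 4 * 29)), c(2, 4, 29))
  s <- handSeries(v, labs)
  out <- pretargetAlpha(s, pools)
  g <- s@gridTimesMs
  wi <- which(g - 50 >= -500 & g + 50 <= 0)
  for (i in 1:2) {
    expect_equal(out$alpha_left[i], mean(v[i, 1:2, wi]))
    expect_equal(out$alpha_right[i], mean(v[i, 3:4, wi]))
    expect_equal(out$alpha_pooled[i], mean(v[i, , wi]))
  }
  expect_error(pretargetAlpha(s, list(left = "P9", right = "P4")),
               "unknown electrode")
})

test_that("desynchronisation metric follows step-function arithmetic", {
  g <- seq(-450, 950, by = 50)
  ## trial 1: right-hemifield target (contralateral for a left electrode)
  ## with envelope stepping 1.0 -> 0.5 at 50 ms; trial 2: left target, flat
  v <- array(1, c(2, 1, length(g)))
  v[1, 1, g - 50 >= 50] <- 0.5
  s <- handSeries(v, "PO7")
  trials <- data.frame(hemifield = c("right", "left"))
  d <- posttargetDesync(s, trials, electrodes = "PO7")
  expect_equal(d$desync_contra, -0.5, tolerance = 1e-12)
  expect_equal(d$desync_ipsi, 0, tolerance = 1e-12)
  expect_equal(d$diff, -0.5, tolerance = 1e-12)
  expect_error(posttargetDesync(s, trials, electrodes = "POz"),
               "midline")
})

test_that("no desynchronisation is generated when the depth is zero", {
  ses <- tinySession(seed = 13, params = quietParams(desync_depth = 0,
                                                     noise_sd_uv = 2))
  env <- alphaEnvelope(bandpassAlpha(baselineEpochs(ses$epochs)))
  d <- posttargetDesync(env, ses$trials)
  expect_true(all(abs(d$diff) < 0.25))   # noise-level fluctuation only
})

test_that("pooled summaries are invariant under left-right mirroring", {
  set.seed(23)
  labs <- c("P3", "P4")
  v <- array(abs(rnorm(4 * 2 * 29)) + 0.5, c(4, 2, 29))
  s <- handSeries(v, labs)
  pools <- list(left = "P3", right = "P4")
  a <- pretargetAlpha(s, pools)
  ## mirror: relabel each channel with its homologue (data unchanged)
  sm <- handSeries(v, c("P4", "P3"))
  am <- pretargetAlpha(sm, pools)
  expect_equal(a$alpha_left, am$alpha_right)
  expect_equal(a$alpha_right, am$alpha_left)
  expect_equal(a$alpha_pooled, am$alpha_pooled)
})
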