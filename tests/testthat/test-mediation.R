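test_that("Sobel arithmetic matches the normal-quadrature oracle", {
  ## z = 0 gives p = 1
  expect_equal(sobelFromSummary(0, 1), list(z = 0, p = 1))
  expect_error(sobelFromSummary(0.3, 0), "positive")
  set.seed(14)
  for (i in 1:10) {
    est <- rnorm(1); se <- runif(1, 0.05, 2)
    st <- sobelFromSummary(est, se)
    oracle <- 2 * integrate(dnorm, abs(est / se), Inf,
                            rel.tol = 1e-12)$value
    expect_equal(st$p, oracle, tolerance = 1e-6)
  }
})

test_that("paths decompose exactly in the fixed-effects-only case", {
  set.seed(15)
  n <- 300
  d <- data.frame(light_condition = rep(c("low", "high"), each = n / 2))
  tr <- as.numeric(d$light_condition == "high")
  d$log_alpha_right <- 0.4 * tr + rnorm(n, 0, 0.5)
  d$rt_ms <- 500 - 8 * tr + 6 * d$log_alpha_right + rnorm(n, 0, 20)
  m <- mediationSobel(d, random = character(0))
  p <- m@paths
  ## OLS identity: c = c' + a b, exactly
  expect_equal(p[["c"]], p[["c_prime"]] + m@indirect, tolerance = 1e-10)
  expect_equal(m@indirect, p[["a"]] * p[["b"]], tolerance = 1e-12)
  expect_equal(m@sobelSe,
               sqrt(p[["b"]]^2 * p[["se_a"]]^2 +
                      p[["a"]]^2 * p[["se_b"]]^2), tolerance = 1e-12)
})

test_that("mediation is equivariant to rescaling the mediator", {
  set.seed(16)
  n <- 200
  d <- data.frame(light_condition = rep(c("low", "high"), each = n / 2),
                  participant_id = rep(1:10, times = n / 10))
  tr <- as.numeric(d$light_condition == "high")
  d$log_alpha_right <- 0.3 * tr + rnorm(n, 0, 0.4)
  d$rt_ms <- 500 - 5 * tr + 8 * d$log_alpha_right + rnorm(n, 0, 15)
  m1 <- mediationSobel(d, random = character(0), standardize = FALSE)
  k <- 4
  d2 <- d; d2$log_alpha_right <- k * d$log_alpha_right
  m2 <- mediationSobel(d2, random = character(0), standardize = FALSE)
  expect_equal(m2@paths[["a"]], k * m1@paths[["a"]], tolerance = 1e-8)
  expect_equal(m2@paths[["b"]], m1@paths[["b"]] / k, tolerance = 1e-8)
  expect_equal(m2@indirect, m1@indirect, tolerance = 1e-8)
  expect_equal(m2@sobelZ, m1@sobelZ, tolerance = 1e-8)
  expect_equal(m2@sobelP, m1@sobelP, tolerance = 1e-8)
})

test_that("input contracts are enforced", {
  d <- data.frame(light_condition = rep(c("low", "medium"), 10),
                  log_alpha_right = rnorm(20), rt_ms = rnorm(20))
  expect_error(mediationSobel(d), "binary")
  d2 <- data.frame(light_condition = rep(c("low", "high"), 10),
                   log_alpha_right = 1, rt_ms = rnorm(20))
  expect_error(mediationSobel(d2), "constant")
})

test_that("the calibrated generator produces inconsistent mediation", {
  d <- screenedStudy(n = 24, seed = 20)
  d <- d[d$hemifield == "left" & d$light_condition %in% c("low", "high"), ]
  m <- mediationSobel(d)
  expect_gt(m@paths[["a"]], 0)          # light raises right-hemisphere alpha
  expect_gt(m@paths[["b"]], 0)          # higher alpha slows RT
  expect_lt(m@paths[["c_prime"]], 0)    # yet high light speeds RT
  expect_equal(m@consistency, "inconsistent")
  expect_lt(m@sobelP, 0.05)
})

test_that("a null treatment-to-mediator path yields a null indirect effect", {
  p <- generatorParams(light_gain_left = c(1, 1, 1),
                       light_gain_right = c(1, 1, 1))
  ps <- sapply(1:15, function(s) {
    d <- screenedStudy(p, n = 12, seed = 400 + s)
    d <- d[d$hemifield == "left" &
             d$light_condition %in% c("low", "high"), ]
    m <- mediationSobel(d)
    c(m@sobelP, m@indirect)
  })
  ## around alpha = 0.05 rejections and indirect effects centred on zero
  expect_lte(sum(ps[1, ] < 0.05), 3L)
  expect_lt(abs(mean(ps[2, ])), 0.2)
})
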