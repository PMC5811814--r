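test_that("model constructor validates the constant consistency", {
  m <- adam()
  expect_s3_class(m, "adam")
  expect_equal(coef(m)[["kp"]], 0.04)
  expect_equal(coef(m)[["static_stimulus"]], 0.35)
  expect_error(adam(kp = -0.1))
  expect_error(adam(static_stimulus = 0.4), "must equal")
})

test_that("normalization divides by the constant and enforces the range", {
  m <- adam()
  expect_equal(normalize_value(3500, m), 0.35)
  expect_equal(normalize_value(0, m), 0)
  expect_equal(normalize_value(4021.44, m), 0.402144)
  expect_error(normalize_value(-1, m), "unit interval")
  expect_error(normalize_value(10001, m), "unit interval")
})

test_that("stimulus and task items are 0.35 or the normalized last value", {
  m <- adam()
  pos <- zero_noise_series("positive")
  posi <- zero_noise_series("positive", "inconsistent")
  neg <- zero_noise_series("negative")
  expect_equal(stimulus_item(m, pos, "static"), 0.35)
  expect_equal(stimulus_item(m, pos, "historic_dynamic"), 0.402144)
  expect_equal(stimulus_item(m, pos, "momentary_dynamic"), 0.402144)
  expect_equal(stimulus_item(m, posi, "momentary_dynamic"), 0.35)
  expect_equal(task_item(m, pos, "judgment"), 0.35)
  expect_equal(task_item(m, neg, "forecast"), 0.297856)
  expect_equal(task_item(m, zero_noise_series("stationary"), "forecast"), 0.35)
  expect_error(stimulus_item(m, numeric(0), "static"), "non-empty")
})

test_that("similarity weight is exponential in the signed distance", {
  expect_equal(similarity_weight(0.35, 0.35), 1)
  # frozen from independent evaluation of exp(0.052144)
  expect_equal(similarity_weight(0.35, 0.402144), 1.0535274395,
               tolerance = 1e-9)
  set.seed(1)
  for (i in 1:20) {
    S <- runif(1); T <- runif(1)
    expect_equal(similarity_weight(S, T) * similarity_weight(T, S), 1)
    if (S < T) expect_gt(similarity_weight(S, T), 1)
  }
  expect_error(similarity_weight(-0.1, 0.5))
})

test_that("experience anchor is 3500 (static) or the last value (dynamic)", {
  m <- adam()
  pos <- zero_noise_series("positive")
  expect_equal(experience_anchor(m, pos, "static"), 3500)
  expect_equal(experience_anchor(m, pos, "historic_dynamic"), 4021.44)
  for (dir in c("positive", "negative", "stationary")) {
    expect_equal(
      experience_anchor(m, zero_noise_series(dir, "inconsistent"),
                        "momentary_dynamic"), 3500)
  }
})

test_that("deterministic responses (kp = 0) match the closed forms", {
  m <- adam(kp = 0)
  pos <- zero_noise_series("positive")
  neg <- zero_noise_series("negative")
  # dynamic forecast returns the last element; static judgment the mean
  for (mode in c("historic_dynamic", "momentary_dynamic")) {
    expect_equal(behavioral_response(m, pos, mode, "forecast"), 4021.44)
    expect_equal(behavioral_response(m, neg, mode, "forecast"), 2978.56)
  }
  expect_equal(behavioral_response(m, pos, "static", "judgment"), 3500)
  # frozen independent evaluations of SW * EA
  expect_equal(behavioral_response(m, pos, "static", "forecast"),
               3687.3460384, tolerance = 1e-9)
  expect_equal(behavioral_response(m, neg, "static", "forecast"),
               3322.1726066, tolerance = 1e-9)
  expect_equal(behavioral_response(m, pos, "historic_dynamic", "judgment"),
               3817.1193735, tolerance = 1e-9)
  expect_equal(predict(m, pos, "static", "forecast"),
               behavioral_response(m, pos, "static", "forecast"))
})

test_that("both dynamic modes produce identically distributed responses", {
  m <- adam(kp = 0.04)
  sp <- trend_spec("positive", "consistent")
  a <- simulate_condition(m, sp, "historic_dynamic", "forecast", n = 200,
                          seed = 9)
  b <- simulate_condition(m, sp, "momentary_dynamic", "forecast", n = 200,
                          seed = 9)
  expect_identical(a, b)
})

test_that("response mean and SD follow the multiplicative-noise contract", {
  set.seed(21)
  m <- adam(kp = 0.04)
  pos <- generate_series(trend_spec("positive", "consistent"))
  for (mode in c("static", "historic_dynamic")) {
    for (task in c("forecast", "judgment")) {
      mu <- predict(m, pos, mode, task)
      draws <- behavioral_response(m, pos, mode, task, n = 1e4)
      expect_equal(mean(draws), mu, tolerance = 0.01)
      expect_equal(sd(draws) / (mu * 0.04), 1, tolerance = 0.03)
    }
  }
})

test_that("simulated cells are reproducible and deterministic when noise-free", {
  m0 <- adam(kp = 0)
  sp0 <- trend_spec("positive", "consistent", noise_variance = 0)
  r <- simulate_condition(m0, sp0, "historic_dynamic", "forecast", n = 90,
                          seed = 3)
  expect_equal(r, rep(4021.44, 90))
  m <- adam(kp = 0.04)
  sp <- trend_spec("negative", "consistent")
  r1 <- simulate_condition(m, sp, "static", "judgment", n = 90, seed = 17)
  r2 <- simulate_condition(m, sp, "static", "judgment", n = 90, seed = 17)
  expect_identical(r1, r2)
  expect_error(simulate_condition(m, sp, "static", "judgment", n = 0), ">= 1")
})

test_that("at kp = 0 every mode and task yields 3500 on inconsistent trends", {
  m <- adam(kp = 0)
  for (dir in c("positive", "negative", "stationary")) {
    s <- zero_noise_series(dir, "inconsistent")
    for (mode in c("static", "historic_dynamic", "momentary_dynamic")) {
      for (task in c("forecast", "judgment")) {
        expect_equal(behavioral_response(m, s, mode, task), 3500)
      }
    }
  }
})

test_that("trend damping and anchoring emerge from the deterministic model", {
  m <- adam(kp = 0)
  pos <- zero_noise_series("positive")
  neg <- zero_noise_series("negative")
  next_pos <- 4042.72
  next_neg <- 2957.28
  # static forecasts damp the trend beyond the last-element error
  expect_lt(behavioral_response(m, pos, "static", "forecast"), next_pos)
  expect_gt(behavioral_response(m, neg, "static", "forecast"), next_neg)
  expect_gt(abs(behavioral_response(m, pos, "static", "forecast") - next_pos),
            abs(behavioral_response(m, pos, "historic_dynamic", "forecast") -
                  next_pos))
  expect_gt(abs(behavioral_response(m, neg, "static", "forecast") - next_neg),
            abs(behavioral_response(m, neg, "momentary_dynamic", "forecast") -
                  next_neg))
  # dynamic judgments anchor on the recent values; static judgment is exact
  expect_gt(behavioral_response(m, pos, "historic_dynamic", "judgment"), 3500)
  expect_lt(behavioral_response(m, neg, "momentary_dynamic", "judgment"), 3500)
  expect_equal(behavioral_response(m, pos, "static", "judgment"), 3500)
})

test_that("simulate method mirrors simulate_condition", {
  m <- adam(kp = 0.04)
  sp <- trend_spec("stationary", "consistent")
  expect_identical(
    simulate(m, nsim = 25, seed = 4, spec = sp, mode = "static",
             task = "forecast"),
    simulate_condition(m, sp, "static", "forecast", n = 25, seed = 4))
})
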