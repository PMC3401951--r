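test_that("angular_error returns the minimal signed wrap of the difference", {
  expect_equal(angular_error(0.3, 0.3, pi), 0)
  # orientations are pi-periodic: a full period apart is the same orientation
  expect_equal(angular_error(0.8 + pi, 0.8, pi), 0)
  expect_equal(angular_error(2.1, 2.1 + 3 * pi, pi), 0)

  # brute force over wrap candidates: the result must be the smallest
  # |response - target + k * period| and lie in (-period/2, period/2]
  cases <- expand.grid(r = c(0.1, 1.5, 3.0, 0.77), t = c(0.0, 0.6, 3.0, 2.9))
  for (i in seq_len(nrow(cases))) {
    got <- angular_error(cases$r[i], cases$t[i], pi)
    cand <- cases$r[i] - cases$t[i] + (-3:3) * pi
    expect_lte(abs(got), min(abs(cand)) + 1e-12)
    expect_true(got > -pi / 2 && got <= pi / 2)
    expect_true(any(abs(cand - got) < 1e-12))
  }

  expect_error(angular_error(NaN, 0), "finite")
  expect_error(angular_error(0, Inf), "finite")
  expect_error(angular_error(0, 0, period = -1), "positive")
})

test_that("circular_sd matches the closed-form resultant and caps at the floor", {
  expect_equal(circular_sd(rep(0.4, 10)), 0)

  # two errors at +/- delta on the doubled circle: Rbar = cos(delta)
  for (delta in c(0.2, 0.7, 1.0)) {
    expect_equal(circular_sd(c(delta, -delta), period = 2 * pi),
                 sqrt(-2 * log(cos(delta))), tolerance = 1e-12)
  }
  # beyond the n = 2 resolution floor (Rbar < 1/2) the SD is capped
  expect_equal(circular_sd(c(1.2, -1.2), period = 2 * pi),
               sqrt(-2 * log(0.5)), tolerance = 1e-12)
  expect_equal(circular_sd(c(1.2, -1.2), period = 2 * pi, rbar_floor = 0),
               sqrt(-2 * log(cos(1.2))), tolerance = 1e-12)

  # invariances: permutation, sign flip, rotation of responses and targets
  set.seed(42)
  resp <- runif(40, 0, pi); targ <- runif(40, 0, pi)
  err <- angular_error(resp, targ, pi)
  base <- circular_sd(err)
  expect_equal(circular_sd(sample(err)), base, tolerance = 1e-12)
  expect_equal(circular_sd(-err), base, tolerance = 1e-12)
  for (shift in c(0.3, 1.1, 2.9)) {
    err_rot <- angular_error((resp + shift) %% pi, (targ + shift) %% pi, pi)
    expect_equal(circular_sd(err_rot), base, tolerance = 1e-12)
    expect_equal(precision(err_rot, chance = 0.2)$corrected_precision,
                 precision(err, chance = 0.2)$corrected_precision,
                 tolerance = 1e-12)
  }

  # near-uniform sample: SD is large but bounded by the resolution cap
  set.seed(7)
  u <- runif(10000, 0, pi)
  sd_u <- circular_sd(u)
  expect_gt(sd_u, 2.5)
  expect_lte(sd_u, sqrt(2 * log(10000)))

  expect_error(circular_sd(0.3), "at least 2")
})

test_that("chance precision is positive, decreasing in n, and seed-stable", {
  ns <- c(5, 10, 25, 30, 90)
  vals <- vapply(ns, function(n) chance_precision(n, 10000L, seed = 3L), numeric(1))
  expect_true(all(vals > 0))
  expect_true(all(diff(vals) <= 0))

  # Monte Carlo consistency: two seeds agree within 3 standard errors,
  # with the SE taken from an explicit replicate simulation
  set.seed(99)
  reps <- replicate(3000, {
    a <- runif(30, 0, 2 * pi)
    rbar <- max(sqrt(mean(cos(a))^2 + mean(sin(a))^2), 1 / 30)
    1 / sqrt(-2 * log(rbar))
  })
  se <- sd(reps) / sqrt(10000)
  e1 <- chance_precision(30, 10000L, seed = 1L)
  e2 <- chance_precision(30, 10000L, seed = 2L)
  expect_lt(abs(e1 - e2), 3 * sqrt(2) * se)

  expect_error(chance_precision(1), ">= 2")
  expect_error(chance_precision(30, 100), ">= 1000")
})

test_that("precision is 1/SD minus chance, ~0 for random responding", {
  # construct a sample with exact SD 0.25 on the doubled scale
  delta <- acos(exp(-0.25^2 / 2))
  p <- precision(c(delta, -delta), chance = 0.1, period = 2 * pi)
  expect_equal(p$circular_sd, 0.25, tolerance = 1e-12)
  expect_equal(p$raw_precision, 4, tolerance = 1e-12)
  expect_equal(p$corrected_precision, 3.9, tolerance = 1e-12)
  expect_equal(p$n_trials, 2L)
  expect_equal(p$chance_method, "monte_carlo")

  # uniform random responding scores ~0 after matched chance correction
  chance <- chance_precision(30, 10000L, seed = 5L)
  set.seed(123)
  reps <- replicate(200, {
    err <- angular_error(runif(30, 0, pi), runif(30, 0, pi), pi)
    precision(err, chance = chance)$corrected_precision
  })
  se <- sd(reps) / sqrt(length(reps))
  expect_lt(abs(mean(reps)), 3 * se)

  # tighter dispersion than chance gives positive corrected precision
  tight <- precision(rnorm(30, 0, 0.1), chance = chance, period = 2 * pi)
  expect_gt(tight$corrected_precision, 0)
})

test_that("variance-subtraction corrections follow the stated formulas", {
  expect_equal(as.numeric(sensorimotor_corrected_precision(0.5, 0.3)), 2.5,
               tolerance = 1e-12)
  for (s in c(0.2, 0.9, 1.7)) {
    expect_equal(as.numeric(sensorimotor_corrected_precision(s, 0)), 1 / s,
                 tolerance = 1e-12)
  }
  und <- sensorimotor_corrected_precision(0.3, 0.5)
  expect_true(is.na(und))
  expect_true(isTRUE(attr(und, "undefined")))

  # exact identity 1/sqrt((a^2+b^2) - b^2) = 1/a
  for (a in c(0.1, 0.5, 2)) {
    for (b in c(0, 0.3, 1.5)) {
      expect_equal(as.numeric(sensorimotor_corrected_precision(sqrt(a^2 + b^2), b)),
                   1 / a, tolerance = 1e-10)
    }
  }
  expect_error(sensorimotor_corrected_precision(-0.1, 0.2), "non-negative")

  expect_equal(as.numeric(precision_difference(sqrt(2) * 0.4, 0.4)), 1 / 0.4,
               tolerance = 1e-12)
  expect_equal(as.numeric(precision_difference(1.0, 0.6)), 1.25, tolerance = 1e-12)
  expect_true(is.na(precision_difference(0.7, 0.7)))
})

test_that("rvonmises concentrates around mu and reduces to uniform at kappa 0", {
  set.seed(31)
  x <- rvonmises(5000, 1.2, 50)
  expect_lt(circular_sd(angular_error(x, 1.2, 2 * pi), period = 2 * pi), 0.25)
  u <- rvonmises(2000, 0, 0)
  expect_gt(rayleigh_p(u), 0.01)
})
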