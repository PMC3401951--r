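test_that("cohort generation is deterministic and respects the configured design", {
  cfg <- cohort_config(seed = 77)
  cohort <- generate_cohort(cfg)
  expect_equal(nrow(cohort), 87L)
  expect_true(all(cohort$age >= 7.9 & cohort$age <= 13.6))
  expect_true(all(cohort$kappa1 > 0 & cohort$kappa3 > 0 & cohort$sm_sd > 0))
  expect_true(all(abs(cohort$alpha3 + cohort$beta3 + cohort$gamma3 - 1) < 1e-8))

  # byte-identical regeneration from the same master seed
  study1 <- generate_study(cohort_config(n_participants = 5, seed = 12))
  study2 <- generate_study(cohort_config(n_participants = 5, seed = 12))
  expect_identical(study1, study2)

  # IQ covariate correlates with age at the configured strength
  expect_lt(abs(cor(cohort$age, cohort$fsiq_e) - 0.26), 0.15)

  # constant-kappa config produces no age-kappa correlation
  null_cfg <- cohort_config(n_participants = 500, kappa3 = 3, kappa1 = 8,
                            seed = 4)
  null_cohort <- generate_cohort(null_cfg)
  expect_lt(abs(cor(null_cohort$age, null_cohort$kappa3)), 0.1)

  # infeasible configs are rejected up front
  expect_error(cohort_config(kappa3 = c(-10, 0.5)), "non-positive")
  expect_error(cohort_config(alpha3 = 0.9, beta3 = 0.2, gamma3 = 0.1), "invalid")
  expect_error(cohort_config(n_participants = 0), "positive")
})

test_that("three-item orientation sets respect the minimum separation", {
  set.seed(41)
  tri <- sample_orientation_triples(20000, 0.175)
  sep <- function(a, b) {
    d <- abs(a - b) %% pi
    pmin(d, pi - d)
  }
  min_sep <- min(sep(tri[, 1], tri[, 2]), sep(tri[, 1], tri[, 3]),
                 sep(tri[, 2], tri[, 3]))
  expect_gte(min_sep, 0.175)
  expect_true(all(tri >= 0 & tri < pi))
})

test_that("pooled stimulus orientations stay effectively uniform", {
  # rejection sampling at 0.175 rad separation barely perturbs uniformity:
  # Rayleigh test (doubled angles) non-significant in nearly all seeded runs
  pvals <- vapply(1:40, function(s) {
    set.seed(s)
    tri <- sample_orientation_triples(700, 0.175)
    rayleigh_p(2 * as.vector(tri))
  }, numeric(1))
  expect_gte(mean(pvals > 0.01), 0.95)
})

test_that("trial generation delivers the designed session structure", {
  cfg <- cohort_config(n_participants = 2, seed = 6)
  cohort <- generate_cohort(cfg)
  trials <- generate_trials(cohort[1, ], cfg, seed = 60)

  expect_equal(sum(trials$condition == "sensorimotor"), 25L)
  expect_equal(sum(trials$condition == "vwm1"), 30L)
  expect_equal(sum(trials$condition == "vwm3"), 90L)

  v3 <- trials[trials$condition == "vwm3", ]
  expect_true(all(lengths(v3$stimulus_orientations) == 3L))
  expect_true(all(vapply(v3$stimulus_colours,
                         function(x) anyDuplicated(x) == 0, logical(1))))
  expect_true(all(unlist(v3$stimulus_orientations) >= 0 &
                    unlist(v3$stimulus_orientations) < pi))
  expect_true(all(trials$response_orientation >= 0 &
                    trials$response_orientation < pi))

  # probed uniformly among the three items: 3 binomial SEs over 9000 trials
  big_cfg <- cohort_config(
    n_participants = 1,
    n_trials = c(sensorimotor = 2, vwm1 = 2, vwm3 = 9000), seed = 8
  )
  big <- generate_trials(generate_cohort(big_cfg)[1, ], big_cfg, seed = 9)
  probed <- big$probed_index[big$condition == "vwm3"]
  se3 <- sqrt((1 / 3) * (2 / 3) / 9000)
  for (sp in 1:3) {
    expect_lt(abs(mean(probed == sp) - 1 / 3), 3 * se3)
  }
})

test_that("sensorimotor responses carry only the configured motor noise", {
  cfg <- cohort_config(
    n_participants = 1,
    n_trials = c(sensorimotor = 10000, vwm1 = 2, vwm3 = 2), seed = 3
  )
  prof <- generate_cohort(cfg)[1, ]
  prof$sm_sd <- 0.2
  trials <- generate_trials(prof, cfg, seed = 30)
  sm <- trials[trials$condition == "sensorimotor", ]
  err <- angular_error(sm$response_orientation,
                       vapply(sm$stimulus_orientations, `[[`, numeric(1), 1), pi)
  expect_lt(abs(circular_sd(err) - 0.2) / 0.2, 0.05)
})

test_that("session truncation removes trials only as configured", {
  cfg <- cohort_config(n_participants = 87, seed = 10)
  study <- generate_study(cfg)
  expect_identical(truncate_sessions(study$trials, 0), study$trials)

  cut <- truncate_sessions(study$trials, 4 / 87, seed = 2)
  counts <- table(cut$participant_id[cut$condition == "vwm3"])
  expect_equal(sum(counts < 90), 4L)
  expect_true(all(counts >= 45))
  # other conditions untouched
  expect_equal(sum(cut$condition == "vwm1"), 87L * 30L)
  expect_error(truncate_sessions(study$trials, 1), "0, 1")
})
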