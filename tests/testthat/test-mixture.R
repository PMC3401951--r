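test_that("von Mises density matches a quadrature Bessel oracle and normalises", {
  # uniform limit
  expect_equal(vonmises_density(c(0, 1, 3), 0.5, 0), rep(1 / (2 * pi), 3))

  # peak density at kappa = 2 against I0 computed by quadrature
  i0 <- bessel_quadrature(2, 0)
  expect_equal(vonmises_density(1.1, 1.1, 2), exp(2) / (2 * pi * i0),
               tolerance = 1e-10)

  for (k in c(0.5, 5, 50)) {
    intg <- integrate(function(x) vonmises_density(x, 1, k), 0, 2 * pi,
                      rel.tol = 1e-10)
    expect_equal(intg$value, 1, tolerance = 1e-6)
  }

  expect_error(vonmises_density(0, 0, 1e4), "overflow")
  expect_error(vonmises_density(0, 0, -1), ">= 0")
})

test_that("Bessel-ratio inversion is a two-sided inverse of A1", {
  for (r in c(0.01, 0.2, 0.52, 0.6, 0.84, 0.9, 0.99)) {
    k <- vwmprecision:::a1_inv(r)
    expect_equal(vwmprecision:::bessel_a1(k), r, tolerance = 1e-8)
  }
  expect_equal(vwmprecision:::a1_inv(0), 0)
  expect_equal(vwmprecision:::a1_inv(1), 700)
})

test_that("mixture log-likelihood follows the component densities", {
  geom1 <- trial_geometry(target = 1.0, response = 2.5,
                          nontargets = matrix(c(3, 5), 1))
  expect_equal(mixture_loglik(geom1, mixture_params(3, 0, 0, 1)),
               log(1 / (2 * pi)), tolerance = 1e-12)

  geom2 <- trial_geometry(target = 1.3, response = 1.3)
  i0 <- bessel_quadrature(2, 0)
  expect_equal(mixture_loglik(geom2, mixture_params(2, 1, 0, 0)),
               log(exp(2) / (2 * pi * i0)), tolerance = 1e-9)

  # permutation invariance over trials
  params <- mixture_params(4, 0.7, 0.1, 0.2)
  sim <- make_vwm3_geometry(60, params, seed = 8)
  perm <- withr::with_seed(1, sample(60))
  shuffled <- trial_geometry(sim$target[perm], sim$response[perm],
                             sim$nontargets[perm, ])
  expect_equal(mixture_loglik(shuffled, params), mixture_loglik(sim, params),
               tolerance = 1e-10)

  # beta > 0 is invalid without non-targets
  expect_error(mixture_loglik(geom2, mixture_params(2, 0.8, 0.1, 0.1)),
               "non-target")
})

test_that("mixture parameter validation enforces the simplex and kappa bounds", {
  expect_error(mixture_params(2, 0.5, 0.2, 0.2), "sum to 1")
  expect_error(mixture_params(2, 1.2, -0.2, 0), "0, 1")
  expect_error(mixture_params(-1, 0.5, 0.2, 0.3), "kappa")
  p <- mixture_params(5, 0.8, 0.1)
  expect_equal(p$p_uniform, 0.1, tolerance = 1e-12)
})

test_that("simulated responses have the requested component mix", {
  params <- mixture_params(8, 0.6, 0.25, 0.15)
  geom <- make_vwm3_geometry(100000, mixture_params(8, 1, 0, 0), seed = 2)
  sim <- simulate_responses(params, trial_geometry(geom$target,
                                                   nontargets = geom$nontargets),
                            seed = 11)
  frac <- prop.table(table(attr(sim, "component")))
  # empirical fractions within 3 binomial SEs at n = 1e5
  expect_lt(abs(frac[["target"]] - 0.6), 3 * sqrt(0.6 * 0.4 / 1e5))
  expect_lt(abs(frac[["nontarget"]] - 0.25), 3 * sqrt(0.25 * 0.75 / 1e5))
  expect_lt(abs(frac[["uniform"]] - 0.15), 3 * sqrt(0.15 * 0.85 / 1e5))

  # noiseless limit: responses sit on the targets
  tight <- simulate_responses(mixture_params(650, 1, 0, 0),
                              trial_geometry(runif(200, 0, 2 * pi)), seed = 3)
  expect_lt(max(abs(angular_error(tight$response, tight$target, 2 * pi))), 0.2)

  # pure guessing: uniform responses (Rayleigh non-significant in most runs)
  pu <- vapply(1:100, function(s) {
    g <- trial_geometry(runif(500, 0, 2 * pi))
    rayleigh_p(simulate_responses(mixture_params(0, 0, 0, 1), g, seed = s)$response)
  }, numeric(1))
  expect_gte(mean(pu > 0.01), 0.95)
})

test_that("EM recovers generating parameters from large simulated datasets", {
  truth <- mixture_params(8, 0.8, 0.1, 0.1)
  sim <- make_vwm3_geometry(5000, truth, seed = 14)
  fit <- fit_em(sim, seed = 7)
  expect_true(fit$converged)
  expect_lt(abs(fit$params$p_target - 0.8), 0.03)
  expect_lt(abs(fit$params$p_nontarget - 0.1), 0.03)
  expect_lt(abs(fit$params$p_uniform - 0.1), 0.03)
  expect_lt(abs(fit$params$kappa - 8) / 8, 0.15)
  # simplex-valid to tight tolerance
  expect_equal(fit$params$p_target + fit$params$p_nontarget + fit$params$p_uniform,
               1, tolerance = 1e-10)
})

test_that("EM on pure-guessing data lands on the uniform ridge and flags kappa", {
  # with gamma = 1 the likelihood is flat along the kappa ~ 0 ridge where
  # the von Mises components coincide with the uniform: the fit must reach
  # the uniform log-likelihood and declare kappa unidentifiable
  sim <- make_vwm3_geometry(400, mixture_params(1, 0, 0, 1), seed = 5)
  fit <- fit_em(sim, seed = 5)
  # the fit gains essentially nothing over the uniform model ...
  expect_lt(fit$log_likelihood - 400 * log(1 / (2 * pi)), qchisq(0.95, 2) / 2)
  expect_equal(fit$log_likelihood, 400 * log(1 / (2 * pi)),
               tolerance = 0.01 * 400 * abs(log(1 / (2 * pi))))
  # ... so kappa (and the weight split) is flagged unidentifiable
  expect_false(fit$kappa_identifiable)
})

test_that("EM never falls below the grid-search oracle", {
  kappa_grid <- c(1, 2, 4, 6, 8, 12)
  weight_grid <- seq(0, 1, by = 0.1)
  for (s in 1:10) {
    truth <- mixture_params(6, 0.75, 0.1, 0.15)
    sim <- make_vwm3_geometry(200, truth, seed = 100 + s)
    em <- fit_em(sim, seed = s)
    oracle <- grid_oracle_fit(sim, kappa_grid, weight_grid)
    expect_gte(em$log_likelihood, oracle$log_likelihood - 1e-9)
  }
})

test_that("grid oracle is an arg-max and handles degenerate grids", {
  sim <- make_vwm3_geometry(100, mixture_params(5, 0.7, 0.1, 0.2), seed = 21)
  oracle <- grid_oracle_fit(sim, c(2, 5, 9), seq(0, 1, 0.25))
  # no grid point beats the returned one
  for (k in c(2, 5, 9)) {
    for (a in seq(0, 1, 0.25)) {
      for (b in seq(0, 1, 0.25)) {
        if (a + b > 1) next
        ll <- mixture_loglik(sim, mixture_params(k, a, b, 1 - a - b))
        expect_lte(ll, oracle$log_likelihood + 1e-12)
      }
    }
  }
  single <- grid_oracle_fit(sim, 5, 0.5)
  expect_equal(single$params$kappa, 5)
  expect_equal(single$params$p_target, 0.5)
  expect_error(grid_oracle_fit(sim, numeric(0), 0.5), "empty")
  big <- trial_geometry(runif(501), runif(501))
  expect_error(grid_oracle_fit(big, 1, 0.5), "500")
})

test_that("one-item fits reduce exactly to the two-component model", {
  set.seed(9)
  g0 <- trial_geometry(runif(1000, 0, 2 * pi))
  sim <- simulate_responses(mixture_params(6, 0.85, 0, 0.15), g0, seed = 9)
  fit <- fit_em(sim, seed = 9)
  expect_equal(fit$params$p_nontarget, 0)

  # independent direct optimisation of the two-component likelihood
  nll <- function(par) {
    a <- plogis(par[1]); k <- exp(par[2])
    -mixture_loglik(sim, mixture_params(k, a, 0, 1 - a))
  }
  opt <- optim(c(qlogis(0.8), log(5)), nll, method = "L-BFGS-B",
               lower = c(-10, log(1e-3)), upper = c(10, log(650)))
  expect_equal(fit$log_likelihood, -opt$value, tolerance = 1e-6)
})

test_that("per-group concentrations recover serial-position structure", {
  truth <- mixture_params(3, 0.75, 0.08, 0.17)
  sim <- make_vwm3_geometry(6000, truth, seed = 33, sp_boost = 3)
  probed <- attr(sim, "probed")
  fit <- fit_em(sim, groups = probed, seed = 4)
  expect_length(fit$kappa_by_group, 3)
  # SP3 concentration ~3x SP1/2
  expect_gt(fit$kappa_by_group[3], 2 * fit$kappa_by_group[1])
  expect_lt(abs(fit$kappa_by_group[1] - 3) / 3, 0.2)
  expect_lt(abs(fit$kappa_by_group[3] - 9) / 9, 0.2)
  # weights still recovered
  expect_lt(abs(fit$params$p_target - 0.75), 0.03)
  # grouped fit cannot be worse than the shared-kappa fit
  shared <- fit_em(sim, seed = 4)
  expect_gte(fit$log_likelihood, shared$log_likelihood - 1e-6)
})
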