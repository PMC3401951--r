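# Shared fixture builders (all data generated in code, seeded).

# Three-item trial geometry with simulated mixture responses, on the
# doubled-angle space. Optionally applies a serial-position kappa boost as
# the study design does.
make_vwm3_geometry <- function(n, params, seed, sp_boost = NULL) {
  withr::with_seed(seed, {
    ori <- sample_orientation_triples(n, 0.175)
    probed <- sample.int(3L, n, replace = TRUE)
    target <- 2 * ori[cbind(seq_len(n), probed)]
    nts <- 2 * t(vapply(seq_len(n), function(i) ori[i, -probed[i]], numeric(2)))
    geom <- trial_geometry(target, nontargets = nts)
    if (is.null(sp_boost)) {
      sim <- simulate_responses(params, geom, seed = seed + 1L)
    } else {
      # boost the target concentration when SP3 is probed
      resp <- numeric(n)
      comp <- character(n)
      for (b in c(FALSE, TRUE)) {
        idx <- which((probed == 3L) == b)
        p <- mixture_params(params$kappa * if (b) sp_boost else 1,
                            params$p_target, params$p_nontarget,
                            params$p_uniform)
        sub <- trial_geometry(target[idx], nontargets = nts[idx, , drop = FALSE])
        s <- simulate_responses(p, sub, seed = seed + 1L + b)
        resp[idx] <- s$response
        comp[idx] <- as.character(attr(s, "component"))
      }
      sim <- trial_geometry(target, resp, nts)
      attr(sim, "component") <- factor(comp, c("target", "nontarget", "uniform"))
    }
    attr(sim, "probed") <- probed
    sim
  })
}

# Modified Bessel function of the first kind, order nu, by numerical
# quadrature: an oracle independent of base besselI and of the package.
bessel_quadrature <- function(kappa, nu = 0) {
  stats::integrate(function(t) exp(kappa * cos(t)) * cos(nu * t), 0, pi,
                   rel.tol = 1e-12)$value / pi
}

# Rayleigh test p-value for circular uniformity (large-sample approximation).
rayleigh_p <- function(angles) {
  n <- length(angles)
  rbar <- sqrt(mean(cos(angles))^2 + mean(sin(angles))^2)
  z <- n * rbar^2
  exp(-z) * (1 + (2 * z - z^2) / (4 * n))
}
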