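# Three-component mixture model of continuous-report response error:
# a von Mises component centred on the target (probability alpha), von Mises
# components centred on each non-target (misbinding, total probability beta
# split uniformly over the m non-targets), and a uniform guessing component
# (gamma = 1 - alpha - beta). A single concentration kappa is shared by the
# target and non-target components. All angles are on the doubled,
# 2*pi-periodic representation of orientation space.

KAPPA_MAX <- 700  # besselI overflows shortly beyond this

#' von Mises probability density
#'
#' `exp(kappa * cos(x - mu)) / (2 * pi * I0(kappa))`, evaluated with
#' exponentially scaled Bessel functions so large concentrations do not
#' overflow.
#'
#' @param x angles (radians, 2*pi-periodic space).
#' @param mu mean direction.
#' @param kappa concentration (>= 0); `kappa = 0` is the circular uniform.
#' @param kappa_max overflow guard; `kappa` beyond this is an error.
#' @return densities (1/rad).
#' @export
vonmises_density <- function(x, mu = 0, kappa, kappa_max = KAPPA_MAX) {
  if (!is.numeric(kappa) || any(!is.finite(kappa)) || any(kappa < 0)) {
    stop_invalid("`kappa` must be finite and >= 0")
  }
  if (any(kappa > kappa_max)) {
    stop_invalid(sprintf("`kappa` exceeds overflow guard kappa_max = %g", kappa_max))
  }
  exp(kappa * (cos(x - mu) - 1)) / (2 * pi * besselI(kappa, 0, expon.scaled = TRUE))
}

# Bessel function ratio A1(kappa) = I1(kappa) / I0(kappa).
bessel_a1 <- function(kappa) {
  besselI(kappa, 1, expon.scaled = TRUE) / besselI(kappa, 0, expon.scaled = TRUE)
}

# Invert A1: find kappa with I1(kappa)/I0(kappa) = rbar. Two-regime
# closed-form approximation (Fisher 1993) refined by Newton steps using
# A1'(k) = 1 - A1/k - A1^2.
a1_inv <- function(rbar, kappa_max = KAPPA_MAX) {
  if (!is.finite(rbar)) stop_invalid("`rbar` must be finite")
  if (rbar <= 0) return(0)
  if (rbar >= 1) return(kappa_max)
  k <- if (rbar < 0.53) {
    2 * rbar + rbar^3 + 5 * rbar^5 / 6
  } else if (rbar < 0.85) {
    -0.4 + 1.39 * rbar + 0.43 / (1 - rbar)
  } else {
    1 / (rbar^3 - 4 * rbar^2 + 3 * rbar)
  }
  k <- min(max(k, 1e-8), kappa_max)
  for (i in 1:8) {
    a <- bessel_a1(k)
    d <- 1 - a / k - a^2
    if (!is.finite(d) || d <= 0) break
    step <- (a - rbar) / d
    k <- k - step
    if (!is.finite(k) || k <= 0) {
      k <- 1e-8
      break
    }
    if (abs(step) < 1e-10) break
  }
  min(max(k, 0), kappa_max)
}

#' Mixture parameters (target / non-target / uniform weights + concentration)
#'
#' @param kappa shared von Mises concentration, in `[0, kappa_max]`.
#' @param p_target probability alpha of reporting the target.
#' @param p_nontarget probability beta of reporting one of the non-targets
#'   (misbinding); split uniformly across them.
#' @param p_uniform probability gamma of a uniform random response; defaults
#'   to `1 - p_target - p_nontarget`.
#' @param kappa_max upper bound for `kappa`.
#' @return a validated `mixture_params` list.
#' @export
mixture_params <- function(kappa, p_target, p_nontarget = 0,
                           p_uniform = 1 - p_target - p_nontarget,
                           kappa_max = KAPPA_MAX) {
  p <- c(p_target, p_nontarget, p_uniform)
  if (any(!is.finite(p)) || any(p < -1e-10) || any(p > 1 + 1e-10)) {
    stop_invalid("mixture probabilities must lie in [0, 1]")
  }
  if (abs(sum(p) - 1) > 1e-10) {
    stop_invalid("mixture probabilities must sum to 1 (within 1e-10)")
  }
  if (!is.finite(kappa) || kappa < 0 || kappa > kappa_max) {
    stop_invalid(sprintf("`kappa` must lie in [0, %g]", kappa_max))
  }
  structure(
    list(kappa = kappa, p_target = max(p_target, 0),
         p_nontarget = max(p_nontarget, 0), p_uniform = max(p_uniform, 0)),
    class = "mixture_params"
  )
}

#' Per-trial geometry for the mixture model
#'
#' Bundles target orientation, non-target orientations and (optionally)
#' response for a set of trials, all on the doubled 2*pi-periodic space.
#' The number of non-targets `m` must be shared by all trials (0 for
#' one-item data, 2 for the three-item design).
#'
#' @param target numeric vector of target angles.
#' @param response numeric vector of responses, or `NULL` for
#'   geometry-without-response (input to [simulate_responses()]).
#' @param nontargets numeric matrix (`length(target)` rows) of non-target
#'   angles, or `NULL` for `m = 0`.
#' @return a `trial_geometry` list with elements `target`, `response`,
#'   `nontargets`, `n`, `m`.
#' @export
trial_geometry <- function(target, response = NULL, nontargets = NULL) {
  assert_finite(target, "target")
  n <- length(target)
  if (!is.null(response)) {
    assert_finite(response, "response")
    if (length(response) != n) stop_invalid("`response` must match `target` length")
  }
  if (is.null(nontargets)) {
    nontargets <- matrix(numeric(0), nrow = n, ncol = 0)
  } else {
    if (is.vector(nontargets)) nontargets <- matrix(nontargets, nrow = n)
    assert_finite(c(nontargets), "nontargets")
    if (nrow(nontargets) != n) stop_invalid("`nontargets` must have one row per trial")
  }
  structure(
    list(target = wrap_angle(target, 2 * pi),
         response = if (is.null(response)) NULL else wrap_angle(response, 2 * pi),
         nontargets = wrap_angle(nontargets, 2 * pi),
         n = n, m = ncol(nontargets)),
    class = "trial_geometry"
  )
}

#' Mixture model log-likelihood
#'
#' Sum over trials of
#' `log(alpha * vm(err_T) + (beta/m) * sum_k vm(err_NTk) + gamma / (2*pi))`.
#' With `m = 0` the non-target term is absent and `p_nontarget` must be 0.
#'
#' @param geometry a [trial_geometry()] with responses.
#' @param params a [mixture_params()].
#' @return the log-likelihood (scalar).
#' @export
mixture_loglik <- function(geometry, params) {
  stopifnot(inherits(geometry, "trial_geometry"), inherits(params, "mixture_params"))
  if (geometry$n < 1L) stop_invalid("`geometry` must contain at least one trial")
  if (is.null(geometry$response)) stop_invalid("`geometry` has no responses")
  if (geometry$m == 0L && params$p_nontarget > 0) {
    stop_invalid("p_nontarget > 0 is invalid for trials without non-target items")
  }
  cosT <- cos(geometry$response - geometry$target)
  k <- params$kappa
  i0 <- besselI(k, 0, expon.scaled = TRUE)
  dens <- params$p_target * exp(k * (cosT - 1)) / (2 * pi * i0) +
    params$p_uniform / (2 * pi)
  if (geometry$m > 0L && params$p_nontarget > 0) {
    cosNT <- cos(geometry$response - geometry$nontargets)
    dens <- dens + rowSums((params$p_nontarget / geometry$m) *
                             exp(k * (cosNT - 1)) / (2 * pi * i0))
  }
  sum(log(pmax(dens, 1e-300)))
}

# One EM run from a given start. Precomputed cosines/sines of the response
# errors relative to each component centre keep the per-iteration cost to a
# handful of vectorised operations.
# One EM run. `grp` partitions trials into groups sharing a concentration
# (a single group gives the standard common-kappa model); mixture weights
# are always shared across groups.
em_single <- function(cosT, cosNT, grp, n_grp, start, tol, max_iter, kappa_max) {
  n <- length(cosT)
  m <- if (is.null(cosNT)) 0L else ncol(cosNT)
  a <- start$alpha; b <- start$beta; g <- start$gamma
  k <- rep(start$kappa, n_grp)
  ll_old <- -Inf
  converged <- FALSE
  it <- 0L
  repeat {
    it <- it + 1L
    ktr <- k[grp]
    inv_norm <- 1 / (2 * pi * besselI(k, 0, expon.scaled = TRUE))[grp]
    dT <- a * exp(ktr * (cosT - 1)) * inv_norm
    dU <- g / (2 * pi)
    if (m > 0L) {
      dNT <- (b / m) * exp(ktr * (cosNT - 1)) * inv_norm
      L <- dT + dU + rowSums(dNT)
    } else {
      L <- dT + dU
    }
    L <- pmax(L, 1e-300)
    ll <- sum(log(L))
    if (!is.finite(ll)) stop("degenerate likelihood")
    # EM guarantees a non-decreasing likelihood; a real decrease means a bug
    if (ll < ll_old - 1e-8) stop("EM log-likelihood decreased")
    if (abs(ll - ll_old) < tol) {
      converged <- TRUE
      break
    }
    if (it >= max_iter) break
    ll_old <- ll
    wT <- dT / L
    wU <- dU / L
    a <- mean(wT)
    g <- mean(wU)
    # The component means are fixed at zero (target- / non-target-aligned),
    # so the exact M-step for kappa inverts A1 against the responsibility-
    # weighted mean cosine of the aligned errors (the resultant component
    # along the component axis), not the free-mean resultant magnitude.
    if (m > 0L) {
      wNT <- dNT / L
      b <- max(1 - a - g, 0)
      rc_tr <- wT * cosT + rowSums(wNT * cosNT)
      w_tr <- wT + rowSums(wNT)
    } else {
      b <- 0
      rc_tr <- wT * cosT
      w_tr <- wT
    }
    for (j in seq_len(n_grp)) {
      sel <- grp == j
      rc <- sum(rc_tr[sel])
      wsum <- sum(w_tr[sel])
      if (wsum < 1e-10 * sum(sel) || rc <= 0) {
        k[j] <- 0  # no (or anti-aligned) responsibility mass in this group
      } else {
        k[j] <- a1_inv(min(rc / wsum, 1 - 1e-12), kappa_max)
      }
    }
  }
  list(alpha = a, beta = b, gamma = g, kappa = k,
       loglik = ll, n_iter = it, converged = converged)
}

#' Fit the mixture model by expectation-maximization
#'
#' Maximum-likelihood fit of ([mixture_params()]) to a set of trials. The
#' E-step computes per-trial component responsibilities; the M-step updates
#' the weights as mean responsibilities and `kappa` by inverting the Bessel
#' ratio `A1(kappa) = I1/I0` against the responsibility-weighted resultant
#' of target- and non-target-aligned errors (the component along each
#' component's axis, since the component means are fixed). A deterministic
#' method-of-moments start is supplemented with random restarts; the best
#' log-likelihood wins.
#'
#' With `groups` given (e.g. the probed serial position of each trial), the
#' mixture weights remain shared across all trials but each group receives
#' its own concentration; `params$kappa` is then the trial-count-weighted
#' mean concentration across groups ("mean across serial positions"), and
#' the per-group values are returned in `kappa_by_group`. This accommodates
#' designs where dispersion differs systematically between serial positions
#' (recency), which a single shared `kappa` would misattribute to the
#' uniform component.
#'
#' @param geometry a [trial_geometry()] with responses; all trials share the
#'   same number of non-targets.
#' @param n_restarts number of additional random starts (default 9).
#' @param tol convergence tolerance on the log-likelihood change.
#' @param max_iter iteration cap per start.
#' @param min_trials smallest admissible dataset (default 20).
#' @param kappa_max concentration bound.
#' @param seed optional seed for the random restarts.
#' @param groups optional per-trial factor (or vector) giving the
#'   concentration groups; `NULL` fits a single shared `kappa`.
#' @return a `mixture_fit`: `params`, `log_likelihood`, `n_iterations`,
#'   `converged`, `n_restarts_used`, `n_trials`, `m`, `kappa_by_group`,
#'   `kappa_identifiable` (FALSE when essentially no von Mises
#'   responsibility remains), `method`.
#' @export
fit_em <- function(geometry, n_restarts = 9L, tol = 1e-6, max_iter = 10000L,
                   min_trials = 20L, kappa_max = KAPPA_MAX, seed = NULL,
                   groups = NULL) {
  stopifnot(inherits(geometry, "trial_geometry"))
  if (is.null(geometry$response)) stop_invalid("`geometry` has no responses")
  if (geometry$n < min_trials) {
    stop_invalid(sprintf("fit_em() needs at least %d trials (got %d)",
                         min_trials, geometry$n))
  }
  if (is.null(groups)) {
    grp <- rep(1L, geometry$n)
    n_grp <- 1L
  } else {
    if (length(groups) != geometry$n) {
      stop_invalid("`groups` must have one entry per trial")
    }
    grp <- as.integer(factor(groups))
    n_grp <- max(grp)
  }
  errT <- geometry$response - geometry$target
  cosT <- cos(errT); sinT <- sin(errT)
  m <- geometry$m
  cosNT <- if (m > 0L) cos(geometry$response - geometry$nontargets) else NULL

  # Method-of-moments start: kappa from the resultant of target errors as if
  # all responses were target reports.
  rbar0 <- min(sqrt(mean(cosT)^2 + mean(sinT)^2), 1 - 1e-12)
  moment <- list(alpha = if (m > 0L) 0.6 else 0.8,
                 beta = if (m > 0L) 0.2 else 0,
                 gamma = if (m > 0L) 0.2 else 0.2,
                 kappa = a1_inv(rbar0, kappa_max))

  starts <- list(moment)
  if (n_restarts > 0L) {
    rand <- with_seed(seed, {
      lapply(seq_len(n_restarts), function(i) {
        w <- stats::runif(3)
        if (m == 0L) w[2] <- 0
        w <- w / sum(w)
        list(alpha = w[1], beta = w[2], gamma = w[3],
             kappa = exp(stats::runif(1, log(0.5), log(100))))
      })
    })
    starts <- c(starts, rand)
  }

  best <- NULL
  used <- 0L
  for (s in starts) {
    used <- used + 1L
    res <- tryCatch(
      em_single(cosT, cosNT, grp, n_grp, s, tol, max_iter, kappa_max),
      error = function(e) NULL
    )
    if (is.null(res)) next
    if (is.null(best) || res$loglik > best$loglik) best <- res
  }
  if (is.null(best)) stop_invalid("all EM starts failed (degenerate data?)")
  if (!best$converged) {
    warning("EM did not converge within max_iter; returning best fit with converged = FALSE")
  }
  # renormalise tiny numerical drift before constructing validated params
  w <- c(best$alpha, best$beta, best$gamma)
  w <- pmax(w, 0); w <- w / sum(w)
  kappa_by_group <- best$kappa
  kappa_mean <- sum(kappa_by_group * tabulate(grp, n_grp)) / geometry$n
  # kappa is meaningless when the von Mises components carry no weight, or
  # when the data are uniform: at kappa ~ 0 the von Mises components
  # coincide with the uniform and the weights sit on a flat ridge, so the
  # fitted weights are arbitrary. Flag via the likelihood-ratio margin over
  # the pure-uniform model (chi-square 95% bar with 2 free parameters).
  ll_uniform <- geometry$n * log(1 / (2 * pi))
  identifiable <- (w[1] + w[2]) >= 0.01 &&
    (best$loglik - ll_uniform) > stats::qchisq(0.95, 2) / 2
  structure(
    list(
      params = mixture_params(kappa_mean, w[1], w[2], w[3], kappa_max = kappa_max),
      log_likelihood = best$loglik,
      n_iterations = best$n_iter,
      converged = best$converged,
      n_restarts_used = used,
      n_trials = geometry$n,
      m = m,
      kappa_by_group = if (n_grp > 1L) kappa_by_group else NULL,
      kappa_identifiable = identifiable,
      method = "em"
    ),
    class = "mixture_fit"
  )
}

#' @export
print.mixture_fit <- function(x, ...) {
  p <- x$params
  cat(sprintf(
    "Mixture fit (%s, n = %d trials, m = %d non-targets)\n  kappa = %.3f%s\n  p(T) = %.3f, p(NT) = %.3f, p(U) = %.3f\n  logLik = %.3f (%d iterations, converged = %s)\n",
    x$method, x$n_trials, x$m, p$kappa,
    if (isFALSE(x$kappa_identifiable)) " [not identifiable]" else "",
    p$p_target, p$p_nontarget, p$p_uniform,
    x$log_likelihood, x$n_iterations, x$converged
  ))
  invisible(x)
}

#' Brute-force grid-search fit (verification oracle)
#'
#' Exhaustively evaluates [mixture_loglik()] over a Cartesian grid of
#' `kappa` and mixture-weight values and returns the arg-max. Intended as an
#' independent check on [fit_em()] for small datasets.
#'
#' @param geometry a [trial_geometry()] with responses (<= 500 trials).
#' @param kappa_grid numeric vector of concentrations.
#' @param weight_grid numeric vector of candidate values for `p_target` and
#'   `p_nontarget`; all simplex-valid pairs are enumerated (for `m = 0`,
#'   `p_nontarget` is fixed at 0).
#' @return a `mixture_fit` with `method = "grid"`.
#' @export
grid_oracle_fit <- function(geometry, kappa_grid, weight_grid) {
  stopifnot(inherits(geometry, "trial_geometry"))
  if (geometry$n > 500L) stop_invalid("grid_oracle_fit() is restricted to <= 500 trials")
  if (length(kappa_grid) == 0L || length(weight_grid) == 0L) {
    stop_invalid("empty parameter grid")
  }
  beta_grid <- if (geometry$m > 0L) weight_grid else 0
  best <- NULL
  for (k in kappa_grid) {
    for (a in weight_grid) {
      for (b in beta_grid) {
        if (a + b > 1 + 1e-12) next
        par <- mixture_params(k, a, b, max(1 - a - b, 0))
        ll <- mixture_loglik(geometry, par)
        if (is.null(best) || ll > best$ll) best <- list(par = par, ll = ll)
      }
    }
  }
  structure(
    list(params = best$par, log_likelihood = best$ll, n_iterations = NA_integer_,
         converged = TRUE, n_restarts_used = 0L, n_trials = geometry$n,
         m = geometry$m, kappa_identifiable = TRUE, method = "grid"),
    class = "mixture_fit"
  )
}

#' Simulate responses from the mixture model
#'
#' Draws one response per trial: with probability `p_target` a von Mises
#' deviate about the target, with probability `p_nontarget` about a
#' uniformly chosen non-target, otherwise uniform on the circle.
#'
#' @param params a [mixture_params()].
#' @param geometry a [trial_geometry()] (responses, if present, are ignored).
#' @param seed optional seed; the draw is deterministic given it.
#' @return the geometry with simulated `response` filled in, plus an
#'   attribute `component` (factor of latent component labels).
#' @export
simulate_responses <- function(params, geometry, seed = NULL) {
  stopifnot(inherits(params, "mixture_params"), inherits(geometry, "trial_geometry"))
  if (geometry$m == 0L && params$p_nontarget > 0) {
    stop_invalid("p_nontarget > 0 is invalid for trials without non-target items")
  }
  n <- geometry$n
  with_seed(seed, {
    comp <- sample(c("target", "nontarget", "uniform"), n, replace = TRUE,
                   prob = c(params$p_target, params$p_nontarget, params$p_uniform))
    centre <- geometry$target
    idx_nt <- which(comp == "nontarget")
    if (length(idx_nt) > 0L) {
      pick <- sample.int(geometry$m, length(idx_nt), replace = TRUE)
      centre[idx_nt] <- geometry$nontargets[cbind(idx_nt, pick)]
    }
    dev <- rvonmises(n, 0, params$kappa)
    resp <- (centre + dev) %% (2 * pi)
    idx_u <- which(comp == "uniform")
    if (length(idx_u) > 0L) resp[idx_u] <- stats::runif(length(idx_u), 0, 2 * pi)
    out <- trial_geometry(geometry$target, resp,
                          if (geometry$m > 0L) geometry$nontargets else NULL)
    attr(out, "component") <- factor(comp, levels = c("target", "nontarget", "uniform"))
    out
  })
}
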