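# Circular measurement layer: angular error, Fisher circular SD,
# chance-corrected precision, sensorimotor correction.
#
# Orientation data live on a pi-periodic space ([0, pi)). All dispersion
# computation is carried out after doubling angles onto the standard
# 2*pi-periodic circle, and SD / precision are reported on that doubled
# scale. See the methods vignette for why this convention is used.

#' Wrap angles into [0, period)
#'
#' @param x numeric vector of angles (radians).
#' @param period angular period (`pi` for orientations, `2*pi` for the
#'   doubled representation).
#' @return angles wrapped into `[0, period)`.
#' @export
wrap_angle <- function(x, period = pi) {
  assert_finite(x, "x")
  if (!is.numeric(period) || length(period) != 1L || !is.finite(period) || period <= 0) {
    stop_invalid("`period` must be a single positive number")
  }
  x %% period
}

#' Signed circular error between a response and a target
#'
#' Minimal signed angular deviation `response - target` modulo `period`,
#' mapped into `(-period/2, period/2]`.
#'
#' @param response,target angles in radians (finite).
#' @param period angular period; `pi` for orientation stimuli.
#' @return signed errors in `(-period/2, period/2]`.
#' @examples
#' angular_error(0.3, 0.3)            # 0
#' angular_error(0.1, 3.0)            # wraps across the pi boundary
#' @export
angular_error <- function(response, target, period = pi) {
  assert_finite(response, "response")
  assert_finite(target, "target")
  if (!is.numeric(period) || length(period) != 1L || !is.finite(period) || period <= 0) {
    stop_invalid("`period` must be a single positive number")
  }
  d <- (response - target) %% period
  ifelse(d > period / 2, d - period, d)
}

#' Fisher's circular standard deviation
#'
#' Computes `sqrt(-2 * log(Rbar))` where `Rbar` is the mean resultant length
#' of the errors after mapping to the 2*pi-periodic (doubled-angle)
#' representation. For `period = pi` inputs each error is doubled; inputs
#' already on the full circle are used as-is with `period = 2*pi`.
#'
#' In finite samples of diffuse data `Rbar` can be arbitrarily small, which
#' would send the SD to infinity; `Rbar` is therefore floored at `rbar_floor`
#' (default `1/n`, the resolution limit of `n` unit vectors), capping the SD
#' at `sqrt(2 * log(n))`.
#'
#' @param errors numeric vector of at least two angular errors (radians).
#' @param period period of the input errors.
#' @param rbar_floor lower bound applied to the mean resultant length;
#'   defaults to `1/length(errors)`.
#' @return circular SD in radians on the doubled scale.
#' @export
circular_sd <- function(errors, period = pi, rbar_floor = NULL) {
  assert_finite(errors, "errors")
  if (length(errors) < 2L) {
    stop_invalid("circular_sd() needs at least 2 error values (insufficient data)")
  }
  z <- errors * (2 * pi / period)
  rbar <- sqrt(mean(cos(z))^2 + mean(sin(z))^2)
  if (is.null(rbar_floor)) rbar_floor <- 1 / length(errors)
  rbar <- min(max(rbar, rbar_floor), 1)
  sqrt(-2 * log(rbar))
}

# Shared cache so per-participant chance estimates with matched n are
# computed once per (n, replicates, seed) triple.
.chance_cache <- new.env(parent = emptyenv())

#' Monte Carlo estimate of chance-level precision
#'
#' Expected value of `1/circular_sd` for `n_trials` i.i.d. uniform responses
#' on the circle. Subtracting this from raw precision makes a score of zero
#' correspond to responding at random. Deterministic given `seed`, and cached
#' per `(n_trials, n_replicates, seed)`.
#'
#' @param n_trials number of trials the estimate is matched to (>= 2).
#' @param n_replicates Monte Carlo replicates (>= 1000).
#' @param seed integer seed for the simulation.
#' @param sd_floor smallest SD used when inverting to precision.
#' @return chance precision in rad^-1 (doubled scale).
#' @export
chance_precision <- function(n_trials, n_replicates = 10000L, seed = 1L,
                             sd_floor = 1e-6) {
  if (!is.numeric(n_trials) || length(n_trials) != 1L || n_trials < 2) {
    stop_invalid("`n_trials` must be a single count >= 2")
  }
  if (n_replicates < 1000) {
    stop_invalid("`n_replicates` must be >= 1000 for a stable chance estimate")
  }
  n_trials <- as.integer(n_trials)
  n_replicates <- as.integer(n_replicates)
  key <- paste(n_trials, n_replicates, seed, sep = ":")
  if (!is.null(.chance_cache[[key]])) return(.chance_cache[[key]])
  est <- with_seed(seed, {
    ang <- matrix(stats::runif(n_trials * n_replicates, 0, 2 * pi),
                  nrow = n_replicates)
    rbar <- sqrt(rowMeans(cos(ang))^2 + rowMeans(sin(ang))^2)
    rbar <- pmin(pmax(rbar, 1 / n_trials), 1)
    mean(1 / pmax(sqrt(-2 * log(rbar)), sd_floor))
  })
  .chance_cache[[key]] <- est
  est
}

#' Chance-corrected precision estimate
#'
#' Precision is the reciprocal of the Fisher circular SD of response error,
#' minus the value expected for uniform random responding, so that zero
#' corresponds to chance performance.
#'
#' @param errors angular errors (radians), period `period`.
#' @param chance chance precision to subtract (rad^-1); typically from
#'   [chance_precision()] with matched trial count. `0` disables correction.
#' @param period period of the input errors.
#' @param sd_floor floor applied to the SD before inversion, so that
#'   zero-dispersion samples yield a large finite precision.
#' @param rbar_floor passed to [circular_sd()].
#' @return a `precision_estimate`: list with `circular_sd`, `raw_precision`,
#'   `chance_precision`, `corrected_precision`, `n_trials`, `chance_method`.
#' @export
precision <- function(errors, chance = 0, period = pi, sd_floor = 1e-6,
                      rbar_floor = NULL) {
  sd <- circular_sd(errors, period = period, rbar_floor = rbar_floor)
  raw <- 1 / max(sd, sd_floor)
  structure(
    list(
      circular_sd = sd,
      raw_precision = raw,
      chance_precision = chance,
      corrected_precision = raw - chance,
      n_trials = length(errors),
      chance_method = if (identical(chance, 0) || chance == 0) "none" else "monte_carlo"
    ),
    class = "precision_estimate"
  )
}

#' @export
print.precision_estimate <- function(x, ...) {
  cat(sprintf(
    "Precision estimate (n = %d trials)\n  circular SD: %.4f rad\n  raw precision: %.4f rad^-1\n  chance (%s): %.4f rad^-1\n  corrected precision: %.4f rad^-1\n",
    x$n_trials, x$circular_sd, x$raw_precision, x$chance_method,
    x$chance_precision, x$corrected_precision
  ))
  invisible(x)
}

#' Sensorimotor-corrected precision
#'
#' Assuming sensorimotor and recall errors contribute independently to
#' response variability, recall precision is estimated from the variance
#' difference: `1 / sqrt(sd_vwm^2 - sd_sm^2)`. When the memory-task SD does
#' not exceed the sensorimotor SD the subtraction is non-positive and the
#' estimate is undefined; `NA` is returned (with attribute
#' `undefined = TRUE` for scalar input) so callers can log the exclusion
#' rather than silently drop it.
#'
#' @param sd_vwm circular SD on the memory task (radians, >= 0).
#' @param sd_sm circular SD on the sensorimotor control task (radians, >= 0).
#' @return corrected precision in rad^-1, or `NA` where undefined.
#' @export
sensorimotor_corrected_precision <- function(sd_vwm, sd_sm) {
  assert_finite(sd_vwm, "sd_vwm")
  assert_finite(sd_sm, "sd_sm")
  if (any(sd_vwm < 0) || any(sd_sm < 0)) {
    stop_invalid("circular SDs must be non-negative")
  }
  v <- sd_vwm^2 - sd_sm^2
  out <- ifelse(v > 0, 1 / sqrt(pmax(v, 0)), NA_real_)
  if (length(out) == 1L && is.na(out)) attr(out, "undefined") <- TRUE
  out
}

#' Precision difference between two memory loads
#'
#' Variance-subtraction comparison of a larger-load and a smaller-load
#' condition: `1 / sqrt(sd_large_load^2 - sd_small_load^2)`. Same contract
#' as [sensorimotor_corrected_precision()], with `NA` flagging a
#' non-positive variance difference.
#'
#' @param sd_large_load,sd_small_load circular SDs (radians, >= 0).
#' @return precision difference in rad^-1, or `NA` where undefined.
#' @export
precision_difference <- function(sd_large_load, sd_small_load) {
  sensorimotor_corrected_precision(sd_large_load, sd_small_load)
}

#' Draw from a von Mises distribution
#'
#' Best-Fisher rejection sampler on the 2*pi circle. Used by the response
#' simulators; uses the current RNG stream (seed management is done by the
#' callers).
#'
#' @param n number of deviates.
#' @param mu mean direction (radians).
#' @param kappa concentration (>= 0); `kappa = 0` gives the uniform.
#' @return angles in `[0, 2*pi)`.
#' @export
rvonmises <- function(n, mu = 0, kappa) {
  if (!is.numeric(kappa) || length(kappa) != 1L || !is.finite(kappa) || kappa < 0) {
    stop_invalid("`kappa` must be a single finite number >= 0")
  }
  if (n == 0L) return(numeric(0))
  if (kappa < 1e-10) return(stats::runif(n, 0, 2 * pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(0)
  while (length(out) < n) {
    m <- ceiling((n - length(out)) * 1.8) + 10L
    z <- cos(pi * stats::runif(m))
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    u2 <- stats::runif(m)
    keep <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    th <- sign(stats::runif(sum(keep)) - 0.5) * acos(pmin(pmax(f[keep], -1), 1))
    out <- c(out, th)
  }
  (mu + out[seq_len(n)]) %% (2 * pi)
}
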