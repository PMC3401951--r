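# Synthetic cohort and trial generator.
#
# Emulates a cross-sectional developmental study of visual working memory:
# each participant completes a sensorimotor control task (25 trials, probe
# adjusted to a visible target), a one-item delayed-reproduction task
# (30 trials) and a three-item sequential task (90 trials; 5 colours drawn
# without replacement, orientations uniform on pi rad with a minimum
# pairwise separation, each item probed with equal probability). Responses
# are drawn from per-participant mixture parameters that follow linear age
# trends, composed with independent von Mises sensorimotor noise.

#' Cohort configuration
#'
#' Defaults emulate the study design the package targets: 87 boys aged
#' 7.9-13.6 years, 25/30/90 trials per condition, IQ weakly correlated with
#' age, and generative parameters whose linear age trends produce cohort
#' precision magnitudes comparable to published year-group values (see the
#' methods vignette for the calibration reasoning). All SDs and
#' concentrations are on the doubled-angle scale.
#'
#' Generative trend parameters may be given as a scalar (constant over age)
#' or as `c(intercept, slope)` in years of age.
#'
#' @param n_participants cohort size.
#' @param n_trials named counts per condition (`sensorimotor`, `vwm1`, `vwm3`).
#' @param age_range sampled uniformly.
#' @param year_breaks,year_labels cut points mapping age to school year
#'   group (years 3 and 4 collapsed by default).
#' @param fsiq_mean,fsiq_sd,fsiq_age_r marginal moments of the estimated IQ
#'   covariate and its correlation with age.
#' @param sm_sd sensorimotor (motor + perceptual matching) circular SD, rad.
#' @param kappa1,kappa3 target-component concentration in the one-item and
#'   three-item tasks.
#' @param alpha1,gamma1 one-item mixture weights (no non-targets, beta = 0).
#' @param alpha3,beta3,gamma3 three-item mixture weights.
#' @param recency_boost multiplicative kappa boost when the final (third)
#'   serial position is probed.
#' @param kappa_cv,sm_sd_cv participant-level lognormal coefficient of
#'   variation around the age trend.
#' @param min_separation minimum pairwise circular separation (pi space)
#'   among the three orientations of a three-item trial, rad.
#' @param colours stimulus colour set (drawn without replacement).
#' @param seed master seed; all generation is deterministic given it.
#' @return a validated `cohort_config` list.
#' @export
cohort_config <- function(n_participants = 87L,
                          n_trials = c(sensorimotor = 25L, vwm1 = 30L, vwm3 = 90L),
                          age_range = c(7.9, 13.6),
                          year_breaks = c(-Inf, 10.0, 10.75, 11.75, 12.75, Inf),
                          year_labels = c("3-4", "5", "6", "7", "8"),
                          fsiq_mean = 113, fsiq_sd = 12, fsiq_age_r = 0.26,
                          sm_sd = c(0.197, -0.009),
                          kappa1 = c(-53.3, 6.9),
                          kappa3 = c(-7.2, 0.98),
                          alpha1 = 0.98, gamma1 = 0.02,
                          alpha3 = 0.92, beta3 = 0.03, gamma3 = 0.05,
                          recency_boost = 3,
                          kappa_cv = 0.2, sm_sd_cv = 0.15,
                          min_separation = 0.175,
                          colours = c("red", "yellow", "green", "blue", "pink"),
                          seed = 1L) {
  cfg <- structure(
    list(n_participants = as.integer(n_participants), n_trials = n_trials,
         age_range = age_range, year_breaks = year_breaks,
         year_labels = year_labels, fsiq_mean = fsiq_mean, fsiq_sd = fsiq_sd,
         fsiq_age_r = fsiq_age_r, sm_sd = sm_sd, kappa1 = kappa1,
         kappa3 = kappa3, alpha1 = alpha1, gamma1 = gamma1, alpha3 = alpha3,
         beta3 = beta3, gamma3 = gamma3, recency_boost = recency_boost,
         kappa_cv = kappa_cv, sm_sd_cv = sm_sd_cv,
         min_separation = min_separation, colours = colours,
         seed = as.integer(seed)),
    class = "cohort_config"
  )
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(cfg) {
  if (cfg$n_participants < 1L) stop_invalid("`n_participants` must be positive")
  need <- c("sensorimotor", "vwm1", "vwm3")
  if (!all(need %in% names(cfg$n_trials)) || any(cfg$n_trials[need] < 1)) {
    stop_invalid("`n_trials` must give positive counts for sensorimotor, vwm1, vwm3")
  }
  if (length(cfg$age_range) != 2L || diff(cfg$age_range) <= 0) {
    stop_invalid("`age_range` must be an increasing pair")
  }
  if (length(cfg$colours) < 3L) stop_invalid("need at least 3 stimulus colours")
  if (cfg$min_separation < 0 || cfg$min_separation >= pi / 3) {
    stop_invalid("`min_separation` must lie in [0, pi/3) to be feasible for 3 items")
  }
  if (cfg$recency_boost <= 0) stop_invalid("`recency_boost` must be positive")
  # linear trends: positivity / simplex validity need only hold at the ends
  for (age in cfg$age_range) {
    if (lin_at(cfg$sm_sd, age) <= 0) {
      stop_invalid(sprintf("sensorimotor SD non-positive at age %.2f", age))
    }
    for (nm in c("kappa1", "kappa3")) {
      if (lin_at(cfg[[nm]], age) <= 0) {
        stop_invalid(sprintf("`%s` non-positive at age %.2f (infeasible config)", nm, age))
      }
    }
    w1 <- c(lin_at(cfg$alpha1, age), lin_at(cfg$gamma1, age))
    w3 <- c(lin_at(cfg$alpha3, age), lin_at(cfg$beta3, age), lin_at(cfg$gamma3, age))
    if (any(w1 < 0) || abs(sum(w1) - 1) > 1e-8) {
      stop_invalid(sprintf("one-item mixture weights invalid at age %.2f", age))
    }
    if (any(w3 < 0) || abs(sum(w3) - 1) > 1e-8) {
      stop_invalid(sprintf("three-item mixture weights invalid at age %.2f", age))
    }
  }
  invisible(cfg)
}

#' Generate a cohort of participant profiles
#'
#' Ages are uniform on the configured range and mapped to year groups by the
#' cut points; the IQ covariate is drawn with the configured age
#' correlation; per-participant generative parameters follow the linear age
#' trends with lognormal participant-level noise. Deterministic given the
#' config's master seed.
#'
#' @param config a [cohort_config()].
#' @return a tibble with one row per participant: `participant_id`, `age`,
#'   `year_group`, `fsiq_e`, and generative columns (`sm_sd`, `kappa1`,
#'   `kappa3`, mixture weights, `recency_boost`).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_participants
  with_seed(config$seed, {
    age <- sort(stats::runif(n, config$age_range[1], config$age_range[2]))
    z_age <- as.numeric(scale(age))
    r <- config$fsiq_age_r
    fsiq <- config$fsiq_mean +
      config$fsiq_sd * (r * z_age + sqrt(1 - r^2) * stats::rnorm(n))
    year <- cut(age, breaks = config$year_breaks, labels = config$year_labels,
                right = TRUE)
    lnoise <- function(cv) {
      if (cv <= 0) return(rep(1, n))
      sdl <- sqrt(log(1 + cv^2))
      exp(stats::rnorm(n, -sdl^2 / 2, sdl))
    }
    tibble::tibble(
      participant_id = sprintf("S%03d", seq_len(n)),
      age = age,
      year_group = as.character(year),
      fsiq_e = fsiq,
      sm_sd = lin_at(config$sm_sd, age) * lnoise(config$sm_sd_cv),
      kappa1 = lin_at(config$kappa1, age) * lnoise(config$kappa_cv),
      kappa3 = lin_at(config$kappa3, age) * lnoise(config$kappa_cv),
      alpha1 = lin_at(config$alpha1, age),
      gamma1 = lin_at(config$gamma1, age),
      alpha3 = lin_at(config$alpha3, age),
      beta3 = lin_at(config$beta3, age),
      gamma3 = lin_at(config$gamma3, age),
      recency_boost = config$recency_boost
    )
  })
}

#' Sample three-item orientation sets under a separation constraint
#'
#' Orientations are uniform on `[0, pi)` subject to every pairwise circular
#' separation (on the pi-periodic space) being at least `min_sep`. Batch
#' rejection sampling; uses the current RNG stream.
#'
#' @param n number of triples.
#' @param min_sep minimum pairwise circular separation, rad.
#' @param max_tries rejection-round cap before erroring.
#' @return an `n` x 3 matrix of orientations in `[0, pi)`.
#' @export
sample_orientation_triples <- function(n, min_sep = 0.175, max_tries = 1000L) {
  if (n == 0L) return(matrix(numeric(0), 0, 3))
  sep <- function(a, b) {
    d <- abs(a - b) %% pi
    pmin(d, pi - d)
  }
  out <- matrix(NA_real_, n, 3)
  filled <- 0L
  tries <- 0L
  while (filled < n) {
    tries <- tries + 1L
    if (tries > max_tries) stop_invalid("orientation rejection sampling exceeded retry cap")
    m <- ceiling((n - filled) * 1.8) + 10L
    cand <- matrix(stats::runif(3 * m, 0, pi), m, 3)
    ok <- sep(cand[, 1], cand[, 2]) >= min_sep &
      sep(cand[, 1], cand[, 3]) >= min_sep &
      sep(cand[, 2], cand[, 3]) >= min_sep
    kept <- cand[ok, , drop = FALSE]
    take <- min(nrow(kept), n - filled)
    if (take > 0L) {
      out[(filled + 1L):(filled + take), ] <- kept[seq_len(take), , drop = FALSE]
      filled <- filled + take
    }
  }
  out
}

# Memory + motor deviate on the pi-periodic orientation space: a von Mises
# draw on the doubled circle, halved. kappa = Inf means no deviate.
half_vm <- function(n, kappa) {
  if (n == 0L) return(numeric(0))
  th <- rvonmises(n, 0, kappa)
  angular_error(th, 0, 2 * pi) / 2
}

# Motor concentration equivalent to a target circular SD (doubled scale):
# SD = sqrt(-2 log Rbar) inverted through the Bessel ratio.
kappa_from_sd <- function(sd) {
  a1_inv(exp(-sd^2 / 2))
}

#' Generate all trials for one participant
#'
#' Produces the per-condition trial counts of the configured design.
#' Sensorimotor responses are the target plus motor noise only; memory
#' responses are drawn from the participant's mixture parameters (target /
#' misbinding / uniform) and then perturbed by independent von Mises motor
#' noise whose SD is the participant's sensorimotor SD, so error-variance
#' additivity holds by construction. When the third (most recent) serial
#' position is probed, the target concentration is multiplied by the
#' configured recency boost.
#'
#' @param profile one row of [generate_cohort()] output (or an equivalent
#'   list).
#' @param config the [cohort_config()].
#' @param seed optional seed; [generate_study()] derives one per participant
#'   from the master seed.
#' @return a tibble of trial records: `participant_id`, `condition`,
#'   `trial_index`, `stimulus_orientations` (list of radians in `[0, pi)`),
#'   `stimulus_colours` (list), `probed_index`, `response_orientation`.
#' @export
generate_trials <- function(profile, config, seed = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  profile <- as.list(profile)
  if (is.list(profile$sm_sd)) profile <- lapply(profile, `[[`, 1)
  kap_m <- kappa_from_sd(profile$sm_sd)

  with_seed(seed, {
    ## sensorimotor: target visible, response = target + motor noise
    n_sm <- as.integer(config$n_trials[["sensorimotor"]])
    sm_target <- stats::runif(n_sm, 0, pi)
    sm_resp <- (sm_target + half_vm(n_sm, kap_m)) %% pi
    sm_col <- sample(config$colours, n_sm, replace = TRUE)

    ## one-item VWM: two-component mixture (target + uniform) + motor noise
    n_v1 <- as.integer(config$n_trials[["vwm1"]])
    v1_target <- stats::runif(n_v1, 0, pi)
    comp1 <- stats::runif(n_v1) < profile$alpha1
    v1_resp <- ifelse(comp1,
                      v1_target + half_vm(n_v1, profile$kappa1),
                      stats::runif(n_v1, 0, pi))
    v1_resp <- (v1_resp + half_vm(n_v1, kap_m)) %% pi
    v1_col <- sample(config$colours, n_v1, replace = TRUE)

    ## three-item VWM: sequential, probed with equal probability
    n_v3 <- as.integer(config$n_trials[["vwm3"]])
    ori <- sample_orientation_triples(n_v3, config$min_separation)
    cols <- t(replicate(n_v3, sample(config$colours, 3L, replace = FALSE)))
    probed <- sample.int(3L, n_v3, replace = TRUE)
    u <- stats::runif(n_v3)
    comp <- ifelse(u < profile$alpha3, "T",
                   ifelse(u < profile$alpha3 + profile$beta3, "NT", "U"))
    target_ori <- ori[cbind(seq_len(n_v3), probed)]
    centre <- target_ori
    idx_nt <- which(comp == "NT")
    if (length(idx_nt) > 0L) {
      others <- vapply(idx_nt, function(i) {
        o <- setdiff(1:3, probed[i])
        ori[i, sample(o, 1L)]
      }, numeric(1))
      centre[idx_nt] <- others
    }
    # memory noise: kappa takes only two values (plain / recency-boosted),
    # so draw each group in one batch
    mem_dev <- numeric(n_v3)
    for (boosted in c(FALSE, TRUE)) {
      idx <- which(comp != "U" & ((probed == 3L) == boosted))
      kap <- profile$kappa3 * if (boosted) profile$recency_boost else 1
      mem_dev[idx] <- half_vm(length(idx), kap)
    }
    v3_resp <- centre + mem_dev
    idx_u <- which(comp == "U")
    if (length(idx_u) > 0L) v3_resp[idx_u] <- stats::runif(length(idx_u), 0, pi)
    v3_resp <- (v3_resp + half_vm(n_v3, kap_m)) %% pi

    tibble::tibble(
      participant_id = profile$participant_id,
      condition = rep(c("sensorimotor", "vwm1", "vwm3"), c(n_sm, n_v1, n_v3)),
      trial_index = c(seq_len(n_sm), seq_len(n_v1), seq_len(n_v3)),
      stimulus_orientations = c(as.list(sm_target), as.list(v1_target),
                                lapply(seq_len(n_v3), function(i) ori[i, ])),
      stimulus_colours = c(as.list(sm_col), as.list(v1_col),
                           lapply(seq_len(n_v3), function(i) cols[i, ])),
      probed_index = c(rep(1L, n_sm + n_v1), probed),
      response_orientation = c(sm_resp, v1_resp, v3_resp)
    )
  })
}

#' Generate a full synthetic study (cohort + trials)
#'
#' @param config a [cohort_config()].
#' @return list with `participants` (cohort tibble) and `trials` (trial
#'   tibble, all participants stacked).
#' @export
generate_study <- function(config) {
  participants <- generate_cohort(config)
  trials <- lapply(seq_len(nrow(participants)), function(i) {
    generate_trials(participants[i, ], config,
                    seed = derive_seed(config$seed, i))
  })
  list(participants = participants, trials = do.call(rbind, trials))
}

#' Randomly truncate three-item sessions
#'
#' Emulates participants who did not complete the full three-item session:
#' a random subset of participants keeps only their first `L` three-item
#' trials, `L` drawn uniformly from `min_trials` to one less than the full
#' count. Other conditions are untouched.
#'
#' @param trials trial tibble from [generate_study()].
#' @param fraction_incomplete fraction of participants to truncate, in `[0, 1)`.
#' @param seed seed for the selection.
#' @param min_trials smallest retained three-item count (default 45).
#' @return the trial tibble with some vwm3 sessions shortened.
#' @export
truncate_sessions <- function(trials, fraction_incomplete, seed = 1L,
                              min_trials = 45L) {
  if (fraction_incomplete < 0 || fraction_incomplete >= 1) {
    stop_invalid("`fraction_incomplete` must lie in [0, 1)")
  }
  if (fraction_incomplete == 0) return(trials)
  ids <- unique(trials$participant_id)
  n_cut <- round(length(ids) * fraction_incomplete)
  if (n_cut == 0L) return(trials)
  with_seed(seed, {
    cut_ids <- sample(ids, n_cut)
    keep <- rep(TRUE, nrow(trials))
    for (id in cut_ids) {
      sel <- trials$participant_id == id & trials$condition == "vwm3"
      full <- sum(sel)
      len <- sample(seq(min_trials, full - 1L), 1L)
      keep[sel & trials$trial_index > len] <- FALSE
    }
    trials[keep, ]
  })
}
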