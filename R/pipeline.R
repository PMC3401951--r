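# Staged statistical pipeline: per-participant precision measures, outlier
# handling, age regressions and partial correlations, serial-position
# analyses, mixture-parameter regressions, response histograms.

#' Single-pass outlier exclusion
#'
#' Removes values more than `threshold` sample SDs from the sample mean
#' (strict inequality; a value at exactly the threshold is retained). The
#' mean and SD come from the full sample in a single pass, and the rule is
#' applied per dependent variable only. `NA`s are never "excluded" by the
#' rule but are reported separately so exclusion logs stay complete.
#'
#' @param values numeric vector (>= 5 non-missing values, unless all equal).
#' @param threshold z-score cutoff (default 2.5).
#' @return list with `values` (retained, `NA`s dropped), `kept` (logical
#'   mask over the input, `FALSE` for excluded outliers and `NA` entries),
#'   and `log` (tibble of excluded/missing entries: index, value, z, reason).
#' @export
exclude_outliers <- function(values, threshold = 2.5) {
  if (sum(is.finite(values)) < 5L) {
    stop_invalid("exclude_outliers() needs at least 5 finite values")
  }
  mu <- mean(values, na.rm = TRUE)
  sdv <- stats::sd(values, na.rm = TRUE)
  z <- if (sdv > 0) (values - mu) / sdv else rep(0, length(values))
  out <- is.finite(values) & abs(z) > threshold
  miss <- !is.finite(values)
  kept <- !out & !miss
  log <- tibble::tibble(
    index = which(out | miss),
    value = values[out | miss],
    z = z[out | miss],
    reason = ifelse(miss[out | miss], "missing_or_undefined", "outlier")
  )
  list(values = values[kept], kept = kept, log = log)
}

#' Per-participant precision measures and mixture fit
#'
#' Computes, for one participant's trials: circular SD and chance-corrected
#' precision per condition and serial position, sensorimotor-corrected
#' precision for the memory tasks, variance-subtraction precision
#' differences (three-item vs one-item load; recency, i.e. third vs pooled
#' first/second serial position), and the mixture-model fit on the
#' three-item trials (all serial positions pooled).
#'
#' The three-item mean is computed by averaging error variance across
#' serial positions, then inverting - never by averaging precisions. Chance
#' precision is matched to the usable trial count of each measure. The
#' sensorimotor correction (`1/sqrt(SD_vwm^2 - SD_sm^2)`, then chance
#' subtraction) is applied to both memory tasks and each serial position.
#'
#' @param trials trial tibble for a single participant.
#' @param chance_replicates,chance_seed Monte Carlo settings for
#'   [chance_precision()].
#' @param fit_settings list of overrides passed to [fit_em()]
#'   (`n_restarts`, `tol`, `max_iter`, `min_trials`, `seed`).
#' @param min_trials smallest usable trial count per measure.
#' @return one-row tibble of measures (`NA` marks an undefined variance
#'   subtraction or insufficient data; see the exclusion log downstream).
#' @export
compute_measures <- function(trials, chance_replicates = 10000L,
                             chance_seed = 20120701L,
                             fit_settings = list(), min_trials = 2L) {
  stopifnot(all(c("condition", "stimulus_orientations", "probed_index",
                  "response_orientation") %in% names(trials)))
  id <- unique(trials$participant_id)
  if (length(id) != 1L) stop_invalid("compute_measures() expects a single participant")

  errors_of <- function(rows) {
    target <- vapply(seq_len(nrow(rows)), function(i) {
      rows$stimulus_orientations[[i]][rows$probed_index[i]]
    }, numeric(1))
    angular_error(rows$response_orientation, target, period = pi)
  }
  sd_of <- function(err) {
    if (length(err) < min_trials || length(err) < 2L) return(NA_real_)
    circular_sd(err, period = pi)
  }
  chance_of <- function(n) {
    if (is.na(n) || n < 2) return(NA_real_)
    chance_precision(n, chance_replicates, chance_seed)
  }

  sm <- trials[trials$condition == "sensorimotor", ]
  v1 <- trials[trials$condition == "vwm1", ]
  v3 <- trials[trials$condition == "vwm3", ]

  sd_sm <- sd_of(errors_of(sm))
  sd_v1 <- sd_of(errors_of(v1))
  err_v3 <- errors_of(v3)
  sd_sp <- vapply(1:3, function(sp) sd_of(err_v3[v3$probed_index == sp]), numeric(1))
  n_sp <- vapply(1:3, function(sp) sum(v3$probed_index == sp), integer(1))
  # mean across serial positions = average the variances, then invert
  sd_v3 <- if (any(is.na(sd_sp))) NA_real_ else sqrt(mean(sd_sp^2))

  prec_sm <- if (is.na(sd_sm)) NA_real_ else 1 / max(sd_sm, 1e-6) - chance_of(nrow(sm))
  corr_prec <- function(sd_task, n) {
    if (is.na(sd_task) || is.na(sd_sm)) return(NA_real_)
    base <- sensorimotor_corrected_precision(sd_task, sd_sm)
    if (is.na(base)) return(NA_real_)
    as.numeric(base) - chance_of(n)
  }
  prec_v1 <- corr_prec(sd_v1, nrow(v1))
  prec_v3 <- corr_prec(sd_v3, nrow(v3))
  prec_sp <- vapply(1:3, function(sp) corr_prec(sd_sp[sp], n_sp[sp]), numeric(1))

  pd_load <- if (is.na(sd_v3) || is.na(sd_v1)) NA_real_ else {
    as.numeric(precision_difference(sd_v3, sd_v1))
  }
  pd_recency <- if (any(is.na(sd_sp))) NA_real_ else {
    pooled <- sqrt(mean(sd_sp[1:2]^2))
    as.numeric(precision_difference(pooled, sd_sp[3]))
  }

  # mixture fit on pooled three-item trials (doubled-angle geometry)
  fit <- NULL
  fit_floor <- fit_settings$min_trials %||% 20L
  if (nrow(v3) >= fit_floor) {
    target <- vapply(seq_len(nrow(v3)), function(i) {
      v3$stimulus_orientations[[i]][v3$probed_index[i]]
    }, numeric(1))
    nts <- t(vapply(seq_len(nrow(v3)), function(i) {
      v3$stimulus_orientations[[i]][-v3$probed_index[i]]
    }, numeric(2)))
    geom <- trial_geometry(2 * target, 2 * v3$response_orientation, 2 * nts)
    # weights shared across serial positions, concentration per serial
    # position (the recency effect makes dispersion SP-dependent; a single
    # shared kappa would misread SP1/2 tails as uniform guessing);
    # params$kappa is the mean across serial positions
    by_sp <- fit_settings$kappa_by_sp %||% TRUE
    # moment start + 3 restarts: restarts essentially never improve on the
    # moment start at this scale (see methods vignette)
    fit <- suppressWarnings(fit_em(
      geom,
      n_restarts = fit_settings$n_restarts %||% 3L,
      tol = fit_settings$tol %||% 1e-6,
      max_iter = fit_settings$max_iter %||% 10000L,
      min_trials = fit_floor,
      seed = fit_settings$seed %||% 20120702L,
      groups = if (by_sp) v3$probed_index else NULL
    ))
  }

  tibble::tibble(
    participant_id = id,
    n_sm = nrow(sm), n_vwm1 = nrow(v1), n_vwm3 = nrow(v3),
    sd_sm = sd_sm, sd_vwm1 = sd_v1, sd_vwm3 = sd_v3,
    sd_sp1 = sd_sp[1], sd_sp2 = sd_sp[2], sd_sp3 = sd_sp[3],
    prec_sm = prec_sm, prec_vwm1 = prec_v1, prec_vwm3 = prec_v3,
    prec_sp1 = prec_sp[1], prec_sp2 = prec_sp[2], prec_sp3 = prec_sp[3],
    pd_load = pd_load, pd_recency = pd_recency,
    kappa = if (is.null(fit)) NA_real_ else fit$params$kappa,
    p_target = if (is.null(fit)) NA_real_ else fit$params$p_target,
    p_nontarget = if (is.null(fit)) NA_real_ else fit$params$p_nontarget,
    p_uniform = if (is.null(fit)) NA_real_ else fit$params$p_uniform,
    fit_loglik = if (is.null(fit)) NA_real_ else fit$log_likelihood,
    fit_converged = if (is.null(fit)) NA else fit$converged
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Ordinary least-squares age regression
#'
#' @param measure numeric dependent variable (one value per participant).
#' @param ages participant ages in years.
#' @return tibble with `slope`, `adj_r_squared`, `p_value`, `n`.
#' @export
age_regression <- function(measure, ages) {
  ok <- is.finite(measure) & is.finite(ages)
  if (sum(ok) < 10L) stop_invalid("age_regression() needs >= 10 retained participants")
  if (stats::sd(ages[ok]) == 0) stop_invalid("degenerate predictor: ages are constant")
  fit <- stats::lm(measure[ok] ~ ages[ok])
  s <- summary(fit)
  tibble::tibble(
    slope = unname(stats::coef(fit)[2]),
    adj_r_squared = s$adj.r.squared,
    p_value = unname(s$coefficients[2, 4]),
    n = sum(ok)
  )
}

#' Partial correlation controlling for a covariate
#'
#' Correlation of the residuals of `measure` and `ages` after each is
#' regressed on `covariate` (Pearson by default; `"spearman"` ranks all
#' three variables first). The test uses `df = n - 3`.
#'
#' @param measure,ages,covariate numeric vectors of equal length.
#' @param method `"pearson"` or `"spearman"`.
#' @return tibble with `rho`, `p_value`, `n`.
#' @export
partial_correlation <- function(measure, ages, covariate,
                                method = c("pearson", "spearman")) {
  method <- match.arg(method)
  ok <- is.finite(measure) & is.finite(ages) & is.finite(covariate)
  if (sum(ok) < 10L) stop_invalid("partial_correlation() needs >= 10 retained participants")
  x <- measure[ok]; y <- ages[ok]; z <- covariate[ok]
  if (method == "spearman") {
    x <- rank(x); y <- rank(y); z <- rank(z)
  }
  n <- length(x)
  if (stats::sd(z) == 0) {
    warning("constant covariate: partial correlation reduces to the plain correlation")
    rho <- stats::cor(x, y)
    df <- n - 2
  } else {
    rx <- stats::resid(stats::lm(x ~ z))
    ry <- stats::resid(stats::lm(y ~ z))
    # a variable fully explained by the covariate has no residual variance
    # left to correlate
    if (stats::sd(rx) < 1e-12 || stats::sd(ry) < 1e-12) {
      return(tibble::tibble(rho = 0, p_value = 1, n = n))
    }
    rho <- stats::cor(rx, ry)
    df <- n - 3
  }
  tstat <- rho * sqrt(df / (1 - rho^2))
  tibble::tibble(rho = rho, p_value = 2 * stats::pt(-abs(tstat), df), n = n)
}

#' One-way repeated-measures ANOVA over serial positions
#'
#' Within-subject one-way ANOVA on an `n x k` matrix of per-participant
#' serial-position precisions, with Greenhouse-Geisser correction of the
#' degrees of freedom for non-sphericity, plus all pairwise paired t-tests.
#' Rows with any missing value are dropped (complete cases).
#'
#' @param sp_matrix numeric matrix, participants x serial positions
#'   (k >= 2; column names used in the pairwise table).
#' @return list with `anova` (tibble: `F`, `df1`, `df2`, `epsilon`,
#'   `p_value`, `n`) and `pairwise` (tibble of paired t-tests).
#' @export
serial_position_anova <- function(sp_matrix) {
  sp_matrix <- as.matrix(sp_matrix)
  k <- ncol(sp_matrix)
  if (k < 2L) stop_invalid("need at least two serial positions")
  if (is.null(colnames(sp_matrix))) colnames(sp_matrix) <- paste0("SP", seq_len(k))
  cc <- stats::complete.cases(sp_matrix) & apply(is.finite(sp_matrix), 1, all)
  y <- sp_matrix[cc, , drop = FALSE]
  n <- nrow(y)
  if (n < 3L) stop_invalid("fewer than 3 complete cases")

  grand <- mean(y)
  col_m <- colMeans(y)
  row_m <- rowMeans(y)
  ss_sp <- n * sum((col_m - grand)^2)
  resid <- y - outer(row_m, rep(1, k)) - outer(rep(1, n), col_m) + grand
  ss_err <- sum(resid^2)
  df1 <- k - 1
  df2 <- (n - 1) * (k - 1)

  # Greenhouse-Geisser epsilon from the eigenvalues of the double-centred
  # covariance of the repeated measures
  S <- stats::cov(y)
  C <- diag(k) - 1 / k
  Sc <- C %*% S %*% C
  lam <- Re(eigen(Sc, symmetric = TRUE, only.values = TRUE)$values)
  lam <- pmax(lam, 0)
  eps <- if (sum(lam^2) > 0) sum(lam)^2 / (df1 * sum(lam^2)) else 1
  eps <- min(max(eps, 1 / df1), 1)

  if (ss_sp < 1e-12) {
    Fstat <- 0
    p <- 1
  } else if (ss_err < 1e-12) {
    Fstat <- Inf
    p <- 0
  } else {
    Fstat <- (ss_sp / df1) / (ss_err / df2)
    p <- stats::pf(Fstat, eps * df1, eps * df2, lower.tail = FALSE)
  }

  pairs <- utils::combn(k, 2)
  pairwise <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    d <- y[, i2] - y[, i1]
    if (stats::sd(d) < 1e-12) {
      # constant differences carry no evidence either way
      return(tibble::tibble(
        comparison = paste(colnames(y)[i2], "vs", colnames(y)[i1]),
        t = 0, df = n - 1, p_value = 1, mean_difference = mean(d)
      ))
    }
    tt <- stats::t.test(y[, i2], y[, i1], paired = TRUE)
    tibble::tibble(
      comparison = paste(colnames(y)[i2], "vs", colnames(y)[i1]),
      t = unname(tt$statistic), df = unname(tt$parameter),
      p_value = tt$p.value, mean_difference = unname(tt$estimate)
    )
  }))
  list(
    anova = tibble::tibble(F = Fstat, df1 = eps * df1, df2 = eps * df2,
                           epsilon = eps, p_value = p, n = n),
    pairwise = pairwise
  )
}

#' Binned response histograms relative to target and non-targets
#'
#' Response errors of three-item trials are re-centred on the target (and,
#' separately, on each non-target), then binned into `n_bins` equal bins
#' spanning the pi rad of response space. Target-centred counts sum to the
#' trial count; non-target-centred counts sum to the number of
#' (trial, non-target) pairs.
#'
#' @param trials trial tibble (three-item trials are selected by
#'   `condition == "vwm3"`; a tibble of only vwm3 trials also works).
#' @param n_bins number of equal bins across `(-pi/2, pi/2]` (default 9).
#' @return list with `target` and `nontarget` count vectors, `breaks`, and
#'   `n_trials`.
#' @export
response_histograms <- function(trials, n_bins = 9L) {
  v3 <- trials[trials$condition == "vwm3", ]
  if (nrow(v3) == 0L) stop_invalid("no three-item (vwm3) trials found")
  breaks <- seq(-pi / 2, pi / 2, length.out = n_bins + 1L)
  target <- vapply(seq_len(nrow(v3)), function(i) {
    v3$stimulus_orientations[[i]][v3$probed_index[i]]
  }, numeric(1))
  err_t <- angular_error(v3$response_orientation, target, period = pi)
  nts <- lapply(seq_len(nrow(v3)), function(i) {
    v3$stimulus_orientations[[i]][-v3$probed_index[i]]
  })
  err_nt <- unlist(lapply(seq_len(nrow(v3)), function(i) {
    angular_error(rep(v3$response_orientation[i], length(nts[[i]])),
                  nts[[i]], period = pi)
  }))
  bin <- function(e) {
    # half-open bins (lo, hi]; the lowest edge is closed so -pi/2 is kept
    idx <- findInterval(e, breaks, left.open = TRUE, rightmost.closed = FALSE)
    idx[idx == 0L] <- 1L
    idx[idx > n_bins] <- n_bins
    tabulate(idx, nbins = n_bins)
  }
  list(target = bin(err_t), nontarget = bin(err_nt), breaks = breaks,
       n_trials = nrow(v3))
}

#' Per-parameter age regressions for the mixture fits
#'
#' Applies [age_regression()] and [partial_correlation()] to each of the
#' four mixture parameters separately (the parameters are non-independent,
#' so they are tested one at a time). Only converged fits enter; others are
#' listed in the returned exclusion log.
#'
#' @param measures measures tibble from [compute_measures()] rows, plus
#'   `age` and covariate columns.
#' @param covariate numeric covariate (e.g. estimated IQ).
#' @param outlier_threshold z cutoff forwarded to [exclude_outliers()].
#' @param method correlation variant for the partial correlations.
#' @return list with `regressions` (tibble: parameter, slope, adj r^2, p,
#'   partial rho, partial p, n) and `exclusions` (tibble).
#' @export
parameter_age_regressions <- function(measures, covariate,
                                      outlier_threshold = 2.5,
                                      method = "pearson") {
  stopifnot(all(c("age", "kappa", "p_target", "p_nontarget", "p_uniform",
                  "fit_converged") %in% names(measures)))
  conv <- !is.na(measures$fit_converged) & measures$fit_converged
  exclusions <- tibble::tibble(
    measure = "mixture_fit",
    participant_id = measures$participant_id[!conv],
    value = NA_real_, z = NA_real_, reason = "fit_missing_or_not_converged"
  )
  rows <- list()
  for (par in c("kappa", "p_target", "p_nontarget", "p_uniform")) {
    vals <- ifelse(conv, measures[[par]], NA_real_)
    ex <- exclude_outliers(vals, outlier_threshold)
    keep <- ex$kept
    if (nrow(ex$log) > 0L) {
      out_rows <- ex$log[ex$log$reason == "outlier", ]
      if (nrow(out_rows) > 0L) {
        exclusions <- rbind(exclusions, tibble::tibble(
          measure = par, participant_id = measures$participant_id[out_rows$index],
          value = out_rows$value, z = out_rows$z, reason = "outlier"
        ))
      }
    }
    reg <- age_regression(measures[[par]][keep], measures$age[keep])
    pc <- partial_correlation(measures[[par]][keep], measures$age[keep],
                              covariate[keep], method = method)
    rows[[par]] <- tibble::tibble(
      parameter = par, slope = reg$slope, adj_r_squared = reg$adj_r_squared,
      p_value = reg$p_value, partial_rho = pc$rho, partial_p = pc$p_value,
      n = reg$n
    )
  }
  list(regressions = do.call(rbind, rows), exclusions = exclusions)
}

#' Run the full cohort analysis
#'
#' Computes per-participant measures, applies the per-variable outlier rule,
#' runs age regressions and partial correlations (controlling for the IQ
#' covariate) on every precision measure and mixture parameter, one-sample
#' t-tests against chance per year group, the serial-position ANOVA with
#' pairwise comparisons, and pooled response histograms. Every excluded
#' outlier, undefined variance subtraction and non-converged fit is
#' enumerated in the exclusion log.
#'
#' @param participants cohort tibble (`participant_id`, `age`, `year_group`,
#'   `fsiq_e`).
#' @param trials trial tibble for all participants.
#' @param fit_settings,chance_replicates,chance_seed forwarded to
#'   [compute_measures()].
#' @param outlier_threshold z cutoff of the outlier rule.
#' @param method partial-correlation variant.
#' @return a `cohort_result` list: `measures`, `regressions`,
#'   `group_ttests`, `sp_anova`, `histograms`, `parameter_regressions`,
#'   `exclusions`.
#' @export
analyze_cohort <- function(participants, trials, fit_settings = list(),
                           chance_replicates = 10000L,
                           chance_seed = 20120701L,
                           outlier_threshold = 2.5,
                           method = "pearson") {
  stopifnot(all(c("participant_id", "age", "year_group", "fsiq_e")
                %in% names(participants)))
  ids <- participants$participant_id
  meas <- do.call(rbind, lapply(ids, function(id) {
    compute_measures(trials[trials$participant_id == id, ],
                     chance_replicates = chance_replicates,
                     chance_seed = chance_seed,
                     fit_settings = fit_settings)
  }))
  measures <- merge(participants, meas, by = "participant_id", sort = FALSE)
  measures <- tibble::as_tibble(measures[match(ids, measures$participant_id), ])

  prec_vars <- c("prec_sm", "prec_vwm1", "prec_vwm3",
                 "prec_sp1", "prec_sp2", "prec_sp3", "pd_load", "pd_recency")
  exclusions <- tibble::tibble(measure = character(), participant_id = character(),
                               value = numeric(), z = numeric(), reason = character())
  kept_mask <- list()
  for (v in prec_vars) {
    ex <- exclude_outliers(measures[[v]], outlier_threshold)
    kept_mask[[v]] <- ex$kept
    if (nrow(ex$log) > 0L) {
      exclusions <- rbind(exclusions, tibble::tibble(
        measure = v, participant_id = measures$participant_id[ex$log$index],
        value = ex$log$value, z = ex$log$z, reason = ex$log$reason
      ))
    }
  }

  regressions <- do.call(rbind, lapply(prec_vars, function(v) {
    keep <- kept_mask[[v]]
    reg <- age_regression(measures[[v]][keep], measures$age[keep])
    pc <- partial_correlation(measures[[v]][keep], measures$age[keep],
                              measures$fsiq_e[keep], method = method)
    tibble::tibble(measure = v, slope = reg$slope,
                   adj_r_squared = reg$adj_r_squared, p_value = reg$p_value,
                   partial_rho = pc$rho, partial_p = pc$p_value, n = reg$n)
  }))

  # one-sample t-tests vs chance (0 after correction), per year group
  tt_vars <- c("prec_sm", "prec_vwm1", "prec_vwm3",
               "prec_sp1", "prec_sp2", "prec_sp3")
  group_ttests <- do.call(rbind, lapply(tt_vars, function(v) {
    keep <- kept_mask[[v]]
    do.call(rbind, lapply(unique(measures$year_group), function(g) {
      sel <- keep & measures$year_group == g
      x <- measures[[v]][sel]
      if (sum(is.finite(x)) < 3L) {
        return(tibble::tibble(measure = v, year_group = g, mean = mean(x, na.rm = TRUE),
                              t = NA_real_, df = NA_real_, p_value = NA_real_,
                              n = sum(is.finite(x))))
      }
      tt <- stats::t.test(x, mu = 0)
      tibble::tibble(measure = v, year_group = g, mean = mean(x),
                     t = unname(tt$statistic), df = unname(tt$parameter),
                     p_value = tt$p.value, n = length(x))
    }))
  }))

  sp_keep <- kept_mask$prec_sp1 & kept_mask$prec_sp2 & kept_mask$prec_sp3
  sp_mat <- cbind(SP1 = measures$prec_sp1, SP2 = measures$prec_sp2,
                  SP3 = measures$prec_sp3)[sp_keep, , drop = FALSE]
  sp_anova <- serial_position_anova(sp_mat)

  hist_out <- response_histograms(trials)

  par_reg <- parameter_age_regressions(measures, measures$fsiq_e,
                                       outlier_threshold, method)
  exclusions <- rbind(exclusions, par_reg$exclusions)

  structure(
    list(measures = measures, regressions = regressions,
         group_ttests = group_ttests, sp_anova = sp_anova,
         histograms = hist_out,
         parameter_regressions = par_reg$regressions,
         exclusions = exclusions),
    class = "cohort_result"
  )
}

#' @export
print.cohort_result <- function(x, ...) {
  cat(sprintf("Cohort analysis: %d participants\n", nrow(x$measures)))
  cat("\nAge regressions (precision measures):\n")
  print(as.data.frame(x$regressions), digits = 3)
  cat("\nSerial-position ANOVA:\n")
  print(as.data.frame(x$sp_anova$anova), digits = 3)
  cat("\nMixture-parameter age regressions:\n")
  print(as.data.frame(x$parameter_regressions), digits = 3)
  cat(sprintf("\nExclusions logged: %d\n", nrow(x$exclusions)))
  invisible(x)
}
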