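# Canonical on-disk formats: delimited-text trial and participant tables,
# YAML run configuration, provenance records. Angles are radians-only on
# disk; list-valued fields are semicolon-joined.

TRIAL_COLUMNS <- c("participant_id", "condition", "trial_index",
                   "stimulus_orientations", "stimulus_colours",
                   "probed_index", "response_orientation")

fmt_num <- function(x) sprintf("%.17g", x)

#' Write a trial table
#'
#' One row per trial; orientations are written as semicolon-joined radians
#' at full float precision, so a write-read round trip is lossless.
#'
#' @param trials trial tibble (see [generate_trials()] for the schema).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  stopifnot(all(TRIAL_COLUMNS %in% names(trials)))
  flat <- data.frame(
    participant_id = trials$participant_id,
    condition = trials$condition,
    trial_index = trials$trial_index,
    stimulus_orientations = vapply(trials$stimulus_orientations,
                                   function(x) paste(fmt_num(x), collapse = ";"),
                                   character(1)),
    stimulus_colours = vapply(trials$stimulus_colours,
                              function(x) paste(x, collapse = ";"), character(1)),
    probed_index = trials$probed_index,
    response_orientation = fmt_num(trials$response_orientation),
    stringsAsFactors = FALSE
  )
  utils::write.csv(flat, path, row.names = FALSE)
  invisible(path)
}

#' Read a trial table
#'
#' Validates the header, parses semicolon-joined angle lists, and checks
#' that all orientations lie in `[0, pi)`, that probed indices are valid,
#' and that three-item trials carry exactly three stimuli with distinct
#' colours. Errors name the offending data rows.
#'
#' @param path CSV path written by [write_trials()] (or conforming to its
#'   schema).
#' @return a trial tibble.
#' @export
read_trials <- function(path) {
  header <- strsplit(readLines(path, n = 1L), ",", fixed = TRUE)[[1]]
  header <- gsub('"', "", header, fixed = TRUE)
  if (!identical(sort(header), sort(TRIAL_COLUMNS))) {
    stop_invalid(sprintf("unexpected trial-table header: got [%s]",
                         paste(header, collapse = ", ")))
  }
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(stimulus_orientations = "character",
                                        stimulus_colours = "character"))
  if (nrow(raw) == 0L) {
    warning("empty trial table (header only)")
    return(tibble::tibble(
      participant_id = character(), condition = character(),
      trial_index = integer(), stimulus_orientations = list(),
      stimulus_colours = list(), probed_index = integer(),
      response_orientation = numeric()
    ))
  }
  ori <- lapply(strsplit(raw$stimulus_orientations, ";", fixed = TRUE), as.numeric)
  cols <- strsplit(raw$stimulus_colours, ";", fixed = TRUE)
  bad_parse <- which(vapply(ori, function(x) any(is.na(x)), logical(1)) |
                       !is.finite(raw$response_orientation))
  if (length(bad_parse) > 0L) {
    stop_invalid(sprintf("malformed rows (unparseable angles): %s",
                         paste(bad_parse, collapse = ", ")))
  }
  bad_range <- which(vapply(ori, function(x) any(x < 0 | x >= pi), logical(1)) |
                       raw$response_orientation < 0 | raw$response_orientation >= pi)
  if (length(bad_range) > 0L) {
    stop_invalid(sprintf("orientations outside [0, pi) in rows: %s",
                         paste(bad_range, collapse = ", ")))
  }
  n_stim <- lengths(ori)
  bad_probe <- which(raw$probed_index < 1 | raw$probed_index > n_stim)
  if (length(bad_probe) > 0L) {
    stop_invalid(sprintf("probed_index out of range in rows: %s",
                         paste(bad_probe, collapse = ", ")))
  }
  v3 <- raw$condition == "vwm3"
  bad_v3 <- which(v3 & (n_stim != 3L |
                          vapply(cols, function(x) anyDuplicated(x) > 0, logical(1))))
  if (length(bad_v3) > 0L) {
    stop_invalid(sprintf(
      "vwm3 trials must have exactly 3 stimuli with distinct colours; bad rows: %s",
      paste(bad_v3, collapse = ", ")))
  }
  tibble::tibble(
    participant_id = raw$participant_id,
    condition = raw$condition,
    trial_index = as.integer(raw$trial_index),
    stimulus_orientations = ori,
    stimulus_colours = cols,
    probed_index = as.integer(raw$probed_index),
    response_orientation = raw$response_orientation
  )
}

#' Write / read a participant table
#'
#' @param participants cohort tibble ([generate_cohort()] schema or the
#'   minimal `participant_id`, `age`, `year_group`, `fsiq_e`).
#' @param path CSV path.
#' @return `path` (write) or a tibble (read).
#' @export
write_participants <- function(participants, path) {
  need <- c("participant_id", "age", "year_group", "fsiq_e")
  stopifnot(all(need %in% names(participants)))
  df <- as.data.frame(participants)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], fmt_num)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_participants
#' @export
read_participants <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant_id", "age", "year_group", "fsiq_e")
  if (!all(need %in% names(raw))) {
    stop_invalid(sprintf("participant table must contain columns: %s",
                         paste(need, collapse = ", ")))
  }
  raw$year_group <- as.character(raw$year_group)
  tibble::as_tibble(raw)
}

run_config_keys <- function() {
  list(
    paths = c("input", "output"),
    cohort = names(formals(cohort_config)),
    fit = c("n_restarts", "tol", "max_iter", "min_trials", "seed"),
    analysis = c("grouping", "correlation_method", "multiple_testing",
                 "outlier_threshold", "chance_replicates", "chance_seed"),
    seed = NULL,
    log_level = NULL
  )
}

#' Read and validate a YAML run configuration
#'
#' The schema has blocks `paths`, `cohort`, `fit`, `analysis` plus scalar
#' `seed` and `log_level`. Unknown keys at any level are rejected before
#' any computation.
#'
#' @param path YAML file.
#' @return list with the validated blocks; `cohort` is a built
#'   [cohort_config()].
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  RUN_CONFIG_KEYS <- run_config_keys()
  unknown <- setdiff(names(cfg), names(RUN_CONFIG_KEYS))
  if (length(unknown) > 0L) {
    stop_invalid(sprintf("unknown config keys: %s", paste(unknown, collapse = ", ")))
  }
  for (block in c("paths", "cohort", "fit", "analysis")) {
    if (!is.null(cfg[[block]])) {
      bad <- setdiff(names(cfg[[block]]), RUN_CONFIG_KEYS[[block]])
      if (length(bad) > 0L) {
        stop_invalid(sprintf("unknown keys in `%s`: %s", block,
                             paste(bad, collapse = ", ")))
      }
    }
  }
  cohort_args <- cfg$cohort %||% list()
  if (!is.null(cohort_args$n_trials)) {
    cohort_args$n_trials <- unlist(cohort_args$n_trials)
  }
  for (nm in c("age_range", "year_breaks", "year_labels", "colours",
               "sm_sd", "kappa1", "kappa3")) {
    if (!is.null(cohort_args[[nm]])) cohort_args[[nm]] <- unlist(cohort_args[[nm]])
  }
  if (!is.null(cfg$seed) && is.null(cohort_args$seed)) cohort_args$seed <- cfg$seed
  list(
    paths = cfg$paths %||% list(),
    cohort = do.call(cohort_config, cohort_args),
    fit = cfg$fit %||% list(),
    analysis = cfg$analysis %||% list(),
    seed = cfg$seed %||% (cohort_args$seed %||% 1L),
    log_level = cfg$log_level %||% "info"
  )
}

#' Provenance record for a run
#'
#' @param config any serialisable configuration object.
#' @param seed the master seed of the run.
#' @return list with the package version, the seed, and an FNV-1a hash of
#'   the YAML-serialised configuration.
#' @export
provenance_record <- function(config, seed) {
  txt <- yaml::as.yaml(lapply(unclass(config), function(x) x))
  list(
    package = "vwmprecision",
    version = as.character(utils::packageVersion("vwmprecision")),
    seed = as.integer(seed),
    config_hash = fnv1a(txt)
  )
}

#' Write cohort analysis results as CSV tables
#'
#' Writes one CSV per analysis family (measures, regressions, group t-tests,
#' serial-position ANOVA and pairwise tests, parameter regressions,
#' histograms, exclusion log) into a directory.
#'
#' @param result a `cohort_result` from [analyze_cohort()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_results <- function(result, dir) {
  stopifnot(inherits(result, "cohort_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(as.data.frame(result$measures), file.path(dir, "measures.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(result$regressions),
                   file.path(dir, "age_regressions.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(result$group_ttests),
                   file.path(dir, "group_ttests.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(result$sp_anova$anova),
                   file.path(dir, "sp_anova.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(result$sp_anova$pairwise),
                   file.path(dir, "sp_pairwise.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(result$parameter_regressions),
                   file.path(dir, "parameter_regressions.csv"), row.names = FALSE)
  h <- result$histograms
  utils::write.csv(data.frame(bin_low = h$breaks[-length(h$breaks)],
                              bin_high = h$breaks[-1],
                              target = h$target, nontarget = h$nontarget),
                   file.path(dir, "response_histograms.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(result$exclusions),
                   file.path(dir, "exclusions.csv"), row.names = FALSE)
  invisible(dir)
}
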