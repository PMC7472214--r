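# CSV/JSON handling and the end-to-end pipeline driver. All writers stamp a
# provenance header (comment lines) with the package version, seed and a
# configuration fingerprint; readers skip comment lines.

write_with_header <- function(df, path, meta = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  meta <- c(list(generator = paste0("betabandit ",
                                    as.character(utils::packageVersion("betabandit")))),
            meta)
  for (nm in names(meta)) {
    writeLines(sprintf("# %s: %s", nm, meta[[nm]]), con)
  }
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
}

read_csv_checked <- function(path) {
  if (!file.exists(path)) stop_domain("file not found: ", path)
  if (file.size(path) == 0) stop_domain("empty input file: ", path)
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop_domain("no data rows in: ", path)
  df
}

#' Read and write session CSV files
#'
#' Sessions are stored as \code{trial,choice,reward,p0,p1} with \code{choice}
#' and \code{reward} empty on missed trials and 1-based consecutive trial
#' indices; lines starting with \code{#} are provenance metadata. Reading
#' validates choice codes, binary rewards and the miss convention, naming
#' offending rows.
#'
#' @param path File path.
#' @param session A \code{bandit_session} (for writing).
#' @param meta Named list of extra metadata lines to stamp.
#' @return \code{read_session} returns a \code{bandit_session};
#'   \code{write_session} returns the path invisibly.
#' @export
read_session <- function(path) {
  df <- read_csv_checked(path)
  need <- c("trial", "choice", "reward", "p0", "p1")
  if (!all(need %in% names(df))) {
    stop_domain("malformed session header; expected columns: ",
                paste(need, collapse = ","))
  }
  bandit_session(df, subject_id = sub("[.]csv$", "", basename(path)))
}

#' @rdname read_session
#' @export
write_session <- function(session, path, meta = list()) {
  if (!inherits(session, "bandit_session")) session <- bandit_session(session)
  ws <- attr(session, "schedule")
  if (!is.null(ws)) meta$schedule_seed <- ws$seed
  meta$subject_id <- attr(session, "subject_id") %||% "s1"
  write_with_header(as.data.frame(session), path, meta)
  invisible(path)
}

#' Read and write walk-schedule CSV files
#'
#' Schedules are stored as \code{trial,p0,p1} (true reward probabilities per
#' trial). Reading validates the probability range; generator settings
#' travel in the metadata header and are not required to reconstruct the
#' trajectories.
#'
#' @param path File path.
#' @param schedule A \code{walk_schedule} (for writing).
#' @param meta Named list of extra metadata lines.
#' @return \code{read_schedule} returns a data.frame with \code{trial},
#'   \code{p0}, \code{p1}.
#' @export
read_schedule <- function(path) {
  df <- read_csv_checked(path)
  need <- c("trial", "p0", "p1")
  if (!all(need %in% names(df))) {
    stop_domain("malformed schedule header; expected columns: ",
                paste(need, collapse = ","))
  }
  bad <- which(df$p0 < 0 | df$p0 > 1 | df$p1 < 0 | df$p1 > 1)
  if (length(bad)) {
    stop_domain("probabilities outside [0, 1] at rows: ",
                paste(bad, collapse = ", "))
  }
  df
}

#' @rdname read_schedule
#' @export
write_schedule <- function(schedule, path, meta = list()) {
  stopifnot(inherits(schedule, "walk_schedule"))
  meta <- c(list(seed = schedule$seed, sigma = schedule$sigma,
                 bounds = paste(schedule$bounds, collapse = ",")), meta)
  df <- data.frame(trial = seq_len(schedule$n_trials),
                   p0 = schedule$p[, 1], p1 = schedule$p[, 2])
  write_with_header(df, path, meta)
  invisible(path)
}

#' Read and write cohort CSV files
#'
#' Cohorts are stored as
#' \code{subject_id,age_group,age,fa,bpnd,q_signal,wins}.
#'
#' @param path File path.
#' @param cohort Cohort data.frame (for writing).
#' @param meta Named list of extra metadata lines.
#' @return \code{read_cohort} returns the cohort data.frame.
#' @export
read_cohort <- function(path) {
  df <- read_csv_checked(path)
  need <- c("subject_id", "age_group", "age", "fa", "bpnd", "q_signal", "wins")
  if (!all(need %in% names(df))) {
    stop_domain("malformed cohort header; expected columns: ",
                paste(need, collapse = ","))
  }
  df$age_group <- factor(df$age_group, levels = c("young", "old"))
  if (anyNA(df$age_group)) stop_domain("age_group must be 'young' or 'old'")
  df
}

#' @rdname read_cohort
#' @export
write_cohort <- function(cohort, path, meta = list()) {
  write_with_header(cohort, path, meta)
  invisible(path)
}

#' Write observer latents to CSV
#'
#' Exports the per-trial latent table
#' (\code{trial,Q0,Q1,V0,V1,Crel,m0,m1,p_choice0,p_choice1}).
#'
#' @param latents An \code{observer_latents} data.frame.
#' @param path File path.
#' @param meta Named list of extra metadata lines.
#' @export
write_latents <- function(latents, path, meta = list()) {
  write_with_header(as.data.frame(latents), path, meta)
  invisible(path)
}

#' Read and write observer parameters as JSON
#'
#' JSON object with fields \code{beta}, \code{omega}, \code{lambda},
#' \code{upsilon}, \code{kappa}.
#'
#' @param params An \code{observer_params} (for writing).
#' @param path File path.
#' @export
write_params <- function(params, path) {
  params <- validate_observer_params(params)
  jsonlite::write_json(unclass(params), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  observer_params(obj$beta, obj$omega, obj$lambda,
                  obj$upsilon %||% 0, obj$kappa %||% 0)
}

#' Pipeline configuration
#'
#' Collects every knob of the end-to-end run: task settings, fitting
#' settings, cohort spec, output directory and the global seed from which
#' all per-stage seeds derive (see \code{\link{derive_seed}}).
#'
#' @param seed Global integer seed.
#' @param n_trials,sigma,bounds Task walk settings.
#' @param fixed_schedule Logical; reuse one schedule for every subject (as
#'   in the original task) or draw per-subject schedules.
#' @param fit_starts Random restarts per model fit; set \code{fit_models =
#'   FALSE} to skip fitting for fast structural runs.
#' @param fit_models Logical; fit the observer to each simulated session.
#' @param spec A \code{cohort_spec} (or path to a YAML file with its
#'   fields).
#' @param value_timing Propensity timing convention.
#' @param out_dir Optional output directory; when given, every artifact is
#'   written there with provenance headers.
#' @return A \code{pipeline_config} list.
#' @export
pipeline_config <- function(seed = 1L, n_trials = 220L, sigma = 0.05,
                            bounds = c(0.1, 0.9), fixed_schedule = TRUE,
                            fit_starts = 10L, fit_models = TRUE,
                            spec = default_study_spec(),
                            value_timing = "literal", out_dir = NULL) {
  if (is.character(spec)) {
    fields <- yaml::read_yaml(spec)
    spec <- do.call(cohort_spec, fields)
  }
  stopifnot(inherits(spec, "cohort_spec"))
  spec$n_trials <- as.integer(n_trials)
  structure(list(seed = as.integer(seed), n_trials = as.integer(n_trials),
                 sigma = sigma, bounds = bounds,
                 fixed_schedule = isTRUE(fixed_schedule),
                 fit_starts = as.integer(fit_starts),
                 fit_models = isTRUE(fit_models), spec = spec,
                 value_timing = value_timing, out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the full analysis pipeline on synthetic data
#'
#' Cohort generation, session simulation (each subject's value signal sets
#' their softmax temperature), observer fits, value regressors and
#' performance summaries, and the group-level statistical battery: the
#' standardized regressions for the value-signal outcome (age + FA + BP_ND,
#' with single-predictor-beyond-age alternatives compared by BIC) and for
#' wins (age + FA + BP_ND + q_signal), the age-partialled correlation of
#' q_signal with wins, and the old-vs-young performance contrast.
#'
#' @param config A \code{pipeline_config}.
#' @return List with \code{cohort}, \code{sessions}, \code{fits} (or NULL),
#'   \code{performance}, \code{regressors}, \code{stats} (regression
#'   reports, BIC table, correlation, group contrast), and \code{provenance}.
#' @export
run_end_to_end <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  prov <- list(seed = config$seed, config_hash = config_hash(unclass(config)))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_domain("pipeline stage '", name, "' failed: ", conditionMessage(e))
    })
  }

  cohort <- stage("cohort", generate_cohort(config$spec,
                                            derive_seed(config$seed, "cohort")))
  n <- nrow(cohort)

  schedule0 <- generate_walk(config$n_trials,
                             seed = derive_seed(config$seed, "schedule"),
                             sigma = config$sigma, bounds = config$bounds)
  sessions <- stage("sessions", lapply(seq_len(n), function(i) {
    ws <- if (config$fixed_schedule) schedule0 else {
      generate_walk(config$n_trials,
                    seed = derive_seed(config$seed, paste0("schedule", i)),
                    sigma = config$sigma, bounds = config$bounds)
    }
    pars <- observer_params(beta = q_to_beta(cohort$q_signal[i]), omega = 0.3,
                            lambda = 0.1, upsilon = 0.5, kappa = 0.5)
    simulate_session(ws, observer_agent(pars, config$value_timing),
                     seed = derive_seed(config$seed, paste0("session", i)),
                     subject_id = cohort$subject_id[i])
  }))

  performance <- stage("metrics",
                       do.call(rbind, lapply(sessions, summarize_performance)))
  cohort$wins <- performance$wins   # wins observed in the simulated sessions

  fits <- NULL
  regressors <- NULL
  if (config$fit_models) {
    fits <- stage("fits", lapply(seq_len(n), function(i) {
      fit_observer(sessions[[i]], n_starts = config$fit_starts,
                   seed = derive_seed(config$seed, paste0("fit", i)),
                   value_timing = config$value_timing)
    }))
    regressors <- stage("regressors", lapply(seq_len(n), function(i) {
      lat <- run_observer(sessions[[i]], fits[[i]]$params_hat,
                          config$value_timing)
      extract_value_regressor(sessions[[i]], lat)
    }))
  }

  # The wins regression has k = 4 predictors; below n = 7 subjects the
  # group-level battery is not estimable and is skipped (structural smoke
  # runs at tiny n still complete).
  stats_out <- if (n < 7L) {
    warning("fewer than 7 subjects: group-level statistics skipped",
            call. = FALSE)
    NULL
  } else stage("stats", {
    preds_q <- data.frame(age = as.integer(cohort$age_group == "old"),
                          fa = cohort$fa, bpnd = cohort$bpnd)
    rep_q <- standardized_regression(cohort$q_signal, preds_q)
    rep_q$outcome <- "q_signal"
    alt <- list(
      "age+bpnd" = standardized_regression(cohort$q_signal,
                                           preds_q[c("age", "bpnd")]),
      "age+fa" = standardized_regression(cohort$q_signal,
                                         preds_q[c("age", "fa")]),
      "age+bpnd+fa" = rep_q
    )
    rep_wins <- standardized_regression(cohort$wins,
                                        cbind(preds_q,
                                              q_signal = cohort$q_signal))
    rep_wins$outcome <- "wins"
    list(
      q_signal_regression = rep_q,
      q_signal_model_comparison = compare_models_bic(alt),
      wins_regression = rep_wins,
      wins_q_correlation = correlation(cohort$wins, cohort$q_signal,
                                       control = preds_q["age"]),
      performance_age_contrast = group_difference(
        cohort$wins[cohort$age_group == "old"],
        cohort$wins[cohort$age_group == "young"], tail = "one")
    )
  })

  out <- list(cohort = cohort, sessions = sessions, fits = fits,
              performance = performance, regressors = regressors,
              stats = stats_out, provenance = prov)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    meta <- list(seed = prov$seed, config_hash = prov$config_hash)
    write_cohort(cohort, file.path(config$out_dir, "cohort.csv"), meta)
    write_with_header(performance,
                      file.path(config$out_dir, "performance.csv"), meta)
    write_schedule(schedule0, file.path(config$out_dir, "schedule.csv"), meta)
    for (i in seq_len(n)) {
      write_session(sessions[[i]],
                    file.path(config$out_dir,
                              paste0(cohort$subject_id[i], "_session.csv")),
                    meta)
      if (!is.null(regressors)) {
        write_with_header(regressors[[i]],
                          file.path(config$out_dir,
                                    paste0(cohort$subject_id[i],
                                           "_q_regressor.csv")), meta)
      }
    }
  }
  out
}
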