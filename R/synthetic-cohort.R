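#' Specify a synthetic subject cohort
#'
#' Defines a linear-Gaussian generative model on standardized variables for
#' a two-group (young/old) cohort with the covariate structure the group
#' analysis assumes: age group influences white-matter integrity (FA) and
#' dopamine D1 receptor availability (BP_ND) through separate paths; FA and
#' BP_ND receive independent residuals (their marginal correlation arises
#' only through age); both predict the vmPFC value-signal strength
#' (q_signal); q_signal alone predicts task wins.
#'
#' @param n_young,n_old Group sizes (each >= 2).
#' @param paths Named list of standardized path coefficients:
#'   \code{age_fa}, \code{age_bpnd}, \code{fa_q}, \code{bpnd_q},
#'   \code{q_wins}. Age is coded old = 1, so age-related decline means
#'   negative \code{age_fa} / \code{age_bpnd}.
#' @param fa_scale \code{c(mean, sd)} mapping standardized FA to its raw
#'   fractional-anisotropy scale.
#' @param bpnd_scale \code{c(mean, sd)} for the raw BP_ND scale (floored at
#'   0.05 to keep binding potentials positive).
#' @param wins_scale \code{c(mean, sd)} mapping standardized wins to a
#'   trial count (used by the linear wins mode).
#' @param age_ranges List with integer \code{young} and \code{old} age ranges.
#' @param wins_mode \code{"linear"} (wins from q_signal plus Gaussian noise,
#'   fast) or \code{"mechanistic"} (q_signal maps to a softmax temperature
#'   through a logistic link and wins come from simulated bandit sessions).
#' @param n_trials Trials per session in mechanistic mode.
#' @return A \code{cohort_spec}.
#' @export
cohort_spec <- function(n_young = 23L, n_old = 22L,
                        paths = list(age_fa = -0.5, age_bpnd = -0.5,
                                     fa_q = 0.49, bpnd_q = 0.41,
                                     q_wins = 0.54),
                        fa_scale = c(0.3253, 0.03),
                        bpnd_scale = c(1.5, 0.25),
                        wins_scale = c(128.21, 10),
                        age_ranges = list(young = c(19L, 32L),
                                          old = c(66L, 75L)),
                        wins_mode = c("linear", "mechanistic"),
                        n_trials = 220L) {
  wins_mode <- match.arg(wins_mode)
  stopifnot(n_young >= 2L, n_old >= 2L)
  needed <- c("age_fa", "age_bpnd", "fa_q", "bpnd_q", "q_wins")
  if (!all(needed %in% names(paths))) {
    stop_domain("paths must name: ", paste(needed, collapse = ", "))
  }
  if (abs(paths$age_fa) >= 1 || abs(paths$age_bpnd) >= 1 ||
      abs(paths$q_wins) >= 1) {
    stop_domain("single-parent standardized paths must have |coef| < 1")
  }
  # q_signal residual variance must be positive given the implied FA-BP_ND
  # correlation (which runs only through age).
  r_ab <- paths$age_fa * paths$age_bpnd
  explained <- paths$fa_q^2 + paths$bpnd_q^2 +
    2 * paths$fa_q * paths$bpnd_q * r_ab
  if (explained >= 1) {
    stop_domain("infeasible effect map: q_signal explained variance ",
                sprintf("%.3f >= 1", explained))
  }
  structure(list(n_young = as.integer(n_young), n_old = as.integer(n_old),
                 paths = paths, fa_scale = fa_scale, bpnd_scale = bpnd_scale,
                 wins_scale = wins_scale, age_ranges = age_ranges,
                 wins_mode = wins_mode, n_trials = as.integer(n_trials),
                 q_resid_var = 1 - explained),
            class = "cohort_spec")
}

#' Default cohort specification mirroring the study's structure
#'
#' 23 young and 22 old subjects; the FA scale is chosen so that the implied
#' raw group means are 0.34 (young) and 0.31 (old) with overall sd 0.03;
#' the q_signal paths are the multivariate standardized coefficients of the
#' value-signal regression (FA 0.49, BP_ND 0.41) and the wins path is the
#' value signal's multivariate coefficient for wins (0.54).
#'
#' @return A \code{cohort_spec}.
#' @export
default_study_spec <- function() cohort_spec()

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf("Synthetic cohort spec: %d young + %d old, wins mode '%s'\n",
              x$n_young, x$n_old, x$wins_mode))
  cat("  paths:", paste(sprintf("%s = %g", names(x$paths), unlist(x$paths)),
                        collapse = ", "), "\n")
  invisible(x)
}

# Logistic link from the standardized value signal to a softmax temperature,
# spanning near-random (beta ~ 0.5) to fairly deterministic (beta ~ 5.5).
q_to_beta <- function(q) 0.5 + 5 / (1 + exp(-1.5 * q))

#' Generate a synthetic cohort
#'
#' Draws subject records from the linear-Gaussian path model defined by the
#' supplied specification.
#' Age group is standardized as a 0/1 indicator; FA and BP_ND are each a
#' path coefficient times standardized age plus an independent Gaussian
#' residual scaled to unit marginal variance; q_signal combines the FA and
#' BP_ND paths the same way. In \code{"linear"} mode wins are
#' \code{q_wins * q_signal} plus matched residual noise, mapped to a count;
#' in \code{"mechanistic"} mode each subject's q_signal sets an observer
#' softmax temperature and wins are counted from a simulated session on a
#' shared walk schedule.
#'
#' @param spec A \code{cohort_spec}.
#' @param seed Integer seed; identical seeds give identical cohorts.
#' @return data.frame with columns \code{subject_id}, \code{age_group},
#'   \code{age}, \code{fa}, \code{bpnd}, \code{q_signal}, \code{wins}.
#' @export
generate_cohort <- function(spec = default_study_spec(), seed = 1L) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_young + spec$n_old
  pth <- spec$paths
  with_seed(seed, {
    old01 <- c(rep(0L, spec$n_young), rep(1L, spec$n_old))
    p_old <- spec$n_old / n
    age_z <- (old01 - p_old) / sqrt(p_old * (1 - p_old))
    age <- ifelse(old01 == 0L,
                  sample(seq(spec$age_ranges$young[1], spec$age_ranges$young[2]),
                         n, replace = TRUE),
                  sample(seq(spec$age_ranges$old[1], spec$age_ranges$old[2]),
                         n, replace = TRUE))
    fa_z <- pth$age_fa * age_z + sqrt(1 - pth$age_fa^2) * stats::rnorm(n)
    bpnd_z <- pth$age_bpnd * age_z + sqrt(1 - pth$age_bpnd^2) * stats::rnorm(n)
    q_signal <- pth$fa_q * fa_z + pth$bpnd_q * bpnd_z +
      sqrt(spec$q_resid_var) * stats::rnorm(n)
    fa <- spec$fa_scale[1] + spec$fa_scale[2] * fa_z
    bpnd <- pmax(spec$bpnd_scale[1] + spec$bpnd_scale[2] * bpnd_z, 0.05)
    wins <- if (spec$wins_mode == "linear") {
      wins_z <- pth$q_wins * q_signal + sqrt(1 - pth$q_wins^2) * stats::rnorm(n)
      pmin(pmax(round(spec$wins_scale[1] + spec$wins_scale[2] * wins_z), 0),
           spec$n_trials)
    } else {
      ws <- generate_walk(spec$n_trials, seed = derive_seed(seed, "schedule"))
      vapply(seq_len(n), function(i) {
        pars <- observer_params(beta = q_to_beta(q_signal[i]), omega = 0.3,
                                lambda = 0.1, upsilon = 0.5, kappa = 0.5)
        sess <- simulate_session(ws, observer_agent(pars),
                                 seed = derive_seed(seed, paste0("subj", i)))
        sum(sess$reward, na.rm = TRUE)
      }, numeric(1))
    }
    data.frame(
      subject_id = sprintf("sub%03d", seq_len(n)),
      age_group = factor(ifelse(old01 == 0L, "young", "old"),
                         levels = c("young", "old")),
      age = as.integer(age),
      fa = fa, bpnd = bpnd, q_signal = q_signal, wins = as.numeric(wins)
    )
  })
}
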