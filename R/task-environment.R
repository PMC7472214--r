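#' Generate reflected Gaussian random-walk reward probabilities
#'
#' Produces the restless two-armed bandit environment: two independent
#' reward-probability trajectories, each a Gaussian random walk reflected at
#' the configured bounds so probabilities never leave them. Each walk starts
#' at an independent uniform draw within the bounds.
#'
#' @param n_trials Number of trials (>= 1). The task used 2 x 110 = 220.
#' @param seed Integer seed; the same seed reproduces the schedule exactly.
#' @param sigma Per-step Gaussian standard deviation, in probability units.
#' @param bounds Length-2 numeric, reflection limits with
#'   \code{0 < lower < upper < 1}.
#' @return A \code{walk_schedule} object: list with \code{n_trials},
#'   \code{p} (an \code{n_trials} x 2 matrix of true reward probabilities),
#'   \code{seed}, \code{sigma}, \code{bounds}.
#' @examples
#' ws <- generate_walk(220, seed = 7)
#' range(ws$p)
#' @export
generate_walk <- function(n_trials, seed, sigma = 0.05, bounds = c(0.1, 0.9)) {
  if (!is_count(n_trials)) {
    stop_domain("`n_trials` must be a positive integer")
  }
  if (length(bounds) != 2L || !is.numeric(bounds) ||
      !(0 < bounds[1] && bounds[1] < bounds[2] && bounds[2] < 1)) {
    stop_domain("`bounds` must satisfy 0 < lower < upper < 1")
  }
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0) {
    stop_domain("`sigma` must be a positive step standard deviation")
  }
  p <- with_seed(seed, {
    start <- stats::runif(2, bounds[1], bounds[2])
    steps <- matrix(stats::rnorm(2 * n_trials, 0, sigma), n_trials, 2)
    out <- matrix(NA_real_, n_trials, 2)
    x <- start
    for (t in seq_len(n_trials)) {
      x <- reflect_into(x + steps[t, ], bounds[1], bounds[2])
      out[t, ] <- x
    }
    out
  })
  colnames(p) <- c("p0", "p1")
  structure(
    list(n_trials = as.integer(n_trials), p = p, seed = as.integer(seed),
         sigma = sigma, bounds = bounds),
    class = "walk_schedule"
  )
}

# Fold values back into [lo, hi] by repeated reflection at the bounds.
reflect_into <- function(x, lo, hi) {
  width <- hi - lo
  for (i in seq_along(x)) {
    while (x[i] < lo || x[i] > hi) {
      if (x[i] > hi) x[i] <- 2 * hi - x[i]
      if (x[i] < lo) x[i] <- 2 * lo - x[i]
    }
  }
  x
}

#' @export
print.walk_schedule <- function(x, ...) {
  cat(sprintf(
    "Two-armed bandit walk schedule: %d trials, sigma = %g, bounds = [%g, %g], seed = %d\n",
    x$n_trials, x$sigma, x$bounds[1], x$bounds[2], x$seed))
  invisible(x)
}

#' Play a single bandit trial
#'
#' Draws a Bernoulli reward from the true probability of the chosen bandit
#' at trial \code{t}. Uses the current RNG stream.
#'
#' @param schedule A \code{walk_schedule}.
#' @param t 1-based trial index.
#' @param choice Bandit index, 0 or 1.
#' @return A one-row data.frame: \code{trial}, \code{choice}, \code{reward},
#'   \code{p0}, \code{p1}.
#' @export
play_trial <- function(schedule, t, choice) {
  stopifnot(inherits(schedule, "walk_schedule"))
  if (!is_count(t) || t > schedule$n_trials) {
    stop_domain("trial index `t` out of range 1..", schedule$n_trials)
  }
  if (!choice %in% c(0, 1)) stop_domain("`choice` must be 0 or 1")
  p <- schedule$p[t, choice + 1L]
  reward <- as.integer(stats::runif(1) < p)
  data.frame(trial = as.integer(t), choice = as.integer(choice),
             reward = reward, p0 = schedule$p[t, 1], p1 = schedule$p[t, 2])
}

#' Construct a session object from trial data
#'
#' @param trials data.frame with columns \code{trial}, \code{choice} (0, 1 or
#'   NA for a missed trial), \code{reward} (0, 1 or NA iff missed),
#'   \code{p0}, \code{p1} (true probabilities; may be NA when unknown).
#' @param schedule Optional \code{walk_schedule} the session was played on.
#' @param subject_id Opaque subject label.
#' @return A \code{bandit_session} (data.frame subclass).
#' @export
bandit_session <- function(trials, schedule = NULL, subject_id = "s1") {
  required <- c("trial", "choice", "reward", "p0", "p1")
  missing_cols <- setdiff(required, names(trials))
  if (length(missing_cols)) {
    stop_domain("session is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  trials <- as.data.frame(trials)[required]
  n <- nrow(trials)
  if (n < 1L) stop_domain("session must contain at least one trial")
  if (!identical(as.integer(trials$trial), seq_len(n))) {
    stop_domain("trial indices must be consecutive from 1")
  }
  bad_choice <- !(trials$choice %in% c(0, 1) | is.na(trials$choice))
  if (any(bad_choice)) {
    stop_domain("invalid choice codes at rows: ",
                paste(which(bad_choice), collapse = ", "))
  }
  miss <- is.na(trials$choice)
  if (any(!miss & is.na(trials$reward)) || any(miss & !is.na(trials$reward))) {
    stop_domain("reward must be present exactly for non-missed trials")
  }
  bad_reward <- !miss & !(trials$reward %in% c(0, 1))
  if (any(bad_reward)) {
    stop_domain("rewards must be 0/1; offending rows: ",
                paste(which(bad_reward), collapse = ", "))
  }
  if (!is.null(schedule)) {
    stopifnot(inherits(schedule, "walk_schedule"))
    if (n != schedule$n_trials) {
      stop_domain("session length must equal the schedule's n_trials")
    }
  }
  structure(trials, class = c("bandit_session", "data.frame"),
            schedule = schedule, subject_id = subject_id)
}

#' Number of non-missed trials in a session
#' @param session A \code{bandit_session}.
#' @return Integer count.
#' @export
n_valid_trials <- function(session) {
  sum(!is.na(session$choice))
}

#' Agents for session simulation
#'
#' An agent is a list with two closures: \code{choose(t)} returning a bandit
#' index in \{0, 1\} and \code{observe(choice, reward)} informing it of the
#' outcome. \code{random_agent} picks uniformly; \code{fixed_agent} always
#' plays one bandit; \code{observer_agent} plays the Bayesian observer policy
#' under \code{params}, sampling choices from its softmax probabilities.
#'
#' @param params An \code{observer_params} object.
#' @param value_timing Propensity timing convention; see
#'   \code{\link{run_observer}}.
#' @return An agent list.
#' @export
observer_agent <- function(params, value_timing = c("literal", "post_update")) {
  params <- validate_observer_params(params)
  value_timing <- match.arg(value_timing)
  state <- init_beliefs()
  m <- c(0.5, 0.5)
  list(
    choose = function(t) {
      pr <- choice_probabilities(m, params$beta)
      as.integer(stats::runif(1) >= pr[1])
    },
    observe = function(choice, reward) {
      a <- choice + 1L
      u <- 2L - choice
      q_pre <- posterior_mean(state)
      v_pre <- posterior_variance(state)
      crel <- relative_confidence(state, choice)
      state <<- update_unchosen(update_chosen(state, choice, reward,
                                              params$omega),
                                1L - choice, params$lambda)
      if (value_timing == "post_update") {
        q_pre <- posterior_mean(state)
        v_pre <- posterior_variance(state)
        crel <- relative_confidence(state, choice)
      }
      m_new <- numeric(2)
      m_new[a] <- posterior_mean(state)[a]
      m_new[u] <- q_pre[u] + params$upsilon * v_pre[u] + params$kappa * crel
      m <<- m_new
      invisible(NULL)
    }
  )
}

#' @rdname observer_agent
#' @export
random_agent <- function() {
  list(choose = function(t) as.integer(stats::runif(1) < 0.5),
       observe = function(choice, reward) invisible(NULL))
}

#' @rdname observer_agent
#' @param bandit Bandit index the fixed agent always chooses.
#' @export
fixed_agent <- function(bandit = 0L) {
  stopifnot(bandit %in% c(0, 1))
  list(choose = function(t) as.integer(bandit),
       observe = function(choice, reward) invisible(NULL))
}

#' Simulate a full session of an agent playing a schedule
#'
#' Queries the agent in trial order, draws Bernoulli rewards from the true
#' walk probabilities, and informs the agent of each outcome. With
#' \code{miss_rate > 0}, trials are marked missed uniformly at random
#' (the agent is neither queried nor informed on missed trials).
#'
#' @param schedule A \code{walk_schedule}.
#' @param agent Agent list (see \code{\link{observer_agent}}).
#' @param seed Integer seed for rewards, agent choice sampling, and misses.
#' @param miss_rate Probability a trial is missed; default 0.
#' @param subject_id Session label.
#' @return A \code{bandit_session}.
#' @export
simulate_session <- function(schedule, agent, seed, miss_rate = 0,
                             subject_id = "s1") {
  stopifnot(inherits(schedule, "walk_schedule"))
  stopifnot(is.numeric(miss_rate), miss_rate >= 0, miss_rate < 1)
  n <- schedule$n_trials
  with_seed(seed, {
    choice <- rep(NA_integer_, n)
    reward <- rep(NA_integer_, n)
    missed <- stats::runif(n) < miss_rate
    for (t in seq_len(n)) {
      if (missed[t]) next
      a <- agent$choose(t)
      if (!isTRUE(a %in% c(0, 1))) {
        stop_domain("agent returned an invalid bandit index: ", a)
      }
      choice[t] <- as.integer(a)
      reward[t] <- as.integer(stats::runif(1) < schedule$p[t, a + 1L])
      agent$observe(choice[t], reward[t])
    }
    bandit_session(
      data.frame(trial = seq_len(n), choice = choice, reward = reward,
                 p0 = schedule$p[, 1], p1 = schedule$p[, 2]),
      schedule = schedule, subject_id = subject_id)
  })
}
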