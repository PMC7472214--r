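#' Observer model parameters
#'
#' Bundles the five free parameters of the Bayesian-observer choice model:
#' softmax temperature \code{beta} (> 0), chosen-bandit update/relaxation rate
#' \code{omega} in (0, 1), unchosen-bandit forgetting rate \code{lambda} in
#' (0, 1), exploration-bonus weight \code{upsilon} (any real, applied to the
#' unchosen bandit's posterior variance), and relative-confidence weight
#' \code{kappa} (any real).
#'
#' @param beta Softmax temperature, strictly positive (0 tolerated for the
#'   uniform-policy limit in tests).
#' @param omega Update rate of the chosen bandit's beta parameters, in (0, 1)
#'   (boundaries tolerated for limit tests).
#' @param lambda Forgetting rate of the unchosen bandit, in (0, 1)
#'   (boundaries tolerated).
#' @param upsilon Exploration-bonus weight, unbounded.
#' @param kappa Relative-confidence weight, unbounded.
#' @return An \code{observer_params} list.
#' @examples
#' observer_params(beta = 5, omega = 0.3, lambda = 0.1)
#' @export
observer_params <- function(beta, omega, lambda, upsilon = 0, kappa = 0) {
  validate_observer_params(
    structure(list(beta = beta, omega = omega, lambda = lambda,
                   upsilon = upsilon, kappa = kappa),
              class = "observer_params"))
}

validate_observer_params <- function(p) {
  if (!inherits(p, "observer_params")) {
    if (is.list(p) && all(c("beta", "omega", "lambda") %in% names(p))) {
      p$upsilon <- p$upsilon %||% 0
      p$kappa <- p$kappa %||% 0
      p <- structure(p[c("beta", "omega", "lambda", "upsilon", "kappa")],
                     class = "observer_params")
    } else {
      stop_domain("expected an observer_params object")
    }
  }
  v <- unlist(p)
  if (!all(is.finite(v))) stop_domain("observer parameters must be finite")
  if (p$beta < 0) stop_domain("softmax temperature beta must be >= 0")
  if (p$omega < 0 || p$omega > 1) stop_domain("omega must lie in [0, 1]")
  if (p$lambda < 0 || p$lambda > 1) stop_domain("lambda must lie in [0, 1]")
  p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.observer_params <- function(x, ...) {
  cat(sprintf(
    "Bayesian observer parameters: beta = %g, omega = %g, lambda = %g, upsilon = %g, kappa = %g\n",
    x$beta, x$omega, x$lambda, x$upsilon, x$kappa))
  invisible(x)
}

#' Initialize beta-distribution beliefs
#'
#' Both bandits start with a uniform Beta(1, 1) belief over their reward
#' probability, so the expected value of either bandit is 0.5 (chance level)
#' on the first trial.
#'
#' @return A \code{belief_state}: list with numeric \code{gamma} and
#'   \code{epsilon}, one entry per bandit, all equal to 1.
#' @examples
#' posterior_mean(init_beliefs())  # 0.5 0.5
#' @export
init_beliefs <- function() {
  structure(list(gamma = c(1, 1), epsilon = c(1, 1)), class = "belief_state")
}

check_belief <- function(state) {
  if (!is.list(state) || is.null(state$gamma) || is.null(state$epsilon)) {
    stop_domain("expected a belief_state with gamma and epsilon")
  }
  if (any(state$gamma <= 0) || any(state$epsilon <= 0)) {
    stop_domain("beta-distribution parameters must be strictly positive")
  }
  state
}

#' Posterior mean reward probability of each bandit
#'
#' The expected value Q of a Beta(gamma, epsilon) belief:
#' \code{gamma / (gamma + epsilon)}.
#'
#' @param state A \code{belief_state}.
#' @return Numeric length-2 vector in (0, 1).
#' @export
posterior_mean <- function(state) {
  state <- check_belief(state)
  state$gamma / (state$gamma + state$epsilon)
}

#' Posterior variance of each bandit's reward probability
#'
#' The variance V of a Beta(gamma, epsilon) belief:
#' \code{gamma * epsilon / ((gamma + epsilon)^2 * (gamma + epsilon + 1))}.
#' At the uniform initialization this is 1/12 for both bandits.
#'
#' @param state A \code{belief_state}.
#' @return Numeric length-2 vector in (0, 0.25].
#' @export
posterior_variance <- function(state) {
  state <- check_belief(state)
  s <- state$gamma + state$epsilon
  state$gamma * state$epsilon / (s^2 * (s + 1))
}

#' Update the chosen bandit's belief after an outcome
#'
#' The chosen bandit's beta parameters are relaxed toward 1 at rate
#' \code{omega} and the parameter matching the outcome is incremented:
#' after a reward, \code{gamma' = (1 - omega) * gamma + omega + 1} and
#' \code{epsilon' = (1 - omega) * epsilon + omega}; after an omission the
#' increment goes to \code{epsilon} instead. The other bandit is untouched.
#'
#' @param state A \code{belief_state}.
#' @param choice Chosen bandit index, 0 or 1.
#' @param reward Outcome, 0 or 1.
#' @param omega Relaxation rate in [0, 1].
#' @return The updated \code{belief_state}.
#' @export
update_chosen <- function(state, choice, reward, omega) {
  state <- check_belief(state)
  if (!choice %in% c(0, 1)) stop_domain("`choice` must be 0 or 1")
  if (!reward %in% c(0, 1)) stop_domain("`reward` must be 0 or 1")
  if (omega < 0 || omega > 1) stop_domain("omega must lie in [0, 1]")
  i <- choice + 1L
  g <- (1 - omega) * state$gamma[i] + omega + (reward == 1)
  e <- (1 - omega) * state$epsilon[i] + omega + (reward == 0)
  state$gamma[i] <- max(g, 1e-8)
  state$epsilon[i] <- max(e, 1e-8)
  state
}

#' Relax the unchosen bandit's belief toward the uniform prior
#'
#' Both beta parameters of the unchosen bandit decay geometrically toward 1:
#' \code{x' = (1 - lambda) * x + lambda}. A bandit never chosen again
#' therefore forgets at rate \code{1 - lambda} per trial, converging to the
#' chance-level belief Beta(1, 1).
#'
#' @param state A \code{belief_state}.
#' @param unchosen Unchosen bandit index, 0 or 1.
#' @param lambda Forgetting rate in [0, 1].
#' @return The updated \code{belief_state}.
#' @export
update_unchosen <- function(state, unchosen, lambda) {
  state <- check_belief(state)
  if (!unchosen %in% c(0, 1)) stop_domain("`unchosen` must be 0 or 1")
  if (lambda < 0 || lambda > 1) stop_domain("lambda must lie in [0, 1]")
  i <- unchosen + 1L
  state$gamma[i] <- max((1 - lambda) * state$gamma[i] + lambda, 1e-8)
  state$epsilon[i] <- max((1 - lambda) * state$epsilon[i] + lambda, 1e-8)
  state
}

# Cached Gauss-Legendre nodes/weights on [0, 1].
.gl_cache <- new.env(parent = emptyenv())
gl_rule <- function(n) {
  key <- as.character(n)
  if (is.null(.gl_cache[[key]])) {
    .gl_cache[[key]] <- pracma::gaussLegendre(n, 0, 1)
  }
  .gl_cache[[key]]
}

#' Probability that one beta variate exceeds another
#'
#' Computes \eqn{P(\theta_1 > \theta_0)} for independent
#' \eqn{\theta_1 \sim Beta(\gamma_1, \varepsilon_1)} and
#' \eqn{\theta_0 \sim Beta(\gamma_0, \varepsilon_0)} as
#' \eqn{\int_0^1 f_1(x) F_0(x) dx} by deterministic quadrature.
#'
#' The default adaptive rule handles shape parameters below 1 (integrable
#' endpoint singularities); \code{method = "gauss"} uses a fixed
#' Gauss-Legendre rule, accurate when all shapes are >= 1 (always true inside
#' the observer recursion) and much faster.
#'
#' @param gamma1,epsilon1 Shape parameters of the first distribution (> 0).
#' @param gamma0,epsilon0 Shape parameters of the second distribution (> 0).
#' @param method \code{"auto"} (Gauss-Legendre when all shapes >= 1, else
#'   adaptive), \code{"adaptive"}, or \code{"gauss"}.
#' @param nodes Number of Gauss-Legendre nodes.
#' @return The probability, absolute accuracy better than 1e-6.
#' @examples
#' prob_first_beta_greater(2, 1, 1, 1)  # 2/3
#' @export
prob_first_beta_greater <- function(gamma1, epsilon1, gamma0, epsilon0,
                                    method = c("auto", "adaptive", "gauss"),
                                    nodes = 64L) {
  method <- match.arg(method)
  sh <- c(gamma1, epsilon1, gamma0, epsilon0)
  if (!all(is.finite(sh)) || any(sh <= 0)) {
    stop_domain("all four beta shape parameters must be positive")
  }
  if (method == "auto") {
    method <- if (all(sh >= 1)) "gauss" else "adaptive"
  }
  p <- if (method == "gauss") {
    gl <- gl_rule(nodes)
    sum(gl$w * stats::dbeta(gl$x, gamma1, epsilon1) *
          stats::pbeta(gl$x, gamma0, epsilon0))
  } else {
    stats::integrate(
      function(x) stats::dbeta(x, gamma1, epsilon1) *
        stats::pbeta(x, gamma0, epsilon0),
      0, 1, rel.tol = 1e-10, abs.tol = 1e-10, subdivisions = 1000L,
      stop.on.error = FALSE)$value
  }
  min(max(p, 0), 1)
}

# Vectorized Gauss-Legendre P(theta1 > theta0) over rows of shape vectors.
# Valid for shapes >= 1 (guaranteed inside the observer recursion, where all
# beta parameters stay >= 1 under omega, lambda in [0, 1]).
prob_greater_batch <- function(g1, e1, g0, e0, nodes = 64L) {
  n <- length(g1)
  if (n == 0L) return(numeric(0))
  gl <- gl_rule(nodes)
  x <- matrix(gl$x, n, nodes, byrow = TRUE)
  d <- stats::dbeta(x, g1, e1)       # shape vectors recycle down columns
  f <- stats::pbeta(x, g0, e0)
  p <- as.numeric((d * f) %*% gl$w)
  pmin(pmax(p, 0), 1)
}

#' Relative confidence in the chosen bandit
#'
#' The signed probability that the chosen bandit's reward rate exceeds the
#' unchosen one's: \code{2 * P(theta_chosen > theta_unchosen) - 1}, in
#' [-1, 1]. Swapping the roles of the bandits flips the sign (the two
#' complementary probabilities sum to 1 for continuous beliefs).
#'
#' @param state A \code{belief_state}.
#' @param chosen Chosen bandit index, 0 or 1.
#' @param ... Passed to \code{\link{prob_first_beta_greater}}.
#' @return A scalar in [-1, 1].
#' @export
relative_confidence <- function(state, chosen, ...) {
  state <- check_belief(state)
  if (!chosen %in% c(0, 1)) stop_domain("`chosen` must be 0 or 1")
  a <- chosen + 1L
  u <- 2L - chosen
  2 * prob_first_beta_greater(state$gamma[a], state$epsilon[a],
                              state$gamma[u], state$epsilon[u], ...) - 1
}

#' Action propensities for the next trial
#'
#' After the trial-t outcome has been observed and beliefs updated, the
#' propensities entering the softmax at trial t+1 are: for the bandit chosen
#' at t, its post-update expected value; for the unchosen bandit, its
#' expected value plus \code{upsilon} times its posterior variance (the
#' exploration bonus) plus \code{kappa} times the relative confidence in the
#' trial-t choice. Under the default \code{"literal"} timing the unchosen
#' bandit's terms are evaluated from the pre-update trial-t belief state;
#' under \code{"post_update"} they come from the updated state.
#'
#' @param state_prev Belief state under which the trial-t choice was made.
#' @param state_new Belief state after the trial-t updates.
#' @param chosen_prev Bandit chosen at trial t (0 or 1).
#' @param params An \code{observer_params}.
#' @param value_timing \code{"literal"} or \code{"post_update"}.
#' @return Numeric length-2 propensity vector.
#' @export
propensities <- function(state_prev, state_new, chosen_prev, params,
                         value_timing = c("literal", "post_update")) {
  value_timing <- match.arg(value_timing)
  params <- validate_observer_params(params)
  state_prev <- check_belief(state_prev)
  state_new <- check_belief(state_new)
  if (!chosen_prev %in% c(0, 1)) stop_domain("`chosen_prev` must be 0 or 1")
  a <- chosen_prev + 1L
  u <- 2L - chosen_prev
  ref <- if (value_timing == "literal") state_prev else state_new
  q <- posterior_mean(ref)
  v <- posterior_variance(ref)
  crel <- relative_confidence(ref, chosen_prev)
  m <- numeric(2)
  m[a] <- posterior_mean(state_new)[a]
  m[u] <- q[u] + params$upsilon * v[u] + params$kappa * crel
  m
}

#' Softmax choice probabilities
#'
#' Maps a pair of action propensities to choice probabilities through a
#' temperature-scaled softmax, computed in max-subtracted form for numerical
#' stability. \code{beta = 0} gives the uniform policy.
#'
#' @param m Numeric length-2 propensity vector.
#' @param beta Softmax temperature, >= 0.
#' @return Numeric length-2 probability vector summing to 1.
#' @export
choice_probabilities <- function(m, beta) {
  if (length(m) != 2L || !all(is.finite(m))) {
    stop_domain("propensities must be two finite numbers")
  }
  if (!is.finite(beta) || beta < 0) stop_domain("beta must be >= 0 and finite")
  z <- beta * m
  z <- z - max(z)
  ez <- exp(z)
  ez / sum(ez)
}

#' Run the Bayesian observer over an observed session
#'
#' Forward pass of the belief recursion over a session's choices and rewards,
#' returning the per-trial latent variables: expected values Q, posterior
#' variances V, relative confidence C_rel of the trial's choice, action
#' propensities m, and softmax choice probabilities. On the first trial the
#' propensities equal the prior means (0.5), so the model predicts chance
#' choice. Missed trials trigger no belief update and carry the previous
#' propensities forward; their C_rel is NA.
#'
#' @param session A \code{bandit_session}.
#' @param params An \code{observer_params}.
#' @param value_timing Timing convention for the unchosen-bandit propensity
#'   terms; see \code{\link{propensities}}.
#' @param nodes Gauss-Legendre node count for the confidence integrals.
#' @return An \code{observer_latents} data.frame with columns \code{trial},
#'   \code{Q0}, \code{Q1}, \code{V0}, \code{V1}, \code{Crel}, \code{m0},
#'   \code{m1}, \code{p_choice0}, \code{p_choice1}. Attribute \code{"beliefs"}
#'   holds the gamma/epsilon trajectories (rows = trial-start states 1..T+1).
#' @export
run_observer <- function(session, params,
                         value_timing = c("literal", "post_update"),
                         nodes = 64L) {
  value_timing <- match.arg(value_timing)
  params <- validate_observer_params(params)
  if (!inherits(session, "bandit_session")) {
    session <- bandit_session(session)
  }
  n <- nrow(session)
  choice <- session$choice
  reward <- session$reward
  miss <- is.na(choice)

  # Belief trajectories depend only on (omega, lambda) and the data, so one
  # cheap sequential pass suffices; everything else is vectorized.
  G <- matrix(1, n + 1L, 2L)
  E <- matrix(1, n + 1L, 2L)
  om <- params$omega; la <- params$lambda
  for (t in seq_len(n)) {
    g <- G[t, ]; e <- E[t, ]
    if (!miss[t]) {
      i <- choice[t] + 1L
      j <- 3L - i
      keep <- 1 - om
      if (reward[t] == 1) {
        g[i] <- keep * g[i] + om + 1
        e[i] <- keep * e[i] + om
      } else {
        g[i] <- keep * g[i] + om
        e[i] <- keep * e[i] + om + 1
      }
      g[j] <- (1 - la) * g[j] + la
      e[j] <- (1 - la) * e[j] + la
    }
    G[t + 1L, ] <- pmax(g, 1e-8)
    E[t + 1L, ] <- pmax(e, 1e-8)
  }

  S <- G + E
  Q <- G / S
  V <- G * E / (S^2 * (S + 1))

  # Relative confidence of each non-missed trial's choice, evaluated from
  # the reference state required by the timing convention.
  ref_row <- if (value_timing == "literal") 0L else 1L
  crel <- rep(NA_real_, n)
  idx <- which(!miss)
  if (length(idx)) {
    r <- idx + ref_row
    ai <- choice[idx] + 1L
    ui <- 3L - ai
    g_a <- G[cbind(r, ai)]; e_a <- E[cbind(r, ai)]
    g_u <- G[cbind(r, ui)]; e_u <- E[cbind(r, ui)]
    crel[idx] <- 2 * prob_greater_batch(g_a, e_a, g_u, e_u, nodes) - 1
  }

  m <- matrix(NA_real_, n, 2L)
  m[1L, ] <- Q[1L, ]
  if (n > 1L) {
    for (t in 2L:n) {
      s <- t - 1L
      if (miss[s]) {
        m[t, ] <- m[s, ]
      } else {
        a <- choice[s] + 1L
        u <- 3L - a
        ref <- s + ref_row
        m[t, a] <- Q[t, a]
        m[t, u] <- Q[ref, u] + params$upsilon * V[ref, u] +
          params$kappa * crel[s]
      }
    }
  }

  z <- params$beta * m
  zmax <- pmax(z[, 1], z[, 2])
  ez <- exp(z - zmax)
  p <- ez / (ez[, 1] + ez[, 2])

  out <- data.frame(
    trial = seq_len(n),
    Q0 = Q[seq_len(n), 1], Q1 = Q[seq_len(n), 2],
    V0 = V[seq_len(n), 1], V1 = V[seq_len(n), 2],
    Crel = crel,
    m0 = m[, 1], m1 = m[, 2],
    p_choice0 = p[, 1], p_choice1 = p[, 2]
  )
  structure(out, class = c("observer_latents", "data.frame"),
            beliefs = list(gamma = G, epsilon = E),
            params = params, value_timing = value_timing)
}
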