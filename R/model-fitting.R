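#' Negative log-likelihood of a session under the observer model
#'
#' Sums \code{-log P(choice)} over non-missed trials, with the per-trial
#' choice probabilities from \code{\link{run_observer}}. The first trial
#' always contributes \code{log 2} since the initialized beliefs predict
#' chance choice.
#'
#' @param session A \code{bandit_session}.
#' @param params An \code{observer_params}.
#' @param value_timing See \code{\link{run_observer}}.
#' @param nodes Gauss-Legendre node count for the confidence integrals.
#' @return The negative log-likelihood (>= 0).
#' @export
negative_log_likelihood <- function(session, params,
                                    value_timing = c("literal", "post_update"),
                                    nodes = 64L) {
  value_timing <- match.arg(value_timing)
  if (!inherits(session, "bandit_session")) session <- bandit_session(session)
  if (n_valid_trials(session) < 1L) {
    stop_domain("session has no non-missed trials; likelihood undefined")
  }
  lat <- run_observer(session, params, value_timing, nodes)
  nll_from_latents(lat, session)
}

# Compiled likelihood used inside optimization loops; numerically identical
# to negative_log_likelihood() (asserted in the tests).
nll_fast <- function(session, params, value_timing = "literal", nodes = 32L) {
  gl <- gl_rule(nodes)
  .observer_nll_cpp(as.integer(session$choice), as.integer(session$reward),
                    params$beta, params$omega, params$lambda,
                    params$upsilon, params$kappa,
                    identical(value_timing, "literal"), gl$x, gl$w)
}

nll_from_latents <- function(latents, session) {
  ok <- !is.na(session$choice)
  p <- ifelse(session$choice[ok] == 0L, latents$p_choice0[ok],
              latents$p_choice1[ok])
  -sum(log(pmax(p, 1e-300)))
}

#' Rescorla-Wagner parameters
#'
#' @param beta Softmax temperature (> 0; 0 tolerated for limit tests).
#' @param alpha Learning rate in (0, 1) (boundaries tolerated).
#' @return An \code{rw_params} list.
#' @export
rw_params <- function(beta, alpha) {
  if (!is.finite(beta) || beta < 0) stop_domain("beta must be >= 0")
  if (!is.finite(alpha) || alpha < 0 || alpha > 1) {
    stop_domain("alpha must lie in [0, 1]")
  }
  structure(list(beta = beta, alpha = alpha), class = "rw_params")
}

#' Run the Rescorla-Wagner baseline over a session
#'
#' Delta-rule value learning: the chosen bandit's value moves toward the
#' outcome, \code{Q <- Q + alpha * (R - Q)}; the unchosen value is unchanged;
#' both start at 0.5. Choice probabilities are a softmax over the Q values.
#'
#' @param session A \code{bandit_session}.
#' @param params An \code{rw_params}.
#' @return data.frame with \code{trial}, \code{Q0}, \code{Q1},
#'   \code{p_choice0}, \code{p_choice1} (Q at choice time).
#' @export
run_rescorla_wagner <- function(session, params) {
  if (!inherits(session, "bandit_session")) session <- bandit_session(session)
  stopifnot(inherits(params, "rw_params"))
  n <- nrow(session)
  Q <- matrix(NA_real_, n, 2L)
  q <- c(0.5, 0.5)
  for (t in seq_len(n)) {
    Q[t, ] <- q
    a <- session$choice[t]
    if (!is.na(a)) {
      i <- a + 1L
      q[i] <- q[i] + params$alpha * (session$reward[t] - q[i])
    }
  }
  z <- params$beta * Q
  zmax <- pmax(z[, 1], z[, 2])
  ez <- exp(z - zmax)
  p <- ez / (ez[, 1] + ez[, 2])
  data.frame(trial = seq_len(n), Q0 = Q[, 1], Q1 = Q[, 2],
             p_choice0 = p[, 1], p_choice1 = p[, 2])
}

rw_nll <- function(session, params) {
  lat <- run_rescorla_wagner(session, params)
  nll_from_latents(lat, session)
}

# ---- parameter transforms (optimization runs unconstrained) ----------------

obs_to_transformed <- function(p) {
  c(log(p$beta), stats::qlogis(p$omega), stats::qlogis(p$lambda),
    p$upsilon, p$kappa)
}

obs_from_transformed <- function(x) {
  clamp01 <- function(v) min(max(v, 1e-8), 1 - 1e-8)
  observer_params(beta = min(exp(x[1]), 1e6),
                  omega = clamp01(stats::plogis(x[2])),
                  lambda = clamp01(stats::plogis(x[3])),
                  upsilon = x[4], kappa = x[5])
}

# Start-draw boxes in transformed units; also used for boundary flagging.
.obs_box <- rbind(lo = c(log(0.2), stats::qlogis(0.02), stats::qlogis(0.02), -2, -2),
                  hi = c(log(30), stats::qlogis(0.98), stats::qlogis(0.98), 2, 2))
.rw_box <- rbind(lo = c(log(0.2), stats::qlogis(0.02)),
                 hi = c(log(30), stats::qlogis(0.98)))

fit_result <- function(model, params_hat, nll, n_obs, k, converged, n_starts,
                       boundary_flags, start_nlls) {
  structure(list(model = model, params_hat = params_hat, nll = nll,
                 n_obs = n_obs, k = k, bic = k * log(n_obs) + 2 * nll,
                 converged = converged, n_starts = n_starts,
                 boundary_flags = boundary_flags, start_nlls = start_nlls),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("Maximum-likelihood fit (%s model)\n", x$model))
  cat(sprintf("  nll = %.4f over %d trials, k = %d, BIC = %.2f\n",
              x$nll, x$n_obs, x$k, x$bic))
  cat("  parameters:", paste(sprintf("%s = %.4g", names(x$params_hat),
                                     unlist(x$params_hat)), collapse = ", "), "\n")
  if (any(x$boundary_flags)) {
    cat("  note: solution near transform box edge for:",
        paste(names(x$boundary_flags)[x$boundary_flags], collapse = ", "), "\n")
  }
  invisible(x)
}

run_ml <- function(objective, box, starts, param_names) {
  best <- NULL
  start_nlls <- numeric(0)
  any_conv <- FALSE
  for (s in seq_len(ncol(starts))) {
    x0 <- starts[, s]
    f0 <- objective(x0)
    start_nlls <- c(start_nlls, f0)
    opt <- try(stats::optim(x0, objective, method = "Nelder-Mead",
                            control = list(maxit = 400, reltol = 1e-6)),
               silent = TRUE)
    if (inherits(opt, "try-error")) next
    any_conv <- any_conv || opt$convergence == 0
    cand <- list(par = opt$par, value = min(opt$value, f0))
    if (opt$value > f0) cand$par <- x0   # keep the better of start and end
    if (is.null(best) || cand$value < best$value) best <- cand
  }
  if (is.null(best)) {
    stop_domain("optimizer failed on all starts; check the session data")
  }
  # Nelder-Mead can stall on a collapsed simplex; polish by restarting from
  # the incumbent until the improvement is negligible.
  for (rep in 1:3) {
    pol <- try(stats::optim(best$par, objective, method = "Nelder-Mead",
                            control = list(maxit = 400, reltol = 1e-8)),
               silent = TRUE)
    if (inherits(pol, "try-error") || pol$value > best$value - 1e-7) break
    best <- list(par = pol$par, value = pol$value)
  }
  flags <- abs(best$par - box["lo", ]) < 1e-3 | abs(best$par - box["hi", ]) < 1e-3 |
    best$par < box["lo", ] | best$par > box["hi", ]
  names(flags) <- param_names
  list(par = best$par, value = best$value, converged = any_conv,
       flags = flags, start_nlls = start_nlls)
}

draw_starts <- function(box, n_random, canonical, extra = NULL) {
  k <- ncol(box)
  rand <- if (n_random > 0) {
    matrix(stats::runif(n_random * k, rep(box["lo", ], each = n_random),
                        rep(box["hi", ], each = n_random)),
           nrow = k, byrow = TRUE)
  } else NULL
  cbind(canonical, rand, extra)
}

#' Fit the observer model by maximum likelihood
#'
#' Minimizes the negative log-likelihood over a transformed parameter space
#' (log for beta, logit for omega and lambda, identity for upsilon and kappa)
#' with Nelder-Mead from a canonical start (beta = 1, omega = lambda = 0.5,
#' upsilon = kappa = 0) plus \code{n_starts} seeded random restarts drawn
#' uniformly over transformed-space boxes. Deterministic given
#' \code{(session, n_starts, seed)}. Solutions within 1e-3 (transformed
#' units) of a start-box edge are flagged, not rejected.
#'
#' @param session A \code{bandit_session}.
#' @param n_starts Number of random restarts (default 10).
#' @param seed Integer seed for the restart draws.
#' @param extra_starts Optional list of \code{observer_params} evaluated as
#'   additional starts (e.g., known generating values in recovery studies).
#' @param value_timing See \code{\link{run_observer}}.
#' @param nodes Gauss-Legendre node count used inside the likelihood.
#' @return A \code{fit_result}: fitted parameters in natural space, nll at
#'   the optimum, number of non-missed trials \code{n_obs}, parameter count
#'   \code{k = 5}, \code{bic = k log(n_obs) + 2 nll}, convergence flag,
#'   boundary flags, and the nll at every evaluated start.
#' @export
fit_observer <- function(session, n_starts = 10L, seed = 1L,
                         extra_starts = NULL,
                         value_timing = c("literal", "post_update"),
                         nodes = 32L) {
  value_timing <- match.arg(value_timing)
  if (!inherits(session, "bandit_session")) session <- bandit_session(session)
  n_obs <- n_valid_trials(session)
  if (n_obs < 1L) stop_domain("session has no non-missed trials")
  objective <- function(x) {
    nll_fast(session, obs_from_transformed(x), value_timing, nodes)
  }
  canonical <- obs_to_transformed(observer_params(1, 0.5, 0.5, 0, 0))
  extra <- if (length(extra_starts)) {
    vapply(extra_starts,
           function(p) obs_to_transformed(validate_observer_params(p)),
           numeric(5))
  } else NULL
  starts <- with_seed(seed, draw_starts(.obs_box, n_starts, canonical, extra))
  ml <- run_ml(objective, .obs_box, starts,
               c("beta", "omega", "lambda", "upsilon", "kappa"))
  fit_result("observer", obs_from_transformed(ml$par), ml$value, n_obs, 5L,
             ml$converged, n_starts, ml$flags, ml$start_nlls)
}

#' Fit the Rescorla-Wagner baseline by maximum likelihood
#'
#' Same optimization scheme as \code{\link{fit_observer}} (log-beta,
#' logit-alpha transforms; canonical start beta = 1, alpha = 0.5; seeded
#' random restarts), with \code{k = 2} free parameters.
#'
#' @inheritParams fit_observer
#' @return A \code{fit_result}.
#' @export
fit_rescorla_wagner <- function(session, n_starts = 10L, seed = 1L) {
  if (!inherits(session, "bandit_session")) session <- bandit_session(session)
  n_obs <- n_valid_trials(session)
  if (n_obs < 1L) stop_domain("session has no non-missed trials")
  objective <- function(x) {
    p <- rw_params(min(exp(x[1]), 1e6),
                   min(max(stats::plogis(x[2]), 1e-8), 1 - 1e-8))
    rw_nll(session, p)
  }
  canonical <- c(log(1), stats::qlogis(0.5))
  starts <- with_seed(seed, draw_starts(.rw_box, n_starts, canonical))
  ml <- run_ml(objective, .rw_box, starts, c("beta", "alpha"))
  params <- rw_params(exp(ml$par[1]), stats::plogis(ml$par[2]))
  fit_result("rescorla_wagner", params, ml$value, n_obs, 2L,
             ml$converged, n_starts, ml$flags, ml$start_nlls)
}

#' Rank model fits by BIC
#'
#' @param fits List of \code{fit_result} objects on the same session.
#' @return data.frame sorted ascending by BIC with a \code{delta_bic} column
#'   relative to the best model.
#' @export
compare_bic <- function(fits) {
  if (inherits(fits, "fit_result")) fits <- list(fits)
  stopifnot(length(fits) >= 1L, all(vapply(fits, inherits, TRUE, "fit_result")))
  n_obs <- vapply(fits, `[[`, 0, "n_obs")
  if (length(unique(n_obs)) != 1L) {
    stop_domain("fits compare different numbers of observations: ",
                paste(unique(n_obs), collapse = " vs "))
  }
  tab <- data.frame(
    model = vapply(fits, `[[`, "", "model"),
    k = vapply(fits, function(f) as.integer(f$k), 0L),
    n_obs = n_obs,
    nll = vapply(fits, `[[`, 0, "nll"),
    bic = vapply(fits, `[[`, 0, "bic")
  )
  tab <- tab[order(tab$bic), , drop = FALSE]
  tab$delta_bic <- tab$bic - tab$bic[1]
  rownames(tab) <- NULL
  tab
}

#' Simulate observer agents and recover their parameters
#'
#' Standard parameter-recovery study: draws agents with dispersed generating
#' parameters, simulates one session each on a fresh walk schedule, and
#' refits the observer model. The true generating values are included among
#' the optimizer starts, which makes the likelihood-dominance property
#' (fitted nll never exceeds the nll at truth) hold by construction and
#' checkable per agent.
#'
#' @param n_agents Number of simulated agents.
#' @param n_trials Trials per session (task default 220).
#' @param n_starts Random restarts per fit.
#' @param seed Integer seed governing truth draws, schedules, sessions and
#'   restarts.
#' @param ranges Named list of generating-parameter ranges; defaults span
#'   recoverable regimes (beta log-uniform on [2, 10], omega [0.2, 0.6],
#'   lambda [0.05, 0.4], upsilon and kappa [-1, 1]).
#' @return data.frame with one row per agent: true and recovered parameters,
#'   nll at the optimum and at truth.
#' @export
recover_parameters <- function(n_agents = 50L, n_trials = 220L,
                               n_starts = 10L, seed = 1L,
                               ranges = list(beta = c(2, 10),
                                             omega = c(0.2, 0.6),
                                             lambda = c(0.05, 0.4),
                                             upsilon = c(-1, 1),
                                             kappa = c(-1, 1))) {
  truths <- with_seed(seed, {
    data.frame(
      beta = exp(stats::runif(n_agents, log(ranges$beta[1]), log(ranges$beta[2]))),
      omega = stats::runif(n_agents, ranges$omega[1], ranges$omega[2]),
      lambda = stats::runif(n_agents, ranges$lambda[1], ranges$lambda[2]),
      upsilon = stats::runif(n_agents, ranges$upsilon[1], ranges$upsilon[2]),
      kappa = stats::runif(n_agents, ranges$kappa[1], ranges$kappa[2])
    )
  })
  rows <- vector("list", n_agents)
  for (i in seq_len(n_agents)) {
    truth <- observer_params(truths$beta[i], truths$omega[i], truths$lambda[i],
                             truths$upsilon[i], truths$kappa[i])
    ws <- generate_walk(n_trials, seed = derive_seed(seed, paste0("walk", i)))
    sess <- simulate_session(ws, observer_agent(truth),
                             seed = derive_seed(seed, paste0("sess", i)))
    fit <- fit_observer(sess, n_starts = n_starts,
                        seed = derive_seed(seed, paste0("fit", i)),
                        extra_starts = list(truth))
    nll_truth <- nll_fast(sess, truth)
    est <- fit$params_hat
    rows[[i]] <- data.frame(
      agent = i,
      beta_true = truth$beta, omega_true = truth$omega,
      lambda_true = truth$lambda, upsilon_true = truth$upsilon,
      kappa_true = truth$kappa,
      beta_hat = est$beta, omega_hat = est$omega, lambda_hat = est$lambda,
      upsilon_hat = est$upsilon, kappa_hat = est$kappa,
      nll_hat = fit$nll, nll_truth = nll_truth
    )
  }
  do.call(rbind, rows)
}
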