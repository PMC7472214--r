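test_that("initialized beliefs are uniform with chance-level expected value", {
  b <- init_beliefs()
  expect_identical(b$gamma, c(1, 1))
  expect_identical(b$epsilon, c(1, 1))
  expect_identical(posterior_mean(b), c(0.5, 0.5))
  expect_equal(posterior_variance(b), c(1 / 12, 1 / 12))
})

test_that("posterior mean and variance follow the beta-distribution formulas", {
  st <- list(gamma = c(3, 2.5), epsilon = c(1, 7.5))
  expect_equal(posterior_mean(st), c(0.75, 0.25))
  st2 <- list(gamma = c(2, 10), epsilon = c(2, 10))
  expect_equal(posterior_variance(st2)[1], 0.05)
  expect_lt(posterior_variance(st2)[2], posterior_variance(init_beliefs())[2])
  expect_error(posterior_mean(list(gamma = c(0, 1), epsilon = c(1, 1))),
               "positive")
})

test_that("chosen-bandit update increments the outcome parameter and relaxes", {
  st <- list(gamma = c(2, 1), epsilon = c(3, 1))
  up <- update_chosen(st, 0, 1, omega = 0)
  expect_equal(up$gamma[1], 3)
  expect_equal(up$epsilon[1], 3)
  up1 <- update_chosen(list(gamma = c(9, 1), epsilon = c(4, 1)), 0, 1, omega = 1)
  expect_equal(c(up1$gamma[1], up1$epsilon[1]), c(2, 1))
  up2 <- update_chosen(list(gamma = c(2, 1), epsilon = c(2, 1)), 0, 0, omega = 0.5)
  expect_equal(c(up2$gamma[1], up2$epsilon[1]), c(1.5, 2.5))
  # other bandit untouched
  expect_equal(c(up2$gamma[2], up2$epsilon[2]), c(1, 1))
  expect_error(update_chosen(st, 0, 2, 0.5), "reward")
})

test_that("unchosen-bandit forgetting relaxes both parameters toward 1", {
  st <- list(gamma = c(1, 3), epsilon = c(1, 2))
  expect_equal(update_unchosen(st, 1, 0)[c("gamma", "epsilon")],
               st[c("gamma", "epsilon")])
  full <- update_unchosen(st, 1, 1)
  expect_equal(c(full$gamma[2], full$epsilon[2]), c(1, 1))
  half <- update_unchosen(list(gamma = c(1, 3), epsilon = c(1, 1)), 1, 0.5)
  expect_equal(c(half$gamma[2], half$epsilon[2]), c(2, 1))
})

test_that("beta dominance probability matches closed forms and is complementary", {
  expect_equal(prob_first_beta_greater(1, 1, 1, 1), 0.5, tolerance = 1e-9)
  expect_equal(prob_first_beta_greater(2, 1, 1, 1), 2 / 3, tolerance = 1e-9)
  expect_equal(prob_first_beta_greater(1, 2, 2, 1), 1 / 6, tolerance = 1e-9)
  expect_error(prob_first_beta_greater(-1, 1, 1, 1), "positive")

  shapes <- c(0.7, 1, 2.3, 8)
  for (g1 in shapes) for (g0 in shapes) {
    p <- prob_first_beta_greater(g1, 2, g0, 1.3, method = "adaptive")
    q <- prob_first_beta_greater(g0, 1.3, g1, 2, method = "adaptive")
    expect_lt(abs(p + q - 1), 1e-9)
  }
})

test_that("fixed-node and adaptive quadrature agree, and match Monte Carlo", {
  # integer shapes: the fixed rule is essentially exact
  for (sh in list(c(2, 3, 4, 2), c(1, 1, 4, 4), c(5, 2, 3, 6))) {
    expect_equal(
      prob_first_beta_greater(sh[1], sh[2], sh[3], sh[4], method = "gauss"),
      prob_first_beta_greater(sh[1], sh[2], sh[3], sh[4], method = "adaptive"),
      tolerance = 1e-9)
  }
  # fractional shapes: endpoint behavior limits the fixed rule to ~1e-4
  for (sh in list(c(1.5, 2, 3, 1.2), c(6, 1.2, 2, 9))) {
    expect_equal(
      prob_first_beta_greater(sh[1], sh[2], sh[3], sh[4], method = "gauss"),
      prob_first_beta_greater(sh[1], sh[2], sh[3], sh[4], method = "adaptive"),
      tolerance = 5e-4)
  }
  set.seed(99)
  n <- 2e5
  for (sh in list(c(0.6, 2, 1.5, 0.8), c(3, 5, 2, 2))) {
    mc <- mean(rbeta(n, sh[1], sh[2]) > rbeta(n, sh[3], sh[4]))
    p <- prob_first_beta_greater(sh[1], sh[2], sh[3], sh[4])
    expect_lt(abs(p - mc), 3 * sqrt(p * (1 - p) / n))
  }
})

test_that("relative confidence is signed, symmetric, and antisymmetric", {
  expect_equal(relative_confidence(init_beliefs(), 0), 0, tolerance = 1e-9)
  st <- list(gamma = c(2, 1), epsilon = c(1, 1))
  expect_equal(relative_confidence(st, 0), 1 / 3, tolerance = 1e-9)
  expect_equal(relative_confidence(st, 1), -relative_confidence(st, 0),
               tolerance = 1e-9)
})

test_that("propensities combine value, exploration bonus, and confidence", {
  p00 <- observer_params(1, 0.5, 0.5, 0, 0)
  st <- list(gamma = c(2, 2), epsilon = c(1, 2))
  m <- propensities(st, st, 0, p00)
  expect_equal(m, posterior_mean(st))

  # unchosen Beta(2,2): Q = 0.5, V = 0.05; upsilon = 2 adds 0.1
  pv <- observer_params(1, 0.5, 0.5, 2, 0)
  st_prev <- list(gamma = c(3, 2), epsilon = c(1, 2))
  m2 <- propensities(st_prev, st_prev, 0, pv)
  expect_equal(m2[2], 0.6)

  # kappa = 1 with chosen Beta(2,1) vs unchosen Beta(1,1): C_rel = 1/3
  pk <- observer_params(1, 0.5, 0.5, 0, 1)
  st3 <- list(gamma = c(2, 1), epsilon = c(1, 1))
  m3 <- propensities(st3, st3, 0, pk)
  expect_equal(m3[2], 0.5 + 1 / 12 * 0 + 1 / 3, tolerance = 1e-9)
})

test_that("softmax choice probabilities are normalized, uniform at beta 0, and greedy at large beta", {
  expect_equal(choice_probabilities(c(0.3, 0.3), 5), c(0.5, 0.5))
  expect_equal(choice_probabilities(c(0.9, 0.1), 0), c(0.5, 0.5))
  expect_equal(choice_probabilities(c(0.8, 0.2), 2)[1],
               1 / (1 + exp(-1.2)), tolerance = 1e-12)
  expect_error(choice_probabilities(c(Inf, 0), 1), "finite")

  # greedy limit: mass > 1 - 1e-6 whenever beta * gap exceeds ~ln(1e6)
  for (d in c(0.01, 0.05, 0.3)) {
    pr <- choice_probabilities(c(0.5 + d, 0.5), 2e3)
    expect_gt(pr[1], 1 - 1e-6)
  }

  set.seed(1)
  for (i in 1:50) {
    pr <- choice_probabilities(rnorm(2), runif(1, 0, 20))
    expect_lt(abs(sum(pr) - 1), 1e-12)
  }
})

test_that("the forward recursion reproduces an independently hand-computed 3-trial session", {
  # Frozen oracle: computed step-by-step with arbitrary-precision arithmetic
  # (mpmath) outside this package, before the recursion was implemented.
  sess <- make_session(c(0, 0, 1), c(1, 0, 1))
  lat <- run_observer(sess, observer_params(3, 0.5, 0.5, 1, 1), nodes = 256L)
  tol <- 1e-10
  expect_equal(lat$Q0, c(0.5, 2 / 3, 3 / 7), tolerance = tol)
  expect_equal(lat$Q1, c(0.5, 0.5, 0.5), tolerance = tol)
  expect_equal(lat$V0, c(1 / 12, 1 / 18, 0.054421768707482993), tolerance = tol)
  expect_equal(lat$V1, rep(1 / 12, 3), tolerance = tol)
  expect_equal(lat$Crel, c(0, 1 / 3, 1 / 7), tolerance = tol)
  expect_equal(lat$m0, c(0.5, 2 / 3, 3 / 7), tolerance = tol)
  expect_equal(lat$m1, c(0.5, 0.58333333333333333, 0.91666666666666667),
               tolerance = tol)
  expect_equal(lat$p_choice0, c(0.5, 0.5621765008857981, 0.18781271139172642),
               tolerance = tol)
  expect_equal(lat$p_choice1, 1 - lat$p_choice0, tolerance = tol)
})

test_that("first-trial choice probabilities are chance for any parameters", {
  sess <- make_session(c(1, 0), c(0, 1))
  for (pars in list(observer_params(10, 0.9, 0.2, -3, 5),
                    observer_params(0.1, 0.1, 0.9, 2, -2))) {
    lat <- run_observer(sess, pars)
    expect_equal(c(lat$p_choice0[1], lat$p_choice1[1]), c(0.5, 0.5))
    expect_equal(c(lat$m0[1], lat$m1[1]), c(0.5, 0.5))
  }
})

test_that("with no forgetting or bonuses the chosen-option value is the conjugate posterior mean", {
  set.seed(7)
  choices <- rbinom(40, 1, 0.5)
  rewards <- rbinom(40, 1, 0.6)
  sess <- make_session(choices, rewards)
  lat <- run_observer(sess, observer_params(2, 0, 0, 0, 0))
  g <- c(1, 1); e <- c(1, 1)
  for (t in seq_len(40)) {
    i <- choices[t] + 1L
    expect_equal(lat[[paste0("Q", choices[t])]][t], g[i] / (g[i] + e[i]))
    if (rewards[t] == 1) g[i] <- g[i] + 1 else e[i] <- e[i] + 1
  }
})

test_that("belief parameters stay positive and finite over long random sessions", {
  set.seed(21)
  sess <- make_session(rbinom(10000, 1, 0.5), rbinom(10000, 1, 0.5))
  lat <- run_observer(sess, observer_params(1, runif(1, 0.05, 0.95),
                                            runif(1, 0.05, 0.95), 0.5, 0.5))
  b <- attr(lat, "beliefs")
  expect_true(all(is.finite(b$gamma)) && all(b$gamma > 0))
  expect_true(all(is.finite(b$epsilon)) && all(b$epsilon > 0))
  expect_true(all(b$gamma >= 1) && all(b$epsilon >= 1))
  expect_true(all(abs(lat$p_choice0 + lat$p_choice1 - 1) < 1e-12))
})

test_that("a bandit never chosen again forgets geometrically toward chance", {
  lambda <- 0.3
  choices <- c(1, 1, 1, rep(0, 30))
  rewards <- c(1, 1, 1, rbinom(30, 1, 0.5))
  lat <- run_observer(make_session(choices, rewards),
                      observer_params(2, 0.5, lambda, 0, 0))
  g1 <- attr(lat, "beliefs")$gamma[, 2]
  dev <- abs(g1[5:25] - 1)
  ratio <- dev[-1] / dev[-length(dev)]
  expect_equal(ratio, rep(1 - lambda, length(ratio)), tolerance = 1e-8)
  expect_lt(abs(lat$Q1[30] - 0.5), 1e-3)
})

test_that("missed trials trigger no update and carry propensities forward", {
  sess <- bandit_session(data.frame(
    trial = 1:5, choice = c(0L, NA, NA, 0L, 1L),
    reward = c(1L, NA, NA, 0L, 1L), p0 = 0.5, p1 = 0.5))
  lat <- run_observer(sess, observer_params(3, 0.4, 0.2, 0.5, 0.5))
  b <- attr(lat, "beliefs")
  expect_identical(b$gamma[2, ], b$gamma[3, ])
  expect_identical(b$gamma[3, ], b$gamma[4, ])
  expect_identical(c(lat$m0[2], lat$m1[2]), c(lat$m0[3], lat$m1[3]))
  expect_identical(c(lat$m0[3], lat$m1[3]), c(lat$m0[4], lat$m1[4]))
  expect_true(all(is.na(lat$Crel[2:3])))
})

test_that("run_observer agrees with single-step propensities under both timing modes", {
  sess <- make_session(c(0, 1, 1, 0), c(1, 1, 0, 0))
  for (vt in c("literal", "post_update")) {
    pars <- observer_params(2, 0.4, 0.25, 0.7, -0.4)
    lat <- run_observer(sess, pars, value_timing = vt, nodes = 64L)
    b <- attr(lat, "beliefs")
    st_prev <- list(gamma = b$gamma[2, ], epsilon = b$epsilon[2, ])
    st_new <- list(gamma = b$gamma[3, ], epsilon = b$epsilon[3, ])
    m <- propensities(st_prev, st_new, chosen_prev = 1, pars, value_timing = vt)
    expect_equal(c(lat$m0[3], lat$m1[3]), m, tolerance = 1e-8)
  }
})
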