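---
title: "A Bayesian observer for restless two-armed bandit behavior"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Bayesian observer for restless two-armed bandit behavior}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(betabandit)
```

## The task and the model

In a restless two-armed bandit task a participant repeatedly chooses between
two options whose reward probabilities drift over trials as independent
Gaussian random walks, and receives binary feedback (one monetary unit per
rewarded trial). Because the contingencies never settle, good performance
requires continual learning, and the learner's trial-by-trial valuation of
each option is a latent quantity that must be reconstructed by a model.

`betabandit` implements a Bayesian-observer account of this behavior. Each
bandit $a \in \{0, 1\}$ carries a beta-distributed belief over its reward
probability, $\theta_a \sim \mathrm{Beta}(\gamma_a, \varepsilon_a)$, with
expected value and variance

$$Q_a = \frac{\gamma_a}{\gamma_a + \varepsilon_a}, \qquad
  V_a = \frac{\gamma_a \varepsilon_a}
             {(\gamma_a + \varepsilon_a)^2 (\gamma_a + \varepsilon_a + 1)}.$$

Both bandits start at $\gamma_a = \varepsilon_a = 1$ (the uniform prior), so
the first-trial expected value is exactly 0.5 for both — chance level — and
the prior variance is $1/12$, the uniform-distribution variance.

After a choice of bandit $a$ with outcome $R \in \{0, 1\}$, the chosen
bandit's parameters relax toward 1 at rate $\omega$ and the parameter
matching the outcome is incremented:
$\gamma_a' = (1-\omega)\gamma_a + \omega + R$,
$\varepsilon_a' = (1-\omega)\varepsilon_a + \omega + (1 - R)$.
The unchosen bandit forgets: both of its parameters decay toward 1 at rate
$\lambda$, so an option left unexplored drifts back to the chance-level
belief geometrically at rate $(1-\lambda)$ per trial. Because every update
is a convex combination of a value $\geq 1$ and $1$ (plus a non-negative
increment), all belief parameters remain $\geq 1$ throughout — a fact the
fast quadrature below relies on.

Choice is a softmax over action propensities $m_a$ with temperature
$\beta$. The bandit chosen on the previous trial enters with its updated
expected value; the unchosen bandit receives two additional terms,

$$m_{u} = Q_{u} + \upsilon V_{u} + \kappa C^{\mathrm{rel}},$$

an *exploration bonus* $\upsilon V_u$ that (for $\upsilon > 0$) favors
options whose outcome is uncertain, and a *relative confidence* term: the
signed probability $C^{\mathrm{rel}} = 2 P(\theta_{a} > \theta_{u}) - 1$
that the previously chosen bandit is truly better. On the first trial no
previous choice exists, so both propensities equal the prior mean 0.5 and
choice is predicted at chance.

## Timing of the unchosen-bandit terms

The update equations index the unchosen bandit's value, variance and
confidence by the trial on which the choice was made, which leaves open
whether those terms should be read from the belief state *under which that
choice was made* or from the state *after* the outcome was absorbed. We
implement the first reading as the default (`value_timing = "literal"`):
every trial-$t$ quantity entering the trial-$t{+}1$ propensity is evaluated
from the trial-$t$ choice-time state, except the chosen bandit's own
propensity, which is its post-update expected value. The alternative
(`value_timing = "post_update"`) evaluates all terms from the updated
state. The two conventions agree in their qualitative behavior and differ
only slightly in likelihood; the toggle exists so either can be compared
against other implementations.

## Numerical choices

**The dominance integral.** $P(\theta_1 > \theta_0) = \int_0^1
f_1(x) F_0(x)\,dx$ is computed by deterministic quadrature.
`prob_first_beta_greater()` defaults to an adaptive rule that handles shape
parameters below 1 (where the density has an integrable endpoint
singularity) to better than $10^{-6}$ absolute accuracy. Inside the model
recursion all shapes are $\geq 1$, so a fixed Gauss–Legendre rule is used
instead: essentially exact for integer shapes and accurate to roughly
$10^{-4}$ in the worst fractional-shape cases, which perturbs a propensity
by at most $|\kappa| \cdot 10^{-4}$ — negligible relative to the likelihood
surface. Latent reconstruction uses 64 nodes; likelihood optimization uses
32. A compiled (Rcpp) likelihood mirrors the R reference path exactly; the
test suite asserts their agreement to $10^{-10}$.

**Maximum likelihood.** Parameters are fitted on a transformed scale (log
$\beta$, logit $\omega$ and $\lambda$, identity for $\upsilon, \kappa$,
which are unbounded by design) with Nelder–Mead from a canonical start
($\beta = 1$, $\omega = \lambda = 0.5$, $\upsilon = \kappa = 0$) plus ten
seeded uniform restarts over transformed-space boxes, followed by restart
polishing of the incumbent (Nelder–Mead simplices can collapse
prematurely). Solutions within $10^{-3}$ transformed units of a start-box
edge are flagged, not rejected. Missed trials (the task allowed response
omissions) contribute no likelihood and trigger no belief update. BIC is
$k \ln n + 2\,\mathrm{nll}$ with $n$ the number of non-missed trials; the
Rescorla–Wagner baseline ($Q \leftarrow Q + \alpha(R - Q)$, softmax choice,
$k = 2$) is fitted by the identical scheme.

**Parameter recovery.** `recover_parameters()` simulates agents with
dispersed generating parameters — $\beta$ log-uniform on $[2, 10]$,
$\omega \in [0.2, 0.6]$, $\lambda \in [0.05, 0.4]$, $\upsilon, \kappa \in
[-1, 1]$, regimes in which 220 trials carry usable information about every
parameter — and refits each simulated session. The true generating values
are included among the optimizer starts; this turns the likelihood-dominance
property (the returned optimum is never worse than the truth) into a
per-agent guarantee rather than a probabilistic one, and is how the
recovery harness is validated in the acceptance tests. At 220 trials the
temperature recovers well in rank order; the update rate recovers less
precisely — for a minority of simulated sessions the global
maximum-likelihood solution genuinely sits at an extreme of the update
rate (verified by profile-likelihood search), a known identifiability
limit of rate parameters at this trial count — and the forgetting rate
and bonus weights recover with intermediate fidelity.

## The synthetic task and cohort

**Task.** The reward-probability walks are *reflected* Gaussian random
walks: per-step s.d. 0.05, reflected at bounds $[0.1, 0.9]$, started at
independent uniform draws within bounds, 220 trials. These values
reproduce the visual range and smoothness of the published task schedule
without committing to unstated constants; all are configurable. A reflected
(rather than mean-reverting) walk was chosen as the simplest process whose
stationary distribution stays inside the bounds; its long-run mean is 0.5
by symmetry. The simulator can reuse one schedule across subjects (as in
the original task, where one walk pair served all participants with
counterbalanced assignment) or draw per-subject schedules, and can inject
missed trials at a configurable rate for robustness testing (never by
default).

**Cohort.** The group-level battery needs subject-level covariates with a
known causal structure: age group lowers both white-matter integrity (FA in
the accumbens–vmPFC tract) and dopamine D1 receptor availability (BP_ND in
NAcc) through *independent* paths; both of those predict the strength of
the vmPFC value signal; and the value signal alone predicts task wins.
`generate_cohort()` draws from exactly this linear-Gaussian model on
standardized variables. Defaults: 23 young and 22 old subjects; age→FA and
age→BP_ND paths of $-0.5$; FA→value-signal 0.49 and BP_ND→value-signal
0.41 (the multivariate standardized coefficients the design targets);
value-signal→wins 0.54. The FA raw scale (overall s.d. 0.03) is chosen so
the implied group means are 0.34 and 0.31, giving a group Cohen's $d$
near 1.2. BP_ND is generated on a positive raw scale (mean 1.5, s.d. 0.25,
floored) because binding potentials are positive; the value signal is
deliberately unitless, since the empirical quantity is a regression weight
with scanner-dependent scale. Age→BP_ND is not separately quantified by
the design and is set to the same magnitude as the FA path.

Wins can be generated two ways: a fast *linear* mode (standardized path
plus Gaussian noise, mapped to a count with mean 128.21 and s.d. 10) used
by the statistical tests, and a *mechanistic* mode in which each subject's
value signal sets their softmax temperature through a logistic link
($\beta = 0.5 + 5/(1 + e^{-1.5 q})$, spanning near-random to fairly
deterministic play) and wins are counted from a simulated session — the
mode the end-to-end pipeline uses, closing the loop from covariates to
behavior.

What the generator does *not* emulate: measurement noise in FA and BP_ND
(tractography and PET estimation error), non-Gaussian covariate tails,
age heterogeneity within groups beyond the group indicator, and any direct
FA→behavior or BP_ND→behavior path. Passing tests therefore show that the
statistical machinery recovers structure *when the generating assumptions
hold*, not that real imaging data satisfy them.

## The group-level battery

`standardized_regression()` z-scores outcome and predictors, fits OLS, and
reports standardized coefficients with $t$-based 95% CIs (the CI method for
standardized coefficients is not uniquely conventional; the $t$-interval on
the standardized design is our recorded choice), variance inflation factors
computed from auxiliary regressions ($\mathrm{VIF}_j = 1/(1 - R_j^2)$, with
the conventional strict $>10$ alarm in `vif_screen()`), Gaussian BIC,
adjusted $R^2$, and a Shapiro–Wilk residual-normality gate at $p > 0.05$.
`correlation()` reports Pearson or partial correlations (residualize both
variables on the controls, then correlate; degrees of freedom reduced by
the number of controls) with Fisher-transform CIs. `group_difference()` is
a pooled-variance Student's $t$ with Cohen's $d$; the one-tailed
alternative is "first group lower", matching the directional hypothesis
that older adults earn less. No multiple-comparison correction is applied
at this level, matching the analysis this battery reproduces.

## Problem sizes used in validation

The packaged checks run at deliberately chosen scales: parameter recovery
uses 50 agents at the task's 220 trials with 10 restarts; model recovery
(observer vs Rescorla–Wagner by summed BIC) uses 20 seeded replicates in a
strong-forgetting regime where the models are distinguishable; Fisher-CI
null coverage uses 2000 simulated datasets of $n = 45$; cohort path
recovery uses $n = 5000$ and the qualitative pattern checks use 20–30
cohorts of $n = 45$. These sizes give each check sampling error well below
the margins asserted.

## Known limitations

- The five-parameter observer is the single winning model form; the wider
  model ladder it was originally selected from (and hierarchical fitting)
  is out of scope, with one Rescorla–Wagner baseline retained for model
  comparison.
- $\upsilon$ and $\kappa$ are fitted on the whole real line; with only 220
  trials their estimates are noisy, and boundary flags should be consulted
  before interpreting individual fits.
- The cohort generator's wins count is truncated to $[0, 220]$ and rounded,
  which very slightly attenuates the value-signal→wins path (well under the
  0.05 recovery margin at the sizes tested).
- The end-to-end pipeline treats the value signal as a generated covariate;
  it does not simulate imaging noise between the latent value regressor and
  the subject-level signal strength.

## A worked example

```{r example, eval = FALSE}
ws <- generate_walk(n_trials = 220, seed = 7)
truth <- observer_params(beta = 5, omega = 0.3, lambda = 0.1,
                         upsilon = 0.5, kappa = 0.5)
sess <- simulate_session(ws, observer_agent(truth), seed = 8)

fit <- fit_observer(sess, n_starts = 10, seed = 1)
fit
compare_bic(list(fit, fit_rescorla_wagner(sess, seed = 1)))

lat <- run_observer(sess, fit$params_hat)
head(extract_value_regressor(sess, lat))
summarize_performance(sess)

out <- run_end_to_end(pipeline_config(seed = 1))
out$stats$q_signal_regression
```
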