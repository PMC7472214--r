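#' Pearson or partial correlation with Fisher confidence interval
#'
#' Computes the Pearson correlation of \code{x} and \code{y}, optionally
#' partialled on control covariates by residualizing both variables on the
#' controls (plus an intercept) before correlating. The 95\% CI uses the
#' Fisher z transform with standard error \code{1 / sqrt(n - 3 - k)} and the
#' p-value a t test on \code{n - 2 - k} degrees of freedom, where k is the
#' number of controls.
#'
#' @param x,y Numeric vectors of equal length.
#' @param control Optional numeric vector/matrix of control covariates.
#' @param conf_level Confidence level (default 0.95).
#' @return A \code{correlation_report}: list with \code{r}, \code{df},
#'   \code{p}, \code{ci95}, \code{n}, \code{partial_on}.
#' @examples
#' with(cars, correlation(speed, dist))
#' @export
correlation <- function(x, y, control = NULL, conf_level = 0.95) {
  stopifnot(length(x) == length(y))
  ok <- stats::complete.cases(x, y, control)
  x <- x[ok]; y <- y[ok]
  k <- 0L
  partial_on <- character(0)
  if (!is.null(control)) {
    control <- as.matrix(control)[ok, , drop = FALSE]
    k <- ncol(control)
    partial_on <- colnames(control) %||% paste0("c", seq_len(k))
    X <- cbind(1, control)
    x <- stats::lm.fit(X, x)$residuals
    y <- stats::lm.fit(X, y)$residuals
  }
  n <- length(x)
  if (n < 4L + k) stop_domain("need at least ", 4L + k, " complete cases")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop_domain("correlation undefined for constant input")
  }
  r <- stats::cor(x, y)
  df <- n - 2L - k
  tval <- r * sqrt(df / max(1 - r^2, 1e-300))
  p <- 2 * stats::pt(-abs(tval), df)
  z <- atanh(min(max(r, -1 + 1e-15), 1 - 1e-15))
  se <- 1 / sqrt(n - 3 - k)
  qz <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci <- tanh(c(z - qz * se, z + qz * se))
  structure(list(r = r, df = df, p = p, ci95 = ci, n = n,
                 partial_on = partial_on),
            class = "correlation_report")
}

#' @export
print.correlation_report <- function(x, ...) {
  lab <- if (length(x$partial_on)) {
    sprintf("partial r (controlling %s)", paste(x$partial_on, collapse = ", "))
  } else "r"
  cat(sprintf("%s(%d) = %.3f, p = %.4g, 95%% CI [%.3f, %.3f]\n",
              lab, x$df, x$r, x$p, x$ci95[1], x$ci95[2]))
  invisible(x)
}

#' Standardized multiple regression with collinearity diagnostics
#'
#' z-scores the outcome and every predictor, fits ordinary least squares,
#' and reports standardized coefficients with t-based 95\% CIs, variance
#' inflation factors from auxiliary regressions
#' (\code{VIF_j = 1 / (1 - R2_j)} with \code{R2_j} from regressing predictor
#' j on the others), the Gaussian-likelihood BIC, adjusted R-squared, and a
#' Shapiro-Wilk test of residual normality (residuals considered normal at
#' p > 0.05).
#'
#' @param outcome Numeric outcome vector.
#' @param predictors Named numeric matrix or data.frame of predictors.
#' @param conf_level Confidence level for coefficient CIs.
#' @return A \code{regression_report}: list with a \code{coefficients}
#'   data.frame (\code{predictor}, \code{estimate}, \code{ci_lo},
#'   \code{ci_hi}, \code{p}, \code{vif}), plus \code{bic}, \code{adj_r2},
#'   \code{shapiro_p}, \code{normality_ok}, \code{n}, \code{k},
#'   \code{outcome}.
#' @export
standardized_regression <- function(outcome, predictors, conf_level = 0.95) {
  X <- as.matrix(as.data.frame(predictors))
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  stopifnot(length(outcome) == nrow(X))
  ok <- stats::complete.cases(outcome, X)
  y <- outcome[ok]; X <- X[ok, , drop = FALSE]
  n <- nrow(X); k <- ncol(X)
  if (n <= k + 1L) stop_domain("need n > k + 1 observations")
  sds <- apply(X, 2, stats::sd)
  if (stats::sd(y) == 0) stop_domain("outcome is constant")
  if (any(sds == 0)) {
    stop_domain("constant predictor column(s): ",
                paste(colnames(X)[sds == 0], collapse = ", "))
  }
  Xz <- scale(X)
  yz <- as.numeric(scale(y))
  qrX <- qr(cbind(Intercept = 1, Xz))
  if (qrX$rank < k + 1L) {
    dep <- qrX$pivot[seq.int(qrX$rank + 1L, k + 1L)] - 1L
    stop_domain("collinear (rank-deficient) predictors: ",
                paste(colnames(X)[dep], collapse = ", "))
  }
  dat <- data.frame(.y = yz, Xz)
  names(dat) <- c(".y", colnames(X))
  fit <- stats::lm(.y ~ ., data = dat)
  sm <- summary(fit)
  ci <- stats::confint(fit, level = conf_level)

  vif <- vapply(seq_len(k), function(j) {
    if (k == 1L) return(1)
    rss <- sum(stats::lm.fit(cbind(1, Xz[, -j, drop = FALSE]),
                             Xz[, j])$residuals^2)
    r2j <- 1 - rss / (n - 1)          # standardized columns: TSS = n - 1
    1 / max(1 - r2j, 1e-300)
  }, numeric(1))

  sw <- stats::shapiro.test(stats::residuals(fit))
  coefs <- data.frame(
    predictor = colnames(X),
    estimate = unname(stats::coef(fit)[-1]),
    ci_lo = unname(ci[-1, 1]),
    ci_hi = unname(ci[-1, 2]),
    p = unname(sm$coefficients[-1, 4]),
    vif = vif
  )
  structure(list(outcome = deparse(substitute(outcome)), coefficients = coefs,
                 bic = stats::BIC(fit), adj_r2 = sm$adj.r.squared,
                 shapiro_p = sw$p.value, normality_ok = sw$p.value > 0.05,
                 n = n, k = k),
            class = "regression_report")
}

#' @export
print.regression_report <- function(x, ...) {
  cat(sprintf("Standardized regression (n = %d, k = %d)\n", x$n, x$k))
  print(transform(x$coefficients,
                  estimate = round(estimate, 3), ci_lo = round(ci_lo, 3),
                  ci_hi = round(ci_hi, 3), p = signif(p, 3),
                  vif = round(vif, 2)), row.names = FALSE)
  cat(sprintf("BIC = %.2f, adjusted R2 = %.3f, Shapiro-Wilk p = %.3f (%s)\n",
              x$bic, x$adj_r2, x$shapiro_p,
              if (x$normality_ok) "residuals normal" else "non-normal residuals"))
  invisible(x)
}

#' Flag predictors with inflated variance
#'
#' Applies the conventional multicollinearity alarm: a predictor is flagged
#' when its VIF strictly exceeds the threshold (default 10).
#'
#' @param report A \code{regression_report}.
#' @param threshold VIF alarm threshold.
#' @return Named logical vector, one entry per predictor.
#' @export
vif_screen <- function(report, threshold = 10) {
  stopifnot(inherits(report, "regression_report"))
  stats::setNames(report$coefficients$vif > threshold,
                  report$coefficients$predictor)
}

#' Two-group comparison with Cohen's d
#'
#' Student's t test with pooled variance, one- or two-tailed (the one-tailed
#' alternative is \code{mean(a) < mean(b)}; pass the group hypothesized to
#' be lower as \code{a}). Cohen's d uses the pooled standard deviation with
#' a normal-approximation 95\% CI.
#'
#' @param a,b Numeric vectors (each n >= 2).
#' @param tail \code{"two"} or \code{"one"}.
#' @return List with \code{t}, \code{df}, \code{p}, \code{cohens_d},
#'   \code{d_ci95}, \code{mean_a}, \code{mean_b}.
#' @export
group_difference <- function(a, b, tail = c("two", "one")) {
  tail <- match.arg(tail)
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  n1 <- length(a); n2 <- length(b)
  stopifnot(n1 >= 2L, n2 >= 2L)
  sp2 <- ((n1 - 1) * stats::var(a) + (n2 - 1) * stats::var(b)) / (n1 + n2 - 2)
  if (sp2 <= 0) stop_domain("zero pooled variance; groups are degenerate")
  tt <- stats::t.test(a, b, var.equal = TRUE,
                      alternative = if (tail == "one") "less" else "two.sided")
  d <- (mean(a) - mean(b)) / sqrt(sp2)
  se_d <- sqrt((n1 + n2) / (n1 * n2) + d^2 / (2 * (n1 + n2 - 2)))
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, cohens_d = d,
       d_ci95 = d + c(-1, 1) * stats::qnorm(0.975) * se_d,
       mean_a = mean(a), mean_b = mean(b))
}

#' Rank regression models by BIC
#'
#' @param reports Named list of \code{regression_report} objects fitted to
#'   the same outcome and observations.
#' @return data.frame sorted ascending by BIC with \code{delta_bic} and
#'   adjusted R-squared columns.
#' @export
compare_models_bic <- function(reports) {
  stopifnot(length(reports) >= 1L,
            all(vapply(reports, inherits, TRUE, "regression_report")))
  ns <- vapply(reports, `[[`, 0L, "n")
  if (length(unique(ns)) != 1L) {
    stop_domain("models were fitted on different numbers of observations")
  }
  nm <- names(reports) %||% paste0("model", seq_along(reports))
  tab <- data.frame(
    model = nm,
    k = vapply(reports, `[[`, 0L, "k"),
    bic = vapply(reports, `[[`, 0, "bic"),
    adj_r2 = vapply(reports, `[[`, 0, "adj_r2")
  )
  tab <- tab[order(tab$bic), , drop = FALSE]
  tab$delta_bic <- tab$bic - tab$bic[1]
  rownames(tab) <- NULL
  tab
}
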