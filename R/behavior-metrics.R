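#' Summarize task performance for one session
#'
#' Computes the performance measures used at the group level: \code{wins},
#' the number of rewarded trials (equal to the monetary units earned at one
#' unit per reward); \code{pct_optimal_choice}, the fraction of non-missed
#' trials on which the chosen bandit had the (weakly) higher true reward
#' probability; and \code{pct_optimal_switch}, the fraction of switch trials
#' that moved to the objectively better bandit. A switch trial is a
#' non-missed trial whose choice differs from the previous non-missed
#' choice; it is optimal if the new bandit's true probability is greater
#' than or equal to the other's at that trial. Ties count as optimal.
#'
#' @param session A \code{bandit_session} with true probabilities present.
#' @return A one-row data.frame: \code{subject_id}, \code{wins},
#'   \code{pct_optimal_choice}, \code{pct_optimal_switch} (NA when no
#'   switches occurred), \code{n_missed}.
#' @export
summarize_performance <- function(session) {
  if (!inherits(session, "bandit_session")) session <- bandit_session(session)
  if (anyNA(session$p0) || anyNA(session$p1)) {
    stop_domain("true reward probabilities are required to score optimality")
  }
  ok <- !is.na(session$choice)
  choice <- session$choice[ok]
  p <- cbind(session$p0, session$p1)[ok, , drop = FALSE]
  chosen_p <- p[cbind(seq_along(choice), choice + 1L)]
  other_p <- p[cbind(seq_along(choice), 2L - choice)]
  optimal <- chosen_p >= other_p

  switches <- which(diff(choice) != 0) + 1L   # indices within non-missed trials
  pct_switch <- if (length(switches)) mean(optimal[switches]) else NA_real_

  data.frame(
    subject_id = attr(session, "subject_id") %||% "s1",
    wins = sum(session$reward[ok]),
    pct_optimal_choice = mean(optimal),
    pct_optimal_switch = pct_switch,
    n_missed = sum(!ok)
  )
}

#' Trial-by-trial value regressor (Q of the chosen option)
#'
#' Extracts the expected value of the chosen option at choice time on each
#' non-missed trial — the parametric modulator used to localize value
#' anticipation. The first trial's value is always 0.5 (chance-level prior).
#'
#' @param session A \code{bandit_session}.
#' @param latents The \code{observer_latents} from \code{\link{run_observer}}
#'   on the same session.
#' @return data.frame with \code{trial} and \code{q_chosen}, one row per
#'   non-missed trial; values strictly inside (0, 1).
#' @export
extract_value_regressor <- function(session, latents) {
  if (!inherits(session, "bandit_session")) session <- bandit_session(session)
  if (nrow(latents) != nrow(session)) {
    stop_domain("latents and session have different lengths: ",
                nrow(latents), " vs ", nrow(session))
  }
  ok <- !is.na(session$choice)
  q <- ifelse(session$choice[ok] == 0L, latents$Q0[ok], latents$Q1[ok])
  data.frame(trial = session$trial[ok], q_chosen = q)
}
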