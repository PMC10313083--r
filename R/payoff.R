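# Long-term payoffs and cooperation levels of a strategy pair under
# implementation error, via the stationary distribution of the pair
# Markov chain.

check_game_params <- function(b, e, require_positive_e = TRUE) {
  stopifnot(is.numeric(b), length(b) == 1L, is.numeric(e), length(e) == 1L)
  if (b <= 1) stop("benefit b must exceed the cost of cooperation (b > 1)")
  if (e < 0 || e >= 0.5) stop("error rate e must satisfy 0 <= e < 0.5")
  if (require_positive_e && e <= 0)
    stop("the stationary distribution is unique only for e > 0")
  invisible(NULL)
}

#' Effective strategy under implementation error
#'
#' With probability e the intended action is flipped, so a player with
#' deterministic prescriptions p effectively cooperates with probability
#' (1 - e) p + e (1 - p) at each history profile.
#'
#' @param s an [ipd_strategy()].
#' @param e implementation-error probability in [0, 1).
#' @return numeric vector of per-profile cooperation probabilities.
#' @export
effective_strategy <- function(s, e) {
  s <- ipd_strategy(s)
  stopifnot(is.numeric(e), length(e) == 1L, e >= 0, e < 1)
  (1 - e) * s$table + e * (1 - s$table)
}

#' Transition matrix of the pair Markov chain
#'
#' Both strategies are lifted to the common capacity
#' \code{max(1, m_cap(p), m_cap(q))}; the chain state is the joint
#' full-memory history profile.  An entry is nonzero only when the
#' target's older history equals the source's history shifted by one
#' round, and then equals the product of the two players' effective
#' cooperation/defection probabilities (the co-player reads the
#' index-swapped profile).
#'
#' @param p,q strategies.
#' @param e implementation-error probability.
#' @return a row-stochastic square matrix of dimension 2^(2 m*).
#' @export
transition_matrix <- function(p, q, e) {
  p <- ipd_strategy(p); q <- ipd_strategy(q)
  stopifnot(is.numeric(e), length(e) == 1L, e >= 0, e < 1)
  transition_matrix_cpp(p$table, q$table, e)
}

#' Stationary payoffs and cooperation levels of a strategy pair
#'
#' Solves v T = v, sum(v) = 1 for the unique stationary distribution of
#' the pair chain (guaranteed by Perron-Frobenius for e > 0), and reads
#' off the cooperation levels gamma_pq (probability that p's most recent
#' action is C) and gamma_qp.  Long-term payoffs follow as
#' \code{pi_pq = b * gamma_qp - gamma_pq} (the donation game has unit
#' cost).
#'
#' @param p,q strategies.
#' @param b benefit of cooperation (> 1).
#' @param e implementation-error probability (0 < e < 0.5).
#' @return a list with \code{gamma_pq}, \code{gamma_qp}, \code{pi_pq},
#'   \code{pi_qp} and the stationary distribution \code{v}.
#' @examples
#' pair_payoff("WSLS", "WSLS", b = 3, e = 1e-4)$gamma_pq  # > 0.99
#' @export
pair_payoff <- function(p, q, b, e) {
  check_game_params(b, e)
  p <- ipd_strategy(p); q <- ipd_strategy(q)
  st <- pair_stationary_cpp(p$table, q$table, e)
  list(gamma_pq = st$gamma_pq,
       gamma_qp = st$gamma_qp,
       pi_pq = b * st$gamma_qp - st$gamma_pq,
       pi_qp = b * st$gamma_pq - st$gamma_qp,
       v = st$v)
}

#' The four payoffs entering the fixation probability
#'
#' @param p,q strategies.
#' @inheritParams pair_payoff
#' @return named numeric vector \code{(pi_pp, pi_pq, pi_qp, pi_qq)}.
#' @export
payoff_entries <- function(p, q, b, e) {
  check_game_params(b, e)
  p <- ipd_strategy(p); q <- ipd_strategy(q)
  self_p <- pair_payoff(p, p, b, e)
  self_q <- pair_payoff(q, q, b, e)
  cross <- pair_payoff(p, q, b, e)
  c(pi_pp = self_p$pi_pq, pi_pq = cross$pi_pq,
    pi_qp = cross$pi_qp, pi_qq = self_q$pi_pq)
}

#' Self-cooperation level gamma_pp
#'
#' @param s a strategy.
#' @param e implementation-error probability.
#' @export
self_cooperation <- function(s, e) {
  s <- ipd_strategy(s)
  stopifnot(e > 0, e < 0.5)
  pair_stationary_cpp(s$table, s$table, e)$gamma_pq
}
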